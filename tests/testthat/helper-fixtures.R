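# Shared fixtures and independent oracles for the test suite.

# memoized small simulated dataset reused across test files
.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- simulate_family(sim_config(seed = 101, n_species = 4))
  }
  .fixture_env$small
}

# screening + typing on the small dataset, computed once
small_screened <- function() {
  if (is.null(.fixture_env$small_screened)) {
    ds <- small_sim()
    con1 <- extract_con1_all(ds$proteins)
    res <- filter_candidates(ds$proteins, ds$domain_hits, con1)
    acc <- ds$proteins[res$accepted, , drop = FALSE]
    tab <- architecture_table(acc, ds$domain_hits, con1)
    .fixture_env$small_screened <- list(
      ds = ds, con1 = con1, screen = res, accepted = acc, arch = tab,
      types = setNames(tab$type_label, tab$protein_id))
  }
  .fixture_env$small_screened
}

write_fasta_tmp <- function(entries) {
  path <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(entries), function(h) {
    c(paste0(">", h), entries[[h]])
  })), path)
  path
}

# --- independent oracle: brute-force minimal-span motif triple ------------
# enumerates every ordered non-overlapping (start, middle, end) triple over
# the scan hits and selects min span, then leftmost start/middle/end
brute_force_con1 <- function(seq, patterns = con1_patterns()) {
  hits <- scan_motifs(seq, patterns)
  role <- setNames(patterns$role, patterns$motif_name)
  hs <- hits[role[hits$motif_name] == "start", , drop = FALSE]
  hm <- hits[role[hits$motif_name] == "middle", , drop = FALSE]
  he <- hits[role[hits$motif_name] == "end", , drop = FALSE]
  if (!nrow(hs) || !nrow(hm) || !nrow(he)) return(NULL)
  g <- expand.grid(i = seq_len(nrow(hs)), j = seq_len(nrow(hm)),
                   k = seq_len(nrow(he)))
  ok <- hm$start[g$j] >= hs$end[g$i] & he$start[g$k] >= hm$end[g$j]
  g <- g[ok, , drop = FALSE]
  if (!nrow(g)) return(NULL)
  g$span <- he$end[g$k] - hs$start[g$i]
  g <- g[order(g$span, hs$start[g$i], hm$start[g$j], he$start[g$k]), ,
         drop = FALSE]
  c(start = hs$start[g$i[1]], end = he$end[g$k[1]])
}

# random sequence with planted motif instances at random positions
random_motif_layout <- function(len = 400, n_each = 2) {
  aa_bg <- setdiff(c("A","C","D","F","G","H","I","K","M","N","P","S","T","V"),
                   character(0))  # background without Q/E/Y/R/W/L/D triggers
  s <- sample(aa_bg, len, replace = TRUE)
  inst <- list(
    QxxEY = function() c("Q", sample(aa_bg, 2, TRUE), "E", "Y"),
    EDRxL = function() c("E", "D", "R", sample(aa_bg, 1), "L"),
    QxRRW = function() c("Q", sample(aa_bg, 1), "R", "R", "W"))
  for (m in names(inst)) {
    for (r in seq_len(n_each)) {
      pos <- sample.int(len - 5L, 1)
      s[pos:(pos + 4L)] <- inst[[m]]()
    }
  }
  paste(s, collapse = "")
}

# --- independent oracle: topology from the four-point condition -----------
# the unique unrooted topology an additive matrix fits, found by checking
# every nontrivial split of every enumerable topology (n <= 6)
tree_splits_of <- function(tree) {
  tips <- sort(tree$tip.label)
  pp <- ape::prop.part(tree)
  keys <- vapply(pp, function(idx) {
    leaves <- tree$tip.label[idx]
    if (tips[1] %in% leaves) leaves <- setdiff(tips, leaves)
    paste(sort(leaves), collapse = "|")
  }, "")
  sort(unique(keys[nzchar(keys) &
                     vapply(strsplit(keys, "|", fixed = TRUE), length, 1L) >= 2 &
                     vapply(strsplit(keys, "|", fixed = TRUE), length, 1L) <= length(tips) - 2]))
}

split_fits_fourpoint <- function(side, other, D) {
  for (a in side) for (b in side[side > a]) {
    for (c_ in other) for (d_ in other[other > c_]) {
      s1 <- D[a, b] + D[c_, d_]
      s2 <- D[a, c_] + D[b, d_]
      s3 <- D[a, d_] + D[b, c_]
      if (!(s1 < s2 - 1e-9 && s1 < s3 - 1e-9 && abs(s2 - s3) < 1e-9)) {
        return(FALSE)
      }
    }
  }
  TRUE
}

brute_force_topology_splits <- function(D) {
  ids <- rownames(D)
  n <- length(ids)
  all_topos <- phangorn::allTrees(n, rooted = FALSE, tip.label = ids)
  fits <- Filter(function(t) {
    all(vapply(tree_splits_of(t), function(key) {
      side <- strsplit(key, "|", fixed = TRUE)[[1]]
      split_fits_fourpoint(side, setdiff(ids, side), D)
    }, TRUE))
  }, all_topos)
  stopifnot(length(fits) == 1)  # additive matrices fit exactly one topology
  tree_splits_of(fits[[1]])
}

# random additive distance matrix from a random binary tree
random_additive_case <- function(n, seed) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n, br = NULL))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.2, 1.5)
  D <- ape::cophenetic.phylo(tr)
  D <- D[sort(rownames(D)), sort(rownames(D))]
  list(tree = tr, D = D)
}
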