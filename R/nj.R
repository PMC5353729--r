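# Neighbor-joining (Saitou-Nei) with deterministic tie-breaking and
# column-resampling bootstrap.

canonical_split <- function(leaves, all_leaves) {
  # canonical side of a bipartition: the side NOT containing the
  # alphabetically first leaf
  first <- min(all_leaves)
  if (first %in% leaves) leaves <- setdiff(all_leaves, leaves)
  paste(sort(leaves), collapse = "|")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# core agglomeration: returns the Newick string and the canonical splits of
# all internal edges
nj_core <- function(D) {
  labels <- rownames(D)
  n0 <- length(labels)
  if (n0 < 3) stop("neighbor joining needs at least 3 taxa")
  frag <- labels
  leafset <- as.list(labels)
  minlab <- labels  # smallest leaf name per cluster, for tie order
  splits <- character(0)
  Dm <- unname(D)
  while (length(frag) > 3) {
    n <- length(frag)
    R <- rowSums(Dm)
    Q <- (n - 2) * Dm - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ord <- order(pmin(minlab[cand[, 1]], minlab[cand[, 2]]),
                 pmax(minlab[cand[, 1]], minlab[cand[, 2]]))
    i <- cand[ord[1], 1]; j <- cand[ord[1], 2]
    dij <- Dm[i, j]
    vi <- 0.5 * dij + (R[i] - R[j]) / (2 * (n - 2))
    vj <- dij - vi
    # clamp negative branch lengths, deficit to the sister branch
    if (vi < 0) { vi <- 0; vj <- dij }
    if (vj < 0) { vj <- 0; vi <- dij }
    newfrag <- sprintf("(%s:%.12g,%s:%.12g)", frag[i], vi, frag[j], vj)
    newset <- sort(c(leafset[[i]], leafset[[j]]))
    newd <- pmax(0.5 * (Dm[i, ] + Dm[j, ] - dij), 0)
    keep <- setdiff(seq_len(n), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], newd[keep]),
                c(newd[keep], 0))
    frag <- c(frag[keep], newfrag)
    leafset <- c(leafset[keep], list(newset))
    minlab <- c(minlab[keep], min(newset))
    if (length(newset) >= 2 && length(newset) <= n0 - 2) {
      splits <- c(splits, canonical_split(newset, labels))
    }
  }
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  v1 <- max(0, 0.5 * (d12 + d13 - d23))
  v2 <- max(0, 0.5 * (d12 + d23 - d13))
  v3 <- max(0, 0.5 * (d13 + d23 - d12))
  newick <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                    frag[1], v1, frag[2], v2, frag[3], v3)
  list(newick = newick, splits = unique(splits))
}

#' Build a neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration on a distance matrix. Negative branch
#' lengths are clamped to zero with the deficit transferred to the sister
#' branch; equal minimal Q values are broken by lexicographic order of the
#' joined clusters' smallest leaf names, so the result is deterministic.
#'
#' @param D Symmetric distance matrix with ids as dimnames (>= 3 taxa).
#' @return An unrooted `phylo` tree.
#' @export
build_nj_tree <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (is.null(rownames(D))) stop("distance matrix needs dimnames")
  if (!isSymmetric(unname(D))) stop("distance matrix must be symmetric")
  core <- nj_core(D)
  tr <- ape::read.tree(text = core$newick)
  attr(tr, "splits") <- core$splits
  tr
}

tree_split_keys <- function(tree) {
  pp <- ape::prop.part(tree)
  tips <- tree$tip.label
  vapply(pp, function(idx) canonical_split(tips[idx], tips), "")
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement `n_reps` times; an NJ
#' tree is built per replicate and each internal edge of the point-estimate
#' tree is annotated with the percentage of replicates containing the same
#' bipartition. Reproducible for a fixed seed.
#'
#' @param x An alignment matrix (or CON1 regions, aligned first).
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed for column resampling.
#' @param site_rule,coverage,correction Passed to [compute_distances()].
#' @return The point-estimate `phylo` tree with `node.label` holding
#'   supports in \[0, 100\] (`NA` at the root node). Attributes
#'   `split_support` (named percentages for the tree's internal edges),
#'   `split_counts` (replicate counts for every observed bipartition) and
#'   `n_reps` support downstream placement.
#' @export
bootstrap_support <- function(x, n_reps = 100, seed = 1,
                              site_rule = "pairwise_deletion",
                              coverage = 0.95, correction = "p") {
  stopifnot(n_reps >= 1)
  aln <- if (is.matrix(x)) x else align_con1(x)
  D <- compute_distances(aln, site_rule = site_rule, coverage = coverage,
                         correction = correction)
  tree <- build_nj_tree(D)
  L <- ncol(aln)
  counts <- new.env(parent = emptyenv())
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      idx <- sample.int(L, L, replace = TRUE)
      Dr <- compute_distances(aln[, idx, drop = FALSE], site_rule = site_rule,
                              coverage = coverage, correction = correction)
      for (s in nj_core(Dr)$splits) {
        counts[[s]] <- (if (is.null(counts[[s]])) 0L else counts[[s]]) + 1L
      }
    }
  })
  count_of <- function(s) {
    if (!nzchar(s) || is.null(counts[[s]])) 0L else counts[[s]]
  }
  keys <- tree_split_keys(tree)
  support <- vapply(keys, function(k) 100 * count_of(k) / n_reps, 0)
  support[1] <- NA_real_  # root of the displayed (trifurcating) tree
  tree$node.label <- as.character(round(support, 1))
  tree$node.label[is.na(support)] <- ""
  all_counts <- unlist(as.list(counts))
  if (is.null(all_counts)) all_counts <- integer(0)
  attr(tree, "split_support") <- setNames(support, keys)
  attr(tree, "split_counts") <- all_counts
  attr(tree, "n_reps") <- n_reps
  tree
}
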