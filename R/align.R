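# Progressive multiple alignment of CON1 regions.
#
# Pairwise/profile global alignment (Needleman-Wunsch, affine gaps, BLOSUM62
# column scores) merged along a k-mer distance guide tree. This is a
# deliberately small deterministic aligner: CON1 regions are short and
# largely indel-free, so a full MUSCLE-style iterative refiner is not
# needed; externally computed alignments can be imported instead
# (see read_alignment()).

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[AA_VALID, AA_VALID]
    }
    cache
  }
})

as_seq_vector <- function(x) {
  if (is.matrix(x)) return(setNames(apply(x, 1, paste, collapse = ""), rownames(x)))
  if (is.data.frame(x)) return(setNames(x$sequence, x$protein_id))
  if (is.list(x) && !is.null(x[[1]]$sequence)) {
    return(setNames(vapply(x, function(r) r$sequence, ""),
                    vapply(x, function(r) r$protein_id, "")))
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  stop("cannot interpret sequences input")
}

seq_to_matrix <- function(seqs) {
  if (length(unique(nchar(seqs))) != 1) stop("rows of unequal length")
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(seqs)
  m
}

# column frequency profile over AA_VALID (gaps contribute nothing)
profile_freq <- function(mat) {
  n <- nrow(mat)
  f <- matrix(0, ncol(mat), length(AA_VALID),
              dimnames = list(NULL, AA_VALID))
  for (a in AA_VALID) f[, a] <- colSums(mat == a) / n
  f
}

# global profile-profile alignment; returns list(a_idx, b_idx) of aligned
# column indices (0 = gap)
profile_align <- function(A, B, gap_open = -10, gap_extend = -1) {
  S <- profile_freq(A) %*% blosum62_matrix() %*% t(profile_freq(B))
  la <- nrow(S); lb <- ncol(S)
  NEG <- -1e18
  M <- matrix(NEG, la + 1, lb + 1)
  X <- matrix(NEG, la + 1, lb + 1)  # gap in B (consumes A)
  Y <- matrix(NEG, la + 1, lb + 1)  # gap in A (consumes B)
  M[1, 1] <- 0
  for (i in seq_len(la) + 1)
    X[i, 1] <- gap_open + (i - 2) * gap_extend
  for (j in seq_len(lb) + 1)
    Y[1, j] <- gap_open + (j - 2) * gap_extend
  for (i in seq_len(la) + 1) {
    for (j in seq_len(lb) + 1) {
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
        S[i - 1, j - 1]
      X[i, j] <- max(M[i - 1, j] + gap_open, X[i - 1, j] + gap_extend,
                     X[i, j])
      Y[i, j] <- max(M[i, j - 1] + gap_open, Y[i, j - 1] + gap_extend,
                     Y[i, j])
    }
  }
  # traceback, deterministic preference: match > gap-in-B > gap-in-A
  i <- la + 1; j <- lb + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  a_idx <- integer(0); b_idx <- integer(0)
  while (i > 1 || j > 1) {
    if (state == 1 && i > 1 && j > 1) {
      a_idx <- c(i - 1, a_idx); b_idx <- c(j - 1, b_idx)
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      i <- i - 1; j <- j - 1
      state <- which.max(prev)
    } else if ((state == 2 && i > 1) || (j == 1 && i > 1)) {
      a_idx <- c(i - 1, a_idx); b_idx <- c(0, b_idx)
      from_open <- M[i - 1, j] + gap_open
      from_ext <- X[i - 1, j] + gap_extend
      i <- i - 1
      state <- if (from_open >= from_ext) 1 else 2
    } else {
      a_idx <- c(0, a_idx); b_idx <- c(j - 1, b_idx)
      from_open <- M[i, j - 1] + gap_open
      from_ext <- Y[i, j - 1] + gap_extend
      j <- j - 1
      state <- if (from_open >= from_ext) 1 else 3
    }
  }
  list(a_idx = a_idx, b_idx = b_idx)
}

expand_profile <- function(mat, idx) {
  out <- matrix("-", nrow(mat), length(idx), dimnames = list(rownames(mat), NULL))
  out[, idx != 0] <- mat[, idx[idx != 0], drop = FALSE]
  out
}

# k-mer (k=3) distance for the guide tree
kmer_distance <- function(seqs, k = 3) {
  km <- lapply(seqs, function(s) {
    if (nchar(s) < k) return(s)
    unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
  })
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- length(intersect(km[[i]], km[[j]]))
    D[i, j] <- D[j, i] <- 1 - shared / max(1L, min(length(km[[i]]),
                                                   length(km[[j]])))
  }
  D
}

#' Align CON1 regions progressively
#'
#' @param regions CON1 regions: output of [extract_con1_all()] (NULL entries
#'   dropped), a `con1_table()` data.frame, or a named character vector of
#'   sequences.
#' @param guide Optional guide tree (`phylo`); by default an average-linkage
#'   guide is built from 3-mer distances.
#' @param gap_open,gap_extend Affine gap penalties (negative).
#' @return A character matrix (rows = sequences, one residue or `-` per
#'   cell) with sequence ids as rownames.
#' @export
align_con1 <- function(regions, guide = NULL, gap_open = -10,
                       gap_extend = -1) {
  if (is.list(regions) && !is.data.frame(regions)) {
    regions <- regions[!vapply(regions, is.null, TRUE)]
  }
  seqs <- as_seq_vector(regions)
  if (length(seqs) < 2) stop("alignment needs at least 2 sequences")
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  n <- length(seqs)
  profiles <- lapply(seqs, function(s) {
    m <- matrix(strsplit(s, "")[[1]], 1)
    m
  })
  for (i in seq_len(n)) rownames(profiles[[i]]) <- names(seqs)[i]

  merge_order <- if (is.null(guide)) {
    hc <- stats::hclust(stats::as.dist(kmer_distance(seqs)), method = "average")
    hc$merge
  } else {
    guide_merge_order(guide, names(seqs))
  }
  clusters <- vector("list", nrow(merge_order))
  get_prof <- function(ref) if (ref < 0) profiles[[-ref]] else clusters[[ref]]
  for (m in seq_len(nrow(merge_order))) {
    A <- get_prof(merge_order[m, 1])
    B <- get_prof(merge_order[m, 2])
    tb <- profile_align(A, B, gap_open, gap_extend)
    clusters[[m]] <- rbind(expand_profile(A, tb$a_idx),
                           expand_profile(B, tb$b_idx))
  }
  aln <- clusters[[nrow(merge_order)]]
  aln <- aln[names(seqs), , drop = FALSE]  # stable input order
  stopifnot(identical(gsub("-", "", apply(aln, 1, paste, collapse = "")),
                      setNames(unname(seqs), rownames(aln))))
  aln
}

# convert a rooted guide phylo into an hclust-style merge matrix
guide_merge_order <- function(tree, ids) {
  if (!all(sort(tree$tip.label) == sort(ids)))
    stop("guide tree leaves must match sequence ids")
  merges <- matrix(0L, 0, 2)
  cluster_of <- list()  # internal node -> merge row index
  tip_idx <- match(tree$tip.label, ids)
  node_ref <- function(node) {
    if (node <= length(tree$tip.label)) -tip_idx[node] else cluster_of[[as.character(node)]]
  }
  internal <- sort(unique(tree$edge[, 1]), decreasing = TRUE)
  for (node in internal) {
    children <- tree$edge[tree$edge[, 1] == node, 2]
    ref <- node_ref(children[1])
    for (ch in children[-1]) {
      merges <- rbind(merges, c(ref, node_ref(ch)))
      ref <- nrow(merges)
    }
    cluster_of[[as.character(node)]] <- nrow(merges)
  }
  merges
}

#' Read / write alignments in aligned-FASTA
#' @param path FASTA path.
#' @return Character matrix as from [align_con1()].
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- setNames(toupper(as.character(set)),
                   vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L))
  seq_to_matrix(seqs)
}

#' @rdname read_alignment
#' @param aln Alignment matrix.
#' @export
write_alignment <- function(aln, path) {
  seqs <- apply(aln, 1, paste, collapse = "")
  set <- Biostrings::AAStringSet(setNames(seqs, rownames(aln)))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
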