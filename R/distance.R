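# Pairwise distances from an alignment.
#
# p-distance = mismatches / compared sites, computed over sites where both
# rows carry a residue (gaps and X are treated as missing). "Partial
# deletion" first drops alignment columns below a residue-occupancy
# threshold (MEGA's convention, default 95%); "pairwise deletion" keeps all
# columns. The Poisson correction d = -ln(1 - p) accounts for multiple hits.

encode_alignment <- function(aln) {
  enc <- match(aln, AA_ALPHABET)  # gaps and X -> NA
  dim(enc) <- dim(aln)
  rownames(enc) <- rownames(aln)
  enc
}

#' Compute a pairwise distance matrix from an alignment
#'
#' @param aln Alignment matrix from [align_con1()].
#' @param site_rule `"partial_deletion"` (occupancy filter, see `coverage`)
#'   or `"pairwise_deletion"`.
#' @param coverage Minimum residue occupancy for a column under partial
#'   deletion.
#' @param correction `"p"` for the raw p-distance or `"poisson"` for
#'   d = -ln(1 - p).
#' @return A symmetric numeric matrix (zero diagonal) with sequence ids as
#'   dimnames, in substitutions/site.
#' @export
compute_distances <- function(aln,
                              site_rule = c("partial_deletion",
                                            "pairwise_deletion"),
                              coverage = 0.95,
                              correction = c("p", "poisson")) {
  site_rule <- match.arg(site_rule)
  correction <- match.arg(correction)
  enc <- encode_alignment(aln)
  if (site_rule == "partial_deletion") {
    keep <- colMeans(!is.na(enc)) >= coverage
    if (!any(keep)) stop("no columns pass the occupancy filter")
    enc <- enc[, keep, drop = FALSE]
  }
  n <- nrow(enc)
  ids <- rownames(enc)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(max(0, n - 1))) {
    a <- enc[i, ]
    for (j in (i + 1):n) {
      b <- enc[j, ]
      ok <- !is.na(a) & !is.na(b)
      ncomp <- sum(ok)
      if (ncomp == 0) {
        stop("no comparable sites between ", ids[i], " and ", ids[j])
      }
      p <- sum(a[ok] != b[ok]) / ncomp
      if (correction == "poisson") {
        if (p >= 1) {
          warning("saturated p-distance between ", ids[i], " and ", ids[j],
                  "; capped")
          p <- 1 - 1e-6
        }
        p <- -log(1 - p)
      }
      D[i, j] <- D[j, i] <- p
    }
  }
  stopifnot(isSymmetric(D), all(diag(D) == 0), all(D >= 0))
  D
}
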