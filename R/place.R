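# Phylogenetic placement of a query CON1 region into a labeled reference
# alignment: the query is profile-aligned to the reference, the joint NJ
# tree is rebuilt with bootstrap, and the query is assigned to the smallest
# clade that contains it together with the complete reference set of a
# single class label.

#' Build a labeled CON1 reference from FASTA
#'
#' Headers must carry a `class=<label>` token, e.g. `>REF_V_1 class=V`.
#' Reference sequences must already be aligned (equal lengths) or be
#' alignable; unaligned input is aligned with [align_con1()].
#'
#' @param path FASTA path.
#' @return A list of class `con1_reference` with `alignment` (matrix) and
#'   `labels` (named character vector, id -> class label).
#' @export
parse_con1_reference <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  lab <- gff_attr(gsub(" ", ";", names(set)), "class")
  if (anyNA(lab)) stop("reference FASTA header without class= label: ",
                       names(set)[which(is.na(lab))[1]])
  seqs <- setNames(toupper(as.character(set)), ids)
  aln <- if (length(unique(nchar(seqs))) == 1) seq_to_matrix(seqs)
         else align_con1(seqs)
  con1_reference(aln, setNames(lab, ids))
}

#' @rdname parse_con1_reference
#' @param alignment Reference alignment matrix.
#' @param labels Named character vector of class labels, one per row.
#' @export
con1_reference <- function(alignment, labels) {
  if (!all(rownames(alignment) %in% names(labels)))
    stop("reference labels must cover every alignment row")
  structure(list(alignment = alignment,
                 labels = labels[rownames(alignment)]),
            class = "con1_reference")
}

#' Write a labeled reference to FASTA
#' @param reference A `con1_reference`.
#' @param path Output path.
#' @export
write_con1_reference <- function(reference, path) {
  seqs <- apply(reference$alignment, 1, paste, collapse = "")
  hdr <- paste0(names(seqs), " class=", reference$labels[names(seqs)])
  Biostrings::writeXStringSet(Biostrings::AAStringSet(setNames(seqs, hdr)),
                              path)
  invisible(path)
}

#' Place a query CON1 region into a labeled reference tree
#'
#' The query is aligned to the reference profile, the joint tree is rebuilt
#' by bootstrapped neighbor joining, and the host clade is the smallest
#' clade of the point-estimate tree containing the query plus the complete
#' reference leaf set of exactly one class label. The reported support is
#' the bootstrap percentage of that clade's edge; no qualifying clade means
#' no host (`NA`), which downstream classification treats as unclassified.
#'
#' @param query A `con1_region`, or a single named character sequence.
#' @param reference A `con1_reference`.
#' @param n_reps,seed Bootstrap replicates and seed.
#' @param site_rule,coverage,correction Distance options, see
#'   [compute_distances()].
#' @param gap_open,gap_extend Profile-alignment gap penalties.
#' @return A list of class `chs_placement`: `query_id`, `host_clade_label`
#'   (`NA` when none), `support` (percentage, `NA` when no host), `sister`
#'   (leaf names of the query's sister group), `tree`.
#' @export
place_query <- function(query, reference, n_reps = 100, seed = 1,
                        site_rule = "pairwise_deletion", coverage = 0.95,
                        correction = "p", gap_open = -10, gap_extend = -1) {
  if (!inherits(reference, "con1_reference") ||
      nrow(reference$alignment) == 0) {
    stop("empty or invalid reference")
  }
  if (inherits(query, "con1_region")) {
    qid <- query$protein_id
    qseq <- query$sequence
  } else {
    qid <- names(query)[1]
    qseq <- unname(query[1])
  }
  if (is.null(qid) || is.na(qid)) stop("query needs an id")
  if (qid %in% rownames(reference$alignment)) {
    stop("query id already present in reference: ", qid)
  }
  qmat <- matrix(strsplit(qseq, "")[[1]], 1, dimnames = list(qid, NULL))
  tb <- profile_align(reference$alignment, qmat, gap_open, gap_extend)
  joint <- rbind(expand_profile(reference$alignment, tb$a_idx),
                 expand_profile(qmat, tb$b_idx))
  tree <- bootstrap_support(joint, n_reps = n_reps, seed = seed,
                            site_rule = site_rule, coverage = coverage,
                            correction = correction)
  point_keys <- names(attr(tree, "split_support"))
  counts <- attr(tree, "split_counts")
  tips <- tree$tip.label
  labs <- reference$labels
  cand <- data.frame(label = character(), size = integer(),
                     key = character(), stringsAsFactors = FALSE)
  for (L in sort(unique(labs))) {
    clade <- c(qid, names(labs)[labs == L])
    key <- canonical_split(clade, tips)
    if (key %in% point_keys) {
      cand <- rbind(cand, data.frame(label = L, size = length(clade),
                                     key = key, stringsAsFactors = FALSE))
    }
  }
  interior <- NA
  # two labels can only qualify simultaneously when the reference carries
  # exactly two label clades and the query sits between them: ambiguous
  if (nrow(cand) > 1) cand <- cand[0, , drop = FALSE]
  if (nrow(cand)) {
    cand <- cand[order(cand$size, cand$label), , drop = FALSE]
    key <- cand$key[1]
    host <- cand$label[1]
    cnt <- counts[key]
    support <- 100 * (if (is.na(cnt)) 0 else unname(cnt)) / attr(tree, "n_reps")
    # interior placement: the query breaks the pure reference clade of the
    # host label (vs. attaching basal/sister to it)
    pure_key <- canonical_split(names(labs)[labs == host], tips)
    interior <- !(pure_key %in% point_keys)
  } else {
    host <- NA_character_
    support <- NA_real_
  }
  # sister leaves: tips under the query's parent node, excluding the query
  qtip <- match(qid, tips)
  parent <- tree$edge[tree$edge[, 2] == qtip, 1]
  sister <- setdiff(ape::extract.clade(tree, parent)$tip.label, qid)
  structure(list(query_id = qid, host_clade_label = host,
                 support = support, interior = interior, sister = sister,
                 tree = tree),
            class = "chs_placement")
}
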