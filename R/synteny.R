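# Head-to-head ChsV/ChsVII arrangement detection.
#
# "Head-to-head" means divergently transcribed adjacent genes: same contig,
# opposite strands, 5' ends facing each other across the intergenic
# interval (left gene on "-", right gene on "+"), with at most
# `max_intervening` annotated genes strictly between them.

#' Intron status of a gene model
#' @param model One-row gene-model data.frame (or a bare exon count).
#' @return `TRUE` (exon_count >= 2), `FALSE` (exon_count == 1) or `NA`
#'   (unknown).
#' @export
intron_status <- function(model) {
  n <- if (is.data.frame(model)) model$exon_count[1] else model[1]
  if (is.na(n)) NA else n >= 2
}

pair_call <- function(gv, g7, models, max_intervening, max_span) {
  both_introns <- {
    iv <- intron_status(gv); i7 <- intron_status(g7)
    if (isFALSE(iv) || isFALSE(i7)) FALSE
    else if (is.na(iv) || is.na(i7)) NA
    else TRUE
  }
  if (gv$contig != g7$contig) {
    return(list(arrangement = "different_contig", intervening = NA_integer_,
                both_have_introns = both_introns))
  }
  left <- if (gv$start <= g7$start) gv else g7
  right <- if (gv$start <= g7$start) g7 else gv
  between <- models$contig == gv$contig &
    models$start > left$end & models$end < right$start &
    !(models$gene_id %in% c(gv$gene_id, g7$gene_id))
  n_between <- sum(between)
  span <- right$end - left$start + 1L
  arrangement <- if (left$strand == right$strand) {
    "same_strand"
  } else if (left$strand == "+" && right$strand == "-") {
    "tail_to_tail"
  } else if (n_between <= max_intervening && span <= max_span) {
    "head_to_head"
  } else {
    "distant"
  }
  list(arrangement = arrangement, intervening = n_between,
       both_have_introns = both_introns)
}

#' Detect the head-to-head ChsV/ChsVII arrangement
#'
#' For every species carrying Class V and Class VII genes, the V x VII gene
#' pairs are classified by arrangement. Species with exactly one gene of
#' each class yield one call; species with several yield one call per pair,
#' flagged ambiguous.
#'
#' @param models Gene-model table from [parse_gene_models()].
#' @param assignments Class assignments (`protein_id`, `species_id`,
#'   `class_label`) identifying which genes encode Class V and VII
#'   proteins.
#' @param max_intervening Maximum number of annotated genes allowed between
#'   a head-to-head pair (default 1).
#' @param max_span Optional cap on the genomic span of the pair (default
#'   none).
#' @return Data.frame with columns `species_id`, `gene_v`, `gene_vii`,
#'   `arrangement`, `intervening_gene_count`, `both_have_introns`,
#'   `ambiguous`.
#' @export
detect_head_to_head <- function(models, assignments, max_intervening = 1,
                                max_span = Inf) {
  cls <- setNames(assignments$class_label, assignments$protein_id)
  sp <- setNames(assignments$species_id, assignments$protein_id)
  models$class_label <- unname(cls[models$protein_id])
  models$species_id <- unname(sp[models$protein_id])
  rows <- list()
  for (s in sort(unique(models$species_id[!is.na(models$species_id)]))) {
    msp <- models[!is.na(models$species_id) & models$species_id == s, ,
                  drop = FALSE]
    gv_all <- msp[!is.na(msp$class_label) & msp$class_label == "V", ,
                  drop = FALSE]
    g7_all <- msp[!is.na(msp$class_label) & msp$class_label == "VII", ,
                  drop = FALSE]
    if (!nrow(gv_all) || !nrow(g7_all)) next
    ambiguous <- nrow(gv_all) > 1 || nrow(g7_all) > 1
    for (i in seq_len(nrow(gv_all))) for (j in seq_len(nrow(g7_all))) {
      # intervening genes are counted over the full annotation (a gene
      # without a protein product still separates the pair)
      call <- pair_call(gv_all[i, ], g7_all[j, ], models, max_intervening,
                        max_span)
      rows[[length(rows) + 1L]] <- data.frame(
        species_id = s, gene_v = gv_all$gene_id[i],
        gene_vii = g7_all$gene_id[j], arrangement = call$arrangement,
        intervening_gene_count = call$intervening,
        both_have_introns = call$both_have_introns,
        ambiguous = ambiguous, stringsAsFactors = FALSE)
    }
  }
  rbind_rows(rows, data.frame(species_id = character(),
                              gene_v = character(), gene_vii = character(),
                              arrangement = character(),
                              intervening_gene_count = integer(),
                              both_have_introns = logical(),
                              ambiguous = logical(),
                              stringsAsFactors = FALSE))
}

#' Tally synteny calls
#' @param calls Data.frame from [detect_head_to_head()].
#' @return List with per-arrangement species counts and the head-to-head
#'   with/without-intervening-gene split (their sum is asserted equal to
#'   the head-to-head total).
#' @export
summarize_synteny <- function(calls) {
  hh <- calls[calls$arrangement == "head_to_head", , drop = FALSE]
  n_with <- length(unique(hh$species_id[hh$intervening_gene_count > 0]))
  n_without <- length(unique(hh$species_id[hh$intervening_gene_count == 0]))
  n_hh <- length(unique(hh$species_id))
  stopifnot(n_with + n_without == n_hh)
  list(arrangement_counts = table(calls$arrangement),
       head_to_head_species = n_hh,
       with_intervening = n_with,
       without_intervening = n_without,
       all_introns = all(hh$both_have_introns, na.rm = TRUE))
}
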