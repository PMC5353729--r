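# Per-species and per-taxon CHS repertoire profiles (family expansion and
# contraction bookkeeping).

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Per-species counts of CHSs per class
#'
#' @param assignments Data.frame from [classify_species_set()].
#' @param taxonomy Taxonomy table from [parse_taxonomy()]; every species in
#'   the taxonomy gets a row (all-zero when it has no accepted CHSs), and a
#'   species absent from the taxonomy is an error.
#' @return An integer matrix, rows = species, columns = class labels plus
#'   `unclassified`; row sums equal each species' accepted CHS count.
#' @export
profile_counts <- function(assignments, taxonomy) {
  missing_sp <- setdiff(unique(assignments$species_id), taxonomy$species_id)
  if (length(missing_sp)) {
    stop("species absent from taxonomy: ", paste(missing_sp, collapse = ", "))
  }
  levels_all <- c(CLASS_LABELS, "unclassified")
  m <- table(factor(assignments$species_id, levels = taxonomy$species_id),
             factor(assignments$class_label, levels = levels_all))
  m <- matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m))
  m
}

taxon_species <- function(taxonomy, taxon) {
  sel <- rep(FALSE, nrow(taxonomy))
  for (col in c("phylum", "subphylum", "class")) {
    sel <- sel | (!is.na(taxonomy[[col]]) & taxonomy[[col]] == taxon)
  }
  if (taxon %in% names(taxonomy) && is.logical(taxonomy[[taxon]])) {
    sel <- sel | (!is.na(taxonomy[[taxon]]) & taxonomy[[taxon]])
  }
  taxonomy$species_id[sel]
}

#' Repertoire summary for one taxon
#'
#' @param profile Count matrix from [profile_counts()].
#' @param taxonomy Taxonomy table.
#' @param taxon A taxon name matched against the `phylum`, `subphylum` and
#'   `class` columns, or the name of a logical tag column (e.g.
#'   `early_diverging`).
#' @return A list of class `taxon_summary`: `taxon`, `n_species`,
#'   `mean_chs` (average CHSs per species, half-up to 1 decimal),
#'   `presence` (per class, fractions of species with multiple / one / no
#'   members; the three sum to 1).
#' @export
taxon_summary <- function(profile, taxonomy, taxon) {
  sp <- taxon_species(taxonomy, taxon)
  if (!length(sp)) stop("no species in taxon: ", taxon)
  sub <- profile[sp, , drop = FALSE]
  n <- length(sp)
  mean_chs <- round_half_up(sum(sub) / n, 1)
  presence <- t(apply(sub, 2, function(x) {
    c(multiple = mean(x >= 2), one = mean(x == 1), none = mean(x == 0))
  }))
  stopifnot(all(abs(rowSums(presence) - 1) < 1e-12))
  structure(list(taxon = taxon, n_species = n, mean_chs = mean_chs,
                 presence = presence),
            class = "taxon_summary")
}

#' @export
print.taxon_summary <- function(x, ...) {
  cat(sprintf("%s: %d species, mean %.1f CHSs/species\n",
              x$taxon, x$n_species, x$mean_chs))
  invisible(x)
}
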