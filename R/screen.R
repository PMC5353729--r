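# Candidate screening: the three false-positive filters applied after an
# HMM sweep of a proteome — characteristic chitin-synthase domain present,
# CON1 motif triple present, exact within-species duplicates collapsed.

#' Screening configuration
#'
#' @param characteristic_domains Accessions accepted as characteristic CHS
#'   domains (after alias resolution). PF01644 (CS1) is included because
#'   Division 1 CHSs carry only a truncated CS2 remnant.
#' @param evalue_max Maximum E-value for a characteristic-domain hit.
#' @param aliases Named vector mapping alias accessions to their canonical
#'   accession; cd04190 (CDD) is an alias of the PF03142 criterion.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(characteristic_domains = c("PF03142", "PF01644"),
                          evalue_max = 1e-5,
                          aliases = c(cd04190 = "PF03142")) {
  structure(list(characteristic_domains = characteristic_domains,
                 evalue_max = evalue_max, aliases = aliases),
            class = "screen_config")
}

resolve_aliases <- function(accession, aliases) {
  hit <- accession %in% names(aliases)
  accession[hit] <- unname(aliases[accession[hit]])
  accession
}

#' Apply the three selection criteria to candidate proteins
#'
#' A protein is accepted when (1) it has at least one characteristic-domain
#' hit at or below the E-value threshold, (2) a CON1 region was extracted,
#' and (3) it is not an exact full-length duplicate of another protein of
#' the same species (the lexicographically smallest protein id of a
#' duplicate group is kept).
#'
#' @param records Protein table from [parse_sequences()].
#' @param hits Domain-hit table from [parse_domain_hits()].
#' @param con1 Named list from [extract_con1_all()]; must have an entry
#'   (possibly `NULL`) for every record that has no domain hits.
#' @param config A [screen_config()].
#' @return A data.frame with columns `protein_id`, `accepted`, `reasons`
#'   (comma-joined subset of `no_characteristic_domain`, `missing_motifs`,
#'   `duplicate`; empty when accepted).
#' @export
filter_candidates <- function(records, hits, con1, config = screen_config()) {
  covered <- records$protein_id %in% names(con1) |
    records$protein_id %in% hits$protein_id
  if (any(!covered)) {
    stop("incomplete inputs: no domain-hit or CON1 entry for ",
         records$protein_id[which(!covered)[1]])
  }
  acc <- resolve_aliases(hits$accession, config$aliases)
  char_ok_ids <- unique(hits$protein_id[acc %in% config$characteristic_domains &
                                          hits$evalue <= config$evalue_max])
  has_domain <- records$protein_id %in% char_ok_ids
  has_con1 <- vapply(records$protein_id, function(p) {
    !is.null(con1[[p]])
  }, TRUE)
  # within-species exact-sequence duplicate collapse
  dup <- logical(nrow(records))
  key <- paste(records$species_id, records$sequence, sep = "\r")
  for (grp in split(seq_len(nrow(records)), key)) {
    if (length(grp) > 1) {
      keep <- grp[order(records$protein_id[grp])][1]
      dup[setdiff(grp, keep)] <- TRUE
    }
  }
  reasons <- vapply(seq_len(nrow(records)), function(i) {
    r <- c(if (!has_domain[i]) "no_characteristic_domain",
           if (!has_con1[i]) "missing_motifs",
           if (dup[i]) "duplicate")
    paste(r, collapse = ",")
  }, "")
  data.frame(protein_id = records$protein_id,
             accepted = !nzchar(reasons),
             reasons = reasons, stringsAsFactors = FALSE)
}

#' Write a screening report TSV
#' @param results Output of [filter_candidates()].
#' @param path Output path.
#' @export
write_screen_report <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
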