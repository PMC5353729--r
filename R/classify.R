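# Class assignment: domain-structure type x phylogenetic placement, with
# the exclusion rule for architecture types that scatter across the tree.

CLASS_LABELS <- c("I", "II", "III", "IV", "V", "VI", "VII", "23b")

# class -> compatible structure type; class -> division
CLASS_TYPE <- c(I = "A2", II = "A2", III = "A2", "23b" = "A2",
                IV = "B2", V = "B4", VII = "B4", VI = "B1")
CLASS_DIVISION <- c(I = 1L, II = 1L, III = 1L, "23b" = 1L,
                    IV = 2L, V = 2L, VII = 2L, VI = 3L)

support_passes <- function(support, threshold, strict) {
  !is.na(support) && if (strict) support > threshold else support >= threshold
}

#' Combine structure type and placement into a class call
#'
#' A class is called iff the placement's host clade label matches a class
#' whose expected domain structure equals the protein's type, and the
#' clade's bootstrap support exceeds the threshold (strictly, by default).
#' CHS23b is called through the labeled basal clade of the Division 1
#' reference set. Everything else is unclassified.
#'
#' @param type_label Structure type (`A1`..`B4`, `other`).
#' @param placement A `chs_placement` from [place_query()] (or a list with
#'   `host_clade_label` and `support`).
#' @param threshold Support threshold in percent (default 60).
#' @param strict Require support strictly above the threshold.
#' @return A list with `class_label`, `division` (`NA` when unclassified),
#'   `support`, `basis` (type and host label).
#' @export
assign_class <- function(type_label, placement, threshold = 60,
                         strict = TRUE) {
  host <- placement$host_clade_label
  support <- placement$support
  called <- !is.na(host) && host %in% names(CLASS_TYPE) &&
    CLASS_TYPE[[host]] == type_label &&
    support_passes(support, threshold, strict)
  if (called) {
    list(class_label = host, division = CLASS_DIVISION[[host]],
         support = support,
         basis = list(type_label = type_label, host_clade_label = host))
  } else {
    list(class_label = "unclassified", division = NA_integer_,
         support = if (is.na(host)) NA_real_ else support,
         basis = list(type_label = type_label, host_clade_label = host))
  }
}

#' Flag proteins excluded from the master phylogeny as noise
#'
#' Architecture types A1, A3 and B3 scatter across the tree regardless of
#' placement and are always flagged. Type B1 is flagged unless it is placed
#' inside the Division 3 (Class VI) reference clade — interior attachment,
#' not merely basal to it — with sufficient support. Other types are never
#' flagged.
#'
#' @inheritParams assign_class
#' @return Logical.
#' @export
flag_noisy <- function(type_label, placement, threshold = 60,
                       strict = TRUE) {
  if (type_label %in% c("A1", "A3", "B3")) return(TRUE)
  if (type_label == "B1") {
    host <- placement$host_clade_label
    interior <- if (is.null(placement$interior) || is.na(placement$interior))
      TRUE else placement$interior
    in_div3 <- !is.na(host) && host == "VI" && interior &&
      support_passes(placement$support, threshold, strict)
    return(!in_div3)
  }
  FALSE
}

#' Classify the screened proteins of a species set
#'
#' Reproduces the species-by-species master-tree procedure: every accepted
#' protein's CON1 region is placed into the labeled reference and the class
#' called from placement plus structure type. A query whose CON1 is an
#' exact duplicate of a reference sequence is assigned that reference's
#' label directly (support 100), mirroring the removal of repeat sequences
#' before tree building.
#'
#' @param proteins Data.frame of accepted proteins (`protein_id`,
#'   `species_id`); species with zero accepted proteins simply contribute
#'   no rows.
#' @param con1 Named list of `con1_region`s covering `proteins`.
#' @param types Named character vector protein_id -> structure type (from
#'   [architecture_table()]).
#' @param reference A `con1_reference`; must carry all seven class labels.
#' @param n_reps,seed Bootstrap replicates and base seed (each protein uses
#'   `seed + its index`, so runs are reproducible).
#' @param threshold,strict Support rule, see [assign_class()].
#' @return Data.frame with one row per protein: `protein_id`, `species_id`,
#'   `class_label`, `division`, `support`, `type_label`,
#'   `host_clade_label`, `noisy`.
#' @export
classify_species_set <- function(proteins, con1, types, reference,
                                 n_reps = 100, seed = 1, threshold = 60,
                                 strict = TRUE) {
  need <- setdiff(c("I", "II", "III", "IV", "V", "VI", "VII"),
                  unique(reference$labels))
  if (length(need)) {
    stop("reference is missing class labels: ", paste(need, collapse = ", "))
  }
  ref_seqs <- gsub("-", "", apply(reference$alignment, 1, paste, collapse = ""))
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    pid <- proteins$protein_id[i]
    region <- con1[[pid]]
    if (is.null(region)) stop("no CON1 region for accepted protein ", pid)
    ty <- types[[pid]]
    dup <- match(region$sequence, ref_seqs)
    if (!is.na(dup)) {
      placement <- list(host_clade_label = unname(reference$labels[dup]),
                        support = 100, interior = TRUE)
    } else {
      placement <- place_query(
        structure(list(protein_id = pid, sequence = region$sequence),
                  class = "con1_region"),
        reference, n_reps = n_reps, seed = seed + i)
    }
    cl <- assign_class(ty, placement, threshold, strict)
    data.frame(protein_id = pid, species_id = proteins$species_id[i],
               class_label = cl$class_label, division = cl$division,
               support = if (is.null(cl$support)) NA_real_ else cl$support,
               type_label = ty,
               host_clade_label = if (is.na(placement$host_clade_label[1]))
                 NA_character_ else placement$host_clade_label,
               noisy = flag_noisy(ty, placement, threshold, strict),
               stringsAsFactors = FALSE)
  })
  rbind_rows(rows, data.frame(protein_id = character(),
                              species_id = character(),
                              class_label = character(),
                              division = integer(), support = numeric(),
                              type_label = character(),
                              host_clade_label = character(),
                              noisy = logical(), stringsAsFactors = FALSE))
}

#' Summarize a set of class assignments
#'
#' @param assignments Data.frame from [classify_species_set()].
#' @return A list of class `classification_summary`: `class_counts` (named,
#'   all class labels plus `unclassified`), `total`, `classified`,
#'   `excluded_count` (noisy proteins) and `type_counts`. The partition
#'   identity (class counts sum to total) is asserted.
#' @export
summarize_classification <- function(assignments) {
  levels_all <- c(CLASS_LABELS, "unclassified")
  cc <- table(factor(assignments$class_label, levels = levels_all))
  cc <- setNames(as.integer(cc), names(cc))
  total <- nrow(assignments)
  stopifnot(sum(cc) == total)
  tc <- table(assignments$type_label)
  structure(list(class_counts = cc, total = total,
                 classified = sum(cc[CLASS_LABELS]),
                 unclassified = cc[["unclassified"]],
                 excluded_count = sum(assignments$noisy),
                 type_counts = setNames(as.integer(tc), names(tc))),
            class = "classification_summary")
}

#' Load the published survey tallies fixture
#'
#' Printed bookkeeping counts from the 231-proteome CHS survey (1,571
#' proteins), shipped with the package for the identity checks in
#' [check_survey_identities()].
#'
#' @param path Path to the JSON fixture; default is the installed copy.
#' @return A named list of counts.
#' @export
load_survey_tallies <- function(path = system.file("extdata",
                                                   "survey_tallies.json",
                                                   package = "chsfam")) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Bookkeeping identities over the survey tallies
#'
#' Recomputes every stated total from its parts: total identified CHSs
#' (classified + CHS23b + unclassified), proteins retained for the
#' phylogeny (total - excluded), Type B1 total (Division-3 residents +
#' excluded B1), head-to-head species (with + without an intervening gene),
#' and non-fungal outgroup CHSs (Division-1-clade + Division-2-clade
#' members), then compares each against the stated count.
#'
#' @param tallies Output of [load_survey_tallies()].
#' @return A list with each recomputed quantity and `consistent` (TRUE when
#'   all identities hold).
#' @export
check_survey_identities <- function(tallies = load_survey_tallies()) {
  t <- tallies
  total <- t$classified + t$chs23b + t$unclassified
  retained <- total - t$excluded
  b1_total <- t$b1_division3 + t$b1_excluded
  hh <- t$head_to_head_with_intervening + t$head_to_head_without_intervening
  outgroup <- t$outgroup_division1_clade + t$outgroup_division2_clade
  list(total = total,
       retained_for_phylogeny = retained,
       b1_total = b1_total,
       head_to_head_species = hh,
       outgroup_total = outgroup,
       consistent = total == t$total_stated &&
         retained == t$retained_stated &&
         b1_total == t$b1_total_stated &&
         hh == t$head_to_head_species_stated &&
         outgroup == t$outgroup_total_stated)
}

#' Write an assignment table TSV
#' @param assignments Data.frame from [classify_species_set()].
#' @param path Output path.
#' @export
write_assignments <- function(assignments, path) {
  write.table(assignments, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
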