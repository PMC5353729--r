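# Ordered domain architectures and Group/Type assignment.
#
# Typing uses six focal Pfam domains plus the CON1 token:
#   PF08407, PF01644 (CS1), PF03142 (CS2), PF00173 (cyt-b5-like),
#   PF00063 (myosin motor-like), PF08766 (DEK_C-like).
# Group A architectures carry CS1 immediately followed by the CON1 remnant
# of a truncated CS2; Group B architectures carry an intact CS2 with CON1
# inside it.

FOCAL_DOMAINS <- c("PF08407", "PF01644", "PF00063", "PF00173",
                   "PF03142", "PF08766")

#' Build the ordered domain architecture of one protein
#'
#' Focal-domain hits are kept (other accessions are recorded as auxiliary
#' and never influence typing); overlapping hits of the same accession are
#' merged; overlapping hits of different accessions are resolved in favour
#' of the higher bit score. A PF03142 hit contained in the CON1 region is
#' replaced by the `CON1` token; a CON1 region contained in a retained
#' PF03142 hit is represented by that hit (no token).
#'
#' @param protein A one-row protein data.frame or a protein id string.
#' @param hits Domain hits restricted to this protein (rows for other
#'   proteins are dropped).
#' @param con1 A `con1_region` for this protein or `NULL`.
#' @param aliases Accession alias map (see [screen_config()]).
#' @return A list of class `chs_architecture` with `protein_id`, `elements`
#'   (ordered character vector), `intervals` (element, start, end, score)
#'   and `auxiliary` (non-focal accessions seen).
#' @export
build_architecture <- function(protein, hits, con1 = NULL,
                               aliases = c(cd04190 = "PF03142")) {
  pid <- if (is.character(protein)) protein[1] else protein$protein_id[1]
  h <- hits[hits$protein_id == pid, , drop = FALSE]
  h$accession <- resolve_aliases(h$accession, aliases)
  aux <- sort(unique(h$accession[!(h$accession %in% FOCAL_DOMAINS)]))
  h <- h[h$accession %in% FOCAL_DOMAINS, , drop = FALSE]

  # merge overlapping same-accession hits
  merged <- do.call(rbind, lapply(split(h, h$accession), function(g) {
    g <- g[order(g$start, g$end), , drop = FALSE]
    out <- g[0, ]
    for (i in seq_len(nrow(g))) {
      n <- nrow(out)
      if (n > 0 && g$start[i] < out$end[n]) {
        out$end[n] <- max(out$end[n], g$end[i])
        out$score[n] <- max(out$score[n], g$score[i])
        out$evalue[n] <- min(out$evalue[n], g$evalue[i])
      } else {
        out <- rbind(out, g[i, ])
      }
    }
    out
  }))
  if (is.null(merged)) {
    merged <- data.frame(protein_id = character(), accession = character(),
                         start = integer(), end = integer(),
                         score = numeric(), evalue = numeric())
  }

  # resolve cross-accession overlaps: greedy by descending score,
  # deterministic ties by accession then start
  merged <- merged[order(-merged$score, merged$accession, merged$start), ,
                   drop = FALSE]
  kept <- merged[0, ]
  for (i in seq_len(nrow(merged))) {
    overlaps <- any(merged$start[i] < kept$end & kept$start < merged$end[i])
    if (!overlaps) kept <- rbind(kept, merged[i, ])
  }

  elements <- data.frame(element = kept$accession, start = kept$start,
                         end = kept$end, score = kept$score,
                         stringsAsFactors = FALSE)
  if (!is.null(con1)) {
    inside_cs2 <- with(elements, element == "PF03142" &
                         start <= con1$start & con1$end <= end)
    if (!any(inside_cs2)) {
      # drop truncated CS2 remnants contained in the region, add the token
      drop <- with(elements, element == "PF03142" &
                     start >= con1$start & end <= con1$end)
      elements <- elements[!drop, , drop = FALSE]
      elements <- rbind(elements,
                        data.frame(element = "CON1", start = con1$start,
                                   end = con1$end, score = NA_real_))
    }
  }
  elements <- elements[order(elements$start), , drop = FALSE]
  rownames(elements) <- NULL
  structure(list(protein_id = pid, elements = elements$element,
                 intervals = elements, auxiliary = aux),
            class = "chs_architecture")
}

#' @export
print.chs_architecture <- function(x, ...) {
  cat(x$protein_id, ": [", paste(x$elements, collapse = ", "), "]\n", sep = "")
  invisible(x)
}

# the type table: focal-element multisets (order checked separately)
TYPE_SETS <- list(
  A1 = c("PF01644", "CON1"),
  A2 = c("PF08407", "PF01644", "CON1"),
  A3 = c("PF08407", "PF01644", "CON1", "PF03142"),
  B1 = c("PF03142"),
  B2 = c("PF03142", "PF00173"),
  B3 = c("PF00063", "PF03142", "PF08766"),
  B4 = c("PF00063", "PF00173", "PF03142", "PF08766")
)

#' Assign the Group/Type label of a domain architecture
#'
#' Pure function of the focal-element list. Multiset membership decides
#' the type; order is enforced only where the pattern definitions require
#' it: Group A needs PF01644 immediately followed by CON1 (the fused CS1 +
#' CS2-remnant arrangement), and A3 needs its intact PF03142 after CON1.
#'
#' @param arch A `chs_architecture` from [build_architecture()], or a plain
#'   character vector of elements.
#' @return A list with `group` (`"A"`, `"B"` or `"none"`) and `type_label`
#'   (`A1`-`A3`, `B1`-`B4` or `"other"`).
#' @export
assign_structure_type <- function(arch) {
  el <- if (is.character(arch)) arch else arch$elements
  same_multiset <- function(a, b) {
    length(a) == length(b) && identical(sort(a), sort(b))
  }
  label <- "other"
  for (ty in names(TYPE_SETS)) {
    if (same_multiset(el, TYPE_SETS[[ty]])) { label <- ty; break }
  }
  if (label %in% c("A1", "A2", "A3")) {
    i <- match("PF01644", el)
    fused <- !is.na(i) && i < length(el) && el[i + 1L] == "CON1"
    if (!fused) label <- "other"
  }
  if (label == "A3") {
    if (match("PF03142", el) < match("CON1", el)) label <- "other"
  }
  group <- if (label %in% c("A1", "A2", "A3")) "A"
           else if (label %in% c("B1", "B2", "B3", "B4")) "B"
           else "none"
  list(group = group, type_label = label)
}

#' Build architectures and types for a protein set
#' @param records Protein table.
#' @param hits Domain-hit table.
#' @param con1 Named CON1 list from [extract_con1_all()].
#' @param aliases Accession alias map.
#' @return Data.frame with `protein_id`, `elements` (comma-joined),
#'   `group`, `type_label`.
#' @export
architecture_table <- function(records, hits, con1,
                               aliases = c(cd04190 = "PF03142")) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    pid <- records$protein_id[i]
    a <- build_architecture(records[i, ], hits, con1[[pid]], aliases)
    ty <- assign_structure_type(a)
    data.frame(protein_id = pid,
               elements = paste(a$elements, collapse = ","),
               group = ty$group, type_label = ty$type_label,
               stringsAsFactors = FALSE)
  })
  rbind_rows(rows, data.frame(protein_id = character(),
                              elements = character(), group = character(),
                              type_label = character(),
                              stringsAsFactors = FALSE))
}
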