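# CON1 motif detection and motif-anchored region extraction.
#
# Chitin synthases carry a conserved catalytic region (CON1) delimited by
# three short motifs. Patterns are fixed-length wildcard patterns over the
# amino-acid alphabet: "x" matches any residue, bracketed alternatives are
# allowed (e.g. "[ED]Dx").

#' Named CON1 motif pattern sets
#'
#' The `"primary"` set (QxxEY, EDRxL, QxRRW) is the default used for
#' screening; the `"alternate"` set keeps the looser variants
#' (QxxEY, \[ED\]Dx, Q\[RQ\]xRW) sometimes quoted for the CON1 region.
#' Each pattern carries a role: `start`, `middle` or `end` anchor of the
#' region.
#'
#' @param set Pattern-set name.
#' @return A data.frame with columns `motif_name`, `pattern`, `role`,
#'   `length`.
#' @export
con1_patterns <- function(set = c("primary", "alternate")) {
  set <- match.arg(set)
  if (set == "primary") {
    data.frame(motif_name = c("QxxEY", "EDRxL", "QxRRW"),
               pattern = c("QxxEY", "EDRxL", "QxRRW"),
               role = c("start", "middle", "end"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(motif_name = c("QxxEY", "EDx", "QRQxRW"),
               pattern = c("QxxEY", "[ED]Dx", "Q[RQ]xRW"),
               role = c("start", "middle", "end"),
               stringsAsFactors = FALSE)
  }
}

# wildcard pattern -> anchored-width regex; returns list(regex, width)
motif_regex <- function(pattern) {
  # width = literal letters + x's + one per bracket group
  stripped <- gsub("\\[[^]]+\\]", "#", pattern)
  width <- nchar(stripped)
  rx <- gsub("x", ".", pattern, fixed = TRUE)
  list(regex = rx, width = width)
}

#' Scan a protein sequence for CON1 motifs
#'
#' Reports every occurrence of every pattern, including overlapping
#' occurrences. Coordinates are 0-based half-open residue indices.
#'
#' @param record A one-row protein data.frame (see [parse_sequences()]) or a
#'   plain character sequence.
#' @param patterns A pattern set from [con1_patterns()].
#' @return A data.frame with columns `motif_name`, `start`, `end`,
#'   `matched`, sorted by `start` then `motif_name`.
#' @export
scan_motifs <- function(record, patterns = con1_patterns()) {
  seq <- if (is.character(record)) record[1] else record$sequence[1]
  out <- lapply(seq_len(nrow(patterns)), function(i) {
    mr <- motif_regex(patterns$pattern[i])
    # lookahead so overlapping occurrences are all reported
    pos <- gregexpr(paste0("(?=", mr$regex, ")"), seq, perl = TRUE)[[1]]
    if (pos[1] == -1) return(NULL)
    data.frame(motif_name = patterns$motif_name[i],
               start = as.integer(pos) - 1L,
               end = as.integer(pos) - 1L + mr$width,
               matched = substring(seq, pos, pos + mr$width - 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(motif_name = character(), start = integer(),
                      end = integer(), matched = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$start, out$motif_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the CON1 region delimited by an ordered motif triple
#'
#' Among all ordered, non-overlapping (start-motif, middle-motif,
#' end-motif) triples found in the sequence, the triple with minimal span
#' is chosen (leftmost start, then leftmost middle, breaking ties). The
#' region runs from the start-motif's first residue to the end-motif's last
#' residue; the middle motif lies strictly inside. Returns `NULL` when no
#' valid triple exists — absence is a screening outcome, not an error.
#'
#' @param record A one-row protein data.frame or plain sequence string.
#' @param hits Motif hits from [scan_motifs()] on the same record; computed
#'   when omitted.
#' @param patterns Pattern set (used to recompute hits and identify roles).
#' @return A list of class `con1_region` with `protein_id`, `start`, `end`,
#'   `sequence`, `motif_hits`, or `NULL`.
#' @export
extract_con1 <- function(record, hits = NULL, patterns = con1_patterns()) {
  seq <- if (is.character(record)) record[1] else record$sequence[1]
  pid <- if (is.character(record)) NA_character_ else record$protein_id[1]
  if (is.null(hits)) hits <- scan_motifs(seq, patterns)
  role_of <- setNames(patterns$role, patterns$motif_name)
  hs <- hits[role_of[hits$motif_name] == "start", , drop = FALSE]
  hm <- hits[role_of[hits$motif_name] == "middle", , drop = FALSE]
  he <- hits[role_of[hits$motif_name] == "end", , drop = FALSE]
  if (!nrow(hs) || !nrow(hm) || !nrow(he)) return(NULL)
  lex_less <- function(a, b) {
    d <- which(a != b)
    length(d) > 0 && a[d[1]] < b[d[1]]
  }
  best <- NULL
  best_idx <- NULL
  for (i in seq_len(nrow(hs))) {
    for (j in seq_len(nrow(hm))) {
      if (hm$start[j] < hs$end[i]) next
      for (k in seq_len(nrow(he))) {
        if (he$start[k] < hm$end[j]) next
        span <- he$end[k] - hs$start[i]
        cand <- c(span, hs$start[i], hm$start[j], he$start[k])
        if (is.null(best) || lex_less(cand, best)) {
          best <- cand
          best_idx <- c(i, j, k)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  triple <- rbind(hs[best_idx[1], ], hm[best_idx[2], ], he[best_idx[3], ])
  rownames(triple) <- NULL
  start <- triple$start[1]
  end <- triple$end[3]
  structure(list(protein_id = pid, start = start, end = end,
                 sequence = substr(seq, start + 1L, end),
                 motif_hits = triple),
            class = "con1_region")
}

#' Extract CON1 regions for a set of proteins
#'
#' @param records Protein table from [parse_sequences()].
#' @param patterns Pattern set.
#' @return A named list (protein_id -> `con1_region` or `NULL`), one entry
#'   per input record.
#' @export
extract_con1_all <- function(records, patterns = con1_patterns()) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    extract_con1(records[i, ], patterns = patterns)
  })
  names(out) <- records$protein_id
  out
}

#' Tabulate a CON1 region list
#' @param con1 Named list from [extract_con1_all()].
#' @return Data.frame with `protein_id`, `start`, `end`, `length`,
#'   `sequence` for proteins with a region.
#' @export
con1_table <- function(con1) {
  keep <- !vapply(con1, is.null, TRUE)
  rows <- lapply(con1[keep], function(r) {
    data.frame(protein_id = r$protein_id, start = r$start, end = r$end,
               length = r$end - r$start, sequence = r$sequence,
               stringsAsFactors = FALSE)
  })
  rbind_rows(rows, data.frame(protein_id = character(), start = integer(),
                              end = integer(), length = integer(),
                              sequence = character(),
                              stringsAsFactors = FALSE))
}
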