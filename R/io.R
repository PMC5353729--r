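#' @importFrom utils read.delim write.table
#' @importFrom stats setNames
NULL

# Amino-acid alphabet used throughout: the 20 standard residues plus X.
AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")
AA_VALID <- c(AA_ALPHABET, "X")

#' Read protein sequences from a FASTA file
#'
#' Reads one record per FASTA entry. The species is taken from the header
#' under a configurable convention: with `header = "species_pipe_protein"`
#' (the default) the first whitespace-delimited token is split as
#' `speciesID|proteinID`; with `header = "plain"` the whole token is the
#' protein id and the species is looked up in `taxonomy` (if given) or left
#' `NA`.
#'
#' @param path Path to a FASTA file.
#' @param header Header convention, `"species_pipe_protein"` or `"plain"`.
#' @param taxonomy Optional taxonomy table (see [parse_taxonomy()]) used to
#'   attach lineages; with the `"plain"` convention it may carry a
#'   `protein_id` column mapping proteins to species.
#' @return A data.frame with columns `protein_id`, `species_id`, `sequence`.
#' @export
parse_sequences <- function(path, header = c("species_pipe_protein", "plain"),
                            taxonomy = NULL) {
  header <- match.arg(header)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) {
    return(data.frame(protein_id = character(), species_id = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  bad_codes <- FALSE
  set <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        bad_codes <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (bad_codes) report_invalid_residue(path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, "", 1L)
  seqs <- toupper(as.character(set))
  if (header == "species_pipe_protein") {
    parts <- strsplit(ids, "|", fixed = TRUE)
    species <- vapply(parts, `[`, "", 1L)
    protein <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, "")
    if (anyNA(protein)) {
      stop("FASTA header without 'speciesID|proteinID' structure: ",
           ids[which(is.na(protein))[1]])
    }
  } else {
    protein <- ids
    species <- rep(NA_character_, length(ids))
  }
  if (anyDuplicated(protein)) {
    stop("duplicate protein_id in FASTA: ",
         protein[which(duplicated(protein))[1]])
  }
  bad <- regexpr(sprintf("[^%s]", paste(AA_VALID, collapse = "")), seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop(sprintf("non-amino-acid character '%s' in %s at position %d",
                 substr(seqs[i], bad[i], bad[i]), protein[i], bad[i]))
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for ", protein[which(!nzchar(seqs))[1]])
  }
  df <- data.frame(protein_id = protein, species_id = species,
                   sequence = seqs, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

# locate the first non-amino-acid character in a FASTA file and stop with
# its record and residue position
report_invalid_residue <- function(path) {
  lines <- readLines(path)
  id <- NA_character_
  offset <- 0L
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      id <- strsplit(sub("^>", "", ln), "[ \t]")[[1]][1]
      offset <- 0L
      next
    }
    chars <- strsplit(toupper(ln), "")[[1]]
    bad <- which(!(chars %in% c(AA_VALID, "*", "-")))
    if (length(bad)) {
      stop(sprintf("non-amino-acid character '%s' in %s at position %d",
                   chars[bad[1]], id, offset + bad[1]))
    }
    offset <- offset + length(chars)
  }
  stop("invalid sequence codes in FASTA: ", path)
}

# rbind a list of data.frames; NULL-safe for empty lists
rbind_rows <- function(rows, prototype = NULL) {
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(prototype)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a species taxonomy table
#'
#' Tab-separated with columns `species_id`, `phylum`, `subphylum`, `class`;
#' further columns (e.g. a logical `early_diverging` tag) are kept and can be
#' used as taxon selectors by [taxon_summary()].
#'
#' @param path Path to the TSV file.
#' @return A data.frame, one row per species.
#' @export
parse_taxonomy <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("species_id", "phylum", "subphylum", "class")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("taxonomy table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$species_id)) stop("duplicate species_id in taxonomy")
  for (cl in names(tab)) {
    if (is.character(tab[[cl]]) && all(tab[[cl]] %in% c("TRUE", "FALSE")))
      tab[[cl]] <- as.logical(tab[[cl]])
  }
  tab
}

#' Read per-protein domain hits
#'
#' Two dialects are supported. `"tsv"` expects a header line with columns
#' `protein_id`, `accession`, `start`, `end`, `score`, `evalue`, coordinates
#' 0-based half-open. `"hmmer_domtbl"` is the standard whitespace-delimited
#' per-domain table written by `hmmsearch --domtblout`; envelope coordinates
#' (1-based inclusive) are used and converted. Accession version suffixes
#' (".NN") are stripped in both dialects.
#'
#' @param path Path to the hits file.
#' @param dialect `"tsv"` or `"hmmer_domtbl"`.
#' @param sequences Optional protein table from [parse_sequences()]; when
#'   given, coordinates are checked against sequence lengths.
#' @return A data.frame with columns `protein_id`, `accession`, `start`,
#'   `end` (0-based half-open), `score`, `evalue`.
#' @export
parse_domain_hits <- function(path, dialect = c("tsv", "hmmer_domtbl"),
                              sequences = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "tsv") {
    lines_keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
    if (!length(lines_keep)) {
      hits <- data.frame(protein_id = character(), accession = character(),
                         start = integer(), end = integer(),
                         score = numeric(), evalue = numeric())
      return(hits)
    }
    head_ln <- lines_keep[1]
    cols <- strsplit(trimws(lines[head_ln]), "\t")[[1]]
    need <- c("protein_id", "accession", "start", "end", "score", "evalue")
    if (!all(need %in% cols)) {
      stop("TSV domain-hit file must have header columns: ",
           paste(need, collapse = ", "))
    }
    rows <- lines_keep[-1]
    rec <- lapply(rows, function(ln) {
      f <- strsplit(lines[ln], "\t")[[1]]
      if (length(f) != length(cols))
        stop("malformed domain-hit row at line ", ln)
      setNames(as.list(f), cols)
    })
    hits <- data.frame(
      protein_id = vapply(rec, function(r) r$protein_id, ""),
      accession  = vapply(rec, function(r) r$accession, ""),
      start = suppressWarnings(as.integer(vapply(rec, function(r) r$start, ""))),
      end   = suppressWarnings(as.integer(vapply(rec, function(r) r$end, ""))),
      score = suppressWarnings(as.numeric(vapply(rec, function(r) r$score, ""))),
      evalue = suppressWarnings(as.numeric(vapply(rec, function(r) r$evalue, ""))),
      stringsAsFactors = FALSE)
    bad <- which(is.na(hits$start) | is.na(hits$end) | is.na(hits$score) |
                   is.na(hits$evalue))
    if (length(bad)) stop("malformed domain-hit row at line ", rows[bad[1]])
  } else {
    keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
    rec <- lapply(keep, function(ln) {
      f <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
      if (length(f) < 22) stop("malformed domtbl row at line ", ln)
      f
    })
    acc <- vapply(rec, function(f) if (f[5] != "-") f[5] else f[4], "")
    hits <- data.frame(
      protein_id = vapply(rec, `[`, "", 1L),
      accession  = acc,
      start = as.integer(vapply(rec, `[`, "", 20L)) - 1L,
      end   = as.integer(vapply(rec, `[`, "", 21L)),
      score = as.numeric(vapply(rec, `[`, "", 14L)),
      evalue = as.numeric(vapply(rec, `[`, "", 13L)),
      stringsAsFactors = FALSE)
  }
  hits$accession <- sub("\\.\\d+$", "", hits$accession)
  bad <- which(!(hits$start >= 0 & hits$start < hits$end))
  if (length(bad)) {
    stop(sprintf("invalid domain-hit coordinates for %s: [%d,%d)",
                 hits$protein_id[bad[1]], hits$start[bad[1]], hits$end[bad[1]]))
  }
  if (any(hits$evalue < 0, na.rm = TRUE)) stop("negative E-value in domain hits")
  if (!is.null(sequences)) {
    len <- setNames(nchar(sequences$sequence), sequences$protein_id)
    known <- hits$protein_id %in% names(len)
    over <- which(known & hits$end > len[hits$protein_id])
    if (length(over)) {
      stop("domain hit beyond sequence end for ", hits$protein_id[over[1]])
    }
  }
  rownames(hits) <- NULL
  hits
}

#' Write domain hits in the TSV dialect
#' @param hits Data.frame as returned by [parse_domain_hits()].
#' @param path Output path.
#' @export
write_domain_hits <- function(hits, path) {
  write.table(hits[, c("protein_id", "accession", "start", "end",
                       "score", "evalue")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

gff_attr <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), attr))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
}

#' Read gene models from GFF3
#'
#' Gene features are collected with their coordinates and strand; the exon
#' count of the gene's primary transcript (the first mRNA by file order, or
#' exons attached directly to the gene) is recorded, `NA` when no exon
#' features are present. The protein product id is taken from a
#' `protein_id` attribute on the gene or its primary mRNA, when present.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `gene_id`, `protein_id`, `contig`,
#'   `start`, `end`, `strand`, `exon_count` (coordinates 1-based inclusive).
#' @export
parse_gene_models <- function(path) {
  gff <- ape::read.gff(path, na.strings = c(".", "?"), GFF3 = TRUE)
  genes <- gff[gff$type == "gene", , drop = FALSE]
  if (nrow(genes) && any(is.na(genes$strand))) {
    bad <- gff_attr(genes$attributes[which(is.na(genes$strand))[1]], "ID")
    stop("gene without strand in GFF3: ", bad)
  }
  mrna <- gff[gff$type == "mRNA", , drop = FALSE]
  exon <- gff[gff$type == "exon", , drop = FALSE]
  gene_id <- gff_attr(genes$attributes, "ID")
  if (anyNA(gene_id)) stop("gene feature without ID attribute")
  mrna_id <- gff_attr(mrna$attributes, "ID")
  mrna_parent <- gff_attr(mrna$attributes, "Parent")
  exon_parent <- gff_attr(exon$attributes, "Parent")
  protein_id <- gff_attr(genes$attributes, "protein_id")
  exon_count <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- gene_id[i]
    tr <- which(mrna_parent == g)
    if (length(tr)) {
      primary <- mrna_id[tr[1]]
      if (is.na(protein_id[i])) {
        p <- gff_attr(mrna$attributes[tr[1]], "protein_id")
        protein_id[i] <- p
      }
      n <- sum(exon_parent == primary, na.rm = TRUE)
    } else {
      n <- sum(exon_parent == g, na.rm = TRUE)
    }
    exon_count[i] <- if (n > 0) n else NA_integer_
  }
  data.frame(gene_id = gene_id, protein_id = protein_id,
             contig = as.character(genes$seqid),
             start = genes$start, end = genes$end,
             strand = as.character(genes$strand),
             exon_count = exon_count, stringsAsFactors = FALSE)
}

#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] with validation; internal node
#' labels are kept (bootstrap supports), so `parse_tree` and
#' [serialize_tree()] round-trip topology, branch lengths and supports.
#'
#' @param path Path to a Newick file, or a Newick string via `text`.
#' @param text Newick text (alternative to `path`).
#' @return An object of class `phylo`.
#' @export
parse_tree <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path), collapse = "")
  nopen <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  nclose <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (nopen != nclose) {
    stop("unbalanced parentheses in Newick (", nopen, " '(' vs ",
         nclose, " ')')")
  }
  if (nopen == 0) {
    # single-leaf tree "A;" or "A:1.5;" (ape::read.tree mishandles these)
    m <- regexec("^\\s*([^:;,()]+?)\\s*(?::([0-9.eE+-]+))?\\s*;\\s*$", text)
    g <- regmatches(text, m)[[1]]
    if (length(g) < 2 || !nzchar(g[2])) stop("failed to parse Newick: ", text)
    tr <- structure(list(edge = matrix(c(2L, 1L), 1, 2),
                         tip.label = g[2], Nnode = 1L),
                    class = "phylo", order = "cladewise")
    if (length(g) >= 3 && nzchar(g[3])) tr$edge.length <- as.numeric(g[3])
    return(tr)
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("failed to parse Newick: ", text)
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf names in tree")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0))
    stop("negative branch length in tree")
  tr
}

#' Serialize a tree to Newick
#' @param tree A `phylo` object.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when written to `path`.
#' @export
serialize_tree <- function(tree, path = NULL, digits = 10) {
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Write protein records to FASTA
#' @param records Data.frame with `protein_id`, `species_id`, `sequence`.
#' @param path Output path.
#' @export
write_sequences <- function(records, path) {
  hdr <- ifelse(is.na(records$species_id), records$protein_id,
                paste0(records$species_id, "|", records$protein_id))
  set <- Biostrings::AAStringSet(setNames(records$sequence, hdr))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
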