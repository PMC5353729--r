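# Stage orchestration: a declarative config drives the full survey
# (simulate -> screen -> con1 -> type -> classify -> dynamics -> synteny ->
# report), each stage reading its declared inputs from the working
# directory and writing its declared outputs there, so reruns with the same
# config and seed are bitwise reproducible.

PIPELINE_STAGES <- c("simulate", "screen", "con1", "type", "classify",
                     "dynamics", "synteny", "report", "all")

#' Pipeline configuration
#'
#' Unknown keys are rejected (any misspelled argument fails the call).
#'
#' @param out_dir Working directory for all stage outputs.
#' @param seed Base seed for every stochastic stage.
#' @param sim A [sim_config()] when the dataset is simulated; `NULL` when
#'   real inputs are supplied through `inputs`.
#' @param inputs Named list of input paths (`fasta`, `hits`, `hits_dialect`,
#'   `gff`, `taxonomy`, `reference`); defaults to the files written by the
#'   simulate stage.
#' @param motif_set CON1 pattern set name, see [con1_patterns()].
#' @param evalue_max Screening E-value threshold.
#' @param support_threshold,strict_support Class-call support rule.
#' @param n_reps Bootstrap replicates for placement.
#' @param site_rule,coverage,correction Distance options.
#' @param gap_open,gap_extend Alignment gap penalties.
#' @param max_intervening Head-to-head intervening-gene allowance.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, sim = NULL, inputs = NULL,
                            motif_set = "primary", evalue_max = 1e-5,
                            support_threshold = 60, strict_support = TRUE,
                            n_reps = 100, site_rule = "pairwise_deletion",
                            coverage = 0.95, correction = "p",
                            gap_open = -10, gap_extend = -1,
                            max_intervening = 1) {
  cfg <- as.list(environment())
  if (is.null(cfg$inputs)) {
    d <- file.path(out_dir, "data")
    cfg$inputs <- list(fasta = file.path(d, "proteins.fasta"),
                       hits = file.path(d, "domain_hits.tsv"),
                       hits_dialect = "tsv",
                       gff = file.path(d, "genes.gff3"),
                       taxonomy = file.path(d, "taxonomy.tsv"),
                       reference = file.path(d, "reference_con1.fasta"))
  }
  known_inputs <- c("fasta", "hits", "hits_dialect", "gff", "taxonomy",
                    "reference")
  extra <- setdiff(names(cfg$inputs), known_inputs)
  if (length(extra)) stop("unknown input keys: ", paste(extra, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' Build a pipeline configuration from a JSON file
#'
#' Top-level keys must be arguments of [pipeline_config()] (`sim` is passed
#' through [sim_config()]); unknown keys raise a validation error naming
#' the key.
#'
#' @param path JSON config path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  }
  if (!is.null(raw$sim)) {
    sim_known <- names(formals(sim_config))
    sim_extra <- setdiff(names(raw$sim), sim_known)
    if (length(sim_extra)) {
      stop("unknown sim config keys: ", paste(sim_extra, collapse = ", "))
    }
    raw$sim <- do.call(sim_config, lapply(raw$sim, function(x) {
      if (is.list(x)) unlist(x) else x
    }))
  }
  do.call(pipeline_config, raw)
}

log_line <- function(config, ...) {
  cat(paste0(..., "\n"), file = file.path(config$out_dir, "pipeline.log"),
      append = TRUE)
}

pipeline_paths <- function(config) {
  o <- config$out_dir
  list(screen = file.path(o, "screen_report.tsv"),
       con1 = file.path(o, "con1_regions.tsv"),
       arch = file.path(o, "architectures.tsv"),
       assign = file.path(o, "assignments.tsv"),
       dynamics = file.path(o, "taxon_summaries.json"),
       synteny = file.path(o, "synteny.tsv"),
       report_json = file.path(o, "report.json"),
       report_txt = file.path(o, "report.txt"))
}

load_stage_inputs <- function(config) {
  ins <- config$inputs
  for (f in c("fasta", "hits", "taxonomy", "reference")) {
    if (!file.exists(ins[[f]])) stop("missing input file: ", ins[[f]])
  }
  records <- parse_sequences(ins$fasta)
  list(records = records,
       hits = parse_domain_hits(ins$hits, ins$hits_dialect,
                                sequences = records),
       taxonomy = parse_taxonomy(ins$taxonomy),
       reference = parse_con1_reference(ins$reference))
}

#' Run pipeline stages
#'
#' @param config A [pipeline_config()].
#' @param stage One of `simulate`, `screen`, `con1`, `type`, `classify`,
#'   `dynamics`, `synteny`, `report`, or `all` to chain every stage
#'   (simulation only when `config$sim` is set).
#' @return Invisibly, the list of output paths.
#' @export
run_pipeline <- function(config, stage = "all") {
  stage <- match.arg(stage, PIPELINE_STAGES)
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  stages <- if (stage == "all") {
    c(if (!is.null(config$sim)) "simulate",
      "con1", "screen", "type", "classify", "dynamics", "synteny", "report")
  } else stage
  paths <- pipeline_paths(config)
  for (st in stages) {
    switch(st,
           simulate = stage_simulate(config),
           con1 = stage_con1(config, paths),
           screen = stage_screen(config, paths),
           type = stage_type(config, paths),
           classify = stage_classify(config, paths),
           dynamics = stage_dynamics(config, paths),
           synteny = stage_synteny(config, paths),
           report = stage_report(config, paths))
    log_line(config, "stage=", st, " seed=", config$seed,
             " n_reps=", config$n_reps,
             " support_threshold=", config$support_threshold)
  }
  invisible(paths)
}

stage_simulate <- function(config) {
  if (is.null(config$sim)) stop("simulate stage requires config$sim")
  ds <- simulate_family(config$sim)
  emit_dataset(ds, file.path(config$out_dir, "data"))
}

stage_con1 <- function(config, paths) {
  ins <- load_stage_inputs(config)
  con1 <- extract_con1_all(ins$records, con1_patterns(config$motif_set))
  write.table(con1_table(con1), paths$con1, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

stage_screen <- function(config, paths) {
  ins <- load_stage_inputs(config)
  con1 <- extract_con1_all(ins$records, con1_patterns(config$motif_set))
  res <- filter_candidates(ins$records, ins$hits, con1,
                           screen_config(evalue_max = config$evalue_max))
  write_screen_report(res, paths$screen)
}

stage_type <- function(config, paths) {
  ins <- load_stage_inputs(config)
  con1 <- extract_con1_all(ins$records, con1_patterns(config$motif_set))
  tab <- architecture_table(ins$records, ins$hits, con1)
  write.table(tab, paths$arch, sep = "\t", quote = FALSE, row.names = FALSE)
}

stage_classify <- function(config, paths) {
  ins <- load_stage_inputs(config)
  con1 <- extract_con1_all(ins$records, con1_patterns(config$motif_set))
  res <- filter_candidates(ins$records, ins$hits, con1,
                           screen_config(evalue_max = config$evalue_max))
  acc <- ins$records[res$accepted, , drop = FALSE]
  types_tab <- architecture_table(acc, ins$hits, con1)
  types <- setNames(types_tab$type_label, types_tab$protein_id)
  asn <- classify_species_set(acc, con1, types, ins$reference,
                              n_reps = config$n_reps, seed = config$seed,
                              threshold = config$support_threshold,
                              strict = config$strict_support)
  write_assignments(asn, paths$assign)
}

read_assignments <- function(paths) {
  if (!file.exists(paths$assign)) {
    stop("missing input file: ", paths$assign, " (run the classify stage)")
  }
  read.delim(paths$assign, stringsAsFactors = FALSE,
             colClasses = c(protein_id = "character",
                            species_id = "character"))
}

stage_dynamics <- function(config, paths) {
  ins <- load_stage_inputs(config)
  asn <- read_assignments(paths)
  prof <- profile_counts(asn, ins$taxonomy)
  taxa <- unique(c(ins$taxonomy$phylum, ins$taxonomy$subphylum))
  tags <- names(ins$taxonomy)[vapply(ins$taxonomy, is.logical, TRUE)]
  taxa <- c(taxa, tags[vapply(tags, function(t) any(ins$taxonomy[[t]]), TRUE)])
  summ <- lapply(taxa, function(t) {
    s <- taxon_summary(prof, ins$taxonomy, t)
    list(taxon = s$taxon, n_species = s$n_species, mean_chs = s$mean_chs,
         presence = as.data.frame(s$presence))
  })
  jsonlite::write_json(summ, paths$dynamics, auto_unbox = TRUE, digits = NA)
}

stage_synteny <- function(config, paths) {
  ins <- load_stage_inputs(config)
  asn <- read_assignments(paths)
  models <- parse_gene_models(config$inputs$gff)
  calls <- detect_head_to_head(models, asn,
                               max_intervening = config$max_intervening)
  write.table(calls, paths$synteny, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

stage_report <- function(config, paths) {
  asn <- read_assignments(paths)
  summ <- summarize_classification(asn)
  calls <- read.delim(paths$synteny, stringsAsFactors = FALSE)
  syn <- summarize_synteny(calls)
  rep <- list(classification = list(class_counts = as.list(summ$class_counts),
                                    total = summ$total,
                                    classified = summ$classified,
                                    excluded = summ$excluded_count),
              synteny = list(head_to_head_species = syn$head_to_head_species,
                             with_intervening = syn$with_intervening,
                             without_intervening = syn$without_intervening),
              parameters = list(seed = config$seed, n_reps = config$n_reps,
                                support_threshold = config$support_threshold))
  jsonlite::write_json(rep, paths$report_json, auto_unbox = TRUE, digits = NA)
  txt <- c("CHS family survey report",
           sprintf("proteins classified: %d of %d (excluded as noise: %d)",
                   summ$classified, summ$total, summ$excluded_count),
           sprintf("head-to-head ChsV/ChsVII species: %d (%d with an intervening gene, %d without)",
                   syn$head_to_head_species, syn$with_intervening,
                   syn$without_intervening))
  writeLines(txt, paths$report_txt)
}
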