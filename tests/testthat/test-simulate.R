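test_that("zero within-class divergence collapses each class to one sequence", {
  ds <- simulate_family(sim_config(seed = 5, n_species = 2,
                                   within_class_divergence = 0))
  con1 <- extract_con1_all(ds$proteins)
  truth <- ds$truth$proteins
  for (cls in c("I", "II", "V")) {
    pids <- truth$protein_id[truth$class == cls]
    seqs <- vapply(con1[pids], function(r) r$sequence, "")
    expect_equal(length(unique(seqs)), 1)
  }
})

test_that("simulation is byte-identical for a fixed config and seed", {
  cfg <- sim_config(seed = 33, n_species = 2)
  d1 <- simulate_family(cfg)
  d2 <- simulate_family(cfg)
  expect_identical(d1$proteins, d2$proteins)
  expect_identical(d1$domain_hits, d2$domain_hits)
  expect_identical(d1$gene_models, d2$gene_models)
  d3 <- simulate_family(sim_config(seed = 34, n_species = 2))
  expect_false(identical(d1$proteins$sequence, d3$proteins$sequence))
})

test_that("planted truth covers every protein and CON1 coordinates are exact", {
  ds <- small_sim()
  expect_setequal(ds$truth$proteins$protein_id, ds$proteins$protein_id)
  con1 <- extract_con1_all(ds$proteins)
  truth <- ds$truth$proteins
  for (i in seq_len(nrow(truth))) {
    r <- con1[[truth$protein_id[i]]]
    if (truth$class[i] == "decoy_motif_free") {
      expect_null(r)
    } else {
      expect_equal(r$start, truth$con1_start[i])
      expect_equal(r$end, truth$con1_end[i])
    }
  }
})

test_that("motif-free decoys lack a full motif complement by construction", {
  ds <- small_sim()
  truth <- ds$truth$proteins
  pids <- truth$protein_id[truth$class == "decoy_motif_free"]
  for (pid in pids) {
    s <- ds$proteins$sequence[ds$proteins$protein_id == pid]
    hits <- scan_motifs(s)
    expect_lt(length(unique(hits$motif_name)), 3)
  }
})

test_that("CON1 lengths sit inside the observed survey range", {
  ds <- small_sim()
  con1 <- extract_con1_all(ds$proteins)
  lens <- con1_table(con1)$length
  expect_true(all(lens >= 97 & lens <= 1200))
  expect_equal(unique(lens), 141)  # default region length is the survey mean
})

test_that("observed within-class divergence matches the configured expectation", {
  t_cfg <- 0.12
  ds <- simulate_family(sim_config(seed = 9, n_species = 6,
                                   within_class_divergence = t_cfg,
                                   n_ref_per_class = 2))
  con1 <- extract_con1_all(ds$proteins)
  truth <- ds$truth$proteins
  # pairs of same-class members across species; divergence measured on
  # mutable (non-motif) sites only, expectation from the closed form
  n_free <- 141 - 15
  p_exp <- expected_p_distance(t_cfg)
  ps <- c()
  for (cls in c("I", "II", "III", "IV", "V", "VII")) {
    pids <- truth$protein_id[truth$class == cls]
    if (length(pids) < 2) next
    combos <- utils::combn(pids, 2)
    for (k in seq_len(ncol(combos))) {
      a <- strsplit(con1[[combos[1, k]]]$sequence, "")[[1]]
      b <- strsplit(con1[[combos[2, k]]]$sequence, "")[[1]]
      mism <- sum(a != b)
      ps <- c(ps, mism / n_free)
      if (length(ps) >= 50) break
    }
    if (length(ps) >= 50) break
  }
  expect_gte(length(ps), 50)
  se <- sqrt(p_exp * (1 - p_exp) / n_free) / sqrt(length(ps))
  expect_lt(abs(mean(ps) - p_exp), 3 * se + 0.005)
})

test_that("emit/parse round trip reproduces the dataset", {
  ds <- small_sim()
  out <- tempfile()
  paths <- emit_dataset(ds, out)
  expect_true(all(file.exists(paths)))
  rec <- parse_sequences(paths[["fasta"]])
  expect_equal(rec[order(rec$protein_id), ]$sequence,
               ds$proteins[order(ds$proteins$protein_id), ]$sequence)
  hits <- parse_domain_hits(paths[["hits"]], "tsv", sequences = rec)
  expect_equal(nrow(hits), nrow(ds$domain_hits))
  gm <- parse_gene_models(paths[["gff"]])
  key <- c("gene_id", "protein_id", "contig", "start", "end", "strand",
           "exon_count")
  a <- gm[order(gm$gene_id), key]
  b <- ds$gene_models[order(ds$gene_models$gene_id), key]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
  ref <- parse_con1_reference(paths[["reference"]])
  expect_identical(ref$labels, ds$reference$labels)
  expect_identical(ref$alignment, ds$reference$alignment)
  tr <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_setequal(tr$proteins$protein_id, ds$proteins$protein_id)
})

test_that("inconsistent configurations are rejected or warned about", {
  expect_error(sim_config(repertoire = c(I = 1, bogus = 2)), "unknown class")
  expect_error(sim_config(repertoire = c(I = -1, II = 1, III = 1, IV = 1,
                                         V = 1, VI = 1, VII = 1)),
               "negative")
  expect_warning(sim_config(within_class_divergence = 0.9,
                            between_class_divergence = 0.1),
                 "identifiable")
  expect_error(sim_config(con1_length = 10), "too short")
})

test_that("V and VII genes always carry introns", {
  ds <- small_sim()
  truth <- ds$truth$proteins
  vids <- paste0("g_", truth$protein_id[truth$class %in% c("V", "VII")])
  gm <- ds$gene_models
  expect_true(all(gm$exon_count[gm$gene_id %in% vids] >= 2))
})
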