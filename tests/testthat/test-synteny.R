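mk_models <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_id = r[[1]], protein_id = r[[2]], contig = r[[3]],
               start = as.integer(r[[4]]), end = as.integer(r[[5]]),
               strand = r[[6]], exon_count = as.integer(r[[7]]),
               stringsAsFactors = FALSE)
  }))
}

mk_cls <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(protein_id = r[[1]], species_id = r[[2]], class_label = r[[3]],
               stringsAsFactors = FALSE)
  }))
}

test_that("divergent adjacent V/VII pairs are head-to-head", {
  models <- mk_models(list("gV", "pV", "c1", 1000, 3000, "-", 3),
                      list("gVII", "pVII", "c1", 3500, 6000, "+", 2))
  asn <- mk_cls(list("pV", "s1", "V"), list("pVII", "s1", "VII"))
  calls <- detect_head_to_head(models, asn)
  expect_equal(calls$arrangement, "head_to_head")
  expect_equal(calls$intervening_gene_count, 0L)
  expect_true(calls$both_have_introns)
  expect_false(calls$ambiguous)
})

test_that("same-strand, convergent, and split-contig pairs are not head-to-head", {
  asn <- mk_cls(list("pV", "s1", "V"), list("pVII", "s1", "VII"))
  same <- mk_models(list("gV", "pV", "c1", 1000, 3000, "+", 3),
                    list("gVII", "pVII", "c1", 3500, 6000, "+", 2))
  expect_equal(detect_head_to_head(same, asn)$arrangement, "same_strand")
  conv <- mk_models(list("gV", "pV", "c1", 1000, 3000, "+", 3),
                    list("gVII", "pVII", "c1", 3500, 6000, "-", 2))
  expect_equal(detect_head_to_head(conv, asn)$arrangement, "tail_to_tail")
  split <- mk_models(list("gV", "pV", "c1", 1000, 3000, "-", 3),
                     list("gVII", "pVII", "c2", 3500, 6000, "+", 2))
  expect_equal(detect_head_to_head(split, asn)$arrangement,
               "different_contig")
})

test_that("one intervening hypothetical gene is tolerated, more are not", {
  asn <- mk_cls(list("pV", "s1", "V"), list("pVII", "s1", "VII"))
  with1 <- mk_models(list("gV", "pV", "c1", 1000, 3000, "-", 3),
                     list("hyp", NA_character_, "c1", 3200, 3400, "+", 1),
                     list("gVII", "pVII", "c1", 3500, 6000, "+", 2))
  c1 <- detect_head_to_head(with1, asn)
  expect_equal(c1$arrangement, "head_to_head")
  expect_equal(c1$intervening_gene_count, 1L)

  with2 <- mk_models(list("gV", "pV", "c1", 1000, 3000, "-", 3),
                     list("h1", NA_character_, "c1", 3100, 3150, "+", 1),
                     list("h2", NA_character_, "c1", 3200, 3300, "+", 1),
                     list("gVII", "pVII", "c1", 3500, 6000, "+", 2))
  c2 <- detect_head_to_head(with2, asn)
  expect_equal(c2$arrangement, "distant")
  expect_equal(c2$intervening_gene_count, 2L)
  # configurable allowance
  c3 <- detect_head_to_head(with2, asn, max_intervening = 2)
  expect_equal(c3$arrangement, "head_to_head")
})

test_that("arrangement calls are invariant under swapping V and VII labels", {
  models <- mk_models(list("gA", "pA", "c1", 1000, 3000, "-", 3),
                      list("gB", "pB", "c1", 3500, 6000, "+", 2))
  a1 <- detect_head_to_head(models, mk_cls(list("pA", "s1", "V"),
                                           list("pB", "s1", "VII")))
  a2 <- detect_head_to_head(models, mk_cls(list("pA", "s1", "VII"),
                                           list("pB", "s1", "V")))
  expect_equal(a1$arrangement, a2$arrangement)
  expect_equal(a1$intervening_gene_count, a2$intervening_gene_count)
})

test_that("multiple V or VII copies yield per-pair ambiguous calls", {
  models <- mk_models(list("gV1", "pV1", "c1", 1000, 3000, "-", 3),
                      list("gV2", "pV2", "c1", 9000, 11000, "+", 3),
                      list("gVII", "pVII", "c1", 3500, 6000, "+", 2))
  asn <- mk_cls(list("pV1", "s1", "V"), list("pV2", "s1", "V"),
                list("pVII", "s1", "VII"))
  calls <- detect_head_to_head(models, asn)
  expect_equal(nrow(calls), 2)
  expect_true(all(calls$ambiguous))
})

test_that("intron status follows exon counts", {
  expect_true(intron_status(3L))
  expect_false(intron_status(1L))
  expect_true(is.na(intron_status(NA_integer_)))
})

test_that("planted head-to-head pairs are recovered with no false positives", {
  sc <- small_screened()
  truth <- sc$ds$truth
  asn <- truth$proteins[truth$proteins$class %in% c("V", "VII"), ]
  asn$class_label <- asn$class
  calls <- detect_head_to_head(sc$ds$gene_models, asn)
  syn <- summarize_synteny(calls)
  m <- merge(calls, truth$synteny, by = "species_id")
  planted_hh <- m$planted == "head_to_head"
  expect_true(all(m$arrangement[planted_hh] == "head_to_head"))
  expect_true(all(m$arrangement[!planted_hh] != "head_to_head"))
  expect_equal(m$intervening_gene_count[planted_hh], m$intervening[planted_hh])
  expect_true(all(m$both_have_introns[planted_hh]))
  expect_equal(syn$with_intervening + syn$without_intervening,
               syn$head_to_head_species)
})
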