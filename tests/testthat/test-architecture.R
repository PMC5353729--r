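mk_hits <- function(pid, ...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(protein_id = pid, accession = r[[1]],
               start = as.integer(r[[2]]), end = as.integer(r[[3]]),
               score = as.numeric(r[[4]]),
               evalue = 1e-20, stringsAsFactors = FALSE)
  }))
}

mk_region <- function(start, end) {
  structure(list(protein_id = "p", start = start, end = end,
                 sequence = strrep("A", end - start), motif_hits = NULL),
            class = "con1_region")
}

test_that("ordered architectures assemble from hits plus the CON1 token", {
  hits <- mk_hits("p", list("PF08407", 10, 80, 60),
                  list("PF01644", 100, 300, 150),
                  list("PF03142", 320, 440, 40))  # remnant inside CON1
  arch <- build_architecture("p", hits, mk_region(310, 450))
  expect_equal(arch$elements, c("PF08407", "PF01644", "CON1"))
})

test_that("overlapping same-accession hits merge; cross-accession overlap resolves by score", {
  hits <- mk_hits("p", list("PF03142", 300, 400, 90),
                  list("PF03142", 380, 500, 80))
  arch <- build_architecture("p", hits, NULL)
  expect_equal(arch$elements, "PF03142")
  expect_equal(arch$intervals$start, 300L)
  expect_equal(arch$intervals$end, 500L)

  hits2 <- mk_hits("p", list("PF00173", 100, 200, 30),
                   list("PF00063", 150, 400, 55))
  arch2 <- build_architecture("p", hits2, NULL)
  expect_equal(arch2$elements, "PF00063")
})

test_that("a CON1 region inside an intact PF03142 does not emit the token", {
  hits <- mk_hits("p", list("PF03142", 100, 500, 200))
  arch <- build_architecture("p", hits, mk_region(200, 380))
  expect_equal(arch$elements, "PF03142")
})

test_that("auxiliary domains are recorded but never typed", {
  hits <- mk_hits("p", list("PF03142", 100, 500, 200),
                  list("PF07690", 600, 700, 25))
  arch <- build_architecture("p", hits, NULL)
  expect_equal(arch$elements, "PF03142")
  expect_equal(arch$auxiliary, "PF07690")
  expect_equal(assign_structure_type(arch)$type_label, "B1")
})

test_that("the Group/Type table matches the published architectures", {
  expect_equal(assign_structure_type(c("PF08407", "PF01644", "CON1"))$type_label, "A2")
  expect_equal(assign_structure_type(c("PF01644", "CON1"))$type_label, "A1")
  expect_equal(assign_structure_type(
    c("PF08407", "PF01644", "CON1", "PF03142"))$type_label, "A3")
  expect_equal(assign_structure_type(
    c("PF00063", "PF00173", "PF03142", "PF08766"))$type_label, "B4")
  expect_equal(assign_structure_type(
    c("PF00063", "PF03142", "PF08766"))$type_label, "B3")
  expect_equal(assign_structure_type(c("PF03142", "PF00173"))$type_label, "B2")
  expect_equal(assign_structure_type("PF03142")$type_label, "B1")
  expect_equal(assign_structure_type(character(0))$type_label, "other")
  ty <- assign_structure_type(c("PF08407", "PF01644", "CON1"))
  expect_equal(ty$group, "A")
  expect_equal(assign_structure_type("PF03142")$group, "B")
})

test_that("typing is order-insensitive except the stated constraints", {
  # B4 in any order stays B4
  expect_equal(assign_structure_type(
    c("PF08766", "PF03142", "PF00173", "PF00063"))$type_label, "B4")
  # Group A requires PF01644 immediately followed by CON1
  expect_equal(assign_structure_type(
    c("PF01644", "PF08407", "CON1"))$type_label, "other")
  # A3 requires its intact PF03142 after CON1
  expect_equal(assign_structure_type(
    c("PF03142", "PF08407", "PF01644", "CON1"))$type_label, "other")
})

test_that("planted architectures are recovered exactly on synthetic data", {
  sc <- small_screened()
  truth <- sc$ds$truth$proteins
  m <- merge(sc$arch, truth, by = "protein_id")
  expect_true(all(m$type_label.x == m$type_label.y))
})
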