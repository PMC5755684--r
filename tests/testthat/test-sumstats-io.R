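test_that("a well-formed file parses to a validated study table", {
  dir <- withr::local_tempdir()
  path <- write_study_fixture(dir, "ok", c(
    "rs1 1 1000 A G 0.30 5000 0.021 0.011",
    "rs2 1 2000 T C 0.52 5000 -0.007 0.010"))
  st <- read_study_file(path, study_id = "ok")
  expect_s3_class(st, "study_table")
  expect_equal(nrow(st), 2)
  expect_equal(st$beta, c(0.021, -0.007))
  expect_equal(attr(st, "study_id"), "ok")
  qc <- attr(st, "qc")
  expect_equal(qc$n[qc$reason == "rows_kept"], 2)
})

test_that("invalid rows are dropped and counted, not fatal", {
  dir <- withr::local_tempdir()
  path <- write_study_fixture(dir, "bad", c(
    "rs1 1 1000 A G 0.30 5000 0.021 0.011",
    "rs2 1 2000 T C 0.52 5000 -0.007 0",       # se = 0
    "rs3 1 3000 A C 1.40 5000 0.003 0.010",    # eaf out of range
    "rs4 1 4000 A A 0.20 5000 0.001 0.010",    # ea == nea
    "rs5 1 5000 G T 0.20 5000 xyz 0.010"))     # unparseable beta
  st <- read_study_file(path)
  expect_equal(nrow(st), 1)
  qc <- attr(st, "qc")
  get <- function(r) qc$n[qc$reason == r]
  expect_equal(get("se_nonpositive"), 1)
  expect_equal(get("eaf_out_of_range"), 1)
  expect_equal(get("allele_invalid"), 1)
  expect_equal(get("bad_numeric"), 1)
})

test_that("a missing required column is a fatal error naming the column", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "nose.txt")
  writeLines(c("MARKERNAME CHR POS EA NEA EAF N BETA",
               "rs1 1 1000 A G 0.30 5000 0.021"), path)
  expect_error(read_study_file(path), "se")
})

test_that("duplicate markers keep the first occurrence with a warning", {
  dir <- withr::local_tempdir()
  path <- write_study_fixture(dir, "dup", c(
    "rs1 1 1000 A G 0.30 5000 0.021 0.011",
    "rs1 1 1000 A G 0.31 5000 0.022 0.011"))
  expect_warning(st <- read_study_file(path), "duplicate")
  expect_equal(st$eaf, 0.30)
})

test_that("column remapping and gzip input are supported", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "m.txt.gz")
  con <- gzfile(path, "w")
  writeLines(c("SNPID CHR POS A1 A2 FRQ NTOT B STDERR",
               "rs1 1 1000 A G 0.30 5000 0.021 0.011"), con)
  close(con)
  st <- read_study_file(path, column_map = c(marker = "SNPID", ea = "A1",
                                             nea = "A2", eaf = "FRQ",
                                             n = "NTOT"))
  expect_equal(st$marker, "rs1")
})

test_that("allele harmonisation flips and rejects as specified", {
  same <- harmonize_alleles("A", "G", 0.1, 0.3, "A", "G")
  expect_equal(same$status, "ok")
  expect_equal(same$beta, 0.1)
  flip <- harmonize_alleles("G", "A", 0.1, 0.3, "A", "G")
  expect_equal(flip$status, "flipped")
  expect_equal(flip$beta, -0.1)
  expect_equal(flip$eaf, 0.7)
  bad <- harmonize_alleles("C", "T", 0.1, 0.3, "A", "G")
  expect_equal(bad$status, "allele_mismatch")
  expect_true(is.na(bad$beta))
})

test_that("flipping a record twice restores the original values", {
  set.seed(7)
  for (i in 1:20) {
    b <- rnorm(1); f <- runif(1)
    once <- harmonize_alleles("G", "A", b, f, "A", "G")
    twice <- harmonize_alleles("A", "G", once$beta, once$eaf, "G", "A")
    expect_equal(twice$beta, b, tolerance = 1e-12)
    expect_equal(twice$eaf, f, tolerance = 1e-12)
  }
})

test_that("panel assembly aligns swapped alleles to the first study's reference", {
  panel <- fixture_panel()
  expect_equal(length(panel$studies), 3)
  expect_equal(nrow(panel$variants), 3)
  expect_true(all(panel$present))
  # study2's rs2 row was (EA=T, NEA=C, beta=0.03, eaf=0.45) vs reference (C,T)
  j <- which(panel$variants$position == 1500000)
  manual <- harmonize_alleles("T", "C", 0.03, 0.45, "C", "T")
  expect_equal(unname(panel$beta[j, 2]), manual$beta)
  expect_equal(unname(panel$eaf[j, 2]), manual$eaf)
  # marker names come from the first study carrying the variant
  expect_equal(panel$variants$marker[j], "rs2")
})

test_that("assembly is order-insensitive up to the reference allele choice", {
  files <- fixture_study_files()
  tabs <- lapply(files, read_study_file)
  p1 <- assemble_panel(tabs)
  p2 <- assemble_panel(rev(tabs))
  # re-align p2 to p1's reference alleles and compare study-by-study
  key <- function(p) paste(p$variants$chromosome, p$variants$position)
  m <- match(key(p1), key(p2))
  for (k in seq_along(p1$studies)) {
    k2 <- match(p1$studies[k], p2$studies)
    h <- harmonize_alleles(p2$variants$ea[m], p2$variants$nea[m],
                           p2$beta[m, k2], p2$eaf[m, k2],
                           p1$variants$ea, p1$variants$nea)
    expect_equal(h$beta, unname(p1$beta[, k]))
    expect_equal(h$eaf, unname(p1$eaf[, k]))
  }
})

test_that("fewer than three studies is fatal", {
  files <- fixture_study_files()
  tabs <- lapply(files[1:2], read_study_file)
  expect_error(assemble_panel(tabs), "3 studies")
})

test_that("variants missing from one study keep a presence flag", {
  dir <- withr::local_tempdir()
  f1 <- write_study_fixture(dir, "s1", c("rs1 1 1000 A G 0.3 1000 0.1 0.1",
                                         "rs2 1 2000 C T 0.4 1000 0.1 0.1"))
  f2 <- write_study_fixture(dir, "s2", c("rs1 1 1000 A G 0.3 1000 0.1 0.1"))
  f3 <- write_study_fixture(dir, "s3", c("rs1 1 1000 A G 0.3 1000 0.1 0.1",
                                         "rs2 1 2000 C T 0.4 1000 0.1 0.1"))
  panel <- assemble_panel(lapply(c(f1, f2, f3), read_study_file))
  j <- which(panel$variants$position == 2000)
  expect_equal(unname(panel$present[j, ]), c(TRUE, FALSE, TRUE))
  expect_equal(panel$variants$n_studies[j], 2)
})

test_that("presence filter retains variants by summed sample-size fraction", {
  dir <- withr::local_tempdir()
  # rs2 present only in the small study pair: 2000 of 12000 total (17%)
  f1 <- write_study_fixture(dir, "s1", c("rs1 1 1000 A G 0.3 5000 0.1 0.1"))
  f2 <- write_study_fixture(dir, "s2", c("rs1 1 1000 A G 0.3 5000 0.1 0.1",
                                         "rs2 1 2000 C T 0.4 1000 0.1 0.1"))
  f3 <- write_study_fixture(dir, "s3", c("rs1 1 1000 A G 0.3 1000 0.1 0.1",
                                         "rs2 1 2000 C T 0.4 1000 0.1 0.1"))
  panel <- assemble_panel(lapply(c(f1, f2, f3), read_study_file))
  kept <- presence_filter(panel, 0.5)
  expect_equal(kept$variants$marker, "rs1")
  # a vanishing threshold is the identity
  all_kept <- presence_filter(panel, 1e-9)
  expect_equal(nrow(all_kept$variants), nrow(panel$variants))
  # full-coverage panel is unchanged at threshold 0.8
  p <- fixture_panel()
  expect_equal(nrow(presence_filter(p, 0.8)$variants), nrow(p$variants))
})

test_that("strand-ambiguous variants are flagged, not resolved", {
  dir <- withr::local_tempdir()
  path <- write_study_fixture(dir, "amb", c(
    "rs1 1 1000 A T 0.30 5000 0.021 0.011",
    "rs2 1 2000 C G 0.52 5000 -0.007 0.010",
    "rs3 1 3000 A G 0.52 5000 -0.007 0.010"))
  st <- read_study_file(path)
  expect_equal(st$ambiguous, c(TRUE, TRUE, FALSE))
})
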