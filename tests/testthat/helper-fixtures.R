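# In-code fixtures: small summary-statistic files and panels.

write_study_fixture <- function(dir, study, rows,
                                header = "MARKERNAME CHR POS EA NEA EAF N BETA SE") {
  path <- file.path(dir, paste0(study, ".txt"))
  writeLines(c(header, rows), path)
  path
}

# three overlapping studies; study2 carries rs2 with swapped alleles
fixture_study_files <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("fixtures")
    dir.create(dir)
  }
  f1 <- write_study_fixture(dir, "study1", c(
    "rs1 1 500000 A G 0.30 4000 0.050 0.020",
    "rs2 1 1500000 C T 0.60 4000 -0.020 0.021",
    "rs3 2 700000 G A 0.45 4000 0.010 0.019"))
  f2 <- write_study_fixture(dir, "study2", c(
    "rs1 1 500000 A G 0.35 3000 0.060 0.025",
    "rs2b 1 1500000 T C 0.45 3000 0.030 0.024",
    "rs3 2 700000 G A 0.40 3000 0.000 0.023"))
  f3 <- write_study_fixture(dir, "study3", c(
    "rs1 1 500000 A G 0.25 5000 0.040 0.018",
    "rs2 1 1500000 C T 0.55 5000 -0.010 0.017",
    "rs3 2 700000 G A 0.50 5000 0.020 0.016"))
  c(f1, f2, f3)
}

fixture_panel <- function() {
  files <- fixture_study_files()
  assemble_panel(lapply(files, read_study_file))
}

# a random complete panel for property checks
random_panel <- function(V = 20, K = 6, seed = 42) {
  set.seed(seed)
  beta <- matrix(rnorm(V * K, 0, 0.05), V, K)
  var <- matrix(runif(V * K, 5e-4, 5e-3), V, K)
  eaf <- matrix(runif(V * K, 0.1, 0.9), V, K)
  panel_from_matrices(beta, var, eaf, n = 4000)
}
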