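test_that("scenario specifications honour their group constraints", {
  pops <- kgp_populations()
  hom <- scenario_spec("homogeneous")
  expect_equal(hom$psi, rep(1.10, 26))
  afr <- scenario_spec("african_specific")
  expect_true(all(afr$psi[afr$group == "AFR"] == 1.25))
  expect_true(all(afr$psi[afr$group != "AFR"] == 1))
  eur <- scenario_spec("eurasian")
  expect_true(all(eur$psi[eur$group == "AFR"] == 1))
  expect_true(all(eur$psi[eur$group == "EAS"] == 1.10))
  expect_equal(unique(eur$psi[eur$group %in% c("EUR", "SAS", "AMR")]),
               sqrt(1.10))
  nat <- scenario_spec("native_american", seed = 1)
  expect_true(all(nat$psi[nat$group != "AMR"] == 1))
  expect_true(all(nat$psi[nat$group == "AMR"] >= 1.15 &
                    nat$psi[nat$group == "AMR"] <= 1.30))
  rnd <- scenario_spec("non_ancestral", seed = 2)
  for (g in unique(pops$group))
    expect_equal(sum(rnd$psi[rnd$group == g] == 1.35), 1)
  expect_true(all(rnd$psi %in% c(1, 1.35)))
  expect_equal(scenario_spec("null")$psi, rep(1, 26))
})

test_that("frequency draws are seeded, bounded and collapse in the no-drift limit", {
  a <- draw_population_frequencies(50, seed = 9)
  b <- draw_population_frequencies(50, seed = 9)
  expect_identical(a, b)                      # determinism contract
  expect_true(all(a > 0 & a < 1))
  expect_true(all(pmin(a, 1 - a) > 0.01))     # MAF floor enforced
  lim <- draw_population_frequencies(30, fst_between = 1e-6,
                                     fst_within = 1e-6, seed = 10)
  expect_lt(max(abs(sweep(lim, 2, attr(lim, "ancestral")))), 0.01)
})

test_that("between-group frequency variance matches the drift parameter", {
  set.seed(33)
  # one population per group isolates the between-group component
  pops <- data.frame(pop = letters[1:5], group = LETTERS[1:5])
  P <- draw_population_frequencies(4000, pops, fst_between = 0.1,
                                   fst_within = 1e-6, maf_min = 1e-4)
  p0 <- attr(P, "ancestral")
  ratio <- apply(P, 2, stats::var) / (p0 * (1 - p0))
  expect_equal(mean(ratio), 0.1, tolerance = 0.1)
})

test_that("case-control genotypes follow HWE with odds-ratio tilted cases", {
  set.seed(34)
  nullsim <- simulate_case_control(rep(0.3, 2000), psi = 1,
                                   n_cases = 500, n_controls = 500)
  expect_equal(colMeans(nullsim$cases) / 500,
               colMeans(nullsim$controls) / 500, tolerance = 0.02)
  expect_true(all(rowSums(nullsim$cases) == 500))
  # vanishing frequency: everyone homozygous reference
  rare <- simulate_case_control(1e-9, psi = 2, n_cases = 100,
                                n_controls = 100)
  expect_equal(unname(rare$cases), cbind(100, 0, 0))
  # enumeration oracle for the case allele frequency at psi = 1.25, p = 0.3
  p <- 0.3; psi <- 1.25
  hwe <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  wts <- hwe * psi^(0:2)
  expected <- sum((0:2) * wts) / (2 * sum(wts))
  big <- simulate_case_control(p, psi, n_cases = 2e5, n_controls = 10)
  observed <- sum(big$cases * rep(0:2, each = 1)) / (2 * 2e5)
  expect_equal(observed, expected, tolerance = 0.005)
})

test_that("vectorised logistic fit matches glm and scales like Fisher information", {
  cases <- rbind(c(350, 450, 200), c(120, 260, 220), c(480, 95, 25))
  ctrls <- rbind(c(490, 420, 90), c(200, 250, 150), c(430, 140, 30))
  f <- logistic_association(cases, ctrls)
  for (i in 1:3) {
    d <- data.frame(g = rep(0:2, 2), y = rep(1:0, each = 3),
                    w = c(cases[i, ], ctrls[i, ]))
    gm <- stats::glm(y ~ g, binomial, d, weights = w)
    expect_equal(f$beta[i], unname(coef(gm)[2]), tolerance = 1e-8)
    expect_equal(f$se[i], sqrt(vcov(gm)[2, 2]), tolerance = 1e-6)
  }
  # doubling all counts halves the squared standard error
  f2 <- logistic_association(2 * cases, 2 * ctrls)
  expect_equal(f2$se^2, f$se^2 / 2, tolerance = 1e-6)
  expect_equal(f2$beta, f$beta, tolerance = 1e-8)
})

test_that("balanced tables give a null estimate; degenerate tables are flagged", {
  bal <- logistic_association(c(250, 500, 250), c(250, 500, 250))
  expect_equal(bal$beta, 0, tolerance = 1e-10)
  sep <- logistic_association(c(0, 0, 100), c(100, 0, 0))
  expect_false(sep$ok)
  expect_true(is.na(sep$beta))
  const <- logistic_association(c(100, 0, 0), c(100, 0, 0))
  expect_false(const$ok)
})

test_that("genotype matrices collapse to the same counts the fit consumes", {
  set.seed(35)
  g <- sample(0:2, 300, replace = TRUE, prob = c(0.5, 0.4, 0.1))
  y <- rep(c(TRUE, FALSE), 150)
  cnt <- counts_from_genotypes(g, y)
  expect_equal(sum(cnt$cases) + sum(cnt$controls), 300)
  expect_equal(unname(cnt$cases[1, ]), unname(table(factor(g[y], 0:2))),
               ignore_attr = TRUE)
})

test_that("locus haplotypes reduce to ancestral copies without switching or mutation", {
  loc <- simulate_locus(n_variants = 20, ancestral_panel_size = 40,
                        group_bottleneck = 40, pop_bottleneck = 40,
                        switch_rate = 0, mutation_rate = 0,
                        n_haplotypes = 30, seed = 36)
  anc_keys <- apply(loc$ancestral, 1, paste, collapse = "")
  for (hp in loc$haplotypes[c("YRI", "CEU", "JPT")])
    expect_true(all(apply(hp, 1, paste, collapse = "") %in% anc_keys))
})

test_that("locus LD decays with distance and groups differentiate", {
  loc <- simulate_locus(n_variants = 80, n_haplotypes = 400, seed = 37)
  h <- loc$haplotypes[["GBR"]]
  poly <- apply(h, 2, stats::sd) > 0
  r2 <- suppressWarnings(stats::cor(h[, poly])^2)
  d <- abs(outer(loc$positions[poly], loc$positions[poly], "-"))
  ut <- upper.tri(d)
  med <- tapply(r2[ut], cut(d[ut], c(0, 5e4, 2e5, 1e6)), stats::median,
                na.rm = TRUE)
  expect_true(all(diff(med) < 0))
  # distinct ancestry groups show positive frequency differentiation
  fr <- loc$frequencies
  cross <- mean((fr["YRI", ] - fr["CEU", ])^2)
  within <- mean((fr["CEU", ] - fr["GBR", ])^2)
  expect_gt(cross, 1e-4)
  expect_gt(cross, within)
  # causal variant is common everywhere and mid-locus
  expect_true(all(pmin(fr[, loc$causal], 1 - fr[, loc$causal]) > 0.01))
  expect_lt(abs(loc$positions[loc$causal] - 5e5), 2.5e5)
})

test_that("experiment runners are deterministic under a fixed seed", {
  e1 <- run_power_experiment("null", n_replicates = 25, seed = 7)
  e2 <- run_power_experiment("null", n_replicates = 25, seed = 7)
  expect_identical(e1$pvalues, e2$pvalues)
  expect_identical(e1$rates, e2$rates)
  f1 <- run_finemap_experiment("homogeneous", n_replicates = 2,
                               n_variants = 12, seed = 8)
  f2 <- run_finemap_experiment("homogeneous", n_replicates = 2,
                               n_variants = 12, seed = 8)
  expect_identical(f1$metrics, f2$metrics)
  expect_true(all(f1$per_replicate$causal_posterior >= 0 &
                    f1$per_replicate$causal_posterior <= 1, na.rm = TRUE))
  expect_equal(f1$metrics$coverage,
               colMeans(f1$per_replicate$covered, na.rm = TRUE),
               ignore_attr = TRUE)
})

test_that("all five aggregate tests hold their size under the global null", {
  ex <- run_power_experiment("null", n_replicates = 1000, seed = 44)
  band <- 3 * sqrt(0.05 * 0.95 / ex$n_used)
  for (i in seq_len(nrow(ex$rates)))
    expect_lt(abs(ex$rates$rate_nominal[i] - 0.05), band)
})

test_that("power ordering across heterogeneity scenarios matches expectation", {
  sep <- function(ex, a, b, col = "rate_gws") {
    r <- ex$rates
    (r[[col]][r$test == a] - r[[col]][r$test == b]) /
      sqrt(r[[sub("rate", "se", col)]][r$test == a]^2 +
             r[[sub("rate", "se", col)]][r$test == b]^2 + 1e-12)
  }
  afr <- run_power_experiment("african_specific", 1000, seed = 45)
  nat <- run_power_experiment("native_american", 1000, seed = 46)
  # ancestry-correlated effects: meta-regression beats fixed effects
  expect_gt(sep(afr, "mr_assoc", "fe"), 5)
  expect_gt(sep(nat, "mr_assoc", "fe"), 5)
  # ancestry-heterogeneity test beats Cochran's Q (off the rate ceiling:
  # genome-wide threshold for the strong African-specific signal, nominal
  # for the Native-American one)
  expect_gt(sep(afr, "mr_anc_het", "cochran_q", "rate_gws"), 5)
  expect_gt(sep(nat, "mr_anc_het", "cochran_q", "rate_nominal"), 5)
  # homogeneous effects: fixed effects at least as powerful
  hom <- run_power_experiment("homogeneous", 1000, seed = 47)
  expect_gte(sep(hom, "fe", "mr_assoc"), 0)
})
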