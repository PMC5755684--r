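# Seeded simulation engine: hierarchical drifted allele frequencies,
# Hardy-Weinberg case-control genotypes under population-specific odds
# ratios, vectorised additive logistic fits, mosaic locus haplotypes with
# population-specific LD, and the power / type-I / fine-mapping experiment
# runners.

#' Reference population panel: 26 populations in 5 ancestry groups
#'
#' The population labels and continental group assignment of the 1000
#' Genomes Project Phase 3 panel (African, East Asian, European, admixed
#' American / Native American, South Asian), the configuration used
#' throughout the simulation experiments.
#'
#' @return Data frame with columns `pop` and `group`.
#' @export
kgp_populations <- function() {
  data.frame(
    pop = c("ACB", "ASW", "ESN", "GWD", "LWK", "MSL", "YRI",
            "CDX", "CHB", "CHS", "JPT", "KHV",
            "CEU", "FIN", "GBR", "IBS", "TSI",
            "CLM", "MXL", "PEL", "PUR",
            "BEB", "GIH", "ITU", "PJL", "STU"),
    group = rep(c("AFR", "EAS", "EUR", "AMR", "SAS"), c(7, 5, 5, 4, 5)))
}

#' Define a heterogeneity scenario of population-specific odds ratios
#'
#' Builds the per-population allelic odds-ratio vector for one of the
#' simulation scenarios for heterogeneity of the causal-variant effect
#' across ancestry groups:
#' \describe{
#'   \item{null}{no effect anywhere (odds ratio 1).}
#'   \item{homogeneous}{the same odds ratio (default 1.10) in every
#'     population.}
#'   \item{african_specific}{effect (default 1.25) confined to African
#'     populations.}
#'   \item{eurasian}{no effect in African populations; odds ratio (default
#'     1.10) in East Asian populations and its square root in European,
#'     South Asian and Native American populations.}
#'   \item{native_american}{effect confined to Native American / admixed
#'     American populations, heterogeneous between them: per-population odds
#'     ratios drawn uniformly from [1.15, 1.30].}
#'   \item{non_ancestral}{effect (default 1.35) in exactly one randomly
#'     chosen population per ancestry group.}
#' }
#' The default magnitudes are the per-scenario odds ratios giving roughly
#' 80% meta-regression power at genome-wide significance in the fine-mapping
#' experiments; all are overridable via `psi_base` or a full `psi` vector.
#'
#' @param name scenario name (see above).
#' @param psi_base scalar effect magnitude overriding the scenario default.
#' @param psi optional full per-population odds-ratio vector (overrides
#'   everything else).
#' @param populations population panel data frame (`pop`, `group`).
#' @param seed optional seed for the scenarios that draw odds ratios at
#'   random.
#' @return A `scenario_spec`: data frame `pop`, `group`, `psi` with
#'   attribute `name`.
#' @export
scenario_spec <- function(name = c("null", "homogeneous", "african_specific",
                                   "eurasian", "native_american",
                                   "non_ancestral"),
                          psi_base = NULL, psi = NULL,
                          populations = kgp_populations(), seed = NULL) {
  name <- match.arg(name)
  if (!is.null(seed)) set.seed(seed)
  g <- populations$group
  K <- nrow(populations)
  if (is.null(psi)) {
    psi <- rep(1, K)
    if (name == "homogeneous") {
      psi[] <- psi_base %||% 1.10
    } else if (name == "african_specific") {
      psi[g == "AFR"] <- psi_base %||% 1.25
    } else if (name == "eurasian") {
      b <- psi_base %||% 1.10
      psi[g == "EAS"] <- b
      psi[g %in% c("EUR", "SAS", "AMR")] <- sqrt(b)
    } else if (name == "native_american") {
      lo <- 1.15; hi <- psi_base %||% 1.30
      psi[g == "AMR"] <- stats::runif(sum(g == "AMR"), lo, hi)
    } else if (name == "non_ancestral") {
      b <- psi_base %||% 1.35
      for (gr in unique(g)) {
        i <- which(g == gr)
        psi[i[sample.int(length(i), 1)]] <- b
      }
    }
  }
  stopifnot(length(psi) == K, all(psi > 0))
  structure(data.frame(pop = populations$pop, group = g, psi = psi),
            name = name, class = c("scenario_spec", "data.frame"))
}

# Balding-Nichols drift step: Beta with mean p, variance fst * p * (1 - p)
.rbn <- function(p, fst) {
  if (fst <= 0) return(p)
  stats::rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
}

# relative branch lengths (at fst_between = 0.10) of the continental drift
# tree: AFR splits at the root; out-of-Africa bottleneck; a West-Eurasian
# branch carrying EUR and SAS and an East branch carrying EAS and AMR, the
# latter with strong founder drift
.DRIFT_TREE <- c(afr = 0.05, ooa = 0.05, west = 0.02, east = 0.03,
                 eur = 0.01, sas = 0.02, eas = 0.02, amr = 0.06)

# group-level frequencies for one batch of markers (ancestral vector anc)
.group_frequencies <- function(anc, groups, fst_between) {
  canonical <- setequal(groups, c("AFR", "EAS", "EUR", "AMR", "SAS"))
  if (canonical) {
    b <- .DRIFT_TREE * (fst_between / 0.10)
    ooa <- .rbn(anc, b["ooa"])
    west <- .rbn(ooa, b["west"])
    east <- .rbn(ooa, b["east"])
    gf <- rbind(AFR = .rbn(anc, b["afr"]), EUR = .rbn(west, b["eur"]),
                SAS = .rbn(west, b["sas"]), EAS = .rbn(east, b["eas"]),
                AMR = .rbn(east, b["amr"]))
    gf[groups, , drop = FALSE]
  } else {
    # star-shaped drift: every group independently around the ancestor
    matrix(.rbn(rep(anc, each = length(groups)), fst_between),
           length(groups), length(anc), dimnames = list(groups, NULL))
  }
}

#' Draw drifted per-population allele frequencies
#'
#' Hierarchical Balding-Nichols model emulating the continental structure of
#' a worldwide reference panel: for each marker an ancestral frequency is
#' drawn uniformly on (0.05, 0.95); ancestry-group frequencies drift from it
#' by Beta (Balding-Nichols) steps with variance `fst * p * (1 - p)`; and
#' each population's frequency drifts around its group value with
#' `fst_within`. For the canonical five continental groups the group-level
#' drift follows a fixed tree mirroring human demographic history — African
#' populations split at the root, the remaining groups share an
#' out-of-Africa bottleneck, European and South Asian groups share a western
#' branch, East Asian and Native American / admixed American groups an
#' eastern branch with strong founder drift into the Americas — so that
#' three axes of genetic variation suffice to separate the five groups, as
#' in the reference panel the model emulates. Branch lengths scale
#' proportionally with `fst_between` (at the default 0.10 the implied
#' pairwise group F_ST is about 0.13 AFR-EUR, 0.08 EUR-EAS, 0.03 EUR-SAS and
#' 0.08 EAS-AMR, in line with published human estimates). Panels whose
#' groups are not the canonical five use star-shaped group drift with
#' variance `fst_between * p0 * (1 - p0)` directly.
#'
#' Markers are rejection-resampled until the minor allele frequency exceeds
#' `maf_min` in every population.
#'
#' @param n_markers number of markers to draw.
#' @param populations population panel data frame (`pop`, `group`).
#' @param fst_between group-level drift scale in (0, 1); default 0.10.
#' @param fst_within within-group drift in (0, 1); default 0.02.
#' @param maf_min minimum per-population minor allele frequency
#'   (default 0.01).
#' @param seed optional RNG seed.
#' @return K-by-`n_markers` matrix of effect-allele frequencies (rows named
#'   by population) with attribute `ancestral` (the ancestral frequencies).
#' @export
draw_population_frequencies <- function(n_markers, populations = kgp_populations(),
                                        fst_between = 0.10, fst_within = 0.02,
                                        maf_min = 0.01, seed = NULL) {
  stopifnot(fst_between > 0, fst_between < 1, fst_within > 0, fst_within < 1,
            n_markers >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- populations$group
  groups <- unique(g)
  K <- nrow(populations)
  P <- matrix(NA_real_, K, n_markers, dimnames = list(populations$pop, NULL))
  p0 <- numeric(n_markers)
  todo <- seq_len(n_markers)
  attempts <- 0L
  while (length(todo)) {
    attempts <- attempts + 1L
    if (attempts > 1e4) stop("could not satisfy MAF > ", maf_min,
                             " in all populations after 10000 attempts")
    m <- length(todo)
    anc <- stats::runif(m, 0.05, 0.95)
    gf <- .group_frequencies(anc, groups, fst_between)
    pf <- matrix(.rbn(rep(gf[match(g, groups), ], 1), fst_within), K, m)
    ok <- apply(pmin(pf, 1 - pf) > maf_min, 2, all)
    if (any(ok)) {
      P[, todo[ok]] <- pf[, ok]
      p0[todo[ok]] <- anc[ok]
      todo <- todo[!ok]
    }
  }
  attr(P, "ancestral") <- p0
  P
}

#' Simulate case-control genotype counts under Hardy-Weinberg equilibrium
#'
#' Control genotype counts are multinomial draws from the Hardy-Weinberg
#' genotype distribution at the population frequency; case counts are drawn
#' from the retrospective (rare-disease) case distribution, proportional to
#' the Hardy-Weinberg probabilities multiplied by `psi^g` for genotype `g`
#' copies of the effect allele. Under this sampling the per-population
#' additive log odds-ratio is identifiable as `log(psi)`.
#'
#' @param freq effect-allele frequency: scalar, vector, or matrix (e.g.
#'   populations by replicates); all cells are simulated.
#' @param psi allelic odds ratio(s): recycled over the rows of `freq`, or a
#'   matrix shaped like `freq`.
#' @param n_cases,n_controls samples per cell (defaults 1000 and 1000).
#' @param seed optional RNG seed.
#' @return List with elements `cases` and `controls`: count matrices with
#'   one row per cell of `freq` (in column-major order) and columns
#'   `g0`, `g1`, `g2`.
#' @export
simulate_case_control <- function(freq, psi, n_cases = 1000,
                                  n_controls = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dm <- dim(freq)
  p <- as.vector(freq)
  stopifnot(all(p > 0), all(p < 1), all(psi > 0))
  if (length(psi) == length(p)) psi <- as.vector(psi)
  else if (!is.null(dm)) psi <- rep(rep_len(psi, dm[1]), times = dm[2])
  else psi <- rep_len(psi, length(p))
  hwe <- cbind(g0 = (1 - p)^2, g1 = 2 * p * (1 - p), g2 = p^2)
  case_w <- hwe * cbind(1, psi, psi^2)
  case_p <- case_w / rowSums(case_w)
  rmult3 <- function(n, pr) {
    # vectorised trinomial via two binomial stages
    n2 <- stats::rbinom(nrow(pr), n, pr[, 3])
    n1 <- stats::rbinom(nrow(pr), n - n2,
                        ifelse(pr[, 3] >= 1, 0,
                               pr[, 2] / pmax(1 - pr[, 3],
                                              .Machine$double.xmin)))
    cbind(g0 = n - n2 - n1, g1 = n1, g2 = n2)
  }
  list(cases = rmult3(n_cases, case_p), controls = rmult3(n_controls, hwe))
}

#' Additive logistic regression on case-control genotype counts
#'
#' Maximum-likelihood fit of the additive (per-allele) logistic model
#' `logit P(case | g) = a + beta * g` from 2-by-3 genotype count tables, by
#' Newton-Raphson on the two-parameter likelihood — vectorised across any
#' number of tables, which is what makes the simulation experiments
#' tractable. Returns the log odds-ratio estimate and its Wald standard
#' error. Tables with a constant informative genotype, or showing
#' separation (diverging estimates), are flagged and returned as `NA`.
#'
#' @param cases,controls genotype counts: length-3 vectors `(g0, g1, g2)`
#'   or M-by-3 matrices (one row per table).
#' @param max_iter,tol Newton-Raphson controls.
#' @return List with vectors `beta`, `se`, and logical `ok`.
#' @examples
#' logistic_association(c(350, 450, 200), c(490, 420, 90))
#' @export
logistic_association <- function(cases, controls, max_iter = 60,
                                 tol = 1e-10) {
  ca <- if (is.matrix(cases)) cases else matrix(cases, 1)
  co <- if (is.matrix(controls)) controls else matrix(controls, 1)
  stopifnot(ncol(ca) == 3, all(dim(ca) == dim(co)),
            all(ca >= 0), all(co >= 0))
  M <- nrow(ca)
  tot <- ca + co
  # identifiable only if genotypes with observations are not constant
  informative <- rowSums(tot > 0) >= 2
  both_classes <- rowSums(ca) > 0 & rowSums(co) > 0
  usable <- informative & both_classes
  a <- log(pmax(rowSums(ca), 0.5) / pmax(rowSums(co), 0.5))
  b <- numeric(M)
  g <- matrix(rep(0:2, each = M), M)
  conv <- rep(FALSE, M)
  act <- which(usable)
  for (it in seq_len(max_iter)) {
    if (!length(act)) break
    eta0 <- a[act]; eta <- cbind(eta0, eta0 + b[act], eta0 + 2 * b[act])
    mu <- stats::plogis(eta)
    w <- tot[act, , drop = FALSE] * mu * (1 - mu)
    r <- ca[act, , drop = FALSE] - tot[act, , drop = FALSE] * mu
    ga <- rowSums(r); gb <- rowSums(r * g[act, , drop = FALSE])
    haa <- rowSums(w); hab <- rowSums(w * g[act, , drop = FALSE])
    hbb <- rowSums(w * g[act, , drop = FALSE]^2)
    det <- haa * hbb - hab^2
    bad <- det <= 1e-12
    da <- (hbb * ga - hab * gb) / det
    db <- (haa * gb - hab * ga) / det
    da[bad] <- 0; db[bad] <- 0
    a[act] <- a[act] + da
    b[act] <- b[act] + db
    done <- (abs(da) < tol & abs(db) < tol) | bad
    conv[act[done & !bad]] <- TRUE
    usable[act[bad]] <- FALSE
    act <- act[!done]
  }
  ok <- conv & usable & abs(b) < 15
  se <- rep(NA_real_, M)
  if (any(ok)) {
    i <- which(ok)
    eta <- cbind(a[i], a[i] + b[i], a[i] + 2 * b[i])
    mu <- stats::plogis(eta)
    w <- tot[i, , drop = FALSE] * mu * (1 - mu)
    haa <- rowSums(w); hab <- rowSums(w * g[i, , drop = FALSE])
    hbb <- rowSums(w * g[i, , drop = FALSE]^2)
    se[i] <- sqrt(haa / (haa * hbb - hab^2))
  }
  b[!ok] <- NA_real_
  list(beta = b, se = se, ok = ok)
}

#' Collapse individual genotypes to case-control count tables
#'
#' @param genotypes numeric vector (one variant) or matrix (individuals by
#'   variants) of genotypes in `{0, 1, 2}`.
#' @param phenotype 0/1 (or logical) case indicator per individual.
#' @return List of `cases` and `controls` count matrices (variants by 3),
#'   ready for [logistic_association()].
#' @export
counts_from_genotypes <- function(genotypes, phenotype) {
  G <- if (is.matrix(genotypes)) genotypes else matrix(genotypes)
  y <- as.logical(phenotype)
  stopifnot(nrow(G) == length(y), all(G %in% 0:2))
  count3 <- function(m) cbind(g0 = colSums(m == 0), g1 = colSums(m == 1),
                              g2 = colSums(m == 2))
  list(cases = count3(G[y, , drop = FALSE]),
       controls = count3(G[!y, , drop = FALSE]))
}

#' Simulate per-population locus haplotype pools with drifted LD
#'
#' Generates multi-population haplotypes for a locus with a single
#' mid-locus causal variant, emulating the group structure of a worldwide
#' reference panel. An ancestral haplotype panel is drawn from a Gaussian
#' copula first-order Markov chain over sites (allelic correlation decaying
#' exponentially with inter-site distance, scale `ld_scale`). Each ancestry
#' group bottlenecks the ancestral panel (subsampling without replacement),
#' each population bottlenecks its group's panel again (with replacement),
#' and population haplotypes are produced by Li-Stephens-style mosaic
#' copying from the population's template set, switching templates between
#' adjacent sites with probability `1 - exp(-switch_rate * distance)` and
#' flipping alleles with a small mutation probability. This yields
#' group-differentiated allele frequencies and population-specific LD. The
#' whole locus is redrawn until the causal variant has minor allele
#' frequency above `maf_min` in every population.
#'
#' @param populations population panel data frame (`pop`, `group`).
#' @param n_variants number of variants in the locus (default 60).
#' @param region_bp locus width in bp (default 1 Mb, the analysis window of
#'   the fine-mapping experiments).
#' @param n_haplotypes haplotypes per population pool (default 200).
#' @param ancestral_panel_size ancestral haplotypes (default 120).
#' @param group_bottleneck,pop_bottleneck bottleneck sizes (defaults 40
#'   and 24).
#' @param ld_scale ancestral LD decay scale in bp (default 5e4).
#' @param switch_rate mosaic template switch rate per bp (default 1e-5).
#' @param mutation_rate per-site allele flip probability during copying
#'   (default 2e-3).
#' @param maf_min causal-variant minor allele frequency floor (default
#'   0.01).
#' @param seed optional RNG seed.
#' @return List with `haplotypes` (per-population 0/1 matrices, haplotypes
#'   by variants), `positions` (bp), `causal` (variant index),
#'   `frequencies` (populations-by-variants effect-allele frequencies) and
#'   `ancestral` (the ancestral haplotype panel).
#' @export
simulate_locus <- function(populations = kgp_populations(), n_variants = 60,
                           region_bp = 1e6, n_haplotypes = 200,
                           ancestral_panel_size = 120,
                           group_bottleneck = 40, pop_bottleneck = 24,
                           ld_scale = 5e4, switch_rate = 1e-5,
                           mutation_rate = 2e-3, maf_min = 0.01,
                           seed = NULL) {
  stopifnot(n_variants >= 2, group_bottleneck <= ancestral_panel_size)
  if (!is.null(seed)) set.seed(seed)
  g <- populations$group
  groups <- unique(g)
  K <- nrow(populations)
  for (attempt in seq_len(50)) {
    positions <- sort(round(stats::runif(n_variants, 1, region_bp)))
    causal <- which.min(abs(positions - region_bp / 2))
    q <- stats::runif(n_variants, 0.05, 0.95)
    d <- diff(positions)
    rho <- exp(-pmax(d, 1) / ld_scale)

    # ancestral panel: Gaussian copula AR(1) across sites
    A <- ancestral_panel_size
    Z <- matrix(NA_real_, A, n_variants)
    Z[, 1] <- stats::rnorm(A)
    for (v in 2:n_variants)
      Z[, v] <- rho[v - 1] * Z[, v - 1] +
        sqrt(1 - rho[v - 1]^2) * stats::rnorm(A)
    anc <- Z < matrix(stats::qnorm(q), A, n_variants, byrow = TRUE)
    storage.mode(anc) <- "integer"

    sw <- 1 - exp(-switch_rate * pmax(d, 1))
    haps <- vector("list", K)
    names(haps) <- populations$pop
    group_panel <- lapply(groups, function(gr)
      anc[sample.int(A, group_bottleneck), , drop = FALSE])
    names(group_panel) <- groups
    for (k in seq_len(K)) {
      tmplt <- group_panel[[g[k]]][
        sample.int(group_bottleneck, pop_bottleneck, replace = TRUE), ,
        drop = FALSE]
      H <- n_haplotypes
      idx <- sample.int(pop_bottleneck, H, replace = TRUE)
      hp <- matrix(0L, H, n_variants)
      hp[, 1] <- tmplt[idx, 1]
      for (v in 2:n_variants) {
        s <- stats::runif(H) < sw[v - 1]
        if (any(s)) idx[s] <- sample.int(pop_bottleneck, sum(s),
                                         replace = TRUE)
        hp[, v] <- tmplt[idx, v]
      }
      mut <- matrix(stats::runif(H * n_variants) < mutation_rate, H)
      hp[mut] <- 1L - hp[mut]
      haps[[k]] <- hp
    }
    freq <- t(vapply(haps, colMeans, numeric(n_variants)))
    maf_causal <- pmin(freq[, causal], 1 - freq[, causal])
    if (all(maf_causal > maf_min))
      return(list(haplotypes = haps, positions = positions, causal = causal,
                  frequencies = freq, ancestral = anc))
  }
  stop("could not generate a locus with causal MAF > ", maf_min,
       " in all populations after 50 attempts")
}

# sample a case-control cohort from a haplotype pool by retrospective
# sampling on the causal genotype; returns genotype matrices
sample_cohort <- function(hp, causal, psi, n_cases, n_controls,
                          pool_size = 4000) {
  H <- nrow(hp)
  i1 <- sample.int(H, pool_size, replace = TRUE)
  i2 <- sample.int(H, pool_size, replace = TRUE)
  gc_ <- hp[i1, causal] + hp[i2, causal]
  wi <- psi^gc_
  ca <- sample.int(pool_size, n_cases, replace = TRUE, prob = wi)
  co <- sample.int(pool_size, n_controls, replace = TRUE)
  list(cases = hp[i1[ca], , drop = FALSE] + hp[i2[ca], , drop = FALSE],
       controls = hp[i1[co], , drop = FALSE] + hp[i2[co], , drop = FALSE])
}

# derive axes of genetic variation for a simulated population panel from a
# fresh genome-wide marker draw (markers common in all populations)
simulated_axes <- function(populations, T = 3, n_axis_markers = 500,
                           fst_between = 0.10, fst_within = 0.02,
                           seed = NULL) {
  P <- draw_population_frequencies(n_axis_markers, populations,
                                   fst_between = fst_between,
                                   fst_within = fst_within,
                                   maf_min = 0.05, seed = seed)
  D <- compute_distance_matrix(P)
  derive_axes(D, T)
}

#' Run the power / type-I-error experiment
#'
#' Reproduces the single-variant simulation design: per replicate, a causal
#' variant's per-population allele frequencies are drawn from the
#' hierarchical drift model; case-control genotype counts are simulated
#' under Hardy-Weinberg equilibrium with the scenario's population-specific
#' odds ratios; each population is analysed by additive logistic
#' regression; and the per-population summary statistics are aggregated by
#' (i) meta-regression on `T` axes of genetic variation (axes computed once
#' per experiment from a genome-wide marker draw of the same population
#' panel) and (ii) fixed-effects inverse-variance meta-analysis with
#' Cochran's Q. Rejection rates are reported at the nominal (0.05) and
#' genome-wide (5e-8) thresholds with binomial Monte-Carlo standard errors.
#'
#' All randomness flows from `seed` through named substreams
#' ([substream_seed()]), so any replicate can be regenerated in isolation.
#'
#' @param scenario a `scenario_spec`, or a scenario name passed to
#'   [scenario_spec()] (random-psi scenarios are then resolved from the
#'   experiment seed).
#' @param n_replicates number of replicates.
#' @param T number of axes of genetic variation (default 3).
#' @param n_cases,n_controls per-population sample sizes (defaults 1000).
#' @param alpha nominal significance threshold (default 0.05).
#' @param alpha_gws genome-wide significance threshold (default 5e-8).
#' @param n_axis_markers genome-wide markers for the axes (default 500).
#' @param fst_between,fst_within drift parameters of the frequency model.
#' @param populations population panel.
#' @param seed experiment seed (default 1).
#' @return A `power_experiment` object: list with `rates` (data frame of
#'   per-test rejection rates and Monte-Carlo standard errors at both
#'   thresholds), `pvalues` (per-replicate p-value matrix), `n_used`,
#'   `n_dropped`, `scenario`, `axes` and `seed`.
#' @export
run_power_experiment <- function(scenario, n_replicates = 1000, T = 3,
                                 n_cases = 1000, n_controls = 1000,
                                 alpha = 0.05, alpha_gws = 5e-8,
                                 n_axis_markers = 500,
                                 fst_between = 0.10, fst_within = 0.02,
                                 populations = kgp_populations(),
                                 seed = 1) {
  if (is.character(scenario))
    scenario <- scenario_spec(scenario, populations = populations,
                              seed = substream_seed(seed, "scenario"))
  stopifnot(inherits(scenario, "scenario_spec"), n_replicates >= 1)
  K <- nrow(scenario)
  axes <- simulated_axes(populations, T = T, n_axis_markers = n_axis_markers,
                         fst_between = fst_between, fst_within = fst_within,
                         seed = substream_seed(seed, "axes"))
  X <- unclass(axes)

  freq <- draw_population_frequencies(n_replicates, populations,
                                      fst_between = fst_between,
                                      fst_within = fst_within, maf_min = 0.01,
                                      seed = substream_seed(seed,
                                                            "frequencies"))
  sim <- simulate_case_control(freq, scenario$psi, n_cases, n_controls,
                               seed = substream_seed(seed, "genotypes"))
  fit <- logistic_association(sim$cases, sim$controls)
  B <- matrix(fit$beta, K, n_replicates)
  S <- matrix(fit$se, K, n_replicates)
  OK <- matrix(fit$ok, K, n_replicates)

  pv <- matrix(NA_real_, n_replicates, 5,
               dimnames = list(NULL, c("mr_assoc", "mr_anc_het",
                                       "mr_res_het", "fe", "cochran_q")))
  dropped <- 0L
  for (r in seq_len(n_replicates)) {
    use <- OK[, r]
    if (sum(use) < T + 2) { dropped <- dropped + 1L; next }
    f <- fit_variant(B[use, r], S[use, r]^2, X[use, , drop = FALSE],
                     per_axis = FALSE)
    fe <- fixed_effects_ivw(B[use, r], S[use, r]^2)
    pv[r, ] <- c(f$p_assoc, f$p_anc_het, f$p_res_het, fe$p, fe$p_Q)
  }
  used <- !is.na(pv[, 1])
  rate <- function(p, a) {
    x <- mean(p[used] < a)
    c(rate = x, se = sqrt(x * (1 - x) / sum(used)))
  }
  rates <- do.call(rbind, lapply(colnames(pv), function(m) {
    nom <- rate(pv[, m], alpha); gws <- rate(pv[, m], alpha_gws)
    data.frame(test = m, rate_nominal = nom["rate"], se_nominal = nom["se"],
               rate_gws = gws["rate"], se_gws = gws["se"])
  }))
  rownames(rates) <- NULL
  structure(list(rates = rates, pvalues = pv, n_used = sum(used),
                 n_dropped = dropped, scenario = scenario, axes = axes,
                 alpha = alpha, alpha_gws = alpha_gws, seed = seed),
            class = "power_experiment")
}

#' @export
print.power_experiment <- function(x, ...) {
  cat("Power / type-I-error experiment: scenario '",
      attr(x$scenario, "name"), "', ", x$n_used, " replicates used",
      if (x$n_dropped) paste0(" (", x$n_dropped, " dropped)"), "\n", sep = "")
  cat(sprintf("  thresholds: nominal %.3g, genome-wide %.3g\n",
              x$alpha, x$alpha_gws))
  print(x$rates, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Run the fine-mapping calibration experiment
#'
#' Reproduces the 'perfect data' single-causal-variant fine-mapping design:
#' per replicate a multi-population locus is simulated
#' ([simulate_locus()]), case-control cohorts are drawn by retrospective
#' sampling on the causal genotype with the scenario's population-specific
#' odds ratios, every variant is tested in every population by additive
#' logistic regression, and per-variant Bayes' factors are computed from
#' (i) the meta-regression on `T` axes of genetic variation and (ii)
#' fixed-effects meta-analysis with a Wakefield N(0, 0.2^2) prior.
#' Posterior probabilities of driving the signal and the 99% credible set
#' follow for each method. Three metrics are accumulated per method: the
#' median credible-set size, the mean posterior probability of the causal
#' variant, and the coverage of the causal variant by the credible set.
#'
#' @param scenario a `scenario_spec` or scenario name.
#' @param n_replicates number of replicate loci.
#' @param T number of axes of genetic variation (default 3).
#' @param n_cases,n_controls per-population sample sizes (defaults 1000).
#' @param mass credible-set coverage level (default 0.99).
#' @param n_axis_markers genome-wide markers for the axes (default 500).
#' @param fst_between,fst_within drift parameters of the frequency model.
#' @param populations population panel.
#' @param seed experiment seed (default 1).
#' @param ... locus settings passed to [simulate_locus()] (e.g.
#'   `n_variants`).
#' @return A `finemap_experiment` object: list with `metrics` (data frame:
#'   method, median set size, mean causal posterior, coverage and its
#'   Monte-Carlo standard error), `per_replicate` (set sizes, causal
#'   posteriors and coverage indicators), `n_used`, `n_dropped`,
#'   `scenario`, `seed`.
#' @export
run_finemap_experiment <- function(scenario, n_replicates = 200, T = 3,
                                   n_cases = 1000, n_controls = 1000,
                                   mass = 0.99, n_axis_markers = 500,
                                   fst_between = 0.10, fst_within = 0.02,
                                   populations = kgp_populations(),
                                   seed = 1, ...) {
  if (is.character(scenario))
    scenario <- scenario_spec(scenario, populations = populations,
                              seed = substream_seed(seed, "scenario"))
  stopifnot(inherits(scenario, "scenario_spec"), n_replicates >= 1)
  K <- nrow(scenario)
  axes <- simulated_axes(populations, T = T, n_axis_markers = n_axis_markers,
                         fst_between = fst_between, fst_within = fst_within,
                         seed = substream_seed(seed, "axes"))
  X <- unclass(axes)

  methods <- c("meta_regression", "fixed_effects")
  size <- matrix(NA_real_, n_replicates, 2, dimnames = list(NULL, methods))
  cpost <- size; hit <- size
  dropped <- 0L
  for (r in seq_len(n_replicates)) {
    loc <- simulate_locus(populations, seed = substream_seed(seed, "locus", r),
                          ...)
    set.seed(substream_seed(seed, "phenotypes", r))
    V <- length(loc$positions)
    B <- matrix(NA_real_, V, K); S <- matrix(NA_real_, V, K)
    for (k in seq_len(K)) {
      coh <- sample_cohort(loc$haplotypes[[k]], loc$causal,
                           scenario$psi[k], n_cases, n_controls)
      cnt <- list(cases = counts_from_genotypes(coh$cases,
                                                rep(TRUE, n_cases))$cases,
                  controls = counts_from_genotypes(coh$controls,
                                                   rep(FALSE,
                                                       n_controls))$controls)
      f <- logistic_association(cnt$cases, cnt$controls)
      B[, k] <- f$beta; S[, k] <- f$se
    }
    pres <- is.finite(B) & is.finite(S)
    keep <- rowSums(pres) >= T + 2
    if (!keep[loc$causal]) { dropped <- dropped + 1L; next }
    idx <- which(keep)
    lnbf_mr <- rep(NA_real_, V); lnbf_fe <- rep(NA_real_, V)
    for (v in idx) {
      use <- pres[v, ]
      f <- fit_variant(B[v, use], S[v, use]^2, X[use, , drop = FALSE],
                       per_axis = FALSE)
      lnbf_mr[v] <- f$lnbf
      fe <- fixed_effects_ivw(B[v, use], S[v, use]^2)
      lnbf_fe[v] <- ln_abf_wakefield(fe$beta, fe$se)
    }
    for (m in 1:2) {
      ln <- if (m == 1) lnbf_mr[idx] else lnbf_fe[idx]
      post <- posterior_probabilities(ln)
      cs <- credible_set(post, mass = mass, position = loc$positions[idx])
      size[r, m] <- attr(cs, "size")
      ci <- match(loc$causal, idx)
      cpost[r, m] <- post[ci]
      hit[r, m] <- as.numeric(cs[ci])
    }
  }
  used <- !is.na(size[, 1])
  metrics <- do.call(rbind, lapply(1:2, function(m) {
    cov <- mean(hit[used, m])
    data.frame(method = methods[m],
               median_set_size = stats::median(size[used, m]),
               mean_causal_posterior = mean(cpost[used, m]),
               coverage = cov,
               coverage_se = sqrt(cov * (1 - cov) / sum(used)))
  }))
  structure(list(metrics = metrics,
                 per_replicate = list(size = size, causal_posterior = cpost,
                                      covered = hit),
                 n_used = sum(used), n_dropped = dropped,
                 scenario = scenario, axes = axes, mass = mass, seed = seed),
            class = "finemap_experiment")
}

#' @export
print.finemap_experiment <- function(x, ...) {
  cat("Fine-mapping calibration experiment: scenario '",
      attr(x$scenario, "name"), "', ", x$n_used, " replicates used",
      if (x$n_dropped) paste0(" (", x$n_dropped, " dropped)"), "\n", sep = "")
  cat(sprintf("  credible-set mass: %.2f\n", x$mass))
  print(x$metrics, digits = 3, row.names = FALSE)
  invisible(x)
}
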