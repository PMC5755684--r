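# Per-variant weighted meta-regression of allelic effects on axes of genetic
# variation, with deviance tests partitioning heterogeneity, approximate
# Bayes' factors, and genomic control.

#' Meta-regression of one variant's allelic effects on ancestry axes
#'
#' Fits, by weighted least squares with weights equal to the inverse variance
#' of each study's allelic effect, the linear model
#' \deqn{E[b_{k}] = \alpha + \sum_{t=1}^{T} \beta_t x_{kt}} across the
#' contributing studies, treating the per-study variances as known. Because
#' the variances are known, deviance differences between nested models are
#' exact weighted residual-sum-of-squares differences, giving:
#' \itemize{
#'   \item the association statistic (all coefficients zero vs free),
#'     chi-squared with `T + 1` df;
#'   \item the ancestry-correlated heterogeneity statistic (axis coefficients
#'     zero vs free), chi-squared with `T` df;
#'   \item the residual-heterogeneity statistic (the full-model weighted RSS),
#'     chi-squared with `K - T - 1` df;
#'   \item per-axis 1-df statistics from dropping each axis in turn.
#' }
#'
#' @param beta numeric vector of per-study allelic effects (length K).
#' @param var numeric vector of per-study effect variances (se squared),
#'   strictly positive.
#' @param axes K-by-T matrix of axes of genetic variation for the
#'   contributing studies (rows in study order), or `NULL` for `T = 0`, in
#'   which case the fit reduces to fixed-effects inverse-variance weighted
#'   meta-analysis and the residual statistic to Cochran's Q.
#' @param per_axis also compute the per-axis 1-df statistics (default TRUE).
#' @return A list of class `variant_meta` with elements `coef`, `se` (length
#'   `T + 1`, intercept first), `K`, `T`, `chisq_assoc`, `df_assoc`,
#'   `p_assoc`, `log10p_assoc`, `chisq_anc_het`, `df_anc_het`, `p_anc_het`,
#'   `chisq_res_het`, `df_res_het`, `p_res_het`, `axis_chisq`, `axis_p`,
#'   `lnbf` and `ok`. Tests whose degrees of freedom are not available for
#'   the given K and T are `NA`; a rank-deficient design sets `ok = FALSE`
#'   and suppresses all tests.
#' @export
fit_variant <- function(beta, var, axes = NULL, per_axis = TRUE) {
  K <- length(beta)
  stopifnot(length(var) == K, all(is.finite(beta)), all(is.finite(var)),
            all(var > 0))
  if (is.null(axes)) {
    Z <- matrix(1, K, 1)
  } else {
    axes <- as.matrix(axes)
    stopifnot(nrow(axes) == K)
    Z <- cbind(1, axes)
  }
  T <- ncol(Z) - 1L
  nc <- list(coef = rep(NA_real_, T + 1), se = rep(NA_real_, T + 1),
             K = K, T = T,
             chisq_assoc = NA_real_, df_assoc = T + 1L, p_assoc = NA_real_,
             log10p_assoc = NA_real_,
             chisq_anc_het = NA_real_, df_anc_het = T, p_anc_het = NA_real_,
             chisq_res_het = NA_real_, df_res_het = K - T - 1L,
             p_res_het = NA_real_,
             axis_chisq = rep(NA_real_, T), axis_p = rep(NA_real_, T),
             lnbf = NA_real_, ok = FALSE)
  if (K < T + 1) return(structure(nc, class = "variant_meta"))

  w <- 1 / var
  sw <- sqrt(w)
  qrz <- qr(Z * sw)
  if (qrz$rank < ncol(Z)) return(structure(nc, class = "variant_meta"))
  theta <- qr.coef(qrz, beta * sw)
  res <- beta - drop(Z %*% theta)
  rss_full <- sum(w * res^2)
  ss_zero <- sum(w * beta^2)
  bfe <- sum(w * beta) / sum(w)
  q_int <- sum(w * (beta - bfe)^2)      # intercept-only weighted RSS

  covm <- chol2inv(chol(crossprod(Z * sw)))
  out <- nc
  out$ok <- TRUE
  out$coef <- unname(theta)
  out$se <- sqrt(diag(covm))
  out$chisq_assoc <- max(ss_zero - rss_full, 0)
  ap <- chisq_p(out$chisq_assoc, T + 1)
  out$p_assoc <- ap$p; out$log10p_assoc <- ap$log10p
  if (T >= 1) {
    out$chisq_anc_het <- max(q_int - rss_full, 0)
    out$p_anc_het <- chisq_p(out$chisq_anc_het, T)$p
  }
  if (K >= T + 2) {
    out$chisq_res_het <- max(rss_full, 0)
    out$p_res_het <- chisq_p(out$chisq_res_het, K - T - 1)$p
  } else {
    out$chisq_res_het <- NA_real_
  }
  if (per_axis && T >= 1) {
    for (t in seq_len(T)) {
      qrd <- qr((Z * sw)[, -(t + 1), drop = FALSE])
      rt <- beta - drop(Z[, -(t + 1), drop = FALSE] %*%
                          qr.coef(qrd, beta * sw))
      out$axis_chisq[t] <- max(sum(w * rt^2) - rss_full, 0)
      out$axis_p[t] <- chisq_p(out$axis_chisq[t], 1)$p
    }
  }
  out$lnbf <- ln_bayes_factor(out$chisq_assoc, T, K)
  structure(out, class = "variant_meta")
}

#' @export
print.variant_meta <- function(x, ...) {
  cat("Variant meta-regression (K = ", x$K, ", T = ", x$T, ")\n", sep = "")
  if (!x$ok) { cat("  fit not available (rank-deficient or K < T + 1)\n")
    return(invisible(x)) }
  cf <- data.frame(estimate = x$coef, se = x$se,
                   row.names = c("(intercept)",
                                 if (x$T) paste0("axis", seq_len(x$T))))
  print(cf, digits = 4)
  cat(sprintf("  association:     X2 = %.3f (%d df), P = %.3g\n",
              x$chisq_assoc, x$df_assoc, x$p_assoc))
  if (x$T >= 1)
    cat(sprintf("  ancestry het.:   X2 = %.3f (%d df), P = %.3g\n",
                x$chisq_anc_het, x$df_anc_het, x$p_anc_het))
  if (!is.na(x$chisq_res_het))
    cat(sprintf("  residual het.:   X2 = %.3f (%d df), P = %.3g\n",
                x$chisq_res_het, x$df_res_het, x$p_res_het))
  cat(sprintf("  ln Bayes factor: %.3f\n", x$lnbf))
  invisible(x)
}

#' Approximate log Bayes' factor in favour of association
#'
#' Converts the association chi-squared statistic of the meta-regression into
#' an approximate Bayes' factor in favour of association,
#' \deqn{\ln\Lambda = \frac{X - (T+1)\ln K}{2},} a BIC-style approximation
#' penalising the `T + 1` regression parameters by the (study) sample size K.
#'
#' @param chisq association chi-squared statistic(s), `T + 1` df.
#' @param T number of axes of genetic variation in the model.
#' @param K number of contributing studies.
#' @return Natural-log Bayes' factor(s).
#' @export
ln_bayes_factor <- function(chisq, T, K) {
  stopifnot(all(K >= 2))
  (chisq - (T + 1) * log(K)) / 2
}

#' Genomic-control inflation factor
#'
#' The median of the observed association statistics divided by the median of
#' the central chi-squared distribution with the same degrees of freedom.
#' Values below 1 are reported as computed; correction routines floor the
#' factor at 1.
#'
#' @param statistics chi-squared association statistics (non-finite values
#'   are dropped).
#' @param df degrees of freedom of the statistics.
#' @return The inflation factor lambda.
#' @export
lambda_gc <- function(statistics, df) {
  statistics <- statistics[is.finite(statistics)]
  if (length(statistics) == 0) stop("no finite statistics for genomic control")
  if (length(statistics) < 100)
    warning("genomic control estimated from fewer than 100 statistics")
  stats::median(statistics) / stats::qchisq(0.5, df)
}

#' Apply genomic control to meta-regression association statistics
#'
#' Divides the association chi-squared statistics by the inflation factor and
#' recomputes p-values and log Bayes' factors. A factor below 1 leaves the
#' results unchanged, with a warning.
#'
#' @param fit a `transmeta` fit (or a data frame with columns `chisq_assoc`,
#'   `df_assoc`, `K`).
#' @param lambda inflation factor; by default estimated from the fit's own
#'   association statistics with [lambda_gc()].
#' @return The corrected object, with attribute/field `lambda_output`.
#' @export
genomic_control_correct <- function(fit, lambda = NULL) {
  res <- if (inherits(fit, "transmeta")) fit$results else fit
  if (is.null(lambda))
    lambda <- lambda_gc(res$chisq_assoc, df = res$df_assoc[1])
  if (lambda < 1) {
    warning("lambda = ", format(lambda, digits = 4),
            " < 1; no correction applied")
    lam_eff <- 1
  } else lam_eff <- lambda
  res$chisq_assoc <- res$chisq_assoc / lam_eff
  pp <- chisq_p(res$chisq_assoc, res$df_assoc)
  res$p_assoc <- pp$p
  res$log10p_assoc <- pp$log10p
  T <- res$df_assoc - 1L
  res$lnbf <- ln_bayes_factor(res$chisq_assoc, T, res$K)
  if (inherits(fit, "transmeta")) {
    fit$results <- res
    fit$lambda_output <- lambda
    fit
  } else {
    attr(res, "lambda_output") <- lambda
    res
  }
}

#' Trans-ethnic meta-regression across a summary-statistic panel
#'
#' The main fitting function. For every variant of the panel, the per-study
#' allelic effects are regressed on the studies' axes of genetic variation by
#' inverse-variance weighted least squares ([fit_variant()]), partitioning
#' between-study heterogeneity into an ancestry-correlated and a residual
#' component and producing association, heterogeneity and per-axis tests,
#' plus an approximate log Bayes' factor per variant. Axes are genome-wide
#' study properties: they are computed once, from LD-thinned distance markers
#' ([select_distance_markers()], [compute_distance_matrix()],
#' [derive_axes()]), and variants missing from some studies are fitted on
#' their contributing subset with the same global axes.
#'
#' @param panel a `study_panel` from [assemble_panel()].
#' @param T number of axes of genetic variation (default 3, the choice
#'   separating the five continental ancestry groups in the simulation
#'   design); ignored when `axes` is supplied.
#' @param axes optional precomputed `ancestry_axes` (rows matching
#'   `panel$studies`).
#' @param min_presence optional presence fraction passed to
#'   [presence_filter()] before fitting.
#' @param bin_size,min_maf distance-marker selection parameters.
#' @param gc_input apply study-level genomic control: per-study inflation
#'   factors are estimated from the studies' squared z-scores (1 df) and the
#'   effect variances inflated accordingly before fitting.
#' @param gc_output apply genomic control to the meta-regression association
#'   statistics afterwards ([genomic_control_correct()]).
#' @return A `transmeta` object: list with `results` (one row per variant:
#'   identifiers, pooled effect-allele frequency, total sample size, K,
#'   coefficient estimates with standard errors, the three tests with
#'   degrees of freedom and p-values, per-axis p-values and `lnbf`), `axes`,
#'   `distance` matrix, `lambda_input`, `lambda_output` and `call`.
#' @examples
#' set.seed(1)
#' pops <- kgp_populations()
#' freq <- draw_population_frequencies(200, pops)
#' # a synthetic panel: effects null everywhere
#' sim <- simulate_case_control(freq, psi = 1, n_cases = 500, n_controls = 500)
#' fit <- logistic_association(sim$cases, sim$controls)
#' B <- matrix(fit$beta, nrow(freq))   # populations by markers
#' S <- matrix(fit$se, nrow(freq))
#' panel <- panel_from_matrices(t(B), t(S^2), t(freq),
#'                              n = 1000, positions = seq_len(200) * 2e6)
#' m <- transmeta(panel, T = 3)
#' m
#' @export
transmeta <- function(panel, T = 3, axes = NULL, min_presence = NULL,
                      bin_size = 1e6, min_maf = 0.05,
                      gc_input = FALSE, gc_output = FALSE) {
  stopifnot(inherits(panel, "study_panel"))
  cl <- match.call()
  if (!is.null(min_presence)) panel <- presence_filter(panel, min_presence)
  D <- NULL
  if (is.null(axes)) {
    mk <- select_distance_markers(panel, bin_size = bin_size,
                                  min_maf = min_maf)
    D <- compute_distance_matrix(panel, mk)
    axes <- derive_axes(D, T)
  } else {
    stopifnot(nrow(axes) == length(panel$studies))
    T <- ncol(axes)
  }

  lam_in <- NULL
  if (isTRUE(gc_input)) {
    z2 <- panel$beta^2 / panel$var
    lam_in <- apply(z2, 2, function(s) lambda_gc(s[is.finite(s)], df = 1))
    infl <- pmax(lam_in, 1)
    panel$var <- sweep(panel$var, 2, infl, `*`)
  }

  V <- nrow(panel$variants)
  Tn <- T
  res <- vector("list", V)
  X <- unclass(axes)
  for (j in seq_len(V)) {
    pr <- panel$present[j, ]
    f <- fit_variant(panel$beta[j, pr], panel$var[j, pr],
                     X[pr, , drop = FALSE])
    w <- 1 / panel$var[j, pr]
    eafj <- panel$eaf[j, pr]
    pooled_eaf <- if (all(is.na(eafj))) NA_real_ else
      stats::weighted.mean(eafj, w, na.rm = TRUE)
    res[[j]] <- c(list(eaf = pooled_eaf,
                       n_total = sum(panel$n[j, pr], na.rm = TRUE),
                       K = f$K),
                  f[c("chisq_assoc", "df_assoc", "p_assoc", "log10p_assoc",
                      "chisq_anc_het", "df_anc_het", "p_anc_het",
                      "chisq_res_het", "df_res_het", "p_res_het", "lnbf",
                      "ok")],
                  stats::setNames(as.list(f$coef),
                                  c("alpha", if (Tn) paste0("beta_",
                                                            seq_len(Tn)))),
                  stats::setNames(as.list(f$se),
                                  c("alpha_se", if (Tn) paste0("se_",
                                                               seq_len(Tn)))),
                  stats::setNames(as.list(f$axis_p),
                                  if (Tn) paste0("p_axis_", seq_len(Tn))))
  }
  results <- cbind(panel$variants[, c("marker", "chromosome", "position",
                                      "ea", "nea")],
                   do.call(rbind, lapply(res, function(r)
                     as.data.frame(r, stringsAsFactors = FALSE))))
  rownames(results) <- NULL

  out <- structure(list(results = results, axes = axes, distance = D,
                        T = T, studies = panel$studies,
                        lambda_input = lam_in, lambda_output = NULL,
                        call = cl),
                   class = "transmeta")
  if (isTRUE(gc_output)) out <- genomic_control_correct(out)
  out
}

#' @export
print.transmeta <- function(x, n = 6, ...) {
  r <- x$results
  cat("Trans-ethnic meta-regression: ", nrow(r), " variant(s), ",
      length(x$studies), " studies, T = ", x$T, " axes\n", sep = "")
  if (!is.null(x$lambda_output))
    cat("  genomic control (output): lambda =",
        format(x$lambda_output, digits = 4), "\n")
  ord <- order(r$p_assoc)
  show <- utils::head(ord, n)
  cols <- c("marker", "chromosome", "position", "K", "chisq_assoc",
            "p_assoc", "p_anc_het", "p_res_het", "lnbf")
  cat("  strongest associations:\n")
  print(r[show, cols], digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
summary.transmeta <- function(object, alpha = 5e-8, ...) {
  r <- object$results
  lam <- if (sum(is.finite(r$chisq_assoc)) >= 1)
    suppressWarnings(lambda_gc(r$chisq_assoc, df = r$df_assoc[1])) else NA
  out <- list(n_variants = nrow(r), n_studies = length(object$studies),
              T = object$T, alpha = alpha,
              n_significant = sum(r$p_assoc < alpha, na.rm = TRUE),
              lambda = lam,
              eigenvalues = attr(object$axes, "eigenvalues"))
  class(out) <- "summary.transmeta"
  out
}

#' @export
print.summary.transmeta <- function(x, ...) {
  cat("Trans-ethnic meta-regression summary\n")
  cat("  variants: ", x$n_variants, "; studies: ", x$n_studies,
      "; axes: ", x$T, "\n", sep = "")
  cat("  associations with P < ", format(x$alpha), ": ", x$n_significant,
      "\n", sep = "")
  cat("  genomic-control lambda of association statistics: ",
      format(x$lambda, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.transmeta <- function(object, ...) {
  r <- object$results
  cols <- c("alpha", if (object$T) paste0("beta_", seq_len(object$T)))
  m <- as.matrix(r[, cols, drop = FALSE])
  rownames(m) <- r$marker
  m
}

#' QQ plot of meta-regression association p-values
#'
#' @param x a `transmeta` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.transmeta <- function(x, ...) {
  p <- sort(x$results$p_assoc)
  n <- length(p)
  exp_ <- -log10((seq_len(n) - 0.5) / n)
  obs <- -log10(pmax(p, .Machine$double.xmin))
  graphics::plot(exp_, obs, xlab = "expected -log10 P",
                 ylab = "observed -log10 P",
                 main = "Meta-regression association", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Write a meta-regression result table
#'
#' Tab-delimited, one row per variant, with a header comment recording the
#' fit parameters, the standard column set for trans-ethnic meta-regression
#' output: identifiers, pooled effect-allele frequency, sample size, study
#' count, coefficients, the association / ancestry-heterogeneity /
#' residual-heterogeneity chi-squared statistics with their degrees of
#' freedom and p-values, and the log Bayes' factor.
#'
#' @param fit a `transmeta` object.
#' @param path output file path.
#' @param seed optional seed to record in the header comment.
#' @return Invisibly, the results data frame written.
#' @export
write_transmeta <- function(fit, path, seed = NULL) {
  stopifnot(inherits(fit, "transmeta"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# transmeta meta-regression; T=", fit$T,
                    "; studies=", length(fit$studies),
                    if (!is.null(fit$lambda_output))
                      paste0("; lambda_gc=", format(fit$lambda_output,
                                                    digits = 6)) else "",
                    if (!is.null(seed)) paste0("; seed=", seed) else ""), con)
  utils::write.table(fit$results, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fit$results)
}
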