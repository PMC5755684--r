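# Fixed-effects inverse-variance weighted meta-analysis with Cochran's Q,
# the benchmark comparator, and Wakefield-style approximate Bayes' factors.

#' Fixed-effects inverse-variance weighted meta-analysis
#'
#' Pools per-study allelic effects with inverse-variance weights,
#' \eqn{\hat b = \sum w_k b_k / \sum w_k}, \eqn{se = (\sum w_k)^{-1/2}}
#' with \eqn{w_k = 1/v_k}, and assesses between-study heterogeneity with
#' Cochran's Q statistic, \eqn{Q = \sum w_k (b_k - \hat b)^2}, chi-squared
#' with `K - 1` df. With a single study the pooled values are the study's own
#' and Q is not available.
#'
#' @param beta per-study allelic effects.
#' @param var per-study effect variances (se squared), strictly positive.
#' @return A list of class `fixed_effects` with `beta`, `se`, `z`, `p`,
#'   `log10p`, `Q`, `df_Q`, `p_Q` and `K`.
#' @examples
#' fixed_effects_ivw(c(0.1, 0.3), c(0.01, 0.01))
#' @export
fixed_effects_ivw <- function(beta, var) {
  K <- length(beta)
  stopifnot(K >= 1, length(var) == K, all(is.finite(beta)),
            all(is.finite(var)), all(var > 0))
  w <- 1 / var
  b <- sum(w * beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- b / se
  pp <- chisq_p(z^2, 1)
  if (K >= 2) {
    Q <- sum(w * (beta - b)^2)
    qq <- chisq_p(Q, K - 1)
    p_Q <- qq$p
  } else {
    Q <- NA_real_; p_Q <- NA_real_
  }
  structure(list(beta = b, se = se, z = z, p = pp$p, log10p = pp$log10p,
                 Q = Q, df_Q = K - 1L, p_Q = p_Q, K = K),
            class = "fixed_effects")
}

#' @export
print.fixed_effects <- function(x, ...) {
  cat(sprintf("Fixed-effects IVW meta-analysis (K = %d)\n", x$K))
  cat(sprintf("  beta = %.4f (se %.4f), z = %.3f, P = %.3g\n",
              x$beta, x$se, x$z, x$p))
  if (x$K >= 2)
    cat(sprintf("  Cochran's Q = %.3f (%d df), P = %.3g\n",
                x$Q, x$df_Q, x$p_Q))
  invisible(x)
}

#' Approximate log Bayes' factor from a pooled effect estimate
#'
#' Wakefield's approximation for a single Gaussian effect estimate with a
#' Gaussian prior on the true effect: given estimate `beta`, squared standard
#' error `var` and prior variance `prior_sd^2`,
#' \deqn{\ln ABF = \tfrac12 \ln\frac{v}{v + W} +
#'   \frac{z^2}{2}\,\frac{W}{v + W},}
#' the Bayes' factor in favour of association. Used to fine-map from
#' fixed-effects meta-analysis output with the standard N(0, 0.2^2) prior on
#' log odds-ratios.
#'
#' @param beta effect estimate(s).
#' @param se standard error(s) of the estimate.
#' @param prior_sd prior standard deviation of the true effect (default 0.2).
#' @return Natural-log approximate Bayes' factor(s).
#' @export
ln_abf_wakefield <- function(beta, se, prior_sd = 0.2) {
  v <- se^2
  W <- prior_sd^2
  z2 <- (beta / se)^2
  0.5 * log(v / (v + W)) + 0.5 * z2 * W / (v + W)
}

#' Fixed-effects meta-analysis across a panel
#'
#' Applies [fixed_effects_ivw()] to every variant of a panel, on each
#' variant's contributing studies.
#'
#' @param panel a `study_panel`.
#' @param prior_sd prior standard deviation for the Wakefield log Bayes'
#'   factor column.
#' @return Data frame with one row per variant: identifiers, `K`, `beta`,
#'   `se`, `z`, `p`, `Q`, `df_Q`, `p_Q`, `lnabf`.
#' @export
fixed_effects_meta <- function(panel, prior_sd = 0.2) {
  stopifnot(inherits(panel, "study_panel"))
  V <- nrow(panel$variants)
  rows <- lapply(seq_len(V), function(j) {
    pr <- panel$present[j, ]
    f <- fixed_effects_ivw(panel$beta[j, pr], panel$var[j, pr])
    data.frame(K = f$K, beta = f$beta, se = f$se, z = f$z, p = f$p,
               Q = f$Q, df_Q = f$df_Q, p_Q = f$p_Q,
               lnabf = ln_abf_wakefield(f$beta, f$se, prior_sd))
  })
  out <- cbind(panel$variants[, c("marker", "chromosome", "position",
                                  "ea", "nea")],
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
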