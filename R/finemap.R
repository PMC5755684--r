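# Posterior probabilities of driving an association signal and 99% credible
# sets over a locus.

#' Posterior probability that each variant drives the locus signal
#'
#' Normalises per-variant Bayes' factors over the locus,
#' \eqn{\pi_j = \Lambda_j / \sum_i \Lambda_i}, assuming a single causal
#' variant and a uniform prior over variants. Computed in log space
#' (log-sum-exp) so association statistics in the hundreds do not overflow.
#'
#' @param lnbf per-variant natural-log Bayes' factors (finite).
#' @return Posterior probabilities summing to 1.
#' @examples
#' posterior_probabilities(c(log(3), log(1)))  # 0.75, 0.25
#' @export
posterior_probabilities <- function(lnbf) {
  if (length(lnbf) == 0) stop("empty locus: no Bayes' factors")
  if (!all(is.finite(lnbf))) stop("non-finite log Bayes' factor in locus")
  exp(lnbf - logsumexp(lnbf))
}

#' Construct a credible set from posterior probabilities
#'
#' Ranks variants by posterior probability (descending; ties broken by
#' ascending genomic position for determinism) and includes ranked variants
#' until their cumulative posterior probability attains or exceeds `mass`.
#'
#' @param posteriors posterior probabilities over the locus (should sum
#'   to 1).
#' @param mass required cumulative posterior mass, in (0, 1); default 0.99.
#' @param position optional genomic positions used to break ties.
#' @return Logical membership vector (aligned with `posteriors`), with
#'   attributes `size` (variant count) and `order` (the ranking used).
#' @export
credible_set <- function(posteriors, mass = 0.99, position = NULL) {
  stopifnot(length(posteriors) >= 1, mass > 0, mass < 1,
            all(posteriors >= 0))
  ord <- if (is.null(position)) order(-posteriors)
  else order(-posteriors, position)
  cum <- cumsum(posteriors[ord])
  m <- which(cum >= mass)
  take <- if (length(m)) m[1] else length(posteriors)
  member <- logical(length(posteriors))
  member[ord[seq_len(take)]] <- TRUE
  structure(member, size = take, order = ord)
}

#' Fine-map a locus from meta-regression (or comparator) results
#'
#' Restricts a result table to a locus — either an explicit
#' `chromosome:start-end` window or a flank around an index variant — and
#' converts its log Bayes' factors into posterior probabilities of driving
#' the association and a credible set.
#'
#' @param results a `transmeta` fit, or a data frame with columns
#'   `marker`, `chromosome`, `position` and a log Bayes' factor column.
#' @param chromosome,start,end explicit locus window (1-based, inclusive).
#' @param index marker name of an index variant; the locus is then
#'   `position(index) +/- flank`.
#' @param flank half-width of the index-variant window in bp (default
#'   500 kb).
#' @param mass credible-set coverage level (default 0.99).
#' @param lnbf_col name of the log Bayes'-factor column (default `"lnbf"`;
#'   use `"lnabf"` for fixed-effects output).
#' @return A `finemap` object: the locus table ranked by Bayes' factor with
#'   columns `posterior`, `cumulative` and `in_set`, plus attributes `size`,
#'   `interval` (spanned bp range of the set) and `mass`.
#' @export
finemap <- function(results, chromosome = NULL, start = NULL, end = NULL,
                    index = NULL, flank = 5e5, mass = 0.99,
                    lnbf_col = "lnbf") {
  r <- if (inherits(results, "transmeta")) results$results else results
  stopifnot(lnbf_col %in% names(r))
  if (!is.null(index)) {
    i <- match(index, r$marker)
    if (is.na(i)) stop("index variant not found: ", index)
    chromosome <- r$chromosome[i]
    start <- r$position[i] - flank
    end <- r$position[i] + flank
  }
  if (!is.null(chromosome))
    r <- r[r$chromosome == chromosome & r$position >= (start %||% -Inf) &
             r$position <= (end %||% Inf), , drop = FALSE]
  r <- r[is.finite(r[[lnbf_col]]), , drop = FALSE]
  if (nrow(r) == 0) stop("empty locus: no variants in window")
  post <- posterior_probabilities(r[[lnbf_col]])
  member <- credible_set(post, mass = mass, position = r$position)
  ord <- attr(member, "order")
  out <- r[ord, , drop = FALSE]
  out$posterior <- post[ord]
  out$cumulative <- cumsum(out$posterior)
  out$in_set <- member[ord]
  rownames(out) <- NULL
  structure(out, size = attr(member, "size"),
            interval = range(out$position[out$in_set]),
            mass = mass, class = c("finemap", "data.frame"))
}

#' @export
print.finemap <- function(x, n = 10, ...) {
  iv <- attr(x, "interval")
  cat(sprintf(
    "%.0f%% credible set: %d variant(s), interval %s-%s (%s bp)\n",
    100 * attr(x, "mass"), attr(x, "size"),
    format(iv[1], scientific = FALSE), format(iv[2], scientific = FALSE),
    format(diff(iv), scientific = FALSE, big.mark = ",")))
  cols <- intersect(c("marker", "chromosome", "position", "lnbf", "lnabf",
                      "posterior", "cumulative", "in_set"), names(x))
  print(utils::head(as.data.frame(x)[, cols], n), digits = 3,
        row.names = FALSE)
  if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more variant(s)\n", sep = "")
  invisible(x)
}
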