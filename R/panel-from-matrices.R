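# Direct panel construction from aligned effect/variance/frequency matrices,
# used by the simulation engine and available for programmatic input.

#' Build a study panel from aligned matrices
#'
#' Constructs a `study_panel` directly from variant-by-study matrices that
#' are already aligned to a common effect allele, bypassing file input. This
#' is how the simulation engine feeds per-population summary statistics into
#' the meta-regression.
#'
#' @param beta V-by-K matrix of allelic effects.
#' @param var V-by-K matrix of effect variances (se squared).
#' @param eaf V-by-K matrix of effect-allele frequencies (may contain `NA`).
#' @param n per-study sample size: scalar, length-K vector, or V-by-K matrix.
#' @param positions variant positions in bp (default 1 Mb spacing so that
#'   every variant falls in its own distance-marker bin).
#' @param chromosome chromosome label(s) (default `"1"`).
#' @param studies study labels (default from `eaf` column names).
#' @return A `study_panel`.
#' @export
panel_from_matrices <- function(beta, var, eaf, n,
                                positions = NULL, chromosome = "1",
                                studies = NULL) {
  beta <- as.matrix(beta); var <- as.matrix(var); eaf <- as.matrix(eaf)
  V <- nrow(beta); K <- ncol(beta)
  stopifnot(all(dim(var) == c(V, K)), all(dim(eaf) == c(V, K)), K >= 3)
  if (is.null(studies))
    studies <- colnames(eaf) %||% paste0("study", seq_len(K))
  if (is.null(positions)) positions <- seq_len(V) * 1e6 - 5e5
  if (!is.matrix(n)) n <- matrix(n, V, K, byrow = length(n) == K)
  present <- is.finite(beta) & is.finite(var) & var > 0
  variants <- data.frame(marker = paste0("var", seq_len(V)),
                         chromosome = rep_len(as.character(chromosome), V),
                         position = positions,
                         ea = "A", nea = "G", ambiguous = FALSE,
                         n_studies = rowSums(present))
  dn <- list(NULL, studies)
  dimnames(beta) <- dn; dimnames(var) <- dn; dimnames(eaf) <- dn
  dimnames(n) <- dn; dimnames(present) <- dn
  structure(list(studies = studies,
                 study_n = apply(n, 2, max, na.rm = TRUE),
                 variants = variants,
                 beta = beta, var = var, eaf = eaf, n = n,
                 present = present,
                 rejected = stats::setNames(integer(K), studies)),
            class = "study_panel")
}
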