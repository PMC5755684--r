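# Allele-frequency distance matrix between studies and axes of genetic
# variation by classical multi-dimensional scaling.

#' Select LD-thinned distance markers from a panel
#'
#' Divides the genome into fixed-size bins and selects at most one variant per
#' bin for the between-study distance calculation, to minimise the impact of
#' linkage disequilibrium. A variant qualifies if it is present, with a known
#' effect-allele frequency, in every study, and has minor allele frequency of
#' at least `min_maf` in every study. Within a bin the qualifying variant
#' nearest the bin midpoint is taken (ties go to the lower position), a
#' deterministic rule.
#'
#' @param panel a `study_panel`.
#' @param bin_size bin width in base pairs (default 1 Mb).
#' @param min_maf minimum per-study minor allele frequency (default 0.05).
#' @return Integer vector of selected variant indices into `panel$variants`.
#' @export
select_distance_markers <- function(panel, bin_size = 1e6, min_maf = 0.05) {
  stopifnot(inherits(panel, "study_panel"), bin_size > 0,
            min_maf >= 0, min_maf < 0.5)
  eaf <- panel$eaf
  maf <- pmin(eaf, 1 - eaf)
  qual <- rowSums(panel$present) == length(panel$studies) &
    apply(!is.na(maf) & maf >= min_maf, 1, all)
  if (!any(qual))
    stop("no variant qualifies as a distance marker; ",
         "relax min_maf or bin_size")
  v <- panel$variants
  bin <- paste(v$chromosome, floor(v$position / bin_size), sep = ":")
  mid <- (floor(v$position / bin_size) + 0.5) * bin_size
  sel <- integer(0)
  for (b in unique(bin[qual])) {
    i <- which(qual & bin == b)
    d <- abs(v$position[i] - mid[i])
    # nearest the midpoint; ties resolved to the lower position
    i <- i[order(d, v$position[i])]
    sel <- c(sel, i[1])
  }
  sort(sel)
}

#' Mean pairwise allele-frequency distance between studies
#'
#' For studies k and k' the distance over the selected markers j is
#' \deqn{d_{kk'} = \sqrt{ \sum_j I_j (p_{kj} - p_{k'j})^2 / \sum_j I_j },}
#' the root mean squared effect-allele frequency difference, which makes D a
#' matrix of Euclidean distances between the studies' frequency vectors
#' (scaled by the marker count). Setting `squared = TRUE` returns the raw
#' mean squared differences instead; classical scaling of the default D
#' operates on these squared entries, so the axes of genetic variation are
#' unaffected by the choice.
#'
#' @param panel a `study_panel`, or a K-by-M numeric matrix of effect-allele
#'   frequencies (one row per study).
#' @param markers indices of the selected distance markers (from
#'   [select_distance_markers()]); ignored when `panel` is a matrix. Default:
#'   all panel variants usable in every study.
#' @param squared return mean squared differences instead of their square
#'   root.
#' @return A K-by-K symmetric matrix with zero diagonal and attribute
#'   `n_markers`.
#' @export
compute_distance_matrix <- function(panel, markers = NULL, squared = FALSE) {
  if (inherits(panel, "study_panel")) {
    if (is.null(markers)) markers <- select_distance_markers(panel,
                                                             min_maf = 0)
    P <- t(panel$eaf[markers, , drop = FALSE])
    if (anyNA(P))
      stop("missing allele frequency among selected distance markers")
  } else {
    P <- as.matrix(panel)
    if (anyNA(P)) stop("missing allele frequency in frequency matrix")
  }
  M <- ncol(P)
  if (M < 1) stop("at least one distance marker is required")
  # mean squared difference via the Gram matrix: |p_k - p_k'|^2 / M
  G <- tcrossprod(P)
  sq <- outer(diag(G), diag(G), "+") - 2 * G
  D2 <- pmax(sq, 0) / M
  diag(D2) <- 0
  D <- if (squared) D2 else sqrt(D2)
  dimnames(D) <- list(rownames(P), rownames(P))
  attr(D, "n_markers") <- M
  D
}

#' Derive axes of genetic variation by classical multi-dimensional scaling
#'
#' Applies classical (Torgerson) scaling to the between-study distance matrix:
#' the squared distances are double-centred, eigendecomposed, and the leading
#' `T` coordinates \eqn{x_{kt} = e_{kt}\sqrt{\lambda_t}} are returned as
#' covariates for the meta-regression. The axis count is restricted to
#' `T <= K - 2` so that the residual-heterogeneity test keeps at least one
#' degree of freedom. Columns are mean-centred (a property of the scaling
#' solution) and ordered by decreasing eigenvalue; for a reproducible sign
#' convention, each column is oriented so its largest-magnitude entry is
#' positive.
#'
#' @param D K-by-K symmetric distance matrix (from
#'   [compute_distance_matrix()]).
#' @param T number of axes to extract, `1 <= T <= K - 2`.
#' @return An `ancestry_axes` object: a K-by-T matrix with attribute
#'   `eigenvalues` (all K - 1 scaling eigenvalues).
#' @export
derive_axes <- function(D, T) {
  D <- as.matrix(D)
  K <- nrow(D)
  if (T < 1 || T > K - 2)
    stop("axis count T must satisfy 1 <= T <= K - 2 (K = ", K, ")")
  mds <- stats::cmdscale(stats::as.dist(D), k = K - 2, eig = TRUE)
  eig <- mds$eig
  npos <- sum(eig > .Machine$double.eps * max(abs(eig), 1))
  if (npos < T)
    stop("only ", npos, " positive scaling eigenvalue(s); reduce T")
  X <- mds$points[, seq_len(T), drop = FALSE]
  # deterministic orientation: largest-magnitude entry of each axis positive
  for (t in seq_len(T)) {
    i <- which.max(abs(X[, t]))
    if (X[i, t] < 0) X[, t] <- -X[, t]
  }
  dimnames(X) <- list(rownames(D), paste0("axis", seq_len(T)))
  structure(X, eigenvalues = eig[seq_len(K - 1)], class = "ancestry_axes")
}

#' @export
print.ancestry_axes <- function(x, ...) {
  ev <- attr(x, "eigenvalues")
  cat("Axes of genetic variation (", nrow(x), " studies, ", ncol(x),
      " axes)\n", sep = "")
  tot <- sum(ev[ev > 0])
  cat("  eigenvalue share:",
      paste(sprintf("%.1f%%", 100 * ev[seq_len(ncol(x))] / tot),
            collapse = ", "), "\n")
  print(unclass(x)[, , drop = FALSE], digits = 4)
  invisible(x)
}
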