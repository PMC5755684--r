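# Reading, validation and cross-study harmonisation of GWAS summary statistics.

.CANONICAL_COLS <- c("marker", "chromosome", "position", "ea", "nea",
                     "eaf", "n", "beta", "se")

# default header names plus common aliases, matched case-insensitively
.DEFAULT_ALIASES <- list(
  marker     = c("MARKERNAME", "MARKER", "SNP", "RSID"),
  chromosome = c("CHROMOSOME", "CHR"),
  position   = c("POSITION", "POS", "BP"),
  ea         = c("EA", "EFFECT_ALLELE"),
  nea        = c("NEA", "OTHER_ALLELE", "OA"),
  eaf        = c("EAF", "EFFECT_ALLELE_FREQ", "FREQ"),
  n          = c("N", "SAMPLESIZE"),
  beta       = c("BETA", "B"),
  se         = c("SE", "STDERR")
)

#' Read and validate one study's GWAS summary-statistic file
#'
#' Reads a whitespace- or tab-delimited flat file with one row per variant and
#' a header, resolves the required columns (marker name, chromosome, position,
#' effect/other allele, effect-allele frequency, sample size, allelic effect,
#' standard error), and validates every row. Rows failing validation are
#' dropped and counted in a per-file quality-control report attached to the
#' result. Gzip-compressed files are read transparently.
#'
#' Validation rules: `beta`, `se`, `n`, `position` must parse as numbers; `se`
#' must be strictly positive and `n` positive; `eaf`, when present, must lie
#' in [0, 1] (a missing `eaf` is tolerated — the variant is then unusable for
#' distance-marker selection but still contributes to meta-regression);
#' alleles must be non-empty and distinct. Duplicate marker rows keep the
#' first occurrence, with a warning.
#'
#' @param path path to the summary-statistic file (optionally `.gz`).
#' @param study_id label for the study; defaults to the file name.
#' @param column_map optional named character vector remapping canonical
#'   column names (`marker`, `chromosome`, `position`, `ea`, `nea`, `eaf`,
#'   `n`, `beta`, `se`) to the header names used in the file.
#' @return A `study_table`: a data frame with the canonical columns, an
#'   `ambiguous` strand-ambiguity flag (A/T and C/G variants), and attributes
#'   `study_id` and `qc` (a data frame of drop reasons and counts).
#' @examples
#' tf <- tempfile(fileext = ".txt")
#' writeLines(c("MARKERNAME CHR POS EA NEA EAF N BETA SE",
#'              "rs1 1 1000 A G 0.30 5000 0.021 0.011",
#'              "rs2 1 2000 T C 0.52 5000 -0.007 0.010"), tf)
#' st <- read_study_file(tf, study_id = "demo")
#' nrow(st)
#' @seealso [assemble_panel()], [write_qc_report()]
#' @export
read_study_file <- function(path, study_id = NULL, column_map = NULL) {
  if (!file.exists(path)) stop("summary-statistic file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "")
  hdr <- toupper(names(raw))
  idx <- integer(0)
  for (cc in .CANONICAL_COLS) {
    wanted <- if (!is.null(column_map) && cc %in% names(column_map))
      toupper(column_map[[cc]]) else .DEFAULT_ALIASES[[cc]]
    hit <- which(hdr %in% wanted)
    if (length(hit) == 0)
      stop("required column '", cc, "' not found in ", path,
           " (looked for: ", paste(wanted, collapse = ", "), ")")
    idx[cc] <- hit[1]
  }
  d <- raw[, idx]
  names(d) <- .CANONICAL_COLS
  rows_read <- nrow(d)

  d$marker <- as.character(d$marker)
  d$chromosome <- as.character(d$chromosome)
  d$ea <- toupper(as.character(d$ea))
  d$nea <- toupper(as.character(d$nea))
  for (cc in c("position", "eaf", "n", "beta", "se"))
    d[[cc]] <- suppressWarnings(as.numeric(as.character(d[[cc]])))

  drops <- c(bad_numeric = 0L, se_nonpositive = 0L, n_nonpositive = 0L,
             eaf_out_of_range = 0L, allele_invalid = 0L,
             duplicate_marker = 0L)
  bad <- !is.finite(d$beta) | !is.finite(d$se) | !is.finite(d$n) |
    !is.finite(d$position)
  drops["bad_numeric"] <- sum(bad)
  ok <- !bad
  v <- ok & d$se <= 0
  drops["se_nonpositive"] <- sum(v, na.rm = TRUE); ok <- ok & !v
  v <- ok & d$n <= 0
  drops["n_nonpositive"] <- sum(v, na.rm = TRUE); ok <- ok & !v
  v <- ok & !is.na(d$eaf) & (d$eaf < 0 | d$eaf > 1)
  drops["eaf_out_of_range"] <- sum(v, na.rm = TRUE); ok <- ok & !v
  v <- ok & (is.na(d$ea) | is.na(d$nea) | d$ea == "" | d$nea == "" |
               d$ea == d$nea | !grepl("^[A-Z]+$", d$ea) |
               !grepl("^[A-Z]+$", d$nea))
  drops["allele_invalid"] <- sum(v, na.rm = TRUE); ok <- ok & !v
  d <- d[ok, , drop = FALSE]

  dup <- duplicated(d$marker)
  if (any(dup)) {
    drops["duplicate_marker"] <- sum(dup)
    warning(sum(dup), " duplicate marker row(s) in ", path,
            "; first occurrence kept")
    d <- d[!dup, , drop = FALSE]
  }

  d$ambiguous <- .strand_ambiguous(d$ea, d$nea)
  rownames(d) <- NULL
  structure(d,
            study_id = study_id %||% basename(path),
            qc = data.frame(reason = c("rows_read", names(drops),
                                       "rows_kept"),
                            n = c(rows_read, unname(drops), nrow(d))),
            class = c("study_table", "data.frame"))
}

# A/T and C/G single-nucleotide pairs cannot be disambiguated by strand
.strand_ambiguous <- function(ea, nea) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ea %in% names(comp) & nea %in% names(comp) & unname(comp[ea]) == nea
}

#' Write the per-file quality-control report of a study table
#'
#' @param table a `study_table` from [read_study_file()].
#' @param path output path for the tab-delimited report.
#' @return Invisibly, the report data frame.
#' @export
write_qc_report <- function(table, path) {
  qc <- attr(table, "qc")
  if (is.null(qc)) stop("table carries no QC report")
  utils::write.table(cbind(study = attr(table, "study_id"), qc), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(qc)
}

#' Align summary-statistic records to a reference effect allele
#'
#' Records whose allele pair matches the reference pair in the same
#' orientation are returned unchanged; records matching in the swapped
#' orientation have the allelic effect negated and the effect-allele frequency
#' reflected (`eaf` becomes `1 - eaf`); any other allele pair is rejected with
#' status `"allele_mismatch"`. Strand-ambiguous pairs (A/T, C/G) are
#' harmonised literally, not strand-resolved.
#'
#' @param ea,nea effect and other allele of the record(s); vectors recycle.
#' @param beta,eaf allelic effect and effect-allele frequency of the
#'   record(s); `eaf` may be `NA`.
#' @param ref_ea,ref_nea reference effect and other allele.
#' @return A data frame with columns `status` (`"ok"`, `"flipped"` or
#'   `"allele_mismatch"`), `beta` and `eaf` (both `NA` on mismatch).
#' @examples
#' harmonize_alleles("G", "A", beta = 0.1, eaf = 0.3,
#'                   ref_ea = "A", ref_nea = "G")
#' @export
harmonize_alleles <- function(ea, nea, beta, eaf, ref_ea, ref_nea) {
  n <- max(length(ea), length(nea), length(beta), length(eaf))
  ea <- rep_len(toupper(ea), n); nea <- rep_len(toupper(nea), n)
  beta <- rep_len(beta, n); eaf <- rep_len(eaf, n)
  ref_ea <- rep_len(toupper(ref_ea), n); ref_nea <- rep_len(toupper(ref_nea), n)
  same <- ea == ref_ea & nea == ref_nea
  swap <- ea == ref_nea & nea == ref_ea & !same
  status <- ifelse(same, "ok", ifelse(swap, "flipped", "allele_mismatch"))
  out_beta <- ifelse(same, beta, ifelse(swap, -beta, NA_real_))
  out_eaf <- ifelse(same, eaf, ifelse(swap, 1 - eaf, NA_real_))
  data.frame(status = status, beta = out_beta, eaf = out_eaf)
}

#' Assemble harmonised study tables into a cross-study variant panel
#'
#' Variants are keyed by chromosome, position and unordered allele pair;
#' marker names are carried as labels only. The reference effect allele of
#' each variant is taken from the first study (in the order given) carrying
#' it; later studies are aligned with [harmonize_alleles()], and records whose
#' allele pair does not match are rejected and counted. At least three studies
#' are required (the meta-regression needs `T <= K - 2` with `T >= 1`).
#'
#' @param tables list of `study_table` objects (or data frames with the
#'   canonical columns), in study order.
#' @return A `study_panel`: a list with elements `studies` (study labels),
#'   `study_n` (per-study sample size, the maximum over that study's rows),
#'   `variants` (data frame: marker, chromosome, position, ea, nea,
#'   ambiguous, n_studies), and variant-by-study matrices `beta`, `var`,
#'   `eaf`, `n`, `present`, plus `rejected` (per-study allele-mismatch
#'   counts).
#' @export
assemble_panel <- function(tables) {
  K <- length(tables)
  if (K < 3)
    stop("at least 3 studies are required (axes need T <= K - 2, T >= 1)")
  ids <- vapply(seq_len(K), function(k)
    attr(tables[[k]], "study_id") %||% paste0("study", k), character(1))

  pair_key <- function(d) {
    a1 <- pmin(d$ea, d$nea); a2 <- pmax(d$ea, d$nea)
    paste(d$chromosome, d$position, a1, a2, sep = ":")
  }
  keys <- character(0)
  ref <- list()
  for (k in seq_len(K)) {
    d <- tables[[k]]
    kk <- pair_key(d)
    new <- !(kk %in% keys)
    if (any(new)) {
      keys <- c(keys, kk[new])
      ref[kk[new]] <- lapply(which(new), function(i)
        list(marker = d$marker[i], chromosome = d$chromosome[i],
             position = d$position[i], ea = d$ea[i], nea = d$nea[i],
             ambiguous = isTRUE(d$ambiguous[i])))
    }
  }
  V <- length(keys)
  m <- function() matrix(NA_real_, V, K, dimnames = list(keys, ids))
  beta <- m(); vvar <- m(); eaf <- m(); nn <- m()
  present <- matrix(FALSE, V, K, dimnames = list(keys, ids))
  rejected <- integer(K)

  ref_ea <- vapply(ref[keys], `[[`, character(1), "ea")
  ref_nea <- vapply(ref[keys], `[[`, character(1), "nea")
  for (k in seq_len(K)) {
    d <- tables[[k]]
    kk <- pair_key(d)
    i <- match(kk, keys)
    h <- harmonize_alleles(d$ea, d$nea, d$beta, d$eaf,
                           ref_ea[i], ref_nea[i])
    bad <- h$status == "allele_mismatch"
    rejected[k] <- sum(bad)
    keep <- which(!bad)
    beta[i[keep], k] <- h$beta[keep]
    vvar[i[keep], k] <- d$se[keep]^2
    eaf[i[keep], k] <- h$eaf[keep]
    nn[i[keep], k] <- d$n[keep]
    present[i[keep], k] <- TRUE
  }

  variants <- data.frame(
    marker = vapply(ref[keys], `[[`, character(1), "marker"),
    chromosome = vapply(ref[keys], `[[`, character(1), "chromosome"),
    position = vapply(ref[keys], function(x) as.numeric(x$position),
                      numeric(1)),
    ea = ref_ea, nea = ref_nea,
    ambiguous = vapply(ref[keys], `[[`, logical(1), "ambiguous"),
    n_studies = rowSums(present),
    row.names = NULL)
  if (any(variants$ambiguous))
    warning(sum(variants$ambiguous),
            " strand-ambiguous (A/T or C/G) variant(s); harmonised literally")

  structure(list(studies = ids,
                 study_n = apply(nn, 2, max, na.rm = TRUE),
                 variants = variants,
                 beta = beta, var = vvar, eaf = eaf, n = nn,
                 present = present,
                 rejected = stats::setNames(rejected, ids)),
            class = "study_panel")
}

#' @export
print.study_panel <- function(x, ...) {
  cat("Cross-study GWAS summary-statistic panel\n")
  cat("  studies:  ", length(x$studies), " (",
      paste(utils::head(x$studies, 5), collapse = ", "),
      if (length(x$studies) > 5) ", ..." else "", ")\n", sep = "")
  cat("  variants: ", nrow(x$variants), "\n", sep = "")
  cat("  complete in all studies: ", sum(rowSums(x$present) ==
                                           length(x$studies)), "\n", sep = "")
  if (any(x$rejected > 0))
    cat("  allele-mismatch rejections: ", sum(x$rejected), "\n", sep = "")
  invisible(x)
}

#' Filter panel variants by contributing sample-size fraction
#'
#' Retains variants whose contributing studies' summed sample size reaches at
#' least `min_fraction` of the total sample size across all studies, the
#' quality-control rule used for trans-ethnic meta-analyses (50% for the
#' kidney-function application, 80% for the type 2 diabetes application).
#'
#' @param panel a `study_panel`.
#' @param min_fraction required fraction of the total sample size, in (0, 1].
#' @return The filtered `study_panel`.
#' @export
presence_filter <- function(panel, min_fraction) {
  stopifnot(inherits(panel, "study_panel"),
            is.numeric(min_fraction), min_fraction > 0, min_fraction <= 1)
  total <- sum(panel$study_n)
  contrib <- rowSums(panel$n * panel$present, na.rm = TRUE)
  keep <- contrib >= min_fraction * total
  subset_panel(panel, keep)
}

# subset a panel to a logical/integer variant index
subset_panel <- function(panel, i) {
  panel$variants <- panel$variants[i, , drop = FALSE]
  rownames(panel$variants) <- NULL
  for (f in c("beta", "var", "eaf", "n", "present"))
    panel[[f]] <- panel[[f]][i, , drop = FALSE]
  panel
}
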