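#' Instrument-selection criteria
#'
#' Bundles the thresholds used to select instrumental variables: genome-wide
#' significance, LD clumping parameters, and the minimum F-statistic for
#' instrument strength.
#'
#' @param p_threshold Significance threshold; variants with p-value strictly
#'   below it are candidate instruments. Default `5e-8`.
#' @param clump_r2 Maximum squared LD correlation allowed between retained
#'   instruments. Default `0.001`.
#' @param clump_window_kb Window (kb) within which the r-squared constraint
#'   applies when positions are available. Default `10000`.
#' @param f_min Minimum F-statistic; weaker instruments are excluded.
#'   Default `10`.
#' @return An object of class `instrument_criteria`.
#' @export
instrument_criteria <- function(p_threshold = 5e-8,
                                clump_r2 = 0.001,
                                clump_window_kb = 10000,
                                f_min = 10) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            clump_r2 >= 0, clump_r2 <= 1,
            clump_window_kb > 0, f_min >= 0)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_window_kb = clump_window_kb, f_min = f_min),
            class = "instrument_criteria")
}

#' Select genome-wide-significant variants
#'
#' Keeps variants with p-value strictly below the threshold; the original
#' row order is preserved.
#'
#' @param records Summary-statistics `data.frame`.
#' @param p_threshold Significance threshold, default `5e-8`.
#' @return The filtered `data.frame`.
#' @export
select_significant <- function(records, p_threshold = 5e-8) {
  out <- records[records$pval < p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instrument strength F-statistic
#'
#' F = beta^2 / se^2, the squared z-score used as the per-variant
#' instrument-strength measure; F below 10 conventionally marks a weak
#' instrument.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), strictly positive.
#' @return Numeric vector of F values.
#' @export
f_statistic <- function(beta, se) {
  if (any(se <= 0)) stop("se must be positive")
  beta^2 / se^2
}

#' Exclude weak instruments
#'
#' Retains variants whose F-statistic is at least `f_min` (instruments with
#' F exactly at the threshold are kept; only strictly weaker ones are
#' excluded).
#'
#' @param records Summary-statistics `data.frame`.
#' @param f_min Minimum F-statistic, default 10.
#' @return The filtered `data.frame`.
#' @export
filter_weak <- function(records, f_min = 10) {
  if (nrow(records) == 0) return(records)
  out <- records[f_statistic(records$beta, records$se) >= f_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct an LD matrix
#'
#' @param variant_ids Character vector of variant identifiers.
#' @param r2 Square symmetric matrix of squared correlations in \[0, 1\]
#'   with unit diagonal, in the order of `variant_ids`.
#' @return An `ld_matrix` object.
#' @export
ld_matrix <- function(variant_ids, r2) {
  r2 <- as.matrix(r2)
  stopifnot(length(variant_ids) == nrow(r2), nrow(r2) == ncol(r2))
  if (any(r2 < 0 | r2 > 1)) stop("r2 values must lie in [0, 1]")
  if (any(abs(diag(r2) - 1) > 1e-12)) stop("r2 diagonal must be 1")
  if (any(abs(r2 - t(r2)) > 1e-8)) stop("r2 matrix must be symmetric")
  dimnames(r2) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = as.character(variant_ids), r2 = r2),
            class = "ld_matrix")
}

#' Read an LD matrix from a square TSV
#'
#' Expects a header row of variant IDs and one numeric row per variant.
#'
#' @param path File path.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  m <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  ld_matrix(names(m), as.matrix(m))
}

#' Greedy LD clumping of instruments
#'
#' Prunes correlated instruments by the standard greedy rule: variants are
#' visited in order of ascending p-value (ties broken by lexicographic
#' variant ID for determinism) and accepted only if their squared LD
#' correlation with every already-accepted variant within the window is at
#' most `clump_r2`. Variants absent from the LD matrix are treated as
#' independent and a message is emitted. When chromosome/position columns
#' are unavailable the window is ignored and r-squared alone governs.
#'
#' @param records Summary-statistics `data.frame`.
#' @param ld An [ld_matrix()] (or `NULL`, treating all variants as
#'   independent).
#' @param criteria An [instrument_criteria()].
#' @return Accepted variants, sorted by ascending p-value.
#' @export
clump <- function(records, ld = NULL, criteria = instrument_criteria()) {
  if (nrow(records) == 0) return(records)
  ord <- order(records$pval, records$variant_id)
  rec <- records[ord, , drop = FALSE]
  ids <- rec$variant_id
  in_ld <- if (is.null(ld)) rep(FALSE, nrow(rec)) else ids %in% ld$variant_ids
  if (!is.null(ld) && any(!in_ld)) {
    message(sum(!in_ld), " variant(s) absent from LD matrix, ",
            "treated as independent")
  }
  have_pos <- all(!is.na(rec$pos)) && all(!is.na(rec$chrom))
  accepted <- integer(0)
  for (i in seq_len(nrow(rec))) {
    ok <- TRUE
    if (in_ld[i]) {
      for (j in accepted) {
        if (!in_ld[j]) next
        if (have_pos) {
          same_window <- rec$chrom[i] == rec$chrom[j] &&
            abs(rec$pos[i] - rec$pos[j]) <= criteria$clump_window_kb * 1000
          if (!same_window) next
        }
        if (ld$r2[ids[i], ids[j]] > criteria$clump_r2) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) accepted <- c(accepted, i)
  }
  out <- rec[accepted, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full instrument-selection cascade
#'
#' Applies, in order: the significance threshold, LD clumping, and the
#' weak-instrument F filter. MR-PRESSO outlier removal operates on
#' harmonized exposure-outcome pairs and is applied downstream (see
#' [mr_presso()]).
#'
#' @param records Summary-statistics `data.frame`.
#' @param ld Optional [ld_matrix()].
#' @param criteria An [instrument_criteria()].
#' @return The selected instruments.
#' @export
select_instruments <- function(records, ld = NULL,
                               criteria = instrument_criteria()) {
  sig <- select_significant(records, criteria$p_threshold)
  clumped <- clump(sig, ld, criteria)
  filter_weak(clumped, criteria$f_min)
}
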