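#' Read GWAS summary statistics from delimited text
#'
#' Reads a delimited file of per-variant association statistics and returns a
#' validated summary-statistics table. Rows violating basic invariants
#' (identical alleles, non-positive standard error, p-value outside (0, 1],
#' allele frequency outside \[0, 1\]) are dropped with a message reporting
#' the count. Allele codes are upper-cased. Gzipped files are read
#' transparently.
#'
#' @param path Path to a delimited text file (optionally gzipped).
#' @param column_map Named character vector mapping the canonical field names
#'   (`variant_id`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pval`, `n`, `chrom`, `pos`) to column names in the file. Mandatory
#'   fields: `variant_id`, `effect_allele`, `other_allele`, `beta`, `se`,
#'   `pval`; the rest are optional and filled with `NA` when unmapped.
#' @param delimiter Field delimiter, default tab.
#' @return A `data.frame` with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`, `chrom`, `pos` —
#'   one row per retained variant.
#' @export
read_summary_stats <- function(path,
                               column_map = NULL,
                               delimiter = "\t") {
  if (!file.exists(path)) {
    stop("summary-statistics file not found: ", path)
  }
  canonical <- c("variant_id", "effect_allele", "other_allele", "eaf",
                 "beta", "se", "pval", "n", "chrom", "pos")
  if (is.null(column_map)) {
    column_map <- setNames(canonical, canonical)
  }
  mandatory <- c("variant_id", "effect_allele", "other_allele",
                 "beta", "se", "pval")
  missing_map <- setdiff(mandatory, names(column_map))
  if (length(missing_map) > 0) {
    stop("column_map lacks mandatory fields: ",
         paste(missing_map, collapse = ", "))
  }
  dt <- data.table::fread(path, sep = delimiter, header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  if (nrow(dt) == 0) {
    stop("empty summary-statistics file: ", path)
  }
  absent <- setdiff(unname(column_map[mandatory]), names(dt))
  if (length(absent) > 0) {
    stop("mapped columns absent from file: ", paste(absent, collapse = ", "))
  }
  out <- data.frame(variant_id = as.character(dt[[column_map[["variant_id"]]]]),
                    stringsAsFactors = FALSE)
  out$effect_allele <- toupper(as.character(dt[[column_map[["effect_allele"]]]]))
  out$other_allele <- toupper(as.character(dt[[column_map[["other_allele"]]]]))
  grab_num <- function(field) {
    col <- column_map[field]
    if (!is.na(col) && field %in% names(column_map) && col %in% names(dt)) {
      as.numeric(dt[[col]])
    } else {
      rep(NA_real_, nrow(dt))
    }
  }
  out$eaf <- grab_num("eaf")
  out$beta <- as.numeric(dt[[column_map[["beta"]]]])
  out$se <- as.numeric(dt[[column_map[["se"]]]])
  out$pval <- as.numeric(dt[[column_map[["pval"]]]])
  out$n <- grab_num("n")
  out$chrom <- if ("chrom" %in% names(column_map) &&
                   column_map[["chrom"]] %in% names(dt)) {
    as.character(dt[[column_map[["chrom"]]]])
  } else {
    rep(NA_character_, nrow(dt))
  }
  out$pos <- grab_num("pos")
  validate_sumstats(out)
}

#' Validate a summary-statistics table
#'
#' Drops rows that violate the record invariants and reports how many were
#' removed. Duplicate variant IDs are resolved by keeping the row with the
#' smallest p-value.
#'
#' @param stats A summary-statistics `data.frame` as produced by
#'   [read_summary_stats()].
#' @return The filtered `data.frame`.
#' @export
validate_sumstats <- function(stats) {
  valid_allele <- function(a) a %in% c("A", "C", "G", "T")
  keep <- valid_allele(stats$effect_allele) &
    valid_allele(stats$other_allele) &
    stats$effect_allele != stats$other_allele &
    is.finite(stats$beta) &
    is.finite(stats$se) & stats$se > 0 &
    is.finite(stats$pval) & stats$pval > 0 & stats$pval <= 1 &
    (is.na(stats$eaf) | (stats$eaf >= 0 & stats$eaf <= 1)) &
    (is.na(stats$n) | stats$n >= 1)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(n_drop, " row(s) dropped for invariant violations")
  }
  out <- stats[keep, , drop = FALSE]
  if (anyDuplicated(out$variant_id)) {
    ord <- order(out$pval)
    dup <- duplicated(out$variant_id[ord])
    message(sum(dup), " duplicate variant id(s) resolved by smallest p-value")
    out <- out[ord, , drop = FALSE][!dup, , drop = FALSE]
    out <- out[order(match(out$variant_id, stats$variant_id)), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  unname(COMPLEMENT[a1] == a2)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome study's effects to the exposure study's effect allele
#' at every shared variant, producing the per-SNP table that all MR
#' estimators consume. When the outcome alleles are reported swapped, the
#' outcome beta sign is flipped and the allele frequency complemented;
#' strand-complemented allele codes are recognized for non-palindromic SNPs.
#' Palindromic SNPs (A/T or C/G), whose strand cannot be resolved from
#' allele labels, are handled per `palindrome_policy`: always dropped, or
#' aligned by allele-frequency concordance and dropped only when either
#' study's frequency falls inside `eaf_ambiguity_band` (or is missing).
#' Variants with incompatible allele pairs are removed with a message.
#'
#' @param exposure,outcome Summary-statistics `data.frame`s
#'   (see [read_summary_stats()]).
#' @param palindrome_policy `"infer_by_eaf"` (default) or `"drop"`.
#' @param eaf_ambiguity_band Frequency interval within which a palindromic
#'   SNP is considered unresolvable; default `c(0.42, 0.58)`.
#' @param exposure_name,outcome_name Labels carried into results.
#' @return A `harmonized_set`: a `data.frame` with columns `variant_id`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome` and
#'   attributes `exposure_name` and `outcome_name`.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("infer_by_eaf", "drop"),
                      eaf_ambiguity_band = c(0.42, 0.58),
                      exposure_name = "exposure",
                      outcome_name = "outcome") {
  palindrome_policy <- match.arg(palindrome_policy)
  if (nrow(exposure) == 0 || nrow(outcome) == 0) {
    stop("both exposure and outcome tables must be non-empty")
  }
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0) {
    stop("no shared variants between exposure and outcome: no instruments")
  }
  ex <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$variant_id), , drop = FALSE]

  ea_x <- ex$effect_allele; oa_x <- ex$other_allele
  ea_y <- ou$effect_allele; oa_y <- ou$other_allele
  pal <- is_palindromic(ea_x, oa_x)

  action <- rep(NA_character_, length(shared))  # keep | flip | drop
  same <- ea_y == ea_x & oa_y == oa_x
  swap <- ea_y == oa_x & oa_y == ea_x
  # for palindromic SNPs the strand complement is indistinguishable from a
  # swap, so complement matching applies to non-palindromic variants only
  comp_same <- !pal & ea_y == unname(COMPLEMENT[ea_x]) &
    oa_y == unname(COMPLEMENT[oa_x])
  comp_swap <- !pal & ea_y == unname(COMPLEMENT[oa_x]) &
    oa_y == unname(COMPLEMENT[ea_x])

  action[same | comp_same] <- "keep"
  action[swap | comp_swap] <- "flip"
  incompatible <- is.na(action)
  if (any(incompatible)) {
    message(sum(incompatible), " SNP(s) removed: incompatible allele pairs")
    action[incompatible] <- "drop"
  }

  pal_idx <- which(pal & action != "drop")
  if (length(pal_idx) > 0) {
    if (palindrome_policy == "drop") {
      action[pal_idx] <- "drop"
    } else {
      ambiguous <- function(f) {
        is.na(f) | (f >= eaf_ambiguity_band[1] & f <= eaf_ambiguity_band[2])
      }
      for (i in pal_idx) {
        fx <- ex$eaf[i]
        # a swapped palindromic pair reports the frequency of the opposite
        # allele; compare on the exposure effect-allele scale
        fy <- if (action[i] == "flip") 1 - ou$eaf[i] else ou$eaf[i]
        if (ambiguous(fx) || ambiguous(ou$eaf[i])) {
          action[i] <- "drop"
        } else if ((fx < 0.5) != (fy < 0.5)) {
          # frequencies disagree: the outcome study reports the complement
          # strand, so the apparent alignment is inverted
          action[i] <- if (action[i] == "flip") "keep" else "flip"
        }
      }
    }
  }

  keep <- action != "drop"
  sign_flip <- ifelse(action[keep] == "flip", -1, 1)
  h <- data.frame(variant_id = shared[keep],
                  beta_exposure = ex$beta[keep],
                  se_exposure = ex$se[keep],
                  beta_outcome = sign_flip * ou$beta[keep],
                  se_outcome = ou$se[keep],
                  stringsAsFactors = FALSE)
  if (nrow(h) == 0) {
    stop("no variants survive harmonization: no instruments")
  }
  rownames(h) <- NULL
  structure(h,
            exposure_name = exposure_name,
            outcome_name = outcome_name,
            class = c("harmonized_set", "data.frame"))
}

#' Write a harmonized set as TSV
#'
#' Fixed column order: `variant_id`, `b_x`, `s_x`, `b_y`, `s_y`.
#'
#' @param h A `harmonized_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(h, path) {
  out <- data.frame(variant_id = h$variant_id,
                    b_x = h$beta_exposure, s_x = h$se_exposure,
                    b_y = h$beta_outcome, s_y = h$se_outcome)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
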