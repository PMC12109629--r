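load_study <- function(x, column_map = NULL, delimiter = "\t") {
  if (is.character(x)) {
    read_summary_stats(x, column_map = column_map, delimiter = delimiter)
  } else {
    validate_sumstats(x)
  }
}

sanitize_name <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

#' Assemble a pipeline run configuration
#'
#' @param exposures Named list of exposure studies: each element a
#'   summary-statistics `data.frame` or a file path.
#' @param mediators Named list of candidate mediator studies.
#' @param outcome One outcome study (`data.frame` or path).
#' @param criteria An [instrument_criteria()].
#' @param screen_exposure,screen_mediator,screen_step1 [screen_criteria()]
#'   for the exposure-to-outcome, mediator-to-outcome and
#'   exposure-to-mediator screens. Defaults: IVW p < 0.05 for the exposure
#'   and step-1 screens, p < 0.01 for the mediator screen.
#' @param ld Optional named list of [ld_matrix()] objects, keyed by study
#'   name.
#' @param effects_model,n_boot,bandwidth_factor,n_sim,seed Estimator and
#'   resampling settings.
#' @param presso Apply MR-PRESSO outlier removal after harmonization,
#'   default `TRUE`.
#' @param output_dir Directory for result tables and the manifest.
#' @param column_map,delimiter Passed to the reader for path inputs.
#' @return A `run_config` list.
#' @export
run_config <- function(exposures, mediators, outcome,
                       criteria = instrument_criteria(),
                       screen_exposure = screen_criteria(ivw_p_max = 0.05),
                       screen_mediator = screen_criteria(ivw_p_max = 0.01),
                       screen_step1 = screen_criteria(ivw_p_max = 0.05),
                       ld = list(),
                       effects_model = "multiplicative_random",
                       n_boot = 1000, bandwidth_factor = 1,
                       n_sim = 1000, seed = 42, presso = TRUE,
                       output_dir = tempfile("mrmediation_run_"),
                       column_map = NULL, delimiter = "\t") {
  stopifnot(length(exposures) >= 1, length(mediators) >= 0,
            !is.null(names(exposures)))
  structure(list(exposures = exposures, mediators = mediators,
                 outcome = outcome, criteria = criteria,
                 screen_exposure = screen_exposure,
                 screen_mediator = screen_mediator,
                 screen_step1 = screen_step1, ld = ld,
                 effects_model = effects_model, n_boot = n_boot,
                 bandwidth_factor = bandwidth_factor, n_sim = n_sim,
                 seed = seed, presso = presso, output_dir = output_dir,
                 column_map = column_map, delimiter = delimiter),
            class = "run_config")
}

analyse_pair <- function(iv, to_stats, config, pair_id, screen,
                         out_dir, log) {
  h <- harmonize(iv, to_stats)
  presso_rep <- NULL
  if (config$presso && nrow(h) >= 4) {
    presso_rep <- mr_presso(h, n_sim = config$n_sim, seed = config$seed)
    if (length(presso_rep$outlier_indices) > 0 &&
        length(presso_rep$outlier_indices) < nrow(h) - 1) {
      log(sprintf("%s: %d PRESSO outlier(s) removed", pair_id,
                  length(presso_rep$outlier_indices)))
      h <- h[-presso_rep$outlier_indices, , drop = FALSE]
    }
  }
  log(sprintf("%s: %d instrument(s) after harmonization/outlier removal",
              pair_id, nrow(h)))
  bundle <- mr_all_methods(h, effects_model = config$effects_model,
                           n_boot = config$n_boot, seed = config$seed,
                           bandwidth_factor = config$bandwidth_factor)
  het <- if (nrow(h) >= 2) cochran_q(h, bundle$ivw$beta) else NULL
  egger_p <- if (!is.null(bundle$egger)) bundle$egger$intercept_pval
             else NA_real_
  verdict <- screen_pair(bundle, egger_p, screen, pair_id)

  tag <- sanitize_name(pair_id)
  data.table::fwrite(as.data.frame(bundle),
                     file.path(out_dir, paste0("methods_", tag, ".tsv")),
                     sep = "\t")
  sens <- data.frame(
    stat = c("cochran_q", "cochran_q_pval", "egger_intercept_pval",
             "presso_global_pval", "presso_n_outliers"),
    value = c(het$q %||% NA_real_, het$pval %||% NA_real_, egger_p,
              presso_rep$global_pval %||% NA_real_,
              if (is.null(presso_rep)) NA_real_
              else length(presso_rep$outlier_indices)))
  data.table::fwrite(sens,
                     file.path(out_dir, paste0("sensitivity_", tag, ".tsv")),
                     sep = "\t")
  if (nrow(h) >= 3) {
    data.table::fwrite(leave_one_out(h, config$effects_model),
                       file.path(out_dir, paste0("loo_", tag, ".tsv")),
                       sep = "\t")
    tabs <- diagnostic_tables(h)
    data.table::fwrite(tabs$scatter,
                       file.path(out_dir, paste0("scatter_", tag, ".tsv")),
                       sep = "\t")
    data.table::fwrite(tabs$funnel,
                       file.path(out_dir, paste0("funnel_", tag, ".tsv")),
                       sep = "\t")
  }
  list(bundle = bundle, het = het, verdict = verdict, h = h)
}

#' Run the full two-step MR mediation workflow
#'
#' Orchestrates the end-to-end design: (1) forward MR of every exposure on
#' the outcome with sensitivity diagnostics and screening; (2) reverse MR
#' of the outcome on each exposure (reported, never gating); (3) screening
#' of every candidate mediator against the outcome; (4) screening of each
#' passing exposure against each passing mediator; (5) product-of-
#' coefficients mediation for every surviving triple. Screens
#' short-circuit: pairs failing an upstream screen are not carried
#' forward. Per-pair failures are logged and the pipeline continues;
#' an empty mediation report is a valid outcome.
#'
#' All tables are written as TSV under `config$output_dir`, with a JSON
#' manifest recording every setting and seed so any number in the output
#' is regenerable.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `screens` (verdict table), `mediation`
#'   (Table-2 style `data.frame`), `reverse` (reverse-MR table), and
#'   `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log <- function(msg) {
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  exposures <- lapply(config$exposures, load_study,
                      column_map = config$column_map,
                      delimiter = config$delimiter)
  mediators <- lapply(config$mediators, load_study,
                      column_map = config$column_map,
                      delimiter = config$delimiter)
  outcome <- load_study(config$outcome, column_map = config$column_map,
                        delimiter = config$delimiter)

  screens <- list()
  note_screen <- function(stage, v) {
    screens[[length(screens) + 1]] <<- data.frame(
      stage = stage, pair = v$pair_id, ivw_p = v$ivw_p,
      p_pass = v$p_pass, direction_pass = v$direction_pass,
      pleiotropy_pass = v$pleiotropy_pass, verdict = v$verdict,
      stringsAsFactors = FALSE)
  }
  instruments_of <- function(stats, name) {
    iv <- select_instruments(stats, config$ld[[name]], config$criteria)
    log(sprintf("%s: %d instrument(s) after selection", name, nrow(iv)))
    iv
  }

  # stage 1: forward MR, exposure -> outcome
  exposure_pass <- character(0)
  stage1 <- list()
  for (ex_name in names(exposures)) {
    pair_id <- paste0(ex_name, "->outcome")
    res <- tryCatch({
      iv <- instruments_of(exposures[[ex_name]], ex_name)
      analyse_pair(iv, outcome, config, pair_id,
                   config$screen_exposure, out_dir, log)
    }, error = function(e) {
      log(sprintf("%s: skipped (%s)", pair_id, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    stage1[[ex_name]] <- res
    note_screen("exposure->outcome", res$verdict)
    if (res$verdict$verdict != "fail") exposure_pass <- c(exposure_pass,
                                                          ex_name)
  }

  # stage 2: reverse MR, outcome -> exposure (reported only)
  reverse_rows <- list()
  for (ex_name in names(exposures)) {
    rev_res <- tryCatch(
      reverse_mr(outcome, exposures[[ex_name]], config$criteria,
                 config$ld[["outcome"]],
                 effects_model = config$effects_model,
                 n_boot = config$n_boot, seed = config$seed,
                 bandwidth_factor = config$bandwidth_factor),
      error = function(e) {
        log(sprintf("reverse outcome->%s: %s", ex_name,
                    conditionMessage(e)))
        NULL
      })
    if (!is.null(rev_res)) {
      tab <- as.data.frame(rev_res)
      tab <- cbind(pair = paste0("outcome->", ex_name), tab)
      reverse_rows[[ex_name]] <- tab
    }
  }

  # stage 3: mediator -> outcome screen
  mediator_pass <- character(0)
  stage3 <- list()
  for (md_name in names(mediators)) {
    pair_id <- paste0(md_name, "->outcome")
    res <- tryCatch({
      iv <- instruments_of(mediators[[md_name]], md_name)
      analyse_pair(iv, outcome, config, pair_id,
                   config$screen_mediator, out_dir, log)
    }, error = function(e) {
      log(sprintf("%s: skipped (%s)", pair_id, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    stage3[[md_name]] <- res
    note_screen("mediator->outcome", res$verdict)
    if (res$verdict$verdict != "fail") mediator_pass <- c(mediator_pass,
                                                          md_name)
  }

  # stage 4 + 5: step-1 screen and mediation for surviving triples
  mediation_rows <- list()
  for (ex_name in exposure_pass) {
    for (md_name in mediator_pass) {
      pair_id <- paste0(ex_name, "->", md_name)
      res <- tryCatch({
        iv <- select_instruments(exposures[[ex_name]],
                                 config$ld[[ex_name]], config$criteria)
        analyse_pair(iv, mediators[[md_name]], config, pair_id,
                     config$screen_step1, out_dir, log)
      }, error = function(e) {
        log(sprintf("%s: skipped (%s)", pair_id, conditionMessage(e)))
        NULL
      })
      if (is.null(res)) next
      note_screen("exposure->mediator", res$verdict)
      if (res$verdict$verdict == "fail") next
      med <- mediation_result(
        res$bundle$ivw$beta, res$bundle$ivw$se,
        stage3[[md_name]]$bundle$ivw$beta, stage3[[md_name]]$bundle$ivw$se,
        stage1[[ex_name]]$bundle$ivw$beta, stage1[[ex_name]]$bundle$ivw$se,
        exposure = ex_name, mediator = md_name, outcome = "outcome")
      mediation_rows[[pair_id]] <- data.frame(
        exposure = ex_name, mediator = md_name, outcome = "outcome",
        beta_x = med$beta_x, beta_y = med$beta_y,
        beta_total = med$beta_total,
        mediated_effect = med$beta_xy,
        ci_low = med$beta_xy_ci[1], ci_high = med$beta_xy_ci[2],
        direct_effect = med$direct_effect,
        mediated_proportion = med$mediated_proportion,
        proportion_ci_1 = med$proportion_ci[1],
        proportion_ci_2 = med$proportion_ci[2],
        label = mediation_label(med),
        stringsAsFactors = FALSE)
    }
  }

  screen_tab <- if (length(screens) > 0) do.call(rbind, screens) else
    data.frame(stage = character(0), pair = character(0),
               ivw_p = numeric(0), p_pass = logical(0),
               direction_pass = logical(0), pleiotropy_pass = logical(0),
               verdict = character(0))
  mediation_tab <- if (length(mediation_rows) > 0) {
    do.call(rbind, mediation_rows)
  } else {
    data.frame(exposure = character(0), mediator = character(0),
               outcome = character(0), beta_x = numeric(0),
               beta_y = numeric(0), beta_total = numeric(0),
               mediated_effect = numeric(0), ci_low = numeric(0),
               ci_high = numeric(0), direct_effect = numeric(0),
               mediated_proportion = numeric(0),
               proportion_ci_1 = numeric(0), proportion_ci_2 = numeric(0),
               label = character(0))
  }
  rownames(mediation_tab) <- NULL
  reverse_tab <- if (length(reverse_rows) > 0) {
    do.call(rbind, c(reverse_rows, make.row.names = FALSE))
  } else {
    NULL
  }

  data.table::fwrite(screen_tab, file.path(out_dir, "screens.tsv"),
                     sep = "\t")
  data.table::fwrite(mediation_tab, file.path(out_dir, "mediation.tsv"),
                     sep = "\t")
  if (!is.null(reverse_tab)) {
    data.table::fwrite(reverse_tab, file.path(out_dir, "reverse_mr.tsv"),
                       sep = "\t")
  }
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  manifest <- list(
    settings = list(
      criteria = unclass(config$criteria),
      screen_exposure = unclass(config$screen_exposure),
      screen_mediator = unclass(config$screen_mediator),
      screen_step1 = unclass(config$screen_step1),
      effects_model = config$effects_model, n_boot = config$n_boot,
      bandwidth_factor = config$bandwidth_factor, n_sim = config$n_sim,
      seed = config$seed, presso = config$presso),
    studies = list(exposures = names(config$exposures),
                   mediators = names(config$mediators)),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(screens = screen_tab, mediation = mediation_tab,
                 reverse = reverse_tab, output_dir = out_dir))
}
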