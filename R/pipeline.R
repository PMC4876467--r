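cohort_schema_columns <- function() {
  c("patient_id", "side", "time_months", "event", "censor_reason",
    "age", "sex", "t_stage", "chemo", dvh_metric_names())
}

#' Read a lobe-level cohort table from CSV
#'
#' One row per temporal lobe. Required columns: `patient_id`, `side`
#' (`left`/`right`), `time_months` (> 0, from IMRT completion),
#' `event` (0/1), `censor_reason` (`alive_no_injury`, `death`,
#' `repeat_rt`, `end_of_followup`, or empty for injured lobes), `age`,
#' `sex` (`male`/`female`), `t_stage` (`T1-2`/`T3-4`), `chemo`
#' (`yes`/`no`), and the 15 DVH metric columns of [dvh_metric_names()]
#' (doses in Gy, volumes in cc). All validation failures are reported
#' together with their row numbers.
#'
#' @param path CSV file path.
#' @return Validated data.frame in the cohort schema.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  tab <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  validate_cohort(tab)
}

#' Validate a lobe-level cohort table
#' @param tab data.frame in the schema of [read_cohort()].
#' @return The validated data.frame (invisible errors are collected and
#'   reported together).
#' @export
validate_cohort <- function(tab) {
  miss <- setdiff(cohort_schema_columns(), names(tab))
  if (length(miss))
    stop("missing cohort column(s): ", paste(miss, collapse = ", "))
  errs <- character(0)
  bad_time <- which(!is.finite(tab$time_months) | tab$time_months <= 0)
  if (length(bad_time))
    errs <- c(errs, paste0("row ", bad_time, ": time_months must be > 0"))
  bad_event <- which(!tab$event %in% c(0, 1))
  if (length(bad_event))
    errs <- c(errs, paste0("row ", bad_event, ": event must be 0 or 1"))
  chk <- list(side = c("left", "right"), sex = c("male", "female"),
              t_stage = c("T1-2", "T3-4"), chemo = c("yes", "no"))
  for (v in names(chk)) {
    bad <- which(!tab[[v]] %in% chk[[v]])
    if (length(bad))
      errs <- c(errs, paste0("row ", bad, ": bad ", v, " level '",
                             tab[[v]][bad], "'"))
  }
  tab$censor_reason[tab$censor_reason %in% c("", NA)] <- NA_character_
  cr <- tab$censor_reason
  ok_reason <- c("alive_no_injury", "death", "repeat_rt", "end_of_followup")
  bad <- which(tab$event == 0 &
                 !(cr %in% ok_reason))
  if (length(bad))
    errs <- c(errs, paste0("row ", bad,
                           ": censored lobe needs a censor_reason in {",
                           paste(ok_reason, collapse = ", "), "}"))
  for (m in dvh_metric_names()) {
    bad <- which(!is.finite(tab[[m]]) & !is.na(tab[[m]]))
    if (length(bad))
      errs <- c(errs, paste0("row ", bad, ": non-finite ", m))
  }
  if (length(errs))
    stop("invalid cohort table:\n  ", paste(errs, collapse = "\n  "))
  tab$event <- as.integer(tab$event)
  tab
}

#' Write a lobe-level cohort table to CSV
#'
#' Inverse of [read_cohort()]; the round trip is lossless.
#'
#' @param lobes cohort data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(lobes, path) {
  utils::write.csv(lobes[cohort_schema_columns()], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Assemble a full pipeline run configuration
#'
#' @param mode input mode: `"simulate"` (use the synthetic generator),
#'   `"cohort_csv"` (load a prepared lobe table), or `"dvh_dir"`
#'   (per-structure DVH CSVs plus an outcomes table).
#' @param cohort a [cohort_config()] (simulate mode).
#' @param cohort_csv path to a cohort CSV (cohort_csv mode).
#' @param dvh_dir directory of per-lobe DVH CSVs (dvh_dir mode).
#' @param outcomes_csv outcomes CSV with a `dvh_file` column naming each
#'   lobe's DVH file (dvh_dir mode) plus the non-metric cohort columns.
#' @param dose_variables dose metrics to model; `NULL` = the dosimetric
#'   variables chosen by the elastic-net screen (fallback `d_max`,
#'   `d_1cc` if the screen selects none).
#' @param horizons months at which actuarial rates are reported.
#' @param probability_levels tolerance-dose probability levels.
#' @param window eligibility window (months) for the logistic model.
#' @param alpha,nfolds,rule,nlambda,lambda_min_ratio elastic-net
#'   screening settings (see [coxnet_cv()] and [coxnet_path()]).
#' @param outdir output directory for stage artifacts.
#' @param seed integer seed for all randomness in the run.
#' @param verbose print stage banners.
#' @return List of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "cohort_csv", "dvh_dir"),
                       cohort = cohort_config(),
                       cohort_csv = NULL, dvh_dir = NULL,
                       outcomes_csv = NULL,
                       dose_variables = NULL,
                       horizons = c(36, 60),
                       probability_levels = c(0.01, 0.05, 0.10, 0.20,
                                              0.30, 0.50),
                       window = 50, alpha = 0.5, nfolds = 10,
                       rule = "1se", nlambda = 100, lambda_min_ratio = 0.01,
                       outdir = tempfile("ntcp_run_"),
                       seed = 1L, verbose = FALSE) {
  mode <- match.arg(mode)
  if (mode == "cohort_csv" && is.null(cohort_csv))
    stop("cohort_csv mode needs a cohort_csv path")
  if (mode == "dvh_dir" && (is.null(dvh_dir) || is.null(outcomes_csv)))
    stop("dvh_dir mode needs dvh_dir and outcomes_csv")
  structure(list(mode = mode, cohort = cohort, cohort_csv = cohort_csv,
                 dvh_dir = dvh_dir, outcomes_csv = outcomes_csv,
                 dose_variables = dose_variables, horizons = horizons,
                 probability_levels = probability_levels, window = window,
                 alpha = alpha, nfolds = nfolds, rule = rule,
                 nlambda = nlambda, lambda_min_ratio = lambda_min_ratio,
                 outdir = outdir, seed = as.integer(seed),
                 verbose = verbose),
            class = "run_config")
}

stage <- function(name, verbose, expr) {
  if (verbose) message("== stage: ", name, " ==")
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full NTCP analysis pipeline
#'
#' Executes the stages in order — cohort input, elastic-net screening,
#' Cox dose-response + Kaplan-Meier, logistic dose-response + tolerance
#' tables, cohort summary — writing each stage's artifact (CSV/JSON)
#' into `config$outdir` before the next stage starts. Identical config
#' and seed give an identical report.
#'
#' @param config a [run_config()].
#' @return List of class `run_report`: `selection` (chosen lambda and
#'   variables), `cox` (per dose variable: beta, PH test, TD table),
#'   `km` (actuarial rates), `logistic` (per dose variable: fit and TD
#'   table), `eligibility` counts, `cohort_summary`, `crude_rate_pct`,
#'   and a `provenance` block (effective config, seed, package version).
#' @export
run_ntcp_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  verbose <- isTRUE(config$verbose)
  truth <- NULL
  lobes <- stage("cohort", verbose, {
    if (config$mode == "simulate") {
      cfg <- config$cohort
      cfg$seed <- config$seed
      sim <- generate_cohort(cfg)
      truth <- sim$truth
      write_cohort(sim$lobes, file.path(config$outdir, "cohort.csv"))
      jsonlite::write_json(
        truth[c("beta_true", "log_h0_t0", "t0", "shape", "dose_variable")],
        file.path(config$outdir, "truth.json"), auto_unbox = TRUE,
        digits = NA)
      sim$lobes
    } else if (config$mode == "cohort_csv") {
      lb <- read_cohort(config$cohort_csv)
      write_cohort(lb, file.path(config$outdir, "cohort.csv"))
      lb
    } else {
      out <- utils::read.csv(config$outcomes_csv, check.names = FALSE,
                             stringsAsFactors = FALSE)
      if (!"dvh_file" %in% names(out))
        stop("outcomes table needs a dvh_file column")
      mets <- do.call(rbind, lapply(out$dvh_file, function(f)
        dvh_metrics(read_dvh(file.path(config$dvh_dir, f)))))
      lb <- validate_cohort(cbind(out[setdiff(names(out), "dvh_file")],
                                  mets))
      write_cohort(lb, file.path(config$outdir, "cohort.csv"))
      lb
    }
  })
  sel <- stage("screen", verbose, {
    cv <- screen_predictors(lobes, alpha = config$alpha,
                            nfolds = config$nfolds, rule = config$rule,
                            seed = config$seed, nlambda = config$nlambda,
                            lambda_min_ratio = config$lambda_min_ratio)
    utils::write.csv(data.frame(lambda = cv$lambda, cv_deviance = cv$cvm,
                                cv_se = cv$cvse),
                     file.path(config$outdir, "cv_curve.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(lambda_min = cv$lambda_min, lambda_1se = cv$lambda_1se,
           lambda_chosen = cv$lambda_chosen, rule = cv$rule,
           selected = cv$selected,
           coefficients = as.list(cv$coef_chosen[cv$coef_chosen != 0])),
      file.path(config$outdir, "selection.json"), auto_unbox = TRUE,
      digits = NA)
    cv
  })
  dose_vars <- config$dose_variables
  if (is.null(dose_vars)) {
    dose_vars <- intersect(sel$selected, dvh_metric_names())
    if (!length(dose_vars)) dose_vars <- c("d_max", "d_1cc")
  }
  cox_out <- stage("cox", verbose, {
    res <- list()
    for (v in dose_vars) {
      fit <- fit_cox(lobes, v)
      ph <- tryCatch(ph_test(fit), error = function(e) NULL)
      tmax <- max(lobes$time_months[lobes$event == 1])
      thoriz <- min(60, tmax)
      td <- cox_tolerance_dose(fit, config$probability_levels, t = thoriz)
      grid <- seq(floor(min(lobes[[v]])), ceiling(max(lobes[[v]])),
                  by = 0.5)
      utils::write.csv(
        data.frame(dose = grid,
                   failure_prob = failure_probability(fit, grid, thoriz)),
        file.path(config$outdir, paste0("failure_curve_", v, ".csv")),
        row.names = FALSE)
      utils::write.csv(td, file.path(config$outdir,
                                     paste0("cox_td_", v, ".csv")),
                       row.names = FALSE)
      res[[v]] <- list(beta = fit$beta, se = fit$se, p_value = fit$p_value,
                       ph_test = ph, horizon = thoriz,
                       td_table = td)
    }
    res
  })
  km <- stage("kaplan_meier", verbose, {
    k <- kaplan_meier(lobes, horizons = config$horizons)
    utils::write.csv(k$rates, file.path(config$outdir, "km_rates.csv"),
                     row.names = FALSE)
    k
  })
  logistic_out <- stage("logistic", verbose, {
    elig <- eligibility_filter(lobes, window = config$window)
    res <- list(counts = attr(elig, "counts"), fits = list())
    for (v in dose_vars) {
      fit <- fit_logistic(elig, v)
      td <- tolerance_dose(fit, config$probability_levels)
      utils::write.csv(td, file.path(config$outdir,
                                     paste0("td_table_", v, ".csv")),
                       row.names = FALSE)
      utils::write.csv(dose_response_curve(fit),
                       file.path(config$outdir,
                                 paste0("dose_response_", v, ".csv")),
                       row.names = FALSE)
      utils::write.csv(binned_incidence(elig, v),
                       file.path(config$outdir,
                                 paste0("binned_incidence_", v, ".csv")),
                       row.names = FALSE)
      res$fits[[v]] <- list(b0 = fit$b0, b1 = fit$b1,
                            separation = fit$separation, td_table = td)
    }
    res
  })
  summary_out <- stage("report", verbose, {
    cs <- cohort_summary(lobes)
    utils::write.csv(cs, file.path(config$outdir, "cohort_summary.csv"),
                     row.names = FALSE)
    cs
  })
  pat <- lobes_to_patients(lobes)
  report <- list(
    selection = list(lambda_chosen = sel$lambda_chosen,
                     selected = sel$selected, rule = sel$rule),
    cox = cox_out,
    km = km$rates,
    logistic = logistic_out,
    cohort_summary = summary_out,
    crude_rate_pct = crude_rate(sum(pat$event), nrow(pat)),
    n_patients = nrow(pat), n_lobes = nrow(lobes),
    truth = if (!is.null(truth))
      truth[c("beta_true", "log_h0_t0", "t0", "shape", "dose_variable")],
    provenance = list(
      seed = config$seed, mode = config$mode,
      package_version = as.character(utils::packageVersion("tlintcp")),
      window = config$window, alpha = config$alpha,
      nfolds = config$nfolds, rule = config$rule,
      probability_levels = config$probability_levels,
      horizons = config$horizons))
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("NTCP pipeline report\n")
  cat("  cohort:", x$n_patients, "patients /", x$n_lobes, "lobes; crude rate",
      x$crude_rate_pct, "%\n")
  cat("  selected predictors:", if (length(x$selection$selected))
    paste(x$selection$selected, collapse = ", ") else "(none)", "\n")
  for (v in names(x$cox))
    cat(sprintf("  Cox %s: beta = %.4f /Gy (P = %.3g)\n", v, x$cox[[v]]$beta,
                x$cox[[v]]$p_value))
  invisible(x)
}
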