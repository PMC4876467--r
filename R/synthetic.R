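#' Configuration for the synthetic bilateral cohort generator
#'
#' Builds the full parameter set of the cohort simulator. Defaults emulate
#' a bilateral nasopharyngeal-carcinoma IMRT cohort of 132 patients
#' (264 temporal lobes): clinical follow-up spanning roughly 11-106 months,
#' strongly correlated hot-spot dose metrics, a Cox-type generative hazard
#' for injury with a Weibull baseline, and censoring by death and repeat
#' irradiation.
#'
#' @param n_patients number of patients; each contributes two lobes.
#' @param follow_up list: `dist` one of `"uniform"` or `"fixed"`, with
#'   `min`/`max` (months) for uniform or `value` for fixed. Follow-up is
#'   administrative: injury can only be observed while under follow-up.
#' @param dose_model list of DVH generator parameters:
#'   `dmax_mean`, `dmax_sd` (Gy; location/scale of the per-lobe maximum
#'   point dose), `dmax_min`, `dmax_max` (truncation, Gy),
#'   `shoulder`, `shoulder_sd` (shape exponent of the DVH tail; larger
#'   means a steeper shoulder with a smaller hot volume),
#'   `lr_corr` (correlation of left/right lobe dose in `[0,1]`),
#'   `tlv_mean`, `tlv_sd`, `tlv_min`, `tlv_max` (cc),
#'   `bin` (DVH dose resolution, Gy).
#' @param outcome_model list: `dose_variable` (metric driving the hazard),
#'   `beta` (true log hazard per Gy), `log_h0_t0` (log baseline cumulative
#'   hazard at the reference horizon `t0`, for a lobe at dose 0),
#'   `t0` (months), `shape` (Weibull shape of the baseline hazard).
#' @param censor_model list: `p_death`, `death_min`, `death_max`,
#'   `p_repeat_rt`, `rrt_min`, `rrt_max` (probabilities and uniform time
#'   ranges in months for the two censoring causes).
#' @param clinical_model list of marginal frequencies / ranges:
#'   `p_male`, `p_t34`, `p_chemo`, `age_mean`, `age_sd`, `age_min`,
#'   `age_max`, and `t34_dose_shift` (Gy added to the patient dose
#'   location for T3-4 patients; 0 = no confounding).
#' @param seed integer seed for the generator's random stream.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 132,
                          follow_up = list(dist = "uniform", min = 11, max = 106),
                          dose_model = list(dmax_mean = 70.5, dmax_sd = 4.3,
                                            dmax_min = 56.1, dmax_max = 83.1,
                                            shoulder = 1.8, shoulder_sd = 0.12,
                                            lr_corr = 0.7,
                                            tlv_mean = 100, tlv_sd = 12,
                                            tlv_min = 67, tlv_max = 138,
                                            bin = 0.1),
                          outcome_model = list(dose_variable = "d_1cc",
                                               beta = 0.16,
                                               log_h0_t0 = -13.16,
                                               t0 = 60, shape = 1.5),
                          censor_model = list(p_death = 0.17,
                                              death_min = 6, death_max = 100,
                                              p_repeat_rt = 0.06,
                                              rrt_min = 11, rrt_max = 72),
                          clinical_model = list(p_male = 0.727, p_t34 = 0.606,
                                                p_chemo = 0.856,
                                                age_mean = 47, age_sd = 13,
                                                age_min = 12, age_max = 77,
                                                t34_dose_shift = 0),
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), follow_up = follow_up,
              dose_model = dose_model, outcome_model = outcome_model,
              censor_model = censor_model, clinical_model = clinical_model,
              seed = as.integer(seed))
  defaults <- formals(cohort_config)
  for (blk in c("follow_up", "dose_model", "outcome_model", "censor_model",
                "clinical_model")) {
    def <- eval(defaults[[blk]])
    miss <- setdiff(names(def), names(cfg[[blk]]))
    cfg[[blk]][miss] <- def[miss]
  }
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_patients < 1) stop("n_patients must be >= 1")
  pr <- c(cfg$censor_model$p_death, cfg$censor_model$p_repeat_rt,
          cfg$clinical_model$p_male, cfg$clinical_model$p_t34,
          cfg$clinical_model$p_chemo)
  if (any(pr < 0 | pr > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$outcome_model$shape <= 0) stop("Weibull shape must be > 0")
  if (cfg$dose_model$lr_corr < 0 || cfg$dose_model$lr_corr > 1)
    stop("lr_corr must lie in [0, 1]")
  if (cfg$dose_model$bin <= 0) stop("DVH bin width must be > 0")
  invisible(cfg)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(pmin(pmax(mean, lo), hi), n))
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  for (i in seq_len(50)) {
    if (!length(bad)) break
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  pmin(pmax(x, lo), hi)
}

#' Generate one synthetic cumulative DVH curve
#'
#' Draws a smooth monotone cumulative DVH of the power-tail form
#' `V(d) = TLV * (1 - d / Dmax)^g` sampled on the configured dose grid.
#' The shape reproduces the qualitative structure of temporal-lobe DVHs
#' under IMRT: most of the lobe at low-to-intermediate dose with a small,
#' steeply falling hot spot, which makes the hot-spot metrics (d_max,
#' d_0.1cc, d_1cc) strongly rank-correlated across lobes.
#'
#' @param config a [cohort_config()].
#' @param dmax optional maximum point dose (Gy); drawn from the dose model
#'   when `NULL`.
#' @param tlv,shoulder optional overrides of structure volume (cc) and
#'   shoulder exponent.
#' @param structure_id label for the curve.
#' @return A [dvh_curve()].
#' @export
generate_dvh <- function(config = cohort_config(), dmax = NULL, tlv = NULL,
                         shoulder = NULL, structure_id = "synthetic_lobe") {
  dm <- config$dose_model
  if (is.null(dmax))
    dmax <- rtrunc_norm(1, dm$dmax_mean, dm$dmax_sd, dm$dmax_min, dm$dmax_max)
  if (is.null(tlv))
    tlv <- rtrunc_norm(1, dm$tlv_mean, dm$tlv_sd, dm$tlv_min, dm$tlv_max)
  if (is.null(shoulder))
    shoulder <- exp(stats::rnorm(1, log(dm$shoulder), dm$shoulder_sd))
  dmax <- max(dmax, dm$bin)   # degenerate zero-dose model collapses to one bin
  grid <- unique(c(seq(0, dmax, by = dm$bin), dmax))
  vol <- tlv * (pmax(0, 1 - grid / dmax))^shoulder
  vol[length(vol)] <- 0
  dvh_curve(grid, vol, structure_id = structure_id)
}

#' Generate a bilateral synthetic cohort with known ground truth
#'
#' Simulates `n_patients` bilateral patients (two lobes each). Per lobe a
#' DVH is generated ([generate_dvh()]) with left/right doses correlated at
#' the patient level, metrics are extracted with [dvh_metrics()], and an
#' injury latency is drawn from the Cox-type generative model
#' `H(t | D) = exp(log_h0_t0) * (t / t0)^shape * exp(beta * D)` where `D`
#' is the configured dose metric. The observed time is the minimum of the
#' latency, administrative follow-up, and any death / repeat-RT censoring
#' time (censoring acts on both lobes of a patient); injury is recorded
#' only if the latency comes first. Clinical covariates are drawn from
#' their marginal frequencies.
#'
#' @param config a [cohort_config()].
#' @param return_curves if `TRUE`, also return the per-lobe DVH curves.
#' @return A list with elements:
#'   `lobes` — data.frame, one row per lobe, in the cohort-table schema
#'   (see [read_cohort()]);
#'   `truth` — list with `beta_true`, `log_h0_t0`, `t0`, `shape`,
#'   `dose_variable`, and `td_true(p, t)`, the generative tolerance dose;
#'   `curves` — list of `dvh_curve` (only if `return_curves = TRUE`).
#' @export
generate_cohort <- function(config = cohort_config(), return_curves = FALSE) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  # deterministic per-patient substreams: cohorts are reproducible even if
  # individual patients are regenerated
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  m <- 2L * n
  curves <- if (return_curves) vector("list", m) else NULL
  patient_id <- character(m); side <- character(m)
  time_months <- numeric(m); event <- integer(m)
  censor_reason <- character(m); age <- numeric(m)
  sex <- character(m); t_stage <- character(m); chemo <- character(m)
  metrics <- matrix(NA_real_, m, 15,
                    dimnames = list(NULL, dvh_metric_names()))
  for (p in seq_len(n)) {
    set.seed(sub_seeds[p])
    pat <- simulate_patient(config, sprintf("P%04d", p))
    idx <- c(2L * p - 1L, 2L * p)
    patient_id[idx] <- pat$patient_id; side[idx] <- pat$side
    time_months[idx] <- pat$time_months; event[idx] <- pat$event
    censor_reason[idx] <- pat$censor_reason
    age[idx] <- pat$age; sex[idx] <- pat$sex
    t_stage[idx] <- pat$t_stage; chemo[idx] <- pat$chemo
    metrics[idx, ] <- pat$metrics
    if (return_curves) curves[idx] <- pat$curves
  }
  lobes <- cbind(
    data.frame(patient_id = patient_id, side = side,
               time_months = time_months, event = event,
               censor_reason = censor_reason, age = age, sex = sex,
               t_stage = t_stage, chemo = chemo, stringsAsFactors = FALSE),
    as.data.frame(metrics, check.names = FALSE, optional = TRUE))
  om <- config$outcome_model
  truth <- list(
    beta_true = om$beta, log_h0_t0 = om$log_h0_t0, t0 = om$t0,
    shape = om$shape, dose_variable = om$dose_variable,
    td_true = local({
      b <- om$beta; lh <- om$log_h0_t0; t0 <- om$t0; k <- om$shape
      function(p, t = t0) {
        stopifnot(all(p > 0 & p < 1))
        (log(-log(1 - p)) - (lh + k * log(t / t0))) / b
      }
    }))
  out <- list(lobes = lobes, truth = truth)
  if (return_curves) out$curves <- curves
  out
}

simulate_patient <- function(config, patient_id) {
  dm <- config$dose_model; om <- config$outcome_model
  cn <- config$censor_model; cm <- config$clinical_model
  # clinical covariates (marginal by default)
  sex <- if (stats::runif(1) < cm$p_male) "male" else "female"
  t_stage <- if (stats::runif(1) < cm$p_t34) "T3-4" else "T1-2"
  chemo <- if (stats::runif(1) < cm$p_chemo) "yes" else "no"
  age <- round(rtrunc_norm(1, cm$age_mean, cm$age_sd, cm$age_min, cm$age_max))
  # correlated left/right dose: shared patient factor + per-side residual
  rho <- dm$lr_corr
  zp <- stats::rnorm(1)
  zs <- sqrt(rho) * zp + sqrt(1 - rho) * stats::rnorm(2)
  mu <- dm$dmax_mean + if (t_stage == "T3-4") cm$t34_dose_shift else 0
  dmax <- pmin(pmax(mu + dm$dmax_sd * zs, dm$dmax_min), dm$dmax_max)
  tlv <- rtrunc_norm(2, dm$tlv_mean, dm$tlv_sd, dm$tlv_min, dm$tlv_max)
  # follow-up (administrative) and censoring, shared by both lobes
  fu <- switch(config$follow_up$dist,
               uniform = stats::runif(1, config$follow_up$min,
                                      config$follow_up$max),
               fixed = config$follow_up$value,
               stop("unknown follow-up distribution"))
  t_death <- if (stats::runif(1) < cn$p_death)
    stats::runif(1, cn$death_min, cn$death_max) else Inf
  t_rrt <- if (stats::runif(1) < cn$p_repeat_rt)
    stats::runif(1, cn$rrt_min, cn$rrt_max) else Inf
  metrics <- matrix(NA_real_, 2, 15)
  time_v <- numeric(2); event_v <- integer(2); reason_v <- character(2)
  crvs <- vector("list", 2)
  for (s in 1:2) {
    crv <- generate_dvh(config, dmax = dmax[s], tlv = tlv[s],
                        structure_id = paste0(patient_id,
                                              c("_L", "_R")[s]))
    met <- dvh_metrics_vector(crv)
    dose <- met[[om$dose_variable]]
    # latency from the generative hazard, inverse-transform sampling:
    # H(t|D) = exp(log_h0_t0) * (t/t0)^shape * exp(beta * D)
    ee <- stats::rexp(1)
    lat <- om$t0 * (ee / exp(om$log_h0_t0 + om$beta * dose))^(1 / om$shape)
    obs <- min(lat, fu, t_death, t_rrt)
    event_v[s] <- as.integer(lat <= min(fu, t_death, t_rrt))
    reason_v[s] <- if (event_v[s] == 1L) NA_character_
      else if (obs == t_death) "death"
      else if (obs == t_rrt) "repeat_rt"
      else "end_of_followup"
    time_v[s] <- max(obs, 1e-6)
    metrics[s, ] <- met
    crvs[[s]] <- crv
  }
  list(patient_id = rep(patient_id, 2), side = c("left", "right"),
       time_months = time_v, event = event_v, censor_reason = reason_v,
       age = rep(age, 2), sex = rep(sex, 2), t_stage = rep(t_stage, 2),
       chemo = rep(chemo, 2), metrics = metrics, curves = crvs)
}
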