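# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# A small, fast generator configuration: coarser DVH bins and fewer
# patients than the defaults, for replicate-heavy tests.
quick_cfg <- function(n_patients = 132, seed = 1L, bin = 0.5, ...) {
  cfg <- cohort_config(n_patients = n_patients, seed = seed, ...)
  cfg$dose_model$bin <- bin
  cfg
}

# Build a lobe table by hand: metric columns are filled with simple
# dose-consistent values so that schema validation passes.
make_lobes <- function(patient_id, time_months, event,
                       censor_reason = NA_character_,
                       d_max = 70, side = NULL, age = 47, sex = "male",
                       t_stage = "T3-4", chemo = "yes") {
  n <- length(patient_id)
  if (is.null(side)) side <- rep(c("left", "right"), length.out = n)
  d_max <- rep_len(d_max, n)
  met <- data.frame(
    tlv = 100, d_max = d_max, mean_dose = d_max * 0.35,
    median_dose = d_max * 0.3,
    "d_0.1cc" = d_max - 1, d_1cc = d_max - 5, d_5cc = d_max - 15,
    d_10cc = d_max - 22, d_20cc = d_max - 30,
    v_40 = 15, v_50 = 7, v_60 = 2.5, v_65 = 1, v_70 = 0.3, v_75 = 0,
    check.names = FALSE)
  cbind(data.frame(patient_id = patient_id, side = side,
                   time_months = time_months, event = as.integer(event),
                   censor_reason = censor_reason, age = age, sex = sex,
                   t_stage = t_stage, chemo = chemo,
                   stringsAsFactors = FALSE),
        met)
}

# Bilateral cohort for the eligibility-rule arithmetic: `n_censored_early`
# patients censored (death) before the window, everyone else followed
# beyond it; injured lobes assigned within the remaining patients.
make_eligibility_cohort <- function(n_patients = 132, n_censored_early = 21,
                                    n_injured_lobes = 21, window = 50) {
  ids <- rep(sprintf("P%03d", seq_len(n_patients)), each = 2)
  n <- 2 * n_patients
  time <- rep(window + 15, n)
  event <- integer(n)
  reason <- rep("end_of_followup", n)
  early <- seq_len(2 * n_censored_early)       # both lobes of first patients
  time[early] <- window - 20
  reason[early] <- "death"
  inj <- seq(2 * n_censored_early + 1, 2 * n_censored_early + n_injured_lobes)
  event[inj] <- 1L
  time[inj] <- 40
  reason[inj] <- NA_character_
  make_lobes(ids, time, event, censor_reason = reason)
}

# Direct simulation of a lobe table from a Cox model with a single dose
# effect (no DVH machinery): fast input for fitting-level tests.
simulate_cox_lobes <- function(n, beta, log_h0_t0 = -13.16, t0 = 60,
                               shape = 1.5, dose_mean = 65, dose_sd = 5,
                               admin_max = 106) {
  dose <- rnorm(n, dose_mean, dose_sd)
  ee <- rexp(n)
  lat <- t0 * (ee / exp(log_h0_t0 + beta * dose))^(1 / shape)
  fu <- runif(n, 11, admin_max)
  time <- pmin(lat, fu)
  event <- as.integer(lat <= fu)
  reason <- ifelse(event == 1, NA_character_, "end_of_followup")
  make_lobes(sprintf("P%04d", seq_len(n)), time, event,
             censor_reason = reason, d_max = dose + 5)
}
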