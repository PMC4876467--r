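#' Univariate Cox dose-response model for injury
#'
#' Fits a proportional-hazards model of injury on a single dose metric
#' (Newton-Raphson on the partial likelihood via [survival::coxph()],
#' Efron tie handling by default) and attaches the Breslow baseline
#' cumulative hazard evaluated at covariate value 0, together with the
#' quantities needed for delta-method tolerance-dose standard errors.
#' Analysis is at the lobe level, mirroring the assumption that each
#' temporal lobe is independently affected; an optional cluster-robust
#' (sandwich) standard error by patient is available as a sensitivity
#' analysis and is off by default.
#'
#' @param lobes cohort data.frame in the schema of [read_cohort()].
#' @param dose_variable name of the dose metric column (default `d_1cc`).
#' @param ties tie-handling method, `"efron"` (default) or `"breslow"`.
#' @param cluster if `TRUE`, report a patient-clustered robust SE.
#' @return Object of class `ntcp_cox` with elements `beta` (per-Gy log
#'   hazard), `se`, `z`, `p_value`, `loglik` (null, fitted), `basehaz`
#'   (data.frame `time`, `hazard`: Breslow H0 at covariate 0), `n`,
#'   `n_events`, `max_time`, `dose_variable`, `model` (the underlying
#'   `coxph` fit), and delta-method support (`var_h0`, `dh0_dbeta` at
#'   event times).
#' @export
fit_cox <- function(lobes, dose_variable = "d_1cc",
                    ties = c("efron", "breslow"), cluster = FALSE) {
  ties <- match.arg(ties)
  dose <- lobes[[dose_variable]]
  if (is.null(dose)) stop("dose variable '", dose_variable, "' not found")
  time <- lobes$time_months; status <- lobes$event
  if (sum(status) < 1) stop("no events: cannot fit a Cox model")
  if (stats::var(dose) == 0) {
    out <- list(beta = 0, se = Inf, z = NA_real_, p_value = NA_real_,
                loglik = c(NA_real_, NA_real_), basehaz = NULL,
                n = length(time), n_events = sum(status),
                max_time = max(time), dose_variable = dose_variable,
                model = NULL, degenerate = TRUE)
    class(out) <- "ntcp_cox"
    return(out)
  }
  dat <- data.frame(time = time, status = status, dose = dose,
                    patient_id = lobes$patient_id)
  fml <- if (cluster) survival::Surv(time, status) ~ dose +
    survival::cluster(patient_id) else survival::Surv(time, status) ~ dose
  fit <- survival::coxph(fml, data = dat, ties = ties,
                         control = survival::coxph.control(iter.max = 100))
  if (!is.finite(fit$coefficients) || fit$iter >= 100)
    stop("Cox fit did not converge (possible monotone likelihood)")
  beta <- unname(fit$coefficients)
  se <- if (cluster) sqrt(diag(fit$var)[1]) else
    unname(sqrt(diag(fit$var))[1])
  bh <- survival::basehaz(fit, centered = FALSE)
  # Breslow variance machinery for H0(t) at the fitted beta:
  # Var(H0) = sum d_k / S0_k^2 + q' V q with q = dH0/dbeta
  ord <- order(time)
  t_s <- time[ord]; d_s <- status[ord]; x_s <- dose[ord]
  r <- exp(beta * x_s)
  S0 <- rev(cumsum(rev(r)))
  S1 <- rev(cumsum(rev(x_s * r)))
  first <- !duplicated(t_s)
  etimes <- unique(t_s[d_s == 1])
  gi <- match(t_s, t_s[first])                 # tie-group start index
  dk <- as.vector(rowsum(d_s, gi))
  keep <- dk > 0
  tk <- t_s[first][keep]; dk <- dk[keep]
  S0k <- S0[which(first)][keep]; S1k <- S1[which(first)][keep]
  var_h0 <- cumsum(dk / S0k^2)
  dh0_db <- cumsum(-dk * S1k / S0k^2)
  out <- list(beta = beta, se = se,
              z = beta / se,
              p_value = 2 * stats::pnorm(-abs(beta / se)),
              loglik = as.numeric(fit$loglik),
              basehaz = data.frame(time = bh$time, hazard = bh$hazard),
              n = length(time), n_events = sum(status),
              max_time = max(time), dose_variable = dose_variable,
              model = fit, degenerate = FALSE,
              delta_support = data.frame(time = tk, var_h0 = var_h0,
                                         dh0_dbeta = dh0_db),
              var_beta = unname(fit$var[1, 1]))
  class(out) <- "ntcp_cox"
  out
}

#' @export
print.ntcp_cox <- function(x, ...) {
  cat("Cox dose-response model for", x$dose_variable, "\n")
  if (isTRUE(x$degenerate)) {
    cat("  degenerate: dose has no variation; beta = 0, se = Inf\n")
    return(invisible(x))
  }
  cat(sprintf("  beta = %.4f /Gy (se %.4f, z = %.2f, P = %.3g)\n",
              x$beta, x$se, x$z, x$p_value))
  cat("  n =", x$n, "lobes,", x$n_events, "events\n")
  invisible(x)
}

#' Proportional-hazards diagnostic via scaled Schoenfeld residuals
#'
#' Global score test regressing the scaled Schoenfeld residuals on a
#' transform of time ([survival::cox.zph()]).
#'
#' @param fit an [fit_cox()] result.
#' @param transform time transform (default `"km"`).
#' @return List with `chisq`, `df`, `p_value`.
#' @export
ph_test <- function(fit, transform = "km") {
  stopifnot(inherits(fit, "ntcp_cox"))
  if (isTRUE(fit$degenerate))
    stop("PH test undefined: dose metric has no variation")
  if (fit$n_events < 3) stop("PH test unavailable with fewer than 3 events")
  z <- survival::cox.zph(fit$model, transform = transform, global = TRUE)
  tab <- z$table["GLOBAL", , drop = TRUE]
  list(chisq = unname(tab["chisq"]), df = unname(tab["df"]),
       p_value = unname(tab["p"]))
}

h0_at <- function(fit, t) {
  if (is.null(fit$basehaz)) stop("no baseline hazard available")
  if (t > fit$max_time + 1e-9)
    stop("t = ", t, " months lies beyond the observed follow-up (",
         fit$max_time, "); refusing to extrapolate")
  idx <- which(fit$basehaz$time <= t + 1e-9)
  if (!length(idx)) return(0)
  fit$basehaz$hazard[max(idx)]
}

#' Actuarial failure probability from a Cox dose-response model
#'
#' Evaluates `F(t | D) = 1 - exp(-H0(t) * exp(beta * D))`, with the
#' Breslow baseline cumulative hazard held at its value at the largest
#' event time not exceeding `t`.
#'
#' @param fit an `ntcp_cox` object ([fit_cox()] or [cox_from_anchors()]).
#' @param dose dose in Gy (vectorized).
#' @param t horizon in months (default 60); must lie within the observed
#'   follow-up span.
#' @return Failure probability in `[0, 1]`.
#' @export
failure_probability <- function(fit, dose, t = 60) {
  stopifnot(inherits(fit, "ntcp_cox"))
  h0 <- h0_at(fit, t)
  1 - exp(-h0 * exp(fit$beta * dose))
}

#' Tolerance dose from a Cox dose-response model
#'
#' Inverts the actuarial failure function at horizon `t`:
#' `TD_p = (log(-log(1 - p)) - log H0(t)) / beta`. For fits with full
#' uncertainty information a delta-method standard error on
#' `(beta, log H0(t))`, using the Breslow estimator's variance, is also
#' returned; it is approximate and `NA` for anchor-calibrated fits.
#'
#' @param fit an `ntcp_cox` object.
#' @param p response probability / probabilities in (0, 1).
#' @param t horizon in months (default 60).
#' @return data.frame with columns `p`, `td` (Gy), `se` (Gy).
#' @export
cox_tolerance_dose <- function(fit, p, t = 60) {
  stopifnot(inherits(fit, "ntcp_cox"))
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly between 0 and 1")
  if (isTRUE(fit$degenerate) || fit$beta == 0)
    stop("tolerance dose undefined for beta = 0")
  if (fit$beta < 0)
    stop("beta < 0: response probability decreases with dose; ",
         "tolerance dose is not defined in this direction")
  h0 <- h0_at(fit, t)
  if (h0 <= 0) stop("baseline hazard is zero at t = ", t,
                    "; requested probability unreachable")
  td <- (log(-log(1 - p)) - log(h0)) / fit$beta
  se <- rep(NA_real_, length(p))
  if (!is.null(fit$delta_support)) {
    ds <- fit$delta_support
    idx <- which(ds$time <= t + 1e-9)
    if (length(idx)) {
      i <- max(idx)
      vb <- fit$var_beta
      vh0 <- ds$var_h0[i] + ds$dh0_dbeta[i]^2 * vb
      cov_bh <- ds$dh0_dbeta[i] * vb
      v_lnh0 <- vh0 / h0^2
      cov_b_lnh0 <- cov_bh / h0
      se <- vapply(td, function(tdp) {
        g <- c(-tdp / fit$beta, -1 / fit$beta)  # d td / d(beta, ln h0)
        V <- matrix(c(vb, cov_b_lnh0, cov_b_lnh0, v_lnh0), 2)
        sqrt(drop(t(g) %*% V %*% g))
      }, numeric(1))
    }
  }
  data.frame(p = p, td = td, se = se)
}

#' Construct a Cox-type failure function from two printed anchor points
#'
#' Solves `log(-log(1 - F)) = log H0 + beta * D` for `(beta, H0)` from
#' two (dose, failure-probability) anchors at a common horizon, returning
#' an `ntcp_cox` object usable with [failure_probability()] and
#' [cox_tolerance_dose()]. This reproduces a published actuarial
#' dose-response curve from its reported tolerance doses.
#'
#' @param dose1,p1 first anchor: dose (Gy) and failure probability.
#' @param dose2,p2 second anchor.
#' @param t horizon in months the anchors refer to (default 60).
#' @param dose_variable label of the dose metric.
#' @return An `ntcp_cox` object (no uncertainty information).
#' @export
cox_from_anchors <- function(dose1, p1, dose2, p2, t = 60,
                             dose_variable = "dose") {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, dose1 != dose2)
  cll <- function(p) log(-log(1 - p))
  beta <- (cll(p2) - cll(p1)) / (dose2 - dose1)
  log_h0 <- cll(p1) - beta * dose1
  out <- list(beta = beta, se = NA_real_, z = NA_real_, p_value = NA_real_,
              loglik = NULL,
              basehaz = data.frame(time = t, hazard = exp(log_h0)),
              n = NA_integer_, n_events = NA_integer_, max_time = t,
              dose_variable = dose_variable, model = NULL,
              degenerate = FALSE, delta_support = NULL, var_beta = NA_real_)
  class(out) <- "ntcp_cox"
  out
}

#' Kaplan-Meier actuarial injury-free survival
#'
#' Product-limit estimate of injury-free survival at the patient level:
#' a patient is an event at the earlier injured lobe's time, otherwise
#' censored at the later lobe censoring time. Greenwood standard errors;
#' survival rates reported at the requested horizons.
#'
#' @param lobes cohort data.frame (lobe level, collapsed internally), or
#'   a patient-level data.frame with columns `time_months` and `event`
#'   if `collapse = FALSE`.
#' @param horizons months at which to report survival (default 36, 60).
#' @param collapse collapse lobe rows to patients first (default TRUE).
#' @return Object of class `ntcp_km`: `fit` (a `survfit`), `rates`
#'   (data.frame `time`, `survival`, `se`), `n`, `n_events`.
#' @export
kaplan_meier <- function(lobes, horizons = c(36, 60), collapse = TRUE) {
  if (nrow(lobes) == 0) stop("empty cohort")
  pat <- if (collapse) lobes_to_patients(lobes) else lobes
  fit <- survival::survfit(survival::Surv(time_months, event) ~ 1,
                           data = pat, conf.type = "log")
  sm <- summary(fit, times = horizons, extend = TRUE)
  rates <- data.frame(time = horizons, survival = sm$surv, se = sm$std.err)
  structure(list(fit = fit, rates = rates, n = nrow(pat),
                 n_events = sum(pat$event)),
            class = "ntcp_km")
}

#' @export
print.ntcp_km <- function(x, ...) {
  cat("Kaplan-Meier injury-free survival:", x$n, "patients,",
      x$n_events, "events\n")
  for (i in seq_len(nrow(x$rates)))
    cat(sprintf("  S(%g months) = %.3f (se %.3f)\n", x$rates$time[i],
                x$rates$survival[i], x$rates$se[i]))
  invisible(x)
}

#' Collapse a lobe-level cohort table to one row per patient
#'
#' A patient experiences the event at the earliest injured lobe's time;
#' patients with no injured lobe are censored at their latest lobe time.
#'
#' @param lobes cohort data.frame in the schema of [read_cohort()].
#' @return data.frame with `patient_id`, `time_months`, `event`.
#' @export
lobes_to_patients <- function(lobes) {
  sp <- split(lobes, lobes$patient_id)
  out <- lapply(sp, function(d) {
    if (any(d$event == 1)) {
      data.frame(patient_id = d$patient_id[1],
                 time_months = min(d$time_months[d$event == 1]), event = 1L)
    } else {
      data.frame(patient_id = d$patient_id[1],
                 time_months = max(d$time_months), event = 0L)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
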