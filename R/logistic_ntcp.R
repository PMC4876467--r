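#' Eligibility filter for binary-response NTCP analysis
#'
#' Applies the adequate-follow-up rule used to convert censored lobe
#' records into a binary endpoint: injured lobes are always analysable;
#' an uninjured lobe counts as normal only if it was observed injury-free
#' for more than `window` months. Lobes of patients censored by death or
#' repeat irradiation inside the window therefore drop out (their injury
#' status is unknowable). The default window of 50 months reflects that
#' the vast majority of injuries manifest within 50 months of treatment.
#'
#' @param lobes cohort data.frame in the schema of [read_cohort()].
#' @param window months of injury-free follow-up required to call a lobe
#'   normal (default 50).
#' @param strict if `TRUE`, also drop *injured* lobes belonging to
#'   patients censored by death/repeat RT before `window` (by default an
#'   injury observed before such censoring is retained, since the injury
#'   precedes the censoring event).
#' @return The eligible subset of `lobes`, with attribute `counts`: a
#'   list with `n_total`, `n_kept`, `n_dropped`.
#' @export
eligibility_filter <- function(lobes, window = 50, strict = FALSE) {
  keep_injured <- lobes$event == 1
  if (strict) {
    pat_censored_early <- vapply(split(lobes, lobes$patient_id), function(d)
      any(d$event == 0 & d$time_months < window &
            d$censor_reason %in% c("death", "repeat_rt")), logical(1))
    bad <- names(pat_censored_early)[pat_censored_early]
    keep_injured <- keep_injured & !(lobes$patient_id %in% bad)
  }
  keep_normal <- lobes$event == 0 & lobes$time_months > window
  keep <- keep_injured | keep_normal
  out <- lobes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- list(n_total = nrow(lobes), n_kept = sum(keep),
                              n_dropped = sum(!keep))
  out
}

#' Univariate logistic dose-response model
#'
#' Maximum-likelihood logistic regression of the binary injury indicator
#' on a single dose metric, fitted by iteratively reweighted least
#' squares (via [stats::glm()]); the coefficient covariance is the
#' inverse observed Fisher information at the optimum. Complete
#' separation of the two outcome classes is detected and reported rather
#' than returning silently divergent estimates.
#'
#' @param lobes data.frame with the dose column and an `event` column
#'   (typically the output of [eligibility_filter()]).
#' @param dose_variable name of the dose metric column.
#' @return Object of class `ntcp_logistic`: `b0` (intercept), `b1`
#'   (per-Gy slope), `vcov` (2 x 2), `z`, `p_value` (Wald, per
#'   coefficient), `n`, `n_events`, `dose_variable`, `separation`.
#' @export
fit_logistic <- function(lobes, dose_variable = "d_1cc") {
  dose <- lobes[[dose_variable]]
  if (is.null(dose)) stop("dose variable '", dose_variable, "' not found")
  y <- lobes$event
  if (length(unique(y)) < 2)
    stop("both outcome classes must be present")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ dose, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  # complete separation: classes perfectly split by a dose threshold
  separated <- max(dose[y == 0]) < min(dose[y == 1]) ||
    max(dose[y == 1]) < min(dose[y == 0])
  if (separated || (sep_warn && !fit$converged) ||
      abs(stats::coef(fit)[2]) * stats::sd(dose) > 50) {
    warning("complete separation detected: logistic MLE does not exist; ",
            "estimates are unreliable")
    separated <- TRUE
  }
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  z <- cf / sqrt(diag(V))
  out <- list(b0 = unname(cf[1]), b1 = unname(cf[2]), vcov = unname(V),
              z = unname(z), p_value = unname(2 * stats::pnorm(-abs(z))),
              n = length(y), n_events = sum(y),
              dose_variable = dose_variable, separation = separated)
  class(out) <- "ntcp_logistic"
  out
}

#' @export
print.ntcp_logistic <- function(x, ...) {
  cat("Logistic dose-response model for", x$dose_variable, "\n")
  cat(sprintf("  b0 = %.4f, b1 = %.4f /Gy\n", x$b0, x$b1))
  if (!is.null(x$vcov) && all(is.finite(x$vcov)))
    cat(sprintf("  Wald P (slope) = %.3g\n", x$p_value[2]))
  cat("  n =", x$n, "lobes,", x$n_events, "events\n")
  if (isTRUE(x$separation)) cat("  WARNING: complete separation\n")
  invisible(x)
}

#' Construct a logistic dose-response model from two printed anchors
#'
#' Solves the two-parameter logistic `logit(p) = b0 + b1 * D` from two
#' (tolerance dose, probability) anchors, e.g. published TD50 and TD10
#' values, reproducing a published dose-response curve.
#'
#' @param td1,p1 first anchor: dose (Gy) and response probability.
#' @param td2,p2 second anchor.
#' @param dose_variable label of the dose metric.
#' @return An `ntcp_logistic` object (no uncertainty information).
#' @export
logistic_from_anchors <- function(td1, p1, td2, p2,
                                  dose_variable = "dose") {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, td1 != td2)
  b1 <- (stats::qlogis(p2) - stats::qlogis(p1)) / (td2 - td1)
  b0 <- stats::qlogis(p1) - b1 * td1
  out <- list(b0 = b0, b1 = b1, vcov = NULL, z = NULL, p_value = NULL,
              n = NA_integer_, n_events = NA_integer_,
              dose_variable = dose_variable, separation = FALSE)
  class(out) <- "ntcp_logistic"
  out
}

#' Response probability of a logistic dose-response model
#' @param fit an `ntcp_logistic` object.
#' @param dose dose in Gy (vectorized).
#' @return Probability `1 / (1 + exp(-(b0 + b1 * dose)))`.
#' @export
logistic_response <- function(fit, dose) {
  stopifnot(inherits(fit, "ntcp_logistic"))
  stats::plogis(fit$b0 + fit$b1 * dose)
}

#' Tolerance doses with maximum-likelihood standard errors
#'
#' Inverts the fitted logistic model at the requested response
#' probabilities: `TD_p = (logit(p) - b0) / b1`. The standard error is
#' obtained by the delta method with gradient `(-1/b1, -TD_p/b1)` applied
#' to the ML covariance of `(b0, b1)`; it is `NA` when the fit carries no
#' covariance (anchor-calibrated models).
#'
#' @param fit an `ntcp_logistic` object.
#' @param p response probabilities in (0, 1); default
#'   `c(0.01, 0.05, 0.10, 0.20, 0.30, 0.50)`.
#' @return data.frame of class `tolerance_table`: columns `p`, `td`
#'   (Gy), `se` (Gy).
#' @export
tolerance_dose <- function(fit, p = c(0.01, 0.05, 0.10, 0.20, 0.30, 0.50)) {
  stopifnot(inherits(fit, "ntcp_logistic"))
  if (any(p <= 0 | p >= 1)) stop("p must lie strictly between 0 and 1")
  if (fit$b1 == 0) stop("b1 = 0: tolerance dose undefined")
  if (fit$b1 < 0)
    warning("b1 < 0: response probability decreases with dose; ",
            "tolerance doses returned with inverted ordering")
  td <- (stats::qlogis(p) - fit$b0) / fit$b1
  se <- rep(NA_real_, length(p))
  if (!is.null(fit$vcov)) {
    se <- vapply(td, function(tdp) {
      g <- c(-1 / fit$b1, -tdp / fit$b1)
      sqrt(drop(t(g) %*% fit$vcov %*% g))
    }, numeric(1))
  }
  out <- data.frame(p = p, td = td, se = se)
  class(out) <- c("tolerance_table", "data.frame")
  out
}

#' @export
print.tolerance_table <- function(x, ...) {
  cat("Tolerance doses (Gy)\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  TD%-3g = %6.1f %s\n", 100 * x$p[i], x$td[i],
                if (is.na(x$se[i])) "" else sprintf("+/- %.1f", x$se[i])))
  invisible(x)
}

#' Dose-response curve with tolerance-dose error bounds
#'
#' Tabulates the fitted sigmoid over a probability grid together with
#' horizontal (dose-direction) one-standard-error bounds: at each
#' probability level the tolerance dose is shifted by its delta-method
#' SE. A vertical (probability-direction) rendering at fixed doses is
#' available via `orientation = "vertical"`.
#'
#' @param fit an `ntcp_logistic` object with covariance.
#' @param probs probability grid (default 0.01 to 0.99 by 0.01).
#' @param orientation `"horizontal"` (default) or `"vertical"`.
#' @param dose_grid dose grid for the vertical rendering.
#' @return For `"horizontal"`: data.frame `p`, `td_lower`, `td`,
#'   `td_upper` (Gy). For `"vertical"`: data.frame `dose`, `p_lower`,
#'   `p`, `p_upper`.
#' @export
dose_response_curve <- function(fit, probs = seq(0.01, 0.99, by = 0.01),
                                orientation = c("horizontal", "vertical"),
                                dose_grid = NULL) {
  orientation <- match.arg(orientation)
  tt <- tolerance_dose(fit, probs)
  if (orientation == "horizontal") {
    return(data.frame(p = tt$p, td_lower = tt$td - tt$se, td = tt$td,
                      td_upper = tt$td + tt$se))
  }
  if (is.null(dose_grid))
    dose_grid <- seq(min(tt$td), max(tt$td), length.out = 99)
  pr <- logistic_response(fit, dose_grid)
  se_p <- rep(NA_real_, length(dose_grid))
  if (!is.null(fit$vcov)) {
    se_p <- vapply(dose_grid, function(d) {
      g <- stats::dlogis(fit$b0 + fit$b1 * d) * c(1, d)
      sqrt(drop(t(g) %*% fit$vcov %*% g))
    }, numeric(1))
  }
  data.frame(dose = dose_grid, p_lower = pmax(0, pr - se_p), p = pr,
             p_upper = pmin(1, pr + se_p))
}

#' Crude injury incidence in discretized dose bins
#'
#' Groups lobes into half-open dose intervals `[k*width, (k+1)*width)`
#' anchored at `origin` and reports the crude event rate per bin; empty
#' bins are omitted.
#'
#' @param lobes data.frame with the dose column and `event`.
#' @param dose_variable name of the dose metric column.
#' @param width bin width in Gy (default 2.5).
#' @param origin bin origin in Gy (default 0).
#' @return data.frame: `lower`, `upper`, `midpoint`, `n`, `events`,
#'   `rate`.
#' @export
binned_incidence <- function(lobes, dose_variable = "d_1cc", width = 2.5,
                             origin = 0) {
  if (width <= 0) stop("bin width must be positive")
  dose <- lobes[[dose_variable]]
  k <- floor((dose - origin) / width)
  agg <- stats::aggregate(lobes$event, by = list(k = k),
                          FUN = function(e) c(n = length(e), ev = sum(e)))
  out <- data.frame(lower = origin + agg$k * width,
                    upper = origin + (agg$k + 1) * width,
                    n = agg$x[, "n"], events = agg$x[, "ev"])
  out$midpoint <- (out$lower + out$upper) / 2
  out$rate <- out$events / out$n
  out[order(out$lower),
      c("lower", "upper", "midpoint", "n", "events", "rate")]
}
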