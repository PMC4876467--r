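#' Build the candidate predictor matrix for variable screening
#'
#' Assembles the 19 candidate predictors used for elastic-net screening:
#' the 15 DVH metrics plus age, sex, T stage and chemotherapy. Binary
#' covariates are coded 0/1 (male = 1, T3-4 = 1, chemotherapy yes = 1);
#' T stage is dichotomized T1-2 vs T3-4. All columns, including the
#' binary ones, are standardized internally by the penalized fitter.
#'
#' @param lobes cohort data.frame in the schema of [read_cohort()].
#' @return Numeric matrix, one row per lobe, with named columns.
#' @export
predictor_matrix <- function(lobes) {
  need <- c(dvh_metric_names(), "age", "sex", "t_stage", "chemo")
  miss <- setdiff(need, names(lobes))
  if (length(miss)) stop("missing predictor columns: ",
                         paste(miss, collapse = ", "))
  x <- cbind(as.matrix(lobes[dvh_metric_names()]),
             age = as.numeric(lobes$age),
             sex = as.numeric(lobes$sex == "male"),
             t_stage = as.numeric(lobes$t_stage == "T3-4"),
             chemo = as.numeric(lobes$chemo == "yes"))
  if (any(!is.finite(x))) stop("non-finite values in predictor matrix")
  x
}

#' Spearman rank-correlation matrix of candidate predictors
#'
#' Pairwise Spearman coefficients with average-rank tie handling, the
#' standard non-parametric screen for multicollinearity among DVH
#' metrics. Constant columns yield undefined correlations, reported as
#' `NA` with a warning.
#'
#' @param x numeric matrix (rows = lobes, columns = predictors).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 rows for rank correlations")
  const <- apply(x, 2, function(v) stats::var(v) == 0)
  if (any(const))
    warning("constant column(s): ",
            paste(colnames(x)[const], collapse = ", "),
            "; correlations undefined (NA)")
  suppressWarnings(rho <- stats::cor(x, method = "spearman"))
  diag(rho) <- 1
  rho
}

## ---- Breslow partial-likelihood machinery -------------------------------

# Precompute the sorted risk-set structure used by the quadratic
# approximation. Ties share risk sets (Breslow).
cox_structure <- function(time, status) {
  stopifnot(length(time) == length(status), all(time > 0))
  ord <- order(time)
  t_s <- time[ord]
  grp <- cumsum(!duplicated(t_s))              # tie-group index per obs
  first <- which(!duplicated(t_s))             # first obs of each group
  d_g <- as.vector(rowsum(as.numeric(status[ord]), grp))  # events per group
  list(ord = ord, grp = grp, first = first, d_g = d_g,
       delta = as.numeric(status[ord]), n = length(time))
}

# Gradient, diagonal Hessian and log partial likelihood at linear
# predictor eta (original observation order).
cox_quad <- function(eta, st) {
  eta_s <- eta[st$ord]
  r <- exp(eta_s - max(eta_s))                 # rescaled for stability
  Rcum <- rev(cumsum(rev(r)))
  R_g <- Rcum[st$first]                        # risk-set mass per tie group
  a_g <- ifelse(st$d_g > 0, st$d_g / R_g, 0)
  b_g <- ifelse(st$d_g > 0, st$d_g / R_g^2, 0)
  A <- cumsum(a_g)[st$grp]
  B <- cumsum(b_g)[st$grp]
  g_s <- st$delta - r * A
  w_s <- pmax(r * A - r^2 * B, 0)
  ll <- sum(eta_s[st$delta == 1]) -
    sum(st$d_g[st$d_g > 0] * (log(R_g[st$d_g > 0]) + max(eta_s)))
  g <- numeric(st$n); w <- numeric(st$n)
  g[st$ord] <- g_s; w[st$ord] <- w_s
  list(g = g, w = w, loglik = ll)
}

#' Breslow log partial likelihood of a Cox model
#'
#' @param beta coefficient vector.
#' @param x predictor matrix.
#' @param time,status follow-up times and event indicators.
#' @return Log partial likelihood (Breslow tie handling).
#' @export
cox_partial_loglik <- function(beta, x, time, status) {
  st <- cox_structure(time, status)
  cox_quad(drop(as.matrix(x) %*% beta), st)$loglik
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Elastic-net-penalized Cox regression path by coordinate descent
#'
#' Fits the regularization path of the Cox proportional-hazards model
#' under the elastic-net penalty
#' `lambda * (alpha * ||b||_1 + (1 - alpha) / 2 * ||b||_2^2)`,
#' by cyclic coordinate descent on the weighted-least-squares quadratic
#' approximation to the Breslow partial likelihood, with warm starts
#' along a decreasing lambda sequence. Predictors are standardized
#' internally (mean 0, variance 1 with the 1/n convention); coefficients
#' are returned on the original scale. The minimized objective is
#' `-loglik / n + lambda * penalty`; a step-halving safeguard keeps it
#' non-increasing across outer (reweighting) iterations.
#'
#' @param x numeric predictor matrix (no intercept; Cox has none).
#' @param time follow-up times (positive).
#' @param status event indicator, 1 = event, 0 = censored.
#' @param alpha elastic-net mixing weight in `[0, 1]` (1 = lasso,
#'   0 = ridge); default 0.5.
#' @param nlambda path length.
#' @param lambda_min_ratio smallest lambda as a fraction of the smallest
#'   lambda that shrinks every coefficient to zero.
#' @param lambda optional user-supplied decreasing lambda sequence
#'   (overrides `nlambda`/`lambda_min_ratio`). Values may include 0.
#' @param thresh convergence threshold for coordinate descent: iteration
#'   stops when the largest weighted squared coefficient update,
#'   `max_j A_jj * (delta beta_j)^2` on the standardized scale, falls
#'   below `thresh` (the criterion is stable under strongly correlated
#'   predictors; smaller values give tighter solutions).
#' @param maxit maximum total coordinate-descent sweeps per lambda.
#' @return Object of class `coxnet_path`: list with `lambda`, `beta`
#'   (p x nlambda matrix, original scale), `df` (nonzero count),
#'   `loglik`, `objective` (per-iteration traces, one vector per lambda),
#'   `alpha`, `center`, `scale`, `n`, `n_events`.
#' @export
coxnet_path <- function(x, time, status, alpha = 0.5, nlambda = 100,
                        lambda_min_ratio = 0.01, lambda = NULL,
                        thresh = 1e-9, maxit = 1e5) {
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("non-finite values in predictors")
  if (sum(status) < 1) stop("no events: cannot fit a Cox model")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  n <- nrow(x); p <- ncol(x)
  st <- cox_structure(time, status)
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  if (any(scl == 0)) stop("constant predictor column(s): ",
                          paste(colnames(x)[scl == 0], collapse = ", "))
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  # lambda sequence from the null-model gradient
  q0 <- cox_quad(numeric(n), st)
  alpha_eff <- max(alpha, 1e-3)                 # ridge still needs finite path
  lambda_max <- max(abs(crossprod(xs, q0$g))) / (n * alpha_eff)
  if (is.null(lambda)) {
    lambda <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                      length.out = nlambda))
  } else {
    lambda <- sort(as.numeric(lambda), decreasing = TRUE)
  }
  nl <- length(lambda)
  beta <- numeric(p)
  beta_out <- matrix(0, p, nl, dimnames = list(colnames(x), NULL))
  loglik <- numeric(nl)
  obj_trace <- vector("list", nl)
  for (l in seq_len(nl)) {
    lam <- lambda[l]
    eta <- drop(xs %*% beta)
    q <- cox_quad(eta, st)
    pen <- function(b) lam * (alpha * sum(abs(b)) + (1 - alpha) / 2 * sum(b^2))
    obj <- -q$loglik / n + pen(beta)
    trace <- obj
    sweeps <- 0L
    repeat {                                    # outer reweighting loop
      w <- pmax(q$w, 1e-10)
      z <- eta + q$g / w
      beta_old_outer <- beta
      # covariance-form quadratic subproblem: gradient_j of the weighted
      # least squares is A[j, ] %*% beta - bvec[j], with A = X'WX / n
      A <- crossprod(xs, w * xs) / n
      bvec <- drop(crossprod(xs, w * z)) / n
      s_vec <- drop(A %*% beta)
      adiag <- diag(A)
      # cyclic coordinate descent with an active-set strategy: full sweeps
      # establish the active set, which is then iterated to convergence.
      # Stopping rule is the weighted-objective criterion
      # max_j adiag_j * (delta beta_j)^2 < thresh (stable under strongly
      # correlated predictors, where an absolute coefficient criterion
      # stalls along near-null directions).
      cd_sweep <- function(idx) {
        dmax <- 0
        for (j in idx) {
          bj <- beta[j]
          num <- bvec[j] - s_vec[j] + adiag[j] * bj
          bnew <- soft_threshold(num, lam * alpha) /
            (adiag[j] + lam * (1 - alpha))
          if (bnew != bj) {
            s_vec <<- s_vec + A[, j] * (bnew - bj)
            beta[j] <<- bnew
            dmax <- max(dmax, adiag[j] * (bnew - bj)^2)
          }
        }
        dmax
      }
      repeat {                                  # inner coordinate descent
        dmax <- cd_sweep(seq_len(p))
        sweeps <- sweeps + 1L
        if (dmax < thresh || sweeps >= maxit) break
        active <- which(beta != 0)
        while (length(active) && sweeps < maxit) {
          d_act <- cd_sweep(active)
          sweeps <- sweeps + 1L
          if (d_act < thresh) break
        }
      }
      # objective with step-halving safeguard
      step <- 1
      repeat {
        beta_try <- beta_old_outer + step * (beta - beta_old_outer)
        eta_try <- drop(xs %*% beta_try)
        q_try <- cox_quad(eta_try, st)
        obj_try <- -q_try$loglik / n + pen(beta_try)
        if (obj_try <= obj + 1e-12 || step < 1e-4) break
        step <- step / 2
      }
      beta <- beta_try; eta <- eta_try; q <- q_try
      trace <- c(trace, obj_try)
      converged <- max(adiag * (beta - beta_old_outer)^2) < thresh ||
        abs(obj - obj_try) < 1e-13 * (abs(obj) + 1e-13)
      obj <- min(obj, obj_try)
      if (converged || sweeps >= maxit || length(trace) > 100) break
    }
    beta_out[, l] <- beta / scl
    loglik[l] <- q$loglik
    obj_trace[[l]] <- trace
  }
  structure(list(lambda = lambda, beta = beta_out,
                 df = colSums(beta_out != 0), loglik = loglik,
                 objective = obj_trace, alpha = alpha,
                 center = ctr, scale = scl, n = n,
                 n_events = sum(status)),
            class = "coxnet_path")
}

#' @export
print.coxnet_path <- function(x, ...) {
  cat("Elastic-net Cox path (alpha =", x$alpha, "):", length(x$lambda),
      "lambda values,", nrow(x$beta), "predictors,", x$n, "observations,",
      x$n_events, "events\n")
  invisible(x)
}

#' Karush-Kuhn-Tucker optimality check for a coxnet solution
#'
#' Evaluates the subgradient conditions of the elastic-net Cox objective
#' at one point of a fitted path, on the standardized scale. For an
#' active coordinate the penalized gradient must vanish; for an inactive
#' one its magnitude must not exceed `lambda * alpha`.
#'
#' @param fit a [coxnet_path()].
#' @param x,time,status the data the path was fitted to.
#' @param index which lambda (default: last).
#' @return Maximum KKT violation (0 = exact optimality).
#' @export
coxnet_kkt <- function(fit, x, time, status, index = length(fit$lambda)) {
  x <- as.matrix(x)
  st <- cox_structure(time, status)
  xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  b <- fit$beta[, index] * fit$scale           # back to standardized scale
  lam <- fit$lambda[index]; alpha <- fit$alpha
  q <- cox_quad(drop(xs %*% b), st)
  grad <- -drop(crossprod(xs, q$g)) / fit$n + lam * (1 - alpha) * b
  active <- b != 0
  viol <- numeric(length(b))
  viol[active] <- abs(grad[active] + lam * alpha * sign(b[active]))
  viol[!active] <- pmax(abs(grad[!active]) - lam * alpha, 0)
  max(viol)
}

make_patient_folds <- function(patient, event_by_obs, nfolds, seed) {
  pid <- as.character(patient)
  pats <- unique(pid)
  pat_event <- vapply(pats, function(pp) any(event_by_obs[pid == pp] == 1),
                      logical(1))
  for (try in seq_len(20)) {
    set.seed(seed + try - 1L)
    fold_of <- integer(length(pats)); names(fold_of) <- pats
    for (grpval in c(TRUE, FALSE)) {
      idx <- sample(which(pat_event == grpval))
      fold_of[idx] <- rep_len(seq_len(nfolds), length(idx))
    }
    foldid <- fold_of[pid]
    ok <- all(vapply(seq_len(nfolds), function(k)
      sum(event_by_obs[foldid != k]) >= 1 && sum(foldid == k) >= 1,
      logical(1)))
    if (ok) {
      if (try > 1) warning("refolded ", try - 1L,
                           " time(s) to avoid folds without events")
      return(unname(foldid))
    }
  }
  stop("could not build cross-validation folds with events in every fold")
}

#' Cross-validated selection along the elastic-net Cox path
#'
#' Runs k-fold cross-validation of [coxnet_path()] and selects lambda by
#' the minimum-deviance or one-standard-error rule. Folds are assigned at
#' the *patient* level (both lobes of a patient always share a fold) and
#' stratified by patient event status. The CV loss is the cross-validated
#' Cox partial-likelihood deviance, computed by the difference method:
#' for each fold, `-2 * (loglik_all(beta_train) - loglik_train(beta_train))`.
#'
#' @param x,time,status as in [coxnet_path()].
#' @param patient patient identifier per row (both lobes share a value);
#'   defaults to one patient per row.
#' @param nfolds number of folds (default 10).
#' @param rule `"1se"` (largest lambda with mean CV deviance within one
#'   standard error of the minimum; default) or `"min"`.
#' @param seed integer seed controlling fold assignment.
#' @param ... further arguments passed to [coxnet_path()].
#' @return Object of class `coxnet_cv`: the full-data `path` plus
#'   `lambda`, `cvm`, `cvse`, `lambda_min`, `lambda_1se`,
#'   `lambda_chosen`, `rule`, `selected` (names of predictors with
#'   nonzero coefficients at `lambda_chosen`) and `coef_chosen`.
#' @export
coxnet_cv <- function(x, time, status, patient = NULL, nfolds = 10,
                      rule = c("1se", "min"), seed = 1L, ...) {
  rule <- match.arg(rule)
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(patient)) patient <- seq_len(n)
  if (nfolds < 2) stop("k_folds must be >= 2")
  n_event_pat <- length(unique(patient[status == 1]))
  if (nfolds > n_event_pat)
    warning("more folds than patients with events; ",
            "CV estimates will be unstable")
  full <- coxnet_path(x, time, status, ...)
  lambda <- full$lambda
  foldid <- make_patient_folds(patient, status, nfolds, seed)
  dev <- matrix(NA_real_, nfolds, length(lambda))
  for (k in seq_len(nfolds)) {
    tr <- foldid != k
    fit_k <- coxnet_path(x[tr, , drop = FALSE], time[tr], status[tr],
                         lambda = lambda, ...)
    for (l in seq_along(lambda)) {
      b <- fit_k$beta[, l]
      ll_all <- cox_partial_loglik(b, x, time, status)
      ll_tr <- cox_partial_loglik(b, x[tr, , drop = FALSE],
                                  time[tr], status[tr])
      dev[k, l] <- -2 * (ll_all - ll_tr)
    }
  }
  cvm <- colMeans(dev)
  cvse <- apply(dev, 2, stats::sd) / sqrt(nfolds)
  i_min <- which.min(cvm)
  i_1se <- min(which(cvm <= cvm[i_min] + cvse[i_min]))  # largest lambda
  lambda_min <- lambda[i_min]; lambda_1se <- lambda[i_1se]
  i_chosen <- if (rule == "1se") i_1se else i_min
  coef_chosen <- full$beta[, i_chosen]
  structure(list(path = full, lambda = lambda, cvm = cvm, cvse = cvse,
                 foldid = foldid, lambda_min = lambda_min,
                 lambda_1se = lambda_1se,
                 lambda_chosen = lambda[i_chosen], rule = rule,
                 index_chosen = i_chosen,
                 coef_chosen = coef_chosen,
                 selected = names(coef_chosen)[coef_chosen != 0]),
            class = "coxnet_cv")
}

#' @export
print.coxnet_cv <- function(x, ...) {
  cat("Cross-validated elastic-net Cox selection (rule:", x$rule, ")\n")
  cat("  lambda_min =", format(x$lambda_min, digits = 4),
      " lambda_1se =", format(x$lambda_1se, digits = 4), "\n")
  cat("  selected:", if (length(x$selected))
    paste(x$selected, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Screen dosimetric and clinical predictors of injury
#'
#' High-level wrapper: builds the 19-column candidate matrix from a
#' cohort table ([predictor_matrix()]) and runs [coxnet_cv()] with
#' patient-level folds.
#'
#' @param lobes cohort data.frame in the schema of [read_cohort()].
#' @param alpha elastic-net mixing weight (default 0.5).
#' @param nfolds folds for cross-validation (default 10).
#' @param rule lambda selection rule, `"1se"` (default) or `"min"`.
#' @param seed fold-assignment seed.
#' @param ... passed to [coxnet_path()].
#' @return A `coxnet_cv` object.
#' @export
screen_predictors <- function(lobes, alpha = 0.5, nfolds = 10,
                              rule = "1se", seed = 1L, ...) {
  x <- predictor_matrix(lobes)
  const <- apply(x, 2, stats::sd) == 0
  if (any(const)) {
    warning("dropping constant predictor(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  coxnet_cv(x, lobes$time_months, lobes$event,
            patient = lobes$patient_id, nfolds = nfolds, rule = rule,
            seed = seed, alpha = alpha, ...)
}
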