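#' Construct a survival dataset
#'
#' Bundles follow-up times, event indicators and a covariate matrix for Cox
#' proportional-hazards fitting. Times are in months; events are 1 for an
#' observed event (recurrence or disease-specific death) and 0 for censoring.
#'
#' @param time numeric vector of non-negative follow-up times (months).
#' @param event integer vector in \{0, 1\}, same length as `time`.
#' @param covariates numeric matrix (samples x p) with column names, or a
#'   data frame coercible to one.
#' @return an object of class `SurvivalData`.
#' @export
survival_data <- function(time, event, covariates) {
  if (is.data.frame(covariates)) covariates <- as.matrix(covariates)
  if (!is.matrix(covariates)) covariates <- matrix(covariates, ncol = 1L)
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  n <- length(time)
  if (length(event) != n || nrow(covariates) != n)
    stop("time, event and covariates must have matching lengths")
  if (any(!is.finite(time)) || any(time < 0))
    stop("times must be finite and non-negative")
  if (!all(event %in% c(0, 1)))
    stop("event indicators must be 0 or 1")
  if (sum(event) < 1)
    stop("at least one event is required")
  structure(list(time = as.numeric(time), event = as.integer(event),
                 covariates = covariates),
            class = "SurvivalData")
}

#' Fit a Cox proportional-hazards model
#'
#' Maximises the Cox partial likelihood by Newton-Raphson with step-halving,
#' using the Efron (default) or Breslow approximation for tied event times.
#' The two agree exactly when there are no ties. Monotone separation (a
#' coefficient diverging to +/- infinity) is detected via a coefficient
#' magnitude bound and reported as non-convergence rather than a crash, so
#' that large probe screens can treat degenerate probes as non-significant.
#'
#' @param data a `SurvivalData` object from [survival_data()].
#' @param ties `"efron"` or `"breslow"`.
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance on the maximum absolute coefficient
#'   change between accepted Newton steps.
#' @param beta_max separation guard: any |coefficient| beyond this flags the
#'   fit as non-converged.
#' @return an object of class `CoxFit` with elements `coefficients`, `se`,
#'   `hazard_ratios`, `ci95` (matrix with columns low/high), `wald_p`,
#'   `log_partial_likelihood`, `log_partial_likelihood_null`, `converged`,
#'   `ties_method`, `var`, `n`, `n_events`.
#' @export
fit_cox <- function(data, ties = c("efron", "breslow"),
                    max_iter = 100L, tol = 1e-9, beta_max = 20) {
  ties <- match.arg(ties)
  stopifnot(inherits(data, "SurvivalData"))
  X <- data$covariates
  rng <- apply(X, 2L, function(v) max(v) - min(v))
  if (any(rng < 1e-12))
    stop("constant covariate: ", paste(colnames(X)[rng < 1e-12], collapse = ", "))
  if (ncol(X) >= sum(data$event))
    warning("number of covariates (", ncol(X),
            ") is not smaller than the number of events (", sum(data$event), ")")
  res <- .cox_fit_cpp(data$time, as.numeric(data$event), X,
                      efron = (ties == "efron"), max_iter = max_iter,
                      tol = tol, beta_max = beta_max)
  if (!res$converged && (any(!is.finite(res$beta)) || max(abs(res$beta)) > beta_max))
    stop("Cox fit did not converge (monotone separation suspected) for: ",
         paste(colnames(X)[abs(res$beta) > beta_max | !is.finite(res$beta)],
               collapse = ", "))
  beta <- stats::setNames(res$beta, colnames(X))
  se <- stats::setNames(res$se, colnames(X))
  ci <- cbind(low = exp(beta - 1.96 * se), high = exp(beta + 1.96 * se))
  p <- 2 * pnorm(-abs(beta / se))
  p <- pmax(p, .Machine$double.xmin)   # keep p in (0, 1]
  structure(list(coefficients = beta, se = se,
                 hazard_ratios = exp(beta), ci95 = ci, wald_p = p,
                 log_partial_likelihood = res$loglik,
                 log_partial_likelihood_null = res$loglik_null,
                 converged = res$converged, ties_method = ties,
                 var = res$var, n = length(data$time),
                 n_events = sum(data$event)),
            class = "CoxFit")
}

#' @export
print.CoxFit <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties_method, " ties), n = ",
      x$n, ", events = ", x$n_events, "\n", sep = "")
  tab <- data.frame(coef = x$coefficients, se = x$se, HR = x$hazard_ratios,
                    ci_low = x$ci95[, "low"], ci_high = x$ci95[, "high"],
                    p = x$wald_p)
  print(tab, digits = 4)
  invisible(x)
}

#' Wald test for a single covariate of a Cox fit
#'
#' Two-sided p-value from z = coefficient / standard error against the
#' standard normal.
#'
#' @param fit a `CoxFit`.
#' @param covariate_name name of the covariate to test.
#' @return the two-sided p-value.
#' @export
wald_test <- function(fit, covariate_name) {
  stopifnot(inherits(fit, "CoxFit"))
  if (!fit$converged) stop("Wald test requires a converged fit")
  if (!covariate_name %in% names(fit$coefficients))
    stop("unknown covariate: ", covariate_name)
  se <- fit$se[[covariate_name]]
  if (!is.finite(se) || se == 0) stop("standard error is zero or not finite")
  b <- fit$coefficients[[covariate_name]]
  max(2 * pnorm(-abs(b / se)), .Machine$double.xmin)
}

#' Likelihood-ratio test of the full fit against the null model
#'
#' @param fit a `CoxFit`.
#' @return list with `chi_square`, `df`, `p_value`.
#' @export
lr_test <- function(fit) {
  stopifnot(inherits(fit, "CoxFit"))
  chi <- 2 * (fit$log_partial_likelihood - fit$log_partial_likelihood_null)
  df <- length(fit$coefficients)
  list(chi_square = chi, df = df,
       p_value = pchisq(chi, df = df, lower.tail = FALSE))
}

# Score and information of the partial likelihood at a fixed beta; internal,
# used to link the log-rank statistic to the Cox score test.
cox_score_test <- function(time, event, X, ties = "efron") {
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  ev <- .cox_eval_cpp(time, as.numeric(event), X, rep(0, ncol(X)),
                      efron = (ties == "efron"))
  U <- ev$score
  I <- ev$information
  chi <- drop(t(U) %*% solve(I, U))
  list(chi_square = chi,
       p_value = pchisq(chi, df = ncol(X), lower.tail = FALSE))
}
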