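# Kaplan-Meier estimation, two-group log-rank testing and the risk-group /
# multivariate summary tables used to evaluate classifier predictions.

# Censor events beyond the horizon at the horizon ("5-year DFS" = 60 months).
.apply_horizon <- function(times, events, horizon) {
  if (is.null(horizon)) return(list(times = times, events = events))
  over <- times > horizon
  events[over] <- 0L
  times[over] <- horizon
  list(times = times, events = events)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times non-negative follow-up times (months).
#' @param events 0/1 event indicators.
#' @param horizon_months optional horizon; follow-up beyond it is censored
#'   at the horizon (e.g. 60 for 5-year summaries).
#' @return a `KMCurve`: data frame of event times with `n_risk`, `n_event`,
#'   `n_censor` and the step-function `survival`.
#' @export
kaplan_meier <- function(times, events, horizon_months = NULL) {
  if (!length(times)) stop("empty input")
  if (length(times) != length(events)) stop("times and events differ in length")
  if (any(times < 0)) stop("times must be non-negative")
  h <- .apply_horizon(times, as.integer(events), horizon_months)
  ut <- sort(unique(h$times))
  n_risk <- vapply(ut, function(t) sum(h$times >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(h$times == t & h$events == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(h$times == t & h$events == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, survival = surv)
  class(out) <- c("KMCurve", "data.frame")
  out
}

#' Survival probability from a Kaplan-Meier curve at a time point
#'
#' @param curve a `KMCurve`.
#' @param t time (months).
#' @return the step-function value S(t); 1 before the first event time, NA
#'   beyond the last observed time.
#' @export
km_survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "KMCurve"))
  if (t > max(curve$time)) return(NA_real_)
  i <- findInterval(t, curve$time)
  if (i == 0) 1 else curve$survival[i]
}

#' Two-group log-rank test with paired hazard ratio
#'
#' Standard two-group log-rank chi-square (1 df) with the hypergeometric
#' variance and tie correction, plus the hazard ratio of group 2 vs group 1
#' from an unadjusted one-covariate Cox fit, as survival comparisons are
#' conventionally reported (log-rank p next to HR and 95\% CI). With no
#' ties the chi-square equals the score test of that Cox fit.
#'
#' @param times,events as in [kaplan_meier()].
#' @param groups vector with exactly two distinct values.
#' @param horizon_months optional horizon applied before testing.
#' @return a `GroupComparison` list: `chi_square`, `p_value`,
#'   `hazard_ratio`, `hr_ci95`, `hr_p`, `group_sizes`, `surv_at_horizon`.
#' @export
logrank_test <- function(times, events, groups, horizon_months = NULL) {
  g <- as.factor(groups)
  if (nlevels(g) != 2) stop("log-rank test requires exactly 2 groups")
  if (any(table(g) == 0)) stop("both groups must be non-empty")
  h <- .apply_horizon(times, as.integer(events), horizon_months)
  if (sum(h$events) < 1) stop("at least one event is required")
  times <- h$times; events <- h$events
  g2 <- g == levels(g)[2]

  dt <- sort(unique(times[events == 1]))
  obs2 <- 0; exp2 <- 0; varsum <- 0
  for (t in dt) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n2 <- sum(at_risk & g2)
    d <- sum(times == t & events == 1)
    d2 <- sum(times == t & events == 1 & g2)
    obs2 <- obs2 + d2
    exp2 <- exp2 + d * n2 / n
    if (n > 1)
      varsum <- varsum + d * (n2 / n) * (1 - n2 / n) * (n - d) / (n - 1)
  }
  chi <- if (varsum > 0) (obs2 - exp2)^2 / varsum else 0
  p <- pchisq(chi, df = 1, lower.tail = FALSE)
  if (p == 0) p <- .Machine$double.xmin

  hr <- NA_real_; ci <- c(NA_real_, NA_real_); hr_p <- NA_real_
  fit <- tryCatch(
    fit_cox(survival_data(times, events,
                          matrix(as.numeric(g2), ncol = 1,
                                 dimnames = list(NULL, "group")))),
    error = function(e) NULL)
  if (!is.null(fit) && fit$converged) {
    hr <- unname(fit$hazard_ratios["group"])
    ci <- unname(fit$ci95["group", ])
    hr_p <- unname(fit$wald_p["group"])
  }
  surv_h <- if (!is.null(horizon_months)) {
    vapply(levels(g), function(lev) {
      km <- kaplan_meier(times[g == lev], events[g == lev])
      s <- km_survival_at(km, min(horizon_months, max(times[g == lev])))
      if (is.na(s)) utils::tail(km$survival, 1) else s
    }, numeric(1))
  } else NULL

  structure(list(chi_square = chi, p_value = p,
                 hazard_ratio = hr, hr_ci95 = ci, hr_p = hr_p,
                 group_sizes = as.integer(table(g)),
                 group_levels = levels(g),
                 surv_at_horizon = surv_h),
            class = "GroupComparison")
}

#' @export
print.GroupComparison <- function(x, ...) {
  cat(sprintf("log-rank chi-square = %.4f, p = %.4g\n", x$chi_square, x$p_value))
  if (is.finite(x$hazard_ratio))
    cat(sprintf("HR (%s vs %s) = %.2f, 95%% CI %.2f-%.2f\n",
                x$group_levels[2], x$group_levels[1],
                x$hazard_ratio, x$hr_ci95[1], x$hr_ci95[2]))
  invisible(x)
}

#' Risk-group survival table, stratified
#'
#' For each stratum (e.g. stage) and risk group: group size, percent of the
#' series, Kaplan-Meier survival at the horizon, and the within-stratum
#' log-rank p-value comparing high vs low risk. Strata containing a single
#' risk group report survival with a non-computable p-value (NA).
#'
#' @param predictions a `RiskPrediction` data frame from [classify()].
#' @param clinical a `ClinicalTable` covering the predicted samples.
#' @param strata clinical column used for stratification (default
#'   `"stage"`); use NULL for an unstratified table.
#' @param horizon_months survival horizon (default 60 = 5 years).
#' @return a data frame with one row per stratum x risk group.
#' @export
risk_group_table <- function(predictions, clinical, strata = "stage",
                             horizon_months = 60) {
  cl <- as.data.frame(clinical)
  rownames(cl) <- cl$sample_id
  miss <- setdiff(predictions$sample_id, cl$sample_id)
  if (length(miss))
    stop("clinical records missing for: ", paste(head(miss, 3), collapse = ", "))
  cl <- cl[predictions$sample_id, ]
  strat <- if (is.null(strata)) rep("all", nrow(cl)) else as.character(cl[[strata]])
  n_total <- nrow(predictions)
  rows <- list()
  for (s in unique(strat)) {
    in_s <- strat == s
    pv <- NA_real_
    if (length(unique(predictions$risk_group[in_s])) == 2) {
      # not computable (NA) when e.g. no events fall inside the horizon
      lr <- tryCatch(logrank_test(cl$time_months[in_s], cl$event[in_s],
                                  predictions$risk_group[in_s], horizon_months),
                     error = function(e) NULL)
      if (!is.null(lr)) pv <- lr$p_value
    }
    for (gr in intersect(c("low", "high"), unique(predictions$risk_group[in_s]))) {
      sel <- in_s & predictions$risk_group == gr
      km <- kaplan_meier(cl$time_months[sel], cl$event[sel], horizon_months)
      sh <- km_survival_at(km, min(horizon_months, max(cl$time_months[sel])))
      if (is.na(sh)) sh <- utils::tail(km$survival, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, risk_group = gr, n = sum(sel),
        pct_of_series = 100 * sum(sel) / n_total,
        survival_at_horizon_pct = 100 * sh,
        logrank_p = pv, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$stratum, out$risk_group), ]
}

#' Multivariate Cox report including the risk-group call
#'
#' Fits a single Cox model with the available clinical covariates plus the
#' binary risk-group assignment and reports per-covariate hazard ratios,
#' 95\% confidence intervals and Wald p-values. Exactly collinear covariate
#' columns raise an error naming the offending pair.
#'
#' @param clinical a `ClinicalTable`.
#' @param predictions a `RiskPrediction` data frame.
#' @param covariates clinical covariates to adjust for; any of `"age"`,
#'   `"gender"`, `"grade"`, `"stage"`, `"adj_chemo"`, `"adj_radio"`.
#' @return a data frame with one row per model term: `coefficient`, `se`,
#'   `hazard_ratio`, `ci_low`, `ci_high`, `p_value`.
#' @export
multivariate_report <- function(clinical, predictions,
                                covariates = c("age", "gender", "grade", "stage")) {
  cl <- as.data.frame(clinical)
  rownames(cl) <- cl$sample_id
  miss <- setdiff(predictions$sample_id, cl$sample_id)
  if (length(miss))
    stop("clinical records missing for: ", paste(head(miss, 3), collapse = ", "))
  cl <- cl[predictions$sample_id, ]
  cols <- list()
  if ("age" %in% covariates) cols$age <- cl$age_years
  if ("gender" %in% covariates) cols$gender_male <- as.numeric(cl$gender == "male")
  if ("grade" %in% covariates) cols$grade <- suppressWarnings(as.numeric(cl$grade))
  if ("stage" %in% covariates) cols$stage <- suppressWarnings(as.numeric(cl$stage))
  if ("adj_chemo" %in% covariates) cols$adj_chemo <- suppressWarnings(as.numeric(cl$adj_chemo))
  if ("adj_radio" %in% covariates) cols$adj_radio <- suppressWarnings(as.numeric(cl$adj_radio))
  cols$risk_high <- as.numeric(predictions$risk_group == "high")
  X <- do.call(cbind, cols)
  if (anyNA(X))
    stop("incomplete covariates: ",
         paste(colnames(X)[colSums(is.na(X)) > 0], collapse = ", "))
  # exact collinearity check, naming the offending pair
  cc <- suppressWarnings(cor(X))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 0
  if (any(abs(cc) > 1 - 1e-10)) {
    idx <- which(abs(cc) > 1 - 1e-10, arr.ind = TRUE)[1, ]
    stop("collinear covariates: ", colnames(X)[idx[1]], " and ", colnames(X)[idx[2]])
  }
  if (qr(cbind(1, X))$rank < ncol(X) + 1)
    stop("collinear covariates: design matrix is rank deficient")
  fit <- fit_cox(survival_data(cl$time_months, cl$event, X))
  data.frame(term = names(fit$coefficients),
             coefficient = unname(fit$coefficients),
             se = unname(fit$se),
             hazard_ratio = unname(fit$hazard_ratios),
             ci_low = unname(fit$ci95[, "low"]),
             ci_high = unname(fit$ci95[, "high"]),
             p_value = unname(fit$wald_p),
             stringsAsFactors = FALSE)
}
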