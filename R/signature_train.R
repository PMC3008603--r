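# Training of the two-metagene prognostic classifier: multivariate Cox
# probe screen, LOOCV stability selection, percentile-rank PCA metagenes,
# prognostic index, and median threshold.

# Numeric clinical covariate block used by the screen: age in years, grade
# and stage as ordinal numerics. Errors on samples with missing covariates
# (the screen is multivariate and needs complete covariates).
.screen_covariates <- function(clinical, samples) {
  cl <- as.data.frame(clinical)
  rownames(cl) <- cl$sample_id
  miss <- setdiff(samples, cl$sample_id)
  if (length(miss))
    stop("clinical records missing for: ", paste(head(miss, 3), collapse = ", "))
  cl <- cl[samples, ]
  bad <- !is.finite(cl$age_years) | cl$grade == "unknown" | cl$stage == "unknown"
  if (any(bad))
    stop("incomplete training covariates (age/grade/stage) for: ",
         paste(head(cl$sample_id[bad], 3), collapse = ", "))
  Z <- cbind(age = cl$age_years,
             grade = as.numeric(cl$grade),
             stage = as.numeric(cl$stage))
  rownames(Z) <- samples
  list(Z = Z, time = cl$time_months, event = cl$event)
}

#' Screen probes by multivariate Cox regression
#'
#' Fits, for every probe, a Cox proportional-hazards model whose covariates
#' are the probe's expression plus age, grade and stage (ordinal numerics),
#' and tests the expression coefficient with a two-sided Wald test. A probe
#' is selected when its fit converged and its Wald p-value is below `alpha`.
#' Non-convergent fits (e.g. monotone separation on a degenerate probe) are
#' recorded as unselected with a reason; they never abort the screen.
#'
#' @param matrix a log2 `ExpressionMatrix`, already filtered and centred.
#' @param clinical a `ClinicalTable` covering the matrix samples with
#'   complete age, grade, stage, time and event.
#' @param alpha per-probe significance level (default 0.002).
#' @param ties tie handling passed to the Cox fitter.
#' @return a `ScreenResult` data frame with columns `probe_id`,
#'   `coefficient`, `se`, `wald_p`, `converged`, `selected`, `reason`.
#' @export
screen_probes <- function(matrix, clinical, alpha = 0.002, ties = "efron") {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  samples <- sample_ids(matrix)
  cov <- .screen_covariates(clinical, samples)
  if (sum(cov$event) < 10)
    stop("probe screening requires at least 10 events")
  res <- .cox_screen_cpp(cov$time, as.numeric(cov$event),
                         matrix$values, cov$Z,
                         efron = (ties == "efron"))
  b <- res$beta; se <- res$se; conv <- res$converged
  p <- 2 * pnorm(-abs(b / se))
  ok <- conv & is.finite(p) & is.finite(se) & se > 0
  out <- data.frame(probe_id = probe_ids(matrix),
                    coefficient = b, se = se, wald_p = p,
                    converged = conv,
                    selected = ok & p < alpha,
                    reason = ifelse(conv, "",
                                    "non-convergent fit (separation or degenerate probe)"),
                    stringsAsFactors = FALSE)
  attr(out, "alpha") <- alpha
  class(out) <- c("ScreenResult", "data.frame")
  out
}

#' Leave-one-out cross-validated stability selection
#'
#' Repeats the full training procedure with each sample held out once: the
#' probe screen and the metagene model are refit on the remaining samples,
#' the held-out sample's prognostic index is computed from that round's own
#' model, and each probe's selection frequency across rounds is recorded.
#' Probes selected in at least `freq_threshold` of the rounds form the
#' stable signature; the held-out indices later define the classification
#' threshold. A round in which no probe passes the screen is recorded as
#' empty (held-out index NA) without changing the frequency denominator.
#'
#' @inheritParams screen_probes
#' @param freq_threshold minimum selection frequency (default 0.20).
#' @return a `StabilityResult` list: `frequency` (named per-probe),
#'   `stable_probes`, `heldout_indices` (named per-sample), `n_rounds`,
#'   `rounds` (list of per-round selected sets).
#' @export
loocv_stability_selection <- function(matrix, clinical, alpha = 0.002,
                                      freq_threshold = 0.20, ties = "efron") {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  samples <- sample_ids(matrix)
  n <- length(samples)
  if (n < 20) stop("LOOCV stability selection requires n >= 20")
  cov <- .screen_covariates(clinical, samples)
  probes <- probe_ids(matrix)
  counts <- stats::setNames(numeric(length(probes)), probes)
  heldout <- stats::setNames(rep(NA_real_, n), samples)
  rounds <- vector("list", n)
  for (i in seq_len(n)) {
    keep <- setdiff(seq_len(n), i)
    res <- .cox_screen_cpp(cov$time[keep], as.numeric(cov$event[keep]),
                           matrix$values[, keep, drop = FALSE],
                           cov$Z[keep, , drop = FALSE],
                           efron = (ties == "efron"))
    p <- 2 * pnorm(-abs(res$beta / res$se))
    sel <- res$converged & is.finite(p) & p < alpha
    sel_probes <- probes[sel]
    rounds[[i]] <- sel_probes
    counts[sel_probes] <- counts[sel_probes] + 1
    if (length(sel_probes) >= 2) {
      m <- train_metagene_model(
        expression_matrix(matrix$values[, keep, drop = FALSE], scale = "log2"),
        clinical, sel_probes, quiet = TRUE)
      if (!is.null(m))
        heldout[i] <- compute_prognostic_index(m, matrix$values[, i])
    }
  }
  freq <- counts / n
  structure(list(frequency = freq,
                 stable_probes = names(freq)[freq >= freq_threshold],
                 heldout_indices = heldout,
                 n_rounds = n,
                 freq_threshold = freq_threshold,
                 rounds = rounds),
            class = "StabilityResult")
}

#' Train the two-metagene prognostic model on a fixed probe set
#'
#' For each sample, expression over the signature probes is converted to
#' within-sample percentile ranks (0-100); ranks are mean-centred per probe
#' and the first two principal components computed (no variance scaling:
#' ranks share the 0-100 scale). The two PC score vectors - the
#' "metagenes" - enter a two-covariate Cox model on the survival endpoint,
#' and component signs are flipped so every retained Cox coefficient is
#' non-negative: a higher prognostic index always means higher estimated
#' hazard. If the second component carries essentially no variance the
#' model falls back to a single metagene with a warning.
#'
#' @param matrix a log2 `ExpressionMatrix` containing the probes.
#' @param clinical a `ClinicalTable`.
#' @param probes the signature probe ids (length >= 3).
#' @param loocv_indices optional held-out LOOCV indices; when supplied their
#'   50th percentile becomes the classification threshold and they are
#'   stored as the model's training index distribution.
#' @param replicate_sd calibrated between-site standard deviation of the
#'   index used for 95\% prediction intervals (see [replicate_stability()]).
#' @param preprocess_state optional `PreprocessState` recorded in the model.
#' @param quiet internal: return NULL instead of erroring inside LOOCV.
#' @return a `SignatureModel`.
#' @export
train_metagene_model <- function(matrix, clinical, probes,
                                 loocv_indices = NULL,
                                 replicate_sd = NA_real_,
                                 preprocess_state = NULL,
                                 quiet = FALSE) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  fail <- function(msg) if (quiet) return(NULL) else stop(msg)
  if (!quiet && length(probes) < 3)
    stop("the metagene model needs at least 3 signature probes")
  missing_probes <- setdiff(probes, probe_ids(matrix))
  if (length(missing_probes))
    return(fail(paste("probes absent from matrix:",
                      paste(head(missing_probes, 3), collapse = ", "))))
  samples <- sample_ids(matrix)
  cl <- as.data.frame(clinical)
  rownames(cl) <- cl$sample_id
  cl <- cl[samples, ]

  expr <- matrix$values[probes, samples, drop = FALSE]
  ranks <- apply(expr, 2L, percentile_rank_transform)   # probes x samples
  R <- t(ranks)                                         # samples x probes
  center <- colMeans(R)
  Xc <- sweep(R, 2L, center)
  sv <- svd(Xc, nu = 0, nv = min(2L, ncol(Xc)))
  evar <- sv$d^2 / max(1, nrow(R) - 1)
  k <- if (length(evar) >= 2 && evar[2] > 1e-8 * max(evar[1], 1)) 2L else 1L
  if (k == 1L && !quiet)
    warning("second principal component is degenerate; using one metagene")
  loadings <- t(sv$v[, seq_len(k), drop = FALSE])       # k x p, unit-norm rows
  colnames(loadings) <- probes
  scores <- Xc %*% t(loadings)                          # samples x k
  colnames(scores) <- paste0("metagene", seq_len(k))

  fit <- tryCatch(
    fit_cox(survival_data(cl$time_months, cl$event, scores)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged)
    return(fail("metagene Cox model did not converge"))
  betas <- unname(fit$coefficients)
  flip <- betas < 0
  loadings[flip, ] <- -loadings[flip, , drop = FALSE]
  scores[, flip] <- -scores[, flip, drop = FALSE]
  betas[flip] <- -betas[flip]

  final_indices <- drop(scores %*% betas)
  names(final_indices) <- samples
  train_idx <- if (!is.null(loocv_indices)) {
    li <- loocv_indices[is.finite(loocv_indices)]
    if (!length(li)) return(fail("no finite LOOCV indices supplied"))
    li
  } else final_indices
  threshold <- unname(quantile(train_idx, 0.5, names = FALSE))

  structure(list(
    probe_ids = probes,
    pc_loadings = loadings,
    pc_center = center,
    metagene_betas = betas,
    metagene_fit = fit,
    threshold = threshold,
    training_index_quantiles = unname(quantile(train_idx, seq(0, 1, 0.05))),
    training_indices = unname(train_idx),
    final_model_indices = final_indices,
    replicate_sd = replicate_sd,
    retained_probe_ids = if (is.null(preprocess_state)) character(0) else
      preprocess_state$retained_probe_ids,
    reference_probe_ids = if (is.null(preprocess_state)) character(0) else
      preprocess_state$reference_probe_ids,
    filter_threshold = if (is.null(preprocess_state)) NA_real_ else
      preprocess_state$filter_threshold,
    trained = TRUE), class = "SignatureModel")
}

#' @export
print.SignatureModel <- function(x, ...) {
  cat("SignatureModel: ", length(x$probe_ids), " probes, ",
      nrow(x$pc_loadings), " metagene(s)\n", sep = "")
  cat("  metagene Cox coefficients:",
      paste(sprintf("%.4f", x$metagene_betas), collapse = ", "), "\n")
  cat("  classification threshold: ", sprintf("%.4f", x$threshold),
      " (50th percentile of training indices)\n", sep = "")
  if (is.finite(x$replicate_sd))
    cat("  calibrated replicate s.d.:", sprintf("%.4f", x$replicate_sd), "\n")
  invisible(x)
}

#' Full signature training pipeline
#'
#' Runs LOOCV stability selection (probe screen plus metagene fit inside
#' every round), takes the probes selected in at least `freq_threshold` of
#' the rounds as the signature, and retrains the percentile-rank metagene
#' model on the full cohort. The classification threshold is the 50th
#' percentile of the held-out LOOCV indices, so roughly half the training
#' series is called low risk by construction.
#'
#' @inheritParams loocv_stability_selection
#' @param replicate_sd calibrated replicate standard deviation stored in the
#'   model (NA until [replicate_stability()] has been run).
#' @param preprocess_state optional `PreprocessState` stored in the model.
#' @return list with `model` (`SignatureModel`), `stability`
#'   (`StabilityResult`) and `screen` (full-data `ScreenResult`).
#' @export
train_signature <- function(matrix, clinical, alpha = 0.002,
                            freq_threshold = 0.20,
                            replicate_sd = NA_real_,
                            preprocess_state = NULL, ties = "efron") {
  stability <- loocv_stability_selection(matrix, clinical, alpha,
                                         freq_threshold, ties)
  if (length(stability$stable_probes) < 3)
    stop("fewer than 3 probes reached selection frequency ",
         freq_threshold, "; no signature can be trained")
  model <- train_metagene_model(matrix, clinical, stability$stable_probes,
                                loocv_indices = stability$heldout_indices,
                                replicate_sd = replicate_sd,
                                preprocess_state = preprocess_state)
  screen <- screen_probes(matrix, clinical, alpha, ties)
  list(model = model, stability = stability, screen = screen)
}

#' Compute the prognostic index for one or more samples
#'
#' The sample's expression over the signature probes is converted to
#' within-sample percentile ranks, centred on the training mean ranks, and
#' projected onto the metagene loadings; the index is the metagene Cox
#' linear predictor (the score-weighted sum of the principal component
#' values). Higher index means higher estimated hazard.
#'
#' @param model a `SignatureModel`.
#' @param x named numeric vector of one sample's expression over (at least)
#'   the signature probes, a probes x samples matrix, or an
#'   `ExpressionMatrix`.
#' @param ranked set TRUE when `x` already contains percentile ranks over
#'   the signature probes (skips the rank transform).
#' @return numeric vector of prognostic indices (one per sample).
#' @export
compute_prognostic_index <- function(model, x, ranked = FALSE) {
  stopifnot(inherits(model, "SignatureModel"))
  if (inherits(x, "ExpressionMatrix")) x <- as_log2(x)$values
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L, dimnames = list(names(x), "sample"))
  missing_probes <- setdiff(model$probe_ids, rownames(x))
  if (length(missing_probes))
    stop("missing signature probe(s): ",
         paste(head(missing_probes, 5), collapse = ", "),
         if (length(missing_probes) > 5) sprintf(" (+%d more)", length(missing_probes) - 5))
  xs <- x[model$probe_ids, , drop = FALSE]
  ranks <- if (ranked) xs else apply(xs, 2L, percentile_rank_transform)
  centred <- ranks - model$pc_center                    # recycled by probe
  scores <- model$pc_loadings %*% centred               # k x samples
  idx <- drop(crossprod(model$metagene_betas, scores))
  stats::setNames(as.numeric(idx), colnames(x))
}

#' Classify samples into high/low recurrence-risk groups
#'
#' A sample is called high risk when its prognostic index is at or above
#' the model threshold (ties at the threshold go to high risk, the
#' conservative call for a boundary case). Every valid input receives a
#' call; there is no unclassifiable zone. When the model carries a
#' calibrated replicate standard deviation, a 95\% interval
#' (index +/- 1.96 s.d.) is attached and predictions whose interval
#' straddles the threshold are annotated as borderline.
#'
#' @inheritParams compute_prognostic_index
#' @return a data frame of class `RiskPrediction` with columns `sample_id`,
#'   `prognostic_index`, `ci_low`, `ci_high`, `risk_group`, `borderline`.
#' @export
classify <- function(model, x, ranked = FALSE) {
  idx <- compute_prognostic_index(model, x, ranked = ranked)
  sd <- model$replicate_sd
  half <- if (is.finite(sd)) 1.96 * sd else NA_real_
  out <- data.frame(
    sample_id = if (is.null(names(idx))) sprintf("sample_%d", seq_along(idx)) else names(idx),
    prognostic_index = unname(idx),
    ci_low = unname(idx - half), ci_high = unname(idx + half),
    risk_group = ifelse(idx >= model$threshold, "high", "low"),
    borderline = if (is.finite(half))
      unname(idx - half < model$threshold & idx + half >= model$threshold)
    else NA,
    stringsAsFactors = FALSE)
  class(out) <- c("RiskPrediction", "data.frame")
  out
}

#' Hypergeometric significance of the overlap between two gene sets
#'
#' Upper-tail probability P(X >= overlap) that two sets of the observed
#' sizes drawn independently from a common universe share at least the
#' observed number of members, computed by exact summation of the
#' hypergeometric terms in log space.
#'
#' @param set_a,set_b character vectors of gene/probe ids, or integers
#'   giving the set sizes when `overlap` is supplied directly.
#' @param universe_size size of the common universe.
#' @param overlap observed overlap count; defaults to
#'   `length(intersect(set_a, set_b))` when both sets are id vectors.
#' @return the upper-tail probability.
#' @export
signature_overlap_significance <- function(set_a, set_b, universe_size,
                                           overlap = NULL) {
  size_of <- function(s) if (is.character(s)) length(unique(s)) else as.integer(s)
  a <- size_of(set_a); b <- size_of(set_b)
  if (a > universe_size || b > universe_size)
    stop("set sizes cannot exceed the universe size")
  if (is.null(overlap)) {
    if (!is.character(set_a) || !is.character(set_b))
      stop("overlap must be given explicitly when sets are passed as sizes")
    overlap <- length(intersect(set_a, set_b))
  }
  if (overlap > min(a, b))
    stop("overlap (", overlap, ") exceeds the smaller set size (", min(a, b), ")")
  if (overlap < 0) stop("overlap must be non-negative")
  if (overlap == 0) return(1)
  ks <- overlap:min(a, b)
  logs <- lchoose(a, ks) + lchoose(universe_size - a, b - ks) -
    lchoose(universe_size, b)
  m <- max(logs)
  min(exp(m + log(sum(exp(logs - m)))), 1)
}
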