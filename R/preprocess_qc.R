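#' Quality-control configuration for chip evaluation
#'
#' Windows for the four chip-level metrics. A metric outside its window
#' raises a flag; any flag fails the chip. Defaults are deliberately wide:
#' they catch gross hybridisation failures (saturated or empty chips,
#' order-of-magnitude scaling errors) without excluding ordinary biological
#' variation.
#'
#' @param background_window log2 window for the background estimate (mean
#'   log2 intensity of the dimmest 2\% of probes).
#' @param scale_factor_window window for the chip scale factor (chip trimmed
#'   mean intensity over the cohort median trimmed mean, linear scale).
#' @param snr_min minimum signal-to-noise ratio (log2 dynamic range between
#'   the 2.5th and 97.5th percentile, divided by the standard deviation of
#'   the background region).
#' @param replicate_cv_max maximum median coefficient of variation across
#'   genes measured by two or more probes (only evaluated when a
#'   probe-to-gene mapping is supplied).
#' @return a list of class `qc_config`.
#' @export
qc_config <- function(background_window = c(0, 10),
                      scale_factor_window = c(0.25, 4),
                      snr_min = 2,
                      replicate_cv_max = 0.5) {
  structure(list(background_window = background_window,
                 scale_factor_window = scale_factor_window,
                 snr_min = snr_min,
                 replicate_cv_max = replicate_cv_max),
            class = "qc_config")
}

# Trimmed mean of linear intensities (2% two-sided).
.trimmed_mean_linear <- function(v) mean(v, trim = 0.02)

#' Evaluate chip-level quality for one sample
#'
#' Computes four metrics per chip: nonspecific background (mean log2
#' intensity of the dimmest 2\% of probes), scale factor (chip trimmed mean
#' over the cohort median trimmed mean on linear scale), signal-to-noise
#' ratio, and replicate-probe variation (median CV across genes with >= 2
#' probes, when a mapping is given). Chips with any flagged metric should be
#' excluded from training and evaluation.
#'
#' @param matrix an `ExpressionMatrix` (any scale; converted internally).
#' @param sample_id sample to evaluate (must be a column of `matrix`).
#' @param config a [qc_config()].
#' @param probe_to_gene optional named character vector mapping probe id to
#'   gene id, enabling the replicate-probe metric.
#' @return a list of class `QCReport` with the metric values, `flags`
#'   (character vector of failed metric names) and `pass`.
#' @export
qc_evaluate_chip <- function(matrix, sample_id, config = qc_config(),
                             probe_to_gene = NULL) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (!sample_id %in% sample_ids(matrix))
    stop("sample not found: ", sample_id)
  lin <- as_linear(matrix)$values
  chip_lin <- lin[, sample_id]
  if (sum(chip_lin > 0) <= 1L)
    stop("chip has <= 1 positive probe; cannot compute quality metrics")
  chip_log <- log2(chip_lin[chip_lin > 0])   # no flooring: QC wants the raw tail

  n_bg <- max(1L, floor(0.02 * length(chip_log)))
  bg_vals <- sort(chip_log)[seq_len(n_bg)]
  background <- mean(bg_vals)
  bg_sd <- if (length(bg_vals) > 1) sd(bg_vals) else NA_real_

  cohort_tm <- median(apply(lin, 2L, .trimmed_mean_linear))
  scale_factor <- .trimmed_mean_linear(chip_lin) / cohort_tm

  dyn_range <- diff(quantile(chip_log, c(0.025, 0.975), names = FALSE))
  snr <- if (is.finite(bg_sd) && bg_sd > 0) dyn_range / bg_sd else Inf

  rep_cv <- NA_real_
  if (!is.null(probe_to_gene)) {
    genes <- probe_to_gene[probe_ids(matrix)]
    keep <- !is.na(genes)
    tab <- table(genes[keep])
    multi <- names(tab)[tab >= 2]
    if (length(multi)) {
      cvs <- vapply(multi, function(g) {
        v <- chip_lin[keep][genes[keep] == g]
        if (mean(v) == 0) return(NA_real_)
        sd(v) / mean(v)
      }, numeric(1))
      rep_cv <- median(cvs, na.rm = TRUE)
    }
  }

  flags <- character(0)
  if (background < config$background_window[1] ||
      background > config$background_window[2])
    flags <- c(flags, "background_estimate")
  if (scale_factor < config$scale_factor_window[1] ||
      scale_factor > config$scale_factor_window[2])
    flags <- c(flags, "scale_factor")
  if (is.finite(snr) && snr < config$snr_min)
    flags <- c(flags, "signal_to_noise")
  if (is.finite(rep_cv) && rep_cv > config$replicate_cv_max)
    flags <- c(flags, "replicate_probe_cv")

  structure(list(sample_id = sample_id,
                 background_estimate = background,
                 scale_factor = scale_factor,
                 signal_to_noise = snr,
                 replicate_probe_cv = rep_cv,
                 flags = flags, pass = length(flags) == 0L),
            class = "QCReport")
}

#' Evaluate chip quality for every sample in a matrix
#'
#' @inheritParams qc_evaluate_chip
#' @return a data frame with one row per chip (metrics, flags collapsed with
#'   `;`, and `pass`).
#' @export
qc_evaluate_all <- function(matrix, config = qc_config(), probe_to_gene = NULL) {
  reps <- lapply(sample_ids(matrix), function(s)
    qc_evaluate_chip(matrix, s, config, probe_to_gene))
  data.frame(
    sample_id = vapply(reps, `[[`, character(1), "sample_id"),
    background_estimate = vapply(reps, `[[`, numeric(1), "background_estimate"),
    scale_factor = vapply(reps, `[[`, numeric(1), "scale_factor"),
    signal_to_noise = vapply(reps, `[[`, numeric(1), "signal_to_noise"),
    replicate_probe_cv = vapply(reps, `[[`, numeric(1), "replicate_probe_cv"),
    flags = vapply(reps, function(r) paste(r$flags, collapse = ";"), character(1)),
    pass = vapply(reps, `[[`, logical(1), "pass"))
}

#' Remove probes with low median intensity
#'
#' A probe is excluded when its median linear intensity across samples falls
#' below the threshold (default 100, the conventional floor below which
#' microarray intensities are dominated by background). The retained probe
#' list is recorded in a `PreprocessState` so prediction-time chips are
#' restricted to the same probe universe.
#'
#' @param matrix an `ExpressionMatrix`.
#' @param threshold linear-intensity threshold; probes with median `<`
#'   threshold are dropped (a median exactly at the threshold is kept).
#' @param reference optional `ReferenceProbeSet` to record in the state.
#' @return list with elements `matrix` (filtered, same scale as input) and
#'   `state` (a `PreprocessState`).
#' @export
filter_low_intensity <- function(matrix, threshold = 100, reference = NULL) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (threshold < 0) stop("threshold must be non-negative")
  lin <- as_linear(matrix)$values
  med <- apply(lin, 1L, median)
  keep <- med >= threshold
  if (!any(keep)) stop("intensity filter removed every probe")
  out <- expression_matrix(matrix$values[keep, , drop = FALSE],
                           scale = matrix$scale)
  state <- structure(list(retained_probe_ids = probe_ids(out),
                          reference_probe_ids = as.character(reference),
                          filter_threshold = threshold),
                     class = "PreprocessState")
  list(matrix = out, state = state)
}

#' Median-centre each chip on a reference probe set
#'
#' Subtracts, per sample, the log2 median over the reference probes from
#' every probe, so that after centering each sample's reference-probe median
#' is exactly zero. This removes chip-to-chip brightness differences using
#' probes chosen for low cross-tissue variation.
#'
#' @param matrix an `ExpressionMatrix` on log2 scale.
#' @param reference a `ReferenceProbeSet` (or character vector of probe ids).
#' @param min_fraction minimum fraction of reference probes that must be
#'   present in the matrix; below this the call errors (missing a few probes
#'   after intensity filtering is tolerated with a warning).
#' @return the centred `ExpressionMatrix` (log2).
#' @export
median_center_chips <- function(matrix, reference, min_fraction = 0.5) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (matrix$scale != "log2")
    stop("median centering operates on log2 scale; call as_log2() first")
  ref <- intersect(as.character(reference), probe_ids(matrix))
  if (!length(ref)) stop("no reference probe found in matrix")
  frac <- length(ref) / length(as.character(reference))
  if (frac < min_fraction)
    stop(sprintf("only %.0f%% of reference probes present (minimum %.0f%%)",
                 100 * frac, 100 * min_fraction))
  if (frac < 1)
    warning(sprintf("%d of %d reference probes absent from matrix",
                    length(as.character(reference)) - length(ref),
                    length(as.character(reference))))
  meds <- apply(matrix$values[ref, , drop = FALSE], 2L, median)
  centred <- sweep(matrix$values, 2L, meds, "-")
  expression_matrix(centred, scale = "log2")
}

#' Percentile-rank transform of one sample's expression values
#'
#' Maps a vector of expression values to percentile ranks in \[0, 100\]:
#' the value with (average, for ties) rank r among m values maps to
#' 100 (r - 1) / (m - 1), so the minimum maps to 0.00 and the maximum to
#' 100.00. The output depends only on the ordering of the input, making the
#' downstream prognostic index invariant under any strictly increasing
#' per-sample transform of the intensities. An all-constant input maps to
#' 50.00 everywhere by convention.
#'
#' @param values numeric vector (length >= 2).
#' @return numeric vector of percentile ranks in \[0, 100\].
#' @export
percentile_rank_transform <- function(values) {
  m <- length(values)
  if (m < 2L) stop("percentile ranks need at least 2 values")
  if (any(!is.finite(values))) stop("values must be finite")
  if (max(values) == min(values)) return(rep(50, m))
  r <- rank(values, ties.method = "average")
  100 * (r - 1) / (m - 1)
}

#' Apply a stored preprocessing state to new chips
#'
#' Restricts a matrix to the retained probe universe recorded at training
#' time, converts to log2 and median-centres on the stored reference set.
#'
#' @param matrix an `ExpressionMatrix`.
#' @param state a `PreprocessState` from [filter_low_intensity()].
#' @return a log2 `ExpressionMatrix` over the retained probes.
#' @export
apply_preprocess <- function(matrix, state) {
  stopifnot(inherits(matrix, "ExpressionMatrix"),
            inherits(state, "PreprocessState"))
  missing_probes <- setdiff(state$retained_probe_ids, probe_ids(matrix))
  if (length(missing_probes))
    stop("matrix lacks ", length(missing_probes), " retained probe(s), e.g. ",
         paste(head(missing_probes, 3), collapse = ", "))
  x <- as_log2(matrix)
  x <- expression_matrix(x$values[state$retained_probe_ids, , drop = FALSE],
                         scale = "log2")
  if (length(state$reference_probe_ids))
    x <- median_center_chips(x, state$reference_probe_ids)
  x
}
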