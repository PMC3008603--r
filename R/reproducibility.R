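# Multi-site replicate analysis: between-site variation of the prognostic
# index and calibration of the 95% interval attached to single-sample
# predictions.

#' Prognostic indices for a replicate chip set
#'
#' Convenience wrapper: computes the prognostic index of every chip in a
#' replicate expression matrix and joins it to the replicate manifest.
#'
#' @param model a `SignatureModel`.
#' @param matrix a log2 `ExpressionMatrix` of replicate chips.
#' @param manifest data frame with columns `sample`, `site`, `replicate`,
#'   `chip_id` (chip ids must match the matrix columns).
#' @return a `ReplicateSet` data frame: `sample`, `site`, `replicate`,
#'   `prognostic_index`.
#' @export
replicate_indices <- function(model, matrix, manifest) {
  idx <- compute_prognostic_index(model, matrix)
  miss <- setdiff(manifest$chip_id, names(idx))
  if (length(miss)) stop("manifest chip(s) absent from matrix: ",
                         paste(head(miss, 3), collapse = ", "))
  out <- data.frame(sample = manifest$sample, site = manifest$site,
                    replicate = manifest$replicate,
                    prognostic_index = unname(idx[manifest$chip_id]),
                    stringsAsFactors = FALSE)
  class(out) <- c("ReplicateSet", "data.frame")
  out
}

#' Between-site reproducibility of the prognostic index
#'
#' For each replicated sample: the mean index per site and the standard
#' deviation across those site means. The average of the per-sample
#' standard deviations (`mean_sd`) calibrates the 95\% interval attached to
#' single-chip predictions (half-width 1.96 x mean_sd), and is also
#' expressed as a fraction of the prognostic-index range observed in the
#' model's training (LOOCV) indices. Within each site, replicate runs are
#' compared with a two-sided test (one-way ANOVA on replicate number after
#' removing per-sample means, or Kruskal-Wallis); sites with p > 0.05 show
#' no significant replicate-to-replicate difference.
#'
#' @param replicates a `ReplicateSet` data frame (columns `sample`, `site`,
#'   `replicate`, `prognostic_index`), e.g. from [replicate_indices()].
#' @param model optional `SignatureModel` supplying the training index
#'   range; alternatively pass `index_range` directly.
#' @param index_range numeric length-2 range of training indices.
#' @param test within-site comparison method.
#' @return a `StabilityReport` list: `per_sample` (data frame with the site
#'   means' s.d. per sample), `mean_sd`, `fraction_of_range`,
#'   `calibrated_ci_halfwidth`, `within_site` (per-site p-values),
#'   `no_significant_within_site_difference`.
#' @export
replicate_stability <- function(replicates, model = NULL, index_range = NULL,
                                test = c("anova", "kruskal")) {
  test <- match.arg(test)
  req <- c("sample", "site", "replicate", "prognostic_index")
  if (!all(req %in% names(replicates)))
    stop("replicates needs columns: ", paste(req, collapse = ", "))
  if (anyDuplicated(replicates[, c("sample", "site", "replicate")]))
    stop("duplicate (sample, site, replicate) rows")
  if (length(unique(replicates$site)) < 2)
    stop("between-site s.d. is undefined with a single site")
  tab <- table(replicates$sample, replicates$site)
  if (!any(tab >= 2))
    stop("need >= 2 replicates per site for at least one sample")

  per_sample <- do.call(rbind, lapply(unique(replicates$sample), function(s) {
    sub <- replicates[replicates$sample == s, ]
    site_means <- tapply(sub$prognostic_index, sub$site, mean)
    data.frame(sample = s, n_sites = length(site_means),
               mean_index = mean(sub$prognostic_index),
               sd_site_means = sd(site_means), stringsAsFactors = FALSE)
  }))
  mean_sd <- mean(per_sample$sd_site_means)

  rng <- if (!is.null(index_range)) diff(range(index_range))
  else if (!is.null(model)) diff(range(model$training_indices))
  else NA_real_
  fraction <- if (is.finite(rng) && rng > 0) mean_sd / rng else NA_real_

  within <- do.call(rbind, lapply(unique(replicates$site), function(st) {
    sub <- replicates[replicates$site == st, ]
    # remove per-sample means so pools with different indices don't mask
    # a replicate-run effect
    centred <- sub$prognostic_index -
      stats::ave(sub$prognostic_index, sub$sample)
    p <- if (length(unique(sub$replicate)) < 2 || sd(centred) == 0) NA_real_
    else if (test == "anova")
      summary(aov(centred ~ factor(sub$replicate)))[[1]][["Pr(>F)"]][1]
    else kruskal.test(centred, factor(sub$replicate))$p.value
    data.frame(site = st, p_value = p, stringsAsFactors = FALSE)
  }))

  structure(list(per_sample = per_sample,
                 mean_sd = mean_sd,
                 fraction_of_range = fraction,
                 calibrated_ci_halfwidth = 1.96 * mean_sd,
                 within_site = within,
                 no_significant_within_site_difference =
                   all(is.na(within$p_value) | within$p_value > 0.05),
                 test = test),
            class = "StabilityReport")
}

#' @export
print.StabilityReport <- function(x, ...) {
  cat("Replicate stability over", nrow(x$per_sample), "sample(s)\n")
  print(x$per_sample, digits = 4)
  cat(sprintf("mean s.d. of site means: %.4f", x$mean_sd))
  if (is.finite(x$fraction_of_range))
    cat(sprintf(" (%.1f%% of training index range)", 100 * x$fraction_of_range))
  cat(sprintf("\n95%% CI half-width: %.4f\n", x$calibrated_ci_halfwidth))
  invisible(x)
}

#' 95\% prediction interval for a prognostic index
#'
#' Symmetric normal-theory interval index +/- 1.96 x calibrated replicate
#' standard deviation.
#'
#' @param index prognostic index (numeric, possibly vector).
#' @param model a `SignatureModel` carrying a calibrated `replicate_sd`.
#' @return a two-column matrix (`low`, `high`).
#' @export
prediction_interval <- function(index, model) {
  stopifnot(inherits(model, "SignatureModel"))
  sd <- model$replicate_sd
  if (!is.finite(sd))
    stop("model has no calibrated replicate s.d.; run replicate_stability() ",
         "and store its mean_sd in the model, or set replicate_sd explicitly")
  cbind(low = index - 1.96 * sd, high = index + 1.96 * sd)
}

#' Attach a calibrated replicate standard deviation to a model
#'
#' @param model a `SignatureModel`.
#' @param sd replicate standard deviation (e.g. `mean_sd` from
#'   [replicate_stability()]).
#' @return the updated model.
#' @export
set_replicate_sd <- function(model, sd) {
  stopifnot(inherits(model, "SignatureModel"))
  if (!is.finite(sd) || sd < 0) stop("sd must be finite and >= 0")
  model$replicate_sd <- sd
  model
}
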