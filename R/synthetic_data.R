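#' Simulation configuration for synthetic expression cohorts
#'
#' Describes a cohort with the statistical structure the pipeline assumes:
#' tens of thousands of log-normal background probes, a small informative
#' minority whose expression tracks a latent per-sample risk factor entering
#' an exponential proportional-hazards survival time, clinical covariates
#' (age, grade, stage) with their own log-hazard effects, independent
#' right-censoring tuned to a target rate, a block of planted low-intensity
#' probes, and 100 designated low-variance reference probes.
#'
#' Defaults mirror a single-site colon-cancer style training cohort:
#' n = 200 patients, 2000 probes of which 20 carry signal at log-hazard 0.8
#' per standard deviation of expression, ~30\% censoring, a baseline hazard
#' giving median event times of a few years, and a stage mix weighted toward
#' stages 2-3.
#'
#' @param n_samples number of patients.
#' @param n_probes total probes (including reference and low-intensity blocks).
#' @param n_informative probes carrying survival signal.
#' @param effect_size log-hazard per s.d. of informative-probe expression.
#' @param baseline_hazard events per month at the covariate baseline.
#' @param censor_rate target fraction censored (strictly in (0, 1)).
#' @param age_effect,grade_effect,stage_effect log-hazards per year of age
#'   (centred at 65), per grade level (centred at 2) and per stage level
#'   (centred at 2).
#' @param stage_probs probabilities of stages 1-4.
#' @param intensity_location,intensity_scale mean and s.d. of per-probe mean
#'   log2 background intensity.
#' @param noise_sd per-cell log2 measurement noise.
#' @param fraction_low_intensity fraction of probes planted below the
#'   100-intensity filter in every sample.
#' @param n_reference number of low-variance reference probes.
#' @param n_sites,n_replicates,site_noise_sd,replicate_noise_sd multi-site
#'   replicate design used by [generate_replicates()].
#' @param seed mandatory integer seed; the generator is fully reproducible.
#' @return a list of class `SimulationConfig`.
#' @export
sim_config <- function(n_samples = 200L, n_probes = 2000L,
                       n_informative = 20L, effect_size = 0.8,
                       baseline_hazard = 0.01, censor_rate = 0.3,
                       age_effect = 0.01, grade_effect = 0.2,
                       stage_effect = 0.4,
                       stage_probs = c(0.12, 0.40, 0.33, 0.15),
                       intensity_location = 8, intensity_scale = 1.5,
                       noise_sd = 0.4,
                       fraction_low_intensity = 0.1,
                       n_reference = 100L,
                       n_sites = 6L, n_replicates = 5L,
                       site_noise_sd = 0.05, replicate_noise_sd = 0.02,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (n_informative > n_probes) stop("n_informative exceeds n_probes")
  if (censor_rate <= 0 || censor_rate >= 1)
    stop("censor_rate must be strictly between 0 and 1")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  n_low <- floor(fraction_low_intensity * n_probes)
  if (n_informative + n_low + n_reference > n_probes)
    stop("informative + low-intensity + reference blocks exceed n_probes")
  structure(as.list(environment()), class = "SimulationConfig")
}

# Censoring rate for independent exponential censoring at rate c against
# per-sample exponential event rates lambda: P(censored_i) = c / (lambda_i + c).
.solve_censor_rate <- function(lambda, target) {
  f <- function(logc) mean(exp(logc) / (lambda + exp(logc))) - target
  lo <- log(min(lambda)) - 20; hi <- log(max(lambda)) + 20
  exp(uniroot(f, c(lo, hi), tol = 1e-12)$root)
}

#' Generate a synthetic expression cohort with survival outcomes
#'
#' Draws per-probe mean log2 intensities from a Gaussian (log-normal on the
#' linear scale), adds a standard-normal latent risk factor to the
#' informative probes, and generates exponential proportional-hazards event
#' times driven by the latent factor plus clinical covariate effects.
#' Censoring is independent exponential with its rate solved numerically so
#' the expected censored fraction matches `censor_rate`. A configured
#' fraction of probes is planted below the linear intensity filter in every
#' sample (capped just under 100), and `n_reference` near-constant reference
#' probes are included.
#'
#' @param config a [sim_config()].
#' @return list with `expression` (log2 `ExpressionMatrix`), `clinical`
#'   (a `ClinicalTable`), `truth` (a `GroundTruth`: informative probe ids,
#'   per-sample true linear predictor, true risk half) and `reference`
#'   (a `ReferenceProbeSet`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_probes
  n_low <- floor(config$fraction_low_intensity * p)
  n_ref <- config$n_reference
  n_inf <- config$n_informative

  ids <- sprintf("PROBE_%05d", seq_len(p))
  inf_idx <- seq_len(n_inf)
  low_idx <- seq(n_inf + 1L, length.out = n_low)
  ref_idx <- seq(n_inf + n_low + 1L, length.out = n_ref)
  if (n_ref) ids[ref_idx] <- sprintf("REFSET_%03d", seq_len(n_ref))
  sample_id <- sprintf("SAMPLE_%03d", seq_len(n))

  mu <- rnorm(p, config$intensity_location, config$intensity_scale)
  # background and reference probes sit well above the intensity filter
  mu <- pmax(mu, log2(150))
  if (n_low) mu[low_idx] <- rnorm(n_low, 4.5, 0.5)

  z <- rnorm(n)                      # latent per-sample risk factor
  vals <- matrix(rnorm(p * n, 0, config$noise_sd), p, n,
                 dimnames = list(ids, sample_id)) + mu
  if (n_inf) {
    # alternate up-/down-regulated probes: prognostic signatures carry both
    # directions, and a purely one-sided set would cancel out of
    # within-sample ranks
    dir <- rep(c(1, -1), length.out = n_inf)
    vals[inf_idx, ] <- vals[inf_idx, ] + outer(dir, z)
  }
  if (n_ref)   # reference probes: nearly constant across samples
    vals[ref_idx, ] <- mu[ref_idx] + matrix(rnorm(n_ref * n, 0, 0.02), n_ref, n)
  if (n_low)   # planted low-intensity block stays under the filter everywhere
    vals[low_idx, ] <- pmin(vals[low_idx, ], log2(95))

  age <- pmin(pmax(rnorm(n, 66, 12), 30), 95)
  gender <- sample(c("male", "female"), n, replace = TRUE)
  grade <- sample(1:3, n, replace = TRUE, prob = c(0.2, 0.6, 0.2))
  stage <- sample(1:4, n, replace = TRUE, prob = config$stage_probs)
  adj_chemo <- rbinom(n, 1, 0.35)
  adj_radio <- rbinom(n, 1, 0.1)

  eta <- config$effect_size * z +
    config$age_effect * (age - 65) +
    config$grade_effect * (grade - 2) +
    config$stage_effect * (stage - 2)
  lambda <- config$baseline_hazard * exp(eta)
  t_event <- rexp(n, rate = lambda)
  c_rate <- .solve_censor_rate(lambda, config$censor_rate)
  t_cens <- rexp(n, rate = c_rate)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  clinical <- clinical_table(data.frame(
    sample_id = sample_id, age_years = age, gender = gender,
    grade = as.character(grade), stage = as.character(stage),
    time_months = time, event = event, endpoint = "DFS",
    adj_chemo = as.character(adj_chemo), adj_radio = as.character(adj_radio),
    stringsAsFactors = FALSE))

  truth <- structure(list(
    informative_probe_ids = ids[inf_idx],
    low_intensity_probe_ids = ids[low_idx],
    linear_predictor = stats::setNames(eta, sample_id),
    risk_half = stats::setNames(ifelse(eta > median(eta), "high", "low"),
                                sample_id)),
    class = "GroundTruth")

  list(expression = expression_matrix(vals, scale = "log2"),
       clinical = clinical, truth = truth,
       reference = reference_probe_set(ids[ref_idx]))
}

#' Generate multi-site replicate chips for one base sample
#'
#' Emulates a multi-laboratory replicate design: for each site a per-probe
#' site effect is drawn once (shared by all of that site's chips), and each
#' chip additionally receives independent per-probe replicate noise. Both
#' effects are additive on the log2 scale.
#'
#' @param base named numeric vector of log2 expression for the base sample,
#'   or a one-sample `ExpressionMatrix`.
#' @param n_sites,n_replicates design dimensions.
#' @param site_noise_sd,replicate_noise_sd log2 noise standard deviations
#'   (must be >= 0).
#' @param seed integer seed.
#' @param sample_label label used in chip ids and the manifest.
#' @return list with `expression` (log2 `ExpressionMatrix`, probes x chips)
#'   and `manifest` (data frame: sample, site, replicate, chip_id).
#' @export
generate_replicates <- function(base, n_sites = 6L, n_replicates = 5L,
                                site_noise_sd = 0.05,
                                replicate_noise_sd = 0.02, seed,
                                sample_label = "A") {
  if (missing(seed)) stop("a seed is mandatory")
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  if (site_noise_sd < 0 || replicate_noise_sd < 0)
    stop("noise standard deviations must be >= 0")
  if (inherits(base, "ExpressionMatrix")) {
    if (ncol(base$values) != 1L) stop("base must be a single sample")
    base <- stats::setNames(as_log2(base)$values[, 1L], probe_ids(base))
  }
  if (is.null(names(base))) stop("base expression must be named by probe id")
  set.seed(seed)
  p <- length(base)
  chips <- matrix(NA_real_, p, n_sites * n_replicates)
  manifest <- data.frame(sample = character(0), site = character(0),
                         replicate = integer(0), chip_id = character(0))
  k <- 0L
  for (s in seq_len(n_sites)) {
    site_eff <- rnorm(p, 0, site_noise_sd)
    for (r in seq_len(n_replicates)) {
      k <- k + 1L
      chips[, k] <- base + site_eff + rnorm(p, 0, replicate_noise_sd)
      manifest <- rbind(manifest, data.frame(
        sample = sample_label, site = sprintf("site_%d", s),
        replicate = r,
        chip_id = sprintf("%s_site%d_rep%d", sample_label, s, r)))
    }
  }
  dimnames(chips) <- list(names(base), manifest$chip_id)
  list(expression = expression_matrix(chips, scale = "log2"),
       manifest = manifest)
}
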