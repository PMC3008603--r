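test_that("the multivariate screen adjusts probe effects for stage (confounder absorption)", {
  set.seed(61)
  n <- 150
  stage <- sample(1:4, n, replace = TRUE)
  probe <- stage + rnorm(n, 0, 0.2)      # probe nearly a stage readout
  age <- rnorm(n, 65, 10); grade <- sample(1:3, n, replace = TRUE)
  t <- rexp(n, 0.01 * exp(0.5 * stage))
  e <- rbinom(n, 1, 0.8)
  adj <- fit_cox(survival_data(t, e, cbind(probe = probe, age = age,
                                           grade = grade, stage = stage)))
  unadj <- fit_cox(survival_data(t, e, cbind(probe = probe)))
  expect_lt(abs(adj$coefficients["probe"]), abs(unadj$coefficients["probe"]))
})

test_that("the screen flags degenerate probes instead of aborting", {
  co <- small_cohort(seed = 71, n = 40, probes = 50, informative = 5)
  x <- co$expression
  x$values[8, ] <- 5  # constant probe
  res <- screen_probes(x, co$clinical)
  expect_s3_class(res, "ScreenResult")
  expect_false(res$selected[8])
  expect_false(res$converged[8])
  expect_match(res$reason[8], "non-convergent")
  expect_true(any(res$selected))
})

test_that("screen selections agree with per-probe coxph Wald tests", {
  skip_if_not_installed("survival")
  co <- small_cohort(seed = 81, n = 50, probes = 40, informative = 8)
  res <- screen_probes(co$expression, co$clinical)
  cl <- as.data.frame(co$clinical)
  for (k in c(1, 5, 25, 40)) {
    df <- data.frame(t = cl$time_months, e = cl$event,
                     probe = co$expression$values[k, ],
                     age = cl$age_years, grade = as.numeric(cl$grade),
                     stage = as.numeric(cl$stage))
    ref <- survival::coxph(survival::Surv(t, e) ~ probe + age + grade + stage,
                           data = df)
    expect_equal(res$coefficient[k], unname(coef(ref)["probe"]), tolerance = 1e-6)
    expect_equal(res$wald_p[k],
                 unname(summary(ref)$coefficients["probe", "Pr(>|z|)"]),
                 tolerance = 1e-6)
  }
})

test_that("LOOCV stability selection: impossible frequency threshold empties the stable set", {
  co <- small_cohort(seed = 91, n = 25, probes = 60, informative = 6)
  st <- loocv_stability_selection(co$expression, co$clinical,
                                  freq_threshold = 1.01)
  expect_length(st$stable_probes, 0)
  expect_equal(st$n_rounds, 25)
  expect_true(all(st$frequency >= 0 & st$frequency <= 1))
})

test_that("strongly informative probes are selected in nearly every LOOCV round", {
  co <- small_cohort(seed = 101, n = 40, probes = 80, informative = 8,
                     effect = 1.5)
  st <- loocv_stability_selection(co$expression, co$clinical)
  freq_inf <- st$frequency[co$truth$informative_probe_ids]
  expect_gte(mean(freq_inf >= 0.9), 0.75)
  expect_true(all(co$truth$informative_probe_ids %in% st$stable_probes))
})

test_that("duplicating every sample reproduces the full-data screen as the stable set", {
  co <- small_cohort(seed = 111, n = 20, probes = 60, informative = 6,
                     effect = 1.5)
  v <- co$expression$values
  dup_vals <- cbind(v, v)
  colnames(dup_vals) <- c(colnames(v), paste0(colnames(v), "_dup"))
  dup_x <- expression_matrix(dup_vals, "log2")
  cl <- as.data.frame(co$clinical)
  cl2 <- cl; cl2$sample_id <- paste0(cl2$sample_id, "_dup")
  dup_cl <- clinical_table(rbind(cl, cl2))
  st <- loocv_stability_selection(dup_x, dup_cl, freq_threshold = 0.5)
  full <- screen_probes(dup_x, dup_cl)
  # every twin survives each hold-out, so each round's screen is essentially
  # the full-data screen; majority vote reproduces it (up to probes whose
  # p-value sits within rounding of alpha itself)
  full_sel <- full$probe_id[full$selected]
  expect_true(all(full$wald_p[match(st$stable_probes, full$probe_id)] < 0.004))
  expect_true(all(full_sel %in% st$stable_probes |
                    abs(full$wald_p[full$selected] - 0.002) < 5e-4))
})

test_that("the metagene model is deterministic and its training scores are uncorrelated", {
  co <- small_cohort(seed = 121)
  st <- loocv_stability_selection(co$expression, co$clinical)
  m1 <- train_metagene_model(co$expression, co$clinical, st$stable_probes,
                             loocv_indices = st$heldout_indices)
  m2 <- train_metagene_model(co$expression, co$clinical, st$stable_probes,
                             loocv_indices = st$heldout_indices)
  expect_identical(m1$pc_loadings, m2$pc_loadings)
  expect_identical(m1$metagene_betas, m2$metagene_betas)
  expect_identical(m1$threshold, m2$threshold)

  # loadings rows are unit norm; projected training scores are orthogonal
  expect_equal(unname(rowSums(m1$pc_loadings^2)), rep(1, nrow(m1$pc_loadings)))
  ranks <- apply(co$expression$values[m1$probe_ids, ], 2,
                 percentile_rank_transform)
  Xc <- sweep(t(ranks), 2, m1$pc_center)
  scores <- Xc %*% t(m1$pc_loadings)
  cv <- crossprod(scores) / (nrow(scores) - 1)
  expect_lt(abs(cv[1, 2]) / sqrt(cv[1, 1] * cv[2, 2]), 1e-10)
  # metagene Cox coefficients are non-negative by the sign convention
  expect_true(all(m1$metagene_betas >= 0))
})

test_that("the prognostic index reproduces hand arithmetic on a 2-probe toy model", {
  toy <- structure(list(
    probe_ids = c("g1", "g2"),
    pc_loadings = matrix(c(1, 1, 1, -1) / sqrt(2), nrow = 2, byrow = TRUE,
                         dimnames = list(NULL, c("g1", "g2"))),
    pc_center = c(g1 = 50, g2 = 50),
    metagene_betas = c(0.5, 0.2),
    threshold = 0, training_indices = c(-1, 1),
    training_index_quantiles = numeric(0),
    replicate_sd = NA_real_, retained_probe_ids = character(0),
    reference_probe_ids = character(0), filter_threshold = NA_real_,
    trained = TRUE), class = "SignatureModel")
  # ranks (100, 0): s1 = 0, s2 = 100/sqrt(2) = 70.71...; index = 0.2*70.71
  idx <- compute_prognostic_index(toy, c(g1 = 100, g2 = 0), ranked = TRUE)
  expect_equal(unname(idx), 0.2 * 100 / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(idx), 14.1421356, tolerance = 1e-6)
  # centering identity: the training mean-rank vector maps to index 0
  expect_equal(unname(compute_prognostic_index(toy, toy$pc_center, ranked = TRUE)),
               0, tolerance = 1e-12)
  expect_error(compute_prognostic_index(toy, c(g1 = 1)), "missing signature probe")
})

test_that("a dominant hazard-increasing probe raises the index (sign convention)", {
  set.seed(131)
  n <- 80
  driver <- rnorm(n)                   # strong hazard driver
  vals <- rbind(drv = 8 + 3 * driver,
                b1 = rnorm(n, 8, 0.3), b2 = rnorm(n, 8, 0.3),
                b3 = rnorm(n, 8, 0.3))
  colnames(vals) <- sprintf("S%02d", 1:n)
  x <- expression_matrix(vals, "log2")
  cl <- clinical_table(data.frame(
    sample_id = colnames(vals), age_years = rnorm(n, 65, 8),
    gender = "male", grade = "2", stage = "2",
    time_months = rexp(n, 0.02 * exp(1.2 * driver)),
    event = rbinom(n, 1, 0.85), endpoint = "DFS"))
  m <- train_metagene_model(x, cl, rownames(vals))
  idx <- compute_prognostic_index(m, x)
  expect_gt(cor(idx, driver), 0.5)
  # PC1 loading concentrates on the dominant-variance probe
  expect_equal(which.max(abs(m$pc_loadings[1, ])), c(drv = 1L))
})

test_that("classification uses the >= threshold tie rule and is stable to tiny perturbations", {
  co <- small_cohort(seed = 141)
  tr <- train_signature(co$expression, co$clinical)
  model <- tr$model

  ranks <- apply(co$expression$values[model$probe_ids, ], 2,
                 percentile_rank_transform)
  preds <- classify(model, ranks, ranked = TRUE)
  jitter <- classify(model, ranks + 1e-9, ranked = TRUE)
  expect_identical(preds$risk_group, jitter$risk_group)

  # an index exactly equal to the threshold is called high risk (tie rule)
  model_at <- model
  model_at$threshold <- preds$prognostic_index[1]   # exact float match
  expect_identical(classify(model_at, ranks, ranked = TRUE)$risk_group[1],
                   "high")
  model_at$threshold <- preds$prognostic_index[1] + 1e-12
  expect_identical(classify(model_at, ranks, ranked = TRUE)$risk_group[1],
                   "low")

  # self-classification of the training series brackets the LOOCV median
  self <- classify(model, co$expression)
  frac_low <- mean(self$risk_group == "low")
  expect_gte(frac_low, 0.4)
  expect_lte(frac_low, 0.6)
})

test_that("the LOOCV threshold splits held-out training indices half and half", {
  co <- small_cohort(seed = 151)
  tr <- train_signature(co$expression, co$clinical)
  idx <- tr$stability$heldout_indices
  idx <- idx[is.finite(idx)]
  below <- sum(idx < tr$model$threshold)
  expect_true(below %in% c(floor(length(idx) / 2), ceiling(length(idx) / 2)))
})

test_that("prognostic indices are invariant under strictly increasing per-sample intensity transforms", {
  co <- small_cohort(seed = 161)
  tr <- train_signature(co$expression, co$clinical)
  x <- co$expression$values
  idx0 <- compute_prognostic_index(tr$model, x)
  expect_identical(idx0, compute_prognostic_index(tr$model, x^3))
  expect_identical(idx0, compute_prognostic_index(tr$model, 2^x))
  expect_identical(idx0, compute_prognostic_index(tr$model, 5 * x - 40))
  # and per-sample transforms that differ between samples
  warped <- sapply(seq_len(ncol(x)), function(j) exp(x[, j] / j))
  dimnames(warped) <- dimnames(x)
  expect_identical(idx0, compute_prognostic_index(tr$model, warped))
})

test_that("probe and sample order do not affect training", {
  co <- small_cohort(seed = 171, n = 40, probes = 100, informative = 8,
                     effect = 1.8)
  set.seed(1)
  pperm <- sample(nrow(co$expression$values))
  sperm <- sample(ncol(co$expression$values))
  shuffled <- expression_matrix(co$expression$values[pperm, sperm], "log2")
  # redundant informative probes can degenerate PC2; the fallback warning is
  # expected and irrelevant to the invariance being checked
  tr1 <- suppressWarnings(train_signature(co$expression, co$clinical))
  tr2 <- suppressWarnings(train_signature(shuffled, co$clinical))
  expect_setequal(tr1$stability$stable_probes, tr2$stability$stable_probes)
  expect_equal(tr1$model$threshold, tr2$model$threshold, tolerance = 1e-9)
  idx1 <- compute_prognostic_index(tr1$model, co$expression$values)
  idx2 <- compute_prognostic_index(tr2$model, co$expression$values)
  expect_equal(idx1, idx2, tolerance = 1e-8)
})

test_that("hypergeometric overlap significance matches enumeration and phyper", {
  expect_equal(signature_overlap_significance(letters[1:3], letters[4:6], 10), 1)
  p_pkg <- signature_overlap_significance(3, 3, 10, overlap = 2)
  expect_equal(p_pkg, enumerated_overlap_tail(10, 3, 3, 2), tolerance = 1e-12)
  # cross-check against the survival-function form of the same distribution
  expect_equal(p_pkg, phyper(1, 3, 7, 3, lower.tail = FALSE), tolerance = 1e-12)
  # tail probability is monotone non-increasing in the observed overlap
  ps <- vapply(0:3, function(k)
    signature_overlap_significance(3, 3, 10, overlap = k), numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_error(signature_overlap_significance(3, 3, 10, overlap = 4),
               "exceeds")
  expect_error(signature_overlap_significance(11, 3, 10, overlap = 1),
               "universe")
})
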