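test_that("Kaplan-Meier reproduces the hand-computed product limit", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2/3, 1/3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  expect_equal(km_survival_at(km, 2.5), 1/3)
  expect_equal(km_survival_at(km, 0.5), 1)

  all_cens <- kaplan_meier(c(5, 10, 15), c(0, 0, 0))
  expect_true(all(all_cens$survival == 1))
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
})

test_that("Kaplan-Meier matches survival::survfit with censoring and ties", {
  skip_if_not_installed("survival")
  set.seed(7)
  t <- ceiling(rexp(60, 0.05))
  e <- rbinom(60, 1, 0.6)
  km <- kaplan_meier(t, e)
  ref <- survival::survfit(survival::Surv(t, e) ~ 1)
  expect_equal(km$survival[km$n_event > 0],
               summary(ref)$surv, tolerance = 1e-12)
})

test_that("the empirical curve tracks the exponential closed form", {
  lambda <- 0.05
  for (seed in 1:4) {
    set.seed(seed)
    t <- rexp(100, lambda)
    km <- kaplan_meier(t, rep(1, 100))
    sup <- max(abs(km$survival - exp(-lambda * km$time)))
    expect_lt(sup, 0.17)  # DKW-style bound at n = 100
  }
})

test_that("KM and log-rank are invariant to time-unit rescaling", {
  set.seed(71)
  t <- rexp(50, 0.1); e <- rbinom(50, 1, 0.7); g <- rep(c("a", "b"), 25)
  km1 <- kaplan_meier(t, e); km2 <- kaplan_meier(t * 12, e)
  expect_equal(km1$survival, km2$survival)
  lr1 <- logrank_test(t, e, g); lr2 <- logrank_test(t * 12, e, g)
  expect_equal(lr1$chi_square, lr2$chi_square, tolerance = 1e-12)
})

test_that("identical groups give chi-square 0 and p = 1", {
  t <- c(1, 2, 3, 4, 1, 2, 3, 4)
  e <- c(1, 1, 0, 1, 1, 1, 0, 1)
  g <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(t, e, g)
  expect_equal(lr$chi_square, 0)
  expect_equal(lr$p_value, 1)
  expect_error(logrank_test(t, e, rep("a", 8)), "2 groups")
})

test_that("log-rank agrees with survival::survdiff and with the Cox score test", {
  skip_if_not_installed("survival")
  set.seed(77)
  t <- rexp(80, 0.1) + seq(0, 1e-4, length.out = 80)  # untied
  e <- rbinom(80, 1, 0.8)
  g <- rep(c("lo", "hi"), 40)
  lr <- logrank_test(t, e, g)
  ref <- survival::survdiff(survival::Surv(t, e) ~ g)
  expect_equal(lr$chi_square, ref$chisq, tolerance = 1e-9)
  st <- survsig:::cox_score_test(t, e, as.numeric(g == unique(g)[1]),
                                 ties = "breslow")
  expect_equal(lr$chi_square, st$chi_square, tolerance = 1e-6)
})

test_that("doubling every subject increases the chi-square and decreases p", {
  t <- c(2, 4, 6, 8, 3, 9, 12, 14)
  e <- c(1, 1, 1, 0, 1, 1, 0, 1)
  g <- rep(c("a", "b"), each = 4)
  lr1 <- logrank_test(t, e, g)
  lr2 <- logrank_test(rep(t, 2), rep(e, 2), rep(g, 2))
  expect_gt(lr2$chi_square, lr1$chi_square)
  expect_lt(lr2$p_value, lr1$p_value)
})

test_that("the risk-group table composes and matches direct per-stratum computation", {
  co <- small_cohort(seed = 181)
  tr <- train_signature(co$expression, co$clinical)
  preds <- classify(tr$model, co$expression)
  tab <- risk_group_table(preds, co$clinical, strata = "stage",
                          horizon_months = 60)
  expect_equal(sum(tab$pct_of_series), 100, tolerance = 1e-9)
  expect_true(all(tab$survival_at_horizon_pct >= 0 &
                    tab$survival_at_horizon_pct <= 100))

  # recomputing one stratum from its subset matches the table row
  cl <- as.data.frame(co$clinical)
  s <- tab$stratum[1]
  in_s <- cl$stage[match(preds$sample_id, cl$sample_id)] == s
  if (length(unique(preds$risk_group[in_s])) == 2) {
    direct <- logrank_test(cl$time_months[match(preds$sample_id, cl$sample_id)][in_s],
                           cl$event[match(preds$sample_id, cl$sample_id)][in_s],
                           preds$risk_group[in_s], horizon_months = 60)
    expect_equal(tab$logrank_p[tab$stratum == s][1], direct$p_value,
                 tolerance = 1e-12)
  }

  # a group with zero events within the horizon reports 100% survival
  few <- preds[1:5, ]
  few$risk_group <- "low"
  cl5 <- as.data.frame(co$clinical)[match(few$sample_id, co$clinical$sample_id), ]
  cl5$event <- 0L
  tab0 <- risk_group_table(few, clinical_table(cl5), strata = NULL)
  expect_equal(tab0$survival_at_horizon_pct, 100)
  expect_true(is.na(tab0$logrank_p))  # single risk group: p not computable
})

test_that("the multivariate report recovers a planted risk-group hazard despite confounding", {
  set.seed(191)
  n <- 400
  stage <- sample(1:4, n, replace = TRUE)
  risk <- rbinom(n, 1, plogis(0.5 * (stage - 2.5)))  # confounded with stage
  t <- rexp(n, 0.01 * exp(1.2 * risk + 0.4 * (stage - 2)))
  e <- rbinom(n, 1, 0.8)
  cl <- clinical_table(data.frame(
    sample_id = sprintf("S%03d", 1:n), age_years = rnorm(n, 65, 10),
    gender = sample(c("male", "female"), n, TRUE),
    grade = as.character(sample(1:3, n, TRUE)), stage = as.character(stage),
    time_months = t, event = e, endpoint = "DFS"))
  preds <- data.frame(sample_id = cl$sample_id,
                      risk_group = ifelse(risk == 1, "high", "low"))
  rep <- multivariate_report(cl, preds)
  row <- rep[rep$term == "risk_high", ]
  expect_lt(abs(row$coefficient - 1.2), 3 * row$se)
  expect_lt(row$p_value, 0.01)
})

test_that("collinear covariates are rejected by name", {
  co <- small_cohort(seed = 201)
  cl <- as.data.frame(co$clinical)
  cl$age_years <- as.numeric(cl$grade)   # age duplicates grade
  preds <- data.frame(sample_id = cl$sample_id,
                      risk_group = rep(c("high", "low"), length.out = nrow(cl)))
  expect_error(multivariate_report(clinical_table(cl), preds),
               "collinear.*age.*grade|collinear.*grade.*age")
})

test_that("a randomly assigned risk group has HR covering 1.0 in most repetitions", {
  covered <- 0L
  for (seed in 1:30) {
    set.seed(seed)
    n <- 150
    t <- rexp(n, 0.02); e <- rbinom(n, 1, 0.7)
    if (sum(e) < 10) next
    cl <- clinical_table(data.frame(
      sample_id = sprintf("S%03d", 1:n), age_years = rnorm(n, 65, 10),
      gender = "male", grade = "2", stage = "2",
      time_months = t, event = e, endpoint = "DFS"))
    preds <- data.frame(sample_id = cl$sample_id,
                        risk_group = sample(c("high", "low"), n, TRUE))
    rep <- multivariate_report(cl, preds, covariates = "age")
    row <- rep[rep$term == "risk_high", ]
    if (row$ci_low <= 1 && row$ci_high >= 1) covered <- covered + 1L
  }
  expect_gte(covered / 30, 0.9)
})
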