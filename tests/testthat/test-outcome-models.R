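# folds, penalized fits, concordance metrics, KM / log-rank, Wald / Fisher,
# risk stratification, cross-validation plumbing

test_that("every patient tests exactly once and KM profiles are matched", {
  co <- generate_cohort(synthetic_config(
    n_patients = c(NYU = 25, UCSF = 60, BWH = 35), seed = 23),
    render_tiles = FALSE)
  pm <- patient_manifest(co$manifest)
  folds <- make_folds(pm, n_folds = 3, seed = 4, km_tolerance = 0.15)
  test_counts <- dplyr::count(dplyr::filter(folds, split == "test"), patient_id)
  expect_equal(nrow(test_counts), nrow(pm))
  expect_true(all(test_counts$n == 1))
  # within each fold the splits partition the patients
  per_fold <- dplyr::count(folds, fold, patient_id)
  expect_true(all(per_fold$n == 1))
  # recompute the KM gap of the accepted split and check the tolerance
  for (f in 0:2) {
    te <- folds$patient_id[folds$fold == f & folds$split == "test"]
    tr <- folds$patient_id[folds$fold == f & folds$split != "test"]
    gap <- hplkit:::max_km_gap(
      pm$dfs_months[pm$patient_id %in% tr], pm$event[pm$patient_id %in% tr],
      pm$dfs_months[pm$patient_id %in% te], pm$event[pm$patient_id %in% te])
    expect_lte(gap, 0.15 + 1e-12)
  }
  # identical survival for everyone: the first draw is accepted with gap 0
  flat <- dplyr::mutate(pm, dfs_months = 12, event = 1)
  f0 <- make_folds(flat, seed = 1)
  expect_equal(attr(f0, "km_gap"), 0)
})

test_that("auroc equals exhaustive pair enumeration", {
  expect_equal(auroc(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(auroc(rep(2, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  s <- c(0.1, 0.4, 0.4, 0.8, 0.35, 0.9)
  y <- c(0, 0, 1, 1, 0, 1)
  expect_equal(auroc(s, y), oracle_auroc(s, y), tolerance = 1e-12)
  expect_error(auroc(1:3, c(1, 1, 1)), "Both classes")
})

test_that("Harrell's c matches the pair oracle on a mixed-censoring fixture", {
  time <- c(2, 5, 7, 10, 12, 15, 20, 25)
  event <- c(1, 0, 1, 1, 0, 1, 0, 1)
  scores <- c(8, 7, 6, 6, 4, 3, 2, 1)
  expect_equal(harrell_c(scores, time, event),
               oracle_harrell(scores, time, event), tolerance = 1e-12)
  # perfect and reversed orderings without censoring
  t2 <- 1:6
  e2 <- rep(1, 6)
  expect_equal(harrell_c(6:1, t2, e2), 1)
  expect_equal(harrell_c(1:6, t2, e2), 0)
  # invariance to strictly monotone transforms of the scores
  expect_equal(harrell_c(exp(scores / 2), time, event),
               harrell_c(scores, time, event))
})

test_that("Uno's c matches the direct IPCW double sum", {
  time <- c(2, 5, 7, 10, 12, 15, 20, 25)
  event <- c(1, 0, 1, 1, 0, 1, 0, 1)
  scores <- c(8, 7, 6, 6, 4, 3, 2, 1)
  tau <- 20
  expect_equal(uno_c(scores, time, event, tau = tau),
               oracle_uno(scores, time, event, tau), tolerance = 1e-6)
  # without censoring and tau at the horizon it degenerates to Harrell's c
  e1 <- rep(1, 8)
  expect_equal(uno_c(scores, time, e1, tau = max(time)),
               harrell_c(scores, time, e1), tolerance = 1e-12)
  expect_equal(uno_c(8:1, time, e1, tau = max(time)), 1)
})

test_that("Kaplan-Meier matches hand product-limit computations", {
  # no events: flat at 1
  km0 <- kaplan_meier(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(km0$surv == 1))
  # distinct event times, no censoring: S(t_i) = (n - i)/n
  km1 <- kaplan_meier(1:5, rep(1, 5))
  expect_equal(km1$surv, (5 - 1:5) / 5)
  # textbook 6-subject fixture with interleaved censoring
  time <- c(3, 5, 7, 9, 11, 14)
  event <- c(1, 0, 1, 0, 1, 0)
  km <- kaplan_meier(time, event)
  # hand: S(3) = 5/6; S(7) = 5/6 * 3/4; S(11) = 5/6 * 3/4 * 1/2
  expect_equal(km$surv[km$time == 3], 5 / 6)
  expect_equal(km$surv[km$time == 7], 5 / 6 * 3 / 4)
  expect_equal(km$surv[km$time == 11], 5 / 6 * 3 / 4 * 1 / 2)
})

test_that("log-rank matches the single-event closed form and the chi-square law", {
  # identical survival in both groups: statistic 0, p 1
  lr0 <- logrank_test(rep(c(1, 2, 3), 2), rep(c(1, 0, 1), 2),
                      rep(c("a", "b"), each = 3))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)
  # one death at t=1 with 2 vs 2 at risk, death in group a
  lr1 <- logrank_test(c(1, 5, 5, 5), c(1, 0, 0, 0), c("a", "a", "b", "b"))
  expect_equal(lr1$statistic, oracle_logrank_single(2, 2, TRUE),
               tolerance = 1e-12)
  # p is the chi-square(1) upper tail of the statistic
  expect_equal(lr1$p_value, pchisq(lr1$statistic, 1, lower.tail = FALSE))
  expect_error(logrank_test(1:3, c(1, 1, 1), c("a", "a", "a")), "two")
})

test_that("Wald tests agree with direct information-matrix algebra", {
  set.seed(31)
  n <- 200
  X <- cbind(hpc_0 = rnorm(n), hpc_1 = rnorm(n))
  lp <- 0.8 * X[, 1] - 0.5 * X[, 2]
  y <- rbinom(n, 1, plogis(lp))
  fit <- fit_logistic_en(X, y, alpha = 1e-9, l1_ratio = 0.5)
  w <- wald_pvalues(fit, X, y = y)
  # oracle: observed information of the unpenalized refit
  Xd <- cbind(1, X)
  b <- coef(suppressWarnings(glm(y ~ X, family = binomial())))
  p <- plogis(drop(Xd %*% b))
  info <- t(Xd) %*% (Xd * (p * (1 - p)))
  se_oracle <- sqrt(diag(solve(info)))[2:3]
  expect_equal(w$se, unname(se_oracle), tolerance = 1e-6)
  expect_equal(w$p_value, unname(2 * pnorm(-abs(b[2:3] / se_oracle))),
               tolerance = 1e-6)
  # p-values are symmetric in the sign of the coefficient
  fit_neg <- fit_logistic_en(-X, y, alpha = 1e-9, l1_ratio = 0.5)
  w_neg <- wald_pvalues(fit_neg, -X, y = y)
  expect_equal(w_neg$p_value, w$p_value, tolerance = 1e-9)
})

test_that("Fisher combination follows the chi-square tail", {
  expect_equal(fisher_combine(1), 1)
  expect_equal(fisher_combine(c(1, 1, 1)), 1)
  p <- 0.037
  expect_equal(fisher_combine(p), p, tolerance = 1e-12)  # chi-sq(2) identity
  expect_equal(fisher_combine(c(0.05, 0.05)),
               pchisq(-2 * (log(0.05) + log(0.05)), df = 4,
                      lower.tail = FALSE), tolerance = 1e-12)
  expect_error(fisher_combine(c(0.5, 0)), "0, 1")
})

test_that("risk stratification uses the train median and is translation-equivariant", {
  rg <- suppressWarnings(
    stratify_risk(c(1, 2, 3, 4), c(0.5, 2.5, 3.5), c(10, 5, 2), c(1, 1, 1)))
  expect_equal(rg$threshold, 2)  # lower-median convention for even n
  expect_equal(rg$groups$group, c("low", "high", "high"))
  rg2 <- suppressWarnings(
    stratify_risk(c(1, 2, 3, 4) + 7, c(0.5, 2.5, 3.5) + 7,
                  c(10, 5, 2), c(1, 1, 1)))
  expect_equal(rg2$threshold, rg$threshold + 7)
  expect_equal(rg2$groups$group, rg$groups$group)
  # degenerate split: warning, no log-rank
  expect_warning(
    rg3 <- stratify_risk(c(1, 2, 3), c(9, 9, 9), c(1, 2, 3), c(1, 1, 1)),
    "one side")
  expect_null(rg3$logrank)
})

test_that("null features shrink to zero; duplicated rows leave fits unchanged", {
  set.seed(17)
  n <- 400
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("hpc_", 0:5)))
  y <- rbinom(n, 1, 0.4)
  fit <- fit_logistic_en(X, y, alpha = 0.25, l1_ratio = 0.5)
  expect_lt(max(abs(fit$coefficients)), 0.05)
  dup <- fit_logistic_en(X[rep(1:n, 2), ], rep(y, 2), alpha = 0.25,
                         l1_ratio = 0.5)
  expect_equal(dup$coefficients, fit$coefficients, tolerance = 1e-6)
  expect_error(fit_logistic_en(X, rep(1, n)), "Both")
})

test_that("Cox partial likelihood is rank-invariant in time", {
  set.seed(18)
  n <- 150
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("hpc_", 0:3)))
  time <- rexp(n, 0.05)
  event <- rbinom(n, 1, 0.7)
  f1 <- fit_cox_en(X, time, event)
  f2 <- fit_cox_en(X, time + 100, event)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-9)
  expect_error(fit_cox_en(X, time, rep(0, n)), "event")
})

test_that("the planted outcome-linked cluster keeps its sign across folds", {
  co <- generate_cohort(synthetic_config(
    n_patients = c(NYU = 30, UCSF = 70, BWH = 40), seed = 29),
    render_tiles = FALSE)
  dat <- model_data(co)
  folds <- make_folds(patient_manifest(co$manifest), seed = 5)
  cv <- cross_validate(dat, folds, "logistic")
  # phenotype 1 carries the strongest planted log-hazard (+1.5): its
  # coefficient should be positive (toward poor outcome) in >= 2/3 folds
  signs <- cv$coefficients$estimate[cv$coefficients$term == "hpc_0"]
  expect_gte(sum(signs > 0), 2)
})

test_that("cross-validation reporting is an exact recomputation", {
  co <- generate_cohort(synthetic_config(
    n_patients = c(NYU = 20, UCSF = 50, BWH = 30), seed = 37),
    render_tiles = FALSE)
  dat <- model_data(co)
  folds <- make_folds(patient_manifest(co$manifest), seed = 6)
  cv <- cross_validate(dat, folds, "cox")
  # three folds, each with validation and test rows for both metrics
  counts <- dplyr::count(cv$metrics, metric, split)
  expect_true(all(counts$n[counts$metric %in% c("harrell_c", "uno_c")] == 3))
  # aggregated coefficients are the plain mean across folds
  manual <- cv$coefficients %>% dplyr::group_by(term) %>%
    dplyr::summarise(estimate = mean(estimate))
  expect_equal(cv$mean_coefficients, manual)
  # glance exposes one aggregated value per metric/split pair
  gl <- glance(cv)
  expect_equal(gl$test_harrell_c,
               mean(cv$metrics$value[cv$metrics$metric == "harrell_c" &
                                       cv$metrics$split == "test"]))
})
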