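# synthetic cohort generator: determinism, structure, survival model,
# procedural tile rendering

test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- small_cohort_config(seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_identical(a$tiles$pixels[[7]], b$tiles$pixels[[7]])
})

test_that("cohort structure follows the configuration", {
  cfg <- small_cohort_config(seed = 3)
  co <- generate_cohort(cfg, render_tiles = FALSE)
  pm <- patient_manifest(co$manifest)
  expect_equal(nrow(pm), sum(cfg$n_patients))
  counts <- dplyr::count(dplyr::distinct(co$manifest, patient_id, institution),
                         institution)
  expect_equal(setNames(counts$n, counts$institution)[names(cfg$n_patients)],
               setNames(as.integer(cfg$n_patients), names(cfg$n_patients)))
  # only the multi-slide institution may exceed one slide per patient
  multi <- pm$n_slides[pm$institution == cfg$multi_slide_institution]
  single <- pm$n_slides[pm$institution != cfg$multi_slide_institution]
  expect_true(all(single == 1))
  expect_true(all(multi >= 1 & multi <= 5))
  # tiles per slide within range
  per_slide <- dplyr::count(co$tiles, slide_id)
  expect_true(all(per_slide$n >= cfg$tiles_per_slide[1] &
                    per_slide$n <= cfg$tiles_per_slide[2]))
  # event implies poor outcome; compositions are probability vectors
  expect_true(all(co$manifest$outcome[co$manifest$event == 1] == "poor"))
  comp <- as.matrix(co$ground_truth$patient_composition[, -1])
  expect_true(all(abs(rowSums(comp) - 1) < 1e-9))
  expect_equal(nrow(validate_manifest(co$manifest)), 0)
})

test_that("artifact_fraction = 0 yields no artifact tiles", {
  co <- generate_cohort(small_cohort_config(artifact_fraction = 0),
                        render_tiles = FALSE)
  expect_false(any(co$ground_truth$tile_phenotype$is_artifact))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_patients = c(NYU = 0, UCSF = 2, BWH = 2)),
               "positive")
  expect_error(synthetic_config(artifact_fraction = 1), "artifact_fraction")
  expect_error(synthetic_config(slides_per_patient = list(
    NYU = c(1L, 5L), UCSF = c(1L, 2L), BWH = c(1L, 1L))),
    "Exactly one institution")
  expect_error(sample_survival(c(0.5, 0.5), c(0, 0), baseline_hazard = -1),
               "positive")
})

test_that("under a null hazard vector the true hazard carries no information", {
  # 500 patients, beta = 0: concordance of the (constant) hazard against the
  # generated times is exactly the tie value 1/2
  set.seed(21)
  comp <- matrix(rgamma(500 * 8, 1), 500, 8)
  comp <- comp / rowSums(comp)
  sv <- sample_survival(comp, rep(0, 8), baseline_hazard = 0.01,
                        censoring_rate = 0.008, admin_censor_time = 120)
  expect_lt(abs(harrell_c(sv$true_hazard, sv$dfs_months, sv$event) - 0.5),
            0.05)
  # and a strong vector is predictive of its own generated times
  sv2 <- sample_survival(comp, c(2, -2, 1, -1, 0, 0, 0, 0),
                         baseline_hazard = 0.01, censoring_rate = 0.008,
                         admin_censor_time = 120)
  expect_gt(harrell_c(sv2$true_hazard, sv2$dfs_months, sv2$event), 0.6)
})

test_that("survival sampler matches exponential closed forms", {
  set.seed(5)
  comp <- matrix(1 / 4, 10000, 4)
  lam <- 0.02
  sv <- sample_survival(comp, rep(0, 4), baseline_hazard = lam)
  expect_equal(median(sv$dfs_months), log(2) / lam, tolerance = 0.05)
  expect_true(all(sv$event == 1))  # no censoring configured
  # administrative horizon zero censors everything at zero
  sv0 <- sample_survival(comp[1:50, ], rep(0, 4), baseline_hazard = lam,
                         admin_censor_time = 0)
  expect_true(all(sv0$dfs_months == 0))
  expect_true(all(sv0$event == 0))
  # doubling the hazard (via the covariate) halves the median event time
  comp2 <- matrix(rep(c(0.4, 0.2, 0.2, 0.2), each = 10000), 10000, 4)
  beta <- c(log(2), 0, 0, 0) / (log(0.4) - mean(log(c(0.4, 0.2, 0.2, 0.2))))
  sv_hi <- sample_survival(comp2, beta, baseline_hazard = lam)
  expect_equal(median(sv_hi$dfs_months), log(2) / (2 * lam), tolerance = 0.05)
})

test_that("censoring fraction increases with the censoring rate", {
  set.seed(8)
  comp <- matrix(1 / 4, 4000, 4)
  frac <- vapply(c(0.002, 0.01, 0.05), function(cr) {
    mean(sample_survival(comp, rep(0, 4), 0.01, censoring_rate = cr,
                         admin_censor_time = 120)$event == 0)
  }, 0)
  expect_true(all(diff(frac) > 0))
})

test_that("patient compositions follow the configured Dirichlet", {
  cfg <- synthetic_config(n_patients = c(NYU = 40, UCSF = 120, BWH = 40),
                          dirichlet_concentration = c(4, 2, 1, 1, 1, 1, 1, 1),
                          seed = 13)
  co <- generate_cohort(cfg, render_tiles = FALSE)
  comp <- as.matrix(co$ground_truth$patient_composition[, -1])
  expect_equal(unname(colMeans(comp)), cfg$dirichlet_concentration /
                 sum(cfg$dirichlet_concentration), tolerance = 0.03)
})

test_that("tile rendering is deterministic and phenotype-specific", {
  expect_identical(render_tile_image(3, 64, seed = 42),
                   render_tile_image(3, 64, seed = 42))
  expect_error(render_tile_image(99, 64, seed = 1, n_phenotypes = 8),
               "Unknown phenotype")
  # artifacts are near-white yet not rejected by the background filter
  pp <- preprocess_config(tile_px = 64)
  for (s in c(1, 7, 19)) {
    art <- render_tile_image("artifact", 64, seed = s)
    expect_gte(mean_lum <- mean(0.299 * art[, , 1] + 0.587 * art[, , 2] +
                                  0.114 * art[, , 3]), 220 / 255)
    expect_lte(background_fraction(art, pp), pp$background_reject_threshold)
  }
})

test_that("an intensity-histogram classifier separates two rendered phenotypes", {
  set.seed(2)
  n <- 200
  feats <- function(ph) {
    t(vapply(seq_len(n), function(i) {
      px <- render_tile_image(ph, 64, seed = 1000 * ph + i)
      c(mean(px[, , 1]), mean(px[, , 2]), mean(px[, , 3]))
    }, numeric(3)))
  }
  X <- rbind(feats(1), feats(2))
  y <- rep(c(0, 1), each = n)
  train <- c(1:150, n + 1:150)
  g <- suppressWarnings(glm(y[train] ~ X[train, ], family = binomial()))
  pred <- cbind(1, X[-train, ]) %*% coef(g)
  acc <- mean((pred > 0) == y[-train])
  expect_gt(acc, 0.9)
})

test_that("the published preset arithmetic reproduces the cohort totals", {
  pre <- cohort_presets()
  res <- dplyr::filter(pre, preset == "results")
  expect_equal(sum(res$n_patients), 163)
  expect_equal(sum(res$n_good), 109)
  expect_equal(sum(res$n_poor), 54)
  expect_true(all(res$n_good + res$n_poor == res$n_patients))
  met <- dplyr::filter(pre, preset == "methods")
  expect_equal(met$n_good + met$n_poor, met$n_patients)
  expect_equal(met$n_patients, 163)
})
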