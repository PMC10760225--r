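# SHAP, forest summaries, Spearman enrichment, BH, adjacency interactions,
# heatmap export

test_that("linear SHAP equals exhaustive Shapley enumeration", {
  w <- c(0.7, -1.2, 0.4)
  b <- 0.3
  fit <- structure(list(coefficients = setNames(w, paste0("hpc_", 0:2)),
                        intercept = b, terms = paste0("hpc_", 0:2),
                        family = "logistic"),
                   class = "hpl_logistic_fit")
  x <- c(1.5, -0.5, 2)
  bg <- c(0.2, 0.1, -0.3)
  sh <- linear_shap(fit, matrix(x, 1, dimnames = list(NULL, fit$terms)), bg)
  phi <- as.numeric(sh$values[1, paste0("hpc_", 0:2)])
  expect_equal(phi, oracle_linear_shapley(w, x, bg), tolerance = 1e-12)
  # additivity: base + sum(phi) = w.x + b, exactly
  expect_equal(sh$base_value + sum(phi), sum(w * x) + b, tolerance = 1e-12)
  # x at the background: all contributions zero
  sh0 <- linear_shap(fit, matrix(bg, 1, dimnames = list(NULL, fit$terms)), bg)
  expect_equal(as.numeric(sh0$values[1, paste0("hpc_", 0:2)]), rep(0, 3))
})

test_that("SHAP additivity holds for every patient of a fitted cohort", {
  co <- generate_cohort(small_cohort_config(seed = 41), render_tiles = FALSE)
  dat <- model_data(co)
  feat <- grep("^hpc_", names(dat), value = TRUE)
  fit <- fit_cox_en(as.matrix(dat[feat]), dat$dfs_months, dat$event)
  bg <- colMeans(as.matrix(dat[feat]))
  sh <- linear_shap(fit, as.matrix(dat[feat]), bg)
  pred <- predict(fit, as.matrix(dat[feat]))
  recon <- sh$base_value + rowSums(as.matrix(sh$values[feat]))
  expect_equal(recon, pred, tolerance = 1e-9)
})

test_that("forest summary reduces to the single fold and counts presence", {
  co <- generate_cohort(small_cohort_config(seed = 43), render_tiles = FALSE)
  dat <- model_data(co)
  pm <- patient_manifest(co$manifest)
  folds <- make_folds(pm, seed = 2)
  cv <- cross_validate(dat, folds, "cox")
  comp <- patient_composition(truth_assignment(co), co$manifest)
  fs <- forest_summary(cv, comp)
  # mean log HR is the across-fold mean
  manual <- cv$coefficients %>% dplyr::group_by(term) %>%
    dplyr::summarise(m = mean(estimate))
  expect_equal(fs$mean_log_hr, manual$m[match(fs$term, manual$term)])
  # presence equals direct counting on the composition matrix
  m <- composition_matrix(comp)
  expect_equal(fs$presence_pct,
               unname(100 * colMeans(m[, fs$term] > 0)))
  # single fold: combined p equals that fold's Wald p
  cv1 <- cv
  cv1$coefficients <- dplyr::filter(cv$coefficients, fold == 0)
  cv1$wald <- dplyr::filter(cv$wald, fold == 0)
  fs1 <- forest_summary(cv1, comp)
  w0 <- dplyr::filter(cv$wald, fold == 0)
  expect_equal(fs1$combined_p, w0$p_value[match(fs1$term, w0$term)],
               tolerance = 1e-12)
  # fold order cannot matter
  cvr <- cv
  cvr$coefficients <- dplyr::arrange(cv$coefficients, dplyr::desc(fold))
  cvr$wald <- dplyr::arrange(cv$wald, dplyr::desc(fold))
  expect_equal(forest_summary(cvr, comp), fs)
})

test_that("Spearman enrichment matches the tie-corrected rank formula", {
  comp <- tibble::tibble(entity_id = sprintf("p%d", 1:6),
                         hpc_0 = c(0.05, 0.10, 0.10, 0.20, 0.25, 0.30),
                         hpc_1 = c(0.95, 0.90, 0.90, 0.80, 0.75, 0.70),
                         n_tiles = 100L)
  target <- c(0, 0, 1, 1, 2, 2)
  se <- spearman_enrichment(comp, target)
  expect_equal(se$rho[se$term == "hpc_0"],
               oracle_spearman(comp$hpc_0, target), tolerance = 1e-12)
  expect_equal(se$rho[se$term == "hpc_1"],
               oracle_spearman(comp$hpc_1, target), tolerance = 1e-12)
  # strictly monotone compositions: rho = +/- 1
  comp2 <- tibble::tibble(entity_id = sprintf("p%d", 1:5),
                          hpc_0 = 1:5 / 15, hpc_1 = (10 - 1:5) / 35,
                          n_tiles = 50L)
  se2 <- spearman_enrichment(comp2, 1:5)
  expect_equal(se2$rho, c(1, -1))
  # constant target: correlations undefined, reported missing
  se3 <- spearman_enrichment(comp, rep(1, 6))
  expect_true(all(is.na(se3$rho)))
})

test_that("BH adjustment is the step-up rule", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(12)
  p <- runif(40)^2
  q <- bh_adjust(p)
  expect_equal(q, oracle_bh(p), tolerance = 1e-12)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # order-preserving
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH at 1% controls the empirical false discovery rate", {
  # 200 all-null replicates with 26 clusters: any rejection is false, so the
  # empirical FDR is the fraction of replicates with at least one q < 0.01
  set.seed(77)
  fdp <- vapply(seq_len(200), function(i) {
    any(bh_adjust(runif(26)) < 0.01)
  }, TRUE)
  expect_lte(mean(fdp), 0.015)
})

test_that("adjacency interactions match exhaustive neighbour counting", {
  board <- checkerboard_assignment(10)
  M4 <- adjacency_interactions(board, neighborhood = 4)
  # checkerboard under 4-connectivity: every neighbour is the other cluster
  expect_equal(unname(M4), matrix(c(0, 1, 1, 0), 2, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(colSums(M4)), c(1, 1))
  # exhaustive oracle on the full 8-neighbourhood
  M8 <- adjacency_interactions(board, neighborhood = 8)
  tally <- matrix(0, 2, 2)
  lab <- function(r, c) (r + c) %% 2
  for (r in 0:9) for (c in 0:9) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 0 || rr > 9 || cc < 0 || cc > 9) next
      tally[lab(rr, cc) + 1, lab(r, c) + 1] <-
        tally[lab(rr, cc) + 1, lab(r, c) + 1] + 1
    }
  }
  expect_equal(unname(M8), sweep(tally, 2, colSums(tally), "/"),
               tolerance = 1e-12, ignore_attr = TRUE)
  # single-cluster slide: the column is one-hot on itself
  solo <- dplyr::mutate(board, hpc_id = 0L)
  expect_equal(unname(adjacency_interactions(solo)), matrix(1, 1, 1),
               ignore_attr = TRUE)
  # invariance to traversal order
  expect_equal(adjacency_interactions(board[sample(nrow(board)), ],
                                      neighborhood = 4), M4)
})

test_that("interaction heatmap ordering groups planted blocks", {
  blockA <- matrix(0.45, 3, 3) + diag(0.1, 3)
  M <- rbind(cbind(blockA, matrix(0.02, 3, 3)),
             cbind(matrix(0.02, 3, 3), blockA))
  rownames(M) <- colnames(M) <- paste0("h", 1:6)
  M <- sweep(M, 2, colSums(M), "/")
  ord <- cluster_interaction_heatmap(M)
  pos <- match(paste0("h", 1:6), ord$col_order)
  expect_true(max(pos[1:3]) < min(pos[4:6]) ||
                min(pos[1:3]) > max(pos[4:6]))
  # permuting rows and columns yields the same block partition
  perm <- c(4, 1, 6, 3, 2, 5)
  ord2 <- cluster_interaction_heatmap(M[perm, perm])
  runs <- rle(vapply(ord2$col_order,
                     function(h) as.integer(substring(h, 2)) > 3, TRUE))
  expect_equal(length(runs$lengths), 2)  # the two blocks stay contiguous
  # identical rows merge first
  M2 <- M
  M2["h2", ] <- M2["h1", ]
  ord3 <- cluster_interaction_heatmap(M2)
  first_merge <- ord3$row_hclust$merge[1, ]
  expect_setequal(rownames(M2)[-first_merge], c("h1", "h2"))
})

test_that("heatmap export matches compositions and decodes exactly", {
  board <- checkerboard_assignment(6)
  # drop one grid cell to emulate a rejected tile
  board <- board[-8, ]
  hm <- hpc_heatmap_export(board, "board", block_px = 4)
  comp <- slide_composition(board)
  expect_equal(hm$legend$pct,
               unname(100 * composition_matrix(comp)[1, paste0("hpc_", 0:1)]))
  # the dropped tile renders transparent
  missing_cell <- board_missing <- setdiff(
    sprintf("b_%d_%d", rep(0:5, each = 6), rep(0:5, 6)), board$tile_id)
  expect_length(missing_cell, 1)
  dec <- decode_heatmap(hm, block_px = 4)
  expect_equal(nrow(dec), nrow(board))
  merged <- dplyr::inner_join(dec, board, by = c("grid_row", "grid_col"))
  expect_equal(merged$hpc_id.x, merged$hpc_id.y)
})
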