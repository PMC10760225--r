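# kNN graph construction, Leiden clustering, artifact filtering, presence
# metrics and the resolution sweep

test_that("kNN graph geometry on hand-checked points", {
  X <- matrix(c(0, 0, 1, 0, 2, 0), 3, 2, byrow = TRUE)
  rownames(X) <- c("a", "b", "c")
  g <- build_knn_graph(X, k = 1, metric = "euclidean")
  deg <- igraph::degree(g)
  expect_equal(unname(deg[["b"]]), 2)  # middle point is everyone's neighbour
  expect_true(all(deg >= 1))
  # duplicated points are mutual nearest neighbours
  Y <- rbind(p1 = c(0, 0), p2 = c(0, 0), p3 = c(5, 5))
  g2 <- build_knn_graph(Y, k = 1, metric = "euclidean")
  expect_true(igraph::are_adjacent(g2, "p1", "p2"))
  # symmetry is structural: the graph is undirected
  expect_false(igraph::is_directed(g))
  expect_error(build_knn_graph(X, k = 3), "smaller")
})

test_that("Leiden recovers two well-separated blobs exactly", {
  skip_if_not_installed("mclust")
  lab <- rep(1:2, each = 150)
  Z <- synthetic_embeddings(lab, z_dim = 32, separation = 10, seed = 6)
  g <- build_knn_graph(Z, k = 10)
  asn <- leiden_cluster(g, resolution = 0.5, seed = 3)
  expect_equal(attr(asn, "n_clusters"), 2)
  expect_equal(mclust::adjustedRandIndex(asn$hpc_id, lab), 1)
  # partition: every point exactly once, ids contiguous from 0
  expect_equal(nrow(asn), 300)
  expect_equal(anyDuplicated(asn$tile_id), 0)
  expect_equal(sort(unique(asn$hpc_id)), 0:1)
})

test_that("Leiden is seed-reproducible and stable across seeds on clean data", {
  skip_if_not_installed("mclust")
  lab <- rep(1:3, each = 100)
  Z <- synthetic_embeddings(lab, z_dim = 16, separation = 10, seed = 1)
  g <- build_knn_graph(Z, k = 10)
  a1 <- leiden_cluster(g, resolution = 0.6, seed = 42)
  a2 <- leiden_cluster(g, resolution = 0.6, seed = 42)
  expect_identical(a1, a2)
  seeds <- c(1, 2, 3, 4, 5)
  parts <- lapply(seeds, function(s) leiden_cluster(g, 0.6, seed = s)$hpc_id)
  for (i in 1:4) for (j in (i + 1):5) {
    expect_gte(mclust::adjustedRandIndex(parts[[i]], parts[[j]]), 0.99)
  }
})

test_that("artifact filtering removes exactly the flagged clusters", {
  asn <- tibble::tibble(tile_id = sprintf("t%d", 1:10),
                        slide_id = "s",
                        hpc_id = c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L))
  expect_identical(filter_artifact_hpcs(asn, integer(0)), asn)
  out <- filter_artifact_hpcs(asn, 1L)
  expect_setequal(out$tile_id, asn$tile_id[asn$hpc_id != 1L])
  expect_equal(sort(unique(out$hpc_id)), 0:1)  # contiguous relabel
  expect_error(filter_artifact_hpcs(asn, 9L), "Unknown HPC")
})

test_that("artifact candidates rank near-white clusters first", {
  tiles <- tibble::tibble(
    tile_id = sprintf("t%d", 1:40),
    is_artifact = rep(c(TRUE, FALSE), c(10, 30)),
    pixels = c(purrr::map(1:10, ~render_tile_image("artifact", 32, seed = .x)),
               purrr::map(1:30, ~render_tile_image(1 + .x %% 3, 32, seed = .x))))
  asn <- tibble::tibble(tile_id = tiles$tile_id,
                        slide_id = "s",
                        hpc_id = rep(c(0L, 1L, 2L, 3L), each = 10))
  cand <- propose_artifact_clusters(asn, tiles)
  expect_equal(cand$hpc_id[1], 0L)
  expect_equal(cand$artifact_purity[1], 1)
  expect_gt(cand$mean_luminance[1], max(cand$mean_luminance[-1]))
})

test_that("presence metrics match exhaustive counting on a hand-built table", {
  # 3 patients, 2 clusters; patient p3 has only 1 of its 101 tiles in hpc 1
  asn <- tibble::tibble(
    tile_id = sprintf("t%d", 1:221),
    slide_id = c(rep("s1", 60), rep("s2", 60), rep("s3", 101)),
    hpc_id = c(rep(0L, 30), rep(1L, 30),      # p1: both clusters, 50/50
               rep(0L, 60),                   # p2: only cluster 0
               rep(0L, 100), 1L))             # p3: 1 tile of 101 in cluster 1
  manifest <- tibble::tibble(slide_id = c("s1", "s2", "s3"),
                             patient_id = c("p1", "p2", "p3"),
                             institution = c("A", "A", "B"))
  pm <- presence_metrics(asn, manifest)
  pat <- pm[pm$level == "patient", ]
  # any-tile: hpc0 3/3, hpc1 2/3 -> mean 5/6; 1% threshold: hpc1 loses p3
  # (1/101 < 1%) -> hpc0 3/3, hpc1 1/3 -> mean 2/3
  expect_equal(pat$presence_any, 100 * mean(c(1, 2 / 3)))
  expect_equal(pat$presence_1pct, 100 * mean(c(1, 1 / 3)))
  ins <- pm[pm$level == "institution", ]
  expect_equal(ins$presence_any, 100 * mean(c(1, 1)))
  # invariance to tile order and cluster relabelling
  perm <- sample(nrow(asn))
  pm2 <- presence_metrics(asn[perm, ], manifest)
  expect_equal(pm2$presence_any, pm$presence_any)
  relab <- dplyr::mutate(asn, hpc_id = 1L - hpc_id)
  pm3 <- presence_metrics(relab, manifest)
  expect_equal(pm3$presence_1pct, pm$presence_1pct)
})

test_that("degenerate presence cases hit their closed forms", {
  manifest <- tibble::tibble(slide_id = sprintf("s%d", 1:4),
                             patient_id = sprintf("p%d", 1:4),
                             institution = "A")
  one_cluster <- tibble::tibble(tile_id = sprintf("t%d", 1:8),
                                slide_id = rep(manifest$slide_id, each = 2),
                                hpc_id = 0L)
  pm <- presence_metrics(one_cluster, manifest)
  expect_equal(pm$presence_any, c(100, 100))
  expect_equal(pm$presence_1pct, c(100, 100))
  # each patient its own cluster: any-tile presence 100/N
  own <- dplyr::mutate(one_cluster, hpc_id = as.integer(rep(0:3, each = 2)))
  pm2 <- presence_metrics(own, manifest)
  expect_equal(pm2$presence_any[pm2$level == "patient"], 100 / 4)
})

test_that("resolution sweep finds the planted cluster count", {
  skip_if_not_installed("mclust")
  K <- 5
  lab <- rep(seq_len(K), each = 120)
  Z <- synthetic_embeddings(lab, z_dim = 32, separation = 8, seed = 9)
  emb <- dplyr::bind_cols(
    tibble::tibble(tile_id = sprintf("t%d", seq_along(lab)),
                   slide_id = sprintf("s%d", 1 + (seq_along(lab) %% 12))),
    tibble::as_tibble(`colnames<-`(Z, sprintf("z%03d", 1:32))))
  manifest <- tibble::tibble(slide_id = sprintf("s%d", 1:12),
                             patient_id = sprintf("p%d", 1:12),
                             institution = rep(c("A", "B", "C"), 4))
  sw <- resolution_sweep(emb, manifest, resolutions = c(0.3, 0.75, 1.5, 3, 6),
                         k = 15, seed = 2)
  expect_equal(nrow(sw), 5)
  expect_true(all(sw$patient_presence_1pct <= sw$patient_presence_any + 1e-9))
  expect_true(all(sw$institution_presence_1pct <=
                    sw$institution_presence_any + 1e-9))
  r_sel <- select_resolution(sw)
  n_sel <- sw$n_clusters[sw$resolution == r_sel]
  expect_lte(abs(n_sel - K), 2)
  asn <- cluster_tiles(emb, resolution = r_sel, k = 15, seed = 3)
  expect_gt(mclust::adjustedRandIndex(asn$hpc_id, lab), 0.9)
  # single-value grid yields a single record
  sw1 <- resolution_sweep(emb, manifest, resolutions = 0.75, k = 15, seed = 2)
  expect_equal(nrow(sw1), 1)
})
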