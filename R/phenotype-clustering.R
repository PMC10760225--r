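# Phenotype clustering: kNN graph over tile embeddings, Leiden community
# detection (including the high-resolution artifact over-clustering pass),
# artifact filtering, and the presence metrics used to choose a resolution.

#' Build a k-nearest-neighbour graph over embeddings
#'
#' Each tile is linked to its `k` nearest neighbours (cosine distance by
#' default — embeddings are direction-coded); the union of directed kNN links
#' is returned as a simple undirected graph.
#'
#' @param embeddings Embedding tibble (see [embed_tiles()]) or numeric matrix.
#' @param k Number of neighbours; must satisfy `k < n`.
#' @param metric `"cosine"` or `"euclidean"`.
#' @return An undirected `igraph` graph with `tile_id` vertex names.
#' @export
build_knn_graph <- function(embeddings, k = 50L, metric = c("cosine",
                                                            "euclidean")) {
  metric <- match.arg(metric)
  X <- embedding_matrix(embeddings)
  n <- nrow(X)
  if (k < 1) abort("`k` must be at least 1.")
  if (k >= n) abort(sprintf("k (%d) must be smaller than the number of points (%d).",
                            k, n))
  if (is.null(rownames(X))) rownames(X) <- sprintf("pt_%d", seq_len(n))
  if (metric == "cosine") {
    nrm <- sqrt(rowSums(X^2))
    nrm[nrm == 0] <- 1
    X <- X / nrm
  }
  # chunked exact neighbour search: distances to all points, top-k per row
  chunk <- max(1L, floor(2e7 / n))
  sq <- rowSums(X^2)
  edges <- vector("list", ceiling(n / chunk))
  ci <- 0L
  for (start in seq(1L, n, by = chunk)) {
    ix <- start:min(start + chunk - 1L, n)
    G <- X[ix, , drop = FALSE] %*% t(X)
    D <- outer(sq[ix], sq, "+") - 2 * G  # squared euclidean
    D[cbind(seq_along(ix), ix)] <- Inf
    nb <- matrix(apply(D, 1, function(d) order(d)[seq_len(k)]), nrow = k)
    ci <- ci + 1L
    edges[[ci]] <- cbind(rep(ix, each = k), as.integer(nb))
  }
  em <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- rownames(X)
  g
}

#' Leiden community detection at a given resolution
#'
#' Partitions the graph by the resolution-parameterized modularity objective.
#' Cluster ids are 0-based and contiguous, relabelled by decreasing cluster
#' size; isolated vertices become singleton clusters. Reproducible for a fixed
#' seed.
#'
#' @param graph Undirected `igraph` graph from [build_knn_graph()].
#' @param resolution Positive Leiden resolution.
#' @param seed Integer seed.
#' @param n_iterations Leiden refinement iterations.
#' @return Tibble `tile_id`, `hpc_id` with attributes `resolution` and
#'   `n_clusters`.
#' @export
leiden_cluster <- function(graph, resolution = 0.75, seed = 1L,
                           n_iterations = 5L) {
  if (igraph::vcount(graph) == 0) abort("Empty graph.")
  if (resolution <= 0) abort("`resolution` must be positive.")
  memb <- with_seed(seed, {
    igraph::membership(igraph::cluster_leiden(
      graph, objective_function = "modularity",
      resolution = resolution, n_iterations = n_iterations))
  })
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  out <- tibble(tile_id = igraph::V(graph)$name,
                hpc_id = as.integer(relabel[as.character(memb)]))
  attr(out, "resolution") <- resolution
  attr(out, "n_clusters") <- length(sizes)
  out
}

#' Cluster tile embeddings end to end
#'
#' Convenience wrapper: kNN graph + Leiden, carrying slide and grid metadata
#' from the embedding table into the assignment.
#'
#' @inheritParams build_knn_graph
#' @inheritParams leiden_cluster
#' @return Assignment tibble with `tile_id`, `hpc_id` and any of `slide_id`,
#'   `grid_row`, `grid_col` present in `embeddings`.
#' @export
cluster_tiles <- function(embeddings, resolution = 0.75, k = 50L,
                          metric = "cosine", seed = 1L) {
  g <- build_knn_graph(embeddings, k = k, metric = metric)
  asn <- leiden_cluster(g, resolution = resolution, seed = seed)
  if (is.data.frame(embeddings)) {
    meta_cols <- intersect(c("tile_id", "slide_id", "grid_row", "grid_col",
                             "phenotype", "is_artifact"), names(embeddings))
    if ("tile_id" %in% meta_cols) {
      res <- attr(asn, "resolution"); ncl <- attr(asn, "n_clusters")
      asn <- left_join(asn, embeddings[meta_cols], by = "tile_id")
      attr(asn, "resolution") <- res
      attr(asn, "n_clusters") <- ncl
    }
  }
  asn
}

#' Remove artifact clusters from an assignment
#'
#' Drops all tiles assigned to the listed clusters (identified on the
#' over-clustering pass) and relabels the remaining clusters contiguously by
#' size. The retained tiles are the input to the second, final clustering
#' pass.
#'
#' @param assignment Assignment tibble from [leiden_cluster()] /
#'   [cluster_tiles()].
#' @param artifact_hpc_ids Integer cluster ids to remove; must all exist.
#' @return The filtered, relabelled assignment tibble.
#' @export
filter_artifact_hpcs <- function(assignment, artifact_hpc_ids) {
  if (!length(artifact_hpc_ids)) return(assignment)
  unknown <- setdiff(artifact_hpc_ids, unique(assignment$hpc_id))
  if (length(unknown)) {
    abort(paste0("Unknown HPC id(s): ", paste(unknown, collapse = ", ")))
  }
  out <- filter(assignment, !hpc_id %in% artifact_hpc_ids)
  sizes <- sort(table(out$hpc_id), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes) - 1L, names(sizes))
  out$hpc_id <- as.integer(relabel[as.character(out$hpc_id)])
  attr(out, "resolution") <- attr(assignment, "resolution")
  attr(out, "n_clusters") <- length(sizes)
  out
}

#' Rank clusters as artifact candidates
#'
#' Artifact identification is a visual call at production scale; this helper
#' ranks clusters by mean tile luminance (artifact tiles are near-white) and,
#' when ground-truth flags are available, reports artifact purity.
#'
#' @param assignment Assignment tibble.
#' @param tiles Tile table with `tile_id` and `pixels` and/or `is_artifact`.
#' @return Tibble `hpc_id`, `n_tiles`, `mean_luminance` (when pixels exist),
#'   `artifact_purity` (when ground truth exists), sorted most-suspect first.
#' @export
propose_artifact_clusters <- function(assignment, tiles) {
  joined <- left_join(assignment, tiles, by = "tile_id",
                      suffix = c("", ".tile"))
  per <- joined %>% group_by(hpc_id) %>%
    summarise(n_tiles = n(),
              mean_luminance = if ("pixels" %in% names(joined) &&
                                   !all(vapply(pixels, is.null, TRUE))) {
                mean(vapply(pixels, mean_luminance, 0))
              } else NA_real_,
              artifact_purity = if ("is_artifact" %in% names(joined)) {
                mean(is_artifact)
              } else NA_real_,
              .groups = "drop")
  arrange(per, dplyr::desc(dplyr::coalesce(artifact_purity, -Inf)),
          dplyr::desc(dplyr::coalesce(mean_luminance, -Inf)))
}

#' Patient and institution presence metrics
#'
#' For each cluster, the percentage of patients (institutions) having at least
#' one tile in it, and having at least 1% of their own tiles in it; both are
#' averaged over clusters. Declining presence as resolution grows signals
#' patient- or institution-specific clusters (overfitting).
#'
#' @param assignment Assignment tibble carrying `slide_id`.
#' @param manifest Per-slide manifest mapping `slide_id` to `patient_id` and
#'   `institution`.
#' @param level `"patient"`, `"institution"`, or both (default).
#' @return Tibble with one row per level: `level`, `presence_any`,
#'   `presence_1pct` (percent), `n_clusters`, `resolution`.
#' @export
presence_metrics <- function(assignment, manifest,
                             level = c("patient", "institution")) {
  level <- match.arg(level, several.ok = TRUE)
  joined <- left_join(assignment,
                      distinct(manifest, slide_id, patient_id, institution),
                      by = "slide_id")
  if (anyNA(joined$patient_id)) {
    abort("Every tile must map to a patient via the manifest.")
  }
  n_clusters <- dplyr::n_distinct(joined$hpc_id)
  one <- function(entity_col) {
    ent <- joined %>%
      group_by(entity_id = .data[[entity_col]]) %>%
      mutate(ent_total = n()) %>%
      group_by(entity_id, hpc_id, ent_total) %>%
      summarise(k = n(), .groups = "drop")
    n_entities <- dplyr::n_distinct(joined[[entity_col]])
    per_hpc <- ent %>% group_by(hpc_id) %>%
      summarise(any_pct = 100 * n() / n_entities,
                thr_pct = 100 * sum(k / ent_total >= 0.01) / n_entities,
                .groups = "drop")
    # clusters with no tiles cannot occur (ids come from the assignment)
    tibble(level = sub("_id$", "", entity_col),
           presence_any = mean(per_hpc$any_pct),
           presence_1pct = mean(per_hpc$thr_pct))
  }
  cols <- c(patient = "patient_id", institution = "institution")[level]
  out <- bind_rows(lapply(cols, one))
  out$n_clusters <- n_clusters
  out$resolution <- attr(assignment, "resolution") %||% NA_real_
  out
}

#' Sweep Leiden resolutions and score each
#'
#' Builds the kNN graph once, clusters at every resolution in the grid, and
#' reports cluster counts plus presence metrics. Resolutions whose
#' 1%-threshold patient presence has declined from the grid maximum are
#' flagged (the overfitting signal used to freeze a resolution).
#'
#' @param embeddings Embedding tibble or matrix (must carry `slide_id` for
#'   presence metrics).
#' @param manifest Per-slide manifest.
#' @param resolutions Numeric grid of resolutions.
#' @param k,metric kNN graph parameters.
#' @param seed Integer seed.
#' @return Tibble with one row per resolution: `resolution`, `n_clusters`,
#'   presence columns per level, and `declined`.
#' @export
resolution_sweep <- function(embeddings, manifest,
                             resolutions = c(0.25, 0.5, 0.75, 1, 1.5, 2, 4, 7),
                             k = 50L, metric = "cosine", seed = 1L) {
  stopifnot(length(resolutions) >= 1, all(resolutions > 0))
  g <- build_knn_graph(embeddings, k = k, metric = metric)
  meta <- embeddings[intersect(c("tile_id", "slide_id"), names(embeddings))]
  rows <- lapply(resolutions, function(r) {
    asn <- leiden_cluster(g, resolution = r,
                          seed = substream_seed(seed, "sweep", r))
    asn <- left_join(asn, meta, by = "tile_id")
    attr(asn, "resolution") <- r
    pm <- presence_metrics(asn, manifest)
    wide <- tidyr::pivot_wider(
      pm, id_cols = c(resolution, n_clusters), names_from = level,
      values_from = c(presence_any, presence_1pct), names_glue = "{level}_{.value}")
    wide
  })
  out <- bind_rows(rows)
  out$declined <- out$patient_presence_1pct <
    max(out$patient_presence_1pct) - 1e-9
  out
}

#' Select the working resolution from a sweep
#'
#' Picks the largest resolution whose 1%-threshold patient presence is within
#' `slack` percentage points of the sweep maximum — i.e. the finest clustering
#' before presence starts to decline.
#'
#' @param sweep Output of [resolution_sweep()].
#' @param slack Allowed drop in percentage points (default 5).
#' @return The selected resolution (numeric scalar).
#' @export
select_resolution <- function(sweep, slack = 5) {
  ok <- sweep$patient_presence_1pct >= max(sweep$patient_presence_1pct) - slack
  max(sweep$resolution[ok])
}
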