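# Interpretation outputs: exact SHAP values for the linear models, forest-plot
# summaries across folds, Spearman enrichment with BH correction, the
# tile-adjacency interaction matrix, and cluster heatmap exports.

#' Exact SHAP values for a linear model
#'
#' For a linear predictor `w . x + b` the Shapley value of feature `k`
#' relative to a background point is exactly `w_k * (x_k - background_k)`;
#' additivity (`base + sum(phi) = prediction`) holds to machine precision.
#' The background defaults to the per-fold training-set feature means.
#'
#' @param fit An `hpl_logistic_fit` or `hpl_cox_fit`.
#' @param X Feature matrix or CLR tibble to explain.
#' @param background Numeric vector of background feature values (training
#'   means), or a matrix/tibble whose column means are used.
#' @return A list of class `hpl_shap`: `values` (entities x features tibble),
#'   `base_value`, `family`.
#' @export
linear_shap <- function(fit, X, background) {
  Xm <- glmnet_xy(X)[, fit$terms, drop = FALSE]
  bg <- if (is.numeric(background) && is.null(dim(background))) {
    background
  } else {
    colMeans(glmnet_xy(background)[, fit$terms, drop = FALSE])
  }
  if (length(bg) != length(fit$terms)) {
    abort("Background dimension does not match the model terms.")
  }
  phi <- sweep(Xm, 2, bg) %*% diag(fit$coefficients, length(fit$coefficients))
  colnames(phi) <- fit$terms
  values <- as_tibble(phi)
  if (is.data.frame(X) && "entity_id" %in% names(X)) {
    values <- bind_cols(tibble(entity_id = X$entity_id), values)
  } else if (!is.null(rownames(Xm))) {
    values <- bind_cols(tibble(entity_id = rownames(Xm)), values)
  }
  structure(list(values = values,
                 base_value = sum(fit$coefficients * bg) + fit$intercept,
                 family = fit$family),
            class = "hpl_shap")
}

#' @export
print.hpl_shap <- function(x, ...) {
  cat(sprintf("<hpl_shap> %d entities x %d features, base value %.4f (%s)\n",
              nrow(x$values), sum(grepl("^hpc_", names(x$values))),
              x$base_value, x$family))
  invisible(x)
}

#' Forest-plot summary of cross-validated Cox fits
#'
#' Per cluster: the mean log hazard ratio across folds, the Fisher-combined
#' Wald p-value, and the percentage of patients with at least one tile in the
#' cluster.
#'
#' @param cv An `hpl_cv` object (Cox family) from [cross_validate()].
#' @param composition Patient composition tibble (raw proportions) used for
#'   the presence percentages.
#' @return Tibble `term`, `mean_log_hr`, `combined_p`, `presence_pct`.
#' @export
forest_summary <- function(cv, composition) {
  stopifnot(inherits(cv, "hpl_cv"))
  mean_cf <- cv$coefficients %>% group_by(term) %>%
    summarise(mean_log_hr = mean(estimate), .groups = "drop")
  comb <- cv$wald %>% group_by(term) %>%
    summarise(combined_p = fisher_combine(p_value), .groups = "drop")
  m <- composition_matrix(composition)
  pres <- tibble(term = colnames(m),
                 presence_pct = unname(100 * colMeans(m > 0)))
  mean_cf %>% left_join(comb, by = "term") %>% left_join(pres, by = "term")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control: `q_(i) = min_{j >= i} m p_(j) / j`,
#' capped at 1; order-preserving and never below the raw p-value.
#'
#' @param pvalues Numeric vector in `[0, 1]` (`NA` passed through).
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

#' Spearman enrichment of clusters against a label
#'
#' Per-cluster Spearman rank correlation between composition (raw proportions
#' by default) and a binary or ordinal target (e.g. whole-slide diagnosis, or
#' local recurrence vs overall metastasis — nodal and distant metastases
#' grouped together), with BH-adjusted q-values. A constant target yields
#' `NA` correlations.
#'
#' @param composition Composition tibble (`entity_id`, `hpc_*`).
#' @param target Named or positional vector aligned with `composition` rows;
#'   ordered factors are ranked by level.
#' @param use_clr Correlate CLR values instead of raw proportions.
#' @return Tibble `term`, `rho`, `p_value`, `q_value`.
#' @export
spearman_enrichment <- function(composition, target, use_clr = FALSE) {
  if (nrow(composition) < 3) abort("Need at least 3 entities.")
  x <- if (use_clr) clr_transform(composition) else composition
  m <- composition_matrix(x)
  tv <- if (is.factor(target)) as.integer(target) else as.numeric(target)
  if (length(tv) != nrow(m)) abort("`target` must align with composition rows.")
  res <- purrr::map(colnames(m), function(cl) {
    if (length(unique(tv[!is.na(tv)])) < 2 || sd(m[, cl]) == 0) {
      return(tibble(term = cl, rho = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(cor.test(m[, cl], tv, method = "spearman",
                                    exact = FALSE))
    tibble(term = cl, rho = unname(ct$estimate), p_value = ct$p.value)
  })
  out <- bind_rows(res)
  out$q_value <- bh_adjust(out$p_value)
  out
}

#' Tile-adjacency interaction matrix
#'
#' For every kept tile, the cluster labels of its existing grid neighbours
#' (8-connectivity by default) are tallied; tallies are aggregated per focal
#' cluster and column-normalized, so entry `(j, k)` is the proportion of
#' neighbours of cluster-`k` tiles that belong to cluster `j`. Same-cluster
#' neighbours are counted (the diagonal is retained) unless
#' `include_self = FALSE`.
#'
#' @param assignment Assignment tibble with `slide_id`, `grid_row`,
#'   `grid_col`, `hpc_id`.
#' @param neighborhood 8 (default) or 4 connectivity.
#' @param include_self Keep same-cluster interactions before normalizing.
#' @return `K x K` matrix (rows = neighbour cluster, columns = focal cluster);
#'   observed columns sum to 1, unobserved columns are `NA` and flagged in the
#'   `missing_hpcs` attribute.
#' @export
adjacency_interactions <- function(assignment, neighborhood = 8,
                                   include_self = TRUE) {
  stopifnot(neighborhood %in% c(4, 8))
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (neighborhood == 8) {
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  ids <- sort(unique(assignment$hpc_id))
  K <- length(ids)
  tally <- matrix(0, K, K, dimnames = list(ids, ids))
  key <- paste(assignment$slide_id, assignment$grid_row, assignment$grid_col,
               sep = "|")
  label <- setNames(assignment$hpc_id, key)
  for (off in offs) {
    nk <- paste(assignment$slide_id, assignment$grid_row + off[1],
                assignment$grid_col + off[2], sep = "|")
    hit <- nk %in% names(label)
    if (!any(hit)) next
    focal <- as.character(assignment$hpc_id[hit])
    nb <- as.character(label[nk[hit]])
    tt <- table(factor(nb, levels = ids), factor(focal, levels = ids))
    tally <- tally + as.matrix(tt)
  }
  if (!include_self) diag(tally) <- 0
  if (sum(tally) == 0) abort("No adjacent tile pairs found.")
  cs <- colSums(tally)
  out <- sweep(tally, 2, ifelse(cs > 0, cs, NA_real_), "/")
  attr(out, "missing_hpcs") <- ids[cs == 0]
  attr(out, "neighborhood") <- neighborhood
  out
}

#' Bi-hierarchical ordering of an interaction matrix
#'
#' Agglomerative clustering (correlation distance, average linkage) of rows
#' and columns, as in interaction heatmaps with marginal dendrograms.
#'
#' @param mat Numeric matrix (`K >= 2`); `NA` columns are dropped first.
#' @return List `matrix` (reordered), `row_order`, `col_order`, `row_hclust`,
#'   `col_hclust`.
#' @export
cluster_interaction_heatmap <- function(mat) {
  keep <- colSums(is.na(mat)) == 0
  m <- mat[, keep, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) abort("Need at least a 2x2 matrix.")
  cor_dist <- function(x) {
    cc <- suppressWarnings(stats::cor(t(x)))
    cc[!is.finite(cc)] <- 0
    as.dist(1 - cc)
  }
  rh <- hclust(cor_dist(m), method = "average")
  ch <- hclust(cor_dist(t(m)), method = "average")
  list(matrix = m[rh$order, ch$order, drop = FALSE],
       row_order = rownames(m)[rh$order],
       col_order = colnames(m)[ch$order],
       row_hclust = rh, col_hclust = ch)
}

#' Export a cluster heatmap of one slide
#'
#' Renders one colour block per tile (rejected/missing grid positions stay
#' blank) and a legend listing per-cluster tile percentages; colours index
#' clusters, so the assignment can be decoded back from the image.
#'
#' @param assignment Assignment tibble with grid coordinates.
#' @param slide One slide id present in the assignment.
#' @param block_px Pixel size of each tile block.
#' @param path Optional PNG output path.
#' @return A list of class `hpl_heatmap`: `image` (RGBA array), `legend`
#'   (tibble `hpc_id`, `colour`, `pct`), `palette` (named colours),
#'   `grid` (tibble of blocks).
#' @export
hpc_heatmap_export <- function(assignment, slide, block_px = 8L, path = NULL) {
  tiles <- filter(assignment, slide_id == slide)
  if (!nrow(tiles)) abort(sprintf("Slide %s has no kept tiles.", slide))
  ids <- sort(unique(assignment$hpc_id))
  pal <- setNames(hpc_palette(length(ids)), ids)
  comp <- slide_composition(tiles, hpc_ids = ids)
  props <- composition_matrix(comp)[1, ]
  legend <- tibble(hpc_id = ids, colour = unname(pal),
                   pct = unname(100 * props[paste0("hpc_", ids)]))
  nr <- max(tiles$grid_row) + 1L
  nc <- max(tiles$grid_col) + 1L
  img <- array(0, dim = c(nr * block_px, nc * block_px, 4))  # transparent
  for (i in seq_len(nrow(tiles))) {
    rgb <- as.numeric(grDevices::col2rgb(pal[as.character(tiles$hpc_id[i])])) / 255
    rr <- tiles$grid_row[i] * block_px + seq_len(block_px)
    cc <- tiles$grid_col[i] * block_px + seq_len(block_px)
    for (ch in 1:3) img[rr, cc, ch] <- rgb[ch]
    img[rr, cc, 4] <- 1
  }
  if (!is.null(path)) png::writePNG(img, path)
  structure(list(image = img, legend = legend, palette = pal,
                 slide_id = slide,
                 grid = select(tiles, tile_id, grid_row, grid_col, hpc_id)),
            class = "hpl_heatmap")
}

#' Decode a cluster heatmap image back to tile assignments
#'
#' @param heatmap An `hpl_heatmap` (or its `image`) plus the palette used.
#' @param block_px Block size used at export.
#' @return Tibble `grid_row`, `grid_col`, `hpc_id` for opaque blocks.
#' @export
decode_heatmap <- function(heatmap, block_px = 8L) {
  img <- if (inherits(heatmap, "hpl_heatmap")) heatmap$image else heatmap
  pal <- if (inherits(heatmap, "hpl_heatmap")) heatmap$palette else
    abort("Pass an `hpl_heatmap` to decode.")
  pal_rgb <- sapply(pal, function(cl) as.numeric(grDevices::col2rgb(cl)) / 255)
  nr <- dim(img)[1] / block_px
  nc <- dim(img)[2] / block_px
  rows <- list()
  for (r in seq_len(nr) - 1L) {
    for (cl in seq_len(nc) - 1L) {
      px <- img[r * block_px + 1L, cl * block_px + 1L, ]
      if (px[4] == 0) next
      d <- colSums((pal_rgb - px[1:3])^2)
      rows[[length(rows) + 1]] <- tibble(
        grid_row = r, grid_col = cl,
        hpc_id = as.integer(names(pal)[which.min(d)]))
    }
  }
  bind_rows(rows)
}
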