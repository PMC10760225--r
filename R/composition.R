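# Compositional representation: per-slide and per-patient fractions of tiles
# in each phenotype cluster, and the centred log-ratio transform feeding all
# linear models.

# count tiles per (entity, hpc) and normalize rows; K fixed by the assignment
composition_from_counts <- function(counts, entities, K_ids) {
  wide <- tidyr::pivot_wider(counts, id_cols = entity_id, names_from = hpc_id,
                             values_from = k, values_fill = 0,
                             names_prefix = "hpc_")
  # entities missing entirely would have zero tiles; caller guards against it
  for (id in K_ids) {
    col <- paste0("hpc_", id)
    if (!col %in% names(wide)) wide[[col]] <- 0
  }
  cols <- paste0("hpc_", K_ids)
  wide <- wide[c("entity_id", cols)]
  m <- as.matrix(wide[cols])
  n_tiles <- rowSums(m)
  wide[cols] <- m / n_tiles
  wide$n_tiles <- as.integer(n_tiles)
  as_tibble(wide)
}

#' Slide composition vectors
#'
#' The fraction of a slide's kept tiles falling in each phenotype cluster.
#' The cluster set `K` is fixed by the assignment (or by `hpc_ids`); clusters
#' absent from a slide contribute structural zeros.
#'
#' @param assignment Assignment tibble with `tile_id`, `slide_id`, `hpc_id`.
#' @param hpc_ids Optional integer vector fixing the cluster universe.
#' @return Tibble: `entity_id` (slide), one `hpc_<id>` proportion column per
#'   cluster (rows sum to 1), and `n_tiles`.
#' @export
slide_composition <- function(assignment, hpc_ids = NULL) {
  if (!nrow(assignment)) abort("Assignment has no tiles.")
  K_ids <- sort(unique(c(assignment$hpc_id, hpc_ids)))
  counts <- assignment %>% group_by(entity_id = slide_id, hpc_id) %>%
    summarise(k = n(), .groups = "drop")
  composition_from_counts(counts, unique(assignment$slide_id), K_ids)
}

#' Patient composition vectors
#'
#' Tile counts are pooled across all of a patient's slides and then normalized
#' (tile-pooling: a slide with three times the tiles weighs three times as
#' much). Slide-averaging is available for sensitivity analyses.
#'
#' @param assignment Assignment tibble with `slide_id` and `hpc_id`.
#' @param manifest Per-slide manifest mapping `slide_id` to `patient_id`.
#' @param hpc_ids Optional integer vector fixing the cluster universe.
#' @param method `"pool"` (default) or `"average"` (mean of per-slide
#'   compositions).
#' @return Tibble as in [slide_composition()] with `entity_id` = patient.
#' @export
patient_composition <- function(assignment, manifest, hpc_ids = NULL,
                                method = c("pool", "average")) {
  method <- match.arg(method)
  joined <- left_join(assignment, distinct(manifest, slide_id, patient_id),
                      by = "slide_id")
  if (anyNA(joined$patient_id)) abort("Every slide must map to a patient.")
  K_ids <- sort(unique(c(assignment$hpc_id, hpc_ids)))
  if (method == "pool") {
    counts <- joined %>% group_by(entity_id = patient_id, hpc_id) %>%
      summarise(k = n(), .groups = "drop")
    return(composition_from_counts(counts, unique(joined$patient_id), K_ids))
  }
  slides <- slide_composition(assignment, hpc_ids = K_ids)
  slides <- left_join(slides,
                      distinct(manifest, entity_id = slide_id, patient_id),
                      by = "entity_id")
  cols <- grep("^hpc_", names(slides), value = TRUE)
  out <- slides %>% group_by(entity_id = patient_id) %>%
    summarise(dplyr::across(dplyr::all_of(cols), mean),
              n_tiles = as.integer(sum(n_tiles)), .groups = "drop")
  out
}

#' Centred log-ratio transform
#'
#' `clr_k = log(x'_k) - mean_j log(x'_j)` where `x'` is the composition after
#' adding `pseudocount` and renormalizing. Output rows sum to zero; the
#' transform is invariant to rescaling of the input.
#'
#' @param composition Composition tibble from [slide_composition()] /
#'   [patient_composition()] (columns `hpc_*`, `n_tiles`), or a bare numeric
#'   matrix/vector of proportions.
#' @param pseudocount Additive pseudocount in proportion units. The default
#'   `NULL` uses one tile-count per cluster, i.e. `1 / n_tiles` per entity
#'   (requires the `n_tiles` column); pass `0` for the raw transform (errors
#'   if any proportion is zero).
#' @return Same shape as the input with `hpc_*` columns replaced by CLR
#'   values (matrix in, matrix out).
#' @export
clr_transform <- function(composition, pseudocount = NULL) {
  bare <- !is.data.frame(composition)
  if (bare) {
    m <- if (is.matrix(composition)) composition else matrix(composition, 1)
    pc <- rep(pseudocount %||% 0, nrow(m))
  } else {
    cols <- grep("^hpc_", names(composition), value = TRUE)
    if (length(cols) < 2) abort("CLR needs at least 2 components.")
    m <- as.matrix(composition[cols])
    pc <- if (is.null(pseudocount)) {
      if (!"n_tiles" %in% names(composition)) {
        abort("Default pseudocount needs an `n_tiles` column; pass `pseudocount` explicitly.")
      }
      1 / composition$n_tiles
    } else {
      rep(pseudocount, nrow(m))
    }
  }
  if (ncol(m) < 2) abort("CLR needs at least 2 components.")
  if (any(pc < 0)) abort("`pseudocount` must be non-negative.")
  if (any(pc == 0 & apply(m, 1, function(r) any(r == 0)))) {
    abort("Zero proportions require a positive pseudocount.")
  }
  shifted <- m + pc
  shifted <- shifted / rowSums(shifted)
  lx <- log(shifted)
  clr <- lx - rowMeans(lx)
  if (bare) {
    return(if (is.matrix(composition)) clr else drop(clr))
  }
  out <- composition
  out[grep("^hpc_", names(out), value = TRUE)] <- clr
  attr(out, "pseudocount") <- pc
  out
}

#' Invert a CLR vector back to the simplex
#'
#' Softmax of the CLR values; recovers the (pseudocounted) composition.
#'
#' @param clr Numeric vector/matrix of CLR values, or a tibble with `hpc_*`
#'   columns.
#' @return Proportions of the same shape, rows summing to 1.
#' @export
clr_inverse <- function(clr) {
  if (is.data.frame(clr)) {
    cols <- grep("^hpc_", names(clr), value = TRUE)
    m <- as.matrix(clr[cols])
    e <- exp(m)
    out <- clr
    out[cols] <- e / rowSums(e)
    return(out)
  }
  m <- if (is.matrix(clr)) clr else matrix(clr, 1)
  e <- exp(m)
  res <- e / rowSums(e)
  if (is.matrix(clr)) res else drop(res)
}

#' Extract the numeric feature matrix from a composition/CLR tibble
#'
#' @param x Tibble with `entity_id` and `hpc_*` columns.
#' @return Numeric matrix with `entity_id` rownames.
#' @export
composition_matrix <- function(x) {
  cols <- grep("^hpc_", names(x), value = TRUE)
  m <- as.matrix(x[cols])
  rownames(m) <- x$entity_id
  m
}
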