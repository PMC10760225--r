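# Tile preprocessing: tessellation of slide images into fixed field-of-view
# tiles, background rejection, and Reinhard colour-transfer normalization in
# the Ruderman l-alpha-beta space.

#' Preprocessing configuration
#'
#' @param tile_px Tile side length in pixels (224 at production scale).
#' @param target_mpp Target resolution in microns per pixel; slides are
#'   rescaled by `mpp / target_mpp` before gridding.
#' @param background_reject_threshold A tile is rejected when its background
#'   fraction exceeds this value.
#' @param background_pixel_threshold A pixel counts as background when
#'   `min(R, G, B)` (after 3x3 mean smoothing) is at least this value —
#'   standard white-glass detection.
#' @param reinhard_target Optional list `list(mean =, sd =)` of per-channel
#'   l-alpha-beta statistics to normalize towards. When `NULL`, pooled
#'   statistics of the run's own kept tiles are used (see
#'   [reinhard_target_stats()]).
#' @return A list of class `hpl_preprocess_config`.
#' @export
preprocess_config <- function(tile_px = 224L, target_mpp = 0.5,
                              background_reject_threshold = 0.75,
                              background_pixel_threshold = 220 / 255,
                              reinhard_target = NULL) {
  stopifnot(tile_px >= 1, target_mpp > 0,
            background_reject_threshold >= 0, background_reject_threshold <= 1)
  structure(list(tile_px = as.integer(tile_px), target_mpp = target_mpp,
                 background_reject_threshold = background_reject_threshold,
                 background_pixel_threshold = background_pixel_threshold,
                 reinhard_target = reinhard_target),
            class = "hpl_preprocess_config")
}

#' Wrap a pixel array as a slide image
#'
#' @param pixels `h x w x 3` numeric array in `[0, 1]`.
#' @param slide_id Identifier string.
#' @param mpp Microns per pixel of the array; must be positive.
#' @return A list of class `hpl_slide`.
#' @export
slide_image <- function(pixels, slide_id, mpp = 0.5) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3, mpp > 0)
  structure(list(slide_id = slide_id, pixels = pixels, mpp = mpp),
            class = "hpl_slide")
}

#' Read a PNG or TIFF file as a slide image
#'
#' @inheritParams slide_image
#' @param path Path to a PNG (or TIFF, when the `tiff` package is installed)
#'   file.
#' @return A list of class `hpl_slide`.
#' @export
read_slide <- function(path, slide_id = basename(path), mpp = 0.5) {
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      abort("Reading TIFF requires the 'tiff' package.")
    }
    tiff::readTIFF(path)
  } else {
    abort(sprintf("Unsupported slide format '%s' (PNG/TIFF supported).", ext))
  }
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3]
  slide_image(px, slide_id, mpp)
}

# Interpolation weight matrix mapping n_old samples to n_new.
# Downscale: exact area averaging over half-open source windows.
# Upscale: bilinear on pixel centres, edge-clamped.
interp_weights <- function(n_old, n_new) {
  if (n_new == n_old) return(diag(n_old))
  W <- matrix(0, n_new, n_old)
  if (n_new < n_old) {
    r <- n_old / n_new
    for (i in seq_len(n_new)) {
      a <- (i - 1) * r
      b <- i * r
      j0 <- floor(a) + 1
      j1 <- ceiling(b)
      for (j in j0:min(j1, n_old)) {
        W[i, j] <- (min(b, j) - max(a, j - 1)) / r
      }
    }
  } else {
    for (i in seq_len(n_new)) {
      src <- (i - 0.5) * n_old / n_new + 0.5
      j <- floor(src)
      w <- src - j
      j0 <- min(max(j, 1), n_old)
      j1 <- min(max(j + 1, 1), n_old)
      W[i, j0] <- W[i, j0] + (1 - w)
      W[i, j1] <- W[i, j1] + w
    }
  }
  W
}

#' Rescale an RGB array
#'
#' Area averaging when shrinking a dimension, bilinear interpolation when
#' enlarging it.
#'
#' @param pixels `h x w x 3` array.
#' @param new_h,new_w Target dimensions.
#' @return Rescaled `new_h x new_w x 3` array.
#' @export
resize_rgb <- function(pixels, new_h, new_w) {
  d <- dim(pixels)
  Wh <- interp_weights(d[1], new_h)
  Ww <- interp_weights(d[2], new_w)
  out <- array(0, dim = c(new_h, new_w, 3))
  for (ch in 1:3) out[, , ch] <- Wh %*% pixels[, , ch] %*% t(Ww)
  out
}

# 3x3 mean filter with edge replication
mean_filter3 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  p <- m[c(1, seq_len(h), h), c(1, seq_len(w), w)]
  (p[1:h, 1:w] + p[1:h, 2:(w + 1)] + p[1:h, 3:(w + 2)] +
     p[2:(h + 1), 1:w] + p[2:(h + 1), 2:(w + 1)] + p[2:(h + 1), 3:(w + 2)] +
     p[3:(h + 2), 1:w] + p[3:(h + 2), 2:(w + 1)] + p[3:(h + 2), 3:(w + 2)]) / 9
}

#' Background fraction of a tile
#'
#' A pixel is background when the minimum of its smoothed R, G, B values is at
#' least `background_pixel_threshold` (near-white glass). The fraction is
#' scale-invariant for solid-colour tiles.
#'
#' @param pixels `h x w x 3` array in `[0, 1]`.
#' @param config An [preprocess_config()] object.
#' @return Fraction of background pixels in `[0, 1]`.
#' @export
background_fraction <- function(pixels, config = preprocess_config()) {
  sm <- pmin(pmin(mean_filter3(pixels[, , 1]), mean_filter3(pixels[, , 2])),
             mean_filter3(pixels[, , 3]))
  mean(sm >= config$background_pixel_threshold)
}

#' Tessellate a slide into tiles
#'
#' The slide is first rescaled to `target_mpp` (factor `mpp / target_mpp`),
#' then cut into a non-overlapping row-major grid of `tile_px`-sided tiles on
#' half-open pixel windows; partial edge tiles are discarded. Each tile gets a
#' background fraction and is kept iff that fraction does not exceed
#' `background_reject_threshold`.
#'
#' @param slide An [slide_image()] object.
#' @param config An [preprocess_config()] object.
#' @return Tibble with columns `slide_id`, `tile_id`, `grid_row`, `grid_col`
#'   (0-based), `pixels` (list of arrays), `background_fraction`, `kept`.
#'   Zero rows (with a warning) when the slide is smaller than one tile.
#' @export
tessellate <- function(slide, config = preprocess_config()) {
  stopifnot(inherits(slide, "hpl_slide"))
  s <- slide$mpp / config$target_mpp
  d <- dim(slide$pixels)
  new_h <- max(1L, floor(d[1] * s))
  new_w <- max(1L, floor(d[2] * s))
  px <- if (new_h == d[1] && new_w == d[2]) slide$pixels else
    resize_rgb(slide$pixels, new_h, new_w)
  tp <- config$tile_px
  n_rows <- new_h %/% tp
  n_cols <- new_w %/% tp
  empty <- tibble(slide_id = character(), tile_id = character(),
                  grid_row = integer(), grid_col = integer(),
                  pixels = list(), background_fraction = double(),
                  kept = logical())
  if (n_rows < 1 || n_cols < 1) {
    warn(sprintf("Slide %s is smaller than one tile after rescaling; no tiles.",
                 slide$slide_id))
    return(empty)
  }
  grid <- expand.grid(grid_col = seq_len(n_cols) - 1L,
                      grid_row = seq_len(n_rows) - 1L)[, 2:1]
  rows <- purrr::pmap(grid, function(grid_row, grid_col) {
    tile <- px[grid_row * tp + seq_len(tp), grid_col * tp + seq_len(tp), ,
               drop = FALSE]
    bf <- background_fraction(tile, config)
    tibble(slide_id = slide$slide_id,
           tile_id = sprintf("%s_R%d_C%d", slide$slide_id, grid_row, grid_col),
           grid_row = as.integer(grid_row), grid_col = as.integer(grid_col),
           pixels = list(tile), background_fraction = bf,
           kept = bf <= config$background_reject_threshold)
  })
  bind_rows(rows)
}

# Ruderman l-alpha-beta colour space (the space of Reinhard colour transfer).
.rgb2lms <- matrix(c(0.3811, 0.5783, 0.0402,
                     0.1967, 0.7244, 0.0782,
                     0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)
.lms2rgb <- solve(.rgb2lms)
.lms2lab <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1, 1, 1, 1, 1, -2, 1, -1, 0), 3, 3, byrow = TRUE)
.lab2lms <- solve(.lms2lab)

#' Convert RGB pixels to Ruderman l-alpha-beta
#'
#' @param pixels `h x w x 3` RGB array in `[0, 1]`.
#' @return Array of the same shape in l-alpha-beta coordinates.
#' @export
rgb_to_lab <- function(pixels) {
  d <- dim(pixels)
  m <- matrix(pixels, ncol = 3)
  lms <- pmax(m %*% t(.rgb2lms), 1e-6)
  lab <- log10(lms) %*% t(.lms2lab)
  array(lab, dim = d)
}

#' Convert Ruderman l-alpha-beta pixels back to RGB
#'
#' @param lab `h x w x 3` array in l-alpha-beta coordinates.
#' @return RGB array clipped to `[0, 1]`.
#' @export
lab_to_rgb <- function(lab) {
  d <- dim(lab)
  m <- matrix(lab, ncol = 3)
  lms <- 10^(m %*% t(.lab2lms))
  rgb <- lms %*% t(.lms2rgb)
  array(pmin(pmax(rgb, 0), 1), dim = d)
}

# per-channel mean/sd in lab space
lab_stats <- function(lab) {
  m <- matrix(lab, ncol = 3)
  list(mean = colMeans(m), sd = apply(m, 2, function(x) sqrt(mean((x - mean(x))^2))))
}

#' Pooled Reinhard target statistics for a set of tiles
#'
#' Computes per-channel l-alpha-beta mean and standard deviation pooled over
#' the pixels of the given (typically kept tissue) tiles — the run-level
#' default target for [reinhard_normalize()].
#'
#' @param tiles Tibble with a `pixels` list-column (optionally a `kept`
#'   column; only kept tiles are pooled).
#' @return `list(mean =, sd =)` with length-3 numeric elements.
#' @export
reinhard_target_stats <- function(tiles) {
  if ("kept" %in% names(tiles)) tiles <- filter(tiles, kept)
  stopifnot(nrow(tiles) > 0)
  mats <- purrr::map(tiles$pixels, function(px) matrix(rgb_to_lab(px), ncol = 3))
  pooled <- do.call(rbind, mats)
  list(mean = colMeans(pooled),
       sd = apply(pooled, 2, function(x) sqrt(mean((x - mean(x))^2))))
}

#' Reinhard colour-transfer normalization
#'
#' Matches the tile's per-channel mean and standard deviation in the Ruderman
#' l-alpha-beta space to target statistics, then converts back to (clipped)
#' RGB. A channel with zero source spread only receives the mean shift, with a
#' warning. The operation is idempotent up to tolerance.
#'
#' @param pixels `h x w x 3` RGB array in `[0, 1]`.
#' @param target `list(mean =, sd =)` per-channel l-alpha-beta statistics,
#'   e.g. from [reinhard_target_stats()].
#' @return Normalized RGB array.
#' @export
reinhard_normalize <- function(pixels, target) {
  stopifnot(is.list(target), length(target$mean) == 3, length(target$sd) == 3)
  lab <- rgb_to_lab(pixels)
  st <- lab_stats(lab)
  m <- matrix(lab, ncol = 3)
  for (ch in 1:3) {
    if (st$sd[ch] < 1e-12) {
      warn(sprintf("Channel %d has zero spread; applying mean shift only.", ch))
      m[, ch] <- m[, ch] - st$mean[ch] + target$mean[ch]
    } else {
      m[, ch] <- (m[, ch] - st$mean[ch]) / st$sd[ch] * target$sd[ch] +
        target$mean[ch]
    }
  }
  lab_to_rgb(array(m, dim = dim(pixels)))
}

#' Preprocess every slide of a cohort tile table
#'
#' Convenience stage used by [run_pipeline()]: applies Reinhard normalization
#' to kept tiles of a tessellated tile table (computing pooled target
#' statistics when the config carries none).
#'
#' @param tiles Tessellation output with `pixels` and `kept` columns.
#' @param config An [preprocess_config()] object.
#' @return The tile table with normalized pixels and a `reinhard_target`
#'   attribute.
#' @export
normalize_tiles <- function(tiles, config = preprocess_config()) {
  target <- config$reinhard_target %||% reinhard_target_stats(tiles)
  idx <- which(tiles$kept)
  tiles$pixels[idx] <- purrr::map(tiles$pixels[idx], reinhard_normalize,
                                  target = target)
  attr(tiles, "reinhard_target") <- target
  tiles
}
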