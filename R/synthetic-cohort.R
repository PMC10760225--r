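#' Configuration for the synthetic multi-institution cohort
#'
#' Builds the parameter object consumed by [generate_cohort()]. The defaults
#' emulate a three-institution skin-cancer biopsy cohort: unequal institution
#' sizes, one institution contributing several slides per patient while the
#' others contribute exactly one, a planted set of tile phenotypes (plus a
#' near-white artifact phenotype), per-patient phenotype compositions drawn
#' from a Dirichlet, and disease-free survival generated from a proportional
#' hazards model on the centred log-ratio of the true composition.
#'
#' @param n_patients Named integer vector, patients per institution. The
#'   default matches the post-exclusion per-institution counts of the emulated
#'   cohort (38 + 85 + 40 = 163).
#' @param slides_per_patient Named list of `c(min, max)` integer ranges per
#'   institution. Exactly one institution may have `max > 1`.
#' @param tiles_per_slide Integer `c(min, max)` range of kept tiles per slide.
#' @param n_phenotypes Number of planted (non-artifact) tile phenotypes.
#' @param artifact_fraction Proportion of tiles per slide drawn from the
#'   artifact phenotype; must be in `[0, 1)`.
#' @param phenotype_log_hazards Numeric vector of per-phenotype log hazard
#'   ratios (length `n_phenotypes`) applied to the hazard covariate.
#' @param baseline_hazard Baseline event rate per month.
#' @param censoring_rate Rate per month of the exponential random censoring
#'   process; `0` disables random censoring.
#' @param admin_censor_time Administrative censoring horizon in months.
#' @param dirichlet_concentration Dirichlet concentration vector (length
#'   `n_phenotypes`) for per-patient compositions.
#' @param tile_px Side length in pixels of rendered tiles. 64 keeps tests
#'   fast; set 224 for production parity — all geometry is side-length
#'   agnostic.
#' @param hazard_covariate Either `"clr"` (default; matches the downstream
#'   model family) or `"proportions"`.
#' @param seed Global integer seed; all sub-streams are derived from it via
#'   [substream_seed()].
#' @return A list of class `hpl_synth_config`.
#' @seealso [generate_cohort()], [cohort_presets()]
#' @export
synthetic_config <- function(n_patients = c(NYU = 38, UCSF = 85, BWH = 40),
                             slides_per_patient = list(NYU = c(1L, 5L),
                                                       UCSF = c(1L, 1L),
                                                       BWH = c(1L, 1L)),
                             tiles_per_slide = c(30L, 80L),
                             n_phenotypes = 8L,
                             artifact_fraction = 0.1,
                             phenotype_log_hazards =
                               c(1.5, -1.5, 1, -1, 0.5, -0.5, 0, 0),
                             baseline_hazard = 0.01,
                             censoring_rate = 0.008,
                             admin_censor_time = 120,
                             dirichlet_concentration = rep(1, n_phenotypes),
                             tile_px = 64L,
                             hazard_covariate = c("clr", "proportions"),
                             seed = 1L) {
  hazard_covariate <- match.arg(hazard_covariate)
  if (is.null(names(n_patients)) || any(!nzchar(names(n_patients)))) {
    abort("`n_patients` must be a named vector (institution -> count).")
  }
  if (any(n_patients <= 0) || any(tiles_per_slide <= 0) || tile_px <= 0) {
    abort("All counts and sizes must be positive.")
  }
  if (!setequal(names(slides_per_patient), names(n_patients))) {
    abort("`slides_per_patient` must name the same institutions as `n_patients`.")
  }
  multi <- names(slides_per_patient)[vapply(slides_per_patient,
                                            function(r) r[2] > 1, TRUE)]
  if (length(multi) != 1) {
    abort("Exactly one institution must allow more than one slide per patient.")
  }
  if (artifact_fraction < 0 || artifact_fraction >= 1) {
    abort("`artifact_fraction` must lie in [0, 1).")
  }
  if (length(phenotype_log_hazards) != n_phenotypes ||
      any(!is.finite(phenotype_log_hazards))) {
    abort("`phenotype_log_hazards` must be finite and of length `n_phenotypes`.")
  }
  if (baseline_hazard <= 0 || censoring_rate < 0 || admin_censor_time < 0) {
    abort("Rates must be non-negative and `baseline_hazard` positive.")
  }
  if (length(dirichlet_concentration) != n_phenotypes ||
      any(dirichlet_concentration <= 0)) {
    abort("`dirichlet_concentration` must be positive, length `n_phenotypes`.")
  }
  structure(list(
    n_patients = n_patients,
    slides_per_patient = lapply(slides_per_patient, as.integer),
    multi_slide_institution = multi,
    tiles_per_slide = as.integer(tiles_per_slide),
    n_phenotypes = as.integer(n_phenotypes),
    artifact_fraction = artifact_fraction,
    phenotype_log_hazards = phenotype_log_hazards,
    baseline_hazard = baseline_hazard,
    censoring_rate = censoring_rate,
    admin_censor_time = admin_censor_time,
    dirichlet_concentration = dirichlet_concentration,
    tile_px = as.integer(tile_px),
    hazard_covariate = hazard_covariate,
    seed = as.integer(seed)
  ), class = "hpl_synth_config")
}

#' Published per-institution cohort splits
#'
#' The emulated cohort's good/poor outcome splits are reported twice with
#' slightly different totals; both are exposed as presets rather than
#' silently resolved. `"results"` carries per-institution granularity
#' (38 + 85 + 40 = 163 patients; 109 good / 54 poor); `"methods"` gives the
#' alternative combined split (119 good / 44 poor over the same 163).
#'
#' @return A tibble with columns `preset`, `institution`, `n_patients`,
#'   `n_good`, `n_poor`.
#' @export
cohort_presets <- function() {
  tibble(
    preset = c(rep("results", 3), "methods"),
    institution = c("NYU", "UCSF", "BWH", "combined"),
    n_patients = c(38L, 85L, 40L, 163L),
    n_good = c(31L, 58L, 20L, 119L),
    n_poor = c(7L, 27L, 20L, 44L)
  )
}

# one Dirichlet draw via normalized gammas
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Draw disease-free survival times from the planted hazard model
#'
#' Event times are exponential with rate
#' `baseline_hazard * exp(beta . h(composition))`, where `h` is either the
#' centred log-ratio of the composition (default, matching the downstream
#' linear models) or the raw proportions. The observed time is the minimum of
#' the event time, an exponential random censoring time, and the
#' administrative horizon; the event flag records which came first.
#'
#' @param composition Numeric vector summing to 1, or a matrix with one
#'   composition per row.
#' @param beta Per-phenotype log hazard ratios.
#' @param baseline_hazard Event rate per month; must be positive.
#' @param censoring_rate Random-censoring rate per month (0 disables).
#' @param admin_censor_time Administrative horizon in months.
#' @param covariate `"clr"` or `"proportions"`.
#' @return A tibble with columns `dfs_months`, `event`, `true_hazard`.
#' @export
sample_survival <- function(composition, beta, baseline_hazard,
                            censoring_rate = 0, admin_censor_time = Inf,
                            covariate = c("clr", "proportions")) {
  covariate <- match.arg(covariate)
  if (baseline_hazard <= 0 || censoring_rate < 0 || admin_censor_time < 0) {
    abort("Rates must be non-negative and `baseline_hazard` positive.")
  }
  x <- if (is.matrix(composition)) composition else matrix(composition, nrow = 1)
  if (any(abs(rowSums(x) - 1) > 1e-6)) {
    abort("Each composition must sum to 1.")
  }
  z <- if (covariate == "clr") {
    lx <- log(x)
    lx - rowMeans(lx)
  } else {
    x
  }
  hazard <- baseline_hazard * exp(drop(z %*% beta))
  n <- length(hazard)
  t_event <- rexp(n, rate = hazard)
  t_cens <- if (censoring_rate > 0) rexp(n, rate = censoring_rate) else rep(Inf, n)
  obs <- pmin(t_event, t_cens, admin_censor_time)
  tibble(
    dfs_months = obs,
    event = as.integer(t_event <= pmin(t_cens, admin_censor_time) &
                         t_event == obs),
    true_hazard = hazard
  )
}

#' Render a procedural tile image for a planted phenotype
#'
#' Stands in for an H&E tile: a tissue-toned base colour with
#' phenotype-specific blob texture (density, radius and palette are stable
#' functions of the phenotype id), so that simple intensity statistics
#' separate phenotypes. The `"artifact"` phenotype renders near-white, above
#' the background threshold used by tile preprocessing.
#'
#' @param phenotype_id Integer phenotype id in `1..n_phenotypes`, or
#'   `"artifact"`.
#' @param tile_px Side length in pixels.
#' @param seed Integer seed; identical `(phenotype_id, seed)` give identical
#'   pixels.
#' @param n_phenotypes Number of non-artifact phenotypes known to the config.
#' @return A `tile_px x tile_px x 3` numeric array in `[0, 1]`.
#' @export
render_tile_image <- function(phenotype_id, tile_px = 64L, seed = 1L,
                              n_phenotypes = 8L) {
  is_artifact <- identical(phenotype_id, "artifact")
  if (!is_artifact) {
    phenotype_id <- as.integer(phenotype_id)
    if (is.na(phenotype_id) || phenotype_id < 1 || phenotype_id > n_phenotypes) {
      abort(sprintf("Unknown phenotype id %s (config knows 1..%d or 'artifact').",
                    phenotype_id, n_phenotypes))
    }
  }
  with_seed(seed, {
    if (is_artifact) {
      # near-white with pale grey bubble blotches: bright (high luminance) yet
      # with enough sub-threshold pixels to pass the 75% background filter, so
      # artifact removal is exercised downstream by cluster filtering
      px <- array(0.96, dim = c(tile_px, tile_px, 3))
      rows <- matrix(rep(seq_len(tile_px), tile_px), tile_px, tile_px)
      cols <- t(rows)
      bubble <- c(0.80, 0.82, 0.84)
      n_bub <- round(10 * (tile_px / 64)^2)
      for (b in seq_len(n_bub)) {
        cy <- runif(1, 1, tile_px); cx <- runif(1, 1, tile_px)
        r <- tile_px * runif(1, 0.09, 0.18)
        mask <- (rows - cy)^2 + (cols - cx)^2 <= r^2
        for (ch in 1:3) {
          plane <- px[, , ch]
          plane[mask] <- bubble[ch]
          px[, , ch] <- plane
        }
      }
      px <- px + array(rnorm(tile_px * tile_px * 3, sd = 0.008), dim = dim(px))
      return(pmin(pmax(px, 0), 1))
    }
    hue <- (0.618034 * phenotype_id) %% 1
    base_col <- grDevices::hsv(hue, 0.25 + 0.05 * (phenotype_id %% 3), 0.88)
    blob_col <- grDevices::hsv(hue, 0.75, 0.40 + 0.05 * (phenotype_id %% 2))
    base_rgb <- as.numeric(grDevices::col2rgb(base_col)) / 255
    blob_rgb <- as.numeric(grDevices::col2rgb(blob_col)) / 255
    px <- array(rep(base_rgb, each = tile_px * tile_px),
                dim = c(tile_px, tile_px, 3))
    scale2 <- (tile_px / 64)^2
    n_blobs <- round((10 + 6 * ((phenotype_id * 7) %% 5)) * scale2)
    radius <- tile_px * (0.05 + 0.02 * ((phenotype_id * 3) %% 4))
    rows <- matrix(rep(seq_len(tile_px), tile_px), tile_px, tile_px)
    cols <- t(rows)
    for (b in seq_len(n_blobs)) {
      cy <- runif(1, 1, tile_px)
      cx <- runif(1, 1, tile_px)
      r <- radius * runif(1, 0.7, 1.3)
      mask <- (rows - cy)^2 + (cols - cx)^2 <= r^2
      for (ch in 1:3) {
        plane <- px[, , ch]
        plane[mask] <- blob_rgb[ch]
        px[, , ch] <- plane
      }
    }
    px <- px + array(rnorm(tile_px * tile_px * 3, sd = 0.02), dim = dim(px))
    pmin(pmax(px, 0), 1)
  })
}

#' Generate a fully labelled synthetic cohort
#'
#' Draws, per patient: a phenotype composition from the configured Dirichlet;
#' disease-free survival from the proportional hazards model
#' ([sample_survival()]); a binary outcome (`poor` iff an event occurred) and,
#' for poor-outcome patients, a subtype (`LR` vs `NM`/`DM`/`DSD`) decided by
#' which planted driver phenotype dominates the composition. Each patient gets
#' 1 slide (or 1-5 for the designated multi-slide institution), each slide a
#' row-major tile grid whose tiles are artifact with probability
#' `artifact_fraction` and otherwise multinomial in the patient composition.
#'
#' @param config An `hpl_synth_config` from [synthetic_config()].
#' @param render_tiles If `TRUE`, procedural pixel data is rendered into the
#'   `pixels` list-column; if `FALSE` (fast path for model-level studies) the
#'   tile table carries labels and grid geometry only.
#' @return A list of class `hpl_cohort` with elements `manifest` (one row per
#'   slide), `tiles` (one row per tile), and `ground_truth` (list with
#'   `tile_phenotype`, `patient_composition`, `true_hazard`).
#' @examples
#' cfg <- synthetic_config(n_patients = c(NYU = 4, UCSF = 6, BWH = 4),
#'                         tiles_per_slide = c(8, 16), seed = 7)
#' cohort <- generate_cohort(cfg, render_tiles = FALSE)
#' dplyr::count(cohort$manifest, institution)
#' @export
generate_cohort <- function(config, render_tiles = TRUE) {
  stopifnot(inherits(config, "hpl_synth_config"))
  K <- config$n_phenotypes
  beta <- config$phenotype_log_hazards
  drivers <- order(beta, decreasing = TRUE)[1:2]  # metastasis- and LR-linked
  inst_names <- names(config$n_patients)

  manifest <- list(); tiles <- list(); comps <- list(); hazards <- list()
  for (inst in inst_names) {
    for (j in seq_len(config$n_patients[[inst]])) {
      pid <- sprintf("%s_P%03d", inst, j)
      res <- with_seed(substream_seed(config$seed, "patient", pid), {
        comp <- rdirichlet1(config$dirichlet_concentration)
        sv <- sample_survival(comp, beta, config$baseline_hazard,
                              config$censoring_rate, config$admin_censor_time,
                              covariate = config$hazard_covariate)
        outcome <- if (sv$event == 1) "poor" else "good"
        subtype <- "none"
        if (outcome == "poor") {
          if (comp[drivers[1]] >= comp[drivers[2]]) {
            u <- runif(1)
            subtype <- if (u < 0.1) "DSD" else if (u < 0.55) "NM" else "DM"
          } else {
            subtype <- "LR"
          }
        }
        rng <- config$slides_per_patient[[inst]]
        n_slides <- if (rng[1] == rng[2]) rng[1] else
          sample(seq(rng[1], rng[2]), 1)
        slide_rows <- vector("list", n_slides)
        tile_rows <- vector("list", n_slides)
        for (s in seq_len(n_slides)) {
          sid <- sprintf("%s_S%d", pid, s)
          tl <- config$tiles_per_slide
          nt <- if (tl[1] == tl[2]) tl[1] else sample(seq(tl[1], tl[2]), 1)
          nc <- ceiling(sqrt(nt))
          idx <- seq_len(nt) - 1L
          art <- runif(nt) < config$artifact_fraction
          phen <- integer(nt)
          n_tissue <- sum(!art)
          if (n_tissue > 0) {
            phen[!art] <- sample.int(K, n_tissue, replace = TRUE, prob = comp)
          }
          phen[art] <- NA_integer_
          slide_rows[[s]] <- tibble(
            patient_id = pid, institution = inst, slide_id = sid,
            outcome = outcome, outcome_subtype = subtype,
            dfs_months = sv$dfs_months, event = sv$event,
            diagnosis = if (inst == config$multi_slide_institution)
              sprintf("dx%d", which.max(comp)) else NA_character_
          )
          tile_rows[[s]] <- tibble(
            slide_id = sid,
            tile_id = sprintf("%s_T%04d", sid, idx),
            grid_row = idx %/% nc,
            grid_col = idx %% nc,
            phenotype = phen,
            is_artifact = art
          )
        }
        list(manifest = bind_rows(slide_rows), tiles = bind_rows(tile_rows),
             comp = comp, hazard = sv$true_hazard)
      })
      manifest[[pid]] <- res$manifest
      tiles[[pid]] <- res$tiles
      comps[[pid]] <- res$comp
      hazards[[pid]] <- res$hazard
    }
  }
  manifest <- bind_rows(manifest)
  tiles <- bind_rows(tiles)
  if (render_tiles) {
    tiles$pixels <- purrr::map2(
      ifelse(tiles$is_artifact, "artifact", tiles$phenotype), tiles$tile_id,
      function(ph, tid) {
        id <- if (identical(ph, "artifact")) "artifact" else as.integer(ph)
        render_tile_image(id, config$tile_px,
                          seed = substream_seed(config$seed, "tile", tid),
                          n_phenotypes = K)
      })
  }
  comp_mat <- do.call(rbind, comps)
  colnames(comp_mat) <- sprintf("phenotype_%d", seq_len(K))
  ground_truth <- list(
    tile_phenotype = select(tiles, slide_id, tile_id, phenotype, is_artifact),
    patient_composition = bind_cols(tibble(patient_id = names(comps)),
                                    as_tibble(comp_mat)),
    true_hazard = tibble(patient_id = names(hazards),
                         true_hazard = unlist(hazards))
  )
  structure(list(manifest = manifest, tiles = tiles,
                 ground_truth = ground_truth, config = config),
            class = "hpl_cohort")
}

#' @export
print.hpl_cohort <- function(x, ...) {
  cat(sprintf(
    "<hpl_cohort> %d patients / %d slides / %d tiles (%d phenotypes + artifacts)\n",
    length(unique(x$manifest$patient_id)), nrow(x$manifest), nrow(x$tiles),
    x$config$n_phenotypes))
  invisible(x)
}

#' Patient-level manifest of a cohort
#'
#' Collapses the per-slide manifest to one row per patient (slide counts
#' aside, all clinical columns are constant within patient).
#'
#' @param manifest A per-slide manifest tibble.
#' @return A tibble with one row per patient and an `n_slides` column.
#' @export
patient_manifest <- function(manifest) {
  manifest %>%
    group_by(patient_id, institution, outcome, outcome_subtype,
             dfs_months, event) %>%
    summarise(n_slides = dplyr::n_distinct(slide_id),
              diagnosis = dplyr::first(diagnosis), .groups = "drop")
}
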