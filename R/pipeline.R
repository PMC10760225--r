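# End-to-end orchestration: synthesize -> preprocess -> embed -> artifact
# over-clustering + filtering -> final clustering -> compositions -> models ->
# interpretation, under one config and one global seed, with provenance
# sidecars. Completed stages can be reused by passing the previous run's
# result as `state`.

#' Pipeline configuration
#'
#' @param synth [synthetic_config()] for the cohort stage.
#' @param preprocess [preprocess_config()]; `tile_px` should match the
#'   synthetic tile size for mosaic round-tripping.
#' @param encoder [encoder_config()] (used when `embedding = "encoder"`).
#' @param embedding `"encoder"` (train the Barlow-Twins encoder) or
#'   `"synthetic"` (ground-truth-structured Gaussian embeddings; fast path
#'   that decouples clustering and statistics from training stochasticity).
#' @param artifact_resolution Leiden resolution of the over-clustering pass.
#' @param artifact_luminance Mean-luminance threshold above which an
#'   over-clustered cluster is flagged as artifact.
#' @param filter_artifacts Set `FALSE` to skip artifact-cluster removal (the
#'   over-clustering pass still runs; useful as an ablation).
#' @param resolutions Grid for the final-resolution sweep.
#' @param k_neighbors,metric kNN graph parameters.
#' @param logistic_alpha,logistic_l1_ratio,cox_alpha,cox_l1_ratio Elastic-net
#'   parameters.
#' @param n_folds,km_tolerance Fold construction parameters.
#' @param stages Character vector of stages to run (in dependency order).
#' @param out_dir Output directory (`NULL` = no files written).
#' @param seed Global seed; stage sub-streams derive from it.
#' @return A list of class `hpl_pipeline_config`.
#' @export
pipeline_config <- function(synth = synthetic_config(),
                            preprocess = preprocess_config(
                              tile_px = synth$tile_px),
                            encoder = encoder_config(),
                            embedding = c("synthetic", "encoder"),
                            artifact_resolution = 7,
                            artifact_luminance = 0.88,
                            filter_artifacts = TRUE,
                            resolutions = c(0.25, 0.5, 0.75, 1, 1.5, 2),
                            k_neighbors = 50L, metric = "cosine",
                            logistic_alpha = 0.25, logistic_l1_ratio = 0.5,
                            cox_alpha = 0.35, cox_l1_ratio = 0.01,
                            n_folds = 3L, km_tolerance = 0.15,
                            stages = c("synthesize", "preprocess", "embed",
                                       "cluster", "represent", "model",
                                       "interpret"),
                            out_dir = NULL, seed = 1L) {
  embedding <- match.arg(embedding)
  structure(list(synth = synth, preprocess = preprocess, encoder = encoder,
                 embedding = embedding,
                 artifact_resolution = artifact_resolution,
                 artifact_luminance = artifact_luminance,
                 filter_artifacts = filter_artifacts,
                 resolutions = resolutions, k_neighbors = as.integer(k_neighbors),
                 metric = metric, logistic_alpha = logistic_alpha,
                 logistic_l1_ratio = logistic_l1_ratio, cox_alpha = cox_alpha,
                 cox_l1_ratio = cox_l1_ratio, n_folds = as.integer(n_folds),
                 km_tolerance = km_tolerance, stages = stages,
                 out_dir = out_dir, seed = as.integer(seed),
                 version = as.character(utils::packageVersion("hplkit"))),
            class = "hpl_pipeline_config")
}

config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(rapply(unclass(config), unclass,
                                          how = "replace")),
                           auto_unbox = TRUE, force = TRUE, digits = NA)
  h <- fnv1a32(as.character(json))
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

#' Reassemble a slide image from a cohort's tile grid
#'
#' Mosaics the rendered tiles of one synthetic slide back into a single pixel
#' array at the target resolution, so the tessellation stage can be exercised
#' end to end.
#'
#' @param cohort An `hpl_cohort` with rendered tiles.
#' @param slide One slide id.
#' @param mpp Microns per pixel to stamp on the slide.
#' @return An [slide_image()].
#' @export
assemble_slide <- function(cohort, slide, mpp = 0.5) {
  tiles <- filter(cohort$tiles, slide_id == slide)
  if (!nrow(tiles) || is.null(tiles$pixels)) {
    abort("Slide not found or tiles not rendered.")
  }
  tp <- cohort$config$tile_px
  nr <- max(tiles$grid_row) + 1L
  nc <- max(tiles$grid_col) + 1L
  px <- array(1, dim = c(nr * tp, nc * tp, 3))  # unfilled cells are glass
  for (i in seq_len(nrow(tiles))) {
    rr <- tiles$grid_row[i] * tp + seq_len(tp)
    cc <- tiles$grid_col[i] * tp + seq_len(tp)
    px[rr, cc, ] <- tiles$pixels[[i]]
  }
  slide_image(px, slide, mpp)
}

write_stage <- function(out_dir, name, obj, config) {
  if (is.null(out_dir)) return(invisible(NULL))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- file.path(out_dir, name)
  if (is.data.frame(obj)) {
    readr::write_tsv(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  invisible(path)
}

#' Run the phenotype-learning pipeline end to end
#'
#' Executes the configured stages in dependency order. Pass a previous run's
#' return value as `state` to resume: stages already present there (and not
#' listed in `config$stages`) are reused unchanged.
#'
#' @param config An [pipeline_config()].
#' @param state Optional result of a previous [run_pipeline()] call.
#' @return A list of class `hpl_run` with (depending on stages): `cohort`,
#'   `tiles`, `embeddings`, `artifact_pass` (assignment, flagged ids),
#'   `assignment`, `sweep`, `resolution`, `compositions`, `clr`, `folds`,
#'   `cv_logistic`, `cv_cox`, `interpretation`, plus `config` and `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), state = NULL) {
  stopifnot(inherits(config, "hpl_pipeline_config"))
  res <- state %||% list()
  res$config <- config
  res$provenance <- list(config_hash = config_hash(config),
                         seed = config$seed,
                         version = config$version,
                         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  on <- function(stage) stage %in% config$stages
  need <- function(what, stage) {
    if (is.null(res[[what]])) {
      abort(sprintf("Stage '%s' needs '%s'; rerun the stage that produces it.",
                    stage, what))
    }
    res[[what]]
  }

  if (on("synthesize")) {
    res$cohort <- generate_cohort(config$synth,
                                  render_tiles = config$embedding == "encoder" ||
                                    on("preprocess"))
    write_stage(config$out_dir, "manifest.tsv", res$cohort$manifest, config)
    write_stage(config$out_dir, "ground_truth_tiles.tsv",
                res$cohort$ground_truth$tile_phenotype, config)
  }

  if (on("preprocess")) {
    cohort <- need("cohort", "preprocess")
    slides <- unique(cohort$manifest$slide_id)
    pp <- config$preprocess
    tiles <- bind_rows(lapply(slides, function(s) {
      tessellate(assemble_slide(cohort, s, mpp = pp$target_mpp), pp)
    }))
    tiles <- normalize_tiles(tiles, pp)
    # carry ground-truth labels by grid position
    tiles <- left_join(
      tiles,
      select(cohort$tiles, slide_id, grid_row, grid_col, phenotype,
             is_artifact),
      by = c("slide_id", "grid_row", "grid_col"))
    res$tiles <- tiles
    write_stage(config$out_dir, "tiles.tsv",
                select(tiles, -pixels), config)
  }

  if (on("embed")) {
    if (config$embedding == "encoder") {
      tiles <- need("tiles", "embed")
      cohort <- need("cohort", "embed")
      enc_cfg <- config$encoder
      enc_cfg$seed <- substream_seed(config$seed, "encoder")
      res$encoder <- train_encoder(tiles, enc_cfg, cohort$manifest)
      emb <- embed_tiles(tiles, res$encoder)
      meta_cols <- intersect(c("phenotype", "is_artifact"), names(tiles))
      if (length(meta_cols)) {
        emb <- left_join(emb, tiles[c("tile_id", meta_cols)], by = "tile_id")
      }
      res$embeddings <- emb
    } else {
      cohort <- need("cohort", "embed")
      res$embeddings <- cohort_embeddings(
        cohort, z_dim = config$encoder$z_dim,
        seed = substream_seed(config$seed, "embeddings"))
    }
  }

  if (on("cluster")) {
    emb <- need("embeddings", "cluster")
    cohort <- need("cohort", "cluster")
    over <- cluster_tiles(emb, resolution = config$artifact_resolution,
                          k = config$k_neighbors, metric = config$metric,
                          seed = substream_seed(config$seed, "overcluster"))
    cand <- propose_artifact_clusters(
      over, if (!is.null(res$tiles)) res$tiles else cohort$tiles)
    flagged <- cand$hpc_id[!is.na(cand$mean_luminance) &
                             cand$mean_luminance >= config$artifact_luminance]
    if (!length(flagged) && any(!is.na(cand$artifact_purity))) {
      flagged <- cand$hpc_id[cand$artifact_purity > 0.5]
    }
    if (!config$filter_artifacts) flagged <- integer(0)
    retained <- filter_artifact_hpcs(over, flagged)
    res$artifact_pass <- list(assignment = over, candidates = cand,
                              flagged = flagged)
    emb2 <- filter(emb, tile_id %in% retained$tile_id)
    res$sweep <- resolution_sweep(emb2, cohort$manifest,
                                  resolutions = config$resolutions,
                                  k = config$k_neighbors,
                                  metric = config$metric,
                                  seed = substream_seed(config$seed, "sweep"))
    res$resolution <- select_resolution(res$sweep)
    res$assignment <- cluster_tiles(
      emb2, resolution = res$resolution, k = config$k_neighbors,
      metric = config$metric,
      seed = substream_seed(config$seed, "final_cluster"))
    write_stage(config$out_dir, "assignments.tsv",
                res$assignment, config)
    write_stage(config$out_dir, "resolution_sweep.tsv", res$sweep, config)
  }

  if (on("represent")) {
    asn <- need("assignment", "represent")
    cohort <- need("cohort", "represent")
    res$compositions <- list(
      slide = slide_composition(asn),
      patient = patient_composition(asn, cohort$manifest))
    res$clr <- clr_transform(res$compositions$patient)
    write_stage(config$out_dir, "patient_composition.tsv",
                res$compositions$patient, config)
    write_stage(config$out_dir, "patient_clr.tsv", res$clr, config)
  }

  if (on("model")) {
    clr <- need("clr", "model")
    cohort <- need("cohort", "model")
    pm <- patient_manifest(cohort$manifest)
    data <- left_join(rename(clr, patient_id = entity_id), pm,
                      by = "patient_id")
    res$folds <- make_folds(pm, n_folds = config$n_folds,
                            seed = substream_seed(config$seed, "folds"),
                            km_tolerance = config$km_tolerance)
    res$cv_logistic <- tryCatch(
      cross_validate(data, res$folds, "logistic",
                     alpha = config$logistic_alpha,
                     l1_ratio = config$logistic_l1_ratio),
      error = function(e) {
        warn(paste("Logistic CV failed:", conditionMessage(e)))
        NULL
      })
    res$cv_cox <- cross_validate(data, res$folds, "cox",
                                 alpha = config$cox_alpha,
                                 l1_ratio = config$cox_l1_ratio)
    if (!is.null(res$cv_logistic)) {
      write_stage(config$out_dir, "cv_logistic_metrics.tsv",
                  res$cv_logistic$metrics, config)
    }
    write_stage(config$out_dir, "cv_cox_metrics.tsv", res$cv_cox$metrics,
                config)
  }

  if (on("interpret")) {
    cv <- need("cv_cox", "interpret")
    comps <- need("compositions", "interpret")
    asn <- need("assignment", "interpret")
    cohort <- need("cohort", "interpret")
    clr <- res$clr
    folds <- res$folds
    shap <- lapply(names(cv$fits), function(f) {
      te_ids <- folds$patient_id[folds$fold == as.integer(f) &
                                   folds$split == "test"]
      tr_ids <- folds$patient_id[folds$fold == as.integer(f) &
                                   folds$split == "train"]
      linear_shap(cv$fits[[f]], filter(clr, entity_id %in% te_ids),
                  background = filter(clr, entity_id %in% tr_ids))
    })
    forest <- forest_summary(cv, comps$patient)
    pm <- patient_manifest(cohort$manifest)
    poor <- filter(pm, outcome == "poor")
    spearman <- NULL
    if (nrow(poor) >= 3 && length(unique(poor$outcome_subtype)) >= 2) {
      pc <- filter(comps$patient, entity_id %in% poor$patient_id)
      target <- as.integer(
        poor$outcome_subtype[match(pc$entity_id, poor$patient_id)] != "LR")
      spearman <- spearman_enrichment(pc, target)
    }
    interactions <- adjacency_interactions(asn)
    res$interpretation <- list(shap = shap, forest = forest,
                               spearman = spearman,
                               interactions = interactions)
    write_stage(config$out_dir, "forest_summary.tsv", forest, config)
    if (!is.null(spearman)) {
      write_stage(config$out_dir, "spearman_subtype.tsv", spearman, config)
    }
    if (!is.null(config$out_dir)) {
      hm_slide <- asn$slide_id[1]
      hm <- hpc_heatmap_export(asn, hm_slide,
                               path = file.path(config$out_dir,
                                                "heatmap_example.png"))
      write_stage(config$out_dir, "heatmap_example_legend.tsv", hm$legend,
                  config)
    }
  }

  if (!is.null(config$out_dir)) {
    write_stage(config$out_dir, "run_info.json", res$provenance, config)
  }
  structure(res, class = "hpl_run")
}

#' @export
print.hpl_run <- function(x, ...) {
  done <- intersect(c("cohort", "tiles", "embeddings", "assignment",
                      "compositions", "cv_cox", "interpretation"), names(x))
  cat(sprintf("<hpl_run> seed %d, config %s; artifacts: %s\n",
              x$config$seed, x$provenance$config_hash,
              paste(done, collapse = ", ")))
  invisible(x)
}

#' Validate a cohort manifest
#'
#' Schema and consistency checks: required columns, duplicated slide rows,
#' patients spanning institutions, invalid outcome or subtype codes, negative
#' or missing survival times with recorded events, inconsistent event/outcome
#' pairs.
#'
#' @param manifest Manifest tibble or path to a manifest TSV.
#' @return Tibble of violations (`rule`, `message`, `n`); zero rows when the
#'   manifest is clean.
#' @export
validate_manifest <- function(manifest) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) abort(sprintf("No file at %s.", manifest))
    manifest <- readr::read_tsv(manifest, show_col_types = FALSE)
  }
  v <- list()
  add <- function(rule, message, n) {
    v[[length(v) + 1]] <<- tibble(rule = rule, message = message,
                                  n = as.integer(n))
  }
  required <- c("patient_id", "institution", "slide_id", "outcome",
                "outcome_subtype", "dfs_months", "event")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols)) {
    add("schema", paste("Missing columns:",
                        paste(missing_cols, collapse = ", ")),
        length(missing_cols))
    return(bind_rows(v))
  }
  dup <- manifest %>% count(slide_id) %>% filter(n > 1)
  if (nrow(dup)) add("duplicate_slide", "Duplicated slide rows", nrow(dup))
  multi_inst <- manifest %>% distinct(patient_id, institution) %>%
    count(patient_id) %>% filter(n > 1)
  if (nrow(multi_inst)) {
    add("patient_institution", "Patients listed under several institutions",
        nrow(multi_inst))
  }
  bad_outcome <- !manifest$outcome %in% c("good", "poor")
  if (any(bad_outcome)) add("outcome_values", "Outcome not good/poor",
                            sum(bad_outcome))
  bad_sub <- !manifest$outcome_subtype %in% c("none", "LR", "NM", "DM", "DSD")
  if (any(bad_sub)) add("subtype_values", "Invalid outcome subtype",
                        sum(bad_sub))
  bad_event <- !manifest$event %in% c(0, 1)
  if (any(bad_event)) add("event_values", "Event flag not 0/1",
                          sum(bad_event))
  miss_t <- manifest$event == 1 & (is.na(manifest$dfs_months))
  if (any(miss_t, na.rm = TRUE)) {
    add("event_time", "event = 1 with missing dfs_months",
        sum(miss_t, na.rm = TRUE))
  }
  neg_t <- !is.na(manifest$dfs_months) & manifest$dfs_months < 0
  if (any(neg_t)) add("negative_time", "Negative dfs_months", sum(neg_t))
  incons <- manifest$event == 1 & manifest$outcome == "good"
  if (any(incons, na.rm = TRUE)) {
    add("event_outcome", "event = 1 on a good-outcome patient",
        sum(incons, na.rm = TRUE))
  }
  if (!length(v)) {
    return(tibble(rule = character(), message = character(), n = integer()))
  }
  bind_rows(v)
}
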