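# shared fixtures, generated in code

small_cohort_config <- function(seed = 7, ...) {
  synthetic_config(n_patients = c(NYU = 5, UCSF = 8, BWH = 5),
                   tiles_per_slide = c(9L, 16L), seed = seed, ...)
}

# perfect assignment from ground truth (artifacts dropped), as if clustering
# had recovered the planted phenotypes exactly
truth_assignment <- function(cohort) {
  dplyr::transmute(dplyr::filter(cohort$tiles, !is_artifact),
                   tile_id, slide_id, hpc_id = phenotype - 1L)
}

# patient-level CLR + outcome table ready for cross_validate()
model_data <- function(cohort) {
  asn <- truth_assignment(cohort)
  clr <- clr_transform(patient_composition(asn, cohort$manifest))
  dplyr::left_join(dplyr::rename(clr, patient_id = entity_id),
                   patient_manifest(cohort$manifest), by = "patient_id")
}

# checkerboard assignment on one slide
checkerboard_assignment <- function(n = 10) {
  g <- tidyr::expand_grid(grid_row = 0:(n - 1), grid_col = 0:(n - 1))
  dplyr::mutate(g, slide_id = "board",
                tile_id = sprintf("b_%d_%d", grid_row, grid_col),
                hpc_id = (grid_row + grid_col) %% 2L)
}

# zero-mean mutually orthogonal columns (orthogonal polynomial contrasts):
# after batch normalization the cross-correlation of the batch with itself is
# the identity to machine precision
whitened_batch <- function(n, d) {
  matrix(stats::poly(seq_len(n), degree = d), n, d)
}
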