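#' @keywords internal
"_PACKAGE"

#' @import rlang
#' @importFrom dplyr %>% arrange bind_cols bind_rows count distinct filter
#'   group_by left_join mutate n pull rename row_number select summarise
#'   ungroup
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median pchisq pnorm quantile rbinom rexp rgamma rnorm
#'   runif sd setNames cor.test p.adjust glm binomial coef predict hclust
#'   as.dist cutree
NULL

#' @export
dplyr::`%>%`

utils::globalVariables(c(
  ".", "patient_id", "slide_id", "tile_id", "grid_row", "grid_col",
  "institution", "outcome", "outcome_subtype", "dfs_months", "event",
  "hpc_id", "phenotype", "is_artifact", "n_tiles", "kept", "value",
  "proportion", "entity_id", "fold", "split", "time", "surv", "group",
  "hpc", "p_value", "q_value", "rho", "estimate", "metric", "n_slides",
  "background_fraction", "prop", "presence_any", "presence_1pct",
  "resolution", "n_clusters", "diagnosis", "pixels", "luminance"
))

# 32-bit FNV-1a hash of a string; used only to derive reproducible
# sub-stream seeds from (seed, entity labels).
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keep h as double (can exceed
    # .Machine$integer.max)
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b %% 256))
    # 32-bit multiply by 16777619 without overflow, via split arithmetic
    lo <- (h %% 65536) * 16777619
    hi <- (h %/% 65536) * 16777619 %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  h
}

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows from one global integer seed; per-entity
#' sub-streams (a patient, a tile, a fold sweep) are derived by hashing the
#' seed together with stable entity labels, so regenerating one entity never
#' perturbs another.
#'
#' @param seed Global integer seed.
#' @param ... Further labels (coerced to character) identifying the stream.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, ...) {
  lab <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "\x1f")
  as.integer(fnv1a32(lab) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Qualitative palette for phenotype clusters
#'
#' @param n Number of colours.
#' @return Character vector of hex colours.
#' @export
hpc_palette <- function(n) {
  stopifnot(n >= 1)
  grDevices::hcl.colors(max(n, 2), palette = "Dark 3")[seq_len(n)]
}

# mean RGB luminance (Rec. 601) of an rgb array in [0, 1]
mean_luminance <- function(px) {
  mean(0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
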