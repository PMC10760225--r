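# Self-supervised tile encoder. The Barlow-Twins objective is implemented
# from its cross-correlation definition, with analytic gradients, and drives
# a small fully-connected encoder suitable for desk-scale experiments. The
# contract downstream modules rely on is only (tile -> z_dim vector).

#' Encoder configuration
#'
#' @param z_dim Embedding dimension (128 by default).
#' @param input_px Tiles are area-averaged down to `input_px x input_px`
#'   before the fully-connected encoder; the feature dimension is
#'   `3 * input_px^2`.
#' @param hidden_dims Integer vector of encoder hidden-layer widths.
#' @param projector_dims Integer vector of projector widths; the loss is
#'   computed on the projector output.
#' @param lambda_offdiag Weight of the off-diagonal term of the loss
#'   (original Barlow-Twins setting 5e-3).
#' @param batch_size,epochs,learning_rate Optimization parameters (Adam).
#' @param train_fraction Fraction of tiles (per institution when a manifest is
#'   supplied) used for training; 0.40 by default.
#' @param augment Named list of augmentation strengths: `crop` (max fraction
#'   of side length cropped away), `flip` (probability of horizontal mirror),
#'   `jitter` (colour gain/offset half-range), `blur` (gaussian sigma in
#'   pixels; applied with probability 1/2 when positive). All zero gives
#'   identity views.
#' @param seed Integer seed for initialization, view sampling and batching.
#' @return A list of class `hpl_encoder_config`.
#' @export
encoder_config <- function(z_dim = 128L, input_px = 12L,
                           hidden_dims = c(256L), projector_dims = c(128L),
                           lambda_offdiag = 5e-3, batch_size = 128L,
                           epochs = 5L, learning_rate = 1e-3,
                           train_fraction = 0.4,
                           augment = list(crop = 0.3, flip = 0.5,
                                          jitter = 0.2, blur = 0.8),
                           seed = 1L) {
  stopifnot(z_dim >= 2, lambda_offdiag > 0,
            train_fraction > 0, train_fraction <= 1, batch_size >= 2)
  structure(list(z_dim = as.integer(z_dim), input_px = as.integer(input_px),
                 hidden_dims = as.integer(hidden_dims),
                 projector_dims = as.integer(projector_dims),
                 lambda_offdiag = lambda_offdiag,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 train_fraction = train_fraction,
                 augment = utils::modifyList(list(crop = 0, flip = 0,
                                                  jitter = 0, blur = 0),
                                             augment),
                 seed = as.integer(seed)),
            class = "hpl_encoder_config")
}

# cached interpolation weights (resize is called thousands of times in training)
.interp_cache <- new.env(parent = emptyenv())
cached_interp <- function(n_old, n_new) {
  key <- paste0(n_old, "_", n_new)
  w <- .interp_cache[[key]]
  if (is.null(w)) {
    w <- interp_weights(n_old, n_new)
    .interp_cache[[key]] <- w
  }
  w
}

resize_rgb_cached <- function(pixels, new_h, new_w) {
  d <- dim(pixels)
  Wh <- cached_interp(d[1], new_h)
  Ww <- cached_interp(d[2], new_w)
  out <- array(0, dim = c(new_h, new_w, 3))
  for (ch in 1:3) out[, , ch] <- Wh %*% pixels[, , ch] %*% t(Ww)
  out
}

gaussian_blur3 <- function(px, sigma) {
  k <- exp(-(c(-1, 0, 1)^2) / (2 * sigma^2))
  k <- k / sum(k)
  blur1 <- function(m) {
    h <- nrow(m); w <- ncol(m)
    p <- m[c(1, seq_len(h), h), c(1, seq_len(w), w)]
    horiz <- k[1] * p[, 1:w] + k[2] * p[, 2:(w + 1)] + k[3] * p[, 3:(w + 2)]
    k[1] * horiz[1:h, ] + k[2] * horiz[2:(h + 1), ] + k[3] * horiz[3:(h + 2), ]
  }
  out <- px
  for (ch in 1:3) out[, , ch] <- blur1(px[, , ch])
  out
}

augment_once <- function(px, a) {
  d <- dim(px)
  if (a$crop > 0) {
    keep <- 1 - runif(1, 0, a$crop)
    ch <- max(2L, round(d[1] * keep)); cw <- max(2L, round(d[2] * keep))
    r0 <- sample.int(d[1] - ch + 1L, 1L) - 1L
    c0 <- sample.int(d[2] - cw + 1L, 1L) - 1L
    px <- resize_rgb_cached(px[r0 + seq_len(ch), c0 + seq_len(cw), ,
                               drop = FALSE], d[1], d[2])
  }
  if (a$flip > 0 && runif(1) < a$flip) px <- px[, rev(seq_len(dim(px)[2])), , drop = FALSE]
  if (a$jitter > 0) {
    gain <- 1 + runif(3, -a$jitter, a$jitter)
    offs <- runif(3, -a$jitter, a$jitter) / 2
    for (ch in 1:3) px[, , ch] <- px[, , ch] * gain[ch] + offs[ch]
    px <- pmin(pmax(px, 0), 1)
  }
  if (a$blur > 0 && runif(1) < 0.5) px <- gaussian_blur3(px, a$blur)
  px
}

#' Generate the two distorted views of a tile
#'
#' Two stochastic augmentations (crop-resize, horizontal flip, colour jitter,
#' gaussian blur) with independent sub-seeds; deterministic for a given seed.
#' With all strengths zero both views equal the input.
#'
#' @param pixels `h x w x 3` RGB array in `[0, 1]`.
#' @param seed Integer seed.
#' @param augment Strength list as in [encoder_config()].
#' @return `list(viewA =, viewB =)`.
#' @export
make_views <- function(pixels, seed, augment = encoder_config()$augment) {
  a <- utils::modifyList(list(crop = 0, flip = 0, jitter = 0, blur = 0), augment)
  list(viewA = with_seed(substream_seed(seed, "viewA"), augment_once(pixels, a)),
       viewB = with_seed(substream_seed(seed, "viewB"), augment_once(pixels, a)))
}

# column batch-normalization (population variance); errors on a (near-)
# zero-variance column, naming it, so no eps is folded into the scale and the
# loss-zero identity is exact
bt_normalize <- function(Z, eps = 1e-12, label = "Z") {
  mu <- colMeans(Z)
  v <- colMeans(sweep(Z, 2, mu)^2)
  zero <- which(v <= eps)
  if (length(zero)) {
    abort(sprintf("Zero-variance column %d in %s; cannot batch-normalize.",
                  zero[1], label))
  }
  s <- sqrt(v)
  list(hat = sweep(sweep(Z, 2, mu), 2, s, "/"), mu = mu, s = s, v = v)
}

#' Barlow-Twins loss from the empirical cross-correlation
#'
#' Both embedding batches are batch-normalized per column, the empirical
#' cross-correlation `C = t(ZA_hat) %*% ZB_hat / n` is formed, and the loss
#' pushes `C` towards the identity:
#' `total = sum((1 - diag(C))^2) + lambda * sum(offdiag(C)^2)`.
#' The loss is zero exactly when `C` is the identity.
#'
#' @param ZA,ZB `n x d` embedding matrices of the two views (`n >= 2`).
#' @param lambda Off-diagonal weight.
#' @param return_grad If `TRUE`, analytic gradients of the total loss with
#'   respect to the raw `ZA` and `ZB` (through the batch normalization) are
#'   attached as `grad_ZA`, `grad_ZB`.
#' @return A list of class `hpl_bt_loss` with `C`, `on_diag_term`,
#'   `off_diag_term`, `total` (and gradients when requested).
#' @export
barlow_twins_loss <- function(ZA, ZB, lambda = 5e-3, return_grad = FALSE) {
  stopifnot(is.matrix(ZA), is.matrix(ZB), all(dim(ZA) == dim(ZB)),
            nrow(ZA) >= 2, lambda > 0)
  n <- nrow(ZA); d <- ncol(ZA)
  na <- bt_normalize(ZA, label = "ZA")
  nb <- bt_normalize(ZB, label = "ZB")
  C <- crossprod(na$hat, nb$hat) / n
  on_diag <- sum((1 - diag(C))^2)
  off <- C; diag(off) <- 0
  off_diag <- sum(off^2)
  out <- structure(list(C = C, on_diag_term = on_diag, off_diag_term = off_diag,
                        total = on_diag + lambda * off_diag, lambda = lambda),
                   class = "hpl_bt_loss")
  if (return_grad) {
    G <- 2 * lambda * off
    diag(G) <- -2 * (1 - diag(C))
    dA_hat <- nb$hat %*% t(G) / n
    dB_hat <- na$hat %*% G / n
    bn_back <- function(dhat, nz) {
      centered <- dhat - matrix(colMeans(dhat), n, d, byrow = TRUE) -
        nz$hat * matrix(colMeans(dhat * nz$hat), n, d, byrow = TRUE)
      sweep(centered, 2, nz$s, "/")
    }
    out$grad_ZA <- bn_back(dA_hat, na)
    out$grad_ZB <- bn_back(dB_hat, nb)
  }
  out
}

#' @export
print.hpl_bt_loss <- function(x, ...) {
  cat(sprintf("<barlow-twins loss> total %.5f (on-diag %.5f, off-diag %.5f, lambda %.3g)\n",
              x$total, x$on_diag_term, x$off_diag_term, x$lambda))
  invisible(x)
}

# --- tiny fully-connected network -------------------------------------------

init_mlp <- function(dims, seed) {
  with_seed(seed, {
    lapply(seq_len(length(dims) - 1), function(l) {
      fan_in <- dims[l]
      list(W = matrix(rnorm(fan_in * dims[l + 1], sd = sqrt(2 / fan_in)),
                      fan_in, dims[l + 1]),
           b = rep(0, dims[l + 1]))
    })
  })
}

mlp_forward <- function(layers, X) {
  acts <- list(X)
  L <- length(layers)
  for (l in seq_len(L)) {
    Z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    acts[[l + 1]] <- if (l < L) pmax(Z, 0) else Z
  }
  acts
}

mlp_backward <- function(layers, acts, dOut) {
  L <- length(layers)
  grads <- vector("list", L)
  d <- dOut
  for (l in rev(seq_len(L))) {
    if (l < L) d <- d * (acts[[l + 1]] > 0)
    grads[[l]] <- list(W = crossprod(acts[[l]], d), b = colSums(d))
    if (l > 1) d <- d %*% t(layers[[l]]$W)
  }
  grads
}

adam_state <- function(layers) {
  lapply(layers, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(layers, grads, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  for (l in seq_along(layers)) {
    st[[l]]$mW <- b1 * st[[l]]$mW + (1 - b1) * grads[[l]]$W
    st[[l]]$vW <- b2 * st[[l]]$vW + (1 - b2) * grads[[l]]$W^2
    st[[l]]$mb <- b1 * st[[l]]$mb + (1 - b1) * grads[[l]]$b
    st[[l]]$vb <- b2 * st[[l]]$vb + (1 - b2) * grads[[l]]$b^2
    corr <- lr * sqrt(1 - b2^t) / (1 - b1^t)
    layers[[l]]$W <- layers[[l]]$W - corr * st[[l]]$mW / (sqrt(st[[l]]$vW) + eps)
    layers[[l]]$b <- layers[[l]]$b - corr * st[[l]]$mb / (sqrt(st[[l]]$vb) + eps)
  }
  list(layers = layers, st = st)
}

tile_features <- function(pixels, input_px) {
  small <- resize_rgb_cached(pixels, input_px, input_px)
  as.numeric(small) - 0.5
}

#' Train the Barlow-Twins tile encoder
#'
#' Draws a training subset (per institution when a manifest links slides to
#' institutions) at `train_fraction`, then minimizes the Barlow-Twins loss of
#' the two augmented views by mini-batch Adam. Pure R numerics: runs are
#' bit-reproducible for a fixed seed.
#'
#' @param tiles Tile table with `tile_id`, `slide_id` and `pixels` columns
#'   (kept tiles only are used when a `kept` column is present).
#' @param config An [encoder_config()] object.
#' @param manifest Optional per-slide manifest supplying `institution`.
#' @return A list of class `hpl_encoder`: encoder and projector weights, the
#'   config, and the per-epoch loss trace (`epoch`, `total`, `on_diag`,
#'   `off_diag`). With `epochs = 0` the randomly initialized state is
#'   returned with an empty trace.
#' @export
train_encoder <- function(tiles, config = encoder_config(), manifest = NULL) {
  if ("kept" %in% names(tiles)) tiles <- filter(tiles, kept)
  if (!nrow(tiles)) abort("No tiles to train on.")
  sel <- with_seed(substream_seed(config$seed, "train_subset"), {
    if (!is.null(manifest)) {
      inst <- manifest$institution[match(tiles$slide_id, manifest$slide_id)]
      unlist(lapply(split(seq_len(nrow(tiles)), inst), function(ix) {
        sample(ix, max(1, round(length(ix) * config$train_fraction)))
      }), use.names = FALSE)
    } else {
      sample(seq_len(nrow(tiles)),
             max(1, round(nrow(tiles) * config$train_fraction)))
    }
  })
  train <- tiles[sort(sel), ]
  if (nrow(train) < config$batch_size) {
    abort(sprintf("Fewer training tiles (%d) than batch_size (%d).",
                  nrow(train), config$batch_size))
  }
  feat_dim <- 3 * config$input_px^2
  enc_dims <- c(feat_dim, config$hidden_dims, config$z_dim)
  proj_dims <- c(config$z_dim, config$projector_dims)
  enc <- init_mlp(enc_dims, substream_seed(config$seed, "enc_init"))
  proj <- if (length(proj_dims) > 1) {
    init_mlp(proj_dims, substream_seed(config$seed, "proj_init"))
  } else {
    list()
  }
  st_enc <- adam_state(enc)
  st_proj <- if (length(proj)) adam_state(proj) else list()
  trace <- list()
  t_global <- 0
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(substream_seed(config$seed, "epoch_order", epoch),
                     sample(nrow(train)))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    batches <- batches[lengths(batches) >= 2]
    ep_tot <- ep_on <- ep_off <- 0
    for (bi in seq_along(batches)) {
      ix <- batches[[bi]]
      XA <- matrix(0, length(ix), feat_dim)
      XB <- matrix(0, length(ix), feat_dim)
      for (r in seq_along(ix)) {
        v <- make_views(train$pixels[[ix[r]]],
                        substream_seed(config$seed, "view", epoch,
                                       train$tile_id[ix[r]]),
                        config$augment)
        XA[r, ] <- tile_features(v$viewA, config$input_px)
        XB[r, ] <- tile_features(v$viewB, config$input_px)
      }
      actsA_e <- mlp_forward(enc, XA); actsB_e <- mlp_forward(enc, XB)
      ZA <- actsA_e[[length(actsA_e)]]; ZB <- actsB_e[[length(actsB_e)]]
      if (length(proj)) {
        actsA_p <- mlp_forward(proj, ZA); actsB_p <- mlp_forward(proj, ZB)
        PA <- actsA_p[[length(actsA_p)]]; PB <- actsB_p[[length(actsB_p)]]
      } else {
        PA <- ZA; PB <- ZB
      }
      loss <- barlow_twins_loss(PA, PB, config$lambda_offdiag,
                                return_grad = TRUE)
      ep_tot <- ep_tot + loss$total
      ep_on <- ep_on + loss$on_diag_term
      ep_off <- ep_off + loss$off_diag_term
      if (length(proj)) {
        gpA <- mlp_backward(proj, actsA_p, loss$grad_ZA)
        gpB <- mlp_backward(proj, actsB_p, loss$grad_ZB)
        gproj <- purrr::map2(gpA, gpB, function(a, b)
          list(W = a$W + b$W, b = a$b + b$b))
        dZA <- backprop_input(proj, actsA_p, loss$grad_ZA)
        dZB <- backprop_input(proj, actsB_p, loss$grad_ZB)
      } else {
        gproj <- NULL
        dZA <- loss$grad_ZA
        dZB <- loss$grad_ZB
      }
      geA <- mlp_backward(enc, actsA_e, dZA)
      geB <- mlp_backward(enc, actsB_e, dZB)
      genc <- purrr::map2(geA, geB, function(a, b)
        list(W = a$W + b$W, b = a$b + b$b))
      t_global <- t_global + 1
      up <- adam_step(enc, genc, st_enc, config$learning_rate, t_global)
      enc <- up$layers; st_enc <- up$st
      if (length(proj)) {
        up <- adam_step(proj, gproj, st_proj, config$learning_rate, t_global)
        proj <- up$layers; st_proj <- up$st
      }
    }
    nb <- length(batches)
    trace[[epoch]] <- tibble(epoch = epoch, total = ep_tot / nb,
                             on_diag = ep_on / nb, off_diag = ep_off / nb)
  }
  structure(list(encoder = enc, projector = proj, config = config,
                 loss_trace = bind_rows(trace),
                 n_train_tiles = nrow(train)),
            class = "hpl_encoder")
}

# gradient of a (possibly multi-layer) mlp w.r.t. its input
backprop_input <- function(layers, acts, dOut) {
  L <- length(layers)
  d <- dOut
  for (l in rev(seq_len(L))) {
    if (l < L) d <- d * (acts[[l + 1]] > 0)
    d <- d %*% t(layers[[l]]$W)
  }
  d
}

#' @export
print.hpl_encoder <- function(x, ...) {
  last <- if (nrow(x$loss_trace)) sprintf("final loss %.4f",
                                          utils::tail(x$loss_trace$total, 1))
          else "untrained"
  cat(sprintf("<hpl_encoder> z_dim %d, %d train tiles, %d epochs (%s)\n",
              x$config$z_dim, x$n_train_tiles, nrow(x$loss_trace), last))
  invisible(x)
}

#' Project tiles onto the trained encoder
#'
#' Deterministic: augmentations are disabled; duplicate tiles map to identical
#' embeddings.
#'
#' @param tiles Tile table with `tile_id` and `pixels` (kept tiles only when a
#'   `kept` column is present).
#' @param state An `hpl_encoder` from [train_encoder()].
#' @return Tibble with `tile_id`, `slide_id`, grid coordinates when available,
#'   and `z_dim` embedding columns `z001`, `z002`, ...
#' @export
embed_tiles <- function(tiles, state) {
  stopifnot(inherits(state, "hpl_encoder"))
  if ("kept" %in% names(tiles)) tiles <- filter(tiles, kept)
  if (!nrow(tiles)) abort("No tiles to embed.")
  if (any(vapply(tiles$pixels, is.null, TRUE))) {
    bad <- unique(tiles$slide_id[vapply(tiles$pixels, is.null, TRUE)])
    abort(paste0("Missing pixel data for slides: ",
                 paste(bad, collapse = ", ")))
  }
  X <- t(vapply(tiles$pixels, tile_features, numeric(3 * state$config$input_px^2),
                input_px = state$config$input_px))
  acts <- mlp_forward(state$encoder, X)
  Z <- acts[[length(acts)]]
  colnames(Z) <- sprintf("z%03d", seq_len(ncol(Z)))
  keep_cols <- intersect(c("tile_id", "slide_id", "grid_row", "grid_col"),
                         names(tiles))
  bind_cols(tiles[keep_cols], as_tibble(Z))
}

#' Ground-truth-structured synthetic embeddings (encoder bypass)
#'
#' Draws one Gaussian-mixture embedding per label: each distinct label gets a
#' mean vector of norm `separation` (random direction) and unit isotropic
#' noise. Lets clustering and statistics be tested independently of encoder
#' training stochasticity.
#'
#' @param labels Vector of phenotype labels (one per tile).
#' @param z_dim Embedding dimension.
#' @param separation Distance of each cluster mean from the origin.
#' @param seed Integer seed.
#' @return `length(labels) x z_dim` matrix.
#' @export
synthetic_embeddings <- function(labels, z_dim = 128L, separation = 8,
                                 seed = 1L) {
  labs <- sort(unique(labels))
  centers <- with_seed(substream_seed(seed, "centers"), {
    m <- matrix(rnorm(length(labs) * z_dim), length(labs), z_dim)
    m / sqrt(rowSums(m^2)) * separation
  })
  rownames(centers) <- as.character(labs)
  out <- with_seed(substream_seed(seed, "noise"), {
    centers[as.character(labels), , drop = FALSE] +
      matrix(rnorm(length(labels) * z_dim), length(labels), z_dim)
  })
  rownames(out) <- NULL
  out
}

#' Synthetic embeddings for a whole cohort
#'
#' Applies [synthetic_embeddings()] to a cohort's true tile phenotypes
#' (artifact tiles form their own cluster), returning the same tabular shape
#' as [embed_tiles()].
#'
#' @param cohort An `hpl_cohort`.
#' @param z_dim,separation,seed Passed to [synthetic_embeddings()].
#' @return Tibble with tile identifiers, `phenotype`, `is_artifact` and
#'   embedding columns.
#' @export
cohort_embeddings <- function(cohort, z_dim = 128L, separation = 8,
                              seed = cohort$config$seed) {
  tiles <- cohort$tiles
  labels <- ifelse(tiles$is_artifact, "artifact", as.character(tiles$phenotype))
  Z <- synthetic_embeddings(labels, z_dim, separation, seed)
  colnames(Z) <- sprintf("z%03d", seq_len(ncol(Z)))
  bind_cols(select(tiles, tile_id, slide_id, grid_row, grid_col,
                   phenotype, is_artifact),
            as_tibble(Z))
}

#' Extract the embedding matrix from an embedding tibble
#'
#' @param embeddings Tibble with `z...` columns (or already a matrix).
#' @return Numeric matrix with `tile_id` rownames when available.
#' @export
embedding_matrix <- function(embeddings) {
  if (is.matrix(embeddings)) return(embeddings)
  zc <- grep("^z[0-9]+$", names(embeddings), value = TRUE)
  m <- as.matrix(embeddings[zc])
  if ("tile_id" %in% names(embeddings)) rownames(m) <- embeddings$tile_id
  m
}

#' Save / load encoder state
#'
#' The state is serialized as versioned JSON (plain text).
#'
#' @param state An `hpl_encoder`.
#' @param path File path.
#' @return `write_encoder` returns `path` invisibly; `read_encoder` the state.
#' @export
write_encoder <- function(state, path) {
  payload <- list(
    format = "hplkit-encoder-v1",
    config = unclass(state$config),
    n_train_tiles = state$n_train_tiles,
    loss_trace = state$loss_trace,
    encoder = lapply(state$encoder, function(l)
      list(W = as.numeric(l$W), dim = dim(l$W), b = l$b)),
    projector = lapply(state$projector, function(l)
      list(W = as.numeric(l$W), dim = dim(l$W), b = l$b))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_encoder
#' @export
read_encoder <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "hplkit-encoder-v1")) {
    abort("Not a recognized encoder state file.")
  }
  rebuild <- function(raw) {
    if (is.null(raw) || length(raw) == 0) return(list())
    if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
    lapply(raw, function(l) list(W = matrix(unlist(l$W), unlist(l$dim)[1],
                                            unlist(l$dim)[2]),
                                 b = unlist(l$b)))
  }
  cfg <- p$config
  cfg$augment <- as.list(cfg$augment)
  structure(list(encoder = rebuild(p$encoder), projector = rebuild(p$projector),
                 config = structure(cfg, class = "hpl_encoder_config"),
                 loss_trace = as_tibble(p$loss_trace),
                 n_train_tiles = p$n_train_tiles),
            class = "hpl_encoder")
}
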