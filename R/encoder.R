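# im2col index maps, cached per input geometry ---------------------------

.im2col_cache <- new.env(parent = emptyenv())

# index matrix (Cin*k*k) x (Ho*Wo) into the zero-padded flat input
im2col_idx <- function(cin, h, w, k, stride, pad) {
  key <- paste(cin, h, w, k, stride, pad, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  hp <- h + 2L * pad; wp <- w + 2L * pad
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  c_r <- rep(seq_len(cin), times = k * k)
  ki_r <- rep(rep(seq_len(k), each = cin), times = k)
  kj_r <- rep(seq_len(k), each = cin * k)
  oi <- rep(seq_len(ho), times = wo)
  oj <- rep(seq_len(wo), each = ho)
  i_mat <- outer(ki_r, (oi - 1L) * stride, `+`)
  j_mat <- outer(kj_r, (oj - 1L) * stride, `+`)
  idx <- c_r + (i_mat - 1L) * cin + (j_mat - 1L) * (cin * hp)
  out <- list(idx = idx, ho = ho, wo = wo, hp = hp, wp = wp)
  .im2col_cache[[key]] <- out
  out
}

pad_chw <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, dim = c(d[1], d[2] + 2L * pad, d[3] + 2L * pad))
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3])] <- x
  xp
}

#' Initialize the compact convolutional encoder
#'
#' A small randomly initialized fully-convolutional backbone honouring the
#' fixed feature contract: 3-channel input, 256 output channels, spatial
#' downsampling by exactly 8. Three stride-2 3x3 convolutions (He-initialized,
#' ReLU) are followed by a linear 1x1 projection to 256 channels. The encoder
#' is pluggable: anything producing `(batch, 256, H/8, W/8)` features can
#' stand behind the same contract.
#'
#' @param seed RNG seed for the weight draw.
#' @param hidden channel widths of the three stride-2 stages.
#' @param out_channels output channels (default 256, the prototype length).
#' @return a `proto_encoder` object (list of layers).
#' @export
encoder_init <- function(seed = 1L, hidden = c(16L, 32L, 64L),
                         out_channels = 256L) {
  stopifnot(length(hidden) == 3)
  with_local_seed(seed, {
    mk <- function(cin, cout, k, stride, pad, act) {
      fan_in <- cin * k * k
      sd <- sqrt(2 / fan_in)
      list(w = matrix(rnorm(cout * fan_in, 0, sd), cout, fan_in),
           b = runif(cout, -0.1, 0.1),  # nonzero: breaks scale homogeneity
           k = k, stride = stride, pad = pad, act = act, cin = cin, cout = cout)
    }
    layers <- list(
      mk(3L, hidden[1], 3L, 2L, 1L, "relu"),
      mk(hidden[1], hidden[2], 3L, 2L, 1L, "relu"),
      mk(hidden[2], hidden[3], 3L, 2L, 1L, "relu"),
      mk(hidden[3], out_channels, 1L, 1L, 0L, "linear"))
    structure(list(layers = layers, out_channels = as.integer(out_channels)),
              class = "proto_encoder")
  })
}

# forward pass for one (C,H,W) image; returns features and optional cache
encode_one <- function(enc, x, keep_cache = FALSE) {
  cache <- if (keep_cache) vector("list", length(enc$layers)) else NULL
  for (li in seq_along(enc$layers)) {
    ly <- enc$layers[[li]]
    d <- dim(x)
    im <- im2col_idx(d[1], d[2], d[3], ly$k, ly$stride, ly$pad)
    xp <- pad_chw(x, ly$pad)
    cols <- matrix(as.vector(xp)[im$idx], nrow = nrow(im$idx))
    z <- ly$w %*% cols + ly$b
    a <- if (ly$act == "relu") pmax(z, 0) else z
    if (keep_cache)
      cache[[li]] <- list(cols = cols, pos = if (ly$act == "relu") z > 0 else NULL,
                          in_dim = d)
    x <- array(a, dim = c(ly$cout, im$ho, im$wo))
  }
  list(features = x, cache = cache)
}

#' Encode an image batch into dense feature grids
#'
#' Maps a batch of 3-channel images with side divisible by 8 to feature grids
#' of shape `(batch, 256, H/8, W/8)`. Deterministic for fixed weights (the
#' encoder has no stochastic layers).
#'
#' @param enc a `proto_encoder`.
#' @param batch `N x 3 x H x W` numeric array.
#' @param keep_cache keep per-image intermediates for backpropagation.
#' @return `N x 256 x H/8 x W/8` array; when `keep_cache = TRUE`, the cache is
#'   attached as attribute `"cache"`.
#' @export
encode <- function(enc, batch, keep_cache = FALSE) {
  stopifnot(inherits(enc, "proto_encoder"))
  d <- dim(batch)
  if (length(d) != 4) stop("batch must be a 4-D array (N x C x H x W)")
  if (d[2] != 3) stop("encoder expects 3-channel input, got ", d[2])
  if (d[3] %% 8 != 0 || d[4] %% 8 != 0)
    stop("image sides must be divisible by 8, got ", d[3], "x", d[4])
  out <- array(0, dim = c(d[1], enc$out_channels, d[3] %/% 8, d[4] %/% 8))
  caches <- if (keep_cache) vector("list", d[1]) else NULL
  for (n in seq_len(d[1])) {
    r <- encode_one(enc, array(batch[n, , , ], dim = d[2:4]), keep_cache)
    out[n, , , ] <- r$features
    if (keep_cache) caches[[n]] <- r$cache
  }
  if (keep_cache) attr(out, "cache") <- caches
  out
}

# backward pass: dtop is a list of (Cout x P) gradient matrices, one per image
# in the cached batch; returns summed weight/bias gradients per layer
encoder_backward <- function(enc, caches, dtop) {
  nl <- length(enc$layers)
  grads <- lapply(enc$layers, function(ly)
    list(dw = matrix(0, nrow(ly$w), ncol(ly$w)), db = numeric(length(ly$b))))
  for (n in seq_along(caches)) {
    da <- dtop[[n]]  # Cout x P at the top layer
    for (li in rev(seq_len(nl))) {
      ly <- enc$layers[[li]]
      cc <- caches[[n]][[li]]
      dz <- if (ly$act == "relu") da * cc$pos else da
      grads[[li]]$dw <- grads[[li]]$dw + dz %*% t(cc$cols)
      grads[[li]]$db <- grads[[li]]$db + rowSums(dz)
      if (li > 1) {
        d <- cc$in_dim
        im <- im2col_idx(d[1], d[2], d[3], ly$k, ly$stride, ly$pad)
        dcols <- crossprod(ly$w, dz)
        dxp <- numeric(d[1] * im$hp * im$wp)
        for (r in seq_len(nrow(im$idx)))
          dxp[im$idx[r, ]] <- dxp[im$idx[r, ]] + dcols[r, ]
        dxp <- array(dxp, dim = c(d[1], im$hp, im$wp))
        dx <- if (ly$pad > 0)
          dxp[, ly$pad + seq_len(d[2]), ly$pad + seq_len(d[3]), drop = FALSE]
        else dxp
        da <- matrix(dx, nrow = d[1])  # (Cin x P_prev)
      }
    }
  }
  grads
}
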