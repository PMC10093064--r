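#' @importFrom stats plogis quantile rnorm runif setNames
NULL

# Cache of 1-D interpolation operators, keyed by "n_in->n_out".
.interp_cache <- new.env(parent = emptyenv())

#' Linear (align-corners) 1-D interpolation operator
#'
#' Builds the `n_out x n_in` matrix `A` such that `A %*% x` linearly
#' interpolates a signal sampled at `n_in` points onto `n_out` points, with the
#' first and last samples mapped onto each other exactly. When
#' `n_in == n_out` the operator is the exact identity, so resizing to the same
#' size is bitwise lossless. Because the operator is an explicit linear map,
#' its transpose is the exact adjoint used during backpropagation.
#'
#' @param n_in,n_out positive integers.
#' @return an `n_out x n_in` dense matrix with rows summing to 1.
#' @export
interp_matrix_linear <- function(n_in, n_out) {
  stopifnot(n_in >= 1, n_out >= 1)
  key <- paste0(n_in, "->", n_out)
  if (!is.null(.interp_cache[[key]])) return(.interp_cache[[key]])
  A <- matrix(0, n_out, n_in)
  if (n_in == 1L) {
    A[, 1] <- 1
  } else {
    t <- seq(0, n_in - 1, length.out = n_out)
    lo <- pmin(floor(t), n_in - 2)
    w <- t - lo
    A[cbind(seq_len(n_out), lo + 1)] <- 1 - w
    A[cbind(seq_len(n_out), lo + 2)] <- A[cbind(seq_len(n_out), lo + 2)] + w
  }
  .interp_cache[[key]] <- A
  A
}

#' Bilinear resize of a 2-D grid
#'
#' Separable bilinear resampling `A %*% x %*% t(B)` with align-corners
#' convention. Values at grid-aligned points are preserved; an identity resize
#' returns the input exactly; a constant grid stays constant.
#'
#' @param x numeric matrix.
#' @param dims target `c(rows, cols)`.
#' @return resized matrix.
#' @export
resize_bilinear <- function(x, dims) {
  stopifnot(is.matrix(x), length(dims) == 2, all(dims >= 1))
  A <- interp_matrix_linear(nrow(x), dims[1])
  B <- interp_matrix_linear(ncol(x), dims[2])
  A %*% x %*% t(B)
}

# nearest-neighbour source indices under pixel-centre alignment
nearest_index <- function(n_in, n_out) {
  idx <- floor((seq_len(n_out) - 0.5) * n_in / n_out) + 1
  pmin(pmax(idx, 1L), n_in)
}

#' Nearest-neighbour resize of a 2-D grid
#'
#' Used for masks and label slices: the output value set is always a subset of
#' the input value set, so binary masks stay binary and BraTS label values
#' stay in \{0, 1, 2, 4\}.
#'
#' @param x matrix.
#' @param dims target `c(rows, cols)`.
#' @return resized matrix.
#' @export
resize_nearest <- function(x, dims) {
  stopifnot(is.matrix(x), length(dims) == 2, all(dims >= 1))
  x[nearest_index(nrow(x), dims[1]), nearest_index(ncol(x), dims[2]), drop = FALSE]
}

#' Affine warp of a 2-D image about its centre
#'
#' Inverse-mapping warp: for every output pixel the source location under the
#' inverse of rotation ∘ shear followed by translation is sampled, bilinearly
#' for images or by nearest neighbour for masks. Out-of-bounds samples are 0.
#' A zero-amplitude transform reproduces the input exactly.
#'
#' @param x matrix (image or mask slice).
#' @param rotation rotation angle in degrees (counter-clockwise).
#' @param shear shear angle in degrees (applied along the column axis).
#' @param translate length-2 numeric, `c(rows, cols)` shift in pixels.
#' @param filter `"bilinear"` or `"nearest"`.
#' @return warped matrix of the same size.
#' @export
warp_affine <- function(x, rotation = 0, shear = 0, translate = c(0, 0),
                        filter = c("bilinear", "nearest")) {
  filter <- match.arg(filter)
  stopifnot(is.matrix(x), length(translate) == 2)
  h <- nrow(x); w <- ncol(x)
  th <- rotation * pi / 180
  sh <- tan(shear * pi / 180)
  # forward map in (row, col): rotate then shear cols by rows, then translate
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(1, 0, sh, 1), 2, 2)
  M <- R %*% S
  Minv <- solve(M)
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  gr <- rep(seq_len(h), times = w) - cr - translate[1]
  gc <- rep(seq_len(w), each = h) - cc - translate[2]
  sr <- Minv[1, 1] * gr + Minv[1, 2] * gc + cr
  sc <- Minv[2, 1] * gr + Minv[2, 2] * gc + cc
  out <- numeric(h * w)
  if (filter == "nearest") {
    ri <- round(sr); ci <- round(sc)
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    out[ok] <- x[cbind(ri[ok], ci[ok])]
  } else {
    r0 <- floor(sr); c0 <- floor(sc)
    wr <- sr - r0; wc <- sc - c0
    for (dr in 0:1) for (dc in 0:1) {
      rr <- r0 + dr; cc2 <- c0 + dc
      wt <- (if (dr == 0) 1 - wr else wr) * (if (dc == 0) 1 - wc else wc)
      ok <- rr >= 1 & rr <= h & cc2 >= 1 & cc2 <= w & wt > 0
      if (any(ok)) out[ok] <- out[ok] + wt[ok] * x[cbind(rr[ok], cc2[ok])]
    }
  }
  matrix(out, h, w)
}

# run code with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
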