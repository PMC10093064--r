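# coerce (C,H,W) feature arrays / C x P matrices to C x P matrix form
as_feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  d <- dim(features)
  if (length(d) == 3) return(matrix(features, nrow = d[1]))
  stop("features must be a (C,H,W) array or a C x P matrix")
}

#' Masked average pooling of a feature grid
#'
#' Computes the foreground prototype: the mean of the feature vectors at all
#' spatial locations where the class mask is 1 (the Dirac-measure selection of
#' foreground positions). Undefined — and an error — for an empty mask.
#'
#' @param features `(C, H, W)` feature array or `C x P` matrix (columns in
#'   column-major spatial order, matching `as.vector(mask)`).
#' @param mask binary matrix/vector spatially aligned with the features.
#' @return prototype vector of length C.
#' @export
masked_average_pool <- function(features, mask) {
  fm <- as_feature_matrix(features)
  m <- as.vector(mask) != 0
  if (length(m) != ncol(fm))
    stop("mask size ", length(m), " does not match feature grid ", ncol(fm))
  if (!any(m)) stop("masked average pooling is undefined for an empty mask")
  rowMeans(fm[, m, drop = FALSE])
}

#' Pool one prototype from several support slices
#'
#' For C-shot K-way support sets the single foreground prototype is the mean
#' over all foreground feature locations pooled across every support slice.
#'
#' @param features `(S, C, Hf, Wf)` support feature array.
#' @param masks `(S, Hf, Wf)` binary masks at feature resolution.
#' @return prototype vector of length C.
#' @export
pool_prototype <- function(features, masks) {
  s <- dim(features)[1]
  stopifnot(dim(masks)[1] == s)
  total <- numeric(dim(features)[2]); n <- 0L
  for (k in seq_len(s)) {
    fm <- matrix(features[k, , , ], nrow = dim(features)[2])
    m <- as.vector(masks[k, , ]) != 0
    if (any(m)) {
      total <- total + rowSums(fm[, m, drop = FALSE])
      n <- n + sum(m)
    }
  }
  if (n == 0L) stop("masked average pooling is undefined for an empty mask")
  total / n
}

#' Scaled negative-cosine similarity map
#'
#' Scores every feature location against the prototype with
#' `R(i,j) = -alpha * cos(chi(i,j), rho)`: an anomaly-style score where the
#' most prototype-like pixels approach `-alpha` and incongruent pixels
#' approach `+alpha`. Zero feature vectors receive score 0 (zero-padding
#' regions occur in practice). Invariant to positive rescaling of either
#' argument.
#'
#' @param features `(C, H, W)` array or `C x P` matrix.
#' @param prototype nonzero vector of length C.
#' @param alpha scaling factor (default 20).
#' @param dims optional spatial dims when `features` is a matrix.
#' @return matrix of scores in `[-alpha, alpha]` with attribute `"alpha"`.
#' @export
similarity_map <- function(features, prototype, alpha = 20, dims = NULL) {
  fm <- as_feature_matrix(features)
  if (is.null(dims)) {
    d <- dim(features)
    dims <- if (length(d) == 3) d[2:3] else c(1L, ncol(fm))
  }
  pn <- sqrt(sum(prototype^2))
  if (pn == 0) stop("prototype must be nonzero")
  fn <- sqrt(colSums(fm^2))
  s <- as.vector(crossprod(fm, prototype))
  cosv <- pmin(pmax(ifelse(fn > 0, s / (fn * pn), 0), -1), 1)
  structure(matrix(-alpha * cosv, dims[1], dims[2]), alpha = alpha)
}

#' Soft thresholding of similarity scores into foreground probabilities
#'
#' `M(i,j) = 1 - sigmoid(R(i,j) - beta)`: strictly decreasing in R, exactly
#' 0.5 where the score equals the learned threshold `beta`, approaching 1 for
#' strongly prototype-like pixels (R near `-alpha`) and 0 for incongruent
#' ones.
#'
#' @param R similarity score matrix.
#' @param beta scalar threshold parameter.
#' @return matrix of probabilities in (0, 1).
#' @export
soft_threshold <- function(R, beta) {
  stopifnot(is.finite(beta))
  1 - plogis(R - beta)
}

#' Resize a feature/score grid to mask dimensions
#'
#' Bilinear resize used to carry feature-resolution similarity maps up to the
#' mask resolution before thresholding and loss computation.
#'
#' @param x numeric matrix.
#' @param dims target `c(rows, cols)`.
#' @return resized matrix.
#' @export
resize_to_mask <- function(x, dims) resize_bilinear(x, dims)

#' Downsample a binary mask to feature resolution
#'
#' Nearest-neighbour downsampling used to align 256x256 masks with the
#' stride-8 feature grid for masked average pooling; output stays binary.
#'
#' @param mask binary matrix.
#' @param dims target `c(rows, cols)`.
#' @return binary matrix.
#' @export
downsample_mask <- function(mask, dims) {
  out <- resize_nearest(mask, dims)
  out[out != 0] <- 1
  out
}
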