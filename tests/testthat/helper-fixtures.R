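# Small, programmatically built fixtures shared across test files.

# compact generator settings: enough slices/voxels to exercise the pipeline,
# small enough for fast tests
tiny_synth_config <- function(...) {
  synth_config(n_slices = 40L, grid = c(48L, 48L),
               tumor_radius_range = c(0.12, 0.2), ...)
}

# hand-built slice stack with a bright square "tumor" on dim noise; images
# are separable by construction so similarity scoring has signal
toy_stack <- function(seed, n = 6L, side = 32L, id = paste0("toy", seed)) {
  set.seed(seed)
  images <- array(0, dim = c(n, 3, side, side))
  masks <- array(0L, dim = c(n, side, side))
  for (k in seq_len(n)) {
    img <- matrix(runif(side * side, 0, 0.3), side)
    r0 <- sample(5:(side - 14), 1); c0 <- sample(5:(side - 14), 1)
    img[r0:(r0 + 8), c0:(c0 + 8)] <- img[r0:(r0 + 8), c0:(c0 + 8)] + 0.6
    for (ch in 1:3) images[k, ch, , ] <- img
    masks[k, r0:(r0 + 8), c0:(c0 + 8)] <- 1L
  }
  structure(list(images = images, masks = masks, id = id),
            class = "slice_stack")
}

toy_dataset <- function(n_cases = 5L, ...) {
  lapply(seq_len(n_cases), function(i) toy_stack(seed = 100 + i, ...))
}

# training config sized for unit tests (32x32 toy stacks, narrow encoder)
toy_train_config <- function(iterations = 50L, ...) {
  train_config(iterations = iterations, seed = 5L,
               hidden = c(8L, 16L, 32L), ...)
}

random_mask <- function(side = 8L, p = 0.4) {
  matrix(as.integer(runif(side * side) < p), side, side)
}
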