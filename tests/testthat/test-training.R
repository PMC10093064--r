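test_that("weighted cross-entropy matches closed forms and a pixel oracle", {
  side <- 32L
  all_fg <- matrix(1L, side, side)
  all_bg <- matrix(0L, side, side)
  half <- matrix(0.5, side, side)
  expect_equal(segmentation_loss(half, all_fg), log(2))
  expect_equal(segmentation_loss(half, all_bg), 0.2 * log(2))
  # near-perfect prediction has near-zero loss
  eps <- 1e-6
  truth <- random_mask(side)
  perfect <- truth * (1 - eps) + (1 - truth) * eps
  expect_lt(segmentation_loss(perfect, truth), 1e-5)

  # brute-force per-pixel oracle on random predictions
  set.seed(6)
  pred <- matrix(runif(side * side, 0.01, 0.99), side)
  truth <- random_mask(side)
  oracle <- 0
  for (i in seq_len(side)) for (j in seq_len(side)) {
    oracle <- oracle + if (truth[i, j] == 1) -log(pred[i, j])
                       else -0.2 * log(1 - pred[i, j])
  }
  expect_equal(segmentation_loss(pred, truth), oracle / side^2,
               tolerance = 1e-6)
})

test_that("total loss is linear in the PAR term", {
  expect_identical(total_loss(0.4, 0.2, 1.0), 0.4 + 0.2)
  expect_identical(total_loss(0.4, 0.2, 0.0), 0.4)
  expect_identical(total_loss(0, 0, 17), 0)
})

test_that("PAR mirrors the segmentation loss for an identical support/query", {
  ds <- toy_dataset(3)
  cfg <- toy_train_config(iterations = 120)
  fit <- train(ds, cfg)
  st <- ds[[1]]
  k <- foreground_slices(st)[1]
  ep <- structure(list(
    support_images = st$images[k, , , , drop = FALSE],
    support_masks = st$masks[k, , , drop = FALSE],
    query_images = st$images[k, , , , drop = FALSE],
    query_masks = st$masks[k, , , drop = FALSE]), class = "episode")
  eb <- build_encoder_batch(ep)
  feats <- encode(fit$state$encoder, eb$batch)
  pq <- protoseg:::predict_query_masks(feats, 1L, ep$support_masks, fit$state,
                                       dim(st$masks)[2:3])
  lseg <- segmentation_loss(pq$pred[1, , ], ep$query_masks[1, , ])
  lpar <- par_loss(ep, fit$state)
  # a trained model predicting its own support slice: both losses small,
  # and role reversal nearly symmetric
  expect_lt(lseg, 0.2)
  expect_lt(abs(lpar - lseg), 0.15)
})

test_that("an empty predicted query mask contributes zero PAR", {
  st <- toy_stack(3, n = 3)
  cfg <- toy_train_config(iterations = 0)
  state <- protoseg:::init_state(cfg)
  state$beta <- -1e6  # every score sits far above threshold: M ~ 0 everywhere
  ep <- structure(list(
    support_images = st$images[1, , , , drop = FALSE],
    support_masks = st$masks[1, , , drop = FALSE],
    query_images = st$images[2, , , , drop = FALSE],
    query_masks = st$masks[2, , , drop = FALSE]), class = "episode")
  expect_identical(par_loss(ep, state), 0)
})

test_that("training reduces the loss, moves beta, and logs exactly", {
  ds <- toy_dataset(6)
  cfg <- toy_train_config(iterations = 200)
  fit <- train(ds, cfg)
  h <- fit$history
  expect_identical(nrow(h), 200L)
  expect_identical(h$l_total, h$l_seg + cfg$lambda * h$l_par)
  expect_lt(mean(h$l_total[151:200]), mean(h$l_total[1:50]))
  expect_false(isTRUE(all.equal(fit$state$beta, cfg$beta_init)))
  # lr decay schedule: constant within the first window
  expect_identical(unique(h$lr), cfg$lr)
})

test_that("training is deterministic and iterations = 0 returns init state", {
  ds <- toy_dataset(3)
  cfg <- toy_train_config(iterations = 25)
  f1 <- train(ds, cfg)
  f2 <- train(ds, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$state, f2$state)
  f0 <- train(ds, toy_train_config(iterations = 0))
  expect_identical(nrow(f0$history), 0L)
  expect_identical(f0$state$beta, -10)
})

test_that("with lambda = 0 the PAR term provably does not affect updates", {
  ds <- toy_dataset(3)
  on <- train(ds, toy_train_config(iterations = 25, lambda = 0,
                                   compute_par = TRUE))
  off <- train(ds, toy_train_config(iterations = 25, lambda = 0,
                                    compute_par = FALSE))
  expect_identical(on$state$encoder, off$state$encoder)
  expect_identical(on$state$beta, off$state$beta)
  expect_true(any(on$history$l_par > 0))   # PAR was evaluated, just unused
  expect_true(all(off$history$l_par == 0))
})

test_that("learning-rate decay follows the 0.97-per-window schedule", {
  ds <- toy_dataset(3)
  cfg <- toy_train_config(iterations = 12, decay_every = 5L)
  fit <- train(ds, cfg)
  expect_equal(fit$history$lr,
               cfg$lr * cfg$lr_decay^(((seq_len(12)) - 1) %/% 5))
})

test_that("checkpoints and history round-trip through disk", {
  ds <- toy_dataset(3)
  fit <- train(ds, toy_train_config(iterations = 5))
  d <- withr::local_tempdir()
  paths <- save_checkpoint(fit, d)
  state <- readRDS(paths$checkpoint)
  expect_identical(state$beta, fit$state$beta)
  lines <- readLines(paths$history)
  expect_length(lines, 5)
  rec <- jsonlite::fromJSON(lines[1])
  expect_equal(rec$l_total, fit$history$l_total[1])
})
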