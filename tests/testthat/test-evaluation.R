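test_that("support slice selection returns the median foreground slice", {
  masks <- array(0L, dim = c(20, 8, 8))
  masks[5:15, 3, 3] <- 1L
  expect_identical(select_support_slice(masks), 10L)
  one <- array(0L, dim = c(20, 8, 8)); one[7, 2, 2] <- 1L
  expect_identical(select_support_slice(one), 7L)
  expect_error(select_support_slice(array(0L, dim = c(5, 8, 8))),
               "no slice contains foreground")
  # volume layout (H, W, S)
  vol <- array(0L, dim = c(8, 8, 20)); vol[3, 3, 5:15] <- 1L
  expect_identical(select_support_slice(vol, slice_dim = 3), 10L)
  # stochastic mode stays within the middle third
  set.seed(1)
  draws <- replicate(50, select_support_slice(masks, mode = "random-middle"))
  expect_true(all(draws >= 8 & draws <= 13))
})

test_that("overlap metrics match set arithmetic and their identities", {
  a <- matrix(0L, 6, 6); a[2:3, 2:3] <- 1L           # 4 pixels
  b <- matrix(0L, 6, 6); b[3:4, 2:3] <- 1L           # 4 pixels, overlap 2
  m <- compute_metrics(a, b)
  expect_equal(m$dice, 0.5)
  expect_equal(m$iou, 1 / 3)
  expect_equal(m$precision, 0.5)

  same <- compute_metrics(a, a)
  expect_identical(c(same$dice, same$iou, same$precision), c(1, 1, 1))
  disj <- matrix(0L, 6, 6); disj[5:6, 5:6] <- 1L
  z <- compute_metrics(a, disj)
  expect_identical(c(z$dice, z$iou, z$precision), c(0, 0, 0))

  empty <- matrix(0L, 6, 6)
  e <- compute_metrics(empty, empty)
  expect_identical(c(e$dice, e$iou), c(1, 1))
  expect_true(is.na(e$precision))

  expect_error(compute_metrics(a, matrix(0L, 5, 5)), "shape mismatch")

  # dice = 2*iou/(1+iou); dice/iou symmetric, precision not
  set.seed(3)
  for (i in 1:200) {
    x <- random_mask(8); y <- random_mask(8)
    mm <- compute_metrics(x, y)
    expect_equal(mm$dice, 2 * mm$iou / (1 + mm$iou), tolerance = 1e-12)
    expect_lte(mm$iou, mm$dice)
    rev <- compute_metrics(y, x)
    expect_equal(rev$dice, mm$dice)
    expect_equal(rev$iou, mm$iou)
  }
})

test_that("whole-volume segmentation honours the shape contract untrained", {
  st <- toy_stack(4, n = 5)
  state <- protoseg:::init_state(toy_train_config(iterations = 0))
  si <- select_support_slice(st$masks)
  pred <- segment_query_volume(st$images[si, , , ], st$masks[si, , ], st, state)
  expect_identical(dim(pred), dim(st$masks))
  expect_true(all(pred %in% c(0L, 1L)))
  expect_error(
    segment_query_volume(st$images[si, , , ], st$masks[si, , ], st, state,
                         prob_threshold = 1.0),
    "strictly inside")
  empty_mask <- st$masks[si, , ] * 0L
  expect_error(
    segment_query_volume(st$images[si, , , ], empty_mask, st, state),
    "no foreground")
})

test_that("cross-validation partitions cases and is reproducible", {
  ds <- toy_dataset(10)
  cfg <- toy_train_config(iterations = 40)
  cv <- cross_validate(ds, cfg, k = 5, seed = 3)
  expect_identical(sort(as.vector(table(cv$folds))), rep(2L, 5))
  expect_identical(nrow(cv$per_case), 10L)
  expect_identical(sort(cv$per_case$case_id),
                   sort(vapply(ds, `[[`, character(1), "id")))
  expect_true(all(cv$per_case$dice >= 0 & cv$per_case$dice <= 1))
  expect_identical(cv$summary$metric, c("dice", "iou", "precision"))

  cv2 <- cross_validate(ds, cfg, k = 5, seed = 3)
  expect_identical(cv$per_case, cv2$per_case)

  expect_error(cross_validate(ds, cfg, k = 1), "k = 1")
  expect_error(cross_validate(ds[1:3], cfg, k = 5), "smaller")
})
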