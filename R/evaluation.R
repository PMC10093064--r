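#' Select the support slice from a labelled volume
#'
#' Picks the annotated slice used to build the support prototype at inference:
#' a slice from the middle of the foreground-bearing range, which carries the
#' most information about the foreground class. In deterministic mode the
#' median foreground-bearing slice index is returned; in stochastic mode a
#' uniform draw from the middle third of the foreground-bearing slices.
#'
#' @param masks binary/label array with slices along `slice_dim`
#'   (`S x H x W` stacks by default; pass `slice_dim = 3` for `H x W x S`
#'   volumes).
#' @param slice_dim which dimension indexes slices.
#' @param mode `"median"` (deterministic) or `"random-middle"`.
#' @return a slice index.
#' @export
select_support_slice <- function(masks, slice_dim = 1L,
                                 mode = c("median", "random-middle")) {
  mode <- match.arg(mode)
  stopifnot(length(dim(masks)) == 3, slice_dim %in% c(1L, 3L))
  fg <- which(apply(masks, slice_dim, function(m) any(m != 0)))
  if (length(fg) == 0) stop("no slice contains foreground")
  if (mode == "median") return(fg[ceiling(length(fg) / 2)])
  n <- length(fg)
  lo <- floor(n / 3) + 1L
  hi <- max(lo, ceiling(2 * n / 3))
  fg[if (hi > lo) sample(lo:hi, 1L) else lo]
}

#' Segment a whole query scan from one annotated support slice
#'
#' Builds a single foreground prototype from the support slice, scores every
#' query slice against it (scaled negative cosine, soft threshold), upsamples
#' the score maps to mask resolution, and binarizes at `prob_threshold`.
#'
#' @param support_image `3 x H x W` (or `1 x 3 x H x W`) support image.
#' @param support_mask `H x W` binary support mask with >= 1 foreground pixel.
#' @param query_images `Q x 3 x H x W` query slice stack (or a `slice_stack`).
#' @param state model state (`encoder`, `beta`, `alpha`).
#' @param prob_threshold binarization threshold, strictly inside (0, 1).
#' @return `Q x H x W` integer binary mask volume.
#' @export
segment_query_volume <- function(support_image, support_mask, query_images,
                                 state, prob_threshold = 0.5) {
  if (!(prob_threshold > 0 && prob_threshold < 1))
    stop("prob_threshold must lie strictly inside (0, 1)")
  if (inherits(query_images, "slice_stack")) query_images <- query_images$images
  if (length(dim(support_image)) == 3)
    support_image <- array(support_image, dim = c(1L, dim(support_image)))
  if (!any(support_mask != 0)) stop("support slice has no foreground")
  d <- dim(query_images)
  ep <- structure(list(
    support_images = support_image,
    support_masks = array(support_mask, dim = c(1L, dim(support_mask))),
    query_images = query_images,
    query_masks = array(0L, dim = c(d[1], d[3], d[4]))), class = "episode")
  eb <- build_encoder_batch(ep)
  feats <- encode(state$encoder, eb$batch)
  pq <- predict_query_masks(feats, eb$n_support, ep$support_masks, state,
                            d[3:4])
  out <- array(0L, dim = c(d[1], d[3], d[4]))
  out[pq$pred >= prob_threshold] <- 1L
  out
}

#' Segmentation overlap metrics
#'
#' Dice `2|X∩Y| / (|X|+|Y|)`, IoU `|X∩Y| / |X∪Y|`, and precision
#' `TP / (TP+FP)`, computed with integer pixel counts before division
#' (3-D pooled over slices when given volumes). For two empty masks Dice and
#' IoU are defined as 1; precision is `NA` when nothing is predicted.
#'
#' @param pred predicted binary mask/volume.
#' @param truth ground-truth binary mask/volume of the same shape.
#' @return list with `dice`, `iou`, `precision`.
#' @export
compute_metrics <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("shape mismatch between prediction and truth")
  x <- pred != 0; y <- truth != 0
  tp <- sum(x & y); fp <- sum(x & !y); fn <- sum(!x & y)
  dice <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  iou <- if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  list(dice = dice, iou = iou, precision = precision)
}

#' k-fold cross-validated training and evaluation
#'
#' Partitions the cases into `k` disjoint validation folds. For each fold the
#' model is trained on the remaining cases; every validation case is then
#' segmented as a whole query scan, with the support slice drawn from a
#' (seeded) randomly chosen training case — the median foreground slice of
#' that case. Reports per-case metrics plus mean, standard deviation and
#' maximum across folds.
#'
#' @param dataset list of `slice_stack` objects (length >= k).
#' @param config a [train_config()].
#' @param k number of folds (>= 2).
#' @param seed seed for fold assignment and support-case choice.
#' @return list with `per_case` (data frame), `summary` (data frame of
#'   mean/sd/max per metric), and `folds` (assignment vector).
#' @export
cross_validate <- function(dataset, config = train_config(), k = 5L,
                           seed = 1L) {
  n <- length(dataset)
  if (k < 2) stop("k must be >= 2 (k = 1 leaves no held-out data)")
  if (n < k) stop("dataset smaller than the number of folds")
  folds <- with_local_seed(seed, sample(rep_len(seq_len(k), n)))
  rows <- list()
  for (f in seq_len(k)) {
    tr <- which(folds != f); va <- which(folds == f)
    cfg <- config; cfg$seed <- config$seed + f
    fit <- train(dataset[tr], cfg)
    sup_choice <- with_local_seed(seed + 1000L + f,
                                  sample(tr, length(va), replace = TRUE))
    for (j in seq_along(va)) {
      sup <- dataset[[sup_choice[j]]]
      si <- select_support_slice(sup$masks)
      qs <- dataset[[va[j]]]
      pred <- segment_query_volume(sup$images[si, , , ], sup$masks[si, , ],
                                   qs, fit$state)
      m <- compute_metrics(pred, qs$masks)
      rows[[length(rows) + 1]] <- data.frame(
        case_id = qs$id, fold = f, dice = m$dice, iou = m$iou,
        precision = m$precision)
    }
  }
  per_case <- do.call(rbind, rows)
  summarize <- function(v) c(mean = mean(v, na.rm = TRUE),
                             sd = stats::sd(v, na.rm = TRUE),
                             max = max(v, na.rm = TRUE))
  summary <- as.data.frame(t(vapply(per_case[c("dice", "iou", "precision")],
                                    summarize, numeric(3))))
  summary$metric <- rownames(summary)
  rownames(summary) <- NULL
  list(per_case = per_case, summary = summary[c("metric", "mean", "sd", "max")],
       folds = folds)
}
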