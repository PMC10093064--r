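#' Training configuration
#'
#' Defaults follow the method's published settings: SGD with momentum 0.9,
#' batch size 1 (one episode per step), learning rate 1e-3 decayed by 0.97
#' every 1000 iterations, an additional L2 weight decay of 5e-4 on the
#' convolution weights, cross-entropy class weights of 1.0 (foreground) and
#' 0.2 (background), PAR weight lambda = 1, and similarity scaling alpha = 20.
#' The iteration count is configurable down from the full-scale 50,000 for
#' desk-scale runs.
#'
#' @param iterations number of episodic SGD steps.
#' @param lr initial learning rate.
#' @param momentum SGD momentum.
#' @param lr_decay multiplicative decay factor.
#' @param decay_every apply `lr_decay` every this many iterations.
#' @param weight_decay L2 penalty on convolution weights.
#' @param w_fg,w_bg cross-entropy class weights.
#' @param lambda weight of the prototype alignment regularizer.
#' @param alpha similarity scaling factor.
#' @param beta_init initial soft-threshold parameter (default `-alpha/2`,
#'   centring the sigmoid between the perfect-match score `-alpha` and the
#'   orthogonal score 0).
#' @param C,K shots and ways of the training episodes.
#' @param seed master seed (weights, episode sampling, augmentation).
#' @param hidden encoder stage widths (see [encoder_init()]).
#' @param compute_par evaluate the PAR term even when its gradient
#'   contribution is zero (`lambda = 0`); set `FALSE` to skip it entirely.
#' @param augment `NULL` (off) or an [augment_config()] applied per episode.
#' @return a `train_config` list.
#' @export
train_config <- function(iterations = 50000L, lr = 1e-3, momentum = 0.9,
                         lr_decay = 0.97, decay_every = 1000L,
                         weight_decay = 5e-4, w_fg = 1, w_bg = 0.2,
                         lambda = 1, alpha = 20, beta_init = -alpha / 2,
                         C = 1L, K = 1L, seed = 1L,
                         hidden = c(16L, 32L, 64L),
                         compute_par = TRUE, augment = NULL) {
  stopifnot(iterations >= 0, lr > 0, momentum >= 0, lr_decay > 0,
            decay_every >= 1, weight_decay >= 0, lambda >= 0, alpha > 0)
  structure(list(iterations = as.integer(iterations), lr = lr,
                 momentum = momentum, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every),
                 weight_decay = weight_decay, w_fg = w_fg, w_bg = w_bg,
                 lambda = lambda, alpha = alpha, beta_init = beta_init,
                 C = as.integer(C), K = as.integer(K), seed = as.integer(seed),
                 hidden = hidden, compute_par = isTRUE(compute_par),
                 augment = augment), class = "train_config")
}

#' Class-weighted binary cross-entropy segmentation loss
#'
#' Per-pixel mean of `-w_fg * y * log(M) - w_bg * (1 - y) * log(1 - M)`.
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]` for numerical safety.
#'
#' @param pred predicted foreground probability matrix/array in (0, 1).
#' @param truth binary ground-truth of the same shape.
#' @param w_fg,w_bg foreground/background class weights.
#' @return nonnegative scalar.
#' @export
segmentation_loss <- function(pred, truth, w_fg = 1, w_bg = 0.2) {
  stopifnot(length(pred) == length(truth))
  eps <- 1e-7
  p <- pmin(pmax(pred, eps), 1 - eps)
  y <- as.numeric(truth != 0)
  mean(-w_fg * y * log(p) - w_bg * (1 - y) * log(1 - p))
}

#' Total episodic loss
#'
#' `l_total = l_seg + lambda * l_par`.
#'
#' @param l_seg segmentation loss.
#' @param l_par prototype alignment loss.
#' @param lambda PAR weight.
#' @return scalar.
#' @export
total_loss <- function(l_seg, l_par, lambda = 1) {
  stopifnot(is.finite(l_seg), is.finite(l_par))
  l_seg + lambda * l_par
}

# model state -------------------------------------------------------------

init_state <- function(config) {
  list(encoder = encoder_init(config$seed, config$hidden),
       beta = config$beta_init, alpha = config$alpha,
       w_fg = config$w_fg, w_bg = config$w_bg)
}

# forward pieces shared by training and standalone loss evaluation ---------

# query prediction for an encoded episode; feats is the encode() output
predict_query_masks <- function(feats, n_support, support_masks, state,
                                mask_side) {
  hf <- dim(feats)[3]; wf <- dim(feats)[4]
  sm <- array(0L, dim = c(n_support, hf, wf))
  for (k in seq_len(n_support))
    sm[k, , ] <- downsample_mask(matrix(support_masks[k, , ],
                                        dim(support_masks)[2]), c(hf, wf))
  rho <- pool_prototype(feats[seq_len(n_support), , , , drop = FALSE], sm)
  nq <- dim(feats)[1] - n_support
  out <- array(0, dim = c(nq, mask_side[1], mask_side[2]))
  for (q in seq_len(nq)) {
    fq <- array(feats[n_support + q, , , ], dim = dim(feats)[2:4])
    R <- similarity_map(fq, rho, alpha = state$alpha)
    out[q, , ] <- soft_threshold(resize_to_mask(R, mask_side), state$beta)
  }
  list(pred = out, prototype = rho)
}

#' Prototype alignment regularization loss of an episode
#'
#' Reverses the roles of support and query: the predicted query mask
#' (binarized at 0.5) selects query features whose masked average becomes a
#' query-derived prototype; the support features are scored against it,
#' soft-thresholded, and compared to the support ground truth with the
#' class-weighted cross-entropy (averaged over support slices). An empty
#' predicted query mask contributes 0.
#'
#' @param episode a training `episode` (single query slice).
#' @param state model state as returned by [train()] (`encoder`, `beta`,
#'   `alpha`, `w_fg`, `w_bg`).
#' @return nonnegative scalar.
#' @export
par_loss <- function(episode, state) {
  eb <- build_encoder_batch(episode)
  feats <- encode(state$encoder, eb$batch)
  side <- dim(episode$query_masks)[2:3]
  pq <- predict_query_masks(feats, eb$n_support, episode$support_masks,
                            state, side)
  hf <- dim(feats)[3]; wf <- dim(feats)[4]
  mq <- downsample_mask((pq$pred[1, , ] >= 0.5) * 1, c(hf, wf))
  if (!any(mq != 0)) return(0)
  fq <- array(feats[eb$n_support + 1, , , ], dim = dim(feats)[2:4])
  rq <- masked_average_pool(fq, mq)
  if (sqrt(sum(rq^2)) == 0) return(0)
  losses <- vapply(seq_len(eb$n_support), function(k) {
    fs <- array(feats[k, , , ], dim = dim(feats)[2:4])
    R <- similarity_map(fs, rq, alpha = state$alpha)
    M <- soft_threshold(resize_to_mask(R, side), state$beta)
    segmentation_loss(M, episode$support_masks[k, , ], state$w_fg, state$w_bg)
  }, numeric(1))
  mean(losses)
}

# fused forward + backward for one training episode -----------------------

# gradient of the weighted BCE w.r.t. z = R - beta, given sig = sigmoid(z)
bce_dz <- function(y, sig, w_fg, w_bg, npix) {
  (w_fg * y * sig - w_bg * (1 - y) * (1 - sig)) / npix
}

# cosine-score backward: given dcos (per pixel), features fm (C x P),
# prototype rho, returns dF (C x P) and drho
cosine_backward <- function(dcos, fm, fn, pn, cosv, rho) {
  valid <- fn > 0
  coef1 <- ifelse(valid, dcos / (fn * pn), 0)
  coef2 <- ifelse(valid, dcos * cosv / fn^2, 0)
  dF <- outer(rho, coef1) - fm * rep(coef2, each = length(rho))
  drho <- as.vector(fm %*% coef1) - rho * sum(dcos * cosv) / pn^2
  list(dF = dF, drho = drho)
}

episode_grads <- function(state, episode, config) {
  eb <- build_encoder_batch(episode)
  s <- eb$n_support
  feats <- encode(state$encoder, eb$batch, keep_cache = TRUE)
  caches <- attr(feats, "cache")
  cdim <- dim(feats)[2]; hf <- dim(feats)[3]; wf <- dim(feats)[4]
  side <- dim(episode$query_masks)[2:3]
  npix <- prod(side)
  A <- interp_matrix_linear(hf, side[1])
  B <- interp_matrix_linear(wf, side[2])
  fmat <- lapply(seq_len(s + 1), function(n)
    matrix(feats[n, , , ], nrow = cdim))
  dF <- lapply(seq_len(s + 1), function(n) matrix(0, cdim, hf * wf))

  # support prototype by pooled masked average
  msf <- lapply(seq_len(s), function(k)
    as.vector(downsample_mask(matrix(episode$support_masks[k, , ], side[1]),
                              c(hf, wf))) != 0)
  n_tot <- sum(vapply(msf, sum, integer(1)))
  if (n_tot == 0) return(NULL)  # degenerate episode; caller resamples
  rho <- Reduce(`+`, lapply(seq_len(s), function(k)
    rowSums(fmat[[k]][, msf[[k]], drop = FALSE]))) / n_tot
  pn <- sqrt(sum(rho^2))
  if (pn == 0) return(NULL)

  # query prediction and segmentation loss
  fq <- fmat[[s + 1]]
  fn <- sqrt(colSums(fq^2))
  cosv <- ifelse(fn > 0, as.vector(crossprod(fq, rho)) / (fn * pn), 0)
  R32 <- matrix(-config$alpha * cosv, hf, wf)
  z <- A %*% R32 %*% t(B) - state$beta
  sig <- plogis(z)
  yq <- matrix(as.numeric(episode$query_masks[1, , ] != 0), side[1])
  l_seg <- segmentation_loss(1 - sig, yq, config$w_fg, config$w_bg)

  dz <- bce_dz(yq, sig, config$w_fg, config$w_bg, npix)
  dbeta <- -sum(dz)
  dR32 <- crossprod(A, dz) %*% B
  cb <- cosine_backward(-config$alpha * as.vector(dR32), fq, fn, pn, cosv, rho)
  dF[[s + 1]] <- dF[[s + 1]] + cb$dF
  drho <- cb$drho

  # prototype alignment: swap roles using the hard predicted query mask
  l_par <- 0
  if (config$compute_par) {
    mq <- as.vector(downsample_mask((1 - sig >= 0.5) * 1, c(hf, wf))) != 0
    if (any(mq)) {
      nq <- sum(mq)
      rq <- rowSums(fq[, mq, drop = FALSE]) / nq
      pnq <- sqrt(sum(rq^2))
      if (pnq > 0) {
        gscale <- config$lambda / s
        drq <- numeric(cdim)
        for (k in seq_len(s)) {
          fs <- fmat[[k]]
          fns <- sqrt(colSums(fs^2))
          coss <- ifelse(fns > 0,
                         as.vector(crossprod(fs, rq)) / (fns * pnq), 0)
          Rs <- matrix(-config$alpha * coss, hf, wf)
          zs <- A %*% Rs %*% t(B) - state$beta
          sigs <- plogis(zs)
          ys <- matrix(as.numeric(episode$support_masks[k, , ] != 0), side[1])
          l_par <- l_par + segmentation_loss(1 - sigs, ys,
                                             config$w_fg, config$w_bg) / s
          if (gscale > 0) {
            dzs <- gscale * bce_dz(ys, sigs, config$w_fg, config$w_bg, npix)
            dbeta <- dbeta - sum(dzs)
            dRs <- crossprod(A, dzs) %*% B
            cbs <- cosine_backward(-config$alpha * as.vector(dRs),
                                   fs, fns, pnq, coss, rq)
            dF[[k]] <- dF[[k]] + cbs$dF
            drq <- drq + cbs$drho
          }
        }
        if (gscale > 0) dF[[s + 1]][, mq] <- dF[[s + 1]][, mq] + drq / nq
      }
    }
  }

  # support-prototype backward into support features
  for (k in seq_len(s))
    if (any(msf[[k]]))
      dF[[k]][, msf[[k]]] <- dF[[k]][, msf[[k]]] + drho / n_tot

  enc_grads <- encoder_backward(state$encoder, caches, dF)
  list(l_seg = l_seg, l_par = l_par,
       l_total = total_loss(l_seg, l_par, config$lambda),
       enc_grads = enc_grads, dbeta = dbeta)
}

#' Train the one-shot segmentation model episodically
#'
#' Per iteration: sample a C-shot K-way episode, encode support and query in
#' one batch, pool the foreground prototype, score the query, soft-threshold,
#' evaluate the weighted cross-entropy and the prototype alignment
#' regularizer, and take one SGD-with-momentum step on the encoder weights and
#' the threshold `beta`. The learning rate is multiplied by `lr_decay` every
#' `decay_every` iterations; `weight_decay` is an L2 penalty on convolution
#' weights (not biases or `beta`). Fully seeded and deterministic.
#'
#' @param dataset list of `slice_stack` objects.
#' @param config a [train_config()].
#' @return list with `state` (`encoder`, `beta`, `alpha`, class weights) and
#'   `history` (data frame of per-iteration losses; `l_total` equals
#'   `l_seg + lambda * l_par` exactly at every iteration).
#' @export
train <- function(dataset, config = train_config()) {
  stopifnot(inherits(config, "train_config"), length(dataset) >= 1)
  state <- init_state(config)
  hist <- vector("list", config$iterations)
  if (config$iterations == 0)
    return(list(state = state, history = empty_history()))
  vel <- lapply(state$encoder$layers, function(ly)
    list(vw = matrix(0, nrow(ly$w), ncol(ly$w)), vb = numeric(length(ly$b))))
  vbeta <- 0
  with_local_seed(config$seed + 1L, {
    for (it in seq_len(config$iterations)) {
      lr <- config$lr * config$lr_decay^((it - 1) %/% config$decay_every)
      g <- NULL
      for (try in 1:20) {
        ep <- sample_training_episode(dataset, config$C, config$K)
        if (!is.null(config$augment)) ep <- augment_episode(ep, config$augment)
        g <- episode_grads(state, ep, config)
        if (!is.null(g)) break
      }
      if (is.null(g)) stop("could not sample a non-degenerate episode")
      if (!is.finite(g$l_total))
        stop("non-finite loss at iteration ", it,
             " (l_seg=", g$l_seg, ", l_par=", g$l_par, ")")
      for (li in seq_along(state$encoder$layers)) {
        ly <- state$encoder$layers[[li]]
        vel[[li]]$vw <- config$momentum * vel[[li]]$vw -
          lr * (g$enc_grads[[li]]$dw + config$weight_decay * ly$w)
        vel[[li]]$vb <- config$momentum * vel[[li]]$vb - lr * g$enc_grads[[li]]$db
        state$encoder$layers[[li]]$w <- ly$w + vel[[li]]$vw
        state$encoder$layers[[li]]$b <- ly$b + vel[[li]]$vb
      }
      vbeta <- config$momentum * vbeta - lr * g$dbeta
      state$beta <- state$beta + vbeta
      hist[[it]] <- data.frame(iteration = it, l_seg = g$l_seg,
                               l_par = g$l_par, l_total = g$l_total,
                               lr = lr, beta = state$beta,
                               case_id = ep$case_id,
                               query_idx = ep$query_idx,
                               support_idx = paste(ep$support_idx,
                                                   collapse = ";"))
    }
  })
  list(state = state, history = do.call(rbind, hist))
}

empty_history <- function() {
  data.frame(iteration = integer(), l_seg = numeric(), l_par = numeric(),
             l_total = numeric(), lr = numeric(), beta = numeric(),
             case_id = character(), query_idx = integer(),
             support_idx = character())
}

# apply one augmentation pass to the slices of an episode; if the transform
# empties a mask the original episode is kept (prototypes need foreground)
augment_episode <- function(episode, aug) {
  si <- augment(episode$support_images, episode$support_masks, aug)
  qi <- augment(episode$query_images, episode$query_masks, aug)
  ok <- all(apply(si$masks, 1, function(m) any(m != 0))) &&
    all(apply(qi$masks, 1, function(m) any(m != 0)))
  if (!ok) return(episode)
  episode$support_images <- si$images; episode$support_masks <- si$masks
  episode$query_images <- qi$images; episode$query_masks <- qi$masks
  episode
}

#' Write a training run to disk
#'
#' Saves the model state as an RDS checkpoint and the loss history as JSON
#' lines.
#'
#' @param fit result of [train()].
#' @param out_dir output directory.
#' @return paths, invisibly.
#' @export
save_checkpoint <- function(fit, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ckpt <- file.path(out_dir, "checkpoint.rds")
  histf <- file.path(out_dir, "history.jsonl")
  saveRDS(fit$state, ckpt)
  con <- file(histf, "w"); on.exit(close(con))
  if (nrow(fit$history) > 0)
    for (i in seq_len(nrow(fit$history)))
      writeLines(jsonlite::toJSON(as.list(fit$history[i, ]),
                                  auto_unbox = TRUE, digits = NA), con)
  invisible(list(checkpoint = ckpt, history = histf))
}
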