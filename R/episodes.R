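#' Indices of slices with nonzero foreground
#'
#' @param stack a `slice_stack`.
#' @return integer vector of slice indices.
#' @export
foreground_slices <- function(stack) {
  which(apply(stack$masks, 1, function(m) any(m != 0)))
}

#' Sample a C-shot K-way training episode
#'
#' Draws one case at random, then `C * K + 1` distinct foreground-bearing
#' slice indices from it without replacement: the first becomes the single
#' query slice, the rest the support set. All tumor levels are merged into one
#' foreground class, so the K "ways" only multiply the support count. Cases
#' with too few foreground slices are skipped; if no case qualifies an error
#' is raised. Consumes the current RNG stream (seed for determinism).
#'
#' @param dataset list of `slice_stack` objects.
#' @param C shots per way.
#' @param K ways.
#' @return an `episode`: list with `support_images` (`CK x 3 x H x W`),
#'   `support_masks` (`CK x H x W`), `query_images` (`1 x 3 x H x W`),
#'   `query_masks`, `case_id`, `support_idx`, `query_idx`.
#' @export
sample_training_episode <- function(dataset, C = 1L, K = 1L) {
  stopifnot(length(dataset) >= 1, C >= 1, K >= 1)
  n_support <- C * K
  order <- sample.int(length(dataset))
  for (ci in order) {
    fg <- foreground_slices(dataset[[ci]])
    if (length(fg) >= n_support + 1) {
      picked <- fg[sample.int(length(fg), n_support + 1)]
      st <- dataset[[ci]]
      qi <- picked[1]; si <- picked[-1]
      return(structure(list(
        support_images = st$images[si, , , , drop = FALSE],
        support_masks = st$masks[si, , , drop = FALSE],
        query_images = st$images[qi, , , , drop = FALSE],
        query_masks = st$masks[qi, , , drop = FALSE],
        case_id = st$id, support_idx = si, query_idx = qi), class = "episode"))
    }
  }
  stop("no case has at least C*K + 1 = ", n_support + 1,
       " foreground-bearing slices")
}

#' Assemble an inference episode from a support case and a query stack
#'
#' Support is a single annotated slice (by default the median foreground slice
#' of the support case); the query is the full standardized slice stack of the
#' scan to segment.
#'
#' @param support_stack `slice_stack` providing the annotated support slice.
#' @param query_stack `slice_stack` to segment.
#' @param support_slice slice index into `support_stack`; default the median
#'   foreground slice (see [select_support_slice()]).
#' @return an `episode` whose query set is the whole stack.
#' @export
make_inference_episode <- function(support_stack, query_stack,
                                   support_slice = NULL) {
  if (is.null(support_slice))
    support_slice <- select_support_slice(support_stack$masks)
  if (!any(support_stack$masks[support_slice, , ] != 0))
    stop("support slice ", support_slice, " has no foreground")
  structure(list(
    support_images = support_stack$images[support_slice, , , , drop = FALSE],
    support_masks = support_stack$masks[support_slice, , , drop = FALSE],
    query_images = query_stack$images,
    query_masks = query_stack$masks,
    case_id = query_stack$id, support_idx = support_slice,
    query_idx = seq_len(dim(query_stack$images)[1])), class = "episode")
}

#' Concatenate support and query slices into one encoder batch
#'
#' The encoder processes support and query slices in a single forward pass;
#' the batch axis is `[support (C*K) || query]`, giving batch dimension
#' `C*K + 21` for a standard 21-slice inference query stack (and `C*K + 1`
#' for a single-query training episode).
#'
#' @param episode an `episode`.
#' @return list with `batch` (`(S+Q) x 3 x H x W` array) and `n_support`.
#' @export
build_encoder_batch <- function(episode) {
  s <- dim(episode$support_images)[1]
  q <- dim(episode$query_images)[1]
  if (is.null(s) || s < 1) stop("episode has no support slices")
  if (!all(dim(episode$support_images)[2:4] == dim(episode$query_images)[2:4]))
    stop("support and query image sizes differ")
  d <- dim(episode$support_images)
  batch <- array(0, dim = c(s + q, d[2], d[3], d[4]))
  batch[seq_len(s), , , ] <- episode$support_images
  batch[s + seq_len(q), , , ] <- episode$query_images
  list(batch = batch, n_support = s)
}
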