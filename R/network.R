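## R surface over the compiled network engine.

images_to_array <- function(images, spec) {
  if (inherits(images, "spectrum_image")) images <- list(images)
  side <- spec$input_side
  arr <- array(0, dim = c(side, side, length(images)))
  for (i in seq_along(images)) {
    p <- if (inherits(images[[i]], "spectrum_image")) images[[i]]$pixels else images[[i]]
    if (nrow(p) != side || ncol(p) != side) {
      stop(sprintf("image %d is %d x %d but the architecture expects %d x %d",
                   i, nrow(p), ncol(p), side, side))
    }
    arr[, , i] <- p
  }
  arr
}

dropout_masks <- function(spec, n_cols) {
  if (spec$dropout_p <= 0) return(list())
  lapply(spec$fc_sizes, function(u) {
    keep <- matrix(stats::runif(u * n_cols) >= spec$dropout_p, u, n_cols)
    keep / (1 - spec$dropout_p)
  })
}

#' Embed spectra into the K-dimensional cluster space
#'
#' Computes \eqn{G_W(x)} for one or more spectra. In evaluation mode
#' (`training_mode = FALSE`, the default) the map is deterministic: dropout
#' is off and batch normalization uses the stored running statistics.
#' In training mode batch statistics and (seeded) dropout masks are used.
#'
#' @param weights A `network_weights` list from [init_weights()] or training.
#' @param spec The matching [architecture_spec()].
#' @param images A [spectrum_image()], a list of them, or a
#'   `side x side x n` array.
#' @param training_mode Logical; see above.
#' @param seed Seed for the dropout masks when `training_mode = TRUE`.
#' @param precision `"single"` (default; the training workhorse) or
#'   `"double"`; both run the identical compiled code path.
#' @return An `n x K` matrix of embeddings, entries in (-1, 1).
#' @export
embed <- function(weights, spec, images, training_mode = FALSE, seed = 1L,
                  precision = c("single", "double")) {
  use_double <- match.arg(precision) == "double"
  arr <- if (is.array(images) && length(dim(images)) == 3L) images
         else images_to_array(images, spec)
  n <- dim(arr)[3]
  masks <- if (training_mode) with_seed(seed, dropout_masks(spec, n)) else list()
  ## chunk evaluation-mode batches to bound im2col memory
  if (!training_mode) {
    chunk <- max(1L, as.integer(4e6 / spec$input_side^2))
    out <- matrix(0, n, spec$K)
    for (s in seq(1L, n, by = chunk)) {
      e <- min(n, s + chunk - 1L)
      E <- cpp_embed(weights, unclass(spec), arr[, , s:e, drop = FALSE],
                     FALSE, list(), use_double)
      out[s:e, ] <- t(E)
    }
    return(out)
  }
  t(cpp_embed(weights, unclass(spec), arr, TRUE, masks, use_double))
}

#' Euclidean distance between embeddings
#'
#' The distance \eqn{d(x_i, x_j) = \lVert G_W(x_i) - G_W(x_j) \rVert_2}
#' underlying both the loss and all retrieval.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
pairwise_distance <- function(a, b) {
  if (length(a) != length(b)) stop("embedding dimensions differ")
  sqrt(sum((a - b)^2))
}

#' Margin-based contrastive loss
#'
#' The spring energy minimized during training, with the margin applied on
#' both branches:
#' same pair, \eqn{L = \frac12 \max(0, d - m)^2}; different pair,
#' \eqn{L = \frac12 \max(0, m - d)^2}. Same-family pairs are pulled inside
#' the margin, different-family pairs pushed beyond it; within those regions
#' the loss is flat.
#'
#' @param d Non-negative distance (vectorized).
#' @param same Logical: do the two spectra share a family label?
#' @param m Margin, strictly positive. Default 1.
#' @return Non-negative loss value(s).
#' @export
contrastive_loss <- function(d, same, m = 1) {
  if (!(is.numeric(m) && length(m) == 1L && m > 0)) stop("margin m must be > 0")
  if (any(d < 0)) stop("distances must be non-negative")
  ifelse(same, 0.5 * pmax(0, d - m)^2, 0.5 * pmax(0, m - d)^2)
}

#' Aligned batch of spectrum pairs
#'
#' @param left_images,right_images Lists of [spectrum_image()] of equal
#'   length.
#' @param left_labels,right_labels Family labels; the same/different flag is
#'   always derived from these, never supplied directly.
#' @return A `pair_batch`.
#' @export
pair_batch <- function(left_images, right_images, left_labels, right_labels) {
  n <- length(left_images)
  stopifnot(length(right_images) == n, length(left_labels) == n,
            length(right_labels) == n)
  structure(list(left = left_images, right = right_images,
                 same = as.character(left_labels) == as.character(right_labels)),
            class = "pair_batch")
}

#' Mean contrastive loss of a pair batch
#'
#' Both members of every pair pass through the same weights (the twin pass),
#' so the loss is invariant to swapping left and right inputs.
#'
#' @param weights,spec Network weights and architecture.
#' @param batch A [pair_batch()].
#' @param m Margin.
#' @param training_mode Use batch statistics + dropout (TRUE) or running
#'   statistics (FALSE, default).
#' @param seed Dropout seed for the training-mode pass.
#' @param precision `"single"` (default) or `"double"` compiled path.
#' @return Scalar mean loss.
#' @export
batch_loss <- function(weights, spec, batch, m = 1, training_mode = FALSE,
                       seed = 1L, precision = "single") {
  if (length(batch$left) == 0L) stop("empty pair batch")
  fb <- forward_batch(weights, spec, batch, m, training_mode, seed,
                      want_grad = FALSE, precision = precision)
  fb$loss
}

## Shared forward(/backward) driver used by batch_loss and the trainer.
forward_batch <- function(weights, spec, batch, m, training_mode, seed,
                          want_grad, precision = "single") {
  left <- images_to_array(batch$left, spec)
  right <- images_to_array(batch$right, spec)
  n <- length(batch$same)
  masks <- if (training_mode) with_seed(seed, dropout_masks(spec, 2L * n))
           else list()
  cpp_loss_grad(weights, unclass(spec), left, right, batch$same, m, masks,
                training_mode, want_grad,
                identical(precision, "double"))
}

#' Analytic gradient of the batch loss
#'
#' Training-mode loss and its gradient with respect to every trainable
#' tensor (convolution kernels, fully connected matrices, biases, batch-norm
#' scales and offsets), computed by backpropagation through the twin pass.
#' Also returns the per-layer batch-norm batch statistics so a trainer can
#' maintain running averages.
#'
#' @inheritParams batch_loss
#' @return List with `loss`, `grads` (named like the weights), `stats`, and
#'   per-pair `distances`.
#' @export
batch_gradient <- function(weights, spec, batch, m = 1, seed = 1L,
                           precision = "single") {
  if (length(batch$left) == 0L) stop("empty pair batch")
  forward_batch(weights, spec, batch, m, training_mode = TRUE, seed = seed,
                want_grad = TRUE, precision = precision)
}

#' Largest attainable embedding distance
#'
#' Embeddings live in the tanh hypercube \eqn{[-1,1]^K}, so no two spectra
#' can be farther apart than the diagonal \eqn{2\sqrt{K}}.
#'
#' @param K Embedding dimension.
#' @return `2 * sqrt(K)`.
#' @export
max_embedding_distance <- function(K) 2 * sqrt(K)
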