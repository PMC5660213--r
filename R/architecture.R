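#' Architecture of the embedding network
#'
#' The 8-layer convolutional network realizing the embedding function
#' \eqn{G_W}: four convolutional layers (8, 16, 16, 16 filters of 4x4, stride
#' 1, size-preserving padding), each followed by 4x4 max-pooling with stride
#' 2, then three fully connected layers of 128 units with dropout 0.5, and a
#' final fully connected embedding layer of `K` units. Every layer, including
#' the output, uses the hyperbolic tangent activation, so embeddings live in
#' \eqn{[-1, 1]^K}. Batch normalization is applied after every linear map
#' except the embedding layer.
#'
#' `input_side` is configurable: the four conv/pool stages are fixed and the
#' flattened size adapts. Pooling without padding requires the map entering
#' each pool stage to be at least 4 px, which bounds `input_side` from below
#' (46 px for four stages).
#'
#' @param input_side Input image side in pixels (default 512).
#' @param K Embedding dimension (default 10).
#' @param conv_filters Filters per conv layer.
#' @param fc_sizes Widths of the three hidden fully connected layers.
#' @param dropout_p Dropout probability on the hidden fully connected layers.
#' @return An `architecture_spec`.
#' @export
architecture_spec <- function(input_side = 512L, K = 10L,
                              conv_filters = c(8L, 16L, 16L, 16L),
                              fc_sizes = c(128L, 128L, 128L),
                              dropout_p = 0.5) {
  input_side <- as.integer(input_side); K <- as.integer(K)
  if (K < 2L) stop("embedding dimension K must be >= 2")
  if (dropout_p < 0 || dropout_p >= 1) stop("dropout_p must lie in [0, 1)")
  spec <- structure(list(input_side = input_side, K = K,
                         conv_filters = as.integer(conv_filters),
                         kernel = 4L, pool = 4L, pool_stride = 2L,
                         fc_sizes = as.integer(fc_sizes),
                         dropout_p = dropout_p),
                    class = "architecture_spec")
  feature_map_sizes(spec)  # validates feasibility
  spec
}

#' Per-stage feature-map sizes
#'
#' @param spec An [architecture_spec()].
#' @return List with `conv_sides` (map side after each pool stage) and
#'   `flatten` (flattened feature count entering the fully connected stack).
#' @export
feature_map_sizes <- function(spec) {
  s <- spec$input_side
  sides <- integer(length(spec$conv_filters))
  for (l in seq_along(spec$conv_filters)) {
    if (s < spec$pool) {
      stop(sprintf("architecture infeasible: map entering pool stage %d is %d px (< pool window %d); increase input_side",
                   l, s, spec$pool))
    }
    s <- (s - spec$pool) %/% spec$pool_stride + 1L
    if (s < 1L) stop(sprintf("architecture infeasible: map collapses at stage %d", l))
    sides[l] <- s
  }
  list(conv_sides = sides,
       flatten = spec$conv_filters[length(spec$conv_filters)] * s * s)
}

#' @export
print.architecture_spec <- function(x, ...) {
  fm <- feature_map_sizes(x)
  cat(sprintf("siamese CNN: input %dx%d -> conv/pool maps %s -> fc %s -> K=%d (tanh output)\n",
              x$input_side, x$input_side,
              paste(fm$conv_sides, collapse = "/"),
              paste(x$fc_sizes, collapse = "/"), x$K))
  invisible(x)
}

#' Initialize network weights
#'
#' Xavier (Glorot) initialization: every weight tensor is drawn from a
#' zero-mean Gaussian with variance `2 / (fan_in + fan_out)`; biases start at
#' zero, batch-norm scales at 1 and offsets at 0, and the batch-norm running
#' statistics at (0, 1).
#'
#' @param spec An [architecture_spec()].
#' @param seed Integer seed; deterministic given it.
#' @return A named list of parameter tensors (class `network_weights`).
#' @export
init_weights <- function(spec, seed = 1L) {
  fm <- feature_map_sizes(spec)
  k2 <- spec$kernel^2
  in_ch <- c(1L, spec$conv_filters[-length(spec$conv_filters)])
  with_seed(seed, {
    w <- list()
    for (l in seq_along(spec$conv_filters)) {
      out <- spec$conv_filters[l]
      fan_in <- in_ch[l] * k2; fan_out <- out * k2
      nm <- paste0("conv", l)
      w[[paste0(nm, ".W")]] <- matrix(
        stats::rnorm(out * in_ch[l] * k2, 0, sqrt(2 / (fan_in + fan_out))),
        out, in_ch[l] * k2)
      w[[paste0(nm, ".b")]] <- numeric(out)
      w[[paste0(nm, ".gamma")]] <- rep(1, out)
      w[[paste0(nm, ".beta")]] <- numeric(out)
      w[[paste0(nm, ".rmean")]] <- numeric(out)
      w[[paste0(nm, ".rvar")]] <- rep(1, out)
    }
    fc_in <- c(fm$flatten, spec$fc_sizes[-length(spec$fc_sizes)])
    for (l in seq_along(spec$fc_sizes)) {
      out <- spec$fc_sizes[l]
      nm <- paste0("fc", l + length(spec$conv_filters))
      w[[paste0(nm, ".W")]] <- matrix(
        stats::rnorm(out * fc_in[l], 0, sqrt(2 / (fc_in[l] + out))),
        out, fc_in[l])
      w[[paste0(nm, ".b")]] <- numeric(out)
      w[[paste0(nm, ".gamma")]] <- rep(1, out)
      w[[paste0(nm, ".beta")]] <- numeric(out)
      w[[paste0(nm, ".rmean")]] <- numeric(out)
      w[[paste0(nm, ".rvar")]] <- rep(1, out)
    }
    last_in <- spec$fc_sizes[length(spec$fc_sizes)]
    w[["fc8.W"]] <- matrix(stats::rnorm(spec$K * last_in, 0,
                                        sqrt(2 / (last_in + spec$K))),
                           spec$K, last_in)
    w[["fc8.b"]] <- numeric(spec$K)
    class(w) <- "network_weights"
    w
  })
}

#' Names of the trainable tensors (running statistics excluded)
#' @param weights A `network_weights` list.
#' @return Character vector of names.
#' @export
trainable_names <- function(weights) {
  nm <- names(weights)
  nm[!grepl("\\.(rmean|rvar)$", nm)]
}
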