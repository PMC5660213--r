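#' Training configuration
#'
#' Hyperparameters of the siamese training protocol. Defaults follow the
#' reference protocol: initial learning rate 0.001 (Adagrad), mini-batch of
#' 256 pairs split exactly 50/50 into positive (same family) and negative
#' (different family) pairs. `batch_size` counts pairs and must be even so
#' the split is exact; `positive_fraction` is fixed at 0.5 and exposed only
#' for documentation. Validation average precision is evaluated every
#' `eval_interval` iterations; training stops early after `patience`
#' consecutive evaluations without improvement.
#'
#' @param learning_rate Adagrad initial step size.
#' @param batch_size Pairs per mini-batch (even).
#' @param margin Contrastive-loss margin m.
#' @param max_iterations Hard iteration cap.
#' @param patience Evaluations without improvement before stopping.
#' @param eval_interval Iterations between validation evaluations.
#' @param positive_fraction Fraction of positive pairs per batch (fixed 0.5).
#' @param seed Master seed for initialization, pair sampling and dropout.
#' @return A `training_config`.
#' @export
training_config <- function(learning_rate = 0.001, batch_size = 256L,
                            margin = 1, max_iterations = 1000L,
                            patience = 5L, eval_interval = 100L,
                            positive_fraction = 0.5, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  batch_size <- as.integer(batch_size)
  if (batch_size < 2L || batch_size %% 2L != 0L) {
    stop("batch_size must be an even integer >= 2 (exact 50/50 pair split)")
  }
  if (positive_fraction != 0.5) {
    stop("positive_fraction is fixed at 0.5 by the training protocol")
  }
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 margin = margin, max_iterations = as.integer(max_iterations),
                 patience = as.integer(patience),
                 eval_interval = as.integer(eval_interval),
                 positive_fraction = 0.5, seed = as.integer(seed)),
            class = "training_config")
}

#' k-fold train/validation/test splits
#'
#' One random shuffle of the dataset, then fold k takes the k-th tenth as its
#' test set, the cyclically next tenth as validation, and the remaining 80%
#' for training (8:1:1 with `n_folds = 10`). Across the folds every spectrum
#' appears in exactly one test set.
#'
#' @param manifest A `dataset_manifest`.
#' @param n_folds Number of folds (default 10).
#' @param seed Shuffle seed.
#' @return A list of `fold_split` objects with fields `fold_index`,
#'   `train_ids`, `validation_ids`, `test_ids`.
#' @export
make_folds <- function(manifest, n_folds = 10L, seed = 1L) {
  n <- nrow(manifest)
  n_folds <- as.integer(n_folds)
  if (n < n_folds) stop("dataset smaller than the number of folds")
  ids <- with_seed(seed, sample(manifest$spectrum_id))
  bounds <- floor(n * seq(0L, n_folds) / n_folds)
  chunks <- lapply(seq_len(n_folds), function(k) ids[(bounds[k] + 1L):bounds[k + 1L]])
  lapply(seq_len(n_folds), function(k) {
    val_k <- if (k == n_folds) 1L else k + 1L
    structure(list(fold_index = k - 1L,
                   test_ids = chunks[[k]],
                   validation_ids = chunks[[val_k]],
                   train_ids = unlist(chunks[-c(k, val_k)], use.names = FALSE)),
              class = "fold_split")
  })
}

#' Sample a 50/50 mini-batch of spectrum pairs
#'
#' Exactly half the pairs are positive (two distinct spectra from the same
#' family, sampled uniformly with replacement over all eligible same-family
#' pairs) and half negative (two spectra from different families, uniform
#' over cross-family pairs).
#'
#' @param manifest A `dataset_manifest`.
#' @param images Named list of [spectrum_image()] keyed by spectrum_id.
#' @param ids Spectrum ids eligible for sampling (the training set).
#' @param batch_size Even number of pairs.
#' @param seed Sampling seed.
#' @return A [pair_batch()] with additional fields `left_ids`, `right_ids`.
#' @export
sample_minibatch_pairs <- function(manifest, images, ids, batch_size,
                                   seed = 1L) {
  batch_size <- as.integer(batch_size)
  if (batch_size %% 2L != 0L) stop("batch_size must be even")
  sub <- manifest[manifest$spectrum_id %in% ids, , drop = FALSE]
  fam_ids <- split(sub$spectrum_id, sub$family)
  sizes <- lengths(fam_ids)
  if (length(fam_ids) < 2L) {
    stop("training set has a single family: cannot form negative pairs")
  }
  pos_fams <- fam_ids[sizes >= 2L]
  if (length(pos_fams) == 0L) {
    stop("no family with >= 2 members: cannot form positive pairs")
  }
  n_half <- batch_size %/% 2L
  with_seed(seed, {
    pos_w <- choose(lengths(pos_fams), 2)
    pf <- sample.int(length(pos_fams), n_half, replace = TRUE,
                     prob = pos_w / sum(pos_w))
    pos <- t(vapply(pf, function(f) sample(pos_fams[[f]], 2L), character(2)))
    neg <- matrix("", n_half, 2L)
    fam_of <- stats::setNames(sub$family, sub$spectrum_id)
    for (i in seq_len(n_half)) {
      repeat {
        pick <- sub$spectrum_id[sample.int(nrow(sub), 2L)]
        if (fam_of[[pick[1]]] != fam_of[[pick[2]]]) break
      }
      neg[i, ] <- pick
    }
    left_ids <- c(pos[, 1], neg[, 1])
    right_ids <- c(pos[, 2], neg[, 2])
    batch <- pair_batch(images[left_ids], images[right_ids],
                        fam_of[left_ids], fam_of[right_ids])
    batch$left_ids <- left_ids
    batch$right_ids <- right_ids
    batch
  })
}

#' One Adagrad update
#'
#' Elementwise: the squared-gradient accumulator grows by `gradient^2` and
#' the weight moves by `-learning_rate * gradient / (sqrt(accumulator) +
#' epsilon)`, so the effective step size shrinks automatically for
#' frequently-updated coordinates.
#'
#' @param weights,gradients,accumulators Named lists of matching tensors
#'   (`gradients` may cover a subset of `weights`; only those entries move).
#' @param learning_rate Positive scalar.
#' @param epsilon Small stabilizer (default 1e-8).
#' @return List with updated `weights` and `accumulators`.
#' @export
adagrad_step <- function(weights, gradients, accumulators, learning_rate,
                         epsilon = 1e-8) {
  for (nm in names(gradients)) {
    g <- gradients[[nm]]
    if (is.null(weights[[nm]]) || length(weights[[nm]]) != length(g)) {
      stop(sprintf("gradient/weight shape mismatch for %s", nm))
    }
    accumulators[[nm]] <- accumulators[[nm]] + g * g
    weights[[nm]] <- weights[[nm]] - learning_rate * g / (sqrt(accumulators[[nm]]) + epsilon)
  }
  list(weights = weights, accumulators = accumulators)
}

zero_like <- function(weights, names) {
  out <- lapply(weights[names], function(x) x * 0)
  names(out) <- names
  out
}

BN_MOMENTUM <- 0.1

update_running_stats <- function(weights, stats) {
  for (nm in names(stats)) {
    if (grepl("\\.mean$", nm)) {
      key <- sub("\\.mean$", ".rmean", nm)
      weights[[key]] <- (1 - BN_MOMENTUM) * weights[[key]] + BN_MOMENTUM * stats[[nm]]
    } else if (grepl("\\.var$", nm)) {
      key <- sub("\\.var$", ".rvar", nm)
      weights[[key]] <- (1 - BN_MOMENTUM) * weights[[key]] + BN_MOMENTUM * stats[[nm]]
    }
  }
  weights
}

validation_ap <- function(weights, spec, manifest, images, train_ids, val_ids) {
  corpus_ids <- train_ids
  emb_c <- embed(weights, spec, images[corpus_ids])
  emb_q <- embed(weights, spec, images[val_ids])
  fam <- stats::setNames(manifest$family, manifest$spectrum_id)
  corpus <- embedding_set(corpus_ids, fam[corpus_ids], emb_c)
  queries <- embedding_set(val_ids, fam[val_ids], emb_q)
  pr <- precision_recall_curve(corpus, queries)
  pr$auc
}

#' Train the siamese network on one fold
#'
#' Mini-batch Adagrad on the contrastive loss, with 50/50 pair sampling,
#' dropout and batch normalization active during training passes, validation
#' average precision (area under the retrieval precision-recall curve, with
#' validation spectra querying the training corpus) monitored every
#' `eval_interval` iterations, and early stopping: the weights returned are
#' those of the best evaluation, with batch-norm running statistics frozen
#' at that checkpoint.
#'
#' @param manifest A `dataset_manifest`.
#' @param images Named list of [spectrum_image()].
#' @param split A `fold_split` from [make_folds()].
#' @param spec An [architecture_spec()].
#' @param config A [training_config()].
#' @param verbose Print progress lines.
#' @return List with `weights` (best checkpoint), `log` (data frame of
#'   iteration, loss, validation AP), `best_ap`, `best_iteration`.
#' @export
train_siamese <- function(manifest, images, split, spec, config,
                          verbose = FALSE) {
  stopifnot(inherits(split, "fold_split"), inherits(config, "training_config"))
  weights <- init_weights(spec, derive_seed(config$seed, 101L))
  acc <- zero_like(weights, trainable_names(weights))
  best <- list(ap = -Inf, weights = weights, iteration = 0L)
  bad_evals <- 0L
  log_it <- integer(0); log_loss <- numeric(0); log_ap <- numeric(0)
  for (iter in seq_len(config$max_iterations)) {
    batch <- sample_minibatch_pairs(manifest, images, split$train_ids,
                                    config$batch_size,
                                    derive_seed(config$seed, 202L, iter))
    fb <- batch_gradient(weights, spec, batch, config$margin,
                         seed = derive_seed(config$seed, 303L, iter))
    if (!is.finite(fb$loss)) {
      stop(sprintf("non-finite training loss at iteration %d", iter))
    }
    weights <- update_running_stats(weights, fb$stats)
    upd <- adagrad_step(weights, fb$grads, acc, config$learning_rate)
    weights <- upd$weights; acc <- upd$accumulators
    ap <- NA_real_
    if (iter %% config$eval_interval == 0L || iter == config$max_iterations) {
      ap <- validation_ap(weights, spec, manifest, images,
                          split$train_ids, split$validation_ids)
      if (ap > best$ap) {
        best <- list(ap = ap, weights = weights, iteration = iter)
        bad_evals <- 0L
      } else {
        bad_evals <- bad_evals + 1L
      }
      if (verbose) {
        message(sprintf("iter %d: loss %.4f, val AP %.4f (best %.4f @ %d)",
                        iter, fb$loss, ap, best$ap, best$iteration))
      }
    }
    log_it <- c(log_it, iter); log_loss <- c(log_loss, fb$loss)
    log_ap <- c(log_ap, ap)
    if (!is.na(ap) && bad_evals >= config$patience) break
  }
  class(best$weights) <- "network_weights"
  list(weights = best$weights,
       log = data.frame(iteration = log_it, loss = log_loss,
                        validation_ap = log_ap),
       best_ap = best$ap, best_iteration = best$iteration)
}

#' k-fold cross-validated training and evaluation
#'
#' Trains one network per fold and evaluates it on that fold's held-out test
#' spectra (test queries against the fold's training corpus): retrieval
#' PR-AUC and closest-retrieval fractions at ranks 1, 5, 10 and 20. Reported
#' aggregates are arithmetic means across folds.
#'
#' @inheritParams train_siamese
#' @param n_folds Number of folds (default 10).
#' @return List with `per_fold` (data frame), `mean` (named vector),
#'   `models` (per-fold training results).
#' @export
crossvalidate <- function(manifest, images, spec, config, n_folds = 10L,
                          verbose = FALSE) {
  folds <- make_folds(manifest, n_folds, derive_seed(config$seed, 404L))
  fam <- stats::setNames(manifest$family, manifest$spectrum_id)
  models <- vector("list", n_folds)
  rows <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    fit <- train_siamese(manifest, images, folds[[k]], spec, config, verbose)
    models[[k]] <- fit
    tr_ids <- folds[[k]]$train_ids; te_ids <- folds[[k]]$test_ids
    corpus <- embedding_set(tr_ids, fam[tr_ids],
                            embed(fit$weights, spec, images[tr_ids]))
    queries <- embedding_set(te_ids, fam[te_ids],
                             embed(fit$weights, spec, images[te_ids]))
    pr <- precision_recall_curve(corpus, queries)
    crc <- closest_retrieval_curve(corpus, queries)
    at <- function(k_) if (k_ <= length(crc$fraction)) crc$fraction[k_] else 1
    rows[[k]] <- data.frame(fold = k - 1L, pr_auc = pr$auc,
                            top1 = at(1L), top5 = at(5L),
                            top10 = at(10L), top20 = at(20L))
  }
  per_fold <- do.call(rbind, rows)
  list(per_fold = per_fold,
       mean = colMeans(per_fold[, -1, drop = FALSE]),
       models = models)
}
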