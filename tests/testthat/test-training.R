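test_that("fold splits are 8:1:1 partitions covering every spectrum once", {
  man <- dataset_manifest(sprintf("s%03d", 1:100),
                          family = rep(sprintf("f%02d", 1:20), each = 5))
  folds <- make_folds(man, 10, seed = 4)
  expect_length(folds, 10)
  for (f in folds) {
    expect_length(f$test_ids, 10)
    expect_length(f$validation_ids, 10)
    expect_length(f$train_ids, 80)
    expect_equal(sort(c(f$train_ids, f$validation_ids, f$test_ids)),
                 sort(man$spectrum_id))
  }
  all_tests <- unlist(lapply(folds, `[[`, "test_ids"))
  expect_equal(sort(all_tests), sort(man$spectrum_id))  # disjoint cover
  expect_identical(make_folds(man, 10, seed = 4), folds)
  expect_error(make_folds(man[1:5, ], 10), "smaller")
})

test_that("mini-batches are an exact 50/50 split of valid positive and negative pairs", {
  ds <- tiny_dataset(4, 8, seed = 6)
  fam <- setNames(ds$manifest$family, ds$manifest$spectrum_id)
  b <- sample_minibatch_pairs(ds$manifest, ds$images, ds$manifest$spectrum_id,
                              256, seed = 1)
  expect_length(b$same, 256)
  expect_equal(sum(b$same), 128)
  expect_equal(sum(!b$same), 128)
  expect_true(all((fam[b$left_ids] == fam[b$right_ids]) == b$same))
  expect_true(all(b$left_ids != b$right_ids | !b$same))  # no self pairs

  single <- ds$manifest[ds$manifest$family == ds$manifest$family[1], ]
  expect_error(sample_minibatch_pairs(single, ds$images, single$spectrum_id, 8),
               "single family")

  ## no family with two members -> positives impossible
  onesies <- dataset_manifest(c("a", "b"), family = c("f1", "f2"))
  expect_error(sample_minibatch_pairs(onesies, ds$images[1:2], c("a", "b"), 8),
               "positive")
})

test_that("every training spectrum appears with positive frequency (no starvation)", {
  ds <- tiny_dataset(4, 8, seed = 6)
  counts <- setNames(numeric(nrow(ds$manifest)), ds$manifest$spectrum_id)
  for (s in 1:40) {
    b <- sample_minibatch_pairs(ds$manifest, ds$images,
                                ds$manifest$spectrum_id, 64, seed = s)
    tab <- table(c(b$left_ids, b$right_ids))
    counts[names(tab)] <- counts[names(tab)] + tab
  }
  expect_true(all(counts > 0))
  ## chi-square against uniform at coarse tolerance
  p <- suppressWarnings(chisq.test(counts)$p.value)
  expect_gt(p, 1e-4)
})

test_that("the Adagrad update follows its recursion", {
  ## fixed point at zero gradient
  w <- list(a = matrix(c(1, 2, 3, 4), 2), b = c(0.5, -0.5))
  g0 <- list(a = matrix(0, 2, 2), b = c(0, 0))
  acc <- list(a = matrix(0, 2, 2), b = c(0, 0))
  out <- adagrad_step(w, g0, acc, 0.1)
  expect_identical(out$weights, w)
  expect_identical(out$accumulators, acc)

  ## scalar case: w=0, g=2, acc=0, lr=0.1 -> acc=4, w ~ -0.1
  s <- adagrad_step(list(x = 0), list(x = 2), list(x = 0), 0.1, 1e-8)
  expect_equal(s$accumulators$x, 4)
  expect_equal(s$weights$x, -0.1 * 2 / (2 + 1e-8))

  ## repeated identical gradients -> non-increasing step magnitude
  wv <- list(x = 0); av <- list(x = 0)
  steps <- numeric(10)
  for (i in 1:10) {
    prev <- wv$x
    upd <- adagrad_step(wv, list(x = 3), av, 0.05)
    wv <- upd$weights; av <- upd$accumulators
    steps[i] <- abs(wv$x - prev)
  }
  expect_true(all(diff(steps) <= 1e-12))

  expect_error(adagrad_step(list(a = 1:2), list(a = 1:3), list(a = 1:2), 0.1),
               "mismatch")
})

test_that("training reduces the loss and is reproducible end to end", {
  ds <- tiny_dataset(2, 8, seed = 10,
                     model = perturbation_model(peak_add_rate = 0.5))
  spec <- architecture_spec(64L, 5L)
  split <- make_folds(ds$manifest, 4, seed = 2)[[1]]
  cfg <- training_config(batch_size = 8L, max_iterations = 150L,
                         eval_interval = 50L, patience = 5L, seed = 3L)
  fit <- train_siamese(ds$manifest, ds$images, split, spec, cfg)
  first10 <- mean(fit$log$loss[1:10])
  last10 <- mean(tail(fit$log$loss, 10))
  expect_lt(last10, first10)

  fit2 <- train_siamese(ds$manifest, ds$images, split, spec, cfg)
  expect_identical(fit$log, fit2$log)
  expect_identical(fit$weights, fit2$weights)
})

test_that("early stopping halts after `patience` flat evaluations", {
  ds <- tiny_dataset(2, 6, seed = 11)
  spec <- architecture_spec(64L, 4L)
  split <- make_folds(ds$manifest, 4, seed = 1)[[1]]
  ## learning rate 0: weights frozen, validation AP constant -> the second
  ## evaluation is not an improvement and patience 1 stops there
  cfg <- training_config(learning_rate = 1e-12, batch_size = 4L,
                         max_iterations = 500L, eval_interval = 50L,
                         patience = 1L, seed = 5L)
  fit <- train_siamese(ds$manifest, ds$images, split, spec, cfg)
  expect_equal(max(fit$log$iteration), 100L)
  expect_equal(fit$best_iteration, 50L)
})

test_that("cross-validation reports one metric row per fold plus their mean", {
  ds <- tiny_dataset(5, 4, seed = 12)
  spec <- architecture_spec(64L, 4L)
  cfg <- training_config(batch_size = 4L, max_iterations = 10L,
                         eval_interval = 10L, patience = 2L, seed = 9L)
  ## tiny folds can lose a family from the corpus; those queries warn
  cv <- suppressWarnings(crossvalidate(ds$manifest, ds$images, spec, cfg,
                                       n_folds = 4L))
  expect_equal(nrow(cv$per_fold), 4)
  expect_equal(unname(cv$mean["pr_auc"]), mean(cv$per_fold$pr_auc))
  expect_equal(unname(cv$mean["top1"]), mean(cv$per_fold$top1))
  expect_true(all(cv$per_fold$pr_auc >= 0 & cv$per_fold$pr_auc <= 1))
})
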