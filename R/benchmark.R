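## Standard seeded desk-scale experiments. These fix the study conditions
## (corpus composition, image size, training protocol) in one place so that
## tests, scripts and interactive use all run the identical procedure.

#' Siamese-versus-PCA retrieval benchmark
#'
#' The standard desk-scale benchmark: a synthetic corpus of 20 compound
#' families with 8 members each at 128 px, one 8:1:1 fold, siamese training
#' with mini-batches of 32 pairs (Adagrad, early stopping on validation
#' average precision), and the k = 10 pixel-space PCA baseline evaluated on
#' the identical split. Test spectra query the fold's training corpus.
#'
#' @param seed Master seed controlling corpus, split, initialization, pair
#'   sampling and dropout.
#' @param input_side Raster size (default 128).
#' @param n_families,members Corpus composition (default 20 x 8).
#' @param max_iterations,eval_interval,patience Training protocol: at most
#'   150 iterations (validation average precision plateaus slowly beyond
#'   that at this corpus size; the trajectory is in the training log),
#'   evaluated every 25 with early stopping after 3 flat evaluations.
#' @param verbose Print training progress.
#' @return List with `pr_auc_siamese`, `pr_auc_pca`, `top1`, the training
#'   `fit`, and the evaluated embedding sets.
#' @export
run_retrieval_benchmark <- function(seed, input_side = 128L,
                                    n_families = 20L, members = 8L,
                                    max_iterations = 150L,
                                    eval_interval = 25L, patience = 3L,
                                    verbose = FALSE) {
  cal <- default_calibration(input_side)
  tpl <- generate_templates(n_families, size_range = c(members, members),
                            calibration = cal, seed = derive_seed(seed, 1L))
  ds <- build_dataset(tpl, perturbation_model(), cal, derive_seed(seed, 2L))
  spec <- architecture_spec(input_side, K = 10L)
  split <- make_folds(ds$manifest, 10L, derive_seed(seed, 3L))[[1]]
  fam <- stats::setNames(ds$manifest$family, ds$manifest$spectrum_id)
  cfg <- training_config(batch_size = 32L, max_iterations = max_iterations,
                         eval_interval = eval_interval, patience = patience,
                         seed = derive_seed(seed, 4L))
  fit <- train_siamese(ds$manifest, ds$images, split, spec, cfg,
                       verbose = verbose)
  corpus <- embedding_set(split$train_ids, fam[split$train_ids],
                          embed(fit$weights, spec, ds$images[split$train_ids]))
  queries <- embedding_set(split$test_ids, fam[split$test_ids],
                           embed(fit$weights, spec, ds$images[split$test_ids]))
  pr <- precision_recall_curve(corpus, queries)
  crc <- closest_retrieval_curve(corpus, queries)
  base <- pca_baseline(ds$images, ds$manifest, k = 10L)
  sub <- function(ids) embedding_set(ids, fam[ids],
    base$coordinates[match(ids, base$spectrum_ids), , drop = FALSE])
  pr_pca <- precision_recall_curve(sub(split$train_ids), sub(split$test_ids))
  list(pr_auc_siamese = pr$auc, pr_auc_pca = pr_pca$auc,
       top1 = crc$fraction[1], fit = fit, corpus = corpus, queries = queries,
       dataset = ds, split = split, spec = spec)
}

#' Novel-category placement experiment
#'
#' Emulates exposing the trained network to a compound family it never saw:
#' one family's template is duplicated into a structurally similar "sibling"
#' (shared parent scaffold, slightly displaced peaks plus one
#' insertion/deletion), the sibling family is excluded from training
#' entirely, and its members are then embedded. Proper placement means the
#' held-out members land nearer their sibling's cluster than a typical
#' unrelated family's cluster.
#'
#' @param seed Master seed.
#' @param input_side Raster size (default 64 for speed).
#' @param n_families Trained families (default 8).
#' @param members Members per family (default 6).
#' @param verbose Print training progress.
#' @return List with `dist_to_sibling`, `dist_to_others` (per family),
#'   `median_other`, and `placed` (TRUE when sibling < median other).
#' @export
run_novel_family_experiment <- function(seed, input_side = 64L,
                                        n_families = 8L, members = 6L,
                                        verbose = FALSE) {
  cal <- default_calibration(input_side)
  tpl <- generate_templates(n_families, size_range = c(members, members),
                            calibration = cal, seed = derive_seed(seed, 11L))
  ## sibling of family 1: same scaffold, peaks nudged, one peak swapped
  sib <- tpl[[1]]
  sib$family_id <- "novel"
  pk <- as.data.frame(sib$template_peaks)
  set.seed(derive_seed(seed, 12L))
  pk$h_ppm <- pmin(pmax(pk$h_ppm + stats::rnorm(nrow(pk), 0, 0.05),
                        cal$h_min_ppm), cal$h_max_ppm)
  pk$c_ppm <- pmin(pmax(pk$c_ppm + stats::rnorm(nrow(pk), 0, 0.5),
                        cal$c_min_ppm), cal$c_max_ppm)
  drop_one <- sample.int(nrow(pk), 1L)
  pk <- pk[-drop_one, ]
  pk <- rbind(pk, data.frame(h_ppm = stats::runif(1, cal$h_min_ppm, cal$h_max_ppm),
                             c_ppm = stats::runif(1, cal$c_min_ppm, cal$c_max_ppm),
                             intensity = 1))
  sib$template_peaks <- peak_list("novel_template", pk$h_ppm, pk$c_ppm)
  ds <- build_dataset(c(tpl, list(sib)), perturbation_model(), cal,
                      derive_seed(seed, 13L))
  man_train <- ds$manifest[ds$manifest$family != "novel", ]
  class(man_train) <- class(ds$manifest)
  spec <- architecture_spec(input_side, K = 10L)
  split <- make_folds(man_train, 10L, derive_seed(seed, 14L))[[1]]
  cfg <- training_config(batch_size = 16L, max_iterations = 200L,
                         eval_interval = 25L, patience = 3L,
                         seed = derive_seed(seed, 15L))
  fit <- train_siamese(man_train, ds$images, split, spec, cfg,
                       verbose = verbose)
  emb <- embed_dataset(fit$weights, spec, ds$images, ds$manifest)
  novel_rows <- which(emb$family_labels == "novel")
  novel_xy <- emb$coordinates[novel_rows, , drop = FALSE]
  fam_dist <- function(f) {
    rows <- which(emb$family_labels == f)
    D <- cross_distances(novel_xy, emb$coordinates[rows, , drop = FALSE])
    mean(D)
  }
  others <- setdiff(unique(emb$family_labels), c("novel", tpl[[1]]$family_id))
  dist_others <- vapply(others, fam_dist, numeric(1))
  dist_sib <- fam_dist(tpl[[1]]$family_id)
  list(dist_to_sibling = dist_sib, dist_to_others = dist_others,
       median_other = stats::median(dist_others),
       placed = dist_sib < stats::median(dist_others), fit = fit)
}

#' Noise-robustness benchmark
#'
#' Trains a small network on a synthetic corpus, then runs the
#' noise-injection protocol on one held-out spectrum: per level, noisy
#' replicates are embedded and their distance to the clean embedding
#' recorded, and the rank-1 corpus neighbour's family is checked. Reports
#' the per-level mean distance trend (Spearman correlation against the
#' noise fraction) and rank-1 retrieval accuracy per level.
#'
#' @param seed Master seed.
#' @param input_side Raster size (default 64).
#' @param n_levels,n_reps,max_fraction Noise protocol (default 20 x 10 up
#'   to half the pixels).
#' @param verbose Print training progress.
#' @return List with `per_level` (data frame: level, fraction,
#'   mean_distance, rank1_accuracy), `spearman_rho`, `spearman_p`, and the
#'   raw `results`.
#' @export
run_noise_benchmark <- function(seed, input_side = 64L, n_levels = 20L,
                                n_reps = 10L, max_fraction = 0.5,
                                verbose = FALSE) {
  cal <- default_calibration(input_side)
  tpl <- generate_templates(8L, size_range = c(6L, 6L), calibration = cal,
                            seed = derive_seed(seed, 21L))
  ds <- build_dataset(tpl, perturbation_model(), cal, derive_seed(seed, 22L))
  spec <- architecture_spec(input_side, K = 10L)
  split <- make_folds(ds$manifest, 10L, derive_seed(seed, 23L))[[1]]
  cfg <- training_config(batch_size = 16L, max_iterations = 200L,
                         eval_interval = 25L, patience = 3L,
                         seed = derive_seed(seed, 24L))
  fit <- train_siamese(ds$manifest, ds$images, split, spec, cfg,
                       verbose = verbose)
  fam <- stats::setNames(ds$manifest$family, ds$manifest$spectrum_id)
  corpus <- embedding_set(split$train_ids, fam[split$train_ids],
                          embed(fit$weights, spec, ds$images[split$train_ids]))
  ## the noise target is a training-corpus spectrum, mirroring the
  ## protocol of degrading a database compound and re-querying the database
  target_id <- split$train_ids[1]
  target_fam <- fam[[target_id]]
  proto <- noise_protocol(n_levels = n_levels, max_fraction = max_fraction,
                          n_reps = n_reps, seed = derive_seed(seed, 25L))
  res <- noise_experiment(fit$weights, spec, ds$images[[target_id]], proto,
                          compound_id = target_id)
  ## rank-1 family per noisy replicate
  sched <- noise_schedule(proto)
  rank1 <- character(nrow(sched))
  noisy <- lapply(seq_len(nrow(sched)), function(r)
    median_filter_cross(
      inject_noise(ds$images[[target_id]], sched$fraction[r],
                   sched$seed[r])$image))
  emb <- embed(fit$weights, spec, noisy)
  D <- cross_distances(emb, corpus$coordinates)
  for (r in seq_len(nrow(sched))) {
    rank1[r] <- corpus$family_labels[order(D[r, ], corpus$spectrum_ids)[1]]
  }
  res$rank1_family <- rank1
  agg <- stats::aggregate(cbind(distance_to_original, correct = rank1 == target_fam)
                          ~ level_index + fraction, data = res, FUN = mean)
  names(agg) <- c("level", "fraction", "mean_distance", "rank1_accuracy")
  ct <- suppressWarnings(stats::cor.test(agg$fraction, agg$mean_distance,
                                         method = "spearman"))
  list(per_level = agg[order(agg$level), ],
       spearman_rho = unname(ct$estimate), spearman_p = ct$p.value,
       results = res, target_family = target_fam)
}
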