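#' Embedding set
#'
#' Coordinates of a set of spectra in the K-dimensional cluster space (or a
#' 2D projection of it), aligned with their ids and family labels.
#'
#' @param spectrum_ids Character ids.
#' @param family_labels Family labels aligned with the ids.
#' @param coordinates `n x K` numeric matrix, finite entries.
#' @return An `embedding_set`.
#' @export
embedding_set <- function(spectrum_ids, family_labels, coordinates) {
  coordinates <- as.matrix(coordinates)
  spectrum_ids <- as.character(spectrum_ids)
  family_labels <- as.character(family_labels)
  if (nrow(coordinates) != length(spectrum_ids) ||
      length(family_labels) != length(spectrum_ids)) {
    stop("ids, labels and coordinate rows must align")
  }
  if (!all(is.finite(coordinates))) stop("coordinates must be finite")
  structure(list(spectrum_ids = spectrum_ids, family_labels = family_labels,
                 coordinates = coordinates),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("embedding_set: %d spectra, %d families, K=%d\n",
              length(x$spectrum_ids), length(unique(x$family_labels)),
              ncol(x$coordinates)))
  invisible(x)
}

#' Embed a labelled dataset
#'
#' Evaluation-mode embeddings for every spectrum in the manifest, row order
#' matching the manifest.
#'
#' @param weights,spec Trained network weights and architecture.
#' @param images Named list of [spectrum_image()] keyed by spectrum_id.
#' @param manifest A `dataset_manifest`.
#' @return An [embedding_set()].
#' @export
embed_dataset <- function(weights, spec, images, manifest) {
  coords <- embed(weights, spec, images[manifest$spectrum_id])
  embedding_set(manifest$spectrum_id, manifest$family, coords)
}

cross_distances <- function(qcoords, ccoords) {
  ## |q - c|^2 = |q|^2 + |c|^2 - 2 q.c
  qn <- rowSums(qcoords^2)
  cn <- rowSums(ccoords^2)
  d2 <- outer(qn, cn, "+") - 2 * qcoords %*% t(ccoords)
  sqrt(pmax(d2, 0))
}

#' k-nearest neighbours in the cluster space
#'
#' Euclidean retrieval with a stable tie rule (ascending spectrum_id) and
#' self-exclusion when a query id is present in the corpus.
#'
#' @param space Corpus [embedding_set()].
#' @param query_rows Either integer row indices into `space` or a separate
#'   [embedding_set()] of queries.
#' @param k Neighbours per query; must be < corpus size.
#' @return A `retrieval_report` data frame: query_id, rank, neighbor_id,
#'   family, distance (non-decreasing within each query).
#' @export
nearest_neighbors <- function(space, query_rows = seq_along(space$spectrum_ids),
                              k = 5L) {
  k <- as.integer(k)
  n_corpus <- length(space$spectrum_ids)
  if (k >= n_corpus) stop("k must be smaller than the corpus size")
  if (inherits(query_rows, "embedding_set")) {
    q <- query_rows
  } else {
    q <- embedding_set(space$spectrum_ids[query_rows],
                       space$family_labels[query_rows],
                       space$coordinates[query_rows, , drop = FALSE])
  }
  D <- cross_distances(q$coordinates, space$coordinates)
  out <- vector("list", length(q$spectrum_ids))
  for (i in seq_along(q$spectrum_ids)) {
    keep <- space$spectrum_ids != q$spectrum_ids[i]
    ord <- order(D[i, keep], space$spectrum_ids[keep])[seq_len(k)]
    idx <- which(keep)[ord]
    out[[i]] <- data.frame(query_id = q$spectrum_ids[i],
                           rank = seq_len(k),
                           neighbor_id = space$spectrum_ids[idx],
                           family = space$family_labels[idx],
                           distance = D[i, idx])
  }
  rep <- do.call(rbind, out)
  rownames(rep) <- NULL
  class(rep) <- c("retrieval_report", "data.frame")
  rep
}

pca_rotation <- function(coords, out_dim) {
  ctr <- colMeans(coords)
  pc <- stats::prcomp(coords, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(out_dim), drop = FALSE]
  ## deterministic sign: largest-magnitude loading positive
  for (j in seq_len(out_dim)) {
    lead <- which.max(abs(rot[, j]))
    if (rot[lead, j] < 0) rot[, j] <- -rot[, j]
  }
  list(center = ctr, rotation = rot)
}

#' Project an embedding set onto its principal axes
#'
#' Used to flatten the K-dimensional cluster space to the 2D cluster map.
#' Deterministic sign convention: each component's largest-magnitude loading
#' is positive.
#'
#' @param space An [embedding_set()].
#' @param out_dim Output dimension (default 2; at most K).
#' @return An [embedding_set()] with `out_dim` columns.
#' @export
pca_project <- function(space, out_dim = 2L) {
  K <- ncol(space$coordinates)
  n <- nrow(space$coordinates)
  if (out_dim > K) stop("out_dim exceeds the embedding dimension")
  if (n <= out_dim) stop("need more points than output dimensions")
  pr <- pca_rotation(space$coordinates, out_dim)
  scores <- sweep(space$coordinates, 2, pr$center) %*% pr$rotation
  embedding_set(space$spectrum_ids, space$family_labels, scores)
}

#' Linear PCA baseline embedding
#'
#' The linear comparator to the trained network: spectra are flattened to
#' pixel vectors, centred, and projected onto the top `k` principal
#' components of the pixel space.
#'
#' @param images Named list of [spectrum_image()].
#' @param manifest A `dataset_manifest`.
#' @param k Embedding dimension (default 10, matching the network's K).
#' @return An [embedding_set()].
#' @export
pca_baseline <- function(images, manifest, k = 10L) {
  n <- nrow(manifest)
  if (n <= k) stop("need more than k images for the PCA baseline")
  X <- t(vapply(manifest$spectrum_id,
                function(id) as.numeric(images[[id]]$pixels),
                numeric(length(images[[manifest$spectrum_id[1]]]$pixels))))
  pr <- pca_rotation(X, k)
  scores <- sweep(X, 2, pr$center) %*% pr$rotation
  embedding_set(manifest$spectrum_id, manifest$family, scores)
}

#' Expanding-hypersphere precision-recall curve
#'
#' For every query, corpus spectra are retrieved in order of distance (an
#' expanding hypersphere centred on the query). At each rank, precision =
#' TP / (TP + FP) and recall = TP / (number of same-family corpus members).
#' Per-query curves are interpolated onto a common 101-point recall grid and
#' averaged; the AUC is the trapezoidal integral of mean precision over
#' recall. Queries whose family is absent from the corpus are skipped with a
#' warning. Query ids present in the corpus are self-excluded.
#'
#' @param space Corpus [embedding_set()] (with labels).
#' @param queries Query [embedding_set()] (with labels).
#' @return A `pr_curve`: list with `recall`, `precision`, `auc`,
#'   `n_queries_used`.
#' @export
precision_recall_curve <- function(space, queries) {
  grid <- seq(0, 1, length.out = 101L)
  D <- cross_distances(queries$coordinates, space$coordinates)
  acc <- matrix(NA_real_, length(queries$spectrum_ids), length(grid))
  used <- 0L
  for (i in seq_along(queries$spectrum_ids)) {
    keep <- space$spectrum_ids != queries$spectrum_ids[i]
    fam <- space$family_labels[keep]
    rel <- fam == queries$family_labels[i]
    n_rel <- sum(rel)
    if (n_rel == 0L) {
      warning(sprintf("query %s: family %s absent from corpus; skipped",
                      queries$spectrum_ids[i], queries$family_labels[i]))
      next
    }
    ord <- order(D[i, keep], space$spectrum_ids[keep])
    tp <- cumsum(rel[ord])
    precision <- tp / seq_along(tp)
    ## smallest rank reaching each grid recall (right-continuous step)
    idx <- findInterval(grid * n_rel - 1e-9, tp) + 1L
    idx <- pmin(idx, length(tp))
    used <- used + 1L
    acc[i, ] <- precision[idx]
  }
  if (used == 0L) stop("no evaluable queries")
  mean_prec <- colMeans(acc, na.rm = TRUE)
  auc <- sum(diff(grid) * (mean_prec[-1] + mean_prec[-length(mean_prec)]) / 2)
  structure(list(recall = grid, precision = mean_prec, auc = auc,
                 n_queries_used = used),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf("precision-recall curve: AUC %.4f over %d queries\n",
              x$auc, x$n_queries_used))
  invisible(x)
}

#' Retrieval accuracy as the hypersphere radius grows
#'
#' For each node and radius r, the fraction of that node's true family
#' co-members (self excluded) lying within distance r, averaged over all
#' nodes that have at least one co-member. Non-decreasing in r.
#'
#' @param space An [embedding_set()].
#' @param radii Numeric vector of radii.
#' @return Data frame with `radius` and `fraction`.
#' @export
accuracy_vs_radius <- function(space, radii) {
  n <- length(space$spectrum_ids)
  if (n < 2L) stop("need at least 2 points")
  D <- cross_distances(space$coordinates, space$coordinates)
  fracs <- matrix(NA_real_, n, length(radii))
  for (i in seq_len(n)) {
    mates <- which(space$family_labels == space$family_labels[i])
    mates <- setdiff(mates, i)
    if (length(mates) == 0L) next
    fracs[i, ] <- vapply(radii, function(r) mean(D[i, mates] <= r), numeric(1))
  }
  if (all(is.na(fracs))) stop("no node has a family co-member")
  data.frame(radius = radii, fraction = colMeans(fracs, na.rm = TRUE))
}

#' Closest-retrieval curve
#'
#' Corpus spectra are ordered by distance from the query and collapsed to
#' the sequence of distinct family labels in first-occurrence order (a
#' ranked list of family predictions). The curve value at rank k is the
#' fraction of queries whose true family appears among the first k
#' predictions; it is non-decreasing and reaches 1 by k = number of corpus
#' families.
#'
#' @inheritParams precision_recall_curve
#' @return Data frame with `rank` and `fraction`.
#' @export
closest_retrieval_curve <- function(space, queries) {
  n_fam <- length(unique(space$family_labels))
  D <- cross_distances(queries$coordinates, space$coordinates)
  ranks <- rep(NA_integer_, length(queries$spectrum_ids))
  for (i in seq_along(queries$spectrum_ids)) {
    keep <- space$spectrum_ids != queries$spectrum_ids[i]
    if (!any(space$family_labels[keep] == queries$family_labels[i])) {
      warning(sprintf("query %s: family %s absent from corpus; skipped",
                      queries$spectrum_ids[i], queries$family_labels[i]))
      next
    }
    ord <- order(D[i, keep], space$spectrum_ids[keep])
    fam_seq <- unique(space$family_labels[keep][ord])
    ranks[i] <- match(queries$family_labels[i], fam_seq)
  }
  if (all(is.na(ranks))) stop("no evaluable queries")
  ranks <- ranks[!is.na(ranks)]
  data.frame(rank = seq_len(n_fam),
             fraction = vapply(seq_len(n_fam),
                               function(k) mean(ranks <= k), numeric(1)))
}

#' Most-occurring (MO) baseline retrieval curve
#'
#' Query-independent baseline: families are predicted in descending order of
#' member count (ties broken by ascending label). The curve value at rank k
#' is the fraction of queries whose family lies among the first k
#' predictions.
#'
#' @param manifest A `dataset_manifest` defining family sizes.
#' @param query_families Family labels of the queries; defaults to every
#'   record in the manifest.
#' @return Data frame with `rank` and `fraction`.
#' @export
mo_baseline_curve <- function(manifest, query_families = NULL) {
  sizes <- table(manifest$family)
  if (length(sizes) == 0L) stop("manifest has no families")
  pred_order <- names(sizes)[order(-as.integer(sizes), names(sizes))]
  if (is.null(query_families)) query_families <- manifest$family
  pos <- match(query_families, pred_order)
  data.frame(rank = seq_along(pred_order),
             fraction = vapply(seq_along(pred_order),
                               function(k) mean(pos <= k, na.rm = TRUE),
                               numeric(1)))
}

#' Noise-robustness experiment
#'
#' Runs a [noise_schedule()] against one clean spectrum: at every (level,
#' replicate) entry, FFT-structured noise is injected at that level's
#' fraction, the noisy spectrum is preprocessed with the standard
#' cross-median filter (like every other network input) and embedded with
#' the trained network, and
#' its distance to the clean spectrum's embedding is recorded — either in
#' the full K-dimensional space (default) or in the 2D PCA cluster-map
#' projection defined by a reference embedding set.
#'
#' @param weights,spec Trained network weights and architecture.
#' @param image Clean (preprocessed) [spectrum_image()].
#' @param protocol A [noise_protocol()].
#' @param space_for_distance `"K-dim"` or `"pca2d"`.
#' @param reference_space Corpus [embedding_set()]; required for `"pca2d"`.
#' @param compound_id Identifier recorded in the results.
#' @return Data frame: compound_id, level_index, fraction, rep_index,
#'   distance_to_original, space.
#' @export
noise_experiment <- function(weights, spec, image, protocol,
                             space_for_distance = c("K-dim", "pca2d"),
                             reference_space = NULL,
                             compound_id = "compound") {
  space_for_distance <- match.arg(space_for_distance)
  sched <- noise_schedule(protocol)
  clean <- embed(weights, spec, image)
  noisy_imgs <- vector("list", nrow(sched))
  realized <- numeric(nrow(sched))
  for (r in seq_len(nrow(sched))) {
    inj <- inject_noise(image, sched$fraction[r], sched$seed[r])
    ## noisy spectra receive the same preprocessing as every network input
    noisy_imgs[[r]] <- median_filter_cross(inj$image)
    realized[r] <- inj$realized_fraction
  }
  emb <- embed(weights, spec, noisy_imgs)
  if (space_for_distance == "pca2d") {
    if (is.null(reference_space)) stop("pca2d distances need a reference_space")
    pr <- pca_rotation(reference_space$coordinates, 2L)
    clean <- sweep(clean, 2, pr$center) %*% pr$rotation
    emb <- sweep(emb, 2, pr$center) %*% pr$rotation
  }
  dists <- sqrt(rowSums(sweep(emb, 2, as.numeric(clean))^2))
  data.frame(compound_id = compound_id,
             level_index = sched$level_index,
             fraction = sched$fraction,
             realized_fraction = realized,
             rep_index = sched$rep_index,
             distance_to_original = dists,
             space = space_for_distance)
}

#' Export the 2D cluster map
#'
#' Writes a TSV with one row per spectrum: id, family, the 2D PCA
#' cluster-map coordinates (x, y), and the full K-dimensional embedding.
#' Numeric columns are written with 17 significant digits so a re-import
#' reproduces the coordinates bit-exactly. Optionally renders a static
#' scatter plot colour-coded by family.
#'
#' @param space An [embedding_set()] (K >= 2).
#' @param path Output TSV path.
#' @param plot_path Optional PNG path for the scatter plot.
#' @return `path`, invisibly.
#' @export
export_cluster_map <- function(space, path, plot_path = NULL) {
  n <- length(space$spectrum_ids)
  if (n == 0L) stop("empty embedding set")
  K <- ncol(space$coordinates)
  xy <- if (K > 2L && n > 2L) pca_project(space, 2L)$coordinates
        else space$coordinates[, 1:2, drop = FALSE]
  df <- data.frame(spectrum_id = space$spectrum_ids,
                   family = space$family_labels,
                   x = sprintf("%.17g", xy[, 1]),
                   y = sprintf("%.17g", xy[, 2]))
  for (j in seq_len(K)) {
    df[[paste0("emb", j)]] <- sprintf("%.17g", space$coordinates[, j])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(plot_path)) {
    fam <- factor(space$family_labels)
    grDevices::png(plot_path, width = 800, height = 800)
    graphics::plot(xy[, 1], xy[, 2], col = as.integer(fam), pch = 19,
                   xlab = "PC1", ylab = "PC2",
                   main = "HSQC cluster map (2D PCA of embeddings)")
    grDevices::dev.off()
  }
  invisible(path)
}

#' Re-import an exported cluster map
#' @param path TSV written by [export_cluster_map()].
#' @return An [embedding_set()] restored from the full K-dim columns.
#' @export
read_cluster_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  emb_cols <- grep("^emb", names(df), value = TRUE)
  embedding_set(df$spectrum_id, df$family,
                unname(as.matrix(df[, emb_cols, drop = FALSE])))
}
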