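## Shared fixtures: everything is generated in code at test time.

cal64 <- default_calibration(64L)
cal512 <- default_calibration(512L)

## blank binary image of a calibration's size
blank_image <- function(cal) {
  spectrum_image(matrix(0, cal$height_px, cal$width_px), cal)
}

## small deterministic synthetic dataset (families x members at 64 px)
tiny_dataset <- function(n_families = 4L, members = 6L, seed = 1L,
                         cal = cal64, model = perturbation_model()) {
  tpl <- generate_templates(n_families, peaks_range = c(5L, 10L),
                            size_range = c(members, members),
                            calibration = cal, seed = seed)
  build_dataset(tpl, model, cal, seed = seed)
}

## random labelled embedding set for retrieval oracles
random_space <- function(n, K = 3L, n_fam = 3L, seed = 1L, prefix = "s") {
  set.seed(seed)
  embedding_set(sprintf("%s%03d", prefix, seq_len(n)),
                sample(paste0("f", seq_len(n_fam)), n, replace = TRUE),
                matrix(runif(n * K, -1, 1), n, K))
}

## Brute-force expanding-hypersphere PR curve: naive per-rank loops, no
## interpolation shortcuts; independent of the package implementation.
brute_pr_curve <- function(space, queries, grid = seq(0, 1, length.out = 101)) {
  per_query <- list()
  for (i in seq_along(queries$spectrum_ids)) {
    keep <- which(space$spectrum_ids != queries$spectrum_ids[i])
    d <- sapply(keep, function(j)
      sqrt(sum((queries$coordinates[i, ] - space$coordinates[j, ])^2)))
    ord <- keep[order(d, space$spectrum_ids[keep])]
    rel <- space$family_labels[ord] == queries$family_labels[i]
    n_rel <- sum(rel)
    if (n_rel == 0) next
    prec_at <- numeric(length(grid))
    for (g in seq_along(grid)) {
      r <- 1
      while (sum(rel[1:r]) / n_rel < grid[g] - 1e-9 && r < length(rel)) r <- r + 1
      prec_at[g] <- sum(rel[1:r]) / r
    }
    per_query[[length(per_query) + 1]] <- prec_at
  }
  mp <- colMeans(do.call(rbind, per_query))
  list(precision = mp,
       auc = sum(diff(grid) * (mp[-1] + mp[-length(mp)]) / 2))
}

brute_accuracy_vs_radius <- function(space, radii) {
  n <- length(space$spectrum_ids)
  per_node <- list()
  for (i in seq_len(n)) {
    mates <- setdiff(which(space$family_labels == space$family_labels[i]), i)
    if (length(mates) == 0) next
    d <- sapply(mates, function(j)
      sqrt(sum((space$coordinates[i, ] - space$coordinates[j, ])^2)))
    per_node[[length(per_node) + 1]] <-
      sapply(radii, function(r) sum(d <= r) / length(d))
  }
  colMeans(do.call(rbind, per_node))
}

brute_closest_retrieval <- function(space, queries) {
  n_fam <- length(unique(space$family_labels))
  hits <- integer(0)
  for (i in seq_along(queries$spectrum_ids)) {
    keep <- which(space$spectrum_ids != queries$spectrum_ids[i])
    if (!any(space$family_labels[keep] == queries$family_labels[i])) next
    d <- sapply(keep, function(j)
      sqrt(sum((queries$coordinates[i, ] - space$coordinates[j, ])^2)))
    ord <- keep[order(d, space$spectrum_ids[keep])]
    fams <- character(0)
    for (j in ord) {
      f <- space$family_labels[j]
      if (!f %in% fams) fams <- c(fams, f)
    }
    hits <- c(hits, match(queries$family_labels[i], fams))
  }
  sapply(seq_len(n_fam), function(k) mean(hits <= k))
}
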