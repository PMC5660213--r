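test_that("nearest neighbours respect geometry, self-exclusion and stable ties", {
  space <- embedding_set(c("a", "b", "c"), c("f", "f", "g"),
                         matrix(c(0, 1, 4,
                                  0, 0, 0), 3, 2))
  rep <- nearest_neighbors(space, 1L, k = 1)
  expect_equal(rep$neighbor_id, "b")  # middle of three collinear points

  ## a query duplicating a corpus point finds it at distance 0
  q <- embedding_set("query", "f", space$coordinates[2, , drop = FALSE])
  rep2 <- nearest_neighbors(space, q, k = 2)
  expect_equal(rep2$neighbor_id[1], "b")
  expect_equal(rep2$distance[1], 0)
  expect_true(all(diff(rep2$distance) >= 0))

  expect_error(nearest_neighbors(space, 1L, k = 3), "smaller")

  ## permutation invariance via the id-stable tie rule
  big <- random_space(12, K = 2, seed = 3)
  perm <- sample(12)
  shuffled <- embedding_set(big$spectrum_ids[perm], big$family_labels[perm],
                            big$coordinates[perm, ])
  q2 <- embedding_set("q", "f1", matrix(c(0.1, 0.2), 1))
  r1 <- nearest_neighbors(big, q2, k = 5)
  r2 <- nearest_neighbors(shuffled, q2, k = 5)
  expect_equal(r1$neighbor_id, r2$neighbor_id)
})

test_that("PCA projection preserves planar geometry and orders variance", {
  set.seed(8)
  ## points on a 2-plane inside 10-space: projection is an isometry
  basis <- qr.Q(qr(matrix(rnorm(20), 10, 2)))
  flat <- matrix(rnorm(30), 15, 2) %*% t(basis)
  sp <- embedding_set(sprintf("p%02d", 1:15), rep("f", 15), flat)
  proj <- pca_project(sp, 2)
  expect_equal(as.matrix(dist(proj$coordinates)), as.matrix(dist(flat)),
               tolerance = 1e-8)

  full <- random_space(20, K = 5, seed = 9)
  rot <- pca_project(full, 5)
  expect_equal(as.matrix(dist(rot$coordinates)),
               as.matrix(dist(full$coordinates)), tolerance = 1e-8)
  vars <- apply(pca_project(full, 4)$coordinates, 2, var)
  expect_true(all(diff(vars) <= 1e-12))
  expect_error(pca_project(random_space(2, K = 5), 3), "more points")
})

test_that("the pixel-space PCA baseline embeds and separates block-separable families", {
  ds <- tiny_dataset(3, 5, seed = 13)
  base <- pca_baseline(ds$images, ds$manifest, k = 10)
  expect_equal(dim(base$coordinates), c(15L, 10L))
  expect_identical(base, pca_baseline(ds$images, ds$manifest, k = 10))

  ## perfectly family-separated one-hot block images -> PR-AUC 1
  cal <- axis_calibration(width_px = 16, height_px = 16)
  mk_block <- function(r) {
    m <- matrix(0, 16, 16); m[r:(r + 3), r:(r + 3)] <- 1
    spectrum_image(m, cal)
  }
  imgs <- c(lapply(c(1, 1, 2), mk_block), lapply(c(9, 9, 10), mk_block))
  names(imgs) <- sprintf("s%d", 1:6)
  man <- dataset_manifest(names(imgs), family = rep(c("A", "B"), each = 3))
  bs <- pca_baseline(imgs, man, k = 3)
  pr <- precision_recall_curve(bs, bs)
  expect_equal(pr$auc, 1.0)
})

test_that("the hypersphere PR curve matches brute-force enumeration on random instances", {
  for (seed in 1:60) {
    n <- sample(6:30, 1)
    sp <- random_space(n, K = sample(2:4, 1), n_fam = sample(2:4, 1),
                       seed = seed)
    qs <- random_space(sample(2:6, 1), K = ncol(sp$coordinates),
                       n_fam = length(unique(sp$family_labels)),
                       seed = seed + 1000, prefix = "q")
    qs$family_labels <- sample(unique(sp$family_labels),
                               length(qs$spectrum_ids), replace = TRUE)
    got <- precision_recall_curve(sp, qs)
    want <- brute_pr_curve(sp, qs)
    expect_equal(got$precision, want$precision, tolerance = 1e-10)
    expect_equal(got$auc, want$auc, tolerance = 1e-10)
  }
})

test_that("a separated embedding gives precision 1 everywhere; permuted labels give prevalence", {
  set.seed(20)
  coords <- rbind(matrix(rnorm(20, mean = 0, sd = 0.01), 10, 2),
                  matrix(rnorm(20, mean = 50, sd = 0.01), 10, 2))
  sp <- embedding_set(sprintf("s%02d", 1:20), rep(c("A", "B"), each = 10),
                      coords)
  pr <- precision_recall_curve(sp, sp)
  expect_equal(pr$auc, 1.0)
  expect_true(all(pr$precision == 1))

  ## permutation null: balanced families -> precision ~ prevalence (0.5)
  set.seed(21)
  aucs <- replicate(100, {
    perm <- embedding_set(sp$spectrum_ids, sample(sp$family_labels),
                          sp$coordinates)
    precision_recall_curve(perm, perm)$auc
  })
  ## random ranking has a small positive finite-sample bias above the 0.5
  ## prevalence, plus Monte-Carlo error over 100 permutations
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("queries with corpus-absent families are skipped with a warning", {
  sp <- random_space(8, n_fam = 2, seed = 30)
  qs <- embedding_set(c("q1", "q2"), c("f1", "ghost"),
                      matrix(runif(2 * ncol(sp$coordinates)), 2, ncol(sp$coordinates)))
  expect_warning(pr <- precision_recall_curve(sp, qs), "absent")
  expect_equal(pr$n_queries_used, 1L)
})

test_that("accuracy-vs-radius matches exhaustive counting and is monotone", {
  ## hand-placed 3-point configuration: A1-(1)-A2, B1 at distance 5
  sp <- embedding_set(c("a1", "a2", "b1"), c("A", "A", "B"),
                      matrix(c(0, 1, 5, 0, 0, 0), 3, 2))
  out <- accuracy_vs_radius(sp, c(0, 0.5, 1, 2))
  ## only a1,a2 have co-members; each captures the other at r >= 1
  expect_equal(out$fraction, c(0, 0, 1, 1))

  rs <- random_space(15, n_fam = 3, seed = 31)
  radii <- seq(0, 3, by = 0.25)
  got <- accuracy_vs_radius(rs, radii)
  expect_equal(got$fraction, brute_accuracy_vs_radius(rs, radii),
               tolerance = 1e-10)
  expect_true(all(diff(got$fraction) >= 0))
  expect_equal(got$fraction[1], 0)                      # r = 0
  expect_equal(got$fraction[length(radii)] , 1)          # r >= diameter
})

test_that("closest-retrieval curves count distinct families in distance order", {
  ## perfect embedding: own family always nearest
  sp <- embedding_set(sprintf("s%d", 1:6), rep(c("A", "B", "C"), each = 2),
                      matrix(c(0, 0.1, 10, 10.1, 20, 20.1, rep(0, 6)), 6, 2))
  crc <- closest_retrieval_curve(sp, sp)
  expect_equal(crc$fraction[1], 1.0)

  ## adversarial: own family member always the farthest -> hit only at k = n_fam
  adv <- embedding_set(c("x1", "x2", "y1", "z1"), c("X", "X", "Y", "Z"),
                       matrix(c(0, 100, 1, 2, rep(0, 4)), 4, 2))
  qa <- embedding_set("x1", "X", matrix(c(0, 0), 1, 2))
  crca <- closest_retrieval_curve(adv, qa)
  expect_equal(crca$fraction, c(0, 0, 1))

  for (seed in 1:40) {
    rs <- random_space(sample(8:30, 1), n_fam = sample(2:5, 1), seed = seed)
    got <- suppressWarnings(closest_retrieval_curve(rs, rs))
    expect_equal(got$fraction, suppressWarnings(brute_closest_retrieval(rs, rs)),
                 tolerance = 1e-10)
    expect_true(all(diff(got$fraction) >= 0))
    expect_equal(got$fraction[nrow(got)], 1)
  }
})

test_that("the most-occurring baseline predicts by family size with stable ties", {
  man <- dataset_manifest(sprintf("s%d", 1:6),
                          family = rep(c("A", "B", "C"), c(3, 2, 1)))
  mo <- mo_baseline_curve(man)
  expect_equal(mo$fraction, c(3, 5, 6) / 6)

  single <- dataset_manifest("s1", family = "A")
  expect_equal(mo_baseline_curve(single)$fraction, 1.0)

  ## equal sizes: deterministic label-order ties
  eq <- dataset_manifest(sprintf("s%d", 1:4), family = c("B", "B", "A", "A"))
  m1 <- mo_baseline_curve(eq, query_families = "A")
  expect_equal(m1$fraction, c(1, 1))  # A wins the tie alphabetically
})

test_that("cluster-map export round trips bit-exactly", {
  sp <- random_space(10, K = 4, seed = 40)
  path <- tempfile(fileext = ".tsv")
  export_cluster_map(sp, path)
  back <- read_cluster_map(path)
  expect_identical(back$coordinates, unname(sp$coordinates))
  expect_equal(back$spectrum_ids, sp$spectrum_ids)
  expect_equal(back$family_labels, sp$family_labels)
  lines <- readLines(path)
  expect_length(lines, 11)  # header + n rows
  empty <- embedding_set(character(0), character(0), matrix(0, 0, 2))
  expect_error(export_cluster_map(empty, tempfile()), "empty")
})

test_that("noise experiment records one distance per schedule entry", {
  spec <- architecture_spec(64L, 4L)
  w <- init_weights(spec, 3L)
  ds <- tiny_dataset(2, 5, seed = 15)
  proto <- noise_protocol(n_levels = 3, max_fraction = 0.3, n_reps = 2,
                          seed = 8)
  res <- noise_experiment(w, spec, ds$images[[1]], proto)
  expect_equal(nrow(res), 6)
  expect_true(all(res$distance_to_original >= 0))
  expect_equal(res$fraction, rep(c(0.1, 0.2, 0.3), each = 2))

  ## zero noise embeds to exactly the clean coordinates
  z <- inject_noise(ds$images[[1]], 0, 1)$image
  expect_identical(embed(w, spec, z), embed(w, spec, ds$images[[1]]))

  ## pca2d distances use the reference projection
  ref <- embedding_set(ds$manifest$spectrum_id, ds$manifest$family,
                       embed(w, spec, ds$images))
  res2 <- noise_experiment(w, spec, ds$images[[1]], proto,
                           space_for_distance = "pca2d",
                           reference_space = ref)
  expect_equal(nrow(res2), 6)
  expect_true(all(res2$space == "pca2d"))
})
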