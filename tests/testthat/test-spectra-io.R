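test_that("binarize follows the darkness threshold rule and is idempotent", {
  gray <- matrix(c(0.2, 0.5, 0.8, 0), 2, 2)
  cal <- axis_calibration(width_px = 2, height_px = 2)
  bin <- binarize(gray, 0.5, cal)
  expect_equal(as.numeric(bin$pixels), c(0, 1, 1, 0))

  expect_equal(binarize(matrix(0, 2, 2), 0.5, cal)$pixels, matrix(0, 2, 2))
  expect_equal(binarize(matrix(0.6, 2, 2), 0.5, cal)$pixels, matrix(1, 2, 2))

  for (thr in c(0.2, 0.5, 0.9)) {
    once <- binarize(gray, thr, cal)
    twice <- binarize(once$pixels, thr, cal)
    expect_identical(once$pixels, twice$pixels)
  }
  expect_error(binarize(gray, 0, cal), "threshold")
  expect_error(binarize(gray, 1, cal), "threshold")
})

test_that("cross median filter removes isolated pixels, keeps blocks, never hallucinates", {
  img <- blank_image(cal64)
  img$pixels[10, 20] <- 1
  expect_equal(sum(median_filter_cross(img)$pixels), 0)

  block <- blank_image(cal64)
  block$pixels[10:12, 20:22] <- 1
  expect_equal(median_filter_cross(block)$pixels[11, 21], 1)

  ones <- spectrum_image(matrix(1, 64, 64), cal64)
  expect_equal(median_filter_cross(ones)$pixels, ones$pixels)

  ## property: no foreground created away from existing foreground; every
  ## isolated interior pixel removed
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(0, 64, 64)
    pts <- cbind(sample(3:62, 12), sample(3:62, 12))
    m[pts] <- 1
    out <- median_filter_cross(spectrum_image(m, cal64))
    expect_true(all(out$pixels <= 0 | m > 0 |
                      (m[c(1, 1:63), ] + m[c(2:64, 64), ] +
                         m[, c(1, 1:63)] + m[, c(2:64, 64)]) > 0))
    iso <- which(m == 1 &
                   (m[c(1, 1:63), ] + m[c(2:64, 64), ] +
                      m[, c(1, 1:63)] + m[, c(2:64, 64)]) == 0)
    iso_rc <- arrayInd(iso, c(64, 64))
    interior <- iso[iso_rc[, 1] > 1 & iso_rc[, 1] < 64 &
                      iso_rc[, 2] > 1 & iso_rc[, 2] < 64]
    expect_true(all(out$pixels[interior] == 0))
  }
})

test_that("peak rasterization maps ppm to pixels as documented", {
  cal <- cal512
  img <- rasterize_peaklist(peak_list("x", 5.0, 91.43), cal, footprint_px = 1)
  hit <- which(img$pixels == 1, arr.ind = TRUE)
  ## 0-based column floor((10-5)*51.2) = 256, row floor(91.43*2.8) = 256
  expect_equal(unname(hit[1, ]), c(256 + 1, 256 + 1))
  expect_equal(sum(img$pixels), 1)

  corner <- rasterize_peaklist(peak_list("x", cal$h_min_ppm, cal$c_min_ppm),
                               cal, footprint_px = 1)
  hit <- which(corner$pixels == 1, arr.ind = TRUE)
  expect_equal(unname(hit[1, ]), c(0 + 1, (cal$width_px - 1) + 1))

  expect_error(rasterize_peaklist(data.frame(h_ppm = numeric(0),
                                             c_ppm = numeric(0)), cal),
               "empty")
  expect_error(rasterize_peaklist(peak_list("x", 11, 50), cal), "outside")
})

test_that("rasterization round-trip recovers shifts to within half a pixel", {
  cal <- cal64
  px_h <- (cal$h_max_ppm - cal$h_min_ppm) / cal$width_px
  px_c <- (cal$c_max_ppm - cal$c_min_ppm) / cal$height_px
  set.seed(3)
  ## peaks on exact pixel centres
  cols <- sample(0:(cal$width_px - 1), 10)
  rows <- sample(0:(cal$height_px - 1), 10)
  h <- cal$h_max_ppm - (cols + 0.5) * px_h
  c_ <- cal$c_min_ppm + (rows + 0.5) * px_c
  img <- rasterize_peaklist(peak_list("x", h, c_), cal, footprint_px = 1)
  hits <- which(img$pixels == 1, arr.ind = TRUE)
  h_rec <- cal$h_max_ppm - (hits[, 2] - 1 + 0.5) * px_h
  c_rec <- cal$c_min_ppm + (hits[, 1] - 1 + 0.5) * px_c
  expect_true(all(sapply(seq_along(h), function(i)
    min(abs(h_rec - h[i])) <= px_h / 2 + 1e-9)))
  expect_true(all(sapply(seq_along(c_), function(i)
    min(abs(c_rec - c_[i])) <= px_c / 2 + 1e-9)))
})

test_that("PNG round trip preserves the binary raster and checks calibration", {
  img <- blank_image(cal64)
  img$pixels[c(5, 100, 2000)] <- 1
  path <- tempfile(fileext = ".png")
  write_spectrum_image(img, path)
  back <- binarize(load_spectrum_image(path, cal64))
  expect_equal(back$pixels, img$pixels)

  expect_error(load_spectrum_image(path, cal512), "calibration error")
  expect_error(load_spectrum_image(tempfile(), cal64), "not found")

  ## all-white PNG -> empty after binarization at any threshold < 1
  white <- tempfile(fileext = ".png")
  png::writePNG(matrix(1, 64, 64), white)
  expect_equal(sum(binarize(load_spectrum_image(white, cal64), 0.3)$pixels), 0)

  ## one black pixel at (row 10, col 20) survives in place
  m <- matrix(1, 64, 64); m[10, 20] <- 0
  one <- tempfile(fileext = ".png")
  png::writePNG(m, one)
  got <- binarize(load_spectrum_image(one, cal64))
  expect_equal(which(got$pixels == 1, arr.ind = TRUE)[1, ], c(row = 10, col = 20))
  expect_equal(sum(got$pixels), 1)
})

test_that("family filtering keeps exactly the large-enough families in order", {
  man <- dataset_manifest(sprintf("s%02d", 1:22),
                          family = rep(c("A", "B", "C"), c(6, 4, 12)))
  out <- filter_families(man, 5)
  expect_equal(nrow(out), 18)
  expect_setequal(unique(out$family), c("A", "C"))
  expect_equal(out$spectrum_id, man$spectrum_id[man$family != "B"])

  expect_identical(filter_families(man, 1)$spectrum_id, man$spectrum_id)
  expect_equal(nrow(filter_families(man, 13)), 0)
  expect_error(filter_families(man, 0), "positive")

  ## property: all retained families have >= min members; count adds up
  set.seed(5)
  for (rep in 1:5) {
    fam <- sample(letters[1:6], 40, replace = TRUE)
    m2 <- dataset_manifest(sprintf("r%02d", 1:40), family = fam)
    mm <- sample(2:8, 1)
    f2 <- filter_families(m2, mm)
    sizes <- table(fam)
    expect_true(all(table(f2$family) >= mm))
    expect_equal(nrow(f2), sum(sizes[sizes >= mm]))
  }
})

test_that("manifest TSV round trips", {
  man <- dataset_manifest(c("a", "b"), c("p1.png", "p2.png"), c("f1", "f1"),
                          c("cmpd1", "cmpd2"), "synthetic")
  path <- tempfile(fileext = ".tsv")
  write_manifest(man, path)
  expect_equal(as.data.frame(read_manifest(path)), as.data.frame(man))
  expect_error(dataset_manifest(c("a", "a"), family = c("f", "f")), "unique")
  expect_error(dataset_manifest(c("a", "b"), family = c("f", "")), "non-empty")
})

test_that("grid capacity matches the printed HSQC figure and brute-force cell counts", {
  expect_equal(grid_capacity(0.5, 9.5, 0.02, 10, 215, 0.1), 922500)
  expect_equal(grid_capacity(0, 1, 1, 0, 1, 1), 1)
  expect_equal(grid_capacity(0, 2, 0.5, 0, 3, 1), 12)
  set.seed(2)
  for (rep in 1:10) {
    nh <- sample(1:200, 1); nc <- sample(1:200, 1)
    h_res <- runif(1, 0.01, 0.5); c_res <- runif(1, 0.05, 2)
    got <- grid_capacity(0, nh * h_res, h_res, 0, nc * c_res, c_res)
    ## brute-force enumeration of the grid cells
    cells <- length(seq(h_res / 2, nh * h_res - h_res / 4, by = h_res)) *
      length(seq(c_res / 2, nc * c_res - c_res / 4, by = c_res))
    expect_equal(got, cells)
  }
  expect_error(grid_capacity(1, 1, 0.1, 0, 1, 0.1), "exceed")
  expect_error(grid_capacity(0, 1, 0, 0, 1, 0.1), "positive")
})

test_that("NUS sampling density is the acquired fraction of increments", {
  expect_equal(nus_density(32, 128), 0.25)
  expect_equal(nus_density(128, 128), 1.0)
  expect_equal(nus_density(0, 128), 0.0)
  expect_error(nus_density(129, 128), "sampled_increments")
})
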