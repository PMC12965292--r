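test_that("ROI enrichment is exactly 1 on uniform nuclei and scale-invariant", {
  sc <- render_scene(synthetic_scene(fold_enrichment = 1, noise_sd = 0,
                                     seed = 1))
  em <- roi_enrichment(sc$image, sc$mask, sc$loci, seed = 2)
  expect_equal(em$enrichment, 1, tolerance = 1e-12)
  expect_equal(dim(em$map), c(30, 30))

  sc2 <- render_scene(synthetic_scene(fold_enrichment = 2, noise_sd = 1,
                                      seed = 3), seed = 4)
  a <- roi_enrichment(sc2$image, sc2$mask, sc2$loci, seed = 5)
  b <- roi_enrichment(sc2$image * 7.5, sc2$mask, sc2$loci, seed = 5)
  expect_equal(a$enrichment, b$enrichment, tolerance = 1e-12)
})

test_that("planted fold-enrichments are recovered within 10%", {
  for (f in c(1, 1.5, 2, 4)) {
    sc <- render_scene(synthetic_scene(fold_enrichment = f, noise_sd = 2,
                                       seed = 10 + round(10 * f)),
                       seed = 20 + round(10 * f))
    em <- roi_enrichment(sc$image, sc$mask, sc$loci, seed = 5)
    expect_lt(abs(em$enrichment - f), 0.1 * f)
  }
})

test_that("pixel profiles average the map along y and peak at the locus column", {
  sc <- render_scene(synthetic_scene(fold_enrichment = 3, noise_sd = 0,
                                     seed = 6))
  em <- roi_enrichment(sc$image, sc$mask, sc$loci, seed = 7)
  prof <- average_pixel_profile(em)
  expect_equal(nrow(prof), 30)
  # the locus sits at the ROI center: peak at column 16 (center + rounding)
  expect_lt(abs(prof$column[which.max(prof$mean)] - 16), 2)
  flat <- average_pixel_profile(matrix(2, 8, 8))
  expect_true(all(flat$mean == 2) && all(flat$sem == 0))
})

test_that("ATS counting matches a per-nucleus pixel-scan oracle", {
  # blank image
  mask <- matrix(0L, 40, 40); mask[5:15, 5:15] <- 1L; mask[25:35, 25:35] <- 2L
  blank <- matrix(0, 40, 40)
  expect_equal(count_ats(blank, mask, 1)$n_ats, 0)

  # 3 planted spots in 10 nuclei -> 30% active
  img <- matrix(0, 40, 110); msk <- matrix(0L, 40, 110)
  for (i in 1:10) msk[10:20, (i * 10 - 5):(i * 10 + 2)] <- i
  for (i in c(2, 5, 9)) img[15, i * 10] <- 10
  ca <- count_ats(img, msk, 1)
  expect_equal(ca$n_ats, 3)
  expect_equal(ca$proportion, 0.3)

  # random small images: agreement with the flood-fill oracle
  set.seed(71)
  for (rep in 1:10) {
    m <- matrix(0L, 32, 32)
    m[3:14, 3:14] <- 1L; m[18:30, 18:30] <- 2L
    im <- matrix(runif(32 * 32), 32, 32)
    thr <- runif(1, 0.6, 0.95)
    expect_equal(count_ats(im, m, thr)$n_ats, oracle_count_ats(im, m, thr))
  }
  expect_error(count_ats(blank, matrix(0L, 4, 4), 1), "no nuclei")
})

test_that("colocalized two-channel spots are recovered exactly without noise", {
  mask <- matrix(0L, 50, 50); mask[5:20, 5:20] <- 1L; mask[30:45, 30:45] <- 2L
  ch1 <- matrix(0, 50, 50); ch2 <- matrix(0, 50, 50)
  ch1[10, 10] <- 5; ch2[10, 10] <- 5      # joint spot in nucleus 1
  ch1[38, 38] <- 5                        # channel-1-only spot in nucleus 2
  a1 <- count_ats(ch1, mask, 1)$per_nucleus
  a2 <- count_ats(ch2, mask, 1)$per_nucleus
  joint <- a1$has_ats & a2$has_ats &
    (abs(a1$peak_row - a2$peak_row) <= 1) & (abs(a1$peak_col - a2$peak_col) <= 1)
  expect_equal(sum(joint, na.rm = TRUE), 1)
  expect_equal(sum(a1$has_ats), 2)
})

test_that("focus pairing is mutual-nearest-neighbor within 1 um and symmetric", {
  hub <- data.frame(track_id = c("h1", "h2"), x_um = c(0, 5), y_um = c(0, 0))
  ms2 <- data.frame(track_id = c("m1", "m2"), x_um = c(0.5, 6.2), y_um = c(0, 0))
  pr <- pair_foci(hub, ms2)
  expect_equal(pr$pairs$hub_id, "h1")
  expect_equal(pr$pairs$dist_um, 0.5)
  expect_equal(pr$unpaired_hub, "h2")   # 1.2 um away: unpaired
  # symmetric in its inputs
  rev <- pair_foci(ms2, hub)
  expect_equal(nrow(rev$pairs), 1)
  expect_equal(rev$pairs$dist_um, pr$pairs$dist_um)

  # planted pairs under small jitter: perfect precision
  set.seed(81)
  n <- 12
  base <- data.frame(track_id = paste0("h", 1:n),
                     x_um = runif(n, 0, 40), y_um = runif(n, 0, 40))
  jit <- data.frame(track_id = paste0("m", 1:n),
                    x_um = base$x_um + runif(n, -0.14, 0.14),
                    y_um = base$y_um + runif(n, -0.14, 0.14))
  got <- pair_foci(base, jit)$pairs
  expect_equal(nrow(got), n)
  expect_true(all(got$ms2_id == sub("^h", "m", got$hub_id)))
})

test_that("min-max normalization maps to [0, 1], idempotently and order-preservingly", {
  expect_equal(minmax_normalize(c(2, 4, 6)), c(0, 0.5, 1))
  x <- c(3, 9, 1, 7)
  once <- minmax_normalize(x)
  expect_equal(minmax_normalize(once), once)
  expect_equal(order(once), order(x))
  expect_error(minmax_normalize(c(2, 2, 2)), "constant")
  tr <- fluor_trace(c(10, 30), 20)
  expect_equal(minmax_normalize(tr)$intensity, c(0, 1))
})

test_that("grid fluctuation scoring keeps only persistent high cells", {
  nf <- 10
  mask <- matrix(1L, 50, 50)
  movie <- array(1, c(50, 50, nf))
  out_flat <- grid_fluctuations(movie, mask, grid = 10, persist_frames = 5)
  expect_false(any(out_flat$retained))

  plant <- function(frames) {
    m <- array(1, c(50, 50, nf))
    for (f in frames) m[6:10, 6:10, f] <- 2   # cell (2, 2), 2x nuclear level
    m
  }
  keep <- grid_fluctuations(plant(2:7), mask, grid = 10, persist_frames = 5)
  expect_true(keep$retained[keep$cell_row == 2 & keep$cell_col == 2])
  expect_equal(sum(keep$retained), 1)
  drop <- grid_fluctuations(plant(2:5), mask, grid = 10, persist_frames = 5)
  expect_false(any(drop$retained))
  expect_error(grid_fluctuations(plant(1:2), mask, persist_frames = 5,
                                 span_frames = 3), "shorter")
})

test_that("scene images and masks round-trip through TIFF bit-identically", {
  dir <- tempfile("scene")
  scn <- synthetic_scene(fold_enrichment = 2, noise_sd = 1, seed = 5)
  out <- generate_locus_image_stack(scn, dir, seed = 6)
  expect_true(all(file.exists(unlist(out$paths))))
  mask_back <- read_label_mask(out$paths$mask)
  expect_identical(dim(mask_back), dim(out$mask))
  expect_true(all(mask_back == out$mask))
  truth <- jsonlite::read_json(out$paths$truth)
  expect_equal(truth$background, 100)
  unlink(dir, recursive = TRUE)
})
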