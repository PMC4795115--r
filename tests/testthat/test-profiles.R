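test_that("bilinear sampling is exact at pixel centers and on ramps", {
  set.seed(5)
  img <- matrix(stats::runif(30 * 40, 0, 100), 30, 40)
  r <- sample(0:29, 20, replace = TRUE)
  c <- sample(0:39, 20, replace = TRUE)
  expect_equal(bilinear_sample(img, r, c), img[cbind(r + 1, c + 1)])
  # bilinear interpolation is exact for a (bi)linear image
  ramp <- matrix(0:39, 30, 40, byrow = TRUE)  # I(r, c) = c
  rr <- stats::runif(50, 0, 29)
  cc <- stats::runif(50, 0, 39)
  expect_equal(bilinear_sample(ramp, rr, cc), cc, tolerance = 1e-12)
})

test_that("IN profiles sample the segment inclusively with the stated count", {
  img <- matrix(7, 50, 50)
  p <- extract_in_profile(img, c(10, 10), c(10, 30), step_px = 1)
  expect_equal(length(p$samples), 21L)
  expect_true(all(p$samples == 7))
  ramp <- matrix(0:49, 50, 50, byrow = TRUE)
  p2 <- extract_in_profile(ramp, c(25, 10), c(25, 20), step_px = 1)
  expect_equal(p2$samples, 10:20, tolerance = 1e-12)
  expect_error(extract_in_profile(img, c(10, 10), c(10, 10)), "identical")
  expect_error(extract_in_profile(img, c(2, 2), c(80, 80)), "bounds")
})

test_that("IN profile is reversal-invariant under anchor swap", {
  set.seed(6)
  img <- matrix(stats::runif(60 * 60, 0, 50), 60, 60)
  a <- c(12.3, 9.8); b <- c(41.2, 50.1)
  p_ab <- extract_in_profile(img, a, b)$samples
  p_ba <- extract_in_profile(img, b, a)$samples
  expect_equal(p_ab, rev(p_ba), tolerance = 1e-12)
})

test_that("WT-like pair profile peaks at the shared membrane crossing", {
  sc <- make_scene(4, c(256, 256), 0.2, seed = 3)
  ch <- render_channels(sc, wt_phenotype())
  adj <- sc$adjacency
  for (i in seq_len(nrow(adj))) {
    c1 <- unlist(sc$cells[adj$cell1[i], c("nucleus_row", "nucleus_col")])
    c2 <- unlist(sc$cells[adj$cell2[i], c("nucleus_row", "nucleus_col")])
    p <- extract_in_profile(ch$protein, c1, c2)
    n <- length(p$samples)
    t <- seq(0, 1, length.out = n)
    # boundary crossing from the ground-truth label map
    labs <- sc$labels[cbind(round(c1[1] + t * (c2[1] - c1[1])) + 1,
                            round(c1[2] + t * (c2[2] - c1[2])) + 1)]
    # a segment may graze a third cell near a vertex; the global maximum
    # must sit on one of the membrane crossings it makes
    crossings <- which(diff(labs) != 0)
    expect_lte(min(abs(which.max(p$samples) - crossings)), 2)
  }
})

test_that("radial profiles respect image symmetry", {
  n <- 101
  img <- matrix(0, n, n)
  rr <- matrix(0:(n - 1), n, n); cc <- t(rr)
  R <- 30
  rho <- sqrt((rr - 50)^2 + (cc - 50)^2)
  img <- exp(-(rho - R)^2 / (2 * 2^2)) * 100  # ring of radius 30
  profs <- extract_rd_profiles(img, c(50, 50), n_angles = 8,
                               ray_length = 45, step_px = 1)
  expect_equal(length(profs), 8L)
  mats <- sapply(profs, `[[`, "samples")
  expect_lt(max(abs(mats - rowMeans(mats))), 1.5)  # rotationally identical
  peaks <- apply(mats, 2, which.max)
  expect_true(all(abs(peaks - 1 - R) <= 1))
})

test_that("radial profiles on a ramp are monotone along x and flat along y", {
  ramp <- matrix(0:99, 100, 100, byrow = TRUE)  # I(r, c) = c
  profs <- extract_rd_profiles(ramp, c(50, 50), n_angles = 4,
                               ray_length = 40)
  # angles 0, 90, 180, 270 degrees = +col, +row, -col, -row
  expect_true(all(diff(profs[[1]]$samples) > 0))
  expect_true(all(abs(diff(profs[[2]]$samples)) < 1e-9))
  expect_true(all(diff(profs[[3]]$samples) < 0))
  expect_true(all(abs(diff(profs[[4]]$samples)) < 1e-9))
})

test_that("rays leaving the image are excluded and flagged", {
  img <- matrix(1, 60, 60)
  profs <- extract_rd_profiles(img, c(30, 50), n_angles = 8,
                               ray_length = 25)
  expect_lt(length(profs), 8L)
  expect_gt(length(attr(profs, "excluded_angles")), 0L)
  expect_error(extract_rd_profiles(img, c(-5, 30), n_angles = 8,
                                   ray_length = 10), "center")
})

test_that("length normalization is the identity at L and preserves ramps and peaks", {
  v <- stats::runif(100)
  expect_equal(as.numeric(normalize_length(v)), v, tolerance = 1e-12)
  ramp <- seq(3, 47, length.out = 271)
  nr <- normalize_length(ramp)
  expect_equal(nr[1], 3)
  expect_equal(nr[100], 47)
  expect_equal(as.numeric(nr), seq(3, 47, length.out = 100),
               tolerance = 1e-9)
  # delta-like (narrow triangular) peak at fraction f of a 333-sample
  # profile; a finite width survives linear resampling
  for (f in c(0.2, 0.5, 0.8)) {
    prof <- numeric(333)
    k <- round(f * 332) + 1
    prof[k + (-3:3)] <- c(1, 2, 3, 4, 3, 2, 1)
    expect_lte(abs(which.max(normalize_length(prof)) - 1L - round(f * 99)),
               1)
  }
})

test_that("length normalization preserves the mean of smooth profiles", {
  x <- seq(0, 1, length.out = 157)
  prof <- 10 + 40 * exp(-(x - 0.6)^2 / 0.02)
  np <- normalize_length(prof)
  expect_lt(abs(mean(np) - mean(prof)) / mean(prof), 0.01)
})

test_that("profile maps stack columns in input order", {
  p1 <- normalize_length(stats::runif(80))
  p2 <- normalize_length(stats::runif(120))
  p3 <- normalize_length(stats::runif(100))
  m <- build_map(list(p1, p2, p3))
  expect_equal(dim(m), c(100L, 3L))
  expect_equal(m$values, cbind(as.numeric(p1), as.numeric(p2),
                               as.numeric(p3)))
  expect_equal(m$stage, "raw")
  one <- build_map(list(p1))
  expect_equal(one$values[, 1], as.numeric(p1))
  same <- build_map(list(p1, p1, p1))
  expect_true(all(apply(same$values, 1, var) == 0))
  expect_error(build_map(list(p1, stats::runif(50))), "mixed")
})

test_that("profile map CSV round-trips", {
  m <- build_map(matrix(stats::runif(300), 100, 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_map_csv(m, path)
  back <- read_profile_map_csv(path)
  expect_equal(back$values, m$values, tolerance = 1e-12,
               ignore_attr = TRUE)
})
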