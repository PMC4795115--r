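test_that("single-cell scene is degenerate: one centered cell, nucleus at centroid", {
  sc <- make_scene(1, c(120, 120), shape_jitter = 0, seed = 0)
  expect_equal(nrow(sc$cells), 1L)
  expect_true(all(sc$labels == 1L))
  # deepest point of the full frame = image center = cell centroid
  expect_lt(abs(sc$cells$nucleus_row - 59.5), 1.1)
  expect_lt(abs(sc$cells$nucleus_col - 59.5), 1.1)
})

test_that("scenes and renders are deterministic under a fixed seed", {
  s1 <- make_scene(4, c(256, 256), 0.2, seed = 1)
  s2 <- make_scene(4, c(256, 256), 0.2, seed = 1)
  expect_identical(s1$labels, s2$labels)
  expect_equal(s1$cells, s2$cells)
  ph <- mutant_phenotype(noise_model = "poisson")
  r1 <- render_channels(s1, ph)
  r2 <- render_channels(s2, ph)
  expect_identical(r1$protein$pixels, r2$protein$pixels)
  expect_identical(r1$nuclear$pixels, r2$nuclear$pixels)
})

test_that("tessellation covers the frame and respects cell count", {
  sc <- make_scene(9, c(512, 512), 0.3, seed = 7)
  expect_equal(sort(unique(as.vector(sc$labels))), 1:9)
  # rasterized union of cells covers >= 80% of the tessellated region
  expect_gte(mean(sc$labels > 0), 0.8)
  # nucleus centers inside their own cells
  for (i in 1:9) {
    r <- round(sc$cells$nucleus_row[i]) + 1L
    c <- round(sc$cells$nucleus_col[i]) + 1L
    expect_equal(sc$labels[r, c], i)
  }
})

test_that("image too small for the requested cell count errors", {
  expect_error(make_scene(100, c(64, 64), 0.2, seed = 1), "too small")
})

test_that("zero-amplitude phenotype renders an identically zero protein channel", {
  sc <- make_scene(4, c(128, 128), 0.1, seed = 2)
  ph <- phenotype_spec(membrane_amplitude = 0, cytoplasm_baseline = 0,
                       perinuclear_peak_amplitude = 0)
  ch <- render_channels(sc, ph)
  expect_true(all(ch$protein$pixels == 0))
})

test_that("WT-like rendering puts baseline+amplitude on boundaries, baseline inside", {
  sc <- make_scene(4, c(256, 256), 0.1, seed = 5)
  ch <- render_channels(sc, wt_phenotype())
  d2b <- profilecad:::boundary_distance(sc$labels)
  expect_equal(max(ch$protein$pixels[d2b == 0]), 120, tolerance = 1e-8)
  far <- d2b > 15  # far from any membrane
  expect_lt(max(abs(ch$protein$pixels[far] - 20)), 0.5)
})

test_that("mutant-like brightest non-membrane structure sits at the stated radial fraction", {
  sc <- make_scene(4, c(256, 256), 0.1, seed = 5)
  ph <- phenotype_spec(membrane_amplitude = 30, cytoplasm_baseline = 20,
                       perinuclear_peak_amplitude = 80,
                       perinuclear_peak_position = 0.8)
  ch <- render_channels(sc, ph)
  d2b <- profilecad:::boundary_distance(sc$labels)
  px <- ch$protein$pixels
  nr <- nrow(px)
  rows <- matrix(0:(nr - 1), nr, ncol(px))
  cols <- matrix(0:(ncol(px) - 1), nr, ncol(px), byrow = TRUE)
  for (i in 1:4) {
    ci <- sc$cells[i, ]
    dn <- sqrt((rows - ci$nucleus_row)^2 + (cols - ci$nucleus_col)^2)
    sel <- sc$labels == i & d2b > 3 * ph$membrane_thickness_px / 2
    vals <- px[sel]
    tfrac <- ((dn - ci$nucleus_radius) /
                (dn - ci$nucleus_radius + d2b))[sel]
    expect_lt(abs(tfrac[which.max(vals)] - 0.8), 0.05)
  }
})

test_that("increasing membrane amplitude strictly increases boundary intensity", {
  sc <- make_scene(4, c(192, 192), 0.15, seed = 9)
  d2b <- profilecad:::boundary_distance(sc$labels)
  means <- sapply(c(20, 60, 120), function(a) {
    ph <- phenotype_spec(membrane_amplitude = a)
    mean(render_channels(sc, ph)$protein$pixels[d2b == 0])
  })
  expect_true(all(diff(means) > 0))
})

test_that("Poisson noise has shot-noise variance scaling", {
  set.seed(11)
  photon_scale <- 10
  v <- matrix(50, 10, 10)
  draws <- replicate(1000, add_poisson_noise(v, photon_scale))
  pixel_var <- apply(draws, c(1, 2), var)
  expect_lt(abs(mean(pixel_var) - 50 / photon_scale) / (50 / photon_scale),
            0.1)
})

test_that("fixtures round-trip and are reproducible", {
  sc <- make_scene(4, c(160, 160), 0.2, seed = 4)
  ph <- wt_phenotype(noise_model = "poisson")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(sc, ph, d1)
  write_fixture(sc, ph, d2)
  ch <- render_channels(sc, ph)
  stored <- round(ch$protein$pixels * 16)
  back <- read_channel_tiff(file.path(d1, "protein.tif"))
  expect_equal(back$pixels, stored, ignore_attr = TRUE)
  # identical generation -> identical checksums
  expect_identical(unname(tools::md5sum(file.path(d1, "protein.tif"))),
                   unname(tools::md5sum(file.path(d2, "protein.tif"))))
  sel <- read_selection_csv(file.path(d1, "selections.csv"))
  expect_equal(sum(sel$type == "point"), nrow(sc$cells))
  expect_equal(sum(sel$type == "pair"), nrow(sc$adjacency))
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(manifest$generator$seed, sc$seed)
})
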