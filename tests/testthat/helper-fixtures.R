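# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from disk unless a test writes it first.

# Normalized IN profile map for a scene, using ground-truth geometry
# (bypasses segmentation so profile/compensation tests are isolated).
ground_truth_in_map <- function(scene, channels, n_max = Inf, L = 100L) {
  adj <- scene$adjacency
  n <- min(nrow(adj), n_max)
  profs <- lapply(seq_len(n), function(i) {
    c1 <- unlist(scene$cells[adj$cell1[i], c("nucleus_row", "nucleus_col")])
    c2 <- unlist(scene$cells[adj$cell2[i], c("nucleus_row", "nucleus_col")])
    normalize_length(extract_in_profile(channels$protein, c1, c2), L = L)
  })
  build_map(profs)
}

# Template profile map whose columns are translated copies of a Gaussian
# membrane-like peak with known zero-mean offsets (the translation gauge
# of alignment-to-consensus is unidentifiable, hence centered offsets).
shifted_peak_map <- function(n_cols = 50, max_offset = 0.05, seed = 42,
                             poisson_scale = NULL) {
  set.seed(seed)
  x <- seq(0, 1, length.out = 100)
  template <- 20 + 100 * exp(-(x - 0.5)^2 / (2 * 0.04^2))
  shifts <- stats::runif(n_cols, -max_offset, max_offset)
  shifts <- shifts - mean(shifts)
  cols <- sapply(shifts, function(s) {
    v <- stats::approx(x, template, xout = pmin(pmax(x - s, 0), 1),
                       rule = 2)$y
    if (!is.null(poisson_scale)) {
      v <- stats::rpois(length(v), v * poisson_scale) / poisson_scale
    }
    v
  })
  list(map = build_map(cols), shifts = shifts, template = template)
}

row_variance_objective <- function(map) sum(apply(map$values, 1, stats::var))

# Two-population fixture directories for pipeline-level tests.
write_population_fixture <- function(phenotype, seed, dir,
                                     n_cells = 49, shape = c(640, 640),
                                     n_pairs = 100) {
  scene <- make_scene(n_cells, shape, shape_jitter = 0.2, seed = seed)
  write_fixture(scene, phenotype, dir)
  sel <- read_selection_csv(file.path(dir, "selections.csv"))
  pairs <- sel[sel$type == "pair", , drop = FALSE]
  stopifnot(nrow(pairs) >= n_pairs)
  write_selection_csv(rbind(sel[sel$type == "point", , drop = FALSE],
                            pairs[seq_len(n_pairs), , drop = FALSE]),
                      file.path(dir, "selections.csv"))
  scene
}

population_paths <- function(dir) {
  list(nuclear = file.path(dir, "nuclear.tif"),
       protein = file.path(dir, "protein.tif"),
       selections = file.path(dir, "selections.csv"))
}

# Mean intensity of a virtual cell in a radial band [r0, r1] (px).
virtual_cell_band <- function(vc, r0, r1) {
  side <- nrow(vc$cartesian)
  cen <- vc$radius
  rr <- matrix(0:(side - 1L), side, side) - cen
  rho <- sqrt(rr^2 + t(rr)^2)
  mean(vc$cartesian[rho >= r0 & rho <= r1])
}

# Brute-force Otsu oracle: direct between-class variance over every
# candidate threshold, independent of the cumulative-sum implementation.
# Same convention as the implementation: the threshold sits half a gray
# level above the last background intensity.
otsu_bruteforce <- function(values) {
  counts <- tabulate(as.integer(values) + 1L, nbins = 256L)
  levels <- 0:255
  best_t <- NA; best_v <- -Inf
  for (k in 1:255) {
    n1 <- sum(counts[1:k]); n2 <- sum(counts) - n1
    if (n1 == 0 || n2 == 0) next
    m1 <- sum(counts[1:k] * levels[1:k]) / n1
    m2 <- sum(counts[(k + 1):256] * levels[(k + 1):256]) / n2
    v <- (n1 / sum(counts)) * (n2 / sum(counts)) * (m1 - m2)^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- levels[k] + 0.5
    }
  }
  best_t
}
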