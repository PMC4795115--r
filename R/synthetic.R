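#' Phenotype specification for the synthetic image generator
#'
#' Parameterizes the protein-channel appearance of a simulated cell
#' population. A wild-type-like phenotype concentrates signal in a ridge
#' along the cell boundaries (adherens-junction-like membrane staining);
#' a mutant-like phenotype reduces the membrane amplitude and may add a
#' perinuclear accumulation — a Gaussian annulus centered at a fixed
#' fraction of the nucleus-edge-to-membrane distance, emulating retention
#' of the protein in a cytoplasmic compartment such as the endoplasmic
#' reticulum.
#'
#' @param membrane_amplitude Intensity (a.u., >= 0) of the membrane ridge.
#' @param cytoplasm_baseline Diffuse intensity (a.u., >= 0) inside cells.
#' @param perinuclear_peak_amplitude Intensity (a.u., >= 0) of the
#'   perinuclear annulus; 0 disables it.
#' @param perinuclear_peak_position Radial position of the annulus as a
#'   fraction of the nucleus-edge-to-membrane distance, strictly in (0, 1).
#' @param perinuclear_peak_width Gaussian width of the annulus on the same
#'   fractional scale.
#' @param membrane_thickness_px Membrane ridge thickness in pixels (> 0);
#'   the ridge is a Gaussian of the distance to the cell boundary with
#'   `sigma = membrane_thickness_px / 2`.
#' @param noise_model `"none"` or `"poisson"`.
#' @param photon_scale Counts per intensity unit for Poisson draws (> 0);
#'   larger values mean less noise.
#'
#' @return An object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(membrane_amplitude = 100,
                           cytoplasm_baseline = 20,
                           perinuclear_peak_amplitude = 0,
                           perinuclear_peak_position = 0.8,
                           perinuclear_peak_width = 0.05,
                           membrane_thickness_px = 6,
                           noise_model = c("none", "poisson"),
                           photon_scale = 10) {
  noise_model <- match.arg(noise_model)
  stopifnot(
    membrane_amplitude >= 0, cytoplasm_baseline >= 0,
    perinuclear_peak_amplitude >= 0,
    perinuclear_peak_position > 0, perinuclear_peak_position < 1,
    perinuclear_peak_width > 0,
    membrane_thickness_px > 0, photon_scale > 0
  )
  structure(
    list(membrane_amplitude = membrane_amplitude,
         cytoplasm_baseline = cytoplasm_baseline,
         perinuclear_peak_amplitude = perinuclear_peak_amplitude,
         perinuclear_peak_position = perinuclear_peak_position,
         perinuclear_peak_width = perinuclear_peak_width,
         membrane_thickness_px = membrane_thickness_px,
         noise_model = noise_model,
         photon_scale = photon_scale),
    class = "phenotype_spec"
  )
}

#' @rdname phenotype_spec
#' @param noise_model,photon_scale Passed on to [phenotype_spec()].
#' @export
wt_phenotype <- function(noise_model = "none", photon_scale = 10) {
  phenotype_spec(membrane_amplitude = 100, cytoplasm_baseline = 20,
                 perinuclear_peak_amplitude = 0,
                 noise_model = noise_model, photon_scale = photon_scale)
}

#' @rdname phenotype_spec
#' @export
mutant_phenotype <- function(noise_model = "none", photon_scale = 10) {
  phenotype_spec(membrane_amplitude = 40, cytoplasm_baseline = 20,
                 perinuclear_peak_amplitude = 80,
                 perinuclear_peak_position = 0.8,
                 noise_model = noise_model, photon_scale = photon_scale)
}

#' Generate a synthetic confluent-monolayer scene
#'
#' Cells are the Voronoi regions of a jittered hex-offset grid of seed
#' points (alternate rows shifted by half a spacing, which yields rounder,
#' more isotropic cells than a square lattice), giving contiguous convex
#' polygonal cells that share boundaries, as in a confluent epithelial
#' monolayer. Each cell receives a circular nucleus
#' placed at an interior point: the deepest point of the cell (maximum
#' distance to any boundary), jittered proportionally to `shape_jitter`,
#' so the nucleus always lies fully inside its cell.
#'
#' @param n_cells Number of cells (>= 1).
#' @param image_shape Integer vector `c(rows, cols)`.
#' @param shape_jitter Geometry irregularity in `[0, 1]`; 0 gives a regular
#'   grid with nuclei at the cell centers.
#' @param seed Integer seed; the scene is deterministic given the seed.
#'
#' @return An object of class `synthetic_scene`: a list with `cells`
#'   (tibble: `cell`, `nucleus_row`, `nucleus_col`, `nucleus_radius`,
#'   `area`), `labels` (integer matrix, cell id per pixel), `polygons`
#'   (list of vertex matrices, 0-based `(row, col)`), `adjacency`
#'   (tibble of adjacent cell pairs), `image_shape` and `seed`.
#' @export
make_scene <- function(n_cells, image_shape = c(256L, 256L),
                       shape_jitter = 0.2, seed = 1L) {
  stopifnot(n_cells >= 1, length(image_shape) == 2,
            shape_jitter >= 0, shape_jitter <= 1)
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  gc_ <- ceiling(sqrt(n_cells))
  gr_ <- ceiling(n_cells / gc_)
  sp_r <- nr / gr_; sp_c <- nc / gc_
  if (min(sp_r, sp_c) < 20) {
    stop("make_scene: image too small to host ", n_cells,
         " cells (need >= 20 px grid spacing)", call. = FALSE)
  }
  set.seed(as.integer(seed))
  idx <- seq_len(n_cells) - 1L
  g_row <- idx %/% gc_; g_col <- idx %% gc_
  hex_off <- ifelse(gr_ > 1L, 0.25 * (2 * (g_row %% 2L) - 1L), 0)
  seed_r <- (g_row + 0.5) * sp_r +
    shape_jitter * (sp_r / 2) * stats::runif(n_cells, -1, 1)
  seed_c <- (g_col + 0.5 + hex_off) * sp_c +
    shape_jitter * (sp_c / 2) * stats::runif(n_cells, -1, 1)

  # nearest-seed (Voronoi) label assignment over the full frame
  rows <- matrix(0:(nr - 1L), nr, nc)
  cols <- matrix(0:(nc - 1L), nr, nc, byrow = TRUE)
  best_d <- matrix(Inf, nr, nc)
  labels <- matrix(0L, nr, nc)
  for (i in seq_len(n_cells)) {
    d <- (rows - seed_r[i])^2 + (cols - seed_c[i])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    labels[upd] <- i
  }

  depth <- boundary_distance(labels)
  cells <- vector("list", n_cells)
  polygons <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    in_cell <- labels == i
    area <- sum(in_cell)
    pix <- which(in_cell, arr.ind = TRUE) - 1L  # 0-based (row, col)
    cent <- colMeans(pix)
    dmax <- max(depth[in_cell])
    cand <- which(in_cell & depth > dmax - 0.5, arr.ind = TRUE) - 1L
    # deepest point closest to the cell centroid (stable tie-break)
    dd <- (cand[, 1] - cent[1])^2 + (cand[, 2] - cent[2])^2
    deep <- cand[which.min(dd), ]
    r_nuc <- min(0.35 * sqrt(area / pi), 0.6 * dmax)
    jit_max <- shape_jitter * max(0, min(0.25 * dmax, dmax - r_nuc - 1))
    ang <- stats::runif(1, 0, 2 * pi)
    rad <- jit_max * sqrt(stats::runif(1))
    nuc <- c(deep[1] + rad * sin(ang), deep[2] + rad * cos(ang))
    hull <- grDevices::chull(pix[, 2], pix[, 1])
    polygons[[i]] <- pix[hull, , drop = FALSE]
    cells[[i]] <- tibble::tibble(
      cell = i, nucleus_row = nuc[1], nucleus_col = nuc[2],
      nucleus_radius = r_nuc, area = area
    )
  }

  structure(
    list(cells = dplyr::bind_rows(cells), labels = labels,
         polygons = polygons, adjacency = label_adjacency(labels),
         image_shape = c(nr, nc), seed = as.integer(seed)),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d cells, %d x %d px, %d adjacent pairs, seed %d\n",
              nrow(x$cells), x$image_shape[1], x$image_shape[2],
              nrow(x$adjacency), x$seed))
  invisible(x)
}

# Distance from each pixel to the nearest cell boundary pixel; boundaries
# are pixels whose 4-neighborhood crosses a label change, plus the frame.
boundary_distance <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  b <- matrix(FALSE, nr, nc)
  b[-nr, ][labels[-nr, ] != labels[-1, ]] <- TRUE
  b[-1, ][labels[-nr, ] != labels[-1, ]] <- TRUE
  b[, -nc][labels[, -nc] != labels[, -1]] <- TRUE
  b[, -1][labels[, -nc] != labels[, -1]] <- TRUE
  b[1, ] <- TRUE; b[nr, ] <- TRUE; b[, 1] <- TRUE; b[, nc] <- TRUE
  as.matrix(EBImage::distmap(1 - b))
}

# Adjacent label pairs under 4-connectivity.
label_adjacency <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  p <- rbind(
    cbind(as.vector(labels[-nr, ]), as.vector(labels[-1, ])),
    cbind(as.vector(labels[, -nc]), as.vector(labels[, -1]))
  )
  p <- p[p[, 1] != p[, 2], , drop = FALSE]
  p <- cbind(pmin(p[, 1], p[, 2]), pmax(p[, 1], p[, 2]))
  p <- unique(p)
  p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
  tibble::tibble(cell1 = as.integer(p[, 1]), cell2 = as.integer(p[, 2]))
}

#' Apply Poisson photon-counting noise
#'
#' Each intensity `v` is replaced by `rpois(v * photon_scale) /
#' photon_scale`, so the per-pixel variance equals `mean / photon_scale`
#' (shot-noise scaling).
#'
#' @param pixels Numeric matrix of non-negative intensities.
#' @param photon_scale Counts per intensity unit (> 0).
#' @return Matrix of the same shape.
#' @export
add_poisson_noise <- function(pixels, photon_scale) {
  stopifnot(photon_scale > 0)
  out <- stats::rpois(length(pixels), pmax(pixels, 0) * photon_scale) /
    photon_scale
  matrix(out, nrow(pixels), ncol(pixels))
}

#' Render the two fluorescence channels of a synthetic scene
#'
#' The nuclear channel contains filled nucleus disks at constant intensity.
#' The protein channel is the sum of a cytoplasmic baseline, a Gaussian
#' membrane ridge along cell boundaries, and (if the phenotype requests it)
#' a perinuclear Gaussian annulus placed per pixel at the phenotype's
#' radial fraction of the nucleus-edge-to-membrane distance. Poisson noise
#' is applied as photon counts when `noise_model = "poisson"`.
#'
#' @param scene A [make_scene()] result.
#' @param phenotype A [phenotype_spec()].
#' @param nuclear_intensity Intensity of the nucleus disks (a.u.).
#' @param seed Seed for the noise draws; defaults to the scene seed.
#' @return List with `nuclear` and `protein` [channel_image()]s.
#' @export
render_channels <- function(scene, phenotype,
                            nuclear_intensity = 200, seed = scene$seed) {
  stopifnot(inherits(scene, "synthetic_scene"),
            inherits(phenotype, "phenotype_spec"))
  nr <- scene$image_shape[1]; nc <- scene$image_shape[2]
  rows <- matrix(0:(nr - 1L), nr, nc)
  cols <- matrix(0:(nc - 1L), nr, nc, byrow = TRUE)

  nuclear <- matrix(0, nr, nc)
  dist_nuc <- matrix(Inf, nr, nc)  # distance to own-cell nucleus center
  for (i in seq_len(nrow(scene$cells))) {
    ci <- scene$cells[i, ]
    d <- sqrt((rows - ci$nucleus_row)^2 + (cols - ci$nucleus_col)^2)
    in_cell <- scene$labels == ci$cell
    dist_nuc[in_cell] <- d[in_cell]
    nuclear[in_cell & d <= ci$nucleus_radius] <- nuclear_intensity
  }

  d2b <- boundary_distance(scene$labels)
  sigma_m <- phenotype$membrane_thickness_px / 2
  protein <- phenotype$cytoplasm_baseline +
    phenotype$membrane_amplitude * exp(-d2b^2 / (2 * sigma_m^2))

  if (phenotype$perinuclear_peak_amplitude > 0) {
    rad <- scene$cells$nucleus_radius[scene$labels]
    edge_dist <- dist_nuc - rad  # distance past the nucleus edge
    t_frac <- edge_dist / (edge_dist + d2b)
    t_frac[!is.finite(t_frac)] <- -1
    protein <- protein + phenotype$perinuclear_peak_amplitude *
      exp(-(t_frac - phenotype$perinuclear_peak_position)^2 /
            (2 * phenotype$perinuclear_peak_width^2))
  }

  if (phenotype$noise_model == "poisson") {
    set.seed(as.integer(seed))
    nuclear <- add_poisson_noise(nuclear, phenotype$photon_scale)
    protein <- add_poisson_noise(protein, phenotype$photon_scale)
  }
  list(nuclear = channel_image(nuclear), protein = channel_image(protein))
}

#' Write a synthetic fixture to disk
#'
#' Renders the scene, quantizes intensities with a fixed linear scale,
#' writes both channels as 16-bit grayscale TIFF, a ground-truth selection
#' CSV (one `point` row per nucleus, one `pair` row per adjacent cell
#' pair) and a JSON manifest recording the generating parameters, the
#' intensity scale and the file checksums.
#'
#' @param scene A [make_scene()] result.
#' @param phenotype A [phenotype_spec()].
#' @param directory Output directory (created if needed).
#' @param image_id Identifier used in the selection CSV.
#' @param intensity_scale Stored value = `round(intensity * scale)`.
#' @return Path of the manifest JSON, invisibly.
#' @export
write_fixture <- function(scene, phenotype, directory,
                          image_id = "synthetic", intensity_scale = 16) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  ch <- render_channels(scene, phenotype)
  paths <- list(
    nuclear = file.path(directory, "nuclear.tif"),
    protein = file.path(directory, "protein.tif"),
    selections = file.path(directory, "selections.csv"),
    manifest = file.path(directory, "manifest.json")
  )
  for (nm in c("nuclear", "protein")) {
    write_channel_tiff(ch[[nm]]$pixels * intensity_scale, paths[[nm]])
  }

  cells <- scene$cells
  pts <- tibble::tibble(
    type = "point", image_id = image_id,
    row1 = round(cells$nucleus_row), col1 = round(cells$nucleus_col),
    row2 = NA_real_, col2 = NA_real_
  )
  adj <- scene$adjacency
  prs <- tibble::tibble(
    type = "pair", image_id = image_id,
    row1 = round(cells$nucleus_row[adj$cell1]),
    col1 = round(cells$nucleus_col[adj$cell1]),
    row2 = round(cells$nucleus_row[adj$cell2]),
    col2 = round(cells$nucleus_col[adj$cell2])
  )
  write_selection_csv(dplyr::bind_rows(pts, prs), paths$selections)

  manifest <- list(
    generator = list(
      n_cells = nrow(cells), image_shape = scene$image_shape,
      seed = scene$seed, phenotype = unclass(phenotype),
      intensity_scale = intensity_scale, image_id = image_id
    ),
    files = lapply(paths[c("nuclear", "protein", "selections")], basename),
    checksums = as.list(tools::md5sum(unlist(
      paths[c("nuclear", "protein", "selections")]
    )))
  )
  names(manifest$checksums) <- c("nuclear", "protein", "selections")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths$manifest)
}
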