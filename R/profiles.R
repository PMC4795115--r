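#' Bilinear interpolation of image intensities at sub-pixel points
#'
#' Coordinates are 0-based with pixel centers at integers; sampling at an
#' integer coordinate returns the exact pixel value. Points must lie within
#' the convex hull of pixel centers, `[0, nrow-1] x [0, ncol-1]`.
#'
#' @param image [channel_image()] or matrix.
#' @param rows,cols Numeric vectors of sample coordinates.
#' @return Numeric vector of interpolated intensities.
#' @export
bilinear_sample <- function(image, rows, cols) {
  px <- as_pixels(image)
  nr <- nrow(px); nc <- ncol(px)
  if (any(rows < 0 | rows > nr - 1 | cols < 0 | cols > nc - 1)) {
    stop("bilinear_sample: sample point outside image bounds", call. = FALSE)
  }
  r0 <- pmin(floor(rows), nr - 2); c0 <- pmin(floor(cols), nc - 2)
  fr <- rows - r0; fc <- cols - c0
  v <- px[cbind(r0 + 1, c0 + 1)] * (1 - fr) * (1 - fc) +
    px[cbind(r0 + 2, c0 + 1)] * fr * (1 - fc) +
    px[cbind(r0 + 1, c0 + 2)] * (1 - fr) * fc +
    px[cbind(r0 + 2, c0 + 2)] * fr * fc
  as.vector(v)
}

new_profile <- function(samples, geometry, anchors, source_id = NA_character_) {
  structure(
    list(samples = as.numeric(samples), geometry = geometry,
         anchors = anchors, source_id = source_id),
    class = "profile_1d"
  )
}

#' @export
print.profile_1d <- function(x, ...) {
  cat(sprintf("<profile_1d> %s, %d samples, range [%.4g, %.4g]\n",
              x$geometry, length(x$samples), min(x$samples), max(x$samples)))
  invisible(x)
}

#' Extract an internuclear (IN) intensity profile
#'
#' Samples the protein channel along the straight segment joining the
#' centroids of two neighboring nuclei — the line crossing both cytoplasms
#' and the shared plasma membrane. Sampling uses bilinear interpolation at
#' `floor(d / step_px) + 1` uniformly spaced points including both
#' endpoints (`d` = centroid distance in px).
#'
#' @param protein Protein [channel_image()] or matrix.
#' @param c1,c2 Nucleus centroids, numeric `c(row, col)`, 0-based.
#' @param step_px Approximate sample spacing in px.
#' @param source_id Optional provenance identifier.
#' @return A `profile_1d` with geometry `"IN"`.
#' @export
extract_in_profile <- function(protein, c1, c2, step_px = 1,
                               source_id = NA_character_) {
  c1 <- as.numeric(c1); c2 <- as.numeric(c2)
  d <- sqrt(sum((c2 - c1)^2))
  if (d == 0) stop("extract_in_profile: identical anchor points", call. = FALSE)
  n <- floor(d / step_px) + 1L
  if (n < 2L) n <- 2L
  t <- seq(0, 1, length.out = n)
  samples <- bilinear_sample(protein,
                             c1[1] + t * (c2[1] - c1[1]),
                             c1[2] + t * (c2[2] - c1[2]))
  new_profile(samples, "IN", list(c1 = c1, c2 = c2), source_id)
}

#' Extract radial (RD) intensity profiles
#'
#' One profile per angle `theta_k = 2*pi*k / n_angles` (k = 0, ...,
#' n_angles-1), sampled from the nucleus centroid outward along the ray of
#' length `ray_length`; the direction at angle 0 points along increasing
#' column. Rays that leave the image are excluded and reported in the
#' `excluded_angles` attribute of the result.
#'
#' @param protein Protein [channel_image()] or matrix.
#' @param center Nucleus centroid, `c(row, col)`, 0-based.
#' @param n_angles Number of equally spaced rays (>= 4); default 72
#'   (5-degree spacing).
#' @param ray_length Ray length in px.
#' @param step_px Approximate sample spacing in px.
#' @param source_id Optional provenance identifier.
#' @return List of `profile_1d` objects (geometry `"RD"`), with attribute
#'   `excluded_angles` (radians) for clipped rays.
#' @export
extract_rd_profiles <- function(protein, center, n_angles = 72L,
                                ray_length, step_px = 1,
                                source_id = NA_character_) {
  stopifnot(n_angles >= 4, ray_length > 0)
  px <- as_pixels(protein)
  center <- as.numeric(center)
  if (center[1] < 0 || center[1] > nrow(px) - 1 ||
      center[2] < 0 || center[2] > ncol(px) - 1) {
    stop("extract_rd_profiles: center outside image", call. = FALSE)
  }
  n <- max(2L, floor(ray_length / step_px) + 1L)
  t <- seq(0, 1, length.out = n)
  profiles <- list(); excluded <- numeric(); kept_k <- integer()
  for (k in seq_len(n_angles) - 1L) {
    theta <- 2 * pi * k / n_angles
    end <- center + ray_length * c(sin(theta), cos(theta))
    rr <- center[1] + t * (end[1] - center[1])
    cc <- center[2] + t * (end[2] - center[2])
    if (any(rr < 0 | rr > nrow(px) - 1 | cc < 0 | cc > ncol(px) - 1)) {
      excluded <- c(excluded, theta)
      next
    }
    p <- new_profile(bilinear_sample(px, rr, cc), "RD",
                     list(center = center, angle = theta,
                          ray_length = ray_length), source_id)
    profiles[[length(profiles) + 1L]] <- p
    kept_k <- c(kept_k, k)
  }
  attr(profiles, "excluded_angles") <- excluded
  attr(profiles, "kept_k") <- kept_k
  profiles
}

#' Normalize a profile to a constant length
#'
#' Resamples the profile by linear interpolation onto `L` uniformly spaced
#' positions spanning its full extent (both endpoints included), so that
#' profiles from cells of different sizes become comparable on a common
#' normalized axis in `[0, 1]`. For IN profiles position 0 is the first
#' nucleus centroid, 1 the second, and the shared membrane is expected
#' near 0.5; for RD profiles 0 is the nucleus center and 1 the ray end.
#'
#' @param profile A `profile_1d` (or numeric vector).
#' @param L Target length (default 100).
#' @return Numeric vector of length `L` with attributes `positions`
#'   (the normalized axis) and `parent` (the source profile, if any).
#' @export
normalize_length <- function(profile, L = 100L) {
  samples <- if (inherits(profile, "profile_1d")) profile$samples
             else as.numeric(profile)
  n <- length(samples)
  if (n < 2L) stop("normalize_length: need >= 2 samples", call. = FALSE)
  x <- seq(0, 1, length.out = n)
  xo <- seq(0, 1, length.out = L)
  out <- stats::approx(x, samples, xout = xo)$y
  attr(out, "positions") <- xo
  if (inherits(profile, "profile_1d")) attr(out, "parent") <- profile
  out
}

#' Stack normalized profiles into a profile map
#'
#' Columns are length-normalized profiles on the common axis; rows index
#' normalized position. The map records its processing stage (`raw`,
#' `denoised` or `compensated`) and, after compensation, the per-column
#' monotone warps.
#'
#' @param profiles List of normalized profiles (equal length) or a matrix
#'   whose columns are profiles.
#' @param stage Processing stage of the values.
#' @return An object of class `profile_map`: list with `values` (L x N
#'   matrix), `positions`, `stage`, `warps` (NULL until compensated) and
#'   `provenance`.
#' @export
build_map <- function(profiles, stage = "raw") {
  if (is.matrix(profiles)) {
    values <- profiles
    prov <- NULL
  } else {
    lens <- vapply(profiles, length, integer(1))
    if (length(unique(lens)) != 1L) {
      stop("build_map: profiles have mixed lengths", call. = FALSE)
    }
    values <- do.call(cbind, lapply(profiles, as.numeric))
    prov <- lapply(profiles, function(p) {
      par <- attr(p, "parent")
      if (is.null(par)) NULL else par[c("geometry", "anchors", "source_id")]
    })
  }
  structure(
    list(values = values,
         positions = seq(0, 1, length.out = nrow(values)),
         stage = stage, warps = NULL, provenance = prov),
    class = "profile_map"
  )
}

#' @export
print.profile_map <- function(x, ...) {
  cat(sprintf("<profile_map> %d x %d (%s)\n",
              nrow(x$values), ncol(x$values), x$stage))
  invisible(x)
}

#' @export
dim.profile_map <- function(x) dim(x$values)

#' Write / read a profile map as CSV
#'
#' Plain CSV with one row per normalized position and one column per
#' profile, so intermediates remain inspectable with any table tool.
#'
#' @param map A [build_map()] result.
#' @param path Output path.
#' @return `path` / a `profile_map`.
#' @export
write_profile_map_csv <- function(map, path) {
  df <- as.data.frame(map$values)
  names(df) <- paste0("profile_", seq_len(ncol(df)))
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_profile_map_csv
#' @param stage Stage to record on the map read back.
#' @export
read_profile_map_csv <- function(path, stage = "raw") {
  df <- readr::read_csv(path, show_col_types = FALSE)
  build_map(as.matrix(df), stage = stage)
}
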