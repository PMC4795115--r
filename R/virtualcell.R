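#' Reconstruct a 2D virtual cell from per-angle radial profiles
#'
#' Assembles the per-angle average compensated RD profiles into a polar
#' intensity matrix (angles x radial positions) and resamples it onto a
#' Cartesian disk of radius `L` pixels by inverse polar mapping with
#' bilinear interpolation in (angle, radius). The result depicts the
#' typical protein distribution of a population on a normalized geometry,
#' independent of individual cell morphology; it is a qualitative output
#' (quantitative claims belong to the profile statistics).
#'
#' @param rd_profiles Per-angle mean profiles: a numeric matrix with one
#'   row per angle (angles assumed equally spaced over `[0, 2*pi)`, in
#'   row order) or a list of equal-length numeric vectors. At least 4
#'   angles, profiles of length L (default 100).
#' @return An object of class `virtual_cell`: list with `polar` (A x L
#'   matrix), `cartesian` (square matrix of side `2L + 1`), `radius`
#'   (L) and `enhancement` (`"none"`).
#' @export
build_virtual_cell <- function(rd_profiles) {
  if (is.list(rd_profiles) && !is.matrix(rd_profiles)) {
    lens <- vapply(rd_profiles, length, integer(1))
    if (length(unique(lens)) != 1L) {
      stop("build_virtual_cell: profiles have inconsistent lengths",
           call. = FALSE)
    }
    polar <- do.call(rbind, lapply(rd_profiles, as.numeric))
  } else {
    polar <- as.matrix(rd_profiles)
  }
  n_ang <- nrow(polar); L <- ncol(polar)
  if (n_ang < 4L) {
    stop("build_virtual_cell: need >= 4 angles", call. = FALSE)
  }
  side <- 2L * L + 1L
  center <- L  # 0-based center index
  rows <- matrix(0:(side - 1L), side, side) - center
  cols <- matrix(0:(side - 1L), side, side, byrow = TRUE) - center
  rho <- sqrt(rows^2 + cols^2)
  theta <- atan2(rows, cols) %% (2 * pi)

  # continuous indices into the polar matrix; radius of sample k
  # (1-based) is (k - 1) / (L - 1) * L px, so a delta at normalized
  # radial position r reconstructs at rho = r * L
  a_idx <- theta / (2 * pi) * n_ang           # in [0, n_ang)
  r_idx <- rho / L * (L - 1) + 1              # in [1, L] inside the disk

  inside <- rho <= L
  a0 <- floor(a_idx); fa <- a_idx - a0
  r0 <- pmin(floor(r_idx), L - 1L); fr <- r_idx - r0
  a1 <- (a0 %% n_ang) + 1L                    # wrap angles
  a2 <- ((a0 + 1) %% n_ang) + 1L

  val <- function(ai, ri) polar[cbind(ai[inside], ri[inside])]
  cart <- matrix(0, side, side)
  cart[inside] <-
    val(a1, r0) * (1 - fa[inside]) * (1 - fr[inside]) +
    val(a2, r0) * fa[inside] * (1 - fr[inside]) +
    val(a1, r0 + 1L) * (1 - fa[inside]) * fr[inside] +
    val(a2, r0 + 1L) * fa[inside] * fr[inside]
  cart[center + 1L, center + 1L] <- mean(polar[, 1L])

  structure(
    list(polar = polar, cartesian = cart, radius = L,
         enhancement = "none"),
    class = "virtual_cell"
  )
}

#' @export
print.virtual_cell <- function(x, ...) {
  cat(sprintf("<virtual_cell> %d angles x %d radii, %s, peak %.4g\n",
              nrow(x$polar), ncol(x$polar), x$enhancement,
              max(x$cartesian)))
  invisible(x)
}

#' Contrast-enhance a virtual cell
#'
#' Percentile-clipped linear stretch of the Cartesian image to the 8-bit
#' display range (computed over the disk interior). The mapping is
#' monotone, so intensity rank order — in particular the location of the
#' maximum — is preserved. A constant image is returned unchanged with
#' the `constant_image` attribute set.
#'
#' @param cell A [build_virtual_cell()] result.
#' @param low_pct,high_pct Clipping percentiles (0-100).
#' @return A `virtual_cell` with `enhancement = "contrast_enhanced"`.
#' @export
enhance_contrast <- function(cell, low_pct = 1, high_pct = 99) {
  stopifnot(inherits(cell, "virtual_cell"), low_pct < high_pct)
  img <- cell$cartesian
  side <- nrow(img)
  center <- cell$radius
  rows <- matrix(0:(side - 1L), side, side) - center
  cols <- matrix(0:(side - 1L), side, side, byrow = TRUE) - center
  inside <- sqrt(rows^2 + cols^2) <= cell$radius
  q <- stats::quantile(img[inside], c(low_pct, high_pct) / 100,
                       names = FALSE)
  out <- cell
  # treat float fuzz from interpolation weights as a constant image
  if (q[2] - q[1] <= 1e-9 * max(1, abs(q[2]))) {
    attr(out, "constant_image") <- TRUE
    return(out)
  }
  stretched <- (img - q[1]) / (q[2] - q[1]) * 255
  stretched <- pmin(pmax(stretched, 0), 255)
  stretched[!inside] <- 0
  out$cartesian <- stretched
  out$enhancement <- "contrast_enhanced"
  out
}

#' Write a virtual cell as an 8-bit PNG
#'
#' @param cell A `virtual_cell`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_virtual_cell_png <- function(cell, path) {
  img <- cell$cartesian
  hi <- max(img)
  if (hi > 0) img <- img / hi
  png::writePNG(img, path)
  invisible(path)
}
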