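#' Otsu threshold of a fluorescence channel
#'
#' Computes the histogram-based threshold that maximizes the between-class
#' variance of the binarized image. For an 8-bit image the histogram has
#' 256 integer bins and candidate thresholds are the integer intensities;
#' otherwise the intensity range is split into `bins` equal-width bins and
#' the returned threshold is the upper edge of the chosen bin. When several
#' thresholds attain the maximal between-class variance the lowest is
#' returned. Pixels strictly above the threshold are foreground.
#'
#' @param image A [channel_image()] or numeric matrix.
#' @param bins Number of histogram bins for non-8-bit data.
#' @return A single numeric threshold.
#' @export
otsu_threshold <- function(image, bins = 256L) {
  px <- as_pixels(image)
  if (length(unique(as.vector(px))) < 2L) {
    stop("otsu_threshold: constant image has no threshold", call. = FALSE)
  }
  is8 <- inherits(image, "channel_image") && image$bit_depth == 8L
  if (is8 || (max(px) <= 255 && all(px == round(px)))) {
    counts <- tabulate(as.integer(px) + 1L, nbins = 256L)
    levels <- 0:255 + 0.5
  } else {
    lo <- min(px); hi <- max(px)
    edges <- seq(lo, hi, length.out = bins + 1L)
    bin <- pmin(findInterval(px, edges, rightmost.closed = TRUE), bins)
    counts <- tabulate(bin, nbins = bins)
    levels <- edges[-1L]  # thresholds at upper bin edges
  }
  otsu_from_histogram(counts, levels)
}

# Vectorized between-class-variance maximization over all candidate
# thresholds; threshold k means "class 1 = bins 1..k, class 2 = rest".
# For integer (8-bit) histograms the returned threshold is the class
# boundary + 0.5, so it falls strictly between the two classes.
otsu_from_histogram <- function(counts, levels) {
  n <- sum(counts)
  p <- counts / n
  w1 <- cumsum(p)
  mu <- cumsum(p * levels)
  mu_t <- mu[length(mu)]
  k <- seq_len(length(counts) - 1L)
  w1k <- w1[k]; w2k <- 1 - w1k
  valid <- w1k > 0 & w2k > 0
  bcv <- rep(-Inf, length(k))
  bcv[valid] <- (mu_t * w1k[valid] - mu[k][valid])^2 /
    (w1k[valid] * w2k[valid])
  if (!any(is.finite(bcv))) {
    stop("otsu_threshold: degenerate histogram", call. = FALSE)
  }
  best <- which(bcv >= max(bcv) - 1e-12)[1L]  # lowest maximizer
  levels[best]
}

#' Segment nuclei by Otsu thresholding and watershed splitting
#'
#' The nuclear channel is Gaussian-smoothed, binarized at the Otsu
#' threshold, and touching nuclei are split by a watershed on the Euclidean
#' distance transform of the foreground mask. Components smaller than
#' `min_area` are removed, labels are relabeled consecutively and the
#' geometric (binary, intensity-unweighted) centroid of each nucleus is
#' reported with sub-pixel precision.
#'
#' @param image Nuclear [channel_image()] or matrix.
#' @param min_area Minimum nucleus area in px^2.
#' @param smoothing_sigma Gaussian pre-smoothing sigma in px (0 disables).
#' @param seed_separation Minimum separation (px) of watershed seeds, i.e.
#'   the neighborhood radius used when detecting distance-map maxima.
#' @return An object of class `nucleus_label_map`: list with `labels`
#'   (integer matrix, 0 = background) and `nuclei` (tibble: `label`,
#'   `row`, `col`, `area`; 0-based sub-pixel centroids).
#' @export
segment_nuclei <- function(image, min_area = 30, smoothing_sigma = 1,
                           seed_separation = 5) {
  px <- as_pixels(image)
  sm <- if (smoothing_sigma > 0) {
    as.matrix(EBImage::gblur(px, sigma = smoothing_sigma))
  } else px
  thr <- otsu_threshold(if (inherits(image, "channel_image")) {
    channel_image(pmax(sm, 0), bit_depth = image$bit_depth)
  } else pmax(sm, 0))
  mask <- sm > thr
  # nuclei are a bright minority: a "foreground" covering nearly half the
  # frame means the histogram had no signal class, only noise
  if (!any(mask) || mean(mask) >= 0.45) {
    return(new_nucleus_label_map(matrix(0L, nrow(px), ncol(px))))
  }
  dm <- EBImage::distmap(mask)
  labels <- as.matrix(EBImage::watershed(dm, tolerance = 1,
                                         ext = seed_separation))
  storage.mode(labels) <- "integer"
  # drop small components, relabel consecutively
  areas <- tabulate(labels[labels > 0L])
  keep <- which(areas >= min_area)
  remap <- integer(length(areas))
  remap[keep] <- seq_along(keep)
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]
  new_nucleus_label_map(labels)
}

new_nucleus_label_map <- function(labels) {
  k <- max(labels)
  if (k == 0L) {
    nuclei <- tibble::tibble(label = integer(), row = double(),
                             col = double(), area = double())
  } else {
    idx <- which(labels > 0L, arr.ind = TRUE)
    lab <- labels[labels > 0L]
    nuclei <- tibble::tibble(
      label = seq_len(k),
      row = as.vector(tapply(idx[, 1] - 1, lab, mean)),
      col = as.vector(tapply(idx[, 2] - 1, lab, mean)),
      area = as.vector(tapply(lab, lab, length))
    )
  }
  structure(list(labels = labels, nuclei = nuclei),
            class = "nucleus_label_map")
}

#' @export
print.nucleus_label_map <- function(x, ...) {
  cat(sprintf("<nucleus_label_map> %d nuclei in %d x %d px\n",
              nrow(x$nuclei), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Match operator-selected points to segmented nuclei
#'
#' Each selected point maps to the nucleus whose labeled region contains
#' it; points on background snap to the nucleus with the nearest labeled
#' pixel if that pixel lies within `max_snap_distance`, and are otherwise
#' reported as unmatched (with a warning) and excluded from analysis.
#'
#' @param label_map A [segment_nuclei()] result.
#' @param points Data frame or matrix with columns `row`, `col` (0-based).
#' @param max_snap_distance Maximum centroid snap distance in px.
#' @return Tibble: `point`, `row`, `col`, `label` (NA if unmatched),
#'   `snap_distance`, `matched`.
#' @export
match_selection <- function(label_map, points, max_snap_distance = 10) {
  pts <- as.data.frame(points)
  if (is.null(pts$row)) { colnames(pts)[1:2] <- c("row", "col") }
  nr <- nrow(label_map$labels); nc <- ncol(label_map$labels)
  fg <- which(label_map$labels > 0L, arr.ind = TRUE)
  fg_lab <- label_map$labels[fg]
  res <- purrr::map_dfr(seq_len(nrow(pts)), function(i) {
    r <- pts$row[i]; c <- pts$col[i]
    ri <- round(r) + 1L; ci <- round(c) + 1L
    lab <- NA_integer_; snap <- NA_real_
    if (ri >= 1 && ri <= nr && ci >= 1 && ci <= nc &&
        label_map$labels[ri, ci] > 0L) {
      lab <- label_map$labels[ri, ci]
      snap <- 0
    } else if (nrow(fg) > 0) {
      d2 <- (fg[, 1] - 1 - r)^2 + (fg[, 2] - 1 - c)^2
      j <- which.min(d2)
      if (sqrt(d2[j]) <= max_snap_distance) {
        lab <- fg_lab[j]; snap <- sqrt(d2[j])
      }
    }
    tibble::tibble(point = i, row = r, col = c, label = lab,
                   snap_distance = snap, matched = !is.na(lab))
  })
  if (any(!res$matched)) {
    warning(sum(!res$matched), " selection point(s) unmatched (farther than ",
            max_snap_distance, " px from any nucleus); excluded",
            call. = FALSE)
  }
  res
}
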