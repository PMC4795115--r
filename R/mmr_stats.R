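#' Maximum-mean ratio (MMR) of a profile
#'
#' The maximum fluorescence value of the profile divided by its mean.
#' MMR quantifies the sharpness of the fluorescence peak at the membrane:
#' values near 1 indicate diffuse signal, high values a concentrated
#' membrane peak. For non-negative, non-constant profiles MMR > 1, and
#' MMR is invariant under intensity rescaling.
#'
#' @param profile Numeric vector (normalized profile) with positive mean.
#' @return A single dimensionless value.
#' @export
compute_mmr <- function(profile) {
  s <- as.numeric(profile)
  m <- mean(s)
  if (!is.finite(m) || m <= 0) {
    stop("compute_mmr: profile mean must be positive", call. = FALSE)
  }
  max(s) / m
}

#' Membrane mean fluorescence of a normalized IN profile
#'
#' Mean intensity over the samples whose normalized axis position lies
#' within `window` of 0.5, the expected position of the shared plasma
#' membrane on the internuclear axis.
#'
#' @param profile Numeric vector on the normalized axis (length L,
#'   positions `seq(0, 1, length.out = L)`).
#' @param window Half-width of the membrane window in normalized units
#'   (default 0.05, i.e. 5 of 100 units).
#' @return Mean intensity in the window.
#' @export
membrane_mean <- function(profile, window = 0.05) {
  stopifnot(window > 0, window < 0.5)
  s <- as.numeric(profile)
  pos <- attr(profile, "positions")
  if (is.null(pos)) pos <- seq(0, 1, length.out = length(s))
  mean(s[abs(pos - 0.5) <= window + 1e-12])
}

#' Per-profile quantitative features of a profile map
#'
#' Computes, for every column of a (typically compensated) profile map,
#' the membrane mean fluorescence, the MMR and the position of the
#' profile maximum on the normalized axis.
#'
#' @param map A `profile_map`.
#' @param window Membrane window half-width (see [membrane_mean()]).
#' @return Tibble: `profile_id`, `membrane_mean`, `mmr`, `peak_position`.
#' @export
profile_features <- function(map, window = 0.05) {
  stopifnot(inherits(map, "profile_map"))
  v <- map$values
  purrr::map_dfr(seq_len(ncol(v)), function(j) {
    col <- v[, j]
    tibble::tibble(
      profile_id = j,
      membrane_mean = mean(col[abs(map$positions - 0.5) <= window + 1e-12]),
      mmr = compute_mmr(col),
      peak_position = map$positions[which.max(col)]
    )
  })
}

#' Summarize per-profile features of one population
#'
#' Means and standard errors (sample SD / sqrt(n)) of the membrane mean
#' fluorescence and the MMR across profiles, mirroring the per-population
#' rows of a quantification table. With a single profile the SEs are
#' reported as zero and flagged.
#'
#' @param features Tibble from [profile_features()].
#' @param population Optional population label.
#' @return One-row tibble: `population`, `n_profiles`,
#'   `membrane_mean_mean`, `membrane_mean_se`, `mmr_mean`, `mmr_se`,
#'   with attribute `se_undefined` when n = 1.
#' @export
summarize_population <- function(features, population = NA_character_) {
  stopifnot(nrow(features) >= 1)
  n <- nrow(features)
  se <- function(x) if (n >= 2L) stats::sd(x) / sqrt(n) else 0
  out <- tibble::tibble(
    population = population,
    n_profiles = n,
    membrane_mean_mean = mean(features$membrane_mean),
    membrane_mean_se = se(features$membrane_mean),
    mmr_mean = mean(features$mmr),
    mmr_se = se(features$mmr)
  )
  attr(out, "se_undefined") <- n < 2L
  out
}

# U statistic (number of (a, b) pairs with a > b, ties counted 1/2).
mw_u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

#' Two-sided Mann-Whitney U test
#'
#' Computes the Mann-Whitney U statistic for samples `a` vs `b` with an
#' exact two-sided p-value by full enumeration of all
#' `choose(n_a + n_b, n_a)` group labelings when both samples are small
#' (`n <= exact_max_n`), which remains valid under ties; larger samples
#' use the normal approximation with tie correction and continuity
#' correction.
#'
#' @param a,b Numeric samples (each non-empty).
#' @param exact_max_n Use exact enumeration when both sample sizes are at
#'   most this value.
#' @return Tibble: `statistic` (U for `a`), `p_value`, `method`.
#' @export
mann_whitney <- function(a, b, exact_max_n = 8L) {
  if (length(a) < 1L || length(b) < 1L) {
    stop("mann_whitney: empty sample", call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  u <- mw_u_statistic(a, b)
  if (na <= exact_max_n && nb <= exact_max_n) {
    pooled <- c(a, b)
    combos <- utils::combn(na + nb, na)
    r <- rank(pooled)
    u_all <- apply(combos, 2, function(idx) {
      sum(r[idx]) - na * (na + 1) / 2
    })
    p <- 2 * min(mean(u_all <= u + 1e-9), mean(u_all >= u - 1e-9))
    p <- min(p, 1)
    method <- "exact enumeration"
  } else {
    mu <- na * nb / 2
    n <- na + nb
    ties <- table(c(a, b))
    tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tie_corr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation"
  }
  tibble::tibble(statistic = u, p_value = p, method = method)
}

#' Compare feature distributions across populations
#'
#' Tests each non-reference population's membrane mean fluorescence and
#' MMR vectors against the reference population with two-sided
#' Mann-Whitney tests, applying a Bonferroni correction whose denominator
#' is the total number of tests performed in the batch
#' (`alpha_corrected = alpha / n_comparisons`).
#'
#' @param populations Named list of [profile_features()] tibbles.
#' @param reference Name of the reference population (e.g. `"WT"`).
#' @param alpha Family-wise significance level.
#' @param exact_max_n Passed to [mann_whitney()].
#' @return An object of class `population_comparison`: tibble with
#'   `population`, `feature`, `statistic`, `p_raw`, `n_comparisons`,
#'   `alpha_corrected`, `significant`.
#' @export
compare_populations <- function(populations, reference = "WT",
                                alpha = 0.05, exact_max_n = 8L) {
  if (!reference %in% names(populations)) {
    stop("compare_populations: unknown reference '", reference, "'",
         call. = FALSE)
  }
  if (length(populations) < 2L) {
    stop("compare_populations: need >= 2 populations", call. = FALSE)
  }
  ref <- populations[[reference]]
  others <- setdiff(names(populations), reference)
  feats <- c("membrane_mean", "mmr")
  res <- purrr::map_dfr(others, function(nm) {
    purrr::map_dfr(feats, function(f) {
      mw <- mann_whitney(populations[[nm]][[f]], ref[[f]],
                         exact_max_n = exact_max_n)
      tibble::tibble(population = nm, feature = f,
                     statistic = mw$statistic, p_raw = mw$p_value)
    })
  })
  n_comp <- nrow(res)
  res$n_comparisons <- n_comp
  res$alpha_corrected <- alpha / n_comp
  res$significant <- res$p_raw < res$alpha_corrected
  class(res) <- c("population_comparison", class(res))
  attr(res, "alpha") <- alpha
  attr(res, "reference") <- reference
  res
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise level.
#' @param n_comparisons Number of tests in the batch.
#' @return `alpha / n_comparisons`.
#' @export
bonferroni_alpha <- function(alpha, n_comparisons) {
  stopifnot(n_comparisons >= 1)
  alpha / n_comparisons
}
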