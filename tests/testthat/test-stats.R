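test_that("MMR satisfies its axioms", {
  expect_identical(compute_mmr(rep(7.3, 100)), 1)
  expect_identical(compute_mmr(c(rep(0, 99), 100)), 100)
  expect_error(compute_mmr(rep(0, 100)), "positive")
  set.seed(10)
  for (i in 1:20) {
    p <- stats::runif(100, 0, 50)
    expect_gte(compute_mmr(p), 1)
    for (cc in c(0.1, 3, 117)) {
      expect_equal(compute_mmr(cc * p), compute_mmr(p), tolerance = 1e-12)
    }
  }
})

test_that("membrane mean averages the central window and scales linearly", {
  expect_equal(membrane_mean(rep(4.2, 100)), 4.2)
  ramp <- as.numeric(0:99)
  expect_equal(membrane_mean(ramp, window = 0.05), mean(45:54))
  set.seed(11)
  p <- stats::runif(100, 0, 30)
  expect_equal(membrane_mean(3 * p), 3 * membrane_mean(p),
               tolerance = 1e-12)
})

test_that("population summaries report means and standard errors", {
  f2 <- tibble::tibble(profile_id = 1:2, membrane_mean = c(50, 60),
                       mmr = c(1.2, 1.4), peak_position = c(0.5, 0.5))
  s <- summarize_population(f2, "demo")
  expect_equal(s$mmr_mean, 1.3)
  expect_equal(s$mmr_se, stats::sd(c(1.2, 1.4)) / sqrt(2))
  expect_equal(s$mmr_se, 0.1, tolerance = 1e-9)
  s1 <- summarize_population(f2[1, ])
  expect_equal(s1$mmr_se, 0)
  expect_true(attr(s1, "se_undefined"))
})

test_that("standard errors shrink as 1/sqrt(n)", {
  set.seed(12)
  mk <- function(n) tibble::tibble(profile_id = seq_len(n),
                                   membrane_mean = stats::rnorm(n, 100, 10),
                                   mmr = stats::rlnorm(n, 0.4, 0.1),
                                   peak_position = 0.5)
  s1 <- summarize_population(mk(300))
  s2 <- summarize_population(mk(600))
  expect_lt(abs((s2$mmr_se / s1$mmr_se) / (1 / sqrt(2)) - 1), 0.15)
})

test_that("Mann-Whitney exact p matches the textbook cases", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)
  same <- mann_whitney(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(same$p_value, 1)
  expect_error(mann_whitney(numeric(), 1:3), "empty")
})

test_that("exact Mann-Whitney agrees with the reference implementation", {
  set.seed(13)
  for (na in 1:6) {
    for (nb in 1:6) {
      a <- stats::rnorm(na)
      b <- stats::rnorm(nb)
      mine <- mann_whitney(a, b)
      ref <- stats::wilcox.test(a, b, exact = TRUE)
      expect_equal(mine$statistic, unname(ref$statistic))
      expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("large-sample path matches the tie-corrected normal approximation", {
  set.seed(14)
  a <- sample(1:20, 30, replace = TRUE)
  b <- sample(3:22, 25, replace = TRUE)
  mine <- mann_whitney(a, b)
  expect_equal(mine$method, "normal approximation")
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("Bonferroni correction divides alpha by the batch size", {
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 3), 0.05 / 3)
  expect_equal(round(bonferroni_alpha(0.05, 3), 3), 0.017)
})

test_that("population comparisons flag separated populations and stay tidy", {
  set.seed(15)
  mk <- function(n, mu) tibble::tibble(
    profile_id = seq_len(n),
    membrane_mean = stats::rnorm(n, mu, 8),
    mmr = stats::rlnorm(n, log(mu) / 4, 0.08),
    peak_position = 0.5)
  pops <- list(WT = mk(200, 100), mutant = mk(200, 40))
  cmp <- compare_populations(pops, reference = "WT")
  expect_s3_class(cmp, "population_comparison")
  expect_equal(nrow(cmp), 2L)
  expect_equal(unique(cmp$n_comparisons), 2L)
  expect_equal(unique(cmp$alpha_corrected), 0.025)
  expect_true(all(cmp$significant))
  td <- tidy(cmp)
  expect_false(inherits(td, "population_comparison"))
  gl <- glance(cmp)
  expect_equal(gl$n_significant, 2L)
  expect_error(compare_populations(pops, reference = "nope"), "unknown")
})

test_that("corrected type-I error stays at or below the nominal level", {
  set.seed(16)
  n_rep <- 500
  rejections <- 0L
  for (i in seq_len(n_rep)) {
    a <- stats::rlnorm(15, 0.4, 0.1)
    b <- stats::rlnorm(15, 0.4, 0.1)
    p <- mann_whitney(a, b)$p_value
    if (p < bonferroni_alpha(0.05, 2)) rejections <- rejections + 1L
  }
  rate <- rejections / n_rep
  nominal <- bonferroni_alpha(0.05, 2)
  expect_lte(rate, nominal + 3 * sqrt(nominal * (1 - nominal) / n_rep))
})
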