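test_that("Anscombe transform and unbiased inverse are consistent", {
  v <- c(20, 50, 200, 1000)
  back <- inverse_anscombe(anscombe(v))
  expect_lt(max(abs(back - v) / v), 0.02)
  # the inverse is *unbiased*: E[inv(anscombe(Poisson(mu)))] ~ mu
  set.seed(2)
  for (mu in c(20, 50, 200)) {
    est <- mean(inverse_anscombe(anscombe(stats::rpois(50000, mu))))
    expect_lt(abs(est - mu) / mu, 0.01)
  }
  # variance stabilization: Poisson draws have ~unit sd in the z-domain
  set.seed(3)
  for (mu in c(10, 50, 200)) {
    z <- anscombe(stats::rpois(20000, mu))
    expect_lt(abs(stats::sd(z) - 1), 0.1)
  }
})

test_that("1D total variation denoising solves the ROF model", {
  # closed-form two-point solutions
  expect_equal(tv_denoise_1d(c(0, 10), 2), c(2, 8), tolerance = 1e-7)
  expect_equal(tv_denoise_1d(c(0, 10), 6), c(5, 5), tolerance = 1e-7)
  expect_equal(tv_denoise_1d(c(4, 4, 4), 3), c(4, 4, 4))
  # matches a smoothed-objective optimizer on a random signal
  set.seed(7)
  y <- cumsum(stats::rnorm(40)); lam <- 0.8
  x <- tv_denoise_1d(y, lam)
  obj <- function(x) 0.5 * sum((x - y)^2) + lam * sum(abs(diff(x)))
  ref <- stats::optim(y, function(x) {
    0.5 * sum((x - y)^2) + lam * sum(sqrt(diff(x)^2 + 1e-14))
  }, method = "BFGS", control = list(maxit = 3000, reltol = 1e-14))
  expect_lte(obj(x), ref$value + 1e-6)
  expect_identical(tv_denoise_1d(y, 0), y)
})

test_that("denoising is a no-op at zero strength and reduces Poisson noise", {
  set.seed(9)
  truth <- matrix(50, 100, 50)
  noisy <- matrix(stats::rpois(5000, 50), 100, 50)
  m <- build_map(noisy)
  expect_equal(denoise_map(m, strength = 0)$values, m$values)
  dn <- denoise_map(m)
  expect_equal(dn$stage, "denoised")
  sd_before <- mean(apply(m$values, 1, sd))
  sd_after <- mean(apply(dn$values, 1, sd))
  expect_lt(sd_after, 0.5 * sd_before)
  # denoising bias under the unbiased inverse stays below 2%
  expect_lt(abs(mean(dn$values) - mean(m$values)) / mean(m$values), 0.02)
  expect_true(all(dn$values >= 0))
})

test_that("denoising preserves step-edge position and validates stages", {
  step <- c(rep(10, 50), rep(110, 50))
  m <- build_map(matrix(step, 100, 5))
  dn <- denoise_map(m)
  for (j in 1:5) {
    expect_equal(which.max(diff(dn$values[, j])),
                 which.max(diff(step)))
  }
  expect_error(denoise_map(dn), "raw")
  neg <- build_map(matrix(c(-1, rep(1, 99)), 100, 2))
  expect_error(denoise_map(neg), "negative")
})

test_that("already-aligned maps get identity warps and zero objective", {
  prof <- 20 + 100 * exp(-(seq(0, 1, length.out = 100) - 0.5)^2 / 0.005)
  m <- build_map(matrix(prof, 100, 8))
  cm <- compensate_map(m)
  expect_equal(cm$stage, "compensated")
  expect_lt(max(abs(cm$warps$displacements)), 1e-4)
  expect_lt(attr(cm, "objective_trace")[length(attr(cm, "objective_trace"))],
            1e-6)
  expect_lte(attr(cm, "n_iterations"), 2L)
  expect_error(compensate_map(build_map(matrix(prof, 100, 1))), ">= 2")
})

test_that("known column shifts are recovered and the objective is monotone", {
  sim <- shifted_peak_map(n_cols = 20, seed = 21)
  cm <- compensate_map(sim$map)
  rec <- warp_displacement(cm, at = 0.5)
  expect_lt(mean(abs(rec - sim$shifts)) * 100, 1.5)
  tr <- attr(cm, "objective_trace")
  expect_true(all(diff(tr) <= 1e-9))
  # warp validity: strictly increasing, endpoints fixed
  for (j in seq_len(ncol(cm$values))) {
    kn <- cm$warps$knots + c(0, cm$warps$displacements[, j], 0)
    expect_true(all(diff(kn) > 0))
    expect_equal(kn[1], 0)
    expect_equal(kn[length(kn)], 1)
  }
})

test_that("compensation sharpens the average peak and shrinks row SDs", {
  sim <- shifted_peak_map(n_cols = 20, seed = 22)
  cm <- compensate_map(sim$map)
  raw_avg <- summarize_map(sim$map)
  comp_avg <- summarize_map(cm)
  expect_gt(max(comp_avg$mean), max(raw_avg$mean))
  expect_lt(mean(comp_avg$sd), mean(raw_avg$sd))
})

test_that("map summaries compute row means and sample SDs", {
  v <- stats::runif(100, 10, 20)
  same <- summarize_map(build_map(matrix(v, 100, 6)))
  expect_equal(same$mean, v)
  expect_true(all(same$sd == 0))
  two <- summarize_map(build_map(cbind(rep(0, 100), rep(2, 100))))
  expect_true(all(two$mean == 1))
  expect_equal(two$sd, rep(sqrt(2), 100))
  one <- summarize_map(build_map(matrix(v, 100, 1)))
  expect_true(attr(one, "sd_undefined"))
  expect_true(all(one$sd == 0))
  expect_equal(attr(one, "n"), 1L)
})
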