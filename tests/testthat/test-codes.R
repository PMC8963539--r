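make_pair <- function(grid) {
  # a bimodal and a unimodal field with matched total mass
  c1 <- exp(-rowSums(sweep(grid$centers, 2L, c(-2, 0))^2) / 2)
  c2 <- exp(-rowSums(sweep(grid$centers, 2L, c(2, 0))^2) / 2)
  c0 <- exp(-rowSums(grid$centers^2) / 2)
  list(p1 = probability_field(grid, c1 + c2), p2 = probability_field(grid, c0))
}

test_that("mean rates are deterministic, nonnegative and delta-selective", {
  g <- tiny_grid_2d(11L)
  code <- distributional_code(g, "linear_moment", n_neurons = 16L, gain = 10,
                              baseline = 0, seed = 2)
  flds <- make_pair(g)
  expect_identical(mean_rates(code, flds$p1), mean_rates(code, flds$p1))
  expect_true(all(mean_rates(code, flds$p1) >= 0))
  # point mass at cell k reads out column k of the weights
  k <- 37L
  delta <- probability_field(g, replace(numeric(g$n_cells), k, 1))
  expect_equal(mean_rates(code, delta), 10 * code$weights[, k])
})

test_that("sampled responses are integer counts matching their means", {
  g <- tiny_grid_2d(11L)
  flds <- make_pair(g)
  for (kind in c("linear_moment", "linear_sampling", "nonlinear_rate",
                 "natural_param")) {
    code <- distributional_code(g, kind, n_neurons = 12L, gain = 8, seed = 3)
    set.seed(1)
    r <- sample_response(code, flds$p1)
    expect_true(all(r >= 0), info = kind)
    expect_true(all(r == round(r)), info = kind)
  }
  # Monte Carlo mean matches mean_rates for the sampling code
  code <- distributional_code(g, "linear_sampling", n_neurons = 12L, gain = 4,
                              seed = 3)
  set.seed(2)
  R <- vapply(seq_len(20000L), function(i) sample_response(code, flds$p1),
              integer(12L))
  mr <- mean_rates(code, flds$p1)
  se <- apply(R, 1L, stats::sd) / sqrt(ncol(R))
  expect_true(all(abs(rowMeans(R) - mr) < 4 * se + 1e-9))
  # gain 0 emits only baseline spikes; with baseline 0, silence
  code0 <- distributional_code(g, "linear_sampling", n_neurons = 12L, gain = 0,
                               baseline = 0, seed = 3)
  expect_true(all(sample_response(code0, flds$p1, seed = 1) == 0L))
})

test_that("Poisson kinds have variance approximately equal to the mean", {
  g <- tiny_grid_2d(11L)
  flds <- make_pair(g)
  code <- distributional_code(g, "linear_moment", n_neurons = 10L, gain = 30,
                              seed = 4)
  set.seed(3)
  R <- vapply(seq_len(20000L), function(i) sample_response(code, flds$p2),
              integer(10L))
  m <- rowMeans(R); v <- apply(R, 1L, stats::var)
  expect_true(all(abs(v / m - 1) < 0.1))
})

test_that("LDC classification: linear codes pass, nonlinear codes fail", {
  g <- tiny_grid_2d(11L)
  flds <- make_pair(g)
  # linear kinds: analytic mixture gap identically zero
  for (kind in c("linear_moment", "linear_sampling")) {
    code <- distributional_code(g, kind, n_neurons = 16L, gain = 15, seed = 5)
    gap <- ldc_mixture_gap(code, flds$p1, flds$p2, alpha = 0.3)
    expect_lt(max(gap$gap), 1e-10)
  }
  # degenerate mixtures give zero gap for any code
  cn <- distributional_code(g, "nonlinear_rate", n_neurons = 16L, gain = 15,
                            seed = 5)
  expect_lt(max(ldc_mixture_gap(cn, flds$p1, flds$p2, alpha = 0)$gap), 1e-10)
  expect_lt(max(ldc_mixture_gap(cn, flds$p1, flds$p2, alpha = 1)$gap), 1e-10)
  # nonlinear kinds: Monte Carlo gap exceeds 5 standard errors somewhere
  for (kind in c("nonlinear_rate", "natural_param")) {
    code <- distributional_code(g, kind, n_neurons = 16L, gain = 15, seed = 5)
    gap <- ldc_mixture_gap(code, flds$p1, flds$p2, alpha = 0.5, n_mc = 12000L,
                           seed = 6)
    expect_gt(max(gap$gap / pmax(gap$se, 1e-12)), 5)
  }
})

test_that("random-pair LDC property holds for linear kinds", {
  g <- tiny_grid_2d(9L)
  set.seed(7)
  for (i in 1:5) {
    p1 <- probability_field(g, runif(g$n_cells))
    p2 <- probability_field(g, runif(g$n_cells))
    a <- runif(1)
    for (kind in c("linear_moment", "linear_sampling")) {
      code <- distributional_code(g, kind, n_neurons = 8L, seed = i)
      expect_lt(max(ldc_mixture_gap(code, p1, p2, alpha = a)$gap), 1e-10)
    }
  }
})

test_that("tuning curves expose slopes consistent with the rate map", {
  st <- neurometrics_setup(bins = 21L, n_neurons = 24L, gain = 50, seed = 2)
  tun <- st$tuning
  expect_equal(dim(tun$rates), c(24L, 3L))
  expect_true(all(tun$sigma > 0))
  # chain rule identity for a linear code: f' equals the readout applied to
  # the (noise-averaged) posterior derivative field
  dpds <- dposterior_ds(st$brain, st$exp, delta_s = 1, zero_noise = TRUE)
  fp_field <- st$code$gain * as.numeric(st$code$weights %*% dpds$delta_mass)
  expect_equal(tun$fprime, fp_field, tolerance = 1e-8)
  # constant posterior across s (flat likelihood): flat tuning, zero slope
  gflat <- tiny_grid_2d(11L)
  bflat <- brain_model(gflat, sigma_e2 = 1e8)
  cflat <- distributional_code(gflat, "linear_moment", n_neurons = 8L, seed = 3)
  tflat <- tuning_curve(cflat, bflat, st$exp, s_values = c(-1, 0, 1),
                        zero_noise = TRUE, fprime_delta = 1,
                        n_sd_draws = 200L, seed = 4)
  expect_lt(max(abs(tflat$fprime)), 1e-5)
  expect_lt(max(abs(tflat$rates - tflat$rates[, 1])), 1e-5)
})
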