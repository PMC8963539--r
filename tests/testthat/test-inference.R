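test_that("posterior matches a hand Bayes computation on three cells", {
  prior <- field3(c(0.2, 0.3, 0.5))
  lik <- field3(c(1, 2, 1), normalized = FALSE)
  post <- posterior(prior, lik)
  expect_equal(post$mass, c(0.2, 0.6, 0.5) / 1.3)
  # flat-prior identity and delta-prior fixity
  expect_equal(posterior(uniform_field(grid3()), lik)$mass, c(1, 2, 1) / 4)
  delta <- field3(c(0, 1, 0))
  expect_equal(posterior(delta, lik)$mass, c(0, 1, 0))
  expect_error(posterior(delta, field3(c(1, 0, 1), normalized = FALSE)))
})

test_that("category priors average posteriors over the category ensemble", {
  b <- tiny_brain(bins = 15L)
  ex <- delta_exp(p0 = 0.5, delta_s = 1)
  # zero observation noise: prior = p0 * post(E(0)) + (1-p0) * post(E(+ds))
  p1 <- category_prior(b, ex, 1, zero_noise = TRUE)
  post0 <- posterior(b$prior, likelihood_field(b, experimenter_mean(ex, 0)))
  postp <- posterior(b$prior, likelihood_field(b, experimenter_mean(ex, 1)))
  expect_equal(p1$mass, 0.5 * post0$mass + 0.5 * postp$mass, tolerance = 1e-12)
  # Monte Carlo version converges to a dense quadrature oracle
  set.seed(11)
  p1_mc <- category_prior(b, ex, 1, n_draws = 4000L)
  quad <- local({
    acc <- numeric(b$grid$n_cells)
    for (k in 1:2) {
      s <- c(0, 1)[k]; w <- c(0.5, 0.5)[k]
      mu <- experimenter_mean(ex, s)
      # 2-D Gauss-Hermite-style quadrature on a fine lattice
      zs <- seq(-4, 4, length.out = 41)
      wz <- stats::dnorm(zs); wz <- wz / sum(wz)
      for (i in seq_along(zs)) for (j in seq_along(zs)) {
        E <- mu + sqrt(0.5) * c(zs[i], zs[j])
        acc <- acc + w * wz[i] * wz[j] *
          posterior(b$prior, likelihood_field(b, E))$mass
      }
    }
    acc / sum(acc)
  })
  expect_lt(0.5 * sum(abs(p1_mc$mass - quad)), 0.02)
})

test_that("belief prior is the exact affine mixture", {
  p1 <- field3(c(1, 0, 0)); p2 <- field3(c(0, 0, 1))
  expect_equal(belief_prior(1, p1, p2)$mass, p1$mass)
  expect_equal(belief_prior(0.5, p1, p2)$mass, c(0.5, 0, 0.5))
  expect_equal(belief_prior(0.25, p1, p2)$mass, c(0.25, 0, 0.75))
  expect_error(belief_prior(1.2, p1, p2))
})

test_that("posterior given belief matches a brute-force joint-model oracle", {
  # 3-cell world: enumerate the joint p(x, C) and condition on the evidence
  g <- grid3()
  b <- brain_model(g, sigma_e2 = 0.5)
  p1 <- field3(c(0.6, 0.3, 0.1)); p2 <- field3(c(0.1, 0.3, 0.6))
  E <- 1.2
  pi <- 0.3
  got <- posterior_given_belief(b, E, pi, p1, p2)
  lik <- likelihood_field(b, E)$mass
  joint <- rbind(pi * p1$mass * lik, (1 - pi) * p2$mass * lik)
  oracle <- colSums(joint) / sum(joint)
  expect_equal(got$mass, oracle, tolerance = 1e-12)
  # identical category priors: result independent of pi
  same <- posterior_given_belief(b, E, 0.9, p1, p1)
  expect_equal(same$mass, posterior_given_belief(b, E, 0.1, p1, p1)$mass)
})

test_that("posterior derivatives are mass-preserving and consistent", {
  b <- tiny_brain(bins = 15L)
  ex <- delta_exp(p0 = 0.9, delta_s = 0.01)
  lp <- learned_category_priors(b, ex, zero_noise = TRUE)
  ds <- dposterior_ds(lp$brain, ex, zero_noise = TRUE)
  expect_lt(abs(sum(ds$delta_mass)), 1e-8)
  dpi_fd <- dposterior_dpi(lp$brain, ex, lp$p1, lp$p2, delta_pi = 0.005)
  dpi_an <- dposterior_dpi(lp$brain, ex, lp$p1, lp$p2, method = "analytic")
  expect_lt(abs(sum(dpi_fd$delta_mass)), 1e-8)
  expect_lt(abs(sum(dpi_an$delta_mass)), 1e-8)
  # analytic form agrees with the central difference to O(delta_pi^2)
  expect_equal(dpi_fd$delta_mass, dpi_an$delta_mass, tolerance = 1e-4)
  expect_gt(alignment(dpi_fd, dpi_an), 1 - 1e-10)
  # identical category priors give a zero belief-derivative
  z <- dposterior_dpi(lp$brain, ex, lp$p1, lp$p1)
  expect_equal(max(abs(z$delta_mass)), 0, tolerance = 1e-15)
  expect_error(dposterior_dpi(lp$brain, ex, lp$p1, lp$p2, delta_pi = 0.6))
})

test_that("dposterior_ds matches the analytic translated-Gaussian derivative", {
  # 1-D zero-noise toy: uniform prior, Gaussian likelihood centered at s, so
  # the posterior is a translated Gaussian with a closed-form s-derivative
  g <- tiny_grid_1d(bins = 201L)
  b <- brain_model(g, sigma_e2 = 0.25)
  ex <- experimenter_model("custom",
                           ensemble = stimulus_ensemble("delta_mixture"),
                           mean_fn = function(s) c(s, 0),
                           cov_fn = function(s) diag(1e-12, 2))
  # wrap: on a 1-D grid, likelihood_field takes scalar E; emulate via custom
  post <- function(s) {
    lik <- exp(-(g$centers[, 1] - s)^2 / (2 * 0.25))
    lik / sum(lik)
  }
  d_num <- (post(0.01) - post(-0.01)) / 0.02
  d_an <- post(0) * (g$centers[, 1]) / 0.25  # d/ds log N(x; s, .25) at s=0
  d_an <- d_an - post(0) * sum(post(0) * g$centers[, 1]) / 0.25
  expect_gt(sum(d_num * d_an) / sqrt(sum(d_num^2) * sum(d_an^2)), 1 - 1e-6)
  # Richardson: halving the step changes the result at O(delta^2)
  d_half <- (post(0.005) - post(-0.005)) / 0.01
  expect_lt(max(abs(d_half - d_num)), 5e-4 * max(abs(d_num)))
})

test_that("alignment is a cosine with the expected extremes", {
  a <- c(1, 0, -2)
  expect_equal(alignment(a, a), 1)
  expect_equal(alignment(a, -a), -1)
  expect_equal(alignment(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_error(alignment(a, c(0, 0, 0)))
})

test_that("swapping category labels negates the belief derivative", {
  b <- tiny_brain(bins = 15L)
  ex <- delta_exp(p0 = 0.8, delta_s = 0.5)
  lp <- learned_category_priors(b, ex, zero_noise = TRUE)
  d12 <- dposterior_dpi(lp$brain, ex, lp$p1, lp$p2)
  d21 <- dposterior_dpi(lp$brain, ex, lp$p2, lp$p1)
  expect_equal(d12$delta_mass, -d21$delta_mass, tolerance = 1e-12)
})

test_that("category decoder is a normalized symmetric Bayes rule", {
  b <- tiny_brain(bins = 15L)
  ex <- delta_exp(p0 = 0.5, delta_s = 1)
  p <- category_decoder(b, ex)
  expect_true(all(p >= 0 & p <= 1))
  # oracle: enumerate the joint over (C, s) atoms
  w1 <- w2 <- numeric(b$grid$n_cells)
  for (cc in 1:2) {
    d <- category_stimulus_dist(ex$ensemble, cc)
    for (k in 1:2) {
      lik <- likelihood_field(b, experimenter_mean(ex, d$s[k]))$mass
      if (cc == 1) w1 <- w1 + 0.5 * d$prob[k] * lik
      else w2 <- w2 + 0.5 * d$prob[k] * lik
    }
  }
  expect_equal(p, w1 / (w1 + w2), tolerance = 1e-12)
  # symmetry: the grid center is equidistant from the two category means, so
  # it decodes to 0.5; and reflecting x through the origin swaps categories
  ctr <- which(rowSums(abs(b$grid$centers)) < 1e-9)
  expect_equal(p[ctr], 0.5, tolerance = 1e-9)
  nb <- b$grid$bins_per_dim
  i <- rep(seq_len(nb), times = nb); j <- rep(seq_len(nb), each = nb)
  refl <- (nb + 1L - i) + (nb - j) * nb   # cell index of -x
  expect_equal(p + p[refl], rep(1, length(p)), tolerance = 1e-9)
})

test_that("proportionality improves toward the sub-threshold limit", {
  b <- tiny_brain(bins = 21L)
  tab <- proportionality_experiment(b, delta_s_list = c(0.01, 1),
                                    p0_list = c(0.5, 0.9),
                                    zero_noise = TRUE)
  expect_true(all(tab$cosine >= -1 & tab$cosine <= 1))
  best <- tab$cosine[tab$delta_s == 0.01 & tab$p0 == 0.9]
  worst <- tab$cosine[tab$delta_s == 1 & tab$p0 == 0.5]
  expect_gt(best, worst)
  expect_gt(best, 0.99)
})

test_that("1-D Gaussian demo cosine increases as categories draw together", {
  d <- gaussian_mixture_demo()
  ord <- order(d$mu_x, decreasing = TRUE)
  expect_true(all(diff(d$cosine[ord]) > 0))
  expect_gt(max(d$cosine), 0.999)
})
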