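test_that("learning schedule follows the halving rule", {
  sch <- learning_schedule()
  expect_equal(sch$n_iterations, 300L)
  expect_equal(sch$initial_step, 100)
  expect_equal(sch$lambda_entropy, 0.001)
  expect_equal(schedule_step(sch, 1), 100)
  expect_equal(schedule_step(sch, 100), 100)
  expect_equal(schedule_step(sch, 101), 50)
  expect_equal(schedule_step(sch, 300), 25)
})

test_that("loss is zero when the brain matches the experimenter exactly", {
  # realizable target: a single fixed E-distribution the grid can express.
  # Custom experimenter: E ~ N(0, (sigma_E^2 + sigma_x^2) I) equals the
  # brain's marginal when the prior is the matching discretized Gaussian.
  g <- latent_grid(2L, c(-5, 5), 41L)
  sigma_e2 <- 0.36; sigma_x2 <- 1
  ex <- experimenter_model("custom",
                           ensemble = stimulus_ensemble("uniform"),
                           mean_fn = function(s) c(0, 0),
                           cov_fn = function(s) diag(sigma_e2 + sigma_x2, 2))
  pr <- exp(-rowSums(g$centers^2) / (2 * sigma_x2))
  brain <- set_prior(brain_model(g, sigma_e2), probability_field(g, pr))
  set.seed(9)
  ll <- learning_loss(brain, ex, lambda = 0, n_draws = 4000L)
  expect_lt(abs(ll$kl), 0.01)   # zero up to discretization + MC error
  # entropy term of a uniform prior contributes -lambda * log(n_cells)
  bu <- brain_model(g, sigma_e2)
  l2 <- learning_loss(bu, ex, lambda = 0.5, E = matrix(rnorm(20), 10, 2))
  l0 <- learning_loss(bu, ex, lambda = 0, E = matrix(rnorm(20), 10, 2))
  expect_equal(l2$entropy, log(g$n_cells))
})

test_that("analytic gradient matches numerical differentiation of the loss", {
  g <- latent_grid(2L, c(-5, 5), 5L)
  brain <- brain_model(g, 0.36)
  set.seed(3)
  pr <- probability_field(g, runif(g$n_cells) + 0.2)
  brain <- set_prior(brain, pr)
  ex <- experimenter_model("mean_coded")
  st <- sample_stimuli(ex$ensemble, 200, seed = 4)
  E <- beliefcov:::draw_observations(ex, st$s)
  lambda <- 0.01
  ga <- grad_logprior(brain, ex, lambda = lambda, E = E)
  th <- log(pr$mass); h <- 1e-5
  gn <- vapply(seq_along(th), function(k) {
    tp <- th; tp[k] <- th[k] + h
    tm <- th; tm[k] <- th[k] - h
    (learning_loss_logmass(brain, ex, tp, lambda, E) -
       learning_loss_logmass(brain, ex, tm, lambda, E)) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(ga - gn)) / max(abs(gn)), 1e-4)
})

test_that("at self-consistency with lambda 0 the unconstrained gradient is -prior", {
  # a flat likelihood makes every posterior equal the prior, so any prior is
  # a self-consistent fixed point and the KL gradient reduces to -prior
  g <- latent_grid(2L, c(-5, 5), 9L)
  brain <- brain_model(g, sigma_e2 = 1e8)
  set.seed(5)
  pr <- probability_field(g, runif(g$n_cells) + 0.1)
  brain <- set_prior(brain, pr)
  ex <- experimenter_model("mean_coded")
  E <- matrix(c(0.1, -0.3, 1.2, 0.4), 2, 2)
  g31 <- grad_logprior(brain, ex, lambda = 0, E = E)
  expect_equal(g31, -pr$mass, tolerance = 1e-6)
})

test_that("prior learning reduces KL and tightens self-consistency", {
  fx <- make_fixture("tiny", "mean_coded", "imprecise", seed = 2)
  sch <- fx$schedule
  sch$n_iterations <- 120L
  fit <- learn_prior(fx$brain, fx$exp, sch, track_kl = TRUE, track_tv = TRUE)
  expect_s3_class(fit, "prior_fit")
  expect_lt(fit$trace$kl[120], fit$trace$kl[1])
  expect_lt(fit$trace$sc_tv[120], fit$trace$sc_tv[1])
  expect_equal(sum(fit$prior$mass), 1, tolerance = 1e-10)
  expect_true(all(fit$prior$mass >= 0))
  # zero-iteration schedule is a no-op on the uniform prior
  sch0 <- fx$schedule; sch0$n_iterations <- 0L
  fit0 <- learn_prior(fx$brain, fx$exp, sch0)
  expect_equal(fit0$prior$mass, fx$brain$prior$mass)
})

test_that("learning recovers a realizable evidence distribution", {
  # target p_e(E) = N(0, (sigma_x^2 + sigma_E^2) I) is exactly expressible by
  # a Gaussian prior on the grid; after learning, p_b(E) should match in
  # total variation on a probe sample
  g <- latent_grid(2L, c(-5, 5), 21L)
  sigma_e2 <- 0.36
  ex <- experimenter_model("custom",
                           ensemble = stimulus_ensemble("uniform"),
                           mean_fn = function(s) c(0, 0),
                           cov_fn = function(s) diag(sigma_e2 + 1, 2))
  brain <- brain_model(g, sigma_e2)
  # large-draw regime: heavier batches and an extra step-halving so the
  # stochastic-gradient jitter settles
  sch <- learning_schedule(n_iterations = 500L, draws_per_iteration = 2000L,
                           seed = 3)
  fit <- learn_prior(brain, ex, sch, track_kl = FALSE)
  # compare p_b(E) to p_e(E) on a grid of probe points by relative density
  probes <- as.matrix(expand.grid(seq(-2, 2, 0.5), seq(-2, 2, 0.5)))
  pb <- beliefcov:::marginal_evidence(fit$brain, probes)
  pe <- beliefcov:::experimenter_density(ex, probes)
  # normalized over probe set, total-variation style discrepancy
  expect_lt(0.5 * sum(abs(pb / sum(pb) - pe / sum(pe))), 0.05)
})

test_that("learned prior concentrates along the cubic mean curve", {
  fx <- make_fixture("tiny", "mean_coded", "imprecise", seed = 4)
  fit <- learn_prior(fx$brain, fx$exp, fx$schedule, track_kl = FALSE)
  ctr <- fx$grid$centers
  d_curve <- abs(ctr[, 2] - (ctr[, 1] + ctr[, 1]^3) / 10)
  on_curve <- d_curve < 0.75 & abs(ctr[, 1]) < 3
  frac_mass <- sum(fit$prior$mass[on_curve])
  expect_gt(frac_mass / mean(on_curve), 3)  # strong enrichment vs uniform
})
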