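# shared setup for the decision-statistics tests (moderate size for speed)
nm <- NULL
get_nm <- function() {
  if (is.null(nm)) nm <<- neurometrics_setup(bins = 31L, n_neurons = 32L,
                                             gain = 300, seed = 1)
  nm
}

test_that("sessions respect the belief/choice bookkeeping", {
  st <- get_nm()
  tr <- simulate_session(st$brain, st$exp, st$code, st$p1, st$p2,
                         var_pi = 0.02, n_trials = 2000L, seed = 2)
  expect_equal(dim(tr$response), c(2000L, 32L))
  expect_true(all(tr$response >= 0))
  expect_true(all(tr$choice[tr$pi > 0.5] == 1L))
  expect_true(all(tr$choice[tr$pi < 0.5] == 2L))
  # symmetric beliefs give near-50/50 choices
  expect_lt(abs(mean(tr$choice == 1L) - 0.5), 3 * sqrt(0.25 / 2000))
  # var_pi = 0: all beliefs exactly 1/2, tie-broken choices ~ 50/50
  tr0 <- simulate_session(st$brain, st$exp, st$code, st$p1, st$p2,
                          var_pi = 0, n_trials = 2000L, seed = 3)
  expect_true(all(tr0$pi == 0.5))
  expect_lt(abs(mean(tr0$choice == 1L) - 0.5), 3 * sqrt(0.25 / 2000))
  # mean response matches the boundary tuning within Monte Carlo error
  f0 <- st$tuning$rates[, st$tuning$s_values == 0]
  se <- apply(tr0$response, 2L, stats::sd) / sqrt(2000)
  expect_true(all(abs(colMeans(tr0$response) - f0) < 5 * se + 0.05 * f0))
})

test_that("CTA is zero without belief variability and tracks f' with it", {
  st <- get_nm()
  tr0 <- simulate_session(st$brain, st$exp, st$code, st$p1, st$p2,
                          var_pi = 0, n_trials = 4000L, seed = 4)
  ct0 <- cta(tr0)
  se <- apply(tr0$response, 2L, stats::sd) * sqrt(4 / 4000)
  expect_true(all(abs(ct0) < 4 * se))
  tr <- simulate_session(st$brain, st$exp, st$code, st$p1, st$p2,
                         var_pi = 0.02, n_trials = 10000L, seed = 5)
  ct <- cta(tr)
  fp <- st$tuning$fprime
  expect_gt(sum(ct * fp) / sqrt(sum(ct^2) * sum(fp^2)), 0.9)
  # relabeling choices negates the CTA
  tr_sw <- tr
  tr_sw$choice <- 3L - tr$choice
  expect_equal(cta(tr_sw), -ct)
})

test_that("choice probability equals the pairwise-comparison oracle", {
  set.seed(6)
  n <- 120L
  trials <- structure(list(
    response = cbind(rpois(n, 6), rpois(n, 3) + rep(0:1, each = n / 2) * 2),
    choice = rep(c(2L, 1L), each = n / 2), pi = rep(c(0.4, 0.6), each = n / 2),
    var_pi = 0.01, code_kind = "linear_moment", s = numeric(n), seed = 6L),
    class = "trial_set")
  cp <- choice_probability(trials)
  oracle <- apply(trials$response, 2L, function(x) {
    x1 <- x[trials$choice == 1L]; x2 <- x[trials$choice == 2L]
    cnt <- 0
    for (a in x1) cnt <- cnt + sum(a > x2) + 0.5 * sum(a == x2)
    cnt / (length(x1) * length(x2))
  })
  expect_equal(cp, oracle, tolerance = 1e-12)
  # perfect separation gives CP 1, independence gives about 1/2
  perfect <- trials
  perfect$response[, 1] <- ifelse(perfect$choice == 1L, 10, 0)
  expect_equal(choice_probability(perfect)[1], 1)
  # CP is invariant under monotone response transforms
  tr2 <- trials
  tr2$response <- sqrt(trials$response + 1)
  expect_equal(choice_probability(tr2), cp)
})

test_that("d-prime has the sign of f' and errors on zero sigma", {
  st <- get_nm()
  dp <- dprime_vector(st$tuning)
  expect_equal(sign(dp), sign(st$tuning$fprime))
  bad <- st$tuning
  bad$sigma[1] <- 0
  expect_error(dprime_vector(bad))
})

test_that("CP relates to d-prime under belief feedback and not without", {
  st <- get_nm()
  tr <- simulate_session(st$brain, st$exp, st$code, st$p1, st$p2,
                         var_pi = 0.02, n_trials = 10000L, seed = 7)
  r <- cp_dprime_relation(tr, st$tuning)
  expect_gt(r, 0.9)
  tr0 <- simulate_session(st$brain, st$exp, st$code, st$p1, st$p2,
                          var_pi = 0, n_trials = 10000L, seed = 8)
  r0 <- cp_dprime_relation(tr0, st$tuning)
  # no belief signal: correlation consistent with 0 (|r| below ~4/sqrt(n-3))
  expect_lt(abs(r0), 4 / sqrt(32 - 3))
})

test_that("covariance decomposition isolates the rank-1 belief component", {
  st <- get_nm()
  tw <- simulate_session(st$brain, st$exp, st$code, st$p1, st$p2,
                         var_pi = 0.01, n_trials = 20000L, seed = 9)
  tw0 <- simulate_session(st$brain, st$exp, st$code, st$p1, st$p2,
                          var_pi = 0, n_trials = 20000L, seed = 10)
  cd <- covariance_decomposition(tw, tw0, st$tuning)
  expect_equal(cd$sigma_belief, cd$sigma_total - cd$sigma_intrinsic)
  expect_gt(abs(cd$alignment), 0.99)
  # leading eigenvalue scales linearly with var(pi)
  tw4 <- simulate_session(st$brain, st$exp, st$code, st$p1, st$p2,
                          var_pi = 0.04, n_trials = 20000L, seed = 11)
  cd4 <- covariance_decomposition(tw4, tw0, st$tuning)
  expect_gt(cd4$top_eigenvalue / cd$top_eigenvalue, 3)
  expect_lt(cd4$top_eigenvalue / cd$top_eigenvalue, 5)
  # both sessions belief-free: belief component at the noise floor
  tw0b <- simulate_session(st$brain, st$exp, st$code, st$p1, st$p2,
                           var_pi = 0, n_trials = 20000L, seed = 12)
  cd0 <- covariance_decomposition(tw0b, tw0, st$tuning)
  expect_lt(norm(cd0$sigma_belief, "F") / norm(cd$sigma_belief, "F"), 0.5)
})

test_that("variance along f' grows monotonically with belief variance", {
  st <- get_nm()
  fp <- st$tuning$fprime
  u <- fp / sqrt(sum(fp^2))
  fracs <- vapply(c(0, 0.01, 0.04, 0.09), function(v) {
    tr <- simulate_session(st$brain, st$exp, st$code, st$p1, st$p2,
                           var_pi = v, n_trials = 8000L, seed = 13)
    S <- stats::cov(tr$response)
    as.numeric(u %*% S %*% u) / sum(diag(S))
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})
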