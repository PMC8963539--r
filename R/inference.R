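#' Posterior field from a prior and a likelihood
#'
#' Pointwise product of prior mass and likelihood mass, renormalized:
#' p(x | E) proportional to p(E | x) p(x).
#'
#' @param prior Normalized \code{probability_field}.
#' @param lik \code{probability_field} of likelihood values (unnormalized).
#' @return Normalized \code{probability_field}.
#' @export
posterior <- function(prior, lik) {
  stopifnot(same_grid(prior$grid, lik$grid))
  m <- prior$mass * lik$mass
  if (sum(m) <= 0) stop("impossible evidence: prior and likelihood have disjoint support")
  probability_field(prior$grid, m, normalized = TRUE)
}

# Column-normalized posteriors for a batch of observations.
# Returns n_cells x n_obs matrix; each column is a normalized posterior.
posterior_matrix <- function(brain, E) {
  L <- likelihood_matrix(brain, E)
  P <- L * brain$prior$mass
  tot <- colSums(P)
  if (any(tot <= 0)) stop("impossible evidence in posterior batch")
  P / rep(tot, each = nrow(P))
}

# Average normalized posterior over a batch of observations without
# materializing the normalized matrix (single GEMV on the unnormalized one).
average_posterior <- function(brain, E) {
  L <- likelihood_matrix(brain, E)
  P <- L * brain$prior$mass
  tot <- colSums(P)
  if (any(tot <= 0)) stop("impossible evidence in posterior batch")
  as.numeric(P %*% (1 / tot)) / ncol(P)
}

#' Self-consistent per-category prior (average posterior)
#'
#' Monte Carlo estimate of E_{p_e(s | C = c)} E_{p_e(E | s)} [ p_b(x | E) ]:
#' the optimal prior over x given the category is the average posterior over
#' stimuli of that category, the self-consistency rule of a learned model.
#'
#' @param brain A \code{brain_model} (its current prior is used inside each
#'   posterior).
#' @param exp An \code{experimenter_model} whose ensemble is a delta mixture.
#' @param category 1 or 2.
#' @param n_draws Monte Carlo draws of E per distinct stimulus value; with
#'   \code{zero_noise = TRUE} the expectation over s is exact quadrature and
#'   no E noise is drawn.
#' @param seed Optional integer seed.
#' @param zero_noise If \code{TRUE}, observations are the noiseless means
#'   E = mean(s) (the sub-threshold proof regime).
#' @return Normalized \code{probability_field}.
#' @export
category_prior <- function(brain, exp, category, n_draws = 1000L, seed = NULL,
                           zero_noise = FALSE) {
  dist <- category_stimulus_dist(exp$ensemble, category)
  if (!is.null(seed)) set.seed(seed)
  acc <- numeric(brain$grid$n_cells)
  for (k in seq_len(nrow(dist))) {
    s <- dist$s[k]; w <- dist$prob[k]
    if (w == 0) next
    if (zero_noise) {
      E <- matrix(experimenter_mean(exp, s), nrow = 1L)
    } else {
      E <- draw_observations(exp, rep(s, n_draws))
    }
    acc <- acc + w * average_posterior(brain, E)
  }
  probability_field(brain$grid, acc, normalized = TRUE)
}

#' Belief-weighted mixture prior
#'
#' The expectation over x given a graded belief pi = p_b(C = 1 | ...) is the
#' mixture pi * p(x | C = 1) + (1 - pi) * p(x | C = 2).
#'
#' @param pi Scalar belief in [0, 1].
#' @param p1,p2 Normalized per-category priors on a shared grid.
#' @return Normalized \code{probability_field}.
#' @export
belief_prior <- function(pi, p1, p2) {
  if (pi < 0 || pi > 1) stop("pi must lie in [0, 1]")
  stopifnot(same_grid(p1$grid, p2$grid))
  probability_field(p1$grid, pi * p1$mass + (1 - pi) * p2$mass, normalized = TRUE)
}

#' Posterior conditioned on an observation and a belief
#'
#' p_b(x | E, pi) proportional to p_b(E | x) [pi p(x|C=1) + (1-pi) p(x|C=2)].
#'
#' @param brain A \code{brain_model}.
#' @param E Observation vector.
#' @param pi Belief in [0, 1].
#' @param p1,p2 Per-category priors (see \code{\link{category_prior}}).
#' @return Normalized \code{probability_field}.
#' @export
posterior_given_belief <- function(brain, E, pi, p1, p2) {
  posterior(belief_prior(pi, p1, p2), likelihood_field(brain, E))
}

#' Finite-difference derivative of the posterior with respect to s
#'
#' Central difference of the noise-averaged posterior at s = +/- delta_s,
#' ((mean posterior at +delta_s) - (mean posterior at -delta_s)) / (2 delta_s),
#' under the brain's current prior (the marginal prior, appropriate at the
#' category boundary where pi = 1/2 and categories are equiprobable).
#'
#' @param brain A \code{brain_model}.
#' @param exp An \code{experimenter_model}.
#' @param delta_s Step size (default 0.01).
#' @param n_draws Observation draws per side.
#' @param seed Optional integer seed.
#' @param zero_noise If \code{TRUE}, use the noiseless E = mean(s).
#' @param E_noise Optional precomputed n_draws x 2 matrix of zero-mean noise
#'   deviations shared between the two sides (variance reduction).
#' @return List of class \code{posterior_derivative} with \code{grid},
#'   \code{delta_mass} (sums to 0), \code{wrt = "s"}, \code{step}.
#' @export
dposterior_ds <- function(brain, exp, delta_s = 0.01, n_draws = 1000L,
                          seed = NULL, zero_noise = FALSE, E_noise = NULL) {
  stopifnot(delta_s > 0)
  if (!is.null(seed)) set.seed(seed)
  avg_post <- function(s) {
    if (zero_noise) {
      E <- matrix(experimenter_mean(exp, s), nrow = 1L)
    } else if (!is.null(E_noise)) {
      mu <- experimenter_mean(exp, s)
      L <- chol(experimenter_cov(exp, s))
      E <- sweep(E_noise %*% L, 2L, mu, "+")
    } else {
      E <- draw_observations(exp, rep(s, n_draws))
    }
    average_posterior(brain, E)
  }
  d <- (avg_post(delta_s) - avg_post(-delta_s)) / (2 * delta_s)
  structure(list(grid = brain$grid, delta_mass = d, wrt = "s", step = delta_s),
            class = "posterior_derivative")
}

#' @export
print.posterior_derivative <- function(x, ...) {
  cat(sprintf("posterior_derivative wrt %s (step %g), norm %.4g, sum %.2e\n",
              x$wrt, x$step, sqrt(sum(x$delta_mass^2)), sum(x$delta_mass)))
  invisible(x)
}

#' Derivative of the posterior with respect to the belief pi
#'
#' Central finite difference of \code{posterior_given_belief} around
#' pi = 1/2 at a fixed observation (default the zero-signal mean E(0)), or
#' the analytic form: the derivative equals the likelihood-weighted
#' difference of category priors, lik(E) * (p1 - p2) / Z(E), with
#' Z(E) = sum_x lik(E) * mixture prior.
#'
#' @param brain A \code{brain_model}.
#' @param exp An \code{experimenter_model}.
#' @param p1,p2 Per-category priors.
#' @param E Observation at which to evaluate (default the noiseless E(0)).
#' @param delta_pi Finite-difference step (default 0.01); must keep
#'   1/2 +/- delta_pi inside [0, 1].
#' @param method \code{"finite_diff"} or \code{"analytic"}.
#' @return A \code{posterior_derivative} with \code{wrt = "pi"}.
#' @export
dposterior_dpi <- function(brain, exp, p1, p2, E = NULL, delta_pi = 0.01,
                           method = c("finite_diff", "analytic")) {
  method <- match.arg(method)
  stopifnot(delta_pi > 0)
  if (0.5 + delta_pi > 1 || 0.5 - delta_pi < 0)
    stop("pi +/- delta_pi must remain inside [0, 1]")
  if (is.null(E)) E <- experimenter_mean(exp, 0)
  if (method == "finite_diff") {
    hi <- posterior_given_belief(brain, E, 0.5 + delta_pi, p1, p2)
    lo <- posterior_given_belief(brain, E, 0.5 - delta_pi, p1, p2)
    d <- (hi$mass - lo$mass) / (2 * delta_pi)
  } else {
    lik <- likelihood_field(brain, E)$mass
    mix <- 0.5 * p1$mass + 0.5 * p2$mass
    z <- sum(lik * mix)
    num <- lik * (p1$mass - p2$mass)
    # quotient rule for d/dpi [lik * prior(pi) / Z(pi)] at pi = 1/2
    dz <- sum(num)
    d <- num / z - (lik * mix / z) * (dz / z)
  }
  structure(list(grid = brain$grid, delta_mass = d, wrt = "pi", step = delta_pi),
            class = "posterior_derivative")
}

#' Cosine alignment of two posterior derivatives
#'
#' Cosine similarity between the two delta-mass vectors; the numerical
#' reading of the "approximately proportional" relation between stimulus- and
#' belief-driven changes in the posterior.
#'
#' @param a,b \code{posterior_derivative}s (or plain numeric vectors) on the
#'   same grid.
#' @return Scalar in [-1, 1].
#' @export
alignment <- function(a, b) {
  va <- if (inherits(a, "posterior_derivative")) a$delta_mass else as.numeric(a)
  vb <- if (inherits(b, "posterior_derivative")) b$delta_mass else as.numeric(b)
  stopifnot(length(va) == length(vb))
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) stop("alignment undefined for a zero vector")
  sum(va * vb) / (na * nb)
}

#' Self-consistent category priors by fixed-point iteration
#'
#' Iterates the self-consistency rule "prior = average posterior": starting
#' from the brain's current prior, repeatedly sets the marginal prior to the
#' category-weighted average of the per-category average posteriors until the
#' total-variation change falls below \code{tol}. The returned per-category
#' priors and marginal prior are mutually consistent, which the
#' belief-derivative identity requires. (Each iteration is one
#' multiplicative Richardson-Lucy-type update of the prior.)
#'
#' @param brain A \code{brain_model} providing the starting prior.
#' @param exp An \code{experimenter_model} with a delta-mixture ensemble.
#' @param n_iter Maximum fixed-point iterations.
#' @param tol Total-variation convergence tolerance.
#' @param n_draws,zero_noise,seed Passed to \code{\link{category_prior}}; with
#'   \code{zero_noise = TRUE} every iteration reuses the exact noiseless
#'   observations so the fixed point is deterministic.
#' @return List with normalized fields \code{p1}, \code{p2}, \code{marginal},
#'   the updated \code{brain}, and \code{iterations} used.
#' @export
learned_category_priors <- function(brain, exp, n_iter = 25L, tol = 1e-10,
                                    n_draws = 1000L, zero_noise = TRUE,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p_cat <- exp$ensemble$p_cat
  p1 <- p2 <- NULL
  for (it in seq_len(n_iter)) {
    p1 <- category_prior(brain, exp, 1, n_draws = n_draws, zero_noise = zero_noise)
    p2 <- category_prior(brain, exp, 2, n_draws = n_draws, zero_noise = zero_noise)
    marg <- probability_field(brain$grid, p_cat[1] * p1$mass + p_cat[2] * p2$mass)
    delta <- field_tv(marg, brain$prior)
    brain <- set_prior(brain, marg)
    if (delta < tol) break
  }
  list(p1 = p1, p2 = p2, marginal = brain$prior, brain = brain, iterations = it)
}

#' Stimulus-belief proportionality experiment
#'
#' For each (delta_s, p0) pair, builds the delta-mixture ensemble, forms the
#' self-consistent category priors, and measures the cosine alignment between
#' the finite-difference posterior derivatives with respect to s and pi at
#' the zero-signal observation. In the sub-threshold limit (small delta_s,
#' p0 near 1) the cosine approaches 1.
#'
#' @param brain A \code{brain_model}.
#' @param delta_s_list,p0_list Numeric vectors of sweep values.
#' @param coding Experimenter coding mode.
#' @param n_draws Observation draws for the noise-averaged quantities
#'   (ignored when \code{zero_noise}).
#' @param zero_noise If \code{TRUE} (default), run in the noiseless proof
#'   regime.
#' @param seed Optional integer seed.
#' @return data.frame with columns \code{delta_s}, \code{p0}, \code{cosine}.
#' @export
proportionality_experiment <- function(brain, delta_s_list = c(0.01, 0.1, 0.5, 1),
                                       p0_list = c(0.5, 0.9, 0.99),
                                       coding = "mean_coded",
                                       n_draws = 500L, zero_noise = TRUE,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- expand.grid(delta_s = delta_s_list, p0 = p0_list,
                     KEEP.OUT.ATTRS = FALSE)
  out$cosine <- NA_real_
  for (i in seq_len(nrow(out))) {
    ens <- stimulus_ensemble("delta_mixture", p0 = out$p0[i],
                             delta_s = out$delta_s[i])
    exp <- experimenter_model(coding = coding, ensemble = ens)
    lp <- learned_category_priors(brain, exp, n_draws = n_draws,
                                  zero_noise = zero_noise)
    b <- lp$brain
    ds <- dposterior_ds(b, exp, delta_s = out$delta_s[i], n_draws = n_draws,
                        zero_noise = zero_noise)
    dpi <- dposterior_dpi(b, exp, lp$p1, lp$p2, delta_pi = 0.01)
    out$cosine[i] <- alignment(ds, dpi)
  }
  out
}

#' Category decoder p_b(C = 1 | x)
#'
#' Posterior probability of category 1 at each grid cell, from the joint
#' of (C, s, E) under the experimenter's ensemble and the brain's
#' likelihood: quadrature over the ensemble's support of
#' p_e(C | s) p_b(E(s) | x), normalized over C per cell.
#'
#' @param brain A \code{brain_model}.
#' @param exp An \code{experimenter_model} with a delta-mixture ensemble.
#' @return Numeric vector of p(C = 1 | x) per cell, in [0, 1].
#' @export
category_decoder <- function(brain, exp) {
  ens <- exp$ensemble
  stopifnot(ens$kind == "delta_mixture")
  w1 <- numeric(brain$grid$n_cells)
  w2 <- numeric(brain$grid$n_cells)
  for (c in 1:2) {
    dist <- category_stimulus_dist(ens, c)
    for (k in seq_len(nrow(dist))) {
      E <- experimenter_mean(exp, dist$s[k])
      lik <- likelihood_field(brain, E)$mass
      contrib <- ens$p_cat[c] * dist$prob[k] * lik
      if (c == 1) w1 <- w1 + contrib else w2 <- w2 + contrib
    }
  }
  tot <- w1 + w2
  tot[tot == 0] <- 1  # cells with no evidence mass: defined as 0.5 below
  p <- w1 / tot
  p[(w1 + w2) == 0] <- 0.5
  p
}

#' One-dimensional Gaussian-mixture demonstration of the proportionality limit
#'
#' A scalar latent x is drawn from N(+/- mu_x, sigma_x^2) depending on the
#' category, and the stimulus observation is Gaussian around x. The prior on
#' x is the two-component mixture; posterior derivatives with respect to the
#' observation and the belief are compared on a 1-D grid. The cosine
#' approaches 1 as mu_x approaches 0 (categories drawing together).
#'
#' @param mu_x_values Category offsets to sweep.
#' @param sigma_x SD of x around its category mean.
#' @param sigma_s SD of the observation around x.
#' @param bins,bounds 1-D grid settings.
#' @param delta_s Finite-difference step for the observation derivative.
#' @return data.frame with columns \code{mu_x} and \code{cosine}.
#' @export
gaussian_mixture_demo <- function(mu_x_values = c(3, 2, 1, 0.5, 0.25),
                                  sigma_x = 1, sigma_s = 0.5,
                                  bins = 401L, bounds = c(-8, 8),
                                  delta_s = 0.01) {
  grid <- latent_grid(1L, bounds, bins)
  xc <- grid$axis
  out <- data.frame(mu_x = mu_x_values, cosine = NA_real_)
  for (i in seq_along(mu_x_values)) {
    mu <- mu_x_values[i]
    p1 <- stats::dnorm(xc, +mu, sigma_x)  # category 1: x > 0 side
    p2 <- stats::dnorm(xc, -mu, sigma_x)
    p1 <- p1 / sum(p1); p2 <- p2 / sum(p2)
    prior <- 0.5 * p1 + 0.5 * p2
    post <- function(s) {
      m <- prior * stats::dnorm(s, xc, sigma_s)
      m / sum(m)
    }
    dps <- (post(delta_s) - post(-delta_s)) / (2 * delta_s)
    # analytic d/dpi at s = 0: lik * (p1 - p2), normalization-corrected
    lik <- stats::dnorm(0, xc, sigma_s)
    z <- sum(lik * prior)
    num <- lik * (p1 - p2)
    dppi <- num / z - (lik * prior / z) * (sum(num) / z)
    out$cosine[i] <- sum(dps * dppi) / sqrt(sum(dps^2) * sum(dppi^2))
  }
  out
}
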