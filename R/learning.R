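#' Gradient-descent schedule for prior learning
#'
#' Holds the optimization settings used by \code{\link{learn_prior}}: 300
#' iterations starting at step size 100, halved every 100 iterations, with
#' entropy regularization weight lambda = 0.001 and a fresh batch of
#' stimulus/observation draws per iteration.
#'
#' @param n_iterations Total gradient steps (default 300).
#' @param initial_step Initial step size (default 100).
#' @param halving_period Iterations between step halvings (default 100).
#' @param lambda_entropy Entropy-regularization weight (default 0.001).
#' @param draws_per_iteration Observations drawn per iteration to estimate the
#'   average posterior (default 1000).
#' @param seed Integer seed for the per-iteration draw stream.
#' @return An object of class \code{learning_schedule}.
#' @export
learning_schedule <- function(n_iterations = 300L, initial_step = 100,
                              halving_period = 100L, lambda_entropy = 0.001,
                              draws_per_iteration = 1000L, seed = 1L) {
  stopifnot(n_iterations >= 0, initial_step > 0, halving_period > 0,
            lambda_entropy >= 0, draws_per_iteration >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 initial_step = initial_step,
                 halving_period = as.integer(halving_period),
                 lambda_entropy = lambda_entropy,
                 draws_per_iteration = as.integer(draws_per_iteration),
                 seed = as.integer(seed)),
            class = "learning_schedule")
}

#' @export
print.learning_schedule <- function(x, ...) {
  cat(sprintf(
    "learning_schedule: %d iterations, step %g halved every %d, lambda = %g, %d draws/iter\n",
    x$n_iterations, x$initial_step, x$halving_period, x$lambda_entropy,
    x$draws_per_iteration))
  invisible(x)
}

#' Step size at iteration t (1-based)
#' @param schedule A \code{learning_schedule}.
#' @param t Iteration index (1-based).
#' @return Scalar step size initial_step / 2^floor((t - 1) / halving_period).
#' @export
schedule_step <- function(schedule, t) {
  schedule$initial_step / 2^floor((t - 1) / schedule$halving_period)
}

# Marginal likelihood of each observation under the brain's model:
# p_b(E_j) = sum_x prior_x * p_b(E_j | x). Mass convention: likelihood_matrix
# already contains the cell measure, so this approximates the density
# integral; we divide the measure back out to get a density in E.
marginal_evidence <- function(brain, E) {
  L <- likelihood_matrix(brain, E)
  as.numeric(crossprod(L, brain$prior$mass)) / brain$grid$cell_measure
}

# Density of E under the experimenter model at a matrix of observation/stimulus
# pairs (densities needed for the KL estimate; the stimulus integral is
# estimated by the pairing of each E with its own s plus optional extra
# quadrature over s).
experimenter_density <- function(exp, E, s_quad = 101L) {
  ens <- exp$ensemble
  if (ens$kind == "uniform") {
    sq <- seq(ens$bounds[1], ens$bounds[2], length.out = s_quad)
    w <- rep(1 / s_quad, s_quad)
  } else {
    d <- rbind(category_stimulus_dist(ens, 1), category_stimulus_dist(ens, 2))
    # average over categories with the category prior
    sq <- d$s
    w <- c(ens$p_cat[1] * d$prob[1:2], ens$p_cat[2] * d$prob[3:4])
  }
  dens <- numeric(nrow(E))
  for (k in seq_along(sq)) {
    mu <- experimenter_mean(exp, sq[k])
    sig <- experimenter_cov(exp, sq[k])
    si <- solve(sig)
    dx <- sweep(E, 2L, mu)
    q <- rowSums((dx %*% si) * dx)
    dens <- dens + w[k] * exp(-q / 2) / (2 * pi * sqrt(det(sig)))
  }
  dens
}

#' Learning objective: KL(p_e(E) || p_b(E)) minus lambda times prior entropy
#'
#' Monte Carlo estimate of the Kullback-Leibler divergence from the
#' experimenter's marginal observation distribution to the brain's (sampling
#' E from the experimenter and averaging log(p_e(E)/p_b(E))), minus
#' lambda * H(p_b(x)) with entropy on the mass vector.
#'
#' @param brain A \code{brain_model}.
#' @param exp An \code{experimenter_model}.
#' @param lambda Entropy-regularization weight.
#' @param n_draws Monte Carlo sample size (ignored if \code{E} given).
#' @param E Optional frozen n x 2 observation sample (for deterministic
#'   gradient checks); its rows must be draws from p_e(E).
#' @param seed Optional integer seed.
#' @return List with \code{loss}, \code{kl}, \code{entropy}.
#' @export
learning_loss <- function(brain, exp, lambda = 0.001, n_draws = 1000L,
                          E = NULL, seed = NULL) {
  if (is.null(E)) {
    st <- sample_stimuli(exp$ensemble, n_draws, seed = seed)
    E <- draw_observations(exp, st$s)
  }
  pb <- marginal_evidence(brain, E)
  if (any(pb <= 0)) {
    warning("p_b(E) underflow at sampled E; clamping to 1e-300")
    pb <- pmax(pb, 1e-300)
  }
  pe <- experimenter_density(exp, E)
  kl <- mean(log(pe) - log(pb))
  H <- field_entropy(brain$prior)
  list(loss = kl - lambda * H, kl = kl, entropy = H)
}

#' Learning objective at an unconstrained log-mass vector
#'
#' Evaluates the same objective as \code{\link{learning_loss}} but treating
#' the log-mass vector as free coordinates (no renormalization), which is the
#' parameterization the analytic gradient differentiates: the marginal
#' evidence is sum_x exp(log_mass)_x p_b(E | x) and the entropy term is
#' -sum m log m on the unnormalized mass. Used for numerical gradient checks.
#'
#' @param brain A \code{brain_model} (its prior is ignored; \code{log_mass}
#'   is used instead).
#' @param exp An \code{experimenter_model}.
#' @param log_mass Unconstrained log-mass vector, one entry per cell.
#' @param lambda Entropy weight.
#' @param E Frozen n x 2 observation sample.
#' @return Scalar objective value.
#' @export
learning_loss_logmass <- function(brain, exp, log_mass, lambda, E) {
  stopifnot(length(log_mass) == brain$grid$n_cells, is.matrix(E))
  m <- exp(log_mass)
  L <- likelihood_matrix(brain, E)
  pb <- as.numeric(crossprod(L, m)) / brain$grid$cell_measure
  pe <- experimenter_density(exp, E)
  kl <- mean(log(pe) - log(pmax(pb, 1e-300)))
  H <- -sum(m * log_mass)
  kl - lambda * H
}

#' Gradient of the learning objective with respect to the log prior
#'
#' Combined gradient: -(average posterior over E ~ p_e(E)) plus
#' lambda * p(x) (1 + log p(x)), the entropy term. Both terms treat the
#' log-mass vector as unconstrained coordinates; normalization is restored
#' after each step by \code{\link{learn_prior}}.
#'
#' @param brain A \code{brain_model} (prior strictly positive; zero-mass cells
#'   are floored at 1e-12).
#' @param exp An \code{experimenter_model}.
#' @param lambda Entropy weight.
#' @param n_draws Monte Carlo draws (ignored if \code{E} given).
#' @param E Optional frozen observation sample.
#' @param seed Optional integer seed.
#' @return Numeric gradient vector, one entry per cell.
#' @export
grad_logprior <- function(brain, exp, lambda = 0.001, n_draws = 1000L,
                          E = NULL, seed = NULL) {
  if (is.null(E)) {
    st <- sample_stimuli(exp$ensemble, n_draws, seed = seed)
    E <- draw_observations(exp, st$s)
  }
  p <- brain$prior$mass
  if (any(p <= 0)) {
    p <- pmax(p, 1e-12)
    brain <- set_prior(brain, probability_field(brain$grid, p))
  }
  avg_post <- average_posterior(brain, E)
  -avg_post + lambda * p * (1 + log(p))
}

# Step sizes are quoted at the reference resolution of 85 bins/dim; the
# KL gradient (an average posterior mass vector) scales with cell measure, so
# the step is rescaled to keep the log-prior dynamics resolution-invariant.
step_scale <- function(grid) {
  ref <- ((grid$bounds[2] - grid$bounds[1]) / 85)^grid$n_dims
  ref / grid$cell_measure
}

#' Learn the brain's prior by gradient descent on the KL objective
#'
#' Starting from the brain's current prior (uniform by default), iterates
#' log-prior <- log-prior - step * gradient, renormalizing the mass to 1
#' after every step. Each iteration draws a fresh batch of stimuli and
#' observations from the experimenter's model; the draw stream is fully
#' reproducible from the schedule seed.
#'
#' The gradient used for the update is the simplex-constrained (softmax
#' parameterization) form, -(average posterior - prior) plus the matching
#' entropy term: it has the same fixed point as the unconstrained form in
#' \code{\link{grad_logprior}} -- the self-consistency rule, prior = average
#' posterior -- but the restoring -prior term makes the multiplicative
#' update dynamically stable (the unconstrained form followed by
#' renormalization lets cells that already dominate their neighbourhood
#' capture ever more posterior mass, a runaway that collapses the prior onto
#' single cells at practical step sizes).
#'
#' @param brain A \code{brain_model}.
#' @param exp An \code{experimenter_model}.
#' @param schedule A \code{learning_schedule}.
#' @param track_kl If \code{TRUE} (default), records the Monte Carlo KL
#'   estimate each iteration on the iteration's own sample.
#' @param track_tv If \code{TRUE}, also records the total-variation distance
#'   between the current prior and the iteration's average posterior (the
#'   self-consistency gap).
#' @return An object of class \code{prior_fit}: list with \code{prior} (the
#'   learned \code{probability_field}), \code{brain} (with the learned prior
#'   installed), \code{trace} (data.frame: iteration, step, loss, kl,
#'   entropy, sc_tv), and the \code{schedule}.
#' @export
learn_prior <- function(brain, exp, schedule = learning_schedule(),
                        track_kl = TRUE, track_tv = FALSE) {
  lambda <- schedule$lambda_entropy
  n <- schedule$n_iterations
  trace <- data.frame(iteration = seq_len(n), step = rep(NA_real_, n),
                      loss = rep(NA_real_, n), kl = rep(NA_real_, n),
                      entropy = rep(NA_real_, n), sc_tv = rep(NA_real_, n))
  set.seed(schedule$seed)
  logp <- log(brain$prior$mass)
  for (t in seq_len(n)) {
    st <- sample_stimuli(exp$ensemble, schedule$draws_per_iteration)
    E <- draw_observations(exp, st$s)
    p <- exp(logp)
    brain <- set_prior(brain, probability_field(brain$grid, p))
    pm <- brain$prior$mass
    avg_post <- average_posterior(brain, E)
    logpm <- log(pmax(pm, 1e-300))
    H <- -sum(pm * logpm)
    g <- -(avg_post - pm) + lambda * pm * (logpm + H)
    step <- schedule_step(schedule, t) * step_scale(brain$grid)
    logp <- log(brain$prior$mass) - step * g
    logp <- logp - max(logp)           # overflow guard before exponentiation
    mass <- exp(logp)
    mass <- mass / sum(mass)
    logp <- log(pmax(mass, 1e-300))
    trace$step[t] <- step
    if (track_kl) {
      b2 <- set_prior(brain, probability_field(brain$grid, mass))
      ll <- learning_loss(b2, exp, lambda = lambda, E = E)
      if (!is.finite(ll$loss)) stop("non-finite loss at iteration ", t)
      trace$loss[t] <- ll$loss; trace$kl[t] <- ll$kl; trace$entropy[t] <- ll$entropy
    }
    if (track_tv) {
      trace$sc_tv[t] <- 0.5 * sum(abs(mass - avg_post))
    }
  }
  final_prior <- probability_field(brain$grid, exp(logp))
  brain <- set_prior(brain, final_prior)
  structure(list(prior = final_prior, brain = brain, trace = trace,
                 schedule = schedule, exp = exp),
            class = "prior_fit")
}

#' @export
print.prior_fit <- function(x, ...) {
  n <- nrow(x$trace)
  cat(sprintf("prior_fit: %d iterations on %d cells\n", n, x$prior$grid$n_cells))
  if (n > 0 && any(is.finite(x$trace$kl)))
    cat(sprintf("  KL estimate: %.4f (first) -> %.4f (last)\n",
                x$trace$kl[which(is.finite(x$trace$kl))[1]],
                x$trace$kl[max(which(is.finite(x$trace$kl)))]))
  invisible(x)
}

#' @export
coef.prior_fit <- function(object, ...) object$prior$mass

#' @export
plot.prior_fit <- function(x, which = c("prior", "trace"), ...) {
  which <- match.arg(which)
  if (which == "prior") {
    plot(x$prior, ...)
  } else {
    graphics::plot(x$trace$iteration, x$trace$kl, type = "l",
                   xlab = "iteration", ylab = "KL estimate", ...)
  }
  invisible(x)
}
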