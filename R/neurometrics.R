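#' Standard setup for belief-feedback session studies
#'
#' Builds the canonical configuration used by the decision-statistics
#' analyses: a 2-D grid observer with the imprecise likelihood, a
#' delta-mixture task (half the trials zero-signal, category offset 1), the
#' self-consistent category priors, a linear-moment distributional code, and
#' its tuning curve at the category boundary. These defaults give the belief
#' feedback enough contrast against Poisson encoding noise for stable
#' covariance decompositions at 10^4-scale sessions.
#'
#' @param bins Grid bins per dimension.
#' @param p0 Zero-signal probability of the task ensemble.
#' @param delta_s Category offset of the task ensemble.
#' @param n_neurons,gain,code_kind,seed Code settings
#'   (see \code{\link{distributional_code}}).
#' @param sigma_e2 Brain likelihood variance.
#' @return List with \code{brain} (prior set to the learned marginal),
#'   \code{exp}, \code{p1}, \code{p2}, \code{code}, \code{tuning}.
#' @export
neurometrics_setup <- function(bins = 41L, p0 = 0.5, delta_s = 1,
                               n_neurons = 64L, gain = 300,
                               code_kind = "linear_moment", sigma_e2 = 0.36,
                               seed = 1L) {
  grid <- latent_grid(2L, c(-5, 5), bins)
  brain <- brain_model(grid, sigma_e2 = sigma_e2)
  exp <- experimenter_model("mean_coded",
                            ensemble = stimulus_ensemble("delta_mixture",
                                                         p0 = p0,
                                                         delta_s = delta_s))
  lp <- learned_category_priors(brain, exp, zero_noise = TRUE)
  code <- distributional_code(grid, code_kind, n_neurons = n_neurons,
                              gain = gain, seed = seed)
  tuning <- tuning_curve(code, lp$brain, exp,
                         s_values = c(-delta_s, 0, delta_s),
                         zero_noise = TRUE, fprime_delta = delta_s,
                         n_sd_draws = 2000L, seed = seed)
  list(brain = lp$brain, exp = exp, p1 = lp$p1, p2 = lp$p2, code = code,
       tuning = tuning)
}

#' Simulate a session of zero-signal trials with variable beliefs
#'
#' All trials are at the category boundary (s = 0). Per trial a belief pi is
#' drawn from the symmetric Beta family with variance \code{var_pi}, the
#' posterior over x is formed from the belief-mixture prior and the trial's
#' observation, a response is sampled from the code, and the choice is 1 if
#' pi > 1/2, 2 if pi < 1/2, a fair coin at exactly 1/2.
#'
#' @param brain A \code{brain_model}.
#' @param exp An \code{experimenter_model} with a delta-mixture ensemble.
#' @param code A \code{distributional_code} on the brain's grid.
#' @param p1,p2 Per-category priors (from
#'   \code{\link{learned_category_priors}}).
#' @param var_pi Belief variance in [0, 0.25].
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @param zero_noise If \code{TRUE} (default), the observation is the fixed
#'   zero-signal mean E(0) on every trial, isolating belief feedback; if
#'   \code{FALSE}, E is drawn from p_e(E | s = 0) each trial.
#' @return Object of class \code{trial_set}: list with \code{response}
#'   (n_trials x n_neurons integer matrix), \code{pi}, \code{choice},
#'   \code{s} (all 0), \code{var_pi}, \code{code_kind}, \code{seed}.
#' @export
simulate_session <- function(brain, exp, code, p1, p2, var_pi = 0.01,
                             n_trials = 10000L, seed = 1L, zero_noise = TRUE) {
  stopifnot(var_pi >= 0, var_pi <= 0.25, n_trials >= 2)
  set.seed(seed)
  pi_vals <- sample_beliefs(var_pi, n_trials)
  choice <- ifelse(pi_vals > 0.5, 1L, ifelse(pi_vals < 0.5, 2L,
                   sample(1:2, n_trials, replace = TRUE)))
  a1 <- NULL
  if (zero_noise) {
    # posterior(pi) = (pi a + (1-pi) b) / (pi A + (1-pi) B) with
    # a = lik(E0) p1, b = lik(E0) p2: rates are cheap per trial for linear
    # codes; generic path otherwise.
    E0 <- experimenter_mean(exp, 0)
    lik <- likelihood_field(brain, E0)$mass
    a <- lik * p1$mass; b <- lik * p2$mass
    A <- sum(a); B <- sum(b)
    if (code$kind %in% c("linear_moment", "linear_sampling")) {
      ra <- mean_rates(code, a / A); rb <- mean_rates(code, b / B)
      # rate(pi) = (pi A ra + (1-pi) B rb) / (pi A + (1-pi) B)
      wA <- pi_vals * A; wB <- (1 - pi_vals) * B
      rate_mat <- (outer(ra, wA) + outer(rb, wB)) /
        rep(wA + wB, each = code$n_neurons)
      resp <- matrix(stats::rpois(length(rate_mat), rate_mat),
                     nrow = code$n_neurons)
      if (code$kind == "linear_sampling") {
        # replace Poisson-around-mean shortcut by the true two-stage draw
        resp <- vapply(seq_len(n_trials), function(t) {
          m <- (pi_vals[t] * a + (1 - pi_vals[t]) * b)
          sample_response(code, m / sum(m))
        }, integer(code$n_neurons))
      }
    } else {
      resp <- vapply(seq_len(n_trials), function(t) {
        m <- (pi_vals[t] * a + (1 - pi_vals[t]) * b)
        sample_response(code, m / sum(m))
      }, integer(code$n_neurons))
    }
  } else {
    E <- draw_observations(exp, rep(0, n_trials))
    resp <- matrix(0L, code$n_neurons, n_trials)
    block <- 1000L
    for (start in seq(1L, n_trials, by = block)) {
      idx <- start:min(start + block - 1L, n_trials)
      L <- likelihood_matrix(brain, E[idx, , drop = FALSE])
      for (k in seq_along(idx)) {
        t <- idx[k]
        m <- L[, k] * (pi_vals[t] * p1$mass + (1 - pi_vals[t]) * p2$mass)
        resp[, t] <- sample_response(code, m / sum(m))
      }
    }
  }
  structure(list(response = t(resp), pi = pi_vals, choice = choice,
                 s = rep(0, n_trials), var_pi = var_pi,
                 code_kind = code$kind, seed = as.integer(seed)),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("trial_set: %d trials x %d neurons (var_pi = %g, %s code)\n",
              nrow(x$response), ncol(x$response), x$var_pi, x$code_kind))
  invisible(x)
}

#' Choice-triggered average
#'
#' Difference in mean response between choice-1 and choice-2 trials, per
#' neuron.
#'
#' @param trials A \code{trial_set}.
#' @return Numeric vector (n_neurons).
#' @export
cta <- function(trials) {
  c1 <- trials$choice == 1L
  if (!any(c1) || all(c1)) stop("both choices must be present")
  colMeans(trials$response[c1, , drop = FALSE]) -
    colMeans(trials$response[!c1, , drop = FALSE])
}

# Rank-statistic ROC area for one response vector vs a binary choice;
# average ranks make ties count 1/2, matching the pairwise-comparison count.
auc_rank <- function(x, is_c1) {
  n1 <- sum(is_c1); n2 <- sum(!is_c1)
  r <- rank(x)
  (sum(r[is_c1]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Choice probabilities
#'
#' Per-neuron area under the ROC curve separating choice-1 from choice-2
#' response distributions (rank-statistic implementation; 0.5 = no choice
#' association, invariant to monotone response transforms).
#'
#' @param trials A \code{trial_set}.
#' @return Numeric vector of CPs in [0, 1].
#' @export
choice_probability <- function(trials) {
  is_c1 <- trials$choice == 1L
  if (!any(is_c1) || all(is_c1)) stop("both choices must be present")
  apply(trials$response, 2L, auc_rank, is_c1 = is_c1)
}

#' Per-neuron d-prime sensitivity
#'
#' d'_i = f'_i / sigma_i from a tuning curve: the tuning slope at the
#' category boundary normalized by the response SD there.
#'
#' @param tuning A \code{tuning_curve}.
#' @return Numeric vector (n_neurons).
#' @export
dprime_vector <- function(tuning) {
  if (any(tuning$sigma <= 0)) stop("zero response SD: d-prime undefined")
  tuning$fprime / tuning$sigma
}

#' Across-neuron correlation between (CP - 1/2) and d-prime
#'
#' Pearson correlation over neurons between the choice-probability excess and
#' the normalized sensitivity, the signature of decision-related feedback.
#'
#' @param trials A \code{trial_set}.
#' @param tuning A \code{tuning_curve} for the same code/model.
#' @return Scalar correlation.
#' @export
cp_dprime_relation <- function(trials, tuning) {
  if (ncol(trials$response) < 20L) stop("need at least 20 neurons")
  cp <- choice_probability(trials) - 0.5
  dp <- dprime_vector(tuning)
  if (stats::sd(cp) == 0 || stats::sd(dp) == 0) stop("degenerate variance")
  stats::cor(cp, dp)
}

#' Decompose session covariance into intrinsic and belief components
#'
#' Sigma_total is the response covariance of a session with belief
#' variability; Sigma_intrinsic that of a matched session with var_pi = 0;
#' Sigma_belief their difference, predicted to be approximately rank-1 in the
#' f'f'^T direction with magnitude proportional to var(pi).
#'
#' @param trials_with \code{trial_set} with var_pi > 0.
#' @param trials_without \code{trial_set} with var_pi = 0 (same code/model).
#' @param tuning A \code{tuning_curve} supplying f'.
#' @return Object of class \code{covariance_decomposition}: list with
#'   \code{sigma_total}, \code{sigma_intrinsic}, \code{sigma_belief},
#'   \code{fprime}, \code{var_pi}, \code{alignment} (cosine of Sigma_belief's
#'   top eigenvector with f'), \code{top_eigenvalue} and \code{fitted_scale}
#'   (top eigenvalue / |f'|^2, the empirical alpha^2 var(pi)).
#' @export
covariance_decomposition <- function(trials_with, trials_without, tuning) {
  stopifnot(trials_without$var_pi == 0,
            ncol(trials_with$response) == ncol(trials_without$response))
  if (nrow(trials_with$response) < 100L) stop("too few trials for stable covariance")
  st <- stats::cov(trials_with$response)
  si <- stats::cov(trials_without$response)
  sb <- st - si
  e <- eigen((sb + t(sb)) / 2, symmetric = TRUE)
  v <- e$vectors[, 1L]
  fp <- tuning$fprime
  al <- sum(v * fp) / sqrt(sum(v^2) * sum(fp^2))
  structure(list(sigma_total = st, sigma_intrinsic = si, sigma_belief = sb,
                 fprime = fp, var_pi = trials_with$var_pi,
                 alignment = al, top_eigenvalue = e$values[1L],
                 fitted_scale = e$values[1L] / sum(fp^2)),
            class = "covariance_decomposition")
}

#' @export
print.covariance_decomposition <- function(x, ...) {
  cat(sprintf(paste0("covariance_decomposition: top belief eigenvalue %.4g, ",
                     "|alignment with f'| = %.3f (var_pi = %g)\n"),
              x$top_eigenvalue, abs(x$alignment), x$var_pi))
  invisible(x)
}
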