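#' Stimulus ensembles for two-category discrimination
#'
#' The experimenter draws a scalar stimulus s each trial. Two ensembles are
#' supported: \code{"uniform"}, s ~ U(bounds) (the ensemble used for prior
#' learning), and \code{"delta_mixture"}, the sub-threshold ensemble in which
#' s takes the value 0 with probability \code{p0} and otherwise +/- delta_s
#' with equal probability. The category boundary is s = 0; category 1 is
#' s > 0 and category 2 is s < 0 (a labeling convention; zero-signal trials
#' belong to either category with equal probability).
#'
#' @param kind \code{"uniform"} or \code{"delta_mixture"}.
#' @param bounds Support of the uniform ensemble (default [-3, 3]).
#' @param p0 Zero-signal probability of the delta mixture, in [0, 1].
#' @param delta_s Category offset of the delta mixture, > 0.
#' @param p_cat Length-2 prior over categories (default 50/50).
#' @return An object of class \code{stimulus_ensemble}.
#' @export
stimulus_ensemble <- function(kind = c("uniform", "delta_mixture"),
                              bounds = c(-3, 3), p0 = 0.9, delta_s = 0.01,
                              p_cat = c(0.5, 0.5)) {
  kind <- match.arg(kind)
  stopifnot(is.finite(bounds), bounds[2] > bounds[1],
            p0 >= 0, p0 <= 1, delta_s > 0,
            length(p_cat) == 2L, all(p_cat >= 0), abs(sum(p_cat) - 1) < 1e-12)
  structure(list(kind = kind, bounds = as.numeric(bounds), p0 = p0,
                 delta_s = delta_s, p_cat = as.numeric(p_cat)),
            class = "stimulus_ensemble")
}

#' @export
print.stimulus_ensemble <- function(x, ...) {
  if (x$kind == "uniform") {
    cat(sprintf("stimulus_ensemble: uniform on [%g, %g]\n", x$bounds[1], x$bounds[2]))
  } else {
    cat(sprintf("stimulus_ensemble: delta mixture, p0 = %g, delta_s = %g\n",
                x$p0, x$delta_s))
  }
  invisible(x)
}

#' Sample stimuli (and category labels) from an ensemble
#'
#' For the delta mixture, s is -delta_s, 0, or +delta_s with probabilities
#' (1-p0)/2, p0, (1-p0)/2; the category equals sign(s) for signal trials and
#' is drawn from the category prior for zero-signal trials. For the uniform
#' ensemble s ~ U(bounds) and the category is sign(s).
#'
#' @param ensemble A \code{stimulus_ensemble}.
#' @param n Number of trials.
#' @param seed Optional integer seed for reproducibility.
#' @return A data.frame with columns \code{s} and \code{category} (1 or 2).
#' @export
sample_stimuli <- function(ensemble, n, seed = NULL) {
  stopifnot(inherits(ensemble, "stimulus_ensemble"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (ensemble$kind == "uniform") {
    s <- stats::runif(n, ensemble$bounds[1], ensemble$bounds[2])
    category <- ifelse(s > 0, 1L, 2L)
  } else {
    u <- stats::runif(n)
    p0 <- ensemble$p0
    s <- numeric(n)
    sig <- u >= p0
    half <- p0 + (1 - p0) / 2
    s[sig] <- ifelse(u[sig] < half, ensemble$delta_s, -ensemble$delta_s)
    category <- integer(n)
    category[sig] <- ifelse(s[sig] > 0, 1L, 2L)
    nz <- sum(!sig)
    if (nz > 0)
      category[!sig] <- sample(1:2, nz, replace = TRUE, prob = ensemble$p_cat)
  }
  data.frame(s = s, category = category)
}

#' Per-category stimulus distribution of a delta-mixture ensemble
#'
#' Returns the support and probabilities of s conditioned on the category:
#' mass p0 at 0 and (1 - p0) at +delta_s (category 1) or -delta_s
#' (category 2).
#'
#' @param ensemble A delta-mixture \code{stimulus_ensemble}.
#' @param category 1 or 2.
#' @return A data.frame with columns \code{s} and \code{prob}.
#' @export
category_stimulus_dist <- function(ensemble, category) {
  stopifnot(ensemble$kind == "delta_mixture", category %in% 1:2)
  sgn <- if (category == 1) 1 else -1
  data.frame(s = c(0, sgn * ensemble$delta_s),
             prob = c(ensemble$p0, 1 - ensemble$p0))
}

# Beta(a, a) shape parameter matching a requested variance of pi on [0, 1]:
# var = 1 / (4 (2a + 1))  =>  a = (1/(4 var) - 1) / 2
beta_shape_from_var <- function(var_pi) {
  (1 / (4 * var_pi) - 1) / 2
}

#' Sample trial-by-trial category beliefs
#'
#' Beliefs pi = p(C = 1 | ...) are i.i.d. symmetric draws on [0, 1] with mean
#' 1/2 and the requested variance, from a Beta(a, a) family. var_pi = 0 gives
#' the constant 1/2 and var_pi = 0.25 the limiting fair Bernoulli on {0, 1}.
#'
#' @param var_pi Belief variance, in [0, 0.25].
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of beliefs in [0, 1].
#' @export
sample_beliefs <- function(var_pi, n, seed = NULL) {
  stopifnot(var_pi >= 0, n >= 1)
  if (var_pi > 0.25) stop("var_pi must be <= 0.25 (maximum variance on [0,1])")
  if (!is.null(seed)) set.seed(seed)
  if (var_pi == 0) return(rep(0.5, n))
  if (var_pi == 0.25) return(sample(c(0, 1), n, replace = TRUE))
  a <- beta_shape_from_var(var_pi)
  stats::rbeta(n, a, a)
}

#' Prebuilt experiment configurations
#'
#' Bundles a grid, experimenter model, brain model and learning schedule for
#' one of the standard study configurations. The \code{"full"} profile is
#' the full printed configuration (85 bins/dim on [-5, 5]); \code{"reduced"}
#' uses 41 bins/dim and \code{"tiny"} 21 bins/dim with fewer Monte Carlo
#' draws, for fast test suites. All profiles share the same code path.
#'
#' @param profile One of \code{"tiny"}, \code{"reduced"}, \code{"full"}.
#' @param coding \code{"mean_coded"} or \code{"covariance_coded"}.
#' @param precision \code{"precise"} (sigma_E^2 = 0.04) or \code{"imprecise"}
#'   (sigma_E^2 = 0.36).
#' @param seed Integer seed recorded in the fixture.
#' @return A list of class \code{experiment_fixture} with elements
#'   \code{grid}, \code{exp}, \code{brain}, \code{schedule}, \code{n_cov_draws},
#'   \code{profile} and \code{seed}.
#' @export
make_fixture <- function(profile = c("tiny", "reduced", "full"),
                         coding = c("mean_coded", "covariance_coded"),
                         precision = c("imprecise", "precise"),
                         seed = 1L) {
  profile <- match.arg(profile)
  coding <- match.arg(coding)
  precision <- match.arg(precision)
  bins <- switch(profile, tiny = 21L, reduced = 41L, full = 85L)
  draws <- switch(profile, tiny = 400L, reduced = 1000L, full = 1000L)
  cov_draws <- switch(profile, tiny = 1000L, reduced = 2000L, full = 2000L)
  grid <- latent_grid(2L, c(-5, 5), bins)
  exp <- experimenter_model(coding = coding)
  sigma_e2 <- if (precision == "precise") 0.04 else 0.36
  brain <- brain_model(grid, sigma_e2 = sigma_e2)
  schedule <- learning_schedule(draws_per_iteration = draws, seed = seed)
  structure(list(grid = grid, exp = exp, brain = brain, schedule = schedule,
                 n_cov_draws = cov_draws, profile = profile,
                 coding = coding, precision = precision, seed = as.integer(seed)),
            class = "experiment_fixture")
}

#' @export
print.experiment_fixture <- function(x, ...) {
  cat(sprintf("experiment_fixture: %s / %s / %s (%d bins/dim, seed %d)\n",
              x$profile, x$coding, x$precision, x$grid$bins_per_dim, x$seed))
  invisible(x)
}
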