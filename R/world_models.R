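#' Experimenter's stimulus-generating model
#'
#' The experimenter maps a scalar stimulus s to a Gaussian distribution over
#' 2-D observations E. Two parameterizations are supported:
#' \describe{
#'   \item{mean_coded}{the mean of E follows the cubic curve
#'     (s, (s + s^3)/10) and the covariance is the constant 0.5 I.}
#'   \item{covariance_coded}{the mean is (0, 0) and the covariance is
#'     Sigma0 + tanh(s) Sigma_+ for s > 0 and Sigma0 - tanh(s) Sigma_- for
#'     s <= 0, with Sigma0 = 0.5 I and Sigma_+/- = [[1, +/-1], [+/-1, 1]].}
#' }
#' A \code{"custom"} mode accepts arbitrary \code{mean_fn} / \code{cov_fn}
#' for controlled numerical experiments.
#'
#' @param coding One of \code{"mean_coded"}, \code{"covariance_coded"},
#'   \code{"custom"}.
#' @param ensemble A \code{stimulus_ensemble}; defaults to uniform on [-3, 3].
#' @param mean_fn,cov_fn Only for \code{coding = "custom"}: functions of s
#'   returning a 2-vector and a 2x2 positive-definite matrix.
#' @return An object of class \code{experimenter_model}.
#' @export
experimenter_model <- function(coding = c("mean_coded", "covariance_coded", "custom"),
                               ensemble = stimulus_ensemble("uniform"),
                               mean_fn = NULL, cov_fn = NULL) {
  coding <- match.arg(coding)
  if (coding == "custom") {
    stopifnot(is.function(mean_fn), is.function(cov_fn))
  }
  structure(list(coding = coding, ensemble = ensemble,
                 mean_fn = mean_fn, cov_fn = cov_fn),
            class = "experimenter_model")
}

#' @export
print.experimenter_model <- function(x, ...) {
  cat(sprintf("experimenter_model: %s coding, stimulus ensemble %s\n",
              x$coding, x$ensemble$kind))
  invisible(x)
}

#' Mean of p_e(E | s)
#' @param model An \code{experimenter_model}.
#' @param s Scalar stimulus.
#' @return Length-2 numeric vector.
#' @export
experimenter_mean <- function(model, s) {
  stopifnot(is.finite(s))
  switch(model$coding,
         mean_coded = c(s, (s + s^3) / 10),
         covariance_coded = c(0, 0),
         custom = as.numeric(model$mean_fn(s)))
}

#' Covariance of p_e(E | s)
#' @param model An \code{experimenter_model}.
#' @param s Scalar stimulus.
#' @return 2x2 positive-definite matrix; continuous in s (both branches of the
#'   covariance-coded form agree at s = 0).
#' @export
experimenter_cov <- function(model, s) {
  if (!is.finite(s)) stop("s must be finite")
  switch(model$coding,
         mean_coded = diag(0.5, 2),
         covariance_coded = {
           sigma0 <- diag(0.5, 2)
           if (s > 0) sigma0 + tanh(s) * matrix(c(1, 1, 1, 1), 2)
           else       sigma0 - tanh(s) * matrix(c(1, -1, -1, 1), 2)
         },
         custom = {
           m <- model$cov_fn(s)
           stopifnot(is.matrix(m), all(dim(m) == 2L))
           m
         })
}

# Draw n observations E ~ N(mean(s), cov(s)); returns n x 2 matrix. The two
# named parameterizations have closed-form 2x2 Cholesky factors, vectorized
# over draws; custom models fall back to a per-unique-s loop.
draw_observations <- function(model, s_values, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(s_values)
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  if (model$coding == "mean_coded") {
    sd0 <- sqrt(0.5)
    return(cbind(s_values + sd0 * z1,
                 (s_values + s_values^3) / 10 + sd0 * z2))
  }
  if (model$coding == "covariance_coded") {
    # both tanh branches give diag 0.5 + |tanh(s)|, off-diagonal tanh(s)
    a <- 0.5 + abs(tanh(s_values))
    b <- tanh(s_values)
    sa <- sqrt(a)
    return(cbind(sa * z1, (b / sa) * z1 + sqrt(a - b^2 / a) * z2))
  }
  out <- matrix(0, n, 2L)
  for (s in unique(s_values)) {
    idx <- which(s_values == s)
    mu <- experimenter_mean(model, s)
    L <- chol(experimenter_cov(model, s))
    z <- cbind(z1[idx], z2[idx])
    out[idx, ] <- sweep(z %*% L, 2L, mu, "+")
  }
  out
}

#' Sample one observation from the experimenter's model
#' @param model An \code{experimenter_model}.
#' @param s Scalar stimulus.
#' @param seed Optional integer seed.
#' @return Length-2 observation vector E.
#' @export
sample_observation <- function(model, s, seed = NULL) {
  as.numeric(draw_observations(model, s, seed = seed))
}

#' Brain's internal generative model on a grid
#'
#' The brain assumes E is Gaussian around the latent x with isotropic
#' variance sigma_E^2 per axis: p_b(E | x) = N(E; x, sigma_E^2 I). Its prior
#' over x lives on the grid (uniform before learning).
#'
#' @param grid A \code{latent_grid}.
#' @param sigma_e2 Likelihood variance per axis: 0.04 in the precise regime,
#'   0.36 in the imprecise regime.
#' @param prior Optional normalized \code{probability_field}; defaults to
#'   uniform.
#' @return An object of class \code{brain_model}.
#' @export
brain_model <- function(grid, sigma_e2 = 0.36, prior = NULL) {
  stopifnot(inherits(grid, "latent_grid"), sigma_e2 > 0)
  if (is.null(prior)) prior <- uniform_field(grid)
  stopifnot(inherits(prior, "probability_field"), same_grid(prior$grid, grid),
            prior$normalized)
  structure(list(grid = grid, sigma_e2 = sigma_e2, prior = prior),
            class = "brain_model")
}

#' @export
print.brain_model <- function(x, ...) {
  cat(sprintf("brain_model: sigma_E^2 = %g on %d-cell grid\n",
              x$sigma_e2, x$grid$n_cells))
  invisible(x)
}

#' Replace the prior of a brain model
#' @param brain A \code{brain_model}.
#' @param prior A normalized \code{probability_field} on the same grid.
#' @return The brain model with the new prior.
#' @export
set_prior <- function(brain, prior) {
  stopifnot(inherits(prior, "probability_field"), same_grid(prior$grid, brain$grid),
            prior$normalized)
  brain$prior <- prior
  brain
}

# Likelihood mass matrix for a batch of observations: n_cells x n_obs, entry
# [i, j] = N(E_j; x_i, sigma_E^2 I) * cell_measure. Workhorse for all
# Monte Carlo averages over observations. The isotropic Gaussian factorizes
# over dimensions, so the exp() is evaluated on bins x draws per axis and the
# full matrix assembled by an indexed product.
likelihood_matrix <- function(brain, E) {
  if (is.null(dim(E))) E <- matrix(E, nrow = 1L)
  g <- brain$grid
  s2 <- brain$sigma_e2
  norm_const <- (2 * pi * s2)^(-g$n_dims / 2) * g$cell_measure
  if (g$n_dims == 1L) {
    k1 <- exp(-outer(g$axis, E[, 1L], "-")^2 / (2 * s2))
    return(k1 * norm_const)
  }
  k1 <- exp(-outer(g$axis, E[, 1L], "-")^2 / (2 * s2))
  k2 <- exp(-outer(g$axis, E[, 2L], "-")^2 / (2 * s2))
  nb <- g$bins_per_dim
  ix <- rep(seq_len(nb), times = nb)   # first coordinate varies fastest
  iy <- rep(seq_len(nb), each = nb)
  k1[ix, , drop = FALSE] * k2[iy, , drop = FALSE] * norm_const
}

#' Likelihood field of an observation over the latent grid
#'
#' Evaluates the brain's Gaussian likelihood p_b(E | x) at every grid cell
#' (times the cell measure), as an unnormalized field over x.
#'
#' @param brain A \code{brain_model}.
#' @param E Length-2 (or length-1 for 1-D grids) observation.
#' @return An unnormalized \code{probability_field}.
#' @export
likelihood_field <- function(brain, E) {
  stopifnot(all(is.finite(E)), length(E) == brain$grid$n_dims)
  mass <- as.numeric(likelihood_matrix(brain, matrix(E, nrow = 1L)))
  probability_field(brain$grid, mass, normalized = FALSE)
}
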