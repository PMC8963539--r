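#' Distributional code from posterior fields to spike counts
#'
#' A code maps a probability field over the latent grid to a population
#' spike-count distribution. Four kinds are provided:
#' \describe{
#'   \item{linear_sampling}{latent samples are drawn from the field and
#'     binned by each neuron's preferred (Voronoi) region; spikes are Poisson
#'     around gain x samples-in-region. Mean rates are affine in the mass
#'     vector (an LDC).}
#'   \item{linear_moment}{mean rates are gain x (W mass) for a fixed
#'     nonnegative readout matrix W of Gaussian bumps around preferred
#'     points; Poisson counts (an LDC).}
#'   \item{nonlinear_rate}{mean rates are gain x (W mass)^2; the squared
#'     drive breaks mixture linearity (not an LDC).}
#'   \item{natural_param}{mean rates are gain x W (log mass - log floor),
#'     floored at 0: an exponential-family natural-parameter encoding (not an
#'     LDC).}
#' }
#'
#' @param grid The \code{latent_grid} the encoded fields live on.
#' @param kind Code kind, see above.
#' @param n_neurons Number of neurons.
#' @param gain Scalar gain (expected spikes per unit drive).
#' @param baseline Spontaneous rate added to every neuron's mean (spikes per
#'   trial); keeps response SDs positive everywhere. Being an affine offset it
#'   does not affect mixture linearity.
#' @param k_samples Latent samples per trial for the sampling code.
#' @param bump_width SD (latent units) of the Gaussian readout bumps for the
#'   weight-based kinds.
#' @param seed Seed for the placement of preferred points.
#' @return Object of class \code{distributional_code} with elements
#'   \code{kind}, \code{n_neurons}, \code{gain}, \code{k_samples},
#'   \code{weights} (n_neurons x n_cells), \code{region} (Voronoi cell
#'   assignment, for the sampling code), \code{preferred} (n_neurons x n_dims
#'   preferred points).
#' @export
distributional_code <- function(grid,
                                kind = c("linear_moment", "linear_sampling",
                                         "nonlinear_rate", "natural_param"),
                                n_neurons = 64L, gain = 20, baseline = 0.5,
                                k_samples = 20L, bump_width = 1.0, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(inherits(grid, "latent_grid"), n_neurons >= 1, gain >= 0,
            baseline >= 0, k_samples >= 1, bump_width > 0)
  set.seed(seed)
  pref_idx <- sample.int(grid$n_cells, n_neurons, replace = FALSE)
  pref <- grid$centers[pref_idx, , drop = FALSE]
  # squared latent distance of every cell to every preferred point
  d2 <- outer(pref[, 1L], grid$centers[, 1L], "-")^2
  if (grid$n_dims == 2L)
    d2 <- d2 + outer(pref[, 2L], grid$centers[, 2L], "-")^2
  W <- exp(-d2 / (2 * bump_width^2))
  region <- apply(d2, 2L, which.min)   # nearest preferred point per cell
  structure(list(grid = grid, kind = kind, n_neurons = as.integer(n_neurons),
                 gain = gain, baseline = baseline,
                 k_samples = as.integer(k_samples),
                 weights = W, region = region, preferred = pref,
                 log_floor = 1e-10),
            class = "distributional_code")
}

#' @export
print.distributional_code <- function(x, ...) {
  cat(sprintf("distributional_code: %s, %d neurons, gain %g\n",
              x$kind, x$n_neurons, x$gain))
  invisible(x)
}

# mass -> n_neurons x n_fields mean-rate matrix; mass may be a vector or an
# n_cells x n_fields matrix of normalized fields.
mean_rate_matrix <- function(code, mass) {
  if (is.null(dim(mass))) mass <- matrix(mass, ncol = 1L)
  code$baseline + switch(code$kind,
    linear_moment = code$gain * (code$weights %*% mass),
    nonlinear_rate = code$gain * (code$weights %*% mass)^2,
    natural_param = {
      lm <- log(pmax(mass, code$log_floor)) - log(code$log_floor)
      code$gain * 0.05 * (code$weights %*% lm)
    },
    linear_sampling = {
      # expected samples per region, scaled by gain
      reg_mass <- rowsum(mass, code$region)
      out <- matrix(0, code$n_neurons, ncol(mass))
      out[sort(unique(code$region)), ] <- as.matrix(reg_mass)
      code$gain * code$k_samples * out
    })
}

#' Mean firing rates of a code for an encoded field
#'
#' Deterministic expected spike counts for a normalized probability field.
#'
#' @param code A \code{distributional_code}.
#' @param field A normalized \code{probability_field} (or bare mass vector).
#' @return Numeric vector of n_neurons nonnegative mean rates.
#' @export
mean_rates <- function(code, field) {
  mass <- if (inherits(field, "probability_field")) field$mass else as.numeric(field)
  stopifnot(length(mass) == code$grid$n_cells)
  as.numeric(mean_rate_matrix(code, mass))
}

#' Sample a population spike-count response to an encoded field
#'
#' For the sampling code, k latent samples are drawn from the field, binned
#' by preferred region, and each binned sample emits Poisson(gain) spikes;
#' for the other kinds counts are Poisson around \code{\link{mean_rates}}.
#'
#' @param code A \code{distributional_code}.
#' @param field A normalized \code{probability_field}.
#' @param seed Optional integer seed.
#' @return Integer vector of n_neurons spike counts.
#' @export
sample_response <- function(code, field, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mass <- if (inherits(field, "probability_field")) field$mass else as.numeric(field)
  if (code$kind == "linear_sampling") {
    cells <- sample.int(code$grid$n_cells, code$k_samples, replace = TRUE,
                        prob = mass)
    cnt <- tabulate(code$region[cells], nbins = code$n_neurons)
    stats::rpois(code$n_neurons, code$baseline + code$gain * cnt)
  } else {
    stats::rpois(code$n_neurons, mean_rate_matrix(code, mass))
  }
}

#' Mixture-linearity gap of a code (the LDC test)
#'
#' Compares the mean response to a mixture field alpha p1 + (1 - alpha) p2
#' with the same mixture of mean responses to p1 and p2. Linear
#' distributional codes give an identically zero gap; nonlinear codes do not.
#' With \code{n_mc = 0} the gap is computed exactly from
#' \code{\link{mean_rates}}; with \code{n_mc > 0} it is estimated from
#' sampled responses and returned with its Monte Carlo standard error.
#'
#' @param code A \code{distributional_code}.
#' @param p1,p2 Normalized \code{probability_field}s on the code's grid.
#' @param alpha Mixture weight in [0, 1].
#' @param n_mc Monte Carlo responses per field (0 = analytic means).
#' @param seed Optional integer seed.
#' @return data.frame with per-neuron columns \code{gap} (absolute
#'   difference) and \code{se} (0 for the analytic path).
#' @export
ldc_mixture_gap <- function(code, p1, p2, alpha = 0.5, n_mc = 0L, seed = NULL) {
  stopifnot(alpha >= 0, alpha <= 1)
  mix <- probability_field(code$grid, alpha * p1$mass + (1 - alpha) * p2$mass)
  if (n_mc == 0L) {
    gap <- abs(mean_rates(code, mix) -
                 (alpha * mean_rates(code, p1) + (1 - alpha) * mean_rates(code, p2)))
    return(data.frame(gap = gap, se = 0))
  }
  if (!is.null(seed)) set.seed(seed)
  draw_mean <- function(f) {
    R <- matrix(0L, code$n_neurons, n_mc)
    for (j in seq_len(n_mc)) R[, j] <- sample_response(code, f)
    list(mean = rowMeans(R), var = apply(R, 1L, stats::var))
  }
  dm <- draw_mean(mix); d1 <- draw_mean(p1); d2 <- draw_mean(p2)
  gap <- dm$mean - (alpha * d1$mean + (1 - alpha) * d2$mean)
  se <- sqrt(dm$var / n_mc + alpha^2 * d1$var / n_mc +
               (1 - alpha)^2 * d2$var / n_mc)
  data.frame(gap = abs(gap), se = se)
}

#' Tuning curves, slopes and response SDs of a code
#'
#' f_i(s): mean rate of each neuron at each stimulus value, averaging over
#' observation noise; f' by central difference around s = 0 at step
#' \code{fprime_delta}; per-neuron response SD at s = 0 from sampled
#' responses.
#'
#' @param code A \code{distributional_code}.
#' @param brain A \code{brain_model} (its prior is the encoding prior; pass a
#'   belief-mixture prior via \code{\link{set_prior}} if needed).
#' @param exp An \code{experimenter_model}.
#' @param s_values Sorted stimulus values for the curve.
#' @param n_draws Observation draws per stimulus value (1 if
#'   \code{zero_noise}).
#' @param fprime_delta Central-difference step for f'.
#' @param n_sd_draws Sampled responses at s = 0 for the SD estimate.
#' @param zero_noise If \code{TRUE}, use noiseless observations E(s).
#' @param seed Optional integer seed.
#' @return Object of class \code{tuning_curve}: list with \code{s_values},
#'   \code{rates} (n_neurons x n_s), \code{fprime}, \code{sigma}.
#' @export
tuning_curve <- function(code, brain, exp, s_values = seq(-1, 1, by = 0.25),
                         n_draws = 500L, fprime_delta = 0.01,
                         n_sd_draws = 1000L, zero_noise = FALSE, seed = NULL) {
  stopifnot(!is.unsorted(s_values))
  if (!is.null(seed)) set.seed(seed)
  avg_rate <- function(s) {
    E <- if (zero_noise) matrix(experimenter_mean(exp, s), nrow = 1L)
         else draw_observations(exp, rep(s, n_draws))
    P <- posterior_matrix(brain, E)
    rowMeans(mean_rate_matrix(code, P))
  }
  rates <- vapply(s_values, avg_rate, numeric(code$n_neurons))
  fprime <- (avg_rate(fprime_delta) - avg_rate(-fprime_delta)) / (2 * fprime_delta)
  # response SD at s = 0 including encoding noise
  E0 <- if (zero_noise) matrix(rep(experimenter_mean(exp, 0), n_sd_draws),
                               ncol = 2L, byrow = TRUE)
        else draw_observations(exp, rep(0, n_sd_draws))
  P0 <- posterior_matrix(brain, E0)
  R <- matrix(0, code$n_neurons, n_sd_draws)
  for (j in seq_len(n_sd_draws))
    R[, j] <- sample_response(code, probability_field(code$grid, P0[, j]))
  structure(list(s_values = s_values,
                 rates = matrix(rates, nrow = code$n_neurons),
                 fprime = fprime, sigma = apply(R, 1L, stats::sd)),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("tuning_curve: %d neurons at %d stimulus values; |f'| in [%.3g, %.3g]\n",
              nrow(x$rates), length(x$s_values), min(abs(x$fprime)),
              max(abs(x$fprime))))
  invisible(x)
}

#' @export
plot.tuning_curve <- function(x, neurons = seq_len(min(8L, nrow(x$rates))), ...) {
  graphics::matplot(x$s_values, t(x$rates[neurons, , drop = FALSE]), type = "l",
                    xlab = "s", ylab = "mean rate", ...)
  invisible(x)
}
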