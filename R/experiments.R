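#' Run the four-condition noise-filtering experiment
#'
#' Driver around \code{\link{noise_filtering_experiment}} that also reports the number
#' of conditions in which the fraction of posterior-density variance along
#' dp/ds increased after learning, and which condition (if any) decreased.
#'
#' @param profile \code{"tiny"}, \code{"reduced"} or \code{"full"}.
#' @param n_repeats Repeats per condition.
#' @param seed Base integer seed.
#' @return Object of class \code{experiment_result} with \code{id},
#'   \code{result} (the \code{noise_filtering_result}), \code{n_increased},
#'   \code{decreased_conditions}, \code{config}.
#' @export
run_noise_filtering <- function(profile = "reduced", n_repeats = 4L, seed = 1L) {
  res <- noise_filtering_experiment(profile = profile, n_repeats = n_repeats, seed = seed)
  dec <- res$summary[!res$summary$increased, c("coding", "precision")]
  structure(list(id = "noise_filtering_2x2", result = res,
                 n_increased = sum(res$summary$increased),
                 decreased_conditions = dec,
                 config = list(profile = profile, n_repeats = n_repeats,
                               seed = seed)),
            class = "experiment_result")
}

#' Run the V1 belief-spectrum experiment
#'
#' Simulates a cued task-switching V1 session on zero-signal (white noise)
#' trials and analyzes the eigenstructure of the noise-correlation matrix,
#' including a sensitivity sweep of the significant-component count over
#' shuffle-floor quantiles.
#'
#' @param n_neurons,n_trials Population and session size.
#' @param cue_reliability Cue validity in (0.5, 1].
#' @param n_shuffles Shuffles for the significance floor.
#' @param seed Integer seed.
#' @param sensitivity_quantiles Floor quantiles to report the significant
#'   count at.
#' @param ... Further arguments to \code{\link{v1_model}}.
#' @return Object of class \code{experiment_result} with the
#'   \code{belief_spectrum} in \code{result}, the \code{session}, and a
#'   \code{sensitivity} data.frame (quantile, n_significant).
#' @export
run_belief_spectrum <- function(n_neurons = 1024L, n_trials = 2000L,
                     cue_reliability = 0.8, n_shuffles = 100L, seed = 1L,
                     sensitivity_quantiles = c(0.9, 0.95, 0.99), ...) {
  model <- v1_model(n_neurons = n_neurons, cue_reliability = cue_reliability,
                    seed = seed, ...)
  session <- simulate_v1_session(model, n_trials = n_trials, seed = seed)
  spec <- belief_spectrum(session, n_shuffles = n_shuffles, seed = seed)
  sens <- data.frame(quantile = sensitivity_quantiles,
                     n_significant = vapply(sensitivity_quantiles, function(q) {
                       sum(spec$values > stats::quantile(spec$shuffle_max, q,
                                                         names = FALSE))
                     }, numeric(1)))
  structure(list(id = "v1_belief_spectrum", result = spec, session = session,
                 sensitivity = sens,
                 config = list(n_neurons = n_neurons, n_trials = n_trials,
                               cue_reliability = cue_reliability,
                               n_shuffles = n_shuffles, seed = seed)),
            class = "experiment_result")
}

#' Run the stimulus-belief proportionality sweeps
#'
#' Sweeps the delta-mixture parameters (delta_s, p0) on the 2-D grid model
#' and the category separation mu_x in the 1-D Gaussian-mixture demo,
#' reporting cosine alignments between the stimulus- and belief-derivatives
#' of the posterior and a monotonicity summary for the 1-D sweep.
#'
#' @param bins_per_dim Grid resolution for the 2-D model.
#' @param delta_s_list,p0_list 2-D sweep values.
#' @param mu_x_values 1-D demo category separations (swept downward).
#' @param seed Integer seed.
#' @return Object of class \code{experiment_result}: \code{result} holds
#'   \code{grid_sweep} (data.frame delta_s, p0, cosine), \code{demo_sweep}
#'   (mu_x, cosine) and \code{demo_monotone} (logical: cosine increases as
#'   mu_x decreases).
#' @export
run_proportionality <- function(bins_per_dim = 41L,
                                delta_s_list = c(0.01, 0.1, 0.5, 1),
                                p0_list = c(0.5, 0.9, 0.99),
                                mu_x_values = c(3, 2, 1, 0.5, 0.25),
                                seed = 1L) {
  grid <- latent_grid(2L, c(-5, 5), bins_per_dim)
  brain <- brain_model(grid, sigma_e2 = 0.36)
  sweep2d <- proportionality_experiment(brain, delta_s_list = delta_s_list,
                                        p0_list = p0_list, seed = seed)
  demo <- gaussian_mixture_demo(mu_x_values = mu_x_values)
  mono <- all(diff(demo$cosine[order(demo$mu_x, decreasing = TRUE)]) >= 0)
  structure(list(id = "proportionality", result = list(grid_sweep = sweep2d,
                                                       demo_sweep = demo,
                                                       demo_monotone = mono),
                 config = list(bins_per_dim = bins_per_dim, seed = seed)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment_result: %s\n", x$id))
  if (x$id == "noise_filtering_2x2") {
    print(x$result)
  } else if (x$id == "v1_belief_spectrum") {
    print(x$result)
    cat("sensitivity to the floor quantile:\n")
    print(x$sensitivity, row.names = FALSE)
  } else {
    print(x$result$grid_sweep, row.names = FALSE)
    print(x$result$demo_sweep, row.names = FALSE)
  }
  invisible(x)
}
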