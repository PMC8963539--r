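#' Draw a matrix of posterior mass vectors at a fixed stimulus
#'
#' Samples n_draws observations E ~ p_e(E | s) and returns the matrix of
#' normalized posterior mass vectors (n_cells x n_draws), the raw material
#' for posterior-density covariance estimates.
#'
#' @param brain A \code{brain_model}.
#' @param exp An \code{experimenter_model}.
#' @param s Stimulus value (default 0, the zero-signal condition).
#' @param n_draws Number of observation draws.
#' @param seed Optional integer seed.
#' @param E Optional precomputed n_draws x 2 observation matrix (reuse the
#'   same noise stream across priors).
#' @return n_cells x n_draws numeric matrix.
#' @export
posterior_draws <- function(brain, exp, s = 0, n_draws = 2000L, seed = NULL,
                            E = NULL) {
  if (is.null(E)) E <- draw_observations(exp, rep(s, n_draws), seed = seed)
  posterior_matrix(brain, E)
}

#' Trial-to-trial covariance of the posterior density
#'
#' Sample covariance, across observation draws at fixed s, of the posterior
#' mass at every pair of grid cells: Sigma_p[i, j] = cov(p(x_i | E),
#' p(x_j | E)).
#'
#' @inheritParams posterior_draws
#' @return Object of class \code{density_covariance}: list with \code{grid},
#'   \code{matrix} (n_cells x n_cells), \code{n_draws}.
#' @export
empirical_sigma_p <- function(brain, exp, s = 0, n_draws = 2000L, seed = NULL,
                              E = NULL) {
  stopifnot(is.null(E) || nrow(E) >= 2, n_draws >= 2)
  P <- posterior_draws(brain, exp, s, n_draws, seed, E)
  structure(list(grid = brain$grid, matrix = stats::cov(t(P)),
                 n_draws = ncol(P)),
            class = "density_covariance")
}

#' @export
print.density_covariance <- function(x, ...) {
  cat(sprintf("density_covariance: %d x %d over %d cells (%d draws)\n",
              nrow(x$matrix), ncol(x$matrix), x$grid$n_cells, x$n_draws))
  invisible(x)
}

#' Trial-to-trial covariance of the likelihood field
#'
#' As \code{\link{empirical_sigma_p}} but on the unnormalized likelihood mass
#' p_b(E | x) across observation draws at fixed s; this is the
#' task-independent noise covariance that the prior filters.
#'
#' @inheritParams posterior_draws
#' @return A \code{density_covariance} (field: likelihood).
#' @export
empirical_sigma_lh <- function(brain, exp, s = 0, n_draws = 2000L, seed = NULL,
                               E = NULL) {
  if (is.null(E)) E <- draw_observations(exp, rep(s, n_draws), seed = seed)
  L <- likelihood_matrix(brain, E)
  structure(list(grid = brain$grid, matrix = stats::cov(t(L)),
                 n_draws = ncol(L)),
            class = "density_covariance")
}

#' Prior-filtered likelihood covariance
#'
#' The first-order approximation to the posterior-density covariance:
#' diag(prior) %*% Sigma_LH %*% diag(prior), up to a proportionality
#' constant. Learning a task-specific prior "filters" the task-independent
#' likelihood noise, suppressing variability where the prior is small.
#'
#' @param prior Normalized \code{probability_field}.
#' @param lh_cov A \code{density_covariance} of the likelihood on the same
#'   grid.
#' @return A \code{density_covariance}.
#' @export
filtered_sigma <- function(prior, lh_cov) {
  stopifnot(same_grid(prior$grid, lh_cov$grid))
  p <- prior$mass
  m <- lh_cov$matrix * outer(p, p)
  structure(list(grid = prior$grid, matrix = m, n_draws = lh_cov$n_draws),
            class = "density_covariance")
}

#' Unit vector along the stimulus derivative of the posterior
#'
#' Normalizes the \code{\link{dposterior_ds}} field to unit length; the
#' direction in density space whose neural-space image is the differential
#' (f') direction.
#'
#' @inheritParams dposterior_ds
#' @return Unit-norm numeric vector over cells.
#' @export
dpds_direction <- function(brain, exp, delta_s = 0.01, n_draws = 1000L,
                           seed = NULL, zero_noise = FALSE, E_noise = NULL) {
  d <- dposterior_ds(brain, exp, delta_s, n_draws, seed,
                     zero_noise = zero_noise, E_noise = E_noise)$delta_mass
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) stop("zero derivative field")
  d / nrm
}

#' Fraction of density variance along a direction
#'
#' u' Sigma u / trace(Sigma): the relative variance of the posterior density
#' along the unit direction u. Accepts either a \code{density_covariance} or
#' a matrix of stored posterior draws (n_cells x n_draws), in which case the
#' quantity is computed streaming without materializing Sigma.
#'
#' @param u Unit vector over cells.
#' @param cov A \code{density_covariance}, or an n_cells x n_draws draw
#'   matrix.
#' @return Scalar in [0, 1].
#' @export
fraction_along <- function(u, cov) {
  u <- as.numeric(u)
  if (inherits(cov, "density_covariance")) {
    tr <- sum(diag(cov$matrix))
    if (tr <= 0) stop("zero-trace covariance")
    return(as.numeric(u %*% cov$matrix %*% u) / tr)
  }
  P <- cov
  stopifnot(is.matrix(P), nrow(P) == length(u), ncol(P) >= 2)
  n <- ncol(P)
  mu <- rowMeans(P)
  proj <- as.numeric(crossprod(P, u)) - sum(mu * u)
  num <- sum(proj^2) / (n - 1)
  tot <- (sum(P^2) - n * sum(mu^2)) / (n - 1)
  if (tot <= 0) stop("zero-trace covariance")
  num / tot
}

#' Leading eigenpairs of a density covariance
#' @param cov A \code{density_covariance}.
#' @param k Number of leading eigenpairs.
#' @return List with \code{values} and \code{vectors} (columns).
#' @export
top_eigen <- function(cov, k = 1L) {
  e <- eigen(cov$matrix, symmetric = TRUE)
  list(values = e$values[seq_len(k)], vectors = e$vectors[, seq_len(k), drop = FALSE])
}

#' Before/after-learning variance fractions along dp/ds (one condition)
#'
#' Runs the full noise-filtering experiment for one configuration: learn the
#' prior from uniform, then, using one shared set of zero-signal observation
#' draws, compute the fraction of posterior-density variance along the
#' dp/ds direction under the pre-learning (uniform) prior and under the
#' learned prior. Repeated \code{n_repeats} times with independent seeds.
#'
#' @param fixture An \code{experiment_fixture} from \code{\link{make_fixture}}
#'   (grid, models, schedule).
#' @param n_repeats Independent repetitions (default 4).
#' @param seed Base seed; repeat r uses seed + r - 1.
#' @return data.frame with one row per repeat: \code{repeat_},
#'   \code{fraction_before}, \code{fraction_after}.
#' @export
noise_filtering_condition <- function(fixture, n_repeats = 4L, seed = fixture$seed) {
  out <- data.frame(repeat_ = seq_len(n_repeats),
                    fraction_before = NA_real_, fraction_after = NA_real_)
  for (r in seq_len(n_repeats)) {
    rs <- seed + r - 1L
    sched <- fixture$schedule
    sched$seed <- rs
    brain0 <- fixture$brain     # uniform prior
    fit <- learn_prior(brain0, fixture$exp, sched, track_kl = FALSE)
    set.seed(rs + 10000L)
    E <- draw_observations(fixture$exp, rep(0, fixture$n_cov_draws))
    # shared zero-mean noise stream for the dp/ds estimates on both sides
    nd <- min(fixture$n_cov_draws, 1000L)
    E_noise <- matrix(stats::rnorm(2L * nd), ncol = 2L)
    for (phase in c("before", "after")) {
      b <- if (phase == "before") brain0 else fit$brain
      u <- dpds_direction(b, fixture$exp, delta_s = 0.01, E_noise = E_noise)
      P <- posterior_draws(b, fixture$exp, E = E)
      frac <- fraction_along(u, P)
      if (phase == "before") out$fraction_before[r] <- frac
      else out$fraction_after[r] <- frac
    }
  }
  out
}

#' Full four-condition noise-filtering experiment
#'
#' Runs \code{\link{noise_filtering_condition}} for the 2 x 2 design (mean- vs
#' covariance-coded stimulus dependence; precise vs imprecise brain
#' likelihood) and summarizes before/after variance fractions with SEM over
#' repeats.
#'
#' @param profile Grid/draw profile passed to \code{\link{make_fixture}}.
#' @param n_repeats Repeats per condition (default 4).
#' @param seed Base integer seed.
#' @return Object of class \code{noise_filtering_result}: list with \code{runs} (per
#'   repeat rows) and \code{summary} (per condition: mean/SEM fractions and
#'   the direction of change).
#' @export
noise_filtering_experiment <- function(profile = "reduced", n_repeats = 4L, seed = 1L) {
  conds <- expand.grid(coding = c("mean_coded", "covariance_coded"),
                       precision = c("precise", "imprecise"),
                       stringsAsFactors = FALSE)
  runs <- NULL
  for (i in seq_len(nrow(conds))) {
    fx <- make_fixture(profile, coding = conds$coding[i],
                       precision = conds$precision[i],
                       seed = seed + 100L * (i - 1L))
    res <- noise_filtering_condition(fx, n_repeats = n_repeats, seed = fx$seed)
    res$coding <- conds$coding[i]
    res$precision <- conds$precision[i]
    runs <- rbind(runs, res)
  }
  agg <- do.call(rbind, lapply(split(runs, list(runs$coding, runs$precision),
                                     drop = TRUE), function(d) {
    data.frame(coding = d$coding[1], precision = d$precision[1],
               fraction_before = mean(d$fraction_before),
               fraction_after = mean(d$fraction_after),
               sem_before = stats::sd(d$fraction_before) / sqrt(nrow(d)),
               sem_after = stats::sd(d$fraction_after) / sqrt(nrow(d)),
               increased = mean(d$fraction_after) > mean(d$fraction_before))
  }))
  rownames(agg) <- NULL
  structure(list(runs = runs, summary = agg, profile = profile, seed = seed),
            class = "noise_filtering_result")
}

#' @export
print.noise_filtering_result <- function(x, ...) {
  cat(sprintf("noise-filtering experiment (%s profile, seed %d)\n",
              x$profile, x$seed))
  print(x$summary, digits = 4)
  cat(sprintf("fraction increased after learning in %d of %d conditions\n",
              sum(x$summary$increased), nrow(x$summary)))
  invisible(x)
}
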