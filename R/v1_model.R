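# Windowed oriented grating on a square patch (column vector of pixels).
v1_grating <- function(patch, spatial_freq, ori, phase = 0, unit_norm = FALSE) {
  ax <- seq(-1, 1, length.out = patch)
  gx <- matrix(rep(ax, patch), patch, patch)
  gy <- t(gx)
  th <- ori * pi / 180
  u <- gx * cos(th) + gy * sin(th)
  win <- exp(-(gx^2 + gy^2) / (2 * 0.5^2))
  tpl <- as.numeric(win * cos(pi * spatial_freq * u + phase))
  if (unit_norm) tpl / sqrt(sum(tpl^2)) else tpl
}

#' Sampling-based sparse-coding V1 model under cued task switching
#'
#' A linear sparse-coding model of a V1 population: the image is explained as
#' a nonnegative combination of oriented grating projective fields plus pixel
#' noise, intensities carry exponential (sparse) priors, and inference is by
#' Gibbs sampling. Task context enters through the prior: in each of the two
#' contexts (cardinal: 0/90 deg; oblique: 45/135 deg) one of the context's
#' two orientations is expected, lowering the prior rate (raising expected
#' intensity) of neurons preferring it. The context and the expected side are
#' resampled each sweep jointly with the intensities, so uncertainty about
#' the task state produces trial-to-trial belief fluctuations. An unreliable
#' cue (correct with probability \code{cue_reliability}) sets the per-trial
#' prior over contexts.
#'
#' @param n_neurons Number of neurons; preferred orientations uniformly tile
#'   [0, 180).
#' @param patch Pixels per side of the square image patch.
#' @param spatial_freq Grating cycles across the patch (low values give broad
#'   orientation correlations).
#' @param pixel_noise_sd SD of the white pixel noise assumed by the model and
#'   used to generate zero-signal stimuli.
#' @param lambda0 Baseline exponential prior rate on intensities.
#' @param prior_boost Log-scale reduction of the prior rate at the expected
#'   orientation: rate = lambda0 * exp(-prior_boost * profile), so the most
#'   strongly expected neurons have their exponential-prior rate divided by
#'   exp(prior_boost).
#' @param prior_profile How task expectation falls off across neurons:
#'   \code{"overlap"} (default) uses each neuron's rectified, normalized
#'   feedforward response profile to the expected grating -- the
#'   self-consistent choice, since a learned prior mirrors the average
#'   stimulus-driven activity -- while \code{"gaussian"} uses a Gaussian bump
#'   of angular SD \code{prior_bw_deg} around the expected orientation.
#' @param prior_bw_deg Angular SD (degrees) of the Gaussian expectation bump
#'   (only for \code{prior_profile = "gaussian"}).
#' @param prior_sharpness Exponent applied to the overlap profile (only for
#'   \code{prior_profile = "overlap"}): higher values concentrate the
#'   expectation on strongly driven neurons, separating the four task states
#'   while preserving the profile's shape.
#' @param cue_reliability Probability that the pre-trial cue indicates the
#'   session's true context, in (0.5, 1].
#' @param session_context The session's true (more likely) context,
#'   \code{"cardinal"} or \code{"oblique"}.
#' @param n_burn,n_samples Gibbs sweeps discarded and retained per trial; the
#'   response is the sum of retained intensity samples.
#' @param state_update_every Sweeps between resamplings of the discrete task
#'   state. The default (n_burn + n_samples, i.e. one draw per trial) makes
#'   task beliefs persist on the trial timescale, the regime in which belief
#'   fluctuations appear as trial-to-trial covariability; setting it to 1
#'   resamples the state jointly with the intensities every sweep, letting
#'   the belief equilibrate within a trial and averaging its effect away.
#' @param seed Seed for the (deterministic) template phases.
#' @return Object of class \code{v1_model}.
#' @export
v1_model <- function(n_neurons = 1024L, patch = 16L, spatial_freq = 1.5,
                     pixel_noise_sd = 0.9, lambda0 = 4, prior_boost = 3,
                     prior_profile = c("overlap", "gaussian"),
                     prior_bw_deg = 20, prior_sharpness = 1,
                     cue_reliability = 0.8,
                     session_context = c("cardinal", "oblique"),
                     n_burn = 10L, n_samples = 20L,
                     state_update_every = n_burn + n_samples, seed = 1L) {
  prior_profile <- match.arg(prior_profile)
  session_context <- match.arg(session_context)
  stopifnot(n_neurons >= 4, patch >= 4, cue_reliability > 0.5,
            cue_reliability <= 1)
  theta <- (seq_len(n_neurons) - 1L) / n_neurons * 180
  set.seed(seed)
  # cosine-phase gratings: projective-field correlations then depend on the
  # orientation difference alone, so stimulus-driven covariance is organized
  # by preferred orientation
  A <- matrix(0, patch * patch, n_neurons)
  for (i in seq_len(n_neurons)) {
    A[, i] <- v1_grating(patch, spatial_freq, theta[i], unit_norm = TRUE)
  }
  contexts <- list(cardinal = c(0, 90), oblique = c(45, 135))
  # prior rate vectors for the 4 (context, side) combos
  ang_dist <- function(a, b) {
    d <- abs(a - b) %% 180
    pmin(d, 180 - d)
  }
  bumps <- matrix(0, n_neurons, 4L)
  combo <- expand.grid(side = 1:2, context = c("cardinal", "oblique"),
                       stringsAsFactors = FALSE)
  for (k in 1:4) {
    ori <- contexts[[combo$context[k]]][combo$side[k]]
    if (prior_profile == "overlap") {
      ov <- pmax(as.numeric(crossprod(A, v1_grating(patch, spatial_freq, ori))), 0)
      bumps[, k] <- (ov / max(ov))^prior_sharpness
    } else {
      bumps[, k] <- exp(-ang_dist(theta, ori)^2 / (2 * prior_bw_deg^2))
    }
  }
  # equalize total expectation mass across states: pixel-grid anisotropy
  # otherwise biases the state posterior (sum log lambda differs by state)
  bumps <- sweep(bumps, 2L, mean(colSums(bumps)) / colSums(bumps), "*")
  lambda <- lambda0 * exp(-prior_boost * bumps)
  structure(list(n_neurons = as.integer(n_neurons), patch = as.integer(patch),
                 theta = theta, A = A, G = crossprod(A),
                 pixel_noise_sd = pixel_noise_sd, lambda = lambda,
                 combo = combo, contexts = contexts,
                 lambda0 = lambda0, prior_boost = prior_boost,
                 prior_profile = prior_profile, prior_bw_deg = prior_bw_deg,
                 prior_sharpness = prior_sharpness,
                 cue_reliability = cue_reliability,
                 session_context = session_context,
                 n_burn = as.integer(n_burn), n_samples = as.integer(n_samples),
                 state_update_every = as.integer(state_update_every),
                 spatial_freq = spatial_freq, seed = as.integer(seed)),
            class = "v1_model")
}

#' @export
print.v1_model <- function(x, ...) {
  cat(sprintf(paste0("v1_model: %d neurons on a %dx%d patch, cue reliability ",
                     "%g, true context %s\n"),
              x$n_neurons, x$patch, x$patch, x$cue_reliability,
              x$session_context))
  invisible(x)
}

#' Simulate a session of zero-signal trials from the V1 model
#'
#' Presents independent white-noise images, one per trial; each trial a cue is
#' drawn (pointing at the session's true context with probability
#' \code{cue_reliability}), the cue sets the model's prior over contexts, and
#' the Gibbs sampler alternates between the discrete task state and the
#' intensities. The response of a neuron is the sum of its retained intensity
#' samples.
#'
#' @param model A \code{v1_model}.
#' @param n_trials Number of trials (>= 2).
#' @param seed Integer seed (controls images, cues and the sampler).
#' @return List of class \code{v1_session}: \code{counts} (n_trials x
#'   n_neurons), \code{cue} (context cued per trial), \code{state_freq}
#'   (fraction of retained sweeps per context/side combo), \code{model}.
#' @export
simulate_v1_session <- function(model, n_trials = 2000L, seed = 1L) {
  stopifnot(n_trials >= 2)
  set.seed(seed)
  n_pix <- model$patch^2
  images <- matrix(stats::rnorm(n_trials * n_pix, 0, model$pixel_noise_sd),
                   n_pix, n_trials)
  correct <- model$session_context
  other <- setdiff(c("cardinal", "oblique"), correct)
  cue <- ifelse(stats::runif(n_trials) < model$cue_reliability, correct, other)
  # model's prior over the 4 (side, context) combos given the cue: the cue is
  # known to be reliable with probability cue_reliability; sides equiprobable
  rel <- model$cue_reliability
  logprior <- matrix(0, n_trials, 4L)
  for (k in 1:4) {
    pc <- ifelse(model$combo$context[k] == cue, rel, 1 - rel)
    logprior[, k] <- log(pc / 2)
  }
  B <- crossprod(model$A, images) / model$pixel_noise_sd^2
  res <- gibbs_v1_session_cpp(model$G, B, model$pixel_noise_sd^2,
                              model$lambda, logprior,
                              model$n_burn, model$n_samples,
                              model$state_update_every)
  structure(list(counts = res$counts, cue = cue, state_freq = res$state_freq,
                 model = model, seed = as.integer(seed)),
            class = "v1_session")
}

#' @export
print.v1_session <- function(x, ...) {
  cat(sprintf("v1_session: %d trials x %d neurons (mean count %.2f)\n",
              nrow(x$counts), ncol(x$counts), mean(x$counts)))
  invisible(x)
}

#' Noise-correlation matrix of a count matrix
#'
#' Pearson correlations across trials; zero-variance neurons are excluded
#' with a warning.
#'
#' @param counts n_trials x n_neurons matrix (or a \code{v1_session}).
#' @return n x n correlation matrix with unit diagonal (attribute
#'   \code{kept}: indices of retained neurons).
#' @export
noise_correlation <- function(counts) {
  if (inherits(counts, "v1_session")) counts <- counts$counts
  v <- apply(counts, 2L, stats::var)
  keep <- which(v > 0)
  if (length(keep) < ncol(counts))
    warning(sprintf("excluding %d zero-variance neurons",
                    ncol(counts) - length(keep)))
  m <- stats::cor(counts[, keep, drop = FALSE])
  attr(m, "kept") <- keep
  m
}

#' Task f-prime template of a context
#'
#' The population response axis separating the context's two discriminanda:
#' the difference in mean response between noiseless gratings at the two
#' context orientations, measured with the model performing the cued task
#' (its context prior engaged), as tuning curves are measured in an
#' experiment. Estimated by repeated sampler runs per orientation. Positive
#' entries at neurons preferring the first orientation, negative at the
#' second; sums to zero; unit norm.
#'
#' @param model A \code{v1_model}.
#' @param context \code{"cardinal"} or \code{"oblique"}.
#' @param contrast Amplitude of the probe gratings.
#' @param n_avg Repeated sampler runs averaged per orientation.
#' @param seed Integer seed.
#' @return Numeric vector (n_neurons), unit norm.
#' @export
task_fprime_template <- function(model, context = c("cardinal", "oblique"),
                                 contrast = 2, n_avg = 20L, seed = 1L) {
  context <- match.arg(context)
  oris <- model$contexts[[context]]
  set.seed(seed)
  # cue-consistent prior over the four (side, context) states
  rel <- model$cue_reliability
  pc <- ifelse(model$combo$context == context, rel, 1 - rel)
  logprior <- matrix(rep(log(pc / 2), each = n_avg), n_avg, 4L)
  mean_resp <- function(ori) {
    img <- v1_grating(model$patch, model$spatial_freq, ori) * contrast
    B <- matrix(crossprod(model$A, img) / model$pixel_noise_sd^2,
                model$n_neurons, n_avg)
    # state resampled every sweep so the engaged expectation locks onto the
    # probe, as it does for a suprathreshold task stimulus
    res <- gibbs_v1_session_cpp(model$G, B, model$pixel_noise_sd^2,
                                model$lambda, logprior,
                                model$n_burn, model$n_samples, 1L)
    colMeans(res$counts)
  }
  d <- mean_resp(oris[1]) - mean_resp(oris[2])
  d <- d - mean(d)
  d / sqrt(sum(d^2))
}

# least-squares R^2 of a vector onto low-order sinusoids of preferred
# orientation (harmonics in 2*theta), used to label stimulus-driven PCs
sinusoid_r2 <- function(v, theta_deg, max_harmonic = 4L) {
  th <- theta_deg * pi / 180
  X <- cbind(1, do.call(cbind, lapply(seq_len(max_harmonic), function(k)
    cbind(cos(2 * k * th), sin(2 * k * th)))))
  fit <- stats::lm.fit(X, v)
  1 - sum(fit$residuals^2) / sum((v - mean(v))^2)
}

#' Eigenstructure of V1 noise correlations with belief-component labels
#'
#' Eigen-decomposes the zero-signal noise-correlation matrix, determines how
#' many leading components exceed a trial-shuffled significance floor (each
#' neuron's responses independently permuted across trials; the floor is the
#' 95th percentile of the largest shuffled eigenvalue), and labels each
#' significant component by cosine similarity to the two task f' templates
#' (difference-of-bumps at the context's orientations) or as stimulus-driven
#' when it is a low-order sinusoid of preferred orientation.
#'
#' @param session A \code{v1_session} (or a bare count matrix plus
#'   \code{model}).
#' @param n_shuffles Number of trial shuffles for the significance floor.
#' @param seed Integer seed for the shuffles.
#' @param template_threshold |cosine| above which a component is labeled as a
#'   belief direction.
#' @param quantile_level Quantile of the shuffled largest eigenvalue used as
#'   the floor (default 0.95).
#' @param model Required if \code{session} is a bare matrix.
#' @return Object of class \code{belief_spectrum}: \code{values} (descending
#'   eigenvalues), \code{vectors}, \code{floor}, \code{n_significant},
#'   \code{labels}, \code{align_cardinal}, \code{align_oblique} (max
#'   |cosine| over significant components with each template),
#'   \code{templates}, \code{theta}.
#' @export
belief_spectrum <- function(session, n_shuffles = 100L, seed = 1L,
                            template_threshold = 0.5, quantile_level = 0.95,
                            model = NULL) {
  if (inherits(session, "v1_session")) {
    counts <- session$counts
    model <- session$model
  } else {
    counts <- session
    stopifnot(!is.null(model))
  }
  corr <- noise_correlation(counts)
  kept <- attr(corr, "kept")
  theta <- model$theta[kept]
  e <- eigen(corr, symmetric = TRUE)
  set.seed(seed)
  n <- nrow(counts)
  shuf_max <- numeric(n_shuffles)
  for (b in seq_len(n_shuffles)) {
    shuffled <- apply(counts[, kept, drop = FALSE], 2L, sample)
    shuf_max[b] <- max(eigen(stats::cor(shuffled), symmetric = TRUE,
                             only.values = TRUE)$values)
  }
  floor_val <- stats::quantile(shuf_max, quantile_level, names = FALSE)
  n_sig <- sum(e$values > floor_val)
  tpl_c <- task_fprime_template(model, "cardinal", seed = seed)[kept]
  tpl_o <- task_fprime_template(model, "oblique", seed = seed)[kept]
  tpl_c <- tpl_c / sqrt(sum(tpl_c^2)); tpl_o <- tpl_o / sqrt(sum(tpl_o^2))
  labels <- character(n_sig)
  ac <- ao <- 0
  for (j in seq_len(n_sig)) {
    v <- e$vectors[, j]
    cc <- abs(sum(v * tpl_c)); co <- abs(sum(v * tpl_o))
    ac <- max(ac, cc); ao <- max(ao, co)
    dc <- abs(mean(v)) * sqrt(length(v))  # loading on the uniform direction
    if (cc >= template_threshold && cc >= co) labels[j] <- "cardinal_belief"
    else if (co >= template_threshold) labels[j] <- "oblique_belief"
    else if (dc > 0.7 || sinusoid_r2(v, theta) > 0.5) labels[j] <- "stimulus_driven"
    else labels[j] <- "noise"
  }
  structure(list(values = e$values, vectors = e$vectors, floor = floor_val,
                 n_significant = n_sig, labels = labels,
                 align_cardinal = ac, align_oblique = ao,
                 templates = list(cardinal = tpl_c, oblique = tpl_o),
                 theta = theta, shuffle_max = shuf_max,
                 quantile_level = quantile_level),
            class = "belief_spectrum")
}

#' @export
print.belief_spectrum <- function(x, ...) {
  cat(sprintf("belief_spectrum: %d significant components (floor %.3f)\n",
              x$n_significant, x$floor))
  if (x$n_significant > 0) {
    for (j in seq_len(x$n_significant))
      cat(sprintf("  PC%d: eigenvalue %.3f, %s\n", j, x$values[j], x$labels[j]))
  }
  cat(sprintf("  max |cos| with cardinal f': %.3f, oblique f': %.3f\n",
              x$align_cardinal, x$align_oblique))
  invisible(x)
}

#' @export
plot.belief_spectrum <- function(x, n_pc = min(5L, length(x$values)), ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(x$values[seq_len(20)], xlab = "rank", ylab = "eigenvalue", ...)
  graphics::abline(h = x$floor, lty = 2)
  graphics::matplot(x$theta, x$vectors[, seq_len(n_pc)], type = "l",
                    xlab = "preferred orientation (deg)", ylab = "PC weight")
  invisible(x)
}
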