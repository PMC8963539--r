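# Small shared fixtures for fast tests. All grids here are deliberately
# coarse; the full study configurations are exercised in test-acceptance.R.

tiny_grid_2d <- function(bins = 15L) latent_grid(2L, c(-5, 5), bins)
tiny_grid_1d <- function(bins = 101L) latent_grid(1L, c(-5, 5), bins)

tiny_brain <- function(bins = 15L, sigma_e2 = 0.36) {
  brain_model(tiny_grid_2d(bins), sigma_e2 = sigma_e2)
}

delta_exp <- function(p0 = 0.9, delta_s = 0.01, coding = "mean_coded") {
  experimenter_model(coding,
                     ensemble = stimulus_ensemble("delta_mixture", p0 = p0,
                                                  delta_s = delta_s))
}

# deterministic 3-cell setting for hand-computed Bayes checks
grid3 <- function() latent_grid(1L, c(0, 3), 3L)
field3 <- function(mass, normalized = TRUE) {
  probability_field(grid3(), mass, normalized = normalized)
}
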