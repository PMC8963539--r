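# beliefcov

Simulation and analysis toolkit for studying how Bayesian learning and
inference shape correlated variability in sensory neural populations.

## The scientific problem

When an observer learns a discrimination task, feedback of their
trial-by-trial category belief π = p(C = 1 | …) to sensory populations, and
the "filtering" of sensory noise by a learned task prior, both leave
signatures in neural covariability. Under the hypothesis that sensory
responses encode posterior beliefs p(**x** | **E**, π) over latent variables
**x**, a learned (self-consistent) model satisfies *prior = average
posterior*, which forces a symmetry between stimulus-driven and
belief-driven changes in the posterior:

    d p(x|·)/dπ  ∝~  d p(x|·)/ds        (at the category boundary)

so belief fluctuations add covariance along **f′f′**ᵀ ("differential
correlations", Σ ≈ Σ_intrinsic + α² var(π) **f′f′**ᵀ) and a top-down
component of choice probability proportional to d′ᵢ = f′ᵢ/σᵢ. A second
mechanism needs no belief variability at all: the posterior-density
covariance across trials is, to first order, the likelihood covariance
filtered by the prior, diag(p) Σᴸᴴ diag(p), so learning a task prior
reshapes noise. The package implements all of this on discretized latent
grids, learns priors by gradient descent on KL(p_e(**E**) ‖ p_b(**E**)) −
λH(p), encodes posteriors in spike counts through linear and nonlinear
distributional codes (with the Linear Distributional Code mixture test),
computes the decision statistics (CTA, choice probability, d′, covariance
decompositions), and includes a Gibbs-sampling sparse-coding V1 model whose
zero-signal noise-correlation eigenstructure reveals internal task beliefs
under cued task switching.

Audience: computational neuroscientists simulating or testing
posterior-coding accounts of task-dependent neural covariability.

## Worked example

Learning a task prior and measuring how it filters posterior-density noise
(the four-condition experiment; 41 bins/dim profile, 4 repeats):

```r
library(beliefcov)
nf <- run_noise_filtering(profile = "reduced", n_repeats = 4, seed = 1)
print(nf)
#> noise-filtering experiment (reduced profile, seed 1)
#>             coding precision fraction_before fraction_after sem_before sem_after increased
#> 1 covariance_coded imprecise         0.07952        0.07844  0.0018345  0.001471     FALSE
#> 2       mean_coded imprecise         0.24860        0.62679  0.0017519  0.032965      TRUE
#> 3 covariance_coded   precise         0.02901        0.03089  0.0018029  0.001907      TRUE
#> 4       mean_coded   precise         0.05383        0.05731  0.0006416  0.000843      TRUE
#> fraction increased after learning in 3 of 4 conditions
```

The numbers are the fraction of trial-to-trial posterior-density variance
lying along the dp/ds direction before and after prior learning. Learning
concentrates noise along the stimulus direction (differential correlations)
in three conditions; when the stimulus is covariance-coded and the brain's
likelihood is imprecise the fraction instead decreases slightly.

Inferring internal task beliefs from simulated V1 responses (256 neurons,
2000 zero-signal white-noise trials, 80/20 context cue):

```r
bs <- run_belief_spectrum(n_neurons = 256, n_trials = 2000, seed = 1)
print(bs$result)
#> belief_spectrum: 5 significant components (floor 1.851)
#>   PC1: eigenvalue 13.351, cardinal_belief
#>   PC2: eigenvalue 9.723, oblique_belief
#>   PC3: eigenvalue 6.803, stimulus_driven
#>   PC4: eigenvalue 2.644, stimulus_driven
#>   PC5: eigenvalue 2.215, stimulus_driven
#>   max |cos| with cardinal f': 0.984, oblique f': 0.980
```

Five principal components exceed the trial-shuffle significance floor: one
aligned with each task's f′ template (fluctuating beliefs about the cued
and the alternative task), a global image-energy component, and a
stimulus-driven sinusoidal quadrature pair.

Other entry points: `learn_prior()` (the fitting routine; returns a classed
object with `print`/`plot`/`coef` methods), `learned_category_priors()`,
`dposterior_ds()`/`dposterior_dpi()`/`alignment()`,
`empirical_sigma_p()`/`filtered_sigma()`/`fraction_along()`,
`distributional_code()`/`ldc_mixture_gap()`/`tuning_curve()`,
`simulate_session()`/`cta()`/`choice_probability()`/
`covariance_decomposition()`, and `run_proportionality()`. The methods
vignette (`vignettes/belief-covariability-methods.Rmd`) documents the
models, parameter choices and limitations.

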