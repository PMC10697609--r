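# Shared fixtures, built in code at test time.

# Cohort of deterministic (noise-free) Bayesian observers with spread-out
# subjective variances: responses are an exact linear function of the
# perceived centroid, so estimators must recover generating values exactly.
zero_noise_spec <- function(n = 10, seed = 42, sigma_between = 0.5,
                            beta_prior = 0.3, beta_lik = 0.1) {
  cohort_spec(n_participants = n, beta_prior = beta_prior,
              beta_lik = beta_lik, sigma_between = sigma_between,
              perceptual_noise_sd = 0, motor_noise_sd = 0, lapse_rate = 0,
              seed = seed)
}

quiet_fit <- function(...) suppressMessages(coin_fit(...))

# Independent oracle: posterior mean of a Gaussian prior x Gaussian
# likelihood by dense numerical integration (never uses the package's
# closed form).
posterior_mean_numeric <- function(mu_L, mu_P, prior_var, lik_var,
                                   half = 6, n_grid = 200001) {
  x <- seq(mu_P - half, mu_L + half, length.out = n_grid)
  w <- exp(-(x - mu_P)^2 / (2 * prior_var) - (x - mu_L)^2 / (2 * lik_var))
  sum(x * w) / sum(w)
}

# Generating sensory weights of every observer in a cohort, as a matrix
# (participants x condition codes), straight from the stored parameters.
generating_sw_matrix <- function(cohort) {
  t(vapply(cohort$observers, function(o) o$sw_gen, numeric(4)))
}
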