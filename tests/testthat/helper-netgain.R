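# Shared fixtures and independent oracles.

# Analysis table from a synthetic config, messages silenced.
make_table <- function(config, seed, required = NULL) {
  tr <- simulate_trial(config, seed = seed)
  if (is.null(required)) required <- range(config$visit_weeks)
  tab <- suppressMessages(to_analysis_table(complete_cases(tr, required)))
  tab
}

# Near-noise-free configuration: deterministic mean structure.
quiet_config <- function(...) {
  synthetic_config(random_intercept_sd = 1e-8, residual_sd = 1e-8,
                   weight_effect = 0, ...)
}

# Independent brute-force Nadaraya-Watson smoother (loop arithmetic only;
# gaussian kernel on the standardized scale).
brute_nw <- function(x_grid, X, Y, h, standardize = TRUE) {
  s <- if (standardize) sqrt(sum((X - mean(X))^2) / (length(X) - 1)) else 1
  out <- numeric(length(x_grid))
  for (g in seq_along(x_grid)) {
    num <- 0
    den <- 0
    for (i in seq_along(X)) {
      u <- (x_grid[g] - X[i]) / (h * s)
      kv <- exp(-0.5 * u * u)
      num <- num + kv * Y[i]
      den <- den + kv
    }
    out[g] <- num / den
  }
  out
}

# Hand-rolled arm_model with chosen coefficients and covariance, for
# exact-arithmetic checks of the contrast machinery.
fake_arm_model <- function(arm, coefficients, covariance = NULL,
                           final_week = 12) {
  if (is.null(covariance)) {
    covariance <- matrix(0, length(coefficients), length(coefficients),
                         dimnames = list(names(coefficients),
                                         names(coefficients)))
  }
  structure(list(arm = arm, coefficients = coefficients,
                 covariance = covariance, residual_variance = 0,
                 n = 100, final_week = final_week,
                 design_descriptor = "synthetic", fit = NULL, data = NULL),
            class = "arm_model")
}

# Draws from a multivariate normal via the Cholesky factor.
rmvn <- function(n, mean, cov) {
  p <- length(mean)
  z <- matrix(rnorm(n * p), n, p)
  sweep(z %*% chol(cov), 2, mean, "+")
}

zero_profile <- list(age = 0, sexfemale = 0, body_size = 0)
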