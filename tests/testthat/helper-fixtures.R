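# Shared fixtures and independent oracles, all built in code.

# Small, fast generator configuration for unit tests.
tiny_config <- function(n_per_class = 6, n_replicates = 2, seed = 42,
                        noise_sd = 0.01, n_points = 300, ...) {
  generator_config(
    grid = make_grid(4000, 11000, n_points),
    n_per_class = n_per_class, n_replicates = n_replicates,
    noise_sd = noise_sd, seed = seed, ...
  )
}

# Noise- and drift-free configuration (fully separable classes).
clean_config <- function(n_per_class = 6, n_points = 300, seed = 7) {
  generator_config(
    grid = make_grid(4000, 11000, n_points),
    baseline = list(offset_sd = 0, slope_sd = 0, curvature_sd = 0),
    noise_sd = 0, amplitude_jitter_sd = 0, scale_jitter_sd = 0,
    n_per_class = n_per_class, n_replicates = 1, seed = seed
  )
}

# Exhaustive maximum over all injective row -> column assignments
# (rows may stay unmatched), the independent matching oracle.
brute_force_matching <- function(F) {
  r <- nrow(F); cls <- seq_len(ncol(F))
  best <- 0
  rec <- function(i, used, acc) {
    if (i > r) {
      best <<- max(best, acc)
      return(invisible())
    }
    rec(i + 1L, used, acc)
    for (j in setdiff(cls, used)) rec(i + 1L, c(used, j), acc + F[i, j])
  }
  rec(1L, integer(0), 0)
  best
}

# Lower convex envelope by brute force: at each grid point the envelope
# equals the minimum over all chords between data points spanning it.
brute_force_lower_envelope <- function(x, y) {
  n <- length(x)
  vapply(seq_len(n), function(t) {
    vals <- c()
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (x[i] <= x[t] && x[t] <= x[j]) {
          vals <- c(vals, if (i == j) y[i] else {
            y[i] + (y[j] - y[i]) * (x[t] - x[i]) / (x[j] - x[i])
          })
        }
      }
    }
    min(vals)
  }, numeric(1))
}

# Central finite difference of fun at params[[nm]][idx].
finite_diff <- function(fun, params, nm, idx, eps = 1e-6) {
  p1 <- params; p1[[nm]][idx] <- p1[[nm]][idx] + eps
  p2 <- params; p2[[nm]][idx] <- p2[[nm]][idx] - eps
  (fun(p1) - fun(p2)) / (2 * eps)
}

# Random smooth test spectrum: a few Gaussian bumps plus noise.
random_spectrum <- function(n = 80) {
  x <- seq(0, 1, length.out = n)
  y <- numeric(n)
  for (k in seq_len(3)) {
    y <- y + runif(1, 0.2, 1) * exp(-0.5 * ((x - runif(1)) / 0.08)^2)
  }
  y + rnorm(n, 0, 0.02)
}
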