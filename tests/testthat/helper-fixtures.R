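# Shared fixtures, built once per test run. Sizes are deliberately small so
# module tests stay fast; the acceptance suite builds its own full-scale
# fixtures.

fast_mcmc <- function(seed = 1L) mcmc_config(6000, 1000, 5, seed = seed)

# A compact simulated survey: 15 catch years, 8 species (two drifting
# uphill, one downhill, one unresponsive tundra specialist).
small_species_set <- function() {
  dplyr::bind_rows(
    species_config("spA", 600, 375, 40, 1.0, 195, 10,
                   genus = "GenusA", family = "FamA", superfamily = "SfA"),
    species_config("spB", 300, 385, 40, 1.0, 205, 12,
                   genus = "GenusA", family = "FamA", superfamily = "SfA"),
    species_config("spC", 400, 360, 35, 0, 190, 9,
                   genus = "GenusB", family = "FamA", superfamily = "SfA"),
    species_config("spD", 250, 400, 40, 0, 210, 11,
                   genus = "GenusB", family = "FamB", superfamily = "SfA"),
    species_config("spE", 150, 470, 40, 0, 200, 10, climate_response = 0,
                   genus = "GenusC", family = "FamB", superfamily = "SfB"),
    species_config("spF", 200, 420, 40, -0.5, 215, 12,
                   genus = "GenusC", family = "FamB", superfamily = "SfB"),
    species_config("spG", 100, 350, 30, 0, 185, 8,
                   genus = "GenusD", family = "FamC", superfamily = "SfB"),
    species_config("spH", 15, 390, 45, 0, 200, 10,
                   genus = "GenusD", family = "FamC", superfamily = "SfB")
  )
}

small_weather <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_weather(weather_config(n_years = 17, seed = 71))
    }
    cache
  }
})

small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_catches(small_weather(), species = small_species_set(),
                                 seed = 72)
    }
    cache
  }
})

small_metrics <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- season_metrics(small_weather())
    cache
  }
})

# Closed-form OLS slope/SE/t/p, the textbook oracle for trend_regression.
ols_oracle <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  e <- y - a - b * x
  s2 <- sum(e^2) / (n - 2)
  se <- sqrt(s2 / sum((x - mean(x))^2))
  t <- b / se
  list(slope = b, se = se, t = t, p = 2 * pt(-abs(t), n - 2))
}

# Exhaustive constrained least squares over all partitions of 1..n into
# consecutive blocks with non-decreasing block means: the brute-force
# oracle for the pool-adjacent-violators fit.
isotonic_brute <- function(y) {
  n <- length(y)
  best <- NULL
  best_sse <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    means <- numeric(length(bounds) - 1)
    fit <- numeric(n)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      means[b] <- mean(y[idx])
      fit[idx] <- means[b]
    }
    if (is.unsorted(means)) next
    sse <- sum((y - fit)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}
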