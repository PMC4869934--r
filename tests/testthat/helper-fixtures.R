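# Shared fixtures: small, fast configurations used across test files.

# tiny treated population with full ODE traces
tiny_population <- function(n = 6, seed = 101, ...) {
  generate_population(population_config(n_cells = n, seed = seed, ...))
}

# duration-only population (no ODE) for cycle-timing tests
duration_population <- function(n, seed, dose = 1, ...) {
  generate_population(population_config(
    n_cells = n, seed = seed, dose_scale = dose,
    simulate_traces = FALSE, fucci = FALSE, ...))
}

# equilibrated base-model state, cached per session
base_equilibrium <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      eq <- equilibrate(nfkb_model("base"), horizon = 40000,
                        tol = 1e-6)
      cache <<- eq
    }
    cache
  }
})

# brute-force Kruskal-Wallis H via the explicit rank-sum formula with
# tie correction, independent of the implementation under test
oracle_kruskal_H <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (N + 1)
  tie <- table(x)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# brute-force Dunn z for one pair by direct formula
oracle_dunn_z <- function(groups, i, j) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  tie <- table(x)
  tt <- sum(tie^3 - tie) / (12 * (N - 1))
  ni <- lengths(groups)
  (rbar[i] - rbar[j]) /
    sqrt((N * (N + 1) / 12 - tt) * (1 / ni[i] + 1 / ni[j]))
}

# brute-force Theil-Sen slope by full pairwise enumeration
oracle_theil_sen <- function(x, y) {
  sl <- c()
  for (i in seq_along(x)) for (j in seq_along(x)) {
    if (j > i && x[j] != x[i])
      sl <- c(sl, (y[j] - y[i]) / (x[j] - x[i]))
  }
  median(sl)
}
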