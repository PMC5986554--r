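# Independent oracles used across tests. These never call the code paths
# they check.

# Closed form evaluated naively in the growing-exponential parameterization
# (safe only for moderate exponents; that is the point of the comparison).
naive_fraction <- function(k, rho, t) {
  ex <- exp((1 + rho) * k * t)
  rho * (ex - 1) / (1 + rho * ex)
}

# Brute-force tangent-at-maximum-slope lag construction on a dense grid.
numeric_lag <- function(k, rho, t_max = NULL, n = 200001L) {
  if (is.null(t_max)) t_max <- 4 * log((1 + 2 * rho) / rho) / ((1 + rho) * k)
  t <- seq(0, t_max, length.out = n)
  f <- naive_fraction(k, rho, pmin(t, 700 / ((1 + rho) * k)))
  mid <- (t[-1] + t[-length(t)]) / 2
  slopes <- diff(f) / diff(t)
  i <- which.max(slopes)
  fm <- (f[i] + f[i + 1]) / 2
  max(0, mid[i] - fm / slopes[i])
}

# Exact half-away-from-zero rounding via string formatting is unreliable;
# use integer arithmetic.
round2_away <- function(x) sign(x) * floor(abs(x) * 100 + 0.5) / 100

make_fraction_grid <- function(k, rho, n = 25L, t_end = 48 * 3600) {
  t <- seq(0, t_end, length.out = n)
  fraction_curve(t, fibril_fraction(reduced_params(k, rho), t))
}
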