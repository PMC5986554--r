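test_that("reduce_rates computes k = ke*a and rho = kn/(ke*a)", {
  # packaged control condition: kn = 3.73e-6 /s, ke = 3.378 L/mol/s, a = 80 uM
  p <- reduce_rates(kinetic_rates(kn = 3.73e-6, ke = 3.378, a = 80e-6))
  expect_equal(p$k, 3.378 * 80e-6, tolerance = 1e-14)
  expect_equal(p$rho, 3.73e-6 / (3.378 * 80e-6), tolerance = 1e-14)

  # 7-ketocholesterol condition
  p7 <- reduce_rates(kinetic_rates(kn = 4.4e-6, ke = 1.227, a = 80e-6))
  expect_equal(p7$k, 1.227 * 80e-6, tolerance = 1e-14)
  expect_equal(p7$rho, 4.4e-6 / (1.227 * 80e-6), tolerance = 1e-14)

  # identity case
  p1 <- reduce_rates(kinetic_rates(1, 1, 1))
  expect_equal(p1$k, 1)
  expect_equal(p1$rho, 1)
})

test_that("constructors reject non-positive fields", {
  expect_error(kinetic_rates(0, 1, 1), "kn")
  expect_error(kinetic_rates(1, -2, 1), "ke")
  expect_error(kinetic_rates(1, 1, 0), "'a'")
  expect_error(reduced_params(0, 1), "'k'")
  expect_error(reduced_params(1, 0), "rho")
  expect_error(expand_params(reduced_params(1, 1), 0), "'a'")
})

test_that("expand_params inverts reduce_rates to machine precision", {
  expect_equal(unclass(expand_params(reduced_params(1, 1), 1)),
               list(kn = 1, ke = 1, a = 1))
  # round trip over the four packaged conditions
  consts <- abeta_rate_constants()
  for (i in seq_len(nrow(consts))) {
    r <- kinetic_rates(consts$kn_per_s[i], consts$ke_per_mol_s[i], 80e-6)
    back <- expand_params(reduce_rates(r), r$a)
    expect_equal(back$kn, r$kn, tolerance = 1e-12)
    expect_equal(back$ke, r$ke, tolerance = 1e-12)
  }
  # forward from reduced values recovers the control constants
  k <- 3.378 * 80e-6
  r <- expand_params(reduced_params(k, 3.73e-6 / k), 80e-6)
  expect_equal(r$kn, 3.73e-6, tolerance = 1e-12)
  expect_equal(r$ke, 3.378, tolerance = 1e-12)
})

test_that("fibril_fraction satisfies boundary, saturation and half-rise identities", {
  p <- reduced_params(k = 1e-4, rho = 0.02)
  expect_identical(fibril_fraction(p, 0), 0)
  # saturation: exponent >= 700 must not overflow and must sit at 1
  t_big <- 701 / ((1 + p$rho) * p$k)
  expect_equal(fibril_fraction(p, t_big), 1, tolerance = 1e-12)
  expect_equal(fibril_fraction(p, 1e12), 1, tolerance = 1e-12)
  # closed-form inversion: f = 1/2 at t50
  t50 <- log((1 + 2 * p$rho) / p$rho) / ((1 + p$rho) * p$k)
  expect_equal(fibril_fraction(p, t50), 0.5, tolerance = 1e-12)
  # agrees with the naive growing-exponential form where that is safe
  t <- seq(0, 20 / p$k, length.out = 50)
  expect_equal(fibril_fraction(p, t), naive_fraction(p$k, p$rho, t),
               tolerance = 1e-12)
  expect_error(fibril_fraction(p, -1), "t")
})

test_that("fibril_fraction is monotone and in [0,1) on random parameter grids", {
  set.seed(11)
  for (i in 1:25) {
    p <- reduced_params(k = 10^runif(1, -6, -3), rho = 10^runif(1, -4, 0))
    t <- sort(runif(60, 0, 48 * 3600))
    f <- fibril_fraction(p, t)
    expect_true(all(f >= 0 & f <= 1))  # saturates to 1 at double precision
    expect_true(all(diff(f) >= 0))
  }
})

test_that("ode oracle matches the closed form and handles edge cases", {
  p <- reduced_params(k = 1e-4, rho = 0.01)
  t <- seq(0, 48 * 3600, length.out = 50)
  oc <- ode_oracle(p, t, rel_tol = 1e-8)
  expect_equal(oc$fraction, fibril_fraction(p, t), tolerance = 1e-6)
  expect_lt(max(abs(oc$fraction - fibril_fraction(p, t))), 1e-6)
  # times = [0] returns the initial condition
  expect_equal(ode_oracle(p, 0)$fraction, 0)
  # rho = 0 limit: no nucleation, autocatalysis never seeds, f stays 0.
  # reduced_params requires rho > 0, so integrate the rate law directly.
  rhs <- function(t, y, parms) list(parms$k * (1 - y[1]) * (parms$rho + y[1]))
  sol <- deSolve::ode(c(f = 0), t, rhs, list(k = 1e-4, rho = 0),
                      rtol = 1e-10, atol = 1e-12)
  expect_equal(max(abs(sol[, "f"])), 0)
  expect_error(ode_oracle(p, c(3, 1)), "increasing")
  expect_error(ode_oracle(p, t, rel_tol = 1), "rel_tol")
})

test_that("half_time matches algebra and scales inversely with k", {
  # rho = 1: t50 = ln(3) / (2k)
  expect_equal(half_time(reduced_params(k = 5e-4, rho = 1)),
               log(3) / (2 * 5e-4), tolerance = 1e-12)
  p <- reduced_params(k = 2.3e-4, rho = 0.07)
  expect_equal(fibril_fraction(p, half_time(p)), 0.5, tolerance = 1e-12)
  expect_equal(half_time(reduced_params(2 * p$k, p$rho)), half_time(p) / 2,
               tolerance = 1e-12)
  # rho -> 0 at fixed k: half time grows monotonically without bound
  rhos <- 10^seq(-1, -8, by = -1)
  t50s <- vapply(rhos, function(r) half_time(reduced_params(1e-4, r)), 0)
  expect_true(all(diff(t50s) > 0))
})

test_that("lag_time follows the tangent construction and respects rho >= 1", {
  for (case in list(c(1e-4, 0.001), c(3e-4, 0.01), c(5e-5, 0.05))) {
    k <- case[1]; rho <- case[2]
    expect_equal(lag_time(reduced_params(k, rho)), numeric_lag(k, rho),
                 tolerance = 1e-3)
  }
  expect_true(is.na(lag_time(reduced_params(1e-4, 1))))
  expect_true(is.na(lag_time(reduced_params(1e-4, 2.5))))
  # lag < half time whenever defined
  set.seed(21)
  for (i in 1:20) {
    p <- reduced_params(10^runif(1, -6, -3), 10^runif(1, -4, -0.05))
    expect_lt(lag_time(p), half_time(p))
  }
  # clamped at zero for rho near 1
  expect_gte(lag_time(reduced_params(1e-4, 0.999)), 0)
})

test_that("fraction_curve and tht_timecourse validate their contracts", {
  expect_error(fraction_curve(c(0, 1), c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(fraction_curve(c(1, 0), c(0, 0.5)), "increasing")
  expect_error(fraction_curve(c(0, 1), 0.5), "equal length")
  expect_error(tht_timecourse(c(0, 3600), c(-1, 5)), ">= 0")
  tc <- tht_timecourse(c(0, 3600), c(2, 5), condition = "Chol", replicate = "2")
  expect_identical(attr(tc, "condition"), "Chol")
  expect_equal(hours_to_seconds(1.5), 5400)
})
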