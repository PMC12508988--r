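test_that("eigenvalues match closed-form special cases and reject bad input", {
  e <- eigenvalues(1, 0.01)
  expect_equal(e$lambda1, 1.1, tolerance = 1e-12)
  expect_equal(e$lambda2, 0.9, tolerance = 1e-12)
  e <- eigenvalues(2, 1)
  expect_equal(e$lambda1, 3, tolerance = 1e-12)
  expect_equal(e$lambda2, 0, tolerance = 1e-12)
  e <- eigenvalues(0, 0.5)
  expect_equal(e$lambda1, 1, tolerance = 1e-12)
  expect_equal(e$lambda2, 0, tolerance = 1e-12)
  expect_error(eigenvalues(-0.1, 0.5), "must be finite and >= 0")
  expect_error(eigenvalues(1, -0.5), ">= 0")
})

test_that("eigenvalue pair satisfies the Vieta identities over random draws", {
  set.seed(42)
  s <- stats::runif(1e4, 0, 5)
  sig <- stats::runif(1e4, 0, 1)
  worst_sum <- 0; worst_prod <- 0
  for (i in seq_along(s)) {
    e <- eigenvalues(s[i], sig[i])
    worst_sum <- max(worst_sum, abs(e$lambda1 + e$lambda2 - (1 + s[i])))
    worst_prod <- max(worst_prod,
                      abs(e$lambda1 * e$lambda2 - s[i] * (1 - sig[i])))
  }
  expect_lt(worst_sum, 1e-12)
  expect_lt(worst_prod, 1e-12)
})

test_that("stability parameter: zero energies give zero, and the frozen
           arbitrary-precision regression value is reproduced", {
  p0 <- zb_params(t0 = 200, h = 0, hps = 0, Q = 7, q = 16)
  expect_equal(stability_parameter(c(250, 300, 400), p0), rep(0, 3))
  p <- zb_params(t0 = 200, h = 4000, hps = 4500, Q = 100, q = 16)
  expect_equal(stability_parameter(300, p), STILDE_REF, tolerance = 1e-12)
  expect_error(stability_parameter(150, p), "must exceed t0")
  # bounded below by -1/Q (squared-reciprocal bracket is >= 0)
  pneg <- zb_params(t0 = 200, h = 1000, hps = 8000, Q = 50, q = 16)
  svals <- stability_parameter(seq(201, 500, by = 1), pneg)
  expect_true(all(svals >= -1 / 50))
})

test_that("solvent occupancy: 1/q at zero energy, saturates at 1, matches
           the frozen regression value", {
  p0 <- zb_params(t0 = 200, h = 0, hps = 0, Q = 10, q = 16)
  expect_equal(solvent_occupancy(300, p0), 1 / 16, tolerance = 1e-14)
  pbig <- zb_params(t0 = 200, h = 0, hps = 1e5, Q = 10, q = 16)
  expect_equal(solvent_occupancy(210, pbig), 1, tolerance = 1e-12)
  p <- zb_params(t0 = 200, h = 4000, hps = 4500, Q = 100, q = 16)
  expect_equal(solvent_occupancy(300, p), OCC_X_REF, tolerance = 1e-12)
  x <- solvent_occupancy(seq(205, 500, by = 5), p)
  expect_true(all(x > 0 & x <= 1))
})

test_that("finite-chain partition function collapses to Z = 1 at N = 1 and
           matches the compensated recurrence oracle", {
  for (s in c(0.3, 1, 2.5)) {
    expect_equal(exp(partition_function(s, 0.05, 1, "finite")), 1,
                 tolerance = 1e-14)
  }
  worst <- 0
  for (s in c(0.05, 0.7, 1.137, 2, 3)) {
    for (sig in c(1e-4, 1e-2, 0.5, 1)) {
      for (N in c(2, 5, 17, 50)) {
        closed <- exp(partition_function(s, sig, N, "finite"))
        oracle <- recurrence_Z(s, sig, N)
        worst <- max(worst, abs(closed - oracle) / abs(oracle))
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("per-unit log partition function converges to the long-chain
           limit as N grows", {
  gaps <- sapply(c(10, 100, 1e4), function(N) {
    abs(partition_function(2, 0.1, N, "finite") -
          partition_function(2, 0.1, N, "long")) / N
  })
  expect_true(all(diff(gaps) < 0))
  # the per-unit gap is the boundary term ln(V/D)/N, i.e. O(1/N)
  expect_equal(gaps[2] / gaps[3], 100, tolerance = 0.01)
  expect_lt(gaps[3], 1e-3)
})

test_that("helicity is a proper order parameter: bounded, saturating, and
           monotone across a heat-denaturation transition", {
  fx <- fixture_params()
  grid <- seq(280, 370, length.out = 200)
  th <- helicity(grid, fx, "long")
  expect_true(all(th >= 0 & th <= 1))
  expect_true(all(diff(th) <= 0))        # non-increasing across the melt
  thf <- helicity(grid, fx, "finite")
  expect_true(all(thf >= 0 & thf <= 1))
  # strong-helix limit
  ph <- zb_params(t0 = 200, h = 30000, hps = 1000, Q = 10, q = 16)
  expect_equal(helicity(300, ph, "long"), 1, tolerance = 1e-9)
})

test_that("finite-chain helicity approaches the long-chain value with the
           expected 1/N boundary correction", {
  gaps <- sapply(c(1e2, 1e3, 1e5), function(N) {
    fx <- fixture_params(N = as.integer(N))
    grid <- seq(300, 360, length.out = 101)
    max(abs(helicity(grid, fx, "finite") - helicity(grid, fx, "long")))
  })
  expect_true(all(diff(gaps) < 0))
  # leading correction is O(1/N): N=1e2 -> N=1e3 shrinks the gap ~10x
  expect_equal(gaps[1] / gaps[2], 10, tolerance = 0.15)
  expect_lt(gaps[3], 1e-4)
})

test_that("internal energy is constant when both bond energies vanish and
           its conformational part matches the log-partition derivative", {
  p0 <- zb_params(t0 = 200, h = 0, hps = 0, Q = 10, q = 16, N = 50)
  E <- internal_energy(c(250, 300, 350, 400), p0, "long")
  expect_equal(max(E) - min(E), 0, tolerance = 1e-9)
  # E_conf = -d(lnZ)/d(beta) with beta the effective inverse temperature;
  # internal_energy returns E_conf - 2 N hps X (solvent reservoir term)
  fx <- fixture_params()
  for (Temp in c(310, 320, 331, 345)) {
    lnZ_of_b <- function(b) {
      Tb <- fx$t0 + 1 / (R_GAS * b)
      partition_function(stability_parameter(Tb, fx), 1 / fx$Q, fx$N, "long")
    }
    b0 <- 1 / (R_GAS * (Temp - fx$t0))
    E_conf <- -central_diff(lnZ_of_b, b0, 1e-9)
    E_closed <- internal_energy(Temp, fx, "long") +
      2 * fx$N * fx$hps * solvent_occupancy(Temp, fx)
    expect_equal(E_closed, E_conf, tolerance = 1e-4)
  }
})

test_that("heat capacity is the exact temperature derivative of the
           internal energy in both chain-length modes", {
  fx <- fixture_params()
  grid <- seq(285, 365, length.out = 200)
  for (mode in c("long", "finite")) {
    cv <- heat_capacity(grid, fx, mode)
    dE <- (internal_energy(grid + 1e-3, fx, mode) -
             internal_energy(grid - 1e-3, fx, mode)) / 2e-3
    rel <- abs(cv - dE) / pmax(abs(cv), 1e-3 * max(abs(cv)))
    expect_lt(max(rel), 1e-3)
  }
})

test_that("with hps = 0 the heat capacity reduces to -2 N h dtheta/dT", {
  p <- zb_params(t0 = 200, h = 3000, hps = 0, Q = 100, q = 16, N = 40)
  grid <- seq(300, 360, length.out = 50)
  cv <- heat_capacity(grid, p, "long")
  dth <- sapply(grid, function(Temp)
    central_diff(function(x) helicity(x, p, "long"), Temp, 1e-4))
  expect_equal(cv, -2 * p$N * p$h * dth, tolerance = 1e-6)
})

test_that("heat-capacity peak sits within 2 K of the helicity midpoint", {
  fx <- fixture_params()
  grid <- seq(285, 365, length.out = 2000)
  cv <- heat_capacity(grid, fx, "long")
  peaks <- which(diff(sign(diff(cv))) == -2) + 1
  expect_length(peaks, 1L)               # single local maximum
  tm <- melting_temperature(fx, "long")
  expect_lt(abs(grid[peaks] - tm), 2)
})

test_that("per-residue heat capacity is the chain value divided by N", {
  fx <- fixture_params(N = 37L)
  grid <- seq(300, 360, length.out = 20)
  expect_equal(heat_capacity(grid, fx, "long", per_residue = TRUE),
               heat_capacity(grid, fx, "long") / 37)
})

test_that("melting temperature: bisection agrees with a dense-grid argmin,
           is grid-refinement invariant, and errors without a crossing", {
  fx <- fixture_params()
  tm <- melting_temperature(fx, "long")
  expect_equal(tm, TM_REF, tolerance = 1e-6)
  grid <- seq(280, 370, length.out = 2e5)
  tm_grid <- grid[which.min(abs(helicity(grid, fx, "long") - 0.5))]
  expect_lt(abs(tm - tm_grid), 1e-3)
  # invariance under a different search window containing the root
  tm2 <- melting_temperature(fx, "long", t_range = c(300, 360))
  expect_lt(abs(tm - tm2), 1e-3)
  ph <- zb_params(t0 = 200, h = 30000, hps = 1000, Q = 10, q = 16)
  expect_error(melting_temperature(ph, "long", t_range = c(280, 370)),
               "does not cross")
})

test_that("all observables stay finite at extreme-but-valid inputs", {
  ex <- zb_params(t0 = 200, h = 1e5, hps = -1e5, Q = 1000, q = 16, N = 1e6)
  expect_true(is.finite(helicity(201, ex, "finite")))
  expect_true(is.finite(internal_energy(201, ex, "long")))
  expect_true(is.finite(heat_capacity(201, ex, "finite")))
  ex2 <- zb_params(t0 = 200, h = -1e5, hps = 1e5, Q = 1, q = 16, N = 1e6)
  expect_true(is.finite(solvent_occupancy(201, ex2)))
  expect_true(is.finite(partition_function(1e300, 0.5, 1e6, "long")))
})

test_that("parameter constructor enforces physical invariants", {
  expect_error(zb_params(200, 1, 1, Q = 0), "positive")
  expect_error(zb_params(200, 1, 1, Q = 10, q = 1), "> 1")
  expect_error(zb_params(200, 1, 1, Q = 10, N = 0), "positive integer")
})
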