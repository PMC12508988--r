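#' @keywords internal
"_PACKAGE"

#' Ideal gas constant (J mol-1 K-1)
#'
#' Module-level constant used by every Boltzmann factor in the package.
#' @export
R_GAS <- 8.314

#' Model parameter set for the water-renormalized Zimm-Bragg model
#'
#' Bundles the physical parameters that drive all model evaluation:
#' the glass-transition reference temperature `t0`, the intramolecular
#' (N-H...C=O) hydrogen-bond energy `h`, the polypeptide-solvent
#' hydrogen-bond energy `hps`, the entropic cost `Q` of intra-polymer
#' hydrogen bonding (inverse of the cooperativity parameter, `sigma = 1/Q`),
#' the entropic cost `q` of polymer-solvent hydrogen bonding (16 for water),
#' and the chain length `N` in repeat units (amino acids).
#'
#' Temperature dependence is non-Arrhenius: every Boltzmann factor uses the
#' effective inverse temperature `1/(R_GAS * (T - t0))`, which diverges at
#' `T = t0`, so all evaluations require `T > t0`.
#'
#' @param t0 Glass-transition reference temperature (K).
#' @param h Intra-polypeptide hydrogen-bond energy (J/mol).
#' @param hps Polypeptide-solvent hydrogen-bond energy (J/mol).
#' @param Q Entropic cost of intra-polymer hydrogen bonding (dimensionless,
#'   `> 0`); the helix nucleation parameter is `sigma = 1/Q`.
#' @param q Entropic cost of polymer-solvent hydrogen bonding (dimensionless,
#'   `> 1`). Default 16, the value for water.
#' @param N Number of repeat units (positive integer). Default 1.
#' @return An object of class `"zb_params"`.
#' @examples
#' p <- zb_params(t0 = 200, h = 3000, hps = 2500, Q = 100, N = 100)
#' helicity(330, p, mode = "long")
#' @export
zb_params <- function(t0, h, hps, Q, q = 16, N = 1L) {
  stopifnot(is.numeric(t0), length(t0) == 1L, is.finite(t0),
            is.numeric(h), length(h) == 1L, is.finite(h),
            is.numeric(hps), length(hps) == 1L, is.finite(hps))
  if (!is.numeric(Q) || length(Q) != 1L || !is.finite(Q) || Q <= 0)
    stop("`Q` must be a single positive number (sigma = 1/Q).", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 1)
    stop("`q` must be > 1 so the solvent-state denominator stays positive.",
         call. = FALSE)
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("`N` must be a positive integer.", call. = FALSE)
  structure(list(t0 = as.numeric(t0), h = as.numeric(h), hps = as.numeric(hps),
                 Q = as.numeric(Q), q = as.numeric(q), N = N),
            class = "zb_params")
}

#' @export
print.zb_params <- function(x, ...) {
  cat("Water-renormalized Zimm-Bragg parameters\n")
  cat(sprintf("  t0  = %.6g K   (glass-transition reference)\n", x$t0))
  cat(sprintf("  h   = %.6g J/mol (intra-polypeptide H-bond)\n", x$h))
  cat(sprintf("  hps = %.6g J/mol (polypeptide-solvent H-bond)\n", x$hps))
  cat(sprintf("  Q   = %.6g      (sigma = 1/Q = %.3g)\n", x$Q, 1 / x$Q))
  cat(sprintf("  q   = %.6g      (solvent entropic cost)\n", x$q))
  cat(sprintf("  N   = %d repeat units\n", x$N))
  invisible(x)
}

# Effective inverse temperature beta = 1/(R (T - t0)); the single site of
# truth for the exponent convention shared by the stability parameter and
# the solvent occupancy.
zb_beta <- function(temperature, t0) {
  if (any(temperature <= t0))
    stop("All temperatures must exceed t0 = ", t0,
         " K (the effective Boltzmann factor diverges at T = t0).",
         call. = FALSE)
  1 / (R_GAS * (temperature - t0))
}

#' Boltzmann factor with non-Arrhenius temperature scaling
#'
#' Evaluates `exp(energy / (R_GAS * (T - t0)))`. All Boltzmann factors in the
#' model (stability parameter and solvent occupancy alike) are produced by
#' this one function, so the exponent convention lives in a single place.
#'
#' @param energy Energy (J/mol); may be a vector.
#' @param temperature Temperature (K), strictly above `t0`; may be a vector.
#' @param t0 Glass-transition reference temperature (K).
#' @return `exp(energy * beta)` with `beta = 1/(R_GAS * (temperature - t0))`.
#' @export
boltzmann_factor <- function(energy, temperature, t0) {
  exp(energy * zb_beta(temperature, t0))
}

#' Transfer-matrix eigenvalues of the Zimm-Bragg characteristic equation
#'
#' Roots of `lambda^2 - (s + 1) lambda + s (1 - sigma) = 0`, i.e.
#' `lambda_{1,2} = (1 + s +/- sqrt((1 - s)^2 + 4 sigma s)) / 2`.
#' The pair satisfies the Vieta identities
#' `lambda1 + lambda2 = 1 + s` and `lambda1 * lambda2 = s (1 - sigma)`.
#'
#' @param s Stability weight of a helical unit (dimensionless, `>= 0`);
#'   may be a vector.
#' @param sigma Cooperativity (nucleation) parameter (dimensionless, `>= 0`).
#' @return A list with numeric components `lambda1` and `lambda2`
#'   (`lambda1 >= lambda2`), of class `"zb_eigen"`.
#' @examples
#' eigenvalues(1, 0.01)  # lambda = 1 +/- 0.1
#' @export
eigenvalues <- function(s, sigma) {
  if (any(!is.finite(s)) || any(s < 0))
    stop("`s` must be finite and >= 0.", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma < 0)
    stop("`sigma` must be a single finite number >= 0.", call. = FALSE)
  es <- eigen_system(s, sigma)
  structure(list(lambda1 = es$l1, lambda2 = es$l2), class = "zb_eigen")
}

# Eigenvalues plus first and second s-derivatives; no domain checks so the
# fitting path can traverse s slightly below 0 (down to -sigma) untroubled.
# D''(s) simplifies to 4 sigma (1 - sigma) / D^3.
eigen_system <- function(s, sigma) {
  disc <- (1 - s)^2 + 4 * sigma * s
  disc[disc < 0] <- NaN
  D <- sqrt(disc)
  Dp <- (s - 1 + 2 * sigma) / D
  Dpp <- 4 * sigma * (1 - sigma) / D^3
  l1 <- (1 + s + D) / 2
  l2 <- (1 + s - D) / 2
  l1p <- (1 + Dp) / 2
  l2p <- (1 - Dp) / 2
  l1pp <- Dpp / 2
  l2pp <- -Dpp / 2
  big <- s > 1e100   # (1-s)^2 overflows near 1e154; use the s->Inf limit
  if (any(big)) {
    l1[big] <- s[big]; l2[big] <- 1 - sigma; D[big] <- s[big]
    l1p[big] <- 1; l2p[big] <- 0; l1pp[big] <- 0; l2pp[big] <- 0
  }
  list(l1 = l1, l2 = l2, D = D, l1p = l1p, l2p = l2p,
       l1pp = l1pp, l2pp = l2pp)
}

# log((q - 1 + exp(u)) / q), evaluated without overflow for any real u.
log_solvent_sum <- function(u, q) {
  out <- numeric(length(u))
  big <- u > 50
  out[big] <- u[big] + log1p((q - 1) * exp(-u[big])) - log(q)
  out[!big] <- log1p(expm1(u[!big]) / q)
  out
}

# Internal state shared by the stability parameter and its T-derivative:
# f = log of the squared-reciprocal bracket of the renormalization,
# s = expm1(f)/Q, X = solvent occupancy, and analytic dT derivatives.
stilde_state <- function(temperature, params) {
  b <- zb_beta(temperature, params$t0)
  u <- params$hps * b
  f <- 2 * params$h * b - 2 * log_solvent_sum(u, params$q)
  X <- 1 / (1 + (params$q - 1) * exp(-u))
  s <- expm1(f) / params$Q
  dbdT <- -R_GAS * b^2
  dXdT <- params$hps * X * (1 - X) * dbdT
  # ds/dT = (e^f / Q) * f'(beta) * dbeta/dT; e^f/Q = s + 1/Q
  dsdT <- (s + 1 / params$Q) * (2 * params$h - 2 * params$hps * X) * dbdT
  list(s = s, dsdT = dsdT, X = X, dXdT = dXdT, f = f, beta = b)
}

#' Water-renormalized stability parameter
#'
#' Statistical weight of a helical unit after summing over the hydrogen-bond
#' degrees of freedom of the surrounding water:
#' \deqn{\tilde{s}(T) = \frac{1}{Q}\left[\left(A + \frac{B - A}{q}\right)^{-2}
#'   - 1\right],}
#' where `A = exp(-h * beta)` and `B = exp((hps - h) * beta)` are the
#' intra-polymer and polymer-solvent Boltzmann factors with
#' `beta = 1/(R_GAS * (T - t0))`. The bracket factors as
#' `exp(-h beta) * (q - 1 + exp(hps beta)) / q`, so it is evaluated entirely
#' in log space and no intermediate exponential can overflow. The result is
#' bounded below by `-1/Q` and decays to 0 as `T` grows.
#'
#' For extreme-but-valid inputs (e.g. `|h|` near 1e5 J/mol within a kelvin of
#' `t0`) the mathematical value of the stability parameter itself exceeds
#' double-precision range; `Inf` is returned and the observables
#' ([helicity()], [internal_energy()], [heat_capacity()]) take their
#' saturated all-helix branch so that every reported quantity stays finite.
#'
#' @param temperature Temperature(s) (K), strictly above `params$t0`.
#' @param params A [zb_params()] object.
#' @return Numeric vector of stability-parameter values.
#' @examples
#' p <- zb_params(t0 = 200, h = 4000, hps = 4500, Q = 100)
#' stability_parameter(300, p)
#' @export
stability_parameter <- function(temperature, params) {
  stopifnot(inherits(params, "zb_params"))
  stilde_state(temperature, params)$s
}

#' Solvent-bond occupancy
#'
#' Fraction of the `q` orientational states of water in which a
#' polypeptide-solvent hydrogen bond is formed:
#' `X = exp(hps * beta) / (q + exp(hps * beta) - 1)` with the same
#' non-Arrhenius `beta = 1/(R_GAS * (T - t0))` as the stability parameter
#' (single site of truth for the exponent convention). `X` lies in (0, 1];
#' at `hps = 0` it equals `1/q`.
#'
#' @inheritParams stability_parameter
#' @return Numeric vector of occupancies in (0, 1].
#' @export
solvent_occupancy <- function(temperature, params) {
  stopifnot(inherits(params, "zb_params"))
  stilde_state(temperature, params)$X
}

# Finite-chain log partition function and s-derivatives.
# Z = [(1 - l2) l1^N + (l1 - 1) l2^N] / (l1 - l2); l1^N is factored out so
# only the decaying ratio r = l2/l1 is ever raised to the Nth power.
# Returns logZ, dlogZ/ds, d2logZ/ds2 (vectors over s).
logZ_finite <- function(s, sigma, N) {
  es <- eigen_system(s, sigma)
  l1 <- es$l1; l2 <- es$l2; D <- es$D
  l1p <- es$l1p; l2p <- es$l2p; l1pp <- es$l1pp; l2pp <- es$l2pp
  r <- l2 / l1
  rN <- r^N
  rN1 <- if (N >= 2L) r^(N - 1L) else rep(1, length(r))
  rN2 <- if (N >= 3L) r^(N - 2L) else rep(1, length(r))
  # 1 - l2 and l1 - 1 suffer catastrophic cancellation for small sigma on
  # the side where D nearly equals |s - 1|; the rationalized forms
  # 2 sigma s / (D +/- (s - 1)) are exact there (D^2 - (s-1)^2 = 4 sigma s)
  oml2 <- ifelse(s > 1, 2 * sigma * s / (D + s - 1), (1 - s + D) / 2)
  l1m1 <- ifelse(s < 1, 2 * sigma * s / (D + 1 - s), (s - 1 + D) / 2)
  V <- oml2 + l1m1 * rN

  degen <- is.finite(D) & (abs(l1 - l2) < 1e-10 * abs(l1))
  logZ <- N * log(l1) + log(V) - log(D)
  if (any(degen)) {
    # confluent limit of the 0/0 form: Z = l^(N-1) * (l - N (l - 1))
    l <- l1[degen]
    logZ[degen] <- (N - 1) * log(l) + log(l - N * (l - 1))
  }

  # W = U / l1^N with U the numerator of Z; logZ = N log l1 + log V - log D
  # and dlogZ/ds = U'/U - D'/D with U'/U = Wp/V.
  Dp <- l1p - l2p
  Wp <- -l2p + N * oml2 * l1p / l1 + l1p * rN +
    N * l1m1 * l2p * rN1 / l1
  d1 <- Wp / V - Dp / D

  Dpp <- l1pp - l2pp
  Wpp <- -l2pp - 2 * N * l2p * l1p / l1 +
    N * (N - 1) * oml2 * (l1p / l1)^2 +
    N * oml2 * l1pp / l1 +
    l1pp * rN + 2 * N * l1p * l2p * rN1 / l1 +
    N * (N - 1) * l1m1 * l2p^2 * rN2 / l1^2 +
    N * l1m1 * l2pp * rN1 / l1
  d2 <- Wpp / V - (Wp / V)^2 - Dpp / D + (Dp / D)^2
  list(logZ = logZ, d1 = d1, d2 = d2)
}

# Long-chain limit: logZ = N log l1.
logZ_long <- function(s, sigma, N) {
  es <- eigen_system(s, sigma)
  list(logZ = N * log(es$l1),
       d1 = N * es$l1p / es$l1,
       d2 = N * (es$l1pp * es$l1 - es$l1p^2) / es$l1^2)
}

#' Log partition function of the helix-coil chain
#'
#' Finite-chain transfer-matrix partition function
#' `Z = [(1 - lambda2) lambda1^N + (lambda1 - 1) lambda2^N] /
#' (lambda1 - lambda2)` (mode `"finite"`), or its long-chain limit
#' `Z = lambda1^N` (mode `"long"`). The log is the canonical return value
#' and `lambda1^N` is factored out internally, so no overflow occurs up to
#' `N = 1e6`. When the eigenvalues are degenerate
#' (`|lambda1 - lambda2| < 1e-10 lambda1`) the analytic confluent limit
#' `Z = lambda^(N-1) (lambda - N (lambda - 1))` is used instead of a 0/0
#' evaluation. With the printed boundary convention the finite chain gives
#' `Z = 1` identically at `N = 1`.
#'
#' @param s_tilde Renormalized stability parameter(s) (dimensionless,
#'   `>= 0`).
#' @param sigma Cooperativity parameter (dimensionless, `> 0`).
#' @param n_units Chain length `N` (positive integer).
#' @param mode `"finite"` or `"long"`.
#' @return `log Z`, a numeric vector matching `s_tilde`.
#' @examples
#' partition_function(2, 0.1, 5, "finite")
#' @export
partition_function <- function(s_tilde, sigma, n_units,
                               mode = c("finite", "long")) {
  mode <- match.arg(mode)
  if (any(!is.finite(s_tilde)) || any(s_tilde < 0))
    stop("`s_tilde` must be finite and >= 0.", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be a single number > 0.", call. = FALSE)
  N <- as.integer(n_units)
  if (is.na(N) || N < 1L) stop("`n_units` must be >= 1.", call. = FALSE)
  if (mode == "finite") logZ_finite(s_tilde, sigma, N)$logZ
  else logZ_long(s_tilde, sigma, N)$logZ
}

# Order parameter theta(s) = (s + sigma)/N * dlogZ/ds and its s-derivative.
theta_of_s <- function(s, sigma, N, mode, deriv = FALSE) {
  lz <- if (mode == "finite") logZ_finite(s, sigma, N)
        else logZ_long(s, sigma, N)
  th <- (s + sigma) / N * lz$d1
  if (!deriv) return(list(theta = th))
  list(theta = th, dtheta = lz$d1 / N + (s + sigma) / N * lz$d2)
}

#' Degree of helicity
#'
#' Order parameter of the helix-coil transition: the average fraction of
#' repeat units whose backbone hydrogen bond is formed,
#' `theta = (s_tilde + sigma)/N * d(log Z)/d(s_tilde)`, evaluated with the
#' analytic closed-form derivative of the finite-chain partition function
#' (mode `"finite"`) or of its long-chain limit (mode `"long"`; this is the
#' closed-form expression in terms of the leading eigenvalue). The two modes
#' agree in the large-`N` limit. `theta` lies in `[0, 1]`.
#'
#' @inheritParams stability_parameter
#' @param mode `"long"` (chain-length-independent limit) or `"finite"`
#'   (uses `params$N`).
#' @return Numeric vector of helicity degrees.
#' @examples
#' p <- zb_params(t0 = 200, h = 3000, hps = 2500, Q = 100, N = 100)
#' helicity(c(300, 331, 360), p, mode = "long")
#' @export
helicity <- function(temperature, params, mode = c("long", "finite")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "zb_params"))
  s <- stability_parameter(temperature, params)
  out <- numeric(length(s))
  sat <- !is.finite(s) | s > 1e100   # saturated all-helix branch
  out[sat] <- 1
  if (any(!sat))
    out[!sat] <- theta_of_s(s[!sat], 1 / params$Q, params$N, mode)$theta
  out
}

#' Mean hydrogen-bonding energy of the chain
#'
#' Internal (average) energy obtained from the temperature derivative of the
#' full (solvent-summed) log partition function, expressed in closed form as
#' \deqn{E(T) = -2 N h \theta(T) - 2 N h_{ps} X(T) (1 - \theta(T)),}
#' i.e. two intra-polypeptide bonds of energy `h` per helical unit plus two
#' polypeptide-solvent bonds of energy `hps`, occupied with probability `X`,
#' per coil unit. The conformational part `-d(log Z)/d(beta)` (with the
#' model's effective inverse temperature `beta = 1/(R_GAS (T - t0))`) equals
#' `E + 2 N hps X`; the difference is the solvent reservoir term that the
#' traced-out partition function measures relative to. The heat capacity
#' ([heat_capacity()]) is the exact temperature derivative of this `E`.
#'
#' @inheritParams helicity
#' @return Energy (J per mol of chain); divide by `params$N` for per-residue
#'   values.
#' @export
internal_energy <- function(temperature, params, mode = c("long", "finite")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "zb_params"))
  st <- stilde_state(temperature, params)
  th <- numeric(length(st$s))
  sat <- !is.finite(st$s) | st$s > 1e100
  th[sat] <- 1
  if (any(!sat))
    th[!sat] <- theta_of_s(st$s[!sat], 1 / params$Q, params$N, mode)$theta
  N <- params$N
  -2 * N * params$h * th - 2 * N * params$hps * st$X * (1 - th)
}

#' Excess heat capacity of the helix-coil transition
#'
#' Closed-form evaluation of
#' \deqn{C_V = -2 N h \frac{\partial\theta}{\partial T}
#'   - 2 N h_{ps} \frac{\partial X}{\partial T}(1-\theta)
#'   + 2 N h_{ps} X \frac{\partial\theta}{\partial T},}
#' with `dtheta/dT` computed analytically through the chain rule in the
#' stability parameter and `dX/dT` from the closed-form derivative of the
#' solvent occupancy (`dX/dT = hps X (1 - X) dbeta/dT`). This is the exact
#' temperature derivative of [internal_energy()]. For comparison with
#' constant-pressure calorimetry the usual `C_V ~ C_P` approximation is
#' invoked (an interpretation note, not a computation).
#'
#' @inheritParams helicity
#' @param per_residue If `TRUE`, divide the chain value by `params$N`
#'   (DSC results are conventionally reported per repeat unit).
#' @return Heat capacity (J mol-1 K-1), per chain unless `per_residue`.
#' @export
heat_capacity <- function(temperature, params, mode = c("long", "finite"),
                          per_residue = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "zb_params"))
  st <- stilde_state(temperature, params)
  n <- length(st$s)
  th <- numeric(n); thp <- numeric(n)
  sat <- !is.finite(st$s) | st$s > 1e100
  th[sat] <- 1; thp[sat] <- 0
  if (any(!sat)) {
    tt <- theta_of_s(st$s[!sat], 1 / params$Q, params$N, mode, deriv = TRUE)
    th[!sat] <- tt$theta
    thp[!sat] <- tt$dtheta * st$dsdT[!sat]
  }
  N <- params$N
  cv <- -2 * N * params$h * thp -
    2 * N * params$hps * st$dXdT * (1 - th) +
    2 * N * params$hps * st$X * thp
  if (per_residue) cv / N else cv
}

#' Melting temperature (transition midpoint)
#'
#' Temperature at which the degree of helicity crosses one half, located by
#' bracketing bisection to an absolute tolerance of 1e-4 K. The search
#' window is scanned on a dense grid first; if several crossings exist
#' (cold plus heat denaturation) the heat-denaturation crossing (helicity
#' decreasing through one half) at the highest temperature is returned.
#'
#' @param params A [zb_params()] object.
#' @param mode `"long"` or `"finite"` (as for [helicity()]).
#' @param t_range Length-2 search window (K); defaults to
#'   `c(t0 + 5, t0 + 500)`.
#' @return Melting temperature (K).
#' @export
melting_temperature <- function(params, mode = c("long", "finite"),
                                t_range = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "zb_params"))
  if (is.null(t_range)) t_range <- params$t0 + c(5, 500)
  if (t_range[1] <= params$t0 || t_range[2] <= t_range[1])
    stop("`t_range` must satisfy t0 < t_range[1] < t_range[2].",
         call. = FALSE)
  grid <- seq(t_range[1], t_range[2], length.out = 512L)
  g <- helicity(grid, params, mode) - 0.5
  sgn <- sign(g)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(idx) == 0L) {
    if (any(g == 0)) return(grid[which(g == 0)[1]])
    stop(structure(class = c("helixfit_no_crossing", "error", "condition"),
                   list(message = paste0(
                     "helicity does not cross 1/2 in [",
                     t_range[1], ", ", t_range[2], "] K"),
                     call = NULL)))
  }
  # prefer the highest-temperature decreasing (heat-denaturation) crossing
  dec <- idx[g[idx] > 0]
  i <- if (length(dec)) max(dec) else max(idx)
  stats::uniroot(function(T) helicity(T, params, mode) - 0.5,
                 lower = grid[i], upper = grid[i + 1], tol = 1e-4)$root
}
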