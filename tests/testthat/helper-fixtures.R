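# Shared fixtures and independent oracles for the test suite.

# Cooperative heat-denaturation fixture: a single sharp sigmoid with both
# tails inside the [280, 370] K grid; T_m ~ 331.32 K.
fixture_params <- function(N = 100L) {
  zb_params(t0 = 200, h = 3000, hps = 2500, Q = 100, q = 16, N = N)
}
fixture_truth <- c(t0 = 200, h = 3000, hps = 2500, Q = 100)

# Frozen reference values computed with an independent arbitrary-precision
# (50-digit) evaluation of the renormalization bracket and occupancy.
STILDE_REF <- 0.665498796800777   # t0=200 h=4000 hps=4500 Q=100 q=16 T=300
OCC_X_REF <- 0.937292064423418    # t0=200 hps=4500 q=16 T=300
TM_REF <- 331.319711482           # fixture melting temperature (K)

# Independent oracle for the finite-chain partition function: the
# three-term recurrence Z_{k+1} = (1+s) Z_k - s(1-sigma) Z_{k-1} from
# Z_0 = Z_1 = 1, run in compensated double-double arithmetic with exactly
# represented coefficients so that its own roundoff (~1e-12 at small sigma
# in plain doubles) cannot mask the comparison.
two_sum <- function(a, b) {
  s <- a + b; bb <- s - a
  c(s, (a - (s - bb)) + (b - bb))
}
split_d <- function(a) {
  c <- 134217729 * a; hi <- c - (c - a)
  c(hi, a - hi)
}
two_prod <- function(a, b) {
  p <- a * b; as <- split_d(a); bs <- split_d(b)
  c(p, ((as[1] * bs[1] - p) + as[1] * bs[2] + as[2] * bs[1]) + as[2] * bs[2])
}
dd_norm <- function(p) two_sum(p[1], p[2])
dd_add <- function(x, y) {
  s <- two_sum(x[1], y[1])
  dd_norm(c(s[1], s[2] + x[2] + y[2]))
}
dd_mul <- function(x, y) {
  p <- two_prod(x[1], y[1])
  dd_norm(c(p[1], p[2] + x[1] * y[2] + x[2] * y[1]))
}
recurrence_Z <- function(s, sigma, N) {
  a_dd <- two_sum(1, s)
  c_dd <- dd_add(c(s, 0), -two_prod(s, sigma))
  z0 <- c(1, 0); z1 <- c(1, 0)
  if (N == 1L) return(1)
  for (k in 2:N) {
    z2 <- dd_add(dd_mul(z1, a_dd), -dd_mul(z0, c_dd))
    z0 <- z1; z1 <- z2
  }
  z1[1] + z1[2]
}

# Central finite difference, used only as a derivative cross-check.
central_diff <- function(f, x, h) (f(x + h) - f(x - h)) / (2 * h)
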