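# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (grid search, quadratic formula,
# finite differences) rather than calling the implementation under test.

# argmin of the least-cost function f(Ci) = 1.6 eta* D / (Ca - Ci)
#   + beta (Ci + K) / (Ci - Gamma*) by dense grid search over (Gamma*, Ca)
oracle_chi_grid <- function(ks, dg_pa, beta, n_grid = 200001L) {
  ci <- seq(ks$gammastar * (1 + 1e-6), ks$ca * (1 - 1e-6),
            length.out = n_grid)
  f <- 1.6 * ks$eta_star * dg_pa / (ks$ca - ci) +
    beta * (ci + ks$K) / (ci - ks$gammastar)
  ci[which.min(f)] / ks$ca
}

# electron-transport-limited assimilation: smaller root of the
# non-rectangular hyperbola theta J^2 - (phi I + Jmax) J + phi I Jmax = 0,
# then Aj = m J / 4 (built from the quadratic formula, not the package's
# folded expression)
oracle_aj <- function(jmax, I, m, phi, theta) {
  b <- phi * I + jmax
  J <- (b - sqrt(b^2 - 4 * theta * phi * I * jmax)) / (2 * theta)
  m * J / 4
}

# central finite difference of Aj in Jmax
oracle_dAj_dJmax <- function(jmax, I, m, phi, theta, h = NULL) {
  if (is.null(h)) h <- max(jmax * 1e-6, 1e-8)
  (oracle_aj(jmax + h, I, m, phi, theta) -
     oracle_aj(jmax - h, I, m, phi, theta)) / (2 * h)
}

# solve dAj/dJmax = cc for Jmax by bisection, return omega = Jmax/(phi I)
oracle_omega_bisect <- function(theta, cc, m, I = 800, phi = 0.257) {
  f <- function(j) oracle_dAj_dJmax(j, I, m, phi, theta) - cc
  lo <- 1e-7; hi <- 1e6
  stopifnot(f(lo) > 0, f(hi) < 0)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2 / (phi * I)
}

# one-line peaked-Arrhenius evaluation (scalar, independent spelling)
oracle_kk <- function(rate, t1, t2, dS, Ha = 71513, Hd = 2e5, R = 8.314) {
  rate * exp(Ha * (t2 - t1) / (R * t2 * t1)) *
    (1 + exp((t1 * dS - Hd) / (R * t1))) /
    (1 + exp((t2 * dS - Hd) / (R * t2)))
}

std_params <- model_params()
std_ks <- calc_kinetics(25, calc_patm(0))

# random but physically sensible environment draws for property tests
draw_envs <- function(n, seed) {
  set.seed(seed)
  data.frame(
    ig = runif(n, 100, 2000),
    tg = runif(n, 1, 38),
    dg = runif(n, 50, 4000),
    z = runif(n, 0, 4500),
    ca_ppm = runif(n, 280, 600)
  )
}
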