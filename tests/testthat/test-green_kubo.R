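kB <- unit_system()$kB

mk_stress <- function(comp, V = 1e5, T = 300, dt = 0.01) {
  stress_series(seq_len(nrow(comp)) * dt - dt, comp, V, T, units = "kcal_molA3")
}

test_that("zero stress gives a zero relaxation modulus and zero viscosity", {
  comp <- matrix(0, 2000, 6,
                 dimnames = list(NULL, c("Pxx", "Pyy", "Pzz", "Pxy", "Pxz", "Pyz")))
  G <- relaxation_modulus(mk_stress(as.data.frame(comp)))
  expect_equal(G$G, rep(0, length(G$G)))
  eta <- gk_viscosity(G, maxwell_modes(0, 1), t_switch = 5)
  expect_equal(eta, 0)
})

test_that("off-diagonal OU stress with zero normal differences recovers 3/5 of
           the prescribed relaxation, and the consistent generator recovers all
           of it", {
  V <- 1e5; T <- 300; G0 <- 0.02; tau <- 1; dt <- 0.02; n <- 1e6
  # off-diagonals only: equal diagonals => N_ab = 0
  set.seed(4)
  phi <- exp(-dt / tau)
  sd0 <- sqrt(kB * T * G0 / V)
  ou <- function() as.numeric(stats::filter(
    c(rnorm(1, 0, sd0), rnorm(n - 1, 0, sd0 * sqrt(1 - phi^2))),
    phi, method = "recursive"))
  comp <- data.frame(Pxx = 0, Pyy = 0, Pzz = 0,
                     Pxy = ou(), Pxz = ou(), Pyz = ou())
  G <- relaxation_modulus(mk_stress(comp, V, T, dt))
  sel <- G$t > 0 & G$t <= 5 * tau
  target <- (3 / 5) * G0 * exp(-G$t[sel] / tau)
  expect_lt(max(abs(G$G[sel] - target) / (G0 * 3 / 5)), 0.1)
  # full synthetic generator (off-diagonals + consistent normal differences)
  st <- synth_stress(maxwell_modes(G0, tau), V, T, dt, n, seed = 8)
  G2 <- relaxation_modulus(st)
  sel2 <- G2$t > 0 & G2$t <= 5 * tau
  target2 <- G0 * exp(-G2$t[sel2] / tau)
  expect_lt(max(abs(G2$G[sel2] - target2) / G0), 0.1)
})

test_that("permuting exchangeable off-diagonal components leaves G(t) fixed", {
  st <- synth_stress(maxwell_modes(0.02, 1), 1e5, 300, dt = 0.05,
                     n_steps = 20000, seed = 5)
  G1 <- relaxation_modulus(st)
  st2 <- st
  st2$components[c("Pxy", "Pxz", "Pyz")] <- st$components[c("Pyz", "Pxy", "Pxz")]
  G2 <- relaxation_modulus(st2)
  expect_lt(max(abs(G1$G - G2$G)), 1e-12)
})

test_that("Maxwell-mode fits recover representable relaxation moduli", {
  t <- seq(0, 50, by = 0.05)
  tau_true <- 2; G0 <- 0.05
  G <- list(t = t, G = G0 * exp(-t / tau_true))
  # single mode with the true time on the mode grid (t_start = tau puts tau
  # at the first grid point): recovered exactly
  fit <- fit_modes(G, n_modes = 4, t_start = tau_true)
  expect_equal(fit$tau_i[1], tau_true, tolerance = 1e-9)
  expect_equal(fit$G_i[1], G0, tolerance = 0.01)
  expect_lt(sum(fit$G_i[-1]), 0.01 * G0)
  # two on-grid exponentials with amplitudes 1 and 0.1
  tau_grid <- 10^seq(log10(0.5), log10(50), length.out = 4)
  G2 <- list(t = t, G = 1 * exp(-t / tau_grid[1]) + 0.1 * exp(-t / tau_grid[4]))
  fit2 <- fit_modes(G2, n_modes = 4, t_start = 0.5)
  expect_equal(fit2$G_i[1], 1, tolerance = 0.05)
  expect_equal(fit2$G_i[4], 0.1, tolerance = 0.05)
  expect_lt(fit2$G_i[2] + fit2$G_i[3], 0.02)
  # default mode count is four
  expect_equal(length(formals(fit_modes)$n_modes), 1)
  expect_equal(eval(formals(fit_modes)$n_modes), 4)
})

test_that("mode-fit residual does not grow as the mode grid is refined", {
  t <- seq(0, 30, by = 0.05)
  G <- list(t = t, G = 0.05 * exp(-t / 1.3) + 0.02 * exp(-t / 6))
  # 2, 4 and 7 log-equidistant times over the same span are nested grids
  # (interior fractions k/3 are a subset of k/6), so the least-squares
  # residual cannot increase
  res <- vapply(c(2, 4, 7), function(n)
    attr(fit_modes(G, n_modes = n, t_start = 0.3), "residual"), 0)
  expect_true(all(diff(res) <= 1e-10))
})

test_that("hybrid Green-Kubo integral is exact for a representable mode and
           agrees with quadrature for the hybrid split", {
  tau <- 2; G0 <- 0.05
  t <- seq(0, 100, by = 0.01)
  G <- list(t = t, G = G0 * exp(-t / tau))
  eta0 <- gk_viscosity(G, maxwell_modes(G0, tau), t_switch = 0)
  expect_equal(eta0, G0 * tau, tolerance = 1e-12)
  # hybrid: numerical to t_switch, analytic beyond, vs dense quadrature
  # (tau on the mode grid so the tail model is representable)
  fit <- fit_modes(G, n_modes = 4, t_start = tau)
  eta_h <- gk_viscosity(G, fit, t_switch = tau)
  eta_q <- integrate(function(x) G0 * exp(-x / tau), 0, 50 * tau,
                     rel.tol = 1e-12)$value
  expect_equal(eta_h, eta_q, tolerance = 0.01)
})

test_that("synthetic stress analyzed end to end recovers the viscosity", {
  modes <- maxwell_modes(c(0.0212, 0.01), c(0.05, 1))
  st <- synth_stress(modes, V = 125000, T = 300, dt = 0.01, n_steps = 1e6,
                     seed = 11)
  G <- relaxation_modulus(st)
  fit <- fit_modes(G, n_modes = 4)
  eta <- gk_viscosity(G, fit)
  eta_true <- sum(modes$G_i * modes$tau_i)
  expect_lt(abs(eta - eta_true) / eta_true, 0.15)
})

test_that("Maxwell moduli obey the crossover identity and terminal exponents", {
  G0 <- 0.02; tau <- 1.7
  mod <- maxwell_moduli(maxwell_modes(G0, tau), 1 / tau)
  expect_equal(mod$G_prime, G0 / 2, tolerance = 1e-12)
  expect_equal(mod$G_double_prime, G0 / 2, tolerance = 1e-12)
  om <- c(1e-4, 2e-4) / tau
  lo <- maxwell_moduli(maxwell_modes(G0, tau), om)
  sl_p <- diff(log(lo$G_prime)) / diff(log(om))
  sl_pp <- diff(log(lo$G_double_prime)) / diff(log(om))
  expect_equal(sl_p, 2, tolerance = 0.01)
  expect_equal(sl_pp, 1, tolerance = 0.01)
})

test_that("raw-G(t) transform agrees with the mode closed form", {
  tau <- 1; G0 <- 0.05
  t <- seq(0, 40, by = 0.002)
  G <- structure(list(t = t, G = G0 * exp(-t / tau), V = 1, T = 300),
                 class = "mr_gt")
  om <- c(0.2, 1, 5)
  raw <- gk_moduli(G, om)
  closed <- maxwell_moduli(maxwell_modes(G0, tau), om)
  expect_equal(raw$G_prime, closed$G_prime, tolerance = 0.02)
  expect_equal(raw$G_double_prime, closed$G_double_prime, tolerance = 0.02)
})

test_that("zero-frequency limit of G''/w equals the Green-Kubo viscosity", {
  modes <- maxwell_modes(c(0.03, 0.01), c(0.3, 2))
  t <- seq(0, 200, by = 0.01)
  G <- list(t = t, G = 0.03 * exp(-t / 0.3) + 0.01 * exp(-t / 2))
  eta_gk <- gk_viscosity(G, modes, t_switch = 0)
  w0 <- 1e-4
  eta_w <- maxwell_moduli(modes, w0)$G_double_prime / w0
  expect_lt(abs(eta_gk - eta_w) / eta_gk, 0.02)
})
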