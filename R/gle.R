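## synthetic_gle: generalized-Langevin fixture generator with exactly known
## complex modulus, for validating the full analysis chain.
##
## Per axis the passive GLE with an exponential (multi-Maxwell) memory kernel
##   m dv/dt = -INT Z(t-t') v dt' + F_B,   Z(t) = zeta_n 2delta(t) + sum_j c_j exp(-t/tau_j)
## is embedded as a linear Markov system (x, v, u_1..u_K) with one auxiliary
## OU force per mode:
##   du_j = (-u_j/tau_j - c_j v) dt + sqrt(2 kB T c_j / tau_j) dW_j
## whose noise autocorrelation kB T c_j exp(-t/tau_j) satisfies the
## fluctuation-dissipation theorem with the same kernel. The one-step
## propagator (matrix exponential + Van Loan covariance) is exact in
## distribution at any dt.

#' Define a GLE probe-in-medium model
#'
#' Kernels: `newtonian(zeta0)` is instantaneous friction `zeta0`
#' (kcal ns/(mol A^2)); `maxwell(zeta0, tau_M)` is `Z(t) = zeta0 exp(-t/tau_M)`
#' with total friction `zeta0 tau_M` and one-sided transform
#' `zeta0 tau_M/(1 + i w tau_M)`; `multi_maxwell` sums several such modes.
#' The nominal hydrodynamic radius maps the kernel onto moduli through the
#' generalized Stokes drag `zeta*(w) = 6 pi R_h G*(w)/(i w)`, so a Maxwell
#' kernel corresponds to a single-mode Maxwell fluid with plateau
#' `G0 = zeta0/(6 pi R_h)` and viscosity `eta = zeta0 tau_M/(6 pi R_h)`.
#'
#' @param kernel list: `list(type = "newtonian", zeta0 = )`,
#'   `list(type = "maxwell", zeta0 = , tau_M = )`, or
#'   `list(type = "multi_maxwell", zeta0 = c(...), tau_M = c(...))`; zeta0 in
#'   kcal/(mol A^2) per mode amplitude (friction rate), tau in ns. Maxwell
#'   kernels accept an optional instantaneous component `zeta_n`
#'   (kcal ns/(mol A^2)), the background solvent/thermostat friction that
#'   keeps the caged probe overdamped, as in Langevin-dynamics simulations.
#' @param m probe mass (g/mol).
#' @param T temperature (K).
#' @param dt integration/save step (ns); must satisfy `dt <= min(tau_M)/50`.
#' @param n_steps number of steps.
#' @param seed RNG seed.
#' @param R_h_nominal nominal hydrodynamic radius (A).
#' @param n_probes number of independent probes.
#' @return object of class `mr_gle_model`.
#' @export
gle_model <- function(kernel, m, T, dt, n_steps, seed = 1,
                      R_h_nominal = 10, n_probes = 1) {
  type <- match.arg(kernel$type, c("newtonian", "maxwell", "multi_maxwell"))
  zeta_n <- 0; c_j <- numeric(0); tau_j <- numeric(0)
  if (type == "newtonian") {
    zeta_n <- kernel$zeta0
  } else {
    if (!is.null(kernel$zeta_n)) zeta_n <- kernel$zeta_n
    c_j <- kernel$zeta0; tau_j <- kernel$tau_M
    stopifnot(length(c_j) == length(tau_j), all(tau_j > 0), all(c_j >= 0))
    if (dt > min(tau_j) / 50)
      stop("dt exceeds min(tau_M)/50 (step error)", call. = FALSE)
  }
  stopifnot(m > 0, T > 0, dt > 0, n_steps >= 1)
  structure(list(type = type, zeta_n = zeta_n, c_j = c_j, tau_j = tau_j,
                 m = m, T = T, dt = dt, n_steps = n_steps, seed = seed,
                 R_h_nominal = R_h_nominal, n_probes = n_probes,
                 zeta_total = zeta_n + sum(c_j * tau_j)),
            class = "mr_gle_model")
}

## drift matrix A and diffusion Q = B B' for state (x, v, u_1..u_K)
.gle_system <- function(model) {
  K <- length(model$c_j)
  d <- 2 + K
  mi <- mass_internal(model$m)
  kT <- .const$kB * model$T
  A <- matrix(0, d, d)
  A[1, 2] <- 1
  A[2, 2] <- -model$zeta_n / mi
  if (K > 0) {
    A[2, 2 + seq_len(K)] <- 1 / mi
    for (j in seq_len(K)) {
      A[2 + j, 2] <- -model$c_j[j]
      A[2 + j, 2 + j] <- -1 / model$tau_j[j]
    }
  }
  Q <- matrix(0, d, d)
  Q[2, 2] <- 2 * kT * model$zeta_n / mi^2
  if (K > 0) for (j in seq_len(K)) Q[2 + j, 2 + j] <- 2 * kT * model$c_j[j] / model$tau_j[j]
  list(A = A, Q = Q, d = d, mi = mi, kT = kT)
}

## exact one-step propagator: F = expm(A dt); Sigma by the Van Loan block
## exponential [[A, Q], [0, -A']] -> Sigma = F %*% (top-right block)
.gle_propagator <- function(model) {
  sys <- .gle_system(model)
  d <- sys$d; dt <- model$dt
  M <- rbind(cbind(sys$A, sys$Q), cbind(matrix(0, d, d), -t(sys$A))) * dt
  E <- as.matrix(Matrix::expm(M))
  F <- E[1:d, 1:d, drop = FALSE]
  # top-right block is INT exp(A(h-s)) Q exp(-A's) ds; right-multiplying by
  # exp(A'h) = t(F) gives the one-step noise covariance
  Sigma <- E[1:d, d + (1:d), drop = FALSE] %*% t(F)
  Sigma <- (Sigma + t(Sigma)) / 2
  ev <- eigen(Sigma, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), d) %*% t(ev$vectors)
  list(F = F, L = L, d = d, sys = sys)
}

#' Integrate the passive GLE forward (fixture trajectories)
#'
#' Simulates `n_probes` independent probes (three independent axes each) with
#' the exact-in-distribution one-step propagator; initial velocities and
#' auxiliary forces are drawn from the stationary (equilibrium) distribution.
#' Deterministic given the model seed.
#'
#' @param model an [gle_model()].
#' @param save_every save every k-th step (default 1).
#' @param save_velocities also store velocities in the trajectory.
#' @return an [trajectory()] (probe beads, no box) with `times` in ns.
#' @export
simulate_gle <- function(model, save_every = 1, save_velocities = FALSE) {
  pr <- .gle_propagator(model)
  d <- pr$d
  nc <- 3 * model$n_probes
  set.seed(model$seed)
  # stationary initial condition: x = 0, v ~ N(0, kT/m), u_j ~ N(0, kT c_j)
  X0 <- matrix(0, d, nc)
  X0[2, ] <- rnorm(nc, 0, sqrt(pr$sys$kT / pr$sys$mi))
  if (d > 2) for (j in seq_len(d - 2))
    X0[2 + j, ] <- rnorm(nc, 0, sqrt(pr$sys$kT * model$c_j[j]))
  rows <- if (save_velocities) c(1L, 2L) else 1L
  res <- gle_propagate_cpp(pr$F, pr$L, X0, model$n_steps, save_every, rows)
  xs <- res[[1]]
  n_saved <- nrow(xs)
  pos <- array(0, c(n_saved, model$n_probes, 3))
  for (p in seq_len(model$n_probes)) pos[, p, ] <- xs[, (p - 1) * 3 + (1:3)]
  vel <- NULL
  if (save_velocities) {
    vel <- array(0, c(n_saved, model$n_probes, 3))
    for (p in seq_len(model$n_probes)) vel[, p, ] <- res[[2]][, (p - 1) * 3 + (1:3)]
  }
  trajectory(times = seq_len(n_saved) * model$dt * save_every,
             positions = pos, box = NULL,
             roles = rep("probe_center", model$n_probes),
             probe_ids = seq_len(model$n_probes),
             periodic = c(FALSE, FALSE, FALSE),
             velocities = vel)
}

## one-sided kernel transform zeta*(s), s = i w
.gle_kernel_transform <- function(model, s) {
  z <- rep(model$zeta_n + 0i, length(s))
  for (j in seq_along(model$c_j))
    z <- z + model$c_j[j] * model$tau_j[j] / (1 + s * model$tau_j[j])
  z
}

#' Analytic ground truth for a GLE model
#'
#' Moduli from the kernel via `G*(w) = i w zeta*(w)/(6 pi R_h)`; the exact
#' MSD by partial-fraction inversion of
#' `MSD(s) = 2 d kB T/(s^2 (m s + zeta*(s)))` (rational for exponential
#' kernels); `eta_true = zeta*(0)/(6 pi R_h)`; `tau_true` from the analytic
#' crossover.
#'
#' @param model an [gle_model()].
#' @param omega frequency grid (1/ns).
#' @param t lag times for the exact MSD (ns).
#' @return list with `moduli` (an `mr_modulus`), `eta_true`, `tau_true`,
#'   `G0` (plateau `zeta*(inf->modes)` sum of `c_j tau_j/tau_j` over
#'   `6 pi R_h` for Maxwell kernels), `msd_true`, `D_true`.
#' @export
gle_ground_truth <- function(model, omega, t = NULL) {
  s <- complex(imaginary = omega)
  G <- s * .gle_kernel_transform(model, s) / (6 * pi * model$R_h_nominal)
  mod <- structure(list(omega = omega, G_prime = Re(G), G_double_prime = Im(G),
                        n_masked = 0L), class = "mr_modulus")
  eta_true <- Re(.gle_kernel_transform(model, 0 + 0i)) / (6 * pi * model$R_h_nominal)
  G0 <- sum(model$c_j) / (6 * pi * model$R_h_nominal)
  cx <- crossover(mod)
  msd <- NULL
  if (!is.null(t)) msd <- .gle_msd_exact(model, t)
  list(moduli = mod, eta_true = eta_true, tau_true = cx$tau, G0 = G0,
       msd_true = msd, D_true = .const$kB * model$T / model$zeta_total)
}

## rational Laplace structure of the GLE:
## VACF(s) = kT P(s)/Q(s), MSD(s) = 2 d kT P(s)/(s^2 Q(s)) with
## P(s) = prod_j (1 + s tau_j),
## Q(s) = (m s + zeta_n) P(s) + sum_j c_j tau_j prod_{k!=j} (1 + s tau_k)
.gle_rational <- function(model) {
  polymul <- function(a, b) {
    out <- numeric(length(a) + length(b) - 1)
    for (i in seq_along(a)) out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
    out
  }
  mi <- mass_internal(model$m)
  P <- 1
  for (tj in model$tau_j) P <- polymul(P, c(1, tj))
  Q <- polymul(c(model$zeta_n, mi), P)
  for (j in seq_along(model$c_j)) {
    Pj <- 1
    for (k in seq_along(model$tau_j)) if (k != j) Pj <- polymul(Pj, c(1, model$tau_j[k]))
    add <- model$c_j[j] * model$tau_j[j] * Pj
    Q[seq_along(add)] <- Q[seq_along(add)] + add
  }
  peval <- function(cf) function(x) {
    acc <- 0 + 0i * x
    for (i in seq_along(cf)) acc <- acc + cf[i] * x^(i - 1)
    acc
  }
  dP <- if (length(P) > 1) P[-1] * seq_len(length(P) - 1) else 0
  dQ <- Q[-1] * seq_len(length(Q) - 1)
  list(P = P, Q = Q, Pf = peval(P), Qf = peval(Q), dPf = peval(dP),
       dQf = peval(dQ), mi = mi, kT = .const$kB * model$T)
}

## exact MSD (d_dims-dimensional) by partial fractions of the transform
.gle_msd_exact <- function(model, t, d_dims = 3) {
  ra <- .gle_rational(model)
  A <- Re(ra$Pf(0) / ra$Qf(0))
  B <- Re((ra$dPf(0) * ra$Qf(0) - ra$Pf(0) * ra$dQf(0)) / ra$Qf(0)^2)
  roots <- polyroot(ra$Q)
  msd <- 2 * d_dims * ra$kT * (A * t + B)
  for (r in roots) {
    Rr <- ra$Pf(r) / (r^2 * ra$dQf(r))
    msd <- msd + 2 * d_dims * ra$kT * Re(Rr * exp(r * t))
  }
  Re(msd)
}

## exact velocity autocorrelation (per axis) by partial fractions
.gle_vacf_exact <- function(model, t) {
  ra <- .gle_rational(model)
  roots <- polyroot(ra$Q)
  out <- numeric(length(t))
  for (r in roots) out <- out + Re(ra$kT * ra$Pf(r) / ra$dQf(r) * exp(r * t))
  out
}

#' Synthetic pressure-tensor series with prescribed Maxwell relaxation
#'
#' Generates six components whose off-diagonal autocorrelations equal
#' `(kB T / V) sum_i G_i exp(-t/tau_i)` (one exact-discretization OU process
#' per mode) and whose normal-stress differences carry the consistent
#' variance `4 kB T G_i / V`, so that [relaxation_modulus()] recovers
#' `sum G_i exp(-t/tau_i)`. Deterministic given the seed.
#'
#' @param modes an [maxwell_modes()].
#' @param V box volume (A^3).
#' @param T temperature (K).
#' @param dt sampling interval (ns).
#' @param n_steps number of samples.
#' @param seed RNG seed.
#' @return an [stress_series()] (components in kcal/(mol A^3)).
#' @export
synth_stress <- function(modes, V, T, dt, n_steps, seed = 1) {
  set.seed(seed)
  kT <- .const$kB * T
  ou <- function(sd_target, tau) {
    if (sd_target == 0) return(numeric(n_steps))
    phi <- exp(-dt / tau)
    innov <- rnorm(n_steps, 0, sd_target * sqrt(1 - phi^2))
    innov[1] <- rnorm(1, 0, sd_target)
    as.numeric(stats::filter(innov, phi, method = "recursive"))
  }
  comp <- matrix(0, n_steps, 6,
                 dimnames = list(NULL, c("Pxx", "Pyy", "Pzz", "Pxy", "Pxz", "Pyz")))
  for (i in seq_along(modes$G_i)) {
    sd_off <- sqrt(kT * modes$G_i[i] / V)
    sd_diag <- sqrt(2) * sd_off
    for (nm in c("Pxy", "Pxz", "Pyz")) comp[, nm] <- comp[, nm] + ou(sd_off, modes$tau_i[i])
    for (nm in c("Pxx", "Pyy", "Pzz")) comp[, nm] <- comp[, nm] + ou(sd_diag, modes$tau_i[i])
  }
  stress_series(times = seq_len(n_steps) * dt - dt, components = comp,
                volume = V, temperature = T, units = "kcal_molA3")
}
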