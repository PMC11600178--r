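## igser: invert probe motion into the medium's complex modulus via the
## inertial generalized Stokes-Einstein relation.
##
## Frequency-domain GLE (one-sided transform, kernel exp(-i w t), s = i w):
##   Z*(w) = 6 pi R_h G*/s + 6 pi R_h^2 sqrt(rho_i G*)   (Stokes + Basset)
## with the added-mass part of the medium inertia absorbed into
## m_eff = m_bare + m_add, m_add = (2/3) pi R_h^3 rho. Probe friction follows
## from the MSD as
##   Z*(w) = 2 d kB T / (s^2 MSD(w)) - m_eff s.
## Friction is carried in kcal ns/(mol A^2); masses and densities are
## converted to energy-consistent units internally.

#' Probe specification for IGSER
#'
#' @param R_h hydrodynamic radius (A), from the first RDF peak.
#' @param m_bare bare probe mass (g/mol).
#' @param m_add added (medium) mass (g/mol); see [added_mass()].
#' @param R_b bare (carve) radius (A), optional metadata.
#' @param eps_ratio probe-protein interaction strength over eps_HPS, optional.
#' @return object of class `mr_probe_spec` with `m_eff = m_bare + m_add`.
#' @export
probe_spec <- function(R_h, m_bare, m_add = 0, R_b = NULL, eps_ratio = NULL) {
  stopifnot(R_h > 0, m_bare > 0, m_add >= 0)
  if (!is.null(R_b) && R_h < R_b)
    stop("hydrodynamic radius below bare radius", call. = FALSE)
  structure(list(R_h = R_h, R_b = R_b, m_bare = m_bare, m_add = m_add,
                 m_eff = m_bare + m_add, eps_ratio = eps_ratio),
            class = "mr_probe_spec")
}

#' Medium specification
#' @param rho dense-phase mass density (g/(mol A^3)).
#' @param T temperature (K).
#' @export
medium_spec <- function(rho, T) {
  stopifnot(rho >= 0, T > 0)
  structure(list(rho = rho, T = T), class = "mr_medium_spec")
}

#' Added mass of a sphere accelerating in a medium
#'
#' Half the displaced medium mass, `(2/3) pi R_h^3 rho`, the continuum
#' unsteady-Stokes result.
#'
#' @param R_h hydrodynamic radius (A).
#' @param rho medium mass density (g/(mol A^3)).
#' @return added mass in g/mol.
#' @export
added_mass <- function(R_h, rho) {
  stopifnot(R_h > 0, rho >= 0)
  2 / 3 * pi * R_h^3 * rho
}

#' Friction spectrum from the one-sided Fourier transform of the MSD
#'
#' `Z*(w) = 2 d kB T / ((i w)^2 MSD(w)) - i w m_eff`. In the inertialess
#' Newtonian limit this reduces to the constant Stokes friction `kB T / D`.
#'
#' @param msd_fourier complex MSD(omega) (A^2 ns), e.g. from [bsw_fourier()].
#' @param omega frequency grid (1/ns).
#' @param d number of tracked dimensions (2 or 3).
#' @param T temperature (K).
#' @param m_eff effective probe mass (g/mol).
#' @return object of class `mr_friction`: `omega`, complex `Z`
#'   (kcal ns/(mol A^2)).
#' @export
friction_from_msd <- function(msd_fourier, omega, d, T, m_eff) {
  stopifnot(length(msd_fourier) == length(omega), d %in% c(2, 3), T > 0)
  if (any(!is.finite(Re(msd_fourier))) || any(Mod(msd_fourier) == 0))
    stop("invalid MSD transform values (numeric error)", call. = FALSE)
  s <- complex(imaginary = omega)
  Z <- 2 * d * .const$kB * T / (s^2 * msd_fourier) - mass_internal(m_eff) * s
  structure(list(omega = omega, Z = Z, d = d, T = T, m_eff = m_eff),
            class = "mr_friction")
}

#' Complex modulus from the friction spectrum (IGSER)
#'
#' Solves the frequency-domain force balance
#' `Z* = 6 pi R_h G*/(i w) + 6 pi R_h^2 sqrt(rho G*)` for `G*` at each
#' frequency. With medium density present this is a quadratic in `sqrt(G*)`;
#' the branch with positive real part of `sqrt(G*)` (passivity under the
#' `exp(-i w t)` convention) is selected. Frequencies with no admissible root
#' are masked (NA) and counted, never silently dropped.
#'
#' @param Z an `mr_friction`.
#' @param probe an [probe_spec()].
#' @param medium an [medium_spec()]; `rho = 0` drops the Basset term.
#' @return object of class `mr_modulus`: `omega`, `G_prime`, `G_double_prime`
#'   (kcal/(mol A^3)), plus `n_masked`.
#' @export
modulus_from_friction <- function(Z, probe, medium) {
  R <- probe$R_h
  rho_i <- mass_internal(medium$rho)  # kcal ns^2/(mol A^5)
  s <- complex(imaginary = Z$omega)
  G <- complex(length(s))
  if (rho_i == 0) {
    G <- s * Z$Z / (6 * pi * R)
  } else {
    a <- 6 * pi * R / s
    b <- 6 * pi * R^2 * sqrt(rho_i)
    disc <- sqrt(b^2 + 4 * a * Z$Z)
    for (i in seq_along(s)) {
      roots <- c((-b + disc[i]) / (2 * a[i]), (-b - disc[i]) / (2 * a[i]))
      ok <- roots[Re(roots) > 0]
      G[i] <- if (length(ok) == 0) NA_complex_ else ok[1]^2
    }
  }
  n_masked <- sum(is.na(G))
  if (n_masked > 0)
    warning(n_masked, " frequencies without admissible root were masked", call. = FALSE)
  structure(list(omega = Z$omega, G_prime = Re(G), G_double_prime = Im(G),
                 n_masked = n_masked),
            class = "mr_modulus")
}

#' @export
print.mr_modulus <- function(x, ...) {
  cat(sprintf("<mr_modulus> %d frequencies in [%g, %g] 1/ns\n",
              length(x$omega), min(x$omega), max(x$omega)))
  cx <- tryCatch(crossover(x), error = function(e) NULL)
  if (!is.null(cx) && !is.na(cx$omega_c))
    cat(sprintf("  crossover omega_c = %g 1/ns, tau = %g ns\n", cx$omega_c, cx$tau))
  invisible(x)
}

#' Maxwell-mode complex modulus (closed form)
#'
#' `G' = sum G_i w^2 tau_i^2/(1 + w^2 tau_i^2)`,
#' `G'' = sum G_i w tau_i/(1 + w^2 tau_i^2)`. Used for ground truth and for
#' the Green-Kubo route.
#'
#' @param modes an [maxwell_modes()] or list with `G_i`, `tau_i`.
#' @param omega frequencies (1/ns).
#' @return an `mr_modulus`.
#' @export
maxwell_moduli <- function(modes, omega) {
  gp <- rep(0, length(omega)); gpp <- rep(0, length(omega))
  for (i in seq_along(modes$G_i)) {
    wt <- omega * modes$tau_i[i]
    gp <- gp + modes$G_i[i] * wt^2 / (1 + wt^2)
    gpp <- gpp + modes$G_i[i] * wt / (1 + wt^2)
  }
  structure(list(omega = omega, G_prime = gp, G_double_prime = gpp,
                 n_masked = 0L), class = "mr_modulus")
}

#' Crossover frequency and relaxation time
#'
#' Finds the lowest-frequency crossing where `G'' > G'` below and `G' > G''`
#' above. The crossing is located in log-log space by a local linear fit of
#' `log(G'/G'')` against `log(omega)` over up to `smooth` grid points on each
#' side of the sign change (for a Maxwell fluid this ratio is exactly
#' `log(omega tau)`, so the fit is exact; for fitted spectra it averages out
#' parametrization ripple). The relaxation time is `tau = 1/omega_c`. Without
#' a crossing (no dominant elastic response) both are NA.
#'
#' @param mod an `mr_modulus`.
#' @param smooth number of grid points on each side of the crossing used in
#'   the local fit (1 reduces to two-point interpolation).
#' @return list `omega_c` (1/ns), `tau` (ns), `n_crossings`.
#' @export
crossover <- function(mod, smooth = 3) {
  ok <- is.finite(mod$G_prime) & is.finite(mod$G_double_prime) &
    mod$G_prime > 0 & mod$G_double_prime > 0
  w <- mod$omega[ok]
  r <- log(mod$G_prime[ok] / mod$G_double_prime[ok])
  if (length(w) < 2) return(list(omega_c = NA_real_, tau = NA_real_, n_crossings = 0L))
  ord <- order(w); w <- w[ord]; r <- r[ord]
  up <- which(r[-length(r)] < 0 & r[-1] >= 0)
  if (length(up) == 0) return(list(omega_c = NA_real_, tau = NA_real_, n_crossings = 0L))
  i <- up[1]
  sel <- max(1, i - smooth + 1):min(length(w), i + smooth)
  fit <- lm(r[sel] ~ log(w[sel]))
  wc <- if (abs(coef(fit)[2]) > 0) exp(-coef(fit)[1] / coef(fit)[2]) else NA_real_
  # guard: stay within the bracketing interval's neighborhood
  if (!is.na(wc) && (wc < w[max(1, i - smooth)] || wc > w[min(length(w), i + smooth + 1)])) {
    lw <- log(w[i]) + (0 - r[i]) * (log(w[i + 1]) - log(w[i])) / (r[i + 1] - r[i])
    wc <- exp(lw)
  }
  list(omega_c = unname(wc), tau = 1 / unname(wc), n_crossings = length(up))
}

#' Terminal viscosity from the viscous modulus
#'
#' `eta = mean(G''/w)` over a window in the terminal regime; the window must
#' verify `G'' ~ w` (log-log slope within 0.05 of 1), otherwise a
#' terminal-region error is raised.
#'
#' @param mod an `mr_modulus`.
#' @param terminal_window `c(wmin, wmax)` (1/ns); default: the lowest decade
#'   of the grid.
#' @param slope_tol allowed deviation of the log-log slope from 1.
#' @return eta in kcal ns/(mol A^3).
#' @export
terminal_viscosity <- function(mod, terminal_window = NULL, slope_tol = 0.05) {
  ok <- is.finite(mod$G_double_prime) & mod$G_double_prime > 0
  w <- mod$omega[ok]; g2 <- mod$G_double_prime[ok]
  if (is.null(terminal_window)) terminal_window <- c(min(w), min(w) * 10)
  i <- which(w >= terminal_window[1] & w <= terminal_window[2])
  if (length(i) < 3) stop("terminal window holds fewer than 3 frequencies", call. = FALSE)
  slope <- coef(lm(log(g2[i]) ~ log(w[i])))[2]
  if (abs(slope - 1) > slope_tol)
    stop(sprintf("window not terminal: d log G''/d log w = %.3f (terminal-region error)",
                 slope), call. = FALSE)
  mean(g2[i] / w[i])
}

#' Write moduli as TSV plus a JSON summary
#' @param mod an `mr_modulus`.
#' @param path output TSV (`omega, G_prime, G_double_prime`); the summary
#'   (`omega_c`, `tau`, `eta`, optional `eta_over_eta_GK`) goes to `<path>.json`.
#' @param eta_GK optional Green-Kubo viscosity for the ratio diagnostic.
#' @param terminal_window passed to [terminal_viscosity()].
#' @export
write_modulus <- function(mod, path, eta_GK = NULL, terminal_window = NULL) {
  write.table(data.frame(omega = mod$omega, G_prime = mod$G_prime,
                         G_double_prime = mod$G_double_prime),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  cx <- crossover(mod)
  eta <- tryCatch(terminal_viscosity(mod, terminal_window), error = function(e) NA_real_)
  sm <- list(omega_c = cx$omega_c, tau = cx$tau, eta = eta)
  if (!is.null(eta_GK)) sm$eta_over_eta_GK <- eta / eta_GK
  jsonlite::write_json(sm, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
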