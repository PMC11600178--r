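## green_kubo: bulk-rheology route from equilibrium pressure-tensor
## fluctuations; validates the microrheology route.

## unbiased autocorrelation <x(0) x(t)> of a (mean-free) series via FFT
.acf_fft <- function(x, n_lags = length(x)) {
  n <- length(x)
  nf <- 2^ceiling(log2(2 * n))
  fx <- fft(c(x, rep(0, nf - n)))
  ac <- Re(fft(fx * Conj(fx), inverse = TRUE))[1:n_lags] / nf
  ac / (n - 0:(n_lags - 1))
}

#' Shear stress relaxation modulus from a pressure-tensor series
#'
#' Uses the symmetric-traceless estimator combining the three off-diagonal
#' autocorrelations (weight 1/5) and the three normal-stress-difference
#' autocorrelations `N_ab = P_aa - P_bb` (weight 1/30), scaled by
#' `V/(kB T)`. For an isotropic equilibrium fluid this equals
#' `V/(kB T) <P_xy(0) P_xy(t)>` with much better statistics. Sample means are
#' removed before correlating.
#'
#' @param stress an [stress_series()].
#' @param max_lag_frac fraction of the series length to keep as lags
#'   (autocorrelations beyond ~1/2 of the series are mostly noise).
#' @return object of class `mr_gt`: `t` (ns), `G` (kcal/(mol A^3)), `V`, `T`.
#' @export
relaxation_modulus <- function(stress, max_lag_frac = 0.5) {
  comp <- stress$components
  n <- length(stress$times)
  n_lags <- max(2L, floor(n * max_lag_frac))
  ctr <- function(x) x - mean(x)
  off <- c("Pxy", "Pxz", "Pyz")
  acc <- numeric(n_lags)
  for (nm in off) acc <- acc + .acf_fft(ctr(comp[[nm]]), n_lags) / 5
  pairs <- list(c("Pxx", "Pyy"), c("Pxx", "Pzz"), c("Pyy", "Pzz"))
  for (p in pairs) {
    nab <- ctr(comp[[p[1]]] - comp[[p[2]]])
    acc <- acc + .acf_fft(nab, n_lags) / 30
  }
  dt <- stress$times[2] - stress$times[1]
  G <- acc * stress$volume / (.const$kB * stress$temperature)
  structure(list(t = (0:(n_lags - 1)) * dt, G = G,
                 V = stress$volume, T = stress$temperature),
            class = "mr_gt")
}

#' Maxwell modes container
#' @param G_i mode amplitudes (kcal/(mol A^3)), non-negative.
#' @param tau_i mode times (ns), strictly increasing.
#' @export
maxwell_modes <- function(G_i, tau_i) {
  stopifnot(length(G_i) == length(tau_i), all(G_i >= 0), all(diff(tau_i) > 0) || length(tau_i) == 1)
  structure(list(G_i = G_i, tau_i = tau_i), class = "mr_maxwell")
}

## small active-set non-negative least squares (A x ~ b, x >= 0)
.nnls <- function(A, b) {
  p <- ncol(A)
  active <- rep(TRUE, p)
  x <- rep(0, p)
  for (it in seq_len(3 * p + 3)) {
    if (!any(active)) break
    Aa <- A[, active, drop = FALSE]
    xa <- tryCatch(qr.solve(Aa, b), error = function(e) rep(0, sum(active)))
    if (all(xa >= -1e-12)) {
      x[active] <- pmax(xa, 0)
      break
    }
    drop_i <- which(active)[which.min(xa)]
    active[drop_i] <- FALSE
    x[drop_i] <- 0
  }
  x
}

#' Fit Maxwell modes to the tail of G(t)
#'
#' Non-negative least squares for the amplitudes `G_i` at fixed
#' log-equidistant relaxation times spanning `[t_start, t_max]` (default 4
#' modes).
#'
#' @param G an `mr_gt` from [relaxation_modulus()] (or any list with `t`, `G`).
#' @param n_modes number of modes (default 4).
#' @param t_start start of the fitted tail (ns); default: first time G falls
#'   below 5% of G(0).
#' @return an [maxwell_modes()] with attribute `residual` (RMS of fit).
#' @export
fit_modes <- function(G, n_modes = 4, t_start = NULL) {
  t <- G$t; g <- G$G
  if (is.null(t_start)) {
    i0 <- which(g < 0.05 * g[1])[1]
    t_start <- if (is.na(i0)) t[max(2, floor(length(t) / 4))] else t[i0]
    t_start <- max(t_start, t[2])
  }
  if (t_start < min(t) || t_start >= max(t))
    stop("t_start outside grid", call. = FALSE)
  tau <- 10^seq(log10(t_start), log10(max(t)), length.out = n_modes)
  sel <- t >= t_start
  A <- exp(-outer(t[sel], tau, "/"))
  Gi <- .nnls(A, g[sel])
  if (all(Gi == 0) && any(g[sel] != 0))
    warning("all-zero Maxwell-mode solution for nonzero input (fit warning)", call. = FALSE)
  out <- maxwell_modes(Gi, tau)
  attr(out, "residual") <- sqrt(mean((A %*% Gi - g[sel])^2))
  out
}

#' Green-Kubo viscosity (hybrid numerical + analytic integral)
#'
#' `eta_GK = trapz(G, 0..t_switch) + sum_i G_i tau_i exp(-t_switch/tau_i)`:
#' numerical integration of the (noisy) short-time modulus plus the analytic
#' integral of the fitted Maxwell modes beyond `t_switch`.
#'
#' @param G an `mr_gt`.
#' @param modes an [maxwell_modes()].
#' @param t_switch switch time (ns); default: first time G falls below 5% of
#'   G(0) (0 uses the modes only).
#' @return eta_GK in kcal ns/(mol A^3).
#' @export
gk_viscosity <- function(G, modes, t_switch = NULL) {
  if (is.null(t_switch)) {
    i0 <- which(G$G < 0.05 * G$G[1])[1]
    t_switch <- if (is.na(i0)) max(G$t) / 2 else G$t[i0]
  }
  if (t_switch > max(G$t)) stop("t_switch beyond grid", call. = FALSE)
  eta_num <- 0
  if (t_switch > 0) {
    sel <- G$t <= t_switch
    ts <- G$t[sel]; gs <- G$G[sel]
    eta_num <- sum(diff(ts) * (head(gs, -1) + tail(gs, -1)) / 2)
  }
  eta <- eta_num + sum(modes$G_i * modes$tau_i * exp(-t_switch / modes$tau_i))
  if (eta < 0) stop("negative viscosity (integration error): pathological input", call. = FALSE)
  eta
}

#' Elastic and viscous moduli from G(t) or Maxwell modes
#'
#' For Maxwell modes, the exact closed forms are used (see
#' [maxwell_moduli()]). For a raw relaxation modulus, a damped numerical
#' one-sided transform `G*(w) = i w INT G(t) e^(-i w t) dt` is computed by
#' trapezoidal quadrature with an `exp(-t/t_max)`-free damping of the noisy
#' tail handled by windowing at the last reliable lag.
#'
#' @param G an [maxwell_modes()] or an `mr_gt`.
#' @param omega frequency grid (1/ns).
#' @return an `mr_modulus`.
#' @export
gk_moduli <- function(G, omega) {
  if (inherits(G, "mr_maxwell")) return(maxwell_moduli(G, omega))
  t <- G$t; g <- G$G
  dt <- t[2] - t[1]
  Gs <- vapply(omega, function(w) {
    s <- complex(imaginary = w)
    kern <- g * exp(-s * t)
    s * (sum(kern) - (kern[1] + kern[length(kern)]) / 2) * dt
  }, complex(1))
  structure(list(omega = omega, G_prime = Re(Gs), G_double_prime = Im(Gs),
                 n_masked = 0L), class = "mr_modulus")
}
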