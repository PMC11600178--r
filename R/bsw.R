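## bsw_spectrum: power-law-spectrum (BSW-like) parametrization of MSD(t)
## with closed forms in time and frequency domains.
##
## Arrangement adopted here: the MSD is a continuous piecewise power law on
## the fixed relaxation-time grid tau_0 < ... < tau_max,
##   MSD(t) = C t^2                         t <= tau_0      (ballistic)
##          = g_j t^alpha_j                 tau_{j-1} <= t <= tau_j
##          = (6 D) t                       t >= tau_max    (diffusive)
## with weights chained by continuity: g_1 = C tau_0^(2 - alpha_1),
## g_{j+1} = g_j tau_j^(alpha_j - alpha_{j+1}), 6 D = g_n tau_max^(alpha_n-1).
## Each window's exponent is the local log-log slope of the MSD, which makes
## the representation flexible enough to track any monotone MSD spanning
## ballistic to diffusive behavior. The one-sided Fourier transform of each
## piece reduces to complex upper incomplete gamma functions at the window
## edges; the diffusive tail is Abel-regularized.

#' Construct a BSW-like MSD parametrization
#'
#' `n_max` modes on the windows `(tau[j], tau[j+1]]` carry exponents
#' `alpha_j` (the local log-log slope of the MSD, in (0, 2]); weights `g_j`
#' follow from the ballistic coefficient `C` and continuity at the window
#' edges, so the curve is exactly `C t^2` below `tau[1]`, exactly diffusive
#' beyond `tau_max`, and continuous everywhere (in particular the last mode
#' and the terminal term agree exactly at `t = tau_max`).
#'
#' @param tau relaxation-time grid, length `n_max + 1`, strictly increasing (ns).
#' @param alpha mode exponents, length `n_max`, each in (0, 2].
#' @param C ballistic coefficient (A^2/ns^2).
#' @return object of class `mr_bsw` with fields `n_max`, `tau`, `alpha`, `g`,
#'   `g0` (the MSD value at `tau_max`), `C`, `D` (diffusion coefficient,
#'   3-d convention `MSD = 6 D t`).
#' @export
bsw_spectrum <- function(tau, alpha, C) {
  n <- length(alpha)
  stopifnot(length(tau) == n + 1, n >= 1, C > 0)
  if (any(diff(tau) <= 0) || any(tau <= 0))
    stop("tau must be positive and strictly increasing", call. = FALSE)
  if (any(alpha <= 0) || any(alpha > 2))
    stop("alpha must lie in (0, 2]", call. = FALSE)
  g <- numeric(n)
  g[1] <- C * tau[1]^(2 - alpha[1])
  if (n > 1) for (j in 2:n) g[j] <- g[j - 1] * tau[j]^(alpha[j - 1] - alpha[j])
  tmax <- tau[n + 1]
  sixD <- g[n] * tmax^(alpha[n] - 1)
  structure(list(n_max = n, tau = tau, alpha = alpha, g = g,
                 g0 = g[n] * tmax^alpha[n], C = C, D = sixD / 6),
            class = "mr_bsw")
}

#' @export
print.mr_bsw <- function(x, ...) {
  cat(sprintf("<mr_bsw> %d modes, tau in [%g, %g] ns\n", x$n_max,
              x$tau[1], x$tau[x$n_max + 1]))
  cat("  alpha:", signif(x$alpha, 4), "\n")
  cat(sprintf("  C = %g A^2/ns^2, D = %g A^2/ns (3-d convention)\n", x$C, x$D))
  if (!is.null(x$chi2)) cat(sprintf("  fit chi2 = %g\n", x$chi2))
  invisible(x)
}

#' Evaluate the closed-form MSD of a BSW parametrization
#'
#' @param spec an [bsw_spectrum()].
#' @param t positive lag times (ns).
#' @param components if TRUE, also return the two matched terms at
#'   `tau_max` (last power-law mode and terminal diffusive term), whose
#'   equality there is the continuity property of the construction.
#' @return MSD values (A^2), or a list `msd`, `term_spectrum`,
#'   `term_terminal`.
#' @export
eval_msd <- function(spec, t, components = FALSE) {
  if (any(t <= 0)) stop("t must be positive (domain error)", call. = FALSE)
  n <- spec$n_max; tau <- spec$tau; a <- spec$alpha; g <- spec$g
  tmax <- tau[n + 1]
  k <- findInterval(t, c(0, tau), rightmost.closed = FALSE)  # 1 = ballistic
  msd <- numeric(length(t))
  bal <- k == 1
  msd[bal] <- spec$C * t[bal]^2
  dif <- k >= n + 2
  msd[dif] <- 6 * spec$D * t[dif]
  for (j in seq_len(n)) {
    sel <- k == j + 1
    if (any(sel)) msd[sel] <- g[j] * t[sel]^a[j]
  }
  if (!components) return(msd)
  list(msd = msd,
       term_spectrum = g[n] * pmin(t, tmax)^a[n],
       term_terminal = 6 * spec$D * pmin(t, tmax))
}

## ---- one-sided Fourier transform, kernel exp(-i w t) --------------------

## upper incomplete gamma Gamma(a, z) for complex z (principal branch),
## a real > 0. Kummer series for small |z|, asymptotic expansion for large
## |z|; both accurate to ~1e-8 or better on the imaginary axis for a <= 4.
.cgamma_upper <- function(a, z) {
  if (Mod(z) < 1e-300) return(complex(real = gamma(a)))
  if (Mod(z) <= 15) {
    term <- 1 / a
    s <- term
    n <- 0
    while (n < 2000) {
      n <- n + 1
      term <- term * z / (a + n)
      s <- s + term
      if (Mod(term) < 1e-17 * Mod(s)) break
    }
    gamma(a) - exp(a * log(z) - z) * s
  } else {
    s <- complex(real = 1)
    term <- complex(real = 1)
    prev <- Inf
    k <- 0
    repeat {
      k <- k + 1
      term <- term * (a - k) / z
      # optimal truncation: stop once terms stop shrinking
      if (Mod(term) >= prev || k > 60) break
      s <- s + term
      prev <- Mod(term)
      if (prev < 1e-17 * Mod(s)) break
    }
    exp((a - 1) * log(z) - z) * s
  }
}

## integral of t^p exp(-s t) over [lo, hi] for integer p in 0:2 (hi may be
## Inf in the Abel-regularized sense for purely imaginary s)
.ft_poly <- function(p, lo, hi, s) {
  anti <- function(t) {
    if (is.infinite(t)) return(0 + 0i)
    e <- exp(-s * t)
    switch(p + 1,
           -e / s,
           -e * (t / s + 1 / s^2),
           -e * (t^2 / s + 2 * t / s^2 + 2 / s^3))
  }
  anti(hi) - anti(lo)
}

## integral of t^alpha exp(-s t) over [lo, hi], alpha real > -1
.ft_power <- function(alpha, lo, hi, s) {
  if (abs(alpha - round(alpha)) < 1e-12 && round(alpha) %in% 0:2)
    return(.ft_poly(round(alpha), lo, hi, s))
  a1 <- alpha + 1
  glo <- if (lo <= 0) complex(real = gamma(a1)) else .cgamma_upper(a1, s * lo)
  ghi <- if (is.infinite(hi)) 0 + 0i else .cgamma_upper(a1, s * hi)
  exp(-a1 * log(s)) * (glo - ghi)
}

## piecewise description: ballistic + power-law windows + linear tail
.bsw_pieces <- function(spec) {
  n <- spec$n_max
  pieces <- list(list(lo = 0, hi = spec$tau[1], coef = spec$C, alpha = 2))
  for (j in seq_len(n))
    pieces[[j + 1]] <- list(lo = spec$tau[j], hi = spec$tau[j + 1],
                            coef = spec$g[j], alpha = spec$alpha[j])
  list(pieces = pieces, tail_slope = 6 * spec$D, tmax = spec$tau[n + 1])
}

#' One-sided Fourier transform of the BSW closed-form MSD
#'
#' Computes `MSD(omega) = INT_0^Inf MSD(t) exp(-i omega t) dt` analytically:
#' each power-law piece transforms to complex upper incomplete gamma
#' functions evaluated at the window edges, and the diffusive tail beyond
#' `tau_max` is Abel-regularized (`INT t exp(-i w t) dt -> -1/w^2`). The same
#' kernel convention `exp(-i omega t)` is used everywhere downstream, so for
#' a diffusive MSD `6 D t` the transform is `-6D/w^2` and for a ballistic
#' `C t^2` it is `2 i C/w^3`.
#'
#' @param spec an [bsw_spectrum()].
#' @param omega positive frequencies (1/ns).
#' @return complex vector MSD(omega) (A^2 ns).
#' @details To keep the assembly numerically stable, the diffusive asymptote
#'   `6 D t` is transformed analytically over the whole half-line
#'   (`6D/s^2 = -6D/omega^2`) and only the compactly supported remainder
#'   `MSD(t) - 6 D t` (identically zero beyond `tau_max`) is assembled from
#'   the window integrals; this avoids cancellation between the oscillatory
#'   regularized tail and the finite windows.
#' @export
bsw_fourier <- function(spec, omega) {
  if (any(omega <= 0)) stop("omega must be positive", call. = FALSE)
  pw <- .bsw_pieces(spec)
  sixD <- pw$tail_slope
  vapply(omega, function(w) {
    s <- complex(imaginary = w)
    acc <- sixD / s^2   # transform of the 6 D t asymptote
    for (p in pw$pieces) {
      acc <- acc + p$coef * .ft_power(p$alpha, p$lo, p$hi, s) -
        sixD * .ft_poly(1, p$lo, p$hi, s)
    }
    acc
  }, complex(1))
}

## ---- fitting -------------------------------------------------------------

## build a spectrum from the free exponents; when sixD is given the last
## exponent is determined by requiring the model to land exactly on the
## measured diffusive amplitude 6 D at tau_max (both-end anchoring); a
## penalty is returned when that exponent must be clamped into (0, 2]
.bsw_make <- function(alpha_free, tau, C, sixD = NULL) {
  n <- length(tau) - 1
  if (is.null(sixD)) {
    return(list(spec = bsw_spectrum(tau, alpha_free, C), penalty = 0))
  }
  lM <- log(C) + 2 * log(tau[1])
  if (n > 1) lM <- lM + sum(alpha_free * diff(log(tau[seq_len(n)])))
  a_n <- (log(sixD * tau[n + 1]) - lM) / log(tau[n + 1] / tau[n])
  a_cl <- min(max(a_n, 0.05), 2)
  penalty <- (a_n - a_cl)^2
  list(spec = bsw_spectrum(tau, c(alpha_free, a_cl), C), penalty = penalty)
}

.bsw_chi2 <- function(alpha, tau, C, td, md, sixD = NULL) {
  mk <- .bsw_make(alpha, tau, C, sixD)
  mod <- eval_msd(mk$spec, td)
  mean(((mod - md) / md)^2) + 10 * mk$penalty
}

## curvature-adaptive knot placement: knot density proportional to the local
## log-log curvature of the (smoothed) data plus a uniform floor
.bsw_adaptive_tau <- function(lg, md, n_max, lo, hi) {
  lt <- log10(lg); lm <- log10(md)
  sl <- diff(lm) / diff(lt)
  mid <- (lt[-1] + lt[-length(lt)]) / 2
  ns <- max(3, round(length(sl) / 15))
  sls <- stats::filter(sl, rep(1 / ns, ns), sides = 2)
  ok <- !is.na(sls)
  cur <- abs(diff(sls[ok])) / diff(mid[ok])
  cmid <- (mid[ok][-1] + mid[ok][-sum(ok)]) / 2
  sel <- cmid >= log10(lo) & cmid <= log10(hi) & !is.na(cur)
  if (sum(sel) < n_max)
    return(10^seq(log10(lo), log10(hi), length.out = n_max + 1))
  w <- cur[sel] + 0.15
  cumw <- cumsum(w) / sum(w)
  qs <- seq(0, 1, length.out = n_max + 1)[2:n_max]
  knots <- approx(cumw, cmid[sel], xout = qs, ties = "ordered")$y
  tau <- 10^c(log10(lo), knots, log10(hi))
  tau[!duplicated(signif(tau, 10))]
}

#' Fit a BSW parametrization to an MSD curve
#'
#' Relaxation times `tau_j` are fixed (default: `n_max + 1` log-equidistant
#' values between 3x the shortest positive lag and the longest lag / 3) and
#' the exponents `alpha_j` are optimized to minimize the chi-squared of
#' relative residuals on a log-spaced lag grid (each decade weighted
#' equally). The ballistic coefficient is taken from the curve's fitted `C`
#' ([fit_limits()]), or, failing that, from the lowest half-decade of lags;
#' weights `g_j` then follow from the continuity chain (see
#' [bsw_spectrum()]). Optimization is bounded (`alpha` in [0.05, 2]) with
#' deterministic multi-start (three flat levels plus the local data slope);
#' ties are broken by lowest chi-squared.
#'
#' @param curve an `mr_msd` (positive lags spanning >= 3 decades recommended).
#' @param n_max number of modes.
#' @param tau_grid `"auto"` (log-equidistant), `"adaptive"` (knot density
#'   follows the log-log curvature of the data, concentrating resolution at
#'   the ballistic-to-caged elbow), or an explicit numeric grid of length
#'   `n_max + 1`.
#' @param points_per_decade density of the chi-squared evaluation grid.
#' @param anchor_D when the curve carries a fitted diffusion coefficient
#'   ([fit_limits()]), tie the terminal amplitude of the model to it exactly:
#'   the last exponent is then determined by the two-sided anchoring
#'   (ballistic `C` at `tau_0`, diffusive `6 D` at `tau_max`) and only
#'   `n_max - 1` exponents are optimized. This keeps the terminal regime of
#'   the transform exact where the data constrain it best.
#' @return an `mr_bsw` with extra fields `chi2` (mean squared relative
#'   residual) and `n_data`.
#' @export
bsw_fit <- function(curve, n_max = 5, tau_grid = "auto", points_per_decade = 30,
                    anchor_D = TRUE, anchor_C = c("auto", "first_lag", "curve")) {
  anchor_C <- match.arg(anchor_C)
  pos <- curve$t > 0 & curve$msd > 0
  t <- curve$t[pos]; m <- curve$msd[pos]
  if (length(t) < n_max + 3) stop("too few positive lags for fit", call. = FALSE)
  lg <- 10^seq(log10(min(t)), log10(max(t)), by = 1 / points_per_decade)
  md <- exp(approx(log(t), log(m), xout = log(lg), rule = 2)$y)
  if (identical(tau_grid, "auto") || identical(tau_grid, "adaptive")) {
    # first window opens at the shortest lag (the pure-ballistic closed form
    # then never competes with data), last closes a third of a decade early
    lo <- min(t); hi <- max(t) / 2
    if (hi <= lo) stop("lag range too narrow for tau grid (grid error)", call. = FALSE)
    tau <- if (identical(tau_grid, "adaptive"))
      .bsw_adaptive_tau(lg, md, n_max, lo, hi)
    else 10^seq(log10(lo), log10(hi), length.out = n_max + 1)
    n_max <- length(tau) - 1
  } else {
    tau <- as.numeric(tau_grid)
    if (length(tau) != n_max + 1) stop("tau grid must have n_max + 1 points (grid error)", call. = FALSE)
    if (min(tau) < min(t) || max(tau) > max(t))
      stop("tau grid outside data range (grid error)", call. = FALSE)
  }
  # short-time amplitude anchor: the fitted ballistic coefficient when the
  # ballistic regime is resolved, else the exact value anchor at the first lag
  # (C tau_0^2 = MSD(tau_0); appropriate when the probe velocity decorrelates
  # within one save interval, as for Langevin-dynamics probes)
  C <- switch(anchor_C,
    curve = curve$C,
    first_lag = m[1] / t[1]^2,
    auto = if (!is.null(curve$C)) curve$C else m[1] / t[1]^2)
  if (is.null(C)) stop("curve carries no ballistic coefficient; run fit_limits()",
                       call. = FALSE)
  sixD <- if (anchor_D && !is.null(curve$D)) 2 * curve$d * curve$D else NULL
  n_free <- if (is.null(sixD)) n_max else n_max - 1
  if (n_free < 1) stop("need at least 2 modes with D anchoring", call. = FALSE)
  slope_init <- local({
    mid <- sqrt(tau[-1] * tau[-(n_max + 1)])
    ls <- diff(log(md)) / diff(log(lg))
    s <- approx(log(sqrt(lg[-1] * lg[-length(lg)])), ls, xout = log(mid), rule = 2)$y
    pmin(pmax(s, 0.1), 2)[seq_len(n_free)]
  })
  starts <- list(rep(0.5, n_free), rep(1.0, n_free), rep(1.5, n_free), slope_init)
  best <- NULL
  for (st in starts) {
    op <- tryCatch(
      optim(st, .bsw_chi2, tau = tau, C = C, td = lg, md = md, sixD = sixD,
            method = "L-BFGS-B", lower = rep(0.05, n_free),
            upper = rep(2, n_free),
            control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best))
    stop("BSW optimizer failed to converge (fit error)", call. = FALSE)
  mk <- .bsw_make(best$par, tau, C, sixD)
  sp <- mk$spec
  sp$chi2 <- best$value - 10 * mk$penalty
  sp$n_data <- length(lg)
  sp
}

#' Serialize / write a BSW parametrization as JSON
#' @param spec an `mr_bsw`.
#' @param path output JSON path.
#' @export
write_bsw <- function(spec, path) {
  jsonlite::write_json(list(n_max = spec$n_max, tau = spec$tau,
                            alpha = spec$alpha, g = spec$g, g0 = spec$g0,
                            C = spec$C),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
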