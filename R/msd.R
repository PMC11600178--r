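## msd: time-origin-averaged mean-square displacement, single and multi probe.

## FFT MSD over all time origins for one scalar series (Kneller algorithm).
## MSD(k) = (1/(N-k)) sum_i (x_{i+k}-x_i)^2 = SS(k) - 2*AC(k)
## with AC the raw autocorrelation and SS from cumulative sums of squares.
.msd_fft_1d <- function(x) {
  n <- length(x)
  nf <- 2^ceiling(log2(2 * n))
  fx <- fft(c(x, rep(0, nf - n)))
  ac <- Re(fft(fx * Conj(fx), inverse = TRUE))[1:n] / nf
  x2 <- x^2
  ss <- numeric(n)
  # D(k) = sum_{i=0}^{N-k-1} (x2_i + x2_{i+k})
  csum <- cumsum(x2)
  tot <- csum[n]
  # sum_{i=1}^{N-k} x2_i = csum[N-k]; sum_{i=k+1}^{N} x2_i = tot - csum[k]
  k <- 0:(n - 1)
  head_sum <- c(tot, csum[(n - 1):1])   # csum[n-k] for k=0..n-1
  tail_sum <- tot - c(0, csum[1:(n - 1)])
  (head_sum + tail_sum - 2 * ac) / (n - k)
}

## Brute-force O(N^2) reference estimator (used as oracle in tests and
## selectable for verification).
.msd_brute_1d <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k) {
    if (k == 0) return(0)
    d <- x[(k + 1):n] - x[1:(n - k)]
    mean(d * d)
  }, 0)
}

.lag_index <- function(n, dt, lag_grid, points_per_decade = 30) {
  if (is.numeric(lag_grid)) {
    idx <- unique(pmax(1L, pmin(n, round(lag_grid / dt) + 1L)))
    return(sort(idx))
  }
  switch(lag_grid,
    linear = seq_len(n),
    log = {
      lo <- 0; hi <- log10(n - 1)
      k <- unique(c(1L, round(10^seq(lo, hi, by = 1 / points_per_decade)) + 1L))
      sort(k[k <= n])
    },
    stop("unknown lag grid", call. = FALSE))
}

#' Mean-square displacement of probe particles
#'
#' Computes the time-origin-averaged MSD (all origins) for each selected probe
#' and averages the probes with equal weight. Motion can be restricted to a
#' subset of axes (restrained-probe mode): the returned dimensionality `d` is
#' the number of unmasked axes and propagates to all downstream frequency-
#' domain formulas.
#'
#' @param traj an unwrapped [trajectory()].
#' @param probes integer probe ids to include (default: all probe groups).
#' @param dims axes to track: `"xyz"`, `"xy"`, `"xz"`, `"yz"`, or a logical
#'   length-3 mask.
#' @param lag_grid `"log"` (default, 30 points/decade), `"linear"`, or an
#'   explicit numeric vector of lags in ns.
#' @param points_per_decade log-grid density.
#' @param method `"fft"` (O(N log N)) or `"brute"` (O(N^2) reference); both
#'   give identical results to floating-point accumulation.
#' @return object of class `mr_msd`: list with `t` (ns), `msd` (A^2), `d`,
#'   `n_probes`, and NULL slots `C`, `D` until [fit_limits()] is applied.
#' @export
compute_msd <- function(traj, probes = NULL, dims = "xyz", lag_grid = "log",
                        points_per_decade = 30, method = c("fft", "brute")) {
  method <- match.arg(method)
  mask <- if (is.logical(dims)) dims else {
    d <- strsplit(match.arg(dims, c("xyz", "xy", "xz", "yz")), "")[[1]]
    c("x", "y", "z") %in% d
  }
  if (sum(mask) < 2) stop("fewer than 2 tracked dimensions (dimension error)", call. = FALSE)
  n <- length(traj$times)
  if (n < 2) stop("need at least 2 frames", call. = FALSE)
  grp <- traj$probe_ids
  cand <- sort(unique(grp[!is.na(grp) & traj$roles != "residue"]))
  if (is.null(probes)) probes <- cand
  if (!all(probes %in% cand)) stop("probe ids absent from trajectory (selection error)", call. = FALSE)
  dt <- traj$times[2] - traj$times[1]
  est <- if (method == "fft") .msd_fft_1d else .msd_brute_1d
  msd_sum <- numeric(n)
  for (p in probes) {
    cols <- which(grp == p & traj$roles != "residue")
    # probe position = centre of mass of its beads (equal masses)
    m <- numeric(n)
    for (ax in which(mask)) {
      xs <- traj$positions[, cols, ax, drop = FALSE]
      x <- rowMeans(matrix(xs, nrow = n))
      m <- m + est(x)
    }
    msd_sum <- msd_sum + m
  }
  msd <- msd_sum / length(probes)
  idx <- .lag_index(n, dt, lag_grid, points_per_decade)
  structure(list(t = (idx - 1) * dt, msd = msd[idx], d = sum(mask),
                 n_probes = length(probes), C = NULL, D = NULL,
                 volume_fraction_warning = FALSE),
            class = "mr_msd")
}

#' @export
print.mr_msd <- function(x, ...) {
  cat(sprintf("<mr_msd> %d lags [%g, %g] ns, d = %d, n_probes = %d\n",
              length(x$t), min(x$t), max(x$t), x$d, x$n_probes))
  if (!is.null(x$C)) cat(sprintf("  ballistic C = %g A^2/ns^2\n", x$C))
  if (!is.null(x$D)) cat(sprintf("  diffusion D = %g A^2/ns\n", x$D))
  invisible(x)
}

#' Average MSD curves from independent probes
#'
#' Pointwise unweighted mean of curves on identical lag grids. A warning flag
#' is set when the combined probe volume fraction exceeds 0.1, above which
#' probe-probe interactions start to bias viscoelastic measurements.
#'
#' @param curves list of `mr_msd` objects with identical grids and `d`.
#' @param volume_fraction total probe volume fraction (optional diagnostic).
#' @return averaged `mr_msd`.
#' @export
average_probes <- function(curves, volume_fraction = NULL) {
  stopifnot(length(curves) >= 1)
  t0 <- curves[[1]]$t; d0 <- curves[[1]]$d
  for (c in curves) {
    if (length(c$t) != length(t0) || max(abs(c$t - t0)) > 1e-12 * max(t0, 1) || c$d != d0)
      stop("mismatched lag grids (grid error)", call. = FALSE)
  }
  m <- rowMeans(vapply(curves, `[[`, numeric(length(t0)), "msd"))
  out <- curves[[1]]
  out$msd <- m
  out$n_probes <- sum(vapply(curves, `[[`, 0, "n_probes"))
  out$volume_fraction_warning <- FALSE
  if (!is.null(volume_fraction) && volume_fraction > 0.1) {
    out$volume_fraction_warning <- TRUE
    warning("probe volume fraction ", volume_fraction,
            " > 0.1: probe-probe interactions may bias the measurement",
            call. = FALSE)
  }
  out
}

#' Fit the ballistic and diffusive limits of an MSD curve
#'
#' `C` is the least-squares slope of MSD against t^2 in the ballistic window
#' (MSD = C t^2); `D` is the slope of MSD against t in the diffusive window
#' divided by `2 d` (MSD = 2 d D t).
#'
#' @param curve an `mr_msd`.
#' @param ballistic_window `c(tmin, tmax)` in ns.
#' @param diffusive_window `c(tmin, tmax)` in ns.
#' @return the curve with `C` (A^2/ns^2) and `D` (A^2/ns) filled in.
#' @export
fit_limits <- function(curve, ballistic_window, diffusive_window) {
  pick <- function(w) {
    i <- which(curve$t >= w[1] & curve$t <= w[2] & curve$t > 0)
    if (length(i) < 3) stop("fit window holds fewer than 3 positive lags (window error)", call. = FALSE)
    i
  }
  ib <- pick(ballistic_window)
  id <- pick(diffusive_window)
  C <- sum(curve$msd[ib] * curve$t[ib]^2) / sum(curve$t[ib]^4)
  slope <- coef(lm(curve$msd[id] ~ curve$t[id]))[2]
  curve$C <- unname(C)
  curve$D <- unname(slope) / (2 * curve$d)
  curve
}

#' Write an MSD curve as TSV with a JSON sidecar
#' @param curve an `mr_msd`.
#' @param path output TSV (`lag_ns`, `msd_A2`); metadata goes to `<path>.json`.
#' @export
write_msd <- function(curve, path) {
  write.table(data.frame(lag_ns = curve$t, msd_A2 = curve$msd), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(d = curve$d, n_probes = curve$n_probes,
               C = curve$C, D = curve$D)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
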