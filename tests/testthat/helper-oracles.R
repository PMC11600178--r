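# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms (direct double loops, quadrature, enumeration).

# time-origin-averaged MSD by the direct O(N^2) definition, one scalar series
oracle_msd_1d <- function(x) {
  n <- length(x)
  vapply(0:(n - 1), function(k) {
    if (k == 0) return(0)
    mean((x[(k + 1):n] - x[1:(n - k)])^2)
  }, 0)
}

# multi-axis trajectory MSD (matrix n_frames x n_axes)
oracle_msd <- function(xyz) {
  rowSums(vapply(seq_len(ncol(xyz)), function(a) oracle_msd_1d(xyz[, a]),
                 numeric(nrow(xyz))))
}

# damped one-sided Fourier transform of a BSW curve by chunked quadrature,
# Richardson-extrapolated to zero damping; the damping rate is a fraction of
# the inverse curve span so its perturbation stays uniformly small
oracle_bsw_fourier <- function(spec, w, eps_fracs = c(0.02, 0.01)) {
  tmax <- spec$tau[spec$n_max + 1]
  b <- 6 * spec$D
  one_eps <- function(eps) {
    s <- complex(real = eps, imaginary = w)
    brk <- sort(unique(c(0, spec$tau[spec$tau < tmax],
                         seq(0, tmax, by = pi / max(w, pi / tmax)), tmax)))
    acc <- 0 + 0i
    f <- function(t) eval_msd(spec, pmax(t, 1e-300))
    for (k in seq_len(length(brk) - 1)) {
      re <- integrate(function(t) f(t) * exp(-eps * t) * cos(w * t),
                      brk[k], brk[k + 1], rel.tol = 1e-11, abs.tol = 1e-13,
                      stop.on.error = FALSE)$value
      im <- -integrate(function(t) f(t) * exp(-eps * t) * sin(w * t),
                       brk[k], brk[k + 1], rel.tol = 1e-11, abs.tol = 1e-13,
                       stop.on.error = FALSE)$value
      acc <- acc + complex(real = re, imaginary = im)
    }
    # analytic damped tail of the linear asymptote b * t beyond tmax
    acc + b * exp(-s * tmax) * (tmax / s + 1 / s^2)
  }
  scale <- min(w, 1 / tmax)
  f1 <- one_eps(eps_fracs[1] * scale)
  f2 <- one_eps(eps_fracs[2] * scale)
  f2 + (f2 - f1)
}

# sequence charge decoration by the plain double loop
oracle_scd <- function(q) {
  N <- length(q)
  s <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N)
    s <- s + q[i] * q[j] * sqrt(j - i)
  s / N
}

# number of FCC lattice sites within radius R of the origin, by direct
# enumeration over cells and the 4-point basis
oracle_fcc_count <- function(R, a) {
  nmax <- ceiling(R / a) + 1
  basis <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0)) * a
  count <- 0
  for (i in -nmax:nmax) for (j in -nmax:nmax) for (k in -nmax:nmax)
    for (b in 1:4) {
      p <- c(i, j, k) * a + basis[b, ]
      if (sum(p^2) <= R^2 + 1e-9) count <- count + 1
    }
  count
}

# brute-force minimum-image pair-distance histogram counts
oracle_rdf_counts <- function(centers, residues, box, edges) {
  counts <- numeric(length(edges) - 1)
  for (c in seq_len(nrow(centers))) {
    for (r in seq_len(nrow(residues))) {
      d <- residues[r, ] - centers[c, ]
      d <- d - box * round(d / box)
      rr <- sqrt(sum(d^2))
      if (rr < max(edges)) {
        b <- findInterval(rr, edges, rightmost.closed = TRUE)
        if (b >= 1 && b <= length(counts)) counts[b] <- counts[b] + 1
      }
    }
  }
  counts
}

# the standard single-mode Maxwell fixture used by several tests
maxwell_fixture_model <- function(n_steps = 2e5, n_probes = 4, seed = 42) {
  R_h <- 10; G0 <- 0.01; tau_M <- 1
  gle_model(list(type = "maxwell", zeta0 = 6 * pi * R_h * G0, tau_M = tau_M,
                 zeta_n = 0.2),
            m = 1.7e5, T = 300, dt = 0.01, n_steps = n_steps, seed = seed,
            R_h_nominal = R_h, n_probes = n_probes)
}
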