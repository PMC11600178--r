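## probe_toolkit: rough-sphere probe construction and validity diagnostics.

## all pairs closer than cutoff via cell lists; returns matrix (i, j, dist)
.pairs_within <- function(pos, cutoff) {
  n <- nrow(pos)
  cell <- floor(sweep(pos, 2, apply(pos, 2, min)) / cutoff)
  key <- cell[, 1] * 73856093 + cell[, 2] * 19349663 + cell[, 3] * 83492791
  split_idx <- split(seq_len(n), key)
  cellmap <- new.env(hash = TRUE, parent = emptyenv())
  for (k in names(split_idx)) assign(k, split_idx[[k]], envir = cellmap)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(0); out_j <- integer(0); out_d <- numeric(0)
  for (k in names(split_idx)) {
    ii <- split_idx[[k]]
    c0 <- cell[ii[1], ]
    neigh <- integer(0)
    for (o in seq_len(nrow(offs))) {
      ck <- (c0[1] + offs[o, 1]) * 73856093 + (c0[2] + offs[o, 2]) * 19349663 +
        (c0[3] + offs[o, 3]) * 83492791
      kk <- as.character(ck)
      if (exists(kk, envir = cellmap, inherits = FALSE))
        neigh <- c(neigh, get(kk, envir = cellmap))
    }
    for (i in ii) {
      js <- neigh[neigh > i]
      if (length(js) == 0) next
      d2 <- (pos[js, 1] - pos[i, 1])^2 + (pos[js, 2] - pos[i, 2])^2 +
        (pos[js, 3] - pos[i, 3])^2
      sel <- d2 <= cutoff^2
      if (any(sel)) {
        out_i <- c(out_i, rep(i, sum(sel))); out_j <- c(out_j, js[sel])
        out_d <- c(out_d, sqrt(d2[sel]))
      }
    }
  }
  cbind(i = out_i, j = out_j, dist = out_d)
}

#' Build a rough spherical probe from an FCC lattice
#'
#' Carves all lattice sites within `R_b` of the origin out of a face-centered
#' cubic lattice with cubic cell edge `lattice_spacing` (the distance between
#' corner atoms; nearest corner-face neighbors then sit at
#' `lattice_spacing/sqrt(2)`, 1.5 A for the default 2.12 A spacing, i.e. just
#' touching for 1.5 A beads). Neighboring beads are connected by stiff
#' harmonic bonds so the carved cluster moves as one rough rigid sphere that
#' enforces no-slip at its surface.
#'
#' @param R_b carve radius (A).
#' @param lattice_spacing FCC cubic-cell edge (A), default 2.12.
#' @param bond_cut bond cutoff (A); default 1.05x the nearest-neighbor
#'   distance.
#' @param bead_mass per-bead mass (g/mol), default 100.
#' @param bead_sigma bead diameter (A), default 1.5.
#' @param bond_k bond spring constant (kcal/(mol A^2)), default 250.
#' @return object of class `mr_probe`: `positions` (n x 3), `bonds` (m x 2),
#'   `m_bare`, and the build parameters.
#' @export
build_probe <- function(R_b, lattice_spacing = 2.12, bond_cut = NULL,
                        bead_mass = 100, bead_sigma = 1.5, bond_k = 250) {
  stopifnot(R_b > 0, lattice_spacing > 0)
  a <- lattice_spacing
  nn <- a / sqrt(2)
  if (is.null(bond_cut)) bond_cut <- 1.05 * nn
  nmax <- ceiling(R_b / a) + 1
  base <- as.matrix(expand.grid(x = -nmax:nmax, y = -nmax:nmax, z = -nmax:nmax)) * a
  basis <- rbind(c(0, 0, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5), c(0.5, 0.5, 0)) * a
  pos <- do.call(rbind, lapply(seq_len(4), function(b) sweep(base, 2, basis[b, ], "+")))
  keep <- rowSums(pos^2) <= R_b^2 + 1e-9
  pos <- pos[keep, , drop = FALSE]
  if (nrow(pos) == 1)
    warning("carve radius below the first shell: single-bead probe", call. = FALSE)
  bonds <- if (nrow(pos) > 1) {
    p <- .pairs_within(pos, bond_cut)
    p[, 1:2, drop = FALSE]
  } else matrix(integer(0), ncol = 2)
  structure(list(positions = pos, bonds = bonds,
                 R_b = R_b, lattice_spacing = lattice_spacing,
                 bead_mass = bead_mass, bead_sigma = bead_sigma,
                 bond_k = bond_k, m_bare = bead_mass * nrow(pos)),
            class = "mr_probe")
}

#' @export
print.mr_probe <- function(x, ...) {
  cat(sprintf("<mr_probe> %d beads, R_b = %g A, m_bare = %g g/mol, %d bonds\n",
              nrow(x$positions), x$R_b, x$m_bare, nrow(x$bonds)))
  invisible(x)
}

#' Minimum interbead distance of a probe
#' @param probe an [build_probe()] result.
#' @return minimum pair distance (A); for the default FCC spacing 2.12 A this
#'   is `2.12/sqrt(2) = 1.499` A.
#' @export
min_interbead_distance <- function(probe) {
  pos <- probe$positions
  if (nrow(pos) < 2) return(NA_real_)
  p <- .pairs_within(pos, probe$lattice_spacing * 1.2)
  min(p[, "dist"])
}

#' Gyration radius and relative shape anisotropy
#'
#' `Rg` is the root of the gyration-tensor trace; the relative shape
#' anisotropy is `kappa^2 = 1 - 3 (l1 l2 + l2 l3 + l3 l1)/(l1+l2+l3)^2` from
#' the tensor eigenvalues (`kappa^2 = 0` for a sphere, 1 for a rod). For a
#' uniform sphere of radius R the expectation is `Rg = sqrt(3/5) R`.
#'
#' @param x an `mr_probe` or an `n x 3` matrix of bead positions.
#' @return list `Rg` (A), `kappa2`, `eigenvalues`.
#' @export
probe_geometry <- function(x) {
  pos <- if (inherits(x, "mr_probe")) x$positions else as.matrix(x)
  if (nrow(pos) < 4) warning("fewer than 4 beads: shape tensor may be degenerate", call. = FALSE)
  ctr <- sweep(pos, 2, colMeans(pos))
  S <- crossprod(ctr) / nrow(pos)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  tr <- sum(ev)
  if (tr <= 0) stop("degenerate bead set (tensor warning)", call. = FALSE)
  kappa2 <- 1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] + ev[3] * ev[1]) / tr^2
  list(Rg = sqrt(tr), kappa2 = max(kappa2, 0), eigenvalues = ev)
}

#' Radial distribution function between probe centers and residues
#'
#' Distance-histogram RDF with minimum-image convention in an orthorhombic
#' box, normalized by the spherical-shell volume and the mean residue density.
#'
#' @param traj an [trajectory()].
#' @param probe_center indices (columns) of center particles, or NULL to use
#'   the center of mass of all probe beads per probe id.
#' @param residues indices of residue particles (default: role == "residue").
#' @param r_max histogram range (A); must be below half the smallest box edge.
#' @param bin_width bin width (A).
#' @return list `r` (bin centers), `g`, `counts`.
#' @export
rdf_probe_residue <- function(traj, probe_center = NULL, residues = NULL,
                              r_max = NULL, bin_width = 0.2) {
  box <- traj$box
  if (is.null(box)) stop("RDF requires box dimensions", call. = FALSE)
  if (is.null(r_max)) r_max <- min(box) / 2
  if (r_max > min(box) / 2 + 1e-9)
    stop("r_max exceeds half the smallest box edge (range error)", call. = FALSE)
  if (is.null(residues)) residues <- which(traj$roles == "residue")
  if (length(residues) == 0) stop("no residue particles selected", call. = FALSE)
  n_frames <- length(traj$times)
  edges <- seq(0, r_max, by = bin_width)
  if (max(edges) < r_max) edges <- c(edges, max(edges) + bin_width)
  counts <- numeric(length(edges) - 1)
  centers_per_frame <- function(f) {
    if (!is.null(probe_center))
      return(matrix(traj$positions[f, probe_center, , drop = FALSE],
                    ncol = 3))
    grp <- traj$probe_ids
    ids <- sort(unique(grp[!is.na(grp) & traj$roles != "residue"]))
    t(vapply(ids, function(p) {
      cols <- which(grp == p & traj$roles != "residue")
      colMeans(matrix(traj$positions[f, cols, , drop = FALSE], ncol = 3))
    }, numeric(3)))
  }
  n_centers <- NULL
  for (f in seq_len(n_frames)) {
    ctr <- centers_per_frame(f)
    n_centers <- nrow(ctr)
    res <- matrix(traj$positions[f, residues, , drop = FALSE], ncol = 3)
    for (c in seq_len(nrow(ctr))) {
      d <- sweep(res, 2, ctr[c, ])
      for (ax in 1:3) {
        if (traj$periodic[ax]) d[, ax] <- d[, ax] - box[ax] * round(d[, ax] / box[ax])
      }
      r <- sqrt(rowSums(d^2))
      h <- hist(r[r < max(edges)], breaks = edges, plot = FALSE)$counts
      counts <- counts + h
    }
  }
  rho <- length(residues) / prod(box)
  rc <- (head(edges, -1) + tail(edges, -1)) / 2
  shell <- 4 / 3 * pi * (tail(edges, -1)^3 - head(edges, -1)^3)
  g <- counts / (n_frames * n_centers * rho * shell)
  list(r = rc, g = g, counts = counts)
}

#' Hydrodynamic radius from the first RDF peak
#'
#' The probe's hydrodynamic radius is the location of the first local maximum
#' of the probe-residue RDF exceeding 1, refined by quadratic interpolation
#' through the peak bin and its two neighbors.
#'
#' @param rdf list with `r` and `g` (from [rdf_probe_residue()]).
#' @return R_h (A).
#' @export
hydrodynamic_radius <- function(rdf) {
  g <- rdf$g; r <- rdf$r
  n <- length(g)
  pk <- which(g > 1 & c(-Inf, g[-n]) <= g & g >= c(g[-1], -Inf))
  pk <- pk[pk > 1 & pk < n]
  if (length(pk) == 0) stop("no RDF peak above 1 (no-structure error)", call. = FALSE)
  i <- pk[1]
  # quadratic through (r[i-1], g[i-1]), (r[i], g[i]), (r[i+1], g[i+1])
  num <- (g[i - 1] - g[i + 1])
  den <- (g[i - 1] - 2 * g[i] + g[i + 1])
  if (den >= 0) return(r[i])
  r[i] + 0.5 * (r[i] - r[i - 1]) * num / den
}

#' Radial velocity profile around a translating probe
#'
#' Bins the x-velocity of residues by distance from the probe center; the
#' no-slip diagnostic is `v_x(first bin)/v_x_probe` (1 for perfect no-slip,
#' 0 for full slip). Velocities are taken from the trajectory if stored,
#' otherwise by central finite differences of positions.
#'
#' @param traj an [trajectory()] (unwrapped, probe translating along x).
#' @param probe_center column indices of the probe-center particle(s).
#' @param v_x_probe imposed probe velocity (A/ns).
#' @param bins radial bin edges (A).
#' @return list `r` (bin centers), `v_x`, `n` (samples/bin), `no_slip`
#'   (first-bin diagnostic), with empty bins NA and flagged.
#' @export
velocity_profile <- function(traj, probe_center, v_x_probe, bins) {
  n_frames <- length(traj$times)
  res <- which(traj$roles == "residue")
  if (length(res) == 0) stop("no residue particles", call. = FALSE)
  dt <- traj$times[2] - traj$times[1]
  vel <- traj$velocities
  vsum <- numeric(length(bins) - 1); vn <- numeric(length(bins) - 1)
  frames <- if (is.null(vel)) 2:(n_frames - 1) else seq_len(n_frames)
  for (f in frames) {
    ctr <- colMeans(matrix(traj$positions[f, probe_center, , drop = FALSE], ncol = 3))
    rp <- matrix(traj$positions[f, res, , drop = FALSE], ncol = 3)
    d <- sqrt(rowSums(sweep(rp, 2, ctr)^2))
    vx <- if (is.null(vel)) {
      (traj$positions[f + 1, res, 1] - traj$positions[f - 1, res, 1]) / (2 * dt)
    } else vel[f, res, 1]
    bi <- findInterval(d, bins, rightmost.closed = TRUE)
    ok <- bi >= 1 & bi <= length(vsum)
    for (b in unique(bi[ok])) {
      sel <- ok & bi == b
      vsum[b] <- vsum[b] + sum(vx[sel]); vn[b] <- vn[b] + sum(sel)
    }
  }
  v <- ifelse(vn > 0, vsum / pmax(vn, 1), NA_real_)
  if (any(vn == 0)) warning(sum(vn == 0), " empty radial bins masked", call. = FALSE)
  first <- which(vn > 0)[1]
  list(r = (head(bins, -1) + tail(bins, -1)) / 2, v_x = v, n = vn,
       no_slip = v[first] / v_x_probe)
}

#' Export a probe structure
#'
#' Writes the bead coordinates and bond list as a LAMMPS data file, or the
#' coordinates alone as XYZ.
#'
#' @param probe an `mr_probe`.
#' @param path output file.
#' @param format `"lammps_data"` or `"xyz"`.
#' @param box box edge lengths for the data file (default: tight cube).
#' @export
write_probe <- function(probe, path, format = c("lammps_data", "xyz"),
                        box = NULL) {
  format <- match.arg(format)
  pos <- probe$positions
  con <- file(path, "w"); on.exit(close(con))
  if (format == "xyz") {
    writeLines(c(sprintf("%d", nrow(pos)), "probe"), con)
    writeLines(sprintf("B %.6f %.6f %.6f", pos[, 1], pos[, 2], pos[, 3]), con)
  } else {
    if (is.null(box)) box <- rep(2 * probe$R_b + 4, 3)
    writeLines(c("LAMMPS data file: rough-sphere probe", "",
                 sprintf("%d atoms", nrow(pos)),
                 sprintf("%d bonds", nrow(probe$bonds)),
                 "1 atom types", "1 bond types", "",
                 sprintf("%.6f %.6f xlo xhi", -box[1] / 2, box[1] / 2),
                 sprintf("%.6f %.6f ylo yhi", -box[2] / 2, box[2] / 2),
                 sprintf("%.6f %.6f zlo zhi", -box[3] / 2, box[3] / 2), "",
                 "Masses", "", sprintf("1 %.4f", probe$bead_mass), "",
                 "Atoms", ""), con)
    writeLines(sprintf("%d 1 1 0.0 %.6f %.6f %.6f",
                       seq_len(nrow(pos)), pos[, 1], pos[, 2], pos[, 3]), con)
    if (nrow(probe$bonds) > 0) {
      writeLines(c("", "Bonds", ""), con)
      writeLines(sprintf("%d 1 %d %d", seq_len(nrow(probe$bonds)),
                         probe$bonds[, 1], probe$bonds[, 2]), con)
    }
  }
  invisible(path)
}
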