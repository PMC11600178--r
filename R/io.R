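## core_io: trajectory / stress-series containers and text-format readers.

.check_uniform_times <- function(times, rtol = 1e-6) {
  if (length(times) < 2) return(invisible(TRUE))
  dt <- diff(times)
  if (any(dt <= 0)) stop("trajectory times must be strictly increasing", call. = FALSE)
  if ((max(dt) - min(dt)) > rtol * mean(dt))
    stop("non-uniform frame spacing beyond tolerance (timing error)", call. = FALSE)
  invisible(TRUE)
}

#' Construct a particle trajectory
#'
#' Positions are stored as an `n_frames x n_particles x 3` array in Angstrom on
#' a uniform time grid in ns. Each particle carries a role (`probe_bead`,
#' `probe_center`, or `residue`) and, for probe beads/centers, an integer probe
#' group id. Boxes are orthorhombic only.
#'
#' @param times frame times in ns (strictly increasing, uniform).
#' @param positions numeric array `n_frames x n_particles x 3` (A).
#' @param box orthorhombic edge lengths, length 3 (A), or NULL if unknown.
#' @param roles character vector per particle.
#' @param probe_ids integer per particle (NA for residues).
#' @param periodic logical per axis.
#' @param velocities optional array like `positions`, in A/ns.
#' @return object of class `mr_trajectory`.
#' @export
trajectory <- function(times, positions, box = NULL,
                       roles = NULL, probe_ids = NULL,
                       periodic = c(TRUE, TRUE, TRUE), velocities = NULL) {
  stopifnot(length(dim(positions)) == 3, dim(positions)[3] == 3)
  n_frames <- dim(positions)[1]
  n_part <- dim(positions)[2]
  stopifnot(length(times) == n_frames)
  .check_uniform_times(times)
  if (!all(is.finite(positions))) stop("positions must be finite", call. = FALSE)
  if (is.null(roles)) roles <- rep("probe_bead", n_part)
  roles <- match.arg(roles, c("probe_bead", "probe_center", "residue"),
                     several.ok = TRUE)
  if (length(roles) == 1) roles <- rep(roles, n_part)
  stopifnot(length(roles) == n_part)
  if (is.null(probe_ids)) {
    probe_ids <- ifelse(roles == "residue", NA_integer_, seq_len(n_part))
  }
  if (!is.null(box)) {
    stopifnot(length(box) == 3, all(box > 0))
  }
  structure(list(times = as.numeric(times), positions = positions,
                 box = box, roles = roles,
                 probe_ids = as.integer(probe_ids),
                 periodic = as.logical(periodic),
                 velocities = velocities),
            class = "mr_trajectory")
}

#' @export
print.mr_trajectory <- function(x, ...) {
  cat(sprintf("<mr_trajectory> %d frames, %d particles, dt = %g ns\n",
              length(x$times), dim(x$positions)[2],
              if (length(x$times) > 1) x$times[2] - x$times[1] else NA))
  cat(sprintf("  roles: %s\n",
              paste(sprintf("%s(%d)", names(table(x$roles)), table(x$roles)),
                    collapse = ", ")))
  if (!is.null(x$box)) cat(sprintf("  box: %s A\n", paste(signif(x$box, 6), collapse = " x ")))
  invisible(x)
}

#' Read a trajectory from disk
#'
#' Supported text formats:
#' \describe{
#' \item{`csv`}{header `time,id,x,y,z` (comma or tab separated); one row per
#'   particle per frame.}
#' \item{`xyz`}{plain XYZ; frame times are `frame * dt`; the element symbol
#'   column is mapped to roles through `role_map`.}
#' \item{`lammps_dump`}{LAMMPS text dump with `ITEM:` headers; `ITEM: BOX
#'   BOUNDS` lines are parsed into orthorhombic edge lengths and `ITEM: ATOMS`
#'   must contain `id type x y z` (or `xu yu zu`); times are
#'   `TIMESTEP * timestep_ns`.}
#' }
#' GSD is a binary format without an R reader and is not supported.
#'
#' @param path file path.
#' @param format one of `"csv"`, `"xyz"`, `"lammps_dump"`, `"gsd"`.
#' @param role_map named character vector mapping particle type / element to a
#'   role, e.g. `c("1" = "probe_bead", "2" = "residue")`. Unmapped types become
#'   `"residue"`.
#' @param dt frame spacing in ns (xyz).
#' @param timestep_ns ns per LAMMPS timestep unit (lammps_dump).
#' @param box box edge lengths if the format does not store them.
#' @return an [trajectory()] object.
#' @export
read_trajectory <- function(path, format = c("csv", "xyz", "lammps_dump", "gsd"),
                            role_map = NULL, dt = 1, timestep_ns = 1,
                            box = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
    csv = .read_traj_csv(path, role_map, box),
    xyz = .read_traj_xyz(path, role_map, dt, box),
    lammps_dump = .read_traj_lammps(path, role_map, timestep_ns),
    gsd = stop("GSD is a binary format with no reader available here; ",
               "convert to a LAMMPS text dump, XYZ, or CSV first (format error)",
               call. = FALSE)
  )
}

.roles_from_map <- function(types, role_map) {
  if (is.null(role_map)) return(rep("residue", length(types)))
  r <- unname(role_map[as.character(types)])
  r[is.na(r)] <- "residue"
  r
}

.read_traj_csv <- function(path, role_map, box) {
  d <- read.table(path, header = TRUE, sep = ",", strip.white = TRUE)
  if (ncol(d) == 1) d <- read.table(path, header = TRUE, sep = "\t")
  need <- c("time", "id", "x", "y", "z")
  if (!all(need %in% names(d)))
    stop("csv trajectory needs header time,id,x,y,z (format error)", call. = FALSE)
  times <- sort(unique(d$time))
  ids <- sort(unique(d$id))
  pos <- array(NA_real_, c(length(times), length(ids), 3))
  fi <- match(d$time, times); pi <- match(d$id, ids)
  idx <- cbind(fi, pi)
  pos[cbind(idx, 1)] <- d$x; pos[cbind(idx, 2)] <- d$y; pos[cbind(idx, 3)] <- d$z
  if (anyNA(pos)) stop("incomplete frames in csv trajectory", call. = FALSE)
  roles <- if ("role" %in% names(d)) {
    vapply(ids, function(i) as.character(d$role[d$id == i][1]), "")
  } else if (is.null(role_map)) rep("probe_bead", length(ids))
  else .roles_from_map(ids, role_map)
  trajectory(times, pos, box = box, roles = roles)
}

.read_traj_xyz <- function(path, role_map, dt, box) {
  lines <- readLines(path)
  frames <- list(); elems <- NULL; i <- 1; f <- 0
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ atom-count line (format error)", call. = FALSE)
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    el <- vapply(parts, `[[`, "", 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    f <- f + 1
    frames[[f]] <- xyz
    if (is.null(elems)) elems <- el
    i <- i + 2 + n
  }
  pos <- array(0, c(length(frames), length(elems), 3))
  for (k in seq_along(frames)) pos[k, , ] <- frames[[k]]
  trajectory((seq_along(frames) - 1) * dt, pos, box = box,
             roles = .roles_from_map(elems, role_map))
}

.read_traj_lammps <- function(path, role_map, timestep_ns) {
  lines <- readLines(path)
  i <- 1; steps <- c(); frames <- list(); types <- NULL; box <- NULL
  while (i <= length(lines)) {
    if (startsWith(lines[i], "ITEM: TIMESTEP")) {
      steps <- c(steps, as.numeric(lines[i + 1])); i <- i + 2
    } else if (startsWith(lines[i], "ITEM: NUMBER OF ATOMS")) {
      n <- as.integer(lines[i + 1]); i <- i + 2
    } else if (startsWith(lines[i], "ITEM: BOX BOUNDS")) {
      if (grepl("xy xz yz", lines[i]))
        stop("triclinic boxes are not supported (box error)", call. = FALSE)
      b <- t(vapply(strsplit(trimws(lines[i + (1:3)]), "\\s+"),
                    function(p) as.numeric(p[1:2]), numeric(2)))
      box <- b[, 2] - b[, 1]
      i <- i + 4
    } else if (startsWith(lines[i], "ITEM: ATOMS")) {
      cols <- strsplit(sub("ITEM: ATOMS\\s*", "", lines[i]), "\\s+")[[1]]
      xc <- match(c("x", "y", "z"), cols)
      if (anyNA(xc)) xc <- match(c("xu", "yu", "zu"), cols)
      idc <- match("id", cols); tyc <- match("type", cols)
      if (anyNA(c(xc, idc)))
        stop("LAMMPS dump must provide id and x y z (or xu yu zu) columns",
             call. = FALSE)
      block <- do.call(rbind, lapply(strsplit(trimws(lines[i + (1:n)]), "\\s+"),
                                     as.numeric))
      ord <- order(block[, idc])
      block <- block[ord, , drop = FALSE]
      frames[[length(frames) + 1]] <- block[, xc, drop = FALSE]
      if (is.null(types) && !is.na(tyc)) types <- block[, tyc]
      i <- i + 1 + n
    } else i <- i + 1
  }
  if (is.null(box)) stop("LAMMPS dump without ITEM: BOX BOUNDS (box error)", call. = FALSE)
  pos <- array(0, c(length(frames), nrow(frames[[1]]), 3))
  for (k in seq_along(frames)) pos[k, , ] <- frames[[k]]
  trajectory(steps * timestep_ns, pos, box = box,
             roles = .roles_from_map(if (is.null(types)) seq_len(dim(pos)[2]) else types,
                                     role_map))
}

#' Write a trajectory as CSV (lossless round trip) or XYZ
#'
#' The CSV dialect writes coordinates with 17 significant digits so that a
#' write/read cycle reproduces positions bit-exactly.
#'
#' @param traj an [trajectory()] object.
#' @param path output file.
#' @param format `"csv"` or `"xyz"`.
#' @export
write_trajectory <- function(traj, path, format = c("csv", "xyz")) {
  format <- match.arg(format)
  n_frames <- length(traj$times); n_part <- dim(traj$positions)[2]
  con <- file(path, "w"); on.exit(close(con))
  if (format == "csv") {
    writeLines("time,id,x,y,z,role", con)
    for (f in seq_len(n_frames)) {
      p <- traj$positions[f, , , drop = FALSE]
      writeLines(sprintf("%.17g,%d,%.17g,%.17g,%.17g,%s",
                         traj$times[f], seq_len(n_part),
                         p[1, , 1], p[1, , 2], p[1, , 3], traj$roles), con)
    }
  } else {
    for (f in seq_len(n_frames)) {
      writeLines(c(sprintf("%d", n_part), sprintf("frame %d t= %.17g", f, traj$times[f])), con)
      p <- traj$positions[f, , , drop = FALSE]
      writeLines(sprintf("%s %.10f %.10f %.10f", traj$roles,
                         p[1, , 1], p[1, , 2], p[1, , 3]), con)
    }
  }
  invisible(path)
}

#' Unwrap periodic-boundary coordinates
#'
#' Makes each particle's path continuous by removing minimum-image jumps.
#' Correct whenever true frame-to-frame displacements are below half a box
#' edge; jumps at exactly half a box edge are ambiguous and raise an error.
#' Already-continuous input is returned unchanged.
#'
#' @param traj an [trajectory()] with `box` set.
#' @return unwrapped trajectory.
#' @export
unwrap <- function(traj) {
  if (is.null(traj$box)) stop("unwrap requires box dimensions (box error)", call. = FALSE)
  pos <- traj$positions
  for (ax in 1:3) {
    if (!traj$periodic[ax]) next
    L <- traj$box[ax]
    x <- pos[, , ax, drop = FALSE]
    dim(x) <- dim(pos)[1:2]
    if (nrow(x) < 2) next
    dx <- x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE]
    shift <- round(dx / L)
    dxc <- dx - shift * L
    if (any(abs(abs(dxc) - L / 2) < 1e-9 * L & shift != 0))
      stop("displacement at exactly half a box edge: unwrap ambiguous ",
           "(undersampled trajectory)", call. = FALSE)
    xu <- apply(rbind(x[1, ], dxc), 2, cumsum)
    if (is.null(dim(xu))) xu <- matrix(xu, ncol = ncol(x))
    pos[, , ax] <- xu
  }
  out <- traj
  out$positions <- pos
  out
}

#' Wrap coordinates into the primary periodic box
#'
#' @param traj an [trajectory()] with `box` set.
#' @return trajectory with coordinates folded into `[0, box)` on periodic axes.
#' @export
wrap <- function(traj) {
  if (is.null(traj$box)) stop("wrap requires box dimensions", call. = FALSE)
  pos <- traj$positions
  for (ax in 1:3) {
    if (!traj$periodic[ax]) next
    L <- traj$box[ax]
    pos[, , ax] <- pos[, , ax] - floor(pos[, , ax] / L) * L
  }
  out <- traj
  out$positions <- pos
  out
}

#' Construct a pressure-tensor time series
#'
#' @param times ns, uniform grid.
#' @param components data frame / matrix with columns `Pxx,Pyy,Pzz,Pxy,Pxz,Pyz`.
#' @param volume box volume in A^3.
#' @param temperature K.
#' @param units `"atm"` (converted internally) or `"kcal_molA3"`.
#' @return object of class `mr_stress`.
#' @export
stress_series <- function(times, components, volume, temperature,
                          units = c("atm", "kcal_molA3")) {
  units <- match.arg(units)
  comp <- as.data.frame(components)
  need <- c("Pxx", "Pyy", "Pzz", "Pxy", "Pxz", "Pyz")
  if (!all(need %in% names(comp)))
    stop("stress series needs all six components ", paste(need, collapse = ","),
         " (input error)", call. = FALSE)
  comp <- comp[need]
  .check_uniform_times(times)
  if (units == "atm") comp[] <- lapply(comp, function(x) x * .const$atm)
  structure(list(times = as.numeric(times), components = comp,
                 volume = volume, temperature = temperature),
            class = "mr_stress")
}

#' Read a stress series from TSV
#'
#' Expects a header `time,Pxx,Pyy,Pzz,Pxy,Pxz,Pyz` (tab or comma separated).
#'
#' @inheritParams stress_series
#' @param path file path.
#' @export
read_stress <- function(path, volume, temperature, units = c("atm", "kcal_molA3")) {
  d <- read.table(path, header = TRUE, sep = "\t")
  if (ncol(d) == 1) d <- read.table(path, header = TRUE, sep = ",")
  stress_series(d$time, d[, -1], volume, temperature, units = match.arg(units))
}

#' Write a stress series as TSV
#' @param stress an [stress_series()] object (components written in kcal/(mol A^3)).
#' @param path output file.
#' @export
write_stress <- function(stress, path) {
  d <- cbind(time = stress$times, stress$components)
  write.table(format(d, digits = 17, trim = TRUE), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read amino-acid sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of one-letter sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("not a FASTA file: ", path, call. = FALSE)
  idx <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) toupper(gsub("[^A-Za-z]", "", paste(x, collapse = ""))), "")
  names(seqs) <- sub("^>\\s*", "", lines[hdr])
  seqs
}
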