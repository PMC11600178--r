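## hps_medium: residue-level hydropathy-scale (HPS) force-field terms,
## sequence charge patterning (nSCD), and probe-design criteria.

#' HPS force-field parameters
#'
#' Residue-level coarse-grained model: one bead per residue, harmonic bonds,
#' hydropathy-scaled (Ashbaugh-Hatch) van der Waals interactions and
#' Debye-Hueckel screened electrostatics. Per-residue hydropathies come from
#' either the Kapcha-Rossky-derived scale (`"kr"`, used for charge-rich model
#' sequences) or the Urry-derived scale (`"urry"`, used for natural sequences
#' such as A1-LCD variants).
#'
#' @param scale hydropathy scale, `"kr"` or `"urry"`.
#' @param eps_HPS vdW interaction strength (kcal/mol), default 0.2.
#' @param k_b bond spring constant (kcal/(mol A^2)), default 20.
#' @param r0 equilibrium bond length (A), default 3.8.
#' @param eps_r relative permittivity, default 80.
#' @param debye_l Debye screening length (A), default 10.
#' @param elec_cutoff electrostatic cutoff (A), default 35.
#' @param vdw_cutoff_sigma vdW cutoff in units of sigma, default 4.
#' @param his_charge histidine charge, default 0.
#' @return object of class `mr_hps` including the residue table (`$residues`
#'   with `mass`, `sigma`, `charge`, `lambda`).
#' @export
hps_params <- function(scale = c("kr", "urry"), eps_HPS = 0.2, k_b = 20,
                       r0 = 3.8, eps_r = 80, debye_l = 10, elec_cutoff = 35,
                       vdw_cutoff_sigma = 4, his_charge = 0) {
  scale <- match.arg(scale)
  path <- system.file("extdata", "hps_residues.tsv", package = "microrheo")
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  tab$lambda <- if (scale == "kr") tab$lambda_kr else tab$lambda_urry
  tab$charge[tab$aa == "H"] <- his_charge
  rownames(tab) <- tab$aa
  structure(list(scale = scale, eps_HPS = eps_HPS, k_b = k_b, r0 = r0,
                 eps_r = eps_r, debye_l = debye_l, elec_cutoff = elec_cutoff,
                 vdw_cutoff_sigma = vdw_cutoff_sigma, residues = tab),
            class = "mr_hps")
}

#' Harmonic bond energy
#'
#' `U = 1/2 k_b (r - r0)^2`, the half-factor convention of the simulation
#' engines this model is run in.
#'
#' @param r distance (A).
#' @param params an [hps_params()].
#' @return energy in kcal/mol.
#' @export
bond_energy <- function(r, params = hps_params()) {
  stopifnot(all(r > 0))
  0.5 * params$k_b * (r - params$r0)^2
}

#' Hydropathy-scaled van der Waals pair energy (Ashbaugh-Hatch form)
#'
#' With `lambda = (lambda_i + lambda_j)/2` and `sigma = (sigma_i + sigma_j)/2`:
#' `U = U_LJ + (1 - lambda) eps` for `r <= 2^(1/6) sigma`, `U = lambda U_LJ`
#' beyond, and plain truncation to zero at `4 sigma` (the discontinuity at the
#' cutoff is intentional, matching the model definition).
#'
#' @param r distance(s) (A).
#' @param lambda_i,lambda_j per-residue hydropathies (a probe bead may use
#'   values outside [0, 1] to tune the interaction strength).
#' @param sigma_i,sigma_j per-residue diameters (A).
#' @param eps interaction strength (kcal/mol).
#' @return energy in kcal/mol.
#' @export
vdw_energy <- function(r, lambda_i, lambda_j, sigma_i, sigma_j, eps = 0.2) {
  stopifnot(all(r > 0))
  lambda <- (lambda_i + lambda_j) / 2
  sigma <- (sigma_i + sigma_j) / 2
  sr6 <- (sigma / r)^6
  ulj <- 4 * eps * (sr6^2 - sr6)
  rmin <- 2^(1 / 6) * sigma
  u <- ifelse(r <= rmin, ulj + (1 - lambda) * eps, lambda * ulj)
  u[r > 4 * sigma] <- 0
  u
}

#' Debye-Hueckel screened Coulomb pair energy
#'
#' `U = q_i q_j e^2/(4 pi eps0 eps_r r) exp(-r/l)`, truncated to zero at the
#' electrostatic cutoff.
#'
#' @param r distance(s) (A).
#' @param q_i,q_j charges in elementary units.
#' @param params an [hps_params()].
#' @return energy in kcal/mol.
#' @export
coulomb_energy <- function(r, q_i, q_j, params = hps_params()) {
  stopifnot(all(r > 0))
  u <- q_i * q_j * .const$e2_coul / (params$eps_r * r) * exp(-r / params$debye_l)
  u[r > params$elec_cutoff] <- 0
  u
}

#' Sequence record with charges
#'
#' @param seq one-letter amino-acid string.
#' @param params an [hps_params()] supplying the charge assignment
#'   (E/D: -1, K/R: +1, H configurable).
#' @return list with `residues`, `charges`, `N`.
#' @export
sequence_record <- function(seq, params = hps_params()) {
  res <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(res, rownames(params$residues))
  if (length(bad) > 0) stop("unknown residues: ", paste(bad, collapse = ","), call. = FALSE)
  list(residues = res, charges = params$residues[res, "charge"], N = length(res))
}

#' Sequence charge decoration (SCD)
#'
#' `SCD = (1/N) sum_{i<j} q_i q_j sqrt(j - i)`; more negative values indicate
#' stronger segregation of opposite charges.
#'
#' @param charges per-residue charge vector.
#' @return SCD (dimensionless).
#' @export
scd <- function(charges) {
  N <- length(charges)
  idx <- which(charges != 0)
  if (length(idx) < 2) stop("need at least 2 charged residues (undefined error)", call. = FALSE)
  s <- 0
  for (a in seq_len(length(idx) - 1)) {
    i <- idx[a]; rest <- idx[(a + 1):length(idx)]
    s <- s + sum(charges[i] * charges[rest] * sqrt(rest - i))
  }
  s / N
}

## extremal arrangements of a charge composition over the same length; the
## constructions start with the majority sign so that globally flipping all
## charges maps them onto themselves (SCD is flip- and reversal-invariant)
.charges_alternating <- function(charges) {
  qp <- sort(abs(charges[charges > 0]), decreasing = TRUE)
  qn <- -sort(abs(charges[charges < 0]), decreasing = TRUE)
  if (length(qn) > length(qp)) { tmp <- qp; qp <- qn; qn <- tmp }
  out <- numeric(0)
  while (length(qp) > 0 || length(qn) > 0) {
    if (length(qp) > 0) { out <- c(out, qp[1]); qp <- qp[-1] }
    if (length(qn) > 0) { out <- c(out, qn[1]); qn <- qn[-1] }
  }
  c(out, rep(0, sum(charges == 0)))
}
.charges_diblock <- function(charges) {
  qp <- sort(abs(charges[charges > 0]), decreasing = TRUE)
  qn <- -sort(abs(charges[charges < 0]), decreasing = TRUE)
  if (length(qn) > length(qp)) { tmp <- qp; qp <- qn; qn <- tmp }
  c(qp, rep(0, sum(charges == 0)), qn)
}

#' Normalized sequence charge decoration (nSCD)
#'
#' Normalizes SCD between the perfectly alternating arrangement (nSCD = 0)
#' and the diblock arrangement (nSCD = 1) of the same charge composition, so
#' that nSCD is a [0,1] measure of charge segregation. The alternating and
#' diblock constructs are the exact extremal arrangements for charge-balanced
#' compositions (equal numbers of positive and negative residues, as in E-K
#' polyampholytes); for strongly unbalanced compositions the normalization is
#' approximate and values may fall slightly outside [0, 1].
#'
#' @param seq one-letter sequence string, or a numeric charge vector.
#' @param params an [hps_params()] (charge assignment) when `seq` is a string.
#' @return nSCD (dimensionless, in [0, 1] for realizable sequences).
#' @export
nscd <- function(seq, params = hps_params()) {
  charges <- if (is.character(seq)) sequence_record(seq, params)$charges else seq
  s <- scd(charges)
  s_alt <- scd(.charges_alternating(charges))
  s_di <- scd(.charges_diblock(charges))
  if (abs(s_di - s_alt) < 1e-14)
    stop("degenerate composition: extremal arrangements coincide", call. = FALSE)
  (s - s_alt) / (s_di - s_alt)
}

#' Correlation length of the dense phase from the overlap concentration
#'
#' Semidilute scaling `xi = Re (rho/rho*)^(nu/(1 - 3 nu))` with the overlap
#' concentration `rho* = 3 Mw/(4 pi Re^3)` (per-mole units: g/(mol A^3)).
#' With the ideal-chain exponent `nu = 1/2` this reduces to
#' `xi = Re rho*/rho`.
#'
#' @param rho dense-phase mass concentration (g/(mol A^3)).
#' @param Re chain end-to-end distance (A).
#' @param Mw chain molecular weight (g/mol).
#' @param nu Flory scaling exponent (default 1/2; `nu = 1/3` is singular).
#' @return list with `xi` (A), `rho_star`, `Re`, `Mw`, `nu`.
#' @export
correlation_length <- function(rho, Re, Mw, nu = 0.5) {
  stopifnot(rho > 0, Re > 0, Mw > 0)
  if (abs(nu - 1 / 3) < 1e-9)
    stop("nu = 1/3 is a singular exponent for the semidilute scaling", call. = FALSE)
  rho_star <- 3 * Mw / (4 * pi * Re^3)
  xi <- Re * (rho / rho_star)^(nu / (1 - 3 * nu))
  list(xi = xi, rho_star = rho_star, Re = Re, Mw = Mw, nu = nu)
}

#' Probe-size criterion for continuum validity
#'
#' A probe must be larger than the condensate mesh: `R_h/xi >= 1.5` is
#' required (boundary inclusive); the recommended band is `R_h` between
#' `1.5 xi` and `2 xi` (larger probes sample the condensate too slowly).
#'
#' @param R_h hydrodynamic radius (A).
#' @param xi correlation length (A).
#' @return list `status` (`"ok"` or `"too_small"`), `ratio`, `note`.
#' @export
probe_size_criterion <- function(R_h, xi) {
  stopifnot(R_h > 0, xi > 0)
  ratio <- R_h / xi
  if (ratio < 1.5)
    return(list(status = "too_small", ratio = ratio,
                note = "probe smaller than 1.5 correlation lengths"))
  note <- if (ratio <= 2) "within recommended band [1.5 xi, 2 xi]"
          else "above recommended band (sampling may be slow)"
  list(status = "ok", ratio = ratio, note = note)
}

#' Probe-protein interaction-strength window
#'
#' Classifies `eps/eps_HPS`: below 0.75 the no-slip condition fails
#' (`below_no_slip`); the window [1, 1.5] yields macroscopic viscosity
#' (`optimal`); at and beyond 1.75 chains adsorb onto the probe
#' (`adsorption_risk`). Ratios in the gaps are assigned to the nearest band
#' with a warning flag.
#'
#' @param eps_ratio `eps/eps_HPS` >= 0.
#' @return list `status`, `eps_ratio`, `in_gap`.
#' @export
interaction_window_check <- function(eps_ratio) {
  stopifnot(eps_ratio >= 0)
  if (eps_ratio < 0.75) return(list(status = "below_no_slip", eps_ratio = eps_ratio, in_gap = FALSE))
  if (eps_ratio >= 1 && eps_ratio <= 1.5) return(list(status = "optimal", eps_ratio = eps_ratio, in_gap = FALSE))
  if (eps_ratio >= 1.75) return(list(status = "adsorption_risk", eps_ratio = eps_ratio, in_gap = FALSE))
  if (eps_ratio < 1) {
    st <- if (eps_ratio < 0.875) "below_no_slip" else "optimal"
  } else {
    st <- if (eps_ratio < 1.625) "optimal" else "adsorption_risk"
  }
  warning("eps/eps_HPS = ", eps_ratio, " falls between labeled bands; ",
          "classified to nearest (", st, ")", call. = FALSE)
  list(status = st, eps_ratio = eps_ratio, in_gap = TRUE)
}

#' Pair-energy profile between two residues
#'
#' @param aa_i,aa_j one-letter residue codes.
#' @param r distances (A).
#' @param params an [hps_params()].
#' @return data frame `r, U_vdw, U_elec, U_total` (kcal/mol).
#' @export
pair_energy <- function(aa_i, aa_j, r, params = hps_params()) {
  ri <- params$residues[aa_i, ]; rj <- params$residues[aa_j, ]
  uv <- vdw_energy(r, ri$lambda, rj$lambda, ri$sigma, rj$sigma, params$eps_HPS)
  ue <- coulomb_energy(r, ri$charge, rj$charge, params)
  data.frame(r = r, U_vdw = uv, U_elec = ue, U_total = uv + ue)
}
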