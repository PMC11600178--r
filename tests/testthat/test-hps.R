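p_kr <- hps_params("kr")

test_that("harmonic bonds are zero and symmetric about the rest length", {
  expect_equal(bond_energy(3.8, p_kr), 0)
  expect_equal(bond_energy(3.8 + 0.7, p_kr), bond_energy(3.8 - 0.7, p_kr))
  # half-factor convention with k_b = 20 kcal/(mol A^2): U(r0 + 1) = 10
  expect_equal(bond_energy(4.8, p_kr), 0.5 * 20 * 1^2)
})

test_that("hydropathy-scaled vdW has the stated minimum, repulsive limit,
           branch continuity and cutoff", {
  sig <- 5.8; rmin <- 2^(1 / 6) * sig
  # lambda = 1 at the LJ minimum: U = -eps
  expect_equal(vdw_energy(rmin, 1, 1, sig, sig, eps = 0.2), -0.2,
               tolerance = 1e-12)
  # lambda = 0: purely repulsive, zero at the branch point
  expect_equal(vdw_energy(rmin, 0, 0, sig, sig, eps = 0.2), 0, tolerance = 1e-12)
  r <- seq(0.8 * sig, 4 * sig, length.out = 400)
  expect_true(all(vdw_energy(r, 0, 0, sig, sig, eps = 0.2) >= 0))
  # branch continuity for random hydropathies in [0, 4] (probe interactions
  # use lambda beyond 1)
  set.seed(2)
  for (lam in runif(100, 0, 4)) {
    below <- vdw_energy(rmin * (1 - 1e-12), lam, lam, sig, sig, 0.2)
    above <- vdw_energy(rmin * (1 + 1e-12), lam, lam, sig, sig, 0.2)
    expect_lt(abs(below - above), 1e-12)
  }
  # lambda = 1 reduces to the plain LJ everywhere in range
  r <- seq(0.9 * sig, 3.9 * sig, length.out = 50)
  ulj <- 4 * 0.2 * ((sig / r)^12 - (sig / r)^6)
  expect_equal(vdw_energy(r, 1, 1, sig, sig, 0.2), ulj, tolerance = 1e-12)
  # plain truncation beyond 4 sigma
  expect_equal(vdw_energy(4 * sig + 1e-9, 1, 1, sig, sig, 0.2), 0)
})

test_that("screened electrostatics recover bare Coulomb at infinite screening
           and vanish beyond the cutoff", {
  p_inf <- hps_params("kr", debye_l = 1e9)
  r <- 10
  bare <- -332.06371 / (80 * r)
  # screening factor exp(-10/1e9) deviates from 1 at the 1e-8 level
  expect_equal(coulomb_energy(r, -1, 1, p_inf), bare, tolerance = 1e-7)
  expect_equal(coulomb_energy(35.0001, -1, 1, p_kr), 0)
  # E-K pair at contact conditions: hand-folded constant
  want <- -1 * 332.06371 / (80 * 10) * exp(-1)
  expect_equal(coulomb_energy(10, -1, 1, p_kr), want, tolerance = 1e-12)
})

test_that("nSCD maps alternating to 0, diblock to 1, and matches the
           brute-force pipeline on random sequences", {
  alt <- strrep("EK", 25)
  di <- paste0(strrep("E", 25), strrep("K", 25))
  expect_equal(nscd(alt, p_kr), 0, tolerance = 1e-12)
  expect_equal(nscd(di, p_kr), 1, tolerance = 1e-12)
  set.seed(9)
  for (rep in 1:10) {
    # random arrangements of a charge-balanced 20-mer (the regime in which
    # the alternating/diblock normalization is exactly extremal)
    seq20 <- paste(sample(c(rep("E", 10), rep("K", 10))), collapse = "")
    q <- sequence_record(seq20, p_kr)$charges
    # brute-force recomputation of the whole normalization
    s <- oracle_scd(q)
    np <- sum(q > 0); nn <- sum(q < 0)
    # same canonical extremal patterns: majority sign leads
    s1 <- if (nn > np) -1 else 1
    n1 <- max(np, nn); n2 <- min(np, nn)
    qa <- c(); k1 <- n1; k2 <- n2
    while (k1 > 0 || k2 > 0) {
      if (k1 > 0) { qa <- c(qa, s1); k1 <- k1 - 1 }
      if (k2 > 0) { qa <- c(qa, -s1); k2 <- k2 - 1 }
    }
    di_q <- c(rep(s1, n1), rep(-s1, n2))
    want <- (s - oracle_scd(qa)) / (oracle_scd(di_q) - oracle_scd(qa))
    expect_equal(nscd(seq20, p_kr), want, tolerance = 1e-12)
    expect_gte(nscd(seq20, p_kr), -1e-12)
    expect_lte(nscd(seq20, p_kr), 1 + 1e-12)
  }
  expect_error(nscd("GSGS", p_kr), "charged")
})

test_that("nSCD is invariant under charge sign flip and sequence reversal,
           and the extremal constructs are extremal for short sequences", {
  set.seed(10)
  for (rep in 1:5) {
    q <- sample(c(1, -1), 12, replace = TRUE)
    if (all(q > 0) || all(q < 0)) next
    expect_equal(nscd(q), nscd(-q), tolerance = 1e-12)
    expect_equal(nscd(q), nscd(rev(q)), tolerance = 1e-12)
  }
  # exhaustive check: among all arrangements of 4 E + 4 K, the diblock
  # maximizes |SCD| and the alternating arrangement minimizes it
  perms <- unique(combn(8, 4, simplify = FALSE))
  scds <- vapply(perms, function(ix) {
    q <- rep(-1, 8); q[ix] <- 1
    oracle_scd(q)
  }, 0)
  di <- oracle_scd(c(1, 1, 1, 1, -1, -1, -1, -1))
  alt <- oracle_scd(c(1, -1, 1, -1, 1, -1, 1, -1))
  expect_equal(min(scds), di)       # SCD is most negative for the diblock
  expect_equal(max(scds), alt)      # and closest to zero when alternating
})

test_that("correlation length follows the semidilute scaling", {
  # at the overlap concentration the correlation length is the coil size
  cl <- correlation_length(rho = 3 * 6407 / (4 * pi * 40^3), Re = 40, Mw = 6407)
  expect_equal(cl$xi, 40, tolerance = 1e-12)
  # nu = 1/2: doubling the concentration halves xi
  cl2 <- correlation_length(rho = 2 * cl$rho_star, Re = 40, Mw = 6407)
  expect_equal(cl2$xi, 20, tolerance = 1e-12)
  expect_error(correlation_length(1e-3, 40, 6407, nu = 1 / 3), "singular")
})

test_that("probe-size and interaction-strength criteria match the stated bands", {
  expect_equal(probe_size_criterion(1.5 * 7, 7)$status, "ok")
  expect_equal(probe_size_criterion(1.49 * 7, 7)$status, "too_small")
  above <- probe_size_criterion(2.5 * 7, 7)
  expect_equal(above$status, "ok")
  expect_match(above$note, "above recommended")
  within <- probe_size_criterion(10.6, 7)
  expect_equal(within$status, "ok")
  expect_match(within$note, "within recommended")

  expect_equal(interaction_window_check(1.0)$status, "optimal")
  expect_equal(interaction_window_check(1.5)$status, "optimal")
  expect_equal(interaction_window_check(0.5)$status, "below_no_slip")
  expect_equal(interaction_window_check(2.0)$status, "adsorption_risk")
  expect_equal(interaction_window_check(1.75)$status, "adsorption_risk")
  expect_warning(gap <- interaction_window_check(0.9), "between")
  expect_true(gap$in_gap)
})

test_that("residue tables carry both hydropathy scales and charge assignment", {
  expect_equal(p_kr$eps_HPS, 0.2)
  expect_equal(p_kr$debye_l, 10)
  expect_equal(p_kr$eps_r, 80)
  expect_equal(unname(p_kr$residues["E", "charge"]), -1)
  expect_equal(unname(p_kr$residues["K", "charge"]), 1)
  expect_equal(unname(p_kr$residues["H", "charge"]), 0)
  p_his <- hps_params("kr", his_charge = 0.5)
  expect_equal(unname(p_his$residues["H", "charge"]), 0.5)
  p_urry <- hps_params("urry")
  expect_false(isTRUE(all.equal(p_urry$residues$lambda, p_kr$residues$lambda)))
  pe <- pair_energy("E", "K", c(5, 10, 40), p_kr)
  expect_equal(pe$U_total, pe$U_vdw + pe$U_elec)
  expect_equal(pe$U_elec[3], 0)  # beyond the electrostatic cutoff
})
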