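# MM-GBSA-style energy engine: gas-phase nonbonded terms (Coulomb + 12-6
# Lennard-Jones), generalized Born polar solvation (Still's pairwise formula
# over Hawkins-Cramer-Truhlar effective radii), SASA-proportional nonpolar
# solvation, the self-assembly energy, and per-monomer / pairwise
# decomposition with strict bookkeeping conservation.

COULOMB_K <- 332.0636  # kcal A / (mol e^2)

#' Energy-model settings
#'
#' @param cutoff nonbonded cutoff in Angstrom (plain truncation, no
#'   switching; default 10).
#' @param eps_in,eps_out interior and exterior dielectric constants
#'   (defaults 1 and 78.5).
#' @param gb_g,gb_b nonpolar solvation coefficients in
#'   `E_NP = g * SASA + b`: g = 0.00542 kcal/(mol A^2), b = 0.92 kcal/mol.
#' @param probe,n_points SASA probe radius and point count.
#' @return list of settings, class `energy_settings`.
#' @export
energy_settings <- function(cutoff = 10, eps_in = 1, eps_out = 78.5,
                            gb_g = 0.00542, gb_b = 0.92,
                            probe = 1.4, n_points = 960) {
  structure(list(cutoff = cutoff, eps_in = eps_in, eps_out = eps_out,
                 gb_g = gb_g, gb_b = gb_b, probe = probe,
                 n_points = n_points), class = "energy_settings")
}

pair_table <- function(topology) {
  n <- nrow(topology$atoms)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  mono <- topology$atoms$monomer
  keep <- mono[ij[, 1]] != mono[ij[, 2]]  # all intra-monomer pairs excluded
  ij[keep, , drop = FALSE]
}

#' Gas-phase nonbonded energy
#'
#' Pairwise Coulomb (332.0636 q_i q_j / r) plus 12-6 Lennard-Jones energy
#' (Lorentz-Berthelot combining) over all inter-monomer atom pairs within the
#' cutoff; intra-monomer pairs are excluded and electrostatics are truncated
#' (no switching) at the cutoff.
#'
#' @param frame a `fiber_frame`.
#' @param topology the matching `fiber_topology` (charges and LJ parameters
#'   are taken from its atom table).
#' @param settings an [energy_settings()].
#' @return list with `E_gas`, `E_coulomb`, `E_lj` and per-pair data.frame
#'   `pairs` (atom indices, monomers, r, coulomb, lj).
#' @export
energy_gas <- function(frame, topology, settings = energy_settings()) {
  at <- topology$atoms
  assert_that(!anyNA(at$charge) && !anyNA(at$eps) && !anyNA(at$sigma),
              "missing charge or LJ parameters")
  ij <- pair_table(topology)
  dv <- frame$coords[ij[, 1], , drop = FALSE] - frame$coords[ij[, 2], , drop = FALSE]
  r <- sqrt(rowSums(dv^2))
  keep <- r < settings$cutoff
  ij <- ij[keep, , drop = FALSE]; r <- r[keep]
  qq <- at$charge[ij[, 1]] * at$charge[ij[, 2]]
  coul <- COULOMB_K * qq / r
  epsij <- sqrt(at$eps[ij[, 1]] * at$eps[ij[, 2]])
  sigij <- (at$sigma[ij[, 1]] + at$sigma[ij[, 2]]) / 2
  sr6 <- (sigij / r)^6
  lj <- 4 * epsij * (sr6^2 - sr6)
  list(E_gas = sum(coul) + sum(lj), E_coulomb = sum(coul), E_lj = sum(lj),
       pairs = data.frame(i = ij[, 1], j = ij[, 2],
                          mono_i = at$monomer[ij[, 1]],
                          mono_j = at$monomer[ij[, 2]],
                          r = r, coulomb = coul, lj = lj))
}

#' Effective Born radii (Hawkins-Cramer-Truhlar)
#'
#' Pairwise-descreening effective radii: the inverse intrinsic radius of each
#' atom is reduced by the analytic integral of r^-4 over every neighbour
#' sphere. An isolated atom keeps its intrinsic radius.
#'
#' @param coords n x 3 coordinates, Angstrom.
#' @param rho intrinsic Born radii, Angstrom (> 0).
#' @param scale screening factor applied to neighbour radii in the
#'   descreening integral (default 0.8, compensating the double counting of
#'   overlapping neighbour spheres; use 1 for the bare pairwise integral).
#' @param r_max_eff cap on the effective radius for deeply buried atoms,
#'   Angstrom.
#' @return effective radii, Angstrom.
#' @export
born_radii <- function(coords, rho, scale = 0.8, r_max_eff = 30) {
  coords <- rbind(coords)
  n <- nrow(coords)
  rho <- rep_len(rho, n)
  assert_that(all(rho > 0), "intrinsic radii must be > 0")
  if (n == 1) return(rho)
  d <- as.matrix(stats::dist(coords))
  assert_that(all(d[upper.tri(d)] > 1e-9), "overlapping identical centres")
  inv <- 1 / rho
  sj <- scale * rho
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(n)[-i]) {
      r <- d[i, j]
      if (r + sj[j] <= rho[i]) next  # neighbour fully engulfed
      L <- max(abs(r - sj[j]), rho[i])
      U <- r + sj[j]
      s <- s + 0.5 * (1 / L - 1 / U + (r / 4) * (1 / U^2 - 1 / L^2) +
                        (1 / (2 * r)) * log(L / U) +
                        (sj[j]^2 / (4 * r)) * (1 / L^2 - 1 / U^2))
    }
    inv[i] <- max(inv[i] - s, 1 / r_max_eff)
  }
  1 / inv
}

gb_fgb <- function(r2, RiRj) sqrt(r2 + RiRj * exp(-r2 / (4 * RiRj)))

#' Generalized Born polar solvation energy
#'
#' Still's pairwise expression including self (i = j) terms:
#' `E_GB = -(k/2)(1/eps_in - 1/eps_out) sum_ij q_i q_j / f_GB` with
#' `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / 4 R_i R_j))`. For a single ion this
#' reduces to the Born equation.
#'
#' @param coords n x 3 coordinates, Angstrom.
#' @param charges atomic partial charges, e.
#' @param radii effective Born radii from [born_radii()].
#' @param eps_in,eps_out dielectric constants.
#' @return list with `E_GB` (kcal/mol) and the symmetric per-pair matrix
#'   `pair_matrix` (diagonal = self terms).
#' @export
energy_gb <- function(coords, charges, radii, eps_in = 1, eps_out = 78.5) {
  coords <- rbind(coords)
  n <- nrow(coords)
  assert_that(all(radii > 0), "non-positive Born radii")
  pref <- -(COULOMB_K / 2) * (1 / eps_in - 1 / eps_out)
  d2 <- as.matrix(stats::dist(coords))^2
  RiRj <- outer(radii, radii)
  fgb <- gb_fgb(d2, RiRj)
  qq <- outer(charges, charges)
  m <- pref * qq / fgb
  # off-diagonal terms appear twice in the double sum; keep the full matrix
  # and sum it directly
  list(E_GB = sum(m), pair_matrix = m)
}

#' Nonpolar solvation energy
#'
#' `E_NP = g * SASA + b` with the printed coefficients g = 0.00542
#' kcal/(mol A^2) and b = 0.92 kcal/mol.
#'
#' @param sasa_area solvent-accessible surface area, square Angstrom (>= 0).
#' @param g,b linear coefficients.
#' @return E_NP in kcal/mol.
#' @export
energy_np <- function(sasa_area, g = 0.00542, b = 0.92) {
  assert_that(all(sasa_area >= 0), "SASA must be >= 0")
  g * sasa_area + b
}

# Total MM-GBSA energy of one frame (gas inter-monomer + GB + NP).
frame_energy <- function(frame, topology, settings = energy_settings()) {
  gas <- energy_gas(frame, topology, settings)
  R <- born_radii(frame$coords, topology$atoms$rho_born)
  gb <- energy_gb(frame$coords, topology$atoms$charge, R,
                  settings$eps_in, settings$eps_out)
  sa <- frame_sasa(frame, topology, settings$probe, settings$n_points)
  np <- energy_np(sa$total, settings$gb_g, settings$gb_b)
  e_sol <- gb$E_GB + np
  list(E_gas = gas$E_gas, E_GB = gb$E_GB, E_NP = np, E_sol = e_sol,
       E_total = gas$E_gas + e_sol, gas = gas, gb = gb, sasa = sa,
       settings = settings)
}

#' Per-monomer ensemble energies
#'
#' Evaluates the total MM-GBSA energy of every frame of a trajectory and
#' returns per-frame totals normalized per monomer.
#'
#' @param trajectory a `fiber_trajectory` (or list of frames).
#' @param topology the matching topology.
#' @param settings an [energy_settings()].
#' @param window_fraction trailing fraction of frames analysed.
#' @return list with `per_bta` (per-frame energy per monomer), `frames`
#'   (frame energy objects) and `settings`.
#' @export
ensemble_energy <- function(trajectory, topology,
                            settings = energy_settings(),
                            window_fraction = 1) {
  frames <- if (inherits(trajectory, "fiber_trajectory"))
    equilibrated_frames(trajectory, window_fraction) else trajectory
  fe <- lapply(frames, frame_energy, topology = topology, settings = settings)
  per_bta <- vapply(fe, function(x) x$E_total, numeric(1)) / topology$n_monomers
  list(per_bta = per_bta, frames = fe, settings = settings)
}

#' Self-assembly energy
#'
#' Average energy per monomer inside the fibre minus the average energy of a
#' dissolved monomer; negative values indicate favourable incorporation into
#' the fibre.
#'
#' @param fiber_ensemble result of [ensemble_energy()] on the fibre.
#' @param monomer_ensemble result of [ensemble_energy()] on a single
#'   dissolved monomer, evaluated with identical settings.
#' @return Delta E in kcal/mol.
#' @export
assembly_energy <- function(fiber_ensemble, monomer_ensemble) {
  assert_that(identical(fiber_ensemble$settings, monomer_ensemble$settings),
              "ensembles evaluated with different energy settings")
  mean(fiber_ensemble$per_bta) - mean(monomer_ensemble$per_bta)
}

#' Per-monomer and pairwise energy decomposition
#'
#' Attributes every energy term to monomers: gas-phase pair terms and GB
#' cross terms between monomers n and m go to the symmetric pairwise matrix
#' `pairwise` (with electrostatic, van der Waals and solvation components);
#' intra-monomer GB terms (incl. self terms) and the per-atom-attributed
#' nonpolar term form each monomer's own solvation share. The per-monomer
#' energy is `Delta E_n = sum_m pairwise(n, m) + own_n`, and
#' `(1/2) sum_{n != m} pairwise + sum own` reproduces the frame total.
#'
#' @param trajectory a `fiber_trajectory` (or list of frames); time-averaged.
#' @param topology the matching topology.
#' @param settings an [energy_settings()].
#' @param window_fraction trailing fraction of frames analysed.
#' @return object of class `energy_decomposition` with fields `pairwise`,
#'   `ele`, `vdw`, `sol` (n x n matrices, zero diagonal), `own`,
#'   `per_monomer`, `total`.
#' @export
decompose <- function(trajectory, topology, settings = energy_settings(),
                      window_fraction = 1) {
  frames <- if (inherits(trajectory, "fiber_trajectory"))
    equilibrated_frames(trajectory, window_fraction) else trajectory
  n <- topology$n_monomers
  mono <- topology$atoms$monomer
  acc <- function() matrix(0, n, n)
  ele <- acc(); vdw <- acc(); sol <- acc()
  own <- numeric(n); total <- 0
  for (fr in frames) {
    fe <- frame_energy(fr, topology, settings)
    p <- fe$gas$pairs
    if (nrow(p) > 0) {
      grp <- (p$mono_i - 1) * n + p$mono_j
      agg <- rowsum(cbind(p$coulomb, p$lj), group = grp)
      ids <- as.integer(rownames(agg))
      idx <- cbind((ids - 1) %/% n + 1, (ids - 1) %% n + 1)
      ele[idx] <- ele[idx] + agg[, 1]
      vdw[idx] <- vdw[idx] + agg[, 2]
    }
    gbm <- fe$gb$pair_matrix
    mono_f <- factor(mono, levels = seq_len(n))
    gb_by_mono <- rowsum(t(rowsum(gbm, mono_f)), mono_f)  # n x n monomer sums
    # full cross interaction between monomers n and m: both orderings of the
    # Still double sum (gb_by_mono is symmetric, so this is 2x off-diagonal)
    cross <- gb_by_mono + t(gb_by_mono)
    diag(cross) <- 0
    sol <- sol + cross
    np_atom <- settings$gb_g * fe$sasa$per_atom
    own <- own + diag(gb_by_mono) +
      as.numeric(rowsum(np_atom, mono_f)) + settings$gb_b / n
    total <- total + fe$E_total
  }
  nf <- length(frames)
  ele <- (ele + t(ele)) / nf
  vdw <- (vdw + t(vdw)) / nf
  sol <- sol / nf  # gb_by_mono is already symmetric
  own <- unname(own / nf); total <- total / nf
  pairwise <- ele + vdw + sol
  dimnames(ele) <- dimnames(vdw) <- dimnames(sol) <- dimnames(pairwise) <- NULL
  per_monomer <- rowSums(pairwise) + own
  structure(list(pairwise = pairwise, ele = ele, vdw = vdw, sol = sol,
                 own = own, per_monomer = per_monomer, total = total,
                 n_monomers = n, settings = settings),
            class = "energy_decomposition")
}

#' Mean pair interaction versus neighbour separation
#'
#' Averages the pairwise interaction energy over all monomer pairs at
#' separation k (periodic indexing), k = 1..floor(N/2), plus the cumulative
#' per-monomer interaction profile used to assess saturation with the fibre
#' matrix.
#'
#' @param decomposition an `energy_decomposition`.
#' @return data.frame with columns `k`, `mean_interaction`, `cumulative`
#'   (per-monomer interaction with both neighbours up to separation k).
#' @export
neighbor_profile <- function(decomposition) {
  m <- decomposition$pairwise
  n <- decomposition$n_monomers
  kmax <- floor(n / 2)
  prof <- vapply(seq_len(kmax), function(k) {
    idx <- cbind(seq_len(n), ((seq_len(n) - 1 + k) %% n) + 1)
    mean(m[idx])
  }, numeric(1))
  both <- ifelse(seq_len(kmax) == n / 2, 1, 2)  # antipodal neighbour counted once
  data.frame(k = seq_len(kmax), mean_interaction = prof,
             cumulative = cumsum(both * prof))
}

#' Hydrogen-bond energy bookkeeping
#'
#' Persistent bonds per monomer (`2 * count / N`, each monomer sharing bonds
#' with two stacking neighbours) and the associated energy using the typical
#' peptide hydrogen-bond energy in water, -1.58 kcal/mol. Reported values
#' follow the summary-table protocol: HBs/BTA is rounded to one decimal, the
#' energy is computed from the unrounded HBs/BTA and then rounded to one
#' decimal.
#'
#' @param persistent_count number of persistent hydrogen bonds (>= 0).
#' @param n_monomers number of monomers (>= 1).
#' @param e_hb per-bond energy, kcal/mol (default -1.58).
#' @return object of class `hbond_energy` with `hbs_per_bta`, `dE_HBs`
#'   (rounded, as reported) and `hbs_per_bta_raw`, `dE_HBs_raw`.
#' @export
hbond_energy <- function(persistent_count, n_monomers, e_hb = -1.58) {
  assert_that(persistent_count >= 0 && n_monomers >= 1,
              "invalid count or monomer number")
  raw <- 2 * persistent_count / n_monomers
  de_raw <- raw * e_hb
  structure(list(persistent_count = persistent_count,
                 hbs_per_bta = round(raw, 1), hbs_per_bta_raw = raw,
                 dE_HBs = round(de_raw, 1), dE_HBs_raw = de_raw,
                 e_hb = e_hb),
            class = "hbond_energy")
}

#' Solvation-to-hydrogen-bond and solvation-to-electrostatic energy ratios
#'
#' Ratios of magnitudes as printed in energy summary tables. Following the
#' reporting protocol, the hydrogen-bond denominator is the one-decimal
#' rounded `dE_HBs`, and both ratios are reported to one decimal.
#'
#' @param dE_sol global solvation energy, kcal/mol.
#' @param hbe an [hbond_energy()].
#' @param dE_int_sol,dE_ele optional pairwise solvation and electrostatic
#'   components for the second ratio.
#' @return list with `sol_over_hbs` and (when components are given)
#'   `intsol_over_ele`.
#' @export
energy_ratios <- function(dE_sol, hbe, dE_int_sol = NULL, dE_ele = NULL) {
  assert_that(hbe$dE_HBs != 0, "zero hydrogen-bond energy denominator")
  out <- list(sol_over_hbs = round(abs(dE_sol) / abs(hbe$dE_HBs), 1))
  if (!is.null(dE_int_sol) && !is.null(dE_ele)) {
    assert_that(dE_ele != 0, "zero electrostatic denominator")
    out$intsol_over_ele <- round(abs(dE_int_sol) / abs(dE_ele), 1)
  }
  out
}

#' Moment statistics of a per-monomer energy profile
#'
#' Mean, median, standard deviation and adjusted Fisher-Pearson skewness
#' (the sample-size-corrected third standardized moment).
#'
#' @param energies numeric vector (n >= 3).
#' @return list with `mean`, `median`, `sd`, `skewness`.
#' @export
energy_histogram_stats <- function(energies) {
  n <- length(energies)
  assert_that(n >= 3, "need at least 3 values")
  m <- mean(energies)
  m2 <- mean((energies - m)^2)
  m3 <- mean((energies - m)^3)
  g1 <- m3 / m2^1.5
  skew <- g1 * sqrt(n * (n - 1)) / (n - 2)
  list(mean = m, median = median(energies), sd = sd(energies),
       skewness = skew)
}
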