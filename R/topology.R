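# Coarse-grained fibre topology and ideal-geometry builder.
#
# Each monomer carries a C3-symmetric aromatic core (six ring carbons), three
# amide arms and a short radial chain of side-chain beads. Per arm the atoms
# are: two ring carbons (CA1, CA2) that define the torsion axis, the carbonyl
# carbon (C) and oxygen (O) completing the CA1-CA2-C-O amide dihedral, the
# amide nitrogen (N) and its hydrogen (H). The N-H of monomer i donates to the
# carbonyl O of monomer i+1 along the stack, the threefold hydrogen-bonding
# motif of a BTA helix. Atom parameters (charge, 12-6 Lennard-Jones, intrinsic
# Born radius, van der Waals radius) are stored per atom and travel with the
# topology (and with its sidecar CSV on disk).

ATOM_PARAMS <- data.frame(
  name   = c("CA1", "CA2", "C", "O", "N", "H", "B"),
  charge = c(-0.10, 0.10, 0.60, -0.50, -0.40, 0.30, 0.00),
  eps    = c(0.086, 0.086, 0.086, 0.210, 0.170, 0.0157, 0.150),
  sigma  = c(3.20, 3.20, 3.20, 2.80, 3.00, 2.00, 3.00),
  rho    = c(1.70, 1.70, 1.70, 1.50, 1.55, 1.20, 2.00),
  stringsAsFactors = FALSE
)

#' Generator configuration for synthetic fibre data
#'
#' Collects every knob of the synthetic-data module with defaults set to the
#' construction geometry of the simulated BTA fibres: 48 stacked monomers,
#' 3.4 Angstrom intercore spacing, amide dihedrals at -140 degrees
#' (P-helicity) and a 6.8 nm extended diameter.
#'
#' @param n_monomers number of stacked monomers (>= 2).
#' @param intercore_distance core-to-core spacing in Angstrom (> 0).
#' @param dihedral0 initial amide dihedral in degrees, in (-180, 180].
#' @param n_frames number of trajectory frames to generate.
#' @param stacking_sigma Gaussian jitter (Angstrom) of the core spacing.
#' @param dihedral_mix length-3 fractions (P, M, flipped) summing to 1.
#' @param fold_factor equilibrated length / initial length, in (0, 1].
#' @param extended_diameter lateral bead-envelope diameter, Angstrom.
#' @param hbond_spec optional data.frame (bond, occupancy) for occupancy
#'   pattern generation.
#' @param energy_spec list with `mean` and `sd` (kcal/mol) of the per-monomer
#'   self-assembly energy baseline and `domains`, a list of
#'   `c(start, length, depth)` stable-domain runs.
#' @param seed master integer seed; every generator derives its own stream.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_monomers = 48,
                             intercore_distance = 3.4,
                             dihedral0 = -140,
                             n_frames = 25,
                             stacking_sigma = 0.05,
                             dihedral_mix = c(P = 1, M = 0, flipped = 0),
                             fold_factor = 1,
                             extended_diameter = 68,
                             hbond_spec = NULL,
                             energy_spec = list(mean = -3, sd = 1, domains = list()),
                             seed = 1L) {
  assert_that(n_monomers >= 2, "n_monomers must be >= 2")
  assert_that(intercore_distance > 0, "intercore_distance must be > 0")
  assert_that(dihedral0 > -180 && dihedral0 <= 180, "dihedral0 must lie in (-180, 180]")
  assert_that(length(dihedral_mix) == 3 && all(dihedral_mix >= 0),
              "dihedral_mix must be three nonnegative fractions")
  assert_that(abs(sum(dihedral_mix) - 1) <= 1e-9, "dihedral_mix fractions must sum to 1")
  assert_that(fold_factor > 0 && fold_factor <= 1, "fold_factor must lie in (0, 1]")
  assert_that(extended_diameter > 0, "extended_diameter must be > 0")
  if (!is.null(hbond_spec))
    assert_that(all(hbond_spec$occupancy >= 0 & hbond_spec$occupancy <= 1),
                "hbond occupancies must lie in [0, 1]")
  names(dihedral_mix) <- c("P", "M", "flipped")
  structure(list(
    n_monomers = as.integer(n_monomers),
    intercore_distance = intercore_distance,
    dihedral0 = dihedral0,
    n_frames = as.integer(n_frames),
    stacking_sigma = stacking_sigma,
    dihedral_mix = dihedral_mix,
    fold_factor = fold_factor,
    extended_diameter = extended_diameter,
    hbond_spec = hbond_spec,
    energy_spec = energy_spec,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Reference (monomer-local) coordinates for one monomer placed with its core
# centroid at the origin and arms in the xy plane.
monomer_template <- function(dihedral0, extended_diameter) {
  atoms <- list(); coords <- list(); quads <- list(); arm_of <- integer(0)
  bead_radii <- seq(8.5, extended_diameter / 2, length.out = 4)
  idx <- 0L
  id_of <- function(arm, name) paste0(name, arm)
  for (arm in 1:3) {
    alpha <- (arm - 1) * 2 * pi / 3
    u <- c(cos(alpha), sin(alpha), 0)
    v <- c(-sin(alpha), cos(alpha), 0)
    ca1 <- 1.4 * u
    ca2 <- 2.8 * u
    cc  <- ca2 + 1.5 * (cos(pi / 3) * u + sin(pi / 3) * v)
    o   <- place_dihedral_atom(ca1, ca2, cc, 1.23, 120, dihedral0)
    n   <- o - 0.3 * u + c(0, 0, 0.4)
    h   <- n + c(0, 0, 1.0)
    arm_atoms <- list(CA1 = ca1, CA2 = ca2, C = cc, O = o, N = n, H = h)
    for (nm in names(arm_atoms)) {
      idx <- idx + 1L
      atoms[[idx]] <- data.frame(name = nm, arm = arm, stringsAsFactors = FALSE)
      coords[[idx]] <- arm_atoms[[nm]]
    }
    for (rb in bead_radii) {
      idx <- idx + 1L
      atoms[[idx]] <- data.frame(name = "B", arm = arm, stringsAsFactors = FALSE)
      coords[[idx]] <- rb * u
    }
  }
  tab <- do.call(rbind, atoms)
  tab$local_index <- seq_len(nrow(tab))
  list(atoms = tab, coords = do.call(rbind, coords))
}

#' Build an ideal stacked fibre
#'
#' Constructs the extended starting geometry: cores stacked on the z axis with
#' spacing exactly `intercore_distance`, all 3n amide dihedrals equal to
#' `dihedral0`, and the periodic repeat length along z equal to
#' `n_monomers * intercore_distance` (so 48 monomers at 3.4 Angstrom give a
#' 16.3 nm periodic fibre). The side-chain bead envelope spans the configured
#' extended diameter.
#'
#' @param config a [generator_config()].
#' @return list with elements `topology` (class `fiber_topology`) and `frame`
#'   (class `fiber_frame`).
#' @export
build_ideal_fiber <- function(config) {
  assert_that(inherits(config, "generator_config"), "config must be a generator_config")
  n <- config$n_monomers
  d <- config$intercore_distance
  tmpl <- monomer_template(config$dihedral0, config$extended_diameter)
  per <- nrow(tmpl$atoms)

  atoms <- do.call(rbind, lapply(seq_len(n), function(i) {
    a <- tmpl$atoms
    a$monomer <- i
    a
  }))
  atoms$id <- seq_len(nrow(atoms))
  p <- ATOM_PARAMS[match(atoms$name, ATOM_PARAMS$name), ]
  atoms$charge <- p$charge
  atoms$eps <- p$eps
  atoms$sigma <- p$sigma
  atoms$rho_born <- p$rho
  atoms$r_vdw <- p$rho
  atoms$is_core <- atoms$name %in% c("CA1", "CA2")
  atoms$is_bead <- atoms$name == "B"
  rownames(atoms) <- NULL

  coords <- do.call(rbind, lapply(seq_len(n), function(i) {
    sweep(tmpl$coords, 2, c(0, 0, (i - 1) * d), "+")
  }))

  lookup <- function(mono, arm, name)
    atoms$id[atoms$monomer == mono & atoms$arm == arm & atoms$name == name]
  quads <- do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(1:3, function(k) {
      data.frame(monomer = i, arm = k,
                 a1 = lookup(i, k, "CA1"), a2 = lookup(i, k, "CA2"),
                 a3 = lookup(i, k, "C"), a4 = lookup(i, k, "O"))
    }))
  }))
  donors <- do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(1:3, function(k) {
      data.frame(monomer = i, arm = k,
                 donor = lookup(i, k, "N"), hydrogen = lookup(i, k, "H"))
    }))
  }))
  acceptors <- do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(1:3, function(k) {
      data.frame(monomer = i, arm = k, acceptor = lookup(i, k, "O"))
    }))
  }))

  topology <- structure(list(
    atoms = atoms,
    quadruplets = quads,
    donors = donors,
    acceptors = acceptors,
    n_monomers = n,
    atoms_per_monomer = per,
    intercore_distance = d,
    dihedral0 = config$dihedral0,
    extended_diameter = config$extended_diameter,
    periodic_axis = "z",
    template = tmpl
  ), class = "fiber_topology")

  frame <- structure(list(coords = coords, box_z = n * d, time = 0),
                     class = "fiber_frame")
  list(topology = topology, frame = frame)
}

core_centroids <- function(frame, topology) {
  idx <- split(topology$atoms$id[topology$atoms$is_core],
               topology$atoms$monomer[topology$atoms$is_core])
  unname(t(vapply(idx[as.character(seq_len(topology$n_monomers))],
                  function(ii) colMeans(frame$coords[ii, , drop = FALSE]),
                  numeric(3))))
}

#' @export
print.fiber_topology <- function(x, ...) {
  cat("Coarse fibre topology:", x$n_monomers, "monomers,",
      nrow(x$atoms), "atoms (", x$atoms_per_monomer, "per monomer )\n")
  cat("  intercore distance:", x$intercore_distance, "A; dihedral0:",
      x$dihedral0, "deg; extended diameter:", x$extended_diameter, "A\n")
  invisible(x)
}

#' @export
print.fiber_frame <- function(x, ...) {
  cat("Fibre frame:", nrow(x$coords), "atoms, box_z =", x$box_z,
      "A, t =", x$time, "ns\n")
  invisible(x)
}
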