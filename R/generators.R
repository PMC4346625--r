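# Synthetic-data generators: perturbed trajectories, hydrogen-bond occupancy
# matrices, per-monomer energy profiles, scattering curves and FRET traces.
# All randomness flows from the master seed through per-generator streams
# (derive_seed), so each generator is independently reproducible.

draw_dihedrals <- function(k, mix, dihedral0) {
  cls <- sample(c("P", "M", "flipped"), k, replace = TRUE, prob = mix)
  ang <- numeric(k)
  nP <- sum(cls == "P"); nM <- sum(cls == "M"); nF <- sum(cls == "flipped")
  if (nP) ang[cls == "P"] <- pmin(pmax(rnorm(nP, dihedral0, 15), -179.5), -90.5)
  if (nM) ang[cls == "M"] <- pmin(pmax(rnorm(nM, -60, 15), -89.5), -0.5)
  if (nF) ang[cls == "flipped"] <- pmin(pmax(rnorm(nF, 120, 40), 0.5), 179.5)
  list(class = cls, angle = ang)
}

#' Generate a perturbed fibre trajectory
#'
#' Emulates the relaxation of an ideal stack: axial spacings are jittered
#' (Gaussian, `stacking_sigma`), amide dihedrals are redrawn per frame from
#' the configured P/M/flipped mixture, and folding is modelled as axial
#' compression to `fold_factor` times the initial periodic length combined
#' with a closed-loop lateral bend that restores the three-dimensional
#' intercore spacing to the configured value. Identical config and seed give
#' a bit-identical trajectory.
#'
#' @param topology a `fiber_topology` from [build_ideal_fiber()].
#' @param config the [generator_config()] used to build it.
#' @return object of class `fiber_trajectory`: a list of `fiber_frame`s plus
#'   the generating truth (per-frame dihedral classes) as attribute `truth`.
#' @export
perturb_trajectory <- function(topology, config) {
  assert_that(inherits(topology, "fiber_topology"), "topology must be a fiber_topology")
  assert_that(config$fold_factor > 0 && config$fold_factor <= 1,
              "fold_factor must lie in (0, 1]")
  n <- topology$n_monomers
  d <- topology$intercore_distance
  fold <- config$fold_factor
  box_z <- fold * n * d
  chord <- d * sqrt(max(0, 1 - fold^2))
  bend_amp <- if (chord > 0) chord / (2 * sin(pi / n)) else 0
  theta <- 2 * pi * (seq_len(n) - 1) / n
  lateral <- cbind(bend_amp * cos(theta), bend_amp * sin(theta))
  tmpl_coords <- topology$template$coords
  quads <- topology$quadruplets

  frames <- vector("list", config$n_frames)
  classes <- vector("list", config$n_frames)
  with_stream(config$seed, "trajectory", {
    for (f in seq_len(config$n_frames)) {
      s <- rnorm(n, d, config$stacking_sigma)
      s <- pmax(s, 0.01 * d)
      gaps <- fold * s
      gaps <- gaps - mean(gaps) + fold * d  # close the periodic loop exactly
      z <- c(0, cumsum(gaps))[seq_len(n)]
      pos <- cbind(lateral, z)
      # monomer planes tilt with the local fibre axis (central-difference
      # tangent, periodic), so the hydrogen-bond register follows the bend
      coords <- do.call(rbind, lapply(seq_len(n), function(i) {
        nxt <- pos[i %% n + 1, ] + c(0, 0, if (i == n) box_z else 0)
        prv <- pos[(i - 2) %% n + 1, ] - c(0, 0, if (i == 1) box_z else 0)
        tang <- nxt - prv
        tang <- tang / vnorm(tang)
        R <- rotation_from_z(tang)
        sweep(tmpl_coords %*% t(R), 2, pos[i, ], "+")
      }))
      dd <- draw_dihedrals(nrow(quads), config$dihedral_mix, config$dihedral0)
      for (q in seq_len(nrow(quads))) {
        coords[quads$a4[q], ] <- place_dihedral_atom(
          coords[quads$a1[q], ], coords[quads$a2[q], ], coords[quads$a3[q], ],
          1.23, 120, dd$angle[q])
      }
      frames[[f]] <- structure(list(coords = coords, box_z = box_z,
                                    time = f - 1), class = "fiber_frame")
      classes[[f]] <- dd$class
    }
  })
  structure(list(frames = frames, n_frames = config$n_frames,
                 times = vapply(frames, `[[`, numeric(1), "time")),
            class = "fiber_trajectory",
            truth = list(dihedral_classes = classes, fold_factor = fold))
}

#' @export
print.fiber_trajectory <- function(x, ...) {
  cat("Fibre trajectory:", x$n_frames, "frames, box_z =",
      x$frames[[1]]$box_z, "A\n")
  invisible(x)
}

#' Generate a Bernoulli hydrogen-bond presence matrix
#'
#' Each bond is present in each frame independently with its configured
#' occupancy rate; realized occupancies are stored alongside the matrix.
#'
#' @param n_bonds number of candidate bonds.
#' @param occupancies per-bond presence probabilities in \[0, 1\] (recycled).
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return object of class `hbond_table` with fields `presence`
#'   (frames x bonds logical matrix), `occupancy` (realized fractions) and
#'   `rate` (generating probabilities).
#' @export
generate_hbond_occupancy <- function(n_bonds, occupancies, n_frames, seed = 1L) {
  assert_that(all(occupancies >= 0 & occupancies <= 1),
              "occupancies must lie in [0, 1]")
  occupancies <- rep_len(occupancies, n_bonds)
  pres <- with_stream(seed, "hbonds", {
    matrix(rbinom(n_frames * n_bonds, 1L,
                  rep(occupancies, each = n_frames)) == 1L,
           nrow = n_frames, ncol = n_bonds)
  })
  structure(list(presence = pres,
                 occupancy = colMeans(pres),
                 rate = occupancies,
                 bonds = data.frame(bond = seq_len(n_bonds)),
                 cutoffs = NULL),
            class = "hbond_table")
}

#' Generate a per-monomer self-assembly energy profile
#'
#' Gaussian baseline with optional stable domains: runs of consecutive
#' monomers whose energies are shifted down by a configured depth, emulating
#' ordered segments of a fibre.
#'
#' @param energy_spec list with `mean`, `sd` (kcal/mol) and `domains`, a list
#'   of numeric `c(start, length, depth)` triples. Runs must not overlap and
#'   must lie inside `[1, n_monomers]`.
#' @param n_monomers number of monomers.
#' @param seed integer seed.
#' @return numeric vector of per-monomer energies with attribute `domains`.
#' @export
generate_energy_profile <- function(energy_spec, n_monomers, seed = 1L) {
  domains <- energy_spec$domains %||% list()
  covered <- integer(0)
  for (dom in domains) {
    idx <- seq(dom[1], dom[1] + dom[2] - 1)
    assert_that(min(idx) >= 1 && max(idx) <= n_monomers,
                "domain run lies outside [1, n_monomers]")
    assert_that(!any(idx %in% covered), "overlapping domain runs")
    covered <- c(covered, idx)
  }
  e <- with_stream(seed, "energy", rnorm(n_monomers, energy_spec$mean, energy_spec$sd))
  for (dom in domains) {
    idx <- seq(dom[1], dom[1] + dom[2] - 1)
    e[idx] <- e[idx] - dom[3]
  }
  attr(e, "domains") <- domains
  e
}

#' Generate a synthetic scattering curve from the worm-like chain model
#'
#' Evaluates [model_intensity()] on a q grid (default: 150 points spanning
#' the experimentally accessed 0.15-4.47 nm^-1 window) and applies
#' multiplicative Gaussian noise; the uncertainty column is
#' `noise_fraction * model`.
#'
#' @param params a [wlc_params()] parameter set.
#' @param q_grid ascending positive q values, nm^-1.
#' @param noise_fraction relative noise level (>= 0).
#' @param seed integer seed.
#' @return a `saxs_profile` (see [saxs_profile()]) with the generating
#'   parameters attached as attribute `truth`.
#' @export
generate_saxs_curve <- function(params,
                                q_grid = seq(0.15, 4.47, length.out = 150),
                                noise_fraction = 0.02, seed = 1L) {
  assert_that(length(q_grid) > 0, "empty q grid")
  assert_that(all(q_grid > 0) && !is.unsorted(q_grid, strictly = TRUE),
              "q grid must be positive and strictly increasing")
  assert_that(noise_fraction >= 0, "noise_fraction must be >= 0")
  model <- model_intensity(q_grid, params)
  eps <- if (noise_fraction > 0)
    with_stream(seed, "saxs", rnorm(length(q_grid), 0, noise_fraction))
  else rep(0, length(q_grid))
  prof <- saxs_profile(q_grid, model * (1 + eps), noise_fraction * model)
  attr(prof, "truth") <- params
  prof
}

#' Generate a synthetic FRET mixing trace
#'
#' The FRET ratio follows a rising biexponential
#' `F(t) = F_plateau - A_fast exp(-t/tau_fast) - A_slow exp(-t/tau_slow)`
#' plus Gaussian noise; donor and acceptor intensities are emitted with unit
#' total intensity so that the acceptor/(donor+acceptor) ratio reproduces the
#' noisy curve.
#'
#' @param fit_params list or `biexp_fit` with `F_plateau`, `A_fast`,
#'   `tau_fast`, `A_slow`, `tau_slow` (timescales > 0, amplitudes >= 0).
#' @param t_grid strictly increasing times (same unit as the timescales).
#' @param noise_sd Gaussian noise on the ratio.
#' @param seed integer seed.
#' @return a `fret_trace` (see [fret_trace()]) with attribute `truth`.
#' @export
generate_fret_trace <- function(fit_params, t_grid, noise_sd = 0, seed = 1L) {
  p <- fit_params
  assert_that(p$tau_fast > 0 && p$tau_slow > 0, "timescales must be > 0")
  assert_that(p$A_fast >= 0 && p$A_slow >= 0, "amplitudes must be >= 0")
  f <- p$F_plateau - p$A_fast * exp(-t_grid / p$tau_fast) -
    p$A_slow * exp(-t_grid / p$tau_slow)
  if (noise_sd > 0)
    f <- f + with_stream(seed, "fret", rnorm(length(t_grid), 0, noise_sd))
  f <- pmin(pmax(f, 0), 1)
  tr <- fret_trace(t_grid, I_donor = 1 - f, I_acceptor = f)
  attr(tr, "truth") <- p
  tr
}
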