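# Shared fixtures: small fibres and random toys, built in code.

small_fiber <- function(n = 6, d = 3.4, dihedral0 = -140, n_frames = 4,
                        sigma = 0.05, mix = c(1, 0, 0), fold = 1, seed = 7) {
  cfg <- generator_config(n_monomers = n, intercore_distance = d,
                          dihedral0 = dihedral0, n_frames = n_frames,
                          stacking_sigma = sigma, dihedral_mix = mix,
                          fold_factor = fold, seed = seed)
  c(build_ideal_fiber(cfg), list(config = cfg))
}

# Random charged toy system: k "monomers" of m atoms each, coordinates spread
# out so that every geometric routine has a nondegenerate input.
random_toy <- function(k = 3, m = 4, seed = 1, spread = 6) {
  withr::with_seed(seed, {
    atoms <- data.frame(
      id = seq_len(k * m),
      monomer = rep(seq_len(k), each = m),
      name = "X", arm = 1L,
      charge = round(runif(k * m, -0.5, 0.5), 3),
      eps = runif(k * m, 0.05, 0.2),
      sigma = runif(k * m, 2.5, 3.5),
      rho_born = runif(k * m, 1.2, 2.0),
      r_vdw = runif(k * m, 1.2, 2.0),
      is_core = FALSE, is_bead = FALSE)
    coords <- cbind(runif(k * m, 0, spread), runif(k * m, 0, spread),
                    rep(seq_len(k), each = m) * 4 + rnorm(k * m, 0, 0.5))
    topo <- structure(list(atoms = atoms, n_monomers = k,
                           atoms_per_monomer = m, intercore_distance = 4,
                           periodic_axis = "z"), class = "fiber_topology")
    frame <- structure(list(coords = coords, box_z = 4 * k + 20, time = 0),
                       class = "fiber_frame")
    list(topology = topo, frame = frame)
  })
}

# Brute-force gas-phase energy oracle: plain double loop over atom pairs.
gas_oracle <- function(coords, atoms, cutoff = 10) {
  tot_c <- 0; tot_l <- 0
  n <- nrow(coords)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (atoms$monomer[i] == atoms$monomer[j]) next
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (r >= cutoff) next
    tot_c <- tot_c + 332.0636 * atoms$charge[i] * atoms$charge[j] / r
    ep <- sqrt(atoms$eps[i] * atoms$eps[j])
    sg <- (atoms$sigma[i] + atoms$sigma[j]) / 2
    tot_l <- tot_l + 4 * ep * ((sg / r)^12 - (sg / r)^6)
  }
  c(coulomb = tot_c, lj = tot_l)
}
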