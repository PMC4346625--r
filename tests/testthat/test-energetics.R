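test_that("gas-phase energy reproduces closed forms and the brute-force oracle", {
  # two +1e charges at 3.32 A, no LJ
  topo <- random_toy(k = 2, m = 1)$topology
  topo$atoms$charge <- c(1, 1)
  topo$atoms$eps <- c(0, 0)
  fr <- structure(list(coords = rbind(c(0, 0, 0), c(3.32, 0, 0)),
                       box_z = 100, time = 0), class = "fiber_frame")
  g <- energy_gas(fr, topo)
  expect_equal(g$E_gas, 332.0636 / 3.32, tolerance = 1e-9)
  expect_equal(g$E_gas, 100.0191, tolerance = 1e-4)
  # LJ pair at the 12-6 minimum r = sigma * 2^(1/6) gives exactly -eps
  topo$atoms$charge <- c(0, 0)
  topo$atoms$eps <- c(0.3, 0.3)
  topo$atoms$sigma <- c(3, 3)
  frm <- structure(list(coords = rbind(c(0, 0, 0), c(3 * 2^(1 / 6), 0, 0)),
                        box_z = 100, time = 0), class = "fiber_frame")
  expect_equal(energy_gas(frm, topo)$E_gas, -0.3, tolerance = 1e-12)
  # random 6-atom frame vs exhaustive double loop
  toy <- random_toy(k = 3, m = 2, seed = 17)
  g6 <- energy_gas(toy$frame, toy$topology)
  orc <- gas_oracle(toy$frame$coords, toy$topology$atoms)
  expect_equal(g6$E_coulomb, unname(orc["coulomb"]), tolerance = 1e-9)
  expect_equal(g6$E_lj, unname(orc["lj"]), tolerance = 1e-9)
})

test_that("effective Born radii obey limits and the field-integral oracle", {
  expect_equal(born_radii(matrix(c(0, 0, 0), 1, 3), 2.0), 2.0)
  far <- born_radii(rbind(c(0, 0, 0), c(500, 0, 0)), c(1.5, 2.0))
  expect_equal(far, c(1.5, 2.0), tolerance = 1e-6)
  expect_error(born_radii(rbind(c(0, 0, 0), c(0, 0, 0)), c(1, 1)),
               "overlapping")
  # close (non-overlapping) pair: numerical Coulomb-field integral over the
  # neighbour sphere, scale = 1
  rho <- c(1.6, 1.4); d <- 3.4
  got <- born_radii(rbind(c(0, 0, 0), c(d, 0, 0)), rho, scale = 1)
  num_int <- function(center_d, rj) {
    # integral of 1/(4 pi r^4) over the neighbour sphere, spherical grid
    nr <- 80; na <- 80
    rr <- seq(1e-3, rj, length.out = nr)
    aa <- seq(0, pi, length.out = na)
    tot <- 0
    for (r in rr) for (a in aa) {
      x <- center_d + r * cos(a); y <- r * sin(a)
      dist2 <- x^2 + y^2
      vol <- r^2 * sin(a) * (rr[2] - rr[1]) * (aa[2] - aa[1]) * 2 * pi
      tot <- tot + vol / (4 * pi * dist2^2)
    }
    tot
  }
  inv1 <- 1 / rho[1] - num_int(d, rho[2])
  expect_true(all(got >= rho))
  expect_equal(got[1], 1 / inv1, tolerance = 0.1)
})

test_that("single-ion GB reduces to the Born equation over a parameter grid", {
  for (q in c(-2, -1, 0.5, 1, 3)) {
    for (R in c(1, 2, 4.5)) {
      for (eo in c(2, 20, 78.5, 1000)) {
        e <- energy_gb(matrix(0, 1, 3), q, R, eps_in = 1, eps_out = eo)$E_GB
        born <- -(332.0636 / 2) * (1 - 1 / eo) * q^2 / R
        expect_equal(e, born, tolerance = 1e-9 * max(1, abs(born)))
      }
    }
  }
  # zero charge and matched dielectrics give zero
  expect_equal(energy_gb(matrix(0, 1, 3), 0, 2)$E_GB, 0)
  expect_equal(energy_gb(rbind(c(0, 0, 0), c(3, 0, 0)), c(1, -1), c(2, 2),
                         eps_in = 78.5, eps_out = 78.5)$E_GB, 0)
})

test_that("GB energy is invariant under rigid rotation and translation", {
  toy <- random_toy(k = 2, m = 3, seed = 23)
  co <- toy$frame$coords
  q <- toy$topology$atoms$charge
  R <- born_radii(co, toy$topology$atoms$rho_born)
  e0 <- energy_gb(co, q, R)$E_GB
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  co2 <- sweep(co %*% rot, 2, c(5, -3, 11), "+")
  R2 <- born_radii(co2, toy$topology$atoms$rho_born)
  expect_equal(energy_gb(co2, q, R2)$E_GB, e0, tolerance = 1e-9 * abs(e0))
})

test_that("nonpolar term is the printed linear SASA relation", {
  expect_equal(energy_np(0), 0.92)
  expect_equal(energy_np(1000), 6.34)
  expect_equal(energy_np(184.5), 1.92, tolerance = 1e-3)
  expect_error(energy_np(-1), "SASA")
})

test_that("assembly energy compares fibre and dissolved-monomer ensembles", {
  fb <- small_fiber(n = 4, n_frames = 2, sigma = 0.05)
  tr <- perturb_trajectory(fb$topology, fb$config)
  es <- energy_settings(n_points = 120)
  fib <- ensemble_energy(tr, fb$topology, es)
  expect_equal(assembly_energy(fib, fib), 0)
  # identical settings enforced
  fib2 <- ensemble_energy(tr, fb$topology, energy_settings(n_points = 60))
  expect_error(assembly_energy(fib, fib2), "settings")
  # two-frame toy vs hand-computed averages
  mono_cfg <- generator_config(n_monomers = 2, intercore_distance = 60,
                               n_frames = 2, stacking_sigma = 0, seed = 2)
  mono <- build_ideal_fiber(mono_cfg)
  mtr <- perturb_trajectory(mono$topology, mono_cfg)
  menn <- ensemble_energy(mtr, mono$topology, es)
  de <- assembly_energy(fib, menn)
  hand <- mean(vapply(fib$frames, `[[`, numeric(1), "E_total")) / 4 -
    mean(vapply(menn$frames, `[[`, numeric(1), "E_total")) / 2
  expect_equal(de, hand, tolerance = 1e-9)
})

test_that("decomposition is symmetric, zero-diagonal and conserves the total", {
  toy <- random_toy(k = 5, m = 3, seed = 31)
  es <- energy_settings(n_points = 120)
  dec <- decompose(list(toy$frame), toy$topology, es)
  expect_true(isTRUE(all.equal(dec$pairwise, t(dec$pairwise))))
  expect_equal(diag(dec$pairwise), rep(0, 5))
  fe <- fibremetrics:::frame_energy(toy$frame, toy$topology, es)
  expect_equal(sum(dec$pairwise) / 2 + sum(dec$own), fe$E_total,
               tolerance = 1e-6)
  expect_equal(dec$per_monomer, rowSums(dec$pairwise) + dec$own,
               tolerance = 1e-9)
  # exhaustive re-summation of the gas cross terms per monomer pair
  p <- fe$gas$pairs
  for (a in 1:4) for (b in (a + 1):5) {
    sel <- p$mono_i == a & p$mono_j == b
    expect_equal(dec$ele[a, b] + dec$vdw[a, b],
                 sum(p$coulomb[sel]) + sum(p$lj[sel]), tolerance = 1e-9)
  }
})

test_that("two-monomer toy splits the single cross term symmetrically", {
  toy <- random_toy(k = 2, m = 1, seed = 3)
  toy$topology$atoms$charge <- c(0.5, -0.5)
  toy$topology$atoms$eps <- c(0, 0)
  toy$frame$coords <- rbind(c(0, 0, 0), c(4, 0, 0))
  es <- energy_settings(n_points = 120)
  dec <- decompose(list(toy$frame), toy$topology, es)
  expect_equal(dec$ele[1, 2], 332.0636 * 0.5 * -0.5 / 4, tolerance = 1e-9)
  # distant, uncharged monomers decouple
  toy$topology$atoms$charge <- c(0, 0)
  toy$frame$coords <- rbind(c(0, 0, 0), c(60, 0, 0))
  dec0 <- decompose(list(toy$frame), toy$topology, es)
  expect_lt(max(abs(dec0$pairwise)), 1e-8)
})

test_that("neighbour profile isolates constructed separations", {
  dec <- structure(list(pairwise = matrix(0, 8, 8), n_monomers = 8),
                   class = "energy_decomposition")
  idx <- cbind(1:8, c(2:8, 1))
  dec$pairwise[idx] <- -2; dec$pairwise[idx[, 2:1]] <- -2
  prof <- neighbor_profile(dec)
  expect_equal(prof$mean_interaction[1], -2)
  expect_equal(prof$mean_interaction[-1], rep(0, 3))
  # exponentially decaying terms: cumulative reaches 95% at the closed-form
  # geometric-series depth
  n <- 20; lam <- 0.4
  m <- matrix(0, n, n)
  for (k in 1:(n / 2)) {
    v <- -exp(-lam * k)
    i1 <- cbind(1:n, ((1:n - 1 + k) %% n) + 1)
    m[i1] <- v; m[i1[, 2:1]] <- v
  }
  decg <- structure(list(pairwise = m, n_monomers = n),
                    class = "energy_decomposition")
  pg <- neighbor_profile(decg)
  expect_equal(pg$mean_interaction, -exp(-lam * (1:10)), tolerance = 1e-9)
  frac <- pg$cumulative / pg$cumulative[10]
  k95_closed <- which(cumsum(exp(-lam * (1:10)) * c(rep(2, 9), 1)) /
                        sum(exp(-lam * (1:10)) * c(rep(2, 9), 1)) >= 0.95)[1]
  expect_equal(which(frac >= 0.95)[1], k95_closed)
  # symmetric ring: profile independent of the monomer index
  for (k in 1:(n / 2)) {
    vals <- vapply(1:n, function(i) m[i, ((i - 1 + k) %% n) + 1], numeric(1))
    expect_equal(max(vals) - min(vals), 0)
  }
})

test_that("hydrogen-bond energy bookkeeping reproduces the printed protocol", {
  h1 <- hbond_energy(39, 48)
  expect_equal(h1$hbs_per_bta, 1.6)
  expect_equal(h1$dE_HBs, -2.6)
  h2 <- hbond_energy(56, 48)
  expect_equal(h2$hbs_per_bta, 2.3)
  expect_equal(h2$dE_HBs, -3.7)
  h3 <- hbond_energy(48, 48)
  expect_equal(h3$hbs_per_bta, 2.0)
  expect_equal(h3$dE_HBs, -3.2)
  h0 <- hbond_energy(0, 48)
  expect_equal(h0$hbs_per_bta, 0)
  expect_equal(h0$dE_HBs, 0)
  expect_error(energy_ratios(-39.5, h0), "denominator")
  expect_equal(energy_ratios(-39.5, h1)$sol_over_hbs, 15.2)
  expect_equal(energy_ratios(-38.9, h2)$sol_over_hbs, 10.5)
  expect_equal(energy_ratios(-40.3, h3)$sol_over_hbs, 12.6)
  expect_equal(energy_ratios(-2.6, h1)$sol_over_hbs, 1.0)
  expect_equal(energy_ratios(-10.8, h1, dE_int_sol = -10.8,
                             dE_ele = -5.2)$intsol_over_ele, 2.1)
})

test_that("histogram statistics match hand-computed moments", {
  x <- c(-1, 0, 1)
  s <- energy_histogram_stats(c(x, -x))
  expect_lt(abs(s$skewness), 1e-12)
  y <- c(1, 2, 3, 4, 100)
  sy <- energy_histogram_stats(y)
  m <- mean(y); m2 <- mean((y - m)^2); m3 <- mean((y - m)^3)
  hand <- (m3 / m2^1.5) * sqrt(5 * 4) / 3
  expect_equal(sy$skewness, hand, tolerance = 1e-12)
  expect_gt(sy$skewness, 0)
  expect_equal(sy$median, 3)
})
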