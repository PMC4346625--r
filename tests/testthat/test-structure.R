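test_that("intercore distances honour the periodic wrap and match brute force", {
  fb <- small_fiber(n = 6, n_frames = 3, sigma = 0.2, seed = 11)
  tr <- perturb_trajectory(fb$topology, fb$config)
  fr <- tr$frames[[2]]
  got <- intercore_distances(fr, fb$topology)
  # brute-force oracle over consecutive centroids with minimum image in z
  cen <- t(vapply(seq_len(6), function(i) {
    ids <- fb$topology$atoms$id[fb$topology$atoms$is_core &
                                  fb$topology$atoms$monomer == i]
    colMeans(fr$coords[ids, ])
  }, numeric(3)))
  oracle <- vapply(seq_len(6), function(i) {
    j <- i %% 6 + 1
    dv <- cen[j, ] - cen[i, ]
    dv[3] <- dv[3] - fr$box_z * round(dv[3] / fr$box_z)
    sqrt(sum(dv^2))
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-9)
})

test_that("two cores across the boundary both see the 3.4 A image", {
  topo <- small_fiber(n = 2, d = 3.4)$topology
  fr <- small_fiber(n = 2, d = 3.4)$frame
  expect_equal(intercore_distances(fr, topo), c(3.4, 3.4), tolerance = 1e-9)
})

test_that("g(r) of a noiseless ideal stack concentrates at the spacing", {
  fb <- small_fiber(n = 12, n_frames = 3, sigma = 0)
  tr <- perturb_trajectory(fb$topology, fb$config)
  g <- radial_distribution(tr, fb$topology, r_max = 8, bin_width = 0.1)
  pk <- first_peak(g)
  expect_equal(pk$r_peak, 3.45, tolerance = 0.051)  # bin centre containing 3.4
  nonzero <- g$r[g$g > 0]
  expect_true(all(abs(nonzero - 3.4) < 0.1 | abs(nonzero - 6.8) < 0.1))
})

test_that("g(r) of uniform random points in a periodic box is about 1", {
  withr::with_seed(42, {
    box <- 30
    pts_list <- lapply(1:12, function(i)
      cbind(runif(260, 0, box), runif(260, 0, box), runif(260, 0, box)))
  })
  # wrap x and y into the z-minimum-image convention by keeping r_max small
  # relative to the box and using the exact box density
  g <- fibremetrics:::gofr_from_points(pts_list, box, r_max = 6,
                                       bin_width = 0.5,
                                       density = 260 / box^3)
  # x/y are not wrapped: points near the lateral faces lose neighbours, so
  # allow a modest downward bias at the largest r
  expect_true(all(g$g[g$r > 1] > 0.6 & g$g[g$r > 1] < 1.3))
  expect_lt(abs(mean(g$g[g$r > 2 & g$r < 5]) - 1), 0.25)
})

test_that("small-frame g(r) bin counts equal exhaustive pair enumeration", {
  fb <- small_fiber(n = 5, n_frames = 2, sigma = 0.3, seed = 9)
  tr <- perturb_trajectory(fb$topology, fb$config)
  g <- radial_distribution(tr, fb$topology, r_max = 9, bin_width = 0.25,
                           density = 1, window_fraction = 1)
  # oracle: enumerate all pairs in both frames by hand
  counts <- numeric(length(g$r))
  for (fr in tr$frames) {
    cen <- t(vapply(seq_len(5), function(i) {
      ids <- fb$topology$atoms$id[fb$topology$atoms$is_core &
                                    fb$topology$atoms$monomer == i]
      colMeans(fr$coords[ids, ])
    }, numeric(3)))
    for (i in 1:4) for (j in (i + 1):5) {
      dv <- cen[j, ] - cen[i, ]
      dv[3] <- dv[3] - fr$box_z * round(dv[3] / fr$box_z)
      r <- sqrt(sum(dv^2))
      if (r <= 9) {
        b <- min(floor(r / 0.25) + 1, length(counts))
        counts[b] <- counts[b] + 1
      }
    }
  }
  shell <- 4 / 3 * pi * ((g$r + 0.125)^3 - (g$r - 0.125)^3)
  oracle <- (2 * counts / 2) / (5 * shell * 1)
  expect_equal(g$g, oracle, tolerance = 1e-9)
})

test_that("first_peak breaks ties toward smaller r and order_increase is arithmetic", {
  g <- structure(list(r = seq(0.05, 9.95, 0.1), g = rep(0, 100),
                      bin_width = 0.1), class = "gofr")
  g$g[which.min(abs(g$r - 3.45))] <- 5
  expect_equal(first_peak(g)$r_peak, 3.45)
  g2 <- g
  g2$g[which.min(abs(g2$r - 3.65))] <- 5  # equal maxima at 3.45 and 3.65
  expect_equal(first_peak(g2)$r_peak, 3.45)
  gref <- g; gref$g[35] <- 1
  gtest <- g; gtest$g[35] <- 1.52
  expect_equal(order_increase(gref, gtest), 52)
  expect_equal(order_increase(gref, gref), 0)
  ghalf <- g; ghalf$g[35] <- 0.5
  gone <- g; gone$g[35] <- 1
  expect_equal(order_increase(gone, ghalf), -50)
  expect_error(first_peak(g, c(20, 30)), "empty")
})

test_that("dihedral angles match an independent projection-based oracle", {
  # praxeolitic formulation: project out the central bond, then atan2
  oracle <- function(a, b, c, d) {
    b0 <- -(b - a); b1 <- (c - b); b1 <- b1 / sqrt(sum(b1^2)); b2 <- d - c
    v <- b0 - sum(b0 * b1) * b1
    w <- b2 - sum(b2 * b1) * b1
    x <- sum(v * w)
    y <- sum(c(b1[2] * v[3] - b1[3] * v[2],
               b1[3] * v[1] - b1[1] * v[3],
               b1[1] * v[2] - b1[2] * v[1]) * w)
    atan2(y, x) * 180 / pi
  }
  withr::with_seed(8, {
    for (i in 1:25) {
      p <- matrix(rnorm(12), 4, 3)
      expect_equal(dihedral_angle(p[1, ], p[2, ], p[3, ], p[4, ]),
                   oracle(p[1, ], p[2, ], p[3, ], p[4, ]), tolerance = 1e-9)
    }
  })
  # planar cis quadruplet -> 0
  expect_equal(dihedral_angle(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  # collinear triple flagged
  expect_true(is.na(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                                   c(3, 1, 0))))
})

test_that("helicity classification partitions the circle with stated tie-breaks", {
  expect_equal(classify_helicity(-140), "P")
  expect_equal(classify_helicity(30), "flipped")
  expect_equal(classify_helicity(-90), "P")   # boundary to P
  expect_equal(classify_helicity(0), "M")     # boundary to M
  expect_equal(classify_helicity(-89.999), "M")
  angs <- withr::with_seed(1, runif(500, -179.999, 180))
  cls <- classify_helicity(angs)
  expect_true(all(cls %in% c("P", "M", "flipped")))
  # constructed 76/19/5 mixture is recovered by counting
  mix <- c(rep(-140, 76), rep(-45, 19), rep(120, 5))
  tab <- table(classify_helicity(mix))
  expect_equal(as.numeric(100 * tab[c("P", "M", "flipped")] / 100),
               c(76, 19, 5))
})

test_that("helicity fractions sum to 100 on any trajectory", {
  fb <- small_fiber(n = 6, n_frames = 8, mix = c(0.6, 0.3, 0.1), seed = 13)
  tr <- perturb_trajectory(fb$topology, fb$config)
  hf <- helicity_fractions(tr, fb$topology)
  expect_equal(hf$fraction_P + hf$fraction_M + hf$fraction_flipped, 100,
               tolerance = 0.1)
})

test_that("flipped-dihedral percentages follow the printed arithmetic", {
  expect_equal(round(100 * 7 / 144), 5)
  fb <- small_fiber(n = 4, n_frames = 2, mix = c(0.5, 0.2, 0.3), seed = 21)
  tr <- perturb_trajectory(fb$topology, fb$config)
  cf <- count_flipped(tr$frames[[1]], fb$topology)
  ang <- amide_dihedrals(tr$frames[[1]], fb$topology)
  expect_equal(cf$count, sum(ang > 0))
  expect_equal(cf$percent, round(100 * sum(ang > 0) / 12))
  fb0 <- small_fiber(n = 4, n_frames = 2, mix = c(1, 0, 0))
  tr0 <- perturb_trajectory(fb0$topology, fb0$config)
  expect_equal(count_flipped(tr0, fb0$topology)$count, 0)
})

test_that("geometric hydrogen-bond detection matches a brute-force check", {
  fb <- small_fiber(n = 6)
  hb <- detect_hbonds(fb$frame, fb$topology)
  # ideal geometry: three bonds per interface, periodic -> 3n
  expect_equal(nrow(hb), 18)
  expect_true(all(hb$distance < 3.5))
  expect_true(all(hb$angle > 120))
  # pushing the acceptor 5 A away removes the bond
  fr2 <- fb$frame
  one_o <- fb$topology$acceptors$acceptor[1]
  fr2$coords[one_o, ] <- fr2$coords[one_o, ] + c(5, 5, 0)
  hb2 <- detect_hbonds(fr2, fb$topology)
  expect_equal(nrow(hb2), 17)
  # randomized frame: exhaustive geometric oracle
  fbr <- small_fiber(n = 4, n_frames = 2, sigma = 0.4, mix = c(0.6, 0.3, 0.1),
                     seed = 5)
  trr <- perturb_trajectory(fbr$topology, fbr$config)
  frr <- trr$frames[[1]]
  got <- detect_hbonds(frr, fbr$topology)
  oracle_n <- 0
  for (i in seq_len(nrow(fbr$topology$donors))) {
    for (j in seq_len(nrow(fbr$topology$acceptors))) {
      if (fbr$topology$donors$monomer[i] == fbr$topology$acceptors$monomer[j]) next
      dpos <- frr$coords[fbr$topology$donors$donor[i], ]
      hpos <- frr$coords[fbr$topology$donors$hydrogen[i], ]
      apos <- frr$coords[fbr$topology$acceptors$acceptor[j], ]
      dv <- apos - dpos
      dv[3] <- dv[3] - frr$box_z * round(dv[3] / frr$box_z)
      if (sqrt(sum(dv^2)) >= 3.5) next
      av <- apos - hpos
      av[3] <- av[3] - frr$box_z * round(av[3] / frr$box_z)
      hd <- dpos - hpos
      ang <- acos(sum(av * hd) / sqrt(sum(av^2) * sum(hd^2))) * 180 / pi
      if (ang > 120) oracle_n <- oracle_n + 1
    }
  }
  expect_equal(nrow(got), oracle_n)
})

test_that("persistence threshold is strict and monotone", {
  tb <- list(occupancy = c(1.0, 0.96, 0.94))
  expect_equal(persistent_hbonds(tb)$count, 2)
  expect_equal(persistent_hbonds(list(occupancy = c(0.95)))$count, 0)
  expect_equal(persistent_hbonds(list(occupancy = numeric(0)))$count, 0)
  # synthetic matrix with 39 high-occupancy bonds among low ones
  tb39 <- generate_hbond_occupancy(60, c(rep(0.995, 39), rep(0.4, 21)),
                                   n_frames = 2000, seed = 6)
  expect_equal(persistent_hbonds(tb39)$count, 39)
  # monotone non-increasing in threshold
  occ <- withr::with_seed(3, runif(50))
  counts <- vapply(seq(0, 1, 0.05), function(th)
    persistent_hbonds(list(occupancy = occ), th)$count, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("fibre dimensions and contraction follow their definitions", {
  fb <- small_fiber(n = 48)
  dims <- fiber_dimensions(fb$frame, fb$topology)
  expect_equal(round(dims$length_nm, 1), 16.3)
  fr <- fb$frame; fr$box_z <- 95
  expect_equal(fiber_dimensions(fr, fb$topology)$length_nm, 9.5)
  # all beads at one radius -> degenerate thickness envelope
  fr17 <- fb$frame
  beads <- fb$topology$atoms$is_bead
  th <- atan2(fr17$coords[beads, 2], fr17$coords[beads, 1])
  fr17$coords[beads, 1] <- 17 * cos(th)
  fr17$coords[beads, 2] <- 17 * sin(th)
  expect_equal(fiber_dimensions(fr17, fb$topology)$thickness_nm, c(3.4, 3.4))
  expect_equal(contraction(16.3, 9.5), 42)
  expect_equal(contraction(16.3, 7.1), 56)
  expect_equal(contraction(5, 5), 0)
  expect_warning(neg <- contraction(5, 6), "elongation")
  expect_lt(neg, 0)
  # contraction of a generated fold-factor trajectory is exact
  fbf <- small_fiber(n = 10, fold = 0.75, n_frames = 2)
  trf <- perturb_trajectory(fbf$topology, fbf$config)
  L0 <- 10 * 3.4 / 10
  expect_equal(contraction(L0, trf$frames[[1]]$box_z / 10, digits = 6), 25)
})

test_that("stable-domain detection recovers constructed runs", {
  e <- rep(0, 48)
  e[25:31] <- -2
  runs <- detect_stable_domains(e, min_run = 5)
  expect_equal(nrow(runs), 1)
  expect_equal(runs$start, 25)
  expect_equal(runs$end, 31)
  expect_equal(runs$length, 7)
  expect_equal(nrow(detect_stable_domains(rep(1, 20))), 0)
  expect_equal(nrow(detect_stable_domains(rep(c(-1, 1), 10), min_run = 5)), 0)
})
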