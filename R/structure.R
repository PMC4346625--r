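# Structural order analysis of fibre trajectories: intercore spacings and
# radial distribution functions, amide dihedral helicity, hydrogen bonds,
# fibre dimensions and stable-domain detection.

wrap_dz <- function(dz, box_z) dz - box_z * round(dz / box_z)

# Restrict a trajectory to its equilibrated trailing window (default: last
# 25% of frames, the analysis convention for relaxation runs).
equilibrated_frames <- function(trajectory, window_fraction = 0.25) {
  nf <- trajectory$n_frames
  keep <- max(1L, ceiling(window_fraction * nf))
  trajectory$frames[seq.int(nf - keep + 1L, nf)]
}

#' Consecutive intercore distances of a fibre frame
#'
#' Centroid-to-centroid distances between consecutive monomer cores,
#' including the wrap-around spacing through the periodic z boundary, so the
#' result has length `n_monomers`.
#'
#' @param frame a `fiber_frame`.
#' @param topology the matching `fiber_topology`.
#' @return numeric vector of distances in Angstrom.
#' @export
intercore_distances <- function(frame, topology) {
  assert_that(topology$n_monomers >= 2, "need at least 2 monomers")
  cen <- core_centroids(frame, topology)
  nxt <- c(2:nrow(cen), 1)
  dxy <- cen[nxt, 1:2, drop = FALSE] - cen[, 1:2, drop = FALSE]
  dz <- wrap_dz(cen[nxt, 3] - cen[, 3], frame$box_z)
  sqrt(rowSums(dxy^2) + dz^2)
}

gofr_from_points <- function(points_list, box_z, r_max, bin_width, density) {
  breaks <- seq(0, r_max + bin_width, by = bin_width)
  breaks <- breaks[breaks <= r_max + bin_width / 2]
  counts <- numeric(length(breaks) - 1)
  n_pts <- nrow(points_list[[1]])
  for (pts in points_list) {
    d2 <- as.matrix(stats::dist(pts[, 1:2, drop = FALSE]))^2
    dz <- outer(pts[, 3], pts[, 3], "-")
    dz <- wrap_dz(dz, box_z)
    dd <- sqrt(d2 + dz^2)
    dd <- dd[upper.tri(dd)]
    dd <- dd[dd <= r_max & dd > 0]
    bins <- pmin(floor(dd / bin_width) + 1L, length(counts))
    counts <- counts + tabulate(bins, nbins = length(counts))
  }
  centres <- (head(breaks, -1) + tail(breaks, -1)) / 2
  shell <- 4 / 3 * pi * (tail(breaks, -1)^3 - head(breaks, -1)^3)
  # 2 * pairs / n = per-particle neighbour count; divide by shell volume and
  # the reference density so an uncorrelated arrangement averages to 1
  g <- (2 * counts / length(points_list)) / (n_pts * shell * density)
  structure(list(r = centres, g = g, bin_width = bin_width),
            class = "gofr")
}

#' Radial distribution function of core centroids
#'
#' Histogram of all core-core centroid distances up to `r_max` (minimum-image
#' convention along the periodic z axis), averaged over the equilibrated
#' window of the trajectory and normalized by spherical-shell volume and a
#' reference core density so that an uncorrelated arrangement averages to 1.
#'
#' @param trajectory a `fiber_trajectory`.
#' @param topology the matching `fiber_topology`.
#' @param r_max histogram range, Angstrom.
#' @param bin_width bin width, Angstrom (default 0.1).
#' @param density reference number density (cores per cubic Angstrom). When
#'   `NULL`, uses `n_cores / (box_z * pi * r_env^2)` with `r_env` the maximal
#'   lateral core extent plus `r_max`. Peak-height comparisons between fibres
#'   must use the same convention.
#' @param window_fraction trailing fraction of frames analysed (default 0.25).
#' @return object of class `gofr` with fields `r`, `g`, `bin_width`.
#' @export
radial_distribution <- function(trajectory, topology, r_max = 10,
                                bin_width = 0.1, density = NULL,
                                window_fraction = 0.25) {
  assert_that(bin_width > 0, "bin_width must be > 0")
  assert_that(r_max > bin_width, "r_max must exceed bin_width")
  assert_that(topology$n_monomers >= 2, "need at least 2 cores")
  frames <- equilibrated_frames(trajectory, window_fraction)
  cents <- lapply(frames, core_centroids, topology = topology)
  box_z <- frames[[1]]$box_z
  if (is.null(density)) {
    r_env <- max(sqrt(rowSums(cents[[1]][, 1:2, drop = FALSE]^2))) + r_max
    density <- topology$n_monomers / (box_z * pi * r_env^2)
  }
  gofr_from_points(cents, box_z, r_max, bin_width, density)
}

#' Locate the first peak of a g(r)
#'
#' Maximum of g within a search window; ties are broken toward smaller r.
#'
#' @param g a `gofr`.
#' @param search_window length-2 numeric range of r, Angstrom.
#' @return list with `r_peak` and `height`.
#' @export
first_peak <- function(g, search_window = range(g$r)) {
  sel <- which(g$r >= search_window[1] & g$r <= search_window[2])
  assert_that(length(sel) > 0, "empty search window")
  k <- sel[which.max(g$g[sel])]  # which.max takes the first (smallest r) tie
  list(r_peak = g$r[k], height = g$g[k])
}

#' Relative change in stacking order between two fibres
#'
#' Percent change of the first-peak height of a test g(r) relative to a
#' reference g(r) sharing the same binning.
#'
#' @param g_ref,g_test `gofr` objects with identical bins.
#' @param search_window passed to [first_peak()].
#' @param digits rounding of the reported percentage.
#' @return percent change (positive = more ordered than the reference).
#' @export
order_increase <- function(g_ref, g_test, search_window = range(g_ref$r),
                           digits = 0) {
  assert_that(isTRUE(all.equal(g_ref$r, g_test$r)), "g(r) curves must share binning")
  h0 <- first_peak(g_ref, search_window)$height
  h1 <- first_peak(g_test, search_window)$height
  assert_that(h0 > 0, "zero reference peak height")
  percent_change(h0, h1, digits = digits)
}

#' Amide dihedral angles of a frame
#'
#' Signed dihedral (IUPAC convention, degrees in (-180, 180]) of every
#' CA1-CA2-C-O amide quadruplet; 3n angles for an n-monomer fibre. Collinear
#' quadruplets yield `NA`.
#'
#' @param frame a `fiber_frame`.
#' @param topology the matching `fiber_topology`.
#' @return numeric vector of 3n angles, ordered as `topology$quadruplets`.
#' @export
amide_dihedrals <- function(frame, topology) {
  q <- topology$quadruplets
  vapply(seq_len(nrow(q)), function(i) {
    dihedral_angle(frame$coords[q$a1[i], ], frame$coords[q$a2[i], ],
                   frame$coords[q$a3[i], ], frame$coords[q$a4[i], ])
  }, numeric(1))
}

#' Classify an amide dihedral by helicity
#'
#' P for angles in \[-180, -90\] (the initial P-helicity window), M for
#' (-90, 0\], flipped for positive angles (amides flipped over the aromatic
#' plane). The boundaries -90 and 0 are assigned to P and M respectively.
#'
#' @param angle dihedral angle(s) in degrees, (-180, 180].
#' @return character vector of "P", "M" or "flipped".
#' @export
classify_helicity <- function(angle) {
  out <- ifelse(angle > 0, "flipped", ifelse(angle > -90, "M", "P"))
  out[is.na(angle)] <- NA_character_
  out
}

#' Helicity fractions over a trajectory
#'
#' Time-and-dihedral-averaged percentages of P, M and flipped amide states
#' over the equilibrated window, plus the mean dihedral angle.
#'
#' @param trajectory a `fiber_trajectory`.
#' @param topology the matching `fiber_topology`.
#' @param window_fraction trailing fraction of frames analysed.
#' @param circular if `TRUE`, report the circular mean angle instead of the
#'   arithmetic mean.
#' @return object of class `helicity_stats`: `fraction_P`, `fraction_M`,
#'   `fraction_flipped` (percent), `mean_dihedral` (degrees).
#' @export
helicity_fractions <- function(trajectory, topology, window_fraction = 0.25,
                               circular = FALSE) {
  frames <- equilibrated_frames(trajectory, window_fraction)
  ang <- unlist(lapply(frames, amide_dihedrals, topology = topology))
  ang <- ang[!is.na(ang)]
  cls <- classify_helicity(ang)
  pc <- 100 * c(P = mean(cls == "P"), M = mean(cls == "M"),
                flipped = mean(cls == "flipped"))
  mean_dih <- if (circular) {
    atan2(mean(sin(ang * pi / 180)), mean(cos(ang * pi / 180))) * 180 / pi
  } else mean(ang)
  structure(list(fraction_P = unname(pc["P"]), fraction_M = unname(pc["M"]),
                 fraction_flipped = unname(pc["flipped"]),
                 mean_dihedral = mean_dih),
            class = "helicity_stats")
}

#' @export
print.helicity_stats <- function(x, ...) {
  cat(sprintf("Helicity: P %.1f%%  M %.1f%%  flipped %.1f%%  (mean dihedral %.1f deg)\n",
              x$fraction_P, x$fraction_M, x$fraction_flipped, x$mean_dihedral))
  invisible(x)
}

#' Count flipped amide dihedrals
#'
#' Number and percentage (of 3n dihedrals) with positive angles, i.e. amides
#' flipped over the plane of the aromatic core. For a trajectory the counts
#' are averaged over the equilibrated window.
#'
#' @param x a `fiber_frame` or `fiber_trajectory`.
#' @param topology the matching `fiber_topology`.
#' @param window_fraction trailing fraction of frames (trajectory input).
#' @return list with `count`, `percent` (rounded to integer) and
#'   `percent_raw`.
#' @export
count_flipped <- function(x, topology, window_fraction = 0.25) {
  ang <- if (inherits(x, "fiber_trajectory")) {
    frames <- equilibrated_frames(x, window_fraction)
    rowMeans(vapply(frames, function(fr)
      as.numeric(amide_dihedrals(fr, topology) > 0),
      numeric(3 * topology$n_monomers)))
  } else {
    as.numeric(amide_dihedrals(x, topology) > 0)
  }
  count <- sum(ang)
  pct <- 100 * count / (3 * topology$n_monomers)
  list(count = count, percent = round(pct), percent_raw = pct)
}

#' Geometric hydrogen-bond detection
#'
#' A candidate donor-acceptor pair (amide N-H of one monomer, carbonyl O of
#' another) is present when the donor-acceptor heavy-atom distance is below
#' `d_cut` and the D-H...A angle exceeds `angle_cut`. Intra-monomer pairs are
#' excluded; distances honour the periodic z wrap.
#'
#' @param frame a `fiber_frame`.
#' @param topology the matching `fiber_topology`.
#' @param d_cut donor-acceptor distance cutoff, Angstrom (default 3.5).
#' @param angle_cut D-H...A angle cutoff, degrees (default 120).
#' @return data.frame of present bonds: donor/acceptor monomer and arm,
#'   donor, hydrogen and acceptor atom ids, distance and angle.
#' @export
detect_hbonds <- function(frame, topology, d_cut = 3.5, angle_cut = 120) {
  don <- topology$donors
  acc <- topology$acceptors
  co <- frame$coords
  out <- vector("list", 0)
  for (i in seq_len(nrow(don))) {
    dpos <- co[don$donor[i], ]
    hpos <- co[don$hydrogen[i], ]
    keep <- acc$monomer != don$monomer[i]
    cand <- acc[keep, , drop = FALSE]
    apos <- co[cand$acceptor, , drop = FALSE]
    dvec <- sweep(apos, 2, dpos)
    dvec[, 3] <- wrap_dz(dvec[, 3], frame$box_z)
    dda <- sqrt(rowSums(dvec^2))
    sel <- which(dda < d_cut)
    for (j in sel) {
      avec <- apos[j, ] - hpos
      avec[3] <- wrap_dz(avec[3], frame$box_z)
      hd <- dpos - hpos
      ang <- acos(pmin(pmax(sum(avec * hd) / (vnorm(avec) * vnorm(hd)), -1), 1)) * 180 / pi
      if (ang > angle_cut) {
        out[[length(out) + 1L]] <- data.frame(
          donor_monomer = don$monomer[i], donor_arm = don$arm[i],
          acceptor_monomer = cand$monomer[j], acceptor_arm = cand$arm[j],
          donor = don$donor[i], hydrogen = don$hydrogen[i],
          acceptor = cand$acceptor[j], distance = dda[j], angle = ang)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(donor_monomer = integer(0), donor_arm = integer(0),
                      acceptor_monomer = integer(0), acceptor_arm = integer(0),
                      donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle = numeric(0)))
  }
  do.call(rbind, out)
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Runs [detect_hbonds()] on the equilibrated window and tabulates, per
#' candidate donor-acceptor pair ever observed, the fraction of frames in
#' which it is present.
#'
#' @inheritParams detect_hbonds
#' @param trajectory a `fiber_trajectory`.
#' @param window_fraction trailing fraction of frames analysed.
#' @return an `hbond_table` with `presence` matrix, `occupancy`, `bonds` and
#'   the geometric `cutoffs` used.
#' @export
hbond_occupancy <- function(trajectory, topology, d_cut = 3.5,
                            angle_cut = 120, window_fraction = 0.25) {
  frames <- equilibrated_frames(trajectory, window_fraction)
  per_frame <- lapply(frames, detect_hbonds, topology = topology,
                      d_cut = d_cut, angle_cut = angle_cut)
  keys <- unique(do.call(rbind, lapply(per_frame, function(x)
    x[, c("donor_monomer", "donor_arm", "acceptor_monomer", "acceptor_arm")])))
  if (is.null(keys) || nrow(keys) == 0) {
    return(structure(list(presence = matrix(FALSE, length(frames), 0),
                          occupancy = numeric(0), bonds = keys,
                          cutoffs = c(d_cut = d_cut, angle_cut = angle_cut)),
                     class = "hbond_table"))
  }
  key_id <- function(x) paste(x$donor_monomer, x$donor_arm,
                              x$acceptor_monomer, x$acceptor_arm)
  ids <- key_id(keys)
  pres <- t(vapply(per_frame, function(x) ids %in% key_id(x),
                   logical(nrow(keys))))
  if (nrow(keys) == 1) pres <- matrix(pres, ncol = 1)
  structure(list(presence = pres, occupancy = colMeans(pres), bonds = keys,
                 cutoffs = c(d_cut = d_cut, angle_cut = angle_cut)),
            class = "hbond_table")
}

#' Persistent hydrogen bonds
#'
#' Bonds whose occupancy strictly exceeds the threshold (default 0.95, the
#' "present more than 95% of the time" criterion).
#'
#' @param table an `hbond_table`.
#' @param threshold strict occupancy threshold.
#' @return list with `count` and `bonds` (indices of persistent bonds).
#' @export
persistent_hbonds <- function(table, threshold = 0.95) {
  occ <- table$occupancy
  if (length(occ) == 0) return(list(count = 0L, bonds = integer(0)))
  sel <- which(occ > threshold)
  list(count = length(sel), bonds = sel)
}

#' Fibre length and thickness
#'
#' Length is the periodic repeat along z (box_z, reported in nm); thickness
#' is twice the (5th, 95th) percentile of the side-chain bead radial distance
#' from the z axis, a percentile-envelope stand-in for the section-dependent
#' thickness of a folded fibre.
#'
#' @param frame a `fiber_frame`.
#' @param topology the matching `fiber_topology`.
#' @param probs percentile pair for the thickness envelope.
#' @return list with `length_nm` and `thickness_nm` (length-2 range).
#' @export
fiber_dimensions <- function(frame, topology, probs = c(0.05, 0.95)) {
  beads <- topology$atoms$id[topology$atoms$is_bead]
  rad <- sqrt(rowSums(frame$coords[beads, 1:2, drop = FALSE]^2))
  list(length_nm = frame$box_z / 10,
       thickness_nm = unname(2 * quantile(rad, probs) / 10))
}

#' Fibre contraction
#'
#' Percent reduction of the equilibrated length relative to the initial one:
#' `100 * (1 - Leq / L0)`. An equilibrated length exceeding the initial one
#' triggers a warning and returns a negative percentage.
#'
#' @param L0 initial length (nm), > 0.
#' @param Leq equilibrated length (nm).
#' @param digits rounding of the reported percentage (default 0).
#' @return percent contraction.
#' @export
contraction <- function(L0, Leq, digits = 0) {
  assert_that(L0 > 0, "initial length must be > 0")
  if (Leq > L0) warning("equilibrated length exceeds initial length (elongation)")
  round(100 * (1 - Leq / L0), digits)
}

#' Detect stable self-assembled domains
#'
#' Maximal runs of at least `min_run` consecutive monomers whose per-monomer
#' self-assembly energies lie strictly below the fibre mean. Runs do not wrap
#' the periodic boundary unless `wrap = TRUE`.
#'
#' @param energies per-monomer energies (kcal/mol).
#' @param min_run minimal run length (default 5).
#' @param wrap allow runs to wrap the periodic boundary.
#' @return data.frame with columns `start`, `end`, `length`.
#' @export
detect_stable_domains <- function(energies, min_run = 5, wrap = FALSE) {
  n <- length(energies)
  assert_that(n >= min_run, "fewer monomers than min_run")
  below <- energies < mean(energies)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_run
  runs <- data.frame(start = starts[keep], end = ends[keep],
                     length = r$lengths[keep])
  if (wrap && nrow(runs) >= 2 && below[1] && below[n] &&
      runs$start[1] == 1 && runs$end[nrow(runs)] == n) {
    merged <- data.frame(start = runs$start[nrow(runs)], end = runs$end[1] + n,
                         length = runs$length[1] + runs$length[nrow(runs)])
    runs <- rbind(runs[-c(1, nrow(runs)), ], merged[merged$length >= min_run, ])
  }
  rownames(runs) <- NULL
  runs
}
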