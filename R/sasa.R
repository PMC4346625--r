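# Shrake-Rupley solvent-accessible surface area with a deterministic
# Fibonacci-lattice point set (no random rotation), so results are exactly
# reproducible for a given point count.

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  golden <- pi * (1 + sqrt(5))
  theta <- golden * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the atomic van der Waals spheres: each atom's
#' accessible area is the fraction of a deterministic Fibonacci point set on
#' its probe-expanded sphere not buried inside any neighbour, times the
#' sphere area. Per-atom values sum to the total.
#'
#' @param coords n x 3 coordinate matrix, Angstrom.
#' @param radii per-atom van der Waals radii, Angstrom (> 0).
#' @param probe probe radius, Angstrom (default 1.4, water).
#' @param n_points points per sphere (default 960).
#' @return list with `total` and `per_atom` areas in square Angstrom.
#' @export
sasa <- function(coords, radii, probe = 1.4, n_points = 960) {
  coords <- rbind(coords)
  n <- nrow(coords)
  radii <- rep_len(radii, n)
  assert_that(all(radii > 0), "radii must be > 0")
  pts <- fibonacci_sphere(n_points)
  rr <- radii + probe
  per_atom <- numeric(n)
  if (n > 1) {
    dmat <- as.matrix(stats::dist(coords))
  }
  for (i in seq_len(n)) {
    sphere <- sweep(pts * rr[i], 2, coords[i, ], "+")
    acc <- rep(TRUE, n_points)
    nbrs <- if (n > 1) setdiff(which(dmat[, i] < rr + rr[i]), i) else integer(0)
    for (j in nbrs) {
      dj <- sweep(sphere, 2, coords[j, ])
      acc <- acc & (rowSums(dj^2) >= rr[j]^2)
      if (!any(acc)) break
    }
    per_atom[i] <- 4 * pi * rr[i]^2 * mean(acc)
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

# SASA of a fibre frame using the topology's van der Waals radii.
frame_sasa <- function(frame, topology, probe = 1.4, n_points = 960) {
  sasa(frame$coords, topology$atoms$r_vdw, probe = probe, n_points = n_points)
}
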