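#' @importFrom stats rnorm runif rbinom median sd quantile uniroot complete.cases setNames
#' @importFrom utils head tail read.csv write.csv read.table write.table modifyList
NULL

# Derive an independent 31-bit stream seed from a master seed and a purpose tag,
# so sub-generators are reproducible in isolation (one seed, one counter per tag).
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 2654435761 + h * 97 + 1) %% 2147483647)
}

with_stream <- function(seed, tag, expr) {
  withr::with_seed(derive_seed(seed, tag), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Vector helpers -------------------------------------------------------------

vnorm <- function(v) sqrt(sum(v * v))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle of four points
#'
#' Standard IUPAC-signed torsion angle defined by atoms A-B-C-D, computed with
#' the atan2 formulation. The angle is reported in degrees in (-180, 180].
#'
#' @param a,b,c,d numeric length-3 Cartesian coordinates (Angstrom).
#' @return angle in degrees; `NA` if any of the bonded triples is collinear.
#' @export
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10) return(NA_real_)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * (b2 / vnorm(b2)))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Place atom D given positions A, B, C, the C-D bond length, the B-C-D angle
# (degrees) and the A-B-C-D dihedral (degrees). Natural-extension reference
# frame construction.
place_dihedral_atom <- function(a, b, c, length, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  n <- cross3(ab, bc)
  assert_that(vnorm(n) > 1e-10, "collinear reference atoms in internal-coordinate placement")
  n <- n / vnorm(n)
  m <- cross3(n, bc)
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(dih),
          length * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Minimal rotation taking the z axis onto unit vector t (Rodrigues formula).
rotation_from_z <- function(t) {
  z <- c(0, 0, 1)
  v <- cross3(z, t)
  s <- vnorm(v)
  c_ <- sum(z * t)
  if (s < 1e-12) {
    return(if (c_ > 0) diag(3) else diag(c(1, -1, -1)))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

# Percent change of a scalar metric relative to a reference value.
#' Percent change between a reference and a test value
#'
#' @param ref reference value (nonzero).
#' @param test test value.
#' @param digits rounding applied to the reported percentage (default 0,
#'   i.e. integer percent as used in summary tables).
#' @return percentage `100 * (test - ref) / ref`, rounded.
#' @export
percent_change <- function(ref, test, digits = 0) {
  assert_that(is.finite(ref) && ref != 0, "zero or non-finite reference value")
  round(100 * (test - ref) / ref, digits)
}
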