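# Worm-like chain (flexible cylinder) scattering model and weighted
# least-squares fitting, plus a Debye-sum theoretical profile from bead
# coordinates.
#
# The chain factor follows the Pedersen-Schurtenberger parametrization for
# semi-flexible self-avoiding chains ("method 3" with excluded-volume
# corrections): a blend of an excluded-volume chain function and a local-rod
# correction below the crossover at q*b = 3.1, and the power-law + pi/(qL)
# rod asymptote above it, with the two power-law amplitudes fixed by value
# and slope continuity at the crossover. In the stiff regime (L_c <= 4 L_k)
# the chain is essentially fully extended and the exact orientation-averaged
# rigid-rod (Neugebauer) form factor is used.

#' Worm-like chain parameters
#'
#' @param L_c contour length, nm.
#' @param L_k Kuhn length (twice the persistence length), nm.
#' @param r_cs cross-section radius, nm.
#' @param dispersity Gaussian standard deviation on `r_cs`, nm (0 = none).
#' @param scale forward-scattering scale factor.
#' @param background flat background.
#' @return object of class `wlc_params`.
#' @export
wlc_params <- function(L_c, L_k, r_cs, dispersity = 0, scale = 1,
                       background = 0) {
  assert_that(L_c > 0 && L_k > 0 && r_cs > 0, "lengths must be > 0")
  assert_that(L_c >= L_k, "contour length must be >= Kuhn length")
  assert_that(dispersity >= 0, "dispersity must be >= 0")
  structure(list(L_c = L_c, L_k = L_k, r_cs = r_cs, dispersity = dispersity,
                 scale = scale, background = background),
            class = "wlc_params")
}

#' A 1D scattering profile
#'
#' @param q scattering vector, nm^-1, strictly increasing and positive.
#' @param I intensity.
#' @param sigma per-point uncertainty (>= 0).
#' @return object of class `saxs_profile` (a data.frame q, I, sigma).
#' @export
saxs_profile <- function(q, I, sigma = rep(0, length(q))) {
  assert_that(all(q > 0) && !is.unsorted(q, strictly = TRUE),
              "q must be strictly increasing and positive")
  assert_that(all(sigma >= 0), "sigma must be >= 0")
  structure(data.frame(q = q, I = I, sigma = sigma),
            class = c("saxs_profile", "data.frame"))
}

rgsquare_short <- function(L, b) {
  x <- b / L
  (L * b / 6) * (1 - 1.5 * x + 1.5 * x^2 - 0.75 * x^3 * (1 - exp(-2 / x)))
}

alpha_exv <- function(nb) (1 + (nb / 3.12)^2 + (nb / 8.67)^3)^(0.176 / 3)

rgsquare <- function(L, b) alpha_exv(L / b)^2 * rgsquare_short(L, b)

w_cross <- function(x) 0.5 * (1 + tanh((x - 1.523) / 0.1477))

s_debye <- function(u) ifelse(u < 1e-8, 1 - u / 3, 2 * (exp(-u) + u - 1) / u^2)

# Excluded-volume chain function with the monotonicity safeguard: the
# power-series branch is dropped wherever it would make S increase with q.
s_exv <- function(q, L, b) {
  rg <- sqrt(rgsquare(L, b))
  qr <- q * rg
  u <- qr^2
  miu <- 0.585
  series <- 1.22 * qr^(-1 / miu) + 0.4288 * qr^(-2 / miu) - 1.651 * qr^(-3 / miu)
  w <- w_cross(qr)
  base <- (1 - w) * s_debye(u)
  qr_d <- qr * 1.05
  series_d <- 1.22 * qr_d^(-1 / miu) + 0.4288 * qr_d^(-2 / miu) -
    1.651 * qr_d^(-3 / miu)
  increasing <- (w_cross(qr_d) * series_d - w * series) > 0
  base + ifelse(increasing & qr > 0, 0, w * series)
}

# Low-q flexible-chain function: excluded-volume chain plus the local
# stiffness (rod-like) correction term.
s_flex_low <- function(q, L, b) {
  nb <- L / b
  u <- q^2 * rgsquare(L, b)
  C <- if (nb > 10) 3.06 * nb^(-0.44) else 1
  corr <- C * (b / L) *
    (4 / 15 + 7 / (15 * u) - (11 / 15 + 7 / (15 * u)) * exp(-u))
  corr[u < 1e-8] <- 0
  s_exv(q, L, b) + corr
}

# Orientation-averaged rigid-rod (Neugebauer) form factor.
s_rod <- function(q, L) {
  x <- q * L
  ifelse(x < 1e-6, 1, 2 * pracma::Si(x) / x - 4 * sin(x / 2)^2 / x^2)
}

#' Worm-like chain scattering function
#'
#' Dimensionless chain factor S(q) with S(0) = 1. Flexible chains
#' (L_c > 4 L_k) use the excluded-volume chain function with local-rod
#' correction below the q L_k = 3.1 crossover and a
#' `a1 (qb)^-4.12 + a2 (qb)^-4.42 + pi/(q L_c)` asymptote above it, with a1
#' and a2 set by value and slope continuity at the crossover; stiff chains
#' (L_c <= 4 L_k) use the exact rigid-rod form factor.
#'
#' @param q scattering vector, nm^-1 (vector).
#' @param L_c contour length, nm.
#' @param L_k Kuhn length, nm.
#' @return S(q), dimensionless.
#' @export
wlc_chain_factor <- function(q, L_c, L_k) {
  assert_that(all(q >= 0) && L_c > 0 && L_k > 0, "arguments must be positive")
  if (L_c <= 4 * L_k) return(s_rod(q, L_c))
  qb <- q * L_k
  out <- numeric(length(q))
  low <- qb <= 3.1
  out[low] <- s_flex_low(q[low], L_c, L_k)
  if (any(!low)) {
    q0 <- 3.1 / L_k
    h <- 1e-4 * q0
    f0 <- s_flex_low(q0, L_c, L_k) - pi / (q0 * L_c)
    f1 <- (s_flex_low(q0 + h, L_c, L_k) - s_flex_low(q0 - h, L_c, L_k)) /
      (2 * h) + pi / (q0^2 * L_c)
    p1 <- 4.12; p2 <- 4.42
    # solve a1*x^-p1 + a2*x^-p2 = f0 ; derivative matching at x = 3.1
    x <- 3.1
    A <- matrix(c(x^(-p1), x^(-p2),
                  -p1 * x^(-p1 - 1) * L_k, -p2 * x^(-p2 - 1) * L_k),
                2, 2, byrow = TRUE)
    a <- solve(A, c(f0, f1))
    qbh <- qb[!low]
    out[!low] <- a[1] * qbh^(-p1) + a[2] * qbh^(-p2) + pi / (q[!low] * L_c)
  }
  out
}

#' Circular cross-section form factor
#'
#' `[2 J1(q r_cs) / (q r_cs)]^2`, optionally averaged over a Gaussian
#' distribution of the cross-section radius (15-point Gauss-Legendre
#' quadrature over +/- 4 standard deviations, truncated at positive radii).
#'
#' @param q scattering vector, nm^-1.
#' @param r_cs cross-section radius, nm.
#' @param dispersity Gaussian sd of `r_cs`, nm.
#' @return dimensionless factor, 1 at q = 0.
#' @export
cross_section_factor <- function(q, r_cs, dispersity = 0) {
  assert_that(r_cs > 0, "r_cs must be > 0")
  single <- function(r) {
    x <- q * r
    ifelse(x < 1e-8, 1, (2 * besselJ(x, 1) / x)^2)
  }
  if (dispersity <= 0) return(single(r_cs))
  lo <- max(r_cs - 4 * dispersity, 1e-6)
  hi <- r_cs + 4 * dispersity
  gl <- pracma::gaussLegendre(15, lo, hi)
  wts <- gl$w * stats::dnorm(gl$x, r_cs, dispersity)
  wts <- wts / sum(wts)
  out <- numeric(length(q))
  for (k in seq_along(gl$x)) out <- out + wts[k] * single(gl$x[k])
  out
}

#' Model scattering intensity of a worm-like chain
#'
#' `I(q) = scale * S_chain(q; L_c, L_k) * S_cs(q; r_cs, dispersity)
#'  + background`.
#'
#' @param q scattering vector, nm^-1.
#' @param params a [wlc_params()].
#' @return intensity vector.
#' @export
model_intensity <- function(q, params) {
  params$scale * wlc_chain_factor(q, params$L_c, params$L_k) *
    cross_section_factor(q, params$r_cs, params$dispersity) +
    params$background
}

#' Fit the worm-like chain model to a scattering profile
#'
#' Weighted least squares (Levenberg-Marquardt) minimizing
#' `sum(((I - model)/sigma)^2)`; points with zero sigma get unit weight.
#' Parameters can be fixed (e.g. `L_c` at its bound when the contour length
#' exceeds the accessible window) via the `fixed` argument; box bounds are
#' enforced and a parameter ending within `bound_tol` of a bound is flagged.
#'
#' @param profile a `saxs_profile` with >= 10 points.
#' @param initial a [wlc_params()] with the starting values.
#' @param lower,upper named numeric bounds for the free parameters among
#'   `L_k`, `r_cs`, `dispersity`, `scale`, `background`, `L_c`.
#' @param fixed character vector of parameter names to hold at their initial
#'   values (default fixes `dispersity`; include `"L_c"` to pin the contour
#'   length at a bound).
#' @param bound_tol relative tolerance for the bound-hit diagnostic.
#' @return object of class `wlc_fit`: `params` (fitted [wlc_params()]),
#'   `uncertainties`, `chi2_per_N`, `converged`, `at_bound`, `message`.
#' @export
fit_wlc <- function(profile, initial,
                    lower = c(L_k = 1, r_cs = 0.2, scale = 1e-6,
                              background = -1, L_c = 5, dispersity = 0),
                    upper = c(L_k = Inf, r_cs = Inf, scale = Inf,
                              background = Inf, L_c = Inf, dispersity = 1),
                    fixed = "dispersity", bound_tol = 1e-3) {
  assert_that(nrow(profile) >= 10, "need at least 10 points")
  free <- setdiff(c("L_c", "L_k", "r_cs", "dispersity", "scale", "background"),
                  fixed)
  # keep flexible-branch consistency: L_k may not exceed L_c / 4 during the fit
  if ("L_k" %in% free) {
    lk_cap <- (if ("L_c" %in% free) upper["L_c"] else initial$L_c) / 4
    upper["L_k"] <- min(upper["L_k"] %||% Inf, lk_cap, na.rm = TRUE)
  }
  # guard against near-zero uncertainties (e.g. at form-factor minima of a
  # noise-proportional synthetic sigma): cap any single point's weight at
  # 100x the median weight so a handful of minimum points cannot dominate
  sig <- profile$sigma
  if (any(sig > 0)) sig <- pmax(sig, stats::median(sig[sig > 0]) * 1e-2)
  wts <- ifelse(sig > 0, 1 / sig, 1)
  resid_fn <- function(p) {
    pars <- initial
    pars[free] <- as.list(p)
    (profile$I - model_intensity(profile$q, pars)) * wts
  }
  # multi-start over the cross-section radius: its Bessel minima create
  # local optima, so try a small factor grid around the initial value
  rcs_starts <- if ("r_cs" %in% free)
    initial$r_cs * c(1, 0.6, 0.8, 1.25, 1.6) else initial$r_cs
  fit <- NULL
  for (r0 in rcs_starts) {
    start <- unlist(initial[free])
    if ("r_cs" %in% free)
      start["r_cs"] <- min(max(r0, lower["r_cs"]), upper["r_cs"])
    cand <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn,
                         lower = unname(lower[free]),
                         upper = unname(upper[free]),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(cand) && (is.null(fit) || cand$deviance < fit$deviance))
      fit <- cand
  }
  n <- nrow(profile)
  if (is.null(fit)) {
    return(structure(list(params = initial, uncertainties = NULL,
                          chi2_per_N = NA_real_, converged = FALSE,
                          at_bound = character(0),
                          message = "all starts failed"),
                     class = "wlc_fit"))
  }
  pars <- initial
  pars[free] <- as.list(fit$par)
  chi2 <- sum(resid_fn(fit$par)^2) / n
  unc <- tryCatch({
    se <- summary(fit)$coefficients[, "Std. Error"]
    setNames(as.numeric(se), free)
  }, error = function(e) setNames(rep(NA_real_, length(free)), free))
  at_bound <- free[
    abs(fit$par - lower[free]) <= bound_tol * pmax(1, abs(fit$par)) |
      abs(fit$par - upper[free]) <= bound_tol * pmax(1, abs(fit$par))]
  if ("L_c" %in% fixed) at_bound <- union(at_bound, "L_c")
  converged <- fit$info %in% 1:4
  structure(list(params = pars, uncertainties = unc, chi2_per_N = chi2,
                 converged = converged, at_bound = at_bound,
                 ill_conditioned = any(!is.finite(unc)) ||
                   any(unc > 10 * abs(unlist(pars[free])), na.rm = TRUE),
                 message = fit$message),
            class = "wlc_fit")
}

#' @export
print.wlc_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("WLC fit: L_c %.1f  L_k %.2f  r_cs %.3f nm  scale %.3g  bkg %.3g\n",
              p$L_c, p$L_k, p$r_cs, p$scale, p$background))
  cat(sprintf("  chi2/N = %.4g; converged: %s%s\n", x$chi2_per_N, x$converged,
              if (length(x$at_bound)) paste0("; at bound: ",
                                             paste(x$at_bound, collapse = ", "))
              else ""))
  invisible(x)
}

#' Debye-sum theoretical scattering profile from bead coordinates
#'
#' Orientation-averaged intensity of a rigid bead assembly,
#' `I(q) = sum_ij f_i f_j sin(q r_ij)/(q r_ij)` (self terms `f_i^2`), used as
#' the theoretical-profile stand-in for all-atom scattering calculators.
#' Coordinates are in Angstrom and q in nm^-1; the conversion is internal.
#'
#' @param coords n x 3 bead coordinates, Angstrom.
#' @param form_factors per-bead scattering amplitudes (recycled; default 1).
#' @param q_grid q values, nm^-1.
#' @return a `saxs_profile` (sigma 0).
#' @export
debye_profile <- function(coords, form_factors = 1,
                          q_grid = seq(0.15, 4.47, length.out = 150)) {
  coords <- rbind(coords)
  n <- nrow(coords)
  assert_that(n >= 1, "need at least one bead")
  f <- rep_len(form_factors, n)
  I <- rep(sum(f^2), length(q_grid))
  if (n > 1) {
    d_nm <- as.matrix(stats::dist(coords)) / 10
    iu <- which(upper.tri(d_nm))
    dij <- d_nm[iu]
    ff <- outer(f, f)[iu]
    for (k in seq_along(q_grid)) {
      x <- q_grid[k] * dij
      I[k] <- I[k] + 2 * sum(ff * ifelse(x < 1e-10, 1, sin(x) / x))
    }
  }
  saxs_profile(q_grid, I, rep(0, length(q_grid)))
}

#' Read / write three-column scattering profiles
#'
#' Whitespace-delimited text with columns q (nm^-1), I and sigma.
#'
#' @param path file path.
#' @param profile a `saxs_profile`.
#' @return `read_saxs` returns a `saxs_profile`; `write_saxs` its path,
#'   invisibly.
#' @export
read_saxs <- function(path) {
  d <- read.table(path, header = FALSE, col.names = c("q", "I", "sigma"))
  saxs_profile(d$q, d$I, d$sigma)
}

#' @rdname read_saxs
#' @export
write_saxs <- function(profile, path) {
  write.table(format(profile[, c("q", "I", "sigma")], digits = 10),
              path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
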