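# FRET-ratio computation and biexponential exchange-kinetics fitting.
#
# The mixing assay: two fibre populations carrying a donor (Cy3) or acceptor
# (Cy5) dye are mixed, and monomer exchange brings dye pairs into the same
# fibre, raising the FRET ratio until a plateau. The ratio rises as
# F(t) = F_plateau - A_fast exp(-t/tau_fast) - A_slow exp(-t/tau_slow).

#' A FRET time trace
#'
#' @param time strictly increasing times (s or h).
#' @param I_donor donor-channel intensity (570 nm), >= 0.
#' @param I_acceptor acceptor-channel intensity (670 nm), >= 0.
#' @return object of class `fret_trace` (a data.frame).
#' @export
fret_trace <- function(time, I_donor, I_acceptor) {
  assert_that(!is.unsorted(time, strictly = TRUE), "time must be strictly increasing")
  assert_that(all(I_donor >= 0) && all(I_acceptor >= 0),
              "intensities must be >= 0")
  structure(data.frame(time = time, I_donor = I_donor,
                       I_acceptor = I_acceptor),
            class = c("fret_trace", "data.frame"))
}

#' FRET ratio of a trace
#'
#' `ratio = I_acceptor / (I_donor + I_acceptor)`, in \[0, 1\]; points with
#' zero total intensity are masked (`NA`). The alternative acceptor/donor
#' definition is available via `method = "acceptor_over_donor"`.
#'
#' @param trace a `fret_trace`.
#' @param method ratio definition.
#' @return numeric vector of ratios.
#' @export
fret_ratio <- function(trace, method = c("acceptor_over_total",
                                         "acceptor_over_donor")) {
  method <- match.arg(method)
  tot <- trace$I_donor + trace$I_acceptor
  out <- switch(method,
                acceptor_over_total = trace$I_acceptor / tot,
                acceptor_over_donor = trace$I_acceptor / trace$I_donor)
  out[tot <= 0] <- NA_real_
  out
}

biexp_value <- function(t, p) {
  p$F_plateau - p$A_fast * exp(-t / p$tau_fast) -
    p$A_slow * exp(-t / p$tau_slow)
}

new_biexp_fit <- function(F_plateau, A_fast, tau_fast, A_slow, tau_slow,
                          residual_sd = NA_real_, uncertainties = NULL,
                          converged = TRUE, degenerate = FALSE) {
  if (tau_fast > tau_slow) {  # canonical ordering
    tmp <- c(A_fast, tau_fast)
    A_fast <- A_slow; tau_fast <- tau_slow
    A_slow <- tmp[1]; tau_slow <- tmp[2]
  }
  structure(list(F_plateau = F_plateau, A_fast = A_fast, tau_fast = tau_fast,
                 A_slow = A_slow, tau_slow = tau_slow,
                 residual_sd = residual_sd, uncertainties = uncertainties,
                 converged = converged, degenerate = degenerate),
            class = "biexp_fit")
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf("Biexponential fit: plateau %.4f; fast A %.4f tau %.4g; slow A %.4f tau %.4g\n",
              x$F_plateau, x$A_fast, x$tau_fast, x$A_slow, x$tau_slow))
  if (x$degenerate) cat("  (degenerate: effectively monoexponential)\n")
  invisible(x)
}

#' Fit a rising biexponential to a FRET-ratio series
#'
#' Least-squares fit of
#' `F(t) = F_plateau - A_fast exp(-t/tau_fast) - A_slow exp(-t/tau_slow)`
#' with multi-start initialization over log-spaced timescale pairs,
#' Levenberg-Marquardt refinement, canonical `tau_fast <= tau_slow`
#' ordering, and graceful collapse to a monoexponential when one amplitude
#' degenerates.
#'
#' @param time time points (strictly increasing).
#' @param ratio FRET-ratio values (NAs dropped).
#' @param n_starts number of timescale starting pairs.
#' @return object of class `biexp_fit`; `converged = FALSE` flags failure of
#'   every start.
#' @export
fit_biexponential <- function(time, ratio, n_starts = 6) {
  keep <- is.finite(ratio)
  t <- time[keep]; y <- ratio[keep]
  assert_that(length(t) >= 8, "need at least 8 points")
  if (sd(y) < 1e-12) {
    return(new_biexp_fit(mean(y), 0, diff(range(t)) / 10, 0, diff(range(t)),
                         residual_sd = 0, degenerate = TRUE))
  }
  t_span <- max(t) - min(t)
  amp0 <- max(y) - min(y)
  tau_grid <- exp(seq(log(max(t_span / 200, min(diff(t)))), log(2 * t_span),
                      length.out = n_starts))
  starts <- list()
  for (i in seq_len(n_starts - 1)) {
    starts[[length(starts) + 1L]] <- c(Fp = max(y), A1 = amp0 / 2,
                                       lt1 = log(tau_grid[i]),
                                       A2 = amp0 / 2,
                                       lt2 = log(tau_grid[i + 1]))
  }
  starts[[length(starts) + 1L]] <- c(Fp = max(y), A1 = amp0 * 0.6,
                                     lt1 = log(t_span / 50),
                                     A2 = amp0 * 0.4, lt2 = log(t_span / 2))
  resid_fn <- function(p) {
    y - (p["Fp"] - p["A1"] * exp(-t / exp(p["lt1"])) -
           p["A2"] * exp(-t / exp(p["lt2"])))
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         lower = c(-Inf, 0, log(t_span) - 12, 0, log(t_span) - 12),
                         upper = c(Inf, Inf, log(t_span) + 6, Inf, log(t_span) + 6),
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(new_biexp_fit(mean(y), NA, NA, NA, NA, converged = FALSE))
  }
  p <- best$par
  unc <- tryCatch({
    se <- summary(best)$coefficients[, "Std. Error"]
    # delta method for tau = exp(lt)
    c(F_plateau = unname(se["Fp"]), A_fast = unname(se["A1"]),
      tau_fast = unname(se["lt1"] * exp(p["lt1"])),
      A_slow = unname(se["A2"]), tau_slow = unname(se["lt2"] * exp(p["lt2"])))
  }, error = function(e) NULL)
  res_sd <- sqrt(best$deviance / max(1, length(t) - 5))
  amp_tol <- 1e-3 * max(amp0, 1e-12)
  degen <- p["A1"] < amp_tol || p["A2"] < amp_tol ||
    abs(p["lt1"] - p["lt2"]) < 0.05
  if (abs(p["lt1"] - p["lt2"]) < 0.05) {
    # indistinguishable timescales: collapse to a monoexponential, pooling
    # the amplitude on the slow component
    p["A2"] <- p["A1"] + p["A2"]
    p["A1"] <- 0
    p["lt2"] <- (p["lt1"] + p["lt2"]) / 2
    p["lt1"] <- p["lt2"] - 1e-6
  }
  fit <- new_biexp_fit(unname(p["Fp"]), unname(p["A1"]), unname(exp(p["lt1"])),
                       unname(p["A2"]), unname(exp(p["lt2"])),
                       residual_sd = res_sd, uncertainties = unc,
                       converged = best$info %in% 1:4, degenerate = degen)
  if (!is.null(unc)) {
    # re-align uncertainty names with the canonical ordering
    if (fit$tau_fast != unname(exp(p["lt1"]))) {
      unc[c("A_fast", "tau_fast", "A_slow", "tau_slow")] <-
        unc[c("A_slow", "tau_slow", "A_fast", "tau_fast")]
      fit$uncertainties <- unc
    }
  }
  fit
}

#' Time to reach a fraction of the plateau
#'
#' Smallest t with `F(t) >= F(0) + fraction * (F_plateau - F(0))`, solved
#' numerically on the fitted curve. For a monoexponential at fraction 0.95
#' this is `-log(0.05) * tau` (about 3 tau). `fraction >= 1` returns `Inf`.
#'
#' @param fit a `biexp_fit`.
#' @param fraction plateau fraction in (0, 1).
#' @return time (same unit as the fitted timescales).
#' @export
plateau_time <- function(fit, fraction = 0.95) {
  amp <- fit$A_fast + fit$A_slow
  if (amp <= 0) return(0)
  if (fraction >= 1) {
    warning("fraction >= 1: plateau reached only asymptotically")
    return(Inf)
  }
  target_deficit <- (1 - fraction) * amp
  g <- function(t) fit$A_fast * exp(-t / fit$tau_fast) +
    fit$A_slow * exp(-t / fit$tau_slow) - target_deficit
  upper <- 1
  while (g(upper) > 0) upper <- upper * 2
  uniroot(g, c(0, upper), tol = 1e-10)$root
}

#' Compare exchange kinetics between two systems
#'
#' Fold changes `tau_b / tau_a` of the fast and slow timescales, with
#' first-order (delta-method) propagated uncertainties when both fits carry
#' parameter uncertainties.
#'
#' @param fit_a,fit_b `biexp_fit` objects (a = reference).
#' @return data.frame with columns `component`, `fold_change`, `se`.
#' @export
compare_kinetics <- function(fit_a, fit_b) {
  comp <- function(name) {
    ta <- fit_a[[name]]; tb <- fit_b[[name]]
    fc <- tb / ta
    se <- NA_real_
    ua <- fit_a$uncertainties; ub <- fit_b$uncertainties
    if (!is.null(ua) && !is.null(ub) &&
        is.finite(ua[name]) && is.finite(ub[name])) {
      se <- abs(fc) * sqrt((ua[[name]] / ta)^2 + (ub[[name]] / tb)^2)
    }
    data.frame(component = sub("tau_", "", name), fold_change = fc, se = se)
  }
  rbind(comp("tau_fast"), comp("tau_slow"))
}

#' Read / write FRET traces as CSV
#'
#' CSV with header `time_s, I_donor, I_acceptor`.
#'
#' @param path file path.
#' @param trace a `fret_trace`.
#' @return `read_fret` returns a `fret_trace`; `write_fret` its path,
#'   invisibly.
#' @export
read_fret <- function(path) {
  d <- read.csv(path)
  fret_trace(d$time_s, d$I_donor, d$I_acceptor)
}

#' @rdname read_fret
#' @export
write_fret <- function(trace, path) {
  d <- data.frame(time_s = trace$time, I_donor = trace$I_donor,
                  I_acceptor = trace$I_acceptor)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
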