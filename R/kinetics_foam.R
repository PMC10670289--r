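# Michaelis-Menten kinetics fitting, catalytic efficiency, relative-activity
# normalization, and egg-white foaming indices.

#' Kinetic assay dataset
#'
#' Substrate-concentration / initial-rate pairs from a chromogenic lipase
#' assay (p-nitrophenyl esters of chain length C6-C18).
#'
#' @param substrate_conc Substrate concentrations, mM (>= 4 values, strictly
#'   positive, not all equal).
#' @param rate Initial rates, uM min^-1 (same length).
#' @param substrate_label Optional chain-length tag, e.g. `"C6"`.
#' @param temperature Optional assay temperature, degrees C.
#' @return A `kinetics_dataset`.
#' @export
kinetics_dataset <- function(substrate_conc, rate, substrate_label = NA_character_,
                             temperature = NA_real_) {
  if (length(substrate_conc) != length(rate))
    stop("substrate_conc and rate must have equal length")
  if (length(substrate_conc) < 4L)
    stop("need at least 4 concentration-rate pairs")
  if (any(substrate_conc <= 0)) stop("concentrations must be strictly positive")
  if (length(unique(substrate_conc)) < 2L)
    stop("concentrations must not all be equal")
  structure(list(substrate_conc = as.numeric(substrate_conc),
                 rate = as.numeric(rate),
                 substrate_label = substrate_label,
                 temperature = temperature),
            class = "kinetics_dataset")
}

#' Read a kinetics CSV (columns substrate_mM, rate_uM_min)
#' @param path CSV path.
#' @param ... Passed to [kinetics_dataset()].
#' @return A `kinetics_dataset`.
#' @export
read_kinetics_csv <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- read.csv(path)
  if (!all(c("substrate_mM", "rate_uM_min") %in% names(d)))
    stop("expected columns substrate_mM and rate_uM_min")
  kinetics_dataset(d$substrate_mM, d$rate_uM_min, ...)
}

#' Fit the Michaelis-Menten equation by damped nonlinear least squares
#'
#' Minimizes `sum (v - Vmax*S/(Km+S))^2` with Levenberg-Marquardt iteration
#' on log-parameterized `(Vmax, Km)` (so the parameters cannot go negative).
#' Starting values: `Vmax0 = max(v)`, `Km0 = S` at the observation whose rate
#' is nearest `Vmax0/2`. Asymptotic standard errors come from the Jacobian at
#' the optimum (delta method from the log scale). Non-convergence and
#' boundary collapse (`Km` driven to ~0, as happens when only saturating
#' concentrations were measured) are flagged, not thrown.
#'
#' @param data A `kinetics_dataset`.
#' @param tol Relative SSE convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 1000).
#' @param enzyme_conc_uM Optional total enzyme concentration, uM; when given,
#'   `kcat = Vmax / enzyme_conc_uM / 60` (s^-1) and the catalytic efficiency
#'   `kcat/Km` (M^-1 s^-1) are filled in.
#' @return A `kinetics_fit`: list with `Vmax` (uM min^-1), `Km` (mM), their
#'   `se`, `kcat` (s^-1, or NA), `efficiency` (M^-1 s^-1, or NA), `sse`,
#'   `converged`, and the input data.
#' @export
fit_michaelis_menten <- function(data, tol = 1e-10, max_iter = 1000,
                                 enzyme_conc_uM = NULL) {
  stopifnot(inherits(data, "kinetics_dataset"))
  S <- data$substrate_conc; v <- data$rate
  Vmax0 <- max(v)
  Km0 <- S[which.min(abs(v - Vmax0 / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ exp(lV) * S / (exp(lK) + S),
                      start = list(lV = log(Vmax0), lK = log(max(Km0, 1e-8))),
                      control = minpack.lm::nls.lm.control(
                        maxiter = min(max_iter, 1024), ftol = tol, ptol = 1e-12)),
    error = function(e) e)
  out <- list(Vmax = NA_real_, Km = NA_real_, se = c(Vmax = NA_real_, Km = NA_real_),
              kcat = NA_real_, efficiency = NA_real_, sse = NA_real_,
              converged = FALSE, data = data)
  class(out) <- "kinetics_fit"
  if (inherits(fit, "error")) {
    out$message <- conditionMessage(fit)
    return(out)
  }
  est <- exp(coef(fit))
  out$Vmax <- unname(est["lV"]); out$Km <- unname(est["lK"])
  out$sse <- sum(residuals(fit)^2)
  vc <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 2, 2))
  # delta method: SE(theta) = theta * SE(log theta)
  out$se <- c(Vmax = out$Vmax * sqrt(vc[1, 1]), Km = out$Km * sqrt(vc[2, 2]))
  out$converged <- isTRUE(fit$convInfo$isConv) && out$Km > 1e-6 &&
    all(is.finite(out$se))
  if (!is.null(enzyme_conc_uM)) {
    stopifnot(enzyme_conc_uM > 0)
    out$kcat <- out$Vmax / enzyme_conc_uM / 60
    out$efficiency <- catalytic_efficiency(out$kcat, out$Km)
  }
  out
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit: Vmax = %.4g +/- %.2g uM/min, Km = %.4g +/- %.2g mM\n",
              x$Vmax, x$se["Vmax"], x$Km, x$se["Km"]))
  if (is.finite(x$kcat))
    cat(sprintf("  kcat = %.4g /s, kcat/Km = %.4g /M/s\n", x$kcat, x$efficiency))
  if (!x$converged) cat("  (fit did not converge cleanly)\n")
  invisible(x)
}

#' Catalytic efficiency kcat/Km
#'
#' Returns `kcat / Km` on the M^-1 s^-1 scale: `kcat` in s^-1 divided by the
#' Michaelis constant converted from mM to M. This is the scale on which
#' published per-substrate efficiency columns are numerically consistent
#' (e.g. kcat 0.61 s^-1 with Km 9.26 mM gives 65.87).
#'
#' @param kcat Turnover number, s^-1 (> 0).
#' @param Km Michaelis constant, mM (> 0).
#' @return Efficiency in M^-1 s^-1.
#' @export
catalytic_efficiency <- function(kcat, Km) {
  if (any(kcat <= 0) || any(Km <= 0))
    stop("kcat and Km must be strictly positive")
  kcat / (Km * 1e-3)
}

#' Relative activity normalization
#'
#' Expresses raw activities as percentages of a reference: the maximum
#' (default, as in optimum-temperature / optimum-pH profiles) or the value at
#' a given index (control-referenced mode, as when an ion-treated sample is
#' reported against an untreated control).
#'
#' @param x Raw activity values.
#' @param reference `"max"` or an integer index into `x`.
#' @return Percentages, `100 * x / reference`.
#' @export
relative_activity <- function(x, reference = "max") {
  ref <- if (identical(reference, "max")) max(x)
  else {
    i <- as.integer(reference)
    if (is.na(i) || i < 1L || i > length(x)) stop("reference index out of range")
    x[i]
  }
  if (!is.finite(ref) || ref <= 0) stop("reference activity must be positive")
  100 * x / ref
}

#' Foam measurement record
#'
#' @param m0 Mass of the unwhipped sample solution, g.
#' @param m1 Mass of the same volume of whipped sample, g.
#' @param mp Mass of liquid precipitated after standing, g.
#' @param mi Initial mass of the foam, g.
#' @return A `foam_measurement`.
#' @export
foam_measurement <- function(m0, m1, mp, mi) {
  if (any(c(m0, m1, mp, mi) <= 0)) stop("all masses must be positive")
  if (m1 > m0) warning("m1 > m0: whipped sample denser than unwhipped")
  structure(list(m0 = m0, m1 = m1, mp = mp, mi = mi),
            class = "foam_measurement")
}

#' Foaming ability
#'
#' `FA (%) = (m0 - m1) / m1 * 100`: the whipping expansion index, where `m0`
#' is the unwhipped sample mass and `m1` the mass of an equal volume of foam.
#'
#' @param m0 Unwhipped mass (g), or a [foam_measurement()].
#' @param m1 Whipped same-volume mass (g); ignored when `m0` is a record.
#' @return FA in percent.
#' @export
foaming_ability <- function(m0, m1 = NULL) {
  if (inherits(m0, "foam_measurement")) { m1 <- m0$m1; m0 <- m0$m0 }
  if (any(m1 <= 0)) stop("m1 must be positive")
  (m0 - m1) / m1 * 100
}

#' Foaming stability (liquid precipitation rate)
#'
#' `FS (%) = mp / mi * 100`, the fraction of the initial foam mass `mi` that
#' drains as liquid `mp` after standing. More precipitation means a less
#' stable foam, so larger values indicate worse stability.
#'
#' @param mp Precipitated liquid mass (g), or a [foam_measurement()].
#' @param mi Initial foam mass (g); ignored when `mp` is a record.
#' @return FS in percent.
#' @export
foaming_stability <- function(mp, mi = NULL) {
  if (inherits(mp, "foam_measurement")) { mi <- mp$mi; mp <- mp$mp }
  if (any(mi <= 0)) stop("mi must be positive")
  if (any(mp > mi)) stop("measurement inconsistency: mp exceeds mi")
  mp / mi * 100
}
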