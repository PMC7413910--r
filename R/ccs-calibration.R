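#' Monoisotopic mass of the N2 drift gas in Da.
#' @noRd
N2_MASS <- 28.00615

#' Reduced-mass factor of the single-field drift relation
#'
#' The Mason-Schamp low-field mobility carries a reduced-mass term; for the
#' linear single-field calibration it enters as
#' gamma = sqrt(m_ion * m_gas / (m_ion + m_gas)) / z, with m_ion = mz * z.
#'
#' @param mz Ion m/z in Da (positive).
#' @param charge Integer charge state (>= 1, default 1).
#' @param drift_gas_mass Drift-gas monoisotopic mass in Da (default N2).
#' @return gamma in sqrt(Da).
#' @examples
#' reduced_mass_gamma(481.3430) # 5.1445
#' @export
reduced_mass_gamma <- function(mz, charge = 1L, drift_gas_mass = N2_MASS) {
  if (any(mz <= 0) || any(charge < 1) || drift_gas_mass <= 0) {
    stop("mz and drift_gas_mass must be positive and charge >= 1")
  }
  m_ion <- mz * charge
  sqrt(m_ion * drift_gas_mass / (m_ion + drift_gas_mass)) / charge
}

#' Fit a single-field drift-time/CCS calibration
#'
#' Least-squares fit of the linear single-field relation
#' t_D = beta * gamma(m/z) * Omega + t_fix over reference ions with known
#' drift time and CCS. The instrument constants beta and t_fix are estimated
#' from the data; residuals are reported in CCS units (residual drift time
#' divided by beta * gamma) for interpretability.
#'
#' @param mz Reference m/z values (Da).
#' @param drift_ms Measured drift times (ms).
#' @param ccs_A2 Known collision cross sections (Angstrom^2).
#' @param charge Charge state shared by the reference ions (default 1).
#' @param drift_gas_mass Drift-gas mass in Da (default N2).
#' @return List of class \code{single_field_cal} with \code{beta} (ms per
#'   Angstrom^2 sqrt(Da)), \code{t_fix} (ms), \code{drift_gas_mass},
#'   \code{charge}, \code{rms_residual} (Angstrom^2) and \code{n_points}.
#' @examples
#' lib <- load_reference_library()
#' cal <- fit_single_field(lib$mz_precursor, lib$drift_ms, lib$ccs_A2)
#' @export
fit_single_field <- function(mz, drift_ms, ccs_A2, charge = 1L,
                             drift_gas_mass = N2_MASS) {
  n <- length(mz)
  if (length(drift_ms) != n || length(ccs_A2) != n) {
    stop("mz, drift_ms, ccs_A2 must have equal length")
  }
  if (n < 2L) stop("at least 2 calibration points are required")
  gamma <- reduced_mass_gamma(mz, charge, drift_gas_mass)
  x <- gamma * ccs_A2
  if (diff(range(x)) < 1e-12) {
    stop("rank-deficient calibration design: all gamma*Omega equal")
  }
  fit <- stats::lm(drift_ms ~ x)
  beta <- unname(stats::coef(fit)[2])
  t_fix <- unname(stats::coef(fit)[1])
  if (beta <= 0) stop("fitted slope is non-positive; calibration rejected")
  res_ccs <- stats::resid(fit) / (beta * gamma)
  structure(
    list(
      beta = beta,
      t_fix = t_fix,
      drift_gas_mass = drift_gas_mass,
      charge = as.integer(charge),
      rms_residual = sqrt(mean(res_ccs^2)),
      n_points = n
    ),
    class = "single_field_cal"
  )
}

#' @export
print.single_field_cal <- function(x, ...) {
  cat(sprintf(
    paste0("Single-field CCS calibration (n = %d, drift gas %.5f Da)\n",
           "  beta  = %.6f ms / (A2 sqrt(Da))\n",
           "  t_fix = %.4f ms\n",
           "  RMS residual = %.4f A2\n"),
    x$n_points, x$drift_gas_mass, x$beta, x$t_fix, x$rms_residual
  ))
  invisible(x)
}

#' Convert a drift time to a collision cross section
#'
#' Inverse of the fitted single-field relation:
#' Omega = (t_D - t_fix) / (beta * gamma(m/z)).
#'
#' @param drift_ms Drift time(s) in ms; must exceed the calibration intercept.
#' @param mz Ion m/z in Da.
#' @param cal A \code{single_field_cal} from \code{\link{fit_single_field}}.
#' @return CCS in Angstrom^2.
#' @export
ccs_from_drift <- function(drift_ms, mz, cal) {
  stopifnot(inherits(cal, "single_field_cal"))
  if (any(drift_ms <= cal$t_fix)) {
    stop("drift time must exceed the calibration intercept t_fix")
  }
  gamma <- reduced_mass_gamma(mz, cal$charge, cal$drift_gas_mass)
  (drift_ms - cal$t_fix) / (cal$beta * gamma)
}

#' Convert a collision cross section to a drift time
#'
#' Forward single-field relation: t_D = beta * gamma(m/z) * Omega + t_fix.
#'
#' @param ccs_A2 CCS in Angstrom^2 (positive).
#' @inheritParams ccs_from_drift
#' @return Drift time in ms.
#' @export
drift_from_ccs <- function(ccs_A2, mz, cal) {
  stopifnot(inherits(cal, "single_field_cal"))
  if (any(ccs_A2 <= 0)) stop("CCS must be positive")
  gamma <- reduced_mass_gamma(mz, cal$charge, cal$drift_gas_mass)
  cal$beta * gamma * ccs_A2 + cal$t_fix
}

#' Serialize a single-field calibration to a key-value text file
#'
#' @param cal A \code{single_field_cal}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "single_field_cal"))
  lines <- c(
    sprintf("beta\t%.12g", cal$beta),
    sprintf("t_fix\t%.12g", cal$t_fix),
    sprintf("drift_gas_mass\t%.12g", cal$drift_gas_mass),
    sprintf("charge\t%d", cal$charge),
    sprintf("rms_residual\t%.12g", cal$rms_residual),
    sprintf("n_points\t%d", cal$n_points)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a single-field calibration written by \code{\link{write_calibration}}
#'
#' @param path Input path.
#' @return A \code{single_field_cal}.
#' @export
read_calibration <- function(path) {
  kv <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("key", "value"))
  get <- function(k) {
    i <- match(k, kv$key)
    if (is.na(i)) stop("calibration file lacks key '", k, "'")
    as.numeric(kv$value[i])
  }
  structure(
    list(
      beta = get("beta"),
      t_fix = get("t_fix"),
      drift_gas_mass = get("drift_gas_mass"),
      charge = as.integer(get("charge")),
      rms_residual = get("rms_residual"),
      n_points = as.integer(get("n_points"))
    ),
    class = "single_field_cal"
  )
}

#' Default single-field calibration fitted from the packaged library
#'
#' Convenience wrapper: fits \code{\link{fit_single_field}} to the 52 packaged
#' (m/z, drift time, CCS) triples. Used as the default drift-synthesis
#' calibration by the data generator.
#'
#' @return A \code{single_field_cal}.
#' @export
library_calibration <- function() {
  lib <- load_reference_library()
  fit_single_field(lib$mz_precursor, lib$drift_ms, lib$ccs_A2)
}
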