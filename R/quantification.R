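#' Fit an external calibration curve for targeted quantification
#'
#' Weighted least-squares line through (concentration, response) pairs with
#' 1/x weighting by default, the conventional choice for decade-spanning
#' LC-MS calibrations. Per-level accuracy is the back-calculated
#' concentration divided by the nominal one; levels outside the accepted
#' 0.75-1.25 band are flagged. Flagged top levels (detector saturation) are
#' dropped iteratively and the curve refitted, so the ULOQ is the highest
#' level that back-calculates within the band. The LOD and LLOQ are taken
#' from per-level signal-to-noise ratios when supplied (s/n > 3 and s/n > 9
#' respectively); otherwise the LLOQ defaults to the lowest accepted level.
#'
#' @param levels Nominal concentrations in nM (>= 2, not all equal).
#' @param responses Instrument responses (areas or area ratios to an
#'   internal standard), one per level.
#' @param snr Optional per-level signal-to-noise ratios.
#' @param weighting "1/x" (default), "none" or "1/x^2".
#' @param analyte Optional analyte name carried into the result.
#' @param accuracy_band Accepted back-calculated/nominal band (default
#'   c(0.75, 1.25)).
#' @return List of class \code{cal_curve}: slope, intercept, r2, per-level
#'   accuracy, flagged levels, lod, lloq, uloq, and the retained levels.
#' @export
fit_calibration <- function(levels, responses, snr = NULL,
                            weighting = c("1/x", "none", "1/x^2"),
                            analyte = NA_character_,
                            accuracy_band = c(0.75, 1.25)) {
  weighting <- match.arg(weighting)
  n <- length(levels)
  if (length(responses) != n) stop("levels and responses differ in length")
  if (n < 2L) stop("at least 2 calibration levels are required")
  if (diff(range(levels)) < 1e-12) stop("all calibration levels are equal")
  ord <- order(levels)
  levels <- levels[ord]
  responses <- responses[ord]
  if (!is.null(snr)) snr <- snr[ord]

  wts <- switch(weighting,
    "none" = rep(1, n),
    "1/x" = 1 / levels,
    "1/x^2" = 1 / levels^2
  )
  fit_line <- function(lv, rs, w) {
    fit <- stats::lm(rs ~ lv, weights = w)
    res <- stats::resid(fit)
    ybar <- stats::weighted.mean(rs, w)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = 1 - sum(w * res^2) / sum(w * (rs - ybar)^2))
  }

  # a band breach anywhere signals top-level saturation distorting the
  # curve: drop the highest level and refit until all retained levels
  # back-calculate within the band
  retained <- rep(TRUE, n)
  repeat {
    f <- fit_line(levels[retained], responses[retained], wts[retained])
    back <- (responses - f$intercept) / f$slope
    accuracy <- back / levels
    ok <- accuracy >= accuracy_band[1] - 1e-9 &
      accuracy <= accuracy_band[2] + 1e-9
    if (all(ok[retained]) || sum(retained) <= 2L) break
    retained[max(which(retained))] <- FALSE
  }
  if (f$slope <= 0) stop("calibration slope is non-positive; curve rejected")

  lod <- lloq <- NA_real_
  if (!is.null(snr)) {
    lims <- estimate_lod_lloq(levels, snr)
    lod <- lims$lod
    lloq <- lims$lloq
  }
  if (is.na(lloq)) lloq <- min(levels[retained & ok])
  uloq <- max(levels[retained & ok])

  structure(
    list(analyte = analyte, levels = levels, responses = responses,
         snr = snr, weighting = weighting, slope = f$slope,
         intercept = f$intercept, r2 = f$r2, accuracy = accuracy,
         flagged = !ok, retained = retained,
         minimal_design = n == 2L,
         lod = lod, lloq = lloq, uloq = uloq),
    class = "cal_curve"
  )
}

#' @export
print.cal_curve <- function(x, ...) {
  cat(sprintf(
    paste0("Calibration curve%s: response = %.4g * c + %.4g (weighting %s)\n",
           "  R2 = %.4f over %d/%d levels; LOD %s, LLOQ %s, ULOQ %s nM\n"),
    if (is.na(x$analyte)) "" else paste0(" for ", x$analyte),
    x$slope, x$intercept, x$weighting, x$r2, sum(x$retained),
    length(x$levels), format(x$lod), format(x$lloq), format(x$uloq)
  ))
  invisible(x)
}

#' Determine LOD and LLOQ from per-level signal-to-noise ratios
#'
#' LOD is the lowest concentration with s/n > 3, LLOQ the lowest with
#' s/n > 9 (strict inequalities). In the default nearest-level mode the
#' reported limits are measured levels; with \code{interpolate = TRUE}, the
#' concentration at which s/n crosses the criterion is estimated by
#' log-linear interpolation of s/n against concentration between the
#' bracketing levels. LLOQ >= LOD is enforced. When no level meets a
#' criterion the corresponding limit is NA (above the top level).
#'
#' @param levels Ascending concentrations in nM.
#' @param snr Positive per-level signal-to-noise ratios.
#' @param interpolate Log-linear interpolation between levels (default
#'   FALSE).
#' @return List with \code{lod} and \code{lloq} in nM (NA when undefined).
#' @export
estimate_lod_lloq <- function(levels, snr, interpolate = FALSE) {
  if (length(levels) != length(snr)) stop("levels and snr differ in length")
  if (any(snr <= 0)) stop("s/n values must be positive")
  if (is.unsorted(levels, strictly = TRUE)) {
    stop("levels must be strictly ascending")
  }
  crossing <- function(threshold) {
    idx <- which(snr > threshold)
    if (length(idx) == 0L) return(NA_real_)
    i <- min(idx)
    if (!interpolate || i == 1L || snr[i - 1L] > threshold) {
      return(levels[i])
    }
    # log-linear: solve log(snr) linear in log(c) between levels i-1 and i
    lx <- log(levels[(i - 1L):i])
    ly <- log(snr[(i - 1L):i])
    exp(lx[1] + (log(threshold) - ly[1]) * diff(lx) / diff(ly))
  }
  lod <- crossing(3)
  lloq <- crossing(9)
  if (!is.na(lod) && !is.na(lloq) && lloq < lod) lloq <- lod
  list(lod = lod, lloq = lloq)
}

#' Quantify responses against a fitted calibration curve
#'
#' c = (response - intercept) / slope, optionally on internal-standard
#' normalized responses (response / is_response * is_nominal). Results are
#' floored at zero and flagged when outside [LLOQ, ULOQ].
#'
#' @param responses Instrument responses.
#' @param curve A \code{cal_curve} from \code{\link{fit_calibration}};
#'   its response unit must match (raw area vs area ratio).
#' @param is_response Optional internal-standard responses (same length or
#'   length 1); when given, \code{responses / is_response} is quantified.
#' @param is_nominal Optional IS nominal amount multiplier applied to the
#'   ratio (default 1).
#' @return Data.frame with \code{response}, \code{conc_nM}, \code{flag}
#'   ("ok", "below_lloq", "above_uloq", "below_range").
#' @export
quantify <- function(responses, curve, is_response = NULL, is_nominal = 1) {
  stopifnot(inherits(curve, "cal_curve"))
  if (curve$slope <= 0) stop("calibration slope must be positive")
  r <- responses
  if (!is.null(is_response)) {
    if (any(is_response <= 0)) stop("internal-standard responses must be > 0")
    r <- responses / is_response * is_nominal
  }
  conc <- (r - curve$intercept) / curve$slope
  flag <- rep("ok", length(conc))
  eps <- 1e-9 * pmax(1, abs(conc))
  flag[!is.na(curve$lloq) & conc < curve$lloq - eps] <- "below_lloq"
  flag[!is.na(curve$uloq) & conc > curve$uloq + eps] <- "above_uloq"
  below <- conc < 0
  conc[below] <- 0
  flag[below] <- "below_range"
  data.frame(response = r, conc_nM = conc, flag = flag,
             stringsAsFactors = FALSE)
}

#' Normalize a concentration to pmol per million cells
#'
#' amount [pmol] = c [nM] x extract volume [mL] (1 nM = 1 pmol/mL); the
#' result is expressed per 10^6 cells.
#'
#' @param conc_nM Concentration in the extract, nM.
#' @param extract_volume_mL Extract volume in mL (> 0).
#' @param cell_count Number of cells (> 0).
#' @return pmol per 10^6 cells.
#' @examples
#' per_cell_normalize(100, 0.1, 1e6) # 10
#' @export
per_cell_normalize <- function(conc_nM, extract_volume_mL, cell_count) {
  if (extract_volume_mL <= 0) stop("extract volume must be positive")
  if (cell_count <= 0) stop("cell count must be positive")
  conc_nM * extract_volume_mL / (cell_count / 1e6)
}
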