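#' Pair light (AMPP) and heavy (2H5-AMPP) features in a mixed run
#'
#' In a mixed dual-channel run every derivatized acid appears twice, spaced
#' by the exact five-deuterium shift of 5.03138 Da. Pairing is greedy and
#' one-to-one: candidate pairs are features whose m/z difference is within
#' \code{mz_tol} of the shift, co-eluting within \code{rt_tol} and with
#' drift times within \code{drift_tol_rel} (relative; the heavy derivative's
#' mobility shift is negligible). Candidates are ranked by ascending
#' |observed - expected| mass error and assigned deterministically, each
#' feature at most once.
#'
#' @param set A mixed-run \code{\link{feature_set}}.
#' @param delta_mz Expected heavy-light spacing in Da (default
#'   \code{heavy_light_shift()}, 5.03138).
#' @param mz_tol Pairing m/z tolerance in Da (default 0.01).
#' @param rt_tol Co-elution tolerance in min (default 0.1; both channels are
#'   in the same run, so tighter than the cross-sample rule).
#' @param drift_tol_rel Relative drift-time tolerance (default 0.005).
#' @return Data.frame of class \code{isotope_pairs}: one row per pair with
#'   \code{light_id}, \code{heavy_id}, \code{mz_light}, \code{mz_heavy},
#'   \code{delta_mz_obs}, \code{rt_min}, \code{raw_ratio} (heavy/light
#'   intensity). Unpaired feature ids are attached as the
#'   \code{unpaired} attribute.
#' @export
pair_light_heavy <- function(set, delta_mz = heavy_light_shift(),
                             mz_tol = 0.01, rt_tol = 0.1,
                             drift_tol_rel = 0.005) {
  stopifnot(inherits(set, "feature_set"))
  if (mz_tol <= 0 || rt_tol <= 0 || drift_tol_rel <= 0) {
    stop("pairing tolerances must be positive")
  }
  f <- set$features
  n <- nrow(f)
  cands <- list()
  for (i in seq_len(n)) {
    dmz <- f$mz - f$mz[i] - delta_mz
    hits <- which(abs(dmz) <= mz_tol &
                    abs(f$rt_min - f$rt_min[i]) <= rt_tol &
                    abs(f$drift_ms - f$drift_ms[i]) <=
                      drift_tol_rel * f$drift_ms[i])
    hits <- setdiff(hits, i)
    for (j in hits) {
      cands[[length(cands) + 1L]] <- data.frame(
        light = i, heavy = j, err = abs(dmz[j]), stringsAsFactors = FALSE)
    }
  }
  rows <- list()
  if (length(cands) > 0L) {
    cands <- do.call(rbind, cands)
    cands <- cands[order(cands$err, f$feature_id[cands$light],
                         f$feature_id[cands$heavy]), , drop = FALSE]
    used <- logical(n)
    for (k in seq_len(nrow(cands))) {
      i <- cands$light[k]
      j <- cands$heavy[k]
      if (used[i] || used[j]) next
      used[i] <- used[j] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        light_id = f$feature_id[i], heavy_id = f$feature_id[j],
        mz_light = f$mz[i], mz_heavy = f$mz[j],
        delta_mz_obs = f$mz[j] - f$mz[i], rt_min = f$rt_min[i],
        intensity_light = f$intensity[i], intensity_heavy = f$intensity[j],
        raw_ratio = f$intensity[j] / f$intensity[i],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(light_id = character(0), heavy_id = character(0),
               mz_light = numeric(0), mz_heavy = numeric(0),
               delta_mz_obs = numeric(0), rt_min = numeric(0),
               intensity_light = numeric(0), intensity_heavy = numeric(0),
               raw_ratio = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  paired <- c(out$light_id, out$heavy_id)
  structure(out, class = c("isotope_pairs", "data.frame"),
            unpaired = setdiff(f$feature_id, paired))
}

#' Internal-standard corrected heavy/light ratios
#'
#' Raw heavy/light ratios confound the biological ratio with the relative
#' derivatization yield and detection response of the two channels. Dividing
#' every raw ratio by the raw ratio of an internal-standard pair spiked at
#' equal amounts into both channels (2H4-9-HODE) cancels any global
#' heavy-channel gain exactly; the IS pair's own corrected ratio is 1 by
#' construction. Orientation: heavy/light corresponds to treated/control
#' when the control is derivatized with AMPP and the treated sample with
#' 2H5-AMPP.
#'
#' @param pairs An \code{isotope_pairs} data.frame from
#'   \code{\link{pair_light_heavy}}.
#' @param is_light_id The light feature_id of the internal-standard pair.
#' @return The pairs data.frame with added columns \code{corrected_ratio}
#'   and \code{is_internal_standard}; pairs with zero light intensity carry
#'   NA with the \code{flag} column set to "undefined".
#' @export
relative_ratio <- function(pairs, is_light_id) {
  stopifnot(inherits(pairs, "isotope_pairs"))
  k <- match(is_light_id, pairs$light_id)
  if (is.na(k)) stop("internal-standard pair '", is_light_id,
                     "' not found among the pairs")
  is_ratio <- pairs$raw_ratio[k]
  if (!is.finite(is_ratio) || is_ratio <= 0) {
    stop("internal-standard pair has non-positive or undefined raw ratio")
  }
  out <- pairs
  out$corrected_ratio <- out$raw_ratio / is_ratio
  out$is_internal_standard <- seq_len(nrow(out)) == k
  out$flag <- ifelse(is.finite(out$corrected_ratio) & out$corrected_ratio > 0,
                     "ok", "undefined")
  out$corrected_ratio[out$flag == "undefined"] <- NA_real_
  out
}
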