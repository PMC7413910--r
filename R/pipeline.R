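#' Stage-count logger shared by the pipeline runners
#' @noRd
log_stage <- function(log, stage, n_in, n_out) {
  entry <- data.frame(stage = stage, n_input = n_in, n_retained = n_out,
                      n_removed = n_in - n_out, stringsAsFactors = FALSE)
  message(sprintf("[%s] %s: %d -> %d (removed %d)",
                  format(Sys.time(), "%H:%M:%S"), stage, n_in, n_out,
                  n_in - n_out))
  rbind(log, entry)
}

#' Run the non-targeted consensus workflow end to end
#'
#' Pre-filter -> diagnostic-fragment filter -> cross-sample consensus
#' matching -> optional library annotation, with per-stage feature counts
#' logged and returned. Retained plus removed counts per stage always equal
#' the stage input count.
#'
#' @param sets List of \code{\link{feature_set}}s (>= 2), or paths to
#'   feature tables (then \code{spectra_paths} must give the matching MGF
#'   files).
#' @param params A \code{\link{match_params}}.
#' @param anchor Anchor sample id (default: first set).
#' @param library Optional \code{oxylipin_library} for annotation.
#' @param prefilter Apply the vendor-style pre-filter first? Default TRUE.
#' @param spectra_paths MGF paths parallel to \code{sets} when paths are
#'   given.
#' @param channel Channel label used when reading from paths.
#' @param ... Passed to \code{\link{prefilter_features}}.
#' @return List with \code{consensus} (a \code{consensus_set}),
#'   \code{report} (from \code{\link{consensus_report}}) and
#'   \code{stage_counts} (data.frame, summed over samples).
#' @export
run_nontargeted <- function(sets, params = match_params(), anchor = NULL,
                            library = NULL, prefilter = TRUE,
                            spectra_paths = NULL, channel = "light", ...) {
  if (is.character(sets)) {
    paths <- sets
    sets <- lapply(seq_along(paths), function(i) {
      read_feature_table(paths[i], spectra_path = spectra_paths[i],
                         channel = channel)
    })
  }
  if (length(sets) < 2L) {
    stop("matching stage requires at least 2 samples")
  }
  log <- data.frame(stage = character(0), n_input = integer(0),
                    n_retained = integer(0), n_removed = integer(0))
  n0 <- sum(vapply(sets, function(s) nrow(s$features), integer(1)))
  if (prefilter) {
    sets <- lapply(sets, prefilter_features, ...)
    n1 <- sum(vapply(sets, function(s) nrow(s$features), integer(1)))
    log <- log_stage(log, "prefilter", n0, n1)
  } else {
    n1 <- n0
  }
  sets <- lapply(sets, ampp_fragment_filter,
                 tol = params$fragment_tol, mode = params$diagnostic_mode)
  n2 <- sum(vapply(sets, function(s) nrow(s$features), integer(1)))
  log <- log_stage(log, "ampp_fragment_filter", n1, n2)
  consensus <- match_across_samples(sets, params, anchor)
  n3 <- length(unique(consensus$consensus_id))
  log <- log_stage(log, "consensus_matching", n2, n3)
  report <- consensus_report(consensus, library)
  list(consensus = consensus, report = report, stage_counts = log)
}

#' Run targeted quantification for a panel of analytes
#'
#' Fits one calibration curve per analyte from a long-format calibration
#' table, then quantifies sample responses against it, with optional
#' internal-standard normalization and per-cell normalization. Analytes
#' whose calibration is missing are flagged and skipped; the run continues.
#'
#' @param calibration_data Data.frame with columns \code{analyte},
#'   \code{level_nM}, \code{response} and optionally \code{snr},
#'   \code{is_response}.
#' @param sample_data Optional data.frame with columns \code{analyte},
#'   \code{sample_id}, \code{response} and optionally \code{is_response}.
#' @param weighting Calibration weighting (see
#'   \code{\link{fit_calibration}}).
#' @param extract_volume_mL,cell_count Optional per-cell normalization
#'   parameters applied to all samples.
#' @return List with \code{curves} (named list of \code{cal_curve}),
#'   \code{curve_summary} (per-analyte limits table) and \code{results}
#'   (per-sample concentrations with flags; NULL when no samples given).
#' @export
run_targeted <- function(calibration_data, sample_data = NULL,
                         weighting = "1/x", extract_volume_mL = NULL,
                         cell_count = NULL) {
  needed <- c("analyte", "level_nM", "response")
  missing <- setdiff(needed, names(calibration_data))
  if (length(missing) > 0L) {
    stop("calibration data lack column(s): ", paste(missing, collapse = ", "))
  }
  analytes <- unique(calibration_data$analyte)
  curves <- list()
  for (a in analytes) {
    d <- calibration_data[calibration_data$analyte == a, ]
    resp <- d$response
    if ("is_response" %in% names(d) && !all(is.na(d$is_response))) {
      resp <- d$response / d$is_response
    }
    curves[[a]] <- fit_calibration(
      d$level_nM, resp, snr = if ("snr" %in% names(d)) d$snr else NULL,
      weighting = weighting, analyte = a)
  }
  curve_summary <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(analyte = cv$analyte, slope = cv$slope,
               intercept = cv$intercept, r2 = cv$r2, lod_nM = cv$lod,
               lloq_nM = cv$lloq, uloq_nM = cv$uloq,
               stringsAsFactors = FALSE)
  }))
  rownames(curve_summary) <- NULL

  results <- NULL
  if (!is.null(sample_data) && nrow(sample_data) > 0L) {
    rows <- list()
    for (i in seq_len(nrow(sample_data))) {
      r <- sample_data[i, ]
      if (!r$analyte %in% names(curves)) {
        rows[[i]] <- data.frame(sample_id = r$sample_id,
                                analyte = r$analyte, response = r$response,
                                conc_nM = NA_real_, flag = "no_calibration",
                                stringsAsFactors = FALSE)
        next
      }
      isr <- if ("is_response" %in% names(r)) r$is_response else NULL
      if (!is.null(isr) && is.na(isr)) isr <- NULL
      q <- quantify(r$response, curves[[r$analyte]], is_response = isr)
      rows[[i]] <- data.frame(sample_id = r$sample_id, analyte = r$analyte,
                              response = r$response, conc_nM = q$conc_nM,
                              flag = q$flag, stringsAsFactors = FALSE)
    }
    results <- do.call(rbind, rows)
    if (!is.null(extract_volume_mL) && !is.null(cell_count)) {
      results$pmol_per_1e6_cells <- per_cell_normalize(
        results$conc_nM, extract_volume_mL, cell_count)
    }
    rownames(results) <- NULL
  }
  list(curves = curves, curve_summary = curve_summary, results = results)
}

#' Run light/heavy relative quantification on a mixed run
#'
#' Pairs features across the five-deuterium shift, corrects the raw
#' heavy/light ratios with the internal-standard pair, and states the ratio
#' orientation. Fails with an explicit message when the internal-standard
#' pair is not found.
#'
#' @param set A mixed-run \code{\link{feature_set}}.
#' @param is_light_id Light feature_id of the internal-standard pair.
#' @param ... Pairing tolerances passed to \code{\link{pair_light_heavy}}.
#' @return List with \code{pairs} (corrected ratio table) and
#'   \code{orientation} (a statement of what the ratio means).
#' @export
run_relative <- function(set, is_light_id, ...) {
  pairs <- pair_light_heavy(set, ...)
  if (!is_light_id %in% pairs$light_id) {
    stop("internal-standard pair with light feature '", is_light_id,
         "' was not found in the mixed run; cannot correct ratios")
  }
  pairs <- relative_ratio(pairs, is_light_id)
  list(
    pairs = pairs,
    orientation = paste("corrected_ratio is heavy/light =",
                        "treated/control (control derivatized with AMPP,",
                        "treated with 2H5-AMPP)")
  )
}
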