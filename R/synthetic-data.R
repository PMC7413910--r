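#' Exact truncated normal draws (zero-mean), vectorized; sd 0 gives zeros.
#' @noRd
rtrunc_norm <- function(n, sd, bound) {
  if (sd <= 0) return(rep(0, n))
  if (all(!is.finite(bound))) return(stats::rnorm(n, 0, sd))
  plo <- stats::pnorm(-bound, sd = sd)
  phi <- stats::pnorm(bound, sd = sd)
  stats::qnorm(stats::runif(n, plo, phi), sd = sd)
}

#' Draw a per-feature measurement error as a shared (analyte-level) offset
#' plus a bounded per-sample deviation. The shared component emulates a
#' systematic calibration offset reproduced across runs; only the bounded
#' within-run scatter separates replicates, which keeps planted ground truth
#' unambiguous while the total error magnitude matches the configured SD.
#' @noRd
split_error_sds <- function(total_sd, bound) {
  within <- min(total_sd, bound / 2.5)
  shared <- sqrt(max(total_sd^2 - within^2, 0))
  list(within = within, shared = shared)
}

#' Configuration for the synthetic feature-set generator
#'
#' Defaults emulate vendor feature exports of derivatized-oxylipin IM-MS
#' runs: singly charged [M+] features with ppm-scale m/z error, small RT and
#' drift jitter, spectra carrying the diagnostic AMPP fragment pair plus a
#' quantifier fragment and Poisson-count background peaks, and decoy
#' (non-acid) features without diagnostic ions. Measurement error is drawn
#' as an analyte-level shared offset plus a per-sample deviation bounded at
#' half the corresponding consensus-matching tolerance, so replicate
#' features always satisfy the matching criteria while the total error SD
#' equals the configured value.
#'
#' @param analytes Data.frame of planted analytes with columns \code{name},
#'   \code{acid_formula} (or \code{mz} directly), \code{rt_min},
#'   \code{ccs_A2}, \code{intensity_scale} and optionally
#'   \code{fragment_mz}. Library records can be converted with
#'   \code{\link{library_analytes}}; ad-hoc panels with
#'   \code{\link{synthetic_analyte_panel}}.
#' @param n_samples Number of replicate samples (default 3).
#' @param seed Integer seed fixing the full output stream.
#' @param n_decoys Decoy features per sample (default 500).
#' @param mz_error_ppm Total m/z error SD in ppm (default 5).
#' @param rt_jitter_sd Total RT error SD in min (default 0.05).
#' @param drift_jitter_sd Total drift error SD in ms (default 0.05).
#' @param fragment_jitter_sd Fragment m/z jitter SD in Da (default 0.02).
#' @param background_mean Poisson mean of analyte background fragment peaks,
#'   drawn once per analyte and shared across samples (default 15).
#' @param unique_background_mean Poisson mean of per-sample contaminant
#'   peaks unique to a run (default 0).
#' @param intensity_sdlog Log-normal SD of feature intensities (default
#'   0.25).
#' @param channel Derivatization channel of the simulated runs.
#' @param calibration \code{single_field_cal} used to synthesize drift
#'   times; default: the calibration fitted from the packaged library.
#' @param match_tols Tolerances (fragment Da, ccs, rt, precursor ppm) whose
#'   halves bound the per-sample jitter; defaults mirror
#'   \code{\link{match_params}}.
#' @return List of class \code{synth_config}.
#' @export
synth_config <- function(analytes, n_samples = 3L, seed = 1L,
                         n_decoys = 500L, mz_error_ppm = 5,
                         rt_jitter_sd = 0.05, drift_jitter_sd = 0.05,
                         fragment_jitter_sd = 0.02, background_mean = 15,
                         unique_background_mean = 0,
                         intensity_sdlog = 0.25, channel = "light",
                         calibration = NULL,
                         match_tols = list(fragment = 0.1, ccs = 2.5,
                                           rt = 0.2, precursor_ppm = 10)) {
  analytes <- as.data.frame(analytes, stringsAsFactors = FALSE)
  if (!"mz" %in% names(analytes)) {
    if (!"acid_formula" %in% names(analytes)) {
      stop("analytes need either an 'mz' or an 'acid_formula' column")
    }
    analytes$mz <- vapply(analytes$acid_formula, derivatized_mz, numeric(1),
                          channel = channel)
  }
  needed <- c("name", "rt_min", "ccs_A2", "intensity_scale")
  missing <- setdiff(needed, names(analytes))
  if (length(missing) > 0L) {
    stop("analytes lack column(s): ", paste(missing, collapse = ", "))
  }
  if (!"fragment_mz" %in% names(analytes)) analytes$fragment_mz <- NA_real_
  if (any(c(mz_error_ppm, rt_jitter_sd, drift_jitter_sd,
            fragment_jitter_sd) < 0)) {
    stop("jitter SDs must be >= 0")
  }
  if (is.null(calibration)) calibration <- library_calibration()
  structure(
    list(analytes = analytes, n_samples = as.integer(n_samples),
         seed = as.integer(seed), n_decoys = as.integer(n_decoys),
         mz_error_ppm = mz_error_ppm, rt_jitter_sd = rt_jitter_sd,
         drift_jitter_sd = drift_jitter_sd,
         fragment_jitter_sd = fragment_jitter_sd,
         background_mean = background_mean,
         unique_background_mean = unique_background_mean,
         intensity_sdlog = intensity_sdlog, channel = channel,
         calibration = calibration, match_tols = match_tols),
    class = "synth_config"
  )
}

#' Planted-analyte table from reference-library records
#'
#' @param library An \code{oxylipin_library}.
#' @param names Analyte names to plant (default: all).
#' @param intensity_scale Mean feature intensity (recycled).
#' @return Data.frame usable as the \code{analytes} argument of
#'   \code{\link{synth_config}}.
#' @export
library_analytes <- function(library, names = NULL, intensity_scale = 1e5) {
  lib <- as.data.frame(library)
  if (!is.null(names)) {
    idx <- match(names, lib$name)
    if (anyNA(idx)) stop("unknown analyte(s): ",
                         paste(names[is.na(idx)], collapse = ", "))
    lib <- lib[idx, , drop = FALSE]
  }
  data.frame(name = lib$name, acid_formula = lib$acid_formula,
             rt_min = lib$rt_min, ccs_A2 = lib$ccs_A2,
             fragment_mz = lib$mz_fragment,
             intensity_scale = intensity_scale, stringsAsFactors = FALSE)
}

#' Generate an ad-hoc panel of synthetic carboxylic-acid analytes
#'
#' Enumerates plausible fatty-acid-like formulas CcH(2c-2d)Oo (c 12-30,
#' d 0-6 double-bond equivalents beyond the acid, o 2-4), keeps derivatized
#' masses separated by at least 0.02 Da, and samples \code{n} of them with
#' uniform retention times in 3-22 min and CCS in 200-232 Angstrom^2.
#'
#' @param n Number of analytes.
#' @param seed Integer seed.
#' @param intensity_scale Mean feature intensity.
#' @return Data.frame usable as \code{analytes} in
#'   \code{\link{synth_config}}.
#' @export
synthetic_analyte_panel <- function(n, seed = 1L, intensity_scale = 1e5) {
  grid <- expand.grid(c = 12:30, d = 0:6, o = 2:4)
  grid$formula <- sprintf("C%dH%dO%d", grid$c, 2 * grid$c - 2 * grid$d,
                          grid$o)
  grid$mz <- vapply(grid$formula, derivatized_mz, numeric(1))
  grid <- grid[order(grid$mz), ]
  keep <- c(TRUE, diff(grid$mz) >= 0.02)
  # drop the later of any close pair until all gaps are >= 0.02 Da
  while (any(!keep)) {
    grid <- grid[keep, ]
    keep <- c(TRUE, diff(grid$mz) >= 0.02)
  }
  if (n > nrow(grid)) stop("at most ", nrow(grid),
                           " well-separated analytes are available")
  set.seed(seed)
  pick <- sort(sample.int(nrow(grid), n))
  sel <- grid[pick, ]
  data.frame(
    name = sprintf("acid_%03d", seq_len(n)),
    acid_formula = sel$formula,
    rt_min = round(stats::runif(n, 3, 22), 3),
    ccs_A2 = round(stats::runif(n, 200, 232), 2),
    fragment_mz = NA_real_,
    intensity_scale = intensity_scale,
    stringsAsFactors = FALSE
  )
}

#' Simulate replicate per-sample feature sets with known ground truth
#'
#' For every planted analyte and sample a singly charged feature is emitted
#' at the derivatized m/z (with configured error), library-style RT and a
#' drift time synthesized from the analyte CCS through the configured
#' single-field calibration; the attached spectrum holds the channel's
#' diagnostic fragment pair, the quantifier fragment, and the analyte's
#' shared background peaks, all with bounded m/z jitter. Decoy features lack
#' diagnostic ions and their precursors keep at least 0.05 Da away from any
#' planted m/z.
#'
#' @param config A \code{\link{synth_config}}.
#' @return List with \code{sets} (list of \code{\link{feature_set}}s) and
#'   \code{truth} (data.frame of planted analytes and their per-sample
#'   feature ids; every planted analyte is an expected consensus feature).
#' @export
simulate_samples <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  an <- config$analytes
  n_an <- nrow(an)
  cal <- config$calibration
  diag <- diagnostic_fragments(config$channel)
  tols <- config$match_tols

  mz_sds <- split_error_sds(config$mz_error_ppm, tols$precursor_ppm / 2)
  rt_sds <- split_error_sds(config$rt_jitter_sd, tols$rt / 2)
  gamma <- reduced_mass_gamma(an$mz, 1L, cal$drift_gas_mass)
  drift_bound <- (tols$ccs / 2) * cal$beta * gamma
  frag_bound <- tols$fragment / 2

  # per-analyte truth, drawn once and shared across samples
  truth <- an
  truth$mz_true <- an$mz
  truth$drift_true <- drift_from_ccs(an$ccs_A2, an$mz, cal)
  truth$shared_ppm <- rtrunc_norm(n_an, mz_sds$shared, Inf)
  truth$shared_rt <- rtrunc_norm(n_an, rt_sds$shared, Inf)
  frag_sets <- vector("list", n_an)
  for (i in seq_len(n_an)) {
    quant <- an$fragment_mz[i]
    if (is.na(quant)) quant <- stats::runif(1, 200, an$mz[i] - 20)
    n_bg <- stats::rpois(1, config$background_mean)
    bg <- stats::runif(n_bg, 150, an$mz[i] - 10)
    frag_sets[[i]] <- data.frame(
      mz = c(diag, quant, bg),
      intensity = c(100, 80, 60, stats::runif(n_bg, 5, 50))
    )
  }

  planted_mz <- an$mz
  sets <- vector("list", config$n_samples)
  id_mat <- matrix(NA_character_, n_an, config$n_samples)
  for (s in seq_len(config$n_samples)) {
    sample_id <- sprintf("S%d", s)
    # planted features
    eps_ppm <- truth$shared_ppm + rtrunc_norm(n_an, mz_sds$within,
                                              tols$precursor_ppm / 2)
    mz_obs <- an$mz * (1 + eps_ppm * 1e-6)
    rt_obs <- an$rt_min + truth$shared_rt +
      rtrunc_norm(n_an, rt_sds$within, tols$rt / 2)
    drift_obs <- truth$drift_true +
      rtrunc_norm(n_an, config$drift_jitter_sd, drift_bound)
    ccs_obs <- ccs_from_drift(drift_obs, mz_obs, cal)
    intensity <- an$intensity_scale *
      stats::rlnorm(n_an, -config$intensity_sdlog^2 / 2,
                    config$intensity_sdlog)
    ids <- sprintf("%s_F%04d", sample_id, seq_len(n_an))
    id_mat[, s] <- ids
    spectra <- list()
    for (i in seq_len(n_an)) {
      sp <- frag_sets[[i]]
      sp$mz <- sp$mz + rtrunc_norm(nrow(sp), config$fragment_jitter_sd,
                                   frag_bound)
      n_u <- stats::rpois(1, config$unique_background_mean)
      if (n_u > 0) {
        sp <- rbind(sp, data.frame(
          mz = stats::runif(n_u, 150, an$mz[i] - 10),
          intensity = stats::runif(n_u, 1, 4)))
      }
      spectra[[ids[i]]] <- sp
    }
    feats <- data.frame(
      feature_id = ids, mz = mz_obs, z = 1L, rt_min = rt_obs,
      drift_ms = drift_obs, ccs_A2 = ccs_obs, intensity = intensity,
      q_score = stats::runif(n_an, 60, 100), stringsAsFactors = FALSE
    )
    # decoy features: no diagnostic ions, precursors away from planted m/z
    if (config$n_decoys > 0L) {
      d_mz <- numeric(config$n_decoys)
      for (k in seq_len(config$n_decoys)) {
        repeat {
          cand <- stats::runif(1, 300, 600)
          if (min(abs(cand - planted_mz)) > 0.05) break
        }
        d_mz[k] <- cand
      }
      d_ids <- sprintf("%s_D%04d", sample_id, seq_len(config$n_decoys))
      d_ccs <- stats::runif(config$n_decoys, 195, 235)
      d_drift <- drift_from_ccs(d_ccs, d_mz, cal)
      d_feats <- data.frame(
        feature_id = d_ids, mz = d_mz, z = 1L,
        rt_min = stats::runif(config$n_decoys, 2, 25),
        drift_ms = d_drift, ccs_A2 = d_ccs,
        intensity = stats::rlnorm(config$n_decoys, log(500), 1),
        q_score = stats::runif(config$n_decoys, 20, 100),
        stringsAsFactors = FALSE
      )
      for (k in seq_len(config$n_decoys)) {
        n_p <- stats::rpois(1, 10) + 1L
        p_mz <- stats::runif(n_p, 150, d_mz[k] - 10)
        # keep decoys free of accidental diagnostic hits
        for (d in diag) p_mz <- p_mz[abs(p_mz - d) > 0.2]
        spectra[[d_ids[k]]] <- data.frame(
          mz = p_mz, intensity = stats::runif(length(p_mz), 5, 100))
      }
      feats <- rbind(feats, d_feats)
    }
    sets[[s]] <- feature_set(sample_id, feats, spectra,
                             channel = config$channel)
  }
  colnames(id_mat) <- sprintf("feature_id_S%d", seq_len(config$n_samples))
  truth_out <- cbind(
    data.frame(name = an$name, mz_true = truth$mz_true,
               rt_true = an$rt_min, ccs_true = an$ccs_A2,
               intensity_scale = an$intensity_scale,
               stringsAsFactors = FALSE),
    as.data.frame(id_mat, stringsAsFactors = FALSE)
  )
  list(sets = sets, truth = truth_out)
}

#' Simulate a mixed light/heavy dual-channel run with planted ratios
#'
#' Every planted analyte appears as a light/heavy twin spaced by the exact
#' five-deuterium shift; the heavy/light intensity ratio is the planted
#' ratio times an optional global heavy-channel bias times multiplicative
#' pair noise. An internal-standard pair spiked at ratio 1 (before bias) is
#' always included so the channel bias can be cancelled downstream.
#'
#' @param config A \code{\link{synth_config}} (its analytes are planted; the
#'   first \code{length(ratios)} rows are used when \code{ratios} is
#'   shorter).
#' @param ratios Planted heavy/light (treated/control) ratios, one per
#'   analyte or recycled.
#' @param heavy_bias Global heavy-channel gain (default 1).
#' @param ratio_noise_sdlog Log-normal SD of pair-level ratio noise (default
#'   0.1).
#' @param is_name Name of the internal-standard pair (required).
#' @return List with \code{set} (mixed \code{\link{feature_set}}, sample id
#'   "mixed") and \code{truth} (data.frame with light/heavy feature ids,
#'   planted ratio, and \code{is_light_id} attribute naming the IS pair).
#' @export
simulate_dual_channel <- function(config, ratios, heavy_bias = 1,
                                  ratio_noise_sdlog = 0.1,
                                  is_name = "IS_d4-9-HODE") {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(is_name) || is.na(is_name) || !nzchar(is_name)) {
    stop("an internal-standard name must be specified")
  }
  if (any(ratios <= 0)) stop("planted ratios must be positive")
  set.seed(config$seed)
  an <- config$analytes
  n_an <- nrow(an)
  ratios <- rep_len(ratios, n_an)
  cal <- config$calibration
  shift <- heavy_light_shift()
  light_diag <- diagnostic_fragments("light")
  heavy_diag <- diagnostic_fragments("heavy")

  # the IS pair rides along at planted ratio exactly 1
  names_all <- c(an$name, is_name)
  mz_all <- c(an$mz, derivatized_mz("C18H28D4O3"))
  rt_all <- c(an$rt_min, 13.33)
  ccs_all <- c(an$ccs_A2, 214.5)
  scale_all <- c(an$intensity_scale, stats::median(an$intensity_scale))
  ratio_all <- c(ratios, 1)
  n_all <- n_an + 1L

  ppm_bound <- config$match_tols$precursor_ppm / 2
  eps_l <- rtrunc_norm(n_all, min(config$mz_error_ppm, ppm_bound), ppm_bound)
  eps_h <- rtrunc_norm(n_all, min(config$mz_error_ppm, ppm_bound), ppm_bound)
  rt_jit <- rtrunc_norm(n_all, min(config$rt_jitter_sd, 0.02), 0.02)
  drift_true <- drift_from_ccs(ccs_all, mz_all, cal)
  shared <- stats::rlnorm(n_all, 0, config$intensity_sdlog)
  pair_noise <- stats::rlnorm(n_all, 0, ratio_noise_sdlog)

  light_int <- scale_all * shared
  heavy_int <- light_int * ratio_all * heavy_bias * pair_noise

  light_ids <- sprintf("L%04d", seq_len(n_all))
  heavy_ids <- sprintf("H%04d", seq_len(n_all))
  feats <- data.frame(
    feature_id = c(light_ids, heavy_ids),
    mz = c(mz_all * (1 + eps_l * 1e-6),
           (mz_all + shift) * (1 + eps_h * 1e-6)),
    z = 1L,
    rt_min = rep(rt_all + rt_jit, 2),
    drift_ms = rep(drift_true, 2),
    ccs_A2 = rep(ccs_all, 2),
    intensity = c(light_int, heavy_int),
    q_score = 90,
    stringsAsFactors = FALSE
  )
  spectra <- list()
  for (i in seq_len(n_all)) {
    spectra[[light_ids[i]]] <- data.frame(
      mz = light_diag, intensity = c(100, 80))
    spectra[[heavy_ids[i]]] <- data.frame(
      mz = heavy_diag, intensity = c(100, 80))
  }
  set <- feature_set("mixed", feats, spectra, channel = config$channel)
  truth <- data.frame(
    name = names_all, light_id = light_ids, heavy_id = heavy_ids,
    ratio_true = ratio_all,
    is_internal_standard = names_all == is_name,
    stringsAsFactors = FALSE
  )
  attr(truth, "is_light_id") <- light_ids[n_all]
  list(set = set, truth = truth)
}
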