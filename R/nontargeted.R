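#' Matching parameters for the non-targeted consensus workflow
#'
#' Defaults follow the published filtering rules: diagnostic and fragment
#' matching at 0.1 Da, >= 80% of the 25 most abundant fragments shared, CCS
#' within 2.5 Angstrom^2, retention time within 0.2 min, and precursor m/z
#' within 10 ppm (inherited from the vendor feature-alignment mass
#' tolerance).
#'
#' @param fragment_tol Fragment m/z tolerance in Da (default 0.1).
#' @param top_n Number of most abundant fragments compared (default 25).
#' @param min_overlap Minimum shared-fragment fraction (default 0.80,
#'   inclusive; set \code{strict_overlap = TRUE} for a strict > comparison).
#' @param ccs_tol CCS tolerance in Angstrom^2 (default 2.5).
#' @param rt_tol Retention-time tolerance in min (default 0.2).
#' @param precursor_tol Precursor tolerance value (default 10).
#' @param precursor_tol_unit "ppm" (default) or "Da".
#' @param diagnostic_mode "both" (default): both diagnostic ions required;
#'   "either": at least one.
#' @param strict_overlap Use strict > instead of >= for min_overlap.
#' @return List of class \code{match_params}.
#' @export
match_params <- function(fragment_tol = 0.1, top_n = 25L, min_overlap = 0.80,
                         ccs_tol = 2.5, rt_tol = 0.2, precursor_tol = 10,
                         precursor_tol_unit = c("ppm", "Da"),
                         diagnostic_mode = c("both", "either"),
                         strict_overlap = FALSE) {
  precursor_tol_unit <- match.arg(precursor_tol_unit)
  diagnostic_mode <- match.arg(diagnostic_mode)
  if (fragment_tol <= 0 || ccs_tol <= 0 || rt_tol <= 0 || precursor_tol <= 0) {
    stop("all tolerances must be positive")
  }
  if (min_overlap <= 0 || min_overlap > 1) stop("min_overlap must be in (0, 1]")
  if (top_n < 1) stop("top_n must be >= 1")
  structure(
    list(fragment_tol = fragment_tol, top_n = as.integer(top_n),
         min_overlap = min_overlap, ccs_tol = ccs_tol, rt_tol = rt_tol,
         precursor_tol = precursor_tol,
         precursor_tol_unit = precursor_tol_unit,
         diagnostic_mode = diagnostic_mode,
         strict_overlap = strict_overlap),
    class = "match_params"
  )
}

#' Filter a feature set for the diagnostic AMPP head-group fragments
#'
#' Retains features whose MS/MS spectrum contains peaks within \code{tol} of
#' the channel's diagnostic fragment pair (m/z 169.0 and 183.1 for AMPP,
#' 174.0 and 188.1 for the 2H5 channel). Features without an attached
#' spectrum are excluded and counted in the attached report rather than
#' raising an error. Spectra are never modified; the filter is idempotent.
#'
#' @param set A \code{\link{feature_set}}.
#' @param channel Channel whose diagnostics to require; defaults to the
#'   set's own channel label.
#' @param tol Matching tolerance in Da (default 0.1).
#' @param mode "both" (default): both diagnostic ions required; "either":
#'   at least one suffices.
#' @return Filtered \code{feature_set} carrying an
#'   \code{ampp_filter_report} attribute (n_input, n_retained,
#'   n_without_spectrum).
#' @export
ampp_fragment_filter <- function(set, channel = NULL, tol = 0.1,
                                 mode = c("both", "either")) {
  stopifnot(inherits(set, "feature_set"))
  mode <- match.arg(mode)
  if (tol <= 0) stop("tol must be positive")
  if (is.null(channel)) channel <- set$channel
  diag <- diagnostic_fragments(channel)
  ids <- set$features$feature_id
  has_spectrum <- ids %in% names(set$spectra)
  hit <- vapply(ids, function(id) {
    if (!id %in% names(set$spectra)) return(FALSE)
    mzs <- set$spectra[[id]]$mz
    found <- vapply(diag, function(d) any(abs(mzs - d) <= tol), logical(1))
    if (mode == "both") all(found) else any(found)
  }, logical(1))
  out <- subset_feature_set(set, ids[hit])
  attr(out, "ampp_filter_report") <- list(
    n_input = length(ids),
    n_retained = sum(hit),
    n_without_spectrum = sum(!has_spectrum)
  )
  out
}

#' The n most abundant peaks of a spectrum
#'
#' Intensity-descending; ties broken by ascending m/z. Returns all peaks when
#' the spectrum has fewer than \code{n}.
#'
#' @param spectrum Data.frame with \code{mz}, \code{intensity}.
#' @param n Number of peaks to keep (default 25).
#' @return Data.frame of at most \code{n} peaks.
#' @export
top_n_fragments <- function(spectrum, n = 25L) {
  if (n < 1) stop("n must be >= 1")
  ord <- order(-spectrum$intensity, spectrum$mz)
  out <- spectrum[ord[seq_len(min(n, nrow(spectrum)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Maximum one-to-one matching count of two sorted m/z lists within a
#' tolerance. Ascending greedy: each peak of a is matched to the smallest
#' unused peak of b within tol, which attains maximum cardinality for
#' threshold matching on a line.
#' @noRd
count_peak_matches <- function(a_mz, b_mz, tol) {
  a_mz <- sort(a_mz)
  b_mz <- sort(b_mz)
  j <- 1L
  nb <- length(b_mz)
  count <- 0L
  for (a in a_mz) {
    while (j <= nb && b_mz[j] < a - tol) j <- j + 1L
    if (j <= nb && b_mz[j] <= a + tol) {
      count <- count + 1L
      j <- j + 1L
    }
  }
  count
}

#' Shared-fragment fraction of two spectra
#'
#' Truncates both spectra to their \code{n} most abundant peaks, forms the
#' maximum one-to-one pairing within \code{tol} (each peak used at most
#' once), and returns the matched count divided by the smaller truncated
#' list size. The min denominator handles features with fewer than \code{n}
#' fragments. Symmetric in its two arguments. An empty spectrum yields 0
#' with a warning.
#'
#' @param a,b Spectra (data.frames with \code{mz}, \code{intensity}).
#' @param tol Fragment tolerance in Da (default 0.1).
#' @param n Truncation depth (default 25).
#' @return Fraction in [0, 1].
#' @export
fragment_overlap <- function(a, b, tol = 0.1, n = 25L) {
  if (nrow(a) == 0L || nrow(b) == 0L) {
    warning("empty spectrum in fragment_overlap; returning 0")
    return(0)
  }
  ta <- top_n_fragments(a, n)
  tb <- top_n_fragments(b, n)
  matched <- count_peak_matches(ta$mz, tb$mz, tol)
  matched / min(nrow(ta), nrow(tb))
}

#' Precursor m/z agreement check under the configured unit
#' @noRd
precursor_within <- function(mz_a, mz_b, params) {
  if (params$precursor_tol_unit == "ppm") {
    abs(mz_a - mz_b) / mz_a * 1e6 <= params$precursor_tol
  } else {
    abs(mz_a - mz_b) <= params$precursor_tol
  }
}

#' Match features across samples into consensus features
#'
#' Anchored consensus matching: every feature of the anchor sample is
#' compared against the features of each other sample. A candidate matches
#' when (i) its precursor m/z agrees with the anchor within the precursor
#' tolerance, (ii) the shared fraction of the 25 most abundant fragments is
#' at least \code{min_overlap} at the fragment tolerance, (iii) CCS agrees
#' within \code{ccs_tol}, and (iv) retention time agrees within
#' \code{rt_tol}. The best candidate per sample (highest overlap, ties by
#' smallest precursor error, then lowest feature_id) is selected greedily;
#' every feature joins at most one consensus, and a consensus is emitted
#' only when every sample contributes a member.
#'
#' All criteria are evaluated anchor-vs-member, not all-pairs, so member RT
#' values may straddle the anchor by up to the tolerance on each side.
#'
#' @param sets List of \code{\link{feature_set}}s (>= 2).
#' @param params A \code{\link{match_params}}.
#' @param anchor Sample id of the anchor set; defaults to the first set.
#' @return Data.frame of class \code{consensus_set}: one row per member with
#'   columns \code{consensus_id}, \code{sample_id}, \code{feature_id},
#'   \code{mz}, \code{rt_min}, \code{drift_ms}, \code{ccs_A2},
#'   \code{intensity}, \code{overlap}, \code{is_anchor}.
#' @export
match_across_samples <- function(sets, params = match_params(),
                                 anchor = NULL) {
  if (length(sets) < 2L) stop("at least 2 feature sets are required")
  stopifnot(inherits(params, "match_params"))
  sample_ids <- vapply(sets, function(s) s$sample_id, character(1))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids among sets")
  if (is.null(anchor)) anchor <- sample_ids[1]
  ai <- match(anchor, sample_ids)
  if (is.na(ai)) stop("anchor sample '", anchor, "' not among the sets")
  anchor_set <- sets[[ai]]
  others <- sets[-ai]

  overlap_ok <- function(ov) {
    if (params$strict_overlap) ov > params$min_overlap
    else ov >= params$min_overlap
  }
  used <- lapply(others, function(s) character(0))
  rows <- list()
  cid <- 0L
  af <- anchor_set$features
  for (i in seq_len(nrow(af))) {
    aid <- af$feature_id[i]
    aspec <- anchor_set$spectra[[aid]]
    if (is.null(aspec) || nrow(aspec) == 0L) next
    atop <- top_n_fragments(aspec, params$top_n)
    members <- list()
    complete <- TRUE
    for (k in seq_along(others)) {
      of <- others[[k]]$features
      mz_err <- abs(of$mz - af$mz[i])
      cand <- which(
        precursor_within(af$mz[i], of$mz, params) &
          abs(of$rt_min - af$rt_min[i]) <= params$rt_tol &
          !(of$feature_id %in% used[[k]])
      )
      ccs_known <- !is.na(of$ccs_A2) & !is.na(af$ccs_A2[i])
      cand <- cand[!ccs_known[cand] |
                     abs(of$ccs_A2[cand] - af$ccs_A2[i]) <= params$ccs_tol]
      if (length(cand) == 0L) { complete <- FALSE; break }
      ov <- vapply(cand, function(j) {
        sp <- others[[k]]$spectra[[of$feature_id[j]]]
        if (is.null(sp) || nrow(sp) == 0L) return(-1)
        tb <- top_n_fragments(sp, params$top_n)
        count_peak_matches(atop$mz, tb$mz, params$fragment_tol) /
          min(nrow(atop), nrow(tb))
      }, numeric(1))
      cand <- cand[overlap_ok(ov)]
      ov <- ov[overlap_ok(ov)]
      if (length(cand) == 0L) { complete <- FALSE; break }
      ord <- order(-ov, mz_err[cand], of$feature_id[cand])
      best <- cand[ord[1]]
      members[[k]] <- list(set = others[[k]], row = best, overlap = ov[ord[1]])
    }
    if (!complete) next
    cid <- cid + 1L
    mk_row <- function(set, j, overlap, is_anchor) {
      f <- set$features[j, ]
      data.frame(consensus_id = cid, sample_id = set$sample_id,
                 feature_id = f$feature_id, mz = f$mz, rt_min = f$rt_min,
                 drift_ms = f$drift_ms, ccs_A2 = f$ccs_A2,
                 intensity = f$intensity, overlap = overlap,
                 is_anchor = is_anchor, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- mk_row(anchor_set, i, 1.0, TRUE)
    for (k in seq_along(others)) {
      m <- members[[k]]
      rows[[length(rows) + 1L]] <- mk_row(m$set, m$row, m$overlap, FALSE)
      used[[k]] <- c(used[[k]], m$set$features$feature_id[m$row])
    }
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(consensus_id = integer(0), sample_id = character(0),
               feature_id = character(0), mz = numeric(0),
               rt_min = numeric(0), drift_ms = numeric(0),
               ccs_A2 = numeric(0), intensity = numeric(0),
               overlap = numeric(0), is_anchor = logical(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("consensus_set", "data.frame"),
            anchor = anchor, params = params)
}

#' Summarize consensus features, optionally annotating against the library
#'
#' @param consensus A \code{consensus_set} from
#'   \code{\link{match_across_samples}}.
#' @param library Optional \code{oxylipin_library} for annotation of the
#'   anchor values.
#' @param mz_tol_ppm,rt_tol,ccs_tol Annotation tolerances (see
#'   \code{\link{annotate_feature}}).
#' @return Data.frame, one row per consensus feature: anchor m/z, rt, drift,
#'   CCS, member count, overlap statistics, and (when a library is given) the
#'   top annotation hit. Header-only when the consensus set is empty.
#' @export
consensus_report <- function(consensus, library = NULL, mz_tol_ppm = 10,
                             rt_tol = 0.2, ccs_tol = 2.5) {
  stopifnot(inherits(consensus, "consensus_set"))
  ids <- unique(consensus$consensus_id)
  rows <- lapply(ids, function(id) {
    grp <- consensus[consensus$consensus_id == id, ]
    a <- grp[grp$is_anchor, ][1, ]
    hit <- NA_character_
    if (!is.null(library)) {
      ann <- annotate_feature(a$mz, a$rt_min, a$ccs_A2, library,
                              mz_tol_ppm = mz_tol_ppm, rt_tol = rt_tol,
                              ccs_tol = ccs_tol)
      if (nrow(ann) > 0L) hit <- ann$name[1]
    }
    data.frame(consensus_id = id, anchor_feature_id = a$feature_id,
               mz = a$mz, rt_min = a$rt_min, drift_ms = a$drift_ms,
               ccs_A2 = a$ccs_A2, n_members = nrow(grp),
               min_overlap = min(grp$overlap[!grp$is_anchor]),
               mean_overlap = mean(grp$overlap[!grp$is_anchor]),
               annotation = hit, stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(consensus_id = integer(0), anchor_feature_id = character(0),
               mz = numeric(0), rt_min = numeric(0), drift_ms = numeric(0),
               ccs_A2 = numeric(0), n_members = integer(0),
               min_overlap = numeric(0), mean_overlap = numeric(0),
               annotation = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
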