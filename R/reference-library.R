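#' Load the packaged oxylipin reference library
#'
#' The package ships a 52-analyte library of AMPP-derivatized hydroxy,
#' dihydroxy, and epoxy PUFAs: for each analyte the derivatized [M+] m/z,
#' quantifier fragment m/z, retention time, drift time, collision cross
#' section, calibration limits (LOD, LLOQ, ULOQ) and calibration R^2.
#' Quantifier fragment m/z values are empirical and are never recomputed
#' from structure. LLOQ/ULOQ entries that correspond to the lowest/highest
#' calibration point rather than a determined limit carry provenance flags.
#'
#' @param path Optional path to a library file in the packaged format;
#'   defaults to the fixture shipped with the package.
#' @return A data.frame of class \code{oxylipin_library}, one row per analyte,
#'   with columns \code{name}, \code{family} (hydroxy/dihydroxy/epoxy),
#'   \code{precursor_pufa} (LA/ALA/ARA/EPA/DHA), \code{position} (lower carbon
#'   index of the functional group), \code{acid_formula}, \code{mz_precursor},
#'   \code{mz_fragment}, \code{rt_min}, \code{drift_ms}, \code{ccs_A2},
#'   \code{lod_nM}, \code{lloq_nM}, \code{uloq_nM}, \code{r2},
#'   \code{quantifier} (precursor/fragment ion used for quantification),
#'   \code{lloq_at_cal_limit}, \code{uloq_at_cal_limit} (provenance flags) and
#'   \code{unresolved_with} (name of a co-eluting partner that cannot be
#'   separated chromatographically or by mobility, NA otherwise).
#' @examples
#' lib <- load_reference_library()
#' nrow(lib) # 52
#' @export
load_reference_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "oxylipin_library.tsv", package = "oximpp",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) stop("library file not found: ", path)
  lib <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = "NA",
                           colClasses = c(position = "integer"))
  required <- c(
    "name", "family", "precursor_pufa", "position", "acid_formula",
    "mz_precursor", "mz_fragment", "rt_min", "drift_ms", "ccs_A2",
    "lod_nM", "lloq_nM", "uloq_nM", "r2", "quantifier",
    "lloq_at_cal_limit", "uloq_at_cal_limit", "unresolved_with"
  )
  missing <- setdiff(required, names(lib))
  if (length(missing) > 0L) {
    stop("library file lacks column(s): ", paste(missing, collapse = ", "))
  }
  for (i in seq_len(nrow(lib))) {
    rec <- lib[i, ]
    ok <- !is.na(rec$mz_precursor) && !is.na(rec$mz_fragment) &&
      rec$mz_fragment < rec$mz_precursor &&
      rec$ccs_A2 >= 200 && rec$ccs_A2 <= 240 &&
      rec$lod_nM <= rec$lloq_nM && rec$lloq_nM <= rec$uloq_nM
    if (!ok) stop("malformed library row ", i, " ('", rec$name, "')")
  }
  class(lib) <- c("oxylipin_library", "data.frame")
  lib
}

#' Write a reference library in the packaged fixture format
#'
#' Inverse of \code{\link{load_reference_library}}: a written library
#' re-loads with all fields identical.
#'
#' @param library An \code{oxylipin_library} data.frame.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_reference_library <- function(library, path) {
  utils::write.table(as.data.frame(library), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Annotate a feature against the reference library
#'
#' Candidate identifications are library records whose precursor m/z,
#' retention time, and CCS all lie within the given tolerances of the
#' feature's values. Criteria for which the feature carries no value (rt or
#' ccs absent) are skipped. Matches are ranked by ascending absolute mass
#' error, so retention time separates isobaric regioisomers only through the
#' tolerance gate.
#'
#' @param mz Feature precursor m/z (required).
#' @param rt Feature retention time in min, or NA.
#' @param ccs Feature CCS in Angstrom^2, or NA.
#' @param library Library from \code{\link{load_reference_library}}.
#' @param mz_tol_ppm m/z tolerance in ppm (default 10).
#' @param rt_tol Retention-time tolerance in min (default 0.2).
#' @param ccs_tol CCS tolerance in Angstrom^2 (default 2.5).
#' @return Data.frame of matching records with extra columns
#'   \code{mz_error_ppm}, \code{rt_error_min}, \code{ccs_error_A2}, ranked by
#'   ascending |mz error|; zero rows when nothing matches.
#' @export
annotate_feature <- function(mz, rt = NA, ccs = NA, library,
                             mz_tol_ppm = 10, rt_tol = 0.2, ccs_tol = 2.5) {
  if (mz_tol_ppm <= 0 || rt_tol <= 0 || ccs_tol <= 0) {
    stop("annotation tolerances must be positive")
  }
  if (is.na(mz) || mz <= 0) stop("feature m/z is required")
  lib <- as.data.frame(library)
  err_ppm <- (mz - lib$mz_precursor) / lib$mz_precursor * 1e6
  keep <- abs(err_ppm) <= mz_tol_ppm
  if (!is.na(rt)) keep <- keep & abs(rt - lib$rt_min) <= rt_tol
  if (!is.na(ccs)) keep <- keep & abs(ccs - lib$ccs_A2) <= ccs_tol
  out <- lib[keep, , drop = FALSE]
  out$mz_error_ppm <- err_ppm[keep]
  out$rt_error_min <- if (is.na(rt)) rep(NA_real_, nrow(out)) else
    rt - out$rt_min
  out$ccs_error_A2 <- if (is.na(ccs)) rep(NA_real_, nrow(out)) else
    ccs - out$ccs_A2
  out <- out[order(abs(out$mz_error_ppm)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' CCS of a regioisomer series as a function of functional-group position
#'
#' Projects the library onto (position, CCS) pairs for one structural family
#' and one precursor PUFA, e.g. the hydroxy-ARA series 5-HETE ... 20-HETE.
#' Positions use the lower carbon index of the functional group (the first
#' carbon of a vicinal diol or epoxide). The derivatized regioisomer series
#' show a CCS maximum in the mid-chain (roughly C10-C12) region.
#'
#' @param library Library from \code{\link{load_reference_library}}.
#' @param family "hydroxy", "dihydroxy" or "epoxy".
#' @param precursor_pufa "LA", "ALA", "ARA", "EPA" or "DHA".
#' @return Data.frame with columns \code{position}, \code{ccs_A2},
#'   \code{name}, sorted by ascending position.
#' @export
ccs_trend <- function(library, family, precursor_pufa) {
  family <- match.arg(family, c("hydroxy", "dihydroxy", "epoxy"))
  precursor_pufa <- match.arg(precursor_pufa,
                              c("LA", "ALA", "ARA", "EPA", "DHA"))
  lib <- as.data.frame(library)
  sel <- lib$family == family & lib$precursor_pufa == precursor_pufa
  if (sum(sel) < 2L) {
    stop("fewer than 2 library records for family '", family,
         "' and precursor '", precursor_pufa, "'")
  }
  out <- data.frame(
    position = lib$position[sel],
    ccs_A2 = lib$ccs_A2[sel],
    name = lib$name[sel],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
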