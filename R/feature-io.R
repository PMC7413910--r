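#' Construct a per-sample feature set
#'
#' A feature set holds the molecular features exported for one sample
#' (m/z, charge, retention time, drift time, optional CCS, intensity,
#' optional quality score) together with the high-fragmentation-frame MS/MS
#' spectrum attached to each feature.
#'
#' @param sample_id Sample identifier.
#' @param features Data.frame with columns \code{feature_id}, \code{mz},
#'   \code{z}, \code{rt_min}, \code{drift_ms}, \code{intensity} and optionally
#'   \code{ccs_A2}, \code{q_score}. Optional columns absent from the input are
#'   carried as NA, never as zeros.
#' @param spectra Named list of data.frames (columns \code{mz},
#'   \code{intensity}), keyed by feature_id. Features without a spectrum are
#'   allowed.
#' @param channel Derivatization channel label, "light" or "heavy".
#' @return List of class \code{feature_set}.
#' @export
feature_set <- function(sample_id, features, spectra = list(),
                        channel = "light") {
  channel <- match.arg(channel, c("light", "heavy"))
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  required <- c("feature_id", "mz", "z", "rt_min", "drift_ms", "intensity")
  missing <- setdiff(required, names(features))
  if (length(missing) > 0L) {
    stop("feature table lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  for (opt in c("ccs_A2", "q_score")) {
    if (!opt %in% names(features)) {
      features[[opt]] <- rep(NA_real_, nrow(features))
    }
  }
  features$feature_id <- as.character(features$feature_id)
  if (anyDuplicated(features$feature_id)) {
    stop("duplicate feature_id in sample '", sample_id, "': ",
         features$feature_id[duplicated(features$feature_id)][1])
  }
  if (nrow(features) > 0L) {
    bad <- features$z < 1 | features$rt_min < 0 | features$drift_ms <= 0 |
      features$intensity < 0
    if (any(bad, na.rm = TRUE)) {
      stop("invalid feature row(s): ",
           paste(features$feature_id[which(bad)], collapse = ", "))
    }
  }
  unknown <- setdiff(names(spectra), features$feature_id)
  if (length(unknown) > 0L) {
    stop("spectra keyed to unknown feature_id(s): ",
         paste(unknown, collapse = ", "))
  }
  for (id in names(spectra)) {
    sp <- spectra[[id]]
    if (!all(c("mz", "intensity") %in% names(sp))) {
      stop("spectrum for '", id, "' lacks mz/intensity columns")
    }
    if (any(sp$mz <= 0) || any(sp$intensity < 0)) {
      stop("invalid peaks in spectrum for '", id, "'")
    }
    prec <- features$mz[features$feature_id == id]
    if (any(sp$mz > prec + 0.5)) {
      stop("spectrum for '", id, "' contains peaks above the precursor m/z")
    }
  }
  structure(
    list(sample_id = sample_id, channel = channel,
         features = features, spectra = spectra),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("Feature set '%s' (%s channel): %d features, %d with spectra\n",
              x$sample_id, x$channel, nrow(x$features), length(x$spectra)))
  invisible(x)
}

#' Number of features in a feature set
#' @param x A \code{feature_set}.
#' @param ... Ignored.
#' @export
length.feature_set <- function(x) nrow(x$features)

# Canonical feature-table columns, in writing order.
FEATURE_COLUMNS <- c("feature_id", "sample_id", "mz", "z", "rt_min",
                     "drift_ms", "ccs_A2", "intensity", "q_score")

# Header names whose unit annotation contradicts the package convention
# (RT minutes, drift ms, m/z Da).
CONFLICTING_HEADERS <- c("rt_s", "rt_sec", "rt_seconds", "drift_s",
                         "drift_us", "mz_ppm")

#' Read a per-sample feature table (with optional MGF spectra)
#'
#' Reads a delimited feature export (tab or comma separated, autodetected
#' from the header line) into a \code{\link{feature_set}}. Spectra are joined
#' by feature_id from a companion MGF file when given. Missing optional
#' columns (\code{ccs_A2}, \code{q_score}) become NA.
#'
#' @param path Feature table path.
#' @param spectra_path Optional MGF file (TITLE = feature_id).
#' @param sample_id Sample identifier; defaults to the table's
#'   \code{sample_id} column (which must then be single-valued).
#' @param channel Channel label, "light" or "heavy".
#' @return A \code{feature_set}.
#' @export
read_feature_table <- function(path, spectra_path = NULL, sample_id = NULL,
                               channel = "light") {
  if (!file.exists(path)) stop("feature table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE)
  bad_units <- intersect(tolower(names(tab)), CONFLICTING_HEADERS)
  if (length(bad_units) > 0L) {
    stop("header unit annotation disagrees with package convention ",
         "(rt in min, drift in ms, m/z in Da): ",
         paste(bad_units, collapse = ", "))
  }
  if (is.null(sample_id)) {
    if (!"sample_id" %in% names(tab)) {
      stop("feature table lacks required column(s): sample_id")
    }
    ids <- unique(tab$sample_id)
    if (length(ids) > 1L) stop("feature table mixes multiple sample_ids")
    sample_id <- if (length(ids) == 1L) ids else "sample"
  }
  spectra <- if (!is.null(spectra_path)) read_mgf(spectra_path) else list()
  spectra <- spectra[names(spectra) %in% as.character(tab$feature_id)]
  feature_set(sample_id, tab, spectra, channel = channel)
}

#' Write a feature set to a delimited table (and optional MGF)
#'
#' Round trip: a written set re-reads with all fields equal at printed
#' precision.
#'
#' @param set A \code{feature_set}.
#' @param path Output table path (tab-separated).
#' @param spectra_path Optional MGF output path for the attached spectra.
#' @return \code{path}, invisibly.
#' @export
write_feature_table <- function(set, path, spectra_path = NULL) {
  stopifnot(inherits(set, "feature_set"))
  tab <- set$features
  tab$sample_id <- rep(set$sample_id, nrow(tab))
  tab <- tab[, FEATURE_COLUMNS, drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  if (!is.null(spectra_path)) {
    pepmass <- stats::setNames(set$features$mz, set$features$feature_id)
    write_mgf(set$spectra, spectra_path, pepmass = pepmass)
  }
  invisible(path)
}

#' Read an MGF (Mascot generic format) spectrum file
#'
#' Parses BEGIN IONS / END IONS blocks; the TITLE line keys each spectrum.
#'
#' @param path MGF file path.
#' @return Named list of data.frames with columns \code{mz},
#'   \code{intensity}.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path)
  begins <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(begins) != length(ends)) stop("unbalanced MGF blocks in ", path)
  spectra <- list()
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    title_line <- grep("^TITLE=", block, value = TRUE)
    if (length(title_line) == 0L) stop("MGF block ", k, " lacks a TITLE")
    title <- sub("^TITLE=", "", title_line[1])
    peak_lines <- block[!grepl("=", block, fixed = TRUE)]
    peak_lines <- peak_lines[nzchar(trimws(peak_lines))]
    if (length(peak_lines) > 0L) {
      vals <- do.call(rbind, lapply(strsplit(trimws(peak_lines), "[ \t]+"),
                                    function(v) as.numeric(v[1:2])))
      sp <- data.frame(mz = vals[, 1], intensity = vals[, 2])
    } else {
      sp <- data.frame(mz = numeric(0), intensity = numeric(0))
    }
    spectra[[title]] <- sp
  }
  spectra
}

#' Write spectra as an MGF file
#'
#' @param spectra Named list of peak data.frames (\code{mz},
#'   \code{intensity}).
#' @param path Output path.
#' @param pepmass Optional named vector of precursor m/z per spectrum title.
#' @return \code{path}, invisibly.
#' @export
write_mgf <- function(spectra, path, pepmass = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (title in names(spectra)) {
    sp <- spectra[[title]]
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", title), con)
    if (!is.null(pepmass) && title %in% names(pepmass)) {
      writeLines(sprintf("PEPMASS=%.6f", pepmass[[title]]), con)
    }
    if (nrow(sp) > 0L) {
      writeLines(sprintf("%.6f %.6f", sp$mz, sp$intensity), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Subset a feature set to the given feature ids, keeping spectra in step
#' @noRd
subset_feature_set <- function(set, keep_ids) {
  feats <- set$features[set$features$feature_id %in% keep_ids, , drop = FALSE]
  rownames(feats) <- NULL
  set$features <- feats
  set$spectra <- set$spectra[names(set$spectra) %in% keep_ids]
  set
}

#' Pre-filter a feature set on retention time, charge, q-score and intensity
#'
#' Mirrors the vendor feature-extraction pre-filter: retention-time window
#' 2.0-25.0 min, charge state +1, q-score >= 40 and intensity >= 100 counts
#' by default. All thresholds are inclusive. Features lacking a q-score fail
#' the q-score criterion only when that criterion is enabled; disable it with
#' \code{min_q_score = NULL}.
#'
#' @param set A \code{feature_set}.
#' @param rt_range Length-2 inclusive retention-time window in min.
#' @param charge Required charge state, or NULL to skip.
#' @param min_q_score Minimum q-score, or NULL to skip.
#' @param min_intensity Minimum intensity in counts.
#' @return Filtered \code{feature_set}; a subset of the input with no field
#'   modified. Idempotent.
#' @export
prefilter_features <- function(set, rt_range = c(2.0, 25.0), charge = 1L,
                               min_q_score = 40, min_intensity = 100) {
  stopifnot(inherits(set, "feature_set"))
  if (rt_range[1] >= rt_range[2]) stop("rt_range must satisfy min < max")
  f <- set$features
  keep <- f$rt_min >= rt_range[1] & f$rt_min <= rt_range[2] &
    f$intensity >= min_intensity
  if (!is.null(charge)) keep <- keep & f$z == charge
  if (!is.null(min_q_score)) {
    keep <- keep & !is.na(f$q_score) & f$q_score >= min_q_score
  }
  subset_feature_set(set, f$feature_id[keep])
}
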