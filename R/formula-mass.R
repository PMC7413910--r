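#' Monoisotopic atomic masses used throughout the package
#'
#' Standard monoisotopic masses in Da for the elements occurring in
#' AMPP-derivatized oxylipins. Deuterium is carried as the distinct symbol
#' \code{D} so that light and heavy derivatization channels can be expressed
#' as ordinary elemental formulas.
#'
#' @format Named numeric vector (C, H, D, N, O).
#' @export
ATOMIC_MASSES <- c(
  C = 12.000000,
  H = 1.00782503,
  D = 2.01410178,
  N = 14.0030740,
  O = 15.9949146
)

#' Mass of the electron in Da (used only when electron correction is enabled).
#' @noRd
ELECTRON_MASS <- 0.000548579909

#' Parse a Hill-order elemental formula string
#'
#' Accepts strings such as \code{"C18H34O4"} or \code{"C12H8D5N2"} with
#' \code{D} as a literal element token for deuterium. An omitted count means 1;
#' zero counts are dropped, so \code{"H0"} parses to an empty formula.
#'
#' @param formula Formula string, or an already-parsed named integer vector
#'   (returned unchanged after validation).
#' @return Named integer vector of element counts, Hill order, zero counts
#'   removed.
#' @examples
#' parse_formula("C18H34O4")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula) && !is.null(names(formula))) {
    counts <- formula
  } else {
    if (!is.character(formula) || length(formula) != 1L || is.na(formula)) {
      stop("'formula' must be a single formula string or a named count vector")
    }
    tokens <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
    if (length(tokens) == 0L || paste(tokens, collapse = "") != formula) {
      stop("malformed formula string: '", formula, "'")
    }
    elements <- gsub("[0-9]", "", tokens)
    n <- gsub("[^0-9]", "", tokens)
    n <- as.integer(ifelse(n == "", "1", n))
    counts <- tapply(n, elements, sum)
    counts <- stats::setNames(as.integer(counts), names(counts))
  }
  unknown <- setdiff(names(counts), names(ATOMIC_MASSES))
  if (length(unknown) > 0L) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  if (any(counts < 0)) stop("negative element counts are not allowed")
  counts <- counts[counts > 0]
  hill <- c("C", "H", "D", "N", "O")
  counts[order(match(names(counts), hill))]
}

#' Combine two elemental formulas by summing counts element-wise
#'
#' @param a,b Formula strings or named count vectors.
#' @return Named integer vector of summed counts.
#' @export
combine_formulas <- function(a, b) {
  fa <- parse_formula(a)
  fb <- parse_formula(b)
  all_el <- union(names(fa), names(fb))
  out <- stats::setNames(integer(length(all_el)), all_el)
  out[names(fa)] <- out[names(fa)] + fa
  out[names(fb)] <- out[names(fb)] + fb
  parse_formula(out)
}

#' Monoisotopic mass of an elemental formula
#'
#' @param formula Formula string or named count vector (see
#'   \code{\link{parse_formula}}).
#' @return Monoisotopic mass in Da; 0 for a formula that is empty after zero
#'   counts are removed.
#' @examples
#' monoisotopic_mass("C18H34O4") # 314.2457
#' @export
monoisotopic_mass <- function(formula) {
  f <- parse_formula(formula)
  if (length(f) == 0L) return(0)
  sum(ATOMIC_MASSES[names(f)] * f)
}

#' AMPP derivatization channels
#'
#' The light channel is the AMPP (N-(4-aminomethylphenyl)pyridinium) head
#' group; the heavy channel is its five-fold deuterated analog. Head-group
#' atoms are those transferred to the analyte on amide formation, before loss
#' of water: C12H13N2 (light) and C12H8D5N2 (heavy). Diagnostic head-group
#' fragments are stored at the nominal precision used by the filtering rules
#' (m/z 169.0 / 183.1 light; 174.0 / 188.1 heavy).
#'
#' @param label "light" or "heavy".
#' @return List of class \code{ampp_channel} with fields \code{label},
#'   \code{head_formula}, \code{head_mass} and \code{diagnostic} (length-2
#'   m/z vector).
#' @examples
#' ampp_channel("heavy")$diagnostic
#' @export
ampp_channel <- function(label = c("light", "heavy")) {
  label <- match.arg(label)
  head_formula <- switch(label, light = "C12H13N2", heavy = "C12H8D5N2")
  diagnostic <- switch(label,
    light = c(169.0, 183.1),
    heavy = c(174.0, 188.1)
  )
  structure(
    list(
      label = label,
      head_formula = head_formula,
      head_mass = monoisotopic_mass(head_formula),
      diagnostic = diagnostic
    ),
    class = "ampp_channel"
  )
}

#' @export
print.ampp_channel <- function(x, ...) {
  cat(sprintf(
    "AMPP channel '%s': head group %s (%.5f Da), diagnostic fragments m/z %.1f / %.1f\n",
    x$label, x$head_formula, x$head_mass, x$diagnostic[1], x$diagnostic[2]
  ))
  invisible(x)
}

#' Mass shift between the heavy and light derivatization channels
#'
#' Five deuterium-for-hydrogen substitutions: 5 x (m(2H) - m(1H)) = 5.03138 Da.
#'
#' @return Mass difference in Da.
#' @export
heavy_light_shift <- function() {
  5 * (ATOMIC_MASSES[["D"]] - ATOMIC_MASSES[["H"]])
}

#' m/z of the derivatized [M+] cation of a carboxylic acid
#'
#' The charge-switch derivatization forms an amide between the acid and the
#' AMPP amine: the [M+] cation is acid + head-group atoms - H2O, singly
#' charged. By default no electron mass is subtracted: the reference-table
#' convention for [M+] is a plain atom sum, which this package follows so
#' computed values agree with tabulated ones to 0.0005 Da. Set
#' \code{electron_correction = TRUE} for the physically exact cation mass
#' (one electron lighter).
#'
#' @param acid_formula Neutral acid formula (string or named counts),
#'   e.g. "C18H34O4" for 9,10-DiHOME.
#' @param channel "light", "heavy", or an \code{\link{ampp_channel}} object.
#' @param electron_correction Subtract one electron mass? Default FALSE.
#' @return m/z of the singly charged derivatized cation, in Da.
#' @examples
#' derivatized_mz("C18H34O4") # 481.3430
#' @export
derivatized_mz <- function(acid_formula, channel = "light",
                           electron_correction = FALSE) {
  if (!inherits(channel, "ampp_channel")) channel <- ampp_channel(channel)
  f <- parse_formula(acid_formula)
  if (length(f) == 0L) stop("acid formula is empty")
  mz <- monoisotopic_mass(f) + channel$head_mass - monoisotopic_mass("H2O")
  if (isTRUE(electron_correction)) mz <- mz - ELECTRON_MASS
  mz
}

#' Diagnostic head-group fragment pair of a derivatization channel
#'
#' The AMPP cleavage yields characteristic cations at nominal m/z 169.0 and
#' 183.1 (light); the 2H5 analogs are shifted by +5 to 174.0 and 188.1.
#'
#' @inheritParams derivatized_mz
#' @return Numeric length-2 vector of nominal fragment m/z values.
#' @export
diagnostic_fragments <- function(channel = "light") {
  if (!inherits(channel, "ampp_channel")) channel <- ampp_channel(channel)
  channel$diagnostic
}
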