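#' Parse a physical quantity with units
#'
#' Converts strings like `"75 nM"`, `"48 h"` or `"1e-12 L"` to the package's
#' internal units: concentrations to mol/L, times to seconds, volumes to
#' litres. Bare numbers pass through unchanged, so internal-unit values can be
#' used wherever a quantity string is accepted.
#'
#' @param x a single string (e.g. `"300 nM"`, `"60 s"`, `"48 h"`) or a number.
#' @return numeric scalar in internal units.
#' @examples
#' parse_quantity("75 nM")   # 7.5e-08
#' parse_quantity("48 h")    # 172800
#' @export
parse_quantity <- function(x) {
  if (is.numeric(x)) {
    stopifnot(length(x) == 1L)
    return(as.numeric(x))
  }
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  m <- regexec("^([+-]?[0-9.]+(?:[eE][+-]?[0-9]+)?)\\s*([A-Za-zµμ]*)$", x)
  parts <- regmatches(x, m)[[1L]]
  if (length(parts) != 3L) {
    stop("cannot parse quantity: '", x, "'", call. = FALSE)
  }
  value <- as.numeric(parts[2L])
  unit <- parts[3L]
  if (unit == "") {
    return(value)
  }
  scale <- c(
    # concentration -> mol/L
    M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12,
    # time -> seconds
    s = 1, sec = 1, min = 60, h = 3600, hr = 3600, d = 86400, day = 86400,
    # volume -> litres
    L = 1, mL = 1e-3, uL = 1e-6, nL = 1e-9, pL = 1e-12, fL = 1e-15
  )
  # accept the Greek micro sign as a synonym for 'u'
  unit <- chartr("µμ", "uu", unit)
  if (!unit %in% names(scale)) {
    stop("unknown unit '", unit, "' in quantity '", x, "'", call. = FALSE)
  }
  value * scale[[unit]]
}

#' Convenience time-unit constructors
#'
#' @param x numeric value in hours or days.
#' @return the same duration in seconds.
#' @export
hours <- function(x) x * 3600

#' @rdname hours
#' @export
days <- function(x) x * 86400
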