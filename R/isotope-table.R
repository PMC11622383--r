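# Isotope masses and abundances (IUPAC 2013 representative values),
# bundled so that simulations are bit-stable across machines.

#' Physical constants used throughout the package
#'
#' Monoisotopic mass conventions: the proton mass is used for charge
#' conversion, and the per-label mass increments are the exact isotope mass
#' differences 13C - 12C and 15N - 14N.
#'
#' @format Named numeric vector with elements `proton` (1.00727646 Da),
#'   `shift_13C` (1.0033548378 Da), `shift_15N` (0.9970348932 Da) and
#'   `water` (monoisotopic mass of H2O).
#' @export
iso_constants <- c(
  proton    = 1.00727646,
  shift_13C = 13.0033548378 - 12,
  shift_15N = 15.0001088984 - 14.0030740052,
  water     = 2 * 1.0078250319 + 15.9949146221
)

#' Default isotope mass/abundance table
#'
#' Returns the table of isotope masses and natural abundances for the
#' elements C, H, N, O, S, augmented with two single-isotope pseudo-elements,
#' `C13label` and `N15label`, that represent enforced heavy labels (100%
#' abundance).  Treating a selective label as its own element lets the
#' pattern simulator handle sparse labeling by composition editing alone.
#'
#' @param pseudo include the `C13label`/`N15label` pseudo-elements
#'   (default `TRUE`).
#' @return An object of class `isotope_table`: a named list, one entry per
#'   element symbol, each a `data.frame` with columns `mass` (Da,
#'   ascending), `abundance` (fractions summing to 1) and `nshift` (integer
#'   neutron count above the element's lightest isotope).
#' @examples
#' tab <- default_isotope_table()
#' tab$C
#' @export
default_isotope_table <- function(pseudo = TRUE) {
  el <- function(mass, abundance) {
    data.frame(mass = mass, abundance = abundance,
               nshift = as.integer(round(mass - mass[1])))
  }
  tab <- list(
    C = el(c(12.0000000000, 13.0033548378), c(0.9893, 0.0107)),
    H = el(c(1.0078250319, 2.0141017781), c(0.999885, 0.000115)),
    N = el(c(14.0030740052, 15.0001088984), c(0.99636, 0.00364)),
    O = el(c(15.9949146221, 16.9991315, 17.9991604),
           c(0.99757, 0.00038, 0.00205)),
    S = el(c(31.97207069, 32.97145850, 33.96786683, 35.96708088),
           c(0.9499, 0.0075, 0.0425, 0.0001))
  )
  if (pseudo) {
    tab$C13label <- el(13.0033548378, 1)
    tab$N15label <- el(15.0001088984, 1)
  }
  structure(tab, class = "isotope_table")
}

#' Validate an isotope table
#'
#' Checks the structural invariants: per-element abundances sum to 1 within
#' 1e-6, masses strictly positive and ascending, and pseudo-elements
#' (single-isotope entries named `*label`) have abundance exactly 1.
#'
#' @param table an `isotope_table`.
#' @return `table`, invisibly; errors describe the offending element.
#' @export
validate_isotope_table <- function(table) {
  stopifnot(inherits(table, "isotope_table"))
  for (sym in names(table)) {
    e <- table[[sym]]
    if (any(e$mass <= 0) || is.unsorted(e$mass, strictly = TRUE))
      stop("isotope masses for '", sym, "' must be positive and ascending")
    if (abs(sum(e$abundance) - 1) > 1e-6)
      stop("abundances for '", sym, "' sum to ", sum(e$abundance),
           ", expected 1")
    if (grepl("label$", sym) &&
        (nrow(e) != 1L || e$abundance[1] != 1))
      stop("pseudo-element '", sym,
           "' must have exactly one isotope with abundance 1")
  }
  invisible(table)
}

#' @export
print.isotope_table <- function(x, ...) {
  cat("<isotope_table> elements:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
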