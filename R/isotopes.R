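# Embedded isotope constants (IUPAC 2013 atomic masses and representative
# natural abundances). Kept in one place so that every mass and every
# natural-abundance distribution in the package is derived from the same
# versioned table. Elements cover the formulas this workflow encounters
# (C, H, N, O, S, P); abundances per element sum to 1.
.isotope_data <- list(
  C = list(mass = c(12.0, 13.00335483507),
           abundance = c(0.9893, 0.0107)),
  H = list(mass = c(1.00782503207, 2.01410177812),
           abundance = c(0.999885, 0.000115)),
  N = list(mass = c(14.0030740048, 15.0001088989),
           abundance = c(0.99636, 0.00364)),
  O = list(mass = c(15.99491461956, 16.99913170, 17.99915961),
           abundance = c(0.99757, 0.00038, 0.00205)),
  S = list(mass = c(31.97207100, 32.97145876, 33.96786690, 35.96708076),
           abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  P = list(mass = 30.97376163,
           abundance = 1.0)
)

# Mass of a proton (Da); used for the M+H / M-H adduct conventions.
.proton_mass <- 1.007276466622

#' Mass difference between 13C and 12C
#'
#' The spacing of the unit-resolution isotopologue ladder used throughout
#' the package (1.003355 Da).
#'
#' @return A single numeric value in Dalton.
#' @export
c13_spacing <- function() 1.003355

#' Isotope constants used by the package
#'
#' Returns the embedded table of isotope masses and natural abundances
#' (IUPAC 2013 values) backing all formula arithmetic and the
#' natural-abundance correction.
#'
#' @return A data frame with columns `element`, `isotope` (nominal mass
#'   shift from the lightest isotope), `mass` (Da) and `abundance`
#'   (fraction, summing to 1 per element).
#' @examples
#' subset(isotope_table(), element == "C")
#' @export
isotope_table <- function() {
  do.call(rbind, lapply(names(.isotope_data), function(el) {
    x <- .isotope_data[[el]]
    data.frame(element = el,
               isotope = as.integer(round(x$mass - x$mass[1])),
               mass = x$mass,
               abundance = x$abundance,
               stringsAsFactors = FALSE)
  }))
}

# Per-atom nominal mass-shift distribution for one element: a numeric
# vector p[k+1] = P(shift == k). Shifts are nominal (unit Da).
.atom_shift_dist <- function(element, exclude_tracer = FALSE) {
  x <- .isotope_data[[element]]
  if (is.null(x)) stop("unknown element: ", element, call. = FALSE)
  if (exclude_tracer && element == "C") return(1.0)
  shifts <- as.integer(round(x$mass - x$mass[1]))
  out <- numeric(max(shifts) + 1L)
  out[shifts + 1L] <- x$abundance
  out
}
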