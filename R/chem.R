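#' Parse an elemental formula string
#'
#' Parses Hill-notation element-count strings such as `"C18H14O5"` or
#' `"C24H45NO9"` into an `elemental_formula` object (a named integer vector
#' of element counts). An absent count means 1 (`"CH4"` is C1 H4).
#'
#' @param text A single formula string. Supported elements are C, H, N, O,
#'   S and P.
#' @return An object of class `elemental_formula`: a named integer vector
#'   of non-negative element counts.
#' @examples
#' parse_formula("C18H14O5")
#' parse_formula("C24H45NO9")
#' @seealso [formula_string()], [monoisotopic_mass()]
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string", call. = FALSE)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    # locate the first character not consumed by the grammar
    covered <- rep(FALSE, nchar(text))
    for (i in seq_along(m)) {
      covered[seq(m[i], length.out = attr(m, "match.length")[i])] <- TRUE
    }
    bad <- substr(text, which(!covered)[1], nchar(text))
    stop("cannot parse formula near '", bad, "'", call. = FALSE)
  }
  counts <- integer(0)
  for (tok in tokens) {
    el <- sub("[0-9]*$", "", tok)
    if (!el %in% names(.isotope_data)) {
      stop("unknown element symbol '", el, "' in formula '", text, "'",
           call. = FALSE)
    }
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  elemental_formula(counts)
}

#' Construct an elemental formula from element counts
#'
#' @param counts A named integer vector or list mapping element symbols to
#'   non-negative counts, e.g. `c(C = 6, H = 12, O = 6)`.
#' @return An `elemental_formula` object.
#' @export
elemental_formula <- function(counts) {
  counts <- unlist(counts)
  stopifnot(length(counts) >= 1L, !is.null(names(counts)))
  bad <- setdiff(names(counts), names(.isotope_data))
  if (length(bad)) {
    stop("unknown element symbol '", bad[1], "'", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  counts <- counts[counts > 0]
  if (!length(counts)) stop("formula must contain at least one atom", call. = FALSE)
  out <- as.integer(counts)
  names(out) <- names(counts)
  structure(out, class = "elemental_formula")
}

#' Canonical Hill-order string for a formula
#'
#' @param f An `elemental_formula` (or a string, which is parsed first).
#' @return A single character string: carbon first, hydrogen second, then
#'   remaining elements alphabetically; counts of 1 are omitted.
#' @examples
#' formula_string(parse_formula("H12C6O6"))  # "C6H12O6"
#' @export
formula_string <- function(f) {
  f <- as_formula(f)
  els <- names(f)
  ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  paste0(vapply(ord, function(el) {
    n <- f[[el]]
    if (n == 1L) el else paste0(el, n)
  }, character(1)), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula>", formula_string(x), "\n")
  invisible(x)
}

# Coerce a string or named vector to elemental_formula.
as_formula <- function(f) {
  if (inherits(f, "elemental_formula")) return(f)
  if (is.character(f)) return(parse_formula(f))
  elemental_formula(f)
}

#' Number of carbon atoms in a formula
#'
#' Defines the length (N + 1) of the isotopologue ladder M+0..M+N used for
#' a feature.
#'
#' @param f An `elemental_formula` or formula string.
#' @return Integer carbon count (0 if the formula has no carbon).
#' @export
carbon_count <- function(f) {
  f <- as_formula(f)
  if ("C" %in% names(f)) unname(f[["C"]]) else 0L
}

#' Monoisotopic mass of a formula under an adduct convention
#'
#' Sums lightest-isotope masses over all atoms and applies the adduct:
#' `"M"` (neutral), `"M+H"` (adds a proton) or `"M-H"` (removes a proton).
#' The proton mass convention includes the electron, so `M+H` adds
#' 1.007276 Da.
#'
#' @param f An `elemental_formula` or formula string.
#' @param adduct One of `"M"`, `"M+H"`, `"M-H"`.
#' @return Mass (for `"M"`) or m/z of the singly charged ion, in Da.
#' @examples
#' monoisotopic_mass("C6H12O6")            # 180.0634
#' monoisotopic_mass("C24H45NO9", "M-H")
#' @export
monoisotopic_mass <- function(f, adduct = c("M", "M+H", "M-H")) {
  f <- as_formula(f)
  if (!is.character(adduct) || !(adduct[1] %in% c("M", "M+H", "M-H"))) {
    stop("unknown adduct '", adduct[1],
         "'; supported adducts are M, M+H, M-H", call. = FALSE)
  }
  adduct <- adduct[1]
  m <- sum(vapply(names(f), function(el) {
    f[[el]] * .isotope_data[[el]]$mass[1]
  }, numeric(1)))
  switch(adduct,
         "M" = m,
         "M+H" = m + .proton_mass,
         "M-H" = m - .proton_mass)
}

#' Signed mass accuracy error in parts per million
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z; must be positive.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @examples
#' ppm_error(500.0005, 500.0)  # +1 ppm
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) {
    stop("theoretical m/z must be positive", call. = FALSE)
  }
  1e6 * (observed - theoretical) / theoretical
}

# Convolve two nominal-shift probability vectors, truncating at max_shift.
.conv_trunc <- function(a, b, max_shift) {
  n <- min(length(a) + length(b) - 1L, max_shift + 1L)
  out <- numeric(n)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    jmax <- min(length(b), n - i + 1L)
    if (jmax < 1L) break
    idx <- i + seq_len(jmax) - 1L
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

# n-fold self-convolution of a per-atom shift distribution (truncated).
.atoms_shift_dist <- function(d, n, max_shift) {
  out <- 1.0
  base <- d
  # binary exponentiation keeps this cheap for large atom counts
  while (n > 0L) {
    if (n %% 2L == 1L) out <- .conv_trunc(out, base, max_shift)
    n <- n %/% 2L
    if (n > 0L) base <- .conv_trunc(base, base, max_shift)
  }
  if (length(out) < max_shift + 1L) out <- c(out, numeric(max_shift + 1L - length(out)))
  out
}

#' Natural-abundance isotopologue distribution of a formula
#'
#' Probability of nominal mass shifts 0..`max_shift` obtained by convolving
#' the per-element multinomial isotope distributions. This is the
#' theoretical isotope pattern at unit resolution that an unlabeled
#' molecule produces on a QTOF instrument.
#'
#' @param f An `elemental_formula` or formula string.
#' @param max_shift Largest nominal shift to report (default: the carbon
#'   count, the ladder length used for tracer work).
#' @param exclude_tracer If `TRUE`, carbon contributes no 13C terms; used
#'   when natural 13C must not be part of the correction.
#' @return Numeric vector of length `max_shift + 1`, entries in \[0, 1\].
#'   The entries sum to 1 minus the (tiny) probability mass beyond
#'   `max_shift`.
#' @examples
#' natural_isotopologue_distribution("C", 1)  # c(0.9893, 0.0107)
#' natural_isotopologue_distribution("C6H12O6", 3)
#' @export
natural_isotopologue_distribution <- function(f, max_shift = NULL,
                                              exclude_tracer = FALSE) {
  f <- as_formula(f)
  if (is.null(max_shift)) max_shift <- carbon_count(f)
  stopifnot(max_shift >= 0)
  max_shift <- as.integer(max_shift)
  out <- 1.0
  for (el in names(f)) {
    d <- .atom_shift_dist(el, exclude_tracer = exclude_tracer)
    out <- .conv_trunc(out, .atoms_shift_dist(d, f[[el]], max_shift), max_shift)
  }
  if (length(out) < max_shift + 1L) out <- c(out, numeric(max_shift + 1L - length(out)))
  out
}

#' Natural-isotope correction matrix for a 13C tracer
#'
#' Builds the square matrix used by the matrix-based natural-abundance
#' correction. Column `j` (0-based) is the theoretical nominal mass-shift
#' distribution of a molecule in which exactly `j` carbon atoms are fixed
#' as 13C: those atoms contribute shift `j` deterministically, and the
#' remaining atoms (including the remaining `N - j` carbons unless
#' `exclude_tracer` is set) contribute natural-abundance shifts. Rows are
#' truncated at shift N, so columns sum to at most 1.
#'
#' A measured raw isotopologue vector `raw` relates to the tracer mass
#' isotopomer distribution `x` by `raw = cm %*% x`; see
#' [correct_natural_abundance()].
#'
#' @param f An `elemental_formula` or formula string containing at least
#'   one carbon.
#' @param exclude_tracer If `TRUE`, natural 13C on the unlabeled carbons is
#'   not modeled (and hence not corrected). Default `FALSE`, the usual
#'   convention for a 13C tracer.
#' @return An (N+1) x (N+1) matrix, N = carbon count.
#' @examples
#' cm <- correction_matrix("CH4")
#' cm[, 1]  # natural distribution of CH4
#' @export
correction_matrix <- function(f, exclude_tracer = FALSE) {
  f <- as_formula(f)
  n <- carbon_count(f)
  if (n < 1L) stop("formula must contain at least one carbon", call. = FALSE)
  cm <- matrix(0, n + 1L, n + 1L)
  counts <- unclass(f)
  for (j in 0:n) {
    rest <- counts
    rest[["C"]] <- n - j
    rest <- rest[rest > 0]
    d <- if (length(rest)) {
      natural_isotopologue_distribution(elemental_formula(rest),
                                        max_shift = n - j,
                                        exclude_tracer = exclude_tracer)
    } else {
      1.0
    }
    cm[j + seq_along(d), j + 1L] <- d
  }
  cm
}
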