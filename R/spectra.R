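#' Construct a centroided spectrum
#'
#' @param mz Numeric vector of peak m/z values (Da); will be sorted and
#'   must be strictly increasing after sorting.
#' @param intensity Non-negative peak intensities (arbitrary counts),
#'   parallel to `mz`.
#' @param rt Retention time in minutes.
#' @param ms_level MS level (1 for full scans, 2 for MS/MS).
#' @param precursor_mz Optional precursor m/z for MS2 scans.
#' @param polarity Optional polarity tag, `"pos"` or `"neg"`.
#' @return A `centroid_spectrum` object.
#' @export
centroid_spectrum <- function(mz, intensity, rt, ms_level = 1L,
                              precursor_mz = NA_real_, polarity = NA_character_) {
  stopifnot(length(mz) == length(intensity), rt >= 0)
  if (any(intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  o <- order(mz)
  mz <- mz[o]
  intensity <- intensity[o]
  if (length(mz) > 1L && any(diff(mz) <= 0)) {
    stop("m/z values must be strictly increasing", call. = FALSE)
  }
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity),
                 rt = as.numeric(rt), ms_level = as.integer(ms_level),
                 precursor_mz = as.numeric(precursor_mz),
                 polarity = polarity),
            class = "centroid_spectrum")
}

#' @export
print.centroid_spectrum <- function(x, ...) {
  cat(sprintf("<centroid_spectrum> MS%d, RT %.2f min, %d peaks\n",
              x$ms_level, x$rt, length(x$mz)))
  invisible(x)
}

#' Read centroided spectra from file
#'
#' Supports mzML (via the mzR package) and the package's delimited long
#' table format (columns `spectrum_id`, `rt`, `ms_level`, `precursor_mz`,
#' `mz`, `intensity`; tab-separated).
#'
#' @param path Path to a `.mzML` or delimited `.tsv`/`.txt` file.
#' @param format `"auto"` (by extension), `"mzML"` or `"table"`.
#' @return A list of [centroid_spectrum()] objects sorted by retention
#'   time.
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, format = c("auto", "mzML", "table")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "mzml") "mzML" else "table"
  }
  spectra <- if (format == "mzML") .read_mzml(path) else .read_spectra_table(path)
  spectra[order(vapply(spectra, `[[`, numeric(1), "rt"))]
}

.read_mzml <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package", call. = FALSE)
  }
  h <- NULL
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms), add = TRUE)
  h <- mzR::header(ms)
  if (nrow(h) == 0L) stop("no spectra in mzML file: ", path, call. = FALSE)
  lapply(seq_len(nrow(h)), function(i) {
    pk <- mzR::peaks(ms, i)
    centroid_spectrum(mz = pk[, 1], intensity = pk[, 2],
                      rt = h$retentionTime[i] / 60,  # mzR reports seconds
                      ms_level = h$msLevel[i],
                      precursor_mz = if (h$msLevel[i] > 1) h$precursorMZ[i] else NA_real_,
                      polarity = c("neg", NA, "pos")[h$polarity[i] + 2L])
  })
}

.read_spectra_table <- function(path) {
  df <- tryCatch(utils::read.delim(path, stringsAsFactors = FALSE),
                 error = function(e) {
                   stop("malformed spectrum table '", path, "': ",
                        conditionMessage(e), call. = FALSE)
                 })
  need <- c("spectrum_id", "rt", "ms_level", "precursor_mz", "mz", "intensity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("spectrum table '", path, "' lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("empty spectrum table: ", path, call. = FALSE)
  lapply(split(df, df$spectrum_id), function(s) {
    centroid_spectrum(mz = s$mz, intensity = s$intensity, rt = s$rt[1],
                      ms_level = s$ms_level[1], precursor_mz = s$precursor_mz[1],
                      polarity = if ("polarity" %in% names(s)) s$polarity[1] else NA_character_)
  })
}

#' Write centroided spectra to file
#'
#' @param spectra A list of [centroid_spectrum()] objects.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"mzML"` (requires mzR) or
#'   `"table"` (tab-separated long format; the reader's native format).
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path, format = c("auto", "mzML", "table")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "mzml") "mzML" else "table"
  }
  if (format == "mzML") return(.write_mzml(spectra, path))
  rows <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    if (!length(s$mz)) return(NULL)
    data.frame(spectrum_id = sprintf("S%05d", i), rt = s$rt,
               ms_level = s$ms_level, precursor_mz = s$precursor_mz,
               polarity = if (is.null(s$polarity)) NA_character_ else s$polarity,
               mz = s$mz, intensity = s$intensity, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

.write_mzml <- function(spectra, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("writing mzML requires the mzR package", call. = FALSE)
  }
  n <- length(spectra)
  pol <- vapply(spectra, function(s) {
    if (is.null(s$polarity) || is.na(s$polarity)) 1L else if (s$polarity == "neg") 0L else 1L
  }, integer(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = vapply(spectra, `[[`, integer(1), "ms_level"),
    polarity = pol,
    peaksCount = vapply(spectra, function(s) length(s$mz), integer(1)),
    totIonCurrent = vapply(spectra, function(s) sum(s$intensity), numeric(1)),
    retentionTime = vapply(spectra, `[[`, numeric(1), "rt") * 60,
    basePeakMZ = vapply(spectra, function(s) if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, numeric(1)),
    basePeakIntensity = vapply(spectra, function(s) if (length(s$mz)) max(s$intensity) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(spectra, function(s) if (length(s$mz)) min(s$mz) else 0, numeric(1)),
    highMZ = vapply(spectra, function(s) if (length(s$mz)) max(s$mz) else 0, numeric(1)),
    precursorScanNum = 0L,
    precursorMZ = vapply(spectra, function(s) if (is.na(s$precursor_mz)) 0 else s$precursor_mz, numeric(1)),
    precursorCharge = 0L, precursorIntensity = 0,
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = TRUE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = 50, scanWindowUpperLimit = 1200,
    stringsAsFactors = FALSE)
  pks <- lapply(spectra, function(s) cbind(mz = s$mz, intensity = s$intensity))
  mzR::writeMSData(pks, path, header = hdr)
  invisible(path)
}

#' Describe a feature to extract from spectra
#'
#' @param feature_id Feature identifier.
#' @param mz Monoisotopic (M+0) m/z of the feature.
#' @param rt Retention time in minutes.
#' @param formula Elemental formula (string or `elemental_formula`);
#'   its carbon count N sets the ladder length M+0..M+N.
#' @param polarity `"pos"` or `"neg"`.
#' @param adduct Adduct label (`"M"`, `"M+H"`, `"M-H"`), informational.
#' @return A `feature_target` object.
#' @export
feature_target <- function(feature_id, mz, rt, formula, polarity = "neg",
                           adduct = if (identical(polarity, "pos")) "M+H" else "M-H") {
  stopifnot(mz >= 50, mz <= 1200, rt >= 0)
  structure(list(feature_id = as.character(feature_id), mz = as.numeric(mz),
                 rt = as.numeric(rt), formula = as_formula(formula),
                 polarity = polarity, adduct = adduct),
            class = "feature_target")
}

#' Extract an isotopologue intensity ladder for a feature
#'
#' Sums, across all MS1 spectra whose retention time lies within
#' `rt_window` of the target, the intensity of peaks lying within
#' `mz_tol` of each ladder position `target mz + i * 1.003355`,
#' i = 0..N (N = carbon count of the target formula). A peak is assigned
#' to its nearest ladder slot; exact ties resolve toward the lower slot.
#' Absent peaks contribute zero.
#'
#' @param spectra List of [centroid_spectrum()] objects.
#' @param target A [feature_target()].
#' @param mz_tol Match tolerance, interpreted per `mz_tol_unit`
#'   (default 10 ppm, the usual QTOF setting).
#' @param mz_tol_unit `"ppm"` or `"Da"`.
#' @param rt_window Half-width of the retention-time window in minutes.
#' @return An `isotopologue_measurement`: list with `feature_id`,
#'   `intensity` (named vector M0..MN), `n_spectra` used, and `empty`
#'   (`TRUE` when no spectrum fell inside the RT window).
#' @export
extract_isotopologues <- function(spectra, target, mz_tol = 10,
                                  mz_tol_unit = c("ppm", "Da"),
                                  rt_window = 0.2) {
  mz_tol_unit <- match.arg(mz_tol_unit)
  n <- carbon_count(target$formula)
  stopifnot(n >= 1L)
  spacing <- c13_spacing()
  out <- numeric(n + 1L)
  names(out) <- paste0("M", 0:n)
  used <- 0L
  for (s in spectra) {
    if (s$ms_level != 1L) next
    if (abs(s$rt - target$rt) > rt_window) next
    used <- used + 1L
    if (!length(s$mz)) next
    d <- s$mz - target$mz
    # nearest ladder slot; floor(x + 0.5) sends exact half-way ties down
    slot <- floor(d / spacing + 0.5)
    ok <- slot >= 0 & slot <= n
    if (!any(ok)) next
    expected <- target$mz + slot * spacing
    tol <- if (mz_tol_unit == "ppm") mz_tol * 1e-6 * expected else mz_tol
    ok <- ok & abs(s$mz - expected) <= tol
    if (!any(ok)) next
    hits <- tapply(s$intensity[ok], slot[ok], sum)
    idx <- as.integer(names(hits)) + 1L
    out[idx] <- out[idx] + as.numeric(hits)
  }
  structure(list(feature_id = target$feature_id, intensity = out,
                 n_spectra = used, empty = used == 0L),
            class = "isotopologue_measurement")
}

#' @export
print.isotopologue_measurement <- function(x, ...) {
  cat(sprintf("<isotopologue_measurement> %s: %d slots, %d spectra%s\n",
              x$feature_id, length(x$intensity), x$n_spectra,
              if (x$empty) " (empty: no spectra in RT window)" else ""))
  invisible(x)
}
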