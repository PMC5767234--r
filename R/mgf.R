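# Minimal MGF (Mascot Generic Format) reader/writer for MS/MS peak lists.
# Only the keys this workflow needs are handled: TITLE (spectrum id),
# PEPMASS (precursor m/z), and a GROUP tag carrying the culture group.

#' Read MS/MS spectra from an MGF file
#'
#' @param path Path to an MGF file. Each `BEGIN IONS`/`END IONS` block
#'   becomes one spectrum; `TITLE` is used as the spectrum id, `PEPMASS`
#'   as the precursor m/z, and an optional `GROUP` key as the source
#'   group tag.
#' @return A list of [msms_spectrum()] objects.
#' @seealso [write_mgf()]
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  spectra <- list()
  in_block <- FALSE
  title <- NA_character_
  pepmass <- NA_real_
  group <- NA_character_
  mz <- numeric(0)
  intensity <- numeric(0)
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (line == "BEGIN IONS") {
      if (in_block) stop("malformed MGF at line ", ln, ": nested BEGIN IONS",
                         call. = FALSE)
      in_block <- TRUE
      title <- NA_character_
      pepmass <- NA_real_
      group <- NA_character_
      mz <- numeric(0)
      intensity <- numeric(0)
    } else if (line == "END IONS") {
      if (!in_block) stop("malformed MGF at line ", ln, ": END IONS without BEGIN",
                          call. = FALSE)
      if (is.na(pepmass)) stop("malformed MGF at line ", ln, ": block lacks PEPMASS",
                               call. = FALSE)
      spectra[[length(spectra) + 1L]] <- msms_spectrum(
        precursor_mz = pepmass, mz = mz, intensity = intensity,
        id = if (is.na(title)) sprintf("spectrum_%d", length(spectra) + 1L) else title,
        group = group)
      in_block <- FALSE
    } else if (in_block && grepl("=", line, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", line))
      val <- sub("^[^=]*=", "", line)
      if (key == "TITLE") title <- val
      if (key == "PEPMASS") pepmass <- as.numeric(strsplit(val, "\\s+")[[1]][1])
      if (key == "GROUP") group <- val
    } else if (in_block) {
      parts <- strsplit(line, "[\t ]+")[[1]]
      if (length(parts) < 2L || anyNA(suppressWarnings(as.numeric(parts[1:2])))) {
        stop("malformed MGF at line ", ln, ": expected 'mz intensity'",
             call. = FALSE)
      }
      mz <- c(mz, as.numeric(parts[1]))
      intensity <- c(intensity, as.numeric(parts[2]))
    }
  }
  if (in_block) stop("malformed MGF: unterminated BEGIN IONS block", call. = FALSE)
  spectra
}

#' Write MS/MS spectra to an MGF file
#'
#' @param spectra List of [msms_spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$id), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    if (!is.na(s$group)) writeLines(paste0("GROUP=", s$group), con)
    writeLines(sprintf("%.6f %.6g", s$mz, s$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}
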