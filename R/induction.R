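#' Construct a feature-by-sample intensity matrix
#'
#' The container for aligned, gap-filled LC-MS feature tables: a numeric
#' intensity matrix plus sample metadata (culture group, biological and
#' analytical replicate) and feature metadata (m/z, RT, polarity,
#' optional formula).
#'
#' @param intensity Numeric matrix, features x samples, non-negative.
#' @param samples Data frame with one row per column of `intensity` and
#'   columns `sample_id`, `group` (one of `"co"`, `"monoA"`, `"monoB"`),
#'   `bio`, `tech`.
#' @param features Data frame with one row per row of `intensity` and
#'   columns `feature_id`, `mz`, `rt`, `polarity`; optionally `formula`.
#' @return A `feature_matrix` object.
#' @export
feature_matrix <- function(intensity, samples, features) {
  intensity <- as.matrix(intensity)
  stopifnot(nrow(samples) == ncol(intensity), nrow(features) == nrow(intensity))
  if (any(intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  need_s <- c("sample_id", "group", "bio", "tech")
  if (!all(need_s %in% names(samples))) {
    stop("sample metadata needs columns: ", paste(need_s, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(samples$group))) stop("every sample needs a group", call. = FALSE)
  need_f <- c("feature_id", "mz", "rt", "polarity")
  if (!all(need_f %in% names(features))) {
    stop("feature metadata needs columns: ", paste(need_f, collapse = ", "),
         call. = FALSE)
  }
  rownames(intensity) <- features$feature_id
  colnames(intensity) <- samples$sample_id
  structure(list(intensity = intensity, samples = samples, features = features),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d features x %d samples (%s)\n",
              nrow(x$intensity), ncol(x$intensity),
              paste(names(table(x$samples$group)), table(x$samples$group),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

#' Write / read a feature matrix as a delimited file
#'
#' One tab-separated file: feature metadata columns first, then one
#' intensity column per sample named `group.bio.tech`.
#'
#' @param fm A [feature_matrix()].
#' @param path File path.
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` returns a `feature_matrix`.
#' @export
write_feature_matrix <- function(fm, path) {
  cn <- with(fm$samples, paste(group, bio, tech, sep = "."))
  df <- cbind(fm$features, as.data.frame(fm$intensity))
  names(df)[(ncol(fm$features) + 1):ncol(df)] <- cn
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta_cols <- intersect(c("feature_id", "mz", "rt", "polarity", "formula"),
                         names(df))
  sample_cols <- setdiff(names(df), meta_cols)
  parts <- strsplit(sample_cols, ".", fixed = TRUE)
  samples <- data.frame(
    sample_id = sample_cols,
    group = vapply(parts, `[`, character(1), 1),
    bio = as.integer(vapply(parts, `[`, character(1), 2)),
    tech = as.integer(vapply(parts, `[`, character(1), 3)),
    stringsAsFactors = FALSE)
  feature_matrix(as.matrix(df[sample_cols]), samples, df[meta_cols])
}

# Per-feature biological-replicate means for one group (analytical
# replicates averaged first).
.bio_means <- function(fm, group) {
  sel <- fm$samples$group == group
  sub <- fm$intensity[, sel, drop = FALSE]
  bio <- fm$samples$bio[sel]
  t(apply(sub, 1L, function(v) aggregate_analytical(v, bio)))
}

#' Fold change of a feature between co-culture and mono-culture
#'
#' Ratio of group means, with an SD propagated across per-biological-
#' replicate ratios. When the mono-culture mean lies below the detection
#' floor no ratio is defined and the feature follows the
#' "newly synthesized" path instead.
#'
#' @param co Per-biological-replicate mean intensities in the co-culture.
#' @param mono Per-biological-replicate mean intensities in the
#'   mono-culture (paired with `co` by position).
#' @param detection_floor Intensity below which the mono-culture is
#'   considered absent (default 1e3, the usual peak-detection threshold).
#' @return List with `ratio`, `sd` (SD of per-replicate ratios; `NA` when
#'   replicates are unpaired) and `newly_synthesized` (logical).
#' @examples
#' fold_change(c(15, 16, 15.5) * 1e4, c(1, 1.1, 0.9) * 1e4)
#' @export
fold_change <- function(co, mono, detection_floor = 1e3) {
  if (mean(mono) < detection_floor) {
    return(list(ratio = NA_real_, sd = NA_real_, newly_synthesized = TRUE))
  }
  ratio <- mean(co) / mean(mono)
  sd <- if (length(co) == length(mono) && length(co) > 1L) {
    stats::sd(co / mono)
  } else {
    NA_real_
  }
  list(ratio = ratio, sd = sd, newly_synthesized = FALSE)
}

#' Detect features induced by the co-culture
#'
#' Classifies each feature of a three-group feature matrix as
#' `newly_synthesized` (detected in the co-culture, absent from both
#' control mono-cultures), `fold_increased` (at least `fold_threshold`
#' times more intense in the co-culture than the larger of the two
#' mono-culture means), or neither. Detection in the co-culture requires
#' the biological-replicate mean to clear the detection floor in at least
#' `min_detected_reps` replicates. "Absent" from a mono-culture is judged
#' against a much lower `absence_floor`: gap-filled feature tables carry
#' real sub-threshold intensities for strongly fold-increased features
#' (a 400-fold increase at co-culture signal 4e4 implies a mono signal of
#' 100 counts), so a truly absent feature is one whose gap-filled mono
#' signal is essentially zero, not merely below the peak-detection
#' threshold.
#'
#' @param fm A [feature_matrix()] containing groups `"co"`, `"monoA"`,
#'   `"monoB"`.
#' @param fold_threshold Minimum co/mono ratio for the fold-increase call
#'   (default 5).
#' @param detection_floor MS-signal peak-detection threshold (default 1e3
#'   counts), applied to co-culture detection.
#' @param min_detected_reps Biological replicates that must clear the
#'   floor for the co-culture detection call (default 2 of 3).
#' @param absence_floor Mono-culture mean below which a feature counts as
#'   absent (default `detection_floor / 100`).
#' @return A data frame of induced features: `feature_id`, `class`,
#'   `ratio`, `ratio_sd`, `co_mean`.
#' @export
detect_induced <- function(fm, fold_threshold = 5, detection_floor = 1e3,
                           min_detected_reps = 2L,
                           absence_floor = detection_floor / 100) {
  groups <- unique(fm$samples$group)
  missing_groups <- setdiff(c("co", "monoA", "monoB"), groups)
  if (length(missing_groups)) {
    stop("feature matrix lacks culture group(s): ",
         paste(missing_groups, collapse = ", "), call. = FALSE)
  }
  co <- .bio_means(fm, "co")
  ma <- .bio_means(fm, "monoA")
  mb <- .bio_means(fm, "monoB")
  rows <- vector("list", nrow(co))
  for (i in seq_len(nrow(co))) {
    co_detected <- sum(co[i, ] >= detection_floor) >= min_detected_reps
    if (!co_detected) next
    mean_a <- mean(ma[i, ])
    mean_b <- mean(mb[i, ])
    if (mean_a < absence_floor && mean_b < absence_floor) {
      rows[[i]] <- data.frame(feature_id = fm$features$feature_id[i],
                              class = "newly_synthesized",
                              ratio = NA_real_, ratio_sd = NA_real_,
                              co_mean = mean(co[i, ]),
                              stringsAsFactors = FALSE)
      next
    }
    # conservative: compare against the larger control mono-culture
    mono <- if (mean_a >= mean_b) ma[i, ] else mb[i, ]
    fc <- fold_change(co[i, ], mono, detection_floor = absence_floor)
    if (!fc$newly_synthesized && fc$ratio >= fold_threshold) {
      rows[[i]] <- data.frame(feature_id = fm$features$feature_id[i],
                              class = "fold_increased",
                              ratio = fc$ratio, ratio_sd = fc$sd,
                              co_mean = mean(co[i, ]),
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(feature_id = character(0), class = character(0),
                      ratio = numeric(0), ratio_sd = numeric(0),
                      co_mean = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
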