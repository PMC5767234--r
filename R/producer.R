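#' Assign an induced feature to its producing organism(s)
#'
#' An organism is credited as producer when the feature is significantly
#' 13C-labeled in that organism's post-induction mono-culture (with
#' co-culture supernatant) at any timepoint; slow labelers are often only
#' weakly labeled early, so one labeled timepoint suffices.
#'
#' @param results_A,results_B Lists of [labeling_result()] objects for the
#'   two organism arms, with-supernatant condition, one per timepoint.
#' @return A `producer_call`: list with `feature_id`, `call` (one of
#'   `"A_only"`, `"B_only"`, `"both"`, `"unassigned"`) and the supporting
#'   per-arm evidence.
#' @export
assign_producer <- function(results_A, results_B) {
  if (inherits(results_A, "labeling_result")) results_A <- list(results_A)
  if (inherits(results_B, "labeling_result")) results_B <- list(results_B)
  if (!length(results_A) || !length(results_B)) {
    stop("labeling results are required for both organism arms", call. = FALSE)
  }
  feature_id <- results_A[[1]]$feature_id
  lab_a <- any(vapply(results_A, function(r) isTRUE(r$labeled), logical(1)))
  lab_b <- any(vapply(results_B, function(r) isTRUE(r$labeled), logical(1)))
  call <- if (lab_a && lab_b) "both"
  else if (lab_a) "A_only"
  else if (lab_b) "B_only"
  else "unassigned"
  evidence <- do.call(rbind, lapply(c(results_A, results_B), function(r) {
    data.frame(organism = r$organism, day = r$day, condition = r$condition,
               incorporation = r$mean, p_value = r$p_value,
               labeled = isTRUE(r$labeled), stringsAsFactors = FALSE)
  }))
  structure(list(feature_id = feature_id, call = call, evidence = evidence,
                 supernatant_dependent = NA, physical_interaction = FALSE),
            class = "producer_call")
}

#' @export
print.producer_call <- function(x, ...) {
  cat(sprintf("<producer_call> %s: %s\n", x$feature_id, x$call))
  invisible(x)
}

#' Flag dependence of labeling on the co-culture supernatant
#'
#' A feature whose labeling requires added co-culture supernatant points
#' to diffusible signaling molecules as the induction mechanism.
#'
#' @param with_sup,without_sup [labeling_result()] objects (or lists over
#'   timepoints) for the same feature and organism, with and without
#'   supernatant.
#' @return `TRUE` (dependent), `FALSE` (constitutively labeled), or `NA`
#'   (not evaluable: unlabeled in both conditions or a condition missing).
#' @export
supernatant_dependence <- function(with_sup, without_sup) {
  if (inherits(with_sup, "labeling_result")) with_sup <- list(with_sup)
  if (inherits(without_sup, "labeling_result")) without_sup <- list(without_sup)
  if (!length(with_sup) || !length(without_sup)) return(NA)
  lab_with <- any(vapply(with_sup, function(r) isTRUE(r$labeled), logical(1)))
  lab_without <- any(vapply(without_sup, function(r) isTRUE(r$labeled), logical(1)))
  if (!lab_with && !lab_without) return(NA)
  lab_with && !lab_without
}

#' Flag a physical-interaction candidate
#'
#' An induced feature with strong co-culture signal but no 13C
#' incorporation in either separated mono-culture suggests that its
#' synthesis requires direct mycelial contact. Weak-signal unassigned
#' features are not flagged (their missing label is attributed to
#' sensitivity, not mechanism).
#'
#' @param induced One row of the [detect_induced()] table (needs
#'   `co_mean`).
#' @param call A `producer_call` for the same feature.
#' @param high_signal_floor Co-culture mean intensity required for the
#'   flag (default 1e4 counts).
#' @return Logical flag.
#' @export
flag_physical_interaction <- function(induced, call, high_signal_floor = 1e4) {
  call$call == "unassigned" && induced$co_mean >= high_signal_floor
}

#' Merge cross-polarity duplicates into compound-level calls
#'
#' Features detected in both ionization modes appear twice in a feature
#' table. Rows sharing an elemental formula whose retention times agree
#' within `rt_tol` are merged into one compound-level producer call;
#' conflicting calls resolve to the union (`both` > single organism >
#' `unassigned`) with a conflict note. Same-formula features further apart
#' in RT are kept separate (isomers).
#'
#' @param calls Data frame with columns `feature_id` and `call` (and any
#'   further columns, carried from the first member of each compound).
#' @param targets Data frame with columns `feature_id`, `formula`, `rt`.
#' @param rt_tol Retention-time tolerance in minutes (default 0.2).
#' @return Data frame of compound-level calls with columns `compound_id`,
#'   `members` (semicolon-joined feature ids), `n_members`, `call`,
#'   `conflict`, plus carried columns.
#' @export
deduplicate_features <- function(calls, targets, rt_tol = 0.2) {
  stopifnot(all(c("feature_id", "call") %in% names(calls)),
            all(c("feature_id", "formula", "rt") %in% names(targets)))
  idx <- match(calls$feature_id, targets$feature_id)
  if (anyNA(idx)) {
    stop("no target metadata for feature(s): ",
         paste(calls$feature_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  fstr <- vapply(targets$formula[idx], function(f) formula_string(as_formula(f)),
                 character(1))
  rt <- targets$rt[idx]
  ord <- order(fstr, rt)
  group <- integer(nrow(calls))
  gid <- 0L
  last_f <- ""
  last_rt <- -Inf
  for (k in ord) {
    if (fstr[k] != last_f || rt[k] - last_rt > rt_tol) gid <- gid + 1L
    group[k] <- gid
    last_f <- fstr[k]
    last_rt <- rt[k]
  }
  merge_calls <- function(cs) {
    cs <- unique(cs)
    if ("both" %in% cs || all(c("A_only", "B_only") %in% cs)) return("both")
    if ("A_only" %in% cs) return("A_only")
    if ("B_only" %in% cs) return("B_only")
    "unassigned"
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(calls)), group), function(ii) {
    cs <- calls$call[ii]
    merged <- merge_calls(cs)
    conflict <- length(unique(cs)) > 1L
    row <- calls[ii[1], setdiff(names(calls), c("feature_id", "call")), drop = FALSE]
    cbind(data.frame(compound_id = paste0(fstr[ii[1]], "@", round(min(rt[ii]), 2)),
                     members = paste(calls$feature_id[ii], collapse = ";"),
                     n_members = length(ii), call = merged,
                     conflict = if (conflict) paste(sort(unique(cs)), collapse = "|") else "",
                     stringsAsFactors = FALSE),
          row)
  }))
  rownames(out) <- NULL
  out
}
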