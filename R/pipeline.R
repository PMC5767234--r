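#' Pipeline configuration
#'
#' Collects every tunable threshold of the workflow in one validated
#' object that round-trips through a YAML file.
#'
#' @param seed Scenario / simulation seed.
#' @param n_background Background features in the simulated matrix.
#' @param noise_sd Relative SD of multiplicative intensity noise.
#' @param fold_threshold Minimum co/mono fold change for induction
#'   (default 5).
#' @param detection_floor MS peak-detection threshold (default 1e3).
#' @param alpha Significance level of the labeling t-tests (default
#'   0.05).
#' @param enrichment_floor Minimum mean 13C incorporation (%) for a
#'   labeled call (default 1).
#' @param high_signal_floor Co-culture intensity for the
#'   physical-interaction flag (default 1e4).
#' @param mz_tol,rt_window Isotopologue extraction tolerances (10 ppm,
#'   0.2 min).
#' @param dedup_rt_tol RT tolerance for cross-polarity deduplication
#'   (0.2 min).
#' @param min_cosine,min_matched,max_component,min_cluster Molecular
#'   network parameters (0.65, 6, 50, 2).
#' @param do_network Whether to run the networking stage.
#' @return A `pipeline_config` object (a validated named list).
#' @export
pipeline_config <- function(seed = 1L, n_background = 4000L, noise_sd = 0.05,
                            fold_threshold = 5, detection_floor = 1e3,
                            alpha = 0.05, enrichment_floor = 1,
                            high_signal_floor = 1e4,
                            mz_tol = 10, rt_window = 0.2, dedup_rt_tol = 0.2,
                            min_cosine = 0.65, min_matched = 6L,
                            max_component = 50L, min_cluster = 2L,
                            do_network = TRUE) {
  cfg <- list(seed = as.integer(seed), n_background = as.integer(n_background),
              noise_sd = noise_sd, fold_threshold = fold_threshold,
              detection_floor = detection_floor, alpha = alpha,
              enrichment_floor = enrichment_floor,
              high_signal_floor = high_signal_floor, mz_tol = mz_tol,
              rt_window = rt_window, dedup_rt_tol = dedup_rt_tol,
              min_cosine = min_cosine, min_matched = as.integer(min_matched),
              max_component = as.integer(max_component),
              min_cluster = as.integer(min_cluster),
              do_network = isTRUE(do_network))
  for (key in c("fold_threshold", "detection_floor", "alpha",
                "enrichment_floor", "high_signal_floor", "mz_tol",
                "rt_window", "dedup_rt_tol", "min_cosine")) {
    if (!is.numeric(cfg[[key]]) || cfg[[key]] <= 0) {
      stop("configuration value '", key, "' must be positive", call. = FALSE)
    }
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' @param path YAML file path.
#' @param cfg A [pipeline_config()].
#' @return `read_pipeline_config` returns a validated `pipeline_config`;
#'   `write_pipeline_config` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals[intersect(names(vals),
                                          names(formals(pipeline_config)))])
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Run extraction + correction + incorporation for every induced feature
# across the labeling arms of one scenario. Returns a long data frame
# with one row per feature x organism x day x condition x replicate.
.labeling_measurements <- function(sc, targets, mz_tol = 10, rt_window = 0.2) {
  cm_cache <- new.env(parent = emptyenv())
  get_cm <- function(f) {
    key <- formula_string(f)
    if (is.null(cm_cache[[key]])) cm_cache[[key]] <- correction_matrix(f)
    cm_cache[[key]]
  }
  arms <- rbind(
    expand.grid(organism = c("A", "B"), day = sc$days,
                condition = c("with_sup", "without_sup"),
                stringsAsFactors = FALSE),
    data.frame(organism = c("A", "B"), day = NA_integer_,
               condition = "baseline", stringsAsFactors = FALSE))
  rows <- list()
  for (a in seq_len(nrow(arms))) {
    samples <- simulate_labeling_spectra(
      sc, organism = arms$organism[a],
      day = if (is.na(arms$day[a])) sc$days[1] else arms$day[a],
      condition = arms$condition[a])
    for (smp in samples) {
      rts <- vapply(smp$spectra, `[[`, numeric(1), "rt")
      for (tg in targets) {
        sub <- smp$spectra[abs(rts - tg$rt) <= rt_window]
        meas <- extract_isotopologues(sub, tg, mz_tol = mz_tol,
                                      rt_window = rt_window)
        inc <- if (meas$empty || sum(meas$intensity) <= 0) NA_real_ else {
          mid <- correct_natural_abundance(meas$intensity, get_cm(tg$formula))
          total_incorporation(mid)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = tg$feature_id, organism = smp$organism,
          day = arms$day[a], condition = smp$condition,
          bio = smp$bio, tech = smp$tech, incorporation = inc,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# Collapse analytical replicates and attach significance calls. Returns
# a list: `results` (nested feature -> organism -> condition/day
# labeling_result objects) and `table` (long per-arm summary).
.labeling_statistics <- function(meas, alpha, enrichment_floor) {
  out <- list()
  tab <- list()
  for (fid in unique(meas$feature_id)) {
    mf <- meas[meas$feature_id == fid, ]
    out[[fid]] <- list()
    for (org in c("A", "B")) {
      mo <- mf[mf$organism == org, ]
      base <- mo[mo$condition == "baseline", ]
      base_bio <- aggregate_analytical(base$incorporation, base$bio)
      arms <- unique(mo[mo$condition != "baseline", c("day", "condition")])
      res <- list(baseline = base_bio)
      for (k in seq_len(nrow(arms))) {
        sel <- mo$condition == arms$condition[k] & mo$day == arms$day[k]
        inc_bio <- aggregate_analytical(mo$incorporation[sel], mo$bio[sel])
        sig <- labeling_significance(inc_bio, base_bio, alpha = alpha,
                                     enrichment_floor = enrichment_floor)
        lr <- labeling_result(fid, org, arms$day[k], arms$condition[k],
                              inc_bio, p_value = sig$p_value,
                              labeled = sig$labeled)
        res[[paste(arms$condition[k], arms$day[k], sep = "_d")]] <- lr
        tab[[length(tab) + 1L]] <- data.frame(
          feature_id = fid, organism = org, day = arms$day[k],
          condition = arms$condition[k], incorporation = lr$mean,
          sd = lr$sd, p_value = lr$p_value, labeled = lr$labeled,
          stringsAsFactors = FALSE)
      }
      out[[fid]][[org]] <- res
    }
  }
  list(results = out, table = do.call(rbind, tab))
}

#' Run the full co-culture labeling pipeline
#'
#' Executes induction detection, 13C-labeling analysis, producer
#' assignment (with supernatant-dependence and physical-interaction
#' flags) and, optionally, molecular networking on the packaged synthetic
#' scenario, and summarizes the partition of induced features.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional directory; when given, the stage tables are
#'   written there as tab-separated files (`induced.tsv`,
#'   `labeling.tsv`, `producers.tsv`, `network.graphml`, `summary.yaml`).
#' @param quiet Suppress per-stage progress messages.
#' @return A `pipeline_report`: list of stage tables and summary counts.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  sc <- coculture_scenario(seed = cfg$seed, n_background = cfg$n_background,
                           noise_sd = cfg$noise_sd)
  say("[simulate] scenario seed %d: %d features", cfg$seed, nrow(sc$roster))

  fm <- simulate_feature_matrix(sc)
  induced <- detect_induced(fm, fold_threshold = cfg$fold_threshold,
                            detection_floor = cfg$detection_floor)
  say("[induce] %d induced features (%d newly synthesized, %d fold-increased)",
      nrow(induced), sum(induced$class == "newly_synthesized"),
      sum(induced$class == "fold_increased"))

  targets <- scenario_targets(sc)
  targets <- targets[intersect(names(targets), induced$feature_id)]
  meas <- .labeling_measurements(sc, targets, mz_tol = cfg$mz_tol,
                                 rt_window = cfg$rt_window)
  stats <- .labeling_statistics(meas, alpha = cfg$alpha,
                                enrichment_floor = cfg$enrichment_floor)
  say("[label] %d features x organism/day/condition arms analyzed",
      length(stats$results))

  calls <- lapply(names(stats$results), function(fid) {
    r <- stats$results[[fid]]
    with_a <- r$A[grep("^with_sup", names(r$A))]
    with_b <- r$B[grep("^with_sup", names(r$B))]
    call <- assign_producer(with_a, with_b)
    dep <- c(A = supernatant_dependence(with_a, r$A[grep("^without_sup", names(r$A))]),
             B = supernatant_dependence(with_b, r$B[grep("^without_sup", names(r$B))]))
    call$supernatant_dependent <- if (all(is.na(dep))) NA else any(dep, na.rm = TRUE)
    ind_row <- induced[induced$feature_id == fid, ]
    call$physical_interaction <- flag_physical_interaction(
      ind_row, call, high_signal_floor = cfg$high_signal_floor)
    # labeling kinetics at the with-supernatant condition
    traj <- function(r_org) {
      if (length(r_org) < 2L) return("not_applicable")
      steady_state_assessment(r_org[[1]], r_org[[2]], alpha = cfg$alpha)
    }
    data.frame(feature_id = fid, call = call$call,
               supernatant_dependent = call$supernatant_dependent,
               physical_interaction = call$physical_interaction,
               trajectory_A = traj(with_a), trajectory_B = traj(with_b),
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)

  target_meta <- do.call(rbind, lapply(targets, function(tg) {
    data.frame(feature_id = tg$feature_id,
               formula = formula_string(tg$formula), rt = tg$rt,
               stringsAsFactors = FALSE)
  }))
  compounds <- deduplicate_features(calls, target_meta,
                                    rt_tol = cfg$dedup_rt_tol)
  partition <- table(factor(compounds$call,
                            levels = c("A_only", "B_only", "both", "unassigned")))
  say("[assign] producers: %s",
      paste(names(partition), as.integer(partition), sep = "=", collapse = ", "))

  net <- NULL
  if (cfg$do_network) {
    net <- build_network(scenario_msms_spectra(sc),
                         min_cosine = cfg$min_cosine,
                         min_matched = cfg$min_matched,
                         max_component = cfg$max_component,
                         min_cluster = cfg$min_cluster)
    say("[network] %d nodes in %d components", nrow(net$nodes),
        length(unique(net$nodes$component)))
  }

  summary_counts <- list(
    n_features = nrow(fm$intensity),
    n_induced = nrow(induced),
    n_newly_synthesized = sum(induced$class == "newly_synthesized"),
    n_fold_increased = sum(induced$class == "fold_increased"),
    n_labeled = sum(compounds$call != "unassigned"),
    n_A_only = unname(partition[["A_only"]]),
    n_B_only = unname(partition[["B_only"]]),
    n_both = unname(partition[["both"]]),
    n_unassigned = unname(partition[["unassigned"]]),
    n_physical_interaction = sum(calls$physical_interaction),
    n_supernatant_dependent = sum(calls$supernatant_dependent, na.rm = TRUE),
    n_steady = sum(apply(calls[c("trajectory_A", "trajectory_B")] == "steady",
                         1, any)),
    n_increasing = sum(apply(calls[c("trajectory_A", "trajectory_B")] == "increasing",
                             1, any)),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  report <- structure(list(config = cfg, induced = induced,
                           labeling = stats$table, calls = calls,
                           compounds = compounds, network = net,
                           summary = summary_counts),
                      class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(induced, file.path(out_dir, "induced.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(stats$table, file.path(out_dir, "labeling.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(calls, file.path(out_dir, "producers.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(compounds, file.path(out_dir, "compounds.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(net)) export_network(net, file.path(out_dir, "network.graphml"))
    yaml::write_yaml(summary_counts, file.path(out_dir, "summary.yaml"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_report>\n")
  cat(sprintf("  features: %d total, %d induced (%d newly synthesized, %d fold-increased)\n",
              s$n_features, s$n_induced, s$n_newly_synthesized,
              s$n_fold_increased))
  cat(sprintf("  producers: A_only=%d, B_only=%d, both=%d, unassigned=%d (labeled %d)\n",
              s$n_A_only, s$n_B_only, s$n_both, s$n_unassigned, s$n_labeled))
  cat(sprintf("  flags: %d physical-interaction candidates, %d supernatant-dependent\n",
              s$n_physical_interaction, s$n_supernatant_dependent))
  cat(sprintf("  kinetics: %d steady, %d increasing\n", s$n_steady, s$n_increasing))
  if (!is.null(x$network)) {
    cat(sprintf("  network: %d nodes, %d edges\n", nrow(x$network$nodes),
                nrow(x$network$edges)))
  }
  cat(sprintf("  elapsed: %.1f s\n", s$elapsed_s))
  invisible(x)
}
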