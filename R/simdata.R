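# Seeded synthetic-data generator. The packaged scenario encodes, at
# compound level, the induced-feature roster of the T. versicolor /
# G. applanatum co-culture experiment the pipeline is built for: 58 newly
# synthesized + 16 fold-increased features among ~4,000 background
# features, producer truth 20 (organism A = T. versicolor) / 6 (organism
# B = G. applanatum) / 5 (both) / 43 (none), 12 of the 43 with high
# co-culture signal, and per-feature binomial 13C enrichment trajectories
# at days 10 and 20.

# Evaluate expr under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max, kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  expr
}

#' Load the packaged induced-feature roster
#'
#' Compound-level list of the 74 co-culture-induced features with their
#' planted truth: induction class and fold ratio, producing organism,
#' co-culture intensity, high-signal flag, per-organism per-day binomial
#' 13C enrichment, labeling trajectory and supernatant dependence. One
#' roster entry (`F453.2101`, flagged in the `synthetic` column) is a
#' constructed feature added to reconcile the compound-level table with
#' the experiment's headline tallies.
#'
#' @return A data frame with one row per induced compound.
#' @export
induced_roster <- function() {
  path <- system.file("extdata", "induced_features.tsv", package = "cotracer",
                      mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$feature_id <- as.character(df$feature_id)
  df
}

#' Build the packaged co-culture labeling scenario
#'
#' Assembles the full synthetic study design: the induced-feature roster
#' (see [induced_roster()]), `n_background` unremarkable background
#' features, the replicate design (3 biological x 2 analytical), the two
#' sampling days, the log-normal intensity noise level, and two MS/MS
#' structural families for networking.
#'
#' @param seed Integer seed; all generated data are deterministic given
#'   the seed.
#' @param n_background Number of background (non-induced) features
#'   (default 4000).
#' @param noise_sd Relative SD of the multiplicative log-normal intensity
#'   noise (default 0.05; 0 gives noiseless data).
#' @param n_bio,n_tech Biological and analytical replicates per sample
#'   (defaults 3 and 2).
#' @param days Sampling days of the labeling mono-cultures (default
#'   c(10, 20)).
#' @return A `coculture_scenario` object.
#' @examples
#' sc <- coculture_scenario(seed = 1)
#' table(sc$roster$class)
#' @export
coculture_scenario <- function(seed = 1L, n_background = 4000L,
                               noise_sd = 0.05, n_bio = 3L, n_tech = 2L,
                               days = c(10L, 20L)) {
  stopifnot(noise_sd >= 0, n_background >= 0, n_bio >= 2, n_tech >= 1)
  ind <- induced_roster()
  stopifnot(!anyDuplicated(ind$feature_id),
            all(ind$p10_A >= 0 & ind$p10_A <= 1),
            all(ind$p20_B >= 0 & ind$p20_B <= 1),
            all(is.na(ind$ratio) | ind$ratio >= 1))
  bg <- if (n_background == 0L) ind[0, ] else with_seed(seed, {
    data.frame(
      feature_id = sprintf("BG%04d", seq_len(n_background)),
      mz = stats::runif(n_background, 50, 1200),
      rt = stats::runif(n_background, 0.5, 28),
      polarity = sample(c("neg", "pos"), n_background, replace = TRUE),
      formula = NA_character_,
      class = "background",
      ratio = NA_real_, ratio_sd = NA_real_,
      producer = "none",
      intensity = 10^stats::runif(n_background, 3.1, 5),
      high_signal = FALSE, trajectory = "na",
      p10_A = 0, p20_A = 0, p10_B = 0, p20_B = 0,
      sup_dependent = NA, synthetic = FALSE,
      stringsAsFactors = FALSE)
  })
  roster <- rbind(ind, bg)
  fam1 <- list(
    name = "formamide_analogs",
    backbone_mz = c(65.039, 77.039, 81.034, 92.050, 95.049, 108.044,
                    120.045, 123.032),
    precursors = c(168.0653, 140.0708, 150.0548, 230.1177, 287.1030,
                   196.0944, 216.1021))
  fam2 <- list(
    name = "polyketide_derivatives",
    backbone_mz = c(77.040, 91.054, 117.034, 145.028, 163.039, 189.070,
                    207.081, 235.076),
    precursors = c(279.0656, 251.0712, 281.0808, 306.0775, 334.0733,
                   581.1208, 629.1419))
  structure(list(seed = as.integer(seed), n_background = as.integer(n_background),
                 noise_sd = noise_sd, n_bio = as.integer(n_bio),
                 n_tech = as.integer(n_tech), days = as.integer(days),
                 roster = roster, msms_families = list(fam1, fam2)),
            class = "coculture_scenario")
}

#' @export
print.coculture_scenario <- function(x, ...) {
  ind <- x$roster[x$roster$class != "background", ]
  cat(sprintf(paste0("<coculture_scenario> seed %d: %d induced features ",
                     "(%d newly synthesized, %d fold-increased) + %d background\n"),
              x$seed, nrow(ind), sum(ind$class == "newly_synthesized"),
              sum(ind$class == "fold_increased"), x$n_background))
  cat("  producer truth:",
      paste(names(table(ind$producer)), table(ind$producer), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Feature targets of the packaged scenario's induced features
#'
#' @param sc A [coculture_scenario()].
#' @return A named list of [feature_target()] objects, one per induced
#'   feature.
#' @export
scenario_targets <- function(sc) {
  ind <- sc$roster[sc$roster$class != "background", ]
  targets <- lapply(seq_len(nrow(ind)), function(i) {
    feature_target(ind$feature_id[i], ind$mz[i], ind$rt[i],
                   formula = ind$formula[i], polarity = ind$polarity[i])
  })
  names(targets) <- ind$feature_id
  targets
}

# mean-preserving multiplicative log-normal noise
.lognoise <- function(n, noise_sd) {
  if (noise_sd == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + noise_sd^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Simulate the aligned feature matrix of the co-culture comparison
#'
#' Produces the features x samples intensity table of the three culture
#' groups (co-culture and the two control mono-cultures). Group means
#' honor the planted truth: background features are equal across groups;
#' newly synthesized features are absent (zero) from both mono-cultures;
#' fold-increased features sit at `intensity / ratio` in both
#' mono-cultures. Each cell gets mean-preserving multiplicative
#' log-normal noise; with `noise_sd = 0` group means are exact. The
#' result is deterministic given the scenario seed.
#'
#' @param sc A [coculture_scenario()].
#' @return A [feature_matrix()].
#' @export
simulate_feature_matrix <- function(sc) {
  r <- sc$roster
  mono_mean <- ifelse(r$class == "background", r$intensity,
                      ifelse(r$class == "newly_synthesized", 0,
                             r$intensity / r$ratio))
  groups <- c("co", "monoA", "monoB")
  design <- expand.grid(tech = seq_len(sc$n_tech), bio = seq_len(sc$n_bio),
                        group = groups, stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = with(design, paste(group, bio, tech, sep = ".")),
    group = design$group, bio = design$bio, tech = design$tech,
    stringsAsFactors = FALSE)
  means <- cbind(co = r$intensity, monoA = mono_mean, monoB = mono_mean)
  intensity <- with_seed(sc$seed + 1L, {
    m <- matrix(0, nrow(r), nrow(samples))
    for (j in seq_len(nrow(samples))) {
      mu <- means[, samples$group[j]]
      m[, j] <- mu * .lognoise(length(mu), sc$noise_sd)
    }
    m
  })
  feature_matrix(intensity, samples,
                 r[c("feature_id", "mz", "rt", "polarity", "formula")])
}

#' Simulate one isotopologue ladder spectrum
#'
#' Generates the centroided MS1 peaks of a single feature labeled under
#' the binomial model: the tracer mass isotopomer distribution
#' `dbinom(0:N, N, p)` is convolved with the natural-abundance pattern of
#' the formula (via the same forward matrix used by the correction), and
#' peaks are placed on the ladder `mz + i * 1.003355`.
#'
#' @param mz Monoisotopic m/z of the feature.
#' @param formula Elemental formula (string or object); carbon count N.
#' @param p Per-carbon 13C enrichment in \[0, 1\] (0 = natural abundance
#'   only).
#' @param rt Retention time (min) of the generated spectrum.
#' @param total_intensity Total ion intensity of the ladder.
#' @param noise_sd Relative SD of multiplicative peak noise (0 =
#'   noiseless).
#' @param polarity Polarity tag for the spectrum.
#' @return A [centroid_spectrum()].
#' @export
simulate_isotopologue_spectrum <- function(mz, formula, p, rt = 0,
                                           total_intensity = 1e5,
                                           noise_sd = 0, polarity = "neg") {
  stopifnot(p >= 0, p <= 1)
  f <- as_formula(formula)
  n <- carbon_count(f)
  cm <- correction_matrix(f)
  raw <- as.numeric(cm %*% stats::dbinom(0:n, n, p))
  intensity <- total_intensity * raw * .lognoise(n + 1L, noise_sd)
  keep <- intensity > total_intensity * 1e-9
  centroid_spectrum(mz = (mz + (0:n) * c13_spacing())[keep],
                    intensity = intensity[keep], rt = rt,
                    polarity = polarity)
}

#' Simulate the labeling mono-culture spectra of the packaged scenario
#'
#' Generates, for one organism arm, day and condition, the centroided
#' MS1 spectra of every replicate sample (`n_bio x n_tech`). Each induced
#' feature contributes one spectrum at its retention time; its tracer
#' enrichment is the roster truth for this organism/day when the
#' condition provides label (`"with_sup"`), and 0 for `"without_sup"`
#' (all labeled roster features are supernatant-dependent) and for the
#' unlabeled `"baseline"` control.
#'
#' @param sc A [coculture_scenario()].
#' @param organism `"A"` or `"B"`.
#' @param day Sampling day (one of `sc$days`; ignored for baseline).
#' @param condition `"with_sup"`, `"without_sup"` or `"baseline"`.
#' @return A list of samples; each sample is a list with `organism`,
#'   `day`, `condition`, `bio`, `tech` and `spectra` (list of
#'   [centroid_spectrum()], sorted by RT).
#' @export
simulate_labeling_spectra <- function(sc, organism = c("A", "B"),
                                      day = sc$days[1],
                                      condition = c("with_sup", "without_sup",
                                                    "baseline")) {
  organism <- match.arg(organism)
  condition <- match.arg(condition)
  if (condition != "baseline" && !day %in% sc$days) {
    stop("day must be one of the scenario days: ",
         paste(sc$days, collapse = ", "), call. = FALSE)
  }
  ind <- sc$roster[sc$roster$class != "background", ]
  pcol <- paste0("p", if (condition == "baseline") sc$days[1] else day,
                 "_", organism)
  p <- ind[[pcol]]
  if (condition != "with_sup") p <- rep(0, length(p))  # label requires supernatant
  off <- 1000L * match(organism, c("A", "B")) + 100L * match(condition,
         c("with_sup", "without_sup", "baseline")) +
         (if (condition == "baseline") 0L else as.integer(day))
  with_seed(sc$seed + 10000L + off, {
    samples <- list()
    for (b in seq_len(sc$n_bio)) {
      for (t in seq_len(sc$n_tech)) {
        spectra <- lapply(seq_len(nrow(ind)), function(i) {
          simulate_isotopologue_spectrum(
            mz = ind$mz[i], formula = ind$formula[i], p = p[i],
            rt = ind$rt[i], total_intensity = ind$intensity[i],
            noise_sd = sc$noise_sd, polarity = ind$polarity[i])
        })
        spectra <- spectra[order(vapply(spectra, `[[`, numeric(1), "rt"))]
        samples[[length(samples) + 1L]] <- list(
          organism = organism, day = if (condition == "baseline") NA_integer_ else day,
          condition = condition, bio = b, tech = t, spectra = spectra)
      }
    }
    samples
  })
}

#' Simulate an MS/MS structural family
#'
#' Members share a fragment backbone (identical m/z and intensities) and
#' differ by a precursor-mass modification plus a few member-specific
#' minor fragments, so every pair exceeds the usual modified-cosine
#' network threshold by construction.
#'
#' @param backbone_mz Fragment m/z values shared by all members (>= 1).
#' @param precursors Precursor m/z per member (length = number of
#'   members).
#' @param backbone_intensity Intensities of the backbone fragments
#'   (default: all 100).
#' @param unique_intensity Intensity of the two member-specific fragments
#'   (default 20).
#' @param group Source group tag applied to all members.
#' @return A list of [msms_spectrum()] objects.
#' @export
simulate_msms_family <- function(backbone_mz, precursors,
                                 backbone_intensity = rep(100, length(backbone_mz)),
                                 unique_intensity = 20, group = "co") {
  stopifnot(length(backbone_mz) >= 1L, length(precursors) >= 1L)
  lapply(seq_along(precursors), function(k) {
    pre <- precursors[k]
    extra_mz <- c(pre - 18.0106, pre - 46.0055)  # water / formic-acid losses
    msms_spectrum(precursor_mz = pre,
                  mz = c(backbone_mz, extra_mz),
                  intensity = c(backbone_intensity,
                                rep(unique_intensity, length(extra_mz))),
                  id = sprintf("%.4f", pre), group = group)
  })
}

#' MS/MS spectra of the packaged scenario
#'
#' @param sc A [coculture_scenario()].
#' @param n_singletons Number of additional mutually dissimilar spectra
#'   (dropped from the network as sub-threshold singletons).
#' @return A list of [msms_spectrum()] objects covering the scenario's
#'   structural families.
#' @export
scenario_msms_spectra <- function(sc, n_singletons = 3L) {
  fams <- lapply(sc$msms_families, function(f) {
    simulate_msms_family(f$backbone_mz, f$precursors, group = "co")
  })
  singles <- with_seed(sc$seed + 99L, {
    lapply(seq_len(n_singletons), function(k) {
      pre <- stats::runif(1, 700, 1100)
      msms_spectrum(precursor_mz = pre,
                    mz = sort(stats::runif(8, 50, pre - 20)),
                    intensity = stats::runif(8, 10, 100),
                    id = sprintf("single_%d", k), group = "monoA")
    })
  })
  c(do.call(c, fams), singles)
}
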