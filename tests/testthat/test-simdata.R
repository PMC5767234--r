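test_that("the packaged scenario encodes the planted study truth", {
  sc <- coculture_scenario(seed = 1)
  ind <- sc$roster[sc$roster$class != "background", ]
  expect_equal(nrow(ind), 74L)
  expect_equal(sum(ind$class == "newly_synthesized"), 58L)
  expect_equal(sum(ind$class == "fold_increased"), 16L)
  expect_equal(as.list(table(ind$producer)),
               list(A = 20L, B = 6L, both = 5L, none = 43L))
  expect_equal(sum(ind$high_signal), 12L)
  expect_true(all(ind$high_signal[ind$producer != "none"] == FALSE))
  # kinetic truth: 11 still-accumulating vs 20 steady labeled features
  expect_equal(sum(ind$trajectory == "increasing"), 11L)
  expect_equal(sum(ind$trajectory == "steady"), 20L)
  # the reference enrichments used in the worked examples
  f490 <- ind[ind$feature_id == "F490.3025", ]
  expect_equal(c(f490$p10_A, f490$p20_A), c(0.19, 0.25))
  expect_equal(ind$p20_B[ind$feature_id == "F167.0348"], 0.14)
  # exactly one constructed roster entry, clearly flagged
  expect_equal(sum(ind$synthetic), 1L)
  expect_equal(nrow(sc$roster), 74L + 4000L)
})

test_that("feature matrices are deterministic in the seed", {
  sc <- coculture_scenario(seed = 42, n_background = 50)
  m1 <- simulate_feature_matrix(sc)
  m2 <- simulate_feature_matrix(sc)
  expect_identical(m1$intensity, m2$intensity)
  m3 <- simulate_feature_matrix(coculture_scenario(seed = 43, n_background = 50))
  expect_false(identical(m1$intensity, m3$intensity))
})

test_that("noiseless feature matrices hit the planted group means exactly", {
  sc <- coculture_scenario(seed = 1, n_background = 10, noise_sd = 0)
  fm <- simulate_feature_matrix(sc)
  r <- sc$roster
  co_cols <- fm$samples$group == "co"
  expect_equal(unname(rowMeans(fm$intensity[, co_cols])), r$intensity,
               tolerance = 1e-12)
  ratio_rows <- which(r$class == "fold_increased")
  mono_cols <- fm$samples$group == "monoA"
  expect_equal(unname(rowMeans(fm$intensity[ratio_rows, mono_cols])),
               r$intensity[ratio_rows] / r$ratio[ratio_rows],
               tolerance = 1e-12)
  newly_rows <- which(r$class == "newly_synthesized")
  expect_true(all(fm$intensity[newly_rows, !co_cols] == 0))
})

test_that("planted fold ratios are recovered within sampling error", {
  sc <- coculture_scenario(seed = 7, n_background = 0)
  fm <- simulate_feature_matrix(sc)
  ind <- detect_induced(fm)
  r <- sc$roster
  # ratio of two group means, each over n_bio * n_tech samples with 5% CV
  rel_sd <- sc$noise_sd * sqrt(2 / (sc$n_bio * sc$n_tech))
  for (fid in c("F309.0756", "F311.0931", "F165.0554")) {
    planted <- r$ratio[r$feature_id == fid]
    got <- ind$ratio[ind$feature_id == fid]
    expect_lt(abs(got - planted), 3 * rel_sd * planted)
  }
})

test_that("labeling spectra follow the binomial tracer model", {
  # p = 0: indistinguishable from natural abundance
  s0 <- simulate_isotopologue_spectrum(167.0348, "C8H8O4", p = 0,
                                       total_intensity = 1e5)
  nat <- natural_isotopologue_distribution("C8H8O4", 8)
  expect_equal(s0$intensity / sum(s0$intensity),
               (nat / sum(nat))[seq_along(s0$intensity)], tolerance = 1e-9)
  # p = 1: the dominant ion is M+N
  s1 <- simulate_isotopologue_spectrum(167.0348, "C8H8O4", p = 1,
                                       total_intensity = 1e5)
  expect_equal(which.max(s1$intensity), length(s1$intensity))
  expect_gt(s1$mz[which.max(s1$intensity)], 167.0348 + 8 * 1.0033)
})

test_that("noiseless spectra recover every planted enrichment end-to-end", {
  # The excess incorporation over the unlabeled baseline must equal the
  # planted 100 p for every roster feature. Co-eluting isotopic envelopes
  # (the roster carries one genuine interference pair at RT 20.07) add
  # the same apparent incorporation to both arms, so the excess is exact
  # even where the raw value is not.
  sc <- coculture_scenario(seed = 3, noise_sd = 0)
  targets <- scenario_targets(sc)
  r <- sc$roster[sc$roster$class != "background", ]
  one_inc <- function(smp, rts, tg) {
    sub <- smp$spectra[abs(rts - tg$rt) <= 0.2]
    meas <- extract_isotopologues(sub, tg)
    total_incorporation(
      correct_natural_abundance(meas$intensity, correction_matrix(tg$formula)))
  }
  for (org in c("A", "B")) {
    labeled_smp <- simulate_labeling_spectra(sc, organism = org, day = 20,
                                             condition = "with_sup")[[1]]
    base_smp <- simulate_labeling_spectra(sc, organism = org,
                                          condition = "baseline")[[1]]
    rts_l <- vapply(labeled_smp$spectra, `[[`, numeric(1), "rt")
    rts_b <- vapply(base_smp$spectra, `[[`, numeric(1), "rt")
    p_true <- r[[paste0("p20_", org)]]
    for (k in seq_len(nrow(r))) {
      tg <- targets[[r$feature_id[k]]]
      excess <- one_inc(labeled_smp, rts_l, tg) - one_inc(base_smp, rts_b, tg)
      expect_equal(excess, 100 * p_true[k], tolerance = 1e-6,
                   label = sprintf("feature %s (%s arm)", r$feature_id[k], org))
    }
  }
})

test_that("labeling spectra are deterministic and supernatant-gated", {
  sc <- coculture_scenario(seed = 5)
  a1 <- simulate_labeling_spectra(sc, "A", day = 10, condition = "with_sup")
  a2 <- simulate_labeling_spectra(sc, "A", day = 10, condition = "with_sup")
  expect_identical(a1, a2)
  # without supernatant no feature carries label beyond natural abundance
  wo <- simulate_labeling_spectra(coculture_scenario(seed = 5, noise_sd = 0),
                                  "A", day = 20, condition = "without_sup")
  tg <- scenario_targets(sc)[["F490.3025"]]
  rts <- vapply(wo[[1]]$spectra, `[[`, numeric(1), "rt")
  meas <- extract_isotopologues(wo[[1]]$spectra[abs(rts - tg$rt) <= 0.2], tg)
  inc <- total_incorporation(
    correct_natural_abundance(meas$intensity, correction_matrix(tg$formula)))
  expect_equal(inc, 0, tolerance = 1e-6)
})

test_that("MS/MS family simulation honors its construction guarantees", {
  fam1 <- simulate_msms_family(c(77.04, 117.03, 235.08, 91.05, 145.03, 163.04),
                               precursors = 279.0656)
  expect_length(fam1, 1L)
  expect_error(build_network(fam1), "at least 2")
  fam6 <- simulate_msms_family(c(77.04, 117.03, 235.08, 91.05, 145.03,
                                 163.04, 189.07, 207.08),
                               precursors = c(279.0656, 306.0775, 334.0733,
                                              581.1208, 629.1419, 251.0712))
  for (i in 1:5) {
    mc <- modified_cosine(fam6[[i]], fam6[[i + 1]])
    expect_gt(mc$score, 0.65)
    expect_gte(mc$matched, 6L)
  }
  net <- build_network(fam6)
  expect_equal(length(unique(net$nodes$component)), 1L)
  expect_equal(nrow(net$nodes), 6L)
})
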