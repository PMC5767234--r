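rand_msms <- function(id, precursor, n_peaks, seed) {
  set.seed(seed)
  msms_spectrum(precursor, mz = sort(runif(n_peaks, 50, precursor - 10)),
                intensity = runif(n_peaks, 5, 100), id = id)
}

test_that("modified cosine is 1 on identical spectra and 0 with no matches", {
  s <- rand_msms("a", 400, 8, seed = 1)
  res <- modified_cosine(s, s)
  expect_equal(res$score, 1.0, tolerance = 1e-12)
  expect_equal(res$matched, 8L)
  s2 <- msms_spectrum(400, s$mz + 7.7, s$intensity, id = "b")  # off-ladder
  expect_equal(modified_cosine(s, s2)$score, 0)
  empty <- msms_spectrum(300, numeric(0), numeric(0), id = "e")
  expect_equal(modified_cosine(s, empty)$score, 0)
  expect_equal(modified_cosine(s, empty)$matched, 0L)
})

test_that("a hand-enumerated two-peak case gives the expected score", {
  # one shared fragment of equal relative intensity; the second fragments
  # of the two spectra match nothing
  s1 <- msms_spectrum(300, c(100.00, 150.00), c(4, 4), id = "s1")
  s2 <- msms_spectrum(300.0001, c(100.00, 180.00), c(9, 9), id = "s2")
  # sqrt weights: each peak = 1/sqrt(2) after normalization; one match
  expect_equal(modified_cosine(s1, s2)$score, 0.5, tolerance = 1e-9)
  expect_equal(modified_cosine(s1, s2)$matched, 1L)
})

test_that("precursor-shifted fragments of modified analogs match", {
  backbone <- c(77.04, 117.03, 235.08)
  s1 <- msms_spectrum(279.0656, c(backbone, 261.055), c(100, 80, 90, 40),
                      id = "parent")
  # derivative: backbone conserved, precursor-dependent peak shifted by +27.995
  s2 <- msms_spectrum(307.0605, c(backbone, 289.050), c(100, 80, 90, 40),
                      id = "derivative")
  res <- modified_cosine(s1, s2)
  expect_equal(res$matched, 4L)  # 3 direct + 1 shifted
  expect_equal(res$score, 1.0, tolerance = 1e-6)
})

test_that("modified cosine is symmetric and scale invariant", {
  for (seed in 1:5) {
    s1 <- rand_msms("a", 350 + seed, 7, seed)
    s2 <- rand_msms("b", 390 + seed, 9, seed + 100)
    f <- modified_cosine(s1, s2)
    r <- modified_cosine(s2, s1)
    expect_equal(f$score, r$score, tolerance = 1e-12)
    expect_equal(f$matched, r$matched)
    s1_scaled <- msms_spectrum(s1$precursor_mz, s1$mz, s1$intensity * 37.5,
                               id = "a2")
    expect_equal(modified_cosine(s1_scaled, s2)$score, f$score,
                 tolerance = 1e-12)
  }
})

test_that("greedy matching agrees with the exhaustive assignment oracle", {
  # planted cases with unambiguous matchings
  s1 <- msms_spectrum(300, c(100.00, 150.00), c(4, 4), id = "s1")
  s2 <- msms_spectrum(300.0001, c(100.00, 180.00), c(9, 9), id = "s2")
  expect_equal(modified_cosine(s1, s2)$score,
               oracle_best_matching_score(s1, s2), tolerance = 1e-12)
  # random small spectra with well-separated peaks (no ambiguous pairs)
  for (seed in 1:8) {
    set.seed(seed)
    mz1 <- sort(sample(seq(60, 290, by = 2), 6)) + runif(6, -0.1, 0.1)
    mz2 <- mz1 + sample(c(0, 0.2, 5), 6, replace = TRUE)
    a <- msms_spectrum(300, mz1, runif(6, 10, 100), id = "a")
    b <- msms_spectrum(300.0001, sort(mz2), runif(6, 10, 100), id = "b")
    expect_equal(modified_cosine(a, b)$score,
                 oracle_best_matching_score(a, b), tolerance = 1e-9)
  }
  # the greedy score never exceeds the optimal assignment
  for (seed in 1:5) {
    a <- rand_msms("a", 320, 8, seed + 20)
    b <- rand_msms("b", 335, 8, seed + 40)
    expect_lte(modified_cosine(a, b, fragment_tol = 5)$score,
               oracle_best_matching_score(a, b, fragment_tol = 5) + 1e-12)
  }
})

test_that("a planted derivative family forms a single component", {
  fam <- simulate_msms_family(
    backbone_mz = c(77.04, 91.05, 117.03, 145.03, 163.04, 189.07, 207.08, 235.08),
    precursors = c(279.0656, 306.0775, 334.0733, 581.1208, 629.1419, 251.0712))
  net <- build_network(fam)
  expect_equal(nrow(net$nodes), 6L)
  expect_equal(length(unique(net$nodes$component)), 1L)
  # all-dissimilar spectra give an empty network
  strangers <- lapply(1:4, function(k) rand_msms(paste0("s", k), 300 + 50 * k,
                                                 8, seed = k + 7))
  empty_net <- build_network(strangers)
  expect_equal(nrow(empty_net$nodes), 0L)
  expect_equal(nrow(empty_net$edges), 0L)
})

test_that("two disjoint families give two components", {
  famA <- simulate_msms_family(seq(60, 130, by = 10) + 0.05,
                               precursors = c(200.1, 214.1, 228.1))
  famB <- simulate_msms_family(seq(310, 380, by = 10) + 0.05,
                               precursors = c(500.2, 514.2, 542.2))
  net <- build_network(c(famA, famB))
  expect_equal(length(unique(net$nodes$component)), 2L)
  comp_sizes <- table(net$nodes$component)
  expect_equal(sort(as.integer(comp_sizes)), c(3L, 3L))
})

test_that("component sizes never exceed the maximum and thresholds are monotone", {
  fam <- simulate_msms_family(seq(60, 130, by = 10) + 0.05,
                              precursors = seq(200, 200 + 13 * 14, by = 14) + 0.1)
  net <- build_network(fam, max_component = 5L)
  expect_true(all(table(net$nodes$component) <= 5L))
  # raising min_cosine never adds edges
  loose <- build_network(fam, min_cosine = 0.5)
  tight <- build_network(fam, min_cosine = 0.9)
  key <- function(n) paste(pmin(n$edges$from, n$edges$to),
                           pmax(n$edges$from, n$edges$to))
  expect_true(all(key(tight) %in% key(loose)))
  expect_lte(nrow(tight$edges), nrow(loose$edges))
})

test_that("GraphML export round-trips nodes, edges and scores", {
  fam <- simulate_msms_family(seq(60, 130, by = 10) + 0.05,
                              precursors = c(200.1, 214.1, 228.1),
                              group = "co")
  net <- build_network(fam)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, path)
  back <- read_network(path)
  expect_setequal(back$nodes$name, net$nodes$name)
  expect_equal(back$nodes$group[match(net$nodes$name, back$nodes$name)],
               net$nodes$group)
  expect_equal(nrow(back$edges), nrow(net$edges))
  ek <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
  expect_setequal(ek(back$edges), ek(net$edges))
  expect_equal(sort(back$edges$score), sort(net$edges$score), tolerance = 1e-9)
  # a two-node, one-edge network and an empty network both round-trip
  two <- build_network(fam[1:2])
  p2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(two, p2)
  expect_equal(nrow(read_network(p2)$edges), 1L)
  strangers <- lapply(1:3, function(k) rand_msms(paste0("s", k), 300 + 70 * k,
                                                 8, seed = k))
  p3 <- withr::local_tempfile(fileext = ".graphml")
  export_network(build_network(strangers), p3)
  expect_equal(nrow(read_network(p3)$nodes), 0L)
  expect_error(export_network(two, file.path(tempdir(), "nope", "x.graphml")),
               "directory")
})
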