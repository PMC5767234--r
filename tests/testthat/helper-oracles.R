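# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms: the convolution oracle enumerates isotope
# assignments atom by atom, the matching oracle enumerates one-to-one
# peak assignments exhaustively, and the t-test oracle is the textbook
# pooled-variance formula.

# Brute-force natural isotopologue distribution: enumerate the isotope
# choice of every atom (feasible for <= ~6 atoms total).
oracle_isotopologue_distribution <- function(counts, max_shift,
                                             exclude_tracer = FALSE) {
  iso <- isotope_table()
  atoms <- rep(names(counts), counts)
  atom_tab <- function(el) {
    tab <- iso[iso$element == el, ]
    if (exclude_tracer && el == "C") {
      tab <- tab[1, , drop = FALSE]
      tab$abundance <- 1  # tracer element treated as mono-isotopic
    }
    tab
  }
  choice_list <- lapply(atoms, function(el) seq_len(nrow(atom_tab(el))))
  grid <- do.call(expand.grid, choice_list)
  out <- numeric(max_shift + 1L)
  for (r in seq_len(nrow(grid))) {
    p <- 1
    shift <- 0L
    for (a in seq_along(atoms)) {
      tab <- atom_tab(atoms[a])
      k <- grid[r, a]
      p <- p * tab$abundance[k]
      shift <- shift + tab$isotope[k]
    }
    if (shift <= max_shift) out[shift + 1L] <- out[shift + 1L] + p
  }
  out
}

# Exhaustive maximum-weight one-to-one matching over candidate peak
# pairs (feasible for <= ~10 peaks per spectrum).
oracle_best_matching_score <- function(s1, s2, fragment_tol = 0.5,
                                       parent_tol = 1.0) {
  if (!length(s1$mz) || !length(s2$mz)) return(0)
  w1 <- sqrt(s1$intensity); w1 <- w1 / sqrt(sum(w1^2))
  w2 <- sqrt(s2$intensity); w2 <- w2 / sqrt(sum(w2^2))
  shift <- s1$precursor_mz - s2$precursor_mz
  ok <- abs(outer(s1$mz, s2$mz, "-")) <= fragment_tol
  if (abs(shift) > parent_tol) {
    ok <- ok | abs(outer(s1$mz, s2$mz + shift, "-")) <= fragment_tol
  }
  cand <- which(ok, arr.ind = TRUE)
  if (!nrow(cand)) return(0)
  best <- 0
  # exhaustive branch: every candidate pair is either skipped or taken
  rec <- function(k, used1, used2, acc) {
    if (k > nrow(cand)) { best <<- max(best, acc); return() }
    rec(k + 1L, used1, used2, acc)  # skip
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!(i %in% used1) && !(j %in% used2)) {
      rec(k + 1L, c(used1, i), c(used2, j), acc + w1[i] * w2[j])
    }
  }
  rec(1L, integer(0), integer(0), 0)
  min(best, 1)
}

# Textbook pooled-variance two-sample two-sided t-test p-value.
oracle_t_pvalue <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}
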