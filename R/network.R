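#' Construct an MS/MS spectrum
#'
#' @param precursor_mz Precursor m/z.
#' @param mz,intensity Fragment peak lists (parallel vectors).
#' @param id Spectrum identifier (defaults to the precursor m/z).
#' @param group Source group tag (`"co"`, `"monoA"`, `"monoB"`, ...).
#' @return An `msms_spectrum` object.
#' @export
msms_spectrum <- function(precursor_mz, mz, intensity,
                          id = sprintf("%.4f", precursor_mz), group = NA_character_) {
  stopifnot(length(mz) == length(intensity))
  if (any(intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  o <- order(mz)
  structure(list(id = as.character(id), precursor_mz = as.numeric(precursor_mz),
                 mz = as.numeric(mz[o]), intensity = as.numeric(intensity[o]),
                 group = group),
            class = "msms_spectrum")
}

#' @export
print.msms_spectrum <- function(x, ...) {
  cat(sprintf("<msms_spectrum> %s: precursor %.4f, %d fragments\n",
              x$id, x$precursor_mz, length(x$mz)))
  invisible(x)
}

#' Modified cosine similarity between two MS/MS spectra
#'
#' Fragments match either directly (within `fragment_tol`) or shifted by
#' the precursor mass difference, which links structural analogs that
#' differ by one modification. Intensities are square-root scaled and
#' unit-normalized per spectrum; a one-to-one peak matching is built
#' greedily by descending intensity product (a documented, deterministic
#' approximation of the optimal assignment). When the precursor masses
#' agree within `parent_tol` the pair is treated as same-mass and only
#' direct matches are used.
#'
#' @param s1,s2 [msms_spectrum()] objects.
#' @param fragment_tol Fragment ion tolerance in Da (default 0.5).
#' @param parent_tol Parent (precursor) mass tolerance in Da (default 1.0).
#' @return List with `score` in \[0, 1\] and `matched` (number of matched
#'   peak pairs). Empty spectra give score 0.
#' @export
modified_cosine <- function(s1, s2, fragment_tol = 0.5, parent_tol = 1.0) {
  if (!length(s1$mz) || !length(s2$mz)) return(list(score = 0, matched = 0L))
  w1 <- sqrt(s1$intensity)
  w1 <- w1 / sqrt(sum(w1^2))
  w2 <- sqrt(s2$intensity)
  w2 <- w2 / sqrt(sum(w2^2))
  shift <- s1$precursor_mz - s2$precursor_mz
  # candidate pairs: direct, plus precursor-shifted when the parents differ
  d <- abs(outer(s1$mz, s2$mz, "-"))
  cand <- which(d <= fragment_tol, arr.ind = TRUE)
  if (abs(shift) > parent_tol) {
    ds <- abs(outer(s1$mz, s2$mz + shift, "-"))
    cand <- rbind(cand, which(ds <= fragment_tol, arr.ind = TRUE))
    cand <- cand[!duplicated(cand), , drop = FALSE]
  }
  if (!nrow(cand)) return(list(score = 0, matched = 0L))
  prod <- w1[cand[, 1]] * w2[cand[, 2]]
  o <- order(-prod, cand[, 1], cand[, 2])
  used1 <- logical(length(w1))
  used2 <- logical(length(w2))
  score <- 0
  matched <- 0L
  for (k in o) {
    i <- cand[k, 1]
    j <- cand[k, 2]
    if (used1[i] || used2[j]) next
    used1[i] <- TRUE
    used2[j] <- TRUE
    score <- score + prod[k]
    matched <- matched + 1L
  }
  list(score = min(score, 1), matched = matched)
}

#' Build a molecular network from MS/MS spectra
#'
#' Computes all pairwise modified-cosine scores, retains edges with
#' `score >= min_cosine` and at least `min_matched` matched peaks, trims
#' oversized connected components by removing their lowest-scoring edges
#' (ties broken by lexicographic node ids), and drops components smaller
#' than `min_cluster`.
#'
#' @param spectra List of [msms_spectrum()] objects (>= 2).
#' @param min_cosine Minimum pairwise cosine (default 0.65).
#' @param min_matched Minimum matched peaks per edge (default 6).
#' @param max_component Maximum connected-component size (default 50).
#' @param min_cluster Minimum component size to keep (default 2).
#' @param fragment_tol,parent_tol Tolerances passed to
#'   [modified_cosine()].
#' @return A `molecular_network`: list with an igraph `graph`, the
#'   retained `edges` data frame, a `nodes` data frame with group tags and
#'   component labels.
#' @export
build_network <- function(spectra, min_cosine = 0.65, min_matched = 6L,
                          max_component = 50L, min_cluster = 2L,
                          fragment_tol = 0.5, parent_tol = 1.0) {
  if (length(spectra) < 2L) stop("at least 2 spectra are required", call. = FALSE)
  ids <- vapply(spectra, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("spectrum ids must be unique", call. = FALSE)
  n <- length(spectra)
  edges <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      mc <- modified_cosine(spectra[[i]], spectra[[j]],
                            fragment_tol = fragment_tol, parent_tol = parent_tol)
      if (mc$score >= min_cosine && mc$matched >= min_matched) {
        edges[[length(edges) + 1L]] <- data.frame(
          from = ids[i], to = ids[j], score = mc$score,
          matched = mc$matched, stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0),
               score = numeric(0), matched = integer(0))
  nodes <- data.frame(
    name = ids,
    precursor_mz = vapply(spectra, `[[`, numeric(1), "precursor_mz"),
    group = vapply(spectra, function(s)
      if (is.null(s$group)) NA_character_ else as.character(s$group), character(1)),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  # trim: repeatedly drop the weakest edge inside any oversized component
  repeat {
    comp <- igraph::components(g)
    if (!any(comp$csize > max_component)) break
    big <- which(comp$csize > max_component)
    in_big <- comp$membership[igraph::tail_of(g, igraph::E(g))] %in% big
    es <- igraph::E(g)[in_big]
    sc <- es$score
    ends <- igraph::ends(g, es)
    key_lo <- pmin(ends[, 1], ends[, 2])
    key_hi <- pmax(ends[, 1], ends[, 2])
    victim <- es[order(sc, key_lo, key_hi)[1]]
    g <- igraph::delete_edges(g, victim)
  }
  # drop components below the minimum cluster size
  comp <- igraph::components(g)
  small <- which(comp$csize < min_cluster)
  if (length(small)) {
    g <- igraph::delete_vertices(g, which(comp$membership %in% small))
  }
  comp <- igraph::components(g)
  nodes_kept <- data.frame(name = igraph::V(g)$name,
                           precursor_mz = igraph::V(g)$precursor_mz,
                           group = igraph::V(g)$group,
                           component = comp$membership,
                           stringsAsFactors = FALSE)
  edges_kept <- igraph::as_data_frame(g, what = "edges")
  structure(list(graph = g, edges = edges_kept, nodes = nodes_kept,
                 params = list(min_cosine = min_cosine, min_matched = min_matched,
                               max_component = max_component,
                               min_cluster = min_cluster,
                               fragment_tol = fragment_tol,
                               parent_tol = parent_tol)),
            class = "molecular_network")
}

#' @export
print.molecular_network <- function(x, ...) {
  nc <- if (nrow(x$nodes)) length(unique(x$nodes$component)) else 0L
  cat(sprintf("<molecular_network> %d nodes, %d edges, %d components\n",
              nrow(x$nodes), nrow(x$edges), nc))
  invisible(x)
}

#' Export / import a molecular network as GraphML
#'
#' Node group tags and edge cosine scores are preserved, so a write/read
#' round-trip reproduces the network.
#'
#' @param net A `molecular_network`.
#' @param path Output path (`.graphml`).
#' @return `export_network` returns `path` invisibly; `read_network`
#'   returns a `molecular_network` (graph, nodes, edges; construction
#'   parameters are not stored in the file).
#' @export
export_network <- function(net, path) {
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) stop("cannot write network: no such directory ", dirname(path),
                    call. = FALSE)
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname export_network
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::vcount(g) == 0L) {
    return(structure(list(graph = g,
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             score = numeric(0)),
                          nodes = data.frame(name = character(0),
                                             precursor_mz = numeric(0),
                                             group = character(0),
                                             component = integer(0)),
                          params = list()),
                     class = "molecular_network"))
  }
  comp <- igraph::components(g)
  nodes <- data.frame(name = igraph::V(g)$name,
                      precursor_mz = if ("precursor_mz" %in% igraph::vertex_attr_names(g))
                        igraph::V(g)$precursor_mz else NA_real_,
                      group = if ("group" %in% igraph::vertex_attr_names(g))
                        igraph::V(g)$group else NA_character_,
                      component = if (length(comp$membership)) comp$membership else integer(0),
                      stringsAsFactors = FALSE)
  structure(list(graph = g, edges = igraph::as_data_frame(g, what = "edges"),
                 nodes = nodes, params = list()),
            class = "molecular_network")
}
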