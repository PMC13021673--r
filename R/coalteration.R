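# Co-alteration structure: for each region pair, the number of studies
# reporting both regions abnormal (direction-blind), the thresholded
# undirected graph, and the tau-sensitivity sweep.

#' Co-alteration count matrix
#'
#' `C(r1, r2)` counts the studies in which both regions are reported
#' abnormal, ignoring direction. The diagonal `C(r, r)` is the number of
#' studies reporting region `r` abnormal and is retained for reuse (it is not
#' interpreted as a self-loop).
#'
#' @param m A `fingerprint_matrix`.
#' @return Object of class `coalteration_matrix`: list with `counts`
#'   (symmetric integer matrix, roi_id dimnames) and `regions`.
#' @export
coalteration_matrix <- function(m) {
  z <- (m$entries != 0L) * 1L
  counts <- tcrossprod(z)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, regions = m$regions),
            class = "coalteration_matrix")
}

#' @export
print.coalteration_matrix <- function(x, ...) {
  off <- x$counts[upper.tri(x$counts)]
  cat("<coalteration_matrix> ", nrow(x$counts), " regions; max co-occurrence ",
      if (length(off)) max(off) else 0L, "\n", sep = "")
  invisible(x)
}

#' Thresholded co-alteration graph
#'
#' Builds the undirected simple graph whose nodes are the regions abnormal in
#' at least one study and whose edges join region pairs co-reported in at
#' least `tau` studies (edge weight = the co-occurrence count). Never-abnormal
#' regions are excluded from the node set: they cannot bear edges and would
#' deflate density. Each node is tagged with its dominant network affiliation.
#'
#' @param c A [coalteration_matrix()].
#' @param tau Minimum co-occurrence count for an edge; default 2 (replication
#'   in at least two independent studies).
#' @param scheme A [network_scheme()] used for dominant-network node tags.
#' @return Object of class `coalteration_graph`: list with `graph` (igraph),
#'   `tau`, `density`, `node_restriction = "abnormal_only"`.
#' @export
build_graph <- function(c, tau = 2L, scheme = NULL) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 1 || tau != round(tau))
    stop("tau must be a positive integer (got ", deparse(tau), ")")
  tau <- as.integer(tau)
  keep <- diag(c$counts) >= 1L
  counts <- c$counts[keep, keep, drop = FALSE]
  adj <- counts
  diag(adj) <- 0L
  adj[adj < tau] <- 0L
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  nodes <- rownames(counts)
  lab <- c$regions$label[match(nodes, c$regions$roi_id)]
  igraph::V(g)$label <- ifelse(is.na(lab), nodes, lab)
  if (!is.null(scheme))
    igraph::V(g)$dominant_network <- unname(dominant_network(scheme, nodes))
  nv <- length(nodes)
  dens <- if (nv > 1L) 2 * as.integer(igraph::ecount(g)) / (nv * (nv - 1)) else 0
  structure(list(graph = g, tau = tau, density = dens,
                 node_restriction = "abnormal_only"),
            class = "coalteration_graph")
}

#' @export
print.coalteration_graph <- function(x, ...) {
  cat("<coalteration_graph> tau=", x$tau, "; ", igraph::vcount(x$graph),
      " nodes, ", igraph::ecount(x$graph), " edges, density ",
      sprintf("%.4f", x$density), "\n", sep = "")
  invisible(x)
}

#' Connected modules of the co-alteration graph
#'
#' Modules are operationalized as connected components of the thresholded
#' graph, returned largest first (ties broken by lexicographically smallest
#' member).
#'
#' @param g A [build_graph()] result.
#' @return List of character vectors (sorted roi_ids), largest first.
#' @export
connected_modules <- function(g) {
  comp <- igraph::components(g$graph)
  mods <- split(names(comp$membership), comp$membership)
  mods <- lapply(mods, sort)
  first <- vapply(mods, `[`, "", 1L)
  mods <- mods[order(-lengths(mods), first)]
  names(mods) <- NULL
  mods
}

#' Weighted greedy-modularity communities (optional alternative to components)
#'
#' @param g A [build_graph()] result.
#' @return List of character vectors (sorted roi_ids), largest first.
#' @export
modularity_modules <- function(g) {
  cl <- igraph::cluster_fast_greedy(g$graph,
                                    weights = igraph::E(g$graph)$weight)
  mods <- lapply(igraph::groups(cl), sort)
  first <- vapply(mods, `[`, "", 1L)
  mods <- mods[order(-lengths(mods), first)]
  names(mods) <- NULL
  mods
}

#' Node strength (sum of incident edge weights)
#'
#' @param g A [build_graph()] result.
#' @return Named numeric vector over the graph's nodes; isolated nodes 0.
#' @export
node_strength <- function(g) {
  s <- igraph::strength(g$graph, weights = igraph::E(g$graph)$weight)
  if (is.null(names(s))) names(s) <- igraph::V(g$graph)$name
  s
}

#' Threshold sensitivity sweep over tau
#'
#' For each threshold: edge count, density, component partition, and whether
#' a designated seed set of regions remains inside a single connected module
#' ("module persistence").
#'
#' @param c A [coalteration_matrix()].
#' @param taus Strictly increasing positive integers; default `c(1, 2, 3)`.
#' @param seed_set Character vector of roi_ids whose joint connectivity is
#'   tracked; may be empty (persistence reported as NA).
#' @param scheme Optional [network_scheme()] passed to [build_graph()].
#' @return Object of class `threshold_sweep`: list with `summary` (data.frame
#'   `tau, n_nodes, n_edges, density, n_components, seed_set_connected`),
#'   `graphs`, `modules` (per-tau component lists), `seed_set`.
#' @export
threshold_sweep <- function(c, taus = c(1L, 2L, 3L), seed_set = character(),
                            scheme = NULL) {
  if (!length(taus) || any(diff(taus) <= 0))
    stop("taus must be a non-empty strictly increasing sequence")
  bad <- setdiff(seed_set, rownames(c$counts))
  if (length(bad))
    stop("seed roi_id absent from the region axis: ", paste(bad, collapse = ", "))
  graphs <- lapply(taus, function(t) build_graph(c, t, scheme))
  modules <- lapply(graphs, connected_modules)
  persist <- vapply(modules, function(mods) {
    if (!length(seed_set)) return(NA)
    any(vapply(mods, function(mm) all(seed_set %in% mm), NA))
  }, NA)
  summary <- data.frame(
    tau = as.integer(taus),
    n_nodes = vapply(graphs, function(g) as.integer(igraph::vcount(g$graph)), 0L),
    n_edges = vapply(graphs, function(g) as.integer(igraph::ecount(g$graph)), 0L),
    density = vapply(graphs, function(g) g$density, 0),
    n_components = lengths(modules),
    seed_set_connected = persist,
    stringsAsFactors = FALSE
  )
  structure(list(summary = summary, graphs = graphs, modules = modules,
                 seed_set = seed_set),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("<threshold_sweep>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write the edge list of a co-alteration graph as TSV
#'
#' Columns `source, target, weight` (integer weights), edges ordered by
#' (source, target) roi_id.
#'
#' @param g A [build_graph()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_data_frame(g$graph, what = "edges")
  if (nrow(el)) {
    swap <- el$from > el$to
    tmp <- el$from[swap]; el$from[swap] <- el$to[swap]; el$to[swap] <- tmp
    el <- el[order(el$from, el$to), , drop = FALSE]
  }
  out <- data.frame(source = el$from, target = el$to,
                    weight = as.integer(el$weight),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Export a co-alteration graph to GraphML
#'
#' Node attributes `label`, `dominant_network` (when a scheme was supplied to
#' [build_graph()]) and `strength`; edge attribute `weight`.
#'
#' @param g A [build_graph()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  gg <- g$graph
  igraph::V(gg)$strength <- as.numeric(node_strength(g))
  igraph::write_graph(gg, path, format = "graphml")
  invisible(path)
}
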