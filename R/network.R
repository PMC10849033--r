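# Build the structurally resolved PPI network from docking z-scores and
# summarize its topology.  The graph container is igraph.

#' Build an interaction network from docking z-scores
#'
#' Keeps every pair with `z >= threshold` as an undirected z-weighted edge.
#' Self-pairs are rejected and duplicate pair entries are allowed only when
#' their z-scores agree; by default proteins left without any surviving edge
#' are dropped from the node set (a protein that never crosses the threshold
#' is not part of the interactome).
#'
#' @param zscores data frame with columns `idA`, `idB`, `z` (e.g. from
#'   [all_vs_all()]).
#' @param threshold decision threshold (default 8.8).
#' @param keep_isolated keep proteins with no surviving edge as isolated
#'   nodes.
#' @return object of class `interaction_network`: list with `graph` (igraph),
#'   `threshold`.
#' @export
build_network <- function(zscores, threshold = 8.8, keep_isolated = FALSE) {
  stopifnot(all(c("idA", "idB", "z") %in% names(zscores)))
  cp <- canonical_pairs(zscores$idA, zscores$idB)
  key <- pair_key(cp$idA, cp$idB)
  if (anyDuplicated(key)) {
    agg <- tapply(zscores$z, key, function(v) diff(range(v)))
    if (any(agg > 1e-9))
      stop("duplicate pair entries with conflicting z-scores")
    keep <- !duplicated(key)
    cp <- cp[keep, , drop = FALSE]
    zs <- zscores$z[keep]
  } else zs <- zscores$z
  sel <- zs >= threshold
  edges <- data.frame(from = cp$idA[sel], to = cp$idB[sel], z = zs[sel])
  verts <- if (keep_isolated) unique(c(cp$idA, cp$idB))
  else unique(c(edges$from, edges$to))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = verts))
  structure(list(graph = g, threshold = threshold),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network: %d proteins, %d interactions (z >= %g)>\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$threshold))
  invisible(x)
}

#' Extract the edge list of a network
#'
#' @param net an `interaction_network`.
#' @return data frame `idA`, `idB`, `z` (canonical pair order).
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  el <- igraph::as_data_frame(net$graph, what = "edges")
  if (nrow(el) == 0L)
    return(data.frame(idA = character(), idB = character(), z = numeric()))
  out <- canonical_pairs(el$from, el$to)
  out$z <- el$z
  out
}

#' Degree statistics of an interaction network
#'
#' Mean degree is `2E/N` (reported rounded to the nearest integer in
#' summaries); the histogram uses closed-open bins `[lo, hi)` of
#' `bin_width`; the mid-degree share counts nodes with degree inside
#' `mid_range` (closed interval, default 10-30 connections).
#'
#' @param net an `interaction_network` with at least one node.
#' @param bin_width histogram bin width (default 10).
#' @param mid_range closed degree interval for the mid-degree share.
#' @return list: `degrees` (named), `mean_degree`, `mean_degree_reported`,
#'   `histogram` (data frame `lo`, `hi`, `count`), `pct_mid` (one-decimal
#'   percent of nodes in `mid_range`).
#' @export
degree_stats <- function(net, bin_width = 10L, mid_range = c(10L, 30L)) {
  stopifnot(inherits(net, "interaction_network"))
  deg <- igraph::degree(net$graph)
  if (length(deg) == 0L) stop("empty network")
  lo <- seq(0L, max(deg), by = bin_width)
  hist <- data.frame(lo = lo, hi = lo + bin_width,
                     count = vapply(lo, function(l)
                       sum(deg >= l & deg < l + bin_width), 0L))
  list(degrees = deg,
       mean_degree = mean(deg),
       mean_degree_reported = round(mean(deg)),
       histogram = hist,
       pct_mid = fraction_pct(sum(deg >= mid_range[1] & deg <= mid_range[2]),
                              length(deg)))
}

#' Overlap of network edges with external interaction sets
#'
#' Counts how many network edges are present in each named external edge set
#' and in their union, and reports the union overlap as a one-decimal percent
#' of the network's edges (e.g. 1,350 of 24,653 edges = 5.5%).
#'
#' @param net an `interaction_network`.
#' @param other_edge_sets named list of data frames with `idA`, `idB`.
#' @return list: `per_set` (named counts), `union_count`, `union_pct`,
#'   `n_edges`.
#' @export
overlap_with <- function(net, other_edge_sets) {
  stopifnot(inherits(net, "interaction_network"), is.list(other_edge_sets))
  el <- network_edges(net)
  keys <- pair_key(el$idA, el$idB)
  set_keys <- lapply(other_edge_sets, function(s)
    unique(pair_key(pmin(s$idA, s$idB), pmax(s$idA, s$idB))))
  per_set <- vapply(set_keys, function(k) sum(keys %in% k), 0L)
  uni <- unique(unlist(set_keys))
  union_count <- sum(keys %in% uni)
  list(per_set = per_set, union_count = union_count,
       union_pct = if (length(keys)) fraction_pct(union_count, length(keys))
       else 0,
       n_edges = length(keys))
}
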