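#' Build the dispersal network of occupied patches
#'
#' Nodes are the currently occupied patches; an undirected link joins two
#' nodes when their gap distance is less than or equal to the threshold
#' dispersal distance \code{D} (the boundary case \code{gap == D} is
#' linked). Each edge carries its gap length in metres.
#'
#' @param occupied logical vector (or integer indices) of occupied patches.
#' @param gaps full gap-distance matrix (m).
#' @param D threshold dispersal distance (m).
#' @param ids optional node labels (defaults to patch indices).
#' @return Object of class \code{"network_snapshot"}: a list with the
#'   \code{igraph} \code{graph} (edge attribute \code{gap}), the node
#'   \code{ids}, and \code{n_components}.
#' @export
build_network <- function(occupied, gaps, D, ids = NULL) {
  n <- nrow(gaps)
  idx <- if (is.logical(occupied)) which(occupied) else as.integer(occupied)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  m <- length(idx)
  g_sub <- gaps[idx, idx, drop = FALSE]
  adj <- g_sub <= D
  diag(adj) <- FALSE
  graph <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(graph)$name <- ids[idx]
  el <- igraph::as_edgelist(graph, names = FALSE)
  igraph::E(graph)$gap <- g_sub[cbind(el[, 1], el[, 2])]
  structure(list(graph = graph, ids = ids[idx],
                 n_components = if (m > 0)
                   igraph::count_components(graph) else 0L),
            class = "network_snapshot")
}

#' @export
print.network_snapshot <- function(x, ...) {
  cat(sprintf("network_snapshot: %d nodes, %d edges, %d component(s), L = %.0f m\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              x$n_components, network_length(x)))
  invisible(x)
}

#' Node degree of a dispersal network
#'
#' Number of links incident to each occupied patch; patches with low degree
#' are more isolated and more prone to extinction.
#'
#' @param snapshot a [build_network()] result.
#' @return Named integer vector (one entry per occupied patch).
#' @export
node_degree <- function(snapshot) {
  igraph::degree(snapshot$graph)
}

#' Node betweenness of a dispersal network
#'
#' Shortest-path betweenness on the unweighted graph: for each ordered-free
#' pair of other nodes, the fraction of their shortest (fewest-hop) paths
#' passing through the node, summed over pairs; endpoints excluded. High
#' betweenness marks stepping-stone patches.
#'
#' @param snapshot a [build_network()] result.
#' @return Named numeric vector.
#' @export
node_betweenness <- function(snapshot) {
  igraph::betweenness(snapshot$graph, directed = FALSE, weights = NA)
}

#' Network length
#'
#' The gap-length-weighted shortest-path distance between the two most
#' distant mutually reachable nodes (the weighted network diameter). For a
#' fragmented network this is the maximum over connected components of
#' their diameters (default) or the diameter of the largest component.
#' Zero for edgeless graphs.
#'
#' @param snapshot a [build_network()] result.
#' @param fragmented \code{"max"} (maximum over components) or
#'   \code{"largest"} (largest component only; largest by node count).
#' @return Length in metres.
#' @export
network_length <- function(snapshot, fragmented = c("max", "largest")) {
  fragmented <- match.arg(fragmented)
  graph <- snapshot$graph
  if (igraph::ecount(graph) == 0) return(0)
  if (fragmented == "largest") {
    comp <- igraph::components(graph)
    keep <- which(comp$membership == which.max(comp$csize))
    graph <- igraph::induced_subgraph(graph, keep)
    if (igraph::ecount(graph) == 0) return(0)
  }
  d <- igraph::distances(graph, weights = igraph::E(graph)$gap)
  max(d[is.finite(d)])
}

#' Daily dispersal-network metrics along one occupancy realization
#'
#' Rebuilds the network of occupied patches for each day of a simulation
#' (occupancy from one recorded realization, geometry from the hydrologic
#' series) and tabulates mean node degree, mean node betweenness, number of
#' components and network length.
#'
#' @param run a \code{spom_run} produced with \code{record_states = TRUE}.
#' @param hydro the \code{hydro_series} used for the run.
#' @param D threshold dispersal distance (m); defaults to the run's trait.
#' @param realization which realization's occupancy to follow.
#' @param fragmented passed to [network_length()].
#' @return Data frame with columns \code{day}, \code{n_occupied},
#'   \code{mean_degree}, \code{mean_betweenness}, \code{n_components},
#'   \code{L}.
#' @export
network_metrics_series <- function(run, hydro, D = run$traits$D,
                                   realization = 1L,
                                   fragmented = "max") {
  if (is.null(run$states))
    stop("run must be produced with record_states = TRUE")
  L <- hydro$landscape
  cd <- as.matrix(stats::dist(cbind(L$x, L$y)))
  T_days <- dim(run$states)[1]
  out <- data.frame(day = seq_len(T_days), n_occupied = 0L,
                    mean_degree = NA_real_, mean_betweenness = NA_real_,
                    n_components = 0L, L = 0)
  for (t in seq_len(T_days)) {
    occ <- run$states[t, , realization]
    out$n_occupied[t] <- sum(occ)
    if (!any(occ)) next
    g <- gap_matrix(L, hydro$A[t, ], centre_dist = cd)
    snap <- build_network(occ, g, D, ids = L$id)
    out$mean_degree[t] <- mean(node_degree(snap))
    out$mean_betweenness[t] <- mean(node_betweenness(snap))
    out$n_components[t] <- snap$n_components
    out$L[t] <- network_length(snap, fragmented = fragmented)
  }
  out
}

#' Network length duration curve
#'
#' Empirical exceedance curve of the network length over time: the k-th
#' largest length is assigned exceedance probability \code{k/(n+1)}
#' (Weibull plotting position), so the curve is a valid survival function
#' and lengths are non-increasing in the exceedance probability.
#'
#' @param lengths daily network lengths (m).
#' @return Data frame with columns \code{exceedance} (increasing) and
#'   \code{length} (non-increasing), one row per day.
#' @export
nldc <- function(lengths) {
  lengths <- as.numeric(lengths)
  lengths <- lengths[!is.na(lengths)]
  if (!length(lengths)) stop("need at least one length")
  s <- sort(lengths, decreasing = TRUE)
  data.frame(exceedance = seq_along(s) / (length(s) + 1), length = s)
}
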