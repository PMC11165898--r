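## Exact node centralities for hub ranking: degree, betweenness (Brandes,
## via igraph), closeness (component-local convention), and Maximal Clique
## Centrality (MCC), the CytoHubba-style score MCC(v) = sum over maximal
## cliques C containing v of (|C| - 1)!.

## coerce package network objects / edge lists to a simple undirected igraph
as_ncreg_igraph <- function(graph) {
  if (inherits(graph, "igraph")) {
    g <- igraph::as_undirected(graph, mode = "collapse")
    return(igraph::simplify(g))
  }
  if (is.list(graph) && !is.null(graph$edges)) {
    e <- graph$edges
    nodes <- if (!is.null(graph$nodes)) graph$nodes
      else sort(unique(c(e$a, e$b)))
    g <- igraph::graph_from_data_frame(
      data.frame(from = e$a, to = e$b, stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
    return(igraph::simplify(g))
  }
  stop("cannot interpret 'graph' as a network")
}

#' Node degree
#'
#' @param graph a network object (`coexpr_network`, `cerna_graph`, an edge
#'   list with `$edges`, or an igraph).
#' @return named integer vector of incident-edge counts.
#' @export
degree_centrality <- function(graph) {
  g <- as_ncreg_igraph(graph)
  igraph::degree(g)
}

#' Betweenness centrality (exact, unnormalized)
#'
#' For each node v, the sum over unordered pairs \{s, t\} (s, t != v) of the
#' fraction of shortest s-t paths passing through v; disconnected pairs
#' contribute 0. Computed exactly with Brandes' algorithm.
#'
#' @inheritParams degree_centrality
#' @param normalized divide by `(n - 1)(n - 2) / 2` (default `FALSE`, the
#'   CytoHubba convention).
#' @return named numeric vector.
#' @export
betweenness_centrality <- function(graph, normalized = FALSE) {
  g <- as_ncreg_igraph(graph)
  bc <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  if (normalized) {
    n <- igraph::vcount(g)
    if (n > 2) bc <- bc / ((n - 1) * (n - 2) / 2)
  }
  bc
}

#' Closeness centrality (component-local)
#'
#' `closeness(v) = (number of nodes reachable from v) / (sum of shortest-path
#' distances to them)`; isolated nodes get 0. This is the harmonic-free,
#' component-local convention used by CytoHubba-style node ranking.
#'
#' @inheritParams degree_centrality
#' @return named numeric vector.
#' @export
closeness_centrality <- function(graph) {
  g <- as_ncreg_igraph(graph)
  d <- igraph::distances(g)
  diag(d) <- Inf
  reach <- rowSums(is.finite(d))
  tot <- rowSums(ifelse(is.finite(d), d, 0))
  ifelse(reach > 0, reach / tot, 0)
}

#' Maximal Clique Centrality (MCC)
#'
#' `MCC(v)` is the sum of `(|C| - 1)!` over all maximal cliques C that
#' contain v. Maximal cliques are enumerated exactly (Bron-Kerbosch with
#' pivoting). Nodes with no incident edges score 0 (degree-consistent
#' convention for edgeless nodes). Because clique enumeration is exponential
#' in the worst case, graphs larger than `node_cap` raise an explicit error
#' rather than being truncated.
#'
#' @inheritParams degree_centrality
#' @param node_cap maximum node count accepted (default 2000).
#' @return named numeric vector.
#' @export
mcc_centrality <- function(graph, node_cap = 2000) {
  g <- as_ncreg_igraph(graph)
  n <- igraph::vcount(g)
  if (n > node_cap)
    stop("graph has ", n, " nodes, above the clique-enumeration cap of ",
         node_cap, "; raise 'node_cap' explicitly to proceed")
  mcc <- stats::setNames(numeric(n), igraph::V(g)$name)
  if (igraph::ecount(g) > 0) {
    cliques <- igraph::max_cliques(g, min = 2)
    for (cl in cliques) {
      w <- factorial(length(cl) - 1)
      ids <- igraph::V(g)$name[as.integer(cl)]
      mcc[ids] <- mcc[ids] + w
    }
  }
  mcc
}

#' Full centrality report
#'
#' @inheritParams mcc_centrality
#' @return data.frame with columns `node`, `degree`, `betweenness`,
#'   `closeness`, `mcc`, in node-name order.
#' @export
centrality_report <- function(graph, node_cap = 2000) {
  g <- as_ncreg_igraph(graph)
  deg <- igraph::degree(g)
  data.frame(node = names(deg),
             degree = unname(deg),
             betweenness = unname(betweenness_centrality(g)),
             closeness = unname(closeness_centrality(g)),
             mcc = unname(mcc_centrality(g, node_cap = node_cap)),
             stringsAsFactors = FALSE)
}

#' Top-k hubs by a centrality metric
#'
#' @param report data.frame from [centrality_report()].
#' @param metric one of `"degree"`, `"betweenness"`, `"closeness"`, `"mcc"`.
#' @param k number of hubs requested (>= 1); when k exceeds the node count,
#'   all nodes are returned with a warning.
#' @return data.frame of the k top rows, ties broken by lexicographic node
#'   id, with a `rank` column.
#' @export
top_k_hubs <- function(report, metric = c("degree", "betweenness",
                                          "closeness", "mcc"), k) {
  metric <- match.arg(metric)
  if (k < 1) stop("'k' must be >= 1")
  if (k > nrow(report)) {
    warning("k = ", k, " exceeds node count ", nrow(report),
            "; returning all nodes")
    k <- nrow(report)
  }
  ord <- order(-report[[metric]], report$node)
  out <- report[ord[seq_len(k)], , drop = FALSE]
  out$rank <- seq_len(k)
  rownames(out) <- NULL
  out
}
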