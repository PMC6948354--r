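#' Degree centrality
#'
#' Raw (unnormalized) degree: the number of edges incident to each node.
#' Edge weights are ignored; the topological screen operates on the
#' unweighted interaction graph.
#'
#' @param graph A simple undirected `igraph` graph with named vertices.
#' @return Named integer vector, one entry per node.
#' @export
degree_centrality <- function(graph) {
  d <- igraph::degree(graph, loops = FALSE)
  setNames(as.integer(d), igraph::V(graph)$name)
}

#' Shortest-path betweenness centrality
#'
#' Fraction-of-geodesics betweenness: for node v, the sum over ordered-free
#' pairs (s, t), s != v != t, of the share of shortest s-t paths passing
#' through v. Endpoints are excluded. With `normalized = TRUE` the value is
#' divided by `(n - 1)(n - 2) / 2`, the number of pairs a node could lie
#' between.
#'
#' @param graph A simple undirected `igraph` graph with named vertices.
#' @param normalized Divide by the pair count; default `FALSE`.
#' @return Named numeric vector.
#' @export
betweenness_centrality <- function(graph, normalized = FALSE) {
  n <- igraph::vcount(graph)
  nm <- igraph::V(graph)$name
  if (n < 3) return(setNames(numeric(n), nm))
  b <- igraph::betweenness(graph, directed = FALSE, weights = NA,
                           normalized = FALSE)
  if (normalized) b <- b / ((n - 1) * (n - 2) / 2)
  setNames(as.numeric(b), nm)
}

#' Component-scaled closeness centrality
#'
#' For node v in a connected component of size s inside a graph of n nodes,
#' with d(v, u) the geodesic distance to the other s - 1 nodes of its
#' component:
#' \deqn{cc(v) = \frac{s - 1}{n - 1} \cdot \frac{s - 1}{\sum_u d(v, u)}}
#' This is the Wasserman-Faust correction: the reciprocal mean distance
#' within the component, scaled by the fraction of the graph the node can
#' reach, so values remain comparable across components of a disconnected
#' graph (confidence filtering routinely disconnects PPI networks). Isolated
#' nodes score 0; cc is in \[0, 1\] and reaches 1 only for a node adjacent to
#' all others in a connected graph.
#'
#' @param graph A simple undirected `igraph` graph with named vertices.
#' @return Named numeric vector in \[0, 1\].
#' @export
closeness_centrality <- function(graph) {
  n <- igraph::vcount(graph)
  nm <- igraph::V(graph)$name
  if (n == 0) return(setNames(numeric(0), character(0)))
  if (n == 1) return(setNames(0, nm))
  d <- igraph::distances(graph, weights = NA)
  cc <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    s1 <- length(reach)             # s - 1
    if (s1 == 0) return(0)
    (s1 / (n - 1)) * (s1 / sum(reach))
  }, numeric(1))
  setNames(cc, nm)
}

#' Per-node centrality table
#' @param graph A simple undirected `igraph` graph with named vertices.
#' @return `data.frame` with columns `node`, `dc`, `bc`, `cc`.
#' @export
centrality_table <- function(graph) {
  data.frame(node = igraph::V(graph)$name,
             dc = as.integer(degree_centrality(graph)),
             bc = as.numeric(betweenness_centrality(graph)),
             cc = as.numeric(closeness_centrality(graph)),
             stringsAsFactors = FALSE)
}

#' Two-stage median screen for core targets
#'
#' Stage 1 nominates hub nodes: nodes whose degree is at least twice the
#' median degree of the whole graph (`dc >= 2 * median(dc)`; with
#' `strict_hub = TRUE` the comparison is strict). Stage 2 extracts the
#' subgraph induced by the hubs, recomputes degree, betweenness and closeness
#' on that hub network, and keeps the nodes meeting or exceeding the median
#' of all three simultaneously — the core targets. Medians are the usual
#' sample medians (mean of the two central order statistics for even counts)
#' and all thresholds actually applied are recorded so a run is auditable.
#'
#' Because both stages compare each statistic to the median of the same
#' vector, the screened sets are invariant to any positive rescaling of a
#' centrality (e.g. toggling betweenness normalization).
#'
#' @param graph A nonempty simple undirected `igraph` graph with named
#'   vertices.
#' @param strict_hub Use a strict `>` comparison at stage 1.
#' @param bc_normalized Use normalized betweenness at stage 2. The screened
#'   sets are unaffected (the criterion is a within-vector median
#'   comparison); the flag only changes the scale of the recorded
#'   betweenness threshold.
#' @return An object of class `netpharm_screen`: a list with `hub_nodes`,
#'   `core_targets` (both sorted character vectors, `core_targets` a subset
#'   of `hub_nodes`), `thresholds` (stage-1 degree median and threshold,
#'   stage-2 medians of dc/bc/cc on the hub subgraph), `centrality` (full
#'   graph table) and `hub_centrality` (hub subgraph table). An empty hub set
#'   yields empty results with a warning, not an error.
#' @export
median_screen <- function(graph, strict_hub = FALSE,
                          bc_normalized = FALSE) {
  if (igraph::vcount(graph) == 0) stop("graph is empty", call. = FALSE)
  tab <- centrality_table(graph)
  med_dc <- stats::median(tab$dc)
  thr <- 2 * med_dc
  hub <- if (strict_hub) tab$node[tab$dc > thr] else tab$node[tab$dc >= thr]
  thresholds <- list(stage1_median_dc = med_dc, stage1_threshold = thr,
                     stage1_strict = strict_hub,
                     stage2_median_dc = NA_real_, stage2_median_bc = NA_real_,
                     stage2_median_cc = NA_real_)
  if (length(hub) == 0) {
    warning("no node reaches the stage-1 degree threshold; core set is empty",
            call. = FALSE)
    out <- list(hub_nodes = character(), core_targets = character(),
                thresholds = thresholds, centrality = tab,
                hub_centrality = tab[0, , drop = FALSE])
    class(out) <- "netpharm_screen"
    return(out)
  }
  sub <- igraph::induced_subgraph(graph, hub)
  stab <- centrality_table(sub)
  if (bc_normalized) {
    stab$bc <- as.numeric(betweenness_centrality(sub, normalized = TRUE))
  }
  m_dc <- stats::median(stab$dc)
  m_bc <- stats::median(stab$bc)
  m_cc <- stats::median(stab$cc)
  core <- stab$node[stab$dc >= m_dc & stab$bc >= m_bc & stab$cc >= m_cc]
  thresholds$stage2_median_dc <- m_dc
  thresholds$stage2_median_bc <- m_bc
  thresholds$stage2_median_cc <- m_cc
  out <- list(hub_nodes = sort(hub), core_targets = sort(core),
              thresholds = thresholds, centrality = tab,
              hub_centrality = stab)
  class(out) <- "netpharm_screen"
  out
}

#' @export
print.netpharm_screen <- function(x, ...) {
  cat("Two-stage median centrality screen\n")
  cat(sprintf("  stage 1: dc %s 2 x median (%g) -> %d hub node(s)\n",
              if (isTRUE(x$thresholds$stage1_strict)) ">" else ">=",
              x$thresholds$stage1_median_dc, length(x$hub_nodes)))
  cat(sprintf("  stage 2: dc/bc/cc >= medians (%g / %g / %g) -> %d core target(s)\n",
              x$thresholds$stage2_median_dc, x$thresholds$stage2_median_bc,
              x$thresholds$stage2_median_cc, length(x$core_targets)))
  if (length(x$core_targets) > 0) {
    cat("  core:", paste(x$core_targets, collapse = ", "), "\n")
  }
  invisible(x)
}
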