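# node types used across the three study networks
NODE_TYPES <- c("component", "target", "disease_target", "disease", "pathway")

# internal: build a typed igraph from a node table and an edge matrix,
# enforcing the simple-graph and one-type-per-id invariants
typed_graph <- function(ids, types, edges) {
  stopifnot(length(ids) == length(types), all(types %in% NODE_TYPES))
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("node id used with more than one role/type: ", dup, call. = FALSE)
  }
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(ids)
  igraph::V(g)$type <- types
  if (!is.null(edges) && nrow(edges) > 0) {
    if (any(edges[, 1] == edges[, 2])) stop("self-loop edge", call. = FALSE)
    key <- paste(pmin(edges[, 1], edges[, 2]),
                 pmax(edges[, 1], edges[, 2]), sep = "\r")
    edges <- edges[!duplicated(key), , drop = FALSE]
    g <- igraph::add_edges(g, t(edges))
  }
  g
}

#' Build the component-target bipartite network
#'
#' One node per active component with at least one mapped target and one node
#' per distinct target symbol; an edge per (component, target) pair.
#' Components with zero surviving targets are omitted: isolated nodes carry
#' no information and distort degree statistics.
#'
#' @param components Active component `data.frame`.
#' @param mapped Mapped edge `data.frame` (`component_id`, `symbol`); every
#'   edge must reference an active component.
#' @return An undirected `igraph` graph with vertex attribute `type`
#'   (`"component"` or `"target"`). Bipartiteness is asserted on every build.
#' @export
build_component_target_network <- function(components, mapped) {
  unknown <- setdiff(mapped$component_id, components$component_id)
  if (length(unknown) > 0) {
    stop("edge references non-active component(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  comp <- sort(unique(mapped$component_id))
  targ <- sort(unique(mapped$symbol))
  g <- typed_graph(c(comp, targ),
                   c(rep("component", length(comp)), rep("target", length(targ))),
                   cbind(mapped$component_id, mapped$symbol))
  el <- igraph::as_edgelist(g)
  tmap <- setNames(igraph::V(g)$type, igraph::V(g)$name)
  if (any(tmap[el[, 1]] == tmap[el[, 2]])) {
    stop("component-target network is not bipartite", call. = FALSE)
  }
  g
}

#' Build the component-putative target-disease mapping network
#'
#' Nodes are (i) components with at least one edge into the putative target
#' set, (ii) every gene of the combined disease set — genes that are putative
#' therapeutic targets typed `"target"`, the rest `"disease_target"` — and
#' (iii) a single disease node. Edges join components to their putative
#' targets and every disease gene to the disease node, so the node count
#' decomposes as `qualifying components + |combined| + 1`.
#'
#' @param components Active component `data.frame`.
#' @param mapped Mapped edge `data.frame`.
#' @param putative_targets Putative therapeutic targets; must be a subset of
#'   `combined`.
#' @param combined Combined disease gene set.
#' @param disease_label Name of the disease node.
#' @return An undirected typed `igraph` graph.
#' @export
build_disease_mapping_network <- function(components, mapped, putative_targets,
                                          combined,
                                          disease_label = "AF_OSAHS") {
  putative_targets <- unique(toupper(putative_targets))
  combined <- unique(toupper(combined))
  if (length(putative_targets) == 0) {
    stop("putative target set is empty", call. = FALSE)
  }
  if (!all(putative_targets %in% combined)) {
    stop("putative targets must be contained in the combined disease set",
         call. = FALSE)
  }
  hits <- mapped[mapped$symbol %in% putative_targets, , drop = FALSE]
  unknown <- setdiff(hits$component_id, components$component_id)
  if (length(unknown) > 0) {
    stop("edge references non-active component(s): ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  comp <- sort(unique(hits$component_id))
  other <- sort(setdiff(combined, putative_targets))
  ids <- c(comp, sort(putative_targets), other, disease_label)
  types <- c(rep("component", length(comp)),
             rep("target", length(putative_targets)),
             rep("disease_target", length(other)),
             "disease")
  edges <- rbind(cbind(hits$component_id, hits$symbol),
                 cbind(combined, disease_label))
  typed_graph(ids, types, edges)
}

#' Build the component-putative target-pathway network
#'
#' Joins components to their putative therapeutic targets and those targets
#' to the pathway terms that contain them (usually the significantly enriched
#' pathways).
#'
#' @param components Active component `data.frame`.
#' @param mapped Mapped edge `data.frame`.
#' @param putative_targets Putative therapeutic targets.
#' @param terms Annotation terms (as from [read_gmt()]) to use as pathway
#'   nodes; only their overlap with `putative_targets` is wired.
#' @return An undirected typed `igraph` graph with `component`, `target` and
#'   `pathway` nodes.
#' @export
build_target_pathway_network <- function(components, mapped, putative_targets,
                                         terms) {
  putative_targets <- unique(toupper(putative_targets))
  hits <- mapped[mapped$symbol %in% putative_targets, , drop = FALSE]
  comp <- sort(unique(hits$component_id))
  pw_edges <- do.call(rbind, lapply(terms, function(tm) {
    ov <- intersect(toupper(tm$genes), putative_targets)
    if (length(ov) == 0) return(NULL)
    cbind(ov, tm$term_id)
  }))
  pw <- if (is.null(pw_edges)) character() else sort(unique(pw_edges[, 2]))
  ids <- c(comp, sort(putative_targets), pw)
  types <- c(rep("component", length(comp)),
             rep("target", length(putative_targets)),
             rep("pathway", length(pw)))
  edges <- rbind(cbind(hits$component_id, hits$symbol), pw_edges)
  typed_graph(ids, types, edges)
}

#' Tally a network
#' @param graph An `igraph` graph, optionally with a `type` vertex attribute.
#' @return A list with `nodes`, `edges` and `per_type` (named counts; a
#'   single `"untyped"` entry when the graph carries no `type` attribute).
#' @export
count_network <- function(graph) {
  types <- igraph::vertex_attr(graph, "type")
  per_type <- if (is.null(types)) {
    c(untyped = igraph::vcount(graph))
  } else {
    tab <- table(types)
    setNames(as.integer(tab), names(tab))
  }
  list(nodes = igraph::vcount(graph), edges = igraph::ecount(graph),
       per_type = per_type)
}
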