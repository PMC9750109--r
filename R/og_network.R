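#' Build the node-level OG network
#'
#' Nodes are OG ids; edges are the OG pairs accepted as syntenic at the node
#' of interest, weighted by their ancestral distance `d_N` (the raw graph).
#' Paralog self-pairs are stored as node attributes, never as clique-relevant
#' edges.
#'
#' @param pairs a `data.table` with columns `og_a, og_b, d_N` (output of
#'   [infer_node_synteny()]).
#' @return an object of class `og_network`: list with `graph` (igraph, edge
#'   attribute `d_N`), `edges` (data.table), `self_pairs` (data.table of
#'   paralog self-pairs with their `d_N`).
#' @export
build_og_network <- function(pairs) {
  pairs <- data.table::as.data.table(pairs)
  if (nrow(pairs) == 0L) {
    g <- igraph::make_empty_graph(directed = FALSE)
    return(structure(list(graph = g,
                          edges = data.table::data.table(og_a = character(),
                                                         og_b = character(),
                                                         d_N = numeric()),
                          self_pairs = data.table::data.table(og_id = character(),
                                                              d_N = numeric())),
                     class = "og_network"))
  }
  pairs <- pairs[, .(og_a = pmin(og_a, og_b), og_b = pmax(og_a, og_b), d_N)]
  dup <- pairs[, .(nd = data.table::uniqueN(d_N), .N), by = .(og_a, og_b)]
  if (any(dup$nd > 1L)) {
    bad <- dup[nd > 1L][1L]
    stop(sprintf("conflicting d_N values for pair %s-%s", bad$og_a, bad$og_b))
  }
  pairs <- unique(pairs, by = c("og_a", "og_b"))
  self <- pairs[og_a == og_b, .(og_id = og_a, d_N)]
  edges <- pairs[og_a != og_b]
  data.table::setorder(edges, og_a, og_b)
  nodes <- sort(unique(c(edges$og_a, edges$og_b, self$og_id)))
  g <- igraph::graph_from_data_frame(edges[, .(og_a, og_b)],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  igraph::E(g)$d_N <- edges$d_N
  structure(list(graph = g, edges = edges, self_pairs = self),
            class = "og_network")
}

#' @export
print.og_network <- function(x, ...) {
  cat("OG network:", igraph::vcount(x$graph), "OGs,",
      nrow(x$edges), "raw edges,", nrow(x$self_pairs), "paralog self-pairs\n")
  invisible(x)
}

#' Trim the OG network and isolate connected components
#'
#' Keeps only edges with `d_N < nmax` (strict inequality) and returns the
#' connected components of the trimmed graph with at least two nodes, sorted
#' by decreasing size then by lexically smallest member OG.
#'
#' @param net an [build_og_network()] object.
#' @param nmax positive distance threshold in gene-count units.
#' @return list of character vectors (sorted OG ids per component).
#' @export
trim_and_components <- function(net, nmax) {
  stopifnot(inherits(net, "og_network"))
  if (!is.numeric(nmax) || length(nmax) != 1L || nmax <= 0) {
    stop("nmax must be a single positive number")
  }
  kept <- net$edges[d_N < nmax]
  if (nrow(kept) == 0L) return(list())
  g <- igraph::graph_from_data_frame(kept[, .(og_a, og_b)], directed = FALSE)
  comps <- igraph::components(g)
  members <- split(names(comps$membership), comps$membership)
  members <- lapply(members, function(x) sort(x))
  members <- members[lengths(members) >= 2L]
  ord <- order(-lengths(members),
               vapply(members, `[`, character(1L), 1L))
  unname(members[ord])
}

#' Refine a component into maximal cliques of the raw graph
#'
#' Enumerates all maximal cliques of the raw graph induced on a trimmed-graph
#' component's node set. Cliques must be complete in the RAW graph (edges
#' trimmed away by `nmax` still count); overlapping cliques are all reported.
#'
#' @param component character vector of OG ids (one trimmed component).
#' @param net the [build_og_network()] object (raw graph source).
#' @param min_len minimum OGs per clique (default 3).
#' @return list of sorted character vectors, deterministically ordered by
#'   decreasing size then lexically.
#' @export
clique_refine <- function(component, net, min_len = 3L) {
  stopifnot(inherits(net, "og_network"))
  sub <- igraph::induced_subgraph(net$graph,
                                  intersect(component, igraph::V(net$graph)$name))
  cl <- igraph::max_cliques(sub, min = max(1L, as.integer(min_len)))
  cliques <- lapply(cl, function(v) sort(igraph::V(sub)$name[as.integer(v)]))
  if (length(cliques) == 0L) return(list())
  key <- vapply(cliques, paste, character(1L), collapse = "|")
  cliques[order(-lengths(cliques), key)]
}

#' Ancestral OG sets of a node
#'
#' Full network decomposition: trim at `nmax`, take connected components,
#' refine each into maximal cliques of the raw graph. Each clique of size
#' `>= min_len` becomes one ancestral OG set.
#'
#' @param net an [build_og_network()] object.
#' @param nmax trimming threshold.
#' @param min_len minimum OGs per set (default 3; 2-OG cliques are emitted
#'   only when explicitly requested, as pairwise-only blocks are noise-prone).
#' @return a `data.table` with columns `set_id, component_id, ogs`
#'   (comma-separated sorted OG ids).
#' @export
ancestral_og_sets <- function(net, nmax, min_len = 3L) {
  comps <- trim_and_components(net, nmax)
  rows <- list()
  for (ci in seq_along(comps)) {
    cliques <- clique_refine(comps[[ci]], net, min_len = min_len)
    for (cl in cliques) {
      rows[[length(rows) + 1L]] <- data.table::data.table(
        component_id = ci, ogs = paste(cl, collapse = ","))
    }
  }
  if (length(rows) == 0L) {
    return(data.table::data.table(set_id = character(), component_id = integer(),
                                  ogs = character()))
  }
  out <- data.table::rbindlist(rows)
  data.table::setorder(out, component_id, ogs)
  out[, set_id := sprintf("set%04d", seq_len(.N))]
  data.table::setcolorder(out, c("set_id", "component_id", "ogs"))
  out[]
}
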