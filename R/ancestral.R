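#' Leaf-set context of an internal tree node
#'
#' For a labeled internal node `N` of the species cladogram, returns the three
#' ingredient sets used to polarize synteny presence at `N`:
#' the ingroup clades (one leaf set per child of `N`), the sister group
#' (leaves under the siblings of `N`), and the outgroup (every leaf outside
#' `N`'s clade, a superset of the sister group).
#'
#' @param tree an `ape::phylo` with internal node labels.
#' @param node_label label of the internal node of interest.
#' @return a list of class `node_context` with elements `node`,
#'   `ingroup_clades` (named list of character vectors), `sister_group`,
#'   `outgroup`, and `ingroup` (union of the ingroup clades).
#' @export
node_context <- function(tree, node_label) {
  stopifnot(inherits(tree, "phylo"))
  if (node_label %in% tree$tip.label) {
    stop("'", node_label, "' is a leaf, not an internal node")
  }
  labs <- tree$node.label
  if (is.null(labs)) stop("tree has no internal node labels")
  hit <- which(labs == node_label)
  if (length(hit) != 1L) stop("unknown internal node label: ", node_label)
  ntip <- length(tree$tip.label)
  node <- ntip + hit
  children <- tree$edge[tree$edge[, 1L] == node, 2L]
  ingroup_clades <- lapply(children, function(ch) .clade_tips(tree, ch))
  names(ingroup_clades) <- vapply(seq_along(children), function(i) {
    ch <- children[i]
    if (ch <= ntip) {
      tree$tip.label[ch]
    } else {
      lab <- labs[ch - ntip]
      if (is.na(lab) || !nzchar(lab)) paste0(node_label, ".clade", i) else lab
    }
  }, character(1L))
  parent_row <- which(tree$edge[, 2L] == node)
  if (length(parent_row) == 0L) {
    warning("node '", node_label,
            "' is the root: empty sister group, no outgroup polarization possible")
    sister <- character()
  } else {
    parent <- tree$edge[parent_row, 1L]
    sibs <- setdiff(tree$edge[tree$edge[, 1L] == parent, 2L], node)
    sister <- sort(unique(unlist(lapply(sibs, .clade_tips, tree = tree))))
  }
  ingroup <- sort(unique(unlist(ingroup_clades)))
  structure(list(
    node = node_label,
    ingroup_clades = ingroup_clades,
    sister_group = sister,
    outgroup = sort(setdiff(tree$tip.label, ingroup)),
    ingroup = ingroup
  ), class = "node_context")
}

# tips under a node (the node itself if it is a tip), by edge traversal
.clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  tips <- character()
  stack <- node
  while (length(stack)) {
    cur <- stack[[1L]]
    stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == cur, 2L]
    tips <- c(tips, tree$tip.label[kids[kids <= ntip]])
    stack <- c(stack, kids[kids > ntip])
  }
  sort(tips)
}

#' @export
print.node_context <- function(x, ...) {
  cat("node context for '", x$node, "'\n", sep = "")
  cat("  ingroup clades:",
      paste(sprintf("%s{%s}", names(x$ingroup_clades),
                    vapply(x$ingroup_clades, paste, "", collapse = ",")),
            collapse = " "), "\n")
  cat("  sister group:", paste(x$sister_group, collapse = ","), "\n")
  cat("  outgroup:", paste(x$outgroup, collapse = ","), "\n")
  invisible(x)
}

#' Major mode of a Gaussian kernel density estimate on the integer grid
#'
#' With a single observation the value itself is returned. With two or more,
#' a Gaussian KDE with Silverman's rule-of-thumb bandwidth (floored at
#' `bw_floor` so zero-variance samples survive) is evaluated on the integer
#' grid `[min(x), max(x)]`; the argmax is returned, ties broken toward the
#' smallest value.
#'
#' @param x numeric observations (intervening-gene distances).
#' @param bw_floor minimum bandwidth (default 0.5).
#' @return the modal value, a single number.
#' @export
kde_mode <- function(x, bw_floor = 0.5) {
  if (length(x) == 0L) stop("kde_mode needs at least one observation")
  if (length(x) == 1L || min(x) == max(x)) return(as.numeric(x[1L]))
  h <- tryCatch(stats::bw.nrd0(x), error = function(e) bw_floor)
  h <- max(h, bw_floor)
  grid <- seq(min(x), max(x))
  dens <- colSums(stats::dnorm(outer(x, grid, "-") / h)) / (length(x) * h)
  grid[which.max(dens)]  # first maximum = smallest mode on an ascending grid
}

#' Ancestral distance of an OG pair within one clade
#'
#' The clade-level ancestral distance `d_g` is the major KDE mode of the
#' per-species minimum distances observed within the clade (see
#' [kde_mode()]).
#'
#' @param d_values per-species distance observations within the clade.
#' @return `d_g`, a single number.
#' @export
clade_distance <- function(d_values) {
  if (length(d_values) == 0L) stop("clade_distance: empty observation set")
  kde_mode(d_values)
}

#' Ancestral distance at the node of interest
#'
#' `d_N` is the arithmetic mean of the clade-level distances `d_g` over the
#' `k` supporting clades.
#'
#' @param d_g numeric vector of per-clade ancestral distances.
#' @return `d_N`, a single number.
#' @export
ancestral_distance <- function(d_g) {
  if (length(d_g) == 0L) stop("ancestral_distance: no supporting clades")
  mean(d_g)
}

# species -> clade map for a node context; pseudo-clades ".sister"/".outgroup"
.species_clade_map <- function(ctx) {
  map <- character()
  for (nm in names(ctx$ingroup_clades)) {
    map[ctx$ingroup_clades[[nm]]] <- nm
  }
  map[ctx$sister_group] <- ".sister"
  rest <- setdiff(ctx$outgroup, ctx$sister_group)
  map[rest] <- ".outgroup"
  map
}

#' Decide synteny presence of one OG pair at a node
#'
#' A clade supports the pair if at least one of its species has a distance
#' record for it. The pair is stated syntenic at `N` if (a) at least
#' `min_clades` distinct ingroup clades support it, or (b) at least one
#' ingroup clade supports it and at least one sister-group or outgroup
#' species does (presence on both sides of `N` implies presence in `N` by
#' Dollo-style parsimony). When route (b) is needed, the sister group and the
#' remaining outgroup each contribute a pseudo-clade to the `d_g` terms.
#'
#' @param pair character vector `c(og_a, og_b)`.
#' @param records distance records (filtered to retained pairs).
#' @param ctx a [node_context()].
#' @param min_clades minimum supporting ingroup clades (default 2).
#' @return a list with `accepted`, `k`, `supporting_clades`, `d_g` (named),
#'   `d_N` (`NA` when rejected).
#' @export
is_syntenic_at_node <- function(pair, records, ctx, min_clades = 2L) {
  records <- data.table::as.data.table(records)
  oa <- min(pair); ob <- max(pair)
  recs <- records[og_a == oa & og_b == ob]
  res <- .evaluate_pair(recs$species, recs$d, .species_clade_map(ctx), min_clades)
  res
}

# shared single-pair rule evaluation
.evaluate_pair <- function(species, d, clade_map, min_clades) {
  clade <- clade_map[species]
  keep <- !is.na(clade)
  clade <- clade[keep]; d <- d[keep]
  is_ing <- !clade %in% c(".sister", ".outgroup")
  ing_clades <- unique(clade[is_ing])
  n_ing <- length(ing_clades)
  has_out <- any(!is_ing)
  accepted <- n_ing >= min_clades || (n_ing >= 1L && has_out)
  if (!accepted) {
    return(list(accepted = FALSE, k = 0L, supporting_clades = character(),
                d_g = numeric(), d_N = NA_real_))
  }
  use_pseudo <- n_ing < min_clades
  sel <- is_ing | use_pseudo
  d_g <- vapply(split(d[sel], clade[sel]), clade_distance, numeric(1L))
  d_g <- d_g[order(names(d_g))]
  list(accepted = TRUE, k = length(d_g), supporting_clades = names(d_g),
       d_g = d_g, d_N = ancestral_distance(d_g))
}

#' Infer all syntenic OG pairs at a node
#'
#' Applies the node-level decision rule of [is_syntenic_at_node()] to every
#' retained OG pair and computes its ancestral distance `d_N`.
#'
#' @param records retained distance records (after [filter_min_species()]).
#' @param ctx a [node_context()].
#' @param min_clades minimum supporting ingroup clades (default 2).
#' @return a `data.table` with one row per accepted pair:
#'   `og_a, og_b, k, supporting_clades` (comma-separated), `d_N`.
#' @export
infer_node_synteny <- function(records, ctx, min_clades = 2L) {
  records <- data.table::as.data.table(records)
  empty <- data.table::data.table(og_a = character(), og_b = character(),
                                  k = integer(), supporting_clades = character(),
                                  d_N = numeric())
  if (nrow(records) == 0L) return(empty)
  clade_map <- .species_clade_map(ctx)
  recs <- records[species %in% names(clade_map),
                  .(og_a, og_b, species, d)]
  if (nrow(recs) == 0L) return(empty)
  min_clades <- as.integer(min_clades)
  recs[, clade := clade_map[species]]
  recs[, is_ing := !clade %in% c(".sister", ".outgroup")]
  # pair-level acceptance rule, vectorized
  acc <- recs[, .(n_ing = data.table::uniqueN(clade[is_ing]),
                  has_out = any(!is_ing)), by = .(og_a, og_b)]
  acc <- acc[n_ing >= min_clades | (n_ing >= 1L & has_out)]
  if (nrow(acc) == 0L) return(empty)
  acc[, use_pseudo := n_ing < min_clades]
  sel <- recs[acc, on = c("og_a", "og_b")][is_ing | use_pseudo]
  # clade-level d_g. For 0-variance, single- and two-observation samples the
  # KDE major mode equals the smallest observation (for two points the
  # density maxima sit at the observations and ties break low), so only
  # groups with >= 3 distinct-valued observations need the full estimator;
  # the equivalence with kde_mode() is covered by a property test.
  dg <- sel[, .(n = .N, dmin = min(d), dmax = max(d)), by = .(og_a, og_b, clade)]
  dg[, d_g := as.numeric(dmin)]
  slow <- dg[n >= 3L & dmin < dmax, .(og_a, og_b, clade)]
  if (nrow(slow)) {
    obs <- sel[slow, on = c("og_a", "og_b", "clade")]
    modes <- obs[, .(mode = kde_mode(d)), by = .(og_a, og_b, clade)]
    dg[modes, d_g := i.mode, on = c("og_a", "og_b", "clade")]
  }
  data.table::setorder(dg, og_a, og_b, clade)
  out <- dg[, .(k = .N, supporting_clades = paste(clade, collapse = ","),
                d_N = mean(d_g)), by = .(og_a, og_b)]
  data.table::setorder(out, og_a, og_b)
  out[]
}

#' Depth rank of an internal node
#'
#' The number of internal-node levels between `N` and its deepest descendant
#' leaf, minus one: nodes whose children are all leaves have rank 0 and the
#' rank grows toward the root. Used by the default `nmax` policy.
#'
#' @param tree an `ape::phylo`.
#' @param node_label internal node label.
#' @return integer depth rank.
#' @export
node_depth_rank <- function(tree, node_label) {
  ntip <- length(tree$tip.label)
  hit <- which(tree$node.label == node_label)
  if (length(hit) != 1L) stop("unknown internal node label: ", node_label)
  height <- function(node) {
    if (node <= ntip) return(0L)
    kids <- tree$edge[tree$edge[, 1L] == node, 2L]
    1L + max(vapply(kids, height, integer(1L)))
  }
  height(ntip + hit) - 1L
}

#' Default nmax policy
#'
#' `nmax = base + step * depth_rank`. The published intuition is that deeper
#' nodes tolerate more micro/macrosyntenic rearrangement, which `step > 0`
#' expresses; the shipped default is a flat `base = 2` with `step = 0`
#' because the number of spurious trimmed edges grows with the square of
#' `nmax` (and with ingroup clade sizes, but not with genome size), and from
#' `nmax = 3` upward chance coincidences of small distances already
#' percolate into false multi-species blocks on desk-scale datasets; see the
#' methods vignette for the noise-edge law and measurements. The per-dataset
#' optimization of the original method is replaced by these documented,
#' fully configurable constants.
#'
#' @param tree an `ape::phylo`.
#' @param node_label internal node label.
#' @param base gene-count threshold at the shallowest nodes (default 2).
#' @param step additional gene-count units per depth level (default 0).
#' @return the nmax threshold for that node.
#' @export
default_nmax <- function(tree, node_label, base = 2, step = 0) {
  base + step * node_depth_rank(tree, node_label)
}
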