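# fixture builders and independent brute-force oracles used across test files

library(data.table)

# compact gene-table builder: one call per gene table, ranks assigned by the
# package loader logic
make_genes <- function(species, chrom, start, gene_id, og_id = NA_character_,
                       end = start + 10L, strand = "+") {
  rank_genes(data.table(species = species, chrom = chrom,
                        start = as.integer(start), end = as.integer(end),
                        strand = strand, gene_id = gene_id,
                        og_id = og_id))
}

# a random single-species genome: n genes over chroms, a subset carrying OGs
random_genome <- function(n_genes, n_ogs, n_chroms, species = "sp1",
                          og_copies_lambda = 0.3) {
  chrom <- sprintf("chr%d", sample.int(n_chroms, n_genes, replace = TRUE))
  start <- sample.int(n_genes * 100L, n_genes)
  ogs <- sprintf("OG%03d", seq_len(n_ogs))
  # most OGs single-copy, a few with extra copies (paralogs)
  copies <- 1L + stats::rpois(n_ogs, og_copies_lambda)
  labels <- rep(ogs, copies)
  og_id <- rep(NA_character_, n_genes)
  k <- min(length(labels), n_genes)
  og_id[sample.int(n_genes, k)] <- labels[seq_len(k)]
  make_genes(species, chrom, start, sprintf("%s_g%04d", species, seq_len(n_genes)),
             og_id)
}

# brute-force minimum intervening-gene distance over all cross pairs,
# distance ties broken toward the lexically smallest chromosome
oracle_pair_distance <- function(genes_a, genes_b) {
  best_d <- NULL
  best_chrom <- NULL
  for (i in seq_len(nrow(genes_a))) {
    for (j in seq_len(nrow(genes_b))) {
      if (genes_a$gene_id[i] == genes_b$gene_id[j]) next
      if (genes_a$chrom[i] != genes_b$chrom[j]) next
      d <- abs(genes_a$rank[i] - genes_b$rank[j]) - 1L
      if (is.null(best_d) || d < best_d ||
          (d == best_d && genes_a$chrom[i] < best_chrom)) {
        best_d <- d
        best_chrom <- genes_a$chrom[i]
      }
    }
  }
  if (is.null(best_d)) NULL else list(d = best_d, chrom = best_chrom)
}

# O(n^2) all-pairs distance matrix oracle (per species, incl. self-pairs)
oracle_distance_matrix <- function(genes) {
  genes <- as.data.table(genes)[!is.na(og_id)]
  rows <- list()
  for (sp in sort(unique(genes$species))) {
    gsp <- genes[species == sp]
    by_og <- split(gsp, by = "og_id", sorted = TRUE)
    ogs <- names(by_og)
    for (a in seq_along(ogs)) {
      for (b in a:length(ogs)) {
        res <- oracle_pair_distance(by_og[[a]], by_og[[b]])
        if (!is.null(res)) {
          rows[[length(rows) + 1L]] <- data.table(
            og_a = ogs[a], og_b = ogs[b], species = sp,
            chrom = res$chrom, d = res$d)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.table(og_a = character(), og_b = character(),
                      species = character(), chrom = character(),
                      d = integer()))
  }
  out <- rbindlist(rows)
  setkey(out, og_a, og_b, species)
  out[]
}

# direct density evaluation on the integer grid (KDE argmax oracle)
oracle_kde_argmax <- function(x, bw_floor = 0.5) {
  if (length(x) == 1L || min(x) == max(x)) return(as.numeric(x[1L]))
  h <- max(stats::bw.nrd0(x), bw_floor)
  grid <- seq(min(x), max(x))
  dens <- vapply(grid, function(g) sum(stats::dnorm((g - x) / h)) / (length(x) * h),
                 numeric(1L))
  grid[which.max(dens)]
}

# connected components by breadth-first search over an edge list
oracle_components <- function(edges, min_size = 2L) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  adj <- lapply(setNames(nodes, nodes), function(n) {
    sort(unique(c(edges$to[edges$from == n], edges$from[edges$to == n])))
  })
  seen <- character()
  comps <- list()
  for (n in nodes) {
    if (n %in% seen) next
    comp <- character()
    queue <- n
    while (length(queue)) {
      cur <- queue[[1L]]
      queue <- queue[-1L]
      if (cur %in% comp) next
      comp <- c(comp, cur)
      queue <- c(queue, setdiff(adj[[cur]], comp))
    }
    comp <- sort(comp)
    seen <- c(seen, comp)
    comps[[length(comps) + 1L]] <- comp
  }
  comps <- comps[lengths(comps) >= min_size]
  comps[order(-lengths(comps), vapply(comps, `[`, "", 1L))]
}

# exhaustive maximal-clique oracle via bitmask subset enumeration (<= 15
# nodes), vectorized over all 2^n - 1 subsets
oracle_max_cliques <- function(nodes, edges, min_len = 1L) {
  n <- length(nodes)
  stopifnot(n <= 15L)
  adj <- integer(n)  # bitmask adjacency
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$from[r], nodes)
    j <- match(edges$to[r], nodes)
    if (i == j) next
    adj[i] <- bitwOr(adj[i], bitwShiftL(1L, j - 1L))
    adj[j] <- bitwOr(adj[j], bitwShiftL(1L, i - 1L))
  }
  masks <- seq_len(bitwShiftL(1L, n) - 1L)
  is_clique <- rep(TRUE, length(masks))
  popcount <- integer(length(masks))
  for (v in seq_len(n)) {
    bit <- bitwShiftL(1L, v - 1L)
    member <- bitwAnd(masks, bit) != 0L
    popcount <- popcount + member
    rest <- bitwAnd(masks, bitwNot(bit))
    is_clique <- is_clique & (!member | bitwAnd(adj[v], rest) == rest)
  }
  cand <- masks[is_clique & popcount >= min_len]
  maximal <- rep(TRUE, length(cand))
  for (v in seq_len(n)) {
    bit <- bitwShiftL(1L, v - 1L)
    outside <- bitwAnd(cand, bit) == 0L
    extends <- bitwAnd(adj[v], cand) == cand
    maximal <- maximal & !(outside & extends)
  }
  cand <- cand[maximal]
  cliques <- lapply(cand, function(mask) {
    sort(nodes[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L])
  })
  key <- vapply(cliques, paste, "", collapse = "|")
  cliques[order(key)]
}

# canonical form for comparing clique / component lists
canon_sets <- function(sets) {
  sets <- lapply(sets, sort)
  key <- vapply(sets, paste, "", collapse = "|")
  unname(sets[order(key)])
}

# small labeled test cladograms
tree8 <- function() {
  ape::read.tree(text = paste0(
    "((((sp1,sp2)cladeA,(sp3,sp4)cladeB)nodeAB,(sp5,sp6)cladeC)nodeABC,",
    "(sp7,sp8)cladeD)root;"))
}

tree5_polytomy <- function() {
  ape::read.tree(text = "((sp1,sp2)cladeA,(sp3,sp4)cladeB,sp5)root;")
}

# the fixed world used by the end-to-end acceptance checks
acceptance_sim <- function(seed = 42L) {
  simulation_config(tree8(), n_blocks = 10L,
                    block_nodes = c("cladeA", "nodeAB"), seed = seed)
}

.block_genes <- function(ranks_by_chrom, species = "sp1", ogs = NULL) {
  # genome with filler genes; OG members at the requested ranks
  rows <- list()
  for (ch in names(ranks_by_chrom)) {
    n <- max(ranks_by_chrom[[ch]]) + 3L
    og <- rep(NA_character_, n)
    members <- ranks_by_chrom[[ch]]
    og[members + 1L] <- if (is.null(ogs)) sprintf("OG_%s_%d", ch, seq_along(members)) else
      ogs[[ch]]
    rows[[ch]] <- data.table::data.table(
      species = species, chrom = ch, start = (seq_len(n) - 1L) * 100L,
      end = (seq_len(n) - 1L) * 100L + 50L, strand = "+",
      gene_id = sprintf("%s_%s_g%03d", species, ch, seq_len(n)), og_id = og)
  }
  rank_genes(data.table::rbindlist(rows))
}
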