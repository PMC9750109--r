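#' Recover the extant descendants of an ancestral OG set in one genome
#'
#' Collects ALL genes of the set's OGs in the species, wherever they lie: no
#' distance cap and no collinearity requirement — only synteny-class labels
#' (not detection) depend on proximity. Paralogs are all included.
#'
#' @param og_set character vector of OG ids (one ancestral set).
#' @param genes ranked gene table with `og_id` assigned.
#' @param species species key to recover in.
#' @param min_ogs_extant minimum distinct OGs that must be present; default
#'   `min(3, length(og_set))` so small cliques remain recoverable.
#' @param set_id provenance id carried through to outputs.
#' @return an object of class `extant_block` (list with `set_id, species,
#'   members` data.table) or `NULL` when fewer than `min_ogs_extant` OGs are
#'   found.
#' @export
recover_extant <- function(og_set, genes, species,
                           min_ogs_extant = NULL, set_id = NA_character_) {
  if (is.null(min_ogs_extant)) min_ogs_extant <- min(3L, length(og_set))
  genes <- data.table::as.data.table(genes)
  sp <- species
  members <- genes[list(sp), on = "species"][og_id %in% og_set]
  if (nrow(members) == 0L) return(NULL)
  if (data.table::uniqueN(members$og_id) < min_ogs_extant) return(NULL)
  data.table::setorder(members, chrom, rank)
  structure(list(set_id = set_id, species = sp, og_set = sort(og_set),
                 members = members),
            class = "extant_block")
}

#' Classify the synteny state of an extant block
#'
#' Members are rank-sorted per chromosome. Maximal runs whose successive
#' intervening-gene gaps are `<= micro_gap` are micro-syntenic (`uSy`);
#' same-chromosome neighbors with a gap `> micro_gap` are linked as
#' macro-syntenic (`MSy`) with the exact gap reported; members on a different
#' chromosome than the main group (largest member count, ties broken toward
#' the lexically smallest chromosome name) are non-syntenic (`noSy`).
#'
#' The threshold affects only labels, never which genes belong to the block.
#'
#' @param block an [recover_extant()] block.
#' @param micro_gap maximum intervening genes within a micro-syntenic run
#'   (default 10).
#' @return the block with `members` gaining `gap_to_prev, run_id,
#'   synteny_class`, plus `main_chrom` and `msy_links` (data.table
#'   `chrom, from_gene, to_gene, gap`).
#' @export
classify_synteny <- function(block, micro_gap = 10L) {
  stopifnot(inherits(block, "extant_block"))
  members <- data.table::copy(block$members)
  if (nrow(members) == 0L) stop("classify_synteny: empty block")
  data.table::setorder(members, chrom, rank)
  members[, gap_to_prev := rank - data.table::shift(rank) - 1L, by = chrom]
  members[, run_id := cumsum(is.na(gap_to_prev) | gap_to_prev > micro_gap),
          by = chrom]
  tab <- members[, .N, by = chrom]
  data.table::setorder(tab, -N, chrom)
  main_chrom <- tab$chrom[1L]
  members[, synteny_class := "noSy"]
  run_sizes <- members[chrom == main_chrom, .(size = .N), by = run_id]
  big_runs <- run_sizes[size >= 2L, run_id]
  n_main <- sum(members$chrom == main_chrom)
  members[chrom == main_chrom,
          synteny_class := data.table::fifelse(
            run_id %in% big_runs | n_main == 1L, "uSy", "MSy")]
  links <- members[chrom == main_chrom & !is.na(gap_to_prev) & gap_to_prev > micro_gap,
                   .(chrom, to_gene = gene_id, gap = gap_to_prev, idx = .I)]
  if (nrow(links)) {
    main_rows <- members[chrom == main_chrom]
    pos <- match(links$to_gene, main_rows$gene_id)
    links[, `:=`(from_gene = main_rows$gene_id[pos - 1L], idx = NULL)]
    data.table::setcolorder(links, c("chrom", "from_gene", "to_gene", "gap"))
  } else {
    links <- data.table::data.table(chrom = character(), from_gene = character(),
                                    to_gene = character(), gap = integer())
  }
  block$members <- members
  block$main_chrom <- main_chrom
  block$msy_links <- links
  block
}

#' Group per-species extant blocks into multi-species blocks
#'
#' Builds a graph with extant blocks as vertices and edges whenever two
#' blocks share at least one OG; each connected component becomes one
#' multi-species block. Ids are deterministic, assigned in lexical order of
#' the sorted OG union.
#'
#' @param blocks list of classified [recover_extant()] blocks (all species,
#'   all ancestral sets of one node).
#' @param node node label carried into the result.
#' @return list of `multi_species_block` objects: `block_id, node, og_union,
#'   species, blocks`.
#' @export
group_multispecies <- function(blocks, node = NA_character_) {
  blocks <- blocks[!vapply(blocks, is.null, logical(1L))]
  if (length(blocks) == 0L) return(list())
  ogs <- lapply(blocks, function(b) unique(b$members$og_id))
  # union-find over blocks via OG incidence
  og_ids <- sort(unique(unlist(ogs)))
  parent <- seq_along(blocks)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  og_owner <- stats::setNames(rep(NA_integer_, length(og_ids)), og_ids)
  for (bi in seq_along(blocks)) {
    for (og in ogs[[bi]]) {
      if (is.na(og_owner[[og]])) {
        og_owner[[og]] <- bi
      } else {
        ra <- find(og_owner[[og]]); rb <- find(bi)
        if (ra != rb) parent[rb] <- ra
      }
    }
  }
  roots <- vapply(seq_along(blocks), find, integer(1L))
  groups <- split(seq_along(blocks), roots)
  msbs <- lapply(groups, function(idx) {
    og_union <- sort(unique(unlist(ogs[idx])))
    structure(list(block_id = NA_character_, node = node,
                   og_union = og_union,
                   species = sort(unique(vapply(blocks[idx], `[[`, "", "species"))),
                   blocks = blocks[idx]),
              class = "multi_species_block")
  })
  ord <- order(vapply(msbs, function(m) paste(m$og_union, collapse = ","), ""))
  msbs <- unname(msbs[ord])
  for (i in seq_along(msbs)) msbs[[i]]$block_id <- sprintf("msb%04d", i)
  msbs
}

#' Validate inheritance of a multi-species block from the node of interest
#'
#' The same taxonomic rule as pair-level acceptance: the species carrying
#' member blocks must cover at least `min_clades` ingroup clades, or at least
#' one ingroup clade plus at least one sister-group/outgroup species.
#'
#' @param msb a `multi_species_block`.
#' @param ctx the [node_context()] of the block's node.
#' @param min_clades minimum ingroup clades (default 2).
#' @return the block with `$validated` set.
#' @export
validate_inheritance <- function(msb, ctx, min_clades = 2L) {
  stopifnot(inherits(msb, "multi_species_block"))
  clade_map <- .species_clade_map(ctx)
  clades <- clade_map[intersect(msb$species, names(clade_map))]
  ing <- unique(clades[!clades %in% c(".sister", ".outgroup")])
  has_out <- any(clades %in% c(".sister", ".outgroup"))
  msb$clade_presence <- sort(unique(clades))
  msb$validated <- length(ing) >= min_clades || (length(ing) >= 1L && has_out)
  msb
}

#' Full block recovery for one node
#'
#' Runs [recover_extant()] and [classify_synteny()] for every ancestral OG
#' set and species, groups the results into multi-species blocks, and
#' validates their inheritance. Rejected blocks are returned for audit, not
#' silently dropped.
#'
#' @param og_sets output of [ancestral_og_sets()].
#' @param genes ranked gene table with OG labels.
#' @param ctx [node_context()] of the node.
#' @param min_ogs_extant,micro_gap,min_clades see the stage functions.
#' @return list with `validated` and `rejected` (lists of multi-species
#'   blocks), `gene_table` (one row per member gene of a validated block) and
#'   `summary` (one row per multi-species block incl. rejected ones).
#' @export
recover_node_blocks <- function(og_sets, genes, ctx,
                                min_ogs_extant = NULL, micro_gap = 10L,
                                min_clades = 2L) {
  og_sets <- data.table::as.data.table(og_sets)
  genes <- data.table::as.data.table(genes)
  empty <- list(validated = list(), rejected = list(),
                gene_table = .msb_gene_table(list()),
                summary = .msb_summary(list()))
  if (nrow(og_sets) == 0L) return(empty)

  # batch equivalent of recover_extant() + classify_synteny() over all
  # (ancestral set x species) combinations; equivalence with the per-block
  # operations is covered by a property test
  setmap <- og_sets[, .(og_id = strsplit(ogs, ",", fixed = TRUE)[[1L]]),
                    by = set_id]
  set_size <- setmap[, .(set_n = .N), by = set_id]
  mem <- merge(genes[!is.na(og_id)], setmap, by = "og_id",
               allow.cartesian = TRUE)
  if (nrow(mem) == 0L) return(empty)
  mem <- merge(mem, set_size, by = "set_id")
  mem[, n_og := data.table::uniqueN(og_id), by = .(set_id, species)]
  if (is.null(min_ogs_extant)) {
    mem <- mem[n_og >= pmin(3L, set_n)]
  } else {
    mem <- mem[n_og >= min_ogs_extant]
  }
  if (nrow(mem) == 0L) return(empty)
  data.table::setorder(mem, set_id, species, chrom, rank)
  mem[, gap_to_prev := rank - data.table::shift(rank) - 1L,
      by = .(set_id, species, chrom)]
  mem[, run_id := cumsum(is.na(gap_to_prev) | gap_to_prev > micro_gap),
      by = .(set_id, species, chrom)]
  # main chromosome: most members, ties toward lexically smallest name
  chrom_n <- mem[, .N, by = .(set_id, species, chrom)]
  data.table::setorder(chrom_n, set_id, species, -N, chrom)
  main <- chrom_n[, .(chrom = chrom[1L], n_main = N[1L]), by = .(set_id, species)]
  mem[, synteny_class := "noSy"]
  mem[main, on = c("set_id", "species", "chrom"),
      synteny_class := "MSy"]
  mem[, run_n := .N, by = .(set_id, species, chrom, run_id)]
  mem[main, on = c("set_id", "species", "chrom"),
      synteny_class := data.table::fifelse(run_n >= 2L | i.n_main == 1L,
                                           "uSy", "MSy")]
  mem[, c("set_n", "n_og", "run_n") := NULL]

  # group extant blocks into multi-species blocks by shared OGs (union-find)
  eb <- unique(mem[, .(set_id, species)])
  eb[, eb_id := .I]
  mem[eb, on = c("set_id", "species"), eb_id := i.eb_id]
  inc <- unique(mem[, .(eb_id, og_id)])
  parent <- seq_len(nrow(eb))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  inc_split <- split(inc$eb_id, inc$og_id)
  for (ids in inc_split) {
    if (length(ids) > 1L) {
      r0 <- find(ids[1L])
      for (j in ids[-1L]) {
        rj <- find(j)
        if (rj != r0) parent[rj] <- r0
      }
    }
  }
  eb[, comp := vapply(eb_id, find, integer(1L))]
  mem[eb, on = "eb_id", comp := i.comp]

  # deterministic block ids by sorted OG union
  comp_union <- mem[, .(og_union = paste(sort(unique(og_id)), collapse = ",")),
                    by = comp]
  data.table::setorder(comp_union, og_union)
  comp_union[, block_id := sprintf("msb%04d", .I)]
  mem[comp_union, on = "comp", block_id := i.block_id]
  eb[comp_union, on = "comp", block_id := i.block_id]

  mem_split <- split(mem, by = "block_id", sorted = TRUE)
  msbs <- lapply(comp_union$block_id, function(bid) {
    sub <- mem_split[[bid]]
    blocks <- lapply(split(sub, by = c("set_id", "species"), sorted = TRUE),
                     function(m) {
                       structure(list(set_id = m$set_id[1L], species = m$species[1L],
                                      og_set = sort(unique(m$og_id)),
                                      members = m[, .(species, chrom, start, end,
                                                      strand, gene_id, og_id, rank,
                                                      gap_to_prev, run_id,
                                                      synteny_class)]),
                                 class = "extant_block")
                     })
    msb <- structure(list(block_id = bid, node = ctx$node,
                          og_union = sort(unique(sub$og_id)),
                          species = sort(unique(sub$species)),
                          blocks = unname(blocks)),
                     class = "multi_species_block")
    validate_inheritance(msb, ctx, min_clades = min_clades)
  })
  msbs <- unname(msbs)
  ok <- vapply(msbs, `[[`, logical(1L), "validated")
  list(validated = msbs[ok],
       rejected = msbs[!ok],
       gene_table = .msb_gene_table(msbs[ok]),
       summary = .msb_summary(msbs))
}

.msb_gene_table <- function(msbs) {
  rows <- lapply(msbs, function(m) {
    data.table::rbindlist(lapply(m$blocks, function(b) {
      data.table::data.table(block_id = m$block_id, node = m$node,
                             species = b$species, chrom = b$members$chrom,
                             start = b$members$start, end = b$members$end,
                             gene_id = b$members$gene_id, og_id = b$members$og_id,
                             synteny_class = b$members$synteny_class,
                             gap_to_prev = b$members$gap_to_prev)
    }))
  })
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0L) {
    out <- data.table::data.table(block_id = character(), node = character(),
                                  species = character(), chrom = character(),
                                  start = integer(), end = integer(),
                                  gene_id = character(), og_id = character(),
                                  synteny_class = character(),
                                  gap_to_prev = integer())
  }
  data.table::setorder(out, block_id, species, chrom, start)
  out[]
}

.msb_summary <- function(msbs) {
  if (length(msbs) == 0L) {
    return(data.table::data.table(block_id = character(), node = character(),
                                  n_ogs = integer(), n_species = integer(),
                                  og_union = character(), species = character(),
                                  clades = character(), validated = logical()))
  }
  data.table::rbindlist(lapply(msbs, function(m) {
    data.table::data.table(block_id = m$block_id, node = m$node,
                           n_ogs = length(m$og_union),
                           n_species = length(m$species),
                           og_union = paste(m$og_union, collapse = ","),
                           species = paste(m$species, collapse = ","),
                           clades = paste(m$clade_presence, collapse = ","),
                           validated = m$validated)
  }))
}
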