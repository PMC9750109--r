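#' Configuration for the synthetic multi-species genome simulator
#'
#' The simulator plants micro-syntenic OG blocks at chosen origin nodes of a
#' species cladogram and evolves genomes top-down along the tree, applying
#' per-branch events with fixed probabilities (the input is a cladogram, so
#' there are no branch lengths to scale by).
#'
#' @param tree an `ape::phylo` with internal node labels, or a newick string.
#' @param n_genes background genes per genome (default 2000), split evenly
#'   over `n_chroms` chromosomes; each background gene founds its own OG
#'   shared by all species.
#' @param n_chroms chromosomes per genome (default 24). A realistic
#'   metazoan-like karyotype keeps chromosome co-residence of random OG pairs
#'   rare, which is the regime the method operates in; translocations across
#'   chromosomes exercise the cross-chromosome `noSy` paths.
#' @param n_blocks number of planted blocks (default 10).
#' @param block_size_range OGs per planted block (default 4 to 8).
#' @param block_nodes internal node labels where blocks originate; recycled
#'   over blocks. Default: the root label.
#' @param expansion_rate per-block per-branch probability of inserting 1-3
#'   OG-less genes inside the block span (default 0.3).
#' @param translocation_rate per-block per-branch probability of moving one
#'   member gene to a random position on a random chromosome (default 0.1).
#' @param gene_loss_rate per-block per-branch probability of deleting one
#'   member gene copy (default 0.1).
#' @param block_loss_rate per-block per-branch probability of deleting the
#'   whole block (default 0.05).
#' @param tandem_dup_rate per-block per-branch probability of duplicating a
#'   member gene in place, creating a syntenic paralog (default 0.05).
#' @param background_shuffle_rate per-branch probability that each background
#'   gene is translocated to a random position (default 0.8). Without
#'   scrambling, gene order would be identical across species and every
#'   chromosome would be one genuine ancestral syntenic block; the high
#'   default makes background synteny decay within about one branch, so the
#'   planted blocks are the only local gene order maintained over time --
#'   the regime the method is designed to detect.
#' @param seed integer RNG seed; a fixed seed gives byte-identical output.
#' @return a list of class `sim_config`.
#' @export
simulation_config <- function(tree, n_genes = 2000L, n_chroms = 24L,
                              n_blocks = 10L, block_size_range = c(4L, 8L),
                              block_nodes = NULL,
                              expansion_rate = 0.3, translocation_rate = 0.1,
                              gene_loss_rate = 0.1, block_loss_rate = 0.05,
                              tandem_dup_rate = 0.05,
                              background_shuffle_rate = 0.8, seed = 1L) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  validate_species_tree(tree)
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label))) {
    stop("simulator tree must have labels on all internal nodes")
  }
  rates <- c(expansion_rate, translocation_rate, gene_loss_rate,
             block_loss_rate, tandem_dup_rate, background_shuffle_rate)
  if (any(rates < 0 | rates > 1)) stop("event rates must lie in [0, 1]")
  if (max(block_size_range) > n_genes) stop("block size exceeds n_genes")
  if (is.null(block_nodes)) block_nodes <- tree$node.label[1L]
  unknown <- setdiff(block_nodes, tree$node.label)
  if (length(unknown)) stop("block_nodes not in tree: ", paste(unknown, collapse = ", "))
  structure(list(tree = tree, n_genes = as.integer(n_genes),
                 n_chroms = as.integer(n_chroms), n_blocks = as.integer(n_blocks),
                 block_size_range = as.integer(block_size_range),
                 block_nodes = block_nodes,
                 expansion_rate = expansion_rate,
                 translocation_rate = translocation_rate,
                 gene_loss_rate = gene_loss_rate,
                 block_loss_rate = block_loss_rate,
                 tandem_dup_rate = tandem_dup_rate,
                 background_shuffle_rate = background_shuffle_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# genome = named list chrom -> character vector of OG ids (NA = OG-less gene)

.insert_at <- function(vec, pos, vals) {
  append(vec, vals, after = pos - 1L)
}

# positions of a block's member genes: data.frame(chrom, idx)
.block_positions <- function(genome, block_ogs) {
  hits <- lapply(names(genome), function(ch) {
    idx <- which(genome[[ch]] %in% block_ogs)
    if (length(idx)) data.frame(chrom = ch, idx = idx) else NULL
  })
  do.call(rbind, hits)
}

# insertion points on a chromosome that do not fall strictly inside a planted
# block span: planted blocks are modelled as selection-maintained units, so
# random background insertions into them are reserved for the explicit
# expansion event
.allowed_insertion_points <- function(v, block_of) {
  pts <- seq_len(length(v) + 1L)
  if (length(v) == 0L) return(pts)
  bl <- block_of[v]
  occ <- stats::na.omit(unique(bl))
  if (length(occ) == 0L) return(pts)
  bad <- logical(length(v) + 1L)
  for (bk in occ) {
    idx <- which(!is.na(bl) & bl == bk)
    if (length(idx) >= 2L) {
      lo <- min(idx); hi <- max(idx)
      if (hi > lo) bad[(lo + 1L):hi] <- TRUE  # insertion before pos i lands inside
    }
  }
  pts[!bad]
}

# per-branch translocation of individual background (non-block) genes;
# OG-less filler genes count as background too
.shuffle_background <- function(genome, block_of, rate) {
  if (rate <= 0) return(genome)
  moved <- character()
  for (ch in sort(names(genome))) {
    v <- genome[[ch]]
    bg <- which(is.na(v) | is.na(block_of[v]))
    if (length(bg) == 0L) next
    mv <- bg[stats::runif(length(bg)) < rate]
    if (length(mv)) {
      moved <- c(moved, v[mv])
      genome[[ch]] <- v[-mv]
    }
  }
  for (og in moved) {
    dest <- sample(names(genome), 1L)
    pts <- .allowed_insertion_points(genome[[dest]], block_of)
    at <- pts[sample.int(length(pts), 1L)]
    genome[[dest]] <- .insert_at(genome[[dest]], at, og)
  }
  genome
}

.apply_branch_events <- function(genome, block_ogs_list, cfg) {
  for (bk in names(block_ogs_list)) {
    ogs <- block_ogs_list[[bk]]
    pos <- .block_positions(genome, ogs)
    if (is.null(pos) || nrow(pos) == 0L) next
    # block loss
    if (stats::runif(1L) < cfg$block_loss_rate) {
      for (ch in unique(pos$chrom)) {
        genome[[ch]] <- genome[[ch]][-pos$idx[pos$chrom == ch]]
      }
      next
    }
    # single-gene loss
    if (stats::runif(1L) < cfg$gene_loss_rate && nrow(pos) > 1L) {
      vic <- pos[sample.int(nrow(pos), 1L), ]
      genome[[vic$chrom]] <- genome[[vic$chrom]][-vic$idx]
      pos <- .block_positions(genome, ogs)
    }
    # expansion: OG-less genes inserted inside the block span
    if (stats::runif(1L) < cfg$expansion_rate) {
      tab <- table(pos$chrom)
      multi <- names(tab)[tab >= 2L]
      if (length(multi)) {
        ch <- if (length(multi) == 1L) multi else sample(multi, 1L)
        idx <- pos$idx[pos$chrom == ch]
        q <- sample.int(3L, 1L)
        for (j in seq_len(q)) {
          span <- range(pos$idx[pos$chrom == ch])
          at <- sample(seq(span[1L] + 1L, span[2L] + 1L), 1L)
          genome[[ch]] <- .insert_at(genome[[ch]], at, NA_character_)
          pos <- .block_positions(genome, ogs)
        }
      }
    }
    # translocation of one member gene
    if (stats::runif(1L) < cfg$translocation_rate) {
      pos <- .block_positions(genome, ogs)
      vic <- pos[sample.int(nrow(pos), 1L), ]
      og <- genome[[vic$chrom]][vic$idx]
      genome[[vic$chrom]] <- genome[[vic$chrom]][-vic$idx]
      dest <- sample(names(genome), 1L)
      at <- sample.int(length(genome[[dest]]) + 1L, 1L)
      genome[[dest]] <- .insert_at(genome[[dest]], at, og)
    }
    # tandem duplication (syntenic paralog)
    if (stats::runif(1L) < cfg$tandem_dup_rate) {
      pos <- .block_positions(genome, ogs)
      if (nrow(pos)) {
        vic <- pos[sample.int(nrow(pos), 1L), ]
        og <- genome[[vic$chrom]][vic$idx]
        genome[[vic$chrom]] <- .insert_at(genome[[vic$chrom]], vic$idx + 1L, og)
      }
    }
  }
  block_of <- unlist(lapply(names(block_ogs_list), function(bk) {
    stats::setNames(rep(bk, length(block_ogs_list[[bk]])), block_ogs_list[[bk]])
  }))
  if (is.null(block_of)) block_of <- character()
  .shuffle_background(genome, block_of, cfg$background_shuffle_rate)
}

#' Simulate a multi-species dataset with known ground truth
#'
#' Builds a root genome of background genes, plants blocks at their origin
#' nodes during a deterministic top-down traversal, applies per-branch
#' events, and emits the leaf genomes in the package's tabular dialects.
#'
#' @param cfg a [simulation_config()].
#' @param out_dir optional directory; when given, writes `coords_<sp>.tsv`
#'   per species, `orthology.tsv`, `tree.nwk`, `truth_blocks.tsv` and
#'   `truth_species.tsv`.
#' @return a list with `genes` (ranked gene table with `og_id`), `orthology`,
#'   `tree`, `truth` (list of `blocks` and `species` data.tables) and `cfg`.
#' @export
simulate_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  tree <- cfg$tree
  ntip <- length(tree$tip.label)

  # root genome: background genes, each its own OG
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  bg <- sprintf("bOG%04d", seq_len(cfg$n_genes))
  chrom_names <- sprintf("chr%d", seq_len(cfg$n_chroms))
  genome0 <- stats::setNames(
    split(bg, rep(seq_len(cfg$n_chroms), each = per_chrom)[seq_len(cfg$n_genes)]),
    chrom_names)

  # planted blocks
  sizes <- sample(seq(cfg$block_size_range[1L], cfg$block_size_range[2L]),
                  cfg$n_blocks, replace = TRUE)
  origin <- rep_len(cfg$block_nodes, cfg$n_blocks)
  block_ogs <- lapply(seq_len(cfg$n_blocks), function(i) {
    sprintf("pOG%02d_%02d", i, seq_len(sizes[i]))
  })
  names(block_ogs) <- sprintf("block%02d", seq_len(cfg$n_blocks))

  plant <- function(genome, bk) {
    ch <- sample(names(genome), 1L)
    at <- sample.int(length(genome[[ch]]) + 1L, 1L)
    genome[[ch]] <- .insert_at(genome[[ch]], at, block_ogs[[bk]])
    genome
  }

  node_label_of <- function(node) tree$node.label[node - ntip]
  leaf_genomes <- list()
  recurse <- function(node, genome, present) {
    if (node > ntip) {
      lab <- node_label_of(node)
      for (bk in names(block_ogs)[origin == lab]) {
        genome <- plant(genome, bk)
        present <- c(present, bk)
      }
      kids <- tree$edge[tree$edge[, 1L] == node, 2L]
      for (ch in kids) {
        g2 <- .apply_branch_events(genome, block_ogs[present], cfg)
        recurse(ch, g2, present)
      }
    } else {
      leaf_genomes[[tree$tip.label[node]]] <<- genome
    }
  }
  recurse(ntip + 1L, genome0, character())

  # emit leaf genomes as gene tables + orthology
  gene_rows <- list()
  orth_rows <- list()
  for (sp in sort(names(leaf_genomes))) {
    genome <- leaf_genomes[[sp]]
    ctr <- 0L
    for (ch in sort(names(genome))) {
      ogs <- genome[[ch]]
      n <- length(ogs)
      if (n == 0L) next
      ids <- sprintf("%s_g%05d", sp, ctr + seq_len(n))
      ctr <- ctr + n
      starts <- (seq_len(n) - 1L) * 1000L
      gene_rows[[length(gene_rows) + 1L]] <- data.table::data.table(
        species = sp, chrom = ch, start = starts, end = starts + 500L,
        strand = "+", gene_id = ids)
      has_og <- !is.na(ogs)
      if (any(has_og)) {
        orth_rows[[length(orth_rows) + 1L]] <- data.table::data.table(
          og_id = ogs[has_og], species = sp, gene_id = ids[has_og])
      }
    }
  }
  genes <- rank_genes(data.table::rbindlist(gene_rows))
  orthology <- data.table::rbindlist(orth_rows)
  data.table::setkey(orthology, og_id, species, gene_id)
  genes <- assign_orthology(genes, orthology)

  truth <- .build_truth(genes, block_ogs, origin)

  out <- list(genes = genes, orthology = orthology, tree = tree,
              truth = truth, cfg = cfg)
  if (!is.null(out_dir)) write_dataset(out, out_dir)
  out
}

.build_truth <- function(genes, block_ogs, origin) {
  blocks <- data.table::data.table(
    block = names(block_ogs), origin_node = origin,
    og_list = vapply(block_ogs, paste, "", collapse = ","),
    n_ogs = lengths(block_ogs))
  sp_rows <- list()
  for (bk in names(block_ogs)) {
    mem <- genes[og_id %in% block_ogs[[bk]]]
    for (sp in sort(unique(genes$species))) {
      m <- mem[species == sp]
      if (nrow(m) == 0L) {
        cls <- "absent"; chroms <- ""; ogs <- ""
      } else {
        chroms <- paste(sort(unique(m$chrom)), collapse = ",")
        ogs <- paste(sort(unique(m$og_id)), collapse = ",")
        if (data.table::uniqueN(m$chrom) > 1L) {
          cls <- "noSy"
        } else {
          gaps <- diff(sort(m$rank)) - 1L
          cls <- if (length(gaps) == 0L || max(gaps) <= 10L) "uSy" else "MSy"
        }
      }
      sp_rows[[length(sp_rows) + 1L]] <- data.table::data.table(
        block = bk, species = sp, surviving_ogs = ogs, chroms = chroms,
        expected_class = cls)
    }
  }
  list(blocks = blocks, species = data.table::rbindlist(sp_rows))
}

#' Write a simulated dataset to a directory
#'
#' @param sim output of [simulate_dataset()].
#' @param out_dir destination directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in sort(unique(sim$genes$species))) {
    write_gene_coordinates(sim$genes[species == sp],
                           file.path(out_dir, paste0("coords_", sp, ".tsv")))
  }
  write_orthology(sim$orthology, file.path(out_dir, "orthology.tsv"))
  write_species_tree(sim$tree, file.path(out_dir, "tree.nwk"))
  data.table::fwrite(sim$truth$blocks, file.path(out_dir, "truth_blocks.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(sim$truth$species, file.path(out_dir, "truth_species.tsv"),
                     sep = "\t", quote = FALSE)
  invisible(out_dir)
}

#' Fully shuffle gene orders within each species
#'
#' Null-model transform: every gene keeps its identity and OG label but is
#' assigned a uniformly random (chromosome, position) slot within its
#' species. Coordinates and ranks are rebuilt from the new order.
#'
#' @param genes ranked gene table.
#' @param seed RNG seed.
#' @return a re-ranked gene table with shuffled order.
#' @export
shuffle_gene_orders <- function(genes, seed = 1L) {
  set.seed(seed)
  genes <- data.table::copy(data.table::as.data.table(genes))
  out <- genes[, {
    perm <- sample.int(.N)
    s <- .SD[perm]
    s[, start := (seq_len(.N) - 1L) * 1000L, by = chrom]
    s[, end := start + 500L]
    s
  }, by = species, .SDcols = setdiff(names(genes), "species")]
  rank_genes(out[, .(species, chrom, start, end, strand, gene_id, og_id)])
}

#' Score pipeline output against simulation truth
#'
#' A planted block is recovered when a validated multi-species block at its
#' origin node shares at least `min_overlap` of the planted OGs. Recall is
#' the fraction of planted blocks recovered at their true origin node;
#' precision is the fraction of validated blocks (over all scored nodes)
#' matching some planted block; the core-OG fraction of a matched block is
#' the share of its OG union that was truly planted.
#'
#' @param results named list: node label -> summary `data.table` as returned
#'   in `recover_node_blocks()$summary` (or a list of multi-species blocks).
#' @param truth the `truth` element of [simulate_dataset()].
#' @param min_overlap minimum fraction of planted OGs present (default 0.5).
#' @return list with `recall`, `precision` (`NA` when no validated blocks),
#'   `core_og_fraction` (mean over matched blocks), `matches` (per planted
#'   block x node table) and `per_node` confusion counts.
#' @export
score_against_truth <- function(results, truth, min_overlap = 0.5) {
  needed <- unique(truth$blocks$origin_node)
  missing <- setdiff(needed, names(results))
  if (length(missing)) {
    stop("results missing for origin node(s): ", paste(missing, collapse = ", "))
  }
  summaries <- lapply(results, function(r) {
    if (data.table::is.data.table(r)) r else .msb_summary(r)
  })
  planted <- strsplit(truth$blocks$og_list, ",", fixed = TRUE)
  names(planted) <- truth$blocks$block
  match_rows <- list()
  n_validated <- 0L
  n_matched_blocks <- 0L
  core_fracs <- numeric()
  for (nd in names(summaries)) {
    sm <- summaries[[nd]][validated == TRUE]
    n_validated <- n_validated + nrow(sm)
    unions <- strsplit(sm$og_union, ",", fixed = TRUE)
    blk_matched <- rep(FALSE, nrow(sm))
    for (bi in seq_along(planted)) {
      ovl <- vapply(unions, function(u) {
        length(intersect(u, planted[[bi]])) / length(planted[[bi]])
      }, numeric(1L))
      hit <- length(ovl) > 0L && any(ovl >= min_overlap)
      match_rows[[length(match_rows) + 1L]] <- data.table::data.table(
        block = names(planted)[bi], node = nd, matched = hit)
      blk_matched <- blk_matched | (if (length(ovl)) ovl >= min_overlap else FALSE)
      if (hit) {
        j <- which(ovl >= min_overlap)
        core_fracs <- c(core_fracs, max(vapply(j, function(jj) {
          length(intersect(unions[[jj]], planted[[bi]])) / length(unions[[jj]])
        }, numeric(1L))))
      }
    }
    n_matched_blocks <- n_matched_blocks + sum(blk_matched)
  }
  matches <- data.table::rbindlist(match_rows)
  at_origin <- merge(matches, truth$blocks[, .(block, origin_node)], by = "block")
  recall_tab <- at_origin[node == origin_node]
  recall <- mean(recall_tab$matched)
  precision <- if (n_validated == 0L) NA_real_ else n_matched_blocks / n_validated
  per_node <- matches[, .(n_matched = sum(matched), n_planted_checked = .N), by = node]
  list(recall = recall, precision = precision,
       core_og_fraction = if (length(core_fracs)) mean(core_fracs) else NA_real_,
       matches = matches, per_node = per_node)
}
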