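test_that("extant recovery collects all copies with no proximity requirement", {
  g <- .block_genes(list(chr1 = c(0L, 1L, 2L, 50L)),
                    ogs = list(chr1 = c("A", "B", "C", "D")))
  b <- recover_extant(c("A", "B", "C", "D"), g, "sp1")
  expect_s3_class(b, "extant_block")
  expect_equal(nrow(b$members), 4L)  # the far-away copy is still collected

  # 3 OGs split over 2 chromosomes
  g2 <- .block_genes(list(chr1 = c(0L, 1L), chr2 = 0L),
                     ogs = list(chr1 = c("A", "B"), chr2 = "C"))
  b2 <- recover_extant(c("A", "B", "C", "D"), g2, "sp1")
  expect_equal(sort(unique(b2$members$chrom)), c("chr1", "chr2"))
  expect_equal(nrow(b2$members), 3L)

  # below the completeness threshold -> absent
  g3 <- .block_genes(list(chr1 = c(0L, 1L)), ogs = list(chr1 = c("A", "B")))
  expect_null(recover_extant(c("A", "B", "C", "D"), g3, "sp1"))
  # min_ogs_extant adapts to small cliques: a full 2-OG set is recoverable
  expect_s3_class(recover_extant(c("A", "B"), g3, "sp1"), "extant_block")
})

test_that("synteny classification follows the 10-gene display threshold", {
  # gaps {0, 2, 9}: one micro-syntenic run
  g <- .block_genes(list(chr1 = c(0L, 1L, 4L, 14L)),
                    ogs = list(chr1 = c("A", "B", "C", "D")))
  b <- classify_synteny(recover_extant(c("A", "B", "C", "D"), g, "sp1"))
  expect_true(all(b$members$synteny_class == "uSy"))
  expect_equal(b$members$gap_to_prev, c(NA, 0L, 2L, 9L))
  expect_equal(nrow(b$msy_links), 0L)

  # gaps {0, 57}: micro pair plus one macro link labeled 57
  g2 <- .block_genes(list(chr1 = c(0L, 1L, 59L)),
                     ogs = list(chr1 = c("A", "B", "C")))
  b2 <- classify_synteny(recover_extant(c("A", "B", "C"), g2, "sp1"))
  expect_equal(b2$members$synteny_class, c("uSy", "uSy", "MSy"))
  expect_equal(b2$msy_links$gap, 57L)

  # members on chr1 (3 genes) and chr2 (1 gene): the chr2 member is noSy
  g3 <- .block_genes(list(chr1 = c(0L, 1L, 2L), chr2 = 5L),
                     ogs = list(chr1 = c("A", "B", "C"), chr2 = "D"))
  b3 <- classify_synteny(recover_extant(c("A", "B", "C", "D"), g3, "sp1"))
  expect_equal(b3$main_chrom, "chr1")
  expect_equal(b3$members[chrom == "chr2"]$synteny_class, "noSy")
  expect_true(all(b3$members[chrom == "chr1"]$synteny_class == "uSy"))

  # boundary: a gap of exactly 10 is still micro-syntenic, 11 is not
  g4 <- .block_genes(list(chr1 = c(0L, 11L)), ogs = list(chr1 = c("A", "B")))
  b4 <- classify_synteny(recover_extant(c("A", "B"), g4, "sp1"))
  expect_true(all(b4$members$synteny_class == "uSy"))
  g5 <- .block_genes(list(chr1 = c(0L, 12L)), ogs = list(chr1 = c("A", "B")))
  b5 <- classify_synteny(recover_extant(c("A", "B"), g5, "sp1"))
  expect_equal(b5$members$synteny_class, c("MSy", "MSy"))
  expect_equal(b5$msy_links$gap, 11L)
})

.fake_block <- function(species, ogs, set_id = "set1") {
  members <- data.table::data.table(
    species = species, chrom = "chr1",
    start = seq_along(ogs) * 100L, end = seq_along(ogs) * 100L + 50L,
    strand = "+", gene_id = sprintf("%s_%s", species, ogs), og_id = ogs,
    rank = seq_along(ogs) - 1L, gap_to_prev = NA_integer_,
    run_id = 1L, synteny_class = "uSy")
  structure(list(set_id = set_id, species = species, og_set = sort(ogs),
                 members = members),
            class = "extant_block")
}

test_that("multi-species grouping by shared OGs", {
  b1 <- .fake_block("sp1", c("A", "B", "C"))
  b2 <- .fake_block("sp2", c("B", "C", "D"))
  b3 <- .fake_block("sp3", c("X", "Y", "Z"))
  msbs <- group_multispecies(list(b1, b2, b3), node = "N")
  expect_length(msbs, 2L)
  unions <- lapply(msbs, `[[`, "og_union")
  expect_equal(canon_sets(unions), list(c("A", "B", "C", "D"), c("X", "Y", "Z")))

  # grouping equals a pairwise-overlap component oracle on random fixtures
  set.seed(103)
  for (i in 1:10) {
    blocks <- lapply(1:12, function(j) {
      .fake_block(sprintf("sp%d", sample.int(4L, 1L)),
                  sample(sprintf("OG%02d", 1:15), sample(2:5, 1L)),
                  set_id = sprintf("set%02d", j))
    })
    msbs <- group_multispecies(blocks, node = "N")
    # oracle: components of the block-overlap graph
    ov <- data.table::CJ(i = 1:12, j = 1:12)[i < j]
    ov <- ov[mapply(function(a, b) length(intersect(blocks[[a]]$og_set,
                                                    blocks[[b]]$og_set)) > 0,
                    i, j)]
    want <- oracle_components(data.table::data.table(from = as.character(ov$i),
                                                     to = as.character(ov$j)),
                              min_size = 1L)
    singletons <- setdiff(as.character(1:12), unlist(want))
    want <- c(want, as.list(singletons))
    got_parts <- lapply(msbs, function(m)
      sort(unlist(lapply(m$blocks, function(b) which(vapply(blocks, identical, TRUE, b))))))
    want_parts <- lapply(want, function(x) sort(as.integer(x)))
    expect_equal(canon_sets(lapply(got_parts, as.character)),
                 canon_sets(lapply(want_parts, as.character)))
  }
})

test_that("inheritance validation follows the taxonomic rule", {
  ctx <- node_context(tree8(), "nodeAB")
  msb <- function(species) {
    structure(list(block_id = "m", node = "nodeAB", og_union = c("A", "B", "C"),
                   species = species, blocks = list()),
              class = "multi_species_block")
  }
  expect_true(validate_inheritance(msb(c("sp1", "sp3")), ctx)$validated)   # 2 ingroup clades
  expect_false(validate_inheritance(msb(c("sp1", "sp2")), ctx)$validated)  # 1 clade only
  expect_true(validate_inheritance(msb(c("sp1", "sp5")), ctx)$validated)   # ingroup + sister
  expect_true(validate_inheritance(msb(c("sp3", "sp8")), ctx)$validated)   # ingroup + outgroup
  expect_false(validate_inheritance(msb(c("sp5", "sp7")), ctx)$validated)  # outside only
})

test_that("batch node-level recovery equals the per-block operations", {
  set.seed(107)
  genes <- rbind(
    .block_genes(list(chr1 = c(0L, 1L, 2L, 20L), chr2 = 3L),
                 species = "sp1",
                 ogs = list(chr1 = c("A", "B", "C", "D"), chr2 = "E")),
    .block_genes(list(chr1 = c(0L, 2L, 40L)),
                 species = "sp3",
                 ogs = list(chr1 = c("A", "B", "C"))),
    .block_genes(list(chr1 = c(0L, 1L)),
                 species = "sp5", ogs = list(chr1 = c("D", "E"))))
  genes <- rank_genes(genes)
  og_sets <- data.table::data.table(set_id = c("set1", "set2"),
                                    component_id = 1:2,
                                    ogs = c("A,B,C", "C,D,E"))
  ctx <- node_context(tree8(), "nodeAB")
  res <- recover_node_blocks(og_sets, genes, ctx)

  for (i in 1:2) {
    for (sp in c("sp1", "sp3", "sp5")) {
      ref <- recover_extant(strsplit(og_sets$ogs[i], ",")[[1L]], genes, sp,
                            set_id = og_sets$set_id[i])
      rows <- res$gene_table[species == sp &
                               gene_id %in% (if (is.null(ref)) character() else ref$members$gene_id)]
      if (is.null(ref)) next
      ref <- classify_synteny(ref)
      got <- unlist(lapply(c(res$validated, res$rejected), function(m) {
        for (b in m$blocks) {
          if (b$set_id == og_sets$set_id[i] && b$species == sp) return(list(b))
        }
        NULL
      }), recursive = FALSE)
      expect_length(got, 1L)
      expect_equal(got[[1L]]$members$synteny_class, ref$members$synteny_class)
      expect_equal(got[[1L]]$members$gap_to_prev, ref$members$gap_to_prev)
      expect_equal(got[[1L]]$members$gene_id, ref$members$gene_id)
    }
  }
  # every output gene carries an OG from the set that seeded it
  expect_true(all(res$gene_table$og_id %in% unlist(strsplit(og_sets$ogs, ","))))
})

test_that("rejected blocks are reported, not dropped", {
  genes <- rbind(
    .block_genes(list(chr1 = c(0L, 1L, 2L)), species = "sp1",
                 ogs = list(chr1 = c("A", "B", "C"))),
    .block_genes(list(chr1 = c(0L, 1L, 2L)), species = "sp2",
                 ogs = list(chr1 = c("A", "B", "C"))))
  genes <- rank_genes(genes)
  og_sets <- data.table::data.table(set_id = "set1", component_id = 1L,
                                    ogs = "A,B,C")
  ctx <- node_context(tree8(), "nodeAB")
  res <- recover_node_blocks(og_sets, genes, ctx)
  # both carriers are in cladeA: clade-internal, must be rejected but audited
  expect_length(res$validated, 0L)
  expect_length(res$rejected, 1L)
  expect_equal(nrow(res$summary), 1L)
  expect_false(res$summary$validated)
})
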