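test_that("node context partitions the tree correctly", {
  ctx <- node_context(tree5_polytomy(), "cladeA")
  expect_equal(ctx$ingroup_clades, list(sp1 = "sp1", sp2 = "sp2"))
  expect_setequal(ctx$outgroup, c("sp3", "sp4", "sp5"))
  # sister group of cladeA under the root polytomy: cladeB and sp5
  expect_setequal(ctx$sister_group, c("sp3", "sp4", "sp5"))

  expect_error(node_context(tree5_polytomy(), "sp1"), "leaf")
  expect_error(node_context(tree5_polytomy(), "nope"), "unknown")
  expect_warning(node_context(tree5_polytomy(), "root"), "root")
})

test_that("node context is consistent on every internal node of a large tree", {
  set.seed(31)
  tr <- ape::rtree(40, tip.label = sprintf("t%02d", 1:40))
  tr$node.label <- sprintf("n%02d", seq_len(tr$Nnode))
  for (lab in tr$node.label[-1L]) {  # skip root (warning case, checked above)
    ctx <- node_context(tr, lab)
    ing <- unname(unlist(ctx$ingroup_clades))
    # ingroup clades partition the leaves under the node
    expect_equal(sort(ing), ctx$ingroup)
    expect_equal(anyDuplicated(ing), 0L)
    # outgroup is the complement; sister group is inside the outgroup
    expect_setequal(c(ctx$ingroup, ctx$outgroup), tr$tip.label)
    expect_length(intersect(ctx$ingroup, ctx$outgroup), 0L)
    expect_true(all(ctx$sister_group %in% ctx$outgroup))
    # oracle: leaves under the node via ape extraction
    node_id <- length(tr$tip.label) + which(tr$node.label == lab)
    expect_setequal(ctx$ingroup, ape::extract.clade(tr, node_id)$tip.label)
  }
})

test_that("kde mode: stated examples and oracle equivalence", {
  expect_equal(kde_mode(3), 3)
  expect_equal(kde_mode(c(2, 2, 2, 40)), 2)
  expect_equal(kde_mode(c(5, 5, 9, 9)), 5)  # perfect tie -> smaller mode

  set.seed(41)
  for (i in 1:50) {
    x <- sample.int(60L, sample(1:8, 1L), replace = TRUE)
    m <- kde_mode(x)
    expect_equal(m, oracle_kde_argmax(x))
    expect_gte(m, min(x))
    expect_lte(m, max(x))
  }
  expect_error(kde_mode(numeric()), "at least one")
  expect_error(clade_distance(numeric()), "empty")
})

test_that("clade-level and node-level distance formulas", {
  expect_equal(ancestral_distance(c(3, 5)), 4.0)
  expect_equal(ancestral_distance(7), 7.0)
  expect_equal(ancestral_distance(c(0, 0, 1)), 1 / 3)
  expect_error(ancestral_distance(numeric()), "no supporting")
})

.records <- function(...) {
  # build records for one pair AB from species -> d pairs
  obs <- list(...)
  data.table::data.table(og_a = "A", og_b = "B",
                         species = names(obs), chrom = "chr1",
                         d = as.integer(unlist(obs)))
}

test_that("acceptance rule: ingroup routes and outgroup rescue", {
  ctx <- suppressWarnings(node_context(tree5_polytomy(), "root"))
  # root of the polytomy tree: three ingroup clades cladeA, cladeB, sp5
  r <- is_syntenic_at_node(c("A", "B"), .records(sp1 = 1, sp3 = 5), ctx)
  expect_true(r$accepted)  # two ingroup clades -> route (a)
  expect_setequal(r$supporting_clades, c("cladeA", "cladeB"))
  expect_equal(r$d_N, 3.0)

  # two species of the SAME ingroup clade only: clade-internal innovation
  r2 <- is_syntenic_at_node(c("A", "B"), .records(sp1 = 1, sp2 = 1), ctx)
  expect_false(r2$accepted)

  ctxA <- node_context(tree8(), "nodeAB")
  # one ingroup clade + one outgroup species -> route (b), pseudo-clades join
  r3 <- is_syntenic_at_node(c("A", "B"), .records(sp1 = 2, sp7 = 6), ctxA)
  expect_true(r3$accepted)
  expect_setequal(r3$supporting_clades, c(".outgroup", "cladeA"))
  expect_equal(r3$d_N, 4.0)

  # sister species rescue
  r4 <- is_syntenic_at_node(c("A", "B"), .records(sp3 = 2, sp5 = 2), ctxA)
  expect_true(r4$accepted)
  expect_setequal(r4$supporting_clades, c(".sister", "cladeB"))

  # outgroup alone never suffices
  r5 <- is_syntenic_at_node(c("A", "B"), .records(sp5 = 1, sp7 = 1), ctxA)
  expect_false(r5$accepted)
})

test_that("pseudo-clades do not dilute d_N when route (a) already holds", {
  ctxA <- node_context(tree8(), "nodeAB")
  r <- is_syntenic_at_node(c("A", "B"),
                           .records(sp1 = 2, sp3 = 4, sp7 = 100), ctxA)
  expect_true(r$accepted)
  expect_setequal(r$supporting_clades, c("cladeA", "cladeB"))
  expect_equal(r$d_N, 3.0)
})

test_that("decision rule is monotone in added support", {
  ctxA <- node_context(tree8(), "nodeAB")
  set.seed(53)
  for (i in 1:20) {
    sp <- sample(sprintf("sp%d", 1:8), sample(2:6, 1L))
    d <- sample.int(20L, length(sp), replace = TRUE)
    rec <- data.table::data.table(og_a = "A", og_b = "B", species = sp,
                                  chrom = "chr1", d = d)
    base <- is_syntenic_at_node(c("A", "B"), rec, ctxA)
    extra_sp <- sample(setdiff(sprintf("sp%d", 1:8), sp), 1L)
    rec2 <- rbind(rec, data.table::data.table(og_a = "A", og_b = "B",
                                              species = extra_sp,
                                              chrom = "chr1", d = 3L))
    grown <- is_syntenic_at_node(c("A", "B"), rec2, ctxA)
    if (base$accepted) expect_true(grown$accepted)
  }
})

test_that("batch inference equals the single-pair rule on random fixtures", {
  ctxA <- node_context(tree8(), "nodeAB")
  set.seed(67)
  rows <- list()
  for (p in 1:40) {
    sp <- sample(sprintf("sp%d", 1:8), sample(1:8, 1L))
    rows[[p]] <- data.table::data.table(
      og_a = sprintf("OG%02da", p), og_b = sprintf("OG%02db", p),
      species = sp, chrom = "chr1",
      d = sample.int(30L, length(sp), replace = TRUE))
  }
  recs <- data.table::rbindlist(rows)
  batch <- infer_node_synteny(recs, ctxA)
  for (p in 1:40) {
    single <- is_syntenic_at_node(c(rows[[p]]$og_a[1], rows[[p]]$og_b[1]),
                                  recs, ctxA)
    hit <- batch[og_a == rows[[p]]$og_a[1]]
    if (single$accepted) {
      expect_equal(nrow(hit), 1L)
      expect_equal(hit$d_N, single$d_N, tolerance = 1e-12)
      expect_equal(hit$k, single$k)
      expect_equal(hit$supporting_clades,
                   paste(single$supporting_clades, collapse = ","))
    } else {
      expect_equal(nrow(hit), 0L)
    }
  }
})

test_that("a pair planted below node M is accepted at M and at no ancestor", {
  # pair syntenic only in cladeA species (below nodeAB's child cladeA)
  tr <- tree8()
  recs <- .records(sp1 = 0, sp2 = 0)
  ctx_cladeA <- node_context(tr, "cladeA")
  ctx_nodeAB <- node_context(tr, "nodeAB")
  ctx_nodeABC <- node_context(tr, "nodeABC")
  expect_true(is_syntenic_at_node(c("A", "B"), recs, ctx_cladeA)$accepted)
  expect_false(is_syntenic_at_node(c("A", "B"), recs, ctx_nodeAB)$accepted)
  expect_false(is_syntenic_at_node(c("A", "B"), recs, ctx_nodeABC)$accepted)
})

test_that("d_N always lies within the range of its clade distances", {
  ctx <- node_context(tree8(), "nodeABC")
  set.seed(71)
  for (i in 1:30) {
    sp <- sample(sprintf("sp%d", 1:8), sample(2:8, 1L))
    rec <- data.table::data.table(og_a = "A", og_b = "B", species = sp,
                                  chrom = "chr1",
                                  d = sample.int(50L, length(sp), TRUE))
    r <- is_syntenic_at_node(c("A", "B"), rec, ctx)
    if (r$accepted) {
      expect_gte(r$d_N, min(r$d_g))
      expect_lte(r$d_N, max(r$d_g))
    }
  }
})

test_that("default nmax policy follows depth rank", {
  tr <- tree8()
  expect_equal(node_depth_rank(tr, "cladeA"), 0L)
  expect_equal(node_depth_rank(tr, "nodeAB"), 1L)
  expect_equal(node_depth_rank(tr, "root"), 3L)
  expect_equal(default_nmax(tr, "cladeA"), 2)
  expect_equal(default_nmax(tr, "nodeAB"), 2)             # flat default
  expect_equal(default_nmax(tr, "root", step = 5), 17)    # depth-scaled option
})
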