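#' @import data.table
#' @importFrom stats setNames density
#' @importFrom utils head tail
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", ".N", ".I", ".SD", ".GRP", "species", "chrom", "start", "end", "strand",
  "gene_id", "og_id", "rank", "og_a", "og_b", "d", "n_species", "d_N", "k",
  "supporting_clades", "i.og_id", "gap_to_prev", "run_id", "block_id",
  "synteny_class", "set_id", "node", "og_list", "origin_node", "msb_id",
  "rank_a", "rank_b", "ga", "gb", "og_x", "og_y", "idx", "clade", "is_ing",
  "n_ing", "has_out", "use_pseudo", "dmin", "dmax", "d_g", "i.mode", "N",
  "n_og", "ns", "nd", "validated", "og_union", "origin_node", "matched",
  "size", "n_matched", "line", "set_n", "n_og", "run_n", "eb_id", "i.eb_id",
  "comp", "i.comp", "i.block_id", "i.n_main"
))

.COORD_COLS <- c("species", "chrom", "start", "end", "strand", "gene_id")

#' Read gene coordinate tables
#'
#' Parses one or more BED-like tab-separated files with columns
#' `species, chrom, start, end, strand, gene_id`. Coordinates are 0-based
#' half-open; lines starting with `#` are skipped. Genes are ranked 0-based
#' along each chromosome in transcription-start order (ties broken by
#' `(end, gene_id)`); strand is stored but never affects rank.
#'
#' @param paths character vector of file paths.
#' @return a `data.table` with one row per gene and columns
#'   `species, chrom, start, end, strand, gene_id, og_id, rank`, keyed by
#'   `(species, chrom, rank)`. `og_id` is `NA` until [assign_orthology()].
#' @export
read_gene_coordinates <- function(paths) {
  stopifnot(is.character(paths))
  parts <- lapply(paths, .read_one_coord_file)
  genes <- data.table::rbindlist(parts)
  if (nrow(genes) == 0L) {
    genes <- data.table::data.table(
      species = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), gene_id = character()
    )
  }
  rank_genes(genes)
}

.read_one_coord_file <- function(path) {
  if (!file.exists(path)) stop("coordinate file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.table::data.table(
      species = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), gene_id = character()
    ))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L)) {
    bad <- which(nf != 6L)[1L]
    stop(sprintf("malformed row in %s line %d: expected 6 tab-separated columns, got %d",
                 path, lineno[bad], nf[bad]))
  }
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  dt <- data.table::data.table(
    species = m[, 1L], chrom = m[, 2L],
    start = suppressWarnings(as.integer(m[, 3L])),
    end = suppressWarnings(as.integer(m[, 4L])),
    strand = m[, 5L], gene_id = m[, 6L]
  )
  bad <- which(is.na(dt$start) | is.na(dt$end) | dt$start < 0L | dt$end < 0L)
  if (length(bad)) {
    stop(sprintf("malformed row in %s line %d: start/end must be non-negative integers",
                 path, lineno[bad[1L]]))
  }
  bad <- which(dt$start > dt$end)
  if (length(bad)) {
    stop(sprintf("malformed row in %s line %d: start > end", path, lineno[bad[1L]]))
  }
  bad <- which(!dt$strand %in% c("+", "-", "."))
  if (length(bad)) {
    stop(sprintf("malformed row in %s line %d: strand must be one of + - .",
                 path, lineno[bad[1L]]))
  }
  dt
}

#' Assign chromosome-order ranks to a gene table
#'
#' Sorts genes within each `(species, chrom)` by `(start, end, gene_id)` and
#' assigns a 0-based `rank`. All annotated genes consume a rank, including
#' overlapping genes and genes without an ortholog group: the distance unit
#' downstream is a count over annotation entries.
#'
#' @param genes a `data.table` with at least the six coordinate columns.
#' @return the ranked, keyed gene table (a copy).
#' @export
rank_genes <- function(genes) {
  genes <- data.table::as.data.table(genes)
  dup <- genes[, .N, by = .(species, gene_id)][N > 1L]
  if (nrow(dup)) {
    stop("duplicate gene_id within a species: ",
         paste(sprintf("%s|%s", dup$species, dup$gene_id), collapse = ", "))
  }
  if (!"og_id" %in% names(genes)) genes[, og_id := NA_character_]
  data.table::setorder(genes, species, chrom, start, end, gene_id)
  genes[, rank := seq_len(.N) - 1L, by = .(species, chrom)]
  data.table::setkey(genes, species, chrom, rank)
  genes[]
}

#' Write gene coordinates in the package's tabular dialect
#'
#' @param genes gene table as returned by [read_gene_coordinates()].
#' @param path output file.
#' @export
write_gene_coordinates <- function(genes, path) {
  out <- data.table::as.data.table(genes)[, .SD, .SDcols = .COORD_COLS]
  data.table::setorder(out, species, chrom, start, end, gene_id)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an orthology file
#'
#' One ortholog group (OG) per line: the OG id, then whitespace-separated
#' `species|gene_id` members. A gene may belong to at most one OG
#' (single-membership). OGs with members from fewer than two species are
#' retained but flagged: they can never pass the two-species synteny filter.
#'
#' @param path orthology file.
#' @param species optional character vector of known species keys; members
#'   with a prefix outside this set raise an error.
#' @return a `data.table` with columns `og_id, species, gene_id` and an
#'   attribute `single_species_ogs` (character vector of flagged OG ids).
#' @export
read_orthology <- function(path, species = NULL) {
  if (!file.exists(path)) stop("orthology file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(toks) < 2L) {
      stop(sprintf("malformed orthology line %d: need an OG id and >=1 member",
                   lineno[i]))
    }
    members <- toks[-1L]
    bad <- !grepl("\\|", members)
    if (any(bad)) {
      stop(sprintf("malformed member '%s' on line %d: expected species|gene_id",
                   members[bad][1L], lineno[i]))
    }
    sp <- sub("\\|.*$", "", members)
    gid <- sub("^[^|]*\\|", "", members)
    recs[[i]] <- data.table::data.table(og_id = toks[1L], species = sp, gene_id = gid)
  }
  orth <- data.table::rbindlist(recs)
  if (nrow(orth) == 0L) {
    orth <- data.table::data.table(og_id = character(), species = character(),
                                   gene_id = character())
  }
  dup <- orth[, .(n_og = data.table::uniqueN(og_id)), by = .(species, gene_id)][n_og > 1L]
  if (nrow(dup)) {
    stop("gene listed in more than one OG: ",
         paste(sprintf("%s|%s", dup$species, dup$gene_id), collapse = ", "))
  }
  if (!is.null(species)) {
    unk <- setdiff(unique(orth$species), species)
    if (length(unk)) stop("unknown species prefix in orthology: ",
                          paste(unk, collapse = ", "))
  }
  single <- orth[, .(ns = data.table::uniqueN(species)), by = og_id][ns < 2L, og_id]
  data.table::setattr(orth, "single_species_ogs", single)
  data.table::setkey(orth, og_id, species, gene_id)
  orth[]
}

#' Write an orthology map
#'
#' @param orth orthology table from [read_orthology()].
#' @param path output file.
#' @export
write_orthology <- function(orth, path) {
  orth <- data.table::as.data.table(orth)
  data.table::setorder(orth, og_id, species, gene_id)
  lines <- orth[, .(line = paste(og_id[1L],
                                 paste(sprintf("%s|%s", species, gene_id), collapse = " "),
                                 sep = "\t")), by = og_id]$line
  writeLines(lines, path)
  invisible(path)
}

#' Attach OG labels to a gene table
#'
#' Joins the orthology map onto the ranked gene table. Orthology members that
#' do not exist in the coordinate tables are reported as dangling (message +
#' `dangling` attribute), not silently dropped.
#'
#' @param genes ranked gene table.
#' @param orth orthology table.
#' @return the gene table with `og_id` filled where known.
#' @export
assign_orthology <- function(genes, orth) {
  genes <- data.table::copy(data.table::as.data.table(genes))
  orth <- data.table::as.data.table(orth)
  genes[, og_id := NA_character_]
  genes[orth, og_id := i.og_id, on = c("species", "gene_id")]
  dangling <- orth[!genes, on = c("species", "gene_id")]
  if (nrow(dangling)) {
    message(nrow(dangling), " dangling orthology member(s) not found in coordinates, e.g. ",
            paste(utils::head(sprintf("%s|%s", dangling$species, dangling$gene_id), 3L),
                  collapse = ", "))
  }
  data.table::setattr(genes, "dangling", dangling)
  genes[]
}

#' Read a species cladogram
#'
#' Reads a rooted newick tree whose leaves are species keys and whose internal
#' nodes carry clade-name labels. Polytomies are preserved, never resolved.
#'
#' @param path newick file.
#' @param species optional character vector; if given, the leaf set must match
#'   it exactly.
#' @return an `ape::phylo` object.
#' @export
read_species_tree <- function(path, species = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick tree: ", path)
  validate_species_tree(tree, species)
}

#' Validate a species tree against a species set
#'
#' @param tree an `ape::phylo`.
#' @param species optional leaf set to check against.
#' @return the tree, invisibly checked.
#' @export
validate_species_tree <- function(tree, species = NULL) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  labs <- tree$node.label
  labs <- labs[!is.na(labs) & nzchar(labs)]
  if (anyDuplicated(labs)) {
    stop("duplicate internal node labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  }
  if (any(labs %in% tree$tip.label)) {
    stop("internal label collides with a leaf name: ",
         paste(intersect(labs, tree$tip.label), collapse = ", "))
  }
  if (!is.null(species)) {
    extra <- setdiff(tree$tip.label, species)
    missing <- setdiff(species, tree$tip.label)
    if (length(extra) || length(missing)) {
      stop("tree/species mismatch.",
           if (length(extra)) paste0(" Leaves not in data: ", paste(extra, collapse = ", ")),
           if (length(missing)) paste0(" Species not in tree: ", paste(missing, collapse = ", ")))
    }
  }
  tree
}

#' Write a species tree to newick
#'
#' @param tree an `ape::phylo`.
#' @param path output file.
#' @export
write_species_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
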