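#' Minimum intervening-gene distance between two sets of gene copies
#'
#' Computes the smallest number of annotated genes lying strictly between any
#' gene of `genes_a` and any gene of `genes_b` on a shared chromosome of one
#' species: `d = |rank_a - rank_b| - 1`, so adjacent genes have `d = 0`.
#' For a paralog self-pair pass the same table twice; the two copies realizing
#' the distance are always distinct genes.
#'
#' @param genes_a,genes_b gene tables (rows of one species) with columns
#'   `chrom, rank, gene_id`.
#' @return `list(d =, chrom =)` or `NULL` when no two distinct copies share a
#'   chromosome.
#' @export
og_pair_distance <- function(genes_a, genes_b) {
  a <- data.table::as.data.table(genes_a)
  b <- data.table::as.data.table(genes_b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(NULL)
  ab <- merge(a[, .(chrom, rank_a = rank, ga = gene_id)],
              b[, .(chrom, rank_b = rank, gb = gene_id)],
              by = "chrom", allow.cartesian = TRUE)
  ab <- ab[ga != gb]
  if (nrow(ab) == 0L) return(NULL)
  ab[, d := abs(rank_a - rank_b) - 1L]
  data.table::setorder(ab, d, chrom)
  list(d = ab$d[1L], chrom = ab$chrom[1L])
}

# all unordered index pairs (i < j) of 1..m, vectorized
.index_pairs <- function(m) {
  if (m < 2L) return(list(i = integer(), j = integer()))
  len <- rev(seq_len(m - 1L))
  list(i = rep.int(seq_len(m - 1L), len),
       j = sequence(len, from = seq_len(m - 1L) + 1L))
}

#' Build the per-species OG pair distance matrix
#'
#' For every species and every unordered pair of ortholog groups (including
#' self-pairs, i.e. syntenic paralogs) that share a chromosome, records the
#' smallest number of intervening genes `d` and the chromosome where that
#' minimum is achieved. Intervening genes count every annotated gene between
#' the two copies, whether or not it belongs to an OG.
#'
#' Implemented as a per-chromosome sweep over ranked OG-member positions;
#' genes without an OG influence only the rank gaps.
#'
#' @param genes ranked gene table with `og_id` assigned (see
#'   [assign_orthology()]).
#' @param max_d optional distance cap: records with `d > max_d` are dropped at
#'   build time. Default `Inf` keeps everything (the method is scale-free).
#' @return a `data.table` of distance records
#'   `og_a, og_b, species, chrom, d`, canonicalized (`og_a <= og_b`) and
#'   sorted by `(og_a, og_b, species)`.
#' @export
build_distance_matrix <- function(genes, max_d = Inf) {
  genes <- data.table::as.data.table(genes)
  mem <- genes[!is.na(og_id), .(species, chrom, rank, og_id)]
  if (nrow(mem) == 0L) return(.empty_records())
  data.table::setorder(mem, species, chrom, rank)
  recs <- mem[, {
    p <- .index_pairs(.N)
    if (length(p$i) == 0L) {
      list(og_a = character(), og_b = character(), d = integer())
    } else {
      oi <- og_id[p$i]; oj <- og_id[p$j]
      list(og_a = pmin(oi, oj), og_b = pmax(oi, oj),
           d = rank[p$j] - rank[p$i] - 1L)
    }
  }, by = .(species, chrom)]
  if (nrow(recs) == 0L) return(.empty_records())
  # minimum per pair within a chromosome, then across chromosomes
  # (distance ties broken toward the lexically smallest chromosome name)
  recs <- recs[, .(d = min(d)), by = .(species, chrom, og_a, og_b)]
  data.table::setorder(recs, og_a, og_b, species, d, chrom)
  recs <- recs[, .SD[1L], by = .(og_a, og_b, species)]
  if (is.finite(max_d)) recs <- recs[d <= max_d]
  data.table::setcolorder(recs, c("og_a", "og_b", "species", "chrom", "d"))
  data.table::setkey(recs, og_a, og_b, species)
  recs[]
}

.empty_records <- function() {
  data.table::data.table(og_a = character(), og_b = character(),
                         species = character(), chrom = character(),
                         d = integer(), key = c("og_a", "og_b", "species"))
}

#' Retain OG pairs syntenic in a minimum number of species
#'
#' Only OG pairs with distance records from at least `min_species` distinct
#' species are kept; all records of dropped pairs are removed.
#'
#' @param records distance records from [build_distance_matrix()].
#' @param min_species minimum distinct species per pair (default 2).
#' @return the filtered record table.
#' @export
filter_min_species <- function(records, min_species = 2L) {
  if (!is.numeric(min_species) || length(min_species) != 1L || min_species < 1) {
    stop("min_species must be a single integer >= 1")
  }
  records <- data.table::as.data.table(records)
  if (nrow(records) == 0L) return(records)
  if (anyDuplicated(records, by = c("og_a", "og_b", "species"))) {
    records <- unique(records, by = c("og_a", "og_b", "species"))
  }
  # records are unique per (pair, species), so the group size IS the species
  # count (GForce-optimized, unlike uniqueN)
  records[, n_species := .N, by = .(og_a, og_b)]
  out <- records[n_species >= min_species][, n_species := NULL]
  records[, n_species := NULL]
  out[]
}

#' Write / read distance records
#'
#' Plain TSV with header `og_a og_b species chrom d`, deterministically sorted.
#'
#' @param records record table.
#' @param path file path.
#' @export
write_distance_records <- function(records, path) {
  out <- data.table::as.data.table(records)
  data.table::setorder(out, og_a, og_b, species)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_records
#' @export
read_distance_records <- function(path) {
  recs <- data.table::fread(path, sep = "\t",
                            colClasses = list(character = c("og_a", "og_b", "species", "chrom"),
                                              integer = "d"))
  data.table::setkey(recs, og_a, og_b, species)
  recs[]
}
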