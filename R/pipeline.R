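#' Pipeline run configuration
#'
#' Bundles inputs and thresholds for the staged pipeline: distance matrix ->
#' per-node pair filtering -> network communities -> block recovery.
#'
#' @param coordinate_paths character vector of coordinate files.
#' @param orthology_path orthology file.
#' @param tree_path newick species cladogram with internal labels.
#' @param nodes internal node labels to analyse.
#' @param out_dir output directory.
#' @param min_species minimum species per retained OG pair (default 2).
#' @param min_clades minimum supporting ingroup clades (default 2).
#' @param nmax `NULL` for the depth-scaled default policy (see
#'   [default_nmax()]), a single number applied to all nodes, or a named
#'   vector keyed by node label.
#' @param nmax_base,nmax_step constants of the default policy (see
#'   [default_nmax()]).
#' @param min_len minimum OGs per ancestral set (default 3).
#' @param min_ogs_extant minimum distinct OGs per extant block; `NULL` means
#'   `min(3, set size)`.
#' @param micro_gap micro-synteny display threshold (default 10 intervening
#'   genes).
#' @param max_d optional distance-matrix cap (default `Inf`).
#' @param quiet suppress progress messages.
#' @return a list of class `run_config`.
#' @export
run_config <- function(coordinate_paths, orthology_path, tree_path, nodes,
                       out_dir, min_species = 2L, min_clades = 2L,
                       nmax = NULL, nmax_base = 2, nmax_step = 0, min_len = 3L,
                       min_ogs_extant = NULL, micro_gap = 10L, max_d = Inf,
                       quiet = FALSE) {
  cfg <- list(coordinate_paths = coordinate_paths,
              orthology_path = orthology_path, tree_path = tree_path,
              nodes = nodes, out_dir = out_dir,
              min_species = as.integer(min_species),
              min_clades = as.integer(min_clades),
              nmax = nmax, nmax_base = nmax_base, nmax_step = nmax_step,
              min_len = as.integer(min_len),
              min_ogs_extant = min_ogs_extant,
              micro_gap = as.integer(micro_gap), max_d = max_d,
              quiet = isTRUE(quiet))
  class(cfg) <- "run_config"
  cfg
}

.log <- function(cfg, stage, ...) {
  if (!cfg$quiet) message(sprintf("[%s] %s", stage, paste0(...)))
}

.node_nmax <- function(cfg, tree, node) {
  if (is.null(cfg$nmax)) {
    default_nmax(tree, node, base = cfg$nmax_base, step = cfg$nmax_step)
  } else if (!is.null(names(cfg$nmax))) {
    if (!node %in% names(cfg$nmax)) stop("no nmax given for node ", node)
    unname(cfg$nmax[[node]])
  } else {
    cfg$nmax
  }
}

# -- resume bookkeeping -------------------------------------------------------
# A stage is skipped when all its outputs exist and the manifest holds the
# same stage key (md5 over the md5s of its inputs plus its parameters).

.manifest_path <- function(cfg) file.path(cfg$out_dir, "manifest.json")

.read_manifest <- function(cfg) {
  p <- .manifest_path(cfg)
  if (file.exists(p)) jsonlite::read_json(p, simplifyVector = TRUE) else list()
}

.write_manifest <- function(cfg, manifest) {
  jsonlite::write_json(manifest, .manifest_path(cfg), auto_unbox = TRUE,
                       pretty = TRUE)
}

.stage_key <- function(input_files, params) {
  hashes <- unname(tools::md5sum(input_files))
  blob <- paste(c(hashes, vapply(params, function(x) paste(format(x), collapse = ","),
                                 character(1L))), collapse = ";")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(blob, tmp)
  unname(tools::md5sum(tmp))
}

.stage_current <- function(cfg, manifest, stage, key, out_files) {
  all(file.exists(out_files)) &&
    !is.null(manifest$stages[[stage]]) &&
    identical(manifest$stages[[stage]], unname(key))
}

# -- stages -------------------------------------------------------------------

#' Run the full pipeline
#'
#' Executes the distance stage, then per node: pair filtering, network
#' decomposition and block recovery. Every stage writes a plain TSV; a JSON
#' manifest records input hashes and parameters so unchanged stages are
#' skipped on re-run (resume). All computation is deterministic for fixed
#' inputs and parameters.
#'
#' @param cfg a [run_config()].
#' @return a `data.table` report: one row per node with counts of accepted
#'   pairs, ancestral sets and validated / rejected multi-species blocks.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- .read_manifest(cfg)
  if (is.null(manifest$stages)) manifest$stages <- list()

  genes <- read_gene_coordinates(cfg$coordinate_paths)
  orth <- read_orthology(cfg$orthology_path, species = unique(genes$species))
  genes <- assign_orthology(genes, orth)
  tree <- read_species_tree(cfg$tree_path, species = unique(genes$species))
  unknown <- setdiff(cfg$nodes, tree$node.label)
  if (length(unknown)) stop("nodes not in tree: ", paste(unknown, collapse = ", "))

  # distance stage
  dist_file <- file.path(cfg$out_dir, "distances.tsv")
  dist_key <- .stage_key(c(cfg$coordinate_paths, cfg$orthology_path),
                         list(max_d = cfg$max_d))
  if (.stage_current(cfg, manifest, "dist", dist_key, dist_file)) {
    .log(cfg, "dist", "up to date, skipping")
    records <- read_distance_records(dist_file)
  } else {
    records <- build_distance_matrix(genes, max_d = cfg$max_d)
    write_distance_records(records, dist_file)
    manifest$stages[["dist"]] <- unname(dist_key)
    .log(cfg, "dist", nrow(records), " distance records")
  }

  retained <- filter_min_species(records, cfg$min_species)
  .log(cfg, "filt", "pairs in: ",
       nrow(unique(records[, .(og_a, og_b)])), ", retained (>=",
       cfg$min_species, " species): ", nrow(unique(retained[, .(og_a, og_b)])))

  report_rows <- list()
  for (node in cfg$nodes) {
    ctx <- node_context(tree, node)
    nmax <- .node_nmax(cfg, tree, node)
    node_key <- .stage_key(dist_file,
                           list(node = node, min_species = cfg$min_species,
                                min_clades = cfg$min_clades, nmax = nmax,
                                min_len = cfg$min_len,
                                min_ogs_extant = cfg$min_ogs_extant,
                                micro_gap = cfg$micro_gap))
    files <- file.path(cfg$out_dir, sprintf(
      c("pairs_%s.tsv", "sets_%s.tsv", "blocks_%s.tsv", "summary_%s.tsv",
        "rejected_%s.tsv"), node))
    stage <- paste0("node:", node)
    if (.stage_current(cfg, manifest, stage, node_key, files)) {
      .log(cfg, stage, "up to date, skipping")
      summary <- data.table::fread(files[4L], sep = "\t")
      n_pairs <- nrow(data.table::fread(files[1L], sep = "\t"))
      n_sets <- nrow(data.table::fread(files[2L], sep = "\t"))
    } else {
      pairs <- infer_node_synteny(retained, ctx, min_clades = cfg$min_clades)
      data.table::fwrite(pairs, files[1L], sep = "\t", quote = FALSE)
      .log(cfg, stage, nrow(pairs), " pairs accepted at ", node,
           " (nmax=", nmax, ")")
      net <- build_og_network(pairs)
      sets <- ancestral_og_sets(net, nmax = nmax, min_len = cfg$min_len)
      sets_out <- data.table::copy(sets)[, node := node]
      data.table::fwrite(sets_out, files[2L], sep = "\t", quote = FALSE)
      .log(cfg, stage, nrow(sets), " ancestral OG sets")
      res <- recover_node_blocks(sets, genes, ctx,
                                 min_ogs_extant = cfg$min_ogs_extant,
                                 micro_gap = cfg$micro_gap,
                                 min_clades = cfg$min_clades)
      data.table::fwrite(res$gene_table, files[3L], sep = "\t", quote = FALSE)
      data.table::fwrite(res$summary, files[4L], sep = "\t", quote = FALSE)
      data.table::fwrite(res$summary[validated == FALSE], files[5L],
                         sep = "\t", quote = FALSE)
      .log(cfg, stage, length(res$validated), " validated / ",
           length(res$rejected), " rejected multi-species blocks")
      manifest$stages[[stage]] <- unname(node_key)
      summary <- res$summary
      n_pairs <- nrow(pairs)
      n_sets <- nrow(sets)
    }
    report_rows[[node]] <- data.table::data.table(
      node = node, nmax = nmax, n_pairs = n_pairs, n_sets = n_sets,
      n_validated = if (nrow(summary)) sum(summary$validated) else 0L,
      n_rejected = if (nrow(summary)) sum(!summary$validated) else 0L)
  }
  report <- data.table::rbindlist(report_rows)
  data.table::fwrite(report, file.path(cfg$out_dir, "report.tsv"),
                     sep = "\t", quote = FALSE)
  manifest$parameters <- cfg[setdiff(names(cfg), c("quiet"))]
  .write_manifest(cfg, manifest)
  report[]
}

#' Read the per-node summaries of a finished run
#'
#' Convenience accessor for scoring: returns the `summary_<node>.tsv` tables
#' of a pipeline output directory as a named list.
#'
#' @param out_dir pipeline output directory.
#' @param nodes node labels to read.
#' @return named list of `data.table`s.
#' @export
read_node_summaries <- function(out_dir, nodes) {
  stats::setNames(lapply(nodes, function(nd) {
    f <- file.path(out_dir, sprintf("summary_%s.tsv", nd))
    if (!file.exists(f)) stop("missing summary for node ", nd)
    data.table::fread(f, sep = "\t",
                      colClasses = list(character = c("block_id", "node", "og_union",
                                                      "species", "clades")))
  }), nodes)
}
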