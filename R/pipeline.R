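#' Pipeline configuration
#'
#' Validates and assembles the configuration for a full two-disease run.
#' A configuration round-trips losslessly through a flat YAML document
#' ([read_pipeline_config()] / [write_pipeline_config()]); on the command
#' line every key can be overridden by a flag.
#'
#' @param network path to the edge-list file.
#' @param seeds_a,seeds_b paths to the two seed lists (disease A and B).
#' @param out_dir output directory (created if absent).
#' @param score_threshold,score_scale,strip_taxon_prefix see
#'   [read_edge_list()].
#' @param restart,tol,max_iter see [random_walk_restart()].
#' @param positive_mode see [expand_seed_set()].
#' @param include_seeds see [common_genes()].
#' @param driver_alpha see [identify_key_drivers()].
#' @return object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(network, seeds_a, seeds_b, out_dir,
                            score_threshold = 0.9,
                            score_scale = "per_mille",
                            strip_taxon_prefix = FALSE,
                            restart = 0.7, tol = 1e-6, max_iter = 10000L,
                            positive_mode = "cross", include_seeds = TRUE,
                            driver_alpha = 1e-8) {
  stopifnot(is.character(network), is.character(seeds_a),
            is.character(seeds_b), is.character(out_dir))
  if (!(score_threshold >= 0 && score_threshold <= 1)) {
    stop("`score_threshold` must lie in [0, 1]", call. = FALSE)
  }
  if (!score_scale %in% c("per_mille", "unit")) {
    stop("`score_scale` must be \"per_mille\" or \"unit\"", call. = FALSE)
  }
  if (!(restart > 0 && restart <= 1)) {
    stop("`restart` must lie in (0, 1]", call. = FALSE)
  }
  if (!(tol > 0) || !(max_iter >= 1)) {
    stop("`tol` must be positive and `max_iter` at least 1", call. = FALSE)
  }
  if (!positive_mode %in% c("cross", "self")) {
    stop("`positive_mode` must be \"cross\" or \"self\"", call. = FALSE)
  }
  if (!(driver_alpha > 0 && driver_alpha <= 1)) {
    stop("`driver_alpha` must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(network = network, seeds_a = seeds_a, seeds_b = seeds_b,
         out_dir = out_dir, score_threshold = score_threshold,
         score_scale = score_scale,
         strip_taxon_prefix = isTRUE(strip_taxon_prefix),
         restart = restart, tol = tol, max_iter = as.integer(max_iter),
         positive_mode = positive_mode,
         include_seeds = isTRUE(include_seeds),
         driver_alpha = driver_alpha),
    class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full two-disease key-driver pipeline
#'
#' Executes the complete network stage: reads and filters the interaction
#' network, expands both seed sets by random walk with restart, cuts each
#' expansion at its running-sum peak, intersects the expansions, and scores
#' every network gene for key-driver enrichment. Writes, into
#' `cfg$out_dir`: `curve_a.tsv` / `curve_b.tsv` (rank, gene, increment,
#' running sum), `expanded_a.txt` / `expanded_b.txt` (predicted genes, one
#' per line), `common_genes.txt`, `key_drivers.tsv`, and `manifest.json`
#' recording the parameters, stage gene counts, package version and
#' timings. Given identical inputs and configuration the tabular outputs
#' are byte-identical across runs.
#'
#' @param cfg a [pipeline_config()].
#' @param quiet suppress stage progress messages.
#' @return (invisibly) the manifest as a list; `manifest$files` names every
#'   file written.
#' @export
run_full_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  say <- function(...) if (!quiet) message("[driverscan] ", ...)
  t0 <- Sys.time()
  for (f in c(cfg$network, cfg$seeds_a, cfg$seeds_b)) {
    if (!file.exists(f)) stop("input file not found: ", f, call. = FALSE)
  }
  net <- read_edge_list(cfg$network, score_threshold = cfg$score_threshold,
                        score_scale = cfg$score_scale,
                        strip_taxon_prefix = cfg$strip_taxon_prefix)
  say("network: ", length(net$genes), " genes, ", nrow(net$edges), " edges")
  seeds_a <- read_seed_list(cfg$seeds_a)
  seeds_b <- read_seed_list(cfg$seeds_b)

  exp_a <- expand_seed_set(net, seeds_a, positives = seeds_b,
                           restart = cfg$restart, tol = cfg$tol,
                           max_iter = cfg$max_iter,
                           positive_mode = cfg$positive_mode)
  say("disease A: ", length(exp_a$seeds), " mapped seeds -> ",
      length(exp_a$predicted), " predicted (cutoff rank ",
      exp_a$cutoff_rank, ")")
  exp_b <- expand_seed_set(net, seeds_b, positives = seeds_a,
                           restart = cfg$restart, tol = cfg$tol,
                           max_iter = cfg$max_iter,
                           positive_mode = cfg$positive_mode)
  say("disease B: ", length(exp_b$seeds), " mapped seeds -> ",
      length(exp_b$predicted), " predicted (cutoff rank ",
      exp_b$cutoff_rank, ")")
  common <- common_genes(exp_a, exp_b, include_seeds = cfg$include_seeds)
  say("common genes: ", length(common))
  if (length(common) == 0L) {
    stop("key-driver stage: the two expansions share no genes", call. = FALSE)
  }
  drivers <- identify_key_drivers(net, common,
                                  driver_alpha = cfg$driver_alpha)
  say("key drivers at FDR < ", cfg$driver_alpha, ": ",
      sum(drivers$is_driver))

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$out_dir, f)
  write_tsv <- function(d, f) {
    utils::write.table(d, out(f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_tsv(exp_a$curve$table[c("rank", "gene", "increment", "running")],
            "curve_a.tsv")
  write_tsv(exp_b$curve$table[c("rank", "gene", "increment", "running")],
            "curve_b.tsv")
  writeLines(exp_a$predicted, out("expanded_a.txt"))
  writeLines(exp_b$predicted, out("expanded_b.txt"))
  writeLines(common, out("common_genes.txt"))
  write_tsv(drivers, "key_drivers.tsv")

  files <- c("curve_a.tsv", "curve_b.tsv", "expanded_a.txt",
             "expanded_b.txt", "common_genes.txt", "key_drivers.tsv")
  manifest <- list(
    package = "driverscan",
    version = as.character(utils::packageVersion("driverscan")),
    config = unclass(cfg),
    counts = list(network_genes = length(net$genes),
                  network_edges = nrow(net$edges),
                  seeds_a_mapped = length(exp_a$seeds),
                  seeds_b_mapped = length(exp_b$seeds),
                  predicted_a = length(exp_a$predicted),
                  predicted_b = length(exp_b$predicted),
                  common = length(common),
                  drivers = sum(drivers$is_driver)),
    files = as.list(stats::setNames(vapply(files, out, ""), files)),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  say("wrote ", length(files) + 1L, " files to ", cfg$out_dir)
  invisible(manifest)
}
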