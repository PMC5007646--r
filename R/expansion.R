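#' GSEA-style running sum over a ranked gene list
#'
#' Walks a ranked gene list from top to bottom, adding `sqrt((N - G) / G)`
#' when the gene belongs to the positive set and subtracting
#' `sqrt(G / (N - G))` otherwise, where `N` is the total number of network
#' genes and `G` the positive-set size. These are the classical unweighted
#' Kolmogorov-Smirnov enrichment increments; scanning all `N` genes with all
#' `G` positives present brings the sum back to exactly 0, and the position
#' of the maximum (the peak) marks the rank at which the positives are most
#' concentrated -- the expansion cutoff.
#'
#' @param ranked character vector of genes, best first.
#' @param positives character vector defining the positive set (already
#'   restricted to network genes).
#' @param N total number of genes on the network (not the length of
#'   `ranked`, which may exclude seeds).
#' @return object of class `running_sum_curve`: list with `table`
#'   (data.frame: rank, gene, positive, increment, running), `peak_index`
#'   (first rank attaining the maximum), `peak_value`, `N`, `G`, and
#'   `degenerate` (TRUE when the maximum never rises above 0, i.e. the
#'   positives sit no higher than chance).
#' @export
running_sum <- function(ranked, positives, N) {
  ranked <- as.character(ranked)
  if (anyDuplicated(ranked)) stop("`ranked` contains duplicates", call. = FALSE)
  G <- length(unique(positives))
  if (N < length(ranked)) {
    stop("`N` must be at least the length of the ranked list", call. = FALSE)
  }
  if (G < 1L || G >= N) {
    stop("degenerate increments: need 1 <= G < N (G = ", G, ", N = ", N, ")",
         call. = FALSE)
  }
  pos <- ranked %in% positives
  inc <- ifelse(pos, sqrt((N - G) / G), -sqrt(G / (N - G)))
  run <- cumsum(inc)
  peak_value <- max(run)
  peak_index <- which.max(run)  # first index attaining the maximum
  structure(
    list(table = data.frame(rank = seq_along(ranked), gene = ranked,
                            positive = pos, increment = inc, running = run,
                            stringsAsFactors = FALSE),
         peak_index = peak_index, peak_value = peak_value,
         N = N, G = G, degenerate = peak_value <= 0),
    class = "running_sum_curve")
}

#' @export
print.running_sum_curve <- function(x, ...) {
  cat("running_sum_curve: ", nrow(x$table), " ranked genes, G = ", x$G,
      ", N = ", x$N, "; peak ", format(x$peak_value, digits = 4),
      " at rank ", x$peak_index,
      if (x$degenerate) " [degenerate]" else "", "\n", sep = "")
  invisible(x)
}

#' Expand a seed set on the network and cut at the running-sum peak
#'
#' Composes the full expansion for one disease: restart distribution over
#' its seeds, random walk with restart, ranking of all non-seed genes by
#' visiting probability, and the running-sum cutoff. Under the default
#' `positive_mode = "cross"` the positive set is the *other* disease's seed
#' genes, so the peak marks where the expansion from disease A is maximally
#' enriched for known genes of disease B. `positive_mode = "self"` instead
#' labels the expanding disease's own seeds positive (they are then kept in
#' the ranked list so the curve is well defined) and the predicted genes are
#' the non-seed genes above the peak.
#'
#' @param net a [ppi_network()].
#' @param seeds seed symbols for the disease being expanded.
#' @param positives seed symbols of the other disease (ignored under
#'   `positive_mode = "self"`).
#' @param restart,tol,max_iter passed to [random_walk_restart()].
#' @param positive_mode `"cross"` (default) or `"self"`.
#' @return object of class `expansion_result`: list with `seeds` (mapped),
#'   `predicted` (genes ranked at or above the peak, own seeds excluded),
#'   `cutoff_rank`, `curve` (the [running_sum()] object), and
#'   `network_genes` (the gene index the result was computed on).
#' @export
expand_seed_set <- function(net, seeds, positives = NULL, restart = 0.7,
                            tol = 1e-6, max_iter = 10000L,
                            positive_mode = c("cross", "self")) {
  positive_mode <- match.arg(positive_mode)
  scores <- rwr_scores(net, seeds, restart = restart, tol = tol,
                       max_iter = max_iter)
  mapped_seeds <- scores$seeds
  if (positive_mode == "cross") {
    if (is.null(positives)) {
      stop("`positives` is required under positive_mode = \"cross\"",
           call. = FALSE)
    }
    pos <- intersect(unique(as.character(positives)), net$genes)
    if (length(pos) == 0L) {
      stop("no positive gene maps onto the network", call. = FALSE)
    }
    ranked <- rank_genes(scores, exclude = mapped_seeds)
  } else {
    pos <- mapped_seeds
    ranked <- rank_genes(scores)
  }
  curve <- running_sum(ranked$gene, pos, N = length(net$genes))
  top <- ranked$gene[seq_len(curve$peak_index)]
  structure(
    list(seeds = mapped_seeds,
         predicted = setdiff(top, mapped_seeds),
         cutoff_rank = curve$peak_index,
         curve = curve,
         positive_mode = positive_mode,
         network_genes = net$genes),
    class = "expansion_result")
}

#' @export
print.expansion_result <- function(x, ...) {
  cat("expansion_result: ", length(x$seeds), " seeds -> ",
      length(x$predicted), " predicted genes (cutoff rank ",
      x$cutoff_rank, ", mode ", x$positive_mode, ")\n", sep = "")
  invisible(x)
}

#' Overlap of two seed-set expansions
#'
#' @param a,b `expansion_result` objects computed on the same network.
#' @param include_seeds when TRUE (default) each disease's mapped seeds are
#'   unioned with its predictions before intersecting, so a gene that is a
#'   known gene of one disease and a predicted gene of the other counts as
#'   common.
#' @return sorted character vector of common genes.
#' @export
common_genes <- function(a, b, include_seeds = TRUE) {
  stopifnot(inherits(a, "expansion_result"), inherits(b, "expansion_result"))
  if (!identical(a$network_genes, b$network_genes)) {
    stop("expansions were computed on different networks", call. = FALSE)
  }
  sa <- if (include_seeds) union(a$predicted, a$seeds) else a$predicted
  sb <- if (include_seeds) union(b$predicted, b$seeds) else b$predicted
  sort(intersect(sa, sb), method = "radix")
}
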