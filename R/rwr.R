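#' Initial restart distribution over a seed set
#'
#' Places probability 1/m on each of the m seed genes that map onto the
#' network and 0 elsewhere. Seeds absent from the network are dropped with a
#' warning and the mass renormalized over the mapped seeds; curated disease
#' gene lists routinely contain symbols missing from any given interaction
#' database, so an error here would be unhelpful. At least one seed must map.
#'
#' @param net a [ppi_network()].
#' @param seeds character vector of seed gene symbols.
#' @return named probability vector over the gene index, with attribute
#'   `"seeds"` holding the mapped seed symbols.
#' @export
initial_state <- function(net, seeds) {
  stopifnot(inherits(net, "ppi_network"))
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) stop("`seeds` is empty", call. = FALSE)
  mapped <- intersect(seeds, net$genes)
  missing <- setdiff(seeds, net$genes)
  if (length(mapped) == 0L) {
    stop("no seed maps onto the network; unmatched: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (length(missing)) {
    warning(length(missing), " seed(s) not on the network, dropped: ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  p0 <- stats::setNames(numeric(length(net$genes)), net$genes)
  p0[mapped] <- 1 / length(mapped)
  attr(p0, "seeds") <- mapped
  p0
}

#' Random walk with restart to steady state
#'
#' Iterates `p <- (1 - restart) * T p + restart * p0` until the L1 distance
#' between successive iterates falls below `tol`. At the fixed point the
#' entry for each gene is its steady-state visiting probability: a measure of
#' network proximity to the seed set, with the restart term continually
#' re-injecting mass at the seeds.
#'
#' @param tm a `transition_matrix` from [column_normalize()].
#' @param p0 initial/restart probability vector (see [initial_state()]).
#' @param restart restart probability r in (0, 1\]; default 0.7.
#' @param tol L1 convergence tolerance between successive iterates
#'   (default 1e-6).
#' @param max_iter iteration cap; exceeding it is an error carrying the last
#'   residual.
#' @return object of class `node_scores`: list with `probabilities` (named,
#'   sums to 1), `seeds`, `restart`, `iterations`, `converged`, `residual`.
#' @export
random_walk_restart <- function(tm, p0, restart = 0.7, tol = 1e-6,
                                max_iter = 10000L) {
  stopifnot(inherits(tm, "transition_matrix"))
  if (!(restart > 0 && restart <= 1)) {
    stop("`restart` must lie in (0, 1]", call. = FALSE)
  }
  if (length(p0) != length(tm$genes)) {
    stop("`p0` length does not match the gene index", call. = FALSE)
  }
  if (abs(sum(p0) - 1) > 1e-8 || any(p0 < 0)) {
    stop("`p0` must be a probability vector summing to 1", call. = FALSE)
  }
  M <- tm$matrix
  p <- as.numeric(p0)
  it <- 0L
  resid <- Inf
  while (it < max_iter) {
    pn <- (1 - restart) * as.numeric(M %*% p) + restart * as.numeric(p0)
    resid <- sum(abs(pn - p))
    p <- pn
    it <- it + 1L
    if (resid < tol) break
  }
  if (resid >= tol) {
    stop("random walk did not converge in ", max_iter,
         " iterations (last L1 residual ", format(resid), ")", call. = FALSE)
  }
  structure(
    list(probabilities = stats::setNames(p, tm$genes),
         seeds = attr(p0, "seeds"),
         restart = restart, iterations = it,
         converged = TRUE, residual = resid),
    class = "node_scores")
}

#' @export
print.node_scores <- function(x, ...) {
  cat("node_scores:", length(x$probabilities), "genes,",
      length(x$seeds), "seeds, r =", x$restart,
      "| converged in", x$iterations, "iterations\n")
  invisible(x)
}

#' Propagate a seed set over a network (convenience wrapper)
#'
#' @inheritParams initial_state
#' @inheritParams random_walk_restart
#' @return a `node_scores` object.
#' @export
rwr_scores <- function(net, seeds, restart = 0.7, tol = 1e-6,
                       max_iter = 10000L) {
  tm <- column_normalize(net)
  random_walk_restart(tm, initial_state(net, seeds),
                      restart = restart, tol = tol, max_iter = max_iter)
}

#' Rank genes by steady-state visiting probability
#'
#' Sorts genes by probability, descending; exact ties are broken by
#' lexicographic symbol order so that rankings are reproducible across
#' platforms. Genes in `exclude` (typically the expanding disease's own
#' seeds, which are known rather than predicted) are removed first.
#'
#' @param scores a `node_scores` object.
#' @param exclude symbols to drop from the ranking.
#' @return data.frame with columns `rank`, `gene`, `probability`.
#' @export
rank_genes <- function(scores, exclude = character()) {
  stopifnot(inherits(scores, "node_scores"))
  p <- scores$probabilities
  p <- p[!names(p) %in% exclude]
  ord <- order(-p, names(p), method = "radix")
  data.frame(rank = seq_along(ord), gene = names(p)[ord],
             probability = as.numeric(p[ord]),
             stringsAsFactors = FALSE, row.names = NULL)
}
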