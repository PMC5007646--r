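#' Upper tail of the hypergeometric distribution
#'
#' P(X >= m) for X ~ Hypergeometric(N, M, n): the probability that drawing
#' `n` genes without replacement from a universe of `N` containing `M`
#' marked genes yields at least `m` marked ones. This is the enrichment
#' p-value for observing `m` common disease genes among the `n` neighbors of
#' a candidate driver. Computed through the stable survival function
#' ([stats::phyper]), which is exact for small N.
#'
#' @param N universe size (all network genes).
#' @param M number of marked genes (common disease genes).
#' @param n draw size (neighbor count).
#' @param m observed overlap; must satisfy `0 <= m <= min(n, M)`.
#' @return P(X >= m), vectorized over the arguments.
#' @export
hypergeom_upper_tail <- function(N, M, n, m) {
  bad <- M < 0 | M > N | n < 0 | n > N | m < 0 | m > pmin(n, M)
  if (any(bad)) {
    stop("hypergeometric bounds violated: need 0 <= M <= N, 0 <= n <= N, ",
         "0 <= m <= min(n, M)", call. = FALSE)
  }
  stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values in the original order (via
#'   [stats::p.adjust]`(method = "BH")`).
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Score every network gene as a candidate key driver
#'
#' For each gene on the network, counts its interaction neighbors (`n`) and
#' how many of them belong to the common disease-gene set (`m`), and tests
#' the neighborhood for enrichment with the hypergeometric upper tail
#' (universe = all network genes, marked set = the common genes). P-values
#' are Benjamini-Hochberg adjusted over the whole network -- every gene is
#' screened, so the family size is the network size -- and genes with
#' adjusted p below `driver_alpha` are flagged as key drivers. Common genes
#' are themselves eligible.
#'
#' @param net a [ppi_network()].
#' @param common character vector of common disease genes; must be a
#'   non-empty subset of the network genes.
#' @param driver_alpha FDR threshold for the driver flag (default 1e-8).
#' @return data.frame with columns `gene`, `n_neighbors`, `m_common`,
#'   `p_raw`, `p_fdr`, `is_driver`, sorted by `p_fdr` then symbol.
#' @export
identify_key_drivers <- function(net, common, driver_alpha = 1e-8) {
  stopifnot(inherits(net, "ppi_network"))
  common <- unique(as.character(common))
  if (length(common) == 0L) {
    stop("`common` is empty: nothing to test enrichment against",
         call. = FALSE)
  }
  extra <- setdiff(common, net$genes)
  if (length(extra)) {
    stop("`common` contains genes not on the network: ",
         paste(utils::head(extra, 5L), collapse = ", "), call. = FALSE)
  }
  A <- adjacency(net)
  N <- length(net$genes)
  M <- length(common)
  n <- as.integer(Matrix::colSums(A))
  ind <- as.numeric(net$genes %in% common)
  m <- as.integer(round(as.numeric(A %*% ind)))
  p_raw <- hypergeom_upper_tail(N, M, n, m)
  p_fdr <- bh_adjust(p_raw)
  out <- data.frame(gene = net$genes, n_neighbors = n, m_common = m,
                    p_raw = p_raw, p_fdr = p_fdr,
                    is_driver = p_fdr < driver_alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_fdr, out$gene, method = "radix"), , drop = FALSE]
  row.names(out) <- NULL
  out
}
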