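#' Build a protein-interaction network from an edge table
#'
#' Constructs the undirected, unweighted interaction network that all
#' downstream propagation and enrichment steps operate on. Edge confidence
#' scores are used only to filter edges (strictly greater than
#' `score_threshold`); the retained network is binary, exactly as in the
#' adjacency-matrix formulation where entry (i, j) is 1 iff proteins i and j
#' interact.
#'
#' Self-loops are removed, duplicate pairs (in either orientation) are
#' collapsed keeping the highest score, and genes left without any surviving
#' edge are dropped so that every column of the transition matrix is
#' well-defined.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `score`
#'   (score in \[0, 1\]).
#' @param score_threshold edges with score strictly greater than this value
#'   are kept. Default 0 keeps everything.
#' @return An object of class `ppi_network` with components `graph` (an
#'   [igraph::graph] over the sorted gene index), `genes` (character vector,
#'   lexicographic order), `edges` (the surviving edge table) and
#'   `score_threshold`.
#' @seealso [read_edge_list()] to build directly from a STRING-style file.
#' @export
ppi_network <- function(edges, score_threshold = 0) {
  stopifnot(is.data.frame(edges))
  need <- c("gene_a", "gene_b", "score")
  if (!all(need %in% names(edges))) {
    stop("`edges` must have columns gene_a, gene_b, score", call. = FALSE)
  }
  if (!is.numeric(edges$score) || anyNA(edges$score)) {
    stop("edge scores must be numeric and non-missing", call. = FALSE)
  }
  if (any(edges$score < 0 | edges$score > 1)) {
    stop("edge scores must lie in [0, 1]", call. = FALSE)
  }
  if (score_threshold < 0 || score_threshold > 1) {
    stop("`score_threshold` must lie in [0, 1]", call. = FALSE)
  }
  a <- as.character(edges$gene_a)
  b <- as.character(edges$gene_b)
  s <- as.numeric(edges$score)

  keep <- a != b & s > score_threshold
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  if (length(a) == 0L) {
    stop("no edges survive the construction (threshold ", score_threshold,
         "); refusing to build an empty network", call. = FALSE)
  }
  # canonical unordered orientation, then collapse duplicates (max score)
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  ord <- order(key, -s, method = "radix")
  dup <- duplicated(key[ord])
  ed <- data.frame(gene_a = lo[ord][!dup], gene_b = hi[ord][!dup],
                   score = s[ord][!dup], stringsAsFactors = FALSE)

  genes <- sort(unique(c(ed$gene_a, ed$gene_b)), method = "radix")
  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = genes, stringsAsFactors = FALSE))
  structure(
    list(graph = g, genes = genes, edges = ed,
         score_threshold = score_threshold),
    class = "ppi_network")
}

#' Read a STRING-style edge list from disk
#'
#' Parses a whitespace- or tab-separated file with at least three columns
#' (gene_a, gene_b, score). Raw STRING "protein links" files carry integer
#' confidence scores on a 0--1000 scale; `score_scale = "per_mille"` divides
#' by 1000 before thresholding so that the conventional "confidence score
#' > 0.900" filter applies bit-exactly to both dialects. A header line is
#' skipped automatically when its third field is not numeric.
#'
#' @param path file path.
#' @param score_threshold retain edges with (rescaled) score strictly greater
#'   than this; default 0.9, the highest-confidence STRING cut.
#' @param score_scale `"per_mille"` (raw scores divided by 1000, the STRING
#'   file convention) or `"unit"` (scores already in \[0, 1\]).
#' @param strip_taxon_prefix drop a leading `"<digits>."` taxon prefix
#'   (e.g. `"9606."`) from gene identifiers. Off by default; identifiers are
#'   otherwise treated as opaque case-sensitive strings.
#' @return A [ppi_network()].
#' @export
read_edge_list <- function(path, score_threshold = 0.9,
                           score_scale = c("per_mille", "unit"),
                           strip_taxon_prefix = FALSE) {
  score_scale <- match.arg(score_scale)
  if (!file.exists(path)) {
    stop("edge list file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("edge list is empty: ", path, call. = FALSE)

  toks <- strsplit(trimws(lines[idx]), "[\t ]+")
  # header detection: first data line whose third field is not numeric
  first <- toks[[1L]]
  if (length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3L])))) {
    toks <- toks[-1L]; idx <- idx[-1L]
    if (length(toks) == 0L) stop("edge list has a header but no rows: ",
                                 path, call. = FALSE)
  }
  nfield <- lengths(toks)
  bad <- which(nfield < 3L)
  if (length(bad)) {
    stop("malformed edge row (expected >= 3 columns) at line ", idx[bad[1L]],
         " of ", path, call. = FALSE)
  }
  a <- vapply(toks, `[[`, "", 1L)
  b <- vapply(toks, `[[`, "", 2L)
  s <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 3L)))
  if (anyNA(s)) {
    stop("non-numeric score at line ", idx[which(is.na(s))[1L]], " of ",
         path, call. = FALSE)
  }
  if (score_scale == "per_mille") s <- s / 1000
  if (any(s < 0 | s > 1)) {
    stop("scores outside [0, 1] after rescaling; check `score_scale`",
         call. = FALSE)
  }
  if (strip_taxon_prefix) {
    a <- sub("^[0-9]+\\.", "", a)
    b <- sub("^[0-9]+\\.", "", b)
  }
  before <- unique(c(a[a != b], b[a != b]))
  net <- ppi_network(
    data.frame(gene_a = a, gene_b = b, score = s, stringsAsFactors = FALSE),
    score_threshold = score_threshold)
  dropped <- setdiff(before, net$genes)
  if (length(dropped)) {
    message(length(dropped), " gene(s) dropped (no edge above threshold)")
  }
  net
}

#' Read a seed-gene list (one symbol per line, '#' comments ignored)
#'
#' @param path UTF-8 text file.
#' @return character vector of unique symbols, input order preserved.
#' @export
read_seed_list <- function(path) {
  if (!file.exists(path)) {
    stop("seed list file not found: ", path, call. = FALSE)
  }
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[!grepl("^(#|$)", x)]
  unique(x)
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network: ", length(x$genes), " genes, ", nrow(x$edges),
      " edges (score > ", x$score_threshold, ")\n", sep = "")
  invisible(x)
}

#' Interaction neighbors of a gene
#'
#' @param net a [ppi_network()].
#' @param gene a gene symbol present in the network.
#' @return character vector of adjacent genes (sorted), excluding `gene`.
#' @export
gene_neighbors <- function(net, gene) {
  stopifnot(inherits(net, "ppi_network"))
  if (!gene %in% net$genes) {
    stop("gene not in network: ", gene, call. = FALSE)
  }
  nb <- igraph::neighbors(net$graph, gene)
  sort(setdiff(names(nb), gene), method = "radix")
}

#' Binary adjacency matrix of a network
#'
#' @param net a [ppi_network()].
#' @return sparse symmetric 0/1 matrix with zero diagonal, rows/columns in
#'   gene-index order.
#' @export
adjacency <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  A <- igraph::as_adjacency_matrix(net$graph, type = "both", sparse = TRUE)
  A <- A[net$genes, net$genes, drop = FALSE]
  A@x[] <- 1  # collapsed multiplicities, keep it strictly binary
  A
}

#' Column-normalized transition matrix
#'
#' Divides every column of the binary adjacency matrix by the corresponding
#' node degree, giving the column-stochastic transition operator of the
#' random walk (each entry is the probability of stepping from gene j to a
#' uniformly chosen interaction partner i).
#'
#' @param net a [ppi_network()].
#' @return object of class `transition_matrix`: list with `matrix` (sparse
#'   column-stochastic) and `genes`.
#' @export
column_normalize <- function(net) {
  A <- adjacency(net)
  deg <- Matrix::colSums(A)
  if (any(deg == 0)) {
    stop("zero-degree column in adjacency; network is corrupted",
         call. = FALSE)
  }
  Tm <- A %*% Matrix::Diagonal(x = 1 / deg)
  dimnames(Tm) <- list(net$genes, net$genes)
  structure(list(matrix = Tm, genes = net$genes),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("transition_matrix over", length(x$genes), "genes (column-stochastic)\n")
  invisible(x)
}
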