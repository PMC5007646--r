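# small graph builders used across the network-stage tests

make_net <- function(a, b, score = 0.95, threshold = 0.9) {
  ppi_network(data.frame(gene_a = a, gene_b = b, score = score,
                         stringsAsFactors = FALSE),
              score_threshold = threshold)
}

# path v1 - v2 - ... - vn
path_network <- function(n, prefix = "N") {
  v <- sprintf("%s%02d", prefix, seq_len(n))
  make_net(v[-n], v[-1])
}

# star with one center and k leaves
star_network <- function(k) {
  make_net(rep("HUB", k), sprintf("L%02d", seq_len(k)))
}

# Erdos-Renyi graph; isolated vertices are dropped by construction
er_network <- function(n, p, seed) {
  withr::with_seed(seed, {
    cmb <- utils::combn(sprintf("V%03d", seq_len(n)), 2L)
    keep <- stats::runif(ncol(cmb)) < p
  })
  make_net(cmb[1L, keep], cmb[2L, keep])
}

# independent hand tally of a gene's neighbors from the raw edge table
scan_neighbors <- function(net, gene) {
  ed <- net$edges
  sort(unique(c(ed$gene_b[ed$gene_a == gene], ed$gene_a[ed$gene_b == gene])))
}
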