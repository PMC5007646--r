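test_that("running-sum increments and peak follow the enrichment formula", {
  ranked <- sprintf("g%02d", 1:10)
  rs <- running_sum(ranked, positives = c("g01", "g02"), N = 10)
  # sqrt((10-2)/2) = 2 at positives, sqrt(2/8) = 0.5 down elsewhere
  expect_equal(rs$table$increment[1:3], c(2, 2, -0.5))
  expect_equal(rs$peak_index, 2L)
  expect_equal(rs$peak_value, 4)
  expect_false(rs$degenerate)
  # the full scan returns to zero
  expect_lt(abs(rs$table$running[10]), 1e-9)

  # positives ranked last: the curve never rises above zero
  worst <- running_sum(ranked, positives = c("g09", "g10"), N = 10)
  expect_lte(worst$peak_value, 0)
  expect_true(worst$degenerate)

  expect_error(running_sum(ranked, character(), N = 10), "degenerate")
  expect_error(running_sum(ranked, ranked, N = 10), "degenerate")
})

test_that("peak matches a brute-force cumulative scan on random orderings", {
  withr::with_seed(31, {
    for (i in 1:25) {
      genes <- sprintf("g%02d", 1:30)
      ranked <- sample(genes)
      pos <- sample(genes, 5)
      rs <- running_sum(ranked, pos, N = 30)
      inc <- ifelse(ranked %in% pos, sqrt(25 / 5), -sqrt(5 / 25))
      cum <- cumsum(inc)
      expect_equal(rs$peak_index, which.max(cum))
      expect_equal(rs$peak_value, max(cum))
    }
  })
})

test_that("peak is invariant to permuting genes below the cutoff", {
  withr::with_seed(8, {
    genes <- sprintf("g%02d", 1:40)
    ranked <- sample(genes)
    pos <- sample(genes, 6)
    rs <- running_sum(ranked, pos, N = 40)
    below <- ranked[-seq_len(rs$peak_index)]
    ranked2 <- c(ranked[seq_len(rs$peak_index)], sample(below))
    rs2 <- running_sum(ranked2, pos, N = 40)
    expect_equal(rs2$peak_index, rs$peak_index)
    expect_equal(rs2$peak_value, rs$peak_value)
  })
})

test_that("expansion recovers a planted bridge between two seed modules", {
  sim <- simulate_network(n_genes = 200, module_sizes = c(15, 15),
                          driver_degree = 30, p_background = 0.02,
                          seed = 42)
  ex <- expand_seed_set(sim$network, sim$seeds_a, sim$seeds_b)
  expect_true(all(sim$drivers %in% ex$predicted))
  expect_gte(mean(sim$seeds_b %in% ex$predicted), 0.8)
  expect_length(intersect(ex$predicted, ex$seeds), 0L)
  expect_equal(ex$cutoff_rank, ex$curve$peak_index)

  # deterministic: identical inputs give identical predictions
  ex2 <- expand_seed_set(sim$network, sim$seeds_a, sim$seeds_b)
  expect_identical(ex$predicted, ex2$predicted)
  expect_identical(ex$curve$table, ex2$curve$table)
})

test_that("pure restart collapses the ranking to the lexicographic order", {
  net <- er_network(30, 0.2, seed = 4)
  seeds <- net$genes[1:3]
  pos <- net$genes[10:15]
  ex <- expand_seed_set(net, seeds, pos, restart = 1)
  nonseed <- setdiff(net$genes, seeds)
  expect_identical(ex$curve$table$gene,
                   sort(nonseed, method = "radix"))
  ex2 <- expand_seed_set(net, seeds, pos, restart = 1)
  expect_identical(ex$predicted, ex2$predicted)
})

test_that("self-positive mode keeps seeds in the scan and flags them", {
  net <- er_network(40, 0.15, seed = 17)
  seeds <- net$genes[1:5]
  ex <- expand_seed_set(net, seeds, positive_mode = "self")
  expect_equal(ex$curve$G, length(ex$seeds))
  expect_length(intersect(ex$predicted, ex$seeds), 0L)
})

test_that("overlap of two expansions is plain set algebra", {
  sim <- simulate_network(seed = 7)
  ea <- expand_seed_set(sim$network, sim$seeds_a, sim$seeds_b)
  eb <- expand_seed_set(sim$network, sim$seeds_b, sim$seeds_a)
  cg <- common_genes(ea, eb, include_seeds = TRUE)
  oracle <- sort(intersect(union(ea$predicted, ea$seeds),
                           union(eb$predicted, eb$seeds)))
  expect_identical(cg, oracle)
  cg0 <- common_genes(ea, eb, include_seeds = FALSE)
  expect_identical(cg0, sort(intersect(ea$predicted, eb$predicted)))
  expect_identical(common_genes(ea, ea), sort(union(ea$predicted, ea$seeds)))

  other <- simulate_network(n_genes = 150, seed = 8)
  eo <- expand_seed_set(other$network, other$seeds_a, other$seeds_b)
  expect_error(common_genes(ea, eo), "different networks")
})
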