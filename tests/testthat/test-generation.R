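test_that("ER generation places exactly the requested nodes and edges", {
  spec <- generation_spec(200, "erdos-renyi", n_edges = 400)
  net <- generate_topology(spec, seed = 1)
  expect_equal(n_nodes(net), 200)
  expect_equal(n_edges(net), 400)
  e <- network_edges(net)
  expect_false(any(e$from == e$to))            # self-loops off by default
  expect_false(anyDuplicated(paste(e$from, e$to)) > 0)
  # maximum density forces the complete digraph
  full <- generate_topology(generation_spec(5, "erdos-renyi", n_edges = 20),
                            seed = 2)
  e <- network_edges(full)
  expect_equal(nrow(e), 20)
  expect_equal(nrow(unique(e)), 20)
  expect_true(all(table(e$to) == 4))
})

test_that("fixed-indegree gives every node exactly k regulators", {
  net <- generate_topology(generation_spec(10, "fixed-indegree", k = 2),
                           seed = 3)
  e <- network_edges(net)
  expect_equal(unname(table(factor(e$to, levels = net$nodes))),
               rep(2L, 10), ignore_attr = TRUE)
  expect_error(generation_spec(5, "fixed-indegree", k = 5),
               "infeasible")
})

test_that("ER in-degrees fit the binomial null on a large instance", {
  set.seed(4)
  net <- generate_topology(generation_spec(10000, "erdos-renyi",
                                           n_edges = 20000))
  indeg <- tabulate(match(network_edges(net)$to, net$nodes), 10000)
  # expected Binomial(9999, p) ~ Poisson(2); chi-square GOF over 0..6, tail pooled
  p_edge <- 20000 / (10000 * 9999)
  probs <- dbinom(0:6, 9999, p_edge)
  obs <- c(vapply(0:6, function(d) sum(indeg == d), numeric(1)),
           sum(indeg > 6))
  gof <- chisq.test(obs, p = c(probs, 1 - sum(probs)))
  expect_gt(gof$p.value, 0.01)
})

test_that("preferential attachment has a heavier in-degree tail than ER", {
  set.seed(5)
  ba <- generate_topology(generation_spec(3000, "barabasi-preferential",
                                          k = 6))
  er <- generate_topology(generation_spec(3000, "erdos-renyi",
                                          n_edges = n_edges(ba)))
  q99 <- function(net) {
    indeg <- tabulate(match(network_edges(net)$to, net$nodes), 3000)
    quantile(indeg, 0.99)
  }
  expect_gt(q99(ba), q99(er))
})

test_that("small-world with rewiring probability 0 is the exact ring lattice", {
  net <- generate_topology(generation_spec(12, "watts-strogatz", k = 2,
                                           rewire_prob = 0), seed = 6)
  e <- network_edges(net)
  expected <- do.call(rbind, lapply(1:12, function(i) {
    src <- ((i - 1:2 - 1) %% 12) + 1
    data.frame(from = net$nodes[src], to = net$nodes[i])
  }))
  key <- function(d) sort(paste(d$from, d$to))
  expect_identical(key(e), key(expected))
})

test_that("power-law in-degrees stay within [1, N-1]", {
  set.seed(7)
  net <- generate_topology(generation_spec(100, "power-law",
                                           power_law_exponent = 2.5))
  indeg <- tabulate(match(network_edges(net)$to, net$nodes), 100)
  expect_true(all(indeg >= 1 & indeg <= 99))
})

test_that("bias-random functions recover the requested bias", {
  # degenerate bias: every entry 1
  net <- generate_topology(generation_spec(20, "fixed-indegree", k = 3),
                           seed = 8)
  all1 <- generate_functions(net, "bias-random", bias = 1)
  expect_true(all(unlist(lapply(all1$functions, `[[`, "table")) == 1L))
  # parameter recovery: >= 10^4 sampled bits within 3 binomial sigma
  set.seed(9)
  big <- generate_topology(generation_spec(1500, "fixed-indegree", k = 3))
  fns <- generate_functions(big, "bias-random", bias = 0.5)
  bits <- unlist(lapply(fns$functions, `[[`, "table"))
  expect_gte(length(bits), 1e4)
  expect_lt(abs(mean(bits) - 0.5), 3 * sqrt(0.25 / length(bits)))
})

test_that("canalyzing functions have a forcing input/value pair", {
  set.seed(10)
  net <- generate_topology(generation_spec(30, "fixed-indegree", k = 3))
  fns <- generate_functions(net, "canalyzing", bias = 0.5)
  for (f in fns$functions) {
    can <- attr(f, "canalyzing")
    expect_false(is.null(can))
    j <- match(can$input, f$inputs)
    for (r in 0:(2^3 - 1)) {
      v <- as.integer(bitwAnd(bitwShiftR(r, 2:0), 1L))
      if (v[j] == can$input_value)
        expect_equal(evaluate_function(f, v), can$output)
    }
  }
  # the canalyzing-inhibitor pattern: input value 1 forces output 0
  inh <- generate_functions(net, "canalyzing", bias = 0.5, seed = 11,
                            canalyzing_value = list(input_value = 1,
                                                    output = 0))
  f <- inh$functions[[1]]
  can <- attr(f, "canalyzing")
  expect_equal(can$input_value, 1)
  expect_equal(can$output, 0)
})

test_that("ensemble generation is reproducible from the master seed", {
  spec <- generation_spec(15, "erdos-renyi", n_edges = 30)
  e1 <- generate_ensemble(spec, 4, seed = 12)
  e2 <- generate_ensemble(spec, 4, seed = 12)
  f1 <- tempfile(); f2 <- tempfile()
  for (i in 1:4) {
    write_network(e1[[i]], f1)
    write_network(e2[[i]], f2)
    expect_identical(readLines(f1), readLines(f2))
  }
  e3 <- generate_ensemble(spec, 4, seed = 13)
  expect_false(identical(readLines(write_network(e1[[1]], f1)),
                         readLines(write_network(e3[[1]], f2))))
  expect_length(generate_ensemble(spec, 1, seed = 1), 1)
})
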