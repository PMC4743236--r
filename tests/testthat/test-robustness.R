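test_that("knockout clamps to 0, reversibly, and is idempotent", {
  net <- and_pair_network()
  ko <- knockout(net, "n1")
  expect_equal(net$clamps[["n1"]], NA_integer_)   # original untouched
  for (s in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1)))
    expect_equal(step_network(ko, s)[1], 0L)
  expect_identical(knockout(ko, "n1"), ko)        # idempotent
  ki <- knockin(net, "n2")
  expect_equal(step_network(ki, c(0, 0))[2], 1L)
  restored <- release_clamps(ko)
  expect_identical(step_network(restored, c(1, 1)),
                   step_network(net, c(1, 1)))
  expect_error(knockout(net, "zz"), "unknown gene")
})

test_that("avalanche counts nodes whose attractor pattern changed", {
  net <- and_pair_network()
  # from (1,1): wild type stays at (1,1); KO n1 relaxes to (0,0)
  av <- avalanche(net, knockout(net, "n1"), c(1, 1))
  expect_true(av$resolved)
  expect_equal(av$size, 2)
  expect_setequal(av$affected, c("n1", "n2"))
  # identical networks: avalanche 0
  av0 <- avalanche(net, net, c(1, 0))
  expect_equal(av0$size, 0)
  # no propagation channel: KO of an isolated constant gene
  iso <- regulatory_network(list(
    a = boolean_function(character(), 0L),
    b = boolean_function("b", c(0L, 1L))))
  av1 <- avalanche(iso, knockout(iso, "a"), c(0, 1))
  expect_lte(av1$size, 1)
  expect_equal(av1$size, 0)  # a is already 0 in the wild-type attractor
})

test_that("avalanches are bounded by N and conserved into sensitivity", {
  set.seed(701)
  for (i in 1:10) {
    net <- random_small_net()
    exps <- run_perturbations(net, "knockout", targets = "all",
                              repetitions = 2, seed = i)
    ok <- exps$resolved
    expect_true(all(exps$avalanche[ok] >= 0 & exps$avalanche[ok] <= n_nodes(net)))
    sens <- sensitivity_matrix(net, exps)
    expect_true(all(sens <= nrow(exps)))
    expect_equal(sum(sens), sum(exps$avalanche[ok]))
  }
})

test_that("random target selection is seeded and without replacement", {
  set.seed(702)
  net <- random_small_net(N = 8)
  e1 <- run_perturbations(net, "knockout", targets = 3, seed = 9)
  e2 <- run_perturbations(net, "knockout", targets = 3, seed = 9)
  expect_identical(e1$target, e2$target)
  expect_equal(anyDuplicated(unique(e1$target)), 0)
  expect_length(unique(e1$target), 3)
})

test_that("flip perturbations reuse the flip machinery and score returns", {
  set.seed(703)
  net <- random_small_net(N = 6)
  exps <- run_perturbations(net, "flip", targets = "all", repetitions = 2,
                            seed = 4)
  expect_equal(nrow(exps), 12)
  ok <- exps$resolved
  expect_true(all(exps$avalanche[ok] >= 0))
})

test_that("the knockout screen reports per-gene tree distances", {
  set.seed(704)
  net <- generate_network(generation_spec(12, "fixed-indegree", k = 2,
                                          bias = 0.5), seed = 31)
  atlas <- find_attractors(net, "exhaustive")
  atm <- build_atm(net, atlas)
  target <- build_tree(sweep_thresholds(atm, auto_levels(atm)))
  screen <- ko_tree_screen(net, genes = net$nodes[1:4], target = target,
                           n_samples = 64, seed = 5)
  expect_equal(nrow(screen), 4)
  expect_true(all(screen$status %in% c("ok", "undetermined")))
  expect_true(all(screen$distance[screen$status == "ok"] >= 0))
  # baseline: the wild-type emergent tree matches the target
  expect_equal(attr(screen, "baseline")$distance, 0)
})

test_that("a knockout that leaves the dynamics unchanged gives distance 0", {
  # gene a is constant 0 and regulates nothing: KO is a dynamical no-op
  net <- regulatory_network(list(
    a = boolean_function(character(), 0L),
    b = boolean_function(c("b", "c"), c(0L, 0L, 0L, 1L)),
    c = boolean_function("b", c(0L, 1L))))
  atlas <- find_attractors(net, "exhaustive")
  atm <- build_atm(net, atlas)
  target <- build_tree(sweep_thresholds(atm, auto_levels(atm)))
  screen <- ko_tree_screen(net, genes = "a", target = target,
                           n_samples = 32, seed = 6)
  expect_equal(screen$distance, 0)
})

test_that("classical network measures match hand-computed values", {
  # directed 3-cycle: diameter 2, average path length 1.5
  cyc <- regulatory_network(list(
    a = boolean_function("c", c(0L, 1L)),
    b = boolean_function("a", c(0L, 1L)),
    c = boolean_function("b", c(0L, 1L))))
  ms <- network_measures(cyc)
  expect_equal(ms$diameter, 2)
  expect_equal(ms$average_path_length, 1.5)
  # edgeless graph: clustering 0, diameter flagged undefined
  iso <- regulatory_network(list(
    a = boolean_function(character(), 0L),
    b = boolean_function(character(), 1L)))
  ms2 <- network_measures(iso)
  expect_equal(ms2$clustering_coefficient, 0)
  expect_true(is.na(ms2$diameter))
  # complete undirected skeleton on 4 nodes: clustering 1
  nodes <- c("a", "b", "c", "d")
  fns <- lapply(nodes, function(nd) {
    ins <- setdiff(nodes, nd)
    boolean_function(ins, rep(0L, 2^3))
  })
  names(fns) <- nodes
  ms3 <- network_measures(regulatory_network(fns))
  expect_equal(ms3$clustering_coefficient, 1)
})
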