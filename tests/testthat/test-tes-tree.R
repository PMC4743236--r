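test_that("threshold pruning removes transitions strictly below delta", {
  p <- rbind(c(0.7, 0.3), c(0.0, 1.0))
  expect_equal(threshold_atn(p, 0), p)                # delta = 0 keeps all
  at_half <- threshold_atn(p, 0.5)
  expect_equal(at_half, rbind(c(0.7, 0), c(0, 1)))
  expect_equal(threshold_atn(p, 1), rbind(c(0, 0), c(0, 1)))  # only p = 1
  expect_equal(threshold_atn(p, 0.3)[1, 2], 0.3)      # boundary kept
})

test_that("TESs are the terminal strongly connected components", {
  net <- and_pair_network()
  atm <- build_atm(net, find_attractors(net, "exhaustive"))
  part <- compute_tes(threshold_atn(atm, 0), 0)
  expect_equal(part$tes_list, list(1L))      # {A1}; A2 transient
  expect_equal(part$transient_attractors, 2L)
  # empty edge set: every attractor its own TES
  iso <- compute_tes(matrix(0, 3, 3))
  expect_equal(iso$tes_list, list(1L, 2L, 3L))
  # reciprocal edges fuse into one 2-attractor TES
  rec <- compute_tes(rbind(c(0, 0.5), c(0.5, 0)))
  expect_equal(rec$tes_list, list(c(1L, 2L)))
})

test_that("threshold sweeps partition attractors level by level", {
  p <- rbind(c(0.5, 0.5, 0),
             c(0.4, 0.5, 0.1),
             c(0, 0.2, 0.8))
  sw <- sweep_thresholds(p, c(0, 0.3, 1))
  expect_length(sw, 3)
  expect_equal(sw[[1]]$tes_list, list(c(1L, 2L, 3L)))
  expect_equal(sw[[3]]$tes_list, list(1L, 2L, 3L))
  for (part in sw) {
    ids <- unlist(c(part$tes_list, part$transient_attractors))
    expect_setequal(ids, 1:3)                 # coverage
    expect_equal(anyDuplicated(ids), 0)       # disjointness
  }
  # auto levels: distinct off-diagonal probabilities plus sentinels
  expect_equal(auto_levels(p), c(0, 0.1, 0.2, 0.4, 0.5, 1))
  net <- and_pair_network()
  atm <- build_atm(net, find_attractors(net, "exhaustive"))
  expect_equal(auto_levels(atm), c(0, 1))
  expect_length(sweep_thresholds(p, 0), 1)
})

test_that("TES refinement holds along increasing thresholds", {
  set.seed(601)
  for (i in 1:100) {
    p <- random_atm_matrix(sample(3:8, 1))
    levels <- auto_levels(p)
    sw <- sweep_thresholds(p, levels)
    for (j in seq_along(sw)[-1]) {
      prev <- sw[[j - 1]]
      prev_cover <- lapply(prev$tes_list, function(s)
        sort(unique(c(s, prev$transient_attractors))))
      for (s in sw[[j]]$tes_list)
        expect_true(any(vapply(prev_cover, function(cv) all(s %in% cv),
                               logical(1))))
    }
  }
})

test_that("trees are built by attractor-set inclusion with merging", {
  part <- function(delta, ...) structure(
    list(delta = delta, tes_list = list(...),
         transient_attractors = integer()), class = "tes_partition")
  # minimal split: root with two leaf children
  tr <- build_tree(list(part(0, 1:2), part(1, 1L, 2L)))
  expect_equal(tree_size(tr), 3)
  expect_equal(tree_depth(tr), 1)
  # unchanged TES persists without a unary chain
  tr2 <- build_tree(list(part(0, 1:2), part(0.5, 1:2), part(1, 1L, 2L)))
  expect_equal(tree_size(tr2), 3)
  # single attractor, any sweep: single-node tree
  tr3 <- build_tree(list(part(0, 1L), part(1, 1L)))
  expect_equal(tree_size(tr3), 1)
  # root to 7 leaves across a progressive split
  tr4 <- build_tree(list(part(0, 1:8), part(0.5, 1:4, 5:8),
                         part(1, 1L, 2L, 3L, 4L, 5L, 6L, c(7L, 8L))))
  expect_equal(tree_depth(tr4), 2)
  expect_equal(sum(vapply(seq_len(tree_size(tr4)), function(i)
    sum(!is.na(tr4$parent) & tr4$parent == i) == 0, logical(1))), 7)
})

test_that("non-nested TESs attach by maximal overlap or open a forest", {
  part <- function(delta, tes, transient = integer()) structure(
    list(delta = delta, tes_list = tes, transient_attractors = transient),
    class = "tes_partition")
  # attractor 3 transient at level 1, own TES at level 2
  tr <- build_tree(list(part(0, list(1:2), 3L),
                        part(1, list(1L, 2L, 3L))))
  expect_true(isTRUE(attr(tr, "virtual_root")) ||
                any(grepl("no overlapping parent", attr(tr, "notes"))))
})

test_that("tree distance is the L1 gap between shape tables", {
  h <- tree_from_edges(c("r", "r"), c("a", "b"))
  t3 <- tree_from_edges(c("r", "r", "r"), c("a", "b", "c"))
  expect_equal(tree_distance(h, h), 0)
  expect_equal(tree_distance(h, t3), 3)
  expect_equal(tree_distance(t3, h), 3)       # symmetry
  # distance works on shape tables directly
  expect_equal(tree_distance(shape_table(h), shape_table(t3)), 3)
})

test_that("tree distance matches the naive oracle and is a pseudometric", {
  set.seed(602)
  trees <- replicate(60, random_tree(sample(2:20, 1)), simplify = FALSE)
  # oracle equality on random pairs
  for (i in 1:300) {
    pair <- sample(length(trees), 2)
    expect_equal(tree_distance(trees[[pair[1]]], trees[[pair[2]]]),
                 oracle_tree_distance(trees[[pair[1]]], trees[[pair[2]]]))
  }
  # identity on shapes, symmetry, triangle inequality
  for (i in 1:100) {
    abc <- sample(length(trees), 3)
    a <- trees[[abc[1]]]; b <- trees[[abc[2]]]; c <- trees[[abc[3]]]
    expect_equal(tree_distance(a, a), 0)
    expect_equal(tree_distance(a, b), tree_distance(b, a))
    expect_lte(tree_distance(a, c),
               tree_distance(a, b) + tree_distance(b, c))
  }
})

test_that("representative tree is the modal shape over threshold combos", {
  net <- and_pair_network()
  atm <- build_atm(net, find_attractors(net, "exhaustive"))
  # single off-diagonal probability value: a unique possible tree
  rep1 <- representative_tree(atm, depth = 2)
  expect_equal(rep1$frequency, 1)
  # depth 1: always the delta = 0 tree (one TES node)
  rep0 <- representative_tree(atm, depth = 1)
  expect_equal(tree_size(rep0$tree), 1)
  # frequency is stable under resampling on a fixed ATM
  set.seed(603)
  p <- random_atm_matrix(6)
  f1 <- representative_tree(p, 3, n_threshold_samples = 200, seed = 1,
                            enumerate_cap = 0)$frequency
  f2 <- representative_tree(p, 3, n_threshold_samples = 200, seed = 2,
                            enumerate_cap = 0)$frequency
  expect_lt(abs(f1 - f2), 0.25)
})

test_that("ensemble matching flags networks within tolerance", {
  net <- and_pair_network()
  atm <- build_atm(net, find_attractors(net, "exhaustive"))
  own <- best_tree_match(atm, hematopoietic_tree(), seed = 1)
  expect_true(own$distance > 0)
  # a network whose own emergent tree is the target matches at d = 0
  target <- build_tree(sweep_thresholds(atm, c(0, 1)))
  report <- match_ensemble(list(net, net), target, tolerance = 0,
                           n_samples = 16, seed = 2)
  expect_true(all(report$matched))
  expect_equal(report$best_distance, c(0, 0))
  # infinite tolerance matches every resolved network
  report2 <- match_ensemble(list(net), hematopoietic_tree(),
                            tolerance = Inf, n_samples = 16, seed = 3)
  expect_true(all(report2$matched))
})
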