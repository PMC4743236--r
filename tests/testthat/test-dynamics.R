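test_that("worked examples: toggle cycle and AND pair", {
  a <- find_attractors(toggle_cycle_network(), "exhaustive")
  expect_equal(length(a$attractors), 1)
  expect_equal(a$attractors[[1]]$length, 4)
  expect_equal(a$attractors[[1]]$basin, 4)

  b <- find_attractors(and_pair_network(), "exhaustive")
  expect_equal(length(b$attractors), 2)
  expect_equal(vapply(b$attractors, `[[`, integer(1), "length"), c(1, 1))
  expect_equal(sort(vapply(b$attractors, `[[`, numeric(1), "basin")),
               c(1, 3))
  # canonical sorting puts (0,0) first
  expect_equal(unname(b$attractors[[1]]$states[1, ]), c(0, 0))
  expect_equal(b$attractors[[1]]$basin, 3)
})

test_that("exhaustive search equals the brute-force oracle on random nets", {
  set.seed(401)
  n_nets <- 60  # complemented by the larger acceptance-suite run
  for (i in seq_len(n_nets)) {
    net <- random_small_net()
    atlas <- find_attractors(net, "exhaustive")
    oa <- oracle_attractors(net)
    expect_equal(length(atlas$attractors), length(oa))
    got <- lapply(atlas$attractors, function(a) {
      states <- lapply(seq_len(nrow(a$states)), function(r) a$states[r, ])
      list(key = oracle_cycle_key(states), length = a$length,
           basin = a$basin)
    })
    got_keys <- vapply(got, `[[`, character(1), "key")
    expect_setequal(got_keys, names(oa))
    for (g in got) {
      expect_equal(g$length, oa[[g$key]]$length)
      expect_equal(g$basin, oa[[g$key]]$basin)
    }
    expect_equal(atlas$unresolved_count, 0)
  }
})

test_that("sampling the full state set without replacement matches exhaustive", {
  set.seed(402)
  for (i in 1:10) {
    net <- random_small_net(N = sample(3:6, 1))
    N <- n_nodes(net)
    ex <- find_attractors(net, "exhaustive")
    sm <- find_attractors(net, "sampled", n_samples = 2^N, seed = 7,
                          replace = FALSE)
    expect_equal(length(sm$attractors), length(ex$attractors))
    for (j in seq_along(ex$attractors)) {
      expect_identical(sm$attractors[[j]]$states, ex$attractors[[j]]$states)
      expect_equal(sm$attractors[[j]]$basin, ex$attractors[[j]]$basin)
    }
  }
})

test_that("basins plus unresolved account for every initial state", {
  set.seed(403)
  for (i in 1:10) {
    net <- random_small_net()
    atlas <- find_attractors(net, "sampled", n_samples = 200, seed = i,
                             max_steps = 30)
    basins <- vapply(atlas$attractors, `[[`, numeric(1), "basin")
    expect_equal(sum(basins) + atlas$unresolved_count, 200)
  }
})

test_that("growing the sample never loses attractors (seed-prefix sampling)", {
  set.seed(404)
  net <- random_small_net(N = 8)
  keys <- function(atlas) vapply(atlas$attractors, function(a)
    paste(a$states[1, ], collapse = ""), character(1))
  small <- find_attractors(net, "sampled", n_samples = 50, seed = 5)
  large <- find_attractors(net, "sampled", n_samples = 200, seed = 5)
  expect_true(all(keys(small) %in% keys(large)))
})

test_that("attractor set is invariant under node reordering", {
  set.seed(405)
  for (i in 1:8) {
    net <- random_small_net()
    N <- n_nodes(net)
    perm <- sample(N)
    pnet <- permute_network(net, perm)
    a1 <- find_attractors(net, "exhaustive")
    a2 <- find_attractors(pnet, "exhaustive")
    expect_equal(length(a1$attractors), length(a2$attractors))
    # lengths and basins agree as multisets
    sig <- function(a) sort(paste(
      vapply(a$attractors, `[[`, integer(1), "length"),
      vapply(a$attractors, `[[`, numeric(1), "basin")))
    expect_equal(sig(a1), sig(a2))
  }
})

test_that("canonicalization is rotation-invariant and verifies closure", {
  cyc <- rbind(c(1, 0), c(0, 0), c(0, 1), c(1, 1))
  canon <- canonicalize_cycle(cyc)
  expect_equal(unname(canon[1, ]), c(0, 0))
  rot <- cyc[c(3, 4, 1, 2), ]
  expect_identical(canonicalize_cycle(rot), canon)
  fp <- matrix(c(1L, 1L), 1)
  expect_identical(unname(canonicalize_cycle(fp)), fp)
  expect_error(canonicalize_cycle(rbind(c(0, 0), c(0, 0))), "distinct")
  net <- toggle_cycle_network()
  expect_error(canonicalize_cycle(rbind(c(0, 0), c(1, 1)), net),
               "not a closed orbit")
})

test_that("attractor statistics report lengths, basins and frozen nodes", {
  b <- find_attractors(and_pair_network(), "exhaustive")
  st <- attractor_statistics(b)
  expect_equal(unname(st$length_histogram["1"]), 2L)
  expect_equal(st$basin_table$basin, c(3, 1))
  expect_equal(st$frozen_proportion, c(1, 1))  # fixed points freeze all
  a <- find_attractors(toggle_cycle_network(), "exhaustive")
  st2 <- attractor_statistics(a)
  expect_equal(st2$frozen_proportion, 0)       # both nodes oscillate
  expect_equal(st2$basin_table$reachability, 1)
})

test_that("exhaustive mode is refused above the cap with guidance", {
  net <- generate_network(generation_spec(25, "fixed-indegree", k = 2),
                          seed = 1)
  expect_error(find_attractors(net, "exhaustive"), "sampled")
})

test_that("unresolved trajectories are counted, not dropped", {
  # a 4-cycle cannot close within 1 step from outside
  net <- toggle_cycle_network()
  atlas <- find_attractors(net, "sampled", n_samples = 10, seed = 1,
                           max_steps = 1)
  expect_equal(sum(vapply(atlas$attractors, `[[`, numeric(1), "basin")) +
                 atlas$unresolved_count, 10)
  expect_gt(atlas$unresolved_count, 0)
})
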