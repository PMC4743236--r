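# Independent plain-R oracles used to cross-check the C++ engine: a direct
# step function, brute-force attractor enumeration over the full state
# space, a triple-loop flip/ATM re-implementation and a naive two-pass
# tree-distance. Deliberately simple and slow.

oracle_step <- function(net, s) {
  out <- integer(length(net$nodes))
  for (i in seq_along(net$nodes)) {
    cl <- net$clamps[i]
    if (!is.na(cl)) { out[i] <- cl; next }
    f <- net$functions[[i]]
    v <- s[match(f$inputs, net$nodes)]
    row <- 0L
    for (b in v) row <- row * 2L + b
    out[i] <- f$table[row + 1L]
  }
  out
}

oracle_key <- function(s) paste(s, collapse = "")

# canonical cycle key: rotation starting at the smallest state key
oracle_cycle_key <- function(states) {
  keys <- vapply(states, oracle_key, character(1))
  start <- which(keys == min(keys))[1]
  n <- length(keys)
  paste(keys[((start - 1 + seq_len(n) - 1) %% n) + 1], collapse = "|")
}

# full-state-space brute force; returns per-attractor canonical key,
# length and basin, keyed by canonical key
oracle_attractors <- function(net) {
  N <- length(net$nodes)
  attr_of_state <- new.env(parent = emptyenv())
  attractors <- list()
  for (code in seq_len(2^N) - 1) {
    s <- decode_state(code, N)
    path <- list()
    seen <- new.env(parent = emptyenv())
    repeat {
      k <- oracle_key(s)
      hit <- get0(k, envir = attr_of_state)
      if (!is.null(hit)) { dest <- hit; break }
      pos <- get0(k, envir = seen)
      if (!is.null(pos)) {
        cyc <- path[pos:length(path)]
        ck <- oracle_cycle_key(cyc)
        if (is.null(attractors[[ck]]))
          attractors[[ck]] <- list(states = cyc, length = length(cyc),
                                   basin = 0L)
        dest <- ck
        break
      }
      assign(k, length(path) + 1L, envir = seen)
      path[[length(path) + 1L]] <- s
      s <- oracle_step(net, s)
    }
    for (p in path) assign(oracle_key(p), dest, envir = attr_of_state)
    attractors[[dest]]$basin <- attractors[[dest]]$basin + 1L
  }
  attractors
}

# relax a state to an attractor id given a state->id lookup
oracle_relax <- function(net, s, state2id, max_steps = 10000) {
  for (t in 0:max_steps) {
    id <- get0(oracle_key(s), envir = state2id)
    if (!is.null(id)) return(id)
    s <- oracle_step(net, s)
  }
  NA_integer_
}

# triple-loop ATM: attractors in (length, canonical key) order, duration-1
# flips of every node at every phase
oracle_atm <- function(net) {
  oa <- oracle_attractors(net)
  ord <- order(vapply(oa, `[[`, integer(1), "length"), names(oa))
  oa <- oa[ord]
  state2id <- new.env(parent = emptyenv())
  for (i in seq_along(oa))
    for (s in oa[[i]]$states) assign(oracle_key(s), i, envir = state2id)
  K <- length(oa)
  counts <- matrix(0L, K, K)
  for (a in seq_len(K)) {
    for (s in oa[[a]]$states) {
      for (i in seq_along(net$nodes)) {
        held <- clamp_nodes(net, net$nodes[i], 1L - s[i])
        rel <- oracle_step(held, s)
        dest <- oracle_relax(net, rel, state2id)
        counts[a, dest] <- counts[a, dest] + 1L
      }
    }
  }
  counts
}

# naive two-pass tree distance: materialize n_x(k, l) by explicit loops
oracle_tree_distance <- function(t1, t2) {
  nkl <- function(tree, k, l) {
    cnt <- 0L
    for (i in seq_along(tree$labels)) {
      if (tree$level[i] != l) next
      kids <- sum(!is.na(tree$parent) & tree$parent == i)
      if (kids == k) cnt <- cnt + 1L
    }
    cnt
  }
  max_depth <- max(max(t1$level), max(t2$level))
  max_kids <- 0L
  for (tr in list(t1, t2))
    for (i in seq_along(tr$labels))
      max_kids <- max(max_kids, sum(!is.na(tr$parent) & tr$parent == i))
  d <- 0L
  for (l in 0:max_depth)
    for (k in 0:max_kids)
      d <- d + abs(nkl(t1, k, l) - nkl(t2, k, l))
  d
}

# random rooted tree with n nodes (node i's parent drawn among 1..i-1)
random_tree <- function(n) {
  parent <- c(NA_integer_,
              if (n > 1) vapply(2:n, function(i)
                sample.int(i - 1L, 1L), integer(1)))
  differentiation_tree(paste0("n", seq_len(n)), parent)
}

# random small network in a random regime
random_small_net <- function(N = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(N)) N <- sample(3:10, 1)
  regime <- regime_preset(sample(c("ordered", "critical", "chaotic"), 1))
  k <- min(regime$k, N - 1)
  spec <- generation_spec(N, topology = "fixed-indegree", k = k,
                          function_scheme = "bias-random",
                          bias = regime$bias)
  generate_network(spec)
}

# random row-stochastic ATM-like matrix with a few zero entries
random_atm_matrix <- function(K) {
  m <- matrix(runif(K * K), K, K)
  m[m < 0.4] <- 0
  diag(m)[rowSums(m) == 0] <- 1
  m / rowSums(m)
}
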