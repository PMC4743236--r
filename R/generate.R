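# Random generation of NRBN ensembles: topology schemes (fixed in-degree,
# Erdos-Renyi, preferential attachment, power-law in-degree, small-world)
# and function schemes (bias-based random, canalyzing, random logic).

#' Dynamical-regime presets
#'
#' Named structural presets pairing mean connectivity K with function bias
#' b: `ordered` (K=2, b=0.3), `critical` (K=2, b=0.5), `chaotic` (K=3,
#' b=0.5) and the lower-bias chaotic variant `chaotic-low-bias` (K=3,
#' b=0.3).
#'
#' @param name preset name.
#' @return list with elements `k` and `bias`.
#' @export
regime_preset <- function(name = c("ordered", "critical", "chaotic",
                                   "chaotic-low-bias")) {
  switch(match.arg(name),
         "ordered" = list(k = 2, bias = 0.3),
         "critical" = list(k = 2, bias = 0.5),
         "chaotic" = list(k = 3, bias = 0.5),
         "chaotic-low-bias" = list(k = 3, bias = 0.3))
}

#' Specification for random network generation
#'
#' @param n_nodes number of genes.
#' @param topology one of `"fixed-indegree"`, `"erdos-renyi"`,
#'   `"barabasi-preferential"`, `"power-law"`, `"watts-strogatz"`.
#' @param n_edges target edge count (ER); exactly this many edges are
#'   placed. Alternative to `k`.
#' @param k mean in-degree; for `fixed-indegree` every node gets exactly
#'   `k` regulators, for ER it sets `n_edges = round(k * n_nodes)`, for
#'   preferential attachment it is the per-node attachment count, for
#'   `watts-strogatz` the lattice in-degree.
#' @param power_law_exponent exponent of the discrete in-degree power law
#'   (`power-law` topology); per-node in-degrees are sampled from
#'   `P(d) ~ d^-exponent` truncated to `[1, n_nodes - 1]`, so the total
#'   edge count is stochastic under this mode.
#' @param rewire_prob per-edge source rewiring probability
#'   (`watts-strogatz`); 0 returns the directed ring lattice exactly.
#' @param function_scheme one of `"bias-random"`, `"canalyzing"`,
#'   `"logic"`.
#' @param bias probability that a random truth-table entry is 1.
#' @param allow_self_loops permit self-regulation (fixed-indegree and ER
#'   only; default off).
#' @return a `generation_spec` list, validated.
#' @export
generation_spec <- function(n_nodes,
                            topology = c("erdos-renyi", "fixed-indegree",
                                         "barabasi-preferential",
                                         "power-law", "watts-strogatz"),
                            n_edges = NULL, k = NULL,
                            power_law_exponent = 2.5,
                            rewire_prob = 0.1,
                            function_scheme = c("bias-random", "canalyzing",
                                                "logic"),
                            bias = 0.5, allow_self_loops = FALSE) {
  topology <- match.arg(topology)
  function_scheme <- match.arg(function_scheme)
  n_nodes <- as.integer(n_nodes)
  stopifnot(n_nodes >= 1, bias >= 0, bias <= 1)
  if (is.null(n_edges) && is.null(k) && topology %in%
      c("erdos-renyi", "fixed-indegree", "barabasi-preferential",
        "watts-strogatz"))
    stop("supply `n_edges` or `k` for topology ", topology)
  if (!is.null(k) && k > n_nodes - 1L + allow_self_loops)
    stop("infeasible: k = ", k, " exceeds the maximum in-degree")
  max_edges <- n_nodes * (n_nodes - 1L) + if (allow_self_loops) n_nodes else 0L
  if (!is.null(n_edges) && n_edges > max_edges)
    stop("infeasible: ", n_edges, " edges exceed the maximum ", max_edges)
  structure(list(n_nodes = n_nodes, topology = topology,
                 n_edges = if (is.null(n_edges)) NULL else as.integer(n_edges),
                 k = k, power_law_exponent = power_law_exponent,
                 rewire_prob = rewire_prob,
                 function_scheme = function_scheme, bias = bias,
                 allow_self_loops = allow_self_loops),
            class = "generation_spec")
}

# sample() without the scalar-x surprise
safe_sample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

node_names <- function(n, prefix = "G") {
  sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))
}

# Build an nrbn_network from an in-edge list (functions unset).
network_from_in_edges <- function(nodes, in_lists, core = TRUE) {
  fns <- vector("list", length(nodes))
  names(fns) <- nodes
  net <- structure(list(nodes = nodes, functions = fns,
                        core = setNames(rep_len(as.logical(core),
                                                length(nodes)), nodes),
                        clamps = setNames(rep(NA_integer_, length(nodes)),
                                          nodes)),
                   class = "nrbn_network")
  attr(net, "in_lists") <- in_lists  # regulators per node, unordered draw order
  net
}

#' Generate a random topology
#'
#' Places directed edges according to the topology scheme of a
#' [generation_spec()]; functions are left unset (use
#' [generate_functions()] next, or [generate_network()] for both at
#' once). Deterministic for a fixed RNG seed.
#'
#' @param spec a [generation_spec()].
#' @param seed optional integer seed (`set.seed` is called when given).
#' @return an `nrbn_network` with functions unset; the per-node regulator
#'   draw order is kept in `attr(net, "in_lists")`.
#' @export
generate_topology <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "generation_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_nodes
  nodes <- node_names(n)
  in_lists <- switch(spec$topology,
    "fixed-indegree" = topology_fixed_indegree(n, spec$k, spec$allow_self_loops),
    "erdos-renyi" = topology_er(n, er_edge_count(spec), spec$allow_self_loops),
    "barabasi-preferential" = topology_ba(n, spec),
    "power-law" = topology_power_law(n, spec$power_law_exponent),
    "watts-strogatz" = topology_ws(n, spec$k, spec$rewire_prob))
  network_from_in_edges(nodes, lapply(in_lists, function(i) nodes[i]))
}

er_edge_count <- function(spec) {
  if (!is.null(spec$n_edges)) spec$n_edges else as.integer(round(spec$k * spec$n_nodes))
}

# each node gets exactly k regulators drawn uniformly
topology_fixed_indegree <- function(n, k, self_loops) {
  stopifnot(!is.null(k), k == as.integer(k))
  lapply(seq_len(n), function(i) {
    pool <- if (self_loops) seq_len(n) else setdiff(seq_len(n), i)
    if (k > length(pool)) stop("infeasible: k exceeds available regulators")
    safe_sample(pool, k)
  })
}

# exactly m ordered pairs drawn uniformly without replacement
topology_er <- function(n, m, self_loops) {
  max_edges <- n * (n - 1L) + if (self_loops) n else 0L
  if (m > max_edges) stop("infeasible: too many edges requested")
  # enumerate ordered pairs by code: from = code %/% n, to = code %% n (0-based)
  codes <- sample.int(n * n, n * n) - 1L
  from <- codes %/% n + 1L
  to <- codes %% n + 1L
  keep <- if (self_loops) rep(TRUE, length(codes)) else from != to
  from <- from[keep][seq_len(m)]
  to <- to[keep][seq_len(m)]
  split(from, factor(to, levels = seq_len(n)))
}

# undirected preferential-attachment skeleton, each edge oriented
# uniformly at random
topology_ba <- function(n, spec) {
  m_per <- if (!is.null(spec$k)) max(1L, as.integer(round(spec$k / 2)))
           else max(1L, as.integer(round(spec$n_edges / spec$n_nodes / 2)))
  g <- igraph::sample_pa(n, power = 1, m = m_per, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  flip <- runif(nrow(el)) < 0.5
  from <- ifelse(flip, el[, 2], el[, 1])
  to <- ifelse(flip, el[, 1], el[, 2])
  # drop duplicate ordered pairs (skeleton may yield none, but be safe)
  keep <- !duplicated(paste(from, to))
  split(as.integer(from[keep]), factor(as.integer(to[keep]), levels = seq_len(n)))
}

# per-node in-degree sampled from a truncated discrete power law
topology_power_law <- function(n, exponent) {
  dmax <- n - 1L
  p <- (1:dmax)^(-exponent)
  degs <- sample.int(dmax, n, replace = TRUE, prob = p)
  lapply(seq_len(n), function(i) safe_sample(setdiff(seq_len(n), i), degs[i]))
}

# directed ring lattice: node i receives edges from its k predecessors;
# each edge's source rewired with probability p. p = 0 is the exact lattice.
topology_ws <- function(n, k, p) {
  stopifnot(!is.null(k), k < n)
  lapply(seq_len(n), function(i) {
    src <- ((i - seq_len(k) - 1L) %% n) + 1L  # i-1, i-2, ..., i-k (mod n)
    if (p > 0) {
      rew <- runif(k) < p
      for (j in which(rew)) {
        pool <- setdiff(seq_len(n), c(i, src))
        if (length(pool)) src[j] <- safe_sample(pool, 1L)
      }
    }
    src
  })
}

#' Generate Boolean functions for a wired network
#'
#' Assigns a Boolean function to every node according to the scheme:
#' `bias-random` draws each truth-table bit independently with
#' probability `bias` of being 1; `canalyzing` designates one input/value
#' pair that alone forces the output and fills the remaining rows
#' bias-randomly; `logic` builds random AND/OR/NOT expressions over the
#' regulators and compiles them. Nodes with zero regulators become
#' bias-random constants (for `canalyzing` this fallback is messaged).
#'
#' @param net an `nrbn_network` (functions may be unset).
#' @param scheme one of `"bias-random"`, `"canalyzing"`, `"logic"`.
#' @param bias probability of a 1 output.
#' @param seed optional integer seed.
#' @param canalyzing_value optional forced canalyzing behaviour: a list
#'   with `input_value` and `output` (e.g. `list(input_value = 1, output
#'   = 0)` for a canalyzing inhibitor, the standard Boolean reading of a
#'   miRNA silencing its target); by default both are drawn at random per
#'   node.
#' @return the network with all functions set.
#' @export
generate_functions <- function(net, scheme = c("bias-random", "canalyzing",
                                               "logic"),
                               bias = 0.5, seed = NULL,
                               canalyzing_value = NULL) {
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  in_lists <- attr(net, "in_lists")
  if (is.null(in_lists))
    in_lists <- lapply(net$functions, function(f) if (is.null(f)) character() else f$inputs)
  fns <- vector("list", length(net$nodes))
  names(fns) <- net$nodes
  fell_back <- character()
  for (i in seq_along(net$nodes)) {
    inputs <- as.character(in_lists[[i]])
    k <- length(inputs)
    if (scheme == "bias-random" || k == 0L) {
      if (scheme == "canalyzing" && k == 0L)
        fell_back <- c(fell_back, net$nodes[i])
      tab <- rbinom(2L^k, 1L, bias)
      fns[[i]] <- boolean_function(inputs, tab)
    } else if (scheme == "canalyzing") {
      can_in <- sample.int(k, 1L)
      can_val <- if (is.null(canalyzing_value)) sample(0:1, 1L) else canalyzing_value$input_value
      can_out <- if (is.null(canalyzing_value)) sample(0:1, 1L) else canalyzing_value$output
      tab <- rbinom(2L^k, 1L, bias)
      rows <- vapply(seq_len(2L^k) - 1L,
                     function(r) bits_of_row(r, k)[can_in] == can_val,
                     logical(1))
      tab[rows] <- can_out
      f <- boolean_function(inputs, tab)
      attr(f, "canalyzing") <- list(input = inputs[can_in],
                                    input_value = can_val, output = can_out)
      fns[[i]] <- f
    } else {  # logic
      expr <- random_logic_expression(inputs)
      fns[[i]] <- boolean_function(inputs, expr = expr)
    }
  }
  if (length(fell_back))
    message("canalyzing scheme: constant fallback for 0-input node(s): ",
            paste(fell_back, collapse = ", "))
  out <- regulatory_network(fns, core = net$core,
                            clamps = {
                              cl <- net$clamps[!is.na(net$clamps)]
                              if (length(cl)) cl else NULL
                            })
  out
}

#' Generate a complete random network
#'
#' Convenience wrapper: [generate_topology()] followed by
#' [generate_functions()] under one seed.
#'
#' @param spec a [generation_spec()].
#' @param seed optional integer seed.
#' @return an `nrbn_network` with functions set.
#' @export
generate_network <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  net <- generate_topology(spec)
  generate_functions(net, spec$function_scheme, spec$bias)
}

#' Generate an ensemble of networks
#'
#' Produces `count` independent networks from one master seed; per-network
#' seeds are derived from it, so the ensemble is reproducible and each
#' member can be regenerated in isolation.
#'
#' @param spec a [generation_spec()] or [augmentation_spec()]; in the
#'   latter case `core` must be given and each member augments it.
#' @param count ensemble size (>= 1).
#' @param seed master integer seed.
#' @param core core network for augmentation specs.
#' @return list of `nrbn_network` objects; per-network seeds are attached
#'   as `attr(, "seeds")`.
#' @export
generate_ensemble <- function(spec, count, seed, core = NULL) {
  stopifnot(count >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, count)
  out <- if (inherits(spec, "augmentation_spec")) {
    stopifnot(!is.null(core))
    lapply(seeds, function(s) augment(core, spec, seed = s))
  } else {
    lapply(seeds, function(s) generate_network(spec, seed = s))
  }
  attr(out, "seeds") <- seeds
  out
}
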