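# Augmentation: extend a fixed topological + functional core with randomly
# generated nodes and edges up to a target size. The core's nodes, edges
# and (up to input-extension) functions are preserved; ensembles of
# augmented networks share the core and differ in the random portion.

#' Specification for core augmentation
#'
#' @param n_nodes target node count N (> core size n).
#' @param n_edges target edge count M (>= core edge count m). Exactly
#'   `M - m` new edges are placed; no new edge may run core -> core, so
#'   restricting the result to the core reproduces the core edge set.
#' @param topology placement scheme for the new edges: `"erdos-renyi"`
#'   (uniform over admissible ordered pairs), `"fixed-indegree"` (each new
#'   node first receives `k` regulators, the remainder uniform),
#'   `"barabasi-preferential"` (endpoints sampled proportionally to
#'   degree + 1) or `"power-law"` (per-new-node in-degrees sampled from a
#'   truncated power law, then trimmed/topped up to hit `M`).
#'   `"watts-strogatz"` is not supported for augmentation.
#' @param function_scheme,bias function generation for new nodes, as in
#'   [generation_spec()].
#' @param core_extension_policy how a core node's function absorbs newly
#'   attached inputs: `"duplicate-then-bias"` (default) replicates the
#'   table over the new-input combinations, then resamples every row in
#'   which at least one new input is active with probability `bias` — so
#'   new edges are functional but the all-new-inputs-off behaviour equals
#'   the original core function exactly; `"silent"` is pure duplication
#'   (new inputs non-functional).
#' @param protect_core forbid new in-edges on core nodes entirely.
#' @param power_law_exponent exponent for the `"power-law"` placement.
#' @param k per-new-node in-degree for `"fixed-indegree"`.
#' @return an `augmentation_spec` list.
#' @export
augmentation_spec <- function(n_nodes, n_edges,
                              topology = c("erdos-renyi", "fixed-indegree",
                                           "barabasi-preferential",
                                           "power-law", "watts-strogatz"),
                              function_scheme = c("bias-random", "canalyzing",
                                                  "logic"),
                              bias = 0.5,
                              core_extension_policy = c("duplicate-then-bias",
                                                        "silent"),
                              protect_core = FALSE,
                              power_law_exponent = 2.5, k = NULL) {
  topology <- match.arg(topology)
  if (topology == "watts-strogatz")
    stop("watts-strogatz placement is not supported for augmentation; ",
         "use erdos-renyi, fixed-indegree, barabasi-preferential or power-law")
  structure(list(n_nodes = as.integer(n_nodes), n_edges = as.integer(n_edges),
                 topology = topology,
                 function_scheme = match.arg(function_scheme), bias = bias,
                 core_extension_policy = match.arg(core_extension_policy),
                 protect_core = protect_core,
                 power_law_exponent = power_law_exponent, k = k),
            class = "augmentation_spec")
}

#' Augment a core network to a target size
#'
#' Adds `N - n` new nodes and `M - m` new edges to a fully characterized
#' core. Every core node, edge and function is preserved; core functions
#' that gain inputs are extended according to the spec's
#' `core_extension_policy` (the core behaviour with all new inputs off is
#' always retained exactly). New nodes receive functions from the spec's
#' function scheme.
#'
#' @param core an `nrbn_network` with functions set.
#' @param spec an [augmentation_spec()].
#' @param seed optional integer seed.
#' @return an `nrbn_network` with `spec$n_nodes` nodes and `spec$n_edges`
#'   edges; new nodes are flagged non-core.
#' @export
augment <- function(core, spec, seed = NULL) {
  stopifnot(inherits(core, "nrbn_network"), inherits(spec, "augmentation_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(core$nodes)
  m <- n_edges(core)
  N <- spec$n_nodes
  M <- spec$n_edges
  if (N < n) stop("target node count ", N, " below core size ", n)
  if (M < m) stop("target edge count ", M, " below core edge count ", m)
  if (N == n && M == m) return(core)
  if (N == n && M > m)
    stop("cannot add edges without new nodes: new core->core edges are not allowed")

  new_nodes <- setdiff(node_names(N, "A"), core$nodes)[seq_len(N - n)]
  nodes <- c(core$nodes, new_nodes)
  is_new <- c(rep(FALSE, n), rep(TRUE, N - n))

  existing <- network_edges(core)
  new_edges <- place_new_edges(nodes, is_new, existing, M - m, spec)

  # assemble regulator lists: core inputs first, then the new ones
  added_in <- split(new_edges$from, factor(new_edges$to, levels = nodes))
  fns <- vector("list", N)
  names(fns) <- nodes
  for (i in seq_along(nodes)) {
    nd <- nodes[i]
    extra <- as.character(added_in[[nd]])
    if (!is_new[i]) {
      f <- core$functions[[nd]]
      fns[[nd]] <- if (length(extra))
        extend_function(f, extra, spec$core_extension_policy, spec$bias)
      else f
    } else {
      fns[[nd]] <- NULL  # generated below
    }
  }
  skeleton <- network_from_in_edges(nodes, c(
    lapply(seq_len(n), function(i) fns[[i]]$inputs),
    lapply(added_in[new_nodes], as.character)),
    core = !is_new)
  filled <- generate_functions(skeleton, spec$function_scheme, spec$bias)
  # keep the (extended) core functions
  for (nd in core$nodes) filled$functions[[nd]] <- fns[[nd]]
  out <- regulatory_network(filled$functions, core = !is_new)
  out
}

# choose M_add new ordered pairs; admissible = not existing, not core->core,
# not self, and (optionally) not targeting core nodes
place_new_edges <- function(nodes, is_new, existing, m_add, spec) {
  N <- length(nodes)
  if (m_add == 0L)
    return(data.frame(from = character(), to = character()))
  existing_key <- paste(existing$from, existing$to)
  admissible <- function(from, to) {
    ok <- from != to & !(paste(nodes[from], nodes[to]) %in% existing_key) &
      !(!is_new[from] & !is_new[to])
    if (spec$protect_core) ok <- ok & is_new[to]
    ok
  }
  pick_uniform <- function(k_pick, taken_key) {
    # rejection sampling with a deterministic fallback enumeration
    out_from <- integer(0); out_to <- integer(0)
    tries <- 0L
    while (length(out_from) < k_pick && tries < 50L * k_pick + 200L) {
      tries <- tries + 1L
      f <- sample.int(N, 1L); t <- sample.int(N, 1L)
      key <- paste(f, t)
      if (admissible(f, t) && !(key %in% taken_key)) {
        out_from <- c(out_from, f); out_to <- c(out_to, t)
        taken_key <- c(taken_key, key)
      }
    }
    if (length(out_from) < k_pick) {
      all_pairs <- expand.grid(from = seq_len(N), to = seq_len(N))
      ok <- admissible(all_pairs$from, all_pairs$to) &
        !(paste(all_pairs$from, all_pairs$to) %in% taken_key)
      pool <- which(ok)
      need <- k_pick - length(out_from)
      if (length(pool) < need)
        stop("infeasible: cannot place ", need, " more new edges")
      sel <- safe_sample(pool, need)
      out_from <- c(out_from, all_pairs$from[sel])
      out_to <- c(out_to, all_pairs$to[sel])
    }
    list(from = out_from, to = out_to)
  }

  from <- integer(0); to <- integer(0)
  key_of <- function() paste(from, to)

  if (spec$topology == "fixed-indegree") {
    k <- if (is.null(spec$k)) max(1L, as.integer(round(m_add / sum(is_new))))
         else as.integer(spec$k)
    for (i in which(is_new)) {
      budget <- min(k, m_add - length(from))
      if (budget <= 0) break
      pool <- which(vapply(seq_len(N), function(f)
        admissible(f, i) && !(paste(f, i) %in% key_of()), logical(1)))
      sel <- safe_sample(pool, min(budget, length(pool)))
      from <- c(from, sel); to <- c(to, rep(i, length(sel)))
    }
    if (length(from) < m_add) {
      extra <- pick_uniform(m_add - length(from), key_of())
      from <- c(from, extra$from); to <- c(to, extra$to)
    }
  } else if (spec$topology == "power-law") {
    dmax <- N - 1L
    p <- (1:dmax)^(-spec$power_law_exponent)
    degs <- sample.int(dmax, sum(is_new), replace = TRUE, prob = p)
    for (j in seq_along(which(is_new))) {
      i <- which(is_new)[j]
      budget <- min(degs[j], m_add - length(from))
      if (budget <= 0) break
      pool <- which(vapply(seq_len(N), function(f)
        admissible(f, i) && !(paste(f, i) %in% key_of()), logical(1)))
      sel <- safe_sample(pool, min(budget, length(pool)))
      from <- c(from, sel); to <- c(to, rep(i, length(sel)))
    }
    if (length(from) < m_add) {
      extra <- pick_uniform(m_add - length(from), key_of())
      from <- c(from, extra$from); to <- c(to, extra$to)
    }
  } else if (spec$topology == "barabasi-preferential") {
    deg <- tabulate(match(c(existing$from, existing$to), nodes), N)
    while (length(from) < m_add) {
      f <- safe_sample(seq_len(N), 1L, prob = deg + 1)
      t <- safe_sample(seq_len(N), 1L, prob = deg + 1)
      if (admissible(f, t) && !(paste(f, t) %in% key_of())) {
        from <- c(from, f); to <- c(to, t)
        deg[f] <- deg[f] + 1L; deg[t] <- deg[t] + 1L
      }
    }
  } else {  # erdos-renyi
    res <- pick_uniform(m_add, character(0))
    from <- res$from; to <- res$to
  }
  data.frame(from = nodes[from], to = nodes[to], stringsAsFactors = FALSE)
}

# extend a core function with new inputs appended after the original ones
extend_function <- function(f, new_inputs, policy, bias) {
  j <- length(new_inputs)
  k_old <- length(f$inputs)
  old_tab <- f$table
  # row = old_row * 2^j + new_combo (new inputs are least significant)
  tab <- rep(old_tab, each = 2L^j)
  if (policy == "duplicate-then-bias") {
    any_new_on <- rep(c(FALSE, rep(TRUE, 2L^j - 1L)), times = 2L^k_old)
    tab[any_new_on] <- rbinom(sum(any_new_on), 1L, bias)
  }
  boolean_function(c(f$inputs, new_inputs), tab)
}
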