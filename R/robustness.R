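# Robustness analysis: permanent knockouts/knock-ins and temporary flips,
# scored by avalanches (number of nodes whose activation pattern differs
# from wild type) and sensitivity (number of experiments affecting each
# node), plus classical topology measures.

# Which nodes differ between two attractor patterns?
# - frozen in both with equal value: unaffected;
# - equal cycle lengths: compare under the cyclic rotation of the second
#   cycle minimizing total Hamming mismatch; a node is affected iff its
#   column mismatches anywhere at that alignment;
# - different lengths: every node is affected unless frozen-and-equal in
#   both.
compare_attractor_patterns <- function(a, b) {
  stopifnot(ncol(a) == ncol(b))
  frozen_a <- apply(a, 2, function(x) all(x == x[1]))
  frozen_b <- apply(b, 2, function(x) all(x == x[1]))
  both_frozen_eq <- frozen_a & frozen_b & (a[1, ] == b[1, ])
  if (nrow(a) == nrow(b)) {
    L <- nrow(a)
    best_mis <- NULL
    best_total <- Inf
    for (r in seq_len(L) - 1L) {
      rot <- b[((seq_len(L) - 1L + r) %% L) + 1L, , drop = FALSE]
      mis <- colSums(a != rot) > 0
      total <- sum(a != rot)
      if (total < best_total) { best_total <- total; best_mis <- mis }
    }
    affected <- best_mis
  } else {
    affected <- !both_frozen_eq
  }
  affected
}

#' Avalanche of a perturbation experiment
#'
#' Evolves the wild-type and the perturbed network from the same initial
#' state until each is inside an attractor (or the horizon is hit), then
#' counts the nodes whose activation pattern differs between the two
#' attractors. See the package vignette for the pattern-alignment rule.
#'
#' @param net wild-type `nrbn_network`.
#' @param perturbed_net perturbed copy (same node set), e.g. from
#'   [knockout()].
#' @param initial_state common initial state.
#' @param horizon per-trajectory update budget.
#' @return list with `affected` (character vector of node names),
#'   `size` (`avalanche = |affected|`), and `resolved` (logical; `FALSE`
#'   when either trajectory failed to close, in which case the experiment
#'   is unresolved and `size` is `NA`).
#' @export
avalanche <- function(net, perturbed_net, initial_state, horizon = 1000L) {
  stopifnot(identical(net$nodes, perturbed_net$nodes))
  s0 <- check_state(net, initial_state)
  att <- function(nw) {
    eng <- net_to_engine(nw)
    res <- C_attractor_search(eng$reg, eng$tab, eng$clamp,
                              matrix(s0, nrow = 1), FALSE,
                              as.integer(horizon), list(), 2e6)
    if (is.na(res$assign[1])) NULL else res$attractors[[res$assign[1]]]
  }
  wt <- att(net)
  pt <- att(perturbed_net)
  if (is.null(wt) || is.null(pt))
    return(list(affected = character(), size = NA_integer_, resolved = FALSE))
  affected <- compare_attractor_patterns(wt, pt)
  list(affected = net$nodes[affected], size = sum(affected), resolved = TRUE)
}

#' Run a batch of perturbation experiments
#'
#' Applies temporary flips or permanent knockouts/knock-ins to chosen or
#' randomly selected target nodes and scores each experiment's avalanche
#' from a random initial state.
#'
#' @param net an `nrbn_network` with functions set.
#' @param kind `"knockout"`, `"knockin"` or `"flip"`.
#' @param targets `"all"`, a character vector of nodes, or a count of
#'   randomly selected nodes (drawn without replacement per repetition).
#' @param repetitions initial states tested per target (>= 1).
#' @param flip_duration hold length for `kind = "flip"`.
#' @param horizon per-trajectory update budget.
#' @param seed integer seed.
#' @return data.frame with one row per experiment: `target`, `rep`,
#'   `avalanche`, `resolved`, and an `affected` list-column of node
#'   names. Feed to [sensitivity_matrix()].
#' @export
run_perturbations <- function(net, kind = c("knockout", "knockin", "flip"),
                              targets = "all", repetitions = 1L,
                              flip_duration = 1L, horizon = 1000L,
                              seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(repetitions >= 1)
  set.seed(seed)
  if (identical(targets, "all")) targets <- net$nodes
  else if (is.numeric(targets)) targets <- safe_sample(net$nodes, targets)
  stopifnot(length(targets) >= 1, all(targets %in% net$nodes))
  N <- length(net$nodes)
  rows <- list()
  for (tg in targets) {
    for (r in seq_len(repetitions)) {
      s0 <- rbinom(N, 1L, 0.5)
      if (kind == "flip") {
        rel <- apply_flip(net, s0, tg, flip_duration)
        # compare relaxations of the unperturbed vs post-flip state
        res <- avalanche_states(net, s0, rel, horizon)
      } else {
        pnet <- if (kind == "knockout") knockout(net, tg) else knockin(net, tg)
        res <- avalanche(net, pnet, s0, horizon)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(target = tg, rep = r, avalanche = res$size,
                   resolved = res$resolved, stringsAsFactors = FALSE)
      rows[[length(rows)]]$affected <- list(res$affected)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "kind") <- kind
  out
}

# avalanche between the attractors reached from two states of the same net
avalanche_states <- function(net, s0, s1, horizon) {
  eng <- net_to_engine(net)
  res <- C_attractor_search(eng$reg, eng$tab, eng$clamp,
                            rbind(s0, s1), FALSE, as.integer(horizon),
                            list(), 2e6)
  if (anyNA(res$assign))
    return(list(affected = character(), size = NA_integer_, resolved = FALSE))
  a <- res$attractors[[res$assign[1]]]
  b <- res$attractors[[res$assign[2]]]
  affected <- compare_attractor_patterns(a, b)
  list(affected = net$nodes[affected], size = sum(affected), resolved = TRUE)
}

#' Per-node sensitivity counts of a perturbation batch
#'
#' `sensitivity[v]` is the number of experiments whose affected set
#' contains node v; summed over nodes it equals the summed avalanche
#' sizes (conservation identity).
#'
#' @param net the network the experiments were run on.
#' @param experiments result of [run_perturbations()].
#' @return named integer vector over nodes.
#' @export
sensitivity_matrix <- function(net, experiments) {
  stopifnot(nrow(experiments) >= 1)
  sens <- setNames(integer(length(net$nodes)), net$nodes)
  for (aff in experiments$affected)
    if (length(aff)) sens[aff] <- sens[aff] + 1L
  sens
}

#' Knockout screen against a target differentiation tree
#'
#' For each gene: knock it out, recompute the atlas and ATM, extract the
#' best emergent tree at the target's depth, and report the tree distance
#' to the target. The wild-type emergent tree gives the baseline
#' distance. Genes whose screen fails (e.g. no attractor resolved within
#' budget) are marked undetermined.
#'
#' @param net an `nrbn_network` with functions set.
#' @param genes genes to silence (default: the core nodes).
#' @param target an `nrbn_tree`.
#' @param n_samples,max_steps,max_phases,n_threshold_samples,enumerate_cap
#'   per-gene simulation budgets (see [match_ensemble()]).
#' @param seed integer seed.
#' @return data.frame with one row per gene: `gene`, `distance`,
#'   `n_attractors`, `status` (`"ok"` / `"undetermined"`); the baseline
#'   (no KO) distance is in `attr(, "baseline")`.
#' @export
ko_tree_screen <- function(net, genes = net$nodes[net$core], target,
                           n_samples = 500L, max_steps = 1000L,
                           max_phases = 8L, n_threshold_samples = 50L,
                           enumerate_cap = 200L, seed = 1L) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(genes) + 1L)
  screen_one <- function(nw, s) {
    atlas <- find_attractors(nw, "sampled", n_samples = n_samples,
                             max_steps = max_steps, seed = s)
    if (length(atlas$attractors) == 0) stop("no attractor resolved")
    atm <- suppressWarnings(build_atm(nw, atlas, max_phases = max_phases,
                                      max_steps = max_steps, seed = s))
    bm <- best_tree_match(atm, target,
                          n_threshold_samples = n_threshold_samples,
                          seed = s, enumerate_cap = enumerate_cap)
    list(distance = bm$distance, n_attractors = length(atm$atlas$attractors))
  }
  baseline <- tryCatch(screen_one(net, seeds[length(seeds)]),
                       error = function(e) list(distance = NA_real_,
                                                n_attractors = NA_integer_))
  rows <- lapply(seq_along(genes), function(i) {
    res <- tryCatch(screen_one(knockout(net, genes[i]), seeds[i]),
                    error = function(e) NULL)
    if (is.null(res))
      data.frame(gene = genes[i], distance = NA_real_,
                 n_attractors = NA_integer_, status = "undetermined",
                 stringsAsFactors = FALSE)
    else
      data.frame(gene = genes[i], distance = res$distance,
                 n_attractors = res$n_attractors, status = "ok",
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- baseline
  out
}

#' Classical topology measures of a network
#'
#' Global clustering coefficient (transitivity of the undirected
#' skeleton), diameter and average shortest-path length (directed, on the
#' largest weakly connected component), and in-/out-degree distributions.
#' Disconnected graphs report component-restricted path measures with
#' `restricted = TRUE`; an edgeless graph reports `NA` diameter with a
#' flag.
#'
#' @param net an `nrbn_network` (functions may be unset).
#' @return a list of measures.
#' @export
network_measures <- function(net) {
  g <- as_igraph(net)
  und <- igraph::as_undirected(g, mode = "collapse")
  clustering <- igraph::transitivity(und, type = "global")
  if (is.nan(clustering)) clustering <- 0
  comp <- igraph::components(g, mode = "weak")
  restricted <- comp$no > 1
  if (igraph::ecount(g) == 0) {
    diam <- NA_real_; apl <- NA_real_
  } else {
    big <- which.max(comp$csize)
    sub <- igraph::induced_subgraph(g, which(comp$membership == big))
    diam <- igraph::diameter(sub, directed = TRUE)
    apl <- igraph::mean_distance(sub, directed = TRUE)
  }
  indeg <- igraph::degree(g, mode = "in")
  outdeg <- igraph::degree(g, mode = "out")
  list(clustering_coefficient = clustering,
       diameter = diam, average_path_length = apl,
       restricted_to_largest_component = restricted,
       in_degree = table(indeg), out_degree = table(outdeg),
       mean_in_degree = mean(indeg))
}
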