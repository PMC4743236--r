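# Attractor discovery: exhaustive enumeration of the 2^N state space (small
# networks) or uniform sampling of initial conditions, with per-trajectory
# cycle detection in the C++ engine and canonical deduplication.

#' Discover the attractors of a network
#'
#' Relaxes trajectories from initial states and collects the state cycles
#' they end in. In `exhaustive` mode all `2^N` states are tested (small
#' networks only); in `sampled` mode `n_samples` initial states are drawn
#' uniformly (with replacement by default, the only scalable reading for
#' large N; without replacement is available up to the exhaustive cap).
#' Trajectories that do not close within `max_steps` updates are counted
#' as unresolved, never silently dropped.
#'
#' Attractors are canonicalized (rotation starting at the
#' lexicographically smallest state) and sorted by (length, canonical
#' state) so their ids are stable across runs.
#'
#' @param net an `nrbn_network` with functions set.
#' @param mode `"exhaustive"` or `"sampled"`.
#' @param n_samples number of initial states for sampled mode.
#' @param max_steps per-trajectory update budget (default 1000).
#' @param seed optional integer seed for the sampling.
#' @param replace sample initial states with replacement (default) or
#'   without (requires `N <= exhaustive_cap`).
#' @param exhaustive_cap refuse exhaustive search above this node count.
#' @return an object of class `nrbn_atlas`: a list with `attractors`
#'   (each a list with `states` matrix, `length`, `basin`, `id`), `mode`,
#'   `n_initial_states`, `max_steps`, `unresolved_count` and (sampled
#'   mode) `seed`.
#' @export
find_attractors <- function(net, mode = c("sampled", "exhaustive"),
                            n_samples = 1000L, max_steps = 1000L,
                            seed = NULL, replace = TRUE,
                            exhaustive_cap = 20L) {
  mode <- match.arg(mode)
  stopifnot(max_steps >= 1)
  eng <- net_to_engine(net)
  N <- length(net$nodes)
  if (mode == "exhaustive") {
    if (N > exhaustive_cap)
      stop("exhaustive search refused for N = ", N, " > cap ", exhaustive_cap,
           "; use mode = \"sampled\" with a sample size you can afford")
    res <- C_attractor_search(eng$reg, eng$tab, eng$clamp,
                              matrix(integer(), 0, N), TRUE,
                              as.integer(max_steps), list(), 2e6)
    n_init <- 2^N
  } else {
    stopifnot(n_samples >= 1)
    if (!is.null(seed)) set.seed(seed)
    if (replace) {
      inits <- matrix(rbinom(n_samples * N, 1L, 0.5), nrow = n_samples,
                      byrow = TRUE)
    } else {
      if (N > exhaustive_cap)
        stop("without-replacement sampling requires N <= ", exhaustive_cap)
      if (n_samples > 2^N) stop("cannot draw ", n_samples,
                                " distinct states from a space of ", 2^N)
      codes <- sample.int(2^N, n_samples) - 1
      inits <- t(vapply(codes, decode_state, integer(N), n = N))
    }
    res <- C_attractor_search(eng$reg, eng$tab, eng$clamp, inits, FALSE,
                              as.integer(max_steps), list(), 2e6)
    n_init <- n_samples
  }
  build_atlas(net, res, mode, n_init, max_steps, seed)
}

build_atlas <- function(net, res, mode, n_init, max_steps, seed) {
  n_att <- length(res$attractors)
  basins <- tabulate(res$assign[!is.na(res$assign)], nbins = n_att)
  # stable ordering: by (length, canonical first state)
  keys <- vapply(res$attractors, function(m)
    paste(m[1, ], collapse = ""), character(1))
  ord <- order(res$lengths, keys)
  attractors <- lapply(seq_along(ord), function(i) {
    a <- ord[i]
    list(states = res$attractors[[a]], length = res$lengths[a],
         basin = basins[a], id = i)
  })
  structure(list(attractors = attractors, mode = mode,
                 n_initial_states = n_init,
                 max_steps = max_steps,
                 unresolved_count = sum(is.na(res$assign)),
                 seed = seed, nodes = net$nodes,
                 assignment_order = ord),
            class = "nrbn_atlas")
}

#' Number of attractors in an atlas
#' @param atlas an `nrbn_atlas`.
#' @return integer count.
#' @export
n_attractors <- function(atlas) length(atlas$attractors)

#' Canonicalize a state cycle
#'
#' Rotates a closed orbit so that it starts at the lexicographically
#' smallest state (first node = most significant bit). Two rotations of
#' the same cycle have equal canonical forms, which is what attractor
#' deduplication relies on.
#'
#' @param cycle matrix of states (rows = consecutive cycle states) or a
#'   list of state vectors.
#' @param net optional `nrbn_network`; when given, the orbit is verified
#'   to be closed under the dynamics.
#' @return matrix of states starting at the canonical rotation.
#' @export
canonicalize_cycle <- function(cycle, net = NULL) {
  if (is.list(cycle)) cycle <- do.call(rbind, cycle)
  storage.mode(cycle) <- "integer"
  if (!is.null(net)) {
    eng <- net_to_engine(net)
    nxt <- C_step_many(eng$reg, eng$tab, eng$clamp, cycle, 1L)
    expect <- cycle[c(2:nrow(cycle), 1L), , drop = FALSE]
    if (!identical(unname(nxt), unname(expect)))
      stop("input is not a closed orbit of the network")
  }
  keys <- apply(cycle, 1, paste, collapse = "")
  if (anyDuplicated(keys)) stop("cycle states must be pairwise distinct")
  start <- which(keys == min(keys))[1]
  idx <- ((start - 1L + seq_len(nrow(cycle)) - 1L) %% nrow(cycle)) + 1L
  cycle[idx, , drop = FALSE]
}

#' Attractor-level statistics of an atlas
#'
#' @param atlas an `nrbn_atlas`.
#' @return a list with `n_attractors`, `length_histogram` (table of cycle
#'   lengths), `basin_table` (basin size and reachability = basin
#'   fraction per attractor), `frozen_proportion` per attractor (share of
#'   nodes whose value is constant across the cycle; the rest oscillate)
#'   and `mean_frozen_proportion` across attractors.
#' @export
attractor_statistics <- function(atlas) {
  stopifnot(inherits(atlas, "nrbn_atlas"), length(atlas$attractors) > 0)
  lens <- vapply(atlas$attractors, `[[`, integer(1), "length")
  basins <- vapply(atlas$attractors, `[[`, numeric(1), "basin")
  frozen <- vapply(atlas$attractors, function(a) {
    constant <- apply(a$states, 2, function(col) all(col == col[1]))
    mean(constant)
  }, numeric(1))
  resolved <- atlas$n_initial_states - atlas$unresolved_count
  list(n_attractors = length(lens),
       length_histogram = table(lens),
       basin_table = data.frame(id = seq_along(lens), length = lens,
                                basin = basins,
                                reachability = if (resolved > 0)
                                  basins / resolved else NA_real_),
       frozen_proportion = frozen,
       mean_frozen_proportion = mean(frozen),
       unresolved_count = atlas$unresolved_count)
}

#' @export
print.nrbn_atlas <- function(x, ...) {
  lens <- vapply(x$attractors, `[[`, integer(1), "length")
  cat("Attractor atlas (", x$mode, " mode): ", length(x$attractors),
      " attractor(s) over ", x$n_initial_states, " initial states\n",
      sep = "")
  cat("  lengths: ", paste(lens, collapse = ", "), "\n", sep = "")
  if (x$unresolved_count > 0)
    cat("  unresolved trajectories: ", x$unresolved_count, "\n", sep = "")
  invisible(x)
}

# states of all attractors as one matrix list keyed by atlas id
atlas_state_matrices <- function(atlas) lapply(atlas$attractors, `[[`, "states")
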