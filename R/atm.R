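# Noise protocol: transient single-node flips applied to attractor states,
# and the attractor transition matrix (ATM) built from the destinations of
# the ensuing relaxations. Row a of the ATM gives the empirical probability
# that a flip experiment started in attractor a relaxes to each attractor.

#' Apply a transient flip to a state
#'
#' Inverts one node's value and holds the inverted value for `duration`
#' synchronous updates (a temporary clamp: the node's function is
#' suspended during the hold while every other node updates normally).
#' The inversion takes effect together with the first update, so after
#' duration 1 the flipped node carries the inverted value and the others
#' carry their ordinary next-state values. The state at release time is
#' returned; relaxation under the unperturbed dynamics starts there.
#'
#' @param net an `nrbn_network` with functions set.
#' @param state state the flip is applied to.
#' @param node name of the flipped node.
#' @param duration hold length in steps (>= 1, default 1).
#' @return the state at release time.
#' @export
apply_flip <- function(net, state, node, duration = 1L) {
  stopifnot(duration >= 1)
  state <- check_state(net, state)
  if (!(node %in% net$nodes)) stop("unknown node: ", node)
  i <- match(node, net$nodes)
  held <- clamp_nodes(net, node, 1L - state[i])
  eng <- net_to_engine(held)
  drop(C_step_many(eng$reg, eng$tab, eng$clamp, matrix(state, nrow = 1),
                   as.integer(duration)))
}

#' Build the attractor transition matrix
#'
#' For every attractor in the atlas, every (or a sampled subset of its)
#' phase states, and every (or a chosen subset of) target nodes, a flip
#' of the given duration is applied and the network relaxed; the
#' destination attractor is tallied. Counts are row-normalized into
#' transition probabilities.
#'
#' A relaxation may end in a cycle absent from a sampled atlas. By
#' default (`on_new_attractor = "extend"`) the atlas is extended, a
#' warning is emitted, and flip experiments are run for the appended
#' attractors too (bounded by `max_extension_rounds`), so the matrix
#' stays square and row-stochastic; `"strict"` tallies such experiments
#' as unresolved instead. Experiments that do not relax within
#' `max_steps` are always unresolved.
#'
#' @param net an `nrbn_network` with functions set.
#' @param atlas an `nrbn_atlas` computed on the same network.
#' @param duration flip hold length (default 1 step).
#' @param targets `"all"` or a character vector of nodes to flip.
#' @param max_phases cap on the number of phase states tested per
#'   attractor (`Inf` = all; a cap is the standard budget knob for large
#'   networks, sampled without replacement, seeded).
#' @param max_steps relaxation budget per experiment.
#' @param seed optional integer seed (phase sampling).
#' @param on_new_attractor `"extend"` or `"strict"`.
#' @param max_extension_rounds bound on atlas-extension iterations.
#' @return an object of class `nrbn_atm`: list with `counts`, `probs`
#'   (row-stochastic where a row has resolved experiments), `unresolved`
#'   per row, `n_experiments` per row, the (possibly extended) `atlas`,
#'   `duration` and `targets`.
#' @export
build_atm <- function(net, atlas, duration = 1L, targets = "all",
                      max_phases = Inf, max_steps = 1000L, seed = NULL,
                      on_new_attractor = c("extend", "strict"),
                      max_extension_rounds = 20L) {
  stopifnot(inherits(net, "nrbn_network"), inherits(atlas, "nrbn_atlas"))
  on_new_attractor <- match.arg(on_new_attractor)
  if (length(atlas$attractors) == 0) stop("empty atlas")
  if (!identical(atlas$nodes, net$nodes))
    stop("atlas was not computed on this network (node mismatch)")
  if (identical(targets, "all")) targets <- net$nodes
  if (!all(targets %in% net$nodes)) stop("unknown target node(s)")
  if (!is.null(seed)) set.seed(seed)

  eng <- net_to_engine(net)
  N <- length(net$nodes)
  cycles <- atlas_state_matrices(atlas)          # known attractors, id order
  counts <- matrix(0L, 0, 0)
  unresolved <- integer(0)
  n_exp <- integer(0)
  done <- 0L                                      # rows already processed
  rounds <- 0L
  extended <- FALSE

  while (done < length(cycles)) {
    rounds <- rounds + 1L
    if (rounds > max_extension_rounds + 1L) {
      warning("atlas extension budget exhausted; remaining rows unprocessed")
      break
    }
    todo <- seq(done + 1L, length(cycles))
    # grow matrices to current attractor count
    counts <- grow_square(counts, length(cycles))
    unresolved <- c(unresolved, integer(length(todo)))
    n_exp <- c(n_exp, integer(length(todo)))

    for (a in todo) {
      states <- cycles[[a]]
      phases <- seq_len(nrow(states))
      if (is.finite(max_phases) && length(phases) > max_phases)
        phases <- sort(safe_sample(phases, max_phases))
      # release states for all (phase, target) experiments
      rel <- matrix(0L, length(phases) * length(targets), N)
      r <- 0L
      for (node in targets) {
        i <- match(node, net$nodes)
        ph <- states[phases, , drop = FALSE]
        clamp2 <- eng$clamp
        for (p in seq_along(phases)) {
          r <- r + 1L
          clamp2[i] <- 1L - ph[p, i]
          rel[r, ] <- C_step_many(eng$reg, eng$tab, clamp2,
                                  ph[p, , drop = FALSE],
                                  as.integer(duration))
        }
      }
      res <- C_attractor_search(eng$reg, eng$tab, eng$clamp, rel, FALSE,
                                as.integer(max_steps), cycles, 2e6)
      dest <- res$assign
      n_known <- length(cycles)
      if (length(res$attractors) > n_known) {
        if (on_new_attractor == "extend") {
          extended <- TRUE
          cycles <- res$attractors
        } else {
          dest[dest > n_known] <- NA_integer_
        }
      }
      n_exp[a] <- length(dest)
      unresolved[a] <- sum(is.na(dest))
      counts <- grow_square(counts, length(cycles))
      tal <- tabulate(dest[!is.na(dest)], nbins = ncol(counts))
      counts[a, ] <- counts[a, ] + tal
    }
    done <- max(todo)
    if (on_new_attractor == "strict") break
  }
  if (extended)
    warning("flip relaxations reached attractor(s) absent from the atlas; ",
            "atlas extended to ", length(cycles), " attractors")

  atlas2 <- atlas
  if (length(cycles) > length(atlas$attractors)) {
    for (a in seq(length(atlas$attractors) + 1L, length(cycles)))
      atlas2$attractors[[a]] <- list(states = cycles[[a]],
                                     length = nrow(cycles[[a]]),
                                     basin = 0L, id = a)
  }
  probs <- counts / pmax(rowSums(counts), 1)
  probs[rowSums(counts) == 0, ] <- NA_real_
  ids <- paste0("A", seq_len(ncol(counts)))
  dimnames(counts) <- dimnames(probs) <- list(ids, ids)
  structure(list(counts = counts, probs = probs, unresolved = unresolved,
                 n_experiments = n_exp, atlas = atlas2,
                 duration = duration, targets = targets),
            class = "nrbn_atm")
}

grow_square <- function(m, k) {
  if (nrow(m) == k && ncol(m) == k) return(m)
  out <- matrix(0L, k, k)
  if (nrow(m) > 0) out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

#' @export
print.nrbn_atm <- function(x, ...) {
  cat("Attractor transition matrix: ", nrow(x$counts), " attractors, ",
      sum(x$n_experiments), " flip experiments (duration ", x$duration,
      ")\n", sep = "")
  print(round(x$probs, 3))
  if (sum(x$unresolved) > 0)
    cat("  unresolved experiments: ", sum(x$unresolved), "\n", sep = "")
  invisible(x)
}

#' Export an ATM as a weighted edge list
#'
#' One row per transition with positive probability:
#' `source_attractor target_attractor probability` — the "TES network"
#' input format.
#'
#' @param atm an `nrbn_atm`.
#' @return data.frame with columns `from`, `to`, `probability`.
#' @export
atm_edge_list <- function(atm) {
  idx <- which(atm$probs > 0 & !is.na(atm$probs), arr.ind = TRUE)
  out <- data.frame(from = rownames(atm$probs)[idx[, 1]],
                    to = colnames(atm$probs)[idx[, 2]],
                    probability = atm$probs[idx],
                    stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}
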