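# Threshold ergodic sets: prune the attractor transition network at a
# noise-resistance threshold delta, then take the terminal strongly
# connected components — the attractor sets the dynamics can wander within
# but not leave. Each threshold models a differentiation stage; sweeping
# increasing thresholds yields the emergent differentiation hierarchy.

#' Prune an ATM at a threshold
#'
#' Removes transitions with probability strictly below `delta`
#' (`delta = 0` removes nothing); self-transitions are subject to the
#' same rule.
#'
#' @param atm an `nrbn_atm` or a square probability matrix.
#' @param delta threshold in \[0, 1\].
#' @return the pruned weighted adjacency matrix (probabilities kept on
#'   surviving edges, 0 elsewhere).
#' @export
threshold_atn <- function(atm, delta) {
  stopifnot(delta >= 0, delta <= 1)
  p <- atm_probs(atm)
  p[is.na(p)] <- 0
  p[p < delta] <- 0
  p
}

atm_probs <- function(atm) {
  if (inherits(atm, "nrbn_atm")) atm$probs
  else {
    stopifnot(is.matrix(atm), nrow(atm) == ncol(atm))
    atm
  }
}

#' Threshold ergodic sets of a pruned ATN
#'
#' TESs are the terminal strongly connected components of the pruned
#' graph: SCCs with no surviving edge leaving the component. Attractors
#' in non-terminal SCCs are transient at this threshold. Self-loops never
#' affect SCC membership.
#'
#' @param pruned a pruned adjacency matrix from [threshold_atn()].
#' @param delta the threshold, recorded in the result.
#' @return a `tes_partition`: list with `delta`, `tes_list` (list of
#'   integer vectors of attractor ids, sorted) and `transient_attractors`.
#' @export
compute_tes <- function(pruned, delta = NA_real_) {
  n <- nrow(pruned)
  adj <- pruned > 0
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  # terminal = no edge from the component to another component
  edge_out <- which(adj, arr.ind = TRUE)
  leaving <- unique(memb[edge_out[, 1]][memb[edge_out[, 1]] != memb[edge_out[, 2]]])
  terminal <- setdiff(seq_len(comp$no), leaving)
  memb <- unname(memb)
  tes_list <- lapply(terminal, function(cc) sort(which(memb == cc)))
  # deterministic order: by smallest member id
  tes_list <- tes_list[order(vapply(tes_list, min, integer(1)))]
  transient <- sort(which(memb %in% leaving))
  structure(list(delta = delta, tes_list = tes_list,
                 transient_attractors = transient),
            class = "tes_partition")
}

#' Sweep a threshold sequence over an ATM
#'
#' @param atm an `nrbn_atm` or probability matrix.
#' @param levels strictly increasing thresholds in \[0, 1\], or `"auto"`
#'   to use the sorted distinct off-diagonal transition probabilities
#'   plus the sentinels 0 and 1.
#' @return list of [compute_tes()] partitions, one per level.
#' @export
sweep_thresholds <- function(atm, levels = "auto") {
  if (identical(levels, "auto")) levels <- auto_levels(atm)
  stopifnot(all(levels >= 0), all(levels <= 1),
            all(diff(levels) > 0) || length(levels) == 1)
  lapply(levels, function(d) compute_tes(threshold_atn(atm, d), d))
}

#' Automatic threshold level set of an ATM
#'
#' The sorted distinct off-diagonal transition probabilities, with 0 and
#' 1 included as sentinels.
#'
#' @param atm an `nrbn_atm` or probability matrix.
#' @return increasing numeric vector of thresholds.
#' @export
auto_levels <- function(atm) {
  p <- atm_probs(atm)
  off <- p[row(p) != col(p)]
  off <- off[!is.na(off) & off > 0]
  sort(unique(c(0, off, 1)))
}

#' @export
print.tes_partition <- function(x, ...) {
  cat("TES partition at delta = ", format(x$delta), ": ",
      length(x$tes_list), " TES(s)", sep = "")
  if (length(x$transient_attractors))
    cat(", ", length(x$transient_attractors), " transient attractor(s)",
        sep = "")
  cat("\n")
  for (i in seq_along(x$tes_list))
    cat("  TES ", i, ": {", paste(x$tes_list[[i]], collapse = ", "), "}\n",
        sep = "")
  invisible(x)
}
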