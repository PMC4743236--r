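# Differentiation trees: rooted trees of TESs across a threshold sweep,
# compared by their level-by-level shape table n_x(k, l) — the number of
# nodes at depth l with exactly k children. The tree distance is the L1
# distance between shape tables, summed over all (k, l) up to the maxima
# of both trees; labels never enter the comparison.

#' Create a differentiation tree
#'
#' A rooted tree stored as a parent vector. Node levels are depths (root
#' = 0). Multi-root inputs are joined under a virtual root and flagged.
#'
#' @param labels character vector of node labels (unique).
#' @param parent integer vector: `parent[i]` is the index of node `i`'s
#'   parent, `NA` for the root.
#' @param annotation optional list (e.g. attractor-id sets per node).
#' @return an object of class `nrbn_tree` with elements `labels`,
#'   `parent`, `level`.
#' @export
differentiation_tree <- function(labels, parent, annotation = NULL) {
  labels <- as.character(labels)
  parent <- as.integer(parent)
  stopifnot(length(labels) == length(parent))
  if (anyDuplicated(labels)) stop("node labels must be unique")
  roots <- which(is.na(parent))
  if (length(roots) == 0) stop("tree has no root")
  virtual_root <- FALSE
  if (length(roots) > 1) {
    labels <- c(".virtual_root", labels)
    parent <- c(NA_integer_, ifelse(is.na(parent), 1L, parent + 1L))
    virtual_root <- TRUE
    if (!is.null(annotation)) annotation <- c(list(NULL), annotation)
  }
  level <- tree_levels(parent)
  out <- structure(list(labels = labels, parent = parent, level = level,
                        annotation = annotation),
                   class = "nrbn_tree")
  attr(out, "virtual_root") <- virtual_root
  out
}

tree_levels <- function(parent) {
  n <- length(parent)
  level <- rep(NA_integer_, n)
  level[is.na(parent)] <- 0L
  remaining <- sum(is.na(level))
  while (remaining > 0) {
    ready <- which(is.na(level) & !is.na(level[parent]))
    if (length(ready) == 0) stop("parent vector contains a cycle")
    level[ready] <- level[parent[ready]] + 1L
    remaining <- sum(is.na(level))
  }
  level
}

#' Build a tree from a parent -> child edge list
#'
#' @param parents,children equal-length character vectors of labels.
#' @return an `nrbn_tree`.
#' @export
tree_from_edges <- function(parents, children) {
  if (anyDuplicated(children))
    stop("a node may have at most one parent")
  labels <- unique(c(parents, children))
  parent <- match(parents[match(labels, children)], labels)
  differentiation_tree(labels, parent)
}

#' Depth of a tree
#' @param tree an `nrbn_tree`.
#' @return maximum node level (root = 0).
#' @export
tree_depth <- function(tree) max(tree$level)

#' Number of nodes of a tree
#' @param tree an `nrbn_tree`.
#' @return integer count.
#' @export
tree_size <- function(tree) length(tree$labels)

#' Shape table of a tree
#'
#' Materializes n_x(k, l): the number of nodes at level l having exactly
#' k children, for k = 0..k_max and l = 0..depth.
#'
#' @param tree an `nrbn_tree`.
#' @return integer matrix, rows = k (0-based, named `k0...`), columns =
#'   l (named `l0...`).
#' @export
shape_table <- function(tree) {
  n <- length(tree$labels)
  kids <- tabulate(tree$parent[!is.na(tree$parent)], nbins = n)
  k_max <- max(kids)
  l_max <- max(tree$level)
  m <- matrix(0L, k_max + 1L, l_max + 1L,
              dimnames = list(paste0("k", 0:k_max), paste0("l", 0:l_max)))
  for (i in seq_len(n))
    m[kids[i] + 1L, tree$level[i] + 1L] <- m[kids[i] + 1L, tree$level[i] + 1L] + 1L
  m
}

#' Level-by-level tree distance
#'
#' The structural similarity of two rooted trees, computed as the sum of
#' absolute differences of their shape tables over all levels l = 0..l*
#' and child counts k = 0..k*, where l* and k* are the maximum depth and
#' maximum number of children in both trees. It is a pseudometric on
#' shape tables: symmetric, zero iff the shape tables are identical, and
#' satisfies the triangle inequality. Labels are ignored. For
#' differentiation trees it measures, per stage, how the capacity of
#' progenitors to split into subtypes differs.
#'
#' @param h,t `nrbn_tree` objects or shape-table matrices.
#' @return a non-negative integer.
#' @export
tree_distance <- function(h, t) {
  a <- if (inherits(h, "nrbn_tree")) shape_table(h) else h
  b <- if (inherits(t, "nrbn_tree")) shape_table(t) else t
  k_max <- max(nrow(a), nrow(b))
  l_max <- max(ncol(a), ncol(b))
  pad <- function(m) {
    out <- matrix(0L, k_max, l_max)
    out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    out
  }
  sum(abs(pad(a) - pad(b)))
}

#' Build the differentiation tree of a threshold sweep
#'
#' TESs of consecutive threshold levels are connected by attractor-set
#' inclusion: a TES at one level is the child of the TES at the previous
#' level that contains it. A TES identical to its parent persists as the
#' same node (no unary chain) when `merge_identical` is `TRUE`. A TES
#' with no containing parent (a transient attractor re-entering at a
#' higher threshold) is attached to the parent with maximal overlap, or
#' becomes an extra root when it overlaps nothing; multi-root results are
#' returned as a forest under a virtual root, flagged.
#'
#' @param partitions list of [compute_tes()] partitions from one sweep
#'   (increasing thresholds).
#' @param merge_identical merge TESs unchanged across consecutive levels.
#' @return an `nrbn_tree`; each node's annotation holds its attractor id
#'   set and the threshold at which it appeared.
#' @export
build_tree <- function(partitions, merge_identical = TRUE) {
  stopifnot(length(partitions) >= 1,
            length(partitions[[1]]$tes_list) >= 1)
  sets <- list()    # attractor sets per tree node
  parent <- integer(0)
  deltas <- numeric(0)
  notes <- character(0)
  # first level
  for (s in partitions[[1]]$tes_list) {
    sets[[length(sets) + 1L]] <- s
    parent <- c(parent, NA_integer_)
    deltas <- c(deltas, partitions[[1]]$delta)
  }
  active <- seq_along(sets)   # tree nodes representing the previous level
  if (length(partitions) >= 2) for (lev in 2:length(partitions)) {
    new_active <- integer(0)
    for (s in partitions[[lev]]$tes_list) {
      same <- active[vapply(active, function(a) identical(sets[[a]], s),
                            logical(1))]
      if (merge_identical && length(same)) {
        new_active <- c(new_active, same[1])
        next
      }
      containing <- active[vapply(active, function(a) all(s %in% sets[[a]]),
                                  logical(1))]
      if (length(containing)) {
        par <- containing[1]
      } else {
        overlap <- vapply(active, function(a) length(intersect(s, sets[[a]])),
                          integer(1))
        if (length(active) && max(overlap) > 0) {
          par <- active[which.max(overlap)]
          notes <- c(notes, sprintf(
            "level %d: TES {%s} not nested; attached by maximal overlap",
            lev, paste(s, collapse = ",")))
        } else {
          par <- NA_integer_
          notes <- c(notes, sprintf(
            "level %d: TES {%s} has no overlapping parent; new root",
            lev, paste(s, collapse = ",")))
        }
      }
      sets[[length(sets) + 1L]] <- s
      parent <- c(parent, par)
      deltas <- c(deltas, partitions[[lev]]$delta)
      new_active <- c(new_active, length(sets))
    }
    active <- new_active
  }
  labels <- vapply(seq_along(sets), function(i)
    paste0("T", i, "{", paste(sets[[i]], collapse = ","), "}"), character(1))
  tree <- differentiation_tree(labels, parent,
                               annotation = lapply(seq_along(sets), function(i)
                                 list(attractors = sets[[i]],
                                      delta = deltas[i])))
  attr(tree, "notes") <- notes
  tree
}

#' @export
print.nrbn_tree <- function(x, ...) {
  cat("Differentiation tree: ", length(x$labels), " nodes, depth ",
      max(x$level), "\n", sep = "")
  if (isTRUE(attr(x, "virtual_root")))
    cat("  (forest joined under a virtual root)\n")
  ord <- order(x$level, x$parent, na.last = FALSE)
  for (i in ord)
    cat(strrep("  ", x$level[i] + 1L), x$labels[i], "\n", sep = "")
  invisible(x)
}

shape_key <- function(tree) {
  m <- shape_table(tree)
  paste0(nrow(m), "x", ncol(m), ":", paste(m, collapse = ","))
}

# strictly increasing threshold combinations of size `size` from `levels`
threshold_combinations <- function(levels, size, n_samples, enumerate_cap) {
  n_all <- choose(length(levels), size)
  if (n_all <= enumerate_cap) {
    cb <- combn(levels, size)
    lapply(seq_len(ncol(cb)), function(j) cb[, j])
  } else {
    unique(lapply(seq_len(n_samples), function(i)
      sort(safe_sample(levels, size))))
  }
}

#' Representative differentiation tree of an ATM
#'
#' Samples threshold combinations of a given depth from the automatic
#' level set, builds the emergent tree for each, groups trees by shape
#' table, and returns the modal shape with its frequency. Ties are broken
#' by smaller total node count, then lexicographic shape key.
#'
#' @param atm an `nrbn_atm` or probability matrix.
#' @param depth number of threshold levels per combination (>= 1).
#' @param n_threshold_samples number of sampled combinations when
#'   enumeration is too large.
#' @param seed optional integer seed.
#' @param enumerate_cap enumerate all combinations when their number is
#'   at most this.
#' @return list with `tree` (a representative instance of the modal
#'   shape), `frequency` (modal share of combinations), `thresholds`
#'   (a combination realizing it) and `n_combinations`.
#' @export
representative_tree <- function(atm, depth, n_threshold_samples = 100L,
                                seed = NULL, enumerate_cap = 500L) {
  stopifnot(depth >= 1)
  if (!is.null(seed)) set.seed(seed)
  levels <- auto_levels(atm)
  size <- min(depth, length(levels))
  combos <- threshold_combinations(levels, size, n_threshold_samples,
                                   enumerate_cap)
  if (length(combos) == 0) stop("no valid threshold combination")
  trees <- lapply(combos, function(ds) build_tree(sweep_thresholds(atm, ds)))
  keys <- vapply(trees, shape_key, character(1))
  freq <- table(keys)
  best_n <- max(freq)
  cand <- names(freq)[freq == best_n]
  if (length(cand) > 1) {
    sizes <- vapply(cand, function(k) tree_size(trees[[match(k, keys)]]),
                    numeric(1))
    cand <- cand[order(sizes, cand)]
  }
  pick <- match(cand[1], keys)
  list(tree = trees[[pick]], frequency = best_n / length(combos),
       thresholds = combos[[pick]], n_combinations = length(combos))
}

#' Best tree match of an ATM against a target tree
#'
#' Enumerates (or samples) threshold combinations whose level count
#' equals the target tree's, builds each emergent tree and returns the
#' minimum tree distance to the target.
#'
#' @param atm an `nrbn_atm` or probability matrix.
#' @param target an `nrbn_tree`.
#' @param n_threshold_samples,enumerate_cap combination budget, as in
#'   [representative_tree()].
#' @param seed optional integer seed.
#' @return list with `distance`, `tree`, `thresholds`.
#' @export
best_tree_match <- function(atm, target, n_threshold_samples = 100L,
                            seed = NULL, enumerate_cap = 500L) {
  if (!is.null(seed)) set.seed(seed)
  levels <- auto_levels(atm)
  size <- min(tree_depth(target) + 1L, length(levels))
  combos <- threshold_combinations(levels, size, n_threshold_samples,
                                   enumerate_cap)
  target_shape <- shape_table(target)
  best <- list(distance = Inf, tree = NULL, thresholds = NULL)
  for (ds in combos) {
    tr <- build_tree(sweep_thresholds(atm, ds))
    d <- tree_distance(tr, target_shape)
    if (d < best$distance) best <- list(distance = d, tree = tr,
                                        thresholds = ds)
    if (d == 0) break
  }
  best
}

#' Select ensemble networks matching a target differentiation tree
#'
#' For each network: attractor atlas, ATM, candidate emergent trees over
#' threshold combinations at the target's depth; a network matches iff
#' some candidate tree is within `tolerance` of the target. Networks
#' whose per-network budget is exhausted (no attractor resolved) are
#' marked undetermined, never silently matched.
#'
#' @param networks list of `nrbn_network` objects.
#' @param target an `nrbn_tree`.
#' @param tolerance maximum accepted tree distance (>= 0).
#' @param n_samples,max_steps atlas parameters per network.
#' @param max_phases,atm_max_steps ATM parameters per network.
#' @param n_threshold_samples,enumerate_cap threshold-combination budget.
#' @param seed master integer seed (per-network seeds derived).
#' @return data.frame with one row per network: `network`, `n_attractors`,
#'   `best_distance`, `matched` (logical; `NA` = undetermined),
#'   `thresholds` (comma-separated realizing combination).
#' @export
match_ensemble <- function(networks, target, tolerance = 0,
                           n_samples = 500L, max_steps = 1000L,
                           max_phases = 8L, atm_max_steps = 1000L,
                           n_threshold_samples = 50L, enumerate_cap = 200L,
                           seed = 1L) {
  stopifnot(tolerance >= 0)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, length(networks))
  rows <- lapply(seq_along(networks), function(i) {
    net <- networks[[i]]
    res <- tryCatch({
      atlas <- find_attractors(net, "sampled", n_samples = n_samples,
                               max_steps = max_steps, seed = seeds[i])
      if (length(atlas$attractors) == 0)
        return(data.frame(network = i, n_attractors = 0L,
                          best_distance = NA_real_, matched = NA,
                          thresholds = NA_character_))
      atm <- suppressWarnings(
        build_atm(net, atlas, max_phases = max_phases,
                  max_steps = atm_max_steps, seed = seeds[i]))
      bm <- best_tree_match(atm, target,
                            n_threshold_samples = n_threshold_samples,
                            seed = seeds[i], enumerate_cap = enumerate_cap)
      data.frame(network = i, n_attractors = length(atm$atlas$attractors),
                 best_distance = bm$distance,
                 matched = bm$distance <= tolerance,
                 thresholds = paste(signif(bm$thresholds, 6), collapse = ";"))
    }, error = function(e)
      data.frame(network = i, n_attractors = NA_integer_,
                 best_distance = NA_real_, matched = NA,
                 thresholds = NA_character_))
    res
  })
  do.call(rbind, rows)
}
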