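# Regulatory networks: ordered node list, one Boolean function per node,
# core/augmented bookkeeping and optional clamp overrides (knockout /
# knock-in). The directed edge set is implied by the function inputs.

#' Create a regulatory network
#'
#' @param functions named list of [boolean_function()] objects, one per
#'   node, in node order. Entries may be `NULL` for a topology-only
#'   network (e.g. imported from an edge list); such networks cannot be
#'   simulated until functions are set.
#' @param core logical vector (recycled) marking nodes that belong to an
#'   imported core, as opposed to an augmented portion.
#' @param clamps optional named integer vector of forced values in
#'   `{0, 1}`; clamped nodes ignore their function. Used for permanent
#'   knockouts/knock-ins.
#' @return an object of class `nrbn_network`.
#' @examples
#' net <- regulatory_network(list(
#'   n1 = boolean_function("n2", c(0, 1)),
#'   n2 = boolean_function(expr = "NOT n1")))
#' step_network(net, c(0, 0))
#' @export
regulatory_network <- function(functions, core = TRUE, clamps = NULL) {
  nodes <- names(functions)
  if (is.null(nodes) || any(!nzchar(nodes)) || anyDuplicated(nodes))
    stop("`functions` must be a named list with unique node names")
  bad <- grep("^[A-Za-z0-9_.-]+$", nodes, invert = TRUE, value = TRUE)
  if (length(bad))
    stop("node names restricted to [A-Za-z0-9_.-]: ",
         paste(bad, collapse = ", "))
  core <- rep_len(as.logical(core), length(nodes))
  names(core) <- nodes
  cl <- rep(NA_integer_, length(nodes))
  names(cl) <- nodes
  if (!is.null(clamps)) {
    if (is.null(names(clamps))) stop("`clamps` must be named")
    unknown <- setdiff(names(clamps), nodes)
    if (length(unknown)) stop("clamp on unknown node: ",
                              paste(unknown, collapse = ", "))
    if (!all(clamps %in% c(0L, 1L))) stop("clamp values must be 0 or 1")
    cl[names(clamps)] <- as.integer(clamps)
  }
  for (n in nodes) {
    f <- functions[[n]]
    if (is.null(f)) next
    if (!inherits(f, "nrbn_function")) stop("function for ", n,
                                            " is not an nrbn_function")
    unknown <- setdiff(f$inputs, nodes)
    if (length(unknown)) stop("function for ", n,
                              " references unknown regulator(s): ",
                              paste(unknown, collapse = ", "))
  }
  structure(list(nodes = nodes, functions = functions, core = core,
                 clamps = cl),
            class = "nrbn_network")
}

#' Number of nodes of a network
#' @param net an `nrbn_network`.
#' @return integer node count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' Are all node functions set?
#' @param net an `nrbn_network`.
#' @return `TRUE` iff every node has a Boolean function.
#' @export
functions_set <- function(net) !any(vapply(net$functions, is.null, logical(1)))

#' Directed edge list of a network
#'
#' One row per regulatory interaction (regulator -> target), implied by
#' the function input lists.
#'
#' @param net an `nrbn_network`.
#' @return data.frame with columns `from`, `to`.
#' @export
network_edges <- function(net) {
  in_lists <- attr(net, "in_lists")
  regs <- lapply(seq_along(net$nodes), function(i) {
    f <- net$functions[[i]]
    if (!is.null(f)) f$inputs
    else if (!is.null(in_lists)) as.character(in_lists[[i]])
    else character()
  })
  data.frame(from = as.character(unlist(regs, use.names = FALSE)),
             to = rep(net$nodes, lengths(regs)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Number of edges of a network
#' @param net an `nrbn_network`.
#' @return integer edge count.
#' @export
n_edges <- function(net) nrow(network_edges(net))

# Low-level representation consumed by the C++ engine: 0-based regulator
# index lists, truth tables and a -1/0/1 clamp vector.
net_to_engine <- function(net) {
  if (!functions_set(net))
    stop("network has unset functions; set or generate them before simulating")
  idx <- seq_along(net$nodes)
  names(idx) <- net$nodes
  list(reg = lapply(net$functions, function(f) as.integer(idx[f$inputs] - 1L)),
       tab = lapply(net$functions, function(f) f$table),
       clamp = ifelse(is.na(net$clamps), -1L, net$clamps))
}

#' Synchronous update of a network state
#'
#' All nodes are updated simultaneously from the current state, each by
#' its own Boolean function; clamped nodes take their clamp value
#' regardless of their function. The dynamics is deterministic.
#'
#' @param net an `nrbn_network` with functions set.
#' @param state vector of 0/1 values in node order.
#' @return the next state (integer vector of 0/1).
#' @export
step_network <- function(net, state) {
  state <- check_state(net, state)
  eng <- net_to_engine(net)
  drop(C_step_many(eng$reg, eng$tab, eng$clamp,
                   matrix(state, nrow = 1), 1L))
}

check_state <- function(net, state) {
  s <- as.integer(state)
  if (length(s) != length(net$nodes))
    stop("state length ", length(s), " != node count ", length(net$nodes))
  if (!all(s %in% c(0L, 1L))) stop("state values must be 0 or 1")
  s
}

#' Iterate the synchronous dynamics from an initial state
#'
#' Applies [step_network()] repeatedly, stopping as soon as a previously
#' visited state recurs (the orbit has entered a cycle) or after
#' `max_steps` updates. Non-closure within the budget is reported, not an
#' error.
#'
#' @param net an `nrbn_network` with functions set.
#' @param s0 initial state.
#' @param max_steps maximum number of synchronous updates (>= 1).
#' @return a list with `states` (matrix of distinct visited states, rows
#'   in visit order starting at `s0`), `closed` (logical), and `entry`
#'   (1-based row index the orbit re-entered; `NA` when not closed).
#' @export
trajectory <- function(net, s0, max_steps = 1000L) {
  stopifnot(max_steps >= 1)
  s0 <- check_state(net, s0)
  eng <- net_to_engine(net)
  res <- C_trajectory(eng$reg, eng$tab, eng$clamp, s0, as.integer(max_steps))
  colnames(res$states) <- net$nodes
  res
}

#' Encode / decode a network state as an integer code
#'
#' The code is the integer whose binary digits are the node values in node
#' order, the first node being the most significant bit. Exact up to
#' N = 53 nodes (double precision); larger networks use states directly.
#'
#' @param state vector of 0/1 values.
#' @param code non-negative numeric code.
#' @param n number of nodes.
#' @return `encode_state`: a numeric code; `decode_state`: an integer
#'   vector of 0/1.
#' @export
encode_state <- function(state) {
  n <- length(state)
  if (n > 53) stop("integer encoding exact only up to 53 nodes")
  sum(as.numeric(state) * 2^((n - 1):0))
}

#' @rdname encode_state
#' @export
decode_state <- function(code, n) {
  out <- integer(n)
  for (j in seq_len(n)) {
    w <- 2^(n - j)
    if (code >= w) { out[j] <- 1L; code <- code - w }
  }
  out
}

#' Clamp, knock out or knock in genes
#'
#' A knockout permanently forces a gene's value to 0 (its Boolean function
#' is silenced: 0 output for any regulatory input); a knock-in forces 1.
#' Clamps are overrides: the wild-type function is retained and can be
#' restored with `release_clamps()`.
#'
#' @param net an `nrbn_network`.
#' @param genes character vector of node names.
#' @param value forced value, 0 or 1.
#' @return a modified copy of the network; the input is untouched.
#' @export
knockout <- function(net, genes) clamp_nodes(net, genes, 0L)

#' @rdname knockout
#' @export
knockin <- function(net, genes) clamp_nodes(net, genes, 1L)

#' @rdname knockout
#' @export
clamp_nodes <- function(net, genes, value) {
  stopifnot(inherits(net, "nrbn_network"))
  unknown <- setdiff(genes, net$nodes)
  if (length(unknown)) stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  if (!(value %in% c(0L, 1L))) stop("clamp value must be 0 or 1")
  net$clamps[genes] <- as.integer(value)
  net
}

#' @rdname knockout
#' @export
release_clamps <- function(net, genes = net$nodes) {
  net$clamps[genes] <- NA_integer_
  net
}

#' Reorder the nodes of a network
#'
#' Relabels positions by a permutation, with consistent re-indexing of
#' functions, core flags and clamps. The synchronous dynamics commutes
#' with node reordering.
#'
#' @param net an `nrbn_network`.
#' @param perm a permutation of `seq_len(n_nodes(net))` giving the new
#'   order.
#' @return the reordered network.
#' @export
permute_network <- function(net, perm) {
  stopifnot(identical(sort(perm), seq_along(net$nodes)))
  regulatory_network(net$functions[perm], core = net$core[perm],
                     clamps = {
                       cl <- net$clamps[perm]
                       cl <- cl[!is.na(cl)]
                       if (length(cl)) cl else NULL
                     })
}

#' Convert a network to an igraph object
#' @param net an `nrbn_network`.
#' @return a directed `igraph` graph; vertex attribute `core` is kept.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(network_edges(net), directed = TRUE,
                                     vertices = data.frame(name = net$nodes,
                                                           core = net$core))
  g
}

#' @export
print.nrbn_network <- function(x, ...) {
  e <- network_edges(x)
  cat("NRBN regulatory network: ", length(x$nodes), " nodes, ",
      nrow(e), " edges\n", sep = "")
  cat("  core nodes: ", sum(x$core), "; augmented: ", sum(!x$core), "\n",
      sep = "")
  if (!functions_set(x)) cat("  functions: not set (topology only)\n")
  ncl <- sum(!is.na(x$clamps))
  if (ncl) cat("  clamped nodes: ", ncl, "\n", sep = "")
  invisible(x)
}

#' @export
summary.nrbn_network <- function(object, ...) {
  e <- network_edges(object)
  indeg <- table(factor(e$to, levels = object$nodes))
  biases <- if (functions_set(object))
    vapply(object$functions, function_bias, numeric(1)) else NULL
  out <- list(n_nodes = length(object$nodes), n_edges = nrow(e),
              mean_in_degree = mean(indeg),
              mean_bias = if (is.null(biases)) NA_real_ else mean(biases))
  class(out) <- "summary.nrbn_network"
  out
}

#' @export
print.summary.nrbn_network <- function(x, ...) {
  cat("nodes:", x$n_nodes, " edges:", x$n_edges,
      " mean in-degree:", format(x$mean_in_degree),
      " mean bias:", format(x$mean_bias), "\n")
  invisible(x)
}
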