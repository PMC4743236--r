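# Plain-text readers/writers. The network format is line-oriented:
#   nodes <N>
#   node <name> core|augmented
#   fn <name> <regulator,...> table <bitstring of length 2^k>
#   fn <name> expr <AND/OR/NOT formula>
# A zero-input constant is written as `fn <name> - table <bit>`.
# All writers are canonical (stable ordering), so reproducibility is
# byte-testable. SIF and GraphML are export formats for external viewers;
# SIF can also be imported topology-only.

#' Write / read a network in the package text format
#'
#' `write_network` is canonical: reading the file back and writing it
#' again reproduces it byte for byte. `read_network` reports malformed
#' lines with their line number. SBML files are detected and refused
#' (SBML-qual support is not implemented).
#'
#' @param net an `nrbn_network`.
#' @param path file path.
#' @return `read_network` returns an `nrbn_network`; `write_network`
#'   returns `path` invisibly.
#' @export
write_network <- function(net, path) {
  lines <- c(paste("nodes", length(net$nodes)),
             paste("node", net$nodes,
                   ifelse(net$core, "core", "augmented")))
  for (nd in net$nodes) {
    f <- net$functions[[nd]]
    if (is.null(f)) next
    lines <- c(lines, if (!is.null(f$expr))
      paste("fn", nd, "expr", f$expr)
    else
      paste("fn", nd,
            if (length(f$inputs)) paste(f$inputs, collapse = ",") else "-",
            "table", paste(f$table, collapse = "")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("<sbml", lines, fixed = TRUE)))
    stop("this looks like an SBML file; SBML-qual import is not supported")
  perr <- function(i, msg) stop("parse error at line ", i, ": ", msg,
                                call. = FALSE)
  lines_t <- trimws(lines)
  keep <- which(nzchar(lines_t) & !startsWith(lines_t, "#"))
  if (!length(keep)) stop("empty network file")
  first <- strsplit(lines_t[keep[1]], "\\s+")[[1]]
  if (first[1] != "nodes" || length(first) != 2) perr(keep[1],
                                                     "expected `nodes N`")
  n_decl <- as.integer(first[2])
  nodes <- character(0); core <- logical(0)
  fn_lines <- list()
  for (i in keep[-1]) {
    tok <- strsplit(lines_t[i], "\\s+")[[1]]
    if (tok[1] == "node") {
      if (length(tok) != 3 || !(tok[3] %in% c("core", "augmented")))
        perr(i, "expected `node <name> core|augmented`")
      nodes <- c(nodes, tok[2]); core <- c(core, tok[3] == "core")
    } else if (tok[1] == "fn") {
      fn_lines[[length(fn_lines) + 1L]] <- list(i = i, tok = tok,
                                                raw = lines_t[i])
    } else perr(i, paste("unknown directive:", tok[1]))
  }
  if (length(nodes) != n_decl)
    stop("declared ", n_decl, " nodes but found ", length(nodes))
  fns <- setNames(vector("list", length(nodes)), nodes)
  for (fl in fn_lines) {
    tok <- fl$tok
    if (length(tok) < 3) perr(fl$i, "truncated fn line")
    nd <- tok[2]
    if (!(nd %in% nodes)) perr(fl$i, paste("unknown node:", nd))
    if (tok[3] == "expr") {
      expr <- sub("^\\s*fn\\s+\\S+\\s+expr\\s+", "", fl$raw)
      f <- tryCatch(boolean_function(expr = expr),
                    error = function(e) perr(fl$i, conditionMessage(e)))
    } else {
      if (length(tok) != 5 || tok[4] != "table")
        perr(fl$i, "expected `fn <name> <regs> table <bits>`")
      inputs <- if (tok[3] == "-") character() else
        strsplit(tok[3], ",", fixed = TRUE)[[1]]
      bits <- strsplit(tok[5], "")[[1]]
      if (!all(bits %in% c("0", "1"))) perr(fl$i, "table must be 0/1 bits")
      if (length(bits) != 2^length(inputs))
        perr(fl$i, sprintf("table length %d does not match 2^%d inputs",
                           length(bits), length(inputs)))
      f <- tryCatch(boolean_function(inputs, as.integer(bits)),
                    error = function(e) perr(fl$i, conditionMessage(e)))
    }
    unknown <- setdiff(f$inputs, nodes)
    if (length(unknown))
      stop("reference error at line ", fl$i, ": unknown regulator(s) ",
           paste(unknown, collapse = ", "), call. = FALSE)
    fns[[nd]] <- f
  }
  regulatory_network(fns, core = core)
}

#' Export a network edge list in SIF format
#'
#' One line per interaction: `<source> regulates <target>`.
#'
#' @param net an `nrbn_network`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  e <- network_edges(net)
  e <- e[order(e$from, e$to), , drop = FALSE]
  writeLines(paste(e$from, "regulates", e$to), path)
  invisible(path)
}

#' Import a topology-only network from a SIF edge list
#'
#' Functions are left unset; generate them (or load a fully characterized
#' network) before simulating.
#'
#' @param path file path.
#' @return an `nrbn_network` with functions unset.
#' @export
read_sif <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\\s+")
  bad <- which(vapply(parts, length, integer(1)) != 3)
  if (length(bad)) stop("parse error at line ", bad[1],
                        ": expected `<source> <relation> <target>`")
  from <- vapply(parts, `[`, character(1), 1)
  to <- vapply(parts, `[`, character(1), 3)
  nodes <- sort(unique(c(from, to)))
  in_lists <- split(from, factor(to, levels = nodes))
  network_from_in_edges(nodes, lapply(in_lists, as.character))
}

#' Export a network in GraphML format
#'
#' Minimal GraphML (directed; `core` as a node attribute) readable by
#' Cytoscape and other graph viewers.
#'
#' @param net an `nrbn_network`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  e <- network_edges(net)
  e <- e[order(e$from, e$to), , drop = FALSE]
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="core" for="node" attr.name="core" attr.type="boolean"/>',
    '  <graph id="G" edgedefault="directed">',
    sprintf('    <node id="%s"><data key="core">%s</data></node>',
            net$nodes, tolower(as.character(net$core))),
    sprintf('    <edge source="%s" target="%s"/>', e$from, e$to),
    "  </graph>",
    "</graphml>")
  writeLines(lines, path)
  invisible(path)
}

## ---- trees ------------------------------------------------------------

#' Read / write a rooted tree
#'
#' Tab-separated parent/child edge lists (`parent<TAB>child`, root
#' declared in a `# root: <label>` comment or inferred as the label that
#' is never a child) and Newick (topology plus labels; parsed with
#' \pkg{ape}). Round-trips preserve the shape table exactly and labels
#' where present.
#'
#' @param path file path; format chosen by extension (`.nwk`/`.newick`
#'   for Newick, otherwise TSV) or by `format`.
#' @param tree an `nrbn_tree`.
#' @param format `"tsv"` or `"newick"`.
#' @return `read_tree` returns an `nrbn_tree`.
#' @export
read_tree <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.(nwk|newick|tree)$", path)) "newick" else "tsv"
  if (format == "newick") {
    phy <- ape::read.tree(path)
    return(phylo_to_tree(phy))
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  root_decl <- sub("^#\\s*root:\\s*", "", grep("^#\\s*root:", lines, value = TRUE))
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) {
    if (length(root_decl) == 1)          # single-node tree: root only
      return(differentiation_tree(root_decl, NA_integer_))
    stop("empty tree file")
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2)
  if (length(bad)) stop("parse error: expected `parent<TAB>child` at data line ",
                        bad[1])
  parents <- vapply(parts, `[`, character(1), 1)
  children <- vapply(parts, `[`, character(1), 2)
  tree <- tree_from_edges(parents, children)
  if (length(root_decl) == 1) {
    root <- tree$labels[is.na(tree$parent)]
    if (!identical(root, root_decl))
      stop("declared root ", root_decl, " but edges imply root ", root)
  }
  tree
}

#' @rdname read_tree
#' @export
write_tree <- function(tree, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.(nwk|newick|tree)$", path)) "newick" else "tsv"
  if (format == "newick") {
    writeLines(tree_to_newick(tree), path)
    return(invisible(path))
  }
  root <- tree$labels[is.na(tree$parent)]
  ord <- preorder_indices(tree)
  lines <- c(paste0("# root: ", root),
             unlist(lapply(ord, function(i) {
               kids <- which(tree$parent == i)
               if (!length(kids)) return(character(0))
               paste0(tree$labels[i], "\t", tree$labels[kids])
             })))
  writeLines(lines, path)
  invisible(path)
}

preorder_indices <- function(tree) {
  root <- which(is.na(tree$parent))
  out <- integer(0)
  visit <- function(i) {
    out <<- c(out, i)
    for (k in which(tree$parent == i)) visit(k)
  }
  for (r in root) visit(r)
  out
}

tree_to_newick <- function(tree) {
  lab <- gsub("[,;:()\\[\\]\\s]", "_", tree$labels, perl = TRUE)
  rec <- function(i) {
    kids <- which(tree$parent == i)
    if (!length(kids)) return(lab[i])
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","),
           ")", lab[i])
  }
  root <- which(is.na(tree$parent))
  paste0(rec(root[1]), ";")
}

phylo_to_tree <- function(phy) {
  n_tip <- length(phy$tip.label)
  n_node <- phy$Nnode
  labels <- c(phy$tip.label,
              if (!is.null(phy$node.label) && length(phy$node.label))
                phy$node.label
              else paste0("I", seq_len(n_node)))
  labels[!nzchar(labels)] <- paste0("I", which(!nzchar(labels)))
  if (anyDuplicated(labels)) labels <- make.unique(labels, sep = "_")
  parent <- rep(NA_integer_, n_tip + n_node)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  differentiation_tree(labels, parent)
}

## ---- fixtures ---------------------------------------------------------

#' Synthetic 40-gene / 51-interaction core network
#'
#' A fully characterized stand-in for a curated signalling core of the
#' size used in the augmentation worked example (the published T-helper
#' wiring itself is not redistributed here): 40 genes wired as an
#' Erdos-Renyi random digraph with 51 interactions and bias-0.5 random
#' Boolean functions, from a fixed internal seed. Identical to the copy
#' shipped in `inst/extdata/synthetic_thelper_core.txt`.
#'
#' @return an `nrbn_network` with 40 nodes and 51 edges, all core.
#' @export
synthetic_core_network <- function() {
  spec <- generation_spec(40, topology = "erdos-renyi", n_edges = 51,
                          function_scheme = "bias-random", bias = 0.5)
  generate_network(spec, seed = 20160204L)
}

#' The hematopoietic differentiation tree
#'
#' The standard rooted scheme from the multipotent progenitor (MPP)
#' through the common myeloid (CMP) and lymphoid (CLP) progenitors down
#' to mature blood cells: MEP to erythrocytes (EC) and megakaryocytes
#' (MK); GMP to monocytes (M) and granulocytes (N/E/B); B and T/NK
#' progenitors to B, T and NK cells. 14 nodes, depth 3 (four levels).
#' The MEP/GMP parent assignment of the mature myeloid types follows the
#' standard scheme. Also shipped as
#' `inst/extdata/hematopoietic_tree.tsv`.
#'
#' @return an `nrbn_tree`.
#' @export
hematopoietic_tree <- function() {
  edges <- list(
    c("MPP", "CMP"), c("MPP", "CLP"),
    c("CMP", "MEP"), c("CMP", "GMP"),
    c("MEP", "EC"), c("MEP", "MK"),
    c("GMP", "M"), c("GMP", "N/E/B"),
    c("CLP", "B_PROG"), c("CLP", "T/NK_PROG"),
    c("B_PROG", "B"),
    c("T/NK_PROG", "T"), c("T/NK_PROG", "NK"))
  tree_from_edges(vapply(edges, `[`, character(1), 1),
                  vapply(edges, `[`, character(1), 2))
}

#' Small worked-example networks
#'
#' `toggle_cycle_network()`: two genes, `n1 := n2`, `n2 := NOT n1`; a
#' single length-4 attractor. `and_pair_network()`: `n1 := n1 AND n2`,
#' `n2 := n1 AND n2`; two fixed points with basins 3 and 1.
#'
#' @return an `nrbn_network`.
#' @export
toggle_cycle_network <- function() {
  regulatory_network(list(
    n1 = boolean_function("n2", c(0L, 1L)),
    n2 = boolean_function(expr = "NOT n1")))
}

#' @rdname toggle_cycle_network
#' @export
and_pair_network <- function() {
  regulatory_network(list(
    n1 = boolean_function(c("n1", "n2"), c(0L, 0L, 0L, 1L)),
    n2 = boolean_function(c("n1", "n2"), c(0L, 0L, 0L, 1L))))
}

#' Export an atlas as text files
#'
#' Writes one attractor state matrix per attractor (rows = cycle states,
#' columns = genes) to `<path>` plus a CSV of per-attractor statistics
#' (length, basin, reachability, frozen proportion).
#'
#' @param atlas an `nrbn_atlas`.
#' @param path output file for the state matrices.
#' @param stats_path optional CSV path for the statistics table.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path, stats_path = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (a in atlas$attractors) {
    writeLines(sprintf("attractor %d length %d basin %d", a$id, a$length,
                       a$basin), con)
    writeLines(paste(atlas$nodes, collapse = " "), con)
    writeLines(apply(a$states, 1, paste, collapse = " "), con)
    writeLines("", con)
  }
  if (!is.null(stats_path)) {
    st <- attractor_statistics(atlas)
    tab <- st$basin_table
    tab$frozen_proportion <- st$frozen_proportion
    write.csv(format_num_df(tab), stats_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# stable decimal formatting so writers are byte-reproducible
format_num_df <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.10g", df[[j]])
  df
}
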