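# Batch sessions: one YAML (or list) configuration drives a chain of
# stages — generate/augment -> simulate -> atm -> tree -> match -> perturb
# -> stats — with all randomness derived from one master seed and every
# artifact written as plain text, so a rerun with the same configuration
# reproduces the output directory byte for byte.

#' Validate a session configuration
#'
#' @param config a list or a YAML file path. Recognised top-level fields:
#'   `seed` (integer, required), `stages` (character vector), `core`
#'   (path to a network file, or `"synthetic"` for the bundled core),
#'   and per-stage blocks `generate`, `augment`, `simulate`, `atm`,
#'   `tree`, `match`, `perturb`.
#' @return the resolved configuration (defaults filled in).
#' @export
session_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$seed)) stop("config error: `seed` is required")
  config$seed <- as.integer(config$seed)
  if (is.null(config$stages)) config$stages <- character()
  known <- c("generate", "augment", "simulate", "atm", "tree", "match",
             "perturb", "stats")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stop("config error: unknown stage(s): ",
                        paste(bad, collapse = ", "))
  if ("generate" %in% config$stages && "augment" %in% config$stages)
    stop("config error: use either `generate` or `augment`, not both")
  dflt <- function(block, defaults) {
    b <- config[[block]]
    if (is.null(b)) b <- list()
    for (nm in names(defaults)) if (is.null(b[[nm]])) b[[nm]] <- defaults[[nm]]
    b
  }
  config$simulate <- dflt("simulate", list(mode = "sampled", n_samples = 500L,
                                           max_steps = 1000L))
  config$atm <- dflt("atm", list(flip_duration = 1L, max_phases = 8L,
                                 max_steps = 1000L))
  config$tree <- dflt("tree", list(depth = 4L, n_threshold_samples = 50L,
                                   enumerate_cap = 200L))
  config$match <- dflt("match", list(tolerance = 0))
  config$perturb <- dflt("perturb", list(kind = "knockout", targets = "all",
                                         repetitions = 1L))
  config
}

#' Run a batch session
#'
#' Executes the configured stage chain, logging per-stage progress and
#' writing all artifacts (networks, attractor summaries, ATN edge lists,
#' trees, match and perturbation reports, network statistics) under
#' `out_dir`, together with the resolved configuration and the package
#' version. A stage failure halts the chain with prior artifacts intact.
#' Reruns with the same configuration are byte-identical.
#'
#' @param config list or YAML path (see [session_config()]).
#' @param out_dir output directory (created; must be empty or absent).
#' @param quiet suppress progress messages.
#' @return `out_dir`, invisibly.
#' @export
run_session <- function(config, out_dir, quiet = FALSE) {
  cfg <- session_config(config)
  if (dir.exists(out_dir) && length(list.files(out_dir)))
    stop("output directory exists and is not empty: ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[session] ", ...)

  cfg_out <- cfg
  cfg_out$package_version <- as.character(packageVersion("nrbnkit"))
  yaml::write_yaml(cfg_out, file.path(out_dir, "session_config.yaml"))

  set.seed(cfg$seed)
  stage_seeds <- setNames(as.list(sample.int(.Machine$integer.max, 8)),
                          c("generate", "augment", "simulate", "atm", "tree",
                            "match", "perturb", "stats"))

  networks <- NULL
  if ("generate" %in% cfg$stages) {
    g <- cfg$generate
    spec <- generation_spec(g$n_nodes, topology = g$topology %||% "erdos-renyi",
                            n_edges = g$n_edges, k = g$k,
                            function_scheme = g$function_scheme %||% "bias-random",
                            bias = g$bias %||% 0.5)
    networks <- generate_ensemble(spec, g$count %||% 1L,
                                  seed = stage_seeds$generate)
    say("generated ", length(networks), " network(s)")
  }
  if ("augment" %in% cfg$stages) {
    a <- cfg$augment
    core <- if (is.null(cfg$core) || identical(cfg$core, "synthetic"))
      synthetic_core_network() else read_network(cfg$core)
    spec <- augmentation_spec(a$n_nodes, a$n_edges,
                              topology = a$topology %||% "erdos-renyi",
                              function_scheme = a$function_scheme %||% "bias-random",
                              bias = a$bias %||% 0.5)
    networks <- generate_ensemble(spec, a$count %||% 1L,
                                  seed = stage_seeds$augment, core = core)
    say("augmented core to ", length(networks), " network(s) of ",
        spec$n_nodes, " nodes / ", spec$n_edges, " edges")
  }
  if (!is.null(networks)) {
    dir.create(file.path(out_dir, "networks"))
    for (i in seq_along(networks))
      write_network(networks[[i]],
                    file.path(out_dir, "networks",
                              sprintf("net_%03d.txt", i)))
  }

  atlases <- NULL
  if ("simulate" %in% cfg$stages) {
    if (is.null(networks)) stop("simulate stage requires generate/augment")
    s <- cfg$simulate
    set.seed(stage_seeds$simulate)
    seeds <- sample.int(.Machine$integer.max, length(networks))
    atlases <- lapply(seq_along(networks), function(i)
      find_attractors(networks[[i]], s$mode, n_samples = s$n_samples,
                      max_steps = s$max_steps, seed = seeds[i]))
    summ <- do.call(rbind, lapply(seq_along(atlases), function(i) {
      lens <- vapply(atlases[[i]]$attractors, `[[`, integer(1), "length")
      data.frame(network = i, n_attractors = length(lens),
                 lengths = paste(lens, collapse = ";"),
                 unresolved = atlases[[i]]$unresolved_count)
    }))
    write.csv(summ, file.path(out_dir, "attractor_summary.csv"),
              row.names = FALSE, quote = FALSE)
    say("simulated ", length(atlases), " network(s); attractor counts: ",
        paste(summ$n_attractors, collapse = ","))
  }

  atms <- NULL
  if ("atm" %in% cfg$stages) {
    if (is.null(atlases)) stop("atm stage requires simulate")
    a <- cfg$atm
    set.seed(stage_seeds$atm)
    seeds <- sample.int(.Machine$integer.max, length(networks))
    dir.create(file.path(out_dir, "atn"))
    atms <- lapply(seq_along(networks), function(i) {
      if (length(atlases[[i]]$attractors) == 0) return(NULL)
      atm <- suppressWarnings(
        build_atm(networks[[i]], atlases[[i]], duration = a$flip_duration,
                  max_phases = a$max_phases, max_steps = a$max_steps,
                  seed = seeds[i]))
      el <- atm_edge_list(atm)
      write.table(format_num_df(el),
                  file.path(out_dir, "atn", sprintf("atn_%03d.txt", i)),
                  row.names = FALSE, col.names = FALSE, quote = FALSE)
      atm
    })
    say("built ", sum(!vapply(atms, is.null, logical(1))), " ATM(s)")
  }

  target <- NULL
  if (any(c("tree", "match") %in% cfg$stages)) {
    tgt <- cfg$match$target_tree %||% cfg$tree$target_tree
    target <- if (is.null(tgt) || identical(tgt, "hematopoietic"))
      hematopoietic_tree() else read_tree(tgt)
  }

  if ("tree" %in% cfg$stages) {
    if (is.null(atms)) stop("tree stage requires atm")
    t <- cfg$tree
    set.seed(stage_seeds$tree)
    seeds <- sample.int(.Machine$integer.max, length(networks))
    dir.create(file.path(out_dir, "trees"))
    for (i in seq_along(atms)) {
      if (is.null(atms[[i]])) next
      rep <- representative_tree(atms[[i]], depth = t$depth,
                                 n_threshold_samples = t$n_threshold_samples,
                                 seed = seeds[i],
                                 enumerate_cap = t$enumerate_cap)
      write_tree(rep$tree,
                 file.path(out_dir, "trees", sprintf("tree_%03d.tsv", i)))
    }
    say("wrote representative trees")
  }

  if ("match" %in% cfg$stages) {
    if (is.null(networks)) stop("match stage requires networks")
    m <- cfg$match
    t <- cfg$tree
    if (!is.null(atms)) {
      # reuse the ATMs computed by the atm stage
      set.seed(stage_seeds$match)
      seeds <- sample.int(.Machine$integer.max, length(networks))
      report <- do.call(rbind, lapply(seq_along(atms), function(i) {
        if (is.null(atms[[i]]))
          return(data.frame(network = i, n_attractors = 0L,
                            best_distance = NA_real_, matched = NA,
                            thresholds = NA_character_))
        bm <- best_tree_match(atms[[i]], target,
                              n_threshold_samples = t$n_threshold_samples,
                              seed = seeds[i],
                              enumerate_cap = t$enumerate_cap)
        data.frame(network = i,
                   n_attractors = length(atms[[i]]$atlas$attractors),
                   best_distance = bm$distance,
                   matched = bm$distance <= m$tolerance,
                   thresholds = paste(signif(bm$thresholds, 6),
                                      collapse = ";"))
      }))
    } else {
      report <- match_ensemble(networks, target, tolerance = m$tolerance,
                               n_samples = cfg$simulate$n_samples,
                               max_steps = cfg$simulate$max_steps,
                               max_phases = cfg$atm$max_phases,
                               atm_max_steps = cfg$atm$max_steps,
                               n_threshold_samples = t$n_threshold_samples,
                               enumerate_cap = t$enumerate_cap,
                               seed = stage_seeds$match)
    }
    write.csv(format_num_df(report), file.path(out_dir, "match_report.csv"),
              row.names = FALSE, quote = FALSE)
    say("match report: ", sum(report$matched, na.rm = TRUE), " of ",
        nrow(report), " network(s) within tolerance ", m$tolerance)
  }

  if ("perturb" %in% cfg$stages) {
    if (is.null(networks)) stop("perturb stage requires networks")
    p <- cfg$perturb
    set.seed(stage_seeds$perturb)
    seeds <- sample.int(.Machine$integer.max, length(networks))
    dir.create(file.path(out_dir, "perturb"))
    for (i in seq_along(networks)) {
      exps <- run_perturbations(networks[[i]], kind = p$kind,
                                targets = p$targets,
                                repetitions = p$repetitions,
                                seed = seeds[i])
      out <- exps[, c("target", "rep", "avalanche", "resolved")]
      write.csv(out,
                file.path(out_dir, "perturb", sprintf("perturb_%03d.csv", i)),
                row.names = FALSE, quote = FALSE)
    }
    say("perturbation reports written")
  }

  if ("stats" %in% cfg$stages) {
    if (is.null(networks)) stop("stats stage requires networks")
    st <- do.call(rbind, lapply(seq_along(networks), function(i) {
      ms <- network_measures(networks[[i]])
      data.frame(network = i,
                 clustering = ms$clustering_coefficient,
                 diameter = ms$diameter,
                 average_path_length = ms$average_path_length,
                 mean_in_degree = ms$mean_in_degree)
    }))
    write.csv(format_num_df(st), file.path(out_dir, "network_stats.csv"),
              row.names = FALSE, quote = FALSE)
    say("network statistics written")
  }

  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
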