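#' Read and validate a run configuration
#'
#' Flat YAML config driving the end-to-end pipelines. Recognized fields:
#' `measurements` (CSV path), `tip_states` (CSV path), `consensus_tree`
#' (Newick path), `tree_sample` (multi-tree Newick/Nexus path), `indices`
#' (subset of RDT/IFA/TJI), `output_dir`, `seed`, and optional `model`
#' (`chains`, `iter`, `warmup`) and `simmap` (`model`, `root_prior`,
#' `n_maps_per_tree`) blocks.
#'
#' @param path YAML file path, or a named list already in config shape.
#' @return Validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) abort(paste0("config file not found: ", path))
    yaml::read_yaml(path)
  } else as.list(path)
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$indices <- cfg$indices %||% c("RDT", "IFA", "TJI")
  bad <- setdiff(cfg$indices, c("RDT", "IFA", "TJI"))
  if (length(bad) > 0L) abort(paste0("unknown index: ", paste(bad, collapse = ", ")))
  cfg$output_dir <- cfg$output_dir %||% "."
  cfg$model <- utils::modifyList(list(chains = 4L, iter = 5000L, warmup = 0.5),
                                 cfg$model %||% list())
  cfg$simmap <- utils::modifyList(
    list(model = "ER", root_prior = "equal", n_maps_per_tree = NULL),
    cfg$simmap %||% list())
  for (f in c("measurements", "tip_states", "consensus_tree", "tree_sample")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      abort(paste0("configured ", f, " file not found: ", cfg[[f]]))
    }
  }
  structure(cfg, class = c("run_config", "list"))
}

#' @keywords internal
#' FNV-1a hash of the deparsed config, stamped on every output table.
config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @keywords internal
write_report_csv <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d config=%s", cfg$seed, config_hash(cfg)), con)
  write.csv(format(as.data.frame(df), digits = 10, trim = TRUE), con,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the regression analysis end-to-end
#'
#' Reads the measurement table and consensus tree, computes the
#' morpho-functional indices, and for each configured index: builds the
#' regression dataset (species lacking the superstructure drop out via their
#' missing index values), fits the body-mass and intercept-only models,
#' compares them by WAIC, and writes posterior-summary, comparison, and
#' variance-share tables to `output_dir`. Convergence failures (R-hat >
#' 1.05) are flagged in the summary table and a warning is raised.
#'
#' @param config A `run_config` (or path to one). Requires `measurements` and
#'   `consensus_tree`.
#' @return Invisibly, a named list per index with `fit_bm`, `fit_no_bm`,
#'   `comparison`, `summary`, `shares`, `dataset`.
#' @export
run_regression_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  for (f in c("measurements", "consensus_tree")) {
    if (is.null(cfg[[f]])) abort(paste0("config lacks required field: ", f))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", name, "] ", conditionMessage(e)))
    })
  }
  measurements <- stage("read-measurements", read.csv(cfg$measurements))
  tree <- stage("read-tree", validate_tree(ape::read.tree(cfg$consensus_tree)))
  records <- if (all(c("index", "value") %in% names(measurements))) {
    tibble::as_tibble(measurements)  # already an index table
  } else {
    stage("compute-indices", compute_indices(measurements))
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  for (idx in intersect(cfg$indices, unique(records$index))) {
    ds <- stage(paste0("build-dataset-", idx),
                build_dataset(records, idx, tree))
    n_dropped <- sum(records$index == idx) - ds$n
    if (n_dropped > 0) {
      message(sprintf("[%s] excluded %d rows with missing index values", idx,
                      n_dropped))
    }
    fit_bm <- stage(paste0("fit-bm-", idx), fit_varying_effects(
      ds, include_bm = TRUE, chains = cfg$model$chains, iter = cfg$model$iter,
      warmup = cfg$model$warmup, seed = spawn_seed(cfg$seed, paste0("bm", idx))))
    fit_nb <- stage(paste0("fit-nobm-", idx), fit_varying_effects(
      ds, include_bm = FALSE, chains = cfg$model$chains, iter = cfg$model$iter,
      warmup = cfg$model$warmup, seed = spawn_seed(cfg$seed, paste0("nb", idx))))
    cmp <- compare_models(fit_bm, fit_nb, labels = c("with_bm", "without_bm"))
    summ <- dplyr::bind_rows(
      dplyr::mutate(tidy(fit_bm), model = "with_bm"),
      dplyr::mutate(tidy(fit_nb), model = "without_bm")
    )
    if (any(!summ$converged, na.rm = TRUE)) {
      warn(sprintf("[%s] %d parameter(s) with R-hat > 1.05", idx,
                   sum(!summ$converged, na.rm = TRUE)))
    }
    shares <- variance_shares(fit_bm)
    write_report_csv(summ, file.path(cfg$output_dir,
                                     paste0("regression_summary_", idx, ".csv")), cfg)
    write_report_csv(cmp, file.path(cfg$output_dir,
                                    paste0("waic_comparison_", idx, ".csv")), cfg)
    write_report_csv(shares, file.path(cfg$output_dir,
                                       paste0("variance_shares_", idx, ".csv")), cfg)
    out[[idx]] <- list(fit_bm = fit_bm, fit_no_bm = fit_nb, comparison = cmp,
                       summary = summ, shares = shares, dataset = ds)
  }
  if (length(out) == 0L) abort("no configured index present in the measurement table")
  invisible(out)
}

#' Run the ancestral-state reconstruction end-to-end
#'
#' Reads the tip-state table and the posterior tree sample, and for every
#' character with at least two observed states estimates the Mk generator per
#' tree, samples stochastic character maps, pools node states by clade across
#' all (tree, map) draws, and writes one node-posterior CSV per character.
#' Constant characters are skipped with a notice.
#'
#' @param config A `run_config` (or path). Requires `tip_states` and
#'   `tree_sample`.
#' @return Invisibly, a named list of `node_pp` tables per character, with a
#'   `skipped` attribute naming constant characters.
#' @export
run_asr_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  for (f in c("tip_states", "tree_sample")) {
    if (is.null(cfg[[f]])) abort(paste0("config lacks required field: ", f))
  }
  states <- tryCatch(tibble::as_tibble(read.csv(cfg$tip_states)),
                     error = function(e) abort(paste0("[read-tip-states] ",
                                                      conditionMessage(e))))
  trees <- tryCatch(read_tree_sample(cfg$tree_sample),
                    error = function(e) abort(paste0("[read-tree-sample] ",
                                                     conditionMessage(e))))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  skipped <- character()
  for (char in unique(states$character)) {
    tv <- tip_state_vector(states, char)
    if (length(unique(tv)) < 2L) {
      message(sprintf("[%s] constant character, skipped", char))
      skipped <- c(skipped, char)
      next
    }
    pp <- tryCatch(
      summarize_node_pp(trees, tv, model = cfg$simmap$model,
                        root_prior = cfg$simmap$root_prior,
                        n_maps_per_tree = cfg$simmap$n_maps_per_tree,
                        seed = spawn_seed(cfg$seed, paste0("asr", char))),
      error = function(e) abort(paste0("[simmap-", char, "] ",
                                       conditionMessage(e))))
    write_report_csv(pp, file.path(cfg$output_dir,
                                   paste0("node_pp_", char, ".csv")), cfg)
    out[[char]] <- pp
  }
  attr(out, "skipped") <- skipped
  invisible(out)
}

#' Generate a synthetic study bundle on disk
#'
#' Writes a complete synthetic input set — measurement CSV, tip-state CSV,
#' consensus tree, and jittered tree sample — in the formats the analysis
#' pipelines consume, plus a `truth.json`-style flat text file recording the
#' generating parameters.
#'
#' @param output_dir Directory to populate.
#' @param seed Integer seed.
#' @param index Index to simulate (default `"IFA"`).
#' @param n_trees Size of the tree sample (default 100).
#' @return Invisibly, a `run_config` pointing at the generated files.
#' @export
simulate_study <- function(output_dir, seed = 1, index = "IFA", n_trees = 100) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- simulate_molerat_study(index = index, seed = seed)
  truth <- attr(rec, "truth")
  write.csv(rec, file.path(output_dir, "measurements.csv"), row.names = FALSE)
  write.csv(molerat_tip_states(), file.path(output_dir, "tip_states.csv"),
            row.names = FALSE)
  write_newick(molerat_reference_tree(),
               file.path(output_dir, "consensus_tree.nwk"))
  write_newick(molerat_reference_tree_sample(n_trees,
                                             seed = spawn_seed(seed, "trees")),
               file.path(output_dir, "tree_sample.nwk"))
  tj <- vapply(truth, function(v) paste(format(v, digits = 12), collapse = ","),
               character(1))
  writeLines(c("{", paste0('  "', names(tj), '": ', ifelse(
    suppressWarnings(is.na(as.numeric(tj))), paste0('"', tj, '"'), tj),
    c(rep(",", length(tj) - 1), "")), "}"),
    file.path(output_dir, "truth.json"))
  cfg <- read_run_config(list(
    measurements = file.path(output_dir, "measurements.csv"),
    tip_states = file.path(output_dir, "tip_states.csv"),
    consensus_tree = file.path(output_dir, "consensus_tree.nwk"),
    tree_sample = file.path(output_dir, "tree_sample.nwk"),
    indices = index, output_dir = output_dir, seed = seed
  ))
  invisible(cfg)
}
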