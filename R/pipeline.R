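#' Pipeline run configuration
#'
#' Bundles every tunable of the end-to-end analysis: the single RNG seed
#' all stages draw from, cohort size, bootstrap replicates (desk-scale
#' default 200; the study-scale run uses 2000), consensus thresholds
#' (strength floor 0.700, direction 0.666), score parameters, CPT
#' pseudocount, cross-validation folds, and file locations.
#'
#' @param seed integer master seed.
#' @param n synthetic cohort size (ignored when `cohort_path` is given).
#' @param replicates bootstrap replicates (>= 1).
#' @param strength_floor,direction_threshold consensus thresholds in
#'   `[0, 1]`.
#' @param alpha,ess G2 test level and BDeu equivalent sample size.
#' @param pseudocount CPT fitting pseudocount.
#' @param folds cross-validation folds.
#' @param cohort_path optional CSV of an existing cohort (replaces the
#'   simulate stage).
#' @param out_dir artifact output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 2024, n = 1073, replicates = 200,
                       strength_floor = 0.700, direction_threshold = 0.666,
                       alpha = 0.05, ess = 1, pseudocount = 1, folds = 10,
                       cohort_path = NULL, out_dir = tempfile("icubn_run_")) {
  if (replicates < 1) stop("replicates must be >= 1")
  if (strength_floor < 0 || strength_floor > 1 ||
      direction_threshold < 0 || direction_threshold > 1) {
    stop("thresholds must be in [0, 1]")
  }
  structure(list(seed = as.integer(seed), n = n, replicates = replicates,
                 strength_floor = strength_floor,
                 direction_threshold = direction_threshold,
                 alpha = alpha, ess = ess, pseudocount = pseudocount,
                 folds = folds, cohort_path = cohort_path,
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> bootstrap structure learning ->
#' consensus -> CPT fitting -> query tree -> diagnostic evaluation, writes
#' every artifact to `config$out_dir` (cohort, confidence table, consensus
#' graph, fitted network, query tree, metrics report, and a `run.json`
#' stamp with the configuration, its MD5 hash, seed, and per-stage
#' durations), and returns the artifacts invisibly. All randomness flows
#' from `config$seed`. Any stage failure aborts with the stage name in
#' the error message.
#'
#' @param config a [run_config()].
#' @param verbose print stage progress.
#' @return (invisibly) list with elements `cohort`, `confidence`,
#'   `consensus`, `dag`, `bn`, `tree`, `metrics`, `cv`, `timings`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), verbose = FALSE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    if (verbose) {
      message(sprintf("[%s] done in %.1fs", name, timings[[name]]))
    }
    res
  }
  cohort <- stage("simulate", {
    if (!is.null(config$cohort_path)) {
      read_cohort(config$cohort_path, default_variable_specs())
    } else {
      generate_cohort(n = config$n, seed = config$seed)
    }
  })
  modelled <- setdiff(names(cohort), "cardiac_index")
  params <- score_params(ess = config$ess, alpha = config$alpha)
  constraints <- sics_constraints(modelled)
  confidence <- stage("learn", {
    bootstrap_confidence(cohort[, modelled, drop = FALSE],
                         replicates = config$replicates,
                         seed = config$seed + 1L,
                         params = params, constraints = constraints,
                         nodes = modelled)
  })
  consensus <- stage("consensus", {
    build_consensus(confidence, config$strength_floor,
                    config$direction_threshold, nodes = sort(modelled))
  })
  dag_final <- stage("orient", {
    orient_undirected(consensus, sics_expert_orientations())
  })
  bn <- stage("fit", {
    complete <- cohort[, modelled, drop = FALSE]
    attr(complete, "specs") <- cohort_specs(cohort)[modelled]
    class(complete) <- class(cohort)
    fit_cpts(dag_final, complete, config$pseudocount)
  })
  tree <- stage("query", {
    order <- intersect(c("ventilated", "noradrenaline", "dcrt_m"), modelled)
    query_tree(bn, "estimate", order)
  })
  eval_out <- stage("evaluate", {
    valid <- !is.na(cohort$cardiac_index)
    t <- crosstab(dichotomize_estimate(cohort$estimate[valid]),
                  as.character(cohort$cardiac_index[valid]))
    metrics <- dx_metrics(t)
    cv <- cross_validate(cohort, dag_final, folds = config$folds,
                         seed = config$seed + 2L,
                         pseudocount = config$pseudocount)
    list(table = t, metrics = metrics, cv = cv)
  })
  stage("write", {
    out <- config$out_dir
    write_cohort(cohort, file.path(out, "cohort.csv"))
    write_confidence_csv(confidence, file.path(out, "confidence.csv"))
    write_consensus_csv(consensus, file.path(out, "consensus.csv"))
    write_dag_csv(dag_final, file.path(out, "dag.csv"))
    write_bn_json(bn, file.path(out, "network.json"))
    write_query_tree_csv(tree, file.path(out, "query_tree.csv"))
    write_metrics_csv(eval_out$metrics, file.path(out, "metrics.csv"))
    cfg_path <- file.path(out, "config.json")
    cfg <- unclass(config)
    cfg$out_dir <- NULL
    jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    jsonlite::write_json(
      list(seed = config$seed,
           config_hash = unname(tools::md5sum(cfg_path)),
           timings = timings,
           n = nrow(cohort),
           arcs = nrow(dag_final$arcs),
           undirected_edges = nrow(consensus$undirected),
           strength_threshold = consensus$strength_threshold,
           cv_auroc = eval_out$cv$auroc),
      file.path(out, "run.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  })
  invisible(list(cohort = cohort, confidence = confidence,
                 consensus = consensus, dag = dag_final, bn = bn,
                 tree = tree, metrics = eval_out$metrics,
                 table = eval_out$table, cv = eval_out$cv,
                 timings = timings, out_dir = config$out_dir))
}

config_from_options <- function(opt) {
  base <- if (!is.null(opt$config) && nzchar(opt$config)) {
    vals <- jsonlite::read_json(opt$config, simplifyVector = TRUE)
    do.call(run_config, vals[intersect(names(vals),
                                       names(formals(run_config)))])
  } else {
    run_config()
  }
  if (!is.null(opt$seed)) base$seed <- as.integer(opt$seed)
  if (!is.null(opt$replicates)) base$replicates <- as.integer(opt$replicates)
  if (!is.null(opt$n)) base$n <- as.integer(opt$n)
  if (!is.null(opt$cohort) && nzchar(opt$cohort)) {
    base$cohort_path <- opt$cohort
  }
  if (!is.null(opt$out) && nzchar(opt$out)) base$out_dir <- opt$out
  base
}

cli_option_list <- function() {
  list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "JSON configuration file"),
    optparse::make_option("--seed", type = "integer", default = NULL,
                          help = "master RNG seed"),
    optparse::make_option("--replicates", type = "integer", default = NULL,
                          help = "bootstrap replicates"),
    optparse::make_option("--n", type = "integer", default = NULL,
                          help = "synthetic cohort size"),
    optparse::make_option("--cohort", type = "character", default = NULL,
                          help = "existing cohort CSV"),
    optparse::make_option("--out", type = "character", default = NULL,
                          help = "output directory"),
    optparse::make_option("--evidence", type = "character", default = "",
                          help = "query evidence, e.g. 'ventilated=yes,noradrenaline=no'"),
    optparse::make_option("--target", type = "character",
                          default = "estimate", help = "query target"),
    optparse::make_option("--verbose", action = "store_true",
                          default = FALSE, help = "stage progress"))
}

parse_evidence <- function(s) {
  if (!nzchar(s)) return(list())
  parts <- strsplit(strsplit(s, ",")[[1]], "=")
  stats::setNames(lapply(parts, function(p) trimws(p[2])),
                  vapply(parts, function(p) trimws(p[1]), ""))
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `learn`, `consensus`, `query`,
#' `tree`, `evaluate` and `reproduce` (the full chain), each driven by
#' `--config/--seed/--replicates/--n/--cohort/--out/--verbose` flags. An
#' executable wrapper ships in `inst/cli/icubn`.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first).
#' @return integer exit status, invisibly (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    message("usage: icubn <simulate|learn|consensus|query|tree|evaluate|reproduce> [options]")
    return(invisible(0L))
  }
  cmd <- args[1]
  parser <- optparse::OptionParser(option_list = cli_option_list())
  status <- tryCatch({
    opt <- optparse::parse_args(parser, args = args[-1])
    cfg <- config_from_options(opt)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    modelled <- names(default_variable_specs(include_outcome = FALSE))
    load_cohort_arg <- function() {
      if (is.null(cfg$cohort_path)) {
        stop("this subcommand needs --cohort")
      }
      read_cohort(cfg$cohort_path)
    }
    if (cmd == "simulate") {
      cohort <- generate_cohort(n = cfg$n, seed = cfg$seed)
      write_cohort(cohort, file.path(cfg$out_dir, "cohort.csv"))
      message("wrote ", file.path(cfg$out_dir, "cohort.csv"))
    } else if (cmd == "learn") {
      cohort <- load_cohort_arg()
      use <- intersect(modelled, names(cohort))
      conf <- bootstrap_confidence(cohort[, use, drop = FALSE],
                                   replicates = cfg$replicates,
                                   seed = cfg$seed,
                                   params = score_params(ess = cfg$ess,
                                                         alpha = cfg$alpha),
                                   constraints = sics_constraints(use),
                                   nodes = use)
      write_confidence_csv(conf, file.path(cfg$out_dir, "confidence.csv"))
      message("wrote ", file.path(cfg$out_dir, "confidence.csv"))
    } else if (cmd == "consensus") {
      conf <- read_confidence_csv(file.path(cfg$out_dir, "confidence.csv"))
      cons <- build_consensus(conf, cfg$strength_floor,
                              cfg$direction_threshold)
      write_consensus_csv(cons, file.path(cfg$out_dir, "consensus.csv"))
      message("wrote ", file.path(cfg$out_dir, "consensus.csv"))
    } else if (cmd %in% c("query", "tree")) {
      cohort <- load_cohort_arg()
      use <- intersect(modelled, names(cohort))
      g <- read_dag_csv(file.path(cfg$out_dir, "dag.csv"), nodes = use)
      sub <- cohort[, use, drop = FALSE]
      attr(sub, "specs") <- cohort_specs(cohort)[use]
      class(sub) <- class(cohort)
      bn <- fit_cpts(g, sub, cfg$pseudocount)
      if (cmd == "query") {
        d <- posterior(bn, opt$target, parse_evidence(opt$evidence))
        jsonlite::write_json(as.list(d),
                             file.path(cfg$out_dir, "query.json"),
                             auto_unbox = TRUE, digits = NA)
        print(round(d, 4))
      } else {
        tr <- query_tree(bn, opt$target,
                         intersect(c("ventilated", "noradrenaline",
                                     "dcrt_m"), use))
        write_query_tree_csv(tr, file.path(cfg$out_dir, "query_tree.csv"))
        message("wrote ", file.path(cfg$out_dir, "query_tree.csv"))
      }
    } else if (cmd == "evaluate") {
      cohort <- load_cohort_arg()
      valid <- !is.na(cohort$cardiac_index)
      t <- crosstab(dichotomize_estimate(cohort$estimate[valid]),
                    as.character(cohort$cardiac_index[valid]))
      write_metrics_csv(dx_metrics(t), file.path(cfg$out_dir, "metrics.csv"))
      message("wrote ", file.path(cfg$out_dir, "metrics.csv"))
    } else if (cmd == "reproduce") {
      run_pipeline(cfg, verbose = isTRUE(opt$verbose))
      message("artifacts in ", cfg$out_dir)
    } else {
      stop("unknown subcommand: ", cmd)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
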