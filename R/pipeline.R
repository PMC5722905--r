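#' Default pipeline configuration
#'
#' A nested list configuring the four pipeline stages. Any subset of keys
#' can be overridden via `modifyList()` semantics in [run_pipeline()]; the
#' effective configuration is always echoed into the run manifest.
#'
#' @param seed root seed for every stochastic stage.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    stages = c("simulate", "transform", "infer", "evaluate"),
    seed = as.integer(seed),
    simulate = list(),                       # simulation_config() overrides
    transform = list(bootstrap = TRUE, bootstrap_reps = 10000L,
                     tail = "smaller"),
    infer = list(feature = "exranges",       # exranges | ranges | expression
                 n_trees = 2000L, importance = "permutation",
                 normalize = FALSE, n_jobs = 1L),
    evaluate = list(top_fraction = 0.1),
    inputs = list(expression = NULL, design = NULL, regulators = NULL,
                  gold = NULL, annotation = NULL))
}

#' Run the simulate -> transform -> infer -> evaluate pipeline
#'
#' Executes the requested stages in order, writing every intermediate
#' artifact (expression and design tables, feature matrices, edge lists,
#' per-regulator evaluation table) under `out_dir`, and finally a JSON run
#' manifest recording the effective configuration, input file digests,
#' seed, package version and per-stage timings. Reruns with an identical
#' manifest reproduce identical outputs. When `simulate` is among the
#' stages its outputs feed the later stages; otherwise `config$inputs`
#' must name the expression/design/regulator (and, for `evaluate`, gold
#' standard) files. A stage failure aborts with the stage name; artifacts
#' written before the failure are preserved.
#'
#' @param config nested list as in [default_pipeline_config()]; partial
#'   lists are merged over the defaults.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = ".") {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  stages <- match.arg(cfg$stages,
                      c("simulate", "transform", "infer", "evaluate"),
                      several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # fail early on missing prerequisites
  if ("evaluate" %in% stages && !"simulate" %in% stages &&
      is.null(cfg$inputs$gold))
    stop("stage 'evaluate' needs a gold standard: supply inputs$gold or ",
         "run the simulate stage")
  if (!"simulate" %in% stages &&
      ("transform" %in% stages || "infer" %in% stages) &&
      (is.null(cfg$inputs$expression) || is.null(cfg$inputs$design)))
    stop("without the simulate stage, inputs$expression and inputs$design ",
         "are required")

  state <- list()
  timings <- list()
  digests <- list()
  for (p in Filter(Negate(is.null), cfg$inputs))
    if (is.character(p) && file.exists(p))
      digests[[p]] <- unname(tools::md5sum(p))

  run_stage <- function(name, fun) {
    message(sprintf("[%s] start (seed=%d)", name, cfg$seed))
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    message(sprintf("[%s] done in %.1fs", name, timings[[name]]))
    res
  }

  if ("simulate" %in% stages) {
    state$dataset <- run_stage("simulate", function() {
      sim_args <- utils::modifyList(cfg$simulate, list(seed = cfg$seed))
      ds <- assemble_dataset(do.call(simulation_config, sim_args))
      write_expression(ds$expr, file.path(out_dir, "expression.tsv"),
                       file.path(out_dir, "design.tsv"))
      writeLines(ds$regulators, file.path(out_dir, "regulators.txt"))
      write_edges(ds$true_edges, file.path(out_dir, "truth_edges.tsv"))
      jsonlite::write_json(ds$params, file.path(out_dir, "truth_params.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
      ds
    })
    state$expr <- state$dataset$expr
    state$regulators <- state$dataset$regulators
    state$gold_pairs <- state$dataset$true_edges
  } else if (!is.null(cfg$inputs$expression)) {
    state$expr <- read_expression(cfg$inputs$expression, cfg$inputs$design)
    if (!is.null(cfg$inputs$regulators))
      state$regulators <- read_gene_list(cfg$inputs$regulators)
    if (!is.null(cfg$inputs$gold))
      state$gold_pairs <- read_edges(cfg$inputs$gold)
  }

  if ("transform" %in% stages) {
    state$features <- run_stage("transform", function() {
      tcfg <- transform_config(
        bootstrap = isTRUE(cfg$transform$bootstrap),
        bootstrap_reps = cfg$transform$bootstrap_reps %||% 10000L,
        seed = cfg$seed, tail = cfg$transform$tail %||% "smaller")
      R <- ranges(state$expr, tcfg)
      E <- exranges(state$expr, R)
      write_feature_matrix(R, file.path(out_dir, "ranges.tsv"))
      write_feature_matrix(E, file.path(out_dir, "exranges.tsv"))
      list(ranges = R, exranges = E)
    })
  }

  if ("infer" %in% stages) {
    state$scores <- run_stage("infer", function() {
      feat <- switch(cfg$infer$feature %||% "exranges",
        expression = state$expr$values,
        ranges = state$features$ranges,
        exranges = state$features$exranges,
        stop("unknown feature type: ", cfg$infer$feature))
      if (is.null(feat))
        stop("feature '", cfg$infer$feature, "' not available; ",
             "did the transform stage run?")
      if (is.null(state$regulators)) stop("no regulator list available")
      icfg <- inference_config(
        n_trees = cfg$infer$n_trees %||% 2000L,
        importance = cfg$infer$importance %||% "permutation",
        normalize = isTRUE(cfg$infer$normalize),
        seed = cfg$seed, n_jobs = cfg$infer$n_jobs %||% 1L)
      sc <- infer_network(feat, state$regulators, cfg = icfg)
      el <- rank_edges(sc)
      write_edges(el, file.path(out_dir, "edges.tsv"))
      write_matrix_tsv(sc$scores, file.path(out_dir, "edge_scores.tsv"),
                       id_col = "regulator")
      sc
    })
  }

  if ("evaluate" %in% stages) {
    state$evaluation <- run_stage("evaluate", function() {
      if (is.null(state$scores)) stop("no edge scores; run the infer stage")
      if (is.null(state$gold_pairs) || nrow(state$gold_pairs) == 0L)
        stop("empty gold standard")
      edges <- rank_edges(state$scores)
      universe <- colnames(state$scores$scores)
      per_reg <- lapply(intersect(unique(state$gold_pairs$regulator),
                                  rownames(state$scores$scores)),
                        function(r) {
        pos <- intersect(state$gold_pairs$target[state$gold_pairs$regulator == r],
                         universe)
        uni <- setdiff(universe, r)
        pos <- setdiff(pos, r)
        if (length(pos) == 0L || length(pos) == length(uni)) return(NULL)
        gs <- gold_standard(r, pos, uni)
        sc <- state$scores$scores[r, uni]
        data.frame(regulator = r, auc = roc_auc(sc, gs)$auc,
                   average_precision = pr_curve(sc, gs)$average_precision,
                   n_positive = length(pos), stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, per_reg)
      frac <- cfg$evaluate$top_fraction %||% 0.1
      res <- list(per_regulator = tab,
                  mean_auc = mean(tab$auc),
                  recall_at_fraction = recall_at_fraction(
                    edges, state$gold_pairs, frac),
                  top_fraction = frac)
      utils::write.table(tab, file.path(out_dir, "per_regulator_auc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(res[c("mean_auc", "recall_at_fraction",
                                 "top_fraction")],
                           file.path(out_dir, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA)
      res
    })
  }

  manifest <- list(
    package = "exranges",
    version = as.character(utils::packageVersion("exranges")),
    seed = cfg$seed,
    stages = stages,
    config = cfg[c("seed", "simulate", "transform", "infer", "evaluate")],
    input_digests = digests,
    timings_sec = timings,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  state$manifest <- manifest
  invisible(state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
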