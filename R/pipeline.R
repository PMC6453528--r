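#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run: input paths, the ALS block,
#' evaluation thresholds and filter flags. Defaults reproduce the standard
#' analysis configuration: rank 20, 20 iterations, lambda 0.1, alpha 0.1,
#' recall thresholds 5% and 20%, direct interactors removed after ranking.
#'
#' @param edges path to the relation-triple CSV edge list.
#' @param target target gene symbol.
#' @param outdir output directory (created if absent).
#' @param gold optional path to a gold-standard gene list.
#' @param direction `"downstream"` or `"upstream"`.
#' @param als an [als_config()] block.
#' @param thresholds recall percentile thresholds.
#' @param remove_direct drop direct interactors after ranking.
#' @param include_known keep known partners in the ranked list.
#' @param rounding recall rounding mode.
#' @param explain_top number of top novel predictions to explain.
#' @param seed run seed; overrides the ALS block's seed.
#' @param columns column-name mapping passed to [read_triples()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(edges, target, outdir = "litnetmf-out",
                            gold = NULL,
                            direction = c("downstream", "upstream"),
                            als = als_config(), thresholds = c(5, 20),
                            remove_direct = TRUE, include_known = TRUE,
                            rounding = c("nearest", "strict"),
                            explain_top = 3L, seed = 1L,
                            columns = c(agent = "agent", relation = "relation",
                                        theme = "theme", count = "count")) {
  structure(list(edges = edges, target = target, outdir = outdir,
                 gold = gold, direction = match.arg(direction),
                 als = als, thresholds = thresholds,
                 remove_direct = isTRUE(remove_direct),
                 include_known = isTRUE(include_known),
                 rounding = match.arg(rounding),
                 explain_top = as.integer(explain_top),
                 seed = as.integer(seed), columns = columns),
            class = "pipeline_config")
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$als <- unclass(out$als)
  out$columns <- as.list(out$columns)
  out
}

#' @rdname pipeline_config
#' @param path JSON file written by a previous run (`config.json`).
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$als <- do.call(als_config, as.list(x$als))
  x$columns <- unlist(x$columns)
  do.call(pipeline_config, x[setdiff(names(x), "config_hash")])
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full ranking pipeline
#'
#' Executes read -> build -> factorize -> rank -> (filter) -> evaluate ->
#' explain, writing each artifact to the output directory: `ranked.csv`
#' (gene, score, known 0/1, rank, percentile), `evaluation.json` (when a
#' gold list is supplied), `explanations.txt` for the top novel predictions,
#' `config.json` echoing the configuration with a hash, and `run.log`.
#' The run is deterministic given the configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the ranked list, evaluation report (or
#'   NULL), explanations, and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$outdir, "run.log")
  logcon <- file(logf, "w")
  on.exit(close(logcon))
  say <- function(...) writeLines(sprintf(...), logcon)

  cfg_list <- config_to_list(config)
  # hash the analytic configuration only, so identical analyses written to
  # different directories stamp identical hashes
  hash_json <- jsonlite::toJSON(cfg_list[setdiff(names(cfg_list), "outdir")],
                                auto_unbox = TRUE, digits = NA)
  cfg_hash <- sprintf("%08x", sum(utf8ToInt(as.character(hash_json)) *
                                  (seq_len(nchar(hash_json)) %% 97 + 1)) %% .Machine$integer.max)
  cfg_json <- jsonlite::toJSON(cfg_list, auto_unbox = TRUE, digits = NA)
  cfg_list$config_hash <- cfg_hash
  jsonlite::write_json(cfg_list, file.path(config$outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("config hash %s, seed %d", cfg_hash, config$seed)

  triples <- stage("read", read_triples(config$edges, columns = config$columns))
  say("read %d triples (%d rejected)", nrow(triples),
      attr(triples, "n_rejected") %||% 0L)
  m <- stage("build", build_matrix(triples))
  say("matrix: %d genes, %d nonzero cells", length(m$genes),
      Matrix::nnzero(m$counts))

  als <- config$als; als$seed <- config$seed
  fit <- stage("rank", fit_implicit_als(m, als))
  ranked <- stage("rank", rank_relation(m, config$target, config$direction,
                                        als, model = fit,
                                        include_known = config$include_known))
  if (config$remove_direct) ranked <- stage("filter", remove_direct(ranked, m))
  ranked_path <- file.path(config$outdir, "ranked.csv")
  out_df <- as.data.frame(ranked)
  out_df$known <- as.integer(out_df$known)
  utils::write.csv(
    cbind(out_df, config_hash = cfg_hash, seed = config$seed),
    ranked_path, row.names = FALSE, quote = FALSE)
  say("ranked %d genes for %s %s", nrow(ranked), config$target,
      config$direction)

  report <- NULL
  if (!is.null(config$gold)) {
    gold <- stage("evaluate", read_gold_set(config$gold))
    report <- stage("evaluate",
                    evaluate_ranking(ranked, gold, config$thresholds,
                                     config$rounding))
    jsonlite::write_json(
      list(auc = report$auc,
           recall_at = as.list(report$recall_at),
           gold_ranks = as.list(report$gold_ranks),
           n_ranked = report$n_ranked,
           unresolved = report$unresolved,
           config_hash = cfg_hash, seed = config$seed),
      file.path(config$outdir, "evaluation.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("evaluation AUC %.4f", report$auc)
  }

  novel <- ranked$symbol[!ranked$known]
  to_explain <- utils::head(novel, config$explain_top)
  explanations <- lapply(to_explain, function(g)
    stage("explain",
          explain_prediction(m, fit, config$target, g, config$direction)))
  expl_path <- file.path(config$outdir, "explanations.txt")
  expl_con <- file(expl_path, "w")
  writeLines(sprintf("# config %s seed %d", cfg_hash, config$seed), expl_con)
  sink(expl_con)
  for (e in explanations) print(e)
  sink()
  close(expl_con)
  say("explained top %d novel predictions", length(explanations))

  invisible(list(ranked = ranked, report = report,
                 explanations = explanations,
                 paths = list(ranked = ranked_path,
                              evaluation = if (!is.null(report))
                                file.path(config$outdir, "evaluation.json"),
                              explanations = expl_path,
                              config = file.path(config$outdir, "config.json"),
                              log = logf)))
}
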