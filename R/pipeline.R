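#' Run the staged prediction pipeline
#'
#' Executes the full workflow -- build network, compute associations,
#' predict, evaluate -- from a single configuration, writing each stage's
#' outputs (TSV tables, keyed summaries, the resolved configuration) into a
#' run directory so stages can be inspected or resumed from their files.
#' Stage outputs are pure functions of (inputs, config): re-running with the
#' same configuration reproduces them byte for byte.
#'
#' The configuration is a named list (or path to a YAML file) with fields:
#' \describe{
#'   \item{outDir}{run directory (created if needed).}
#'   \item{seed}{integer seed driving every stochastic stage.}
#'   \item{metric}{association index (default \code{"simpson"}).}
#'   \item{combiner}{\code{"stouffer"} (default) or \code{"fisher"};
#'     \code{"fisher"} requires \code{metric = "hyi"}.}
#'   \item{minScore}{spurious-prediction removal threshold (default 0.001).}
#'   \item{simulate}{optional list of [syntheticSpec()] arguments; when
#'     present the annotation layers are generated, otherwise...}
#'   \item{inputs}{list with \code{domains} and \code{functions}: paths to
#'     the two TSV annotation pair files.}
#'   \item{evaluatePPP}{logical (default TRUE): self-predict the network
#'     proteins and score against their original annotations.}
#' }
#'
#' @param config named list or path to a YAML configuration file.
#' @return (invisibly) a list with \code{outDir}, the
#'   [TripartiteNetwork-class], the [PredictionSet-class] and, when
#'   evaluated, the [EvaluationReport-class].
#' @export
runPipeline <- function(config) {
  cfg <- .resolveConfig(config)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg[order(names(cfg))], file.path(cfg$outDir, "config.yaml"))

  .stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  if (!is.null(cfg$simulate)) {
    sim <- .stage("simulate", {
      spec <- do.call(syntheticSpec,
                      c(cfg$simulate, list(seed = cfg$seed)))
      generateNetwork(spec)
    })
    domainPairs <- sim$domainPairs
    functionPairs <- sim$functionPairs
    writePairsFile(domainPairs, file.path(cfg$outDir, "domains.tsv"))
    writePairsFile(functionPairs, file.path(cfg$outDir, "functions.tsv"))
  } else {
    domainPairs <- .stage("read-input",
      readPairsFile(cfg$inputs$domains, layer = "domain"))
    functionPairs <- .stage("read-input",
      readPairsFile(cfg$inputs$functions, layer = "function"))
  }

  network <- .stage("build-network", buildNetwork(domainPairs, functionPairs))
  s <- networkSummary(network)
  writeLines(paste(names(s), s, sep = "\t"),
             file.path(cfg$outDir, "network_summary.txt"), useBytes = TRUE)

  assoc <- .stage("associate", computeAssociations(network, cfg$metric))
  writeAssociations(assoc, file.path(cfg$outDir,
                                     paste0("associations_", cfg$metric, ".tsv")))

  predictions <- .stage("predict", {
    lookup <- if (cfg$combiner == "stouffer")
      standardizeTable(assoc, takeAbsolute = (cfg$metric == "pcc"))
    else assoc
    predictAll(names(network@proteinDomains), network, lookup,
               method = cfg$combiner, minScore = cfg$minScore)
  })
  writePredictions(predictions, file.path(cfg$outDir, "predictions.tsv"))

  report <- NULL
  if (isTRUE(cfg$evaluatePPP)) {
    report <- .stage("evaluate-ppp",
      pppEvaluate(predictions, network@proteinFunctions))
    writeReport(report, file.path(cfg$outDir, "ppp"))
  }
  invisible(list(outDir = cfg$outDir, network = network,
                 predictions = predictions, report = report))
}

.resolveConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("configuration file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a named list or a YAML path")
  defaults <- list(seed = 1L, metric = "simpson", combiner = "stouffer",
                   minScore = 0.001, evaluatePPP = TRUE)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$outDir)) stop("config is missing 'outDir'")
  cfg$seed <- as.integer(cfg$seed)
  cfg$metric <- match.arg(cfg$metric, .METRICS)
  cfg$combiner <- match.arg(cfg$combiner, .COMBINERS)
  if (cfg$combiner == "fisher" && cfg$metric != "hyi")
    stop("the fisher combiner requires metric = 'hyi'")
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$inputs$domains) || is.null(cfg$inputs$functions))
      stop("config needs either 'simulate' parameters or 'inputs' paths")
    for (p in c(cfg$inputs$domains, cfg$inputs$functions))
      if (!file.exists(p)) stop("input file not found: ", p)
  }
  cfg
}
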