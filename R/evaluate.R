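# (1:100)/100 rather than seq(): each grid point is then the same double as
# a score rounded to two decimals, so lattice scores compare exactly
.TAU_GRID <- (1:100) / 100
.TAU_EPS <- 1e-9

#' Construct a BenchmarkSet
#'
#' @param truth named list: protein id -> character vector of true terms
#'   (propagate with [propagateAnnotations()] first for ontology
#'   benchmarks).
#' @param subsetTag \code{"no-knowledge"}, \code{"limited-knowledge"} or
#'   \code{"all"} (the classification of real benchmark proteins into the
#'   knowledge categories is supplied by the caller).
#' @param ontologyTag free-text annotation-source label.
#' @return a [BenchmarkSet-class].
#' @export
benchmarkSet <- function(truth, subsetTag = "all", ontologyTag = "") {
  new("BenchmarkSet", truth = truth, subsetTag = subsetTag,
      ontologyTag = ontologyTag)
}

#' Restrict a benchmark to a protein subset
#'
#' @param benchmark a [BenchmarkSet-class].
#' @param proteins protein ids to keep.
#' @param subsetTag tag for the restricted set.
#' @return a [BenchmarkSet-class].
#' @export
subsetBenchmark <- function(benchmark, proteins, subsetTag = benchmark@subsetTag) {
  keep <- intersect(names(benchmark@truth), proteins)
  if (!length(keep)) stop("benchmark subset is empty")
  new("BenchmarkSet", truth = benchmark@truth[keep], subsetTag = subsetTag,
      ontologyTag = benchmark@ontologyTag)
}

.predTermsByProtein <- function(predictions) {
  r <- if (is(predictions, "PredictionSet")) predictions@records else predictions
  split(r[c("fun", "normalized")], r$protein)
}

#' Protein-centric precision and recall at a threshold
#'
#' For threshold tau, each protein's predicted term set is the set of terms
#' with normalized score >= tau. Precision is averaged over proteins with at
#' least one predicted term at tau (0 when there is none); recall is
#' averaged over ALL benchmark proteins in \code{"full"} mode (penalizing
#' proteins the method cannot predict for) or only over benchmark proteins
#' with at least one retained prediction at any threshold in
#' \code{"partial"} mode.
#'
#' @param predictions a [PredictionSet-class] (propagated consistently with
#'   the benchmark truth).
#' @param benchmark a [BenchmarkSet-class].
#' @param tau score threshold in (0, 1].
#' @param mode \code{"full"} or \code{"partial"}.
#' @return named numeric vector \code{c(precision, recall)}.
#' @export
precisionRecallAt <- function(predictions, benchmark, tau,
                              mode = c("full", "partial")) {
  mode <- match.arg(mode)
  if (tau <= 0 || tau > 1) stop("tau must lie in (0, 1]")
  stopifnot(is(benchmark, "BenchmarkSet"))
  byProt <- .predTermsByProtein(predictions)
  .prAt(byProt, benchmark@truth, tau, mode)
}

.prAt <- function(byProt, truth, tau, mode) {
  prots <- names(truth)
  predSets <- lapply(prots, function(p) {
    pp <- byProt[[p]]
    if (is.null(pp)) character() else pp$fun[pp$normalized >= tau - .TAU_EPS]
  })
  nPred <- lengths(predSets)
  tp <- vapply(seq_along(prots),
               function(i) length(intersect(predSets[[i]], truth[[i]])),
               numeric(1))
  precision <- if (any(nPred > 0L)) mean((tp / nPred)[nPred > 0L]) else 0
  rcPer <- tp / lengths(truth)
  covered <- prots %in% names(byProt)
  recall <- if (mode == "full") mean(rcPer)
            else if (any(covered)) mean(rcPer[covered]) else 0
  c(precision = precision, recall = recall)
}

.prCurve <- function(predictions, benchmark, mode, tauGrid = .TAU_GRID) {
  byProt <- .predTermsByProtein(predictions)
  pr <- vapply(tauGrid, function(tau)
    .prAt(byProt, benchmark@truth, tau, mode), numeric(2))
  data.frame(tau = tauGrid, precision = pr[1, ], recall = pr[2, ])
}

#' Maximum protein-centric F-measure
#'
#' Sweeps the threshold grid tau = 0.01, 0.02, ..., 1.00 and returns the
#' maximum harmonic mean of averaged precision and recall,
#' \eqn{F = 2 pr \cdot rc / (pr + rc)} (0 where both vanish). Among tied
#' thresholds the largest tau is reported (the most confident threshold
#' attaining the maximum).
#'
#' @inheritParams precisionRecallAt
#' @param tauGrid threshold grid.
#' @return list with \code{fmax}, \code{tau}, and the \code{prPoints}
#'   data.frame.
#' @export
fmax <- function(predictions, benchmark, mode = c("full", "partial"),
                 tauGrid = .TAU_GRID) {
  mode <- match.arg(mode)
  stopifnot(is(benchmark, "BenchmarkSet"))
  if (!length(benchmark@truth)) stop("empty benchmark")
  pts <- .prCurve(predictions, benchmark, mode, tauGrid)
  f <- .fscore(pts$precision, pts$recall)
  best <- max(f)
  list(fmax = best, tau = max(pts$tau[f >= best - 1e-12]), prPoints = pts)
}

.fscore <- function(pr, rc) ifelse(pr + rc > 0, 2 * pr * rc / (pr + rc), 0)

#' Minimum semantic distance
#'
#' Sweeps the threshold grid and returns the minimum of
#' \eqn{\sqrt{ru(\tau)^2 + mi(\tau)^2}}, where remaining uncertainty
#' \eqn{ru} is the benchmark-average total information accretion of true
#' terms the prediction misses at tau, and misinformation \eqn{mi} the
#' average accretion of predicted terms not in the truth. Averages are over
#' all benchmark proteins (\code{"full"}) or over covered proteins
#' (\code{"partial"}). Among tied thresholds the largest tau is reported.
#'
#' @inheritParams fmax
#' @param ic a [TermIC-class] covering the truth and prediction terms
#'   (missing terms fall back to the pseudo-count ia with a warning).
#' @return list with \code{smin}, \code{tau}, and a data.frame
#'   \code{points} (tau, ru, mi).
#' @export
smin <- function(predictions, benchmark, ic, mode = c("full", "partial"),
                 tauGrid = .TAU_GRID) {
  mode <- match.arg(mode)
  stopifnot(is(benchmark, "BenchmarkSet"), is(ic, "TermIC"))
  if (!length(benchmark@truth)) stop("empty benchmark")
  byProt <- .predTermsByProtein(predictions)
  truth <- benchmark@truth
  prots <- names(truth)
  allTerms <- unique(c(unlist(truth, use.names = FALSE),
                       unlist(lapply(byProt, `[[`, "fun"), use.names = FALSE)))
  iaMap <- termIA(ic, allTerms)
  names(iaMap) <- allTerms
  covered <- prots %in% names(byProt)
  denom <- function(x) if (mode == "full") mean(x)
                       else if (any(covered)) mean(x[covered]) else 0
  pts <- t(vapply(tauGrid, function(tau) {
    ru <- mi <- numeric(length(prots))
    for (i in seq_along(prots)) {
      pp <- byProt[[prots[i]]]
      pred <- if (is.null(pp)) character() else pp$fun[pp$normalized >= tau - .TAU_EPS]
      ru[i] <- sum(iaMap[setdiff(truth[[i]], pred)])
      mi[i] <- sum(iaMap[setdiff(pred, truth[[i]])])
    }
    c(ru = denom(ru), mi = denom(mi))
  }, numeric(2)))
  s <- sqrt(pts[, "ru"]^2 + pts[, "mi"]^2)
  best <- min(s)
  list(smin = best, tau = max(tauGrid[s <= best + 1e-12]),
       points = data.frame(tau = tauGrid, ru = pts[, "ru"], mi = pts[, "mi"]))
}

#' Benchmark coverage
#'
#' Fraction of benchmark proteins for which at least one prediction was
#' retained.
#'
#' @inheritParams precisionRecallAt
#' @return numeric in \[0, 1\].
#' @export
benchmarkCoverage <- function(predictions, benchmark) {
  stopifnot(is(benchmark, "BenchmarkSet"))
  if (!length(benchmark@truth)) stop("empty benchmark")
  preds <- if (is(predictions, "PredictionSet")) predictions@predicted
           else unique(predictions$protein)
  mean(names(benchmark@truth) %in% preds)
}

#' Full protein-centric benchmark evaluation
#'
#' Convenience wrapper computing Fmax (with its PR curve), coverage and,
#' when term weights are supplied, Smin, optionally ancestor-propagating
#' the predictions first.
#'
#' @inheritParams fmax
#' @param ic optional [TermIC-class] for Smin.
#' @param dag optional [OntologyDAG-class]; when given and
#'   \code{propagate = TRUE}, predictions are propagated with
#'   [propagatePredictions()] before scoring (benchmark truth is expected
#'   propagated already).
#' @param propagate whether to propagate predictions.
#' @return an [EvaluationReport-class].
#' @export
evaluateBenchmark <- function(predictions, benchmark,
                              mode = c("full", "partial"), ic = NULL,
                              dag = NULL, propagate = TRUE) {
  mode <- match.arg(mode)
  if (!is.null(dag) && propagate)
    predictions <- propagatePredictions(predictions, dag)
  fm <- fmax(predictions, benchmark, mode)
  sm <- if (!is.null(ic)) smin(predictions, benchmark, ic, mode)
        else list(smin = NA_real_, tau = NA_real_)
  new("EvaluationReport", fmax = fm$fmax, fmaxTau = fm$tau,
      smin = sm$smin, sminTau = sm$tau,
      coverage = benchmarkCoverage(predictions, benchmark),
      prPoints = fm$prPoints, aucpr = NA_real_, mode = mode)
}

#' Pathway Prediction Performance (pooled self-prediction PR curve)
#'
#' Scores self-predictions for the proteins used to build the network
#' against their original annotations. All (protein, function, score)
#' records are pooled; a record is a true positive when the function is in
#' the protein's original (as-annotated, or propagated when
#' \code{propagate = TRUE} and a DAG is given) annotation set, a false
#' positive otherwise. The precision-recall curve is built over the ranked
#' score list (one point per distinct score threshold) and summarized by
#' its step-interpolated area (AUC-PR) and its maximum F-measure.
#'
#' @param predictions a [PredictionSet-class] of self-predictions.
#' @param originalAnnotations named list: protein -> originally annotated
#'   function terms.
#' @param dag,propagate optionally propagate both predictions and
#'   annotations before matching (default: literal as-annotated matching).
#' @return an [EvaluationReport-class] with \code{mode = "ppp"}; its
#'   \code{prPoints} hold (score threshold, precision, recall).
#' @export
pppEvaluate <- function(predictions, originalAnnotations, dag = NULL,
                        propagate = FALSE) {
  stopifnot(is(predictions, "PredictionSet"))
  if (propagate && !is.null(dag)) {
    predictions <- propagatePredictions(predictions, dag)
    originalAnnotations <- propagateAnnotations(originalAnnotations, dag)
  }
  r <- predictions@records
  if (!nrow(r)) stop("no predictions to evaluate")
  label <- vapply(seq_len(nrow(r)), function(i)
    r$fun[i] %in% originalAnnotations[[r$protein[i]]], logical(1))
  ord <- order(-r$normalized, r$protein, r$fun)
  score <- r$normalized[ord]
  label <- label[ord]
  nPos <- sum(label)
  cumTP <- cumsum(label)
  # one PR point per distinct score threshold (all records >= threshold)
  lastOfScore <- !duplicated(score, fromLast = TRUE)
  idx <- which(lastOfScore)
  precision <- cumTP[idx] / idx
  recall <- if (nPos > 0) cumTP[idx] / nPos else rep(0, length(idx))
  pts <- data.frame(tau = score[idx], precision = precision, recall = recall)
  aucpr <- sum(diff(c(0, recall)) * precision)
  fm <- max(.fscore(precision, recall))
  new("EvaluationReport", fmax = fm,
      fmaxTau = max(pts$tau[.fscore(precision, recall) >= fm - 1e-12]),
      smin = NA_real_, sminTau = NA_real_,
      coverage = mean(names(originalAnnotations) %in% predictions@predicted),
      prPoints = pts, aucpr = aucpr, mode = "ppp")
}

#' Frequency naive baseline
#'
#' Assigns to every benchmark protein every term seen in the (propagated)
#' training annotations, scored by the fraction of training proteins
#' annotated with that term; coverage is 1 by construction.
#'
#' @param trainingAnnotations named list: protein -> term set (propagated).
#' @param benchmarkProteins protein ids to predict for.
#' @param minScore removal threshold (the same spurious-prediction filter
#'   applied to model scores).
#' @return a [PredictionSet-class] with \code{method = "naive"}.
#' @export
naiveBaseline <- function(trainingAnnotations, benchmarkProteins,
                          minScore = 0.001) {
  if (!length(trainingAnnotations)) stop("empty training annotations")
  if (!length(benchmarkProteins)) stop("no benchmark proteins")
  freq <- table(unlist(lapply(trainingAnnotations, unique),
                       use.names = FALSE)) / length(trainingAnnotations)
  keep <- freq >= minScore
  terms <- names(freq)[keep]
  sc <- as.numeric(freq[keep])
  benchmarkProteins <- unique(benchmarkProteins)
  rec <- data.frame(
    protein = rep(benchmarkProteins, each = length(terms)),
    fun = rep(terms, length(benchmarkProteins)),
    domains = "", k = 0L,
    raw = rep(sc, length(benchmarkProteins)),
    normalized = rep(sc, length(benchmarkProteins)),
    stringsAsFactors = FALSE)
  rec <- rec[order(rec$protein, -rec$normalized, rec$fun), , drop = FALSE]
  rownames(rec) <- NULL
  new("PredictionSet", records = rec, method = "naive",
      predicted = benchmarkProteins,
      unpredictable = data.frame(protein = character(), reason = character(),
                                 stringsAsFactors = FALSE))
}

#' Write an evaluation report as keyed text plus a PR-point TSV
#'
#' @param report an [EvaluationReport-class].
#' @param prefix output path prefix; writes \code{<prefix>_report.txt} and
#'   \code{<prefix>_pr.tsv}.
#' @return the two paths, invisibly.
#' @export
writeReport <- function(report, prefix) {
  stopifnot(is(report, "EvaluationReport"))
  txt <- paste0(prefix, "_report.txt")
  keyed <- c(mode = report@mode,
             fmax = format(report@fmax, digits = 6),
             fmax_tau = format(report@fmaxTau, digits = 6),
             smin = format(report@smin, digits = 6),
             smin_tau = format(report@sminTau, digits = 6),
             coverage = format(report@coverage, digits = 6),
             auc_pr = format(report@aucpr, digits = 6))
  writeLines(paste(names(keyed), keyed, sep = "\t"), txt, useBytes = TRUE)
  tsv <- paste0(prefix, "_pr.tsv")
  p <- report@prPoints
  writeLines(c("tau\tprecision\trecall",
               paste(format(p$tau, digits = 10),
                     format(p$precision, digits = 10),
                     format(p$recall, digits = 10), sep = "\t")),
             tsv, useBytes = TRUE)
  invisible(c(txt, tsv))
}
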