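#' Specify a synthetic tripartite study
#'
#' Defines the generating conditions for a synthetic domain-protein-function
#' network with planted domain-function associations. The defaults are the
#' package's reference study conditions: 500 proteins, 50 domains, 20
#' functions, 1-3 domains per protein, planted associations only (no noise,
#' no domainless proteins).
#'
#' @param nProteins,nDomains,nFunctions layer sizes.
#' @param domainsPerProtein length-2 integer range of domains per protein.
#' @param functionsPerDomain length-2 integer range of planted functions per
#'   domain (ignored when \code{plantedMap} is given).
#' @param plantedMap optional named list domain id -> planted function ids.
#' @param noiseRate probability a planted (protein, function) edge is
#'   replaced by a uniformly random function edge.
#' @param fractionDomainless probability a protein receives no domain
#'   annotation (it then draws 1-3 random function annotations, so it can
#'   still appear in a benchmark).
#' @param functionIds optional explicit function identifiers (e.g. leaves of
#'   [generateOntology()] output).
#' @param seed integer seed; identical specs generate identical data.
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(nProteins = 500, nDomains = 50, nFunctions = 20,
                          domainsPerProtein = c(1L, 3L),
                          functionsPerDomain = c(1L, 3L),
                          plantedMap = list(), noiseRate = 0,
                          fractionDomainless = 0,
                          functionIds = character(), seed = 1L) {
  new("SyntheticSpec", nProteins = as.integer(nProteins),
      nDomains = as.integer(nDomains), nFunctions = as.integer(nFunctions),
      domainsPerProtein = as.integer(domainsPerProtein),
      functionsPerDomain = as.integer(functionsPerDomain),
      plantedMap = plantedMap, noiseRate = noiseRate,
      fractionDomainless = fractionDomainless,
      functionIds = functionIds, seed = as.integer(seed))
}

#' Generate a synthetic annotation network with planted associations
#'
#' Each domain is planted with a small set of functions (drawn once, or taken
#' from \code{spec@plantedMap}). Each protein draws its domains uniformly;
#' its function annotation is the union of the planted functions of its
#' domains, with each edge independently replaced by a uniformly random
#' function with probability \code{noiseRate}. This emulates the structural
#' assumption the prediction method exploits -- functions co-occurring with
#' their domains via shared proteins -- without imitating real degree
#' distributions.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with elements \code{domainPairs} and \code{functionPairs}
#'   ([AnnotationPairs-class]) and \code{truth}: a list holding
#'   \code{plantedMap} (domain -> functions), \code{proteinFunctions}
#'   (the pre-noise planted protein annotation) and \code{domainless}
#'   (protein ids generated without domains).
#' @examples
#' net <- generateNetwork(syntheticSpec(nProteins = 20, nDomains = 5,
#'                                      nFunctions = 4, seed = 7))
#' head(records(net$domainPairs))
#' @export
generateNetwork <- function(spec) {
  stopifnot(is(spec, "SyntheticSpec"))
  validObject(spec)
  withr::local_seed(spec@seed)
  doms <- sprintf("D%04d", seq_len(spec@nDomains))
  funs <- if (length(spec@functionIds)) spec@functionIds
          else sprintf("F%04d", seq_len(spec@nFunctions))
  planted <- spec@plantedMap
  if (!length(planted)) {
    planted <- lapply(seq_len(spec@nDomains), function(i) {
      nf <- sample(spec@functionsPerDomain[1]:spec@functionsPerDomain[2], 1L)
      sort(sample(funs, nf))
    })
    names(planted) <- doms
  } else if (!all(names(planted) %in% doms))
    stop("plantedMap names must be the generated domain ids (D0001, ...)")
  prots <- sprintf("P%05d", seq_len(spec@nProteins))
  dp <- vector("list", spec@nProteins)
  fp <- vector("list", spec@nProteins)
  plantedPF <- vector("list", spec@nProteins)
  domainless <- logical(spec@nProteins)
  for (i in seq_len(spec@nProteins)) {
    if (spec@fractionDomainless > 0 &&
        stats::runif(1) < spec@fractionDomainless) {
      domainless[i] <- TRUE
      dp[[i]] <- character()
      fset <- sort(sample(funs, sample(1:3, 1L)))
      plantedPF[[i]] <- character()
    } else {
      nd <- sample(spec@domainsPerProtein[1]:spec@domainsPerProtein[2], 1L)
      myDoms <- sort(sample(doms, nd))
      dp[[i]] <- myDoms
      fset <- sort(unique(unlist(planted[myDoms], use.names = FALSE)))
      plantedPF[[i]] <- fset
    }
    if (spec@noiseRate > 0 && length(fset)) {
      flip <- stats::runif(length(fset)) < spec@noiseRate
      if (any(flip))
        fset <- unique(c(fset[!flip], sample(funs, sum(flip), replace = TRUE)))
    }
    fp[[i]] <- fset
  }
  names(plantedPF) <- prots
  domainPairs <- annotationPairs(rep(prots, lengths(dp)),
                                 unlist(dp, use.names = FALSE),
                                 layer = "domain", sourceLabel = "synthetic")
  functionPairs <- annotationPairs(rep(prots, lengths(fp)),
                                   unlist(fp, use.names = FALSE),
                                   layer = "function",
                                   sourceLabel = "synthetic")
  list(domainPairs = domainPairs, functionPairs = functionPairs,
       truth = list(plantedMap = planted,
                    proteinFunctions = plantedPF[lengths(plantedPF) > 0L],
                    domainless = prots[domainless]))
}

#' Generate a toy rooted-tree ontology in OBO format
#'
#' Builds a complete tree of the given depth and branching factor
#' (\eqn{\sum_{l=0}^{depth} branching^l} terms), serialized as OBO 1.2 so it
#' round-trips through [parseOBO()].
#'
#' @param depth tree depth (>= 1; depth 1 is a root plus its children).
#' @param branching children per internal node (>= 1).
#' @param seed integer seed (term ids are deterministic; the seed is kept in
#'   the header for provenance).
#' @param path output file path (default: a tempfile).
#' @return \code{path}, with attribute \code{"leaves"} holding the leaf term
#'   ids.
#' @export
generateOntology <- function(depth, branching, seed = 1L,
                             path = tempfile(fileext = ".obo")) {
  stopifnot(depth >= 1, branching >= 1)
  nTerms <- sum(branching^(0:depth))
  ids <- sprintf("SYN:%07d", seq_len(nTerms))
  lines <- c("format-version: 1.2",
             paste0("remark: synthetic toy ontology (depth ", depth,
                    ", branching ", branching, ", seed ", seed, ")"), "")
  parentOf <- rep(NA_integer_, nTerms)
  # breadth-first layout: node i's children are branching*(i-1)+2 .. +1+branching
  for (i in seq_len(nTerms)) {
    firstChild <- branching * (i - 1L) + 2L
    if (firstChild <= nTerms)
      parentOf[firstChild:(firstChild + branching - 1L)] <- i
  }
  for (i in seq_len(nTerms)) {
    lines <- c(lines, "[Term]", paste0("id: ", ids[i]),
               paste0("name: synthetic term ", i),
               "namespace: synthetic_process")
    if (!is.na(parentOf[i]))
      lines <- c(lines, paste0("is_a: ", ids[parentOf[i]],
                               " ! synthetic term ", parentOf[i]))
    lines <- c(lines, "")
  }
  writeLines(lines, path, useBytes = TRUE)
  leaves <- ids[!(seq_len(nTerms) %in% parentOf)]
  attr(path, "leaves") <- leaves
  path
}

#' Hold out a benchmark protein set from a synthetic network
#'
#' Withholds the function annotations of a random protein subset as
#' benchmark truth, mimicking a train/test annotation split: benchmark
#' proteins keep their domain annotations (they remain predictable) but
#' contribute nothing to the training function layer.
#'
#' @param domainPairs,functionPairs the two annotation layers.
#' @param holdoutFraction fraction of function-annotated proteins withheld
#'   (0 < f < 1; exact count \code{round(f * n)}).
#' @param seed integer seed.
#' @param subsetTag,ontologyTag passed to the returned [BenchmarkSet-class].
#' @return list with \code{trainingFunctionPairs} ([AnnotationPairs-class]),
#'   \code{benchmark} ([BenchmarkSet-class]) and \code{benchmarkProteins}.
#' @export
splitBenchmark <- function(domainPairs, functionPairs, holdoutFraction,
                           seed = 1L, subsetTag = "all", ontologyTag = "") {
  stopifnot(is(functionPairs, "AnnotationPairs"))
  if (holdoutFraction <= 0 || holdoutFraction >= 1)
    stop("holdoutFraction must lie strictly between 0 and 1")
  withr::local_seed(as.integer(seed))
  ff <- functionPairs@pairs
  prots <- sort(unique(ff$protein))
  nHold <- round(holdoutFraction * length(prots))
  if (nHold == 0L) stop("holdout fraction leaves no benchmark proteins")
  if (nHold == length(prots)) stop("split would leave an empty training set")
  bench <- sort(sample(prots, nHold))
  train <- ff[!ff$protein %in% bench, , drop = FALSE]
  if (!nrow(train)) stop("split would leave an empty training set")
  truth <- split(ff$feature[ff$protein %in% bench],
                 ff$protein[ff$protein %in% bench])
  list(trainingFunctionPairs = new("AnnotationPairs", pairs = train,
                                   layer = "function",
                                   sourceLabel = functionPairs@sourceLabel,
                                   nRead = functionPairs@nRead,
                                   nDuplicates = functionPairs@nDuplicates),
       benchmark = benchmarkSet(truth, subsetTag = subsetTag,
                                ontologyTag = ontologyTag),
       benchmarkProteins = bench)
}
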