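#' @import methods
NULL

.LAYERS <- c("domain", "function")
.METRICS <- c("jaccard", "simpson", "pcc", "hyi")
.COMBINERS <- c("stouffer", "fisher")
.UNPREDICTABLE_REASONS <- c("no-domains", "no-associations", "below-threshold")
.EVAL_MODES <- c("full", "partial", "ppp")

#' AnnotationPairs: one layer of protein annotations
#'
#' Holds deduplicated (protein, feature) annotation pairs for one layer of the
#' tripartite network: either protein-domain pairs (e.g. UniProt accession to
#' CATH FunFam or superfamily identifier) or protein-function pairs (GO term,
#' KEGG or Reactome pathway identifier), with an optional evidence-code column.
#'
#' @slot pairs data.frame with columns \code{protein}, \code{feature} and
#'   \code{evidence} (\code{NA} when the source file had no third column).
#' @slot layer either \code{"domain"} or \code{"function"}.
#' @slot sourceLabel free-text label for the annotation source
#'   (e.g. \code{"FunFam"}, \code{"GOMF"}, \code{"KEGG"}).
#' @slot nRead number of data lines read from the source file.
#' @slot nDuplicates number of duplicated (protein, feature) entries dropped.
#'
#' @seealso [readPairsFile()], [filterAnnotations()], [buildNetwork()]
#' @export
setClass("AnnotationPairs",
  representation(
    pairs = "data.frame",
    layer = "character",
    sourceLabel = "character",
    nRead = "integer",
    nDuplicates = "integer"
  ),
  prototype(
    pairs = data.frame(protein = character(), feature = character(),
                       evidence = character(), stringsAsFactors = FALSE),
    layer = "domain",
    sourceLabel = "",
    nRead = 0L,
    nDuplicates = 0L
  )
)

setValidity("AnnotationPairs", function(object) {
  p <- object@pairs
  msgs <- character()
  if (!all(c("protein", "feature", "evidence") %in% names(p)))
    msgs <- c(msgs, "pairs must have columns protein, feature, evidence")
  if (length(object@layer) != 1L || !object@layer %in% .LAYERS)
    msgs <- c(msgs, "layer must be one of 'domain', 'function'")
  if (nrow(p) > 0L) {
    if (anyDuplicated(paste(p$protein, p$feature, sep = "\r")))
      msgs <- c(msgs, "duplicate (protein, feature) entries present")
    if (any(!nzchar(p$protein)) || any(!nzchar(p$feature)))
      msgs <- c(msgs, "identifiers must be non-empty strings")
  }
  if (length(msgs)) msgs else TRUE
})

#' TripartiteNetwork: domains - proteins - functions
#'
#' The domain-protein-function tripartite network restricted to proteins
#' annotated in BOTH outer layers. Proteins connect domains to functions;
#' associations between the outer layers are computed from the protein
#' neighbour sets Np(D) and Np(F) and the total protein count nT.
#'
#' @slot proteinDomains named list: protein id -> character vector of domains.
#' @slot proteinFunctions named list: protein id -> character vector of
#'   function terms.
#' @slot domainProteins named list: domain id -> protein ids (Np(D)).
#' @slot functionProteins named list: function id -> protein ids (Np(F)).
#' @slot nTotal total number of protein nodes (nT).
#' @slot dropped named integer vector: proteins discarded from each input
#'   layer for lacking annotation in the other layer.
#' @slot multiplicityDropped count of repeated protein-feature mentions
#'   collapsed to set membership during loading (diagnostic only).
#'
#' @seealso [buildNetwork()], [neighborProteins()], [computeAssociations()]
#' @export
setClass("TripartiteNetwork",
  representation(
    proteinDomains = "list",
    proteinFunctions = "list",
    domainProteins = "list",
    functionProteins = "list",
    nTotal = "integer",
    dropped = "integer",
    multiplicityDropped = "integer"
  )
)

setValidity("TripartiteNetwork", function(object) {
  msgs <- character()
  prots <- names(object@proteinDomains)
  if (!identical(sort(prots), sort(names(object@proteinFunctions))))
    msgs <- c(msgs, "protein keys differ between the two forward maps")
  if (object@nTotal != length(prots))
    msgs <- c(msgs, "nTotal must equal the number of distinct protein keys")
  if (any(lengths(object@proteinDomains) == 0L) ||
      any(lengths(object@proteinFunctions) == 0L))
    msgs <- c(msgs, "every protein needs >= 1 edge in each layer")
  if (any(lengths(object@domainProteins) == 0L) ||
      any(lengths(object@functionProteins) == 0L))
    msgs <- c(msgs, "empty neighbour set in an inverse index")
  # inverse indexes must be exact inverses of the forward maps
  fwd <- sort(paste(rep(prots, lengths(object@proteinDomains)),
                    unlist(object@proteinDomains, use.names = FALSE)))
  inv <- sort(paste(unlist(object@domainProteins, use.names = FALSE),
                    rep(names(object@domainProteins),
                        lengths(object@domainProteins))))
  if (!identical(fwd, inv))
    msgs <- c(msgs, "domainProteins is not the inverse of proteinDomains")
  fwd <- sort(paste(rep(prots, lengths(object@proteinFunctions)),
                    unlist(object@proteinFunctions, use.names = FALSE)))
  inv <- sort(paste(unlist(object@functionProteins, use.names = FALSE),
                    rep(names(object@functionProteins),
                        lengths(object@functionProteins))))
  if (!identical(fwd, inv))
    msgs <- c(msgs, "functionProteins is not the inverse of proteinFunctions")
  if (length(msgs)) msgs else TRUE
})

#' AssociationTable: domain-function association values for one index
#'
#' One record per (domain, function) pair that shares at least one protein in
#' the network, holding the association value a_i^j under one index, together
#' with the mean and (population) standard deviation of the whole value
#' distribution used for later z-standardization.
#'
#' @slot records data.frame with columns \code{domain}, \code{fun},
#'   \code{value}.
#' @slot metric one of \code{"jaccard"}, \code{"simpson"}, \code{"pcc"},
#'   \code{"hyi"}.
#' @slot mean mean association value over all records.
#' @slot sd population standard deviation of the association values.
#'
#' @seealso [computeAssociations()], [standardizeTable()]
#' @export
setClass("AssociationTable",
  representation(records = "data.frame", metric = "character",
                 mean = "numeric", sd = "numeric")
)

setValidity("AssociationTable", function(object) {
  msgs <- character()
  if (!all(c("domain", "fun", "value") %in% names(object@records)))
    msgs <- c(msgs, "records needs columns domain, fun, value")
  if (!object@metric %in% .METRICS)
    msgs <- c(msgs, "unknown metric")
  if (nrow(object@records) &&
      anyDuplicated(paste(object@records$domain, object@records$fun, sep = "\r")))
    msgs <- c(msgs, "more than one record for a (domain, function) pair")
  if (length(object@sd) == 1L && !is.na(object@sd) && object@sd < 0)
    msgs <- c(msgs, "sd must be >= 0")
  v <- object@records$value
  if (length(v)) {
    ok <- switch(object@metric,
      jaccard = all(v >= 0 & v <= 1),
      simpson = all(v > 0 & v <= 1),
      pcc     = all(v >= -1 & v <= 1),
      hyi     = all(v >= 0 & is.finite(v)))
    if (!ok) msgs <- c(msgs, sprintf("values out of range for metric '%s'",
                                     object@metric))
  }
  if (length(msgs)) msgs else TRUE
})

#' StandardizedTable: z-scored association values
#'
#' @slot records data.frame with columns \code{domain}, \code{fun}, \code{z}.
#' @slot metric the source association index.
#' @slot absTransformed whether absolute values were taken before
#'   standardization (intended for the signed PCC index).
#'
#' @seealso [standardizeTable()]
#' @export
setClass("StandardizedTable",
  representation(records = "data.frame", metric = "character",
                 absTransformed = "logical")
)

setValidity("StandardizedTable", function(object) {
  msgs <- character()
  if (!all(c("domain", "fun", "z") %in% names(object@records)))
    msgs <- c(msgs, "records needs columns domain, fun, z")
  z <- object@records$z
  if (length(z) && !all(is.finite(z)))
    msgs <- c(msgs, "z values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' PredictionSet: ranked per-protein function predictions
#'
#' @slot records data.frame with columns \code{protein}, \code{fun},
#'   \code{domains} (comma-joined contributing domain ids), \code{k}
#'   (number of contributing domains), \code{raw} (combined Stouffer Z or
#'   Fisher p-value) and \code{normalized} (range-normalized score in
#'   \[0.001, 1\]).
#' @slot method \code{"stouffer"}, \code{"fisher"} or \code{"naive"}.
#' @slot predicted protein ids with at least one retained prediction.
#' @slot unpredictable data.frame with columns \code{protein}, \code{reason}
#'   (\code{"no-domains"}, \code{"no-associations"} or
#'   \code{"below-threshold"}).
#'
#' @seealso [predictAll()], [writePredictions()]
#' @export
setClass("PredictionSet",
  representation(records = "data.frame", method = "character",
                 predicted = "character", unpredictable = "data.frame")
)

setValidity("PredictionSet", function(object) {
  msgs <- character()
  r <- object@records
  need <- c("protein", "fun", "domains", "k", "raw", "normalized")
  if (!all(need %in% names(r)))
    msgs <- c(msgs, paste("records needs columns", paste(need, collapse = ", ")))
  if (length(intersect(object@predicted, object@unpredictable$protein)))
    msgs <- c(msgs, "predicted and unpredictable sets must be disjoint")
  if (nrow(r)) {
    if (!all(r$protein %in% object@predicted))
      msgs <- c(msgs, "every record's protein must be in the predicted set")
    if (any(r$normalized < 0.001 - 1e-12 | r$normalized > 1 + 1e-12))
      msgs <- c(msgs, "normalized scores must lie in [0.001, 1]")
  }
  if (nrow(object@unpredictable) &&
      !all(object@unpredictable$reason %in% .UNPREDICTABLE_REASONS))
    msgs <- c(msgs, "unknown unpredictable reason")
  if (length(msgs)) msgs else TRUE
})

#' OntologyDAG: parsed ontology term graph
#'
#' A minimal directed acyclic term graph read from an OBO 1.2 file, keeping
#' is_a and part_of parent edges, per-term namespaces, root terms, obsolete
#' flags, and alt_id aliases mapped to primary identifiers.
#'
#' @slot parents named list: term id -> character vector of parent term ids.
#' @slot namespace named character: term id -> namespace.
#' @slot roots term ids with no parents (one or more per namespace).
#' @slot obsolete term ids flagged is_obsolete (carry no edges).
#' @slot altId named character: alternate id -> primary id.
#'
#' @seealso [parseOBO()], [propagateTerms()], [informationAccretion()]
#' @export
setClass("OntologyDAG",
  representation(parents = "list", namespace = "character",
                 roots = "character", obsolete = "character",
                 altId = "character")
)

setValidity("OntologyDAG", function(object) {
  msgs <- character()
  if (length(object@obsolete) &&
      any(lengths(object@parents[object@obsolete]) > 0L))
    msgs <- c(msgs, "obsolete terms must carry no edges")
  if (length(msgs)) msgs else TRUE
})

#' TermIC: per-term information accretion (bits)
#'
#' Information accretion ia(t) = -log2 P(t | parents of t), estimated from a
#' propagated annotation corpus; the per-term weight used by the Smin
#' semantic-distance metric. Root terms have ia = 0.
#'
#' @slot ia named numeric vector of non-negative bit weights.
#' @slot pseudoCount pseudo-count used for never-annotated terms.
#' @slot defaultIA ia assigned to terms absent from the vector.
#'
#' @seealso [informationAccretion()], [smin()]
#' @export
setClass("TermIC",
  representation(ia = "numeric", pseudoCount = "numeric", defaultIA = "numeric")
)

setValidity("TermIC", function(object) {
  if (length(object@ia) && any(object@ia < -1e-12))
    "information accretion must be non-negative" else TRUE
})

#' BenchmarkSet: ground-truth annotations for evaluation
#'
#' @slot truth named list: protein id -> character vector of true terms
#'   (expected propagated and root-free for ontology benchmarks).
#' @slot subsetTag \code{"no-knowledge"}, \code{"limited-knowledge"} or
#'   \code{"all"}.
#' @slot ontologyTag free-text label of the annotation source.
#'
#' @seealso [fmax()], [smin()], [benchmarkCoverage()]
#' @export
setClass("BenchmarkSet",
  representation(truth = "list", subsetTag = "character",
                 ontologyTag = "character"),
  prototype(subsetTag = "all", ontologyTag = "")
)

setValidity("BenchmarkSet", function(object) {
  msgs <- character()
  if (!object@subsetTag %in% c("no-knowledge", "limited-knowledge", "all"))
    msgs <- c(msgs, "unknown subsetTag")
  if (length(object@truth) && any(lengths(object@truth) == 0L))
    msgs <- c(msgs, "every truth set must be non-empty")
  if (length(object@truth) && is.null(names(object@truth)))
    msgs <- c(msgs, "truth must be a named list")
  if (length(msgs)) msgs else TRUE
})

#' EvaluationReport: protein-centric benchmark results
#'
#' @slot fmax maximum harmonic mean of averaged precision and recall.
#' @slot fmaxTau score threshold attaining fmax.
#' @slot smin minimum semantic distance (NA when no term weights supplied).
#' @slot sminTau threshold attaining smin.
#' @slot coverage fraction of benchmark proteins with >= 1 prediction.
#' @slot prPoints data.frame with columns \code{tau}, \code{precision},
#'   \code{recall}.
#' @slot aucpr area under the pooled precision-recall curve (step
#'   interpolation; NA for threshold-grid protein-centric reports).
#' @slot mode \code{"full"}, \code{"partial"} or \code{"ppp"}.
#'
#' @export
setClass("EvaluationReport",
  representation(fmax = "numeric", fmaxTau = "numeric",
                 smin = "numeric", sminTau = "numeric",
                 coverage = "numeric", prPoints = "data.frame",
                 aucpr = "numeric", mode = "character"),
  prototype(smin = NA_real_, sminTau = NA_real_, aucpr = NA_real_)
)

setValidity("EvaluationReport", function(object) {
  msgs <- character()
  if (!object@mode %in% .EVAL_MODES)
    msgs <- c(msgs, "mode must be 'full', 'partial' or 'ppp'")
  if (!is.na(object@fmax) && (object@fmax < 0 || object@fmax > 1))
    msgs <- c(msgs, "fmax out of [0,1]")
  if (!is.na(object@coverage) && (object@coverage < 0 || object@coverage > 1))
    msgs <- c(msgs, "coverage out of [0,1]")
  if (!is.na(object@smin) && object@smin < 0)
    msgs <- c(msgs, "smin must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' SyntheticSpec: parameters of the synthetic network generator
#'
#' @slot nProteins,nDomains,nFunctions layer sizes.
#' @slot domainsPerProtein integer range (min, max) of domains drawn per
#'   protein.
#' @slot functionsPerDomain integer range (min, max) of planted functions per
#'   domain (used when no explicit planted map is supplied).
#' @slot plantedMap named list: domain id -> planted function ids (empty list
#'   means draw one at generation time).
#' @slot noiseRate probability that a planted (protein, function) edge is
#'   replaced by a uniformly random function edge.
#' @slot fractionDomainless probability that a protein receives no domain
#'   annotation (it still receives random function annotations).
#' @slot functionIds optional explicit function identifiers (e.g. leaves of a
#'   generated toy ontology).
#' @slot seed integer seed; identical seed implies identical output.
#'
#' @seealso [syntheticSpec()], [generateNetwork()]
#' @export
setClass("SyntheticSpec",
  representation(nProteins = "integer", nDomains = "integer",
                 nFunctions = "integer", domainsPerProtein = "integer",
                 functionsPerDomain = "integer", plantedMap = "list",
                 noiseRate = "numeric", fractionDomainless = "numeric",
                 functionIds = "character", seed = "integer")
)

setValidity("SyntheticSpec", function(object) {
  msgs <- character()
  if (any(c(object@nProteins, object@nDomains, object@nFunctions) < 1L))
    msgs <- c(msgs, "layer sizes must be >= 1")
  if (length(object@domainsPerProtein) != 2L ||
      object@domainsPerProtein[1] > object@domainsPerProtein[2] ||
      object@domainsPerProtein[1] < 1L)
    msgs <- c(msgs, "domainsPerProtein must be an increasing range >= 1")
  if (object@domainsPerProtein[2] > object@nDomains)
    msgs <- c(msgs, "domainsPerProtein exceeds the number of domains")
  if (length(object@functionsPerDomain) != 2L ||
      object@functionsPerDomain[1] > object@functionsPerDomain[2] ||
      object@functionsPerDomain[1] < 1L)
    msgs <- c(msgs, "functionsPerDomain must be an increasing range >= 1")
  if (object@functionsPerDomain[2] > object@nFunctions)
    msgs <- c(msgs, "functionsPerDomain exceeds the number of functions")
  if (object@noiseRate < 0 || object@noiseRate > 1 ||
      object@fractionDomainless < 0 || object@fractionDomainless > 1)
    msgs <- c(msgs, "probabilities must lie in [0,1]")
  if (length(object@functionIds) &&
      length(object@functionIds) != object@nFunctions)
    msgs <- c(msgs, "functionIds length must equal nFunctions")
  if (length(msgs)) msgs else TRUE
})
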