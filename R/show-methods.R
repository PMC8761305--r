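setMethod("show", "AnnotationPairs", function(object) {
  cat(sprintf("AnnotationPairs: %d pairs (%s layer, source '%s')\n",
              nrow(object@pairs), object@layer, object@sourceLabel))
  cat(sprintf("  proteins: %d  features: %d  lines read: %d  duplicates dropped: %d\n",
              length(unique(object@pairs$protein)),
              length(unique(object@pairs$feature)),
              object@nRead, object@nDuplicates))
})

setMethod("show", "TripartiteNetwork", function(object) {
  s <- networkSummary(object)
  cat("TripartiteNetwork (domains - proteins - functions)\n")
  cat(sprintf("  proteins (nT): %d  domains: %d  functions: %d\n",
              s["proteins"], s["domains"], s["functions"]))
  cat(sprintf("  edges: %d protein-domain, %d protein-function\n",
              s["domainEdges"], s["functionEdges"]))
  cat(sprintf("  dropped at layer intersection: %d domain-only, %d function-only proteins\n",
              s["droppedDomainLayer"], s["droppedFunctionLayer"]))
})

setMethod("show", "AssociationTable", function(object) {
  cat(sprintf("AssociationTable: %d domain-function records, metric '%s'\n",
              nrow(object@records), object@metric))
  cat(sprintf("  value mean %.4g, population sd %.4g\n",
              object@mean, object@sd))
})

setMethod("show", "StandardizedTable", function(object) {
  cat(sprintf("StandardizedTable: %d z-scored records (metric '%s'%s)\n",
              nrow(object@records), object@metric,
              if (object@absTransformed) ", abs-transformed" else ""))
})

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet (%s): %d predictions for %d proteins\n",
              object@method, nrow(object@records), length(object@predicted)))
  if (nrow(object@unpredictable)) {
    tab <- table(object@unpredictable$reason)
    cat("  unpredictable:",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "OntologyDAG", function(object) {
  cat(sprintf("OntologyDAG: %d terms (%d obsolete), %d parent edges, %d root(s)\n",
              length(object@parents), length(object@obsolete),
              sum(lengths(object@parents)), length(object@roots)))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport (%s mode)\n", object@mode))
  cat(sprintf("  Fmax: %.4f at tau %.3g   coverage: %.4f\n",
              object@fmax, object@fmaxTau, object@coverage))
  if (!is.na(object@smin))
    cat(sprintf("  Smin: %.4f at tau %.3g\n", object@smin, object@sminTau))
  if (!is.na(object@aucpr))
    cat(sprintf("  AUC-PR: %.4f\n", object@aucpr))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d proteins, %d domains, %d functions (seed %d)\n",
              object@nProteins, object@nDomains, object@nFunctions,
              object@seed))
  cat(sprintf("  domains/protein %d-%d, noise %.2f, domainless fraction %.2f\n",
              object@domainsPerProtein[1], object@domainsPerProtein[2],
              object@noiseRate, object@fractionDomainless))
})
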