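#' Build the domain-protein-function tripartite network
#'
#' Combines one protein-domain and one protein-function annotation layer into
#' a tripartite network. Only proteins annotated in BOTH layers are kept
#' (associations are computed from dually annotated proteins); the counts of
#' proteins dropped from each layer are recorded. Repeated feature mentions
#' within one protein are collapsed to set membership.
#'
#' @param domainPairs [AnnotationPairs-class] with \code{layer = "domain"}.
#' @param functionPairs [AnnotationPairs-class] with
#'   \code{layer = "function"}.
#' @return a [TripartiteNetwork-class].
#' @examples
#' dom <- annotationPairs(c("P1", "P2"), c("D1", "D1"), layer = "domain")
#' fun <- annotationPairs("P1", "F1", layer = "function")
#' net <- buildNetwork(dom, fun)   # P2 has no function annotation: dropped
#' nProteins(net)
#' @export
buildNetwork <- function(domainPairs, functionPairs) {
  stopifnot(is(domainPairs, "AnnotationPairs"),
            is(functionPairs, "AnnotationPairs"))
  if (domainPairs@layer != "domain" || functionPairs@layer != "function")
    stop("buildNetwork() expects a domain-layer and a function-layer object")
  dd <- domainPairs@pairs
  ff <- functionPairs@pairs
  if (!nrow(dd) || !nrow(ff)) stop("both annotation layers must be non-empty")
  shared <- intersect(unique(dd$protein), unique(ff$protein))
  if (!length(shared))
    stop("empty network: no protein is annotated in both layers")
  droppedDomain <- length(unique(dd$protein)) - length(shared)
  droppedFunction <- length(unique(ff$protein)) - length(shared)
  dd <- dd[dd$protein %in% shared, , drop = FALSE]
  ff <- ff[ff$protein %in% shared, , drop = FALSE]
  new("TripartiteNetwork",
      proteinDomains = split(dd$feature, dd$protein),
      proteinFunctions = split(ff$feature, ff$protein),
      domainProteins = split(dd$protein, dd$feature),
      functionProteins = split(ff$protein, ff$feature),
      nTotal = length(shared),
      dropped = c(domain = droppedDomain, "function" = droppedFunction),
      multiplicityDropped = domainPairs@nDuplicates + functionPairs@nDuplicates)
}

#' @describeIn neighborProteins look up Np(node) in a TripartiteNetwork
#' @export
setMethod("neighborProteins", "TripartiteNetwork", function(network, id, layer) {
  layer <- match.arg(layer, .LAYERS)
  idx <- if (layer == "domain") network@domainProteins else network@functionProteins
  if (!id %in% names(idx))
    stop(sprintf("node '%s' not found in the %s layer", id, layer))
  idx[[id]]
})

#' Keyed summary of a tripartite network
#'
#' @param network a [TripartiteNetwork-class].
#' @return named numeric vector: protein/domain/function node counts, edge
#'   counts per layer, and proteins dropped from each input layer.
#' @export
networkSummary <- function(network) {
  stopifnot(is(network, "TripartiteNetwork"))
  c(proteins = network@nTotal,
    domains = length(network@domainProteins),
    functions = length(network@functionProteins),
    domainEdges = sum(lengths(network@proteinDomains)),
    functionEdges = sum(lengths(network@proteinFunctions)),
    droppedDomainLayer = unname(network@dropped["domain"]),
    droppedFunctionLayer = unname(network@dropped["function"]))
}

#' Dump a tripartite network as two TSV edge lists
#'
#' Writes \code{<prefix>_domains.tsv} (protein, domain) and
#' \code{<prefix>_functions.tsv} (protein, function), sorted so a rebuild is
#' byte-reproducible.
#'
#' @param network a [TripartiteNetwork-class].
#' @param prefix output path prefix.
#' @return character vector of the two paths written, invisibly.
#' @export
writeNetwork <- function(network, prefix) {
  stopifnot(is(network, "TripartiteNetwork"))
  dump1 <- function(map, path) {
    df <- data.frame(protein = rep(names(map), lengths(map)),
                     feature = unlist(map, use.names = FALSE))
    df <- df[order(df$protein, df$feature), ]
    writeLines(paste(df$protein, df$feature, sep = "\t"), path, useBytes = TRUE)
    path
  }
  paths <- c(dump1(network@proteinDomains, paste0(prefix, "_domains.tsv")),
             dump1(network@proteinFunctions, paste0(prefix, "_functions.tsv")))
  invisible(paths)
}
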