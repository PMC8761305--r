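#' Access the record table of a container
#'
#' Returns the underlying data.frame of an [AnnotationPairs-class],
#' [AssociationTable-class], [StandardizedTable-class] or
#' [PredictionSet-class] object.
#'
#' @param x the container object.
#' @return a data.frame (a copy; containers are immutable).
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname records
#' @export
setMethod("records", "AnnotationPairs", function(x) x@pairs)

#' @rdname records
#' @export
setMethod("records", "AssociationTable", function(x) x@records)

#' @rdname records
#' @export
setMethod("records", "StandardizedTable", function(x) x@records)

#' @rdname records
#' @export
setMethod("records", "PredictionSet", function(x) x@records)

#' Protein neighbour set of a domain or function node
#'
#' Returns Np(node): the set of protein nodes connected to the given node in
#' the stated layer of the tripartite network. Network construction
#' guarantees the result is never empty.
#'
#' @param network a [TripartiteNetwork-class].
#' @param id node identifier.
#' @param layer \code{"domain"} or \code{"function"}.
#' @return character vector of protein ids.
#' @examples
#' net <- buildNetwork(
#'   annotationPairs(c("P1", "P2"), c("D1", "D1"), layer = "domain"),
#'   annotationPairs(c("P1", "P2"), c("F1", "F2"), layer = "function"))
#' neighborProteins(net, "D1", "domain")
#' @export
setGeneric("neighborProteins",
           function(network, id, layer) standardGeneric("neighborProteins"))

#' Number of protein nodes in the network (nT)
#' @param x a [TripartiteNetwork-class].
#' @return integer count of protein nodes.
#' @export
setGeneric("nProteins", function(x) standardGeneric("nProteins"))

#' @rdname nProteins
#' @export
setMethod("nProteins", "TripartiteNetwork", function(x) x@nTotal)

#' Compute domain-function associations over a tripartite network
#'
#' @param network a [TripartiteNetwork-class].
#' @param metric \code{"jaccard"}, \code{"simpson"}, \code{"pcc"} or
#'   \code{"hyi"}.
#' @param ... further arguments passed to methods (\code{hyiCap}).
#' @return an [AssociationTable-class].
#' @export
setGeneric("computeAssociations",
           function(network, metric, ...) standardGeneric("computeAssociations"))

#' Association-distribution accessors
#'
#' Mean and population standard deviation of all association values in the
#' table (the quantities used for z-standardization).
#'
#' @param x an [AssociationTable-class].
#' @return a single numeric value.
#' @export
setGeneric("assocMean", function(x) standardGeneric("assocMean"))

#' @rdname assocMean
#' @export
setGeneric("assocSd", function(x) standardGeneric("assocSd"))

#' @rdname assocMean
#' @export
setMethod("assocMean", "AssociationTable", function(x) x@mean)

#' @rdname assocMean
#' @export
setMethod("assocSd", "AssociationTable", function(x) x@sd)

#' Prediction-set partitions
#'
#' \code{predictedProteins} returns the proteins with at least one retained
#' prediction; \code{unpredictableProteins} returns a data.frame of proteins
#' without predictions and the reason (\code{no-domains},
#' \code{no-associations}, \code{below-threshold}). The two partitions are
#' disjoint and together cover every queried protein.
#'
#' @param x a [PredictionSet-class].
#' @export
setGeneric("predictedProteins", function(x) standardGeneric("predictedProteins"))

#' @rdname predictedProteins
#' @export
setGeneric("unpredictableProteins",
           function(x) standardGeneric("unpredictableProteins"))

#' @rdname predictedProteins
#' @export
setMethod("predictedProteins", "PredictionSet", function(x) x@predicted)

#' @rdname predictedProteins
#' @export
setMethod("unpredictableProteins", "PredictionSet", function(x) x@unpredictable)
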