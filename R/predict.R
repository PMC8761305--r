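.assocLookup <- function(associations, method) {
  if (method == "stouffer") {
    if (!is(associations, "StandardizedTable"))
      stop("the stouffer combiner needs a StandardizedTable of z-scores; ",
           "run standardizeTable() first")
    r <- associations@records
    r$value <- r$z
  } else {
    if (!is(associations, "AssociationTable"))
      stop("the fisher combiner needs an AssociationTable of HyI values")
    if (associations@metric != "hyi")
      stop("the fisher combiner is defined for HyI-derived p-values only")
    r <- associations@records
    r$value <- hyiToPvalue(r$value)
  }
  split(r[c("domain", "fun", "value")], r$domain)
}

.asDomainMap <- function(domainMap) {
  if (is(domainMap, "AnnotationPairs")) {
    if (domainMap@layer != "domain")
      stop("domainMap must be domain-layer annotation")
    split(domainMap@pairs$feature, domainMap@pairs$protein)
  } else if (is(domainMap, "TripartiteNetwork")) {
    domainMap@proteinDomains
  } else if (is.list(domainMap)) {
    domainMap
  } else stop("unsupported domainMap type")
}

#' Predict functions for a single protein
#'
#' Looks up the protein's domains, gathers every function associated with at
#' least one of them, and combines the per-domain association values into one
#' raw score per function. Absence of predictions is a value, not an error:
#' proteins without domain annotation report \code{"no-domains"}, proteins
#' whose domains carry no association records report \code{"no-associations"}.
#'
#' @param protein protein identifier.
#' @param domainMap named list protein -> domains, an [AnnotationPairs-class]
#'   domain layer, or a [TripartiteNetwork-class].
#' @param associations a [StandardizedTable-class] (for \code{"stouffer"}) or
#'   an HyI [AssociationTable-class] (for \code{"fisher"}).
#' @param method the combiner.
#' @return a list with elements \code{status} (\code{"predicted"} or an
#'   unpredictable reason) and \code{scores} (data.frame \code{fun},
#'   \code{domains}, \code{k}, \code{raw}; \code{NULL} when unpredictable).
#' @examples
#' net <- buildNetwork(
#'   annotationPairs(c("P1", "P2"), c("D1", "D1"), layer = "domain"),
#'   annotationPairs(c("P1", "P2"), c("F1", "F1"), layer = "function"))
#' tab <- computeAssociations(net, "hyi")
#' predictProtein("P1", net, tab, method = "fisher")
#' @export
predictProtein <- function(protein, domainMap, associations,
                           method = c("stouffer", "fisher")) {
  method <- match.arg(method)
  lookup <- .assocLookup(associations, method)
  .predictOne(protein, .asDomainMap(domainMap), lookup, method)
}

.predictOne <- function(protein, domainMap, lookup, method) {
  doms <- domainMap[[protein]]
  if (is.null(doms) || !length(doms))
    return(list(status = "no-domains", scores = NULL))
  rows <- lookup[intersect(doms, names(lookup))]
  if (!length(rows))
    return(list(status = "no-associations", scores = NULL))
  rows <- do.call(rbind, rows)
  perFun <- split(rows[c("domain", "value")], rows$fun)
  list(status = "predicted", scores = combineForProtein(perFun, method))
}

#' Predict functions for a set of proteins
#'
#' Runs [predictProtein()] over every query, pools the combined scores,
#' applies [normalizeScores()] (range normalization plus the
#' \code{minScore} removal filter) over the whole run, and partitions the
#' queries into predicted and unpredictable proteins. A protein whose every
#' score falls below \code{minScore} is recorded with reason
#' \code{"below-threshold"}, so
#' \code{length(predicted) + nrow(unpredictable)} always equals the number
#' of queried proteins.
#'
#' @param proteins character vector of query protein ids.
#' @inheritParams predictProtein
#' @param minScore removal threshold on normalized scores.
#' @return a [PredictionSet-class].
#' @export
predictAll <- function(proteins, domainMap, associations,
                       method = c("stouffer", "fisher"), minScore = 0.001) {
  method <- match.arg(method)
  if (!length(proteins)) stop("no query proteins supplied")
  proteins <- unique(proteins)
  lookup <- .assocLookup(associations, method)
  dmap <- .asDomainMap(domainMap)
  reasons <- character()
  scored <- vector("list", length(proteins))
  for (i in seq_along(proteins)) {
    res <- .predictOne(proteins[i], dmap, lookup, method)
    if (res$status == "predicted") {
      res$scores$protein <- proteins[i]
      scored[[i]] <- res$scores
    } else {
      reasons[proteins[i]] <- res$status
    }
  }
  pooled <- do.call(rbind, scored[!vapply(scored, is.null, TRUE)])
  if (is.null(pooled))
    pooled <- data.frame(protein = character(), fun = character(),
                         domains = character(), k = integer(),
                         raw = numeric(), stringsAsFactors = FALSE)
  kept <- normalizeScores(pooled, method, minScore = minScore)
  hadScores <- setdiff(unique(pooled$protein), unique(kept$protein))
  reasons[hadScores] <- "below-threshold"
  rec <- kept[c("protein", "fun", "domains", "k", "raw", "normalized")]
  rec <- rec[order(rec$protein, -rec$normalized, rec$fun), , drop = FALSE]
  rownames(rec) <- NULL
  new("PredictionSet", records = rec, method = method,
      predicted = unique(rec$protein),
      unpredictable = data.frame(protein = names(reasons),
                                 reason = unname(reasons),
                                 stringsAsFactors = FALSE))
}

#' Write predictions to disk
#'
#' \code{format = "tsv"} writes the full record table (header line; columns
#' protein, fun, domains, k, raw, normalized). \code{format = "cafa"} writes
#' benchmark-submission rows: target id, term id, score rounded to 2
#' decimals, with zero-rounded scores floored at 0.01 to stay inside
#' (0, 1]. Output ordering is deterministic: protein ascending, score
#' descending, function id ascending.
#'
#' @param set a [PredictionSet-class].
#' @param path output path.
#' @param format \code{"tsv"} or \code{"cafa"}.
#' @return \code{path}, invisibly.
#' @export
writePredictions <- function(set, path, format = c("tsv", "cafa")) {
  format <- match.arg(format)
  stopifnot(is(set, "PredictionSet"))
  r <- set@records
  r <- r[order(r$protein, -r$normalized, r$fun), , drop = FALSE]
  if (!nrow(r)) warning("writing an empty prediction set")
  if (format == "tsv") {
    header <- paste(c("protein", "fun", "domains", "k", "raw", "normalized"),
                    collapse = "\t")
    body <- paste(r$protein, r$fun, r$domains, r$k,
                  formatC(r$raw, digits = 17, format = "g"),
                  formatC(r$normalized, digits = 17, format = "g"), sep = "\t")
    writeLines(c(header, body), path, useBytes = TRUE)
  } else {
    score <- pmax(round(r$normalized, 2), 0.01)
    writeLines(paste(r$protein, r$fun, sprintf("%.2f", score), sep = "\t"),
               path, useBytes = TRUE)
  }
  invisible(path)
}

#' Re-read a TSV prediction file written by [writePredictions()]
#'
#' @param path path to a TSV prediction table.
#' @param method method tag to attach.
#' @param queried optional character vector of the originally queried
#'   proteins, used to rebuild the unpredictable partition (reason cannot be
#'   recovered from the table and is recorded as \code{"no-associations"}).
#' @return a [PredictionSet-class].
#' @export
readPredictions <- function(path, method = c("stouffer", "fisher", "naive"),
                            queried = NULL) {
  method <- match.arg(method)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "character",
                                         "integer", "numeric", "numeric"),
                          quote = "", comment.char = "")
  names(df) <- c("protein", "fun", "domains", "k", "raw", "normalized")
  unpred <- data.frame(protein = character(), reason = character(),
                       stringsAsFactors = FALSE)
  if (!is.null(queried)) {
    missing <- setdiff(queried, unique(df$protein))
    unpred <- data.frame(protein = missing,
                         reason = rep("no-associations", length(missing)),
                         stringsAsFactors = FALSE)
  }
  new("PredictionSet", records = df, method = method,
      predicted = unique(df$protein), unpredictable = unpred)
}
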