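#' Association indices between two protein neighbour sets
#'
#' The four indices scoring how strongly a domain D and a function F
#' co-occur over proteins, given their protein neighbour sets Np(D), Np(F)
#' and the total protein count nT:
#' \describe{
#'   \item{Jaccard}{\eqn{|Np(D) \cap Np(F)| / |Np(D) \cup Np(F)|}}
#'   \item{Simpson}{\eqn{|Np(D) \cap Np(F)| / \min(|Np(D)|, |Np(F)|)};
#'     normalizes by the less-connected node, which compensates for the large
#'     size discrepancies between domain and function neighbourhoods.}
#'   \item{PCC}{the phi coefficient of the two binary protein-membership
#'     profiles:
#'     \eqn{(|\cap| nT - |Np(D)||Np(F)|) / \sqrt{|Np(D)||Np(F)|(nT-|Np(D)|)(nT-|Np(F)|)}}}
#'   \item{HyI}{\eqn{-\log_{10}} of the upper-tail hypergeometric probability
#'     of observing at least the given overlap; an over-representation
#'     score.}
#' }
#'
#' @param npD,npF character vectors: the protein neighbour sets (non-empty).
#' @param nTotal total number of protein nodes nT.
#' @param cap maximum HyI returned when the tail probability underflows to
#'   zero (no infinities are emitted).
#' @return a single numeric association value.
#' @examples
#' jaccardIndex(c("p1", "p2", "p3"), c("p2", "p3", "p4"))   # 0.5
#' simpsonIndex(c("p1", "p2", "p3"), c("p2", "p3", "p4"))   # 2/3
#' hypergeometricIndex(c("p1", "p2"), c("p1", "p2"), nTotal = 5)  # 1
#' @name associationIndices
NULL

.checkSets <- function(npD, npF) {
  if (!length(npD) || !length(npF))
    stop("association indices are undefined for empty protein sets")
}

#' @rdname associationIndices
#' @export
jaccardIndex <- function(npD, npF) {
  .checkSets(npD, npF)
  i <- length(intersect(npD, npF))
  i / (length(unique(npD)) + length(unique(npF)) - i)
}

#' @rdname associationIndices
#' @export
simpsonIndex <- function(npD, npF) {
  .checkSets(npD, npF)
  length(intersect(npD, npF)) / min(length(unique(npD)), length(unique(npF)))
}

#' @rdname associationIndices
#' @export
pccIndex <- function(npD, npF, nTotal) {
  .checkSets(npD, npF)
  d <- length(unique(npD)); f <- length(unique(npF))
  if (d >= nTotal || f >= nTotal)
    stop("PCC undefined: a neighbour set covers all protein nodes")
  i <- length(intersect(npD, npF))
  (i * nTotal - d * f) / sqrt(d * f * (nTotal - d) * (nTotal - f))
}

#' @rdname associationIndices
#' @export
hypergeometricIndex <- function(npD, npF, nTotal, cap = 300) {
  .checkSets(npD, npF)
  d <- length(unique(npD)); f <- length(unique(npF))
  i <- length(intersect(npD, npF))
  if (d > nTotal || f > nTotal)
    stop("neighbour set larger than the network")
  if (i == 0L) return(0)
  # upper tail P(X >= i), X ~ Hypergeom(nT, |Np(D)|, draws |Np(F)|), log space
  logTail <- stats::phyper(i - 1L, d, nTotal - d, f,
                           lower.tail = FALSE, log.p = TRUE)
  hyi <- -logTail / log(10)
  if (!is.finite(hyi) || hyi > cap) {
    warning("hypergeometric tail underflow; HyI capped at ", cap)
    hyi <- cap
  }
  max(hyi, 0)
}

.popSd <- function(v) sqrt(mean((v - mean(v))^2))

#' @describeIn computeAssociations one record per (domain, function) pair
#'   sharing at least one protein; pairs with empty protein intersection are
#'   omitted (they carry no co-occurrence signal). Pairs for which PCC is
#'   undefined (a layer node connected to every protein) are dropped with a
#'   warning.
#' @param hyiCap cap on HyI for underflowing tails (see
#'   [hypergeometricIndex()]).
#' @export
setMethod("computeAssociations", "TripartiteNetwork",
          function(network, metric, hyiCap = 300) {
  metric <- match.arg(metric, .METRICS)
  nT <- network@nTotal
  fSize <- lengths(network@functionProteins)
  doms <- names(network@domainProteins)
  out <- vector("list", length(doms))
  dropped <- 0L
  for (di in seq_along(doms)) {
    pd <- network@domainProteins[[di]]
    nd <- length(pd)
    # each protein lists each function once, so tabulating gives |Np(D) n Np(F)|
    overlap <- table(unlist(network@proteinFunctions[pd], use.names = FALSE))
    funs <- names(overlap)
    ov <- as.integer(overlap)
    nf <- fSize[funs]
    value <- switch(metric,
      jaccard = ov / (nd + nf - ov),
      simpson = ov / pmin(nd, nf),
      pcc = {
        den <- nd * nf * (nT - nd) * (nT - nf)
        val <- ifelse(den > 0, (ov * nT - nd * nf) / sqrt(den), NA_real_)
        dropped <- dropped + sum(is.na(val))
        val
      },
      hyi = {
        v <- -stats::phyper(ov - 1L, nd, nT - nd, nf,
                            lower.tail = FALSE, log.p = TRUE) / log(10)
        v[!is.finite(v) | v > hyiCap] <- hyiCap
        pmax(v, 0)
      })
    keep <- !is.na(value)
    out[[di]] <- data.frame(domain = rep(doms[di], sum(keep)),
                            fun = funs[keep],
                            value = unname(value[keep]),
                            stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, out)
  rec <- rec[order(rec$domain, rec$fun), , drop = FALSE]
  rownames(rec) <- NULL
  if (metric == "pcc" && dropped > 0L)
    warning(dropped, " pair(s) dropped: PCC undefined for nodes covering all proteins")
  new("AssociationTable", records = rec, metric = metric,
      mean = mean(rec$value), sd = .popSd(rec$value))
})

#' Write / read an association table as 3-column TSV
#'
#' Serializes the (domain, function, value) records of one metric, the
#' layer-pair output convention of multipartite network analysers.
#'
#' @param table an [AssociationTable-class].
#' @param path file path.
#' @param metric metric tag to attach on reading.
#' @return \code{path} (write) or an [AssociationTable-class] (read).
#' @export
writeAssociations <- function(table, path) {
  stopifnot(is(table, "AssociationTable"))
  r <- table@records
  writeLines(paste(r$domain, r$fun,
                   formatC(r$value, digits = 17, format = "g"), sep = "\t"),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname writeAssociations
#' @export
readAssociations <- function(path, metric = c("jaccard", "simpson", "pcc", "hyi")) {
  metric <- match.arg(metric)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("domain", "fun", "value"),
                          colClasses = c("character", "character", "numeric"),
                          quote = "", comment.char = "")
  new("AssociationTable", records = df, metric = metric,
      mean = mean(df$value), sd = .popSd(df$value))
}
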