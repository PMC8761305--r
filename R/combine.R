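#' Standardize an association table to z-scores
#'
#' Each association value a_i^j is replaced by
#' \eqn{z = (a_i^j - \bar a) / s}, where \eqn{\bar a} and \eqn{s} are the
#' mean and population standard deviation of ALL association values in the
#' table (the table is the full population of associations for its network
#' and metric, not a sample). With \code{takeAbsolute = TRUE} the absolute
#' values are taken first and the moments recomputed afterwards; this is
#' intended for the signed PCC index, whose values in [-1, 1] are combined
#' by magnitude.
#'
#' @param table an [AssociationTable-class].
#' @param takeAbsolute take \code{abs(value)} before standardizing.
#' @return a [StandardizedTable-class].
#' @examples
#' net <- buildNetwork(
#'   annotationPairs(c("P1", "P2", "P3"), c("D1", "D1", "D2"), layer = "domain"),
#'   annotationPairs(c("P1", "P2", "P3"), c("F1", "F2", "F2"), layer = "function"))
#' standardizeTable(computeAssociations(net, "jaccard"))
#' @export
standardizeTable <- function(table, takeAbsolute = FALSE) {
  stopifnot(is(table, "AssociationTable"))
  r <- table@records
  if (!nrow(r)) stop("cannot standardize an empty association table")
  v <- if (takeAbsolute) abs(r$value) else r$value
  m <- mean(v)
  s <- .popSd(v)
  if (s == 0)
    stop("degenerate association distribution: zero spread, z-scores undefined")
  new("StandardizedTable",
      records = data.frame(domain = r$domain, fun = r$fun, z = (v - m) / s,
                           stringsAsFactors = FALSE),
      metric = table@metric, absTransformed = takeAbsolute)
}

#' Stouffer's Z combination
#'
#' Combines k z-scores into \eqn{Z = \sum z_i / \sqrt{k}}, which is again
#' standard normal under the null.
#'
#' @param z numeric vector of z-scores (non-empty).
#' @return combined Z.
#' @examples
#' stoufferCombine(c(1, 1))   # 2 / sqrt(2)
#' @export
stoufferCombine <- function(z) {
  if (!length(z)) stop("Stouffer combination of an empty vector is undefined")
  sum(z) / sqrt(length(z))
}

#' Antilog transform of a hypergeometric index
#'
#' Maps HyI back to the upper-tail probability it encodes:
#' \eqn{p = 10^{-HyI} \in (0, 1]}.
#'
#' @param hyi non-negative HyI value(s).
#' @return probability in (0, 1].
#' @export
hyiToPvalue <- function(hyi) {
  if (any(hyi < 0)) stop("HyI must be non-negative")
  10^(-hyi)
}

#' Fisher's combined probability test
#'
#' Combines k p-values via \eqn{X = -2 \sum \ln p_i}, which follows a
#' chi-square distribution with 2k degrees of freedom under the null; the
#' combined p-value is the upper-tail probability of X.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return combined p-value.
#' @examples
#' fisherCombine(0.05)          # k = 1 identity
#' fisherCombine(c(0.05, 0.05)) # ~ 0.01747
#' @export
fisherCombine <- function(p) {
  if (!length(p)) stop("Fisher combination of an empty vector is undefined")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  x <- -2 * sum(log(p))
  stats::pchisq(x, df = 2 * length(p), lower.tail = FALSE)
}

#' Combine per-domain association values into protein-level scores
#'
#' For one protein, collapses the association values its domains carry for
#' each candidate function into a single combined score: Stouffer's method
#' over z-scores, or Fisher's method over HyI-derived p-values. k is the
#' number of domains contributing a value for that function.
#'
#' @param perDomainValues named list: function id -> data.frame with columns
#'   \code{domain} and \code{value} (z-scores for \code{"stouffer"},
#'   p-values for \code{"fisher"}).
#' @param method \code{"stouffer"} or \code{"fisher"}.
#' @return data.frame with columns \code{fun}, \code{domains} (comma-joined),
#'   \code{k}, \code{raw}.
#' @export
combineForProtein <- function(perDomainValues, method = c("stouffer", "fisher")) {
  method <- match.arg(method)
  if (!length(perDomainValues)) stop("no per-domain values supplied")
  if (is.null(names(perDomainValues)))
    stop("perDomainValues must be named by function id")
  rows <- lapply(names(perDomainValues), function(fn) {
    df <- perDomainValues[[fn]]
    if (!nrow(df)) stop("function '", fn, "' has no contributing values")
    if (method == "fisher" && any(df$value <= 0 | df$value > 1))
      stop("fisher combiner given values outside (0, 1]; pass p-values")
    raw <- if (method == "stouffer") stoufferCombine(df$value)
           else fisherCombine(df$value)
    data.frame(fun = fn,
               domains = paste(sort(unique(df$domain)), collapse = ","),
               k = length(unique(df$domain)), raw = raw,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Normalize combined scores to the (0, 1] prediction range
#'
#' Applies the benchmark-submission range rules. Stouffer path: the raw
#' combined values of the run are re-standardized to z-scores, any value
#' with absolute value greater than 2 is set to (sign-preserving) 2, and the
#' clipped distribution is mapped into range by dividing by its width (4)
#' and adding 0.5. Fisher path: the combined p-value is subtracted from 1.
#' Finally every prediction with a transformed score below \code{minScore}
#' (default 0.001) is removed as spurious, so all retained scores lie in
#' \[0.001, 1\].
#'
#' @param scores data.frame of combined scores with columns \code{protein}
#'   (optional), \code{fun}, \code{k}, \code{raw} as produced by
#'   [combineForProtein()], pooled over one prediction run of ONE method.
#' @param method \code{"stouffer"} or \code{"fisher"}.
#' @param minScore removal threshold for transformed scores.
#' @return the input data.frame with a \code{normalized} column added and
#'   sub-threshold rows removed.
#' @export
normalizeScores <- function(scores, method = c("stouffer", "fisher"),
                            minScore = 0.001) {
  method <- match.arg(method)
  if (!nrow(scores)) {
    scores$normalized <- numeric(0)
    return(scores)
  }
  if (method == "stouffer") {
    s <- .popSd(scores$raw)
    z <- if (s == 0) {
      warning("zero spread in combined scores; all map to 0.5")
      rep(0, nrow(scores))
    } else (scores$raw - mean(scores$raw)) / s
    z <- pmin(pmax(z, -2), 2)
    scores$normalized <- z / 4 + 0.5
  } else {
    if (any(scores$raw < 0 | scores$raw > 1))
      stop("fisher path expects combined p-values in [0, 1]")
    scores$normalized <- 1 - scores$raw
  }
  scores[scores$normalized >= minScore, , drop = FALSE]
}
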