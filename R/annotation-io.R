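#' Construct AnnotationPairs from vectors
#'
#' Programmatic constructor used by the synthetic generators and in tests.
#' Duplicated (protein, feature) entries are collapsed (first evidence kept).
#'
#' @param protein,feature character vectors of equal length.
#' @param evidence optional character vector of evidence codes.
#' @param layer \code{"domain"} or \code{"function"}.
#' @param sourceLabel free-text annotation source label.
#' @return an [AnnotationPairs-class].
#' @examples
#' annotationPairs(c("P1", "P1"), c("D1", "D2"), layer = "domain")
#' @export
annotationPairs <- function(protein, feature, evidence = NULL,
                            layer = c("domain", "function"),
                            sourceLabel = "") {
  layer <- match.arg(layer)
  stopifnot(length(protein) == length(feature))
  if (is.null(evidence)) evidence <- rep(NA_character_, length(protein))
  df <- data.frame(protein = as.character(protein),
                   feature = as.character(feature),
                   evidence = as.character(evidence),
                   stringsAsFactors = FALSE)
  dup <- duplicated(paste(df$protein, df$feature, sep = "\r"))
  new("AnnotationPairs", pairs = df[!dup, , drop = FALSE],
      layer = layer, sourceLabel = sourceLabel,
      nRead = nrow(df), nDuplicates = sum(dup))
}

#' Read a tab-separated annotation pair file
#'
#' Each non-empty, non-comment line must have 2 or 3 tab-separated columns:
#' protein id, feature id and an optional evidence code. Lines starting with
#' \code{#} are skipped. Duplicate (protein, feature) entries are dropped and
#' counted.
#'
#' @param path path to a UTF-8 TSV file.
#' @inheritParams annotationPairs
#' @return an [AnnotationPairs-class]; the counts of lines read and
#'   duplicates dropped are available in the object's show() output.
#' @export
readPairsFile <- function(path, layer = c("domain", "function"),
                          sourceLabel = basename(path)) {
  layer <- match.arg(layer)
  if (!file.exists(path))
    stop("annotation pair file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    warning("empty annotation pair file: ", path)
    return(annotationPairs(character(), character(), layer = layer,
                           sourceLabel = sourceLabel))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected 2-3 tab-separated columns, got %d",
                 lineno[bad[1]], path, nf[bad[1]]))
  annotationPairs(
    protein = vapply(fields, `[`, "", 1L),
    feature = vapply(fields, `[`, "", 2L),
    evidence = vapply(fields, function(f) if (length(f) >= 3L) f[3L] else NA_character_, ""),
    layer = layer, sourceLabel = sourceLabel)
}

#' Write an AnnotationPairs object back to TSV
#'
#' @param pairs an [AnnotationPairs-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePairsFile <- function(pairs, path) {
  stopifnot(is(pairs, "AnnotationPairs"))
  df <- pairs@pairs
  lines <- ifelse(is.na(df$evidence),
                  paste(df$protein, df$feature, sep = "\t"),
                  paste(df$protein, df$feature, df$evidence, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Filter annotations by evidence code and protein flags
#'
#' Removes pairs whose evidence code is excluded (e.g. \code{IEA}, the GO
#' "Inferred from Electronic Annotation" code, discarded to keep only
#' high-quality annotations) and removes every annotation of proteins
#' carrying an excluded flag (e.g. \code{fragment}).
#'
#' @param pairs an [AnnotationPairs-class].
#' @param excludedEvidence character vector of evidence codes to drop.
#' @param proteinFlags named list or data.frame (\code{protein}, \code{flag})
#'   assigning free-text flags to proteins; may be \code{NULL}.
#' @param excludedFlags character vector of protein flags whose carriers are
#'   removed entirely.
#' @return a filtered [AnnotationPairs-class]; a no-op when both excluded
#'   sets are empty.
#' @examples
#' ap <- annotationPairs(c("P1", "P2"), c("GO:1", "GO:1"),
#'                       evidence = c("IEA", "EXP"), layer = "function")
#' records(filterAnnotations(ap, excludedEvidence = "IEA"))
#' @export
filterAnnotations <- function(pairs, excludedEvidence = character(),
                              proteinFlags = NULL,
                              excludedFlags = character()) {
  stopifnot(is(pairs, "AnnotationPairs"))
  df <- pairs@pairs
  if (length(excludedEvidence)) {
    if (nrow(df) && all(is.na(df$evidence)))
      stop("evidence filter requested but the pairs carry no evidence column")
    df <- df[is.na(df$evidence) | !df$evidence %in% excludedEvidence, ,
             drop = FALSE]
  }
  if (length(excludedFlags) && !is.null(proteinFlags)) {
    if (is.data.frame(proteinFlags)) {
      flagged <- unique(proteinFlags$protein[proteinFlags$flag %in% excludedFlags])
    } else {
      flagged <- names(proteinFlags)[vapply(proteinFlags, function(f)
        any(f %in% excludedFlags), logical(1))]
    }
    df <- df[!df$protein %in% flagged, , drop = FALSE]
  }
  new("AnnotationPairs", pairs = df, layer = pairs@layer,
      sourceLabel = pairs@sourceLabel, nRead = pairs@nRead,
      nDuplicates = pairs@nDuplicates)
}
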