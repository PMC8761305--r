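#' Parse an OBO 1.2 ontology file
#'
#' Minimal reader for the fields the evaluation pipeline needs: \code{id},
#' \code{name}, \code{namespace}, \code{is_a}, \code{relationship: part_of},
#' \code{alt_id} and \code{is_obsolete}. Other relationship types (e.g.
#' regulates) are ignored, matching the edge set conventionally used for
#' annotation propagation. Edges to unknown parent ids are dropped with a
#' warning; a cycle among the kept edges is a fatal error.
#'
#' @param path path to an OBO file.
#' @return an [OntologyDAG-class].
#' @export
parseOBO <- function(path) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas in ", path)
  bounds <- c(starts, length(lines) + 1L)
  parents <- list(); namespace <- character(); obsolete <- character()
  altId <- character()
  for (si in seq_along(starts)) {
    stanza <- lines[(bounds[si] + 1L):(bounds[si + 1L] - 1L)]
    stanza <- stanza[nzchar(stanza) & !startsWith(stanza, "[")]
    getv <- function(key) {
      hits <- stanza[startsWith(stanza, paste0(key, ": "))]
      sub("\\s*!.*$", "", substring(hits, nchar(key) + 3L))
    }
    id <- getv("id")[1]
    if (is.na(id) || !nzchar(id)) next
    obs <- any(getv("is_obsolete") == "true")
    par <- getv("is_a")
    rel <- getv("relationship")
    par <- c(par, sub("^part_of\\s+", "", rel[startsWith(rel, "part_of ")]))
    ns <- getv("namespace")[1]
    namespace[id] <- if (is.na(ns)) "" else ns
    parents[[id]] <- if (obs) character() else trimws(par)
    if (obs) obsolete <- c(obsolete, id)
    for (a in getv("alt_id")) altId[a] <- id
  }
  known <- names(parents)
  nUnknown <- 0L
  for (id in known) {
    p <- parents[[id]]
    bad <- !p %in% known
    if (any(bad)) {
      nUnknown <- nUnknown + sum(bad)
      parents[[id]] <- p[!bad]
    }
  }
  if (nUnknown > 0L)
    warning(nUnknown, " edge(s) to unknown parent ids dropped")
  dag <- new("OntologyDAG", parents = parents, namespace = namespace,
             roots = setdiff(known[lengths(parents) == 0L], obsolete),
             obsolete = obsolete, altId = altId)
  .checkAcyclic(dag)
  dag
}

.checkAcyclic <- function(dag) {
  # Kahn-style peeling: all terms must be removable in topological order
  remaining <- lengths(dag@parents)
  children <- .childIndex(dag)
  queue <- names(remaining)[remaining == 0L]
  seen <- 0L
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (ch in children[[t]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen != length(dag@parents))
    stop("cycle detected in ontology parent relations")
  invisible(TRUE)
}

.childIndex <- function(dag) {
  n <- lengths(dag@parents)
  kids <- split(rep(names(dag@parents), n),
                unlist(dag@parents, use.names = FALSE))
  out <- rep(list(character()), length(dag@parents))
  names(out) <- names(dag@parents)
  out[names(kids)] <- kids
  out
}

.ancestorsOf <- function(term, dag, cache) {
  # memoized transitive closure over parent edges (term itself excluded)
  if (!is.null(cache[[term]])) return(cache[[term]])
  anc <- character()
  stack <- dag@parents[[term]]
  while (length(stack)) {
    t <- stack[[1]]; stack <- stack[-1]
    if (t %in% anc) next
    anc <- c(anc, t)
    hit <- cache[[t]]
    if (!is.null(hit)) anc <- union(anc, hit)
    else stack <- c(stack, dag@parents[[t]])
  }
  cache[[term]] <- anc
  anc
}

#' Propagate a term set to its ancestors
#'
#' Closure of a term set under the is_a / part_of parent relations, the
#' standard pre-processing for protein-centric ontology benchmarks; alt_ids
#' are resolved to primary ids and unknown terms dropped with a warning.
#' Idempotent: propagating a propagated set returns it unchanged.
#'
#' @param terms character vector of term ids.
#' @param dag an [OntologyDAG-class].
#' @param excludeRoots drop namespace root terms from the result (roots are
#'   uninformative: every protein trivially has them).
#' @return character vector: the ancestor closure.
#' @export
propagateTerms <- function(terms, dag, excludeRoots = TRUE) {
  stopifnot(is(dag, "OntologyDAG"))
  terms <- unique(terms)
  aliased <- terms %in% names(dag@altId)
  terms[aliased] <- dag@altId[terms[aliased]]
  unknown <- !terms %in% names(dag@parents)
  if (any(unknown)) {
    warning(sum(unknown), " unknown term(s) dropped during propagation")
    terms <- terms[!unknown]
  }
  cache <- new.env(parent = emptyenv())
  out <- unique(c(terms, unlist(lapply(terms, .ancestorsOf, dag = dag,
                                       cache = cache), use.names = FALSE)))
  if (excludeRoots) out <- setdiff(out, dag@roots)
  sort(out)
}

#' Propagate every annotation set in a protein -> terms mapping
#'
#' @param annotations named list: protein -> character vector of terms.
#' @inheritParams propagateTerms
#' @return named list with each term set replaced by its ancestor closure;
#'   proteins whose set becomes empty are removed.
#' @export
propagateAnnotations <- function(annotations, dag, excludeRoots = TRUE) {
  out <- lapply(annotations, propagateTerms, dag = dag,
                excludeRoots = excludeRoots)
  out[lengths(out) > 0L]
}

#' Propagate prediction scores up the ontology
#'
#' Expands each protein's predicted terms with their ancestors; an ancestor
#' receives the maximum normalized score among its predicted descendants
#' (the consistency rule used when scoring ontology predictions). Root terms
#' are excluded.
#'
#' @param set a [PredictionSet-class].
#' @param dag an [OntologyDAG-class].
#' @return a [PredictionSet-class] with expanded records; propagated records
#'   carry \code{k = 0} and an empty domain list.
#' @export
propagatePredictions <- function(set, dag) {
  stopifnot(is(set, "PredictionSet"), is(dag, "OntologyDAG"))
  r <- set@records
  if (!nrow(r)) return(set)
  cache <- new.env(parent = emptyenv())
  known <- r$fun %in% c(names(dag@parents), names(dag@altId))
  pieces <- lapply(split(r[known, , drop = FALSE], r$protein[known]),
    function(pr) {
      extra <- list()
      for (j in seq_len(nrow(pr))) {
        anc <- setdiff(.ancestorsOf(.resolveId(pr$fun[j], dag), dag, cache),
                       dag@roots)
        if (length(anc))
          extra[[j]] <- data.frame(protein = pr$protein[1], fun = anc,
                                   domains = "", k = 0L, raw = NA_real_,
                                   normalized = pr$normalized[j],
                                   stringsAsFactors = FALSE)
      }
      all <- rbind(pr, do.call(rbind, extra))
      # keep the best-scoring row per term
      all <- all[order(all$fun, -all$normalized), , drop = FALSE]
      all[!duplicated(all$fun), , drop = FALSE]
    })
  rec <- rbind(do.call(rbind, pieces), r[!known, , drop = FALSE])
  rec <- rec[order(rec$protein, -rec$normalized, rec$fun), , drop = FALSE]
  rownames(rec) <- NULL
  methods::initialize(set, records = rec, predicted = unique(rec$protein))
}

.resolveId <- function(id, dag) {
  if (id %in% names(dag@altId)) dag@altId[[id]] else id
}

#' Per-term information accretion from an annotation corpus
#'
#' Estimates, for every ontology term, the information gained when a protein
#' annotated with all of the term's parents is also annotated with the term:
#' \deqn{ia(t) = -\log_2 \frac{|\{p : t \in A(p)\}|}{|\{p : parents(t) \subseteq A(p)\}|}}
#' computed over a propagated annotation corpus. Root terms get 0. Terms
#' never annotated in the corpus get a pseudo-count value
#' \eqn{-\log_2(pc / (n_{parents} + pc))}.
#'
#' @param annotations named list protein -> PROPAGATED term sets.
#' @param dag an [OntologyDAG-class].
#' @param pseudoCount pseudo-count for never-annotated terms.
#' @return a [TermIC-class]; its \code{defaultIA}
#'   (\eqn{-\log_2(pc/(n_{proteins}+pc))}) is used for terms outside the
#'   ontology.
#' @export
informationAccretion <- function(annotations, dag, pseudoCount = 1) {
  stopifnot(is(dag, "OntologyDAG"))
  n <- length(annotations)
  terms <- setdiff(names(dag@parents), dag@obsolete)
  counts <- table(unlist(lapply(annotations, unique), use.names = FALSE))
  ia <- numeric(length(terms)); names(ia) <- terms
  for (t in terms) {
    if (t %in% dag@roots) { ia[t] <- 0; next }
    pars <- dag@parents[[t]]
    nPar <- sum(vapply(annotations, function(s) all(pars %in% s), logical(1)))
    nt <- if (t %in% names(counts)) as.integer(counts[[t]]) else 0L
    ia[t] <- if (nt > 0L) -log2(nt / nPar)
             else -log2(pseudoCount / (nPar + pseudoCount))
  }
  new("TermIC", ia = pmax(ia, 0),
      pseudoCount = pseudoCount,
      defaultIA = -log2(pseudoCount / (n + pseudoCount)))
}

#' Look up information-accretion weights for a term vector
#'
#' @param ic a [TermIC-class].
#' @param terms character vector.
#' @param warn warn when terms are missing from the table.
#' @return numeric vector of ia weights (missing terms get
#'   \code{ic@defaultIA}).
#' @export
termIA <- function(ic, terms, warn = TRUE) {
  stopifnot(is(ic, "TermIC"))
  out <- ic@ia[terms]
  miss <- is.na(out)
  if (any(miss)) {
    if (warn) warning(sum(miss), " term(s) missing from the IC table; ",
                      "using the pseudo-count ia")
    out[miss] <- ic@defaultIA
  }
  unname(out)
}
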