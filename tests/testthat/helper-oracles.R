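# Independent brute-force oracles and random fixtures used across the suite.
# These deliberately avoid the package's own code paths: naive set
# arithmetic, direct choose() enumeration for the hypergeometric tail, and
# the closed-form even-dof chi-square survival function.

bfJaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

bfSimpson <- function(a, b) {
  length(intersect(a, b)) / min(length(a), length(b))
}

bfPcc <- function(a, b, nT) {
  i <- length(intersect(a, b)); d <- length(a); f <- length(b)
  (i * nT - d * f) / sqrt(d * f * (nT - d) * (nT - f))
}

# -log10 upper-tail hypergeometric probability by full pmf enumeration
bfHyi <- function(a, b, nT) {
  i0 <- length(intersect(a, b)); d <- length(a); f <- length(b)
  if (i0 == 0) return(0)
  upper <- min(d, f)
  tail <- sum(vapply(i0:upper, function(i)
    choose(d, i) * choose(nT - d, f - i) / choose(nT, f), numeric(1)))
  -log10(tail)
}

# survival function of chi-square with even dof 2k at x, closed form
bfChisqSurvEven <- function(x, k) {
  exp(-x / 2) * sum((x / 2)^(0:(k - 1)) / factorial(0:(k - 1)))
}

bfPopSd <- function(v) sqrt(sum((v - mean(v))^2) / length(v))

# random annotation layers over nT proteins where every protein is annotated
# in both layers (so the layer intersection drops nothing)
randomLayers <- function(nT, nD = 4, nF = 4) {
  prots <- sprintf("p%02d", seq_len(nT))
  doms <- sprintf("d%d", seq_len(nD))
  funs <- sprintf("f%d", seq_len(nF))
  dp <- lapply(prots, function(p) sample(doms, sample.int(nD, 1)))
  fp <- lapply(prots, function(p) sample(funs, sample.int(nF, 1)))
  list(domains = annotationPairs(rep(prots, lengths(dp)),
                                 unlist(dp), layer = "domain"),
       functions = annotationPairs(rep(prots, lengths(fp)),
                                   unlist(fp), layer = "function"))
}

# a tiny standardized table built directly (arbitrary z values)
makeZTable <- function(domain, fun, z, metric = "simpson") {
  new("StandardizedTable",
      records = data.frame(domain = domain, fun = fun, z = z,
                           stringsAsFactors = FALSE),
      metric = metric, absTransformed = FALSE)
}

# random single-protein-style prediction/benchmark instances for Fmax checks;
# scoreDigits = 2 puts scores on the tau grid (the precision predictions are
# serialized at), scoreDigits = 3 puts them between grid points
randomEvalInstance <- function(nProteins = 5, nTerms = 8, scoreDigits = 2) {
  prots <- sprintf("q%d", seq_len(nProteins))
  terms <- sprintf("t%d", seq_len(nTerms))
  truth <- lapply(prots, function(p) sample(terms, sample.int(nTerms - 1, 1)))
  names(truth) <- prots
  predFor <- prots[stats::runif(nProteins) < 0.85]
  rec <- do.call(rbind, lapply(predFor, function(p) {
    k <- sample.int(nTerms, 1)
    data.frame(protein = p, fun = sample(terms, k), domains = "", k = 1L,
               raw = 0,
               normalized = pmax(round(stats::runif(k, 0.001, 1), scoreDigits),
                                 10^(-scoreDigits)),
               stringsAsFactors = FALSE)
  }))
  set <- if (is.null(rec)) {
    new("PredictionSet",
        records = data.frame(protein = character(), fun = character(),
                             domains = character(), k = integer(),
                             raw = numeric(), normalized = numeric()),
        method = "stouffer", predicted = character(),
        unpredictable = data.frame(protein = prots,
                                   reason = "no-domains"))
  } else {
    new("PredictionSet", records = rec, method = "stouffer",
        predicted = unique(rec$protein),
        unpredictable = data.frame(
          protein = setdiff(prots, rec$protein),
          reason = rep("no-domains", length(setdiff(prots, rec$protein))),
          stringsAsFactors = FALSE))
  }
  list(predictions = set, benchmark = benchmarkSet(truth))
}

# protein-centric Fmax by brute force at every distinct predicted score,
# with the per-protein averaging done by naive set arithmetic
bfFmaxExact <- function(set, benchmark, mode) {
  rec <- records(set)
  truth <- benchmark@truth
  covered <- names(truth)[names(truth) %in% rec$protein]
  taus <- sort(unique(rec$normalized))
  if (!length(taus)) taus <- 1
  f <- vapply(taus, function(tau) {
    precs <- c(); recalls <- c()
    for (p in names(truth)) {
      pred <- rec$fun[rec$protein == p & rec$normalized >= tau]
      tp <- length(intersect(pred, truth[[p]]))
      if (length(pred)) precs <- c(precs, tp / length(pred))
      recalls <- c(recalls, tp / length(truth[[p]]))
    }
    pr <- if (length(precs)) mean(precs) else 0
    rc <- if (mode == "full") mean(recalls)
          else if (length(covered))
            mean(recalls[names(truth) %in% covered]) else 0
    if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  }, numeric(1))
  max(f)
}
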