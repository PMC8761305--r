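onePred <- function(scores, protein = "Q1") {
  rec <- data.frame(protein = protein, fun = names(scores), domains = "D",
                    k = 1L, raw = 0, normalized = unname(scores),
                    stringsAsFactors = FALSE)
  new("PredictionSet", records = rec, method = "stouffer",
      predicted = unique(rec$protein),
      unpredictable = data.frame(protein = character(), reason = character()))
}

test_that("threshold precision/recall counts match hand arithmetic", {
  bench <- benchmarkSet(list(Q1 = c("A", "B")))
  set <- onePred(c(A = 0.9, C = 0.8))
  expect_equal(precisionRecallAt(set, bench, 0.9, "full"),
               c(precision = 1.0, recall = 0.5))
  expect_equal(precisionRecallAt(set, bench, 0.8, "full"),
               c(precision = 0.5, recall = 0.5))
  perfect <- onePred(c(A = 0.7, B = 0.7))
  expect_equal(precisionRecallAt(perfect, bench, 0.5, "full"),
               c(precision = 1.0, recall = 1.0))
  expect_error(precisionRecallAt(set, bench, 0, "full"), "tau")
  expect_error(precisionRecallAt(set, bench, 1.5, "full"), "tau")
})

test_that("the hand-worked Fmax instance gives 2/3 at tau 0.9", {
  bench <- benchmarkSet(list(Q1 = c("A", "B")))
  set <- onePred(c(A = 0.9, C = 0.8))
  fm <- fmax(set, bench, "full")
  expect_equal(fm$fmax, 2 / 3, tolerance = 1e-12)
  expect_equal(fm$tau, 0.9)

  perfect <- onePred(c(A = 1, B = 1))
  expect_equal(fmax(perfect, bench, "full")$fmax, 1.0)

  nothing <- new("PredictionSet",
                 records = records(set)[0, ], method = "stouffer",
                 predicted = character(),
                 unpredictable = data.frame(protein = "Q1",
                                            reason = "no-domains"))
  expect_equal(fmax(nothing, bench, "full")$fmax, 0.0)
  expect_error(fmax(set, benchmarkSet(list())), "empty")
})

test_that("partial-mode Fmax never falls below full-mode Fmax", {
  set.seed(33)
  for (rep in 1:30) {
    inst <- randomEvalInstance()
    full <- fmax(inst$predictions, inst$benchmark, "full")$fmax
    part <- fmax(inst$predictions, inst$benchmark, "partial")$fmax
    expect_gte(part, full - 1e-12)
  }
})

test_that("grid Fmax agrees with the exact-threshold brute-force maximum", {
  set.seed(44)
  for (rep in 1:100) {
    # scores on the 0.01 lattice (the precision predictions are written at):
    # every distinct score is a grid point, so the sweep is exhaustive
    inst <- randomEvalInstance(nProteins = sample(2:6, 1),
                               nTerms = sample(4:9, 1))
    for (mode in c("full", "partial")) {
      grid <- fmax(inst$predictions, inst$benchmark, mode)
      exact <- bfFmaxExact(inst$predictions, inst$benchmark, mode)
      expect_equal(grid$fmax, exact, tolerance = 1e-12)
      pts <- grid$prPoints
      expect_true(all(pts$precision >= 0 & pts$precision <= 1))
      expect_true(all(pts$recall >= 0 & pts$recall <= 1))
      expect_true(all(diff(pts$recall) <= 1e-12))  # non-increasing in tau
    }
  }
  # off-lattice scores: every grid threshold realizes some exact-score
  # predicted set, so the grid maximum can only fall below the exact one
  for (rep in 1:20) {
    inst <- randomEvalInstance(scoreDigits = 3)
    grid <- fmax(inst$predictions, inst$benchmark, "full")$fmax
    exact <- bfFmaxExact(inst$predictions, inst$benchmark, "full")
    expect_lte(grid, exact + 1e-12)
  }
})

test_that("semantic distance is zero iff predictions are perfect", {
  bench <- benchmarkSet(list(Q1 = c("A", "B")))
  ic <- new("TermIC", ia = c(A = 1, B = 0.5, C = 2), pseudoCount = 1,
            defaultIA = 3)
  perfect <- onePred(c(A = 0.9, B = 0.9))
  sm <- smin(perfect, bench, ic, "full")
  expect_equal(sm$smin, 0.0)

  # one missed term with ia = 1, nothing wrong
  ic1 <- new("TermIC", ia = c(A = 1, B = 1), pseudoCount = 1, defaultIA = 3)
  half <- onePred(c(B = 0.9))
  sm1 <- smin(half, benchmarkSet(list(Q1 = c("A", "B"))), ic1, "full")
  expect_equal(min(sqrt((1)^2 + 0^2)), 1.0)
  expect_equal(sm1$smin, 1.0)

  # no predictions at all: smin = average total ia of the truth sets
  nothing <- new("PredictionSet", records = records(perfect)[0, ],
                 method = "stouffer", predicted = character(),
                 unpredictable = data.frame(protein = "Q1",
                                            reason = "no-domains"))
  sm0 <- smin(nothing, bench, ic, "full")
  expect_equal(sm0$smin, 1 + 0.5)

  # adding a wrong prediction with positive ia cannot lower the distance
  wrong <- onePred(c(A = 0.9, B = 0.9, C = 0.9))
  smw <- smin(wrong, bench, ic, "full")
  expect_gte(smw$smin, sm$smin)
})

test_that("coverage is the predicted fraction of the benchmark", {
  bench <- benchmarkSet(list(Q1 = "A", Q2 = "A", Q3 = "A", Q4 = "A"))
  threeOfFour <- new("PredictionSet",
    records = data.frame(protein = c("Q1", "Q2", "Q3"), fun = "A",
                         domains = "D", k = 1L, raw = 0, normalized = 0.5),
    method = "stouffer", predicted = c("Q1", "Q2", "Q3"),
    unpredictable = data.frame(protein = "Q4", reason = "no-domains"))
  expect_equal(benchmarkCoverage(threeOfFour, bench), 0.75)
  expect_equal(benchmarkCoverage(threeOfFour,
                                 benchmarkSet(list(Q1 = "A", Q2 = "A"))), 1.0)
  expect_equal(benchmarkCoverage(threeOfFour,
                                 benchmarkSet(list(Q9 = "A"))), 0.0)
  expect_error(benchmarkCoverage(threeOfFour, benchmarkSet(list())), "empty")
})

test_that("pooled self-prediction PR curves follow the ranked list", {
  ann <- list(P1 = c("F1", "F2"), P2 = "F3")
  allRight <- new("PredictionSet",
    records = data.frame(protein = c("P1", "P1", "P2"),
                         fun = c("F1", "F2", "F3"), domains = "D", k = 1L,
                         raw = 0, normalized = c(0.9, 0.8, 0.7)),
    method = "stouffer", predicted = c("P1", "P2"),
    unpredictable = data.frame(protein = character(), reason = character()))
  repAll <- pppEvaluate(allRight, ann)
  expect_equal(repAll@aucpr, 1.0)
  expect_equal(repAll@fmax, 1.0)
  expect_equal(repAll@coverage, 1.0)

  allWrong <- new("PredictionSet",
    records = data.frame(protein = "P1", fun = "F9", domains = "D", k = 1L,
                         raw = 0, normalized = 0.9),
    method = "stouffer", predicted = "P1",
    unpredictable = data.frame(protein = character(), reason = character()))
  repWrong <- pppEvaluate(allWrong, ann)
  expect_true(all(repWrong@prPoints$precision == 0))
  expect_equal(repWrong@aucpr, 0)

  # 4 scored pairs, hits at ranks 1 and 4: step-interpolated area 0.75
  mixed <- new("PredictionSet",
    records = data.frame(protein = "P1", fun = c("F1", "F8", "F9", "F2"),
                         domains = "D", k = 1L, raw = 0,
                         normalized = c(0.9, 0.8, 0.7, 0.6)),
    method = "stouffer", predicted = "P1",
    unpredictable = data.frame(protein = character(), reason = character()))
  repMix <- pppEvaluate(mixed, ann)
  expect_equal(repMix@aucpr, 0.5 * 1.0 + 0.5 * 0.5)
  hitPts <- repMix@prPoints[repMix@prPoints$tau %in% c(0.9, 0.6), ]
  expect_equal(hitPts$precision, c(1.0, 0.5))
  expect_equal(hitPts$recall, c(0.5, 1.0))
})

test_that("the naive baseline scores terms by training frequency", {
  train <- c(lapply(1:50, function(i) "T1"), lapply(1:50, function(i) "T2"))
  names(train) <- sprintf("p%03d", 1:100)
  train <- lapply(train, function(t) c(t, "ROOTLIKE"))
  nb <- naiveBaseline(train, c("q1", "q2"))
  rec <- records(nb)
  expect_equal(unique(rec$normalized[rec$fun == "T1"]), 0.5)
  expect_equal(unique(rec$normalized[rec$fun == "ROOTLIKE"]), 1.0)
  expect_equal(benchmarkCoverage(nb, benchmarkSet(list(q1 = "T1", q2 = "T2"))),
               1.0)
})
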