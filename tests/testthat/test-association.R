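test_that("index formulas reproduce hand-derived set arithmetic", {
  a <- c("p1", "p2", "p3"); b <- c("p2", "p3", "p4")
  expect_equal(jaccardIndex(a, b), 0.5)
  expect_equal(jaccardIndex(a, a), 1.0)
  expect_equal(jaccardIndex(a, c("x", "y")), 0.0)

  expect_equal(simpsonIndex(a, b), 2 / 3)
  expect_equal(simpsonIndex(c("p1", "p2"), c("p1", "p2", "p3", "p4")), 1.0)
  expect_equal(simpsonIndex(a, c("x")), 0.0)

  # numerator vanishes when |inter| * nT = |Np(D)| * |Np(F)|
  expect_equal(pccIndex(c("p1", "p2", "p3", "p4"),
                        c("p3", "p4", "p5", "p6", "p7"), nTotal = 10), 0.0)
  expect_equal(pccIndex(c("p1", "p2"), c("p1", "p2"), nTotal = 4), 1.0)
  expect_equal(pccIndex(c("p1", "p2"), c("p3", "p4"), nTotal = 4), -1.0)
  expect_error(pccIndex(c("p1", "p2"), c("p1", "p2"), nTotal = 2), "undefined")

  expect_equal(hypergeometricIndex(c("p1", "p2"), c("p1", "p2"), nTotal = 5),
               1.0)  # tail = 1 / choose(5,2) = 0.1
  expect_equal(hypergeometricIndex(c("p1", "p2"), c("p1", "p3"), nTotal = 4),
               -log10(5 / 6), tolerance = 1e-12)
  expect_equal(hypergeometricIndex(c("p1"), c("p2"), nTotal = 4), 0.0)

  expect_error(jaccardIndex(character(), a), "empty")
  expect_error(simpsonIndex(a, character()), "empty")
})

test_that("indices are symmetric and Jaccard never exceeds Simpson", {
  set.seed(5)
  for (rep in 1:25) {
    nT <- sample(4:15, 1)
    univ <- sprintf("p%d", seq_len(nT))
    a <- sample(univ, sample(nT - 1, 1))
    b <- sample(univ, sample(nT - 1, 1))
    expect_equal(jaccardIndex(a, b), jaccardIndex(b, a))
    expect_equal(simpsonIndex(a, b), simpsonIndex(b, a))
    expect_equal(pccIndex(a, b, nT), pccIndex(b, a, nT))
    expect_equal(hypergeometricIndex(a, b, nT), hypergeometricIndex(b, a, nT))
    expect_lte(jaccardIndex(a, b), simpsonIndex(a, b) + 1e-12)
  }
})

test_that("HyI is monotone non-decreasing in the overlap", {
  nT <- 12
  univ <- sprintf("p%d", 1:nT)
  d <- 5; f <- 6
  prev <- -Inf
  for (i in 1:5) {
    a <- univ[1:d]
    b <- c(univ[1:i], univ[(d + 1):(d + f - i)])  # overlap exactly i
    val <- hypergeometricIndex(a, b, nT)
    expect_gte(val, prev - 1e-12)
    prev <- val
  }
})

test_that("underflowing hypergeometric tails are capped, not infinite", {
  univ <- sprintf("p%d", 1:400)
  expect_warning(v <- hypergeometricIndex(univ[1:200], univ[1:200],
                                          nTotal = 400, cap = 50),
                 "capped")
  expect_equal(v, 50)
})

test_that("association tables enumerate co-occurring pairs with correct stats", {
  dom <- annotationPairs(c("P1", "P2", "P2"), c("D1", "D1", "D2"),
                         layer = "domain")
  fun <- annotationPairs(c("P1", "P2"), c("F1", "F2"), layer = "function")
  net <- buildNetwork(dom, fun)
  tab <- computeAssociations(net, "simpson")
  # D1 co-occurs with F1 and F2, D2 only with F2: 3 records
  expect_equal(nrow(records(tab)), 3L)
  expect_false(any(records(tab)$domain == "D2" & records(tab)$fun == "F1"))
  expect_equal(assocMean(tab), mean(records(tab)$value))
  expect_equal(assocSd(tab), bfPopSd(records(tab)$value))

  # Np(D2) = {P2} subset of Np(F2): Simpson exactly 1
  expect_equal(records(tab)$value[records(tab)$domain == "D2"], 1.0)

  # 2 domains x 2 functions all co-annotated on every protein: 4 records
  domB <- annotationPairs(rep(c("P1", "P2"), each = 2),
                          rep(c("D1", "D2"), 2), layer = "domain")
  funB <- annotationPairs(rep(c("P1", "P2"), each = 2),
                          rep(c("F1", "F2"), 2), layer = "function")
  tabB <- computeAssociations(buildNetwork(domB, funB), "jaccard")
  expect_equal(nrow(records(tabB)), 4L)
  expect_true(all(records(tabB)$value == 1))

  expect_error(computeAssociations(net, "counting"))
})

test_that("all four indices match brute-force oracles on random networks", {
  set.seed(101)
  for (rep in 1:60) {
    layers <- randomLayers(nT = sample(3:20, 1),
                           nD = sample(2:5, 1), nF = sample(2:5, 1))
    net <- buildNetwork(layers$domains, layers$functions)
    nT <- nProteins(net)
    for (metric in c("jaccard", "simpson", "pcc", "hyi")) {
      tab <- suppressWarnings(computeAssociations(net, metric))
      rec <- records(tab)
      for (j in seq_len(nrow(rec))) {
        a <- neighborProteins(net, rec$domain[j], "domain")
        b <- neighborProteins(net, rec$fun[j], "function")
        expected <- switch(metric,
          jaccard = bfJaccard(a, b), simpson = bfSimpson(a, b),
          pcc = bfPcc(a, b, nT), hyi = bfHyi(a, b, nT))
        tol <- if (metric == "hyi") 1e-6 else 1e-9
        expect_equal(rec$value[j], expected, tolerance = tol)
      }
    }
  }
})

test_that("association tables survive a TSV round trip", {
  set.seed(3)
  layers <- randomLayers(12)
  tab <- computeAssociations(buildNetwork(layers$domains, layers$functions),
                             "jaccard")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeAssociations(tab, f)
  back <- readAssociations(f, "jaccard")
  expect_equal(records(back), records(tab))
  expect_equal(assocMean(back), assocMean(tab))
})
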