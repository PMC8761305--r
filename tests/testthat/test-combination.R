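test_that("standardization uses the population moments of the table", {
  tab <- new("AssociationTable",
             records = data.frame(domain = c("D1", "D2", "D3"), fun = "F1",
                                  value = c(1, 2, 3)),
             metric = "hyi", mean = 2, sd = bfPopSd(c(1, 2, 3)))
  z <- records(standardizeTable(tab))$z
  expect_equal(z[3], (3 - 2) / bfPopSd(c(1, 2, 3)), tolerance = 1e-12)
  expect_equal(z[3], 1.224745, tolerance = 1e-6)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(bfPopSd(z), 1, tolerance = 1e-12)

  same <- new("AssociationTable",
              records = data.frame(domain = c("D1", "D2"), fun = "F1",
                                   value = c(0.4, 0.4)),
              metric = "jaccard", mean = 0.4, sd = 0)
  expect_error(standardizeTable(same), "degenerate")

  # abs() collapses a symmetric PCC pair to zero spread
  pcc <- new("AssociationTable",
             records = data.frame(domain = c("D1", "D2"), fun = "F1",
                                  value = c(-0.5, 0.5)),
             metric = "pcc", mean = 0, sd = 0.5)
  expect_error(standardizeTable(pcc, takeAbsolute = TRUE), "degenerate")
  expect_silent(standardizeTable(pcc, takeAbsolute = FALSE))
})

test_that("Stouffer combination is sum over sqrt(k)", {
  expect_equal(stoufferCombine(c(1, 1)), 2 / sqrt(2), tolerance = 1e-12)
  expect_equal(stoufferCombine(0.73), 0.73)
  expect_equal(stoufferCombine(c(1.3, -1.3)), 0)
  expect_error(stoufferCombine(numeric()), "empty")
  # k identical values z combine to z * sqrt(k)
  for (k in 1:6) for (z in c(-1.7, 0.2, 2.5))
    expect_equal(stoufferCombine(rep(z, k)), z * sqrt(k), tolerance = 1e-12)
})

test_that("HyI antilog recovers the tail probability", {
  expect_equal(hyiToPvalue(1), 0.1)
  expect_equal(hyiToPvalue(0), 1)
  expect_equal(hyiToPvalue(2), 0.01)
  expect_error(hyiToPvalue(-0.1), "non-negative")
})

test_that("Fisher combination matches the even-dof chi-square survival", {
  expect_equal(fisherCombine(0.05), 0.05, tolerance = 1e-12)
  expect_equal(fisherCombine(c(1, 1)), 1, tolerance = 1e-12)
  expect_equal(fisherCombine(c(0.05, 0.05)),
               bfChisqSurvEven(-2 * 2 * log(0.05), 2), tolerance = 1e-9)
  expect_equal(fisherCombine(c(0.05, 0.05)), 0.01747866, tolerance = 1e-6)
  expect_error(fisherCombine(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fisherCombine(c(0.5, 1.2)), "\\(0, 1\\]")

  set.seed(77)
  for (rep in 1:50) {
    k <- sample(1:6, 1)
    p <- stats::runif(k, 1e-6, 1)
    x <- -2 * sum(log(p))
    expect_equal(fisherCombine(p), bfChisqSurvEven(x, k), tolerance = 1e-9)
  }
})

test_that("per-protein combination fans out per function with correct k", {
  vals <- list(F1 = data.frame(domain = c("D1", "D2"), value = c(1, 1)))
  out <- combineForProtein(vals, "stouffer")
  expect_equal(out$raw, sqrt(2), tolerance = 1e-12)
  expect_equal(out$k, 2L)
  expect_equal(out$domains, "D1,D2")

  one <- combineForProtein(list(F1 = data.frame(domain = "D1", value = 0.2)),
                           "fisher")
  expect_equal(one$raw, 0.2, tolerance = 1e-12)
  expect_equal(one$k, 1L)

  two <- combineForProtein(list(F1 = data.frame(domain = "D1", value = 0.5),
                                F2 = data.frame(domain = "D1", value = 0.1)),
                           "fisher")
  expect_equal(nrow(two), 2L)

  bad <- list(F1 = data.frame(domain = c("D1", "D2"), value = c(1.4, 0.2)))
  expect_error(combineForProtein(bad, "fisher"), "outside")
})

test_that("score normalization maps, clips and filters as specified", {
  mk <- function(raw) data.frame(protein = "P", fun = sprintf("F%02d", seq_along(raw)),
                                 domains = "D", k = 1L, raw = raw)
  # run whose re-standardized z-scores are exactly (-2, 0, ..., 0, 2):
  # {-2, 0, 2} -> {removed (maps to 0.0), 0.5, 1.0}
  raw <- c(-2, rep(0, 6), 2)            # population sd exactly 1
  out <- normalizeScores(mk(raw), "stouffer")
  expect_equal(nrow(out), 7L)           # the z = -2 row is filtered out
  expect_false("F01" %in% out$fun)
  expect_equal(out$normalized[out$fun == "F08"], 1.0, tolerance = 1e-12)
  expect_equal(unique(out$normalized[out$fun != "F08"]), 0.5,
               tolerance = 1e-12)

  # |z| > 2 is clipped to 2 before the range map
  clip <- normalizeScores(mk(c(100, rep(0, 9))), "stouffer")
  expect_equal(max(clip$normalized), 1.0, tolerance = 1e-12)

  fish <- normalizeScores(mk(c(0.2, 0.9995)), "fisher")
  expect_equal(fish$normalized[1], 0.8)
  expect_equal(nrow(fish), 1L)  # 1 - 0.9995 < 0.001 removed

  # retained scores always lie in [0.001, 1]; rank order preserved
  set.seed(9)
  for (rep in 1:20) {
    raw <- stats::rnorm(30, sd = stats::runif(1, 0.5, 3))
    out <- normalizeScores(mk(raw), "stouffer")
    expect_true(all(out$normalized >= 0.001 & out$normalized <= 1))
    kept <- match(out$fun, mk(raw)$fun)
    ord <- order(raw[kept])
    expect_true(all(diff(out$normalized[ord]) >= -1e-12))
  }
})
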