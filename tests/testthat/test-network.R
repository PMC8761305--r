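test_that("pair files are parsed, deduplicated and validated", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "P1\tD1", "P1\tD2", "P1\tD1", "", "P2\tD1\tEXP"), f)
  ap <- readPairsFile(f, layer = "domain")
  expect_s4_class(ap, "AnnotationPairs")
  expect_equal(nrow(records(ap)), 3L)
  expect_equal(sum(records(ap)$protein == "P1"), 2L)
  expect_equal(ap@nDuplicates, 1L)
  expect_equal(records(ap)$evidence[records(ap)$protein == "P2"], "EXP")

  writeLines("P1", f)
  expect_error(readPairsFile(f, layer = "domain"), "malformed line 1")
  writeLines(c("# only a comment"), f)
  expect_warning(empty <- readPairsFile(f, layer = "domain"), "empty")
  expect_equal(nrow(records(empty)), 0L)
  expect_error(readPairsFile("/nonexistent/file.tsv", "domain"), "not found")
})

test_that("evidence and protein-flag filters drop exactly what they should", {
  ap <- annotationPairs(c("P1", "P2"), c("GO:1", "GO:1"),
                        evidence = c("IEA", "EXP"), layer = "function")
  kept <- filterAnnotations(ap, excludedEvidence = "IEA")
  expect_equal(records(kept)$protein, "P2")

  expect_equal(records(filterAnnotations(ap)), records(ap))  # no-op

  flags <- data.frame(protein = "P3", flag = "fragment")
  ap3 <- annotationPairs(rep("P3", 3), c("GO:1", "GO:2", "GO:3"),
                         layer = "function")
  gone <- filterAnnotations(ap3, proteinFlags = flags,
                            excludedFlags = "fragment")
  expect_equal(nrow(records(gone)), 0L)

  noEv <- annotationPairs("P1", "GO:1", layer = "function")
  expect_error(filterAnnotations(noEv, excludedEvidence = "IEA"),
               "no evidence column")
})

test_that("network construction intersects layers and builds exact inverses", {
  dom <- annotationPairs(c("P1", "P2"), c("D1", "D1"), layer = "domain")
  fun <- annotationPairs("P1", "F1", layer = "function")
  net <- buildNetwork(dom, fun)
  expect_equal(nProteins(net), 1L)
  expect_equal(unname(net@dropped["domain"]), 1L)

  dom2 <- annotationPairs(c("P1", "P1"), c("D1", "D2"), layer = "domain")
  fun2 <- annotationPairs(c("P1", "P1"), c("F1", "F2"), layer = "function")
  net2 <- buildNetwork(dom2, fun2)
  expect_equal(neighborProteins(net2, "D1", "domain"), "P1")
  expect_equal(neighborProteins(net2, "F2", "function"), "P1")
  expect_equal(nProteins(net2), 1L)

  # 10 fully annotated proteins: nT equals a brute-force distinct-key recount
  prots <- sprintf("P%02d", 1:10)
  domA <- annotationPairs(prots, rep(c("D1", "D2"), 5), layer = "domain")
  funA <- annotationPairs(prots, rep(c("F1", "F2"), 5), layer = "function")
  netA <- buildNetwork(domA, funA)
  expect_equal(nProteins(netA),
               length(unique(intersect(records(domA)$protein,
                                       records(funA)$protein))))
  expect_equal(sum(netA@dropped), 0L)

  expect_error(buildNetwork(annotationPairs("P1", "D1", layer = "domain"),
                            annotationPairs("P2", "F1", layer = "function")),
               "empty network")
  expect_error(neighborProteins(net2, "F1", "domain"), "not found")
})

test_that("network round-trips through serialized pair files", {
  set.seed(11)
  layers <- randomLayers(nT = 30, nD = 6, nF = 5)
  net <- buildNetwork(layers$domains, layers$functions)
  d <- withr::local_tempfile(fileext = ".tsv")
  f <- withr::local_tempfile(fileext = ".tsv")
  writePairsFile(layers$domains, d)
  writePairsFile(layers$functions, f)
  net2 <- buildNetwork(readPairsFile(d, "domain"), readPairsFile(f, "function"))
  expect_equal(networkSummary(net2), networkSummary(net))
  expect_equal(net2@proteinDomains, net@proteinDomains)
  expect_equal(net2@functionProteins, net@functionProteins)
})

test_that("neighbour-set sizes obey the edge-count invariants", {
  set.seed(42)
  for (rep in 1:20) {
    nT <- sample(3:50, 1)
    layers <- randomLayers(nT, nD = sample(2:6, 1), nF = sample(2:6, 1))
    net <- buildNetwork(layers$domains, layers$functions)
    sizes <- lengths(net@domainProteins)
    expect_true(all(sizes >= 1 & sizes <= nProteins(net)))
    fsizes <- lengths(net@functionProteins)
    expect_true(all(fsizes >= 1 & fsizes <= nProteins(net)))
    # sum over domains of |Np(D)| = brute-force protein-domain edge count
    edges <- nrow(unique(records(layers$domains)[c("protein", "feature")]))
    expect_equal(sum(sizes), edges)
  }
})
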