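# r <- a <- {b <- d, c}
predGraph <- function() {
  loadOntology(data.frame(child = c("a", "b", "c", "d"),
                          parent = c("r", "a", "a", "b")))
}

test_that("unanimity scoring: 1.0 for terms in all hits, 0.5 otherwise", {
  g <- predGraph()
  db <- makeDB(setNames(rep(list("d"), 6), paste0("P", 1:6)))
  hits <- makeHits("Q", paste0("P", 1:6), rep(1e-10, 6))
  p <- predictStudentA(hits, db, g)
  expect_equal(p[c("a", "b", "d")], c(a = 1, b = 1, d = 1))
  expect_false("r" %in% names(p))

  # term in only 5 of 6 hits scores 0.5
  db2 <- makeDB(c(setNames(rep(list("d"), 5), paste0("P", 1:5)),
                  list(P6 = "c")))
  p2 <- predictStudentA(hits, db2, g)
  expect_true(all(p2 <= 0.5))
  p3 <- predictStudentA(hits, db2, g,
                        predictorParams("A", excludeHalfScores = TRUE))
  expect_length(p3, 0L)

  expect_length(predictStudentA(makeHits("Q", character(), numeric()),
                                db, g), 0L)
})

test_that("redundancy filter keeps the deeper leaf of overlapping branches", {
  g <- predGraph()
  db <- makeDB(list(P1 = "d", P2 = "c"))
  hits <- makeHits("Q", c("P1", "P2"), c(1e-8, 1e-6))
  p <- predictStudentA(hits, db, g)
  # branches of leaves d and c overlap 2/3.5 = 0.57 >= 0.10: one cluster,
  # deeper leaf d survives, c is dropped
  expect_setequal(names(p), c("a", "b", "d"))
  expect_equal(unname(p["d"]), 0.5)
})

test_that("near-identical branches restore their deepest common term", {
  n <- 9L
  chain <- sprintf("c%02d", seq_len(n))
  edges <- data.frame(child = c(chain, "x", "y"),
                      parent = c("r", chain[-n], chain[n], chain[n]))
  g <- loadOntology(edges)
  db <- makeDB(list(P1 = "x", P2 = "y"))
  hits <- makeHits("Q", c("P1", "P2"), c(1e-8, 1e-6))
  # branch(x) and branch(y) share 10 of 11 terms: overlap 10/11 > 0.90
  expect_gt(branchOverlap(branchOf("x", g), branchOf("y", g)), 0.9)
  p <- predictStudentA(hits, db, g)
  # single cluster -> lexicographically first of the equally deep leaves
  expect_true("x" %in% names(p))
  expect_false("y" %in% names(p))
  expect_true(chain[n] %in% names(p))  # restored common core
})

test_that("raw template score is mean(ln E) + 2 sd(ln E)", {
  expect_equal(rawTemplateScore(makeHits("Q", c("S1", "S2"),
                                         c(1e-2, 1e-4))),
               mean(log(c(1e-2, 1e-4))) + 2 * sd(log(c(1e-2, 1e-4))))
  expect_equal(rawTemplateScore(makeHits("Q", c("S1", "S2"),
                                         c(1e-2, 1e-4))),
               -0.395, tolerance = 1e-3)
  expect_equal(rawTemplateScore(makeHits("Q", "S1", 1e-3)), log(1e-3))
  expect_equal(rawTemplateScore(makeHits("Q", c("S1", "S2"),
                                         c(1e-3, 1e-3))), log(1e-3))
})

test_that("template quality score is a survival percentile in [0,1]", {
  bg <- 1:10
  expect_equal(templateQualityScore(0, bg), 1.0)
  expect_equal(templateQualityScore(11, bg), 0.0)
  expect_equal(templateQualityScore(9, bg), 0.1)  # beaten by 90%
})

test_that("term support divides log-E-value mass", {
  g <- chainGraph()
  db <- makeDB(list(P1 = "a", P2 = "b"))
  hits <- makeHits("Q", c("P1", "P2"), c(1e-4, 1e-2))
  # a lies in both propagated annotations, b only in the weaker hit
  expect_equal(termSupport("a", hits, db, g), 1.0)
  expect_equal(termSupport("b", hits, db, g),
               log(1e-2) / (log(1e-4) + log(1e-2)))
  expect_equal(termSupport("zzz", hits, db, g), 0.0)

  # equal E-values collapse to a simple hit fraction
  eq <- makeHits("Q", c("P1", "P2"), c(1e-3, 1e-3))
  expect_equal(termSupport("b", eq, db, g), 0.5)
})

test_that("combined leaf score averages supports along the ancestry", {
  g <- chainGraph()
  expect_equal(combinedLeafScore("b", c(b = 1 / 3, a = 1.0), g), 2 / 3)
  expect_equal(combinedLeafScore("b", c(b = 1, a = 1), g), 1.0)
  expect_equal(combinedLeafScore("a", c(a = 0.4), g), 0.4)  # under root
})

test_that("E-value-weighted predictor multiplies TQS and leaf scores", {
  g <- chainGraph()
  db <- makeDB(list(P1 = "a", P2 = "b"))
  hits <- makeHits("Q", c("P1", "P2"), c(1e-4, 1e-3))
  bg <- c(0, 1)  # raw score beats the whole background: TQS = 1
  p <- predictStudentB(hits, db, g, background = bg)
  supB <- log(1e-3) / (log(1e-4) + log(1e-3))
  cls <- mean(c(supB, 1.0))
  expect_equal(p[["b"]], cls)
  expect_equal(p[["a"]], cls)  # max-propagated from the single leaf
  expect_false("r" %in% names(p))

  # TQS = 0 zeroes every score
  p0 <- predictStudentB(hits, db, g, background = c(-1000, -999))
  expect_true(all(p0 == 0))
  expect_length(predictStudentB(makeHits("Q", character(), numeric()),
                                db, g, background = bg), 0L)
})

test_that("count-based predictor multiplies support and identity", {
  g <- chainGraph()
  db <- makeDB(list(P1 = "b", P2 = "b"))
  hits <- makeHits("Q", c("P1", "P2"), c(1e-8, 1e-6), ppos = c(80, 90),
                   pident = c(70, 85))
  p <- predictStudentC(hits, db, g)
  expect_equal(p[["b"]], 0.9)   # counts {b:2} -> cum 1.0, times ppos 0.9
  expect_equal(p[["a"]], 0.9)
  expect_false("r" %in% names(p))

  # identity kind switches the multiplier but not the counts
  pid <- predictStudentC(hits, db, g,
                         predictorParams("C", identityKind = "identity"))
  expect_equal(pid[["b"]], 0.85)

  expect_length(predictStudentC(makeHits("Q", character(), numeric()),
                                db, g), 0L)
})

test_that("the best-supported leaf wins and allBranches keeps both", {
  g <- predGraph()
  db <- makeDB(c(setNames(rep(list("d"), 3), paste0("P", 1:3)),
                 list(P4 = "c")))
  hits <- makeHits("Q", paste0("P", 1:4), rep(1e-6, 4), ppos = 90)
  p <- predictStudentC(hits, db, g)
  expect_true("d" %in% names(p))   # count 3 beats count 1
  expect_false("c" %in% names(p))
  pAll <- predictStudentC(hits, db, g,
                          predictorParams("C", allBranches = TRUE))
  expect_true(all(c("c", "d") %in% names(pAll)))
})

test_that("noise-free homologs let every predictor recover the truth", {
  cfg <- simConfig(seed = 31, nTerms = 40, nProteins = 60,
                   maxLeavesPerProtein = 1, fidelity = 1.0,
                   identityNoiseSd = 0, hitsPerTarget = 8)
  bench <- genBenchmark(cfg)
  hits <- bench$hitsByIteration[["2"]]
  bg <- compileBackground(hits, bench$db, predictorParams("B"))
  for (tg in bench$targets[seq_len(min(5, length(bench$targets)))]) {
    truth <- sort(bench$truths[[tg]])
    pa <- predictStudentA(hits[[tg]], bench$db, bench$graph)
    expect_equal(sort(names(pa)), truth, info = tg)
    expect_true(all(pa == 1.0), info = tg)
    pb <- predictStudentB(hits[[tg]], bench$db, bench$graph,
                          background = bg)
    expect_equal(sort(names(pb)), truth, info = tg)
    # supports and combined leaf scores are all 1: every score equals TQS
    expect_true(all(pb == pb[[1L]]), info = tg)
    pc <- predictStudentC(hits[[tg]], bench$db, bench$graph)
    expect_equal(sort(names(pc)), truth, info = tg)
    expect_equal(unname(pc[leafTerms(names(pc), bench$graph)]), 1.0,
                 info = tg)
  }
})
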