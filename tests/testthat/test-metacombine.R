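test_that("parameter grids enumerate 36, 54 and 72 settings", {
  gA <- enumerateGrid("A"); gB <- enumerateGrid("B"); gC <- enumerateGrid("C")
  expect_length(gA, 36L)
  expect_length(gB, 54L)
  expect_length(gC, 72L)
  expect_error(enumerateGrid("D"), "unknown method")

  # deterministic order and the documented axes
  expect_equal(vapply(enumerateGrid("A"), function(p) p@maxHits, numeric(1)),
               vapply(gA, function(p) p@maxHits, numeric(1)))
  expect_setequal(unique(vapply(gA, function(p) p@maxHits, numeric(1))),
                  c(1, 5, 9))
  expect_setequal(unique(vapply(gB, function(p) p@maxEvalue, numeric(1))),
                  c(1e0, 1e-3, 1e-6))
  expect_setequal(unique(vapply(gB, function(p) p@maxHits, numeric(1))),
                  c(5, 50, 500))
  expect_setequal(unique(vapply(gC, function(p) p@identityKind,
                                character(1))), c("positives", "identity"))
  expect_true(all(vapply(gA, function(p) p@maxEvalue, numeric(1)) == 0.1))
})

test_that("parameter optimization picks the Fmax-argmax of the grid", {
  g <- loadOntology(data.frame(child = c("a", "b", "c", "d"),
                               parent = c("r", "a", "r", "c")))
  db <- makeDB(list(P1 = "b", P2 = "d"))
  # one faithful strong hit and one junk weak hit carrying a wrong branch
  hits <- list(T1 = makeHits("T1", c("P1", "P2"), c(1e-8, 0.5)))
  byIter <- list(`1` = hits, `2` = hits, `3` = hits)
  truths <- list(T1 = c("a", "b"))

  grid1 <- list(predictorParams("B", maxEvalue = 1e-3))
  opt1 <- optimizeParams("B", "T1", truths, byIter, db, g, grid = grid1)
  expect_identical(opt1$params, grid1[[1L]])

  # a lenient E-value cutoff only adds the wrong branch: strict must win
  grid2 <- list(predictorParams("B", maxEvalue = 1e0),
                predictorParams("B", maxEvalue = 1e-3))
  opt2 <- optimizeParams("B", "T1", truths, byIter, db, g, grid = grid2)
  expect_equal(opt2$params@maxEvalue, 1e-3)
  expect_equal(opt2$fmax, max(opt2$fmaxAll))

  # the reported Fmax is the threshold-measure Fmax of the winning run
  bg <- compileBackground(hits, db, opt2$params)
  preds <- list(T1 = predictStudentB(hits$T1, db, g, opt2$params, bg))
  expect_equal(opt2$fmax, fmax(thresholdCurve(preds, truths, g)))
})

test_that("two-fold protocol covers every target exactly once per method", {
  cfg <- simConfig(seed = 51, nTerms = 25, nProteins = 50,
                   maxLeavesPerProtein = 2, hitsPerTarget = 5,
                   fidelity = 0.9, identityNoiseSd = 3,
                   targetFraction = 0.2)
  bench <- genBenchmark(cfg)
  tf <- twoFoldPredictions(bench$targets, bench$truths,
                           bench$hitsByIteration, bench$db, bench$graph,
                           seed = 4, methods = "A")
  expect_setequal(unlist(tf$folds), bench$targets)
  expect_equal(abs(diff(lengths(tf$folds))), length(bench$targets) %% 2)
  expect_setequal(names(tf$predictions$A), bench$targets)

  tf2 <- twoFoldPredictions(bench$targets, bench$truths,
                            bench$hitsByIteration, bench$db, bench$graph,
                            seed = 4, methods = "A")
  expect_identical(tf$folds, tf2$folds)
  expect_identical(tf$predictions, tf2$predictions)

  # odd-sized sets split floor/ceil
  odd <- twoFoldPredictions(paste0("T", 1:11),
                            setNames(rep(list("a"), 11), paste0("T", 1:11)),
                            list(`1` = list(), `2` = list(), `3` = list()),
                            bench$db, bench$graph, seed = 1,
                            methods = character())
  expect_equal(sort(lengths(odd$folds)), c(5L, 6L))
})

test_that("meta regression recovers the informative method", {
  rows <- withr::with_seed(61, data.frame(scoreA = runif(1000),
                                          scoreB = rbinom(1000, 1, 0.3),
                                          scoreC = runif(1000)))
  rows$label <- rows$scoreB
  model <- fitMeta(rows)
  co <- metaCoefficients(model)
  expect_lt(abs(co[["y"]] - 1), 0.05)
  expect_lt(abs(co[["x"]]), 0.05)
  expect_lt(abs(co[["z"]]), 0.05)
  expect_lt(abs(co[["i"]]), 0.05)
  expect_false(model@rankDeficient)
})

test_that("full-rank fits match the closed-form normal equations", {
  rows <- data.frame(scoreA = c(0.1, 0.9, 0.2, 0.7),
                     scoreB = c(0.5, 0.1, 0.8, 0.3),
                     scoreC = c(0.9, 0.4, 0.1, 0.2),
                     label = c(0, 1, 0, 1))
  model <- fitMeta(rows, weighting = "uniform")
  X <- cbind(1, rows$scoreA, rows$scoreB, rows$scoreC)
  beta <- solve(t(X) %*% X, t(X) %*% rows$label)
  expect_equal(unname(metaCoefficients(model)), as.numeric(beta),
               tolerance = 1e-8)
})

test_that("degenerate designs fall back to a flagged minimum-norm fit", {
  rows <- data.frame(scoreA = 1, scoreB = 1, scoreC = 1,
                     label = rep(1, 6))
  model <- fitMeta(rows)
  expect_true(model@rankDeficient)
  expect_equal(sum(metaCoefficients(model)), 1.0, tolerance = 1e-6)
})

test_that("meta prediction combines, clamps and propagates", {
  g <- chainGraph()
  predsA <- list(T1 = c(a = 0.8, b = 0.6))
  predsB <- list(T1 = c(a = 0.2, b = 0.1))
  predsC <- list(T1 = setNames(numeric(), character()))
  mk <- function(i, x, y, z)
    new("MetaModel", coefficients = c(i = i, x = x, y = y, z = z),
        rankDeficient = FALSE, weighting = "uniform")
  pj <- predictMeta(mk(0, 1, 0, 0), predsA, predsB, predsC, g)
  expect_equal(pj$T1[c("a", "b")], predsA$T1[c("a", "b")])
  pc <- predictMeta(mk(0.5, 0, 0, 0), predsA, predsB, predsC, g)
  expect_true(all(pc$T1 == 0.5))
  pcl <- predictMeta(mk(0, 2, 0, 0), predsA, predsB, predsC, g)
  expect_equal(unname(pcl$T1["a"]), 1.0)  # 1.6 clamped

  # model files round-trip
  f <- tempfile()
  writeMetaModel(mk(0.1, 0.2, 0.3, 0.4), f)
  m2 <- readMetaModel(f)
  expect_equal(metaCoefficients(m2), c(i = 0.1, x = 0.2, y = 0.3, z = 0.4))
})

test_that("an ensemble does not fall below a dominant member", {
  cfg <- simConfig(seed = 71, nTerms = 30, nProteins = 60,
                   maxLeavesPerProtein = 1, hitsPerTarget = 6,
                   fidelity = 1.0, identityNoiseSd = 0)
  bench <- genBenchmark(cfg)
  hits <- bench$hitsByIteration[["2"]]
  predsA <- setNames(lapply(bench$targets, function(tg)
    predictStudentA(hits[[tg]], bench$db, bench$graph)), bench$targets)
  noise <- function(seed) withr::with_seed(seed, setNames(
    lapply(bench$targets, function(tg) {
      lv <- sample(setdiff(ontologyTerms(bench$graph),
                           ontologyRoot(bench$graph)), 2)
      propagateMax(setNames(runif(2), lv), bench$graph)
    }), bench$targets))
  predsB <- noise(72); predsC <- noise(73)
  rows <- metaRows(predsA, predsB, predsC, bench$truths, bench$graph)
  model <- fitMeta(rows)
  meta <- predictMeta(model, predsA, predsB, predsC, bench$graph)
  fmA <- fmax(thresholdCurve(predsA, bench$truths, bench$graph))
  fmM <- fmax(thresholdCurve(meta, bench$truths, bench$graph))
  expect_gte(fmM, fmA - 0.02)
})
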