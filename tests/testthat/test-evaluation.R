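test_that("F1 and Fmax follow the harmonic-mean definition", {
  expect_equal(f1(0.5, 0.5), 0.5)
  expect_equal(f1(0.2, 1.0), 1 / 3)
  expect_equal(f1(0, 0.7), 0)
  expect_equal(f1(0.7, 0), 0)
  expect_equal(f1(0, 0), 0)

  mk <- function(rp) new("RPCurve", measure = "threshold", points =
    data.frame(control = seq_len(nrow(rp)), recall = rp$r, precision = rp$p,
               f1 = mapply(f1, rp$p, rp$r),
               n_predicted_targets = 1L))
  expect_equal(fmax(mk(data.frame(r = 0.5, p = 0.5))), 0.5)
  expect_equal(fmax(mk(data.frame(r = c(1.0, 0.5), p = c(0.2, 0.5)))), 0.5)
  expect_equal(fmax(mk(data.frame(r = 1, p = 1))), 1.0)
})

test_that("top-20 tiers select distinct reliability classes", {
  toy <- toyInstance()
  pt <- curvePoints(top20Curve(toy$preds, toy$truths, toy$graph))
  expect_equal(pt$recall[[1L]], 1 / 11, tolerance = 1e-9)
  expect_equal(pt$precision[[1L]], 1 / 2)
  # at tier 2 the whole 4-term prediction is in: 3 of 4 correct
  expect_equal(pt$recall[[2L]], 3 / 11, tolerance = 1e-9)
  expect_equal(pt$precision[[2L]], 3 / 4)

  # a perfect single-tier prediction scores (1, 1) at every k
  g <- chainGraph()
  preds <- list(T1 = c(a = 1, b = 1))
  truths <- list(T1 = c("a", "b"))
  pt2 <- curvePoints(top20Curve(preds, truths, g))
  expect_true(all(pt2$recall == 1) && all(pt2$precision == 1))
})

test_that("curves agree with a naive reimplementation on random instances", {
  for (seed in c(41, 42)) {
    edges <- randomDagEdges(25, seed)
    g <- loadOntology(edges)
    root <- ontologyRoot(g)
    sim <- withr::with_seed(seed + 100, {
      targets <- paste0("T", 1:6)
      truths <- setNames(lapply(targets, function(tg) {
        lv <- sample(setdiff(ontologyTerms(g), root), sample(2:4, 1))
        setdiff(naiveAncestorsOfSet(edges, lv), root)
      }), targets)
      preds <- setNames(lapply(targets, function(tg) {
        if (runif(1) < 0.2) return(setNames(numeric(), character()))
        lv <- sample(setdiff(ontologyTerms(g), root), sample(1:4, 1))
        sc <- setNames(round(runif(length(lv)), 2), lv)
        propagateMax(sc, g)[setdiff(naiveAncestorsOfSet(edges, lv), root)]
      }), targets)
      list(truths = truths, preds = preds)
    })
    topC <- curvePoints(top20Curve(sim$preds, sim$truths, g))
    thrC <- curvePoints(thresholdCurve(sim$preds, sim$truths, g))
    leafC <- curvePoints(leafThresholdCurve(sim$preds, sim$truths, g))
    for (k in c(1, 3, 7)) {
      o <- naiveTop20(sim$preds, sim$truths, k)
      expect_equal(topC$recall[[k]], o[["recall"]], info = paste(seed, k))
      expect_equal(topC$precision[[k]], o[["precision"]],
                   info = paste(seed, k))
    }
    for (t in c(1.0, 0.82, 0.5, 0.0)) {
      i <- which(abs(thrC$control - t) < 1e-9)
      o <- naiveThreshold(sim$preds, sim$truths, t)
      expect_equal(thrC$recall[[i]], o[["recall"]], info = paste(seed, t))
      expect_equal(thrC$precision[[i]], o[["precision"]],
                   info = paste(seed, t))
      ol <- naiveLeafThreshold(sim$preds, sim$truths, t, edges)
      expect_equal(leafC$recall[[i]], ol[["recall"]], info = paste(seed, t))
      expect_equal(leafC$precision[[i]], ol[["precision"]],
                   info = paste(seed, t))
    }
    # recall is monotone non-increasing as the threshold rises
    expect_true(all(diff(thrC$recall) >= 0))  # controls run 1.00 -> 0.00
    expect_true(all(diff(leafC$recall) >= 0))
  }
})

test_that("threshold inclusion is >= and unpredicted targets count 0 recall", {
  g <- chainGraph()
  preds <- list(T1 = c(b = 0.82, a = 0.82))
  truths <- list(T1 = c("a", "b"), T2 = c("a", "b"))
  pt <- curvePoints(thresholdCurve(preds, truths, g))
  at82 <- pt[abs(pt$control - 0.82) < 1e-9, ]
  expect_equal(at82$recall, 0.5)       # T1 full recall, T2 contributes 0
  expect_equal(at82$precision, 1.0)    # averaged over predicted targets only
  expect_equal(at82$n_predicted_targets, 1L)
  at83 <- pt[abs(pt$control - 0.83) < 1e-9, ]
  expect_equal(at83$recall, 0.0)
})

test_that("leaf measure penalizes over-general and bloated predictions", {
  toy <- toyInstance()
  pt <- curvePoints(leafThresholdCurve(toy$preds, toy$truths, toy$graph))
  at80 <- pt[abs(pt$control - 0.80) < 1e-9, ]
  expect_equal(at80$recall, 0.0)       # 0 of 3 true leaves
  expect_equal(at80$precision, 0.0)    # 0 of 1 predicted leaf

  # predicting the entire ontology hides the true leaves inside
  g <- toy$graph
  all1 <- setNames(rep(1, length(ontologyTerms(g))), ontologyTerms(g))
  whole <- list(A = stripRoot(all1, g))
  ptw <- curvePoints(leafThresholdCurve(whole, toy$truths, g))
  # truth leaves t06/t10/t11 are ontology leaves here, but so are others:
  # recall is full, precision diluted by the extra ontology leaves
  lvAll <- leafTerms(names(whole$A), g)
  expect_equal(ptw$recall[[1L]], 1.0)
  expect_equal(ptw$precision[[1L]], 3 / length(lvAll))

  # perfect leaf prediction scores (1,1) everywhere
  perf <- list(A = setNames(rep(1, 11), paste0("t", sprintf("%02d", 1:11))))
  ptp <- curvePoints(leafThresholdCurve(perf, toy$truths, g))
  expect_true(all(ptp$recall == 1) && all(ptp$precision == 1))
})

test_that("a truth-equal prediction reaches Fmax 1 under all measures", {
  toy <- toyInstance()
  perf <- list(A = setNames(rep(1, 11), paste0("t", sprintf("%02d", 1:11))))
  expect_equal(fmax(top20Curve(perf, toy$truths, toy$graph)), 1.0)
  expect_equal(fmax(thresholdCurve(perf, toy$truths, toy$graph)), 1.0)
  expect_equal(fmax(leafThresholdCurve(perf, toy$truths, toy$graph)), 1.0)
})

test_that("the root never contributes to any count", {
  g <- chainGraph()
  # prediction and truth both include the root; scoring must ignore it
  preds <- list(T1 = c(r = 1, a = 1))
  truths <- list(T1 = c("r", "a"))
  pt <- curvePoints(thresholdCurve(preds, truths, g))
  expect_equal(pt$recall[[1L]], 1.0)
  expect_equal(pt$precision[[1L]], 1.0)
  # a root-only truth is empty after stripping
  expect_error(thresholdCurve(preds, list(T1 = "r"), g), "empty truth")
})

test_that("ranking is descending with shared better rank on ties", {
  rk <- rankMethods(c(m1 = 0.36, m2 = 0.36, m3 = 0.34))
  expect_equal(rk$rank, c(1L, 1L, 3L))
  expect_equal(rk$method[rk$rank == 3L], "m3")
  expect_equal(rankMethods(c(only = 0.5))$rank, 1L)
  rk2 <- rankMethods(c(a = 0.1, b = 0.3, c = 0.2))
  expect_equal(rk2$method, c("b", "c", "a"))
  expect_equal(rk2$rank, 1:3)
})
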