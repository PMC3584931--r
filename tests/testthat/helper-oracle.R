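# Naive, loop-based reimplementation of the assessment measures, kept
# deliberately independent of the package's vectorised code paths.

naiveAncestorsOfSet <- function(edges, terms) {
  sort(unique(unlist(c(terms, lapply(terms, function(t)
    bruteAncestors(edges, t))))))
}

naivePR <- function(pred, truth) {
  tp <- sum(pred %in% truth)
  list(recall = tp / length(truth),
       precision = if (length(pred)) tp / length(pred) else NA_real_)
}

naiveAverage <- function(prs) {
  rec <- mean(vapply(prs, `[[`, numeric(1L), "recall"))
  pv <- vapply(prs, `[[`, numeric(1L), "precision")
  prec <- if (all(is.na(pv))) NA_real_ else mean(pv, na.rm = TRUE)
  c(recall = rec, precision = prec)
}

# preds: named list of named numeric; truths: named list of character
# (root must already be absent from both)
naiveTop20 <- function(preds, truths, k) {
  prs <- lapply(names(truths), function(tg) {
    p <- preds[[tg]]
    if (is.null(p) || !length(p)) return(naivePR(character(), truths[[tg]]))
    tiers <- sort(unique(as.numeric(p)), decreasing = TRUE)
    cut <- tiers[min(k, length(tiers))]
    naivePR(names(p)[p >= cut], truths[[tg]])
  })
  naiveAverage(prs)
}

naiveThreshold <- function(preds, truths, t) {
  prs <- lapply(names(truths), function(tg) {
    p <- preds[[tg]]
    sel <- if (is.null(p)) character() else names(p)[p >= t - 1e-9]
    naivePR(sel, truths[[tg]])
  })
  naiveAverage(prs)
}

naiveLeaves <- function(edges, terms) {
  sort(Filter(function(t) {
    ch <- edges$child[edges$parent == t]
    !any(ch %in% terms)
  }, terms))
}

naiveLeafThreshold <- function(preds, truths, t, edges) {
  prs <- lapply(names(truths), function(tg) {
    truthLv <- naiveLeaves(edges, truths[[tg]])
    p <- preds[[tg]]
    if (is.null(p) || !length(p)) return(naivePR(character(), truthLv))
    predLv <- naiveLeaves(edges, names(p))
    sel <- predLv[p[predLv] >= t - 1e-9]
    naivePR(sel, truthLv)
  })
  naiveAverage(prs)
}

# brute-force max-propagation: score(u) = max over scored terms t with
# u on some path from t to the root (or t itself)
naivePropagateMax <- function(edges, scores) {
  terms <- unique(c(names(scores),
                    unlist(lapply(names(scores), bruteAncestors,
                                  edges = edges))))
  out <- vapply(terms, function(u) {
    covering <- vapply(names(scores), function(t)
      u == t || u %in% bruteAncestors(edges, t), logical(1L))
    max(scores[covering])
  }, numeric(1L))
  out
}
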