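#' Read and write prediction and truth files
#'
#' Predictions are CAFA-style TSV files with columns \code{target},
#' \code{term}, \code{score}; truth files have columns \code{target},
#' \code{term}.  Comment lines starting with \code{#} are ignored; a
#' header row is optional.
#'
#' @param path file path.
#' @return \code{readPredictions}: named list of scored term sets;
#'   \code{readTruth}: named list of character term vectors.
#' @export
readPredictions <- function(path) {
  d <- readTsvFlexible(path, c("target", "term", "score"))
  if (nrow(d) == 0L) return(stats::setNames(list(), character()))
  d$score <- asNumericStrict(d$score, "score", path)
  res <- lapply(split(d, d$target), function(x)
    maxByTerm(x$term, x$score))
  res[unique(d$target)]
}

#' @rdname readPredictions
#' @param preds named list of scored term sets.
#' @param digits number of decimals used for the scores.
#' @export
writePredictions <- function(preds, path, digits = 3L) {
  fmt <- paste0("%s\t%s\t%.", digits, "f")
  rows <- unlist(lapply(names(preds), function(tg) {
    s <- preds[[tg]]
    if (!length(s)) return(character())
    sprintf(fmt, tg, names(s), s)
  }), use.names = FALSE)
  writeLines(c("target\tterm\tscore", rows), path)
  invisible(path)
}

#' @rdname readPredictions
#' @export
readTruth <- function(path) {
  d <- readTsvFlexible(path, c("target", "term"), min_cols = 2L)
  if (nrow(d) == 0L) return(stats::setNames(list(), character()))
  res <- lapply(split(d, d$target), function(x) sort(unique(x$term)))
  res[unique(d$target)]
}

#' @rdname readPredictions
#' @param truths named list of character term vectors.
#' @export
writeTruth <- function(truths, path) {
  rows <- unlist(lapply(names(truths), function(tg)
    sprintf("%s\t%s", tg, truths[[tg]])), use.names = FALSE)
  writeLines(c("target\tterm", rows), path)
  invisible(path)
}

# one recall/precision pair; precision is NA (undefined, excluded from the
# average) when nothing is predicted
prPoint <- function(predTerms, truthTerms) {
  tp <- length(intersect(predTerms, truthTerms))
  c(recall = tp / length(truthTerms),
    precision = if (length(predTerms)) tp / length(predTerms) else NA_real_)
}

# macro-average the per-target pairs: recall over ALL targets (unpredicted
# targets contribute 0), precision only over targets with a non-empty
# prediction
averagePoints <- function(mat) {
  rec <- mean(mat["recall", ])
  prec_vals <- mat["precision", ]
  n_pred <- sum(!is.na(prec_vals))
  prec <- if (n_pred) mean(prec_vals, na.rm = TRUE) else NA_real_
  c(recall = rec, precision = prec, n = n_pred)
}

curveFromSelections <- function(preds, truths, graph, controls, selectFn,
                                truthFn, measure) {
  targets <- names(truths)
  truthSets <- lapply(targets, function(tg)
    truthFn(stripRoot(truths[[tg]], graph)))
  predSets <- lapply(targets, function(tg) {
    p <- preds[[tg]]
    if (is.null(p)) emptyPrediction() else stripRoot(p, graph)
  })
  rows <- lapply(seq_along(controls), function(ci) {
    mat <- vapply(seq_along(targets), function(i)
      prPoint(selectFn(predSets[[i]], controls[[ci]]), truthSets[[i]]),
      numeric(2L))
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = 2L,
                                         dimnames = list(c("recall",
                                                           "precision")))
    averagePoints(mat)
  })
  rec <- vapply(rows, `[[`, numeric(1L), "recall")
  prec <- vapply(rows, `[[`, numeric(1L), "precision")
  points <- data.frame(control = controls, recall = rec, precision = prec,
                       f1 = ifelse(is.na(prec), NA_real_,
                                   mapply(f1, prec, rec)),
                       n_predicted_targets =
                         vapply(rows, `[[`, numeric(1L), "n"))
  new("RPCurve", points = points, measure = measure)
}

#' Top-20 recall-precision curve
#'
#' For \eqn{k = 1, \ldots, 20}, each target's prediction is reduced to the
#' terms whose reliability belongs to the \eqn{k} highest \emph{distinct}
#' score values of that target (terms sharing the top score form one
#' tier).  Recall is the number of correct predicted terms over all true
#' terms, precision over all predicted terms; recall is averaged over
#' every target (unpredicted targets count 0), precision only over
#' targets with a non-empty prediction.  The root never contributes.
#'
#' @param preds named list of scored term sets (one per target).
#' @param truths named list of propagated true term sets (one per
#'   target, each non-empty once the root is stripped).
#' @param graph an \code{OntologyGraph}.
#' @return an \code{RPCurve} with 20 points (control = tier count).
#' @export
top20Curve <- function(preds, truths, graph) {
  checkTruths(truths, graph)
  selectFn <- function(p, k) {
    if (!length(p)) return(character())
    tiers <- sort(unique(p), decreasing = TRUE)
    names(p)[p >= tiers[[min(k, length(tiers))]]]
  }
  curveFromSelections(preds, truths, graph, controls = 1:20,
                      selectFn = selectFn, truthFn = identity,
                      measure = "top20")
}

#' Threshold recall-precision curve
#'
#' Sweeps a reliability threshold from 1.00 down to 0.00 in steps of 0.01
#' (101 points); at each threshold a target's prediction is reduced to the
#' terms scoring greater than or equal to the threshold (with a 1e-9
#' tolerance so that 3-decimal score files behave stably at boundaries
#' like 0.82).  Averaging as in \code{\link{top20Curve}}.
#'
#' @inheritParams top20Curve
#' @return an \code{RPCurve} with 101 points (control = threshold).
#' @export
thresholdCurve <- function(preds, truths, graph) {
  checkTruths(truths, graph)
  selectFn <- function(p, t) names(p)[p >= t - 1e-9]
  curveFromSelections(preds, truths, graph,
                      controls = seq(1, 0, by = -0.01),
                      selectFn = selectFn, truthFn = identity,
                      measure = "threshold")
}

#' Leaf threshold recall-precision curve
#'
#' Both the true and the predicted propagation are first reduced to their
#' leaf terms -- the most specific descriptions present.  The same
#' 101-step threshold sweep as \code{\link{thresholdCurve}} then filters
#' the predicted leaves by score; recall is the number of correctly
#' predicted leaves over all true leaves, precision over all predicted
#' leaves above the threshold.  Over-general or bloated predictions are
#' penalized: a correct term that is not a leaf of the prediction never
#' counts.
#'
#' @inheritParams top20Curve
#' @return an \code{RPCurve} with 101 points (control = threshold).
#' @export
leafThresholdCurve <- function(preds, truths, graph) {
  checkTruths(truths, graph)
  targets <- names(truths)
  # reduce each prediction to the scores of its own leaf terms up front;
  # the threshold then sweeps over leaves only
  predsLeaf <- lapply(targets, function(tg) {
    p <- preds[[tg]]
    if (is.null(p) || !length(p)) return(emptyPrediction())
    p <- stripRoot(p, graph)
    if (!length(p)) return(emptyPrediction())
    p[leafTerms(names(p), graph)]
  })
  names(predsLeaf) <- targets
  selectFn <- function(p, t) names(p)[p >= t - 1e-9]
  curveFromSelections(predsLeaf, truths, graph,
                      controls = seq(1, 0, by = -0.01),
                      selectFn = selectFn,
                      truthFn = function(tr) leafTerms(tr, graph),
                      measure = "leaf")
}

checkTruths <- function(truths, graph) {
  bad <- names(truths)[vapply(truths, function(tr)
    length(stripRoot(tr, graph)) == 0L, logical(1L))]
  if (length(bad))
    stop("empty truth annotation for target(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  invisible(TRUE)
}

#' F1 score
#'
#' Harmonic mean of precision and recall,
#' \eqn{2PR/(P + R)}; defined as 0 when both are 0.
#'
#' @param precision,recall values in \eqn{[0, 1]}.
#' @return the F1 score.
#' @export
f1 <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' Maximum F1 score of a recall-precision curve
#'
#' The maximum F1 over all curve points with defined precision; 0 when no
#' point has defined precision.
#'
#' @param curve an \code{RPCurve}.
#' @return the Fmax value.
#' @export
fmax <- function(curve) {
  p <- curve@points
  if (!nrow(p)) stop("empty curve")
  vals <- p$f1[!is.na(p$f1)]
  if (!length(vals)) return(0)
  max(vals)
}

#' Rank methods by Fmax
#'
#' Orders methods by descending Fmax; tied methods share the better
#' (smaller) rank.
#'
#' @param fmaxByMethod named numeric vector of Fmax values.
#' @return data.frame with columns \code{method}, \code{fmax},
#'   \code{rank}, sorted by rank.
#' @export
rankMethods <- function(fmaxByMethod) {
  if (!length(fmaxByMethod)) stop("no methods to rank")
  rk <- rank(-fmaxByMethod, ties.method = "min")
  d <- data.frame(method = names(fmaxByMethod),
                  fmax = as.numeric(fmaxByMethod),
                  rank = as.integer(rk))
  d <- d[order(d$rank, d$method), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Accessors for recall-precision curves
#'
#' @param curve an \code{RPCurve}.
#' @return \code{curvePoints}: the data.frame of points;
#'   \code{curveMeasure}: the measure label.
#' @export
curvePoints <- function(curve) curve@points

#' @rdname curvePoints
#' @export
curveMeasure <- function(curve) curve@measure

#' @rdname curvePoints
#' @param path output TSV path.
#' @export
writeCurve <- function(curve, path) {
  p <- curve@points
  rows <- sprintf("%s\t%.4f\t%s\t%s\t%d", format(p$control),
                  p$recall,
                  ifelse(is.na(p$precision), "NA", sprintf("%.4f", p$precision)),
                  ifelse(is.na(p$f1), "NA", sprintf("%.4f", p$f1)),
                  as.integer(p$n_predicted_targets))
  writeLines(c(paste0("# measure: ", curve@measure),
               "control\trecall\tprecision\tf1\tn_predicted_targets", rows),
             path)
  invisible(path)
}
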