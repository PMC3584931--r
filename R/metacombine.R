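#' Enumerate the re-parameterization grid of a predictor
#'
#' Returns the full Cartesian product of the option axes explored for each
#' method, in a fixed deterministic order:
#' \itemize{
#'   \item method A: drop-0.5-scores \{off, on\} x hits \{1, 5, 9\} x
#'     iterations \{1, 2, 3\} x experimental-only \{off, on\} = 36;
#'   \item method B: E-value \{1e0, 1e-3, 1e-6\} x hits \{5, 50, 500\} x
#'     iterations x experimental-only = 54;
#'   \item method C: E-value \{1e0, 1e-3, 1e-6\} x identity kind
#'     \{positives, identity\} x all-branches \{off, on\} x iterations x
#'     experimental-only = 72.
#' }
#'
#' @param method \code{"A"}, \code{"B"} or \code{"C"}.
#' @return list of \code{PredictorParams}.
#' @export
enumerateGrid <- function(method) {
  grid <- switch(method,
    A = expand.grid(excludeHalfScores = c(FALSE, TRUE),
                    maxHits = c(1, 5, 9),
                    iterations = 1:3,
                    experimentalOnly = c(FALSE, TRUE),
                    KEEP.OUT.ATTRS = FALSE),
    B = expand.grid(maxEvalue = c(1e0, 1e-3, 1e-6),
                    maxHits = c(5, 50, 500),
                    iterations = 1:3,
                    experimentalOnly = c(FALSE, TRUE),
                    KEEP.OUT.ATTRS = FALSE),
    C = expand.grid(maxEvalue = c(1e0, 1e-3, 1e-6),
                    identityKind = c("positives", "identity"),
                    allBranches = c(FALSE, TRUE),
                    iterations = 1:3,
                    experimentalOnly = c(FALSE, TRUE),
                    KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE),
    stop("unknown method: ", method)
  )
  lapply(seq_len(nrow(grid)), function(i)
    do.call(predictorParams, c(list(method = method),
                               as.list(grid[i, , drop = FALSE]))))
}

# run one predictor over all targets; hitsByIteration is a list indexed by
# iteration ("1".."3"), each a named list of HitTable objects per target
runPredictor <- function(method, params, targets, hitsByIteration, db, graph,
                         background = NULL) {
  tables <- hitsByIteration[[as.character(params@iterations)]]
  if (is.null(tables))
    stop("no hit file provided for iteration setting ", params@iterations)
  if (method == "B" && is.null(background))
    background <- compileBackground(tables, db, params)
  res <- lapply(targets, function(tg) {
    ht <- tables[[tg]]
    if (is.null(ht)) return(emptyPrediction())
    switch(method,
           A = predictStudentA(ht, db, graph, params),
           B = predictStudentB(ht, db, graph, params, background),
           C = predictStudentC(ht, db, graph, params))
  })
  stats::setNames(res, targets)
}

#' Pick the Fmax-optimal parameter setting of a predictor
#'
#' Runs the predictor under every setting of the grid on the given
#' targets, scores each run by the maximum F1 of its threshold curve, and
#' returns the setting with the highest Fmax (ties broken by enumeration
#' order).
#'
#' @param method \code{"A"}, \code{"B"} or \code{"C"}.
#' @param targets character vector of target accessions.
#' @param truths named list of propagated true term sets.
#' @param hitsByIteration list keyed by iteration (\code{"1"}..\code{"3"})
#'   of named lists of \code{HitTable} objects.
#' @param db an \code{AnnotationDB} of templates.
#' @param graph an \code{OntologyGraph}.
#' @param grid list of \code{PredictorParams}; defaults to
#'   \code{enumerateGrid(method)}.
#' @return list with components \code{params} (the winning setting),
#'   \code{fmax}, and \code{fmaxAll} (Fmax of every setting, in grid
#'   order).
#' @export
optimizeParams <- function(method, targets, truths, hitsByIteration, db,
                           graph, grid = enumerateGrid(method)) {
  if (!length(grid)) stop("empty parameter grid")
  fm <- vapply(grid, function(params) {
    preds <- runPredictor(method, params, targets, hitsByIteration, db,
                          graph)
    fmax(thresholdCurve(preds, truths[targets], graph))
  }, numeric(1L))
  best <- which.max(fm)  # first maximum = enumeration-order tie-break
  list(params = grid[[best]], fmax = fm[[best]], fmaxAll = fm)
}

#' Out-of-fold predictions for the meta-combiner
#'
#' Randomly splits the targets into two halves (sizes floor(n/2) and
#' ceil(n/2), seeded), optimizes each method's parameters on one half and
#' predicts the other, then switches roles, so that every target receives
#' exactly one out-of-fold prediction per method.
#'
#' @inheritParams optimizeParams
#' @param seed RNG seed for the half-split.
#' @param methods which predictors to include (default A, B, C).
#' @return list with components \code{predictions} (per method, named list
#'   of scored term sets over all targets), \code{folds} (list of the two
#'   target vectors) and \code{params} (chosen settings per fold and
#'   method).
#' @export
twoFoldPredictions <- function(targets, truths, hitsByIteration, db, graph,
                               seed = 1L, methods = c("A", "B", "C")) {
  n <- length(targets)
  if (n < 2L) stop("need at least 2 targets for a two-fold split")
  perm <- withSeed(seed, sample(targets))
  folds <- list(perm[seq_len(floor(n / 2))],
                perm[seq.int(floor(n / 2) + 1L, n)])
  preds <- stats::setNames(vector("list", length(methods)), methods)
  chosen <- list()
  for (m in methods) {
    out <- list()
    for (k in 1:2) {
      trainFold <- folds[[k]]
      testFold <- folds[[3L - k]]
      opt <- optimizeParams(m, trainFold, truths, hitsByIteration, db, graph)
      chosen[[paste0(m, k)]] <- opt$params
      out <- c(out, runPredictor(m, opt$params, testFold, hitsByIteration,
                                 db, graph))
    }
    preds[[m]] <- out[targets]
  }
  list(predictions = preds, folds = folds, params = chosen)
}

#' Build regression rows from per-method predictions
#'
#' For every target and every term predicted by at least one method, emits
#' one row with the three method scores (0 when a method did not predict
#' the term) and the 0/1 label of whether the term lies in the target's
#' true propagation (root excluded).
#'
#' @param predsA,predsB,predsC named lists of scored term sets.
#' @param truths named list of propagated true term sets.
#' @param graph an \code{OntologyGraph}.
#' @return data.frame with columns \code{target}, \code{term},
#'   \code{scoreA}, \code{scoreB}, \code{scoreC}, \code{label}.
#' @export
metaRows <- function(predsA, predsB, predsC, truths, graph) {
  rows <- lapply(names(truths), function(tg) {
    pa <- predsA[[tg]]; pb <- predsB[[tg]]; pc <- predsC[[tg]]
    terms <- unique(c(names(pa), names(pb), names(pc)))
    terms <- setdiff(terms, graph@root)
    if (!length(terms)) return(NULL)
    getScore <- function(p, t) if (is.null(p) || !t %in% names(p)) 0 else p[[t]]
    truth <- stripRoot(truths[[tg]], graph)
    data.frame(target = tg, term = terms,
               scoreA = vapply(terms, getScore, numeric(1L), p = pa),
               scoreB = vapply(terms, getScore, numeric(1L), p = pb),
               scoreC = vapply(terms, getScore, numeric(1L), p = pc),
               label = as.integer(terms %in% truth))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the weighted least-squares meta-combiner
#'
#' Solves \eqn{x A + y B + z C + i = p} by weighted least squares on rows
#' of per-term method scores labelled 0/1 by membership in the true
#' propagation.  By default each class (positive/negative rows) receives
#' inverse-frequency weights so the overwhelming negative class does not
#' dominate; uniform weighting is available.  A rank-deficient design
#' falls back to the minimum-norm solution and is flagged.
#'
#' @param rows data.frame with columns \code{scoreA}, \code{scoreB},
#'   \code{scoreC} and \code{label} (0/1); at least 4 rows.
#' @param weighting \code{"balanced"} (inverse class frequency) or
#'   \code{"uniform"}.
#' @return a \code{MetaModel}.
#' @export
fitMeta <- function(rows, weighting = c("balanced", "uniform")) {
  weighting <- match.arg(weighting)
  need <- c("scoreA", "scoreB", "scoreC", "label")
  if (!all(need %in% names(rows)))
    stop("rows must have columns ", paste(need, collapse = ", "))
  if (nrow(rows) < 4L) stop("need at least 4 rows to fit 4 coefficients")
  if (!all(rows$label %in% c(0, 1))) stop("labels must be 0 or 1")
  w <- if (weighting == "balanced") {
    tab <- table(factor(rows$label, levels = c(0, 1)))
    if (any(tab == 0)) rep(1, nrow(rows))
    else as.numeric(nrow(rows) / (2 * tab[as.character(rows$label)]))
  } else rep(1, nrow(rows))

  X <- cbind(i = 1, x = rows$scoreA, y = rows$scoreB, z = rows$scoreC)
  qrX <- qr(sqrt(w) * X)
  rankDeficient <- qrX$rank < ncol(X)
  if (rankDeficient) {
    # minimum-norm solution of the weighted normal equations
    co <- as.numeric(MASS::ginv(t(X) %*% (w * X)) %*% t(X) %*%
                       (w * rows$label))
  } else {
    fit <- stats::lm(label ~ scoreA + scoreB + scoreC, data = rows,
                     weights = w)
    co <- unname(stats::coef(fit))
  }
  new("MetaModel",
      coefficients = stats::setNames(co, c("i", "x", "y", "z")),
      rankDeficient = rankDeficient, weighting = weighting)
}

#' Accessor for meta-model coefficients
#'
#' @param model a \code{MetaModel}.
#' @return named numeric vector \code{(i, x, y, z)}.
#' @export
metaCoefficients <- function(model) model@coefficients

#' Apply the meta-combiner to per-method predictions
#'
#' For every term predicted by any of the three methods for a target,
#' computes \eqn{p = x A + y B + z C + i} (a missing method contributes
#' score 0), clamps \eqn{p} into \eqn{[0, 1]} and emits the
#' max-propagation of the scored terms.
#'
#' @param model a fitted \code{MetaModel}.
#' @param predsA,predsB,predsC named lists of scored term sets.
#' @param graph an \code{OntologyGraph}.
#' @return named list of scored term sets (root stripped).
#' @export
predictMeta <- function(model, predsA, predsB, predsC, graph) {
  co <- model@coefficients
  targets <- unique(c(names(predsA), names(predsB), names(predsC)))
  res <- lapply(targets, function(tg) {
    pa <- predsA[[tg]]; pb <- predsB[[tg]]; pc <- predsC[[tg]]
    terms <- unique(c(names(pa), names(pb), names(pc)))
    if (!length(terms)) return(emptyPrediction())
    getScore <- function(p, t) if (is.null(p) || !t %in% names(p)) 0 else p[[t]]
    p <- vapply(terms, function(t)
      co[["i"]] + co[["x"]] * getScore(pa, t) + co[["y"]] * getScore(pb, t) +
        co[["z"]] * getScore(pc, t), numeric(1L))
    finishPrediction(stats::setNames(pmin(pmax(p, 0), 1), terms), graph)
  })
  stats::setNames(res, targets)
}

#' Write and read meta-model files
#'
#' Plain-text key-value files with the four coefficients.
#'
#' @param model a \code{MetaModel}.
#' @param path file path.
#' @export
writeMetaModel <- function(model, path) {
  co <- model@coefficients
  writeLines(c(sprintf("%s\t%.10g", names(co), co),
               paste0("weighting\t", model@weighting),
               paste0("rank_deficient\t", tolower(model@rankDeficient))),
             path)
  invisible(path)
}

#' @rdname writeMetaModel
#' @export
readMetaModel <- function(path) {
  d <- readTsvFlexible(path, c("key", "value"), min_cols = 2L)
  kv <- stats::setNames(d$value, d$key)
  co <- as.numeric(kv[c("i", "x", "y", "z")])
  new("MetaModel", coefficients = stats::setNames(co, c("i", "x", "y", "z")),
      rankDeficient = identical(kv[["rank_deficient"]], "true"),
      weighting = if ("weighting" %in% names(kv)) kv[["weighting"]]
                  else "balanced")
}
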