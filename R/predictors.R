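#' Construct predictor parameters
#'
#' Bundles the tunable options of the three homology-transfer predictors.
#' Defaults reproduce each method's original configuration; the
#' re-parameterization grids explored after the fact are enumerated by
#' \code{\link{enumerateGrid}}.
#'
#' @param method \code{"A"}, \code{"B"} or \code{"C"}.
#' @param maxHits maximum number of hits used (A default 6; B default 250;
#'   C default unlimited).
#' @param maxEvalue strict E-value cutoff (A/C default 0.1; B default
#'   0.01).
#' @param iterations which PSI-BLAST iteration's hit file to consume (1, 2
#'   or 3; the predictor itself never runs PSI-BLAST -- this index selects
#'   among caller-provided hit files).
#' @param experimentalOnly restrict the annotation database to
#'   experimental evidence codes before transferring terms.
#' @param excludeHalfScores (A only) drop terms scored 0.5, keeping only
#'   unanimous terms.
#' @param identityKind (C only) \code{"positives"} uses percent positives,
#'   \code{"identity"} percent sequence identity.
#' @param allBranches (C only) output every branch instead of only the
#'   branch of the highest-scoring leaf.
#' @return a \code{PredictorParams} object.
#' @export
predictorParams <- function(method,
                            maxHits = switch(method, A = 6, B = 250, C = Inf),
                            maxEvalue = switch(method, A = 0.1, B = 0.01,
                                               C = 0.1),
                            iterations = 2L,
                            experimentalOnly = FALSE,
                            excludeHalfScores = FALSE,
                            identityKind = "positives",
                            allBranches = FALSE) {
  new("PredictorParams", method = method, maxHits = as.numeric(maxHits),
      maxEvalue = as.numeric(maxEvalue), iterations = as.integer(iterations),
      experimentalOnly = isTRUE(experimentalOnly),
      excludeHalfScores = isTRUE(excludeHalfScores),
      identityKind = identityKind, allBranches = isTRUE(allBranches))
}

# The hit database consists of annotated proteins only: apply the E-value
# cutoff, drop self-hits and hits whose subject has no annotation left in
# (possibly evidence-filtered) db, then truncate to maxHits.
prepareHits <- function(hits, db, params, excludeSelf = TRUE) {
  ht <- filterHits(hits, maxEvalue = params@maxEvalue, maxHits = Inf,
                   excludeSelf = excludeSelf)
  annotated <- unique(db@records$protein)
  h <- ht@hits[ht@hits$subject %in% annotated, , drop = FALSE]
  if (nrow(h) > params@maxHits)
    h <- h[seq_len(params@maxHits), , drop = FALSE]
  rownames(h) <- NULL
  new("HitTable", query = ht@query, hits = h)
}

maybeExperimental <- function(db, params) {
  if (params@experimentalOnly) filterExperimental(db) else db
}

emptyPrediction <- function() stats::setNames(numeric(), character())

# propagate, clamp into [0,1] and strip the root: the contract of every
# emitted prediction
finishPrediction <- function(scores, graph) {
  if (!length(scores)) return(emptyPrediction())
  out <- propagateMax(scores, graph)
  out <- pmin(pmax(out, 0), 1)
  stripRoot(out, graph)
}

# per-hit propagated annotation sets (list parallel to the hit rows)
hitAnnotationSets <- function(ht, db, graph) {
  lapply(ht@hits$subject, function(s) proteinAnnotation(db, s, graph))
}

# combine duplicate term scores by max
maxByTerm <- function(terms, scores) {
  res <- tapply(scores, terms, max)
  stats::setNames(as.numeric(res), names(res))
}

#' Nearest-neighbour GO transfer with unanimity scoring (method A)
#'
#' Transfers the GO terms of the best homology hits: a term present in the
#' propagated annotation of \emph{all} retained hits scores 1.0, any other
#' transferred term 0.5.  The propagation is reduced to its leaves and a
#' functional-redundancy filter is applied: leaf branches are clustered by
#' single linkage at pairwise overlap \eqn{\ge} 0.10 (so branches in
#' different clusters overlap below 10\%) and only the deepest leaf per
#' cluster survives.  Finally, for any branch pair overlapping above 90\%,
#' their deepest common term is restored with the larger of the two leaf
#' scores.
#'
#' @param hits a \code{HitTable} for the target.
#' @param db an \code{AnnotationDB} of template proteins.
#' @param graph an \code{OntologyGraph}.
#' @param params a \code{PredictorParams} with \code{method = "A"}.
#' @return named numeric score vector (propagated, clamped to
#'   \eqn{[0,1]}, root stripped); empty when no usable hit remains.
#' @export
predictStudentA <- function(hits, db, graph, params = predictorParams("A")) {
  stopifnot(params@method == "A")
  db <- maybeExperimental(db, params)
  ht <- prepareHits(hits, db, params)
  if (nrow(ht@hits) == 0L) return(emptyPrediction())
  annot <- hitAnnotationSets(ht, db, graph)
  direct <- unique(unlist(lapply(ht@hits$subject, proteinTerms, db = db),
                          use.names = FALSE))
  inAll <- vapply(direct, function(t)
    all(vapply(annot, function(a) t %in% a, logical(1L))), logical(1L))
  scores <- stats::setNames(ifelse(inAll, 1.0, 0.5), direct)
  if (params@excludeHalfScores) scores <- scores[scores == 1.0]
  if (!length(scores)) return(emptyPrediction())

  prop <- propagateMax(scores, graph)
  leaves <- leafTerms(prop, graph)
  branches <- lapply(leaves, branchOf, graph = graph)
  names(branches) <- leaves
  n <- length(leaves)
  ov <- matrix(1, n, n)
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n))
      ov[i, j] <- ov[j, i] <- branchOverlap(branches[[i]], branches[[j]])

  # single-linkage clusters: join whenever overlap >= 0.10
  cluster <- seq_len(n)
  if (n > 1L) {
    repeat {
      changed <- FALSE
      for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
        if (ov[i, j] >= 0.10 && cluster[i] != cluster[j]) {
          cluster[cluster == cluster[j]] <- cluster[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
  }
  kept <- vapply(split(seq_len(n), cluster), function(idx) {
    d <- graph@depth[leaves[idx]]
    cand <- sort(leaves[idx][d == max(d)])
    cand[[1L]]
  }, character(1L))
  out <- prop[kept]

  # restore the common core of near-identical branch pairs
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (ov[i, j] > 0.90) {
        common <- deepestCommonTerm(branches[[i]], branches[[j]], graph)
        sc <- max(prop[[leaves[[i]]]], prop[[leaves[[j]]]])
        out <- c(out, stats::setNames(sc, common))
      }
    }
  }
  finishPrediction(maxByTerm(names(out), out), graph)
}

#' Raw template score of a hit list
#'
#' Mean of the natural logarithms of all retained E-values plus twice
#' their sample standard deviation (zero when only one hit remains).
#' E-values are clamped into \eqn{[10^{-180}, 0.999]} before the
#' logarithm.
#'
#' @param hits a \code{HitTable} with at least one hit.
#' @return a real number (the more negative, the better the hit list).
#' @export
rawTemplateScore <- function(hits) {
  e <- hits@hits$evalue
  if (!length(e)) stop("raw template score needs at least one hit")
  lnE <- log(clampEvalue(e))
  m <- mean(lnE)
  s <- if (length(lnE) > 1L) stats::sd(lnE) else 0
  m + 2 * s
}

#' Template quality score
#'
#' Percentile-normalizes a raw template score against a background
#' distribution of raw scores: a score obtained (i.e. reached or beaten
#' upward) by 90\% of the background is mapped to \eqn{1 - 0.9 = 0.1}.
#' Lower (more negative) raw scores give higher quality.
#'
#' @param raw a raw template score (\code{\link{rawTemplateScore}}).
#' @param background non-empty numeric vector of background raw scores.
#' @return a score in \eqn{[0, 1]}.
#' @export
templateQualityScore <- function(raw, background) {
  if (!length(background)) stop("background distribution is empty")
  tqs <- 1 - mean(background <= raw)
  min(max(tqs, 0), 1)
}

#' Compile a background distribution of raw template scores
#'
#' Runs \code{\link{rawTemplateScore}} over the hit tables of a sample of
#' database proteins, applying the same hit filters as the predictor.
#' Queries with no hit left after filtering are skipped.
#'
#' @param hitTables a list of \code{HitTable} objects.
#' @param db an \code{AnnotationDB} (the hit filters drop hits to
#'   unannotated subjects).
#' @param params a \code{PredictorParams} (method B) providing the
#'   filters.
#' @param sampleSize optional number of tables to sample (default: use
#'   all).
#' @param seed RNG seed for the optional sampling.
#' @return sorted numeric vector of raw scores.
#' @export
compileBackground <- function(hitTables, db, params = predictorParams("B"),
                              sampleSize = NULL, seed = 1L) {
  if (!is.null(sampleSize) && sampleSize < length(hitTables))
    hitTables <- withSeed(seed,
      hitTables[sample.int(length(hitTables), sampleSize)])
  db <- maybeExperimental(db, params)
  raws <- vapply(hitTables, function(ht) {
    f <- prepareHits(ht, db, params)
    if (nrow(f@hits) == 0L) NA_real_ else rawTemplateScore(f)
  }, numeric(1L))
  sort(raws[!is.na(raws)])
}

# supports for every term occurring in any hit's propagated annotation
termSupports <- function(ht, db, graph) {
  annot <- hitAnnotationSets(ht, db, graph)
  lnE <- log(clampEvalue(ht@hits$evalue))
  total <- sum(lnE)
  terms <- unique(unlist(annot, use.names = FALSE))
  vapply(stats::setNames(terms, terms), function(t)
    sum(lnE[vapply(annot, function(a) t %in% a, logical(1L))]) / total,
    numeric(1L))
}

#' Support of a term in a hit list
#'
#' Fraction of the total log-E-value mass carried by the hits whose
#' propagated annotation contains the term:
#' \eqn{\sum_{h \ni t} \ln E_h / \sum_h \ln E_h}.  Both sums are negative
#' (E-values are clamped below 1), so the support lies in \eqn{(0, 1]};
#' a term present in every hit has support 1.  A term in no hit has
#' support 0.
#'
#' @param term a term identifier.
#' @param hits a \code{HitTable}.
#' @param db an \code{AnnotationDB}.
#' @param graph an \code{OntologyGraph}.
#' @return a value in \eqn{[0, 1]}.
#' @export
termSupport <- function(term, hits, db, graph) {
  s <- termSupports(hits, db, graph)
  if (!term %in% names(s)) return(0.0)
  s[[term]]
}

#' Combined leaf score
#'
#' Arithmetic mean of the support of a leaf and of all its ancestors,
#' excluding the uninformative root.
#'
#' @param leaf a leaf term present in \code{supports}.
#' @param supports named numeric vector of term supports.
#' @param graph an \code{OntologyGraph}.
#' @return a value in \eqn{[0, 1]}.
#' @export
combinedLeafScore <- function(leaf, supports, graph) {
  path <- setdiff(c(leaf, graph@ancestors[[checkTerms(leaf, graph)]]),
                  graph@root)
  if (!length(path)) path <- leaf  # leaf directly under the root
  mean(supports[path])
}

#' E-value-weighted GO transfer with template quality scoring (method B)
#'
#' Associates every hit with its propagated annotation, computes per-term
#' supports from log-E-value mass, scores each leaf of the pooled
#' propagation by the mean support along its ancestry (combined leaf
#' score) times the query-level template quality score, and outputs the
#' max-propagation of the scored leaves.
#'
#' @inheritParams predictStudentA
#' @param params a \code{PredictorParams} with \code{method = "B"}.
#' @param background background raw-score distribution
#'   (\code{\link{compileBackground}}).
#' @return named numeric score vector (propagated, root stripped).
#' @export
predictStudentB <- function(hits, db, graph, params = predictorParams("B"),
                            background) {
  stopifnot(params@method == "B")
  db <- maybeExperimental(db, params)
  ht <- prepareHits(hits, db, params)
  if (nrow(ht@hits) == 0L) return(emptyPrediction())
  tqs <- templateQualityScore(rawTemplateScore(ht), background)
  supports <- termSupports(ht, db, graph)
  leaves <- leafTerms(names(supports), graph)
  cls <- vapply(leaves, combinedLeafScore, numeric(1L),
                supports = supports, graph = graph)
  finishPrediction(stats::setNames(tqs * cls, leaves), graph)
}

#' Count-based GO transfer with cumulative propagation (method C)
#'
#' Counts how often each GO term appears among the hits' direct
#' annotations, propagates the counts cumulatively (summing distinct
#' descendants, normalized so the root scores 1) and multiplies each
#' term's normalized count by the highest percent positives (or percent
#' identity) of its supporting hits.  By default only the branch of the
#' highest-scoring leaf is emitted; optionally all branches are.
#'
#' @inheritParams predictStudentA
#' @param params a \code{PredictorParams} with \code{method = "C"}.
#' @return named numeric score vector (propagated, root stripped).
#' @export
predictStudentC <- function(hits, db, graph, params = predictorParams("C")) {
  stopifnot(params@method == "C")
  db <- maybeExperimental(db, params)
  ht <- prepareHits(hits, db, params)
  if (nrow(ht@hits) == 0L) return(emptyPrediction())
  directSets <- lapply(ht@hits$subject, proteinTerms, db = db)
  counts <- table(unlist(directSets, use.names = FALSE))
  counts <- stats::setNames(as.numeric(counts), names(counts))
  cum <- propagateCumulative(counts, graph)

  annot <- hitAnnotationSets(ht, db, graph)
  idcol <- if (params@identityKind == "identity") "pident" else "ppos"
  idval <- ht@hits[[idcol]] / 100
  idfac <- vapply(names(cum), function(t)
    max(idval[vapply(annot, function(a) t %in% a, logical(1L))]),
    numeric(1L))
  score <- cum * idfac

  leaves <- leafTerms(names(cum), graph)
  if (params@allBranches) {
    keep <- sort(unique(unlist(lapply(leaves, branchOf, graph = graph),
                               use.names = FALSE)))
  } else {
    ls <- score[leaves]
    best <- sort(leaves[ls == max(ls)])[[1L]]  # lexicographic tie-break
    keep <- branchOf(best, graph)
  }
  finishPrediction(score[intersect(keep, names(score))], graph)
}
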