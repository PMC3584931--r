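#' Term-frequency prior baseline
#'
#' Every target receives the identical prediction: every term of the
#' database, scored by its frequency among the propagated annotations of
#' the database proteins (the probability of observing the term on a
#' random database protein).
#'
#' @param db a non-empty \code{AnnotationDB}.
#' @param graph an \code{OntologyGraph}.
#' @param targets character vector of target accessions.
#' @return named list (one scored term set per target, root stripped; all
#'   entries identical).
#' @export
predictPriors <- function(db, graph, targets) {
  freq <- finishPrediction(termFrequencies(db, graph), graph)
  stats::setNames(rep(list(freq), length(targets)), targets)
}

#' Random-neighbour prior baseline
#'
#' For each target, draws one database protein uniformly at random and
#' returns its propagated annotation, each term scored by its database
#' frequency (as in the priors baseline).
#'
#' @inheritParams predictPriors
#' @param seed RNG seed (draws are reproducible for a fixed seed).
#' @return named list of scored term sets (root stripped).
#' @export
predictPriorsRandom <- function(db, graph, targets, seed = 1L) {
  prots <- annotatedProteins(db)
  if (!length(prots)) stop("annotation database is empty")
  freq <- termFrequencies(db, graph)
  withSeed(seed, {
    picks <- prots[sample.int(length(prots), length(targets), replace = TRUE)]
    res <- lapply(picks, function(p) {
      ann <- proteinAnnotation(db, p, graph)
      finishPrediction(freq[ann], graph)
    })
    stats::setNames(res, targets)
  })
}

#' Maximum-sequence-identity BLAST baseline
#'
#' Scores each term by the maximum percent sequence identity over the
#' hits whose propagated annotation contains it, divided by 100.
#'
#' @param hits a \code{HitTable} for one target.
#' @param db an \code{AnnotationDB}.
#' @param graph an \code{OntologyGraph}.
#' @param excludeSelf drop the self-hit (default \code{TRUE}).
#' @return named numeric score vector (propagated, root stripped); empty
#'   when no hit is available.
#' @export
predictBlastBaseline <- function(hits, db, graph, excludeSelf = TRUE) {
  ht <- filterHits(hits, maxEvalue = Inf, excludeSelf = excludeSelf)
  ht@hits <- ht@hits[ht@hits$subject %in% annotatedProteins(db), ,
                     drop = FALSE]
  if (nrow(ht@hits) == 0L) return(emptyPrediction())
  annot <- hitAnnotationSets(ht, db, graph)
  idv <- ht@hits$pident / 100
  terms <- unique(unlist(annot, use.names = FALSE))
  sc <- vapply(stats::setNames(terms, terms), function(t)
    max(idv[vapply(annot, function(a) t %in% a, logical(1L))]), numeric(1L))
  finishPrediction(sc, graph)
}

#' GOtcha-style I-score baseline
#'
#' The I-score of a term is the sum of \eqn{-\ln E} over the hits whose
#' propagated annotation contains it (E-values clamped below 1 so every
#' contribution is positive).  Scores are normalized into \eqn{[0, 1]} by
#' dividing by the root's I-score, which accumulates every hit; the
#' normalized scores are monotone non-decreasing toward the root.
#'
#' @inheritParams predictBlastBaseline
#' @return named numeric score vector (propagated, root stripped).
#' @export
predictGotcha <- function(hits, db, graph, excludeSelf = TRUE) {
  ht <- filterHits(hits, maxEvalue = Inf, excludeSelf = excludeSelf)
  ht@hits <- ht@hits[ht@hits$subject %in% annotatedProteins(db), ,
                     drop = FALSE]
  if (nrow(ht@hits) == 0L) return(emptyPrediction())
  annot <- hitAnnotationSets(ht, db, graph)
  w <- -log(clampEvalue(ht@hits$evalue))
  terms <- unique(unlist(annot, use.names = FALSE))
  iscore <- vapply(stats::setNames(terms, terms), function(t)
    sum(w[vapply(annot, function(a) t %in% a, logical(1L))]), numeric(1L))
  # the root lies in every hit's propagated annotation, so its I-score is
  # the full sum and already the maximum
  root_i <- iscore[[graph@root]]
  finishPrediction(iscore / root_i, graph)
}

#' Coincidence rate of picking and matching a term of given frequency
#'
#' Monte-Carlo estimate of the probability that a random-neighbour prior
#' both picks a term (it occurs on the drawn database protein, with
#' probability \eqn{p}) and the term is true for the target
#' (independently, also with probability \eqn{p}).  The estimate converges
#' to \eqn{p^2}: e.g. a term of frequency 0.15 is predicted correctly in
#' only about 2\% of cases, whereas an always-predict prior gets it right
#' for about 15\% of targets.
#'
#' @param p term frequency, in \eqn{[0, 1]}.
#' @param nTargets number of simulated targets.
#' @param seed RNG seed.
#' @return the simulated coincidence rate.
#' @export
simulatePriorsCoincidence <- function(p, nTargets = 100000L, seed = 1L) {
  stopifnot(p >= 0, p <= 1, nTargets >= 1)
  withSeed(seed, {
    predicted <- stats::rbinom(nTargets, 1L, p)
    true <- stats::rbinom(nTargets, 1L, p)
    mean(predicted == 1L & true == 1L)
  })
}
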