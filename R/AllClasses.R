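#' @import methods
#' @importFrom stats setNames sd lm coef rbinom runif rnorm
#' @importFrom utils read.delim write.table head
NULL

#' Central data classes
#'
#' @description
#' \code{GOmology} represents its central data objects as S4 classes:
#'
#' \itemize{
#'   \item \code{OntologyGraph}: a rooted directed acyclic graph of GO-like
#'     terms.  Edges point from child to parent, i.e. toward the root, and
#'     carry a relation label (\code{"is_a"}, \code{"part_of"}, ...).  The
#'     ancestor closure and the depth of every term (length of the
#'     \emph{longest} path to the root) are precomputed at construction.
#'   \item \code{AnnotationDB}: a protein-to-term annotation table with GO
#'     evidence codes, deduplicated on (protein, term) pairs.
#'   \item \code{HitTable}: the homology hits of one query protein in BLAST
#'     tabular form, kept sorted by ascending E-value (ties keep input
#'     order).
#'   \item \code{PredictorParams}: the tunable options of the three
#'     homology-transfer predictors (methods \code{"A"}, \code{"B"},
#'     \code{"C"}).
#'   \item \code{RPCurve}: a recall-precision curve produced by one of the
#'     assessment measures; one row per control point (reliability tier or
#'     score threshold).
#'   \item \code{MetaModel}: the coefficients of the weighted least-squares
#'     meta-combiner.
#' }
#'
#' Scored term sets -- the mapping from term identifier to a reliability in
#' \eqn{[0,1]} that predictors emit and the propagation algebra manipulates --
#' are deliberately plain named numeric vectors, and sets of terms plain
#' character vectors.  Collections of predictions or truths are named lists
#' keyed by target accession.
#'
#' @name GOmology-classes
#' @aliases OntologyGraph-class AnnotationDB-class HitTable-class
#'   PredictorParams-class RPCurve-class MetaModel-class
NULL

setClass("OntologyGraph",
  representation(
    terms = "character",
    edges = "data.frame",      # child, parent, relation
    root = "character",
    namespace = "character",
    parents = "list",          # term -> character vector of parents
    children = "list",         # term -> character vector of children
    ancestors = "list",        # term -> all ancestors up to the root
    depth = "integer"          # term -> longest path length to root
  )
)

setValidity("OntologyGraph", function(object) {
  msg <- character()
  if (length(object@root) != 1L || !object@root %in% object@terms)
    msg <- c(msg, "root must be a single term of the graph")
  if (anyDuplicated(object@terms))
    msg <- c(msg, "term identifiers must be unique")
  if (!all(c("child", "parent", "relation") %in% names(object@edges)))
    msg <- c(msg, "edges must have columns child, parent, relation")
  if (length(object@depth) && object@depth[[object@root]] != 0L)
    msg <- c(msg, "root must have depth 0")
  if (length(msg)) msg else TRUE
})

setClass("AnnotationDB",
  representation(records = "data.frame")  # protein, term, evidence
)

setValidity("AnnotationDB", function(object) {
  r <- object@records
  if (!all(c("protein", "term", "evidence") %in% names(r)))
    return("records must have columns protein, term, evidence")
  if (anyDuplicated(r[, c("protein", "term")]))
    return("duplicate (protein, term) pairs")
  if (nrow(r) && any(!nzchar(r$evidence)))
    return("evidence codes must be non-empty")
  TRUE
})

setClass("HitTable",
  representation(
    query = "character",
    hits = "data.frame"  # subject, pident, ppos, length, evalue, bitscore
  )
)

setValidity("HitTable", function(object) {
  h <- object@hits
  need <- c("subject", "pident", "ppos", "length", "evalue", "bitscore")
  if (!all(need %in% names(h)))
    return(paste("hits must have columns", paste(need, collapse = ", ")))
  if (nrow(h)) {
    if (any(h$evalue < 0)) return("E-values must be non-negative")
    if (any(h$pident < 0 | h$pident > 100 | h$ppos < 0 | h$ppos > 100))
      return("percent identity/positives must lie in [0, 100]")
    if (is.unsorted(h$evalue)) return("hits must be sorted by ascending E-value")
  }
  TRUE
})

setClass("PredictorParams",
  representation(
    method = "character",           # "A", "B" or "C"
    maxHits = "numeric",            # Inf = unlimited
    maxEvalue = "numeric",
    iterations = "integer",         # selects which hit file is consumed
    experimentalOnly = "logical",
    excludeHalfScores = "logical",  # A only
    identityKind = "character",     # C only: "positives" or "identity"
    allBranches = "logical"         # C only
  )
)

setValidity("PredictorParams", function(object) {
  msg <- character()
  if (!object@method %in% c("A", "B", "C"))
    msg <- c(msg, "method must be one of 'A', 'B', 'C'")
  if (!(object@maxHits >= 1)) msg <- c(msg, "maxHits must be >= 1")
  if (!(object@maxEvalue > 0)) msg <- c(msg, "maxEvalue must be > 0")
  if (!object@iterations %in% 1:3) msg <- c(msg, "iterations must be 1, 2 or 3")
  if (!object@identityKind %in% c("positives", "identity"))
    msg <- c(msg, "identityKind must be 'positives' or 'identity'")
  if (length(msg)) msg else TRUE
})

setClass("RPCurve",
  representation(
    points = "data.frame",  # control, recall, precision, f1, n_predicted_targets
    measure = "character"   # "top20", "threshold" or "leaf"
  )
)

setValidity("RPCurve", function(object) {
  p <- object@points
  need <- c("control", "recall", "precision", "f1", "n_predicted_targets")
  if (!all(need %in% names(p)))
    return(paste("points must have columns", paste(need, collapse = ", ")))
  if (!object@measure %in% c("top20", "threshold", "leaf"))
    return("measure must be 'top20', 'threshold' or 'leaf'")
  TRUE
})

setClass("MetaModel",
  representation(
    coefficients = "numeric",  # intercept, x (A), y (B), z (C)
    rankDeficient = "logical",
    weighting = "character"
  )
)

setValidity("MetaModel", function(object) {
  if (length(object@coefficients) != 4L ||
      !identical(names(object@coefficients), c("i", "x", "y", "z")))
    return("coefficients must be named i, x, y, z")
  if (any(!is.finite(object@coefficients)))
    return("coefficients must be finite")
  TRUE
})

setMethod("show", "OntologyGraph", function(object) {
  cat("OntologyGraph with", length(object@terms), "terms,",
      nrow(object@edges), "edges\n")
  cat("  namespace:", object@namespace, " root:", object@root,
      " max depth:", max(object@depth), "\n")
})

setMethod("show", "AnnotationDB", function(object) {
  r <- object@records
  cat("AnnotationDB:", nrow(r), "annotations,",
      length(unique(r$protein)), "proteins,",
      length(unique(r$term)), "terms\n")
  if (nrow(r)) {
    ev <- sort(table(r$evidence), decreasing = TRUE)
    cat("  evidence codes:",
        paste(names(ev), ev, sep = ":", collapse = " "), "\n")
  }
})

setMethod("show", "HitTable", function(object) {
  cat("HitTable for query", object@query, "with", nrow(object@hits), "hits\n")
  if (nrow(object@hits))
    cat("  best E-value:", format(min(object@hits$evalue)), "\n")
})

setMethod("show", "PredictorParams", function(object) {
  cat("PredictorParams (Student", object@method, ")\n", sep = "")
  cat("  maxHits:", object@maxHits, " maxEvalue:", object@maxEvalue,
      " iterations:", object@iterations,
      " experimentalOnly:", object@experimentalOnly, "\n")
  if (object@method == "A")
    cat("  excludeHalfScores:", object@excludeHalfScores, "\n")
  if (object@method == "C")
    cat("  identityKind:", object@identityKind,
        " allBranches:", object@allBranches, "\n")
})

setMethod("show", "RPCurve", function(object) {
  cat("RPCurve (", object@measure, " measure), ",
      nrow(object@points), " points, Fmax = ",
      format(fmax(object), digits = 3), "\n", sep = "")
})

setMethod("show", "MetaModel", function(object) {
  co <- object@coefficients
  cat("MetaModel: p = ", format(co[["x"]], digits = 3), "*A + ",
      format(co[["y"]], digits = 3), "*B + ",
      format(co[["z"]], digits = 3), "*C + ",
      format(co[["i"]], digits = 3), "\n", sep = "")
  cat("  weighting:", object@weighting,
      if (object@rankDeficient) " (rank-deficient fit, minimum-norm solution)",
      "\n")
})
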