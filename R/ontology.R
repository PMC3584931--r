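#' Build a validated ontology graph from a child-to-parent edge list
#'
#' Constructs an \code{OntologyGraph} from records of directed edges that
#' point from a term to one of its parents, i.e. toward the root of the
#' ontology.  The graph must be acyclic and have exactly one root (the only
#' term without outgoing edges); every other term then necessarily reaches
#' the root.  The ancestor closure and the depth of every term (number of
#' edges on the \emph{longest} path to the root) are precomputed.
#'
#' @param edges a data.frame with columns \code{child}, \code{parent} and
#'   optionally \code{relation} (defaults to \code{"is_a"}), or a list of
#'   \code{c(child, parent[, relation])} character vectors.
#' @param terms optional character vector with the complete term universe;
#'   when given, any edge endpoint outside it raises a dangling-reference
#'   error.  Defaults to the terms seen in \code{edges}.
#' @param namespace label of the ontology namespace (e.g. \code{"MFO"},
#'   \code{"BPO"}).
#' @return an \code{OntologyGraph}.
#' @examples
#' g <- loadOntology(data.frame(child = c("b", "a"), parent = c("a", "r")))
#' termDepth(g)[["b"]]  # 2
#' @export
loadOntology <- function(edges, terms = NULL, namespace = "MFO") {
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, lapply(edges, function(e) {
      if (length(e) == 2L) e <- c(e, "is_a")
      data.frame(child = e[[1L]], parent = e[[2L]], relation = e[[3L]])
    }))
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!"relation" %in% names(edges)) edges$relation <- "is_a"
  edges <- edges[, c("child", "parent", "relation")]
  edges[] <- lapply(edges, as.character)
  if (nrow(edges) == 0L) stop("ontology edge list is empty")
  if (any(!nzchar(edges$child)) || any(!nzchar(edges$parent)))
    stop("ontology contains empty term identifiers")
  seen <- unique(c(edges$child, edges$parent))
  if (is.null(terms)) {
    terms <- seen
  } else {
    terms <- unique(as.character(terms))
    bad <- setdiff(seen, terms)
    if (length(bad))
      stop("dangling term reference(s) in edges: ",
           paste(utils::head(bad, 5L), collapse = ", "))
  }
  edges <- unique(edges)

  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     directed = TRUE,
                                     vertices = data.frame(name = terms))
  if (!igraph::is_dag(g))
    stop("cycle detected: the ontology must be acyclic")
  outdeg <- igraph::degree(g, mode = "out")
  roots <- names(outdeg)[outdeg == 0L]
  if (length(roots) > 1L)
    stop("multiple roots detected: ", paste(roots, collapse = ", "),
         " (every term must reach a single root)")
  root <- roots

  parents <- split(edges$parent, edges$child)
  children <- split(edges$child, edges$parent)
  parents <- lapply(parents, unique)
  children <- lapply(children, unique)

  # walk terms parents-first so each term's closure/depth is ready when used
  order <- rev(names(igraph::topo_sort(g, mode = "out")))
  ancestors <- setNames(vector("list", length(terms)), terms)
  depth <- setNames(integer(length(terms)), terms)
  for (t in order) {
    ps <- parents[[t]]
    if (is.null(ps)) {
      ancestors[[t]] <- character()
      depth[[t]] <- 0L
    } else {
      ancestors[[t]] <- sort(unique(c(ps, unlist(ancestors[ps], use.names = FALSE))))
      depth[[t]] <- 1L + max(depth[ps])
    }
  }

  new("OntologyGraph", terms = terms, edges = edges, root = root,
      namespace = namespace, parents = parents, children = children,
      ancestors = ancestors, depth = depth)
}

#' Read an ontology from a TSV edge list
#'
#' Expects columns \code{child_id}, \code{parent_id}, \code{relation}
#' (header optional; lines starting with \code{#} are ignored).
#'
#' @inheritParams loadOntology
#' @param path path to the TSV file.
#' @return an \code{OntologyGraph}.
#' @export
readOntologyTSV <- function(path, namespace = "MFO") {
  d <- readTsvFlexible(path, c("child_id", "parent_id", "relation"),
                       min_cols = 2L)
  if (ncol(d) < 3L) d[[3L]] <- "is_a"
  loadOntology(data.frame(child = d[[1L]], parent = d[[2L]],
                          relation = d[[3L]]),
               namespace = namespace)
}

#' Read a minimal OBO file
#'
#' Parses \code{[Term]} stanzas with \code{id}, \code{is_a},
#' \code{relationship: part_of} and \code{namespace} lines; everything else
#' is ignored.  Obsolete terms and cross-namespace subsets are not handled.
#'
#' @param path path to the OBO file.
#' @param namespace if not \code{NULL}, keep only terms of this namespace
#'   (matched against each stanza's \code{namespace} line when present).
#' @return an \code{OntologyGraph}.
#' @export
readOBO <- function(path, namespace = NULL) {
  lines <- readLines(path, warn = FALSE)
  ids <- character(); edges <- list(); cur <- NULL; cur_ns <- NA_character_
  stanza_ns <- character()
  flush <- function() {
    if (!is.null(cur)) {
      ids <<- c(ids, cur)
      stanza_ns[cur] <<- cur_ns
    }
  }
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { flush(); cur <- NULL; cur_ns <- NA; in_term <- TRUE; next }
    if (grepl("^\\[", ln)) { flush(); cur <- NULL; in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) cur <- trimws(sub("^id:", "", ln))
    else if (grepl("^namespace:", ln)) cur_ns <- trimws(sub("^namespace:", "", ln))
    else if (grepl("^is_a:", ln)) {
      p <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      edges[[length(edges) + 1L]] <- c(cur, p, "is_a")
    } else if (grepl("^relationship:\\s*part_of", ln)) {
      p <- trimws(sub("!.*$", "", sub("^relationship:\\s*part_of", "", ln)))
      edges[[length(edges) + 1L]] <- c(cur, p, "part_of")
    }
  }
  flush()
  if (!is.null(namespace)) {
    keep <- ids[is.na(stanza_ns[ids]) | stanza_ns[ids] == namespace]
    edges <- Filter(function(e) e[[1L]] %in% keep && e[[2L]] %in% keep, edges)
    ids <- keep
  }
  if (!length(edges)) stop("no edges found in OBO file")
  ns <- if (is.null(namespace)) {
    obs <- unique(stats::na.omit(stanza_ns))
    if (length(obs) == 1L) obs else "other"
  } else namespace
  loadOntology(edges, terms = ids, namespace = ns)
}

#' Accessors for ontology graphs
#'
#' \code{ontologyTerms} returns all term identifiers, \code{ontologyRoot}
#' the root term, \code{termDepth} the named vector of longest-path depths,
#' \code{termAncestors} the ancestor sets (all terms on any path to the
#' root, excluding the term itself), \code{termChildren} and
#' \code{termParents} the direct neighbours.
#'
#' @param graph an \code{OntologyGraph}.
#' @param terms optional character vector restricting the result.
#' @return see description.
#' @export
ontologyTerms <- function(graph) graph@terms

#' @rdname ontologyTerms
#' @export
ontologyRoot <- function(graph) graph@root

#' @rdname ontologyTerms
#' @export
termDepth <- function(graph, terms = NULL) {
  if (is.null(terms)) graph@depth else graph@depth[checkTerms(terms, graph)]
}

#' @rdname ontologyTerms
#' @export
termAncestors <- function(graph, terms = NULL) {
  if (is.null(terms)) return(graph@ancestors)
  graph@ancestors[checkTerms(terms, graph)]
}

#' @rdname ontologyTerms
#' @export
termChildren <- function(graph, terms) {
  res <- graph@children[checkTerms(terms, graph)]
  names(res) <- terms
  lapply(res, function(x) if (is.null(x)) character() else x)
}

#' @rdname ontologyTerms
#' @export
termParents <- function(graph, terms) {
  res <- graph@parents[checkTerms(terms, graph)]
  names(res) <- terms
  lapply(res, function(x) if (is.null(x)) character() else x)
}

checkTerms <- function(terms, graph) {
  terms <- as.character(terms)
  bad <- setdiff(terms, graph@terms)
  if (length(bad))
    stop("unknown term(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  terms
}

#' Ancestor table of an ontology
#'
#' Returns, for every term, its full ancestor set (every node on any
#' outgoing path to the root) and its depth, the number of edges on the
#' longest path to the root.  The root has an empty ancestor set and
#' depth 0.
#'
#' @param graph an \code{OntologyGraph}.
#' @return a list with components \code{ancestors} (named list of character
#'   vectors) and \code{depth} (named integer vector).
#' @export
ancestorTable <- function(graph) {
  list(ancestors = graph@ancestors, depth = graph@depth)
}

#' Propagate term scores toward the root by the maximum rule
#'
#' Extends a scored term set with all ancestors of its terms; every term
#' (ancestor or originally scored) receives the maximum score over all
#' scored terms in its descendant-or-self set.  Under this rule a parent
#' never scores below any of its scored children, and the operation is
#' idempotent.
#'
#' @param scores named numeric vector, term identifier to score.
#' @param graph an \code{OntologyGraph}.
#' @return named numeric vector over the input terms and all their
#'   ancestors.
#' @examples
#' g <- loadOntology(data.frame(child = c("b", "a"), parent = c("a", "r")))
#' propagateMax(c(b = 0.5), g)  # b, a and r all score 0.5
#' @export
propagateMax <- function(scores, graph) {
  if (!length(scores)) return(stats::setNames(numeric(), character()))
  terms <- checkTerms(names(scores), graph)
  touched <- lapply(terms, function(t) c(t, graph@ancestors[[t]]))
  val <- rep.int(as.numeric(scores), lengths(touched))
  key <- unlist(touched, use.names = FALSE)
  out <- tapply(val, key, max)
  stats::setNames(as.numeric(out), names(out))
}

#' Propagate raw term counts cumulatively and normalize
#'
#' Each term's cumulative count is its own raw count plus the raw counts of
#' all its \emph{distinct} descendants in the scored set -- a descendant
#' reachable along several paths contributes only once, so the root's
#' cumulative count equals the total raw count.  All values are then
#' divided by the maximum (attained at the root), yielding scores in
#' \eqn{(0, 1]}.
#'
#' @param counts named non-negative numeric vector of raw counts.
#' @param graph an \code{OntologyGraph}.
#' @return named numeric vector over the counted terms and all ancestors,
#'   normalized to \eqn{[0,1]} with value 1 at the root.
#' @export
propagateCumulative <- function(counts, graph) {
  if (!length(counts)) stop("cannot normalize an empty count set")
  terms <- checkTerms(names(counts), graph)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (all(counts == 0))
    stop("all counts are zero: normalization undefined")
  touched <- lapply(terms, function(t) c(t, graph@ancestors[[t]]))
  val <- rep.int(as.numeric(counts), lengths(touched))
  key <- unlist(touched, use.names = FALSE)
  res <- tapply(val, key, sum)
  stats::setNames(as.numeric(res) / max(res), names(res))
}

#' Leaf terms of a propagated term set
#'
#' A leaf term of a propagated set is a term that is not the parent of any
#' other term in the set: the most specific functional description present.
#'
#' @param x a character vector of terms, or a named numeric scored set (its
#'   names are used).
#' @param graph an \code{OntologyGraph}.
#' @return character vector of leaf terms (sorted).
#' @export
leafTerms <- function(x, graph) {
  terms <- if (is.character(x)) x else names(x)
  terms <- unique(checkTerms(terms, graph))
  isLeaf <- vapply(terms, function(t) {
    ch <- graph@children[[t]]
    is.null(ch) || !any(ch %in% terms)
  }, logical(1L))
  sort(terms[isLeaf])
}

#' Branch of a leaf term
#'
#' The branch of a term is its own propagation: the term together with all
#' of its ancestors up to (and including) the root.
#'
#' @param leaf a term identifier.
#' @param graph an \code{OntologyGraph}.
#' @return character vector (sorted).
#' @export
branchOf <- function(leaf, graph) {
  leaf <- checkTerms(leaf, graph)
  sort(unique(c(leaf, graph@ancestors[[leaf]])))
}

#' Overlap between two branches
#'
#' Number of common terms divided by the average branch size:
#' \eqn{|b_1 \cap b_2| / ((|b_1| + |b_2|)/2)}.  Symmetric, in
#' \eqn{[0, 1]}, and 1 exactly when the branches are identical.
#'
#' @param b1,b2 non-empty character vectors of terms.
#' @return a fraction in \eqn{[0, 1]}.
#' @export
branchOverlap <- function(b1, b2) {
  b1 <- unique(b1); b2 <- unique(b2)
  if (!length(b1) || !length(b2)) stop("branches must be non-empty")
  length(intersect(b1, b2)) / ((length(b1) + length(b2)) / 2)
}

#' Deepest common term of two branches
#'
#' The term shared by both branches with the longest path to the root
#' (the lowest common ancestor when the branches stem from two leaves).
#' Depth ties are broken lexicographically by term identifier for
#' reproducibility.
#'
#' @param b1,b2 character vectors of terms with non-empty intersection
#'   (branches always share at least the root).
#' @param graph an \code{OntologyGraph}.
#' @return a single term identifier.
#' @export
deepestCommonTerm <- function(b1, b2, graph) {
  common <- checkTerms(intersect(b1, b2), graph)
  if (!length(common)) stop("branches share no term")
  d <- graph@depth[common]
  cand <- sort(common[d == max(d)])
  cand[[1L]]
}

#' Strip the ontology root from a scored term set
#'
#' The root carries no information ("has a molecular function") and is
#' discarded in every evaluation and from every emitted prediction.
#'
#' @param scores named numeric vector or character vector of terms.
#' @param graph an \code{OntologyGraph}.
#' @return the input without the root entry.
#' @export
stripRoot <- function(scores, graph) {
  if (is.character(scores)) return(setdiff(scores, graph@root))
  scores[setdiff(names(scores), graph@root)]
}
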