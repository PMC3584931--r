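# Small in-code fixtures shared across the suite.

chainGraph <- function() {
  # r <- a <- b
  loadOntology(data.frame(child = c("b", "a"), parent = c("a", "r")))
}

diamondGraph <- function() {
  loadOntology(data.frame(child = c("a", "b", "c", "c"),
                          parent = c("r", "r", "a", "b")))
}

# the Figure-style toy instance shipped as extdata: an 11-term truth with
# 3 leaves and a 4-term prediction whose top tier holds 2 terms (1 true)
toyInstance <- function() {
  ext <- system.file("extdata", package = "GOmology")
  graph <- readOntologyTSV(file.path(ext, "toy_ontology.tsv"))
  list(graph = graph,
       truths = readTruth(file.path(ext, "toy_truth.tsv")),
       preds = readPredictions(file.path(ext, "toy_prediction.tsv")))
}

# random DAG with node 1 as root; node i > 1 attaches to 1-2 earlier nodes
randomDagEdges <- function(n, seed, twoParentProb = 0.4) {
  withr::with_seed(seed, {
    edges <- list()
    for (i in 2:n) {
      ps <- sample.int(i - 1L, 1L + (i > 2 && runif(1) < twoParentProb))
      for (p in ps)
        edges[[length(edges) + 1L]] <- c(sprintf("n%03d", i),
                                         sprintf("n%03d", p))
    }
    do.call(rbind, lapply(edges, function(e)
      data.frame(child = e[[1L]], parent = e[[2L]])))
  })
}

# independent transitive-closure oracle: recursive DFS over the edge list
bruteAncestors <- function(edges, term) {
  direct <- edges$parent[edges$child == term]
  out <- direct
  for (p in direct) out <- c(out, bruteAncestors(edges, p))
  sort(unique(out))
}

bruteDepth <- function(edges, term) {
  direct <- edges$parent[edges$child == term]
  if (!length(direct)) return(0L)
  1L + max(vapply(direct, function(p) bruteDepth(edges, p), integer(1L)))
}

makeHits <- function(query, subjects, evalues, pident = 90, ppos = 95,
                     len = 100) {
  n <- length(subjects)
  hitTable(query, data.frame(subject = subjects,
                             pident = rep_len(pident, n),
                             ppos = rep_len(ppos, n),
                             length = rep_len(len, n),
                             evalue = evalues,
                             bitscore = rep_len(50, n)))
}

# makeDB(list(P1 = c("b"), P2 = c("a", "b")))
makeDB <- function(annotations, evidence = "IDA", graph = NULL) {
  recs <- do.call(rbind, lapply(names(annotations), function(p)
    data.frame(protein = p, term = annotations[[p]],
               evidence = rep_len(evidence, length(annotations[[p]])))))
  annotationDB(recs, graph = graph)
}
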