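#' Configuration of the synthetic benchmark generator
#'
#' Collects every tunable of the generators in one validated list.  The
#' generators emulate a Swiss-Prot-like annotation database and
#' PSI-BLAST-like hit tables whose E-values correlate with annotation
#' overlap; see the package vignette for what is and is not emulated.
#'
#' @param seed mandatory integer RNG seed; every generator is fully
#'   deterministic given the seed.
#' @param nTerms approximate number of ontology terms (>= 2).
#' @param depth maximum depth of the generated DAG.
#' @param branching mean number of children per internal node.
#' @param diamondRate probability that a non-root term receives a second
#'   parent (0 produces a tree).
#' @param nProteins number of proteins in the annotation database.
#' @param maxLeavesPerProtein each protein is annotated with 1..k ontology
#'   leaves.
#' @param evidenceMix named probability vector over evidence codes.
#' @param hitsPerTarget number of hits generated per target query.
#' @param evalueLogRange range of log10 E-values (best, worst).
#' @param fidelity probability that a hit is drawn from the templates
#'   most similar to the target (1 = only best-matching templates, 0 =
#'   uniform draws).
#' @param identityNoiseSd standard deviation of the Gaussian noise on
#'   percent positives.
#' @param targetFraction fraction of proteins withheld as targets.
#' @param cloneCount number of template proteins forced to share each
#'   target's annotation, so that faithful hits exist at high fidelity.
#' @return a validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(seed,
                      nTerms = 60L, depth = 5L, branching = 3L,
                      diamondRate = 0.15,
                      nProteins = 100L, maxLeavesPerProtein = 3L,
                      evidenceMix = c(IDA = 0.3, IMP = 0.2, TAS = 0.1,
                                      IEA = 0.4),
                      hitsPerTarget = 10L,
                      evalueLogRange = c(-50, -1),
                      fidelity = 1.0, identityNoiseSd = 0,
                      targetFraction = 0.2, cloneCount = NULL) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(nTerms >= 2, depth >= 1, branching >= 1,
            diamondRate >= 0, diamondRate <= 1,
            nProteins >= 2, maxLeavesPerProtein >= 1,
            all(evidenceMix >= 0), sum(evidenceMix) > 0,
            hitsPerTarget >= 1, length(evalueLogRange) == 2L,
            fidelity >= 0, fidelity <= 1, identityNoiseSd >= 0,
            targetFraction > 0, targetFraction < 1)
  if (is.null(cloneCount)) cloneCount <- 2L
  cfg <- list(seed = as.integer(seed), nTerms = as.integer(nTerms),
              depth = as.integer(depth), branching = as.integer(branching),
              diamondRate = diamondRate, nProteins = as.integer(nProteins),
              maxLeavesPerProtein = as.integer(maxLeavesPerProtein),
              evidenceMix = evidenceMix / sum(evidenceMix),
              hitsPerTarget = as.integer(hitsPerTarget),
              evalueLogRange = sort(as.numeric(evalueLogRange)),
              fidelity = fidelity, identityNoiseSd = identityNoiseSd,
              targetFraction = targetFraction,
              cloneCount = as.integer(cloneCount))
  class(cfg) <- "SimConfig"
  cfg
}

#' Generate a random single-rooted ontology DAG
#'
#' Builds a layered DAG: the root sits at depth 0 and each of roughly
#' \code{nTerms} further terms attaches to one uniformly drawn term of the
#' previous layer; with probability \code{diamondRate} a term receives a
#' second parent from any shallower layer (multiple inheritance).  Every
#' term reaches the root and the graph is deterministic under the seed.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return an \code{OntologyGraph}.
#' @export
genOntology <- function(cfg) {
  withSeed(cfg$seed, {
    root <- "T0000"
    layers <- list(root)
    edges <- list()
    made <- 1L
    perLayer <- max(1L, ceiling((cfg$nTerms - 1L) / cfg$depth))
    for (d in seq_len(cfg$depth)) {
      prev <- layers[[d]]
      n_new <- min(perLayer, cfg$nTerms - made)
      if (n_new <= 0L) break
      ids <- sprintf("T%04d", seq.int(made, made + n_new - 1L))
      made <- made + n_new
      for (i in seq_along(ids)) {
        p <- prev[[sample.int(length(prev), 1L)]]
        edges[[length(edges) + 1L]] <- c(ids[[i]], p, "is_a")
        shallower <- setdiff(unlist(layers[seq_len(d)]), p)
        if (length(shallower) && stats::runif(1L) < cfg$diamondRate) {
          p2 <- shallower[[sample.int(length(shallower), 1L)]]
          edges[[length(edges) + 1L]] <- c(ids[[i]], p2, "part_of")
        }
      }
      layers[[d + 1L]] <- ids
    }
    loadOntology(edges, namespace = "MFO")
  })
}

# leaves of the full ontology (terms without any child)
ontologyLeaves <- function(graph) {
  sort(graph@terms[!graph@terms %in% graph@edges$parent])
}

#' Generate a synthetic annotation database
#'
#' Annotates each of \code{nProteins} proteins with 1 to
#' \code{maxLeavesPerProtein} ontology leaves drawn uniformly; each
#' annotation record receives an evidence code drawn from the configured
#' mix.
#'
#' @param graph an \code{OntologyGraph}.
#' @param cfg a \code{\link{simConfig}}.
#' @return an \code{AnnotationDB}.
#' @export
genAnnotationDB <- function(graph, cfg) {
  leaves <- ontologyLeaves(graph)
  codes <- names(cfg$evidenceMix)
  withSeed(cfg$seed + 1L, {
    recs <- lapply(seq_len(cfg$nProteins), function(i) {
      k <- sample.int(cfg$maxLeavesPerProtein, 1L)
      terms <- leaves[sample.int(length(leaves), min(k, length(leaves)))]
      data.frame(protein = sprintf("P%05d", i), term = terms,
                 evidence = codes[sample.int(length(codes), length(terms),
                                             replace = TRUE,
                                             prob = cfg$evidenceMix)])
    })
    annotationDB(do.call(rbind, recs), graph = graph)
  })
}

#' Generate a homology hit table correlated with a target's annotation
#'
#' Draws \code{hitsPerTarget} subjects from the database.  With
#' probability \code{fidelity} a subject is drawn among the templates
#' whose propagated annotation overlaps the target truth best (Jaccard
#' index); otherwise uniformly.  E-values are log-uniform in
#' \code{evalueLogRange}, shifted so that higher-overlap subjects get
#' smaller E-values; percent positives rises with overlap plus Gaussian
#' noise (clipped to [0, 100]), and percent identity is at most the
#' percent positives.
#'
#' @param target accession of the query.
#' @param targetTruth character vector: the target's propagated true term
#'   set.
#' @param db an \code{AnnotationDB} of candidate subjects (templates).
#' @param graph an \code{OntologyGraph}.
#' @param cfg a \code{\link{simConfig}}.
#' @param seedOffset added to \code{cfg$seed} so each target gets its own
#'   stream.
#' @return a \code{HitTable}.
#' @export
genHitTable <- function(target, targetTruth, db, graph, cfg,
                        seedOffset = 0L) {
  prots <- annotatedProteins(db)
  if (!length(prots)) stop("annotation database is empty")
  ann <- lapply(prots, function(p)
    stripRoot(proteinAnnotation(db, p, graph), graph))
  targetTruth <- stripRoot(targetTruth, graph)
  jac <- vapply(ann, function(a)
    length(intersect(a, targetTruth)) / length(union(a, targetTruth)),
    numeric(1L))
  best <- which(jac == max(jac))
  withSeed(cfg$seed + 7L * seedOffset + 13L, {
    n <- cfg$hitsPerTarget
    faithful <- stats::runif(n) < cfg$fidelity
    idx <- ifelse(faithful,
                  best[sample.int(length(best), n, replace = TRUE)],
                  sample.int(length(prots), n, replace = TRUE))
    overlap <- jac[idx]
    lo <- cfg$evalueLogRange[[1L]]; hi <- cfg$evalueLogRange[[2L]]
    log10e <- lo + (hi - lo) * (1 - overlap) * stats::runif(n)
    ppos <- 50 + 50 * overlap + stats::rnorm(n, 0, cfg$identityNoiseSd)
    ppos <- pmin(pmax(ppos, 0), 100)
    pident <- pmin(pmax(ppos - abs(stats::rnorm(n, 2, cfg$identityNoiseSd)),
                        0), ppos)
    hitTable(target,
             data.frame(subject = prots[idx], pident = pident, ppos = ppos,
                        length = 100L + seq_len(n), evalue = 10 ^ log10e,
                        bitscore = pmax(30, -10 * log10e / 2)))
  })
}

#' Generate a complete synthetic benchmark
#'
#' Splits the generated proteins into disjoint template and target sets
#' (the targets' annotations are withheld from the template database,
#' emulating a temporal template/target split), forces
#' \code{cloneCount} templates to share each target's annotation so that
#' faithful homologs exist, and generates one hit table per target for
#' each of the three iteration settings (later iterations probe a wider
#' E-value range, emulating additional search rounds).
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with components \code{graph}, \code{db} (templates only),
#'   \code{targets}, \code{truths} (propagated, root stripped),
#'   \code{hitsByIteration} (list "1"/"2"/"3" of named \code{HitTable}
#'   lists) and \code{cfg}.
#' @export
genBenchmark <- function(cfg) {
  graph <- genOntology(cfg)
  full <- genAnnotationDB(graph, cfg)
  prots <- annotatedProteins(full)
  nTargets <- max(1L, round(cfg$targetFraction * length(prots)))
  targets <- withSeed(cfg$seed + 2L, sample(prots, nTargets))
  templates <- setdiff(prots, targets)
  if (!length(templates)) stop("no template proteins left")

  rec <- annotationRecords(full)
  truths <- stats::setNames(lapply(targets, function(tg)
    stripRoot(proteinAnnotation(full, tg, graph), graph)), targets)

  # clone each target's direct annotation onto a few templates so that
  # perfectly faithful homologs exist
  tmplRec <- rec[rec$protein %in% templates, , drop = FALSE]
  cloneRecs <- list()
  if (cfg$cloneCount > 0L) {
    # disjoint host blocks per target, so every clone is exact: its own
    # annotation is replaced by one target's direct annotation
    cc <- max(1L, min(cfg$cloneCount,
                      floor(length(templates) / length(targets))))
    pool <- withSeed(cfg$seed + 3L, sample(templates))
    hosts <- split(pool[seq_len(cc * length(targets))],
                   rep(seq_along(targets), each = cc))
    for (i in seq_along(targets)) {
      direct <- rec[rec$protein == targets[[i]], , drop = FALSE]
      for (h in hosts[[i]]) {
        cl <- direct
        cl$protein <- h
        cloneRecs[[length(cloneRecs) + 1L]] <- cl
      }
    }
    tmplRec <- tmplRec[!tmplRec$protein %in% unlist(hosts), , drop = FALSE]
  }
  db <- annotationDB(rbind(tmplRec, do.call(rbind, cloneRecs)),
                     graph = graph)

  ranges <- list(`1` = cfg$evalueLogRange,
                 `2` = cfg$evalueLogRange + c(0, 1),
                 `3` = cfg$evalueLogRange + c(0, 2))
  hitsByIteration <- lapply(ranges, function(rg) {
    cfg2 <- cfg; cfg2$evalueLogRange <- rg
    res <- lapply(seq_along(targets), function(i)
      genHitTable(targets[[i]], truths[[i]], db, graph, cfg2,
                  seedOffset = i))
    stats::setNames(res, targets)
  })
  list(graph = graph, db = db, targets = targets, truths = truths,
       hitsByIteration = hitsByIteration, cfg = cfg)
}

#' Write a generated benchmark to a directory
#'
#' Writes \code{ontology.tsv}, \code{annotations.tsv}, \code{truth.tsv},
#' \code{hits_iter1.tsv} .. \code{hits_iter3.tsv} and \code{config.txt}
#' (provenance echo) in the package's standard plain-text formats.
#'
#' @param bench result of \code{\link{genBenchmark}}.
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
writeBenchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  e <- bench$graph@edges
  writeLines(c("child_id\tparent_id\trelation",
               sprintf("%s\t%s\t%s", e$child, e$parent, e$relation)),
             file.path(dir, "ontology.tsv"))
  writeAnnotations(bench$db, file.path(dir, "annotations.tsv"))
  writeTruth(bench$truths, file.path(dir, "truth.tsv"))
  for (it in names(bench$hitsByIteration))
    writeHits(bench$hitsByIteration[[it]],
              file.path(dir, paste0("hits_iter", it, ".tsv")))
  cfg <- bench$cfg
  writeLines(sprintf("%s\t%s", names(cfg),
                     vapply(cfg, function(x)
                       paste(format(x), collapse = ","), character(1L))),
             file.path(dir, "config.txt"))
  invisible(dir)
}
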