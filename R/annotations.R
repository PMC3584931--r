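#' GO evidence codes regarded as experimental
#'
#' The eight codes used to restrict annotation databases to experimentally
#' supported annotations: IDA, IMP, IPI, IGI, IEP, TAS, IC and EXP.
#'
#' @return character vector of evidence codes.
#' @export
experimentalEvidenceCodes <- function() {
  c("IDA", "IMP", "IPI", "IGI", "IEP", "TAS", "IC", "EXP")
}

#' Create an annotation database
#'
#' @param records data.frame with columns \code{protein}, \code{term},
#'   \code{evidence}.  Duplicate (protein, term) pairs are collapsed,
#'   keeping the first record.
#' @param graph optional \code{OntologyGraph} used to check terms.
#' @param strict if \code{TRUE}, a record whose term is missing from
#'   \code{graph} is an error; otherwise such records are dropped with a
#'   warning.
#' @return an \code{AnnotationDB}.
#' @export
annotationDB <- function(records, graph = NULL, strict = FALSE) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!all(c("protein", "term", "evidence") %in% names(records)))
    stop("records must have columns protein, term, evidence")
  records <- records[, c("protein", "term", "evidence")]
  records[] <- lapply(records, as.character)
  records <- records[!duplicated(records[, c("protein", "term")]), ,
                     drop = FALSE]
  if (!is.null(graph)) {
    unknown <- setdiff(records$term, graph@terms)
    if (length(unknown)) {
      if (strict)
        stop("annotation term(s) absent from the ontology: ",
             paste(utils::head(unknown, 5L), collapse = ", "))
      warning(length(unknown), " annotation term(s) absent from the ",
              "ontology were dropped")
      records <- records[records$term %in% graph@terms, , drop = FALSE]
    }
  }
  rownames(records) <- NULL
  new("AnnotationDB", records = records)
}

#' Read an annotation database from a GAF-like TSV
#'
#' Expects at least three columns: protein accession, term identifier and
#' evidence code.  Lines starting with \code{#} are ignored.
#'
#' @param path path to the TSV file.
#' @inheritParams annotationDB
#' @return an \code{AnnotationDB}.
#' @export
readAnnotations <- function(path, graph = NULL, strict = FALSE) {
  d <- readTsvFlexible(path, c("protein", "term", "evidence"))
  if (nrow(d) == 0L) stop("annotation file is empty: ", path)
  annotationDB(d, graph = graph, strict = strict)
}

#' @rdname readAnnotations
#' @param db an \code{AnnotationDB} to write.
#' @export
writeAnnotations <- function(db, path) {
  writeLines(c("protein\tterm\tevidence",
               sprintf("%s\t%s\t%s", db@records$protein, db@records$term,
                       db@records$evidence)), path)
  invisible(path)
}

#' Accessors for annotation databases
#'
#' \code{annotationRecords} returns the record table;
#' \code{annotatedProteins} the distinct protein accessions;
#' \code{proteinTerms} the set of directly annotated terms of one protein
#' (empty if unknown); \code{proteinAnnotation} its propagated annotation.
#'
#' @param db an \code{AnnotationDB}.
#' @param protein a protein accession.
#' @param graph an \code{OntologyGraph}.
#' @return see description.
#' @export
annotationRecords <- function(db) db@records

#' @rdname annotationRecords
#' @export
annotatedProteins <- function(db) unique(db@records$protein)

#' @rdname annotationRecords
#' @export
proteinTerms <- function(db, protein) {
  unique(db@records$term[db@records$protein == protein])
}

#' @rdname annotationRecords
#' @export
proteinAnnotation <- function(db, protein, graph) {
  direct <- proteinTerms(db, protein)
  if (!length(direct)) return(character())
  sort(unique(c(direct, unlist(graph@ancestors[checkTerms(direct, graph)],
                               use.names = FALSE))))
}

#' Restrict an annotation database to experimental evidence
#'
#' Keeps only the records whose evidence code belongs to \code{codes}.
#'
#' @param db an \code{AnnotationDB}.
#' @param codes evidence codes to keep; defaults to
#'   \code{\link{experimentalEvidenceCodes}}.
#' @return a filtered \code{AnnotationDB} (possibly empty).
#' @export
filterExperimental <- function(db, codes = experimentalEvidenceCodes()) {
  if (!length(codes)) stop("codes must be non-empty")
  new("AnnotationDB",
      records = db@records[db@records$evidence %in% codes, , drop = FALSE])
}

#' Term frequencies over a protein database
#'
#' The frequency of a term is the fraction of database proteins whose
#' \emph{propagated} annotation contains it (document frequency, not record
#' frequency).  Frequencies are monotone non-decreasing toward the root,
#' which always has frequency 1.
#'
#' @param db a non-empty \code{AnnotationDB}.
#' @param graph an \code{OntologyGraph}.
#' @return named numeric vector of frequencies in \eqn{(0, 1]}.
#' @export
termFrequencies <- function(db, graph) {
  prots <- annotatedProteins(db)
  if (!length(prots)) stop("annotation database is empty")
  counts <- table(unlist(lapply(prots, function(p)
    proteinAnnotation(db, p, graph)), use.names = FALSE))
  stats::setNames(as.numeric(counts) / length(prots), names(counts))
}
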