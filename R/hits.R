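#' Create a homology hit table for one query
#'
#' @param query query accession.
#' @param hits data.frame with columns \code{subject}, \code{pident},
#'   \code{ppos}, \code{length}, \code{evalue}, \code{bitscore}.  Rows are
#'   sorted by ascending E-value; ties keep their input order.
#' @return a \code{HitTable}.
#' @export
hitTable <- function(query, hits) {
  hits <- as.data.frame(hits, stringsAsFactors = FALSE)
  need <- c("subject", "pident", "ppos", "length", "evalue", "bitscore")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    stop("hit table misses column(s): ", paste(miss, collapse = ", "))
  hits <- hits[, need]
  hits$subject <- as.character(hits$subject)
  for (cn in need[-1L]) hits[[cn]] <- as.numeric(hits[[cn]])
  hits <- hits[order(hits$evalue), , drop = FALSE]  # stable sort
  rownames(hits) <- NULL
  new("HitTable", query = as.character(query), hits = hits)
}

#' Read BLAST-tabular homology hit files
#'
#' Expects the tabular format
#' \code{qseqid sseqid pident ppos length evalue bitscore} (one row per
#' hit, tab-separated, comment lines starting with \code{#} ignored) and
#' returns one \code{HitTable} per query, each sorted by ascending
#' E-value.
#'
#' @param path path to the TSV file.
#' @return a named list of \code{HitTable} objects, keyed by query
#'   accession (empty list for an empty file).
#' @export
readHits <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "ppos", "length", "evalue",
            "bitscore")
  d <- readTsvFlexible(path, cols)
  if (nrow(d) == 0L) return(stats::setNames(list(), character()))
  for (cn in cols[3:7]) d[[cn]] <- asNumericStrict(d[[cn]], cn, path)
  split_d <- split(d, d$qseqid)
  res <- lapply(split_d, function(q)
    hitTable(q$qseqid[[1L]],
             data.frame(subject = q$sseqid, pident = q$pident, ppos = q$ppos,
                        length = q$length, evalue = q$evalue,
                        bitscore = q$bitscore)))
  res[unique(d$qseqid)]
}

#' @rdname readHits
#' @param tables a list of \code{HitTable} objects to write.
#' @export
writeHits <- function(tables, path) {
  rows <- unlist(lapply(tables, function(tb) {
    h <- tb@hits
    if (!nrow(h)) return(character())
    sprintf("%s\t%s\t%.2f\t%.2f\t%d\t%.3g\t%.1f", tb@query, h$subject,
            h$pident, h$ppos, as.integer(h$length), h$evalue, h$bitscore)
  }), use.names = FALSE)
  writeLines(c("#qseqid\tsseqid\tpident\tppos\tlength\tevalue\tbitscore",
               rows), path)
  invisible(path)
}

#' Accessors for hit tables
#'
#' @param x a \code{HitTable}.
#' @return \code{hitQuery}: the query accession; \code{hitRecords}: the
#'   data.frame of hits.
#' @export
hitQuery <- function(x) x@query

#' @rdname hitQuery
#' @export
hitRecords <- function(x) x@hits

#' Filter a hit table by E-value, self-hits and hit count
#'
#' Applies, in order: the E-value cutoff (strict: \code{evalue <
#' maxEvalue}), removal of the self-hit (subject equal to the query) when
#' \code{excludeSelf}, and truncation to the first \code{maxHits} hits
#' (the table is sorted by ascending E-value, so these are the best hits).
#' Idempotent for fixed parameters.
#'
#' @param table a \code{HitTable}.
#' @param maxEvalue strict upper bound on the E-value (> 0).
#' @param maxHits maximum number of hits kept (\code{Inf} = unlimited).
#' @param excludeSelf drop hits whose subject equals the query (default
#'   \code{TRUE}: in benchmarking a target must not inherit its own
#'   annotation).
#' @return a filtered \code{HitTable}.
#' @export
filterHits <- function(table, maxEvalue = 0.1, maxHits = Inf,
                       excludeSelf = TRUE) {
  stopifnot(maxEvalue > 0, maxHits >= 1)
  h <- table@hits
  h <- h[h$evalue < maxEvalue, , drop = FALSE]
  if (excludeSelf) h <- h[h$subject != table@query, , drop = FALSE]
  if (nrow(h) > maxHits) h <- h[seq_len(maxHits), , drop = FALSE]
  rownames(h) <- NULL
  new("HitTable", query = table@query, hits = h)
}
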