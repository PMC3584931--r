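# Shared file-format helpers.  All tabular readers tolerate comment lines
# starting with '#' and an optional header row matching the expected names.

readTsvFlexible <- function(path, col_names, min_cols = length(col_names)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (!length(lines)) {
    d <- as.data.frame(setNames(rep(list(character()), length(col_names)),
                                col_names))
    return(d)
  }
  first <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (tolower(first[[1L]]) %in% tolower(c(col_names[[1L]], "target", "protein",
                                          "child_id", "qseqid")))
    lines <- lines[-1L]
  if (!length(lines)) stop("file has a header but no data rows: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < min_cols))
    stop("malformed row(s) in ", path, ": expected >= ", min_cols,
         " tab-separated columns")
  n <- min(c(ncols, length(col_names)))
  d <- as.data.frame(lapply(seq_len(n), function(i)
    vapply(parts, `[[`, character(1L), i)))
  names(d) <- col_names[seq_len(n)]
  d
}

asNumericStrict <- function(x, what, path) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v))
    stop("malformed numeric field '", what, "' in ", path)
  v
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(old <- globalenv()$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# floor exact-zero E-values, then clamp below 1 so ln(E) is strictly
# negative everywhere it is used
clampEvalue <- function(e) {
  pmin(pmax(e, 1e-180), 0.999)
}
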