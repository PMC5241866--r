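# shared internal helpers

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## state. All simulators funnel through this so they are pure functions of
## (parameters, seed).
withSeed <- function(seed, expr) {
  if (is.null(seed) || !is.finite(seed))
    .stopf("a finite integer seed is required")
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

## Floats in text outputs carry 6 significant digits.
.fmtNum <- function(x) {
  out <- formatC(x, digits = 6, format = "g")
  out[is.na(x)] <- "NA"
  out[is.infinite(x) & x > 0] <- "Inf"
  out[is.infinite(x) & x < 0] <- "-Inf"
  out
}

## Read a whitespace-delimited text file as a list of tokenized lines,
## keeping original line numbers for error reporting. Comment/track lines
## and blank lines are skipped.
.tokenizeLines <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  lines <- readLines(path)
  trimmed <- trimws(lines)
  keep <- nzchar(trimmed) & !startsWith(trimmed, "#") &
    !startsWith(trimmed, "track") & !startsWith(trimmed, "browser")
  list(fields = strsplit(trimmed[keep], "[ \t]+"), lineno = which(keep))
}

.asNum <- function(x, what, lineno) {
  out <- suppressWarnings(as.numeric(x))
  if (any(is.na(out)))
    .stopf("line %d: cannot parse %s from '%s'", lineno, what,
           paste(x[is.na(out)], collapse = ","))
  out
}

## numeric matrix <-> TSV with a header row of sample/tissue names and a
## transcript_id first column (the external interface for counts, RPKM and
## tissue matrices)
readTsvMatrix <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "")
  if (ncol(tab) < 2L) .stopf("%s: expected transcript_id plus >=1 column", path)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- as.character(tab[[1L]])
  storage.mode(m) <- "double"
  m
}

writeTsvMatrix <- function(m, path, idColumn = "transcript_id",
                           floats = FALSE) {
  m <- as.matrix(m)
  body <- if (floats) apply(m, 2L, .fmtNum) else
    apply(m, 2L, function(x) format(x, trim = TRUE, scientific = FALSE))
  if (is.null(dim(body))) body <- matrix(body, nrow = nrow(m))
  lines <- c(paste(c(idColumn, colnames(m)), collapse = "\t"),
             paste(rownames(m), apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
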