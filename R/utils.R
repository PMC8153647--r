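# internal helpers shared across modules

# reverse complement of plain character vectors (DNA alphabet, N preserved);
# byte-level reversal keeps this cheap enough for per-read use
rc <- function(x) {
  if (!length(x)) return(character(0))
  x <- chartr("ACGTacgtn", "TGCATGCAN", x)
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# run code under a fixed RNG state, restoring the caller's stream afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_int <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

# uniform TSV writer with a versioned header comment; the matching reader
# skips comment lines so stage outputs can be re-ingested
write_tsv_versioned <- function(df, path, what, params = NULL) {
  hdr <- sprintf("# circat %s; %s%s", as.character(packageVersion("circat")), what,
                 if (is.null(params)) "" else paste0("; ", params))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

read_tsv_versioned <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE)
}
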