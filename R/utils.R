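DNA_BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement DNA sequences
#'
#' Vectorised reverse complement over character strings in the `ACGT`
#' alphabet (case is preserved for lower-case input letters).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCAtgca", s))))
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

## evaluate `code` with a temporary RNG state when `seed` is given,
## restoring the caller's stream afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stopifnot_dna <- function(x, what = "sequence") {
  if (!is_string(x) || nchar(x) == 0L)
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  if (grepl("[^ACGT]", x))
    stop(what, " contains letters outside the ACGT alphabet", call. = FALSE)
  invisible(x)
}

empty_calls <- function() {
  data.frame(read_id = character(), concatemer_index = integer(),
             type = character(), template_pos = integer(),
             ref = character(), alt = character(), length = integer(),
             stringsAsFactors = FALSE)
}

## minimal TSV conventions: headered, tab-separated, '.' for missing
write_tsv0 <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

read_tsv0 <- function(path, ...) {
  read.delim(path, sep = "\t", na.strings = ".",
             stringsAsFactors = FALSE, ...)
}
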