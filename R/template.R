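#' Generate a circular DNA template sequence
#'
#' Draws a random sense-strand DNA sequence of the requested length and GC
#' content and, optionally, overwrites evenly spaced stretches with
#' homopolymer runs. Homopolymer tracts matter because polymerase slippage
#' concentrates insertion/deletion errors inside them, so a realistic
#' template needs a few.
#'
#' @param length template length in bases (at least 100).
#' @param gc target GC fraction in `[0, 1]`.
#' @param homopolymer_spec optional `data.frame` with columns `base`,
#'   `length` and `count` (one row per requested run type), or a list of
#'   `list(base =, length =, count =)` entries.
#' @param seed optional integer seed; the template is byte-identical for a
#'   fixed seed.
#' @return A character scalar with attribute `homopolymers`, a `data.frame`
#'   of the placed runs (`base`, `start`, `length`).
#' @export
#' @examples
#' tpl <- make_template(200, homopolymer_spec = data.frame(
#'   base = "A", length = 6, count = 1), seed = 1)
#' attr(tpl, "homopolymers")
make_template <- function(length, gc = 0.5, homopolymer_spec = NULL,
                          seed = NULL) {
  length <- as.integer(length)
  if (length < 100L) stop("template length must be at least 100")
  if (gc < 0 || gc > 1) stop("gc must be in [0, 1]")
  spec <- normalize_hp_spec(homopolymer_spec)
  n_runs <- sum(spec$count)
  if (n_runs > 0 && sum(rep(spec$length, spec$count)) + n_runs > length)
    stop("requested homopolymer runs do not fit in the template length")
  with_seed(seed, {
    probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    bases <- sample(DNA_BASES, length, replace = TRUE, prob = probs)
    placed <- data.frame(base = character(), start = integer(),
                         length = integer(), stringsAsFactors = FALSE)
    if (n_runs > 0) {
      runs <- spec[rep(seq_len(nrow(spec)), spec$count), , drop = FALSE]
      anchors <- floor(length * seq_len(n_runs) / (n_runs + 1))
      for (i in seq_len(n_runs)) {
        s <- anchors[i]
        e <- s + runs$length[i] - 1L
        if (e > length)
          stop("requested homopolymer runs do not fit in the template length")
        bases[s:e] <- runs$base[i]
        ## break up accidental extension on the 5' side so the recorded
        ## start is the true run start
        if (s > 1L && bases[s - 1L] == runs$base[i])
          bases[s - 1L] <- sample(setdiff(DNA_BASES, runs$base[i]), 1L)
        if (e < length && bases[e + 1L] == runs$base[i])
          bases[e + 1L] <- sample(setdiff(DNA_BASES, runs$base[i]), 1L)
        placed <- rbind(placed, data.frame(base = runs$base[i], start = s,
                                           length = runs$length[i],
                                           stringsAsFactors = FALSE))
      }
    }
    tpl <- paste(bases, collapse = "")
    attr(tpl, "homopolymers") <- placed
    tpl
  })
}

normalize_hp_spec <- function(spec) {
  if (is.null(spec))
    return(data.frame(base = character(), length = integer(),
                      count = integer(), stringsAsFactors = FALSE))
  if (is.list(spec) && !is.data.frame(spec))
    spec <- do.call(rbind, lapply(spec, function(e)
      data.frame(base = e$base %||% e[[1]],
                 length = as.integer(e$length %||% e[[2]]),
                 count = as.integer(e$count %||% e[[3]] %||% 1L),
                 stringsAsFactors = FALSE)))
  spec$base <- as.character(spec$base)
  spec$length <- as.integer(spec$length)
  spec$count <- as.integer(spec$count)
  if (!all(spec$base %in% DNA_BASES))
    stop("homopolymer bases must be one of A, C, G, T")
  if (any(spec$length < 2L) || any(spec$count < 1L))
    stop("homopolymer runs need length >= 2 and count >= 1")
  spec
}

#' Rotate a circular template
#'
#' Returns `template[offset + 1 .. L]` followed by `template[1 .. offset]`:
#' the sequence read around the circle starting at 0-based position
#' `offset`. Rotation by 0 is the identity and rotations compose modulo the
#' template length; offsets outside `[0, L)` are an error (reduce modulo `L`
#' before calling).
#'
#' @param template character scalar (sense strand).
#' @param offset 0-based start position, `0 <= offset < nchar(template)`.
#' @return rotated character scalar.
#' @export
rotate_template <- function(template, offset) {
  template <- as.character(template)
  L <- nchar(template)
  offset <- as.integer(offset)
  if (length(offset) != 1L || is.na(offset) || offset < 0L || offset >= L)
    stop("offset must satisfy 0 <= offset < template length")
  if (offset == 0L) return(template)
  paste0(substr(template, offset + 1L, L), substr(template, 1L, offset))
}

#' Locate homopolymer tracts in a template
#'
#' @param template character scalar.
#' @param min_len minimum run length to report (default 3).
#' @return `data.frame` with columns `base`, `start`, `length`.
#' @export
homopolymer_runs <- function(template, min_len = 3L) {
  template <- as.character(template)
  r <- rle(seq_chars(template))
  start <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  keep <- r$lengths >= min_len
  data.frame(base = r$values[keep], start = start[keep],
             length = r$lengths[keep], stringsAsFactors = FALSE)
}

## TRUE when the (circular) template contains duplicated k-mers, which can
## make anchor placement ambiguous during segmentation
template_has_repeats <- function(template, k) {
  template <- as.character(template)
  L <- nchar(template)
  if (L <= k) return(FALSE)
  dbl <- paste0(template, template)
  kmers <- substring(dbl, seq_len(L), seq_len(L) + k - 1L)
  anyDuplicated(kmers) > 0L
}
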