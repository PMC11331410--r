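#' Group identical variant calls across the concatemers of one read
#'
#' Calls sharing an identical variant key (type, template position, ref,
#' alt) within one read are merged into one position group recording which
#' concatemers support it. Distinct alternative alleles at one position
#' form distinct groups.
#'
#' @param calls normalized calls for a single read (columns
#'   `concatemer_index`, `type`, `template_pos`, `ref`, `alt`, `length`).
#' @param n_concatemers number of concatemers in the read.
#' @return `data.frame` with the key columns plus `support` (number of
#'   supporting concatemers), `supporting` (comma-separated indices) and
#'   `n_concatemers`.
#' @export
group_calls <- function(calls, n_concatemers) {
  n_concatemers <- as.integer(n_concatemers)
  if (!nrow(calls)) {
    out <- data.frame(type = character(), template_pos = integer(),
                      ref = character(), alt = character(),
                      length = integer(), support = integer(),
                      supporting = character(), n_concatemers = integer(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  key <- paste(calls$type, calls$template_pos, calls$ref, calls$alt,
               sep = "\r")
  if (anyDuplicated(paste(key, calls$concatemer_index, sep = "\r")))
    stop("duplicate (concatemer, variant) call; caller bug upstream")
  sp <- split(seq_len(nrow(calls)), key)
  out <- do.call(rbind, lapply(sp, function(ix) {
    first <- ix[1]
    data.frame(type = calls$type[first],
               template_pos = calls$template_pos[first],
               ref = calls$ref[first], alt = calls$alt[first],
               length = calls$length[first],
               support = length(ix),
               supporting = paste(sort(calls$concatemer_index[ix]),
                                  collapse = ","),
               n_concatemers = n_concatemers,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$template_pos, out$type, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## the origin rule: present in every concatemer -> RNA polymerase;
## present in exactly one -> reverse transcriptase; anything in between
## is not identifiable and is set aside
classify_origin <- function(support, n_concatemers) {
  ifelse(support == n_concatemers, "RNAP",
         ifelse(support == 1L, "RT", "AMBIGUOUS"))
}

#' Attribute grouped variants to polymerase or reverse transcriptase
#'
#' Applies the origin rule across all eligible reads: a variant present in
#' every concatemer of its read was already in the RNA molecule and is an
#' RNA-polymerase error; a variant private to a single concatemer arose
#' during one reverse-transcription pass. Variants supported by more than
#' one but fewer than all concatemers are labelled `AMBIGUOUS` and
#' excluded from both rate numerators.
#'
#' @param calls normalized calls across reads (columns `read_id`,
#'   `concatemer_index`, `type`, `template_pos`, `ref`, `alt`, `length`).
#' @param segments segments of the same (eligible) reads, used for the
#'   per-read concatemer counts.
#' @return `data.frame` of attributed variants: key columns plus
#'   `support`, `supporting`, `n_concatemers`, `origin`.
#' @export
attribute_variants <- function(calls, segments) {
  nseg <- table(segments$read_id)
  empty <- data.frame(read_id = character(), type = character(),
                      template_pos = integer(), ref = character(),
                      alt = character(), length = integer(),
                      support = integer(), supporting = character(),
                      n_concatemers = integer(), origin = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(calls)) return(empty)
  pieces <- lapply(split(calls, calls$read_id), function(cc) {
    rid <- cc$read_id[1]
    g <- group_calls(cc, nseg[[rid]])
    if (!nrow(g)) return(NULL)
    data.frame(read_id = rid, g, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) return(empty)
  out$origin <- classify_origin(out$support, out$n_concatemers)
  rownames(out) <- NULL
  out
}

#' Tabulate attributed variants into counts and denominators
#'
#' Counts attributed variants by origin and type (one indel event of any
#' length counts once by default) and derives the rate denominators: the
#' reverse transcriptase synthesised every concatemer base
#' (`n_segments x L`), while each eligible read represents exactly one RNA
#' molecule regardless of its concatemer count, so the polymerase
#' denominator is `n_reads x L`. Ambiguous variants are tallied separately
#' and enter neither denominator's numerator.
#'
#' @param attributed output of [attribute_variants()].
#' @param segments segments of the eligible reads.
#' @param template_length template length in bases.
#' @param n_reads number of eligible reads; defaults to the number of
#'   distinct `read_id`s in `segments`.
#' @param per_base count each indel base rather than each indel event.
#' @return object of class `rollseq_tabulation`: a list with `counts`
#'   (origin x type matrix including `AMBIGUOUS`), `denominators`
#'   (named: `RNAP`, `RT`), `n_reads`, `n_segments`, `template_length`.
#' @export
tabulate_variants <- function(attributed, segments, template_length,
                              n_reads = NULL, per_base = FALSE) {
  template_length <- as.integer(template_length)
  n_reads <- as.integer(n_reads %||% length(unique(segments$read_id)))
  n_segments <- nrow(segments)
  origins <- c("RNAP", "RT", "AMBIGUOUS")
  counts <- matrix(0L, 3L, 3L,
                   dimnames = list(origins, TYPE_NAMES))
  if (nrow(attributed)) {
    w <- if (per_base) attributed$length else rep(1L, nrow(attributed))
    for (i in seq_len(nrow(attributed)))
      counts[attributed$origin[i], attributed$type[i]] <-
        counts[attributed$origin[i], attributed$type[i]] + w[i]
  }
  structure(list(counts = counts,
                 denominators = c(RNAP = n_reads * template_length,
                                  RT = n_segments * template_length),
                 n_reads = n_reads, n_segments = n_segments,
                 template_length = template_length),
            class = "rollseq_tabulation")
}

#' @export
print.rollseq_tabulation <- function(x, ...) {
  cat(sprintf("<rollseq_tabulation> %d reads, %d concatemers, L = %d\n",
              x$n_reads, x$n_segments, x$template_length))
  print(x$counts)
  cat(sprintf("denominators: RNAP %g, RT %g bases\n",
              x$denominators["RNAP"], x$denominators["RT"]))
  invisible(x)
}
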