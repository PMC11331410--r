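#' Filter a strand-specific consensus pair
#'
#' Eligibility filters for second-strand analysis: both strands need the
#' minimum pass count and read quality, a length within `length_tol`
#' bases of the expected reference length (inclusive), and the expected
#' sequences at both the 5' and 3' ends (each strand checked in its own
#' orientation). The reason code names the first failed criterion.
#'
#' @param pair list or one-row `data.frame` with `cdna`, `second`,
#'   `passes_cdna`, `passes_second`, `rq_cdna`, `rq_second`.
#' @param reference expected cDNA reference sequence (5' to 3'); supplies
#'   `expected_length` and default end motifs.
#' @param expected_length expected strand length; defaults to
#'   `nchar(reference)`.
#' @param end_motifs optional list with `five` and `three`, the expected
#'   sequences at the cDNA reference ends; default the first/last
#'   `motif_len` bases of `reference`.
#' @param length_tol allowed absolute length deviation in bases
#'   (default 10).
#' @param min_passes,min_read_quality per-strand thresholds (defaults 15
#'   and 1.0).
#' @param motif_len default end-motif length (default 8).
#' @return list with `eligible` and `reason` (`"ok"`, `"min_passes"`,
#'   `"read_quality"`, `"length"` or `"end_motif"`).
#' @export
filter_strand_pair <- function(pair, reference = NULL,
                               expected_length = NULL, end_motifs = NULL,
                               length_tol = 10L, min_passes = 15L,
                               min_read_quality = 1.0, motif_len = 8L) {
  if (is.null(reference) && (is.null(expected_length) ||
                             is.null(end_motifs)))
    stop("supply `reference`, or both `expected_length` and `end_motifs`")
  expected_length <- expected_length %||% nchar(reference)
  if (is.null(end_motifs))
    end_motifs <- list(five = substr(reference, 1L, motif_len),
                       three = substr(reference,
                                      nchar(reference) - motif_len + 1L,
                                      nchar(reference)))
  if (nchar(end_motifs$five) < 6L || nchar(end_motifs$three) < 6L)
    stop("end motifs must be at least 6 bases")
  fail <- function(reason) list(eligible = FALSE, reason = reason)
  if (pair$passes_cdna[1] < min_passes ||
      pair$passes_second[1] < min_passes) return(fail("min_passes"))
  if (pair$rq_cdna[1] < min_read_quality ||
      pair$rq_second[1] < min_read_quality) return(fail("read_quality"))
  if (abs(nchar(pair$cdna[1]) - expected_length) > length_tol ||
      abs(nchar(pair$second[1]) - expected_length) > length_tol)
    return(fail("length"))
  ## the second strand is the reverse complement of the cDNA, so its
  ## expected end motifs are the complements in swapped order
  s5 <- revcomp(end_motifs$three)
  s3 <- revcomp(end_motifs$five)
  if (!startsWith(pair$cdna[1], end_motifs$five) ||
      !endsWith(pair$cdna[1], end_motifs$three) ||
      !startsWith(pair$second[1], s5) || !endsWith(pair$second[1], s3))
    return(fail("end_motif"))
  list(eligible = TRUE, reason = "ok")
}

#' Compare the cDNA strand to its second strand
#'
#' Reverse-complements the second strand into the cDNA frame and aligns
#' it end-to-end against the cDNA. Errors made during cDNA synthesis are
#' present on both strands and remain concordant (invisible); every
#' discordant column is charged to second-strand synthesis, since the
#' cDNA is the template the second strand was copied from. Substitutions
#' are recorded as cDNA template base to the base actually incorporated
#' in the second strand (the complement of the aligned base); indels are
#' left-normalized on the cDNA frame.
#'
#' @param pair list or one-row `data.frame` with `molecule_id`, `cdna`,
#'   `second`.
#' @param params an [align_params()].
#' @param max_divergence reject pairs whose alignment divergence exceeds
#'   this cap (default 0.05).
#' @return one-row `data.frame` of class `strand_comparison` with
#'   `molecule_id`, `matches`, `substitutions`, `deletions`, `insertions`,
#'   `aligned_length`, `eligible`, `reason`; attribute `discordances`
#'   holds the per-event table (`type`, `cdna_pos`, `ref`,
#'   `incorporated`).
#' @export
compare_strands <- function(pair, params = align_params(),
                            max_divergence = 0.05) {
  cdna <- pair$cdna[1]
  mid <- if (!is.null(pair$molecule_id)) pair$molecule_id[1] else "pair"
  b <- revcomp(pair$second[1])
  m <- nchar(cdna)
  if (identical(b, cdna)) {
    out <- data.frame(molecule_id = mid, matches = m, substitutions = 0L,
                      deletions = 0L, insertions = 0L, aligned_length = m,
                      eligible = TRUE, reason = "ok",
                      stringsAsFactors = FALSE)
    attr(out, "discordances") <- empty_discordances()
    class(out) <- c("strand_comparison", "data.frame")
    return(out)
  }
  a <- .gotoh_align_batch(b, cdna, params$match, params$mismatch,
                          params$gap_open, params$gap_extend)
  ops <- a$ops
  aln <- a$aln_len[1]
  div <- op_bases(ops) / aln
  subs <- sum(ops$type == 1L)
  ins <- sum(ops$type == 2L)
  del <- sum(ops$type == 3L)
  del_bases <- sum(nchar(ops$ref[ops$type == 3L]))
  disc <- data.frame(type = TYPE_NAMES[ops$type], cdna_pos = ops$tpos,
                     ref = ops$ref,
                     incorporated = ifelse(ops$type == 3L, "",
                                           complement_base(ops$alt)),
                     stringsAsFactors = FALSE)
  disc <- left_normalize(
    stats::setNames(disc, c("type", "template_pos", "ref", "alt")), cdna)
  names(disc) <- c("type", "cdna_pos", "ref", "incorporated")
  out <- data.frame(molecule_id = mid, matches = m - subs - del_bases,
                    substitutions = subs, deletions = del,
                    insertions = ins, aligned_length = aln,
                    eligible = div <= max_divergence,
                    reason = if (div <= max_divergence) "ok" else
                      "divergence",
                    stringsAsFactors = FALSE)
  attr(out, "discordances") <- disc
  class(out) <- c("strand_comparison", "data.frame")
  out
}

empty_discordances <- function() {
  data.frame(type = character(), cdna_pos = integer(), ref = character(),
             incorporated = character(), stringsAsFactors = FALSE)
}

#' Compare many strand pairs
#'
#' Vectorised driver over a pairs table (e.g. from
#' [simulate_strand_pairs()]), applying [compare_strands()] per molecule.
#'
#' @param pairs `data.frame` with `molecule_id`, `cdna`, `second`.
#' @param params an [align_params()].
#' @param max_divergence per-pair divergence cap.
#' @return `data.frame` of per-pair comparison rows; attribute
#'   `discordances` binds all per-event tables with `molecule_id`.
#' @export
compare_strand_pairs <- function(pairs, params = align_params(),
                                 max_divergence = 0.05) {
  rows <- vector("list", nrow(pairs))
  disc <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    cmp <- compare_strands(pairs[i, ], params, max_divergence)
    d <- attr(cmp, "discordances")
    if (nrow(d))
      disc[[i]] <- data.frame(molecule_id = cmp$molecule_id, d,
                              stringsAsFactors = FALSE)
    attr(cmp, "discordances") <- NULL
    rows[[i]] <- cmp
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  dd <- do.call(rbind, disc)
  attr(out, "discordances") <- dd %||% data.frame(
    molecule_id = character(), type = character(), cdna_pos = integer(),
    ref = character(), incorporated = character(),
    stringsAsFactors = FALSE)
  out
}

#' Second-strand synthesis error rates
#'
#' Pools per-pair discordance counts into per-type error rates:
#' `sum(counts) / sum(aligned length)` per type, with binomial or
#' replicate-based standard errors as in [compute_rates()].
#'
#' @param comparisons per-pair comparison rows
#'   ([compare_strand_pairs()]); ineligible rows are dropped.
#' @param replicates optional factor/character vector (one label per
#'   comparison row) for replicate-based standard errors.
#' @return `data.frame` of class `error_rate_table` with
#'   `origin = "second_strand"`.
#' @export
second_strand_rates <- function(comparisons, replicates = NULL) {
  keep <- comparisons$eligible
  comparisons <- comparisons[keep, , drop = FALSE]
  if (!is.null(replicates)) replicates <- replicates[keep]
  if (!nrow(comparisons))
    stop("no eligible strand comparisons")
  denom <- sum(comparisons$aligned_length)
  counts <- c(substitution = sum(comparisons$substitutions),
              deletion = sum(comparisons$deletions),
              insertion = sum(comparisons$insertions))
  counts <- c(counts, total = sum(counts))
  rows <- lapply(seq_along(counts), function(i) {
    p <- counts[[i]] / denom
    data.frame(origin = "second_strand", type = names(counts)[i],
               count = counts[[i]], denominator = denom, rate = p,
               se = sqrt(p * (1 - p) / denom), se_method = "binomial",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(replicates) && length(unique(replicates)) >= 2L) {
    labs <- unique(replicates)
    for (j in seq_len(nrow(out))) {
      rr <- vapply(labs, function(l) {
        cc <- comparisons[replicates == l, , drop = FALSE]
        ct <- switch(out$type[j],
                     substitution = sum(cc$substitutions),
                     deletion = sum(cc$deletions),
                     insertion = sum(cc$insertions),
                     total = sum(cc$substitutions) + sum(cc$deletions) +
                       sum(cc$insertions))
        ct / sum(cc$aligned_length)
      }, numeric(1))
      out$se[j] <- sd(rr) / sqrt(length(rr))
      out$se_method[j] <- "replicate"
    }
  }
  rownames(out) <- NULL
  class(out) <- c("error_rate_table", "data.frame")
  out
}
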