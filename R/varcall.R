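#' Global alignment scoring parameters
#'
#' Scores for the end-to-end alignment of a concatemer segment against the
#' rotated template. A gap of length `k` scores
#' `gap_open + (k - 1) * gap_extend`. The defaults (1 / -2 / -4 / -1) make
#' a single substitution preferable to an adjacent insertion-plus-deletion
#' pair, which the variant caller relies on; parameter sets violating that
#' ordering are rejected.
#'
#' @param match,mismatch,gap_open,gap_extend alignment scores
#'   (`mismatch`, `gap_open`, `gap_extend` are negative).
#' @return object of class `align_params`.
#' @export
align_params <- function(match = 1, mismatch = -2, gap_open = -4,
                         gap_extend = -1) {
  if (mismatch <= 2 * gap_open)
    stop("scoring must prefer a substitution over adjacent ins+del ",
         "(require mismatch > 2*gap_open)")
  if (gap_extend > 0 || gap_open > 0)
    stop("gap penalties must be <= 0")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_params")
}

#' Globally align one segment to the rotated template
#'
#' End-to-end affine-gap alignment (optimal under `params`) of a
#' sense-oriented segment against the template rotated to the segment's
#' rotation offset. Segments identical to the rotated template take a fast
#' path with no dynamic programming.
#'
#' @param segment segment sequence oriented to template sense (character
#'   scalar, e.g. the `sequence` column of [segment_read()] output).
#' @param template unrotated sense-strand template.
#' @param rotation_offset 0-based rotation offset of the segment.
#' @param params an [align_params()].
#' @return list of class `rollseq_alignment` with `score`, `ops`
#'   (`data.frame` of raw alignment ops in rotated-template coordinates),
#'   `aln_len`, `divergence`, `rotation_offset` and `template_length`.
#' @export
align_segment <- function(segment, template, rotation_offset = 0L,
                          params = align_params()) {
  template <- as.character(template)
  L <- nchar(template)
  rot <- rotate_template(template, rotation_offset)
  if (identical(as.character(segment), rot)) {
    res <- list(score = L * params$match,
                ops = data.frame(pair = integer(), type = integer(),
                                 tpos = integer(), ref = character(),
                                 alt = character(),
                                 stringsAsFactors = FALSE),
                aln_len = L, divergence = 0)
  } else {
    a <- .gotoh_align_batch(as.character(segment), rot, params$match,
                            params$mismatch, params$gap_open,
                            params$gap_extend)
    res <- list(score = a$score[1], ops = a$ops, aln_len = a$aln_len[1],
                divergence = op_bases(a$ops) / a$aln_len[1])
  }
  res$rotation_offset <- as.integer(rotation_offset)
  res$template_length <- L
  class(res) <- "rollseq_alignment"
  res
}

op_bases <- function(ops) {
  if (!nrow(ops)) return(0L)
  sum(ifelse(ops$type == 3L, nchar(ops$ref), pmax(1L, nchar(ops$alt))))
}

## batch alignment of many segments against one template, grouped by
## rotation offset; identical segments skip the DP entirely
align_segments_batch <- function(seqs, template, offsets, params) {
  L <- nchar(template)
  n <- length(seqs)
  score <- numeric(n)
  aln_len <- integer(n)
  divergence <- numeric(n)
  ops_list <- vector("list", n)
  for (off in unique(offsets)) {
    idx <- which(offsets == off)
    rot <- rotate_template(template, off)
    ident <- seqs[idx] == rot
    score[idx[ident]] <- L * params$match
    aln_len[idx[ident]] <- L
    need <- idx[!ident]
    if (length(need)) {
      a <- .gotoh_align_batch(seqs[need], rep(rot, length(need)),
                              params$match, params$mismatch,
                              params$gap_open, params$gap_extend)
      score[need] <- a$score
      aln_len[need] <- a$aln_len
      if (nrow(a$ops)) {
        sp <- split(a$ops, a$ops$pair)
        for (nm in names(sp)) {
          j <- need[as.integer(nm)]
          ops_list[[j]] <- sp[[nm]]
          divergence[j] <- op_bases(sp[[nm]]) / aln_len[j]
        }
      }
    }
  }
  list(score = score, aln_len = aln_len, divergence = divergence,
       ops = ops_list)
}

#' Call variants from a segment alignment
#'
#' Converts alignment ops to variant calls on the unrotated sense
#' template: every substitution column is one call, adjacent gap columns
#' of one kind form one indel event of length `k`. Insertion calls are
#' anchored at the template base immediately 5' of the inserted bases
#' (circularly, so an insertion before template position 1 is reported at
#' position `L`). Calls are then canonicalised with [left_normalize()].
#'
#' @param alignment a `rollseq_alignment` from [align_segment()].
#' @param template the unrotated template.
#' @param read_id,concatemer_index provenance attached to every call.
#' @param normalize left-normalize the calls (default `TRUE`).
#' @return `data.frame` with columns `read_id`, `concatemer_index`,
#'   `type`, `template_pos`, `ref`, `alt`, `length`.
#' @export
call_variants <- function(alignment, template, read_id = "read",
                          concatemer_index = 0L, normalize = TRUE) {
  stopifnot(inherits(alignment, "rollseq_alignment"))
  ops <- alignment$ops
  if (normalize && nrow(ops)) {
    rot <- rotate_template(template, alignment$rotation_offset)
    ops <- normalize_ops(ops, rot)
  }
  calls <- ops_to_calls(ops, alignment$rotation_offset,
                        alignment$template_length)
  if (!nrow(calls)) return(empty_calls())
  data.frame(read_id = read_id,
             concatemer_index = as.integer(concatemer_index),
             calls, stringsAsFactors = FALSE)
}

## rotated-frame ops -> sense-template calls
ops_to_calls <- function(ops, offset, L) {
  if (is.null(ops) || !nrow(ops))
    return(data.frame(type = character(), template_pos = integer(),
                      ref = character(), alt = character(),
                      length = integer(), stringsAsFactors = FALSE))
  pos <- ((ops$tpos - 1L + offset) %% L) + 1L
  data.frame(type = TYPE_NAMES[ops$type],
             template_pos = pos,
             ref = ops$ref, alt = ops$alt,
             length = ifelse(ops$type == 1L, 1L,
                             nchar(paste0(ops$ref, ops$alt))),
             stringsAsFactors = FALSE)
}

## Normalize raw alignment ops in the (linear) frame they were called
## in. `rot` is the frame sequence, either one string or one per op row;
## `ops$pair` scopes which rows belong to one alignment. Shifting an
## indel 5' is an equivalence only across match columns, so a shift
## stops at any position occupied by another op of the same alignment.
## Vectorised: each pass shifts every still-shiftable indel one base,
## so iterations are bounded by the longest homopolymer run.
normalize_ops <- function(ops, rot) {
  if (!nrow(ops)) return(ops)
  BIG <- 1e7
  key <- function(pair, pos) pair * BIG + pos
  is_sub <- ops$type == 1L
  is_ins <- ops$type == 2L
  is_del <- ops$type == 3L
  sub_keys <- key(ops$pair[is_sub], ops$tpos[is_sub])
  dlen <- nchar(ops$ref[is_del])
  del_keys <- key(rep(ops$pair[is_del], dlen),
                  rep(ops$tpos[is_del], dlen) + sequence(dlen) - 1L)
  ins_keys <- key(ops$pair[is_ins], ops$tpos[is_ins])

  shift <- function(idx, allele, cross_off, floor_pos, pool) {
    tp <- ops$tpos[idx]
    al <- allele
    sq <- if (length(rot) == 1L) rep(rot, length(idx)) else rot[idx]
    pr <- ops$pair[idx]
    active <- seq_along(idx)
    repeat {
      if (!length(active)) break
      a <- active
      k <- nchar(al[a])
      cross <- tp[a] + cross_off
      at <- substring(sq[a], cross, cross)
      can <- tp[a] >= floor_pos & at == substring(al[a], k, k) &
        !(key(pr[a], cross) %in% pool)
      hit <- a[can]
      if (!length(hit)) break
      kk <- nchar(al[hit])
      b <- substring(sq[hit], tp[hit] + cross_off, tp[hit] + cross_off)
      al[hit] <- paste0(b, substring(al[hit], 1L, kk - 1L))
      tp[hit] <- tp[hit] - 1L
      active <- hit
    }
    list(tp = tp, al = al)
  }

  idx <- which(is_ins)
  if (length(idx)) {
    ## insertion after base tp: crossing base is tp itself; may reach 0
    r <- shift(idx, ops$alt[idx], cross_off = 0L, floor_pos = 1L,
               pool = c(sub_keys, del_keys))
    ops$tpos[idx] <- r$tp
    ops$alt[idx] <- r$al
  }
  idx <- which(is_del)
  if (length(idx)) {
    ## deletion starting at tp: crossing base is tp - 1; floor is 1
    r <- shift(idx, ops$ref[idx], cross_off = -1L, floor_pos = 2L,
               pool = c(sub_keys, ins_keys))
    ops$tpos[idx] <- r$tp
    ops$ref[idx] <- r$al
  }
  ops
}

#' Left-normalize indel calls
#'
#' Shifts every insertion and deletion to the smallest template position
#' that yields an equivalent alignment, so the same physical event gets
#' identical coordinates in every concatemer (inside a homopolymer tract
#' the 5'-most placement is the canonical one). Substitutions pass through
#' unchanged; the operation is idempotent.
#'
#' The template is circular: an insertion whose equivalent placements
#' reach 5' of template base 1 is labelled at position `L` (its 5'
#' neighbour on the circle is the last template base), and insertions
#' already labelled `L` are treated as canonical junction labels and are
#' not shifted further. Deletions never cross the linear origin.
#'
#' @param calls `data.frame` of calls with columns `type`, `template_pos`,
#'   `ref`, `alt` (extra columns are preserved).
#' @param template the unrotated sense template.
#' @return the calls with canonical `template_pos`, `ref`, `alt`.
#' @export
left_normalize <- function(calls, template) {
  template <- as.character(template)
  L <- nchar(template)
  if (!nrow(calls)) return(calls)
  grp <- if (!is.null(calls$read_id))
    paste(calls$read_id, calls$concatemer_index) else rep("x", nrow(calls))
  ## insertions already labelled L are canonical junction labels
  hold <- calls$type == "insertion" & calls$template_pos == L
  ops <- data.frame(pair = as.integer(factor(grp)),
                    type = match(calls$type, TYPE_NAMES),
                    tpos = calls$template_pos,
                    ref = calls$ref, alt = calls$alt,
                    stringsAsFactors = FALSE)
  ops$type[hold] <- 1L  # treat as fixed; still blocks neighbours
  n <- normalize_ops(ops, template)
  upd <- !hold
  calls$template_pos[upd] <- ifelse(
    calls$type[upd] == "insertion" & n$tpos[upd] == 0L, L, n$tpos[upd])
  calls$ref[upd] <- n$ref[upd]
  calls$alt[upd] <- n$alt[upd]
  calls
}
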