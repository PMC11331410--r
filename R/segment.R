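#' Read-eligibility filter policy
#'
#' Thresholds controlling which consensus reads enter the analysis: at
#' least `min_passes` sequencing passes, read quality at least
#' `min_read_quality`, between `min_concatemers` and `max_concatemers`
#' full template copies (the 3..10 window keeps consensus accuracy at Q40
#' or better for a ~1 kb template), every copy fully mapping to the
#' template (length within `full_map_length_tolerance`) and per-copy
#' alignment divergence at most `max_divergence`.
#'
#' @param min_passes minimum pass count (default 15).
#' @param min_read_quality minimum read quality in `[0, 1]` (default 1.0).
#' @param min_concatemers,max_concatemers allowed concatemer-count window
#'   (defaults 3 and 10).
#' @param full_map_length_tolerance allowed relative deviation of a
#'   segment's length from the template length (default 0.02).
#' @param max_divergence maximum per-segment alignment divergence
#'   (edited bases / alignment columns; default 0.05).
#' @return object of class `filter_policy`.
#' @export
filter_policy <- function(min_passes = 15L, min_read_quality = 1.0,
                          min_concatemers = 3L, max_concatemers = 10L,
                          full_map_length_tolerance = 0.02,
                          max_divergence = 0.05) {
  min_concatemers <- as.integer(min_concatemers)
  max_concatemers <- as.integer(max_concatemers)
  if (min_concatemers < 1L) stop("min_concatemers must be >= 1")
  if (max_concatemers < min_concatemers)
    stop("max_concatemers must be >= min_concatemers")
  structure(list(min_passes = as.integer(min_passes),
                 min_read_quality = as.numeric(min_read_quality),
                 min_concatemers = min_concatemers,
                 max_concatemers = max_concatemers,
                 full_map_length_tolerance = full_map_length_tolerance,
                 max_divergence = max_divergence),
            class = "filter_policy")
}

empty_segments <- function(L = NA_integer_, orientation = NA_character_,
                           mixed = FALSE) {
  s <- data.frame(read_id = character(), concatemer_index = integer(),
                  read_start = integer(), read_end = integer(),
                  orientation = character(), rotation_offset = integer(),
                  length = integer(), divergence = numeric(),
                  sequence = character(), stringsAsFactors = FALSE)
  attr(s, "template_length") <- L
  attr(s, "orientation") <- orientation
  attr(s, "mixed_orientation") <- mixed
  s
}

#' Segment a concatemeric read into full template copies
#'
#' Locates full-length copies of the circular template inside a long read
#' by seed-and-extend against the doubled template (both strands): short
#' exact probes vote for an orientation and a rotation offset, an exact
#' anchor k-mer placed at the copy start tiles the read into consecutive
#' copies, and missed anchors (the rare copies whose start was hit by an
#' error) are interpolated at template-length spacing. Partial copies at
#' either read end are excluded. All returned segments share the
#' better-supported orientation; substantial support for both orientations
#' marks the read as mixed (a chimeric artifact) for rejection by
#' [filter_read()].
#'
#' @param read a character scalar, or a one-row `data.frame` with columns
#'   `read_id` and `sequence` (e.g. a row of [simulate_run()] reads).
#' @param template sense-strand template (length >= 100).
#' @param policy a [filter_policy()]; only the length tolerance is used
#'   here.
#' @param probe_k,anchor_k seed lengths for orientation probes and
#'   copy-start anchors.
#' @param check_repeats warn when the template carries duplicated
#'   `anchor_k`-mers (ambiguous anchors); disable when calling in a loop
#'   after checking once.
#' @return `data.frame` with one row per segment: `read_id`,
#'   `concatemer_index` (0-based, 5' to 3' along the read), `read_start`,
#'   `read_end` (1-based inclusive), `orientation` (`forward`/`reverse`
#'   relative to template sense), `rotation_offset` (0-based template
#'   position at which every copy begins), `length`, `divergence` (filled
#'   by alignment, `NA` here) and `sequence` (the segment oriented to
#'   template sense). Attributes: `template_length`, `orientation`,
#'   `mixed_orientation`.
#' @export
segment_read <- function(read, template, policy = filter_policy(),
                         probe_k = 24L, anchor_k = 20L,
                         check_repeats = TRUE) {
  if (is.data.frame(read)) {
    read_id <- read$read_id[1]
    seq <- read$sequence[1]
  } else {
    read_id <- attr(read, "read_id") %||% "read"
    seq <- as.character(read)
  }
  template <- as.character(template)
  L <- nchar(template)
  if (L < 100L) stop("template length must be at least 100")
  if (check_repeats && template_has_repeats(template, anchor_k))
    warning("template contains repeated ", anchor_k,
            "-mers; anchor placement may be ambiguous")
  n <- nchar(seq)
  tol_len <- ceiling(policy$full_map_length_tolerance * L)
  if (n < L - tol_len) return(empty_segments(L))

  dbl <- paste0(template, template)
  dblrc <- revcomp(dbl)

  probe_at <- function(s, k, n) {
    npr <- min(8L, max(2L, n %/% max(k * 4L, 100L) + 1L))
    unique(pmax(1L, pmin(n - k + 1L,
                         round(seq(1L, n - k + 1L, length.out = npr)))))
  }

  ## orientation vote
  k <- min(probe_k, L)
  pos <- probe_at(seq, k, n)
  probes <- substring(seq, pos, pos + k - 1L)
  inf <- vapply(probes, function(p) regexpr(p, dbl, fixed = TRUE)[1],
                numeric(1), USE.NAMES = FALSE)
  inr <- vapply(probes, function(p) regexpr(p, dblrc, fixed = TRUE)[1],
                numeric(1), USE.NAMES = FALSE)
  vf <- sum(inf > 0 & inr < 0)
  vr <- sum(inr > 0 & inf < 0)
  if (vf == 0L && vr == 0L) return(empty_segments(L))
  orientation <- if (vr > vf) "reverse" else "forward"
  mixed <- min(vf, vr) >= 2L
  oseq <- if (orientation == "reverse") revcomp(seq) else seq

  ## rotation offset = template phase at the read start. Matching probes
  ## vote for a phase, but probes downstream of an indel drift by the
  ## cumulative indel count, so each vote (plus a small drift
  ## neighbourhood) is scored by exact prefix identity against the
  ## correspondingly rotated template; the best-matching phase wins.
  ## Copy-start anchors below match by content, so downstream drift does
  ## not accumulate into the tiling.
  pos <- probe_at(oseq, k, n)
  probes <- substring(oseq, pos, pos + k - 1L)
  hits <- vapply(probes, function(p) regexpr(p, dbl, fixed = TRUE)[1],
                 numeric(1), USE.NAMES = FALSE)
  ok <- hits > 0
  if (!any(ok)) return(empty_segments(L, orientation, mixed))
  votes <- ((hits[ok] - 1) - (pos[ok] - 1)) %% L
  cand <- unique(as.integer(outer(unique(votes), -3:3, "+")) %% L)
  w <- min(64L, L)
  pref <- utf8ToInt(substr(oseq, 1L, w))
  sc <- vapply(cand, function(r)
    sum(pref == utf8ToInt(substr(rotate_template(template, r), 1L, w))),
    numeric(1))
  r <- as.integer(cand[which.max(sc)])

  ## copy-start anchors
  ka <- min(anchor_k, L)
  anchor <- substr(rotate_template(template, r), 1L, ka)
  h <- gregexpr(anchor, oseq, fixed = TRUE)[[1]]
  starts <- if (h[1] == -1L) integer(0) else as.integer(h)
  if (length(starts) > 1L) {
    keep <- c(TRUE, diff(starts) > L %/% 2L)
    starts <- starts[keep]
  }
  if (!length(starts)) {
    ## all anchors hit by errors: fall back to L-spaced tiling when the
    ## read plausibly starts at a copy boundary
    first_tpos <- ((hits[ok][1] - 1) - (pos[ok][1] - 1)) %% L
    if (abs(((first_tpos - r) %% L)) <= 2L)
      starts <- seq(1L, max(1L, n - (L - tol_len) + 1L), by = L)
    else
      return(empty_segments(L, orientation, mixed))
  } else {
    while (starts[1] - L >= 1L) starts <- c(starts[1] - L, starts)
    ## a leading chunk of roughly one template length is a full copy
    ## whose start anchor was hit by an error
    lead <- starts[1] - 1L
    if (lead >= L - tol_len && lead <= L + tol_len)
      starts <- c(1L, starts)
    while (tail(starts, 1L) + L + (L - tol_len) - 1L <= n)
      starts <- c(starts, tail(starts, 1L) + L)
    if (length(starts) > 1L) {
      filled <- starts[1]
      for (j in 2:length(starts)) {
        g <- starts[j] - starts[j - 1L]
        mcopies <- max(1L, round(g / L))
        if (mcopies > 1L)
          filled <- c(filled, starts[j - 1L] +
                        round(g * seq_len(mcopies - 1L) / mcopies))
        filled <- c(filled, starts[j])
      }
      starts <- as.integer(filled)
    }
  }

  ## starts that did not come from an exact anchor hit (interpolated,
  ## extended, or leading-recovery) can be off by the local indel drift;
  ## snap them to the position minimizing edit distance to the anchor,
  ## which tolerates anchors corrupted by a substitution or an indel
  inexact <- !(starts %in% (if (h[1] == -1L) integer(0) else as.integer(h)))
  for (i in which(inexact)) {
    lo <- max(1L, starts[i] - 4L)
    hi <- min(n - ka + 1L, starts[i] + 4L)
    if (hi < lo) next
    cands <- lo:hi
    d <- -.nw_score_gapfn_batch(substring(oseq, cands, cands + ka - 1L),
                                rep(anchor, length(cands)),
                                0, -1, -1, -1)
    starts[i] <- cands[which.min(d)]
  }
  starts <- sort(unique(starts))
  if (length(starts) > 1L)
    starts <- starts[c(TRUE, diff(starts) > L %/% 2L)]

  ends <- c(starts[-1L] - 1L, NA_integer_)
  last <- length(starts)
  rem <- n - starts[last] + 1L
  if (rem < L - tol_len) {
    ## trailing partial copy: its start still marks the previous copy's
    ## end boundary, already recorded in ends[last - 1]
    starts <- starts[-last]
    ends <- ends[-last]
    if (!length(starts)) return(empty_segments(L, orientation, mixed))
  } else {
    ends[last] <- if (rem <= L + tol_len) n else starts[last] + L - 1L
  }

  segs <- data.frame(read_id = read_id,
                     concatemer_index = NA_integer_,
                     o_start = starts, o_end = ends,
                     stringsAsFactors = FALSE)
  if (orientation == "reverse") {
    segs$read_start <- n - segs$o_end + 1L
    segs$read_end <- n - segs$o_start + 1L
  } else {
    segs$read_start <- segs$o_start
    segs$read_end <- segs$o_end
  }
  segs$sequence <- substring(oseq, segs$o_start, segs$o_end)
  segs <- segs[order(segs$read_start), , drop = FALSE]
  segs$concatemer_index <- seq_len(nrow(segs)) - 1L
  segs$orientation <- orientation
  segs$rotation_offset <- r
  segs$length <- segs$read_end - segs$read_start + 1L
  segs$divergence <- NA_real_
  segs <- segs[, c("read_id", "concatemer_index", "read_start", "read_end",
                   "orientation", "rotation_offset", "length", "divergence",
                   "sequence")]
  rownames(segs) <- NULL
  attr(segs, "template_length") <- L
  attr(segs, "orientation") <- orientation
  attr(segs, "mixed_orientation") <- mixed
  segs
}

#' Apply read-level eligibility filters
#'
#' Checks a read and its segments against a [filter_policy()] and returns
#' the verdict together with the first failed criterion. Checks run in a
#' fixed order: `min_passes`, `read_quality`, `mixed_orientation`,
#' `min_concatemers`, `max_concatemers`, `full_map` (every segment length
#' within tolerance of the template length), `divergence` (only for
#' segments whose divergence has been computed).
#'
#' @param read list or one-row `data.frame` with `passes` and
#'   `read_quality`.
#' @param segments segments from [segment_read()] (possibly with
#'   `divergence` filled in by alignment).
#' @param policy a [filter_policy()].
#' @param template_length template length; defaults to the
#'   `template_length` attribute of `segments`.
#' @return list with `eligible` (logical) and `reason` (`"ok"` or the
#'   first failed criterion).
#' @export
filter_read <- function(read, segments, policy = filter_policy(),
                        template_length = NULL) {
  L <- template_length %||% attr(segments, "template_length")
  fail <- function(reason) list(eligible = FALSE, reason = reason)
  if (read$passes[1] < policy$min_passes) return(fail("min_passes"))
  if (read$read_quality[1] < policy$min_read_quality)
    return(fail("read_quality"))
  if (isTRUE(attr(segments, "mixed_orientation")))
    return(fail("mixed_orientation"))
  nseg <- nrow(segments)
  if (nseg < policy$min_concatemers) return(fail("min_concatemers"))
  if (nseg > policy$max_concatemers) return(fail("max_concatemers"))
  tol <- ceiling(policy$full_map_length_tolerance * L)
  if (any(segments$length < L - tol | segments$length > L + tol))
    return(fail("full_map"))
  div <- segments$divergence
  if (any(!is.na(div) & div > policy$max_divergence))
    return(fail("divergence"))
  list(eligible = TRUE, reason = "ok")
}
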