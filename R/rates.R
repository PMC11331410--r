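RATE_TYPES <- c("substitution", "deletion", "insertion", "total")

#' Error rates with uncertainty from a tabulation
#'
#' Converts attributed counts into per-origin, per-type error rates
#' (errors/base). Uncertainty is the binomial standard error
#' `sqrt(p (1 - p) / n)`; when a list of per-replicate tabulations is
#' supplied the standard error of the mean across replicates is reported
#' instead (the pooled counts still define the point estimate).
#'
#' An optional `noise_rate` adds a noise-corrected substitution/total rate
#' for the reverse transcriptase: residual consensus noise is
#' single-concatemer by construction and lands in the RT bucket, so
#' `rate - noise_rate` removes it.
#'
#' @param tabulation a [tabulate_variants()] result.
#' @param replicates optional list of per-replicate tabulations.
#' @param noise_rate optional known residual substitution noise
#'   (errors/base).
#' @return `data.frame` of class `error_rate_table` with columns `origin`,
#'   `type`, `count`, `denominator`, `rate`, `se`, `se_method` (and
#'   `rate_noise_corrected` when `noise_rate` is given). Ambiguous-variant
#'   counts are kept in the `ambiguous` attribute.
#' @export
#' @examples
#' # counts per 1e6 bases matching a benchmarked T7 polymerase
#' tab <- structure(list(
#'   counts = matrix(c(38, 0, 0, 2, 0, 0, 13, 0, 0), 3, 3,
#'     dimnames = list(c("RNAP", "RT", "AMBIGUOUS"),
#'                     c("substitution", "deletion", "insertion"))),
#'   denominators = c(RNAP = 1e6, RT = 1e6),
#'   n_reads = 1, n_segments = 1, template_length = 1e6),
#'   class = "rollseq_tabulation")
#' compute_rates(tab)
compute_rates <- function(tabulation, replicates = NULL,
                          noise_rate = NULL) {
  stopifnot(inherits(tabulation, "rollseq_tabulation"))
  if (any(tabulation$denominators <= 0))
    stop("rate denominators must be positive")
  rows <- list()
  for (origin in c("RNAP", "RT")) {
    denom <- tabulation$denominators[[origin]]
    cn <- tabulation$counts[origin, TYPE_NAMES]
    counts <- c(cn, total = sum(cn))
    for (i in seq_along(RATE_TYPES)) {
      ct <- counts[[RATE_TYPES[i]]]
      p <- ct / denom
      rows[[length(rows) + 1L]] <- data.frame(
        origin = origin, type = RATE_TYPES[i], count = ct,
        denominator = denom, rate = p,
        se = sqrt(p * (1 - p) / denom),
        se_method = "binomial", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(replicates)) {
    if (length(replicates) >= 2L) {
      for (j in seq_len(nrow(out))) {
        rr <- vapply(replicates, function(tb) {
          cn <- tb$counts[out$origin[j], TYPE_NAMES]
          ct <- if (out$type[j] == "total") sum(cn) else cn[[out$type[j]]]
          ct / tb$denominators[[out$origin[j]]]
        }, numeric(1))
        out$se[j] <- sd(rr) / sqrt(length(rr))
        out$se_method[j] <- "replicate"
      }
    }
  }
  if (!is.null(noise_rate)) {
    out$rate_noise_corrected <- out$rate
    rt_fix <- out$origin == "RT" & out$type %in% c("substitution", "total")
    out$rate_noise_corrected[rt_fix] <-
      pmax(0, out$rate[rt_fix] - noise_rate)
  }
  rownames(out) <- NULL
  attr(out, "ambiguous") <- tabulation$counts["AMBIGUOUS", ]
  class(out) <- c("error_rate_table", "data.frame")
  out
}

#' @export
print.error_rate_table <- function(x, ...) {
  cat("Error rates (x 1e-6 errors/base)\n")
  y <- data.frame(origin = x$origin, type = x$type, count = x$count,
                  rate = sprintf("%.1f", x$rate * 1e6),
                  se = sprintf("%.1f", x$se * 1e6))
  print(y, row.names = FALSE)
  amb <- attr(x, "ambiguous")
  if (!is.null(amb) && sum(amb) > 0)
    cat("ambiguous (excluded):", paste(names(amb), amb, collapse = ", "),
        "\n")
  invisible(x)
}

#' Substitution spectrum by template base
#'
#' Cross-tabulates attributed substitutions by sense-frame template base
#' and observed base, and derives the two marginals of interest: the
#' fraction of substitution events occurring at each template base, and
#' the fraction of each misincorporated nucleotide. For the RNA polymerase
#' the misincorporated nucleotide is the ribonucleotide in the transcript,
#' i.e. the sense-frame alternative base (reported with U). For a reverse
#' transcriptase the enzyme synthesises the cDNA strand, so the
#' misincorporated dNMP is the complement of the sense-frame alternative
#' base; template bases are reported in DNA letters (U -> T).
#'
#' @param attributed attributed variants ([attribute_variants()]).
#' @param origin `"RNAP"` or `"RT"`.
#' @param template template sequence (used for composition-normalised
#'   fractions).
#' @param composition_normalized also report per-base fractions divided by
#'   the template base composition.
#' @return list of class `substitution_spectrum` with `matrix` (4x4
#'   sense-frame counts, template base x observed base), `frame` (`"RNA"`
#'   or `"DNA"`), `template_base_fraction`, `misincorporated_fraction`
#'   (named in the frame's alphabet), `n` and optionally
#'   `template_base_fraction_composition`.
#' @export
substitution_spectrum <- function(attributed, origin = c("RNAP", "RT"),
                                  template = NULL,
                                  composition_normalized = FALSE) {
  origin <- match.arg(origin)
  sub <- attributed[attributed$origin == origin &
                      attributed$type == "substitution", , drop = FALSE]
  m <- matrix(0L, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  for (i in seq_len(nrow(sub))) m[sub$ref[i], sub$alt[i]] <-
    m[sub$ref[i], sub$alt[i]] + 1L
  n <- sum(m)
  tf <- if (n > 0) rowSums(m) / n else setNames(rep(0, 4), DNA_BASES)
  if (origin == "RNAP") {
    frame <- "RNA"
    mis <- if (n > 0) colSums(m) / n else setNames(rep(0, 4), DNA_BASES)
    names(tf) <- names(mis) <- sub("T", "U", DNA_BASES)
  } else {
    frame <- "DNA"
    ## incorporated dNMP = complement of the sense-frame alternative base
    inc <- if (n > 0) colSums(m)[complement_base(DNA_BASES)] else
      setNames(rep(0, 4), DNA_BASES)
    mis <- setNames(as.numeric(inc) / max(n, 1L), DNA_BASES)
  }
  out <- list(matrix = m, frame = frame, template_base_fraction = tf,
              misincorporated_fraction = mis, n = n)
  if (composition_normalized && !is.null(template)) {
    comp <- table(factor(seq_chars(as.character(template)),
                         levels = DNA_BASES))
    norm <- rowSums(m) / as.numeric(comp)
    out$template_base_fraction_composition <-
      if (sum(norm) > 0) norm / sum(norm) else norm
  }
  class(out) <- "substitution_spectrum"
  out
}

#' @export
print.substitution_spectrum <- function(x, ...) {
  cat(sprintf("<substitution_spectrum> %s frame, %d events\n", x$frame,
              x$n))
  cat("by template base:  ",
      paste(sprintf("%s %.2f", names(x$template_base_fraction),
                    x$template_base_fraction), collapse = "  "), "\n")
  cat("misincorporated:   ",
      paste(sprintf("%s %.2f", names(x$misincorporated_fraction),
                    x$misincorporated_fraction), collapse = "  "), "\n")
  invisible(x)
}

#' @describeIn substitution_spectrum flatten to a 16-row `data.frame`
#'   (`template_base`, `observed_base`, `count`, `fraction`, `frame`).
#' @param x a `substitution_spectrum`.
#' @export
as.data.frame.substitution_spectrum <- function(x, ...) {
  df <- expand.grid(template_base = DNA_BASES, observed_base = DNA_BASES,
                    stringsAsFactors = FALSE)
  df$count <- as.integer(x$matrix[cbind(df$template_base,
                                        df$observed_base)])
  df$fraction <- if (x$n > 0) df$count / x$n else 0
  df$frame <- x$frame
  df
}

#' Classify a substitution as transition or transversion
#'
#' Transitions are purine-to-purine or pyrimidine-to-pyrimidine changes in
#' the sense frame (`A<->G`, `C<->T/U`); everything else is a
#' transversion. Transversions are subdivided by the physical
#' template:incorporated base pair the enzyme formed: for a reverse
#' transcriptase the template base is the sense (RNA) base and the
#' incorporated base is the complement of the sense alternative; for an
#' RNA polymerase the template is the antisense DNA strand and the
#' incorporated ribonucleotide is the sense alternative itself. A
#' purine:purine mismatch pair is reported as `transversion_purine_purine`,
#' all remaining transversions as `transversion_other`.
#'
#' @param ref,alt sense-frame template and observed bases (vectorised).
#' @param origin `"RT"` or `"RNAP"` (controls the mismatch-pair frame).
#' @return character vector in `c("transition",
#'   "transversion_purine_purine", "transversion_other")`.
#' @export
#' @examples
#' classify_mutation("A", "G", "RNAP")   # transition
#' classify_mutation("A", "C", "RT")     # template A : incorporated dG
classify_mutation <- function(ref, alt, origin = c("RT", "RNAP")) {
  origin <- match.arg(origin)
  if (any(!ref %in% DNA_BASES) || any(!alt %in% DNA_BASES))
    stop("ref and alt must be A, C, G or T")
  if (any(ref == alt)) stop("ref and alt must differ")
  purine <- function(b) b %in% c("A", "G")
  transition <- purine(ref) == purine(alt)
  if (origin == "RT") {
    tmpl <- ref
    inc <- complement_base(alt)
  } else {
    tmpl <- complement_base(ref)
    inc <- alt
  }
  ifelse(transition, "transition",
         ifelse(purine(tmpl) & purine(inc),
                "transversion_purine_purine", "transversion_other"))
}

#' Positional error profile with homopolymer annotation
#'
#' Distribution of attributed variants of one type and origin along the
#' template: per-position counts and fractions, membership in homopolymer
#' tracts (where slippage concentrates indels), and the top-`k` hotspot
#' positions with flanking context.
#'
#' @param attributed attributed variants.
#' @param type `"substitution"`, `"insertion"` or `"deletion"`.
#' @param origin `"RNAP"` or `"RT"`.
#' @param template template sequence.
#' @param homopolymer_min_len minimum run length flagged as a tract
#'   (default 3).
#' @param top_k number of hotspots to report (default 6).
#' @param flank flanking bases shown around each hotspot (default 3).
#' @return list of class `positional_profile` with `profile`
#'   (`data.frame`: `template_pos`, `ref_base`, `count`, `fraction`,
#'   `in_homopolymer`, `run_base`, `run_length`) and `hotspots`
#'   (`data.frame` with flanking `context`).
#' @export
positional_profile <- function(attributed, type, origin, template,
                               homopolymer_min_len = 3L, top_k = 6L,
                               flank = 3L) {
  template <- as.character(template)
  L <- nchar(template)
  sel <- attributed[attributed$type == type &
                      attributed$origin == origin, , drop = FALSE]
  counts <- integer(L)
  if (nrow(sel)) {
    tb <- table(factor(sel$template_pos, levels = seq_len(L)))
    counts <- as.integer(tb)
  }
  total <- sum(counts)
  runs <- homopolymer_runs(template, homopolymer_min_len)
  in_run <- rep(FALSE, L)
  run_base <- rep(NA_character_, L)
  run_len <- rep(NA_integer_, L)
  for (i in seq_len(nrow(runs))) {
    ix <- runs$start[i]:(runs$start[i] + runs$length[i] - 1L)
    in_run[ix] <- TRUE
    run_base[ix] <- runs$base[i]
    run_len[ix] <- runs$length[i]
  }
  profile <- data.frame(template_pos = seq_len(L),
                        ref_base = seq_chars(template),
                        count = counts,
                        fraction = if (total > 0) counts / total else 0,
                        in_homopolymer = in_run, run_base = run_base,
                        run_length = run_len, stringsAsFactors = FALSE)
  hot <- profile[profile$count > 0, , drop = FALSE]
  hot <- hot[order(-hot$count, hot$template_pos), , drop = FALSE]
  hot <- head(hot, top_k)
  if (nrow(hot)) {
    dbl <- paste0(template, template, template)
    ctx_start <- hot$template_pos - flank + L
    hot$context <- substring(dbl, ctx_start, ctx_start + 2L * flank)
  } else hot$context <- character(0)
  structure(list(profile = profile, hotspots = hot, type = type,
                 origin = origin, n = total), class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, ...) {
  cat(sprintf("<positional_profile> %s %s, %d events\n", x$origin, x$type,
              x$n))
  if (nrow(x$hotspots)) {
    cat("hotspots:\n")
    print(x$hotspots[, c("template_pos", "ref_base", "count", "fraction",
                         "in_homopolymer", "context")], row.names = FALSE)
  }
  invisible(x)
}
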