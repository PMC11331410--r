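#' Fit polymerase and reverse-transcriptase error rates from
#' concatemeric reads
#'
#' The end-to-end estimator. Each read is segmented into full template
#' copies, eligibility filters are applied (pass count, read quality,
#' 3..10 concatemer window, full mapping, divergence cap), every segment
#' is globally aligned to the rotated template and left-normalized
#' variants are called, identical calls are grouped across the
#' concatemers of a read, and each group is attributed: present in every
#' concatemer means the error was already in the RNA molecule (RNA
#' polymerase), private to one concatemer means it arose in one
#' reverse-transcription pass (RT). Attributed counts become rates over
#' the appropriate denominators: one template length per molecule for the
#' polymerase, every aligned concatemer base for the RT.
#'
#' @param reads `data.frame` with `read_id`, `sequence`, `passes`,
#'   `read_quality` (e.g. [simulate_run()] output or [read_reads()]), or a
#'   FASTQ path (then supply `meta`).
#' @param template template sequence or FASTA path.
#' @param policy a [filter_policy()].
#' @param params an [align_params()].
#' @param noise_rate optional known residual sequencing-noise rate; adds
#'   noise-corrected RT rates to the rate table.
#' @param replicates optional named vector or `replicate` column in
#'   `reads` mapping reads to replicate labels for replicate-based
#'   standard errors.
#' @param meta metadata TSV path when `reads` is a FASTQ path.
#' @param out_dir optional output directory for TSV/JSON artifacts.
#' @return object of class `rollseq`; see [print.rollseq()],
#'   [summary.rollseq()], [coef.rollseq()], [plot.rollseq()] and
#'   [simulate.rollseq()].
#' @seealso [simulate_run()] for generating test data with ground truth.
#' @export
#' @examples
#' tpl <- make_template(300, seed = 5)
#' sim <- simulate_run(sim_config(
#'   tpl, rnap_model = error_model(substitution_rate = 2e-3),
#'   rt_model = error_model(substitution_rate = 2e-3),
#'   n_molecules = 20, sequencing_noise_rate = 0, seed = 7))
#' fit <- roll_seq(sim$reads, tpl)
#' coef(fit)
roll_seq <- function(reads, template, policy = filter_policy(),
                     params = align_params(), noise_rate = NULL,
                     replicates = NULL, meta = NULL, out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (is.character(reads) && length(reads) == 1L)
    reads <- read_reads(reads, meta)
  if (is.character(template) && file.exists(template) &&
      grepl("\\.(fa|fasta|fna)$", template, ignore.case = TRUE))
    template <- read_template(template)
  template <- as.character(template)
  L <- nchar(template)
  if (template_has_repeats(template, 20L))
    warning("template contains repeated 20-mers; segmentation anchors ",
            "may be ambiguous")
  if (is.null(replicates) && !is.null(reads$replicate))
    replicates <- setNames(reads$replicate, reads$read_id)

  ## stage 1: segmentation + cheap filters
  n_reads <- nrow(reads)
  seg_list <- vector("list", n_reads)
  verdicts <- data.frame(read_id = reads$read_id,
                         eligible = FALSE, reason = NA_character_,
                         n_concatemers = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(n_reads)) {
    r <- reads[i, ]
    if (r$passes < policy$min_passes) {
      verdicts$reason[i] <- "min_passes"; next
    }
    if (r$read_quality < policy$min_read_quality) {
      verdicts$reason[i] <- "read_quality"; next
    }
    segs <- segment_read(r, template, policy, check_repeats = FALSE)
    seg_list[[i]] <- segs
    verdicts$n_concatemers[i] <- nrow(segs)
    v <- filter_read(r, segs, policy, L)
    verdicts$eligible[i] <- v$eligible
    verdicts$reason[i] <- v$reason
  }
  t_seg <- proc.time()[["elapsed"]]

  ## stage 2: alignment + divergence for provisionally eligible reads
  idx_ok <- which(verdicts$eligible)
  segments <- do.call(rbind, seg_list[idx_ok])
  calls <- empty_calls()
  if (!is.null(segments) && nrow(segments)) {
    al <- align_segments_batch(segments$sequence, template,
                               segments$rotation_offset, params)
    segments$divergence <- al$divergence
    ## divergence cap can retract eligibility
    bad <- tapply(al$divergence > policy$max_divergence,
                  segments$read_id, any)
    for (rid in names(bad)[bad]) {
      j <- which(verdicts$read_id == rid)
      verdicts$eligible[j] <- FALSE
      verdicts$reason[j] <- "divergence"
    }
    keep <- segments$read_id %in% verdicts$read_id[verdicts$eligible]
    segments <- segments[keep, , drop = FALSE]
    al_ops <- al$ops[keep]
    ## stage 3: variant calls, left-normalized in the alignment frame
    rot_cache <- new.env(parent = emptyenv())
    call_pieces <- vector("list", nrow(segments))
    for (j in seq_len(nrow(segments))) {
      ops <- al_ops[[j]]
      if (is.null(ops) || !nrow(ops)) next
      off <- segments$rotation_offset[j]
      key <- as.character(off)
      if (is.null(rot_cache[[key]]))
        rot_cache[[key]] <- rotate_template(template, off)
      cc <- ops_to_calls(normalize_ops(ops, rot_cache[[key]]), off, L)
      call_pieces[[j]] <- data.frame(
        read_id = segments$read_id[j],
        concatemer_index = segments$concatemer_index[j],
        cc, stringsAsFactors = FALSE)
    }
    calls <- do.call(rbind, call_pieces) %||% empty_calls()
  } else {
    segments <- empty_segments(L)
  }
  rownames(calls) <- NULL
  t_call <- proc.time()[["elapsed"]]

  ## stage 4: attribution and rates
  attributed <- attribute_variants(calls, segments)
  tab <- tabulate_variants(attributed, segments, L)
  rep_tabs <- NULL
  if (!is.null(replicates) && length(unique(replicates)) >= 2L) {
    labs <- split(names(replicates), as.character(replicates))
    rep_tabs <- lapply(labs, function(ids) {
      ss <- segments[segments$read_id %in% ids, , drop = FALSE]
      aa <- attributed[attributed$read_id %in% ids, , drop = FALSE]
      tabulate_variants(aa, ss, L)
    })
  }
  rates <- compute_rates(tab, rep_tabs, noise_rate)
  t_end <- proc.time()[["elapsed"]]

  report <- list(
    n_reads_in = n_reads,
    n_reads_eligible = sum(verdicts$eligible),
    n_segments = nrow(segments),
    n_calls = nrow(calls),
    n_attributed = nrow(attributed),
    n_by_origin = if (nrow(attributed))
      as.list(table(attributed$origin)) else list(),
    template_length = L,
    policy = unclass(policy), params = unclass(params),
    timings = c(segment = t_seg - t0, call = t_call - t_seg,
                rates = t_end - t_call))

  fit <- structure(list(rates = rates, tabulation = tab,
                        attributed = attributed, calls = calls,
                        segments = segments, verdicts = verdicts,
                        report = report, template = template,
                        policy = policy, params = params),
                   class = "rollseq")
  if (!is.null(out_dir)) write_rollseq_outputs(fit, out_dir)
  fit
}

write_rollseq_outputs <- function(fit, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seg <- fit$segments
  attr(seg, "template_length") <- NULL
  attr(seg, "orientation") <- NULL
  attr(seg, "mixed_orientation") <- NULL
  ## user-facing coordinates are 1-based inclusive throughout
  write_tsv0(seg, file.path(out_dir, "segments.tsv"))
  write_tsv0(fit$verdicts, file.path(out_dir, "read_verdicts.tsv"))
  write_tsv0(fit$calls, file.path(out_dir, "calls.tsv"))
  write_tsv0(fit$attributed, file.path(out_dir, "attributed.tsv"))
  per_read <- per_read_summary(fit)
  write_tsv0(per_read, file.path(out_dir, "per_read_summary.tsv"))
  rates <- fit$rates
  write_tsv0(as.data.frame(rates), file.path(out_dir, "rates.tsv"))
  jsonlite::write_json(
    list(rates = as.data.frame(rates), report = fit$report),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}

per_read_summary <- function(fit) {
  ids <- fit$verdicts$read_id[fit$verdicts$eligible]
  out <- data.frame(read_id = ids, n_concatemers = 0L, n_RNAP = 0L,
                    n_RT = 0L, n_ambiguous = 0L, stringsAsFactors = FALSE)
  ns <- table(fit$segments$read_id)
  out$n_concatemers <- as.integer(ns[out$read_id])
  if (nrow(fit$attributed)) {
    tb <- table(fit$attributed$read_id, fit$attributed$origin)
    for (col in c("RNAP", "RT", "AMBIGUOUS")) {
      if (col %in% colnames(tb)) {
        v <- tb[, col][out$read_id]
        v[is.na(v)] <- 0L
        out[[paste0("n_", if (col == "AMBIGUOUS") "ambiguous" else col)]] <-
          as.integer(v)
      }
    }
  }
  out
}

#' @export
print.rollseq <- function(x, ...) {
  cat("Roll-circle fidelity fit\n")
  cat(sprintf("  reads: %d in, %d eligible; %d concatemers; %d calls\n",
              x$report$n_reads_in, x$report$n_reads_eligible,
              x$report$n_segments, x$report$n_calls))
  print(x$rates)
  invisible(x)
}

#' Summarise a rollseq fit
#'
#' @param object a `rollseq` fit.
#' @param ... unused.
#' @return list of class `summary.rollseq` with the rate table, filter
#'   breakdown and attribution counts.
#' @export
summary.rollseq <- function(object, ...) {
  structure(list(rates = object$rates,
                 reasons = table(object$verdicts$reason),
                 origins = if (nrow(object$attributed))
                   table(object$attributed$origin) else table(character()),
                 report = object$report),
            class = "summary.rollseq")
}

#' @export
print.summary.rollseq <- function(x, ...) {
  print(x$rates)
  cat("\nread verdicts:\n")
  print(x$reasons)
  cat("\nattributed variants by origin:\n")
  print(x$origins)
  invisible(x)
}

#' Extract fitted error rates
#'
#' @param object a `rollseq` fit.
#' @param ... unused.
#' @return named numeric vector of rates (errors/base), names
#'   `origin_type` (e.g. `RNAP_substitution`, `RT_total`).
#' @export
coef.rollseq <- function(object, ...) {
  setNames(object$rates$rate,
           paste(object$rates$origin, object$rates$type, sep = "_"))
}

#' Plot a rollseq fit
#'
#' `which = "rates"` draws per-origin, per-type error rates with +/- 1 SE
#' bars; `which = "positions"` draws the positional profile of one error
#' type/origin along the template.
#'
#' @param x a `rollseq` fit.
#' @param which `"rates"` or `"positions"`.
#' @param type,origin for `which = "positions"`, the error type and
#'   origin to profile.
#' @param ... passed to the underlying graphics calls.
#' @export
plot.rollseq <- function(x, which = c("rates", "positions"),
                         type = "insertion", origin = "RT", ...) {
  which <- match.arg(which)
  if (which == "rates") {
    r <- x$rates[x$rates$type != "total", ]
    h <- matrix(r$rate * 1e6, nrow = 3,
                dimnames = list(unique(r$type), unique(r$origin)))
    bp <- graphics::barplot(h, beside = TRUE, ylab = "errors per 1e6 bases",
                            legend.text = rownames(h), ...)
    se <- matrix(r$se * 1e6, nrow = 3)
    nz <- se > 0
    if (any(nz))
      graphics::arrows(bp[nz], (h - se)[nz], bp[nz], (h + se)[nz],
                       angle = 90, code = 3, length = 0.03)
  } else {
    pp <- positional_profile(x$attributed, type, origin, x$template)
    graphics::plot(pp$profile$template_pos, pp$profile$fraction,
                   type = "h", xlab = "template position",
                   ylab = paste("fraction of", origin, type, "events"),
                   ...)
  }
  invisible(x)
}

#' Simulate reads from a fitted model
#'
#' Generates a synthetic run whose error models carry the fitted per-type
#' rates (with uniform substitution/insertion compositions), useful for
#' parametric-bootstrap style checks.
#'
#' @param object a `rollseq` fit.
#' @param nsim number of molecules.
#' @param seed integer seed (required for reproducibility).
#' @param ... passed to [sim_config()].
#' @return a [simulate_run()] result.
#' @importFrom stats simulate coef
#' @export
simulate.rollseq <- function(object, nsim = 1000L, seed = 1L, ...) {
  co <- coef(object)
  rnap <- error_model(substitution_rate = co[["RNAP_substitution"]],
                      insertion_rate = co[["RNAP_insertion"]],
                      deletion_rate = co[["RNAP_deletion"]])
  rt <- error_model(substitution_rate = co[["RT_substitution"]],
                    insertion_rate = co[["RT_insertion"]],
                    deletion_rate = co[["RT_deletion"]])
  simulate_run(sim_config(object$template, rnap_model = rnap,
                          rt_model = rt, n_molecules = nsim,
                          sequencing_noise_rate = 0, seed = seed, ...))
}
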