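## ---- internal edit machinery -------------------------------------------
## Edits share the variant-op representation used by the caller:
## type 1 = substitution, 2 = insertion (after base tpos), 3 = deletion.

TYPE_NAMES <- c("substitution", "insertion", "deletion")

empty_edits <- function() {
  data.frame(type = integer(), tpos = integer(), ref = character(),
             alt = character(), stringsAsFactors = FALSE)
}

## draw per-base errors for one synthesis pass over `seq`; substitution and
## deletion are mutually exclusive at a base, insertions land 3' of a base
draw_edits <- function(seq, model) {
  L <- nchar(seq)
  s <- model$substitution_rate
  d <- model$deletion_rate
  ii <- model$insertion_rate
  len <- model$indel_length
  out <- list()
  n_sd <- if (s + d > 0) rbinom(1L, L, s + d) else 0L
  if (n_sd > 0) {
    pos <- sort(sample.int(L, n_sd))
    is_sub <- runif(n_sd) < s / (s + d)
    if (any(is_sub)) {
      sp <- pos[is_sub]
      ref <- substring(seq, sp, sp)
      alt <- vapply(ref, function(b)
        sample(DNA_BASES, 1L, prob = model$substitution_matrix[b, ]),
        character(1), USE.NAMES = FALSE)
      out$sub <- data.frame(type = 1L, tpos = sp, ref = ref, alt = alt,
                            stringsAsFactors = FALSE)
    }
    if (any(!is_sub)) {
      dp <- pos[!is_sub]
      dl <- pmin(len, L - dp + 1L)
      ref <- substring(seq, dp, dp + dl - 1L)
      out$del <- data.frame(type = 3L, tpos = dp, ref = ref, alt = "",
                            stringsAsFactors = FALSE)
    }
  }
  n_i <- if (ii > 0) rbinom(1L, L, ii) else 0L
  if (n_i > 0) {
    ip <- sort(sample.int(L, n_i))
    alt <- vapply(seq_len(n_i), function(j)
      paste(sample(DNA_BASES, len, replace = TRUE,
                   prob = model$inserted_base_distribution), collapse = ""),
      character(1))
    out$ins <- data.frame(type = 2L, tpos = ip, ref = "", alt = alt,
                          stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty_edits())
  e <- do.call(rbind, out)
  e[order(e$tpos, e$type), , drop = FALSE]
}

## flat substitution-only residual sequencing noise
draw_noise <- function(seq, rate) {
  L <- nchar(seq)
  n <- if (rate > 0) rbinom(1L, L, rate) else 0L
  if (n == 0L) return(empty_edits())
  pos <- sort(sample.int(L, n))
  ref <- substring(seq, pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES, b), 1L),
                character(1), USE.NAMES = FALSE)
  data.frame(type = 1L, tpos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

apply_edits <- function(seq, edits) {
  if (nrow(edits) == 0L) return(seq)
  o <- order(edits$tpos, edits$type)
  .apply_calls_batch(seq, rep(1L, nrow(edits)), edits$type[o],
                     edits$tpos[o], edits$ref[o], edits$alt[o], TRUE)
}

## template <-> transcript coordinate maps induced by transcription edits
coord_maps <- function(edits, L) {
  if (nrow(edits) == 0L) {
    idx <- seq_len(L)
    return(list(t2r = idx, r2t = idx, r2t_anchor = idx,
                inserted = rep(FALSE, L)))
  }
  contrib <- rep(1L, L)
  ins_at <- integer(L)
  del <- edits[edits$type == 3L, , drop = FALSE]
  for (j in seq_len(nrow(del))) {
    dl <- nchar(del$ref[j])
    contrib[del$tpos[j]:(del$tpos[j] + dl - 1L)] <- 0L
  }
  ins <- edits[edits$type == 2L, , drop = FALSE]
  for (j in seq_len(nrow(ins)))
    ins_at[ins$tpos[j]] <- ins_at[ins$tpos[j]] + nchar(ins$alt[j])
  before <- c(0L, cumsum(contrib + ins_at))[seq_len(L)]
  t2r <- ifelse(contrib == 1L, before + 1L, NA_integer_)
  Lr <- sum(contrib + ins_at)
  r2t <- integer(Lr)
  anchor <- integer(Lr)
  for (p in seq_len(L)) {
    off <- before[p]
    if (contrib[p] == 1L) {
      r2t[off + 1L] <- p
      anchor[off + 1L] <- p
    }
    if (ins_at[p] > 0L) {
      idx <- off + contrib[p] + seq_len(ins_at[p])
      r2t[idx] <- 0L
      anchor[idx] <- p
    }
  }
  list(t2r = t2r, r2t = r2t, r2t_anchor = anchor, inserted = r2t == 0L)
}

## ---- public simulator operations ---------------------------------------

#' Simulate transcription of a circular template
#'
#' Applies the RNA polymerase error model once across the template,
#' producing the (sense-frame) sequence of one circular RNA molecule and
#' the ground-truth records of every planted error.
#'
#' @param template sense-strand template sequence (character scalar).
#' @param rnap_model an [error_model()] for the RNA polymerase.
#' @param seed optional integer seed.
#' @return list with elements `rna` (character scalar), `truth`
#'   (`data.frame` of planted errors, origin `RNAP`) and `edits`
#'   (internal op table).
#' @export
simulate_transcription <- function(template, rnap_model, seed = NULL) {
  template <- as.character(template)
  stopifnot_dna(template, "template")
  with_seed(seed, {
    edits <- draw_edits(template, rnap_model)
    rna <- apply_edits(template, edits)
    truth <- data.frame(
      origin = rep("RNAP", nrow(edits)),
      type = TYPE_NAMES[edits$type],
      template_pos = edits$tpos,
      ref = edits$ref, alt = edits$alt,
      concatemer_index = rep(NA_integer_, nrow(edits)),
      collision = rep(FALSE, nrow(edits)),
      stringsAsFactors = FALSE)
    list(rna = rna, truth = truth, edits = edits)
  })
}

#' Simulate rolling-circle reverse transcription of one RNA molecule
#'
#' Copies the circular RNA `k` times starting at `start_offset`, applying
#' the reverse-transcriptase error model independently to every copy and a
#' flat substitution-only sequencing-noise rate on top, then emits the read
#' in cDNA orientation (reverse complement of the concatenated copies).
#' Any error already present in the RNA appears identically in every copy.
#'
#' Truth positions are reported in (unrotated) RNA coordinates;
#' [simulate_run()] remaps them to template coordinates.
#' `concatemer_index` is 0-based in read order (5' to 3' along the cDNA
#' read, so the last RNA copy synthesised comes first).
#'
#' @param rna circular RNA sequence in sense frame (DNA letters).
#' @param rt_model an [error_model()] for the reverse transcriptase.
#' @param k number of concatemers (full passes around the circle).
#' @param start_offset 0-based RNA position where copying starts.
#' @param noise_rate residual per-base substitution probability of the
#'   consensus read (default 0; 1e-4 corresponds to Q40).
#' @param seed optional integer seed.
#' @return list with `read` (cDNA-orientation character scalar) and
#'   `truth` (`data.frame`, origins `RT` and `NOISE`, positions in RNA
#'   coordinates in column `rna_pos`).
#' @export
simulate_rolling_circle <- function(rna, rt_model, k, start_offset = 0L,
                                    noise_rate = 0, seed = NULL) {
  rna <- as.character(rna)
  Lr <- nchar(rna)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  start_offset <- as.integer(start_offset)
  if (start_offset < 0L || start_offset >= Lr)
    stop("start_offset must be in [0, RNA length)")
  with_seed(seed, {
    rot <- rotate_template(rna, start_offset)
    copies <- character(k)
    truth_list <- vector("list", k)
    for (i in seq_len(k)) {
      rt <- draw_edits(rot, rt_model)
      nz <- draw_noise(rot, noise_rate)
      rt$origin <- rep("RT", nrow(rt))
      nz$origin <- rep("NOISE", nrow(nz))
      all_e <- rbind(rt, nz)
      collide <- rep(FALSE, nrow(all_e))
      if (nrow(all_e) > 1L) {
        basep <- all_e$tpos[all_e$type != 2L]
        dup <- basep[duplicated(basep)]
        collide <- all_e$type != 2L & all_e$tpos %in% dup
      }
      ## apply with 'later overwrites': drop the RT substitution when a
      ## noise substitution hits the same base, drop noise subs on deleted
      ## bases; both truth records stay, flagged
      apply_e <- all_e
      if (any(collide)) {
        drop <- (apply_e$origin == "RT" & apply_e$type == 1L & collide &
                   apply_e$tpos %in% apply_e$tpos[apply_e$origin == "NOISE"]) |
                (apply_e$origin == "NOISE" & collide &
                   apply_e$tpos %in% apply_e$tpos[apply_e$type == 3L])
        apply_e <- apply_e[!drop, , drop = FALSE]
      }
      copies[i] <- apply_edits(rot, apply_e[, 1:4])
      if (nrow(all_e)) {
        truth_list[[i]] <- data.frame(
          origin = all_e$origin,
          type = TYPE_NAMES[all_e$type],
          rna_pos = ((all_e$tpos - 1L + start_offset) %% Lr) + 1L,
          ref = all_e$ref, alt = all_e$alt,
          concatemer_index = k - i,
          collision = collide,
          stringsAsFactors = FALSE)
      }
    }
    read <- revcomp(paste(copies, collapse = ""))
    truth <- do.call(rbind, truth_list)
    if (is.null(truth))
      truth <- data.frame(origin = character(), type = character(),
                          rna_pos = integer(), ref = character(),
                          alt = character(), concatemer_index = integer(),
                          collision = logical(), stringsAsFactors = FALSE)
    list(read = read, truth = truth)
  })
}

#' Simulation configuration
#'
#' Collects everything that defines a simulated sequencing run. Defaults
#' follow the measurement regime the method was designed for: concatemer
#' counts uniform on 3..10, residual consensus noise 1e-4 (Q40), pass
#' count 20 (above the >= 15 eligibility filter) and read quality 1.0.
#'
#' @param template template sequence (character scalar, e.g. from
#'   [make_template()]).
#' @param rnap_model,rt_model [error_model()] objects for transcription and
#'   reverse transcription.
#' @param n_molecules number of molecules (reads) to simulate.
#' @param concatemer_count_distribution named numeric vector mapping
#'   concatemer counts to probabilities; default uniform on `3:10`.
#' @param start_offset_mode `"fixed"` (primer-defined start at template
#'   position 0) or `"uniform"`.
#' @param sequencing_noise_rate residual substitution noise per base.
#' @param passes,read_quality pass counts and read-quality values,
#'   recycled across molecules.
#' @param seed integer seed (mandatory; a fixed seed makes
#'   [simulate_run()] byte-identical).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(template, rnap_model = error_model(),
                       rt_model = error_model(), n_molecules = 1000L,
                       concatemer_count_distribution = NULL,
                       start_offset_mode = c("fixed", "uniform"),
                       sequencing_noise_rate = 1e-4, passes = 20L,
                       read_quality = 1.0, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("seed is mandatory for simulation runs")
  start_offset_mode <- match.arg(start_offset_mode)
  template <- as.character(template)
  stopifnot_dna(template, "template")
  if (is.null(concatemer_count_distribution))
    concatemer_count_distribution <- setNames(rep(1 / 8, 8), 3:10)
  p <- concatemer_count_distribution
  if (is.null(names(p)) || any(is.na(as.integer(names(p)))))
    stop("concatemer_count_distribution must be named by integer counts")
  if (abs(sum(p) - 1) > 1e-9)
    stop("concatemer_count_distribution must sum to 1")
  n_molecules <- as.integer(n_molecules)
  if (n_molecules < 0L) stop("n_molecules must be >= 0")
  stopifnot(inherits(rnap_model, "error_model"),
            inherits(rt_model, "error_model"))
  structure(list(template = template, rnap_model = rnap_model,
                 rt_model = rt_model, n_molecules = n_molecules,
                 concatemer_count_distribution = p,
                 start_offset_mode = start_offset_mode,
                 sequencing_noise_rate = sequencing_noise_rate,
                 passes = as.integer(passes),
                 read_quality = as.numeric(read_quality),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a full sequencing run with ground truth
#'
#' For each molecule: transcribe the template once (RNA polymerase errors,
#' shared by every concatemer), then roll around the circle `k` times
#' (reverse-transcriptase errors private to one concatemer, plus residual
#' sequencing noise), and emit the read in cDNA orientation. Every planted
#' error is recorded in a truth table with template coordinates, origin
#' label and collision flag.
#'
#' Collisions -- errors of different origins landing at the same (or, for
#' indels, left-normalised adjacent) template position of one molecule, or
#' same-type errors recurring at one position across concatemers -- are
#' flagged; attribution on collided sites is not identifiable and such
#' records are excluded from accuracy accounting.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, writes `reads.fastq`,
#'   `read_meta.tsv`, `truth.tsv` and `template.fa`.
#' @return list with `reads` (`data.frame`: `read_id`, `sequence`,
#'   `passes`, `read_quality`), `truth` (`data.frame`), `template` and
#'   (when written) `paths`.
#' @export
simulate_run <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  template <- config$template
  L <- nchar(template)
  n <- config$n_molecules
  ks <- as.integer(names(config$concatemer_count_distribution))
  kp <- as.numeric(config$concatemer_count_distribution)
  passes <- rep_len(config$passes, max(n, 1L))
  rq <- rep_len(config$read_quality, max(n, 1L))

  reads <- vector("list", n)
  truths <- vector("list", n)
  for (m in seq_len(n)) {
    id <- sprintf("mol%06d", m)
    tr <- simulate_transcription(template, config$rnap_model)
    maps <- coord_maps(tr$edits, L)
    k <- if (length(ks) == 1L) ks else sample(ks, 1L, prob = kp)
    off_t <- if (config$start_offset_mode == "fixed") 0L
             else sample.int(L, 1L) - 1L
    off_r <- rna_offset_for(maps, off_t, L)
    rc <- simulate_rolling_circle(tr$rna, config$rt_model, k, off_r,
                                  config$sequencing_noise_rate)
    tru <- remap_truth(tr$truth, rc$truth, maps, template)
    tru <- flag_molecule_collisions(tru, template)
    tru$molecule_id <- rep(id, nrow(tru))
    tru$read_id <- rep(id, nrow(tru))
    reads[[m]] <- data.frame(read_id = id, sequence = rc$read,
                             passes = passes[m], read_quality = rq[m],
                             stringsAsFactors = FALSE)
    truths[[m]] <- tru
  }
  reads <- if (n > 0) do.call(rbind, reads) else
    data.frame(read_id = character(), sequence = character(),
               passes = integer(), read_quality = numeric(),
               stringsAsFactors = FALSE)
  truth_cols <- c("molecule_id", "read_id", "origin", "type",
                  "template_pos", "ref", "alt", "concatemer_index",
                  "collision")
  truth <- if (n > 0 && length(truths)) do.call(rbind, truths) else NULL
  if (is.null(truth) || nrow(truth) == 0L) {
    truth <- data.frame(molecule_id = character(), read_id = character(),
                        origin = character(), type = character(),
                        template_pos = integer(), ref = character(),
                        alt = character(), concatemer_index = integer(),
                        collision = logical(), stringsAsFactors = FALSE)
  }
  truth <- truth[, truth_cols]
  rownames(truth) <- NULL
  out <- list(reads = reads, truth = truth, template = template,
              config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(fastq = file.path(out_dir, "reads.fastq"),
                  meta = file.path(out_dir, "read_meta.tsv"),
                  truth = file.path(out_dir, "truth.tsv"),
                  template = file.path(out_dir, "template.fa"))
    write_reads_fastq(reads, paths$fastq)
    write_tsv0(reads[, c("read_id", "passes", "read_quality")], paths$meta)
    write_tsv0(truth, paths$truth)
    write_template(template, paths$template)
    out$paths <- paths
  }
  out
}

## RNA-frame offset of template position off_t (0-based), skipping bases
## the polymerase deleted
rna_offset_for <- function(maps, off_t, L) {
  t <- off_t + 1L
  for (step in 0:(L - 1L)) {
    tt <- ((t - 1L + step) %% L) + 1L
    if (!is.na(maps$t2r[tt])) return(maps$t2r[tt] - 1L)
  }
  0L
}

remap_truth <- function(rnap_truth, rc_truth, maps, template) {
  if (nrow(rc_truth)) {
    tp <- maps$r2t[rc_truth$rna_pos]
    anchor <- maps$r2t_anchor[rc_truth$rna_pos]
    on_ins <- tp == 0L
    tp[on_ins] <- anchor[on_ins]
    rc_truth$template_pos <- tp
    rc_truth$collision <- rc_truth$collision | on_ins
    ## express ref alleles in template frame where the base is a real
    ## template base (differences only arise on RNAP-edited sites, which
    ## are flagged as collisions below)
    real <- !on_ins & rc_truth$type != "insertion"
    if (any(real))
      rc_truth$ref[real] <-
        substring(template, tp[real],
                  tp[real] + nchar(rc_truth$ref[real]) - 1L)
    rc_truth$rna_pos <- NULL
  } else {
    rc_truth <- data.frame(origin = character(), type = character(),
                           ref = character(), alt = character(),
                           concatemer_index = integer(),
                           collision = logical(),
                           template_pos = integer(),
                           stringsAsFactors = FALSE)
  }
  cols <- c("origin", "type", "template_pos", "ref", "alt",
            "concatemer_index", "collision")
  rbind(rnap_truth[, cols], rc_truth[, cols])
}

## Flag attribution-breaking coincidences within one molecule: errors that
## share (or, with an indel involved, neighbour) a template position in
## the same synthesis product admit equal-score alternative alignment
## representations, and same-key errors recurring across concatemers break
## the single-vs-every support rule. Raw and left-normalized positions are
## both considered because an indel's equivalent placements span its
## homopolymer run.
flag_molecule_collisions <- function(tru, template) {
  n <- nrow(tru)
  if (n < 2L) return(tru)
  np <- normalized_positions(tru, template)
  rp <- tru$template_pos
  indel <- tru$type != "substitution"
  rnap <- tru$origin == "RNAP"
  ci <- tru$concatemer_index
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- min(abs(np[i] - np[j]), abs(rp[i] - rp[j]),
               abs(np[i] - rp[j]), abs(rp[i] - np[j]))
      interact <- d == 0L || (d <= 1L && (indel[i] || indel[j]))
      if (!interact) next
      same_product <- rnap[i] || rnap[j] ||
        (!is.na(ci[i]) && !is.na(ci[j]) && ci[i] == ci[j])
      recurring <- !rnap[i] && !rnap[j] && tru$type[i] == tru$type[j] &&
        np[i] == np[j]
      if (same_product || recurring) {
        tru$collision[i] <- TRUE
        tru$collision[j] <- TRUE
      }
    }
  }
  tru
}

normalized_positions <- function(tru, template) {
  df <- data.frame(type = tru$type, template_pos = tru$template_pos,
                   ref = tru$ref, alt = tru$alt, stringsAsFactors = FALSE)
  left_normalize(df, template)$template_pos
}

#' Simulate strand-specific consensus pairs for second-strand analysis
#'
#' Each molecule gets a cDNA strand (template copied with the cDNA-synthesis
#' error model, emitted as the reverse complement of the sense frame) and a
#' second strand synthesised from that cDNA with its own error model.
#' Errors made during cDNA synthesis are inherited by the second strand and
#' are therefore concordant between the two strands; only second-strand
#' errors appear as discordances.
#'
#' @param n_pairs number of molecules.
#' @param template sense-strand reference sequence.
#' @param cdna_model,second_model [error_model()] objects for cDNA and
#'   second-strand synthesis.
#' @param passes,read_quality per-strand metadata, recycled.
#' @param seed optional integer seed.
#' @return list with `pairs` (`data.frame`: `molecule_id`, `cdna`,
#'   `second`, per-strand `passes_*`/`rq_*`), `truth` (`data.frame` with
#'   `strand` = `cDNA`/`second`) and `cdna_reference` (the error-free cDNA
#'   sequence, 5' to 3').
#' @export
simulate_strand_pairs <- function(n_pairs, template, cdna_model,
                                  second_model, passes = 20L,
                                  read_quality = 1.0, seed = NULL) {
  template <- as.character(template)
  stopifnot_dna(template, "template")
  n_pairs <- as.integer(n_pairs)
  with_seed(seed, {
    L <- nchar(template)
    passes <- rep_len(as.integer(passes), max(n_pairs, 1L))
    rq <- rep_len(as.numeric(read_quality), max(n_pairs, 1L))
    pairs <- vector("list", n_pairs)
    truths <- vector("list", n_pairs)
    for (m in seq_len(n_pairs)) {
      id <- sprintf("pair%06d", m)
      ce <- draw_edits(template, cdna_model)
      cdna_sense <- apply_edits(template, ce)
      maps <- coord_maps(ce, L)
      se <- draw_edits(cdna_sense, second_model)
      second <- apply_edits(cdna_sense, se)
      tr <- list()
      if (nrow(ce))
        tr$c <- data.frame(molecule_id = id, strand = "cDNA",
                           type = TYPE_NAMES[ce$type], template_pos = ce$tpos,
                           ref = ce$ref, alt = ce$alt, collision = FALSE,
                           stringsAsFactors = FALSE)
      if (nrow(se)) {
        tp <- maps$r2t[se$tpos]
        anchor <- maps$r2t_anchor[se$tpos]
        on_ins <- tp == 0L
        tp[on_ins] <- anchor[on_ins]
        coll <- on_ins | tp %in% ce$tpos
        tr$s <- data.frame(molecule_id = id, strand = "second",
                           type = TYPE_NAMES[se$type], template_pos = tp,
                           ref = se$ref, alt = se$alt, collision = coll,
                           stringsAsFactors = FALSE)
      }
      pairs[[m]] <- data.frame(molecule_id = id,
                               cdna = revcomp(cdna_sense),
                               second = second,
                               passes_cdna = passes[m],
                               passes_second = passes[m],
                               rq_cdna = rq[m], rq_second = rq[m],
                               stringsAsFactors = FALSE)
      if (length(tr)) truths[[m]] <- do.call(rbind, tr)
    }
    pairs <- if (n_pairs > 0) do.call(rbind, pairs) else
      data.frame(molecule_id = character(), cdna = character(),
                 second = character(), passes_cdna = integer(),
                 passes_second = integer(), rq_cdna = numeric(),
                 rq_second = numeric(), stringsAsFactors = FALSE)
    truth <- do.call(rbind, truths)
    if (is.null(truth))
      truth <- data.frame(molecule_id = character(), strand = character(),
                          type = character(), template_pos = integer(),
                          ref = character(), alt = character(),
                          collision = logical(), stringsAsFactors = FALSE)
    rownames(pairs) <- rownames(truth) <- NULL
    list(pairs = pairs, truth = truth,
         cdna_reference = revcomp(template), template = template)
  })
}
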