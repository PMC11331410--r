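#' Read the template sequence from a FASTA file
#'
#' @param path FASTA path; the first record is used.
#' @return character scalar (upper-cased).
#' @export
read_template <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) < 1L) stop("no sequences in ", path)
  toupper(as.character(ss[[1]]))
}

#' Write a template sequence to FASTA
#'
#' @param template character scalar.
#' @param path output path.
#' @param name FASTA record name.
#' @export
write_template <- function(template, path, name = "template") {
  ss <- Biostrings::DNAStringSet(as.character(template))
  names(ss) <- name
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write reads as FASTQ
#'
#' Quality characters are constant and informational only (the consensus
#' reads carry their quality in the `read_quality` metadata, not per
#' base).
#'
#' @param reads `data.frame` with `read_id` and `sequence`.
#' @param path output path.
#' @export
write_reads_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- character(4L * nrow(reads))
  lines[seq(1L, length(lines), by = 4L)] <- paste0("@", reads$read_id)
  lines[seq(2L, length(lines), by = 4L)] <- reads$sequence
  lines[seq(3L, length(lines), by = 4L)] <- "+"
  lines[seq(4L, length(lines), by = 4L)] <-
    vapply(nchar(reads$sequence), function(n)
      strrep("~", n), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read consensus reads with pass-count and read-quality metadata
#'
#' Accepts FASTQ plus a sidecar metadata TSV (columns `read_id`, `passes`,
#' `read_quality`), or an unaligned BAM carrying the HiFi-convention
#' integer `np` (passes) and float `rq` (read quality) tags (requires the
#' Rsamtools package). Reads without resolvable metadata are excluded
#' with a message; their ids are kept in the `excluded` attribute.
#'
#' @param path FASTQ (or BAM) path.
#' @param meta metadata TSV path (ignored for BAM input).
#' @return `data.frame` with `read_id`, `sequence`, `passes`,
#'   `read_quality`.
#' @export
read_reads <- function(path, meta = NULL) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("reading BAM input requires the Rsamtools package")
    b <- Rsamtools::scanBam(
      path, param = Rsamtools::ScanBamParam(what = c("qname", "seq"),
                                            tag = c("np", "rq")))[[1]]
    out <- data.frame(read_id = b$qname,
                      sequence = as.character(b$seq),
                      passes = as.integer(b$tag$np),
                      read_quality = as.numeric(b$tag$rq),
                      stringsAsFactors = FALSE)
  } else {
    ss <- Biostrings::readDNAStringSet(path, format = "fastq")
    ids <- sub("\\s.*$", "", names(ss))
    out <- data.frame(read_id = ids, sequence = as.character(ss),
                      passes = NA_integer_, read_quality = NA_real_,
                      stringsAsFactors = FALSE)
    if (!is.null(meta)) {
      md <- read_tsv0(meta)
      i <- match(out$read_id, md$read_id)
      out$passes <- as.integer(md$passes[i])
      out$read_quality <- as.numeric(md$read_quality[i])
    }
  }
  if (anyDuplicated(out$read_id))
    stop("duplicate read_id in ", path)
  miss <- is.na(out$passes) | is.na(out$read_quality)
  excluded <- out$read_id[miss]
  if (any(miss)) {
    message(sum(miss), " read(s) excluded for missing metadata")
    out <- out[!miss, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Export variant calls as minimal VCF-like text
#'
#' One record per call against the template as the single contig; the
#' INFO field carries read and concatemer provenance. Interoperability
#' export only (no genotype columns).
#'
#' @param calls calls `data.frame` ([call_variants()]).
#' @param template template sequence.
#' @param path output path.
#' @param contig contig name for the template.
#' @export
write_calls_vcf <- function(calls, template, path, contig = "template") {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", contig, nchar(template)),
           "##INFO=<ID=READ,Number=1,Type=String,Description=\"Read id\">",
           paste0("##INFO=<ID=CONCAT,Number=1,Type=Integer,",
                  "Description=\"Concatemer index\">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    p <- calls$template_pos[i]
    type <- calls$type[i]
    if (type == "substitution") {
      pos <- p; ref <- calls$ref[i]; alt <- calls$alt[i]
    } else if (type == "deletion") {
      ## VCF-style anchor base 5' of the deleted run
      anchor_pos <- if (p == 1L) nchar(template) else p - 1L
      anchor <- substr(template, anchor_pos, anchor_pos)
      pos <- anchor_pos
      ref <- paste0(anchor, calls$ref[i]); alt <- anchor
    } else {
      anchor <- substr(template, p, p)
      pos <- p
      ref <- anchor; alt <- paste0(anchor, calls$alt[i])
    }
    recs[i] <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tREAD=%s;CONCAT=%d",
                       contig, pos, ref, alt, calls$read_id[i],
                       calls$concatemer_index[i])
  }
  writeLines(c(hdr, recs), path)
  invisible(path)
}
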