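#' Per-base polymerase error model
#'
#' Describes how a polymerase corrupts the sequence it synthesises:
#' independent per-base substitution, insertion and deletion probabilities,
#' a conditional substitution matrix (alternative base given template base)
#' and a composition for inserted bases. Substitution and deletion are
#' mutually exclusive at a given base; an insertion lands immediately 3' of
#' a base.
#'
#' @param substitution_rate,insertion_rate,deletion_rate per-base event
#'   probabilities in `[0, 1)` (errors/base).
#' @param substitution_matrix 4x4 numeric matrix with `ACGT` dimnames; row
#'   `b` is the distribution of the alternative base given template base
#'   `b` (zero diagonal, rows summing to 1). Default: uniform over the
#'   three alternatives.
#' @param inserted_base_distribution named numeric 4-vector over `ACGT`
#'   summing to 1; default uniform.
#' @param indel_length planted indel event length in bases (default 1).
#' @return an object of class `error_model`.
#' @export
#' @examples
#' error_model(substitution_rate = 3.8e-5, insertion_rate = 1.3e-5,
#'             deletion_rate = 2e-6)
error_model <- function(substitution_rate = 0, substitution_matrix = NULL,
                        insertion_rate = 0,
                        inserted_base_distribution = NULL,
                        deletion_rate = 0, indel_length = 1L) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1))
    stop("rates must be finite and in [0, 1]")
  if (substitution_rate + deletion_rate > 1)
    stop("substitution_rate + deletion_rate must be <= 1")
  if (is.null(substitution_matrix)) {
    substitution_matrix <- matrix(1 / 3, 4, 4,
                                  dimnames = list(DNA_BASES, DNA_BASES))
    diag(substitution_matrix) <- 0
  }
  m <- substitution_matrix
  if (!is.matrix(m) || !identical(dim(m), c(4L, 4L)))
    stop("substitution_matrix must be 4x4")
  if (is.null(dimnames(m))) dimnames(m) <- list(DNA_BASES, DNA_BASES)
  m <- m[DNA_BASES, DNA_BASES]
  if (any(abs(diag(m)) > 1e-12))
    stop("substitution_matrix must have a zero diagonal")
  if (any(abs(rowSums(m) - 1) > 1e-9))
    stop("substitution_matrix rows must sum to 1")
  if (is.null(inserted_base_distribution))
    inserted_base_distribution <- setNames(rep(0.25, 4), DNA_BASES)
  d <- inserted_base_distribution[DNA_BASES]
  if (any(is.na(d)) || abs(sum(d) - 1) > 1e-9)
    stop("inserted_base_distribution must be a distribution over ACGT")
  structure(list(substitution_rate = substitution_rate,
                 substitution_matrix = m,
                 insertion_rate = insertion_rate,
                 inserted_base_distribution = d,
                 deletion_rate = deletion_rate,
                 indel_length = as.integer(indel_length)),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf(paste0("<error_model> sub %.3g, ins %.3g, del %.3g",
                     " errors/base (indel length %d)\n"),
              x$substitution_rate, x$insertion_rate, x$deletion_rate,
              x$indel_length))
  invisible(x)
}

#' Reported per-enzyme error rates
#'
#' Published benchmark error rates (units of 1e-6 errors/base, with the
#' reported standard errors) for a T7 RNA polymerase and three reverse
#' transcriptases -- the Group II intron RT Induro, human LINE-1 RT and the
#' *Fasciolopsis buski* R2 RT (FBu) -- measured on the DNA1 template for
#' transcription, cDNA synthesis and second-strand synthesis. These values
#' serve as realistic defaults for the read simulator.
#'
#' @return `data.frame` with columns `enzyme`, `synthesis`
#'   (`transcription`, `cDNA` or `second_strand`), `substitution`,
#'   `deletion`, `insertion`, `total` and matching `*_se` columns, all in
#'   units of 1e-6 errors/base.
#' @export
reported_error_rates <- function() {
  df <- data.frame(
    enzyme = c("T7", "Induro", "L1-RT", "FBu",
               "Induro", "L1-RT", "FBu"),
    synthesis = c("transcription", rep("cDNA", 3), rep("second_strand", 3)),
    substitution = c(38, 57, 220, 117, 37, 567, 101),
    substitution_se = c(5, 3, 4, 67, 5, 40, 15),
    deletion = c(2, 6, 9, 7, 28, 15, 18),
    deletion_se = c(0, 1, 0, 1, 4, 4, 3),
    insertion = c(13, 49, 49, 52, 52, 132, 73),
    insertion_se = c(1, 4, 2, 12, 2, 5, 8),
    total = c(53, 113, 278, 175, 117, 714, 192),
    total_se = c(6, 2, 6, 62, 10, 47, 22),
    stringsAsFactors = FALSE)
  df
}

#' Error model preset for a benchmarked enzyme
#'
#' Builds an [error_model()] whose per-type rates are the reported values
#' from [reported_error_rates()] (converted to errors/base), with uniform
#' substitution and insertion compositions.
#'
#' @param enzyme one of `"T7"`, `"Induro"`, `"L1-RT"`, `"FBu"`.
#' @param synthesis `"transcription"`, `"cDNA"` or `"second_strand"`.
#' @return an `error_model`.
#' @export
#' @examples
#' preset_error_model("T7")
#' preset_error_model("Induro", "cDNA")
preset_error_model <- function(enzyme,
                               synthesis = c("transcription", "cDNA",
                                             "second_strand")) {
  synthesis <- match.arg(synthesis)
  tab <- reported_error_rates()
  row <- tab[tab$enzyme == enzyme & tab$synthesis == synthesis, ]
  if (nrow(row) != 1L)
    stop("no reported rates for enzyme '", enzyme, "' and synthesis '",
         synthesis, "'")
  error_model(substitution_rate = row$substitution * 1e-6,
              insertion_rate = row$insertion * 1e-6,
              deletion_rate = row$deletion * 1e-6)
}
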