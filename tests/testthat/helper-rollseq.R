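## Shared helpers and independent oracles for the test suite.

## Independent full-matrix DP for the optimal global alignment score with
## gap cost gap_open + (k - 1) * gap_ext. O(n * m * (n + m)); small inputs
## only. Deliberately written as a gap-function recursion, not the
## three-state recursion the package aligner uses.
r_align_score <- function(p, t, match = 1, mismatch = -2, go = -4,
                          ge = -1) {
  n <- nchar(p); m <- nchar(t)
  pc <- if (n) strsplit(p, "")[[1]] else character(0)
  tc <- if (m) strsplit(t, "")[[1]] else character(0)
  gapc <- function(k) go + (k - 1) * ge
  S <- matrix(-Inf, n + 1, m + 1)
  S[1, 1] <- 0
  if (n) for (i in seq_len(n)) S[i + 1, 1] <- gapc(i)
  if (m) for (j in seq_len(m)) S[1, j + 1] <- gapc(j)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    best <- S[i, j] + if (pc[i] == tc[j]) match else mismatch
    for (k in seq_len(i)) best <- max(best, S[i - k + 1, j + 1] + gapc(k))
    for (k in seq_len(j)) best <- max(best, S[i + 1, j - k + 1] + gapc(k))
    S[i + 1, j + 1] <- best
  }
  S[n + 1, m + 1]
}

## Apply linear-frame calls to a template by direct string surgery
## (independent of the package's C++ op applier).
apply_calls_r <- function(tpl, calls) {
  chars <- strsplit(tpl, "")[[1]]
  L <- length(chars)
  del <- rep(FALSE, L)
  subs <- rep(NA_character_, L)
  ins <- rep("", L + 1L)  # ins[p + 1] goes after base p (p = 0 allowed)
  for (i in seq_len(nrow(calls))) {
    p <- calls$template_pos[i]
    ty <- calls$type[i]
    if (ty == "substitution") {
      subs[p] <- calls$alt[i]
    } else if (ty == "deletion") {
      del[p:(p + nchar(calls$ref[i]) - 1L)] <- TRUE
    } else {
      ins[p + 1L] <- paste0(ins[p + 1L], calls$alt[i])
    }
  }
  out <- ins[1L]
  for (j in seq_len(L)) {
    if (!del[j]) out <- paste0(out, if (is.na(subs[j])) chars[j] else
      subs[j])
    out <- paste0(out, ins[j + 1L])
  }
  out
}

## All reads one edit away from `t` over a reduced alphabet.
single_edit_reads <- function(t, alphabet = c("A", "C")) {
  L <- nchar(t)
  chars <- strsplit(t, "")[[1]]
  out <- character(0)
  for (i in seq_len(L)) {
    pre <- substr(t, 1, i - 1); post <- substr(t, i + 1, L)
    for (b in setdiff(alphabet, chars[i]))
      out <- c(out, paste0(pre, b, post))              # substitution
    out <- c(out, paste0(pre, post))                   # deletion
  }
  for (i in 0:L) {
    pre <- substr(t, 1, i); post <- substr(t, i + 1, L)
    for (b in alphabet) out <- c(out, paste0(pre, b, post))  # insertion
  }
  out
}

## One random edit applied to `s`.
rand_edit <- function(s, alphabet = c("A", "C")) {
  L <- nchar(s)
  op <- sample(3L, 1L)
  if (op == 1L && L > 0L) {           # substitution
    i <- sample.int(L, 1L)
    b <- sample(setdiff(alphabet, substr(s, i, i)), 1L)
    paste0(substr(s, 1, i - 1), b, substr(s, i + 1, L))
  } else if (op == 2L && L > 1L) {    # deletion
    i <- sample.int(L, 1L)
    paste0(substr(s, 1, i - 1), substr(s, i + 1, L))
  } else {                            # insertion
    i <- sample.int(L + 1L, 1L) - 1L
    paste0(substr(s, 1, i), sample(alphabet, 1L), substr(s, i + 1, L))
  }
}

## Left-normalize a truth table into the same canonical key space the
## caller uses, for exact truth-vs-call comparison.
norm_truth <- function(truth, template) {
  left_normalize(truth, template)
}

## Variant key used for matching calls to truth.
call_key <- function(df) {
  paste(df$read_id, df$type, df$template_pos, df$ref, df$alt, sep = "|")
}

## A deterministic small template with homopolymer tracts, shared across
## tests.
test_template <- function(length = 1000, seed = 11) {
  make_template(length, homopolymer_spec = data.frame(
    base = c("A", "T"), length = c(6, 5), count = c(2, 1)), seed = seed)
}
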