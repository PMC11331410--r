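mk_tab <- function(rnap = c(0, 0, 0), rt = c(0, 0, 0), denom_rnap = 1e6,
                   denom_rt = 1e6) {
  counts <- rbind(RNAP = rnap, RT = rt, AMBIGUOUS = c(0, 0, 0))
  colnames(counts) <- c("substitution", "insertion", "deletion")
  structure(list(counts = counts,
                 denominators = c(RNAP = denom_rnap, RT = denom_rt),
                 n_reads = 1L, n_segments = 1L, template_length = 1L),
            class = "rollseq_tabulation")
}

test_that("rates are counts over denominators with consistent totals", {
  ## 38 substitutions, 2 deletions, 13 insertions per 1e6 bases
  tab <- mk_tab(rnap = c(38, 13, 2))
  r <- compute_rates(tab)
  g <- function(type) r$rate[r$origin == "RNAP" & r$type == type]
  expect_equal(g("substitution"), 3.8e-5)
  expect_equal(g("deletion"), 2e-6)
  expect_equal(g("insertion"), 1.3e-5)
  expect_equal(g("total"), 5.3e-5)
  expect_equal(g("total"),
               g("substitution") + g("deletion") + g("insertion"))
  ## binomial SE
  expect_equal(r$se[r$origin == "RNAP" & r$type == "substitution"],
               sqrt(3.8e-5 * (1 - 3.8e-5) / 1e6))

  expect_true(all(compute_rates(mk_tab())$rate == 0))
  bad <- mk_tab(); bad$denominators["RT"] <- 0
  expect_error(compute_rates(bad), "positive")
})

test_that("replicate labels switch the SE to the SE of the mean", {
  reps <- list(mk_tab(rnap = c(30, 10, 2)),
               mk_tab(rnap = c(40, 14, 2)),
               mk_tab(rnap = c(44, 15, 2)))
  pooled <- mk_tab(rnap = c(38, 13, 2))
  r <- compute_rates(pooled, replicates = reps)
  rr <- c(30, 40, 44) / 1e6
  expect_equal(r$se[r$origin == "RNAP" & r$type == "substitution"],
               sd(rr) / sqrt(3))
  expect_identical(unique(r$se_method), "replicate")
})

test_that("substitution spectra report the correct frames", {
  att <- data.frame(read_id = "r", type = "substitution",
                    template_pos = 1L, ref = "A", alt = "G", length = 1L,
                    support = 1L, supporting = "0", n_concatemers = 5L,
                    origin = c("RNAP", "RT"), stringsAsFactors = FALSE)
  ## RNAP: RNA frame, misincorporated ribonucleotide is the sense alt
  sp_rnap <- substitution_spectrum(att, "RNAP")
  expect_identical(sp_rnap$frame, "RNA")
  expect_equal(names(sp_rnap$misincorporated_fraction),
               c("A", "C", "G", "U"))
  expect_equal(unname(sp_rnap$misincorporated_fraction["G"]), 1)
  expect_equal(unname(sp_rnap$template_base_fraction["A"]), 1)

  ## RT: DNA frame, misincorporated dNMP is the complement of the alt
  sp_rt <- substitution_spectrum(att, "RT")
  expect_identical(sp_rt$frame, "DNA")
  expect_equal(unname(sp_rt$template_base_fraction["A"]), 1)
  expect_equal(unname(sp_rt$misincorporated_fraction["C"]), 1)

  ## complementation is an involution back to the sense frame
  for (b in c("A", "C", "G", "T"))
    expect_identical(rollseq:::complement_base(
      rollseq:::complement_base(b)), b)

  df <- as.data.frame(sp_rt)
  expect_equal(nrow(df), 16L)
  expect_equal(sum(df$count), 1L)
})

test_that("mutation classes split 4 transitions / 8 transversions", {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ref = bases, alt = bases,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  cls <- classify_mutation(pairs$ref, pairs$alt, "RT")
  expect_equal(sum(cls == "transition"), 4L)
  expect_equal(sum(cls != "transition"), 8L)
  expect_identical(classify_mutation("A", "G", "RNAP"), "transition")
  ## sense A>C for an RT means template A paired with incorporated dG
  expect_identical(classify_mutation("A", "C", "RT"),
                   "transversion_purine_purine")
  expect_error(classify_mutation("A", "A"), "differ")
  expect_error(classify_mutation("N", "A"), "must be")
})

test_that("template-base fractions recover a biased composition", {
  ## template with ~68% adenine: with a uniform per-base rate the
  ## expected template-A share of substitution events is the A content
  set.seed(91)
  bases <- sample(c("A", "C", "G", "T"), 2000, TRUE,
                  prob = c(0.68, 0.32 / 3, 0.32 / 3, 0.32 / 3))
  tpl <- paste(bases, collapse = "")
  p_a <- mean(bases == "A")
  em <- error_model(substitution_rate = 2e-3)
  rows <- list()
  for (i in 1:200) {
    tr <- simulate_transcription(tpl, em)
    if (nrow(tr$truth)) rows[[length(rows) + 1L]] <- tr$truth
  }
  tru <- do.call(rbind, rows)
  att <- data.frame(read_id = "r", type = tru$type,
                    template_pos = tru$template_pos, ref = tru$ref,
                    alt = tru$alt, length = 1L, support = 1L,
                    supporting = "0", n_concatemers = 3L,
                    origin = "RNAP", stringsAsFactors = FALSE)
  sp <- substitution_spectrum(att, "RNAP")
  n <- sp$n
  expect_gt(n, 400)
  expect_lt(abs(unname(sp$template_base_fraction["A"]) - p_a),
            3 * sqrt(p_a * (1 - p_a) / n))
})

test_that("positional profiles locate hotspots and homopolymers", {
  tpl <- make_template(1000, homopolymer_spec = data.frame(
    base = "A", length = 6, count = 1), seed = 13)
  hp <- attr(tpl, "homopolymers")
  ## all insertions at one position: fraction 1, sole hotspot
  att <- data.frame(read_id = "r", type = "insertion",
                    template_pos = 500L, ref = "", alt = "T",
                    length = 1L, support = 1L, supporting = "0",
                    n_concatemers = 4L, origin = "RT",
                    stringsAsFactors = FALSE)
  att <- att[rep(1, 20), ]
  pp <- positional_profile(att, "insertion", "RT", tpl)
  expect_equal(pp$profile$fraction[500], 1)
  expect_equal(sum(pp$profile$fraction), 1)
  expect_equal(nrow(pp$hotspots), 1L)
  expect_equal(pp$hotspots$template_pos, 500L)
  expect_equal(nchar(pp$hotspots$context), 7L)

  ## deletions planted anywhere in a homopolymer run normalize into it
  del <- data.frame(read_id = "r", concatemer_index = 0L,
                    type = "deletion",
                    template_pos = hp$start + 0:5, ref = "A", alt = "",
                    length = 1L, stringsAsFactors = FALSE)
  del <- left_normalize(del, tpl)
  att2 <- data.frame(read_id = "r", type = del$type,
                     template_pos = del$template_pos, ref = del$ref,
                     alt = del$alt, length = 1L, support = 1L,
                     supporting = "0", n_concatemers = 4L, origin = "RT",
                     stringsAsFactors = FALSE)
  pp2 <- positional_profile(att2, "deletion", "RT", tpl)
  hit <- pp2$profile[pp2$profile$count > 0, ]
  expect_true(all(hit$in_homopolymer))
  expect_true(all(hit$run_base == "A"))

  ## uniform planting: no position dominates beyond sampling noise
  set.seed(17)
  pos <- sample.int(1000, 10000, TRUE)
  att3 <- data.frame(read_id = "r", type = "insertion",
                     template_pos = pos, ref = "", alt = "T",
                     length = 1L, support = 1L, supporting = "0",
                     n_concatemers = 4L, origin = "RT",
                     stringsAsFactors = FALSE)
  pp3 <- positional_profile(att3, "insertion", "RT", tpl)
  p0 <- 1 / 1000
  ## multinomial bin SD, with the usual extreme-value allowance over
  ## 1000 bins (the max of 1000 bins regularly exceeds mean + 3 SD)
  expect_lt(max(pp3$profile$fraction),
            p0 + 5 * sqrt(p0 * (1 - p0) / 10000))
  expect_lt(abs(max(pp3$profile$fraction) - p0),
            5 * sqrt(p0 * (1 - p0) / 10000))
})
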