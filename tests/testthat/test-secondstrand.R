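mk_pair <- function(ref, cdna = NULL, second = NULL, passes = 20L,
                    rq = 1.0) {
  cdna <- cdna %||% ref
  second <- second %||% revcomp(cdna)
  data.frame(molecule_id = "p1", cdna = cdna, second = second,
             passes_cdna = passes, passes_second = passes,
             rq_cdna = rq, rq_second = rq, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("strand-pair filters fire with inclusive length tolerance", {
  tpl <- test_template(300)
  ref <- revcomp(tpl)  # expected cDNA reference
  ok <- mk_pair(ref)
  expect_true(filter_strand_pair(ok, reference = ref)$eligible)

  ## +10 bases keeps the end motifs and is still eligible (inclusive)
  plus10 <- mk_pair(ref, cdna = paste0(substr(ref, 1, 8),
                                       strrep("A", 10),
                                       substr(ref, 9, 300)))
  plus10$second <- revcomp(plus10$cdna)
  v10 <- filter_strand_pair(plus10, reference = ref)
  expect_true(v10$eligible)

  plus11 <- mk_pair(ref, cdna = paste0(substr(ref, 1, 8),
                                       strrep("A", 11),
                                       substr(ref, 9, 300)))
  plus11$second <- revcomp(plus11$cdna)
  v11 <- filter_strand_pair(plus11, reference = ref)
  expect_false(v11$eligible)
  expect_identical(v11$reason, "length")

  ## missing 5' motif
  nom <- mk_pair(ref, cdna = paste0("TTTTTTTT", substr(ref, 9, 300)))
  nom$second <- revcomp(nom$cdna)
  vm <- filter_strand_pair(nom, reference = ref)
  expect_false(vm$eligible)
  expect_identical(vm$reason, "end_motif")

  vp <- filter_strand_pair(mk_pair(ref, passes = 14L), reference = ref)
  expect_identical(vp$reason, "min_passes")
  vq <- filter_strand_pair(mk_pair(ref, rq = 0.99), reference = ref)
  expect_identical(vq$reason, "read_quality")
})

test_that("perfectly complementary strands show zero discordance", {
  tpl <- test_template(300)
  cmp <- compare_strands(mk_pair(revcomp(tpl)))
  expect_equal(cmp$matches, 300L)
  expect_equal(cmp$substitutions + cmp$deletions + cmp$insertions, 0L)
  expect_equal(cmp$aligned_length, 300L)
})

test_that("a single second-strand substitution is one discordance", {
  tpl <- test_template(300)
  cdna <- revcomp(tpl)
  ## second strand carries one error in its own frame
  second <- revcomp(cdna)
  b <- substr(second, 100, 100)
  alt <- setdiff(c("A", "C", "G", "T"), b)[1]
  second <- paste0(substr(second, 1, 99), alt, substr(second, 101, 300))
  cmp <- compare_strands(mk_pair(cdna, cdna = cdna, second = second))
  expect_equal(cmp$substitutions, 1L)
  expect_equal(cmp$deletions + cmp$insertions, 0L)
  d <- attr(cmp, "discordances")
  expect_equal(nrow(d), 1L)
  ## the incorporated base is the second strand's own base
  expect_identical(d$incorporated, alt)
})

test_that("strand comparison is reverse-complement involutive", {
  tpl <- test_template(300)
  sp <- simulate_strand_pairs(10, tpl,
                              error_model(substitution_rate = 2e-3,
                                          insertion_rate = 5e-4,
                                          deletion_rate = 5e-4),
                              error_model(substitution_rate = 2e-3,
                                          insertion_rate = 5e-4,
                                          deletion_rate = 5e-4),
                              seed = 31)
  for (i in 1:10) {
    p <- sp$pairs[i, ]
    swapped <- p
    swapped$cdna <- revcomp(p$second)
    swapped$second <- revcomp(p$cdna)
    c1 <- compare_strands(p)
    c2 <- compare_strands(swapped)
    expect_equal(c1$substitutions + c1$deletions + c1$insertions,
                 c2$substitutions + c2$deletions + c2$insertions)
    expect_equal(c1$substitutions, c2$substitutions)
  }
})

test_that("shared cDNA-synthesis errors are invisible to the comparison", {
  tpl <- test_template(500)
  sp <- simulate_strand_pairs(50, tpl,
                              error_model(substitution_rate = 2e-3,
                                          insertion_rate = 2e-4,
                                          deletion_rate = 2e-4),
                              error_model(), seed = 32)
  expect_gt(sum(sp$truth$strand == "cDNA"), 0)
  cmp <- compare_strand_pairs(sp$pairs)
  expect_true(all(cmp$substitutions == 0))
  expect_true(all(cmp$deletions == 0))
  expect_true(all(cmp$insertions == 0))
})

test_that("second-strand rates pool counts over aligned bases", {
  tpl <- test_template(400)
  sp <- simulate_strand_pairs(300, tpl, error_model(),
                              error_model(substitution_rate = 5.67e-4,
                                          deletion_rate = 1.5e-5,
                                          insertion_rate = 1.32e-4),
                              seed = 34)
  cmp <- compare_strand_pairs(sp$pairs)
  r <- second_strand_rates(cmp)
  expect_identical(unique(r$origin), "second_strand")
  inj <- c(substitution = 5.67e-4, deletion = 1.5e-5,
           insertion = 1.32e-4)
  for (ty in names(inj)) {
    row <- r[r$type == ty, ]
    se <- sqrt(inj[[ty]] * (1 - inj[[ty]]) / row$denominator)
    expect_lt(abs(row$rate - inj[[ty]]), 3 * se + 1e-12)
  }
  ## doubling all comparisons leaves rates unchanged
  r2 <- second_strand_rates(rbind(cmp, cmp))
  expect_equal(r2$rate, r$rate)
  expect_equal(r2$count, 2L * r$count)

  expect_error(second_strand_rates(cmp[cmp$eligible == FALSE, ]),
               "eligible")
})
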