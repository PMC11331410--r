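test_that("zero-rate models leave sequences untouched", {
  tpl <- test_template(300)
  tr <- simulate_transcription(tpl, error_model(), seed = 1)
  expect_identical(tr$rna, as.character(tpl))
  expect_equal(nrow(tr$truth), 0L)
  rc <- simulate_rolling_circle(tpl, error_model(), 4, 0, 0, seed = 2)
  expect_identical(rc$read, revcomp(strrep(tpl, 4)))
  expect_equal(nrow(rc$truth), 0L)
})

test_that("forced substitutions produce the forced outcome", {
  m <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                       c("A", "C", "G", "T")))
  m["A", "G"] <- 1
  m["C", "A"] <- m["G", "A"] <- m["T", "A"] <- 1
  em <- error_model(substitution_rate = 1, substitution_matrix = m)
  tr <- simulate_transcription("AAAA", em, seed = 1)
  expect_identical(tr$rna, "GGGG")
  expect_equal(nrow(tr$truth), 4L)
  expect_true(all(tr$truth$origin == "RNAP"))
  expect_true(all(tr$truth$ref == "A" & tr$truth$alt == "G"))
})

test_that("an RNA-level error appears in every concatemer of the read", {
  tpl <- test_template(300)
  rna <- paste0(substr(tpl, 1, 149), "G", substr(tpl, 151, 300))
  stopifnot(substr(tpl, 150, 150) != "G")
  rc <- simulate_rolling_circle(rna, error_model(), 4, 0, 0, seed = 3)
  sense <- revcomp(rc$read)
  for (i in 0:3)
    expect_identical(substr(sense, i * 300 + 150, i * 300 + 150), "G")
})

test_that("planted error counts follow their Poisson expectations", {
  tpl <- make_template(1000, seed = 5)
  ## transcription at 3.8e-5 errors/base over 1e7 bases -> mean 380
  em <- error_model(substitution_rate = 3.8e-5)
  set.seed(101)
  total <- 0L
  for (i in 1:10000)
    total <- total + nrow(simulate_transcription(tpl, em)$truth)
  expect_lt(abs(total - 380), 3 * sqrt(380))

  ## reverse transcription at 5.7e-5 errors/base over 5e6 bases -> 285
  rt <- error_model(substitution_rate = 5.7e-5)
  set.seed(102)
  total <- 0L
  for (i in 1:1000)
    total <- total + nrow(simulate_rolling_circle(tpl, rt, 5, 0, 0)$truth)
  expect_lt(abs(total - 285), 3 * sqrt(285))
})

test_that("simulate_run handles the empty case and is byte-deterministic", {
  tpl <- test_template(300)
  d1 <- file.path(tempdir(), "simrun1")
  d2 <- file.path(tempdir(), "simrun2")
  cfg0 <- sim_config(tpl, n_molecules = 0, seed = 1)
  res0 <- simulate_run(cfg0, out_dir = d1)
  expect_equal(nrow(res0$reads), 0L)
  expect_equal(nrow(res0$truth), 0L)
  expect_equal(length(readLines(res0$paths$fastq)), 0L)
  expect_equal(length(readLines(res0$paths$truth)), 1L)  # header only

  cfg <- sim_config(tpl, rnap_model = preset_error_model("T7"),
                    rt_model = preset_error_model("Induro", "cDNA"),
                    n_molecules = 40, seed = 9)
  r1 <- simulate_run(cfg, out_dir = d1)
  r2 <- simulate_run(cfg, out_dir = d2)
  for (f in c("reads.fastq", "read_meta.tsv", "truth.tsv", "template.fa"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  ## a different seed must give different reads
  cfg2 <- sim_config(tpl, rnap_model = preset_error_model("T7"),
                     rt_model = preset_error_model("Induro", "cDNA"),
                     n_molecules = 40, seed = 10)
  r3 <- simulate_run(cfg2)
  expect_false(identical(r1$reads$sequence, r3$reads$sequence))
})

test_that("concatemer counts have the configured distribution", {
  tpl <- test_template(300)
  cfg <- sim_config(tpl, n_molecules = 2000, seed = 21,
                    sequencing_noise_rate = 0)
  sim <- simulate_run(cfg)
  k <- round(nchar(sim$reads$sequence) / 300)
  expect_true(all(k >= 3 & k <= 10))
  ## mean of uniform(3..10) = 6.5, var = (8^2 - 1) / 12
  se <- sqrt((64 - 1) / 12 / 2000)
  expect_lt(abs(mean(k) - 6.5), 3 * se)
})

test_that("every truth record is re-derivable from the emitted read", {
  tpl <- test_template(400)
  ## substitutions only, so copy boundaries stay exact and each record
  ## can be checked by direct string comparison
  cfg <- sim_config(tpl,
                    rnap_model = error_model(substitution_rate = 2e-3),
                    rt_model = error_model(substitution_rate = 2e-3),
                    n_molecules = 40, sequencing_noise_rate = 1e-3,
                    seed = 33)
  sim <- simulate_run(cfg)
  L <- 400L
  for (i in seq_len(nrow(sim$reads))) {
    id <- sim$reads$read_id[i]
    sense <- revcomp(sim$reads$sequence[i])
    k <- nchar(sense) / L
    tru <- sim$truth[sim$truth$read_id == id, ]
    for (j in seq_len(nrow(tru))) {
      p <- tru$template_pos[j]
      if (tru$origin[j] == "RNAP") {
        for (c in 0:(k - 1))
          if (!tru$collision[j])
            expect_identical(substr(sense, c * L + p, c * L + p),
                             tru$alt[j])
      } else if (!tru$collision[j]) {
        c <- k - 1 - tru$concatemer_index[j]  # read-order -> sense-order
        expect_identical(substr(sense, c * L + p, c * L + p), tru$alt[j])
      }
    }
  }
  ## and positions not in the truth table match the template
  clean <- sim$reads$read_id[!(sim$reads$read_id %in% sim$truth$read_id)]
  for (id in head(clean, 5)) {
    sense <- revcomp(sim$reads$sequence[sim$reads$read_id == id])
    expect_identical(sense, strrep(tpl, nchar(sense) / L))
  }
})

test_that("strand pairs are complementary except for planted errors", {
  tpl <- test_template(300)
  sp0 <- simulate_strand_pairs(5, tpl, error_model(), error_model(),
                               seed = 2)
  for (i in 1:5)
    expect_identical(revcomp(sp0$pairs$second[i]), sp0$pairs$cdna[i])

  ## exactly one planted second-strand substitution -> one discordance
  set.seed(41)
  found <- FALSE
  sp1 <- simulate_strand_pairs(200, tpl, error_model(),
                               error_model(substitution_rate = 1 / 300),
                               seed = 41)
  one <- table(sp1$truth$molecule_id)
  ids <- names(one)[one == 1]
  expect_gt(length(ids), 0)
  for (id in head(ids, 10)) {
    i <- which(sp1$pairs$molecule_id == id)
    a <- strsplit(revcomp(sp1$pairs$second[i]), "")[[1]]
    b <- strsplit(sp1$pairs$cdna[i], "")[[1]]
    expect_equal(sum(a != b), 1L)
  }
})

test_that("second-strand substitution counts follow Poisson expectation", {
  tpl <- make_template(1000, seed = 6)
  ## 5.67e-4 errors/base over 1e6 bases -> mean 567
  sp <- simulate_strand_pairs(1000, tpl, error_model(),
                              error_model(substitution_rate = 5.67e-4),
                              seed = 55)
  n <- sum(sp$truth$strand == "second" &
             sp$truth$type == "substitution")
  expect_lt(abs(n - 567), 3 * sqrt(567))
})
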