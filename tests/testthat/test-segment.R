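test_that("exact concatemeric reads segment into full copies", {
  tpl <- test_template(300)
  ## cDNA orientation: 4 exact copies
  read <- revcomp(strrep(tpl, 4))
  segs <- segment_read(read, tpl, check_repeats = FALSE)
  expect_equal(nrow(segs), 4L)
  expect_true(all(segs$orientation == "reverse"))
  expect_true(all(segs$rotation_offset == 0L))
  expect_true(all(segs$sequence == as.character(tpl)))
  expect_equal(segs$concatemer_index, 0:3)

  ## forward orientation too
  segs_f <- segment_read(strrep(tpl, 3), tpl, check_repeats = FALSE)
  expect_equal(nrow(segs_f), 3L)
  expect_true(all(segs_f$orientation == "forward"))
})

test_that("trailing partial copies are excluded", {
  tpl <- test_template(300)
  read <- paste0(strrep(tpl, 3), substr(tpl, 1, 150))
  segs <- segment_read(read, tpl, check_repeats = FALSE)
  expect_equal(nrow(segs), 3L)
  expect_true(all(segs$read_end <= 900))

  ## and a read shorter than the template yields nothing
  expect_equal(nrow(segment_read(substr(tpl, 1, 200), tpl,
                                 check_repeats = FALSE)), 0L)
})

test_that("rotated starts are detected and reported 0-based", {
  tpl <- test_template(300)
  for (off in c(0L, 37L, 250L)) {
    read <- revcomp(strrep(rotate_template(tpl, off), 5))
    segs <- segment_read(read, tpl, check_repeats = FALSE)
    expect_equal(nrow(segs), 5L)
    expect_true(all(segs$rotation_offset == off))
    expect_true(all(segs$sequence == rotate_template(tpl, off)))
  }
})

test_that("segmentation is reverse-complement equivariant", {
  tpl <- test_template(300)
  body <- strrep(tpl, 4)
  ## plant one substitution so the read is not trivially symmetric
  substr(body, 450, 450) <- if (substr(body, 450, 450) == "A") "C" else "A"
  fwd <- segment_read(body, tpl, check_repeats = FALSE)
  rev <- segment_read(revcomp(body), tpl, check_repeats = FALSE)
  n <- nchar(body)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(rev$read_start, sort(n - fwd$read_end + 1L))
  expect_equal(rev$read_end, sort(n - fwd$read_start + 1L))
  expect_true(all(fwd$orientation == "forward"))
  expect_true(all(rev$orientation == "reverse"))
  expect_identical(sort(fwd$sequence), sort(rev$sequence))
})

test_that("segments never overlap and stay within the read", {
  tpl <- test_template(500)
  cfg <- sim_config(tpl, rnap_model = preset_error_model("T7"),
                    rt_model = preset_error_model("L1-RT", "cDNA"),
                    n_molecules = 30, start_offset_mode = "uniform",
                    seed = 14)
  sim <- simulate_run(cfg)
  for (i in seq_len(nrow(sim$reads))) {
    segs <- segment_read(sim$reads[i, ], tpl, check_repeats = FALSE)
    expect_true(all(segs$read_start >= 1))
    expect_true(all(segs$read_end <= nchar(sim$reads$sequence[i])))
    if (nrow(segs) > 1)
      expect_true(all(segs$read_start[-1] > segs$read_end[-nrow(segs)]))
  }
})

test_that("segmentation recovers planted concatemer structure", {
  tpl <- test_template(1000)
  cfg <- sim_config(tpl, rnap_model = preset_error_model("T7"),
                    rt_model = preset_error_model("Induro", "cDNA"),
                    n_molecules = 150, sequencing_noise_rate = 1e-4,
                    seed = 15)
  sim <- simulate_run(cfg)
  planted <- round(nchar(sim$reads$sequence) / 1000)
  found <- integer(nrow(sim$reads))
  for (i in seq_len(nrow(sim$reads)))
    found[i] <- nrow(segment_read(sim$reads[i, ], tpl,
                                  check_repeats = FALSE))
  ## recall at paper-scale error rates
  expect_gte(sum(found) / sum(planted), 0.999)
})

test_that("eligibility filters fire in the documented order", {
  tpl <- test_template(300)
  policy <- filter_policy()
  mk_read <- function(k, passes = 20L, rq = 1.0) {
    list(reads = data.frame(read_id = "r", passes = passes,
                            read_quality = rq,
                            sequence = revcomp(strrep(tpl, k)),
                            stringsAsFactors = FALSE))
  }
  check <- function(k, passes, rq, expect_reason) {
    r <- mk_read(k, passes, rq)$reads
    segs <- segment_read(r, tpl, policy, check_repeats = FALSE)
    v <- filter_read(r, segs, policy, 300L)
    expect_identical(v$reason, expect_reason)
    expect_identical(v$eligible, expect_reason == "ok")
  }
  check(5, 14L, 1.0, "min_passes")
  check(5, 20L, 0.99, "read_quality")
  check(2, 20L, 1.0, "min_concatemers")
  check(11, 20L, 1.0, "max_concatemers")
  check(5, 20L, 1.0, "ok")

  ## partial mapping: one segment grossly short
  r <- mk_read(4)$reads
  segs <- segment_read(r, tpl, policy, check_repeats = FALSE)
  segs$length[2] <- 250L
  expect_identical(filter_read(r, segs, policy, 300L)$reason, "full_map")

  ## divergence cap (filled in by alignment downstream)
  segs <- segment_read(r, tpl, policy, check_repeats = FALSE)
  segs$divergence[1] <- 0.2
  expect_identical(filter_read(r, segs, policy, 300L)$reason,
                   "divergence")
})

test_that("mixed-orientation chimeras get a dedicated reason code", {
  tpl <- test_template(300)
  read <- paste0(strrep(tpl, 2), revcomp(strrep(tpl, 2)))
  segs <- segment_read(read, tpl, check_repeats = FALSE)
  expect_true(attr(segs, "mixed_orientation"))
  r <- data.frame(read_id = "chimera", passes = 20L, read_quality = 1.0)
  v <- filter_read(r, segs, filter_policy(), 300L)
  expect_false(v$eligible)
  expect_identical(v$reason, "mixed_orientation")
})

test_that("repeat-bearing templates trigger a warning", {
  tpl <- test_template(300)
  rep_tpl <- paste0(substr(tpl, 1, 250), substr(tpl, 1, 50))
  expect_warning(segment_read(revcomp(strrep(rep_tpl, 3)), rep_tpl),
                 "repeated")
})
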