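test_that("transcript fixture satisfies its construction guarantees", {
  fx <- make_transcript_fixture(rng_seed = 1)
  tr <- fx$transcript
  win <- fx$editing$editable_window
  expect_equal(length(tr$exon_boundaries), 6L)
  expect_equal(nchar(tr$sequence), 1200L)
  # window GC within 0.02 of 0.68 by direct count
  expect_lt(abs(gc_content(substr(tr$sequence, win[1], win[2])) - 0.68),
            0.02)
  # 200-nt antisense footprint
  fp <- tr$antisense_footprint
  expect_equal(fp[2] - fp[1] + 1L, 200L)
  # exactly two engineered PTC cytosines, both NMD-eligible
  ptc <- scan_ptc(tr, fx$engineered_sites)
  expect_equal(nrow(ptc), 2L)
  expect_true(all(ptc$nmd_eligible))
  # deterministic given seed
  expect_identical(make_transcript_fixture(5)$transcript$sequence,
                   make_transcript_fixture(5)$transcript$sequence)
  # fixtures round-trip through FASTA + layout JSON
  fa <- withr::local_tempfile(fileext = ".fa")
  js <- withr::local_tempfile(fileext = ".json")
  write_transcript_model(tr, fa, js)
  back <- read_transcript_model(fa, js)
  expect_identical(back$sequence, tr$sequence)
  expect_identical(back$exon_boundaries, tr$exon_boundaries)
})

test_that("founder populations match the stated cycle statistics", {
  pop <- make_lineage(rng_seed = 2, n_cells = 1000, cycle_mean = 900)
  expect_lt(abs(mean(pop$cycle_length) - 900) / 900, 0.05)
  expect_true(all(pop$position >= 0 & pop$position <= pop$cycle_length))
  sync <- make_lineage(rng_seed = 2, n_cells = 100, synchronized = TRUE)
  expect_true(all(sync$position == 0))
  expect_identical(make_lineage(3, 50), make_lineage(3, 50))
})

test_that("null ct tables are exchangeable and shifted ones are detected", {
  null_tab <- make_ct_table(rng_seed = 5, shift = 0, n_replicates = 6)
  frac <- function(tab, cond) {
    reps <- unique(tab$replicate[tab$condition == cond])
    t(vapply(reps, function(r)
      unclass(normalize_zones(tab$delta_ct[tab$replicate == r])),
      numeric(5)))
  }
  res <- zone_shift_test(frac(null_tab, "shifted"),
                         frac(null_tab, "baseline"),
                         n_perm = 1000, rng_seed = 1)
  expect_gt(res$p_value, 0.05)

  # power >= 0.9 at the default shift with n = 6 replicates
  hits <- 0
  n_sets <- 30
  for (i in seq_len(n_sets)) {
    tab <- make_ct_table(rng_seed = 100 + i, shift = 1, n_replicates = 6)
    p <- zone_shift_test(frac(tab, "shifted"), frac(tab, "baseline"),
                         n_perm = 500, rng_seed = i)$p_value
    if (p <= 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_sets, 0.9)
})

test_that("event-stream generator recovers the target slope ratio", {
  # a single 1500-min stream at the perturbed rate holds only ~55 events,
  # so the ratio is checked on the seed-averaged estimator
  rs <- vapply(1:10, function(s) {
    st <- make_event_streams(rng_seed = s, rate_a = 0.2, ratio = 5.4)
    fit_a <- linear_rate(cumulative_curve(st$a, 10, 1500))
    fit_b <- linear_rate(cumulative_curve(st$b, 10, 1500))
    rate_fold_change(fit_a, fit_b)$ratio
  }, numeric(1))
  expect_lt(abs(mean(rs) - 5.4) / 5.4, 0.10)

  st1 <- make_event_streams(rng_seed = 2, rate_a = 0.2, ratio = 1)
  f1 <- rate_fold_change(
    linear_rate(cumulative_curve(st1$a, 10, 1500)),
    linear_rate(cumulative_curve(st1$b, 10, 1500)))
  expect_lt(abs(f1$ratio - 1), 0.15)

  # an (almost surely) empty stream still yields a valid curve
  st0 <- make_event_streams(rng_seed = 3, rate_a = 1e-9, ratio = 1)
  cc <- cumulative_curve(st0$a, 10, 1500)
  expect_true(all(cc$count == 0))
})

test_that("read mixtures reflect the edited fraction at engineered sites", {
  fx <- make_transcript_fixture(1)
  pure <- make_read_mixture(rng_seed = 1, fixture = fx,
                            edited_fraction = 0, depth = 300)
  expect_true(all(pure$n_T == 0))

  mx <- make_read_mixture(rng_seed = 2, fixture = fx,
                          edited_fraction = 0.32, depth = 500)
  expect_equal(sum(mx$engineered), 2L)
  est <- estimate_edited_fraction(mx)
  expect_lt(abs(est - 0.32), 0.03)
  # engineered sites carry the full edited fraction; background sites less
  expect_lte(mean(mx$prop_T[!mx$engineered]),
             mean(mx$prop_T[mx$engineered]))
  expect_error(make_read_mixture(1, fx, edited_fraction = 2), "in \\[0, 1\\]")
})
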