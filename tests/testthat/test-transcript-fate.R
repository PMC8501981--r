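test_that("transcript_model validates its layout invariants", {
  expect_error(transcript_model("x", "ACGTACGT", c(4, 3, 8), 1, c(1, 4)),
               "strictly increasing")
  expect_error(transcript_model("x", "ACGTACGT", c(4, 7), 1, c(1, 4)),
               "sequence length")
  expect_error(transcript_model("x", "ACGTACGT", c(4, 8), 99, c(1, 4)),
               "cds_start")
  expect_error(transcript_model("x", "ACGUACGU", c(4, 8), 1, c(1, 4)),
               "A,C,G,T")
  m <- transcript_model("x", "acgtacgt", c(4, 8), 1, c(1, 4))
  expect_s3_class(m, "transcript_model")
  expect_identical(m$sequence, "ACGTACGT")
})

test_that("gc_content counts G+C over called bases only", {
  expect_equal(gc_content("GGCC"), 1)
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("ATGCNN"), 0.5)
  expect_error(gc_content("ATXG"), "A,C,G,T,N")
})

test_that("scan_ptc returns nothing without edits and finds the toy stop", {
  toy <- ptc_toy()
  expect_identical(nrow(scan_ptc(toy, integer(0))), 0L)

  # editing the C of the CGA codon (position 10) creates a TGA stop whose
  # end (12) sits 68 nt upstream of the junction at 80
  res <- scan_ptc(toy, 10L)
  expect_equal(nrow(res), 1L)
  expect_equal(res$position, 10L)
  expect_equal(res$codon, "TGA")
  expect_equal(res$distance_to_downstream_junction, 80 - 12)
  expect_true(res$nmd_eligible)
  # with a sterner threshold the same stop is not an NMD substrate
  expect_false(scan_ptc(toy, 10L, nmd_threshold = 70)$nmd_eligible)
})

test_that("scan_ptc rejects edits at non-C reference positions", {
  toy <- ptc_toy()
  expect_error(scan_ptc(toy, 1L), "non-C reference position: 1")
  expect_error(scan_ptc(toy, 9999L), "outside sequence")
})

test_that("packaged fixture carries two engineered NMD-eligible PTCs", {
  fx <- make_transcript_fixture(rng_seed = 1)
  res <- scan_ptc(fx$transcript, fx$engineered_sites)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$nmd_eligible))
  # penultimate and antepenultimate exons
  ex <- nascycle:::exon_of_position(fx$transcript, res$position)
  expect_setequal(ex, c(4L, 5L))
})

test_that("scan_ptc agrees with the brute-force codon-walk oracle", {
  set.seed(41)
  for (i in 1:200) {
    tr <- random_transcript(len = sample(60:300, 1),
                            n_exons = sample(2:5, 1))
    chars <- strsplit(tr$sequence, "", fixed = TRUE)[[1L]]
    cs <- which(chars == "C")
    edits <- if (length(cs)) sort(sample(cs, min(length(cs),
                                                 sample(0:8, 1)))) else
      integer(0)
    got <- scan_ptc(tr, edits)
    want <- oracle_ptc_scan(tr$sequence, tr$cds_start, edits,
                            tr$exon_boundaries)
    expect_equal(got$position, want$position)
    expect_equal(got$codon, want$codon)
    expect_equal(got$distance_to_downstream_junction, want$distance)
    expect_equal(got$nmd_eligible, want$eligible)
  }
})

test_that("nmd_eligible follows the junction-distance rule", {
  expect_true(nmd_eligible(100, 50))
  expect_false(nmd_eligible(20, 50))
  expect_false(nmd_eligible(NA_real_, 50))  # stop in the last exon
  expect_error(nmd_eligible(10, 0), "> 0")
})

test_that("apply_editing respects masking and per-site probabilities", {
  fx <- make_transcript_fixture(1)
  m0 <- editing_model(p_edit_unmasked = 0, editable_window = c(641, 840))
  out <- apply_editing(fx$transcript, m0, masked = FALSE, rng_seed = 1)
  expect_equal(nrow(out$events), 0L)
  expect_false(out$extensively_edited)

  # full suppression protects completely
  m1 <- editing_model(p_edit_unmasked = 1, masking_suppression = 0,
                      editable_window = c(641, 840))
  out <- apply_editing(fx$transcript, m1, masked = TRUE, rng_seed = 2)
  expect_equal(nrow(out$events), 0L)

  # deterministic hyper-editing hits every window cytosine
  m2 <- editing_model(p_edit_unmasked = 1, editable_window = c(641, 840),
                      p_site = 1)
  out <- apply_editing(fx$transcript, m2, masked = FALSE, rng_seed = 3)
  chars <- strsplit(fx$transcript$sequence, "", fixed = TRUE)[[1L]]
  n_c <- sum(chars[641:840] == "C")
  expect_equal(nrow(out$events), n_c)
  expect_true(out$extensively_edited)
  expect_true(all(out$events$ref == "C" & out$events$alt == "T"))
  # engineered stops appear among the PTC calls
  expect_true(all(fx$engineered_sites %in% out$ptcs$position))
})

test_that("apply_editing counts a 7-cytosine window exactly", {
  seq <- paste0("ATATATATAT", "CACACACACACACA", strrep("AT", 8))
  tr <- transcript_model("w7", seq, nchar(seq), 1, c(1, 10))
  m <- editing_model(p_edit_unmasked = 1, editable_window = c(11, 24),
                     p_site = 1)
  out <- apply_editing(tr, m, masked = FALSE, rng_seed = 1)
  expect_equal(nrow(out$events), 7L)
})

test_that("edited_fraction matches its closed-form expectation", {
  fx <- make_transcript_fixture(1)
  m <- fx$editing
  expect_equal(edited_fraction(500, 1, m, 1, fx$transcript), 0)

  m2 <- editing_model(p_edit_unmasked = 0.5, editable_window = c(641, 840))
  f <- edited_fraction(10000, 0.5, m2, 2, fx$transcript)
  expect_lt(abs(f - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
})

test_that("edited_fraction is non-increasing in masking probability", {
  fx <- make_transcript_fixture(1)
  grid <- seq(0, 1, by = 0.25)
  f <- vapply(seq_along(grid), function(i)
    edited_fraction(10000, grid[i], fx$editing, 100 + i, fx$transcript),
    numeric(1))
  tol <- 3 * sqrt(0.25 / 10000) * 2
  expect_true(all(diff(f) <= tol))
})
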