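test_that("fold_score handles the canonical small cases", {
  expect_equal(fold_score("AAAAAAAA"), 0L)
  expect_equal(fold_score("GGGAAACCC"), 3L)
  expect_error(fold_score("GGGAXACCC"), "A,C,G,T,U")
  expect_error(fold_score("GGGAAAC"), "at least 8")
  # U and T are interchangeable
  expect_equal(fold_score("GGGAAACCC"), fold_score("GGGAAACCC"))
  expect_equal(fold_score("GGGAAAUUUCCC"), fold_score("GGGAAATTTCCC"))
})

test_that("Nussinov score equals exhaustive enumeration up to 12 nt", {
  set.seed(17)
  seqs <- c("GGGAAACCC", "GCGCAAAAGCGC",
            replicate(40, paste(sample(c("A", "C", "G", "T"),
                                       sample(8:12, 1), replace = TRUE),
                                collapse = "")))
  for (s in seqs)
    expect_equal(fold_score(s), oracle_max_pairs(s), info = s)
})

test_that("self-complementary constructs outscore dinucleotide shuffles", {
  set.seed(23)
  for (i in 1:20) {
    x <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
               collapse = "")
    hp <- paste0(x, revcomp(x))
    expect_gte(fold_score(hp), fold_score(dinuc_shuffle(hp)))
  }
})

test_that("pair propensities rank an engineered complementary pair first", {
  set.seed(31)
  exons <- replicate(8, paste(sample(c("A", "C", "G", "T"), 60,
                                     replace = TRUE), collapse = ""))
  names(exons) <- paste0("exon", 1:8)
  # engineer reverse-complement 25-mers into exons 4 and 5
  seg <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
               collapse = "")
  substr(exons[4], 10, 34) <- seg
  substr(exons[5], 10, 34) <- revcomp(seg)
  pp <- pair_propensities(exons)
  expect_equal(pp$pair[pp$rank == 1L], "exon4/exon5")
  # z-scores: population mean 0, sd 1
  expect_lt(abs(mean(pp$z)), 1e-10)
  expect_lt(abs(sqrt(mean(pp$z^2)) - 1), 1e-10)
})

test_that("degenerate all-identical exon sets warn and zero out", {
  exons <- rep("GGGAAACCCGGGAAACCC", 4)
  expect_warning(pp <- pair_propensities(exons), "no variance")
  expect_true(all(pp$z == 0))
  expect_error(pair_propensities(rep("GGGAAACCC", 3)), ">= 3 tandem pairs")
})

test_that("per-nt normalization is stable under spacer duplication", {
  set.seed(37)
  x <- paste(sample(c("G", "C", "A", "T"), 40, replace = TRUE),
             collapse = "")
  spacer <- strrep("A", 12)
  dup <- paste0(x, spacer, x)
  raw_x <- fold_score(x)
  raw_dup <- fold_score(dup)
  expect_gte(raw_dup, 2 * raw_x)  # both copies fold at least independently
  per_x <- raw_x / nchar(x)
  per_dup <- raw_dup / nchar(dup)
  # lower bound from the duplicated copies alone
  expect_gte(per_dup, per_x * 2 * nchar(x) / nchar(dup))
})

test_that("external scores can be plugged in and exported", {
  exons <- c(a = "GGGGAAAACCCC", b = "AAAATTTTAAAA", c = "GCGCGCAAAAAA",
             d = "TTTTGGGGAAAA")
  pp <- pair_propensities(exons, precomputed = c(9, 1, 5))
  expect_equal(pp$raw_score, c(9, 1, 5))
  expect_equal(pp$pair[pp$rank == 1L], "a/b")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_propensity_tsv(pp, path)
  back <- utils::read.delim(path)
  expect_equal(back$z, pp$z, tolerance = 1e-8)
})

test_that("exon FASTA round-trips preserve order and sequence", {
  fx <- make_transcript_fixture(1)
  tr <- fx$transcript
  starts <- c(1L, head(tr$exon_boundaries, -1L) + 1L)
  exons <- substring(tr$sequence, starts, tr$exon_boundaries)
  names(exons) <- paste0("exon", seq_along(exons))
  path <- withr::local_tempfile(fileext = ".fa")
  seqs <- Biostrings::DNAStringSet(exons)
  Biostrings::writeXStringSet(seqs, path)
  back <- read_exon_fasta(path)
  expect_identical(unname(back), unname(exons))
  expect_identical(names(back), names(exons))
})
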