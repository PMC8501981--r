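# Independent oracles and fixture builders used across the suite.

# Brute-force stop-codon scan: walks the coding frame codon by codon on the
# edited character vector and reports codons that are stops in the edited
# but not the unedited sequence. Deliberately naive and loop-based.
oracle_ptc_scan <- function(sequence, cds_start, edit_positions,
                            exon_boundaries, threshold = 50) {
  chars0 <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  chars1 <- chars0
  chars1[edit_positions] <- "T"
  stops <- c("TAA", "TAG", "TGA")
  junctions <- exon_boundaries[-length(exon_boundaries)]
  out <- list()
  p <- cds_start
  while (p + 2L <= length(chars0)) {
    c0 <- paste(chars0[p:(p + 2L)], collapse = "")
    c1 <- paste(chars1[p:(p + 2L)], collapse = "")
    if (c1 %in% stops && !(c0 %in% stops)) {
      dn <- junctions[junctions >= p + 2L]
      d <- if (length(dn)) min(dn) - (p + 2L) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        position = p, codon = c1, distance = d,
        eligible = !is.na(d) && d > threshold)
    }
    p <- p + 3L
  }
  if (length(out) == 0L)
    return(data.frame(position = integer(0), codon = character(0),
                      distance = numeric(0), eligible = logical(0)))
  do.call(rbind, out)
}

# Exhaustive maximum base-pairing by recursion over "pair position i with k
# or leave i unpaired" -- enumerates every nested structure, so only usable
# for short sequences. Independent of the package's DP formulation.
oracle_max_pairs <- function(sequence, min_loop = 3L) {
  chars <- chartr("U", "T", strsplit(toupper(sequence), "",
                                     fixed = TRUE)[[1L]])
  pairset <- c("AT", "TA", "GC", "CG", "GT", "TG")
  can <- function(a, b) paste0(chars[a], chars[b]) %in% pairset
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i + 1L, j)
    for (k in seq.int(i + min_loop + 1L, j)) {
      if (can(i, k))
        best <- max(best, 1L + rec(i + 1L, k - 1L) +
                      (if (k < j) rec(k + 1L, j) else 0L))
    }
    best
  }
  rec(1L, length(chars))
}

# Dinucleotide shuffle (Altschul-Erickson flavour kept simple: permute
# dinucleotide tiles), preserving approximate composition.
dinuc_shuffle <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  tiles <- split(chars, ceiling(seq_len(n) / 2))
  paste(unlist(tiles[sample.int(length(tiles))]), collapse = "")
}

revcomp <- function(sequence) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", sequence), "",
                     fixed = TRUE)[[1L]]), collapse = "")
}

# Random multi-exon transcript fixture for PTC property tests.
random_transcript <- function(len = 120L, n_exons = 3L) {
  len <- max(len, 30L)
  chars <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  cuts <- sort(sample(seq(10L, len - 10L), n_exons - 1L))
  transcript_model("rand", paste(chars, collapse = ""),
                   exon_boundaries = c(cuts, len), cds_start = 1L,
                   antisense_footprint = c(1L, min(10L, len)))
}

# 90-nt single-junction fixture: CGA at CDS codon 4 becomes TGA on editing
# its first-base cytosine; junction at 80.
ptc_toy <- function() {
  seq <- paste0(strrep("GCT", 3), "CGA", strrep("GCT", 26))
  stopifnot(nchar(seq) == 90)
  transcript_model("toy90", seq, exon_boundaries = c(80L, 90L),
                   cds_start = 1L, antisense_footprint = c(1L, 20L))
}
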