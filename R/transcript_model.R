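#' Toy multi-exon transcript model
#'
#' Container for the sequence-level description of a sense transcript as the
#' editing/NMD machinery sees it: the spliced sequence, the exon layout
#' (needed to locate exon-junction complexes downstream of a premature stop),
#' the CDS start that fixes the reading frame, and the interval covered by the
#' complementary natural antisense transcript ("antisense footprint").
#'
#' Coordinates are 1-based and intervals are inclusive throughout.
#'
#' @param name transcript name.
#' @param sequence character scalar over \code{A,C,G,T}.
#' @param exon_boundaries strictly increasing integer vector; element i is the
#'   transcript position of the last base of exon i. The final boundary must
#'   equal \code{nchar(sequence)}.
#' @param cds_start 1-based position of the first base of the coding frame.
#' @param antisense_footprint length-2 integer vector \code{c(start, end)},
#'   the region hybridized by the antisense transcript (default length 200 in
#'   the packaged fixture, mirroring a 200-nt antisense species).
#' @return an object of class \code{"transcript_model"}.
#' @export
transcript_model <- function(name, sequence, exon_boundaries, cds_start,
                             antisense_footprint) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || nchar(sequence) < 1L)
    stop("sequence must be a single non-empty string")
  if (grepl("[^ACGT]", sequence))
    stop("sequence must be over {A,C,G,T}")
  n <- nchar(sequence)
  exon_boundaries <- as.integer(exon_boundaries)
  if (any(diff(exon_boundaries) <= 0L))
    stop("exon_boundaries must be strictly increasing")
  if (exon_boundaries[length(exon_boundaries)] != n)
    stop("last exon boundary must equal sequence length")
  if (exon_boundaries[1L] < 1L)
    stop("exon boundaries must be positive")
  cds_start <- as.integer(cds_start)
  if (cds_start < 1L || cds_start > n)
    stop("cds_start outside sequence")
  antisense_footprint <- as.integer(antisense_footprint)
  if (length(antisense_footprint) != 2L ||
      antisense_footprint[1L] < 1L || antisense_footprint[2L] > n ||
      antisense_footprint[1L] > antisense_footprint[2L])
    stop("antisense_footprint must be a valid interval within the sequence")
  structure(
    list(name = name, sequence = sequence,
         exon_boundaries = exon_boundaries, cds_start = cds_start,
         antisense_footprint = antisense_footprint),
    class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  fp <- x$antisense_footprint
  cat("Transcript model:", x$name, "\n")
  cat(sprintf("  length %d nt, %d exons, CDS from %d\n",
              nchar(x$sequence), length(x$exon_boundaries), x$cds_start))
  cat(sprintf("  antisense footprint %d:%d (%d nt)\n",
              fp[1L], fp[2L], fp[2L] - fp[1L] + 1L))
  invisible(x)
}

#' GC content of a nucleotide sequence
#'
#' Fraction of G+C among called bases; \code{N} is excluded from the
#' denominator.
#'
#' @param sequence character scalar over \code{A,C,G,T,N} (case-insensitive).
#' @return numeric fraction in \eqn{[0, 1]}.
#' @examples
#' gc_content("GGCC")  # 1
#' gc_content("ATGC")  # 0.5
#' @export
gc_content <- function(sequence) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || nchar(sequence) < 1L)
    stop("sequence must be a single non-empty string")
  if (grepl("[^ACGTN]", sequence))
    stop("sequence must be over {A,C,G,T,N}")
  bases <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bases <- bases[bases != "N"]
  if (length(bases) == 0L) stop("sequence has no called bases")
  sum(bases %in% c("G", "C")) / length(bases)
}

## exon index (1-based) of a transcript position
exon_of_position <- function(transcript, pos) {
  findInterval(pos - 1L, c(0L, transcript$exon_boundaries),
               left.open = FALSE)
}

#' Write / read a transcript model as FASTA plus layout JSON
#'
#' The sequence goes to a FASTA file (via Biostrings); exon boundaries, CDS
#' start and the antisense footprint go to a small JSON sidecar so the fixture
#' round-trips exactly.
#'
#' @param x a \code{transcript_model}.
#' @param fasta,layout file paths.
#' @return \code{write_transcript_model} returns the paths invisibly;
#'   \code{read_transcript_model} returns a \code{transcript_model}.
#' @export
write_transcript_model <- function(x, fasta, layout) {
  stopifnot(inherits(x, "transcript_model"))
  seqs <- Biostrings::DNAStringSet(x$sequence)
  names(seqs) <- x$name
  Biostrings::writeXStringSet(seqs, filepath = fasta)
  jsonlite::write_json(
    list(name = x$name,
         exon_boundaries = x$exon_boundaries,
         cds_start = x$cds_start,
         antisense_footprint = x$antisense_footprint),
    layout, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fasta, layout = layout))
}

#' @rdname write_transcript_model
#' @export
read_transcript_model <- function(fasta, layout) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  lay <- jsonlite::read_json(layout, simplifyVector = TRUE)
  transcript_model(
    name = lay$name,
    sequence = as.character(seqs[[1L]]),
    exon_boundaries = lay$exon_boundaries,
    cds_start = lay$cds_start,
    antisense_footprint = lay$antisense_footprint)
}
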