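#' Nussinov maximum base-pairing score
#'
#' Self-contained secondary-structure propensity score: the maximum number
#' of nested base pairs (Watson-Crick plus G-U wobble; T and U are
#' equivalent) subject to a minimum hairpin-loop length, computed by the
#' Nussinov dynamic programme. The pair count serves as a stability proxy;
#' thermodynamic energies from an external folder can be substituted
#' through the \code{score_fun} hook of \code{\link{pair_propensities}}.
#'
#' @param sequence character scalar over \code{A,C,G,T,U}, length >= 8.
#' @param min_loop minimum number of unpaired bases in a hairpin loop.
#' @return integer: maximum number of base pairs.
#' @examples
#' fold_score("AAAAAAAA")   # 0
#' fold_score("GGGAAACCC")  # 3
#' @export
fold_score <- function(sequence, min_loop = 3L) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L) stop("sequence must be a single string")
  if (grepl("[^ACGTU]", sequence))
    stop("sequence must be over {A,C,G,T,U}")
  n <- nchar(sequence)
  if (n < 8L) stop("sequence must be at least 8 nt")
  chars <- chartr("U", "T", strsplit(sequence, "", fixed = TRUE)[[1L]])
  pairset <- c("AT", "TA", "GC", "CG", "GT", "TG")
  can <- matrix(paste0(rep(chars, times = n), rep(chars, each = n)) %in%
                  pairset, n, n)
  M <- matrix(0L, n, n)
  for (L in seq.int(min_loop + 1L, n - 1L)) {
    for (i in seq_len(n - L)) {
      j <- i + L
      best <- M[i, j - 1L]
      ks <- seq.int(i, j - min_loop - 1L)
      ks <- ks[can[ks, j]]
      if (length(ks)) {
        left <- integer(length(ks))
        inner_gt <- ks > i
        left[inner_gt] <- M[cbind(i, ks[inner_gt] - 1L)]
        inner <- M[cbind(ks + 1L, j - 1L)]
        best <- max(best, max(left + inner) + 1L)
      }
      M[i, j] <- best
    }
  }
  M[1L, n]
}

#' Structure propensity of tandem exon pairs
#'
#' For each tandem exon pair (i, i+1) the two sequences are concatenated and
#' scored (default: \code{\link{fold_score}} pair count), the score is
#' normalized to the combined pair length, and the per-nucleotide scores are
#' converted to z-scores across all pairs (population convention: mean 0,
#' unit variance). Pairs are ranked by z-score.
#'
#' @param exons named character vector of ordered exon sequences (>= 4
#'   exons, i.e. >= 3 tandem pairs).
#' @param score_fun scoring hook taking a sequence and returning a numeric
#'   score; swap in an external energy model (e.g. negated centroid minimum
#'   free energies) to reproduce a thermodynamic pipeline.
#' @param precomputed optional numeric vector of raw scores per tandem pair
#'   (overrides \code{score_fun}), the entry point for externally computed
#'   energies.
#' @return object of class \code{"pair_propensity"}: data frame with
#'   \code{pair}, \code{raw_score}, \code{per_nt_score}, \code{z},
#'   \code{rank} (1 = highest propensity).
#' @export
pair_propensities <- function(exons, score_fun = fold_score,
                              precomputed = NULL) {
  if (is.null(names(exons)) || any(names(exons) == ""))
    names(exons) <- paste0("exon", seq_along(exons))
  n_pairs <- length(exons) - 1L
  if (n_pairs < 3L) stop("need >= 3 tandem pairs (>= 4 exons)")
  pair_names <- paste(names(exons)[-length(exons)], names(exons)[-1L],
                      sep = "/")
  lens <- nchar(exons[-length(exons)]) + nchar(exons[-1L])
  raw <- if (!is.null(precomputed)) {
    if (length(precomputed) != n_pairs)
      stop("precomputed must have one score per tandem pair")
    as.numeric(precomputed)
  } else {
    vapply(seq_len(n_pairs), function(i)
      as.numeric(score_fun(paste0(exons[i], exons[i + 1L]))), numeric(1))
  }
  per_nt <- raw / lens
  sd_pop <- sqrt(mean((per_nt - mean(per_nt))^2))
  if (sd_pop == 0) {
    warning("no variance across pairs; z-scores set to 0")
    z <- rep(0, n_pairs)
  } else {
    z <- (per_nt - mean(per_nt)) / sd_pop
  }
  out <- data.frame(pair = pair_names, raw_score = raw,
                    per_nt_score = per_nt, z = z,
                    rank = rank(-z, ties.method = "first"),
                    stringsAsFactors = FALSE)
  class(out) <- c("pair_propensity", "data.frame")
  out
}

#' @export
print.pair_propensity <- function(x, ...) {
  cat("Tandem exon-pair structure propensities:\n")
  print.data.frame(x[order(x$rank), ], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Read ordered exon sequences from FASTA
#'
#' One record per exon, in transcript order; accepts DNA or RNA alphabets.
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_exon_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- names(seqs)
  out
}

#' @rdname pair_propensities
#' @param x a \code{pair_propensity} table.
#' @param path output TSV path.
#' @export
write_propensity_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
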