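#' Toy notch-like transcript fixture
#'
#' Builds the packaged desk-scale stand-in for the sense transcript: a
#' ~1.2-kb, 6-exon synthetic transcript with a GC-rich editable window
#' (target GC 0.68), a 200-nt antisense footprint, and two engineered
#' cytosines whose C-to-T edits create in-frame stop codons in the
#' penultimate and antepenultimate exons (both NMD-eligible by the
#' downstream-junction rule). The real transcript sequence is not used; the
#' fixture reproduces the structural facts the model depends on.
#'
#' @param rng_seed integer seed (the fixture is deterministic given seed).
#' @param gc_target GC fraction of the editable window (within 0.02 by
#'   construction).
#' @param footprint_length antisense footprint length, nt.
#' @return list with \code{transcript} (a \code{\link{transcript_model}}),
#'   \code{editing} (a matching \code{\link{editing_model}}), and
#'   \code{engineered_sites} (the two PTC-generating cytosine positions).
#' @export
make_transcript_fixture <- function(rng_seed = 1L, gc_target = 0.68,
                                    footprint_length = 200L) {
  set.seed(as.integer(rng_seed))
  exon_lengths <- c(180L, 200L, 210L, 220L, 200L, 190L)
  boundaries <- cumsum(exon_lengths)          # 180 380 590 810 1010 1200
  n <- boundaries[length(boundaries)]
  cds_start <- 10L
  window <- c(641L, 840L)                     # spans exons 4-5, 200 nt
  fp_start <- 601L
  footprint <- c(fp_start, fp_start + footprint_length - 1L)

  draw <- function(k, gc) sample(c("G", "C", "A", "T"), k, replace = TRUE,
                                 prob = c(gc / 2, gc / 2,
                                          (1 - gc) / 2, (1 - gc) / 2))
  chars <- draw(n, 0.5)
  win_idx <- window[1L]:window[2L]
  chars[win_idx] <- draw(length(win_idx), gc_target)

  # engineered CAA codons: C-to-T at the first base creates a TAA stop,
  # in frame with cds_start, in exons 4 and 5, inside the editable window
  sites <- c(700L, 820L)
  stopifnot(all((sites - cds_start) %% 3L == 0L))
  for (p in sites) chars[p:(p + 2L)] <- c("C", "A", "A")
  protected <- as.integer(outer(sites, 0:2, "+"))

  # remove pre-existing in-frame stops from the unedited coding frame
  starts <- seq.int(cds_start, n - 2L, by = 3L)
  repeat {
    codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    bad <- starts[codons %in% c("TAA", "TAG", "TGA") &
                    !(starts %in% sites)]
    if (length(bad) == 0L) break
    for (p in bad) chars[p:(p + 2L)] <- draw(3L, 0.5)
  }

  # nudge window GC onto target without touching engineered codons or
  # recreating in-frame stops (flips at second codon positions only)
  target_gc_n <- round(gc_target * length(win_idx))
  adjustable <- setdiff(win_idx, protected)
  adjustable <- adjustable[(adjustable - cds_start) %% 3L == 1L]
  for (step in seq_len(200L)) {
    gc_now <- sum(chars[win_idx] %in% c("G", "C"))
    if (gc_now == target_gc_n) break
    if (gc_now < target_gc_n) {
      cand <- adjustable[chars[adjustable] %in% c("A", "T")]
      chars[cand[1L]] <- "G"
    } else {
      cand <- adjustable[chars[adjustable] %in% c("G", "C")]
      chars[cand[1L]] <- "A"
    }
  }

  transcript <- transcript_model(
    name = "toy_notch_like", sequence = paste(chars, collapse = ""),
    exon_boundaries = boundaries, cds_start = cds_start,
    antisense_footprint = footprint)
  list(transcript = transcript,
       editing = editing_model(p_edit_unmasked = 1, masking_suppression = 0,
                               editable_window = window),
       engineered_sites = sites)
}

#' Asynchronous founder population
#'
#' Draws founder cells with lognormal cycle lengths (mean
#' \code{cycle_mean}, coefficient of variation \code{cv}) and, unless
#' synchronized, a uniformly random position within the cycle.
#'
#' @param rng_seed integer seed.
#' @param n_cells number of founders.
#' @param cycle_mean mean cycle length, minutes.
#' @param cv lognormal coefficient of variation of cycle length.
#' @param synchronized all founders start at cycle position 0?
#' @return data frame (cell_id, cycle_length, position, remaining).
#' @export
make_lineage <- function(rng_seed = 1L, n_cells = 1000L, cycle_mean = 900,
                         cv = 0.15, synchronized = FALSE) {
  set.seed(as.integer(rng_seed))
  n_cells <- as.integer(n_cells)
  sdlog <- sqrt(log(1 + cv^2))
  cycle <- cycle_mean *
    stats::rlnorm(n_cells, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  position <- if (synchronized) rep(0, n_cells) else
    stats::runif(n_cells) * cycle
  data.frame(cell_id = seq_len(n_cells), cycle_length = cycle,
             position = position, remaining = cycle - position)
}

#' Synthetic zone Ct tables with a stated shift
#'
#' Generates replicate delta-Ct tables for two conditions: a null baseline
#' and a shifted condition in which template moves from zone I toward zone V
#' by \code{shift} Ct units across the zone gradient, plus Gaussian
#' measurement noise. \code{shift = 0} gives exchangeable null tables.
#'
#' @param rng_seed integer seed.
#' @param shift shift magnitude in Ct units along the zone gradient.
#' @param n_replicates replicates per condition.
#' @param noise_sd Gaussian noise on each delta-Ct, in Ct units.
#' @param locus locus label.
#' @return long data frame (locus, condition, zone, delta_ct, replicate)
#'   in the CSV layout read by \code{\link{read_ct_table}}.
#' @export
make_ct_table <- function(rng_seed = 1L, shift = 1, n_replicates = 6L,
                          noise_sd = 0.15, locus = "exonA") {
  set.seed(as.integer(rng_seed))
  gradient <- c(-1, -0.5, 0, 0.5, 1)
  zones <- c("I", "II", "III", "IV", "V")
  one_table <- function(cond, eff, rep_id) {
    dct <- eff * gradient + stats::rnorm(5L, sd = noise_sd)
    dct <- dct - dct[1L]
    data.frame(locus = locus, condition = cond, zone = zones,
               delta_ct = dct, replicate = paste0(cond, rep_id),
               stringsAsFactors = FALSE)
  }
  rows <- c(lapply(seq_len(n_replicates), function(r)
              one_table("baseline", 0, r)),
            lapply(seq_len(n_replicates), function(r)
              one_table("shifted", shift, r)))
  do.call(rbind, rows)
}

#' @rdname make_ct_table
#' @param ct_long output of \code{make_ct_table}.
#' @param path output CSV path.
#' @export
write_ct_table <- function(ct_long, path) {
  utils::write.csv(ct_long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Paired division-event streams with a target rate ratio
#'
#' Two homogeneous Poisson division-event streams over \code{[0, t_max]}
#' with rates \code{rate_a} and \code{rate_a / ratio}, emulating a control
#' versus perturbation tracking experiment; the least-squares cumulative
#' slopes recover the stated ratio.
#'
#' @param rng_seed integer seed.
#' @param rate_a control event rate, events/min.
#' @param ratio target slope ratio a/b (\code{ratio = 1} gives matched
#'   streams).
#' @param t_max observation span, minutes.
#' @return list of two \code{\link{division_events}} (\code{a}, \code{b}).
#' @export
make_event_streams <- function(rng_seed = 1L, rate_a = 0.2, ratio = 5.4,
                               t_max = 1500) {
  set.seed(as.integer(rng_seed))
  draw <- function(rate, cond) {
    k <- stats::rpois(1L, rate * t_max)
    division_events(sort(stats::runif(k, 0, t_max)), condition = cond)
  }
  list(a = draw(rate_a, "a"), b = draw(rate_a / ratio, "b"))
}

#' Synthetic Sanger base-call mixture at edit sites
#'
#' Emulates the per-position base-call proportions of a Sanger trace over a
#' mixture of edited and unedited molecules: \code{depth} molecules are
#' drawn, each extensively edited with probability \code{edited_fraction};
#' edited molecules carry T at the engineered predominant edit sites with
#' certainty and at the remaining window cytosines with the per-site
#' editing probability. No chromatogram signal model is attempted, only the
#' proportion table needed to test edited-fraction estimation.
#'
#' @param rng_seed integer seed.
#' @param fixture output of \code{\link{make_transcript_fixture}}.
#' @param edited_fraction fraction of extensively edited molecules.
#' @param depth number of molecules (read depth).
#' @return data frame (position, engineered, depth, n_T, prop_T) over the
#'   editable-window cytosines.
#' @export
make_read_mixture <- function(rng_seed = 1L, fixture = NULL,
                              edited_fraction = 0.32, depth = 500L) {
  if (is.null(fixture)) fixture <- make_transcript_fixture(rng_seed)
  if (edited_fraction < 0 || edited_fraction > 1)
    stop("edited_fraction must be in [0, 1]")
  set.seed(as.integer(rng_seed))
  tr <- fixture$transcript
  win <- fixture$editing$editable_window
  chars <- strsplit(tr$sequence, "", fixed = TRUE)[[1L]]
  c_sites <- which(chars == "C")
  c_sites <- c_sites[c_sites >= win[1L] & c_sites <= win[2L]]
  engineered <- c_sites %in% fixture$engineered_sites
  n_edited <- stats::rbinom(1L, depth, edited_fraction)
  n_T <- ifelse(engineered, n_edited,
                stats::rbinom(length(c_sites), n_edited,
                              fixture$editing$p_site))
  data.frame(position = c_sites, engineered = engineered, depth = depth,
             n_T = n_T, prop_T = n_T / depth)
}

#' @rdname make_read_mixture
#' @param mixture a mixture table from \code{make_read_mixture}.
#' @return \code{estimate_edited_fraction}: the edited fraction estimated
#'   from the T proportion at the engineered predominant sites.
#' @export
estimate_edited_fraction <- function(mixture) {
  eng <- mixture[mixture$engineered, , drop = FALSE]
  if (nrow(eng) == 0L) stop("mixture has no engineered sites")
  mean(eng$prop_T)
}
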