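#' C-to-U hyper-editing model
#'
#' Parameters of the cytidine-deaminase (APOBEC1-like) hyper-editing process
#' acting on the sense transcript. Editing is a two-level process: a molecule
#' is either hyper-edited or untouched (molecule-level probability
#' \code{p_edit_unmasked}, multiplied by \code{masking_suppression} when the
#' molecule is hybridized to the antisense transcript), and a hyper-edited
#' molecule carries independent per-cytosine C-to-T substitutions within the
#' GC-rich editable window (per-site probability \code{p_site}).
#'
#' @param p_edit_unmasked probability that an unmasked molecule is
#'   hyper-edited.
#' @param masking_suppression multiplicative factor on the editing probability
#'   for masked molecules; 0 (default) means full protection by hybridization.
#' @param editable_window length-2 integer vector, 1-based inclusive interval
#'   of the GC-rich editable region.
#' @param min_edits_extensive minimum number of substitutions inside the
#'   editable window for a molecule to count as "extensively edited".
#' @param p_site per-cytosine substitution probability within a hyper-edited
#'   molecule.
#' @return an object of class \code{"editing_model"}.
#' @export
editing_model <- function(p_edit_unmasked, masking_suppression = 0,
                          editable_window, min_edits_extensive = 5L,
                          p_site = 0.6) {
  if (p_edit_unmasked < 0 || p_edit_unmasked > 1)
    stop("p_edit_unmasked must be in [0, 1]")
  if (masking_suppression < 0 || masking_suppression > 1)
    stop("masking_suppression must be in [0, 1]")
  if (p_site < 0 || p_site > 1) stop("p_site must be in [0, 1]")
  editable_window <- as.integer(editable_window)
  if (length(editable_window) != 2L || editable_window[1L] > editable_window[2L])
    stop("editable_window must be c(start, end) with start <= end")
  structure(
    list(p_edit_unmasked = p_edit_unmasked,
         masking_suppression = masking_suppression,
         editable_window = editable_window,
         min_edits_extensive = as.integer(min_edits_extensive),
         p_site = p_site),
    class = "editing_model")
}

validate_edit_events <- function(transcript, positions) {
  positions <- as.integer(positions)
  if (length(positions) == 0L) return(positions)
  n <- nchar(transcript$sequence)
  if (any(positions < 1L | positions > n))
    stop("edit position outside sequence: ",
         paste(positions[positions < 1L | positions > n], collapse = ", "))
  ref <- substring(transcript$sequence, positions, positions)
  bad <- positions[ref != "C"]
  if (length(bad) > 0L)
    stop("edit at non-C reference position: ", paste(bad, collapse = ", "))
  sort(unique(positions))
}

#' Scan for premature termination codons created by C-to-U editing
#'
#' Applies a set of C-to-T substitutions to the transcript, translates the
#' coding frame from \code{cds_start}, and reports every in-frame stop codon
#' present in the edited sequence but absent at the same codon of the
#' unedited sequence. For each new stop the distance to the nearest
#' downstream exon-exon junction is computed (junction = last base of a
#' non-terminal exon; a stop in the last exon has no downstream junction) and
#' NMD eligibility is called by the canonical distance rule (see
#' \code{\link{nmd_eligible}}).
#'
#' @param transcript a \code{\link{transcript_model}}.
#' @param events integer vector of 1-based C-to-T edit positions (or a data
#'   frame with a \code{position} column). Every position must carry a C in
#'   the unedited sequence.
#' @param nmd_threshold junction-distance threshold in nucleotides.
#' @return data frame with one row per novel stop codon, ordered by position:
#'   \code{position} (first base of the stop codon), \code{codon},
#'   \code{distance_to_downstream_junction} (NA when the stop lies in the last
#'   exon), \code{nmd_eligible}.
#' @export
scan_ptc <- function(transcript, events, nmd_threshold = 50) {
  stopifnot(inherits(transcript, "transcript_model"))
  if (is.data.frame(events)) events <- events$position
  positions <- validate_edit_events(transcript, events)

  seq0 <- transcript$sequence
  seq1 <- seq0
  if (length(positions) > 0L) {
    chars <- strsplit(seq1, "", fixed = TRUE)[[1L]]
    chars[positions] <- "T"
    seq1 <- paste(chars, collapse = "")
  }

  n <- nchar(seq0)
  starts <- seq.int(transcript$cds_start, n - 2L, by = 3L)
  if (length(starts) == 0L) return(empty_ptc_table())
  cod0 <- substring(seq0, starts, starts + 2L)
  cod1 <- substring(seq1, starts, starts + 2L)
  stops <- c("TAA", "TAG", "TGA")
  novel <- which(cod1 %in% stops & !(cod0 %in% stops))
  if (length(novel) == 0L) return(empty_ptc_table())

  junctions <- transcript$exon_boundaries
  junctions <- junctions[-length(junctions)]  # last boundary is transcript end
  pos <- starts[novel]
  stop_end <- pos + 2L
  dist <- vapply(stop_end, function(e) {
    dn <- junctions[junctions >= e]
    if (length(dn) == 0L) NA_real_ else min(dn) - e
  }, numeric(1))
  data.frame(
    position = pos,
    codon = cod1[novel],
    distance_to_downstream_junction = dist,
    nmd_eligible = nmd_eligible(dist, nmd_threshold),
    stringsAsFactors = FALSE)
}

empty_ptc_table <- function() {
  data.frame(position = integer(0), codon = character(0),
             distance_to_downstream_junction = numeric(0),
             nmd_eligible = logical(0), stringsAsFactors = FALSE)
}

#' NMD eligibility by the downstream-junction distance rule
#'
#' A premature termination codon triggers nonsense-mediated decay when an
#' exon-exon junction lies sufficiently far downstream of the stop (the
#' canonical 50-nt exon-junction-complex rule). A stop in the last exon (no
#' downstream junction, encoded as \code{NA} distance) is never eligible.
#'
#' @param distance numeric vector of distances (nt) from the stop codon end to
#'   the nearest downstream exon junction; \code{NA} means no downstream
#'   junction.
#' @param threshold distance threshold in nucleotides (default 50).
#' @return logical vector.
#' @export
nmd_eligible <- function(distance, threshold = 50) {
  if (threshold <= 0) stop("threshold must be > 0")
  out <- !is.na(distance) & distance > threshold
  out
}

#' Edit one molecule under the masking/hyper-editing model
#'
#' Draws the fate of a single transcript molecule: with probability
#' \code{p_edit_unmasked} (times \code{masking_suppression} when
#' \code{masked}) the molecule is hyper-edited, i.e. every cytosine in the
#' editable window is substituted C-to-T independently with probability
#' \code{p_site}. Premature stops created by the substitutions are annotated
#' via \code{\link{scan_ptc}}.
#'
#' @param transcript a \code{\link{transcript_model}}.
#' @param model an \code{\link{editing_model}}.
#' @param masked is the molecule hybridized to the antisense transcript?
#' @param rng_seed integer seed (fixed for reproducibility).
#' @param nmd_threshold passed to \code{\link{scan_ptc}}.
#' @return an object of class \code{"edited_molecule"}: list with
#'   \code{events} (data frame position/ref/alt), \code{extensively_edited},
#'   and \code{ptcs} (a PTC table).
#' @export
apply_editing <- function(transcript, model, masked = FALSE, rng_seed,
                          nmd_threshold = 50) {
  stopifnot(inherits(transcript, "transcript_model"),
            inherits(model, "editing_model"))
  win <- model$editable_window
  if (win[2L] > nchar(transcript$sequence))
    stop("editable_window outside sequence")
  set.seed(as.integer(rng_seed))
  p <- model$p_edit_unmasked * (if (masked) model$masking_suppression else 1)
  positions <- integer(0)
  if (stats::runif(1) < p) {
    chars <- strsplit(transcript$sequence, "", fixed = TRUE)[[1L]]
    c_sites <- which(chars == "C")
    c_sites <- c_sites[c_sites >= win[1L] & c_sites <= win[2L]]
    hit <- stats::runif(length(c_sites)) < model$p_site
    positions <- c_sites[hit]
  }
  events <- data.frame(position = positions,
                       ref = rep("C", length(positions)),
                       alt = rep("T", length(positions)),
                       stringsAsFactors = FALSE)
  n_in_window <- sum(positions >= win[1L] & positions <= win[2L])
  structure(
    list(events = events,
         extensively_edited = n_in_window >= model$min_edits_extensive,
         ptcs = scan_ptc(transcript, positions, nmd_threshold)),
    class = "edited_molecule")
}

#' @export
print.edited_molecule <- function(x, ...) {
  cat(sprintf("Edited molecule: %d substitutions, extensively edited: %s, %d PTC(s)\n",
              nrow(x$events), x$extensively_edited, nrow(x$ptcs)))
  invisible(x)
}

#' Write an edited-molecule record to JSON
#'
#' @param molecule an \code{edited_molecule}.
#' @param path output path.
#' @export
write_molecule_json <- function(molecule, path) {
  stopifnot(inherits(molecule, "edited_molecule"))
  jsonlite::write_json(unclass(molecule), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' Simulated fraction of extensively edited molecules
#'
#' Simulates \code{n_molecules} transcript molecules, each hybridized to the
#' antisense transcript with probability \code{masking_prob}, applies the
#' hyper-editing model at aggregate level, and returns the fraction that ends
#' up extensively edited. The expectation is
#' \deqn{(1 - m) p + m\, p\, s}{(1-m)*p + m*p*s}
#' with \eqn{m} the masking probability, \eqn{p} the unmasked editing
#' probability and \eqn{s} the masking suppression (times the probability
#' that a hyper-edited molecule reaches the extensive-editing threshold,
#' which is essentially 1 for the packaged GC-rich window).
#'
#' @param n_molecules number of molecules to simulate (>= 1).
#' @param masking_prob per-molecule probability of being masked.
#' @param model an \code{\link{editing_model}}.
#' @param rng_seed integer seed.
#' @param transcript optional \code{\link{transcript_model}}; when supplied,
#'   the per-molecule substitution count is drawn binomially over the actual
#'   cytosines of the editable window, so the extensive-editing threshold can
#'   fail for windows with few cytosines. Without it a hyper-edited molecule
#'   is assumed to reach the threshold.
#' @return fraction in \eqn{[0, 1]}.
#' @export
edited_fraction <- function(n_molecules, masking_prob, model, rng_seed,
                            transcript = NULL) {
  stopifnot(inherits(model, "editing_model"))
  n_molecules <- as.integer(n_molecules)
  if (n_molecules < 1L) stop("n_molecules must be >= 1")
  if (masking_prob < 0 || masking_prob > 1)
    stop("masking_prob must be in [0, 1]")
  set.seed(as.integer(rng_seed))
  masked <- stats::runif(n_molecules) < masking_prob
  p <- ifelse(masked, model$p_edit_unmasked * model$masking_suppression,
              model$p_edit_unmasked)
  hyper <- stats::runif(n_molecules) < p
  if (is.null(transcript)) {
    extensive <- hyper
  } else {
    win <- model$editable_window
    chars <- strsplit(transcript$sequence, "", fixed = TRUE)[[1L]]
    n_c <- sum(chars[win[1L]:win[2L]] == "C")
    edits <- integer(n_molecules)
    edits[hyper] <- stats::rbinom(sum(hyper), n_c, model$p_site)
    extensive <- edits >= model$min_edits_extensive
  }
  mean(extensive)
}
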