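#' Per-phase molecule pools of the sense transcript
#'
#' Tracks molecule counts of the five fates of the sense transcript within a
#' cell: \code{masked_unedited} (hybridized to the antisense transcript, and
#' thereby shielded), \code{free_unedited}, \code{edited} (hyper-edited, NMD
#' substrate), and the absorbing tallies \code{degraded} and
#' \code{translated}. The total across the five pools is conserved by every
#' update once transcription stops.
#'
#' @param masked_unedited,free_unedited,edited,degraded,translated
#'   non-negative integer counts.
#' @param phase cell-cycle phase, one of \code{G0,G1,S,G2,M}.
#' @return an object of class \code{"pool_state"}.
#' @export
pool_state <- function(masked_unedited = 0L, free_unedited = 0L, edited = 0L,
                       degraded = 0L, translated = 0L, phase = "G0") {
  counts <- c(masked_unedited = masked_unedited,
              free_unedited = free_unedited, edited = edited,
              degraded = degraded, translated = translated)
  if (any(counts < 0)) stop("pool counts must be non-negative")
  phase <- match.arg(phase, c("G0", "G1", "S", "G2", "M"))
  counts <- round(counts)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, phase = phase), class = "pool_state")
}

#' @export
print.pool_state <- function(x, ...) {
  cat("Pool state at phase", x$phase, "\n")
  print(x$counts)
  invisible(x)
}

#' Phase gating of the transcript-fate machinery
#'
#' Which cell-cycle phases each activity runs in. Defaults encode the model:
#' sense transcription and editing (APOBEC1) are confined to G0; the NMD
#' effector UPF1 is absent in G0 (degraded by APC/C) and active from G1
#' onward; translation of the surviving pool happens in G1.
#'
#' @param apobec_active_phases,upf1_active_phases,sense_transcription_phases,
#'   translation_phases character vectors, subsets of
#'   \code{c("G0","G1","S","G2","M")}.
#' @return an object of class \code{"phase_gates"}.
#' @export
phase_gates <- function(apobec_active_phases = "G0",
                        upf1_active_phases = c("G1", "S", "G2", "M"),
                        sense_transcription_phases = "G0",
                        translation_phases = "G1") {
  all_phases <- c("G0", "G1", "S", "G2", "M")
  chk <- function(x, nm) {
    if (!all(x %in% all_phases))
      stop(nm, " must be a subset of {G0,G1,S,G2,M}")
    x
  }
  structure(
    list(apobec = chk(apobec_active_phases, "apobec_active_phases"),
         upf1 = chk(upf1_active_phases, "upf1_active_phases"),
         transcription = chk(sense_transcription_phases,
                             "sense_transcription_phases"),
         translation = chk(translation_phases, "translation_phases")),
    class = "phase_gates")
}

#' One phase-gated update of the transcript pools
#'
#' Applies a single update of the mass balance at the state's current phase.
#' In a transcription phase (G0 by default) new unedited molecules are added;
#' masking then moves free molecules to the masked pool with probability
#' \code{masking_prob}; in an editing phase free molecules are hyper-edited
#' with probability \code{p_edit} (masked ones with
#' \code{p_edit * masking_suppression}). In a UPF1-active phase edited
#' molecules are degraded with probability \code{degradation_rate}; in a
#' translation phase surviving unedited molecules (masked or free) are
#' translated with probability \code{translation_rate}. All moves are
#' binomial draws, so the counts conserve total molecule number exactly.
#'
#' @param state a \code{\link{pool_state}}.
#' @param gates a \code{\link{phase_gates}}.
#' @param params list with elements \code{transcription_n} (molecules added
#'   per transcription-phase update, default 0), \code{masking_prob},
#'   \code{p_edit}, \code{masking_suppression} (default 0),
#'   \code{degradation_rate} (default 1), \code{translation_rate}
#'   (default 0.5).
#' @param rng_seed optional integer seed.
#' @return updated \code{pool_state} (same phase; advance the phase with
#'   \code{set_phase}).
#' @export
phase_pool_update <- function(state, gates = phase_gates(), params = list(),
                              rng_seed = NULL) {
  stopifnot(inherits(state, "pool_state"), inherits(gates, "phase_gates"))
  p <- utils::modifyList(
    list(transcription_n = 0L, masking_prob = 0.68, p_edit = 1,
         masking_suppression = 0, degradation_rate = 1,
         translation_rate = 0.5),
    params)
  rates <- unlist(p[c("masking_prob", "p_edit", "masking_suppression",
                      "degradation_rate", "translation_rate")])
  if (any(rates < 0) || any(rates > 1))
    stop("rates must be probabilities in [0, 1]")
  if (p$transcription_n < 0) stop("transcription_n must be non-negative")
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))

  cnt <- state$counts
  ph <- state$phase

  if (ph %in% gates$transcription)
    cnt["free_unedited"] <- cnt["free_unedited"] + as.integer(p$transcription_n)

  if (ph %in% gates$apobec) {
    # masking partitions the free pool before editing acts
    to_mask <- stats::rbinom(1L, cnt["free_unedited"], p$masking_prob)
    cnt["free_unedited"] <- cnt["free_unedited"] - to_mask
    cnt["masked_unedited"] <- cnt["masked_unedited"] + to_mask
    ed_free <- stats::rbinom(1L, cnt["free_unedited"], p$p_edit)
    ed_mask <- stats::rbinom(1L, cnt["masked_unedited"],
                             p$p_edit * p$masking_suppression)
    cnt["free_unedited"] <- cnt["free_unedited"] - ed_free
    cnt["masked_unedited"] <- cnt["masked_unedited"] - ed_mask
    cnt["edited"] <- cnt["edited"] + ed_free + ed_mask
  }

  if (ph %in% gates$upf1) {
    deg <- stats::rbinom(1L, cnt["edited"], p$degradation_rate)
    cnt["edited"] <- cnt["edited"] - deg
    cnt["degraded"] <- cnt["degraded"] + deg
  }

  if (ph %in% gates$translation) {
    tr_f <- stats::rbinom(1L, cnt["free_unedited"], p$translation_rate)
    tr_m <- stats::rbinom(1L, cnt["masked_unedited"], p$translation_rate)
    cnt["free_unedited"] <- cnt["free_unedited"] - tr_f
    cnt["masked_unedited"] <- cnt["masked_unedited"] - tr_m
    cnt["translated"] <- cnt["translated"] + tr_f + tr_m
  }

  state$counts <- cnt
  state
}

#' @rdname phase_pool_update
#' @param phase new phase for the state.
#' @export
set_phase <- function(state, phase) {
  stopifnot(inherits(state, "pool_state"))
  state$phase <- match.arg(phase, c("G0", "G1", "S", "G2", "M"))
  state
}

#' Run a phase schedule and export the pool trajectory
#'
#' Convenience driver: applies \code{\link{phase_pool_update}} once per phase
#' of \code{schedule} and returns the trajectory in long format
#' (time, phase, pool, count), the CSV layout used for export.
#'
#' @param state starting \code{\link{pool_state}}.
#' @param schedule character vector of phases visited in order.
#' @inheritParams phase_pool_update
#' @return data frame with columns \code{time} (update index, starting at 0
#'   for the initial state), \code{phase}, \code{pool}, \code{count}.
#' @export
run_pool_schedule <- function(state, schedule, gates = phase_gates(),
                              params = list(), rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  rows <- list(pool_snapshot(state, 0L))
  for (i in seq_along(schedule)) {
    state <- set_phase(state, schedule[i])
    state <- phase_pool_update(state, gates, params)
    rows[[i + 1L]] <- pool_snapshot(state, i)
  }
  do.call(rbind, rows)
}

pool_snapshot <- function(state, time) {
  data.frame(time = time, phase = state$phase,
             pool = names(state$counts),
             count = unname(state$counts),
             stringsAsFactors = FALSE)
}

#' @rdname run_pool_schedule
#' @param trajectory data frame from \code{run_pool_schedule}.
#' @param path output CSV path.
#' @export
write_pool_trajectory <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
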