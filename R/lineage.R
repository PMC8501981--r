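#' Simulation parameters of the antisense-inheritance lineage model
#'
#' Parameters of the stochastic cell-lineage model in which the inherited
#' antisense titer (nAS25 F0) masks the sense transcript at G0, setting the
#' available notch-1 signal and thereby the G1 duration, while intra-cycle
#' (E2F1-window) synthesis restores the antisense titer before division.
#'
#' Mass balance per cycle (titers are per-cell concentrations, arbitrary
#' units): of the inherited titer a fraction \code{s_survival} survives
#' editing at G0 and degradation at G1; synthesis adds \code{k_syn} units per
#' minute of G1. \code{k_syn} defaults to \code{(1 - s_survival) / G1_base}
#' so that a control cell exactly restores its pre-G1 titer over a nominal
#' G1 of \code{G1_base} minutes (homeostasis).
#'
#' G1 duration decreases with the available notch-1 signal through
#' \deqn{G1(n) = G1_{min} + (G1_{max} - G1_{min}) e^{-\beta n}}
#' with \eqn{n = \code{masking_slope} \times} inherited titer. By default
#' \code{G1_max} is derived from \code{beta}, \code{G1_min} and the
#' constraint \eqn{G1(\code{masking_slope}) = \code{G1_base}} so a control
#' cell (titer 1) has a mean G1 of \code{G1_base}. The defaults of
#' \code{beta}, \code{G1_min} and the exogenous-bolus size were calibrated
#' (coarse grid then local refinement, seeded) against three anchors: mean
#' control cycle 900 min, a 5.4-fold mitotic-slope reduction under antisense
#' knockdown at efficiency 0.9, and a 2.5-fold initial slope increase under
#' an exogenous antisense bolus.
#'
#' @param s_survival fraction of the inherited antisense pool surviving
#'   editing/degradation (default 0.5).
#' @param G1_base nominal control G1 duration, minutes.
#' @param G1_min,G1_max,beta parameters of the notch-to-G1 mapping;
#'   \code{G1_max = NULL} derives it from the control constraint.
#' @param k_syn antisense synthesis rate per minute of G1; \code{NULL}
#'   derives the homeostatic value.
#' @param masking_slope available notch-1 per unit inherited titer (0.68,
#'   from the 32\% edited fraction at control masking).
#' @param d_S,d_G2,d_M,d_G0 fixed phase durations, minutes (S+G2+M+G1_base
#'   gives the ~900-min mean cycle).
#' @param cv_noise lognormal coefficient of variation on phase durations.
#' @param t_deg duration (min) of the early-G1 degradation transient in
#'   exported titer trajectories.
#' @param grid_step sampling grid for exported time series, minutes.
#' @param partition division partition rule for titers: \code{"equal"}
#'   (concentration convention: each daughter inherits the mother's
#'   concentration) or \code{"binomial"} (molecule-count mode).
#' @return object of class \code{"sim_params"}.
#' @export
sim_params <- function(s_survival = 0.5, G1_base = 460,
                       G1_min = 5, G1_max = NULL, beta = 3.20,
                       k_syn = NULL, masking_slope = 0.68,
                       d_S = 240, d_G2 = 120, d_M = 80, d_G0 = 0,
                       cv_noise = 0.15, t_deg = 60, grid_step = 5,
                       partition = c("equal", "binomial")) {
  partition <- match.arg(partition)
  if (s_survival < 0 || s_survival > 1) stop("s_survival must be in [0, 1]")
  if (is.null(G1_max))
    G1_max <- G1_min + (G1_base - G1_min) * exp(beta * masking_slope)
  if (is.null(k_syn)) k_syn <- (1 - s_survival) / G1_base
  p <- list(s_survival = s_survival, G1_base = G1_base, G1_min = G1_min,
            G1_max = G1_max, beta = beta, k_syn = k_syn,
            masking_slope = masking_slope,
            d_S = d_S, d_G2 = d_G2, d_M = d_M, d_G0 = d_G0,
            cv_noise = cv_noise, t_deg = t_deg, grid_step = grid_step,
            partition = partition)
  vals <- unlist(p[c("G1_base", "G1_min", "G1_max", "beta", "k_syn",
                     "d_S", "d_G2", "d_M", "d_G0", "cv_noise")])
  if (any(!is.finite(vals))) stop("non-finite simulation parameter")
  if (!(G1_min < G1_base && G1_base < G1_max))
    stop("need G1_min < G1_base < G1_max")
  if (any(c(d_S, d_G2, d_M) <= 0) || d_G0 < 0)
    stop("phase durations must be positive (G0 may be zero)")
  structure(p, class = "sim_params")
}

#' Perturbation scenario
#'
#' Builds the scenario flags shared by the closed-form mass balance and the
#' stochastic simulator. Several perturbations can be combined by passing a
#' vector of names (e.g. \code{c("roscovitine", "rnai_nAS25")}).
#'
#' Available scenarios: \code{control}; \code{rnai_nAS25} (continuous
#' knockdown of the antisense transcript at \code{efficiency});
#' \code{roscovitine} and \code{tmp_stabilize} (intra-cycle synthesis fully
#' blocked, via Cdk2/E2F1 inhibition or chromatin-topology stabilization);
#' \code{dcas9_block} (promoter block reducing synthesis by
#' \code{efficiency}); \code{cycloheximide} (multiplicative G1 prolongation,
#' synthesis continuing); \code{crenigacestat} (additive G1-S delay in
#' minutes, synthesis continuing); \code{ro3306_g2_arrest} (cells arrest at
#' G2, titer untouched); \code{apcin_sync} (founders released synchronously
#' from M); \code{serum_starvation} (founders park in G0);
#' \code{nAS25_exo} (exogenous antisense bolus added to founder titer).
#'
#' @param name scenario name(s).
#' @param efficiency knockdown/block efficiency in [0,1]; applies to
#'   \code{rnai_nAS25} if present, else to \code{dcas9_block}. Defaults: 0.9
#'   (RNAi), 0.92 (dCas9).
#' @param prolong_factor G1 prolongation factor for \code{cycloheximide}.
#' @param delay_min additive G1-S delay (min) for \code{crenigacestat}.
#' @param bolus exogenous titer bolus for \code{nAS25_exo} (calibrated
#'   default 8).
#' @param onset_time scenario onset, minutes (0 = from the start).
#' @return object of class \code{"scenario"}.
#' @export
scenario <- function(name = "control", efficiency = NULL,
                     prolong_factor = 1.5, delay_min = 240, bolus = 8,
                     onset_time = 0) {
  known <- c("control", "rnai_nAS25", "roscovitine", "dcas9_block",
             "tmp_stabilize", "cycloheximide", "crenigacestat",
             "ro3306_g2_arrest", "apcin_sync", "serum_starvation",
             "nAS25_exo")
  if (!all(name %in% known))
    stop("unknown scenario: ", paste(setdiff(name, known), collapse = ", "))
  if (!is.null(efficiency) && (efficiency < 0 || efficiency > 1))
    stop("efficiency must be in [0, 1]")
  if (delay_min < 0 || prolong_factor < 0 || bolus < 0)
    stop("delay/prolong/bolus must be non-negative")
  sc <- list(
    name = paste(name, collapse = "+"),
    rnai_efficiency = 0,
    dcas9_efficiency = 0,
    synthesis_blocked = FALSE,
    g1_prolong = 1,
    g1_delay = 0,
    g2_arrest = FALSE,
    sync = FALSE,
    park_g0 = FALSE,
    bolus = 0,
    onset_time = onset_time)
  if ("rnai_nAS25" %in% name)
    sc$rnai_efficiency <- if (is.null(efficiency)) 0.9 else efficiency
  if ("dcas9_block" %in% name)
    sc$dcas9_efficiency <-
      if (is.null(efficiency) || "rnai_nAS25" %in% name) 0.92 else efficiency
  if (any(c("roscovitine", "tmp_stabilize") %in% name))
    sc$synthesis_blocked <- TRUE
  if ("cycloheximide" %in% name) sc$g1_prolong <- prolong_factor
  if ("crenigacestat" %in% name) sc$g1_delay <- delay_min
  if ("ro3306_g2_arrest" %in% name) sc$g2_arrest <- TRUE
  if ("apcin_sync" %in% name) sc$sync <- TRUE
  if ("serum_starvation" %in% name) sc$park_g0 <- TRUE
  if ("nAS25_exo" %in% name) sc$bolus <- bolus
  structure(sc, class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario:", x$name, "\n")
  invisible(x)
}

#' Closed-form antisense titer at G1 exit
#'
#' Deterministic mass balance over one G0-G1 passage: of the inherited
#' (pre-G1) titer, \code{s_survival} survives editing and NMD-mediated
#' degradation (further reduced by the RNAi efficiency when active); the
#' intra-cycle E2F1-window synthesis adds \code{k_syn} per minute of the G1
#' window (zero under Roscovitine or chromatin-topology stabilization,
#' reduced by the dCas9 promoter-block efficiency; the window is lengthened
#' additively by a Crenigacestat G1-S delay and multiplicatively by
#' cycloheximide). With the homeostatic default \code{k_syn} the control
#' total equals the pre-G1 titer exactly.
#'
#' @param pre_G1_titer inherited titer entering G1 (>= 0).
#' @param params a \code{\link{sim_params}}.
#' @param scen a \code{\link{scenario}}.
#' @param g1_window synthesis window, minutes (default the nominal
#'   \code{G1_base}).
#' @return list with \code{surviving}, \code{synthesized}, \code{total}.
#' @examples
#' p <- sim_params()
#' nAS25_titer_at_G1_exit(1, p, scenario("control"))$total        # 1
#' nAS25_titer_at_G1_exit(1, p, scenario("roscovitine"))$total    # 0.5
#' @export
nAS25_titer_at_G1_exit <- function(pre_G1_titer, params = sim_params(),
                                   scen = scenario("control"),
                                   g1_window = params$G1_base) {
  stopifnot(inherits(params, "sim_params"), inherits(scen, "scenario"))
  if (pre_G1_titer < 0) stop("pre_G1_titer must be >= 0")
  surviving <- params$s_survival * pre_G1_titer * (1 - scen$rnai_efficiency)
  window <- g1_window * scen$g1_prolong + scen$g1_delay
  synthesized <- if (scen$synthesis_blocked) 0 else
    params$k_syn * window * (1 - scen$dcas9_efficiency)
  list(surviving = surviving, synthesized = synthesized,
       total = surviving + synthesized)
}

## deterministic notch-to-G1 mapping
g1_det <- function(notch1_available, params) {
  params$G1_min + (params$G1_max - params$G1_min) *
    exp(-params$beta * notch1_available)
}

## lognormal noise factor with mean 1 and coefficient of variation cv
ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' G1-phase duration from available notch-1 signal
#'
#' Deterministic core \eqn{G1_{min} + (G1_{max} - G1_{min}) e^{-\beta n}},
#' strictly decreasing in the notch-1 signal, multiplied by a mean-1
#' lognormal noise factor.
#'
#' @param notch1_available non-negative notch-1 signal (arbitrary units).
#' @param params a \code{\link{sim_params}}.
#' @param rng_seed optional integer seed.
#' @param noise apply the lognormal noise factor?
#' @return duration in minutes.
#' @export
g1_duration <- function(notch1_available, params = sim_params(),
                        rng_seed = NULL, noise = TRUE) {
  stopifnot(inherits(params, "sim_params"))
  if (any(notch1_available < 0)) stop("notch1_available must be >= 0")
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  core <- g1_det(notch1_available, params)
  if (noise) core <- core * ln_noise(length(core), params$cv_noise)
  core
}

#' Cell state
#'
#' Minimal per-cell record used by \code{\link{divide_cell}}.
#'
#' @param cell_id,parent_id identifiers (\code{NA} parent for founders).
#' @param generation integer generation index (founders are 0).
#' @param phase current phase.
#' @param phase_entry_time minutes.
#' @param nAS25_F0 inherited antisense titer.
#' @param nAS25_F1 intra-cycle synthesized titer.
#' @param notch1_available available notch-1 signal.
#' @param realized_G1 realized G1 duration (NA until G1 completes).
#' @return object of class \code{"cell_state"}.
#' @export
cell_state <- function(cell_id, parent_id = NA_integer_, generation = 0L,
                       phase = "G0", phase_entry_time = 0,
                       nAS25_F0 = 1, nAS25_F1 = 0, notch1_available = 0,
                       realized_G1 = NA_real_) {
  if (nAS25_F0 < 0 || nAS25_F1 < 0 || notch1_available < 0)
    stop("titers must be non-negative")
  structure(list(cell_id = cell_id, parent_id = parent_id,
                 generation = as.integer(generation),
                 phase = match.arg(phase, c("G0", "G1", "S", "G2", "M")),
                 phase_entry_time = phase_entry_time,
                 nAS25_F0 = nAS25_F0, nAS25_F1 = nAS25_F1,
                 notch1_available = notch1_available,
                 realized_G1 = realized_G1),
            class = "cell_state")
}

#' Divide a mother cell into two daughters
#'
#' The mother's total antisense titer (F0 surviving + F1) is passed to the
#' daughters either by the concentration convention (\code{"equal"}: each
#' daughter inherits the mother's concentration) or by binomial partitioning
#' of molecule counts (\code{"binomial"}: the two daughter counts sum to the
#' mother's count). Daughters enter G0 with the inherited share as F0 and
#' F1 = 0.
#'
#' @param mother a \code{\link{cell_state}} in M phase.
#' @param time division time, minutes.
#' @param ids integer vector of two daughter ids.
#' @param partition partition rule.
#' @param rng_seed optional seed (binomial mode).
#' @return list of two daughter \code{cell_state}s.
#' @export
divide_cell <- function(mother, time, ids = NULL,
                        partition = c("equal", "binomial"),
                        rng_seed = NULL) {
  stopifnot(inherits(mother, "cell_state"))
  partition <- match.arg(partition)
  if (mother$phase != "M") stop("division outside M phase")
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  if (is.null(ids)) ids <- c(1L, 2L)
  total <- mother$nAS25_F0 + mother$nAS25_F1
  if (partition == "equal") {
    shares <- c(total, total)
  } else {
    n <- round(total)
    k <- stats::rbinom(1L, n, 0.5)
    shares <- c(k, n - k)
  }
  lapply(1:2, function(i)
    cell_state(cell_id = ids[i], parent_id = mother$cell_id,
               generation = mother$generation + 1L, phase = "G0",
               phase_entry_time = time, nAS25_F0 = shares[i], nAS25_F1 = 0))
}

#' Simulate proliferating lineages under a scenario
#'
#' Event-driven, generation-vectorized simulation. Each cell passes
#' G0 (masking of the sense transcript by the inherited antisense titer)
#' \eqn{\to} G1 (editing-driven degradation of half the inherited pool,
#' intra-cycle synthesis at \code{k_syn} per realized G1 minute, duration
#' from \code{\link{g1_duration}}) \eqn{\to} S \eqn{\to} G2 \eqn{\to} M
#' \eqn{\to} division. Founders are initialized asynchronously at a
#' uniformly random position of their scenario-determined cycle (or
#' synchronously at M exit under \code{apcin_sync}; parked in G0 under
#' \code{serum_starvation}).
#'
#' @param n_cells number of founder cells.
#' @param t_max simulated time horizon, minutes.
#' @param params a \code{\link{sim_params}}.
#' @param scen a \code{\link{scenario}}.
#' @param rng_seed integer seed (mandatory; the whole record is a
#'   deterministic function of seed + configuration).
#' @param record_titers compute the population mean titer series on the
#'   sampling grid?
#' @return object of class \code{"lineage_record"}: list with \code{cells}
#'   (per-cell table), \code{events} (division events), \code{titers}
#'   (population mean titer on the grid), plus the configuration.
#' @export
simulate_lineage <- function(n_cells, t_max, params = sim_params(),
                             scen = scenario("control"), rng_seed,
                             record_titers = TRUE) {
  stopifnot(inherits(params, "sim_params"), inherits(scen, "scenario"))
  n_cells <- as.integer(n_cells)
  if (n_cells < 0L) stop("n_cells must be >= 0")
  if (n_cells > 0L && t_max <= 0) stop("t_max must be > 0")
  set.seed(as.integer(rng_seed))

  empty_cells <- data.frame(
    cell_id = integer(0), parent_id = integer(0), generation = integer(0),
    birth_time = numeric(0), nAS25_F0 = numeric(0),
    notch1_available = numeric(0), realized_G1 = numeric(0),
    d_S = numeric(0), d_G2 = numeric(0), d_M = numeric(0),
    g1_exit_titer = numeric(0), division_time = numeric(0),
    divided = logical(0))
  record <- structure(
    list(cells = empty_cells,
         events = data.frame(time = numeric(0), mother_id = integer(0),
                             daughter1_id = integer(0),
                             daughter2_id = integer(0)),
         titers = NULL, params = params, scenario = scen,
         rng_seed = as.integer(rng_seed), t_max = t_max,
         n_founders = n_cells),
    class = "lineage_record")
  if (n_cells == 0L) return(record)

  next_id <- 1L
  gen_tabs <- list()
  ev_tabs <- list()

  # founders
  founder_F0 <- rep(1, n_cells) + scen$bolus
  pend <- data.frame(cell_id = seq_len(n_cells), parent_id = NA_integer_,
                     generation = 0L, birth_time = 0, nAS25_F0 = founder_F0)
  next_id <- n_cells + 1L
  founders <- TRUE

  while (nrow(pend) > 0L) {
    n <- nrow(pend)
    F0_eff <- pend$nAS25_F0 * (1 - scen$rnai_efficiency)
    notch1 <- params$masking_slope * F0_eff

    if (scen$park_g0) {
      # serum starvation: founders park in G0; no cycling, no NMD
      tab <- data.frame(pend, notch1_available = notch1,
                        realized_G1 = NA_real_, d_S = NA_real_,
                        d_G2 = NA_real_, d_M = NA_real_,
                        g1_exit_titer = F0_eff,
                        division_time = NA_real_, divided = FALSE)
      gen_tabs[[length(gen_tabs) + 1L]] <- tab
      break
    }

    g1 <- (g1_det(notch1, params) * scen$g1_prolong + scen$g1_delay) *
      ln_noise(n, params$cv_noise)
    dS <- params$d_S * ln_noise(n, params$cv_noise)
    dG2 <- params$d_G2 * ln_noise(n, params$cv_noise)
    dM <- params$d_M * ln_noise(n, params$cv_noise)
    cycle <- params$d_G0 + g1 + dS + dG2 + dM

    if (founders && !scen$sync) {
      # asynchronous: uniform position within the scenario-paced cycle
      pend$birth_time <- -stats::runif(n) * cycle
    }

    synthesized <- if (scen$synthesis_blocked) 0 else
      params$k_syn * g1 * (1 - scen$dcas9_efficiency) *
        (1 - scen$rnai_efficiency)
    total <- params$s_survival * F0_eff + synthesized

    division <- pend$birth_time + cycle
    g2_entry <- pend$birth_time + params$d_G0 + g1 + dS
    arrested <- if (scen$g2_arrest) g2_entry >= scen$onset_time else
      rep(FALSE, n)
    divided <- !arrested & division <= t_max

    tab <- data.frame(pend, notch1_available = notch1, realized_G1 = g1,
                      d_S = dS, d_G2 = dG2, d_M = dM, g1_exit_titer = total,
                      division_time = ifelse(arrested, NA_real_, division),
                      divided = divided)
    gen_tabs[[length(gen_tabs) + 1L]] <- tab

    moms <- which(divided)
    if (length(moms) == 0L) break
    if (params$partition == "equal") {
      d_titer <- rep(total[moms], each = 2L)
    } else {
      nmol <- round(total[moms])
      k <- stats::rbinom(length(moms), nmol, 0.5)
      d_titer <- as.numeric(rbind(k, nmol - k))
    }
    d_ids <- next_id + seq_len(2L * length(moms)) - 1L
    next_id <- next_id + 2L * length(moms)
    ev_tabs[[length(ev_tabs) + 1L]] <- data.frame(
      time = division[moms], mother_id = pend$cell_id[moms],
      daughter1_id = d_ids[c(TRUE, FALSE)],
      daughter2_id = d_ids[c(FALSE, TRUE)])
    pend <- data.frame(
      cell_id = d_ids,
      parent_id = rep(pend$cell_id[moms], each = 2L),
      generation = rep(pend$generation[moms] + 1L, each = 2L),
      birth_time = rep(division[moms], each = 2L),
      nAS25_F0 = d_titer)
    founders <- FALSE
  }

  record$cells <- do.call(rbind, gen_tabs)
  rownames(record$cells) <- NULL
  if (length(ev_tabs) > 0L) {
    ev <- do.call(rbind, ev_tabs)
    ev <- ev[order(ev$time, ev$mother_id), , drop = FALSE]
    rownames(ev) <- NULL
    record$events <- ev
  }
  if (record_titers)
    record$titers <- population_titer_series(record)
  record
}

#' @export
print.lineage_record <- function(x, ...) {
  cat("Lineage record:", x$scenario$name, "scenario\n")
  cat(sprintf("  %d founders, t_max %g min, seed %d\n",
              x$n_founders, x$t_max, x$rng_seed))
  cat(sprintf("  %d cells, %d division events\n",
              nrow(x$cells), nrow(x$events)))
  invisible(x)
}

#' @export
summary.lineage_record <- function(object, ...) {
  cc <- completed_cycles(object)
  out <- list(
    scenario = object$scenario$name,
    n_cells = nrow(object$cells),
    n_events = nrow(object$events),
    mean_cycle = if (length(cc)) mean(cc) else NA_real_,
    mean_G1 = mean(object$cells$realized_G1, na.rm = TRUE),
    mean_exit_titer = mean(object$cells$g1_exit_titer, na.rm = TRUE))
  class(out) <- "summary.lineage_record"
  out
}

#' @export
print.summary.lineage_record <- function(x, ...) {
  cat("Lineage simulation (", x$scenario, ")\n", sep = "")
  cat(sprintf("  cells: %d   divisions: %d\n", x$n_cells, x$n_events))
  cat(sprintf("  mean completed cycle: %.1f min   mean G1: %.1f min\n",
              x$mean_cycle, x$mean_G1))
  cat(sprintf("  mean G1-exit titer: %.3f\n", x$mean_exit_titer))
  invisible(x)
}

#' @export
plot.lineage_record <- function(x, which = c("cumulative", "titer"), ...) {
  which <- match.arg(which)
  if (which == "cumulative") {
    ev <- division_events(x$events$time, condition = x$scenario$name)
    curve <- cumulative_curve(ev, grid_step = x$params$grid_step)
    graphics::plot(curve$time, curve$count, type = "s",
                   xlab = "time (min)", ylab = "cumulative divisions",
                   main = x$scenario$name, ...)
  } else {
    if (is.null(x$titers)) stop("record has no titer series")
    graphics::plot(x$titers$time, x$titers$mean_titer, type = "l",
                   xlab = "time (min)", ylab = "mean nAS25 titer",
                   main = x$scenario$name, ...)
  }
  invisible(x)
}

## realized full cycles (founders included; censored cells excluded)
completed_cycles <- function(record) {
  cells <- record$cells
  ok <- cells$divided & !is.na(cells$realized_G1)
  with(cells[ok, , drop = FALSE],
       division_time - birth_time)
}

## piecewise-linear titer of one cell on absolute times tt
cell_titer <- function(cells_row, tt, params, scen) {
  F0_eff <- cells_row$nAS25_F0 * (1 - scen$rnai_efficiency)
  if (is.na(cells_row$realized_G1))        # parked in G0
    return(rep(F0_eff, length(tt)))
  birth <- cells_row$birth_time
  g1_start <- birth + params$d_G0
  g1_end <- g1_start + cells_row$realized_G1
  td <- min(params$t_deg, cells_row$realized_G1 / 2)
  low <- params$s_survival * F0_eff
  total <- cells_row$g1_exit_titer
  out <- numeric(length(tt))
  seg1 <- tt < g1_start
  seg2 <- tt >= g1_start & tt < g1_start + td
  seg3 <- tt >= g1_start + td & tt < g1_end
  seg4 <- tt >= g1_end
  out[seg1] <- F0_eff
  out[seg2] <- F0_eff + (low - F0_eff) * (tt[seg2] - g1_start) / td
  out[seg3] <- low + (total - low) * (tt[seg3] - g1_start - td) /
    (cells_row$realized_G1 - td)
  out[seg4] <- total
  out
}

## population mean titer on the sampling grid
population_titer_series <- function(record) {
  grid <- seq(0, record$t_max, by = record$params$grid_step)
  sums <- numeric(length(grid))
  nal <- integer(length(grid))
  cells <- record$cells
  for (i in seq_len(nrow(cells))) {
    row <- cells[i, ]
    t_end <- if (isTRUE(row$divided)) row$division_time else record$t_max
    alive <- grid >= max(row$birth_time, 0) & grid <= t_end
    if (!any(alive)) next
    sums[alive] <- sums[alive] +
      cell_titer(row, grid[alive], record$params, record$scenario)
    nal[alive] <- nal[alive] + 1L
  }
  data.frame(time = grid, mean_titer = ifelse(nal > 0, sums / nal, NA_real_),
             n_alive = nal)
}

#' Per-cell antisense titer series
#'
#' Reconstructs the piecewise-linear titer trajectory of selected cells on
#' the sampling grid: constant at the inherited titer through G0, an early-G1
#' decline to the surviving fraction over the degradation transient, a linear
#' rise to the G1-exit total over the rest of G1, then constant to division.
#'
#' @param record a \code{lineage_record}.
#' @param cell_ids cells to extract (default: all).
#' @param grid_step sampling step, minutes.
#' @return long data frame (cell_id, time, titer), each cell sampled from
#'   birth to division (or the horizon).
#' @export
titer_series <- function(record, cell_ids = NULL, grid_step = NULL) {
  stopifnot(inherits(record, "lineage_record"))
  if (is.null(grid_step)) grid_step <- record$params$grid_step
  cells <- record$cells
  if (!is.null(cell_ids)) cells <- cells[cells$cell_id %in% cell_ids, ]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    row <- cells[i, ]
    t_end <- if (isTRUE(row$divided)) row$division_time else record$t_max
    tt <- seq(max(row$birth_time, 0), t_end, by = grid_step)
    out[[i]] <- data.frame(cell_id = row$cell_id, time = tt,
                           titer = cell_titer(row, tt, record$params,
                                              record$scenario))
  }
  do.call(rbind, out)
}

#' Deterministic single-cell titer trajectory across an M-to-G1 passage
#'
#' Noise-free trajectory of the antisense titer in one cell from G1 entry to
#' G1 exit: the inherited titer declines to its surviving fraction over the
#' editing/degradation transient, after which intra-cycle synthesis restores
#' the level. The ratio of the pre-G1 titer to the early-G1 minimum is
#' \eqn{1 / s_{survival}} (2-fold at the default).
#'
#' @param params a \code{\link{sim_params}}.
#' @param scen a \code{\link{scenario}}.
#' @param pre_G1_titer inherited titer at M exit.
#' @param dt time step, minutes.
#' @return data frame (time, titer) over one G1 passage.
#' @export
titer_trajectory <- function(params = sim_params(),
                             scen = scenario("control"),
                             pre_G1_titer = 1, dt = 1) {
  stopifnot(inherits(params, "sim_params"), inherits(scen, "scenario"))
  F0_eff <- pre_G1_titer * (1 - scen$rnai_efficiency)
  notch1 <- params$masking_slope * F0_eff
  g1 <- g1_det(notch1, params) * scen$g1_prolong + scen$g1_delay
  bal <- nAS25_titer_at_G1_exit(pre_G1_titer, params, scen, g1_window = g1)
  td <- min(params$t_deg, g1 / 2)
  tt <- seq(0, g1, by = dt)
  low <- params$s_survival * F0_eff
  titer <- ifelse(tt < td,
                  F0_eff + (low - F0_eff) * tt / td,
                  low + (bal$total - low) * (tt - td) / (g1 - td))
  data.frame(time = tt, titer = titer)
}

#' Estimate the inherited-survival fraction from a simulated record
#'
#' For in-simulation born cells with a completed G1, the early-G1 minimum of
#' the sampled titer trajectory is divided by the titer at birth; the mean
#' ratio estimates \code{s_survival}.
#'
#' @param record a \code{lineage_record}.
#' @param max_cells number of cells sampled (first-born used).
#' @return estimated survival fraction.
#' @export
estimate_survival <- function(record, max_cells = 200L) {
  stopifnot(inherits(record, "lineage_record"))
  cells <- record$cells
  ok <- cells$birth_time >= 0 & !is.na(cells$realized_G1) &
    (cells$birth_time + record$params$d_G0 + cells$realized_G1) <=
      record$t_max
  cells <- cells[ok, , drop = FALSE]
  if (nrow(cells) == 0L) stop("no cells with a completed in-horizon G1")
  cells <- cells[seq_len(min(nrow(cells), max_cells)), , drop = FALSE]
  ratios <- vapply(seq_len(nrow(cells)), function(i) {
    row <- cells[i, ]
    g1_start <- row$birth_time + record$params$d_G0
    tt <- seq(row$birth_time, g1_start + row$realized_G1,
              by = record$params$grid_step)
    tr <- cell_titer(row, tt, record$params, record$scenario)
    min(tr) / tr[1L]
  }, numeric(1))
  mean(ratios)
}

#' Mother-daughter compensation statistics
#'
#' Two summaries of transgenerational coupling: the Pearson correlation of
#' realized G1 durations across mother-daughter pairs (negative under the
#' model: a long-G1 mother accumulates antisense titer, shortening the
#' daughter's G1), and the dominant oscillation period of per-lineage total
#' antisense titer (first local autocorrelation peak), which tracks the
#' interphase length.
#'
#' @param record a \code{lineage_record}.
#' @param min_pairs minimum number of mother-daughter pairs required.
#' @param n_lineages number of root-to-leaf lineage chains used for the
#'   period estimate.
#' @return list with \code{g1_correlation}, \code{n_pairs},
#'   \code{oscillation_period} (min, NA if the record is too short),
#'   \code{mean_interphase} (min).
#' @export
compensation_statistics <- function(record, min_pairs = 30L,
                                    n_lineages = 20L) {
  stopifnot(inherits(record, "lineage_record"))
  cells <- record$cells
  idx <- match(cells$parent_id, cells$cell_id)
  has <- !is.na(idx) & !is.na(cells$realized_G1) &
    !is.na(cells$realized_G1[idx])
  if (sum(has) < min_pairs)
    stop("too few mother-daughter pairs: ", sum(has))
  g1_d <- cells$realized_G1[has]
  g1_m <- cells$realized_G1[idx[has]]
  rho <- stats::cor(g1_m, g1_d)

  period <- lineage_period(record, n_lineages)
  interphase <- with(cells[!is.na(cells$realized_G1), , drop = FALSE],
                     realized_G1 + d_S + d_G2)
  list(g1_correlation = rho, n_pairs = sum(has),
       oscillation_period = period,
       mean_interphase = mean(interphase, na.rm = TRUE))
}

## dominant titer oscillation period from root-to-leaf chains
lineage_period <- function(record, n_lineages) {
  cells <- record$cells
  leaves <- cells$cell_id[!(cells$cell_id %in% cells$parent_id)]
  if (length(leaves) == 0L) return(NA_real_)
  leaves <- leaves[seq_len(min(length(leaves), n_lineages))]
  step <- record$params$grid_step
  periods <- c()
  for (leaf in leaves) {
    chain <- integer(0)
    id <- leaf
    while (!is.na(id)) {
      chain <- c(id, chain)
      id <- cells$parent_id[match(id, cells$cell_id)]
    }
    ts <- titer_series(record, cell_ids = chain, grid_step = step)
    ts <- ts[order(ts$time), ]
    ts <- ts[!duplicated(ts$time), ]
    x <- ts$titer
    if (length(x) < 60L) next
    a <- stats::acf(x - mean(x), lag.max = length(x) - 1L,
                    plot = FALSE)$acf[, 1, 1]
    # first local maximum after the initial decay
    d <- diff(a)
    turn <- which(d[-1] <= 0 & d[-length(d)] > 0) + 1L
    if (length(turn) == 0L) next
    periods <- c(periods, turn[1L] * step)
  }
  if (length(periods) == 0L) NA_real_ else stats::median(periods)
}

#' Export a lineage record as plain-text CSV
#'
#' Writes the division events and the population titer series; identical
#' seeds and configurations give byte-identical files.
#'
#' @param record a \code{lineage_record}.
#' @param events_path,titers_path output CSV paths.
#' @export
write_lineage_record <- function(record, events_path, titers_path) {
  stopifnot(inherits(record, "lineage_record"))
  fmt <- function(df) {
    df[] <- lapply(df, function(col)
      if (is.numeric(col)) sprintf("%.10g", col) else col)
    df
  }
  utils::write.csv(fmt(record$events), events_path, row.names = FALSE,
                   quote = FALSE)
  titers <- record$titers
  if (is.null(titers)) titers <- population_titer_series(record)
  utils::write.csv(fmt(titers), titers_path, row.names = FALSE,
                   quote = FALSE)
  invisible(c(events = events_path, titers = titers_path))
}

#' Calibrate the notch-to-G1 mapping against mitotic-rate anchors
#'
#' Coarse-grid search (optionally refined once) over the G1-mapping steepness
#' \code{beta} and the exogenous bolus size, holding the control constraint
#' \eqn{G1(\code{masking_slope}) = \code{G1_base}} (so the control cycle
#' stays at its nominal mean). The objective matches two slope-ratio
#' anchors: knockdown/control and exogenous-bolus/control (first
#' \code{exo_window} minutes).
#'
#' @param beta_grid,bolus_grid candidate values.
#' @param target_rnai,target_exo slope-ratio anchors (5.4 and 2.5).
#' @param params base \code{\link{sim_params}} (beta is overridden).
#' @param n_cells,t_max,exo_window simulation design.
#' @param seeds integer seeds averaged per candidate.
#' @param refine perform one local refinement pass?
#' @return list with the selected \code{beta}, \code{bolus}, achieved ratios
#'   and the evaluated grid.
#' @export
calibrate_g1_map <- function(beta_grid = seq(3.0, 4.0, by = 0.25),
                             bolus_grid = c(4, 6, 8),
                             target_rnai = 5.4, target_exo = 2.5,
                             params = sim_params(), n_cells = 150,
                             t_max = 1500, exo_window = 600,
                             seeds = 1:3, refine = TRUE) {
  eval_pair <- function(beta, bolus) {
    p <- sim_params(s_survival = params$s_survival,
                    G1_base = params$G1_base, G1_min = params$G1_min,
                    beta = beta, masking_slope = params$masking_slope,
                    cv_noise = params$cv_noise)
    rr <- vapply(seeds, function(s)
      slope_ratio(p, scenario("rnai_nAS25", efficiency = 0.9), s,
                  n_cells, t_max, t_max), numeric(1))
    ee <- vapply(seeds, function(s)
      1 / slope_ratio(p, scenario("nAS25_exo", bolus = bolus), s,
                      n_cells, t_max, exo_window), numeric(1))
    c(rnai = mean(rr), exo = mean(ee))
  }
  grid <- expand.grid(beta = beta_grid, bolus = bolus_grid)
  res <- t(apply(grid, 1L, function(g) eval_pair(g[["beta"]], g[["bolus"]])))
  grid$rnai <- res[, "rnai"]; grid$exo <- res[, "exo"]
  grid$loss <- (log(grid$rnai / target_rnai))^2 +
    (log(grid$exo / target_exo))^2
  best <- grid[which.min(grid$loss), ]
  if (refine) {
    b2 <- seq(best$beta - 0.15, best$beta + 0.15, by = 0.05)
    o2 <- unique(pmax(0.5, best$bolus + c(-1, 0, 1)))
    sub <- calibrate_g1_map(b2, o2, target_rnai, target_exo, params,
                            n_cells, t_max, exo_window, seeds,
                            refine = FALSE)
    sub$coarse_grid <- grid
    return(sub)
  }
  list(beta = best$beta, bolus = best$bolus,
       achieved = c(rnai = best$rnai, exo = best$exo), grid = grid)
}

## control/scenario cumulative-slope ratio on [0, window]
slope_ratio <- function(params, scen, seed, n_cells, t_max, window) {
  ctl <- simulate_lineage(n_cells, t_max, params, scenario("control"),
                          rng_seed = seed, record_titers = FALSE)
  prt <- simulate_lineage(n_cells, t_max, params, scen,
                          rng_seed = seed + 10000L, record_titers = FALSE)
  slope_of <- function(rec) {
    ev <- division_events(rec$events$time[rec$events$time <= window])
    coef(linear_rate(cumulative_curve(ev, grid_step = 10,
                                      t_max = window)))[["slope"]]
  }
  slope_of(ctl) / slope_of(prt)
}
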