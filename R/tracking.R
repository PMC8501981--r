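#' Division-event stream from single-cell tracking
#'
#' @param time numeric vector of division times in minutes (sorted on
#'   ingest).
#' @param cell_id optional identifiers of the dividing cells.
#' @param condition optional condition label.
#' @param n_tracked number of tracked cells (defaults to the number of
#'   distinct ids, or the event count).
#' @return object of class \code{"division_events"}.
#' @export
division_events <- function(time, cell_id = NULL, condition = NULL,
                            n_tracked = NULL) {
  time <- as.numeric(time)
  if (any(time < 0)) stop("division times must be >= 0")
  ord <- order(time)
  time <- time[ord]
  if (!is.null(cell_id)) cell_id <- cell_id[ord]
  if (is.null(n_tracked))
    n_tracked <- if (!is.null(cell_id)) length(unique(cell_id)) else
      length(time)
  structure(list(time = time, cell_id = cell_id,
                 condition = if (is.null(condition)) NA_character_ else
                   condition,
                 n_tracked = n_tracked),
            class = "division_events")
}

#' Read / write division-event streams as CSV
#'
#' Column layout: \code{time_min, cell_id, condition}.
#'
#' @param path CSV path.
#' @param condition restrict to one condition label (default: all rows).
#' @return a \code{\link{division_events}}.
#' @export
read_division_events <- function(path, condition = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_min", "cell_id") %in% names(df)))
    stop("expected columns time_min, cell_id")
  if (!is.null(condition)) df <- df[df$condition == condition, , drop = FALSE]
  division_events(df$time_min, df$cell_id,
                  condition = if (is.null(condition)) NULL else condition)
}

#' @rdname read_division_events
#' @param events a \code{division_events}.
#' @export
write_division_events <- function(events, path) {
  stopifnot(inherits(events, "division_events"))
  df <- data.frame(time_min = events$time,
                   cell_id = if (is.null(events$cell_id))
                     seq_along(events$time) else events$cell_id,
                   condition = events$condition)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cumulative mitotic curve on a regular grid
#'
#' Right-continuous count of division events up to each grid time.
#'
#' @param events a \code{\link{division_events}}.
#' @param grid_step grid spacing in minutes (> 0).
#' @param t_max grid end (default: last event time, rounded up to the grid).
#' @return data frame (time, count).
#' @export
cumulative_curve <- function(events, grid_step = 10, t_max = NULL) {
  stopifnot(inherits(events, "division_events"))
  if (grid_step <= 0) stop("grid_step must be > 0")
  if (is.null(t_max))
    t_max <- if (length(events$time)) ceiling(max(events$time) / grid_step) *
      grid_step else grid_step
  grid <- seq(0, t_max, by = grid_step)
  count <- findInterval(grid, sort(events$time))
  data.frame(time = grid, count = count)
}

#' Least-squares linear mitotic rate
#'
#' Ordinary least squares of cumulative count on time; the slope is the
#' linear approximation of the mitotic rate (events per minute). Computed
#' from the closed-form normal equations.
#'
#' @param curve data frame (time, count) from \code{\link{cumulative_curve}}
#'   (>= 3 grid points).
#' @param n_tracked optional number of tracked cells; when given, a
#'   per-cell-normalized slope is also reported.
#' @return object of class \code{"rate_fit"} with slope, intercept and the
#'   residual series on the evaluation grid.
#' @export
linear_rate <- function(curve, n_tracked = NULL) {
  if (!all(c("time", "count") %in% names(curve)))
    stop("curve must have columns time, count")
  if (nrow(curve) < 3L) stop("need >= 3 grid points")
  t <- curve$time; y <- curve$count
  st <- t - mean(t)
  slope <- sum(st * y) / sum(st^2)
  intercept <- mean(y) - slope * mean(t)
  fitted <- intercept + slope * t
  structure(
    list(slope = slope, intercept = intercept,
         slope_per_cell = if (is.null(n_tracked)) NA_real_ else
           slope / n_tracked,
         residuals = y - fitted, fitted = fitted, curve = curve),
    class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("Linear mitotic rate: %.5g events/min (intercept %.4g)\n",
              x$slope, x$intercept))
  if (!is.na(x$slope_per_cell))
    cat(sprintf("  per tracked cell: %.5g events/min/cell\n",
                x$slope_per_cell))
  invisible(x)
}

#' @export
coef.rate_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.rate_fit <- function(object, ...) object$residuals

#' @export
predict.rate_fit <- function(object, newtime = NULL, ...) {
  if (is.null(newtime)) return(object$fitted)
  object$intercept + object$slope * newtime
}

#' Fold change between two linear mitotic rates
#'
#' Ratio of slopes \code{a / b}, with a direction flag matching the
#' "reduced / increased by X fold" phrasing of tracking studies.
#'
#' @param fit_a,fit_b \code{rate_fit} objects (both slopes must be > 0).
#' @return list with \code{ratio} (slope_a / slope_b), \code{fold} (the
#'   ratio folded to >= 1) and \code{direction} ("a_faster", "b_faster" or
#'   "equal").
#' @export
rate_fold_change <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "rate_fit"), inherits(fit_b, "rate_fit"))
  if (fit_a$slope <= 0 || fit_b$slope <= 0)
    stop("both slopes must be > 0")
  ratio <- fit_a$slope / fit_b$slope
  list(ratio = ratio,
       fold = max(ratio, 1 / ratio),
       direction = if (ratio > 1) "a_faster" else
         if (ratio < 1) "b_faster" else "equal")
}

#' Deviation-from-linearity breakpoint of a cumulative curve
#'
#' Two-segment least-squares fit over candidate breakpoints on the grid. A
#' breakpoint is reported only when the second segment's slope is lower than
#' the first (negative deviation from linearity) and the two-segment fit
#' improves on the single line by at least the stated F ratio
#' \eqn{F = ((SSE_1 - SSE_2)/2) / (SSE_2/(n-4))}. Because the best
#' breakpoint is selected over all candidates, the F statistic is inflated
#' relative to its nominal null distribution; the default threshold of 8 is
#' chosen so that the false-positive rate on pure-linear noisy curves stays
#' below 5 percent.
#'
#' @param curve data frame (time, count); must span at least
#'   \code{2 * min_segment}.
#' @param min_segment minimum segment length in minutes.
#' @param f_threshold F-ratio acceptance threshold.
#' @return breakpoint time in minutes, or \code{NA} when no qualifying
#'   breakpoint exists (including for degenerate constant curves).
#' @export
linearity_breakpoint <- function(curve, min_segment = 150,
                                 f_threshold = 8.0) {
  if (!all(c("time", "count") %in% names(curve)))
    stop("curve must have columns time, count")
  t <- curve$time; y <- curve$count
  if (max(t) - min(t) < 2 * min_segment)
    stop("curve must span at least 2 * min_segment")
  if (stats::var(y) == 0) return(NA_real_)
  sse_lm <- function(ti, yi) {
    st <- ti - mean(ti)
    s2 <- sum(st^2)
    if (s2 == 0) return(c(sse = sum((yi - mean(yi))^2), slope = 0))
    b <- sum(st * yi) / s2
    a <- mean(yi) - b * mean(ti)
    c(sse = sum((yi - a - b * ti)^2), slope = b)
  }
  one <- sse_lm(t, y)
  if (one[["sse"]] <= 1e-10 * max(1, sum(y^2))) return(NA_real_)  # exact line
  cand <- t[t >= min(t) + min_segment & t <= max(t) - min_segment]
  if (length(cand) == 0L) return(NA_real_)
  best <- NULL
  for (b in cand) {
    left <- t <= b
    f1 <- sse_lm(t[left], y[left])
    f2 <- sse_lm(t[!left], y[!left])
    sse <- f1[["sse"]] + f2[["sse"]]
    if (is.null(best) || sse < best$sse)
      best <- list(b = b, sse = sse, s1 = f1[["slope"]], s2 = f2[["slope"]])
  }
  n <- length(t)
  fr <- ((one[["sse"]] - best$sse) / 2) / (best$sse / (n - 4))
  if (!is.finite(fr)) fr <- Inf  # perfect two-segment fit
  if (best$s2 < best$s1 && fr > f_threshold) best$b else NA_real_
}
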