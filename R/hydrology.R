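#' Stage-discharge rating curve with extrapolation scenarios
#'
#' A power-law rating `Q = a * h^b` (L/s, stage in m), calibrated up to a
#' stage limit `h_cal`. Above the calibrated range, three continuation
#' scenarios bound the true rating: the power law is continued with the
#' exponent multiplied by `scenario_mult` (minimum / moderate / high), all
#' continuous at `h_cal`. The defaults reproduce the field weirs' behaviour:
#' Q(2 cm) = 1.7 L/min, Q(3 cm) = 4.7 L/min, and a calibrated limit at the
#' stage corresponding to 0.5 L/s.
#'
#' @param a coefficient (L/s at 1 m stage).
#' @param b exponent.
#' @param h_cal calibrated upper stage limit (m); default the stage at
#'   0.5 L/s.
#' @param scenario_mult exponent multipliers for the (min, mod, high)
#'   continuation above `h_cal`.
#' @return Object of class `rating_curve`.
#' @export
rating_curve <- function(a = 500, b = 2.5,
                         h_cal = (0.5 / a)^(1 / b),
                         scenario_mult = c(0.8, 1, 1.2)) {
  stopifnot(a > 0, b > 0, h_cal > 0, length(scenario_mult) == 3,
            !is.unsorted(scenario_mult))
  structure(list(a = a, b = b, h_cal = h_cal, scenario_mult = scenario_mult),
            class = "rating_curve")
}

#' @export
print.rating_curve <- function(x, ...) {
  cat(sprintf(
    "<rating_curve> Q = %g * h^%g L/s, calibrated to h = %.4f m (%.3g L/s)\n",
    x$a, x$b, x$h_cal, x$a * x$h_cal^x$b))
  cat(sprintf("  extrapolation exponent multipliers: %s\n",
              paste(x$scenario_mult, collapse = "/")))
  invisible(x)
}

#' Convert a stage series to a discharge triple series
#'
#' Within the calibrated range the three scenarios coincide; above it they
#' diverge according to the rating's continuation scenarios.
#'
#' @param stage data frame with `time` and `stage_m` (>= 0).
#' @param rating a [rating_curve()].
#' @return Data frame `time`, `q_min`, `q_mod`, `q_high` (L/s).
#' @export
stage_to_discharge <- function(stage, rating) {
  if (any(stage$stage_m < 0, na.rm = TRUE)) stop("negative stage")
  h <- stage$stage_m
  qcal <- rating$a * h^rating$b
  q_at_lim <- rating$a * rating$h_cal^rating$b
  out <- data.frame(time = stage$time)
  for (k in 1:3) {
    nm <- c("q_min", "q_mod", "q_high")[k]
    bexp <- rating$b * rating$scenario_mult[k]
    q <- qcal
    hi <- !is.na(h) & h > rating$h_cal
    q[hi] <- q_at_lim * (h[hi] / rating$h_cal)^bexp
    out[[nm]] <- q
  }
  out
}

#' Event volume by trapezoidal integration
#'
#' Integrates a discharge series over an event window extended by a
#' recession tail, so that inlet recession after the last wet minute is
#' captured.
#'
#' @param discharge data frame with `time` and one or more discharge columns
#'   (L/s).
#' @param start,end event window (`POSIXct`).
#' @param tail_h recession tail appended to `end` (hours), default 2.
#' @param cols discharge columns to integrate; default all columns except
#'   `time`.
#' @return Named numeric vector of event volumes (L).
#' @export
event_volume <- function(discharge, start, end, tail_h = 2,
                         cols = setdiff(names(discharge), "time")) {
  sel <- discharge$time >= start &
    discharge$time <= end + tail_h * 3600
  t <- as.numeric(discharge$time[sel])
  vapply(cols, function(cn) {
    q <- discharge[[cn]][sel]
    if (length(q) < 2) return(0)
    sum(diff(t) * (utils::head(q, -1) + utils::tail(q, -1)) / 2)
  }, numeric(1))
}

#' Lyne-Hollick recursive baseflow filter
#'
#' Separates fast (quick) flow from a discharge series with the recursive
#' digital filter of Lyne and Hollick, applied in the standard three-pass
#' scheme (forward, backward, forward); each subsequent pass filters the
#' baseflow of the previous one. The fast-flow component is clamped to
#' `[0, Q]` at every step and the first filtered value of each pass is 0.
#'
#' @param q numeric discharge series, regularly sampled.
#' @param alpha filter parameter in (0, 1); the study used 0.9, 0.925 and
#'   0.95 for low, moderate and high fast-flow estimates.
#' @param passes number of filter passes (default 3).
#' @return Data frame `fast`, `base` with `fast + base == q`.
#' @export
separate_fast_flow <- function(q, alpha, passes = 3) {
  stopifnot(alpha > 0, alpha < 1, passes >= 1)
  bt <- q
  for (p in seq_len(passes)) {
    x <- if (p %% 2 == 0) rev(bt) else bt
    f <- lh_pass(x, alpha)
    b <- x - f
    bt <- if (p %% 2 == 0) rev(b) else b
  }
  data.frame(fast = q - bt, base = bt)
}

# One forward pass of the filter on series x.
lh_pass <- function(x, alpha) {
  n <- length(x)
  f <- numeric(n)
  if (n == 0) return(f)
  f[1] <- 0
  k <- (1 + alpha) / 2
  for (i in seq_len(n - 1L) + 1L) {
    f[i] <- alpha * f[i - 1L] + k * (x[i] - x[i - 1L])
    if (f[i] < 0) f[i] <- 0
    if (f[i] > x[i]) f[i] <- x[i]
  }
  f
}

#' Fast-flow volume triple for a stream hydrograph
#'
#' Runs the filter at the three standard parameters and integrates fast flow
#' over an event window. Because a larger filter parameter removes more of
#' the hydrograph into quickflow on storm-shaped series, the triple is
#' labelled low/moderate/high.
#'
#' @param discharge data frame `time`, `q` (L/s).
#' @param start,end event window.
#' @param alphas filter parameters, default `c(0.9, 0.925, 0.95)`.
#' @param tail_h recession tail (hours), as in [event_volume()].
#' @return Named numeric vector `fast_low`, `fast_mod`, `fast_high` (L).
#' @export
stream_fast_volumes <- function(discharge, start, end,
                                alphas = c(0.9, 0.925, 0.95), tail_h = 2) {
  sep <- lapply(alphas, function(a) separate_fast_flow(discharge$q, a)$fast)
  df <- data.frame(time = discharge$time,
                   fast_low = sep[[1]], fast_mod = sep[[2]],
                   fast_high = sep[[3]])
  event_volume(df, start, end, tail_h = tail_h)
}

#' Inlet/stream discharge ratios for one event
#'
#' `r_Q` compares the discharge volume sum of the sampled inlets against the
#' total stream volume, per scenario. `r_Q,fast` compares the inlet sums
#' against the fast stream volume with conservative cross-pairing: the
#' minimum inlet estimate is divided by the high fast-flow estimate and vice
#' versa, so the triple brackets the truth.
#'
#' @param inlet_volumes matrix (inlets x 3) of event volumes (L) with
#'   columns `q_min`, `q_mod`, `q_high`.
#' @param stream_volume total stream volume for the event (L).
#' @param fast_volumes numeric vector `fast_low`, `fast_mod`, `fast_high`
#'   (L).
#' @return List with `r_q` and `r_q_fast`, each a named numeric triple
#'   (`min`, `mod`, `high`); components with a zero denominator are `NA` and
#'   counted in `undefined`.
#' @export
discharge_ratios <- function(inlet_volumes, stream_volume, fast_volumes) {
  sums <- colSums(inlet_volumes)
  r_q <- c(min = NA_real_, mod = NA_real_, high = NA_real_)
  if (stream_volume > 0) r_q[] <- sums / stream_volume
  r_q_fast <- c(
    min = if (fast_volumes[["fast_high"]] > 0)
      sums[["q_min"]] / fast_volumes[["fast_high"]] else NA_real_,
    mod = if (fast_volumes[["fast_mod"]] > 0)
      sums[["q_mod"]] / fast_volumes[["fast_mod"]] else NA_real_,
    high = if (fast_volumes[["fast_low"]] > 0)
      sums[["q_high"]] / fast_volumes[["fast_low"]] else NA_real_)
  list(r_q = r_q, r_q_fast = r_q_fast,
       undefined = sum(is.na(c(r_q, r_q_fast))))
}

#' Extrapolate sampled-inlet discharge to all inlets
#'
#' Scales the measured inlet volume sum to the whole catchment under three
#' proportionality assumptions: discharge proportional to connected road
#' area, to connected agricultural area, or to the number of inlets.
#'
#' @param measured matrix (sampled inlets x 3) of event volumes (L), columns
#'   `q_min`, `q_mod`, `q_high`.
#' @param weights data frame with one row per inlet in the catchment:
#'   `site`, `road_area_m2`, `agri_area_m2`, and logical `sampled`.
#' @return Data frame with one row per method (`road_area`, `agri_area`,
#'   `count`): the scale factor and the extrapolated `q_min`, `q_mod`,
#'   `q_high` totals (L). Methods with zero sampled weight are `NA` and
#'   flagged in `available`.
#' @export
extrapolate_total_inlet_discharge <- function(measured, weights) {
  sums <- colSums(measured)
  meth <- function(total, sampled) {
    if (sampled <= 0) c(factor = NA_real_, q_min = NA_real_,
                        q_mod = NA_real_, q_high = NA_real_)
    else c(factor = total / sampled, sums * total / sampled)
  }
  sampled <- weights$sampled
  rows <- rbind(
    road_area = meth(sum(weights$road_area_m2),
                     sum(weights$road_area_m2[sampled])),
    agri_area = meth(sum(weights$agri_area_m2),
                     sum(weights$agri_area_m2[sampled])),
    count = meth(nrow(weights), sum(sampled)))
  out <- data.frame(method = rownames(rows), rows, row.names = NULL)
  out$available <- !is.na(out$factor)
  out
}
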