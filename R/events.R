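#' Segment a rainfall record into rain events
#'
#' A rainfall episode qualifies as a rain event if its cumulative depth
#' exceeds 1 mm within some 8-hour window inside the episode. Later rainfall
#' belongs to the same event unless separated by a dry period of at least
#' 8 hours (dry means strictly zero recorded depth at the gauge resolution of
#' 0.1 mm); a dry gap of exactly 8 hours terminates the event. Event start and
#' end are the first and last wet minute of the merged episode. Rainfall that
#' never satisfies the 1-mm test is discarded.
#'
#' @param rainfall data frame with columns `time` (`POSIXct`, regular 1-min
#'   sampling) and `depth_mm` (non-negative depths).
#' @param depth_threshold_mm depth that must be exceeded (strictly) within
#'   `window_h` hours for an episode to qualify. Default 1 mm.
#' @param window_h length of the sliding depth window (hours). Default 8.
#' @param gap_h minimum dry-gap length that separates events (hours).
#'   Default 8.
#' @return Data frame with one row per event: `event` (id, ascending in
#'   time), `start`, `end` (`POSIXct`, first/last wet minute), `total_mm`,
#'   `duration_h`, and logical flags `is_sampling_event`, `is_snowmelt`
#'   (initialised `FALSE`; see [flag_sampling_events()]).
#' @seealso [flag_sampling_events()]
#' @export
classify_events <- function(rainfall, depth_threshold_mm = 1,
                            window_h = 8, gap_h = 8) {
  stopifnot(all(c("time", "depth_mm") %in% names(rainfall)))
  if (nrow(rainfall) == 0) return(empty_events())
  if (is.unsorted(as.numeric(rainfall$time), strictly = TRUE))
    stop("rainfall timestamps must be strictly increasing")
  if (any(rainfall$depth_mm < 0)) stop("negative rainfall depth")

  dt_min <- if (nrow(rainfall) > 1)
    as.numeric(difftime(rainfall$time[2], rainfall$time[1], units = "mins"))
  else 1
  wet <- rainfall$depth_mm > 0
  if (!any(wet)) return(empty_events())

  # Wet bursts and the dry gaps between them.
  r <- rle(wet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  wet_runs <- which(r$values)
  burst <- data.frame(i0 = starts[wet_runs], i1 = ends[wet_runs])

  # Merge bursts separated by < gap_h of dry record (>= gap_h separates).
  gap_steps <- gap_h * 60 / dt_min
  grp <- cumsum(c(1L, as.integer(
    (burst$i0[-1] - burst$i1[-nrow(burst)] - 1L) >= gap_steps)))
  episodes <- do.call(rbind, lapply(split(burst, grp), function(b)
    data.frame(i0 = min(b$i0), i1 = max(b$i1))))

  # Keep episodes with > depth_threshold_mm within a sliding window.
  win_steps <- as.integer(round(window_h * 60 / dt_min))
  qual <- vapply(seq_len(nrow(episodes)), function(k) {
    d <- rainfall$depth_mm[episodes$i0[k]:episodes$i1[k]]
    if (length(d) <= win_steps) return(sum(d) > depth_threshold_mm)
    cs <- cumsum(d)
    any((cs[(win_steps + 1):length(d)] - cs[1:(length(d) - win_steps)]) >
          depth_threshold_mm) || cs[win_steps] > depth_threshold_mm
  }, logical(1))
  episodes <- episodes[qual, , drop = FALSE]
  if (nrow(episodes) == 0) return(empty_events())

  data.frame(
    event = seq_len(nrow(episodes)),
    start = rainfall$time[episodes$i0],
    end = rainfall$time[episodes$i1],
    total_mm = vapply(seq_len(nrow(episodes)), function(k)
      sum(rainfall$depth_mm[episodes$i0[k]:episodes$i1[k]]), numeric(1)),
    duration_h = as.numeric(difftime(rainfall$time[episodes$i1],
                                     rainfall$time[episodes$i0],
                                     units = "hours")),
    is_sampling_event = FALSE,
    is_snowmelt = FALSE
  )
}

empty_events <- function() {
  data.frame(event = integer(0),
             start = as.POSIXct(character(0), tz = "UTC"),
             end = as.POSIXct(character(0), tz = "UTC"),
             total_mm = numeric(0), duration_h = numeric(0),
             is_sampling_event = logical(0), is_snowmelt = logical(0))
}

#' Flag sampling events from inlet stage records
#'
#' Reproduces the field trigger logic: a water-level proportional sampler at
#' an inlet takes one composite sample per event iff the inlet's stage
#' threshold is exceeded during the event window; the automatic samplers at
#' the collector shaft (CS) and the stream (ST) are triggered iff the
#' threshold is exceeded in at least two inlets. Events with no trigger
#' anywhere are left unflagged. Missing stage data for an (inlet, event)
#' window yields `NA` ("unknown"), never `FALSE`.
#'
#' @param events event table from [classify_events()].
#' @param stage named list of per-inlet stage series, each a data frame with
#'   `time` and `stage_m`.
#' @param thresholds named numeric vector of per-inlet stage thresholds (m);
#'   names must match `names(stage)`. The field values were 0.02 m for inlets
#'   with little runoff and 0.03 m for inlets with larger runoff.
#' @param min_inlets_for_cs_st number of triggered inlets needed to start the
#'   CS/ST samplers. Default 2.
#' @return List with `events` (the input with `is_sampling_event` and new
#'   logical columns `cs_st_triggered`), and `triggers`, a (event x inlet)
#'   logical matrix of per-site composite-sample existence (`NA` = unknown).
#' @export
flag_sampling_events <- function(events, stage, thresholds,
                                 min_inlets_for_cs_st = 2L) {
  stopifnot(all(names(stage) %in% names(thresholds)))
  sites <- names(stage)
  trig <- matrix(NA, nrow(events), length(sites),
                 dimnames = list(NULL, sites))
  for (s in sites) {
    ss <- stage[[s]]
    for (k in seq_len(nrow(events))) {
      inwin <- ss$time >= events$start[k] & ss$time <= events$end[k]
      if (!any(inwin) || anyNA(ss$stage_m[inwin])) next
      trig[k, s] <- max(ss$stage_m[inwin]) > thresholds[s]
    }
  }
  n_trig <- rowSums(trig, na.rm = TRUE)
  events$cs_st_triggered <- n_trig >= min_inlets_for_cs_st
  events$is_sampling_event <- n_trig >= 1L
  list(events = events, triggers = trig)
}
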