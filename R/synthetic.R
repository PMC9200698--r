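#' Generator settings for the synthetic catchment
#'
#' The defaults emulate the study system at reduced spatial extent: a
#' valley-shaped terrain with 5% mean slope draining to a stream, a network
#' of farm tracks and a concrete road with 158 storm drainage inlets, and
#' rectangular field plots between the roads.
#'
#' @param nrow,ncol grid size in cells (rejected below 20 x 20).
#' @param cellsize cell edge (m), default 2.
#' @param n_inlets number of inlets placed on road cells, default 158.
#' @param n_plots number of field plots, default 48.
#' @param mean_slope down-valley slope (m/m), default 0.05.
#' @param lateral_slope cross-valley slope towards the central thalweg.
#' @param noise_sd standard deviation of the correlated elevation noise (m).
#' @param noise_smooth half-width (cells) of the smoothing kernel applied to
#'   the noise.
#' @param n_pits number of artificial depressions dug into the terrain.
#' @param pit_depth depth range of the pits (m).
#' @param road_spacing_m spacing of the east-west farm tracks (m).
#' @param concrete_road include a north-south concrete road, default `TRUE`.
#' @return List of class `catchment_config`.
#' @export
catchment_config <- function(nrow = 250, ncol = 250, cellsize = 2,
                             n_inlets = 158, n_plots = 48,
                             mean_slope = 0.05, lateral_slope = 0.02,
                             noise_sd = 0.1, noise_smooth = 4,
                             n_pits = 6, pit_depth = c(0.05, 0.6),
                             road_spacing_m = 100, concrete_road = TRUE) {
  structure(as.list(environment()), class = "catchment_config")
}

#' Generate a synthetic study catchment
#'
#' Builds a DEM (smooth valley trend plus correlated noise plus optional
#' pits), a road network of east-west farm tracks and an optional concrete
#' road, inlets placed on road cells, rectangular crop plots between the
#' roads, and stream cells along the valley bottom. Reproducible for a fixed
#' seed.
#'
#' @param config a [catchment_config()].
#' @param seed integer seed.
#' @return Object of class `synthetic_catchment`: `dem` ([dem_grid()]),
#'   `roads` (segment data frame with `surface`), `road_cells`
#'   (row/col/segment/surface), `inlets` (site, cell, coordinates, stage
#'   threshold, activation rainfall, `via_cs`), `plots` (named list of
#'   rings), `plots_df` (metadata), `stream_cells`, and `config`.
#' @export
generate_catchment <- function(config = catchment_config(), seed = 1) {
  if (config$nrow < 20 || config$ncol < 20)
    stop("grid too small: need at least 20 x 20 cells")
  set.seed(child_seed(seed, "catchment"))
  nr <- config$nrow; nc <- config$ncol; cs <- config$cellsize
  width <- nc * cs; height <- nr * cs

  # Valley trend: rises away from the stream (bottom row) and from the
  # central thalweg.
  yy <- (nr:1 - 0.5) * cs              # y of each row (row 1 = top)
  xx <- (1:nc - 0.5) * cs
  xc <- width / 2
  z <- outer(yy, rep(1, nc)) * config$mean_slope +
    outer(rep(1, nr), abs(xx - xc)) * config$lateral_slope

  # Correlated noise: smoothed white noise.
  if (config$noise_sd > 0) {
    noise <- matrix(stats::rnorm(nr * nc), nr, nc)
    k <- config$noise_smooth
    if (k > 0) {
      kern <- stats::dnorm(seq(-k, k), sd = k / 2)
      kern <- kern / sum(kern)
      noise <- t(apply(noise, 1, function(r)
        stats::filter(r, kern, circular = TRUE)))
      noise <- apply(noise, 2, function(cl)
        stats::filter(cl, kern, circular = TRUE))
    }
    noise <- noise / stats::sd(noise) * config$noise_sd
    z <- z + noise
  }

  # Pits (potential sinks).
  if (config$n_pits > 0) {
    pr <- sample(5:(nr - 5), config$n_pits)
    pc <- sample(5:(nc - 5), config$n_pits)
    pd <- stats::runif(config$n_pits, config$pit_depth[1],
                       config$pit_depth[2])
    for (i in seq_len(config$n_pits)) {
      rr <- max(1, pr[i] - 1):min(nr, pr[i] + 1)
      cc <- max(1, pc[i] - 1):min(nc, pc[i] + 1)
      z[rr, cc] <- z[rr, cc] - pd[i] / 2
      z[pr[i], pc[i]] <- z[pr[i], pc[i]] - pd[i] / 2
    }
  }
  dem <- dem_grid(z, cs)

  # Roads: east-west farm tracks; optional north-south concrete road.
  n_tracks <- max(1, floor(height / config$road_spacing_m) - 1)
  ys <- seq_len(n_tracks) * config$road_spacing_m
  roads <- data.frame(
    road_id = paste0("FT", seq_len(n_tracks)),
    surface = "farm_track",
    x0 = 2 * cs, y0 = ys, x1 = width - 2 * cs, y1 = ys)
  if (config$concrete_road) {
    roads <- rbind(roads, data.frame(
      road_id = "CR1", surface = "concrete",
      x0 = width * 0.25, y0 = 2 * cs, x1 = width * 0.25,
      y1 = height - 2 * cs))
  }
  rc <- rasterize_segments(dem, roads)
  road_cells <- data.frame(row = rc[, "row"], col = rc[, "col"],
                           road_id = roads$road_id[rc[, "segment"]],
                           surface = roads$surface[rc[, "segment"]])
  road_cells <- road_cells[!duplicated(road_cells[, c("row", "col")]), ]

  # Inlets on road cells, spread out; stage thresholds 2 cm / 3 cm and
  # per-inlet activation rainfall bracketing the field observations.
  n_inl <- min(config$n_inlets, nrow(road_cells))
  pick <- sample(nrow(road_cells), n_inl)
  inl_rc <- road_cells[pick, ]
  xy <- cell_xy(dem, inl_rc$row, inl_rc$col)
  inlets <- data.frame(
    site = sprintf("I%03d", seq_len(n_inl)),
    row = inl_rc$row, col = inl_rc$col, x = xy[, 1], y = xy[, 2],
    surface = inl_rc$surface,
    threshold_m = sample(c(0.02, 0.03), n_inl, TRUE, prob = c(0.6, 0.4)),
    activation_mm = stats::runif(n_inl, 1.3, 3.6),
    via_cs = xy[, 1] > width / 2)

  # Stream: the bottom row of the grid.
  stream_cells <- cbind(row = rep(nr, nc), col = seq_len(nc))

  # Plots: rectangles between consecutive farm tracks.
  plots <- list(); meta <- list()
  if (config$n_plots > 0) {
    bands <- c(0, ys, height)
    per_band <- ceiling(config$n_plots / (length(bands) - 1))
    crops <- c("grain", "potato", "sugar_beet", "meadow")
    pid <- 0
    for (b in seq_len(length(bands) - 1)) {
      y0 <- bands[b] + 2 * cs; y1 <- bands[b + 1] - 2 * cs
      if (y1 - y0 < 4 * cs) next
      xs <- seq(2 * cs, width - 2 * cs, length.out = per_band + 1)
      for (p in seq_len(per_band)) {
        if (pid >= config$n_plots) break
        pid <- pid + 1
        id <- sprintf("P%03d", pid)
        ring <- cbind(c(xs[p] + cs, xs[p + 1] - cs, xs[p + 1] - cs,
                        xs[p] + cs),
                      c(y0, y0, y1, y1))
        plots[[id]] <- ring
        meta[[id]] <- data.frame(
          plot_id = id, crop = sample(crops, 1),
          area_m2 = (xs[p + 1] - xs[p] - 2 * cs) * (y1 - y0))
      }
    }
  }
  plots_df <- if (length(meta) > 0) do.call(rbind, meta) else
    data.frame(plot_id = character(0), crop = character(0),
               area_m2 = numeric(0))
  rownames(plots_df) <- NULL

  structure(list(dem = dem, roads = roads, road_cells = road_cells,
                 inlets = inlets, plots = plots, plots_df = plots_df,
                 stream_cells = stream_cells, config = config, seed = seed),
            class = "synthetic_catchment")
}

#' @export
print.synthetic_catchment <- function(x, ...) {
  cat(sprintf(
    "<synthetic_catchment> %d x %d cells @ %g m; %d inlets, %d plots, %d road cells\n",
    nrow(x$dem$z), ncol(x$dem$z), x$dem$cellsize, nrow(x$inlets),
    length(x$plots), nrow(x$road_cells)))
  invisible(x)
}

#' Rainfall generator settings
#'
#' @param start,end simulation window (UTC); the default spans the
#'   study-type high-risk period 1 April to 20 August.
#' @param storm_rate_per_day expected storms per day before merging.
#' @param depth_meanlog,depth_sdlog lognormal parameters of storm totals
#'   (mm).
#' @param duration_meanlog,duration_sdlog lognormal parameters of storm
#'   durations (h).
#' @return List of class `rainfall_config`.
#' @export
rainfall_config <- function(start = as.POSIXct("2019-04-01", tz = "UTC"),
                            end = as.POSIXct("2019-08-20", tz = "UTC"),
                            storm_rate_per_day = 0.30,
                            depth_meanlog = log(3.5), depth_sdlog = 0.9,
                            duration_meanlog = log(5), duration_sdlog = 0.8) {
  structure(as.list(environment()), class = "rainfall_config")
}

#' Generate a 1-minute rainfall series
#'
#' Clustered storms from a marked point process: storm starts are Poisson in
#' time, each storm carries a lognormal total depth and duration and a
#' gamma-shaped within-storm intensity profile. Depths are quantised to the
#' gauge resolution of 0.1 mm while conserving each storm's total.
#'
#' @param config a [rainfall_config()].
#' @param seed integer seed.
#' @return Data frame `time` (`POSIXct`, 1-min), `depth_mm`.
#' @export
generate_rainfall <- function(config = rainfall_config(), seed = 1) {
  days <- as.numeric(difftime(config$end, config$start, units = "days"))
  if (days < 1) stop("rainfall window must be at least one day")
  set.seed(child_seed(seed, "rainfall"))
  n_min <- ceiling(days * 24 * 60)
  depth <- numeric(n_min)
  n_storms <- stats::rpois(1, config$storm_rate_per_day * days)
  if (n_storms > 0) {
    starts <- sort(sample(n_min, n_storms, replace = TRUE))
    totals <- stats::rlnorm(n_storms, config$depth_meanlog,
                            config$depth_sdlog)
    durs <- pmax(20, round(stats::rlnorm(n_storms, config$duration_meanlog,
                                         config$duration_sdlog) * 60))
    for (s in seq_len(n_storms)) {
      i0 <- starts[s]
      i1 <- min(n_min, i0 + durs[s] - 1)
      n <- i1 - i0 + 1
      prof <- stats::dgamma(seq_len(n) / n * 4, shape = 2)
      if (sum(prof) <= 0) prof <- rep(1, n)
      depth[i0:i1] <- depth[i0:i1] + totals[s] * prof / sum(prof)
    }
  }
  # Quantise to 0.1 mm conserving cumulative depth.
  q <- diff(c(0, round(cumsum(depth) * 10))) / 10
  data.frame(time = config$start + (seq_len(n_min) - 1) * 60,
             depth_mm = q)
}

#' Application generator settings
#'
#' @param n_applications number of in-window application records.
#' @param share_in_window mass share applied inside the study window (the
#'   remainder is dated after the window), default 0.96.
#' @param mass_meanlog,mass_sdlog lognormal parameters of applied mass (g).
#' @return List of class `application_config`.
#' @export
application_config <- function(n_applications = 120,
                               share_in_window = 0.96,
                               mass_meanlog = log(200), mass_sdlog = 0.8) {
  structure(as.list(environment()), class = "application_config")
}

#' Generate plot-resolved pesticide application records
#'
#' Applications are concentrated in spring/early summer (Beta(2, 2.5)
#' position within the window), reference existing plots, and place at
#' least `share_in_window` of the total mass inside the window by
#' construction: the complementary mass is dated after the window end.
#'
#' @param catchment a [generate_catchment()] result.
#' @param substances a [substance_properties()] table; transformation
#'   products are not applied.
#' @param config an [application_config()].
#' @param seed integer seed.
#' @param window `POSIXct` length-2 study window (start, end); default the
#'   [rainfall_config()] defaults.
#' @return Data frame: `application_id`, `substance`, `date` (`Date`),
#'   `plot_id`, `mass_g`, `plot_area_m2`.
#' @export
generate_applications <- function(catchment, substances,
                                  config = application_config(), seed = 1,
                                  window = NULL) {
  stopifnot(nrow(substances) > 0)
  if (is.null(window)) {
    rc <- rainfall_config()
    window <- c(rc$start, rc$end)
  }
  set.seed(child_seed(seed, "applications"))
  if (config$n_applications == 0 || length(catchment$plots) == 0)
    return(data.frame(application_id = integer(0), substance = character(0),
                      date = as.Date(character(0)), plot_id = character(0),
                      mass_g = numeric(0), plot_area_m2 = numeric(0)))
  parents <- substances$name[!substances$is_tp]
  n <- config$n_applications
  d0 <- as.Date(window[1]); d1 <- as.Date(window[2])
  span <- as.numeric(d1 - d0)
  dates <- d0 + round(stats::rbeta(n, 2, 2.5) * span)
  plot_ids <- sample(catchment$plots_df$plot_id, n, replace = TRUE)
  mass <- stats::rlnorm(n, config$mass_meanlog, config$mass_sdlog)
  out <- data.frame(application_id = seq_len(n),
                    substance = sample(parents, n, replace = TRUE),
                    date = dates, plot_id = plot_ids, mass_g = mass)
  if (config$share_in_window < 1) {
    extra_mass <- sum(mass) * (1 - config$share_in_window) /
      config$share_in_window
    n_extra <- max(1L, round(n * 0.04))
    out_extra <- data.frame(
      application_id = n + seq_len(n_extra),
      substance = sample(parents, n_extra, replace = TRUE),
      date = d1 + sample(10:60, n_extra, TRUE),
      plot_id = sample(catchment$plots_df$plot_id, n_extra, TRUE),
      mass_g = extra_mass * as.numeric(stats::rmultinom(1, 1000,
        rep(1, n_extra))) / 1000)
    out <- rbind(out, out_extra)
  }
  out$plot_area_m2 <-
    catchment$plots_df$area_m2[match(out$plot_id,
                                     catchment$plots_df$plot_id)]
  out
}

#' Observation simulator settings
#'
#' @param runoff_coefficients event-scale runoff coefficients per surface
#'   class (concrete > farm track > field).
#' @param sigma_log10 multiplicative lognormal concentration noise
#'   (log10 SD), default 0.2.
#' @param washoff_per_mm fraction of decayed applied mass washed towards the
#'   receiving site per mm of effective rain.
#' @param drift_frac fraction of applied mass deposited as spray drift on a
#'   site/road within the drift radius (washed off at the next event).
#' @param tile_washoff_per_mm catchment-scale export fraction per mm of
#'   event rain delivered to the stream via tile drainage and other diffuse
#'   pathways (applies to all applications, site ST; the collector shaft
#'   receives `tile_cs_share` of it).
#' @param tile_cs_share share of the tile-drainage export passing the
#'   collector shaft.
#' @param background_rate probability per (site, event) of a spurious
#'   background/spill pulse.
#' @param background_meanlog,background_sdlog lognormal pulse load (ng).
#' @param reservoir enable stagnant-water carry-over between events.
#' @param reservoir_frac fraction of an event's in-inlet load retained and
#'   re-emitted at the following event.
#' @param n_sampled_inlets how many inlets carry stage sensors and samplers.
#'   The sampled inlets are drawn from the mid-to-upper range of the
#'   contributing-area distribution (instrumentable, but not the extremes).
#' @param urban_fast_frac fraction of the catchment area that responds as
#'   additional fast runoff in the stream (urban surfaces, tile drainage,
#'   pre-event water); the stream's quickflow is dominated by these
#'   non-inlet sources.
#' @param stream_baseflow_lps stream baseflow (L/s).
#' @param tail_h recession tail appended to event windows (h).
#' @param snowmelt mark the first event as snowmelt with elevated road
#'   runoff.
#' @param grab_samples take a stagnant-water grab sample when an inlet did
#'   not trigger, default `TRUE`.
#' @return List of class `observation_config`.
#' @export
observation_config <- function(runoff_coefficients = c(concrete = 0.8,
                                                       farm_track = 0.45,
                                                       field = 0.12),
                               sigma_log10 = 0.2,
                               washoff_per_mm = 1e-7,
                               drift_frac = 3e-7,
                               tile_washoff_per_mm = 4e-6,
                               tile_cs_share = 0.5,
                               background_rate = 0.05,
                               background_meanlog = log(1e5),
                               background_sdlog = 1,
                               reservoir = TRUE, reservoir_frac = 0.25,
                               n_sampled_inlets = 4,
                               urban_fast_frac = 0.35,
                               stream_baseflow_lps = 5,
                               tail_h = 2,
                               snowmelt = FALSE,
                               grab_samples = TRUE) {
  structure(as.list(environment()), class = "observation_config")
}

#' Simulate stage, discharge and concentration observations
#'
#' Runs the forward model on a synthetic catchment: classifies the rainfall
#' into events, routes surface runoff per event through the connectivity
#' model, generates inlet stage and stream discharge series, and produces a
#' censored concentration table per (site, event, substance) together with
#' the uncensored ground truth. Concentrations are constant within an event
#' per site; the mechanism is load/volume with multiplicative lognormal
#' noise. Sources per inlet and event: wash-off of prior applications in the
#' contributing area (first-order decay at rate ln(2)/DT50_soil since
#' application), spray-drift deposits within the drift radius (washed off at
#' the first subsequent event), random background/spill pulses, and
#' stagnant-water reservoir carry-over from the previous event.
#'
#' @param catchment a [generate_catchment()] result.
#' @param rainfall a [generate_rainfall()] series covering the catchment
#'   window.
#' @param applications a [generate_applications()] table.
#' @param substances a [substance_properties()] table.
#' @param config an [observation_config()].
#' @param seed integer seed.
#' @param ca_map optional precomputed [delineate_contributing_areas()]
#'   result for the catchment (computed if missing).
#' @param exposure optional precomputed [build_exposure_table()] for the
#'   sampled sites + CS + ST.
#' @return List of class `synthetic_observations`: `events`, `stage` (named
#'   list, sampled inlets), `stream_discharge`, `samples` (site, event,
#'   substance, value, loq, censored, sample_type), `truth` (list:
#'   `loads` with uncensored loads/volumes/concentrations, `volumes`
#'   (event x all inlets), `categories`, `mass_applied_ng`,
#'   `mass_routed_ng`), `ca_map`, `exposure`, `sampled_sites`, `weights`
#'   (per-inlet extrapolation weights).
#' @export
simulate_observations <- function(catchment, rainfall, applications,
                                  substances = default_substances(),
                                  config = observation_config(), seed = 1,
                                  ca_map = NULL, exposure = NULL) {
  if (max(rainfall$time) < min(rainfall$time))
    stop("empty rainfall series")
  set.seed(child_seed(seed, "observations"))
  events <- classify_events(rainfall)
  if (nrow(events) == 0) stop("rainfall window produced no events")
  if (config$snowmelt) events$is_snowmelt[1] <- TRUE

  dem <- catchment$dem
  cellarea <- dem$cellsize^2
  inl <- catchment$inlets
  n_inl <- nrow(inl)

  # --- connectivity -------------------------------------------------------
  if (is.null(ca_map)) {
    road_mask <- matrix(FALSE, nrow(dem$z), ncol(dem$z))
    road_mask[cbind(catchment$road_cells$row, catchment$road_cells$col)] <- TRUE
    agri_mask <- matrix(FALSE, nrow(dem$z), ncol(dem$z))
    for (ring in catchment$plots)
      agri_mask[rasterize_polygon(dem, ring)] <- TRUE
    cd <- condition_dem(dem, as.matrix(
      catchment$road_cells[, c("row", "col")]),
      connectivity_params(),
      outlets = rbind(catchment$stream_cells,
                      as.matrix(inl[, c("row", "col")])))
    fd <- flow_directions_dinf(cd)
    ca_map <- suppressWarnings(delineate_contributing_areas(
      fd, inl, catchment$stream_cells,
      agri_mask = agri_mask, road_mask = road_mask))
  }
  dest <- ca_map$destinations

  # Sampled sites: largest inlets by contributing area, for sensor-worthy
  # discharge; plus collector shaft (CS) and stream (ST).
  inlet_area <- dest$area_m2[match(paste0("inlet_", inl$site), dest$dest)]
  road_area <- dest$road_area_m2[match(paste0("inlet_", inl$site), dest$dest)]
  agri_area <- dest$agri_area_m2[match(paste0("inlet_", inl$site), dest$dest)]
  n_samp <- min(config$n_sampled_inlets, n_inl)
  ord_area <- order(inlet_area, decreasing = TRUE)
  sampled_idx <- if (n_inl <= 2 * n_samp) ord_area[seq_len(n_samp)] else
    ord_area[pmax(1L, round(stats::quantile(seq_len(n_inl),
      seq(0.15, 0.65, length.out = n_samp), names = FALSE)))]
  sampled_sites <- inl$site[sampled_idx]
  weights <- data.frame(site = inl$site,
                        road_area_m2 = road_area,
                        agri_area_m2 = agri_area,
                        area_m2 = inlet_area,
                        sampled = inl$site %in% sampled_sites)

  sites_df <- data.frame(site = c(sampled_sites, "CS", "ST"),
                         x = c(inl$x[sampled_idx], NA, NA),
                         y = c(inl$y[sampled_idx], NA, NA))
  # CS sits at the catchment outlet side; ST at the outlet. Give them the
  # outlet coordinates for drift distance purposes.
  outlet_xy <- cell_xy(dem, nrow(dem$z), round(ncol(dem$z) / 2))
  sites_df$x[is.na(sites_df$x)] <- outlet_xy[1]
  sites_df$y[is.na(sites_df$y)] <- outlet_xy[2]

  site_labels <- c(
    stats::setNames(as.list(paste0("inlet_", sampled_sites)), sampled_sites),
    list(CS = paste0("inlet_", inl$site[inl$via_cs]),
         ST = c("stream", paste0("inlet_", inl$site))))

  if (is.null(exposure)) {
    exposure <- build_exposure_table(
      ca_map, dem, catchment$plots, applications,
      as.matrix(catchment$road_cells[, c("row", "col")]),
      sites_df, site_labels = site_labels)
  }

  # --- per-event hydrology ------------------------------------------------
  # Per-inlet surface composition of the contributing area.
  lab <- ca_map$labels
  road_lab <- lab[cbind(catchment$road_cells$row, catchment$road_cells$col)]
  rc_road_count <- tabulate(road_lab, nbins = nrow(dest))
  inl_dest_idx <- match(paste0("inlet_", inl$site), dest$dest)
  a_road <- rc_road_count[inl_dest_idx] * cellarea
  a_total <- dest$area_m2[inl_dest_idx]
  a_field <- pmax(0, a_total - a_road)
  rc <- config$runoff_coefficients
  road_rc <- ifelse(inl$surface == "concrete", rc[["concrete"]],
                    rc[["farm_track"]])

  n_ev <- nrow(events)
  P <- events$total_mm
  vol_true <- matrix(0, n_ev, n_inl,
                     dimnames = list(events$event, inl$site))
  for (e in seq_len(n_ev)) {
    eff <- pmax(0, P[e] - inl$activation_mm)   # effective depth, mm
    road_mult <- if (events$is_snowmelt[e]) 3 else 1
    # 1 mm over 1 m2 is 1 L, so effective depth times weighted area is L.
    vol_true[e, ] <- eff * (road_rc * a_road * road_mult +
                              rc[["field"]] * a_field)
  }

  # Stream: whole-catchment quickflow + baseflow, 1-min resolution. Fast
  # flow in the stream combines the inlet drainage, fields directly
  # connected to the stream, and a dominant non-inlet component (urban
  # surfaces, tile drainage, pre-event water).
  total_area <- sum(dest$frac_area_m2)
  stream_direct_area <- sum(dest$frac_area_m2[dest$type == "stream"])
  eff_area <- rc[["field"]] * stream_direct_area +
    sum(road_rc * a_road + rc[["field"]] * a_field) +
    config$urban_fast_frac * total_area
  tau_stream <- 60
  input <- rainfall$depth_mm * eff_area / 1000 * 1000 / 60  # L/s per minute
  qf <- stats::filter(input * (1 - exp(-1 / tau_stream)),
                      exp(-1 / tau_stream), method = "recursive")
  stream_discharge <- data.frame(time = rainfall$time,
                                 q = config$stream_baseflow_lps +
                                   as.numeric(qf))

  # Inlet stage series for the sampled inlets (true rating = moderate law).
  rating <- rating_curve()
  tau_inlet <- 5
  stage <- list()
  for (s in seq_along(sampled_sites)) {
    i <- sampled_idx[s]
    q <- numeric(nrow(rainfall))
    for (e in seq_len(n_ev)) {
      v <- vol_true[e, i]
      if (v <= 0) next
      sel <- which(rainfall$time >= events$start[e] &
                     rainfall$time <= events$end[e] + config$tail_h * 3600)
      prof <- stats::filter(rainfall$depth_mm[sel] *
                              (1 - exp(-1 / tau_inlet)),
                            exp(-1 / tau_inlet), method = "recursive")
      prof <- as.numeric(prof)
      tot <- sum(prof) * 60
      if (tot <= 0) next
      q[sel] <- q[sel] + v * prof / tot  # L/s, integrates to v
    }
    h <- (q / rating$a)^(1 / rating$b)
    stage[[sampled_sites[s]]] <- data.frame(time = rainfall$time,
                                            stage_m = h)
  }

  # --- concentrations -----------------------------------------------------
  all_sites <- c(sampled_sites, "CS", "ST")
  subs <- substances$name
  ln2 <- log(2)
  appl <- applications
  appl$date <- as.Date(appl$date)

  # Per-site exposure lookup split for speed.
  expo_by_site <- split(as.data.frame(exposure), exposure$site)

  # Event volumes per analysis site (L). CS = sum of member inlets; ST =
  # stream event volume.
  member_cs <- which(inl$via_cs)
  vol_site <- matrix(0, n_ev, length(all_sites),
                     dimnames = list(events$event, all_sites))
  for (s in seq_along(sampled_sites))
    vol_site[, s] <- vol_true[, sampled_idx[s]]
  vol_site[, "CS"] <- rowSums(vol_true[, member_cs, drop = FALSE])
  for (e in seq_len(n_ev))
    vol_site[e, "ST"] <- event_volume(
      stats::setNames(stream_discharge, c("time", "q")),
      events$start[e], events$end[e], tail_h = config$tail_h, cols = "q")

  # Trigger state per event: inlet triggered iff stage threshold exceeded.
  trig <- matrix(FALSE, n_ev, length(sampled_sites),
                 dimnames = list(events$event, sampled_sites))
  for (s in seq_along(sampled_sites)) {
    th <- inl$threshold_m[sampled_idx[s]]
    ss <- stage[[sampled_sites[s]]]
    for (e in seq_len(n_ev)) {
      sel <- ss$time >= events$start[e] &
        ss$time <= events$end[e] + config$tail_h * 3600
      trig[e, s] <- any(ss$stage_m[sel] > th)
    }
  }
  cs_st_on <- rowSums(trig) >= 2

  loq_of <- stats::setNames(substances$loq, substances$name)
  dt50_of <- stats::setNames(substances$dt50_soil, substances$name)

  truth_rows <- list(); sample_rows <- list(); cat_rows <- list()
  reservoir_pool <- matrix(0, length(all_sites), length(subs),
                           dimnames = list(all_sites, subs))
  drift_spent <- matrix(FALSE, nrow(appl), length(all_sites),
                        dimnames = list(NULL, all_sites))
  mass_routed <- 0

  for (e in seq_len(n_ev)) {
    ev_date <- as.Date(events$start[e])
    P_eff <- events$total_mm[e]
    for (si in seq_along(all_sites)) {
      site <- all_sites[si]
      v <- vol_site[e, si]
      expo <- expo_by_site[[site]]
      load <- stats::setNames(numeric(length(subs)), subs)
      # True pathway label per substance, computed inline from the
      # generator's own predicates (precedence D > C > B > A).
      lab_true <- stats::setNames(rep("A", length(subs)), subs)
      if (!is.null(expo)) {
        prior <- expo[as.Date(expo$date) <= ev_date, , drop = FALSE]
        if (nrow(prior) > 0) {
          any_in <- tapply(prior$in_ca, prior$substance, any)
          any_dr <- tapply(prior$drift, prior$substance, any)
          pres <- names(any_in)
          lab_true[pres] <- ifelse(any_in[pres], "D",
                                   ifelse(any_dr[pres], "C", "B"))
          t_since <- as.numeric(ev_date - as.Date(prior$date))
          decay <- exp(-ln2 * t_since / dt50_of[prior$substance])
          # Runoff wash-off from the contributing area.
          run <- prior$in_ca
          if (any(run) && v > 0) {
            l <- prior$mass_g[run] * 1e9 * config$washoff_per_mm *
              P_eff * decay[run]
            load[prior$substance[run]] <- load[prior$substance[run]] + l
          }
          # Spray drift: deposited within the radius, washed off at the
          # first event after application.
          dr <- prior$drift & !prior$in_ca
          if (any(dr) && v > 0) {
            ids <- match(prior$application_id[dr], appl$application_id)
            fresh <- !drift_spent[ids, si]
            if (any(fresh)) {
              l <- prior$mass_g[dr][fresh] * 1e9 * config$drift_frac *
                decay[dr][fresh]
              sname <- prior$substance[dr][fresh]
              load[sname] <- load[sname] + l
              drift_spent[ids[fresh], si] <- TRUE
            }
          }
        }
      }
      # Tile drainage / diffuse catchment export to the stream (and, with
      # reduced share, the collector shaft).
      tile_w <- if (site == "ST") config$tile_washoff_per_mm
      else if (site == "CS") config$tile_washoff_per_mm * config$tile_cs_share
      else 0
      if (tile_w > 0 && v > 0 && nrow(appl) > 0) {
        prior_all <- appl[appl$date <= ev_date, , drop = FALSE]
        if (nrow(prior_all) > 0) {
          t_all <- as.numeric(ev_date - prior_all$date)
          dec_all <- exp(-ln2 * t_all / dt50_of[prior_all$substance])
          l <- prior_all$mass_g * 1e9 * tile_w * P_eff * dec_all
          agg <- tapply(l, prior_all$substance, sum)
          load[names(agg)] <- load[names(agg)] + as.numeric(agg)
        }
      }
      # Background / spill pulses.
      if (config$background_rate > 0 &&
          stats::runif(1) < config$background_rate) {
        sname <- sample(subs, 1)
        load[sname] <- load[sname] +
          stats::rlnorm(1, config$background_meanlog, config$background_sdlog)
      }
      # Reservoir carry-over.
      if (config$reservoir) {
        emit <- reservoir_pool[si, ]
        reservoir_pool[si, ] <- config$reservoir_frac * (load + emit)
        load <- load + emit * (1 - config$reservoir_frac)
      }
      mass_routed <- mass_routed + sum(load)
      conc_true <- if (v > 0) load / v else rep(0, length(subs))
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        site = site, event = events$event[e], substance = subs,
        load_ng = as.numeric(load), volume_L = v,
        conc_true = as.numeric(conc_true))
      cat_rows[[length(cat_rows) + 1]] <- data.frame(
        site = site, event = events$event[e], substance = subs,
        category = as.character(lab_true))

      # Sampling: inlets composite iff triggered (grab from reservoir
      # otherwise); CS/ST iff >= 2 inlets triggered.
      is_inlet <- si <= length(sampled_sites)
      has_composite <- if (is_inlet) trig[e, si] else cs_st_on[e]
      stype <- if (has_composite) "composite"
      else if (is_inlet && config$grab_samples) "grab" else NA
      if (is.na(stype)) next
      conc_base <- if (stype == "composite") conc_true else {
        pool <- reservoir_pool[si, ] / config$reservoir_frac
        stagnant_v <- 50  # L of stagnant water in the shaft
        if (config$reservoir) pool * config$reservoir_frac / stagnant_v
        else rep(0, length(subs))
      }
      noise <- 10^stats::rnorm(length(subs), 0, config$sigma_log10)
      obs <- conc_base * noise
      cens <- obs < loq_of[subs]
      sample_rows[[length(sample_rows) + 1]] <- data.frame(
        site = site, event = events$event[e], substance = subs,
        value = ifelse(cens, NA_real_, obs), loq = as.numeric(loq_of[subs]),
        censored = cens, sample_type = stype,
        conc_uncensored = as.numeric(obs))
    }
  }
  truth_loads <- do.call(rbind, truth_rows)
  samples <- do.call(rbind, sample_rows)
  categories <- do.call(rbind, cat_rows)

  mass_applied <- sum(appl$mass_g) * 1e9

  structure(list(
    events = events, stage = stage, stream_discharge = stream_discharge,
    samples = samples,
    truth = list(loads = truth_loads, volumes = vol_true,
                 site_volumes = vol_site, categories = categories,
                 mass_applied_ng = mass_applied,
                 mass_routed_ng = mass_routed,
                 triggers = trig),
    ca_map = ca_map, exposure = exposure, sampled_sites = sampled_sites,
    weights = weights, rating = rating_curve(), config = config),
    class = "synthetic_observations")
}
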