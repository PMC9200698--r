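#' Pipeline configuration
#'
#' Validated settings for the end-to-end synthetic pipeline run. Unknown
#' keys are rejected.
#'
#' @param seed master seed; every random draw in the run derives from it.
#' @param catchment a [catchment_config()].
#' @param rainfall a [rainfall_config()].
#' @param applications an [application_config()].
#' @param observations an [observation_config()].
#' @param mc_runs Monte Carlo runs for the connectivity uncertainty (0
#'   disables the analysis), default 100.
#' @param mc_grid optional c(nrow, ncol) reduced grid size for the Monte
#'   Carlo stage; `NULL` uses the full catchment grid.
#' @param n_load_events number of high-concentration sampling events used
#'   for the load-ratio analysis, default 3.
#' @param large_event_mm rainfall total above which an event counts as
#'   "large" for the discharge-ratio summary, default 10.
#' @param censor_substitution LMM censoring substitution, `"loq"` or
#'   `"half_loq"`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            catchment = catchment_config(),
                            rainfall = rainfall_config(),
                            applications = application_config(),
                            observations = observation_config(),
                            mc_runs = 100,
                            mc_grid = c(60, 60),
                            n_load_events = 3,
                            large_event_mm = 10,
                            censor_substitution = "loq") {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Validate a pipeline configuration list
#'
#' @param x a list of settings (e.g. parsed from JSON); keys must be a
#'   subset of the [pipeline_config()] arguments.
#' @return A `pipeline_config` with `x`'s entries applied.
#' @export
as_pipeline_config <- function(x) {
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown) > 0)
    stop("unknown pipeline config keys: ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, x)
}

#' Run the full synthetic pipeline
#'
#' Generates the synthetic study system and pushes it through every analysis
#' stage: event classification and sampling flags, contributing-area
#' delineation with Monte Carlo parameter uncertainty, stage-to-discharge
#' conversion with extrapolation scenarios, fast-flow separation and
#' inlet/stream discharge ratios, transport-category attribution and
#' category-wise concentration summaries, censored load ratios with
#' uncertainty attribution and catchment extrapolation, and the
#' random-intercept concentration model. Returns a report bundle with a
#' machine-readable manifest.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage progress messages.
#' @return List of class `pipeline_report`; see the stage entries
#'   (`events`, `connectivity`, `mc_connectivity`, `discharge`,
#'   `discharge_ratios`, `discharge_extrapolation`, `site_summary`,
#'   `categories`, `category_summary`, `loads`, `uncertainty`,
#'   `load_extrapolation`, `lmm`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  seed <- config$seed

  say("stage 1/7: generating synthetic catchment and forcing")
  catchment <- generate_catchment(config$catchment, seed)
  rainfall <- generate_rainfall(config$rainfall, seed)
  substances <- default_substances()
  applications <- generate_applications(
    catchment, substances, config$applications, seed,
    window = c(config$rainfall$start, config$rainfall$end))
  if (nrow(applications) == 0 && config$applications$n_applications > 0)
    stop("empty application set despite configured applications")

  say("stage 2/7: simulating observations (incl. connectivity)")
  obs <- simulate_observations(catchment, rainfall, applications,
                               substances, config$observations, seed)
  events <- obs$events
  thresholds <- stats::setNames(
    catchment$inlets$threshold_m[match(obs$sampled_sites,
                                       catchment$inlets$site)],
    obs$sampled_sites)
  flagged <- flag_sampling_events(events, obs$stage, thresholds)
  events <- flagged$events

  say("stage 3/7: Monte Carlo connectivity uncertainty")
  mc <- NULL
  if (config$mc_runs > 0) {
    mc_catch <- if (!is.null(config$mc_grid)) {
      cc <- config$catchment
      cc$nrow <- config$mc_grid[1]; cc$ncol <- config$mc_grid[2]
      cc$n_inlets <- max(4L, round(cc$n_inlets *
        (cc$nrow * cc$ncol) / (config$catchment$nrow * config$catchment$ncol)))
      generate_catchment(cc, seed)
    } else catchment
    agri <- matrix(FALSE, nrow(mc_catch$dem$z), ncol(mc_catch$dem$z))
    for (ring in mc_catch$plots)
      agri[rasterize_polygon(mc_catch$dem, ring)] <- TRUE
    p <- connectivity_params(dists = list(
      road_carving_depth = c(0.05, 0.2), sink_fill_depth = c(0.05, 0.3)))
    mc <- monte_carlo_connectivity(
      mc_catch$dem, as.matrix(mc_catch$road_cells[, c("row", "col")]),
      mc_catch$inlets, mc_catch$stream_cells, p,
      n_runs = config$mc_runs, seed = seed, agri_mask = agri,
      outlets = rbind(mc_catch$stream_cells,
                      as.matrix(mc_catch$inlets[, c("row", "col")])))
  }

  say("stage 4/7: discharge triples and ratios")
  rating <- obs$rating
  vol_triples <- list()   # per event: matrix sampled inlets x 3
  for (s in obs$sampled_sites) {
    q <- stage_to_discharge(obs$stage[[s]], rating)
    vol_triples[[s]] <- t(vapply(seq_len(nrow(events)), function(e)
      event_volume(q, events$start[e], events$end[e],
                   tail_h = config$observations$tail_h),
      numeric(3)))
  }
  # Separate fast flow once per filter parameter over the whole record,
  # then integrate per event.
  fast_df <- data.frame(
    time = obs$stream_discharge$time,
    fast_low = separate_fast_flow(obs$stream_discharge$q, 0.9)$fast,
    fast_mod = separate_fast_flow(obs$stream_discharge$q, 0.925)$fast,
    fast_high = separate_fast_flow(obs$stream_discharge$q, 0.95)$fast)
  ratio_rows <- list()
  for (e in seq_len(nrow(events))) {
    inlet_vol <- do.call(rbind, lapply(vol_triples, function(m) m[e, ]))
    stream_vol <- event_volume(obs$stream_discharge, events$start[e],
                               events$end[e],
                               tail_h = config$observations$tail_h,
                               cols = "q")
    fast <- event_volume(fast_df, events$start[e], events$end[e],
                         tail_h = config$observations$tail_h)
    r <- discharge_ratios(inlet_vol, stream_vol, fast)
    ratio_rows[[e]] <- data.frame(
      event = events$event[e], total_mm = events$total_mm[e],
      is_snowmelt = events$is_snowmelt[e],
      q_inl_mod = sum(inlet_vol[, "q_mod"]), q_stream = stream_vol,
      r_q_min = r$r_q[["min"]], r_q_mod = r$r_q[["mod"]],
      r_q_high = r$r_q[["high"]],
      r_q_fast_min = r$r_q_fast[["min"]],
      r_q_fast_mod = r$r_q_fast[["mod"]],
      r_q_fast_high = r$r_q_fast[["high"]])
  }
  dratios <- do.call(rbind, ratio_rows)

  weights <- obs$weights
  ev_large <- which(dratios$total_mm > config$large_event_mm &
                      !dratios$is_snowmelt)
  dextra <- NULL
  if (length(ev_large) > 0) {
    meas <- Reduce(`+`, lapply(ev_large, function(e)
      do.call(rbind, lapply(vol_triples, function(m) m[e, ]))))
    colnames(meas) <- c("q_min", "q_mod", "q_high")
    dextra <- extrapolate_total_inlet_discharge(meas, weights)
    stream_large <- sum(dratios$q_stream[ev_large])
    fast_large <- colSums(do.call(rbind, lapply(ev_large, function(e)
      event_volume(fast_df, events$start[e], events$end[e],
                   tail_h = config$observations$tail_h))))
    dextra$share_total <- dextra$q_mod / stream_large
    dextra$share_fast <- dextra$q_mod / fast_large[["fast_mod"]]
  }

  say("stage 5/7: categories and concentration summaries")
  samples <- obs$samples
  samples <- assign_categories(samples, events, obs$exposure)
  category_summary <- category_concentration_summary(samples)
  site_summary <- site_concentration_summary(samples)

  say("stage 6/7: load ratios, uncertainty, extrapolation")
  sampling_ev <- events$event[rowSums(obs$truth$triggers) >= 2]
  conc_sums <- tapply(
    ifelse(samples$censored, 0, samples$value)[samples$site %in%
                                                 obs$sampled_sites],
    samples$event[samples$site %in% obs$sampled_sites], sum)
  cand <- intersect(as.integer(names(sort(conc_sums, decreasing = TRUE))),
                    sampling_ev)
  load_events <- utils::head(cand, config$n_load_events)
  cells <- build_load_cells(samples, events, vol_triples, dratios,
                            load_events, obs$sampled_sites)
  loads <- uncert <- lextra <- NULL
  if (nrow(cells) > 0) {
    loads <- load_ratio_table(cells)
    uncert <- uncertainty_attribution(cells)
    lextra <- extrapolate_catchment_load_ratio(cells, weights)
  }

  say("stage 7/7: concentration LMM")
  inlet_samples <- samples[samples$site %in% obs$sampled_sites &
                             samples$sample_type == "composite", ]
  discharge_mod <- do.call(rbind, lapply(obs$sampled_sites, function(s)
    data.frame(site = s, event = events$event,
               q_mod = vol_triples[[s]][, "q_mod"])))
  frame <- build_model_frame(inlet_samples, events, obs$exposure,
                             substances, discharge_mod,
                             censor_substitution = config$censor_substitution)
  lmm <- NULL; collinear <- NULL
  if (nrow(frame) >= 10 && nlevels(droplevels(frame$inlet)) >= 2) {
    collinear <- drop_collinear(frame)
    lmm <- fit_lmm(collinear$frame)
  }

  manifest <- list(
    package = "shortcutflux",
    version = as.character(utils::packageVersion("shortcutflux")),
    seed = seed,
    config_hash = config_hash(unclass_recursive(config)),
    n_events = nrow(events),
    n_samples = nrow(samples),
    stages = c("generate", "events", "connect", "hydro", "attribute",
               "loads", "lmm"))

  structure(list(
    catchment = catchment, rainfall = rainfall,
    applications = applications, observations = obs,
    events = events, triggers = flagged$triggers,
    connectivity = obs$ca_map$destinations, mc_connectivity = mc,
    discharge_ratios = dratios, discharge_extrapolation = dextra,
    samples = samples, site_summary = site_summary,
    category_summary = category_summary,
    load_events = load_events, load_cells = cells, loads = loads,
    uncertainty = uncert, load_extrapolation = lextra,
    model_frame = frame, collinearity = collinear, lmm = lmm,
    manifest = manifest),
    class = "pipeline_report")
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else unclass(x)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  events: %d (%d sampling)\n", nrow(x$events),
              sum(x$events$is_sampling_event)))
  cat(sprintf("  samples: %d rows at %d sites\n", nrow(x$samples),
              length(unique(x$samples$site))))
  if (!is.null(x$loads))
    cat(sprintf("  r_f_mu_subst mod: %.3g; r_f_mu_sum mod: %.3g\n",
                x$loads$r_f_mu_subst[["r_mod"]],
                x$loads$r_f_mu_sum[["r_mod"]]))
  cat(sprintf("  manifest hash: %s\n", x$manifest$config_hash))
  invisible(x)
}

# Assemble the per-(site, event, substance) load-analysis cells for the
# selected events: inlet rows with rating-scenario discharge triples, stream
# rows with the (uncertainty-free) stream volume in all three slots.
build_load_cells <- function(samples, events, vol_triples, dratios,
                             load_events, sampled_sites) {
  rows <- list()
  for (e in load_events) {
    ei <- match(e, events$event)
    for (s in sampled_sites) {
      sub <- samples[samples$site == s & samples$event == e, , drop = FALSE]
      if (nrow(sub) == 0) next
      v <- vol_triples[[s]][ei, ]
      rows[[length(rows) + 1]] <- data.frame(
        site = s, event = e, substance = sub$substance,
        q_min = v[["q_min"]], q_mod = v[["q_mod"]], q_high = v[["q_high"]],
        value = sub$value, loq = sub$loq, censored = sub$censored,
        is_stream = FALSE)
    }
    st <- samples[samples$site == "ST" & samples$event == e, , drop = FALSE]
    if (nrow(st) == 0) next
    qs <- dratios$q_stream[dratios$event == e]
    rows[[length(rows) + 1]] <- data.frame(
      site = "ST", event = e, substance = st$substance,
      q_min = qs, q_mod = qs, q_high = qs,
      value = st$value, loq = st$loq, censored = st$censored,
      is_stream = TRUE)
  }
  if (length(rows) == 0) return(data.frame())
  do.call(rbind, rows)
}

#' Per-site concentration overview with censoring-bounded means
#'
#' Summarises, per sampling site: the number of substances quantified above
#' their LOQ at least once, the mean concentration as a lower/upper bound
#' pair (censored records replaced by 0 for the lower and by the LOQ for the
#' upper bound), the maximal concentration and the substance attaining it.
#'
#' @param samples sample table with `site`, `substance`, `value`, `loq`,
#'   `censored`.
#' @return Data frame with one row per site.
#' @export
site_concentration_summary <- function(samples) {
  out <- lapply(split(samples, samples$site), function(d) {
    lo <- ifelse(d$censored, 0, d$value)
    hi <- ifelse(d$censored, d$loq, d$value)
    imax <- which.max(lo)
    data.frame(site = d$site[1],
               n_substances_detected =
                 length(unique(d$substance[!d$censored])),
               mean_lower = mean(lo), mean_upper = mean(hi),
               max_conc = if (nrow(d) > 0) lo[imax] else NA_real_,
               top_substance = if (nrow(d) > 0) d$substance[imax]
               else NA_character_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
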