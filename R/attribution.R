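#' Assign a transport-process category to one concentration measurement
#'
#' Categories, in decreasing precedence:
#' \describe{
#'   \item{D}{surface runoff/(tile drainage)/spray drift/other: the substance
#'     was applied before the event inside the site's surface-runoff
#'     contributing area. For collector shaft and stream sites the label
#'     carries a tile-drainage annotation.}
#'   \item{C}{spray drift/other: applied before the event within the drift
#'     radius of the site (direct) or of a road draining to the site
#'     (indirect), but without runoff potential.}
#'   \item{B}{other: applied in the catchment before the event, but with
#'     neither runoff nor drift potential.}
#'   \item{A}{no reported application before the event.}
#' }
#' "Before the event" compares the application calendar date with the event
#' start date; a same-day application counts as before (applications are
#' day-resolved).
#'
#' @param site site identifier.
#' @param event_start event start (`POSIXct` or `Date`).
#' @param substance substance name.
#' @param exposure an [build_exposure_table()] result.
#' @param tile_drainage_sites sites whose category D may also involve tile
#'   drainage (collector shaft, stream). Default `c("CS", "ST")`.
#' @return List: `label` (`"A"`..`"D"`), `evidence` (matching exposure rows),
#'   `tile_drainage` flag.
#' @export
assign_category <- function(site, event_start, substance, exposure,
                            tile_drainage_sites = c("CS", "ST")) {
  ev_date <- as.Date(event_start)
  rows <- exposure[exposure$site == site &
                     exposure$substance == substance &
                     as.Date(exposure$date) <= ev_date, , drop = FALSE]
  label <- if (nrow(rows) == 0) "A"
  else if (any(rows$in_ca)) "D"
  else if (any(rows$drift)) "C"
  else "B"
  list(label = label,
       evidence = rows,
       tile_drainage = label == "D" && site %in% tile_drainage_sites)
}

#' Assign categories to a whole sample table
#'
#' @param samples data frame with `site`, `event`, `substance`.
#' @param events event table ([classify_events()]) supplying `start` per
#'   event id.
#' @param exposure an [build_exposure_table()] result.
#' @param ... passed to [assign_category()].
#' @return `samples` with columns `category` and `tile_drainage` appended.
#' @export
assign_categories <- function(samples, events, exposure, ...) {
  start_of <- stats::setNames(events$start, events$event)
  res <- vapply(seq_len(nrow(samples)), function(i) {
    a <- assign_category(samples$site[i],
                         start_of[[as.character(samples$event[i])]],
                         samples$substance[i], exposure, ...)
    c(a$label, as.character(a$tile_drainage))
  }, character(2))
  samples$category <- factor(res[1, ], levels = c("A", "B", "C", "D"))
  samples$tile_drainage <- as.logical(res[2, ])
  samples
}

#' Concentration distribution per transport category
#'
#' Summarises concentrations by category (and optionally a site grouping).
#' Censored values are represented by their LOQ, the convention used when
#' comparing category-wise concentration distributions.
#'
#' @param samples data frame with `value` (ng/L), `loq`, `censored`,
#'   `category`, and optionally a grouping column named by `by`.
#' @param by optional extra grouping column name (e.g. `"site_group"`).
#' @return Data frame with `category` (and `by`), `n`, `n_censored`, `q25`,
#'   `median`, `q75`.
#' @export
category_concentration_summary <- function(samples, by = NULL) {
  d <- data.frame(v = ifelse(samples$censored, samples$loq, samples$value),
                  cens = samples$censored,
                  category = as.character(samples$category))
  if (!is.null(by)) d$grp <- as.character(samples[[by]])
  keys <- if (is.null(by)) list(d$category) else list(d$category, d$grp)
  parts <- split(d, keys, drop = TRUE)
  out <- do.call(rbind, lapply(parts, function(g) {
    row <- data.frame(category = g$category[1], n = nrow(g),
                      n_censored = sum(g$cens),
                      q25 = unname(stats::quantile(g$v, 0.25)),
                      median = stats::median(g$v),
                      q75 = unname(stats::quantile(g$v, 0.75)))
    if (!is.null(by)) {
      row[[by]] <- g$grp[1]
      row <- row[, c("category", by, "n", "n_censored", "q25", "median",
                     "q75")]
    }
    row
  }))
  out <- out[order(out$category), , drop = FALSE]
  rownames(out) <- NULL
  out
}
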