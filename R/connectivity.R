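#' Connectivity model parameters
#'
#' Parameters of the surface-runoff connectivity model: how deep road and
#' farm-track cells are carved into the DEM (sub-grid effect of roads
#' concentrating runoff), and up to which depth terrain depressions are
#' filled (deeper depressions are retained as infiltration sinks). For Monte
#' Carlo uncertainty runs, sampling distributions can be attached per
#' parameter as either a `c(min, max)` uniform range or a `function(n)`.
#'
#' @param road_carving_depth carving depth under roads (m), >= 0.
#' @param sink_fill_depth maximum depression depth that is filled (m), >= 0.
#' @param dists optional named list of sampling distributions for
#'   [monte_carlo_connectivity()].
#' @return Object of class `connectivity_params`.
#' @export
connectivity_params <- function(road_carving_depth = 0.1,
                                sink_fill_depth = 0.1,
                                dists = NULL) {
  stopifnot(road_carving_depth >= 0, sink_fill_depth >= 0)
  structure(list(road_carving_depth = road_carving_depth,
                 sink_fill_depth = sink_fill_depth,
                 dists = dists),
            class = "connectivity_params")
}

#' Condition a DEM for flow routing
#'
#' Lowers cells under the road network by the carving depth, then fills
#' terrain depressions up to their pour level provided their maximum depth
#' does not exceed `sink_fill_depth`; deeper depressions are retained as
#' sinks. Filling applies an epsilon gradient so that filled areas drain
#' towards their pour point. Cells listed in `outlets` (e.g. stream and inlet
#' cells) are treated as drainage seeds and are never raised.
#'
#' @param dem a [dem_grid()].
#' @param roads integer matrix of road cells (`row`, `col`), e.g. from
#'   [rasterize_segments()]; `NULL` for no carving.
#' @param params a [connectivity_params()].
#' @param outlets optional integer matrix (`row`, `col`) of cells that act as
#'   drainage outlets in addition to the grid boundary.
#' @return A [dem_grid()] with conditioned elevations; attribute
#'   `sink_cells` holds the retained-depression cells.
#' @export
condition_dem <- function(dem, roads = NULL, params = connectivity_params(),
                          outlets = NULL) {
  z <- dem$z
  if (!is.null(roads) && nrow(roads) > 0)
    z[cbind(roads[, "row"], roads[, "col"])] <-
      z[cbind(roads[, "row"], roads[, "col"])] - params$road_carving_depth

  seeds <- matrix(FALSE, nrow(z), ncol(z))
  seeds[1, ] <- seeds[nrow(z), ] <- TRUE
  seeds[, 1] <- seeds[, ncol(z)] <- TRUE
  if (!is.null(outlets) && nrow(outlets) > 0)
    seeds[cbind(outlets[, "row"], outlets[, "col"])] <- TRUE

  filled <- fill_depressions(z, seeds, eps = 1e-5)
  depth <- filled - z
  is_filled <- depth > 1e-12

  # Identify depressions as 8-connected components of filled cells; revert
  # those deeper than the cap.
  sink_cells <- NULL
  if (any(is_filled)) {
    comp <- label_components(is_filled)
    maxdepth <- tapply(depth[is_filled], comp[is_filled], max)
    deep <- as.integer(names(maxdepth)[maxdepth > params$sink_fill_depth])
    if (length(deep) > 0) {
      revert <- is_filled & comp %in% deep
      dim(revert) <- dim(z)
      filled[revert] <- z[revert]
      idx <- which(revert, arr.ind = TRUE)
      colnames(idx) <- c("row", "col")
      sink_cells <- idx
    }
  }
  out <- dem_grid(filled, dem$cellsize, dem$xll, dem$yll)
  attr(out, "sink_cells") <- sink_cells
  out
}

# Iterative epsilon-fill (Planchon-Darboux style sweep until convergence).
fill_depressions <- function(z, seeds, eps = 1e-5) {
  w <- matrix(Inf, nrow(z), ncol(z))
  w[seeds] <- z[seeds]
  repeat {
    nbr_min <- matrix(Inf, nrow(z), ncol(z))
    for (k in seq_len(8)) {
      nbr_min <- pmin(nbr_min, shift_mat(w, NEIGHBOUR_OFFSETS[k, "dr"],
                                         NEIGHBOUR_OFFSETS[k, "dc"],
                                         fill = Inf))
    }
    cand <- pmax(z, nbr_min + eps)
    new_w <- pmin(w, cand)
    if (max(abs(new_w - w)[is.finite(w) | is.finite(new_w)]) <= 0 ||
        identical(new_w, w)) break
    w <- new_w
  }
  w
}

# Label 8-connected components of a logical matrix (two-pass scan with
# union-find over provisional labels).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j]) next
    nb <- integer(0)
    if (i > 1 && mask[i - 1, j]) nb <- c(nb, lab[i - 1, j])
    if (j > 1 && mask[i, j - 1]) nb <- c(nb, lab[i, j - 1])
    if (i > 1 && j > 1 && mask[i - 1, j - 1]) nb <- c(nb, lab[i - 1, j - 1])
    if (i < nr && j > 1 && mask[i + 1, j - 1]) nb <- c(nb, lab[i + 1, j - 1])
    if (length(nb) == 0) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[i, j] <- nxt
    } else {
      roots <- vapply(nb, find, integer(1))
      r <- min(roots)
      lab[i, j] <- r
      for (x in roots) parent[x] <- r
    }
  }
  if (nxt > 0) {
    idx <- which(mask)
    lab[idx] <- vapply(lab[idx], find, integer(1))
  }
  lab
}

#' D-infinity flow directions (Tarboton)
#'
#' Computes, per cell, the steepest-descent direction over the eight
#' triangular facets spanned by adjacent neighbour pairs, and the resulting
#' proportional flow split between the facet's cardinal and diagonal
#' neighbour. Cells with no downslope facet are local sinks. Cells on the
#' grid edge can only route to in-grid neighbours; edge cells without an
#' in-grid downslope neighbour are sinks.
#'
#' @param dem a conditioned [dem_grid()].
#' @return Object of class `dinf_directions`: matrices `angle` (radians CCW
#'   from east, `NA` for sinks), `slope`, linear-index receiver matrices
#'   `rec1` (cardinal) and `rec2` (diagonal) with proportions `p1`, `p2`
#'   (`p1 + p2 = 1` for non-sink cells), and logical `is_sink`.
#' @references Tarboton, D. G. (1997) A new method for the determination of
#'   flow directions and upslope areas in grid digital elevation models.
#'   Water Resources Research 33(2), 309-319.
#' @export
flow_directions_dinf <- function(dem) {
  z <- dem$z
  d1 <- dem$cellsize
  nr <- nrow(z); nc <- ncol(z)
  nbr <- lapply(seq_len(8), function(k)
    shift_mat(z, NEIGHBOUR_OFFSETS[k, "dr"], NEIGHBOUR_OFFSETS[k, "dc"],
              fill = Inf))
  # Facets as (cardinal, diagonal) neighbour indices in E,NE,N,NW,W,SW,S,SE
  # order, base angle of the cardinal direction, and rotation sign.
  fac_card <- c(1L, 3L, 3L, 5L, 5L, 7L, 7L, 1L)
  fac_diag <- c(2L, 2L, 4L, 4L, 6L, 6L, 8L, 8L)
  fac_base <- c(0, 1, 1, 2, 2, 3, 3, 4) * (pi / 2)
  fac_sign <- c(1, -1, 1, -1, 1, -1, 1, -1)

  best_s <- matrix(-Inf, nr, nc)
  best_r <- matrix(NA_real_, nr, nc)
  best_f <- matrix(NA_integer_, nr, nc)
  for (f in seq_len(8)) {
    e1 <- nbr[[fac_card[f]]]
    e2 <- nbr[[fac_diag[f]]]
    s1 <- (z - e1) / d1
    s2 <- (e1 - e2) / d1
    r <- atan2(s2, s1)
    s <- sqrt(s1^2 + s2^2)
    s[is.nan(s)] <- -Inf              # both neighbours out of grid
    low <- !is.nan(r) & r < 0
    r[low] <- 0
    s[low] <- s1[low]
    hi <- !is.nan(r) & r > pi / 4
    r[hi] <- pi / 4
    s[hi] <- (z[hi] - e2[hi]) / (d1 * sqrt(2))
    s[!is.finite(s)] <- -Inf
    upd <- s > best_s
    best_s[upd] <- s[upd]
    best_r[upd] <- r[upd]
    best_f[upd] <- f
  }
  is_sink <- !(best_s > 0)
  p2 <- best_r / (pi / 4)
  p1 <- 1 - p2
  p1[is_sink] <- NA_real_; p2[is_sink] <- NA_real_

  idx <- matrix(seq_len(nr * nc), nr, nc)
  off1 <- NEIGHBOUR_OFFSETS[ifelse(is.na(best_f), 1L, fac_card[best_f]), ,
                            drop = FALSE]
  off2 <- NEIGHBOUR_OFFSETS[ifelse(is.na(best_f), 1L, fac_diag[best_f]), ,
                            drop = FALSE]
  rec1 <- idx + off1[, "dr"] + off1[, "dc"] * nr
  rec2 <- idx + off2[, "dr"] + off2[, "dc"] * nr
  dim(rec1) <- dim(rec2) <- c(nr, nc)
  rec1[is_sink | p1 <= 0] <- NA_integer_
  rec2[is_sink | p2 <= 0] <- NA_integer_

  angle <- (fac_base[best_f] + fac_sign[best_f] * best_r) %% (2 * pi)
  dim(angle) <- c(nr, nc)
  angle[is_sink] <- NA_real_
  slope <- best_s
  slope[is_sink] <- NA_real_

  structure(list(angle = angle, slope = slope,
                 rec1 = rec1, rec2 = rec2, p1 = p1, p2 = p2,
                 is_sink = is_sink, z = z, cellsize = d1),
            class = "dinf_directions")
}

# Cells ordered by decreasing elevation (upslope first); receivers with
# positive proportion are always strictly lower, so a single sweep in this
# order propagates flow exactly.
dinf_topo_order <- function(fd) order(fd$z, decreasing = TRUE)

#' D-infinity flow accumulation
#'
#' Accumulated fractional upslope area per cell (own cell included), in
#' cells. Multiply by `fd$cellsize^2` for square metres.
#'
#' @param fd a [flow_directions_dinf()] result.
#' @return Numeric matrix of accumulated cell counts.
#' @export
flow_accumulation <- function(fd) {
  acc <- matrix(1, nrow(fd$z), ncol(fd$z))
  r1 <- fd$rec1; r2 <- fd$rec2; p1 <- fd$p1; p2 <- fd$p2
  for (i in dinf_topo_order(fd)) {
    a <- acc[i]
    if (!is.na(r1[i])) acc[r1[i]] <- acc[r1[i]] + p1[i] * a
    if (!is.na(r2[i])) acc[r2[i]] <- acc[r2[i]] + p2[i] * a
  }
  acc
}

#' Delineate contributing areas
#'
#' Routes every cell's unit area through the D-infinity directions until it
#' is absorbed by a destination: a marked inlet cell, a stream cell, a WWTP
#' cell, or a local sink. Each cell is then assigned to the destination
#' receiving the largest share of its routed flow (majority rule); the
#' fractional shares are used for per-destination area accounting.
#'
#' @param fd a [flow_directions_dinf()] result.
#' @param inlets data frame with columns `site`, `row`, `col` (one cell per
#'   inlet).
#' @param stream_cells integer matrix (`row`, `col`) of stream cells.
#' @param wwtp_mask optional logical matrix marking cells drained to a
#'   wastewater treatment plant (pass-through label).
#' @param agri_mask,road_mask optional logical matrices used for the
#'   per-destination agricultural and road area accounting.
#' @param keep_shares keep the full (cell x destination) share matrix in the
#'   result (memory heavy on large grids).
#' @return Object of class `ca_map`: `labels` (integer matrix indexing
#'   `destinations`), `destinations` (data frame: `dest`, `type`, `site`,
#'   `area_m2`, `frac_area_m2`, `agri_area_m2`, `road_area_m2`),
#'   `unreachable` (count of cells absorbed nowhere; labelled sink), and
#'   optionally `shares`.
#' @export
delineate_contributing_areas <- function(fd, inlets, stream_cells,
                                         wwtp_mask = NULL,
                                         agri_mask = NULL, road_mask = NULL,
                                         keep_shares = FALSE) {
  nr <- nrow(fd$z); nc <- ncol(fd$z)
  n_cells <- nr * nc
  dest_names <- c(if (nrow(inlets) > 0) paste0("inlet_", inlets$site),
                  "stream", "wwtp", "sink")
  n_dest <- length(dest_names)
  dest_of_cell <- integer(n_cells)  # 0 = transit cell
  if (!is.null(wwtp_mask)) dest_of_cell[which(wwtp_mask)] <- n_dest - 1L
  dest_of_cell[(stream_cells[, "col"] - 1L) * nr + stream_cells[, "row"]] <-
    nrow(inlets) + 1L
  dest_of_cell[(inlets$col - 1L) * nr + inlets$row] <- seq_len(nrow(inlets))
  sink_idx <- which(fd$is_sink & dest_of_cell == 0)
  dest_of_cell[sink_idx] <- n_dest

  shares <- matrix(0, n_cells, n_dest)
  absorbing <- dest_of_cell > 0L
  shares[cbind(which(absorbing), dest_of_cell[absorbing])] <- 1

  r1 <- fd$rec1; r2 <- fd$rec2; p1 <- fd$p1; p2 <- fd$p2
  ord <- order(fd$z)  # ascending: receivers resolved before their donors
  for (i in ord) {
    if (absorbing[i]) next
    a <- r1[i]; b <- r2[i]
    if (!is.na(a) && !is.na(b)) shares[i, ] <- p1[i] * shares[a, ] + p2[i] * shares[b, ]
    else if (!is.na(a)) shares[i, ] <- shares[a, ]
    else if (!is.na(b)) shares[i, ] <- shares[b, ]
    # else: no receiver but not flagged sink (cannot happen); leave zero
  }
  tot <- rowSums(shares)
  unreachable <- sum(tot < 1 - 1e-9)
  if (unreachable > 0) {
    # Route the missing mass to sink, per convention.
    shares[, n_dest] <- shares[, n_dest] + pmax(0, 1 - tot)
    warning(sprintf("%d cells with incompletely routed flow labelled sink",
                    unreachable))
  }

  lab <- max.col(shares, ties.method = "first")
  dim(lab) <- c(nr, nc)
  cell_area <- fd$cellsize^2
  counts <- tabulate(lab, nbins = n_dest)
  dest <- data.frame(
    dest = dest_names,
    type = c(rep("inlet", nrow(inlets)), "stream", "wwtp", "sink"),
    site = c(as.character(inlets$site), NA, NA, NA),
    area_m2 = counts * cell_area,
    frac_area_m2 = colSums(shares) * cell_area
  )
  dest$agri_area_m2 <- if (!is.null(agri_mask))
    colSums(shares[which(agri_mask), , drop = FALSE]) * cell_area
  else NA_real_
  dest$road_area_m2 <- if (!is.null(road_mask))
    colSums(shares[which(road_mask), , drop = FALSE]) * cell_area
  else NA_real_

  structure(list(labels = lab, destinations = dest,
                 unreachable = unreachable, cellsize = fd$cellsize,
                 shares = if (keep_shares) shares else NULL),
            class = "ca_map")
}

#' @export
print.ca_map <- function(x, ...) {
  d <- x$destinations
  cat(sprintf("<ca_map> %d x %d cells; %d destinations (%d inlets)\n",
              nrow(x$labels), ncol(x$labels), nrow(d),
              sum(d$type == "inlet")))
  agg <- tapply(d$area_m2, d$type, sum)
  for (t in names(agg))
    cat(sprintf("  %-7s %10.0f m2\n", t, agg[[t]]))
  invisible(x)
}

#' Monte Carlo uncertainty of the connectivity delineation
#'
#' Repeats the full conditioning + routing + delineation chain with model
#' parameters drawn from their sampling distributions and summarises the
#' connected-area fractions. The default 100 runs mirror the study's
#' parameter-uncertainty analysis.
#'
#' @param dem raw (unconditioned) [dem_grid()].
#' @param roads road cells as in [condition_dem()].
#' @param inlets,stream_cells as in [delineate_contributing_areas()].
#' @param params [connectivity_params()] whose `dists` entry supplies the
#'   sampling distributions (`c(min, max)` uniform or `function(n)`); fixed
#'   values are used for parameters without a distribution.
#' @param n_runs number of model runs (default 100).
#' @param seed integer seed.
#' @param agri_mask optional logical matrix; fractions then refer to
#'   agricultural area instead of total area.
#' @param outlets passed to [condition_dem()].
#' @return List with `runs` (data frame: run, sampled parameters, fractions
#'   `frac_stream`, `frac_inlet`, `frac_sink`, `frac_wwtp`) and `summary`
#'   (median and 5/95% quantiles per fraction).
#' @export
monte_carlo_connectivity <- function(dem, roads, inlets, stream_cells,
                                     params = connectivity_params(),
                                     n_runs = 100, seed = 1,
                                     agri_mask = NULL, outlets = NULL) {
  stopifnot(n_runs >= 1)
  set.seed(child_seed(seed, "mc_connectivity"))
  draw <- function(name, n) {
    d <- params$dists[[name]]
    if (is.null(d)) rep(params[[name]], n)
    else if (is.function(d)) d(n)
    else stats::runif(n, d[1], d[2])
  }
  carve <- draw("road_carving_depth", n_runs)
  fill <- draw("sink_fill_depth", n_runs)
  runs <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    p <- connectivity_params(carve[k], fill[k])
    cd <- condition_dem(dem, roads, p, outlets = outlets)
    fd <- flow_directions_dinf(cd)
    ca <- suppressWarnings(
      delineate_contributing_areas(fd, inlets, stream_cells,
                                   agri_mask = agri_mask))
    d <- ca$destinations
    w <- if (!is.null(agri_mask)) d$agri_area_m2 else d$frac_area_m2
    tot <- sum(w)
    runs[[k]] <- data.frame(
      run = k, road_carving_depth = carve[k], sink_fill_depth = fill[k],
      frac_stream = sum(w[d$type == "stream"]) / tot,
      frac_inlet = sum(w[d$type == "inlet"]) / tot,
      frac_sink = sum(w[d$type == "sink"]) / tot,
      frac_wwtp = sum(w[d$type == "wwtp"]) / tot)
  }
  runs <- do.call(rbind, runs)
  qs <- function(v) stats::quantile(v, c(0.05, 0.5, 0.95), names = FALSE)
  summary <- data.frame(
    fraction = c("stream", "inlet", "sink", "wwtp"),
    q05 = c(qs(runs$frac_stream)[1], qs(runs$frac_inlet)[1],
            qs(runs$frac_sink)[1], qs(runs$frac_wwtp)[1]),
    median = c(stats::median(runs$frac_stream), stats::median(runs$frac_inlet),
               stats::median(runs$frac_sink), stats::median(runs$frac_wwtp)),
    q95 = c(qs(runs$frac_stream)[3], qs(runs$frac_inlet)[3],
            qs(runs$frac_sink)[3], qs(runs$frac_wwtp)[3]))
  list(runs = runs, summary = summary)
}

#' Build the site-by-application exposure table
#'
#' Intersects the contributing-area map with the plot-resolved application
#' records and evaluates, per (site, application) pair, the geometric
#' predicates used by transport attribution: surface-runoff potential (plot
#' intersects the site's contributing area), direct spray drift (plot within
#' the drift radius of the site), and indirect spray drift (plot within the
#' drift radius of a road cell draining to the site).
#'
#' @param ca_map a [delineate_contributing_areas()] result.
#' @param dem the [dem_grid()] the map was built on.
#' @param plots named list of plot polygon rings (metres).
#' @param applications data frame with `application_id`, `substance`, `date`
#'   (`Date`), `plot_id`, `mass_g`.
#' @param road_cells integer matrix (`row`, `col`) of road cells.
#' @param sites data frame with `site`, `x`, `y`.
#' @param site_labels named list mapping each site to the destination labels
#'   (in `ca_map$destinations$dest`) whose contributing areas belong to it;
#'   defaults to `inlet_<site>` per site. A collector shaft or the stream can
#'   map to several labels.
#' @param drift_radius_m spray-drift radius (m), default 100 (the distance
#'   below which drift to the site is considered possible). Distances are
#'   measured from the plot polygon boundary to the site point.
#' @return Data frame (class `exposure_table`): one row per (site,
#'   application) with `in_ca`, `dist_m`, `drift_direct`, `drift_road`,
#'   `drift`. Applications referencing unknown plots are dropped and reported
#'   in attribute `rejected`.
#' @export
build_exposure_table <- function(ca_map, dem, plots, applications,
                                 road_cells, sites, site_labels = NULL,
                                 drift_radius_m = 100) {
  bad <- !(applications$plot_id %in% names(plots))
  rejected <- applications[bad, , drop = FALSE]
  if (any(bad)) {
    warning(sprintf("%d application(s) reference unknown plots; rejected",
                    sum(bad)))
    applications <- applications[!bad, , drop = FALSE]
  }
  if (is.null(site_labels)) {
    site_labels <- as.list(paste0("inlet_", sites$site))
    names(site_labels) <- sites$site
  }
  dest_names <- ca_map$destinations$dest
  lab <- ca_map$labels

  plot_cells <- lapply(plots, function(ring) rasterize_polygon(dem, ring))
  road_lab <- if (nrow(road_cells) > 0)
    lab[cbind(road_cells[, "row"], road_cells[, "col"])] else integer(0)
  road_xy <- if (nrow(road_cells) > 0)
    cell_xy(dem, road_cells[, "row"], road_cells[, "col"]) else NULL

  out <- vector("list", nrow(sites))
  for (si in seq_len(nrow(sites))) {
    s <- sites[si, ]
    labs_idx <- which(dest_names %in% site_labels[[as.character(s$site)]])
    rows <- vector("list", nrow(applications))
    road_sel <- which(road_lab %in% labs_idx)
    for (ai in seq_len(nrow(applications))) {
      a <- applications[ai, ]
      ring <- plots[[a$plot_id]]
      cells <- plot_cells[[a$plot_id]]
      in_ca <- nrow(cells) > 0 &&
        any(lab[cells] %in% labs_idx)
      dist <- dist_point_polygon(s$x, s$y, ring)
      drift_direct <- dist < drift_radius_m
      drift_road <- FALSE
      if (length(road_sel) > 0) {
        dr <- dist_point_polygon(road_xy[road_sel, 1], road_xy[road_sel, 2],
                                 ring)
        drift_road <- any(dr < drift_radius_m)
      }
      rows[[ai]] <- data.frame(
        site = s$site, application_id = a$application_id,
        substance = a$substance, date = a$date, plot_id = a$plot_id,
        mass_g = a$mass_g, in_ca = in_ca, dist_m = dist,
        drift_direct = drift_direct, drift_road = drift_road,
        drift = drift_direct || drift_road)
    }
    out[[si]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(
    site = character(0), application_id = integer(0),
    substance = character(0), date = as.Date(character(0)),
    plot_id = character(0), mass_g = numeric(0), in_ca = logical(0),
    dist_m = numeric(0), drift_direct = logical(0), drift_road = logical(0),
    drift = logical(0))
  class(res) <- c("exposure_table", "data.frame")
  attr(res, "rejected") <- rejected
  res
}
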