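#' Censored concentration bounds
#'
#' A concentration below its substance limit of quantification (LOQ) is
#' interval-censored between 0 and the LOQ: the minimal concentration is 0,
#' the maximal the LOQ. Quantified values have both bounds equal to the
#' measured value.
#'
#' @param value measured concentration (ng/L); for censored records the
#'   value may be `NA` or the (unreliable) reading, it is not used.
#' @param loq substance LOQ (ng/L), > 0.
#' @param censored logical flag.
#' @return Data frame `c_min`, `c_max` (ng/L).
#' @export
censored_concentration <- function(value, loq, censored) {
  stopifnot(all(loq > 0))
  n <- max(length(value), length(loq), length(censored))
  value <- rep_len(value, n); loq <- rep_len(loq, n)
  censored <- rep_len(censored, n)
  if (any(!censored & (is.na(value) | value < 0)))
    stop("quantified concentrations must be non-negative and non-missing")
  data.frame(c_min = ifelse(censored, 0, value),
             c_max = ifelse(censored, loq, value))
}

#' Event load triple (discharge x concentration bounds)
#'
#' Minimum, moderate and high load estimates for one (site, event,
#' substance): `f_min = Q_min * c_min`, `f_mod = Q_mod * c_min`,
#' `f_high = Q_high * c_max`. The moderate estimate deliberately uses the
#' minimal concentration, so censored records contribute 0 to the minimum
#' and moderate loads and `Q_high * LOQ` to the high load.
#'
#' @param q discharge triple: named numeric `q_min`, `q_mod`, `q_high` (L),
#'   ordered and non-negative.
#' @param conc one-row result of [censored_concentration()] (ng/L).
#' @return Named numeric `f_min`, `f_mod`, `f_high` (ng).
#' @export
event_load <- function(q, conc) {
  q <- unlist(q)[c("q_min", "q_mod", "q_high")]
  if (any(q < 0) || any(unlist(conc) < 0)) stop("negative inputs")
  if (is.unsorted(q)) stop("discharge triple must satisfy min <= mod <= high")
  c(f_min = q[["q_min"]] * conc$c_min,
    f_mod = q[["q_mod"]] * conc$c_min,
    f_high = q[["q_high"]] * conc$c_max)
}

#' Inlet/stream load ratio for one (event, substance)
#'
#' Conservative cross-pairing: the summed minimal inlet load is divided by
#' the high stream load, the moderate by the moderate, and the high inlet
#' load by the minimal stream load, so the resulting triple brackets the
#' true ratio. A zero denominator makes the corresponding component
#' undefined (`NA`), never silently dropped.
#'
#' @param inlet_loads matrix (inlets x 3) with columns `f_min`, `f_mod`,
#'   `f_high` (ng).
#' @param stream_load named numeric `f_min`, `f_mod`, `f_high` (ng).
#' @return Named numeric `r_min`, `r_mod`, `r_high` (dimensionless) with
#'   attribute `undefined` (count of `NA` components).
#' @export
load_ratio <- function(inlet_loads, stream_load) {
  s <- colSums(rbind(inlet_loads))
  den <- c(stream_load[["f_high"]], stream_load[["f_mod"]],
           stream_load[["f_min"]])
  num <- c(s[["f_min"]], s[["f_mod"]], s[["f_high"]])
  r <- ifelse(den > 0, num / den, NA_real_)
  names(r) <- c("r_min", "r_mod", "r_high")
  attr(r, "undefined") <- sum(is.na(r))
  r
}

#' Aggregate load ratios over events and substances
#'
#' Two aggregates over the included (event, substance) cells: the mean of
#' the per-cell ratio triples (`r_f_mu_subst`), and the ratio of the summed
#' inlet loads to the summed stream loads with the same conservative
#' min/mod/high pairing as [load_ratio()] (`r_f_mu_sum`). Cells whose high
#' ratio is undefined (fully censored stream load) are excluded from the
#' mean; the exclusion count is reported.
#'
#' @param ratios data frame with columns `r_min`, `r_mod`, `r_high`, one row
#'   per (event, substance) cell.
#' @param inlet_sums data frame with columns `f_min`, `f_mod`, `f_high`: the
#'   per-cell inlet load sums (ng).
#' @param stream_loads data frame with columns `f_min`, `f_mod`, `f_high`:
#'   the per-cell stream loads (ng).
#' @return List with triples `r_f_mu_subst` and `r_f_mu_sum`, `n_cells`
#'   (cells in the mean) and `n_excluded`.
#' @export
aggregate_ratios <- function(ratios, inlet_sums, stream_loads) {
  if (nrow(ratios) == 0) stop("empty cell set")
  ok <- stats::complete.cases(ratios[, c("r_min", "r_mod", "r_high")])
  if (!any(ok)) stop("all cells have undefined ratio components")
  mu_subst <- c(r_min = mean(ratios$r_min[ok]),
                r_mod = mean(ratios$r_mod[ok]),
                r_high = mean(ratios$r_high[ok]))
  num <- colSums(inlet_sums[, c("f_min", "f_mod", "f_high")])
  den <- colSums(stream_loads[, c("f_min", "f_mod", "f_high")])
  mu_sum <- c(
    r_min = if (den[["f_high"]] > 0) num[["f_min"]] / den[["f_high"]] else NA_real_,
    r_mod = if (den[["f_mod"]] > 0) num[["f_mod"]] / den[["f_mod"]] else NA_real_,
    r_high = if (den[["f_min"]] > 0) num[["f_high"]] / den[["f_min"]] else NA_real_)
  list(r_f_mu_subst = mu_subst, r_f_mu_sum = mu_sum,
       n_cells = sum(ok), n_excluded = sum(!ok))
}

#' Full load-ratio table from per-cell inputs
#'
#' Convenience wrapper: computes per-cell load triples (Eq.-style algebra)
#' and their ratios from a tidy table of discharge triples and censored
#' concentrations.
#'
#' @param cells data frame with one row per (site, event, substance):
#'   columns `site`, `event`, `substance`, `q_min`, `q_mod`, `q_high` (L),
#'   `value` (ng/L), `loq`, `censored`, and logical `is_stream` marking the
#'   stream site.
#' @return List with `loads` (per-row load triples appended), `ratios` (one
#'   row per (event, substance): inlet sums, stream loads, ratio triple) and
#'   the aggregates of [aggregate_ratios()].
#' @export
load_ratio_table <- function(cells) {
  conc <- censored_concentration(cells$value, cells$loq, cells$censored)
  loads <- cbind(cells,
                 f_min = cells$q_min * conc$c_min,
                 f_mod = cells$q_mod * conc$c_min,
                 f_high = cells$q_high * conc$c_max)
  key <- interaction(loads$event, loads$substance, drop = TRUE)
  rows <- lapply(split(loads, key), function(g) {
    stream <- g[g$is_stream, , drop = FALSE]
    inl <- g[!g$is_stream, , drop = FALSE]
    if (nrow(stream) != 1) return(NULL)
    r <- load_ratio(as.matrix(inl[, c("f_min", "f_mod", "f_high")]),
                    unlist(stream[, c("f_min", "f_mod", "f_high")]))
    data.frame(event = g$event[1], substance = g$substance[1],
               inl_min = sum(inl$f_min), inl_mod = sum(inl$f_mod),
               inl_high = sum(inl$f_high),
               st_min = stream$f_min, st_mod = stream$f_mod,
               st_high = stream$f_high,
               r_min = r[["r_min"]], r_mod = r[["r_mod"]],
               r_high = r[["r_high"]])
  })
  ratios <- do.call(rbind, rows)
  agg <- aggregate_ratios(
    ratios,
    stats::setNames(ratios[, c("inl_min", "inl_mod", "inl_high")],
                    c("f_min", "f_mod", "f_high")),
    stats::setNames(ratios[, c("st_min", "st_mod", "st_high")],
                    c("f_min", "f_mod", "f_high")))
  c(list(loads = loads, ratios = ratios), agg)
}

#' Attribute the load-ratio spread to LOQ vs discharge uncertainty
#'
#' Recomputes the aggregate ratio spreads with one uncertainty source at a
#' time collapsed to its moderate value: LOQ-only spread uses the moderate
#' discharge everywhere, discharge-only spread replaces censored bounds by
#' their moderate substitution. The share of each source is its partial
#' spread divided by the total spread, reported for both aggregates.
#'
#' @param cells as in [load_ratio_table()].
#' @return Data frame with rows `r_f_mu_subst`, `r_f_mu_sum` and columns
#'   `total_spread`, `loq_spread`, `discharge_spread`, `loq_share`,
#'   `discharge_share`. Shares are `NA` when the total spread is zero.
#' @export
uncertainty_attribution <- function(cells) {
  spread <- function(agg)
    c(subst = agg$r_f_mu_subst[["r_high"]] - agg$r_f_mu_subst[["r_min"]],
      sum = agg$r_f_mu_sum[["r_high"]] - agg$r_f_mu_sum[["r_min"]])
  total <- spread(load_ratio_table(cells))

  loq_only <- cells
  loq_only$q_min <- loq_only$q_high <- loq_only$q_mod
  s_loq <- spread(load_ratio_table(loq_only))

  disc_only <- cells
  # Collapse censoring: substitute the moderate (c_min = 0 convention keeps
  # min/mod identical; use 0 for all three so only discharge spreads).
  disc_only$value[disc_only$censored] <- 0
  disc_only$censored <- FALSE
  s_disc <- spread(load_ratio_table(disc_only))

  share <- function(part, tot) ifelse(tot > 0, part / tot, NA_real_)
  data.frame(
    aggregate = c("r_f_mu_subst", "r_f_mu_sum"),
    total_spread = as.numeric(total),
    loq_spread = as.numeric(s_loq),
    discharge_spread = as.numeric(s_disc),
    loq_share = share(as.numeric(s_loq), as.numeric(total)),
    discharge_share = share(as.numeric(s_disc), as.numeric(total)))
}

#' Extrapolate the inlet/stream load ratio to all inlets
#'
#' Scales the summed inlet loads by the same three extrapolation factors as
#' the discharge extrapolation (road area, agricultural area, inlet count)
#' before forming the aggregate ratios, and reports the span across methods.
#'
#' @param cells as in [load_ratio_table()] (sampled inlets + stream).
#' @param weights as in [extrapolate_total_inlet_discharge()].
#' @return List with `per_method` (data frame: method, factor, ratio triples
#'   for both aggregates) and `span` (min/max of the moderate estimates
#'   across available methods, per aggregate).
#' @export
extrapolate_catchment_load_ratio <- function(cells, weights) {
  sampled <- weights$sampled
  factors <- c(
    road_area = sum(weights$road_area_m2) /
      sum(weights$road_area_m2[sampled]),
    agri_area = sum(weights$agri_area_m2) /
      sum(weights$agri_area_m2[sampled]),
    count = nrow(weights) / sum(sampled))
  rows <- lapply(names(factors), function(m) {
    fac <- factors[[m]]
    if (!is.finite(fac) || fac <= 0)
      return(data.frame(method = m, factor = NA_real_,
                        subst_min = NA_real_, subst_mod = NA_real_,
                        subst_high = NA_real_, sum_min = NA_real_,
                        sum_mod = NA_real_, sum_high = NA_real_))
    sc <- cells
    notst <- !sc$is_stream
    # Scaling loads is equivalent to scaling the inlet discharge volumes.
    sc$q_min[notst] <- sc$q_min[notst] * fac
    sc$q_mod[notst] <- sc$q_mod[notst] * fac
    sc$q_high[notst] <- sc$q_high[notst] * fac
    agg <- load_ratio_table(sc)
    data.frame(method = m, factor = fac,
               subst_min = agg$r_f_mu_subst[["r_min"]],
               subst_mod = agg$r_f_mu_subst[["r_mod"]],
               subst_high = agg$r_f_mu_subst[["r_high"]],
               sum_min = agg$r_f_mu_sum[["r_min"]],
               sum_mod = agg$r_f_mu_sum[["r_mod"]],
               sum_high = agg$r_f_mu_sum[["r_high"]])
  })
  per_method <- do.call(rbind, rows)
  ok <- !is.na(per_method$factor)
  span <- data.frame(
    aggregate = c("r_f_mu_subst", "r_f_mu_sum"),
    lo = c(min(per_method$subst_mod[ok]), min(per_method$sum_mod[ok])),
    hi = c(max(per_method$subst_mod[ok]), max(per_method$sum_mod[ok])))
  list(per_method = per_method, span = span)
}
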