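#' Build the model frame for the inlet-concentration model
#'
#' Assembles one row per retained (sample, substance) with the response
#' `log10_c` and the covariates considered relevant for pesticide transport:
#' days since the most recent relevant application (`t_appl`), amount of
#' substance applied (`log10_m_appl`), sorption (`log10_kfoc`, `log10_kow`),
#' persistence (`dt50_water`, `dt50_soil`, days), the moderate event
#' discharge (`log10_q_mod`), the transport category (`p_transport`, 4-level
#' factor with A as reference) and the inlet (`inlet`, grouping factor).
#'
#' The data set is reduced to substances with properties available and at
#' least one application inside the contributing area of an inlet. Censored
#' responses are substituted (by the LOQ by default) before the log
#' transform. `t_appl` uses the most recent application with runoff or drift
#' potential to that inlet, falling back to the most recent in-catchment
#' application; `log10_m_appl` sums the substance's applied mass up to the
#' event.
#'
#' @param samples data frame with `site`, `event`, `substance`, `value`,
#'   `loq`, `censored`, `category` (from [assign_categories()]).
#' @param events event table with `event`, `start`.
#' @param exposure an [build_exposure_table()] result.
#' @param substances substance property table ([substance_properties()]).
#' @param discharge data frame `site`, `event`, `q_mod` (event volume, L).
#' @param censor_substitution `"loq"` (default) or `"half_loq"`.
#' @return Model frame data frame; excluded substances are reported in
#'   attribute `excluded`.
#' @export
build_model_frame <- function(samples, events, exposure, substances,
                              discharge,
                              censor_substitution = c("loq", "half_loq")) {
  censor_substitution <- match.arg(censor_substitution)
  start_of <- stats::setNames(events$start, events$event)

  with_props <- samples$substance %in%
    substances$name[!is.na(substances$kfoc) & !is.na(substances$dt50_soil)]
  in_ca_subst <- unique(exposure$substance[exposure$in_ca])
  keep_subst <- samples$substance %in% in_ca_subst & with_props
  excluded <- sort(unique(samples$substance[!keep_subst]))
  df <- samples[keep_subst, , drop = FALSE]
  if (nrow(df) == 0) {
    out <- data.frame()
    attr(out, "excluded") <- excluded
    return(out)
  }

  sub <- function(loq) switch(censor_substitution, loq = loq,
                              half_loq = loq / 2)
  resp <- ifelse(df$censored, sub(df$loq), df$value)
  ok_resp <- resp > 0
  props <- substances[match(df$substance, substances$name), ]

  qkey <- paste(df$site, df$event)
  dkey <- paste(discharge$site, discharge$event)
  q_mod <- discharge$q_mod[match(qkey, dkey)]

  t_appl <- numeric(nrow(df))
  m_appl <- numeric(nrow(df))
  for (i in seq_len(nrow(df))) {
    ev_date <- as.Date(start_of[[as.character(df$event[i])]])
    rows <- exposure[exposure$site == df$site[i] &
                       exposure$substance == df$substance[i] &
                       as.Date(exposure$date) <= ev_date, , drop = FALSE]
    rel <- rows[rows$in_ca | rows$drift, , drop = FALSE]
    pick <- if (nrow(rel) > 0) rel else rows
    if (nrow(pick) == 0) { t_appl[i] <- NA; m_appl[i] <- NA; next }
    t_appl[i] <- as.numeric(ev_date - max(as.Date(pick$date)))
    m_appl[i] <- sum(rows$mass_g[!duplicated(rows$application_id)])
  }

  frame <- data.frame(
    log10_c = log10(resp),
    t_appl = t_appl,
    log10_m_appl = log10(m_appl),
    log10_kfoc = log10(props$kfoc),
    log10_kow = props$log_kow,
    dt50_water = props$dt50_water,
    dt50_soil = props$dt50_soil,
    log10_q_mod = log10(q_mod),
    p_transport = factor(df$category, levels = c("A", "B", "C", "D")),
    inlet = factor(df$site),
    substance = df$substance)
  keep <- ok_resp & !is.na(frame$t_appl) & is.finite(frame$log10_m_appl) &
    is.finite(frame$log10_q_mod)
  frame <- frame[keep, , drop = FALSE]
  rownames(frame) <- NULL
  attr(frame, "excluded") <- excluded
  frame
}

#' Remove one of a pair of collinear sorption covariates
#'
#' If the two sorption covariates are correlated beyond the threshold, the
#' random-intercept model is fitted twice, deleting one of them each time,
#' and the covariate whose deletion yields the lower AIC is removed (the
#' deletion that loses less information). Below the threshold nothing is
#' removed.
#'
#' @param frame model frame from [build_model_frame()].
#' @param threshold absolute Pearson correlation gate, default 0.7.
#' @param pair covariate pair to examine.
#' @return List: `frame` (possibly reduced), `removed` (`NULL` or name),
#'   `correlation`, `aic` (named AICs of the two candidate deletions, `NULL`
#'   if below the gate).
#' @export
drop_collinear <- function(frame, threshold = 0.7,
                           pair = c("log10_kfoc", "log10_kow")) {
  stopifnot(all(pair %in% names(frame)))
  rho <- stats::cor(frame[[pair[1]]], frame[[pair[2]]],
                    use = "complete.obs")
  if (is.na(rho) || abs(rho) < threshold)
    return(list(frame = frame, removed = NULL, correlation = rho,
                aic = NULL))
  aic <- vapply(pair, function(drop_var) {
    f <- lmm_formula(setdiff(lmm_covariates(frame), drop_var))
    fit <- suppressWarnings(suppressMessages(
      lme4::lmer(f, data = frame, REML = FALSE)))
    stats::AIC(fit)
  }, numeric(1))
  removed <- pair[which.min(aic)]
  reduced <- frame[, setdiff(names(frame), removed), drop = FALSE]
  attr(reduced, "excluded") <- attr(frame, "excluded")
  list(frame = reduced, removed = removed, correlation = rho, aic = aic)
}

lmm_covariates <- function(frame) {
  setdiff(names(frame), c("log10_c", "inlet", "substance"))
}

lmm_formula <- function(covariates) {
  stats::as.formula(paste("log10_c ~",
                          paste(covariates, collapse = " + "),
                          "+ (1 | inlet)"))
}

#' Fit the random-intercept model of log10 inlet concentrations
#'
#' One random intercept per inlet, all other covariates fixed; restricted
#' maximum likelihood estimation with Satterthwaite denominator degrees of
#' freedom for the fixed-effect p-values.
#'
#' @param frame model frame (after [drop_collinear()] if desired) with at
#'   least 10 rows and 2 inlets.
#' @return Object of class `inlet_conc_lmm`: `fit` (the `lmerMod`),
#'   `coefficients` (estimate, SE, df, t, p per fixed effect),
#'   `ranef_variance` (inlet intercept variance), `singular`, `n`,
#'   `n_substances`, `logLik`.
#' @export
fit_lmm <- function(frame) {
  if (nrow(frame) < 10) stop("model frame too small (< 10 rows)")
  if (nlevels(droplevels(frame$inlet)) < 2)
    stop("need >= 2 inlets for a random intercept")
  covs <- lmm_covariates(frame)
  covs <- covs[vapply(covs, function(v) {
    x <- frame[[v]]
    if (is.factor(x)) nlevels(droplevels(x)) > 1 else stats::var(x) > 0
  }, logical(1))]
  f <- lmm_formula(covs)
  fit <- suppressMessages(lmerTest::lmer(f, data = frame, REML = TRUE))
  singular <- lme4::isSingular(fit)
  sm <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  rv <- vc$vcov[vc$grp == "inlet"]
  if (singular) rv <- 0
  structure(list(
    fit = fit,
    coefficients = data.frame(term = rownames(sm),
                              estimate = sm[, "Estimate"],
                              se = sm[, "Std. Error"],
                              df = sm[, "df"], t = sm[, "t value"],
                              p = sm[, "Pr(>|t|)"], row.names = NULL),
    ranef_variance = rv,
    residual_variance = vc$vcov[vc$grp == "Residual"],
    singular = singular,
    n = nrow(frame),
    n_substances = length(unique(frame$substance)),
    logLik = as.numeric(stats::logLik(fit))),
    class = "inlet_conc_lmm")
}

#' @export
print.inlet_conc_lmm <- function(x, ...) {
  cat(sprintf(
    "<inlet_conc_lmm> n = %d rows, %d substances; inlet intercept var = %.4g%s\n",
    x$n, x$n_substances, x$ranef_variance,
    if (x$singular) " (singular fit)" else ""))
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
coef.inlet_conc_lmm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
summary.inlet_conc_lmm <- function(object, ...) summary(object$fit, ...)

#' Simulate a model frame with known coefficients
#'
#' Draws covariates with realistic ranges and generates the response from a
#' known linear predictor plus an inlet random intercept and residual noise.
#' Used for parameter-recovery checks of [fit_lmm()].
#'
#' @param coefs named list/vector of true coefficients; names among
#'   `intercept`, `t_appl`, `log10_m_appl`, `log10_kfoc`, `log10_kow`,
#'   `dt50_water`, `dt50_soil`, `log10_q_mod`. Missing names default to 0.
#' @param n_inlets,n_obs design size.
#' @param sd_inlet,sd_resid random-intercept and residual SDs (log10 units).
#' @param kow_noise_sd if > 0, `log10_kow` is generated as `log10_kfoc`
#'   plus noise of this SD (collinear pair); otherwise independent.
#' @param seed integer seed.
#' @return Model frame as from [build_model_frame()], with attribute
#'   `truth` (the coefficient vector used).
#' @export
simulate_model_frame <- function(coefs = list(), n_inlets = 4, n_obs = 200,
                                 sd_inlet = 0.3, sd_resid = 0.4,
                                 kow_noise_sd = 0.2, seed = 1) {
  set.seed(child_seed(seed, "model_frame"))
  full <- c(intercept = 1, t_appl = 0, log10_m_appl = 0, log10_kfoc = 0,
            log10_kow = 0, dt50_water = 0, dt50_soil = 0, log10_q_mod = 0)
  full[names(coefs)] <- unlist(coefs)
  inlet <- factor(sample(paste0("I", seq_len(n_inlets)), n_obs,
                         replace = TRUE))
  b_inlet <- stats::rnorm(n_inlets, 0, sd_inlet)
  frame <- data.frame(
    t_appl = stats::runif(n_obs, 0, 90),
    log10_m_appl = stats::runif(n_obs, 0, 3),
    log10_kfoc = stats::runif(n_obs, 1, 4),
    dt50_water = stats::runif(n_obs, 2, 60),
    dt50_soil = stats::runif(n_obs, 10, 300),
    log10_q_mod = stats::runif(n_obs, 1, 4),
    p_transport = factor(sample(c("A", "B", "C", "D"), n_obs, TRUE),
                         levels = c("A", "B", "C", "D")),
    inlet = inlet,
    substance = sample(paste0("S", 1:10), n_obs, TRUE))
  frame$log10_kow <- if (kow_noise_sd > 0)
    frame$log10_kfoc + stats::rnorm(n_obs, 0, kow_noise_sd)
  else stats::runif(n_obs, -1, 5)
  lp <- full[["intercept"]] +
    full[["t_appl"]] * frame$t_appl +
    full[["log10_m_appl"]] * frame$log10_m_appl +
    full[["log10_kfoc"]] * frame$log10_kfoc +
    full[["log10_kow"]] * frame$log10_kow +
    full[["dt50_water"]] * frame$dt50_water +
    full[["dt50_soil"]] * frame$dt50_soil +
    full[["log10_q_mod"]] * frame$log10_q_mod
  frame$log10_c <- lp + b_inlet[as.integer(frame$inlet)] +
    stats::rnorm(n_obs, 0, sd_resid)
  frame <- frame[, c("log10_c", "t_appl", "log10_m_appl", "log10_kfoc",
                     "log10_kow", "dt50_water", "dt50_soil", "log10_q_mod",
                     "p_transport", "inlet", "substance")]
  attr(frame, "truth") <- full
  frame
}
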