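test_that("censored concentration bounds follow the LOQ rule", {
  cc <- censored_concentration(c(500, NA, 19), c(20, 20, 20),
                               c(FALSE, TRUE, TRUE))
  expect_equal(cc$c_min, c(500, 0, 0))
  expect_equal(cc$c_max, c(500, 20, 20))
  expect_error(censored_concentration(NA, 20, FALSE), "non-missing")
  expect_error(censored_concentration(10, 0, TRUE))
})

test_that("event loads reproduce the worked discharge-concentration examples", {
  q <- c(q_min = 100, q_mod = 120, q_high = 150)
  f <- event_load(q, censored_concentration(500, 20, FALSE))
  expect_equal(unname(f), c(50000, 60000, 75000))
  f2 <- event_load(q, censored_concentration(NA, 20, TRUE))
  expect_equal(unname(f2), c(0, 0, 3000))
  expect_error(event_load(c(q_min = -1, q_mod = 0, q_high = 1),
                          censored_concentration(5, 20, FALSE)), "negative")
})

test_that("load triples are ordered min <= mod <= high on random inputs", {
  set.seed(4)
  for (k in seq_len(10000)) {
    q <- sort(stats::runif(3, 0, 1000))
    names(q) <- c("q_min", "q_mod", "q_high")
    cens <- stats::runif(1) < 0.5
    f <- event_load(q, censored_concentration(
      if (cens) NA else stats::runif(1, 0, 100), stats::runif(1, 1, 50),
      cens))
    expect_true(f[["f_min"]] <= f[["f_mod"]] &&
                  f[["f_mod"]] <= f[["f_high"]])
  }
})

test_that("load ratio uses conservative cross-pairing and flags zero denominators", {
  inl <- matrix(c(0, 0, 0), 1, 3,
                dimnames = list(NULL, c("f_min", "f_mod", "f_high")))
  st <- c(f_min = 10, f_mod = 20, f_high = 40)
  r <- load_ratio(inl, st)
  expect_equal(unname(r[1:3]), c(0, 0, 0))
  # sum of inlet mod equal to stream mod gives r_mod = 1
  inl2 <- matrix(c(5, 5, 5, 5, 10, 10), 2, 3, byrow = FALSE,
                 dimnames = list(NULL, c("f_min", "f_mod", "f_high")))
  r2 <- load_ratio(inl2, c(f_min = 5, f_mod = 10, f_high = 20))
  expect_equal(r2[["r_mod"]], 1)
  # fully censored stream load leaves r_high undefined
  r3 <- load_ratio(inl2, c(f_min = 0, f_mod = 0, f_high = 100))
  expect_true(is.na(r3[["r_high"]]))
  expect_false(is.na(r3[["r_min"]]))
  expect_equal(attr(r3, "undefined"), 2)
})

test_that("aggregates: single cell, equal-weight mean, and the dominant-substance effect", {
  one <- data.frame(r_min = 0.1, r_mod = 0.2, r_high = 0.3)
  inl <- data.frame(f_min = 1, f_mod = 2, f_high = 3)
  st <- data.frame(f_min = 10, f_mod = 10, f_high = 10)
  a <- aggregate_ratios(one, inl, st)
  expect_equal(unname(a$r_f_mu_subst), c(0.1, 0.2, 0.3))
  expect_equal(unname(a$r_f_mu_sum), c(0.1, 0.2, 0.3))
  # two cells with ratios 0.1 and 0.3 and equal stream loads -> mean 0.2
  two <- data.frame(r_min = c(0.1, 0.3), r_mod = c(0.1, 0.3),
                    r_high = c(0.1, 0.3))
  inl2 <- data.frame(f_min = c(1, 3), f_mod = c(1, 3), f_high = c(1, 3))
  st2 <- data.frame(f_min = c(10, 10), f_mod = c(10, 10),
                    f_high = c(10, 10))
  a2 <- aggregate_ratios(two, inl2, st2)
  expect_equal(a2$r_f_mu_subst[["r_mod"]], 0.2)
  expect_equal(a2$r_f_mu_sum[["r_mod"]], 0.2)
  # a substance dominating the stream sum drags the sum ratio below the
  # per-substance mean when its own ratio is small (hand-computed):
  # substance A: inlets 1, stream 10 (ratio 0.1); substance B: inlets 1,
  # stream 100 (ratio 0.01). mean = 0.055; sums = 2/110 = 0.01818...
  cells <- data.frame(
    site = c("I1", "ST", "I1", "ST"),
    event = 1, substance = c("A", "A", "B", "B"),
    q_min = c(1, 10, 1, 100), q_mod = c(1, 10, 1, 100),
    q_high = c(1, 10, 1, 100),
    value = 1, loq = 0.1, censored = FALSE,
    is_stream = c(FALSE, TRUE, FALSE, TRUE))
  res <- load_ratio_table(cells)
  expect_equal(res$r_f_mu_subst[["r_mod"]], 0.055)
  expect_equal(res$r_f_mu_sum[["r_mod"]], 2 / 110)
  expect_lt(res$r_f_mu_sum[["r_mod"]], res$r_f_mu_subst[["r_mod"]])
  expect_error(aggregate_ratios(one[0, ], inl[0, ], st[0, ]), "empty")
})

test_that("pipeline aggregates match the independent brute-force oracle", {
  for (seed in 1:5) {
    cells <- random_cells(seed = seed)
    got <- load_ratio_table(cells)
    want <- oracle_cells_aggregates(cells)
    expect_equal(unname(got$r_f_mu_subst), want$subst, tolerance = 1e-12)
    expect_equal(unname(got$r_f_mu_sum), want$sum, tolerance = 1e-12)
  }
})

test_that("uncertainty shares match finite-difference source toggling", {
  oracle_spread <- function(cells) {
    a <- oracle_cells_aggregates(cells)
    c(subst = a$subst[3] - a$subst[1], sum = a$sum[3] - a$sum[1])
  }
  for (seed in 1:4) {
    cells <- random_cells(seed = seed + 20)
    # give inlets real discharge spread
    got <- uncertainty_attribution(cells)
    loq_only <- cells
    loq_only$q_min <- loq_only$q_high <- loq_only$q_mod
    disc_only <- cells
    disc_only$value[disc_only$censored] <- 0
    disc_only$censored <- FALSE
    want_total <- oracle_spread(cells)
    want_loq <- oracle_spread(loq_only)
    want_disc <- oracle_spread(disc_only)
    expect_equal(got$total_spread, unname(want_total), tolerance = 1e-12)
    expect_equal(got$loq_spread, unname(want_loq), tolerance = 1e-12)
    expect_equal(got$discharge_spread, unname(want_disc), tolerance = 1e-12)
    expect_equal(got$loq_share, unname(want_loq / want_total),
                 tolerance = 1e-10)
  }
  # no censored values -> LOQ share 0; flat discharge -> discharge share 0
  cells <- random_cells(seed = 3, censor_prob = 0)
  ua <- uncertainty_attribution(cells)
  expect_equal(ua$loq_share, c(0, 0))
  flat <- random_cells(seed = 3)
  flat$q_min <- flat$q_high <- flat$q_mod
  uaf <- uncertainty_attribution(flat)
  expect_equal(uaf$discharge_share, c(0, 0))
})

test_that("catchment load extrapolation is linear and spans the methods", {
  cells <- random_cells(seed = 9)
  w <- data.frame(site = sprintf("I%d", 1:10),
                  road_area_m2 = rep(10, 10), agri_area_m2 = rep(100, 10),
                  sampled = c(rep(TRUE, 4), rep(FALSE, 6)))
  ex <- extrapolate_catchment_load_ratio(cells, w)
  # identical relative weights -> all three factors = 10/4
  expect_equal(ex$per_method$factor, rep(2.5, 3))
  base <- load_ratio_table(cells)
  expect_equal(ex$per_method$sum_mod,
               rep(base$r_f_mu_sum[["r_mod"]] * 2.5, 3), tolerance = 1e-12)
  # scale factor 1 leaves ratios unchanged
  w1 <- w[w$sampled, ]
  ex1 <- extrapolate_catchment_load_ratio(cells, w1)
  expect_equal(ex1$per_method$subst_mod,
               rep(base$r_f_mu_subst[["r_mod"]], 3), tolerance = 1e-12)
  expect_equal(ex$span$lo, ex$span$hi)  # all methods agree here
})
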