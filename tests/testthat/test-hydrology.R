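test_that("rating scenarios coincide below the calibrated limit and diverge above", {
  rc <- rating_curve()
  t0 <- as.POSIXct("2019-05-01", tz = "UTC")
  st <- data.frame(time = t0 + 0:3 * 60,
                   stage_m = c(0, 0.03, rc$h_cal, 0.2))
  q <- stage_to_discharge(st, rc)
  expect_equal(q$q_min[1], 0); expect_equal(q$q_high[1], 0)
  expect_equal(q$q_min[2], q$q_mod[2]); expect_equal(q$q_mod[2], q$q_high[2])
  expect_equal(q$q_min[3], q$q_mod[3], tolerance = 1e-12)
  expect_lt(q$q_min[4], q$q_mod[4])
  expect_lt(q$q_mod[4], q$q_high[4])
  # continuity at the limit
  eps_st <- data.frame(time = t0, stage_m = rc$h_cal * (1 + 1e-9))
  qe <- stage_to_discharge(eps_st, rc)
  expect_equal(qe$q_min, qe$q_high, tolerance = 1e-6)
  expect_error(stage_to_discharge(data.frame(time = t0, stage_m = -0.01), rc),
               "negative")
})

test_that("discharge is monotone in stage in every scenario", {
  rc <- rating_curve()
  t0 <- as.POSIXct("2019-05-01", tz = "UTC")
  st <- data.frame(time = t0 + seq_len(50) * 60,
                   stage_m = seq(0, 0.3, length.out = 50))
  q <- stage_to_discharge(st, rc)
  expect_true(all(diff(q$q_min) > 0 | q$q_min[-1] == 0))
  expect_true(all(diff(q$q_mod) >= 0))
  expect_true(all(diff(q$q_high) >= 0))
  expect_true(all(q$q_min <= q$q_mod & q$q_mod <= q$q_high))
})

test_that("event volumes integrate a constant discharge exactly", {
  t0 <- as.POSIXct("2019-05-01", tz = "UTC")
  dis <- data.frame(time = t0 + 0:119 * 60, q = rep(2, 120))
  v <- event_volume(dis, t0, t0 + 3600, tail_h = 0, cols = "q")
  expect_equal(unname(v), 2 * 3600)
})

test_that("Lyne-Hollick filter matches the naive recursion oracle", {
  set.seed(99)
  for (k in 1:5) {
    q <- pmax(0, 10 + cumsum(stats::rnorm(400)))
    for (a in c(0.9, 0.925, 0.95)) {
      got <- separate_fast_flow(q, a)
      expect_lt(max(abs(got$fast - naive_lh_three_pass(q, a))), 1e-10)
      expect_true(all(got$base >= -1e-12 & got$fast >= -1e-12))
      expect_equal(got$fast + got$base, q)
    }
  }
})

test_that("constant discharge has no fast component; zero series is idempotent", {
  sep <- separate_fast_flow(rep(7, 300), 0.925)
  expect_true(all(sep$fast == 0))
  sep0 <- separate_fast_flow(rep(0, 100), 0.9)
  expect_true(all(sep0$fast == 0) && all(sep0$base == 0))
})

test_that("fast-flow volume increases with the filter parameter on storm hydrographs", {
  t0 <- as.POSIXct("2019-05-01", tz = "UTC")
  for (s in 1:3) {
    set.seed(s)
    q <- storm_hydrograph(peak = stats::runif(1, 20, 80),
                          width = stats::runif(1, 20, 60))
    dis <- data.frame(time = t0 + (seq_along(q) - 1) * 60, q = q)
    fv <- stream_fast_volumes(dis, t0, t0 + length(q) * 60, tail_h = 0)
    expect_lt(fv[["fast_low"]], fv[["fast_mod"]])
    expect_lt(fv[["fast_mod"]], fv[["fast_high"]])
  }
})

test_that("discharge ratios use conservative pairing and flag zero denominators", {
  inlet <- matrix(1, 4, 3, dimnames = list(NULL, c("q_min", "q_mod", "q_high")))
  r <- discharge_ratios(inlet, 400,
                        c(fast_low = 50, fast_mod = 100, fast_high = 200))
  expect_equal(unname(r$r_q), rep(0.01, 3))           # 4 / 400 = 1%
  expect_equal(r$r_q_fast[["min"]], 4 / 200)
  expect_equal(r$r_q_fast[["mod"]], 4 / 100)
  expect_equal(r$r_q_fast[["high"]], 4 / 50)
  # zero inlet volumes give zero ratios
  r0 <- discharge_ratios(matrix(0, 4, 3,
                                dimnames = list(NULL, colnames(inlet))),
                         400, c(fast_low = 1, fast_mod = 2, fast_high = 3))
  expect_equal(unname(r0$r_q), rep(0, 3))
  # zero stream volume undefined-flagged
  rz <- discharge_ratios(inlet, 0, c(fast_low = 0, fast_mod = 0,
                                     fast_high = 0))
  expect_true(all(is.na(rz$r_q)))
  expect_equal(rz$undefined, 6)
})

test_that("ratio bound ordering holds on random triples", {
  set.seed(13)
  for (k in 1:1000) {
    v <- sort(stats::runif(3, 0, 100))
    inlet <- matrix(rep(v, each = 4), 4, 3,
                    dimnames = list(NULL, c("q_min", "q_mod", "q_high")))
    fast <- sort(stats::runif(3, 1, 50))
    r <- discharge_ratios(inlet, stats::runif(1, 1, 1000),
                          c(fast_low = fast[1], fast_mod = fast[2],
                            fast_high = fast[3]))
    expect_true(r$r_q[["min"]] <= r$r_q[["mod"]] &&
                  r$r_q[["mod"]] <= r$r_q[["high"]])
    expect_true(r$r_q_fast[["min"]] <= r$r_q_fast[["mod"]] &&
                  r$r_q_fast[["mod"]] <= r$r_q_fast[["high"]])
  }
})

test_that("extrapolation factors follow road area, agri area and count", {
  meas <- matrix(10, 4, 3, dimnames = list(NULL, c("q_min", "q_mod",
                                                   "q_high")))
  # sampled inlets carry 2.9% of connected road area -> factor 1/0.029
  w <- data.frame(site = sprintf("I%03d", 1:158),
                  road_area_m2 = c(rep(0.029 * 1000 / 4, 4),
                                   rep(0.971 * 1000 / 154, 154)),
                  agri_area_m2 = rep(10, 158),
                  sampled = c(rep(TRUE, 4), rep(FALSE, 154)))
  ex <- extrapolate_total_inlet_discharge(meas, w)
  expect_equal(ex$factor[ex$method == "road_area"], 1 / 0.029,
               tolerance = 1e-9)
  expect_equal(ex$factor[ex$method == "count"], 158 / 4)  # 39.5
  expect_equal(ex$factor[ex$method == "agri_area"], 158 / 4)
  expect_equal(ex$q_mod[ex$method == "count"], 40 * 39.5)
  # zero measured volumes extrapolate to zero
  ex0 <- extrapolate_total_inlet_discharge(meas * 0, w)
  expect_true(all(ex0$q_mod == 0))
  # zero sampled weight flags the method unavailable
  w$road_area_m2[w$sampled] <- 0
  exna <- extrapolate_total_inlet_discharge(meas, w)
  expect_false(exna$available[exna$method == "road_area"])
  expect_true(is.na(exna$q_mod[exna$method == "road_area"]))
})
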