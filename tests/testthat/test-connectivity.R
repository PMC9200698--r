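test_that("DEM conditioning fills shallow pits, keeps deep ones, carves roads", {
  flat <- dem_grid(matrix(5, 9, 9), 2)
  # flat plane without roads stays (numerically) unchanged
  cd <- condition_dem(flat, params = connectivity_params())
  expect_lt(max(abs(cd$z - 5)), 1e-3)
  # shallow pit filled to (at least) its pour level
  z <- matrix(5, 9, 9); z[5, 5] <- 4.95
  cd <- condition_dem(dem_grid(z, 2),
                      params = connectivity_params(sink_fill_depth = 0.1))
  expect_gt(cd$z[5, 5], 4.999)
  # deep pit retained as sink
  z[5, 5] <- 4.5
  cd <- condition_dem(dem_grid(z, 2),
                      params = connectivity_params(sink_fill_depth = 0.1))
  expect_equal(cd$z[5, 5], 4.5)
  expect_true(!is.null(attr(cd, "sink_cells")))
  # road carving lowers exactly the road cells
  z2 <- outer(9:1, rep(1, 9)) * 0.1
  roads <- cbind(row = rep(4, 9), col = 1:9)
  cd2 <- condition_dem(dem_grid(z2, 2), roads,
                       connectivity_params(road_carving_depth = 0.3,
                                           sink_fill_depth = 0))
  expect_equal(cd2$z[4, 5], z2[4, 5] - 0.3, tolerance = 1e-6)
})

test_that("uniform tilt routes 100% east with identical angles", {
  z <- outer(rep(0, 6), 6:1, `+`)
  fd <- flow_directions_dinf(dem_grid(z, 2))
  ang <- fd$angle[!fd$is_sink]
  expect_true(all(ang == 0))
  expect_true(all(fd$p1[!fd$is_sink] == 1))
  expect_equal(sum(fd$is_sink), 6)  # the eastern column exits the grid
})

test_that("flow aimed midway between neighbours splits 50/50; diagonal aim routes fully diagonal", {
  # plane dipping 22.5 degrees south of east: midway between the east and
  # south-east neighbours
  th <- pi / 8
  z <- outer(1:8, 1:8, function(i, j) -(cos(th) * j + sin(th) * i) * 0.2)
  fd <- flow_directions_dinf(dem_grid(z, 2))
  interior <- matrix(FALSE, 8, 8); interior[2:7, 2:7] <- TRUE
  expect_true(all(abs(fd$p1[interior] - 0.5) < 1e-9))
  expect_true(all(abs(fd$p2[interior] - 0.5) < 1e-9))
  # plane dipping exactly to the south-east: all flow to the diagonal
  z2 <- outer(1:8, 1:8, function(i, j) -(i + j) * 0.1)
  fd2 <- flow_directions_dinf(dem_grid(z2, 2))
  expect_true(all(abs(fd2$p2[interior] - 1) < 1e-12))
})

test_that("accumulated area equals the exhaustive routing oracle on random grids", {
  set.seed(11)
  for (k in 1:6) {
    z <- matrix(stats::rnorm(36, sd = 0.4), 6, 6) +
      outer(6:1, 1:6, function(a, b) 0.4 * a + 0.15 * b)
    fd <- flow_directions_dinf(dem_grid(z, 2))
    acc <- flow_accumulation(fd)
    o <- oracle_accumulation(fd)
    expect_lt(max(abs(acc - o) / pmax(o, 1)), 1e-9)
  }
})

test_that("delineation labels a bowl to its inlet and partitions the area", {
  z <- outer(-10:10, -10:10, function(i, j) 0.1 * (i^2 + j^2))
  fd <- flow_directions_dinf(dem_grid(z, 2))
  ca <- delineate_contributing_areas(
    fd, data.frame(site = "I1", row = 11, col = 11),
    cbind(row = integer(0), col = integer(0)))
  d <- ca$destinations
  expect_equal(d$area_m2[d$dest == "inlet_I1"], 21 * 21 * 4)
  expect_equal(sum(d$area_m2), 21 * 21 * 4)
  expect_equal(d$frac_area_m2[d$dest == "inlet_I1"], 21 * 21 * 4)
})

test_that("plane draining to stream edge labels everything stream", {
  z <- outer(20:1, rep(1, 8)) * 0.2  # dips towards the bottom row
  fd <- flow_directions_dinf(dem_grid(z, 2))
  ca <- delineate_contributing_areas(
    fd, data.frame(site = character(0), row = integer(0), col = integer(0)),
    cbind(row = rep(20L, 8), col = 1:8))
  d <- ca$destinations
  expect_equal(d$area_m2[d$dest == "stream"], 20 * 8 * 4)
})

test_that("constructed two-tributary catchment is labelled as built", {
  # two bowls separated by a central ridge; an inlet at each bottom
  z <- matrix(0, 15, 21)
  for (i in 1:15) for (j in 1:21) {
    left <- 0.05 * ((i - 8)^2 + (j - 5)^2)
    right <- 0.05 * ((i - 8)^2 + (j - 17)^2)
    z[i, j] <- min(left, right)
  }
  fd <- flow_directions_dinf(dem_grid(z, 2))
  inl <- data.frame(site = c("L", "R"), row = c(8, 8), col = c(5, 17))
  ca <- suppressWarnings(delineate_contributing_areas(
    fd, inl, cbind(row = integer(0), col = integer(0))))
  lab <- ca$labels
  # far interior of each bowl goes to its own inlet
  expect_equal(ca$destinations$dest[lab[8, 3]], "inlet_L")
  expect_equal(ca$destinations$dest[lab[8, 19]], "inlet_R")
  expect_equal(ca$destinations$dest[lab[4, 5]], "inlet_L")
  expect_equal(ca$destinations$dest[lab[12, 17]], "inlet_R")
})

test_that("destination shares match the exhaustive oracle on small grids", {
  set.seed(23)
  for (k in 1:3) {
    z <- matrix(stats::rnorm(64, sd = 0.3), 8, 8) +
      outer(8:1, rep(1, 8)) * 0.5
    dem <- dem_grid(z, 2)
    fd <- flow_directions_dinf(dem)
    inl <- data.frame(site = "I1", row = 7L, col = sample(2:7, 1))
    stream <- cbind(row = rep(8L, 8), col = 1:8)
    ca <- suppressWarnings(delineate_contributing_areas(
      fd, inl, stream, keep_shares = TRUE))
    # rebuild the absorbing map exactly as the ca-map does
    n_dest <- nrow(ca$destinations)
    dest_of_cell <- integer(64)
    dest_of_cell[(stream[, "col"] - 1L) * 8 + stream[, "row"]] <- 2L
    dest_of_cell[(inl$col - 1L) * 8 + inl$row] <- 1L
    dest_of_cell[fd$is_sink & dest_of_cell == 0] <- n_dest
    o <- oracle_destination_shares(fd, dest_of_cell, n_dest)
    expect_lt(max(abs(ca$shares - o)), 1e-9)
  }
})

test_that("carving more deeply never shrinks road-adjacent area draining to inlets", {
  catch <- generate_catchment(small_catchment_config(), seed = 3)
  roads <- as.matrix(catch$road_cells[, c("row", "col")])
  outlets <- rbind(catch$stream_cells, as.matrix(catch$inlets[, c("row", "col")]))
  frac <- vapply(c(0.02, 0.1, 0.3), function(depth) {
    cd <- condition_dem(catch$dem, roads,
                        connectivity_params(road_carving_depth = depth),
                        outlets = outlets)
    fd <- flow_directions_dinf(cd)
    ca <- suppressWarnings(delineate_contributing_areas(
      fd, catch$inlets, catch$stream_cells))
    d <- ca$destinations
    sum(d$frac_area_m2[d$type == "inlet"])
  }, numeric(1))
  expect_true(all(diff(frac) >= -1e-6))
})

test_that("Monte Carlo: point-mass parameters reproduce identical runs", {
  catch <- generate_catchment(small_catchment_config(nrow = 25, ncol = 25,
                                                     n_inlets = 4), seed = 5)
  p <- connectivity_params(0.1, 0.1,
                           dists = list(road_carving_depth = c(0.1, 0.1),
                                        sink_fill_depth = c(0.1, 0.1)))
  mc <- monte_carlo_connectivity(
    catch$dem, as.matrix(catch$road_cells[, c("row", "col")]),
    catch$inlets, catch$stream_cells, p, n_runs = 5, seed = 2)
  expect_equal(length(unique(mc$runs$frac_inlet)), 1)
  expect_equal(mc$summary$median[mc$summary$fraction == "inlet"],
               mc$runs$frac_inlet[1])
  # median lies inside the per-run range for dispersed parameters
  p2 <- connectivity_params(dists = list(road_carving_depth = c(0.02, 0.3),
                                         sink_fill_depth = c(0.02, 0.3)))
  mc2 <- monte_carlo_connectivity(
    catch$dem, as.matrix(catch$road_cells[, c("row", "col")]),
    catch$inlets, catch$stream_cells, p2, n_runs = 8, seed = 2)
  med <- mc2$summary$median[mc2$summary$fraction == "inlet"]
  expect_gte(med, min(mc2$runs$frac_inlet))
  expect_lte(med, max(mc2$runs$frac_inlet))
})

test_that("exposure predicates: contributing area, 100-m drift boundary, road link", {
  # one inlet in a bowl; plots placed inside the CA, near, and far
  z <- outer(-30:30, -30:30, function(i, j) 0.02 * (i^2 + j^2))
  dem <- dem_grid(z, 2)   # 61 x 61 cells, 122 m x 122 m
  fd <- flow_directions_dinf(dem)
  inl <- data.frame(site = "I1", row = 31L, col = 31L)
  ca <- suppressWarnings(delineate_contributing_areas(
    fd, inl, cbind(row = integer(0), col = integer(0))))
  sxy <- cell_xy(dem, 31, 31)
  sites <- data.frame(site = "I1", x = sxy[1], y = sxy[2])
  # plot rings in metres; the site sits at (61, 61)
  plots <- list(
    inside = cbind(c(55, 67, 67, 55), c(55, 55, 67, 67)),
    near = cbind(c(5, 15, 15, 5), c(5, 5, 15, 15)),      # ~58 m away
    boundary99 = cbind(c(-45, -38, -38, -45), c(55, 55, 67, 67)),
    boundary101 = cbind(c(-47, -40.5, -40.5, -47), c(55, 55, 67, 67)))
  # distances from site x=61: inside 0; boundary99: 61-(-38)=99;
  # boundary101: 61-(-40.5)=101.5
  apps <- data.frame(application_id = 1:4, substance = "metamitron",
                     date = as.Date("2019-05-01"),
                     plot_id = names(plots), mass_g = 100)
  et <- build_exposure_table(ca, dem, plots, apps,
                             cbind(row = integer(0), col = integer(0)),
                             sites)
  et <- et[order(et$application_id), ]
  expect_true(et$in_ca[et$plot_id == "inside"])
  expect_true(et$in_ca[et$plot_id == "near"])  # whole bowl drains to I1
  expect_false(et$in_ca[et$plot_id == "boundary99"])   # outside the grid
  expect_true(et$drift_direct[et$plot_id == "boundary99"])
  expect_false(et$drift_direct[et$plot_id == "boundary101"])
  # unknown plots are rejected with a report
  apps2 <- rbind(apps, data.frame(application_id = 5,
                                  substance = "metamitron",
                                  date = as.Date("2019-05-01"),
                                  plot_id = "ghost", mass_g = 1))
  expect_warning(et2 <- build_exposure_table(
    ca, dem, plots, apps2, cbind(row = integer(0), col = integer(0)),
    sites), "unknown plots")
  expect_equal(nrow(attr(et2, "rejected")), 1)
})
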