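test_that("zero influx gives identically zero fields", {
  cfg <- simulation_config(dye_preset("calcein"),
                           influx_profile("custom", J0 = 0, anode_fraction = 1),
                           cell_radius = 6, grid_n = 32, frame_interval = 0.2,
                           duration = 4, pulse_time = 1, noise_sigma = 0)
  tr <- simulate_uptake(cfg)
  expect_true(all(tr$cf == 0) && all(tr$cb == 0))
  expect_true(all(tr$cumulative_influx == 0))
})

test_that("mass balance matches an independent quadrature of the boundary flux", {
  # anode-only influx, no binding, small grid; oracle integrates
  # J0 * perimeter * exp(-(t - onset)/tau) in time analytically
  J0 <- 1.5; tau <- 5; onset <- 2; r <- 6
  cfg <- simulation_config(dye_preset("calcein"),
                           influx_profile("custom", J0 = J0, anode_fraction = 1,
                                          angular_width = pi / 3,
                                          decay_tau = tau, onset = onset),
                           cell_radius = r, grid_n = 32, pixel_size = 0.5,
                           frame_interval = 0.2, duration = 12,
                           pulse_time = onset, noise_sigma = 0)
  tr <- simulate_uptake(cfg)
  amount <- colSums(tr$cf + tr$cb) * cfg$pixel_size^2
  oracle <- J0 * (2 * pi * r) * tau * (1 - exp(-pmax(tr$times - onset, 0) / tau))
  post <- tr$times > onset + 0.5
  expect_lt(max(abs(amount[post] - oracle[post]) / oracle[post]), 0.01)
  # and the tracked cumulative influx agrees with the field integral exactly
  expect_lt(max(abs(amount[post] - tr$cumulative_influx[post]) /
                tr$cumulative_influx[post]), 1e-10)
})

test_that("mass balance holds with binding switched on", {
  cfg <- fast_config("microsecond_bipolar", dye_name = "YP1", duration = 15)
  tr <- simulate_uptake(cfg)
  amount <- colSums(tr$cf + tr$cb) * cfg$pixel_size^2
  post <- tr$times > cfg$pulse_time + 1
  expect_lt(max(abs(amount[post] - tr$cumulative_influx[post]) /
                tr$cumulative_influx[post]), 0.01)
  expect_gt(max(tr$cb), 0) # binding actually engaged
})

test_that("symmetric influx keeps anode and cathode regions equal", {
  cfg <- fast_config("symmetric_low", dye_name = "calcein", duration = 20)
  tr <- simulate_uptake(cfg)
  reg <- tr$regional
  a <- reg$conc_total_uM[reg$region == "anode"]
  c_ <- reg$conc_total_uM[reg$region == "cathode"]
  m <- reg$conc_total_uM[reg$region == "middle"]
  cellmean <- (a + c_ + m) / 3
  sel <- cellmean > 0.005
  expect_lt(max(abs(a - c_)[sel] / cellmean[sel]), 0.02)
})

test_that("stability bound violations are configuration errors naming dt", {
  expect_error(
    simulation_config(dye_preset("calcein"), influx_preset("symmetric_low"),
                      cell_radius = 6, grid_n = 32, duration = 10, dt = 100),
    "maximum admissible dt")
})

test_that("free dye relaxes toward spatial uniformity after influx ends", {
  cfg <- simulation_config(dye_preset("calcein"),
                           influx_profile("custom", J0 = 2, anode_fraction = 1,
                                          angular_width = pi / 3,
                                          decay_tau = 0.5, onset = 1),
                           cell_radius = 6, grid_n = 32, frame_interval = 0.2,
                           duration = 20, pulse_time = 1, noise_sigma = 0)
  tr <- simulate_uptake(cfg)
  spread <- apply(tr$cf, 2, function(v) diff(range(v)))
  late <- tr$times > 1 + 5 * 0.5 # influx effectively over
  expect_true(all(diff(spread[late]) <= 1e-9))
})

test_that("binding retards the intracellular spread toward the far pole", {
  base <- influx_profile("custom", J0 = 2, anode_fraction = 1,
                         angular_width = pi / 3, decay_tau = 10, onset = 1)
  free_dye <- dye_model("free", 2, 400, 1.2, D_free = 5e-12,
                        phi_free = 1, phi_bound = 0)
  binder <- dye_model("binder", 2, 400, 1.2, D_free = 5e-12,
                      k_on = 0.1, k_off = 0.002, B_max = 150,
                      phi_free = 1, phi_bound = 1)
  half_time <- function(dye) {
    cfg <- simulation_config(dye, base, cell_radius = 6, grid_n = 32,
                             frame_interval = 0.2, duration = 40,
                             pulse_time = 1, noise_sigma = 0)
    tr <- simulate_uptake(cfg)
    reg <- tr$regional
    a <- reg$conc_total_uM[reg$region == "anode"]
    c_ <- reg$conc_total_uM[reg$region == "cathode"]
    hit <- which(c_ >= a / 2 & a > 0.01)
    if (length(hit) == 0) Inf else tr$times[hit[1]]
  }
  expect_gt(half_time(binder), half_time(free_dye))
})

test_that("render_stack is deterministic, calibrated, and noise-faithful", {
  cfg <- fast_config("nanosecond_multi_anode", duration = 6, noise_sigma = 5,
                     grid_n = 48)
  tr <- simulate_uptake(cfg)
  curve <- line_curve(slope = 300, intercept = 100)
  s1 <- render_stack(tr, curve)
  s2 <- render_stack(tr, curve)
  expect_identical(s1$frames, s2$frames) # same truth + seed -> bit-identical
  expect_error(render_stack(tr, NULL), "calibration")

  # noise SD oracle: background (outside the cell) pixels of an early frame
  bg <- which(!tr$mask)
  vals <- s1$frames[[2]][bg]
  expect_equal(sd(vals), 5, tolerance = 0.1)
  expect_equal(mean(vals), 100, tolerance = 1)

  # zero fields + zero noise -> flat stack at the calibration intercept
  cfg0 <- simulation_config(dye_preset("calcein"),
                            influx_profile("custom", J0 = 0, anode_fraction = 0.5),
                            cell_radius = 6, grid_n = 32, frame_interval = 0.5,
                            duration = 2, pulse_time = 1, noise_sigma = 0)
  tr0 <- simulate_uptake(cfg0)
  s0 <- render_stack(tr0, curve)
  expect_true(all(vapply(s0$frames, function(f) all(f == 100), TRUE)))
})

test_that("mirror-symmetric configuration renders a mirror-symmetric stack", {
  cfg <- simulation_config(dye_preset("calcein"), influx_preset("symmetric_low"),
                           cell_radius = 6, grid_n = 32, frame_interval = 0.5,
                           duration = 10, pulse_time = 1, noise_sigma = 0)
  tr <- simulate_uptake(cfg)
  st <- render_stack(tr, line_curve(slope = 300, intercept = 0))
  last <- st$frames[[length(st$frames)]]
  expect_gt(max(last), 0)
  expect_identical(last, last[, ncol(last):1]) # reflect across mid-plane
})

test_that("truth serialization writes regional CSV and parameter JSON", {
  cfg <- fast_config("symmetric_low", dye_name = "calcein", duration = 8,
                     grid_n = 48)
  tr <- simulate_uptake(cfg)
  dir <- withr::local_tempdir()
  write_truth(tr, file.path(dir, "t.csv"), file.path(dir, "p.json"))
  df <- read.csv(file.path(dir, "t.csv"))
  expect_equal(nrow(df), 3 * length(tr$times))
  p <- jsonlite::read_json(file.path(dir, "p.json"))
  expect_equal(p$scenario, "symmetric_low")
  expect_equal(p$seed, 1)
})
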