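test_that("partition_rows implements the one-third rule with equal polar groups", {
  # 9 occupied columns -> 3/3/3
  roi9 <- cell_roi(1, 1, disc_mask(17, radius = 4.4))
  g9 <- partition_rows(roi9, "x", "low")
  expect_equal(lengths(g9[c("anode", "middle", "cathode")]),
               c(anode = 3, middle = 3, cathode = 3))

  # ~50-row cell (the typical size at this magnification) -> 16/18/16
  roi50 <- cell_roi(1, 1, disc_mask(64, radius = 24.6))
  g50 <- partition_rows(roi50, "x", "low")
  expect_equal(lengths(g50[c("anode", "middle", "cathode")]),
               c(anode = 16, middle = 18, cathode = 16))

  # 4 rows -> 1/2/1, and the full remainder rule by enumeration:
  # polar groups floor(R/3) each, middle takes the remainder
  m4 <- matrix(FALSE, 8, 8); m4[3:6, 3:6] <- TRUE
  g4 <- partition_rows(cell_roi(1, 1, m4), "x", "low")
  expect_equal(lengths(g4[c("anode", "middle", "cathode")]),
               c(anode = 1, middle = 2, cathode = 1))
  for (R in 3:40) {
    m <- matrix(FALSE, 44, 44); m[10:20, seq_len(R) + 1] <- TRUE
    g <- partition_rows(cell_roi(1, 1, m), "x", "low")
    expect_equal(length(g$anode), R %/% 3)
    expect_equal(length(g$cathode), R %/% 3)
    expect_equal(length(g$middle), R - 2 * (R %/% 3))
    # a true partition, ordered anode to cathode
    expect_setequal(c(g$anode, g$middle, g$cathode), seq_len(R) + 1)
    expect_equal(c(g$anode, g$middle, g$cathode), seq_len(R) + 1)
  }
  expect_error(partition_rows(cell_roi(1, 1, m4[3:4, , drop = FALSE] & FALSE)),
               "empty")
  m2 <- matrix(FALSE, 8, 8); m2[3:6, 3:4] <- TRUE
  expect_error(partition_rows(cell_roi(1, 1, m2), "x", "low"), "degenerate")
})

test_that("anode side selects which end of the field axis comes first", {
  m <- matrix(FALSE, 10, 10); m[3:8, 2:9] <- TRUE
  lo <- partition_rows(cell_roi(1, 1, m), "x", "low")
  hi <- partition_rows(cell_roi(1, 1, m), "x", "high")
  expect_equal(lo$anode, 2:3)
  expect_equal(hi$anode, 9:8)
  gy <- partition_rows(cell_roi(1, 1, m), "y", "low")
  expect_equal(gy$anode, 3:4)
})

test_that("region_intensity is the row-mean-of-means, not the pooled mean", {
  mask <- disc_mask(16, 5)
  roi <- cell_roi(1, 1, mask)
  g <- partition_rows(roi, "x", "low")
  uni <- matrix(7, 16, 16)
  expect_equal(region_intensity(uni, roi, g),
               c(anode = 7, middle = 7, cathode = 7))

  # two anode rows with row means 1 and 3 -> anode value 2 regardless of
  # how many pixels each row holds
  m <- matrix(FALSE, 8, 8)
  m[4, 2] <- TRUE          # row x=2: 1 pixel
  m[3:6, 3] <- TRUE        # row x=3: 4 pixels
  m[3:6, 4:7] <- TRUE      # filler so partition has 6 rows
  roi2 <- cell_roi(1, 1, m)
  g2 <- partition_rows(roi2, "x", "low")
  fr <- matrix(0, 8, 8)
  fr[4, 2] <- 1
  fr[3:6, 3] <- 3
  expect_equal(unname(region_intensity(fr, roi2, g2)["anode"]), 2)

  # gradient toward the cathode: ordering plus brute-force agreement
  grad <- matrix(rep(seq_len(16), each = 16), 16, 16) # grad[y, x] = x
  vals <- region_intensity(grad, roi, g)
  expect_lt(vals["anode"], vals["middle"])
  expect_lt(vals["middle"], vals["cathode"])
  expect_equal(vals, brute_region_means(grad, mask, "x", "low"))
})

test_that("region_intensity matches the brute-force oracle on random blobs", {
  set.seed(202)
  for (rep in 1:25) {
    mask <- random_blob(24, target = sample(30:120, 1))
    if (length(which(colSums(mask) > 0)) < 3) next
    roi <- cell_roi(1, 1, mask)
    frame <- matrix(runif(24 * 24, 0, 100), 24, 24)
    axis <- sample(c("x", "y"), 1)
    side <- sample(c("low", "high"), 1)
    if (axis == "y" && length(which(rowSums(mask) > 0)) < 3) next
    g <- partition_rows(roi, axis, side)
    expect_equal(region_intensity(frame, roi, g),
                 brute_region_means(frame, mask, axis, side))
  }
})

test_that("mirror reflection swaps anode and cathode and fixes middle", {
  set.seed(33)
  mask <- disc_mask(20, 7)
  frame <- matrix(runif(400), 20, 20)
  roi <- cell_roi(1, 1, mask)
  v <- region_intensity(frame, roi, partition_rows(roi, "x", "low"))
  # reflect about the mid-plane perpendicular to the field axis
  frame_m <- frame[, 20:1]
  roi_m <- cell_roi(1, 1, mask[, 20:1])
  vm <- region_intensity(frame_m, roi_m, partition_rows(roi_m, "x", "low"))
  expect_equal(unname(vm["anode"]), unname(v["cathode"]))
  expect_equal(unname(vm["cathode"]), unname(v["anode"]))
  expect_equal(unname(vm["middle"]), unname(v["middle"]))
})

test_that("track_cells: stationary, moving, and well-separated cells", {
  bright_disc <- function(cy, cx, n = 48) {
    m <- matrix(20, n, n)
    m[disc_mask(n, 6, cx = cx, cy = cy)] <- 1000
    m
  }
  # stationary: identical centroid in all 10 frames
  st <- image_stack(replicate(10, bright_disc(24, 24), simplify = FALSE), 0.1,
                    pulse_time = 0.05)
  tr <- track_cells(st, list(cell_roi(1, 1, disc_mask(48, 6, cx = 24, cy = 24))))
  cents <- t(sapply(tr[[1]]$rois, function(r) r$centroid))
  expect_true(all(cents[, "x"] == cents[1, "x"] & cents[, "y"] == cents[1, "y"]))

  # 1 px/frame along y: centroid path within 0.5 px of ground truth
  mv <- image_stack(lapply(0:9, function(k) bright_disc(18 + k, 24)), 0.1,
                    pulse_time = 0.05)
  trm <- track_cells(mv, list(cell_roi(1, 1, disc_mask(48, 6, cx = 24, cy = 18))))
  path_y <- sapply(trm[[1]]$rois, function(r) r$centroid["y"])
  expect_true(all(abs(path_y - (18 + 0:9)) <= 0.5))

  # two stationary cells 40 px apart: two tracks, no identity swap
  two <- matrix(20, 96, 96)
  two[disc_mask(96, 6, cx = 25, cy = 48)] <- 900
  two[disc_mask(96, 6, cx = 65, cy = 48)] <- 1100
  st2 <- image_stack(replicate(8, two, simplify = FALSE), 0.1, pulse_time = 0.05)
  rois <- list(cell_roi(1, 1, disc_mask(96, 6, cx = 25, cy = 48)),
               cell_roi(2, 1, disc_mask(96, 6, cx = 65, cy = 48)))
  tr2 <- track_cells(st2, rois)
  expect_length(tr2, 2)
  expect_lt(abs(tr2[[1]]$rois[[8]]$centroid["x"] - 25), 1)
  expect_lt(abs(tr2[[2]]$rois[[8]]$centroid["x"] - 65), 1)
})

test_that("extract_traces: uniform stacks give constant traces; baseline works", {
  frames <- replicate(20, matrix(50, 32, 32), simplify = FALSE)
  st <- image_stack(frames, 0.1, pulse_time = 1, dye_name = "YP1")
  roi <- cell_roi(1, 1, disc_mask(32, 10))
  tracks <- list(cell_track(1L, lapply(1:20, function(f) cell_roi(1, f, roi$mask))))
  tr <- extract_traces(st, tracks, curve = NULL, baseline = FALSE)[[1]]
  expect_true(all(tr$intensity == 50))
  trb <- extract_traces(st, tracks, curve = NULL, baseline = TRUE)[[1]]
  expect_true(all(trb$intensity == 0))
  expect_equal(trb$baseline_window, 10) # frames at t = 0 .. 0.9 s
  # calibration dye mismatch is an error
  expect_error(extract_traces(st, tracks, line_curve(dye = "Pr")), "mismatch")
})

test_that("smooth_trace preserves polynomials and reduces noise variance", {
  expect_equal(smooth_trace(rep(4.2, 30), 11), rep(4.2, 30))
  t <- seq_len(60)
  q <- 0.03 * t^2 - 1.4 * t + 7
  expect_equal(smooth_trace(q, 11), q, tolerance = 1e-10)
  expect_equal(smooth_trace(q, 5, order = 2), q, tolerance = 1e-10)
  set.seed(5)
  noise <- rnorm(400)
  expect_lt(var(smooth_trace(noise, 11)), var(noise))
  expect_error(smooth_trace(noise, 10), "odd")
  expect_error(smooth_trace(rnorm(9), 11), "length")
})
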