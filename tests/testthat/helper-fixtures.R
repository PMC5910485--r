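# Shared in-code fixtures: no binary files, everything built at test time.

# circular mask with a given number of occupied columns (field axis x)
disc_mask <- function(n = 32, radius = 10, cx = NULL, cy = NULL) {
  if (is.null(cx)) cx <- (n + 1) / 2
  if (is.null(cy)) cy <- (n + 1) / 2
  yy <- matrix(seq_len(n), n, n)
  xx <- matrix(seq_len(n), n, n, byrow = TRUE)
  (xx - cx)^2 + (yy - cy)^2 <= radius^2
}

# exact straight-line calibration with no replicate noise
line_curve <- function(slope = 2, intercept = 10, dye = "YP1") {
  conc <- c(0, 10, 20)
  fit_calibration(rep(conc, each = 2), rep(slope * conc + intercept, each = 2),
                  dye_name = dye)
}

# a small fast simulation config
fast_config <- function(scenario, dye_name = "YP1", seed = 1, noise_sigma = 0,
                        duration = 20, grid_n = 48, cell_radius = 10, ...) {
  scenario_config(scenario, dye_name = dye_name, seed = seed,
                  grid_n = grid_n, cell_radius = cell_radius,
                  duration = duration, noise_sigma = noise_sigma, ...)
}

# random 4-connected blob mask grown from a seed pixel
random_blob <- function(n = 24, target = 60) {
  m <- matrix(FALSE, n, n)
  cur <- c(sample(5:(n - 4), 1), sample(5:(n - 4), 1))
  m[cur[1], cur[2]] <- TRUE
  frontier <- list(cur)
  while (sum(m) < target && length(frontier) > 0) {
    i <- sample(length(frontier), 1)
    p <- frontier[[i]]
    d <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))[[sample(4, 1)]]
    q <- p + d
    if (all(q >= 2) && all(q <= n - 1)) {
      if (!m[q[1], q[2]]) {
        m[q[1], q[2]] <- TRUE
        frontier[[length(frontier) + 1]] <- q
      }
    }
  }
  m
}

# brute-force row-mean-of-means oracle, independent of partition_rows /
# region_intensity internals
brute_region_means <- function(frame, mask, field_axis, anode_side) {
  coords <- if (field_axis == "x") which(colSums(mask) > 0) else which(rowSums(mask) > 0)
  if (anode_side == "high") coords <- rev(coords)
  R <- length(coords)
  k <- R %/% 3
  groups <- list(anode = coords[seq_len(k)],
                 middle = coords[seq(k + 1, R - k)],
                 cathode = coords[seq(R - k + 1, R)])
  vapply(groups, function(cs) {
    mean(vapply(cs, function(cc) {
      v <- if (field_axis == "x") frame[mask[, cc], cc] else frame[cc, mask[cc, ]]
      mean(v)
    }, 0))
  }, 0)
}

# build a regional_trace directly from three series
toy_trace <- function(times, anode, middle, cathode, cell_id = 1L,
                      pulse_time = 0, as_conc = TRUE) {
  df <- data.frame(anode = anode, middle = middle, cathode = cathode)
  regional_trace(cell_id, times, intensity = df,
                 concentration = if (as_conc) df else NULL,
                 pulse_time = pulse_time)
}
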