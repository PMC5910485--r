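#' Per-frame cell region of interest
#'
#' @param cell_id integer cell label.
#' @param frame_index 1-based frame number.
#' @param mask logical matrix (frame-shaped), TRUE inside the cell.
#' @return object of class `cell_roi` with the centroid precomputed
#'   (`centroid = c(x, y)` in pixel coordinates, x = column, y = row).
#' @export
cell_roi <- function(cell_id, frame_index, mask) {
  if (!is.logical(mask)) mask <- mask > 0
  if (!any(mask)) stop("ROI mask is empty")
  idx <- which(mask, arr.ind = TRUE)
  structure(list(cell_id = as.integer(cell_id),
                 frame_index = as.integer(frame_index),
                 mask = mask,
                 centroid = c(x = mean(idx[, 2]), y = mean(idx[, 1]))),
            class = "cell_roi")
}

#' Per-cell track across all frames
#'
#' @param cell_id integer cell label.
#' @param rois list of [cell_roi()], one per frame in order.
#' @param flagged logical per frame: TRUE where the tracker fell back to a
#'   translated mask because the centroid jump exceeded `max_displacement`.
#' @return object of class `cell_track`.
#' @export
cell_track <- function(cell_id, rois, flagged = logical(length(rois))) {
  structure(list(cell_id = as.integer(cell_id), rois = rois, flagged = flagged),
            class = "cell_track")
}

#' Regional intensity/concentration time series for one cell
#'
#' @param cell_id integer cell label (or the string "population-mean").
#' @param times frame times in seconds, strictly increasing.
#' @param intensity data.frame with columns anode, middle, cathode.
#' @param concentration optional data.frame of calibrated concentrations
#'   (uM), same layout.
#' @param baseline_window number of pre-pulse frames averaged for baseline
#'   subtraction (0 = none).
#' @param pulse_time pulse delivery time in seconds.
#' @return object of class `regional_trace`.
#' @export
regional_trace <- function(cell_id, times, intensity, concentration = NULL,
                           baseline_window = 0L, pulse_time = NA_real_) {
  stopifnot(nrow(intensity) == length(times),
            all(c("anode", "middle", "cathode") %in% names(intensity)))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing")
  }
  if (!is.null(concentration)) stopifnot(nrow(concentration) == length(times))
  structure(list(cell_id = cell_id, times = times, intensity = intensity,
                 concentration = concentration,
                 baseline_window = as.integer(baseline_window),
                 pulse_time = pulse_time),
            class = "regional_trace")
}

# Values used for kinetics: calibrated concentrations when available,
# otherwise intensities.
trace_values <- function(trace) {
  if (!is.null(trace$concentration)) trace$concentration else trace$intensity
}

#' Partition a cell mask into anode/middle/cathode row groups
#'
#' The mask is cut into 1-pixel rows parallel to the electrodes (pixels
#' sharing one coordinate along `field_axis`), ordered from the anode end to
#' the cathode end, and split into three contiguous groups of roughly one
#' third of the rows each. With R rows the polar groups each take
#' `floor(R/3)` rows and the middle takes the remainder, keeping the two
#' polar groups equal-sized so the anode-cathode difference statistic is not
#' biased by group size (a typical ~50-row cell partitions 16/18/16).
#'
#' @param roi a [cell_roi()].
#' @param field_axis "x" or "y" (see [image_stack()] conventions).
#' @param anode_side "low" or "high".
#' @return list with integer vectors `anode`, `middle`, `cathode` of
#'   field-axis coordinates (1-based), each ordered anode-to-cathode, plus
#'   `field_axis` carried through for [region_intensity()].
#' @export
partition_rows <- function(roi, field_axis = c("x", "y"),
                           anode_side = c("low", "high")) {
  field_axis <- match.arg(field_axis)
  anode_side <- match.arg(anode_side)
  mask <- roi$mask
  occupied <- if (field_axis == "x") which(colSums(mask) > 0) else which(rowSums(mask) > 0)
  R <- length(occupied)
  if (R < 3) stop("degenerate ROI: need >= 3 rows, got ", R)
  ordered <- if (anode_side == "low") occupied else rev(occupied)
  n_pol <- R %/% 3
  list(anode = ordered[seq_len(n_pol)],
       middle = ordered[seq(n_pol + 1, R - n_pol)],
       cathode = ordered[seq(R - n_pol + 1, R)],
       field_axis = field_axis)
}

#' Regional mean intensities of one frame
#'
#' For each group the reported value is the average over rows of the row's
#' in-mask pixel mean. This is deliberately NOT the pooled pixel mean: rows
#' near the cell edge hold fewer pixels but carry the same weight as rows
#' through the equator.
#'
#' @param frame numeric matrix.
#' @param roi the [cell_roi()] the groups were derived from.
#' @param groups output of [partition_rows()].
#' @return named numeric vector `c(anode=, middle=, cathode=)`.
#' @export
region_intensity <- function(frame, roi, groups) {
  mask <- roi$mask
  row_mean <- function(coord) {
    vals <- if (groups$field_axis == "x") frame[, coord][mask[, coord]]
            else frame[coord, ][mask[coord, ]]
    if (length(vals) == 0) return(NA_real_)
    mean(vals)
  }
  group_mean <- function(coords) {
    m <- vapply(coords, row_mean, 0)
    if (anyNA(m)) {
      warning("empty row(s) excluded from region mean")
      m <- m[!is.na(m)]
    }
    mean(m)
  }
  c(anode = group_mean(groups$anode),
    middle = group_mean(groups$middle),
    cathode = group_mean(groups$cathode))
}

# Otsu threshold on a numeric vector (256-bin histogram).
otsu_threshold <- function(values) {
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(255L, as.integer(255 * (values - rng[1]) / diff(rng))) + 1L, 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256) - 1))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + diff(rng) * (k - 1) / 255
}

# 4-connected component labelling by iterated frontier dilation (vectorized
# flood fill); returns an integer matrix.
label_components <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  nlab <- 0L
  grow <- function(frontier) {
    # one dilation step of the frontier, restricted to unlabeled mask cells
    y <- (frontier - 1L) %% ny + 1L
    x <- (frontier - 1L) %/% ny + 1L
    cand <- c(frontier[y > 1L] - 1L, frontier[y < ny] + 1L,
              frontier[x > 1L] - ny, frontier[x < nx] + ny)
    unique(cand[mask[cand] & lab[cand] == 0L])
  }
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nlab <- nlab + 1L
    frontier <- start
    while (length(frontier)) {
      lab[frontier] <- nlab
      frontier <- grow(frontier)
    }
  }
  lab
}

translate_mask <- function(mask, dy, dx) {
  ny <- nrow(mask); nx <- ncol(mask)
  out <- matrix(FALSE, ny, nx)
  idx <- which(mask, arr.ind = TRUE)
  yy <- idx[, 1] + dy; xx <- idx[, 2] + dx
  ok <- yy >= 1 & yy <= ny & xx >= 1 & xx <= nx
  out[cbind(yy[ok], xx[ok])] <- TRUE
  out
}

#' Track cells across the stack by nearest-centroid linking
#'
#' Initial ROIs are selected on a pre-pulse frame (manually, or from a label
#' mask). On each subsequent frame every cell is re-segmented by Otsu
#' thresholding within a window around its predicted (= previous) centroid,
#' keeping the 4-connected component nearest the prediction. The component
#' is adopted as the new mask only when it stays clear of the search-window
#' border (a component reaching the border is background speckle connected
#' across the window, the signature of a threshold that fell inside the
#' noise) and its area is consistent with the
#' seeded ROI (within `area_tolerance` of the initial area): a cell whose
#' fluorescence is still confined to one pole segments as a too-small blob,
#' and adopting it would erode the mask, so segmentation is treated as
#' failed and the previous mask is carried forward (translated by the
#' predicted — zero — displacement). A
#' centroid jump beyond `max_displacement` pixels flags the frame and also
#' falls back to the carried-forward mask, so tracks cannot swap identities
#' while cells stay well separated.
#'
#' @param stack an [image_stack()].
#' @param initial_rois list of [cell_roi()] on frame 1.
#' @param max_displacement maximum credible per-frame centroid motion, px.
#' @param search_margin half-width added around the previous bounding box
#'   when re-segmenting.
#' @param area_tolerance maximum relative deviation of a segmented
#'   component's area from the initial ROI area for it to be adopted
#'   (default 0.25).
#' @return list of [cell_track()].
#' @export
track_cells <- function(stack, initial_rois, max_displacement = 5,
                        search_margin = NULL, area_tolerance = 0.25) {
  if (is.null(search_margin)) search_margin <- max_displacement + 2
  n_frames <- length(stack$frames)
  lapply(initial_rois, function(roi0) {
    area0 <- sum(roi0$mask)
    rois <- vector("list", n_frames)
    flagged <- logical(n_frames)
    rois[[1]] <- cell_roi(roi0$cell_id, 1L, roi0$mask)
    prev <- rois[[1]]
    for (f in seq(2, length.out = n_frames - 1)) {
      frame <- stack$frames[[f]]
      idx <- which(prev$mask, arr.ind = TRUE)
      y0 <- max(1, min(idx[, 1]) - search_margin)
      y1 <- min(nrow(frame), max(idx[, 1]) + search_margin)
      x0 <- max(1, min(idx[, 2]) - search_margin)
      x1 <- min(ncol(frame), max(idx[, 2]) + search_margin)
      win <- frame[y0:y1, x0:x1, drop = FALSE]
      seg <- NULL
      thr <- otsu_threshold(as.numeric(win))
      binw <- win > thr
      if (any(binw)) {
        lab <- label_components(binw)
        # component whose centroid is nearest the predicted position
        pred <- prev$centroid
        cents <- lapply(seq_len(max(lab)), function(l) {
          ii <- which(lab == l, arr.ind = TRUE)
          c(x = mean(ii[, 2]) + x0 - 1, y = mean(ii[, 1]) + y0 - 1, n = nrow(ii))
        })
        d2 <- vapply(cents, function(cc) (cc["x"] - pred["x"])^2 + (cc["y"] - pred["y"])^2, 0)
        best <- which.min(d2)
        m <- matrix(FALSE, nrow(frame), ncol(frame))
        ii <- which(lab == best, arr.ind = TRUE)
        m[cbind(ii[, 1] + y0 - 1L, ii[, 2] + x0 - 1L)] <- TRUE
        area_ok <- abs(cents[[best]]["n"] / area0 - 1) <= area_tolerance
        # a segmentation that reaches the search-window border is background
        # speckle connected across the window, not a cell
        comp <- lab == best
        touches_border <- any(comp[1, ]) || any(comp[nrow(comp), ]) ||
                          any(comp[, 1]) || any(comp[, ncol(comp)])
        # distinguish a moved intact cell from a partial-cell blob (dye
        # still confined near one pole): motion gains about as many pixels
        # on the leading edge as it loses on the trailing edge, whereas a
        # blob that is a subset of the cell only loses
        lost <- sum(prev$mask & !m)
        gained <- sum(m & !prev$mask)
        covers_prev <- sum(m & prev$mask) / sum(prev$mask) >= 0.95
        if (area_ok && !touches_border && (covers_prev || gained >= 0.5 * lost)) {
          seg <- cell_roi(prev$cell_id, f, m)
        }
      }
      if (is.null(seg)) {
        rois[[f]] <- cell_roi(prev$cell_id, f, prev$mask)
      } else {
        jump <- sqrt(sum((seg$centroid - prev$centroid)^2))
        if (jump > max_displacement) {
          flagged[f] <- TRUE
          rois[[f]] <- cell_roi(prev$cell_id, f, prev$mask)
        } else {
          rois[[f]] <- seg
        }
      }
      prev <- rois[[f]]
    }
    cell_track(roi0$cell_id, rois, flagged)
  })
}

#' Extract anode/middle/cathode traces for tracked cells
#'
#' Per frame: [partition_rows()] then [region_intensity()]; if a calibration
#' curve is given, intensities are converted to concentrations; if
#' `baseline = TRUE`, the per-region mean over all pre-pulse frames (times
#' strictly before `pulse_time`) is subtracted from the reported values, so
#' traces express uptake-driven changes. The raw intensity series is always
#' retained; baseline subtraction is applied after calibration (order only
#' matters through the intercept, which subtraction cancels).
#'
#' @param stack an [image_stack()].
#' @param tracks list of [cell_track()] covering the stack.
#' @param curve optional [calibration_curve()] for the stack's dye.
#' @param baseline subtract the pre-pulse baseline (default TRUE).
#' @return list of [regional_trace()].
#' @export
extract_traces <- function(stack, tracks, curve = NULL, baseline = TRUE) {
  if (!is.null(curve) && nzchar(stack$dye_name) && nzchar(curve$dye_name) &&
      tolower(curve$dye_name) != tolower(stack$dye_name)) {
    stop("calibration dye mismatch: stack is '", stack$dye_name,
         "', curve is '", curve$dye_name, "'")
  }
  times <- stack_times(stack)
  pre <- which(times < stack$pulse_time)
  lapply(tracks, function(track) {
    vals <- t(vapply(seq_along(stack$frames), function(f) {
      roi <- track$rois[[f]]
      groups <- partition_rows(roi, stack$field_axis, stack$anode_side)
      region_intensity(stack$frames[[f]], roi, groups)
    }, c(anode = 0, middle = 0, cathode = 0)))
    intensity <- as.data.frame(vals)
    conc <- NULL
    if (!is.null(curve)) conc <- to_concentration(curve, intensity)
    bw <- 0L
    if (baseline && length(pre) > 0) {
      bw <- length(pre)
      target <- if (is.null(conc)) intensity else conc
      target[] <- lapply(target, function(v) v - mean(v[pre]))
      if (is.null(conc)) intensity <- target else conc <- target
    }
    regional_trace(track$cell_id, times, intensity, conc,
                   baseline_window = bw, pulse_time = stack$pulse_time)
  })
}

#' Savitzky-Golay smoothing
#'
#' Second-order (by default) Savitzky-Golay filter: each point is replaced
#' by the value at that point of a least-squares polynomial fitted to its
#' `window`-point neighbourhood. Edges are handled by fitting the same
#' polynomial on the truncated window, so the output has the input's length
#' and the filter reproduces polynomials up to `order` exactly everywhere.
#'
#' @param values numeric series.
#' @param window odd window length, `3 <= window <= length(values)`.
#' @param order polynomial order (default 2).
#' @return smoothed series, same length.
#' @export
smooth_trace <- function(values, window = 11, order = 2) {
  n <- length(values)
  if (window %% 2 == 0) stop("'window' must be odd, got ", window)
  if (window < 3 || window > n) {
    stop("'window' must lie in [3, length(values)] = [3, ", n, "], got ", window)
  }
  h <- (window - 1) / 2
  # weights w such that fitted(i) = sum(w * y[window]); one set per distinct
  # window geometry (interior + 2h edge shapes)
  weights_for <- function(offsets, at) {
    X <- outer(offsets, 0:order, `^`)
    e <- (at)^(0:order)
    as.numeric(e %*% solve(crossprod(X), t(X)))
  }
  out <- numeric(n)
  interior_w <- weights_for(-h:h, 0)
  for (i in seq_len(n)) {
    lo <- max(1, i - h); hi <- min(n, i + h)
    if (lo == i - h && hi == i + h) {
      out[i] <- sum(interior_w * values[lo:hi])
    } else {
      out[i] <- sum(weights_for((lo:hi) - i, 0) * values[lo:hi])
    }
  }
  out
}
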