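#' Time-lapse fluorescence image stack
#'
#' Container for a single-channel recording plus the acquisition metadata the
#' regional photometry relies on.
#'
#' Coordinate conventions (fixed package-wide): frames are matrices indexed
#' `[y, x]` with 1-based R indices; `field_axis` names the image axis along
#' which the applied electric field runs ("x" = across columns, "y" = down
#' rows); a photometry "row" is the set of in-mask pixels sharing one
#' coordinate along `field_axis`, i.e. rows lie parallel to the electrodes;
#' `anode_side` says which end of `field_axis` ("low" = small indices) faces
#' the anode, so anode-facing rows are those nearest that end.
#'
#' @param frames list of numeric matrices (equal shapes, intensities >= 0).
#' @param frame_interval frame spacing in seconds (> 0).
#' @param pixel_size pixel edge in micrometres.
#' @param field_axis "x" or "y".
#' @param anode_side "low" or "high".
#' @param pulse_time pulse delivery time in seconds from recording start.
#' @param dye_name dye label (free text).
#' @return object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_interval, pixel_size = 0.5,
                        field_axis = c("x", "y"),
                        anode_side = c("low", "high"),
                        pulse_time = 5, dye_name = "") {
  field_axis <- match.arg(field_axis)
  anode_side <- match.arg(anode_side)
  if (is.matrix(frames)) frames <- list(frames)
  if (length(frames) == 0L) stop("'frames' must contain at least one frame")
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L) stop("mixed frame shapes in stack")
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("'frame_interval' must be a positive number of seconds")
  }
  if (min(vapply(frames, min, 0)) < 0) stop("intensities must be >= 0")
  structure(list(frames = frames, frame_interval = frame_interval,
                 pixel_size = pixel_size, field_axis = field_axis,
                 anode_side = anode_side, pulse_time = pulse_time,
                 dye_name = dye_name),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "image_stack: %d frames of %dx%d px, dt = %g s (duration %g s)\n",
    length(x$frames), d[1], d[2], x$frame_interval, stack_duration(x)))
  cat(sprintf("  field axis %s, anode at %s end; pulse at %g s; dye '%s'\n",
              x$field_axis, x$anode_side, x$pulse_time, x$dye_name))
  invisible(x)
}

#' Recording duration in seconds
#'
#' `n_frames * frame_interval`: a 1200-frame stack at 0.1 s and a 600-frame
#' stack at 0.2 s both report 120 s (the standard 2-minute protocol).
#'
#' @param stack an [image_stack()].
#' @return duration in seconds.
#' @export
stack_duration <- function(stack) {
  length(stack$frames) * stack$frame_interval
}

#' Frame times in seconds
#'
#' Frame k (1-based) is stamped at `(k - 1) * frame_interval`, so the pulse
#' at `pulse_time` = 5 s falls on frame 51 at 100 ms sampling.
#'
#' @param stack an [image_stack()].
#' @return numeric vector of frame times.
#' @export
stack_times <- function(stack) {
  (seq_along(stack$frames) - 1) * stack$frame_interval
}

required_meta_keys <- c("frame_interval_s", "pixel_size_um", "field_axis",
                        "anode_side", "pulse_time_s")

read_metadata_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML metadata requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Read an image stack with its metadata sidecar
#'
#' The TIFF holds the frames; the sidecar (JSON, or YAML if the `yaml`
#' package is installed) holds acquisition metadata with required keys
#' `frame_interval_s`, `pixel_size_um`, `field_axis` ("x"/"y"),
#' `anode_side` ("low"/"high") and `pulse_time_s`; optional keys `dye` and
#' `rotation_deg` (a pre-rotation applied with nearest-neighbour resampling
#' for recordings whose electrode axis is not grid-aligned, default 0).
#'
#' @param path TIFF file path.
#' @param metadata_path sidecar path.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, metadata_path) {
  meta <- read_metadata_file(metadata_path)
  missing_keys <- setdiff(required_meta_keys, names(meta))
  if (length(missing_keys) > 0) {
    stop("metadata file ", metadata_path, " is missing required key(s): ",
         paste(missing_keys, collapse = ", "))
  }
  frames <- read_tiff(path)
  rot <- meta$rotation_deg
  if (!is.null(rot) && rot != 0) {
    frames <- lapply(frames, rotate_frame, degrees = rot)
  }
  image_stack(frames,
              frame_interval = as.numeric(meta$frame_interval_s),
              pixel_size = as.numeric(meta$pixel_size_um),
              field_axis = meta$field_axis,
              anode_side = meta$anode_side,
              pulse_time = as.numeric(meta$pulse_time_s),
              dye_name = if (is.null(meta$dye)) "" else meta$dye)
}

#' Write an image stack and its metadata sidecar
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path (16-bit unsigned on disk).
#' @param metadata_path output JSON sidecar path.
#' @param extra named list merged into the sidecar (e.g. seed).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, metadata_path, extra = list()) {
  write_tiff(stack$frames, path, bits = 16)
  meta <- c(list(frame_interval_s = stack$frame_interval,
                 pixel_size_um = stack$pixel_size,
                 field_axis = stack$field_axis,
                 anode_side = stack$anode_side,
                 pulse_time_s = stack$pulse_time,
                 dye = stack$dye_name),
            extra)
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Nearest-neighbour rotation about the frame centre (counter-clockwise,
# degrees). Out-of-source pixels are filled with 0.
rotate_frame <- function(frame, degrees) {
  th <- degrees * pi / 180
  ny <- nrow(frame); nx <- ncol(frame)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  yy <- matrix(seq_len(ny), ny, nx) - cy
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) - cx
  # inverse map: rotate target coordinates by -theta back into the source
  sx <- round(cos(th) * xx + sin(th) * yy + cx)
  sy <- round(-sin(th) * xx + cos(th) * yy + cy)
  ok <- sx >= 1 & sx <= nx & sy >= 1 & sy <= ny
  out <- matrix(0, ny, nx)
  out[ok] <- frame[cbind(sy[ok], sx[ok])]
  out
}

#' Write regional traces to long-format CSV
#'
#' One row per (cell, frame, region) with columns `cell_id`, `time_s`,
#' `region` (anode/middle/cathode), `intensity` and `concentration_uM`
#' (NA when no calibration was applied). Round-trips through
#' [read_traces()] at full double precision.
#'
#' @param traces list of [regional_trace()] objects on a shared time base.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  regions <- c("anode", "middle", "cathode")
  rows <- lapply(traces, function(tr) {
    do.call(rbind, lapply(regions, function(rg) {
      data.frame(cell_id = tr$cell_id,
                 time_s = tr$times,
                 region = rg,
                 intensity = tr$intensity[[rg]],
                 concentration_uM = if (is.null(tr$concentration)) NA_real_
                                    else tr$concentration[[rg]])
    }))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = integer(), time_s = numeric(), region = character(),
               intensity = numeric(), concentration_uM = numeric())
  df <- df[order(df$cell_id, df$time_s, match(df$region, regions)), ]
  utils::write.csv(format_df_full(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# write.csv truncates doubles to 15 significant digits by default; format
# numerics with digits = 17 so the round-trip is exact.
format_df_full <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.double(col)) {
      out <- vapply(col, function(v)
        if (is.na(v)) "NA" else format(v, digits = 17), "")
      out
    } else col
  })
  df
}

#' Read regional traces written by [write_traces()]
#'
#' @param path CSV path.
#' @return list of [regional_trace()] objects.
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(list())
  lapply(split(df, df$cell_id), function(d) {
    wide <- function(col) {
      out <- lapply(c("anode", "middle", "cathode"), function(rg) {
        dd <- d[d$region == rg, ]
        dd[order(dd$time_s), col]
      })
      names(out) <- c("anode", "middle", "cathode")
      as.data.frame(out)
    }
    times <- sort(unique(d$time_s))
    conc <- wide("concentration_uM")
    regional_trace(cell_id = d$cell_id[1], times = times,
                   intensity = wide("intensity"),
                   concentration = if (all(is.na(conc))) NULL else conc)
  })
}
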