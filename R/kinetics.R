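#' Population-mean regional difference trace
#'
#' Per cell, subtracts one regional series from another frame-by-frame, then
#' averages the per-cell differences across cells. Sign convention: a
#' positive `anode_minus_cathode` value means anode-dominant uptake.
#' Calibrated concentrations are used when the traces carry them, raw
#' intensities otherwise.
#'
#' @param traces list of [regional_trace()] on a shared time base.
#' @param kind one of "anode_minus_cathode", "anode_minus_middle",
#'   "cathode_minus_middle".
#' @return object of class `difference_trace` with fields `cell_id`
#'   ("population-mean"), `times`, `delta`, `kind`, `pulse_time`.
#' @export
difference_trace <- function(traces, kind = c("anode_minus_cathode",
                                              "anode_minus_middle",
                                              "cathode_minus_middle")) {
  kind <- match.arg(kind)
  if (length(traces) == 0) stop("need at least one trace")
  times <- traces[[1]]$times
  for (tr in traces) {
    if (length(tr$times) != length(times) || any(tr$times != times)) {
      stop("traces have mismatched time bases")
    }
  }
  parts <- strsplit(kind, "_minus_")[[1]]
  deltas <- vapply(traces, function(tr) {
    v <- trace_values(tr)
    v[[parts[1]]] - v[[parts[2]]]
  }, numeric(length(times)))
  if (is.null(dim(deltas))) deltas <- matrix(deltas, nrow = length(times))
  structure(list(cell_id = "population-mean", times = times,
                 delta = rowMeans(deltas), kind = kind,
                 pulse_time = traces[[1]]$pulse_time),
            class = "difference_trace")
}

#' Fit a decaying exponential to a difference trace
#'
#' Fits `delta(t) = A * exp(-(t - t_start)/tau)` by nonlinear least squares
#' over the window starting at the post-pulse extremum of the trace's
#' dominant sign. The dominant sign is the sign of the post-pulse integral
#' of delta, which makes the fit robust to a brief opposite-sign transient
#' immediately after the pulse (the early anode-side spike of the
#' microsecond regimen is excluded this way). Start values are analytic:
#' `A = delta(t_start)` and tau from the first crossing of `A/e`. When the
#' optimizer fails to converge the fit falls back to log-linear regression
#' on the dominant-sign samples and is marked unconverged.
#'
#' @param trace a [difference_trace()] (or any list with `times`, `delta`).
#' @param pulse_time pulse delivery time in seconds; defaults to the
#'   trace's own `pulse_time`, else 0.
#' @return object of class `decay_fit`: fields `amplitude`, `tau`,
#'   `t_start`, `rss`, `n_points`, `converged`, `method`.
#' @export
fit_decay <- function(trace, pulse_time = NULL) {
  if (is.null(pulse_time)) {
    pulse_time <- if (!is.null(trace$pulse_time) && is.finite(trace$pulse_time))
      trace$pulse_time else 0
  }
  t_all <- trace$times
  y_all <- trace$delta
  post <- t_all >= pulse_time
  if (sum(post) < 3) stop("need >= 3 post-pulse samples to fit")
  t <- t_all[post]; y <- y_all[post]
  if (all(y == 0)) {
    return(structure(list(amplitude = 0, tau = NA_real_, t_start = t[1],
                          rss = 0, n_points = length(t), converged = FALSE,
                          method = "degenerate"),
                     class = "decay_fit"))
  }
  s <- sign(sum(y))
  if (s == 0) s <- sign(y[which.max(abs(y))])
  i0 <- which.max(s * y)
  t0 <- t[i0]
  tw <- t[i0:length(t)]; yw <- y[i0:length(y)]
  if (length(tw) < 3) {
    # extremum sits at the end of the recording: nothing has decayed yet
    return(structure(list(amplitude = yw[1], tau = NA_real_, t_start = t0,
                          rss = NA_real_, n_points = length(tw),
                          converged = FALSE, method = "window-too-short"),
                     class = "decay_fit"))
  }
  A0 <- yw[1]
  below <- which(s * yw <= s * A0 / exp(1))
  tau0 <- if (length(below)) max(tw[below[1]] - t0, diff(range(tw)) / 10)
          else diff(range(tw)) / 3
  fit <- tryCatch(
    stats::nls(yw ~ A * exp(-(tw - t0) / tau),
               start = list(A = A0, tau = tau0),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE),
               algorithm = "port", lower = c(A = -Inf, tau = 1e-9)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    co <- stats::coef(fit)
    out <- list(amplitude = unname(co["A"]), tau = unname(co["tau"]),
                t_start = t0, rss = sum(stats::resid(fit)^2),
                n_points = length(tw), converged = TRUE, method = "nls")
  } else {
    ok <- s * yw > 0
    if (sum(ok) < 3) {
      return(structure(list(amplitude = A0, tau = NA_real_, t_start = t0,
                            rss = NA_real_, n_points = length(tw),
                            converged = FALSE, method = "degenerate"),
                       class = "decay_fit"))
    }
    lf <- stats::lm(log(s * yw[ok]) ~ I(tw[ok] - t0))
    tau_hat <- -1 / stats::coef(lf)[[2]]
    A_hat <- s * exp(stats::coef(lf)[[1]])
    pred <- A_hat * exp(-(tw - t0) / tau_hat)
    out <- list(amplitude = A_hat, tau = tau_hat, t_start = t0,
                rss = sum((yw - pred)^2), n_points = length(tw),
                converged = FALSE, method = "loglinear")
  }
  structure(out, class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "decay_fit: A = %.4g, tau = %.4g s (from t = %.3g s, %d points, %s%s)\n",
    x$amplitude, x$tau, x$t_start, x$n_points, x$method,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Times at which the middle region overtakes the polar regions
#'
#' Computes population-mean `middle - anode` and `middle - cathode` series
#' and reports, for each, the first post-pulse time at which the difference
#' becomes and stays positive for at least `persist` consecutive frames
#' (an anti-chatter rule; single-frame noise crossings do not count).
#'
#' @param traces list of [regional_trace()] on a shared time base.
#' @param pulse_time pulse delivery time; defaults to the traces' own.
#' @param persist required run length of positive frames (default 5).
#' @return named numeric vector `c(anode=, cathode=)` of crossover times in
#'   seconds; `NA` where the middle region never takes over.
#' @export
crossover_times <- function(traces, pulse_time = NULL, persist = 5) {
  if (is.null(pulse_time)) {
    pulse_time <- if (!is.null(traces[[1]]$pulse_time) &&
                      is.finite(traces[[1]]$pulse_time))
      traces[[1]]$pulse_time else 0
  }
  one <- function(region) {
    d <- difference_trace(traces, paste0(region, "_minus_middle"))
    delta <- -d$delta # middle - region
    times <- d$times
    idx <- which(times >= pulse_time)
    pos <- delta[idx] > 0
    run <- 0L
    for (k in seq_along(pos)) {
      run <- if (pos[k]) run + 1L else 0L
      if (run >= persist) return(times[idx[k - persist + 1L]])
    }
    NA_real_
  }
  c(anode = one("anode"), cathode = one("cathode"))
}

#' Write decay fits to CSV
#'
#' @param fits named list of [fit_decay()] results (names = trace kinds).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) {
  df <- do.call(rbind, lapply(names(fits), function(k) {
    f <- fits[[k]]
    data.frame(kind = k, amplitude = f$amplitude, tau = f$tau,
               t_start = f$t_start, rss = f$rss, n_points = f$n_points,
               converged = f$converged, method = f$method)
  }))
  utils::write.csv(format_df_full(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
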