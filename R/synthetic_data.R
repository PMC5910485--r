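#' Dye transport/fluorescence model
#'
#' Physical parameters of a small-molecule uptake indicator as used by the
#' simulator: free intracellular diffusion, optional binding to immobile
#' intracellular sites (nucleic-acid intercalation), and the relative
#' fluorescence yields of the free and bound pools. The intercalating
#' cations (YO-PRO-1, propidium) are nearly dark in solution and bright when
#' bound (`phi_bound >> phi_free`); calcein is natively fluorescent and does
#' not bind (`k_on = 0`).
#'
#' @param name dye label.
#' @param charge net charge (e.g. +2, -4).
#' @param mw molecular weight, Da.
#' @param cross_section cylindrical cross-section diameter, nm.
#' @param D_free free intracellular diffusion coefficient, m^2 s^-1 (> 0).
#' @param k_on binding rate, uM^-1 s^-1 (>= 0).
#' @param k_off unbinding rate, s^-1 (>= 0).
#' @param B_max concentration of binding sites, uM (>= 0).
#' @param phi_free,phi_bound relative fluorescence yields (>= 0).
#' @return object of class `dye_model`.
#' @export
dye_model <- function(name, charge, mw, cross_section, D_free,
                      k_on = 0, k_off = 0, B_max = 0,
                      phi_free = 1, phi_bound = 0) {
  if (D_free <= 0) stop("'D_free' must be positive")
  if (k_on < 0 || k_off < 0 || B_max < 0) stop("rates and B_max must be >= 0")
  if (phi_free < 0 || phi_bound < 0) stop("fluorescence yields must be >= 0")
  structure(list(name = name, charge = charge, mw = mw,
                 cross_section = cross_section, D_free = D_free,
                 k_on = k_on, k_off = k_off, B_max = B_max,
                 phi_free = phi_free, phi_bound = phi_bound),
            class = "dye_model")
}

#' Built-in dye presets
#'
#' Charges, molecular weights and cross-sections follow the bundled
#' [dye_properties()] table. The intracellular `D_free` default
#' (1e-11 m^2 s^-1) sits inside the published intracellular range for small
#' dyes (5e-12 to 1e-10 m^2 s^-1, a mix of compartmentalized and free
#' volume), which makes regional gradients persist for tens
#' of seconds in cells of this size. Binding to immobile intercalation sites
#' retards spread by the factor `1 + k_on * B_max / k_off` (about 4 for
#' YO-PRO-1, about 13 for propidium), reproducing the observed 3-5x slower
#' intracellular migration of propidium; see the methods vignette.
#'
#' @param name "YP1", "Pr" or "calcein".
#' @return a [dye_model()].
#' @export
dye_preset <- function(name) {
  switch(tolower(name),
    "yp1" = , "yo-pro-1" = dye_model("YP1", charge = +2, mw = 375,
      cross_section = 1.1, D_free = 1e-11,
      k_on = 0.006, k_off = 0.1, B_max = 50,
      phi_free = 0.05, phi_bound = 1),
    "pr" = , "propidium" = dye_model("Pr", charge = +2, mw = 414,
      cross_section = 1.4, D_free = 1e-11,
      k_on = 0.008, k_off = 0.1, B_max = 150,
      phi_free = 0.05, phi_bound = 1),
    "calcein" = dye_model("calcein", charge = -4, mw = 622,
      cross_section = 1.2, D_free = 1e-11,
      k_on = 0, k_off = 0, B_max = 0,
      phi_free = 1, phi_bound = 0),
    stop("unknown dye preset: ", name))
}

#' Angular membrane influx profile
#'
#' Influx enters through raised-cosine caps centred on the anode- and
#' cathode-facing poles: the flux density along the membrane is
#' `J(theta, t) = J0 * exp(-(t - onset)/decay_tau) *
#' [af * cap(theta; anode) + (1 - af) * cap(theta; cathode)]` for
#' `t >= onset`, each cap normalized to unit angular integral. An optional
#' anode-only transient term (`transient_J0`, `transient_tau`) models a
#' brief anode-favouring burst superimposed on an otherwise
#' cathode-dominant flux. Membrane resealing is the exponential decay.
#'
#' @param scenario preset name, see [influx_preset()], or "custom".
#' @param J0 flux amplitude, uM um s^-1 per unit boundary length (>= 0).
#' @param anode_fraction share of total influx through the anode pole,
#'   in [0, 1].
#' @param angular_width half-width of each polar cap, radians in (0, pi].
#' @param decay_tau resealing time constant of the flux, s.
#' @param onset pulse delivery time, s.
#' @param transient_J0 amplitude of the anode-only transient (0 = none).
#' @param transient_tau decay time of the transient, s.
#' @return object of class `influx_profile`.
#' @export
influx_profile <- function(scenario = "custom", J0, anode_fraction,
                           angular_width = pi / 3, decay_tau = 20,
                           onset = 5, transient_J0 = 0, transient_tau = 0.5) {
  if (J0 < 0) stop("'J0' must be >= 0")
  if (anode_fraction < 0 || anode_fraction > 1) {
    stop("'anode_fraction' must lie in [0, 1]")
  }
  if (angular_width <= 0 || angular_width > pi) {
    stop("'angular_width' must lie in (0, pi]")
  }
  structure(list(scenario = scenario, J0 = J0,
                 anode_fraction = anode_fraction,
                 angular_width = angular_width, decay_tau = decay_tau,
                 onset = onset, transient_J0 = transient_J0,
                 transient_tau = transient_tau),
            class = "influx_profile")
}

#' Influx scenario presets
#'
#' Four regimens emulating the qualitative entry patterns observed after
#' different pulse exposures (magnitudes are package choices, fixed once;
#' see the methods vignette):
#' \describe{
#'   \item{microsecond_bipolar}{single long (220 us class) pulse: entry at
#'     both poles, cathode-dominant overall (`anode_fraction` 0.35) with a
#'     brief anode-favouring transient right after the pulse.}
#'   \item{nanosecond_multi_anode}{pulse train of 10 ns-class pulses:
#'     strongly anode-dominant (`anode_fraction` 1).}
#'   \item{nanosecond_single_symmetric}{single ns-class pulse: weak, almost
#'     symmetric entry, slightly anode-favouring; full-circle caps
#'     (`angular_width` = pi) so the profile stays formally symmetric in
#'     coverage.}
#'   \item{symmetric_low}{strictly mirror-symmetric low influx
#'     (`anode_fraction` 0.5), the control scenario.}
#' }
#'
#' @param scenario preset name.
#' @param onset pulse delivery time, s (default 5).
#' @return an [influx_profile()].
#' @export
influx_preset <- function(scenario = c("microsecond_bipolar",
                                       "nanosecond_multi_anode",
                                       "nanosecond_single_symmetric",
                                       "symmetric_low"),
                          onset = 5) {
  scenario <- match.arg(scenario)
  switch(scenario,
    microsecond_bipolar = influx_profile(scenario, J0 = 3,
      anode_fraction = 0.35, angular_width = pi / 3, decay_tau = 20,
      onset = onset, transient_J0 = 4.5, transient_tau = 0.5),
    nanosecond_multi_anode = influx_profile(scenario, J0 = 2,
      anode_fraction = 1, angular_width = pi / 3, decay_tau = 20,
      onset = onset),
    nanosecond_single_symmetric = influx_profile(scenario, J0 = 0.3,
      anode_fraction = 0.55, angular_width = pi, decay_tau = 20,
      onset = onset),
    symmetric_low = influx_profile(scenario, J0 = 0.3,
      anode_fraction = 0.5, angular_width = pi / 3, decay_tau = 20,
      onset = onset))
}

#' Simulation configuration
#'
#' The stated acquisition world: a disc-shaped cell of radius 12 um imaged
#' on a square grid at 0.5 um/px, every 100 ms (intercalating dyes) or
#' 200 ms (calcein) for 2 min, pulse delivered 5 s after recording start.
#'
#' @param dye a [dye_model()].
#' @param influx an [influx_profile()].
#' @param cell_radius cell radius, um (default 12).
#' @param grid_n grid side, px (>= 32; the disc must fit with a margin).
#' @param pixel_size pixel edge, um.
#' @param frame_interval frame spacing, s.
#' @param duration recording length, s.
#' @param pulse_time pulse delivery time, s (must precede `duration`; the
#'   influx onset is tied to it).
#' @param extracellular_conc bath concentration, uM (metadata).
#' @param noise_sigma camera noise SD, intensity units.
#' @param field_axis,anode_side rendered-stack orientation conventions.
#' @param seed integer governing all stochastic draws.
#' @param dt optional solver step, s; must satisfy the diffusion stability
#'   bound `dt <= pixel_size^2 / (4 D)`. Default: half the bound, snapped so
#'   an integer number of steps spans one frame.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(dye, influx, cell_radius = 12, grid_n = 64,
                              pixel_size = 0.5, frame_interval = 0.1,
                              duration = 120, pulse_time = 5,
                              extracellular_conc = 2, noise_sigma = 5,
                              field_axis = "x", anode_side = "low",
                              seed = 1, dt = NULL) {
  stopifnot(inherits(dye, "dye_model"), inherits(influx, "influx_profile"))
  if (grid_n < 32) stop("'grid_n' must be >= 32")
  if (frame_interval <= 0) stop("'frame_interval' must be positive")
  if (pulse_time >= duration) stop("'pulse_time' must precede 'duration'")
  if (cell_radius / pixel_size + 1.5 > grid_n / 2) {
    stop("disc of radius ", cell_radius, " um does not fit a ", grid_n,
         "px grid at ", pixel_size, " um/px")
  }
  D_um2 <- dye$D_free * 1e12 # um^2/s
  dt_stab <- pixel_size^2 / (4 * D_um2)
  if (!is.null(dt) && dt > dt_stab) {
    stop("configuration error: dt = ", dt, " violates the stability bound; ",
         "maximum admissible dt is ", signif(dt_stab, 6), " s")
  }
  structure(list(dye = dye, influx = influx, cell_radius = cell_radius,
                 grid_n = grid_n, pixel_size = pixel_size,
                 frame_interval = frame_interval, duration = duration,
                 pulse_time = pulse_time,
                 extracellular_conc = extracellular_conc,
                 noise_sigma = noise_sigma, field_axis = field_axis,
                 anode_side = anode_side, seed = as.integer(seed), dt = dt),
            class = "simulation_config")
}

# Disc mask and geometry shared by the solver and the renderer.
sim_geometry <- function(config) {
  n <- config$grid_n
  c0 <- (n + 1) / 2
  yy <- matrix(seq_len(n), n, n)
  xx <- matrix(seq_len(n), n, n, byrow = TRUE)
  r_px <- config$cell_radius / config$pixel_size
  mask <- (xx - c0)^2 + (yy - c0)^2 <= r_px^2
  cells <- which(mask)
  # membrane cells: in-mask with an out-of-mask 4-neighbour
  idx <- cbind((cells - 1L) %% n + 1L, (cells - 1L) %/% n + 1L) # (y, x)
  inm <- function(y, x) y >= 1 & y <= n & x >= 1 & x <= n & mask[cbind(pmax(pmin(y, n), 1), pmax(pmin(x, n), 1))]
  on_boundary <- !(inm(idx[, 1] - 1, idx[, 2]) & inm(idx[, 1] + 1, idx[, 2]) &
                   inm(idx[, 1], idx[, 2] - 1) & inm(idx[, 1], idx[, 2] + 1))
  # angle of each cell measured from the anode direction
  dx <- idx[, 2] - c0; dy <- idx[, 1] - c0
  along <- if (config$field_axis == "x") dx else dy
  perp <- if (config$field_axis == "x") dy else dx
  if (config$anode_side == "low") along <- -along
  theta <- atan2(perp, along) # 0 = anode pole, pi = cathode pole
  list(mask = mask, cells = cells, idx = idx, on_boundary = on_boundary,
       theta = theta, n = n)
}

# raised-cosine angular cap, unit integral over theta
cap_weight <- function(dtheta, width) {
  d <- abs(((dtheta + pi) %% (2 * pi)) - pi)
  ifelse(d <= width, (1 + cos(pi * d / width)) / (2 * width), 0)
}

#' Simulate dye uptake on a disc-shaped cell
#'
#' Solves the intracellular reaction-diffusion system
#' `dCf/dt = D grad^2 Cf - k_on Cf (B_max - Cb) + k_off Cb`,
#' `dCb/dt = + k_on Cf (B_max - Cb) - k_off Cb`
#' on a pixel-discretized disc with no-flux walls, dye entering through the
#' angular influx profile at the membrane (explicit five-point finite
#' differences, step at half the diffusion stability bound). Mass is
#' conserved exactly: at every frame the spatial integral of `Cf + Cb`
#' equals the cumulative boundary influx.
#'
#' @param config a [simulation_config()].
#' @return object of class `simulation_truth`: the config, the disc mask,
#'   per-frame free/bound concentration matrices (`cf`, `cb`:
#'   n_cells x n_frames, uM), frame `times`, `cumulative_influx` per frame
#'   (uM um^2), and `regional` ground-truth concentrations (the same
#'   thirds-partition photometry applied to the true fields).
#' @export
simulate_uptake <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  geo <- sim_geometry(config)
  n <- geo$n
  # neighbour table restricted to the mask (0-based, -1 = wall)
  pos <- integer(n * n); pos[geo$cells] <- seq_along(geo$cells)
  nbr_of <- function(dy, dx) {
    y <- geo$idx[, 1] + dy; x <- geo$idx[, 2] + dx
    ok <- y >= 1 & y <= n & x >= 1 & x <= n
    lin <- ifelse(ok, (x - 1L) * n + y, 0L)
    out <- ifelse(ok & lin > 0 & geo$mask[pmax(lin, 1)], pos[pmax(lin, 1)] - 1L, -1L)
    as.integer(out)
  }
  nbr <- cbind(nbr_of(-1, 0), nbr_of(1, 0), nbr_of(0, -1), nbr_of(0, 1))

  inf <- config$influx
  # per-term per-cell share of the total influx (sums to 1 per term)
  share <- function(u) {
    tot <- sum(u)
    if (tot <= 0) stop("influx caps miss every membrane pixel; widen 'angular_width'")
    u / tot
  }
  bcells <- geo$on_boundary
  u_main <- numeric(length(geo$cells))
  u_main[bcells] <- inf$anode_fraction * cap_weight(geo$theta[bcells], inf$angular_width) +
    (1 - inf$anode_fraction) * cap_weight(geo$theta[bcells] - pi, inf$angular_width)
  perimeter <- 2 * pi * config$cell_radius # um
  weights <- matrix(share(u_main), ncol = 1)
  amps <- inf$J0 * perimeter # amount rate (uM um^2 / s) at t = onset
  taus <- inf$decay_tau
  if (inf$transient_J0 > 0) {
    u_tr <- numeric(length(geo$cells))
    u_tr[bcells] <- cap_weight(geo$theta[bcells], inf$angular_width)
    weights <- cbind(weights, share(u_tr))
    amps <- c(amps, inf$transient_J0 * perimeter)
    taus <- c(taus, inf$transient_tau)
  }

  D_um2 <- config$dye$D_free * 1e12
  dt_bound <- config$pixel_size^2 / (4 * D_um2)
  rate_scale <- config$dye$k_on * config$dye$B_max + config$dye$k_off
  if (rate_scale > 0) dt_bound <- min(dt_bound, 0.5 / rate_scale)
  dt_target <- if (is.null(config$dt)) 0.5 * dt_bound else config$dt
  steps_per_frame <- max(1L, as.integer(ceiling(config$frame_interval / dt_target)))
  dt <- config$frame_interval / steps_per_frame
  n_frames <- as.integer(round(config$duration / config$frame_interval))

  sol <- solve_uptake_cpp(nbr, weights, amps, taus, inf$onset,
                          D_um2 / config$pixel_size^2, dt, n_frames,
                          steps_per_frame,
                          config$dye$k_on, config$dye$k_off, config$dye$B_max,
                          config$pixel_size^2)
  if (sol$min_cf < -1e-9 * max(sol$cf, 1e-12)) {
    stop("solver error: negative concentrations beyond tolerance (min ",
         signif(sol$min_cf, 4), "); reduce dt or influx amplitude")
  }
  times <- (seq_len(n_frames) - 1) * config$frame_interval
  truth <- structure(list(config = config, mask = geo$mask, cells = geo$cells,
                          cf = sol$cf, cb = sol$cb, times = times,
                          cumulative_influx = as.numeric(sol$influx),
                          dt = dt),
                     class = "simulation_truth")
  truth$regional <- truth_regional(truth)
  truth
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf(
    "simulation_truth: '%s' scenario, dye %s, %d frames (%g s), %d-px grid\n",
    x$config$influx$scenario, x$config$dye$name, length(x$times),
    x$config$duration, x$config$grid_n))
  cat(sprintf("  cumulative influx %.4g uM um^2; solver dt %.4g s\n",
              x$cumulative_influx[length(x$times)], x$dt))
  invisible(x)
}

#' Expand one simulated frame to a full grid matrix
#'
#' @param truth a [simulate_uptake()] result.
#' @param frame 1-based frame index.
#' @param field "free", "bound", "total" or "fluor" (phi-weighted
#'   fluorescence-equivalent concentration).
#' @return numeric matrix (grid_n x grid_n), uM; 0 outside the cell.
#' @export
truth_frame <- function(truth, frame, field = c("free", "bound", "total", "fluor")) {
  field <- match.arg(field)
  dye <- truth$config$dye
  v <- switch(field,
              free = truth$cf[, frame],
              bound = truth$cb[, frame],
              total = truth$cf[, frame] + truth$cb[, frame],
              fluor = dye$phi_free * truth$cf[, frame] +
                      dye$phi_bound * truth$cb[, frame])
  out <- matrix(0, truth$config$grid_n, truth$config$grid_n)
  out[truth$cells] <- v
  out
}

# Regional ground truth: the same anode/middle/cathode row photometry the
# analysis applies to images, evaluated on the true concentration fields.
truth_regional <- function(truth) {
  cfg <- truth$config
  roi <- cell_roi(1L, 1L, truth$mask)
  groups <- partition_rows(roi, cfg$field_axis, cfg$anode_side)
  rows <- lapply(seq_along(truth$times), function(f) {
    tot <- region_intensity(truth_frame(truth, f, "total"), roi, groups)
    flu <- region_intensity(truth_frame(truth, f, "fluor"), roi, groups)
    data.frame(time_s = truth$times[f],
               region = c("anode", "middle", "cathode"),
               conc_total_uM = as.numeric(tot),
               conc_fluor_uM = as.numeric(flu))
  })
  do.call(rbind, rows)
}

#' Render a simulation as a fluorescence image stack
#'
#' Per-pixel intensity is the calibration line applied to the phi-weighted
#' concentration `phi_free * Cf + phi_bound * Cb` (interpreted on the
#' curve's concentration axis), plus Gaussian camera noise of SD
#' `noise_sigma`, clipped at zero. Rendering is deterministic given the
#' config seed: the same truth rendered twice yields bit-identical stacks.
#'
#' @param truth a [simulate_uptake()] result.
#' @param calibration a [calibration_curve()] for the dye.
#' @return an [image_stack()] carrying the config's acquisition metadata.
#' @export
render_stack <- function(truth, calibration) {
  if (missing(calibration) || is.null(calibration)) {
    stop("a calibration curve is required to render intensities")
  }
  stopifnot(inherits(truth, "simulation_truth"),
            inherits(calibration, "calibration_curve"))
  cfg <- truth$config
  if (cfg$noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed + 7L)
  n <- cfg$grid_n
  frames <- lapply(seq_along(truth$times), function(f) {
    img <- calibration_forward(calibration, truth_frame(truth, f, "fluor"))
    if (cfg$noise_sigma > 0) {
      img <- img + matrix(stats::rnorm(n * n, 0, cfg$noise_sigma), n, n)
    }
    img[img < 0] <- 0
    round(img) # quantize to the on-disk 16-bit grid
  })
  image_stack(frames, frame_interval = cfg$frame_interval,
              pixel_size = cfg$pixel_size, field_axis = cfg$field_axis,
              anode_side = cfg$anode_side, pulse_time = cfg$pulse_time,
              dye_name = cfg$dye$name)
}

#' Write simulation ground truth to CSV + JSON
#'
#' The per-frame regional ground-truth concentrations go to CSV; the
#' generating parameters (dye, influx profile, grid, seed) to JSON.
#'
#' @param truth a [simulate_uptake()] result.
#' @param csv_path output CSV path.
#' @param json_path output JSON path.
#' @return `csv_path`, invisibly.
#' @export
write_truth <- function(truth, csv_path, json_path) {
  utils::write.csv(format_df_full(truth$regional), csv_path,
                   row.names = FALSE, quote = FALSE)
  cfg <- truth$config
  params <- list(scenario = cfg$influx$scenario,
                 dye = unclass(cfg$dye), influx = unclass(cfg$influx),
                 cell_radius_um = cfg$cell_radius, grid_n = cfg$grid_n,
                 pixel_size_um = cfg$pixel_size,
                 frame_interval_s = cfg$frame_interval,
                 duration_s = cfg$duration, pulse_time_s = cfg$pulse_time,
                 extracellular_conc_uM = cfg$extracellular_conc,
                 noise_sigma = cfg$noise_sigma, seed = cfg$seed,
                 solver_dt_s = truth$dt)
  jsonlite::write_json(params, json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
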