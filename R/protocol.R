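#' Infusion protocol configuration
#'
#' Defaults reproduce the bench protocol: 15 mL of dye infused over 30 s
#' (Q_Inf = 30 mL/min), a 60 s balloon-holding phase in the balloon case,
#' 10 Hz recording for 180 s starting 10 s before the infusion, heart rate
#' 69 bpm.
#'
#' @param case "balloon" or "no_balloon".
#' @param frame_rate_hz camera rate.
#' @param pre_roll_s recording time before infusion start.
#' @param infusion_duration_s infusion phase length.
#' @param infusion_volume_ml infused dye volume.
#' @param holding_s balloon-holding phase (balloon case only).
#' @param total_recording_s total recorded time.
#' @param heart_rate_bpm heart rate.
#' @param seed master seed; placement, occlusivity and camera noise use
#'   independent substreams derived from it.
#' @return a `protocol_config`.
#' @export
protocol_config <- function(case = c("balloon", "no_balloon"),
                            frame_rate_hz = 10, pre_roll_s = 10,
                            infusion_duration_s = 30, infusion_volume_ml = 15,
                            holding_s = 60, total_recording_s = 180,
                            heart_rate_bpm = 69, seed = 1L) {
  case <- match.arg(case)
  q_inf <- infusion_volume_ml / infusion_duration_s * 60
  if (total_recording_s < pre_roll_s + infusion_duration_s)
    stop("total_recording_s must cover pre-roll plus infusion")
  structure(list(case = case, frame_rate_hz = frame_rate_hz,
                 pre_roll_s = pre_roll_s,
                 infusion_duration_s = infusion_duration_s,
                 infusion_volume_ml = infusion_volume_ml,
                 q_inf_ml_min = q_inf,
                 holding_s = holding_s,
                 total_recording_s = total_recording_s,
                 heart_rate_bpm = heart_rate_bpm,
                 seed = as.integer(seed)),
            class = "protocol_config")
}

#' Physics configuration of the synthetic experiment
#'
#' @param viscosity_mPa_s blood-mimicking fluid viscosity (40% glycerol).
#' @param D_dye_m2_s dye molecular diffusivity (small-molecule order of
#'   magnitude; not a measured constant of the bench dye).
#' @param compliance_fraction oscillatory leaf flow amplitude as a fraction
#'   of the leaf's mean flow (distal RC surrogate); 0 switches the
#'   compliance component off.
#' @param dx_um transport control-volume length.
#' @param semi_perm diffusive permeability of a permeable thrombus segment's
#'   residual lumen.
#' @param residual_lumen_factor hydraulic resistance multiplier of a
#'   permeable thrombus segment.
#' @return a `physics_config`.
#' @export
physics_config <- function(viscosity_mPa_s = 3.4, D_dye_m2_s = 5e-10,
                           compliance_fraction = 0.8, dx_um = 75,
                           semi_perm = 0.3, residual_lumen_factor = 100) {
  list(viscosity_mPa_s = viscosity_mPa_s, D_dye_m2_s = D_dye_m2_s,
       compliance_fraction = compliance_fraction, dx_um = dx_um,
       semi_perm = semi_perm, residual_lumen_factor = residual_lumen_factor)
}

# pulsatile multiplier: flows scale linearly with the driving pressure,
# p(t) = p_mean (1 + a sin(2 pi f t)), a = pulse amplitude / mean
.pulse_fun <- function(boundary) {
  p_mean <- (boundary$systolic_mmHg + 2 * boundary$diastolic_mmHg) / 3
  a <- (boundary$systolic_mmHg - boundary$diastolic_mmHg) / 2 / p_mean
  f <- boundary$heart_rate_bpm / 60
  function(t) 1 + a * sin(2 * pi * f * t)
}

#' Run a full synthetic infusion experiment
#'
#' Executes the protocol timeline against the physics engine and renders the
#' recording plus calibration frames, returning machine-readable ground
#' truth.
#'
#' Balloon case: pulsatile pre-roll; at t = 0 the proximal balloon replaces
#' coronary flow by the controlled infusion (steady chip flow at the tuned
#' 0.6 mL/min, inlet dye concentration 1) for 30 s; the balloon stays
#' inflated for the 60 s holding phase (stagnant flow, dye diffuses); at
#' t = 90 s pulsatile washout resumes. No-balloon case: pulsatile flow
#' throughout; during the infusion the inlet concentration is the infusion
#' diluted by coronary flow, `Q_Inf / (Q_Inf + Q_cor)`, and the chip flow
#' rises proportionally.
#'
#' @param layout a `chip_layout`.
#' @param maps matching `segment_maps`.
#' @param thrombi list of `microthrombus` from [place_microthrombi].
#' @param protocol a [protocol_config].
#' @param physics a [physics_config].
#' @param optics an [optics_config].
#' @param boundary a [flow_boundary]; the mode is set by the protocol phase.
#' @param noise render camera noise (default TRUE).
#' @param compute_truth also classify occlusivity/contact from the true
#'   (noise-free, calibration-free) concentration field (default TRUE).
#' @param cal_levels,cal_reps calibration frame levels and repeats.
#' @param distal_resistance optional pre-calibrated leaf resistance (reuse
#'   across runs to skip re-tuning).
#' @return list with `frames` (frame_stack), `calibration` (frame_stack with
#'   levels), `truth` (ground_truth), `field` (transport_field), `maps`,
#'   `layout`, `protocol`.
#' @export
run_protocol <- function(layout, maps, thrombi, protocol,
                         physics = physics_config(),
                         optics = optics_config(),
                         boundary = flow_boundary(),
                         noise = TRUE, compute_truth = TRUE,
                         cal_levels = c(0, 0.25, 0.5, 0.75, 1),
                         cal_reps = 3,
                         distal_resistance = NULL) {
  grid <- build_transport_grid(layout, dx_um = physics$dx_um)
  if (is.null(distal_resistance))
    distal_resistance <- calibrate_distal_resistance(layout, boundary,
                                                     physics$viscosity_mPa_s)
  occluded <- sort(unique(unlist(lapply(thrombi, function(th)
    th$occupied_segments[th$per_segment_occlusive]))))
  semi_segments <- sort(unique(unlist(lapply(thrombi, function(th)
    th$occupied_segments[!th$per_segment_occlusive]))))
  mult <- NULL
  if (length(semi_segments)) {
    mult <- rep(physics$residual_lumen_factor, length(semi_segments))
    names(mult) <- semi_segments
  }
  state <- solve_flow(layout, occluded_segments = occluded, boundary = boundary,
                      viscosity_mPa_s = physics$viscosity_mPa_s,
                      resistance_multipliers = mult,
                      distal_resistance = distal_resistance)
  perm <- thrombus_face_permeability(grid, thrombi, semi_perm = physics$semi_perm)
  pulse <- .pulse_fun(boundary)
  fr <- protocol$frame_rate_hz
  record_dt <- 1 / fr
  dilution <- boundary$infusion_rate_ml_min /
    (boundary$infusion_rate_ml_min +
       boundary$target_chip_flow_ml_min / boundary$chip_flow_fraction)
  inf_boost <- 1 / dilution   # chip flow gain while infusing into flowing blood

  phases <- if (protocol$case == "balloon") list(
    list(t0 = -protocol$pre_roll_s, dur = protocol$pre_roll_s,
         mult = pulse, osc = function(t) sin(2 * pi * protocol$heart_rate_bpm / 60 * t),
         cin = function(t) rep(0, length(t))),
    list(t0 = 0, dur = protocol$infusion_duration_s,
         mult = function(t) rep(1, length(t)), osc = function(t) rep(0, length(t)),
         cin = function(t) rep(1, length(t))),
    list(t0 = protocol$infusion_duration_s, dur = protocol$holding_s,
         mult = function(t) rep(0, length(t)), osc = function(t) rep(0, length(t)),
         cin = function(t) rep(0, length(t))),
    list(t0 = protocol$infusion_duration_s + protocol$holding_s,
         dur = protocol$total_recording_s - protocol$pre_roll_s -
           protocol$infusion_duration_s - protocol$holding_s,
         mult = pulse, osc = function(t) sin(2 * pi * protocol$heart_rate_bpm / 60 * t),
         cin = function(t) rep(0, length(t)))
  ) else list(
    list(t0 = -protocol$pre_roll_s, dur = protocol$pre_roll_s,
         mult = pulse, osc = function(t) sin(2 * pi * protocol$heart_rate_bpm / 60 * t),
         cin = function(t) rep(0, length(t))),
    list(t0 = 0, dur = protocol$infusion_duration_s,
         mult = function(t) inf_boost * pulse(t),
         osc = function(t) sin(2 * pi * protocol$heart_rate_bpm / 60 * t),
         cin = function(t) rep(dilution, length(t))),
    list(t0 = protocol$infusion_duration_s,
         dur = protocol$total_recording_s - protocol$pre_roll_s -
           protocol$infusion_duration_s,
         mult = pulse, osc = function(t) sin(2 * pi * protocol$heart_rate_bpm / 60 * t),
         cin = function(t) rep(0, length(t)))
  )

  conc <- NULL; times <- NULL; fld <- NULL
  for (ph in phases) {
    if (ph$dur <= 0) next
    fld <- advect_diffuse(layout, state, inlet_concentration = ph$cin,
                          D_dye = physics$D_dye_m2_s, duration = ph$dur,
                          grid = grid, init = fld,
                          flow_multiplier = ph$mult, oscillation = ph$osc,
                          compliance_fraction = physics$compliance_fraction,
                          face_perm = perm, record_dt = record_dt, t0 = ph$t0)
    conc <- rbind(conc, fld$conc)
    times <- c(times, fld$times)
  }
  # frames are taken at the start of each interval: first at -pre_roll
  n_frames <- round(protocol$total_recording_s * fr)
  timestamps <- -protocol$pre_roll_s + (seq_len(n_frames) - 1) / fr
  # recorded rows are at t0 + k*dt (k >= 1); prepend the all-zero initial
  # frame and drop the final record to align on frame starts
  conc <- rbind(rep(0, ncol(conc)), conc)[seq_len(n_frames), , drop = FALSE]
  field <- structure(list(conc = conc, times = timestamps, final = fld$final,
                          mass_in = fld$mass_in, mass_out = fld$mass_out,
                          D_dye = physics$D_dye_m2_s, dt = fld$dt, grid = grid),
                     class = "transport_field")

  seeds <- .substream_seeds(protocol$seed, 4)
  noise_seed <- seeds[3] + (protocol$case == "balloon")
  frames <- render_frames(layout, maps, field, thrombi, optics,
                          timestamps = timestamps, noise = noise,
                          noise_seed = noise_seed)
  calibration <- render_calibration_frames(layout, maps, optics,
                                           levels = cal_levels,
                                           reps = if (noise) cal_reps else 1,
                                           noise = noise, noise_seed = seeds[4])
  truth <- make_ground_truth(layout, maps, thrombi, protocol, field,
                             frame_rate_hz = fr,
                             heart_rate_bpm = protocol$heart_rate_bpm,
                             compute_effective = compute_truth,
                             optics = optics)
  list(frames = frames, calibration = calibration, truth = truth,
       field = field, flow = state, maps = maps, layout = layout,
       protocol = protocol, physics = physics, optics = optics)
}

#' Ground truth of a synthetic experiment
#'
#' Carries two truth layers: the mechanical layer (where each thrombus sits
#' and which of its segments it physically blocks, drawn at placement time)
#' and, when `compute_effective` is set, the effective layer - occlusivity
#' and contact classified from the true concentration field itself, i.e.
#' what an ideal concentration measurement would report. The two differ when
#' another thrombus upstream shadows a region (no dye arrives at all), a
#' perfusion property the concentration-based classification cannot see
#' past.
#'
#' @param layout,maps,thrombi,protocol,field experiment components.
#' @param frame_rate_hz,heart_rate_bpm smoothing parameters of the effective
#'   classification.
#' @param compute_effective classify from the true field (default TRUE).
#' @param optics optional [optics_config]; when given, the effective
#'   classification is restricted to the pixels the camera can actually
#'   calibrate (full-scale response span above the 8% floor), the same
#'   measurable domain the pipeline uses.
#' @return a `ground_truth` object.
#' @export
make_ground_truth <- function(layout, maps, thrombi, protocol, field,
                              frame_rate_hz, heart_rate_bpm,
                              compute_effective = TRUE, optics = NULL) {
  mech_class <- vapply(thrombi, function(th)
    aggregate_occlusivity(th$per_segment_occlusive), "")
  eff <- NULL
  if (compute_effective && length(thrombi)) {
    po <- .pixel_optics(layout, maps)
    conc_px <- field$conc[, .cv_index_vec(field$grid, po$segment, po$station_um),
                          drop = FALSE]
    valid <- if (is.null(optics)) rep(TRUE, ncol(conc_px)) else
      (1 - 10^(-optics$od_full * po$path_factor)) >= 0.08
    conc_px[, !valid] <- NA_real_
    cs <- concentration_stack(conc_px, po$channel_idx, maps$image_shape,
                              field$times, valid = valid)
    eff <- classify_cohort(cs, lapply(thrombi, function(t) t$footprint),
                           lapply(thrombi, function(t) t$occupied_segments),
                           maps, layout,
                           frame_rate_hz = frame_rate_hz,
                           heart_rate_bpm = heart_rate_bpm)
  }
  structure(list(thrombi = thrombi,
                 true_thrombus_occlusivity = mech_class,
                 true_segment_occlusivity = lapply(thrombi, function(th) {
                   stats::setNames(th$per_segment_occlusive,
                                   th$occupied_segments)
                 }),
                 effective = eff,
                 protocol = protocol),
            class = "ground_truth")
}

#' Serialize ground truth as JSON
#'
#' @param truth a `ground_truth`.
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  th <- lapply(truth$thrombi, function(t) list(
    id = t$id, anchor_um = t$anchor_um,
    footprint = t$footprint,
    occupied_segments = t$occupied_segments,
    per_segment_occlusive = t$per_segment_occlusive,
    at_bifurcation = t$at_bifurcation,
    occlusivity_class = t$occlusivity_class))
  obj <- list(format = "mvochip-truth/1", thrombi = th,
              true_thrombus_occlusivity = as.list(truth$true_thrombus_occlusivity),
              effective = truth$effective,
              case = truth$protocol$case, seed = truth$protocol$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
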