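#' Flow boundary conditions for the chip
#'
#' Defaults reproduce the bench protocol: aortic pressure ~52/82 mmHg at
#' 69 bpm, a balloon infusion rate of 30 mL/min and a chip that carries 2% of
#' the flow through the coronary model, i.e. a target chip flow of
#' 0.6 mL/min.
#'
#' @param mode "pulsatile_pressure" or "balloon_infusion".
#' @param systolic_mmHg,diastolic_mmHg aortic pressure.
#' @param heart_rate_bpm heart rate.
#' @param infusion_rate_ml_min controlled infusion rate Q_Inf.
#' @param chip_flow_fraction fraction of coronary flow carried by the chip.
#' @param target_chip_flow_ml_min steady chip flow after distal-resistor
#'   tuning; defaults to `chip_flow_fraction * infusion_rate_ml_min`.
#' @return a `flow_boundary` list.
#' @export
flow_boundary <- function(mode = c("pulsatile_pressure", "balloon_infusion"),
                          systolic_mmHg = 82, diastolic_mmHg = 52,
                          heart_rate_bpm = 69,
                          infusion_rate_ml_min = 30,
                          chip_flow_fraction = 0.02,
                          target_chip_flow_ml_min = chip_flow_fraction * infusion_rate_ml_min) {
  mode <- match.arg(mode)
  if (systolic_mmHg <= 0 || diastolic_mmHg <= 0) stop("pressures must be positive")
  if (chip_flow_fraction <= 0 || chip_flow_fraction >= 1)
    stop("chip_flow_fraction must lie in (0, 1)")
  structure(list(mode = mode,
                 systolic_mmHg = systolic_mmHg,
                 diastolic_mmHg = diastolic_mmHg,
                 heart_rate_bpm = heart_rate_bpm,
                 infusion_rate_ml_min = infusion_rate_ml_min,
                 chip_flow_fraction = chip_flow_fraction,
                 target_chip_flow_ml_min = target_chip_flow_ml_min),
            class = "flow_boundary")
}

# mean driving pressure of the pulse (diastole-weighted, the usual clinical
# mean); also used as the infusion feed pressure so that tuned flows agree
# between modes.
.mean_pressure_pa <- function(boundary) {
  (boundary$systolic_mmHg + 2 * boundary$diastolic_mmHg) / 3 * MMHG_TO_PA
}

# Poiseuille resistance per segment, SI (Pa s / m^3)
.segment_resistance <- function(layout, viscosity_pa_s) {
  tab <- segment_table(layout)
  128 * viscosity_pa_s * (tab$length_um * 1e-6) / (pi * (tab$diameter_um * 1e-6)^4)
}

#' Tune the distal leaf resistors to the target chip flow
#'
#' Emulates the bench tuning step in which the static resistor distal to the
#' chip is successively closed until the unobstructed chip carries the target
#' flow (0.6 mL/min, 2% of the 30 mL/min infusion). A single resistance value
#' shared by all leaves is found by monotone root finding.
#'
#' @param layout a `chip_layout`.
#' @param boundary a `flow_boundary`.
#' @param viscosity_mPa_s working-fluid viscosity (default 3.4, a 40%
#'   glycerol blood-mimicking fluid).
#' @return distal resistance per leaf in Pa s / m^3.
#' @export
calibrate_distal_resistance <- function(layout, boundary = flow_boundary(),
                                        viscosity_mPa_s = 3.4) {
  target <- boundary$target_chip_flow_ml_min / M3S_TO_MLMIN
  f <- function(log10_rd) {
    st <- solve_flow(layout, occluded_segments = integer(0), boundary = boundary,
                     viscosity_mPa_s = viscosity_mPa_s,
                     distal_resistance = 10^log10_rd)
    st$inflow_m3_s / target - 1
  }
  lo <- 6; hi <- 18
  if (f(lo) < 0) stop("target chip flow not reachable: network too resistive")
  root <- uniroot(f, c(lo, hi), tol = 1e-12)
  10^root$root
}

#' Solve lumped Poiseuille flow in the chip network
#'
#' Hydraulic resistance per segment is `128 mu L / (pi d^4)`; each leaf is
#' terminated by a distal resistor (calibrated with
#' [calibrate_distal_resistance] unless supplied). The inlet is held at the
#' mean driving pressure, the distal resistors drain to the reference
#' pressure, and the nodal pressures solve the linear conductance system.
#' Occluded segments have zero conductance; if every path is blocked the
#' result is a zero-flow state, not an error.
#'
#' @param layout a `chip_layout`.
#' @param occluded_segments integer ids treated as fully blocked.
#' @param boundary a `flow_boundary`.
#' @param viscosity_mPa_s working-fluid viscosity in mPa s.
#' @param resistance_multipliers optional named numeric (segment id ->
#'   multiplier), e.g. residual-lumen factors of semipermeable thrombi.
#' @param distal_resistance optional leaf termination resistance (Pa s/m^3);
#'   calibrated on the unobstructed network when missing.
#' @return a `flow_state`: `flows` data.frame (segment, Q_m3_s, Q_ul_min),
#'   node pressures (mmHg), `inflow_m3_s`, `inflow_ml_min`,
#'   `distal_resistance`.
#' @export
solve_flow <- function(layout, occluded_segments = integer(0),
                       boundary = flow_boundary(),
                       viscosity_mPa_s = 3.4,
                       resistance_multipliers = NULL,
                       distal_resistance = NULL) {
  tab <- segment_table(layout)
  n <- nrow(tab)
  if (length(occluded_segments) && !all(occluded_segments %in% tab$id))
    stop("occluded_segments must be segment ids")
  if (is.null(distal_resistance))
    distal_resistance <- calibrate_distal_resistance(layout, boundary, viscosity_mPa_s)

  R <- .segment_resistance(layout, viscosity_mPa_s * 1e-3)
  mult <- rep(1, n)
  if (!is.null(resistance_multipliers)) {
    idx <- match(as.integer(names(resistance_multipliers)), tab$id)
    mult[idx] <- pmax(mult[idx], as.numeric(resistance_multipliers))
  }
  g <- 1 / (R * mult)
  g[tab$id %in% occluded_segments] <- 0

  # one unknown pressure per segment's distal node; the proximal node of a
  # root is the source at the mean driving pressure, leaves drain through the
  # distal resistor to pressure 0
  p_src <- .mean_pressure_pa(boundary)
  A <- matrix(0, n, n); b <- rep(0, n)
  for (i in seq_len(n)) {
    A[i, i] <- A[i, i] + g[i]
    pid <- tab$parent[i]
    if (is.na(pid)) {
      b[i] <- b[i] + g[i] * p_src
    } else {
      j <- which(tab$id == pid)
      A[i, j] <- A[i, j] - g[i]
      A[j, j] <- A[j, j] + g[i]
      A[j, i] <- A[j, i] - g[i]
    }
    if (tab$n_children[i] == 0L) A[i, i] <- A[i, i] + 1 / distal_resistance
  }
  # nodes whose every connection is occluded have an all-zero row: they carry
  # no flow and relax to the reference pressure; solving only the connected
  # subsystem keeps the matrix well conditioned with no regularization leak
  keep <- which(diag(A) > 0)
  p <- rep(0, n)
  sol <- tryCatch(solve(A[keep, keep, drop = FALSE], b[keep]),
                  error = function(e) NULL)
  if (is.null(sol)) {  # every path blocked: report a zero-flow state
    Q <- rep(0, n)
  } else {
    p[keep] <- sol
    p_up <- ifelse(is.na(tab$parent), p_src, p[match(tab$parent, tab$id)])
    Q <- g * (p_up - p)
  }
  inflow <- sum(Q[is.na(tab$parent)])
  structure(list(
    flows = data.frame(segment = tab$id, Q_m3_s = Q, Q_ul_min = Q * M3S_TO_ULMIN),
    node_pressure_mmHg = p / MMHG_TO_PA,
    inflow_m3_s = inflow,
    inflow_ml_min = inflow * M3S_TO_MLMIN,
    distal_resistance = distal_resistance,
    boundary = boundary,
    viscosity_mPa_s = viscosity_mPa_s,
    occluded_segments = as.integer(occluded_segments)
  ), class = "flow_state")
}

#' Nodal mass-conservation residual of a flow state
#'
#' @param layout a `chip_layout`.
#' @param state a `flow_state`.
#' @return maximum relative imbalance (inflow vs. summed outflow) over
#'   interior nodes.
#' @export
flow_conservation_residual <- function(layout, state) {
  tab <- segment_table(layout)
  Q <- state$flows$Q_m3_s
  scale <- max(abs(Q), 1e-300)
  res <- 0
  for (i in seq_len(nrow(tab))) {
    kids <- layout$segments[[as.character(tab$id[i])]]$children
    if (!length(kids)) next
    out <- sum(Q[match(kids, tab$id)])
    res <- max(res, abs(Q[i] - out) / scale)
  }
  res
}
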