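#' Discretize the chip network into 1-D control volumes
#'
#' Each segment is split into control volumes (CVs) of roughly `dx_um` along
#' its centerline. Faces connect consecutive CVs within a segment, the last
#' CV of a parent to the first CV of each child (junction faces, flow-weighted
#' mixing by upwinding), the source to each root (inlet faces) and each leaf
#' to its distal resistor (outlet faces).
#'
#' @param layout a `chip_layout`.
#' @param dx_um target control-volume length (um).
#' @return a `transport_grid`.
#' @export
build_transport_grid <- function(layout, dx_um = 75) {
  tab <- segment_table(layout)
  n_cv_seg <- pmax(2L, as.integer(round(tab$length_um / dx_um)))
  cv_seg <- rep(tab$id, n_cv_seg)
  cv_first <- cumsum(c(1L, head(n_cv_seg, -1)))
  names(cv_first) <- as.character(tab$id)
  dx_seg <- tab$length_um / n_cv_seg * 1e-6             # m
  area_seg <- pi * (tab$diameter_um * 1e-6 / 2)^2       # m^2
  cv_dx <- rep(dx_seg, n_cv_seg)
  cv_area <- rep(area_seg, n_cv_seg)
  cv_vol <- cv_dx * cv_area
  # station of CV centres, um
  cv_station <- unlist(lapply(seq_len(nrow(tab)), function(i) {
    (seq_len(n_cv_seg[i]) - 0.5) * tab$length_um[i] / n_cv_seg[i]
  }))

  from <- integer(0); to <- integer(0); fseg <- integer(0)
  area <- numeric(0); fdx <- numeric(0); ftype <- character(0)
  for (i in seq_len(nrow(tab))) {
    id <- tab$id[i]
    base <- cv_first[as.character(id)]
    k <- n_cv_seg[i]
    if (k > 1) {
      from <- c(from, base + 0:(k - 2)); to <- c(to, base + 1:(k - 1))
      fseg <- c(fseg, rep(id, k - 1))
      area <- c(area, rep(area_seg[i], k - 1)); fdx <- c(fdx, rep(dx_seg[i], k - 1))
      ftype <- c(ftype, rep("internal", k - 1))
    }
    pid <- tab$parent[i]
    if (is.na(pid)) {  # inlet face feeding this root
      from <- c(from, 0L); to <- c(to, base)
      fseg <- c(fseg, id); area <- c(area, area_seg[i]); fdx <- c(fdx, dx_seg[i])
      ftype <- c(ftype, "inlet")
    } else {           # junction face: parent's last CV -> this segment's first CV
      j <- which(tab$id == pid)
      pl <- cv_first[as.character(pid)] + n_cv_seg[j] - 1L
      from <- c(from, pl); to <- c(to, base)
      fseg <- c(fseg, id); area <- c(area, area_seg[i])
      fdx <- c(fdx, (dx_seg[i] + dx_seg[j]) / 2)
      ftype <- c(ftype, "junction")
    }
    if (tab$n_children[i] == 0L) {  # outlet face
      from <- c(from, base + k - 1L); to <- c(to, -1L)
      fseg <- c(fseg, id); area <- c(area, area_seg[i]); fdx <- c(fdx, dx_seg[i])
      ftype <- c(ftype, "outlet")
    }
  }
  structure(list(
    n_cv = length(cv_seg),
    cv_segment = cv_seg, cv_station_um = cv_station,
    cv_volume = cv_vol, cv_dx = cv_dx, cv_area = cv_area,
    face_from = from, face_to = to, face_segment = fseg,
    face_area = area, face_dx = fdx, face_type = ftype,
    segment_first_cv = cv_first, segment_n_cv = n_cv_seg,
    segment_ids = tab$id
  ), class = "transport_grid")
}

# CV index for a (segment, station) pair
.cv_index <- function(grid, segment, station_um) {
  i <- match(segment, grid$segment_ids)
  k <- grid$segment_n_cv[i]
  first <- grid$segment_first_cv[as.character(segment)]
  dx <- grid$cv_dx[first] * 1e6
  idx <- pmin(pmax(floor(station_um / dx), 0), k - 1)
  as.integer(first + idx)
}

# base + oscillatory face flows (m^3/s) from a flow state.
# The oscillatory component models distal RC compliance: each perfused leaf
# draws `compliance_fraction * |Q_leaf|` of zero-mean oscillatory flow at the
# heart rate; by mass conservation on the rigid tree, the oscillatory flow
# through any interior face is the sum over the leaves it feeds. Blocked
# subtrees carry no base flow and hence no compliance flow.
.face_flows <- function(layout, grid, state, compliance_fraction) {
  tab <- segment_table(layout)
  Q <- state$flows$Q_m3_s[match(grid$face_segment, state$flows$segment)]
  leafQ <- state$flows$Q_m3_s
  leafQ[tab$n_children > 0] <- 0
  osc_seg <- vapply(tab$id, function(id) {
    ids <- c(id, distal_subtree(layout, id))
    compliance_fraction * sum(abs(leafQ[match(ids, tab$id)]))
  }, 0)
  Qosc <- osc_seg[match(grid$face_segment, tab$id)]
  list(Q = Q, Qosc = Qosc)
}

#' Advect and diffuse dye through the chip network
#'
#' Finite-volume upwind advection along the centerlines with axial diffusion,
#' explicit in time under a CFL constraint. Flow may be modulated by a
#' pulsatile multiplier and a compliance-driven oscillatory component; fully
#' occlusive thrombus faces carry no flux.
#'
#' @param layout a `chip_layout`.
#' @param flow a `flow_state` from [solve_flow].
#' @param inlet_concentration function of time (s) giving the inlet dye
#'   concentration in `[0, 1]`, or a single number.
#' @param D_dye molecular diffusivity, m^2/s.
#' @param duration simulated time (s).
#' @param dt time step (s); must satisfy the CFL condition (checked).
#' @param grid optional precomputed `transport_grid`.
#' @param init optional initial `transport_field` (or numeric CV vector).
#' @param flow_multiplier function of time scaling all base flows (default 1).
#' @param oscillation function of time in `[-1, 1]` multiplying the
#'   compliance flow component (default 0 = off).
#' @param compliance_fraction oscillatory leaf flow amplitude as a fraction of
#'   the leaf's mean flow.
#' @param face_perm optional numeric permeability per face (1 = open,
#'   0 = blocked); see [thrombus_face_permeability].
#' @param record_dt interval (s) at which concentrations are recorded.
#' @param t0 time of the initial state (s).
#' @return a `transport_field`: `conc` matrix (time x CV, clamped to
#'   `[0, 1]`), `times`, final state, mass bookkeeping, and the grid.
#' @export
advect_diffuse <- function(layout, flow, inlet_concentration, D_dye = 5e-10,
                           duration, dt = NULL, grid = NULL, init = NULL,
                           flow_multiplier = NULL, oscillation = NULL,
                           compliance_fraction = 0.8, face_perm = NULL,
                           record_dt = 0.1, t0 = 0) {
  if (is.null(grid)) grid <- build_transport_grid(layout)
  ff <- .face_flows(layout, grid, flow, compliance_fraction)
  if (is.null(face_perm)) face_perm <- rep(1, length(grid$face_from))

  mf <- if (is.null(flow_multiplier)) function(t) rep(1, length(t)) else flow_multiplier
  of <- if (is.null(oscillation)) function(t) rep(0, length(t)) else oscillation
  cf <- if (is.function(inlet_concentration)) inlet_concentration else {
    cc <- inlet_concentration; function(t) rep(cc, length(t))
  }

  # CFL: worst-case face velocity over the phase
  tprobe <- seq(t0, t0 + duration, length.out = 201)
  mmax <- max(abs(mf(tprobe)))
  omax <- max(abs(of(tprobe)), 0)
  vmax <- max((abs(ff$Q) * mmax + abs(ff$Qosc) * omax) / grid$face_area)
  dx_min <- min(grid$cv_dx)
  dt_cfl <- if (vmax > 0) 0.9 * dx_min / vmax else Inf
  if (is.null(dt)) {
    # choose dt dividing record_dt exactly
    dt <- record_dt / max(1, ceiling(record_dt / min(dt_cfl, record_dt)))
  } else if (dt > dt_cfl + 1e-15) {
    stop("step-size error: dt violates the CFL condition (max ", signif(dt_cfl, 4), " s)")
  }
  nsub <- round(record_dt / dt)
  if (abs(nsub * dt - record_dt) > 1e-9) stop("dt must divide record_dt")
  nrec <- round(duration / record_dt)
  nsteps <- nrec * nsub

  tt <- t0 + (seq_len(nsteps) - 0.5) * dt
  c0 <- if (is.null(init)) rep(0, grid$n_cv)
        else if (inherits(init, "transport_field")) init$final else as.numeric(init)

  out <- advect_network_cpp(c0, grid$cv_volume,
                            grid$face_from - 1L, ifelse(grid$face_to < 0, -2L, grid$face_to - 1L),
                            grid$face_area, grid$face_dx, ff$Q, ff$Qosc,
                            face_perm, D_dye, dt,
                            mf(tt), of(tt), cf(tt),
                            record_every = nsub, record_initial = FALSE,
                            mass_in0 = if (inherits(init, "transport_field")) init$mass_in else 0,
                            mass_out0 = if (inherits(init, "transport_field")) init$mass_out else 0)
  structure(list(conc = out$records,
                 times = t0 + seq_len(nrec) * record_dt,
                 final = out$conc,
                 mass_in = out$mass_in, mass_out = out$mass_out,
                 D_dye = D_dye, dt = dt, grid = grid),
            class = "transport_field")
}

#' Dye mass currently in the network (m^3 of pure dye equivalent)
#'
#' @param field a `transport_field`.
#' @return scalar mass; `mass_in - mass_out` should match it to the scheme's
#'   conservation error.
#' @export
transport_mass <- function(field) {
  sum(field$final * field$grid$cv_volume)
}

#' Face permeabilities encoding thrombus blockages
#'
#' Faces whose both endpoints (or the face between a covered CV and its
#' neighbour) fall inside a thrombus footprint are blocked: permeability 0
#' for an occlusive thrombus segment, `semi_perm` for a permeable
#' (nonocclusive) thrombus segment whose residual lumen still passes dye.
#'
#' @param grid a `transport_grid`.
#' @param thrombi list of `microthrombus` objects.
#' @param semi_perm diffusive permeability of a residual lumen.
#' @return numeric vector, one permeability per grid face.
#' @export
thrombus_face_permeability <- function(grid, thrombi, semi_perm = 0.3) {
  perm <- rep(1, length(grid$face_from))
  if (!length(thrombi)) return(perm)
  covered_occ <- logical(grid$n_cv)
  covered_semi <- logical(grid$n_cv)
  for (th in thrombi) {
    for (k in seq_along(th$occupied_segments)) {
      seg <- th$occupied_segments[k]
      st <- th$segment_station_range[[k]]
      cvs <- .cv_index(grid, seg, seq(st[1], st[2], length.out = 8))
      if (th$per_segment_occlusive[k]) covered_occ[cvs] <- TRUE else covered_semi[cvs] <- TRUE
    }
  }
  touches <- function(cov) {
    a <- grid$face_from; b <- grid$face_to
    fa <- a >= 1 & cov[pmax(a, 1)]
    fb <- b >= 1 & cov[pmax(b, 1)]
    fa | fb
  }
  perm[touches(covered_semi)] <- semi_perm
  perm[touches(covered_occ)] <- 0
  perm
}

#' Export transport snapshots as CSV
#'
#' One row per recorded time and control volume: time_s, segment_id,
#' station_um, concentration. Intended for debugging and external plotting.
#'
#' @param field a `transport_field`.
#' @param path output CSV path.
#' @param times optional subset of recorded times to export.
#' @export
write_transport_csv <- function(field, path, times = field$times) {
  g <- field$grid
  rows <- match(times, field$times)
  if (anyNA(rows)) stop("requested times were not recorded")
  out <- data.frame(
    time_s = rep(times, each = g$n_cv),
    segment_id = rep(g$cv_segment, length(rows)),
    station_um = rep(g$cv_station_um, length(rows)),
    concentration = as.vector(t(field$conc[rows, , drop = FALSE])))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Diffusion penetration depth into a stagnant channel
#'
#' Semi-infinite medium with the boundary held at concentration c0 and an
#' initially clean interior: `c(x, t) = c0 * erfc(x / (2 sqrt(D t)))`. Returns
#' the depth at which the concentration has fallen to `c0 / reduction_factor`,
#' found by monotone bisection of the complementary error function to 1e-6
#' relative tolerance. This is the length scale behind the 16-px (ca. 240 um)
#' annulus radius: the distance over which a 1-min balloon hold can still
#' deliver an appreciable fraction of the boundary concentration.
#'
#' @param D_dye diffusivity, m^2/s.
#' @param t time, s.
#' @param reduction_factor target reduction (>= 1).
#' @return penetration depth in metres.
#' @export
diffusion_penetration <- function(D_dye = 5e-10, t = 60, reduction_factor = 4) {
  if (reduction_factor < 1) stop("reduction_factor must be >= 1")
  if (reduction_factor == 1) return(0)
  erfc <- function(x) 2 * pnorm(-sqrt(2) * x)
  target <- 1 / reduction_factor
  lo <- 0; hi <- 1
  while (erfc(hi) > target) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (erfc(mid) > target) lo <- mid else hi <- mid
    if ((hi - lo) <= 1e-6 * max(hi, 1e-12)) break
  }
  z <- (lo + hi) / 2
  2 * z * sqrt(D_dye * t)
}
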