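rd_cache <- NULL
tuned_state <- function() {
  if (is.null(rd_cache)) {
    lay <- default_layout()
    rd <- calibrate_distal_resistance(lay, flow_boundary())
    rd_cache <<- solve_flow(lay, distal_resistance = rd)
  }
  rd_cache
}

test_that("zero flow and zero diffusivity leave the field unchanged", {
  lay <- default_layout()
  st <- tuned_state()
  grid <- build_transport_grid(lay)
  init <- runif(grid$n_cv)
  f <- advect_diffuse(lay, st, inlet_concentration = 1, D_dye = 0,
                      duration = 2, grid = grid, init = init,
                      flow_multiplier = function(t) rep(0, length(t)),
                      compliance_fraction = 0, record_dt = 0.5)
  expect_equal(f$final, init, tolerance = 1e-12)
})

test_that("plug-flow front arrives at the analytic transit time", {
  lay <- default_layout()
  st <- tuned_state()
  f <- advect_diffuse(lay, st, inlet_concentration = 1, D_dye = 0,
                      duration = 2, compliance_fraction = 0, record_dt = 0.02)
  grid <- f$grid
  rootQ <- st$flows$Q_m3_s[1]
  transit <- sum(grid$cv_volume[grid$cv_segment == 1]) / rootQ
  i_last <- max(which(grid$cv_segment == 1))
  arrival <- f$times[min(which(f$conc[, i_last] > 0.5))]
  expect_lt(abs(arrival - transit), 2 * 0.02 + f$dt)
})

test_that("steady infusion saturates perfused volumes; occluded stay near zero", {
  lay <- default_layout()
  rd <- calibrate_distal_resistance(lay, flow_boundary())
  st <- solve_flow(lay, occluded_segments = 4L, distal_resistance = rd)
  grid <- build_transport_grid(lay)
  perm <- rep(1, length(grid$face_from))
  perm[grid$face_segment == 4] <- 0   # thrombus face at the occluded branch
  f <- advect_diffuse(lay, st, inlet_concentration = 1, D_dye = 5e-10,
                      duration = 60, grid = grid, compliance_fraction = 0,
                      face_perm = perm, record_dt = 1)
  dead <- match(c(4L, distal_subtree(lay, 4L)), grid$segment_ids)
  dead_cv <- which(grid$cv_segment %in% grid$segment_ids[dead])
  live_cv <- setdiff(seq_len(grid$n_cv), dead_cv)
  expect_true(all(f$final[live_cv] > 0.999))
  expect_true(all(f$final[dead_cv] < 0.05))
})

test_that("dye mass is conserved to 1%", {
  lay <- default_layout()
  st <- tuned_state()
  f <- advect_diffuse(lay, st, inlet_concentration = function(t) as.numeric(t < 10),
                      D_dye = 5e-10, duration = 30, record_dt = 0.5)
  resid <- abs(f$mass_in - f$mass_out - transport_mass(f)) / f$mass_in
  expect_lt(resid, 0.01)
})

test_that("explicit steps violating the CFL bound are rejected", {
  lay <- default_layout()
  st <- tuned_state()
  expect_error(advect_diffuse(lay, st, 1, duration = 1, dt = 0.1,
                              record_dt = 0.1),
               "CFL")
})

test_that("halving dt and control-volume length moves front arrival < 5%", {
  lay <- default_layout()
  st <- tuned_state()
  arrival <- function(dx, dt_frac) {
    grid <- build_transport_grid(lay, dx_um = dx)
    f <- advect_diffuse(lay, st, 1, D_dye = 0, duration = 2, grid = grid,
                        compliance_fraction = 0, record_dt = 0.01)
    i7 <- max(which(grid$cv_segment == 2))   # end of an order-7 branch
    f$times[min(which(f$conc[, i7] > 0.5))]
  }
  a1 <- arrival(75); a2 <- arrival(37.5)
  expect_lt(abs(a1 - a2) / a1, 0.05)
})

test_that("transport snapshots export as tidy CSV", {
  lay <- default_layout()
  st <- tuned_state()
  f <- advect_diffuse(lay, st, 1, duration = 1, compliance_fraction = 0,
                      record_dt = 0.5)
  p <- tempfile(fileext = ".csv")
  write_transport_csv(f, p, times = f$times[1])
  tab <- read.csv(p)
  expect_equal(nrow(tab), f$grid$n_cv)
  expect_named(tab, c("time_s", "segment_id", "station_um", "concentration"))
  expect_equal(tab$concentration, unname(f$conc[1, ]))
  expect_error(write_transport_csv(f, p, times = 99), "not recorded")
})

test_that("diffusion penetration solves the erfc profile", {
  expect_equal(diffusion_penetration(5e-10, 60, 1), 0)
  # closed-form oracle: x = 2 erfc^-1(1/4) sqrt(D t), erfc^-1 via qnorm
  z <- -qnorm(0.125) / sqrt(2)
  oracle <- 2 * z * sqrt(5e-10 * 60)
  expect_equal(diffusion_penetration(5e-10, 60, 4), oracle, tolerance = 1e-5)
  expect_equal(oracle, 2.8178e-4, tolerance = 1e-3)
  # strictly increasing in t and D
  ts <- c(10, 30, 60, 120); Ds <- c(1e-10, 5e-10, 2e-9)
  for (D in Ds) expect_true(all(diff(sapply(ts, function(t) diffusion_penetration(D, t, 4))) > 0))
  for (t in ts) expect_true(all(diff(sapply(Ds, function(D) diffusion_penetration(D, t, 4))) > 0))
  expect_error(diffusion_penetration(5e-10, 60, 0.5), "reduction_factor")
})
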