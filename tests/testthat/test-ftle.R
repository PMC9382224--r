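test_that("tracer seeding follows the fencepost refinement rule", {
  # 6 km parent grid, refinement 10 -> 600 m spacing
  f <- gen_analytic_field(flow_spec("uniform", domain = c(0, 60, 0, 60),
                                    grid_spacing = 6, time_span = c(0, 1)))
  tr <- seed_tracers(f, 10)
  expect_equal(diff(tr$lon)[1], 0.6, tolerance = 1e-12)
  # refinement 1: seeds coincide with parent nodes
  tr1 <- seed_tracers(f, 1)
  expect_identical(tr1$lon, f$lon)
  # 10x10-cell parent (11 nodes), refinement 2 -> 21x21 seeds
  f2 <- gen_analytic_field(flow_spec("uniform", domain = c(0, 60, 0, 60),
                                     grid_spacing = 6, time_span = c(0, 1)))
  tr2 <- seed_tracers(f2, 2)
  expect_identical(c(tr2$ny, tr2$nx), c(21L, 21L))
  expect_error(seed_tracers(f, 0), "refinement")
})

test_that("uniform flow displaces all interior tracers by u0 |T| with FTLE 0", {
  f <- gen_analytic_field(flow_spec("uniform", list(u0 = 0.1, v0 = 0),
                                    domain = c(0, 120, 0, 60),
                                    grid_spacing = 6, time_span = c(0, 48)))
  tr <- seed_tracers(f, 2)
  fm <- integrate_flow_map(f, tr, 48, T = -48)
  ok <- fm$state == 0
  # backward integration moves tracers 0.1 m/s * 48 h = 17.28 km upstream
  expect_equal(unname(fm$xf[ok] - fm$x0[ok]),
               rep(-17.28, sum(ok)), tolerance = 1e-6)
  # only tracers within 17.28 km of the upstream edge exit
  expect_true(all(fm$x0[!ok] <= 17.3))
  ff <- compute_ftle_field(fm)
  expect_lt(max(abs(ff$ftle[ff$valid])), 1e-6)
})

test_that("saddle trajectories follow the exponential closed form", {
  a <- 0.5                                     # day^-1
  f <- gen_analytic_field(flow_spec("saddle", list(a = a),
                                    domain = c(-80, 80, -80, 80),
                                    grid_spacing = 8, time_span = c(0, 48)))
  tr <- seed_tracers(f, 1)
  fm <- integrate_flow_map(f, tr, 48, T = -48, rel_tol = 1e-10)
  # backward over T: x(t0-T) = x0 exp(-a*2days), y grows by the same factor
  ok <- fm$state == 0
  expect_gt(sum(ok), 100)
  expect_equal(fm$xf[ok], fm$x0[ok] * exp(-a * 2), tolerance = 1e-6)
  expect_equal(fm$yf[ok], fm$y0[ok] * exp(a * 2), tolerance = 1e-6)
})

test_that("saddle FTLE equals the strain rate within discretization error", {
  f <- gen_analytic_field(flow_spec("saddle", list(a = 0.5),
                                    domain = c(-60, 60, -60, 60),
                                    grid_spacing = 6, time_span = c(0, 48)))
  ff <- compute_ftle(f, 48, horizon = -48, refinement = 3)
  expect_gt(mean(ff$valid), 0.2)
  expect_lt(max(abs(ff$ftle[ff$valid] - 0.5) / 0.5), 0.02)
})

test_that("FTLE is invariant under a uniform translation of the flow", {
  mk <- function(u_extra) {
    sp <- flow_spec("saddle", list(a = 0.5), domain = c(-60, 60, -60, 60),
                    grid_spacing = 6, time_span = c(0, 48))
    f <- gen_analytic_field(sp)
    f$u <- f$u + u_extra
    f
  }
  f0 <- mk(0); f1 <- mk(0.05)
  ff0 <- compute_ftle(f0, 48, horizon = -48, refinement = 2, rel_tol = 1e-9)
  ff1 <- compute_ftle(f1, 48, horizon = -48, refinement = 2, rel_tol = 1e-9)
  both <- ff0$valid & ff1$valid
  expect_gt(mean(both), 0.1)
  expect_lt(max(abs(ff0$ftle[both] - ff1$ftle[both])), 1e-8)
})

test_that("lambda_max via closed-form quadratic matches eigen()", {
  set.seed(3)
  for (k in 1:50) {
    F <- matrix(rnorm(4), 2, 2)
    C <- t(F) %*% F
    a <- C[1, 1]; b <- C[1, 2]; c2 <- C[2, 2]
    lq <- ((a + c2) + sqrt((a - c2)^2 + 4 * b^2)) / 2
    le <- max(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    expect_equal(lq, le, tolerance = 1e-12)
  }
})

test_that("adaptive integration agrees with a 1 s fixed-step oracle", {
  f <- gen_analytic_field(flow_spec("double_gyre", domain = c(0, 2, 0, 1),
                                    grid_spacing = 0.05, time_span = c(0, 4),
                                    time_step = 0.25))
  tr <- seed_tracers(f, 1)
  fm <- integrate_flow_map(f, tr, 4, T = -2, rel_tol = 1e-8, max_step = 0.1)
  ok <- fm$state == 0
  orc <- rk4_double_gyre(fm$x0[ok], fm$y0[ok], 4, 2, nstep = 7200)
  err_km <- sqrt((fm$xf[ok] - orc$x)^2 + (fm$yf[ok] - orc$y)^2)
  expect_lt(max(err_km), 0.010)               # under 10 m per tracer
})

test_that("halving rel_tol converges the FTLE field", {
  f <- gen_analytic_field(flow_spec("double_gyre", domain = c(0, 2, 0, 1),
                                    grid_spacing = 0.1, time_span = c(0, 4),
                                    time_step = 0.5))
  ff <- lapply(c(1e-3, 1e-5, 1e-7), function(rt)
    compute_ftle(f, 4, horizon = -3, refinement = 2, rel_tol = rt))
  d1 <- sqrt(mean((ff[[1]]$ftle - ff[[2]]$ftle)^2, na.rm = TRUE))
  d2 <- sqrt(mean((ff[[2]]$ftle - ff[[3]]$ftle)^2, na.rm = TRUE))
  expect_lt(d2, d1)
})

test_that("hourly series respects the antecedent-coverage rule and stationarity", {
  f <- gen_analytic_field(flow_spec("saddle", list(a = 0.3),
                                    domain = c(-40, 40, -40, 40),
                                    grid_spacing = 8, time_span = c(0, 72)))
  expect_warning(
    ser <- compute_ftle_series(f, hours = c(24, 47, 48, 60, 72),
                               horizon = -48, refinement = 2),
    "skipped")
  expect_identical(attr(ser, "skipped"), c(24, 47))
  expect_length(ser, 3)
  # time-invariant flow: all hourly fields identical
  expect_lt(max(abs(ser[[1]]$ftle - ser[[3]]$ftle), na.rm = TRUE), 1e-9)
})

test_that("double-gyre FTLE fields repeat with the flow's period", {
  f <- gen_analytic_field(flow_spec("double_gyre", domain = c(0, 2, 0, 1),
                                    grid_spacing = 0.1,
                                    time_span = c(0, 24), time_step = 0.5))
  fa <- compute_ftle(f, 10, horizon = -8, refinement = 2, rel_tol = 1e-9)
  fb <- compute_ftle(f, 20, horizon = -8, refinement = 2, rel_tol = 1e-9)   # one period later
  both <- fa$valid & fb$valid
  rms <- sqrt(mean((fa$ftle[both] - fb$ftle[both])^2))
  expect_lt(rms, 1e-6)
})

test_that("FTLE extraction follows the 30 min nearest-cell rule", {
  z <- matrix(seq(0, 1, length.out = 25), 5, 5)
  fA <- ftle_field(10, 1:5, 1:5, z, planar = TRUE)
  fB <- ftle_field(11, 1:5, 1:5, z + 1, planar = TRUE)
  ser <- ftle_series(list(fA, fB))
  # exact cell centre at a field hour
  expect_identical(extract_ftle_at(ser, 3, 2, 10), z[2, 3])
  # 29 min after the hour uses that hour; 31 min from both hours is missing
  expect_identical(extract_ftle_at(ser, 3, 2, 10 + 29 / 60), z[2, 3])
  expect_true(is.na(extract_ftle_at(ser, 3, 2, 9 + 25 / 60)))
  # masked nearest cell falls back to the nearest valid neighbour
  valid <- matrix(TRUE, 5, 5); valid[2, 3] <- FALSE
  fC <- ftle_field(10, 1:5, 1:5, z, valid = valid, planar = TRUE)
  got <- extract_ftle_at(ftle_series(list(fC)), 3, 2, 10)
  expect_true(got %in% c(z[1, 3], z[3, 3], z[2, 2], z[2, 4]))
})

test_that("growing the gap fraction never revalidates a masked FTLE cell", {
  # uniform flow so that gap filling cannot perturb trajectories: validity
  # then depends on the gap mask alone, which is nested across fractions
  # under a common seed
  f <- gen_analytic_field(flow_spec("uniform", list(u0 = 0.05, v0 = 0.03),
                                    domain = c(0, 60, 0, 60),
                                    grid_spacing = 6, time_span = c(0, 12)))
  masks <- lapply(c(0.05, 0.15, 0.3), function(gf) {
    fg <- degrade_field(f, gf, 0, seed = 6)
    compute_ftle(fg, 12, horizon = -6, refinement = 2)$valid
  })
  # valid at a higher gap fraction implies valid at a lower one
  expect_true(all(!masks[[2]] | masks[[1]]))
  expect_true(all(!masks[[3]] | masks[[2]]))
})
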