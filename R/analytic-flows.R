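#' Specify an analytic benchmark flow
#'
#' Three classical velocity fields with known Lagrangian behaviour serve as
#' oracles for the FTLE engine: a uniform flow (zero FTLE), a linear saddle
#' (constant FTLE equal to the strain rate) and the periodically perturbed
#' double gyre (no closed form; validated against dense numerical oracles).
#' Flows are defined on a planar domain in km with time in hours; set
#' `geographic = TRUE` to map the same flow onto a lon/lat grid through a
#' local equirectangular projection so the geographic code paths are
#' exercised with known truth.
#'
#' @param kind `"uniform"`, `"saddle"` or `"double_gyre"`.
#' @param params Named list of flow parameters: uniform takes `u0`, `v0`
#'   (m s^-1); saddle takes the strain rate `a` (day^-1); double_gyre takes
#'   amplitude `A` (km h^-1 scale of the streamfunction), perturbation `eps`
#'   and angular frequency `omega` (rad h^-1).
#' @param domain Bounding box `c(xmin, xmax, ymin, ymax)` in km.
#' @param grid_spacing Grid spacing in km (> 0).
#' @param time_span `c(t_start, t_end)` in hours.
#' @param time_step Frame interval in hours (> 0; hourly by default).
#' @param geographic Map the planar flow onto lon/lat axes?
#' @param origin `c(lon0, lat0)` anchoring the projection when
#'   `geographic = TRUE`.
#' @return A `flow_spec`.
#' @export
flow_spec <- function(kind = c("uniform", "saddle", "double_gyre"),
                      params = list(), domain = c(0, 100, 0, 100),
                      grid_spacing = 6, time_span = c(0, 72), time_step = 1,
                      geographic = FALSE, origin = c(-122, 36)) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) abort(sprintf(
                     "unknown flow kind '%s' (use uniform, saddle or double_gyre)",
                     kind[1])))
  if (grid_spacing <= 0) abort("grid_spacing must be > 0")
  if (time_step <= 0) abort("time step must be > 0")
  if (domain[2] <= domain[1] || domain[4] <= domain[3])
    abort("degenerate domain")
  defaults <- switch(kind,
    uniform = list(u0 = 0.1, v0 = 0),
    saddle = list(a = 0.5),
    double_gyre = list(A = 0.1, eps = 0.25, omega = 2 * pi / 10))
  params <- utils::modifyList(defaults, params)
  structure(list(kind = kind, params = params, domain = domain,
                 grid_spacing = grid_spacing, time_span = time_span,
                 time_step = time_step, geographic = geographic,
                 origin = origin),
            class = "flow_spec")
}

#' Closed-form double-gyre velocity
#'
#' The standard time-periodic double-gyre benchmark: streamfunction
#' `phi = A sin(pi f(x, t)) sin(pi y)` with `f = eps sin(omega t) x^2 +
#' (1 - 2 eps sin(omega t)) x` on the unit-height domain `[0, 2] x [0, 1]`
#' (here in km). Returns velocities in km h^-1; used pointwise both by the
#' field generator and by independent trajectory oracles in the tests.
#'
#' @param x,y Positions (km).
#' @param t Time (hours).
#' @param A,eps,omega Benchmark parameters.
#' @return List with `u` and `v` in km h^-1.
#' @export
double_gyre_velocity <- function(x, y, t, A = 0.1, eps = 0.25,
                                 omega = 2 * pi / 10) {
  at <- eps * sin(omega * t)
  bt <- 1 - 2 * eps * sin(omega * t)
  f <- at * x^2 + bt * x
  dfdx <- 2 * at * x + bt
  list(u = -pi * A * sin(pi * f) * cos(pi * y),
       v = pi * A * cos(pi * f) * sin(pi * y) * dfdx)
}

#' Sample an analytic flow onto a gridded velocity field
#'
#' Evaluates the specified flow at every grid node and frame time;
#' deterministic given the spec. Saddle strain rates are day^-1 and positions
#' km, so the saddle samples `u = a x / 24 / 3.6` m s^-1.
#'
#' @param spec A [flow_spec()].
#' @return A [velocity_field].
#' @export
gen_analytic_field <- function(spec) {
  stopifnot(inherits(spec, "flow_spec"))
  xs <- seq(spec$domain[1], spec$domain[2], by = spec$grid_spacing)
  ys <- seq(spec$domain[3], spec$domain[4], by = spec$grid_spacing)
  ts <- seq(spec$time_span[1], spec$time_span[2], by = spec$time_step)
  nt <- length(ts); ny <- length(ys); nx <- length(xs)
  u <- array(0, c(nt, ny, nx)); v <- array(0, c(nt, ny, nx))
  X <- matrix(rep(xs, each = ny), ny, nx)
  Y <- matrix(rep(ys, times = nx), ny, nx)
  p <- spec$params
  for (k in seq_len(nt)) {
    uv <- switch(spec$kind,
      uniform = list(u = matrix(p$u0 * MS_TO_KMH, ny, nx),
                     v = matrix(p$v0 * MS_TO_KMH, ny, nx)),
      saddle = list(u = (p$a / 24) * X, v = -(p$a / 24) * Y),
      double_gyre = double_gyre_velocity(X, Y, ts[k], p$A, p$eps, p$omega))
    u[k, , ] <- uv$u / MS_TO_KMH          # store m s^-1
    v[k, , ] <- uv$v / MS_TO_KMH
  }
  if (spec$geographic) {
    lat0 <- spec$origin[2]
    lon <- spec$origin[1] + xs / (KM_PER_DEG_LON_EQ * cos(lat0 * pi / 180))
    lat <- lat0 + ys / KM_PER_DEG_LAT
    velocity_field(lon, lat, ts, u, v, planar = FALSE)
  } else {
    velocity_field(xs, ys, ts, u, v, planar = TRUE)
  }
}

#' Degrade a velocity field with gaps and noise
#'
#' Emulates HF-radar dropouts: a fraction of the water samples (uniformly at
#' random over time and space, identical mask for `u` and `v`) is set
#' missing, and independent Gaussian noise is added to the remaining samples.
#' `round(gap_fraction * n_samples)` cells are masked. Reproducible by seed.
#'
#' @param field A [velocity_field].
#' @param gap_fraction Proportion of samples to mask, in `[0, 1)`.
#' @param noise_sd Noise standard deviation in m s^-1.
#' @param seed Integer seed.
#' @return A degraded [velocity_field].
#' @export
degrade_field <- function(field, gap_fraction = 0, noise_sd = 0, seed = 1) {
  if (gap_fraction < 0 || gap_fraction >= 1)
    abort("gap_fraction must be in [0, 1)")
  nt <- length(field$time)
  water <- which(!rep_land(field))
  u <- field$u; v <- field$v
  withr::with_seed(seed, {
    if (gap_fraction > 0) {
      nmask <- round(gap_fraction * length(water))
      idx <- water[sample.int(length(water), nmask)]
      u[idx] <- NA_real_; v[idx] <- NA_real_
    }
    if (noise_sd > 0) {
      keep <- !is.na(u)
      u[keep] <- u[keep] + rnorm(sum(keep), 0, noise_sd)
      keep <- !is.na(v)
      v[keep] <- v[keep] + rnorm(sum(keep), 0, noise_sd)
    }
  })
  velocity_field(field$lon, field$lat, field$time, u, v,
                 land = field$land, planar = field$planar)
}

# land mask replicated over the time dimension, [time, lat, lon]
rep_land <- function(field) {
  nt <- length(field$time)
  aperm(array(rep(field$land, nt),
              c(length(field$lat), length(field$lon), nt)), c(3, 1, 2))
}

#' Analytic FTLE for flows with a closed form
#'
#' The uniform flow has identity flow-map gradient, so FTLE = 0 for any
#' horizon. The linear saddle stretches as `exp(a |T|)` along one axis, so
#' `ln(lambda_max)/2|T| = a` for any horizon and either time direction.
#' The double gyre has no closed form; request a dense numerical oracle
#' instead.
#'
#' @param spec A [flow_spec()] of kind uniform or saddle.
#' @param T Horizon in hours (unused; FTLE is horizon-free for these flows).
#' @return FTLE in day^-1 (scalar).
#' @export
true_ftle_analytic <- function(spec, T = -48) {
  stopifnot(inherits(spec, "flow_spec"))
  switch(spec$kind,
    uniform = 0,
    saddle = spec$params$a,
    abort("no closed-form FTLE for the double gyre; use a dense numerical oracle"))
}
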