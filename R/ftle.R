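#' Seed a refined tracer grid over a velocity field
#'
#' Tracers are seeded on a regular grid at `refinement` times the spatial
#' resolution of the surface-current grid (default 10, i.e. 600 m seeds on a
#' 6 km current grid). The refined grid spans the same hull as the parent grid
#' with a fencepost rule: a parent grid of `n` nodes yields
#' `(n - 1) * refinement + 1` seeds per axis. Seeds whose nearest parent node
#' is land are flagged invalid.
#'
#' @param field A [velocity_field].
#' @param refinement Integer >= 1; seed spacing = parent spacing / refinement.
#' @return A `tracer_grid`: refined axes (native units and km), seed validity.
#' @export
seed_tracers <- function(field, refinement = 10) {
  if (!is.numeric(refinement) || length(refinement) != 1 || refinement < 1)
    abort("refinement must be a single integer >= 1")
  refinement <- as.integer(refinement)
  nx <- (length(field$lon) - 1L) * refinement + 1L
  ny <- (length(field$lat) - 1L) * refinement + 1L
  lon <- seq(field$lon[1], field$lon[length(field$lon)], length.out = nx)
  lat <- seq(field$lat[1], field$lat[length(field$lat)], length.out = ny)
  ax <- axes_km(field)
  x <- ax$to_x(lon); y <- ax$to_y(lat)
  ip <- round(seq(1, length(field$lon), length.out = nx))
  jp <- round(seq(1, length(field$lat), length.out = ny))
  valid <- !field$land[jp, ip, drop = FALSE]           # [ny, nx]
  structure(list(lon = lon, lat = lat, x = x, y = y,
                 nx = nx, ny = ny, valid = valid,
                 refinement = refinement, planar = field$planar),
            class = "tracer_grid")
}

# Fehlberg 4(5) tableau
RKF_A <- list(
  c(1 / 4),
  c(3 / 32, 9 / 32),
  c(1932 / 2197, -7200 / 2197, 7296 / 2197),
  c(439 / 216, -8, 3680 / 513, -845 / 4104),
  c(-8 / 27, 2, -3544 / 2565, 1859 / 4104, -11 / 40)
)
RKF_C <- c(0, 1 / 4, 3 / 8, 12 / 13, 1, 1 / 2)
RKF_B5 <- c(16 / 135, 0, 6656 / 12825, 28561 / 56430, -9 / 50, 2 / 55)
RKF_B4 <- c(25 / 216, 0, 1408 / 2565, 2197 / 4104, -1 / 5, 0)

#' Advect tracers through a velocity field (adaptive RKF4(5))
#'
#' Integrates every tracer from `t0` over the signed horizon `T` (negative for
#' backward-in-time FTLE) with adaptive fourth/fifth-order
#' Runge--Kutta--Fehlberg stepping under the [velocity_at()] interpolation
#' contract. One common step size is shared by all live tracers and controlled
#' by the worst per-tracer error estimate; sharing the step sequence makes the
#' numerical flow-map gradient exactly invariant to a uniform translation of
#' the flow. Tracers that leave the grid hull are frozen at exit and flagged;
#' tracers that reach an unrestorable data gap freeze likewise.
#'
#' @param field A [velocity_field].
#' @param tracers A tracer grid from [seed_tracers()].
#' @param t0 Analysis time (hours).
#' @param T Signed integration horizon in hours (default -48).
#' @param rel_tol Relative error tolerance per step (default 1e-6).
#' @param max_step Largest step magnitude in hours (default 0.5).
#' @return A `flow_map` with initial/final km positions, exit flags and
#'   integration statistics.
#' @export
integrate_flow_map <- function(field, tracers, t0, T = -48, rel_tol = 1e-6,
                               max_step = 0.5) {
  if (T == 0) abort("integration horizon T must be non-zero")
  t1 <- t0 + T
  tmin <- min(field$time); tmax <- max(field$time)
  if (t1 < tmin - 1e-9 || t1 > tmax + 1e-9 || t0 < tmin - 1e-9 || t0 > tmax + 1e-9)
    abort(sprintf(
      "integration window [%g, %g] h not covered by field span [%g, %g] h (shortfall %g h)",
      min(t0, t1), max(t0, t1), tmin, tmax,
      max(tmin - min(t0, t1), max(t0, t1) - tmax)))
  ctx <- prepare_advection(field)
  X0 <- rep(tracers$x, each = tracers$ny)   # column-major [ny, nx]
  Y0 <- rep(tracers$y, times = tracers$nx)
  n <- length(X0)
  X <- X0; Y <- Y0
  state <- integer(n)                        # 0 ok, 1 exit, 2 gap
  state[!as.vector(tracers$valid)] <- 1L
  live <- state == 0L
  dir <- sign(T)
  h <- dir * min(max_step, abs(T))
  # time is accumulated relative to t0 so the step sequence (and hence the
  # numerical flow map) is invariant to translating the analysis hour
  s <- 0
  naccept <- 0L; nreject <- 0L
  abs_tol <- 1e-7                            # km
  xr <- range(ctx$xs); yr <- range(ctx$ys)
  while (dir * (T - s) > 1e-10 && any(live)) {
    if (dir * (s + h - T) > 0) h <- T - s
    idx <- which(live)
    xs <- X[idx]; ys <- Y[idx]
    k1 <- ctx_velocity(ctx, xs, ys, t0 + s)
    bad <- k1$freeze | k1$oob
    Ku <- matrix(0, length(idx), 6); Kv <- matrix(0, length(idx), 6)
    Ku[, 1] <- k1$u; Kv[, 1] <- k1$v
    for (st in 2:6) {
      au <- RKF_A[[st - 1]]
      dx <- as.vector(Ku[, seq_along(au), drop = FALSE] %*% au)
      dy <- as.vector(Kv[, seq_along(au), drop = FALSE] %*% au)
      ks <- ctx_velocity(ctx, xs + h * dx, ys + h * dy, t0 + s + RKF_C[st] * h)
      bad <- bad | ks$freeze | ks$oob
      ku <- ks$u; kv <- ks$v
      ku[is.na(ku)] <- 0; kv[is.na(kv)] <- 0
      Ku[, st] <- ku; Kv[, st] <- kv
    }
    x5 <- xs + h * as.vector(Ku %*% RKF_B5)
    y5 <- ys + h * as.vector(Kv %*% RKF_B5)
    ex <- h * as.vector(Ku %*% (RKF_B5 - RKF_B4))
    ey <- h * as.vector(Kv %*% (RKF_B5 - RKF_B4))
    err <- sqrt(ex^2 + ey^2)
    tol <- abs_tol + rel_tol * pmax(abs(xs), abs(ys), 1)
    ratio <- err / tol
    ratio[bad] <- 0                          # frozen this step, not an error
    emax <- max(ratio, 0)
    if (emax <= 1 || abs(h) <= 1e-6) {
      # freeze tracers that touched a gap or left the hull during the step
      if (any(bad)) {
        gap_hit <- bad & !(k1$oob)
        state[idx[bad]] <- ifelse(gap_hit[bad], 2L, 1L)
        live[idx[bad]] <- FALSE
      }
      ok <- !bad
      X[idx[ok]] <- x5[ok]; Y[idx[ok]] <- y5[ok]
      s <- s + h
      naccept <- naccept + 1L
      out <- live & (X < xr[1] | X > xr[2] | Y < yr[1] | Y > yr[2])
      if (any(out)) {
        X[out] <- pmin(pmax(X[out], xr[1]), xr[2])
        Y[out] <- pmin(pmax(Y[out], yr[1]), yr[2])
        state[out] <- 1L
        live[out] <- FALSE
      }
    } else {
      nreject <- nreject + 1L
    }
    fac <- if (emax > 0) 0.9 * emax^(-0.2) else 4
    h <- dir * min(max_step, abs(h) * min(4, max(0.2, fac)))
    # quantize the step so last-ulp noise in the error estimate cannot
    # perturb the step sequence (keeps integration invariant to shifting
    # the analysis hour over a time-periodic field)
    h <- dir * max(2^-20, round(abs(h) * 2^20) / 2^20)
  }
  structure(list(x0 = X0, y0 = Y0, xf = X, yf = Y, state = state,
                 nx = tracers$nx, ny = tracers$ny,
                 lon = tracers$lon, lat = tracers$lat,
                 x = tracers$x, y = tracers$y,
                 t0 = t0, T = T, planar = tracers$planar,
                 naccept = naccept, nreject = nreject),
            class = "flow_map")
}

#' Compute an FTLE field from an advected flow map
#'
#' The spatial gradient of the flow map is taken by central differences over
#' the four grid neighbours of each seed (one-sided at the refined-grid edges,
#' flagged lower-confidence but kept). The Cauchy--Green tensor
#' `C = t(F) %*% F` is formed from the 2x2 gradient `F` and the FTLE is
#' `log(lambda_max(C)) / (2 |T|)`, reported in day^-1. Any cell whose own
#' tracer or any neighbour used in the stencil exited the domain or froze in a
#' gap is masked invalid; invalid cells never leak NaN into valid ones.
#'
#' @param flowmap A flow map from [integrate_flow_map()].
#' @param T Signed horizon in hours; defaults to the flow map's own.
#' @return An [ftle_field()].
#' @export
compute_ftle_field <- function(flowmap, T = flowmap$T) {
  nx <- flowmap$nx; ny <- flowmap$ny
  XF <- matrix(flowmap$xf, ny, nx); YF <- matrix(flowmap$yf, ny, nx)
  okm <- matrix(flowmap$state == 0L, ny, nx)
  dx <- diff(flowmap$x); dy <- diff(flowmap$y)
  jm <- c(1L, seq_len(nx - 1L)); jp <- c(2:nx, nx)      # one-sided at edges
  im <- c(1L, seq_len(ny - 1L)); ip <- c(2:ny, ny)
  denx <- matrix(rep(flowmap$x[jp] - flowmap$x[jm], each = ny), ny, nx)
  deny <- matrix(rep(flowmap$y[ip] - flowmap$y[im], times = nx), ny, nx)
  dXdx <- (XF[, jp] - XF[, jm]) / denx
  dYdx <- (YF[, jp] - YF[, jm]) / denx
  dXdy <- (XF[ip, ] - XF[im, ]) / deny
  dYdy <- (YF[ip, ] - YF[im, ]) / deny
  valid <- okm & okm[, jm] & okm[, jp] & okm[im, ] & okm[ip, ]
  a <- dXdx^2 + dYdx^2
  b <- dXdx * dXdy + dYdx * dYdy
  c2 <- dXdy^2 + dYdy^2
  lmax <- ((a + c2) + sqrt(pmax((a - c2)^2 + 4 * b^2, 0))) / 2
  Tdays <- abs(T) / 24
  ftle <- matrix(NA_real_, ny, nx)
  pos <- valid & is.finite(lmax) & lmax > 0
  ftle[pos] <- log(lmax[pos]) / (2 * Tdays)
  valid <- valid & is.finite(ftle)
  edge <- matrix(FALSE, ny, nx)
  edge[c(1, ny), ] <- TRUE; edge[, c(1, nx)] <- TRUE
  ftle_field(time = flowmap$t0, lon = flowmap$lon, lat = flowmap$lat,
             ftle = ftle, valid = valid, horizon = T,
             planar = flowmap$planar, edge = edge)
}

#' Construct an FTLE scalar field
#'
#' Container for one hourly FTLE grid in day^-1 at tracer (refined)
#' resolution. Usually produced by [compute_ftle()]; the constructor is
#' exported so synthetic FTLE series with controlled space-time structure can
#' be built directly for testing downstream statistics.
#'
#' @param time Analysis hour (numeric hours).
#' @param lon,lat Grid axes (degrees, or km when `planar = TRUE`).
#' @param ftle Matrix `length(lat) x length(lon)` of FTLE values (day^-1).
#' @param valid Logical matrix of the same shape; `FALSE` cells are masked.
#' @param horizon Signed integration horizon in hours (default -48).
#' @param planar Planar (km) or geographic axes.
#' @param edge Logical matrix flagging lower-confidence one-sided-gradient
#'   cells; defaults to the outer rim.
#' @return An object of class `ftle_field`.
#' @export
ftle_field <- function(time, lon, lat, ftle, valid = is.finite(ftle),
                       horizon = -48, planar = FALSE, edge = NULL) {
  ftle <- as.matrix(ftle)
  if (!all(dim(ftle) == c(length(lat), length(lon))))
    abort("ftle must be a length(lat) x length(lon) matrix")
  if (is.null(edge)) {
    edge <- matrix(FALSE, nrow(ftle), ncol(ftle))
    edge[c(1, nrow(ftle)), ] <- TRUE; edge[, c(1, ncol(ftle))] <- TRUE
  }
  if (any(!is.finite(ftle[valid])))
    abort("valid cells must hold finite FTLE values")
  structure(list(time = as.numeric(time), lon = as.numeric(lon),
                 lat = as.numeric(lat), ftle = ftle,
                 valid = valid & is.finite(ftle), horizon = horizon,
                 planar = isTRUE(planar), edge = edge),
            class = "ftle_field")
}

#' @export
print.ftle_field <- function(x, ...) {
  cat(sprintf("<ftle_field> t = %g h, %d x %d, horizon %g h, %.1f%% valid, range [%.3g, %.3g] day^-1\n",
              x$time, length(x$lat), length(x$lon), x$horizon,
              100 * mean(x$valid),
              suppressWarnings(min(x$ftle[x$valid])),
              suppressWarnings(max(x$ftle[x$valid]))))
  invisible(x)
}

#' @describeIn ftle_field Long-format view (one row per grid cell).
#' @param x An `ftle_field`.
#' @param ... Unused.
#' @method as_tibble ftle_field
#' @export
as_tibble.ftle_field <- function(x, ...) {
  g <- expand.grid(lat = x$lat, lon = x$lon, KEEP.OUT.ATTRS = FALSE)
  tibble(time = x$time, lat = g$lat, lon = g$lon,
         ftle = as.vector(x$ftle), valid = as.vector(x$valid),
         edge = as.vector(x$edge))
}

#' One-call FTLE computation at a single analysis hour
#'
#' Seeds tracers, integrates the flow map backward (or forward) over the
#' horizon and differentiates it. See [seed_tracers()],
#' [integrate_flow_map()] and [compute_ftle_field()] for the stages.
#'
#' @inheritParams integrate_flow_map
#' @inheritParams seed_tracers
#' @param horizon Signed horizon in hours (default -48, i.e. backward FTLE).
#' @return An [ftle_field()].
#' @export
compute_ftle <- function(field, t0, horizon = -48, refinement = 10,
                         rel_tol = 1e-6, max_step = 0.5) {
  tr <- seed_tracers(field, refinement)
  fm <- integrate_flow_map(field, tr, t0, T = horizon, rel_tol = rel_tol,
                           max_step = max_step)
  compute_ftle_field(fm)
}

#' Hourly FTLE series
#'
#' One backward-in-time FTLE field per requested analysis hour. Hours without
#' the full antecedent coverage (e.g. the first 48 h of a field with a -48 h
#' horizon) are skipped with a warning and listed in the `skipped` attribute.
#'
#' @inheritParams compute_ftle
#' @param hours Analysis hours to compute.
#' @return An `ftle_series` (list of [ftle_field()]s) with attribute
#'   `skipped`.
#' @export
compute_ftle_series <- function(field, hours, horizon = -48, refinement = 10,
                                rel_tol = 1e-6, max_step = 0.5) {
  tmin <- min(field$time); tmax <- max(field$time)
  ok <- (hours + pmin(horizon, 0)) >= tmin - 1e-9 &
    (hours + pmax(horizon, 0)) <= tmax + 1e-9
  if (any(!ok))
    warn(sprintf("%d hour(s) skipped for insufficient antecedent coverage: %s",
                 sum(!ok), paste(utils::head(hours[!ok], 10), collapse = ", ")))
  fields <- lapply(hours[ok], function(h)
    compute_ftle(field, h, horizon = horizon, refinement = refinement,
                 rel_tol = rel_tol, max_step = max_step))
  ftle_series(fields, skipped = hours[!ok])
}

#' Bundle FTLE fields into a series
#'
#' @param fields List of [ftle_field()] objects (any order; sorted by time).
#' @param skipped Hours that could not be computed (manifest).
#' @return An `ftle_series`.
#' @export
ftle_series <- function(fields, skipped = numeric(0)) {
  stopifnot(all(vapply(fields, inherits, TRUE, "ftle_field")))
  times <- vapply(fields, `[[`, numeric(1), "time")
  structure(fields[order(times)], class = "ftle_series", skipped = skipped)
}

#' @export
print.ftle_series <- function(x, ...) {
  times <- vapply(x, `[[`, numeric(1), "time")
  cat(sprintf("<ftle_series> %d fields, t = %g..%g h (%d skipped)\n",
              length(x), min(times), max(times),
              length(attr(x, "skipped"))))
  invisible(x)
}

#' Extract FTLE at points and times (nearest cell, 30 min rule)
#'
#' Matches each query to the temporally nearest FTLE field; if no field lies
#' within `max_dt` hours (default 0.5, i.e. 30 min) the value is missing.
#' Spatially the value of the nearest valid grid cell is returned, searching
#' outward up to `max_cells` rings when the nearest cell itself is masked.
#' Missing is a value here, never an error.
#'
#' @param series An `ftle_series`.
#' @param lon,lat Query positions (units of the series' grids).
#' @param t Query times (hours), recycled.
#' @param max_dt Temporal matching tolerance in hours (default 0.5).
#' @param max_cells Maximum ring radius for the nearest-valid-cell search.
#' @return Numeric vector of FTLE values (day^-1) with `NA` for missing.
#' @export
extract_ftle_at <- function(series, lon, lat, t, max_dt = 0.5, max_cells = 5) {
  if (length(series) == 0) abort("empty ftle_series")
  nq <- max(length(lon), length(lat), length(t))
  lon <- rep_len(lon, nq); lat <- rep_len(lat, nq); t <- rep_len(t, nq)
  times <- vapply(series, `[[`, numeric(1), "time")
  out <- rep(NA_real_, nq)
  for (q in seq_len(nq)) {
    if (is.na(lon[q]) || is.na(lat[q]) || is.na(t[q])) next
    k <- which.min(abs(times - t[q]))
    if (abs(times[k] - t[q]) > max_dt + 1e-9) next
    f <- series[[k]]
    i <- which.min(abs(f$lat - lat[q]))
    j <- which.min(abs(f$lon - lon[q]))
    if (isTRUE(f$valid[i, j])) { out[q] <- f$ftle[i, j]; next }
    ny <- length(f$lat); nx <- length(f$lon)
    for (r in seq_len(max_cells)) {
      ii <- max(1, i - r):min(ny, i + r)
      jj <- max(1, j - r):min(nx, j + r)
      sub <- f$valid[ii, jj, drop = FALSE]
      if (any(sub)) {
        w <- which(sub, arr.ind = TRUE)
        d2 <- (f$lat[ii[w[, 1]]] - lat[q])^2 + (f$lon[jj[w[, 2]]] - lon[q])^2
        b <- which.min(d2)
        out[q] <- f$ftle[ii[w[b, 1]], jj[w[b, 2]]]
        break
      }
    }
  }
  out
}

#' Write an FTLE series to CSV long format
#'
#' Columns `time, lat, lon, ftle, valid`; units day^-1.
#'
#' @param series An `ftle_series`.
#' @param path Output path.
#' @export
write_ftle_csv <- function(series, path) {
  d <- dplyr::bind_rows(lapply(series, as_tibble))
  utils::write.csv(d[, c("time", "lat", "lon", "ftle", "valid")], path,
                   row.names = FALSE)
  invisible(path)
}
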