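# Velocity lookup used by both the public interpolation API and the tracer
# advection loop. All advection arithmetic happens in a local equirectangular
# tangent plane (km); planar benchmark fields skip the projection.

MS_TO_KMH <- 3.6
KM_PER_DEG_LAT <- 110.574
KM_PER_DEG_LON_EQ <- 111.320

axes_km <- function(field) {
  if (field$planar) {
    list(xs = field$lon, ys = field$lat,
         to_x = function(lon) lon, to_y = function(lat) lat,
         from_x = function(x) x, from_y = function(y) y)
  } else {
    lat0 <- mean(range(field$lat))
    lon0 <- field$lon[1]
    lat1 <- field$lat[1]
    kx <- KM_PER_DEG_LON_EQ * cos(lat0 * pi / 180)
    ky <- KM_PER_DEG_LAT
    list(xs = (field$lon - lon0) * kx, ys = (field$lat - lat1) * ky,
         to_x = function(lon) (lon - lon0) * kx,
         to_y = function(lat) (lat - lat1) * ky,
         from_x = function(x) x / kx + lon0,
         from_y = function(y) y / ky + lat1)
  }
}

shift_mat <- function(m, dy, dx) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(NA, ny, nx)
  ys <- seq_len(ny) - dy; xs <- seq_len(nx) - dx
  oky <- ys >= 1 & ys <= ny; okx <- xs >= 1 & xs <= nx
  out[oky, okx] <- m[ys[oky], xs[okx]]
  out
}

# Fill gap (NA) water nodes from the nearest valid neighbour within one parent
# cell (orthogonal neighbours preferred over diagonal); nodes with no valid
# neighbour are flagged far-gap and freeze tracers that reach them. Land nodes
# are then filled from the nearest water node so bilinear interpolation stays
# continuous up to the coast; the free-slip taper handles the boundary itself.
fill_frame <- function(U, V, land) {
  gap <- is.na(U) & !land
  shifts <- list(c(0, -1), c(0, 1), c(-1, 0), c(1, 0),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  fill_from <- function(M, need, donor_ok) {
    out <- M
    still <- need
    for (s in shifts) {
      if (!any(still)) break
      cand <- shift_mat(M, s[1], s[2])
      cand_ok <- shift_mat(donor_ok, s[1], s[2])
      cand_ok[is.na(cand_ok)] <- FALSE
      take <- still & cand_ok
      out[take] <- cand[take]
      still <- still & !take
    }
    list(m = out, unfilled = still)
  }
  donor <- !is.na(U) & !land
  fu <- fill_from(U, gap, donor)
  fv <- fill_from(V, gap, donor)
  fargap <- fu$unfilled
  Uf <- fu$m; Vf <- fv$m
  if (any(land)) {
    water_ok <- !land & !fargap & !is.na(Uf)
    lu <- fill_from(Uf, land, water_ok)
    lv <- fill_from(Vf, land, water_ok)
    Uf <- lu$m; Vf <- lv$m
    Uf[land & lu$unfilled] <- 0
    Vf[land & lv$unfilled] <- 0
  }
  Uf[fargap] <- 0; Vf[fargap] <- 0
  list(u = Uf, v = Vf, fargap = fargap, gap = gap)
}

# Precompute everything the integrator needs: km axes, per-frame filled
# velocity matrices in km/h, far-gap node masks and land-edge cell flags.
prepare_advection <- function(field) {
  ax <- axes_km(field)
  ny <- length(field$lat); nx <- length(field$lon)
  frames <- lapply(seq_along(field$time), function(k) {
    f <- fill_frame(field$u[k, , ], field$v[k, , ], field$land)
    f$u <- f$u * MS_TO_KMH
    f$v <- f$v * MS_TO_KMH
    f
  })
  land <- field$land
  ii <- seq_len(ny - 1); jj <- seq_len(nx - 1)
  edges <- list(
    west  = land[ii, jj, drop = FALSE] & land[ii + 1, jj, drop = FALSE],
    east  = land[ii, jj + 1, drop = FALSE] & land[ii + 1, jj + 1, drop = FALSE],
    south = land[ii, jj, drop = FALSE] & land[ii, jj + 1, drop = FALSE],
    north = land[ii + 1, jj, drop = FALSE] & land[ii + 1, jj + 1, drop = FALSE]
  )
  any_edges <- Reduce(`|`, edges)
  list(ax = ax, xs = ax$xs, ys = ax$ys, times = field$time,
       nx = nx, ny = ny, frames = frames, edges = edges,
       has_land_edges = any(any_edges), has_gaps = any(vapply(frames, function(f) any(f$gap), TRUE)))
}

# Vectorised velocity lookup at km positions (X, Y) and scalar time t.
# Returns km/h components plus freeze (far-gap contact), gap (any enclosing
# node was a data gap) and oob flags.
ctx_velocity <- function(ctx, X, Y, t) {
  n <- length(X)
  oob <- X < ctx$xs[1] | X > ctx$xs[ctx$nx] | Y < ctx$ys[1] | Y > ctx$ys[ctx$ny]
  oob[is.na(oob)] <- TRUE
  tt <- ctx$times
  eps <- 1e-9
  toob <- t < tt[1] - eps | t > tt[length(tt)] + eps
  k <- findInterval(t, tt)
  k <- min(max(k, 1L), length(tt) - 1L)
  if (length(tt) == 1L) k <- 1L
  wt <- if (length(tt) > 1) (t - tt[k]) / (tt[k + 1] - tt[k]) else 0
  wt <- min(max(wt, 0), 1)
  ix <- findInterval(X, ctx$xs, rightmost.closed = TRUE)
  iy <- findInterval(Y, ctx$ys, rightmost.closed = TRUE)
  ix <- pmin(pmax(ix, 1L), ctx$nx - 1L)
  iy <- pmin(pmax(iy, 1L), ctx$ny - 1L)
  fx <- (X - ctx$xs[ix]) / (ctx$xs[ix + 1L] - ctx$xs[ix])
  fy <- (Y - ctx$ys[iy]) / (ctx$ys[iy + 1L] - ctx$ys[iy])
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1)
  i00 <- iy + (ix - 1L) * ctx$ny
  i01 <- iy + ix * ctx$ny          # east neighbour
  i10 <- i00 + 1L                  # north neighbour
  i11 <- i01 + 1L
  f1 <- ctx$frames[[k]]
  f2 <- if (length(tt) > 1) ctx$frames[[k + 1L]] else f1
  lerp4 <- function(m1, m2) {
    v00 <- (1 - wt) * m1[i00] + wt * m2[i00]
    v01 <- (1 - wt) * m1[i01] + wt * m2[i01]
    v10 <- (1 - wt) * m1[i10] + wt * m2[i10]
    v11 <- (1 - wt) * m1[i11] + wt * m2[i11]
    (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  }
  u <- lerp4(f1$u, f2$u)
  v <- lerp4(f1$v, f2$v)
  freeze <- rep(FALSE, n); gap <- rep(FALSE, n)
  if (ctx$has_gaps) {
    fg1 <- f1$fargap; fg2 <- f2$fargap
    freeze <- fg1[i00] | fg1[i01] | fg1[i10] | fg1[i11] |
      fg2[i00] | fg2[i01] | fg2[i10] | fg2[i11]
    g1 <- f1$gap; g2 <- f2$gap
    gap <- g1[i00] | g1[i01] | g1[i10] | g1[i11] |
      g2[i00] | g2[i01] | g2[i10] | g2[i11]
  }
  if (ctx$has_land_edges) {
    icell <- iy + (ix - 1L) * (ctx$ny - 1L)
    w <- ctx$edges$west[icell]; e <- ctx$edges$east[icell]
    s <- ctx$edges$south[icell]; nn <- ctx$edges$north[icell]
    # linear taper of the boundary-normal component to zero at a land edge
    u <- u * ifelse(w, fx, 1) * ifelse(e, 1 - fx, 1)
    v <- v * ifelse(s, fy, 1) * ifelse(nn, 1 - fy, 1)
  }
  u[oob | toob] <- NA_real_
  v[oob | toob] <- NA_real_
  list(u = u, v = v, freeze = freeze, gap = gap, oob = oob, toob = toob)
}

#' Interpolate a velocity field at arbitrary points and times
#'
#' Bilinear in space within the enclosing grid cell and linear in time between
#' the two bracketing frames. Near a land boundary the velocity component
#' normal to the boundary is tapered linearly to zero at the land edge
#' (free-slip), so tracers slide along, not into, the coast. A query inside a
#' cell touching an unrestorable data gap is reported as `missing`; a query
#' outside the grid hull or time span as `out_of_domain` -- the two signals
#' are distinct.
#'
#' @param field A [velocity_field].
#' @param lon,lat Query coordinates (degrees, or km for planar fields).
#' @param t Query times (hours), recycled against positions.
#' @return A tibble with columns `u`, `v` (m s^-1) and `status`
#'   (`"ok"`, `"missing"`, `"out_of_domain"`).
#' @export
velocity_at <- function(field, lon, lat, t) {
  nq <- max(length(lon), length(lat), length(t))
  lon <- rep_len(lon, nq); lat <- rep_len(lat, nq); t <- rep_len(t, nq)
  ctx <- prepare_advection(field)
  X <- ctx$ax$to_x(lon); Y <- ctx$ax$to_y(lat)
  u <- numeric(nq); v <- numeric(nq); status <- character(nq)
  for (tv in unique(t)) {
    sel <- t == tv
    r <- ctx_velocity(ctx, X[sel], Y[sel], tv)
    ui <- r$u / MS_TO_KMH; vi <- r$v / MS_TO_KMH
    st <- rep("ok", sum(sel))
    st[r$gap | r$freeze] <- "missing"
    ui[r$gap | r$freeze] <- NA_real_; vi[r$gap | r$freeze] <- NA_real_
    st[r$oob | r$toob] <- "out_of_domain"
    u[sel] <- ui; v[sel] <- vi; status[sel] <- st
  }
  tibble(u = u, v = v, status = status)
}
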