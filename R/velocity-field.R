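#' Construct a gridded surface-current velocity field
#'
#' A `velocity_field` holds hourly (or otherwise regularly sampled) gridded
#' surface-current vectors, the Eulerian input to the Lagrangian FTLE engine.
#' Grids are regular in each axis; coordinates are either geographic
#' (longitude/latitude on WGS84, velocities in m s^-1) or planar (km, used by
#' the analytic benchmark flows).
#'
#' @param lon Ascending grid coordinates along x (degrees east, or km when
#'   `planar = TRUE`).
#' @param lat Ascending grid coordinates along y (degrees north, or km).
#' @param time Strictly increasing frame times in hours (numeric). A frame
#'   time denotes the instant of that field; no staggering.
#' @param u,v Numeric arrays of dimension `c(length(time), length(lat),
#'   length(lon))`, eastward and northward velocity in m s^-1. `NA` marks a
#'   data gap (e.g. an HF-radar dropout).
#' @param land Optional logical matrix `length(lat) x length(lon)`; `TRUE`
#'   marks land nodes. Land nodes must have `NA` velocities.
#' @param planar If `TRUE`, coordinates are kilometres on a plane and no
#'   geographic projection is applied during advection.
#'
#' @return An object of class `velocity_field`.
#' @seealso [velocity_at()], [load_velocity_grid()], [gen_analytic_field()]
#' @export
velocity_field <- function(lon, lat, time, u, v, land = NULL, planar = FALSE) {
  lon <- as.numeric(lon); lat <- as.numeric(lat); time <- as.numeric(time)
  dims <- c(length(time), length(lat), length(lon))
  if (!identical(dim(u), as.integer(dims)) || !identical(dim(v), as.integer(dims)))
    abort(sprintf("u and v must have dim [time=%d, lat=%d, lon=%d]",
                  dims[1], dims[2], dims[3]))
  if (any(diff(time) <= 0)) {
    bad <- time[which(diff(time) <= 0)[1] + 1]
    abort(sprintf("time axis not strictly increasing (offending timestamp: %g h)", bad))
  }
  check_regular_axis(lon, "lon")
  check_regular_axis(lat, "lat")
  if (!identical(is.na(u), is.na(v)))
    abort("u and v must share their missing-value mask")
  if (is.null(land)) {
    land <- matrix(FALSE, dims[2], dims[3])
  } else {
    land <- matrix(as.logical(land), dims[2], dims[3])
    # land nodes carry no data by definition
    for (k in seq_len(dims[1])) {
      uk <- u[k, , ]; uk[land] <- NA_real_; u[k, , ] <- uk
      vk <- v[k, , ]; vk[land] <- NA_real_; v[k, , ] <- vk
    }
  }
  structure(
    list(lon = lon, lat = lat, time = time, u = u, v = v,
         land = land, planar = isTRUE(planar)),
    class = "velocity_field"
  )
}

check_regular_axis <- function(x, name) {
  if (length(x) < 2) abort(sprintf("%s axis needs at least 2 nodes", name))
  d <- diff(x)
  if (any(d <= 0)) abort(sprintf("%s axis must be ascending", name))
  if (max(d) / min(d) - 1 > 0.01)
    abort(sprintf("%s axis spacing varies by more than 1%%", name))
  invisible(TRUE)
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf(
    "<velocity_field> %d x %d grid, %d frames (%.4g..%.4g h), %s, %.1f%% gaps, %d land nodes\n",
    length(x$lat), length(x$lon), length(x$time), min(x$time), max(x$time),
    if (x$planar) "planar (km)" else "geographic (deg)",
    100 * mean(is.na(x$u[!rep(x$land, each = length(x$time))])),
    sum(x$land)))
  invisible(x)
}

#' @describeIn velocity_field Long-format view: one row per (time, lat, lon)
#'   node with `u`, `v` and a `land` flag.
#' @param x A `velocity_field`.
#' @param ... Unused.
#' @method as_tibble velocity_field
#' @export
as_tibble.velocity_field <- function(x, ...) {
  nt <- length(x$time); ny <- length(x$lat); nx <- length(x$lon)
  g <- expand.grid(time = x$time, lat = x$lat, lon = x$lon,
                   KEEP.OUT.ATTRS = FALSE)
  land3 <- aperm(array(rep(x$land, nt), c(ny, nx, nt)), c(3, 1, 2))
  tibble(time = g$time, lat = g$lat, lon = g$lon,
         u = as.vector(x$u), v = as.vector(x$v),
         land = as.vector(land3))
}

#' Read a gridded velocity field from disk
#'
#' Supports CF-style NetCDF (dimensions time/lat/lon; variables `u`, `v` in
#' m s^-1 with `_FillValue` gaps) and a CSV long format with columns
#' `time, lat, lon, u, v`. Validation failures name the offending coordinate.
#'
#' @param path File path.
#' @param format `"netcdf"` or `"csv_long"`.
#' @param planar Are coordinates planar km rather than lon/lat degrees?
#' @return A [velocity_field].
#' @export
load_velocity_grid <- function(path, format = c("csv_long", "netcdf"),
                               planar = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "netcdf") {
    if (!requireNamespace("ncdf4", quietly = TRUE))
      abort("NetCDF support needs the ncdf4 package; use format = 'csv_long'")
    nc <- ncdf4::nc_open(path)
    on.exit(ncdf4::nc_close(nc))
    lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
    lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
    time <- as.numeric(ncdf4::ncvar_get(nc, "time"))
    # ncdf4 returns [lon, lat, time]; reorder to [time, lat, lon]
    u <- aperm(array(ncdf4::ncvar_get(nc, "u", collapse_degen = FALSE),
                     c(length(lon), length(lat), length(time))), c(3, 2, 1))
    v <- aperm(array(ncdf4::ncvar_get(nc, "v", collapse_degen = FALSE),
                     c(length(lon), length(lat), length(time))), c(3, 2, 1))
    land <- matrix(FALSE, length(lat), length(lon))
    if ("land" %in% names(nc$var))
      land <- t(matrix(ncdf4::ncvar_get(nc, "land") > 0,
                       length(lon), length(lat)))
    if (any(duplicated(time)))
      abort(sprintf("repeated timestamp in %s: %g h", path,
                    time[duplicated(time)][1]))
    return(velocity_field(lon, lat, time, u, v, land = land, planar = planar))
  }
  d <- utils::read.csv(path)
  need <- c("time", "lat", "lon", "u", "v")
  if (!all(need %in% names(d)))
    abort(sprintf("csv_long needs columns %s; missing: %s",
                  paste(need, collapse = ","),
                  paste(setdiff(need, names(d)), collapse = ",")))
  lon <- sort(unique(d$lon)); lat <- sort(unique(d$lat))
  time <- sort(unique(d$time))
  if (anyDuplicated(d[c("time", "lat", "lon")])) {
    dup <- d[duplicated(d[c("time", "lat", "lon")]), ][1, ]
    abort(sprintf("repeated (time,lat,lon) record at time=%g lat=%g lon=%g",
                  dup$time, dup$lat, dup$lon))
  }
  if (nrow(d) != length(lon) * length(lat) * length(time))
    abort("csv_long grid incomplete: row count does not match the coordinate product")
  dims <- c(length(time), length(lat), length(lon))
  u <- array(NA_real_, dims); v <- array(NA_real_, dims)
  it <- match(d$time, time); iy <- match(d$lat, lat); ix <- match(d$lon, lon)
  idx <- cbind(it, iy, ix)
  u[idx] <- d$u; v[idx] <- d$v
  land <- matrix(FALSE, dims[2], dims[3])
  if ("land" %in% names(d)) {
    lidx <- d$time == time[1]
    land[cbind(iy[lidx], ix[lidx])] <- as.logical(d$land[lidx])
  }
  velocity_field(lon, lat, time, u, v, land = land, planar = planar)
}

#' Write a velocity field to CSV long format
#'
#' One row per (time, lat, lon) node, columns `time, lat, lon, u, v, land`.
#' The exact inverse of [load_velocity_grid()] with `format = "csv_long"`.
#'
#' @param field A [velocity_field].
#' @param path Output path.
#' @export
write_velocity_csv <- function(field, path) {
  nt <- length(field$time); ny <- length(field$lat); nx <- length(field$lon)
  g <- expand.grid(time = field$time, lat = field$lat, lon = field$lon,
                   KEEP.OUT.ATTRS = FALSE)
  land3 <- aperm(array(rep(field$land, nt), c(ny, nx, nt)), c(3, 1, 2))
  d <- data.frame(time = g$time, lat = g$lat, lon = g$lon,
                  u = as.vector(field$u), v = as.vector(field$v),
                  land = as.integer(as.vector(land3)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a velocity field to CF-style NetCDF
#'
#' Dimensions time/lat/lon, variables `u` and `v` in m s^-1 with `NA` gaps
#' stored as `_FillValue`, and an integer `land` mask.
#'
#' @inheritParams write_velocity_csv
#' @export
write_velocity_nc <- function(field, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    abort("NetCDF support needs the ncdf4 package; use write_velocity_csv()")
  dlon <- ncdf4::ncdim_def("lon", if (field$planar) "km" else "degrees_east",
                           field$lon)
  dlat <- ncdf4::ncdim_def("lat", if (field$planar) "km" else "degrees_north",
                           field$lat)
  dtim <- ncdf4::ncdim_def("time", "hours", field$time, unlim = TRUE)
  fill <- 9.969209968386869e36
  vu <- ncdf4::ncvar_def("u", "m s-1", list(dlon, dlat, dtim), fill,
                         prec = "double")
  vv <- ncdf4::ncvar_def("v", "m s-1", list(dlon, dlat, dtim), fill,
                         prec = "double")
  vl <- ncdf4::ncvar_def("land", "1", list(dlon, dlat), prec = "integer")
  nc <- ncdf4::nc_create(path, list(vu, vv, vl))
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, vu, aperm(field$u, c(3, 2, 1)))
  ncdf4::ncvar_put(nc, vv, aperm(field$v, c(3, 2, 1)))
  ncdf4::ncvar_put(nc, vl, t(field$land) * 1L)
  invisible(path)
}
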