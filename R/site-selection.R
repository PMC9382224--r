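#' Mixed-effects feeding-site selection model
#'
#' Fits the probability of feeding as a logistic function of FTLE with a
#' per-individual random intercept and a continuous-time first-order
#' autocorrelation structure (corCAR1 on time since deployment start within
#' individual), estimated by penalized quasi-likelihood
#' ([MASS::glmmPQL()]). With `random = "none"` and `correlation = FALSE`
#' the fit reduces to a plain logistic regression, which is also the
#' fallback for a single individual.
#'
#' @param dives Dive table with `feeding`, `ftle`, `individual`, `start_h`.
#'   Dives with missing FTLE or location are dropped.
#' @param random `"individual"` (default) or `"none"`.
#' @param correlation Include the corCAR1 serial-correlation structure?
#' @return A `feeding_model_fit` with slope/intercept estimates, standard
#'   errors, slope p-value, the serial-correlation parameter `phi`, sample
#'   sizes, and the underlying fit.
#' @export
fit_feeding_model <- function(dives, random = c("individual", "none"),
                              correlation = TRUE) {
  random <- match.arg(random)
  d <- as_tibble(dives)
  if (!"individual" %in% names(d)) d$individual <- "all"
  keep <- !is.na(d$ftle) & !is.na(d$feeding)
  if ("lon" %in% names(d)) keep <- keep & !is.na(d$lon)
  d <- d[keep, ]
  if (stats::sd(d$ftle) == 0) abort("FTLE covariate is degenerate (constant)")
  d$feeding <- as.integer(d$feeding)
  d <- d %>% group_by(.data$individual) %>%
    mutate(time_h = .data$start_h - min(.data$start_h)) %>% ungroup()
  n_ind <- length(unique(d$individual))
  if (n_ind < 2 && random == "individual") {
    warn("single individual: dropping the random effect")
    random <- "none"
  }
  # complete-separation guard on the fixed-effect structure
  pre <- glm(feeding ~ ftle, binomial(), data = d)
  if (any(abs(coef(pre)) > 15) || !pre$converged)
    abort(sprintf(
      "apparent complete separation (glm slope %.3g); feeding model aborted",
      coef(pre)[2]))
  if (random == "none" && !correlation) {
    fit <- pre
    sm <- summary(fit)$coefficients
    est <- sm[, "Estimate"]; se <- sm[, "Std. Error"]; p <- sm["ftle", "Pr(>|z|)"]
    phi <- NA_real_
  } else {
    corr <- if (correlation)
      nlme::corCAR1(form = ~ time_h | individual) else NULL
    # Nelder-Mead lme optimizer is markedly more robust than nlminb when the
    # random-intercept variance is near zero
    fit <- MASS::glmmPQL(feeding ~ ftle, random = ~ 1 | individual,
                         family = binomial(), data = as.data.frame(d),
                         correlation = corr, verbose = FALSE,
                         control = nlme::lmeControl(opt = "optim"))
    tt <- summary(fit)$tTable
    est <- tt[, "Value"]; se <- tt[, "Std.Error"]; p <- tt["ftle", "p-value"]
    phi <- if (correlation)
      as.numeric(coef(fit$modelStruct$corStruct, unconstrained = FALSE))
    else NA_real_
  }
  structure(list(intercept = unname(est[1]), slope = unname(est["ftle"]),
                 se_intercept = unname(se[1]), se_slope = unname(se["ftle"]),
                 p_slope = unname(p), phi = phi,
                 n_dives = nrow(d), n_individuals = n_ind,
                 random = random, correlation = correlation, fit = fit),
            class = "feeding_model_fit")
}

#' @export
print.feeding_model_fit <- function(x, ...) {
  cat(sprintf(
    "<feeding_model_fit> logit(feeding) ~ FTLE: slope %.3f (SE %.3f, p = %.3g), phi = %.3f\n  %d dives, %d individuals (%s random effect, corCAR1 %s)\n",
    x$slope, x$se_slope, x$p_slope, if (is.na(x$phi)) NA else x$phi,
    x$n_dives, x$n_individuals, x$random,
    if (x$correlation) "on" else "off"))
  invisible(x)
}

track_steps <- function(lon, lat, planar = FALSE) {
  if (planar) {
    dx <- diff(lon); dy <- diff(lat)
  } else {
    latm <- mean(lat, na.rm = TRUE)
    dx <- diff(lon) * KM_PER_DEG_LON_EQ * cos(latm * pi / 180)
    dy <- diff(lat) * KM_PER_DEG_LAT
  }
  list(len = sqrt(dx^2 + dy^2), heading = atan2(dy, dx))
}

wrap_pi <- function(a) ((a + pi) %% (2 * pi)) - pi

#' Estimate correlated-random-walk parameters from a track
#'
#' `r` is the mean resultant length of the observed turning angles (1 for a
#' perfectly straight track, near 0 for uniform turning); `h` is the
#' step-length scale, taken as the mean step length in km. Tracks whose
#' turning angles are all (numerically) zero return `r = 1` with a warning.
#'
#' @param track Ordered locations (`lon`, `lat`; `time_h` optional).
#' @param planar Planar km coordinates rather than degrees.
#' @return A `crw_params` list with `h` (km) and `r` in `[0, 1]`.
#' @export
estimate_crw_params <- function(track, planar = FALSE) {
  track <- as_tibble(track)
  track <- track[!is.na(track$lon) & !is.na(track$lat), ]
  if (nrow(track) < 3) abort("need at least 3 locations to estimate CRW parameters")
  st <- track_steps(track$lon, track$lat, planar)
  keep <- st$len > 0
  turns <- wrap_pi(diff(st$heading[keep]))
  if (length(turns) == 0 || all(abs(turns) < 1e-12)) {
    warn("degenerate (collinear) track: returning r = 1")
    r <- 1
  } else {
    r <- sqrt(mean(cos(turns))^2 + mean(sin(turns))^2)
  }
  structure(list(h = mean(st$len), r = r,
                 steps = st$len[keep], n = nrow(track), planar = planar),
            class = "crw_params")
}

#' @export
print.crw_params <- function(x, ...) {
  cat(sprintf("<crw_params> h = %.3f km, r = %.3f (%d locations)\n",
              x$h, x$r, x$n))
  invisible(x)
}

rwrappedcauchy <- function(n, rho) {
  if (rho >= 1) return(rep(0, n))
  if (rho <= 0) return(runif(n, -pi, pi))
  wrap_pi(2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (runif(n) - 0.5))))
}

point_in_poly <- function(lon, lat, poly) {
  # ray casting; poly is a data frame / matrix with columns lon, lat
  px <- poly[, 1]; py <- poly[, 2]
  n <- length(px)
  j <- c(n, seq_len(n - 1))
  inside <- rep(FALSE, length(lon))
  for (k in seq_len(n)) {
    jk <- j[k]
    cross <- ((py[k] > lat) != (py[jk] > lat)) &
      (lon < (px[jk] - px[k]) * (lat - py[k]) / (py[jk] - py[k]) + px[k])
    inside <- xor(inside, cross & !is.na(cross))
  }
  inside
}

mcp_hull <- function(lon, lat) {
  idx <- grDevices::chull(lon, lat)
  cbind(lon = lon[idx], lat = lat[idx])
}

sample_in_hull <- function(n, hull) {
  lon_r <- range(hull[, 1]); lat_r <- range(hull[, 2])
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(10, 2 * (n - nrow(out)))
    lon <- runif(m, lon_r[1], lon_r[2])
    lat <- runif(m, lat_r[1], lat_r[2])
    ok <- point_in_poly(lon, lat, hull)
    out <- rbind(out, cbind(lon[ok], lat[ok]))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Correlated-random-walk null tracks
#'
#' Simulates `n_tracks` randomized tracks per individual as a correlated
#' random walk: step lengths resampled from the individual's observed steps
#' (scaled by `h` relative to the observed mean) and turning angles drawn
#' from a wrapped Cauchy distribution with mean resultant length `r`. Each
#' null track starts at a random point inside the minimum convex polygon of
#' the source locations and keeps the source's timestamps and
#' feeding/non-feeding labels, isolating spatial selection from temporal
#' structure. Steps landing on land (per `land`) are redrawn up to
#' `reject_cap` times, after which the track restarts from a new MCP start
#' (counted in the `restarts` attribute).
#'
#' @param dives Located dive table (`individual`, `start_h`, `feeding`,
#'   `lon`, `lat`).
#' @param params Optional `crw_params`; estimated per individual when NULL.
#' @param n_tracks Simulated tracks per individual (default 10).
#' @param land `NULL` (no land), a predicate `function(lon, lat)` returning
#'   TRUE on land, or a polygon (matrix/data frame with lon, lat columns).
#' @param seed Integer seed.
#' @param planar Planar km coordinates.
#' @param reject_cap Step redraws allowed near land before a restart.
#' @return Tibble of null-track locations: `track`, `individual`, `sim`,
#'   `start_h`, `feeding`, `lon`, `lat`.
#' @export
simulate_crw_tracks <- function(dives, params = NULL, n_tracks = 10,
                                land = NULL, seed = 1, planar = FALSE,
                                reject_cap = 100) {
  dives <- as_tibble(dives)
  if (!"individual" %in% names(dives)) dives$individual <- "all"
  on_land <- if (is.null(land)) {
    function(lon, lat) FALSE
  } else if (is.function(land)) {
    land
  } else {
    poly <- as.matrix(land)
    function(lon, lat) point_in_poly(lon, lat, poly)
  }
  restarts <- 0L
  out <- withr::with_seed(seed, {
    parts <- lapply(split(dives, dives$individual), function(d) {
      d <- d[!is.na(d$lon) & !is.na(d$lat), ]
      d <- d[order(d$start_h), ]
      if (nrow(d) < 3) return(NULL)
      pp <- if (is.null(params)) estimate_crw_params(d, planar) else params
      hull <- mcp_hull(d$lon, d$lat)
      steps_obs <- pp$steps
      scale <- pp$h / mean(steps_obs)
      km_x <- if (planar) 1 else KM_PER_DEG_LON_EQ * cos(mean(d$lat) * pi / 180)
      km_y <- if (planar) 1 else KM_PER_DEG_LAT
      n <- nrow(d)
      sims <- lapply(seq_len(n_tracks), function(s) {
        repeat {
          start <- sample_in_hull(1, hull)
          tries_start <- 0L
          while (on_land(start[1], start[2]) && tries_start < reject_cap) {
            start <- sample_in_hull(1, hull)
            tries_start <- tries_start + 1L
          }
          lon <- numeric(n); lat <- numeric(n)
          lon[1] <- start[1]; lat[1] <- start[2]
          heading <- runif(1, 0, 2 * pi)
          failed <- FALSE
          for (k in seq_len(n - 1)) {
            placed <- FALSE
            for (try in seq_len(reject_cap)) {
              turn <- rwrappedcauchy(1, pp$r)
              hh <- heading + turn
              L <- sample(steps_obs, 1) * scale
              nlon <- lon[k] + L * cos(hh) / km_x
              nlat <- lat[k] + L * sin(hh) / km_y
              if (!on_land(nlon, nlat)) {
                lon[k + 1] <- nlon; lat[k + 1] <- nlat; heading <- hh
                placed <- TRUE
                break
              }
            }
            if (!placed) { failed <- TRUE; break }
          }
          if (!failed) {
            return(tibble(track = sprintf("%s_sim%02d", d$individual[1], s),
                          individual = d$individual[1], sim = s,
                          start_h = d$start_h, feeding = d$feeding,
                          lon = lon, lat = lat))
          }
          restarts <<- restarts + 1L
        }
      })
      dplyr::bind_rows(sims)
    })
    dplyr::bind_rows(parts)
  })
  attr(out, "restarts") <- restarts
  out
}

#' Time-shifted dive tables for temporal-persistence nulls
#'
#' Shifts every dive timestamp forward by `shift_h` hours, keeps positions
#' and feeding labels identical, and re-extracts FTLE at the shifted times.
#' If FTLE features are ephemeral, the feeding-FTLE relationship should
#' vanish for shifts beyond the features' decorrelation time.
#'
#' @param dives Located dive table.
#' @param shift_h Forward shift in hours (the study design used 24, 48, 96
#'   and 192).
#' @param ftle_series `ftle_series` with coverage extending `shift_h` beyond
#'   the deployment.
#' @return `dives` with shifted `start_h`, re-extracted `ftle` and a
#'   `shift_h` column; the `n_uncovered` attribute counts dives whose
#'   shifted time had no FTLE coverage.
#' @export
time_shift_extract <- function(dives, shift_h, ftle_series) {
  d <- as_tibble(dives)
  d$start_h <- d$start_h + shift_h
  d$ftle <- extract_ftle_at(ftle_series, d$lon, d$lat, d$start_h)
  d$shift_h <- shift_h
  had <- if ("ftle" %in% names(dives)) !is.na(dives$ftle) else !is.na(d$lon)
  attr(d, "n_uncovered") <- sum(is.na(d$ftle) & had)
  if (attr(d, "n_uncovered") > 0)
    warn(sprintf("%d dive(s) lost FTLE coverage after the %g h shift",
                 attr(d, "n_uncovered"), shift_h))
  d
}
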