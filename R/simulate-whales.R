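#' Specification for a simulated whale deployment
#'
#' Describes the simulated tag data: number of individuals, deployment
#' length, dive-cycle durations, the multinomial-logit coefficients coupling
#' the four feeding states (non-feeding, light, moderate, heavy) to FTLE, the
#' mean lunges per dive in each state, and the GPS gap model. Defaults mimic
#' the scale of real blue whale deployments: roughly week-long records of
#' 8-minute foraging dives with 2-minute surface intervals, dive-by-dive
#' feeding rates averaging in the low 20s of lunges per hour, and a fifth of
#' dives without a usable GPS fix.
#'
#' @param n_individuals Number of simulated animals.
#' @param duration_days Deployment length per animal (2-18 d is realistic).
#' @param dive_mean_s,surface_mean_s Mean dive and post-dive surface
#'   durations in seconds (lognormal draws).
#' @param dive_sdlog,surface_sdlog Lognormal log-scale spreads.
#' @param beta 4 x 4 x 2 array of transition coefficients
#'   (`beta[i, j, 1]` intercept, `beta[i, j, 2]` FTLE slope for the i -> j
#'   transition; diagonal is the reference and must be zero). See
#'   [default_transition_beta()].
#' @param state_lunge_rates Mean lunges per dive for the four states; the
#'   non-feeding state must be 0, feeding states draw zero-truncated Poisson.
#' @param gps_gap_fraction Fraction of dives without a GPS fix, in `[0, 1)`.
#' @param speed_ms Horizontal swim speed (m s^-1) of the simulated track.
#' @param heading_sd Turning-angle s.d. (radians) of the movement walk.
#' @return A `whale_sim_spec`.
#' @export
whale_sim_spec <- function(n_individuals = 10, duration_days = 7,
                           dive_mean_s = 480, dive_sdlog = 0.35,
                           surface_mean_s = 120, surface_sdlog = 0.45,
                           beta = default_transition_beta(),
                           state_lunge_rates = c(0, 2.3, 4, 5.7),
                           gps_gap_fraction = 0.2,
                           speed_ms = 1.5, heading_sd = 0.6) {
  if (duration_days <= 0 || dive_mean_s <= 0 || surface_mean_s <= 0)
    abort("durations must be positive")
  if (state_lunge_rates[1] != 0)
    abort("lunge rate for the non-feeding state must be 0")
  if (gps_gap_fraction < 0 || gps_gap_fraction >= 1)
    abort("gps_gap_fraction must be in [0, 1)")
  if (!identical(dim(beta), c(4L, 4L, 2L)) || any(beta[cbind(1:4, 1:4, 1)] != 0) ||
      any(beta[cbind(1:4, 1:4, 2)] != 0))
    abort("beta must be 4 x 4 x 2 with a zero diagonal (self-transition reference)")
  structure(list(n_individuals = n_individuals, duration_days = duration_days,
                 dive_mean_s = dive_mean_s, dive_sdlog = dive_sdlog,
                 surface_mean_s = surface_mean_s, surface_sdlog = surface_sdlog,
                 beta = beta, state_lunge_rates = state_lunge_rates,
                 gps_gap_fraction = gps_gap_fraction, speed_ms = speed_ms,
                 heading_sd = heading_sd),
            class = "whale_sim_spec")
}

#' Default FTLE-coupled transition coefficients
#'
#' Self-transitions are the reference (logit 0); off-diagonal intercepts of
#' -1.5 give sticky states, and the FTLE slopes push transitions away from
#' non-feeding and towards heavy feeding as FTLE grows, reproducing the
#' qualitative stationary-probability pattern seen in foraging whales
#' (non-feeding probability falls, heavy feeding rises with FTLE).
#'
#' @param slope_scale Multiplier on the FTLE slopes (0 decouples feeding from
#'   FTLE entirely, useful as a null generator).
#' @return A 4 x 4 x 2 coefficient array.
#' @export
default_transition_beta <- function(slope_scale = 1) {
  b <- array(0, c(4, 4, 2))
  b[, , 1] <- -1.5
  dest_slopes <- c(-0.8, 0, 0.3, 0.8) * slope_scale
  for (j in 1:4) b[, j, 2] <- dest_slopes[j]
  for (i in 1:4) b[i, i, ] <- 0
  b
}

# row-stochastic transition matrices from a raw coefficient array at
# covariate values x: returns [S, S, length(x)]
tm_from_beta <- function(beta, x) {
  S <- dim(beta)[1]
  out <- array(NA_real_, c(S, S, length(x)))
  for (q in seq_along(x)) {
    lg <- beta[, , 1] + beta[, , 2] * x[q]
    diag(lg) <- 0
    e <- exp(lg)
    out[, , q] <- e / rowSums(e)
  }
  out
}

#' Simulate a state sequence from FTLE-dependent transition probabilities
#'
#' Draws a Markov chain whose one-step transition matrix at step `k` is the
#' multinomial-logit matrix evaluated at covariate `x[k]` (the covariate at
#' the origin dive governs the transition out of it).
#'
#' @param x Covariate sequence (FTLE, day^-1); length = chain length.
#' @param beta Coefficient array as in [whale_sim_spec()].
#' @param init Initial state (default 1).
#' @param seed Optional integer seed.
#' @return Integer vector of states in `1:S`.
#' @export
simulate_state_sequence <- function(x, beta, init = 1L, seed = NULL) {
  draw <- function() {
    S <- dim(beta)[1]
    s <- integer(length(x))
    s[1] <- init
    for (k in seq_len(length(x) - 1)) {
      lg <- beta[s[k], , 1] + beta[s[k], , 2] * x[k]
      lg[s[k]] <- 0
      p <- exp(lg); p <- p / sum(p)
      s[k + 1] <- sample.int(S, 1, prob = p)
    }
    s
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

rtpois <- function(n, lambda) {
  # zero-truncated Poisson via inverse-cdf conditioning
  u <- runif(n, exp(-lambda), 1)
  qpois(u, lambda)
}

#' Simulate whale deployments coupled to an FTLE series
#'
#' Generates, per individual, an ordered sequence of dive cycles (lognormal
#' dive and surface durations), a meandering horizontal track, behavioural
#' states drawn from the FTLE-dependent transition model, zero-truncated
#' Poisson lunge counts in feeding states, and GPS fixes with configured
#' gaps. Dives outside the FTLE series' space-time coverage keep a missing
#' FTLE value (transitions there use a neutral FTLE of 0) and are flagged,
#' never dropped. All randomness flows from `seed` through one sub-seed per
#' individual, so individuals are reproducible independently.
#'
#' @param spec A [whale_sim_spec()].
#' @param ftle_series An `ftle_series` covering the simulated extent.
#' @param seed Integer seed.
#' @param t_start Deployment start hour (default: first series hour).
#' @return A `whale_sim` list: `dives` and `gps` tibbles plus the generating
#'   spec (the recorded truth for recovery tests).
#' @export
simulate_whale_deployment <- function(spec, ftle_series, seed = 1,
                                      t_start = NULL) {
  stopifnot(inherits(spec, "whale_sim_spec"), inherits(ftle_series, "ftle_series"))
  f1 <- ftle_series[[1]]
  lon_r <- range(f1$lon); lat_r <- range(f1$lat)
  if (is.null(t_start)) t_start <- min(vapply(ftle_series, `[[`, numeric(1), "time"))
  km_x <- if (f1$planar) 1 else KM_PER_DEG_LON_EQ * cos(mean(lat_r) * pi / 180)
  km_y <- if (f1$planar) 1 else KM_PER_DEG_LAT
  sub_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max, spec$n_individuals))
  sim_one <- function(i) {
    withr::with_seed(sub_seeds[i], {
      t_h <- t_start
      end_h <- t_start + spec$duration_days * 24
      lon <- runif(1, lon_r[1] + 0.25 * diff(lon_r), lon_r[2] - 0.25 * diff(lon_r))
      lat <- runif(1, lat_r[1] + 0.25 * diff(lat_r), lat_r[2] - 0.25 * diff(lat_r))
      heading <- runif(1, 0, 2 * pi)
      state <- 1L
      rows <- list(); gps <- list(); k <- 0L
      while (t_h < end_h) {
        k <- k + 1L
        dur <- rlnorm(1, log(spec$dive_mean_s) - spec$dive_sdlog^2 / 2, spec$dive_sdlog)
        srf <- rlnorm(1, log(spec$surface_mean_s) - spec$surface_sdlog^2 / 2,
                      spec$surface_sdlog)
        ftle <- extract_ftle_at(ftle_series, lon, lat, t_h)
        xcov <- if (is.na(ftle)) 0 else ftle
        lunges <- if (state == 1L) 0L else rtpois(1, spec$state_lunge_rates[state])
        rows[[k]] <- data.frame(
          individual = sprintf("whale_%02d", i), dive_id = k,
          start_h = t_h, duration_s = dur, surface_s = srf,
          max_depth_m = runif(1, 15, 250), lunges = lunges,
          lon = lon, lat = lat, ftle = ftle, state_true = state)
        if (runif(1) > spec$gps_gap_fraction)
          gps[[length(gps) + 1L]] <- data.frame(
            individual = sprintf("whale_%02d", i), time_h = t_h,
            lon = lon, lat = lat)
        # transition governed by FTLE at the origin dive
        lg <- spec$beta[state, , 1] + spec$beta[state, , 2] * xcov
        lg[state] <- 0
        p <- exp(lg); p <- p / sum(p)
        state <- sample.int(4L, 1, prob = p)
        # meandering track; reflect at the series bounding box
        heading <- heading + rnorm(1, 0, spec$heading_sd)
        step_km <- spec$speed_ms * (dur + srf) / 1000
        lon <- lon + step_km * cos(heading) / km_x
        lat <- lat + step_km * sin(heading) / km_y
        if (lon < lon_r[1]) { lon <- 2 * lon_r[1] - lon; heading <- pi - heading }
        if (lon > lon_r[2]) { lon <- 2 * lon_r[2] - lon; heading <- pi - heading }
        if (lat < lat_r[1]) { lat <- 2 * lat_r[1] - lat; heading <- -heading }
        if (lat > lat_r[2]) { lat <- 2 * lat_r[2] - lat; heading <- -heading }
        t_h <- t_h + (dur + srf) / 3600
      }
      list(dives = dplyr::bind_rows(rows), gps = dplyr::bind_rows(gps))
    })
  }
  parts <- lapply(seq_len(spec$n_individuals), sim_one)
  dives <- as_tibble(dplyr::bind_rows(lapply(parts, `[[`, "dives")))
  dives$feeding <- dives$lunges >= 1L
  gps <- as_tibble(dplyr::bind_rows(lapply(parts, `[[`, "gps")))
  structure(list(dives = dives, gps = gps, spec = spec, seed = seed),
            class = "whale_sim")
}

#' @export
print.whale_sim <- function(x, ...) {
  cat(sprintf("<whale_sim> %d individuals, %d dives, %d GPS fixes (seed %d)\n",
              length(unique(x$dives$individual)), nrow(x$dives), nrow(x$gps),
              x$seed))
  invisible(x)
}

#' Simulate serially correlated feeding/FTLE dive series
#'
#' Direct generator for feeding-site-selection recovery tests: per
#' individual, an AR(1) FTLE covariate (temporal decorrelation scale
#' `x_tau_h`), a random intercept, and a latent AR(1) logit disturbance
#' produce Bernoulli feeding outcomes with known logit slope on FTLE and
#' within-individual serial correlation -- the data-generating structure the
#' mixed feeding model assumes.
#'
#' @param n_individuals,n_dives Panel dimensions.
#' @param intercept,slope True logit coefficients.
#' @param re_sd Random-intercept s.d. between individuals.
#' @param ar_sd,ar_tau_h Marginal s.d. and decorrelation time (hours) of the
#'   latent serial disturbance.
#' @param x_mean,x_sd,x_tau_h Mean, s.d. and decorrelation time of the FTLE
#'   covariate process (defaults echo encountered-FTLE distributions:
#'   mean 0.25 day^-1, spread 0.45, persistence a few hours).
#' @param cycle_min Dive-cycle length in minutes.
#' @param seed Integer seed.
#' @return Tibble with `individual`, `time_h`, `ftle`, `feeding`.
#' @export
simulate_feeding_series <- function(n_individuals = 10, n_dives = 500,
                                    intercept = 0, slope = 0.45,
                                    re_sd = 0.25, ar_sd = 0.3, ar_tau_h = 2,
                                    x_mean = 0.25, x_sd = 0.45, x_tau_h = 6,
                                    cycle_min = 12, seed = 1) {
  dt_h <- cycle_min / 60
  phi_x <- exp(-dt_h / x_tau_h)
  phi_e <- exp(-dt_h / ar_tau_h)
  withr::with_seed(seed, {
    out <- lapply(seq_len(n_individuals), function(i) {
      b <- rnorm(1, 0, re_sd)
      x <- numeric(n_dives); e <- numeric(n_dives)
      x[1] <- rnorm(1, 0, 1); e[1] <- rnorm(1, 0, 1)
      for (k in 2:n_dives) {
        x[k] <- phi_x * x[k - 1] + sqrt(1 - phi_x^2) * rnorm(1)
        e[k] <- phi_e * e[k - 1] + sqrt(1 - phi_e^2) * rnorm(1)
      }
      ftle <- x_mean + x_sd * x
      eta <- intercept + slope * ftle + b + ar_sd * e
      tibble(individual = sprintf("whale_%02d", i),
             time_h = (seq_len(n_dives) - 1) * dt_h,
             ftle = ftle,
             feeding = rbinom(n_dives, 1, plogis(eta)) == 1)
    })
    dplyr::bind_rows(out)
  })
}

#' Simulate a stochastic FTLE series with controlled decorrelation
#'
#' Builds spatially smooth Gaussian random FTLE fields that evolve as an
#' AR(1) process in time with decorrelation scale `tau_h`. Useful for
#' statistical tests that need FTLE fields whose temporal persistence is
#' known (e.g. time-shift null attenuation), without running the advection
#' engine. Values are `mean + sd * z` with `z` standard Gaussian after
#' spatial smoothing.
#'
#' @param hours Field times.
#' @param lon,lat Grid axes (planar km by default).
#' @param mean,sd Marginal mean and s.d. of the field (day^-1). Defaults
#'   echo observed backward-FTLE distributions (centred near 0.25 day^-1,
#'   spread 0.45, range roughly -1.25 to 1.5).
#' @param tau_h Temporal decorrelation scale in hours.
#' @param smooth_cells Spatial correlation scale in coarse cells (bilinear
#'   upsampling factor).
#' @param seed Integer seed.
#' @param planar Planar axes flag passed to the fields.
#' @return An `ftle_series`.
#' @export
simulate_ftle_series <- function(hours, lon = seq(0, 60, by = 1),
                                 lat = seq(0, 60, by = 1),
                                 mean = 0.25, sd = 0.45, tau_h = 6,
                                 smooth_cells = 6, seed = 1, planar = TRUE) {
  nx <- length(lon); ny <- length(lat)
  ncx <- max(2, ceiling(nx / smooth_cells) + 1)
  ncy <- max(2, ceiling(ny / smooth_cells) + 1)
  ix <- seq(1, ncx, length.out = nx)
  iy <- seq(1, ncy, length.out = ny)
  upsample <- function(z) {
    j0 <- pmin(floor(ix), ncx - 1); i0 <- pmin(floor(iy), ncy - 1)
    fx <- ix - j0; fy <- iy - i0
    FY <- matrix(fy, ny, nx); FX <- matrix(fx, ny, nx, byrow = TRUE)
    z00 <- z[cbind(rep(i0, nx), rep(j0, each = ny))]
    z01 <- z[cbind(rep(i0, nx), rep(j0 + 1, each = ny))]
    z10 <- z[cbind(rep(i0 + 1, nx), rep(j0, each = ny))]
    z11 <- z[cbind(rep(i0 + 1, nx), rep(j0 + 1, each = ny))]
    m <- (1 - FY) * ((1 - FX) * z00 + FX * z01) + FY * ((1 - FX) * z10 + FX * z11)
    matrix(m, ny, nx)
  }
  dt <- diff(hours)
  withr::with_seed(seed, {
    zc <- matrix(rnorm(ncy * ncx), ncy, ncx)
    fields <- vector("list", length(hours))
    fields[[1]] <- ftle_field(hours[1], lon, lat, mean + sd * upsample(zc),
                              planar = planar)
    for (k in seq_along(dt)) {
      phi <- exp(-dt[k] / tau_h)
      zc <- phi * zc + sqrt(1 - phi^2) * matrix(rnorm(ncy * ncx), ncy, ncx)
      fields[[k + 1]] <- ftle_field(hours[k + 1], lon, lat,
                                    mean + sd * upsample(zc), planar = planar)
    }
    ftle_series(fields)
  })
}
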