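#' Detect dives in a 1 Hz depth trace
#'
#' A dive is an excursion to a depth of greater than `threshold` metres: it
#' spans from the downward crossing of the threshold to the next upward
#' crossing. Post-dive surface duration is the time from the end of a dive to
#' the start of the next dive; the final dive has a missing surface duration
#' (and a missing end if the trace stops underwater).
#'
#' @param depth Data frame with strictly increasing `time_s` (seconds, ~1 Hz)
#'   and `depth_m` columns; an optional `individual` column is carried over.
#' @param threshold Dive depth threshold in metres (default 10; strict `>`).
#' @return Tibble of dives: `dive_id`, `start_s`, `end_s`, `duration_s`,
#'   `max_depth_m`, `surface_s`.
#' @export
detect_dives <- function(depth, threshold = 10) {
  if (!all(c("time_s", "depth_m") %in% names(depth)))
    abort("depth needs columns time_s and depth_m")
  if (is.unsorted(depth$time_s, strictly = TRUE))
    abort("time_s must be strictly increasing")
  t <- depth$time_s; d <- depth$depth_m
  below <- d > threshold
  if (!any(below)) {
    return(tibble(dive_id = integer(0), start_s = numeric(0),
                  end_s = numeric(0), duration_s = numeric(0),
                  max_depth_m = numeric(0), surface_s = numeric(0)))
  }
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  start_s <- t[starts[runs]]
  # end = first sample back at/above the threshold; missing if trace stops deep
  end_idx <- ends[runs] + 1L
  end_s <- ifelse(end_idx <= length(t), t[end_idx], NA_real_)
  max_d <- vapply(runs, function(k) max(d[starts[k]:ends[k]]), numeric(1))
  surface_s <- c(utils::tail(start_s, -1), NA_real_) - end_s
  tibble(dive_id = seq_along(runs), start_s = start_s, end_s = end_s,
         duration_s = end_s - start_s, max_depth_m = max_d,
         surface_s = surface_s)
}

gps_speed_ms <- function(lon1, lat1, lon2, lat2, dt_h, planar = FALSE) {
  d_m <- if (planar) {
    sqrt((lon2 - lon1)^2 + (lat2 - lat1)^2) * 1000
  } else {
    geosphere::distGeo(cbind(lon1, lat1), cbind(lon2, lat2))
  }
  d_m / (dt_h * 3600)
}

#' Filter GPS fixes for unrealistic travel speeds
#'
#' Retains the largest possible subset of fixes such that every pair of
#' consecutive retained fixes implies a speed of at most `max_speed`
#' (exact minimal-removal filter; among equally large subsets the earliest
#' fixes are preferred). First and last fixes are retained only if they
#' belong to that optimal subset. With fewer than two fixes the input is
#' returned unchanged.
#'
#' @param gps Time-ordered data frame with `time_h`, `lon`, `lat` (an
#'   `individual` column, if present, is filtered per individual).
#' @param max_speed Maximum plausible speed in m s^-1 (default 6).
#' @param planar Treat lon/lat as planar km instead of degrees.
#' @return The retained fixes, same columns, as a tibble.
#' @export
filter_gps_speed <- function(gps, max_speed = 6, planar = FALSE) {
  gps <- as_tibble(gps)
  if ("individual" %in% names(gps) && length(unique(gps$individual)) > 1) {
    return(gps %>% group_by(.data$individual) %>%
             dplyr::group_modify(~ filter_gps_speed(.x, max_speed, planar)) %>%
             ungroup())
  }
  n <- nrow(gps)
  if (n < 2) return(gps)
  if (is.unsorted(gps$time_h)) abort("fixes must be time-ordered")
  ok <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    sp <- gps_speed_ms(gps$lon[i], gps$lat[i], gps$lon[j], gps$lat[j],
                       pmax(gps$time_h[j] - gps$time_h[i], 1e-12), planar)
    ok[i, j] <- sp <= max_speed
  }
  # g[j]: longest admissible chain starting at j (backward DP)
  g <- integer(n)
  for (j in n:1) {
    succ <- which(ok[j, ])
    g[j] <- 1L + if (length(succ)) max(g[succ]) else 0L
  }
  M <- max(g)
  keep <- integer(0)
  cur <- min(which(g == M))
  keep <- cur
  while (g[cur] > 1L) {
    nxt <- which(ok[cur, ] & g == g[cur] - 1L)
    cur <- min(nxt)
    keep <- c(keep, cur)
  }
  gps[keep, , drop = FALSE]
}

#' Interpolate dive-start locations from GPS fixes
#'
#' Assigns each dive the linearly time-interpolated position between the
#' bracketing GPS fixes when the bracket spans less than `max_gap_min`
#' minutes; otherwise the location is missing. A dive whose start coincides
#' with a fix gets that fix's position exactly. Dives without a location are
#' retained (flagged by `NA`) but are excluded from downstream statistics by
#' the analysis functions.
#'
#' @param dives Dive table with `start_h` (hours); optional `individual`.
#' @param gps Filtered fixes with `time_h`, `lon`, `lat`.
#' @param max_gap_min Maximum bracket span in minutes (default 15, strict).
#' @return `dives` with `lon`/`lat` columns filled where interpolable.
#' @export
assign_dive_locations <- function(dives, gps, max_gap_min = 15) {
  dives <- as_tibble(dives); gps <- as_tibble(gps)
  one <- function(dv, gp) {
    gp <- gp[order(gp$time_h), ]
    lon <- rep(NA_real_, nrow(dv)); lat <- rep(NA_real_, nrow(dv))
    if (nrow(gp) >= 1) {
      i0 <- findInterval(dv$start_h, gp$time_h)
      for (q in seq_len(nrow(dv))) {
        k <- i0[q]
        if (k >= 1 && k <= nrow(gp) && gp$time_h[k] == dv$start_h[q]) {
          lon[q] <- gp$lon[k]; lat[q] <- gp$lat[k]
        } else if (k >= 1 && k < nrow(gp)) {
          span_min <- (gp$time_h[k + 1] - gp$time_h[k]) * 60
          if (span_min < max_gap_min) {
            w <- (dv$start_h[q] - gp$time_h[k]) / (gp$time_h[k + 1] - gp$time_h[k])
            lon[q] <- (1 - w) * gp$lon[k] + w * gp$lon[k + 1]
            lat[q] <- (1 - w) * gp$lat[k] + w * gp$lat[k + 1]
          }
        }
      }
    }
    dv$lon <- lon; dv$lat <- lat
    dv
  }
  if ("individual" %in% names(dives) && "individual" %in% names(gps)) {
    parts <- lapply(split(dives, dives$individual), function(dv)
      one(dv, gps[gps$individual == dv$individual[1], ]))
    out <- dplyr::bind_rows(parts)
    out[order(match(
      paste(out$individual, out$start_h),
      paste(dives$individual, dives$start_h))), ]
  } else {
    one(dives, gps)
  }
}

#' Dive-by-dive feeding rate (lunges per hour)
#'
#' `rate = lunges / (dive duration + post-dive surface duration)`, converted
#' to lunges h^-1. The dive-cycle denominator accounts for transit to and
#' from the prey and the surface recovery period. Dives with no lunges have
#' rate 0 and `feeding = FALSE`; dives with a missing surface duration (the
#' final dive of a record) have an undefined rate and are flagged.
#'
#' @param dives Dive table with `lunges`, `duration_s`, `surface_s`.
#' @return `dives` with `feeding`, `feeding_rate` (lunges h^-1) and
#'   `rate_defined` columns.
#' @export
compute_feeding_rate <- function(dives) {
  dives <- as_tibble(dives)
  need <- c("lunges", "duration_s", "surface_s")
  if (!all(need %in% names(dives)))
    abort(sprintf("dives needs columns %s", paste(need, collapse = ", ")))
  dives %>%
    mutate(feeding = .data$lunges >= 1,
           rate_defined = !is.na(.data$surface_s) & !is.na(.data$duration_s),
           feeding_rate = dplyr::if_else(
             .data$rate_defined,
             .data$lunges / (.data$duration_s + .data$surface_s) * 3600,
             NA_real_))
}

#' Percentile-normalize feeding rates and label behavioural states
#'
#' Within each individual, the feeding rate of every feeding dive is
#' converted to its percentile rank (`fr_pct`, 0-100) among that
#' individual's feeding dives: rank / n x 100 with ties averaged, i.e. the
#' fraction of feeding dives with a rate at or below the value. Non-feeding
#' dives are pinned at `fr_pct = 0`. States split at the 25th and 75th
#' percentiles: non-feeding, light (`fr_pct <= 25`), moderate
#' (`25 < fr_pct < 75`) and heavy (`fr_pct >= 75`; the boundary value 75 is
#' heavy). `fr_pct` is invariant to any strictly monotone transform of an
#' individual's rates.
#'
#' @param dives Dive table with `feeding_rate` and `feeding` (see
#'   [compute_feeding_rate()]); optional `individual`.
#' @return `dives` with `fr_pct` and `state` (factor) columns.
#' @export
normalize_and_label_states <- function(dives) {
  dives <- as_tibble(dives)
  if (!"individual" %in% names(dives)) dives$individual <- "all"
  out <- dives %>%
    group_by(.data$individual) %>%
    mutate(fr_pct = {
      feed <- .data$feeding & !is.na(.data$feeding_rate)
      if (sum(feed) > 0 && sum(feed) < 4)
        warn(sprintf("individual %s has only %d feeding dives; fr_pct is coarse",
                     .data$individual[1], sum(feed)))
      p <- dplyr::if_else(.data$feeding, NA_real_, 0)
      p[feed] <- 100 * rank(.data$feeding_rate[feed], ties.method = "average") /
        sum(feed)
      p
    }) %>%
    ungroup()
  out$state <- factor(
    dplyr::case_when(
      !out$feeding ~ "non-feeding",
      is.na(out$fr_pct) ~ NA_character_,
      out$fr_pct <= 25 ~ "light",
      out$fr_pct < 75 ~ "moderate",
      TRUE ~ "heavy"),
    levels = c("non-feeding", "light", "moderate", "heavy"))
  out
}

#' Build a located, FTLE-matched dive table from raw tag streams
#'
#' Convenience pipeline: [detect_dives()] on the depth trace, lunge events
#' counted into dives, [filter_gps_speed()], [assign_dive_locations()],
#' [compute_feeding_rate()], [normalize_and_label_states()], and optional
#' FTLE matching via [extract_ftle_at()].
#'
#' @param depth 1 Hz depth trace (`time_s`, `depth_m`).
#' @param lunge_times_s Times (s) of identified lunge events.
#' @param gps GPS fixes (`time_h`, `lon`, `lat`).
#' @param ftle_series Optional `ftle_series` for FTLE matching.
#' @param individual Individual id recorded in the output.
#' @param threshold,max_speed,max_gap_min Stage parameters.
#' @param planar Treat GPS lon/lat as planar km (synthetic tracks).
#' @return Tidy dive table (one row per dive).
#' @export
build_dive_table <- function(depth, lunge_times_s = numeric(0), gps = NULL,
                             ftle_series = NULL, individual = "whale_01",
                             threshold = 10, max_speed = 6, max_gap_min = 15,
                             planar = FALSE) {
  dv <- detect_dives(depth, threshold)
  dv$individual <- individual
  dv$start_h <- dv$start_s / 3600
  dv$lunges <- vapply(seq_len(nrow(dv)), function(k)
    sum(lunge_times_s >= dv$start_s[k] &
          lunge_times_s < (ifelse(is.na(dv$end_s[k]), Inf, dv$end_s[k]))),
    integer(1))
  if (!is.null(gps)) {
    gps <- filter_gps_speed(gps, max_speed, planar = planar)
    dv <- assign_dive_locations(dv, gps, max_gap_min)
  } else {
    dv$lon <- NA_real_; dv$lat <- NA_real_
  }
  dv <- compute_feeding_rate(dv)
  dv <- normalize_and_label_states(dv)
  if (!is.null(ftle_series))
    dv$ftle <- extract_ftle_at(ftle_series, dv$lon, dv$lat, dv$start_h)
  dv
}
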