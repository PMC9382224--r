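#' Draw background (availability) locations for a use-availability design
#'
#' For every located dive, `ratio` random locations (default 10:1
#' background:real) are drawn uniformly within the +/-1 degree bounding box
#' around the extent of that individual's locations, at the dive's own
#' timestamp, and FTLE is extracted identically to the real points. A draw
#' whose FTLE is missing (land, no coverage) is retried up to `retry_cap`
#' times, then kept as missing; the exclusion count is reported via the
#' `n_missing` attribute rather than silently discarded.
#'
#' @param dives Located dive table (`individual`, `start_h`, `lon`, `lat`).
#' @param ftle_series `ftle_series` to sample.
#' @param ratio Background:real ratio (integer >= 1, default 10).
#' @param seed Integer seed.
#' @param box_margin Half-width of the availability box around the extent of
#'   each individual's locations (degrees, or km for planar grids).
#' @param retry_cap Maximum resamples per missing-FTLE point.
#' @return Tibble of background points: `individual`, `time_h`, `lon`,
#'   `lat`, `ftle`; attribute `n_missing` counts unresolved points.
#' @export
sample_background <- function(dives, ftle_series, ratio = 10, seed = 1,
                              box_margin = 1, retry_cap = 100) {
  if (ratio < 1) abort("ratio must be >= 1")
  dives <- as_tibble(dives)
  use <- dives[!is.na(dives$lon) & !is.na(dives$lat), ]
  if (nrow(use) == 0) abort("no located dives to sample background for")
  if (!"individual" %in% names(use)) use$individual <- "all"
  withr::with_seed(seed, {
    parts <- lapply(split(use, use$individual), function(d) {
      lon_r <- range(d$lon) + c(-box_margin, box_margin)
      lat_r <- range(d$lat) + c(-box_margin, box_margin)
      n <- nrow(d) * ratio
      t_h <- rep(d$start_h, each = ratio)
      lon <- runif(n, lon_r[1], lon_r[2])
      lat <- runif(n, lat_r[1], lat_r[2])
      ftle <- extract_ftle_at(ftle_series, lon, lat, t_h)
      for (tries in seq_len(retry_cap)) {
        miss <- which(is.na(ftle))
        if (!length(miss)) break
        lon[miss] <- runif(length(miss), lon_r[1], lon_r[2])
        lat[miss] <- runif(length(miss), lat_r[1], lat_r[2])
        ftle[miss] <- extract_ftle_at(ftle_series, lon[miss], lat[miss],
                                      t_h[miss])
      }
      tibble(individual = d$individual[1], time_h = t_h,
             lon = lon, lat = lat, ftle = ftle)
    })
    out <- dplyr::bind_rows(parts)
    attr(out, "n_missing") <- sum(is.na(out$ftle))
    out
  })
}

#' Per-individual weights equalizing deployments
#'
#' Location weight `1 / (n_locations_individual x n_deployments)` and
#' feeding-dive weight `1 / (n_feeding_dives_individual x n_deployments)`,
#' so each individual's distribution counts evenly regardless of deployment
#' length: each individual's weights sum to `1 / n_deployments` and all
#' weights together sum to 1. Individuals with a zero denominator are
#' excluded with a warning.
#'
#' @param dives Dive table with `individual`, locations and feeding flags.
#' @return Tibble: `individual`, `n_locations`, `n_feeding_dives`,
#'   `w_location`, `w_feeding`.
#' @export
compute_weights <- function(dives) {
  dives <- as_tibble(dives)
  if (!"individual" %in% names(dives)) dives$individual <- "all"
  tab <- dives %>%
    group_by(.data$individual) %>%
    summarise(
      n_locations = sum(!is.na(.data$lon) & !is.na(.data$lat)),
      n_feeding_dives = sum(.data$feeding & !is.na(.data$lon), na.rm = TRUE),
      .groups = "drop")
  bad <- tab$n_locations == 0 & tab$n_feeding_dives == 0
  if (any(bad)) {
    warn(sprintf("excluding individual(s) with no usable dives: %s",
                 paste(tab$individual[bad], collapse = ", ")))
    tab <- tab[!bad, ]
  }
  ndep <- nrow(tab)
  tab %>%
    mutate(w_location = ifelse(.data$n_locations > 0,
                               1 / (.data$n_locations * ndep), NA_real_),
           w_feeding = ifelse(.data$n_feeding_dives > 0,
                              1 / (.data$n_feeding_dives * ndep), NA_real_))
}

weighted_ecdf_sup <- function(x, w, g) {
  # one-sided sup_x [F_background(x) - F_whale(x)] over the pooled support;
  # g is TRUE for whale points. Evaluated at sorted pooled values.
  o <- order(x)
  xo <- x[o]; wo <- w[o]; go <- g[o]
  ww <- ifelse(go, wo, 0); wb <- ifelse(go, 0, wo)
  Fw <- cumsum(ww) / sum(ww)
  Fb <- cumsum(wb) / sum(wb)
  # evaluate at the last tied index of each distinct value
  lastv <- c(diff(xo) > 0, TRUE)
  max(c(0, (Fb - Fw)[lastv]))
}

#' Weighted one-sided two-sample Kolmogorov-Smirnov test
#'
#' Tests whether the whale-encountered distribution is stochastically
#' greater than the background distribution using individually weighted
#' ECDFs: `D = sup_x [F_background(x) - F_whale(x)]`. Because weights
#' invalidate the classical K-S null distribution, the p-value is obtained
#' by permuting pooled sample labels (values keep their weights). With all
#' weights equal `D` reduces exactly to the classic one-sided two-sample
#' statistic, and the classical asymptotic p-value is reported alongside.
#'
#' @param whale_values,background_values Sample values (FTLE, day^-1).
#' @param whale_weights,background_weights Non-negative weights (default
#'   equal).
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed for the permutation draw.
#' @return Tibble with `D`, `p_perm`, `p_classic` (NA unless equal weights),
#'   `n_whale`, `n_background`.
#' @export
weighted_ks_test <- function(whale_values, background_values,
                             whale_weights = NULL, background_weights = NULL,
                             n_perm = 10000, seed = 1) {
  wv <- whale_values[!is.na(whale_values)]
  bv <- background_values[!is.na(background_values)]
  if (!length(wv) || !length(bv)) abort("both samples must be non-empty")
  ww <- if (is.null(whale_weights)) rep(1 / length(wv), length(wv))
        else whale_weights[!is.na(whale_values)]
  bw <- if (is.null(background_weights)) rep(1 / length(bv), length(bv))
        else background_weights[!is.na(background_values)]
  if (any(ww < 0) || any(bw < 0)) abort("weights must be non-negative")
  x <- c(wv, bv); w <- c(ww, bw)
  g <- c(rep(TRUE, length(wv)), rep(FALSE, length(bv)))
  D <- weighted_ecdf_sup(x, w, g)
  if (length(unique(x)) == 1) {
    return(tibble(D = 0, p_perm = 1, p_classic = 1,
                  n_whale = length(wv), n_background = length(bv)))
  }
  perm_D <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      weighted_ecdf_sup(x, w, sample(g))
    }, numeric(1))
  })
  p_perm <- (1 + sum(perm_D >= D - 1e-15)) / (n_perm + 1)
  equal_w <- diff(range(ww)) < 1e-12 && diff(range(bw)) < 1e-12
  p_classic <- if (equal_w) {
    suppressWarnings(stats::ks.test(bv, wv, alternative = "greater")$p.value)
  } else NA_real_
  tibble(D = D, p_perm = p_perm, p_classic = p_classic,
         n_whale = length(wv), n_background = length(bv))
}

#' Regional (third-order) habitat-selection test table
#'
#' Runs the weighted K-S comparison of whale-encountered versus background
#' FTLE, pooled across individuals with deployment-equalizing weights and
#' per individual with equal weights, mirroring a use-availability design.
#'
#' @param dives Located, FTLE-matched dive table.
#' @param background Background sample from [sample_background()].
#' @param n_perm,seed Permutation settings for [weighted_ks_test()].
#' @return Tibble, one row per individual plus a pooled row: sample sizes,
#'   weighted means and test results.
#' @export
regional_selection_test <- function(dives, background, n_perm = 2000,
                                    seed = 1) {
  dives <- as_tibble(dives)
  use <- dives[!is.na(dives$ftle) & !is.na(dives$lon), ]
  bg <- background[!is.na(background$ftle), ]
  wt <- compute_weights(dives)
  rows <- lapply(split(use, use$individual), function(d) {
    b <- bg[bg$individual == d$individual[1], ]
    r <- weighted_ks_test(d$ftle, b$ftle, n_perm = n_perm, seed = seed)
    tibble(individual = d$individual[1],
           mean_whale = mean(d$ftle), mean_background = mean(b$ftle),
           r)
  })
  ww <- wt$w_location[match(use$individual, wt$individual)]
  bw_tab <- table(bg$individual)
  bw <- 1 / (as.numeric(bw_tab[bg$individual]) * nrow(wt))
  pooled <- weighted_ks_test(use$ftle, bg$ftle, ww, bw,
                             n_perm = n_perm, seed = seed)
  pooled_row <- tibble(individual = "pooled",
                       mean_whale = sum(use$ftle * ww) / sum(ww),
                       mean_background = sum(bg$ftle * bw) / sum(bw),
                       pooled)
  dplyr::bind_rows(c(rows, list(pooled_row)))
}
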