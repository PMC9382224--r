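test_that("dive detection handles the square-wave and threshold-boundary cases", {
  d <- make_square_depth(list(c(0, 100), c(50, 600), c(0, 200), c(50, 600),
                              c(0, 50)))
  dv <- detect_dives(d)
  expect_equal(nrow(dv), 2)
  expect_equal(dv$duration_s[1], 600)
  expect_equal(dv$surface_s[1], 200)
  expect_equal(dv$max_depth_m, c(50, 50))
  expect_true(is.na(dv$surface_s[2]))

  shallow <- make_square_depth(list(c(0, 50), c(9.9, 300), c(0, 50)))
  expect_equal(nrow(detect_dives(shallow)), 0)
  # exactly 10 m does not count (strict >)
  at10 <- make_square_depth(list(c(0, 50), c(10, 300), c(0, 50)))
  expect_equal(nrow(detect_dives(at10)), 0)
  bad <- tibble::tibble(time_s = c(0, 1, 1), depth_m = c(0, 20, 0))
  expect_error(detect_dives(bad), "strictly increasing")
})

test_that("dive detection matches a brute-force crossing scan on random casts", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 3000
    depth <- pmax(0, 40 * sin(seq(0, 40 * pi, length.out = n)) +
                    rnorm(n, 0, 12))
    d <- tibble::tibble(time_s = seq_len(n) - 1, depth_m = depth)
    dv <- detect_dives(d, threshold = 10)
    # oracle: scan for downward/upward crossings sample by sample
    below <- depth > 10
    starts <- which(below & !c(FALSE, below[-n]))
    ends <- which(!below & c(FALSE, below[-n]))
    expect_equal(dv$start_s, d$time_s[starts])
    expect_equal(dv$end_s[!is.na(dv$end_s)], d$time_s[ends])
    expect_equal(nrow(dv), length(starts))
  }
})

test_that("speed filter removes direct violations and leaves clean tracks alone", {
  # two fixes 1 km apart, 100 s apart -> 10 m/s -> later fix removed
  g <- tibble::tibble(time_h = c(0, 100 / 3600), lon = c(0, 1), lat = c(0, 0))
  out <- filter_gps_speed(g, max_speed = 6, planar = TRUE)
  expect_equal(nrow(out), 1)
  expect_equal(out$time_h, 0)
  # all speeds < 6 -> identical output
  g2 <- tibble::tibble(time_h = seq(0, 2, by = 0.5),
                       lon = seq(0, 0.02, length.out = 5) * 100,
                       lat = rep(0, 5))
  expect_identical(filter_gps_speed(g2, 6, planar = TRUE), g2)
  # fewer than 2 fixes unchanged
  g3 <- g[1, ]
  expect_identical(filter_gps_speed(g3, 6, planar = TRUE), g3)
})

test_that("speed filter equals the exhaustive minimal-removal oracle", {
  set.seed(5)
  for (rep in 1:8) {
    n <- 9
    g <- tibble::tibble(
      time_h = cumsum(runif(n, 0.05, 0.2)),
      lon = cumsum(rnorm(n, 0, 1.2)),       # km steps, some adversarial
      lat = cumsum(rnorm(n, 0, 1.2)))
    # inject spikes
    g$lon[sample(n, 2)] <- g$lon[sample(n, 2)] + 30
    out <- filter_gps_speed(g, max_speed = 6, planar = TRUE)
    brute <- gps_filter_brute(g, 6, planar = TRUE)
    expect_equal(which(g$time_h %in% out$time_h), unname(brute))
  }
})

test_that("dive locations interpolate inside the 15 min gap rule", {
  gps <- tibble::tibble(time_h = c(1, 1 + 10 / 60, 2, 2 + 20 / 60),
                        lon = c(0, 1, 5, 9), lat = c(0, 2, 5, 7))
  dives <- tibble::tibble(start_h = c(1 + 5 / 60, 2 + 10 / 60, 1))
  out <- assign_dive_locations(dives, gps)
  # midway between fixes 10 min apart -> midpoint
  expect_equal(out$lon[1], 0.5); expect_equal(out$lat[1], 1)
  # bracket span 20 min -> missing
  expect_true(is.na(out$lon[2]))
  # coincident with a fix -> that fix exactly
  expect_equal(out$lon[3], 0); expect_equal(out$lat[3], 0)
})

test_that("feeding rate follows the dive-cycle formula", {
  dv <- tibble::tibble(lunges = c(4L, 0L, 6L, 2L),
                       duration_s = c(600, 500, 900, 700),
                       surface_s = c(120, 100, 180, NA))
  out <- compute_feeding_rate(dv)
  expect_equal(out$feeding_rate[1], 20)       # 4 / 720 s -> 20 h^-1
  expect_equal(out$feeding_rate[2], 0)
  expect_false(out$feeding[2])
  expect_equal(out$feeding_rate[3], 20)       # 6 / 1080 s
  expect_true(is.na(out$feeding_rate[4]))     # final dive: rate undefined
  expect_false(out$rate_defined[4])
})

test_that("percentile normalization and state labels follow the rank rule", {
  dv <- tibble::tibble(individual = "a",
                       lunges = c(2L, 3L, 4L, 5L, 0L),
                       duration_s = rep(600, 5), surface_s = rep(120, 5),
                       feeding_rate = c(10, 20, 30, 40, 0),
                       feeding = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  out <- normalize_and_label_states(dv)
  expect_equal(out$fr_pct, c(25, 50, 75, 100, 0))
  expect_equal(as.character(out$state),
               c("light", "moderate", "heavy", "heavy", "non-feeding"))
  # all non-feeding -> all fr_pct 0
  dv0 <- tibble::tibble(individual = "a", feeding = FALSE,
                        feeding_rate = 0, lunges = 0L)
  out0 <- normalize_and_label_states(dv0)
  expect_equal(out0$fr_pct, 0)
  expect_equal(as.character(out0$state), "non-feeding")
})

test_that("fr_pct equals the ECDF oracle and is monotone-transform invariant", {
  set.seed(9)
  rates <- rlnorm(1000, 3, 0.5)
  dv <- tibble::tibble(individual = "w", feeding = TRUE, feeding_rate = rates)
  out <- normalize_and_label_states(dv)
  expect_equal(out$fr_pct, 100 * ecdf(rates)(rates), tolerance = 1e-12)
  # strictly monotone transform leaves fr_pct unchanged
  dv2 <- dv; dv2$feeding_rate <- log(rates)^3 + 5 * rates
  out2 <- normalize_and_label_states(dv2)
  expect_equal(out2$fr_pct, out$fr_pct)
  # state proportions approach 25/50/25 among feeding dives
  pr <- prop.table(table(out$state))[c("light", "moderate", "heavy")]
  expect_true(all(abs(pr - c(0.25, 0.5, 0.25)) < 0.05))
})

test_that("few feeding dives trigger a warning but still get states", {
  dv <- tibble::tibble(individual = "a", feeding = c(TRUE, TRUE, FALSE),
                       feeding_rate = c(10, 20, 0))
  expect_warning(out <- normalize_and_label_states(dv), "feeding dives")
  expect_false(any(is.na(out$state)))
})

test_that("the raw-stream pipeline produces a coherent dive table", {
  d <- make_square_depth(list(c(0, 300), c(60, 600), c(0, 240), c(40, 480),
                              c(0, 300), c(80, 700), c(0, 200)))
  lunges <- c(350, 400, 450, 1300)             # 3 in dive 1, 1 in dive 2
  gps <- tibble::tibble(time_h = c(0.01, 0.1, 0.25, 0.45, 0.7),
                        lon = c(0, 0.5, 1, 1.5, 2), lat = rep(0, 5))
  expect_warning(dv <- build_dive_table(d, lunges, gps, planar = TRUE),
                 "feeding dives")
  expect_equal(nrow(dv), 3)
  expect_equal(dv$lunges, c(3L, 1L, 0L))
  expect_identical(dv$feeding, c(TRUE, TRUE, FALSE))
  expect_true(all(!is.na(dv$lon[1:2])))
  expect_equal(as.character(dv$state)[3], "non-feeding")
})
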