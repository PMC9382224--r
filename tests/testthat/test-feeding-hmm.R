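test_that("with no covariate effect, fitted transitions equal count ratios", {
  set.seed(5)
  # two-state chain with constant transition probabilities
  beta <- array(0, c(2, 2, 2))
  beta[1, 2, 1] <- qlogis(0.3)          # P(1 -> 2) = 0.3
  beta[2, 1, 1] <- qlogis(0.45)         # P(2 -> 1) = 0.45
  x <- rep(0, 4000)
  s <- simulate_state_sequence(x, beta, seed = 2)
  dv <- tibble::tibble(individual = "a", start_h = seq_along(s) * 0.2,
                       feeding = s == 2, ftle = x)
  fit <- fit_transition_model(dv, n_states = 2)
  G <- transition_matrix(fit, 0)
  emp <- prop.table(table(s[-length(s)], s[-1]), 1)
  expect_equal(G[1, 2], emp[1, 2], tolerance = 1e-6)
  expect_equal(G[2, 1], emp[2, 1], tolerance = 1e-6)
})

test_that("transition matrices are exact softmax with the diagonal reference", {
  b0 <- array(0, c(4, 4, 2))
  expect_equal(transition_matrix(b0, 0.7), matrix(0.25, 4, 4))
  # 2-state, intercepts only: logistic closed form
  b2 <- array(0, c(2, 2, 2))
  b2[1, 2, 1] <- 0.8; b2[2, 1, 1] <- -0.3
  G <- transition_matrix(b2, 0)
  expect_equal(G[1, 2], plogis(0.8), tolerance = 1e-12)
  expect_equal(G[2, 1], plogis(-0.3), tolerance = 1e-12)
  # rows sum to 1 within 1e-12 for arbitrary coefficients and x
  set.seed(7)
  for (k in 1:20) {
    b <- array(rnorm(32), c(4, 4, 2))
    for (i in 1:4) b[i, i, ] <- 0
    G <- transition_matrix(b, rnorm(1))
    expect_lt(max(abs(rowSums(G) - 1)), 1e-12)
  }
})

test_that("stationary distributions solve pi G = pi and match oracles", {
  expect_equal(stationary_probabilities(matrix(0.25, 4, 4)), rep(0.25, 4))
  # 2-state closed form pi1 = g21 / (g12 + g21)
  g12 <- 0.2; g21 <- 0.35
  G2 <- matrix(c(1 - g12, g12, g21, 1 - g21), 2, 2, byrow = TRUE)
  expect_equal(stationary_probabilities(G2)[1], g21 / (g12 + g21),
               tolerance = 1e-12)
  # random irreducible 4x4 vs power iteration; residual < 1e-10
  set.seed(8)
  for (k in 1:10) {
    G <- matrix(rexp(16), 4, 4); G <- G / rowSums(G)
    p <- stationary_probabilities(G)
    expect_lt(max(abs(as.vector(p %*% G) - p)), 1e-10)
    expect_equal(p, stationary_power(G), tolerance = 1e-9)
  }
  # reducible chain rejected
  Gr <- diag(4)
  expect_error(stationary_probabilities(Gr), "reducible")
})

test_that("weighted state splits reduce to plain means under equal weights", {
  out <- weighted_state_feeding_rates(1:100)
  expect_equal(out$mean_rate, c(mean(1:25), mean(26:75), mean(76:100)))
  # weighted toy set: brute-force weighted computation
  rates <- c(10, 20, 30, 40, 12, 18, 25, 33, 45, 50)
  w <- c(rep(1 / (2 * 2), 2), rep(1 / (8 * 2), 8))   # individuals with 2, 8 dives
  out2 <- weighted_state_feeding_rates(rates, w)
  o <- order(rates); cw <- cumsum(w[o]) / sum(w)
  q25 <- rates[o][which(cw >= 0.25)[1]]
  q75 <- rates[o][which(cw >= 0.75)[1]]
  seg <- ifelse(rates <= q25, 1, ifelse(rates <= q75, 2, 3))
  brute <- vapply(1:3, function(s)
    sum(rates[seg == s] * w[seg == s]) / sum(w[seg == s]), numeric(1))
  expect_equal(out2$mean_rate, brute)
  expect_error(weighted_state_feeding_rates(numeric(0)), "no feeding rates")
})

test_that("the overall rate is a convex combination of the state rates", {
  rates <- c(13.5, 23.9, 34.1)
  expect_equal(feeding_rate_from_probs(c(1, 0, 0, 0), rates), 0)
  expect_equal(feeding_rate_from_probs(c(0.51, 0.12, 0.22, 0.15), rates),
               0.12 * 13.5 + 0.22 * 23.9 + 0.15 * 34.1)
  set.seed(10)
  for (k in 1:25) {
    p <- rexp(4); p <- p / sum(p)
    r <- feeding_rate_from_probs(p, rates)
    expect_lte(r, max(rates) * (1 - p[1]) + 1e-12)
    expect_gte(r, min(rates) * (1 - p[1]) - 1e-12)
  }
})

test_that("known 4-state coefficients are recovered and order permutation destroys them", {
  set.seed(17)
  beta <- default_transition_beta()
  n <- 6000
  x <- as.numeric(arima.sim(list(ar = 0.9), n, sd = sqrt(1 - 0.81))) * 0.45 + 0.25
  s <- simulate_state_sequence(x, beta, seed = 4)
  dv <- tibble::tibble(individual = "a", start_h = seq_len(n) * 0.2,
                       ftle = x, feeding = s > 1,
                       state = factor(c("non-feeding", "light", "moderate",
                                        "heavy")[s],
                                      levels = c("non-feeding", "light",
                                                 "moderate", "heavy")))
  fit <- fit_transition_model(dv, n_states = 4)
  off <- which(row(matrix(0, 4, 4)) != col(matrix(0, 4, 4)))
  for (q in 1:2) {
    est <- fit$beta[, , q][off]; tru <- beta[, , q][off]
    see <- fit$se[, , q][off]
    expect_gt(mean(abs(est - tru) <= 2.5 * see), 0.85)
  }
  # permuting dive order kills the covariate structure: slopes shrink
  dvp <- dv[sample(nrow(dv)), ]
  dvp$start_h <- sort(dvp$start_h)
  fitp <- fit_transition_model(dvp, n_states = 4)
  expect_lt(mean(abs(fitp$beta[, , 2][off])), mean(abs(fit$beta[, , 2][off])))
  # origin state with no outgoing transitions is rejected
  dv2 <- dv[as.character(dv$state) != "heavy", ]
  expect_error(fit_transition_model(dv2[1:50, ], n_states = 4),
               "outgoing|observed")
})

test_that("feeding-rate curve is a proper convex combination over the grid", {
  set.seed(23)
  x <- as.numeric(arima.sim(list(ar = 0.85), 8000, sd = 0.3)) + 0.25
  s <- simulate_state_sequence(x, default_transition_beta(), seed = 9)
  dv <- tibble::tibble(individual = "a", start_h = seq_along(s) * 0.2,
                       ftle = x, feeding = s > 1,
                       state = factor(c("non-feeding", "light", "moderate",
                                        "heavy")[s],
                                      levels = c("non-feeding", "light",
                                                 "moderate", "heavy")))
  fit <- fit_transition_model(dv, 4)
  cv <- estimate_feeding_rate_curve(fit, c(13.5, 23.9, 34.1),
                                    x_grid = seq(-1.25, 1.5, by = 0.05))
  P <- as.matrix(cv[, c("pi_nonfeeding", "pi_light", "pi_moderate", "pi_heavy")])
  expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
  expect_true(all(P >= -1e-12 & P <= 1 + 1e-12))
  expect_true(all(cv$rate >= 0 & cv$rate <= 34.1))
  expect_true(all(cv$rate_lo <= cv$rate + 1e-9 & cv$rate <= cv$rate_hi + 1e-9))
  # generator pushes heavy feeding up with FTLE: the curve is increasing
  expect_gt(cv$rate[nrow(cv)], cv$rate[1])
  expect_false(any(cv$extrapolated))
  expect_true(estimate_feeding_rate_curve(fit, c(13.5, 23.9, 34.1),
                                          x_grid = 2)$extrapolated)
})

test_that("two-state transition fit corroborates the feeding-model slope sign", {
  d <- simulate_feeding_series(n_individuals = 6, n_dives = 250,
                               slope = 0.6, seed = 41)
  d$start_h <- d$time_h
  fit2 <- fit_transition_model(d, n_states = 2)
  # transitions into feeding get more likely, out of feeding less, as FTLE rises
  expect_gt(fit2$beta[1, 2, 2], 0)
  expect_lt(fit2$beta[2, 1, 2], 0)
  glm_fit <- fit_feeding_model(d, random = "none", correlation = FALSE)
  expect_gt(glm_fit$slope, 0)
})
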