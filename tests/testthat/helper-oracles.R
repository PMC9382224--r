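# Independent oracles used across the suite. These deliberately avoid the
# package's own integration/statistics code paths.

# fixed-step RK4 on the closed-form double-gyre velocity (km, hours)
rk4_double_gyre <- function(x, y, t0, t1, nstep, A = 0.1, eps = 0.25,
                            omega = 2 * pi / 10) {
  h <- (t1 - t0) / nstep
  t <- t0
  for (k in seq_len(nstep)) {
    k1 <- double_gyre_velocity(x, y, t, A, eps, omega)
    k2 <- double_gyre_velocity(x + h / 2 * k1$u, y + h / 2 * k1$v, t + h / 2,
                               A, eps, omega)
    k3 <- double_gyre_velocity(x + h / 2 * k2$u, y + h / 2 * k2$v, t + h / 2,
                               A, eps, omega)
    k4 <- double_gyre_velocity(x + h * k3$u, y + h * k3$v, t + h, A, eps, omega)
    x <- x + h / 6 * (k1$u + 2 * k2$u + 2 * k3$u + k4$u)
    y <- y + h / 6 * (k1$v + 2 * k2$v + 2 * k3$v + k4$v)
    t <- t + h
  }
  list(x = x, y = y)
}

# dense finite-difference FTLE oracle at points (gx, gy): four auxiliary
# tracers at +/- delta around each point, advected by fixed-step RK4 on the
# closed-form velocity, then the Cauchy-Green largest eigenvalue
ftle_oracle_double_gyre <- function(gx, gy, t0, T_h, delta, nstep = 500) {
  G <- expand.grid(y = gy, x = gx)
  ox <- c(G$x - delta, G$x + delta, G$x, G$x)
  oy <- c(G$y, G$y, G$y - delta, G$y + delta)
  fin <- rk4_double_gyre(ox, oy, t0, t0 + T_h, nstep)
  n <- nrow(G)
  dXdx <- (fin$x[(n + 1):(2 * n)] - fin$x[1:n]) / (2 * delta)
  dYdx <- (fin$y[(n + 1):(2 * n)] - fin$y[1:n]) / (2 * delta)
  dXdy <- (fin$x[(3 * n + 1):(4 * n)] - fin$x[(2 * n + 1):(3 * n)]) / (2 * delta)
  dYdy <- (fin$y[(3 * n + 1):(4 * n)] - fin$y[(2 * n + 1):(3 * n)]) / (2 * delta)
  a <- dXdx^2 + dYdx^2
  b <- dXdx * dXdy + dYdx * dYdy
  c2 <- dXdy^2 + dYdy^2
  lmax <- ((a + c2) + sqrt((a - c2)^2 + 4 * b^2)) / 2
  matrix(log(lmax) / (2 * abs(T_h) / 24), length(gy), length(gx))
}

# brute-force one-sided two-sample KS statistic (equal weights):
# sup_x [F_background(x) - F_whale(x)] by a double loop over pooled points
ks_brute <- function(whale, background) {
  xs <- sort(unique(c(whale, background)))
  d <- vapply(xs, function(x)
    mean(background <= x) - mean(whale <= x), numeric(1))
  max(c(0, d))
}

# exhaustive minimal-removal GPS filter for n <= 12 fixes: largest subset
# with all consecutive pairs below the speed cap; lexicographically earliest
# among ties
gps_filter_brute <- function(gps, max_speed, planar = TRUE) {
  n <- nrow(gps)
  speed_ok <- function(i, j) {
    d_m <- if (planar) {
      sqrt((gps$lon[j] - gps$lon[i])^2 + (gps$lat[j] - gps$lat[i])^2) * 1000
    } else {
      geosphere::distGeo(c(gps$lon[i], gps$lat[i]), c(gps$lon[j], gps$lat[j]))
    }
    d_m / ((gps$time_h[j] - gps$time_h[i]) * 3600) <= max_speed
  }
  best <- integer(0)
  for (m in (2^n - 1):1) {
    idx <- which(bitwAnd(m, 2^(0:(n - 1))) > 0)
    if (length(idx) <= length(best)) next
    valid <- TRUE
    if (length(idx) > 1)
      for (k in seq_len(length(idx) - 1))
        if (!speed_ok(idx[k], idx[k + 1])) { valid <- FALSE; break }
    if (valid) best <- idx
  }
  # rescan at the best size for the lexicographically earliest subset
  sz <- length(best)
  cands <- list()
  for (m in 1:(2^n - 1)) {
    idx <- which(bitwAnd(m, 2^(0:(n - 1))) > 0)
    if (length(idx) != sz) next
    valid <- TRUE
    if (length(idx) > 1)
      for (k in seq_len(length(idx) - 1))
        if (!speed_ok(idx[k], idx[k + 1])) { valid <- FALSE; break }
    if (valid) cands[[length(cands) + 1]] <- idx
  }
  ord <- do.call(rbind, cands)
  ord[do.call(order, as.data.frame(ord))[1], ]
}

# logistic-regression MLE via direct optimisation (oracle for the GLM
# reduction of the feeding model)
logistic_mle <- function(y, x) {
  nll <- function(th) {
    eta <- th[1] + th[2] * x
    -sum(y * eta - log1p(exp(eta)))
  }
  optim(c(0, 0), nll, method = "BFGS", control = list(reltol = 1e-14))$par
}

# power-iteration stationary distribution oracle
stationary_power <- function(G, iters = 20000) {
  p <- rep(1 / nrow(G), nrow(G))
  for (k in seq_len(iters)) p <- as.vector(p %*% G)
  p / sum(p)
}

# small planar dive/gps fixture shared by biologging tests
make_square_depth <- function(segments) {
  # segments: list of c(depth, n_seconds)
  depth <- unlist(lapply(segments, function(s) rep(s[1], s[2])))
  tibble::tibble(time_s = seq_along(depth) - 1, depth_m = depth)
}
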