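#' Fit a supervised covariate-dependent transition model
#'
#' With behavioural states known a priori (supervised), the hidden-Markov
#' likelihood factorizes over origin states: for each origin state the
#' observed next state follows a multinomial logit in FTLE at the origin
#' dive, with the self-transition as the reference category. Each origin's
#' coefficients are estimated by maximum likelihood (BFGS with analytic
#' gradient); per-individual dive sequences contribute independently -- the
#' last dive of one individual never transitions into the first of another.
#'
#' @param dives State-labelled dive table ordered in time within
#'   `individual`, with `state` (factor from
#'   [normalize_and_label_states()]), `ftle` and `start_h`; for
#'   `n_states = 2` the `feeding` flag defines the two states.
#' @param n_states 4 (default) or 2.
#' @return A `transition_model`: coefficient array `beta[i, j, 1:2]`
#'   (intercept, FTLE slope; zero diagonal), matching standard errors,
#'   per-origin covariance matrices, transition counts and state labels.
#' @export
fit_transition_model <- function(dives, n_states = 4) {
  d <- as_tibble(dives)
  if (!"individual" %in% names(d)) d$individual <- "all"
  if (n_states == 2) {
    if (!"feeding" %in% names(d)) abort("n_states = 2 needs a feeding column")
    s <- ifelse(d$feeding, 2L, 1L)
    labels <- c("non-feeding", "feeding")
  } else if (n_states == 4) {
    if (!"state" %in% names(d)) abort("n_states = 4 needs a state column")
    s <- as.integer(factor(as.character(d$state),
                           levels = c("non-feeding", "light", "moderate", "heavy")))
    labels <- c("non-feeding", "light", "moderate", "heavy")
  } else abort("n_states must be 2 or 4")
  S <- as.integer(n_states)
  d$s <- s
  d <- d[order(d$individual, d$start_h), ]
  from <- integer(0); to <- integer(0); x <- numeric(0)
  for (id in unique(d$individual)) {
    di <- d[d$individual == id, ]
    okpair <- !is.na(di$s[-nrow(di)]) & !is.na(di$s[-1]) & !is.na(di$ftle[-nrow(di)])
    from <- c(from, di$s[-nrow(di)][okpair])
    to <- c(to, di$s[-1][okpair])
    x <- c(x, di$ftle[-nrow(di)][okpair])
  }
  counts <- table(factor(from, 1:S), factor(to, 1:S))
  if (any(rowSums(counts) == 0))
    abort(sprintf("origin state(s) with no outgoing transitions: %s",
                  paste(labels[rowSums(counts) == 0], collapse = ", ")))
  beta <- array(0, c(S, S, 2)); se <- array(NA_real_, c(S, S, 2))
  vcovs <- vector("list", S)
  for (i in seq_len(S)) {
    sel <- from == i
    xi <- x[sel]; yi <- to[sel]
    alts <- setdiff(seq_len(S), i)
    zero_dest <- alts[!(alts %in% unique(yi))]
    if (length(zero_dest))
      warn(sprintf("no observed %s -> %s transitions; those coefficients are weakly identified",
                   labels[i], paste(labels[zero_dest], collapse = ", ")))
    K <- length(alts)
    Y <- matrix(0, length(yi), K)
    for (k in seq_len(K)) Y[, k] <- as.numeric(yi == alts[k])
    nll <- function(th) {
      A <- matrix(th, K, 2)                     # alt x (intercept, slope)
      eta <- outer(rep(1, length(xi)), A[, 1]) + outer(xi, A[, 2])
      m <- pmax(apply(eta, 1, max), 0)
      lse <- m + log(exp(-m) + rowSums(exp(eta - m)))
      -sum(rowSums(Y * eta) - lse)
    }
    grad <- function(th) {
      A <- matrix(th, K, 2)
      eta <- outer(rep(1, length(xi)), A[, 1]) + outer(xi, A[, 2])
      m <- pmax(apply(eta, 1, max), 0)
      den <- exp(-m) + rowSums(exp(eta - m))
      P <- exp(eta - m) / den
      R <- P - Y
      c(colSums(R), colSums(R * xi))
    }
    op <- optim(rep(0, 2 * K), nll, grad, method = "BFGS", hessian = TRUE,
                control = list(maxit = 500, reltol = 1e-12))
    V <- tryCatch(solve(op$hessian), error = function(e) matrix(NA_real_, 2 * K, 2 * K))
    A <- matrix(op$par, K, 2)
    SEm <- matrix(sqrt(pmax(diag(V), 0)), K, 2)
    for (k in seq_len(K)) {
      beta[i, alts[k], ] <- A[k, ]
      se[i, alts[k], ] <- SEm[k, ]
    }
    vcovs[[i]] <- V
  }
  structure(list(n_states = S, beta = beta, se = se, vcov = vcovs,
                 labels = labels, counts = counts,
                 n_transitions = length(from)),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat(sprintf("<transition_model> %d states, %d transitions\n",
              x$n_states, x$n_transitions))
  cat("FTLE slopes (from -> to):\n")
  sl <- x$beta[, , 2]
  dimnames(sl) <- list(x$labels, x$labels)
  print(round(sl, 3))
  invisible(x)
}

#' Transition matrix at a given FTLE value
#'
#' Softmax over each row of the multinomial-logit coefficients with the
#' diagonal (self-transition) as reference; every row sums to 1.
#'
#' @param model A `transition_model`, or a raw `S x S x 2` coefficient
#'   array with a zero diagonal.
#' @param x FTLE value(s) in day^-1.
#' @return An `S x S` matrix for scalar `x`, else an `S x S x length(x)`
#'   array.
#' @export
transition_matrix <- function(model, x) {
  beta <- if (inherits(model, "transition_model")) model$beta else model
  out <- tm_from_beta(beta, x)
  if (length(x) == 1) out[, , 1] else out
}

#' Stationary distribution of a transition matrix
#'
#' Solves `pi %*% G = pi`, `sum(pi) = 1` by the constrained linear system.
#' A reducible chain (some state unreachable) is rejected with a diagnosis.
#'
#' @param G Row-stochastic square matrix.
#' @return Numeric stationary probability vector.
#' @export
stationary_probabilities <- function(G) {
  S <- nrow(G)
  if (any(abs(rowSums(G) - 1) > 1e-8)) abort("G rows must sum to 1")
  M <- diag(S) + G
  P <- M
  for (k in seq_len(S - 1)) P <- P %*% M
  if (any(P <= 0))
    abort(sprintf("reducible transition matrix: state(s) %s unreachable",
                  paste(which(colSums(P > 0) < S), collapse = ", ")))
  A <- rbind(t(diag(S) - G), rep(1, S))
  pi_hat <- qr.solve(A, c(rep(0, S), 1))
  pi_hat / sum(pi_hat)
}

#' Weighted quantile (inverse weighted ECDF)
#'
#' Smallest sample value whose cumulative normalized weight reaches `p`.
#'
#' @param x Values.
#' @param w Non-negative weights.
#' @param p Probabilities.
#' @return Quantile(s).
#' @export
weighted_quantile <- function(x, w, p) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(p, function(pp) x[o][which(cw >= pp - 1e-12)[1]], numeric(1))
}

#' Mean feeding rate of the light/moderate/heavy states
#'
#' Splits the pooled, individually weighted distribution of feeding-dive
#' rates at its weighted 25th and 75th percentiles and returns the weighted
#' mean rate of each segment: light (rate at or below the 25th percentile),
#' moderate (between the quartiles, upper bound inclusive) and heavy (above
#' the 75th percentile).
#'
#' @param rates Feeding-dive rates (lunges h^-1), feeding dives only.
#' @param weights Per-dive weights (e.g. `w_feeding` from
#'   [compute_weights()]); equal by default.
#' @return Tibble with `state`, `mean_rate`, `lo`, `hi`, `weight`.
#' @export
weighted_state_feeding_rates <- function(rates, weights = NULL) {
  ok <- !is.na(rates)
  rates <- rates[ok]
  if (!length(rates)) abort("no feeding rates supplied")
  w <- if (is.null(weights)) rep(1, length(rates)) else weights[ok]
  q <- weighted_quantile(rates, w, c(0.25, 0.75))
  seg <- ifelse(rates <= q[1], "light",
                ifelse(rates <= q[2], "moderate", "heavy"))
  out <- lapply(c("light", "moderate", "heavy"), function(s) {
    i <- seg == s
    if (!any(i)) abort(sprintf("empty %s segment", s))
    tibble(state = s, mean_rate = sum(rates[i] * w[i]) / sum(w[i]),
           lo = min(rates[i]), hi = max(rates[i]),
           weight = sum(w[i]) / sum(w))
  })
  out <- dplyr::bind_rows(out)
  attr(out, "quantiles") <- q
  out
}

#' Overall feeding rate from stationary probabilities
#'
#' `rate = sum(pi_state * rate_state)` with the non-feeding state
#' contributing rate 0.
#'
#' @param probs Stationary probabilities over (non-feeding, light, moderate,
#'   heavy).
#' @param state_rates Mean rates (lunges h^-1) of the three feeding states.
#' @return Estimated overall feeding rate (lunges h^-1).
#' @export
feeding_rate_from_probs <- function(probs, state_rates) {
  stopifnot(length(probs) == length(state_rates) + 1)
  sum(probs * c(0, state_rates))
}

#' Estimated feeding-rate curve over an FTLE grid
#'
#' For each FTLE value on the grid, the fitted transition matrix yields
#' stationary state probabilities, and the estimated overall feeding rate is
#' their convex combination with the state mean rates (non-feeding
#' contributes 0). Confidence curves re-evaluate the whole calculation at
#' the elementwise interval endpoints `beta +/- 1.96 SE`. Grid values
#' outside `[-1.25, 1.5]` day^-1 are computed but flagged as extrapolation.
#'
#' @param model A fitted `transition_model` (4 states).
#' @param state_rates Mean rates of light/moderate/heavy (lunges h^-1),
#'   increasing.
#' @param x_grid FTLE grid (default `seq(-1.25, 1.5, by = 0.01)`).
#' @return A `stationary_curve` tibble: `x`, one `pi_*` column per state,
#'   `rate`, `rate_lo`, `rate_hi`, `extrapolated`.
#' @export
estimate_feeding_rate_curve <- function(model, state_rates,
                                        x_grid = seq(-1.25, 1.5, by = 0.01)) {
  stopifnot(inherits(model, "transition_model"))
  if (model$n_states != 4) abort("feeding-rate curve needs the 4-state model")
  if (is.unsorted(state_rates) || any(state_rates <= 0))
    abort("state_rates must be positive and increasing")
  curve_for <- function(beta) {
    G <- tm_from_beta(beta, x_grid)
    t(vapply(seq_along(x_grid),
             function(q) stationary_probabilities(G[, , q]), numeric(4)))
  }
  P <- curve_for(model$beta)
  rate <- as.vector(P %*% c(0, state_rates))
  blo <- model$beta - 1.96 * ifelse(is.na(model$se), 0, model$se)
  bhi <- model$beta + 1.96 * ifelse(is.na(model$se), 0, model$se)
  for (i in 1:4) { blo[i, i, ] <- 0; bhi[i, i, ] <- 0 }
  r1 <- as.vector(curve_for(blo) %*% c(0, state_rates))
  r2 <- as.vector(curve_for(bhi) %*% c(0, state_rates))
  out <- tibble(x = x_grid,
                pi_nonfeeding = P[, 1], pi_light = P[, 2],
                pi_moderate = P[, 3], pi_heavy = P[, 4],
                rate = rate,
                rate_lo = pmin(r1, r2, rate), rate_hi = pmax(r1, r2, rate),
                extrapolated = x_grid < -1.25 - 1e-9 | x_grid > 1.5 + 1e-9)
  class(out) <- c("stationary_curve", class(out))
  attr(out, "state_rates") <- state_rates
  out
}
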