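#' Latent quadrature grid
#'
#' The discrete latent distribution is a set of `q` equally spaced support
#' points carrying nonnegative weights that sum to one. The default follows
#' the study settings: 10 points on [-4, 4] (spacing 8/9) with weights
#' proportional to the standard normal density.
#'
#' @param q number of support points (>= 2).
#' @param range numeric length-2 interval for the points.
#' @param weights `"normal"` (normal-density weights, the conventional
#'   default) or `"uniform"`, or a numeric vector of `q` nonnegative weights.
#' @return a tibble with columns `point` and `weight`.
#' @examples
#' latent_grid()
#' latent_grid(10, weights = "uniform")
#' @export
latent_grid <- function(q = 10, range = c(-4, 4), weights = "normal") {
  stopifnot(q >= 2, length(range) == 2, range[1] < range[2])
  points <- seq(range[1], range[2], length.out = q)
  w <- if (is.numeric(weights)) {
    stopifnot(length(weights) == q)
    weights
  } else if (identical(weights, "normal")) {
    dnorm(points)
  } else if (identical(weights, "uniform")) {
    rep(1, q)
  } else {
    stop("unknown `weights` specification", call. = FALSE)
  }
  check_grid_weights(w)
  tibble(point = points, weight = w / sum(w))
}

check_grid_weights <- function(w) {
  if (any(!is.finite(w)) || any(w < 0) || sum(w) <= 0) {
    stop("grid weights must be nonnegative, finite and not all zero", call. = FALSE)
  }
  invisible(w)
}

check_grid <- function(grid) {
  stopifnot(is.data.frame(grid), all(c("point", "weight") %in% names(grid)))
  check_grid_weights(grid$weight)
  if (abs(sum(grid$weight) - 1) > 1e-12) {
    stop("grid weights must sum to 1", call. = FALSE)
  }
  d <- diff(grid$point)
  if (any(d <= 0) || (length(d) > 1 && max(abs(d - d[1])) > 1e-9)) {
    stop("grid points must be strictly increasing with constant spacing", call. = FALSE)
  }
  invisible(grid)
}

#' 2PL correct-response probability
#'
#' Evaluates pi(z) = exp(a (z - b)) / (1 + exp(a (z - b))) overflow-safely.
#' Arguments recycle as in arithmetic.
#'
#' @param a item discrimination (> 0).
#' @param b item difficulty.
#' @param z latent ability.
#' @return probabilities in (0, 1).
#' @examples
#' response_probability(1, 0, 0)      # 0.5
#' response_probability(1.7, 0, 1)    # 0.8455
#' @export
response_probability <- function(a, b, z) {
  if (!all(is.finite(a)) || !all(is.finite(b)) || !all(is.finite(z)) || any(a <= 0)) {
    stop("parameters must be finite with a > 0", call. = FALSE)
  }
  plogis(a * (z - b))
}

# Per-point item log-probabilities: k x q matrices of log pi and log(1 - pi),
# computed via plogis(log.p = TRUE) for stability in the tails.
item_logprobs <- function(a, b, points) {
  eta <- outer(a, points) - a * b # k x q, eta_iq = a_i (z_q - b_i)
  list(lp = plogis(eta, log.p = TRUE),
       lq = plogis(-eta, log.p = TRUE))
}

# Per-testee per-point conditional log-likelihoods: n x q matrix with
# logL_jq = sum_i x_ij log pi_iq + (1 - x_ij) log(1 - pi_iq), computed as
# x (lp - lq) + colSums(lq) with a single matrix product.
pattern_loglik <- function(x, lp, lq) {
  A <- x %*% (lp - lq)
  sweep(A, 2, colSums(lq), "+")
}

#' Marginal log-likelihood of the 2PL over a discrete latent distribution
#'
#' Computes sum_j log sum_q W_q prod_i pi_i(z_q)^x_ij (1 - pi_i(z_q))^(1 -
#' x_ij) in log space (log-sum-exp over support points), so small pattern
#' likelihoods never underflow.
#'
#' @param data response tibble or 0/1 matrix.
#' @param items tibble of item parameters (columns `a`, `b`).
#' @param grid latent grid (see [latent_grid()]).
#' @return the marginal log-likelihood (a single number).
#' @export
marginal_log_likelihood <- function(data, items, grid) {
  x <- response_matrix(data)
  check_grid(grid)
  if (nrow(items) != ncol(x)) stop("item count mismatch", call. = FALSE)
  lpq <- item_logprobs(items$a, items$b, grid$point)
  e_step_core(x, lpq$lp, lpq$lq, grid$weight)$loglik
}

# E-step on precomputed log-probabilities. Returns the marginal log-likelihood,
# the n x q posterior matrix, expected testee counts m (length q) and expected
# correct counts r (k x q).
e_step_core <- function(x, lp, lq, w) {
  A <- pattern_loglik(x, lp, lq)
  A <- sweep(A, 2, log(w), "+")
  A[, w == 0] <- -Inf
  top <- A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
  P <- exp(A - top)
  rs <- rowSums(P)
  if (any(rs == 0) || any(!is.finite(top))) {
    stop("posterior mass underflow in E-step", call. = FALSE)
  }
  loglik <- sum(log(rs) + top)
  P <- P / rs
  list(loglik = loglik, posterior = P, m = colSums(P), r = crossprod(x, P))
}

#' Bock-Aitkin E-step
#'
#' Given current item parameters and latent weights, computes each testee's
#' posterior distribution over the support points, P(z_q | x_j) proportional
#' to W_q L_jq, and the expected counts that drive the M-step: m_q = sum_j
#' P(z_q | x_j) (expected testees at point q) and r_iq = sum_j x_ij
#' P(z_q | x_j) (expected correct responses to item i at point q).
#'
#' @inheritParams marginal_log_likelihood
#' @return a list with `loglik`, `posterior` (n x q matrix), `m` (length-q
#'   vector summing to n), and `r` (k x q matrix).
#' @export
e_step <- function(data, items, grid) {
  x <- response_matrix(data)
  check_grid(grid)
  if (nrow(items) != ncol(x)) stop("item count mismatch", call. = FALSE)
  lpq <- item_logprobs(items$a, items$b, grid$point)
  e_step_core(x, lpq$lp, lpq$lq, grid$weight)
}

# Newton maximization of one item's expected complete-data log-likelihood
# sum_q r_q log pi(z_q) + (m_q - r_q) log(1 - pi(z_q)) in the slope-intercept
# parameterization logit pi = alpha + beta z (beta = a, alpha = -a b).
# The clamps a in [0.05, 10], b in [-10, 10] act as a feasible box inside the
# safeguarded search (infeasible or non-improving steps are halved), so every
# accepted update is ascent: degenerate expected counts (all correct or all
# incorrect) end flagged on the boundary instead of diverging.
item_newton <- function(r, m, points, a0, b0, max_iter = 50) {
  obj <- function(alpha, beta) {
    eta <- alpha + beta * points
    sum(r * plogis(eta, log.p = TRUE) + (m - r) * plogis(-eta, log.p = TRUE))
  }
  feasible <- function(alpha, beta) {
    is.finite(alpha) && is.finite(beta) &&
      beta >= 0.05 && beta <= 10 && abs(alpha) <= 10 * beta
  }
  # project the starting point into the box (a no-op after the first cycle)
  a0 <- min(max(a0, 0.05), 10)
  b0 <- min(max(b0, -10), 10)
  alpha <- -a0 * b0
  beta <- a0
  f <- obj(alpha, beta)
  for (it in seq_len(max_iter)) {
    p <- plogis(alpha + beta * points)
    res <- r - m * p
    g <- c(sum(res), sum(res * points))
    wq <- m * p * (1 - p)
    h11 <- sum(wq); h12 <- sum(wq * points); h22 <- sum(wq * points^2)
    det <- h11 * h22 - h12^2
    if (!is.finite(det) || det <= 1e-12 * max(h11 * h22, 1e-300)) break
    step <- c(h22 * g[1] - h12 * g[2], -h12 * g[1] + h11 * g[2]) / det
    accepted <- FALSE
    for (half in 0:40) {
      an <- alpha + step[1]; bn <- beta + step[2]
      if (feasible(an, bn)) {
        fn <- obj(an, bn)
        if (is.finite(fn) && fn >= f) {
          alpha <- an; beta <- bn
          accepted <- TRUE
          break
        }
      }
      step <- step / 2
    }
    if (!accepted) break
    done <- fn - f < 1e-12 && max(abs(step)) < 1e-9
    f <- fn
    if (done || max(abs(step)) < 1e-10) break
  }
  a <- beta
  b <- -alpha / beta
  flag <- a <= 0.05 + 1e-9 || a >= 10 - 1e-9 || abs(b) >= 10 - 1e-9
  list(a = a, b = b, flagged = flag)
}

#' Bock-Aitkin M-step for item parameters
#'
#' Maximizes, for each item, the expected complete-data log-likelihood
#' sum_q r_iq log pi_i(z_q) + (m_q - r_iq) log(1 - pi_i(z_q)) by safeguarded
#' Newton iterations (step halving) in the slope-intercept parameterization.
#' Degenerate expected counts (all correct or all incorrect) give clamped
#' estimates, a in [0.05, 10] and b in [-10, 10], with a `flagged` marker.
#'
#' @param counts a list with `r` (k x q expected correct counts) and `m`
#'   (length-q expected testee counts), as produced by [e_step()].
#' @param grid latent grid.
#' @param items current item estimates (tibble with `a`, `b`), used as the
#'   Newton starting point.
#' @return a tibble with columns `item`, `a`, `b`, `flagged`.
#' @export
m_step_items <- function(counts, grid, items) {
  k <- nrow(counts$r)
  stopifnot(nrow(items) == k, length(counts$m) == nrow(grid))
  ms <- m_step_items_core(counts$r, counts$m, grid$point, items$a, items$b)
  tibble(item = seq_len(k), a = ms$a, b = ms$b, flagged = ms$flagged)
}

m_step_items_core <- function(r, m, points, a, b) {
  k <- nrow(r)
  a_new <- numeric(k); b_new <- numeric(k); flagged <- logical(k)
  for (i in seq_len(k)) {
    ni <- item_newton(r[i, ], m, points, a[i], b[i])
    a_new[i] <- ni$a; b_new[i] <- ni$b; flagged[i] <- ni$flagged
  }
  list(a = a_new, b = b_new, flagged = flagged)
}

#' Empirical-histogram M-step for the latent weights
#'
#' The weight at each support point is updated to the average posterior mass
#' there: W_q = (1/n) sum_j P(z_q | x_j). This is the maximum-likelihood
#' update of the discrete latent distribution.
#'
#' @param posterior n x q matrix of row-normalized posterior weights.
#' @return a numeric vector of q nonnegative weights summing to 1.
#' @export
m_step_weights <- function(posterior) {
  w <- colMeans(posterior)
  w / sum(w)
}

#' Standardize the latent metric
#'
#' The 2PL with a free latent distribution is identified only up to an affine
#' transformation of the latent scale. At the end of an empirical-histogram
#' fit the metric is anchored to mean 0, SD 1: with m and s the mean and SD
#' of the discrete distribution, items transform as a <- a * s,
#' b <- (b - m) / s, and the weight distribution is re-expressed on the
#' *fixed* original grid by monotone (piecewise-linear) interpolation of the
#' transformed cumulative weights under the histogram convention (each
#' weight occupies its grid cell uniformly).
#'
#' @param items item estimates (tibble with `a`, `b`).
#' @param grid latent grid.
#' @return a list with `items` (rescaled tibble) and `grid` (same points,
#'   re-expressed weights), plus `m` and `s`.
#' @export
standardize_metric <- function(items, grid) {
  check_grid(grid)
  std <- standardize_core(items$a, items$b, grid$weight, grid$point)
  items2 <- items
  items2$a <- std$a
  items2$b <- std$b
  list(items = items2, grid = tibble(point = grid$point, weight = std$w),
       m = std$m, s = std$s)
}

standardize_core <- function(a, b, w, z) {
  m <- sum(w * z)
  s2 <- sum(w * z^2) - m^2
  if (!is.finite(s2) || s2 <= 0) stop("degenerate latent distribution (SD <= 0)", call. = FALSE)
  s <- sqrt(s2)
  # histogram convention: weight q occupies the cell [z_q - dz/2, z_q + dz/2]
  # uniformly, so the CDF is piecewise linear with knots at the cell
  # boundaries; boundaries transform affinely and weights are read back off
  # the fixed grid's cells. An identity map (m = 0, s = 1) reproduces the
  # weights exactly.
  dz <- z[2] - z[1]
  bounds <- c(z[1] - dz / 2, z + dz / 2)
  bt <- (bounds - m) / s
  cdf_y <- c(0, cumsum(w))
  wnew <- diff(approx(bt, cdf_y, xout = bounds, rule = 2, ties = "ordered")$y)
  wnew[wnew < 0] <- 0
  list(a = a * s, b = (b - m) / s, w = wnew / sum(wnew), m = m, s = s)
}

#' Fit the 2PL by the Bock-Aitkin EM algorithm
#'
#' Marginal-maximum-likelihood estimation of the two-parameter logistic
#' model. With `method = "mml"` the latent distribution is held fixed at its
#' initial weights (by default a standard normal discretized on the grid).
#' With `method = "eh"` (empirical histogram) the weights are re-estimated in
#' every maximization step alongside the item parameters; at termination the
#' latent metric is standardized once to mean 0, SD 1 (items rescaled, the
#' weights re-expressed on the fixed grid), so every cycle is a pure EM step
#' and the log-likelihood trace is non-decreasing. Iteration stops
#' when the largest absolute between-cycle change over item parameters falls
#' below `criterion` (weights excluded from the criterion), or at
#' `max_cycles`.
#'
#' @param data response tibble or 0/1 matrix (one row per testee).
#' @param method `"eh"` or `"mml"`.
#' @param init an [initial_values()] object, or `NULL` for the conventional
#'   defaults (classical-test-theory item starts, normal-density weights).
#' @param criterion positive convergence threshold on the largest item
#'   parameter change; 1e-2 is the conventional default.
#' @param max_cycles maximum number of EM cycles (study setting: 10000).
#' @param grid latent grid; its weights are ignored in favour of
#'   `init$w0` / the default normal weights.
#' @return an object of class `ehirt_fit`: a list with `items` (tibble
#'   `item, a, b, flagged`), `grid` (final latent grid), `loglik_trace`
#'   (marginal log-likelihood at the start of each cycle), `loglik`,
#'   `n_cycles`, `converged`, `final_change`, `method`, `criterion`.
#' @examples
#' bank <- make_item_bank()
#' dat <- sim_dataset("normal", 300, 1, bank)
#' fit <- fit_2pl(dat$responses, method = "eh", criterion = 1e-2)
#' fit
#' tidy(fit)
#' @export
fit_2pl <- function(data, method = c("eh", "mml"), init = NULL,
                    criterion = 1e-2, max_cycles = 10000L,
                    grid = latent_grid(10)) {
  method <- match.arg(method)
  if (!is.numeric(criterion) || criterion < 0) stop("`criterion` must be >= 0", call. = FALSE)
  stopifnot(max_cycles >= 1)
  x <- response_matrix(data)
  check_grid(grid)
  k <- ncol(x)
  if (is.null(init)) {
    init <- initial_values(
      items = init_items("default", x),
      weights = init_weights("default", x, grid)
    )
  }
  stopifnot(inherits(init, "ehirt_init"))
  if (length(init$a0) != k) stop("initial values do not match the item count", call. = FALSE)
  if (length(init$w0) != nrow(grid)) stop("initial weights do not match the grid", call. = FALSE)

  # starting values live in the same feasible box the M-step search uses
  a <- pmin(pmax(init$a0, 0.05), 10)
  b <- pmin(pmax(init$b0, -10), 10)
  w <- init$w0 / sum(init$w0)
  points <- grid$point
  flagged <- rep(FALSE, k)
  change <- NA_real_
  converged <- FALSE
  cycle <- 0L
  trace <- numeric(max_cycles)
  while (cycle < max_cycles) {
    cycle <- cycle + 1L
    lpq <- item_logprobs(a, b, points)
    es <- e_step_core(x, lpq$lp, lpq$lq, w)
    trace[cycle] <- es$loglik
    ms <- m_step_items_core(es$r, es$m, points, a, b)
    a_new <- ms$a
    b_new <- ms$b
    flagged <- ms$flagged
    if (method == "eh") {
      w <- es$m / sum(es$m)
    }
    change <- max(abs(c(a_new - a, b_new - b)))
    a <- a_new
    b <- b_new
    if (is.finite(change) && change < criterion) {
      converged <- TRUE
      break
    }
  }
  if (method == "eh") {
    # identify the latent metric once at termination: every cycle above is a
    # pure EM step, so the trace is guaranteed non-decreasing
    std <- standardize_core(a, b, w, points)
    a <- std$a
    b <- std$b
    w <- std$w
  }
  lpq <- item_logprobs(a, b, points)
  structure(list(
    items = tibble(item = seq_len(k), a = a, b = b, flagged = flagged),
    grid = tibble(point = points, weight = w),
    loglik_trace = trace[seq_len(cycle)],
    loglik = e_step_core(x, lpq$lp, lpq$lq, w)$loglik,
    n_cycles = cycle,
    converged = converged,
    final_change = change,
    method = method,
    criterion = criterion,
    n = nrow(x)
  ), class = "ehirt_fit")
}

#' @export
print.ehirt_fit <- function(x, ...) {
  cat(sprintf("<ehirt_fit> 2PL via %s EM: %d items, n = %d\n",
              toupper(x$method), nrow(x$items), x$n))
  cat(sprintf("  %s after %d cycles (criterion %g, final change %.3g), logLik %.2f\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_cycles, x$criterion, x$final_change, x$loglik))
  invisible(x)
}

#' Tidy a 2PL fit
#'
#' `tidy()` returns one row per item with the estimated discrimination and
#' difficulty; `glance()` returns a one-row fit summary.
#'
#' @param x an `ehirt_fit`.
#' @param ... unused.
#' @return a tibble.
#' @method tidy ehirt_fit
#' @export
tidy.ehirt_fit <- function(x, ...) {
  out <- x$items
  names(out)[names(out) == "a"] <- "a_hat"
  names(out)[names(out) == "b"] <- "b_hat"
  out
}

#' @rdname tidy.ehirt_fit
#' @method glance ehirt_fit
#' @export
glance.ehirt_fit <- function(x, ...) {
  tibble(
    method = x$method,
    n = x$n,
    k = nrow(x$items),
    criterion = x$criterion,
    n_cycles = x$n_cycles,
    converged = x$converged,
    final_change = x$final_change,
    logLik = x$loglik
  )
}

#' Plot a 2PL fit
#'
#' Shows the estimated item characteristic curves and, below, the final
#' latent weight distribution.
#'
#' @param object an `ehirt_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ehirt_fit
#' @export
autoplot.ehirt_fit <- function(object, ...) {
  zs <- seq(-4, 4, length.out = 201)
  icc <- purrr::pmap_dfr(object$items, function(item, a, b, ...) {
    tibble(item = item, z = zs, p = response_probability(a, b, zs))
  })
  ggplot2::ggplot(icc, ggplot2::aes(x = .data$z, y = .data$p, group = .data$item)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_col(
      data = object$grid,
      mapping = ggplot2::aes(x = .data$point, y = .data$weight / max(.data$weight) * 0.3),
      inherit.aes = FALSE, alpha = 0.3, width = diff(object$grid$point)[1] * 0.9
    ) +
    ggplot2::labs(
      x = "latent ability z", y = "P(correct)",
      title = sprintf("Estimated ICCs (%s) with final latent weights", toupper(object$method))
    )
}

#' Write fit results to CSV
#'
#' Writes `item,a_hat,b_hat` and, alongside, `point,weight` for the final
#' latent grid.
#'
#' @param fit an `ehirt_fit`.
#' @param items_path,grid_path output CSV paths.
#' @return `fit`, invisibly.
#' @export
write_fit <- function(fit, items_path, grid_path) {
  stopifnot(inherits(fit, "ehirt_fit"))
  readr::write_csv(tidy(fit)[, c("item", "a_hat", "b_hat")], items_path)
  readr::write_csv(fit$grid, grid_path)
  invisible(fit)
}
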