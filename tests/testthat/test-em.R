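test_that("2PL response probability matches its closed form", {
  expect_equal(response_probability(1, 0, 0), 0.5)
  expect_equal(response_probability(2.7, 1.3, 1.3), 0.5) # z = b for any a
  expect_equal(response_probability(1.7, 0, 1), exp(1.7) / (1 + exp(1.7)))
  expect_equal(response_probability(1.7, 0, 1), 0.8455, tolerance = 1e-4)
  z <- seq(-6, 6, by = 0.5)
  expect_true(all(diff(response_probability(2, 0.3, z)) > 0)) # increasing in z
  expect_equal(response_probability(3, 0, c(-200, 200)), c(0, 1)) # overflow-safe
  expect_error(response_probability(Inf, 0, 0), "finite")
  expect_error(response_probability(-1, 0, 0), "finite")
})

test_that("marginal log-likelihood reduces to the Bernoulli log-likelihood on a point mass", {
  x <- rbind(c(1, 0, 1), c(1, 1, 0))
  items <- tibble::tibble(a = c(0.8, 1.2, 2), b = c(-0.5, 0, 1))
  z0 <- 0.4
  grid1 <- tibble::tibble(point = z0, weight = 1)
  p <- response_probability(items$a, items$b, z0)
  bern <- sum(t(x) * log(p) + t(1 - x) * log(1 - p))
  expect_equal(marginal_log_likelihood(x, items, grid1), bern)
})

test_that("a symmetric two-point grid gives log(1/2) for a single response", {
  x <- matrix(1, 1, 1)
  items <- tibble::tibble(a = 1, b = 0)
  grid <- tibble::tibble(point = c(-1, 1), weight = c(0.5, 0.5))
  # sigma(-1) + sigma(1) = 1, so the mixture likelihood is exactly 1/2
  expect_equal(marginal_log_likelihood(x, items, grid), log(0.5))
})

test_that("log-space marginal likelihood equals the brute-force double loop", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:20, 1); k <- sample(2:5, 1); q <- sample(2:5, 1)
    x <- matrix(rbinom(n * k, 1, 0.5), n, k)
    a <- runif(k, 0.4, 2.5); b <- runif(k, -2, 2)
    points <- seq(-3, 3, length.out = q)
    w <- runif(q); w <- w / sum(w)
    oracle <- brute_marginal_loglik(x, a, b, points, w)
    got <- marginal_log_likelihood(x, tibble::tibble(a = a, b = b),
                                   tibble::tibble(point = points, weight = w))
    expect_equal(got, oracle, tolerance = 1e-10)
  }
})

test_that("E-step posteriors are Bayes posteriors with conserved mass", {
  # degenerate one-point grid: every posterior is 1 and m = n
  x <- matrix(rbinom(30, 1, 0.6), 10, 3)
  items <- tibble::tibble(a = c(1, 1.5, 0.7), b = c(0, 0.5, -1))
  es1 <- e_step(x, items, tibble::tibble(point = 0.2, weight = 1))
  expect_equal(as.numeric(es1$posterior), rep(1, 10))
  expect_equal(as.numeric(es1$m), 10)

  # 2 testees x 1 item on {-1, 1}: hand-computed Bayes posteriors
  x2 <- matrix(c(1, 0), 2, 1)
  it2 <- tibble::tibble(a = 1, b = 0)
  g2 <- tibble::tibble(point = c(-1, 1), weight = c(0.5, 0.5))
  es2 <- e_step(x2, it2, g2)
  s <- plogis(c(-1, 1))
  expect_equal(es2$posterior[1, ], s, ignore_attr = TRUE)        # correct response
  expect_equal(es2$posterior[2, ], rev(s), ignore_attr = TRUE)   # incorrect response
  expect_equal(as.numeric(es2$r[1, ]), s)
  expect_equal(sum(es2$m), 2)

  # conservation across random instances
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(10:60, 1)
    x <- matrix(rbinom(n * 4, 1, 0.5), n, 4)
    es <- e_step(x, tibble::tibble(a = runif(4, 0.5, 2), b = rnorm(4)), latent_grid(7))
    expect_equal(sum(es$m), n, tolerance = 1e-8)
    expect_equal(rowSums(es$posterior), rep(1, n), tolerance = 1e-12)
    expect_true(all(es$r >= -1e-12 & es$r <= rep(es$m, each = 4) + 1e-12))
  }
})

test_that("item M-step is a fixed point at counts generated from the truth", {
  g <- latent_grid(10)
  m <- 500 * g$weight
  for (pars in list(c(1.6, 0.4), c(0.7, -1.2), c(2.8, 2.0))) {
    r <- matrix(m * response_probability(pars[1], pars[2], g$point), 1)
    ms <- m_step_items(list(r = r, m = m), g, tibble::tibble(a = 1, b = 0))
    expect_equal(ms$a, pars[1], tolerance = 1e-6)
    expect_equal(ms$b, pars[2], tolerance = 1e-6)
    expect_false(ms$flagged)
  }
})

test_that("symmetric expected counts give zero difficulty", {
  g <- latent_grid(10) # symmetric points, symmetric normal weights
  m <- 200 * g$weight
  r <- matrix(m * response_probability(1, 0, g$point), 1)
  ms <- m_step_items(list(r = r, m = m), g, tibble::tibble(a = 1.4, b = 0.8))
  expect_equal(ms$b, 0, tolerance = 1e-7)
})

test_that("degenerate expected counts are clamped, not divergent", {
  g <- latent_grid(10)
  m <- 100 * g$weight
  r_all <- matrix(m, 1) # every expected response correct
  ms <- m_step_items(list(r = r_all, m = m), g, tibble::tibble(a = 1, b = 0))
  expect_true(is.finite(ms$a) && is.finite(ms$b))
  expect_true(ms$a <= 10 && abs(ms$b) <= 10)
})

test_that("weight M-step returns posterior column means", {
  post <- rbind(c(0.2, 0.8), c(0.5, 0.5), c(0.9, 0.1))
  expect_equal(m_step_weights(post), colMeans(post))
  expect_equal(sum(m_step_weights(post)), 1, tolerance = 1e-12)
  shared <- matrix(rep(c(0.3, 0.7), each = 5), 5, 2)
  expect_equal(m_step_weights(shared), c(0.3, 0.7))
})

test_that("metric standardization is the identity at mean 0, SD 1", {
  g <- latent_grid(10) # normal weights already have discrete mean 0, sd < 1
  w <- g$weight
  # construct weights with exact mean 0 and SD 1 on the grid
  z <- g$point
  # symmetric weights have mean 0; rescale spread by mixing with endpoints
  f <- function(lam) {
    ww <- (1 - lam) * w + lam * c(0.5, rep(0, 8), 0.5)
    sum(ww * z^2) - 1
  }
  lam <- uniroot(f, c(0, 1), tol = 1e-13)$root
  ww <- (1 - lam) * w + lam * c(0.5, rep(0, 8), 0.5)
  gg <- tibble::tibble(point = z, weight = ww)
  items <- tibble::tibble(a = c(1, 2), b = c(0.3, -1))
  std <- standardize_metric(items, gg)
  expect_equal(std$m, 0, tolerance = 1e-10)
  expect_equal(std$s, 1, tolerance = 1e-10)
  expect_equal(std$items$a, items$a, tolerance = 1e-9)
  expect_equal(std$items$b, items$b, tolerance = 1e-9)
  expect_equal(std$grid$weight, ww, tolerance = 1e-8)
})

test_that("standardization preserves response probabilities at matched quantiles", {
  g <- latent_grid(10, weights = "uniform")
  items <- tibble::tibble(a = c(0.9, 2.1), b = c(-0.4, 1.1))
  std <- standardize_metric(items, g)
  z <- c(-2, 0, 1.5)
  zt <- (z - std$m) / std$s
  for (i in 1:2) {
    expect_equal(response_probability(std$items$a[i], std$items$b[i], zt),
                 response_probability(items$a[i], items$b[i], z))
  }
})

test_that("rebinned weights track a known affine relocation within one grid spacing", {
  g <- latent_grid(10)
  set.seed(3)
  w <- runif(10); w <- w / sum(w)
  gg <- tibble::tibble(point = g$point, weight = w)
  std <- standardize_metric(tibble::tibble(a = 1, b = 0), gg)
  # oracle: place the transformed cell boundaries directly and compare CDFs
  dz <- g$point[2] - g$point[1]
  bounds <- c(g$point[1] - dz / 2, g$point + dz / 2)
  bt <- (bounds - std$m) / std$s
  cdf_direct <- stats::stepfun(bt[-1], cumsum(c(0, w)))
  cdf_new <- cumsum(std$grid$weight)
  for (q in 1:10) {
    # interpolated CDF at each boundary within one cell of the relocated CDF
    expect_lt(abs(cdf_new[q] - cdf_direct(bounds[q + 1])), max(w))
  }
  expect_equal(sum(std$grid$weight), 1, tolerance = 1e-12)
})

test_that("EM ascends the marginal likelihood and respects nested stopping rules", {
  for (tld in c("normal", "skew")) {
    ds <- toy_dataset(200, tld)
    for (method in c("eh", "mml")) {
      f_loose <- fit_2pl(ds$responses, method, criterion = 1e-2)
      f_tight <- fit_2pl(ds$responses, method, criterion = 1e-4)
      expect_true(all(diff(f_loose$loglik_trace) > -1e-8))
      expect_true(all(diff(f_tight$loglik_trace) > -1e-8))
      expect_gte(f_tight$n_cycles, f_loose$n_cycles)
      expect_true(f_loose$converged)
      expect_equal(sum(f_tight$grid$weight), 1, tolerance = 1e-12)
    }
  }
})

test_that("the cycle cap returns a flagged, usable result", {
  ds <- toy_dataset(200)
  f <- fit_2pl(ds$responses, "eh", criterion = 1e-8, max_cycles = 3)
  expect_false(f$converged)
  expect_equal(f$n_cycles, 3)
  expect_true(all(is.finite(f$items$a)))
})

test_that("fits recover generating parameters at moderate scale", {
  bank <- make_item_bank()
  ds <- sim_dataset("normal", 2000, 1, bank, master_seed = 7)
  f <- fit_2pl(ds$responses, "mml", criterion = 1e-3)
  est <- tidy(f)
  expect_lt(mean(abs(est$a_hat - bank$a)), 0.15)
  expect_lt(mean(abs(est$b_hat - bank$b)), 0.15)
})

test_that("fit accessors expose tidy, glance and plot surfaces", {
  ds <- toy_dataset(200)
  f <- fit_2pl(ds$responses, "eh", criterion = 1e-2)
  td <- tidy(f)
  expect_named(td, c("item", "a_hat", "b_hat", "flagged"))
  gl <- glance(f)
  expect_equal(gl$n, 200)
  expect_equal(gl$converged, TRUE)
  expect_s3_class(autoplot(f), "ggplot")
  ip <- withr::local_tempfile(fileext = ".csv")
  gp <- withr::local_tempfile(fileext = ".csv")
  write_fit(f, ip, gp)
  expect_equal(nrow(readr::read_csv(ip, show_col_types = FALSE)), 20)
  expect_error(fit_2pl(ds$responses, "eh",
                       init = initial_values(tibble::tibble(a0 = 1, b0 = 0), rep(0.1, 10))),
               "item count|initial")
})
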