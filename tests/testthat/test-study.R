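test_that("study cell enumeration matches the factorial design", {
  full_eh <- study_config(methods = "eh")
  expect_equal(nrow(study_cells(full_eh)), 4 * 4 * 3 * 2 * 4) # 384 cells
  both <- study_config()
  expect_equal(nrow(study_cells(both)), 384 + 4 * 3 * 2 * 4)
  tiny <- study_config(iip = "const", ild = "uniform", tld = "normal",
                       n = 60, criterion = 1e-2, reps = 2, methods = "eh")
  expect_equal(nrow(study_cells(tiny)), 1)
})

test_that("a minimal study yields one record per cell and replication, deterministically", {
  tiny <- study_config(iip = "const", ild = "uniform", tld = "normal",
                       n = 60, criterion = 1e-2, reps = 2, methods = "eh",
                       master_seed = 3)
  r1 <- run_study(tiny)
  expect_equal(nrow(r1), 2)
  expect_named(r1, c("method", "iip", "ild", "tld", "n", "criterion", "rep",
                     "seed", "n_cycles", "converged", "final_change", "loglik",
                     "icc", "emd", "est"))
  r2 <- run_study(tiny)
  expect_equal(r1, r2)
  expect_equal(nrow(study_item_estimates(r1)), 2 * 20)
})

test_that("study records are invariant to the order factor levels are listed", {
  a <- study_config(iip = c("const", "true"), ild = c("uniform", "default"),
                    tld = "normal", n = 60, criterion = c(1e-2, 1e-3),
                    reps = 1, methods = "eh", master_seed = 5)
  b <- study_config(iip = c("true", "const"), ild = c("default", "uniform"),
                    tld = "normal", n = 60, criterion = c(1e-3, 1e-2),
                    reps = 1, methods = "eh", master_seed = 5)
  ra <- run_study(a)
  rb <- run_study(b)
  expect_equal(ra, rb) # run_study sorts records into canonical order
})

test_that("every estimation condition in a data cell consumes identical data", {
  cfg <- study_config(iip = c("const", "default"), ild = c("uniform", "est"),
                      tld = "skew", n = 80, criterion = c(1e-2, 1e-3),
                      reps = 2, methods = c("eh", "mml"), master_seed = 9)
  rec <- run_study(cfg)
  per_cell <- dplyr::count(rec, tld, n, rep, seed, name = "n_fits")
  # a single seed per (tld, n, rep) cell, shared by all 10 fits in it
  expect_equal(nrow(per_cell), 2)
  expect_equal(unique(per_cell$n_fits), (2 * 2 + 1 * 2) * 2) # eh cells + mml cells, 2 criteria
  # EH and MML records are both present, with ild blank only for MML
  expect_true(all(is.na(rec$ild[rec$method == "mml"])))
  expect_true(all(!is.na(rec$ild[rec$method == "eh"])))
  expect_true(all(is.na(rec$emd[rec$method == "mml"])))
})

test_that("cell means aggregate test-level bias the way the outcome is defined", {
  cfg <- study_config(iip = "true", ild = "default", tld = "normal",
                      n = 60, criterion = 1e-2, reps = 3, methods = "eh",
                      master_seed = 13)
  rec <- run_study(cfg)
  bank <- make_item_bank()
  cm <- study_cell_means(rec, bank)
  expect_equal(nrow(cm), 1)
  # oracle: item_bias on the unnested estimates gives the same test level
  est <- study_item_estimates(rec)
  oracle <- item_bias(est[, c("rep", "item", "a_hat", "b_hat")], bank)
  tl <- oracle$test_level
  expect_equal(cm$bias_a, tl$mean_abs_bias[tl$parameter == "a"])
  expect_equal(cm$bias_b, tl$mean_abs_bias[tl$parameter == "b"])
  expect_equal(cm$emd, mean(rec$emd))
  expect_equal(cm$icc, mean(rec$icc))
})

test_that("eta-squared decomposes a single-source toy design completely", {
  toy <- tidyr::expand_grid(A = c("a1", "a2"), B = c("b1", "b2"))
  toy$y <- ifelse(toy$A == "a1", 1, 3)
  # a zero-residual toy: suppress stats's perfect-fit chatter
  tab <- suppressWarnings(eta_squared_table(toy, response = "y", factors = c("A", "B")))
  expect_equal(tab$eta_sq[tab$term == "A"], 1)
  expect_equal(sum(tab$eta_sq[tab$term != "A"]), 0)
  expect_equal(sum(tab$eta_sq), 1, tolerance = 1e-9)
})

test_that("eta-squared tables carry the factorial degrees of freedom", {
  set.seed(6)
  eh_cells <- tidyr::expand_grid(iip = letters[1:4], ild = letters[5:8],
                                 n = c(250, 500, 1000), tld = c("normal", "skew"))
  eh_cells$bias <- rnorm(nrow(eh_cells))
  tab <- eta_squared_table(eh_cells, "bias", c("iip", "ild", "n", "tld"))
  expect_equal(tab$df[tab$term == "residual"], 57)
  expect_equal(sum(tab$df), 96 - 1)
  expect_equal(sum(tab$eta_sq), 1, tolerance = 1e-9)
  expect_true(all(tab$eta_sq >= 0 & tab$eta_sq <= 1))

  mml_cells <- tidyr::expand_grid(iip = letters[1:4], n = c(250, 500, 1000),
                                  tld = c("normal", "skew"))
  mml_cells$bias <- rnorm(nrow(mml_cells))
  tab2 <- eta_squared_table(mml_cells, "bias", c("iip", "n", "tld"))
  expect_equal(tab2$df[tab2$term == "residual"], 6)
  expect_equal(sum(tab2$eta_sq), 1, tolerance = 1e-9)

  expect_error(eta_squared_table(eh_cells[-1, ], "bias", c("iip", "ild", "n", "tld")),
               "balanced")
})

test_that("Welch test and Cohen's d match explicit arithmetic", {
  z <- welch_cohen(c(5, 6, 7), c(5, 6, 7))
  expect_equal(z$t, 0)
  expect_equal(z$d, 0)

  g1 <- c(1, 2, 3); g2 <- c(2, 4, 9)
  wc <- welch_cohen(g1, g2)
  v1 <- var(g1) / 3; v2 <- var(g2) / 3
  expect_equal(wc$t, (mean(g1) - mean(g2)) / sqrt(v1 + v2))
  expect_equal(wc$df, (v1 + v2)^2 / (v1^2 / 2 + v2^2 / 2))
  sp <- sqrt((2 * var(g1) + 2 * var(g2)) / 4)
  expect_equal(wc$d, (mean(g1) - mean(g2)) / sp)

  set.seed(2)
  big1 <- rnorm(2e4, 0.12, 1)
  big2 <- rnorm(2e4, 0, 1)
  expect_lt(abs(welch_cohen(big1, big2)$d - 0.12), 0.03)
})

test_that("difficulty-bias regression matches the normal equations", {
  df <- tibble::tibble(
    difficulty = c(-2, -1, 0, 1, 2),
    density = dnorm(c(-2, -1, 0, 1, 2)),
    bias = c(0.05, -0.02, 0.01, 0.08, 0.22)
  )
  reg <- bias_regression(df)
  X <- cbind(1, df$density, df$difficulty)
  beta <- solve(t(X) %*% X, t(X) %*% df$bias)
  expect_equal(unname(tidy(reg)$estimate), as.numeric(beta))
  # perfect linear structure explains all variance
  df2 <- dplyr::mutate(df, bias = 1 + 2 * density - 0.5 * difficulty)
  r2 <- suppressWarnings(glance(bias_regression(df2))$r.squared)
  expect_equal(r2, 1, tolerance = 1e-12)
})

test_that("EMD summary tables are plain averages in the right layout", {
  fake <- tidyr::expand_grid(method = "eh", tld = c("normal", "skew"),
                             criterion = c(1e-2, 1e-5),
                             ild = c("default", "est"), rep = 1:2)
  fake$emd <- 0.25
  tab <- emd_table(fake)
  expect_equal(dim(tab), c(4L, 4L))
  expect_true(all(tab$default == 0.25) && all(tab$est == 0.25))
  fake$emd <- seq_len(nrow(fake)) # two-record means
  tab2 <- emd_table(fake)
  m <- fake |>
    dplyr::filter(tld == "normal", criterion == 1e-2, ild == "default") |>
    dplyr::pull(emd)
  expect_equal(tab2$default[tab2$tld == "normal" & tab2$criterion == 1e-2], mean(m))
})

test_that("summary tables from a small real run are complete and coherent", {
  cfg <- study_config(iip = c("const", "true"), ild = c("uniform", "default"),
                      tld = c("normal", "skew"), n = c(60, 120),
                      criterion = 1e-2, reps = 2, methods = "eh",
                      master_seed = 17)
  rec <- run_study(cfg)
  out <- summarize_tables(rec, make_item_bank())
  expect_named(out, c("emd", "eta_eh"))
  expect_equal(nrow(out$emd), 2) # one row per tld block at one criterion
  sums <- out$eta_eh |>
    dplyr::group_by(criterion, response) |>
    dplyr::summarise(s = sum(eta_sq), .groups = "drop")
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-9)
  expect_s3_class(plot_emd_by_criterion(rec), "ggplot")
})
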