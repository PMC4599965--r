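#' Configure a Monte Carlo recovery study
#'
#' Describes the full factorial design: initial item parameters (`iip`),
#' initial latent distribution (`ild`, empirical-histogram fits only), true
#' latent distribution (`tld`), sample size (`n`) and convergence criterion.
#' The study defaults are the full design: all four `iip` and `ild`
#' strategies, normal and skewed truth, n in {250, 500, 1000}, criteria
#' 1e-2 (the conventional default) through 1e-5, 100 replications, both the
#' empirical-histogram and the standard MML estimator, ten support points on
#' \[-4, 4\] and a 10000-cycle cap.
#'
#' @param iip initial item parameter strategies (subset of `true`,
#'   `default`, `const`, `shortrun`).
#' @param ild initial latent distribution strategies (subset of `uniform`,
#'   `default`, `est`, `shortrun`).
#' @param tld true latent distributions (subset of `normal`, `skew`).
#' @param n sample sizes.
#' @param criterion convergence criteria.
#' @param reps replications per data cell (>= 1).
#' @param methods estimation methods (subset of `eh`, `mml`).
#' @param bank generating item bank.
#' @param q number of support points.
#' @param range support-point interval.
#' @param max_cycles EM cycle cap.
#' @param master_seed study master seed.
#' @return an object of class `ehirt_config`.
#' @export
study_config <- function(iip = c("true", "default", "const", "shortrun"),
                         ild = c("uniform", "default", "est", "shortrun"),
                         tld = c("normal", "skew"),
                         n = c(250, 500, 1000),
                         criterion = c(1e-2, 1e-3, 1e-4, 1e-5),
                         reps = 100,
                         methods = c("eh", "mml"),
                         bank = make_item_bank(),
                         q = 10, range = c(-4, 4),
                         max_cycles = 10000L,
                         master_seed = 1L) {
  stopifnot(reps >= 1,
            all(iip %in% c("true", "default", "const", "shortrun")),
            all(ild %in% c("uniform", "default", "est", "shortrun")),
            all(tld %in% c("normal", "skew")),
            all(methods %in% c("eh", "mml")),
            all(criterion > 0), all(n >= 2))
  check_item_bank(bank)
  structure(list(iip = iip, ild = ild, tld = tld, n = n, criterion = criterion,
                 reps = as.integer(reps), methods = methods, bank = bank,
                 q = q, range = range, max_cycles = as.integer(max_cycles),
                 master_seed = as.integer(master_seed)),
            class = "ehirt_config")
}

#' @export
print.ehirt_config <- function(x, ...) {
  cells <- nrow(study_cells(x))
  cat(sprintf("<ehirt_config> %d estimation cells x %d replications = %d fits\n",
              cells, x$reps, cells * x$reps))
  cat(sprintf("  iip: %s | ild: %s\n  tld: %s | n: %s | criterion: %s | methods: %s\n",
              paste(x$iip, collapse = ","), paste(x$ild, collapse = ","),
              paste(x$tld, collapse = ","), paste(x$n, collapse = ","),
              paste(format(x$criterion), collapse = ","), paste(x$methods, collapse = ",")))
  invisible(x)
}

#' Enumerate the estimation cells of a study
#'
#' One row per estimation condition (before replication): the
#' empirical-histogram design crosses iip x ild x tld x n x criterion, the
#' MML design omits the initial-latent-distribution factor.
#'
#' @param config an [study_config()].
#' @return a tibble with columns `method`, `iip`, `ild` (`NA` for MML),
#'   `tld`, `n`, `criterion`.
#' @export
study_cells <- function(config) {
  stopifnot(inherits(config, "ehirt_config"))
  out <- list()
  if ("eh" %in% config$methods) {
    out$eh <- tidyr::expand_grid(method = "eh", iip = config$iip, ild = config$ild,
                                 tld = config$tld, n = config$n,
                                 criterion = config$criterion)
  }
  if ("mml" %in% config$methods) {
    out$mml <- tidyr::expand_grid(method = "mml", iip = config$iip, ild = NA_character_,
                                  tld = config$tld, n = config$n,
                                  criterion = config$criterion)
  }
  bind_rows(out)
}

offset_seed <- function(seed, offset) {
  as.integer((as.double(seed) + offset - 1) %% 2147483647 + 1)
}

#' Run the Monte Carlo study
#'
#' For each (true latent distribution, sample size, replication) cell one
#' dataset is generated under [condition_seed()]; every estimation-side
#' condition (initial values, convergence criterion, method) is then fitted
#' on that identical response matrix. Per fit, the record carries the
#' estimated item parameters, the mean ICC-area bias against the generating
#' bank, the Earth Mover's Distance between the final latent weights and the
#' binned generating ability sample (EH fits only), and convergence
#' bookkeeping. Non-converged fits are recorded, not dropped. The output is
#' deterministic under the master seed and invariant to the order in which
#' cells are executed, because every random draw is tied to its own derived
#' seed.
#'
#' @param config an [study_config()].
#' @param verbose print one line per dataset.
#' @return a tibble with one row per fit: `method`, `iip`, `ild`, `tld`,
#'   `n`, `criterion`, `rep`, `seed`, `n_cycles`, `converged`,
#'   `final_change`, `loglik`, `icc`, `emd`, and a list-column `est` of
#'   per-item estimate tibbles (`item`, `a_hat`, `b_hat`).
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "ehirt_config"))
  bank <- config$bank
  grid <- latent_grid(config$q, config$range)
  records <- list()
  ri <- 0L
  for (tld in config$tld) {
    for (n in config$n) {
      for (rep in seq_len(config$reps)) {
        ds <- sim_dataset(tld, n, rep, bank, config$master_seed)
        x <- response_matrix(ds$responses)
        sample_w <- sample_to_grid(ds$abilities, grid)
        if (verbose) {
          message(sprintf("dataset tld=%s n=%d rep=%d (seed %d)", tld, n, rep, ds$seed))
        }
        # initial values shared across estimation conditions on this dataset
        item_inits <- list()
        for (s in setdiff(config$iip, "shortrun")) {
          item_inits[[s]] <- init_items(s, x, truth = bank)
        }
        weight_inits <- list()
        for (s in intersect(config$ild, c("uniform", "default", "est"))) {
          weight_inits[[s]] <- init_weights(s, x, grid)
        }
        shortruns <- list()
        need_sr <- "shortrun" %in% config$iip || "shortrun" %in% config$ild
        for (method in config$methods) {
          if (need_sr && (method == "eh" || "shortrun" %in% config$iip)) {
            shortruns[[method]] <- shortrun_init(
              x, grid = grid, method = method,
              seed = offset_seed(ds$seed, if (method == "eh") 2L else 3L)
            )
          }
        }
        for (method in config$methods) {
          ild_levels <- if (method == "eh") config$ild else NA_character_
          for (iip in config$iip) {
            a0b0 <- if (iip == "shortrun") {
              sr <- shortruns[[method]]
              tibble(a0 = sr$a0, b0 = sr$b0)
            } else {
              item_inits[[iip]]
            }
            for (ild in ild_levels) {
              w0 <- if (method == "mml" || identical(ild, "default")) {
                init_weights("default", x, grid)
              } else if (identical(ild, "shortrun")) {
                shortruns[["eh"]]$w0
              } else {
                weight_inits[[ild]]
              }
              init <- initial_values(a0b0, w0, label_items = iip,
                                     label_weights = if (method == "eh") ild else "default")
              for (criterion in config$criterion) {
                fit <- fit_2pl(x, method = method, init = init,
                               criterion = criterion,
                               max_cycles = config$max_cycles, grid = grid)
                icc <- mean(purrr::map_dbl(seq_len(nrow(bank)), function(i) {
                  icc_bias(fit$items$a[i], fit$items$b[i], bank$a[i], bank$b[i])
                }))
                ri <- ri + 1L
                records[[ri]] <- tibble(
                  method = method, iip = iip, ild = ild, tld = tld,
                  n = n, criterion = criterion, rep = rep, seed = ds$seed,
                  n_cycles = fit$n_cycles, converged = fit$converged,
                  final_change = fit$final_change, loglik = fit$loglik,
                  icc = icc,
                  emd = if (method == "eh") emd(fit$grid$weight, sample_w, grid) else NA_real_,
                  est = list(tibble(item = fit$items$item, a_hat = fit$items$a,
                                    b_hat = fit$items$b))
                )
              }
            }
          }
        }
      }
    }
  }
  out <- bind_rows(records)
  arrange(out, .data$method, .data$iip, .data$ild, .data$tld, .data$n,
          .data$criterion, .data$rep)
}

#' Unnest per-item estimates from study records
#'
#' @param records output of [run_study()].
#' @return a tibble with one row per fit x item.
#' @export
study_item_estimates <- function(records) {
  tidyr::unnest(records[, c("method", "iip", "ild", "tld", "n", "criterion",
                            "rep", "est")], "est")
}

#' Aggregate study records to condition-cell means
#'
#' Collapses replications within each estimation condition: test-level mean
#' absolute bias of discriminations (`bias_a`) and difficulties (`bias_b`)
#' computed as the mean over items of |mean over replications of
#' (estimate - truth)|, plus the mean ICC-area bias (`icc`), mean Earth
#' Mover's Distance (`emd`) and mean cycle count.
#'
#' @param records output of [run_study()].
#' @param bank the generating item bank.
#' @return a tibble with one row per estimation cell.
#' @export
study_cell_means <- function(records, bank) {
  check_item_bank(bank)
  keys <- c("method", "iip", "ild", "tld", "n", "criterion")
  dev <- study_item_estimates(records) |>
    left_join(bank[, c("item", "a", "b")], by = "item") |>
    group_by(across(all_of(c(keys, "item")))) |>
    summarise(bias_a_item = mean(.data$a_hat - .data$a),
              bias_b_item = mean(.data$b_hat - .data$b), .groups = "drop") |>
    group_by(across(all_of(keys))) |>
    summarise(bias_a = mean(abs(.data$bias_a_item)),
              bias_b = mean(abs(.data$bias_b_item)), .groups = "drop")
  agg <- records |>
    group_by(across(all_of(keys))) |>
    summarise(icc = mean(.data$icc), emd = mean(.data$emd),
              n_cycles = mean(.data$n_cycles),
              prop_converged = mean(.data$converged), .groups = "drop")
  left_join(dev, agg, by = keys)
}

#' Effect-size (eta-squared) table for a factorial of cell means
#'
#' Fits a fixed-effects ANOVA with all main effects and two-way interactions
#' on the per-cell means of an outcome and reports each term's eta-squared,
#' SS(term)/SS(total), i.e. the term's relative contribution to the
#' between-condition variation. The design must be a complete balanced
#' factorial (one value per cell); with a balanced design the sums of
#' squares are orthogonal, so the eta-squared values (including the
#' residual) sum to 1. P-values are deliberately not part of the output: on
#' aggregated cell means they reflect the number of simulated cells, not
#' evidence.
#'
#' @param cell_means tibble of cell means (e.g. [study_cell_means()] output,
#'   typically filtered to one method and one criterion).
#' @param response name of the outcome column.
#' @param factors character vector of factor column names.
#' @return a tibble with columns `term`, `df`, `ss`, `eta_sq`; the last row
#'   is the residual.
#' @export
eta_squared_table <- function(cell_means,
                              response = "bias_a",
                              factors = c("iip", "ild", "n", "tld")) {
  stopifnot(response %in% names(cell_means), all(factors %in% names(cell_means)))
  df <- cell_means[, c(factors, response)]
  df[factors] <- lapply(df[factors], factor)
  combos <- prod(vapply(df[factors], function(f) length(levels(f)), integer(1)))
  counts <- dplyr::count(df, across(all_of(factors)), name = "n_cells")
  if (nrow(counts) != combos || any(counts$n_cells != counts$n_cells[1])) {
    stop("design is not a complete balanced factorial of cell means", call. = FALSE)
  }
  df[[response]] <- df[[response]] - mean(df[[response]])
  form <- as.formula(paste0("`", response, "` ~ (",
                            paste(factors, collapse = " + "), ")^2"))
  fit <- lm(form, data = df)
  tab <- anova(fit)
  ss <- tab[["Sum Sq"]]
  total <- sum(ss)
  tibble(
    term = sub("Residuals", "residual", rownames(tab)),
    df = tab[["Df"]],
    ss = ss,
    eta_sq = if (total > 0) ss / total else rep(0, length(ss))
  )
}

#' Welch test and Cohen's d for two groups
#'
#' Unequal-variance t test with Satterthwaite degrees of freedom, plus
#' Cohen's d standardized by the pooled SD.
#'
#' @param group1,group2 numeric vectors (each of length >= 2).
#' @return a one-row tibble with `t`, `df`, `p`, `d`, `mean1`, `mean2`.
#' @export
welch_cohen <- function(group1, group2) {
  stopifnot(length(group1) >= 2, length(group2) >= 2)
  if (sd(group1) == 0 && sd(group2) == 0) {
    stop("zero variance in both groups", call. = FALSE)
  }
  tt <- t.test(group1, group2, var.equal = FALSE)
  n1 <- length(group1); n2 <- length(group2)
  sp <- sqrt(((n1 - 1) * var(group1) + (n2 - 1) * var(group2)) / (n1 + n2 - 2))
  tibble(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    d = (mean(group1) - mean(group2)) / sp,
    mean1 = mean(group1),
    mean2 = mean(group2)
  )
}

#' Regress item difficulty bias on latent density and true difficulty
#'
#' Ordinary least squares of per-item difficulty bias on the true latent
#' density evaluated at the item's difficulty and on the true difficulty
#' itself: the two known drivers of difficulty bias (information available
#' at the difficulty, and the scale expansion effect).
#'
#' @param data tibble with columns `bias`, `density`, `difficulty` (one row
#'   per item).
#' @return an object of class `ehirt_biasreg`; see [tidy.ehirt_biasreg()].
#' @export
bias_regression <- function(data) {
  stopifnot(all(c("bias", "density", "difficulty") %in% names(data)))
  if (nrow(data) < 3) stop("need at least 3 items", call. = FALSE)
  fit <- lm(bias ~ density + difficulty, data = data)
  if (any(!is.finite(coef(fit)))) {
    warning("collinear predictors: some coefficients are not estimable")
  }
  structure(list(fit = fit, n_items = nrow(data)), class = "ehirt_biasreg")
}

#' @export
print.ehirt_biasreg <- function(x, ...) {
  cat(sprintf("<ehirt_biasreg> difficulty bias ~ density + difficulty (%d items), R^2 = %.3f\n",
              x$n_items, summary(x$fit)$r.squared))
  print(coef(x$fit))
  invisible(x)
}

#' Tidy the difficulty-bias regression
#'
#' @param x an `ehirt_biasreg`.
#' @param ... unused.
#' @return `tidy()`: a tibble of coefficient estimates; `glance()`: a
#'   one-row tibble with `r.squared`, `adj.r.squared`, `n_items`.
#' @method tidy ehirt_biasreg
#' @export
tidy.ehirt_biasreg <- function(x, ...) {
  cf <- summary(x$fit)$coefficients
  tibble(term = rownames(cf), estimate = cf[, 1], std.error = cf[, 2],
         statistic = cf[, 3], p.value = cf[, 4])
}

#' @rdname tidy.ehirt_biasreg
#' @method glance ehirt_biasreg
#' @export
glance.ehirt_biasreg <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
         n_items = x$n_items)
}

#' Mean Earth Mover's Distance by criterion and initial latent distribution
#'
#' The latent-recovery summary table: within each true-latent-distribution
#' block, the mean EMD per (convergence criterion x initial latent
#' distribution), averaged over the remaining factors (initial item
#' parameters, sample size) and replications.
#'
#' @param records output of [run_study()] (EH fits are used).
#' @return a tibble with columns `tld`, `criterion`, and one column per
#'   initial-latent-distribution strategy.
#' @export
emd_table <- function(records) {
  records |>
    filter(.data$method == "eh") |>
    group_by(.data$tld, .data$criterion, .data$ild) |>
    summarise(emd = mean(.data$emd), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "ild", values_from = "emd") |>
    arrange(.data$tld, .data$criterion)
}

#' Summary tables for a completed study
#'
#' Produces the latent-recovery EMD table and, per convergence criterion,
#' the eta-squared tables for test-level discrimination bias, difficulty
#' bias and ICC bias (empirical-histogram design: iip x ild x n x tld; MML
#' design: iip x n x tld).
#'
#' @param records output of [run_study()].
#' @param bank the generating item bank.
#' @return a list with elements `emd` (tibble), `eta_eh` and `eta_mml`
#'   (tibbles with one eta-squared table row per criterion x response x
#'   term).
#' @export
summarize_tables <- function(records, bank) {
  out <- list(emd = emd_table(records))
  cm <- study_cell_means(records, bank)
  eta_block <- function(cmm, factors) {
    purrr::map_dfr(unique(cmm$criterion), function(cr) {
      purrr::map_dfr(c("bias_a", "bias_b", "icc"), function(resp) {
        eta_squared_table(filter(cmm, .data$criterion == cr), resp, factors) |>
          mutate(criterion = cr, response = resp, .before = 1)
      })
    })
  }
  if (any(cm$method == "eh")) {
    out$eta_eh <- eta_block(filter(cm, .data$method == "eh"),
                            c("iip", "ild", "n", "tld"))
  }
  if (any(cm$method == "mml")) {
    out$eta_mml <- eta_block(filter(cm, .data$method == "mml"),
                             c("iip", "n", "tld"))
  }
  out
}

#' Plot latent-distribution recovery against the convergence criterion
#'
#' Mean Earth Mover's Distance by convergence criterion, one line per
#' initial-latent-distribution strategy, faceted by the true latent
#' distribution.
#'
#' @param records output of [run_study()].
#' @return a ggplot object.
#' @export
plot_emd_by_criterion <- function(records) {
  dat <- records |>
    filter(.data$method == "eh") |>
    group_by(.data$tld, .data$criterion, .data$ild) |>
    summarise(emd = mean(.data$emd), .groups = "drop")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$criterion, y = .data$emd,
                                    colour = .data$ild, group = .data$ild)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~tld) +
    ggplot2::labs(x = "convergence criterion (log scale)",
                  y = "mean Earth Mover's Distance",
                  colour = "initial latent\ndistribution")
}
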