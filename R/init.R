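#' Container for EM initial values
#'
#' Bundles the initial item parameters and initial latent weights handed to
#' [fit_2pl()], together with labels recording which strategy produced them.
#'
#' @param items tibble with columns `a0`, `b0` (one row per item), as
#'   returned by [init_items()].
#' @param weights numeric vector of nonnegative initial weights, one per
#'   support point, as returned by [init_weights()].
#' @param label_items,label_weights optional strategy labels.
#' @return an object of class `ehirt_init` with fields `a0`, `b0`, `w0`,
#'   `label_items`, `label_weights`.
#' @export
initial_values <- function(items, weights, label_items = NA_character_,
                           label_weights = NA_character_) {
  stopifnot(is.data.frame(items), all(c("a0", "b0") %in% names(items)))
  if (any(items$a0 <= 0) || !all(is.finite(items$a0)) || !all(is.finite(items$b0))) {
    stop("initial discriminations must be positive and finite", call. = FALSE)
  }
  check_grid_weights(weights)
  structure(list(
    a0 = items$a0, b0 = items$b0, w0 = weights / sum(weights),
    label_items = if (!is.na(label_items)) label_items else attr(items, "strategy") %||% NA_character_,
    label_weights = if (!is.na(label_weights)) label_weights else attr(weights, "strategy") %||% NA_character_
  ), class = "ehirt_init")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ehirt_init <- function(x, ...) {
  cat(sprintf("<ehirt_init> %d items (strategy: %s), %d weights (strategy: %s)\n",
              length(x$a0), x$label_items, length(x$w0), x$label_weights))
  invisible(x)
}

#' Classical test theory item statistics
#'
#' Computes, per item, the proportion correct p_i and the biserial
#' correlation of the item with the total score (item included in the
#' total). The point-biserial r_pb is converted to a biserial via
#' r_bis = r_pb * sqrt(p (1 - p)) / phi(Phi^-1(p)), and capped to
#' \[-0.999, 0.999\]. Constant item columns get r_bis = 0 and are flagged.
#'
#' @param data response tibble or 0/1 matrix.
#' @return a tibble with columns `item`, `p`, `r_pb`, `r_bis`, `flagged`.
#' @export
ctt_stats <- function(data) {
  x <- response_matrix(data)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 testees for CTT statistics", call. = FALSE)
  total <- rowSums(x)
  p <- colMeans(x)
  k <- ncol(x)
  r_pb <- vapply(seq_len(k), function(i) {
    if (sd(x[, i]) == 0 || sd(total) == 0) return(NA_real_)
    cor(x[, i], total)
  }, numeric(1))
  flagged <- !is.finite(r_pb)
  r_bis <- ifelse(flagged, 0,
                  r_pb * sqrt(p * (1 - p)) / dnorm(qnorm(pmin(pmax(p, 1e-12), 1 - 1e-12))))
  r_bis <- pmin(pmax(r_bis, -0.999), 0.999)
  tibble(item = seq_len(k), p = unname(p), r_pb = unname(ifelse(flagged, 0, r_pb)),
         r_bis = unname(r_bis), flagged = unname(flagged))
}

#' Classical approximation of the 2PL discrimination
#'
#' Converts a biserial item-total correlation into an initial discrimination
#' via a_hat = 1.7 r_bis / sqrt(1 - r_bis^2), the classical normal-ogive
#' approximation scaled to the logistic metric.
#'
#' @param r_bis biserial correlation(s), |r_bis| < 1.
#' @return numeric discrimination(s).
#' @examples
#' ctt_discrimination(0.5) # 0.9815
#' @export
ctt_discrimination <- function(r_bis) {
  if (any(!is.finite(r_bis)) || any(abs(r_bis) >= 1)) {
    stop("|r_bis| must be < 1", call. = FALSE)
  }
  1.7 * r_bis / sqrt(1 - r_bis^2)
}

#' Initial item parameters
#'
#' Produces the four item-parameter starting-value strategies:
#' \describe{
#'   \item{`true`}{copies the generating parameters (`truth` required); the
#'     reference condition.}
#'   \item{`default`}{classical-test-theory starts: a0 from
#'     [ctt_discrimination()] floored at 0.3, and b0 = -logit(p_i)/a0_i, the
#'     difficulty at which an average-ability testee would match the observed
#'     proportion correct.}
#'   \item{`const`}{a0 = 1 and b0 = 0 for every item.}
#'   \item{`shortrun`}{the item part of [shortrun_init()].}
#' }
#'
#' @param strategy one of `"true"`, `"default"`, `"const"`, `"shortrun"`.
#' @param data response tibble or 0/1 matrix.
#' @param truth generating item bank (required for `"true"`).
#' @param ... passed to [shortrun_init()] (e.g. `grid`, `method`, `seed`).
#' @return a tibble with columns `item`, `a0`, `b0` and a `"strategy"`
#'   attribute.
#' @export
init_items <- function(strategy = c("default", "true", "const", "shortrun"),
                       data, truth = NULL, ...) {
  strategy <- match.arg(strategy)
  x <- response_matrix(data)
  k <- ncol(x)
  out <- switch(strategy,
    true = {
      if (is.null(truth)) stop("strategy 'true' requires the generating item bank", call. = FALSE)
      check_item_bank(truth)
      if (nrow(truth) != k) stop("item bank does not match the data", call. = FALSE)
      tibble(item = seq_len(k), a0 = truth$a, b0 = truth$b)
    },
    const = tibble(item = seq_len(k), a0 = rep(1, k), b0 = rep(0, k)),
    default = {
      stats <- ctt_stats(x)
      a0 <- pmax(ctt_discrimination(stats$r_bis), 0.3)
      n <- nrow(x)
      p <- pmin(pmax(stats$p, 0.5 / n), 1 - 0.5 / n)
      tibble(item = seq_len(k), a0 = a0, b0 = -qlogis(p) / a0)
    },
    shortrun = {
      sr <- shortrun_init(x, ...)
      tibble(item = seq_len(k), a0 = sr$a0, b0 = sr$b0)
    }
  )
  attr(out, "strategy") <- strategy
  out
}

#' Initial latent weights
#'
#' Produces the four latent-distribution starting-value strategies on the
#' grid's support points:
#' \describe{
#'   \item{`uniform`}{equal weights 1/Q.}
#'   \item{`default`}{standard normal density at each point, normalized.}
#'   \item{`est`}{relative frequencies of standardized CTT-weighted sum
#'     scores assigned to the nearest support point; see [est_weights()].}
#'   \item{`shortrun`}{the weight part of [shortrun_init()].}
#' }
#'
#' @param strategy one of `"uniform"`, `"default"`, `"est"`, `"shortrun"`.
#' @param data response tibble or 0/1 matrix (used by `est` and `shortrun`).
#' @param grid latent grid (see [latent_grid()]).
#' @param ... passed to [shortrun_init()].
#' @return a numeric weight vector summing to 1, with a `"strategy"`
#'   attribute.
#' @export
init_weights <- function(strategy = c("default", "uniform", "est", "shortrun"),
                         data = NULL, grid = latent_grid(10), ...) {
  strategy <- match.arg(strategy)
  q <- nrow(grid)
  if (q < 2) stop("need at least 2 support points", call. = FALSE)
  w <- switch(strategy,
    uniform = rep(1 / q, q),
    default = { d <- dnorm(grid$point); d / sum(d) },
    est = est_weights(data, grid),
    shortrun = shortrun_init(data, grid = grid, ...)$w0
  )
  attr(w, "strategy") <- strategy
  w
}

#' CTT-estimated latent weights
#'
#' Each testee's weighted sum score S_j = sum_i a_hat_i x_ij (with a_hat the
#' classical discrimination approximation) is standardized to mean 0, SD 1;
#' testees are assigned to the nearest support point and the relative
#' frequencies form the weights. Zero score variance (every testee sharing
#' one pattern) collapses all mass onto the support point nearest 0 and is
#' flagged.
#'
#' @param data response tibble or 0/1 matrix.
#' @param grid latent grid.
#' @return a numeric weight vector summing to 1 (each a multiple of 1/n).
#' @export
est_weights <- function(data, grid) {
  x <- response_matrix(data)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 testees", call. = FALSE)
  stats <- ctt_stats(x)
  a_hat <- ctt_discrimination(stats$r_bis)
  s <- as.vector(x %*% a_hat)
  flagged <- FALSE
  if (sd(s) == 0) {
    # all testees share one pattern: the standardized score is 0 by
    # convention, putting all mass on the support point nearest 0
    s <- rep(0, n)
    flagged <- TRUE
  } else {
    s <- (s - mean(s)) / sd(s)
  }
  idx <- nearest_point(s, grid$point)
  w <- tabulate(idx, nbins = nrow(grid)) / n
  attr(w, "flagged") <- flagged
  w
}

nearest_point <- function(z, points) {
  # equal spacing: direct index arithmetic, ties round half up to the
  # higher index via floor(+0.5)
  dz <- points[2] - points[1]
  idx <- floor((z - points[1]) / dz + 0.5) + 1
  pmin(pmax(idx, 1), length(points))
}

#' Multi-start (shortrun) initial values
#'
#' Runs `n_starts` short EM runs of exactly `n_cycles` cycles each from
#' random starting values (a ~ LogNormal(0, 0.5), b ~ N(0, 1), weights ~
#' symmetric Dirichlet(1)), and returns the candidate with the highest
#' marginal log-likelihood as initial values. Short runs use the same
#' estimation method (`"eh"` or `"mml"`) as the fit they seed; under
#' `"mml"` the random weights are replaced by the fixed normal weights.
#'
#' @param data response tibble or 0/1 matrix.
#' @param grid latent grid.
#' @param method `"eh"` or `"mml"`.
#' @param n_starts number of random starts (study setting: 50).
#' @param n_cycles EM cycles per start (study setting: 10).
#' @param seed optional integer seed making the whole procedure
#'   reproducible.
#' @return an `ehirt_init` whose `candidate_logliks` attribute records the
#'   final marginal log-likelihood of every start.
#' @export
shortrun_init <- function(data, grid = latent_grid(10), method = c("eh", "mml"),
                          n_starts = 50, n_cycles = 10, seed = NULL) {
  method <- match.arg(method)
  x <- response_matrix(data)
  k <- ncol(x)
  q <- nrow(grid)
  run <- function() {
    best <- NULL
    logliks <- numeric(n_starts)
    for (s in seq_len(n_starts)) {
      a0 <- exp(rnorm(k, 0, 0.5))
      b0 <- rnorm(k)
      w0 <- if (method == "mml") {
        d <- dnorm(grid$point)
        d / sum(d)
      } else {
        g <- -log(runif(q)) # Dirichlet(1) via normalized exponentials
        g / sum(g)
      }
      init <- initial_values(tibble(a0 = a0, b0 = b0), w0,
                             label_items = "random", label_weights = "random")
      fit <- fit_2pl(x, method = method, init = init, criterion = 0,
                     max_cycles = n_cycles, grid = grid)
      logliks[s] <- fit$loglik
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    list(best = best, logliks = logliks)
  }
  res <- if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
  out <- initial_values(
    tibble(a0 = res$best$items$a, b0 = res$best$items$b),
    res$best$grid$weight,
    label_items = "shortrun", label_weights = "shortrun"
  )
  attr(out, "candidate_logliks") <- res$logliks
  out
}

#' Read and write initial-value CSV files
#'
#' Item starts are stored as `item,a0,b0`; weight starts as `point,w0`.
#'
#' @param init an `ehirt_init`.
#' @param items_path,weights_path CSV paths.
#' @param grid latent grid supplying the `point` column on write.
#' @return `write_initial_values()` returns `init` invisibly;
#'   `read_initial_values()` returns an `ehirt_init`.
#' @export
write_initial_values <- function(init, items_path, weights_path, grid = latent_grid(length(init$w0))) {
  stopifnot(inherits(init, "ehirt_init"))
  readr::write_csv(tibble(item = seq_along(init$a0), a0 = init$a0, b0 = init$b0), items_path)
  readr::write_csv(tibble(point = grid$point, w0 = init$w0), weights_path)
  invisible(init)
}

#' @rdname write_initial_values
#' @export
read_initial_values <- function(items_path, weights_path) {
  it <- readr::read_csv(items_path, col_types = readr::cols(.default = readr::col_double()))
  wt <- readr::read_csv(weights_path, col_types = readr::cols(.default = readr::col_double()))
  initial_values(it, wt$w0)
}
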