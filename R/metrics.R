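#' Item parameter bias over replications
#'
#' For each item and parameter, bias is the mean over replications of
#' (estimate - truth). The test-level summary is the mean over items of the
#' *absolute* per-item biases (mean absolute bias), computed separately for
#' the discrimination and the difficulty parameter.
#'
#' @param estimates tibble of per-replication estimates with columns `rep`,
#'   `item`, `a_hat`, `b_hat`.
#' @param truth generating item bank (columns `item`, `a`, `b`).
#' @return an object of class `ehirt_bias`: a list with `per_item` (tibble
#'   `item, parameter, bias`), `test_level` (tibble `parameter, mean_abs_bias`)
#'   and `n_reps`.
#' @export
item_bias <- function(estimates, truth) {
  stopifnot(all(c("rep", "item", "a_hat", "b_hat") %in% names(estimates)))
  check_item_bank(truth)
  if (!all(estimates$item %in% truth$item)) stop("item mismatch between estimates and truth", call. = FALSE)
  per_item <- estimates |>
    left_join(truth[, c("item", "a", "b")], by = "item") |>
    group_by(.data$item) |>
    summarise(a = mean(.data$a_hat - .data$a), b = mean(.data$b_hat - .data$b),
              .groups = "drop") |>
    tidyr::pivot_longer(c("a", "b"), names_to = "parameter", values_to = "bias")
  test_level <- per_item |>
    group_by(.data$parameter) |>
    summarise(mean_abs_bias = mean(abs(.data$bias)), .groups = "drop")
  structure(list(per_item = per_item, test_level = test_level,
                 n_reps = length(unique(estimates$rep))),
            class = "ehirt_bias")
}

#' @export
print.ehirt_bias <- function(x, ...) {
  cat(sprintf("<ehirt_bias> %d items, %d replications\n",
              length(unique(x$per_item$item)), x$n_reps))
  print(x$test_level)
  invisible(x)
}

#' @method tidy ehirt_bias
#' @export
tidy.ehirt_bias <- function(x, ...) x$per_item

#' @method glance ehirt_bias
#' @export
glance.ehirt_bias <- function(x, ...) {
  tidyr::pivot_wider(x$test_level, names_from = "parameter",
                     values_from = "mean_abs_bias", names_prefix = "mean_abs_bias_") |>
    mutate(n_reps = x$n_reps)
}

# Antiderivative of the 2PL ICC: d/dz [log(1 + exp(a (z - b))) / a] = pi(z).
# log1p(exp(.)) evaluated overflow-safely.
icc_antideriv <- function(a, b, z) {
  eta <- a * (z - b)
  ifelse(eta > 30, eta + log1p(exp(-eta)), log1p(exp(eta))) / a
}

#' Area between true and estimated item characteristic curves
#'
#' Computes the integral over \[-10, 10\] of |pi(z | a_hat, b_hat) -
#' pi(z | a_true, b_true)|. Two 2PL curves cross at most once (at
#' z* = (a1 b1 - a2 b2) / (a1 - a2) when the discriminations differ), so the
#' integral is evaluated exactly from the closed-form antiderivative
#' log(1 + exp(a (z - b))) / a, splitting at the crossing point.
#'
#' @param a_hat,b_hat estimated item parameters (`a_hat > 0`).
#' @param a_true,b_true generating item parameters (`a_true > 0`).
#' @param lower,upper integration interval (study setting: \[-10, 10\]).
#' @return the nonnegative area (latent-scale x probability units).
#' @examples
#' icc_bias(1, 0.5, 1, 0) # 0.5: a pure difficulty shift of 0.5
#' @export
icc_bias <- function(a_hat, b_hat, a_true, b_true, lower = -10, upper = 10) {
  if (!all(is.finite(c(a_hat, b_hat, a_true, b_true))) || a_hat <= 0 || a_true <= 0) {
    stop("parameters must be finite with a > 0", call. = FALSE)
  }
  signed <- function(l, u) {
    (icc_antideriv(a_hat, b_hat, u) - icc_antideriv(a_hat, b_hat, l)) -
      (icc_antideriv(a_true, b_true, u) - icc_antideriv(a_true, b_true, l))
  }
  if (a_hat != a_true) {
    zstar <- (a_hat * b_hat - a_true * b_true) / (a_hat - a_true)
    if (zstar > lower && zstar < upper) {
      return(abs(signed(lower, zstar)) + abs(signed(zstar, upper)))
    }
  }
  abs(signed(lower, upper))
}

#' Bin an ability sample onto the support points
#'
#' Assigns each generating ability to its nearest support point and returns
#' the relative frequencies: the sample's discrete histogram on the grid,
#' used as the reference distribution for [emd()].
#'
#' @param abilities tibble with a `z` column, or a numeric vector.
#' @param grid latent grid (equally spaced points).
#' @return a numeric weight vector summing to 1.
#' @export
sample_to_grid <- function(abilities, grid) {
  z <- if (is.data.frame(abilities)) abilities$z else abilities
  if (length(z) < 1) stop("empty ability sample", call. = FALSE)
  idx <- nearest_point(z, grid$point)
  tabulate(idx, nbins = nrow(grid)) / length(z)
}

#' Earth Mover's Distance between two histograms on a shared grid
#'
#' The minimum cost of turning one weight distribution into the other, with
#' cost equal to mass times distance moved. On a one-dimensional equally
#' spaced grid this is the spacing-weighted L1 distance between the
#' cumulative distributions: sum_q |C1_q - C2_q| * dz. Set `spacing = 1` for
#' the unitless grid-step convention.
#'
#' @param w1,w2 probability vectors on the same grid.
#' @param grid latent grid the weights live on.
#' @param spacing transport cost per grid step; defaults to the grid spacing
#'   (latent-scale units).
#' @return the nonnegative distance; zero iff the histograms are equal.
#' @examples
#' g <- latent_grid(10)
#' emd(c(1, rep(0, 9)), c(0, 1, rep(0, 8)), g) # one step: 8/9
#' @export
emd <- function(w1, w2, grid, spacing = NULL) {
  if (length(w1) != nrow(grid) || length(w2) != nrow(grid)) {
    stop("weights must match the grid", call. = FALSE)
  }
  check_grid_weights(w1)
  check_grid_weights(w2)
  if (abs(sum(w1) - 1) > 1e-9 || abs(sum(w2) - 1) > 1e-9) {
    stop("weights must each sum to 1", call. = FALSE)
  }
  dz <- spacing %||% (grid$point[2] - grid$point[1])
  sum(abs(cumsum(w1) - cumsum(w2))) * dz
}
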