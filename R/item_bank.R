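#' Item banks for the two-parameter logistic model
#'
#' An item bank is a tibble with one row per item and columns `item`
#' (integer label), `a` (discrimination, logistic metric) and `b`
#' (difficulty, latent-scale units). `make_item_bank()` called without a
#' seed returns the packaged 20-item reference bank: a synthetic
#' mathematics-achievement-style test spanning easy to very difficult items
#' (difficulties from -2.5 to 2.43) and weakly to very strongly
#' discriminating items (0.5 to 3.0), including one item with a = 3.00 and
#' one with b = 2.43 so that single-item analyses of extreme-parameter
#' sensitivity (scale expansion, high-discrimination bias) have their
#' canonical targets. With a seed, a random bank of `k` items is drawn
#' uniformly over the same ranges.
#'
#' @param k number of items (>= 2). The packaged reference bank requires
#'   `k = 20`.
#' @param seed integer seed for a randomly generated bank, or `NULL`
#'   (default) for the fixed reference bank.
#' @return a tibble with columns `item`, `a`, `b`.
#' @examples
#' make_item_bank()
#' make_item_bank(k = 10, seed = 7)
#' @export
make_item_bank <- function(k = 20, seed = NULL) {
  if (!is.numeric(k) || length(k) != 1 || k < 2) {
    stop("`k` must be a single integer >= 2", call. = FALSE)
  }
  k <- as.integer(k)
  if (is.null(seed)) {
    if (k != 20) {
      stop("the packaged reference bank has 20 items; supply `seed` to generate a bank of size ", k,
           call. = FALSE)
    }
    return(reference_bank())
  }
  withr::with_seed(as.integer(seed), {
    tibble(
      item = seq_len(k),
      a = round(runif(k, 0.5, 3.0), 2),
      b = round(runif(k, -2.5, 2.5), 2)
    )
  })
}

# Fixed synthetic 20-item bank. Discriminations span [0.5, 3.0], difficulties
# [-2.5, 2.43]; item 17 carries a = 3.00 and item 19 carries b = 2.43.
reference_bank <- function() {
  tibble(
    item = 1:20,
    a = c(0.50, 0.70, 0.90, 1.10, 0.60, 1.30, 1.50, 0.80, 1.70, 2.00,
          1.20, 2.20, 1.00, 2.50, 1.40, 1.60, 3.00, 1.80, 1.10, 2.40),
    b = c(-2.50, -1.80, -1.40, -1.00, -0.70, -0.40, -0.20, 0.00, 0.20, 0.40,
          0.60, 0.80, 1.00, 1.20, 1.50, 1.80, 0.50, 2.10, 2.43, -0.60)
  )
}

check_item_bank <- function(bank) {
  stopifnot(is.data.frame(bank), all(c("a", "b") %in% names(bank)))
  if (nrow(bank) < 2) stop("item bank must contain at least 2 items", call. = FALSE)
  if (!all(is.finite(bank$a)) || !all(is.finite(bank$b)) || any(bank$a <= 0)) {
    stop("item bank requires finite parameters with a > 0", call. = FALSE)
  }
  invisible(bank)
}

#' Read and write item-bank CSV files
#'
#' The on-disk format is a CSV with header `item,a,b`, one row per item.
#'
#' @param path file path.
#' @param bank an item bank tibble (see [make_item_bank()]).
#' @return `read_item_bank()` returns an item-bank tibble;
#'   `write_item_bank()` returns `bank` invisibly.
#' @export
read_item_bank <- function(path) {
  bank <- readr::read_csv(path, col_types = readr::cols(
    item = readr::col_integer(),
    a = readr::col_double(),
    b = readr::col_double()
  ))
  check_item_bank(bank)
  bank
}

#' @rdname read_item_bank
#' @export
write_item_bank <- function(bank, path) {
  check_item_bank(bank)
  readr::write_csv(bank[, c("item", "a", "b")], path)
  invisible(bank)
}
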