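#' Simulate binary item responses under the 2PL
#'
#' For every testee j and item i the correct-response probability
#' pi_ij = plogis(a_i (z_j - b_i)) is compared with an independent
#' Uniform(0, 1) draw u_ij; the response is scored 1 (correct) when
#' pi_ij > u_ij and 0 otherwise.
#'
#' @param bank item bank tibble (columns `a`, `b`; see [make_item_bank()]).
#' @param abilities tibble with a `z` column (see [sample_abilities()]), or a
#'   numeric vector of abilities.
#' @param seed optional integer seed for the uniform draws.
#' @return a tibble with one row per testee: an `id` column followed by one
#'   0/1 column per item, named `i1`, `i2`, ...
#' @examples
#' bank <- make_item_bank()
#' ab <- sample_abilities(10, seed = 1)
#' sim_responses(bank, ab, seed = 2)
#' @export
sim_responses <- function(bank, abilities, seed = NULL) {
  check_item_bank(bank)
  z <- if (is.data.frame(abilities)) abilities$z else abilities
  if (length(z) < 1 || !all(is.finite(z))) {
    stop("abilities must be non-empty and finite", call. = FALSE)
  }
  n <- length(z)
  k <- nrow(bank)
  p <- plogis(outer(z, bank$b, "-") * rep(bank$a, each = n)) # n x k
  draw <- function() matrix(runif(n * k), n, k)
  u <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  x <- matrix(as.integer(p > u), n, k, dimnames = list(NULL, paste0("i", seq_len(k))))
  dplyr::bind_cols(tibble(id = seq_len(n)), as_tibble(x))
}

# Extract the n x k 0/1 matrix from a response tibble (drops an `id` column),
# validating that entries are binary.
response_matrix <- function(data) {
  if (is.matrix(data)) {
    x <- data
  } else {
    stopifnot(is.data.frame(data))
    data <- data[, setdiff(names(data), "id"), drop = FALSE]
    x <- as.matrix(data)
  }
  storage.mode(x) <- "double"
  if (!all(x %in% c(0, 1))) stop("responses must be scored 0/1", call. = FALSE)
  if (nrow(x) < 1 || ncol(x) < 1) stop("need at least 1 testee and 1 item", call. = FALSE)
  x
}

#' Condition seeds for the shared-data design
#'
#' The Monte Carlo design shares data across every estimation-side factor
#' (initial item parameters, initial latent distribution, convergence
#' criterion, estimation method): within one combination of true latent
#' distribution, sample size and replication, every fit consumes the identical
#' response matrix. `condition_seed()` maps `(tld, n, rep)` injectively to a
#' 31-bit seed, offset by the study's master seed, so each such cell gets its
#' own reproducible data stream.
#'
#' @param tld true-latent-distribution level, `"normal"` or `"skew"` (or an
#'   integer level index in 1..7).
#' @param n sample size (< 65536).
#' @param rep replication index (1 <= rep < 4096).
#' @param master_seed study master seed.
#' @return a single integer in `[1, 2^31 - 1]`.
#' @examples
#' condition_seed("normal", 250, 1)
#' condition_seed("skew", 250, 1)
#' @export
condition_seed <- function(tld, n, rep, master_seed = 1L) {
  idx <- if (is.character(tld)) match(tld, c("normal", "skew")) else as.integer(tld)
  if (is.na(idx) || idx < 1 || idx > 7) stop("unknown `tld` level", call. = FALSE)
  if (rep < 1 || rep >= 4096) stop("`rep` must be in 1..4095", call. = FALSE)
  if (n < 1 || n >= 65536) stop("`n` must be in 1..65535", call. = FALSE)
  # ((idx*65536 + n)*4096 + rep) is injective and <= 2^31 - 1 for idx <= 7
  s <- ((idx * 65536 + n) * 4096 + rep)
  as.integer((s + (as.double(master_seed) %% 2147483647)) %% 2147483647 + 1)
}

#' Generate one study dataset
#'
#' Draws the abilities and the response matrix for one (true latent
#' distribution, sample size, replication) cell under the shared-seed design.
#'
#' @inheritParams condition_seed
#' @param bank item bank used to generate responses.
#' @return a list with elements `abilities` (tibble `id, z`), `responses`
#'   (response tibble), `seed`, and `spec` (the [ability_spec()] used).
#' @export
sim_dataset <- function(tld, n, rep, bank = make_item_bank(), master_seed = 1L) {
  seed <- condition_seed(tld, n, rep, master_seed)
  spec <- if (identical(tld, "skew")) ability_spec("skew_normal", shape = 10) else ability_spec("normal")
  abilities <- sample_abilities(n, spec, seed = seed)
  responses <- sim_responses(bank, abilities, seed = seed + 1L)
  list(abilities = abilities, responses = responses, seed = seed, spec = spec)
}

#' Read and write response-matrix CSV files
#'
#' One row per testee: an optional `id` column followed by k binary item
#' columns.
#'
#' @param path file path.
#' @param data a response tibble as returned by [sim_responses()].
#' @return `read_responses()` returns a response tibble; `write_responses()`
#'   returns `data` invisibly.
#' @export
read_responses <- function(path) {
  data <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
  response_matrix(data) # validates
  data
}

#' @rdname read_responses
#' @export
write_responses <- function(data, path) {
  response_matrix(data)
  readr::write_csv(data, path)
  invisible(data)
}
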