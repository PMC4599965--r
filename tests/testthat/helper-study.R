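# Shared fixtures and lazily cached study runs (computed once per session;
# several acceptance checks read different summaries off the same run).

.study_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.study_cache[[name]])) .study_cache[[name]] <- force(expr)
  .study_cache[[name]]
}

# Full empirical-histogram factor grid at the conventional criterion 1e-2:
# 4 iip x 4 ild x 3 n x 2 tld cells, 25 replications.
grid_run_1e2 <- function() {
  cached("grid_1e2", {
    cfg <- study_config(criterion = 1e-2, reps = 25, methods = "eh",
                        master_seed = 20260923)
    run_study(cfg)
  })
}

# Convergence-criterion sweep at n = 250 (all four initial-weight strategies,
# both true distributions, constant item starts), 25 replications.
criterion_sweep_run <- function() {
  cached("sweep", {
    cfg <- study_config(iip = "const",
                        tld = c("normal", "skew"), n = 250,
                        criterion = c(1e-2, 1e-3, 1e-4, 1e-5), reps = 25,
                        methods = "eh", master_seed = 20260923)
    run_study(cfg)
  })
}

# MML design (no initial-latent-distribution factor) at criterion 1e-2,
# 25 replications.
mml_run_1e2 <- function() {
  cached("mml_1e2", {
    cfg <- study_config(criterion = 1e-2, reps = 25, methods = "mml",
                        master_seed = 20260923)
    run_study(cfg)
  })
}

# A small shared dataset for unit tests.
toy_dataset <- function(n = 200, tld = "normal", rep = 1) {
  cached(paste("toy", n, tld, rep, sep = "_"),
         sim_dataset(tld, n, rep, make_item_bank(), master_seed = 42))
}

# Brute-force marginal log-likelihood: explicit loops, no log-space tricks.
brute_marginal_loglik <- function(x, a, b, points, w) {
  total <- 0
  for (j in seq_len(nrow(x))) {
    lik <- 0
    for (q in seq_along(points)) {
      prod <- w[q]
      for (i in seq_len(ncol(x))) {
        p <- exp(a[i] * (points[q] - b[i])) / (1 + exp(a[i] * (points[q] - b[i])))
        prod <- prod * (if (x[j, i] == 1) p else 1 - p)
      }
      lik <- lik + prod
    }
    total <- total + log(lik)
  }
  total
}

# Optimal 1-D transport cost by quantile coupling: histograms whose weights
# are exact multiples of 1/N expand to sorted lists of N atoms; the optimal
# coupling matches sorted atoms pairwise.
emd_quantile_oracle <- function(w1, w2, points, N) {
  atoms1 <- rep(points, round(w1 * N))
  atoms2 <- rep(points, round(w2 * N))
  stopifnot(length(atoms1) == N, length(atoms2) == N)
  mean(abs(sort(atoms1) - sort(atoms2)))
}
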