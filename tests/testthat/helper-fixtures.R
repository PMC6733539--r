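# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Default-condition cohort (28 patients / 14 controls, 20^3 grid, 5 sources)
default_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- suppressMessages(simulate_cohort(sim_config(seed = 101L)))
  .fixture_env$cohort
}

# A small, fast cohort for I/O and pipeline tests
small_sim_config <- function(seed = 11L, ...) {
  sim_config(n_patients = 8L, n_controls = 6L, grid_dims = c(10L, 10L, 10L),
             n_sources = 2L, n_timepoints = 60L, n_nodes = 6L,
             seed = seed, ...)
}

# Minimal stand-in decomposition when only the loading matrix matters
fake_decomp <- function(loadings) {
  structure(list(loadings = as.matrix(loadings), sources = NULL,
                 n_components = ncol(as.matrix(loadings)), selected = NULL),
            class = "source_decomposition")
}

# Match estimated to true components and return, per true component, the
# spatial correlation of its best-assigned estimate.
matched_source_correlations <- function(decomp, true_sources) {
  ac <- abs(stats::cor(t(decomp$sources), t(true_sources)))
  m <- match_components(ac)
  list(assignment = m, r = ac[cbind(seq_len(nrow(ac)), m)])
}

# Simulated critical values for the max studentized deviate (Grubbs null),
# memoized per (n, alpha)
grubbs_crit_mc <- function(n, alpha = 0.05, B = 20000L) {
  key <- paste0("g", n, "_", alpha)
  if (is.null(.fixture_env[[key]])) {
    set.seed(424242 + n)
    g <- replicate(B, {
      x <- rnorm(n)
      max(abs(x - mean(x))) / sd(x)
    })
    .fixture_env[[key]] <- unname(stats::quantile(g, 1 - alpha))
  }
  .fixture_env[[key]]
}

# Brute-force iterative Grubbs oracle using Monte-Carlo critical values:
# at each pass delete the most extreme point if its studentized deviation
# exceeds the simulated null quantile.
grubbs_oracle <- function(x, alpha = 0.05) {
  idx <- seq_along(x)
  out <- integer(0)
  while (length(x) >= 3L && sd(x) > 1e-12) {
    dev <- abs(x - mean(x)) / sd(x)
    if (max(dev) <= grubbs_crit_mc(length(x), alpha)) break
    w <- which.max(dev)
    out <- c(out, idx[w])
    x <- x[-w]
    idx <- idx[-w]
  }
  out
}
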