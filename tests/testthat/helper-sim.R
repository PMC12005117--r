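# Shared simulated cohorts, built once per test run.

small_params <- function(seed = 101) {
  sim_params(n_driven = 60, n_enhanced = 60, n_neutral = 80,
             n_markers_per_cluster = 10, n_modules = 6, seed = seed)
}

small_design <- function() {
  d <- default_design()
  d$n_cells <- c(80, 80, 60, 60, 250, 250, 60, 60, 60, 60, 60, 60)
  d
}

.sim_cache <- new.env(parent = emptyenv())

small_exp <- function(seed = 101) {
  key <- paste0("small", seed)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_tec_dataset(small_params(seed),
                                              design = small_design())
  }
  .sim_cache[[key]]
}

# full-size reference cohort (the default study conditions); used by the
# tests that probe the designed correlation structure
default_exp <- function(seed = 11) {
  key <- paste0("default", seed)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- simulate_tec_dataset(sim_params(seed = seed))
  }
  .sim_cache[[key]]
}

# independent pair-counting oracle for the exact rank-sum p-value:
# enumerates every relabeling and scores it by explicit greater/tie
# pair counts, never via pooled ranks
oracle_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_stat(x, y)
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) {
    u_stat(pooled[idx], pooled[-idx])
  })
  p <- 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9))
  min(1, p)
}
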