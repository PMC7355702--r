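# Small in-code fixtures shared across test files.

# a run with explicit registers
make_run <- function(id, t, mz, i, label = NA_integer_) {
  sample_run(id, t, mz, i, label = label)
}

# random run inside a given grid window
random_run <- function(id, n, grid, seed, label = NA_integer_) {
  set.seed(seed)
  sample_run(id,
             time = runif(n, grid$time_start, grid$time_end - 1e-6),
             mz = runif(n, grid$mass_center_min - grid$mass_radius,
                        grid$mass_center_max + grid$mass_radius - 1e-6),
             intensity = rexp(n, 1 / 100),
             label = label)
}

# the standard analysis grid
paper_grid <- function() build_grid(6, 17, 1/3, 49, 170, 0.5)

# Table-3-style printed reckonings: high/low counts per class for the 13
# selected variables (N = 56, 28 treated + 28 non-treated) and their
# published p-values to 2 significant figures. Rows 1-11 are enriched in
# the treated class, rows 12-13 in the non-treated class.
reckoning_56 <- function() {
  data.frame(
    high_nt = c(2, 5, 0, 0, 4, 0, 15, 14, 0, 0, 0, 10, 12),
    high_t  = c(27, 28, 23, 23, 25, 16, 28, 27, 11, 11, 10, 0, 1),
    p_2sf   = c(1.4e-12, 3.1e-11, 3.1e-11, 3.1e-11, 9.3e-9, 7.3e-7,
                2.0e-5, 7.1e-5, 1.4e-4, 1.4e-4, 3.7e-4, 3.7e-4, 4.7e-4),
    direction = c(rep(1L, 11), 0L, 0L))
}

# enrichment arguments (n_selected, k_in_class) implied by a reckoning
# row: the high level selects the samples, counted in the enriched class
reckoning_args <- function(row) {
  n_high <- row$high_nt + row$high_t
  c(n = n_high, k = if (row$direction == 1L) row$high_t else row$high_nt)
}

# fast simulation config for pipeline tests: 8/class keeps perfect
# order-1 splits significant at 5e-4 even inside leave-one-out folds
# (1/C(15,7) = 1.6e-4); the full background library keeps the top-1%
# codification cutoff inside the compound intensity range
small_sim <- function(seed, ...) {
  args <- list(n_per_class = 8, n_background = 24, scan_interval = 0.1,
               intensity_noise_cv = 0.05, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# brute-force hypergeometric upper tail by exhaustive subset enumeration
brute_upper <- function(N, K, n, k) {
  if (n == 0) return(if (k == 0) 1 else 0)
  subsets <- utils::combn(N, n)
  hits <- sum(colSums(subsets <= K) >= k)
  hits / choose(N, n)
}
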