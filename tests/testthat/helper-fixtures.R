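# fixtures shared across test files; all generated in code

national_marginals <- function() {
  capture_marginals(c(2465, 1314, 2211), c(721, 422, 415), 210,
                    stratum = "National")
}

national_cells <- function() {
  c(`100` = 1532, `010` = 388, `001` = 1584,
    `110` = 511, `101` = 212, `011` = 205, `111` = 210)
}

eastern_cells <- function() {
  c(`100` = 333, `010` = 98, `001` = 48,
    `110` = 175, `101` = 14, `011` = 28, `111` = 36)
}

# random consistent marginals: built from a random 7-cell table, so
# inclusion-exclusion can never go negative
random_consistent_marginals <- function(max_count = 500) {
  cells <- stats::setNames(sample.int(max_count + 1, 7) - 1L,
                           pattern_order3())
  marginals_from_table(capture_history_table(cells, stratum = "rand"))
}

pattern_order3 <- function() c("100", "010", "001", "110", "101", "011", "111")

quick_cfg <- function(seed = 1, K = 5, n_samples = 300, burn_in = 500,
                      thinning = 2) {
  lcmcr_config(K_star = K, n_samples = n_samples, burn_in = burn_in,
               thinning = thinning, seed = seed)
}
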