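# exact marginal posterior of N for the homogeneous (K = 1) reduction:
# lambda integrated out under Beta(1,1), p(N) ~ 1/N
exact_k1_posterior <- function(cells, n_max) {
  m <- marginals_from_table(capture_history_table(cells))
  n <- sum(cells)
  Ns <- n:n_max
  lp <- -log(Ns) + lchoose(Ns, n) +
    vapply(Ns, function(N) sum(lbeta(1 + m$n, 1 + N - m$n)), numeric(1))
  w <- exp(lp - max(lp))
  list(N = Ns, p = w / sum(w))
}

test_that("K = 1 posterior matches the exactly enumerated distribution", {
  cells <- national_cells()
  ex <- exact_k1_posterior(cells, 40000)
  cdf <- cumsum(ex$p)
  exact_med <- ex$N[which(cdf >= 0.5)[1]]
  exact_q <- c(ex$N[which(cdf >= 0.025)[1]], ex$N[which(cdf >= 0.975)[1]])

  f <- fit_lcmcr(capture_history_table(cells),
                 lcmcr_config(K_star = 1, n_samples = 2000, burn_in = 2000,
                              thinning = 5, seed = 5))
  expect_lt(abs(f$median_N - exact_med) / exact_med, 0.005)
  et <- credible_set(f$draws_N, 0.95, "equal_tail")
  expect_lt(abs(et[1] - exact_q[1]) / exact_q[1], 0.02)
  expect_lt(abs(et[2] - exact_q[2]) / exact_q[2], 0.02)
})

test_that("compiled and pure-R engines sample the same posterior", {
  t <- capture_history_table(eastern_cells())
  cfg <- lcmcr_config(K_star = 3, n_samples = 800, burn_in = 2000,
                      thinning = 5, seed = 21)
  fc <- fit_lcmcr(t, cfg, engine = "cpp")
  fr <- fit_lcmcr(t, cfg, engine = "r")
  expect_lt(abs(fc$median_N - fr$median_N) / fr$median_N, 0.1)
  expect_lt(abs(mean(fc$draws_p0) - mean(fr$draws_p0)), 0.05)
})

test_that("posterior draws respect the structural invariants", {
  f <- fit_lcmcr(capture_history_table(national_cells()), quick_cfg(seed = 2))
  expect_true(all(f$draws_N >= f$n_observed))
  expect_true(all(f$draws_p0 > 0 & f$draws_p0 < 1))
  expect_true(all(f$draws_alpha > 0))
  expect_true(f$cs_lower <= f$median_N && f$median_N <= f$cs_upper)
  expect_length(f$draws_N, 300)
})

test_that("degenerate all-111 table implies no unseen individuals", {
  cells <- stats::setNames(c(0L, 0L, 0L, 0L, 0L, 0L, 500L), pattern_order3())
  f <- fit_lcmcr(capture_history_table(cells), quick_cfg(seed = 3))
  expect_lt(stats::median(f$draws_p0), 0.01)
  expect_equal(f$median_N, 500)
})

test_that("homogeneous two-occasion fit agrees with the Chapman oracle", {
  sim <- simulate_captures(population_scenario(N = 2000,
                                               lambda = c(0.4, 0.4),
                                               seed = 7))
  m <- marginals_from_table(sim$table)
  ch <- chapman(m$n[1], m$n[2], m$pair_overlaps[[1]])$estimate
  f <- fit_lcmcr(sim$table,
                 lcmcr_config(K_star = 1, n_samples = 1000, burn_in = 2000,
                              thinning = 5, seed = 8))
  expect_lt(abs(f$median_N - ch) / ch, 0.1)
})

test_that("occasion permutation leaves the posterior of N unchanged", {
  cells <- national_cells()
  perm <- names(cells)
  # swap occasions 1 and 3 in each pattern
  perm_names <- vapply(strsplit(perm, ""), function(b)
    paste0(b[3], b[2], b[1]), character(1))
  permuted <- stats::setNames(unname(cells), perm_names)
  f1 <- fit_lcmcr(capture_history_table(cells), quick_cfg(seed = 6))
  f2 <- fit_lcmcr(capture_history_table(permuted), quick_cfg(seed = 6))
  expect_lt(abs(f1$median_N - f2$median_N) / f1$median_N, 0.1)
})

test_that("identical seeds give bit-identical chains", {
  t <- capture_history_table(eastern_cells())
  f1 <- fit_lcmcr(t, quick_cfg(seed = 11))
  f2 <- fit_lcmcr(t, quick_cfg(seed = 11))
  expect_identical(f1$draws_N, f2$draws_N)
  expect_identical(f1$draws_alpha, f2$draws_alpha)
  f3 <- fit_lcmcr(t, quick_cfg(seed = 12))
  expect_false(identical(f1$draws_N, f3$draws_N))
})

test_that("credible sets match quantile and brute-force oracles", {
  expect_equal(credible_set(1:100, 0.95, "equal_tail"),
               stats::quantile(1:100, c(0.025, 0.975), names = FALSE))
  set.seed(9)
  sym <- rnorm(5000)
  expect_lt(max(abs(credible_set(sym, 0.9, "hdi") -
                      credible_set(sym, 0.9, "equal_tail"))), 0.15)

  skew <- rexp(5000)
  hdi <- credible_set(skew, 0.9, "hdi")
  et <- credible_set(skew, 0.9, "equal_tail")
  expect_lt(hdi[2], et[2])
  # brute-force shortest 90% window over the sorted sample
  x <- sort(skew)
  m <- ceiling(0.9 * length(x))
  widths <- x[m:length(x)] - x[1:(length(x) - m + 1)]
  i <- which.min(widths)
  expect_equal(hdi, c(x[i], x[i + m - 1]))

  expect_error(credible_set(1:50), "at least 100")
})

test_that("multi-stratum fits are labelled, seeded and error-tagged", {
  tabs <- list(A = capture_history_table(eastern_cells(), "A"),
               B = capture_history_table(national_cells(), "B"))
  fits <- fit_all_strata(tabs, quick_cfg(seed = 14))
  expect_named(fits, c("A", "B"))
  # per-stratum seeds differ, so chains differ
  expect_false(identical(fits$A$draws_N[1:10], fits$B$draws_N[1:10]))
  expect_equal(fit_all_strata(list(), quick_cfg()), stats::setNames(list(), character(0)))
})

test_that("draw export and JSON summary round-trip", {
  f <- fit_lcmcr(capture_history_table(eastern_cells()), quick_cfg(seed = 4))
  tmp <- withr::local_tempfile(fileext = ".csv")
  export_draws(f, tmp)
  d <- utils::read.csv(tmp)
  expect_equal(d$N, f$draws_N)
  js <- jsonlite::fromJSON(fit_to_json(f))
  expect_equal(js$median, f$median_N)
  expect_equal(js$settings$K_star, 5)
})
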