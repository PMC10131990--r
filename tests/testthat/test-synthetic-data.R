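test_that("deterministic capture regimes tabulate exactly", {
  s <- population_scenario(N = 100, lambda = c(0.999999, 0.999999, 0.999999),
                           seed = 1)
  sim <- simulate_captures(s)
  expect_equal(unname(sim$table$cells[["111"]]), 100)
  expect_equal(sim$n_observed, 100)
})

test_that("homogeneous p = 0.5 captures match the multinomial expectation", {
  s <- population_scenario(N = 10000, lambda = c(0.5, 0.5, 0.5), seed = 77)
  sim <- simulate_captures(s)
  expect_lt(abs(sim$n_observed - 8750), 3 * sqrt(10000 * 7 / 8 * 1 / 8))
  chi <- stats::chisq.test(sim$table$cells,
                           p = rep(1 / 7, 7))
  expect_gt(chi$p.value, 0.01)
})

test_that("scenario calibrated to the national fit reproduces its marginals", {
  lam <- c(2465, 1314, 2211) / 18100
  sim <- simulate_captures(population_scenario(N = 18100, lambda = lam,
                                               seed = 12))
  m <- marginals_from_table(sim$table)
  for (j in 1:3) {
    expected <- c(2465, 1314, 2211)[j]
    expect_lt(abs(m$n[j] - expected), 4 * sqrt(expected))
  }
})

test_that("seeded capture simulation is bit-reproducible", {
  s <- population_scenario(N = 2000, lambda = matrix(c(0.3, 0.2, 0.4,
                                                       0.05, 0.07, 0.06),
                                                     3, 2),
                           weights = c(0.4, 0.6), seed = 99)
  expect_identical(simulate_captures(s)$table$cells,
                   simulate_captures(s)$table$cells)
})

test_that("latent-class structure is tracked for recovery tests", {
  s <- population_scenario(N = 5000,
                           lambda = matrix(c(0.5, 0.5, 0.5,
                                             0.05, 0.05, 0.05), 3, 2),
                           weights = c(0.5, 0.5), seed = 3)
  sim <- simulate_captures(s)
  expect_equal(sum(sim$class_sizes), 5000)
  expect_true(all(sim$observed_by_class <= sim$class_sizes))
  # high-capture class is observed nearly completely, low-capture class not
  frac <- sim$observed_by_class / sim$class_sizes
  expect_gt(frac[1], 0.8)
  expect_lt(frac[2], 0.3)
})

test_that("recruitment chains honour seeds, coupons and the target", {
  ch <- simulate_chain(chain_scenario(n_seeds = 24, target = 600,
                                      proportions = c(0.5, 0.5),
                                      coupons = 3, seed = 8))
  nodes <- ch$nodes
  expect_equal(sum(nodes$is_seed), 24)
  expect_equal(nrow(nodes), 600)
  out_deg <- table(nodes$recruiter_id[!nodes$is_seed])
  expect_lte(max(out_deg), 3)

  # dead recruitment: coupons nearly never return
  expect_warning(
    simulate_chain(chain_scenario(n_seeds = 2, target = 5000,
                                  proportions = c(0.5, 0.5),
                                  return_rate = 0.05, seed = 2)),
    "died out")
})

test_that("seeded chain simulation is bit-reproducible", {
  sc <- chain_scenario(n_seeds = 6, target = 300, proportions = c(0.7, 0.3),
                       h = 0.5, seed = 41)
  expect_identical(simulate_chain(sc)$nodes, simulate_chain(sc)$nodes)
})
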