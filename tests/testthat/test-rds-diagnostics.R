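toy_chain <- function() {
  recruitment_chain(data.frame(
    id = c("A", "B", "C", "D"),
    recruiter_id = c(NA, "A", "A", "B"),
    attribute = c("g1", "g1", "g2", "g1"),
    stringsAsFactors = FALSE))
}

test_that("homophily matches the hand-enumerated 4-node chain", {
  h <- recruitment_homophily(toy_chain())
  # recruits B(g1), C(g2), D(g1): shares 2/3, 1/3; same-group edges A-B, B-D
  expect_equal(h$observed, 2)
  expect_equal(h$expected, 2 / 3 + 1 / 3 + 2 / 3)
  expect_equal(h$H, 1.2)
})

test_that("random mixing gives H near 1, assortativity gives H above 1", {
  ch0 <- simulate_chain(chain_scenario(n_seeds = 24, target = 5000,
                                       proportions = c(0.6, 0.4), h = 0,
                                       seed = 5))
  expect_lt(abs(recruitment_homophily(ch0)$H - 1), 0.05)

  ch1 <- simulate_chain(chain_scenario(n_seeds = 24, target = 2000,
                                       proportions = c(0.6, 0.4), h = 1,
                                       seed = 5))
  h1 <- recruitment_homophily(ch1)
  n_edges <- sum(!ch1$nodes$is_seed)
  expect_equal(h1$observed, n_edges) # perfectly assortative
  expect_gt(h1$H, 1)
})

test_that("homophily is invariant to relabelling attribute values", {
  ch <- simulate_chain(chain_scenario(n_seeds = 8, target = 500,
                                      proportions = c(0.3, 0.7), h = 0.4,
                                      seed = 9))
  h1 <- recruitment_homophily(ch)$H
  relab <- ch$nodes
  relab$attribute <- ifelse(relab$attribute == "g1", "B", "A")
  h2 <- recruitment_homophily(recruitment_chain(
    relab[, c("id", "recruiter_id", "attribute")]))$H
  expect_equal(h1, h2)
})

test_that("chain validation enforces the forest structure", {
  expect_error(recruitment_chain(data.frame(
    id = c("A", "B"), recruiter_id = c("B", "A"),
    attribute = c("x", "x"))), "cycle|seed")
  expect_error(recruitment_chain(data.frame(
    id = c("A", "B"), recruiter_id = c(NA, "Z"),
    attribute = c("x", "x"))), "unknown")
})

test_that("chain CSV reader handles seeds and malformed input", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("recruit_id,recruiter_id,attribute",
               "A,,g1", "B,A,g1", "C,A,g2"), tmp)
  ch <- read_chain_csv(tmp)
  expect_equal(sum(ch$nodes$is_seed), 1)
  expect_equal(recruitment_homophily(ch)$observed, 1)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(read_chain_csv(bad), "malformed")
})

test_that("Geweke z is null-calibrated on iid chains and flags trends", {
  set.seed(31)
  zs <- replicate(50, geweke_z(rnorm(1000)))
  expect_lt(mean(abs(zs) > 3), 0.05)
  expect_lt(abs(mean(zs)), 0.5)

  trend <- seq(0, 10, length.out = 10000) + rnorm(10000)
  expect_gt(abs(geweke_z(trend)), 5)

  expect_error(geweke_z(rep(1, 1000)), "zero-variance")
  expect_error(geweke_z(rnorm(50)), "too short")
})

test_that("trace export produces ordered series and FD histogram bins", {
  te <- trace_export(1:10)
  expect_equal(nrow(te$trace), 10)
  expect_equal(te$trace$N, 1:10)
  expect_equal(sum(te$histogram$count), 10)

  const <- trace_export(rep(7, 25))
  expect_equal(nrow(const$histogram), 1)
  expect_equal(const$histogram$count, 25)

  set.seed(2)
  x <- rnorm(5000)
  te2 <- trace_export(x)
  expect_equal(sum(te2$histogram$count), 5000)
  expect_error(trace_export(numeric(0)), "no draws")
})
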