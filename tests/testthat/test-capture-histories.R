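test_that("inclusion-exclusion recovers the national 7-cell table", {
  t <- table_from_marginals(national_marginals())
  expect_equal(t$cells[names(national_cells())], national_cells())
  expect_equal(sum(t$cells), 2465 + 1314 + 2211 - 721 - 422 - 415 + 210)
})

test_that("complete-overlap marginals put all mass on 111", {
  m <- capture_marginals(c(5, 5, 5), c(5, 5, 5), 5)
  t <- table_from_marginals(m)
  expect_equal(unname(t$cells[["111"]]), 5)
  expect_equal(sum(t$cells), 5)
})

test_that("strict policy rejects the inconsistent Western marginals", {
  western <- capture_marginals(c(357, 164, 609), c(126, 182, 155), 100,
                               stratum = "Western")
  expect_error(table_from_marginals(western, policy = "strict"),
               "010 = -17")
  t <- suppressWarnings(table_from_marginals(western, policy = "clamp"))
  expect_equal(unname(t$cells[["010"]]), 0)
  expect_equal(attr(t, "clamped")$pattern, "010")
  expect_equal(attr(t, "clamped")$deficit, 17L)
  expect_warning(table_from_marginals(western, policy = "clamp"),
                 "deficit 17")
})

test_that("marginalization inverts construction (worked Eastern row)", {
  t <- capture_history_table(eastern_cells(), stratum = "Eastern")
  m <- marginals_from_table(t)
  expect_equal(unname(m$n), c(558, 337, 126))
  expect_equal(unname(m$pair_overlaps), c(211, 50, 64))
  expect_equal(m$triple_overlap, 36L)

  zero <- capture_history_table(
    stats::setNames(rep(0L, 7), pattern_order3()))
  mz <- marginals_from_table(zero)
  expect_true(all(mz$n == 0) && all(mz$pair_overlaps == 0) &&
                mz$triple_overlap == 0)
})

test_that("marginals/table round-trip holds on random consistent inputs", {
  set.seed(20240901)
  for (i in 1:40) {
    m <- random_consistent_marginals()
    m2 <- marginals_from_table(table_from_marginals(m, policy = "strict"))
    expect_equal(m2$n, m$n)
    expect_equal(m2$pair_overlaps, m$pair_overlaps)
    expect_equal(m2$triple_overlap, m$triple_overlap)
  }
})

test_that("total observed matches inclusion-exclusion identity", {
  set.seed(4)
  for (i in 1:20) {
    m <- random_consistent_marginals()
    t <- table_from_marginals(m)
    expect_equal(sum(t$cells),
                 sum(m$n) - sum(m$pair_overlaps) + m$triple_overlap)
  }
})

test_that("pooling is cellwise-linear and commutes with construction", {
  set.seed(11)
  ms <- replicate(5, random_consistent_marginals(), simplify = FALSE)
  tables <- lapply(ms, table_from_marginals, policy = "strict")
  pooled <- pool_strata(tables)
  summed <- capture_marginals(
    Reduce(`+`, lapply(ms, `[[`, "n")),
    Reduce(`+`, lapply(ms, `[[`, "pair_overlaps")),
    Reduce(`+`, lapply(ms, `[[`, "triple_overlap")))
  expect_equal(pooled$cells, table_from_marginals(summed)$cells)

  single <- pool_strata(tables[1])
  expect_equal(single$cells, tables[[1]]$cells)
  expect_error(pool_strata(list()), "no tables")
})

test_that("provincial tallies pool to the national marginals", {
  m <- rwanda_msm_marginals(include_national = FALSE)
  nat <- national_marginals()
  expect_equal(Reduce(`+`, lapply(m, `[[`, "n")), nat$n)
  expect_equal(Reduce(`+`, lapply(m, `[[`, "pair_overlaps")),
               nat$pair_overlaps)
  expect_equal(Reduce(`+`, lapply(m, `[[`, "triple_overlap")),
               nat$triple_overlap)
})

test_that("capture_summary reproduces the published recapture percentages", {
  s <- capture_summary(national_marginals(), n_assigned = 2723)
  expect_equal(s$pct, c(90.53, 54.87, 19.09, 18.77))

  none <- capture_marginals(c(10, 10, 10), c(0, 0, 0), 0)
  expect_true(all(capture_summary(none)$pct == 0))

  degenerate <- capture_marginals(c(10, 0, 0), c(0, 0, 0), 0)
  sd_ <- capture_summary(degenerate)
  expect_true(all(is.na(sd_$pct[sd_$undefined])))
  expect_true(any(sd_$undefined))
})

test_that("marginal and cell CSV round-trips preserve the data", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  m <- rwanda_msm_marginals(include_national = FALSE)
  write_marginals_csv(m, tmp)
  m2 <- read_marginals_csv(tmp)
  expect_equal(names(m2), names(m))
  expect_equal(m2$Kigali$n, m$Kigali$n, ignore_attr = TRUE)

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  tabs <- list(Eastern = capture_history_table(eastern_cells(), "Eastern"))
  write_cells_csv(tabs, tmp2)
  t2 <- read_cells_csv(tmp2)
  expect_equal(t2$Eastern$cells, tabs$Eastern$cells)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("stratum,a,b\nx,1,2", bad)
  expect_error(read_marginals_csv(bad), "malformed")
})

test_that("invalid marginals are rejected with informative errors", {
  expect_error(capture_marginals(c(10, 10, 10), c(11, 0, 0), 0), "exceeds")
  expect_error(capture_marginals(c(10, 10, 10), c(5, 5, 5), 6),
               "triple overlap")
  expect_error(capture_marginals(c(10.5, 10, 10), c(5, 5, 5), 5),
               "non-negative integers")
  expect_error(capture_history_table(c(`100` = 1)), "must appear")
})

test_that("JSON export carries cells and clamping warnings", {
  western <- capture_marginals(c(357, 164, 609), c(126, 182, 155), 100,
                               stratum = "Western")
  t <- suppressWarnings(table_from_marginals(western))
  js <- jsonlite::fromJSON(table_to_json(t))
  expect_equal(js$n_observed, sum(t$cells))
  expect_equal(js$clamped$pattern, "010")
})
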