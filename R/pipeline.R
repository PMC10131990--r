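#' Run the full population-size-estimation pipeline
#'
#' Marginals CSV to report: builds per-stratum capture-history tables
#' (recording any clamping), fits the latent-class model to each requested
#' stratum and to the pooled table, attaches classical pairwise and
#' independence diagnostics, optionally checks recruitment homophily from a
#' chain CSV and converts estimates to proportions of user-supplied
#' denominators, and writes a JSON report plus CSV estimate/draw exports.
#'
#' @param input Path to a marginals CSV
#'   (`stratum,n1,n2,n3,n12,n13,n23,n123`), or a named list of
#'   [capture_marginals()] objects.
#' @param config An [lcmcr_config()]; its `seed` controls every stratum.
#' @param policy Negative-cell policy passed to [table_from_marginals()].
#' @param strata Strata to fit individually (default all in `input`); the
#'   pooled fit always runs.
#' @param denominators Optional named vector of adult-population
#'   denominators for proportion estimates.
#' @param chain Optional path to a recruitment-chain CSV for the homophily
#'   diagnostic.
#' @param out_dir Optional output directory; when supplied, writes
#'   `report.json`, `pse_estimates.csv` and per-stratum `draws_<stratum>.csv`.
#' @return The report, invisibly: a list with `tables`, `fits`, `estimates`
#'   (data frame), `diagnostics`, `homophily`, `warnings` and `settings`.
#' @export
run_pse <- function(input, config = lcmcr_config(), policy = "clamp",
                    strata = NULL, denominators = NULL, chain = NULL,
                    out_dir = NULL) {
  marginals <- if (is.character(input)) read_marginals_csv(input) else input
  stopifnot(length(marginals) > 0,
            all(vapply(marginals, inherits, logical(1), "capture_marginals")))
  if (is.null(names(marginals))) {
    names(marginals) <- vapply(marginals, function(m) m$stratum, character(1))
  }
  strata <- strata %||% names(marginals)
  unknown <- setdiff(strata, names(marginals))
  if (length(unknown) > 0) {
    stop(sprintf("unknown strata: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }

  clamp_log <- list()
  tables <- lapply(marginals, function(m) {
    tb <- withCallingHandlers(
      table_from_marginals(m, policy = policy),
      warning = function(w) {
        clamp_log[[m$stratum]] <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      })
    tb
  })

  pooled_m <- Reduce(function(a, b) capture_marginals(
    a$n + b$n, a$pair_overlaps + b$pair_overlaps,
    a$triple_overlap + b$triple_overlap, stratum = "pooled"), marginals)
  pooled <- table_from_marginals(pooled_m, policy = policy)

  fits <- fit_all_strata(tables[strata], config)
  cfg_pooled <- config
  cfg_pooled$seed <- derive_seed(config$seed, 0L)
  fits$pooled <- fit_lcmcr(pooled, cfg_pooled)

  est <- do.call(rbind, lapply(names(fits), function(s) {
    f <- fits[[s]]
    row <- data.frame(stratum = s, n_observed = f$n_observed,
                      median = f$median_N, cs_lower = f$cs_lower,
                      cs_upper = f$cs_upper, level = f$cs_level,
                      stringsAsFactors = FALSE)
    if (!is.null(denominators)) {
      den <- denominators[s]
      if (!is.na(den)) {
        pr <- proportion_estimate(f, den)
        row$pct_median <- pr$pct_median
        row$pct_lower <- pr$pct_lower
        row$pct_upper <- pr$pct_upper
      } else {
        warning(sprintf("no denominator for stratum '%s'; proportion omitted",
                        s), call. = FALSE)
        row$pct_median <- row$pct_lower <- row$pct_upper <- NA_real_
      }
    }
    row
  }))

  pm <- marginals_from_table(pooled)
  diagnostics <- list(
    chapman_12 = chapman(pm$n[1], pm$n[2], pm$pair_overlaps[["n12"]]),
    chapman_13 = chapman(pm$n[1], pm$n[3], pm$pair_overlaps[["n13"]]),
    chapman_23 = chapman(pm$n[2], pm$n[3], pm$pair_overlaps[["n23"]]),
    independence_mle = independence_mle_3list(pooled),
    geweke_pooled = tryCatch(geweke_z(fits$pooled$draws_N),
                             error = function(e) NA_real_)
  )

  homophily <- NULL
  if (!is.null(chain)) {
    homophily <- recruitment_homophily(read_chain_csv(chain))
  }

  report <- list(tables = tables, pooled_table = pooled, fits = fits,
                 estimates = est, diagnostics = diagnostics,
                 homophily = homophily, warnings = clamp_log,
                 settings = unclass(config), policy = policy)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(est, file.path(out_dir, "pse_estimates.csv"),
                     row.names = FALSE, quote = FALSE)
    for (s in names(fits)) {
      export_draws(fits[[s]], file.path(out_dir, paste0("draws_", s, ".csv")))
    }
    json <- list(
      estimates = est,
      diagnostics = list(
        chapman = lapply(diagnostics[1:3], function(d)
          list(estimate = d$estimate, ci = d$ci)),
        independence_mle = diagnostics$independence_mle,
        geweke_pooled = diagnostics$geweke_pooled,
        homophily = if (!is.null(homophily)) homophily$H else NULL),
      warnings = clamp_log, settings = unclass(config), policy = policy,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    writeLines(jsonlite::toJSON(json, auto_unbox = TRUE, digits = NA,
                                dataframe = "rows", null = "null"),
               file.path(out_dir, "report.json"))
  }
  invisible(report)
}

#' Population size as a proportion of a denominator
#'
#' Divides every posterior draw of N by an externally supplied adult
#' population denominator and summarizes the resulting percentage with its
#' median and credible set.
#'
#' @param fit An `lcmcr_fit`.
#' @param denominator Positive adult-population count.
#' @param digits Decimal places for the printed percentages (default 2).
#' @return List with `pct_median`, `pct_lower`, `pct_upper` and `level`.
#' @export
proportion_estimate <- function(fit, denominator, digits = 2) {
  stopifnot(inherits(fit, "lcmcr_fit"))
  if (!is.numeric(denominator) || length(denominator) != 1 ||
      is.na(denominator) || denominator <= 0) {
    stop("`denominator` must be a positive count", call. = FALSE)
  }
  pct <- 100 * fit$draws_N / denominator
  cs <- credible_set(pct, fit$cs_level, fit$cs_method)
  list(pct_median = round_half_up(stats::median(pct), digits),
       pct_lower = round_half_up(cs[1], digits),
       pct_upper = round_half_up(cs[2], digits),
       level = fit$cs_level)
}
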