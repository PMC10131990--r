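#' Respondent-driven-sampling recruitment chain
#'
#' A recruiter-to-recruit forest: every non-seed node has exactly one
#' recruiter, seeds have none, and each node carries a categorical attribute
#' (e.g. prior-capture status) used for dependency diagnostics.
#'
#' @param nodes Data frame with columns `id`, `recruiter_id` (`NA` for
#'   seeds) and `attribute`.
#' @return An object of class `recruitment_chain`.
#' @export
recruitment_chain <- function(nodes) {
  need <- c("id", "recruiter_id", "attribute")
  if (!all(need %in% names(nodes))) {
    stop("`nodes` needs columns id, recruiter_id, attribute", call. = FALSE)
  }
  nodes$id <- as.character(nodes$id)
  nodes$recruiter_id <- as.character(nodes$recruiter_id)
  nodes$attribute <- as.character(nodes$attribute)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  if (anyNA(nodes$attribute)) {
    stop("attribute must be defined on all nodes", call. = FALSE)
  }
  is_seed <- is.na(nodes$recruiter_id) | !nzchar(nodes$recruiter_id)
  if (!any(is_seed)) stop("a chain needs at least one seed", call. = FALSE)
  if (!all(nodes$recruiter_id[!is_seed] %in% nodes$id)) {
    stop("recruiter_id refers to an unknown node", call. = FALSE)
  }
  # forest check: walking up from any node must terminate at a seed
  parent <- stats::setNames(nodes$recruiter_id, nodes$id)
  parent[is_seed] <- NA_character_
  for (v in nodes$id) {
    seen <- character(0)
    while (!is.na(parent[[v]])) {
      if (v %in% seen) stop("recruitment cycle detected", call. = FALSE)
      seen <- c(seen, v)
      v <- parent[[v]]
    }
  }
  nodes$is_seed <- is_seed
  structure(list(nodes = nodes), class = "recruitment_chain")
}

#' Read a recruitment chain from CSV
#'
#' Expected header: `recruit_id,recruiter_id,attribute` with an empty
#' `recruiter_id` marking seeds.
#'
#' @param path CSV file path.
#' @return A [recruitment_chain()].
#' @export
read_chain_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("recruit_id", "recruiter_id", "attribute")
  if (!all(need %in% names(df))) {
    stop("malformed chain CSV; expected recruit_id,recruiter_id,attribute",
         call. = FALSE)
  }
  recruitment_chain(data.frame(id = df$recruit_id,
                               recruiter_id = ifelse(nzchar(df$recruiter_id),
                                                     df$recruiter_id, NA),
                               attribute = df$attribute,
                               stringsAsFactors = FALSE))
}

#' Recruitment homophily ratio
#'
#' Dependency diagnostic between a node attribute and RDS recruitment:
#' `H = observed / expected`, where `observed` counts recruiter-recruit
#' edges whose endpoints share the attribute and `expected` is the
#' same-attribute count under random mixing, accumulated per edge as the
#' recruit-population share of the recruit's own attribute value (in
#' aggregate `n_edges * sum_g s_g^2` for recruit shares `s_g`). `H` near 1
#' indicates recruitment is not patterned on the attribute, supporting
#' independence between that attribute and the recruitment capture.
#' Seeds recruit but are never counted as recruits.
#'
#' @param chain A [recruitment_chain()].
#' @param attribute Column of the chain's nodes to test (default
#'   `"attribute"`).
#' @return An object of class `homophily_result` with fields `observed`,
#'   `expected` and `H`.
#' @export
recruitment_homophily <- function(chain, attribute = "attribute") {
  stopifnot(inherits(chain, "recruitment_chain"))
  nodes <- chain$nodes
  if (!attribute %in% names(nodes)) {
    stop(sprintf("attribute '%s' not found", attribute), call. = FALSE)
  }
  attr_of <- stats::setNames(as.character(nodes[[attribute]]), nodes$id)
  if (anyNA(attr_of)) {
    stop("attribute must be defined on all nodes", call. = FALSE)
  }
  recruits <- nodes[!nodes$is_seed, ]
  if (nrow(recruits) == 0) stop("chain has no recruitments", call. = FALSE)
  shares <- table(attr_of[recruits$id]) / nrow(recruits)
  rec_attr <- attr_of[recruits$id]
  recr_attr <- attr_of[recruits$recruiter_id]
  observed <- sum(rec_attr == recr_attr)
  expected <- sum(as.numeric(shares[rec_attr]))
  if (expected <= 0) {
    stop("random-mixing expectation is zero; homophily undefined",
         call. = FALSE)
  }
  structure(list(observed = observed, expected = expected,
                 H = observed / expected),
            class = "homophily_result")
}

#' @export
print.homophily_result <- function(x, ...) {
  cat(sprintf("Recruitment homophily: H = %.4f (observed %d, expected %.2f)\n",
              x$H, x$observed, x$expected))
  invisible(x)
}

# AR-based estimate of the spectral density at frequency zero, the
# long-run variance used by the Geweke diagnostic
spectrum0_ar <- function(x) {
  if (stats::var(x) == 0) {
    stop("zero-variance chain segment; diagnostic undefined", call. = FALSE)
  }
  fit <- stats::ar(x, aic = TRUE, order.max = min(30, length(x) - 1))
  if (length(fit$ar) == 0) return(fit$var.pred)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence z-score
#'
#' Compares the mean of the first `frac_a` of a chain with the mean of the
#' last `frac_b`, standardized by AR spectral-density estimates of the
#' long-run variance of each segment. Under stationarity the score is
#' approximately standard normal; large |z| flags non-convergence.
#'
#' @param draws Numeric chain of at least 200 draws.
#' @param frac_a Leading fraction (default 0.1).
#' @param frac_b Trailing fraction (default 0.5).
#' @return The z-score (numeric scalar).
#' @export
geweke_z <- function(draws, frac_a = 0.1, frac_b = 0.5) {
  n <- length(draws)
  if (n < 200) stop("chain too short for the Geweke diagnostic (need >= 200)",
                    call. = FALSE)
  stopifnot(frac_a > 0, frac_b > 0, frac_a + frac_b <= 1)
  a <- draws[seq_len(floor(frac_a * n))]
  b <- draws[(n - floor(frac_b * n) + 1):n]
  sa <- spectrum0_ar(a)
  sb <- spectrum0_ar(b)
  (mean(a) - mean(b)) / sqrt(sa / length(a) + sb / length(b))
}

#' Plot-ready trace series and histogram bins
#'
#' Deterministic summaries for convergence graphics: the ordered (iteration,
#' value) series and histogram bins by the Freedman-Diaconis rule (a single
#' unit-width bin when the draws are constant).
#'
#' @param draws Non-empty numeric vector of kept draws.
#' @return List with `trace` (data frame `iteration`, `N`) and `histogram`
#'   (data frame `lower`, `upper`, `mid`, `count`).
#' @export
trace_export <- function(draws) {
  if (length(draws) == 0) stop("no draws", call. = FALSE)
  trace <- data.frame(iteration = seq_along(draws), N = draws)
  if (diff(range(draws)) == 0) {
    hist_df <- data.frame(lower = draws[1] - 0.5, upper = draws[1] + 0.5,
                          mid = draws[1], count = length(draws))
  } else {
    h <- graphics::hist(draws, breaks = "FD", plot = FALSE)
    hist_df <- data.frame(lower = utils::head(h$breaks, -1),
                          upper = h$breaks[-1],
                          mid = h$mids, count = h$counts)
  }
  list(trace = trace, histogram = hist_df)
}
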