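#' Latent-class capture scenario
#'
#' Generative twin of the fitted model: a closed population of `N` members,
#' each belonging to one of `K` latent classes with class weight
#' `weights[k]`, captured on occasion j independently with probability
#' `lambda[j, k]`.
#'
#' @param N True population size.
#' @param lambda Capture probabilities in (0, 1): a length-k vector (single
#'   class) or a k x K matrix.
#' @param weights Class weights summing to 1 (default uniform).
#' @param seed RNG seed.
#' @return An object of class `population_scenario`.
#' @export
population_scenario <- function(N, lambda, weights = NULL, seed = 1L) {
  N <- assert_count(N, "N", min = 1)
  lambda <- as.matrix(lambda)
  if (any(lambda <= 0) || any(lambda >= 1)) {
    stop("capture probabilities must lie strictly in (0, 1)", call. = FALSE)
  }
  K <- ncol(lambda)
  weights <- weights %||% rep(1 / K, K)
  if (length(weights) != K || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8) {
    stop("`weights` must be a length-K probability vector", call. = FALSE)
  }
  structure(list(N = N, k = nrow(lambda), K = K, weights = weights,
                 lambda = lambda, seed = as.integer(seed)),
            class = "population_scenario")
}

#' Simulate capture histories from a latent-class scenario
#'
#' Draws each member's class, then independent Bernoulli captures per
#' occasion; never-captured members are dropped (they are unobservable) and
#' the rest are tabulated into a [capture_history_table()]. The true latent
#' structure is returned alongside for recovery tests.
#'
#' @param s A [population_scenario()].
#' @return List with `table` (the observable table), `n_observed`,
#'   `class_sizes` (true class membership counts over the whole population)
#'   and `observed_by_class`.
#' @export
#' @examples
#' s <- population_scenario(N = 1000, lambda = c(0.3, 0.3, 0.3), seed = 42)
#' sim <- simulate_captures(s)
#' sim$n_observed
simulate_captures <- function(s) {
  stopifnot(inherits(s, "population_scenario"))
  set.seed(s$seed)
  z <- sample.int(s$K, s$N, replace = TRUE, prob = s$weights)
  probs <- t(s$lambda)[z, , drop = FALSE] # N x k
  caps <- matrix(stats::rbinom(length(probs), 1, probs),
                 nrow = s$N, ncol = s$k)
  pat <- do.call(paste0, as.data.frame(caps))
  observed <- pat != strrep("0", s$k)
  tab <- table(factor(pat[observed], levels = pattern_order(s$k)))
  cells <- stats::setNames(as.integer(tab), names(tab))
  list(
    table = capture_history_table(cells, stratum = "simulated"),
    n_observed = sum(observed),
    class_sizes = tabulate(z, nbins = s$K),
    observed_by_class = tabulate(z[observed], nbins = s$K)
  )
}

#' RDS recruitment-chain scenario
#'
#' Branching peer recruitment from purposively chosen seeds: each
#' participant receives `coupons` coupons, each returned independently with
#' probability `return_rate`; a recruit's attribute copies the recruiter's
#' with probability `h` (assortativity) and is otherwise drawn from the
#' population group shares, so `h = 0` is random mixing and `h = 1` is
#' perfect assortativity.
#'
#' @param n_seeds Number of seeds (e.g. 24 = 3 per site at 8 sites).
#' @param target Target sample size (recruits + seeds).
#' @param proportions Attribute group shares (simplex).
#' @param h Assortativity in `[0, 1]`.
#' @param coupons Coupons per participant (default 3).
#' @param return_rate Per-coupon return probability (default 0.85,
#'   i.e. 15% coupon loss).
#' @param seed RNG seed.
#' @return An object of class `chain_scenario`.
#' @export
chain_scenario <- function(n_seeds, target, proportions, h = 0,
                           coupons = 3, return_rate = 0.85, seed = 1L) {
  stopifnot(n_seeds >= 1, target >= n_seeds, h >= 0, h <= 1, coupons >= 1,
            return_rate > 0, return_rate <= 1,
            all(proportions > 0), abs(sum(proportions) - 1) < 1e-8)
  if (is.null(names(proportions))) {
    names(proportions) <- paste0("g", seq_along(proportions))
  }
  structure(list(n_seeds = as.integer(n_seeds), target = as.integer(target),
                 proportions = proportions, h = h,
                 coupons = as.integer(coupons), return_rate = return_rate,
                 seed = as.integer(seed)),
            class = "chain_scenario")
}

#' Simulate an RDS recruitment chain
#'
#' Breadth-first branching from the seeds until the target sample size is
#' reached; if every coupon chain dies out first, the partial chain is
#' returned with a warning.
#'
#' @param c A [chain_scenario()].
#' @return A [recruitment_chain()].
#' @export
#' @examples
#' ch <- simulate_chain(chain_scenario(n_seeds = 4, target = 200,
#'                                     proportions = c(0.5, 0.5), h = 0,
#'                                     seed = 3))
#' recruitment_homophily(ch)
simulate_chain <- function(c) {
  stopifnot(inherits(c, "chain_scenario"))
  set.seed(c$seed)
  groups <- names(c$proportions)
  id <- character(c$target)
  recruiter <- character(c$target)
  attrib <- character(c$target)
  n <- c$n_seeds
  id[1:n] <- paste0("S", seq_len(n))
  recruiter[1:n] <- NA_character_
  attrib[1:n] <- sample(groups, n, replace = TRUE, prob = c$proportions)
  queue <- 1:n
  qi <- 1L
  while (n < c$target && qi <= length(queue)) {
    r <- queue[qi]
    qi <- qi + 1L
    returned <- stats::rbinom(1, c$coupons, c$return_rate)
    for (j in seq_len(min(returned, c$target - n))) {
      n <- n + 1L
      id[n] <- paste0("R", n)
      recruiter[n] <- id[r]
      attrib[n] <- if (stats::runif(1) < c$h) attrib[r] else
        sample(groups, 1, prob = c$proportions)
      queue <- c(queue, n)
    }
  }
  if (n < c$target) {
    warning(sprintf("recruitment died out at %d of %d participants",
                    n, c$target), call. = FALSE)
  }
  recruitment_chain(data.frame(
    id = id[1:n], recruiter_id = recruiter[1:n], attribute = attrib[1:n],
    stringsAsFactors = FALSE))
}
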