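#' Published capture tallies of the 2021 Rwanda national MSM study
#'
#' Per-province marginals of the three capture rounds (unique-object
#' distribution, MSM-friendly service provision, RDS survey): occasion
#' totals `n1..n3`, pairwise overlaps `n12` (object holders among service
#' recipients), `n13`/`n23` (object holders / service recipients among RDS
#' participants), the triple overlap `n123`, and the number of objects
#' assigned for distribution in round one. The five provincial rows sum to
#' the national marginals (2465, 1314, 2211; 721, 422, 415; 210). The
#' Western row is internally inconsistent (its implied 010 cell is -17),
#' a known feature of the published tallies that the clamp policy of
#' [table_from_marginals()] handles.
#'
#' @param include_national Append a `"National"` row pooled across the five
#'   provinces (default `TRUE`).
#' @return Named list of [capture_marginals()] objects; attribute
#'   `n_assigned` on the list gives the round-one objects assigned per
#'   stratum.
#' @export
#' @examples
#' m <- rwanda_msm_marginals()
#' m$National
rwanda_msm_marginals <- function(include_national = TRUE) {
  path <- system.file("extdata", "rwanda_msm_marginals.csv",
                      package = "crc3s", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- read_marginals_csv(path)
  assigned <- stats::setNames(df$n_assigned, df$stratum)
  if (include_national) {
    out$National <- capture_marginals(
      c(sum(df$n1), sum(df$n2), sum(df$n3)),
      c(sum(df$n12), sum(df$n13), sum(df$n23)),
      sum(df$n123), stratum = "National")
    assigned <- c(assigned, National = sum(df$n_assigned))
  }
  attr(out, "n_assigned") <- assigned
  out
}
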