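#' Per-occasion capture totals and overlaps
#'
#' The published form of multi-source capture-recapture data: how many
#' individuals each occasion captured, how many each pair of occasions both
#' captured, and (for three occasions) how many all three captured.
#'
#' @param n Integer vector of per-occasion capture totals (length k >= 2).
#' @param pair_overlaps Integer vector of pairwise recapture counts, one per
#'   unordered pair of occasions in `combn` order: for k = 3 this is
#'   `c(n12, n13, n23)`.
#' @param triple_overlap Count captured on all three occasions (required when
#'   k = 3).
#' @param stratum Label for the stratum these counts describe.
#' @return An object of class `capture_marginals`.
#' @export
#' @examples
#' capture_marginals(c(2465, 1314, 2211), c(721, 422, 415), 210, "National")
capture_marginals <- function(n, pair_overlaps, triple_overlap = NULL,
                              stratum = "") {
  n <- assert_count(n, "n")
  k <- length(n)
  if (k < 2) stop("at least two capture occasions are required", call. = FALSE)
  pair_overlaps <- assert_count(pair_overlaps, "pair_overlaps")
  pairs <- utils::combn(k, 2)
  if (length(pair_overlaps) != ncol(pairs)) {
    stop(sprintf("expected %d pairwise overlaps for k = %d", ncol(pairs), k),
         call. = FALSE)
  }
  names(pair_overlaps) <- apply(pairs, 2, function(ij)
    paste0("n", ij[1], ij[2]))
  for (j in seq_len(ncol(pairs))) {
    lim <- min(n[pairs[, j]])
    if (pair_overlaps[j] > lim) {
      stop(sprintf("overlap %s = %d exceeds min of its occasion totals (%d)",
                   names(pair_overlaps)[j], pair_overlaps[j], lim),
           call. = FALSE)
    }
  }
  if (k == 3) {
    if (is.null(triple_overlap)) {
      stop("`triple_overlap` is required when k = 3", call. = FALSE)
    }
    triple_overlap <- assert_count(triple_overlap, "triple_overlap")
    if (any(triple_overlap > pair_overlaps)) {
      stop("triple overlap exceeds a pairwise overlap", call. = FALSE)
    }
  } else {
    triple_overlap <- NULL
  }
  structure(
    list(k = k, n = n, pair_overlaps = pair_overlaps,
         triple_overlap = triple_overlap, stratum = as.character(stratum)),
    class = "capture_marginals"
  )
}

#' @export
print.capture_marginals <- function(x, ...) {
  cat(sprintf("Capture marginals [%s], k = %d occasions\n",
              if (nzchar(x$stratum)) x$stratum else "unlabelled", x$k))
  cat("  totals:  ", paste(x$n, collapse = ", "), "\n")
  cat("  overlaps:", paste(sprintf("%s=%d", names(x$pair_overlaps),
                                   x$pair_overlaps), collapse = ", "), "\n")
  if (!is.null(x$triple_overlap)) {
    cat("  triple:  ", x$triple_overlap, "\n")
  }
  invisible(x)
}

# canonical pattern order: by number of occasions captured, then by the
# pattern read as a binary number, descending -- for k = 3 this is
# 100, 010, 001, 110, 101, 011, 111
pattern_order <- function(k) {
  pats <- apply(as.matrix(expand.grid(rep(list(1:0), k)))[, k:1, drop = FALSE],
                1, paste0, collapse = "")
  pats <- pats[pats != strrep("0", k)]
  val <- vapply(pats, function(p) strtoi(p, base = 2), integer(1))
  ones <- vapply(strsplit(pats, ""), function(b) sum(b == "1"), integer(1))
  pats[order(ones, -val)]
}

pattern_matrix <- function(patterns) {
  do.call(rbind, lapply(strsplit(patterns, ""), as.integer))
}

#' Capture-history contingency table
#'
#' The 2^k - 1 observable capture patterns for one stratum, each pattern a
#' length-k binary string whose leftmost character is occasion one ("1" =
#' captured). The all-zero pattern is structurally unobservable and is
#' excluded.
#'
#' @param cells Named non-negative integer vector; names are the capture
#'   patterns. All 2^k - 1 patterns must be present (k between 2 and 5).
#' @param stratum Stratum label.
#' @return An object of class `capture_history_table` with the cells in
#'   canonical order (by number of captures, then pattern value descending).
#' @export
#' @examples
#' capture_history_table(c(`100` = 1532, `010` = 388, `001` = 1584,
#'                         `110` = 511, `101` = 212, `011` = 205,
#'                         `111` = 210), "National")
capture_history_table <- function(cells, stratum = "") {
  if (is.null(names(cells)) || any(!nzchar(names(cells)))) {
    stop("`cells` must be named by capture pattern", call. = FALSE)
  }
  k <- unique(nchar(names(cells)))
  if (length(k) != 1 || k < 2 || k > 5) {
    stop("patterns must share one length k between 2 and 5", call. = FALSE)
  }
  if (any(!grepl("^[01]+$", names(cells)))) {
    stop("patterns must be binary strings of '0' and '1'", call. = FALSE)
  }
  want <- pattern_order(k)
  if (length(cells) != length(want) || !setequal(names(cells), want)) {
    stop(sprintf("all %d non-zero patterns of length %d must appear exactly once",
                 2^k - 1, k), call. = FALSE)
  }
  counts <- assert_count(unname(cells), "cells")
  names(counts) <- names(cells)
  structure(
    list(k = as.integer(k), cells = counts[want],
         stratum = as.character(stratum)),
    class = "capture_history_table"
  )
}

#' @export
print.capture_history_table <- function(x, ...) {
  cat(sprintf("Capture-history table [%s], k = %d, %d observed\n",
              if (nzchar(x$stratum)) x$stratum else "unlabelled",
              x$k, sum(x$cells)))
  print(x$cells)
  cl <- attr(x, "clamped")
  if (!is.null(cl) && nrow(cl) > 0) {
    cat("  clamped cells:",
        paste(sprintf("%s (deficit %d)", cl$pattern, cl$deficit),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Build a three-source capture-history table from marginals
#'
#' Recovers the seven observable cells from occasion totals and overlaps by
#' inclusion-exclusion. Published marginals can be mutually inconsistent
#' (a negative implied cell); `policy` decides whether that is an error or
#' is clamped to zero with the deficit recorded.
#'
#' @param m A [capture_marginals()] object with k = 3.
#' @param policy `"clamp"` (default) sets negative cells to 0, warns, and
#'   attaches a `clamped` attribute listing each pattern and its deficit;
#'   `"strict"` raises an error naming the offending pattern.
#' @return A [capture_history_table()]; under clamping, attribute `clamped`
#'   is a data frame with columns `pattern` and `deficit`.
#' @export
#' @examples
#' m <- capture_marginals(c(2465, 1314, 2211), c(721, 422, 415), 210)
#' table_from_marginals(m)
table_from_marginals <- function(m, policy = c("clamp", "strict")) {
  stopifnot(inherits(m, "capture_marginals"))
  policy <- match.arg(policy)
  if (m$k != 3) {
    stop("marginal construction is defined for k = 3 only", call. = FALSE)
  }
  n1 <- m$n[1]; n2 <- m$n[2]; n3 <- m$n[3]
  n12 <- m$pair_overlaps[["n12"]]
  n13 <- m$pair_overlaps[["n13"]]
  n23 <- m$pair_overlaps[["n23"]]
  n123 <- m$triple_overlap
  cells <- c(
    `111` = n123,
    `110` = n12 - n123,
    `101` = n13 - n123,
    `011` = n23 - n123,
    `100` = n1 - n12 - n13 + n123,
    `010` = n2 - n12 - n23 + n123,
    `001` = n3 - n13 - n23 + n123
  )
  neg <- cells < 0
  clamped <- data.frame(pattern = character(0), deficit = integer(0),
                        stringsAsFactors = FALSE)
  if (any(neg)) {
    if (policy == "strict") {
      bad <- which(neg)[1]
      stop(sprintf(
        "inconsistent marginals%s: cell %s = %d",
        if (nzchar(m$stratum)) paste0(" [", m$stratum, "]") else "",
        names(cells)[bad], cells[bad]), call. = FALSE)
    }
    clamped <- data.frame(pattern = names(cells)[neg],
                          deficit = as.integer(-cells[neg]),
                          stringsAsFactors = FALSE)
    warning(sprintf(
      "marginals%s inconsistent; clamped to 0: %s",
      if (nzchar(m$stratum)) paste0(" [", m$stratum, "]") else "",
      paste(sprintf("%s (deficit %d)", clamped$pattern, clamped$deficit),
            collapse = ", ")), call. = FALSE)
    cells[neg] <- 0L
  }
  out <- capture_history_table(cells, stratum = m$stratum)
  attr(out, "clamped") <- clamped
  out
}

#' Marginalize a capture-history table
#'
#' Inverse of [table_from_marginals()]: per-occasion totals and overlaps are
#' sums over the cells whose pattern captures the relevant occasion(s).
#'
#' @param t A [capture_history_table()].
#' @return A [capture_marginals()] object.
#' @export
marginals_from_table <- function(t) {
  stopifnot(inherits(t, "capture_history_table"))
  X <- pattern_matrix(names(t$cells))
  n <- as.integer(crossprod(X, t$cells))
  pairs <- utils::combn(t$k, 2)
  pair_overlaps <- apply(pairs, 2, function(ij)
    sum(t$cells[X[, ij[1]] == 1 & X[, ij[2]] == 1]))
  triple <- if (t$k == 3) sum(t$cells[rowSums(X) == 3]) else NULL
  capture_marginals(n, pair_overlaps, triple, stratum = t$stratum)
}

#' Pool capture-history tables across strata
#'
#' Cellwise sums; on consistent data pooling commutes with
#' [table_from_marginals()] by linearity of inclusion-exclusion.
#'
#' @param tables Non-empty list of [capture_history_table()] objects sharing k.
#' @param stratum Label for the pooled table.
#' @return A [capture_history_table()].
#' @export
pool_strata <- function(tables, stratum = "pooled") {
  if (length(tables) == 0) stop("no tables to pool", call. = FALSE)
  stopifnot(all(vapply(tables, inherits, logical(1), "capture_history_table")))
  ks <- vapply(tables, function(t) t$k, integer(1))
  if (length(unique(ks)) != 1) {
    stop("all tables must share the same number of occasions", call. = FALSE)
  }
  cells <- Reduce(`+`, lapply(tables, function(t) t$cells))
  capture_history_table(cells, stratum = stratum)
}

#' Recapture fractions by occasion
#'
#' For each occasion after the first, the fraction of its captures that had
#' already been tagged by each earlier occasion, as percentages rounded
#' half-up to two decimals — the quantities a field report prints (e.g. the
#' share of round-two participants presenting the round-one object).
#'
#' @param m A [capture_marginals()] object.
#' @param n_assigned Optional count of objects assigned in occasion one;
#'   if supplied, a distribution-success row (`n1 / n_assigned`) is included.
#' @return Data frame with columns `label`, `numerator`, `denominator`,
#'   `pct` (NA with `undefined = TRUE` where the denominator is zero).
#' @export
#' @examples
#' m <- capture_marginals(c(2465, 1314, 2211), c(721, 422, 415), 210)
#' capture_summary(m, n_assigned = 2723)
capture_summary <- function(m, n_assigned = NULL) {
  stopifnot(inherits(m, "capture_marginals"))
  pairs <- utils::combn(m$k, 2)
  lab <- character(0); num <- integer(0); den <- integer(0)
  if (!is.null(n_assigned)) {
    n_assigned <- assert_count(n_assigned, "n_assigned")
    lab <- "occasion 1: distribution success"
    num <- m$n[1]
    den <- n_assigned
  }
  for (j in 2:m$k) {
    for (i in seq_len(j - 1)) {
      idx <- which(pairs[1, ] == i & pairs[2, ] == j)
      lab <- c(lab, sprintf("occasion %d: tagged in occasion %d", j, i))
      num <- c(num, m$pair_overlaps[idx])
      den <- c(den, m$n[j])
    }
  }
  pct <- ifelse(den > 0, round_half_up(100 * num / den, 2), NA_real_)
  data.frame(label = lab, numerator = num, denominator = den,
             pct = pct, undefined = den == 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read per-stratum capture marginals from CSV
#'
#' Expected header: `stratum,n1,n2,n3,n12,n13,n23,n123`, one row per stratum.
#'
#' @param path CSV file path.
#' @return Named list of [capture_marginals()] objects.
#' @export
read_marginals_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("stratum", "n1", "n2", "n3", "n12", "n13", "n23", "n123")
  if (!identical(names(df)[seq_along(need)], need)) {
    stop(sprintf("malformed marginals CSV header; expected columns %s",
                 paste(need, collapse = ",")), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    capture_marginals(c(df$n1[i], df$n2[i], df$n3[i]),
                      c(df$n12[i], df$n13[i], df$n23[i]),
                      df$n123[i], stratum = df$stratum[i])
  })
  stats::setNames(out, df$stratum)
}

#' Write per-stratum capture marginals to CSV
#'
#' @param marginals List of [capture_marginals()] objects (k = 3).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_marginals_csv <- function(marginals, path) {
  rows <- lapply(marginals, function(m) {
    stopifnot(inherits(m, "capture_marginals"), m$k == 3)
    data.frame(stratum = m$stratum, n1 = m$n[1], n2 = m$n[2], n3 = m$n[3],
               n12 = m$pair_overlaps[["n12"]], n13 = m$pair_overlaps[["n13"]],
               n23 = m$pair_overlaps[["n23"]], n123 = m$triple_overlap,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read capture-history tables in cell form from CSV
#'
#' Expected header: `stratum,pattern,count`; patterns are binary strings.
#'
#' @param path CSV file path.
#' @return Named list of [capture_history_table()] objects.
#' @export
read_cells_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(pattern = "character"))
  need <- c("stratum", "pattern", "count")
  if (!all(need %in% names(df))) {
    stop("malformed cells CSV header; expected columns stratum,pattern,count",
         call. = FALSE)
  }
  out <- lapply(split(df, df$stratum), function(d) {
    capture_history_table(stats::setNames(d$count, d$pattern),
                          stratum = d$stratum[1])
  })
  out[unique(df$stratum)]
}

#' Write capture-history tables in cell form to CSV
#'
#' @param tables List of [capture_history_table()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cells_csv <- function(tables, path) {
  rows <- lapply(tables, function(t) {
    data.frame(stratum = t$stratum, pattern = names(t$cells),
               count = unname(t$cells), stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a capture-history table (with any clamping warnings) as JSON
#'
#' @param t A [capture_history_table()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
table_to_json <- function(t, path = NULL) {
  stopifnot(inherits(t, "capture_history_table"))
  obj <- list(stratum = t$stratum, k = t$k,
              cells = as.list(t$cells),
              n_observed = sum(t$cells),
              clamped = attr(t, "clamped") %||%
                data.frame(pattern = character(0), deficit = integer(0)))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
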