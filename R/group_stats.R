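# Group summaries (mean +- SEM) and two-sided Mann-Whitney comparisons, the
# study's statistical toolkit. No multiple-testing correction is applied,
# matching the original analysis; users comparing many endpoints should
# correct downstream.

#' Mann-Whitney U test (two-sided)
#'
#' U is computed for the first sample by rank sum with midranks on ties.
#' For `min(n, m) <= 8` with no ties the p-value comes from the exact
#' permutation distribution; otherwise a normal approximation with tie and
#' continuity correction is used. The two-sided p doubles the smaller exact
#' tail, capped at 1.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `U` (for `x`), `p_two_sided`, `method` (`"exact"` or
#'   `"normal_approx"`), `n`, `m`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))  # midranks on ties
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(n, m) <= 8 && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(U = unname(U), p_two_sided = unname(wt$p.value),
       method = if (exact) "exact" else "normal_approx", n = n, m = m)
}

#' Group summaries: n, mean, SEM
#'
#' SEM is the sample standard deviation (n - 1 denominator) divided by
#' `sqrt(n)`; a single observation yields SEM `NA`.
#'
#' @param values numeric vector of observations.
#' @param group factor or character vector of group labels, same length.
#' @return data.frame with columns `group`, `n`, `mean`, `sem`.
#' @export
summarize_groups <- function(values, group) {
  stopifnot(length(values) == length(group))
  split_vals <- split(values, group)
  if (any(lengths(split_vals) == 0L)) stop("every group must be non-empty")
  out <- do.call(rbind, lapply(names(split_vals), function(g) {
    v <- split_vals[[g]]
    data.frame(group = g, n = length(v), mean = mean(v),
               sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise Mann-Whitney comparisons of groups in a results table
#'
#' @param df data.frame holding one value per animal.
#' @param value_col,group_col column names of the value and group label.
#' @param pairs list of 2-element character vectors naming group pairs; by
#'   default every unordered pair present in the data.
#' @return data.frame with `group_a`, `group_b`, `n_a`, `n_b`, `U`,
#'   `p_two_sided`, `method`.
#' @export
compare_groups <- function(df, value_col, group_col, pairs = NULL) {
  stopifnot(all(c(value_col, group_col) %in% names(df)))
  groups <- unique(as.character(df[[group_col]]))
  if (is.null(pairs)) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
  }
  out <- lapply(pairs, function(p) {
    a <- df[[value_col]][df[[group_col]] == p[1]]
    b <- df[[value_col]][df[[group_col]] == p[2]]
    mw <- mann_whitney_u(a, b)
    data.frame(group_a = p[1], group_b = p[2], n_a = mw$n, n_b = mw$m,
               U = mw$U, p_two_sided = mw$p_two_sided, method = mw$method)
  })
  do.call(rbind, out)
}
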