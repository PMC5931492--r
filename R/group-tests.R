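#' Tie-corrected Kruskal-Wallis rank test
#'
#' Nonparametric one-way comparison of a numeric response among groups,
#' computed from mid-ranks with the tie correction
#' `H = [12 / (N (N + 1)) * sum(R_i^2 / n_i) - 3 (N + 1)] /
#'      [1 - sum(t^3 - t) / (N^3 - N)]`
#' and a chi-square approximation with `groups - 1` degrees of freedom.
#' Used here to compare per-cave richness among karst regions.
#'
#' @param data A data frame.
#' @param value Unquoted column holding the response.
#' @param group Unquoted column holding the grouping factor.
#' @return An object of class `rank_test` with fields `H`, `df`, `p`,
#'   `group_sizes`, `rank_sums`; [tidy()]/[glance()] return a one-row
#'   tibble.
#' @examples
#' unit_richness(load_fixture("cave_incidence"), "sample") |>
#'   kruskal_wallis(richness, region)
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- dplyr::mutate(data, .v = {{ value }})$.v
  g <- as.factor(dplyr::mutate(data, .g = {{ group }})$.g)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) == 0) || any(is.na(v))) {
    stop("every group needs at least one non-missing observation",
         call. = FALSE)
  }
  N <- length(v)
  r <- rank(v) # mid-ranks for ties
  rank_sums <- tapply(r, g, sum)
  n_i <- tapply(r, g, length)
  H_raw <- 12 / (N * (N + 1)) * sum(rank_sums^2 / n_i) - 3 * (N + 1)
  ties <- table(v)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- if (correction > 0) H_raw / correction else 0
  df <- nlevels(g) - 1
  structure(list(
    H = H, df = df,
    p = stats::pchisq(H, df, lower.tail = FALSE),
    group_sizes = as.integer(n_i),
    rank_sums = as.numeric(rank_sums),
    groups = levels(g)
  ), class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4f, df = %d, p = %.4g\n",
              x$H, x$df, x$p))
  invisible(x)
}

#' @rdname kruskal_wallis
#' @param x A `rank_test` object.
#' @param ... Unused.
#' @export
tidy.rank_test <- function(x, ...) {
  tibble::tibble(statistic = x$H, df = x$df, p_value = x$p,
                 n_groups = length(x$groups))
}

#' @rdname kruskal_wallis
#' @export
glance.rank_test <- tidy.rank_test

#' Ordinary least-squares regression summary
#'
#' Simple OLS of a response on one predictor, reporting the adjusted
#' coefficient of determination `r2_adj = 1 - (1 - r2)(n - 1)/(n - 2)`.
#' Used here to regress total cave richness on per-drip richness summaries
#' (the maximum-richness drip is the better predictor of its cave's total).
#'
#' @param data A data frame.
#' @param x Unquoted predictor column.
#' @param y Unquoted response column.
#' @return An object of class `regression_summary` with `slope`,
#'   `intercept`, `r2`, `r2_adj`, `n` and the underlying [stats::lm()] fit;
#'   [tidy()]/[glance()] return a one-row tibble.
#' @examples
#' load_fixture("cave_summary") |> ols_fit(max_sd, total_s)
#' @export
ols_fit <- function(data, x, y) {
  xv <- dplyr::mutate(data, .x = {{ x }})$.x
  yv <- dplyr::mutate(data, .y = {{ y }})$.y
  if (length(xv) != length(yv)) stop("x and y lengths differ", call. = FALSE)
  if (length(xv) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(xv) == 0) stop("predictor has zero variance", call. = FALSE)
  fit <- stats::lm(yv ~ xv)
  s <- summary(fit)
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r2 = s$r.squared,
    r2_adj = s$adj.r.squared,
    n = length(xv),
    fit = fit
  ), class = "regression_summary")
}

#' @export
print.regression_summary <- function(x, ...) {
  cat(sprintf("OLS: y = %.3f + %.3f x, n = %d, R2 = %.3f, R2_adj = %.3f\n",
              x$intercept, x$slope, x$n, x$r2, x$r2_adj))
  invisible(x)
}

#' Tidy an OLS regression summary
#'
#' @param x A `regression_summary` from [ols_fit()].
#' @param ... Unused.
#' @return A one-row tibble: `intercept`, `slope`, `r2`, `r2_adj`, `n`.
#' @export
tidy.regression_summary <- function(x, ...) {
  tibble::tibble(intercept = x$intercept, slope = x$slope,
                 r2 = x$r2, r2_adj = x$r2_adj, n = x$n)
}

#' @rdname tidy.regression_summary
#' @export
glance.regression_summary <- tidy.regression_summary
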