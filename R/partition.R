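#' Additive partition of species richness across the sampling hierarchy
#'
#' Decomposes total (gamma) richness additively:
#' `gamma = alpha_1 + beta_1 + beta_2 + beta_3`, where `alpha_1` is the mean
#' per-sample richness, `beta_1 = mean site richness - alpha_1` (among
#' samples within sites), `beta_2 = mean region richness - mean site
#' richness` (among sites within regions) and
#' `beta_3 = gamma - mean region richness` (among regions). Means are
#' unweighted across units at each level. When the dataset's samples
#' coincide with its sites (e.g. caves used as samples), `beta_1` is zero
#' and the partition collapses to the levels actually present.
#'
#' @param data An [occurrence()] object.
#' @param include_empty_samples Include empty samples in the mean per-sample
#'   richness (default `FALSE`: mean richness is computed over samples that
#'   caught anything; the flag flips to all-sample means, which is how the
#'   published per-drip means count empty drips).
#' @param weights `"unweighted"` (default; every unit counts equally in the
#'   level means) or `"samples"` (site and region means weighted by their
#'   number of contributing samples). Unweighted means can yield slightly
#'   negative beta components on strongly unbalanced hierarchies (a rich,
#'   heavily sampled site pulls the sample mean above the unweighted site
#'   mean); sample weighting guarantees non-negative components.
#' @return An object of class `partition` with fields `gamma`, `components`
#'   (tibble: `component`, `estimate`, `rounded`, `pct`), `n_samples`,
#'   `include_empty_samples`, `weights`. [tidy()] returns the components
#'   tibble, [glance()] a one-row summary.
#' @examples
#' additive_partition(load_fixture("cave_incidence"))
#' @export
additive_partition <- function(data, include_empty_samples = FALSE,
                               weights = c("unweighted", "samples")) {
  weights <- match.arg(weights)
  m <- occ_matrix(data, "sample")
  hier <- sample_hierarchy(data)
  if (sum(m) == 0) stop("dataset has no non-empty sample", call. = FALSE)
  est <- partition_components(m, hier, include_empty_samples, weights)
  new_partition(est, ncol(m), include_empty_samples, weights)
}

# core computation on a species x sample matrix; returns the component
# vector (alpha, then one beta per level) summing exactly to gamma
partition_components <- function(m, hier, include_empty_samples,
                                 weights = "unweighted") {
  site_of <- hier$site[match(colnames(m), hier$sample)]
  region_of <- hier$region[match(colnames(m), hier$sample)]
  rich <- colSums(m > 0)
  keep <- if (include_empty_samples) rep(TRUE, length(rich)) else rich > 0
  alpha1 <- mean(rich[keep])
  w_of <- function(groups) {
    if (weights == "samples") {
      vapply(unique(groups), function(g) sum(keep[groups == g]), numeric(1))
    } else rep(1, length(unique(groups)))
  }
  alpha2 <- stats::weighted.mean(group_richness(m, site_of), w_of(site_of))
  alpha3 <- stats::weighted.mean(group_richness(m, region_of),
                                 w_of(region_of))
  gamma <- sum(rowSums(m) > 0)
  c(alpha_sample = alpha1,
    beta_among_samples = alpha2 - alpha1,
    beta_among_sites = alpha3 - alpha2,
    beta_among_regions = gamma - alpha3)
}

group_richness <- function(m, groups) {
  vapply(unique(groups),
         function(g) sum(rowSums(m[, groups == g, drop = FALSE]) > 0),
         numeric(1))
}

new_partition <- function(est, n_samples, include_empty_samples,
                          weights = "unweighted", null = NULL) {
  gamma <- sum(est)
  structure(list(
    gamma = gamma,
    components = tibble::tibble(
      component = names(est),
      estimate = unname(est),
      rounded = round(unname(est)),
      pct = 100 * unname(est) / gamma
    ),
    n_samples = n_samples,
    include_empty_samples = include_empty_samples,
    weights = weights,
    null = null
  ), class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> gamma = %g over %d samples%s\n", x$gamma,
              x$n_samples,
              if (is.null(x$null)) "" else
                sprintf(" (null: %d randomizations, seed %s)",
                        x$null$n_randomizations, format(x$null$seed))))
  print(tidy(x))
  invisible(x)
}

#' @rdname additive_partition
#' @param x A `partition` object.
#' @param ... Unused.
#' @export
tidy.partition <- function(x, ...) {
  out <- x$components
  if (!is.null(x$null)) out <- dplyr::left_join(out, x$null$summary,
                                                by = "component")
  out
}

#' @rdname additive_partition
#' @export
glance.partition <- function(x, ...) {
  tibble::tibble(
    gamma = x$gamma,
    alpha_sample = x$components$estimate[1],
    beta_total = sum(x$components$estimate[-1]),
    pct_beta = 100 * sum(x$components$estimate[-1]) / x$gamma,
    n_samples = x$n_samples,
    n_randomizations = if (is.null(x$null)) NA_integer_ else
      x$null$n_randomizations,
    seed = if (is.null(x$null)) NA_integer_ else x$null$seed
  )
}

#' Individual-based randomization null for the additive partition
#'
#' Generates the null expectation of each partition component by repeatedly
#' reallocating every individual independently to a sample with probability
#' proportional to that sample's observed total (so sample sizes are
#' preserved in expectation and species totals exactly), recomputing the
#' partition each time. Randomization destroys all spatial structure while
#' keeping the species-abundance distribution and the unevenness of
#' sampling effort, so observed alpha below the null mean indicates spatial
#' aggregation of conspecifics. Counts are treated as individuals; for
#' presence/absence data each occurrence is shuffled as one individual
#' (there is no way to tell a sparse count matrix from incidence data).
#'
#' @param data An [occurrence()] object with counts.
#' @param n_rand Number of randomizations (default 1000).
#' @param seed Integer seed; the full null distribution is reproducible.
#' @param include_empty_samples,weights Passed to [additive_partition()].
#' @return A `partition` object whose `null` field holds the per-component
#'   null mean, null SD and a two-sided empirical p-value with the
#'   `(r + 1) / (n + 1)` correction, plus the matrix of null component
#'   draws.
#' @examples
#' randomization_null(load_fixture("cave_incidence"), n_rand = 49, seed = 1)
#' @export
randomization_null <- function(data, n_rand = 1000, seed = 1,
                               include_empty_samples = FALSE,
                               weights = c("unweighted", "samples")) {
  weights <- match.arg(weights)
  if (n_rand < 1) stop("n_rand must be at least 1", call. = FALSE)
  m <- occ_matrix(data, "sample")
  if (sum(m) == 0) stop("no individuals to randomize", call. = FALSE)
  hier <- sample_hierarchy(data)
  obs_est <- partition_components(m, hier, include_empty_samples, weights)

  prob <- colSums(m) / sum(m)
  totals <- rowSums(m)
  totals <- totals[totals > 0]

  set.seed(seed)
  draws <- matrix(NA_real_, nrow = n_rand, ncol = length(obs_est),
                  dimnames = list(NULL, names(obs_est)))
  for (r in seq_len(n_rand)) {
    rm <- t(vapply(totals,
                   function(n_k) as.numeric(stats::rmultinom(1, n_k, prob)),
                   numeric(ncol(m))))
    colnames(rm) <- colnames(m)
    draws[r, ] <- partition_components(rm, hier, include_empty_samples,
                                       weights)
  }

  summary <- purrr::map_dfr(names(obs_est), function(comp) {
    nd <- draws[, comp]
    dev <- abs(obs_est[[comp]] - mean(nd))
    tibble::tibble(
      component = comp,
      null_mean = mean(nd),
      null_sd = stats::sd(nd),
      p_value = (1 + sum(abs(nd - mean(nd)) >= dev - 1e-12)) / (n_rand + 1)
    )
  })
  new_partition(obs_est, ncol(m), include_empty_samples, weights,
                null = list(summary = summary, draws = draws,
                            n_randomizations = n_rand, seed = seed))
}

#' Percent contribution of each partition component to gamma
#'
#' @param result A `partition` object.
#' @return A tibble `component`, `pct`; percentages sum to 100.
#' @export
percent_contributions <- function(result) {
  if (result$gamma == 0) stop("gamma is zero", call. = FALSE)
  dplyr::select(result$components, "component", "pct")
}

#' Plot a partition against its randomization null
#'
#' @param object A `partition` object.
#' @param ... Unused.
#' @return A ggplot comparing observed component sizes (and null means when
#'   a randomization null is attached).
#' @export
autoplot.partition <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::mutate(component = factor(.data$component,
                                     levels = rev(.data$component)))
  if (!is.null(object$null)) {
    long <- dplyr::bind_rows(
      dplyr::transmute(df, .data$component, what = "observed",
                       value = .data$estimate),
      dplyr::transmute(df, .data$component, what = "null mean",
                       value = .data$null_mean)
    )
  } else {
    long <- dplyr::transmute(df, .data$component, what = "observed",
                             value = .data$estimate)
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$component, y = .data$value,
                                     fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Species", fill = NULL)
}
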