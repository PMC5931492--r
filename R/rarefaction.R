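#' Exact sample-based rarefaction (analytical accumulation curve)
#'
#' Expected species richness among `t` sampling units drawn without
#' replacement from the `T` observed units, evaluated exactly from the
#' hypergeometric inclusion probabilities (no Monte Carlo): a species found
#' in `T_k` units is missed by a draw of `t` units with probability
#' `choose(T - T_k, t) / choose(T, t)`. The standard deviation is the exact
#' standard deviation of the subset richness, computed from the pairwise
#' joint absence probabilities (conditional on the observed matrix; a
#' reference formula not tied to any published SD column).
#'
#' @param incidence Species x unit matrix (positive entries = presence).
#' @param t Subsample sizes; default the full curve `1:T`.
#' @param sd Compute the exact standard deviation (O(S^2) per t)?
#' @return A tibble of class `rarefaction_curve`: `t`, `expected_S`, `sd`.
#' @examples
#' m <- rbind(a = c(1, 1, 1, 0), b = c(1, 0, 0, 0), c = c(0, 1, 1, 1))
#' rarefaction(m)
#' @export
rarefaction <- function(incidence, t = NULL, sd = TRUE) {
  m <- as_incidence(incidence)
  T_ <- ncol(m)
  occ <- rowSums(m)
  occ <- occ[occ > 0]
  if (is.null(t)) t <- seq_len(T_)
  if (any(t < 1 | t > T_)) {
    stop("t must lie in 1..", T_, call. = FALSE)
  }

  # log-scale hypergeometric absence probability, exact
  p_absent <- function(T_k, t) {
    ifelse(T_ - T_k < t, 0, exp(lchoose(T_ - T_k, t) - lchoose(T_, t)))
  }

  expected <- vapply(t, function(tt) sum(1 - p_absent(occ, tt)), numeric(1))

  sds <- rep(NA_real_, length(t))
  if (sd) {
    pres <- m[names(occ), , drop = FALSE] > 0
    # units occupied by species k or l, for the joint absence probability
    union_occ <- outer(occ, occ, "+") - tcrossprod(pres * 1L)
    sds <- vapply(seq_along(t), function(i) {
      tt <- t[i]
      q <- p_absent(occ, tt)             # per-species absence probability
      Q2 <- p_absent(union_occ, tt)      # pairwise joint absence
      # Var sum_k (1 - absent_k); diagonal of Q2 is q, giving q(1-q) terms
      v <- sum(Q2 - outer(q, q))
      sqrt(max(v, 0))
    }, numeric(1))
  }

  structure(
    tibble::tibble(t = as.integer(t), expected_S = expected, sd = sds),
    class = c("rarefaction_curve", class(tibble::tibble())),
    T = T_, S_obs = length(occ)
  )
}

#' Compare regional accumulation curves at a common number of units
#'
#' Rarefies each region's curve (over member units at `unit_level`) and
#' evaluates it at a common subsample size, the standard way to compare
#' regions whose sampling effort differs; also reports whether any two
#' curves cross over the shared range of unit counts.
#'
#' @param data An [occurrence()] object.
#' @param n_common Number of units at which regions are compared.
#' @param unit_level Level supplying the accumulation units (default
#'   `"site"`, i.e. caves).
#' @param drop_short Drop (with a message) regions with fewer than
#'   `n_common` units instead of erroring — the published comparison itself
#'   omits the two-cave region. `FALSE` turns a short region into an error.
#' @return A list with `at_common` (tibble: region, `t`, `expected_S`,
#'   `S_obs`, `n_units`), `curves` (full per-region curves) and
#'   `curves_cross` (logical over the shared `t` range).
#' @examples
#' accumulation_compare(load_fixture("cave_incidence"), n_common = 3)
#' @export
accumulation_compare <- function(data, n_common, unit_level = "site",
                                 drop_short = TRUE) {
  hier <- sample_hierarchy(data)
  regions <- unique(hier$region)
  n_units_of <- vapply(regions, function(r) {
    dplyr::n_distinct(hier[[unit_level]][hier$region == r])
  }, numeric(1))
  short <- regions[n_units_of < n_common]
  if (length(short) > 0) {
    if (!drop_short) {
      stop("region ", short[1], " has only ",
           n_units_of[match(short[1], regions)], " units at level ",
           unit_level, call. = FALSE)
    }
    message("dropping region(s) with fewer than ", n_common, " units: ",
            paste(short, collapse = ", "))
    regions <- setdiff(regions, short)
  }
  if (length(regions) == 0) {
    stop("no region has ", n_common, " units at level ", unit_level,
         call. = FALSE)
  }
  curves <- purrr::map_dfr(regions, function(r) {
    sub <- occurrence(dplyr::filter(tibble::as_tibble(data),
                                    .data$region == r))
    m <- occ_matrix(sub, unit_level, incidence = TRUE)
    dplyr::mutate(rarefaction(m), region = r, n_units = ncol(m),
                  S_obs = sum(rowSums(m) > 0))
  })
  shared_t <- seq_len(min(curves$n_units))
  wide <- curves |>
    dplyr::filter(.data$t %in% shared_t) |>
    dplyr::select("region", "t", "expected_S") |>
    tidyr::pivot_wider(names_from = "region", values_from = "expected_S")
  crossing <- FALSE
  if (length(regions) > 1) {
    combos <- utils::combn(regions, 2, simplify = FALSE)
    crossing <- any(vapply(combos, function(p) {
      d <- wide[[p[1]]] - wide[[p[2]]]
      any(d > 1e-12) && any(d < -1e-12)
    }, logical(1)))
  }
  list(
    at_common = dplyr::filter(curves, .data$t == n_common) |>
      dplyr::select("region", "t", "expected_S", "S_obs", "n_units"),
    curves = curves,
    curves_cross = crossing
  )
}

#' Plot a rarefaction curve
#'
#' @param object A `rarefaction_curve` from [rarefaction()].
#' @param ... Unused.
#' @return A ggplot: expected richness versus units sampled, with a
#'   plus/minus one SD ribbon when SDs are present.
#' @export
autoplot.rarefaction_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$t,
                                            y = .data$expected_S)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Sampling units", y = "Expected species richness")
  if (!all(is.na(object$sd))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$expected_S - .data$sd,
                   ymax = .data$expected_S + .data$sd),
      alpha = 0.2
    )
  }
  p
}
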