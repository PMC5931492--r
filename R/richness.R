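#' @keywords internal
new_richness_estimate <- function(estimator, S_obs, estimate, sd, variant,
                                  intermediates, candidates = NULL) {
  structure(list(
    estimator = estimator,
    S_obs = S_obs,
    estimate = max(estimate, S_obs), # an estimated richness never drops below S_obs
    sd = sd,
    variant = variant,
    intermediates = intermediates,
    candidates = candidates
  ), class = "richness_estimate")
}

#' @export
print.richness_estimate <- function(x, ...) {
  cat(sprintf("<richness_estimate> %s (%s): S_obs = %d, estimate = %.3f%s\n",
              x$estimator, x$variant, x$S_obs, x$estimate,
              if (is.na(x$sd)) "" else sprintf(", sd = %.3f", x$sd)))
  invisible(x)
}

#' Tidy a richness estimate into a one-row tibble
#'
#' @param x A `richness_estimate`.
#' @param ... Unused.
#' @return A one-row tibble: `estimator`, `variant`, `S_obs`, `estimate`, `sd`.
#' @export
tidy.richness_estimate <- function(x, ...) {
  tibble::tibble(estimator = x$estimator, variant = x$variant,
                 S_obs = x$S_obs, estimate = x$estimate, sd = x$sd)
}

#' Chao1 estimator of true species richness
#'
#' Extrapolates observed richness from the frequencies of rare species:
#' the classic form adds `F1^2 / (2 F2)` (singletons squared over twice the
#' doubletons); the bias-corrected form multiplies by the finite-sample
#' factor `(n - 1) / n` and, when no doubletons exist, replaces the ratio by
#' the Chao-corrected `F1 (F1 - 1) / (2 (F2 + 1))`. Under `variant = "auto"`
#' the classic form is used only when the coefficient of variation of the
#' abundances exceeds 0.5 (the EstimateS selection rule).
#'
#' @param counts Per-species abundance vector (non-negative integers).
#' @param n_samples Number of sampling units; enters only the bias-corrected
#'   finite-sample factor (omitted factor = 1 when `NULL`).
#' @param variant `"auto"`, `"classic"` or `"bias_corrected"`.
#' @return A `richness_estimate`; `sd` follows the standard Chao1 variance
#'   (a reference formula, not tied to any published SD column).
#' @examples
#' chao1(c(1, 1, 1, 1, 2, 2, rep(5, 4)), variant = "classic") # 10 + 16/4
#' @export
chao1 <- function(counts, n_samples = NULL,
                  variant = c("auto", "classic", "bias_corrected")) {
  variant <- match.arg(variant)
  fc <- freq_abundance(counts, n_samples)
  if (variant == "auto") {
    variant <- if (fc$CV > 0.5) "classic" else "bias_corrected"
  }
  est <- chao_point(fc$S_obs, f_of(fc$F, 1), f_of(fc$F, 2), variant,
                    n_units = n_samples)
  new_richness_estimate("chao1", fc$S_obs, est$point, est$sd, variant, fc)
}

#' Chao2 estimator of true species richness from incidence data
#'
#' The incidence analogue of [chao1()]: uniques Q1 and duplicates Q2 replace
#' singletons and doubletons, and the finite-sample factor is
#' `(T - 1) / T` over the `T` sampling units. `variant = "auto"` uses the
#' classic form only when the coefficient of variation of the occupancy
#' frequencies exceeds 0.5.
#'
#' @param incidence Species x unit matrix (positive entries = presence).
#' @param variant `"auto"`, `"classic"` or `"bias_corrected"`.
#' @return A `richness_estimate`.
#' @examples
#' m <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1), d = c(0, 1))
#' chao2(m, variant = "bias_corrected") # 4 + (1/2) * 4 * 3 / 2 = 7
#' @export
chao2 <- function(incidence, variant = c("auto", "classic", "bias_corrected")) {
  variant <- match.arg(variant)
  fc <- freq_incidence(incidence)
  if (variant == "auto") {
    variant <- if (fc$CV > 0.5) "classic" else "bias_corrected"
  }
  est <- chao_point(fc$S_obs, f_of(fc$Q, 1), f_of(fc$Q, 2), variant,
                    n_units = fc$T)
  new_richness_estimate("chao2", fc$S_obs, est$point, est$sd, variant, fc)
}

# shared Chao-family point estimate + reference variance.
# k is the finite-sample factor (1 for classic, (n-1)/n for bias-corrected).
chao_point <- function(S_obs, f1, f2, variant, n_units = NULL) {
  k <- if (variant == "bias_corrected" && !is.null(n_units) && n_units >= 1) {
    (n_units - 1) / n_units
  } else 1
  if (f1 == 0) {
    return(list(point = S_obs, sd = 0))
  }
  if (f2 > 0) {
    add <- if (variant == "classic") f1^2 / (2 * f2) else k * f1^2 / (2 * f2)
    r <- f1 / f2
    var <- f2 * (k * r^2 / 2 + k^2 * r^3 + k^2 * r^4 / 4)
  } else {
    add <- if (variant == "classic") f1 * (f1 - 1) / 2 else
      k * f1 * (f1 - 1) / (2 * (f2 + 1))
    point <- S_obs + add
    var <- k * f1 * (f1 - 1) / 2 + k^2 * f1 * (2 * f1 - 1)^2 / 4 -
      k^2 * f1^4 / (4 * point)
  }
  list(point = S_obs + add, sd = sqrt(max(var, 0)))
}

f_of <- function(F_, i) {
  key <- as.character(i)
  if (key %in% names(F_)) F_[[key]] else 0L
}

#' ACE abundance-based coverage estimator
#'
#' Splits species into an abundant group (more than `rare_cutoff`
#' individuals, counted as observed) and a rare group whose richness is
#' scaled up by the estimated sample coverage `C_ace = 1 - F1 / N_rare`,
#' plus a term for abundance heterogeneity (squared coefficient of variation
#' of the rare group). When the rare group has zero coverage (all rare
#' species are singletons) the estimator is undefined and the function falls
#' back to bias-corrected Chao1 (`variant = "fallback"`).
#'
#' @param counts Per-species abundance vector.
#' @param rare_cutoff Abundance defining the rare group (default 10).
#' @return A `richness_estimate` (`sd` is `NA`: no variance is reported for
#'   this estimator).
#' @export
ace <- function(counts, rare_cutoff = 10) {
  check_counts(counts)
  pos <- counts[counts > 0]
  rare <- pos[pos <= rare_cutoff]
  S_abund <- sum(pos > rare_cutoff)
  S_rare <- length(rare)
  if (S_rare == 0) {
    fc <- freq_abundance(counts)
    return(new_richness_estimate("ace", fc$S_obs, fc$S_obs, NA_real_,
                                 "classic", fc))
  }
  N_rare <- sum(rare)
  F1 <- sum(rare == 1)
  C_ace <- 1 - F1 / N_rare
  fc <- freq_abundance(counts)
  if (C_ace <= 0 || N_rare <= 1) {
    fb <- chao1(counts, variant = "bias_corrected")
    return(new_richness_estimate("ace", fb$S_obs, fb$estimate, fb$sd,
                                 "fallback", fc))
  }
  Fi <- vapply(seq_len(rare_cutoff), function(i) sum(rare == i), numeric(1))
  gamma2 <- max(
    (S_rare / C_ace) * sum(seq_len(rare_cutoff) *
                             (seq_len(rare_cutoff) - 1) * Fi) /
      (N_rare * (N_rare - 1)) - 1,
    0
  )
  point <- S_abund + S_rare / C_ace + (F1 / C_ace) * gamma2
  new_richness_estimate("ace", fc$S_obs, point, NA_real_, "classic", fc)
}

#' ICE incidence-based coverage estimator
#'
#' The incidence analogue of [ace()]: species occupying more than
#' `freq_cutoff` units are counted as observed; the infrequent group is
#' scaled by the sample coverage `C_ice = 1 - Q1 / N_infr` with a
#' heterogeneity term
#' `gamma2 = max((S_infr / C_ice) (m / (m - 1)) sum(j (j-1) Q_j) / N_infr^2 - 1, 0)`
#' over the `m = m_infr` units holding at least one infrequent species.
#' When `C_ice = 0` (every infrequent species is a unique) or `m_infr <= 1`
#' the estimator is undefined and the function falls back to bias-corrected
#' [chao2()] (`variant = "fallback"`).
#'
#' @param incidence Species x unit matrix.
#' @param freq_cutoff Occupancy defining the frequent group (default 10, the
#'   bound of the published formula; exposed as a parameter).
#' @return A `richness_estimate` (`sd` is `NA`).
#' @export
ice <- function(incidence, freq_cutoff = 10) {
  fc <- freq_incidence(incidence, freq_cutoff)
  if (fc$S_infr == 0) {
    return(new_richness_estimate("ice", fc$S_obs, fc$S_obs, NA_real_,
                                 "classic", fc))
  }
  if (is.na(fc$C_ice) || fc$C_ice <= 0 || fc$m_infr <= 1) {
    fb <- chao2(incidence, variant = "bias_corrected")
    return(new_richness_estimate("ice", fb$S_obs, fb$estimate, fb$sd,
                                 "fallback", fc))
  }
  j <- as.integer(names(fc$Q))
  infr <- j <= freq_cutoff
  sum_jj1 <- sum(j[infr] * (j[infr] - 1) * fc$Q[infr])
  gamma2 <- max(
    (fc$S_infr / fc$C_ice) * (fc$m_infr / (fc$m_infr - 1)) *
      sum_jj1 / fc$N_infr^2 - 1,
    0
  )
  Q1 <- f_of(fc$Q, 1)
  point <- fc$S_freq + fc$S_infr / fc$C_ice + (Q1 / fc$C_ice) * gamma2
  new_richness_estimate("ice", fc$S_obs, point, NA_real_, "classic", fc)
}

#' Regional estimate by the coefficient-of-variation selection rule
#'
#' Applies the EstimateS-style rule used for the regional tables: when the
#' coefficient of variation of the (abundance or occupancy) frequencies
#' exceeds 0.5 the classic Chao form is used, otherwise the bias-corrected
#' one; both the Chao estimator and the matching coverage estimator
#' (ACE for abundances, ICE for incidence) are computed and the larger is
#' returned, with both candidates recorded.
#'
#' @param x Either a per-species abundance vector or a species x unit
#'   incidence matrix.
#' @param n_samples For abundance input, the number of sampling units.
#' @return A `richness_estimate` whose `candidates` field holds both
#'   candidate estimates.
#' @examples
#' m <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1), d = c(0, 1))
#' select_regional_estimate(m)$estimate
#' @export
select_regional_estimate <- function(x, n_samples = NULL) {
  if (is.matrix(x) || is.data.frame(x)) {
    fc <- freq_incidence(as_incidence(x))
    variant <- if (fc$CV > 0.5) "classic" else "bias_corrected"
    cand <- list(chao2(x, variant = variant), ice(x))
  } else {
    fc <- freq_abundance(x, n_samples)
    variant <- if (fc$CV > 0.5) "classic" else "bias_corrected"
    cand <- list(chao1(x, n_samples, variant = variant), ace(x))
  }
  pick <- cand[[which.max(vapply(cand, function(e) e$estimate, numeric(1)))]]
  new_richness_estimate(pick$estimator, pick$S_obs, pick$estimate, pick$sd,
                        pick$variant, pick$intermediates,
                        candidates = purrr::map_dfr(cand, tidy))
}

#' Richness estimates for every unit of an occurrence table
#'
#' Data-frame-first wrapper producing a per-unit estimate table in the layout
#' of the published cave and region tables (unit, number of member units,
#' observed and estimated richness).
#'
#' Abundance-based estimators (`chao1`, `ace`) run on the counts pooled
#' within each unit at `level`. Incidence-based estimators (`chao2`, `ice`,
#' and the rule-based `auto`) build, for each unit at `level`, the
#' presence/absence matrix of its member units at `unit_level` (default: the
#' next finer level).
#'
#' @param data An [occurrence()] object.
#' @param level Level whose units are estimated (`"sample"`, `"site"`,
#'   `"region"`).
#' @param estimator `"chao1"`, `"ace"`, `"chao2"`, `"ice"` or `"auto"`
#'   (CV-rule choice of the larger of Chao2/ICE, see
#'   [select_regional_estimate()]).
#' @param variant Passed to the Chao estimators.
#' @param unit_level Finer level supplying the incidence columns.
#' @return A tibble with one row per unit: `unit`, `n_units`, `S_obs`,
#'   `estimator`, `variant`, `estimate`, `sd`.
#' @examples
#' caves <- load_fixture("cave_incidence")
#' estimate_richness(caves, level = "region", estimator = "chao2",
#'                   variant = "classic")
#' @export
estimate_richness <- function(data, level = c("site", "region", "sample"),
                              estimator = c("auto", "chao1", "ace",
                                            "chao2", "ice"),
                              variant = "auto", unit_level = NULL) {
  level <- match.arg(level)
  estimator <- match.arg(estimator)
  hier <- sample_hierarchy(data)

  if (estimator %in% c("chao1", "ace")) {
    m <- occ_matrix(data, level)
    rows <- purrr::map(colnames(m), function(u) {
      n_u <- sum(hier[[level]] == u)
      if (sum(m[, u]) == 0) {
        return(tibble::tibble(unit = u, n_units = n_u, S_obs = 0L,
                              estimator = estimator, variant = NA_character_,
                              estimate = NA_real_, sd = NA_real_))
      }
      est <- if (estimator == "chao1") {
        chao1(m[, u], n_samples = n_u, variant = variant)
      } else {
        ace(m[, u])
      }
      dplyr::bind_cols(tibble::tibble(unit = u, n_units = n_u), tidy(est))
    })
    return(dplyr::bind_rows(rows))
  }

  if (is.null(unit_level)) {
    unit_level <- switch(level, region = "site", site = "sample",
                         sample = "sample")
  }
  groups <- unique(hier[[level]])
  rows <- purrr::map(groups, function(u) {
    member_samples <- hier$sample[hier[[level]] == u]
    sub <- occurrence(dplyr::filter(tibble::as_tibble(data),
                                    .data$sample %in% member_samples))
    m <- occ_matrix(sub, unit_level, incidence = TRUE)
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (nrow(m) == 0) {
      return(tibble::tibble(unit = u, n_units = ncol(m), S_obs = 0L,
                            estimator = estimator, variant = NA_character_,
                            estimate = NA_real_, sd = NA_real_))
    }
    est <- switch(estimator,
      chao2 = chao2(m, variant = variant),
      ice = ice(m),
      auto = select_regional_estimate(m)
    )
    dplyr::bind_cols(tibble::tibble(unit = u, n_units = ncol(m)), tidy(est))
  })
  dplyr::bind_rows(rows)
}
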