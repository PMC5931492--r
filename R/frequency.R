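#' Abundance-based frequency counts
#'
#' Summarises a vector of per-species abundances into the frequency counts
#' that drive the nonparametric estimators: F1 singletons, F2 doubletons and
#' so on, plus the coefficient of variation of the observed abundances used
#' by the estimator-selection rule.
#'
#' @param counts Vector of non-negative integer abundances, one per species.
#' @param n_samples Number of sampling units the abundances came from
#'   (used by the finite-sample Chao1 correction); optional.
#' @return A list of class `freq_counts`: `type`, `S_obs`, `N`, `F`
#'   (named vector, `F[i]` = number of species with exactly i individuals),
#'   `CV`, `n_samples`.
#' @export
freq_abundance <- function(counts, n_samples = NULL) {
  check_counts(counts)
  pos <- counts[counts > 0]
  f <- table(pos)
  F_ <- stats::setNames(as.integer(f), names(f))
  structure(list(
    type = "abundance",
    S_obs = length(pos),
    N = sum(pos),
    F = F_,
    CV = if (length(pos) > 1) stats::sd(pos) / mean(pos) else 0,
    n_samples = n_samples
  ), class = "freq_counts")
}

#' Incidence-based frequency counts
#'
#' @param incidence Species x sampling-unit matrix; any positive entry is
#'   treated as a presence.
#' @param freq_cutoff Occupancy above which a species counts as "frequent"
#'   for the coverage estimator (default 10 units).
#' @return A list of class `freq_counts`: `type`, `S_obs`, `T` (number of
#'   units), `Q` (named vector, `Q[j]` = species in exactly j units), `CV`
#'   (of the occupancy frequencies), plus the infrequent-group summaries
#'   `S_freq`, `S_infr`, `N_infr`, `m_infr`, `C_ice`.
#' @export
freq_incidence <- function(incidence, freq_cutoff = 10) {
  incidence <- as_incidence(incidence)
  T_ <- ncol(incidence)
  occ <- rowSums(incidence)
  occ <- occ[occ > 0]
  q <- table(occ)
  Q <- stats::setNames(as.integer(q), names(q))

  j <- as.integer(names(Q))
  infr <- j <= freq_cutoff
  N_infr <- sum(j[infr] * Q[infr])
  infreq_species <- names(occ)[occ <= freq_cutoff]
  m_infr <- if (length(infreq_species) > 0) {
    sum(colSums(incidence[infreq_species, , drop = FALSE]) > 0)
  } else 0L
  Q1 <- if ("1" %in% names(Q)) Q[["1"]] else 0L

  structure(list(
    type = "incidence",
    S_obs = length(occ),
    T = T_,
    Q = Q,
    CV = if (length(occ) > 1) stats::sd(occ) / mean(occ) else 0,
    freq_cutoff = freq_cutoff,
    S_freq = sum(Q[!infr]),
    S_infr = sum(Q[infr]),
    N_infr = N_infr,
    m_infr = m_infr,
    C_ice = if (N_infr > 0) 1 - Q1 / N_infr else NA_real_
  ), class = "freq_counts")
}

#' @export
print.freq_counts <- function(x, ...) {
  if (x$type == "abundance") {
    cat(sprintf("<freq_counts abundance> S_obs=%d N=%d CV=%.3f\n",
                x$S_obs, x$N, x$CV))
    print(x$F)
  } else {
    cat(sprintf("<freq_counts incidence> S_obs=%d T=%d CV=%.3f C_ice=%s\n",
                x$S_obs, x$T, x$CV, format(x$C_ice)))
    print(x$Q)
  }
  invisible(x)
}

# shared input checks -------------------------------------------------------

check_counts <- function(counts) {
  if (length(counts) == 0 || all(is.na(counts))) {
    stop("no counts supplied", call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0) {
    stop("all counts are zero: no species observed", call. = FALSE)
  }
  invisible(counts)
}

as_incidence <- function(m) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!is.matrix(m) || length(m) == 0) {
    stop("incidence must be a non-empty species x unit matrix", call. = FALSE)
  }
  if (any(is.na(m)) || any(m < 0)) {
    stop("incidence entries must be non-negative", call. = FALSE)
  }
  if (sum(m) == 0) stop("empty incidence matrix: no species present",
                        call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- paste0("sp", seq_len(nrow(m)))
  (m > 0) + 0L
}
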