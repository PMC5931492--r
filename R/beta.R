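#' Pairwise Sorensen dissimilarity decomposed into turnover and nestedness
#'
#' Baselga's decomposition for one pair of assemblages. With `a` shared
#' species, `b` exclusives of the poorer assemblage and `c` exclusives of
#' the richer one (`b <= c`):
#' `beta_sor = (b + c) / (2a + b + c)` (total dissimilarity),
#' `beta_sim = b / (b + a)` (turnover, i.e. species replacement) and
#' `beta_sne = beta_sor - beta_sim` (the nestedness-resultant component,
#' dissimilarity due to the poorer assemblage being a subset of the richer).
#'
#' @param x,y Assemblages: character vectors of species names, or equal
#'   length 0/1 (or count) vectors. At least one must be non-empty; when the
#'   poorer assemblage is empty `beta_sim` is taken as 0 (pure nestedness).
#' @return A one-row tibble of class `beta_decomposition`: `scope`,
#'   `n_units`, `a`, `b`, `c`, `beta_sor`, `beta_sim`, `beta_sne`,
#'   `pct_turnover` (`NA` when `beta_sor = 0`).
#' @examples
#' pairwise_beta(c("sp1", "sp2", "sp3"), c("sp1", "sp2", "sp4"))
#' @export
pairwise_beta <- function(x, y) {
  sets <- to_species_sets(x, y)
  if (length(sets$x) == 0 && length(sets$y) == 0) {
    stop("both assemblages are empty: dissimilarity undefined", call. = FALSE)
  }
  a <- length(intersect(sets$x, sets$y))
  ex <- sort(c(length(setdiff(sets$x, sets$y)),
               length(setdiff(sets$y, sets$x))))
  b <- ex[1]
  c_ <- ex[2]
  beta_sor <- (b + c_) / (2 * a + b + c_)
  beta_sim <- if (a + b == 0) 0 else b / (b + a)
  new_beta(scope = "pairwise", n_units = 2L, a = a, b = b, c = c_,
           beta_sor = beta_sor, beta_sim = beta_sim)
}

#' Multiple-site Sorensen dissimilarity decomposed into turnover and
#' nestedness
#'
#' Baselga's multiple-site generalisation over all units at once. With
#' pairwise exclusives `b_ij` (species in unit i not in j),
#' `Smin = sum_{i<j} min(b_ij, b_ji)`, `Smax = sum_{i<j} max(b_ij, b_ji)`
#' and `K = sum_i S_i - S_total`:
#' `beta_SIM = Smin / (Smin + K)`,
#' `beta_SOR = (Smin + Smax) / (2 K + Smin + Smax)`,
#' `beta_SNE = beta_SOR - beta_SIM`.
#' For exactly two units this reduces to [pairwise_beta()].
#'
#' @param incidence Species x unit matrix (positive entries = presence).
#' @param drop_empty Drop all-zero units first (default `TRUE`: Sorensen
#'   dissimilarity against an empty assemblage is undefined, and empty
#'   drips are excluded from the published within-cave values).
#' @return A one-row `beta_decomposition` tibble (`scope = "multi_site"`).
#' @examples
#' m <- cbind(d1 = c(1, 0, 0), d2 = c(1, 1, 1), d3 = c(1, 1, 1))
#' rownames(m) <- c("x", "y", "z")
#' multi_site_beta(m)
#' @export
multi_site_beta <- function(incidence, drop_empty = TRUE) {
  if (is.data.frame(incidence)) incidence <- as.matrix(incidence)
  if (drop_empty) {
    incidence <- incidence[, colSums(incidence) > 0, drop = FALSE]
  }
  if (ncol(incidence) < 2) {
    stop("need at least 2 non-empty units for multiple-site dissimilarity",
         call. = FALSE)
  }
  m <- as_incidence(incidence)
  n <- ncol(m)
  shared <- crossprod(m)                 # shared species per unit pair
  S_i <- diag(shared)
  b_ij <- matrix(S_i, n, n) - shared     # exclusives of unit i vs j
  upper <- upper.tri(b_ij)
  pmin_ <- pmin(b_ij, t(b_ij))[upper]
  pmax_ <- pmax(b_ij, t(b_ij))[upper]
  Smin <- sum(pmin_)
  Smax <- sum(pmax_)
  K <- sum(S_i) - sum(rowSums(m) > 0)
  beta_sim <- if (Smin + K == 0) 0 else Smin / (Smin + K)
  beta_sor <- if (2 * K + Smin + Smax == 0) 0 else
    (Smin + Smax) / (2 * K + Smin + Smax)
  new_beta(scope = "multi_site", n_units = n, a = NA_integer_,
           b = NA_integer_, c = NA_integer_,
           beta_sor = beta_sor, beta_sim = beta_sim)
}

#' Sorensen decomposition at each level of the sampling hierarchy
#'
#' Computes the multiple-site decomposition among the member units of every
#' group at the requested level: among samples within each site
#' (`"within_site"`), among site-pooled assemblages within each region
#' (`"within_region"`), or among region-pooled assemblages
#' (`"among_regions"`). Groups with fewer than two non-empty member units
#' yield an `NA` row rather than an error (a cave where only one drip held
#' copepods has no defined within-cave dissimilarity).
#'
#' @param data An [occurrence()] object.
#' @param level `"within_site"`, `"within_region"` or `"among_regions"`.
#' @param drop_empty Exclude empty member units (default `TRUE`).
#' @return A tibble with one row per group: `unit`, `n_units`
#'   (non-empty member units), `beta_sor`, `beta_sim`, `beta_sne`,
#'   `pct_turnover`.
#' @examples
#' beta_by_level(load_fixture("cave_incidence"), "among_regions")
#' @export
beta_by_level <- function(data,
                          level = c("within_site", "within_region",
                                    "among_regions"),
                          drop_empty = TRUE) {
  level <- match.arg(level)
  hier <- sample_hierarchy(data)
  df <- tibble::as_tibble(data)

  one <- function(unit_label, m) {
    m <- m[, colSums(m) > 0 | !drop_empty, drop = FALSE]
    if (ncol(m) < 2 || sum(m) == 0) {
      return(tibble::tibble(unit = unit_label, n_units = ncol(m),
                            beta_sor = NA_real_, beta_sim = NA_real_,
                            beta_sne = NA_real_, pct_turnover = NA_real_))
    }
    dplyr::bind_cols(
      tibble::tibble(unit = unit_label),
      dplyr::select(multi_site_beta(m, drop_empty = drop_empty),
                    "n_units", "beta_sor", "beta_sim", "beta_sne",
                    "pct_turnover")
    )
  }

  if (level == "among_regions") {
    m <- occ_matrix(data, "region", incidence = TRUE)
    return(one("all regions", m))
  }
  group_col <- if (level == "within_site") "site" else "region"
  member_level <- if (level == "within_site") "sample" else "site"
  purrr::map_dfr(unique(hier[[group_col]]), function(g) {
    sub <- occurrence(dplyr::filter(df, .data[[group_col]] == g))
    one(g, occ_matrix(sub, member_level, incidence = TRUE))
  })
}

to_species_sets <- function(x, y) {
  if (is.character(x) || is.character(y)) {
    return(list(x = unique(as.character(x)), y = unique(as.character(y))))
  }
  if (length(x) != length(y)) {
    stop("presence vectors must have equal length", call. = FALSE)
  }
  nm <- names(x) %||% paste0("sp", seq_along(x))
  list(x = nm[x > 0], y = nm[y > 0])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_beta <- function(scope, n_units, a, b, c, beta_sor, beta_sim) {
  beta_sne <- beta_sor - beta_sim
  out <- tibble::tibble(
    scope = scope, n_units = n_units, a = a, b = b, c = c,
    beta_sor = beta_sor, beta_sim = beta_sim, beta_sne = beta_sne,
    pct_turnover = ifelse(beta_sor > 0, 100 * beta_sim / beta_sor, NA_real_)
  )
  class(out) <- c("beta_decomposition", class(out))
  out
}
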