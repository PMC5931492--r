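#' Configuration for the hierarchical community generator
#'
#' Defines a three-level (sample in site in region) community with known
#' ground truth, emulating the statistical structure of an epikarst drip
#' survey: region-specific species pools with controllable overlap,
#' occupancy thinning from pool to site to sample, a nestedness/turnover
#' dial for how sample assemblages relate within a site, hotspot samples
#' with inflated occupancy, geometric-series relative abundances, repeated
#' (monthly) sampling events with Poisson detection, and a fraction of
#' samples that are empty regardless (dry or disconnected drips).
#'
#' Defaults mirror the scale of the Slovenian survey: 3 regions holding
#' 8/3/2 sites of 6 samples each (~80 samples), regional pools of 25/8/8
#' species with 10% expected pairwise overlap, 31% empty samples, 10%
#' hotspot samples, 8 monthly events of ~12 expected detections.
#'
#' @param n_regions Number of regions.
#' @param sites_per_region Sites per region; scalar or length-`n_regions`.
#' @param samples_per_site Samples (drips) per site; scalar or per-site.
#' @param regional_pool_size Species-pool size per region; scalar or
#'   per-region.
#' @param pool_overlap Expected fraction of a pool shared with every other
#'   region (a shared core of `round(pool_overlap * pool size)` species).
#' @param site_occupancy Probability a pool species occurs at a site.
#' @param sample_occupancy Probability a site species occurs in a sample.
#' @param nestedness_weight In `[0, 1]`: 1 makes sample assemblages within
#'   a site nested subsets along a fixed species ordering, 0 makes them
#'   independent (turnover-dominated) draws.
#' @param hotspot_fraction Fraction of samples whose occupancy is inflated.
#' @param hotspot_multiplier Multiplier on `sample_occupancy` for hotspots.
#' @param abundance_k Geometric-series parameter in (0, 1): species i in a
#'   regional pool has relative abundance proportional to
#'   `abundance_k * (1 - abundance_k)^(i - 1)` (singleton-heavy for small k).
#' @param detections_per_sample Expected individuals per sampling event in
#'   a non-empty sample (spread over species by relative abundance).
#' @param n_events Repeated sampling events per sample (monthly visits).
#' @param empty_sample_rate Probability a sample is empty regardless of the
#'   community (e.g. a dry drip).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_regions = 3,
                             sites_per_region = c(8, 3, 2),
                             samples_per_site = 6,
                             regional_pool_size = c(25, 8, 8),
                             pool_overlap = 0.1,
                             site_occupancy = 0.45,
                             sample_occupancy = 0.5,
                             nestedness_weight = 0.5,
                             hotspot_fraction = 0.1,
                             hotspot_multiplier = 1.8,
                             abundance_k = 0.5,
                             detections_per_sample = 12,
                             n_events = 8,
                             empty_sample_rate = 0.31) {
  cfg <- as.list(environment())
  probs <- c("pool_overlap", "site_occupancy", "sample_occupancy",
             "nestedness_weight", "hotspot_fraction", "empty_sample_rate")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]",
                                           call. = FALSE)
  }
  if (n_regions < 1) stop("need at least one region", call. = FALSE)
  if (n_regions == 1 && pool_overlap > 0) {
    stop("pool_overlap is meaningless with a single region", call. = FALSE)
  }
  if (abundance_k <= 0 || abundance_k >= 1) {
    stop("abundance_k must lie strictly in (0, 1)", call. = FALSE)
  }
  cfg$sites_per_region <- rep_len(cfg$sites_per_region, n_regions)
  cfg$regional_pool_size <- rep_len(cfg$regional_pool_size, n_regions)
  if (any(c(cfg$sites_per_region, cfg$samples_per_site,
            cfg$regional_pool_size, cfg$n_events) < 1)) {
    stop("sizes must be positive", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a hierarchical community with known ground truth
#'
#' Pure function of `config` and `seed`. Builds regional species pools (a
#' shared core realises the overlap), thins them to site assemblages, then
#' to per-sample "true" assemblages via the nestedness/turnover mixture,
#' and finally observes counts as Poisson detections summed over repeated
#' events, so that rare true members can be missed (false negatives) —
#' which is exactly what the nonparametric estimators must correct for.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return A list with `data` (an [occurrence()] of the observed counts,
#'   empty samples retained) and `truth` (list: `gamma_true`, per-region /
#'   per-site / per-sample true species sets, the hotspot samples, the
#'   forced-empty samples and the generating `config` and `seed`).
#' @examples
#' sim <- generate_community(synthetic_config(), seed = 42)
#' glance(sim$data)
#' sim$truth$gamma_true
#' @export
generate_community <- function(config, seed = 1) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  cfg <- config

  n_core <- round(cfg$pool_overlap * min(cfg$regional_pool_size))
  core <- if (n_core > 0) sprintf("core_%02d", seq_len(n_core)) else
    character(0)
  pools <- lapply(seq_len(cfg$n_regions), function(r) {
    n_excl <- cfg$regional_pool_size[r] - n_core
    c(core, sprintf("r%d_sp%03d", r, seq_len(max(n_excl, 0))))
  })

  rows <- list()
  truth_sites <- list()
  truth_samples <- list()
  hotspot_ids <- character(0)
  forced_empty <- character(0)

  for (r in seq_len(cfg$n_regions)) {
    region_id <- sprintf("region%d", r)
    pool <- pools[[r]]
    # geometric-series relative abundances within the regional pool
    rel <- cfg$abundance_k * (1 - cfg$abundance_k)^(seq_along(pool) - 1)
    rel <- rel / sum(rel)
    n_sites <- cfg$sites_per_region[r]
    for (s in seq_len(n_sites)) {
      site_id <- sprintf("%s_site%d", region_id, s)
      in_site <- stats::runif(length(pool)) < cfg$site_occupancy
      site_species <- pool[in_site]
      truth_sites[[site_id]] <- site_species
      site_rel <- rel[in_site]
      # per-species latent position: shared across samples (nested) vs
      # redrawn per sample (turnover), mixed by nestedness_weight
      u_site <- stats::runif(length(site_species))
      n_samp <- rep_len(cfg$samples_per_site, n_sites)[s]
      for (d in seq_len(n_samp)) {
        sample_id <- sprintf("%s_d%d", site_id, d)
        hot <- stats::runif(1) < cfg$hotspot_fraction
        if (hot) hotspot_ids <- c(hotspot_ids, sample_id)
        p_occ <- min(cfg$sample_occupancy *
                       if (hot) cfg$hotspot_multiplier else 1, 1)
        u_samp <- stats::runif(length(site_species))
        u <- cfg$nestedness_weight * u_site +
          (1 - cfg$nestedness_weight) * u_samp
        present <- site_species[u < p_occ]
        empty_forced <- stats::runif(1) < cfg$empty_sample_rate
        if (empty_forced) {
          forced_empty <- c(forced_empty, sample_id)
          present <- character(0)
        }
        truth_samples[[sample_id]] <- present
        if (length(present) > 0) {
          lam <- site_rel[match(present, site_species)]
          lam <- lam / sum(lam) * cfg$detections_per_sample
          counts <- stats::rpois(length(present), lam * cfg$n_events)
          keep <- counts > 0
          if (any(keep)) {
            rows[[length(rows) + 1]] <- tibble::tibble(
              species = present[keep], sample = sample_id,
              site = site_id, region = region_id, count = counts[keep]
            )
          }
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          species = NA_character_, sample = sample_id, site = site_id,
          region = region_id, count = 0L
        )
      }
    }
  }

  data <- occurrence(dplyr::bind_rows(rows))
  truth_regions <- lapply(seq_len(cfg$n_regions), function(r) {
    sites_r <- grep(sprintf("^region%d_", r), names(truth_sites))
    sort(unique(unlist(truth_sites[sites_r])))
  })
  names(truth_regions) <- sprintf("region%d", seq_len(cfg$n_regions))
  list(
    data = data,
    truth = list(
      gamma_true = length(unique(unlist(truth_samples))),
      pool_gamma = length(unique(unlist(pools))),
      region_species = truth_regions,
      site_species = truth_sites,
      sample_species = truth_samples,
      hotspots = hotspot_ids,
      forced_empty = forced_empty,
      config = cfg,
      seed = seed
    )
  )
}

#' Estimator recovery experiment on synthetic communities
#'
#' Repeatedly generates communities from `config`, applies a richness
#' estimator to the pooled observed counts, and compares the estimates to
#' the true number of species present across the samples, summarising bias,
#' RMSE and coverage of the observed richness bound.
#'
#' @param config A [synthetic_config()].
#' @param n_reps Number of replicate communities (>= 2).
#' @param estimator `"chao1"`, `"chao2"`, `"ace"` or `"ice"`.
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @return A list with `replicates` (tibble: `rep`, `S_true`, `S_obs`,
#'   `estimate`) and `summary` (one-row tibble: mean bias, relative bias,
#'   RMSE, and the fraction of replicates with `estimate >= S_obs`).
#' @export
recovery_experiment <- function(config, n_reps, estimator = "chao1",
                                seed = 1) {
  if (n_reps < 2) stop("n_reps must be at least 2", call. = FALSE)
  estimator <- match.arg(estimator, c("chao1", "chao2", "ace", "ice"))
  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    sim <- generate_community(config, seed = seed + r)
    m <- occ_matrix(sim$data, "sample")
    est <- switch(estimator,
      chao1 = chao1(rowSums(m), n_samples = ncol(m)),
      ace = ace(rowSums(m)),
      chao2 = chao2(m),
      ice = ice(m)
    )
    tibble::tibble(rep = r,
                   S_true = sim$truth$gamma_true,
                   S_obs = est$S_obs,
                   estimate = est$estimate)
  })
  summary <- reps |>
    dplyr::summarise(
      estimator = estimator,
      mean_S_true = mean(.data$S_true),
      mean_S_obs = mean(.data$S_obs),
      mean_estimate = mean(.data$estimate),
      bias = mean(.data$estimate - .data$S_true),
      rel_bias = mean(.data$estimate - .data$S_true) / mean(.data$S_true),
      rmse = sqrt(mean((.data$estimate - .data$S_true)^2)),
      frac_above_obs = mean(.data$estimate >= .data$S_obs)
    )
  list(replicates = reps, summary = summary)
}
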