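test_that("generation is a pure function of config and seed", {
  cfg <- synthetic_config(sites_per_region = 2, samples_per_site = 3,
                          regional_pool_size = 10)
  a <- generate_community(cfg, seed = 5)
  b <- generate_community(cfg, seed = 5)
  expect_identical(occ_matrix(a$data), occ_matrix(b$data))
  expect_identical(a$truth$sample_species, b$truth$sample_species)
  c_ <- generate_community(cfg, seed = 6)
  expect_false(identical(occ_matrix(a$data), occ_matrix(c_$data)))
})

test_that("config validation rejects impossible settings", {
  expect_error(synthetic_config(pool_overlap = 1.5), "\\[0, 1\\]")
  expect_error(synthetic_config(n_regions = 1, pool_overlap = 0.2),
               "single region")
  expect_error(synthetic_config(abundance_k = 1), "strictly")
  expect_error(synthetic_config(samples_per_site = 0), "positive")
})

test_that("generated datasets satisfy the occurrence invariants", {
  withr::local_seed(71)
  for (s in 1:5) {
    sim <- generate_community(synthetic_config(
      sites_per_region = c(2, 3), n_regions = 2, regional_pool_size = 12,
      samples_per_site = 4, empty_sample_rate = 0.3
    ), seed = s)
    g <- glance(sim$data)
    expect_equal(g$n_samples, (2 + 3) * 4)
    expect_equal(g$n_regions, 2L)
    m <- occ_matrix(sim$data)
    expect_true(all(m >= 0))
    expect_true(all(m == round(m)))
    # observed species are a subset of the true sampled community
    expect_true(all(rownames(m)[rowSums(m) > 0] %in%
                      unique(unlist(sim$truth$sample_species))))
  }
})

test_that("disjoint regional pools give complete among-region turnover", {
  sim <- generate_community(synthetic_config(
    pool_overlap = 0, regional_pool_size = 8, sites_per_region = 2,
    samples_per_site = 3, site_occupancy = 0.9, empty_sample_rate = 0
  ), seed = 3)
  pools <- sim$truth$region_species
  for (pair in utils::combn(length(pools), 2, simplify = FALSE)) {
    b <- pairwise_beta(pools[[pair[1]]], pools[[pair[2]]])
    expect_equal(b$beta_sor, 1)
  }
})

test_that("fully nested generation yields zero turnover in the true assemblages", {
  sim <- generate_community(synthetic_config(
    nestedness_weight = 1, empty_sample_rate = 0, hotspot_fraction = 0.3,
    sites_per_region = 1, n_regions = 2, samples_per_site = 6,
    regional_pool_size = 12, site_occupancy = 0.9
  ), seed = 11)
  hier <- sample_hierarchy(sim$data)
  for (st in unique(hier$site)) {
    ids <- hier$sample[hier$site == st]
    sets <- sim$truth$sample_species[ids]
    sets <- sets[lengths(sets) > 0]
    if (length(sets) < 2) next
    species <- unique(unlist(sets))
    m <- vapply(sets, function(s) as.integer(species %in% s),
                integer(length(species)))
    rownames(m) <- species
    expect_equal(multi_site_beta(m)$beta_sim, 0)
  }
})

test_that("the realized empty-sample fraction tracks the configured rate", {
  withr::local_seed(81)
  rate <- 0.31
  n_tot <- 0; n_empty <- 0
  for (s in 1:5) {
    sim <- generate_community(synthetic_config(empty_sample_rate = rate),
                              seed = 200 + s)
    g <- glance(sim$data)
    n_tot <- n_tot + g$n_samples
    # count samples whose true assemblage was forced empty
    n_empty <- n_empty + length(sim$truth$forced_empty)
  }
  # within 4 binomial SDs of the configured rate
  se <- sqrt(rate * (1 - rate) / n_tot)
  expect_lt(abs(n_empty / n_tot - rate), 4 * se)
})

test_that("hotspot inflation raises the variance of per-sample richness", {
  base_cfg <- synthetic_config(hotspot_fraction = 0, empty_sample_rate = 0,
                               sites_per_region = 2, samples_per_site = 5)
  hot_cfg <- synthetic_config(hotspot_fraction = 0.3,
                              hotspot_multiplier = 1.9,
                              empty_sample_rate = 0,
                              sites_per_region = 2, samples_per_site = 5)
  var_of <- function(cfg, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- generate_community(cfg, seed = s)
      stats::var(unit_richness(sim$data, "sample")$richness)
    }, numeric(1)))
  }
  seeds <- 301:315
  expect_gt(var_of(hot_cfg, seeds), var_of(base_cfg, seeds))
})

test_that("chao1 recovers true richness under deep sampling and bounds shallow", {
  deep <- synthetic_config(
    n_regions = 1, sites_per_region = 3, samples_per_site = 4,
    regional_pool_size = 12, pool_overlap = 0, site_occupancy = 0.8,
    sample_occupancy = 0.7, empty_sample_rate = 0,
    detections_per_sample = 120, n_events = 6
  )
  rec <- recovery_experiment(deep, n_reps = 200, estimator = "chao1",
                             seed = 1)
  expect_lt(abs(rec$summary$rel_bias), 0.05)
  expect_equal(rec$summary$frac_above_obs, 1)

  shallow <- synthetic_config(
    n_regions = 1, sites_per_region = 3, samples_per_site = 4,
    regional_pool_size = 12, pool_overlap = 0, site_occupancy = 0.8,
    sample_occupancy = 0.7, empty_sample_rate = 0,
    detections_per_sample = 1.5, n_events = 2
  )
  rec_sh <- recovery_experiment(shallow, n_reps = 60, estimator = "chao1",
                                seed = 1)
  expect_true(all(rec_sh$replicates$S_obs < rec_sh$replicates$S_true))
  expect_true(all(rec_sh$replicates$estimate >= rec_sh$replicates$S_obs))

  # bias shrinks (within Monte-Carlo error) as sampling deepens
  mid <- synthetic_config(
    n_regions = 1, sites_per_region = 3, samples_per_site = 4,
    regional_pool_size = 12, pool_overlap = 0, site_occupancy = 0.8,
    sample_occupancy = 0.7, empty_sample_rate = 0,
    detections_per_sample = 12, n_events = 4
  )
  rec_mid <- recovery_experiment(mid, n_reps = 60, estimator = "chao1",
                                 seed = 1)
  deep_bias <- abs(rec$summary$rel_bias)
  mid_bias <- abs(rec_mid$summary$rel_bias)
  sh_bias <- abs(rec_sh$summary$rel_bias)
  expect_gt(sh_bias, mid_bias - 0.02)
  expect_gt(mid_bias, deep_bias - 0.02)
})
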