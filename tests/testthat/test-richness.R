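test_that("chao1 matches direct evaluation of the printed formulas", {
  # S_obs = 10, F1 = 4, F2 = 2
  v <- c(1, 1, 1, 1, 2, 2, 5, 5, 5, 5)
  expect_equal(chao1(v, variant = "classic")$estimate, 14)
  expect_equal(chao1(v, n_samples = 12, variant = "bias_corrected")$estimate,
               10 + (11 / 12) * 16 / 4)

  # no singletons: estimate collapses to S_obs for every variant
  v0 <- c(2, 2, 3, 3, 4, 4, 5, 5)
  for (vr in c("classic", "bias_corrected", "auto")) {
    est <- chao1(v0, n_samples = 5, variant = vr)
    expect_equal(est$estimate, 8)
    expect_equal(est$sd, 0)
  }

  expect_error(chao1(c(0, 0, 0)), "zero")
  expect_error(chao1(c(-1, 2)), "non-negative")
})

test_that("chao1 classic agrees with an independent reference on frozen cases", {
  # expected values computed beforehand with a reference implementation
  cases <- list(
    list(v = c(1, 1, 2, 3, 5, 8, 1, 2), expected = 10.25),
    list(v = c(1, 1, 1, 2, 2, 4, 6, 6, 10, 1), expected = 14),
    list(v = c(2, 2, 3, 1, 1, 1, 1, 7), expected = 12)
  )
  for (cs in cases) {
    expect_equal(chao1(cs$v, variant = "classic")$estimate, cs$expected,
                 tolerance = 1e-9)
  }
})

test_that("chao1 auto applies the CV > 0.5 selection rule", {
  skewed <- c(1, 1, 1, 2, 50)           # CV well above 0.5 -> classic
  even <- c(4, 5, 5, 6, 4, 5, 1, 1)     # CV below 0.5 -> bias-corrected
  expect_equal(chao1(skewed, n_samples = 10)$variant, "classic")
  expect_equal(chao1(even, n_samples = 10)$variant, "bias_corrected")
  expect_equal(chao1(even, n_samples = 10)$estimate,
               chao1(even, n_samples = 10, variant = "bias_corrected")$estimate)
})

test_that("chao2 reproduces the published zero-duplicate correction", {
  m <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1), d = c(0, 1))
  expect_equal(chao2(m, variant = "bias_corrected")$estimate, 7)

  # no uniques -> S_obs exactly
  m2 <- rbind(a = c(1, 1, 0), b = c(1, 0, 1))
  expect_equal(chao2(m2, variant = "classic")$estimate, 2)

  expect_error(chao2(matrix(0, 2, 2)), "no species")
})

test_that("chao2 classic on Dinaric cave incidence matches hand-tallied counts", {
  caves <- load_fixture("cave_incidence")
  din <- occurrence(dplyr::filter(tibble::as_tibble(caves),
                                  region == "Dinaric"))
  m <- occ_matrix(din, "sample", incidence = TRUE)
  m <- m[rowSums(m) > 0, ]
  fc <- freq_incidence(m)
  expect_equal(fc$S_obs, 25L)
  expect_equal(fc$T, 8L)
  expect_equal(unname(fc$Q[["1"]]), 11L)
  expect_equal(unname(fc$Q[["2"]]), 8L)
  expect_equal(chao2(m, variant = "classic")$estimate, 25 + 121 / 16,
               tolerance = 1e-12)
  # ICE over the same incidence reproduces the published regional value
  expect_equal(round(ice(m)$estimate, 1), 41.4)
})

test_that("ace handles the abundant-only, toy and all-singleton regimes", {
  # everything abundant: nothing to extrapolate
  expect_equal(ace(c(20, 30, 40))$estimate, 3)

  # frozen value from an independent reference implementation
  expect_equal(ace(c(1, 1, 2, 3, 15))$estimate, 6.786667, tolerance = 1e-6)

  # all singletons: zero coverage forces the Chao1 fallback
  fb <- ace(c(1, 1, 1, 1))
  expect_equal(fb$variant, "fallback")
  expect_equal(fb$estimate, chao1(c(1, 1, 1, 1),
                                  variant = "bias_corrected")$estimate)
})

test_that("ice follows the printed formula chain and its fallbacks", {
  # all species in > cutoff units
  m_freq <- matrix(1, 2, 11,
                   dimnames = list(c("a", "b"), paste0("u", 1:11)))
  expect_equal(ice(m_freq)$estimate, 2)

  # Q1=2, Q2=1, Q3=1, T=5: hand-evaluated chain
  # N_infr=7, C_ice=5/7, m_infr=3, gamma2=8.4*8/49-1, ICE = 6.64
  m <- matrix(0, 4, 5, dimnames = list(paste0("sp", 1:4), paste0("u", 1:5)))
  m[1, 1] <- 1; m[2, 2] <- 1; m[3, 1:2] <- 1; m[4, 1:3] <- 1
  expect_equal(ice(m)$estimate, 6.64, tolerance = 1e-9)

  # all uniques: C_ice = 0 forces the Chao2 fallback
  m_uni <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1), d = c(0, 1))
  fb <- ice(m_uni)
  expect_equal(fb$variant, "fallback")
  expect_equal(fb$estimate, 7)
})

test_that("regional selection returns the larger candidate under the CV rule", {
  m_uni <- rbind(a = c(1, 0), b = c(1, 0), c = c(0, 1), d = c(0, 1))
  sel <- select_regional_estimate(m_uni)
  expect_equal(sel$estimate, 7) # both candidates 7.0
  expect_equal(nrow(sel$candidates), 2)
  expect_true(all(sel$candidates$estimate <= sel$estimate))

  withr::local_seed(11)
  for (i in 1:10) {
    m <- random_incidence(12, 6)
    m <- m[rowSums(m) > 0, , drop = FALSE]
    sel <- select_regional_estimate(m)
    expect_equal(sel$estimate, max(sel$candidates$estimate))
    fc <- freq_incidence(m)
    expected_variant <- if (fc$CV > 0.5) "classic" else "bias_corrected"
    chao_row <- sel$candidates[sel$candidates$estimator == "chao2", ]
    expect_equal(chao_row$variant, expected_variant)
  }
})

test_that("estimators never fall below observed richness", {
  withr::local_seed(3)
  for (i in 1:20) {
    counts <- rpois(15, lambda = sample(c(0.5, 2, 8), 1))
    if (sum(counts) == 0) counts[1] <- 1
    S <- sum(counts > 0)
    expect_gte(chao1(counts, n_samples = 6)$estimate, S)
    expect_gte(ace(counts)$estimate, S)
    m <- random_incidence(12, 5)
    S2 <- sum(rowSums(m) > 0)
    expect_gte(chao2(m)$estimate, S2)
    expect_gte(ice(m)$estimate, S2)
  }
})

test_that("empty sampling units leave abundance estimates unchanged and move incidence ones only via T", {
  counts <- c(1, 1, 2, 4, 4)
  # classic chao1 depends on abundances only, not on how many units held them
  expect_equal(chao1(counts, n_samples = 5, variant = "classic")$estimate,
               chao1(counts, n_samples = 6, variant = "classic")$estimate)
  m <- random_incidence_nonempty(8, 4)
  m_plus <- cbind(m, empty = 0L)
  # classic Chao2 has no T dependence: identical after adding an empty unit
  expect_equal(chao2(m_plus, variant = "classic")$estimate,
               chao2(m, variant = "classic")$estimate)
  # bias-corrected changes only through the (T-1)/T factor
  fc <- freq_incidence(m)
  q1 <- sum(rowSums(m) == 1); q2 <- sum(rowSums(m) == 2)
  if (q2 > 0) {
    expect_equal(chao2(m_plus, variant = "bias_corrected")$estimate,
                 fc$S_obs + (4 / 5) * q1^2 / (2 * q2))
  }
})

test_that("chao2 bias-corrected agrees with vegan::specpool on random matrices", {
  skip_if_not_installed("vegan")
  withr::local_seed(42)
  found <- 0
  while (found < 20) {
    m <- random_incidence(15, 7)
    m <- m[rowSums(m) > 0, , drop = FALSE]
    if (sum(rowSums(m) == 2) == 0) next # vegan switches formula when Q2 = 0
    found <- found + 1
    ours <- chao2(m, variant = "bias_corrected")$estimate
    ref <- vegan::specpool(t(m))$chao
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})
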