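test_that("pairwise decomposition matches both printed forms", {
  # disjoint assemblages: pure turnover
  d <- pairwise_beta(c("a", "b"), c("c", "d", "e"))
  expect_equal(d$beta_sor, 1)
  expect_equal(d$beta_sim, 1)
  expect_equal(d$beta_sne, 0)
  expect_equal(d$pct_turnover, 100)

  # identical assemblages
  i <- pairwise_beta(c("a", "b"), c("a", "b"))
  expect_equal(i$beta_sor, 0)
  expect_true(is.na(i$pct_turnover))

  # a = 2, b = 1, c = 3, checking the alternative nestedness form
  x <- c("a", "b", "p")
  y <- c("a", "b", "q", "r", "s")
  d2 <- pairwise_beta(x, y)
  expect_equal(d2$beta_sor, 0.5)
  expect_equal(d2$beta_sim, 1 / 3)
  expect_equal(d2$beta_sne, 1 / 6)
  a <- 2; b <- 1; c_ <- 3
  expect_equal(d2$beta_sne, ((c_ - b) / (2 * a + b + c_)) * (a / (b + a)))

  # 0/1 vector input is equivalent to set input
  v <- pairwise_beta(c(a = 1, b = 1, c = 0), c(a = 1, b = 0, c = 1))
  expect_equal(v$a, 1)
  expect_error(pairwise_beta(character(0), character(0)), "empty")
})

test_that("multiple-site decomposition reproduces the drip reconstructions", {
  # identical assemblages across drips: zero dissimilarity
  sn <- load_fixture("snezna_drips")
  b <- multi_site_beta(occ_matrix(sn, "sample", incidence = TRUE))
  expect_equal(b$beta_sor, 0)
  expect_equal(b$n_units, 3) # the two empty drips are dropped

  # nested drips: dissimilarity entirely from nestedness
  jp <- load_fixture("jpbz_drips")
  b2 <- multi_site_beta(occ_matrix(jp, "sample", incidence = TRUE))
  expect_equal(b2$beta_sor, 8 / 18, tolerance = 1e-12)
  expect_equal(b2$beta_sim, 0)
  expect_equal(b2$pct_turnover, 0)

  # refusing to work on fewer than two non-empty units
  m <- cbind(a = c(1, 0), b = c(0, 0))
  expect_error(multi_site_beta(m), "at least 2")
})

test_that("additivity, ordering and relabelling invariances hold", {
  withr::local_seed(21)
  for (i in 1:25) {
    m <- random_incidence_nonempty(sample(4:12, 1), sample(3:7, 1))
    b <- multi_site_beta(m)
    expect_equal(b$beta_sor, b$beta_sim + b$beta_sne, tolerance = 1e-12)
    expect_gte(b$beta_sim, 0)
    expect_lte(b$beta_sim, b$beta_sor + 1e-12)
    expect_lte(b$beta_sor, 1)

    perm <- sample(ncol(m))
    expect_equal(multi_site_beta(m[, perm])$beta_sor, b$beta_sor,
                 tolerance = 1e-12)
    m2 <- m
    rownames(m2) <- sample(rownames(m))
    expect_equal(multi_site_beta(m2)$beta_sim, b$beta_sim,
                 tolerance = 1e-12)
  }
})

test_that("two-unit multiple-site equals the pairwise decomposition", {
  withr::local_seed(31)
  for (i in 1:20) {
    m <- random_incidence_nonempty(8, 2)
    b_multi <- multi_site_beta(m)
    b_pair <- pairwise_beta(m[, 1], m[, 2])
    expect_equal(b_multi$beta_sor, b_pair$beta_sor, tolerance = 1e-12)
    expect_equal(b_multi$beta_sim, b_pair$beta_sim, tolerance = 1e-12)
  }
})

test_that("nested chains have zero turnover; equal-sized disjoint sets zero nestedness", {
  chain <- cbind(u1 = c(1, 0, 0), u2 = c(1, 1, 0), u3 = c(1, 1, 1))
  rownames(chain) <- c("a", "b", "c")
  b <- multi_site_beta(chain)
  expect_equal(b$beta_sim, 0)
  expect_gt(b$beta_sne, 0)
  expect_equal(b$beta_sor, b$beta_sne)

  disjoint <- cbind(u1 = c(1, 1, 0, 0), u2 = c(0, 0, 1, 1))
  rownames(disjoint) <- paste0("s", 1:4)
  b2 <- multi_site_beta(disjoint)
  expect_equal(b2$beta_sne, 0)
  expect_equal(b2$beta_sor, b2$beta_sim)
})

test_that("multiple-site values agree with vegan's Baselga decomposition", {
  skip_if_not_installed("vegan")
  withr::local_seed(41)
  for (i in 1:15) {
    m <- random_incidence_nonempty(sample(5:12, 1), sample(3:6, 1))
    ours <- multi_site_beta(m)
    ref <- vegan::nestedbetasor(t(m))
    expect_equal(ours$beta_sim, unname(ref["turnover"]), tolerance = 1e-9)
    expect_equal(ours$beta_sne, unname(ref["nestedness"]), tolerance = 1e-9)
    expect_equal(ours$beta_sor, unname(ref["sorensen"]), tolerance = 1e-9)
  }
})

test_that("beta_by_level walks the hierarchy and records undefined groups", {
  occ <- occ_from_sets(list(
    reg1 = list(
      caveA = list(d1 = c("a", "b"), d2 = c("a", "c")),
      caveB = list(d3 = "a", d4 = character(0))
    ),
    reg2 = list(caveC = list(d5 = c("x", "y"), d6 = c("x", "y")))
  ))
  ws <- beta_by_level(occ, "within_site")
  expect_equal(nrow(ws), 3)
  # caveB has a single non-empty drip: undefined, not an error
  expect_true(is.na(ws$beta_sor[ws$unit == "caveB"]))
  expect_equal(ws$beta_sor[ws$unit == "caveC"], 0)

  ar <- beta_by_level(occ, "among_regions")
  expect_equal(ar$n_units, 2)
  expect_equal(ar$beta_sim, 1) # disjoint regional pools

  # Isolated region: two caves sharing nothing -> 100% turnover
  caves <- load_fixture("cave_incidence")
  wr <- beta_by_level(caves, "within_region")
  expect_equal(wr$pct_turnover[wr$unit == "Isolated"], 100)
  # the other regional rows of the published table also reproduce under
  # the multiple-site convention over cave assemblages
  expect_equal(round(wr$beta_sor[wr$unit == "Alpine"], 2), 0.57)
  expect_equal(round(wr$pct_turnover[wr$unit == "Alpine"]), 88)
  expect_equal(round(wr$beta_sor[wr$unit == "Dinaric"], 2), 0.76)
})
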