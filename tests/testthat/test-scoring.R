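test_that("intensity scoring uses left-closed zones", {
  m <- score_matrix(c(10, 20, 30))
  expect_equal(score_from_intensity(0, m), 0)
  expect_equal(score_from_intensity(c(10, 20, 30), m), c(1, 2, 3))  # boundaries up
  expect_equal(score_from_intensity(9.999, m), 0)
  # monotone sweep -> non-decreasing scores
  grid <- seq(0, 40, 0.25)
  expect_true(all(diff(score_from_intensity(grid, m)) >= 0))
  expect_error(score_matrix(c(1, 1, 2)), "increasing")
})

test_that("quartile-calibrated boundaries populate all four levels", {
  set.seed(13)
  cal <- runif(200, 0, 3)
  m <- score_boundaries(cal)
  scores <- score_from_intensity(cal, m)
  expect_setequal(unique(scores), 0:3)
})

test_that("percent agreement counts exact matches", {
  expect_equal(percent_agreement(c(0, 1, 2), c(0, 1, 2)), 100)
  expect_equal(percent_agreement(c(0, 1), c(1, 0)), 0)
  a <- c(rep(0, 7), rep(1, 15)); b <- c(rep(0, 7), rep(2, 15))
  expect_equal(percent_agreement(a, b), 100 * 7 / 22, tolerance = 1e-12)
  expect_equal(round(percent_agreement(a, b)), 32)
  expect_error(percent_agreement(0:1, 0:2), "length")
})

test_that("weighted kappa matches the independent direct-formula oracle", {
  expect_equal(weighted_kappa(c(0, 1, 2, 3), c(0, 1, 2, 3)), 1)
  expect_error(weighted_kappa(c(0, 4), c(0, 1)), "scores must")

  set.seed(17)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    a <- sample(0:3, n, replace = TRUE)
    b <- sample(0:3, n, replace = TRUE)
    if (length(unique(a)) == 1 && identical(a, b)) next
    expect_equal(weighted_kappa(a, b), kappa_oracle(a, b), tolerance = 1e-12)
    # symmetry
    expect_equal(weighted_kappa(a, b), weighted_kappa(b, a), tolerance = 1e-12)
  }

  # chance agreement: independent raters -> kappa near 0 at large n
  set.seed(19)
  a <- sample(0:3, 4000, replace = TRUE)
  b <- sample(0:3, 4000, replace = TRUE)
  expect_lt(abs(weighted_kappa(a, b)), 0.05)

  # both raters constant and identical -> 1 by convention
  expect_message(k1 <- weighted_kappa(rep(2, 5), rep(2, 5)), "convention")
  expect_equal(k1, 1)
})

test_that("kappa never exceeds 1 and hits 1 only on perfect agreement", {
  set.seed(23)
  for (i in 1:50) {
    a <- sample(0:3, 30, replace = TRUE)
    b <- a; flip <- sample(30, 5); b[flip] <- (b[flip] + 1L) %% 4L
    k <- weighted_kappa(a, b)
    expect_lte(k, 1)
    expect_lt(k, 1)   # 5 disagreements -> strictly below 1
    expect_equal(weighted_kappa(a, a), 1)
  }
})

test_that("Landis-Koch bands label kappa magnitudes", {
  expect_equal(kappa_category(c(-0.1, 0, 0.2, 0.45, 0.7, 0.9)),
               c("poor", "slight", "slight", "moderate", "substantial",
                 "almost perfect"))
  expect_equal(kappa_category(c(0.21, 0.4, 1)), c("fair", "fair", "almost perfect"))
})

test_that("three-way overlap reports pairwise and triple agreement", {
  r <- c(0, 1, 2, 3, 2)
  rep1 <- three_way_overlap(r, r, r)
  expect_true(all(rep1$pairwise$percent_agreement == 100))
  expect_equal(rep1$triple_percent, 100)

  r2 <- c(0, 1, 2, 3, 3)
  rep2 <- three_way_overlap(r, r2, r)       # r3 = r1
  pw <- rep2$pairwise
  expect_equal(pw$percent_agreement[pw$a == "rater1" & pw$b == "rater3"], 100)
  expect_equal(rep2$triple_percent,
               pw$percent_agreement[pw$a == "rater1" & pw$b == "rater2"])

  # triple agreement can never exceed any pairwise agreement
  set.seed(29)
  for (i in 1:20) {
    x <- sample(0:3, 40, TRUE); y <- sample(0:3, 40, TRUE); z <- sample(0:3, 40, TRUE)
    rp <- three_way_overlap(x, y, z)
    expect_lte(rp$triple_percent, min(rp$pairwise$percent_agreement))
  }
  expect_error(three_way_overlap(0:3, 0:3, 0:2), "length")
})

test_that("simulated raters stay in range and degrade with noise", {
  truth <- rep(0:3, 25)
  set.seed(31)
  clean <- simulate_rater(truth, 0)
  expect_identical(clean, truth)
  noisy <- simulate_rater(truth, 0.8)
  expect_true(all(noisy %in% 0:3))
  # expected kappa decreases along a noise grid (Monte-Carlo trend)
  kap <- sapply(c(0, 0.25, 0.5, 0.9), function(p) {
    mean(replicate(30, {
      r <- simulate_rater(truth, p)
      suppressMessages(weighted_kappa(truth, r))
    }))
  })
  expect_true(all(diff(kap) < 0))
})
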