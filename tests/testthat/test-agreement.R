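# Weighted-kappa statistics: closed-form cases, brute-force oracle
# equivalence, not-ratable handling, aggregation.

test_that("kappa is 1 on perfect agreement and 0 on exact-independence tables", {
  a <- c(0, 1, 2, 3, 4, 2, 1, 0, 3, 4)
  k <- weightedKappa(a, a)
  expect_equal(kappaValue(k), 1)
  expect_identical(k@nPairsUsed, 10L)

  # cells exactly the outer product of the marginals -> chance agreement
  marg <- c(10, 20, 40, 20, 10)
  O <- outer(marg, marg) / sum(marg)
  k0 <- weightedKappaFromTable(O)
  expect_equal(kappaValue(k0), 0, tolerance = 1e-15)
  expect_identical(k0@interpretation, "chance-or-worse")
})

test_that("kappa matches the brute-force oracle on random tables", {
  set.seed(20)
  for (rep in 1:100) {
    n <- sample(10:60, 1)
    a <- sample(0:4, n, replace = TRUE, prob = runif(5))
    b <- pmin(4, pmax(0, a + sample(-2:2, n, replace = TRUE)))
    # sprinkle NR into both vectors
    a[sample(n, n %/% 10)] <- NA
    b[sample(n, n %/% 10)] <- NA
    if (sum(!is.na(a) & !is.na(b)) < 2) next
    ko <- kappa_oracle(a, b)
    if (is.na(ko)) next
    expect_equal(kappaValue(weightedKappa(a, b)), ko, tolerance = 1e-12)
  }
})

test_that("not-ratable pairs are excluded pairwise-complete and counted", {
  a <- c(2, 3, NA, 1, 0, 4)
  b <- c("1", "3", "2", "1", "NR", "4")
  k <- weightedKappa(a, b)
  expect_identical(k@nPairsUsed, 4L)
  expect_error(weightedKappa(c(1, NA, NA), c(NA, 2, 3)), "usable pairs")
})

test_that("kappa without marginal variation is reported as undefined, not 0", {
  k <- weightedKappa(rep(2, 10), rep(2, 10))
  expect_true(is.na(kappaValue(k)))
  expect_match(k@reason, "marginal")
  expect_identical(k@interpretation, "undefined")
})

test_that("kappa statistics are invariant to reordering videos", {
  set.seed(21)
  g <- sample(0:4, 40, replace = TRUE)
  raters <- lapply(1:3, function(j) raterModel(miscodeSd = 0.7, seed = j,
                                               notRatableProb = 0.1))
  tab <- simulateRatings(g, raters)
  perm <- sample(40)
  tab_perm <- new("RatingTable", ratings = ratings(tab)[perm, ],
                  videoIds = videoIds(tab)[perm], raterIds = raterIds(tab),
                  condition = "original")
  r1 <- interraterAgreement(tab)
  r2 <- interraterAgreement(tab_perm)
  expect_equal(r1$meanKappa, r2$meanKappa, tolerance = 1e-12)
  expect_equal(unname(r1$pairwise), unname(r2$pairwise), tolerance = 1e-12)
  expect_equal(ratableProportion(tab), ratableProportion(tab_perm))
})

test_that("intra-rater agreement is perfect for identical tables and excludes all-NR raters", {
  set.seed(22)
  g <- sample(0:4, 30, replace = TRUE)
  raters <- lapply(1:4, function(j) raterModel(miscodeSd = 0.5, seed = j))
  orig <- simulateRatings(g, raters)
  res <- intraraterAgreement(orig, orig)
  expect_equal(kappaValue(res$pooled), 1)
  for (k in res$perRater) expect_equal(kappaValue(k), 1)

  # one rater entirely not-ratable in the decoded condition
  dec <- orig
  dec@ratings[, 2] <- NA_integer_
  dec@condition <- "decoded"
  res2 <- intraraterAgreement(orig, dec)
  expect_identical(res2$excludedRaters, raterIds(orig)[2])
  expect_equal(kappaValue(res2$perRater[[raterIds(orig)[1]]]), 1)

  bad <- new("RatingTable", ratings = dec@ratings,
             videoIds = rev(videoIds(dec)), raterIds = raterIds(dec),
             condition = "decoded")
  expect_error(intraraterAgreement(orig, bad), "not aligned")
})

test_that("pooled intra-rater kappa decreases as decoded-condition noise grows", {
  set.seed(23)
  g <- sample(0:4, 60, replace = TRUE)
  clean <- lapply(1:3, function(j) raterModel(seed = 100 + j))
  orig <- simulateRatings(g, clean)
  pooled_k <- sapply(c(0.2, 0.8, 2.0), function(sd) {
    ks <- sapply(1:30, function(rep) {
      noisy <- lapply(1:3, function(j)
        raterModel(miscodeSd = sd, seed = 1000 * rep + j))
      dec <- simulateRatings(g, noisy, condition = "decoded")
      kappaValue(intraraterAgreement(orig, dec)$pooled)
    })
    mean(ks)
  })
  expect_true(all(diff(pooled_k) < 0))
})

test_that("inter-rater agreement aggregates pairwise kappas", {
  set.seed(24)
  g <- sample(0:4, 50, replace = TRUE)
  raters2 <- lapply(1:2, function(j) raterModel(miscodeSd = 0.6, seed = j))
  tab2 <- simulateRatings(g, raters2)
  res2 <- interraterAgreement(tab2)
  expect_equal(res2$meanKappa,
               kappaValue(weightedKappa(ratings(tab2)[, 1],
                                        ratings(tab2)[, 2])),
               tolerance = 1e-12)

  # identical raters: mean kappa 1
  same <- simulateRatings(g, lapply(1:3, function(j) raterModel(seed = 5)))
  expect_equal(interraterAgreement(same)$meanKappa, 1)

  # more rater noise -> lower mean pairwise kappa
  mk <- sapply(c(0.2, 1.5), function(sd) {
    mean(sapply(1:20, function(rep) {
      rr <- lapply(1:3, function(j)
        raterModel(miscodeSd = sd, seed = 500 * rep + j))
      interraterAgreement(simulateRatings(g, rr))$meanKappa
    }))
  })
  expect_gt(mk[1], mk[2])
  expect_error(interraterAgreement(simulateRatings(g, list(raterModel()))),
               "2 raters")
})

test_that("mean rating difference follows its hand-computed cases", {
  expect_equal(meanRatingDifference(c(2, 3, 1), c(2, 3, 1)), 0)
  expect_equal(meanRatingDifference(c(3, 4, 2), c(2, 3, 1)), 1)
  # NR pair excluded: (2-1, 3-3, 1-1) over 3 usable pairs
  expect_equal(meanRatingDifference(c(2, 3, NA, 1), c(1, 3, 2, 1)), 1 / 3)
  expect_error(meanRatingDifference(c(NA, NA), c(1, 2)), "no pairs")
})

test_that("ratable proportion and kappa bands reproduce the printed reference values", {
  m <- matrix(2L, 20, 10)
  m[sample(length(m), 28)] <- NA_integer_ # 172 of 200 ratable
  tab <- new("RatingTable", ratings = m,
             videoIds = sprintf("V%02d", 1:20),
             raterIds = sprintf("R%02d", 1:10), condition = "decoded")
  expect_equal(ratableProportion(tab), 0.86)

  expect_identical(interpretKappa(0.317), "fair")
  expect_identical(interpretKappa(0.459), "moderate")
  expect_identical(interpretKappa(0.302), "fair")
  expect_identical(interpretKappa(-0.1), "chance-or-worse")
  expect_identical(interpretKappa(0.2), "slight")
  expect_identical(interpretKappa(0.61), "substantial")
  expect_identical(interpretKappa(0.95), "almost perfect")
})
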