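test_that("generators are deterministic given a seed", {
  s1 <- simulate_pairs(50, 50, a2 = .3, c2 = .1, seed = 61)
  s2 <- simulate_pairs(50, 50, a2 = .3, c2 = .1, seed = 61)
  expect_identical(s1, s2)
  s3 <- simulate_pairs(50, 50, a2 = .3, c2 = .1, seed = 62)
  expect_false(identical(s1$Y, s3$Y))
  c1 <- simulate_cohort(cohort_config(seed = 63))
  c2_ <- simulate_cohort(cohort_config(seed = 63))
  expect_identical(c1$roster, c2_$roster)
  expect_identical(c1$items, c2_$items)
  expect_identical(c1$peg, c2_$peg)
})

test_that("degenerate component limits behave as the model implies", {
  s <- simulate_pairs(500, 500, a2 = .999, c2 = 0, seed = 64)
  mz <- s$zygosity == "MZ"
  expect_gt(cor(s$Y[mz, 1], s$Y[mz, 2]), .98)
  expect_lt(abs(cor(s$Y[!mz, 1], s$Y[!mz, 2]) - .5), .12)
  s <- simulate_pairs(500, 500, a2 = 0, c2 = 0, seed = 65)
  mz <- s$zygosity == "MZ"
  expect_lt(abs(cor(s$Y[mz, 1], s$Y[mz, 2])), .12)
  expect_error(simulate_pairs(10, 10, a2 = .8, c2 = .3), "invalid components")
})

test_that("empirical twin correlations converge to the implied values", {
  s <- simulate_pairs(10000, 10000, a2 = .25, c2 = .10, seed = 66)
  mz <- s$zygosity == "MZ"
  se <- 1 / sqrt(10000)
  expect_lt(abs(cor(s$Y[mz, 1], s$Y[mz, 2]) - .35), 3 * se)
  expect_lt(abs(cor(s$Y[!mz, 1], s$Y[!mz, 2]) - .225), 3 * se)
})

test_that("binary generator hits its prevalence and concordance structure", {
  b <- simulate_binary(5000, 5000, a2 = .266, c2 = 0, prevalence = .08,
                       seed = 67)
  expect_lt(abs(mean(b$Y) - .08), .01)
  mz <- b$zygosity == "MZ"
  conc <- function(Y) mean(Y[, 1] == Y[, 2])
  expect_gt(conc(b$Y[mz, ]), conc(b$Y[!mz, ]))
  # independence limit: concordance cells match marginal products
  b0 <- simulate_binary(5000, 5000, a2 = 0, c2 = 0, prevalence = .3, seed = 68)
  p11 <- mean(b0$Y[, 1] == 1 & b0$Y[, 2] == 1)
  expect_lt(abs(p11 - .09), .015)
  # near-perfect liability correlation: near-perfect concordance
  b1 <- simulate_binary(2000, 0, a2 = .999, c2 = 0, prevalence = .5, seed = 69)
  expect_gt(conc(b1$Y), .97)
})

test_that("item generator produces the J-shaped composite it is built for", {
  set.seed(70)
  L <- handtwin:::.EHI_LIABILITY_MEAN + rnorm(5000)
  sc <- score_cohort(simulate_ehi_items(L, seed = 71))
  # non-right-handedness rate near the 8% design target
  expect_lt(abs(mean(sc$EHI <= 0) - .08), .02)
  # J-shape: strong right-handers dominate, the middle is sparse
  expect_gt(mean(sc$EHI >= 0.6), .45)
  expect_lt(mean(sc$EHI > 0 & sc$EHI < 0.3), .15)
  # noise-free limit: all items agree, EHI exactly +/-1
  sc0 <- score_cohort(simulate_ehi_items(c(3, 3, -3), noise_scale = 0, seed = 72))
  expect_true(all(abs(sc0$EHI) == 1))
  # attenuation: more item noise shrinks item-total correlations
  mkitr <- function(ns, seed) {
    it <- simulate_ehi_items(L[1:2000], item_model = default_item_model(),
                             noise_scale = ns, seed = seed)
    pts <- score_item(it$hand, it$degree)
    it$score <- pts$right_points - pts$left_points
    w <- stats::reshape(it[, c("subject_id", "item", "score")],
                        idvar = "subject_id", timevar = "item",
                        direction = "wide")
    mean(item_total_correlations(as.matrix(w[, -1])))
  }
  expect_gt(mkitr(1, 73), mkitr(3, 73))
  bad <- default_item_model(); bad$always[1] <- bad$np[1] - 0.1
  expect_error(simulate_ehi_items(L[1:5], item_model = bad), "non-monotone")
})

test_that("pegboard generator reproduces the configured laterality", {
  # zero trial noise: the scored index equals the configured truth exactly
  q <- c(.2, 0, -.1)
  pt <- simulate_peg_trials(q, trial_sd = 0, seed = 74)
  sc <- score_cohort(data.frame(subject_id = 1, item = "writing",
                                hand = "right", degree = "always"), pt)
  got <- sc$PegQ[match(1:3, sc$subject_id)]
  expect_equal(got, q, tolerance = 1e-12)
  # default noise, n = 5000: mean within .01 of the .095 target
  set.seed(75)
  qtrue <- .095 + .095 * rnorm(5000)
  pt <- simulate_peg_trials(qtrue, seed = 76)
  sc <- score_cohort(data.frame(subject_id = "x", item = "writing",
                                hand = "right", degree = "always"), pt)
  pq <- sc$PegQ[!is.na(sc$PegQ)]
  expect_lt(abs(mean(pq) - .095), .01)
  # symmetric configuration: distribution symmetric about 0
  set.seed(77)
  pt0 <- simulate_peg_trials(0.3 * rnorm(3000), seed = 78)
  sc0 <- score_cohort(data.frame(subject_id = "x", item = "writing",
                                 hand = "right", degree = "always"), pt0)
  pq0 <- sc0$PegQ[!is.na(sc0$PegQ)]
  skew <- mean((pq0 - mean(pq0))^3) / sd(pq0)^3
  expect_lt(abs(skew), 0.15)
  expect_error(simulate_peg_trials(1.9, base_time = 1, trial_sd = 2, seed = 79),
               "non-positive")
})

test_that("cohort generator emulates the study's shape and sex structure", {
  coh <- simulate_cohort(cohort_config(seed = 80))
  ro <- coh$roster
  expect_equal(sum(ro$cohort == "twin"), 410)
  expect_equal(sum(ro$cohort == "singleton"), 426)
  expect_equal(length(unique(ro$pair_id[ro$cohort == "twin"])), 205)
  expect_equal(sum(ro$zygosity == "MZ", na.rm = TRUE), 182)
  # MZ pairs are same-sex
  for (pid in unique(ro$pair_id[which(ro$zygosity == "MZ")]))
    expect_equal(length(unique(ro$sex[which(ro$pair_id == pid)])), 1)
  # sex effect: with a large cohort, male NRH rate exceeds female
  big <- cohort_config(n_mz_mm = 0, n_mz_ff = 0, n_dz_mm = 0, n_dz_ff = 0,
                       n_dz_os = 0, n_single_m = 4000, n_single_f = 4000,
                       seed = 81)
  cb <- simulate_cohort(big)
  sc <- score_cohort(cb$items)
  sex <- setNames(cb$roster$sex, cb$roster$subject_id)[sc$subject_id]
  nrh <- sc$EHI2 == 0
  expect_gt(mean(nrh[sex == "male"]), mean(nrh[sex == "female"]))
  # no sex effect requested: shift is exactly zero
  expect_equal(handtwin:::.sex_shift(.08, 1), 0)
})
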