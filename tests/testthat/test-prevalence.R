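test_that("Pearson chi-square has its structural invariances", {
  tab <- rbind(c(13, 14), c(4, 2), c(170, 183))
  res <- chisq_contingency(tab)
  expect_equal(res$df, 2)
  # permutation / transpose invariance
  expect_equal(chisq_contingency(tab[c(3, 1, 2), ])$statistic, res$statistic)
  expect_equal(chisq_contingency(t(tab))$statistic, res$statistic)
  # scaling all counts by k multiplies the statistic by exactly k
  expect_equal(chisq_contingency(5 * tab)$statistic, 5 * res$statistic)
  # proportional rows = perfect independence
  expect_equal(chisq_contingency(rbind(c(10, 20), c(30, 60)))$statistic, 0)
  expect_error(chisq_contingency(rbind(c(0, 0), c(1, 2))), "all-zero")
  expect_error(chisq_contingency(rbind(c(-1, 2), c(1, 2))), "negative")
})

test_that("collapsing rows then testing equals testing the merged table", {
  tab <- rbind(LH = c(13, 14), NP = c(4, 2), RH = c(170, 183))
  merged <- rbind(NRH = tab[1, ] + tab[2, ], RH = tab[3, ])
  expect_equal(chisq_contingency(merged)$statistic,
               chisq_contingency(rbind(c(17, 16), c(170, 183)))$statistic)
})

test_that("Bonferroni adjustment divides the level by the comparison count", {
  expect_equal(bonferroni_alpha(0.05, 10), 0.005)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.01, 4), 0.0025)
  expect_error(bonferroni_alpha(0.05, 0))
})

test_that("item-total correlations match a closed-form Pearson oracle", {
  set.seed(21)
  n <- 200
  latent <- rnorm(n)
  m <- sapply(c(0.9, 0.6, 0.3), function(l) l * latent + sqrt(1 - l^2) * rnorm(n))
  colnames(m) <- c("i1", "i2", "i3")
  r <- item_total_correlations(m)
  tot <- rowSums(m)
  for (j in 1:3) {
    oracle <- sum((m[, j] - mean(m[, j])) * (tot - mean(tot))) /
      sqrt(sum((m[, j] - mean(m[, j]))^2) * sum((tot - mean(tot))^2))
    expect_equal(unname(r[j]), oracle, tolerance = 1e-12)
  }
  # corrected variant removes the item from the total
  rc <- item_total_correlations(m, corrected = TRUE)
  expect_equal(unname(rc[1]), cor(m[, 1], m[, 2] + m[, 3]), tolerance = 1e-12)
  # a single-item total correlates 1 with itself
  expect_equal(unname(item_total_correlations(m[, 1, drop = FALSE])[1]), 1)
  m0 <- cbind(m, i4 = rep(2, n))
  expect_warning(r0 <- item_total_correlations(m0), "zero-variance")
  expect_true(is.na(r0["i4"]))
})

test_that("Cronbach's alpha follows the Spearman-Brown closed form", {
  set.seed(22)
  # two identical items
  x <- rnorm(50)
  expect_equal(cronbach_alpha(cbind(x, x)), 1)
  # k parallel items with inter-item correlation rho
  k <- 5; rho <- 0.4; n <- 4000
  latent <- rnorm(n)
  m <- sapply(seq_len(k), function(i) sqrt(rho) * latent + sqrt(1 - rho) * rnorm(n))
  expect_lt(abs(cronbach_alpha(m) - k * rho / (1 + (k - 1) * rho)), 0.04)
  # independent items: alpha near 0
  expect_lt(abs(cronbach_alpha(matrix(rnorm(n * 4), n))), 0.08)
})

test_that("two-way ANOVA agrees with the linear-model projection oracle", {
  set.seed(23)
  # balanced design: all SS types coincide and match explicit projections
  d <- expand.grid(sample = c("twin", "singleton"), sex = c("male", "female"),
                   rep = 1:30)
  d$y <- rnorm(nrow(d)) + 0.5 * (d$sample == "twin")
  f3 <- anova_sample_sex(d$y, d$sample, d$sex, ss_type = "III")
  f2 <- anova_sample_sex(d$y, d$sample, d$sex, ss_type = "II")
  f1 <- anova_sample_sex(d$y, d$sample, d$sex, ss_type = "I")
  expect_equal(f3$F, f2$F, tolerance = 1e-10)
  expect_equal(f3$F, f1$F, tolerance = 1e-10)
  oracle <- anova(lm(y ~ sample * sex, data = d))  # balanced: Type I = all
  expect_equal(f3$F, oracle$`F value`[1:3], tolerance = 1e-10)
  expect_equal(f3$df2, rep(116, 3))
  expect_error(anova_sample_sex(d$y[1:60], d$sample[1:60],
                                rep("male", 60)), "fewer than 2|contrasts")
})

test_that("correlation matrix is pairwise-complete Pearson with flags", {
  set.seed(24)
  n <- 800; rho <- 0.42
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  m <- data.frame(x = x, y = y, negx = -x)
  cm <- correlation_matrix(m)
  expect_equal(diag(cm$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cm$r["x", "negx"], -1)
  se <- (1 - rho^2) / sqrt(n)
  expect_lt(abs(cm$r["x", "y"] - rho), 3 * se)
  expect_equal(cm$flag["x", "y"], "**")
  # missingness: pairwise n bookkeeping
  m$y[1:100] <- NA
  cm2 <- correlation_matrix(m)
  expect_equal(cm2$n["x", "y"], 700)
  expect_equal(cm2$n["x", "negx"], 800)
})

test_that("prevalence tables reproduce their own counts and tests", {
  set.seed(25)
  coh <- simulate_cohort(cohort_config(seed = 77))
  sc <- score_cohort(coh$items, coh$peg)
  grp <- setNames(coh$roster$cohort, coh$roster$subject_id)
  it <- item_preference_tests(coh$items, grp)
  expect_equal(nrow(it), 10)
  expect_true(all(it$df == 2, na.rm = TRUE))
  # counts in the writing row equal a direct tabulation
  w <- coh$items[coh$items$item == "writing", ]
  direct <- table(factor(recode_item_three_class(w$hand), c("LH", "NP", "RH")),
                  factor(grp[w$subject_id]))
  expect_equal(it$LH_singleton[1] + it$NP_singleton[1] + it$RH_singleton[1],
               sum(direct[, "singleton"]))
  dp <- direction_prevalence_tests(sc, grp)
  expect_equal(dp$indicator, c("writing_bin", "drawing_bin", "EHI2", "PegQ2"))
  expect_true(all(dp$df == 1))
  # chi-square recomputed from the emitted counts matches the emitted statistic
  tab <- rbind(c(dp$NRH_singleton[1], dp$NRH_twin[1]),
               c(dp$RH_singleton[1], dp$RH_twin[1]))
  expect_equal(chisq_contingency(tab)$statistic, dp$chisq[1])
})
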