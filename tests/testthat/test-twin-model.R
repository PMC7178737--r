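test_that("expected pair covariance composes the A/C/E blocks correctly", {
  S <- expected_pair_covariance(sqrt(.25), 0, sqrt(.75), "MZ")
  expect_equal(S, matrix(c(1, .25, .25, 1), 2))
  S <- expected_pair_covariance(sqrt(.25), 0, sqrt(.75), "DZ")
  expect_equal(S[1, 2], .125)
  expect_error(expected_pair_covariance(1, 0, 1, "XX"), "zygosity")
  # bivariate: with a21 = 0 the cross-twin cross-trait covariance comes
  # from C alone
  A <- matrix(c(.5, 0, 0, .4), 2); C <- matrix(c(.3, .2, 0, .3), 2)
  E <- matrix(c(.6, .1, 0, .5), 2)
  S <- expected_pair_covariance(A, C, E, "DZ")
  expect_equal(S[1, 4], (tcrossprod(C))[1, 2])       # A contributes 0 there
  expect_equal(S, t(S))
})

test_that("continuous FIML equals closed forms and the density-sum oracle", {
  # single complete pair, identity covariance, zero mean, data (0,0)
  v <- neg2ll_continuous(matrix(c(0, 0), 1), "MZ", 0, 0, 1, 0)
  expect_equal(v, 2 * log(2 * pi))
  # one missing twin: contribution is the univariate normal -2 logL
  y <- matrix(c(1.3, NA), 1)
  v <- neg2ll_continuous(y, "DZ", sqrt(.3), 0, sqrt(.7), 0.2)
  expect_equal(v, -2 * dnorm(1.3, 0.2, 1, log = TRUE))
  # 50 simulated pairs vs brute-force per-pair density summation
  s <- simulate_pairs(30, 20, a2 = .3, c2 = .1, seed = 31)
  s$Y[1, 2] <- NA; s$Y[40, 1] <- NA
  A <- sqrt(.3); C <- sqrt(.1); E <- sqrt(.6)
  v <- neg2ll_continuous(s$Y, s$zygosity, A, C, E, 0.1)
  expect_equal(v, neg2ll_oracle(s$Y, s$zygosity, A, C, E, 0.1),
               tolerance = 1e-10)
})

test_that("binary liability likelihood matches independence and symmetry limits", {
  set.seed(32)
  b <- simulate_binary(40, 40, a2 = .3, c2 = 0, prevalence = .2, seed = 33)
  # a2 = c2 = 0: cell probabilities are products of the marginals; the
  # -2LL equals the independent Bernoulli -2LL
  tau <- qnorm(.8)
  v <- neg2ll_binary_liability(b$Y, b$zygosity, 0, 0, tau)
  n1 <- sum(b$Y == 1); n0 <- sum(b$Y == 0)
  expect_equal(v, -2 * (n1 * log(.2) + n0 * log(.8)), tolerance = 1e-6)
  # orthant quadrature oracle at tau = qnorm(.92), r = .5
  tau <- qnorm(.92)
  expect_equal(handtwin:::.orthant_upper(tau, .5),
               orthant_quadrature(tau, .5), tolerance = 1e-6)
  # tau = 0, r = 0: all four concordance cells are 1/4
  expect_equal(handtwin:::.orthant_upper(0, 0), 0.25, tolerance = 1e-10)
})

test_that("univariate fits recover generating components", {
  # E-only truth: fitted ACE components collapse toward e2 = 1
  s <- simulate_pairs(400, 400, a2 = 0, c2 = 0, seed = 41)
  set.seed(41)
  f <- fit_ace(s$Y, s$zygosity, "ACE")
  expect_lt(f$std[["a2"]] + f$std[["c2"]], 0.08)
  expect_equal(sum(f$std), 1, tolerance = 1e-8)
  # large-n recovery of a2 = .25, c2 = .10
  s <- simulate_pairs(4000, 4000, a2 = .25, c2 = .10, seed = 42)
  set.seed(42)
  f <- fit_ace(s$Y, s$zygosity, "ACE")
  expect_lt(abs(f$std[["a2"]] - .25), .06)
  expect_lt(abs(f$std[["c2"]] - .10), .06)
  expect_true(f$convergence)
  # optimizer -2LL matches the density-sum oracle at the optimum
  est <- f$estimates
  expect_equal(f$minus2LL,
               neg2ll_oracle(s$Y, s$zygosity, est[["a"]], est[["c"]],
                             est[["e"]], est[["mu"]]),
               tolerance = 1e-6)
})

test_that("binary liability fit recovers components and the threshold", {
  b <- simulate_binary(3000, 3000, a2 = .3, c2 = 0, prevalence = .1, seed = 43)
  set.seed(43)
  f <- fit_ace_binary(b$Y, b$zygosity, "AE")
  expect_lt(abs(f$std[["a2"]] - .3), .08)
  expect_lt(abs(f$estimates[["prevalence"]] - .1), .02)
  expect_equal(sum(f$std), 1, tolerance = 1e-8)
})

test_that("df bookkeeping counts observations minus free parameters", {
  # 96 MZ + 96 DZ complete pairs = 384 observed values; ACE has 4 free
  # parameters (mu, a, c, e) so df = 380
  s <- simulate_pairs(96, 96, a2 = .2, c2 = 0, seed = 44)
  set.seed(44)
  f <- fit_ace(s$Y, s$zygosity, "ACE", restarts = 2)
  expect_equal(f$n_obs, 384)
  expect_equal(f$df, 380)
  expect_equal(f$AIC, f$minus2LL - 2 * 380)
  # AE drops one parameter
  f2 <- fit_ace(s$Y, s$zygosity, "AE", restarts = 2)
  expect_equal(f2$df, 381)
})

test_that("likelihood-ratio tests and nesting hold across the ladder", {
  s <- simulate_pairs(300, 300, a2 = .3, c2 = .05, seed = 45)
  set.seed(45)
  lad <- univariate_ladder(s$Y, s$zygosity, "continuous", restarts = 3)
  tab <- lad$table
  # every constrained fit is at least as bad as ACE
  expect_true(all(tab$minus2LL >= tab$minus2LL[tab$model == "ACE"] - 1e-6))
  # identical fits: p = 1
  same <- lrt(lad$fits$ACE, lad$fits$ACE)
  expect_equal(same$delta_LL, 0); expect_equal(same$p_value, 1)
  expect_error(lrt(lad$fits$AE, lad$fits$ACE), "more free parameters")
  # AIC column is consistent with the -2LL and df columns
  expect_equal(tab$AIC, tab$minus2LL - 2 * tab$df)
})

test_that("homogeneity ladder keeps nesting and detects an order effect", {
  s <- simulate_pairs(250, 250, a2 = .2, c2 = 0, seed = 46)
  set.seed(46)
  sex1 <- sample(c("male", "female"), 500, replace = TRUE)
  sex2 <- ifelse(s$zygosity == "MZ", sex1,
                 sample(c("male", "female"), 500, replace = TRUE))
  lad <- homogeneity_ladder(s$Y, s$zygosity, sex1, sex2)
  expect_true(all(diff(lad$minus2LL) >= -1e-4))   # equated >= saturated
  expect_true(all(diff(lad$k) < 0))
  # inject a twin-order mean shift: the order-equating step must reject
  Y2 <- s$Y; Y2[, 2] <- Y2[, 2] + 0.6
  lad2 <- homogeneity_ladder(Y2, s$zygosity, sex1, sex2)
  expect_lt(lad2$p[lad2$step == "equal_order"], 1e-4)
})
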