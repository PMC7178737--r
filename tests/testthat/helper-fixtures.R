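# shared fixture builders (everything generated in code; no stored data)

# one subject's response frame
resp <- function(items, hand, degree = NA_character_) {
  data.frame(item = items, hand = rep_len(hand, length(items)),
             degree = rep_len(degree, length(items)), stringsAsFactors = FALSE)
}

# all 10 items answered identically
resp_all <- function(hand, degree = NA_character_) resp(ehi_items(), hand, degree)

# swap left/right in a response frame (degree preserved)
swap_hands <- function(r) {
  r$hand <- c(left = "right", right = "left", either = "either")[r$hand]
  r
}

# brute-force -2LL oracle: per-pair multivariate-normal density summation
neg2ll_oracle <- function(Y, zygosity, A, C, E, means) {
  mu <- rep(means, 2)
  tot <- 0
  for (i in seq_len(nrow(Y))) {
    obs <- which(!is.na(Y[i, ]))
    Sig <- expected_pair_covariance(A, C, E, zygosity[i])[obs, obs, drop = FALSE]
    tot <- tot - 2 * mvtnorm::dmvnorm(Y[i, obs], mu[obs], Sig, log = TRUE)
  }
  tot
}

# quadrature oracle for the upper orthant P(L1 > tau, L2 > tau | r)
orthant_quadrature <- function(tau, r) {
  f <- function(x, y) {
    z <- (x^2 - 2 * r * x * y + y^2) / (1 - r^2)
    exp(-z / 2) / (2 * pi * sqrt(1 - r^2))
  }
  pracma::integral2(f, tau, 8, tau, 8, reltol = 1e-10)$Q
}
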