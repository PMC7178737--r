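# Bivariate Cholesky decomposition of two traits measured on twin pairs,
# the nested-model ladder, and the correlated-factors reparameterisation.
#
# Observed vector per pair: (twin1 trait1, twin1 trait2, twin2 trait1,
# twin2 trait2). Path matrices are lower-triangular 2x2:
#   X = | x11  0  |      (X in {A, C, E}; the cross path x21 is the one
#       | x21 x22 |       the path diagram labels x_12)

# free-parameter layout per ladder model: which paths of A, C, E are free
.bv_models <- list(
  ACE = list(A = c(TRUE, TRUE, TRUE), C = c(TRUE, TRUE, TRUE), E = c(TRUE, TRUE, TRUE)),
  AE  = list(A = c(TRUE, TRUE, TRUE), C = c(FALSE, FALSE, FALSE), E = c(TRUE, TRUE, TRUE)),
  AE1 = list(A = c(TRUE, FALSE, TRUE), C = c(FALSE, FALSE, FALSE), E = c(TRUE, TRUE, TRUE)),
  AE2 = list(A = c(TRUE, TRUE, FALSE), C = c(FALSE, FALSE, FALSE), E = c(TRUE, TRUE, TRUE)),
  CE  = list(A = c(FALSE, FALSE, FALSE), C = c(TRUE, TRUE, TRUE), E = c(TRUE, TRUE, TRUE)),
  E   = list(A = c(FALSE, FALSE, FALSE), C = c(FALSE, FALSE, FALSE), E = c(TRUE, TRUE, TRUE))
)

.lower2 <- function(x11, x21, x22) matrix(c(x11, x21, 0, x22), 2, 2)

# moment-based starting paths from cross-twin / within-twin covariances
.bv_start <- function(Y, zygosity) {
  W <- B <- list()
  for (z in c("MZ", "DZ")) {
    yy <- Y[zygosity == z, , drop = FALSE]
    yy <- yy[stats::complete.cases(yy), , drop = FALSE]
    # double-entered covariance: within block and cross block
    dd <- rbind(yy, yy[, c(3, 4, 1, 2)])
    V <- stats::var(dd)
    W[[z]] <- V[1:2, 1:2]; B[[z]] <- (V[1:2, 3:4] + t(V[1:2, 3:4])) / 2
  }
  Wm <- (W$MZ + W$DZ) / 2
  Ah <- 2 * (B$MZ - B$DZ)
  Ch <- 2 * B$DZ - B$MZ
  Eh <- Wm - B$MZ
  tochol <- function(M, floor = 0.05) {
    M <- (M + t(M)) / 2
    ev <- eigen(M, symmetric = TRUE)
    ev$values <- pmax(ev$values, floor * mean(diag(Wm)))
    t(chol(ev$vectors %*% diag(ev$values) %*% t(ev$vectors)))
  }
  list(mu = colMeans(Y[, 1:2, drop = FALSE], na.rm = TRUE),
       A = tochol(Ah), C = tochol(Ch), E = tochol(Eh))
}

#' Fit a bivariate Cholesky ACE-family model
#'
#' FIML fit of two traits per twin under the Cholesky path parameterisation.
#' Models: "ACE" (11 free parameters: 2 means + 9 paths), "AE" (8), "AE1"
#' (AE with the genetic cross path fixed to 0: independent genetic factors;
#' 7), "AE2" (AE with the trait-2-specific genetic path fixed to 0: a single
#' shared genetic factor; 7), "CE" (8), "E" (5).
#'
#' @param Y matrix n x 4: (twin1 trait1, twin1 trait2, twin2 trait1,
#'   twin2 trait2); NA = missing.
#' @param zygosity "MZ"/"DZ" per pair.
#' @param model ladder model name.
#' @param restarts jittered optimizer restarts (first start is moment-based).
#' @param init optional warm start: a list with `A`, `C`, `E` (2x2 lower
#'   triangular) and `mu` (length 2), e.g. the paths of a previously fitted
#'   neighbouring model; used as an additional starting point.
#' @return object of class `cholesky_fit`: `paths` (list of 2x2 lower
#'   triangular A, C, E), `means`, `std` (per-trait standardized components),
#'   `minus2LL`, `n_obs`, `k`, `df`, `AIC`, `convergence`.
#' @export
fit_bivariate <- function(Y, zygosity, model = names(.bv_models), restarts = 5,
                          init = NULL) {
  model <- match.arg(model)
  Y <- as.matrix(Y)
  stopifnot(ncol(Y) == 4)
  zygosity <- as.character(zygosity)
  st <- .fiml_stats(Y, zygosity)
  n_obs <- attr(st, "n_obs")
  mask <- .bv_models[[model]]
  s0 <- .bv_start(Y, zygosity)
  pack <- function(A, C, E, mu) {
    c(mu,
      c(A[1, 1], A[2, 1], A[2, 2])[mask$A],
      c(C[1, 1], C[2, 1], C[2, 2])[mask$C],
      c(E[1, 1], E[2, 1], E[2, 2])[mask$E])
  }
  unpack <- function(par) {
    mu <- par[1:2]; i <- 2
    take <- function(m) {
      v <- c(0, 0, 0)
      v[m] <- par[i + seq_len(sum(m))]
      i <<- i + sum(m)
      .lower2(v[1], v[2], v[3])
    }
    A <- take(mask$A); C <- take(mask$C); E <- take(mask$E)
    list(mu = mu, A = A, C = C, E = E)
  }
  obj <- function(par) {
    p <- unpack(par)
    Sig <- list(MZ = expected_pair_covariance(p$A, p$C, p$E, "MZ"),
                DZ = expected_pair_covariance(p$A, p$C, p$E, "DZ"))
    mu4 <- rep(p$mu, 2)
    .fiml_neg2ll(st, Sig, list(MZ = mu4, DZ = mu4))
  }
  par0 <- pack(s0$A, s0$C, s0$E, s0$mu)
  starts <- list(par0)
  if (!is.null(init)) starts <- c(list(pack(init$A, init$C, init$E, init$mu)),
                                  starts)
  for (r in seq_len(max(0, restarts - length(starts))))
    starts <- c(starts, list(par0 * (1 + stats::rnorm(length(par0), 0, 0.3))))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(stats::optim(p0, obj, method = "BFGS",
                                 control = list(maxit = 1000, reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("all optimizer restarts failed")
  p <- unpack(best$par)
  # sign convention: diagonal paths non-negative (likelihood-invariant flips)
  fixsign <- function(M) {
    for (j in 1:2) if (M[j, j] < 0) M[, j] <- -M[, j]
    M
  }
  p$A <- fixsign(p$A); p$C <- fixsign(p$C); p$E <- fixsign(p$E)
  W <- tcrossprod(p$A) + tcrossprod(p$C) + tcrossprod(p$E)
  std <- rbind(a2 = diag(tcrossprod(p$A)) / diag(W),
               c2 = diag(tcrossprod(p$C)) / diag(W),
               e2 = diag(tcrossprod(p$E)) / diag(W))
  colnames(std) <- c("trait1", "trait2")
  k <- length(best$par)
  out <- list(model = model, paths = p[c("A", "C", "E")], means = p$mu,
              std = std, minus2LL = best$value, n_obs = n_obs, k = k,
              df = n_obs - k, AIC = aic_neg2ll(best$value, n_obs - k),
              convergence = best$convergence == 0)
  class(out) <- "cholesky_fit"
  out
}

#' @export
print.cholesky_fit <- function(x, ...) {
  cat(sprintf("Bivariate Cholesky %s model\n", x$model))
  cat(sprintf("  -2LL = %.2f  df = %d  AIC = %.2f  converged: %s\n",
              x$minus2LL, x$df, x$AIC, x$convergence))
  print(round(x$std, 3))
  invisible(x)
}

#' Bivariate nested-model ladder with AIC selection
#'
#' Fits the full bivariate Cholesky ACE model and its nested submodels
#' (AE; AE1 = independent genetic factors; AE2 = single shared genetic
#' factor; CE; E), tests each against the full model by likelihood ratio,
#' and flags the minimum-AIC model.
#'
#' @inheritParams fit_bivariate
#' @return list with `fits` (named list), `table` (model, minus2LL, df, AIC,
#'   delta_LL, delta_df, p) and `best` (name of the minimum-AIC model).
#' @export
fit_bivariate_ladder <- function(Y, zygosity, restarts = 5) {
  models <- names(.bv_models)
  aswarm <- function(f) c(f$paths, list(mu = f$means))
  fits <- list()
  fits$ACE <- fit_bivariate(Y, zygosity, "ACE", restarts)
  fits$AE <- fit_bivariate(Y, zygosity, "AE", restarts, init = aswarm(fits$ACE))
  fits$AE1 <- fit_bivariate(Y, zygosity, "AE1", restarts, init = aswarm(fits$AE))
  fits$AE2 <- fit_bivariate(Y, zygosity, "AE2", restarts, init = aswarm(fits$AE))
  fits$CE <- fit_bivariate(Y, zygosity, "CE", restarts, init = aswarm(fits$ACE))
  fits$E <- fit_bivariate(Y, zygosity, "E", restarts, init = aswarm(fits$CE))
  # repair pass: a nested model must never beat a parent that contains it;
  # when it does, the parent stalled on a ridge -- refit it warm-started
  # from the nested solution
  parents <- list(AE = c("AE1", "AE2", "E"), ACE = c("AE", "CE", "AE1",
                                                     "AE2", "E"),
                  CE = "E")
  for (par_m in c("AE", "CE", "ACE")) {
    for (nst in parents[[par_m]]) {
      if (fits[[nst]]$minus2LL < fits[[par_m]]$minus2LL - 1e-8) {
        ref <- fit_bivariate(Y, zygosity, par_m, restarts = 1,
                             init = aswarm(fits[[nst]]))
        if (ref$minus2LL < fits[[par_m]]$minus2LL) fits[[par_m]] <- ref
      }
    }
  }
  tab <- do.call(rbind, lapply(models, function(m) {
    ft <- fits[[m]]
    cmp <- if (m == "ACE") list(delta_LL = NA, delta_df = NA, p_value = NA)
           else lrt(fits$ACE, ft)
    data.frame(model = m, minus2LL = ft$minus2LL, df = ft$df, AIC = ft$AIC,
               delta_LL = cmp$delta_LL, delta_df = cmp$delta_df,
               p = cmp$p_value)
  }))
  rownames(tab) <- NULL
  list(fits = fits, table = tab, best = tab$model[which.min(tab$AIC)])
}

#' Correlated-factors view of a bivariate Cholesky fit
#'
#' Reparameterises the fitted Cholesky paths as per-trait standardized
#' components plus factor correlations rA, rC, rE between the trait-specific
#' latent factors: rX = (XX')12 / sqrt((XX')11 (XX')22). A correlation is
#' undefined (NA) when either trait's component variance is zero. The
#' reconstruction identity (component covariance matrices are unchanged)
#' holds by construction.
#'
#' @param fit `cholesky_fit` object.
#' @return list with `std` (per-trait a2/c2/e2), `r` (named vector rA, rC,
#'   rE), and `component_cov` (list of the 2x2 component covariance
#'   matrices).
#' @export
to_correlated_factors <- function(fit) {
  stopifnot(inherits(fit, "cholesky_fit"))
  covs <- lapply(fit$paths, tcrossprod)
  r <- vapply(covs, function(V) {
    if (V[1, 1] <= 1e-12 || V[2, 2] <= 1e-12) return(NA_real_)
    V[1, 2] / sqrt(V[1, 1] * V[2, 2])
  }, numeric(1))
  names(r) <- paste0("r", names(covs))
  list(std = fit$std, r = r, component_cov = covs)
}
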