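# Classical twin-design variance decomposition by full-information maximum
# likelihood: univariate ACE/AE/CE/E for continuous and binary
# (liability-threshold) traits, homogeneity ladder, likelihood-ratio tests.
#
# Conventions (documented also in the package help):
#  * path (Cholesky) parameterisation -- implied component covariances are
#    PSD by construction; signs of paths are not identified, report squares;
#  * DZ additive-genetic correlation fixed at 0.5; no dominance component;
#  * df = (# non-missing trait observations) - (# free parameters);
#  * AIC = -2LL - 2*df (OpenMx-style; NOT -2LL + 2k).

# ---- FIML machinery ---------------------------------------------------------

# Group rows of Y (n x d, NA = missing) by `group` and missingness pattern;
# precompute per-cell sufficient statistics so the likelihood is O(#patterns)
# per evaluation rather than O(n).
.fiml_stats <- function(Y, group) {
  Y <- as.matrix(Y)
  group <- as.character(group)
  keep <- rowSums(!is.na(Y)) > 0
  Y <- Y[keep, , drop = FALSE]; group <- group[keep]
  pat <- apply(!is.na(Y), 1, function(b) paste(which(b), collapse = ","))
  cells <- split(seq_len(nrow(Y)), paste(group, pat, sep = "|"))
  stats <- lapply(cells, function(idx) {
    obs <- which(!is.na(Y[idx[1], ]))
    X <- Y[idx, obs, drop = FALSE]
    n <- nrow(X)
    ybar <- colMeans(X)
    Xc <- sweep(X, 2, ybar)
    list(group = group[idx[1]], obs = obs, n = n, ybar = ybar,
         S = crossprod(Xc))
  })
  attr(stats, "n_obs") <- sum(!is.na(Y))
  stats
}

# -2 log likelihood given per-group covariance matrices and mean vectors.
# Non-PD submatrix at the evaluation point returns +Inf (optimizer contract:
# penalised, never an error mid-search).
.fiml_neg2ll <- function(stats, Sigma_by_group, mu_by_group) {
  tot <- 0
  for (cell in stats) {
    S_full <- Sigma_by_group[[cell$group]]
    mu_full <- mu_by_group[[cell$group]]
    s <- cell$obs
    Sig <- S_full[s, s, drop = FALSE]
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    logdet <- 2 * sum(log(diag(ch)))
    Sinv <- chol2inv(ch)
    dmu <- cell$ybar - mu_full[s]
    quad <- sum(Sinv * cell$S) + cell$n * drop(t(dmu) %*% Sinv %*% dmu)
    tot <- tot + cell$n * (length(s) * log(2 * pi) + logdet) + quad
  }
  tot
}

# ---- expected covariance structure -----------------------------------------

#' Expected twin-pair covariance under ACE paths
#'
#' Builds the implied covariance matrix of a twin pair's observed vector from
#' lower-triangular path matrices: within-twin block AA' + CC' + EE';
#' cross-twin block k*AA' + CC' with k = 1 (MZ) or 0.5 (DZ).
#'
#' @param A,C,E path coefficients: scalars (univariate) or lower-triangular
#'   p x p matrices (p traits per twin).
#' @param zygosity "MZ" or "DZ".
#' @return symmetric 2p x 2p covariance matrix, twin-1 traits first.
#' @export
expected_pair_covariance <- function(A, C, E, zygosity) {
  if (!zygosity %in% c("MZ", "DZ")) stop("zygosity must be MZ or DZ")
  k <- if (zygosity == "MZ") 1 else 0.5
  A <- as.matrix(A); C <- as.matrix(C); E <- as.matrix(E)
  W <- tcrossprod(A) + tcrossprod(C) + tcrossprod(E)
  B <- k * tcrossprod(A) + tcrossprod(C)
  rbind(cbind(W, B), cbind(B, W))
}

#' FIML -2 log-likelihood of continuous twin-pair data
#'
#' Each pair contributes the multivariate-normal log density of its observed
#' (non-missing) sub-vector under the marginal of the implied mean and
#' covariance; pairs with a missing co-twin contribute the univariate
#' marginal.
#'
#' @param Y numeric matrix, one row per pair: twin-1 trait(s) then twin-2
#'   trait(s) (2 columns univariate, 4 bivariate). NA = missing.
#' @param zygosity character vector "MZ"/"DZ", one per pair.
#' @param A,C,E path matrices as in [expected_pair_covariance()].
#' @param means trait mean vector (length p), shared by both twins.
#' @return scalar -2 log likelihood (Inf if the implied covariance is not
#'   positive definite).
#' @export
neg2ll_continuous <- function(Y, zygosity, A, C, E, means) {
  p <- nrow(as.matrix(A))
  mu <- rep(means, 2)
  st <- .fiml_stats(Y, zygosity)
  Sig <- list(MZ = expected_pair_covariance(A, C, E, "MZ"),
              DZ = expected_pair_covariance(A, C, E, "DZ"))
  .fiml_neg2ll(st, Sig, list(MZ = mu, DZ = mu))
}

# ---- univariate continuous fits --------------------------------------------

.uv_free <- list(ACE = c("a", "c"), AE = "a", CE = "c", E = character(0))

# moment-based starting values (Falconer-style decomposition)
.uv_start <- function(Y, zygosity) {
  v <- stats::var(as.vector(Y), na.rm = TRUE)
  rz <- function(z) {
    yy <- Y[zygosity == z, , drop = FALSE]
    yy <- yy[stats::complete.cases(yy), , drop = FALSE]
    if (nrow(yy) < 3) return(0)
    # symmetrised intraclass-style correlation (double entry)
    stats::cor(c(yy[, 1], yy[, 2]), c(yy[, 2], yy[, 1]))
  }
  rmz <- rz("MZ"); rdz <- rz("DZ")
  a2 <- min(max(2 * (rmz - rdz), 0.01), 0.9)
  c2 <- min(max(2 * rdz - rmz, 0.01), 0.9 - a2 + 0.05)
  e2 <- max(1 - a2 - c2, 0.05)
  list(mu = mean(Y, na.rm = TRUE), a = sqrt(a2 * v), c = sqrt(c2 * v),
       e = sqrt(e2 * v))
}

#' Fit a univariate ACE-family model to continuous twin data
#'
#' Maximises the FIML likelihood over the free paths (omitted components'
#' paths fixed at zero) with a quasi-Newton optimizer and multiple restarts
#' jittered from moment-based starting values.
#'
#' @param Y matrix n x 2 of trait values (twin 1, twin 2), NA allowed.
#' @param zygosity "MZ"/"DZ" per pair.
#' @param model one of "ACE", "AE", "CE", "E".
#' @param restarts number of jittered restarts (>= 1; first start is the
#'   moment estimate). Jitter uses the current RNG stream.
#' @return object of class `ace_fit`: estimates, standardized components,
#'   `minus2LL`, `n_obs`, `k`, `df`, `AIC`, `convergence`.
#' @export
fit_ace <- function(Y, zygosity, model = c("ACE", "AE", "CE", "E"),
                    restarts = 5, init = NULL) {
  model <- match.arg(model)
  Y <- as.matrix(Y)
  zygosity <- as.character(zygosity)
  if (sum(zygosity == "MZ") < 2 || sum(zygosity == "DZ") < 2)
    stop("need at least 2 MZ and 2 DZ pairs")
  st <- .fiml_stats(Y, zygosity)
  n_obs <- attr(st, "n_obs")
  free <- .uv_free[[model]]
  s0 <- .uv_start(Y, zygosity)
  par0 <- c(mu = s0$mu, unlist(s0[free]), e = s0$e)
  obj <- function(par) {
    a <- if ("a" %in% free) par[["a"]] else 0
    c_ <- if ("c" %in% free) par[["c"]] else 0
    Sig <- list(MZ = expected_pair_covariance(a, c_, par[["e"]], "MZ"),
                DZ = expected_pair_covariance(a, c_, par[["e"]], "DZ"))
    mu2 <- rep(par[["mu"]], 2)
    .fiml_neg2ll(st, Sig, list(MZ = mu2, DZ = mu2))
  }
  starts <- list(par0)
  if (!is.null(init)) {
    pi0 <- par0
    for (nm in names(par0)) if (nm %in% names(init)) pi0[nm] <- init[[nm]]
    starts <- c(list(pi0), starts)
  }
  for (r in seq_len(max(0, restarts - length(starts))))
    starts <- c(starts, list(par0 * (1 + stats::rnorm(length(par0), 0, 0.3))))
  best <- NULL
  for (p0 in starts) {
    if (abs(p0[["e"]]) < 1e-4) p0[["e"]] <- 0.1 * sqrt(stats::var(as.vector(Y), na.rm = TRUE))
    fit <- tryCatch(stats::optim(p0, obj, method = "BFGS",
                                 control = list(maxit = 500, reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("all optimizer restarts failed")
  par <- best$par
  a <- if ("a" %in% free) abs(par[["a"]]) else 0
  c_ <- if ("c" %in% free) abs(par[["c"]]) else 0
  e <- abs(par[["e"]])
  v <- a^2 + c_^2 + e^2
  k <- length(par)
  fit <- list(model = model, trait_kind = "continuous",
              estimates = c(mu = unname(par[["mu"]]), a = a, c = c_, e = e),
              std = c(a2 = a^2 / v, c2 = c_^2 / v, e2 = e^2 / v),
              minus2LL = best$value, n_obs = n_obs, k = k, df = n_obs - k,
              AIC = aic_neg2ll(best$value, n_obs - k),
              convergence = best$convergence == 0)
  class(fit) <- "ace_fit"
  fit
}

# ---- binary liability-threshold fits ---------------------------------------

# concordance-table sufficient statistics for a binary trait
.binary_counts <- function(Y, zygosity) {
  Y <- as.matrix(Y)
  out <- list()
  for (z in c("MZ", "DZ")) {
    yy <- Y[zygosity == z, , drop = FALSE]
    comp <- yy[stats::complete.cases(yy), , drop = FALSE]
    out[[z]] <- c(n11 = sum(comp[, 1] == 1 & comp[, 2] == 1),
                  n10 = sum(comp[, 1] == 1 & comp[, 2] == 0),
                  n01 = sum(comp[, 1] == 0 & comp[, 2] == 1),
                  n00 = sum(comp[, 1] == 0 & comp[, 2] == 0))
  }
  single <- numeric(0)
  for (z in c("MZ", "DZ")) {
    yy <- Y[zygosity == z, , drop = FALSE]
    inc <- yy[!stats::complete.cases(yy), , drop = FALSE]
    single <- c(single, inc[!is.na(inc)])
  }
  out$singles <- c(n1 = sum(single == 1), n0 = sum(single == 0))
  out$n_obs <- sum(!is.na(Y))
  out
}

# upper-orthant probability P(L1 > tau, L2 > tau) for standard bivariate
# normal liabilities with correlation r (deterministic bivariate routine)
.orthant_upper <- function(tau, r) {
  mvtnorm::pmvnorm(lower = c(tau, tau), upper = c(Inf, Inf),
                   corr = matrix(c(1, r, r, 1), 2), keepAttr = FALSE)
}

#' FIML -2 log-likelihood of a binary trait under the liability-threshold model
#'
#' The liability is standard bivariate normal within a pair with correlation
#' a2 + c2 (MZ) or a2/2 + c2 (DZ); trait value 1 means liability above the
#' threshold. Complete pairs contribute concordance-cell orthant
#' probabilities; pairs with a missing co-twin contribute univariate tail
#' probabilities. Total liability variance is constrained to 1.
#'
#' @param Y matrix n x 2 of 0/1 values, NA allowed.
#' @param zygosity "MZ"/"DZ" per pair.
#' @param a2,c2 standardized variance components (a2 + c2 < 1).
#' @param threshold liability threshold tau (trait prevalence of the "1"
#'   class is 1 - pnorm(tau)).
#' @return scalar -2 log likelihood.
#' @export
neg2ll_binary_liability <- function(Y, zygosity, a2, c2, threshold) {
  cnt <- .binary_counts(Y, zygosity)
  .neg2ll_bin(cnt, threshold, a2, c2)
}

.neg2ll_bin <- function(cnt, tau, a2, c2) {
  if (a2 < 0 || c2 < 0 || a2 + c2 >= 1) return(Inf)
  p1 <- 1 - stats::pnorm(tau)
  ll <- 0
  for (z in c("MZ", "DZ")) {
    r <- if (z == "MZ") a2 + c2 else 0.5 * a2 + c2
    if (r <= -1 || r >= 1) return(Inf)
    p11 <- .orthant_upper(tau, r)
    p10 <- p1 - p11
    p00 <- 1 - 2 * p1 + p11
    pr <- c(p11, p10, p10, p00)
    if (any(pr <= 0)) return(Inf)
    ll <- ll + sum(cnt[[z]] * log(pr))
  }
  if (sum(cnt$singles) > 0)
    ll <- ll + cnt$singles[["n1"]] * log(p1) + cnt$singles[["n0"]] * log(1 - p1)
  -2 * ll
}

#' Fit a univariate ACE-family liability-threshold model to binary twin data
#'
#' Maximum likelihood on the concordance-table likelihood with the liability
#' variance constrained to 1; free parameters are the threshold plus the
#' standardized paths of the retained components.
#'
#' @inheritParams fit_ace
#' @param Y matrix n x 2 of 0/1 trait values.
#' @return object of class `ace_fit` with `trait_kind = "binary_liability"`;
#'   estimates include `threshold` and `prevalence` (of the "1" class).
#' @export
fit_ace_binary <- function(Y, zygosity, model = c("ACE", "AE", "CE", "E"),
                           restarts = 5, init = NULL) {
  model <- match.arg(model)
  Y <- as.matrix(Y)
  zygosity <- as.character(zygosity)
  cnt <- .binary_counts(Y, zygosity)
  free <- .uv_free[[model]]
  p1 <- (2 * cnt$MZ[["n11"]] + cnt$MZ[["n10"]] + cnt$MZ[["n01"]] +
           2 * cnt$DZ[["n11"]] + cnt$DZ[["n10"]] + cnt$DZ[["n01"]] +
           cnt$singles[["n1"]]) / cnt$n_obs
  p1 <- min(max(p1, 1e-3), 1 - 1e-3)
  tau0 <- stats::qnorm(1 - p1)
  obj <- function(par) {
    a <- if ("a" %in% free) par[2] else 0
    c_ <- if ("c" %in% free) par[[length(par)]] else 0
    v <- .neg2ll_bin(cnt, par[1], min(a^2, 1), min(c_^2, 1))
    if (!is.finite(v)) 1e10 else v   # finite penalty for the simplex search
  }
  par0 <- c(tau0, if ("a" %in% free) 0.5, if ("c" %in% free) 0.3)
  starts <- list(par0)
  if (!is.null(init)) {
    pi0 <- c(init[["threshold"]], if ("a" %in% free) init[["a"]],
             if ("c" %in% free) init[["c"]])
    starts <- c(list(pi0), starts)
  }
  for (r in seq_len(max(0, restarts - length(starts))))
    starts <- c(starts, list(par0 + stats::rnorm(length(par0), 0, 0.2)))
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      if (length(par0) == 1) {
        stats::optim(p0, obj, method = "Brent", lower = -5, upper = 5)
      } else {
        stats::optim(p0, obj, method = "Nelder-Mead",
                     control = list(maxit = 2000, reltol = 1e-12))
      }, error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("all optimizer restarts failed")
  par <- best$par
  a2 <- if ("a" %in% free) min(par[2]^2, 1) else 0
  c2 <- if ("c" %in% free) min(par[[length(par)]]^2, 1) else 0
  e2 <- 1 - a2 - c2
  k <- length(par)
  fit <- list(model = model, trait_kind = "binary_liability",
              estimates = c(threshold = unname(par[1]),
                            prevalence = 1 - stats::pnorm(unname(par[1])),
                            a = sqrt(a2), c = sqrt(c2), e = sqrt(e2)),
              std = c(a2 = a2, c2 = c2, e2 = e2),
              minus2LL = best$value, n_obs = cnt$n_obs, k = k,
              df = cnt$n_obs - k, AIC = aic_neg2ll(best$value, cnt$n_obs - k),
              convergence = best$convergence == 0)
  class(fit) <- "ace_fit"
  fit
}

#' @export
print.ace_fit <- function(x, ...) {
  cat(sprintf("%s model (%s trait)\n", x$model, x$trait_kind))
  cat(sprintf("  a2 = %.3f  c2 = %.3f  e2 = %.3f\n",
              x$std[["a2"]], x$std[["c2"]], x$std[["e2"]]))
  cat(sprintf("  -2LL = %.2f  df = %d  AIC = %.2f  converged: %s\n",
              x$minus2LL, x$df, x$AIC, x$convergence))
  invisible(x)
}

# ---- model comparison -------------------------------------------------------

#' AIC from -2 log-likelihood and degrees of freedom
#'
#' The OpenMx-style convention used throughout this package:
#' AIC = -2LL - 2*df with df = (observations) - (free parameters). Note this
#' differs from the common -2LL + 2k form by a constant (2 * observations)
#' within a dataset, so model rankings agree.
#'
#' @param minus2LL -2 log-likelihood.
#' @param df observed-statistics degrees of freedom.
#' @return numeric AIC.
#' @export
aic_neg2ll <- function(minus2LL, df) minus2LL - 2 * df

#' Likelihood-ratio test between nested fits
#'
#' @param full,nested fitted models (`ace_fit` or `cholesky_fit`); `nested`'s
#'   free parameters must be a subset of `full`'s.
#' @return list with `delta_LL` (difference in -2LL), `delta_df`, `p_value`
#'   (chi-square upper tail; 1 when the fits are identical).
#' @export
lrt <- function(full, nested) {
  dll <- nested$minus2LL - full$minus2LL
  ddf <- full$k - nested$k
  if (ddf < 0) stop("'nested' has more free parameters than 'full'")
  if (dll < -1e-6)
    stop("nested model fits better than full model beyond numerical ",
         "tolerance; optimizer failure -- refit with more restarts")
  dll <- max(dll, 0)
  p <- if (ddf == 0) 1 else stats::pchisq(dll, ddf, lower.tail = FALSE)
  list(delta_LL = dll, delta_df = ddf, p_value = p)
}

#' Univariate model-comparison ladder (ACE vs AE, CE, E)
#'
#' Fits the full ACE model and its nested submodels for one trait and
#' tabulates fit statistics and likelihood-ratio tests against ACE.
#'
#' @inheritParams fit_ace
#' @param kind "continuous" or "binary_liability".
#' @return list with `fits` (named list of `ace_fit`) and `table`
#'   (data.frame: model, a2, c2, e2, minus2LL, df, AIC, delta_LL, delta_df, p).
#' @export
univariate_ladder <- function(Y, zygosity, kind = c("continuous", "binary_liability"),
                              restarts = 5) {
  kind <- match.arg(kind)
  f <- if (kind == "continuous") fit_ace else fit_ace_binary
  fits <- list()
  fits$ACE <- f(Y, zygosity, model = "ACE", restarts = restarts)
  for (m in c("AE", "CE", "E"))
    fits[[m]] <- f(Y, zygosity, model = m, restarts = restarts,
                   init = fits$ACE$estimates)
  # a nested fit must never beat ACE; refit ACE from the offender if it does
  for (m in c("AE", "CE", "E"))
    if (fits[[m]]$minus2LL < fits$ACE$minus2LL - 1e-8) {
      ref <- f(Y, zygosity, model = "ACE", restarts = 1,
               init = fits[[m]]$estimates)
      if (ref$minus2LL < fits$ACE$minus2LL) fits$ACE <- ref
    }
  tab <- do.call(rbind, lapply(names(fits), function(m) {
    ft <- fits[[m]]
    cmp <- if (m == "ACE") list(delta_LL = NA, delta_df = NA, p_value = NA)
           else lrt(fits$ACE, ft)
    data.frame(model = m, a2 = ft$std[["a2"]], c2 = ft$std[["c2"]],
               e2 = ft$std[["e2"]], minus2LL = ft$minus2LL, df = ft$df,
               AIC = ft$AIC, delta_LL = cmp$delta_LL,
               delta_df = cmp$delta_df, p = cmp$p_value)
  }))
  rownames(tab) <- NULL
  list(fits = fits, table = tab)
}

# ---- homogeneity ladder -----------------------------------------------------

# Saturated-Gaussian fit with equality constraints expressed as index maps.
# grp: pair-level group label; mean_map/sd_map: G x 2 integer matrices mapping
# (group, twin order) to a parameter index; cor_map: length-G map.
.fit_sat_gaussian <- function(Y, grp, mean_map, sd_map, cor_map) {
  st <- .fiml_stats(Y, grp)
  G <- rownames(mean_map)
  n_mu <- max(mean_map); n_sd <- max(sd_map); n_r <- max(cor_map)
  # moment starts
  mu0 <- rep(mean(Y, na.rm = TRUE), n_mu)
  lsd0 <- rep(log(stats::sd(as.vector(Y), na.rm = TRUE)), n_sd)
  z0 <- rep(0, n_r)  # start at r = 0
  obj <- function(par) {
    mu <- par[seq_len(n_mu)]
    lsd <- par[n_mu + seq_len(n_sd)]
    z <- par[n_mu + n_sd + seq_len(n_r)]
    Sig <- mu_by <- list()
    for (g in G) {
      s1 <- exp(lsd[sd_map[g, 1]]); s2 <- exp(lsd[sd_map[g, 2]])
      r <- tanh(z[cor_map[g]])
      Sig[[g]] <- matrix(c(s1^2, r * s1 * s2, r * s1 * s2, s2^2), 2)
      mu_by[[g]] <- c(mu[mean_map[g, 1]], mu[mean_map[g, 2]])
    }
    .fiml_neg2ll(st, Sig, mu_by)
  }
  fit <- stats::optim(c(mu0, lsd0, z0), obj, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  list(minus2LL = fit$value, k = n_mu + n_sd + n_r,
       n_obs = attr(st, "n_obs"), convergence = fit$convergence == 0)
}

#' Homogeneity ladder for a continuous trait
#'
#' Fits a saturated model (group- and order-specific means and variances,
#' group-specific twin correlations) and successively equates parameters:
#' across twin order, then across pair sex composition (male-male,
#' female-female, opposite-sex), then across zygosity (twin correlations
#' remain zygosity-specific throughout -- they carry the genetic signal).
#' Each step is tested against the previous by likelihood ratio.
#'
#' @param Y matrix n x 2 of trait values.
#' @param zygosity "MZ"/"DZ" per pair.
#' @param sex1,sex2 "male"/"female" per twin; if NULL the sex step is skipped.
#' @return data.frame: step, minus2LL, k, delta_LL, delta_df, p.
#' @export
homogeneity_ladder <- function(Y, zygosity, sex1 = NULL, sex2 = NULL) {
  Y <- as.matrix(Y)
  zygosity <- as.character(zygosity)
  use_sex <- !is.null(sex1) && !is.null(sex2)
  sexcomp <- if (use_sex)
    ifelse(sex1 == sex2, ifelse(sex1 == "male", "MM", "FF"), "OS")
  else rep("all", nrow(Y))
  grp <- paste(zygosity, sexcomp, sep = ".")
  tabg <- table(grp)
  small <- names(tabg)[tabg < 2]
  if (length(small)) {
    warning("group(s) with < 2 pairs dropped from the ladder: ",
            paste(small, collapse = ", "))
    keep <- !grp %in% small
    Y <- Y[keep, , drop = FALSE]; zygosity <- zygosity[keep]
    grp <- grp[keep]; sexcomp <- sexcomp[keep]
  }
  G <- sort(unique(grp))
  zg <- sub("\\..*", "", G)
  im <- function(v) { u <- unique(v); match(v, u) }
  maps <- function(mean_key, sd_key, cor_key) {
    list(mean_map = matrix(im(c(paste0(mean_key, ".1"), paste0(mean_key, ".2"))),
                           ncol = 2, dimnames = list(G, NULL)),
         sd_map = matrix(im(c(paste0(sd_key, ".1"), paste0(sd_key, ".2"))),
                         ncol = 2, dimnames = list(G, NULL)),
         cor_map = stats::setNames(im(cor_key), G))
  }
  steps <- list(
    saturated = maps(G, G, G),
    equal_order = list(
      mean_map = matrix(im(c(G, G)), ncol = 2, dimnames = list(G, NULL)),
      sd_map = matrix(im(c(G, G)), ncol = 2, dimnames = list(G, NULL)),
      cor_map = stats::setNames(im(G), G)),
    equal_sex = list(
      mean_map = matrix(im(c(zg, zg)), ncol = 2, dimnames = list(G, NULL)),
      sd_map = matrix(im(c(zg, zg)), ncol = 2, dimnames = list(G, NULL)),
      cor_map = stats::setNames(im(zg), G)),
    equal_zygosity = list(
      mean_map = matrix(1L, nrow = length(G), ncol = 2, dimnames = list(G, NULL)),
      sd_map = matrix(1L, nrow = length(G), ncol = 2, dimnames = list(G, NULL)),
      cor_map = stats::setNames(im(zg), G))
  )
  if (!use_sex) steps$equal_sex <- NULL
  fits <- lapply(steps, function(m)
    .fit_sat_gaussian(Y, grp, m$mean_map, m$sd_map, m$cor_map))
  out <- data.frame(step = names(fits),
                    minus2LL = vapply(fits, `[[`, 0, "minus2LL"),
                    k = vapply(fits, `[[`, 0L, "k"))
  out$delta_LL <- c(NA, diff(out$minus2LL))
  out$delta_df <- c(NA, -diff(out$k))
  out$p <- ifelse(is.na(out$delta_LL), NA,
                  stats::pchisq(pmax(out$delta_LL, 0), pmax(out$delta_df, 1),
                                lower.tail = FALSE))
  rownames(out) <- NULL
  out
}
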