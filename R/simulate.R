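# Synthetic twin/singleton cohort generation. The generator inverts the
# models the analysis stages assume: latent A/C/E factors with twin
# correlations 1 (MZ) and 0.5 (DZ) on A, shared C, independent E; a
# graded-response item model over a handedness liability for the inventory;
# and a laterality-linked speed model for pegboard trials.
#
# RNG contract: one root seed, split deterministically per sub-generator;
# within each sub-generator draws are made in subject order, so appending
# subjects does not perturb earlier subjects' draws.

.subseed <- function(seed, tag) {
  s <- (as.numeric(seed) * 1009 + tag * 9973) %% 2147483629
  as.integer(s)
}

# symmetric matrix square root (handles the singular |r| = 1 edge)
.msqrt <- function(M) {
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE)
  ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(M)) %*% t(ev$vectors)
}

.cormat <- function(r, p) {
  if (p == 1) return(matrix(1, 1, 1))
  matrix(c(1, r, r, 1), 2, 2)
}

#' Simulate continuous twin-pair phenotypes under an ACE structure
#'
#' Draws latent additive-genetic factors with cross-twin correlation 1 (MZ)
#' or 0.5 (DZ), shared-environment factors common to a pair, and independent
#' non-shared factors, with configurable cross-trait factor correlations,
#' and composes phenotypes from standardized variance components.
#'
#' @param n_mz,n_dz numbers of MZ and DZ pairs.
#' @param a2,c2 standardized components per trait (length 1 or 2);
#'   e2 = 1 - a2 - c2 must be positive.
#' @param rA,rC,rE cross-trait correlations of the latent factors (used when
#'   two traits are simulated).
#' @param means,sds trait means and standard deviations (recycled).
#' @param seed integer seed; fixed seed gives bit-reproducible output.
#' @return list with `Y` (matrix n x 2p: twin-1 trait(s) then twin-2
#'   trait(s)) and `zygosity` (character vector).
#' @export
simulate_pairs <- function(n_mz, n_dz, a2, c2, rA = 0, rC = 0, rE = 0,
                           means = 0, sds = 1, seed = NULL) {
  p <- length(a2)
  stopifnot(p %in% c(1, 2), length(c2) == p)
  e2 <- 1 - a2 - c2
  if (any(a2 < 0) || any(c2 < 0) || any(e2 <= 0))
    stop("invalid components: need a2, c2 >= 0 and a2 + c2 < 1")
  if (any(abs(c(rA, rC, rE)) > 1)) stop("factor correlations must be in [-1, 1]")
  means <- rep_len(means, p); sds <- rep_len(sds, p)
  if (!is.null(seed)) set.seed(seed)
  n <- n_mz + n_dz
  zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
  RA <- .cormat(rA, p); RC <- .cormat(rC, p); RE <- .cormat(rE, p)
  sqA <- .msqrt(RA); sqC <- .msqrt(RC); sqE <- .msqrt(RE)
  draw <- function(n, sq) matrix(stats::rnorm(n * p), n, p) %*% t(sq)
  # A: MZ twins share one draw; DZ twins get correlation .5 on every factor
  A1 <- draw(n, sqA)
  Aind <- draw(n, sqA)
  A2 <- ifelse(matrix(zyg == "MZ", n, p), A1, 0.5 * A1 + sqrt(0.75) * Aind)
  Cc <- draw(n, sqC)
  E1 <- draw(n, sqE); E2 <- draw(n, sqE)
  compose <- function(A, C, E)
    sweep(sweep(A %*% diag(sqrt(a2), p) + C %*% diag(sqrt(c2), p) +
                  E %*% diag(sqrt(e2), p), 2, sds, `*`), 2, means, `+`)
  Y <- cbind(compose(A1, Cc, E1), compose(A2, Cc, E2))
  list(Y = Y, zygosity = zyg)
}

#' Simulate binary twin data under the liability-threshold model
#'
#' Thresholds a standardized continuous liability (from [simulate_pairs()])
#' at tau = qnorm(1 - prevalence); the "1" class has the target marginal
#' prevalence, and MZ/DZ tetrachoric correlations converge to a2 + c2 and
#' a2/2 + c2.
#'
#' @inheritParams simulate_pairs
#' @param prevalence target marginal prevalence of the "1" class, in (0, 1).
#' @return list with `Y` (n x 2 matrix of 0/1), `zygosity`, `threshold`.
#' @export
simulate_binary <- function(n_mz, n_dz, a2, c2, prevalence, seed = NULL) {
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  sim <- simulate_pairs(n_mz, n_dz, a2, c2, seed = seed)
  tau <- stats::qnorm(1 - prevalence)
  list(Y = matrix(as.integer(sim$Y > tau), ncol = 2), zygosity = sim$zygosity,
       threshold = tau)
}

#' Default item model of the inventory generator
#'
#' Per-item loading on the handedness liability, half-width of the
#' no-preference band (`np`), and the always/usually cut (`always`), on the
#' standardized item-latent scale. Loadings are highest for writing/drawing
#' and lowest for broom/box-lid; no-preference bands are widest for the
#' weakly lateralised items, producing the J-shaped composite with varying
#' per-item no-preference rates.
#'
#' @return data.frame with columns `item`, `loading`, `np`, `always`.
#' @export
default_item_model <- function() {
  data.frame(
    item = ehi_items(),
    loading = c(0.92, 0.92, 0.55, 0.75, 0.65, 0.80, 0.65, 0.60, 0.45, 0.45),
    np = c(0.10, 0.25, 0.90, 0.55, 0.75, 0.20, 0.80, 0.60, 0.85, 1.00),
    always = c(0.70, 0.85, 1.50, 1.15, 1.35, 0.80, 1.40, 1.20, 1.45, 1.60))
}

# population liability mean giving ~92% right-handers (EHI2 = 1) under the
# default item model; calibrated once at large n and frozen
.EHI_LIABILITY_MEAN <- 1.5

#' Simulate inventory item responses from handedness liabilities
#'
#' Graded-response-style generator: each item's latent value is
#' loading * liability + sqrt(1 - loading^2) * noise; five ordered categories
#' (always-left, usually-left, either, usually-right, always-right) are cut
#' at -always, -np, np, always.
#'
#' @param liability numeric vector of per-subject handedness liabilities
#'   (positive = rightward); include any population mean shift.
#' @param subject_id subject identifiers (default 1..n).
#' @param item_model data.frame as [default_item_model()].
#' @param noise_scale multiplier on the item noise sd (0 = noise-free limit,
#'   in which all items agree and EHI is exactly +/-1).
#' @param seed integer seed.
#' @return long data.frame: `subject_id`, `item`, `hand`, `degree`.
#' @export
simulate_ehi_items <- function(liability, subject_id = seq_along(liability),
                               item_model = default_item_model(),
                               noise_scale = 1, seed = NULL) {
  if (any(item_model$np < 0) || any(item_model$always <= item_model$np))
    stop("non-monotone item thresholds: need 0 <= np < always")
  if (!is.null(seed)) set.seed(seed)
  n <- length(liability)
  out <- vector("list", nrow(item_model))
  for (i in seq_len(nrow(item_model))) {
    lam <- item_model$loading[i]
    y <- lam * liability +
      noise_scale * sqrt(max(1 - lam^2, 0)) * stats::rnorm(n)
    hand <- ifelse(abs(y) <= item_model$np[i], "either",
                   ifelse(y > 0, "right", "left"))
    degree <- ifelse(hand == "either", NA_character_,
                     ifelse(abs(y) > item_model$always[i], "always", "usually"))
    out[[i]] <- data.frame(subject_id = subject_id, item = item_model$item[i],
                           hand = hand, degree = degree,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res[order(match(res$subject_id, subject_id)), , drop = FALSE]
}

#' Simulate pegboard trials from true laterality indices
#'
#' Each subject's true hand mean times are base_time * (1 +/- pegq/2), so the
#' noise-free index 2(L-R)/(L+R) equals `pegq_true` exactly; i.i.d. Gaussian
#' trial noise is added to each of the trials per hand. A configuration that
#' yields a non-positive time is rejected with an error (times are never
#' floored).
#'
#' @param pegq_true numeric vector of per-subject true laterality indices.
#' @param subject_id subject identifiers.
#' @param base_time mean movement time in seconds (default 10).
#' @param trial_sd trial noise sd in seconds (default 0.25).
#' @param n_trials trials per hand (default 5).
#' @param seed integer seed.
#' @return long data.frame: `subject_id`, `hand`, `trial_index`,
#'   `time_seconds`.
#' @export
simulate_peg_trials <- function(pegq_true, subject_id = seq_along(pegq_true),
                                base_time = 10, trial_sd = 0.25, n_trials = 5,
                                seed = NULL) {
  if (base_time <= 0 || trial_sd < 0) stop("invalid pegboard speed model")
  if (!is.null(seed)) set.seed(seed)
  n <- length(pegq_true)
  rows <- vector("list", n)
  for (s in seq_len(n)) {
    L <- base_time * (1 + pegq_true[s] / 2)
    R <- base_time * (1 - pegq_true[s] / 2)
    tl <- L + stats::rnorm(n_trials, 0, trial_sd)
    tr <- R + stats::rnorm(n_trials, 0, trial_sd)
    if (any(c(tl, tr) <= 0))
      stop("configuration yields a non-positive trial time; reduce trial_sd ",
           "or the laterality scale")
    rows[[s]] <- data.frame(subject_id = subject_id[s],
                            hand = rep(c("left", "right"), each = n_trials),
                            trial_index = rep(seq_len(n_trials), 2),
                            time_seconds = c(tl, tr), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Cohort generator configuration
#'
#' Defaults emulate the study conditions: 91 MZ pairs (41 male, 50 female),
#' 114 DZ pairs (25 male, 21 female, 68 opposite-sex), 426 singletons
#' (221 boys, 205 girls); standardized components a2 = .205 (preference
#' liability) and .217 (pegboard laterality) with no shared environment;
#' independent genetic factors and correlated non-shared factors
#' (rE = .53, giving a phenotypic cross-trait correlation of about .42);
#' ~8% non-right-handers with a male:female NRH odds ratio of 1.27; PegQ
#' centred at .095 with sd about .10.
#'
#' @param n_mz_mm,n_mz_ff MZ pair counts by sex.
#' @param n_dz_mm,n_dz_ff,n_dz_os DZ pair counts by sex composition.
#' @param n_single_m,n_single_f singleton counts by sex.
#' @param a2,c2 standardized components, length 2 (preference, performance).
#' @param rA,rC,rE cross-trait latent factor correlations.
#' @param nrh_prevalence target non-right-handedness rate.
#' @param sex_or male:female odds ratio on NRH.
#' @param pegq_mean,pegq_sd population mean and sd of the true pegboard index.
#' @param peg_base_time,peg_trial_sd pegboard speed model (seconds).
#' @param item_model item generator table (see [default_item_model()]).
#' @param twin_age_mean,twin_age_sd,single_age_mean,single_age_sd age models.
#' @param miss_items,miss_peg per-subject missingness rates for the two
#'   instruments (default 0).
#' @param seed root seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_mz_mm = 41, n_mz_ff = 50, n_dz_mm = 25,
                          n_dz_ff = 21, n_dz_os = 68, n_single_m = 221,
                          n_single_f = 205, a2 = c(0.205, 0.217), c2 = c(0, 0),
                          rA = 0, rC = 0, rE = 0.53, nrh_prevalence = 0.08,
                          sex_or = 1.27, pegq_mean = 0.095, pegq_sd = 0.095,
                          peg_base_time = 10, peg_trial_sd = 0.25,
                          item_model = default_item_model(),
                          twin_age_mean = 8.7, twin_age_sd = 1.2,
                          single_age_mean = 8.3, single_age_sd = 1.2,
                          miss_items = 0, miss_peg = 0, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$a2) == 2, length(cfg$c2) == 2,
            all(cfg$a2 + cfg$c2 < 1), cfg$nrh_prevalence > 0,
            cfg$nrh_prevalence < 1)
  class(cfg) <- "cohort_config"
  cfg
}

# sex shift on the preference liability from the configured NRH odds ratio:
# males are shifted down, females up, keeping overall NRH near the target
.sex_shift <- function(nrh_prev, or) {
  if (or == 1) return(0)
  z0 <- stats::qnorm(nrh_prev)   # NRH = liability below z0 (low = leftward)
  f <- function(d) {
    pm <- stats::pnorm(z0 + d / 2); pf <- stats::pnorm(z0 - d / 2)
    (pm / (1 - pm)) / (pf / (1 - pf)) - or
  }
  stats::uniroot(f, c(0, 2))$root
}

#' Simulate a full twin/singleton study bundle
#'
#' Generates the twin and singleton rosters, latent bivariate handedness
#' structure (preference liability + pegboard laterality), inventory item
#' responses and pegboard trials, in exactly the long CSV formats the
#' scoring/prevalence/twin-model stages consume. Deterministic given the
#' config seed.
#'
#' @param config a [cohort_config()].
#' @param dir optional directory; if given, writes `roster.csv`,
#'   `items.csv`, `peg.csv` and `manifest.json` there.
#' @return list with `roster`, `items`, `peg` data.frames and `manifest`.
#' @export
simulate_cohort <- function(config = cohort_config(), dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  n_mz <- cfg$n_mz_mm + cfg$n_mz_ff
  n_dz <- cfg$n_dz_mm + cfg$n_dz_ff + cfg$n_dz_os
  n_tw <- 2 * (n_mz + n_dz)
  n_sg <- cfg$n_single_m + cfg$n_single_f
  # --- roster ---------------------------------------------------------------
  set.seed(.subseed(cfg$seed, 1))
  pair_sex <- c(rep("MM", cfg$n_mz_mm), rep("FF", cfg$n_mz_ff),
                rep("MM", cfg$n_dz_mm), rep("FF", cfg$n_dz_ff),
                rep("OS", cfg$n_dz_os))
  zyg_pair <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
  pair_id <- sprintf("P%03d", seq_len(n_mz + n_dz))
  sex1 <- ifelse(pair_sex == "FF", "female", "male")
  sex2 <- ifelse(pair_sex == "MM", "male",
                 ifelse(pair_sex == "FF", "female", "female"))
  age_pair <- stats::rnorm(n_mz + n_dz, cfg$twin_age_mean, cfg$twin_age_sd)
  roster_tw <- data.frame(
    subject_id = paste0(rep(pair_id, each = 2),
                        rep(c("_1", "_2"), length(pair_id))),
    cohort = rep("twin", 2 * length(pair_id)),
    sex = as.vector(rbind(sex1, sex2)),
    age = round(rep(age_pair, each = 2), 1),
    pair_id = rep(pair_id, each = 2),
    zygosity = rep(zyg_pair, each = 2), stringsAsFactors = FALSE)
  age_sg <- stats::rnorm(n_sg, cfg$single_age_mean, cfg$single_age_sd)
  roster_sg <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n_sg)),
    cohort = rep("singleton", n_sg),
    sex = rep(c("male", "female"), c(cfg$n_single_m, cfg$n_single_f)),
    age = round(age_sg, 1), pair_id = NA_character_,
    zygosity = NA_character_, stringsAsFactors = FALSE)
  roster <- rbind(roster_tw, roster_sg)
  # --- latent bivariate traits ---------------------------------------------
  tw <- simulate_pairs(n_mz, n_dz, cfg$a2, cfg$c2, cfg$rA, cfg$rC, cfg$rE,
                       seed = .subseed(cfg$seed, 2))
  # singletons: same marginal/cross-trait structure, no pairing
  set.seed(.subseed(cfg$seed, 3))
  r12 <- sqrt(cfg$a2[1] * cfg$a2[2]) * cfg$rA +
    sqrt(cfg$c2[1] * cfg$c2[2]) * cfg$rC +
    sqrt(prod(1 - cfg$a2 - cfg$c2)) * cfg$rE
  sg <- matrix(stats::rnorm(n_sg * 2), n_sg) %*% t(.msqrt(.cormat(r12, 2)))
  # subject-level latent values, twins interleaved as twin1, twin2
  lat1 <- c(as.vector(rbind(tw$Y[, 1], tw$Y[, 3])), sg[, 1])  # preference
  lat2 <- c(as.vector(rbind(tw$Y[, 2], tw$Y[, 4])), sg[, 2])  # performance
  sexv <- c(roster_tw$sex, roster_sg$sex)
  shift <- .sex_shift(cfg$nrh_prevalence, cfg$sex_or)
  liab <- .EHI_LIABILITY_MEAN + lat1 + ifelse(sexv == "male", -shift / 2, shift / 2)
  pegq_true <- cfg$pegq_mean + cfg$pegq_sd * lat2
  ids <- c(roster_tw$subject_id, roster_sg$subject_id)
  # --- instruments ----------------------------------------------------------
  items <- simulate_ehi_items(liab, ids, cfg$item_model,
                              seed = .subseed(cfg$seed, 4))
  peg <- simulate_peg_trials(pegq_true, ids, cfg$peg_base_time,
                             cfg$peg_trial_sd, seed = .subseed(cfg$seed, 5))
  if (cfg$miss_items > 0 || cfg$miss_peg > 0) {
    set.seed(.subseed(cfg$seed, 6))
    drop_i <- ids[stats::runif(length(ids)) < cfg$miss_items]
    drop_p <- ids[stats::runif(length(ids)) < cfg$miss_peg]
    items <- items[!items$subject_id %in% drop_i, , drop = FALSE]
    peg <- peg[!peg$subject_id %in% drop_p, , drop = FALSE]
  }
  manifest <- list(generator = "handtwin::simulate_cohort",
                   seed = cfg$seed,
                   config = cfg[setdiff(names(cfg), "item_model")],
                   item_model = cfg$item_model,
                   liability_mean = .EHI_LIABILITY_MEAN)
  out <- list(roster = roster, items = items, peg = peg, manifest = manifest)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(roster, file.path(dir, "roster.csv"), row.names = FALSE,
                     na = "")
    utils::write.csv(items, file.path(dir, "items.csv"), row.names = FALSE,
                     na = "")
    utils::write.csv(peg, file.path(dir, "peg.csv"), row.names = FALSE,
                     na = "")
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
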