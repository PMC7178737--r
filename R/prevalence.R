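# Prevalence and descriptive statistics: contingency tests, reliability,
# group means, two-way ANOVA, cross-measure correlations.

#' Pearson chi-square test on a contingency table
#'
#' Uncorrected Pearson test (no Yates continuity correction), the form whose
#' printed statistics the prevalence tables use. Expected counts are
#' row_total * col_total / N; df = (r-1)(c-1).
#'
#' @param counts numeric matrix of non-negative counts, >= 2 rows and columns.
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chisq_contingency <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative count", call. = FALSE)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least a 2 x 2 table", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("all-zero row or column", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return alpha / m.
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (!is.finite(m) || m < 1) stop("m must be >= 1")
  alpha / m
}

#' Item-total correlations of inventory items
#'
#' Pearson correlation of each item's score (right points minus left points,
#' in -2..2) with the total score. The uncorrected form correlates the item
#' with the total including itself; the corrected form with the rest-of-items
#' total.
#'
#' @param item_scores numeric matrix, subjects x items.
#' @param corrected logical; item-rest correlation if TRUE.
#' @return named numeric vector, one correlation per item (NA with a warning
#'   for a zero-variance item).
#' @export
item_total_correlations <- function(item_scores, corrected = FALSE) {
  item_scores <- as.matrix(item_scores)
  if (nrow(item_scores) < 3) stop("need at least 3 subjects")
  total <- rowSums(item_scores)
  out <- vapply(seq_len(ncol(item_scores)), function(j) {
    x <- item_scores[, j]
    t <- if (corrected) total - x else total
    ok <- stats::complete.cases(x, t)
    if (stats::sd(x[ok]) == 0 || stats::sd(t[ok]) == 0) {
      warning("zero-variance item or total; correlation undefined")
      return(NA_real_)
    }
    stats::cor(x[ok], t[ok])
  }, numeric(1))
  stats::setNames(out, colnames(item_scores))
}

#' Cronbach's alpha
#'
#' alpha = k/(k-1) * (1 - sum(item variances) / variance of the total),
#' over complete cases.
#'
#' @param item_scores numeric matrix, subjects x items (k >= 2 items).
#' @return scalar reliability coefficient.
#' @export
cronbach_alpha <- function(item_scores) {
  item_scores <- as.matrix(item_scores)
  item_scores <- item_scores[stats::complete.cases(item_scores), , drop = FALSE]
  k <- ncol(item_scores)
  if (k < 2) stop("need at least 2 items")
  if (nrow(item_scores) < 3) stop("need at least 3 complete subjects")
  vt <- stats::var(rowSums(item_scores))
  if (vt == 0) stop("zero total-score variance")
  k / (k - 1) * (1 - sum(apply(item_scores, 2, stats::var)) / vt)
}

#' Sample-by-sex two-way ANOVA of a laterality score
#'
#' Unbalanced 2 x 2 ANOVA of a continuous score on cohort (twin vs singleton)
#' and sex, with interaction. Default Type III sums of squares with
#' sum-to-zero contrasts; Types I and II available since software conventions
#' differ.
#'
#' @param values numeric score per subject.
#' @param sample factor-like: "twin"/"singleton".
#' @param sex factor-like: "male"/"female".
#' @param ss_type "III" (default), "II" or "I".
#' @return data.frame with one row per effect: `effect`, `F`, `df1`, `df2`, `p`.
#' @export
anova_sample_sex <- function(values, sample, sex, ss_type = c("III", "II", "I")) {
  ss_type <- match.arg(ss_type)
  ok <- stats::complete.cases(values, sample, sex)
  d <- data.frame(y = values[ok], sample = factor(sample[ok]),
                  sex = factor(sex[ok]))
  cells <- table(d$sample, d$sex)
  if (any(cells < 2)) {
    bad <- which(cells < 2, arr.ind = TRUE)[1, ]
    stop(sprintf("cell (%s, %s) has fewer than 2 observations",
                 rownames(cells)[bad[1]], colnames(cells)[bad[2]]), call. = FALSE)
  }
  fit <- stats::lm(y ~ sample * sex, data = d,
                   contrasts = list(sample = stats::contr.sum,
                                    sex = stats::contr.sum))
  df2 <- fit$df.residual
  if (ss_type == "I") {
    a <- stats::anova(fit)
    eff <- rownames(a)[seq_len(3)]
    res <- data.frame(effect = eff, F = a$`F value`[seq_len(3)],
                      df1 = a$Df[seq_len(3)], df2 = df2,
                      p = a$`Pr(>F)`[seq_len(3)])
  } else {
    a <- car::Anova(fit, type = ss_type)
    keep <- !rownames(a) %in% c("(Intercept)", "Residuals")
    res <- data.frame(effect = rownames(a)[keep], F = a$`F value`[keep],
                      df1 = a$Df[keep], df2 = df2, p = a$`Pr(>F)`[keep])
  }
  res$effect <- sub("sample:sex", "interaction", res$effect)
  rownames(res) <- NULL
  res
}

#' Pairwise Pearson correlation matrix with significance flags
#'
#' Pairwise-complete Pearson correlations among laterality measures and
#' covariates; binary measures enter as their 0/1 codes (sex coded
#' 0 = male, 1 = female). Two-sided p-values; flags at .05 and .01.
#'
#' @param measures data.frame of numeric columns.
#' @return list with matrices `r`, `p`, `n` and character matrix `flag`
#'   ("", "*", "**").
#' @export
correlation_matrix <- function(measures) {
  m <- as.matrix(measures)
  if (!is.numeric(m)) stop("all measure columns must be numeric")
  k <- ncol(m)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ok <- stats::complete.cases(m[, i], m[, j])
    n[i, j] <- sum(ok)
    if (n[i, j] < 3) next
    if (stats::sd(m[ok, i]) == 0 || stats::sd(m[ok, j]) == 0) {
      warning("constant column; correlation undefined for ",
              colnames(m)[i], " vs ", colnames(m)[j])
      next
    }
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    ct <- stats::cor.test(m[ok, i], m[ok, j])
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  flag <- matrix("", k, k, dimnames = dimnames(r))
  flag[!is.na(p) & p < .05] <- "*"
  flag[!is.na(p) & p < .01] <- "**"
  diag(flag) <- ""
  list(r = r, p = p, n = n, flag = flag)
}

#' Per-item three-class preference tables with chi-square tests
#'
#' Builds, for each inventory item, the LH/NP/RH x group contingency table
#' (groups from a subject-level factor) and runs the uncorrected Pearson
#' test, flagging significance before and after Bonferroni correction for
#' the family of 10 item comparisons. Items use their own valid responses,
#' so per-item denominators may differ.
#'
#' @param item_responses long data.frame (`subject_id`, `item`, `hand`, ...).
#' @param group named character/factor vector: subject_id -> group label.
#' @param alpha family-wise level (default .05 over 10 comparisons).
#' @return data.frame: one row per item with counts by class x group
#'   (flattened as `<class>_<group>`), `chisq`, `df`, `p`,
#'   `sig` and `sig_bonferroni`.
#' @export
item_preference_tests <- function(item_responses, group, alpha = 0.05) {
  stopifnot(!is.null(names(group)))
  adj <- bonferroni_alpha(alpha, length(ehi_items()))
  rows <- lapply(ehi_items(), function(it) {
    r <- item_responses[item_responses$item == it & !is.na(item_responses$hand), ]
    cls <- factor(recode_item_three_class(r$hand), levels = c("LH", "NP", "RH"))
    g <- factor(group[as.character(r$subject_id)])
    tab <- table(cls, g)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    res <- tryCatch(chisq_contingency(tab), error = function(e) NULL)
    cnt <- as.list(as.vector(table(cls, g)))
    names(cnt) <- as.vector(outer(c("LH", "NP", "RH"), levels(g), paste, sep = "_"))
    c(list(item = it), cnt,
      list(chisq = if (is.null(res)) NA_real_ else res$statistic,
           df = if (is.null(res)) NA_real_ else res$df,
           p = if (is.null(res)) NA_real_ else res$p_value))
  })
  out <- do.call(rbind, lapply(rows, function(x) as.data.frame(x)))
  out$sig <- !is.na(out$p) & out$p < alpha
  out$sig_bonferroni <- !is.na(out$p) & out$p < adj
  out
}

#' Direction (NRH/RH) prevalence tables with chi-square tests
#'
#' For each binary handedness indicator, cross-tabulates NRH (0) vs RH (1)
#' against a grouping factor and runs the uncorrected Pearson 2 x 2 test.
#'
#' @param scored subject-level data.frame from [score_cohort()] (or any frame
#'   with 0/1 indicator columns).
#' @param group named vector subject_id -> group label.
#' @param indicators column names to tabulate.
#' @return data.frame, one row per indicator: counts `NRH_<g>`, `RH_<g>`,
#'   `chisq`, `df`, `p`.
#' @export
direction_prevalence_tests <- function(scored, group,
                                       indicators = c("writing_bin", "drawing_bin",
                                                      "EHI2", "PegQ2")) {
  rows <- lapply(indicators, function(ind) {
    v <- scored[[ind]]
    ok <- !is.na(v)
    g <- factor(group[as.character(scored$subject_id[ok])])
    cls <- factor(ifelse(v[ok] == 1, "RH", "NRH"), levels = c("NRH", "RH"))
    tab <- table(cls, g)
    res <- tryCatch(chisq_contingency(tab), error = function(e) NULL)
    cnt <- as.list(as.vector(tab))
    names(cnt) <- as.vector(outer(c("NRH", "RH"), levels(g), paste, sep = "_"))
    as.data.frame(c(list(indicator = ind), cnt,
                    list(chisq = if (is.null(res)) NA_real_ else res$statistic,
                         df = if (is.null(res)) NA_real_ else res$df,
                         p = if (is.null(res)) NA_real_ else res$p_value)))
  })
  do.call(rbind, rows)
}

#' Group means and SDs of a continuous score
#'
#' @param values numeric score per subject.
#' @param group grouping factor.
#' @return data.frame with `group`, `n`, `mean`, `sd`.
#' @export
score_means <- function(values, group) {
  ok <- !is.na(values) & !is.na(group)
  g <- factor(group[ok]); v <- values[ok]
  data.frame(group = levels(g), n = as.vector(table(g)),
             mean = as.vector(tapply(v, g, mean)),
             sd = as.vector(tapply(v, g, stats::sd)))
}
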