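# Study input/output: schema-validated CSV reading, the wide twin-pair
# layout, and the one-shot pipeline runner.
#
# CSV dialect: UTF-8, comma-separated, header row required, empty string =
# missing.

.vocab <- list(hand = c("left", "right", "either"),
               degree = c("always", "usually"),
               peg_hand = c("left", "right"),
               cohort = c("twin", "singleton"),
               sex = c("male", "female"),
               zygosity = c("MZ", "DZ"))

.read_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                  fileEncoding = "UTF-8")
}

.check_cols <- function(df, cols, file) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", file, paste(miss, collapse = ", ")),
         call. = FALSE)
}

.vocab_errors <- function(df, col, allowed, file, required = TRUE) {
  v <- df[[col]]
  bad <- which(if (required) is.na(v) | !v %in% allowed else
                 !is.na(v) & !v %in% allowed)
  if (!length(bad)) return(character(0))
  sprintf("%s line %d: column '%s' has value '%s' (allowed: %s)",
          file, bad + 1L, col, ifelse(is.na(v[bad]), "<missing>", v[bad]),
          paste(allowed, collapse = "/"))
}

#' Read and validate a study bundle
#'
#' Loads the long-format inventory responses, pegboard trials and subject
#' roster, enforcing column schemas and controlled vocabularies. Row-level
#' problems are collected and reported together (with line numbers); loading
#' fails outright only when no usable data remain.
#'
#' @param roster,items,peg file paths (items and/or peg may be NULL).
#' @param max_report maximum number of row errors echoed in the error
#'   message.
#' @return list of class `study_bundle` with elements `roster`, `items`,
#'   `peg` and `validation` (character vector of row-level messages for
#'   rows that were dropped).
#' @export
read_study <- function(roster, items = NULL, peg = NULL, max_report = 20) {
  probs <- character(0)
  ro <- .read_csv(roster)
  .check_cols(ro, c("subject_id", "cohort", "sex", "age"), roster)
  if (!"pair_id" %in% names(ro)) ro$pair_id <- NA_character_
  if (!"zygosity" %in% names(ro)) ro$zygosity <- NA_character_
  probs <- c(probs,
             .vocab_errors(ro, "cohort", .vocab$cohort, roster),
             .vocab_errors(ro, "sex", .vocab$sex, roster),
             .vocab_errors(ro, "zygosity", .vocab$zygosity, roster,
                           required = FALSE))
  # MZ pairs must be same-sex
  tw <- ro[ro$cohort == "twin" & !is.na(ro$pair_id) & !is.na(ro$zygosity), ]
  for (pid in unique(tw$pair_id[tw$zygosity == "MZ"])) {
    sx <- tw$sex[tw$pair_id == pid]
    if (length(unique(sx[!is.na(sx)])) > 1)
      probs <- c(probs, sprintf("%s: MZ pair '%s' has discordant sexes",
                                roster, pid))
  }
  it <- NULL
  if (!is.null(items)) {
    it <- .read_csv(items)
    # accept either 'item' or 'item_id' as the item column name
    if (!"item" %in% names(it) && "item_id" %in% names(it))
      names(it)[names(it) == "item_id"] <- "item"
    .check_cols(it, c("subject_id", "item", "hand"), items)
    if (!"degree" %in% names(it)) it$degree <- NA_character_
    e <- c(.vocab_errors(it, "item", ehi_items(), items),
           .vocab_errors(it, "hand", .vocab$hand, items),
           .vocab_errors(it[!is.na(it$hand) & it$hand != "either", ],
                         "degree", .vocab$degree, items))
    dup <- duplicated(it[, c("subject_id", "item")])
    if (any(dup))
      e <- c(e, sprintf("%s line %d: duplicate response for subject '%s' item '%s'",
                        items, which(dup) + 1L, it$subject_id[dup], it$item[dup]))
    probs <- c(probs, e)
    ok <- !is.na(it$hand) & it$hand %in% .vocab$hand &
      it$item %in% ehi_items() & !dup &
      (it$hand == "either" | it$degree %in% .vocab$degree)
    it <- it[ok, , drop = FALSE]
  }
  pg <- NULL
  if (!is.null(peg)) {
    pg <- .read_csv(peg)
    .check_cols(pg, c("subject_id", "hand", "trial_index", "time_seconds"), peg)
    e <- .vocab_errors(pg, "hand", .vocab$peg_hand, peg)
    badt <- which(!is.na(pg$time_seconds) & pg$time_seconds <= 0)
    if (length(badt))
      e <- c(e, sprintf("%s line %d: non-positive time_seconds", peg, badt + 1L))
    probs <- c(probs, e)
    ok <- pg$hand %in% .vocab$peg_hand & !is.na(pg$time_seconds) &
      pg$time_seconds > 0
    pg <- pg[ok, , drop = FALSE]
  }
  if (nrow(ro) == 0 || (is.null(it) && is.null(pg)))
    stop("no usable study data", call. = FALSE)
  if (length(probs))
    warning(sprintf("%d row-level validation problem(s), offending rows dropped:\n%s",
                    length(probs),
                    paste(utils::head(probs, max_report), collapse = "\n")),
            call. = FALSE)
  structure(list(roster = ro, items = it, peg = pg, validation = probs),
            class = "study_bundle")
}

#' Wide twin-pair layout from scored subject-level data
#'
#' Joins scored measures with the roster and reshapes twin subjects into one
#' row per pair: `pair_id`, `zygosity`, `sex1`, `sex2`, `age`, and
#' `<trait>_t1` / `<trait>_t2` for each requested trait. Twin order follows
#' subject order within pair in the roster.
#'
#' @param scored subject-level data.frame (from [score_cohort()]).
#' @param roster roster data.frame.
#' @param traits measure columns to carry.
#' @return wide data.frame, one row per twin pair.
#' @export
build_twin_wide <- function(scored, roster,
                            traits = c("EHI", "PegQ", "writing_bin",
                                       "drawing_bin", "EHI2", "PegQ2")) {
  tw <- roster[roster$cohort == "twin" & !is.na(roster$pair_id), , drop = FALSE]
  m <- merge(tw, scored, by = "subject_id", all.x = TRUE, sort = FALSE)
  m <- m[order(match(m$subject_id, roster$subject_id)), , drop = FALSE]
  out <- NULL
  for (pid in unique(m$pair_id)) {
    pp <- m[m$pair_id == pid, , drop = FALSE]
    if (nrow(pp) != 2) next
    row <- data.frame(pair_id = pid, zygosity = pp$zygosity[1],
                      sex1 = pp$sex[1], sex2 = pp$sex[2], age = pp$age[1],
                      stringsAsFactors = FALSE)
    for (tr in traits) {
      row[[paste0(tr, "_t1")]] <- pp[[tr]][1]
      row[[paste0(tr, "_t2")]] <- pp[[tr]][2]
    }
    out <- rbind(out, row)
  }
  out
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes scoring, prevalence analysis (per-item preference tables,
#' direction prevalence, score means, sample-by-sex ANOVA, cross-measure
#' correlations, inventory reliability) and the twin models (univariate
#' ACE/AE/CE/E ladders for the six handedness measures; bivariate Cholesky
#' ladder for the two continuous scores), writing TSV/JSON reports.
#'
#' @param bundle a `study_bundle` from [read_study()], or a list with
#'   `roster`, `items`, `peg` data.frames (e.g. from [simulate_cohort()]).
#' @param out_dir output directory (created if needed); NULL = no files.
#' @param run_twin_models logical toggles for the heritability stages.
#' @param run_bivariate logical.
#' @param ss_type ANOVA sums-of-squares type ("III" default).
#' @param corrected_item_total use item-rest correlations if TRUE.
#' @param restarts optimizer restarts for twin models.
#' @param seed seed for the (jittered) optimizer restarts.
#' @return list of result objects (invisibly also written as reports).
#' @export
run_pipeline <- function(bundle, out_dir = NULL, run_twin_models = TRUE,
                         run_bivariate = TRUE, ss_type = "III",
                         corrected_item_total = FALSE, restarts = 5,
                         seed = 1L) {
  set.seed(seed)
  roster <- bundle$roster
  scored <- score_cohort(bundle$items, bundle$peg)
  scored <- scored[match(intersect(roster$subject_id, scored$subject_id),
                         scored$subject_id), , drop = FALSE]
  grp_cohort <- stats::setNames(roster$cohort, roster$subject_id)
  grp_sex <- stats::setNames(roster$sex, roster$subject_id)
  res <- list(scored = scored)
  # prevalence stage -----------------------------------------------------
  if (!is.null(bundle$items)) {
    res$item_tests_cohort <- item_preference_tests(bundle$items, grp_cohort)
    res$item_tests_sex <- item_preference_tests(bundle$items, grp_sex)
    pts <- score_item(bundle$items$hand, bundle$items$degree)
    isc <- bundle$items
    isc$score <- pts$right_points - pts$left_points
    wide <- stats::reshape(isc[, c("subject_id", "item", "score")],
                           idvar = "subject_id", timevar = "item",
                           direction = "wide")
    mat <- as.matrix(wide[, -1, drop = FALSE])
    colnames(mat) <- sub("^score\\.", "", colnames(mat))
    res$item_total_r <- item_total_correlations(mat,
                                                corrected = corrected_item_total)
    res$cronbach_alpha <- tryCatch(cronbach_alpha(mat), error = function(e) NA)
  }
  res$direction_cohort <- direction_prevalence_tests(scored, grp_cohort)
  res$direction_sex <- direction_prevalence_tests(scored, grp_sex)
  idx <- match(scored$subject_id, roster$subject_id)
  sample_f <- roster$cohort[idx]; sex_f <- roster$sex[idx]
  res$means_EHI <- score_means(scored$EHI, sample_f)
  res$means_PegQ <- score_means(scored$PegQ, sample_f)
  res$anova_EHI <- tryCatch(
    anova_sample_sex(scored$EHI, sample_f, sex_f, ss_type = ss_type),
    error = function(e) NULL)
  res$anova_PegQ <- tryCatch(
    anova_sample_sex(scored$PegQ, sample_f, sex_f, ss_type = ss_type),
    error = function(e) NULL)
  cm_in <- data.frame(age = roster$age[idx],
                      sex = as.integer(roster$sex[idx] == "female"),
                      scored[, c("writing_bin", "drawing_bin", "EHI", "EHI2",
                                 "PegQ", "PegQ2")])
  res$correlations <- correlation_matrix(cm_in)
  # twin-model stage ------------------------------------------------------
  if (run_twin_models) {
    wide_tw <- build_twin_wide(scored, roster)
    res$twin_wide <- wide_tw
    zy <- wide_tw$zygosity
    measures <- list(EHI = "continuous", PegQ = "continuous",
                     writing_bin = "binary_liability",
                     drawing_bin = "binary_liability",
                     EHI2 = "binary_liability", PegQ2 = "binary_liability")
    res$univariate <- lapply(names(measures), function(tr) {
      Y <- as.matrix(wide_tw[, paste0(tr, c("_t1", "_t2"))])
      tryCatch(univariate_ladder(Y, zy, kind = measures[[tr]],
                                 restarts = restarts)$table,
               error = function(e) NULL)
    })
    names(res$univariate) <- names(measures)
    res$homogeneity_EHI <- tryCatch(
      homogeneity_ladder(as.matrix(wide_tw[, c("EHI_t1", "EHI_t2")]), zy,
                         wide_tw$sex1, wide_tw$sex2),
      error = function(e) NULL)
    if (run_bivariate) {
      Yb <- as.matrix(wide_tw[, c("EHI_t1", "PegQ_t1", "EHI_t2", "PegQ_t2")])
      lad <- fit_bivariate_ladder(Yb, zy, restarts = restarts)
      res$bivariate <- lad$table
      res$bivariate_best <- lad$best
      res$correlated_factors <- to_correlated_factors(lad$fits[[lad$best]])
    }
  }
  # reports ---------------------------------------------------------------
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    .write_tsv(scored, file.path(out_dir, "scored.tsv"))
    if (!is.null(res$item_tests_cohort))
      .write_tsv(res$item_tests_cohort, file.path(out_dir, "item_tests_cohort.tsv"))
    .write_tsv(res$direction_cohort, file.path(out_dir, "direction_cohort.tsv"))
    .write_tsv(rbind(cbind(score = "EHI", res$means_EHI),
                     cbind(score = "PegQ", res$means_PegQ)),
               file.path(out_dir, "score_means.tsv"))
    if (!is.null(res$correlations))
      .write_tsv(as.data.frame(round(res$correlations$r, 3)),
                 file.path(out_dir, "correlations.tsv"))
    if (run_twin_models && length(res$univariate)) {
      uv <- do.call(rbind, lapply(names(res$univariate), function(m)
        if (!is.null(res$univariate[[m]])) cbind(measure = m, res$univariate[[m]])))
      if (!is.null(uv)) .write_tsv(uv, file.path(out_dir, "univariate_models.tsv"))
    }
    if (run_twin_models && run_bivariate && !is.null(res$bivariate))
      .write_tsv(res$bivariate, file.path(out_dir, "bivariate_models.tsv"))
    summ <- list(seed = seed, n_subjects = nrow(scored),
                 cronbach_alpha = res$cronbach_alpha,
                 bivariate_best = res$bivariate_best,
                 package_version = as.character(utils::packageVersion("handtwin")))
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(res)
}
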