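# Scoring of the 10-item hand-preference inventory and the pegboard task.

#' The ten inventory items
#'
#' Canonical item identifiers of the child-adapted 10-item hand-preference
#' inventory ("chopsticks" replaces the adult item "striking a match").
#'
#' @return Character vector of the 10 item ids, in instrument order.
#' @export
ehi_items <- function() {
  c("writing", "drawing", "throwing", "scissors", "toothbrush",
    "chopsticks", "spoon", "knife", "broom", "box_lid")
}

#' Items entering the 8-item switch-inference composite
#' @return Character vector: all items except writing and drawing.
#' @export
ehi_items_noww <- function() {
  setdiff(ehi_items(), c("writing", "drawing"))
}

.check_hand <- function(hand) {
  bad <- !is.na(hand) & !hand %in% c("left", "right", "either")
  if (any(bad))
    stop("invalid value in field 'hand': ", paste(unique(hand[bad]), collapse = ", "),
         " (expected left/right/either)", call. = FALSE)
}

.check_degree <- function(hand, degree) {
  need <- !is.na(hand) & hand != "either"
  bad <- need & (is.na(degree) | !degree %in% c("always", "usually"))
  if (any(bad))
    stop("invalid value in field 'degree': ",
         paste(unique(degree[bad]), collapse = ", "),
         " (expected always/usually when hand is left/right)", call. = FALSE)
}

#' Point decomposition of one inventory response
#'
#' Converts responses to Left/Right column points: "always" puts 2 points in
#' the preferred column, "usually" 1 point in the preferred column (0 in the
#' other), and "either" 1 point in both columns. Vectorised.
#'
#' @param hand character: "left", "right" or "either".
#' @param degree character: "always" or "usually"; ignored when
#'   `hand == "either"`.
#' @return data.frame with integer columns `left_points`, `right_points`.
#' @examples
#' score_item("right", "always")   # 0 left, 2 right
#' score_item("either", NA)        # 1 and 1
#' @export
score_item <- function(hand, degree = NA_character_) {
  n <- max(length(hand), length(degree))
  hand <- rep_len(as.character(hand), n)
  degree <- rep_len(as.character(degree), n)
  .check_hand(hand)
  .check_degree(hand, degree)
  pts <- ifelse(hand == "either", 1L, ifelse(degree == "always", 2L, 1L))
  left <- ifelse(is.na(hand), NA_integer_,
                 ifelse(hand == "right", 0L, pts))
  right <- ifelse(is.na(hand), NA_integer_,
                  ifelse(hand == "left", 0L, pts))
  data.frame(left_points = as.integer(left), right_points = as.integer(right))
}

#' Laterality quotient from a subject's inventory responses
#'
#' Sums Left/Right column points over the selected items and applies
#' (RH - LH) / (RH + LH). Missing items are simply omitted; a record with no
#' usable item in the subset is an error (no silent zero).
#'
#' @param responses data.frame with columns `item`, `hand`, `degree` for one
#'   subject (at most one row per item).
#' @param items item subset to score over; default all 10.
#' @return list with `value` (in \[-1, 1\]), `lh_sum`, `rh_sum`, `n_items`.
#' @export
compute_ehi <- function(responses, items = ehi_items()) {
  if (length(items) == 0) stop("empty item subset", call. = FALSE)
  unknown <- setdiff(items, ehi_items())
  if (length(unknown))
    stop("unknown item id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  r <- responses[responses$item %in% items & !is.na(responses$hand), , drop = FALSE]
  if (anyDuplicated(r$item)) stop("duplicate item response", call. = FALSE)
  if (nrow(r) == 0)
    stop("no usable item responses in the selected subset", call. = FALSE)
  pts <- score_item(r$hand, r$degree)
  lh <- sum(pts$left_points)
  rh <- sum(pts$right_points)
  list(value = (rh - lh) / (rh + lh), lh_sum = lh, rh_sum = rh,
       n_items = nrow(r))
}

#' Binarise a laterality quotient at zero
#'
#' Scores greater than zero are right-handed (1); scores less than or equal
#' to zero are non-right-handed (0). Used for both EHI2 and PegQ2.
#'
#' @param value numeric laterality score(s).
#' @return integer vector of 0/1 (NA propagated).
#' @export
classify_direction <- function(value) {
  ifelse(is.na(value), NA_integer_, ifelse(value > 0, 1L, 0L))
}

#' @rdname classify_direction
#' @export
classify_ehi2 <- classify_direction

#' @rdname classify_direction
#' @export
classify_pegq2 <- classify_direction

#' Binary recode of a single item (right = 1, left or no preference = 0)
#'
#' @param hand character hand response; NA propagates to NA.
#' @return integer 0/1 vector.
#' @export
recode_item_binary <- function(hand) {
  .check_hand(hand)
  ifelse(is.na(hand), NA_integer_, ifelse(hand == "right", 1L, 0L))
}

#' Three-class recode of a single item
#'
#' Left preference (always or usually) -> "LH", no preference -> "NP",
#' right preference -> "RH".
#'
#' @param hand character hand response.
#' @return character vector in {"LH","NP","RH"} (NA propagated).
#' @export
recode_item_three_class <- function(hand) {
  .check_hand(hand)
  ifelse(is.na(hand), NA_character_,
         c(left = "LH", either = "NP", right = "RH")[hand])
}

#' Infer a possible writing-hand switch
#'
#' TRUE when the subject writes with the right hand but, over the eight items
#' other than writing and drawing, the summed left-column points exceed the
#' right-column points (an overall left preference despite right-handed
#' writing). Requires the writing item and at least one of the eight
#' composite items; otherwise NA.
#'
#' @param responses one subject's responses (`item`, `hand`, `degree`).
#' @return logical scalar or NA.
#' @export
infer_switch <- function(responses) {
  w <- responses[responses$item == "writing" & !is.na(responses$hand), , drop = FALSE]
  r8 <- responses[responses$item %in% ehi_items_noww() & !is.na(responses$hand), ,
                  drop = FALSE]
  if (nrow(w) != 1 || nrow(r8) == 0) return(NA)
  if (recode_item_binary(w$hand) != 1L) return(FALSE)
  pts <- score_item(r8$hand, r8$degree)
  sum(pts$left_points) > sum(pts$right_points)
}

#' Pegboard laterality index from timed trials
#'
#' For each hand the three fastest of (nominally five) trials are averaged;
#' the index is 2(L - R)/(L + R) on those means, positive when the right hand
#' is faster. Ties among trial times are resolved by keeping the earliest
#' trials (the mean is unaffected).
#'
#' @param left_times,right_times numeric trial durations in seconds (>0),
#'   at least 3 per hand.
#' @return list with `value` (in (-2, 2)), `left_mean`, `right_mean`.
#' @export
compute_pegq <- function(left_times, right_times) {
  for (x in list(left_times, right_times)) {
    if (sum(!is.na(x)) < 3)
      stop("fewer than 3 trials on one hand", call. = FALSE)
    if (any(x <= 0, na.rm = TRUE))
      stop("non-positive trial time", call. = FALSE)
  }
  best3 <- function(x) mean(sort(x[!is.na(x)])[1:3])
  L <- best3(left_times); R <- best3(right_times)
  list(value = 2 * (L - R) / (L + R), left_mean = L, right_mean = R)
}

#' Score a whole cohort
#'
#' Applies the full scoring stage to long-format inventory responses and
#' pegboard trials, producing one row per subject with the six handedness
#' measures and the switch-inference flag.
#'
#' @param item_responses data.frame: `subject_id`, `item`, `hand`, `degree`.
#' @param peg_trials data.frame: `subject_id`, `hand` ("left"/"right"),
#'   `trial_index`, `time_seconds`. May be NULL.
#' @return data.frame with columns `subject_id`, `writing_bin`,
#'   `drawing_bin`, `EHI`, `EHI2`, `PegQ`, `PegQ2`, `switch_flag`,
#'   `n_items_used`. Subjects missing a whole instrument get NA there.
#' @export
score_cohort <- function(item_responses, peg_trials = NULL) {
  ids <- unique(c(as.character(item_responses$subject_id),
                  if (!is.null(peg_trials)) as.character(peg_trials$subject_id)))
  out <- data.frame(subject_id = ids, writing_bin = NA_integer_,
                    drawing_bin = NA_integer_, EHI = NA_real_,
                    EHI2 = NA_integer_, PegQ = NA_real_, PegQ2 = NA_integer_,
                    switch_flag = NA, n_items_used = 0L,
                    stringsAsFactors = FALSE)
  by_subj <- split(item_responses, as.character(item_responses$subject_id))
  for (sid in names(by_subj)) {
    r <- by_subj[[sid]]
    i <- match(sid, out$subject_id)
    w <- r$hand[r$item == "writing"]
    d <- r$hand[r$item == "drawing"]
    if (length(w) == 1) out$writing_bin[i] <- recode_item_binary(w)
    if (length(d) == 1) out$drawing_bin[i] <- recode_item_binary(d)
    usable <- r[!is.na(r$hand), , drop = FALSE]
    if (nrow(usable) > 0) {
      e <- compute_ehi(usable, items = ehi_items())
      out$EHI[i] <- e$value
      out$EHI2[i] <- classify_direction(e$value)
      out$n_items_used[i] <- e$n_items
    }
    out$switch_flag[i] <- infer_switch(r)
  }
  if (!is.null(peg_trials) && nrow(peg_trials) > 0) {
    by_subj <- split(peg_trials, as.character(peg_trials$subject_id))
    for (sid in names(by_subj)) {
      p <- by_subj[[sid]]
      i <- match(sid, out$subject_id)
      lt <- p$time_seconds[p$hand == "left"]
      rt <- p$time_seconds[p$hand == "right"]
      if (sum(!is.na(lt)) >= 3 && sum(!is.na(rt)) >= 3) {
        q <- compute_pegq(lt, rt)
        out$PegQ[i] <- q$value
        out$PegQ2[i] <- classify_direction(q$value)
      }
    }
  }
  out
}
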