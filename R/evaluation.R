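#' Majority vote over an odd rater panel
#'
#' @param ratings Character vector of "T"/"F" (or logical vector); must have
#'   odd length so a strict majority always exists.
#' @return "T" or "F".
#' @examples
#' majority_vote(c("T", "T", "F"))
#' @export
majority_vote <- function(ratings) {
  if (length(ratings) < 1 || length(ratings) %% 2 == 0) {
    abort("configuration error: majority voting requires an odd number of ratings")
  }
  logi <- as_tf(ratings)
  if (sum(logi) * 2 > length(logi)) "T" else "F"
}

as_tf <- function(x) {
  if (is.logical(x)) return(x)
  if (!all(x %in% c("T", "F"))) abort("ratings must be 'T'/'F' or logical")
  x == "T"
}

#' Confusion counts
#'
#' Container for the true/false positive/negative tallies feeding the
#' evaluation metrics.
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A one-row tibble of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(is.na(counts)) || any(counts < 0)) {
    abort("confusion counts must be non-negative")
  }
  structure(
    tibble(tp = as.integer(tp), tn = as.integer(tn),
           fp = as.integer(fp), fn = as.integer(fn)),
    class = c("confusion_counts", class(tibble())))
}

#' Tally a rating panel into confusion counts
#'
#' Derives per-item ground truth from the panel (majority vote across the
#' `rater_<k>` columns, or a single rater's column) and compares it with the
#' system's output flag: the system asserting an item the truth confirms is a
#' TP; asserting what the truth rejects is an FP; not asserting what the
#' truth rejects is a TN; not asserting what the truth confirms is an FN.
#'
#' @param panel Panel tibble (see [simulate_rater_panel()]): `item_id`,
#'   `system_flag`, and `rater_1` ... `rater_k` columns.
#' @param truth `"majority"` (default) or the integer index of a single rater
#'   to take as ground truth.
#' @return A [confusion_counts()] object.
#' @export
confusion_from_panel <- function(panel, truth = "majority") {
  rater_cols <- grep("^rater_[0-9]+$", names(panel), value = TRUE)
  if (length(rater_cols) == 0) abort("panel has no rater_<k> columns")
  truth_vec <- panel_truth(panel, rater_cols, truth)
  sys <- panel$system_flag
  confusion_counts(
    tp = sum(sys & truth_vec),
    tn = sum(!sys & !truth_vec),
    fp = sum(sys & !truth_vec),
    fn = sum(!sys & truth_vec)
  )
}

panel_truth <- function(panel, rater_cols, truth) {
  if (identical(truth, "majority")) {
    ratings <- as.matrix(panel[rater_cols]) == "T"
    if (length(rater_cols) %% 2 == 0) {
      abort("configuration error: majority truth requires an odd rater count")
    }
    rowSums(ratings) * 2 > length(rater_cols)
  } else {
    col <- paste0("rater_", truth)
    if (!col %in% rater_cols) abort(paste0("no such rater column: ", col))
    panel[[col]] == "T"
  }
}

metric_value <- function(num, den, name) {
  if (den == 0) {
    abort(paste0("undefined metric: ", name,
                 " has a zero denominator (refusing to report 0)"))
  }
  num / den
}

#' Evaluation metrics from confusion counts
#'
#' Accuracy `(TN+TP)/(TN+TP+FN+FP)`, specificity `TN/(TN+FP)`, sensitivity
#' `TP/(TP+FN)` and precision `TP/(TP+FP)`. A zero denominator raises an
#' error - an undefined metric must never be silently reported as 0.
#'
#' @param counts A [confusion_counts()] object (or one-row data frame with
#'   columns tp/tn/fp/fn).
#' @return A proportion in `[0, 1]`.
#' @examples
#' accuracy(confusion_counts(tp = 45, tn = 48, fp = 3, fn = 4))
#' @export
accuracy <- function(counts) {
  with(counts, metric_value(tn + tp, tn + tp + fn + fp, "accuracy"))
}

#' @rdname accuracy
#' @export
specificity <- function(counts) {
  with(counts, metric_value(tn, tn + fp, "specificity"))
}

#' @rdname accuracy
#' @export
sensitivity <- function(counts) {
  with(counts, metric_value(tp, tp + fn, "sensitivity"))
}

#' @rdname accuracy
#' @export
precision <- function(counts) {
  with(counts, metric_value(tp, tp + fp, "precision"))
}

#' Mean squared error between actual and predicted binary sequences
#'
#' `MSE = (1/n) * sum((A_i - P_i)^2)`. Over binary correctness indicators
#' this equals `1 - accuracy`.
#'
#' @param actual,predicted Numeric or logical vectors of equal positive
#'   length.
#' @return Non-negative real.
#' @examples
#' mse(c(1, 0, 1), c(1, 1, 1))
#' @export
mse <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    abort("`actual` and `predicted` must have equal length")
  }
  if (length(actual) == 0) abort("mse needs at least one observation")
  mean((as.numeric(actual) - as.numeric(predicted))^2)
}

safe_metric <- function(f, counts) {
  tryCatch(f(counts), error = function(e) NA_real_)
}

metric_block <- function(panel, rater_cols, truth) {
  counts <- confusion_from_panel(panel, truth)
  truth_vec <- panel_truth(panel, rater_cols, truth)
  tibble(
    tp = counts$tp, tn = counts$tn, fp = counts$fp, fn = counts$fn,
    accuracy = safe_metric(accuracy, counts),
    sensitivity = safe_metric(sensitivity, counts),
    specificity = safe_metric(specificity, counts),
    precision = safe_metric(precision, counts),
    mse = mse(truth_vec, panel$system_flag)
  )
}

#' Evaluate system reports against a rater panel
#'
#' Reconciles report items with panel items (every panel item the system
#' asserted must be a report item and vice versa), derives ground truth per
#' item (majority vote by default), and computes overall, per-category
#' (`drug_dose`, `ddi`, `k_raising`) and per-patient confusion counts and
#' metrics, plus a running MSE curve over patients. In the per-category and
#' per-patient tables a metric whose denominator is zero is reported as `NA`
#' (the scalar metric functions raise instead).
#'
#' @param reports Item tibble from [generate_reports()].
#' @param panel Panel tibble (see [simulate_rater_panel()] for the layout;
#'   external rater CSVs with the same columns work too).
#' @param truth `"majority"` or a rater index.
#' @return A `metric_report`: list with `overall` (one-row tibble),
#'   `per_category`, `per_patient`, `mse_curve`, `truth`, `n_items`.
#' @export
evaluate_cohort <- function(reports, panel, truth = "majority") {
  rater_cols <- grep("^rater_[0-9]+$", names(panel), value = TRUE)
  if (length(rater_cols) == 0) abort("panel has no rater_<k> columns")
  if (!all(c("item_id", "patient_id", "category", "system_flag") %in%
           names(panel))) {
    abort("panel must have item_id, patient_id, category, system_flag columns")
  }

  asserted <- panel$item_id[panel$system_flag]
  missing_in_reports <- setdiff(asserted, reports$item_id)
  missing_in_panel <- setdiff(reports$item_id, asserted)
  if (length(missing_in_reports) > 0 || length(missing_in_panel) > 0) {
    abort(paste0(
      "reconciliation error: ", length(missing_in_reports),
      " panel item(s) not in reports, ", length(missing_in_panel),
      " report item(s) not in panel; first: ",
      head(c(missing_in_reports, missing_in_panel), 1)
    ))
  }

  overall <- metric_block(panel, rater_cols, truth)
  per_category <- panel |>
    dplyr::group_by(.data$category) |>
    dplyr::group_modify(~ metric_block(.x, rater_cols, truth)) |>
    dplyr::ungroup()
  per_patient <- panel |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(~ metric_block(.x, rater_cols, truth)) |>
    dplyr::ungroup()

  # running MSE as patients accumulate, in patient order
  truth_vec <- panel_truth(panel, rater_cols, truth)
  err <- (as.numeric(truth_vec) - as.numeric(panel$system_flag))^2
  ord <- order(match(panel$patient_id, unique(panel$patient_id)))
  per_item <- tibble(patient_id = panel$patient_id[ord], err = err[ord])
  mse_curve <- per_item |>
    dplyr::mutate(cum_mse = cumsum(.data$err) / dplyr::row_number()) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(running_mse = dplyr::last(.data$cum_mse),
                     .groups = "drop") |>
    dplyr::mutate(n_patients = dplyr::row_number())

  structure(
    list(overall = overall, per_category = per_category,
         per_patient = per_patient, mse_curve = mse_curve,
         truth = truth, n_items = nrow(panel)),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>", x$n_items, "items, truth =",
      if (identical(x$truth, "majority")) "majority vote" else
        paste("rater", x$truth), "\n")
  print(x$overall)
  cat("per category:\n")
  print(x$per_category)
  invisible(x)
}

#' @describeIn evaluate_cohort Per-category metric tibble.
#' @param x A `metric_report`.
#' @param ... Unused.
#' @export
tidy.metric_report <- function(x, ...) {
  x$per_category
}

#' @describeIn evaluate_cohort One-row overall metric summary.
#' @export
glance.metric_report <- function(x, ...) {
  dplyr::bind_cols(x$overall, tibble(n_items = x$n_items))
}
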