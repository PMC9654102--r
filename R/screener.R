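#' Built-in sociodemographic subgroups
#'
#' The five binary risk-factor subgroups used when stratifying screener
#' performance: households with children, highest education high school or
#' diploma, not living with a spouse/partner, household income under
#' $70,000, and welfare receipt.
#'
#' @return Named character vector mapping subgroup labels to the
#'   demographic column that defines each subgroup.
#' @export
fs_subgroups <- function() {
  c("Households with children" = "has_children",
    "Highschool or diploma" = "highschool_or_diploma",
    "Not living with spouse" = "not_living_with_spouse",
    "Income under 70,000" = "income_under_70000",
    "Welfare recipient" = "welfare_recipient")
}

#' Apply an OR-rule screener
#'
#' A brief screener flags a respondent as food insecure if *any* of its
#' items is affirmed.
#'
#' @param a Affirmation vector (length 10) or n x 10 matrix.
#' @param items Item ids of the screener, a non-empty subset of 1..10.
#' @return Logical: `TRUE` = screener positive.
#' @examples
#' apply_screener(c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0), items = c(1, 3))
#' @export
apply_screener <- function(a, items) {
  items <- as.integer(items)
  if (length(items) == 0L || anyNA(items) || any(items < 1L | items > 10L))
    stop("'items' must be a non-empty subset of 1..10", call. = FALSE)
  if (is.matrix(a)) return(rowSums(a[, items, drop = FALSE]) > 0)
  if (length(a) != 10L) stop("'a' must have length 10", call. = FALSE)
  sum(a[items]) > 0
}

#' Cross-tabulate a screener against the reference standard
#'
#' Builds the 2x2 confusion table of an OR-rule screener against the
#' 10-item reference classification (>= `reference_threshold` affirmed
#' conditions).
#'
#' @param records Respondent data frame.
#' @param items Screener item ids (see [apply_screener()]).
#' @param reference_threshold Reference cut-point, default 3 (low or very
#'   low food security).
#' @return A `confusion_table` object: list with integer counts `tp`,
#'   `fp`, `tn`, `fn` (summing to `nrow(records)`).
#' @export
cross_tabulate <- function(records, items, reference_threshold = 3L) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  a <- affirmation_matrix(records)
  confusion_table(
    positive = apply_screener(a, items),
    reference = reference_status(a, reference_threshold)
  )
}

#' Construct a confusion table from classifications
#'
#' @param positive Logical vector: screener positive.
#' @param reference Logical vector: reference food insecure.
#' @return A `confusion_table` object (counts `tp`, `fp`, `tn`, `fn`).
#' @export
confusion_table <- function(positive, reference) {
  stopifnot(length(positive) == length(reference),
            !anyNA(positive), !anyNA(reference))
  structure(list(tp = sum(positive & reference),
                 fp = sum(positive & !reference),
                 tn = sum(!positive & !reference),
                 fn = sum(!positive & reference)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(screener = c("positive", "negative"),
                              reference = c("insecure", "secure")))
  print(m, ...)
  invisible(x)
}

#' Diagnostic accuracy of a screener
#'
#' Standard operating characteristics from a 2x2 confusion table, on the
#' percentage scale: sensitivity `100 tp / (tp + fn)`, specificity
#' `100 tn / (tn + fp)`, accuracy `100 (tp + tn) / n`, and reference
#' prevalence `100 (tp + fn) / n`.  These satisfy the identity
#' `accuracy = (sensitivity * prevalence + specificity * (100 - prevalence)) / 100`.
#'
#' When a class is absent (no reference-insecure respondents, or no
#' reference-secure ones) the corresponding metric is undefined and
#' reported as `NA` with a warning -- never silently as 0 or 100.
#'
#' @param ct A `confusion_table`.
#' @return A `diagnostic_result` object: list with `sensitivity`,
#'   `specificity`, `accuracy`, `prevalence` (percent, full precision),
#'   `n`, and the `counts`.
#' @examples
#' diagnostics(confusion_table(positive = c(TRUE, TRUE, FALSE),
#'                             reference = c(TRUE, FALSE, FALSE)))
#' @export
diagnostics <- function(ct) {
  stopifnot(inherits(ct, "confusion_table"))
  n <- ct$tp + ct$fp + ct$tn + ct$fn
  if (n == 0L) stop("empty confusion table", call. = FALSE)
  pos <- ct$tp + ct$fn
  neg <- ct$tn + ct$fp
  sens <- if (pos > 0) 100 * ct$tp / pos else NA_real_
  spec <- if (neg > 0) 100 * ct$tn / neg else NA_real_
  if (pos == 0L)
    warning("no reference-insecure records: sensitivity undefined",
            call. = FALSE)
  if (neg == 0L)
    warning("no reference-secure records: specificity undefined",
            call. = FALSE)
  structure(list(sensitivity = sens, specificity = spec,
                 accuracy = 100 * (ct$tp + ct$tn) / n,
                 prevalence = 100 * pos / n,
                 n = n, counts = ct),
            class = "diagnostic_result")
}

#' @export
print.diagnostic_result <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f", round_half_up(v, 1))
  cat(sprintf(
    "sensitivity %s  specificity %s  accuracy %s  (reference prevalence %s, n = %d)\n",
    fmt(x$sensitivity), fmt(x$specificity), fmt(x$accuracy),
    fmt(x$prevalence), x$n))
  invisible(x)
}

#' Per-item affirmation prevalence
#'
#' Percentage of respondents affirming each of the 10 items, either among
#' reference-insecure respondents (the basis for choosing screener
#' candidate items: the most-affirmed items among the insecure) or among
#' the whole sample.
#'
#' @param records Respondent data frame.
#' @param among `"insecure"` (default) or `"all"`.
#' @param reference_threshold Reference cut-point for `"insecure"`.
#' @return Named numeric vector of 10 percentages.
#' @export
affirmation_prevalence <- function(records, among = c("insecure", "all"),
                                   reference_threshold = 3L) {
  among <- match.arg(among)
  a <- affirmation_matrix(as.data.frame(records))
  if (among == "insecure")
    a <- a[reference_status(a, reference_threshold), , drop = FALSE]
  if (nrow(a) == 0L)
    stop("denominator group is empty", call. = FALSE)
  100 * colMeans(a)
}

#' Evaluate all candidate 2-item screeners, overall and by subgroup
#'
#' Enumerates every unordered pair from `candidate_items`, applies each as
#' an OR-rule screener, and cross-tabulates it against the 10-item
#' reference standard for all households and within each subgroup
#' (subgroup rows re-run the full cross-tabulation on the filtered
#' records; respondents with missing demographics contribute only to the
#' all-households stratum).
#'
#' @param records Respondent data frame.
#' @param candidate_items Items from which pairs are drawn, default
#'   `1:3` (the most-affirmed items among the food insecure).
#' @param subgroups Named character vector of demographic columns, as
#'   [fs_subgroups()]; `NULL` for no stratification.
#' @param reference_threshold Reference cut-point, default 3.
#' @return A `screener_report` data frame, one row per stratum x pair:
#'   columns `stratum`, `items` (label like `"1+3"`), `item_a`, `item_b`,
#'   `n`, `prevalence`, `sensitivity`, `specificity`, `accuracy`, `tp`,
#'   `fp`, `tn`, `fn`.  Percentages are full precision; undefined metrics
#'   are `NA`.
#' @seealso [select_best()], [brief_screener()]
#' @export
evaluate_pairs <- function(records, candidate_items = 1:3,
                           subgroups = fs_subgroups(),
                           reference_threshold = 3L) {
  records <- as.data.frame(records)
  candidate_items <- sort(unique(as.integer(candidate_items)))
  if (length(candidate_items) < 2L)
    stop("need at least two candidate items", call. = FALSE)
  pairs <- utils::combn(candidate_items, 2L, simplify = FALSE)

  strata <- c(list("All households" = rep(TRUE, nrow(records))),
              lapply(subgroups, function(col) {
                v <- records[[col]]
                if (is.null(v))
                  stop("records lack demographic column ", col, call. = FALSE)
                !is.na(v) & as.logical(v)
              }))
  if (length(subgroups)) names(strata)[-1L] <- names(subgroups)

  rows <- list()
  for (s in names(strata)) {
    sub <- records[strata[[s]], , drop = FALSE]
    for (p in pairs) {
      d <- if (nrow(sub) == 0L) NULL else
        suppressWarnings(diagnostics(
          cross_tabulate(sub, p, reference_threshold)))
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, items = paste(p, collapse = "+"),
        item_a = p[1], item_b = p[2],
        n = if (is.null(d)) 0L else d$n,
        prevalence = if (is.null(d)) NA_real_ else d$prevalence,
        sensitivity = if (is.null(d)) NA_real_ else d$sensitivity,
        specificity = if (is.null(d)) NA_real_ else d$specificity,
        accuracy = if (is.null(d)) NA_real_ else d$accuracy,
        tp = if (is.null(d)) NA_integer_ else d$counts$tp,
        fp = if (is.null(d)) NA_integer_ else d$counts$fp,
        tn = if (is.null(d)) NA_integer_ else d$counts$tn,
        fn = if (is.null(d)) NA_integer_ else d$counts$fn,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("screener_report", "data.frame"),
            reference_threshold = reference_threshold)
}

#' @export
print.screener_report <- function(x, ...) {
  cat(sprintf(
    "Two-item OR-rule screeners vs 10-item reference (>= %d affirmations)\n\n",
    attr(x, "reference_threshold")))
  fmt <- function(v) ifelse(is.na(v), "--", sprintf("%.1f", round_half_up(v, 1)))
  for (s in unique(x$stratum)) {
    sub <- x[x$stratum == s, , drop = FALSE]
    cat(sprintf("%s (n = %d, reference prevalence %s%%)\n", s, sub$n[1],
                fmt(sub$prevalence[1])))
    disp <- data.frame(items = sub$items,
                       sensitivity = fmt(sub$sensitivity),
                       specificity = fmt(sub$specificity),
                       accuracy = fmt(sub$accuracy))
    print(disp, row.names = FALSE)
    cat("\n")
  }
  invisible(x)
}

#' Select the recommended screener pair
#'
#' Picks, from a [evaluate_pairs()] report, the pair with the highest
#' all-households accuracy; ties are broken by higher sensitivity, then by
#' lower item numbers.  Accuracy is the primary criterion because it
#' combines sensitivity and specificity on the observed case mix;
#' sensitivity breaks ties because a screening context favours not missing
#' food-insecure patients.
#'
#' @param report A `screener_report`.
#' @return Integer vector of the two selected item ids, with the winning
#'   row's metrics attached as attribute `metrics`.
#' @export
select_best <- function(report) {
  all_rows <- report[report$stratum == "All households" &
                       !is.na(report$accuracy), , drop = FALSE]
  if (nrow(all_rows) == 0L)
    stop("no pair has defined metrics for the all-households stratum",
         call. = FALSE)
  ord <- order(-all_rows$accuracy,
               -ifelse(is.na(all_rows$sensitivity), -Inf, all_rows$sensitivity),
               all_rows$item_a, all_rows$item_b)
  best <- all_rows[ord[1L], ]
  structure(c(best$item_a, best$item_b), metrics = best)
}
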