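#' Derive a brief food-insecurity screener from survey data
#'
#' The central fitting function of the package.  Given scored survey
#' records, it evaluates every unordered pair of `candidate_items` as an
#' OR-rule screener (positive if either item is affirmed) against the
#' 10-item reference standard (food insecure at `reference_threshold` or
#' more affirmed conditions), overall and within sociodemographic
#' subgroups, and selects the recommended pair: highest all-households
#' accuracy, ties broken by sensitivity, then by lower item numbers.
#'
#' @param data Respondent data frame from [read_records()] or
#'   [simulate_respondents()].
#' @param candidate_items Items from which pairs are drawn; default `1:3`,
#'   the items most often affirmed by food-insecure households.
#' @param reference_threshold Reference cut-point on the 10-item score,
#'   default 3 (low or very low food security).
#' @param subgroups Named character vector of demographic columns
#'   ([fs_subgroups()] by default); `NULL` disables stratification.
#' @return An object of class `brief_screener` with components
#'   `recommended` (item ids of the selected pair), `metrics` (its
#'   all-households diagnostics), `report` (the full
#'   [evaluate_pairs()] table), `prevalence` (the [prevalence_table()]),
#'   `item_prevalence` (per-item affirmation % among the reference
#'   insecure), `reference_threshold`, `n`, and `call`.
#' @examples
#' d <- simulate_respondents(generator_config(n = 2000, seed = 11))
#' fit <- brief_screener(d)
#' fit
#' summary(fit)
#' table(predict(fit, d[1:20, ]))
#' @seealso [predict.brief_screener()], [plot.brief_screener()]
#' @export
brief_screener <- function(data, candidate_items = 1:3,
                           reference_threshold = 3L,
                           subgroups = fs_subgroups()) {
  data <- as.data.frame(data)
  report <- evaluate_pairs(data, candidate_items = candidate_items,
                           subgroups = subgroups,
                           reference_threshold = reference_threshold)
  best <- select_best(report)
  item_prev <- tryCatch(
    affirmation_prevalence(data, among = "insecure",
                           reference_threshold = reference_threshold),
    error = function(e) rep(NA_real_, 10L))
  structure(list(recommended = as.integer(best),
                 metrics = attr(best, "metrics"),
                 report = report,
                 prevalence = prevalence_table(data),
                 item_prevalence = item_prev,
                 reference_threshold = reference_threshold,
                 n = nrow(data),
                 call = match.call()),
            class = "brief_screener")
}

#' @export
print.brief_screener <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f", round_half_up(v, 1))
  cat("Brief food-insecurity screener\n")
  cat(sprintf("  n = %d respondents; reference: 10-item score >= %d\n",
              x$n, x$reference_threshold))
  cat(sprintf("  recommended pair: items %d + %d (affirm either)\n",
              x$recommended[1], x$recommended[2]))
  cat(sprintf("  sensitivity %s%%, specificity %s%%, accuracy %s%%\n",
              fmt(x$metrics$sensitivity), fmt(x$metrics$specificity),
              fmt(x$metrics$accuracy)))
  invisible(x)
}

#' @export
summary.brief_screener <- function(object, ...) {
  structure(object, class = c("summary.brief_screener", "brief_screener"))
}

#' @export
print.summary.brief_screener <- function(x, ...) {
  print.brief_screener(x)
  cat("\n")
  print(x$prevalence)
  cat("\n")
  print(x$report)
  invisible(x)
}

#' Apply a fitted brief screener to new respondents
#'
#' @param object A `brief_screener` fit.
#' @param newdata Respondent data frame (same layout as the training
#'   data).
#' @param items Optional item ids overriding the recommended pair.
#' @param ... Unused.
#' @return Factor with levels `negative`/`positive`, one per row of
#'   `newdata`.
#' @export
predict.brief_screener <- function(object, newdata, items = object$recommended,
                                   ...) {
  pos <- apply_screener(affirmation_matrix(as.data.frame(newdata)), items)
  factor(ifelse(pos, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Plot screener operating characteristics
#'
#' Grouped bar chart of sensitivity, specificity and accuracy for every
#' candidate pair in the all-households stratum, with the recommended
#' pair highlighted.
#'
#' @param x A `brief_screener` fit.
#' @param ... Passed to [graphics::barplot()].
#' @return `x`, invisibly.
#' @export
plot.brief_screener <- function(x, ...) {
  rep_all <- x$report[x$report$stratum == "All households", , drop = FALSE]
  m <- t(as.matrix(rep_all[, c("sensitivity", "specificity", "accuracy")]))
  colnames(m) <- paste("items", rep_all$items)
  rec_lab <- paste("items", paste(x$recommended, collapse = "+"))
  graphics::barplot(m, beside = TRUE, ylim = c(0, 100),
                    legend.text = c("sensitivity", "specificity", "accuracy"),
                    args.legend = list(x = "bottomright", bg = "white"),
                    col = c("grey30", "grey60", "grey85"),
                    ylab = "%", ...)
  graphics::mtext(sprintf("recommended: %s", rec_lab), side = 3, line = 0.2,
                  cex = 0.9)
  invisible(x)
}
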