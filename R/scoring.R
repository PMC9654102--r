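.fs_levels <- c("food_secure", "marginal", "low", "very_low")

.instrument_items <- list(ten_item = 1:10, six_item = 2:7, two_item = 1:2)

#' Raw food-security score
#'
#' Counts affirmed food-insecure conditions over the item set of an
#' instrument: all 10 items, items 2-7 (6-item short form), or items 1-2
#' (2-item form).
#'
#' @param a An affirmation vector of length 10, or an n x 10 affirmation
#'   matrix (see [affirmation_matrix()]).
#' @param instrument `"ten_item"`, `"six_item"` or `"two_item"`.
#' @return Integer score(s): one value for a vector, one per row for a
#'   matrix.
#' @examples
#' raw_score(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), "six_item")  # items 2 and 3
#' @export
raw_score <- function(a, instrument = c("ten_item", "six_item", "two_item")) {
  instrument <- match.arg(instrument)
  idx <- .instrument_items[[instrument]]
  if (is.matrix(a)) {
    stopifnot(ncol(a) == 10L)
    return(as.integer(rowSums(a[, idx, drop = FALSE])))
  }
  if (length(a) != 10L || !all(a %in% 0:1))
    stop("'a' must be a binary vector of length 10", call. = FALSE)
  as.integer(sum(a[idx]))
}

#' Severity classification for the 10-item HFSSM
#'
#' Maps the 10-item raw score to the four ordered severity levels:
#' 0 affirmations is food secure, 1-2 marginal food security, 3-5 low food
#' security, 6 or more very low food security.  A household is food
#' insecure whenever its level is not `food_secure`.
#'
#' @param score Integer vector of raw scores in 0..10.
#' @return Ordered factor with levels `food_secure < marginal < low <
#'   very_low`.
#' @seealso [classify_6()], [classify_2()], [is_insecure()]
#' @export
classify_10 <- function(score) {
  .check_score(score, 10L)
  lv <- ifelse(score == 0, 1L, ifelse(score <= 2, 2L, ifelse(score <= 5, 3L, 4L)))
  factor(.fs_levels[lv], levels = .fs_levels, ordered = TRUE)
}

#' Severity classification for the 6-item HFSSM
#'
#' 0 affirmations is food secure, 1 marginal, 2-4 low, 5-6 very low food
#' security (the standard 6-item categories).
#'
#' @param score Integer vector of raw scores in 0..6.
#' @return Ordered factor as in [classify_10()].
#' @export
classify_6 <- function(score) {
  .check_score(score, 6L)
  lv <- ifelse(score == 0, 1L, ifelse(score == 1, 2L, ifelse(score <= 4, 3L, 4L)))
  factor(.fs_levels[lv], levels = .fs_levels, ordered = TRUE)
}

#' Binary classification for the 2-item HFSSM
#'
#' Food insecure if one or more of items 1 and 2 is affirmed.
#'
#' @param score Integer vector of raw scores in 0..2.
#' @return Logical vector, `TRUE` = food insecure.
#' @export
classify_2 <- function(score) {
  .check_score(score, 2L)
  score >= 1
}

#' Binary classification for the single-item measure
#'
#' The single national-survey question ("run out of food and not been able
#' to purchase more"): yes is food insecure, no is food secure.
#'
#' @param answer Character vector of `"yes"`/`"no"`.
#' @return Logical vector, `TRUE` = food insecure.
#' @export
classify_single <- function(answer) {
  bad <- !(answer %in% c("yes", "no"))
  if (any(bad))
    stop("illegal single-item answer: ", sQuote(answer[bad][1]), call. = FALSE)
  answer == "yes"
}

.check_score <- function(score, max) {
  if (any(is.na(score)) || any(score < 0) || any(score > max) ||
      any(score != floor(score)))
    stop(sprintf("score must be an integer in 0..%d", max), call. = FALSE)
  invisible(TRUE)
}

#' Food-insecure flag of a severity level
#'
#' @param level Ordered factor from [classify_10()] or [classify_6()].
#' @return Logical vector: `TRUE` unless the level is `food_secure`.
#' @export
is_insecure <- function(level) level != "food_secure"

#' Reference-standard classification
#'
#' The reference measure for screener evaluation: food insecure iff the
#' 10-item raw score reaches `threshold` affirmed conditions.  The default
#' threshold of 3 corresponds to low or very low food security.
#'
#' @param a Affirmation vector or matrix (see [raw_score()]).
#' @param threshold Minimum number of affirmations, >= 1.
#' @return Logical: `TRUE` = reference food insecure.
#' @export
reference_status <- function(a, threshold = 3L) {
  if (length(threshold) != 1L || is.na(threshold) || threshold < 1)
    stop("'threshold' must be a single integer >= 1", call. = FALSE)
  raw_score(a, "ten_item") >= threshold
}

#' Prevalence of food insecurity by instrument
#'
#' Tabulates, for one respondent dataset, the percentage food secure and
#' food insecure under the single-item measure and the 2-, 6- and 10-item
#' HFSSM, and the severity breakdown (marginal vs low-or-very-low) for the
#' two instruments that can grade severity.
#'
#' @param records Respondent data frame ([read_records()] /
#'   [simulate_respondents()]).
#' @return A `prevalence_table` object: a data frame with rows
#'   `food_secure`, `food_insecure`, `marginal`, `low_or_very_low` and
#'   columns `single_item`, `two_item`, `six_item`, `ten_item`, holding
#'   percentages of `nrow(records)` at full precision (`NA` where an
#'   instrument cannot grade severity).  Its print method rounds to one
#'   decimal.
#' @examples
#' prevalence_table(simulate_respondents(generator_config(n = 500, seed = 1)))
#' @export
prevalence_table <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  a <- affirmation_matrix(records)
  n <- nrow(records)
  pct <- function(x) 100 * sum(x) / n

  c10 <- classify_10(raw_score(a, "ten_item"))
  c6 <- classify_6(raw_score(a, "six_item"))
  ins <- list(
    single_item = classify_single(as.character(records$single_item)),
    two_item = classify_2(raw_score(a, "two_item")),
    six_item = is_insecure(c6),
    ten_item = is_insecure(c10)
  )
  tab <- data.frame(row.names = c("food_secure", "food_insecure",
                                  "marginal", "low_or_very_low"))
  for (col in names(ins)) {
    sev <- switch(col, six_item = c6, ten_item = c10, NULL)
    tab[[col]] <- c(pct(!ins[[col]]), pct(ins[[col]]),
                    if (is.null(sev)) c(NA_real_, NA_real_) else
                      c(pct(sev == "marginal"), pct(sev >= "low")))
  }
  structure(tab, class = c("prevalence_table", "data.frame"), n = n)
}

## round half up to `digits` decimals (mirrors the conventional table
## presentation; base round() is round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  z <- round(abs(x) * p, 8)   # shed binary representation error first
  sign(x) * floor(z + 0.5) / p
}

#' @export
print.prevalence_table <- function(x, ...) {
  cat(sprintf("Food-security prevalence (n = %d), %% of respondents\n\n",
              attr(x, "n")))
  disp <- as.data.frame(lapply(x, function(col)
    ifelse(is.na(col), "NA", sprintf("%.1f", round_half_up(col, 1)))),
    row.names = row.names(x))
  names(disp) <- names(x)
  print(disp, ...)
  invisible(x)
}
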