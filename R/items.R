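#' The 10-item adult HFSSM item bank
#'
#' Returns the item bank for the 10 adult items of the US Household Food
#' Security Survey Module (HFSSM) as administered to households without
#' reference to children: item text, response mode, follow-up structure,
#' and membership in the 6-item and 2-item short forms.
#'
#' Items 1-3 are statements answered on a trichotomous scale (often true /
#' sometimes true / never true); items 4, 6, 7, 8 and 9 are yes/no
#' questions; items 5 and 10 are frequency follow-ups ("How often did this
#' happen?") asked only when their parent item (4 and 9 respectively) is
#' answered yes.  The 6-item short form uses items 2-7; the standard 2-item
#' form uses items 1 and 2.
#'
#' @return A data frame with one row per item and columns `item_id`,
#'   `text`, `response_mode` (one of `"trichotomous"`, `"yes_no"`,
#'   `"frequency"`), `parent_item` (`NA` except 5 -> 4 and 10 -> 9),
#'   `in_6item`, `in_2item`.
#' @examples
#' hfssm_items()[, c("item_id", "response_mode", "in_6item", "in_2item")]
#' @export
hfssm_items <- function() {
  data.frame(
    item_id = 1:10,
    text = c(
      "I worried whether my/our food would run out before I/we got money to buy more.",
      "The food that I/we bought just didn't last, and I/we didn't have money to get more.",
      "I/we couldn't afford to eat balanced meals.",
      "In the last month, did you or other adults in your household ever cut the size of your meals or skip meals because there wasn't enough money for food?",
      "How often did this happen?",
      "In the last month, did you ever eat less than you felt you should because there wasn't enough money for food?",
      "In the last month, were you ever hungry but didn't eat because there wasn't enough money for food?",
      "In the last month, did you lose weight because there wasn't enough money for food?",
      "In the last month, did you or other adults in your household ever not eat for a whole day because there wasn't enough money for food?",
      "How often did this happen?"
    ),
    response_mode = c(rep("trichotomous", 3), "yes_no", "frequency",
                      rep("yes_no", 4), "frequency"),
    parent_item = c(NA, NA, NA, NA, 4L, NA, NA, NA, NA, 9L),
    in_6item = 1:10 %in% 2:7,
    in_2item = 1:10 %in% 1:2,
    stringsAsFactors = FALSE
  )
}

## legal answer tokens per response mode (CSV dialect, lowercase snake_case)
.tokens <- list(
  trichotomous = c("often_true", "sometimes_true", "never_true"),
  yes_no       = c("yes", "no"),
  frequency    = c("almost_every_month", "some_months", "only_1_or_2_months", "na")
)

## answers coded 1 (a reported food-insecure condition), by mode
.affirmative <- list(
  trichotomous = c("often_true", "sometimes_true"),
  yes_no       = "yes",
  frequency    = c("almost_every_month", "some_months")
)

.demographic_cols <- c("has_children", "highschool_or_diploma",
                       "not_living_with_spouse", "income_under_70000",
                       "welfare_recipient")

.instrument_cols <- c(paste0("q", 1:10), "single_item")

#' Code a raw answer as affirmative or not
#'
#' Maps one raw answer for one HFSSM item to its binary "food-insecure
#' condition" indicator.  Often true and sometimes true are affirmative on
#' the trichotomous items; yes on the yes/no items; almost every month and
#' some months on the frequency follow-ups.  `"na"` (follow-up not asked
#' because the parent item was negative) codes 0.
#'
#' @param item_id Item number, 1-10.
#' @param answer Character vector of raw answer tokens (see
#'   [hfssm_items()] for the response mode of each item; tokens are
#'   lowercase snake_case, e.g. `"often_true"`, `"yes"`,
#'   `"almost_every_month"`, `"na"`).
#' @return Integer vector of 0/1, same length as `answer`.
#' @examples
#' code_affirmative(1, c("often_true", "sometimes_true", "never_true"))
#' code_affirmative(5, "na")
#' @export
code_affirmative <- function(item_id, answer) {
  item_id <- as.integer(item_id)
  if (length(item_id) != 1L || is.na(item_id) || item_id < 1L || item_id > 10L)
    stop("'item_id' must be a single integer in 1..10", call. = FALSE)
  mode <- hfssm_items()$response_mode[item_id]
  bad <- !(answer %in% .tokens[[mode]])
  if (any(bad))
    stop(sprintf("illegal answer %s for item %d (%s)",
                 paste(sQuote(unique(answer[bad])), collapse = ", "),
                 item_id, mode), call. = FALSE)
  as.integer(answer %in% .affirmative[[mode]])
}

#' Affirmation vector of a single respondent
#'
#' Converts one respondent's raw answers into the 10-element binary vector
#' of reported food-insecure conditions used by every score.
#'
#' @param record A one-row data frame (or list) with columns/fields
#'   `q1`..`q10` holding raw answer tokens.
#' @return Integer vector of length 10 (named `q1`..`q10`).
#' @seealso [affirmation_matrix()] for whole datasets.
#' @export
affirmation_vector <- function(record) {
  ans <- vapply(paste0("q", 1:10), function(col) {
    v <- record[[col]]
    if (is.null(v) || length(v) != 1L)
      stop("record must carry exactly one answer for ", col, call. = FALSE)
    as.character(v)
  }, character(1))
  .check_skip_pattern(ans["q4"], ans["q5"], 5L)
  .check_skip_pattern(ans["q9"], ans["q10"], 10L)
  a <- vapply(1:10, function(i) code_affirmative(i, ans[[paste0("q", i)]]),
              integer(1))
  names(a) <- paste0("q", 1:10)
  a
}

.check_skip_pattern <- function(parent, child, child_id, row = NULL) {
  where <- if (is.null(row)) "" else sprintf(" (row %d)", row)
  viol <- (parent == "no" & child != "na") | (parent == "yes" & child == "na")
  viol[is.na(viol)] <- FALSE
  if (any(viol))
    stop(sprintf(
      "skip-pattern violation for item %d%s: follow-up must be 'na' exactly when item %d is 'no'",
      child_id, where, child_id - 1L), call. = FALSE)
  invisible(TRUE)
}

#' Affirmation matrix of a dataset
#'
#' @param records A respondent data frame as returned by [read_records()]
#'   or [simulate_respondents()].
#' @return An `nrow(records)` x 10 integer 0/1 matrix, columns `q1`..`q10`.
#'   Element `[r, i]` is 1 iff respondent `r` reported the food-insecure
#'   condition of item `i`.
#' @export
affirmation_matrix <- function(records) {
  records <- as.data.frame(records)
  .check_skip_pattern(records$q4, records$q5, 5L)
  .check_skip_pattern(records$q9, records$q10, 10L)
  a <- vapply(1:10,
              function(i) code_affirmative(i, as.character(records[[paste0("q", i)]])),
              integer(nrow(records)))
  a <- matrix(as.integer(a), nrow = nrow(records), ncol = 10L,
              dimnames = list(NULL, paste0("q", 1:10)))
  a
}
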