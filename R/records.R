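#' Read respondent records from CSV
#'
#' Reads a survey CSV in the package's dialect: header
#' `q1,...,q10,single_item,has_children,highschool_or_diploma,
#' not_living_with_spouse,income_under_70000,welfare_recipient`, one row
#' per respondent, lowercase snake_case answer tokens, and `true`/`false`
#' demographic flags.
#'
#' Rows with any missing instrument answer (any of `q1`..`q10` or
#' `single_item` blank or absent) are excluded from the returned data and
#' counted, mirroring the listwise-exclusion rule used when respondents
#' skip food-security questions.  Missing demographics do not exclude a
#' row: such records are scored in whole-sample analyses and simply never
#' match a subgroup.  Malformed tokens and skip-pattern violations (a
#' frequency follow-up answered although its parent item is `no`, or
#' marked `na` although the parent is `yes`) are errors naming the row.
#'
#' @param path Path to the CSV file.
#' @return A data frame of complete records with character instrument
#'   columns and logical demographic columns, plus attributes
#'   `attempted` (data rows in the file) and `excluded` (rows dropped for
#'   missing instrument answers).
#' @seealso [write_records()], the inverse.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_records(simulate_respondents(generator_config(n = 5, seed = 1)), f)
#' r <- read_records(f)
#' attr(r, "excluded")
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", strip.white = TRUE,
                        na.strings = character(0))
  expected <- c(.instrument_cols, .demographic_cols)
  unknown <- setdiff(names(df), expected)
  if (length(unknown))
    stop("unknown column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  missing_cols <- setdiff(expected, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- df[, expected]
  if (nrow(df) == 0L) stop("empty file: ", path, call. = FALSE)

  attempted <- nrow(df)
  blank <- function(x) is.na(x) | x == ""
  incomplete <- Reduce(`|`, lapply(df[.instrument_cols], blank))
  kept <- df[!incomplete, , drop = FALSE]
  rows <- which(!incomplete)  # original data-row numbers, for messages

  items <- hfssm_items()
  for (i in 1:10) {
    col <- paste0("q", i)
    legal <- .tokens[[items$response_mode[i]]]
    bad <- !(kept[[col]] %in% legal)
    if (any(bad))
      stop(sprintf("row %d, column %s: unrecognised token %s",
                   rows[which(bad)[1]], col,
                   sQuote(kept[[col]][which(bad)[1]])), call. = FALSE)
  }
  bad <- !(kept$single_item %in% c("yes", "no"))
  if (any(bad))
    stop(sprintf("row %d, column single_item: unrecognised token %s",
                 rows[which(bad)[1]], sQuote(kept$single_item[which(bad)[1]])),
         call. = FALSE)

  for (fu in list(c(4L, 5L), c(9L, 10L))) {
    parent <- kept[[paste0("q", fu[1])]]
    child <- kept[[paste0("q", fu[2])]]
    viol <- (parent == "no" & child != "na") | (parent == "yes" & child == "na")
    if (any(viol))
      stop(sprintf(
        "row %d: skip-pattern violation, q%d must be 'na' exactly when q%d is 'no'",
        rows[which(viol)[1]], fu[2], fu[1]), call. = FALSE)
  }

  for (col in .demographic_cols) {
    v <- tolower(kept[[col]])
    bad <- !(v %in% c("true", "false", "", NA))
    if (any(bad))
      stop(sprintf("row %d, column %s: expected true/false, got %s",
                   rows[which(bad)[1]], col, sQuote(kept[[col]][which(bad)[1]])),
           call. = FALSE)
    kept[[col]] <- ifelse(blank(v), NA, v == "true")
  }

  rownames(kept) <- NULL
  structure(kept, attempted = attempted, excluded = sum(incomplete))
}

#' Write respondent records to CSV
#'
#' Writes records in the same dialect [read_records()] reads; the
#' round trip preserves every affirmation vector and demographic flag.
#' Simulation-only columns (the latent severity `theta`) are dropped.
#'
#' @param records Respondent data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  records <- as.data.frame(records)
  cols <- c(.instrument_cols, .demographic_cols)
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols))
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- records[, cols, drop = FALSE]
  for (col in .demographic_cols)
    out[[col]] <- ifelse(is.na(out[[col]]), "",
                         ifelse(as.logical(out[[col]]), "true", "false"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
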