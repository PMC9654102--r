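# Builders for respondent records used across the test files.

# One record row from a 10-element 0/1 affirmation vector.  Affirmed
# trichotomous items read "sometimes_true"; affirmed frequency follow-ups
# "some_months"; a follow-up whose parent is affirmed but which is not
# itself affirmed reads "only_1_or_2_months".
record_from_affirm <- function(a, single = "no",
                               has_children = FALSE,
                               highschool_or_diploma = FALSE,
                               not_living_with_spouse = FALSE,
                               income_under_70000 = FALSE,
                               welfare_recipient = FALSE) {
  stopifnot(length(a) == 10, all(a %in% 0:1),
            a[5] <= a[4], a[10] <= a[9])
  freq <- function(parent, child)
    if (!parent) "na" else if (child) "some_months" else "only_1_or_2_months"
  data.frame(
    q1 = if (a[1]) "sometimes_true" else "never_true",
    q2 = if (a[2]) "sometimes_true" else "never_true",
    q3 = if (a[3]) "sometimes_true" else "never_true",
    q4 = if (a[4]) "yes" else "no",
    q5 = freq(a[4], a[5]),
    q6 = if (a[6]) "yes" else "no",
    q7 = if (a[7]) "yes" else "no",
    q8 = if (a[8]) "yes" else "no",
    q9 = if (a[9]) "yes" else "no",
    q10 = freq(a[9], a[10]),
    single_item = single,
    has_children = has_children,
    highschool_or_diploma = highschool_or_diploma,
    not_living_with_spouse = not_living_with_spouse,
    income_under_70000 = income_under_70000,
    welfare_recipient = welfare_recipient,
    stringsAsFactors = FALSE
  )
}

records_from_matrix <- function(A, ...) {
  do.call(rbind, lapply(seq_len(nrow(A)), function(r)
    record_from_affirm(A[r, ], ...)))
}

secure_records <- function(n) records_from_matrix(matrix(0L, n, 10))

# random legal affirmation matrix honouring the skip pattern
random_affirm_matrix <- function(n, p = 0.3) {
  A <- matrix(rbinom(n * 10, 1, p), n, 10)
  A[, 5] <- A[, 5] & A[, 4]
  A[, 10] <- A[, 10] & A[, 9]
  A + 0L
}
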