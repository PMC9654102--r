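test_that("OR-rule screeners flag any affirmed item", {
  v <- c(1, 0, 0, rep(0, 7))
  expect_true(apply_screener(v, c(1, 3)))
  expect_false(apply_screener(rep(0, 10), c(1, 3)))
  expect_false(apply_screener(v, c(2, 3)))
  expect_error(apply_screener(v, integer(0)), "non-empty")
  expect_error(apply_screener(v, 11), "1..10")
})

test_that("cross tabulation reproduces a hand-worked 2x2", {
  A <- rbind(c(1, 1, 1, rep(0, 7)),   # ref + (3 affirm), screener {1,3} +
             c(1, rep(0, 9)),         # ref - , screener +
             rep(0, 10),              # ref - , screener -
             c(0, 1, 1, 1, rep(0, 6)))# ref + , screener + (item 3)
  ct <- cross_tabulate(records_from_matrix(A), c(1, 3))
  expect_equal(ct[c("tp", "fp", "tn", "fn")],
               list(tp = 2L, fp = 1L, tn = 1L, fn = 0L))

  ct <- cross_tabulate(secure_records(10), c(1, 3))
  expect_equal(ct[c("tp", "fp", "tn", "fn")],
               list(tp = 0L, fp = 0L, tn = 10L, fn = 0L))
  expect_error(cross_tabulate(secure_records(0), c(1, 3)), "no records")
})

test_that("cross_tabulate agrees with a brute-force per-record loop", {
  set.seed(101)
  for (trial in 1:25) {
    n <- sample(500, 1)
    A <- random_affirm_matrix(n, p = runif(1, 0.05, 0.6))
    recs <- records_from_matrix(A)
    items <- sort(sample(10, sample(2:3, 1)))
    thr <- sample(1:4, 1)
    ct <- cross_tabulate(recs, items, thr)
    tp <- fp <- tn <- fn <- 0L
    for (r in seq_len(n)) {
      ref <- sum(A[r, ]) >= thr
      pos <- any(A[r, items] == 1)
      if (ref && pos) tp <- tp + 1L else if (!ref && pos) fp <- fp + 1L
      else if (!ref && !pos) tn <- tn + 1L else fn <- fn + 1L
    }
    expect_identical(ct[c("tp", "fp", "tn", "fn")],
                     list(tp = tp, fp = fp, tn = tn, fn = fn))
  }
})

test_that("diagnostics computes the standard definitions and their identity", {
  d <- diagnostics(structure(list(tp = 9L, fp = 1L, tn = 90L, fn = 0L),
                             class = "confusion_table"))
  expect_equal(d$sensitivity, 100)
  expect_equal(hfssm:::round_half_up(d$specificity, 1), 98.9)
  expect_equal(hfssm:::round_half_up(d$accuracy, 1), 99.0)
  expect_equal(d$prevalence, 9)
  expect_equal(d$accuracy,
               (d$sensitivity * d$prevalence +
                  d$specificity * (100 - d$prevalence)) / 100,
               tolerance = 1e-12)
})

test_that("absent classes yield explicit undefined metrics, never 0 or 100", {
  ct <- structure(list(tp = 0L, fp = 2L, tn = 5L, fn = 0L),
                  class = "confusion_table")
  expect_warning(d <- diagnostics(ct), "sensitivity undefined")
  expect_true(is.na(d$sensitivity))
  expect_false(is.na(d$specificity))
  ct <- structure(list(tp = 3L, fp = 0L, tn = 0L, fn = 1L),
                  class = "confusion_table")
  expect_warning(d <- diagnostics(ct), "specificity undefined")
  expect_true(is.na(d$specificity))
})

test_that("growing the item set is monotone for positivity, sensitivity and specificity", {
  d <- simulate_respondents(generator_config(n = 3000, seed = 21))
  A <- affirmation_matrix(d)
  base <- c(1, 3)
  pos1 <- apply_screener(A, base)
  for (extra in c(2, 4, 8)) {
    pos2 <- apply_screener(A, c(base, extra))
    expect_true(all(pos2[pos1]))        # never turns a positive negative
    d1 <- diagnostics(cross_tabulate(d, base))
    d2 <- diagnostics(cross_tabulate(d, c(base, extra)))
    expect_gte(d2$sensitivity, d1$sensitivity)
    expect_lte(d2$specificity, d1$specificity)
  }
})

test_that("per-item affirmation prevalence matches hand counts", {
  A <- rbind(c(0, 0, 1, rep(0, 7)), rep(0, 10))
  p <- affirmation_prevalence(records_from_matrix(A), among = "all")
  expect_equal(unname(p[3]), 50)
  expect_equal(unname(p[1]), 0)
  # every reference-insecure record affirms item 1
  A <- rbind(c(1, 1, 1, rep(0, 7)), c(1, 1, 1, 1, rep(0, 6)), rep(0, 10))
  p <- affirmation_prevalence(records_from_matrix(A), among = "insecure")
  expect_equal(unname(p[1]), 100)
  expect_error(affirmation_prevalence(secure_records(2), among = "insecure"),
               "empty")
})

test_that("evaluate_pairs covers all pairs and strata with per-stratum denominators", {
  set.seed(55)
  A <- random_affirm_matrix(120, p = 0.25)
  recs <- records_from_matrix(A)
  recs$income_under_70000 <- rep(c(TRUE, FALSE), 60)
  rep_tab <- evaluate_pairs(recs)
  expect_setequal(unique(rep_tab$items), c("1+2", "1+3", "2+3"))
  expect_setequal(unique(rep_tab$stratum),
                  c("All households", names(fs_subgroups())))
  expect_equal(nrow(rep_tab), 3 * 6)
  # subgroup rows are full cross-tabs on the filtered records
  sub <- recs[recs$income_under_70000, ]
  want <- suppressWarnings(diagnostics(cross_tabulate(sub, c(1, 3))))
  got <- rep_tab[rep_tab$stratum == "Income under 70,000" &
                   rep_tab$items == "1+3", ]
  expect_equal(got$sensitivity, want$sensitivity)
  expect_equal(got$n, nrow(sub))
})

test_that("a partitioning pair of subgroups sums to the all-households table", {
  set.seed(77)
  recs <- records_from_matrix(random_affirm_matrix(200, p = 0.3))
  recs$has_children <- rep(c(TRUE, FALSE), 100)
  in_g <- cross_tabulate(recs[recs$has_children, ], c(1, 2))
  out_g <- cross_tabulate(recs[!recs$has_children, ], c(1, 2))
  all_g <- cross_tabulate(recs, c(1, 2))
  for (cell in c("tp", "fp", "tn", "fn"))
    expect_equal(in_g[[cell]] + out_g[[cell]], all_g[[cell]])
})

test_that("an all-secure dataset yields undefined sensitivity and full specificity", {
  rep_tab <- suppressWarnings(evaluate_pairs(secure_records(15)))
  expect_true(all(is.na(rep_tab$sensitivity)))
  nonempty <- rep_tab$n > 0   # all-false demographics leave subgroup strata empty
  expect_true(any(nonempty))
  expect_true(all(rep_tab$specificity[nonempty] == 100))
})

test_that("selection maximises accuracy with sensitivity then item-order tie-breaks", {
  mk <- function(items, acc, sens) {
    p <- as.integer(strsplit(items, "\\+")[[1]])
    data.frame(stratum = "All households", items = items,
               item_a = p[1], item_b = p[2], n = 100L, prevalence = 10,
               sensitivity = sens, specificity = NA_real_, accuracy = acc,
               tp = NA_integer_, fp = NA_integer_, tn = NA_integer_,
               fn = NA_integer_)
  }
  rep_tab <- structure(rbind(mk("1+2", 97.3, 82.4), mk("2+3", 98.0, 93.3),
                             mk("1+3", 98.7, 85.7)),
                       class = c("screener_report", "data.frame"))
  expect_equal(as.integer(select_best(rep_tab)), c(1L, 3L))

  rep_tab <- structure(rbind(mk("1+2", 98, 80), mk("2+3", 98, 90)),
                       class = c("screener_report", "data.frame"))
  expect_equal(as.integer(select_best(rep_tab)), c(2L, 3L))

  rep_tab <- structure(rbind(mk("1+2", 98, 90), mk("2+3", 98, 90)),
                       class = c("screener_report", "data.frame"))
  expect_equal(as.integer(select_best(rep_tab)), c(1L, 2L))

  expect_equal(as.integer(select_best(structure(mk("2+3", 95, 70),
                                                class = c("screener_report", "data.frame")))),
               c(2L, 3L))
})
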