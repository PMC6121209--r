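test_that("score_outcome_table tallies per-patient records and round-trips", {
  pts <- tibble::tibble(s = c(0, 0, 1, 2, 2), dead = c(0, 0, 0, 1, 1))
  tab <- score_outcome_table(pts, s, dead)
  expect_equal(tab$score, c(0, 1, 2))
  expect_equal(tab$dead, c(0L, 0L, 2L))
  expect_equal(tab$alive, c(2L, 1L, 0L))

  # materializing and re-tabulating any fixture is the identity
  for (fx in table_fixtures()) {
    back <- score_outcome_table(materialize_table(fx), score, dead_30d)
    expect_equal(as.data.frame(back), as.data.frame(fx))
  }
})

test_that("metrics_at_cutoff agrees with a patient-materializing oracle", {
  withr::with_seed(101, {
    for (i in 1:200) {
      tab <- random_table()
      cuts <- c(min(tab$score) - 1, tab$score, max(tab$score) + 1)
      for (ct in cuts) {
        got <- metrics_at_cutoff(tab, ct)
        want <- brute_metrics(tab, ct)
        for (f in names(want)) expect_equal(got[[f]], want[[f]])
        expect_equal(got$youden_j, got$sensitivity + got$specificity - 1)
      }
    }
  })
})

test_that("cutoff below the minimum score classifies everyone positive", {
  tab <- table_fixtures()$ich_score
  m <- metrics_at_cutoff(tab, min(tab$score) - 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0)
  expect_equal(m$lr_pos, 1)
})

test_that("sensitivity falls and specificity rises as the cutoff rises", {
  withr::with_seed(202, {
    for (i in 1:100) {
      tab <- random_table()
      cuts <- seq(min(tab$score) - 1, max(tab$score) + 1)
      m <- purrr::map_dfr(cuts, ~ metrics_at_cutoff(tab, .x))
      expect_false(is.unsorted(rev(m$sensitivity)))
      expect_false(is.unsorted(m$specificity))
    }
  })
})

test_that("degenerate one-class tables are rejected", {
  all_dead <- new_score_outcome_table(0:2, c(1L, 2L, 3L), c(0L, 0L, 0L))
  expect_error(metrics_at_cutoff(all_dead, 1), "[Dd]egenerate")
  expect_error(auc(all_dead), "[Dd]egenerate")
  expect_error(roc_points(all_dead), "[Dd]egenerate")
  expect_error(youden_optimal_cutoff(all_dead), "[Dd]egenerate")
})

test_that("ROC points include endpoints and are monotone; fixture gives nine", {
  one <- new_score_outcome_table(3, 4L, 5L)
  r1 <- roc_points(one)
  expect_equal(unique(r1[c("fpr", "tpr")]), tibble::tibble(fpr = c(0, 1), tpr = c(0, 1)))

  sep <- new_score_outcome_table(c(0, 5), c(0L, 7L), c(6L, 0L))
  expect_true(any(roc_points(sep)$fpr == 0 & roc_points(sep)$tpr == 1))

  r <- roc_points(table_fixtures()$ich_score)
  expect_equal(nrow(r), 9)
  expect_false(is.unsorted(r$fpr))
  expect_false(is.unsorted(r$tpr))
  expect_true(all(r$tpr >= r$fpr))  # curve on or above the diagonal
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[9], 1); expect_equal(r$tpr[9], 1)
})

test_that("pair-count AUC equals the ROC trapezoid exactly and matches oracles", {
  withr::with_seed(303, {
    for (i in 1:1000) {
      tab <- random_table()
      expect_identical(auc(tab), auc(tab, "trapezoid"))
    }
    for (i in 1:50) {
      tab <- random_table()
      expect_equal(auc(tab), brute_auc(tab))
    }
  })
})

test_that("AUC matches pROC on materialized patients", {
  skip_if_not_installed("pROC")
  withr::with_seed(404, {
    for (i in 1:20) {
      tab <- random_table()
      pts <- materialize_table(tab)
      ref <- suppressMessages(pROC::auc(pROC::roc(pts$dead_30d, pts$score,
                                                  direction = "<", quiet = TRUE)))
      expect_equal(auc(tab), as.numeric(ref))
    }
  })
})

test_that("AUC is invariant under increasing relabeling and flips under outcome swap", {
  withr::with_seed(505, {
    for (i in 1:100) {
      tab <- random_table()
      relabeled <- tab
      relabeled$score <- tab$score^2 + 3 * tab$score + 1  # strictly increasing on >= 0
      expect_equal(auc(relabeled), auc(tab))
      swapped <- new_score_outcome_table(tab$score, tab$alive, tab$dead)
      expect_equal(auc(swapped), 1 - auc(tab))
    }
  })
})

test_that("single shared score gives chance-level AUC; separation gives 1", {
  expect_equal(auc(new_score_outcome_table(2, 5L, 3L)), 0.5)
  expect_equal(auc(new_score_outcome_table(c(1, 4), c(0L, 6L), c(5L, 0L))), 1)
})

test_that("Youden-optimal cutoff beats every other cutoff, ties to the lower one", {
  withr::with_seed(606, {
    for (i in 1:100) {
      tab <- random_table()
      best <- youden_optimal_cutoff(tab)
      cand <- c(sort(unique(tab$score)), max(tab$score) + 1)
      js <- vapply(cand, function(ct) metrics_at_cutoff(tab, ct)$youden_j, double(1))
      expect_equal(best$youden_j, max(js))
      expect_equal(best$cutoff, min(cand[js == max(js)]))
    }
  })
  sep <- new_score_outcome_table(c(1, 4), c(0L, 6L), c(5L, 0L))
  expect_equal(youden_optimal_cutoff(sep), tibble::tibble(cutoff = 4, youden_j = 1))
})

test_that("stratum mortality and group means handle edge strata", {
  tab <- new_score_outcome_table(0:2, c(1L, 0L, 3L), c(3L, 0L, 1L))
  sm <- stratum_mortality(tab)
  expect_equal(sm$mortality, c(0.25, NA, 0.75))
  expect_equal(group_mean_score(tab, "dead"), (0 * 1 + 2 * 3) / 4)
  one <- new_score_outcome_table(5, 3L, 2L)
  expect_equal(group_mean_score(one, "alive"), 5)
  empty_grp <- new_score_outcome_table(1, 2L, 0L)
  expect_error(group_mean_score(empty_grp, "alive"), "alive")
})

test_that("evaluate_scores aggregates deterministically and is row-order invariant", {
  pts <- materialize_table(table_fixtures()$ich_score)
  pts$ich <- pts$score
  ev <- evaluate_scores(pts, ich, outcome = dead_30d, cutoffs = 2)
  expect_s3_class(ev, "ich_eval")
  expect_equal(glance(ev)$auc, auc(table_fixtures()$ich_score))

  withr::with_seed(707, {
    perm <- pts[sample(nrow(pts)), ]
  })
  ev2 <- evaluate_scores(perm, ich, outcome = dead_30d, cutoffs = 2)
  expect_equal(tidy(ev2), tidy(ev))
  expect_equal(glance(ev2), glance(ev))

  two <- tibble::tibble(s = c(1, 5), dead_30d = c(FALSE, TRUE))
  expect_equal(glance(evaluate_scores(two, s, outcome = dead_30d))$auc, 1)

  one_class <- tibble::tibble(s = c(1, 2), dead_30d = c(FALSE, FALSE))
  expect_error(evaluate_scores(one_class, s, outcome = dead_30d), "[Dd]egenerate")
})

test_that("tidy/glance/autoplot expose the evaluation surface", {
  fx <- table_fixtures()
  ev <- evaluate_table(fx$modified_new_ich_score, "modified_new_ich_score",
                       cutoffs = 3)
  td <- tidy(ev)
  expect_true(all(c("system", "cutoff", "sensitivity", "specificity", "ppv",
                    "npv", "lr_pos", "lr_neg", "youden_j") %in% names(td)))
  expect_equal(sort(td$cutoff), c(3, 4))
  expect_true(td$youden_optimal[td$cutoff == 4])
  gl <- glance(ev)
  expect_equal(gl$n, 107L)
  p <- autoplot(ev)
  expect_s3_class(p, "ggplot")
  expect_s3_class(plot_stratum_mortality(ev), "ggplot")
})
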