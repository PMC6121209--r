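test_that("ABC/2 volume follows the half-ellipsoid formula and its symmetries", {
  expect_equal(abc2_volume(4, 3, 2), 12)
  expect_equal(abc2_volume(0, 5, 5), 0)
  expect_equal(abc2_volume(6.2, 4.0, 3.0), 37.2)
  expect_error(abc2_volume(-1, 2, 3), "non-negative")

  withr::with_seed(11, {
    for (i in 1:25) {
      abc <- runif(3, 0, 8)
      s <- runif(1, 0.1, 4)
      expect_equal(abc2_volume(abc[1], abc[2], abc[3]),
                   abc2_volume(abc[2], abc[1], abc[3]))  # symmetric in A, B
      expect_equal(abc2_volume(s * abc[1], s * abc[2], s * abc[3]),
                   s^3 * abc2_volume(abc[1], abc[2], abc[3]))  # degree-3 homogeneous
    }
  })
})

test_that("pulse pressure is the systolic-diastolic difference with domain check", {
  expect_equal(pulse_pressure(160, 90), 70)
  expect_equal(pulse_pressure(120, 120), 0)
  expect_equal(pulse_pressure(146.48, 70.02), 76.46)
  expect_error(pulse_pressure(80, 90), ">=")
})

test_that("MRS and NIHSS severity bins match the published mapping", {
  expect_equal(mrs_bin_points(0:5), c(0, 0, 0, 1, 1, 2))
  expect_equal(nihss_bin_points(c(0, 10, 11, 20, 21, 40)), c(0, 0, 1, 1, 2, 2))
  # surjective onto {0, 1, 2} and monotone
  expect_setequal(unique(mrs_bin_points(0:5)), 0:2)
  expect_setequal(unique(nihss_bin_points(0:40)), 0:2)
  expect_false(is.unsorted(mrs_bin_points(0:5)))
  expect_false(is.unsorted(nihss_bin_points(0:40)))
  expect_error(mrs_bin_points(6), "0-5")
  expect_error(nihss_bin_points(41), "0-40")
})

test_that("ICH score reproduces its component point table", {
  rec <- function(gcs, volume, ivh, loc, age) {
    tibble::tibble(gcs = gcs, volume_cm3 = volume, ivh = ivh, location = loc, age = age)
  }
  expect_equal(ich_score(rec(13, 10, FALSE, "supra", 50))$ich_score, 0L)
  expect_equal(ich_score(rec(4, 35, TRUE, "infra", 82))$ich_score, 6L)
  expect_equal(ich_score(rec(7, 20, TRUE, "supra", 70))$ich_score, 2L)
  expect_equal(ich_score(rec(5, 30, FALSE, "supra", 80))$ich_score, 3L)  # boundaries: >=30 cm3, >=80 y
  expect_error(ich_score(rec(2, 10, FALSE, "supra", 50)), "gcs")
  expect_error(ich_score(rec(16, 10, FALSE, "supra", 50)), "gcs")
})

test_that("Modified New and New ICH scores sum their five components", {
  rec <- function(mrs, temp, pp, ivh, sah) {
    tibble::tibble(mrs = mrs, temperature = temp, sbp = 100 + pp, dbp = 100,
                   ivh = ivh, sah = sah)
  }
  expect_equal(modified_new_ich_score(rec(2, 36.5, 60, FALSE, FALSE))$modified_new_ich_score, 0L)
  expect_equal(modified_new_ich_score(rec(5, 38.5, 100, TRUE, TRUE))$modified_new_ich_score, 6L)
  expect_equal(modified_new_ich_score(rec(5, 36.5, 60, TRUE, FALSE))$modified_new_ich_score, 3L)

  nrec <- function(nihss, ...) dplyr::mutate(rec(0, ...), nihss = nihss, mrs = NULL)
  expect_equal(new_ich_score(nrec(5, 36.5, 60, FALSE, FALSE))$new_ich_score, 0L)
  expect_equal(new_ich_score(nrec(25, 36.5, 60, TRUE, FALSE))$new_ich_score, 3L)
  expect_equal(new_ich_score(nrec(40, 38.5, 100, TRUE, TRUE))$new_ich_score, 6L)

  # missing component field is named in the error
  expect_error(modified_new_ich_score(tibble::tibble(mrs = 2, temperature = 36.5,
                                                     sbp = 120, dbp = 80, ivh = FALSE)),
               "sah")
})

test_that("scores are monotone in every component over the full discrete grid", {
  grid <- tidyr::expand_grid(
    gcs = c(3, 4, 5, 12, 13, 15), volume_cm3 = c(0, 29.9, 30, 80),
    ivh = c(FALSE, TRUE), location = c("supra", "infra"), age = c(40, 79, 80, 95)
  )
  scored <- ich_score(grid)
  expect_true(all(scored$ich_score >= 0 & scored$ich_score <= 6))
  # raising any single component's severity never lowers the score
  for (comp in c("gcs", "volume_cm3", "ivh", "location", "age")) {
    others <- setdiff(names(grid), comp)
    split_scores <- split(scored, scored[others])
    for (g in split_scores) {
      ord <- switch(comp,
        gcs = order(-g$gcs), location = order(g$location == "infra"),
        order(g[[comp]]))
      expect_false(is.unsorted(g$ich_score[ord]))
    }
  }

  mgrid <- tidyr::expand_grid(
    mrs = 0:5, temperature = c(36.5, 37.5), pp = c(60, 85),
    ivh = c(FALSE, TRUE), sah = c(FALSE, TRUE)
  ) |>
    dplyr::mutate(sbp = 100 + pp, dbp = 100)
  mscored <- modified_new_ich_score(mgrid)
  expect_true(all(mscored$modified_new_ich_score >= 0 &
                    mscored$modified_new_ich_score <= 6))
  for (comp in c("mrs", "temperature", "pp", "ivh", "sah")) {
    others <- setdiff(c("mrs", "temperature", "pp", "ivh", "sah"), comp)
    for (g in split(mscored, mscored[others])) {
      expect_false(is.unsorted(g$modified_new_ich_score[order(g[[comp]])]))
    }
  }
})

test_that("volume precedence: explicit volume wins over diameters with a warning", {
  rec <- tibble::tibble(gcs = 13, volume_cm3 = 50, diam_a = 2, diam_b = 2,
                        slice_extent_c = 2, ivh = FALSE, location = "supra", age = 50)
  expect_warning(s1 <- ich_score(rec), "volume_cm3")
  expect_equal(s1$ich_score, 1L)  # 50 >= 30, not ABC/2 = 4
  rec$volume_cm3 <- NA
  expect_equal(ich_score(rec)$ich_score, 0L)  # falls back to ABC/2
})

test_that("score_cohort scores whole cohorts and reports row-level failures", {
  scored <- score_cohort(example_cohort())
  expect_equal(nrow(scored), 3)
  expect_equal(scored$ich_score, c(0L, 6L, 2L))
  expect_equal(scored$modified_new_ich_score, c(0L, 6L, 3L))

  empty <- score_cohort(example_cohort()[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("ich_score", "modified_new_ich_score") %in% names(empty)))

  bad <- example_cohort()
  bad$gcs[2] <- 2
  expect_error(score_cohort(bad), "row\\(s\\) 2")
  noval <- example_cohort()
  noval$volume_cm3[3] <- NA
  expect_error(score_cohort(noval), "row\\(s\\) 3")
})
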