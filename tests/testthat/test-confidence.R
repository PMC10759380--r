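test_that("the weighted average rule scores contributions 1/2/3", {
  contrib <- c(a = 60, b = 40)
  expect_equal(rate_weighted_domain(contrib, c(a = "low", b = "low")),
               "no_concerns")
  expect_equal(rate_weighted_domain(c(a = 100), c(a = "high")),
               "major_concerns")
  expect_equal(rate_weighted_domain(c(a = 50, b = 50),
                                    c(a = "low", b = "high")),
               "some_concerns")   # weighted score exactly 2
  expect_error(rate_weighted_domain(contrib, c(a = "low")), "judgement-gap")
  # invariant to splitting a trial's contribution at the same level
  split3 <- rate_weighted_domain(c(a = 30, a2 = 30, b = 40),
                                 c(a = "moderate", a2 = "moderate",
                                   b = "high"))
  merged <- rate_weighted_domain(c(a = 60, b = 40),
                                 c(a = "moderate", b = "high"))
  expect_equal(split3, merged)
})

test_that("reporting bias fires on indicators, registration, and discrepancies", {
  clean <- data.frame(trial_id = "a", registered = TRUE,
                      outcome_discrepancy = FALSE)
  expect_equal(rate_reporting_bias(c(grey_literature = FALSE), clean),
               "no_concerns")
  expect_equal(rate_reporting_bias(c(grey_literature = TRUE), clean),
               "some_concerns")
  unreg <- data.frame(trial_id = "a", registered = FALSE,
                      outcome_discrepancy = FALSE)
  expect_equal(rate_reporting_bias(logical(0), unreg), "some_concerns")
  disc <- data.frame(trial_id = "a", registered = TRUE,
                     outcome_discrepancy = TRUE)
  expect_equal(rate_reporting_bias(logical(0), disc), "some_concerns")
})

test_that("imprecision compares the CI against the equivalence range", {
  expect_equal(rate_imprecision(6, 9, 5.4), "no_concerns")
  expect_equal(rate_imprecision(-1, 6, 5.4), "some_concerns")
  expect_equal(rate_imprecision(-7, 7, 5.4), "major_concerns")
  expect_equal(rate_imprecision(-3, 3, 5.4), "no_concerns")  # inside range
  # binary rule: any interval crossing the null is inconclusive
  expect_equal(rate_imprecision(-0.2, 0.4, NA), "major_concerns")
  expect_equal(rate_imprecision(0.1, 0.8, NA), "no_concerns")
  expect_true(is.na(rate_imprecision(NA, NA, 5.4)))
})

test_that("heterogeneity counts boundaries the prediction interval adds", {
  expect_equal(rate_heterogeneity(6, 9, 6, 9, 5.4), "no_concerns")
  expect_equal(rate_heterogeneity(6, 9, 4, 11, 5.4), "some_concerns")
  expect_equal(rate_heterogeneity(-3, 3, -7, 7, 5.4), "major_concerns")
})

test_that("incoherence rating follows SIDE, then the global test", {
  side_ok <- list(applicable = TRUE, p = 0.5, difference = 1)
  side_small <- list(applicable = TRUE, p = 0.05, difference = 2)
  side_big <- list(applicable = TRUE, p = 0.05, difference = 9)
  side_na <- list(applicable = FALSE)
  glob_on <- list(applicable = TRUE, flagged = TRUE)
  glob_off <- list(applicable = TRUE, flagged = FALSE)
  glob_na <- list(applicable = FALSE, flagged = FALSE)
  expect_equal(rate_incoherence(side_ok, glob_on, 5.4), "no_concerns")
  expect_equal(rate_incoherence(side_small, glob_off, 5.4), "some_concerns")
  expect_equal(rate_incoherence(side_big, glob_off, 5.4), "major_concerns")
  expect_equal(rate_incoherence(side_na, glob_on, 5.4), "some_concerns")
  expect_true(is.na(rate_incoherence(side_na, glob_na, 5.4)))
})

test_that("the downgrade ladder starts high and floors at very low", {
  all_no <- rep("no_concerns", 6)
  expect_equal(rate_overall(all_no), "high")
  one <- all_no; one[3] <- "some_concerns"
  expect_equal(rate_overall(one), "moderate")
  three <- all_no; three[1:3] <- "some_concerns"
  expect_equal(rate_overall(three), "very_low")
  na_dom <- one; na_dom[6] <- NA
  expect_equal(rate_overall(na_dom), "moderate")   # NA does not downgrade
})

test_that("the ladder is monotone: worsening a domain never helps", {
  lv <- c("no_concerns", "some_concerns", "major_concerns")
  grades <- c(high = 1, moderate = 2, low = 3, very_low = 4)
  set.seed(3)
  for (i in 1:50) {
    j <- sample(lv, 6, replace = TRUE)
    base <- grades[rate_overall(j)]
    k <- sample(1:6, 1)
    if (j[k] == "major_concerns") next
    worse <- j; worse[k] <- lv[match(j[k], lv) + 1]
    expect_gte(grades[rate_overall(worse)], base)
  }
})

test_that("downgrade summaries count comparisons at least at some concerns", {
  r <- data.frame(
    key = paste0("k", 1:10),
    within_study_bias = rep("major_concerns", 10),
    reporting_bias = rep("some_concerns", 10),
    intransitivity = c(rep("some_concerns", 6), rep("no_concerns", 4)),
    imprecision = c("some_concerns", rep("no_concerns", 9)),
    heterogeneity = rep("no_concerns", 10),
    incoherence = rep(NA_character_, 10),
    overall = "very_low", stringsAsFactors = FALSE)
  s <- summarize_downgrades(r)
  expect_equal(unname(s["within_study_bias"]), 100)
  expect_equal(unname(s["intransitivity"]), 60)
  expect_equal(unname(s["imprecision"]), 10)
  expect_equal(unname(s["heterogeneity"]), 0)
  expect_true(is.na(s["incoherence"]))
  expect_equal(unname(s["n_comparisons"]), 10)
})
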