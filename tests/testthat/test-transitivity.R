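test_that("modifier pooling weights trials by their totals", {
  tr <- rbind(
    data.frame(trial_id = "a", intervention = c("LCP", "RSA"), n = 62,
               mean = c(61, 67), sd = c(15, 13), events = NA_real_,
               mean_age = 75.2, sd_age = 6.4, females = 112,
               fracture_parts = "3-4-part", registered = TRUE,
               outcome_discrepancy = FALSE, rob = "low", outcome = "CS",
               stringsAsFactors = FALSE),
    data.frame(trial_id = c("b", "b", "c", "c"),
               intervention = c("HA", "NOP", "HA", "NOP"),
               n = c(50, 50, 25, 25),
               mean = 60, sd = 14, events = NA_real_,
               mean_age = rep(c(70, 80), each = 2), sd_age = NA_real_,
               females = rep(c(60, 45), each = 2),
               fracture_parts = "3-4-part", registered = TRUE,
               outcome_discrepancy = FALSE, rob = "low", outcome = "CS",
               stringsAsFactors = FALSE))
  s <- pool_modifiers(as_trials(tr))
  lcprsa <- s[s$key == "LCP:RSA", ]
  expect_equal(lcprsa$pooled_age, 75.2)
  expect_equal(lcprsa$female_pct, 100 * 112 / 124)
  expect_equal(lcprsa$n_participants, 124)
  hanop <- s[s$key == "HA:NOP", ]
  expect_equal(hanop$pooled_age, (100 * 70 + 50 * 80) / 150)
  expect_equal(hanop$female_pct, 70)   # (60+45)/(100+50) participants
  expect_equal(hanop$n_trials, 2)
})

test_that("two-sided Fisher p agrees with hypergeometric enumeration", {
  enum_fisher <- function(tab) {
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    xs <- max(0, k - n):min(k, m)
    probs <- stats::dhyper(xs, m, n, k)
    obs <- stats::dhyper(tab[1, 1], m, n, k)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  tabs <- list(matrix(c(95, 10, 133, 51), 2, byrow = TRUE),
               matrix(c(95, 10, 59, 33), 2, byrow = TRUE),
               matrix(c(5, 5, 5, 5), 2),
               matrix(c(12, 3, 4, 11), 2),
               matrix(c(0, 10, 10, 0), 2))
  set.seed(8)
  for (i in 1:10) {
    tabs[[length(tabs) + 1]] <- matrix(sample(0:60, 4, replace = TRUE), 2)
  }
  for (tab in tabs) {
    expect_equal(stats::fisher.test(tab)$p.value, enum_fisher(tab),
                 tolerance = 1e-9)
  }
})

test_that("reference comparison gets zero differences and no flags", {
  s <- compare_to_reference(pool_modifiers(fixture_like_published("davey")))
  ref <- s[s$key == "HA:NOP", ]
  expect_equal(ref$age_diff, 0)
  expect_equal(ref$female_diff, 0)
  expect_equal(ref$fisher_p, 1)
  expect_false(ref$flag_age || ref$flag_gender)
  expect_error(
    compare_to_reference(s[s$key != "HA:NOP", ]), "configuration error")
})

test_that("age flags follow the absolute cutoff, gender flags need both gates", {
  s <- compare_to_reference(pool_modifiers(fixture_like_published("davey")))
  expect_true(s$flag_age[s$key == "IMN:LCP"])      # -12.3 years
  expect_false(s$flag_age[s$key == "LCP:RSA"])     # -2.2 years
  # IMN:LCP female gap is significant but under the 20-point cutoff
  expect_lt(s$fisher_p[s$key == "IMN:LCP"], 0.001)
  expect_false(s$flag_gender[s$key == "IMN:LCP"])
  o <- compare_to_reference(pool_modifiers(fixture_like_published("orman")))
  expect_true(o$flag_gender[o$key == "HA:ORIF"])   # -26 points, significant
  # qualitative flags join as a third modifier
  q <- compare_to_reference(pool_modifiers(fixture_like_published("davey")),
                            qualitative = fixture_qualitative("davey"))
  expect_true(q$flag_qualitative[q$key == "HA:RSA"])
  expect_equal(q$n_flags[q$key == "HA:RSA"], 1)
})

test_that("trial intransitivity counts distinct flagged modifiers", {
  davey <- fixture_like_published("davey")
  s <- compare_to_reference(pool_modifiers(davey),
                            qualitative = fixture_qualitative("davey"))
  lv <- classify_trial_intransitivity(davey, s)
  expect_equal(unname(lv["t1"]), "low")          # reference comparison
  expect_equal(unname(lv["imn1"]), "moderate")   # age flag only
  orman <- fixture_like_published("orman")
  so <- compare_to_reference(pool_modifiers(orman))
  lo <- classify_trial_intransitivity(orman, so)
  expect_equal(unname(lo["cai"]), "high")        # age and gender flags
})

test_that("sensitivity cutoffs unflag exactly the in-between comparisons", {
  for (w in c("davey", "du", "orman")) {
    s1 <- compare_to_reference(pool_modifiers(fixture_like_published(w)))
    s2 <- compare_to_reference(pool_modifiers(fixture_like_published(w)),
                               sensitivity = TRUE)
    # flags cleared are precisely those with |diff| between the cutoffs
    cleared <- s1$key[s1$flag_age & !s2$flag_age]
    expect_setequal(cleared,
                    s1$key[abs(s1$age_diff) > 5 & abs(s1$age_diff) <= 10 &
                             s1$key != "HA:NOP"])
    expect_true(all(s2$flag_age == (abs(s2$age_diff) > 10 &
                                      s2$key != "HA:NOP")))
  }
})
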