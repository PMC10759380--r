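triangle_config <- function(seed = 1, ...) {
  sim_config(c("HA", "NOP", "RSA"), c(NOP = 0, HA = 3, RSA = 5),
             data.frame(t1 = c("HA", "NOP", "HA"),
                        t2 = c("NOP", "RSA", "RSA"),
                        n_trials = 2, n_per_arm = 100),
             seed = seed, ...)
}

test_that("a fixed seed makes generation byte-identical", {
  g1 <- generate_network(triangle_config(seed = 77))
  g2 <- generate_network(triangle_config(seed = 77))
  expect_identical(g1, g2)
  g3 <- generate_network(triangle_config(seed = 78))
  expect_false(identical(g1$trials$mean, g3$trials$mean))
})

test_that("observed contrasts approach the truth in the noise-free limit", {
  cfg <- sim_config(c("HA", "NOP", "RSA"), c(NOP = 0, HA = 3, RSA = 5),
                    data.frame(t1 = c("HA", "NOP"), t2 = c("NOP", "RSA"),
                               n_trials = 1, n_per_arm = 200000),
                    tau = 0, seed = 4)
  g <- generate_network(cfg)
  ct <- network_contrasts(network_spec(g$trials, "CS"))
  merged <- merge(ct, g$truth, by = "trial_id")
  expect_equal(merged$yi, merged$true_contrast, tolerance = 0.05)
  # the realized truth equals the configured consistency value when tau = 0
  expect_equal(sort(g$truth$true_contrast), sort(c(-3, 5)), tolerance = 1e-10)
})

test_that("binary generation respects the logit model and event bounds", {
  cfg <- sim_config(c("HA", "NOP"), c(NOP = 0, HA = -0.7),
                    data.frame(t1 = "HA", t2 = "NOP", n_trials = 30,
                               n_per_arm = 200),
                    outcome = "additional_surgery", outcome_type = "binary",
                    baseline_risk = 0.2, seed = 12)
  g <- generate_network(cfg)
  expect_true(all(g$trials$events <= g$trials$n))
  ct <- network_contrasts(network_spec(g$trials, "additional_surgery"))
  pooled <- pool_pairwise(ct$yi, sqrt(ct$vi), model = "common")
  # HA (alphabetical baseline) carries -0.7, so NOP-vs-HA is +0.7
  expect_equal(pooled$estimate, 0.7, tolerance = 0.15)
})

test_that("universal SD missingness reproduces the unusable-network case", {
  cfg <- triangle_config(seed = 9, sd_missing_prob = 1)
  g <- generate_network(cfg)
  spec <- network_spec(g$trials, "CS")
  expect_error(network_contrasts(spec, sd_action = "error"), "missing-SD")
  expect_error(network_contrasts(spec, sd_action = "drop"), "no trials remain")
  # imputation is impossible when no SD exists anywhere
  expect_error(network_contrasts(spec, sd_action = "impute"), "cannot-impute")
})

test_that("configured modifier imbalance propagates into transitivity flags", {
  mm <- data.frame(intervention = c("HA", "NOP", "LCP"),
                   age_mean = c(78, 78, 64), age_sd = 6,
                   female_p = c(0.85, 0.85, 0.85))
  cfg <- sim_config(c("HA", "NOP", "LCP"), c(NOP = 0, HA = 2, LCP = 4),
                    data.frame(t1 = c("HA", "LCP", "LCP"),
                               t2 = c("NOP", "NOP", "HA"),
                               n_trials = 2, n_per_arm = 2000),
                    modifier_model = mm, seed = 21)
  g <- generate_network(cfg)
  s <- compare_to_reference(pool_modifiers(g$trials))
  # LCP edges mix a 64-year population into a 78-year reference
  expect_true(s$flag_age[s$key == "LCP:NOP"])
  expect_true(s$flag_age[s$key == "HA:LCP"])
  expect_false(s$flag_age[s$key == "HA:NOP"])
})

test_that("offset on a design is rejected when the design does not exist", {
  expect_error(triangle_config(incoherence_offsets = c("HA:ORIF" = 5)),
               "config error")
})

test_that("published-shaped fixtures reproduce the published marginals", {
  # trial counts, participants, pooled age (1 dp), female % (integer), and
  # the printed difference columns
  printed <- list(
    davey = data.frame(
      key = c("HA:NOP", "HA:LCP", "IMN:LCP", "LCP:NOP", "LCP:RSA",
              "HA:RSA", "NOP:RSA"),
      rcts = c(2, 1, 3, 3, 1, 1, 1),
      n = c(105, 32, 184, 197, 124, 61, 59),
      age = c(77.4, 71.6, 65.0, 73.0, 75.2, 74.0, 83.5),
      age_diff = c(NA, -5.7, -12.3, -4.4, -2.2, -3.4, 6.2),
      fem = c(90, 84, 72, 87, 90, 85, 86),
      fem_diff = c(NA, -6, -18, -3, 0, -5, -4)),
    du = data.frame(
      key = c("HA:NOP", "HA:ORIF", "NOP:ORIF", "HA:RSA"),
      rcts = c(2, 1, 3, 1), n = c(105, 32, 149, 61),
      age = c(77.4, 71.6, 73.5, 74.0),
      age_diff = c(NA, -5.7, -3.9, -3.4),
      fem = c(90, 84, 85, 85), fem_diff = c(NA, -6, -5, -5)),
    orman = data.frame(
      key = c("HA:NOP", "HA:ORIF", "NOP:ORIF", "HA:RSA"),
      rcts = c(2, 2, 3, 1), n = c(105, 92, 149, 61),
      age = c(77.4, 68.0, 73.5, 74.0),
      age_diff = c(NA, -9.4, -3.9, -3.4),
      fem = c(90, 64, 85, 85), fem_diff = c(NA, -26, -5, -5)))
  for (w in names(printed)) {
    s <- compare_to_reference(pool_modifiers(fixture_like_published(w)))
    p <- printed[[w]]
    s <- s[match(p$key, s$key), ]
    expect_equal(s$n_trials, p$rcts, info = w)
    expect_equal(s$n_participants, p$n, info = w)
    expect_equal(round_half_up(s$pooled_age, 1), p$age, info = w)
    expect_equal(round_half_up(s$female_pct), p$fem, info = w)
    expect_equal(round_half_up(s$age_diff[-1], 1), p$age_diff[-1], info = w)
    expect_equal(round_half_up(s$female_diff[-1]), p$fem_diff[-1], info = w)
  }
  # network shapes: the du block spans 4 comparisons over 7 trials
  du <- fixture_like_published("du")
  net <- build_network(du)
  expect_equal(length(unique(net$edges$key)), 4)
  expect_equal(length(unique(du$trial_id)), 7)
})
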