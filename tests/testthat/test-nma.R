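test_that("single-edge networks reduce exactly to pairwise pooling", {
  one <- contrast_df("s1", "HA", "NOP", 3, 1)
  fit <- fit_network(one, model = "common")
  expect_equal(unname(fit$basic_estimates["NOP"]), 3)
  expect_equal(unname(sqrt(fit$vcov["NOP", "NOP"])), 1)
  two <- contrast_df(c("s1", "s2"), "HA", "NOP", c(2, 4), 1)
  fit2 <- fit_network(two, model = "common")
  ref <- pool_pairwise(c(2, 4), c(1, 1), model = "common")
  expect_equal(unname(fit2$basic_estimates["NOP"]), ref$estimate)
  expect_equal(unname(sqrt(fit2$vcov["NOP", "NOP"])), ref$se)
})

test_that("indirect estimates add along a path with summed variances", {
  fit <- fit_network(chain_contrasts(), model = "common")
  lg <- league_table(fit)
  row <- lg[lg$key == "HA:RSA", ]
  expect_equal(row$estimate, 7)
  expect_equal(row$se, sqrt(2))
  expect_equal(row$ci_high - row$estimate, 1.959964 * sqrt(2))
})

test_that("a triangle combines direct and indirect evidence as GLS says", {
  fit <- fit_network(triangle_contrasts(), model = "common")
  lg <- league_table(fit)
  row <- lg[lg$key == "HA:RSA", ]
  expect_equal(row$estimate, 7, tolerance = 1e-12)
  expect_equal(row$se, sqrt(2 / 3), tolerance = 1e-12)
})

test_that("the fit matches an independent GLS solve on enumerated networks", {
  # topologies up to 4 nodes / 6 trials, including parallel edges and a
  # three-arm block; the oracle is metafor's multivariate fixed-effect fit
  # with the same block covariance
  topos <- list(
    list(t1 = c("HA", "HA"), t2 = c("NOP", "NOP")),
    list(t1 = c("HA", "NOP"), t2 = c("NOP", "RSA")),
    list(t1 = c("HA", "NOP", "HA"), t2 = c("NOP", "RSA", "RSA")),
    list(t1 = c("HA", "NOP", "HA", "HA"), t2 = c("NOP", "RSA", "RSA", "NOP")),
    list(t1 = c("HA", "NOP", "RSA", "HA"),
         t2 = c("NOP", "RSA", "ORIF", "ORIF")),
    list(t1 = c("HA", "NOP", "RSA", "HA", "NOP", "HA"),
         t2 = c("NOP", "RSA", "ORIF", "ORIF", "ORIF", "RSA")))
  set.seed(99)
  for (tp in topos) {
    k <- length(tp$t1)
    ct <- contrast_df(paste0("t", seq_len(k)), tp$t1, tp$t2,
                      rnorm(k, 1), runif(k, 0.5, 2))
    fit <- fit_network(ct, model = "common")
    params <- setdiff(fit$nodes, fit$reference)
    X <- matrix(0, k, length(params), dimnames = list(NULL, params))
    for (i in seq_len(k)) {
      if (ct$t2[i] %in% params) X[i, ct$t2[i]] <- 1
      if (ct$t1[i] %in% params) X[i, ct$t1[i]] <- -1
    }
    or <- metafor::rma.mv(yi, diag(vi, nrow = k), mods = ~ X - 1,
                          data = ct, method = "FE")
    expect_equal(unname(fit$basic_estimates[params]),
                 unname(coef(or)), tolerance = 1e-8)
    expect_equal(unname(drop(fit$vcov[params, params])),
                 unname(drop(as.matrix(vcov(or)))), tolerance = 1e-8)
  }
  # multi-arm block: one 3-arm trial plus independent two-arm trials
  ct <- rbind(
    contrast_df(c("m", "m"), "HA", c("NOP", "RSA"), c(1.2, 2.5),
                c(0.9, 1.1), cov_base = 0.4, design = "HA+NOP+RSA"),
    contrast_df(c("x", "y"), c("HA", "NOP"), c("NOP", "RSA"),
                c(0.8, 1.4), c(0.7, 0.6)))
  V <- diag(ct$vi); V[1, 2] <- V[2, 1] <- 0.4
  X <- cbind(NOP = c(1, 0, 1, -1), RSA = c(0, 1, 0, 1))
  or <- metafor::rma.mv(yi, V, mods = ~ X - 1, data = ct, method = "FE")
  fit <- fit_network(ct, model = "common")
  expect_equal(unname(fit$basic_estimates[c("NOP", "RSA")]),
               unname(coef(or)), tolerance = 1e-8)
  expect_equal(unname(fit$vcov[c("NOP", "RSA"), c("NOP", "RSA")]),
               unname(as.matrix(vcov(or))), tolerance = 1e-8)
})

test_that("fits satisfy the consistency equations and the Q decomposition", {
  set.seed(5)
  for (i in 1:5) {
    ct <- contrast_df(paste0("t", 1:6),
                      c("HA", "NOP", "RSA", "HA", "NOP", "HA"),
                      c("NOP", "RSA", "ORIF", "ORIF", "ORIF", "RSA"),
                      rnorm(6, 1, 2), runif(6, 0.3, 2))
    fit <- fit_network(ct, model = "random")
    lg <- league_table(fit)
    est <- function(k) lg$estimate[lg$key == k]
    # estimate(A:C) = estimate(A:B) + estimate(B:C) for all triples
    expect_equal(est("HA:RSA"), est("HA:NOP") + est("NOP:RSA"),
                 tolerance = 1e-10)
    expect_equal(est("HA:ORIF"), est("HA:NOP") + est("NOP:ORIF"),
                 tolerance = 1e-10)
    expect_equal(fit$q_total, fit$q_heterogeneity + fit$q_inconsistency,
                 tolerance = 1e-8)
    expect_true(all(eigen(fit$vcov, only.values = TRUE)$values > -1e-10))
    # anti-symmetry of the league table under pair reversal
    rev_est <- fit$basic_estimates["HA"] - fit$basic_estimates["RSA"]
    expect_equal(unname(rev_est), -est("HA:RSA"), tolerance = 1e-12)
    # random-effects uncertainty never beats common-effects
    fitc <- fit_network(ct, model = "common")
    expect_true(all(diag(fit$vcov) >= diag(fitc$vcov) - 1e-12))
  }
})

test_that("disconnected or underdetermined networks are refused", {
  ct <- contrast_df(c("s1", "s2"), c("HA", "RSA"), c("NOP", "ORIF"), 1, 1)
  expect_error(fit_network(ct), "connectivity error")
})

test_that("contribution rows are exact percentages with sensible support", {
  # single edge, one trial
  fit <- fit_network(contrast_df("s1", "HA", "NOP", 3, 1), model = "common")
  cm <- contribution_matrix(fit)
  expect_equal(unname(cm["HA:NOP", "s1"]), 100)
  # two equal trials split evenly
  fit2 <- fit_network(contrast_df(c("s1", "s2"), "HA", "NOP", c(2, 4), 1),
                      model = "common")
  cm2 <- contribution_matrix(fit2)
  expect_equal(unname(cm2["HA:NOP", ]), c(50, 50))
  # equal-variance triangle: direct trial 2/3, each indirect trial 1/6
  fit3 <- fit_network(triangle_contrasts(), model = "common")
  cm3 <- contribution_matrix(fit3)
  expect_equal(unname(cm3["HA:RSA", c("s3", "s1", "s2")]),
               c(200 / 3, 100 / 6, 100 / 6), tolerance = 1e-8)
  expect_equal(unname(rowSums(cm3)), rep(100, 3), tolerance = 0.1)
})

test_that("removing a zero-contribution trial leaves the estimate alone", {
  ct <- chain_contrasts()   # tree: HA:NOP trial contributes 0 to NOP:RSA
  fit <- fit_network(ct, model = "common")
  cm <- contribution_matrix(fit)
  expect_equal(unname(cm["NOP:RSA", "s1"]), 0)
  reduced <- fit_network(ct[ct$trial_id != "s1", ], model = "common")
  lg <- league_table(fit); lgr <- league_table(reduced)
  expect_equal(lg$estimate[lg$key == "NOP:RSA"],
               lgr$estimate[lgr$key == "NOP:RSA"], tolerance = 1e-12)
})
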