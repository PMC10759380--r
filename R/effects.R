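#' Contrast between two arms
#'
#' Converts a pair of arm summaries into a relative effect with standard
#' error. Continuous outcomes use the mean difference (arm2 minus arm1) with
#' \eqn{se = \sqrt{sd_1^2/n_1 + sd_2^2/n_2}}. Binary outcomes use the log
#' odds ratio; when any cell of the 2x2 table is zero, 0.5 is added to all
#' four cells.
#'
#' @param arm1,arm2 Lists or one-row data frames with \code{n} and either
#'   \code{mean}/\code{sd} (continuous) or \code{events} (binary).
#' @param outcome_type \code{"continuous"} or \code{"binary"}.
#' @return List with \code{estimate} and \code{se}.
#' @export
contrast_from_arms <- function(arm1, arm2, outcome_type) {
  if (outcome_type == "continuous") {
    for (a in list(arm1, arm2)) {
      if (is.na(a$mean)) stop("arm has no mean for a continuous outcome")
      if (is.na(a$sd)) {
        stop("missing-SD error: trial ",
             if (!is.null(a$trial_id)) a$trial_id else "?",
             ", arm ", a$intervention,
             " has no SD (impute or drop before forming contrasts)")
      }
    }
    list(estimate = arm2$mean - arm1$mean,
         se = sqrt(arm1$sd^2 / arm1$n + arm2$sd^2 / arm2$n))
  } else if (outcome_type == "binary") {
    a <- arm1$events; b <- arm1$n - arm1$events
    c <- arm2$events; d <- arm2$n - arm2$events
    if (any(is.na(c(a, b, c, d)))) stop("arm has no event count for a binary outcome")
    if ((a == 0 && b == 0) || (c == 0 && d == 0)) {
      stop("degenerate-arm error: arm with no participants")
    }
    if (any(c(a, b, c, d) == 0)) {
      a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    }
    list(estimate = log((c / d) / (a / b)),
         se = sqrt(1 / a + 1 / b + 1 / c + 1 / d))
  } else {
    stop("unknown outcome_type: ", outcome_type)
  }
}

#' Contrast-level data for a network
#'
#' Expands every trial into baseline contrasts (each non-baseline arm versus
#' the trial's first listed arm). Multi-arm trials are kept as one block: the
#' covariance between two of a trial's contrasts equals the variance
#' contribution of the shared baseline arm, which is stored per row in
#' \code{cov_base} so the fit can assemble the exact block-diagonal
#' covariance.
#'
#' @param spec An \code{nma_spec} (see [network_spec()]).
#' @param sd_action What to do with continuous arms lacking an SD:
#'   \code{"error"} (default), \code{"drop"} the whole trial, or
#'   \code{"impute"} via [impute_sd()].
#' @return Data frame with columns \code{trial_id}, \code{t1} (baseline),
#'   \code{t2}, \code{yi} (effect of t2 vs t1), \code{vi} (variance),
#'   \code{cov_base} (shared baseline-arm variance), \code{design};
#'   attribute \code{dropped} lists trials removed by \code{sd_action =
#'   "drop"}.
#' @export
network_contrasts <- function(spec, sd_action = c("error", "drop", "impute")) {
  sd_action <- match.arg(sd_action)
  rows <- spec$trials
  dropped <- character(0)
  if (spec$outcome_type == "continuous") {
    if (sd_action == "impute") {
      rows <- impute_sd(rows, spec$outcome)
    } else if (sd_action == "drop") {
      bad <- unique(rows$trial_id[is.na(rows$sd)])
      dropped <- bad
      rows <- rows[!(rows$trial_id %in% bad), , drop = FALSE]
      if (nrow(rows) == 0) stop("no trials remain after dropping missing-SD trials")
    }
  }
  out <- do.call(rbind, lapply(split(rows, rows$trial_id), function(grp) {
    grp <- grp[order(grp$intervention), , drop = FALSE]
    base <- grp[1, ]
    design <- paste(grp$intervention, collapse = "+")
    do.call(rbind, lapply(seq_len(nrow(grp))[-1], function(i) {
      ct <- contrast_from_arms(base, grp[i, ], spec$outcome_type)
      cov_base <- if (spec$outcome_type == "continuous") {
        base$sd^2 / base$n
      } else {
        a <- base$events; b <- base$n - base$events
        if (a == 0 || b == 0) { a <- a + 0.5; b <- b + 0.5 }
        1 / a + 1 / b
      }
      data.frame(trial_id = grp$trial_id[1], t1 = base$intervention,
                 t2 = grp$intervention[i], yi = ct$estimate,
                 vi = ct$se^2, cov_base = cov_base, design = design,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "outcome") <- spec$outcome
  attr(out, "outcome_type") <- spec$outcome_type
  out
}

#' Inverse-variance pairwise pooling
#'
#' Pools contrasts of one comparison by inverse-variance weighting, with the
#' DerSimonian-Laird moment estimator of the between-trial variance under the
#' random-effects model. With a single contrast the pooled estimate is that
#' contrast and \eqn{\tau^2 = I^2 = 0}.
#'
#' @param yi Effect estimates.
#' @param sei Standard errors (all > 0).
#' @param model \code{"random"} (default) or \code{"common"}.
#' @return List with \code{estimate}, \code{se}, \code{ci_low},
#'   \code{ci_high}, \code{tau2}, \code{i2}, \code{q}, \code{k}.
#' @export
pool_pairwise <- function(yi, sei, model = c("random", "common")) {
  model <- match.arg(model)
  if (length(yi) == 0) stop("no-evidence error: no contrasts to pool")
  if (any(sei <= 0)) stop("all standard errors must be > 0")
  k <- length(yi)
  w <- 1 / sei^2
  mu_c <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - mu_c)^2)
  tau2 <- if (k > 1) {
    max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  } else 0
  i2 <- if (k > 1 && q > 0) max(0, (q - (k - 1)) / q) else 0
  if (model == "random") {
    wr <- 1 / (sei^2 + tau2)
    est <- sum(wr * yi) / sum(wr)
    se <- sqrt(1 / sum(wr))
  } else {
    est <- mu_c
    se <- sqrt(1 / sum(w))
  }
  list(estimate = est, se = se,
       ci_low = est - 1.959964 * se, ci_high = est + 1.959964 * se,
       tau2 = tau2, i2 = i2, q = q, k = k)
}

#' Combined mean of several groups
#'
#' Sample-size weighted mean, as used to pool a modifier (e.g. mean age)
#' over the trials of one comparison.
#'
#' @param n Group sizes (all >= 1).
#' @param m Group means.
#' @return The combined mean \eqn{\sum n_i m_i / \sum n_i}.
#' @export
combined_mean <- function(n, m) {
  if (length(n) == 0) stop("no-data error: no groups to combine")
  if (any(n < 1)) stop("group sizes must be >= 1")
  sum(n * m) / sum(n)
}

#' Combined standard deviation of several groups
#'
#' The combined-group SD formed from within-group and between-group
#' components, i.e. the sample SD of the pooled raw observations
#' reconstructed from each group's (n, mean, sd):
#' \deqn{s = \sqrt{\frac{\sum (n_i-1)s_i^2 + \sum n_i (m_i - \bar m)^2}
#'   {\sum n_i - 1}}}
#' with \eqn{\bar m} the combined mean.
#'
#' @param n Group sizes.
#' @param m Group means.
#' @param s Group SDs (all present and >= 0).
#' @return The combined SD.
#' @export
combined_sd <- function(n, m, s) {
  if (length(n) == 0) stop("no-data error: no groups to combine")
  if (any(is.na(s))) {
    stop("missing-SD error: every group needs an SD to combine SDs")
  }
  if (any(s < 0)) stop("group SDs must be >= 0")
  mbar <- combined_mean(n, m)
  sqrt((sum((n - 1) * s^2) + sum(n * (m - mbar)^2)) / (sum(n) - 1))
}

#' Impute missing SDs by the outcome's mean reported SD
#'
#' Every absent arm-level SD for the given outcome is replaced by the
#' unweighted mean of all reported arm-level SDs for that outcome within the
#' network; reported SDs are untouched. Imputed rows are flagged in an
#' \code{sd_imputed} column.
#'
#' @param trials Trial-arm table.
#' @param outcome Outcome token whose SDs should be imputed.
#' @return The table with SDs filled in and \code{sd_imputed} set.
#' @export
impute_sd <- function(trials, outcome) {
  sel <- trials$outcome == outcome
  reported <- trials$sd[sel & !is.na(trials$sd)]
  missing <- sel & is.na(trials$sd)
  if (!("sd_imputed" %in% names(trials))) trials$sd_imputed <- FALSE
  if (!any(missing)) return(trials)
  if (length(reported) == 0) {
    stop("cannot-impute error: no SDs reported anywhere for outcome ", outcome)
  }
  trials$sd[missing] <- mean(reported)
  trials$sd_imputed[missing] <- TRUE
  trials
}
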