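#' Concern levels and overall grades
#'
#' Concern levels are ordered \code{no_concerns < some_concerns <
#' major_concerns}; overall grades run \code{high, moderate, low, very_low}.
#'
#' @name confidence-scales
NULL

concern_levels <- c("no_concerns", "some_concerns", "major_concerns")
overall_grades <- c("high", "moderate", "low", "very_low")

#' Minimal clinically important difference configuration
#'
#' @param cs_mcid MCID on the Constant score scale (default 5.4 points).
#' @param dash_mcid MCID on the DASH scale (default 8.1 points).
#' @param binary_rule If \code{TRUE} (default), any increase in risk is
#'   clinically relevant, so the equivalence range for binary outcomes
#'   degenerates to the null value.
#' @return List of class \code{mcid_config}.
#' @export
mcid_config <- function(cs_mcid = 5.4, dash_mcid = 8.1, binary_rule = TRUE) {
  stopifnot(cs_mcid > 0, dash_mcid > 0)
  structure(list(cs_mcid = cs_mcid, dash_mcid = dash_mcid,
                 binary_rule = binary_rule), class = "mcid_config")
}

mcid_for <- function(outcome, mcid = mcid_config()) {
  switch(outcome, CS = mcid$cs_mcid, DASH = mcid$dash_mcid, NA_real_)
}

#' Contribution-weighted domain rating
#'
#' The weighted average rule: per-trial judgements (e.g. risk-of-bias or
#' intransitivity levels, \code{low}/\code{moderate}/\code{high}) are scored
#' 1/2/3 and averaged with the trials' percentage contributions to the
#' comparison; a weighted score below 1.5 gives no concerns, below 2.5 some
#' concerns, and otherwise major concerns.
#'
#' @param contribution Named numeric vector of percentage contributions
#'   (summing to 100) for one comparison.
#' @param levels Named character vector of per-trial levels in
#'   \code{c("low", "moderate", "high")}.
#' @param thresholds Cut points on the weighted score (default
#'   \code{c(1.5, 2.5)}).
#' @return A concern level.
#' @export
rate_weighted_domain <- function(contribution, levels,
                                 thresholds = c(1.5, 2.5)) {
  contributing <- names(contribution)[contribution > 0]
  gap <- setdiff(contributing, names(levels))
  if (length(gap) > 0) {
    stop("judgement-gap error: no level for contributing trial(s) ",
         paste(gap, collapse = ", "))
  }
  score <- c(low = 1, moderate = 2, high = 3)[levels[contributing]]
  w <- sum(contribution[contributing] * score) / sum(contribution)
  if (w < thresholds[1]) "no_concerns"
  else if (w < thresholds[2]) "some_concerns"
  else "major_concerns"
}

#' Reporting-bias rating
#'
#' Applies the standard indicators (unpublished/grey literature not covered;
#' evidence based on a small number of positive early findings; comparisons
#' studied mainly in industry-funded trials; documented prior evidence of
#' reporting bias) plus registration screening: an unregistered contributing
#' trial, or a registered trial whose reported outcomes deviate from its
#' registration, also triggers concern. Any trigger yields at least
#' \code{some_concerns} (the default mapping for every rule).
#'
#' @param indicators Logical vector (any subset of
#'   \code{grey_literature, early_findings, industry_funding,
#'   prior_evidence}); \code{TRUE} means the indicator is present.
#' @param trial_meta Data frame with \code{trial_id}, \code{registered},
#'   \code{outcome_discrepancy} for the contributing trials.
#' @param trigger_level Level assigned when any rule fires (default
#'   \code{"some_concerns"}).
#' @return A concern level.
#' @export
rate_reporting_bias <- function(indicators = logical(0), trial_meta = NULL,
                                trigger_level = "some_concerns") {
  fired <- any(indicators)
  if (!is.null(trial_meta) && nrow(trial_meta) > 0) {
    unreg <- !trial_meta$registered
    disc <- trial_meta$registered & trial_meta$outcome_discrepancy
    fired <- fired || any(unreg, na.rm = TRUE) || any(disc, na.rm = TRUE)
  }
  if (fired) trigger_level else "no_concerns"
}

# classify a CI against the equivalence range [-mcid, mcid]:
# number of boundaries "crossed" (0 = conclusive, CI inside or wholly
# outside; for binary the range degenerates to the null value)
boundaries_crossed <- function(low, high, mcid) {
  if (is.na(mcid)) {          # binary: null-value rule
    return(if (low < 0 && high > 0) 2 else 0)
  }
  sum(c(low < -mcid && high > -mcid, low < mcid && high > mcid))
}

#' Imprecision rating
#'
#' Compares the comparison's 95% confidence interval against the equivalence
#' range defined by the MCID: an interval entirely inside or entirely on one
#' side of the range raises no concerns; crossing one boundary raises some
#' concerns; crossing both (or crossing the null for a binary outcome where
#' any risk increase matters) raises major concerns.
#'
#' @param ci_low,ci_high 95% interval bounds.
#' @param mcid MCID half-width on the effect scale, or \code{NA} for the
#'   binary null-value rule.
#' @return A concern level, or \code{NA} (not applicable) when no interval
#'   is computable.
#' @export
rate_imprecision <- function(ci_low, ci_high, mcid) {
  if (is.na(ci_low) || is.na(ci_high)) return(NA_character_)
  concern_levels[boundaries_crossed(ci_low, ci_high, mcid) + 1]
}

#' Heterogeneity rating
#'
#' Compares the conclusions drawn from the confidence interval and from the
#' prediction interval against the equivalence range: if the prediction
#' interval crosses no additional boundary the conclusions agree (no
#' concerns); one additional boundary gives some concerns; two give major
#' concerns. With \eqn{\tau^2 = 0} the two intervals coincide.
#'
#' @param ci_low,ci_high Confidence interval bounds.
#' @param pi_low,pi_high Prediction interval bounds.
#' @param mcid MCID half-width, or \code{NA} for binary.
#' @return A concern level, or \code{NA} when not applicable.
#' @export
rate_heterogeneity <- function(ci_low, ci_high, pi_low, pi_high, mcid) {
  if (any(is.na(c(ci_low, ci_high, pi_low, pi_high)))) return(NA_character_)
  extra <- boundaries_crossed(pi_low, pi_high, mcid) -
    boundaries_crossed(ci_low, ci_high, mcid)
  concern_levels[min(max(extra, 0), 2) + 1]
}

#' Incoherence rating
#'
#' Uses the SIDE result for the comparison when applicable: p below the
#' threshold raises major concerns if the direct-indirect disagreement could
#' change the clinical conclusion (|difference| beyond the MCID), otherwise
#' some concerns; p at or above the threshold raises no concerns. Without an
#' applicable SIDE result the global design-by-treatment result is used
#' (flagged gives some concerns); if neither test is applicable (no closed
#' loop) the domain cannot be assessed.
#'
#' @param side A [side_split()] result (may be not applicable).
#' @param global A [design_by_treatment()] result.
#' @param mcid MCID half-width, or \code{NA} for binary outcomes (any
#'   disagreement crossing the null is conclusion-changing).
#' @param threshold Decision threshold (default 0.10).
#' @return A concern level, or \code{NA} when incoherence cannot be
#'   assessed.
#' @export
rate_incoherence <- function(side, global, mcid, threshold = 0.10) {
  if (!is.null(side) && isTRUE(side$applicable)) {
    if (side$p >= threshold) return("no_concerns")
    big <- if (is.na(mcid)) TRUE else abs(side$difference) > mcid
    return(if (big) "major_concerns" else "some_concerns")
  }
  if (isTRUE(global$applicable)) {
    return(if (global$flagged) "some_concerns" else "no_concerns")
  }
  NA_character_
}

#' Overall confidence grade (downgrade ladder)
#'
#' Every comparison starts at \code{high} and is downgraded one step per
#' domain with some concerns and two steps per domain with major concerns,
#' floored at \code{very_low}. Domains rated \code{NA} (not applicable) do
#' not downgrade.
#'
#' @param judgements Named character vector (or list) of the six domain
#'   levels: \code{within_study_bias, reporting_bias, intransitivity,
#'   imprecision, heterogeneity, incoherence}.
#' @return One of \code{"high", "moderate", "low", "very_low"}.
#' @export
rate_overall <- function(judgements) {
  judgements <- unlist(judgements)
  if (length(judgements) != 6) stop("exactly six domain judgements required")
  steps <- sum(vapply(judgements, function(lv) {
    if (is.na(lv)) 0L
    else switch(lv, no_concerns = 0L, some_concerns = 1L,
                major_concerns = 2L,
                stop("unknown concern level: ", lv))
  }, 0L))
  overall_grades[min(1L + steps, 4L)]
}

#' Six-domain confidence ratings for every network comparison
#'
#' Assembles the domain judgements per comparison: within-study bias and
#' intransitivity by the contribution-weighted average rule over per-trial
#' levels, reporting bias from the indicator rules over contributing trials,
#' imprecision/heterogeneity from the league confidence and prediction
#' intervals against the MCID, incoherence from the SIDE/global tests, and
#' the overall grade from the downgrade ladder.
#'
#' @param fit An \code{nma_fit}.
#' @param contrib Contribution matrix from [contribution_matrix()].
#' @param coherence A [coherence_report()].
#' @param rob_levels Named per-trial risk-of-bias levels
#'   (\code{low/moderate/high}).
#' @param intrans_levels Named per-trial intransitivity levels from
#'   [classify_trial_intransitivity()].
#' @param trial_meta Trial-level metadata (see [trial_table()]).
#' @param mcid An [mcid_config()].
#' @param reporting_indicators Logical vector of network-level reporting
#'   bias indicators (see [rate_reporting_bias()]).
#' @return Data frame with one row per comparison: the six domain levels and
#'   the overall grade; class \code{confidence_ratings}.
#' @export
rate_comparisons <- function(fit, contrib, coherence, rob_levels,
                             intrans_levels, trial_meta,
                             mcid = mcid_config(),
                             reporting_indicators = c(grey_literature = TRUE)) {
  lg <- league_table(fit)
  m <- if (fit$outcome_type == "binary") NA_real_ else
    mcid_for(fit$outcome, mcid)
  out <- do.call(rbind, lapply(seq_len(nrow(lg)), function(i) {
    key <- lg$key[i]
    row <- contrib[key, ]
    contributing <- names(row)[row > 0]
    meta <- trial_meta[trial_meta$trial_id %in% contributing, , drop = FALSE]
    pi <- prediction_interval(fit, key)
    side <- coherence$side[[key]]
    j <- list(
      within_study_bias = rate_weighted_domain(row, rob_levels),
      reporting_bias = rate_reporting_bias(reporting_indicators, meta),
      intransitivity = rate_weighted_domain(row, intrans_levels),
      imprecision = rate_imprecision(lg$ci_low[i], lg$ci_high[i], m),
      heterogeneity = rate_heterogeneity(lg$ci_low[i], lg$ci_high[i],
                                         pi$low, pi$high, m),
      incoherence = rate_incoherence(side, coherence$global, m,
                                     coherence$threshold))
    data.frame(key = key, as.data.frame(j, stringsAsFactors = FALSE),
               overall = rate_overall(j), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("confidence_ratings", "data.frame")
  out
}

#' Percent of comparisons downgraded per domain
#'
#' For each of the six domains, the percentage of comparisons rated at least
#' \code{some_concerns}, rounded to the nearest integer (half up). Domains
#' not applicable for any comparison propagate \code{NA}.
#'
#' @param ratings Output of [rate_comparisons()].
#' @return Named numeric vector (percentages), plus \code{n_comparisons}.
#' @export
summarize_downgrades <- function(ratings) {
  domains <- c("within_study_bias", "reporting_bias", "intransitivity",
               "imprecision", "heterogeneity", "incoherence")
  out <- vapply(domains, function(d) {
    lv <- ratings[[d]]
    ok <- !is.na(lv)
    if (!any(ok)) return(NA_real_)
    round_half_up(100 * sum(lv[ok] != "no_concerns") / sum(ok))
  }, 0)
  c(out, n_comparisons = nrow(ratings))
}
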