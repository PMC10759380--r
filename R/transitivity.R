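#' Transitivity assessment configuration
#'
#' Cutoffs and reference comparison for the quantitative transitivity
#' assessment. Defaults: an absolute difference in pooled mean age over 5
#' years, or a statistically significant absolute difference over 0.20 in
#' the pooled proportion of females, indicates a lack of transitivity;
#' sensitivity values are 10 years and 0.30.
#'
#' @param age_cutoff Years (default 5).
#' @param female_cutoff Absolute proportion difference (default 0.20).
#' @param sensitivity_age_cutoff Years (default 10).
#' @param sensitivity_female_cutoff Proportion (default 0.30).
#' @param alpha Significance level for the Fisher screen (default 0.05).
#' @param reference Reference comparison, length-2 character vector
#'   (default HA vs NOP).
#' @return List of class \code{transitivity_config}.
#' @export
transitivity_config <- function(age_cutoff = 5, female_cutoff = 0.20,
                                sensitivity_age_cutoff = 10,
                                sensitivity_female_cutoff = 0.30,
                                alpha = 0.05, reference = c("HA", "NOP")) {
  stopifnot(age_cutoff > 0, female_cutoff > 0, alpha > 0, alpha < 1)
  structure(list(age_cutoff = age_cutoff, female_cutoff = female_cutoff,
                 sensitivity_age_cutoff = sensitivity_age_cutoff,
                 sensitivity_female_cutoff = sensitivity_female_cutoff,
                 alpha = alpha,
                 reference = pair_key(reference[1], reference[2])),
            class = "transitivity_config")
}

#' Pooled effect modifiers per comparison
#'
#' For every comparison in the network, pools the mean age of the trials
#' informing it (combined mean weighted by trial totals) and the overall
#' proportion of females, together with trial and participant counts. The
#' pooled age SD is only available when every trial reports one.
#'
#' @param trials Trial-arm table (all outcomes; modifier pooling is
#'   outcome-agnostic).
#' @return Data frame with one row per comparison: \code{key},
#'   \code{n_trials}, \code{n_participants}, \code{pooled_age},
#'   \code{pooled_age_sd}, \code{females_n}, \code{female_pct}.
#' @export
pool_modifiers <- function(trials) {
  net <- build_network(trials)
  tl <- trial_table(trials)
  keys <- sort(unique(net$edges$key))
  out <- do.call(rbind, lapply(keys, function(k) {
    ids <- unique(net$edges$trial_id[net$edges$key == k])
    rows <- tl[tl$trial_id %in% ids, ]
    have_age <- !is.na(rows$mean_age)
    if (!all(have_age)) {
      warning("comparison ", k, ": ", sum(!have_age),
              " trial(s) without mean age excluded from age pooling")
    }
    pooled_age <- if (any(have_age)) {
      combined_mean(rows$total_n[have_age], rows$mean_age[have_age])
    } else NA_real_
    pooled_age_sd <- if (all(have_age) && all(!is.na(rows$sd_age))) {
      combined_sd(rows$total_n, rows$mean_age, rows$sd_age)
    } else NA_real_
    have_f <- !is.na(rows$females)
    females_n <- if (all(have_f)) sum(rows$females) else NA_real_
    data.frame(key = k, n_trials = nrow(rows),
               n_participants = sum(rows$total_n),
               pooled_age = pooled_age, pooled_age_sd = pooled_age_sd,
               females_n = females_n,
               female_pct = 100 * females_n / sum(rows$total_n),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare pooled modifiers against the reference comparison
#'
#' Adds, per comparison, the difference in pooled mean age and in female
#' percentage versus the reference comparison, a Fisher's exact test on the
#' pooled female/male counts against the reference, and transitivity flags:
#' the age flag uses the absolute cutoff alone (no significance test, the
#' fallback when trial age SDs are unavailable); the gender flag requires
#' both Fisher significance and an absolute difference beyond the cutoff.
#' Qualitative flags (e.g. fracture morphology, surgical indication) are
#' analyst judgements supplied as input rows, not inferred.
#'
#' @param summaries Output of [pool_modifiers()].
#' @param config A [transitivity_config()].
#' @param qualitative Optional data frame of analyst flags with columns
#'   \code{key}, \code{modifier}, \code{rationale} (non-empty).
#' @param sensitivity Use the sensitivity cutoffs instead of the primary
#'   ones (default \code{FALSE}).
#' @return The summaries with \code{age_diff}, \code{female_diff},
#'   \code{fisher_p}, and logical flags \code{flag_age}, \code{flag_gender},
#'   \code{flag_qualitative}, plus \code{n_flags}.
#' @export
compare_to_reference <- function(summaries, config = transitivity_config(),
                                 qualitative = NULL, sensitivity = FALSE) {
  ref <- config$reference
  if (!(ref %in% summaries$key)) {
    stop("configuration error: reference comparison ", ref,
         " is not in the network")
  }
  age_cut <- if (sensitivity) config$sensitivity_age_cutoff else config$age_cutoff
  fem_cut <- if (sensitivity) config$sensitivity_female_cutoff else config$female_cutoff
  if (!is.null(qualitative) && nrow(qualitative) > 0) {
    if (any(!nzchar(qualitative$rationale))) {
      stop("qualitative flags need a non-empty rationale")
    }
  }
  r <- summaries[summaries$key == ref, ]
  summaries$age_diff <- summaries$pooled_age - r$pooled_age
  summaries$female_diff <- summaries$female_pct - r$female_pct
  summaries$fisher_p <- NA_real_
  for (i in seq_len(nrow(summaries))) {
    s <- summaries[i, ]
    if (is.na(s$females_n) || is.na(r$females_n)) next
    tab <- matrix(c(r$females_n, r$n_participants - r$females_n,
                    s$females_n, s$n_participants - s$females_n), 2)
    summaries$fisher_p[i] <- stats::fisher.test(tab)$p.value
  }
  is_ref <- summaries$key == ref
  summaries$flag_age <- !is_ref & !is.na(summaries$age_diff) &
    abs(summaries$age_diff) > age_cut
  summaries$flag_gender <- !is_ref & !is.na(summaries$fisher_p) &
    summaries$fisher_p < config$alpha &
    abs(summaries$female_diff) > 100 * fem_cut
  summaries$flag_qualitative <- FALSE
  if (!is.null(qualitative) && nrow(qualitative) > 0) {
    summaries$flag_qualitative <- summaries$key %in% qualitative$key & !is_ref
  }
  summaries$n_flags <- summaries$flag_age + summaries$flag_gender +
    summaries$flag_qualitative
  summaries
}

#' Per-trial intransitivity level
#'
#' Each trial inherits the transitivity flags of the comparison(s) it
#' informs: 0 flagged modifiers give a \code{"low"} rating, 1 gives
#' \code{"moderate"}, and 2 or more give \code{"high"}.
#'
#' @param trials Trial-arm table.
#' @param assessed Output of [compare_to_reference()].
#' @return Named character vector of levels, one per trial id.
#' @export
classify_trial_intransitivity <- function(trials, assessed) {
  net <- build_network(trials)
  ids <- unique(trials$trial_id)
  out <- vapply(ids, function(id) {
    keys <- unique(net$edges$key[net$edges$trial_id == id])
    rows <- assessed[assessed$key %in% keys, , drop = FALSE]
    # distinct flagged modifiers across the trial's comparisons
    nf <- any(rows$flag_age) + any(rows$flag_gender) + any(rows$flag_qualitative)
    if (nf == 0) "low" else if (nf == 1) "moderate" else "high"
  }, character(1))
  stats::setNames(out, ids)
}

#' Round half away from zero
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values (ties go away from zero, as in printed tables).
#' @export
round_half_up <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Format a transitivity table for display
#'
#' Renders the assessed summaries in the layout of a published transitivity
#' table: comparison, trial and participant counts, pooled age (SD),
#' age difference, female percent and difference with a significance marker
#' (\code{*} for Fisher p < 0.001, \code{ns} otherwise unless the p-value is
#' printed).
#'
#' @param assessed Output of [compare_to_reference()].
#' @param reference Reference key (its rows print "reference" in the
#'   difference columns).
#' @return Character data frame ready for writing as delimited text.
#' @export
format_transitivity_table <- function(assessed,
                                      reference = "HA:NOP") {
  fmt1 <- function(x) ifelse(is.na(x), "NA",
                             sprintf("%.1f", round_half_up(x, 1)))
  marker <- vapply(assessed$fisher_p, function(p) {
    if (is.na(p)) "NA" else if (p < 0.001) "*"
    else if (p < 0.05) sprintf("%.3f", p) else "ns"
  }, "")
  data.frame(
    comparison = assessed$key,
    rcts = assessed$n_trials,
    participants = assessed$n_participants,
    mean_age = paste0(fmt1(assessed$pooled_age), " (",
                      fmt1(assessed$pooled_age_sd), ")"),
    age_difference = ifelse(assessed$key == reference, "reference",
                            fmt1(assessed$age_diff)),
    females_pct = round_half_up(assessed$female_pct),
    female_difference = ifelse(assessed$key == reference, "reference",
                               paste0(round_half_up(assessed$female_diff),
                                      " (", marker, ")")),
    stringsAsFactors = FALSE)
}
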