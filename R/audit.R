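#' Audit configuration
#'
#' Collects every analytic choice of the reliability audit so the report can
#' echo them: outcomes, effect model, transitivity cutoffs, MCIDs,
#' incoherence threshold, trial exclusions, and the sensitivity toggles.
#'
#' @param outcomes Character vector of outcome tokens to audit.
#' @param model Effect model, \code{"random"} (default) or \code{"common"}.
#' @param transitivity A [transitivity_config()].
#' @param mcid An [mcid_config()].
#' @param coherence_threshold p-value threshold indicating incoherence
#'   (default 0.10; both tests have low power).
#' @param exclude_trials Trial ids to drop before any analysis (e.g. a
#'   duplicated report), with the exclusion logged.
#' @param sd_imputation Impute missing continuous SDs ([impute_sd()]) instead
#'   of dropping the affected trials (default \code{FALSE}).
#' @param sensitivity_cutoffs Use the sensitivity transitivity cutoffs
#'   (default \code{FALSE}).
#' @param qualitative Optional analyst flags (see [compare_to_reference()]).
#' @param reporting_indicators Network-level reporting-bias indicators
#'   (see [rate_reporting_bias()]).
#' @return List of class \code{audit_config}.
#' @export
audit_config <- function(outcomes, model = c("random", "common"),
                         transitivity = transitivity_config(),
                         mcid = mcid_config(),
                         coherence_threshold = 0.10,
                         exclude_trials = character(0),
                         sd_imputation = FALSE,
                         sensitivity_cutoffs = FALSE,
                         qualitative = NULL,
                         reporting_indicators = c(grey_literature = TRUE)) {
  if (length(outcomes) == 0) stop("outcome list must be non-empty")
  structure(list(outcomes = outcomes, model = match.arg(model),
                 transitivity = transitivity, mcid = mcid,
                 coherence_threshold = coherence_threshold,
                 exclude_trials = exclude_trials,
                 sd_imputation = sd_imputation,
                 sensitivity_cutoffs = sensitivity_cutoffs,
                 qualitative = qualitative,
                 reporting_indicators = reporting_indicators),
            class = "audit_config")
}

#' Run the full reliability audit
#'
#' Executes the audit stages in dependency order: trial exclusions,
#' network-level transitivity assessment (pooled modifiers versus the
#' reference comparison, per-trial intransitivity levels), then per outcome
#' the network build and loop check, the network meta-analysis, the
#' contribution matrix, the coherence report (SIDE plus the global
#' design-by-treatment test), and the six-domain confidence ratings with
#' their downgrade summary. Trials with missing continuous SDs are dropped
#' (and logged) unless imputation is enabled. A stage failure for one
#' outcome is captured and the remaining outcomes still produce sections.
#'
#' @param trials Trial-arm table (see [load_trials()]).
#' @param config An [audit_config()].
#' @return List of class \code{audit_report}: \code{transitivity} (assessed
#'   summaries), \code{trial_levels}, per-outcome sections under
#'   \code{outcomes}, and a \code{provenance} block echoing every analytic
#'   choice in effect.
#' @export
run_audit <- function(trials, config) {
  log <- character(0)
  if (length(config$exclude_trials) > 0) {
    present <- intersect(config$exclude_trials, trials$trial_id)
    log <- c(log, paste0("excluded by configuration: ",
                         paste(present, collapse = ", ")))
    trials <- trials[!(trials$trial_id %in% config$exclude_trials), ,
                     drop = FALSE]
  }
  summaries <- pool_modifiers(trials)
  assessed <- compare_to_reference(summaries, config$transitivity,
                                   qualitative = config$qualitative,
                                   sensitivity = config$sensitivity_cutoffs)
  trial_levels <- classify_trial_intransitivity(trials, assessed)
  tl <- trial_table(trials)
  rob_levels <- stats::setNames(tl$rob, tl$trial_id)

  sections <- lapply(config$outcomes, function(oc) {
    tryCatch({
      spec <- network_spec(trials, oc,
                           reference = pair_codes(config$transitivity$reference))
      sd_action <- if (spec$outcome_type == "binary") "error"
        else if (config$sd_imputation) "impute" else "drop"
      contrasts <- network_contrasts(spec, sd_action = sd_action)
      dropped <- attr(contrasts, "dropped")
      used <- trials[trials$trial_id %in% contrasts$trial_id &
                       trials$outcome == oc, , drop = FALSE]
      net <- build_network(used)
      fit <- fit_network(contrasts, model = config$model)
      lg <- league_table(fit)
      contrib <- contribution_matrix(fit)
      coh <- coherence_report(contrasts, model = config$model,
                              threshold = config$coherence_threshold)
      ratings <- rate_comparisons(
        fit, contrib, coh, rob_levels, trial_levels, tl,
        mcid = config$mcid,
        reporting_indicators = config$reporting_indicators)
      list(outcome = oc, ok = TRUE, network = net,
           closed_loop = has_closed_loop(net), dropped_missing_sd = dropped,
           fit = fit, league = lg, contribution = contrib, coherence = coh,
           ratings = ratings, downgrades = summarize_downgrades(ratings))
    }, error = function(e) {
      list(outcome = oc, ok = FALSE, error = conditionMessage(e))
    })
  })
  names(sections) <- config$outcomes
  provenance <- list(
    model = config$model,
    coherence_threshold = config$coherence_threshold,
    age_cutoff = if (config$sensitivity_cutoffs)
      config$transitivity$sensitivity_age_cutoff else
      config$transitivity$age_cutoff,
    female_cutoff = if (config$sensitivity_cutoffs)
      config$transitivity$sensitivity_female_cutoff else
      config$transitivity$female_cutoff,
    fisher_alpha = config$transitivity$alpha,
    reference = config$transitivity$reference,
    mcid = unclass(config$mcid),
    sd_imputation = config$sd_imputation,
    sensitivity_cutoffs = config$sensitivity_cutoffs,
    conventions = c(
      "binary effect measure: log odds ratio, 0.5 added to all cells only when a zero cell occurs",
      "network tau2: multivariate DerSimonian-Laird method of moments, one value per network",
      "node splitting: multi-arm trials containing the split pair attach to the direct side; indirect side is a refit of the reduced network",
      "contribution: proportional stream decomposition of hat-matrix rows, shortest streams first",
      "weighted-average rule cut points 1.5/2.5; Fisher two-sided by summing tables with probability <= observed",
      "age flag: absolute cutoff without significance test (trial age SDs unavailable)"),
    log = log)
  structure(list(transitivity = assessed, trial_levels = trial_levels,
                 outcomes = sections, provenance = provenance,
                 config = config),
            class = "audit_report")
}

#' Primary-versus-sensitivity audits with a change list
#'
#' Runs the primary audit and one variant per enabled toggle (alternative
#' transitivity cutoffs, SD imputation, trial exclusions), and lists every
#' transitivity flag, domain level, or overall grade that changed.
#'
#' @param trials Trial-arm table.
#' @param config The primary [audit_config()].
#' @param alt_cutoffs Run a variant with the sensitivity cutoffs.
#' @param sd_imputation Run a variant with SD imputation.
#' @param exclude_trials Optional trial ids for an exclusion variant.
#' @return List with \code{primary}, \code{variants}, and \code{diff} (data
#'   frame of changes: variant, section, item, field, from, to).
#' @export
run_sensitivity <- function(trials, config, alt_cutoffs = FALSE,
                            sd_imputation = FALSE,
                            exclude_trials = NULL) {
  if (!alt_cutoffs && !sd_imputation && is.null(exclude_trials)) {
    stop("enable at least one sensitivity toggle")
  }
  primary <- run_audit(trials, config)
  variants <- list()
  if (alt_cutoffs) {
    cfg <- config; cfg$sensitivity_cutoffs <- TRUE
    variants$alt_cutoffs <- run_audit(trials, cfg)
  }
  if (sd_imputation) {
    cfg <- config; cfg$sd_imputation <- TRUE
    variants$sd_imputation <- run_audit(trials, cfg)
  }
  if (!is.null(exclude_trials)) {
    cfg <- config; cfg$exclude_trials <- union(config$exclude_trials,
                                               exclude_trials)
    variants$exclusion <- run_audit(trials, cfg)
  }
  diff <- do.call(rbind, lapply(names(variants), function(v) {
    audit_diff(primary, variants[[v]], v)
  }))
  list(primary = primary, variants = variants, diff = diff)
}

audit_diff <- function(a, b, variant) {
  out <- list()
  add <- function(section, item, field, from, to) {
    out[[length(out) + 1]] <<- data.frame(
      variant = variant, section = section, item = item, field = field,
      from = as.character(from), to = as.character(to),
      stringsAsFactors = FALSE)
  }
  ta <- a$transitivity; tb <- b$transitivity
  for (k in intersect(ta$key, tb$key)) {
    for (f in c("flag_age", "flag_gender", "flag_qualitative")) {
      va <- ta[[f]][ta$key == k]; vb <- tb[[f]][tb$key == k]
      if (!identical(va, vb)) add("transitivity", k, f, va, vb)
    }
  }
  for (oc in intersect(names(a$outcomes), names(b$outcomes))) {
    ra <- a$outcomes[[oc]]$ratings; rb <- b$outcomes[[oc]]$ratings
    if (is.null(ra) || is.null(rb)) next
    for (k in intersect(ra$key, rb$key)) {
      for (f in c("within_study_bias", "reporting_bias", "intransitivity",
                  "imprecision", "heterogeneity", "incoherence", "overall")) {
        va <- ra[[f]][ra$key == k]; vb <- rb[[f]][rb$key == k]
        if (!identical(va, vb)) add(oc, k, f, va, vb)
      }
    }
  }
  if (length(out) == 0) {
    data.frame(variant = character(0), section = character(0),
               item = character(0), field = character(0),
               from = character(0), to = character(0),
               stringsAsFactors = FALSE)
  } else do.call(rbind, out)
}

#' Write an audit report to disk
#'
#' Emits a JSON report plus delimited tables: the transitivity table, and
#' per outcome the league table, contribution matrix, coherence edge table,
#' confidence ratings, and downgrade summary.
#'
#' @param report An \code{audit_report}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_audit_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(format_transitivity_table(
    report$transitivity, reference = report$provenance$reference),
    file.path(dir, "transitivity.csv"), row.names = FALSE)
  json <- list(provenance = report$provenance,
               trial_levels = as.list(report$trial_levels))
  for (oc in names(report$outcomes)) {
    s <- report$outcomes[[oc]]
    if (!isTRUE(s$ok)) {
      json[[oc]] <- list(error = s$error)
      next
    }
    stem <- function(x) file.path(dir, paste0(oc, "_", x, ".csv"))
    utils::write.csv(s$league, stem("league"), row.names = FALSE)
    utils::write.csv(as.data.frame(s$contribution), stem("contribution"))
    utils::write.csv(s$coherence$edges, stem("coherence"), row.names = FALSE)
    utils::write.csv(s$ratings, stem("ratings"), row.names = FALSE)
    json[[oc]] <- list(
      closed_loop = s$closed_loop,
      dropped_missing_sd = s$dropped_missing_sd,
      tau2 = s$fit$tau2, i2 = s$fit$i2,
      q_total = s$fit$q_total, q_inconsistency = s$fit$q_inconsistency,
      df_inconsistency = s$fit$df_inconsistency,
      global_incoherence_p = s$coherence$global$p,
      downgrades = as.list(s$downgrades))
  }
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}
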