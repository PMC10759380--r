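#' Configuration for synthetic trial networks
#'
#' Describes a trial network with known truth: interventions, true relative
#' effects versus a reference, between-trial heterogeneity, optional
#' incoherence offsets injected into designated comparisons, the edge list
#' with trial counts and per-arm sizes, intervention-specific effect-modifier
#' distributions (the mechanism behind intransitivity: an intervention
#' predominantly given to younger or more often male patients), and a
#' missingness probability for arm SDs.
#'
#' @param interventions Character vector of codes from
#'   [intervention_codes()].
#' @param true_effects Named numeric vector, one entry per intervention:
#'   the true effect versus the reference (the entry equal to 0). Score
#'   points for continuous outcomes, log odds ratios for binary.
#' @param edges Data frame with columns \code{t1}, \code{t2},
#'   \code{n_trials}, \code{n_per_arm}.
#' @param tau Between-trial SD of the true relative effects (default 0).
#' @param incoherence_offsets Named numeric vector keyed by comparison key;
#'   the offset is added to the true effect of every trial on that
#'   comparison (default none).
#' @param outcome Outcome token (default \code{"CS"}).
#' @param outcome_type \code{"continuous"} or \code{"binary"}.
#' @param baseline_mean True mean outcome under the reference intervention
#'   (Constant-score scale, default 60).
#' @param arm_sd True within-arm SD (default 15 score points).
#' @param baseline_risk True event risk under the reference (binary only,
#'   default 0.10).
#' @param modifier_model Data frame with columns \code{intervention},
#'   \code{age_mean}, \code{age_sd}, \code{female_p}; defaults to age 74
#'   (SD 8) and 80% females for every intervention.
#' @param sd_missing_prob Probability that an arm's reported SD is absent
#'   (default 0).
#' @param seed Integer seed; a fixed seed makes the generated network
#'   byte-identical across runs.
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(interventions, true_effects, edges, tau = 0,
                       incoherence_offsets = numeric(0),
                       outcome = "CS", outcome_type = "continuous",
                       baseline_mean = 60, arm_sd = 15, baseline_risk = 0.10,
                       modifier_model = NULL, sd_missing_prob = 0,
                       seed = 1L) {
  stopifnot(tau >= 0, sd_missing_prob >= 0, sd_missing_prob <= 1)
  bad <- setdiff(interventions, intervention_codes())
  if (length(bad) > 0) stop("unknown intervention code(s): ",
                            paste(bad, collapse = ", "))
  if (!setequal(names(true_effects), interventions)) {
    stop("true_effects must name every intervention")
  }
  if (!all(c(edges$t1, edges$t2) %in% interventions)) {
    stop("edge treatments must be drawn from the interventions")
  }
  edge_keys <- pair_key(edges$t1, edges$t2)
  if (length(incoherence_offsets) > 0 &&
      !all(names(incoherence_offsets) %in% edge_keys)) {
    stop("config error: incoherence offset on a non-existent design")
  }
  if (is.null(modifier_model)) {
    modifier_model <- data.frame(intervention = interventions,
                                 age_mean = 74, age_sd = 8, female_p = 0.8,
                                 stringsAsFactors = FALSE)
  }
  structure(list(interventions = interventions, true_effects = true_effects,
                 edges = edges, tau = tau,
                 incoherence_offsets = incoherence_offsets,
                 outcome = outcome, outcome_type = outcome_type,
                 baseline_mean = baseline_mean, arm_sd = arm_sd,
                 baseline_risk = baseline_risk,
                 modifier_model = modifier_model,
                 sd_missing_prob = sd_missing_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic trial network with known truth
#'
#' Per trial, the true relative effect is the consistency value implied by
#' the configured basic effects, plus the design's incoherence offset (if
#' any), plus a between-trial perturbation: each arm receives an independent
#' shift with variance \eqn{\tau^2/2}, so every within-trial contrast has
#' between-trial variance \eqn{\tau^2} and shared-arm covariance
#' \eqn{\tau^2/2}. Continuous arms then draw an observed mean (normal, known
#' sampling variance) and an observed SD (scaled chi-square); binary arms
#' draw events binomially from logit-linked risks. Trial-level modifiers
#' (mean age, female count) are drawn from the mixture of the arms'
#' intervention-specific modifier models. Each trial uses a substream seeded
#' deterministically from the global seed, so partial regeneration is
#' reproducible.
#'
#' @param config A [sim_config()].
#' @return List with \code{trials} (an \code{nma_trials} table) and
#'   \code{truth} (data frame of realized per-trial true contrasts).
#' @export
generate_network <- function(config) {
  rows <- list()
  truth <- list()
  counter <- 0L
  for (e in seq_len(nrow(config$edges))) {
    ed <- config$edges[e, ]
    arms <- sort(c(ed$t1, ed$t2))
    key <- pair_key(arms[1], arms[2])
    offset <- if (key %in% names(config$incoherence_offsets)) {
      config$incoherence_offsets[[key]]
    } else 0
    for (i in seq_len(ed$n_trials)) {
      counter <- counter + 1L
      set.seed(as.integer((as.numeric(config$seed) * 1000003 +
                             counter * 7919) %% 2147483647))
      id <- sprintf("sim_%s_%s_%02d", arms[1], arms[2], i)
      u <- stats::rnorm(2, 0, config$tau / sqrt(2))
      true_m <- config$baseline_mean + config$true_effects[arms] + u
      true_m[2] <- true_m[2] + offset
      n <- rep(ed$n_per_arm, 2)
      mm <- config$modifier_model
      mi <- match(arms, mm$intervention)
      age_draw <- stats::rnorm(2, mm$age_mean[mi], mm$age_sd[mi] / sqrt(n))
      females <- stats::rbinom(2, n, mm$female_p[mi])
      mean_age <- sum(n * age_draw) / sum(n)
      sd_age <- sqrt(sum(n * mm$age_sd[mi]^2) / sum(n))
      if (config$outcome_type == "continuous") {
        obs_mean <- stats::rnorm(2, true_m, config$arm_sd / sqrt(n))
        obs_mean <- pmin(pmax(obs_mean, 0), 100)
        obs_sd <- config$arm_sd *
          sqrt(stats::rchisq(2, n - 1) / (n - 1))
        obs_sd[stats::runif(2) < config$sd_missing_prob] <- NA
        events <- c(NA, NA)
        truth_contrast <- true_m[2] - true_m[1]
      } else {
        lin <- stats::qlogis(config$baseline_risk) +
          config$true_effects[arms] + u
        lin[2] <- lin[2] + offset
        risk <- stats::plogis(lin)
        events <- stats::rbinom(2, n, risk)
        obs_mean <- c(NA, NA); obs_sd <- c(NA, NA)
        truth_contrast <- lin[2] - lin[1]
      }
      rows[[counter]] <- data.frame(
        trial_id = id, intervention = arms, n = n,
        mean = obs_mean, sd = obs_sd, events = events,
        mean_age = mean_age, sd_age = sd_age,
        females = sum(females), fracture_parts = "3-4-part",
        registered = TRUE, outcome_discrepancy = FALSE, rob = "low",
        outcome = config$outcome, stringsAsFactors = FALSE)
      truth[[counter]] <- data.frame(
        trial_id = id, t1 = arms[1], t2 = arms[2], key = key,
        true_contrast = unname(truth_contrast), offset = offset,
        stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  list(trials = as_trials(trials), truth = do.call(rbind, truth))
}

#' Synthetic networks shaped like the three audited analyses
#'
#' Returns a synthetic trial network whose topology, trial counts per
#' comparison, participant totals, pooled ages, and female percentages match
#' the corresponding published transitivity-table block; all outcome values
#' are synthetic. The \code{du} and \code{orman} fixtures code the pooled
#' fixation arms as LCP/TB in the file and apply the standard remapping to
#' ORIF at load time. In each fixture the plate-versus-hemiarthroplasty
#' trial reports its continuous outcomes without an SD, so continuous
#' networks lose that trial (and, in the \code{du} network, every closed
#' loop) unless SD imputation is switched on.
#'
#' @param which One of \code{"davey"}, \code{"du"}, \code{"orman"}.
#' @return An \code{nma_trials} table.
#' @export
fixture_like_published <- function(which = c("davey", "du", "orman")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, "_trials.csv"),
                      package = "nmaudit")
  if (!nzchar(path)) stop("fixture file not found for ", which)
  remap <- if (which %in% c("du", "orman")) c(LCP = "ORIF", TB = "ORIF")
  load_trials(path, remap = remap)
}

#' Analyst (qualitative) transitivity flags for the published-shaped fixtures
#'
#' The qualitative judgements accompanying [fixture_like_published()]: the
#' reverse-arthroplasty-versus-hemiarthroplasty comparison drew only on a
#' trial restricted to fractures with an absolute surgery indication, and
#' the plate-versus-nonoperative comparison leaned heavily on a trial of
#' two-part fractures.
#'
#' @param which One of \code{"davey"}, \code{"du"}, \code{"orman"}.
#' @return Data frame with columns \code{key}, \code{modifier},
#'   \code{rationale}.
#' @export
fixture_qualitative <- function(which = c("davey", "du", "orman")) {
  which <- match.arg(which)
  out <- data.frame(
    key = pair_key("RSA", "HA"),
    modifier = "indication",
    rationale = "evidence restricted to fractures with an absolute surgery indication, unlike the reference trials",
    stringsAsFactors = FALSE)
  if (which == "davey") {
    out <- rbind(out, data.frame(
      key = pair_key("LCP", "NOP"),
      modifier = "fracture_morphology",
      rationale = "45% of the comparison's participants come from a trial restricted to 2-part fractures",
      stringsAsFactors = FALSE))
  }
  out
}
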