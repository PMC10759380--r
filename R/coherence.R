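#' Node-splitting (SIDE) test for one comparison
#'
#' Separates Indirect from Direct Evidence: the direct estimate pools the
#' within-trial contrasts of the comparison (a multi-arm trial containing
#' both interventions is attached to the direct side); the indirect estimate
#' refits the network with every trial containing both interventions removed.
#' The two are compared with a z-test on their difference. The test is only
#' applicable when the comparison has both direct evidence and an indirect
#' connecting path.
#'
#' @param contrasts Contrast data frame from [network_contrasts()].
#' @param key Comparison key (see [pair_key()]).
#' @param model \code{"random"} or \code{"common"}.
#' @param threshold Decision threshold for flagging incoherence (default
#'   0.10, chosen because the test has low power).
#' @return List of class \code{side_result}: \code{key}, \code{direct},
#'   \code{indirect}, \code{difference}, \code{se}, \code{z}, \code{p},
#'   \code{flagged}, \code{applicable}. When not applicable, \code{reason}
#'   says which side is missing.
#' @export
side_split <- function(contrasts, key, model = c("random", "common"),
                       threshold = 0.10) {
  model <- match.arg(model)
  cd <- pair_codes(key)
  de <- direct_evidence(contrasts)
  dir_rows <- de[de$key == key, , drop = FALSE]
  # trials containing both interventions go to the direct side only
  both <- unique(dir_rows$trial_id)
  reduced <- contrasts[!(contrasts$trial_id %in% both), , drop = FALSE]
  na_result <- function(reason) {
    structure(list(key = key, applicable = FALSE, reason = reason,
                   p = NA_real_, flagged = FALSE), class = "side_result")
  }
  if (nrow(dir_rows) == 0) return(na_result("no direct evidence"))
  if (nrow(reduced) == 0) return(na_result("no indirect evidence"))
  g <- igraph::graph_from_data_frame(
    unique(reduced[, c("t1", "t2")]), directed = FALSE,
    vertices = unique(c(reduced$t1, reduced$t2)))
  if (!all(cd %in% igraph::V(g)$name) ||
      is.infinite(igraph::distances(g, cd[1], cd[2])[1, 1])) {
    return(na_result("no indirect evidence"))
  }
  direct <- pool_pairwise(dir_rows$yi, sqrt(dir_rows$vi), model = model)
  ind_fit <- fit_network(reduced, model = model, reference = cd[1])
  lg <- league_table(ind_fit)
  ind_row <- lg[lg$key == key, ]
  indirect <- list(estimate = ind_row$estimate, se = ind_row$se)
  diff <- direct$estimate - indirect$estimate
  se <- sqrt(direct$se^2 + indirect$se^2)
  z <- diff / se
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(key = key, applicable = TRUE, direct = direct,
                 indirect = indirect, difference = diff, se = se, z = z,
                 p = p, flagged = p < threshold, threshold = threshold),
            class = "side_result")
}

#' Design-by-treatment interaction test
#'
#' Global chi-square test for incoherence: the between-design inconsistency
#' component of the fit's Q decomposition, with degrees of freedom equal to
#' the number of independent design-specific contrasts minus the number of
#' basic parameters. In a network without closed loops there is no
#' inconsistency parameter (df = 0) and the test is not applicable.
#'
#' @param fit An \code{nma_fit}.
#' @param threshold Decision threshold (default 0.10).
#' @return List with \code{q}, \code{df}, \code{p}, \code{flagged},
#'   \code{applicable}.
#' @export
design_by_treatment <- function(fit, threshold = 0.10) {
  df <- fit$df_inconsistency
  if (df <= 0) {
    return(list(q = fit$q_inconsistency, df = df, p = NA_real_,
                flagged = FALSE, applicable = FALSE))
  }
  p <- stats::pchisq(fit$q_inconsistency, df, lower.tail = FALSE)
  list(q = fit$q_inconsistency, df = df, p = p,
       flagged = p < threshold, applicable = TRUE)
}

#' Full coherence report for a network
#'
#' Runs the SIDE test on every comparison with direct evidence and attaches
#' the global design-by-treatment result. Comparisons without both evidence
#' routes are marked not applicable, which is the situation in networks
#' without closed loops where coherence cannot be assessed at all.
#'
#' @param contrasts Contrast data frame from [network_contrasts()].
#' @param model \code{"random"} or \code{"common"}.
#' @param threshold Flagging threshold (default 0.10).
#' @return List of class \code{coherence_report}: \code{edges} (data frame
#'   with key, p, flagged, applicable, reason), \code{side} (the raw
#'   [side_split()] results), \code{global}, \code{threshold}.
#' @export
coherence_report <- function(contrasts, model = c("random", "common"),
                             threshold = 0.10) {
  model <- match.arg(model)
  keys <- sort(unique(pair_key(contrasts$t1, contrasts$t2)))
  de <- direct_evidence(contrasts)
  keys <- sort(unique(de$key))
  side <- lapply(keys, function(k) side_split(contrasts, k, model = model,
                                              threshold = threshold))
  names(side) <- keys
  edges <- data.frame(
    key = keys,
    p = vapply(side, function(s) if (s$applicable) s$p else NA_real_, 0),
    flagged = vapply(side, function(s) isTRUE(s$flagged), TRUE),
    applicable = vapply(side, function(s) s$applicable, TRUE),
    reason = vapply(side, function(s)
      if (s$applicable) "" else s$reason, ""),
    stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  fit <- fit_network(contrasts, model = model)
  global <- design_by_treatment(fit, threshold = threshold)
  structure(list(edges = edges, side = side, global = global,
                 threshold = threshold, model = model),
            class = "coherence_report")
}

#' @export
print.coherence_report <- function(x, ...) {
  cat("Coherence report (threshold p <", format(x$threshold), ")\n")
  for (i in seq_len(nrow(x$edges))) {
    e <- x$edges[i, ]
    cat("  ", e$key, ": ",
        if (e$applicable) sprintf("SIDE p = %s%s", format_p(e$p),
                                  if (e$flagged) " [incoherence]" else "")
        else paste0("NA (", e$reason, ")"), "\n", sep = "")
  }
  g <- x$global
  cat("  global design-by-treatment: ",
      if (g$applicable) sprintf("Q = %.2f, df = %d, p = %s%s", g$q, g$df,
                                format_p(g$p),
                                if (g$flagged) " [incoherence]" else "")
      else "NA (no closed loop)", "\n", sep = "")
  invisible(x)
}

format_p <- function(p) {
  if (is.na(p)) "NA" else if (p < 0.001) "<0.001" else sprintf("%.2f", p)
}
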