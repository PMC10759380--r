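#' Intervention vocabulary
#'
#' Controlled vocabulary of intervention codes for proximal humerus fracture
#' networks: nonoperative treatment (NOP), locking compression plate (LCP),
#' intramedullary nail (IMN), hemi-arthroplasty (HA), reverse shoulder
#' arthroplasty (RSA), tension band (TB), and open reduction with internal
#' fixation (ORIF).
#'
#' @return Character vector of valid intervention codes.
#' @export
intervention_codes <- function() {
  c("NOP", "LCP", "IMN", "HA", "RSA", "TB", "ORIF")
}

#' Canonical comparison key
#'
#' Unordered pair of intervention codes, rendered as a canonical string so
#' that \code{A:B} and \code{B:A} compare equal. The two codes must differ.
#'
#' @param a,b Intervention codes (vectorized).
#' @return Character vector of keys of the form \code{"A:B"} with the two
#'   codes in alphabetical order.
#' @export
pair_key <- function(a, b) {
  if (any(a == b)) stop("a comparison requires two distinct interventions")
  ifelse(a < b, paste(a, b, sep = ":"), paste(b, a, sep = ":"))
}

#' Split a comparison key into its two codes
#' @param key Key produced by [pair_key()].
#' @return Character vector of length 2.
#' @export
pair_codes <- function(key) {
  strsplit(key, ":", fixed = TRUE)[[1]]
}

trial_arm_columns <- function() {
  c("trial_id", "intervention", "n", "mean", "sd", "events",
    "mean_age", "sd_age", "females", "fracture_parts",
    "registered", "outcome_discrepancy", "rob", "outcome")
}

#' Read a trial-arm table
#'
#' Reads a delimited (comma, UTF-8, header row) trial-arm table with one row
#' per trial arm per outcome. Columns: \code{trial_id, intervention, n, mean,
#' sd, events, mean_age, sd_age, females, fracture_parts, registered,
#' outcome_discrepancy, rob, outcome}; an empty cell means absent. An
#' optional remapping collapses intervention codes (e.g. LCP and TB pooled
#' into ORIF) before validation.
#'
#' @param path Path to the CSV file.
#' @param remap Named character vector mapping source code to target code,
#'   or \code{NULL} for no remapping.
#' @return A validated trial-arm \code{data.frame} (class \code{nma_trials}).
#' @export
load_trials <- function(path, remap = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = "")
  missing_cols <- setdiff(trial_arm_columns(), names(df))
  if (length(missing_cols) > 0) {
    stop("trial-arm table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, trial_arm_columns()]
  for (col in c("n", "mean", "sd", "events", "mean_age", "sd_age", "females")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("registered", "outcome_discrepancy")) {
    df[[col]] <- as.logical(df[[col]])
  }
  as_trials(df, remap = remap)
}

#' Construct a validated trial-arm table
#'
#' @param df Data frame following the trial-arm schema (see [load_trials()]).
#' @param remap Optional named character vector of code remappings.
#' @return The validated table with class \code{nma_trials}.
#' @export
as_trials <- function(df, remap = NULL) {
  if (!is.null(remap)) {
    df$intervention <- apply_remap(df$intervention, remap)
  }
  validate_trials(df)
  class(df) <- c("nma_trials", "data.frame")
  df
}

#' Apply an intervention-code remapping
#'
#' The remapping must be a function on codes: each source maps to exactly one
#' target. Codes without an entry pass through unchanged.
#'
#' @param codes Character vector of intervention codes.
#' @param remap Named character vector, names = source, values = target.
#' @return Remapped codes.
#' @export
apply_remap <- function(codes, remap) {
  if (length(remap) == 0) return(codes)
  if (anyDuplicated(names(remap)) > 0) {
    stop("remap is not a function: a source code maps to more than one target")
  }
  hit <- codes %in% names(remap)
  codes[hit] <- unname(remap[codes[hit]])
  codes
}

#' Read a remap file (two columns: source_code,target_code)
#' @param path Path to the CSV file.
#' @return Named character vector usable as \code{remap}.
#' @export
read_remap <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

validate_trials <- function(df) {
  bad <- setdiff(unique(df$intervention), intervention_codes())
  if (length(bad) > 0) {
    stop("unknown intervention code(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.na(df$n) & df$n < 1)) stop("arm sample sizes must be >= 1")
  if (any(!is.na(df$sd) & df$sd < 0)) stop("arm SDs must be >= 0")
  ev <- !is.na(df$events)
  if (any(df$events[ev] > df$n[ev])) {
    stop("validation error: events > n for trial(s) ",
         paste(unique(df$trial_id[ev][df$events[ev] > df$n[ev]]),
               collapse = ", "))
  }
  if (any(ev & !is.na(df$mean))) {
    stop("an arm-outcome row must carry a mean-based or an event-based ",
         "payload, not both")
  }
  # within one trial and outcome, arm interventions must be pairwise distinct
  # after remapping (otherwise no within-trial contrast can be formed)
  split_rows <- split(df, list(df$trial_id, df$outcome), drop = TRUE)
  for (grp in split_rows) {
    if (anyDuplicated(grp$intervention) > 0) {
      stop("design error: trial ", grp$trial_id[1],
           " has two arms mapping to the same intervention (",
           paste(grp$intervention[duplicated(grp$intervention)],
                 collapse = ", "), ")")
    }
    if (nrow(grp) < 2) {
      stop("trial ", grp$trial_id[1], " has fewer than 2 arms for outcome ",
           grp$outcome[1])
    }
  }
  # trial-level fields must be constant within a trial
  tl <- unique(df[, c("trial_id", "mean_age", "females", "registered",
                      "outcome_discrepancy", "rob")])
  if (anyDuplicated(tl$trial_id) > 0) {
    stop("trial-level fields differ across rows of one trial: ",
         paste(unique(tl$trial_id[duplicated(tl$trial_id)]), collapse = ", "))
  }
  tot <- trial_table(df)
  fem <- !is.na(tot$females)
  if (any(tot$females[fem] > tot$total_n[fem])) {
    stop("validation error: females > total participants for trial(s) ",
         paste(tot$trial_id[fem][tot$females[fem] > tot$total_n[fem]],
               collapse = ", "))
  }
  invisible(df)
}

#' Write a trial-arm table
#'
#' Inverse of [load_trials()]: absent values are written as empty cells so
#' that a load/write/load round trip reproduces every field.
#'
#' @param trials Trial-arm table.
#' @param path Output CSV path.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials[, trial_arm_columns()], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Trial-level summary table
#'
#' One row per trial with its total sample size (max over outcomes of the sum
#' of arm sizes) and trial-level modifier/metadata fields.
#'
#' @param trials Trial-arm table.
#' @return Data frame with one row per \code{trial_id}.
#' @export
trial_table <- function(trials) {
  ids <- unique(trials$trial_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    rows <- trials[trials$trial_id == id, ]
    per_outcome <- tapply(rows$n, rows$outcome, sum)
    data.frame(trial_id = id,
               total_n = max(per_outcome),
               mean_age = rows$mean_age[1],
               sd_age = rows$sd_age[1],
               females = rows$females[1],
               fracture_parts = rows$fracture_parts[1],
               registered = rows$registered[1],
               outcome_discrepancy = rows$outcome_discrepancy[1],
               rob = rows$rob[1],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Define the analysis network for one outcome
#'
#' Selects the rows of the trial-arm table carrying the requested outcome and
#' binds the reference comparison used by the transitivity assessment.
#'
#' @param trials Trial-arm table.
#' @param outcome One of \code{"CS"}, \code{"DASH"}, \code{"additional_surgery"}
#'   (or any outcome token present in the table).
#' @param reference Length-2 character vector naming the reference comparison
#'   (default \code{c("HA", "NOP")}).
#' @return List with elements \code{trials} (arm rows for the outcome),
#'   \code{outcome}, \code{outcome_type} (\code{"continuous"} or
#'   \code{"binary"}), \code{reference}; class \code{nma_spec}.
#' @export
network_spec <- function(trials, outcome, reference = c("HA", "NOP")) {
  rows <- trials[trials$outcome == outcome, , drop = FALSE]
  if (nrow(rows) == 0) stop("no trial provides outcome ", outcome)
  outcome_type <- if (all(is.na(rows$events))) "continuous" else "binary"
  spec <- list(trials = rows, outcome = outcome, outcome_type = outcome_type,
               reference = pair_key(reference[1], reference[2]))
  class(spec) <- "nma_spec"
  spec
}

#' Build the comparison network graph
#'
#' Nodes are interventions; each trial contributes one edge per pair of its
#' arms, so a three-arm trial contributes three parallel edges and edge
#' multiplicity equals the number of trials informing a comparison.
#'
#' @param spec An \code{nma_spec} from [network_spec()], or a trial-arm table
#'   (then taken as a single-outcome network).
#' @return List with \code{nodes}, \code{edges} (data frame: \code{t1},
#'   \code{t2}, \code{key}, \code{trial_id}) and \code{designs}; class
#'   \code{nma_network}.
#' @export
build_network <- function(spec) {
  trials <- if (inherits(spec, "nma_spec")) spec$trials else spec
  if (is.null(trials) || nrow(trials) == 0) {
    stop("empty trial list: cannot build a network")
  }
  edges <- do.call(rbind, lapply(split(trials, trials$trial_id), function(grp) {
    arms <- sort(unique(grp$intervention))
    if (length(arms) < 2) return(NULL)
    idx <- utils::combn(length(arms), 2)
    data.frame(t1 = pmin(arms[idx[1, ]], arms[idx[2, ]]),
               t2 = pmax(arms[idx[1, ]], arms[idx[2, ]]),
               trial_id = grp$trial_id[1],
               stringsAsFactors = FALSE)
  }))
  rownames(edges) <- NULL
  edges$key <- pair_key(edges$t1, edges$t2)
  designs <- vapply(split(trials, trials$trial_id), function(grp) {
    paste(sort(unique(grp$intervention)), collapse = "+")
  }, character(1))
  net <- list(nodes = sort(unique(trials$intervention)),
              edges = edges[, c("t1", "t2", "key", "trial_id")],
              designs = designs)
  class(net) <- "nma_network"
  net
}

#' Does the network contain a closed loop?
#'
#' A closed loop is a cycle through at least three distinct interventions,
#' i.e. a configuration in which an indirect estimate of some comparison can
#' be contrasted with direct evidence. Two independent trials on the same
#' comparison do not form a loop. Multi-arm trials create loops (their arm
#' pairs form a triangle), which is the standard convention for the
#' design-based machinery.
#'
#' @param net An \code{nma_network} from [build_network()].
#' @return \code{TRUE} if at least one cycle of length >= 3 exists.
#' @export
has_closed_loop <- function(net) {
  simple <- unique(data.frame(t1 = pmin(net$edges$t1, net$edges$t2),
                              t2 = pmax(net$edges$t1, net$edges$t2),
                              stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(simple, directed = FALSE,
                                     vertices = net$nodes)
  ncomp <- igraph::components(g)$no
  nrow(simple) > length(net$nodes) - ncomp
}

#' Connected components of the comparison network
#' @param net An \code{nma_network}.
#' @return List of character vectors of node names, one per component.
#' @export
network_components <- function(net) {
  g <- igraph::graph_from_data_frame(unique(net$edges[, c("t1", "t2")]),
                                     directed = FALSE, vertices = net$nodes)
  comp <- igraph::components(g)
  split(names(comp$membership), comp$membership)
}

#' @export
print.nma_network <- function(x, ...) {
  mult <- table(x$edges$key)
  cat("Comparison network:", length(x$nodes), "interventions,",
      length(mult), "comparisons,", length(unique(x$edges$trial_id)),
      "trials\n")
  cat("  closed loop:", if (has_closed_loop(x)) "yes" else "no", "\n")
  for (k in names(mult)) cat("  ", k, ": ", mult[[k]], " trial(s)\n", sep = "")
  invisible(x)
}
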