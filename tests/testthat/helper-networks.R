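# hand-built contrast tables used across tests (columns as produced by
# network_contrasts)
contrast_df <- function(trial_id, t1, t2, yi, vi, cov_base = 0,
                        design = NULL) {
  if (is.null(design)) design <- paste(pmin(t1, t2), pmax(t1, t2), sep = "+")
  data.frame(trial_id = trial_id, t1 = t1, t2 = t2, yi = yi, vi = vi,
             cov_base = cov_base, design = design, stringsAsFactors = FALSE)
}

# chain HA--NOP--RSA with unit variances: yi(HA:NOP)=2, yi(NOP:RSA)=5
chain_contrasts <- function() {
  contrast_df(c("s1", "s2"), c("HA", "NOP"), c("NOP", "RSA"), c(2, 5), 1)
}

# chain plus a direct HA:RSA trial
triangle_contrasts <- function(direct_yi = 7, direct_vi = 1) {
  rbind(chain_contrasts(),
        contrast_df("s3", "HA", "RSA", direct_yi, direct_vi))
}

# minimal two-trial two-arm trial-arm table for a continuous outcome
toy_trials <- function() {
  df <- data.frame(
    trial_id = rep(c("a", "b"), each = 2),
    intervention = c("HA", "NOP", "NOP", "RSA"),
    n = 50, mean = c(64, 62, 61, 66), sd = c(15, 14, 15, 13),
    events = NA_real_, mean_age = rep(c(75, 72), each = 2),
    sd_age = NA_real_, females = rep(c(40, 38), each = 2),
    fracture_parts = "3-4-part", registered = TRUE,
    outcome_discrepancy = FALSE, rob = "low", outcome = "CS",
    stringsAsFactors = FALSE)
  as_trials(df)
}

# brute-force search for a simple cycle of length >= 3 on an edge list
brute_force_loop <- function(t1, t2) {
  nodes <- sort(unique(c(t1, t2)))
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    sort(unique(c(t2[t1 == v], t1[t2 == v])))
  })
  found <- FALSE
  walk <- function(start, current, visited) {
    if (found) return(invisible())
    for (nb in adj[[current]]) {
      if (nb == start && length(visited) >= 3) { found <<- TRUE; return(invisible()) }
      if (!(nb %in% visited) && nb > start) walk(start, nb, c(visited, nb))
    }
  }
  for (v in nodes) walk(v, v, v)
  found
}
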