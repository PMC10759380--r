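#' Frequentist network meta-analysis by weighted least squares
#'
#' Contrast-based estimation on the edge-incidence design: basic parameters
#' (one per intervention versus the network reference node) minimize the
#' generalized least-squares criterion with the exact per-trial contrast
#' covariance, so a multi-arm trial's correlated contrasts enter as one block
#' (off-diagonal entries equal the shared baseline-arm variance) and are not
#' double counted. The random-effects model inflates the within-trial
#' covariance by a single network \eqn{\tau^2} (compound symmetry within a
#' trial: \eqn{\tau^2} on the diagonal, \eqn{\tau^2/2} between contrasts),
#' with \eqn{\tau^2} estimated by the multivariate method-of-moments
#' generalization of DerSimonian-Laird:
#' \eqn{\hat\tau^2 = \max(0, (Q - df) / tr(MG))} where \eqn{M} is the
#' residual weight projector of the common-effects fit.
#'
#' The total heterogeneity/inconsistency statistic \eqn{Q} is decomposed into
#' within-design heterogeneity (residual of a model with design-specific
#' relative effects) and between-design inconsistency, the basis of the
#' design-by-treatment interaction test.
#'
#' @param contrasts Contrast data frame from [network_contrasts()] (columns
#'   \code{trial_id, t1, t2, yi, vi, cov_base, design}).
#' @param model \code{"random"} (default) or \code{"common"}.
#' @param reference Reference intervention; default is the alphabetically
#'   first node.
#' @param tau2 Optional fixed value for \eqn{\tau^2} (bypasses estimation).
#' @return An object of class \code{nma_fit}: basic estimates, covariance,
#'   \eqn{\tau^2}, \eqn{I^2}, and the Q decomposition.
#' @export
fit_network <- function(contrasts, model = c("random", "common"),
                        reference = NULL, tau2 = NULL) {
  model <- match.arg(model)
  if (nrow(contrasts) == 0) stop("no contrasts to fit")
  if (any(contrasts$vi <= 0)) stop("all contrast variances must be > 0")
  nodes <- sort(unique(c(contrasts$t1, contrasts$t2)))
  g <- igraph::graph_from_data_frame(
    unique(contrasts[, c("t1", "t2")]), directed = FALSE, vertices = nodes)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    groups <- split(names(comp$membership), comp$membership)
    stop("connectivity error: network has ", comp$no, " components: ",
         paste(vapply(groups, paste, "", collapse = ","), collapse = " | "))
  }
  if (is.null(reference)) reference <- nodes[1]
  if (!(reference %in% nodes)) stop("reference node not in network")
  params <- setdiff(nodes, reference)
  n <- nrow(contrasts)
  if (n < length(params)) {
    stop("underdetermined error: fewer contrasts (", n,
         ") than basic parameters (", length(params), ")")
  }

  X <- matrix(0, n, length(params), dimnames = list(NULL, params))
  for (i in seq_len(n)) {
    if (contrasts$t2[i] != reference) X[i, contrasts$t2[i]] <- 1
    if (contrasts$t1[i] != reference) X[i, contrasts$t1[i]] <- -1
  }

  blocks <- split(seq_len(n), contrasts$trial_id)
  build_V <- function(t2) {
    V <- matrix(0, n, n)
    for (idx in blocks) {
      k <- length(idx)
      B <- matrix(contrasts$cov_base[idx[1]] + t2 / 2, k, k)
      diag(B) <- contrasts$vi[idx] + t2
      V[idx, idx] <- B
    }
    V
  }

  gls <- function(V) {
    W <- solve(V)
    XtW <- crossprod(X, W)
    B <- MASS::ginv(XtW %*% X)
    theta <- drop(B %*% XtW %*% contrasts$yi)
    names(theta) <- params
    resid <- contrasts$yi - drop(X %*% theta)
    list(theta = theta, vcov = B, W = W, XtW = XtW,
         q = drop(crossprod(resid, W %*% resid)))
  }

  common <- gls(build_V(0))
  r <- qr(X)$rank
  df_total <- n - r
  q_total <- common$q

  if (is.null(tau2)) {
    if (df_total > 0) {
      # G: compound-symmetry unit between-trial covariance
      G <- matrix(0, n, n)
      for (idx in blocks) {
        k <- length(idx)
        Gb <- matrix(0.5, k, k); diag(Gb) <- 1
        G[idx, idx] <- Gb
      }
      W <- common$W
      M <- W - t(common$XtW) %*% common$vcov %*% common$XtW
      denom <- sum(diag(M %*% G))
      tau2 <- max(0, (q_total - df_total) / denom)
    } else {
      tau2 <- 0
    }
  }

  fit0 <- if (model == "random") gls(build_V(tau2)) else common

  # design-based decomposition: a model with design-specific relative effects
  design_ids <- unique(contrasts$design)
  dcols <- unlist(lapply(design_ids, function(d) {
    trts <- strsplit(d, "+", fixed = TRUE)[[1]]
    paste(d, trts[-1], sep = "|")
  }))
  Xd <- matrix(0, n, length(dcols), dimnames = list(NULL, dcols))
  for (i in seq_len(n)) {
    d <- contrasts$design[i]
    trts <- strsplit(d, "+", fixed = TRUE)[[1]]
    base <- trts[1]
    if (contrasts$t2[i] != base) Xd[i, paste(d, contrasts$t2[i], sep = "|")] <- 1
    if (contrasts$t1[i] != base) Xd[i, paste(d, contrasts$t1[i], sep = "|")] <- -1
  }
  W0 <- common$W
  Bd <- MASS::ginv(crossprod(Xd, W0) %*% Xd)
  theta_d <- drop(Bd %*% crossprod(Xd, W0) %*% contrasts$yi)
  resid_d <- contrasts$yi - drop(Xd %*% theta_d)
  q_het <- drop(crossprod(resid_d, W0 %*% resid_d))
  r_d <- qr(Xd)$rank
  df_het <- n - r_d
  q_inc <- max(0, q_total - q_het)
  df_inc <- r_d - r

  i2 <- if (df_total > 0 && q_total > 0) max(0, (q_total - df_total) / q_total) else 0

  theta_full <- c(stats::setNames(0, reference), fit0$theta)[nodes]
  vcov_full <- matrix(0, length(nodes), length(nodes),
                      dimnames = list(nodes, nodes))
  vcov_full[params, params] <- fit0$vcov
  vcov_full <- (vcov_full + t(vcov_full)) / 2

  fit <- list(nodes = nodes, reference = reference, model = model,
              basic_estimates = theta_full, vcov = vcov_full,
              tau2 = tau2, i2 = i2,
              q_total = q_total, df_total = df_total,
              q_heterogeneity = q_het, df_heterogeneity = df_het,
              q_inconsistency = q_inc, df_inconsistency = df_inc,
              contrasts = contrasts,
              outcome = attr(contrasts, "outcome"),
              outcome_type = attr(contrasts, "outcome_type"))
  class(fit) <- "nma_fit"
  fit
}

#' @export
print.nma_fit <- function(x, ...) {
  cat("Network meta-analysis (", x$model, "-effects), ",
      length(unique(x$contrasts$trial_id)), " trials, ",
      length(x$nodes), " interventions, reference ", x$reference, "\n",
      sep = "")
  cat(sprintf("  tau2 = %.4f, I2 = %.1f%%, Q = %.2f (df %d) = %.2f het (df %d) + %.2f incons (df %d)\n",
              x$tau2, 100 * x$i2, x$q_total, x$df_total,
              x$q_heterogeneity, x$df_heterogeneity,
              x$q_inconsistency, x$df_inconsistency))
  print(round(x$basic_estimates, 4))
  invisible(x)
}

#' All pairwise network estimates (league table)
#'
#' For every comparison the estimate is the difference of basic parameters
#' with its standard error taken from the fit covariance; the table is
#' anti-symmetric under reversal of the pair.
#'
#' @param fit An \code{nma_fit}.
#' @return Data frame with \code{t1}, \code{t2}, \code{key}, \code{estimate}
#'   (effect of \code{t2} versus \code{t1}), \code{se}, \code{ci_low},
#'   \code{ci_high}.
#' @export
league_table <- function(fit) {
  nodes <- fit$nodes
  idx <- utils::combn(length(nodes), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(idx)), function(j) {
    a <- nodes[idx[1, j]]; b <- nodes[idx[2, j]]
    est <- fit$basic_estimates[b] - fit$basic_estimates[a]
    v <- fit$vcov[a, a] + fit$vcov[b, b] - 2 * fit$vcov[a, b]
    se <- sqrt(max(v, 0))
    data.frame(t1 = a, t2 = b, key = pair_key(a, b), estimate = unname(est),
               se = se, ci_low = unname(est) - 1.959964 * se,
               ci_high = unname(est) + 1.959964 * se,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Prediction interval for one comparison
#'
#' 95% interval for the effect in a new trial: the league estimate with
#' variance inflated by the network \eqn{\tau^2}.
#'
#' @param fit An \code{nma_fit}.
#' @param key Comparison key.
#' @return List with \code{low} and \code{high}.
#' @export
prediction_interval <- function(fit, key) {
  lg <- league_table(fit)
  row <- lg[lg$key == key, ]
  if (nrow(row) == 0) stop("comparison not in network: ", key)
  se_pi <- sqrt(row$se^2 + fit$tau2)
  list(low = row$estimate - 1.959964 * se_pi,
       high = row$estimate + 1.959964 * se_pi)
}

# Direct (within-trial) evidence per comparison: one row per trial per arm
# pair, with the exact contrast variance (for a pair of non-baseline arms,
# var = v_i + v_j - 2 cov_base).
direct_evidence <- function(contrasts, tau2 = 0) {
  out <- do.call(rbind, lapply(split(contrasts, contrasts$trial_id), function(grp) {
    arms <- c(grp$t1[1], grp$t2)
    rows <- list()
    for (i in seq_len(nrow(grp))) {
      rows[[length(rows) + 1]] <- data.frame(
        trial_id = grp$trial_id[1], t1 = grp$t1[i], t2 = grp$t2[i],
        yi = grp$yi[i], vi = grp$vi[i], stringsAsFactors = FALSE)
    }
    if (nrow(grp) > 1) {
      idx <- utils::combn(nrow(grp), 2)
      for (j in seq_len(ncol(idx))) {
        i1 <- idx[1, j]; i2 <- idx[2, j]
        rows[[length(rows) + 1]] <- data.frame(
          trial_id = grp$trial_id[1], t1 = grp$t2[i1], t2 = grp$t2[i2],
          yi = grp$yi[i2] - grp$yi[i1],
          vi = grp$vi[i1] + grp$vi[i2] - 2 * grp$cov_base[i1],
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }))
  rownames(out) <- NULL
  out$key <- pair_key(out$t1, out$t2)
  out$weight <- 1 / (out$vi + tau2)
  out
}

#' Per-trial contribution matrix
#'
#' Derives, for every network comparison, the percentage of the estimate
#' contributed by each trial. The hat-matrix row of the edge-aggregated
#' consistency model is a unit evidence flow from one intervention of the
#' comparison to the other; the flow is decomposed into direct and indirect
#' streams (shortest streams first), each stream's flow is spread equally
#' over the edges of its path, and each edge's share is then allocated to its
#' trials proportionally to their inverse-variance weights. Rows sum to 100;
#' a trial with no path into a comparison contributes 0.
#'
#' @param fit An \code{nma_fit}.
#' @return Matrix (comparisons x trials) of percentage contributions, with
#'   comparison keys as row names and trial ids as column names.
#' @export
contribution_matrix <- function(fit) {
  de <- direct_evidence(fit$contrasts,
                        tau2 = if (fit$model == "random") fit$tau2 else 0)
  edge_keys <- sort(unique(de$key))
  w_edge <- vapply(edge_keys, function(k) sum(de$weight[de$key == k]), 0)
  nodes <- fit$nodes
  params <- setdiff(nodes, fit$reference)
  Xa <- matrix(0, length(edge_keys), length(params),
               dimnames = list(edge_keys, params))
  for (i in seq_along(edge_keys)) {
    cd <- pair_codes(edge_keys[i])
    if (cd[2] != fit$reference) Xa[i, cd[2]] <- 1
    if (cd[1] != fit$reference) Xa[i, cd[1]] <- -1
  }
  Wa <- diag(w_edge, nrow = length(edge_keys))
  B <- MASS::ginv(crossprod(Xa, Wa) %*% Xa)
  proj <- B %*% crossprod(Xa, Wa)   # maps edge data to basic parameters

  trials <- unique(de$trial_id)
  comps <- utils::combn(length(nodes), 2)
  out <- matrix(0, ncol(comps), length(trials),
                dimnames = list(character(ncol(comps)), trials))
  for (j in seq_len(ncol(comps))) {
    a <- nodes[comps[1, j]]; b <- nodes[comps[2, j]]
    xc <- stats::setNames(numeric(length(params)), params)
    if (b != fit$reference) xc[b] <- 1
    if (a != fit$reference) xc[a] <- -1
    h <- drop(xc %*% proj)   # flow per edge, oriented t1 -> t2 when positive
    edge_contrib <- flow_contributions(edge_keys, h, from = a, to = b,
                                       nodes = nodes)
    row <- stats::setNames(numeric(length(trials)), trials)
    for (k in seq_along(edge_keys)) {
      if (edge_contrib[k] <= 0) next
      sel <- de$key == edge_keys[k]
      row[de$trial_id[sel]] <- row[de$trial_id[sel]] +
        edge_contrib[k] * de$weight[sel] / sum(de$weight[sel])
    }
    rownames(out)[j] <- pair_key(a, b)
    out[j, ] <- 100 * row
  }
  out
}

# Decompose a unit evidence flow (hat-matrix row) into streams. Returns the
# per-edge contribution (summing to ~1). Streams are extracted shortest
# first; each stream of flow f along a path of length L contributes f/L to
# every edge on the path.
flow_contributions <- function(edge_keys, h, from, to, nodes,
                               tol = 1e-10, max_streams = 10000) {
  contrib <- stats::setNames(numeric(length(edge_keys)), edge_keys)
  resid <- abs(h)
  resid[resid < tol] <- 0
  # orientation: edge key "A:B" has design direction A -> B; positive flow
  # follows it, negative flow runs B -> A
  ends <- t(vapply(edge_keys, pair_codes, character(2)))
  src <- ifelse(h >= 0, ends[, 1], ends[, 2])
  dst <- ifelse(h >= 0, ends[, 2], ends[, 1])
  for (s in seq_len(max_streams)) {
    active <- resid > tol
    if (!any(active)) break
    g <- igraph::graph_from_data_frame(
      data.frame(from = src[active], to = dst[active]),
      directed = TRUE, vertices = nodes)
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = from, to = to, output = "epath"))
    ep <- sp$epath[[1]]
    if (length(ep) == 0) break
    path_idx <- which(active)[as.integer(ep)]
    f <- min(resid[path_idx])
    contrib[path_idx] <- contrib[path_idx] + f / length(path_idx)
    resid[path_idx] <- resid[path_idx] - f
  }
  total <- sum(contrib)
  if (total > 0) contrib <- contrib / total
  contrib
}
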