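as_adjacency <- function(graph) {
  if (inherits(graph, "correlation_network")) {
    n <- length(graph$nodes)
    A <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
    if (nrow(graph$edges)) {
      i <- match(graph$edges$taxon_i, graph$nodes)
      j <- match(graph$edges$taxon_j, graph$nodes)
      A[cbind(i, j)] <- 1
      A[cbind(j, i)] <- 1
    }
    A
  } else if (inherits(graph, "igraph")) {
    as.matrix(igraph::as_adjacency_matrix(graph, sparse = FALSE)) > 0
  } else {
    A <- as.matrix(graph)
    stopifnot(nrow(A) == ncol(A))
    (A != 0) * 1
  }
}

#' Natural connectivity of a graph
#'
#' The log of the average eigenvalue exponential of the (unweighted)
#' adjacency matrix, ln( (1/N) sum_i exp(lambda_i) ): a robustness index
#' counting weighted closed walks that decreases as a network fragments.
#' Computed overflow-safely via log-sum-exp.
#'
#' @param graph a `correlation_network`, igraph object, or adjacency matrix
#'   with N >= 1 nodes.
#' @return natural connectivity (0 for an edgeless graph).
#' @export
natural_connectivity <- function(graph) {
  A <- as_adjacency(graph) * 1
  if (nrow(A) == 0) stop("graph has no nodes")
  if (all(A == 0)) return(0)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  log_mean_exp(ev)
}

#' Node-removal attack simulation
#'
#' Removes nodes one at a time and tracks natural connectivity of the
#' remaining induced subgraph. Random mode removes uniformly random orders
#' per replicate and reports the pointwise mean with a 95% percentile band;
#' targeted mode removes in static descending initial-degree order (ties by
#' node ID).
#'
#' @param network a `correlation_network` (non-empty).
#' @param mode `"random"` or `"targeted"`.
#' @param replicates random-order replicates (>= 2; default 100).
#' @param seed integer seed (random mode).
#' @return data.frame of class `attack_curve`: `fraction_removed`, `nc`
#'   (mean over replicates in random mode), plus `lower`, `upper` (95%
#'   percentile band) in random mode.
#' @export
attack_simulation <- function(network, mode = c("random", "targeted"),
                              replicates = 100, seed = 1) {
  mode <- match.arg(mode)
  A <- as_adjacency(network)
  V <- nrow(A)
  if (V == 0) stop("empty network")
  nc_along <- function(order_idx) {
    remaining <- seq_len(V)
    vals <- numeric(V)
    vals[1] <- natural_connectivity(A)
    for (k in seq_len(V - 1)) {
      remaining <- setdiff(remaining, order_idx[k])
      vals[k + 1] <- natural_connectivity(A[remaining, remaining, drop = FALSE])
    }
    vals
  }
  frac <- (seq_len(V) - 1) / V
  if (mode == "targeted") {
    deg <- rowSums(A)
    ord <- order(-deg, rownames(A) %||% as.character(seq_len(V)))
    out <- data.frame(fraction_removed = frac, nc = nc_along(ord))
  } else {
    if (replicates < 2) stop("random mode needs at least 2 replicates")
    set.seed(seed)
    mat <- vapply(seq_len(replicates),
                  function(b) nc_along(sample.int(V)), numeric(V))
    out <- data.frame(
      fraction_removed = frac,
      nc = rowMeans(mat),
      lower = apply(mat, 1, lerp_quantile, p = 0.025),
      upper = apply(mat, 1, lerp_quantile, p = 0.975)
    )
  }
  out$mode <- mode
  class(out) <- c("attack_curve", "data.frame")
  out
}

#' Compare two attack curves
#'
#' Interpolates both natural-connectivity trajectories onto a common
#' removal-fraction grid and applies a two-sided unpaired Wilcoxon rank-sum
#' test to the pointwise values. Fully tied inputs (identical curves) return
#' p = 1, since the tie-corrected normal approximation is undefined there.
#'
#' @param curveA,curveB `attack_curve` data.frames.
#' @param grid_points number of common grid points (default 25).
#' @return list `statistic`, `p`, `grid`.
#' @export
compare_attack_curves <- function(curveA, curveB, grid_points = 25) {
  lo <- max(min(curveA$fraction_removed), min(curveB$fraction_removed))
  hi <- min(max(curveA$fraction_removed), max(curveB$fraction_removed))
  grid <- seq(lo, hi, length.out = grid_points)
  if (length(grid) < 3) stop("fewer than 3 common grid points")
  a <- stats::approx(curveA$fraction_removed, curveA$nc, xout = grid)$y
  b <- stats::approx(curveB$fraction_removed, curveB$nc, xout = grid)$y
  if (all(a == b)) return(list(statistic = NA_real_, p = 1, grid = grid))
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value, grid = grid)
}

#' Compact letter display from a pairwise p-value matrix
#'
#' Insert-and-absorb letter assignment: any pair with p < alpha shares no
#' letter; non-significant pairs share at least one letter where
#' consistently possible. Deterministic ordering.
#'
#' @param p_matrix symmetric pairwise p-value matrix with stratum dimnames.
#' @param alpha significance level (default 0.05).
#' @return named character vector of letter codes.
#' @export
compact_letter_display <- function(p_matrix, alpha = 0.05) {
  p_matrix <- as.matrix(p_matrix)
  if (!isSymmetric(unname(p_matrix))) stop("p matrix must be symmetric")
  k <- nrow(p_matrix)
  strata <- rownames(p_matrix) %||% paste0("G", seq_len(k))
  sets <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in seq.int(i + 1, k)) {
    if (is.na(p_matrix[i, j]) || p_matrix[i, j] >= alpha) next
    new_sets <- list()
    for (s in sets) {
      if (all(c(i, j) %in% s)) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: drop sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) for (b in seq_along(new_sets)) {
      if (a != b && keep[a] && keep[b] &&
          all(new_sets[[a]] %in% new_sets[[b]]) &&
          (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
        keep[a] <- FALSE
      }
    }
    sets <- unique(new_sets[keep])
  }
  sets <- sets[order(vapply(sets, min, numeric(1)))]
  letters_out <- vapply(seq_len(k), function(s) {
    paste0(letters[which(vapply(sets, function(st) s %in% st, logical(1)))],
           collapse = "")
  }, character(1))
  names(letters_out) <- strata
  letters_out
}

#' Bootstrap comparison of network topology across strata
#'
#' Per stratum, resamples samples with replacement B times, recomputing the
#' SparCC correlation matrix (closed-form single-resample path), thresholded
#' network and topology metrics per resample. For each metric and stratum
#' pair it forms the bootstrap difference distribution delta* and a
#' two-tailed p-value. The default `"percentile"` method uses
#' p = 2 min(u, 1 - u) with the mid-p tail
#' u = frac\{delta* < 0\} + frac\{delta* = 0\}/2. The `"bc"` method applies
#' Efron's bias correction: with z0 = qnorm(frac\{delta* < delta_hat\})
#' (ties counted half), u is adjusted to pnorm(qnorm(u) - 2 z0) before the
#' two-sided fold. In calibration simulations on thresholded edge-count
#' metrics the bias-corrected variant is markedly anti-conservative — the
#' bootstrap bias it corrects for is an artifact of duplicate-sample
#' correlation inflation, so the correction pushes in the wrong direction —
#' which is why it is not the default; see the package vignette. P-values
#' are Holm-adjusted across the pairwise family per metric, then rendered
#' as compact letters.
#'
#' Per-resample networks threshold on |r| alone (see the package vignette):
#' at the sample sizes involved, edges passing |r| > `edge_r` are virtually
#' always significant at q < 0.005, and re-running a permutation test inside
#' every bootstrap replicate would multiply cost by the permutation count.
#'
#' @param fracs samples-x-taxa relative abundances (or `abundance_table`).
#' @param strata_labels per-sample stratum labels (>= 20 samples each).
#' @param B bootstrap iterations (default 1000).
#' @param edge_r absolute-correlation edge threshold (default 0.5).
#' @param metrics metric names from [fast_topology_metrics()] to compare.
#' @param method `"percentile"` (default) or `"bc"`; see Details.
#' @param alpha significance level for letters (default 0.05).
#' @param seed integer seed.
#' @return list of class `bootstrap_comparison`: per metric a list with
#'   `observed`, `boot` (B x strata), `p` (pairwise),
#'   `p_holm`, `letters`.
#' @export
bootstrap_topology_compare <- function(fracs, strata_labels, B = 1000,
                                       edge_r = 0.5,
                                       metrics = c("n_edges", "n_positive",
                                                   "n_negative", "n_vertices",
                                                   "average_degree",
                                                   "clustering_coefficient"),
                                       method = c("percentile", "bc"),
                                       alpha = 0.05, seed = 1) {
  method <- match.arg(method)
  if (inherits(fracs, "abundance_table")) fracs <- fracs$rel_abundance
  fracs <- as.matrix(fracs)
  strata <- sort(unique(strata_labels))
  if (length(strata) < 2) stop("need at least 2 strata to compare")
  ns <- table(strata_labels)
  if (any(ns < 20)) stop("each stratum needs at least 20 samples")
  if (B < 2) stop("B must be at least 2")
  set.seed(seed)
  obs <- matrix(NA_real_, length(strata), length(metrics),
                dimnames = list(strata, metrics))
  boot <- array(NA_real_, c(B, length(strata), length(metrics)),
                dimnames = list(NULL, strata, metrics))
  for (g in seq_along(strata)) {
    rows <- which(strata_labels == strata[g])
    fr <- smooth_fractions(fracs[rows, , drop = FALSE])
    obs[g, ] <- fast_topology_metrics(sparcc_fast(fr), edge_r)[metrics]
    for (b in seq_len(B)) {
      idx <- sample(rows, length(rows), replace = TRUE)
      frb <- smooth_fractions(fracs[idx, , drop = FALSE])
      boot[b, g, ] <- fast_topology_metrics(sparcc_fast(frb), edge_r)[metrics]
    }
  }
  pairs <- utils::combn(seq_along(strata), 2)
  out <- list()
  for (m in metrics) {
    pm <- matrix(NA_real_, length(strata), length(strata),
                 dimnames = list(strata, strata))
    diag(pm) <- 1
    flags <- character(0)
    for (k in seq_len(ncol(pairs))) {
      g <- pairs[1, k]; h <- pairs[2, k]
      d_hat <- obs[g, m] - obs[h, m]
      d_star <- boot[, g, m] - boot[, h, m]
      if (length(unique(d_star)) == 1) {
        pm[g, h] <- pm[h, g] <- 1
        flags <- c(flags, paste(strata[g], strata[h], sep = ":"))
        next
      }
      # mid-p tail: ties at zero counted half, so discrete difference
      # distributions with an atom at zero stay calibrated
      u <- pmin(pmax((sum(d_star < 0) + 0.5 * sum(d_star == 0)) / B,
                     0.5 / B), 1 - 0.5 / B)
      if (method == "bc") {
        z0 <- stats::qnorm(pmin(pmax(
          (sum(d_star < d_hat) + 0.5 * sum(d_star == d_hat)) / B,
          0.5 / B), 1 - 0.5 / B))
        u <- stats::pnorm(stats::qnorm(u) - 2 * z0)
      }
      pm[g, h] <- pm[h, g] <- 2 * min(u, 1 - u)
    }
    ph <- pm
    up <- pm[upper.tri(pm)]
    ph[upper.tri(ph)] <- stats::p.adjust(up, method = "holm")
    ph[lower.tri(ph)] <- t(ph)[lower.tri(ph)]
    out[[m]] <- list(observed = obs[, m], boot = boot[, , m, drop = TRUE],
                     p = pm, p_holm = ph,
                     letters = compact_letter_display(ph, alpha),
                     degenerate_pairs = flags)
  }
  structure(out, class = "bootstrap_comparison", B = B, method = method)
}
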