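# SparCC: basis correlations from log-ratio variances under a sparsity
# assumption. With t_ij = var(log(x_i/x_j)) and basis variances w_i, the
# sparse approximation gives the linear system
#   (D - 2) w_i + sum_j w_j = sum_{j != i} t_ij
# whose solution yields rho_ij = (w_i + w_j - t_ij) / (2 sqrt(w_i w_j)).
# Strongly correlated pairs violate the sparsity assumption and are
# iteratively excluded from the system.

logratio_variances <- function(fracs) {
  L <- log(fracs)
  C <- stats::cov(L)
  v <- diag(C)
  t_mat <- outer(v, v, "+") - 2 * C
  t_mat[t_mat < 0] <- 0
  diag(t_mat) <- 0
  t_mat
}

solve_basis <- function(t_mat, excluded = NULL) {
  D <- nrow(t_mat)
  if (is.null(excluded) || nrow(excluded) == 0) {
    s <- rowSums(t_mat)
    S <- sum(s) / (2 * D - 2)
    w <- (s - S) / (D - 2)
  } else {
    allowed <- matrix(TRUE, D, D)
    diag(allowed) <- FALSE
    for (k in seq_len(nrow(excluded))) {
      allowed[excluded[k, 1], excluded[k, 2]] <- FALSE
      allowed[excluded[k, 2], excluded[k, 1]] <- FALSE
    }
    M <- allowed * 1
    diag(M) <- rowSums(allowed)
    s <- rowSums(t_mat * allowed)
    w <- tryCatch(solve(M, s), error = function(e)
      stop("basis variance system is singular after exclusions"))
  }
  bad <- w <= 0
  if (any(bad)) {
    warning(sum(bad), " non-positive basis variance(s) clipped")
    w[bad] <- 1e-10
  }
  w
}

rho_from_basis <- function(t_mat, w) {
  r <- (outer(w, w, "+") - t_mat) / (2 * sqrt(outer(w, w)))
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

sparcc_single <- function(fracs, excl_iters = Inf, excl_threshold = 0.1) {
  t_mat <- logratio_variances(fracs)
  D <- nrow(t_mat)
  excluded <- matrix(integer(0), 0, 2)
  w <- solve_basis(t_mat)
  r <- rho_from_basis(t_mat, w)
  if (excl_iters > 0) {
    for (it in seq_len(min(excl_iters, D * (D - 1) / 2))) {
      a <- abs(r)
      diag(a) <- 0
      if (nrow(excluded)) a[excluded] <- 0
      if (nrow(excluded)) a[excluded[, 2:1, drop = FALSE]] <- 0
      m <- which.max(a)
      if (a[m] <= excl_threshold) break
      ij <- arrayInd(m, dim(a))
      # refuse to fully disconnect a taxon from the system
      cnt <- tabulate(c(excluded, ij), nbins = D)
      if (any(cnt[ij] >= D - 3)) break
      excluded <- rbind(excluded, ij)
      w <- suppressWarnings(solve_basis(t_mat, excluded))
      r <- rho_from_basis(t_mat, w)
    }
  }
  list(rho = r, t_mat = t_mat, omega = w, excluded = excluded)
}

smooth_fractions <- function(x) {
  # pseudocount-smoothed fractions: half the smallest nonzero value
  pc <- min(x[x > 0]) / 2
  x <- x + pc
  x / rowSums(x)
}

#' SparCC basis correlations
#'
#' Estimates taxon-taxon basis correlations from compositional data. When
#' counts are supplied, each resample draws fractions from a Dirichlet
#' posterior (counts + 1) and the final correlation is the elementwise
#' median over resamples; plain fractions are pseudocount-smoothed and used
#' directly. Each resample solves the sparse basis-variance system with
#' iterative exclusion of the most strongly correlated pairs: by default the
#' loop runs until no remaining pair exceeds the exclusion threshold (a
#' fixed small cap such as the classic 10 iterations truncates the
#' procedure whenever a correlated block contributes more strong pairs than
#' the cap, leaving sparsity violations that bias the whole matrix — set
#' `excl_iters` to a finite value to reproduce that behavior).
#'
#' @param data an `abundance_table`, a count matrix or a fraction matrix
#'   (samples x taxa, >= 4 taxa).
#' @param resamples Dirichlet resamples when counts are available
#'   (default 20).
#' @param excl_iters maximum strong-pair exclusion iterations
#'   (default `Inf`: iterate to convergence; a guard never lets a taxon be
#'   disconnected from the system).
#' @param excl_threshold exclusion trigger on |rho| (default 0.1).
#' @param seed integer seed for the Dirichlet draws.
#' @return list of class `sparcc_estimate`: `rho`, `t_mat`, `omega`, `taxa`,
#'   `settings`.
#' @export
sparcc_correlations <- function(data, resamples = 20, excl_iters = Inf,
                                excl_threshold = 0.1, seed = 1) {
  if (inherits(data, "abundance_table")) {
    taxa <- data$taxon_ids
    counts <- data$counts
    fracs <- data$rel_abundance
  } else {
    m <- as.matrix(data)
    taxa <- colnames(m) %||% paste0("T", seq_len(ncol(m)))
    is_counts <- all(m == round(m)) && any(m > 1)
    counts <- if (is_counts) m else NULL
    fracs <- if (is_counts) m / rowSums(m) else m
  }
  D <- ncol(fracs)
  if (D < 4) stop("SparCC needs at least 4 taxa")
  set.seed(seed)
  if (!is.null(counts) && resamples > 1) {
    rhos <- array(NA_real_, c(D, D, resamples))
    last <- NULL
    for (b in seq_len(resamples)) {
      alpha <- counts + 1
      g <- matrix(stats::rgamma(length(alpha), shape = alpha), nrow(alpha), D)
      fr <- g / rowSums(g)
      last <- sparcc_single(fr, excl_iters, excl_threshold)
      rhos[, , b] <- last$rho
    }
    rho <- apply(rhos, c(1, 2), stats::median)
    rho <- (rho + t(rho)) / 2
    diag(rho) <- 1
    est <- list(rho = rho, t_mat = last$t_mat, omega = last$omega)
  } else {
    est <- sparcc_single(smooth_fractions(fracs), excl_iters, excl_threshold)
  }
  dimnames(est$rho) <- list(taxa, taxa)
  structure(
    list(rho = est$rho, t_mat = est$t_mat, omega = est$omega, taxa = taxa,
         settings = list(resamples = resamples, excl_iters = excl_iters,
                         excl_threshold = excl_threshold, seed = seed)),
    class = "sparcc_estimate"
  )
}

sparcc_fast <- function(fracs) {
  # single-resample closed-form path (no exclusion): used for permutation
  # nulls and bootstrap resamples
  t_mat <- logratio_variances(fracs)
  D <- nrow(t_mat)
  s <- rowSums(t_mat)
  S <- sum(s) / (2 * D - 2)
  w <- (s - S) / (D - 2)
  w[w <= 0] <- 1e-10
  rho_from_basis(t_mat, w)
}

#' Permutation significance for SparCC correlations
#'
#' Each taxon's sample vector is permuted independently per permutation, the
#' correlation matrix is recomputed on the closed-form single-resample path,
#' and two-sided pseudo p-values are
#' (1 + #\{|rho_perm| >= |rho_obs|\}) / (1 + n_perm), with
#' Benjamini-Hochberg q-values over the upper triangle.
#'
#' With `convention = "pseudocount"` the minimum attainable p is
#' 1/(1 + n_perm), which floors the attainable Benjamini-Hochberg q at
#' m / (k (1 + n_perm)) for k significant pairs among m; the `"raw"`
#' convention (#\{|rho_perm| >= |rho_obs|\} / n_perm, as in the classic
#' SparCC pseudo-p script) can reach 0 and therefore supports stringent
#' q cutoffs such as q < 0.005 at moderate permutation counts.
#'
#' @param estimate a `sparcc_estimate`.
#' @param data the same data the estimate was computed from.
#' @param n_perm number of permutations (>= 19; default 1000).
#' @param convention `"pseudocount"` (default) or `"raw"`; see Details.
#' @param seed integer seed.
#' @return list with matrices `p` and `q`.
#' @export
sparcc_pvalues <- function(estimate, data, n_perm = 1000,
                           convention = c("pseudocount", "raw"), seed = 1) {
  convention <- match.arg(convention)
  if (n_perm < 19) stop("n_perm too small for usable p resolution")
  fracs <- if (inherits(data, "abundance_table")) data$rel_abundance else {
    m <- as.matrix(data)
    if (all(m == round(m)) && any(m > 1)) m / rowSums(m) else m
  }
  fr <- smooth_fractions(fracs)
  n <- nrow(fr); D <- ncol(fr)
  obs <- abs(estimate$rho)
  set.seed(seed)
  exceed <- matrix(0, D, D)
  for (b in seq_len(n_perm)) {
    perm <- fr
    for (j in seq_len(D)) perm[, j] <- fr[sample.int(n), j]
    exceed <- exceed + (abs(sparcc_fast(perm)) >= obs)
  }
  p <- if (convention == "pseudocount") (1 + exceed) / (1 + n_perm) else
    exceed / n_perm
  diag(p) <- NA
  ut <- upper.tri(p)
  q <- p
  q[ut] <- stats::p.adjust(p[ut], method = "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  dimnames(p) <- dimnames(q) <- dimnames(estimate$rho)
  list(p = p, q = q)
}
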