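#' Alpha diversity (observed richness and Shannon index)
#'
#' @param table an `abundance_table`.
#' @return data.frame with `sample_id`, `observed_richness`, `shannon`
#'   (natural log).
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  x <- table$rel_abundance
  data.frame(
    sample_id = table$sample_ids,
    observed_richness = rowSums(x > 0),
    shannon = as.numeric(vegan::diversity(x, index = "shannon")),
    stringsAsFactors = FALSE
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(i, j) = sum |x_i - x_j| / sum (x_i + x_j) over taxa, computed on the
#' relative abundances.
#'
#' @param table an `abundance_table` (>= 2 samples).
#' @return symmetric matrix with zero diagonal, sample IDs as dimnames.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (length(table$sample_ids) < 2) stop("need at least 2 samples")
  d <- as.matrix(vegan::vegdist(table$rel_abundance, method = "bray"))
  dimnames(d) <- list(table$sample_ids, table$sample_ids)
  d
}

#' Dysbiosis score against a reference group
#'
#' A sample's dysbiosis score is its median Bray-Curtis dissimilarity to the
#' reference-group samples, excluding the sample itself and any sample from
#' the same subject. The dysbiotic flag marks scores above the configured
#' percentile (default 90th, linear-interpolation quantile) of the
#' reference-group scores.
#'
#' @param dist symmetric Bray-Curtis matrix (from [bray_curtis()]).
#' @param metadata data.frame with `sample_id`, `subject_id` and the grouping
#'   column.
#' @param reference_group value of `group_col` defining the reference set
#'   (default `"nonASD"`).
#' @param group_col grouping column name (default `"group"`).
#' @param percentile flag threshold percentile in (0, 100\] (default 90).
#' @return data.frame of class `dysbiosis_result` with `sample_id`, `score`,
#'   `dysbiotic`; threshold in attribute `"threshold"`.
#' @export
dysbiosis_score <- function(dist, metadata, reference_group = "nonASD",
                            group_col = "group", percentile = 90) {
  ids <- rownames(dist)
  stopifnot(!is.null(ids), all(ids %in% metadata$sample_id))
  md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  ref_idx <- which(md[[group_col]] == reference_group)
  if (length(ref_idx) < 3) stop("reference group needs at least 3 samples")
  scores <- vapply(seq_along(ids), function(s) {
    adm <- ref_idx[ref_idx != s & md$subject_id[ref_idx] != md$subject_id[s]]
    if (length(adm) == 0) stop("empty admissible reference set for sample ", ids[s])
    stats::median(dist[s, adm])
  }, numeric(1))
  thr <- lerp_quantile(scores[ref_idx], percentile / 100)
  out <- data.frame(sample_id = ids, score = scores,
                    dysbiotic = scores > thr, stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  class(out) <- c("dysbiosis_result", "data.frame")
  out
}

hat_matrix <- function(X) {
  qrX <- qr(X)
  Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  tcrossprod(Q)
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance with sequential (Type I)
#' sums of squares on the Gower-centered squared-distance matrix, terms
#' added in the order given. P-values use whole-row permutations:
#' p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm).
#'
#' @param dist symmetric dissimilarity matrix.
#' @param metadata data.frame aligned to the matrix via `sample_id`.
#' @param terms character vector of metadata columns, in model order.
#' @param n_perm number of permutations (>= 99; default 9999).
#' @param seed integer seed for the permutation stream.
#' @return data.frame with one row per term plus a `Residual` row: `df`,
#'   `SS`, `R2`, `F`, `p`.
#' @export
permanova <- function(dist, metadata, terms, n_perm = 9999, seed = 1) {
  if (n_perm < 99) stop("n_perm must be at least 99")
  ids <- rownames(dist)
  md <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  missing_terms <- setdiff(terms, names(md))
  if (length(missing_terms)) stop("terms not in metadata: ",
                                  paste(missing_terms, collapse = ", "))
  cc <- stats::complete.cases(md[, terms, drop = FALSE])
  md <- md[cc, , drop = FALSE]
  D <- dist[cc, cc, drop = FALSE]
  n <- nrow(D)
  for (tm in terms) {
    v <- md[[tm]]
    if (length(unique(v)) < 2) stop("constant term: ", tm)
  }
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  # sequential hat-matrix differences (fixed under permutation of G)
  Xs <- matrix(1, n, 1)
  hats <- vector("list", length(terms))
  dfs <- numeric(length(terms))
  H_prev <- hat_matrix(Xs)
  rank_prev <- 1L
  for (k in seq_along(terms)) {
    mm <- stats::model.matrix(stats::as.formula(paste("~", paste(terms[seq_len(k)], collapse = "+"))), md)
    qrk <- qr(mm)
    if (qrk$rank <= rank_prev) stop("singular design at term: ", terms[k])
    H_k <- hat_matrix(mm)
    hats[[k]] <- H_k - H_prev
    dfs[k] <- qrk$rank - rank_prev
    H_prev <- H_k
    rank_prev <- qrk$rank
  }
  R <- diag(n) - H_prev
  df_res <- n - rank_prev
  SS_total <- sum(diag(G))
  ss_terms <- vapply(hats, function(Hd) sum(Hd * G), numeric(1))
  # a perfectly explained matrix leaves a residual that is zero up to
  # rounding; clamp so F degenerates to +Inf rather than a signed artifact
  clamp0 <- function(x) if (x < SS_total * 1e-12) 0 else x
  SS_res <- clamp0(sum(R * G))
  F_obs <- (ss_terms / dfs) / (SS_res / df_res)
  set.seed(seed)
  exceed <- numeric(length(terms))
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    Gp <- G[p, p]
    ssp <- vapply(hats, function(Hd) sum(Hd * Gp), numeric(1))
    ssr <- clamp0(sum(R * Gp))
    Fp <- (ssp / dfs) / (ssr / df_res)
    exceed <- exceed + (Fp >= F_obs)
  }
  pvals <- (1 + exceed) / (1 + n_perm)
  data.frame(
    term = c(terms, "Residual"),
    df = c(dfs, df_res),
    SS = c(ss_terms, SS_res),
    R2 = c(ss_terms, SS_res) / SS_total,
    F = c(F_obs, NA),
    p = c(pvals, NA),
    stringsAsFactors = FALSE
  )
}
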