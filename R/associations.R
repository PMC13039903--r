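#' Centered log-ratio transform
#'
#' Per sample, y = log(x + delta) - mean(log(x + delta)); the default
#' pseudocount delta is half the smallest nonzero relative abundance in the
#' whole table.
#'
#' @param table an `abundance_table` or a fraction matrix.
#' @param pseudocount pseudocount; NULL for the half-minimum default.
#' @return transformed samples-x-taxa matrix (rows sum to 0).
#' @export
clr_transform <- function(table, pseudocount = NULL) {
  x <- if (inherits(table, "abundance_table")) table$rel_abundance else as.matrix(table)
  if (any(rowSums(x) == 0)) stop("all-zero sample(s)")
  delta <- pseudocount %||% (min(x[x > 0]) / 2)
  L <- log(x + delta)
  L - rowMeans(L)
}

#' Prepare model covariates
#'
#' Binary yes/no fields become 1/0; continuous covariates can be discretized
#' into quartiles (linear-interpolation cutpoints, ties to the lower
#' quartile); eating-behavior subscales can be reduced to their two leading
#' principal components (centered, unit-scaled), with explained-variance
#' shares attached. Constant covariates are dropped with a warning.
#'
#' @param metadata data.frame.
#' @param covariates columns to carry through.
#' @param binary_vars columns to coerce to 1/0.
#' @param quartile_vars continuous columns to discretize into quartiles.
#' @param pc_vars subscale columns to reduce; ignored when fewer than 3.
#' @param n_pc number of leading components (default 2).
#' @return covariate data.frame; PCA variance shares in attribute
#'   `"pc_variance"`.
#' @export
prepare_covariates <- function(metadata, covariates,
                               binary_vars = character(0),
                               quartile_vars = character(0),
                               pc_vars = character(0), n_pc = 2) {
  missing <- setdiff(c(covariates, binary_vars, quartile_vars, pc_vars),
                     names(metadata))
  if (length(missing)) stop("covariates not in metadata: ",
                            paste(missing, collapse = ", "))
  out <- metadata[, covariates, drop = FALSE]
  for (v in intersect(binary_vars, names(out))) {
    val <- out[[v]]
    out[[v]] <- if (is.numeric(val)) as.integer(val != 0) else
      as.integer(tolower(as.character(val)) %in% c("yes", "y", "1", "true", "m"))
  }
  for (v in intersect(quartile_vars, names(out))) {
    cuts <- unique(vapply(c(.25, .5, .75), lerp_quantile, numeric(1), x = out[[v]]))
    out[[v]] <- as.integer(cut(out[[v]], breaks = c(-Inf, cuts, Inf), right = TRUE))
  }
  keep <- vapply(out, function(col) length(unique(col)) > 1, logical(1))
  if (any(!keep)) {
    warning("dropping constant covariate(s): ",
            paste(names(out)[!keep], collapse = ", "))
    out <- out[, keep, drop = FALSE]
  }
  pc_share <- NULL
  if (length(pc_vars) >= 3) {
    pca <- stats::prcomp(metadata[, pc_vars, drop = FALSE],
                         center = TRUE, scale. = TRUE)
    share <- pca$sdev^2 / sum(pca$sdev^2)
    for (k in seq_len(n_pc)) out[[paste0("behavior_pc", k)]] <- pca$x[, k]
    pc_share <- share[seq_len(n_pc)]
  }
  attr(out, "pc_variance") <- pc_share
  out
}

ols_fit <- function(y, X) {
  # OLS with coefficient SEs via the normal equations on a QR factorization
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) return(NULL)
  coef <- qr.coef(qrX, y)
  res <- y - X %*% coef
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))          # (R'R)^-1 in pivoted order
  piv <- qrX$pivot
  se <- numeric(ncol(X))
  se[piv] <- sqrt(diag(XtXinv) * sigma2)
  names(se) <- colnames(X)
  t_stat <- coef / se
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  list(coef = coef, se = se, p = p, df = df)
}

#' Per-feature diet-microbiome association models
#'
#' For each (feature, diet variable) pair, fits OLS of the transformed
#' abundance on the standardized diet variable plus adjustment covariates
#' (age, sex, gastrointestinal symptoms by convention), with two-sided Wald
#' p-values and Benjamini-Hochberg q-values within each metadata panel.
#' Complete cases per model; models with fewer than `min_n` cases or a
#' rank-deficient design are skipped.
#'
#' @param transformed samples-x-features matrix (e.g. [clr_transform()]
#'   output) with sample IDs as rownames.
#' @param diet_vars data.frame of diet variables with `sample_id` plus one
#'   column per variable.
#' @param covariates data.frame of adjustment covariates with `sample_id`.
#' @param panels named list mapping panel name -> diet variable names;
#'   default puts all variables in one panel.
#' @param min_n minimum complete cases per model (default 20).
#' @return data.frame of class `association_result`: feature, variable,
#'   panel, coef, se, p, q, n, sig_q10, sig_q05.
#' @export
fit_feature_associations <- function(transformed, diet_vars, covariates,
                                     panels = NULL, min_n = 20) {
  ids <- rownames(transformed)
  stopifnot(!is.null(ids))
  vars <- setdiff(names(diet_vars), "sample_id")
  panels <- panels %||% list(all = vars)
  cov_cols <- setdiff(names(covariates), "sample_id")
  rows <- list()
  for (panel in names(panels)) for (v in panels[[panel]]) {
    dv <- diet_vars[[v]][match(ids, diet_vars$sample_id)]
    cv <- covariates[match(ids, covariates$sample_id), cov_cols, drop = FALSE]
    cc <- stats::complete.cases(dv, cv)
    if (sum(cc) < min_n) next
    dvz <- as.numeric(scale(dv[cc]))
    X <- stats::model.matrix(~ ., data = cbind(diet = dvz, cv[cc, , drop = FALSE]))
    for (f in colnames(transformed)) {
      fit <- ols_fit(transformed[cc, f], X)
      if (is.null(fit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, variable = v, panel = panel,
        coef = unname(fit$coef["diet"]), se = unname(fit$se["diet"]),
        p = unname(fit$p["diet"]), n = sum(cc), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no fittable models")
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  for (panel in unique(res$panel)) {
    idx <- res$panel == panel
    res$q[idx] <- stats::p.adjust(res$p[idx], method = "BH")
  }
  res$sig_q10 <- res$q < 0.1
  res$sig_q05 <- res$q < 0.05
  class(res) <- c("association_result", "data.frame")
  res
}

#' Rank features by association breadth and count cross-group overlap
#'
#' Per panel, features are ranked by their number of significant (q < 0.1)
#' associations, descending, with ties broken by the smallest minimum q and
#' then lexicographic feature ID; the top `k` unique features are retained.
#' When a second result set is supplied, overlap counts between the two
#' top lists are reported for Venn-style summaries.
#'
#' @param results an `association_result`.
#' @param k features retained per panel (default 50).
#' @param other optional second `association_result` to intersect with.
#' @return data.frame with `panel`, `feature`, `n_sig`, `min_q`, `rank`;
#'   overlap counts (per panel) in attribute `"overlap"` when `other` given.
#' @export
select_top_features <- function(results, k = 50, other = NULL) {
  rank_panel <- function(res) {
    sig <- res[res$sig_q10, , drop = FALSE]
    if (nrow(sig) == 0) return(NULL)
    agg <- do.call(rbind, lapply(split(sig, sig$feature), function(d) {
      data.frame(feature = d$feature[1], n_sig = nrow(d), min_q = min(d$q),
                 stringsAsFactors = FALSE)
    }))
    agg <- agg[order(-agg$n_sig, agg$min_q, agg$feature), , drop = FALSE]
    utils::head(agg, k)
  }
  out <- list()
  for (panel in unique(results$panel)) {
    top <- rank_panel(results[results$panel == panel, , drop = FALSE])
    if (is.null(top)) {
      warning("no significant associations in panel ", panel)
      next
    }
    top$panel <- panel
    top$rank <- seq_len(nrow(top))
    out[[panel]] <- top
  }
  out <- if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else
    data.frame(feature = character(0), n_sig = integer(0), min_q = numeric(0),
               panel = character(0), rank = integer(0))
  if (!is.null(other)) {
    ov <- vapply(unique(out$panel), function(panel) {
      mine <- out$feature[out$panel == panel]
      theirs <- select_top_features(other[other$panel == panel, , drop = FALSE], k)$feature
      length(intersect(mine, theirs))
    }, numeric(1))
    attr(out, "overlap") <- ov
  }
  out
}

#' Diet-by-group interaction models
#'
#' Per (feature, diet variable), fits
#' feature ~ diet + group + diet:group + covariates and reports the
#' interaction coefficient with Benjamini-Hochberg q-values (flag q < 0.2).
#'
#' @inheritParams fit_feature_associations
#' @param group per-sample two-level factor (data.frame with `sample_id` and
#'   `group`).
#' @return data.frame of class `interaction_result`.
#' @export
fit_interaction_models <- function(transformed, diet_vars, group, covariates,
                                   min_n = 20) {
  ids <- rownames(transformed)
  grp <- factor(group$group[match(ids, group$sample_id)])
  if (nlevels(droplevels(grp)) < 2) stop("both groups must be represented")
  vars <- setdiff(names(diet_vars), "sample_id")
  cov_cols <- setdiff(names(covariates), "sample_id")
  rows <- list()
  for (v in vars) {
    dv <- diet_vars[[v]][match(ids, diet_vars$sample_id)]
    cv <- covariates[match(ids, covariates$sample_id), cov_cols, drop = FALSE]
    cc <- stats::complete.cases(dv, grp, cv)
    if (sum(cc) < min_n) next
    dvz <- as.numeric(scale(dv[cc]))
    dat <- cbind(data.frame(diet = dvz, group = droplevels(grp[cc])),
                 cv[cc, , drop = FALSE])
    X <- stats::model.matrix(~ diet * group + ., data = dat)
    int_col <- grep("^diet:group", colnames(X), value = TRUE)[1]
    for (f in colnames(transformed)) {
      fit <- ols_fit(transformed[cc, f], X)
      if (is.null(fit)) next
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, variable = v,
        coef = unname(fit$coef[int_col]), se = unname(fit$se[int_col]),
        p = unname(fit$p[int_col]), n = sum(cc), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no fittable interaction models")
  res <- do.call(rbind, rows)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res$sig_q20 <- res$q < 0.2
  class(res) <- c("interaction_result", "data.frame")
  res
}

#' Greedy 1:1 nearest-neighbor matching
#'
#' Matches each treated sample to one control without replacement: exact on
#' the categorical variables, minimal absolute age difference among the
#' exact-category candidates, greedy over a seed-shuffled treated order.
#' Unmatched treated units are dropped with a warning. A balance report of
#' standardized mean differences before and after matching is attached.
#'
#' @param metadata data.frame with `sample_id` and the matching variables.
#' @param treat_col,treat_level column/value identifying the treated group.
#' @param exact_vars categorical variables matched exactly
#'   (default sex and gastrointestinal symptoms).
#' @param distance_var continuous variable minimized (default `"age"`).
#' @param strict error when any treated unit has no candidate.
#' @param seed integer seed for the treated-order shuffle.
#' @return data.frame of matched pairs (`treated`, `control`); balance SMDs
#'   in attribute `"balance"`.
#' @export
nearest_neighbor_match <- function(metadata, treat_col = "group",
                                   treat_level = "ASD",
                                   exact_vars = c("sex", "gi_symptoms"),
                                   distance_var = "age",
                                   strict = FALSE, seed = 1) {
  treated <- which(metadata[[treat_col]] == treat_level)
  controls <- which(metadata[[treat_col]] != treat_level)
  if (!length(treated) || !length(controls)) stop("both groups must be non-empty")
  set.seed(seed)
  treated <- treated[sample.int(length(treated))]
  available <- rep(TRUE, nrow(metadata))
  pairs <- list()
  unmatched <- character(0)
  key <- do.call(paste, c(metadata[, exact_vars, drop = FALSE], sep = "\r"))
  for (t in treated) {
    cand <- controls[available[controls] & key[controls] == key[t]]
    if (!length(cand)) {
      if (strict) stop("no matching candidate for treated unit ",
                       metadata$sample_id[t])
      unmatched <- c(unmatched, metadata$sample_id[t])
      next
    }
    d <- abs(metadata[[distance_var]][cand] - metadata[[distance_var]][t])
    best <- cand[order(d, metadata$sample_id[cand])][1]
    available[best] <- FALSE
    pairs[[length(pairs) + 1L]] <- data.frame(
      treated = metadata$sample_id[t], control = metadata$sample_id[best],
      stringsAsFactors = FALSE)
  }
  if (length(unmatched)) {
    warning(length(unmatched), " treated unit(s) unmatched and dropped")
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(treated = character(0), control = character(0))
  smd <- function(x_t, x_c) {
    s <- sqrt((stats::var(x_t) + stats::var(x_c)) / 2)
    if (is.na(s) || s == 0) return(0)
    (mean(x_t) - mean(x_c)) / s
  }
  bal <- vapply(c(distance_var, exact_vars), function(v) {
    x <- metadata[[v]]
    if (!is.numeric(x)) x <- as.numeric(factor(x))
    ti <- match(out$treated, metadata$sample_id)
    ci <- match(out$control, metadata$sample_id)
    c(unmatched = smd(x[metadata[[treat_col]] == treat_level],
                      x[metadata[[treat_col]] != treat_level]),
      matched = if (nrow(out)) smd(x[ti], x[ci]) else NA_real_)
  }, numeric(2))
  attr(out, "balance") <- bal
  out
}

#' Quasi-Bayesian causal mediation analysis
#'
#' Fits the linear mediator model M ~ T + C and outcome model Y ~ T + M + C;
#' the average causal mediation effect (ACME) point estimate is the product
#' of the T->M and M->Y coefficients. Uncertainty comes from `nsim` draws of
#' the coefficients from their asymptotic sampling distributions, giving a
#' 95% percentile interval and a two-sided simulation p-value
#' (2 min(frac <= 0, frac >= 0), floored at 1/nsim).
#'
#' @param T_var,M_var,Y_var numeric vectors (treatment, mediator, outcome).
#' @param covariates optional data.frame of adjustment covariates.
#' @param nsim coefficient draws (default 1000).
#' @param seed integer seed.
#' @return list of class `mediation_result`: `acme`, `acme_ci`, `p`, `ade`,
#'   `total`, `prop_mediated`, `nsim`.
#' @export
run_mediation <- function(T_var, M_var, Y_var, covariates = NULL,
                          nsim = 1000, seed = 1) {
  cc <- stats::complete.cases(T_var, M_var, Y_var,
                              covariates %||% rep(TRUE, length(T_var)))
  if (sum(cc) < 30) stop("need at least 30 complete cases")
  if (abs(stats::cor(T_var[cc], M_var[cc])) > 0.99) {
    stop("treatment and mediator are collinear")
  }
  C <- if (is.null(covariates)) NULL else covariates[cc, , drop = FALSE]
  dat_m <- data.frame(M = M_var[cc], T = T_var[cc])
  dat_y <- data.frame(Y = Y_var[cc], T = T_var[cc], M = M_var[cc])
  if (!is.null(C)) { dat_m <- cbind(dat_m, C); dat_y <- cbind(dat_y, C) }
  fit_m <- stats::lm(M ~ ., data = dat_m)
  fit_y <- stats::lm(Y ~ ., data = dat_y)
  a_hat <- stats::coef(fit_m)["T"]
  b_hat <- stats::coef(fit_y)["M"]
  c_hat <- stats::coef(fit_y)["T"]
  set.seed(seed)
  draw_coef <- function(fit) {
    mu <- stats::coef(fit)
    d <- matrix(stats::rnorm(nsim * length(mu)), nsim) %*% chol(stats::vcov(fit))
    d <- sweep(d, 2, mu, "+")
    colnames(d) <- names(mu)
    t(d)                                 # coefficients x draws
  }
  cm <- draw_coef(fit_m)
  cy <- draw_coef(fit_y)
  acme_draws <- cm["T", ] * cy["M", ]
  ade_draws <- cy["T", ]
  acme <- unname(a_hat * b_hat)
  p <- max(2 * min(mean(acme_draws <= 0), mean(acme_draws >= 0)), 1 / nsim)
  structure(
    list(acme = acme,
         acme_ci = unname(c(lerp_quantile(acme_draws, 0.025),
                            lerp_quantile(acme_draws, 0.975))),
         p = min(p, 1),
         ade = unname(c_hat),
         total = unname(acme + c_hat),
         prop_mediated = if (sign(acme) == sign(acme + c_hat) && acme + c_hat != 0)
           acme / (acme + unname(c_hat)) else NA_real_,
         nsim = nsim,
         draws = list(acme = acme_draws, ade = ade_draws)),
    class = "mediation_result"
  )
}

#' Microbiome-based diet predictability
#'
#' Random-forest regression (scored by per-fold Spearman correlation between
#' out-of-fold predictions and truth) or classification on the median-split
#' binary target (scored by per-fold AUC), with repeated cross-validation.
#'
#' @param features samples-x-features matrix with sample IDs as rownames.
#' @param target numeric vector aligned to the rows.
#' @param mode `"regression"` or `"classification"`.
#' @param folds,repeats cross-validation layout (defaults 10 x 5).
#' @param trees random-forest trees (default 1000, default mtry).
#' @param seed integer seed.
#' @return list of class `prediction_result`: `per_fold`, `median_score`,
#'   `mode`.
#' @export
predict_diet <- function(features, target, mode = c("regression", "classification"),
                         folds = 10, repeats = 5, trees = 1000, seed = 1) {
  mode <- match.arg(mode)
  n <- nrow(features)
  if (n < 5 * folds) stop("need at least 5 samples per fold")
  if (length(unique(target)) < 2) stop("constant target")
  if (mode == "classification") {
    y <- factor(as.integer(target > stats::median(target)), levels = c(0, 1))
    if (min(table(y)) < folds) stop("a class has fewer members than folds")
  } else {
    y <- target
  }
  set.seed(seed)
  scores <- numeric(0)
  for (r in seq_len(repeats)) {
    fold_id <- sample(rep(seq_len(folds), length.out = n))
    for (k in seq_len(folds)) {
      test <- fold_id == k
      rf <- randomForest::randomForest(
        x = features[!test, , drop = FALSE], y = y[!test], ntree = trees)
      if (mode == "regression") {
        pred <- stats::predict(rf, features[test, , drop = FALSE])
        scores <- c(scores, suppressWarnings(
          stats::cor(pred, y[test], method = "spearman")))
      } else {
        if (nlevels(droplevels(y[test])) < 2) next
        pred <- stats::predict(rf, features[test, , drop = FALSE], type = "prob")[, "1"]
        roc <- pROC::roc(response = y[test], predictor = pred,
                         levels = c("0", "1"), direction = "<", quiet = TRUE)
        scores <- c(scores, as.numeric(pROC::auc(roc)))
      }
    }
  }
  structure(list(per_fold = scores, median_score = stats::median(scores),
                 mode = mode, folds = folds, repeats = repeats),
            class = "prediction_result")
}
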