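test_that("CLR rows sum to zero, symmetric input maps to zero, scale invariant", {
  x <- matrix(1 / 3, 2, 3, dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  expect_equal(unname(clr_transform(x)), matrix(0, 2, 3))
  set.seed(51)
  m <- matrix(runif(10 * 6) + 0.01, 10, 6,
              dimnames = list(paste0("s", 1:10), paste0("t", 1:6)))
  y <- clr_transform(m / rowSums(m))
  expect_lt(max(abs(rowSums(y))), 1e-10)
  # scaling a zero-free sample before closure leaves CLR unchanged
  m2 <- m; m2[1, ] <- m2[1, ] * 2
  expect_equal(clr_transform(m2 / rowSums(m2), pseudocount = 0),
               clr_transform(m / rowSums(m), pseudocount = 0))
  expect_error(clr_transform(rbind(m, 0)), "all-zero")
})

test_that("covariate preparation: binary, quartile, and PCA reduction", {
  md <- data.frame(sample_id = paste0("s", 1:8),
                   gi = c("yes", "no", "yes", "no", "no", "yes", "no", "no"),
                   age = 1:8,
                   const = 1)
  suppressWarnings(cov <- prepare_covariates(md, c("sample_id", "gi", "age", "const"),
                                             binary_vars = "gi",
                                             quartile_vars = "age"))
  expect_equal(cov$gi, c(1, 0, 1, 0, 0, 1, 0, 0))
  expect_equal(cov$age, c(1, 1, 2, 2, 3, 3, 4, 4))
  expect_false("const" %in% names(cov))
  set.seed(52)
  sub <- as.data.frame(matrix(rnorm(40 * 8), 40, 8))
  names(sub) <- paste0("cebq", 1:8)
  sub$sample_id <- paste0("s", 1:40)
  cov2 <- prepare_covariates(sub, "sample_id", pc_vars = paste0("cebq", 1:8))
  expect_true(all(c("behavior_pc1", "behavior_pc2") %in% names(cov2)))
  expect_lt(abs(cor(cov2$behavior_pc1, cov2$behavior_pc2)), 1e-10)
  share <- attr(cov2, "pc_variance")
  expect_lt(sum(share), 1)
  expect_gt(share[1], share[2])
})

test_that("association OLS matches the lm oracle and BH is per panel", {
  set.seed(53)
  n <- 60
  ids <- paste0("s", 1:n)
  feat <- matrix(rnorm(n * 4), n, 4, dimnames = list(ids, paste0("f", 1:4)))
  diet <- data.frame(sample_id = ids, d1 = rnorm(n), d2 = rnorm(n))
  cov <- data.frame(sample_id = ids, age = runif(n, 3, 12),
                    sex = rbinom(n, 1, 0.3))
  res <- fit_feature_associations(feat, diet, cov,
                                  panels = list(p1 = "d1", p2 = "d2"))
  for (k in seq_len(nrow(res))) {
    row <- res[k, ]
    fit <- lm(feat[, row$feature] ~ scale(diet[[row$variable]]) + cov$age + cov$sex)
    sm <- summary(fit)$coefficients[2, ]
    expect_equal(row$coef, unname(sm[1]), tolerance = 1e-8)
    expect_equal(row$se, unname(sm[2]), tolerance = 1e-8)
    expect_equal(row$p, unname(sm[4]), tolerance = 1e-8)
  }
  for (panel in c("p1", "p2")) {
    idx <- res$panel == panel
    expect_equal(res$q[idx], bh_oracle(res$p[idx]))
  }
  expect_true(all(res$q >= res$p - 1e-12))
})

test_that("top-feature ranking orders by hit count with the stated tie-breaks", {
  res <- data.frame(
    feature = c(rep("fA", 5), rep("fB", 3), rep("fC", 3), "fD"),
    variable = paste0("v", 1:12), panel = "p",
    coef = 1, se = 1, p = 0.001, n = 100,
    q = c(rep(0.01, 5), rep(0.05, 3), rep(0.02, 3), 0.5),
    stringsAsFactors = FALSE)
  res$sig_q10 <- res$q < 0.1
  class(res) <- c("association_result", "data.frame")
  top <- select_top_features(res, k = 2)
  expect_equal(top$feature, c("fA", "fC"))  # 5 hits, then tie fC beats fB on min q
  expect_equal(top$rank, 1:2)
  # k caps the list; disjoint sets overlap 0
  top_all <- select_top_features(res, k = 50)
  expect_equal(nrow(top_all), 3)            # fD not significant
  other <- transform(res, feature = paste0("x", feature))
  class(other) <- c("association_result", "data.frame")
  withA <- select_top_features(res, k = 50, other = other)
  expect_equal(unname(attr(withA, "overlap")), 0)
})

test_that("interaction models isolate stratum-specific effects", {
  set.seed(54)
  n <- 300
  ids <- paste0("s", 1:n)
  grp <- data.frame(sample_id = ids, group = rep(c("ASD", "nonASD"), n / 2))
  d <- rnorm(n)
  asd <- grp$group == "ASD"
  f_int <- 0.6 * d * asd + rnorm(n)        # ASD-only effect
  f_same <- 0.6 * d + rnorm(n)             # identical effect in both groups
  feat <- cbind(f_int = f_int, f_same = f_same)
  rownames(feat) <- ids
  diet <- data.frame(sample_id = ids, d = d)
  cov <- data.frame(sample_id = ids, age = runif(n, 3, 12))
  res <- fit_interaction_models(feat, diet, grp, cov)
  expect_lt(res$p[res$feature == "f_int"], 0.01)
  expect_lt(abs(res$coef[res$feature == "f_same"]),
            abs(res$coef[res$feature == "f_int"]))
  expect_gt(res$p[res$feature == "f_same"], 0.01)
  grp1 <- transform(grp, group = "ASD")
  expect_error(fit_interaction_models(feat, diet, grp1, cov), "both groups")
})

test_that("matching is 1:1 without replacement, exact on categories, deterministic", {
  set.seed(55)
  md <- data.frame(sample_id = paste0("s", 1:30),
                   group = rep(c("ASD", "nonASD"), c(20, 10)),
                   sex = rep(c("M", "F"), 15),
                   gi_symptoms = rbinom(30, 1, 0.3),
                   age = runif(30, 3, 12))
  m1 <- suppressWarnings(nearest_neighbor_match(md, seed = 3))
  expect_lte(nrow(m1), 10)                       # pigeonhole: at most 10 pairs
  expect_false(anyDuplicated(m1$control) > 0)    # no control reused
  expect_identical(m1, suppressWarnings(nearest_neighbor_match(md, seed = 3)))
  ti <- match(m1$treated, md$sample_id); ci <- match(m1$control, md$sample_id)
  expect_equal(md$sex[ti], md$sex[ci])           # exact on categorical
  expect_equal(md$gi_symptoms[ti], md$gi_symptoms[ci])
  bal <- attr(m1, "balance")
  expect_lte(abs(bal["matched", "age"]), abs(bal["unmatched", "age"]) + 0.25)
  # exact duplicates available -> perfect balance
  md2 <- data.frame(sample_id = paste0("t", 1:10),
                    group = rep(c("ASD", "nonASD"), each = 5),
                    sex = rep("M", 10), gi_symptoms = 0,
                    age = rep(c(4, 5, 6, 7, 8), 2))
  m2 <- nearest_neighbor_match(md2, seed = 1)
  expect_equal(nrow(m2), 5)
  expect_equal(attr(m2, "balance")["matched", "age"], 0)
})

test_that("mediation recovers the planted ACME and behaves under the null", {
  tri <- simulate_mediation_triple(0.5, 0.4, 0.2, 2000,
                                   noise_sds = c(0.2, 0.2), seed = 7)
  med <- run_mediation(tri$T, tri$M, tri$Y, nsim = 1000, seed = 1)
  expect_equal(med$acme, 0.2, tolerance = 0.03)
  expect_true(med$acme_ci[1] <= med$acme && med$acme <= med$acme_ci[2])
  expect_lt(med$p, 0.01)
  expect_gt(med$prop_mediated, 0.4)
  # oracle: product of separately fitted coefficients
  a_hat <- coef(lm(tri$M ~ tri$T))[2]
  b_hat <- coef(lm(tri$Y ~ tri$T + tri$M))[3]
  expect_equal(med$acme, unname(a_hat * b_hat), tolerance = 1e-10)
  # null: b = 0
  tri0 <- simulate_mediation_triple(0.5, 0, 0.2, 500, seed = 8)
  med0 <- run_mediation(tri0$T, tri0$M, tri0$Y, nsim = 500, seed = 2)
  expect_lt(abs(med0$acme), 0.05)
  expect_gt(med0$p, 0.05)
  expect_error(run_mediation(tri$T, tri$T + 1e-9 * rnorm(2000), tri$Y),
               "collinear")
  expect_error(run_mediation(tri$T[1:10], tri$M[1:10], tri$Y[1:10]),
               "complete cases")
})

test_that("random-forest prediction nails a self-predicting fixture and is deterministic", {
  set.seed(56)
  n <- 100
  feat <- matrix(rnorm(n * 5), n, 5, dimnames = list(paste0("s", 1:n), paste0("f", 1:5)))
  target <- feat[, 3]
  pr <- predict_diet(feat, target, "regression", folds = 5, repeats = 1,
                     trees = 300, seed = 1)
  expect_gt(pr$median_score, 0.8)
  pc <- predict_diet(feat, target, "classification", folds = 5, repeats = 1,
                     trees = 300, seed = 1)
  expect_gt(pc$median_score, 0.85)
  # permuted labels: chance-level AUC
  null_auc <- predict_diet(feat, sample(target), "classification", folds = 5,
                           repeats = 1, trees = 100, seed = 2)$median_score
  expect_lt(abs(null_auc - 0.5), 0.25)
  rerun <- predict_diet(feat, target, "regression", folds = 5, repeats = 1,
                        trees = 300, seed = 1)
  expect_identical(pr$per_fold, rerun$per_fold)
  expect_error(predict_diet(feat, rep(1, n), "regression", folds = 5), "constant")
  expect_error(predict_diet(feat[1:10, ], target[1:10], "regression"), "per fold")
})
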