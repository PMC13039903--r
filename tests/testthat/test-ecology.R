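make_table <- function(m) {
  dimnames(m) <- list(sprintf("S%02d", seq_len(nrow(m))),
                      sprintf("T%02d", seq_len(ncol(m))))
  abundance_table(m)
}

test_that("alpha diversity closed forms", {
  tab <- make_table(rbind(rep(0.25, 4), c(1, 0, 0, 0), c(0.5, 0.5, 0, 0)))
  a <- alpha_diversity(tab)
  expect_equal(a$observed_richness, c(4, 1, 2))
  expect_equal(a$shannon, c(log(4), 0, log(2)), tolerance = 1e-12)
})

test_that("bray_curtis matches a brute-force double-loop oracle", {
  set.seed(11)
  m <- matrix(runif(20 * 8), 20, 8)
  tab <- make_table(m)
  d <- bray_curtis(tab)
  x <- tab$rel_abundance
  for (i in 1:20) for (j in 1:20) {
    expect_equal(d[i, j], sum(abs(x[i, ] - x[j, ])) / sum(x[i, ] + x[j, ]),
                 tolerance = 1e-12)
  }
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 20))
  # closed forms: identical -> 0, disjoint -> 1, half-overlap -> 0.5
  tab2 <- make_table(rbind(c(0.5, 0.5, 0), c(0.5, 0.5, 0),
                           c(0, 0.5, 0.5), c(0, 0, 1)))
  d2 <- bray_curtis(tab2)
  expect_equal(d2[1, 2], 0)
  expect_equal(d2[1, 4], 1)
  expect_equal(d2[1, 3], 0.5)
})

test_that("dysbiosis score uses leave-subject-out medians and the stated quantile", {
  set.seed(3)
  n_ref <- 10; n_case <- 4
  m <- matrix(runif((n_ref + n_case) * 12), n_ref + n_case, 12)
  tab <- make_table(m)
  md <- data.frame(sample_id = tab$sample_ids,
                   subject_id = paste0("P", seq_len(n_ref + n_case)),
                   group = c(rep("nonASD", n_ref), rep("ASD", n_case)))
  d <- bray_curtis(tab)
  res <- dysbiosis_score(d, md)
  # oracle: per-sample median over admissible reference set
  for (s in seq_len(n_ref + n_case)) {
    adm <- setdiff(seq_len(n_ref), s)
    expect_equal(res$score[s], median(d[s, adm]), tolerance = 1e-12)
  }
  # threshold oracle at the linear-interpolation quantile convention
  expect_equal(attr(res, "threshold"),
               unname(quantile(res$score[1:n_ref], 0.9, type = 7)))
  expect_true(all(res$dysbiotic == (res$score > attr(res, "threshold"))))
})

test_that("dysbiosis is invariant to taxon relabeling and zero-taxon padding", {
  set.seed(4)
  m <- matrix(runif(15 * 10), 15, 10)
  tab <- make_table(m)
  md <- data.frame(sample_id = tab$sample_ids, subject_id = tab$sample_ids,
                   group = rep(c("nonASD", "ASD"), c(9, 6)))
  base <- dysbiosis_score(bray_curtis(tab), md)
  perm <- sample(10)
  tab_p <- abundance_table(tab$rel_abundance[, perm],
                           sample_ids = tab$sample_ids,
                           taxon_ids = tab$taxon_ids[perm])
  expect_equal(dysbiosis_score(bray_curtis(tab_p), md)$score, base$score)
  tab_z <- abundance_table(cbind(tab$rel_abundance, ZZ = 0))
  expect_equal(dysbiosis_score(bray_curtis(tab_z), md)$score, base$score)
})

test_that("a sample identical to every reference has dysbiosis 0", {
  row <- runif(8); row <- row / sum(row)
  m <- rbind(row, row, row, row)
  tab <- make_table(m)
  md <- data.frame(sample_id = tab$sample_ids, subject_id = tab$sample_ids,
                   group = c("nonASD", "nonASD", "nonASD", "ASD"))
  res <- dysbiosis_score(bray_curtis(tab), md)
  expect_equal(res$score[4], 0)
})

test_that("reference scores 0.1..1.0 give threshold 0.91 under the quantile rule", {
  expect_equal(unname(quantile(seq(0.1, 1, by = 0.1), 0.9, type = 7)), 0.91)
})

test_that("PERMANOVA partitions variance and matches vegan on a shared fixture", {
  set.seed(7)
  n <- 40
  m <- matrix(runif(n * 12), n, 12)
  tab <- make_table(m)
  md <- data.frame(sample_id = tab$sample_ids,
                   group = rep(c("A", "B"), n / 2),
                   age = runif(n, 3, 12))
  d <- bray_curtis(tab)
  res <- permanova(d, md, c("group", "age"), n_perm = 99, seed = 1)
  expect_equal(sum(res$R2), 1, tolerance = 1e-9)
  ref <- vegan::adonis2(as.dist(d) ~ group + age, data = md,
                        permutations = 99, by = "terms")
  expect_equal(res$R2[1:2], ref$R2[1:2], tolerance = 1e-9)
  expect_equal(res$F[1:2], ref$F[1:2], tolerance = 1e-9)
  expect_error(permanova(d, md, "missing_col", n_perm = 99), "not in metadata")
  md$const <- 1
  expect_error(permanova(d, md, "const", n_perm = 99), "constant")
})

test_that("PERMANOVA reaches R2 = 1 and minimal p under perfect separation", {
  a <- c(0.7, 0.2, 0.1); b <- c(0.1, 0.2, 0.7)
  m <- rbind(a, a, a, a, a, a, a, a, b, b, b, b, b, b, b, b)
  tab <- make_table(m)
  md <- data.frame(sample_id = tab$sample_ids, group = rep(c("A", "B"), each = 8))
  res <- permanova(bray_curtis(tab), md, "group", n_perm = 99, seed = 2)
  expect_equal(res$R2[1], 1, tolerance = 1e-9)
  expect_equal(res$p[1], 1 / (1 + 99), tolerance = 0.05)
})

test_that("PERMANOVA p-values are near-uniform under the null", {
  set.seed(8)
  pvals <- replicate(60, {
    m <- matrix(runif(20 * 6), 20, 6)
    tab <- make_table(m)
    md <- data.frame(sample_id = tab$sample_ids, group = sample(rep(c("A", "B"), 10)))
    permanova(bray_curtis(tab), md, "group", n_perm = 99,
              seed = sample.int(1e6, 1))$p[1]
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})
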