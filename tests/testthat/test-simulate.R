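test_that("generator spec validates its inputs", {
  expect_error(generator_spec(n_nonasd = 1), "at least 2")
  expect_error(generator_spec(blocks = list(list(size = 200, rho = 0.5)),
                              n_taxa = 20), "exceed")
  expect_error(generator_spec(blocks = list(list(size = 4, rho = 1))), "\\(-1, 1\\)")
})

test_that("metadata marginals and determinism", {
  spec <- generator_spec(n_nonasd = 50, n_asd = 50, n_taxa = 10,
                         blocks = NULL, asd_fraction = 0.5)
  md <- simulate_metadata(spec, 5)
  expect_equal(nrow(md), 100)
  expect_gt(mean(md$group == "ASD"), 0.3)
  expect_lt(mean(md$group == "ASD"), 0.7)
  expect_identical(md, simulate_metadata(spec, 5))
  all_asd <- simulate_metadata(generator_spec(n_nonasd = 20, n_asd = 20,
                                              asd_fraction = 1), 1)
  expect_true(all(all_asd$group == "ASD"))
  expect_false(anyDuplicated(md$subject_id) > 0)
  expect_true(all(md$bristol_type %in% 1:7))
})

test_that("compositions close to 1, counts sum to depth, and the planted block is in the latent correlations", {
  spec <- generator_spec(n_nonasd = 250, n_asd = 250, n_taxa = 20, depth = 5000,
                         blocks = list(list(size = 8, rho = 0.75)),
                         shift_delta = 0)
  md <- simulate_metadata(spec, 2)
  comp <- simulate_composition(spec, md, 2)
  expect_equal(unname(rowSums(comp$table$rel_abundance)), rep(1, 500),
               tolerance = 1e-6)
  expect_true(all(rowSums(comp$table$counts) == 5000))
  # latent-correlation oracle: empirical block correlation about 0.75 at n=500
  y <- comp$truth$latent_y
  C <- cor(y)
  blk <- C[1:8, 1:8][upper.tri(diag(8))]
  expect_lt(max(abs(blk - 0.75)), 0.1)
  off <- C[9:20, 9:20][upper.tri(diag(12))]
  expect_lt(median(abs(off)), 0.1)   # no blocks planted there
})

test_that("latent correlations converge toward the planted value with n", {
  spec_small <- generator_spec(n_nonasd = 30, n_asd = 30, n_taxa = 12,
                               blocks = list(list(size = 6, rho = 0.6)),
                               shift_delta = 0, depth = 1000)
  spec_big <- generator_spec(n_nonasd = 400, n_asd = 400, n_taxa = 12,
                             blocks = list(list(size = 6, rho = 0.6)),
                             shift_delta = 0, depth = 1000)
  err <- function(spec, seed) {
    md <- simulate_metadata(spec, seed)
    y <- simulate_composition(spec, md, seed)$truth$latent_y
    C <- cor(y)[1:6, 1:6]
    mean(abs(C[upper.tri(C)] - 0.6))
  }
  e_small <- mean(vapply(1:4, function(s) err(spec_small, s), numeric(1)))
  e_big <- mean(vapply(1:4, function(s) err(spec_big, s), numeric(1)))
  expect_lt(e_big, e_small)
})

test_that("deep sequencing recovers the underlying composition", {
  mk <- function(depth, seed) {
    spec <- generator_spec(n_nonasd = 10, n_asd = 10, n_taxa = 15,
                           depth = depth, shift_delta = 0)
    md <- simulate_metadata(spec, seed)
    comp <- simulate_composition(spec, md, seed)
    abs(comp$table$rel_abundance - comp$truth$composition)
  }
  dev_deep <- mk(1e6, 3)
  expect_lt(mean(dev_deep), 1e-3)
  # per-entry multinomial bound: 5 sigma at the worst-case variance
  expect_lt(max(dev_deep), 5 * sqrt(0.25 / 1e6))
  expect_lt(mean(dev_deep), mean(mk(1e4, 3)))   # error shrinks with depth
})

test_that("planted diet effects appear only in their stratum", {
  eff <- data.frame(taxon = 5, diet = "protein_g", beta = 0.8, scope = "ASD")
  spec <- generator_spec(n_nonasd = 300, n_asd = 300, n_taxa = 12, blocks = NULL,
                         diet_effects = eff, shift_delta = 0, depth = 1000)
  md <- simulate_metadata(spec, 4)
  diet <- simulate_diet(spec, md, 4)
  comp <- simulate_composition(spec, md, 4, diet = diet)
  y5 <- comp$truth$latent_y[, 5]
  asd <- md$group == "ASD"
  cor_asd <- cor(y5[asd], diet$protein_g[asd])
  cor_non <- cor(y5[!asd], diet$protein_g[!asd])
  expect_gt(cor_asd, 0.3)
  expect_lt(abs(cor_non), 0.15)
  # beta = 0 everywhere: no coupling
  spec0 <- generator_spec(n_nonasd = 300, n_asd = 300, n_taxa = 12,
                          blocks = NULL, shift_delta = 0, depth = 1000)
  comp0 <- simulate_composition(spec0, md, 4, diet = diet)
  expect_lt(abs(cor(comp0$truth$latent_y[, 5], diet$protein_g)), 0.15)
})

test_that("diet table is positive where it must be and deterministic", {
  spec <- generator_spec(n_nonasd = 40, n_asd = 40, n_taxa = 10, blocks = NULL)
  md <- simulate_metadata(spec, 6)
  d1 <- simulate_diet(spec, md, 6)
  expect_identical(d1, simulate_diet(spec, md, 6))
  expect_true(all(d1$p80_g_yr > 0))
  expect_true(all(d1$energy_kcal > 0))
  expect_error(simulate_diet(generator_spec(emulsifier_sdlog = -1), md, 1),
               "positive")
})

test_that("mediation triples encode the product-of-paths ACME", {
  tri <- simulate_mediation_triple(0.5, 0.4, 0.2, 100, seed = 1)
  expect_equal(attr(tri, "acme"), 0.2)
  expect_equal(attr(simulate_mediation_triple(0.5, 0, 0.2, 50), "acme"), 0)
  # near-noiseless total effect oracle via regression
  tri2 <- simulate_mediation_triple(1, 1, 0, 5000, noise_sds = c(0.01, 0.01),
                                    seed = 2)
  total <- unname(coef(lm(Y ~ T, data = tri2))["T"])
  expect_equal(total, 1, tolerance = 0.05)
  expect_error(simulate_mediation_triple(1, 1, 0, 5), "at least 10")
  expect_error(simulate_mediation_triple(1, 1, 0, 50, noise_sds = c(0, 1)),
               "positive")
})

test_that("whole-cohort simulation is reproducible from the seed", {
  spec <- generator_spec(n_nonasd = 20, n_asd = 20, n_taxa = 12,
                         blocks = NULL, depth = 500)
  a <- simulate_cohort(spec, 9)
  b <- simulate_cohort(spec, 9)
  expect_identical(a$abundance$rel_abundance, b$abundance$rel_abundance)
  expect_identical(a$diet, b$diet)
})
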