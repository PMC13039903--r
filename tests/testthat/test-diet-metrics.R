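test_that("energy adjustment scales to 1000 kcal and %en", {
  adj <- energy_adjust(c(fiber_g = 30, protein_g = 50), 2000)
  expect_equal(unname(adj["fiber_g"]), 15)
  expect_equal(unname(adj["protein_g"]), 10)  # 50 g x 4 / 2000 x 100
  expect_error(energy_adjust(c(fiber_g = 30), 0), "positive")
})

test_that("DII closed forms and unit invariance", {
  ref <- data.frame(parameter = c("a", "b"), mean = c(10, 5), sd = c(2, 1),
                    effect = c(0.5, 0.5))
  # all at reference means -> 0
  expect_equal(compute_dii(c(a = 10, b = 5), ref), 0)
  # symmetric z of +1/-1 with equal effects cancel
  expect_equal(compute_dii(c(a = 12, b = 4), ref), 0)
  # single parameter in the z -> +inf limit contributes the full effect score
  ref1 <- data.frame(parameter = "a", mean = 10, sd = 2, effect = -0.663)
  expect_equal(compute_dii(c(a = 1e9), ref1), -0.663, tolerance = 1e-9)
  # translation/scale invariance when reference shares the units
  ref_scaled <- transform(ref, mean = mean * 1000, sd = sd * 1000)
  expect_equal(compute_dii(c(a = 12000, b = 4000), ref_scaled),
               compute_dii(c(a = 12, b = 4), ref))
  expect_error(compute_dii(c(a = 1), transform(ref1, sd = 0)), "positive")
})

test_that("HFD closed forms and bounds", {
  expect_equal(compute_hfd(5, 0.9), 0)                     # single food
  expect_equal(compute_hfd(rep(1, 4), rep(0.5, 4)), 0.375) # 0.5 x (1 - 1/4)
  for (k in c(2, 5, 10)) {
    expect_equal(compute_hfd(rep(1, k), rep(1, k)), 1 - 1 / k)
  }
  set.seed(2)
  for (i in 1:20) {
    k <- sample(2:8, 1)
    q <- runif(k); hv <- runif(k)
    val <- compute_hfd(q, hv)
    expect_lte(val, max(hv) * (1 - 1 / k) + 1e-12)
  }
  expect_error(compute_hfd(c(0, 0), c(1, 1)), "zero")
})

test_that("component index hits 0, the theoretical max, and interpolates", {
  cfg <- example_ccdi_config()
  healthy <- ifelse(cfg$direction == "higher_better", cfg$cutoff_high, cfg$cutoff_low)
  unhealthy <- ifelse(cfg$direction == "higher_better", cfg$cutoff_low, cfg$cutoff_high)
  expect_equal(compute_component_index(setNames(healthy, cfg$variable), cfg), 140)
  expect_equal(compute_component_index(setNames(unhealthy, cfg$variable), cfg), 0)
  one <- data.frame(variable = "x", direction = "higher_better",
                    cutoff_low = 0, cutoff_high = 10, max_points = 10)
  expect_equal(compute_component_index(c(x = 5), one), 5)
  expect_error(compute_component_index(c(y = 1), one), "missing component")
  # monotone non-decreasing in a higher_better variable
  vals <- vapply(seq(-5, 20, by = 1), function(v)
    compute_component_index(c(x = v), one), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("insufficiency counts use strict inequality on absolute intakes", {
  dri <- example_dri_table()
  above <- setNames(dri$dri + 1, dri$nutrient)
  expect_equal(count_insufficiencies(above, dri, "vitamin"), 0)
  below <- setNames(dri$dri - 0.1, dri$nutrient)
  expect_equal(count_insufficiencies(below, dri, "mineral"), 4)
  at <- setNames(dri$dri, dri$nutrient)
  expect_equal(count_insufficiencies(at, dri, "vitamin"), 0)  # exactly at DRI
  expect_error(count_insufficiencies(c(x = 1), dri, "vitamin"), "missing")
})

test_that("additive exposure normalizes per body weight and sums", {
  e <- compute_additive_exposure(c(p80 = 2, cmc = 3, crn = 5), 20)
  expect_equal(unname(e), c(0.10, 0.15, 0.25, 0.50))
  expect_equal(unname(compute_additive_exposure(c(p80 = 0, cmc = 0, crn = 0), 30)["total"]), 0)
  expect_error(compute_additive_exposure(c(p80 = 1, cmc = 1, crn = 1), 0), "positive")
})

test_that("tertile assignment uses population cutpoints with ties to the lower group", {
  lab <- assign_tertiles(1:9)
  expect_equal(as.character(lab), rep(c("low", "moderate", "high"), each = 3))
  # value equal to the lower cutpoint goes low
  cuts <- attr(lab, "cutpoints")
  expect_equal(as.character(assign_tertiles(cuts[1], population = 1:9)), "low")
  # population-wide cutpoints reused in a subgroup give unequal sizes
  sub <- assign_tertiles(c(7, 8, 9, 9), population = 1:9)
  expect_equal(as.character(sub), rep("high", 4))
  expect_error(assign_tertiles(rep(5, 10)), "degenerate")
})

test_that("diet_profile assembles per-sample metrics with consistent totals", {
  spec <- generator_spec(n_nonasd = 10, n_asd = 10, n_taxa = 10, blocks = NULL)
  md <- simulate_metadata(spec, 1)
  diet <- simulate_diet(spec, md, 1)
  prof <- diet_profile(diet)
  expect_equal(nrow(prof), 20)
  expect_true(all(prof$ccdi >= 0 & prof$ccdi <= 140))
  expect_true(all(prof$hfd >= 0 & prof$hfd < 1))
  expect_equal(prof$total_emulsifier,
               prof$p80_exposure + prof$cmc_exposure + prof$crn_exposure)
  expect_true(all(prof$vitamin_insufficiency == round(prof$vitamin_insufficiency)))
})
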