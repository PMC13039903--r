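#' Energy-adjust nutrient intakes
#'
#' Non-macronutrients are scaled to amounts per 1000 kcal of daily energy;
#' macronutrients (protein, carbohydrate, fat) are expressed as percentage
#' of total energy using Atwater factors.
#'
#' @param intakes named numeric vector of daily intakes (grams unless noted).
#' @param energy_kcal total daily energy (> 0).
#' @param macronutrients names within `intakes` treated as macronutrients.
#' @param atwater named factors kcal/g for the macronutrients.
#' @return named numeric vector: macronutrients as %en, the rest per
#'   1000 kcal.
#' @export
energy_adjust <- function(intakes, energy_kcal,
                          macronutrients = c("protein_g", "carbohydrate_g", "fat_g"),
                          atwater = c(protein_g = 4, carbohydrate_g = 4, fat_g = 9)) {
  if (energy_kcal <= 0) stop("energy must be positive")
  out <- intakes * 1000 / energy_kcal
  mm <- intersect(names(intakes), macronutrients)
  out[mm] <- intakes[mm] * atwater[mm] / energy_kcal * 100
  out
}

#' Dietary inflammatory index (DII)
#'
#' Each food parameter is standardized against a global reference mean and
#' SD, mapped to a centered percentile 2*pnorm(z) - 1, and the percentiles
#' are summed weighted by literature-derived inflammatory effect scores.
#' Positive totals indicate a pro-inflammatory diet.
#'
#' @param intakes named numeric vector of (energy-adjusted) parameter values.
#' @param ref data.frame with columns `parameter`, `mean`, `sd`, `effect`.
#' @return the DII value; parameters absent from `intakes` are skipped with
#'   a message.
#' @export
compute_dii <- function(intakes, ref) {
  stopifnot(all(c("parameter", "mean", "sd", "effect") %in% names(ref)))
  if (any(ref$sd <= 0)) stop("reference SDs must be positive")
  present <- ref$parameter %in% names(intakes)
  if (any(!present)) {
    message("DII: skipping parameters without intake values: ",
            paste(ref$parameter[!present], collapse = ", "))
  }
  r <- ref[present, , drop = FALSE]
  z <- (as.numeric(intakes[r$parameter]) - r$mean) / r$sd
  sum((2 * stats::pnorm(z) - 1) * r$effect)
}

#' Healthy food diversity (HFD) index
#'
#' Weighted mean health value of consumed foods times the Berry index
#' (1 - sum of squared consumption shares). Ranges over \[0, 1); equals 0
#' when a single food is consumed.
#'
#' @param quantities non-negative consumption quantities, at least one > 0.
#' @param health_values health values in \[0, 1\], same length.
#' @return HFD value.
#' @export
compute_hfd <- function(quantities, health_values) {
  stopifnot(length(quantities) == length(health_values))
  if (any(quantities < 0)) stop("quantities must be non-negative")
  if (all(quantities == 0)) stop("all food quantities are zero")
  if (any(health_values < 0 | health_values > 1)) stop("health values must be in [0, 1]")
  s <- quantities / sum(quantities)
  sum(s * health_values) * (1 - sum(s^2))
}

#' Component-based diet-quality index (CCDI / AHEI engine)
#'
#' Scores each component by linear interpolation between an unhealthy and a
#' healthy cutoff (0 points at or beyond the unhealthy cutoff, full points at
#' or beyond the healthy one); `range_optimal` components peak at the window
#' midpoint and fall linearly to 0 at either cutoff. The total is the sum of
#' component points.
#'
#' @param intakes named numeric vector covering every component variable.
#' @param cfg data.frame with columns `variable`,
#'   `direction` (one of `"higher_better"`, `"lower_better"`,
#'   `"range_optimal"`), `cutoff_low`, `cutoff_high`, `max_points`.
#' @return total index score.
#' @export
compute_component_index <- function(intakes, cfg) {
  need <- c("variable", "direction", "cutoff_low", "cutoff_high", "max_points")
  stopifnot(all(need %in% names(cfg)))
  if (any(cfg$cutoff_low >= cfg$cutoff_high)) stop("cutoff_low must be < cutoff_high")
  if (any(cfg$max_points <= 0)) stop("max_points must be positive")
  missing_vars <- setdiff(cfg$variable, names(intakes))
  if (length(missing_vars)) {
    stop("missing component variable(s): ", paste(missing_vars, collapse = ", "))
  }
  pts <- vapply(seq_len(nrow(cfg)), function(i) {
    x <- as.numeric(intakes[[cfg$variable[i]]])
    lo <- cfg$cutoff_low[i]; hi <- cfg$cutoff_high[i]; mp <- cfg$max_points[i]
    frac <- switch(cfg$direction[i],
      higher_better = (x - lo) / (hi - lo),
      lower_better = (hi - x) / (hi - lo),
      range_optimal = {
        mid <- (lo + hi) / 2
        1 - abs(x - mid) / (mid - lo)
      },
      stop("unknown direction: ", cfg$direction[i]))
    mp * min(max(frac, 0), 1)
  }, numeric(1))
  sum(pts)
}

#' Count micronutrient insufficiencies
#'
#' Number of nutrients in a class whose absolute intake falls strictly below
#' its dietary reference intake (DRI). Intakes exactly at the DRI are not
#' counted.
#'
#' @param absolute_intakes named numeric vector of absolute daily intakes.
#' @param dri_table data.frame with columns `nutrient`, `dri`, `class`.
#' @param nutrient_class class to count (e.g. `"vitamin"`, `"mineral"`).
#' @return integer count.
#' @export
count_insufficiencies <- function(absolute_intakes, dri_table, nutrient_class) {
  stopifnot(all(c("nutrient", "dri", "class") %in% names(dri_table)))
  tab <- dri_table[dri_table$class == nutrient_class, , drop = FALSE]
  missing <- setdiff(tab$nutrient, names(absolute_intakes))
  if (length(missing)) {
    stop("nutrient(s) missing from intakes: ", paste(missing, collapse = ", "))
  }
  sum(as.numeric(absolute_intakes[tab$nutrient]) < tab$dri)
}

#' Food-additive exposure per body weight
#'
#' Annual emulsifier intakes (polysorbate-80, carboxymethylcellulose,
#' carrageenan) normalized per kilogram body weight, with their sum as the
#' total exposure.
#'
#' @param annual_grams named numeric vector with elements `p80`, `cmc`, `crn`
#'   (grams/year).
#' @param bodyweight_kg body weight (> 0).
#' @return named vector `p80`, `cmc`, `crn`, `total` in g/kg bw/yr.
#' @export
compute_additive_exposure <- function(annual_grams, bodyweight_kg) {
  if (bodyweight_kg <= 0) stop("body weight must be positive")
  if (any(annual_grams < 0)) stop("intakes must be non-negative")
  e <- annual_grams[c("p80", "cmc", "crn")] / bodyweight_kg
  c(e, total = sum(e))
}

#' Assign exposure tertiles
#'
#' Cutpoints are the 1/3 and 2/3 linear-interpolation quantiles computed over
#' the whole population; labels can then be applied within subgroups, so
#' subgroup tertile sizes may be unequal. Values tied with a cutpoint go to
#' the lower tertile.
#'
#' @param values numeric vector to label.
#' @param population optional numeric vector over which cutpoints are
#'   computed (defaults to `values`).
#' @return factor with levels `low`, `moderate`, `high`; cutpoints in
#'   attribute `"cutpoints"`.
#' @export
assign_tertiles <- function(values, population = values) {
  pop <- population[is.finite(population)]
  if (length(pop) < 3) stop("need at least 3 finite values for tertiles")
  cuts <- c(lerp_quantile(pop, 1 / 3), lerp_quantile(pop, 2 / 3))
  if (cuts[1] == cuts[2] || length(unique(pop)) == 1) {
    stop("degenerate tertiles: cutpoints coincide")
  }
  lab <- cut(values, breaks = c(-Inf, cuts, Inf),
             labels = c("low", "moderate", "high"), right = TRUE)
  attr(lab, "cutpoints") <- cuts
  lab
}

#' Illustrative component-index configuration (CCDI-style, 0-140)
#'
#' The exact published component tables are supplementary data; this shipped
#' configuration is ILLUSTRATIVE: 14 components of 10 points each over the
#' diet variables the generator produces, preserving the 0-140 theoretical
#' range and the direction conventions of the published index.
#'
#' @return a component-config data.frame usable with
#'   [compute_component_index()].
#' @export
example_ccdi_config <- function() {
  data.frame(
    variable = c("vegetables_g", "fruits_g", "beans_g", "whole_grains_g",
                 "fiber_g", "protein_g", "magnesium_mg", "zinc_mg",
                 "vitamin_c_mg", "calcium_mg", "iron_mg",
                 "snacks_g", "sugary_drinks_ml", "starch_g"),
    direction = c(rep("higher_better", 11), rep("lower_better", 3)),
    cutoff_low = c(50, 50, 10, 20, 8, 40, 150, 5, 30, 400, 6, 30, 50, 80),
    cutoff_high = c(300, 250, 80, 120, 25, 75, 350, 12, 120, 1000, 16, 200, 400, 220),
    max_points = rep(10, 14),
    stringsAsFactors = FALSE
  )
}

#' Illustrative DII reference table
#'
#' Global means, SDs and inflammatory effect scores for a small parameter
#' set; ILLUSTRATIVE stand-in for the published reference database, keyed to
#' the generator's diet variables (effect signs follow the published
#' directions: fiber, magnesium, zinc and vitamins anti-inflammatory; total
#' fat and carbohydrate mildly pro-inflammatory).
#'
#' @return data.frame with columns `parameter`, `mean`, `sd`, `effect`.
#' @export
example_dii_reference <- function() {
  data.frame(
    parameter = c("fiber_g", "magnesium_mg", "zinc_mg", "vitamin_c_mg",
                  "vitamin_d_ug", "iron_mg", "protein_g", "carbohydrate_g",
                  "fat_g"),
    mean = c(18.8, 310, 9.8, 118, 6.26, 13.35, 79.4, 272, 71.4),
    sd = c(4.9, 139, 3.8, 43, 2.21, 3.71, 13.9, 40, 19.4),
    effect = c(-0.663, -0.484, -0.313, -0.424, -0.446, 0.032, 0.021, 0.097, 0.298),
    stringsAsFactors = FALSE
  )
}

#' Illustrative dietary-reference-intake table
#' @return data.frame with columns `nutrient`, `dri`, `class`.
#' @export
example_dri_table <- function() {
  data.frame(
    nutrient = c("vitamin_c_mg", "vitamin_d_ug", "calcium_mg", "iron_mg",
                 "magnesium_mg", "zinc_mg"),
    dri = c(65, 10, 800, 12, 250, 7),
    class = c("vitamin", "vitamin", "mineral", "mineral", "mineral", "mineral"),
    stringsAsFactors = FALSE
  )
}

#' Build the per-sample diet profile
#'
#' Computes, for every sample: energy-adjusted nutrients, component-index
#' score (CCDI-style), DII, HFD, vitamin and mineral insufficiency counts,
#' additive exposures per body weight, and population-wide exposure
#' tertiles.
#'
#' @param diet diet data.frame (one row per sample; see [simulate_diet()] for
#'   the expected columns).
#' @param ccdi_cfg,dii_ref,dri component config, DII reference and DRI table
#'   (defaults: the illustrative shipped versions).
#' @return data.frame, one row per sample, of class `diet_profile`.
#' @export
diet_profile <- function(diet, ccdi_cfg = example_ccdi_config(),
                         dii_ref = example_dii_reference(),
                         dri = example_dri_table()) {
  food_cols <- c("vegetables_g", "fruits_g", "beans_g", "whole_grains_g",
                 "snacks_g", "sugary_drinks_ml")
  hv <- c(vegetables_g = 0.9, fruits_g = 0.85, beans_g = 0.8,
          whole_grains_g = 0.8, snacks_g = 0.2, sugary_drinks_ml = 0.1)
  nut_cols <- setdiff(names(diet), c("sample_id", "energy_kcal", "bodyweight_kg",
                                     "p80_g_yr", "cmc_g_yr", "crn_g_yr"))
  rows <- lapply(seq_len(nrow(diet)), function(i) {
    raw <- unlist(diet[i, nut_cols])
    adj <- energy_adjust(raw, diet$energy_kcal[i])
    expo <- compute_additive_exposure(
      c(p80 = diet$p80_g_yr[i], cmc = diet$cmc_g_yr[i], crn = diet$crn_g_yr[i]),
      diet$bodyweight_kg[i])
    data.frame(
      sample_id = diet$sample_id[i],
      energy_kcal = diet$energy_kcal[i],
      ccdi = compute_component_index(raw, ccdi_cfg),
      dii = compute_dii(adj, dii_ref),
      hfd = compute_hfd(unlist(diet[i, food_cols]), hv[food_cols]),
      vitamin_insufficiency = count_insufficiencies(raw, dri, "vitamin"),
      mineral_insufficiency = count_insufficiencies(raw, dri, "mineral"),
      p80_exposure = unname(expo["p80"]),
      cmc_exposure = unname(expo["cmc"]),
      crn_exposure = unname(expo["crn"]),
      total_emulsifier = unname(expo["total"]),
      protein_pct_en = unname(adj["protein_g"]),
      carbohydrate_pct_en = unname(adj["carbohydrate_g"]),
      fat_pct_en = unname(adj["fat_g"]),
      stringsAsFactors = FALSE
    )
  })
  prof <- do.call(rbind, rows)
  for (v in c("p80_exposure", "crn_exposure", "total_emulsifier")) {
    prof[[paste0(v, "_tertile")]] <- as.character(assign_tertiles(prof[[v]]))
  }
  class(prof) <- c("diet_profile", "data.frame")
  prof
}
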