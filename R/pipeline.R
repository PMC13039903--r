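#' Analysis configuration
#'
#' Houses the pipeline's thresholds and iteration counts, with the study
#' conventions as defaults: 10% prevalence floor, dual edge criterion
#' q < 0.005 and |r| > 0.5, association significance q < 0.1, interaction
#' q < 0.2, dysbiosis flag at the 90th reference percentile, 9999 PERMANOVA
#' permutations, 1000-iteration bootstrap, and 5x10-fold random forests with
#' 1000 trees.
#'
#' @param seed root seed; all stage seeds derive from it.
#' @param prevalence_min,edge_q,edge_r,assoc_q,interaction_q thresholds.
#' @param dysbiosis_percentile reference percentile for the dysbiotic flag.
#' @param permanova_perms,bootstrap_B,sparcc_resamples,sparcc_perms
#'   iteration counts.
#' @param rf_folds,rf_repeats,rf_trees random-forest layout.
#' @param permanova_terms metadata terms, in model order.
#' @param prediction_vars diet-profile columns to predict from the
#'   microbiome.
#' @param network_stratum diet-profile tertile column defining network
#'   strata (default total emulsifier exposure).
#' @param stages stage subset to execute, in pipeline order.
#' @param renormalize_after_filter re-close compositions after the
#'   prevalence filter (default FALSE).
#' @return a validated list of class `analysis_config`.
#' @export
analysis_config <- function(seed = 1,
                            prevalence_min = 0.10, edge_q = 0.005, edge_r = 0.5,
                            assoc_q = 0.1, interaction_q = 0.2,
                            dysbiosis_percentile = 90,
                            permanova_perms = 9999, bootstrap_B = 1000,
                            sparcc_resamples = 20, sparcc_perms = 1000,
                            rf_folds = 10, rf_repeats = 5, rf_trees = 1000,
                            permanova_terms = c("group", "age", "sex", "gi_symptoms"),
                            prediction_vars = "ccdi",
                            network_stratum = "total_emulsifier_tertile",
                            stages = c("diet", "ecology", "associations",
                                       "networks", "robustness", "mediation",
                                       "prediction"),
                            renormalize_after_filter = FALSE) {
  cfg <- as.list(environment())
  chk01 <- function(x, nm, lo = 0, hi = 1) {
    if (!is.numeric(x) || x < lo || x > hi) stop("invalid ", nm, ": ", x)
  }
  chk01(prevalence_min, "prevalence_min", 0, 0.999)
  chk01(edge_q, "edge_q"); chk01(edge_r, "edge_r")
  chk01(assoc_q, "assoc_q"); chk01(interaction_q, "interaction_q")
  chk01(dysbiosis_percentile, "dysbiosis_percentile", 1, 100)
  for (nm in c("permanova_perms", "bootstrap_B", "sparcc_resamples",
               "sparcc_perms", "rf_folds", "rf_repeats", "rf_trees")) {
    if (cfg[[nm]] < 1) stop("iteration count ", nm, " must be >= 1")
  }
  bad <- setdiff(stages, c("diet", "ecology", "associations", "networks",
                           "robustness", "mediation", "prediction"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "analysis_config")
}

config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 251)) %% 4294967291)
}

#' Run the full diet-microbiome pipeline
#'
#' Executes the configured stages in order: diet metrics, community ecology
#' (alpha diversity, dysbiosis, PERMANOVA, rank correlations of
#' diversity/dysbiosis with diet metrics per group), per-feature association
#' and interaction models with matching, SparCC networks per exposure
#' stratum, robustness (bootstrap topology comparison and attack curves),
#' mediation and microbiome-based diet prediction. All randomness derives
#' from the root seed, so a rerun with the same inputs and seed is
#' bit-identical.
#'
#' @param config an [analysis_config()].
#' @param cohort a `synthetic_cohort` or the list returned by
#'   [read_cohort()]; when NULL, a packaged synthetic fixture is generated
#'   from the root seed.
#' @param out_dir when non-NULL, one TSV per result table plus a JSON run
#'   manifest are written there.
#' @param spec `generator_spec` used when `cohort` is NULL.
#' @return a list of class `result_bundle` with one element per executed
#'   stage.
#' @export
run_pipeline <- function(config = analysis_config(), cohort = NULL,
                         out_dir = NULL, spec = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(cohort)) {
    spec <- spec %||% generator_spec(
      n_nonasd = 90, n_asd = 110, n_taxa = 60, depth = 2e4,
      blocks = list(list(size = 8, rho = 0.75), list(size = 6, rho = 0.6)),
      diet_effects = data.frame(taxon = c(20, 21), diet = "fiber_g",
                                beta = c(0.5, 0.4), scope = c("all", "ASD")))
    cohort <- simulate_cohort(spec, seed = derive_seed(config$seed, "simulate"))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  res <- list(config = config)
  md <- cohort$metadata
  res$metadata <- md
  tab <- cohort$abundance
  filtered <- filter_prevalence(tab, config$prevalence_min,
                                renormalize = config$renormalize_after_filter)

  if ("diet" %in% config$stages) {
    res$diet <- run_stage("diet", diet_profile(cohort$diet))
  }
  prof <- res$diet

  if ("ecology" %in% config$stages) {
    res$ecology <- run_stage("ecology", {
      alpha <- alpha_diversity(tab)   # pre-filter so richness is untruncated
      bc <- bray_curtis(filtered)
      dys <- dysbiosis_score(bc, md, percentile = config$dysbiosis_percentile)
      perma <- permanova(bc, md, config$permanova_terms,
                         n_perm = config$permanova_perms,
                         seed = derive_seed(config$seed, "permanova"))
      rank_cor <- NULL
      if (!is.null(prof)) {
        eco <- merge(merge(alpha, dys[, c("sample_id", "score")], by = "sample_id"),
                     prof, by = "sample_id")
        eco$group <- md$group[match(eco$sample_id, md$sample_id)]
        diet_cols <- c("ccdi", "dii", "hfd", "total_emulsifier")
        eco_cols <- c("shannon", "observed_richness", "score")
        rows <- list()
        for (g in unique(eco$group)) for (ec in eco_cols) for (dc in diet_cols) {
          sub <- eco[eco$group == g, ]
          rows[[length(rows) + 1L]] <- data.frame(
            group = g, ecology_metric = ec, diet_metric = dc,
            spearman = suppressWarnings(stats::cor(sub[[ec]], sub[[dc]],
                                                   method = "spearman")),
            kendall = suppressWarnings(stats::cor(sub[[ec]], sub[[dc]],
                                                  method = "kendall")),
            stringsAsFactors = FALSE)
        }
        rank_cor <- do.call(rbind, rows)
      }
      list(alpha = alpha, dysbiosis = dys,
           dysbiosis_threshold = attr(dys, "threshold"),
           permanova = perma, rank_correlations = rank_cor)
    })
  }

  if ("associations" %in% config$stages && !is.null(prof)) {
    res$associations <- run_stage("associations", {
      clr <- clr_transform(filtered)
      cov <- prepare_covariates(md, c("sample_id", "age", "sex", "gi_symptoms"),
                                binary_vars = c("sex", "gi_symptoms"))
      panels <- list(
        indices = intersect(c("ccdi", "dii", "hfd"), names(prof)),
        nutrients = intersect(c("protein_pct_en", "carbohydrate_pct_en",
                                "fat_pct_en"), names(prof)),
        additives = intersect(c("p80_exposure", "cmc_exposure", "crn_exposure",
                                "total_emulsifier"), names(prof)))
      diet_vars <- prof[, c("sample_id", unique(unlist(panels))), drop = FALSE]
      per_group <- lapply(split(md$sample_id, md$group), function(ids) {
        fit_feature_associations(clr[intersect(rownames(clr), ids), , drop = FALSE],
                                 diet_vars, cov, panels = panels)
      })
      top <- lapply(per_group, select_top_features, k = 50)
      inter <- fit_interaction_models(clr, diet_vars,
                                      md[, c("sample_id", "group")], cov)
      matches <- nearest_neighbor_match(md, seed = derive_seed(config$seed, "match"))
      list(per_group = per_group, top_features = top, interactions = inter,
           matches = matches)
    })
  }

  strata_col <- NULL
  if (!is.null(prof) && config$network_stratum %in% names(prof)) {
    strata_col <- prof[[config$network_stratum]][match(filtered$sample_ids,
                                                       prof$sample_id)]
  }
  if ("networks" %in% config$stages) {
    res$networks <- run_stage("networks", {
      build_one <- function(rows, label) {
        sub <- filtered$rel_abundance[rows, , drop = FALSE]
        est <- sparcc_correlations(sub, resamples = 1,
                                   seed = derive_seed(config$seed, paste0("sparcc_", label)))
        pq <- sparcc_pvalues(est, sub, n_perm = config$sparcc_perms,
                             convention = "raw",
                             seed = derive_seed(config$seed, paste0("perm_", label)))
        net <- suppressWarnings(build_network(est, pq$q, config$edge_q, config$edge_r))
        list(network = net, topology = topology_summary(net))
      }
      nets <- if (is.null(strata_col)) {
        list(all = build_one(seq_along(filtered$sample_ids), "all"))
      } else {
        labs <- sort(unique(strata_col))
        stats::setNames(lapply(labs, function(l)
          build_one(which(strata_col == l), l)), labs)
      }
      topo <- do.call(rbind, lapply(names(nets), function(l) {
        cbind(stratum = l, nets[[l]]$topology)
      }))
      list(per_stratum = nets, topology = topo)
    })
  }

  if ("robustness" %in% config$stages) {
    res$robustness <- run_stage("robustness", {
      boot <- if (!is.null(strata_col) &&
                  all(table(strata_col) >= 20) && length(unique(strata_col)) > 1) {
        bootstrap_topology_compare(filtered$rel_abundance, strata_col,
                                   B = config$bootstrap_B,
                                   edge_r = config$edge_r,
                                   seed = derive_seed(config$seed, "bootstrap"))
      } else NULL
      curves <- NULL
      if (!is.null(res$networks)) {
        curves <- lapply(res$networks$per_stratum, function(ns) {
          if (nrow(ns$network$edges) == 0) return(NULL)
          list(random = attack_simulation(ns$network, "random", replicates = 100,
                                          seed = derive_seed(config$seed, "attack")),
               targeted = attack_simulation(ns$network, "targeted"))
        })
      }
      list(bootstrap = boot, attack_curves = curves)
    })
  }

  if ("mediation" %in% config$stages && !is.null(prof) &&
      !is.null(res$ecology)) {
    res$mediation <- run_stage("mediation", {
      clr <- clr_transform(filtered)
      # mediator: the taxon most correlated with the treatment variable
      tvar <- prof$ccdi[match(rownames(clr), prof$sample_id)]
      cors <- abs(apply(clr, 2, stats::cor, y = tvar))
      mediator <- names(which.max(cors))
      out <- res$ecology$dysbiosis$score[match(rownames(clr),
                                               res$ecology$dysbiosis$sample_id)]
      med <- run_mediation(tvar, clr[, mediator], out,
                           nsim = 1000, seed = derive_seed(config$seed, "mediation"))
      list(treatment = "ccdi", mediator = mediator, outcome = "dysbiosis",
           result = med)
    })
  }

  if ("prediction" %in% config$stages && !is.null(prof)) {
    res$prediction <- run_stage("prediction", {
      clr <- clr_transform(filtered)
      out <- list()
      for (v in config$prediction_vars) {
        y <- prof[[v]][match(rownames(clr), prof$sample_id)]
        out[[v]] <- list(
          regression = predict_diet(clr, y, "regression",
                                    folds = config$rf_folds,
                                    repeats = config$rf_repeats,
                                    trees = config$rf_trees,
                                    seed = derive_seed(config$seed, paste0("rf_", v))),
          classification = predict_diet(clr, y, "classification",
                                        folds = config$rf_folds,
                                        repeats = config$rf_repeats,
                                        trees = config$rf_trees,
                                        seed = derive_seed(config$seed, paste0("rfc_", v))))
      }
      out
    })
  }

  class(res) <- "result_bundle"
  if (!is.null(out_dir)) write_result_bundle(res, out_dir)
  res
}

#' Write a result bundle as TSV tables plus a JSON manifest
#'
#' @param res a `result_bundle`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_result_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) if (!is.null(x)) write_tsv_table(x, file.path(out_dir, name))
  w(res$diet, "diet_profile.tsv")
  if (!is.null(res$ecology)) {
    w(res$ecology$alpha, "alpha_diversity.tsv")
    w(res$ecology$dysbiosis, "dysbiosis.tsv")
    w(res$ecology$permanova, "permanova.tsv")
    w(res$ecology$rank_correlations, "rank_correlations.tsv")
  }
  if (!is.null(res$associations)) {
    bind_groups <- function(lst) {
      parts <- lapply(names(lst), function(g) {
        d <- lst[[g]]
        if (is.null(d) || nrow(d) == 0) NULL else cbind(group = g, d)
      })
      parts <- Filter(Negate(is.null), parts)
      if (length(parts)) do.call(rbind, parts) else NULL
    }
    w(bind_groups(res$associations$per_group), "associations.tsv")
    w(bind_groups(res$associations$top_features), "top_features.tsv")
    w(res$associations$interactions, "interactions.tsv")
    w(res$associations$matches, "matches.tsv")
  }
  if (!is.null(res$networks)) {
    edge_parts <- Filter(Negate(is.null), lapply(names(res$networks$per_stratum),
      function(l) {
        e <- res$networks$per_stratum[[l]]$network$edges
        if (nrow(e) == 0) NULL else cbind(stratum = l, e)
      }))
    if (length(edge_parts)) w(do.call(rbind, edge_parts), "network_edges.tsv")
    w(res$networks$topology, "topology.tsv")
  }
  if (!is.null(res$robustness)) {
    if (!is.null(res$robustness$bootstrap)) {
      bt <- do.call(rbind, lapply(names(res$robustness$bootstrap), function(m) {
        b <- res$robustness$bootstrap[[m]]
        data.frame(metric = m, stratum = names(b$observed),
                   observed = unname(b$observed),
                   letters = unname(b$letters), stringsAsFactors = FALSE)
      }))
      w(bt, "topology_bootstrap.tsv")
    }
    if (!is.null(res$robustness$attack_curves)) {
      ac <- do.call(rbind, lapply(names(res$robustness$attack_curves), function(l) {
        cv <- res$robustness$attack_curves[[l]]
        if (is.null(cv)) return(NULL)
        rbind(cbind(stratum = l, mode = "random",
                    cv$random[, c("fraction_removed", "nc")]),
              cbind(stratum = l, mode = "targeted",
                    cv$targeted[, c("fraction_removed", "nc")]))
      }))
      w(ac, "attack_curves.tsv")
    }
  }
  if (!is.null(res$mediation)) {
    m <- res$mediation
    w(data.frame(treatment = m$treatment, mediator = m$mediator,
                 outcome = m$outcome, acme = m$result$acme,
                 ci_lower = m$result$acme_ci[1], ci_upper = m$result$acme_ci[2],
                 p = m$result$p, ade = m$result$ade,
                 prop_mediated = m$result$prop_mediated),
      "mediation.tsv")
  }
  if (!is.null(res$prediction)) {
    pr <- do.call(rbind, lapply(names(res$prediction), function(v) {
      data.frame(variable = v,
                 median_rho = res$prediction[[v]]$regression$median_score,
                 median_auc = res$prediction[[v]]$classification$median_score)
    }))
    w(pr, "prediction.tsv")
  }
  manifest <- list(
    package = "dietnet",
    version = as.character(utils::packageVersion("dietnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = res$config$seed,
    config_hash = config_hash(unclass(res$config)),
    stages = res$config$stages
  )
  path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
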