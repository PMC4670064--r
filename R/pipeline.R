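#' Default pipeline configuration
#'
#' Desk-scale defaults for the end-to-end synthetic analysis: virtual
#' species study, occurrence preparation, candidate model grid, evaluation,
#' niche-overlap contrasts and stage classification. Every default is
#' recorded in the emitted report.
#'
#' @param seed master seed; every stage derives its own sub-seed from it.
#' @return Nested configuration list (also accepted as YAML by
#'   [run_pipeline()]).
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    study = list(delta_sd = 1, n_presences = 250, bias_strength = 1),
    prep = list(thin_km = 10, bias_bandwidth_km = 20, background_n = 10000,
                use_bias = TRUE),
    model = list(candidates = default_candidate_grid(), n_hinge_knots = 20,
                 predictors = NULL, max_modes = 2, collinearity = 0.80,
                 jackknife = FALSE),
    eval = list(k = 10, proc_reps = 1000, proc_E = 0),
    overlap = list(R = 100, reps = 100),
    stages = list(tau = 0.5),
    seed = as.integer(seed))
}

# priority order for collinearity pruning: the variables reported as
# model contributors, most important first, then the rest
default_prune_priority <- function() {
  c("degdays10", "bio17", "bio8", "bio4", "bio2", "bio15", "bio16", "bio3",
    paste0("bio", c(1, 5:7, 9:14, 18, 19)))
}

validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  need <- c("study", "prep", "model", "eval", "overlap", "stages", "seed")
  miss <- setdiff(need, names(config))
  if (length(miss)) {
    stop_named("pipeline config is missing required key(s): %s",
               paste(miss, collapse = ", "))
  }
  unknown <- setdiff(names(config), need)
  if (length(unknown)) {
    stop_named("unknown pipeline config key(s): %s",
               paste(unknown, collapse = ", "))
  }
  defaults <- default_pipeline_config(config$seed)
  for (blk in setdiff(need, "seed")) {
    config[[blk]] <- utils::modifyList(defaults[[blk]],
                                       as.list(config[[blk]]))
  }
  config$seed <- as.integer(config$seed)
  config
}

json_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = 12, null = "null")
  unname(tools::md5sum(tmp))
}

#' Run the full invasion-niche analysis pipeline
#'
#' Orchestrates the analysis end to end on a synthetic virtual-species
#' study: generate landscapes and occurrences; deduplicate, thin and
#' bias-correct the occurrences and draw background samples per range;
#' screen predictors for collinearity; fit and AICc-rank the candidate
#' maximum-entropy models for the regional (invaded-range-only) and global
#' (native plus invasive) calibrations; cross-validate and partial-ROC
#' evaluate the selected models; run the four niche-overlap contrasts
#' (native vs each invaded range, the two invaded ranges, native vs all
#' invasive); and classify invasion stages from the paired regional and
#' global predictions. All artifacts are deterministic given the
#' configuration seed.
#'
#' @param config nested configuration list (see
#'   [default_pipeline_config()]) or the path to a YAML file with the same
#'   structure.
#' @param out_dir optional directory; when given, [write_report()] is
#'   called on the result.
#' @return Object of class `invasion_pipeline`: the JSON-serializable
#'   `report` (with `report$hash`), plus in-memory `models`, `evals`,
#'   `overlaps`, `stages` and the `study`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL) {
  config <- validate_pipeline_config(config)
  seed <- config$seed
  step <- function(tag) derive_seed(seed, tag)

  study <- generate_invasion_study(
    do.call(virtual_species_config,
            c(config$study, list(seed = step("study")))))
  ranges <- names(study$ranges)

  # occurrence preparation + background per range
  prep <- lapply(stats::setNames(nm = ranges), function(r) {
    rg <- study$ranges[[r]]
    occ <- dedupe_to_grid(rg$occurrences, rg$predictors[[1L]])
    occ <- spatial_thin(occ, config$prep$thin_km,
                        seed = step(paste0("thin_", r)))
    bias <- NULL
    if (isTRUE(config$prep$use_bias)) {
      bias <- bias_surface(occ, rg$predictors[[1L]],
                           bandwidth_km = config$prep$bias_bandwidth_km)
    }
    bg <- sample_background(rg$mask, n = config$prep$background_n,
                            bias = bias, seed = step(paste0("bg_", r)))
    occ_env <- extract_env_values(occ$records, rg$predictors)
    land_tab <- stack_table(rg$predictors)
    bg_env <- as.data.frame(land_tab[bg$points$cell, , drop = FALSE])
    list(occ = occ, bias = bias, bg = bg, occ_env = occ_env, bg_env = bg_env,
         landscape = as.data.frame(land_tab[!stack_nodata(rg$predictors), ,
                                            drop = FALSE]))
  })

  # collinearity screen on the pooled backgrounds
  pooled_bg <- do.call(rbind, lapply(prep, `[[`, "bg_env"))
  corr <- env_correlation(pooled_bg)
  predictors <- config$model$predictors %||%
    prune_collinear(corr, default_prune_priority(),
                    threshold = config$model$collinearity)

  sel <- function(tab) as.matrix(tab[, predictors, drop = FALSE])
  model_sets <- list(
    regional = list(presence = sel(prep$invasive_conus$occ_env),
                    background = sel(prep$invasive_conus$bg_env),
                    landscape = sel(prep$invasive_conus$landscape)),
    global = list(presence = do.call(rbind, lapply(prep, function(p)
                    sel(p$occ_env))),
                  background = do.call(rbind, lapply(prep, function(p)
                    sel(p$bg_env))),
                  landscape = do.call(rbind, lapply(prep, function(p)
                    sel(p$landscape)))))

  fit_block <- function(ms, tag) {
    cands <- maxent_candidates(ms$presence, ms$background,
                               grid = config$model$candidates,
                               n_hinge_knots = config$model$n_hinge_knots)
    ranking <- rank_candidates(cands, ms$presence, ms$landscape,
                               max_modes = config$model$max_modes)
    best_name <- ranking$model[which(ranking$rank == 1L)]
    best_cfg <- config$model$candidates[[best_name]]
    ev <- evaluate_sdm(ms$presence, ms$background, landscape = ms$landscape,
                       classes = best_cfg$classes, beta = best_cfg$beta,
                       control = list(init = cands[[best_name]]$lambda),
                       k = config$eval$k,
                       n_hinge_knots = config$model$n_hinge_knots,
                       proc_reps = config$eval$proc_reps,
                       proc_E = config$eval$proc_E,
                       seed = step(paste0("eval_", tag)))
    imp <- variable_importance(ev$model, ms$presence, ms$background,
                               seed = step(paste0("imp_", tag)),
                               jackknife = isTRUE(config$model$jackknife))
    list(candidates = cands, ranking = ranking, best = best_name,
         eval = ev, importance = imp)
  }
  regional <- fit_block(model_sets$regional, "regional")
  global <- fit_block(model_sets$global, "global")

  # niche-overlap contrasts on the full 20-variable tables
  contrasts <- list(
    native_vs_conus = c("native", "invasive_conus"),
    native_vs_nonconus = c("native", "invasive_nonconus"),
    conus_vs_nonconus = c("invasive_conus", "invasive_nonconus"),
    native_vs_invasive = c("native", "invasive_all"))
  env_of <- function(r, what) {
    if (r == "invasive_all") {
      do.call(rbind, lapply(c("invasive_conus", "invasive_nonconus"),
                            function(rr) as.matrix(prep[[rr]][[what]])))
    } else as.matrix(prep[[r]][[what]])
  }
  overlaps <- lapply(stats::setNames(nm = names(contrasts)), function(cn) {
    pair <- contrasts[[cn]]
    niche_overlap(env_of(pair[1L], "occ_env"), env_of(pair[2L], "occ_env"),
                  env_of(pair[1L], "bg_env"), env_of(pair[2L], "bg_env"),
                  R = config$overlap$R, reps = config$overlap$reps,
                  seed = step(paste0("overlap_", cn)))
  })

  # invasion stages on the focal invaded landscape
  conus_stack <- study$ranges$invasive_conus$predictors
  reg_raster <- predict(regional$eval$model, conus_stack)
  glob_raster <- predict(global$eval$model, conus_stack)
  occ_env_conus <- sel(prep$invasive_conus$occ_env)
  p_reg <- predict(regional$eval$model, occ_env_conus)
  p_glob <- predict(global$eval$model, occ_env_conus)
  point_stages <- classify_stage(p_reg, p_glob, tau = config$stages$tau)
  stage_map <- classify_stage_raster(reg_raster, glob_raster,
                                     tau = config$stages$tau)

  perf_row <- function(blk) {
    ev <- blk$eval
    list(best_model = blk$best,
         k_nonzero = sum(ev$model$lambda != 0),
         auc_cv_mean = ev$auc_mean, auc_cv_sd = ev$auc_sd,
         pauc_ratio_mean = ev$pauc$ratio_mean,
         pauc_ratio_sd = ev$pauc$ratio_sd, pauc_p = ev$pauc$p,
         sensitivity_0pct = ev$sens0_mean,
         sensitivity_10pct = ev$sens10_mean,
         omission_0pct = ev$omission0_mean,
         omission_10pct = ev$omission10_mean)
  }
  contrib_block <- function(blk) {
    stats::setNames(as.list(round(blk$importance$contribution, 3)),
                    blk$importance$variable)
  }
  overlap_block <- function(ov) {
    list(schoeners_d = ov$d,
         p_equivalency_lower = ov$equivalency$p_lower,
         p_equivalency_upper = ov$equivalency$p_upper,
         p_similarity_lower = ov$similarity$p_lower,
         p_similarity_upper = ov$similarity$p_upper,
         expansion = ov$dynamics$expansion,
         stability = ov$dynamics$stability,
         unfilling = ov$dynamics$unfilling,
         centroid_shift = unname(ov$dynamics$centroid_shift))
  }
  provenance <- lapply(prep, function(p) {
    lapply(seq_len(nrow(p$occ$log)), function(i) as.list(p$occ$log[i, ]))
  })
  report <- list(
    package = "nicheshift",
    version = as.character(utils::packageVersion("nicheshift")),
    config = config,
    config_hash = json_hash(config),
    provenance = provenance,
    predictors = predictors,
    performance = list(regional = perf_row(regional),
                       global = perf_row(global)),
    contribution = list(regional = contrib_block(regional),
                        global = contrib_block(global)),
    overlap = lapply(overlaps, overlap_block),
    stages = list(tau = config$stages$tau,
                  point_counts = as.list(table(point_stages)),
                  cell_counts = as.list(unclass(stage_map$counts))))
  report$hash <- json_hash(report)

  out <- structure(list(report = report, study = study, prep = prep,
                        models = list(regional = regional, global = global),
                        overlaps = overlaps,
                        stages = list(points = point_stages,
                                      map = stage_map,
                                      regional_raster = reg_raster,
                                      global_raster = glob_raster)),
                   class = "invasion_pipeline")
  if (!is.null(out_dir)) write_report(out$report, out_dir)
  out
}

#' @export
print.invasion_pipeline <- function(x, ...) {
  r <- x$report
  cat(sprintf("Invasion-niche analysis (seed %d, report hash %s)\n",
              r$config$seed, r$hash))
  cat(sprintf("  predictors after collinearity screen: %s\n",
              paste(r$predictors, collapse = ", ")))
  for (m in names(r$performance)) {
    p <- r$performance[[m]]
    cat(sprintf("  %s model [%s]: AUC_cv %.3f +/- %.3f, pAUC %.2f, sens0 %.3f\n",
                m, p$best_model, p$auc_cv_mean, p$auc_cv_sd,
                p$pauc_ratio_mean, p$sensitivity_0pct))
  }
  for (cn in names(r$overlap)) {
    o <- r$overlap[[cn]]
    cat(sprintf("  %s: D = %.3f (eq p %.3f), expansion %.2f, unfilling %.2f\n",
                cn, o$schoeners_d, o$p_equivalency_lower, o$expansion,
                o$unfilling))
  }
  cat("  stages (points): ",
      paste(sprintf("%s %d", names(r$stages$point_counts),
                    unlist(r$stages$point_counts)), collapse = ", "), "\n")
  invisible(x)
}

#' Write the analysis report to disk
#'
#' Emits the machine-readable JSON report and a short human-readable
#' summary.
#'
#' @param report the `report` element of a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return Character vector of the written file paths, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop_named("cannot create directory %s", dir)
  }
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = 12,
                       null = "null", pretty = TRUE)
  txt_path <- file.path(dir, "summary.txt")
  con <- file(txt_path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("invasion-niche analysis report (nicheshift %s)", report$version)
  w("config hash: %s", report$config_hash)
  w("report hash: %s", report$hash)
  w("predictors: %s", paste(report$predictors, collapse = ", "))
  for (m in names(report$performance)) {
    p <- report$performance[[m]]
    cand <- report$config$model$candidates[[p$best_model]]
    w("%s model: %s (classes %s, beta %g), AUC_cv %.3f +/- %.3f, pAUC %.3f, sens 0%%/10%% = %.3f/%.3f",
      m, p$best_model, cand$classes, cand$beta, p$auc_cv_mean, p$auc_cv_sd,
      p$pauc_ratio_mean, p$sensitivity_0pct, p$sensitivity_10pct)
  }
  for (cn in names(report$overlap)) {
    o <- report$overlap[[cn]]
    w("%s: D = %.3f, p_eq = %.3f, expansion %.3f, stability %.3f, unfilling %.3f",
      cn, o$schoeners_d, o$p_equivalency_lower, o$expansion, o$stability,
      o$unfilling)
  }
  w("stages (tau = %g): %s", report$stages$tau,
    paste(sprintf("%s %d", names(report$stages$point_counts),
                  unlist(report$stages$point_counts)), collapse = ", "))
  invisible(c(json_path, txt_path))
}
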