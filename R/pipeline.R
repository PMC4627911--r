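#' Pipeline configuration
#'
#' All settings for the config-driven orchestration of the full analysis:
#' simulate terrain/meteorology/points, derive landform metrics and
#' topoclimatic indices, assemble the feature table, then run PCA, the
#' random forest and the conditional inference tree. A single global seed
#' is fanned out to per-stage seeds by stable hashing of the stage names,
#' so any stage re-runs reproducibly in isolation.
#'
#' @param out_dir output directory (created if absent).
#' @param n_sites number of synthetic study areas.
#' @param points_per_site treeline points per site.
#' @param terrain a [terrain_spec] template (per-site seeds derived).
#' @param met_jan,met_jul [met_spec]s for the two months (seeds derived).
#' @param effect an [effect_spec] for the deviation-generating process.
#' @param forest a [forest_config].
#' @param alpha,n_permutations,min_node conditional-inference-tree
#'   settings.
#' @param pd_top number of top-ranked variables given partial-dependence
#'   curves.
#' @param stages character vector of stages to run, in dependency order.
#' @param seed global integer seed.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, n_sites = 2, points_per_site = 25,
                            terrain = terrain_spec(),
                            met_jan = met_spec("Jan"),
                            met_jul = met_spec("Jul"),
                            effect = effect_spec(intercept = 180,
                                                 beta_curvature = -300,
                                                 beta_slope = -0.4,
                                                 noise_sd = 30),
                            forest = forest_config(n_trees = 500),
                            alpha = 0.05, n_permutations = 999,
                            min_node = 20, pd_top = 12,
                            stages = c("simulate", "landform", "indices",
                                       "features", "pca", "forest", "ctree"),
                            seed = 1) {
  known <- c("simulate", "landform", "indices", "features", "pca",
             "forest", "ctree")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(out_dir = out_dir, n_sites = as.integer(n_sites),
                 points_per_site = as.integer(points_per_site),
                 terrain = terrain, met_jan = met_jan, met_jul = met_jul,
                 effect = effect, forest = forest, alpha = alpha,
                 n_permutations = n_permutations, min_node = min_node,
                 pd_top = pd_top, stages = known[known %in% stages],
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Derive a stage seed from the global seed
#'
#' Stable (platform-independent) hash of the stage name combined with the
#' global seed; always a positive integer below 2^31.
#'
#' @param seed global integer seed.
#' @param stage stage name.
#' @return Integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147483647
  as.integer((h + as.numeric(seed) * 10007) %% 2147483647 + 1)
}

pipe_path <- function(config, ...) file.path(config$out_dir, ...)

require_stage_file <- function(config, file, producer) {
  p <- pipe_path(config, file)
  if (!file.exists(p))
    stop("dependency error: '", file, "' not found; run the '", producer,
         "' stage first")
  p
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing text outputs
#' (CSV / JSON / ESRI ASCII) under `config$out_dir`, and returns a run
#' manifest. Re-running with an identical config and seed reproduces
#' bit-identical output files.
#'
#' @param config a [pipeline_config].
#' @param quiet suppress stage log lines on stderr.
#' @return The run manifest (also written as `manifest.json`): config
#'   hash, per-stage outputs and timings, package version.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] ", stage), ...)
  }
  manifest <- list(config_hash = config_hash(config),
                   package_version = as.character(
                     utils::packageVersion("treelinetopo")),
                   seed = config$seed, stages = list())
  for (stage in config$stages) {
    t0 <- proc.time()[["elapsed"]]
    say(stage, "running")
    files <- switch(stage,
      simulate = stage_simulate(config),
      landform = stage_landform(config),
      indices = stage_indices(config),
      features = stage_features(config),
      pca = stage_pca(config),
      forest = stage_forest(config),
      ctree = stage_ctree(config))
    manifest$stages[[stage]] <- list(
      outputs = files, seconds = round(proc.time()[["elapsed"]] - t0, 3))
    say(stage, "wrote ", paste(files, collapse = ", "))
  }
  jsonlite::write_json(manifest, pipe_path(config, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Hash of the config with the output directory excluded, so the same
# analysis in two directories has the same identity.
config_hash <- function(config) {
  c2 <- unclass(config)
  c2$out_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(c2, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

stage_simulate <- function(config) {
  files <- character(0)
  covar <- generate_regional_covariates(
    config$n_sites, derive_seed(config$seed, "covariates"))
  cov_path <- pipe_path(config, "regional_covariates.csv")
  utils::write.csv(covar, cov_path, row.names = FALSE)
  files <- c(files, "regional_covariates.csv")

  all_points <- list(); all_series <- list()
  for (i in seq_len(config$n_sites)) {
    sid <- covar$site_id[i]
    tspec <- config$terrain
    tspec$seed <- derive_seed(config$seed, paste0("terrain_", sid))
    dem <- generate_dem(tspec)
    dem_file <- sprintf("dem_%s.asc", sid)
    write_ascii_grid(dem, pipe_path(config, dem_file))
    files <- c(files, dem_file)

    eff <- config$effect
    eff$seed <- derive_seed(config$seed, paste0("points_", sid))
    pts <- generate_treeline_points(dem, eff, config$points_per_site, sid)
    all_points[[i]] <- pts[, c("point_id", "site_id", "easting",
                               "northing", "elevation")]
    for (m in c("Jan", "Jul")) {
      mspec <- if (m == "Jan") config$met_jan else config$met_jul
      mspec$seed <- derive_seed(config$seed, paste0("met_", m, "_", sid))
      all_series <- c(all_series, generate_hourly_met(dem, mspec, pts))
    }
  }
  pts_path <- pipe_path(config, "treeline_points.csv")
  utils::write.csv(do.call(rbind, all_points), pts_path, row.names = FALSE)
  write_hourly_met_csv(all_series, pipe_path(config, "hourly_met.csv"))
  c(files, "treeline_points.csv", "hourly_met.csv")
}

stage_landform <- function(config) {
  pts_path <- require_stage_file(config, "treeline_points.csv", "simulate")
  points <- utils::read.csv(pts_path, stringsAsFactors = FALSE)
  out <- list(); mmi <- list()
  for (sid in unique(points$site_id)) {
    dem <- read_ascii_grid(
      require_stage_file(config, sprintf("dem_%s.asc", sid), "simulate"))
    sub <- points[points$site_id == sid, , drop = FALSE]
    slp <- extract_at_points(dem, sub, slope_percent(dem))$value
    crv <- extract_at_points(dem, sub, curvature(dem))$value
    sub$slope_percent <- slp
    sub$curvature <- crv
    out[[sid]] <- sub
    mmi[[sid]] <- data.frame(site_id = sid,
                             mountain_mass_index = mountain_mass_index(dem),
                             stringsAsFactors = FALSE)
  }
  feats <- elevation_deviation(do.call(rbind, out))
  rownames(feats) <- NULL
  utils::write.csv(feats, pipe_path(config, "landform_features.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, mmi),
                   pipe_path(config, "mountain_mass.csv"), row.names = FALSE)
  c("landform_features.csv", "mountain_mass.csv")
}

stage_indices <- function(config) {
  met_path <- require_stage_file(config, "hourly_met.csv", "simulate")
  series <- read_hourly_met_csv(met_path)
  tabs <- topoclimate_tables(series)
  utils::write.csv(tabs$indices, pipe_path(config, "topoclimate_indices.csv"),
                   row.names = FALSE)
  utils::write.csv(tabs$summaries, pipe_path(config, "monthly_summaries.csv"),
                   row.names = FALSE)
  c("topoclimate_indices.csv", "monthly_summaries.csv")
}

stage_features <- function(config) {
  landform <- utils::read.csv(
    require_stage_file(config, "landform_features.csv", "landform"),
    stringsAsFactors = FALSE)
  mmi <- utils::read.csv(
    require_stage_file(config, "mountain_mass.csv", "landform"),
    stringsAsFactors = FALSE)
  idx <- utils::read.csv(
    require_stage_file(config, "topoclimate_indices.csv", "indices"),
    stringsAsFactors = FALSE)
  summ <- utils::read.csv(
    require_stage_file(config, "monthly_summaries.csv", "indices"),
    stringsAsFactors = FALSE)
  covar <- utils::read.csv(
    require_stage_file(config, "regional_covariates.csv", "simulate"),
    stringsAsFactors = FALSE)

  wide <- function(df, cols, suffix_by = "month") {
    jan <- df[df[[suffix_by]] == "Jan", c("point_id", cols)]
    jul <- df[df[[suffix_by]] == "Jul", c("point_id", cols)]
    names(jan)[-1] <- paste0(tolower(cols), "_jan")
    names(jul)[-1] <- paste0(tolower(cols), "_jul")
    merge(jan, jul, by = "point_id")
  }
  idx_w <- wide(idx, c("photoinhibition", "desiccation", "frost",
                       "insolation"))
  wt <- summ[summ$month == "Jul", c("point_id", "temp_min", "temp_max")]
  names(wt) <- c("point_id", "winter_temp_min", "winter_temp_max")

  feats <- merge(landform, idx_w, by = "point_id")
  feats <- merge(feats, wt, by = "point_id")
  feats <- merge(feats, covar, by = "site_id")
  feats <- merge(feats, mmi, by = "site_id")
  feats <- feats[order(feats$point_id), , drop = FALSE]
  rownames(feats) <- NULL
  need <- c("elevation_deviation", treeline_explanatory_vars)
  miss <- setdiff(need, names(feats))
  if (length(miss))
    stop("feature assembly missing columns: ", paste(miss, collapse = ", "))
  utils::write.csv(feats, pipe_path(config, "features.csv"),
                   row.names = FALSE)
  "features.csv"
}

stage_pca <- function(config) {
  summ <- utils::read.csv(
    require_stage_file(config, "monthly_summaries.csv", "indices"),
    stringsAsFactors = FALSE)
  mat <- summary_feature_matrix(summ)
  # summaries that do not vary across points (e.g. no frost hours
  # anywhere in January) carry no ordination information
  keep <- apply(mat, 2, stats::sd) > 0
  if (!any(keep)) stop("all summary columns are constant")
  res <- pca_correlation(mat[, keep, drop = FALSE])
  write_pca_csv(res, pipe_path(config, "pca_loadings.csv"))
  "pca_loadings.csv"
}

stage_forest <- function(config) {
  feats <- utils::read.csv(require_stage_file(config, "features.csv",
                                              "features"),
                           stringsAsFactors = FALSE)
  cfg <- config$forest
  cfg$seed <- derive_seed(config$seed, "forest")
  forest <- fit_forest(feats, cfg)
  imp <- permutation_importance(forest)
  utils::write.csv(imp, pipe_path(config, "importance.csv"),
                   row.names = FALSE)
  top <- imp$variable[seq_len(min(config$pd_top, nrow(imp)))]
  pd <- do.call(rbind, lapply(top, function(v)
    partial_dependence(forest, feats, v)))
  utils::write.csv(pd, pipe_path(config, "partial_dependence.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(oob_r2 = forest$oob_r2,
                            oob_mse = forest$oob_mse,
                            n_trees = cfg$n_trees),
                       pipe_path(config, "forest_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  c("importance.csv", "partial_dependence.csv", "forest_summary.json")
}

stage_ctree <- function(config) {
  feats <- utils::read.csv(require_stage_file(config, "features.csv",
                                              "features"),
                           stringsAsFactors = FALSE)
  tree <- fit_ctree(feats, alpha = config$alpha,
                    n_permutations = config$n_permutations,
                    min_node = config$min_node,
                    seed = derive_seed(config$seed, "ctree"))
  ctree_to_json(tree, pipe_path(config, "ctree.json"))
  writeLines(format_ctree(tree), pipe_path(config, "ctree.txt"))
  utils::write.csv(summarize_terminal_nodes(tree, feats),
                   pipe_path(config, "ctree_nodes.csv"), row.names = FALSE)
  c("ctree.json", "ctree.txt", "ctree_nodes.csv")
}

#' Wide twenty-variable summary matrix from the monthly summary table
#'
#' Pivots the per-point January and July summary rows into the
#' twenty-column (ten summaries x two months) matrix used for ordination.
#'
#' @param summaries data.frame from [topoclimate_tables()] /
#'   `monthly_summaries.csv`.
#' @return Numeric matrix, rows labelled by point id.
#' @export
summary_feature_matrix <- function(summaries) {
  cols <- c("temp_min", "temp_max", "wind_min", "wind_max", "rh_min",
            "rh_max", "frost_hours", "rain_days", "total_solar",
            "net_longwave")
  jan <- summaries[summaries$month == "Jan", c("point_id", cols)]
  jul <- summaries[summaries$month == "Jul", c("point_id", cols)]
  names(jan)[-1] <- paste0("jan_", cols)
  names(jul)[-1] <- paste0("jul_", cols)
  wide <- merge(jan, jul, by = "point_id")
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$point_id
  m
}

#' Validate pipeline input files
#'
#' Schema and range checks on the text inputs of the analysis: the hourly
#' meteorology CSV (columns present; relative humidity within [0, 100];
#' non-negative solar radiation), the treeline point CSV, and the
#' assembled feature CSV (non-negative deviation, no missing values).
#' Reports the first offending row or column per file.
#'
#' @param paths named character vector or list; recognised names are
#'   `hourly_met`, `points`, `features`.
#' @return data.frame `file`, `pass`, `message`.
#' @export
validate_inputs <- function(paths) {
  check_one <- function(kind, path) {
    if (!file.exists(path)) return(sprintf("I/O error: missing file %s", path))
    df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                   error = function(e) e)
    if (inherits(df, "error"))
      return(sprintf("I/O error: %s", conditionMessage(df)))
    if (kind == "hourly_met") {
      need <- c("site_id", "point_id", "month", "timestamp_hour", "temp_c",
                "wind_ms", "rh_pct", "solar_wm2", "netrad_wm2", "rain_mm")
      miss <- setdiff(need, names(df))
      if (length(miss)) return(sprintf("missing column: %s", miss[1]))
      bad <- which(df$rh_pct < 0 | df$rh_pct > 100)
      if (length(bad))
        return(sprintf("rh_pct out of [0, 100] at row %d", bad[1]))
      bad <- which(df$solar_wm2 < 0)
      if (length(bad))
        return(sprintf("negative solar_wm2 at row %d", bad[1]))
    } else if (kind == "points") {
      need <- c("point_id", "site_id", "easting", "northing")
      miss <- setdiff(need, names(df))
      if (length(miss)) return(sprintf("missing column: %s", miss[1]))
      if (anyDuplicated(paste(df$site_id, df$point_id)))
        return("duplicate point_id within a site")
    } else if (kind == "features") {
      if (!"elevation_deviation" %in% names(df))
        return("missing column: elevation_deviation")
      bad <- which(df$elevation_deviation < 0)
      if (length(bad))
        return(sprintf("negative elevation_deviation at row %d", bad[1]))
      num <- vapply(df, is.numeric, TRUE)
      nas <- vapply(df[num], function(c) any(!is.finite(c)), TRUE)
      if (any(nas))
        return(sprintf("missing values in column %s", names(df[num])[nas][1]))
    }
    NA_character_
  }
  out <- lapply(names(paths), function(kind) {
    msg <- check_one(kind, paths[[kind]])
    data.frame(file = unname(unlist(paths[kind])), pass = is.na(msg),
               message = ifelse(is.na(msg), "ok", msg),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
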