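#' Random-forest configuration
#'
#' @param n_trees number of bootstrapped regression trees (default 2000).
#' @param candidate_vars_per_split variables tried at each split
#'   (default `ceiling(p/3)`, the regression default; resolved at fit
#'   time when `NULL`).
#' @param min_leaf minimum terminal node size (default 5).
#' @param seed integer seed; fits are deterministic given the seed.
#' @return A `forest_config`.
#' @export
forest_config <- function(n_trees = 2000, candidate_vars_per_split = NULL,
                          min_leaf = 5, seed = 1) {
  if (n_trees < 1) stop("n_trees must be >= 1")
  structure(list(n_trees = as.integer(n_trees),
                 candidate_vars_per_split = candidate_vars_per_split,
                 min_leaf = as.integer(min_leaf), seed = as.integer(seed)),
            class = "forest_config")
}

#' The seventeen explanatory variables of the treeline feature table
#' @export
treeline_explanatory_vars <- c(
  "curvature", "slope_percent",
  "photoinhibition_jan", "photoinhibition_jul",
  "desiccation_jan", "desiccation_jul",
  "frost_jan", "frost_jul",
  "insolation_jan", "insolation_jul",
  "growing_season_temp", "annual_precipitation", "mountain_mass_index",
  "earthquake_intensity", "erosion_index",
  "winter_temp_min", "winter_temp_max")

validate_feature_table <- function(table, response, predictors) {
  if (!response %in% names(table)) stop("missing response column: ", response)
  miss <- setdiff(predictors, names(table))
  if (length(miss))
    stop("missing explanatory columns: ", paste(miss, collapse = ", "))
  cols <- table[, c(response, predictors), drop = FALSE]
  if (any(!vapply(cols, is.numeric, TRUE))) stop("non-numeric feature column")
  bad <- vapply(cols, function(c) any(!is.finite(c)), TRUE)
  if (any(bad))
    stop("missing or non-finite values in: ",
         paste(names(cols)[bad], collapse = ", "))
  invisible(TRUE)
}

#' Fit a random forest to the treeline feature table
#'
#' Bootstrap-resampled regression trees with random candidate-variable
#' subsets per split (backed by the `randomForest` ensemble), reporting
#' out-of-bag predictions and out-of-bag R^2. Deterministic given the
#' config seed.
#'
#' @param table data.frame containing `response` and the predictor
#'   columns; no missing values.
#' @param config a [forest_config].
#' @param response response column name (default `"elevation_deviation"`).
#' @param predictors predictor column names (default the seventeen
#'   standard explanatory variables, intersected with `table`).
#' @return A `treeline_forest`: the fitted ensemble, `oob_predictions`,
#'   `oob_mse`, `oob_r2`, and the variable roster.
#' @export
fit_forest <- function(table, config = forest_config(),
                       response = "elevation_deviation",
                       predictors = NULL) {
  if (is.null(predictors))
    predictors <- intersect(treeline_explanatory_vars, names(table))
  validate_feature_table(table, response, predictors)
  x <- table[, predictors, drop = FALSE]
  y <- table[[response]]
  mtry <- config$candidate_vars_per_split
  if (is.null(mtry)) mtry <- max(1, ceiling(length(predictors) / 3))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  fit <- randomForest::randomForest(
    x = x, y = y, ntree = config$n_trees, mtry = mtry,
    nodesize = config$min_leaf, importance = TRUE, keep.forest = TRUE)
  oob <- fit$predicted
  oob_mse <- mean((y - oob)^2)
  structure(list(fit = fit, response = response, predictors = predictors,
                 oob_predictions = oob, oob_mse = oob_mse,
                 oob_r2 = 1 - oob_mse / mean((y - mean(y))^2),
                 config = config),
            class = "treeline_forest")
}

#' @export
print.treeline_forest <- function(x, ...) {
  cat(sprintf("treeline_forest: %d trees, %d predictors, OOB R^2 = %.3f\n",
              x$config$n_trees, length(x$predictors), x$oob_r2))
  invisible(x)
}

#' Permutation variable importance (%IncMSE)
#'
#' For each predictor, the mean over trees of the increase in out-of-bag
#' mean squared error when that predictor is permuted, expressed as a
#' percentage of the forest's out-of-bag MSE. Variables whose permutation
#' hurts prediction most rank first.
#'
#' @param forest a `treeline_forest` from [fit_forest()].
#' @return data.frame `variable`, `pct_inc_mse`, `rank` (descending
#'   importance; ranks are a permutation of `1..p`).
#' @export
permutation_importance <- function(forest) {
  stopifnot(inherits(forest, "treeline_forest"))
  raw <- randomForest::importance(forest$fit, type = 1, scale = FALSE)
  pct <- 100 * raw[, 1] / forest$oob_mse
  out <- data.frame(variable = rownames(raw), pct_inc_mse = unname(pct),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$pct_inc_mse), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Partial dependence of the response on one predictor
#'
#' Marginal effect curve: for each of `grid_size` quantile-spaced values
#' of the predictor, the mean prediction over all rows with that predictor
#' set to the grid value and every other predictor left at its observed
#' values. Quantile spacing keeps the grid informative for the skewed
#' stress indices.
#'
#' @param forest a `treeline_forest`.
#' @param table the feature table used for averaging (typically the
#'   training table).
#' @param variable predictor name.
#' @param grid_size number of grid points (default 25).
#' @return data.frame `variable`, `grid_value`, `mean_prediction`.
#' @export
partial_dependence <- function(forest, table, variable, grid_size = 25) {
  stopifnot(inherits(forest, "treeline_forest"))
  if (!variable %in% forest$predictors)
    stop("unknown predictor: ", variable)
  x <- table[, forest$predictors, drop = FALSE]
  grid <- unique(stats::quantile(x[[variable]],
                                 probs = seq(0, 1, length.out = grid_size),
                                 names = FALSE, type = 7))
  preds <- vapply(grid, function(v) {
    xt <- x
    xt[[variable]] <- v
    mean(stats::predict(forest$fit, newdata = xt))
  }, 0)
  data.frame(variable = variable, grid_value = grid,
             mean_prediction = preds, stringsAsFactors = FALSE)
}
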