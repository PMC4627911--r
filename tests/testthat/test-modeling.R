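# Random-forest importance / partial dependence and the permutation-test
# conditional inference tree: determinism, signal recovery, null
# behaviour, and the partition property.

test_that("forest fits are deterministic and score signal vs noise", {
  # pure noise: out-of-bag R^2 stays near zero
  tab <- synthetic_feature_table(600, noise_sd = 50, seed = 101)
  cfg <- forest_config(n_trees = 300, seed = 5)
  f1 <- fit_forest(tab, cfg)
  expect_lte(f1$oob_r2, 0.05)
  f2 <- fit_forest(tab, cfg)
  expect_identical(f1$oob_predictions, f2$oob_predictions)

  # a noiseless deterministic response is learned almost perfectly
  tab2 <- synthetic_feature_table(
    600, f = function(t) 3 * t$slope_percent, noise_sd = 0, seed = 102)
  f3 <- fit_forest(tab2, forest_config(n_trees = 300, seed = 5))
  expect_gte(f3$oob_r2, 0.9)

  tab_na <- tab; tab_na$curvature[3] <- NA
  expect_error(fit_forest(tab_na, cfg), "curvature")
})

test_that("permutation importance ranks the driving variable first", {
  tab <- synthetic_feature_table(
    800, f = function(t) 300 * (t$curvature < 0), noise_sd = 30,
    seed = 103)
  f <- fit_forest(tab, forest_config(n_trees = 300, seed = 7))
  imp <- permutation_importance(f)
  expect_setequal(imp$rank, 1:17)
  expect_equal(imp$variable[1], "curvature")
  # the driving variable dominates the sixteen noise variables
  null_vars <- setdiff(imp$variable, "curvature")
  expect_lt(max(abs(imp$pct_inc_mse[imp$variable %in% null_vars])),
            0.2 * imp$pct_inc_mse[1])

  # a variable uncorrelated with the response and all other predictors
  # has importance near zero
  tab_flat <- synthetic_feature_table(800, noise_sd = 40, seed = 105)
  impf <- permutation_importance(
    fit_forest(tab_flat, forest_config(n_trees = 300, seed = 7)))
  expect_lt(max(abs(impf$pct_inc_mse)), 5)

  # permuting the response kills all importances
  tab_null <- tab
  set.seed(1)
  tab_null$elevation_deviation <- sample(tab_null$elevation_deviation)
  f0 <- fit_forest(tab_null, forest_config(n_trees = 300, seed = 7))
  imp0 <- permutation_importance(f0)
  expect_lt(max(abs(imp0$pct_inc_mse)), 5)
})

test_that("partial dependence recovers marginal shapes", {
  # linear response: interior grid slope close to the true coefficient
  tab <- synthetic_feature_table(
    800, f = function(t) 2 * t$growing_season_temp, noise_sd = 0.3,
    seed = 104)
  f <- fit_forest(tab, forest_config(n_trees = 300, seed = 3))
  pd <- partial_dependence(f, tab, "growing_season_temp", grid_size = 25)
  interior <- pd[pd$grid_value > quantile(tab$growing_season_temp, 0.15) &
                   pd$grid_value < quantile(tab$growing_season_temp, 0.85), ]
  slope <- coef(lm(mean_prediction ~ grid_value, interior))[2]
  expect_equal(unname(slope), 2, tolerance = 0.25)
  # an irrelevant variable yields a nearly flat curve
  pd0 <- partial_dependence(f, tab, "erosion_index", grid_size = 25)
  expect_lt(diff(range(pd0$mean_prediction)),
            0.1 * sd(tab$elevation_deviation))
  expect_error(partial_dependence(f, tab, "no_such_var"), "unknown")
})

test_that("ctree keeps null responses unsplit at the nominal level", {
  n_null_split <- 0
  for (i in 1:20) {
    tab <- synthetic_feature_table(300, noise_sd = 40, seed = 200 + i)
    tr <- fit_ctree(tab, alpha = 0.05, n_permutations = 499,
                    min_node = 20, seed = i)
    if (!tr$nodes[[1]]$terminal) n_null_split <- n_null_split + 1
  }
  # Bonferroni keeps the family-wise split rate at or below alpha;
  # with 20 draws at p <= 0.05, 3+ splits has probability < 0.08
  expect_lte(n_null_split, 2)
})

test_that("ctree recovers a precipitation step threshold", {
  tab <- synthetic_feature_table(1000, noise_sd = 0, seed = 301)
  set.seed(302)
  tab$elevation_deviation <- 150 +
    120 * (tab$annual_precipitation > 5664) + rnorm(1000, 0, 20)
  tr <- fit_ctree(tab, n_permutations = 999, seed = 1)
  root <- tr$nodes[[1]]
  expect_false(root$terminal)
  expect_equal(root$split_var, "annual_precipitation")
  expect_gte(root$threshold, 5564)
  expect_lte(root$threshold, 5764)
  expect_lt(root$p_adjusted, 0.05)
})

test_that("ctree recovers nested thresholds in effect-size order", {
  tab <- synthetic_feature_table(1200, noise_sd = 0, seed = 303)
  set.seed(304)
  tab$elevation_deviation <- 150 +
    120 * (tab$annual_precipitation > 5664) +
    60 * (tab$curvature > 0) + rnorm(1200, 0, 20)
  tr <- fit_ctree(tab, n_permutations = 999, seed = 2)
  root <- tr$nodes[[1]]
  expect_equal(root$split_var, "annual_precipitation")
  expect_equal(tr$nodes[[root$left]]$split_var, "curvature")
  expect_equal(tr$nodes[[root$right]]$split_var, "curvature")
})

test_that("terminal nodes partition the data and report honest medians", {
  tab <- synthetic_feature_table(500, noise_sd = 0, seed = 305)
  set.seed(306)
  tab$elevation_deviation <- 100 +
    150 * (tab$slope_percent > 75) + rnorm(500, 0, 25)
  tr <- fit_ctree(tab, n_permutations = 999, seed = 3)
  summ <- summarize_terminal_nodes(tr, tab)
  expect_equal(sum(summ$n), nrow(tab))
  assign_id <- ctree_node_of(tr, tab)
  expect_true(all(assign_id %in% summ$node))
  # medians recomputed by brute-force filtering on the rendered rules
  for (k in seq_len(nrow(summ))) {
    members <- which(assign_id == summ$node[k])
    expect_equal(summ$median_deviation[k],
                 median(tab$elevation_deviation[members]))
    if (summ$rule[k] != "(root)") {
      sel <- with(tab, eval(parse(text = gsub("&", "&", summ$rule[k]))))
      expect_equal(sort(which(sel)), sort(members))
    }
  }
  # a tree with no admissible split is a single root node
  tab0 <- synthetic_feature_table(80, noise_sd = 10, seed = 307)
  tr0 <- fit_ctree(tab0, n_permutations = 499, alpha = 1e-6, seed = 4)
  s0 <- summarize_terminal_nodes(tr0, tab0)
  expect_equal(nrow(s0), 1)
  expect_equal(s0$median_deviation, median(tab0$elevation_deviation))
  expect_equal(s0$rule, "(root)")
})

test_that("fitted trees serialise to JSON and indented text", {
  tab <- synthetic_feature_table(400, noise_sd = 0, seed = 308)
  set.seed(309)
  tab$elevation_deviation <- 200 +
    100 * (tab$annual_precipitation > 5000) + rnorm(400, 0, 15)
  tr <- fit_ctree(tab, n_permutations = 999, seed = 5)
  js <- jsonlite::fromJSON(ctree_to_json(tr), simplifyVector = FALSE)
  expect_equal(js$alpha, 0.05)
  expect_equal(js$tree$n, 400)
  expect_false(js$tree$terminal)
  expect_equal(js$tree$split_var, "annual_precipitation")
  txt <- format_ctree(tr)
  expect_gt(length(txt), 1)
  expect_match(txt[1], "annual_precipitation")
})
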