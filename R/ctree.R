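#' Conditional inference tree for treeline elevation deviation
#'
#' Recursive partitioning in which every split must pass a Monte-Carlo
#' permutation test. At each node, the association between each candidate
#' variable and the response is measured by the absolute Pearson
#' correlation; its p-value is estimated from `n_permutations` random
#' permutations of the response and Bonferroni-adjusted across the
#' candidate variables. If the smallest adjusted p-value is below `alpha`
#' the node splits on that variable, at the threshold maximizing the
#' absolute difference in mean response between the two children (each
#' child at least `min_node` observations); otherwise the node is
#' terminal. Significance testing before splitting controls over-fitting
#' without pruning.
#'
#' @param table data.frame with the response and explanatory columns.
#' @param response response column name (default `"elevation_deviation"`).
#' @param predictors candidate variable names (default the seventeen
#'   standard explanatory variables intersected with `table`).
#' @param alpha significance level a split must beat (default 0.05).
#' @param n_permutations Monte-Carlo draws per node test (default 9999).
#' @param min_node minimum observations in any node (default 20).
#' @param seed integer seed for the permutation draws.
#' @return A `topo_ctree`: list of nodes (`id`, `n`, `terminal`,
#'   `split_var`, `threshold`, `p_adjusted`, `left`, `right`,
#'   `median_response`, `obs`) plus the fit settings.
#' @export
fit_ctree <- function(table, response = "elevation_deviation",
                      predictors = NULL, alpha = 0.05,
                      n_permutations = 9999, min_node = 20, seed = 1) {
  if (is.null(predictors))
    predictors <- intersect(treeline_explanatory_vars, names(table))
  validate_feature_table(table, response, predictors)
  if (nrow(table) < 2 * min_node)
    stop("need at least 2 * min_node = ", 2 * min_node, " rows")
  y <- table[[response]]
  X <- as.matrix(table[, predictors, drop = FALSE])

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  nodes <- list()
  new_node <- function(obs) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, n = length(obs), obs = obs,
                         terminal = TRUE, split_var = NA_character_,
                         threshold = NA_real_, p_adjusted = NA_real_,
                         left = NA_integer_, right = NA_integer_,
                         median_response = stats::median(y[obs]))
    id
  }

  grow <- function(id) {
    obs <- nodes[[id]]$obs
    n <- length(obs)
    if (n < 2 * min_node) return(invisible())
    yv <- y[obs]
    if (stats::sd(yv) == 0) return(invisible())
    test <- node_association_test(X[obs, , drop = FALSE], yv, n_permutations)
    if (is.null(test)) return(invisible())
    if (test$p_adjusted_min >= alpha) return(invisible())
    var <- test$best_var
    sp <- best_mean_difference_split(X[obs, var], yv, min_node)
    if (is.null(sp)) return(invisible())
    left_obs <- obs[X[obs, var] <= sp$threshold]
    right_obs <- obs[X[obs, var] > sp$threshold]
    lid <- new_node(left_obs); rid <- new_node(right_obs)
    nodes[[id]]$terminal <<- FALSE
    nodes[[id]]$split_var <<- var
    nodes[[id]]$threshold <<- sp$threshold
    nodes[[id]]$p_adjusted <<- test$p_adjusted_min
    nodes[[id]]$left <<- lid
    nodes[[id]]$right <<- rid
    grow(lid); grow(rid)
    invisible()
  }

  root <- new_node(seq_len(nrow(table)))
  grow(root)
  structure(list(nodes = nodes, response = response,
                 predictors = predictors, alpha = alpha,
                 n_permutations = n_permutations, min_node = min_node,
                 seed = seed),
            class = "topo_ctree")
}

# Permutation test of |Pearson correlation| between each column of X and
# y. Returns the Bonferroni-adjusted minimum p-value and the variable
# attaining the smallest unadjusted p (ties broken by larger |r|, then
# column order). Constant columns are excluded; returns NULL when no
# candidate varies. Permutations are evaluated in blocks to bound memory.
node_association_test <- function(X, y, n_permutations, block = 2000L) {
  n <- length(y)
  sds <- apply(X, 2, stats::sd)
  keep <- which(sds > 0)
  if (!length(keep)) return(NULL)
  Xs <- scale(X[, keep, drop = FALSE])
  ys <- as.numeric(scale(y))
  r_obs <- abs(as.numeric(crossprod(Xs, ys))) / (n - 1)
  exceed <- integer(length(keep))
  done <- 0L
  while (done < n_permutations) {
    b <- min(block, n_permutations - done)
    Yp <- vapply(seq_len(b), function(i) ys[sample.int(n)], numeric(n))
    r_perm <- abs(crossprod(Xs, Yp)) / (n - 1)
    exceed <- exceed + rowSums(r_perm >= r_obs - 1e-12)
    done <- done + b
  }
  p <- (1 + exceed) / (n_permutations + 1)
  m <- length(keep)
  best <- order(p, -r_obs)[1]
  list(best_var = colnames(X)[keep[best]],
       p_unadjusted = p[best],
       p_adjusted_min = min(1, p[best] * m),
       m_candidates = m)
}

# Exhaustive search for the cutpoint maximizing |mean(left) - mean(right)|
# subject to both children holding at least min_node observations.
# Threshold is the midpoint between the adjacent distinct values.
best_mean_difference_split <- function(x, y, min_node) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(x)
  i <- seq_len(n - 1)
  valid <- i >= min_node & (n - i) >= min_node & xs[i] < xs[i + 1]
  if (!any(valid)) return(NULL)
  cs <- cumsum(ys)
  left_mean <- cs[i] / i
  right_mean <- (cs[n] - cs[i]) / (n - i)
  gap <- abs(left_mean - right_mean)
  gap[!valid] <- -Inf
  k <- which.max(gap)
  list(threshold = (xs[k] + xs[k + 1]) / 2, mean_gap = gap[k])
}

#' @export
print.topo_ctree <- function(x, ...) {
  cat(sprintf("topo_ctree: %d nodes (%d terminal), alpha = %g\n",
              length(x$nodes), sum(vapply(x$nodes, `[[`, TRUE, "terminal")),
              x$alpha))
  cat(format_ctree(x), sep = "\n")
  invisible(x)
}

#' Indented-text rendering of a fitted tree
#'
#' @param tree a `topo_ctree`.
#' @return Character vector, one line per node.
#' @export
format_ctree <- function(tree) {
  out <- character(0)
  recurse <- function(id, depth, label) {
    nd <- tree$nodes[[id]]
    pad <- strrep("  ", depth)
    if (nd$terminal) {
      out <<- c(out, sprintf("%s%s* node %d: n = %d, median = %.1f",
                             pad, label, nd$id, nd$n, nd$median_response))
    } else {
      out <<- c(out, sprintf("%s%s node %d: %s (p = %.4g)", pad, label,
                             nd$id, nd$split_var, nd$p_adjusted))
      recurse(nd$left, depth + 1,
              sprintf("[%s <= %.4g]", nd$split_var, nd$threshold))
      recurse(nd$right, depth + 1,
              sprintf("[%s > %.4g]", nd$split_var, nd$threshold))
    }
  }
  recurse(1L, 0, "")
  out
}

#' Assign observations to terminal nodes
#'
#' @param tree a `topo_ctree`.
#' @param table data.frame with the tree's predictor columns.
#' @return Integer vector of terminal node ids, one per row.
#' @export
ctree_node_of <- function(tree, table) {
  stopifnot(inherits(tree, "topo_ctree"))
  vapply(seq_len(nrow(table)), function(i) {
    id <- 1L
    repeat {
      nd <- tree$nodes[[id]]
      if (nd$terminal) return(nd$id)
      id <- if (table[[nd$split_var]][i] <= nd$threshold) nd$left else nd$right
    }
  }, integer(1))
}

#' Terminal-node summary table
#'
#' One row per terminal node: size, median response of its members, and
#' the defining rule path rendered as a conjunction of inequalities.
#'
#' @param tree a `topo_ctree`.
#' @param table the data.frame the tree was fitted to.
#' @return data.frame `node`, `n`, `median_deviation`, `rule`.
#' @export
summarize_terminal_nodes <- function(tree, table) {
  stopifnot(inherits(tree, "topo_ctree"))
  y <- table[[tree$response]]
  paths <- list()
  walk <- function(id, conds) {
    nd <- tree$nodes[[id]]
    if (nd$terminal) {
      paths[[as.character(id)]] <<- conds
      return(invisible())
    }
    walk(nd$left, c(conds, sprintf("%s <= %.6g", nd$split_var, nd$threshold)))
    walk(nd$right, c(conds, sprintf("%s > %.6g", nd$split_var, nd$threshold)))
  }
  walk(1L, character(0))
  assign_id <- ctree_node_of(tree, table)
  ids <- sort(as.integer(names(paths)))
  do.call(rbind, lapply(ids, function(id) {
    members <- which(assign_id == id)
    rule <- paths[[as.character(id)]]
    data.frame(node = id, n = length(members),
               median_deviation = stats::median(y[members]),
               rule = if (length(rule)) paste(rule, collapse = " & ")
                      else "(root)",
               stringsAsFactors = FALSE)
  }))
}

#' Export a fitted tree as JSON
#'
#' Nested-node JSON with split rules, adjusted p-values, node sizes and
#' medians.
#'
#' @param tree a `topo_ctree`.
#' @param path optional file path; when omitted the JSON string is
#'   returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
ctree_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "topo_ctree"))
  build <- function(id) {
    nd <- tree$nodes[[id]]
    if (nd$terminal)
      list(id = nd$id, terminal = TRUE, n = nd$n,
           median_response = nd$median_response)
    else
      list(id = nd$id, terminal = FALSE, n = nd$n,
           split_var = nd$split_var, threshold = nd$threshold,
           p_adjusted = nd$p_adjusted,
           left = build(nd$left), right = build(nd$right))
  }
  js <- jsonlite::toJSON(list(alpha = tree$alpha,
                              n_permutations = tree$n_permutations,
                              min_node = tree$min_node,
                              tree = build(1L)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(as.character(js)))
  }
  as.character(js)
}
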