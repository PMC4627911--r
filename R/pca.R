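#' Column-wise standardization
#'
#' Centres each column to mean 0 and scales to sample standard deviation
#' 1, the prerequisite for correlation-scale PCA of variables on mixed
#' units (deg C, %, W m^-2, counts).
#'
#' @param x numeric matrix or data.frame of numeric columns with row and
#'   column labels.
#' @return Numeric matrix of z-scores with the same dimnames and
#'   attribute `standardized = TRUE`.
#' @export
standardize_columns <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop("matrix must be numeric")
  if (any(!is.finite(m))) stop("non-finite entries in feature matrix")
  sds <- apply(m, 2, stats::sd)
  zero <- sds == 0
  if (any(zero))
    stop("zero-variance column(s): ",
         paste(colnames(m)[zero], collapse = ", "))
  z <- scale(m, center = TRUE, scale = sds)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  attr(z, "standardized") <- TRUE
  z
}

#' Correlation-matrix principal components analysis
#'
#' Eigen-decomposition of the correlation matrix of the feature set.
#' Components are ordered by decreasing eigenvalue; each loading column
#' carries a deterministic sign (its largest-magnitude entry is positive)
#' so loadings tables reproduce across runs and platforms. Scores are the
#' standardized data projected on the loadings.
#'
#' @param x numeric matrix or data.frame (rows = points or sites,
#'   columns = variables); standardized internally if needed.
#' @return A `topo_pca` list: `loadings` (variables x components,
#'   orthonormal columns), `eigenvalues`,
#'   `explained_variance_proportion`, `scores`.
#' @export
pca_correlation <- function(x) {
  z <- if (isTRUE(attr(x, "standardized"))) as.matrix(x)
       else standardize_columns(x)
  if (any(!is.finite(z))) stop("non-finite entries in feature matrix")
  n <- nrow(z); p <- ncol(z)
  R <- stats::cor(z)
  eig <- eigen(R, symmetric = TRUE)
  ord <- order(eig$values, decreasing = TRUE)
  vals <- pmax(eig$values[ord], 0)
  vecs <- eig$vectors[, ord, drop = FALSE]
  for (j in seq_len(p)) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  dimnames(vecs) <- list(colnames(z), paste0("PC", seq_len(p)))
  structure(list(loadings = vecs, eigenvalues = vals,
                 explained_variance_proportion = vals / sum(vals),
                 scores = z %*% vecs, n = n),
            class = "topo_pca")
}

#' @export
print.topo_pca <- function(x, ...) {
  p <- length(x$eigenvalues)
  cat(sprintf("Correlation PCA: %d variables, %d rows\n", p, x$n))
  k <- min(p, 5)
  cat("Proportion of variance:",
      paste(sprintf("PC%d %.3f", 1:k, x$explained_variance_proportion[1:k]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Biplot coordinates for an axis pair
#'
#' Loading vectors and row scores restricted to two components, ready for
#' plotting or export.
#'
#' @param result a `topo_pca` from [pca_correlation()].
#' @param axes integer vector of two component indices (default `c(1, 2)`).
#' @return list with matrices `variables` (n_vars x 2) and `points`
#'   (n_rows x 2).
#' @export
biplot_coordinates <- function(result, axes = c(1, 2)) {
  stopifnot(inherits(result, "topo_pca"), length(axes) == 2)
  p <- ncol(result$loadings)
  if (any(axes < 1 | axes > p)) stop("axis out of range 1..", p)
  list(variables = result$loadings[, axes, drop = FALSE],
       points = result$scores[, axes, drop = FALSE])
}

#' Export PCA loadings and variance proportions as CSV
#'
#' Variables-by-components layout with a trailing proportion row; a
#' `loading_highlight_threshold` attribute (default 0.25) records the
#' magnitude conventionally emphasised in loadings tables.
#'
#' @param result a `topo_pca`.
#' @param path CSV path.
#' @param n_components number of components to export (default all).
#' @return `path`, invisibly.
#' @export
write_pca_csv <- function(result, path, n_components = NULL) {
  stopifnot(inherits(result, "topo_pca"))
  k <- if (is.null(n_components)) ncol(result$loadings)
       else min(n_components, ncol(result$loadings))
  tab <- as.data.frame(result$loadings[, seq_len(k), drop = FALSE])
  tab <- cbind(variable = rownames(result$loadings), tab)
  prop <- data.frame(variable = "proportion_of_variance",
                     t(result$explained_variance_proportion[seq_len(k)]))
  names(prop) <- names(tab)
  utils::write.csv(rbind(tab, prop), path, row.names = FALSE)
  invisible(path)
}
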