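#' @title Covariate-adjusted correlation structure
#' @description Age/sex-adjusted partial Spearman correlation among
#'   significant markers and a deterministic hierarchical ordering for
#'   heatmap display.
#' @name correlation-structure
NULL

rank_avg <- function(x) rank(x, ties.method = "average")

#' Partial Spearman correlation
#'
#' Operationalized as rank-transform both variables (average ranks for
#' ties), residualize each on the covariates by least squares, and return
#' the Pearson correlation of the residuals. With no covariates this
#' reduces to the ordinary Spearman coefficient.
#'
#' @param x,y numeric vectors of equal length.
#' @param covariates optional data.frame/matrix of adjustment covariates.
#' @return partial Spearman rho in `[-1, 1]`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  ncov <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n < ncov + 3L) stop("too few observations for partial correlation")
  rx <- rank_avg(x); ry <- rank_avg(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined correlation: constant vector after ranking")
  if (ncov == 0L) return(stats::cor(rx, ry))
  R <- residualize(cbind(rx, ry), as.matrix(covariates))
  stats::cor(R[, 1], R[, 2])
}

#' Pairwise partial Spearman matrix for a marker set
#'
#' All markers are rank-transformed and residualized on the shared
#' covariates in one pass, so the result equals pairwise
#' [partial_spearman()] calls. Pairs whose correlation is undefined are set
#' to NA with a warning.
#'
#' @param markers a [marker_matrix()] or numeric matrix restricted to the
#'   markers of interest (>= 2 columns).
#' @param covariates optional data.frame of adjustment covariates (e.g.
#'   age and a sex indicator).
#' @return symmetric matrix of class `correlation_matrix` with unit
#'   diagonal and an `adjusted_for` attribute.
#' @export
correlation_matrix <- function(markers, covariates = NULL) {
  V <- if (inherits(markers, "marker_matrix")) markers$values else as.matrix(markers)
  if (ncol(V) < 2L) stop("need at least 2 markers")
  Rk <- apply(V, 2, rank_avg)
  const <- apply(Rk, 2, stats::sd) == 0
  if (any(const))
    warning("constant markers after ranking set to NA: ",
            paste(colnames(V)[const], collapse = ", "))
  if (!is.null(covariates)) {
    cm <- as.matrix(covariates)
    storage.mode(cm) <- "double"
    Rk <- residualize(Rk, cm)
  }
  M <- suppressWarnings(stats::cor(Rk))
  M[const, ] <- NA; M[, const] <- NA
  diag(M) <- 1
  M <- (M + t(M)) / 2  # enforce exact symmetry against rounding
  attr(M, "adjusted_for") <- colnames(as.data.frame(covariates))
  class(M) <- c("correlation_matrix", class(M))
  M
}

#' Deterministic heatmap ordering by hierarchical clustering
#'
#' Average-linkage agglomerative clustering on distance `1 - rho`; missing
#' correlations are treated as 0 (with a warning) before computing
#' distances.
#'
#' @param mat a [correlation_matrix()].
#' @return integer permutation of the marker columns.
#' @export
cluster_order <- function(mat) {
  M <- unclass(mat)
  attr(M, "adjusted_for") <- NULL
  if (nrow(M) == 1L) return(1L)
  if (anyNA(M)) {
    warning("missing correlations imputed as 0 for clustering")
    M[is.na(M)] <- 0
  }
  stats::hclust(stats::as.dist(1 - M), method = "average")$order
}

#' Write a correlation matrix as square TSV
#' @param mat a [correlation_matrix()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_correlation_matrix <- function(mat, path) {
  df <- data.frame(marker = rownames(mat), unclass(mat), check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
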