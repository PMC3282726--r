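# PCA reduction of FJ descriptors. The centroid components (|.| <= 1) and the
# leading eigenvalues (which grow with sequence length) live on very different
# scales, so columns are standardized before the rotation is fitted. The
# transform is always fitted on the reference (training) rows only and then
# applied to queries, so no information leaks across the split.

#' Fit a PCA reduction on a feature matrix
#'
#' Columns are centred and scaled to unit variance (constant columns get scale
#' 1 and contribute nothing); principal components whose explained-variance
#' ratio falls below `threshold` are dropped, keeping at least one.
#'
#' @param features numeric matrix (>= 2 rows; at least one non-constant
#'   column).
#' @param threshold minimum explained-variance ratio kept (default 0.01).
#' @return Object of class `pca_transform`: `center`, `scale`, `rotation`
#'   (loadings of retained components), `ratios` (all explained-variance
#'   ratios), `retained`.
#' @export
fit_pca <- function(features, threshold = 0.01) {
  features <- as.matrix(features)
  stopifnot(nrow(features) >= 2L, threshold >= 0)
  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  if (all(scl == 0)) {
    stop("degenerate variance: every feature column is constant", call. = FALSE)
  }
  scl[scl == 0] <- 1
  z <- scale(features, center = ctr, scale = scl)
  p <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ratios <- p$sdev^2 / sum(p$sdev^2)
  keep <- which(ratios >= threshold)
  if (length(keep) == 0L) keep <- 1L
  structure(list(center = ctr, scale = scl,
                 rotation = p$rotation[, keep, drop = FALSE],
                 ratios = ratios, retained = length(keep)),
            class = "pca_transform")
}

#' Apply a fitted PCA reduction
#'
#' @param transform a `pca_transform` from [fit_pca].
#' @param features numeric vector or matrix with the dimension the transform
#'   was fitted on.
#' @return Matrix (or vector, for vector input) of scores on the retained
#'   components.
#' @export
apply_pca <- function(transform, features) {
  vec_in <- is.null(dim(features))
  m <- if (vec_in) matrix(features, nrow = 1L) else as.matrix(features)
  if (ncol(m) != length(transform$center)) {
    stop("dimension mismatch: transform fitted on ", length(transform$center),
         " features, got ", ncol(m), call. = FALSE)
  }
  z <- scale(m, center = transform$center, scale = transform$scale)
  out <- z %*% transform$rotation
  if (vec_in) drop(out) else out
}

#' @export
print.pca_transform <- function(x, ...) {
  cat(sprintf("pca_transform: %d -> %d components (variance ratios: %s)\n",
              length(x$center), x$retained,
              paste(sprintf("%.3f", x$ratios), collapse = ", ")))
  invisible(x)
}

#' Persist a PCA transform as JSON
#' @param transform a `pca_transform`.
#' @param path output path.
#' @export
write_pca_transform <- function(transform, path) {
  obj <- list(center = unname(transform$center), scale = unname(transform$scale),
              rotation = unname(transform$rotation), ratios = transform$ratios,
              retained = transform$retained)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a PCA transform from JSON
#' @param path path written by [write_pca_transform].
#' @return A `pca_transform`.
#' @export
read_pca_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(center = obj$center, scale = obj$scale,
                 rotation = as.matrix(obj$rotation), ratios = obj$ratios,
                 retained = obj$retained),
            class = "pca_transform")
}
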