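# FJ-Curve: 3-D chaos-game representation of a DNA sequence. The four bases
# sit at the corners of a regular tetrahedron and the curve starts at the
# origin, halving the distance to the current base's vertex at every step, so
# all points stay inside the tetrahedron and consecutive points never coincide.

#' Tetrahedron vertices of the FJ-Curve
#'
#' @return 4 x 3 matrix with rows A = (-1,1,-1), G = (1,1,1), C = (1,-1,-1),
#'   T = (-1,-1,1): a regular tetrahedron of edge 2*sqrt(2) centred on the
#'   origin.
#' @export
fj_vertices <- function() {
  v <- rbind(A = c(-1, 1, -1), G = c(1, 1, 1), C = c(1, -1, -1), T = c(-1, -1, 1))
  colnames(v) <- c("x", "y", "z")
  v
}

#' Build the FJ-Curve of a DNA sequence
#'
#' P_0 is the origin; P_i = (P_{i-1} + V(s_i)) / 2, the midpoint between the
#' previous point and the vertex of the i-th base.
#'
#' @param sequence ACGT string (non-empty).
#' @return Object of class `fj_curve`: list with `points`, an (N+1) x 3
#'   matrix whose first row is the origin.
#' @export
fj_curve <- function(sequence) {
  idx <- .seq_to_int(sequence)
  verts <- fj_vertices()[c(1L, 3L, 2L, 4L)[idx], , drop = FALSE]  # ACGT order
  pts <- apply(verts / 2, 2, function(col)
    as.numeric(stats::filter(col, 0.5, method = "recursive")))
  if (length(idx) == 1L) pts <- matrix(pts, nrow = 1L)
  pts <- rbind(c(0, 0, 0), pts)
  dimnames(pts) <- list(NULL, c("x", "y", "z"))
  structure(list(points = pts), class = "fj_curve")
}

#' @export
print.fj_curve <- function(x, ...) {
  cat(sprintf("fj_curve: %d bp, %d points\n",
              nrow(x$points) - 1L, nrow(x$points)))
  invisible(x)
}

#' Centroid descriptors of an FJ-Curve
#'
#' The arithmetic mean of P_1..P_N (the origin P_0 carries no sequence
#' information and is excluded). Each component lies in [-1, 1] by convexity.
#'
#' @param curve an `fj_curve` with N >= 1.
#' @return Numeric length-3 vector (x, y, z means).
#' @export
centroid_descriptors <- function(curve) {
  pts <- curve$points
  if (nrow(pts) < 2L) {
    stop("undefined descriptor: curve has no sequence points", call. = FALSE)
  }
  colMeans(pts[-1L, , drop = FALSE])
}

.curve_pts <- function(curve) {
  if (inherits(curve, "fj_curve")) curve$points else as.matrix(curve)
}

#' L/L distance-ratio matrix of a curve
#'
#' Entry (i, j) is the Euclidean distance between curve points i and j divided
#' by the length of the curve walked between them (the sum of the segment
#' lengths from i to j). The diagonal is 0 and off-diagonal entries lie in
#' (0, 1], with 1 exactly when the sub-path is straight.
#'
#' @param curve an `fj_curve` (or a point matrix) with at least 2 points.
#' @return `curve_ratio_matrix` of kind `"L/L"`: symmetric (N+1) x (N+1).
#' @export
ll_matrix <- function(curve) {
  pts <- .curve_pts(curve)
  n <- nrow(pts)
  stopifnot(n >= 2L)
  seg <- sqrt(rowSums((pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE])^2))
  if (any(seg == 0)) {
    stop("zero-length curve segment: along-curve distances undefined",
         call. = FALSE)
  }
  cum <- c(0, cumsum(seg))
  path <- abs(outer(cum, cum, "-"))
  euc <- as.matrix(stats::dist(pts))
  m <- euc / path
  diag(m) <- 0
  structure(m, kind = "L/L", class = c("curve_ratio_matrix", "matrix", "array"))
}

#' M/M distance-ratio matrix of a curve
#'
#' Entry (i, j) is the Euclidean distance between curve points i and j divided
#' by their graph-theoretical distance along the polyline, i.e. the edge count
#' |i - j|.
#'
#' @inheritParams ll_matrix
#' @return `curve_ratio_matrix` of kind `"M/M"`.
#' @export
mm_matrix <- function(curve) {
  pts <- .curve_pts(curve)
  n <- nrow(pts)
  stopifnot(n >= 2L)
  idx <- seq_len(n)
  hops <- abs(outer(idx, idx, "-"))
  euc <- as.matrix(stats::dist(pts))
  m <- euc / hops
  diag(m) <- 0
  structure(m, kind = "M/M", class = c("curve_ratio_matrix", "matrix", "array"))
}

#' Leading eigenvalue of a symmetric matrix
#'
#' For the non-negative symmetric L/L and M/M matrices this equals the
#' spectral radius. Dense symmetric eigendecomposition is used up to
#' 2048 x 2048 (barcodes are ~1.3 kb at most, so this is the common path);
#' larger matrices fall back to power iteration (tolerance 1e-10, at most
#' 10000 iterations).
#'
#' @param m symmetric numeric matrix.
#' @return Largest eigenvalue (a single real).
#' @export
leading_eigenvalue <- function(m) {
  m <- unclass(m)
  attr(m, "kind") <- NULL
  if (!isSymmetric(m, tol = 1e-8)) {
    stop("leading_eigenvalue requires a symmetric matrix", call. = FALSE)
  }
  n <- nrow(m)
  if (n <= 2048L) {
    return(max(eigen(m, symmetric = TRUE, only.values = TRUE)$values))
  }
  v <- rep(1 / sqrt(n), n)
  lam <- 0
  for (it in seq_len(10000L)) {
    w <- m %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v_new <- as.numeric(w / nw)
    lam_new <- sum(v_new * (m %*% v_new))
    if (abs(lam_new - lam) < 1e-10) return(lam_new)
    v <- v_new
    lam <- lam_new
  }
  lam
}

#' Five-descriptor FJ characterization of a sequence
#'
#' The descriptor vector is (centroid_x, centroid_y, centroid_z,
#' leading eigenvalue of L/L, leading eigenvalue of M/M), in that order.
#'
#' @param sequence ACGT string (non-empty).
#' @return Named numeric vector of length 5.
#' @export
fj_feature_vector <- function(sequence) {
  curve <- fj_curve(sequence)
  cen <- centroid_descriptors(curve)
  out <- c(cen, leading_eigenvalue(ll_matrix(curve)),
           leading_eigenvalue(mm_matrix(curve)))
  names(out) <- c("centroid_x", "centroid_y", "centroid_z",
                  "lambda_ll", "lambda_mm")
  out
}

#' FJ feature matrix of a dataset
#'
#' @param ds a `barcode_dataset`.
#' @return Numeric matrix, one row per record (rownames = accessions), 5
#'   columns.
#' @export
fj_feature_matrix <- function(ds) {
  m <- t(vapply(ds$sequence, fj_feature_vector, numeric(5L), USE.NAMES = FALSE))
  rownames(m) <- ds$accession
  colnames(m) <- c("centroid_x", "centroid_y", "centroid_z",
                   "lambda_ll", "lambda_mm")
  m
}
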