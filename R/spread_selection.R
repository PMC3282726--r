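# Data-driven choice of the RBF kernel width. The exact-interpolation
# construction fixes everything about the network except the spread, which
# the training data cannot pin down through the zero-error property (any
# spread interpolates). It is therefore chosen by internal cross-validation
# on the reference library: candidate widths are a geometric ladder scaled by
# the median pairwise distance between standardized training vectors, and the
# width with the best held-out accuracy wins (ties to the smallest width).

.stratified_folds <- function(labels, k) {
  # deterministic round-robin within species; species with < 2 records are
  # never held out (fold 0)
  fold <- integer(length(labels))
  for (sp in unique(labels)) {
    idx <- which(labels == sp)
    fold[idx] <- if (length(idx) < 2L) 0L else rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Select the RBF spread by cross-validation on the training set
#'
#' Candidate spreads are `median pairwise distance * 2^(-2..4)` computed on
#' the standardized training vectors; each is scored by deterministic
#' stratified k-fold cross-validation within the training set and the
#' best-scoring (smallest, on ties) spread is returned. With fewer than
#' `2 * folds` training vectors, or a single species, the median-distance
#' heuristic is returned directly.
#'
#' @param features numeric training matrix (one row per vector).
#' @param labels species labels, one per row.
#' @param candidates optional numeric vector of spreads to try (standardized
#'   feature scale); defaults to the median-distance ladder.
#' @param folds number of internal cross-validation folds (default 3).
#' @return A single positive spread value.
#' @export
select_spread <- function(features, labels, candidates = NULL, folds = 3L) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels), folds >= 2L)
  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  scl[scl == 0 | is.na(scl)] <- 1
  d <- stats::dist(.standardize(features, ctr, scl))
  d <- d[d > 0]
  med <- if (length(d) > 0) stats::median(d) else 1
  if (is.null(candidates)) candidates <- med * 2^seq(-2, 4)
  candidates <- sort(unique(candidates[candidates > 0]))
  if (length(candidates) == 0L) return(1)
  if (nrow(features) < 2L * folds || length(unique(labels)) < 2L) {
    return(med)
  }
  fold <- .stratified_folds(labels, folds)
  acc <- vapply(candidates, function(s) {
    hits <- 0L; total <- 0L
    for (f in seq_len(folds)) {
      hold <- which(fold == f)
      if (length(hold) == 0L) next
      keep <- setdiff(seq_along(labels), hold)
      model <- train_rbf(features[keep, , drop = FALSE], labels[keep], spread = s)
      pred <- predict(model, features[hold, , drop = FALSE])
      hits <- hits + sum(pred$species == labels[hold])
      total <- total + length(hold)
    }
    if (total == 0L) 0 else hits / total
  }, numeric(1))
  candidates[which.max(acc)]
}
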