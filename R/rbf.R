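# Exact-interpolation radial basis function network. One Gaussian hidden unit
# is centred on every (deduplicated) training vector, which is what makes zero
# error on the training set attainable; the linear output layer is solved by
# minimum-norm least squares and the predicted species is the argmax of the
# output scores (the competitive function).

#' One-hot target matrix for species labels
#'
#' @param labels character vector of species labels.
#' @param index ordered character vector of the distinct species; every label
#'   must occur in it.
#' @return Numeric matrix, one row per label, `length(index)` columns; row i
#'   has a single 1 at the index position of `labels[i]`.
#' @export
one_hot_targets <- function(labels, index) {
  stopifnot(!anyDuplicated(index))
  pos <- match(labels, index)
  if (anyNA(pos)) {
    stop("label(s) not in species index: ",
         paste(unique(labels[is.na(pos)]), collapse = ", "), call. = FALSE)
  }
  t_mat <- matrix(0, nrow = length(labels), ncol = length(index),
                  dimnames = list(NULL, index))
  t_mat[cbind(seq_along(labels), pos)] <- 1
  t_mat
}

.standardize <- function(m, center, scale) {
  sweep(sweep(m, 2, center, "-"), 2, scale, "/")
}

#' Train an exact-interpolation RBF network
#'
#' Features are standardized (training-set column means and SDs; constant
#' columns get scale 1); each standardized training vector becomes a Gaussian
#' centre. The hidden bias is `sqrt(log(2)) / spread`, so a hidden unit's
#' activation is exactly 0.5 at distance `spread` from its centre. Output
#' weights and biases solve `[activations | 1] %*% t(cbind(W, b)) = targets`
#' by minimum-norm least squares, which reproduces every training label
#' exactly (zero error on training vectors). Identical feature vectors with
#' the same label are collapsed to one centre; identical vectors with
#' conflicting labels make exact interpolation impossible and are an error.
#'
#' @param features numeric matrix, one row per training vector (rownames, if
#'   present, are used in diagnostics).
#' @param labels character vector of species labels, one per row.
#' @param spread positive kernel width on the standardized feature scale
#'   (default 1), or `"auto"` to choose it by internal cross-validation
#'   ([select_spread]).
#' @return Object of class `rbf_model`.
#' @export
train_rbf <- function(features, labels, spread = 1.0) {
  features <- as.matrix(features)
  stopifnot(nrow(features) >= 1L, nrow(features) == length(labels),
            !anyNA(labels))
  if (identical(spread, "auto")) spread <- select_spread(features, labels)
  if (!is.numeric(spread) || length(spread) != 1L || spread <= 0) {
    stop("spread must be a single positive number", call. = FALSE)
  }
  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  if (nrow(features) == 1L) scl[] <- 1
  scl[scl == 0 | is.na(scl)] <- 1
  z <- .standardize(features, ctr, scl)

  key <- apply(z, 1, paste, collapse = "\r")
  first <- !duplicated(key)
  for (k in unique(key[duplicated(key)])) {
    rows <- which(key == k)
    if (length(unique(labels[rows])) > 1L) {
      ids <- rownames(features)[rows]
      if (is.null(ids)) ids <- paste0("row ", rows)
      stop("interpolation impossible: identical feature vectors with ",
           "conflicting labels (", paste(ids, collapse = ", "), ")",
           call. = FALSE)
    }
  }
  centers <- z[first, , drop = FALSE]
  rownames(centers) <- NULL
  lab <- labels[first]

  species_index <- sort(unique(lab))
  targets <- one_hot_targets(lab, species_index)
  b <- sqrt(log(2)) / spread
  phi <- exp(-(b * as.matrix(stats::dist(centers)))^2)
  a <- cbind(phi, 1)
  wb <- MASS::ginv(a) %*% targets          # (m+1) x S, biases in last row
  model <- list(centers = centers, spread = spread, hidden_bias = b,
                output_weights = t(wb[seq_len(nrow(centers)), , drop = FALSE]),
                output_biases = as.numeric(wb[nrow(centers) + 1L, ]),
                species_index = species_index,
                feature_center = ctr, feature_scale = scl)
  class(model) <- "rbf_model"
  model
}

#' @export
print.rbf_model <- function(x, ...) {
  cat(sprintf("rbf_model: %d centre(s), %d feature(s), %d species, spread %.4g\n",
              nrow(x$centers), ncol(x$centers), length(x$species_index),
              x$spread))
  invisible(x)
}

#' Gaussian hidden-unit activations
#'
#' Component j is `exp(-(hidden_bias * ||z - c_j||)^2)` where z is the query
#' standardized with the model's training statistics: 1 at the centre, 0.5 at
#' distance `spread`, monotone to 0 with distance.
#'
#' @param model an `rbf_model`.
#' @param x numeric feature vector (raw scale) of the trained dimension.
#' @return Numeric vector, one activation per hidden unit.
#' @export
hidden_activations <- function(model, x) {
  x <- as.numeric(x)
  if (length(x) != ncol(model$centers)) {
    stop("dimension mismatch: model expects ", ncol(model$centers),
         " features, got ", length(x), call. = FALSE)
  }
  z <- (x - model$feature_center) / model$feature_scale
  d2 <- colSums((t(model$centers) - z)^2)
  exp(-model$hidden_bias^2 * d2)
}

#' Classify feature vectors with a trained RBF network
#'
#' Scores are `W %*% h(x) + b`; the predicted species is the argmax
#' (competitive function), ties broken toward the earliest species in the
#' model's alphabetical species index and flagged.
#'
#' @param object an `rbf_model`.
#' @param newdata numeric feature vector or matrix (rows = queries) on the raw
#'   feature scale.
#' @param ... unused.
#' @return `list(species = character, scores = matrix, tie = logical)`.
#' @export
predict.rbf_model <- function(object, newdata, ...) {
  m <- if (is.null(dim(newdata))) matrix(as.numeric(newdata), nrow = 1L)
       else as.matrix(newdata)
  if (ncol(m) != ncol(object$centers)) {
    stop("dimension mismatch: model expects ", ncol(object$centers),
         " features, got ", ncol(m), call. = FALSE)
  }
  scores <- t(apply(m, 1, function(x) {
    h <- hidden_activations(object, x)
    as.numeric(object$output_weights %*% h + object$output_biases)
  }))
  if (length(object$species_index) == 1L) scores <- matrix(scores, ncol = 1L)
  colnames(scores) <- object$species_index
  # argmax with tolerance: numerically tied scores go to the earliest
  # species in the (alphabetical) index
  best <- apply(scores, 1, function(s) which(s >= max(s) - 1e-12)[1])
  tie <- apply(scores, 1, function(s) sum(s >= max(s) - 1e-12) > 1L)
  list(species = object$species_index[best], scores = scores, tie = tie)
}

#' Persist an RBF model as JSON
#' @param model an `rbf_model`.
#' @param path output path.
#' @export
write_rbf_model <- function(model, path) {
  obj <- list(centers = unname(model$centers), spread = model$spread,
              hidden_bias = model$hidden_bias,
              output_weights = unname(model$output_weights),
              output_biases = model$output_biases,
              species_index = model$species_index,
              feature_center = unname(model$feature_center),
              feature_scale = unname(model$feature_scale))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an RBF model from JSON
#' @param path path written by [write_rbf_model].
#' @return An `rbf_model`.
#' @export
read_rbf_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(centers = as.matrix(obj$centers), spread = obj$spread,
                hidden_bias = obj$hidden_bias,
                output_weights = matrix(as.matrix(obj$output_weights),
                                        nrow = length(obj$species_index)),
                output_biases = obj$output_biases,
                species_index = obj$species_index,
                feature_center = obj$feature_center,
                feature_scale = obj$feature_scale)
  class(model) <- "rbf_model"
  model
}
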