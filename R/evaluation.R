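# Evaluation protocols: repeated species-level splits (complete/balanced
# species coverage in the reference library) and k-fold cross-validation
# (possibly incomplete/unbalanced coverage), with pooled success rates and
# Wilson score confidence intervals.

.round_half_away <- function(x) floor(x + 0.5)

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Repeated species-level reference/query splits
#'
#' Per repetition, every species with `small_species_max` or fewer records
#' contributes all of them to the reference set; larger species contribute
#' `round(ref_fraction * n)` uniformly chosen records (at least 1, and leaving
#' at least 1 for the query set). Every species is therefore represented in
#' the reference library: complete/balanced coverage.
#'
#' @param ds a `barcode_dataset` (unlabeled records are not allowed here).
#' @param ref_fraction fraction of each large species placed in the reference
#'   set (default 2/3).
#' @param small_species_max species at or below this size go entirely to the
#'   reference set (default 3).
#' @param repetitions number of independent random splits (default 5).
#' @param seed integer seed; repetition r draws from seed + r.
#' @return Object of class `split_plan` with `kind = "species_level_split"`
#'   and a `folds` list of `list(reference =, query =)` index vectors.
#' @export
species_level_split <- function(ds, ref_fraction = 2 / 3, small_species_max = 3L,
                                repetitions = 5L, seed = 1L) {
  stopifnot(nrow(ds) >= 1L, ref_fraction > 0, ref_fraction < 1,
            repetitions >= 1L)
  if (anyNA(ds$species)) {
    stop("dataset has unlabeled records; evaluation requires species labels",
         call. = FALSE)
  }
  tab <- species_table(ds)
  folds <- lapply(seq_len(repetitions), function(r) {
    .with_seed(seed + r, {
      ref <- integer(0)
      for (idx in tab) {
        n <- length(idx)
        if (n <= small_species_max) {
          ref <- c(ref, idx)
        } else {
          n_ref <- .round_half_away(ref_fraction * n)
          n_ref <- min(max(n_ref, 1L), n - 1L)
          ref <- c(ref, sample(idx, n_ref))
        }
      }
      ref <- sort(ref)
      list(reference = ref, query = setdiff(seq_len(nrow(ds)), ref))
    })
  })
  structure(list(kind = "species_level_split", folds = folds, seed = seed,
                 params = list(ref_fraction = ref_fraction,
                               small_species_max = small_species_max,
                               repetitions = repetitions)),
            class = "split_plan")
}

#' k-fold cross-validation split
#'
#' Records are shuffled once by the seed and partitioned into k near-equal
#' folds (sizes differ by at most 1); fold i is the query set against the
#' union of the other folds as reference. Species coverage of the reference
#' library may be incomplete (unbalanced), so the singleton-exclusion rule of
#' [run_identification] can fire.
#'
#' @param ds a `barcode_dataset`.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return A `split_plan` with `kind = "k_fold"`.
#' @export
k_fold_split <- function(ds, k = 5L, seed = 1L) {
  n <- nrow(ds)
  stopifnot(k >= 2L)
  if (k > n) stop("k (", k, ") exceeds the number of records (", n, ")",
                  call. = FALSE)
  if (anyNA(ds$species)) {
    stop("dataset has unlabeled records; evaluation requires species labels",
         call. = FALSE)
  }
  perm <- .with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  folds <- lapply(seq_len(k), function(i) {
    q <- sort(perm[starts[i]:ends[i]])
    list(reference = setdiff(seq_len(n), q), query = q)
  })
  structure(list(kind = "k_fold", folds = folds, seed = seed,
                 params = list(k = k)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$query), integer(1))
  cat(sprintf("split_plan (%s): %d fold(s)/repetition(s), query sizes %s, seed %d\n",
              x$kind, length(x$folds), paste(sizes, collapse = "/"), x$seed))
  invisible(x)
}

#' Success rate of species identification
#'
#' @param n_correct number of correctly assigned (counted) queries.
#' @param n_counted number of counted queries (> 0).
#' @return `n_correct / n_counted`.
#' @export
success_rate <- function(n_correct, n_counted) {
  if (n_counted == 0) {
    stop("success rate undefined: no counted queries", call. = FALSE)
  }
  stopifnot(n_correct >= 0, n_correct <= n_counted)
  n_correct / n_counted
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Inverts the normal-approximation score test: with `p = n_correct/n_counted`
#' and z the two-sided standard-normal quantile at level `gamma`
#' (1.959964 at gamma = 0.95), the interval is centred at
#' `(p + z^2/2n) / (1 + z^2/n)` with half-width
#' `z * sqrt(p(1-p)/n + z^2/4n^2) / (1 + z^2/n)`, clamped to [0, 1].
#'
#' @param n_correct number of successes.
#' @param n_counted number of trials (>= 1).
#' @param gamma confidence level in (0, 1), default 0.95.
#' @return `c(lower, upper)`.
#' @export
wilson_ci <- function(n_correct, n_counted, gamma = 0.95) {
  stopifnot(n_counted >= 1, n_correct >= 0, n_correct <= n_counted,
            gamma > 0, gamma < 1)
  z <- stats::qnorm((1 + gamma) / 2)
  n <- n_counted
  p <- n_correct / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Format a proportion as a truncated percentage
#'
#' Reproduces the reporting convention in which 130/135 = 96.296...% prints
#' as "96.29%": the value is floored (truncated), not rounded, at two
#' decimals. Display only -- never used in computation.
#'
#' @param x proportion in [0, 1].
#' @return String such as `"96.29%"`.
#' @export
format_percent_trunc <- function(x) {
  stopifnot(all(x >= 0), all(x <= 1))
  sprintf("%.2f%%", floor(x * 10000 + 1e-6) / 100)
}

#' Run species identification over a split plan
#'
#' For every repetition/fold: encode the reference sequences (DV: 24-component
#' S/L vector; FJ: 5 descriptors then PCA fitted on the reference rows only),
#' train the RBF network, and classify the queries. A query whose true
#' species is absent from the fold's reference library is marked
#' `excluded_singleton` and omitted from the success-rate denominator, since
#' it can only be assigned to a wrong species. Counts are pooled across
#' repetitions/folds before the confidence interval is computed.
#'
#' @param ds a `barcode_dataset`.
#' @param plan a `split_plan` built on `ds`.
#' @param encoder `"dv"` or `"fj"`.
#' @param spread RBF kernel width on the standardized feature scale, or
#'   `"auto"` (the default) to select it per fold by cross-validation within
#'   the reference set ([select_spread]).
#' @param pca_threshold minimum explained-variance ratio retained by the FJ
#'   PCA reduction (ignored for DV).
#' @param gamma confidence level for the Wilson interval.
#' @param features optional precomputed feature matrix for `ds` (one row per
#'   record) to avoid re-encoding across calls.
#' @return Object of class `evaluation_report`: per-query `assignments`
#'   (fold, accession, true/predicted species, status), pooled counts,
#'   `success_rate`, and `ci`.
#' @export
run_identification <- function(ds, plan, encoder = c("dv", "fj"),
                               spread = "auto",
                               pca_threshold = 0.01, gamma = 0.95,
                               features = NULL) {
  encoder <- match.arg(encoder)
  stopifnot(inherits(plan, "split_plan"))
  if (is.null(features)) {
    features <- if (encoder == "dv") dv_feature_matrix(ds) else fj_feature_matrix(ds)
  }
  stopifnot(nrow(features) == nrow(ds))
  rows <- list()
  for (f in seq_along(plan$folds)) {
    ref_idx <- plan$folds[[f]]$reference
    qry_idx <- plan$folds[[f]]$query
    if (length(qry_idx) == 0L) next
    ref_feat <- features[ref_idx, , drop = FALSE]
    qry_feat <- features[qry_idx, , drop = FALSE]
    if (encoder == "fj") {
      pca <- fit_pca(ref_feat, threshold = pca_threshold)
      ref_feat <- apply_pca(pca, ref_feat)
      qry_feat <- apply_pca(pca, qry_feat)
    }
    model <- train_rbf(ref_feat, ds$species[ref_idx], spread = spread)
    pred <- predict(model, qry_feat)
    truth <- ds$species[qry_idx]
    status <- ifelse(is.na(truth), "unlabeled",
              ifelse(!(truth %in% ds$species[ref_idx]), "excluded_singleton",
              ifelse(truth == pred$species, "correct", "wrong")))
    rows[[f]] <- data.frame(fold = f, accession = ds$accession[qry_idx],
                            true_species = truth,
                            predicted_species = pred$species,
                            status = status, stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, rows)
  if (is.null(assignments)) {
    assignments <- data.frame(fold = integer(), accession = character(),
                              true_species = character(),
                              predicted_species = character(),
                              status = character(), stringsAsFactors = FALSE)
  }
  n_correct <- sum(assignments$status == "correct")
  n_counted <- sum(assignments$status %in% c("correct", "wrong"))
  n_excl <- sum(assignments$status == "excluded_singleton")
  rate <- if (n_counted > 0) n_correct / n_counted else NA_real_
  ci <- if (n_counted > 0) wilson_ci(n_correct, n_counted, gamma)
        else c(lower = NA_real_, upper = NA_real_)
  structure(list(assignments = assignments, n_correct = n_correct,
                 n_counted = n_counted, n_excluded_singletons = n_excl,
                 success_rate = rate, gamma = gamma,
                 ci_lower = unname(ci["lower"]), ci_upper = unname(ci["upper"]),
                 encoder = encoder, plan_kind = plan$kind, seed = plan$seed,
                 spread = spread, pca_threshold = pca_threshold),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report (%s encoder, %s protocol, seed %d)\n",
              toupper(x$encoder), x$plan_kind, x$seed))
  cat(sprintf("  queries counted: %d (correct %d, excluded singletons %d)\n",
              x$n_counted, x$n_correct, x$n_excluded_singletons))
  if (!is.na(x$success_rate)) {
    cat(sprintf("  success rate: %s (%.0f%% CI: %s-%s)\n",
                format_percent_trunc(x$success_rate), 100 * x$gamma,
                format_percent_trunc(x$ci_lower),
                format_percent_trunc(x$ci_upper)))
  }
  invisible(x)
}

#' Write an evaluation report (JSON summary + per-query TSV)
#'
#' @param report an `evaluation_report`.
#' @param json_path path for the JSON summary, or `NULL` to skip.
#' @param tsv_path path for the per-query assignment TSV, or `NULL` to skip.
#' @export
write_evaluation_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    obj <- report[c("n_correct", "n_counted", "n_excluded_singletons",
                    "success_rate", "gamma", "ci_lower", "ci_upper",
                    "encoder", "plan_kind", "seed", "spread", "pca_threshold")]
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(tsv_path)) write_assignments(report$assignments, tsv_path)
  invisible(report)
}
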