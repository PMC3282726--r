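# Dual-Vector (DV) Curve: each base contributes an ordered pair of planar
# unit-slope steps drawn from u = (1,1), d = (1,-1). The x coordinate advances
# by 1 per step, so a length-N sequence gives a 2N-step (2N+1 point) polyline
# with no degeneracy, and the curve decodes uniquely back to the sequence.

# The four ordered step pairs, as y-increments (x always +1): uu < ud < du < dd.
.dv_pairs <- rbind(uu = c(1, 1), ud = c(1, -1), du = c(-1, 1), dd = c(-1, -1))

#' Enumerate the 24 dual-vector assignments
#'
#' A DV assignment maps each base to one of the four ordered pairs of steps
#' `{uu, ud, du, dd}` (u = (1,1), d = (1,-1)) bijectively; the 4! = 24
#' assignments are enumerated lexicographically over the pairs given to
#' (A, C, G, T), with pair order uu < ud < du < dd. Each yields a different
#' DV-Curve of the same sequence, hence the 24-component characterization.
#'
#' @return A 24 x 4 integer matrix; row k is assignment k, columns named
#'   A, C, G, T hold pair indices 1..4 (1 = uu, ..., 4 = dd). Row names are
#'   compact labels such as `"A:uu C:du G:ud T:dd"`.
#' @export
dv_assignments <- function() {
  perms <- matrix(0L, 24L, 4L)
  r <- 0L
  for (a in 1:4) for (b in 1:4) for (g in 1:4) for (t in 1:4) {
    if (length(unique(c(a, b, g, t))) == 4L) {
      r <- r + 1L
      perms[r, ] <- c(a, b, g, t)
    }
  }
  colnames(perms) <- c("A", "C", "G", "T")
  pn <- rownames(.dv_pairs)
  rownames(perms) <- apply(perms, 1, function(p)
    paste(paste0(c("A", "C", "G", "T"), ":", pn[p]), collapse = " "))
  perms
}

#' The canonical dual-vector assignment
#'
#' A -> uu, G -> ud, C -> du, T -> dd, so purines rise first and the poly-A
#' curve is the line y = x. This is the default assignment for single-curve
#' plots and the decode round-trip.
#'
#' @return Named integer vector over A, C, G, T with pair indices.
#' @export
dv_canonical_assignment <- function() {
  c(A = 1L, C = 3L, G = 2L, T = 4L)
}

.dv_check_assignment <- function(assignment) {
  stopifnot(length(assignment) == 4L,
            all(c("A", "C", "G", "T") %in% names(assignment)),
            setequal(assignment, 1:4))
  assignment[c("A", "C", "G", "T")]
}

.seq_to_int <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nchar(sequence) >= 1L)
  code <- utf8ToInt(sequence)
  idx <- match(code, utf8ToInt("ACGT"))
  if (anyNA(idx)) {
    bad <- intToUtf8(code[which(is.na(idx))[1]])
    stop("encoding error: non-ACGT symbol ", sQuote(bad), " in sequence",
         call. = FALSE)
  }
  idx
}

#' Build the DV-Curve of a DNA sequence
#'
#' Starting at the origin, each base appends its two assigned unit-slope
#' vectors cumulatively, giving integer lattice points (i, y_i), i = 0..2N.
#'
#' @param sequence ACGT string (non-empty).
#' @param assignment a row of [dv_assignments()] or [dv_canonical_assignment()].
#' @return Object of class `dv_curve`: list with `x` (0..2N) and `y`
#'   (integer, `|diff(y)| = 1`).
#' @export
dv_curve <- function(sequence, assignment = dv_canonical_assignment()) {
  assignment <- .dv_check_assignment(assignment)
  base_idx <- .seq_to_int(sequence)
  steps <- t(.dv_pairs[assignment[base_idx], , drop = FALSE])  # 2 x N
  y <- c(0L, cumsum(as.integer(steps)))
  structure(list(x = seq_along(y) - 1L, y = y), class = "dv_curve")
}

#' @export
print.dv_curve <- function(x, ...) {
  n <- (length(x$y) - 1L) / 2L
  cat(sprintf("dv_curve: %d bp, %d points, y range [%d, %d]\n",
              n, length(x$y), min(x$y), max(x$y)))
  invisible(x)
}

#' Decode a DV-Curve back to its sequence
#'
#' The DV-Curve loses no information: consecutive step pairs identify the base
#' under the curve's assignment.
#'
#' @param curve a `dv_curve`.
#' @param assignment the assignment the curve was built under.
#' @return The ACGT string, so `dv_decode(dv_curve(s, a), a) == s`.
#' @export
dv_decode <- function(curve, assignment = dv_canonical_assignment()) {
  assignment <- .dv_check_assignment(assignment)
  dy <- diff(curve$y)
  if (length(dy) %% 2L != 0L || length(dy) == 0L) {
    stop("malformed curve: step count must be positive and even", call. = FALSE)
  }
  if (!all(abs(dy) == 1L)) {
    stop("malformed curve: every y step must be +1 or -1", call. = FALSE)
  }
  first <- dy[seq(1L, length(dy), by = 2L)]
  second <- dy[seq(2L, length(dy), by = 2L)]
  # pair index from the two step signs, matching the uu<ud<du<dd order
  pair_idx <- 1L + 2L * (first < 0L) + (second < 0L)
  base_of_pair <- c("A", "C", "G", "T")[order(assignment)]
  paste(base_of_pair[pair_idx], collapse = "")
}

#' S/L descriptor of a DV-Curve
#'
#' S is the trapezoidal area enclosed between the polyline and the x axis
#' (computed on |y|, unit x spacing); L is the total arc length, which equals
#' 2N * sqrt(2) since every step is a unit-slope diagonal. The ratio S/L is a
#' scale-aware shape descriptor of the curve.
#'
#' @param curve a `dv_curve` with at least 2 points.
#' @return S/L as a single non-negative real.
#' @export
sl_descriptor <- function(curve) {
  y <- abs(curve$y)
  if (length(y) < 2L) {
    stop("undefined descriptor: curve has fewer than 2 points", call. = FALSE)
  }
  s <- sum((y[-length(y)] + y[-1]) / 2)
  l <- sum(sqrt(1 + diff(curve$y)^2))
  s / l
}

#' 24-component DV characterization of a sequence
#'
#' Component k is the S/L descriptor of the DV-Curve built under the k-th
#' assignment of [dv_assignments()]. The dimension is 24 for every sequence,
#' independent of its length, so e.g. a 648 bp COI barcode reduces to 24
#' numbers.
#'
#' @param sequence ACGT string (non-empty).
#' @return Named numeric vector of length 24.
#' @export
dv_feature_vector <- function(sequence) {
  base_idx <- .seq_to_int(sequence)
  perms <- dv_assignments()
  out <- numeric(24L)
  for (k in 1:24) {
    steps <- t(.dv_pairs[perms[k, ][base_idx], , drop = FALSE])
    y <- abs(c(0, cumsum(as.numeric(steps))))
    s <- sum((y[-length(y)] + y[-1]) / 2)
    out[k] <- s / (2 * length(base_idx) * sqrt(2))
  }
  names(out) <- rownames(perms)
  out
}

#' DV feature matrix of a dataset
#'
#' @param ds a `barcode_dataset`.
#' @return Numeric matrix, one row per record (rownames = accessions), 24
#'   columns.
#' @export
dv_feature_matrix <- function(ds) {
  m <- t(vapply(ds$sequence, dv_feature_vector, numeric(24L), USE.NAMES = FALSE))
  rownames(m) <- ds$accession
  m
}

#' Export curve points as a two-column table
#'
#' @param curve a `dv_curve` or `fj_curve`.
#' @param path output TSV path.
#' @export
write_curve_points <- function(curve, path) {
  if (inherits(curve, "dv_curve")) {
    df <- data.frame(x = curve$x, y = curve$y)
  } else if (inherits(curve, "fj_curve")) {
    df <- as.data.frame(unclass(curve)$points)
    names(df) <- c("x", "y", "z")
  } else stop("not a curve object", call. = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
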