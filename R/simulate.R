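# Synthetic barcode libraries with a controlled barcode gap: a uniform random
# root sequence, one mutated ancestor per species (star phylogeny), and
# individuals mutated from their ancestor. Substitutions are uniform over the
# three alternative bases (Jukes-Cantor-like). ITS-like data add Poisson
# indel events with geometric lengths, so sequence lengths vary.

.bases <- c("A", "C", "G", "T")

.mutate_sites <- function(chars, p) {
  hit <- which(stats::runif(length(chars)) < p)
  if (length(hit) > 0) {
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(.bases, b), 1L), character(1))
  }
  chars
}

.apply_indels <- function(chars, rate, len_mean, max_retries = 100L) {
  n_events <- stats::rpois(1L, rate)
  for (e in seq_len(n_events)) {
    for (try in seq_len(max_retries)) {
      len <- stats::rgeom(1L, prob = 1 / len_mean) + 1L
      insert <- stats::runif(1) < 0.5
      if (insert) {
        pos <- sample.int(length(chars) + 1L, 1L) - 1L  # insert after pos
        chars <- append(chars, sample(.bases, len, replace = TRUE), after = pos)
        break
      }
      if (len < length(chars)) {                         # deletion must leave >= 1 base
        pos <- sample.int(length(chars) - len + 1L, 1L)
        chars <- chars[-(pos:(pos + len - 1L))]
        break
      }
      if (try == max_retries) {
        stop("indel simulation failed: deletions keep emptying the sequence",
             call. = FALSE)
      }
    }
  }
  chars
}

#' Simulate a labeled barcode library
#'
#' A root sequence is drawn uniformly over ACGT; each species ancestor mutates
#' every root site independently with probability `between_divergence`
#' (uniformly to one of the other three bases), and each individual mutates
#' its ancestor likewise at `within_divergence`. With `indel_rate > 0`
#' (ITS mode) each individual additionally receives Poisson(`indel_rate`)
#' indel events, each inserting or deleting (equal odds) a geometric run of
#' mean `indel_length_mean` bases at a uniform position. With `indel_rate = 0`
#' (COI mode) all sequences share `seq_length` exactly. Deterministic given
#' `seed`.
#'
#' Accessions are `SIM00001`, `SIM00002`, ... and species `Species_01`, ...,
#' so headers round-trip through the BOLD-style parser.
#'
#' @param n_species number of species (>= 1).
#' @param records_per_species records per species: a single integer or a
#'   length-`n_species` vector.
#' @param seq_length root sequence length in bp (default 650, COI-like).
#' @param between_divergence per-site substitution probability root ->
#'   species ancestor (default 0.05).
#' @param within_divergence per-site substitution probability ancestor ->
#'   individual (default 0.005); should be well below `between_divergence`
#'   for a separable benchmark (warned otherwise).
#' @param indel_rate expected indel events per individual (default 0).
#' @param indel_length_mean mean indel length in bp (geometric, default 3).
#' @param seed integer seed.
#' @return A [barcode_dataset].
#' @export
simulate_barcodes <- function(n_species = 10L, records_per_species = 20L,
                              seq_length = 650L, between_divergence = 0.05,
                              within_divergence = 0.005, indel_rate = 0,
                              indel_length_mean = 3, seed = 1L) {
  stopifnot(n_species >= 1L, all(records_per_species >= 1L), seq_length >= 1L,
            between_divergence >= 0, between_divergence <= 1,
            within_divergence >= 0, within_divergence <= 1,
            indel_rate >= 0, indel_length_mean >= 1)
  if (between_divergence <= within_divergence && between_divergence < 1) {
    warning("between_divergence <= within_divergence: species clusters will ",
            "not be separable", call. = FALSE)
  }
  per <- if (length(records_per_species) == 1L)
    rep(as.integer(records_per_species), n_species) else as.integer(records_per_species)
  stopifnot(length(per) == n_species)
  .with_seed(seed, {
    root <- sample(.bases, seq_length, replace = TRUE)
    acc <- character(0); spp <- character(0); seqs <- character(0)
    counter <- 0L
    for (k in seq_len(n_species)) {
      ancestor <- .mutate_sites(root, between_divergence)
      sp_name <- sprintf("Species_%02d", k)
      for (j in seq_len(per[k])) {
        chars <- .mutate_sites(ancestor, within_divergence)
        if (indel_rate > 0) {
          chars <- .apply_indels(chars, indel_rate, indel_length_mean)
        }
        counter <- counter + 1L
        acc <- c(acc, sprintf("SIM%05d", counter))
        spp <- c(spp, sp_name)
        seqs <- c(seqs, paste(chars, collapse = ""))
      }
    }
    barcode_dataset(acc, spp, seqs)
  })
}

#' Add singleton species to a dataset
#'
#' Appends `n` new species with exactly one record each, drawn uniformly over
#' ACGT (hence far from every existing cluster). Useful for exercising the
#' singleton-exclusion rule of k-fold evaluation.
#'
#' @param ds a `barcode_dataset`.
#' @param n number of singleton species to add (>= 0).
#' @param seed integer seed.
#' @param seq_length length of the new sequences; defaults to the median
#'   length in `ds`.
#' @return The augmented `barcode_dataset`.
#' @export
inject_singletons <- function(ds, n, seed = 1L,
                              seq_length = stats::median(nchar(ds$sequence))) {
  stopifnot(n >= 0L)
  if (n == 0L) return(ds)
  .with_seed(seed, {
    existing <- sum(grepl("^Singleton_", unique(ds$species)))
    acc <- sprintf("SING%04d", existing + seq_len(n))
    spp <- sprintf("Singleton_%02d", existing + seq_len(n))
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(.bases, seq_length, replace = TRUE), collapse = ""),
      character(1))
    out <- rbind(ds, barcode_dataset(acc, spp, seqs))
    class(out) <- c("barcode_dataset", "data.frame")
    rownames(out) <- NULL
    out
  })
}
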