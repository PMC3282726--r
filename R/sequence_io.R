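#' Construct a barcode dataset
#'
#' A barcode dataset is a data frame with one row per sequence record and
#' columns `accession`, `species` and `sequence`. Species labels may be `NA`
#' for records that could not be labeled from their FASTA header; such records
#' can still be classified but are unusable for training or evaluation.
#'
#' @param accession character vector of record identifiers.
#' @param species character vector of species names (`NA` allowed).
#' @param sequence character vector of nucleotide sequences (uppercased).
#' @return An object of class `barcode_dataset` (a data frame).
#' @export
barcode_dataset <- function(accession = character(), species = character(),
                            sequence = character()) {
  stopifnot(length(accession) == length(species),
            length(accession) == length(sequence))
  ds <- data.frame(accession = as.character(accession),
                   species = as.character(species),
                   sequence = toupper(as.character(sequence)),
                   stringsAsFactors = FALSE)
  class(ds) <- c("barcode_dataset", "data.frame")
  ds
}

#' @export
print.barcode_dataset <- function(x, ...) {
  cat(sprintf("barcode_dataset: %d record(s), %d species\n",
              nrow(x), length(unique(stats::na.omit(x$species)))))
  if (nrow(x) > 0) {
    show <- utils::head(x, 5)
    show$sequence <- paste0(substr(show$sequence, 1, 24),
                            ifelse(nchar(show$sequence) > 24, "...", ""))
    print.data.frame(show)
    if (nrow(x) > 5) cat(sprintf("... and %d more\n", nrow(x) - 5))
  }
  invisible(x)
}

#' Map species to record indices
#'
#' @param ds a `barcode_dataset`.
#' @return Named list: species name -> integer vector of row indices.
#'   Unlabeled (`NA` species) records appear in no bucket.
#' @export
species_table <- function(ds) {
  keep <- which(!is.na(ds$species))
  split(keep, ds$species[keep])
}

#' Parse a BOLD-style FASTA header
#'
#' Headers of the form `"<accession>-<species name>"` are split at the FIRST
#' hyphen; the species name may itself contain spaces. Both parts are returned
#' trimmed of surrounding whitespace.
#'
#' @param header header string (without the leading `>`).
#' @return `list(accession =, species =)`.
#' @export
parse_bold_header <- function(header) {
  stopifnot(is.character(header), length(header) == 1L)
  pos <- regexpr("-", header, fixed = TRUE)
  if (pos < 0) {
    stop("labeling error: header ", sQuote(header),
         " has no '-' separating accession from species", call. = FALSE)
  }
  list(accession = trimws(substr(header, 1L, pos - 1L)),
       species = trimws(substr(header, pos + 1L, nchar(header))))
}

#' Read a FASTA file of barcode records
#'
#' Each entry's header is parsed as `"<accession>-<species>"`
#' ([parse_bold_header]); entries whose header lacks a hyphen get `NA` species
#' (with a warning) so they can still be classified. Sequences are uppercased;
#' entry order is preserved. Ambiguous symbols (N, IUPAC codes, gaps) are kept
#' at this stage -- rejecting them is the cleaner's job ([clean_dataset]).
#'
#' @param path path to a FASTA file.
#' @return A [barcode_dataset].
#' @export
read_barcode_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(set) == 0L) return(barcode_dataset())
  headers <- trimws(names(set))
  seqs <- toupper(as.character(set))
  acc <- character(length(set))
  spp <- rep(NA_character_, length(set))
  bad <- character(0)
  for (i in seq_along(headers)) {
    parsed <- tryCatch(parse_bold_header(headers[i]), error = function(e) NULL)
    if (is.null(parsed)) {
      acc[i] <- headers[i]
      bad <- c(bad, headers[i])
    } else {
      acc[i] <- parsed$accession
      spp[i] <- parsed$species
    }
  }
  if (length(bad) > 0) {
    warning(length(bad), " header(s) without '-' have no species label: ",
            paste(utils::head(bad, 3), collapse = ", "),
            if (length(bad) > 3) ", ..." else "", call. = FALSE)
  }
  barcode_dataset(acc, spp, seqs)
}

#' Write a barcode dataset as FASTA
#'
#' Headers are reassembled as `accession-species` (accession alone when the
#' species is `NA`), the inverse of [read_barcode_fasta].
#'
#' @param ds a `barcode_dataset`.
#' @param path output path.
#' @param width line-wrap width for sequence lines.
#' @export
write_barcode_fasta <- function(ds, path, width = 70L) {
  headers <- ifelse(is.na(ds$species), ds$accession,
                    paste0(ds$accession, "-", ds$species))
  set <- Biostrings::BStringSet(ds$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Clean a barcode dataset
#'
#' Applies the standard barcode-library cleaning rules: drop records carrying
#' any symbol outside `{A,C,G,T}` (N, IUPAC ambiguity codes, gaps), drop
#' records shorter than `min_length` (or longer than `max_length`), and
#' optionally truncate survivors to their first `trim_to` bases (e.g. reducing
#' ~655 bp COI reads to a uniform 652 bp).
#'
#' @param ds a `barcode_dataset`.
#' @param min_length minimum sequence length kept (default 0 = no filter).
#' @param max_length maximum length kept, or `NULL` for no bound.
#' @param trim_to truncate surviving sequences to this many 5' bases, or
#'   `NULL` for no truncation.
#' @param drop_ambiguous drop records with any non-ACGT symbol (default TRUE).
#' @return `list(dataset =, report =)` where `report` is a `cleaning_report`:
#'   counts of records removed per reason (`ambiguous`, `too_short`,
#'   `too_long`) plus `kept` and `input`.
#' @export
clean_dataset <- function(ds, min_length = 0L, max_length = NULL,
                          trim_to = NULL, drop_ambiguous = TRUE) {
  stopifnot(min_length >= 0L)
  if (!is.null(trim_to) && min_length > 0L) stopifnot(trim_to <= min_length)
  n_in <- nrow(ds)
  keep <- rep(TRUE, n_in)
  ambiguous <- drop_ambiguous & grepl("[^ACGT]", ds$sequence)
  keep[ambiguous] <- FALSE
  len <- nchar(ds$sequence)
  too_short <- keep & len < min_length
  keep[too_short] <- FALSE
  too_long <- if (is.null(max_length)) rep(FALSE, n_in) else keep & len > max_length
  keep[too_long] <- FALSE
  out <- ds[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(trim_to)) out$sequence <- substr(out$sequence, 1L, trim_to)
  class(out) <- c("barcode_dataset", "data.frame")
  report <- list(input = n_in, kept = nrow(out),
                 removed = list(ambiguous = sum(ambiguous),
                                too_short = sum(too_short),
                                too_long = sum(too_long)))
  class(report) <- "cleaning_report"
  list(dataset = out, report = report)
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat(sprintf("cleaning: %d -> %d records (ambiguous %d, too short %d, too long %d)\n",
              x$input, x$kept, x$removed$ambiguous, x$removed$too_short,
              x$removed$too_long))
  invisible(x)
}

#' Write a cleaning report as JSON
#' @param report a `cleaning_report`.
#' @param path output path.
#' @export
write_cleaning_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write per-query species assignments as TSV
#'
#' @param rows data frame with columns `accession`, `true_species` (may be
#'   `NA`), `predicted_species`, `status` (one of `"correct"`, `"wrong"`,
#'   `"excluded_singleton"`, `"unlabeled"`).
#' @param path output path.
#' @export
write_assignments <- function(rows, path) {
  needed <- c("accession", "true_species", "predicted_species", "status")
  stopifnot(all(needed %in% names(rows)))
  ok <- rows$status %in% c("correct", "wrong", "excluded_singleton", "unlabeled")
  if (!all(ok)) stop("invalid status value(s): ",
                     paste(unique(rows$status[!ok]), collapse = ", "),
                     call. = FALSE)
  utils::write.table(rows[, needed, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
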