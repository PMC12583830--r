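#' Spearman rank correlation of predicted vs measured variant effects
#'
#' Benchmarks one scorer of a benchmark set against the measured
#' efficiencies, using Spearman's rank correlation with average ranks for
#' ties. Constant predictions or measurements leave the correlation
#' undefined; this is reported explicitly (`rho = NA` with a reason), never
#' silently coerced to 0.
#'
#' @param set Benchmark data frame with columns `variant`, `measured` and
#'   one numeric column per scorer.
#' @param scorer Name of the scorer column to evaluate.
#' @return A list: `rho`, `n`, and `note` (`NA` unless rho is undefined).
#' @export
spearman_eval <- function(set, scorer) {
  set <- validate_benchmark_set(set)
  if (!scorer %in% names(set))
    fs_stop("invalid_table", sprintf("scorer column '%s' not found", scorer))
  ok <- stats::complete.cases(set[[scorer]], set$measured)
  x <- set[[scorer]][ok]; y <- set$measured[ok]
  n <- length(x)
  if (n < 3L)
    fs_stop("invalid_table", "need at least 3 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    return(list(rho = NA_real_, n = n,
                note = "undefined: constant predictions or measurements"))
  }
  list(rho = stats::cor(x, y, method = "spearman"), n = n, note = NA_character_)
}

validate_benchmark_set <- function(set) {
  if (!all(c("variant", "measured") %in% names(set)))
    fs_stop("invalid_table", "benchmark set needs variant and measured columns")
  tibble::as_tibble(set)
}

#' Pooled amino-acid composition of a sequence set
#'
#' Residue frequencies pooled across all sequences (e.g. a homolog set),
#' summing to 1 over the 20 canonical letters. Used to relate a predictor's
#' mutation-class preferences to the composition of natural sequences.
#'
#' @param sequences List of [protein_seq] (or character vector /
#'   `AAStringSet`).
#' @param skip_nonstandard If `TRUE`, non-canonical letters (X, B, Z, U, ...)
#'   are dropped from the tally instead of raising an error.
#' @return Named numeric vector of length 20 (alphabetical order).
#' @export
aa_composition <- function(sequences, skip_nonstandard = FALSE) {
  if (inherits(sequences, "AAStringSet")) sequences <- as.character(sequences)
  if (is.character(sequences)) sequences <- as.list(sequences)
  if (inherits(sequences, "protein_seq")) sequences <- list(sequences)
  if (length(sequences) == 0L) fs_stop("empty_fasta", "no sequences supplied")
  chars <- unlist(strsplit(toupper(vapply(sequences, function(s)
    if (inherits(s, "protein_seq")) s$residues else as.character(s),
    character(1))), "", fixed = TRUE))
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad)) {
    if (!skip_nonstandard)
      fs_stop("nonstandard_residue",
              sprintf("non-canonical letter(s): %s (use skip_nonstandard = TRUE)",
                      paste(bad, collapse = ", ")))
    chars <- chars[chars %in% AA_ALPHABET]
  }
  counts <- table(factor(chars, levels = AA_ALPHABET))
  as.numeric(counts) / sum(counts) -> freq
  stats::setNames(freq, AA_ALPHABET)
}

#' Compare scorers on a benchmark set
#'
#' For every scorer column, reports Spearman's rho against the measured
#' efficiencies, the number of paired observations, and the rank the scorer
#' assigns to the truly best (highest-measured) variant. Rows are sorted by
#' rho descending.
#'
#' @param set Benchmark data frame (`variant`, `measured`, scorer columns).
#' @return A tibble: `scorer`, `rho`, `n`, `best_variant_rank`, `note`.
#' @export
benchmark_report <- function(set) {
  set <- validate_benchmark_set(set)
  scorers <- setdiff(names(set), c("variant", "measured"))
  if (length(scorers) < 1L)
    fs_stop("invalid_table", "benchmark set carries no scorer columns")
  best <- which.max(set$measured)
  rows <- lapply(scorers, function(sc) {
    ev <- spearman_eval(set, sc)
    # rank of the true-best variant in the scorer's descending order
    r <- rank(-set[[sc]], ties.method = "min")[best]
    tibble::tibble(scorer = sc, rho = ev$rho, n = ev$n,
                   best_variant_rank = as.integer(r), note = ev$note)
  })
  out <- dplyr::bind_rows(rows)
  out[order(-out$rho, out$scorer), ]
}

#' Read / write a benchmark set TSV
#'
#' Columns: `variant`, `measured`, then one column per scorer.
#'
#' @param path TSV path.
#' @return A tibble (reader) or `path` (writer).
#' @export
read_benchmark_set <- function(path) {
  validate_benchmark_set(utils::read.table(path, header = TRUE, sep = "\t",
                                           stringsAsFactors = FALSE))
}

#' @rdname read_benchmark_set
#' @param set Benchmark tibble.
#' @export
write_benchmark_set <- function(set, path) {
  utils::write.table(as.data.frame(validate_benchmark_set(set)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
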