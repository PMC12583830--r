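#' Per-position amino-acid log-probability matrix
#'
#' The interface to an upstream variant-effect predictor: an L x 20 matrix of
#' log-probabilities, row `t` giving the predicted distribution over the 20
#' canonical amino acids at position `t` of the background sequence
#' (columns in alphabetical order, see [AA_ALPHABET]). Each row must be a
#' normalized log-probability vector (`sum(exp(row)) == 1` within `tol`)
#' unless `renormalize = TRUE`, in which case arbitrary finite log-scores
#' (e.g. logits) are accepted and log-softmaxed row-wise.
#'
#' @param logp Numeric L x 20 matrix of log-probabilities.
#' @param background A [protein_seq] of length L: the sequence the predictor
#'   was conditioned on.
#' @param provenance Free-text note naming the upstream predictor.
#' @param renormalize If `TRUE`, rows are renormalized (log-softmax) instead
#'   of being required to already be normalized.
#' @param tol Tolerance on `|sum(exp(row)) - 1|`.
#' @return An object of class `fitness_matrix` with fields `background`,
#'   `logp`, `provenance`.
#' @export
fitness_matrix <- function(logp, background, provenance = "",
                           renormalize = FALSE, tol = 1e-6) {
  stopifnot(inherits(background, "protein_seq"))
  logp <- as.matrix(logp)
  if (ncol(logp) != 20L)
    fs_stop("matrix_shape", sprintf("fitness matrix must have 20 columns, got %d",
                                    ncol(logp)))
  if (nrow(logp) != background$length)
    fs_stop("matrix_shape",
            sprintf("matrix has %d rows but background '%s' has %d residues",
                    nrow(logp), background$id, background$length))
  if (!all(is.finite(logp)))
    fs_stop("matrix_nonfinite", "fitness matrix entries must all be finite")
  if (!is.null(colnames(logp)) && !identical(colnames(logp), AA_ALPHABET))
    logp <- logp[, AA_ALPHABET, drop = FALSE]
  colnames(logp) <- AA_ALPHABET
  rownames(logp) <- NULL
  if (renormalize) {
    logp <- log_softmax_rows(logp)
  } else {
    rs <- rowSums(exp(logp))
    off <- abs(rs - 1) > tol
    if (any(off))
      fs_stop("matrix_unnormalized",
              sprintf(paste0("row(s) %s do not exponentiate to probability 1 ",
                             "(use renormalize = TRUE for raw log-scores)"),
                      paste(utils::head(which(off), 5L), collapse = ", ")))
  }
  structure(list(background = background, logp = logp,
                 provenance = as.character(provenance)),
            class = "fitness_matrix")
}

log_softmax_rows <- function(m) {
  mx <- apply(m, 1L, max)
  sh <- m - mx
  sh - log(rowSums(exp(sh)))
}

#' @export
print.fitness_matrix <- function(x, ...) {
  cat(sprintf("<fitness_matrix> %d x 20 over background '%s'%s\n",
              nrow(x$logp), x$background$id,
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

#' @export
dim.fitness_matrix <- function(x) dim(x$logp)

#' Read a fitness matrix from TSV
#'
#' Expected dialect: a header row `pos res A C D ... Y`, then one row per
#' position carrying the 1-based position, the background residue and the 20
#' log-probabilities in alphabetical column order.
#'
#' @param path TSV file path.
#' @param id Sequence id for the reconstructed background.
#' @param renormalize,tol Passed to [fitness_matrix()].
#' @return A [fitness_matrix].
#' @export
read_fitness_matrix <- function(path, id = NULL, renormalize = FALSE,
                                tol = 1e-6) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("pos", "res", AA_ALPHABET)
  if (!all(need %in% names(df)))
    fs_stop("matrix_format",
            sprintf("matrix TSV must carry columns: %s", paste(need, collapse = " ")))
  df <- df[order(df$pos), ]
  if (!identical(as.integer(df$pos), seq_len(nrow(df))))
    fs_stop("matrix_format", "matrix TSV positions must be exactly 1..L")
  bg <- protein_seq(paste(df$res, collapse = ""),
                    id = id %||% sub("\\.[^.]*$", "", basename(path)))
  fitness_matrix(as.matrix(df[, AA_ALPHABET]), bg,
                 provenance = sprintf("read from %s", basename(path)),
                 renormalize = renormalize, tol = tol)
}

#' Write a fitness matrix to TSV
#'
#' @param m A [fitness_matrix].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fitness_matrix <- function(m, path) {
  df <- data.frame(pos = seq_len(nrow(m$logp)),
                   res = strsplit(m$background$residues, "", fixed = TRUE)[[1]],
                   m$logp, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
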