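#' Protein sequence with 1-based residue coordinates
#'
#' Lightweight container for a reference amino-acid sequence. All mutational
#' coordinates in the package are 1-based indices into this sequence, matching
#' the conventional mutant notation (e.g. `G1218R` means the glycine at
#' residue 1218).
#'
#' @param residues Character scalar over the 20-letter canonical amino-acid
#'   alphabet (see [AA_ALPHABET]). Lower case is accepted and upper-cased.
#' @param id Text label for the sequence.
#' @return An object of class `protein_seq` with fields `id`, `residues` and
#'   `length`.
#' @examples
#' ps <- protein_seq("MKRISTTITTTITITTGNGAG", id = "toy")
#' ps$length
#' @export
protein_seq <- function(residues, id = "seq") {
  if (inherits(residues, "AAString") || inherits(residues, "AAStringSet")) {
    residues <- as.character(residues)[1]
  }
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(gsub("\\s", "", residues))
  if (nchar(residues) < 1L)
    fs_stop("empty_sequence", "protein sequence must contain at least one residue")
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), AA_ALPHABET)
  if (length(bad))
    fs_stop("nonstandard_residue",
            sprintf("non-canonical residue letter(s) in '%s': %s",
                    id, paste(bad, collapse = ", ")))
  structure(list(id = as.character(id), residues = residues,
                 length = nchar(residues)),
            class = "protein_seq")
}

#' @export
print.protein_seq <- function(x, ...) {
  head <- substr(x$residues, 1, 40)
  tail <- if (x$length > 40) "..." else ""
  cat(sprintf("<protein_seq> %s (%d aa)\n  %s%s\n", x$id, x$length, head, tail))
  invisible(x)
}

#' @export
length.protein_seq <- function(x) x$length

# residue letter(s) at 1-based positions
residue_at <- function(ps, pos) {
  substring(ps$residues, pos, pos)
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A list of [protein_seq] objects, one per record.
#' @export
read_fasta_protein <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L)
    fs_stop("empty_fasta", sprintf("no sequences in '%s'", path))
  lapply(seq_along(set), function(i) {
    protein_seq(as.character(set[[i]]), id = names(set)[i])
  })
}

#' Write protein sequences to a FASTA file
#'
#' @param x A [protein_seq] or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_protein <- function(x, path) {
  if (inherits(x, "protein_seq")) x <- list(x)
  set <- Biostrings::AAStringSet(vapply(x, function(p) p$residues, character(1)))
  names(set) <- vapply(x, function(p) p$id, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
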