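#' Construct a variant (set of single-residue substitutions)
#'
#' A variant is an ordered set of substitutions, at most one per position;
#' the empty set denotes the wild type. Substitutions are stored sorted by
#' position.
#'
#' @param wt Character vector of wild-type residue letters.
#' @param pos Integer vector of 1-based residue positions.
#' @param mt Character vector of mutant residue letters.
#' @return An object of class `variant`: a data frame with columns
#'   `wt`, `pos`, `mt`.
#' @examples
#' variant("G", 1218, "R")
#' variant()  # wild type
#' @export
variant <- function(wt = character(), pos = integer(), mt = character()) {
  stopifnot(length(wt) == length(pos), length(mt) == length(pos))
  wt <- toupper(as.character(wt)); mt <- toupper(as.character(mt))
  pos <- as.integer(pos)
  bad <- setdiff(unique(c(wt, mt)), AA_ALPHABET)
  if (length(bad))
    fs_stop("nonstandard_residue",
            sprintf("non-canonical residue letter(s): %s", paste(bad, collapse = ", ")))
  if (any(pos < 1L))
    fs_stop("position_out_of_range", "positions must be >= 1")
  if (any(wt == mt))
    fs_stop("synonymous_substitution",
            "wild-type and mutant letters must differ in every substitution")
  if (anyDuplicated(pos))
    fs_stop("duplicate_position",
            sprintf("duplicate substitution position(s): %s",
                    paste(unique(pos[duplicated(pos)]), collapse = ", ")))
  ord <- order(pos)
  structure(data.frame(wt = wt[ord], pos = pos[ord], mt = mt[ord],
                       stringsAsFactors = FALSE),
            class = c("variant", "data.frame"))
}

#' @export
print.variant <- function(x, ...) {
  cat(sprintf("<variant> %s\n",
              if (nrow(x) == 0L) "(wild type)" else format_variant(x)))
  invisible(x)
}

#' Number of substitutions in a variant
#' @param v A [variant].
#' @return Integer count (0 for wild type).
#' @export
n_substitutions <- function(v) nrow(v)

#' Parse mutant notation into a variant
#'
#' Parses strings such as `"C80K; G1218R; T622W"` — semicolon- or
#' comma-separated tokens of the form `<WT><position><MT>` with optional
#' whitespace. An empty string denotes the wild type.
#'
#' @param spec Character scalar of substitution tokens, or `""`.
#' @param reference Optional [protein_seq]; when supplied, each token's
#'   wild-type letter must agree with the reference at its position and the
#'   position must be within range.
#' @return A [variant].
#' @examples
#' parse_variant("C80K; G1218R; T622W")
#' @export
parse_variant <- function(spec, reference = NULL) {
  stopifnot(is.character(spec), length(spec) == 1L)
  spec <- trimws(spec)
  if (!nzchar(spec)) {
    v <- variant()
  } else {
    tokens <- trimws(strsplit(spec, "[;,]")[[1]])
    tokens <- tokens[nzchar(tokens)]
    m <- regmatches(tokens, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", tokens))
    bad <- tokens[vapply(m, length, integer(1)) != 4L]
    if (length(bad))
      fs_stop("malformed_token",
              sprintf("malformed substitution token(s): %s",
                      paste(sQuote(bad), collapse = ", ")))
    v <- variant(wt = vapply(m, `[`, character(1), 2L),
                 pos = as.integer(vapply(m, `[`, character(1), 3L)),
                 mt = vapply(m, `[`, character(1), 4L))
  }
  if (!is.null(reference)) validate_variant(v, reference)
  v
}

#' Format a variant as mutant notation
#'
#' Inverse of [parse_variant()]: substitutions are emitted sorted by position
#' and joined with `"; "`. The wild type formats as `""`.
#'
#' @param v A [variant].
#' @param collapse Separator between tokens.
#' @return Character scalar.
#' @export
format_variant <- function(v, collapse = "; ") {
  if (nrow(v) == 0L) return("")
  paste0(v$wt, v$pos, v$mt, collapse = collapse)
}

#' Validate a variant against a reference sequence
#'
#' @param v A [variant].
#' @param reference A [protein_seq].
#' @return `v`, invisibly, if valid; otherwise a classed error.
#' @export
validate_variant <- function(v, reference) {
  stopifnot(inherits(v, "variant"), inherits(reference, "protein_seq"))
  if (nrow(v) == 0L) return(invisible(v))
  out <- v$pos > reference$length
  if (any(out))
    fs_stop("position_out_of_range",
            sprintf("position(s) beyond sequence '%s' (L=%d): %s",
                    reference$id, reference$length,
                    paste(v$pos[out], collapse = ", ")))
  ref_aa <- residue_at(reference, v$pos)
  mism <- ref_aa != v$wt
  if (any(mism))
    fs_stop("wt_mismatch",
            sprintf("wild-type letter disagrees with reference at: %s",
                    paste(sprintf("%s%d (reference has %s)",
                                  v$wt[mism], v$pos[mism], ref_aa[mism]),
                          collapse = ", ")))
  invisible(v)
}

#' Apply a variant to a reference sequence
#'
#' @param reference A [protein_seq].
#' @param v A [variant], validated against `reference`.
#' @param id Label for the mutated sequence; default appends the variant
#'   string to the reference id.
#' @return A [protein_seq] differing from `reference` exactly at `v`'s
#'   positions.
#' @export
apply_variant <- function(reference, v, id = NULL) {
  validate_variant(v, reference)
  chars <- strsplit(reference$residues, "", fixed = TRUE)[[1]]
  chars[v$pos] <- v$mt
  if (is.null(id)) {
    id <- if (nrow(v) == 0L) reference$id else
      paste0(reference$id, "|", format_variant(v, collapse = ";"))
  }
  protein_seq(paste(chars, collapse = ""), id = id)
}

#' Invert a variant
#'
#' Swaps wild-type and mutant letters, giving the variant that undoes `v`
#' when applied to the mutated sequence.
#'
#' @param v A [variant].
#' @return A [variant].
#' @export
invert_variant <- function(v) {
  variant(wt = v$mt, pos = v$pos, mt = v$wt)
}

# Construct a variant from components already known to be valid and sorted
# by position (library enumeration hot path; skips all validation).
variant_unsafe <- function(wt, pos, mt) {
  structure(list(wt = wt, pos = pos, mt = mt),
            class = c("variant", "data.frame"),
            row.names = seq_along(pos))
}

# Deterministic tie-break key: position (zero-padded) then mutant letter.
variant_tie_key <- function(pos_list, mt_list) {
  mapply(function(p, m) {
    o <- order(p)
    paste0(sprintf("%06d%s", p[o], m[o]), collapse = "")
  }, pos_list, mt_list, USE.NAMES = FALSE)
}
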