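#' Amplicon and protospacer annotation for outcome quantification
#'
#' Describes one sequenced amplicon: the reference sequence, where the
#' 20-nt protospacer sits in it, and on which strand. Protospacer positions
#' are numbered 1-20 from the 5' end of the protospacer with the PAM
#' 3'-adjacent, matching editing-window figure axes. The indel
#' quantification window defaults to the protospacer extended by 10 nt on
#' each side (clipped to the amplicon).
#'
#' @param amplicon Reference amplicon sequence (character or `DNAString`).
#' @param protospacer_start 1-based offset of the protospacer's first base
#'   in the amplicon (for strand `"-"` this is still the leftmost amplicon
#'   coordinate of the protospacer-matching region).
#' @param strand `"+"` if the protospacer reads forward along the amplicon,
#'   `"-"` if it is the reverse complement of the amplicon region.
#' @param protospacer_length Protospacer length in nt (default 20).
#' @param quant_window Optional integer pair: amplicon coordinates of the
#'   indel-calling window.
#' @return An object of class `amplicon_spec`.
#' @export
amplicon_spec <- function(amplicon, protospacer_start, strand = "+",
                          protospacer_length = 20L, quant_window = NULL) {
  if (inherits(amplicon, "DNAString")) amplicon <- as.character(amplicon)
  stopifnot(is.character(amplicon), length(amplicon) == 1L)
  amplicon <- toupper(amplicon)
  if (!grepl("^[ACGT]+$", amplicon))
    fs_stop("invalid_amplicon", "amplicon must be an unambiguous ACGT sequence")
  strand <- match.arg(strand, c("+", "-"))
  ps <- as.integer(protospacer_start)
  plen <- as.integer(protospacer_length)
  alen <- nchar(amplicon)
  if (ps < 1L || ps + plen - 1L > alen)
    fs_stop("invalid_amplicon", "protospacer does not fit inside the amplicon")
  if (is.null(quant_window)) {
    quant_window <- c(max(1L, ps - 10L), min(alen, ps + plen - 1L + 10L))
  }
  quant_window <- as.integer(quant_window)
  stopifnot(length(quant_window) == 2L, quant_window[1] <= quant_window[2])
  region <- substr(amplicon, ps, ps + plen - 1L)
  protospacer <- if (strand == "+") region else revcomp(region)
  structure(list(amplicon = amplicon, protospacer_start = ps,
                 strand = strand, protospacer_length = plen,
                 quant_window = quant_window, protospacer = protospacer),
            class = "amplicon_spec")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# amplicon coordinate of protospacer position j (1..plen)
protospacer_coord <- function(spec, j) {
  if (spec$strand == "+") spec$protospacer_start + j - 1L
  else spec$protospacer_start + spec$protospacer_length - j
}

#' Read amplicon reads from FASTQ
#'
#' @param path FASTQ file (pre-merged, single orientation).
#' @return A `DNAStringSet`.
#' @export
read_fastq_reads <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}

#' Write reads to FASTQ (constant quality)
#'
#' @param reads A `DNAStringSet` (or character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq_reads <- function(reads, path) {
  if (!inherits(reads, "DNAStringSet")) reads <- Biostrings::DNAStringSet(reads)
  if (is.null(names(reads))) names(reads) <- paste0("read_", seq_along(reads))
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Quantify base-editing outcomes in an amplicon read set
#'
#' Each read is globally aligned to the amplicon reference under unit
#' mismatch/gap costs. Reads whose alignment places a gap inside the
#' quantification window are classified as indel reads and excluded from
#' substitution calls; gap-free reads contribute one base call per
#' protospacer position (strand-resolved: for a minus-strand protospacer the
#' tallies are complemented and reported 5'-to-3' along the protospacer).
#' Reads shorter than `min_read_frac` of the amplicon are discarded as
#' unalignable; reads with gaps only outside the window are excluded from
#' both tallies and counted separately.
#'
#' Quantification is fully deterministic: no random numbers are drawn.
#'
#' @param reads `DNAStringSet`, character vector, or FASTQ path.
#' @param spec An [amplicon_spec].
#' @param edit_from Reference base whose conversion is quantified on the
#'   protospacer strand (default `"C"`, the cytosine-base-editor substrate).
#' @param edit_to Alternative bases to report conversion percentages for.
#' @param min_read_frac Discard reads shorter than this fraction of the
#'   amplicon length.
#' @return An object of class `editing_result`: counts (`n_reads_total`,
#'   `n_reads_aligned`, `n_reads_indel`, `n_reads_eligible`,
#'   `n_reads_gapped_outside`, `n_reads_discarded`), `indel_pct`,
#'   `base_counts` (4 x protospacer-length matrix of A/C/G/T calls in
#'   protospacer frame), and `per_position`: a tibble with one row per
#'   protospacer position carrying the reference base and the conversion
#'   percentage for each `edit_to` base (NA where the reference base is not
#'   `edit_from`).
#' @export
quantify_reads <- function(reads, spec, edit_from = "C",
                           edit_to = c("T", "G", "A"), min_read_frac = 0.5) {
  stopifnot(inherits(spec, "amplicon_spec"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq_reads(reads)
  if (!inherits(reads, "DNAStringSet")) reads <- Biostrings::DNAStringSet(reads)
  n_total <- length(reads)
  if (n_total == 0L) fs_stop("empty_reads", "no reads to quantify")
  edit_from <- match.arg(edit_from, DNA_BASES)
  edit_to <- match.arg(edit_to, DNA_BASES, several.ok = TRUE)

  alen <- nchar(spec$amplicon)
  keep <- Biostrings::width(reads) >= min_read_frac * alen
  n_discarded <- sum(!keep)
  reads <- reads[keep]
  n_aligned <- length(reads)
  if (n_aligned == 0L)
    fs_stop("empty_reads", "every read was too short to align")

  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 0, mismatch = -1,
                                                     baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(reads, spec$amplicon,
                                       substitutionMatrix = submat,
                                       gapOpening = 0, gapExtension = 1,
                                       type = "global")
  indels <- Biostrings::indel(aln)
  ins_rng <- as.list(indels@insertion)   # read coordinates
  del_rng <- as.list(indels@deletion)    # amplicon coordinates
  gapped <- lengths(ins_rng) + lengths(del_rng) > 0L

  w1 <- spec$quant_window[1]; w2 <- spec$quant_window[2]
  indel_in_window <- rep(FALSE, n_aligned)
  for (i in which(gapped)) {
    indel_in_window[i] <- gaps_overlap_window(ins_rng[[i]], del_rng[[i]], w1, w2)
  }
  n_indel <- sum(indel_in_window)
  n_gapped_outside <- sum(gapped & !indel_in_window)
  eligible <- !gapped
  n_eligible <- sum(eligible)

  plen <- spec$protospacer_length
  ps1 <- spec$protospacer_start; ps2 <- ps1 + plen - 1L
  base_counts <- matrix(0L, nrow = 4L, ncol = plen,
                        dimnames = list(DNA_BASES, NULL))
  if (n_eligible > 0L) {
    # gap-free global alignment => read length equals amplicon length
    win <- Biostrings::subseq(reads[eligible], ps1, ps2)
    cm <- Biostrings::consensusMatrix(win)
    present <- intersect(rownames(cm), DNA_BASES)
    base_counts[present, ] <- cm[present, , drop = FALSE]
  }
  if (spec$strand == "-") {
    base_counts <- base_counts[c("T", "G", "C", "A"), plen:1, drop = FALSE]
    rownames(base_counts) <- DNA_BASES
  }
  colnames(base_counts) <- as.character(seq_len(plen))

  ref_bases <- strsplit(spec$protospacer, "")[[1]]
  per_position <- tibble::tibble(position = seq_len(plen), ref = ref_bases)
  for (b in edit_to) {
    pct <- ifelse(ref_bases == edit_from & n_eligible > 0L,
                  100 * base_counts[b, ] / n_eligible, NA_real_)
    per_position[[paste0("pct_", edit_from, "_to_", b)]] <- as.numeric(pct)
  }

  structure(list(
    n_reads_total = n_total,
    n_reads_aligned = n_aligned,
    n_reads_indel = n_indel,
    n_reads_eligible = n_eligible,
    n_reads_gapped_outside = n_gapped_outside,
    n_reads_discarded = n_discarded,
    indel_pct = 100 * n_indel / n_aligned,
    base_counts = base_counts,
    per_position = per_position,
    edit_from = edit_from,
    edit_to = edit_to,
    spec = spec
  ), class = "editing_result")
}

# Does any alignment gap overlap the window [w1, w2] in amplicon
# coordinates? Deletions arrive in amplicon coordinates; insertions arrive
# in read coordinates and are mapped to their amplicon anchor by walking the
# read's gap events in alignment order (an insertion between amplicon
# positions c and c+1 overlaps the window if c is in [w1 - 1, w2]).
gaps_overlap_window <- function(ins, del, w1, w2) {
  ds <- BiocGenerics::start(del); de <- BiocGenerics::end(del)
  if (length(ds) && any(ds <= w2 & de >= w1)) return(TRUE)
  ps <- BiocGenerics::start(ins); pe <- BiocGenerics::end(ins)
  if (!length(ps)) return(FALSE)
  shift <- 0L   # amplicon coordinate minus read coordinate
  di <- 1L; ii <- 1L
  while (ii <= length(ps)) {
    # next deletion (in read frame) vs next insertion, in alignment order
    if (di <= length(ds) && (ds[di] - shift) < ps[ii]) {
      shift <- shift + (de[di] - ds[di] + 1L)
      di <- di + 1L
    } else {
      anchor <- ps[ii] - 1L + shift
      if (anchor >= w1 - 1L && anchor <= w2) return(TRUE)
      shift <- shift - (pe[ii] - ps[ii] + 1L)
      ii <- ii + 1L
    }
  }
  FALSE
}

#' @export
print.editing_result <- function(x, ...) {
  cat(sprintf(paste0("<editing_result> %d reads: %d aligned, %d eligible, ",
                     "%d indel (%.2f%%), %d gapped outside window, %d discarded\n"),
              x$n_reads_total, x$n_reads_aligned, x$n_reads_eligible,
              x$n_reads_indel, x$indel_pct, x$n_reads_gapped_outside,
              x$n_reads_discarded))
  invisible(x)
}

#' Product purity at a protospacer position
#'
#' Among reads converted away from the reference base at one protospacer
#' position, the fraction carrying each alternative base (e.g. C-to-T vs
#' C-to-G vs C-to-A for a CBE/CGBE). Fractions sum to 1.
#'
#' @param result An [quantify_reads()] result.
#' @param position Protospacer position (1-based).
#' @return Named numeric vector of fractions over the three alternative
#'   bases.
#' @export
product_purity <- function(result, position) {
  stopifnot(inherits(result, "editing_result"))
  plen <- ncol(result$base_counts)
  if (position < 1L || position > plen)
    fs_stop("invalid_position", sprintf("position must be in 1..%d", plen))
  ref <- result$per_position$ref[position]
  alts <- setdiff(DNA_BASES, ref)
  counts <- result$base_counts[alts, position]
  total <- sum(counts)
  if (total == 0L)
    fs_stop("no_converted_reads",
            sprintf("no converted reads at protospacer position %d", position))
  counts / total
}

#' Editing-window profile across sites
#'
#' Position-wise mean conversion percentage over a set of quantified sites,
#' the quantity behind "average conversion at protospacer positions 1-20"
#' summaries. A position at a site whose protospacer lacks the editable
#' reference base there is excluded from that position's mean (the
#' denominator is tracked per position).
#'
#' @param results List of [quantify_reads()] results (optionally named by
#'   site).
#' @param to_base Conversion product to profile (default: first `edit_to`
#'   base of the first result, e.g. T for a CBE).
#' @return A tibble: `position`, `mean_pct`, `n_sites` (positions with
#'   `n_sites = 0` carry `mean_pct = NA`).
#' @export
window_profile <- function(results, to_base = NULL) {
  if (inherits(results, "editing_result")) results <- list(results)
  if (length(results) < 1L) fs_stop("empty_reads", "no sites supplied")
  stopifnot(all(vapply(results, inherits, logical(1), "editing_result")))
  to_base <- to_base %||% results[[1]]$edit_to[1]
  col <- paste0("pct_", results[[1]]$edit_from, "_to_", to_base)
  plen <- nrow(results[[1]]$per_position)
  mat <- vapply(results, function(r) {
    if (!col %in% names(r$per_position))
      fs_stop("invalid_library", sprintf("result lacks column %s", col))
    r$per_position[[col]]
  }, numeric(plen))
  mat <- matrix(mat, nrow = plen)
  n_sites <- rowSums(!is.na(mat))
  mean_pct <- ifelse(n_sites > 0, rowMeans(mat, na.rm = TRUE), NA_real_)
  tibble::tibble(position = seq_len(plen), mean_pct = mean_pct,
                 n_sites = as.integer(n_sites))
}

#' Write per-position conversion percentages to TSV
#'
#' Percentages are emitted with 2 decimal places.
#'
#' @param result An [quantify_reads()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_editing_tsv <- function(result, path) {
  df <- as.data.frame(result$per_position)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "position"
  df[num] <- lapply(df[num], function(x) ifelse(is.na(x), NA, sprintf("%.2f", x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
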