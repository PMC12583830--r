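#' Additive log-probability fitness score of a variant
#'
#' For a variant with substitution set T, the fitness score is
#' \deqn{\sum_{t \in T} \log p(x_t = mt_t) - \log p(x_t = wt_t)}
#' under the per-position distributions of the fitness matrix, in nats.
#' The empty (wild-type) variant scores exactly 0, and the score is additive
#' over disjoint substitution sets.
#'
#' @param m A [fitness_matrix].
#' @param v A [variant], valid against `m$background`.
#' @return Numeric scalar (nats).
#' @examples
#' bg <- protein_seq("ACD")
#' lp <- matrix(log(1/20), 3, 20, dimnames = list(NULL, AA_ALPHABET))
#' m <- fitness_matrix(lp, bg)
#' fitness_score(m, parse_variant("C2K", bg))  # 0: uniform rows
#' @export
fitness_score <- function(m, v) {
  stopifnot(inherits(m, "fitness_matrix"), inherits(v, "variant"))
  validate_variant(v, m$background)
  if (nrow(v) == 0L) return(0)
  mt_i <- match(v$mt, AA_ALPHABET)
  wt_i <- match(v$wt, AA_ALPHABET)
  sum(m$logp[cbind(v$pos, mt_i)] - m$logp[cbind(v$pos, wt_i)])
}

#' Size of a k-site saturation mutagenesis library
#'
#' Number of variants obtained by choosing `k` of the `L - n_fixed` mutable
#' positions and substituting each with one of the 19 alternative amino
#' acids: `choose(L - n_fixed, k) * 19^k`. Exact whenever the value is below
#' 2^53 (which covers the three-site Cas9 library of ~2.9e12).
#'
#' @param L Sequence length.
#' @param k Number of mutated sites (`k = 0` counts only the wild type).
#' @param n_fixed Number of positions excluded from mutation.
#' @return Numeric count.
#' @examples
#' saturation_library_size(1368, 1)      # 25992 single mutants
#' saturation_library_size(1368, 3, 5)   # the three-site combination library
#' @export
saturation_library_size <- function(L, k, n_fixed = 0) {
  L <- as.numeric(L); k <- as.numeric(k); n_fixed <- as.numeric(n_fixed)
  if (k < 0 || n_fixed < 0 || n_fixed > L)
    fs_stop("invalid_scope", "require k >= 0 and 0 <= n_fixed <= L")
  if (k > L - n_fixed)
    fs_stop("invalid_scope",
            sprintf("k = %g exceeds the %g mutable positions", k, L - n_fixed))
  choose(L - n_fixed, k) * 19^k
}

#' Stream the variants of a saturation mutagenesis library
#'
#' Returns an iterator (a zero-argument function) that yields each variant of
#' the k-site saturation library over `reference` exactly once, then `NULL`.
#' The library is never materialized, so the full single-point scan of a
#' Cas9-sized protein streams in constant memory.
#'
#' @param reference A [protein_seq].
#' @param k Number of simultaneously mutated sites.
#' @param fixed Integer vector of positions excluded from mutation.
#' @return A function; each call returns the next [variant] or `NULL` when
#'   exhausted.
#' @examples
#' it <- enumerate_saturation(protein_seq("AC"), k = 1)
#' it(); it()
#' @export
enumerate_saturation <- function(reference, k, fixed = integer()) {
  stopifnot(inherits(reference, "protein_seq"))
  fixed <- as.integer(fixed)
  if (length(fixed) && (any(fixed < 1L) || any(fixed > reference$length)))
    fs_stop("invalid_scope", "fixed positions outside the reference sequence")
  positions <- setdiff(seq_len(reference$length), fixed)
  P <- length(positions)
  k <- as.integer(k)
  if (k < 0L || k > P)
    fs_stop("invalid_scope", sprintf("k = %d exceeds the %d mutable positions", k, P))
  ref_chars <- strsplit(reference$residues, "", fixed = TRUE)[[1]]

  if (k == 0L) {
    done <- FALSE
    return(function() {
      if (done) return(NULL)
      done <<- TRUE
      variant()
    })
  }

  comb <- seq_len(k)        # indices into `positions`, strictly increasing
  odo <- rep(1L, k)         # per-site index into the 19 alternative letters
  exhausted <- FALSE
  alt <- lapply(positions, function(p) setdiff(AA_ALPHABET, ref_chars[p]))

  advance_comb <- function() {
    # next k-combination of 1..P in lexicographic order; FALSE when done
    i <- k
    while (i >= 1L && comb[i] == P - k + i) i <- i - 1L
    if (i < 1L) return(FALSE)
    comb[i] <<- comb[i] + 1L
    if (i < k) comb[(i + 1L):k] <<- comb[i] + seq_len(k - i)
    TRUE
  }

  function() {
    if (exhausted) return(NULL)
    pos <- positions[comb]
    mt <- character(k)
    for (j in seq_len(k)) mt[j] <- alt[[comb[j]]][odo[j]]
    v <- variant_unsafe(ref_chars[pos], pos, mt)
    # advance the mutant-letter odometer, then the position combination
    j <- k
    while (j >= 1L && odo[j] == 19L) { odo[j] <- 1L; j <- j - 1L }
    if (j >= 1L) {
      odo[j] <- odo[j] + 1L
    } else if (!advance_comb()) {
      exhausted <<- TRUE
    }
    odo <<- odo; exhausted <<- exhausted
    v
  }
}

#' Score every single mutant of the background sequence
#'
#' Vectorized single-point saturation scan: every position not in `fixed`
#' substituted by each of the 19 alternative amino acids, scored by
#' [fitness_score()] semantics directly off the matrix.
#'
#' @param m A [fitness_matrix].
#' @param fixed Integer vector of positions to exclude.
#' @return A tibble with columns `variant`, `pos`, `wt`, `mt`, `raw_score`,
#'   one row per single mutant (unranked; see [rank_and_normalize()]).
#' @export
scan_single_mutants <- function(m, fixed = integer()) {
  stopifnot(inherits(m, "fitness_matrix"))
  L <- nrow(m$logp)
  positions <- setdiff(seq_len(L), as.integer(fixed))
  ref_chars <- strsplit(m$background$residues, "", fixed = TRUE)[[1]]
  wt_i <- match(ref_chars, AA_ALPHABET)
  # gains for all 20 letters, then drop the synonymous diagonal
  gains <- m$logp[positions, , drop = FALSE] -
    m$logp[cbind(positions, wt_i[positions])]
  pos_rep <- rep(positions, each = 20L)
  mt_rep <- rep(AA_ALPHABET, times = length(positions))
  keep <- mt_rep != ref_chars[pos_rep]
  tibble::tibble(
    variant = paste0(ref_chars[pos_rep[keep]], pos_rep[keep], mt_rep[keep]),
    pos = pos_rep[keep],
    wt = ref_chars[pos_rep[keep]],
    mt = mt_rep[keep],
    raw_score = as.vector(t(gains))[keep]
  )
}

#' Rank a variant library and min-max normalize its scores
#'
#' Sorts by raw score descending with a deterministic tie-break (position
#' ascending, then mutant letter alphabetical), assigns ranks 1..N, and adds
#' `normalized_score = (raw - min) / (max - min)` (defined as 1.0 for every
#' entry when all scores are equal).
#'
#' @param x Either a data frame with a `raw_score` column (e.g. from
#'   [scan_single_mutants()]), or a list of [variant]s (scored against `m`).
#' @param m A [fitness_matrix]; required when `x` is a list of variants.
#' @return A `ranked_library`: a tibble sorted by rank with columns
#'   `variant`, `raw_score`, `normalized_score`, `rank` (plus any columns of
#'   the input).
#' @export
rank_and_normalize <- function(x, m = NULL) {
  if (is.data.frame(x)) {
    if (!"raw_score" %in% names(x))
      fs_stop("invalid_library", "input data frame must carry a raw_score column")
    lib <- tibble::as_tibble(x)
    if (!"variant" %in% names(lib)) {
      if (!all(c("wt", "pos", "mt") %in% names(lib)))
        fs_stop("invalid_library", "need a variant column or wt/pos/mt columns")
      lib$variant <- paste0(lib$wt, lib$pos, lib$mt)
    }
  } else if (is.list(x)) {
    if (is.null(m))
      fs_stop("invalid_library", "a fitness_matrix is required to score variants")
    if (length(x) == 0L)
      fs_stop("invalid_library", "no variants supplied")
    lib <- tibble::tibble(
      variant = vapply(x, format_variant, character(1), collapse = ";"),
      raw_score = vapply(x, function(v) fitness_score(m, v), numeric(1))
    )
    singles <- all(vapply(x, nrow, integer(1)) == 1L)
    if (singles) {
      lib$pos <- vapply(x, function(v) v$pos[1], integer(1))
      lib$wt <- vapply(x, function(v) v$wt[1], character(1))
      lib$mt <- vapply(x, function(v) v$mt[1], character(1))
    }
  } else {
    fs_stop("invalid_library", "x must be a data frame or a list of variants")
  }
  if (nrow(lib) == 0L) fs_stop("invalid_library", "empty library")
  if (anyDuplicated(lib$variant))
    fs_stop("invalid_library", "duplicate variants in library")

  key <- if (all(c("pos", "mt") %in% names(lib))) {
    sprintf("%06d%s", lib$pos, lib$mt)
  } else {
    variant_tie_key(
      lapply(strsplit(lib$variant, "[;,] *"), function(tk)
        as.integer(gsub("[^0-9]", "", tk))),
      lapply(strsplit(lib$variant, "[;,] *"), function(tk)
        sub("^.*[0-9]", "", tk)))
  }
  ord <- order(-lib$raw_score, key)
  lib <- lib[ord, ]
  rng <- range(lib$raw_score)
  lib$normalized_score <- if (rng[1] == rng[2]) rep(1, nrow(lib)) else
    (lib$raw_score - rng[1]) / (rng[2] - rng[1])
  lib$rank <- seq_len(nrow(lib))
  class(lib) <- c("ranked_library", class(lib))
  lib
}

#' Write / read a ranked library TSV
#'
#' Columns: `variant`, `raw_score`, `normalized_score`, `rank`, plus any
#' single-mutant annotation columns present.
#'
#' @param lib A ranked library tibble.
#' @param path File path.
#' @return `path` (writer) or the tibble (reader).
#' @export
write_ranked_library <- function(lib, path) {
  utils::write.table(as.data.frame(lib), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_library
#' @export
read_ranked_library <- function(path) {
  lib <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                             stringsAsFactors = FALSE))
  class(lib) <- c("ranked_library", class(lib))
  lib
}
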