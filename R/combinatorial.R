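#' Size of a k-new-site combination library
#'
#' Convenience wrapper around [saturation_library_size()] phrased for the
#' combination-design stage: `n_fixed` background positions are excluded and
#' `k` new sites are saturated, giving `choose(L - n_fixed, k) * 19^k`
#' variants.
#'
#' @param L Background sequence length.
#' @param n_fixed Number of background (excluded) positions.
#' @param k Number of new sites.
#' @return Numeric count (exact below 2^53).
#' @examples
#' combo_library_size(1368, 5, 3)  # ~2.9e12 three-site library over Cas9-AI-5
#' @export
combo_library_size <- function(L, n_fixed, k) {
  saturation_library_size(L, k, n_fixed)
}

#' Background sequence for a follow-up predictor call
#'
#' Additive multi-site design conditions the predictor on the mutated
#' background (e.g. the five-mutation Cas9-AI-5 sequence): this helper emits
#' that sequence so an upstream predictor can supply a fresh fitness matrix
#' for it. The predictor call itself is outside this package.
#'
#' @param reference A [protein_seq].
#' @param background A [variant] (possibly empty).
#' @return A [protein_seq] carrying the background substitutions.
#' @export
make_background_matrix_request <- function(reference, background) {
  apply_variant(reference, background)
}

# Per-position substitution gains off a fitness matrix, each position's 19
# alternatives sorted by (gain desc, mt alphabetical).
position_gains <- function(m, exclude = integer()) {
  L <- nrow(m$logp)
  positions <- setdiff(seq_len(L), as.integer(exclude))
  ref_chars <- strsplit(m$background$residues, "", fixed = TRUE)[[1]]
  lapply(positions, function(p) {
    wt <- ref_chars[p]
    mts <- setdiff(AA_ALPHABET, wt)
    g <- m$logp[p, mts] - m$logp[p, wt]
    o <- order(-g, mts)
    list(pos = p, wt = wt, mt = mts[o], gain = unname(g[o]))
  })
}

# Minimal binary max-heap on (score desc, tie-key asc); nodes are opaque.
heap_new <- function() {
  env <- new.env(parent = emptyenv())
  env$score <- numeric(0); env$key <- character(0); env$node <- list()
  env
}

heap_less <- function(env, i, j) {
  # TRUE if element i has lower priority than j
  if (env$score[i] != env$score[j]) return(env$score[i] < env$score[j])
  env$key[i] > env$key[j]
}

heap_push <- function(env, score, key, node) {
  n <- length(env$score) + 1L
  env$score[n] <- score; env$key[n] <- key; env$node[[n]] <- node
  i <- n
  while (i > 1L) {
    p <- i %/% 2L
    if (heap_less(env, p, i)) {
      env$score[c(p, i)] <- env$score[c(i, p)]
      env$key[c(p, i)] <- env$key[c(i, p)]
      tmp <- env$node[[p]]; env$node[[p]] <- env$node[[i]]; env$node[[i]] <- tmp
      i <- p
    } else break
  }
}

heap_pop <- function(env) {
  n <- length(env$score)
  if (n == 0L) return(NULL)
  top <- list(score = env$score[1], key = env$key[1], node = env$node[[1]])
  env$score[1] <- env$score[n]; env$key[1] <- env$key[n]
  env$node[[1]] <- env$node[[n]]
  env$score <- env$score[-n]; env$key <- env$key[-n]; env$node[[n]] <- NULL
  i <- 1L; n <- n - 1L
  repeat {
    l <- 2L * i; r <- l + 1L; big <- i
    if (l <= n && heap_less(env, big, l)) big <- l
    if (r <= n && heap_less(env, big, r)) big <- r
    if (big == i) break
    env$score[c(big, i)] <- env$score[c(i, big)]
    env$key[c(big, i)] <- env$key[c(i, big)]
    tmp <- env$node[[big]]; env$node[[big]] <- env$node[[i]]; env$node[[i]] <- tmp
    i <- big
  }
  top
}

#' Exact top-N combination variants by lazy best-first search
#'
#' Finds the `n_select` best k-new-site combination variants under additive
#' scoring on the background matrix, without materializing the combination
#' library (which for the Cas9 three-site design holds ~2.9e12 variants).
#'
#' Per mutable position the 19 substitution gains are pre-sorted; a
#' best-first search with a max-heap then enumerates candidate states
#' (a k-subset of positions plus one alternative letter per chosen
#' position) in exact non-increasing score order: each popped state expands
#' to (a) one-step demotions of a chosen letter to the next-best letter at
#' its position and (b), from letter-optimal states, one-step advances of a
#' chosen position to the next position in best-gain order. Every state's
#' predecessor under this scheme scores at least as high, so the n-th pop is
#' the exact n-th best combination. Ties are broken deterministically
#' (score desc, then position tuple, then mutant letters).
#'
#' @param m A [fitness_matrix] conditioned on the background sequence (the
#'   reference with the background variant already applied).
#' @param background A [variant]: the fixed substitutions defining the
#'   design background; its positions are excluded from the new sites. The
#'   wild-type letters of `background` must match `m$background` (which
#'   already carries them).
#' @param k Number of new sites per combination.
#' @param n_select Number of top candidates to return.
#' @param fixed Extra positions to exclude beyond the background's.
#' @return A tibble with one row per candidate in rank order: `rank`,
#'   `new_sites` (variant string of the k new substitutions),
#'   `full_variant` (background plus new sites), `combo_score` (nats,
#'   additive over the new sites), `n_substitutions`.
#' @export
top_n_combinations <- function(m, background = variant(), k, n_select,
                               fixed = integer()) {
  stopifnot(inherits(m, "fitness_matrix"), inherits(background, "variant"))
  if (nrow(background) > 0L) {
    # the matrix background sequence must already carry the background
    # substitutions (matrix is conditioned on the mutated sequence)
    got <- residue_at(m$background, background$pos)
    if (!all(got == background$mt))
      fs_stop("background_mismatch",
              "matrix background does not carry the background substitutions")
  }
  k <- as.integer(k); n_select <- as.integer(n_select)
  if (k < 1L) fs_stop("invalid_scope", "k must be >= 1")
  if (n_select < 1L) fs_stop("invalid_scope", "n_select must be >= 1")
  exclude <- c(background$pos, as.integer(fixed))
  gains <- position_gains(m, exclude = exclude)
  P <- length(gains)
  if (k > P)
    fs_stop("invalid_scope", sprintf("k = %d exceeds the %d mutable positions", k, P))
  # order positions by (best gain desc, position asc)
  best <- vapply(gains, function(g) g$gain[1], numeric(1))
  pord <- order(-best, vapply(gains, function(g) g$pos, integer(1)))
  gains <- gains[pord]

  state_score <- function(I, J)
    sum(vapply(seq_len(k), function(s) gains[[I[s]]]$gain[J[s]], numeric(1)))
  state_key <- function(I, J) {
    pos <- vapply(seq_len(k), function(s) gains[[I[s]]]$pos, integer(1))
    mt <- vapply(seq_len(k), function(s) gains[[I[s]]]$mt[J[s]], character(1))
    o <- order(pos)
    paste0(sprintf("%06d%s", pos[o], mt[o]), collapse = "")
  }

  heap <- heap_new()
  visited <- new.env(parent = emptyenv())
  push_state <- function(I, J) {
    id <- paste(c(I, J), collapse = ",")
    if (exists(id, envir = visited, inherits = FALSE)) return(invisible())
    visited[[id]] <- TRUE
    heap_push(heap, state_score(I, J), state_key(I, J), list(I = I, J = J))
  }

  push_state(seq_len(k), rep(1L, k))
  total <- combo_library_size(nrow(m$logp), length(unique(exclude)), k)
  n_out <- min(n_select, total)
  out <- vector("list", n_out)
  got <- 0L
  while (got < n_out) {
    top <- heap_pop(heap)
    got <- got + 1L
    out[[got]] <- top
    I <- top$node$I; J <- top$node$J
    # (a) demote one letter
    for (s in seq_len(k)) {
      if (J[s] < 19L) { J2 <- J; J2[s] <- J[s] + 1L; push_state(I, J2) }
    }
    # (b) advance one position (only from letter-optimal states)
    if (all(J == 1L)) {
      for (s in seq_len(k)) {
        nxt <- I[s] + 1L
        limit <- if (s < k) I[s + 1L] - 1L else P
        if (nxt <= limit) { I2 <- I; I2[s] <- nxt; push_state(I2, J) }
      }
    }
  }

  rows <- lapply(seq_len(n_out), function(i) {
    I <- out[[i]]$node$I; J <- out[[i]]$node$J
    pos <- vapply(seq_len(k), function(s) gains[[I[s]]]$pos, integer(1))
    wt <- vapply(seq_len(k), function(s) gains[[I[s]]]$wt, character(1))
    mt <- vapply(seq_len(k), function(s) gains[[I[s]]]$mt[J[s]], character(1))
    new_v <- variant(wt, pos, mt)
    full <- variant(c(background$wt, wt), c(background$pos, pos),
                    c(background$mt, mt))
    tibble::tibble(rank = i,
                   new_sites = format_variant(new_v, collapse = ";"),
                   full_variant = format_variant(full, collapse = ";"),
                   combo_score = out[[i]]$score,
                   n_substitutions = nrow(full))
  })
  dplyr::bind_rows(rows)
}
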