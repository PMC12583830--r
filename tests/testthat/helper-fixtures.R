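# Shared fixtures: built in code, no stored data.

toy_ref <- function() protein_seq("ACDEF", id = "toy5")

# 3-residue matrix with specified log-scores at position 2 (rows are
# renormalized; the score only depends on within-row differences, which the
# row-wise log-softmax preserves).
toy_matrix <- function() {
  bg <- protein_seq("ACA", id = "toy3")
  lp <- matrix(log(1 / 20), 3, 20, dimnames = list(NULL, AA_ALPHABET))
  lp[2, "K"] <- -0.5
  lp[2, "C"] <- -2.5
  lp[1, "D"] <- -1.0
  lp[1, "A"] <- -1.7
  fitness_matrix(lp, bg, renormalize = TRUE)
}

uniform_matrix <- function(residues) {
  bg <- protein_seq(residues)
  fitness_matrix(matrix(log(1 / 20), bg$length, 20,
                        dimnames = list(NULL, AA_ALPHABET)), bg)
}

# a random valid variant on `ref` with k substitutions
random_variant <- function(ref, k) {
  if (k == 0L) return(variant())
  pos <- sort(sample(ref$length, k))
  wt <- substring(ref$residues, pos, pos)
  mt <- vapply(wt, function(w) sample(setdiff(AA_ALPHABET, w), 1), character(1))
  variant(wt, pos, mt)
}

# Brute-force oracle for the top-N combination search: enumerate every
# k-subset of mutable positions and every mutant-letter assignment, score
# additively, sort by (score desc, position tuple, mutant letters).
brute_force_top_n <- function(m, background, k, n_select) {
  exclude <- background$pos
  positions <- setdiff(seq_len(nrow(m$logp)), exclude)
  ref_chars <- strsplit(m$background$residues, "", fixed = TRUE)[[1]]
  combos <- utils::combn(positions, k, simplify = FALSE)
  rows <- list()
  for (cmb in combos) {
    alts <- lapply(cmb, function(p) setdiff(AA_ALPHABET, ref_chars[p]))
    grid <- expand.grid(alts, stringsAsFactors = FALSE)
    gains <- vapply(seq_along(cmb), function(j)
      m$logp[cmb[j], grid[[j]]] - m$logp[cmb[j], ref_chars[cmb[j]]],
      numeric(nrow(grid)))
    score <- if (nrow(grid) == 1L) sum(gains) else rowSums(gains)
    key <- do.call(paste0, lapply(seq_along(cmb), function(j)
      sprintf("%06d%s", cmb[j], grid[[j]])))
    var_str <- do.call(paste, c(lapply(seq_along(cmb), function(j)
      paste0(ref_chars[cmb[j]], cmb[j], grid[[j]])), sep = ";"))
    rows[[length(rows) + 1L]] <-
      data.frame(new_sites = var_str, combo_score = score, key = key,
                 stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  all <- all[order(-all$combo_score, all$key), ]
  utils::head(all[, c("new_sites", "combo_score")], n_select)
}

# small editable amplicon: C at chosen protospacer positions, no other C
make_amplicon <- function(c_positions, protospacer_start = 31L, len = 100L,
                          seed = 11L) {
  withr::with_seed(seed, {
    chars <- sample(c("A", "G", "T"), len, replace = TRUE)
    chars[protospacer_start + c_positions - 1L] <- "C"
    amplicon_spec(paste(chars, collapse = ""),
                  protospacer_start = protospacer_start)
  })
}
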