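#' Simulate a per-position log-probability matrix
#'
#' Generates the statistical shape of a zero-shot predictor's output: per
#' row, baseline log-scores are drawn i.i.d. normal with SD
#' `row_concentration` (larger = more peaked distributions after
#' renormalization), then three structured effects are added before row-wise
#' log-softmax renormalization:
#' \itemize{
#'   \item `class_bias`: a constant (nats) added to a whole target-amino-acid
#'     column, emulating composition bias of the predictor's training
#'     corpus (e.g. a lysine preference);
#'   \item `planted`: position-specific boosts emulating genuinely
#'     beneficial substitutions;
#'   \item `wt_boost`: a constant added to each row's background-residue
#'     entry, emulating a predictor's preference for the wild type.
#' }
#' Identical seeds give bit-identical matrices.
#'
#' @param L Sequence length (ignored if `background` is given).
#' @param planted Optional data frame with columns `position`, `aa`, `boost`
#'   (nats). A boost of ~3 nats marks a decisively beneficial substitution
#'   under the default baseline spread.
#' @param class_bias Optional named numeric vector, target AA -> nats.
#' @param row_concentration SD of the baseline log-scores (nats).
#' @param wt_boost Nats added to the background residue entry per row.
#' @param background Optional [protein_seq]; random otherwise.
#' @param seed Integer seed; generation is deterministic given it.
#' @return A [fitness_matrix].
#' @export
gen_fitness_matrix <- function(L = NULL, planted = NULL, class_bias = NULL,
                               row_concentration = 0.4, wt_boost = 0,
                               background = NULL, seed = 1L) {
  if (is.null(background) && (is.null(L) || L < 1L))
    fs_stop("invalid_scope", "need L >= 1 or a background")
  L0 <- if (is.null(background)) L else background$length
  if (!is.null(planted)) {
    stopifnot(all(c("position", "aa", "boost") %in% names(planted)))
    if (any(planted$position < 1L | planted$position > L0))
      fs_stop("invalid_scope", "planted positions outside 1..L")
    if (!all(planted$aa %in% AA_ALPHABET))
      fs_stop("nonstandard_residue", "planted target letters must be canonical")
    if (!all(is.finite(planted$boost)))
      fs_stop("invalid_scope", "planted boosts must be finite")
  }
  if (!is.null(class_bias)) {
    stopifnot(!is.null(names(class_bias)),
              all(names(class_bias) %in% AA_ALPHABET))
  }
  # one RNG stream for the whole call: background first, then logits
  drawn <- with_seed(seed, {
    bg <- background
    if (is.null(bg))
      bg <- protein_seq(paste(sample(AA_ALPHABET, L0, replace = TRUE),
                              collapse = ""),
                        id = sprintf("sim_L%d_seed%d", L0, seed))
    list(bg = bg, logits = matrix(stats::rnorm(L0 * 20L, sd = row_concentration),
                                  nrow = L0, ncol = 20L))
  })
  background <- drawn$bg
  L <- L0
  logits <- drawn$logits
  colnames(logits) <- AA_ALPHABET
  for (a in names(class_bias)) logits[, a] <- logits[, a] + class_bias[[a]]
  wt_i <- match(strsplit(background$residues, "", fixed = TRUE)[[1]], AA_ALPHABET)
  if (wt_boost != 0) logits[cbind(seq_len(L), wt_i)] <-
      logits[cbind(seq_len(L), wt_i)] + wt_boost
  if (!is.null(planted)) {
    idx <- cbind(planted$position, match(planted$aa, AA_ALPHABET))
    logits[idx] <- logits[idx] + planted$boost
  }
  fitness_matrix(logits, background,
                 provenance = sprintf("fitscan::gen_fitness_matrix seed=%d", seed),
                 renormalize = TRUE)
}

#' Simulate an amplicon read set with planted editing outcomes
#'
#' Each read independently either receives an indel (probability
#' `indel_rate`: a deletion of uniform size in `indel_size_range`, starting
#' at protospacer position 17, i.e. 3 nt 5' of the PAM at the nick site) or
#' receives per-position base conversions (independent Bernoulli draws per
#' planted position). Uniform sequencing errors are then applied to every
#' read. Reads are emitted in the amplicon's forward orientation (pre-merged
#' amplicon sequencing); for a minus-strand protospacer the planted
#' conversions are placed complement-wise so that they read as
#' `edit_from -> to` along the protospacer.
#'
#' @param spec An [amplicon_spec].
#' @param n_reads Number of reads.
#' @param conversion Optional data frame with columns `position`
#'   (protospacer coordinate, 1-20), `to` (product base on the protospacer
#'   strand) and `rate` (proportion). Several `to` rows may share a
#'   position; their rates are the marginal conversion probabilities.
#' @param indel_rate Proportion of reads receiving a deletion.
#' @param indel_size_range Integer pair: uniform deletion size range (nt).
#' @param seq_error_rate Per-base substitution error proportion.
#' @param edit_from Reference base (protospacer strand) that planted
#'   conversions start from; an error is raised if a planted position does
#'   not carry it.
#' @param seed Integer seed.
#' @return A named `DNAStringSet` (use [write_fastq_reads()] for FASTQ).
#' @export
gen_reads <- function(spec, n_reads, conversion = NULL, indel_rate = 0,
                      indel_size_range = c(1L, 3L), seq_error_rate = 0,
                      edit_from = "C", seed = 1L) {
  stopifnot(inherits(spec, "amplicon_spec"), n_reads >= 1L)
  if (indel_rate < 0 || indel_rate > 1 || seq_error_rate < 0 || seq_error_rate > 1)
    fs_stop("invalid_scope", "rates must lie in [0, 1]")
  ref_chars <- strsplit(spec$amplicon, "", fixed = TRUE)[[1]]
  alen <- length(ref_chars)
  conv <- NULL
  if (!is.null(conversion) && nrow(conversion) > 0L) {
    stopifnot(all(c("position", "to", "rate") %in% names(conversion)))
    if (any(conversion$rate < 0 | conversion$rate > 1))
      fs_stop("invalid_scope", "conversion rates must lie in [0, 1]")
    coord <- protospacer_coord(spec, conversion$position)
    proto_base <- substr(spec$protospacer, conversion$position,
                         conversion$position)
    if (any(proto_base != edit_from))
      fs_stop("edit_from_mismatch",
              sprintf("protospacer position(s) %s do not carry reference base %s",
                      paste(conversion$position[proto_base != edit_from],
                            collapse = ", "), edit_from))
    # product base in amplicon frame
    amp_to <- if (spec$strand == "+") conversion$to else
      chartr("ACGT", "TGCA", conversion$to)
    conv <- split(data.frame(coord = coord, to = amp_to,
                             rate = conversion$rate,
                             stringsAsFactors = FALSE),
                  coord)
  }

  with_seed(seed, {
    base <- matrix(rep(ref_chars, each = n_reads), nrow = n_reads)
    is_indel <- stats::runif(n_reads) < indel_rate
    # conversions on non-indel reads only (a read receives an indel OR edits)
    if (!is.null(conv)) {
      for (grp in conv) {
        p_tot <- sum(grp$rate)
        hit <- !is_indel & stats::runif(n_reads) < p_tot
        if (any(hit)) {
          to <- sample(grp$to, sum(hit), replace = TRUE,
                       prob = grp$rate / p_tot)
          base[cbind(which(hit), rep(grp$coord[1], sum(hit)))] <- to
        }
      }
    }
    # uniform sequencing errors everywhere
    if (seq_error_rate > 0) {
      err <- which(stats::runif(n_reads * alen) < seq_error_rate)
      if (length(err)) {
        cur <- base[err]
        repl <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L),
                       character(1))
        base[err] <- repl
      }
    }
    reads <- do.call(paste0, lapply(seq_len(alen), function(j) base[, j]))
    if (any(is_indel)) {
      del_start <- protospacer_coord(spec, 17L)
      sizes <- sample(seq(indel_size_range[1], indel_size_range[2]),
                      sum(is_indel), replace = TRUE)
      idx <- which(is_indel)
      for (j in seq_along(idx)) {
        r <- reads[idx[j]]
        s0 <- min(del_start, alen - sizes[j])
        reads[idx[j]] <- paste0(substr(r, 1L, s0 - 1L),
                                substr(r, s0 + sizes[j], alen))
      }
    }
    out <- Biostrings::DNAStringSet(reads)
    names(out) <- paste0("read_", seq_len(n_reads))
    out
  })
}

#' Simulate a replicate editing-efficiency table
#'
#' Per-site baseline mean efficiencies are drawn uniformly from
#' `baseline_range`; each editor's replicate values are
#' `baseline * fold * m` with `m` a mean-one lognormal multiplier whose
#' coefficient of variation is `cv` (the baseline editor itself has fold 1
#' and the same replicate noise), clamped to [0, 100].
#'
#' @param n_sites Number of genomic sites.
#' @param editors Named numeric vector: editor id -> true fold-change vs the
#'   baseline.
#' @param baseline_range Length-2 numeric: range of baseline mean
#'   efficiencies (%).
#' @param cv Replicate coefficient of variation (0 = noise-free).
#' @param replicates Biological replicates per (site, editor).
#' @param baseline_editor Id of the baseline editor row set.
#' @param seed Integer seed.
#' @return An efficiency tibble (see [read_efficiency_table()]).
#' @export
gen_efficiency_table <- function(n_sites, editors, baseline_range = c(10, 40),
                                 cv = 0.1, replicates = 3L,
                                 baseline_editor = "baseline", seed = 1L) {
  stopifnot(n_sites >= 1L, replicates >= 1L, cv >= 0)
  if (is.null(names(editors)) || any(!nzchar(names(editors))))
    fs_stop("invalid_plan", "editors must be a named vector (editor -> fold)")
  if (any(editors <= 0)) fs_stop("invalid_plan", "fold-changes must be > 0")
  folds <- c(stats::setNames(1, baseline_editor), editors)
  sigma <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  with_seed(seed, {
    baseline <- stats::runif(n_sites, baseline_range[1], baseline_range[2])
    rows <- expand.grid(site = paste0("site_", seq_len(n_sites)),
                        editor = names(folds),
                        replicate = seq_len(replicates),
                        stringsAsFactors = FALSE)
    noise <- if (sigma > 0)
      exp(stats::rnorm(nrow(rows), -sigma^2 / 2, sigma)) else rep(1, nrow(rows))
    site_i <- match(rows$site, paste0("site_", seq_len(n_sites)))
    rows$efficiency_pct <- pmin(100, pmax(0,
      baseline[site_i] * folds[rows$editor] * noise))
    tibble::as_tibble(rows[order(rows$site, rows$editor, rows$replicate), ])
  })
}
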