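#' Mutation-class enrichment in the top fraction of a ranked library
#'
#' Groups single mutants by target amino acid ("X-to-K" style classes) and
#' asks whether each class is over-represented among the top-scoring fraction
#' of the library. Two complementary tests are reported per class: a
#' two-sided t-test on the class members' position-centered scores (each
#' mutant's score minus the mean score of all 19 substitutions at its
#' position — centering removes the per-position wild-type term, which is
#' shared by every mutant at a position and would otherwise make a naive
#' class-vs-rest comparison badly miscalibrated), and a two-sided Fisher
#' exact (hypergeometric) test on membership in the top set.
#' Benjamini-Hochberg adjustment is applied across classes, separately for
#' each test.
#'
#' The top set contains the first `ceiling(top_fraction * N)` ranked entries,
#' extended to include any entries tied with the boundary score.
#'
#' @param lib A ranked library of single mutants (needs `mt`, `raw_score`,
#'   `rank` columns; see [scan_single_mutants()] + [rank_and_normalize()]).
#' @param top_fraction Proportion of the library forming the top set
#'   (default 0.05, the conventional top 5 percent).
#' @param hyper_test Also compute the Fisher/hypergeometric membership test
#'   (default `TRUE`; disable in large simulation sweeps where only the
#'   score-based test is of interest).
#' @return A tibble with one row per target-amino-acid class present:
#'   `class`, `n_total`, `n_top`, `fold_enrichment`, `p_value`
#'   (position-centered t-test), `p_adjusted`, `p_hyper`,
#'   `p_hyper_adjusted`, sorted by fold descending.
#' @export
class_enrichment <- function(lib, top_fraction = 0.05, hyper_test = TRUE) {
  if (!all(c("mt", "pos", "raw_score", "rank") %in% names(lib)))
    fs_stop("invalid_library",
            "enrichment needs a ranked single-mutant library with pos and mt columns")
  if (top_fraction <= 0 || top_fraction > 1)
    fs_stop("invalid_scope", "top_fraction must be in (0, 1]")
  lib <- lib[order(lib$rank), ]
  n <- nrow(lib)
  n_cut <- ceiling(top_fraction * n)
  boundary <- lib$raw_score[n_cut]
  in_top <- lib$rank <= n_cut | lib$raw_score == boundary
  n_top_total <- sum(in_top)
  classes <- sort(unique(lib$mt))
  if (length(classes) < 2L)
    fs_stop("invalid_library", "enrichment needs at least two mutation classes")

  centered <- lib$raw_score - stats::ave(lib$raw_score, lib$pos)
  n_total_c <- integer(length(classes)); n_top_c <- integer(length(classes))
  p_t <- numeric(length(classes)); p_h <- numeric(length(classes))
  for (i in seq_along(classes)) {
    is_a <- lib$mt == classes[i]
    n_total_c[i] <- sum(is_a)
    n_top_c[i] <- sum(is_a & in_top)
    p_t[i] <- tryCatch(
      stats::t.test(centered[is_a], mu = 0)$p.value,
      error = function(e) NA_real_)  # degenerate (constant) scores
    p_h[i] <- if (hyper_test)
      stats::fisher.test(matrix(c(n_top_c[i], n_top_total - n_top_c[i],
                                  n_total_c[i] - n_top_c[i],
                                  n - n_total_c[i] - (n_top_total - n_top_c[i])),
                                nrow = 2L))$p.value
    else NA_real_
  }
  res <- tibble::tibble(class = classes, n_total = n_total_c, n_top = n_top_c,
                        fold_enrichment = (n_top_c / n_top_total) /
                          (n_total_c / n),
                        p_value = p_t, p_hyper = p_h)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res$p_hyper_adjusted <- stats::p.adjust(res$p_hyper, method = "BH")
  res <- res[order(-res$fold_enrichment, res$class),
             c("class", "n_total", "n_top", "fold_enrichment",
               "p_value", "p_adjusted", "p_hyper", "p_hyper_adjusted")]
  attr(res, "top_fraction") <- top_fraction
  attr(res, "n_top_total") <- n_top_total
  res
}

#' Select candidates by mutation-type quotas
#'
#' Hybrid selection: within a high-fitness pool (by default the top
#' `top_fraction` of the ranked library, ties at the boundary included), take
#' the `q` best-ranked mutants of each requested target-amino-acid class.
#' The study's Cas9 screen used quotas `c(K = 6, C = 3, W = 3, M = 3, R = 3)`
#' for 18 candidates.
#'
#' @param lib A ranked single-mutant library.
#' @param quotas Named integer vector mapping target amino acid to count.
#' @param top_fraction Pool cutoff as a proportion of the library; use
#'   `pool = "all"` to draw from the whole ranking instead.
#' @param pool `"top"` (default) or `"all"`.
#' @return A tibble of selected rows ordered by rank, with attribute
#'   `underfilled`: a named integer vector of per-class shortfalls (empty
#'   when every quota was met).
#' @export
quota_select <- function(lib, quotas, top_fraction = 0.05,
                         pool = c("top", "all")) {
  pool <- match.arg(pool)
  if (!all(c("mt", "rank") %in% names(lib)))
    fs_stop("invalid_library", "quota selection needs a ranked single-mutant library")
  if (length(quotas) && is.null(names(quotas)))
    fs_stop("invalid_plan", "quotas must be a named vector (target AA -> count)")
  bad <- setdiff(names(quotas), AA_ALPHABET)
  if (length(bad))
    fs_stop("invalid_plan",
            sprintf("quota class(es) not canonical amino acids: %s",
                    paste(bad, collapse = ", ")))
  if (any(quotas < 0)) fs_stop("invalid_plan", "quota counts must be >= 0")
  lib <- lib[order(lib$rank), ]
  pool_rows <- if (pool == "top") {
    n_cut <- ceiling(top_fraction * nrow(lib))
    lib[lib$rank <= n_cut | lib$raw_score == lib$raw_score[n_cut], ]
  } else lib
  picked <- lapply(names(quotas), function(a) {
    utils::head(pool_rows[pool_rows$mt == a, ], quotas[[a]])
  })
  sel <- dplyr::bind_rows(picked)
  if (nrow(sel) == 0L) sel <- lib[0, ]
  sel <- sel[order(sel$rank), ]
  shortfall <- vapply(seq_along(quotas), function(i)
    quotas[[i]] - nrow(picked[[i]]), numeric(1))
  names(shortfall) <- names(quotas)
  attr(sel, "underfilled") <- shortfall[shortfall > 0]
  attr(sel, "pool_size") <- nrow(pool_rows)
  sel
}

#' Collapse candidates to one substitution per position
#'
#' When several selected mutants share a residue position (e.g. G1218R and
#' G1218K), only one can enter a combination background. The substitution
#' maximal under `priority` survives at each position — measured editing
#' efficiency when available, otherwise the predicted raw score.
#'
#' @param candidates Data frame of single mutants with `pos`, `mt` (and
#'   `raw_score`) columns.
#' @param priority Either a column name in `candidates` (default
#'   `"raw_score"`) or a numeric vector aligned with its rows. Must be
#'   non-missing wherever a position is contested.
#' @return The surviving rows, ordered by position.
#' @export
dedup_positions <- function(candidates, priority = "raw_score") {
  if (!all(c("pos", "mt") %in% names(candidates)))
    fs_stop("invalid_library", "candidates need pos and mt columns")
  pr <- if (is.character(priority) && length(priority) == 1L) {
    if (!priority %in% names(candidates))
      fs_stop("missing_priority",
              sprintf("priority column '%s' not found", priority))
    candidates[[priority]]
  } else {
    if (length(priority) != nrow(candidates))
      fs_stop("missing_priority", "priority vector length mismatch")
    as.numeric(priority)
  }
  contested <- candidates$pos %in% candidates$pos[duplicated(candidates$pos)]
  if (any(is.na(pr) & contested))
    fs_stop("missing_priority",
            sprintf("missing priority value(s) at contested position(s): %s",
                    paste(unique(candidates$pos[is.na(pr) & contested]),
                          collapse = ", ")))
  tie2 <- if ("raw_score" %in% names(candidates)) candidates$raw_score else 0
  ord <- order(candidates$pos, -pr, -tie2, candidates$mt)
  out <- candidates[ord, ]
  out <- out[!duplicated(out$pos), ]
  tibble::as_tibble(out)
}

#' Read a selection plan (top fraction + quotas) from YAML or JSON
#'
#' Expected keys: `top_fraction` (proportion) and `quotas` (map from target
#' amino acid to count), e.g. `quotas: {K: 6, C: 3, W: 3, M: 3, R: 3}`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with `top_fraction` and named numeric `quotas`.
#' @export
read_selection_plan <- function(path) {
  plan <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  top_fraction <- plan$top_fraction %||% 0.05
  quotas <- unlist(plan$quotas)
  if (top_fraction <= 0 || top_fraction > 1)
    fs_stop("invalid_plan", "top_fraction must be in (0, 1]")
  list(top_fraction = top_fraction, quotas = quotas)
}
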