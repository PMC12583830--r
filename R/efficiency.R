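#' Read / write a replicate editing-efficiency table
#'
#' The TSV dialect has columns `site`, `editor`, `replicate`,
#' `efficiency_pct` — one row per biological replicate of one editor at one
#' genomic site, efficiency in percent (0-100).
#'
#' @param path TSV file path.
#' @return A tibble.
#' @export
read_efficiency_table <- function(path) {
  df <- tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                            stringsAsFactors = FALSE))
  validate_efficiency_table(df)
}

#' @rdname read_efficiency_table
#' @param table Efficiency tibble.
#' @export
write_efficiency_table <- function(table, path) {
  validate_efficiency_table(table)
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_efficiency_table <- function(df) {
  need <- c("site", "editor", "replicate", "efficiency_pct")
  if (!all(need %in% names(df)))
    fs_stop("invalid_table",
            sprintf("efficiency table needs columns: %s", paste(need, collapse = ", ")))
  if (any(df$efficiency_pct < 0 | df$efficiency_pct > 100, na.rm = TRUE))
    fs_stop("invalid_table", "efficiency_pct must lie in [0, 100]")
  tibble::as_tibble(df)
}

#' Baseline-normalized fold-changes of editing efficiency
#'
#' Implements the per-site normalization used in editing-efficiency
#' comparisons: at each site the baseline editor's replicate-mean efficiency
#' is set to 1, each editor's fold-change at that site is its replicate mean
#' divided by the baseline mean, and the cross-site summary is the
#' arithmetic mean (with SD) of the per-site folds. Sites where the baseline
#' mean is zero cannot be normalized; they are excluded and reported.
#'
#' @param table Efficiency tibble (see [read_efficiency_table()]).
#' @param baseline_editor Editor id serving as the per-site reference.
#' @return A list with `per_site` (tibble: site, editor, mean_pct, fold),
#'   `summary` (tibble: editor, mean_fold, sd_fold, n_sites) and
#'   `excluded_sites` (character vector of zero-baseline sites).
#' @export
normalize_efficiency <- function(table, baseline_editor) {
  table <- validate_efficiency_table(table)
  if (!baseline_editor %in% table$editor)
    fs_stop("missing_baseline",
            sprintf("baseline editor '%s' absent from table", baseline_editor))
  means <- dplyr::summarise(
    dplyr::group_by(table, .data$site, .data$editor),
    mean_pct = mean(.data$efficiency_pct), .groups = "drop")
  base <- means[means$editor == baseline_editor, c("site", "mean_pct")]
  names(base)[2] <- "baseline_pct"
  missing <- setdiff(unique(means$site), base$site)
  if (length(missing))
    fs_stop("missing_baseline",
            sprintf("baseline '%s' missing at site(s): %s", baseline_editor,
                    paste(missing, collapse = ", ")))
  excluded <- base$site[base$baseline_pct == 0]
  if (length(excluded) == length(base$site))
    fs_stop("missing_baseline", "baseline efficiency is zero at every site")
  per_site <- dplyr::left_join(means, base, by = "site")
  per_site <- per_site[!per_site$site %in% excluded, ]
  per_site$fold <- per_site$mean_pct / per_site$baseline_pct
  summary <- dplyr::summarise(
    dplyr::group_by(per_site, .data$editor),
    mean_fold = mean(.data$fold),
    sd_fold = stats::sd(.data$fold),
    n_sites = dplyr::n(), .groups = "drop")
  summary <- summary[order(-summary$mean_fold), ]
  list(per_site = per_site[, c("site", "editor", "mean_pct", "fold")],
       summary = summary,
       excluded_sites = as.character(excluded))
}
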