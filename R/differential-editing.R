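#' Classify a site's wild-type vs mutant editing change
#'
#' Classes: `abolished` (mutant editing below the detection floor while the
#' wild type is clearly edited), `decreased` / `increased` (change of at
#' least `alter_threshold` percentage points), `unchanged` otherwise, and
#' `undetermined` when either efficiency is undefined (depth failure).
#' Thresholds are in percentage points of efficiency, not relative change
#' (set `relative = TRUE` for the non-default relative mode, where
#' `alter_threshold` is a percentage of the wild-type efficiency).
#'
#' @param eff_wt,eff_mut efficiencies in percent (`[0, 100]`), `NA` allowed.
#' @param alter_threshold minimum |change| to call decreased/increased
#'   (default 10 points).
#' @param zero_floor mutant efficiency below which editing counts as absent
#'   (default 1 point; sequencing error makes exact zero unrealistic).
#' @param wt_min_for_abolished minimum wild-type efficiency for the
#'   `abolished` label, so noise-level wild-type sites are not called
#'   abolished (default 10 points).
#' @param relative interpret `alter_threshold` relative to `eff_wt`.
#' @return character vector of class labels.
#' @export
classify_editing <- function(eff_wt, eff_mut, alter_threshold = 10,
                             zero_floor = 1, wt_min_for_abolished = 10,
                             relative = FALSE) {
  ok <- function(x) is.na(x) | (x >= 0 & x <= 100)
  if (!all(ok(eff_wt)) || !all(ok(eff_mut))) {
    abort("efficiencies must lie in [0, 100] or be NA")
  }
  n <- max(length(eff_wt), length(eff_mut))
  eff_wt <- rep_len(eff_wt, n)
  eff_mut <- rep_len(eff_mut, n)
  delta <- eff_mut - eff_wt
  thr <- if (relative) alter_threshold / 100 * eff_wt else
    rep_len(alter_threshold, n)
  dplyr::case_when(
    is.na(eff_wt) | is.na(eff_mut) ~ "undetermined",
    eff_mut < zero_floor & eff_wt >= wt_min_for_abolished ~ "abolished",
    delta <= -thr ~ "decreased",
    delta >= thr ~ "increased",
    TRUE ~ "unchanged"
  )
}

#' Compare per-site editing between two genotypes
#'
#' Joins wild-type and mutant call tables on the site key (union of sites;
#' a genotype missing a site gets an undefined efficiency) and classifies
#' each site with [classify_editing()].
#'
#' @param wt_calls,mut_calls pooled per-genotype call tibbles (see
#'   [pool_replicates()]) with columns `seqid`, `pos`, `strand`,
#'   `efficiency`.
#' @inheritParams classify_editing
#' @return tibble with `seqid`, `pos`, `strand`, `eff_wt`, `eff_mut`,
#'   `delta` (mutant minus wild type, percentage points) and `class`.
#' @export
compare_editing <- function(wt_calls, mut_calls, alter_threshold = 10,
                            zero_floor = 1, wt_min_for_abolished = 10,
                            relative = FALSE) {
  pick <- function(x, tag) {
    out <- tibble::tibble(seqid = x$seqid, pos = x$pos, strand = x$strand,
                          eff = x$efficiency)
    names(out)[4] <- paste0("eff_", tag)
    out
  }
  j <- dplyr::full_join(pick(wt_calls, "wt"), pick(mut_calls, "mut"),
                        by = c("seqid", "pos", "strand"))
  j |>
    dplyr::mutate(
      delta = .data$eff_mut - .data$eff_wt,
      class = classify_editing(.data$eff_wt, .data$eff_mut,
                               alter_threshold, zero_floor,
                               wt_min_for_abolished, relative)
    ) |>
    dplyr::arrange(.data$seqid, .data$pos)
}

ALTERED_CLASSES <- c("abolished", "decreased", "increased")

#' Per-transcript summary of altered editing
#'
#' Counts, per gene, how many surveyed sites changed class
#' (abolished/decreased/increased) and the percentage of altered sites.
#'
#' @param records differential tibble with a `gene_id` column and a `class`
#'   column (e.g. [compare_editing()] joined to [annotate_sites()] output).
#' @return tibble `gene_id`, `n_sites`, `n_altered`, `pct_altered`
#'   (rounded to 1 decimal place).
#' @export
summarize_transcripts <- function(records) {
  records |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      n_altered = sum(.data$class %in% ALTERED_CLASSES),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_altered = round(100 * .data$n_altered / .data$n_sites, 1))
}

#' Overall fraction of altered editing sites
#'
#' @param records differential tibble with a `class` column.
#' @return one-row tibble `n_affected`, `n_total`, `pct` (percentage of all
#'   surveyed sites in an altered class, rounded to the nearest integer).
#' @export
overall_alteration <- function(records) {
  if (nrow(records) == 0) abort("no records to summarise")
  n_affected <- sum(records$class %in% ALTERED_CLASSES)
  n_total <- nrow(records)
  tibble::tibble(n_affected = n_affected, n_total = n_total,
                 pct = round(100 * n_affected / n_total))
}
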