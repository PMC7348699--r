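#' Caller thresholds
#'
#' Filters used when comparing a DNA pileup against an RNA pileup to call
#' candidate C-to-U editing sites.
#'
#' @param min_depth minimum read depth required of both the DNA and the RNA
#'   column (default 20 reads).
#' @param dna_max_alt_fraction maximum non-reference fraction tolerated in
#'   the DNA column for it to count as homozygous reference; the
#'   pileup-level analogue of a homozygous SNP call.
#' @param min_rna_edit_fraction minimum edited-base fraction of the RNA
#'   column for discovery (bypassed by [quantify_known_sites()]).
#' @param depth_mode `"total"` applies `min_depth` to the whole column
#'   depth; `"cu"` applies it to the C-role + U-role counts only.
#' @return a `caller_thresholds` list.
#' @export
caller_thresholds <- function(min_depth = 20L, dna_max_alt_fraction = 0.02,
                              min_rna_edit_fraction = 0.05,
                              depth_mode = c("total", "cu")) {
  depth_mode <- match.arg(depth_mode)
  if (min_depth < 1) abort("min_depth must be >= 1")
  if (dna_max_alt_fraction < 0 || dna_max_alt_fraction > 1) {
    abort("dna_max_alt_fraction must be in [0, 1]")
  }
  if (min_rna_edit_fraction < 0 || min_rna_edit_fraction > 1) {
    abort("min_rna_edit_fraction must be in [0, 1]")
  }
  structure(
    list(min_depth = as.integer(min_depth),
         dna_max_alt_fraction = dna_max_alt_fraction,
         min_rna_edit_fraction = min_rna_edit_fraction,
         depth_mode = depth_mode),
    class = "caller_thresholds"
  )
}

#' Editing efficiency from unedited/edited read counts
#'
#' Editing (%) = U / (C + U) x 100, where C is the count of reads matching
#' the genomic (unedited) base and U the count matching the edited base.
#' Reads matching neither base are excluded upstream and never enter the
#' denominator.
#'
#' @param unedited_count C-role read count(s).
#' @param edited_count U-role read count(s).
#' @return numeric percentage(s) in `[0, 100]`; `NA` when `C + U = 0`
#'   (efficiency undefined, distinct from 0%).
#' @export
editing_efficiency <- function(unedited_count, edited_count) {
  if (any(unedited_count < 0, na.rm = TRUE) ||
      any(edited_count < 0, na.rm = TRUE)) {
    abort("read counts must be non-negative")
  }
  total <- unedited_count + edited_count
  ifelse(total > 0, 100 * edited_count / total, NA_real_)
}

join_pileups <- function(dna, rna) {
  j <- dplyr::inner_join(dna, rna, by = c("seqid", "pos"),
                         suffix = c("_dna", "_rna"))
  if (any(j$ref_dna != j$ref_rna)) {
    abort("DNA and RNA pileups disagree on reference bases; mismatched references")
  }
  n_dna_only <- nrow(dna) - nrow(j)
  n_rna_only <- nrow(rna) - nrow(j)
  if (n_dna_only > 0 || n_rna_only > 0) {
    warn(sprintf(
      "skipping positions present in only one pileup (%d DNA-only, %d RNA-only)",
      n_dna_only, n_rna_only))
  }
  j
}

call_columns <- function(j, thresholds) {
  plus <- j$ref_dna == "C"
  unedited_rna <- dplyr::if_else(plus, j$C_rna, j$G_rna)
  edited_rna <- dplyr::if_else(plus, j$T_rna, j$A_rna)
  ref_dna_count <- dplyr::if_else(plus, j$C_dna, j$G_dna)

  rna_eff_depth <- if (thresholds$depth_mode == "total") j$depth_rna else
    unedited_rna + edited_rna
  dna_eff_depth <- if (thresholds$depth_mode == "total") j$depth_dna else
    ref_dna_count

  tibble::tibble(
    seqid = j$seqid,
    pos = j$pos,
    ref = j$ref_dna,
    strand = dplyr::if_else(plus, "+", "-"),
    unedited = unedited_rna,
    edited = edited_rna,
    efficiency = editing_efficiency(unedited_rna, edited_rna),
    dna_depth_ok = dna_eff_depth >= thresholds$min_depth,
    rna_depth_ok = rna_eff_depth >= thresholds$min_depth,
    dna_homozygous = j$depth_dna > 0 &
      (j$depth_dna - ref_dna_count) / pmax(j$depth_dna, 1L) <=
        thresholds$dna_max_alt_fraction,
    min_fraction_ok = j$depth_rna > 0 &
      edited_rna / pmax(j$depth_rna, 1L) >= thresholds$min_rna_edit_fraction
  )
}

#' Discover candidate C-to-U editing sites from a DNA/RNA pileup pair
#'
#' Scans every position whose reference base is C (plus orientation, edited
#' reads appear as T) or G (minus orientation, edited reads appear as A) and
#' calls those where (a) DNA and RNA depth both reach `min_depth`, (b) the
#' DNA column is homozygous reference (non-reference fraction at most
#' `dna_max_alt_fraction`), and (c) the RNA edited-base fraction reaches
#' `min_rna_edit_fraction`. Each call carries the editing efficiency
#' U/(C+U) x 100 computed from the RNA column.
#'
#' @param dna,rna pileup tibbles with columns `seqid`, `pos`, `ref`,
#'   `depth`, `A`, `C`, `G`, `T`, indexed on the same reference.
#' @param thresholds a [caller_thresholds()].
#' @return tibble of calls: `seqid`, `pos`, `ref`, `strand`, `unedited`,
#'   `edited`, `efficiency`, and the four filter flags (all `TRUE` for
#'   discovered sites).
#' @export
discover_sites <- function(dna, rna, thresholds = caller_thresholds()) {
  j <- join_pileups(dna, rna)
  j <- dplyr::filter(j, .data$ref_dna %in% c("C", "G"))
  calls <- call_columns(j, thresholds)
  dplyr::filter(calls, .data$dna_depth_ok & .data$rna_depth_ok &
                  .data$dna_homozygous & .data$min_fraction_ok)
}

#' Quantify editing at externally supplied sites
#'
#' Force-quantifies a user-supplied site list (for example a site known from
#' a related species) regardless of the discovery fraction floor. Depth and
#' DNA-homozygosity flags are still computed and recorded; a site absent
#' from the pileups yields an undefined-efficiency row rather than an error.
#'
#' @param sites tibble with columns `seqid` and `pos` (genome coordinates);
#'   an optional `strand` column is ignored, orientation being determined by
#'   the reference base.
#' @inheritParams discover_sites
#' @return one call row per requested site, with `efficiency = NA` and all
#'   flags `NA` for sites not present in the pileups.
#' @export
quantify_known_sites <- function(sites, dna, rna,
                                 thresholds = caller_thresholds()) {
  key <- tibble::tibble(seqid = sites$seqid, pos = sites$pos)
  if (nrow(key) == 0) {
    return(call_columns(join_pileups(dna, rna)[0, ], thresholds))
  }
  j <- join_pileups(dna, rna)
  jk <- dplyr::left_join(key, j, by = c("seqid", "pos"))
  found <- !is.na(jk$ref_dna) & jk$ref_dna %in% c("C", "G")
  out <- call_columns(jk[found, ], thresholds)
  if (any(!found)) {
    miss <- tibble::tibble(
      seqid = key$seqid[!found], pos = key$pos[!found],
      ref = jk$ref_dna[!found], strand = NA_character_,
      unedited = NA_integer_, edited = NA_integer_, efficiency = NA_real_,
      dna_depth_ok = NA, rna_depth_ok = NA, dna_homozygous = NA,
      min_fraction_ok = NA
    )
    out <- dplyr::bind_rows(out, miss)
  }
  dplyr::arrange(out, match(paste(out$seqid, out$pos),
                            paste(key$seqid, key$pos)))
}

#' Pool per-replicate calls into per-genotype calls
#'
#' Sums the C-role and U-role counts of biological replicates site by site
#' and recomputes the efficiency from the pooled counts. Site keys form the
#' union over replicates; a replicate missing a site contributes zero
#' counts. Filter flags are combined with "all replicates passed".
#'
#' @param calls a call tibble (as from [discover_sites()] or
#'   [quantify_known_sites()]) for one genotype, with one row per site per
#'   replicate; extra identifying columns (`sample`, `replicate`, ...) are
#'   dropped.
#' @return one row per `(seqid, pos)` with pooled counts and efficiency.
#' @export
pool_replicates <- function(calls) {
  calls |>
    dplyr::group_by(.data$seqid, .data$pos) |>
    dplyr::summarise(
      ref = .data$ref[1],
      strand = .data$strand[1],
      unedited = sum(.data$unedited, na.rm = TRUE),
      edited = sum(.data$edited, na.rm = TRUE),
      n_replicates = dplyr::n(),
      dna_depth_ok = all(.data$dna_depth_ok),
      rna_depth_ok = all(.data$rna_depth_ok),
      dna_homozygous = all(.data$dna_homozygous),
      min_fraction_ok = all(.data$min_fraction_ok),
      .groups = "drop"
    ) |>
    dplyr::mutate(efficiency = editing_efficiency(.data$unedited, .data$edited)) |>
    dplyr::relocate("efficiency", .after = "edited") |>
    dplyr::arrange(.data$seqid, .data$pos)
}
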