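#' Mendelian segregation chi-square test
#'
#' Tests observed phenotype counts against an expected ratio (3:1 by
#' default, the F2 expectation for a single recessive locus). By default
#' the Yates continuity correction is applied, with the correction term
#' clamped at zero when |O - E| <= 0.5 so near-perfect fits are not
#' overcorrected:
#' chi^2 = sum( max(|O_i - E_i| - 0.5, 0)^2 / E_i ).
#'
#' @param observed integer counts per phenotype class (e.g.
#'   `c(green = 440, yellow = 163)`).
#' @param ratio expected ratio, same length as `observed` (default `c(3, 1)`).
#' @param continuity apply the continuity correction (default `TRUE`).
#' @return an object of class `chisq_segregation` with the statistic,
#'   degrees of freedom (`classes - 1`), exact p-value and a classic
#'   table-style p interval label. Supports [tidy()] and [glance()].
#' @export
chi_square_segregation <- function(observed, ratio = c(3, 1),
                                   continuity = TRUE) {
  if (length(observed) != length(ratio)) {
    abort("observed and ratio must have the same length")
  }
  total <- sum(observed)
  if (total <= 0) abort("total count must be positive")
  if (any(ratio <= 0)) abort("expected ratio entries must be positive")
  expected <- total * ratio / sum(ratio)
  dev <- abs(observed - expected)
  if (continuity) dev <- pmax(dev - 0.5, 0)
  statistic <- sum(dev^2 / expected)
  df <- length(observed) - 1L
  p <- pchisq(statistic, df, lower.tail = FALSE)
  structure(
    list(observed = observed, expected = expected, ratio = ratio,
         chi_square = statistic, df = df, p_value = p,
         p_interval = p_interval_label(p), continuity_corrected = continuity),
    class = "chisq_segregation"
  )
}

# interval label in the style of printed chi-square tables
p_interval_label <- function(p, breaks = c(0.9, 0.75, 0.5, 0.25, 0.1,
                                           0.05, 0.025, 0.01)) {
  if (p > breaks[1]) return(sprintf(">%.1f", breaks[1]))
  if (p <= breaks[length(breaks)]) return(sprintf("<%.2f", breaks[length(breaks)]))
  k <- which(p <= breaks[-length(breaks)] & p > breaks[-1])
  sprintf("%.2f~%.2f", breaks[k], breaks[k + 1])
}

#' @export
print.chisq_segregation <- function(x, ...) {
  cat("Segregation chi-square (ratio ",
      paste(x$ratio, collapse = ":"), ")\n", sep = "")
  cat("  observed:", paste(x$observed, collapse = ", "), "\n")
  cat(sprintf("  chi-square = %.3f (df = %d%s), P %s\n",
              x$chi_square, x$df,
              if (x$continuity_corrected) ", continuity-corrected" else "",
              x$p_interval))
  invisible(x)
}

#' @export
tidy.chisq_segregation <- function(x, ...) {
  tibble::tibble(
    class = if (!is.null(names(x$observed))) names(x$observed) else
      paste0("class", seq_along(x$observed)),
    observed = as.numeric(x$observed),
    expected = x$expected,
    ratio = x$ratio
  )
}

#' @export
glance.chisq_segregation <- function(x, ...) {
  tibble::tibble(
    statistic = x$chi_square, df = x$df, p.value = x$p_value,
    p.interval = x$p_interval, continuity = x$continuity_corrected,
    n = sum(x$observed)
  )
}

#' Delimit a fine-mapping interval from recessive-class marker genotypes
#'
#' For a matrix of F2 individuals that are all phenotypic mutants
#' (homozygous recessive at the causal locus), the locus must lie where
#' every individual is homozygous for the mutant-parent allele (`A`). The
#' interval is delimited by the closest marker on each side of that core
#' region showing at least one recombinant (`H` or `B`) individual.
#' Missing genotypes (`NA` or `"-"`) are ignored cell-wise.
#'
#' @param markers data frame of genotype codes, one row per individual and
#'   one column per marker, columns ordered along the chromosome; codes
#'   `A` (mutant-parent homozygote), `H` (heterozygote), `B` (other-parent
#'   homozygote).
#' @return one-row tibble: `found` (any all-`A` marker at all),
#'   `left_marker` / `right_marker` (`NA` when the core region reaches a
#'   chromosome end, i.e. the interval is open on that side), `core_markers`
#'   (comma-joined all-`A` markers), `n_core`.
#' @export
delimit_interval <- function(markers) {
  m <- as.data.frame(markers)
  codes <- unique(unlist(lapply(m, as.character)))
  codes <- codes[!is.na(codes) & codes != "-"]
  if (!all(codes %in% c("A", "H", "B"))) {
    abort("marker codes must be A, H, B, '-' or NA")
  }
  all_a <- vapply(m, function(col) {
    col <- as.character(col)
    col[col == "-"] <- NA
    ok <- !is.na(col)
    any(ok) && all(col[ok] == "A")
  }, logical(1))
  if (!any(all_a)) {
    return(tibble::tibble(found = FALSE, left_marker = NA_character_,
                          right_marker = NA_character_,
                          core_markers = NA_character_, n_core = 0L))
  }
  core <- range(which(all_a))
  left <- if (core[1] > 1) names(m)[core[1] - 1L] else NA_character_
  right <- if (core[2] < ncol(m)) names(m)[core[2] + 1L] else NA_character_
  tibble::tibble(
    found = TRUE, left_marker = left, right_marker = right,
    core_markers = paste(names(m)[core[1]:core[2]], collapse = ","),
    n_core = core[2] - core[1] + 1L
  )
}

#' Recombination-fraction estimate from a recessive-class marker column
#'
#' Approximate estimator for the recombination fraction between a marker
#' and the causal locus using only the recessive (mutant) class:
#' r_hat = (H + 2 B) / (2 n). Each recombinant gamete turns one `A` dose
#' into a non-`A` dose, so `H` carries one and `B` two recombinant gametes.
#'
#' @param codes character vector of genotype codes (`A`/`H`/`B`; `"-"` and
#'   `NA` are dropped).
#' @return estimated recombination fraction in `[0, 1]`.
#' @export
est_recomb_fraction <- function(codes) {
  codes <- as.character(codes)
  codes <- codes[!is.na(codes) & codes != "-"]
  if (length(codes) == 0) abort("no genotype codes")
  (sum(codes == "H") + 2 * sum(codes == "B")) / (2 * length(codes))
}

#' Simulate recessive-class F2 marker genotypes around a causal locus
#'
#' For each phenotypic-mutant F2 individual (genotype `aa` at the causal
#' locus) and each marker, both gametes independently recombine between the
#' marker and the locus with probability given by the Haldane map function
#' of their distance, yielding marker genotypes `A` with probability
#' `(1-r)^2`, `H` with `2r(1-r)` and `B` with `r^2`.
#'
#' @param n_ind number of mutant individuals.
#' @param marker_cm named numeric vector of marker positions (cM), ordered.
#' @param locus_cm causal-locus position (cM).
#' @param seed integer seed.
#' @return tibble of codes, one column per marker.
#' @export
simulate_f2_mutant_markers <- function(n_ind, marker_cm, locus_cm, seed) {
  if (is.null(names(marker_cm))) {
    names(marker_cm) <- paste0("M", seq_along(marker_cm))
  }
  with_seed(seed, {
    cols <- lapply(marker_cm, function(pos) {
      d <- abs(pos - locus_cm)
      r <- 0.5 * (1 - exp(-2 * d / 100))
      n_rec <- rbinom(n_ind, 2L, r)
      c("A", "H", "B")[n_rec + 1L]
    })
    tibble::as_tibble(cols)
  })
}

#' Chlorophyll contents from ethanol-extract absorbances
#'
#' Applies the spectrophotometric equations for 95% ethanol extracts read
#' at 665 and 649 nm:
#' Chl a (mg/g) = ((13.95 OD665 - 6.88 OD649) x 10) / (fw(g) x 1000),
#' Chl b (mg/g) = ((24.96 OD649 - 7.32 OD665) x 10) / (fw(g) x 1000),
#' total = a + b, ratio = a / b. A physically impossible absorbance
#' combination yielding a negative pigment value is flagged, not clamped.
#'
#' @param od665,od649 absorbances (>= 0), vectorised.
#' @param fresh_weight_g tissue fresh weight in grams (> 0).
#' @return tibble `chl_a`, `chl_b`, `chl_total` (mg per g fresh weight),
#'   `ratio_ab` (`NA` when `chl_b` is 0) and `negative_value` flag.
#' @export
chlorophyll <- function(od665, od649, fresh_weight_g) {
  if (any(od665 < 0) || any(od649 < 0)) abort("absorbances must be >= 0")
  if (any(fresh_weight_g <= 0)) abort("fresh weight must be positive")
  chl_a <- (13.95 * od665 - 6.88 * od649) * 10 / (fresh_weight_g * 1000)
  chl_b <- (24.96 * od649 - 7.32 * od665) * 10 / (fresh_weight_g * 1000)
  tibble::tibble(
    chl_a = chl_a, chl_b = chl_b, chl_total = chl_a + chl_b,
    ratio_ab = ifelse(chl_b != 0, chl_a / chl_b, NA_real_),
    negative_value = chl_a < 0 | chl_b < 0
  )
}

#' Relative expression by the 2^-dCt method
#'
#' @param ct_target Ct value(s) of the target gene.
#' @param ct_reference Ct of the reference gene; a data frame or matrix of
#'   several reference genes is combined by the arithmetic mean per sample.
#' @return fold expression 2^-(Ct_target - Ct_reference).
#' @export
relative_expression <- function(ct_target, ct_reference) {
  if (is.data.frame(ct_reference) || is.matrix(ct_reference)) {
    ct_reference <- rowMeans(as.matrix(ct_reference))
  }
  if (!all(is.finite(ct_target)) || !all(is.finite(ct_reference))) {
    abort("Ct values must be finite")
  }
  2^(-(ct_target - ct_reference))
}

#' Percentage of a reference value
#'
#' @param value measured quantity (vectorised).
#' @param reference reference quantity (> 0).
#' @param digits decimal places for reporting (default 0, i.e. nearest
#'   integer); `NULL` for full precision.
#' @return `100 * value / reference`, rounded as requested.
#' @export
percent_of <- function(value, reference, digits = 0) {
  if (any(reference <= 0)) abort("reference must be positive")
  pct <- 100 * value / reference
  if (is.null(digits)) pct else round(pct, digits)
}
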