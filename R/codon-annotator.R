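# standard genetic code on lowercase RNA codons; "*" marks stop.
# Kept as an explicit table so tests can cross-check it against an external
# implementation.
GENETIC_CODE_RNA <- c(
  uuu = "F", uuc = "F", uua = "L", uug = "L",
  cuu = "L", cuc = "L", cua = "L", cug = "L",
  auu = "I", auc = "I", aua = "I", aug = "M",
  guu = "V", guc = "V", gua = "V", gug = "V",
  ucu = "S", ucc = "S", uca = "S", ucg = "S",
  ccu = "P", ccc = "P", cca = "P", ccg = "P",
  acu = "T", acc = "T", aca = "T", acg = "T",
  gcu = "A", gcc = "A", gca = "A", gcg = "A",
  uau = "Y", uac = "Y", uaa = "*", uag = "*",
  cau = "H", cac = "H", caa = "Q", cag = "Q",
  aau = "N", aac = "N", aaa = "K", aag = "K",
  gau = "D", gac = "D", gaa = "E", gag = "E",
  ugu = "C", ugc = "C", uga = "*", ugg = "W",
  cgu = "R", cgc = "R", cga = "R", cgg = "R",
  agu = "S", agc = "S", aga = "R", agg = "R",
  ggu = "G", ggc = "G", gga = "G", ggg = "G"
)

#' Translate an RNA codon
#' @param codon lowercase 3-base RNA codon(s) (`a`, `c`, `g`, `u`).
#' @return single-letter amino acid(s); `"*"` for a stop codon.
#' @export
translate_codon <- function(codon) {
  aa <- GENETIC_CODE_RNA[tolower(codon)]
  if (any(is.na(aa))) abort("not a valid RNA codon")
  unname(aa)
}

#' Codon site of a transcript position
#'
#' The codon site is the order of the edited nucleotide within its amino
#' acid codon (1, 2 or 3), for positions counted 1-based from the first
#' base of the initiation codon.
#'
#' @param transcript_pos positive integer position(s).
#' @return integer codon site(s) in `{1, 2, 3}`.
#' @export
codon_site <- function(transcript_pos) {
  if (any(transcript_pos < 1)) abort("transcript position must be >= 1")
  ((as.integer(transcript_pos) - 1L) %% 3L) + 1L
}

format_codon <- function(codon, site) {
  paste0(substr(codon, 1, site - 1),
         toupper(substr(codon, site, site)),
         substr(codon, site + 1, 3))
}

#' Amino-acid conversion string for an editing event
#'
#' Formats the codon change of an edit as `X(abc)→Y(abd)`: the edited
#' position is uppercased in both codons, amino acids use single-letter
#' code, and an edited codon that becomes a stop is written as the literal
#' token `stop codon`. Synonymous edits keep the same letter on both
#' sides. The edited base is `c` (converted to `u`, the canonical C-to-U
#' event) or `g` (converted to `a`, the rare reverse-appearance class seen
#' in published organelle editotypes); anything else errors.
#'
#' @param ref_codon lowercase 3-base RNA codon carrying `c` (or `g`) at
#'   `site`.
#' @param site codon site (1, 2 or 3) of the edited base.
#' @return formatted conversion string, e.g. `"S(uCa)→L(uUa)"`.
#' @export
conversion_string <- function(ref_codon, site) {
  ref_codon <- tolower(ref_codon)
  if (nchar(ref_codon) != 3) abort("ref_codon must have 3 bases")
  if (!site %in% 1:3) abort("codon site must be 1, 2 or 3")
  base <- substr(ref_codon, site, site)
  if (!base %in% c("c", "g")) {
    abort("base at the codon site is neither c nor g; not an editable codon")
  }
  edited <- ref_codon
  substr(edited, site, site) <- if (base == "c") "u" else "a"
  aa_ref <- translate_codon(ref_codon)
  aa_ed <- translate_codon(edited)
  left <- paste0(aa_ref, "(", format_codon(ref_codon, site), ")")
  right <- if (aa_ed == "*") {
    paste0("stop codon (", format_codon(edited, site), ")")
  } else {
    paste0(aa_ed, "(", format_codon(edited, site), ")")
  }
  paste0(left, "→", right)
}

dna_to_rna <- function(x) tolower(chartr("Tt", "Uu", x))

annotate_one <- function(gpos, genes, sequence, gene_ids, conflict) {
  rows <- list()
  for (id in gene_ids) {
    loc <- genome_to_transcript(genes, id, gpos)
    if (loc$region == "outside") next
    if (loc$region == "intron" || conflict) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene_id = id, region = loc$region,
        transcript_pos = loc$transcript_pos,
        codon_index = NA_integer_, codon_site = NA_integer_,
        ref_codon = NA_character_, edited_codon = NA_character_,
        conversion = NA_character_, orientation_conflict = conflict
      )
      next
    }
    tp <- loc$transcript_pos
    ci <- (tp - 1L) %/% 3L + 1L
    cs <- codon_site(tp)
    cds <- spliced_cds(genes, sequence, id)
    codon <- dna_to_rna(substr(cds, 3L * ci - 2L, 3L * ci))
    if (substr(codon, cs, cs) == "c") {
      edited <- codon
      substr(edited, cs, cs) <- "u"
      conv <- conversion_string(codon, cs)
    } else {
      edited <- NA_character_
      conv <- NA_character_
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene_id = id, region = "CDS", transcript_pos = tp,
      codon_index = ci, codon_site = cs,
      ref_codon = codon, edited_codon = edited, conversion = conv,
      orientation_conflict = conflict
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      gene_id = NA_character_, region = "intergenic",
      transcript_pos = NA_integer_, codon_index = NA_integer_,
      codon_site = NA_integer_, ref_codon = NA_character_,
      edited_codon = NA_character_, conversion = NA_character_,
      orientation_conflict = FALSE
    ))
  }
  dplyr::bind_rows(rows)
}

#' Annotate editing calls with gene-relative codon information
#'
#' Maps each call's genome position onto the overlapping gene model(s):
#' exonic sites get the spliced transcript position from the initiation
#' codon, the codon index and site, the reference and edited codons (RNA
#' alphabet) and the formatted conversion string; intronic sites are
#' annotated `region = "intron"` with their unspliced pre-mRNA position and
#' no codon fields; sites overlapping no gene are `"intergenic"`. All
#' matching-strand overlapping genes are reported, one row each; a call
#' whose orientation conflicts with every overlapping gene is flagged
#' `orientation_conflict`.
#'
#' @param calls call tibble with columns `seqid`, `pos` and `strand`
#'   (orientation inferred by the caller; may be `NA`).
#' @param genes gene-model tibble.
#' @param sequence genome sequence string matching the gene models.
#' @return one annotation row per call x overlapping gene: the call key
#'   plus `gene_id`, `region`, `transcript_pos`, `codon_index`,
#'   `codon_site`, `ref_codon`, `edited_codon`, `conversion`,
#'   `orientation_conflict`.
#' @export
annotate_sites <- function(calls, genes, sequence) {
  validate_gene_models(genes)
  ids <- unique(genes$gene_id)
  spans <- genes |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(span_start = min(.data$start), span_end = max(.data$end),
                     .groups = "drop")
  strand_of <- genes$strand[match(spans$gene_id, genes$gene_id)]
  purrr::map_dfr(seq_len(nrow(calls)), function(i) {
    gpos <- calls$pos[i]
    call_strand <- calls$strand[i]
    over <- spans$span_start <= gpos & gpos <= spans$span_end
    matching <- over & (is.na(call_strand) | strand_of == call_strand)
    if (any(matching)) {
      ann <- annotate_one(gpos, genes, sequence, spans$gene_id[matching],
                          conflict = FALSE)
    } else {
      ann <- annotate_one(gpos, genes, sequence, spans$gene_id[over],
                          conflict = TRUE)
    }
    dplyr::bind_cols(
      tibble::tibble(seqid = calls$seqid[i], genome_pos = gpos,
                     strand = calls$strand[i])[rep(1, nrow(ann)), ],
      ann
    )
  })
}
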