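#' Gene models for a plastid genome
#'
#' Gene models are plain tibbles with one row per exon and columns
#' `gene_id`, `seqid`, `strand` (`"+"` or `"-"`), `exon` (1-based index in
#' transcript order, 5' to 3'), `start`, `end` (1-based inclusive genome
#' coordinates). Exons are the coding segments: transcript position 1 is the
#' first base of the initiation codon, so a spliced CDS length divisible by 3
#' is required. The helpers below map between genome and transcript
#' coordinates on either strand; positions falling between exons of a gene
#' are intronic and are located on the unspliced pre-mRNA instead.
#'
#' @param genes gene-model tibble as described above.
#' @return `validate_gene_models()` returns its input invisibly after
#'   checking column presence, strand codes, exon ordering and the
#'   divisibility of each spliced CDS length by 3.
#' @export
validate_gene_models <- function(genes) {
  needed <- c("gene_id", "seqid", "strand", "exon", "start", "end")
  missing <- setdiff(needed, names(genes))
  if (length(missing) > 0) {
    abort(paste0("gene models lack column(s): ", paste(missing, collapse = ", ")))
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("gene model strand must be '+' or '-'")
  }
  if (any(genes$end < genes$start)) {
    abort("gene model exon with end < start")
  }
  bad_len <- genes |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(len = sum(.data$end - .data$start + 1L), .groups = "drop") |>
    dplyr::filter(.data$len %% 3L != 0L)
  if (nrow(bad_len) > 0) {
    abort(paste0("spliced CDS length not a multiple of 3 for: ",
                 paste(bad_len$gene_id, collapse = ", ")))
  }
  invisible(genes)
}

# exon table for one gene, in transcript (5'->3') order, with cumulative
# spliced offsets
gene_exon_table <- function(genes, id) {
  ex <- genes |>
    dplyr::filter(.data$gene_id == id) |>
    dplyr::arrange(.data$exon)
  if (nrow(ex) == 0) abort(paste0("unknown gene_id: ", id))
  ex$len <- ex$end - ex$start + 1L
  ex$cum_end <- cumsum(ex$len)
  ex$cum_before <- ex$cum_end - ex$len
  ex
}

#' Spliced CDS length of a gene
#' @param genes gene-model tibble.
#' @param id a single gene id.
#' @return integer number of spliced CDS bases.
#' @export
spliced_length <- function(genes, id) {
  ex <- gene_exon_table(genes, id)
  sum(ex$len)
}

#' Map transcript positions to genome positions
#'
#' Transcript positions are 1-based from the first base of the initiation
#' codon on the spliced transcript.
#'
#' @param genes gene-model tibble.
#' @param id a single gene id.
#' @param tpos integer vector of transcript positions.
#' @return integer vector of 1-based genome positions.
#' @export
transcript_to_genome <- function(genes, id, tpos) {
  ex <- gene_exon_table(genes, id)
  L <- sum(ex$len)
  if (any(tpos < 1 | tpos > L)) {
    abort("transcript position outside spliced CDS")
  }
  k <- findInterval(tpos - 1L, c(0L, ex$cum_end[-nrow(ex)] ))
  off <- tpos - ex$cum_before[k]
  ifelse(ex$strand[k] == "+",
         ex$start[k] + off - 1L,
         ex$end[k] - off + 1L)
}

#' Map genome positions to transcript coordinates
#'
#' Exonic positions get a spliced transcript position (`region = "CDS"`);
#' positions inside the gene span but between exons get the unspliced
#' pre-mRNA position counted from the initiation codon (`region = "intron"`);
#' positions outside the span get `region = "outside"` and `NA`.
#'
#' @param genes gene-model tibble.
#' @param id a single gene id.
#' @param gpos integer vector of 1-based genome positions.
#' @return a tibble with columns `genome_pos`, `region`, `transcript_pos`.
#' @export
genome_to_transcript <- function(genes, id, gpos) {
  ex <- gene_exon_table(genes, id)
  span_start <- min(ex$start)
  span_end <- max(ex$end)
  plus <- ex$strand[1] == "+"
  tss <- if (plus) span_start else span_end

  region <- character(length(gpos))
  tpos <- integer(length(gpos))
  for (i in seq_along(gpos)) {
    g <- gpos[i]
    if (g < span_start || g > span_end) {
      region[i] <- "outside"
      tpos[i] <- NA_integer_
      next
    }
    hit <- which(ex$start <= g & g <= ex$end)
    if (length(hit) == 1) {
      region[i] <- "CDS"
      off <- if (plus) g - ex$start[hit] + 1L else ex$end[hit] - g + 1L
      tpos[i] <- ex$cum_before[hit] + off
    } else {
      region[i] <- "intron"
      tpos[i] <- if (plus) g - tss + 1L else tss - g + 1L
    }
  }
  tibble::tibble(genome_pos = gpos, region = region, transcript_pos = tpos)
}

#' Extract the spliced CDS sequence of a gene
#'
#' @param genes gene-model tibble.
#' @param sequence genome sequence as a single character string (DNA
#'   alphabet).
#' @param id a single gene id.
#' @return upper-case DNA string of the spliced CDS in transcript
#'   orientation (reverse-complemented for minus-strand genes).
#' @export
spliced_cds <- function(genes, sequence, id) {
  ex <- gene_exon_table(genes, id)
  # genome order: ascending starts regardless of strand
  exg <- ex[order(ex$start), ]
  parts <- substring(sequence, exg$start, exg$end)
  cds <- paste(parts, collapse = "")
  if (ex$strand[1] == "-") {
    cds <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  }
  toupper(cds)
}
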