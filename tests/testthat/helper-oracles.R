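# one-column pileup builder for hand-constructed caller cases
pcol <- function(pos, ref, A = 0, C = 0, G = 0, T = 0, seqid = "pt") {
  tibble::tibble(seqid = seqid, pos = as.integer(pos), ref = ref,
                 depth = as.integer(A + C + G + T),
                 A = as.integer(A), C = as.integer(C),
                 G = as.integer(G), T = as.integer(T))
}

# literal brute-force site scan: applies the three discovery predicates
# position by position, independently of the package's vectorised path
brute_force_discover <- function(dna, rna, min_depth = 20,
                                 dna_max_alt = 0.02, min_frac = 0.05) {
  idx <- match(paste(dna$seqid, dna$pos), paste(rna$seqid, rna$pos))
  rows <- list()
  for (i in seq_len(nrow(dna))) {
    ref <- dna$ref[i]
    if (!(ref %in% c("C", "G"))) next
    j <- idx[i]
    if (is.na(j)) next
    if (dna$depth[i] < min_depth) next
    if (rna$depth[j] < min_depth) next
    ref_count <- if (ref == "C") dna$C[i] else dna$G[i]
    if ((dna$depth[i] - ref_count) / dna$depth[i] > dna_max_alt) next
    edited <- if (ref == "C") rna$T[j] else rna$A[j]
    unedited <- if (ref == "C") rna$C[j] else rna$G[j]
    if (edited / rna$depth[j] < min_frac) next
    rows[[length(rows) + 1]] <- data.frame(
      seqid = dna$seqid[i], pos = dna$pos[i],
      strand = if (ref == "C") "+" else "-",
      unedited = unedited, edited = edited,
      efficiency = 100 * edited / (edited + unedited),
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(data.frame(seqid = character(), pos = integer(),
                      strand = character(), unedited = integer(),
                      edited = integer(), efficiency = numeric()))
  }
  do.call(rbind, rows)
}

# reverse-complement a whole pileup table: positions flip around the genome
# end, reference bases complement, and counts swap A<->T, C<->G
revcomp_pileup <- function(pileup, genome_length) {
  tibble::tibble(
    seqid = pileup$seqid,
    pos = as.integer(genome_length - pileup$pos + 1L),
    ref = chartr("ACGT", "TGCA", pileup$ref),
    depth = pileup$depth,
    A = pileup$T, C = pileup$G, G = pileup$C, T = pileup$A
  ) |> dplyr::arrange(pos)
}

sample_cols <- function(pileups, label) {
  dplyr::filter(pileups, sample == label)[
    c("seqid", "pos", "ref", "depth", "A", "C", "G", "T")]
}
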