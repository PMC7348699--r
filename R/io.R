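#' Read and write genome FASTA
#'
#' Thin wrappers over Biostrings for the single-sequence plastid genomes
#' used throughout the package.
#'
#' @param genome_id sequence name.
#' @param sequence genome sequence string.
#' @param path file path.
#' @return `read_genome_fasta()` returns `list(genome_id, sequence)`.
#' @export
write_genome_fasta <- function(genome_id, sequence, path) {
  x <- Biostrings::DNAStringSet(setNames(sequence, genome_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  list(genome_id = names(x)[1], sequence = as.character(x[[1]]))
}

#' Read and write gene models as GFF3
#'
#' Writes one `gene` feature per gene (the genomic span) and one `CDS`
#' feature per exon, 1-based inclusive, with `Parent` linking. Reading
#' reconstructs the exon tibble, numbering exons 5' to 3' on the
#' transcript.
#'
#' @param genes gene-model tibble.
#' @param path file path.
#' @return `read_gene_models()` returns a gene-model tibble.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  validate_gene_models(genes)
  spans <- genes |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(seqid = .data$seqid[1], strand = .data$strand[1],
                     start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  gene_gr <- GenomicRanges::GRanges(
    seqnames = spans$seqid,
    ranges = IRanges::IRanges(spans$start, spans$end),
    strand = spans$strand,
    type = "gene", ID = spans$gene_id, Parent = NA_character_
  )
  cds <- genes |>
    dplyr::arrange(.data$gene_id, .data$exon) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(
      cum_before = cumsum(.data$end - .data$start + 1L) -
        (.data$end - .data$start + 1L),
      phase = (3L - .data$cum_before %% 3L) %% 3L
    ) |>
    dplyr::ungroup()
  cds_gr <- GenomicRanges::GRanges(
    seqnames = cds$seqid,
    ranges = IRanges::IRanges(cds$start, cds$end),
    strand = cds$strand,
    type = "CDS",
    ID = paste0(cds$gene_id, ".cds", cds$exon),
    Parent = cds$gene_id,
    phase = as.integer(cds$phase)
  )
  gr <- c(gene_gr, cds_gr)
  gr <- gr[order(GenomicRanges::start(gr),
                 S4Vectors::mcols(gr)$type != "gene")]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_models_gff3
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[S4Vectors::mcols(gr)$type == "CDS"]
  parent <- as.character(S4Vectors::mcols(cds)$Parent)
  tb <- tibble::tibble(
    gene_id = parent,
    seqid = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(GenomicRanges::strand(cds)),
    start = GenomicRanges::start(cds),
    end = GenomicRanges::end(cds)
  )
  tb <- tb |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(
      dplyr::if_else(.data$strand == "+", .data$start, -.data$start),
      .by_group = TRUE
    ) |>
    dplyr::mutate(exon = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "seqid", "strand", "exon", "start", "end")
  validate_gene_models(tb)
  tb
}

PILEUP_COLS <- c("seqid", "pos", "ref", "depth", "A", "C", "G", "T")

#' Read and write pileup tables
#'
#' Canonical pileup TSV: header line then columns `seqid`, `pos` (1-based),
#' `ref`, `depth`, `A`, `C`, `G`, `T`.
#'
#' @param pileup a pileup tibble (extra identifying columns are dropped on
#'   write).
#' @param path file path.
#' @return `read_pileup()` returns a pileup tibble.
#' @export
write_pileup <- function(pileup, path) {
  readr::write_tsv(pileup[PILEUP_COLS], path)
  invisible(path)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    seqid = readr::col_character(), pos = readr::col_integer(),
    ref = readr::col_character(), depth = readr::col_integer(),
    A = readr::col_integer(), C = readr::col_integer(),
    G = readr::col_integer(), T = readr::col_integer()
  ))
}

#' Write one pileup TSV per sample
#'
#' @param pileups long pileup tibble from [simulate_pileups()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths.
#' @export
write_pileups <- function(pileups, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- unique(pileups$sample)
  paths <- setNames(file.path(dir, paste0(samples, ".pileup.tsv")), samples)
  for (s in samples) {
    write_pileup(dplyr::filter(pileups, .data$sample == s), paths[[s]])
  }
  invisible(paths)
}

#' Read and write planted-truth tables
#' @param truth truth tibble from [plant_sites()].
#' @param path file path.
#' @return `read_truth()` returns a truth tibble.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), transcript_pos = readr::col_integer(),
    genome_pos = readr::col_integer(), strand = readr::col_character(),
    edited_base = readr::col_character(), class = readr::col_character(),
    eff_WT = readr::col_double(), eff_mut = readr::col_double()
  ))
}

#' Published catalogue of soybean chloroplast editing sites
#'
#' Loads the packaged transcription of the published catalogue of 45
#' editing sites in soybean chloroplast transcripts: gene, position with
#' respect to the initiation codon, codon site and amino-acid conversion
#' string for the 43 coding-region sites, and an intron flag for the 2
#' intronic sites (rps12-554 and rps16-499).
#'
#' @return validated tibble with columns `gene`, `position`, `codon_site`,
#'   `conversion`, `intron`.
#' @export
soybean_editing_sites <- function() {
  path <- system.file("extdata", "soybean_chloroplast_editing_sites.tsv",
                      package = "chloroedit", mustWork = TRUE)
  x <- readr::read_tsv(path, col_types = readr::cols(
    gene = readr::col_character(), position = readr::col_integer(),
    codon_site = readr::col_integer(), conversion = readr::col_character(),
    intron = readr::col_logical()
  ))
  ok <- nrow(x) == 45 &&
    sum(!is.na(x$conversion)) == 43 &&
    sum(x$intron) == 2 &&
    setequal(paste(x$gene[x$intron], x$position[x$intron]),
             c("rps12 554", "rps16 499"))
  if (!ok) abort("packaged editing-site catalogue failed validation")
  x
}

#' Run the full synthetic editing pipeline
#'
#' Orchestrates: genome simulation -> site planting -> pileup simulation ->
#' per-replicate discovery -> union quantification -> replicate pooling ->
#' wild-type vs mutant comparison -> codon annotation -> per-transcript and
#' overall summaries. With an `outdir`, all canonical files (FASTA, GFF3,
#' truth, pileups, pooled calls, differential and summary TSVs, and a run
#' log recording seed and thresholds) are written.
#'
#' @param n_genes,genome_length,n_sites simulation sizes.
#' @param sim a [sim_config()] (must have exactly two genotypes, wild type
#'   first).
#' @param thresholds a [caller_thresholds()].
#' @param alter_threshold differential-class threshold in percentage points.
#' @param class_probs planted class mixture, passed to [plant_sites()].
#' @param seed master seed; identical seeds give identical outputs.
#' @param outdir optional output directory.
#' @return a list: `genome`, `truth`, `pileups`, `calls` (pooled, one
#'   tibble per genotype), `differential`, `annotations`,
#'   `transcript_summary`, `overall`.
#' @export
run_pipeline <- function(n_genes = 6, genome_length = 20000, n_sites = 40,
                         sim = sim_config(), thresholds = caller_thresholds(),
                         alter_threshold = 10,
                         class_probs = c(abolished = 3, decreased = 14,
                                         increased = 2, unchanged = 26) / 45,
                         seed = 1L, outdir = NULL) {
  if (length(sim$genotypes) != 2) {
    abort("run_pipeline needs exactly two genotypes (wild type first)")
  }
  gen <- make_genome(n_genes, genome_length, seed)
  truth <- plant_sites(gen$genes, gen$sequence, n_sites, seed = seed + 1L,
                       class_probs = class_probs)
  pileups <- simulate_pileups(gen$sequence, truth, sim, seed = seed + 2L,
                              genome_id = gen$genome_id)
  dna <- dplyr::filter(pileups, .data$sample == "DNA")[PILEUP_COLS]

  rna_tables <- pileups |>
    dplyr::filter(.data$sample != "DNA") |>
    dplyr::group_by(.data$sample, .data$genotype, .data$replicate)
  keys <- dplyr::group_keys(rna_tables)
  splits <- dplyr::group_split(rna_tables)

  discovered <- purrr::map_dfr(seq_along(splits), function(i) {
    discover_sites(dna, splits[[i]][PILEUP_COLS], thresholds)
  })
  union_sites <- dplyr::distinct(discovered, .data$seqid, .data$pos)

  calls <- lapply(sim$genotypes, function(g) {
    idx <- which(keys$genotype == g)
    per_rep <- purrr::map_dfr(idx, function(i) {
      quantify_known_sites(union_sites, dna, splits[[i]][PILEUP_COLS],
                           thresholds)
    })
    pool_replicates(per_rep)
  })
  names(calls) <- sim$genotypes

  differential <- compare_editing(calls[[1]], calls[[2]],
                                  alter_threshold = alter_threshold)
  if (nrow(differential) > 0) {
    annotations <- annotate_sites(differential, gen$genes, gen$sequence)
    differential <- dplyr::left_join(
      differential,
      dplyr::distinct(annotations, .data$genome_pos, .keep_all = TRUE) |>
        dplyr::select("genome_pos", "gene_id", "region", "transcript_pos",
                      "conversion"),
      by = c(pos = "genome_pos")
    )
    transcript_summary <- summarize_transcripts(
      dplyr::filter(differential, !is.na(.data$gene_id)))
    overall <- overall_alteration(differential)
  } else {
    annotations <- tibble::tibble()
    differential$gene_id <- character(0)
    differential$region <- character(0)
    differential$transcript_pos <- integer(0)
    differential$conversion <- character(0)
    transcript_summary <- tibble::tibble(gene_id = character(0),
                                         n_sites = integer(0),
                                         n_altered = integer(0),
                                         pct_altered = numeric(0))
    overall <- tibble::tibble(n_affected = 0L, n_total = 0L, pct = NA_real_)
  }

  res <- list(genome = gen, truth = truth, pileups = pileups, calls = calls,
              differential = differential, annotations = annotations,
              transcript_summary = transcript_summary, overall = overall)
  if (!is.null(outdir)) write_pipeline_outputs(res, thresholds, seed, outdir)
  res
}

write_pipeline_outputs <- function(res, thresholds, seed, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(res$genome$genome_id, res$genome$sequence,
                     file.path(outdir, "genome.fa"))
  write_gene_models_gff3(res$genome$genes, file.path(outdir, "genes.gff3"))
  write_truth(res$truth, file.path(outdir, "truth.tsv"))
  write_pileups(res$pileups, file.path(outdir, "pileups"))
  for (g in names(res$calls)) {
    readr::write_tsv(res$calls[[g]],
                     file.path(outdir, paste0("calls_", g, ".tsv")))
  }
  readr::write_tsv(res$differential, file.path(outdir, "differential.tsv"))
  readr::write_tsv(res$transcript_summary,
                   file.path(outdir, "transcript_summary.tsv"))
  readr::write_tsv(res$overall, file.path(outdir, "overall.tsv"))
  log_lines <- c(
    paste0("chloroedit ", as.character(utils::packageVersion("chloroedit"))),
    paste0("seed\t", seed),
    paste0("min_depth\t", thresholds$min_depth),
    paste0("dna_max_alt_fraction\t", thresholds$dna_max_alt_fraction),
    paste0("min_rna_edit_fraction\t", thresholds$min_rna_edit_fraction),
    paste0("depth_mode\t", thresholds$depth_mode),
    paste0("n_truth_sites\t", nrow(res$truth)),
    paste0("n_called_sites\t", nrow(res$differential)),
    paste0("overall_pct_altered\t", res$overall$pct)
  )
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(outdir)
}
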