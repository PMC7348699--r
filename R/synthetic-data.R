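#' Simulation configuration
#'
#' Holds the knobs of the pileup simulator: sequencing depths, the per-base
#' error rate and the replicate/genotype layout. Defaults mirror a small
#' organelle resequencing + rRNA-depleted strand-specific RNA-seq design with
#' two biological replicates per genotype.
#'
#' @param dna_depth DNA coverage per position (reads).
#' @param rna_depth RNA coverage per position per replicate (reads).
#' @param error_rate probability that a sequenced base is misread, spread
#'   uniformly over the three other bases; must lie in `[0, 0.1]`.
#' @param replicates_per_genotype biological replicates per genotype (>= 1).
#' @param genotypes character vector of genotype labels; the first is the
#'   reference (wild-type) genotype.
#' @return a `sim_config` list.
#' @export
sim_config <- function(dna_depth = 100L, rna_depth = 200L, error_rate = 0.001,
                       replicates_per_genotype = 2L,
                       genotypes = c("WT", "mut")) {
  if (dna_depth < 1 || rna_depth < 1) abort("depths must be positive")
  if (error_rate < 0 || error_rate > 0.1) abort("error_rate must be in [0, 0.1]")
  if (replicates_per_genotype < 1) abort("replicates_per_genotype must be >= 1")
  if (length(genotypes) < 1) abort("at least one genotype label required")
  structure(
    list(dna_depth = as.integer(dna_depth),
         rna_depth = as.integer(rna_depth),
         error_rate = error_rate,
         replicates_per_genotype = as.integer(replicates_per_genotype),
         genotypes = genotypes),
    class = "sim_config"
  )
}

# deterministic 32-bit sub-seed from (master seed, label); keeps independent
# but reproducible RNG streams per output sample
derive_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(label)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

random_cds <- function(n_codons, start_codon) {
  sense <- setdiff(
    apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = ""),
    STOP_CODONS
  )
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  paste(c(start_codon, body, sample(STOP_CODONS, 1L)), collapse = "")
}

#' Generate a seeded toy plastid genome with gene models
#'
#' Places `n_genes` non-overlapping genes on a random circular genome
#' (genes never span the origin). CDS lengths are multiples of 3, each CDS
#' begins with ATG or ACG (the ACG class models editable-start genes whose
#' initiation codon is created by C-to-U editing), internal stop codons are
#' excluded, and strands alternate so that whenever more than one gene is
#' requested at least one is minus-strand. The first gene always carries a
#' single intron.
#'
#' @param n_genes number of genes to place.
#' @param genome_length genome size in bases.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param genome_id sequence name used in all outputs.
#' @param intron_prob probability that genes after the first carry an intron.
#' @return a list with `genome_id`, `sequence` (character string) and
#'   `genes` (gene-model tibble, one row per exon).
#' @export
make_genome <- function(n_genes, genome_length, seed,
                        genome_id = "synth_plastome", intron_prob = 0.25) {
  if (n_genes < 1) abort("n_genes must be >= 1")
  if (genome_length < 100) abort("genome_length too small")
  with_seed(seed, {
    n_codons <- sample(40:140, n_genes, replace = TRUE)
    cds_len <- 3L * n_codons
    has_intron <- c(TRUE, runif(n_genes - 1L) < intron_prob)
    intron_len <- ifelse(has_intron, sample(80:250, n_genes, replace = TRUE), 0L)
    span <- cds_len + intron_len
    min_gap <- 20L
    slack <- genome_length - sum(span) - min_gap * (n_genes + 1L)
    if (slack < 0) {
      abort(paste0("cannot place ", n_genes, " genes (", sum(span),
                   " gene bases + gaps) in a ", genome_length, "-base genome"),
            class = "chloroedit_capacity_error")
    }
    # random partition of the slack into n_genes + 1 gaps
    cuts <- sort(sample.int(slack + 1L, n_genes, replace = TRUE) - 1L)
    extra <- diff(c(0L, cuts, slack))
    gaps <- min_gap + extra

    strand <- rep(c("+", "-"), length.out = n_genes)
    start_codon <- sample(c("ATG", "ACG"), n_genes, replace = TRUE,
                          prob = c(0.8, 0.2))

    sequence <- random_dna(genome_length)
    exon_rows <- vector("list", n_genes)
    cursor <- 1L
    for (i in seq_len(n_genes)) {
      g0 <- cursor + gaps[i]
      cds <- random_cds(n_codons[i], start_codon[i])
      if (has_intron[i]) {
        s <- sample(seq(3L, cds_len[i] - 3L), 1L)
        unspliced <- paste0(substr(cds, 1L, s),
                            random_dna(intron_len[i]),
                            substr(cds, s + 1L, cds_len[i]))
      } else {
        s <- NA_integer_
        unspliced <- cds
      }
      gene_span <- nchar(unspliced)
      inserted <- if (strand[i] == "+") unspliced else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(unspliced)))
      substr(sequence, g0, g0 + gene_span - 1L) <- inserted

      gid <- sprintf("sg%02d", i)
      if (has_intron[i]) {
        if (strand[i] == "+") {
          ex <- tibble::tibble(
            gene_id = gid, seqid = genome_id, strand = "+",
            exon = c(1L, 2L),
            start = c(g0, g0 + s + intron_len[i]),
            end = c(g0 + s - 1L, g0 + gene_span - 1L)
          )
        } else {
          ex <- tibble::tibble(
            gene_id = gid, seqid = genome_id, strand = "-",
            exon = c(1L, 2L),
            start = c(g0 + gene_span - s, g0),
            end = c(g0 + gene_span - 1L, g0 + gene_span - s - intron_len[i] - 1L)
          )
        }
      } else {
        ex <- tibble::tibble(
          gene_id = gid, seqid = genome_id, strand = strand[i],
          exon = 1L, start = g0, end = g0 + gene_span - 1L
        )
      }
      exon_rows[[i]] <- ex
      cursor <- g0 + gene_span
    }
    genes <- dplyr::bind_rows(exon_rows)
    validate_gene_models(genes)
    list(genome_id = genome_id, sequence = sequence, genes = genes)
  })
}

# default per-class efficiency ranges for planted sites (fractions).
# Classes are separated from the 10-point decision threshold by >= 20 points
# and from the 1-point abolished floor by >= 5 points so that truth labels
# are recoverable at the simulated depths.
draw_class_efficiencies <- function(class) {
  n <- length(class)
  wt <- numeric(n)
  mut <- numeric(n)
  for (i in seq_len(n)) {
    switch(class[i],
      abolished = {
        wt[i] <- runif(1, 0.30, 0.90); mut[i] <- 0
      },
      decreased = {
        wt[i] <- runif(1, 0.40, 0.95)
        mut[i] <- wt[i] - runif(1, 0.20, wt[i] - 0.05)
      },
      increased = {
        wt[i] <- runif(1, 0.10, 0.60)
        mut[i] <- min(wt[i] + runif(1, 0.20, 0.35), 0.98)
      },
      unchanged = {
        wt[i] <- runif(1, 0.10, 0.90); mut[i] <- wt[i]
      },
      abort(paste0("unknown class: ", class[i]))
    )
  }
  list(wt = wt, mut = mut)
}

#' Plant C-to-U editing sites with known per-genotype efficiencies
#'
#' Chooses editable positions (sense-strand C within a spliced CDS; these
#' appear as reference C for plus-strand genes and reference G for
#' minus-strand genes) and assigns each a wild-type and mutant editing
#' efficiency, either drawn per differential class or supplied explicitly.
#' The returned truth table drives [simulate_pileups()] and is the ground
#' truth for recovery tests.
#'
#' @param genes gene-model tibble from [make_genome()].
#' @param sequence genome sequence string.
#' @param n_sites number of sites to plant.
#' @param seed integer seed.
#' @param class_probs named mixture over the four differential classes
#'   (`abolished`, `decreased`, `increased`, `unchanged`); the default
#'   follows a 3:14:2:26 mixture typical of an editing-factor mutant survey.
#' @param efficiencies optional data frame with columns `eff_wt` and
#'   `eff_mut` (fractions in `[0, 1]`, recycled to `n_sites`) overriding the
#'   class-based draws; classes are then derived from the supplied values.
#' @return truth tibble: `gene_id`, `transcript_pos`, `genome_pos`, `strand`,
#'   `edited_base` (reference-strand base read in edited molecules),
#'   `class`, `eff_WT`, `eff_mut`.
#' @export
plant_sites <- function(genes, sequence, n_sites, seed,
                        class_probs = c(abolished = 3, decreased = 14,
                                        increased = 2, unchanged = 26) / 45,
                        efficiencies = NULL) {
  validate_gene_models(genes)
  editable <- purrr::map_dfr(unique(genes$gene_id), function(id) {
    cds <- spliced_cds(genes, sequence, id)
    tp <- which(strsplit(cds, "")[[1]] == "C")
    if (length(tp) == 0) return(NULL)
    st <- genes$strand[genes$gene_id == id][1]
    tibble::tibble(
      gene_id = id,
      transcript_pos = tp,
      genome_pos = transcript_to_genome(genes, id, tp),
      strand = st,
      edited_base = ifelse(st == "+", "T", "A")
    )
  })
  if (n_sites > nrow(editable)) {
    abort(paste0("requested ", n_sites, " sites but only ", nrow(editable),
                 " editable C positions exist"),
          class = "chloroedit_capacity_error")
  }
  with_seed(seed, {
    sites <- editable[sort(sample.int(nrow(editable), n_sites)), ]
    if (is.null(efficiencies)) {
      cls <- sample(names(class_probs), n_sites, replace = TRUE,
                    prob = class_probs)
      eff <- draw_class_efficiencies(cls)
      sites$class <- cls
      sites$eff_WT <- eff$wt
      sites$eff_mut <- eff$mut
    } else {
      eff <- tibble::as_tibble(efficiencies)
      if (!all(c("eff_wt", "eff_mut") %in% names(eff))) {
        abort("efficiencies needs columns eff_wt and eff_mut")
      }
      idx <- rep_len(seq_len(nrow(eff)), n_sites)
      sites$eff_WT <- eff$eff_wt[idx]
      sites$eff_mut <- eff$eff_mut[idx]
      if (any(sites$eff_WT < 0 | sites$eff_WT > 1 |
              sites$eff_mut < 0 | sites$eff_mut > 1)) {
        abort("efficiencies must lie in [0, 1]")
      }
      sites$class <- classify_editing(100 * sites$eff_WT, 100 * sites$eff_mut)
    }
    sites[c("gene_id", "transcript_pos", "genome_pos", "strand",
            "edited_base", "class", "eff_WT", "eff_mut")]
  })
}

# vectorised multinomial: one draw of size `depth` per row of `prob`
# (columns A, C, G, T), by sequential conditional binomials
rmultinom_rows <- function(depth, prob) {
  n <- nrow(prob)
  counts <- matrix(0L, n, 4L)
  remaining <- rep.int(as.integer(depth), n)
  pleft <- rep(1, n)
  for (j in 1:3) {
    pj <- ifelse(pleft > 0, pmin(pmax(prob[, j] / pleft, 0), 1), 0)
    counts[, j] <- rbinom(n, remaining, pj)
    remaining <- remaining - counts[, j]
    pleft <- pleft - prob[, j]
  }
  counts[, 4L] <- remaining
  counts
}

sample_pileup <- function(sequence, depth, error_rate, sites, seed,
                          genome_id) {
  n <- nchar(sequence)
  ref <- strsplit(toupper(sequence), "")[[1]]
  ref_idx <- match(ref, BASES)
  prob <- matrix(error_rate / 3, n, 4L)
  prob[cbind(seq_len(n), ref_idx)] <- 1 - error_rate
  if (!is.null(sites) && nrow(sites) > 0) {
    i <- sites$genome_pos
    e <- sites$eff
    un_idx <- ref_idx[i]
    ed_idx <- match(sites$edited_base, BASES)
    prob[cbind(i, un_idx)] <- (1 - e) * (1 - error_rate) + e * error_rate / 3
    prob[cbind(i, ed_idx)] <- e * (1 - error_rate) + (1 - e) * error_rate / 3
  }
  counts <- with_seed(seed, rmultinom_rows(depth, prob))
  tibble::tibble(
    seqid = genome_id, pos = seq_len(n), ref = ref,
    depth = as.integer(depth),
    A = counts[, 1], C = counts[, 2], G = counts[, 3], T = counts[, 4]
  )
}

#' Simulate DNA and RNA base-count pileups from a planted truth table
#'
#' The DNA sample carries only sequencing error (the genome is unedited).
#' Each RNA sample carries, at every planted site, an edited-base count that
#' is binomial in the site's genotype efficiency: reads are edited with
#' probability `eff`, then misread with probability `error_rate`. Counts are
#' reported on the reference strand, so a minus-strand site appears as A
#' reads at a reference-G position. Every sample gets its own RNG stream
#' derived from `(seed, sample label)`.
#'
#' @param sequence genome sequence string.
#' @param truth truth tibble from [plant_sites()] (may have zero rows).
#' @param config a [sim_config()].
#' @param seed master integer seed.
#' @param genome_id sequence name for the `seqid` column.
#' @return a long tibble of pileup columns with identifying columns
#'   `sample` (e.g. `"DNA"`, `"RNA_WT_1"`), `genotype` (`NA` for DNA),
#'   `replicate`, then `seqid`, `pos`, `ref`, `depth`, `A`, `C`, `G`, `T`.
#' @export
simulate_pileups <- function(sequence, truth, config = sim_config(), seed = 1L,
                             genome_id = "synth_plastome") {
  if (!inherits(config, "sim_config")) abort("config must come from sim_config()")
  out <- list()
  dna <- sample_pileup(sequence, config$dna_depth, config$error_rate,
                       sites = NULL, seed = derive_seed(seed, "DNA"),
                       genome_id = genome_id)
  out[[1]] <- dplyr::bind_cols(
    tibble::tibble(sample = "DNA", genotype = NA_character_,
                   replicate = NA_integer_)[rep(1, nrow(dna)), ], dna)
  k <- 2L
  for (g in config$genotypes) {
    eff_col <- paste0("eff_", g)
    if (nrow(truth) > 0 && !eff_col %in% names(truth)) {
      abort(paste0("truth table lacks column ", eff_col))
    }
    gsites <- if (nrow(truth) > 0) {
      tibble::tibble(genome_pos = truth$genome_pos,
                     edited_base = truth$edited_base,
                     eff = truth[[eff_col]])
    } else NULL
    for (r in seq_len(config$replicates_per_genotype)) {
      label <- sprintf("RNA_%s_%d", g, r)
      p <- sample_pileup(sequence, config$rna_depth, config$error_rate,
                         sites = gsites, seed = derive_seed(seed, label),
                         genome_id = genome_id)
      out[[k]] <- dplyr::bind_cols(
        tibble::tibble(sample = label, genotype = g,
                       replicate = r)[rep(1, nrow(p)), ], p)
      k <- k + 1L
    }
  }
  dplyr::bind_rows(out)
}
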