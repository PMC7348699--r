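test_that("generated genomes have valid, seed-deterministic gene structure", {
  g <- make_genome(6, 20000, seed = 1)
  expect_equal(nchar(g$sequence), 20000)
  ids <- unique(g$genes$gene_id)
  expect_length(ids, 6)
  for (id in ids) {
    L <- spliced_length(g$genes, id)
    expect_equal(L %% 3, 0)
    cds <- spliced_cds(g$genes, g$sequence, id)
    expect_true(substr(cds, 1, 3) %in% c("ATG", "ACG"))
    # single terminal stop codon, none internal
    codons <- substring(cds, seq(1, L - 2, 3), seq(3, L, 3))
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }
  expect_setequal(unique(g$genes$strand), c("+", "-"))
  n_exons <- table(g$genes$gene_id)
  expect_true(any(n_exons > 1))
  # exons of a gene never overlap
  by_gene <- split(g$genes, g$genes$gene_id)
  for (ex in by_gene) {
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1) expect_true(all(ex$start[-1] > ex$end[-nrow(ex)]))
  }

  g2 <- make_genome(6, 20000, seed = 1)
  expect_identical(g, g2)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(g$genome_id, g$sequence, f1)
  write_genome_fasta(g2$genome_id, g2$sequence, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_false(identical(g$sequence, make_genome(6, 20000, seed = 2)$sequence))
})

test_that("a single small gene fits a 3-kb genome but 50 genes cannot", {
  g <- make_genome(1, 3000, seed = 7)
  expect_equal(spliced_length(g$genes, g$genes$gene_id[1]) %% 3, 0)
  expect_error(make_genome(50, 3000, seed = 1),
               class = "chloroedit_capacity_error")
})

test_that("plant_sites honours explicit efficiencies and capacity limits", {
  g <- make_genome(3, 9000, seed = 11)
  tr <- plant_sites(g$genes, g$sequence, 3, seed = 2,
                    efficiencies = data.frame(eff_wt = 0.8, eff_mut = 0))
  expect_equal(nrow(tr), 3)
  expect_equal(tr$eff_mut, rep(0, 3))
  expect_equal(tr$class, rep("abolished", 3))

  tr2 <- plant_sites(g$genes, g$sequence, 2, seed = 2,
                     efficiencies = data.frame(eff_wt = 0.5, eff_mut = 0.5))
  expect_equal(tr2$class, rep("unchanged", 2))

  expect_error(plant_sites(g$genes, g$sequence, 10^6, seed = 1),
               class = "chloroedit_capacity_error")

  # truth sites sit on editable sense-strand Cs inside their gene's CDS
  tr3 <- plant_sites(g$genes, g$sequence, 30, seed = 5)
  for (i in seq_len(nrow(tr3))) {
    cds <- spliced_cds(g$genes, g$sequence, tr3$gene_id[i])
    expect_identical(substr(cds, tr3$transcript_pos[i], tr3$transcript_pos[i]),
                     "C")
  }
  expect_true(all(tr3$eff_WT >= 0 & tr3$eff_WT <= 1))
  expect_true(all(tr3$eff_mut >= 0 & tr3$eff_mut <= 1))
})

test_that("pileup counts conserve depth and recover planted efficiencies", {
  g <- make_genome(2, 6000, seed = 3)
  tr <- plant_sites(g$genes, g$sequence, 1, seed = 4,
                    efficiencies = data.frame(eff_wt = 0.8, eff_mut = 0.8))
  cfg <- sim_config(dna_depth = 50, rna_depth = 1000, error_rate = 0,
                    replicates_per_genotype = 1)
  p <- simulate_pileups(g$sequence, tr, cfg, seed = 9,
                        genome_id = g$genome_id)
  expect_true(all(p$A + p$C + p$G + p$T == p$depth))

  rna <- sample_cols(p, "RNA_WT_1")
  site <- rna[rna$pos == tr$genome_pos, ]
  obs <- if (tr$strand == "+") 100 * site$T / (site$C + site$T) else
    100 * site$A / (site$G + site$A)
  # binomial 99.9% interval at n = 1000, p = 0.8 lies inside [75, 85]
  expect_gt(obs, 75)
  expect_lt(obs, 85)
})

test_that("zero-error pileups without sites are pure reference", {
  g <- make_genome(1, 3000, seed = 5)
  truth <- plant_sites(g$genes, g$sequence, 0, seed = 1)
  cfg <- sim_config(dna_depth = 30, rna_depth = 30, error_rate = 0,
                    replicates_per_genotype = 1)
  p <- simulate_pileups(g$sequence, truth, cfg, seed = 2,
                        genome_id = g$genome_id)
  counts <- as.matrix(p[, c("A", "C", "G", "T")])
  ref_count <- counts[cbind(seq_len(nrow(p)), match(p$ref, c("A", "C", "G", "T")))]
  expect_true(all(ref_count == p$depth))
})

test_that("a fully edited minus-strand site reads as A at a reference G", {
  g <- make_genome(2, 6000, seed = 13)
  minus_gene <- unique(g$genes$gene_id[g$genes$strand == "-"])[1]
  genes_minus <- g$genes[g$genes$gene_id == minus_gene, ]
  tr <- plant_sites(genes_minus, g$sequence, 1, seed = 6,
                    efficiencies = data.frame(eff_wt = 1, eff_mut = 1))
  expect_equal(tr$strand, "-")
  expect_equal(tr$edited_base, "A")
  ref_base <- substr(g$sequence, tr$genome_pos, tr$genome_pos)
  expect_equal(ref_base, "G")

  cfg <- sim_config(dna_depth = 30, rna_depth = 200, error_rate = 0,
                    replicates_per_genotype = 1)
  p <- simulate_pileups(g$sequence, tr, cfg, seed = 7,
                        genome_id = g$genome_id)
  rna <- sample_cols(p, "RNA_WT_1")
  site <- rna[rna$pos == tr$genome_pos, ]
  expect_equal(site$A, site$depth)
})

test_that("pileup simulation is seed-deterministic per sample stream", {
  g <- make_genome(1, 3000, seed = 21)
  tr <- plant_sites(g$genes, g$sequence, 5, seed = 22)
  cfg <- sim_config(dna_depth = 40, rna_depth = 40, error_rate = 0.01)
  p1 <- simulate_pileups(g$sequence, tr, cfg, seed = 30)
  p2 <- simulate_pileups(g$sequence, tr, cfg, seed = 30)
  expect_identical(p1, p2)
  p3 <- simulate_pileups(g$sequence, tr, cfg, seed = 31)
  expect_false(identical(p1, p3))
  # replicate streams differ from each other
  r1 <- sample_cols(p1, "RNA_WT_1"); r2 <- sample_cols(p1, "RNA_WT_2")
  expect_false(identical(r1, r2))
})

test_that("sim_config validates its ranges", {
  expect_error(sim_config(error_rate = 0.2), "error_rate")
  expect_error(sim_config(replicates_per_genotype = 0), "replicates")
  expect_error(sim_config(dna_depth = 0), "depths")
})
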