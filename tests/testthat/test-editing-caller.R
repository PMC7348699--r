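test_that("editing efficiency is U/(C+U) x 100 with an undefined zero case", {
  expect_equal(editing_efficiency(20, 80), 80)
  expect_equal(editing_efficiency(50, 0), 0)
  expect_true(is.na(editing_efficiency(0, 0)))
  expect_equal(editing_efficiency(c(20, 50, 0), c(80, 0, 0)),
               c(80, 0, NA))
  expect_error(editing_efficiency(-1, 5), "non-negative")
})

test_that("discovery applies the depth, homozygosity and fraction predicates", {
  thr <- caller_thresholds()

  # RNA depth 19 at an otherwise perfect site: excluded, rna_depth flag false
  dna <- pcol(10, "C", C = 50)
  rna <- pcol(10, "C", C = 4, T = 15)        # depth 19, fraction 0.79
  expect_equal(nrow(discover_sites(dna, rna, thr)), 0)
  q <- quantify_known_sites(data.frame(seqid = "pt", pos = 10), dna, rna, thr)
  expect_false(q$rna_depth_ok)
  expect_true(q$dna_homozygous)

  # heterozygous DNA cannot be editing
  dna_het <- pcol(10, "C", C = 50, T = 50)
  rna_ok <- pcol(10, "C", C = 10, T = 30)
  expect_equal(nrow(discover_sites(dna_het, rna_ok, thr)), 0)
  q2 <- quantify_known_sites(data.frame(seqid = "pt", pos = 10),
                             dna_het, rna_ok, thr)
  expect_false(q2$dna_homozygous)

  # minus orientation: ref G with RNA A reads
  dna_g <- pcol(44, "G", G = 40)
  rna_g <- pcol(44, "G", G = 30, A = 10)
  call <- discover_sites(dna_g, rna_g, thr)
  expect_equal(nrow(call), 1)
  expect_equal(call$strand, "-")
  expect_equal(call$efficiency, 25)
  expect_equal(call$unedited, 30)
  expect_equal(call$edited, 10)

  # non-C/G reference bases are never scanned
  dna_a <- pcol(5, "A", A = 40)
  rna_a <- pcol(5, "A", A = 10, G = 30)
  expect_equal(nrow(discover_sites(dna_a, rna_a, thr)), 0)
})

test_that("pileup pairs must share reference bases; odd positions are skipped", {
  dna <- pcol(1, "C", C = 30)
  rna_bad <- pcol(1, "G", G = 30)
  expect_error(discover_sites(dna, rna_bad), "mismatched references")

  dna2 <- dplyr::bind_rows(pcol(1, "C", C = 30), pcol(2, "G", G = 30))
  rna2 <- pcol(1, "C", C = 10, T = 20)
  expect_warning(out <- discover_sites(dna2, rna2), "only one pileup")
  expect_equal(out$pos, 1L)
})

test_that("known-site quantification bypasses the discovery fraction floor", {
  thr <- caller_thresholds()
  dna <- pcol(7, "C", C = 60)
  rna <- pcol(7, "C", C = 99, T = 1)     # 1% edited: below discovery floor
  expect_equal(nrow(discover_sites(dna, rna, thr)), 0)
  q <- quantify_known_sites(data.frame(seqid = "pt", pos = 7), dna, rna, thr)
  expect_equal(q$efficiency, 1)
  expect_false(q$min_fraction_ok)

  # depth 5: efficiency still reported, depth flag false
  rna5 <- pcol(7, "C", C = 2, T = 3)
  q5 <- quantify_known_sites(data.frame(seqid = "pt", pos = 7), dna, rna5, thr)
  expect_equal(q5$efficiency, 60)
  expect_false(q5$rna_depth_ok)

  # empty site list and absent site
  expect_equal(nrow(quantify_known_sites(
    data.frame(seqid = character(), pos = integer()), dna, rna, thr)), 0)
  qa <- quantify_known_sites(data.frame(seqid = "pt", pos = 999),
                             dna, rna, thr)
  expect_true(is.na(qa$efficiency))
})

test_that("replicate pooling sums counts and recomputes efficiency", {
  r1 <- pcol(3, "C", C = 10, T = 10) |>
    (\(x) discover_sites(pcol(3, "C", C = 40), x,
                         caller_thresholds(min_depth = 10)))()
  r2 <- discover_sites(pcol(3, "C", C = 40), pcol(3, "C", C = 30, T = 10),
                       caller_thresholds(min_depth = 10))
  pooled <- pool_replicates(dplyr::bind_rows(r1, r2))
  expect_equal(pooled$unedited, 40)
  expect_equal(pooled$edited, 20)
  expect_equal(pooled$efficiency, 100 * 20 / 60)

  # single replicate is the identity on counts and efficiency
  single <- pool_replicates(r1)
  expect_equal(single$unedited, r1$unedited)
  expect_equal(single$efficiency, r1$efficiency)

  # replicate missing a site contributes nothing
  other <- discover_sites(pcol(9, "G", G = 40), pcol(9, "G", G = 5, A = 35),
                          caller_thresholds(min_depth = 10))
  pooled2 <- pool_replicates(dplyr::bind_rows(r1, other))
  expect_equal(nrow(pooled2), 2)
  expect_equal(pooled2$efficiency[pooled2$pos == 9], 87.5)
})

test_that("discovery equals the literal brute-force predicate scan", {
  for (seed in 1:4) {
    g <- make_genome(2, 4000, seed = seed)
    tr <- plant_sites(g$genes, g$sequence, 6, seed = seed + 100)
    cfg <- sim_config(dna_depth = 60, rna_depth = 80, error_rate = 0.01,
                      replicates_per_genotype = 1)
    p <- simulate_pileups(g$sequence, tr, cfg, seed = seed,
                          genome_id = g$genome_id)
    dna <- sample_cols(p, "DNA")
    rna <- sample_cols(p, "RNA_WT_1")
    got <- discover_sites(dna, rna)
    want <- brute_force_discover(dna, rna)
    expect_equal(got$pos, want$pos)
    expect_equal(got$strand, want$strand)
    expect_equal(got$unedited, want$unedited)
    expect_equal(got$edited, want$edited)
    expect_equal(got$efficiency, want$efficiency)
  }
})

test_that("raising min_depth never adds a called site", {
  g <- make_genome(2, 4000, seed = 31)
  tr <- plant_sites(g$genes, g$sequence, 8, seed = 32)
  cfg <- sim_config(dna_depth = 40, rna_depth = 60, error_rate = 0.005,
                    replicates_per_genotype = 1)
  p <- simulate_pileups(g$sequence, tr, cfg, seed = 33,
                        genome_id = g$genome_id)
  dna <- sample_cols(p, "DNA"); rna <- sample_cols(p, "RNA_WT_1")
  prev <- NULL
  for (md in c(5, 20, 41, 61)) {
    cur <- discover_sites(dna, rna, caller_thresholds(min_depth = md))$pos
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("reverse-complementing the genome flips orientations only", {
  g <- make_genome(2, 5000, seed = 41)
  tr <- plant_sites(g$genes, g$sequence, 6, seed = 42)
  cfg <- sim_config(dna_depth = 50, rna_depth = 80, error_rate = 0,
                    replicates_per_genotype = 1)
  p <- simulate_pileups(g$sequence, tr, cfg, seed = 43,
                        genome_id = g$genome_id)
  dna <- sample_cols(p, "DNA"); rna <- sample_cols(p, "RNA_WT_1")
  fwd <- discover_sites(dna, rna)
  rev <- discover_sites(revcomp_pileup(dna, 5000), revcomp_pileup(rna, 5000))
  expect_equal(sort(5000 - rev$pos + 1), sort(fwd$pos))
  m <- merge(data.frame(pos = 5000 - rev$pos + 1, strand_rev = rev$strand),
             data.frame(pos = fwd$pos, strand_fwd = fwd$strand), by = "pos")
  expect_true(all(m$strand_rev != m$strand_fwd))
})
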