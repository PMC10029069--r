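mk_snv <- function(pos, ref, alt, chrom = "chr1")
  list(chrom = chrom, pos = pos, ref = ref, alt = alt)

test_that("homopolymer runs flag matching indels only", {
  cons <- rule_profile("conservative")
  len <- rule_profile("lenient")
  #            1234567890123456789012345
  ctx5 <-     "GCTGCTGCAAAAACGTGCTGAGCTA"   # A x 5 at positions 10-14
  del <- variant_bundle("chr1", 107, "CA", "C", "frameshift")  # deletes pos 108 (A)
  r_cons <- homopolymer_run(ctx5, 100, del, cons)
  expect_equal(r_cons$run_length, 5)
  expect_true(r_cons$flagged)
  expect_false(homopolymer_run(ctx5, 100, del, len)$flagged)  # lenient needs 7

  ctx7 <- "GCTGCTGCAAAAAAACGTGCTGAGC"      # A x 7 at positions 10-16
  ins <- variant_bundle("chr1", 111, "A", "AA", "frameshift")
  expect_true(homopolymer_run(ctx7, 100, ins, cons)$flagged)
  expect_true(homopolymer_run(ctx7, 100, ins, len)$flagged)

  # SNV inside the run: never homopolymer-flagged (slippage is indel-specific)
  snv <- variant_bundle("chr1", 112, "A", "G", "nonsense")
  r <- homopolymer_run(ctx7, 100, snv, cons)
  expect_equal(r$run_length, 7)
  expect_false(r$flagged)

  # indel of a base that does not match the adjacent run
  del_g <- variant_bundle("chr1", 107, "CG", "C", "frameshift")
  expect_false(homopolymer_run("GCTGCTGCGAAAAAAACGTGCTGAGC", 100, del_g,
                               cons)$flagged)
  expect_error(homopolymer_run("AAAA", 108, del, cons), "too small")
})

test_that("MNV combination matches brute-force haplotype translation", {
  # toy gene built by the fixture machinery so the genome string is in hand
  for (strand in c("+", "-")) {
    set.seed(11)
    spec <- toy_gene_spec(c(50, 50, 100))
    spec <- set_codon(spec, 60, "TCA")
    g <- realize_gene(spec, "chr1", strand, "g1", "t1")
    ref_seq <- Biostrings::DNAStringSet(c(chr1 = g$seq))

    snv_at <- function(off, alt_tx) {
      v <- gv_snv(g, off, alt_tx)
      mk_snv(v$pos, v$ref, v$alt)
    }
    # TCA codon: C>G alone gives TGA (stop); with A>G the joint codon is TGG
    v1 <- snv_at(178, "G"); v2 <- snv_at(179, "G")
    pg <- phase_group("pg", list(v1, v2))
    expect_equal(combine_mnv(pg, g$map, ref_seq), "missense")
    expect_equal(oracle_mnv(g$seq, g$transcript, list(v1, v2)), "missense")

    # GAA codon: G>T gives TAA (stop); with A>G at position 3 the joint
    # codon is TAG, still a stop
    set.seed(11)
    spec2 <- set_codon(toy_gene_spec(c(50, 50, 100)), 60, "GAA")
    g2 <- realize_gene(spec2, "chr1", strand, "g1", "t1")
    sa2 <- function(off, alt) { v <- gv_snv(g2, off, alt); mk_snv(v$pos, v$ref, v$alt) }
    pg2 <- phase_group("pg", list(sa2(177, "T"), sa2(179, "G")))
    expect_equal(combine_mnv(pg2, g2$map, Biostrings::DNAStringSet(c(chr1 = g2$seq))),
                 "nonsense_retained")

    # single SNV or SNVs in different codons: not an MNV
    expect_equal(combine_mnv(phase_group("pg", list(v1)), g$map, ref_seq),
                 "not_mnv")
    far <- snv_at(60, "A")
    expect_equal(combine_mnv(phase_group("pg", list(v1, far)), g$map, ref_seq),
                 "not_mnv")
  }
})

test_that("MNV combination agrees with the oracle over all codons and SNV pairs", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  prof <- rule_profile("conservative")
  n_checked <- 0
  for (cod in codons) {
    set.seed(11)
    spec <- set_codon(toy_gene_spec(c(50, 50, 100)), 60, cod)
    g <- realize_gene(spec, "chr1", "+", "g1", "t1")
    ref_seq <- Biostrings::DNAStringSet(c(chr1 = g$seq))
    cb <- strsplit(cod, "")[[1]]
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
      # one representative alt per position (cycled) keeps the grid tractable
      a1 <- setdiff(bases, cb[pair[1]])[1 + n_checked %% 3]
      a2 <- setdiff(bases, cb[pair[2]])[1 + (n_checked %/% 3) %% 3]
      offs <- 177 + pair - 1
      v1 <- gv_snv(g, offs[1], a1); v2 <- gv_snv(g, offs[2], a2)
      snvs <- list(mk_snv(v1$pos, v1$ref, v1$alt), mk_snv(v2$pos, v2$ref, v2$alt))
      got <- combine_mnv(phase_group("pg", snvs), g$map, ref_seq)
      expect_equal(got, oracle_mnv(g$seq, g$transcript, snvs),
                   label = paste("codon", cod, "pair", paste(pair, collapse = ",")))
      n_checked <- n_checked + 1
    }
  }
  expect_equal(n_checked, 64 * 3)
})

test_that("net indel frame shift is additive and order-invariant", {
  prof <- rule_profile("conservative")
  ins1 <- mk_snv(110, "C", "CG")            # +1
  del1 <- mk_snv(122, "CA", "C")            # -1
  del2 <- mk_snv(130, "CAT", "C")           # -2
  r <- net_indel_frame(phase_group("p", list(ins1, del1)), prof)
  expect_equal(r$net_shift, 0); expect_true(r$frame_restoring)
  # aggregate -3 is an in-frame deletion
  r2 <- net_indel_frame(phase_group("p", list(del1, del2)), prof)
  expect_equal(r2$net_shift, 0); expect_true(r2$frame_restoring)
  # a lone -1 deletion is not rescued
  r3 <- net_indel_frame(phase_group("p", list(del1)), prof)
  expect_equal(r3$net_shift, 2); expect_false(r3$frame_restoring)
  # permutation invariance and mod-3 additivity over random groups
  set.seed(42)
  pool <- list(ins1, del1, del2, mk_snv(140, "T", "TAAG"), mk_snv(150, "TGCTG", "T"))
  for (i in 1:20) {
    k <- sample(2:5, 1)
    grp <- sample(pool, k, replace = TRUE)
    n1 <- net_indel_frame(phase_group("p", grp), prof)$net_shift
    n2 <- net_indel_frame(phase_group("p", rev(grp)), prof)$net_shift
    expect_equal(n1, n2)
    half <- sample(k, 1)
    na <- net_indel_frame(phase_group("p", grp[seq_len(half)]), prof)$net_shift
    nb <- net_indel_frame(phase_group("p", grp[-seq_len(half)]), prof)$net_shift
    expect_equal((na + nb) %% 3, n1)
  }
  # indels beyond the co-observation window are not a rescue
  wide <- net_indel_frame(phase_group("p", list(ins1, mk_snv(500, "CA", "C"))),
                          prof)
  expect_equal(wide$net_shift, 0); expect_false(wide$frame_restoring)
})

test_that("reinitiation classes follow the ATG offset fraction", {
  prof <- rule_profile("conservative")
  set.seed(11)
  # 400-codon CDS, single coding span in the first exon region
  spec <- toy_gene_spec(c(300, 100))
  spec <- set_codon(spec, 3, "TAC")
  spec <- set_codon(spec, 12, "ATG")
  g <- realize_gene(spec, "chr1", "+", "g1", "t1")
  ref <- Biostrings::DNAStringSet(c(chr1 = g$seq))
  lesion <- genomic_position(g$map, 6)
  # ATG at codon 12 removes 33/1200 = 2.75% <= 25%
  expect_equal(reinitiation_class(g$map, ref, g$transcript, lesion, prof), "strong")
  # conservation below 0.5 demotes strong to weak
  expect_equal(reinitiation_class(g$map, ref, g$transcript, lesion, prof,
                                  conservation_mean = 0.3), "weak")
  # ATG at codon 150 removes 447/1200 = 37% > 25%
  set.seed(11)
  spec2 <- set_codon(set_codon(toy_gene_spec(c(300, 100)), 3, "TAC"), 150, "ATG")
  g2 <- realize_gene(spec2, "chr1", "+", "g1", "t1")
  expect_equal(reinitiation_class(g2$map, Biostrings::DNAStringSet(c(chr1 = g2$seq)),
                                  g2$transcript, genomic_position(g2$map, 6), prof),
               "removes_gt_threshold")
  # no in-frame ATG in the first exon at all
  set.seed(11)
  spec3 <- set_codon(toy_gene_spec(c(300, 100)), 3, "TAC")
  g3 <- realize_gene(spec3, "chr1", "+", "g1", "t1")
  expect_equal(reinitiation_class(g3$map, Biostrings::DNAStringSet(c(chr1 = g3$seq)),
                                  g3$transcript, genomic_position(g3$map, 6), prof),
               "none")
})

test_that("technical context applies QC, GC, strand-bias and repeat rules", {
  cons <- rule_profile("conservative")
  len <- rule_profile("lenient")
  ctx <- paste(rep("GCTA", 100), collapse = "")   # 50% GC
  mkv <- function(...) variant_bundle("chr1", 200, "C", "T", "nonsense",
                                      qc = qc_metrics(...))
  v <- mkv(depth = 12, genotype_quality = 60, allele_balance = 0.48)
  expect_equal(technical_context(v, ctx, 1, 0, cons), "low_depth")
  clean <- mkv(depth = 40, genotype_quality = 60, allele_balance = 0.48)
  expect_length(technical_context(clean, ctx, 1, 0, cons), 0)
  # GC-rich 100 bp window
  gc_ctx <- paste(rep("GGCC", 100), collapse = "")
  expect_true("gc_rich" %in% technical_context(clean, gc_ctx, 1, 0, cons))
  # strand bias needs an extreme fraction and enough ALT reads
  sb <- mkv(depth = 40, genotype_quality = 60, allele_balance = 0.48,
            strand_bias = 0.02)
  expect_true("strand_bias" %in% technical_context(sb, ctx, 1, 0, cons))
  sb_few <- mkv(depth = 12, genotype_quality = 60, allele_balance = 0.3,
                strand_bias = 0.02)   # ~4 ALT reads: too few to call bias
  expect_false("strand_bias" %in% technical_context(sb_few, ctx, 1, 0, cons))
  # repeat-track thresholds (conservative > 5 / lenient > 3, as published)
  expect_equal(setdiff(technical_context(clean, ctx, 1, 4, cons), "gc_rich"),
               "minor_mapping")
  expect_equal(setdiff(technical_context(clean, ctx, 1, 4, len), "gc_rich"),
               "complex_mapping")
  expect_true("complex_mapping" %in% technical_context(clean, ctx, 1, 6, cons))
  expect_true("low_complexity" %in%
                technical_context(clean, ctx, 1, 0, cons,
                                  low_complexity_overlap = TRUE))
})

test_that("lenient technical flags are a subset of conservative ones (repeat rule aside)", {
  cons <- rule_profile("conservative")
  len <- rule_profile("lenient")
  ctx <- paste(rep("GCTA", 100), collapse = "")
  set.seed(7)
  for (i in 1:40) {
    v <- variant_bundle("chr1", 200, "C", "T", "nonsense",
                        qc = qc_metrics(depth = sample(5:50, 1),
                                        genotype_quality = sample(10:80, 1),
                                        allele_balance = runif(1, 0.15, 0.6),
                                        strand_bias = runif(1)))
    fl <- technical_context(v, ctx, 1, 0, len)
    fc <- technical_context(v, ctx, 1, 0, cons)
    expect_true(all(fl %in% fc))
  }
})
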