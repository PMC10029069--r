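test_that("verdict resolution takes the most impactful tier", {
  f1 <- rbind(make_flag("minority_at_max"), make_flag("homopolymer"))
  expect_equal(resolve_verdict(f1, "nonsense", TRUE), "likely_not_LoF")
  expect_equal(resolve_verdict(no_flags(), "nonsense", TRUE), "LoF")
  # frameshift without read data is uncertain unless a higher tier fires
  expect_equal(resolve_verdict(no_flags(), "frameshift", FALSE), "uncertain_LoF")
  expect_equal(resolve_verdict(make_flag("minor_mapping"), "frameshift", FALSE),
               "uncertain_LoF")   # likely_LoF is outranked by the uncertainty
  expect_equal(resolve_verdict(make_flag("low_pext"), "frameshift", FALSE),
               "not_LoF")
  expect_equal(resolve_verdict(make_flag("splice_rescue_stop"),
                               "splice_donor", TRUE), "LoF")
})

test_that("verdicts are monotone under flag-set inclusion", {
  cat_ <- flag_catalog()
  set.seed(19)
  for (i in 1:60) {
    sub <- sort(sample(nrow(cat_), sample(0:6, 1)))
    extra <- sort(unique(c(sub, sample(nrow(cat_), sample(1:4, 1)))))
    f_small <- if (length(sub)) do.call(rbind, lapply(cat_$name[sub], make_flag)) else no_flags()
    f_big <- do.call(rbind, lapply(cat_$name[extra], make_flag))
    for (vc in c("nonsense", "frameshift")) for (rd in c(TRUE, FALSE)) {
      expect_lte(verdict_rank(resolve_verdict(f_small, vc, rd)),
                 verdict_rank(resolve_verdict(f_big, vc, rd)))
    }
  }
})

test_that("primary reason picks the highest tier with the documented tie-break", {
  f <- rbind(make_flag("homopolymer"), make_flag("low_pext"))
  expect_equal(primary_reason(f), "low_pext")
  # tie at likely_not_LoF: rescue category outranks technical
  f2 <- rbind(make_flag("gc_rich"), make_flag("reinitiation_strong"))
  expect_equal(primary_reason(f2), "reinitiation_strong")
  # tie within one category: lexicographic
  f3 <- rbind(make_flag("low_gq"), make_flag("gc_rich"))
  expect_equal(primary_reason(f3), "gc_rich")
  expect_equal(primary_reason(no_flags()), "none")
})

test_that("PVS1 equals the single worst flag's consequence, never a sum", {
  # splice_rescue_weak caps at strong; low_pext says do not use: worst wins
  f <- rbind(make_flag("splice_rescue_weak", fraction_removed = 0.05),
             make_flag("low_pext"))
  d <- pvs1_decision("not_LoF", f)
  expect_equal(d$worst_consequence, "do_not_use")
  expect_equal(d$max_strength, "not_applicable")
  # unconfirmed technical flag: strength pending analytical confirmation
  d2 <- pvs1_decision("likely_not_LoF", make_flag("homopolymer"))
  expect_true(d2$requires_analytical_confirmation)
  expect_equal(d2$max_strength, "pending_confirmation")
  # confirmed technical flag does not modify PVS1
  d3 <- pvs1_decision("likely_not_LoF", make_flag("homopolymer"),
                      analytically_confirmed = TRUE)
  expect_false(d3$requires_analytical_confirmation)
  expect_equal(d3$max_strength, "very_strong")
  # clean LoF keeps full strength
  expect_equal(pvs1_decision("LoF", no_flags())$max_strength, "very_strong")
  # truncation-fraction rule: >= 10% of CDS drops the cap to moderate
  expect_equal(pvs1_decision("likely_not_LoF",
                             make_flag("last_exon", fraction_removed = 0.05)
                             )$max_strength, "strong")
  expect_equal(pvs1_decision("likely_not_LoF",
                             make_flag("last_exon", fraction_removed = 0.15)
                             )$max_strength, "moderate")

  # non-additivity over random non-technical flag sets
  cat_ <- flag_catalog()
  nt <- cat_$name[cat_$category != "technical"]
  set.seed(23)
  for (i in 1:40) {
    nm <- sample(nt, sample(2:5, 1))
    fs <- do.call(rbind, lapply(nm, function(n)
      make_flag(n, fraction_removed = sample(c(NA, 0.05, 0.2), 1))))
    joint <- pvs1_decision("not_LoF", fs)$worst_consequence
    singles <- vapply(seq_len(nrow(fs)), function(k)
      pvs1_decision("not_LoF", fs[k, , drop = FALSE])$worst_consequence,
      character(1))
    worst_single <- singles[which.max(match(singles, c("no_change", "cap_strong",
                                                       "cap_moderate", "do_not_use")))]
    expect_equal(joint, worst_single)
  }
})

test_that("joint rule evaluation: homopolymer frameshift at low depth", {
  set.seed(3)
  spec <- toy_gene_spec(c(50, 50, 100))
  spec <- set_codon(spec, 60, "AAA"); spec <- set_codon(spec, 61, "AAG")
  g <- realize_gene(spec, "chr1", "+", "g1", "t1")   # A x 5 at offsets 177-181
  v <- gv_del(g, 178)
  b <- variant_bundle(g$chrom, v$pos, v$ref, v$alt, "frameshift",
                      qc = qc_metrics(depth = 12, genotype_quality = 60,
                                      allele_balance = 0.48),
                      transcripts_hit = data.frame(transcript_id = "t1",
                                                   is_pLoF = TRUE),
                      gene_id = "g1")
  ctx <- curation_context(list(g$transcript),
                          Biostrings::DNAStringSet(c(chr1 = g$seq)))
  af <- assign_flags(b, ctx, rule_profile("conservative"))
  expect_setequal(af$flags$name, c("homopolymer", "low_depth"))
  expect_true(all(af$flags$tier == "likely_not_LoF"))
  # lenient: run of 5 < 7 and depth 12 >= 10, but depth fails the
  # conservative preset, leaving only the marginal-genotyping flag
  af_len <- assign_flags(b, ctx, rule_profile("lenient"))
  expect_setequal(af_len$flags$name, "genotyping_marginal")
  # skipped rules are recorded, never silent
  expect_true(any(grepl("pext", af_len$notes)))
})

test_that("flags aggregate over transcripts by the worst one", {
  set.seed(3)
  spec <- set_codon(toy_gene_spec(c(50, 50, 100)), 60, "TAC")
  g <- realize_gene(spec, "chr1", "+", "g1", "t1")
  ex <- g$transcript$exons
  skip <- ex[c(1, 3), ]
  t2 <- transcript_model("t2", "g1", "chr1", "+", exons = skip, cds = skip)
  t3 <- transcript_model("t3", "g1", "chr1", "+", exons = skip, cds = skip)
  v <- gv_snv(g, 179, "A")
  # pLoF in 1 of 3 coding transcripts; exon 2 pext at gene max: tier LoF
  b <- variant_bundle("chr1", v$pos, v$ref, v$alt, "nonsense",
                      qc = qc_metrics(40, 60, 0.48),
                      transcripts_hit = data.frame(
                        transcript_id = c("t1", "t2", "t3"),
                        is_pLoF = c(TRUE, FALSE, FALSE)),
                      gene_id = "g1")
  px <- pext_track(data.frame(gene_id = "g1", transcript_id = "t1",
                              exon_index = 1:3, mean_pext = 0.8))
  ctx <- curation_context(list(g$transcript, t2, t3),
                          Biostrings::DNAStringSet(c(chr1 = g$seq)), pext = px)
  res <- curate_variant(b, ctx, rule_profile("conservative"))
  expect_equal(res$transcript_id, "t1")
  expect_equal(res$flags$name, "minority_at_max")
  expect_equal(res$verdict, "LoF")
  expect_equal(res$primary_reason, "minority_at_max")
  expect_error(assign_flags(
    variant_bundle("chr1", v$pos, v$ref, v$alt, "nonsense",
                   transcripts_hit = data.frame(transcript_id = "t9",
                                                is_pLoF = TRUE)),
    ctx, rule_profile("conservative")), "coding transcript")
})

test_that("conservative verdicts sit at or beyond lenient ones across the catalog", {
  for (nm in scenario_catalog()) {
    sc <- generate_scenario(nm, 3, strands = "+")
    rc <- curate_scenario(sc, rule_profile("conservative"))
    rl <- curate_scenario(sc, rule_profile("lenient"))
    for (id in names(rc)) {
      expect_gte(verdict_rank(rc[[id]]$verdict), verdict_rank(rl[[id]]$verdict))
    }
  }
  # documented exception: the published repeat-track thresholds (> 5
  # conservative, > 3 lenient) invert the ordering for counts of 4-5
  set.seed(3)
  spec <- set_codon(toy_gene_spec(c(50, 50, 100)), 60, "TAC")
  g <- realize_gene(spec, "chr1", "+", "g1", "t1")
  v <- gv_snv(g, 179, "A")
  b <- variant_bundle("chr1", v$pos, v$ref, v$alt, "nonsense",
                      qc = qc_metrics(40, 60, 0.48),
                      transcripts_hit = data.frame(transcript_id = "t1",
                                                   is_pLoF = TRUE),
                      gene_id = "g1")
  reps <- data.frame(chrom = "chr1", start = v$pos - 5, end = v$pos + 5,
                     name = paste0("rep", 1:4))
  ctx <- curation_context(list(g$transcript),
                          Biostrings::DNAStringSet(c(chr1 = g$seq)),
                          repeats = reps)
  vc <- curate_variant(b, ctx, rule_profile("conservative"))$verdict
  vl <- curate_variant(b, ctx, rule_profile("lenient"))$verdict
  expect_equal(vc, "likely_LoF")       # minor mapping
  expect_equal(vl, "likely_not_LoF")   # complex mapping: lenient flags harder
})
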