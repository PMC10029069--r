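test_that("SpliceAI INFO strings parse by field position and gene symbol", {
  s <- parse_spliceai_info("T|GENEA|0.01|0.02|0.85|0.90|-10|3|-9|-2", "GENEA")
  expect_equal(s$ds_dl, 0.90); expect_equal(s$dp_dl, -2)
  expect_equal(s$ds_dg, 0.85); expect_equal(s$dp_dg, -9)
  expect_equal(s$ds_ag, 0.01); expect_equal(s$dp_al, 3)
  expect_null(parse_spliceai_info(NA_character_, "GENEA"))
  expect_null(parse_spliceai_info(".", "GENEA"))
  # two comma-separated entries: the matching symbol is selected
  two <- paste("T|GENEA|0.1|0.1|0.1|0.1|0|0|0|0",
               "T|GENEB|0.9|0.9|0.9|0.9|1|1|1|1", sep = ",")
  expect_equal(parse_spliceai_info(two, "GENEB")$ds_ag, 0.9)
  expect_null(parse_spliceai_info(two, "GENEC"))
  expect_error(parse_spliceai_info("T|GENEA|0.5", "GENEA"), "malformed")
})

# shared scaffolding: a donor variant at exon 2 of the standard toy gene
donor_case <- function(strand, gain, gain_offset, loss = 0.95,
                       al = 0.02, al_at_far = FALSE, al_at_exon = FALSE,
                       retained9 = NULL, exon_codons = c(50, 50, 100)) {
  set.seed(5)
  spec <- toy_gene_spec(exon_codons)
  if (!is.null(retained9)) substr(spec$introns[2], 1, 9) <- retained9
  g <- realize_gene(spec, "chr1", strand, "g1", "t1")
  tx <- g$transcript
  ann <- exon_donor_pos(tx, 2)
  dir <- if (strand == "+") 1L else -1L
  v <- gv_snv_at_pos(g, ann + dir)
  pal <- 0
  if (al_at_exon) pal <- exon_acceptor_pos(tx, 2) - v$pos
  if (al_at_far) pal <- exon_acceptor_pos(tx, 3) - v$pos
  scores <- spliceai_scores(ds_al = al, ds_dl = loss, ds_dg = gain,
                            dp_dg = (ann + gain_offset * dir) - v$pos,
                            dp_al = pal, dp_dl = ann - v$pos)
  b <- variant_bundle(g$chrom, v$pos, v$ref, v$alt, "splice_donor",
                      transcripts_hit = data.frame(transcript_id = "t1",
                                                   is_pLoF = TRUE),
                      gene_id = "g1")
  list(g = g, bundle = b, scores = scores,
       ref = Biostrings::DNAStringSet(c(chr1 = g$seq)))
}

test_that("cryptic gains classify by frame parity and strength margin", {
  prof <- rule_profile("conservative")
  for (strand in c("+", "-")) {
    # loss 0.95, gain 0.80 at in-frame offset -9 (exonic): strong rescue
    d <- donor_case(strand, gain = 0.80, gain_offset = -9)
    e <- classify_splice_event(d$bundle, d$g$map, d$g$transcript, d$scores,
                               prof, ref_seq = d$ref)
    expect_equal(e$kind, "in_frame_cryptic_rescue")
    expect_equal(e$strength, "strong")       # 0.95 - 0.80 = 0.15 <= 0.2
    expect_equal(e$fraction_removed, 9 / 600)
    # weaker gain: 0.95 - 0.5 = 0.45 > 0.2
    d2 <- donor_case(strand, gain = 0.50, gain_offset = -9)
    expect_equal(classify_splice_event(d2$bundle, d2$g$map, d2$g$transcript,
                                       d2$scores, prof)$strength, "weak")
    # out-of-frame offset
    d3 <- donor_case(strand, gain = 0.60, gain_offset = -10, loss = 0.9)
    expect_equal(classify_splice_event(d3$bundle, d3$g$map, d3$g$transcript,
                                       d3$scores, prof)$kind,
                 "out_of_frame_cryptic")
    # frame parity: shifting the cryptic offset by +/- 3 never changes it
    for (base_off in c(-9, -10, 7)) {
      kinds <- vapply(c(-3, 0, 3), function(s) {
        dd <- donor_case(strand, gain = 0.6, gain_offset = base_off + s)
        classify_splice_event(dd$bundle, dd$g$map, dd$g$transcript, dd$scores,
                              prof)$kind
      }, character(1))
      expect_length(unique(kinds), 1)
    }
  }
})

test_that("intronic in-frame gains retain sequence and are stop-scanned", {
  prof <- rule_profile("conservative")
  for (strand in c("+", "-")) {
    # 9 retained intronic bases including TAA: rescue introduces a stop
    d <- donor_case(strand, gain = 0.80, gain_offset = +9,
                    retained9 = "GTATAAGCA")
    e <- classify_splice_event(d$bundle, d$g$map, d$g$transcript, d$scores,
                               prof, ref_seq = d$ref)
    expect_equal(e$kind, "in_frame_cryptic_rescue")
    expect_true(e$stop_in_retained)
    # stop-free retained sequence
    d2 <- donor_case(strand, gain = 0.80, gain_offset = +9,
                     retained9 = "GTGGCAGCC")
    e2 <- classify_splice_event(d2$bundle, d2$g$map, d2$g$transcript,
                                d2$scores, prof, ref_seq = d2$ref)
    expect_false(e2$stop_in_retained)
    expect_equal(e2$strength, "strong")
  }
})

test_that("opposite-site loss reads as exon skip or intron retention by position", {
  prof <- rule_profile("conservative")
  for (strand in c("+", "-")) {
    # acceptor loss at the exon's own acceptor, 54 bp in-frame exon
    d <- donor_case(strand, gain = 0.02, gain_offset = -9, loss = 0.9,
                    al = 0.85, al_at_exon = TRUE,
                    exon_codons = c(60, 18, 122))
    e <- classify_splice_event(d$bundle, d$g$map, d$g$transcript, d$scores, prof)
    expect_equal(e$kind, "in_frame_exon_skip")
    expect_equal(e$fraction_removed, 54 / 600)
    # 50-codon exon (150 bp) is also in frame; a 49-codon + 1 base layout
    # is exercised via an out-of-frame exon: 151 bp exon
    d2 <- donor_case(strand, gain = 0.02, gain_offset = -9, loss = 0.9,
                     al = 0.85, al_at_far = TRUE)
    e2 <- classify_splice_event(d2$bundle, d2$g$map, d2$g$transcript,
                                d2$scores, prof, ref_seq = d2$ref)
    expect_equal(e2$kind, "intron_retention")
    expect_equal(diff(e2$retained_interval) + 1, 90)   # the whole intron
  }
})

test_that("no qualifying signal yields uncertain; no loss plus low pext is non-essential", {
  prof <- rule_profile("conservative")
  d <- donor_case("+", gain = 0.05, gain_offset = -9, loss = 0.05)
  e <- classify_splice_event(d$bundle, d$g$map, d$g$transcript, d$scores, prof)
  expect_equal(e$kind, "uncertain")
  e2 <- classify_splice_event(d$bundle, d$g$map, d$g$transcript, d$scores,
                              prof, adjacent_pext_category = "low")
  expect_equal(e2$kind, "non_essential_site")
  expect_equal(classify_splice_event(d$bundle, d$g$map, d$g$transcript, NULL,
                                     prof)$kind, "uncertain")
  nb <- variant_bundle("chr1", 5, "C", "T", "nonsense")
  expect_error(classify_splice_event(nb, d$g$map, d$g$transcript, d$scores,
                                     prof), "essential splice")
})

test_that("retained-sequence stop scan honours the inherited frame and junctions", {
  ref <- Biostrings::DNAStringSet(c(chr1 = paste0("CC", "GCTTAAGCT", "GGGGG")))
  # interval 3..11 in frame 0: codons GCT TAA GCT -> stop
  expect_true(retained_stop_scan(ref, "chr1", 3, 11, "+", 0))
  # the prepended junction base restores the frame: still a stop
  expect_true(retained_stop_scan(ref, "chr1", 4, 11, "+", 1))
  # without the junction base the frame shifts: CTT AAG CT -> no stop
  expect_false(retained_stop_scan(ref, "chr1", 4, 11, "+", 0))
  expect_false(retained_stop_scan(ref, "chr1",
                                  3, 11, "+", 0) &&
                 retained_stop_scan(Biostrings::DNAStringSet(
                   c(chr1 = "CCGCTGCAGCTGG")), "chr1", 3, 11, "+", 0))
  # empty interval
  expect_false(retained_stop_scan(ref, "chr1", 10, 9, "+", 0))
  # minus strand: revcomp of TTA is TAA
  ref2 <- Biostrings::DNAStringSet(c(chr1 = paste0("CCC", "AGCTTAGGC", "CC")))
  expect_true(retained_stop_scan(ref2, "chr1", 4, 12, "-", 0))
})

test_that("pext support of a splice site uses category and per-base junction drop", {
  prof <- rule_profile("conservative")
  tx <- transcript_model("t1", "g1", "chr1", "+",
                         exons = data.frame(start = c(101, 301), end = c(200, 400)),
                         cds = data.frame(start = c(101, 301), end = c(200, 400)))
  mk <- function(vals, per_base = NULL)
    pext_track(data.frame(gene_id = "g1", transcript_id = "t1",
                          exon_index = c(1, 2), mean_pext = vals),
               per_base = per_base)
  # low adjacent exon: not supported
  expect_false(splice_pext_support(mk(c(0.05, 0.8)), tx, "g1", 1, prof))
  # at-max adjacent exon, per-exon only: supported
  expect_true(splice_pext_support(mk(c(0.8, 0.8)), tx, "g1", 1, prof))
  # flat per-base signal across the donor junction (pos 200): not supported
  flat <- data.frame(chrom = "chr1", start = 1, end = 500, value = 0.8)
  expect_false(splice_pext_support(mk(c(0.8, 0.8), flat), tx, "g1", 1, prof,
                                   junction_pos = 200))
  # clear drop into the intron: supported
  drop <- data.frame(chrom = "chr1", start = c(101, 201), end = c(200, 300),
                     value = c(0.8, 0.05))
  expect_true(splice_pext_support(mk(c(0.8, 0.8), drop), tx, "g1", 1, prof,
                                  junction_pos = 200))
  # no pext at all: no evidence either way
  empty <- pext_track(data.frame(gene_id = character(),
                                 transcript_id = character(),
                                 exon_index = integer(), mean_pext = numeric()))
  expect_true(is.na(splice_pext_support(empty, tx, "g1", 1, prof)))
})
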