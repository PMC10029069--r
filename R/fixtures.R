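## Deterministic synthetic-data generator: one toy gene + variant scenario
## per evasion/artifact mechanism, with expected flags/verdict/PVS1 attached
## BY CONSTRUCTION (never by running the engine), emitted in the real file
## formats. Every geometric scenario is generated on both strands; strand
## bugs are the dominant failure mode for CDS arithmetic.

## random filler with no homopolymer run longer than 2 (keeps artifact rules
## quiet outside the scenarios that exercise them)
rand_seq <- function(n) {
  if (n <= 0) return("")
  pool <- c("A", "C", "G", "T")
  b <- character(n)
  for (i in seq_len(n)) {
    choices <- pool
    if (i > 2 && b[i - 1] == b[i - 2]) choices <- setdiff(pool, b[i - 1])
    b[i] <- sample(choices, 1)
  }
  paste(b, collapse = "")
}

## Editable toy-gene layout in transcript space. Codons are per-exon vectors;
## codon 1 is ATG, the final codon TAA (CDS includes the stop codon).
toy_gene_spec <- function(exon_codons, intron_len = 90, pad = 60,
                          filler = "GCT") {
  codons <- lapply(exon_codons, function(k) rep(filler, k))
  codons[[1]][1] <- "ATG"
  nl <- length(codons)
  codons[[nl]][length(codons[[nl]])] <- "TAA"
  introns <- if (nl > 1)
    vapply(seq_len(nl - 1), function(i)
      paste0("GT", rand_seq(intron_len - 4), "AG"), character(1))
  else character()
  list(codons = codons, introns = introns,
       pad5 = rand_seq(pad), pad3 = rand_seq(pad))
}

set_codon <- function(spec, codon_index, value) {
  sizes <- vapply(spec$codons, length, integer(1))
  ends <- cumsum(sizes)
  ex <- which(codon_index <= ends)[1]
  local <- codon_index - c(0, ends)[ex]
  spec$codons[[ex]][local] <- value
  spec
}

## place the layout on a genome contig; minus strand mirrors the axis
realize_gene <- function(spec, chrom, strand, gene_id, tx_id,
                         tags = character()) {
  exon_seqs <- vapply(spec$codons, function(cv) paste(cv, collapse = ""),
                      character(1))
  pieces <- spec$pad5
  for (i in seq_along(exon_seqs)) {
    pieces <- c(pieces, exon_seqs[i])
    if (i < length(exon_seqs)) pieces <- c(pieces, spec$introns[i])
  }
  pieces <- c(pieces, spec$pad3)
  lens <- nchar(pieces)
  ends <- cumsum(lens); starts <- ends - lens + 1
  exon_piece <- seq(2, by = 2, length.out = length(exon_seqs))
  tx_axis <- data.frame(start = starts[exon_piece], end = ends[exon_piece])
  L <- sum(lens)
  seq_tx <- paste(pieces, collapse = "")
  if (strand == "+") {
    gseq <- seq_tx; exons <- tx_axis
  } else {
    gseq <- revcomp(seq_tx)
    exons <- data.frame(start = L - tx_axis$end + 1, end = L - tx_axis$start + 1)
  }
  tx <- transcript_model(tx_id, gene_id, chrom, strand, exons = exons,
                         cds = exons, tags = tags)
  list(chrom = chrom, strand = strand, seq = gseq, transcript = tx,
       map = build_coding_map(tx), length = L)
}

## variant constructors in coding space, realized as genome-strand records
gv_snv <- function(g, offset, alt_tx) {
  pos <- genomic_position(g$map, offset)
  list(pos = pos, ref = substr(g$seq, pos, pos),
       alt = if (g$strand == "-") complement_base(alt_tx) else alt_tx)
}
gv_del <- function(g, off1, off2 = off1) {
  p <- sort(c(genomic_position(g$map, off1), genomic_position(g$map, off2)))
  anchor <- p[1] - 1
  list(pos = anchor, ref = substr(g$seq, anchor, p[2]),
       alt = substr(g$seq, anchor, anchor))
}
gv_ins <- function(g, off_after, bases_tx) {
  p1 <- genomic_position(g$map, off_after)
  p2 <- genomic_position(g$map, off_after + 1)
  anchor <- min(p1, p2)
  ins <- if (g$strand == "-") revcomp(bases_tx) else bases_tx
  a <- substr(g$seq, anchor, anchor)
  list(pos = anchor, ref = a, alt = paste0(a, ins))
}
gv_snv_at_pos <- function(g, pos) {
  ref <- substr(g$seq, pos, pos)
  alt <- c(A = "T", C = "A", G = "T", T = "A")[ref]
  list(pos = pos, ref = ref, alt = unname(alt))
}

vrow <- function(id, g, v, vclass, trhit = NULL, dp = 40, gq = 60,
                 alt_reads = 19, spliceai = NA_character_,
                 pg = NA_character_, noread = FALSE) {
  if (is.null(trhit)) trhit <- paste0(g$transcript$transcript_id, ":1")
  data.frame(id = id, chrom = g$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
             vclass = vclass, gene = g$transcript$gene_id, trhit = trhit,
             dp = dp, gq = gq, alt_reads = alt_reads, spliceai = spliceai,
             pg = pg, noread = noread, stringsAsFactors = FALSE)
}

erow <- function(variant_id, flags, verdict, pvs1, confirm = FALSE,
                 profile = "both", companion = FALSE) {
  data.frame(variant_id = variant_id, profile = profile,
             expected_flags = flags, expected_verdict = verdict,
             expected_pvs1 = pvs1, expected_confirm = confirm,
             companion = companion, stringsAsFactors = FALSE)
}

prow <- function(g, exon_index, val, tx = NULL) {
  if (is.null(tx)) tx <- g$transcript$transcript_id
  data.frame(gene_id = g$transcript$gene_id, transcript_id = tx,
             exon_index = exon_index, mean_pext = val, stringsAsFactors = FALSE)
}

default_pext <- function(g, val = 0.8) {
  do.call(rbind, lapply(seq_len(nrow(g$transcript$exons)), function(i)
    prow(g, i, val)))
}

sai_string <- function(alt, gene, ag = 0, al = 0, dg = 0, dl = 0,
                       pag = 0, pal = 0, pdg = 0, pdl = 0) {
  sprintf("%s|%s|%.2f|%.2f|%.2f|%.2f|%d|%d|%d|%d",
          alt, gene, ag, al, dg, dl, pag, pal, pdg, pdl)
}

empty_repeats <- function() data.frame(chrom = character(), start = integer(),
                                       end = integer(), name = character(),
                                       stringsAsFactors = FALSE)

## ---------------------------------------------------------------------------
## Scenario builders. Each is a pure function of (chrom, strand, pfx) given
## the RNG state set by the caller; expectations are derived from the layout
## arithmetic, not from the engine.
## ---------------------------------------------------------------------------

## base gene: 3 exons of 50/50/100 codons (600 bp CDS incl. stop), 90 bp introns
base_gene <- function(chrom, strand, pfx, edit = identity, exon_codons = c(50, 50, 100),
                      tags = character()) {
  spec <- toy_gene_spec(exon_codons)
  spec <- edit(spec)
  realize_gene(spec, chrom, strand, paste0("G", pfx), paste0("TX", pfx, "a"),
               tags = tags)
}

## clean mid-CDS nonsense in exon 2: negative control, verdict LoF
sc_clean_nonsense <- function(chrom, strand, pfx) {
  g <- base_gene(chrom, strand, pfx, function(s) set_codon(s, 60, "TAC"))
  v <- gv_snv(g, 179, "A")   # TAC -> TAA at codon 60
  list(genes = list(g),
       variants = vrow(paste0(pfx, "v1"), g, v, "nonsense"),
       pext = default_pext(g), repeats = empty_repeats(),
       expected = erow(paste0(pfx, "v1"), "", "LoF", "very_strong"))
}

## frameshift with no read data: frame-restoring indels cannot be excluded
sc_frameshift_no_reads <- function(chrom, strand, pfx) {
  g <- base_gene(chrom, strand, pfx)
  v <- gv_del(g, 178)   # 1 bp deletion mid exon 2
  list(genes = list(g),
       variants = vrow(paste0(pfx, "v1"), g, v, "frameshift", noread = TRUE),
       pext = default_pext(g), repeats = empty_repeats(),
       expected = erow(paste0(pfx, "v1"), "", "uncertain_LoF", "strong"))
}

## 1 bp deletion inside an A x 7 homopolymer run (polymerase slippage risk)
sc_homopolymer_frameshift <- function(chrom, strand, pfx) {
  g <- base_gene(chrom, strand, pfx, function(s) {
    s <- set_codon(s, 60, "AAA"); s <- set_codon(s, 61, "AAA")
    set_codon(s, 62, "ACT")
  })
  v <- gv_del(g, 180)   # one A out of the 7-base run at offsets 177..183
  list(genes = list(g),
       variants = vrow(paste0(pfx, "v1"), g, v, "frameshift"),
       pext = default_pext(g), repeats = empty_repeats(),
       expected = erow(paste0(pfx, "v1"), "homopolymer", "likely_not_LoF",
                       "pending_confirmation", confirm = TRUE))
}

## nonsense inside a GC-rich (capture-hostile) exon segment
sc_gc_rich <- function(chrom, strand, pfx) {
  g <- base_gene(chrom, strand, pfx, function(s) {
    for (k in 51:100) s <- set_codon(s, k, "GCC")
    set_codon(s, 75, "TAC")
  })
  v <- gv_snv(g, 224, "A")   # codon 75 TAC -> TAA, centered in the GCC block
  list(genes = list(g),
       variants = vrow(paste0(pfx, "v1"), g, v, "nonsense"),
       pext = default_pext(g), repeats = empty_repeats(),
       expected = erow(paste0(pfx, "v1"), "gc_rich", "likely_not_LoF",
                       "pending_confirmation", confirm = TRUE))
}

sc_mapping <- function(chrom, strand, pfx, n_tracks, flag, verdict) {
  g <- base_gene(chrom, strand, pfx, function(s) set_codon(s, 60, "TAC"))
  v <- gv_snv(g, 179, "A")
  reps <- data.frame(chrom = chrom, start = v$pos - 10, end = v$pos + 10,
                     name = paste0("repeat_track_", seq_len(n_tracks)),
                     stringsAsFactors = FALSE)
  list(genes = list(g),
       variants = vrow(paste0(pfx, "v1"), g, v, "nonsense"),
       pext = default_pext(g), repeats = reps,
       expected = erow(paste0(pfx, "v1"), flag, verdict,
                       "pending_confirmation", confirm = TRUE))
}
sc_complex_mapping <- function(chrom, strand, pfx)
  sc_mapping(chrom, strand, pfx, 6, "complex_mapping", "likely_not_LoF")
sc_minor_mapping <- function(chrom, strand, pfx)
  sc_mapping(chrom, strand, pfx, 2, "minor_mapping", "likely_LoF")

## QC metrics that fail the conservative but pass the lenient thresholds
sc_genotyping_fail <- function(chrom, strand, pfx) {
  g <- base_gene(chrom, strand, pfx, function(s) set_codon(s, 60, "TAC"))
  v <- gv_snv(g, 179, "A")
  list(genes = list(g),
       variants = vrow(paste0(pfx, "v1"), g, v, "nonsense",
                       dp = 12, gq = 25, alt_reads = 4),   # AB = 1/3
       pext = default_pext(g), repeats = empty_repeats(),
       expected = rbind(
         erow(paste0(pfx, "v1"), "low_depth;low_gq;skewed_ab",
              "likely_not_LoF", "pending_confirmation", confirm = TRUE,
              profile = "conservative"),
         erow(paste0(pfx, "v1"), "genotyping_marginal", "likely_LoF",
              "pending_confirmation", confirm = TRUE, profile = "lenient")))
}

## nonsense in the last exon, removing 5% of the CDS (NMD escape)
sc_last_exon <- function(chrom, strand, pfx) {
  g <- base_gene(chrom, strand, pfx, function(s) set_codon(s, 191, "TAC"))
  v <- gv_snv(g, 572, "A")   # termination offset 570; removes 30/600 = 5%
  list(genes = list(g),
       variants = vrow(paste0(pfx, "v1"), g, v, "nonsense"),
       pext = default_pext(g), repeats = empty_repeats(),
       expected = erow(paste0(pfx, "v1"), "last_exon", "likely_not_LoF",
                       "strong"))
}

## nonsense within the terminal 50 coding bases of the penultimate exon
sc_penultimate_window <- function(chrom, strand, pfx) {
  g <- base_gene(chrom, strand, pfx,
                 function(s) set_codon(s, 189, "TAC"),
                 exon_codons = c(20, 170, 10))
  v <- gv_snv(g, 566, "A")   # offset 564: 6 bases from the exon-2 junction
  list(genes = list(g),
       variants = vrow(paste0(pfx, "v1"), g, v, "nonsense"),
       pext = default_pext(g), repeats = empty_repeats(),
       expected = erow(paste0(pfx, "v1"), "last_exon", "likely_not_LoF",
                       "strong"))   # removes 36/600 = 6%
}

## nonsense in an exon whose pext is 10% of the gene maximum
sc_low_pext <- function(chrom, strand, pfx) {
  g <- base_gene(chrom, strand, pfx, function(s) set_codon(s, 60, "TAC"))
  v <- gv_snv(g, 179, "A")
  px <- rbind(prow(g, 1, 0.5), prow(g, 2, 0.05), prow(g, 3, 0.5))
  list(genes = list(g),
       variants = vrow(paste0(pfx, "v1"), g, v, "nonsense"),
       pext = px, repeats = empty_repeats(),
       expected = erow(paste0(pfx, "v1"), "low_pext", "not_LoF",
                       "not_applicable"))
}

## gene with a cassette exon private to one of three coding transcripts
minority_gene <- function(chrom, strand, pfx) {
  g <- base_gene(chrom, strand, pfx, function(s) set_codon(s, 60, "TAC"))
  ex <- g$transcript$exons
  skip <- ex[c(1, 3), ]
  t2 <- transcript_model(paste0("TX", pfx, "b"), g$transcript$gene_id,
                         chrom, strand, exons = skip, cds = skip)
  t3 <- transcript_model(paste0("TX", pfx, "c"), g$transcript$gene_id,
                         chrom, strand, exons = skip, cds = skip)
  list(g = g, t2 = t2, t3 = t3,
       trhit = paste0(g$transcript$transcript_id, ":1,",
                      t2$transcript_id, ":0,", t3$transcript_id, ":0"))
}

## pLoF in 1 of 3 coding transcripts, exon pext at the gene maximum
sc_minority_at_max <- function(chrom, strand, pfx) {
  m <- minority_gene(chrom, strand, pfx)
  v <- gv_snv(m$g, 179, "A")
  list(genes = list(m$g, list(transcript = m$t2), list(transcript = m$t3)),
       variants = vrow(paste0(pfx, "v1"), m$g, v, "nonsense", trhit = m$trhit),
       pext = default_pext(m$g), repeats = empty_repeats(),
       expected = erow(paste0(pfx, "v1"), "minority_at_max", "LoF",
                       "very_strong"))
}

## as above but exon pext 40% of the gene maximum: the category (and hence
## the tier) differs between the conservative and lenient mid cutoffs
sc_minority_mid <- function(chrom, strand, pfx) {
  m <- minority_gene(chrom, strand, pfx)
  v <- gv_snv(m$g, 179, "A")
  px <- rbind(prow(m$g, 1, 0.8), prow(m$g, 2, 0.32), prow(m$g, 3, 0.8))
  list(genes = list(m$g, list(transcript = m$t2), list(transcript = m$t3)),
       variants = vrow(paste0(pfx, "v1"), m$g, v, "nonsense", trhit = m$trhit),
       pext = px, repeats = empty_repeats(),
       expected = rbind(
         erow(paste0(pfx, "v1"), "minority_mid", "uncertain_LoF", "strong",
              profile = "conservative"),
         erow(paste0(pfx, "v1"), "minority_close_to_max", "likely_LoF",
              "very_strong", profile = "lenient")))
}

## nonsense annotated only in an overprinted (alternate-ORF) transcript
sc_overprinting <- function(chrom, strand, pfx) {
  g <- base_gene(chrom, strand, pfx, function(s) set_codon(s, 60, "TAC"),
                 tags = "overprinted")
  v <- gv_snv(g, 179, "A")
  list(genes = list(g),
       variants = vrow(paste0(pfx, "v1"), g, v, "nonsense"),
       pext = default_pext(g), repeats = empty_repeats(),
       expected = erow(paste0(pfx, "v1"), "overprinting", "likely_not_LoF",
                       "not_applicable"))
}

## variant inside a 30 bp exon extension spliced out in the other transcript
sc_overhang_exon <- function(chrom, strand, pfx) {
  g <- base_gene(chrom, strand, pfx, function(s) set_codon(s, 105, "TAC"),
                 exon_codons = c(50, 60, 90))
  ex <- g$transcript$exons
  short2 <- ex
  if (strand == "+") short2$end[2] <- short2$end[2] - 30
  else short2$start[2] <- short2$start[2] + 30
  t2 <- transcript_model(paste0("TX", pfx, "b"), g$transcript$gene_id,
                         chrom, strand, exons = short2, cds = short2)
  v <- gv_snv(g, 314, "A")   # codon 105, inside the extension
  px <- rbind(prow(g, 1, 0.8), prow(g, 2, 0.45), prow(g, 3, 0.8))
  list(genes = list(g, list(transcript = t2)),
       variants = vrow(paste0(pfx, "v1"), g, v, "nonsense",
                       trhit = paste0(g$transcript$transcript_id, ":1,",
                                      t2$transcript_id, ":0")),
       pext = px, repeats = empty_repeats(),
       expected = erow(paste0(pfx, "v1"), "overhang_exon", "not_LoF",
                       "not_applicable"))
}

## two phased SNVs in one codon whose joint translation is missense
sc_mnv_rescue <- function(chrom, strand, pfx) {
  g <- base_gene(chrom, strand, pfx, function(s) set_codon(s, 60, "TCA"))
  v1 <- gv_snv(g, 178, "G")   # TCA -> TGA (stop) alone
  v2 <- gv_snv(g, 179, "G")   # joint codon TGG (Trp)
  pg <- paste0(pfx, "PG1")
  vars <- rbind(vrow(paste0(pfx, "v1"), g, v1, "nonsense", pg = pg),
                vrow(paste0(pfx, "v2"), g, v2, "missense", pg = pg))
  list(genes = list(g), variants = vars,
       pext = default_pext(g), repeats = empty_repeats(),
       expected = erow(paste0(pfx, "v1"), "mnv_rescue", "not_LoF",
                       "not_applicable"))
}

## +1 insertion and -1 deletion 11 bp apart on one haplotype: net in-frame
sc_frame_restoring_pair <- function(chrom, strand, pfx) {
  g <- base_gene(chrom, strand, pfx)
  v1 <- gv_ins(g, 170, "G")
  v2 <- gv_del(g, 181)
  pg <- paste0(pfx, "PG2")
  vars <- rbind(vrow(paste0(pfx, "v1"), g, v1, "frameshift", pg = pg),
                vrow(paste0(pfx, "v2"), g, v2, "frameshift", pg = pg))
  list(genes = list(g), variants = vars,
       pext = default_pext(g), repeats = empty_repeats(),
       expected = rbind(
         erow(paste0(pfx, "v1"), "frame_restoring_indel", "not_LoF",
              "not_applicable"),
         erow(paste0(pfx, "v2"), "frame_restoring_indel", "not_LoF",
              "not_applicable", companion = TRUE)))
}

## very early nonsense with an in-frame ATG at codon 12 of a 400-codon CDS
sc_reinitiation_strong <- function(chrom, strand, pfx) {
  g <- base_gene(chrom, strand, pfx, function(s) {
    s <- set_codon(s, 3, "TAC"); set_codon(s, 12, "ATG")
  }, exon_codons = c(300, 100))
  v <- gv_snv(g, 8, "A")   # codon 3 TAC -> TAA; reinit removes 33/1200 = 2.75%
  list(genes = list(g),
       variants = vrow(paste0(pfx, "v1"), g, v, "nonsense"),
       pext = default_pext(g), repeats = empty_repeats(),
       expected = erow(paste0(pfx, "v1"), "reinitiation_strong",
                       "likely_not_LoF", "strong"))
}

## shared scaffolding for essential-donor scenarios at exon 2
donor_variant <- function(g, exon = 2) {
  tx <- g$transcript
  ann <- exon_donor_pos(tx, exon)
  dir <- if (g$strand == "+") 1L else -1L
  v <- gv_snv_at_pos(g, ann + dir)
  list(v = v, ann = ann, dir = dir)
}

## in-frame exonic cryptic donor 9 bp from the annotated site
sc_splice_rescue <- function(chrom, strand, pfx, gain, flag, pvs1) {
  g <- base_gene(chrom, strand, pfx)
  d <- donor_variant(g)
  cryptic <- d$ann - 9L * d$dir    # exon side, in frame
  s <- sai_string(d$v$alt, g$transcript$gene_id, al = 0.02, dl = 0.95,
                  dg = gain, pdg = cryptic - d$v$pos, pdl = d$ann - d$v$pos)
  list(genes = list(g),
       variants = vrow(paste0(pfx, "v1"), g, d$v, "splice_donor", spliceai = s),
       pext = default_pext(g), repeats = empty_repeats(),
       expected = erow(paste0(pfx, "v1"), flag,
                       if (flag == "splice_rescue_strong") "not_LoF" else "likely_not_LoF",
                       pvs1))
}
sc_strong_splice_rescue <- function(chrom, strand, pfx)
  sc_splice_rescue(chrom, strand, pfx, 0.80, "splice_rescue_strong", "not_applicable")
sc_weak_splice_rescue <- function(chrom, strand, pfx)
  sc_splice_rescue(chrom, strand, pfx, 0.50, "splice_rescue_weak", "strong")

## in-frame intronic cryptic donor retaining 9 intronic bases incl. a TAA
sc_retained_stop <- function(chrom, strand, pfx) {
  g <- base_gene(chrom, strand, pfx, function(s) {
    substr(s$introns[1], 1, 9) <- "GTATAAGCA"   # retained codons GTA TAA ...
    s
  })
  d <- donor_variant(g, exon = 1)
  cryptic <- d$ann + 9L * d$dir    # intron side, in frame
  s <- sai_string(d$v$alt, g$transcript$gene_id, al = 0.02, dl = 0.95,
                  dg = 0.80, pdg = cryptic - d$v$pos, pdl = d$ann - d$v$pos)
  list(genes = list(g),
       variants = vrow(paste0(pfx, "v1"), g, d$v, "splice_donor", spliceai = s),
       pext = default_pext(g), repeats = empty_repeats(),
       expected = erow(paste0(pfx, "v1"), "splice_rescue_stop", "LoF",
                       "very_strong"))
}

## out-of-frame exonic cryptic donor 10 bp from the annotated site
sc_out_of_frame_cryptic <- function(chrom, strand, pfx) {
  g <- base_gene(chrom, strand, pfx)
  d <- donor_variant(g)
  cryptic <- d$ann - 10L * d$dir
  s <- sai_string(d$v$alt, g$transcript$gene_id, al = 0.02, dl = 0.90,
                  dg = 0.60, pdg = cryptic - d$v$pos, pdl = d$ann - d$v$pos)
  list(genes = list(g),
       variants = vrow(paste0(pfx, "v1"), g, d$v, "splice_donor", spliceai = s),
       pext = default_pext(g), repeats = empty_repeats(),
       expected = erow(paste0(pfx, "v1"), "out_of_frame_cryptic", "LoF",
                       "very_strong"))
}

## donor + acceptor loss of the same 54 bp in-frame exon: predicted skip
sc_in_frame_skip <- function(chrom, strand, pfx) {
  g <- base_gene(chrom, strand, pfx, exon_codons = c(60, 18, 122))
  d <- donor_variant(g)
  opp <- exon_acceptor_pos(g$transcript, 2)
  s <- sai_string(d$v$alt, g$transcript$gene_id, al = 0.85, dl = 0.90,
                  dg = 0.02, ag = 0.01, pal = opp - d$v$pos,
                  pdl = d$ann - d$v$pos)
  list(genes = list(g),
       variants = vrow(paste0(pfx, "v1"), g, d$v, "splice_donor", spliceai = s),
       pext = default_pext(g), repeats = empty_repeats(),
       expected = erow(paste0(pfx, "v1"), "in_frame_exon_skip", "not_LoF",
                       "strong"))   # removes 54/600 = 9%
}

## donor loss + acceptor loss at the far end of the downstream intron:
## predicted retention of the whole intron
sc_intron_retention <- function(chrom, strand, pfx) {
  g <- base_gene(chrom, strand, pfx)
  d <- donor_variant(g)
  far <- exon_acceptor_pos(g$transcript, 3)
  s <- sai_string(d$v$alt, g$transcript$gene_id, al = 0.85, dl = 0.90,
                  pal = far - d$v$pos, pdl = d$ann - d$v$pos)
  list(genes = list(g),
       variants = vrow(paste0(pfx, "v1"), g, d$v, "splice_donor", spliceai = s),
       pext = default_pext(g), repeats = empty_repeats(),
       expected = erow(paste0(pfx, "v1"), "intron_retention", "LoF",
                       "very_strong"))
}

## essential donor with no predicted loss, adjacent exon pext low: the site
## (and transcript) is of low biological relevance
sc_splice_unsupported_pext <- function(chrom, strand, pfx) {
  g <- base_gene(chrom, strand, pfx)
  d <- donor_variant(g)
  s <- sai_string(d$v$alt, g$transcript$gene_id, al = 0.03, dl = 0.05,
                  dg = 0.02, ag = 0.01, pdl = d$ann - d$v$pos)
  px <- rbind(prow(g, 1, 0.8), prow(g, 2, 0.04), prow(g, 3, 0.8))
  list(genes = list(g),
       variants = vrow(paste0(pfx, "v1"), g, d$v, "splice_donor", spliceai = s),
       pext = px, repeats = empty_repeats(),
       expected = erow(paste0(pfx, "v1"), "splice_not_supported_by_pext",
                       "not_LoF", "not_applicable"))
}

#' Names of the available fixture scenarios
#' @return Character vector of scenario names.
#' @export
scenario_catalog <- function() {
  c("clean_nonsense", "frameshift_no_reads", "homopolymer_frameshift",
    "gc_rich", "complex_mapping", "minor_mapping", "genotyping_fail",
    "last_exon", "penultimate_window", "low_pext", "minority_at_max",
    "minority_mid", "overprinting", "overhang_exon", "mnv_rescue",
    "frame_restoring_pair", "reinitiation_strong", "strong_splice_rescue",
    "weak_splice_rescue", "retained_stop", "out_of_frame_cryptic",
    "in_frame_skip", "intron_retention", "splice_unsupported_pext")
}

scenario_builder <- function(name) {
  switch(name,
    clean_nonsense = sc_clean_nonsense,
    frameshift_no_reads = sc_frameshift_no_reads,
    homopolymer_frameshift = sc_homopolymer_frameshift,
    gc_rich = sc_gc_rich,
    complex_mapping = sc_complex_mapping,
    minor_mapping = sc_minor_mapping,
    genotyping_fail = sc_genotyping_fail,
    last_exon = sc_last_exon,
    penultimate_window = sc_penultimate_window,
    low_pext = sc_low_pext,
    minority_at_max = sc_minority_at_max,
    minority_mid = sc_minority_mid,
    overprinting = sc_overprinting,
    overhang_exon = sc_overhang_exon,
    mnv_rescue = sc_mnv_rescue,
    frame_restoring_pair = sc_frame_restoring_pair,
    reinitiation_strong = sc_reinitiation_strong,
    strong_splice_rescue = sc_strong_splice_rescue,
    weak_splice_rescue = sc_weak_splice_rescue,
    retained_stop = sc_retained_stop,
    out_of_frame_cryptic = sc_out_of_frame_cryptic,
    in_frame_skip = sc_in_frame_skip,
    intron_retention = sc_intron_retention,
    splice_unsupported_pext = sc_splice_unsupported_pext,
    stop("unknown scenario '", name, "'; catalog: ",
         paste(scenario_catalog(), collapse = ", ")))
}

## ---------------------------------------------------------------------------
## Format writers (toy scale)
## ---------------------------------------------------------------------------

write_fixture_fasta <- function(seqs, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}

write_fixture_gtf <- function(transcripts, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (tx in transcripts) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     tx$gene_id, tx$transcript_id)
    if (length(tx$tags))
      attrs <- paste(attrs, paste(sprintf('tag "%s";', tx$tags), collapse = " "))
    ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
    for (i in seq_len(nrow(ex)))
      writeLines(paste(tx$chrom, "lofcurate_fixture", "exon", ex$start[i],
                       ex$end[i], ".", tx$strand, ".", attrs, sep = "\t"), con)
    if (tx$is_coding) {
      cd <- tx$cds   # transcript orientation: cumulative phase is in order
      cum <- c(0, cumsum(cd$end - cd$start + 1))
      frame <- (3 - cum[seq_len(nrow(cd))] %% 3) %% 3
      ord <- order(cd$start)
      for (i in ord)
        writeLines(paste(tx$chrom, "lofcurate_fixture", "CDS", cd$start[i],
                         cd$end[i], ".", tx$strand, frame[i], attrs,
                         sep = "\t"), con)
    }
  }
  invisible(path)
}

write_fixture_vcf <- function(variants, contig_lens, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", names(contig_lens), ",length=", contig_lens, ">"),
    '##INFO=<ID=VCLASS,Number=1,Type=String,Description="Annotated variant class">',
    '##INFO=<ID=GENE,Number=1,Type=String,Description="Gene identifier">',
    '##INFO=<ID=TRHIT,Number=.,Type=String,Description="Per-transcript pLoF annotation tx:0/1">',
    '##INFO=<ID=SpliceAI,Number=.,Type=String,Description="SpliceAI ALLELE|SYMBOL|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL">',
    '##INFO=<ID=PG,Number=1,Type=String,Description="Phase group identifier">',
    '##INFO=<ID=NOREAD,Number=0,Type=Flag,Description="Read data unavailable">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "SAMPLE1", sep = "\t")), con)
  v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  for (i in seq_len(nrow(v))) {
    info <- paste0("VCLASS=", v$vclass[i], ";GENE=", v$gene[i],
                   ";TRHIT=", v$trhit[i])
    if (!is.na(v$spliceai[i])) info <- paste0(info, ";SpliceAI=", v$spliceai[i])
    if (!is.na(v$pg[i])) info <- paste0(info, ";PG=", v$pg[i])
    if (isTRUE(v$noread[i])) info <- paste0(info, ";NOREAD")
    ad <- paste0(v$dp[i] - v$alt_reads[i], ",", v$alt_reads[i])
    writeLines(paste(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], ".",
                     "PASS", info, "GT:DP:GQ:AD",
                     paste0("0/1:", v$dp[i], ":", v$gq[i], ":", ad),
                     sep = "\t"), con)
  }
  invisible(path)
}

write_fixture_tsv <- function(variants, path) {
  v <- variants[order(variants$chrom, variants$pos), , drop = FALSE]
  df <- data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
                   variant_class = v$vclass, gene_id = v$gene, depth = v$dp,
                   genotype_quality = v$gq,
                   allele_balance = round(v$alt_reads / v$dp, 6),
                   spliceai = ifelse(is.na(v$spliceai), ".", v$spliceai),
                   phase_group = ifelse(is.na(v$pg), ".", v$pg),
                   has_read_data = !v$noread,
                   transcripts_hit = gsub(",", ";", v$trhit),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_pext_tsv <- function(pext, path) {
  utils::write.table(pext, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_repeats_bed <- function(repeats, path) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(repeats) && nrow(repeats))
    writeLines(paste(repeats$chrom, repeats$start - 1, repeats$end,
                     repeats$name, sep = "\t"), con)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Scenario and cohort generation
## ---------------------------------------------------------------------------

build_scenario_instances <- function(name, seed, strands) {
  idx <- match(name, scenario_catalog())
  builder <- scenario_builder(name)
  out <- list()
  for (k in seq_along(strands)) {
    strand <- strands[k]
    chrom <- paste0("chrT", k)
    pfx <- paste0(name, if (strand == "+") "_p_" else "_m_")
    set.seed((seed * 1009L + idx * 17L + k) %% .Machine$integer.max)
    inst <- builder(chrom, strand, pfx)
    inst$strand <- strand; inst$chrom <- chrom
    out[[k]] <- inst
  }
  out
}

assemble_scenario <- function(name, seed, instances) {
  seqs <- list(); transcripts <- list()
  variants <- NULL; pext <- NULL; repeats <- NULL; expected <- NULL
  for (inst in instances) {
    g1 <- inst$genes[[1]]
    seqs[[inst$chrom]] <- g1$seq
    for (g in inst$genes)
      transcripts[[g$transcript$transcript_id]] <- g$transcript
    ex <- inst$expected
    ex$strand <- inst$strand
    variants <- rbind(variants, inst$variants)
    pext <- rbind(pext, inst$pext)
    repeats <- rbind(repeats, inst$repeats)
    expected <- rbind(expected, ex)
  }
  key <- setNames(paste(variants$chrom, variants$pos, variants$ref,
                        variants$alt, sep = "-"), variants$id)
  expected$variant <- unname(key[expected$variant_id])
  structure(list(name = name, seed = seed, seqs = seqs,
                 transcripts = transcripts, variants = variants, pext = pext,
                 repeats = repeats, expected = expected),
            class = "lof_scenario")
}

#' Generate a synthetic curation scenario
#'
#' Builds the toy gene(s), variant records, pext and repeat tracks for one
#' named evasion/artifact mechanism, on both strands, together with the
#' expected flags, verdict and PVS1 outcome computed by construction from
#' the layout (never by running the engine). Generation is a pure function
#' of `(name, seed)`.
#'
#' @param name Scenario name; see [scenario_catalog()].
#' @param seed Integer seed.
#' @param dir Optional output directory; when given, writes `ref.fasta`,
#'   `genes.gtf`, `variants.vcf`, `variants.tsv`, `pext.tsv`, `repeats.bed`
#'   and `manifest.tsv`.
#' @param strands Strands to generate (default both).
#' @return A `lof_scenario` object (with `$files` when `dir` was given).
#' @export
generate_scenario <- function(name, seed, dir = NULL, strands = c("+", "-")) {
  sc <- assemble_scenario(name, seed,
                          build_scenario_instances(name, seed, strands))
  if (!is.null(dir)) sc <- write_scenario_files(sc, dir)
  sc
}

write_scenario_files <- function(sc, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- list(fasta = file.path(dir, "ref.fasta"),
            gtf = file.path(dir, "genes.gtf"),
            vcf = file.path(dir, "variants.vcf"),
            tsv = file.path(dir, "variants.tsv"),
            pext = file.path(dir, "pext.tsv"),
            repeats = file.path(dir, "repeats.bed"),
            manifest = file.path(dir, "manifest.tsv"))
  write_fixture_fasta(sc$seqs, f$fasta)
  write_fixture_gtf(sc$transcripts, f$gtf)
  write_fixture_vcf(sc$variants, vapply(sc$seqs, nchar, integer(1)), f$vcf)
  write_fixture_tsv(sc$variants, f$tsv)
  write_pext_tsv(sc$pext, f$pext)
  write_repeats_bed(sc$repeats, f$repeats)
  utils::write.table(sc$expected, f$manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sc$files <- f
  sc
}

#' Generate a synthetic cohort across scenarios
#'
#' Allocates `n` primary variants to scenarios by stratified rounding of the
#' mix proportions (largest fractional remainders first), replicating each
#' scenario's primary variant; phase-linked companion records are carried
#' along with re-suffixed phase groups. The manifest records every
#' variant's scenario and expected verdict.
#'
#' @param n Number of primary variants.
#' @param mix Named numeric vector of scenario proportions (must sum to 1).
#' @param seed Integer seed.
#' @param dir Optional output directory (same files as
#'   [generate_scenario()]).
#' @return A `lof_scenario`-like object whose `expected` manifest has `n`
#'   primary rows.
#' @export
generate_cohort <- function(n, mix, seed, dir = NULL) {
  if (abs(sum(mix) - 1) > 1e-9) stop("mix proportions must sum to 1")
  if (is.null(names(mix)) || !all(names(mix) %in% scenario_catalog()))
    stop("mix must be named by scenario; see scenario_catalog()")
  raw <- n * mix
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(-(raw - counts), names(mix))
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  seqs <- list(); transcripts <- list()
  variants <- NULL; pext <- NULL; repeats <- NULL; expected <- NULL
  ci <- 0L
  for (nm in names(mix)) {
    k <- counts[[nm]]
    if (k == 0) next
    ci <- ci + 1L
    inst <- build_scenario_instances(nm, seed, "+")[[1]]
    chrom <- paste0("chrC", ci)
    inst$variants$chrom <- chrom
    if (nrow(inst$repeats)) inst$repeats$chrom <- chrom
    g1 <- inst$genes[[1]]
    seqs[[chrom]] <- g1$seq
    for (g in inst$genes) {
      g$transcript$chrom <- chrom
      transcripts[[g$transcript$transcript_id]] <- g$transcript
    }
    pext <- rbind(pext, inst$pext)
    repeats <- rbind(repeats, inst$repeats)
    for (r in seq_len(k)) {
      v <- inst$variants
      v$id <- paste0(v$id, "_r", r)
      v$pg <- ifelse(is.na(v$pg), NA_character_, paste0(v$pg, "_r", r))
      variants <- rbind(variants, v)
      ex <- inst$expected
      ex$variant_id <- paste0(ex$variant_id, "_r", r)
      ex$scenario <- nm
      expected <- rbind(expected, ex)
    }
  }
  if (is.null(variants)) {           # n = 0: empty but valid outputs
    variants <- data.frame(id = character(), chrom = character(),
                           pos = integer(), ref = character(),
                           alt = character(), vclass = character(),
                           gene = character(), trhit = character(),
                           dp = integer(), gq = integer(),
                           alt_reads = integer(), spliceai = character(),
                           pg = character(), noread = logical())
    expected <- data.frame(variant_id = character(), profile = character(),
                           expected_flags = character(),
                           expected_verdict = character(),
                           expected_pvs1 = character(),
                           expected_confirm = logical(),
                           companion = logical(), scenario = character())
  }
  key <- setNames(paste(variants$chrom, variants$pos, variants$ref,
                        variants$alt, sep = "-"), variants$id)
  expected$variant <- unname(key[expected$variant_id])
  sc <- structure(list(name = "cohort", seed = seed, seqs = seqs,
                       transcripts = transcripts, variants = variants,
                       pext = pext, repeats = repeats, expected = expected,
                       counts = counts),
                  class = "lof_scenario")
  if (!is.null(dir)) sc <- write_scenario_files(sc, dir)
  sc
}

#' Curate a generated scenario in memory
#'
#' Convenience wrapper: builds the curation context straight from a
#' `lof_scenario` object's in-memory pieces and runs the engine. Variant
#' bundles are constructed exactly as the VCF reader would construct them.
#'
#' @param sc A [generate_scenario()] / [generate_cohort()] result.
#' @param profile A [rule_profile()].
#' @return List of `curation_result`s, one per curated (pLoF) variant, named
#'   by variant id.
#' @export
curate_scenario <- function(sc, profile = rule_profile("conservative")) {
  v <- sc$variants
  is_plof <- v$vclass %in% PLOF_CLASSES
  partners <- v[!is_plof & !is.na(v$pg), , drop = FALSE]
  pp <- if (nrow(partners))
    data.frame(chrom = partners$chrom, pos = partners$pos, ref = partners$ref,
               alt = partners$alt, phase_group_id = partners$pg,
               stringsAsFactors = FALSE) else NULL
  ref_seq <- Biostrings::DNAStringSet(unlist(sc$seqs))
  ctx <- curation_context(sc$transcripts, ref_seq,
                          pext = pext_track(sc$pext),
                          repeats = if (nrow(sc$repeats)) sc$repeats else NULL,
                          phase_partners = pp)
  bundles <- lapply(which(is_plof), function(i)
    variant_bundle(v$chrom[i], v$pos[i], v$ref[i], v$alt[i], v$vclass[i],
                   qc = qc_metrics(depth = v$dp[i], genotype_quality = v$gq[i],
                                   allele_balance = v$alt_reads[i] / v$dp[i]),
                   spliceai = if (is.na(v$spliceai[i])) NULL else v$spliceai[i],
                   phase_group_id = v$pg[i], has_read_data = !v$noread[i],
                   transcripts_hit = parse_trhit(v$trhit[i]),
                   gene_id = v$gene[i]))
  names(bundles) <- v$id[is_plof]
  res <- curate_cohort(bundles, ctx, profile)
  names(res) <- names(bundles)
  res
}
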