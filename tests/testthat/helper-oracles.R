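# Independent oracles used to check the implementation by a different route.

# enumerate coding bases of a transcript in transcript orientation;
# returns integer vector of genomic positions, index i = coding offset i-1
oracle_coding_positions <- function(transcript) {
  pos <- integer()
  for (i in seq_len(nrow(transcript$cds))) {
    s <- transcript$cds$start[i]; e <- transcript$cds$end[i]
    pos <- c(pos, if (transcript$strand == "+") s:e else e:s)
  }
  pos
}

# brute-force MNV consequence: apply all SNVs to the full genome string,
# extract and translate the whole CDS, compare the affected residue
oracle_mnv <- function(genome_seq, transcript, snvs) {
  g <- strsplit(genome_seq, "")[[1]]
  for (s in snvs) g[s$pos] <- s$alt
  mutated <- paste(g, collapse = "")
  extract_cds <- function(seqchr) {
    pieces <- vapply(seq_len(nrow(transcript$cds)), function(i)
      substr(seqchr, transcript$cds$start[i], transcript$cds$end[i]),
      character(1))
    if (transcript$strand == "+") paste(pieces, collapse = "")
    else as.character(Biostrings::reverseComplement(Biostrings::DNAString(
      paste(rev(pieces), collapse = ""))))
  }
  tr <- function(cds) as.character(Biostrings::translate(
    Biostrings::DNAString(cds), if.fuzzy.codon = "X"))
  p_ref <- tr(extract_cds(genome_seq))
  p_mut <- tr(extract_cds(mutated))
  map <- build_coding_map(transcript)
  offs <- vapply(snvs, function(s) coding_offset(map, s$pos), numeric(1))
  ci <- unique(offs %/% 3)
  stopifnot(length(ci) == 1)         # oracle defined for one shared codon
  aa_ref <- substr(p_ref, ci + 1, ci + 1)
  aa_mut <- substr(p_mut, ci + 1, ci + 1)
  if (aa_mut == "*") "nonsense_retained"
  else if (aa_mut == aa_ref) "synonymous"
  else "missense"
}

# two-sided Fisher p by explicit enumeration with choose()-based
# hypergeometric probabilities (margins fixed)
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1.0)
  as <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, as) * choose(r2, c1 - as) / choose(n, c1)
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# a small plain two-exon plus-strand transcript used across tests
toy_tx <- function(strand = "+") {
  transcript_model("t1", "g1", "chr1", strand,
                   exons = data.frame(start = c(101, 301), end = c(200, 400)),
                   cds = data.frame(start = c(101, 301), end = c(200, 400)))
}
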