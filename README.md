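# lofcurate

Curation of predicted loss-of-function (pLoF) variants, and adjustment of
the ACMG/AMP PVS1 evidence strength, as an automated and auditable rule
engine.

Nonsense, frameshift, and essential (±1–2) splice-site variants are
annotated pLoF by standard pipelines, but many never abolish protein
expression — especially in population sequencing data, where pLoF calls
are enriched for rescues and artifacts. `lofcurate` is for researchers and
curators who need those calls triaged reproducibly: it evaluates every
variant against three categories of evidence and produces a defensible,
fully audited verdict.

## The model

Each variant accumulates **flags** in three categories:

- **Predicted rescue by secondary sequence properties** — in-phase
  multi-nucleotide variants re-translated per codon; frame-restoring indel
  pairs (Σ indel lengths ≡ 0 mod 3 on one haplotype); SpliceAI-predicted
  cryptic-site rescues classified by frame parity of the distance to the
  annotated site, with retained intronic sequence stop-scanned in the
  inherited reading frame; in-frame exon skipping; translational
  reinitiation at a downstream in-frame ATG; overhang exons.
- **Uncertain biological relevance** — exon pext (proportion expressed
  across transcripts) ratio to the gene maximum; pLoF in < 50% of coding
  transcripts; weak exon conservation; overprinted transcripts; NMD escape
  (last exon, last 50 bp of the penultimate exon, single-exon genes) when
  the truncation removes < 25% (conservative) of the coding sequence.
- **Potential technical artifacts** — depth/GQ/allele-balance below
  threshold, homopolymer slippage indels (run ≥ 5), repeat-track mapping
  problems, GC-rich context, low-complexity overlap, strand bias.

Flags map to tiers of the five-level verdict scale

```
LoF < likely_LoF < uncertain_LoF < likely_not_LoF < not_LoF
```

and the **most impactful tier wins**. A flagless variant is `LoF`; a
frameshift without read data is at least `uncertain_LoF`. For PVS1, each
non-technical flag maps to `no_change` / `cap_strong` / `cap_moderate` /
`do_not_use` and the **single worst consequence** applies (never a sum);
variants with technical flags require analytical confirmation before PVS1
can be assessed at all. Every numeric threshold lives in a `rule_profile`
with published `conservative` and `lenient` presets.

## Worked example

Generate a synthetic last-exon scenario (a nonsense variant escaping NMD
and removing 5% of the coding sequence), curate it, and inspect the result:

```r
library(lofcurate)

sc  <- generate_scenario("last_exon", seed = 7, strands = "+")
res <- curate_scenario(sc, rule_profile("conservative"))
print(res[[1]])
#> <curation_result chrT1-813-C-A: likely_not_LoF  (primary: last_exon; PVS1 max strong)>
#>   - last_exon [biological_relevance -> likely_not_LoF]
res[[1]]$flags$detail
#> [1] "termination escapes NMD, removes 4.7% of CDS"
res[[1]]$pvs1$trail
#>        flag consequence
#> 1 last_exon  cap_strong
```

The variant escapes nonsense-mediated decay (it terminates in the last
exon), so a truncated protein is expected rather than a lost one: the
verdict is `likely_not_LoF`, and because the truncation removes less than
10% of the CDS, PVS1 is capped at Strong rather than Moderate.

The same analysis runs from the shell on real files:

```sh
inst/cli/lofcurate fixtures --scenario last_exon --seed 7 --out fx/
inst/cli/lofcurate curate --vcf fx/variants.vcf --gtf fx/genes.gtf \
    --fasta fx/ref.fasta --pext fx/pext.tsv --repeats fx/repeats.bed \
    --profile conservative --out out/
inst/cli/lofcurate summarize --report out/report.tsv
```

`read_variants()` applies the standard genotype prefilter first (depth
< 10, GQ < 20, allele balance < 20% for heterozygous calls are excluded,
with counts logged), and `write_report()` emits a per-variant TSV plus a
JSON summary of verdicts, flags and primary reasons.

## Layout

- `R/` — domain types and threshold profiles; transcript/CDS geometry
  (coding maps, truncation fractions, NMD escape, pext categories);
  sequence rules (homopolymers, MNVs, indel pairs, reinitiation, technical
  context); SpliceAI interpretation; the flag/verdict/PVS1 engine; format
  IO; the fixture generator; summary statistics.
- `vignettes/lof-curation-methods.Rmd` — the model, every tunable with its
  default and rationale, design decisions, and known limitations.
- `tests/testthat/` — unit, property and acceptance suites, including
  brute-force oracles for coding-offset arithmetic, MNV translation and
  Fisher's exact test.
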