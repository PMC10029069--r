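---
title: "Curating predicted loss-of-function variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating predicted loss-of-function variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Standard annotation pipelines call a variant "predicted loss of function"
(pLoF) when it is a nonsense, frameshift, or essential (±1–2) splice-site
change. In population sequencing data a substantial fraction of these calls
do not abolish protein expression: the surrounding sequence rescues the
lesion (an in-phase multi-nucleotide variant, a frame-restoring indel pair,
a cryptic splice site, in-frame exon skipping, translational reinitiation,
an overhang exon), the affected transcript is of marginal biological
relevance (low relative expression, a minority of transcripts, a weakly
conserved or overprinted exon, NMD-escaping last-exon truncations), or the
call is a sequencing artifact (homopolymer slippage indels, mapping
problems in repetitive sequence, marginal genotypes, GC-rich capture
failure, strand bias). `lofcurate` implements this assessment as a
deterministic, auditable rule engine.

Each variant receives a set of *flags*, each belonging to one of three
categories — `rescue`, `biological_relevance`, `technical` — and each
mapped to one of five verdict tiers:

    LoF < likely_LoF < uncertain_LoF < likely_not_LoF < not_LoF

The final verdict is the *most impactful* (right-most) tier among the
triggered flags. Two special rules live in the resolver rather than in a
flag: a variant with no flags stands as `LoF`, and a frameshift without
inspectable read data contributes an implicit `uncertain_LoF` tier, because
frame-restoring indels in the surrounding sequence cannot be excluded
without read visualization — so such variants are uncertain unless
something more impactful fires.

## Thresholds

All numeric cutoffs live in a single `rule_profile()` object with two
presets. The conservative preset flags more aggressively and is the
recommended setting for population data, where pLoF calls are strongly
enriched for artifacts and rescues; the lenient preset discards less.

| field | conservative | lenient | units / meaning |
|---|---|---|---|
| `depth_min` | 15 | 10 | reads; genotyping flag below this |
| `ab_min` | 0.35 | 0.25 | ALT allele balance |
| `gq_min` | 30 | 20 | phred genotype quality |
| `repeat_track_min` | 5 | 3 | repeat tracks; complex mapping when *exceeded* |
| `homopolymer_min_run` | 5 | 7 | bases; indel-in-run artifact flag |
| `spliceai_rescue_min` | 0.2 | 0.2 | SpliceAI delta score for any predicted event |
| `spliceai_strong_margin` | 0.2 | 0.2 | gain within this of the loss ⇒ strong rescue |
| `reinit_strong_max_fraction` | 0.25 | 0.10 | CDS fraction a reinitiating ATG may remove |
| `truncation_max_fraction` | 0.25 | 0.10 | CDS fraction for last-exon / skip rescues |
| `low_pext_max_ratio` | 0.20 | 0.10 | exon pext / gene max at or below ⇒ low |
| `mid_pext_max_ratio` | 0.50 | 0.30 | upper bound of the mid category |
| `minority_fraction` | 0.50 | 0.50 | strict fraction of coding transcripts |
| `nmd_penultimate_window` | 50 | 50 | bp at the 3' end of the penultimate exon |
| `gc_rich_min` | 0.70 | 0.70 | GC fraction over `gc_window` (100 bp) |
| `indel_pair_window` | 100 | 100 | bp; co-observation span for indel pairs |

Three of these are the package's own decisions where the underlying
protocol names a rule without a number, chosen once and kept configurable:
the GC-rich cutoff (0.70 over a centered 100 bp window, the usual
capture-failure regime), the strand-bias call (ALT forward-strand fraction
≤ 0.05 or ≥ 0.95 with at least 10 ALT reads), and the indel co-observation
window (100 bp, bounded by what a read pile-up can show). The NMD window is
fixed at 50 bp, the stricter of the quoted 50–55 bp range. The SpliceAI
threshold has no lenient relaxation; both presets use 0.2, the tool's
recommended cutoff.

Note one deliberate anomaly: the repeat-track thresholds (complex mapping
when more than 5 / more than 3 tracks overlap) make the *lenient* profile
flag harder for counts of 4–5. The published rule table states these values
verbatim, so they are implemented verbatim, and the profile-monotonicity
test asserts the inversion explicitly instead of hiding it.

## Geometry conventions

All intervals are stored 1-based inclusive, the native convention of GTF,
VCF and the Bioconductor interval stack used for IO (BED input is shifted
at read time). Coding offsets are 0-based — the first base of the
initiation codon is offset 0 — which makes the worked truncation-fraction
examples exact: the fraction removed by a termination event at offset *o*
is `(L − o) / L` for CDS length *L*, counting the termination base itself.
The CDS here includes the stop codon. Exon indices, "upstream", and codon
phases are always in transcript orientation; a minus-strand transcript's
exon 1 is the genomically rightmost. Every geometric fixture scenario is
generated on both strands for exactly this reason.

NMD escape is declared when the termination lands in the last coding exon,
within the final 50 coding bases of the penultimate exon (counted inclusive
of the junction-proximal base: a variant exactly 50 bases from the exon's
3' end escapes, 51 does not), or anywhere in a single-coding-exon
transcript. Escape alone is not a rescue: the `last_exon` flag fires only
when the truncation also removes less than `truncation_max_fraction` of the
CDS; otherwise the escape is recorded in the audit notes and the verdict
stays on the LoF side pending other evidence.

## Splice interpretation

For an essential splice variant the relevant loss score is donor loss for
donors and acceptor loss for acceptors. A gain of the same site type at or
above 0.2 defines a cryptic site; its position (the SpliceAI delta
position, relative to the variant on the genome axis) is converted to a
distance from the annotated splice site through transcript geometry, and
frame parity of that distance decides in-frame versus out-of-frame. A gain
on the exonic side is a cryptic deletion; on the intronic side it is a
partial retention, whose retained interval is translated in the inherited
frame — including the junction-spanning codon — and scanned for stop
codons. An in-frame rescue that introduces a stop is no rescue at all: the
flag is `splice_rescue_stop`, tier `LoF`. Rescue strength is `strong` when
the gain is within 0.2 of the loss, `weak` otherwise, and gains are
compared only against the loss of their own site type (donor gains versus
donor loss), a documented interpretation choice.

When the *opposite* site of the affected exon also loses ≥ 0.2 with no
qualifying gain, the delta position disambiguates two mechanisms: a loss
sitting at the exon's other boundary means exon skipping (in-frame or not
by the exon's CDS length mod 3, with the skipped fraction measured against
the CDS), while a loss at the far end of the variant's intron means
retention of that intron (tier `LoF`). When a qualifying cryptic gain and a
qualifying opposite-site loss disagree in frame parity the event is
`multiple_events` (uncertain); when they agree, the gain wins as the more
direct evidence. A site with no predicted loss at all is either `uncertain`
or, if the adjacent exon's pext is low, a non-essential site — the
transcript's own junction is not biologically supported, which surfaces as
the `splice_not_supported_by_pext` flag. With per-base pext available, a
flat profile across the annotated junction (intron side within 5% of the
exon side) is treated the same way.

For truncation-fraction and NMD arithmetic a splice variant is anchored at
the first coding base its disruption removes: the first coding base of the
downstream exon for donors, of the affected exon for acceptors.

## pext categories and transcript relevance

An exon's mean pext is expressed as a ratio to the gene maximum. The low
and mid boundaries come from the rule table; the upper split between
"close to maximum" (ratio in [mid, 0.9)) and "at maximum" (≥ 0.9) is this
package's decision, needed because the verdict table distinguishes the two
but no source defines the boundary. The combination rules then read:
minority-of-transcripts (strictly fewer than 50% of the gene's coding
transcripts annotated pLoF) with pext at max is `LoF`-tier evidence, close
to max `likely_LoF`, mid `uncertain_LoF`; the same ladder applies to
weakly conserved exons (below the 25th percentile of the gene's exon means,
when a conservation track is supplied), except the mid rung maps to
`likely_not_LoF`. An exon with low pext is `not_LoF` outright. A missing
pext value is never evidence in either direction; the skipped rule is
recorded in the audit notes. A gene whose maximum pext is 0 is treated as
pext-uninformative the same way.

Overhang exons are detected geometrically: the variant's containing exon
overlaps an exon of another coding transcript whose span stops short of the
variant — the variant sits in an extension spliced out elsewhere.
Overprinting is an annotation input (`overprinted` transcript tag), not
recomputed: calling alternate-ORF conservation is out of scope.

## PVS1

Technical flags never modify PVS1 — analytic validity is a separate
question from pathogenicity — but an unconfirmed variant carrying any
technical flag cannot be assessed at all, so its strength is reported as
`pending_confirmation`. For the rest, every non-technical flag maps to one
of `no_change`, `cap_strong`, `cap_moderate`, `do_not_use`, and the single
worst consequence is applied; downgrades are never additive. Truncation-
type rescues (weak splice rescue, strong reinitiation, last exon, in-frame
skip) cap at Strong when the event removes less than 10% of the CDS and at
Moderate from 10% up, mirroring the SVI decision tree's 10% split. Flags
that remove the premise of PVS1 (low pext, unsupported splice site,
overhang exon, overprinting, MNV rescue, frame-restoring indel, strong
splice rescue) mean PVS1 is not applied at any level. A flagless
`uncertain_LoF` verdict (the unverifiable frameshift) caps at Strong.

## The synthetic-data generator

`generate_scenario()` builds one toy gene per mechanism — 2–6 exons,
600–2,000 bp contigs, 90 bp introns, GCT filler codons chosen so that no
incidental ATG, stop, homopolymer run or GC-rich window appears where a
rule could see one — and places the scenario's lesion with its expected
flags, verdict and PVS1 outcome derived from the layout arithmetic, never
from the engine. The files are real formats (FASTA, GTF, VCF 4.2, TSV,
BED), each scenario is emitted on both strands, and generation is a pure
function of `(name, seed)`: the seed randomizes only non-load-bearing
filler (pads, intron interiors, constrained to runs ≤ 2).

What the generator does *not* emulate matters for interpreting green
tests: real exome noise (the QC metrics are stipulated, not sampled from
error processes), real SpliceAI behavior (scores are inputs by
construction), tissue-dependent pext, overlapping genes, multi-sample
VCFs, and gnomAD-scale allele-frequency structure. Passing the scenario
suite shows the rules compute what they are defined to compute on both
strands and under both profiles; it does not validate the thresholds
against biology.

Problem sizes used by the tests and the acceptance script: 24 scenarios ×
2 strands × 2 profiles (≈ 100 expectation checks), a 200-variant synthetic
cohort over a 13-scenario mix, the full 64-codon × 3-position-pair MNV
grid against brute-force translation, and every 2×2 table with total ≤ 30
(46,375 tables) against hypergeometric enumeration.

## Numerical choices and degenerate inputs

Fisher's two-sided p uses the probability-mass definition (sum of tables no
more probable than the observed one, fixed margins), with a 1e−7 relative
tolerance when comparing probabilities so floating-point noise cannot drop
a tied table; degenerate margins return p = 1 by convention. The chi-square
statistic is the closed form with optional Yates correction and errors on a
zero margin. Allele balance is derived from allele depths when not given
directly; the prefilter's AB cut applies to heterozygous calls only, and
all three prefilter cuts are strict (`<`), so DP 10 / GQ 20 / AB 0.20 are
retained. Ties among equal-tier flags when naming a primary reason break by
category (rescue, then biological relevance, then technical), then
lexicographically. Multi-allelic VCF records are expanded to one bundle per
ALT allele.

## Known limitations

The engine assesses single heterozygous variants: diploid genotype logic,
structural variants, and clonal-hematopoiesis handling are out of scope, as
is running the upstream annotators (LOFTEE/VEP consequence calls, SpliceAI
scores and pext values are inputs). Frameshift termination position is
approximated by the variant position itself rather than by scanning for the
downstream PTC, a conservative simplification that matters only near exon
boundaries. Conservation-based rules run only when a per-exon conservation
table is supplied.
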