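#' @import methods
#' @importFrom stats setNames
NULL

## ---------------------------------------------------------------------------
## Verdict tiers
## ---------------------------------------------------------------------------

#' Five-level loss-of-function verdict scale
#'
#' Verdicts are totally ordered by "impact", i.e. distance from a true LoF
#' call: `LoF < likely_LoF < uncertain_LoF < likely_not_LoF < not_LoF`.
#' When several flags apply to one variant the most impactful (largest)
#' tier wins.
#'
#' @format Character vector of the five verdict levels, in increasing impact
#'   order.
#' @export
VERDICT_LEVELS <- c("LoF", "likely_LoF", "uncertain_LoF",
                    "likely_not_LoF", "not_LoF")

#' Rank of a verdict on the impact scale
#'
#' @param verdict Character vector of verdict names.
#' @return Integer rank(s), 1 = `LoF` ... 5 = `not_LoF`.
#' @export
verdict_rank <- function(verdict) {
  r <- match(verdict, VERDICT_LEVELS)
  if (anyNA(r)) stop("unknown verdict: ", paste(verdict[is.na(r)], collapse = ", "))
  r
}

FLAG_CATEGORIES <- c("rescue", "biological_relevance", "technical")

## ---------------------------------------------------------------------------
## Flag catalog
## ---------------------------------------------------------------------------

#' Catalog of curation flags
#'
#' Every rule the engine can trigger, with its category (predicted rescue by
#' secondary sequence properties, uncertain biological relevance, potential
#' technical artifact) and the verdict tier the rule maps to. The tier
#' assignment encodes the verdict-rule table of the framework: e.g. a splice
#' rescue that introduces a stop codon stays `LoF`, a homopolymer indel is
#' `likely_not_LoF`, an exon with low relative pext is `not_LoF`.
#'
#' @return A data.frame with columns `name`, `category`, `tier`.
#' @export
flag_catalog <- function() {
  rbind(
    data.frame(name = c("splice_rescue_stop", "intron_retention",
                        "out_of_frame_cryptic", "out_of_frame_exon_skip",
                        "reinitiation_over_limit",
                        "reinitiation_weak", "mixed_splice_events",
                        "splice_rescue_weak", "reinitiation_strong",
                        "splice_rescue_strong", "in_frame_exon_skip",
                        "overhang_exon", "mnv_rescue", "frame_restoring_indel"),
               category = "rescue",
               tier = c("LoF", "LoF", "LoF", "LoF",
                        "likely_LoF",
                        "uncertain_LoF", "uncertain_LoF",
                        "likely_not_LoF", "likely_not_LoF",
                        "not_LoF", "not_LoF", "not_LoF", "not_LoF", "not_LoF")),
    data.frame(name = c("minority_at_max", "weak_conservation_at_max",
                        "minority_close_to_max", "weak_conservation_close_to_max",
                        "minority_mid", "weak_conservation_mid",
                        "overprinting", "last_exon",
                        "low_pext", "splice_not_supported_by_pext"),
               category = "biological_relevance",
               tier = c("LoF", "LoF", "likely_LoF", "likely_LoF",
                        "uncertain_LoF", "likely_not_LoF",
                        "likely_not_LoF", "likely_not_LoF",
                        "not_LoF", "not_LoF")),
    data.frame(name = c("genotyping_marginal", "minor_mapping",
                        "low_depth", "low_gq", "skewed_ab", "strand_bias",
                        "gc_rich", "low_complexity", "homopolymer",
                        "complex_mapping"),
               category = "technical",
               tier = c("likely_LoF", "likely_LoF",
                        rep("likely_not_LoF", 8)))
  )
}

#' Construct a curation flag
#'
#' @param name Flag identifier; must be in [flag_catalog()].
#' @param detail Free-text audit string.
#' @param fraction_removed Optional fraction of coding sequence removed by the
#'   event the flag describes (used by the PVS1 consequence map).
#' @return A one-row data.frame with columns `name`, `category`, `tier`,
#'   `detail`, `fraction_removed`.
#' @export
make_flag <- function(name, detail = "", fraction_removed = NA_real_) {
  cat_ <- flag_catalog()
  i <- match(name, cat_$name)
  if (is.na(i)) stop("unknown flag name: ", name)
  data.frame(name = name, category = cat_$category[i], tier = cat_$tier[i],
             detail = detail, fraction_removed = fraction_removed,
             stringsAsFactors = FALSE)
}

#' An empty flag set
#' @return Zero-row flag data.frame with the standard columns.
#' @export
no_flags <- function() {
  data.frame(name = character(), category = character(), tier = character(),
             detail = character(), fraction_removed = numeric(),
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Rule profiles (curation thresholds)
## ---------------------------------------------------------------------------

#' Curation threshold profile
#'
#' Holds every numeric threshold used by the curation rules. Two presets are
#' provided: `"conservative"` (flags more variants as potentially evading
#' LoF; recommended for population data) and `"lenient"`. The preset values
#' are the published rule thresholds: read depth < 15/10, allele balance
#' < 35%/25%, genotype quality < 30/20, homopolymer run >= 5/7, repeat-track
#' overlap > 5/3, SpliceAI rescue threshold 0.2 (no lenient relaxation) with
#' a 0.2 strong-rescue margin, truncation/reinitiation coding-sequence
#' fractions 25%/10%, low-pext ratio <= 20%/10%, mid-pext ratio < 50%/30%,
#' minority-of-transcripts fraction 50%, NMD penultimate-exon window 50 bp.
#'
#' @param preset `"conservative"` or `"lenient"`.
#' @param ... Named overrides for individual fields.
#' @return An object of class `rule_profile` (named list of thresholds).
#' @examples
#' rule_profile("conservative")$depth_min   # 15
#' rule_profile("lenient", depth_min = 12)$depth_min
#' @export
rule_profile <- function(preset = c("conservative", "lenient"), ...) {
  preset <- match.arg(preset)
  p <- if (preset == "conservative") {
    list(depth_min = 15, ab_min = 0.35, gq_min = 30,
         repeat_track_min = 5, homopolymer_min_run = 5,
         spliceai_rescue_min = 0.2, spliceai_strong_margin = 0.2,
         reinit_strong_max_fraction = 0.25, truncation_max_fraction = 0.25,
         low_pext_max_ratio = 0.20, mid_pext_max_ratio = 0.50,
         minority_fraction = 0.50, nmd_penultimate_window = 50,
         gc_rich_min = 0.70, gc_window = 100, indel_pair_window = 100)
  } else {
    list(depth_min = 10, ab_min = 0.25, gq_min = 20,
         repeat_track_min = 3, homopolymer_min_run = 7,
         spliceai_rescue_min = 0.2, spliceai_strong_margin = 0.2,
         reinit_strong_max_fraction = 0.10, truncation_max_fraction = 0.10,
         low_pext_max_ratio = 0.10, mid_pext_max_ratio = 0.30,
         minority_fraction = 0.50, nmd_penultimate_window = 50,
         gc_rich_min = 0.70, gc_window = 100, indel_pair_window = 100)
  }
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad)) stop("unknown rule_profile fields: ", paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  p$preset <- preset
  structure(p, class = "rule_profile")
}

#' @export
print.rule_profile <- function(x, ...) {
  cat("<rule_profile:", x$preset, "preset>\n")
  flds <- setdiff(names(x), "preset")
  for (f in flds) cat(sprintf("  %-28s %s\n", f, format(x[[f]])))
  invisible(x)
}

## ---------------------------------------------------------------------------
## QC metrics and SpliceAI scores
## ---------------------------------------------------------------------------

#' Per-genotype quality-control metrics
#'
#' @param depth Read depth (non-negative integer), or `NA`.
#' @param genotype_quality Phred-scaled genotype quality, or `NA`.
#' @param allele_balance Fraction of reads supporting the ALT allele in
#'   `[0, 1]`, or `NA`.
#' @param strand_bias Optional fraction of ALT reads on the forward strand
#'   in `[0, 1]`.
#' @return A `qc_metrics` list.
#' @export
qc_metrics <- function(depth = NA_real_, genotype_quality = NA_real_,
                       allele_balance = NA_real_, strand_bias = NA_real_) {
  if (!is.na(depth) && depth < 0) stop("depth must be >= 0")
  if (!is.na(allele_balance) && (allele_balance < 0 || allele_balance > 1))
    stop("allele_balance must be in [0, 1]")
  if (!is.na(strand_bias) && (strand_bias < 0 || strand_bias > 1))
    stop("strand_bias must be in [0, 1]")
  structure(list(depth = depth, genotype_quality = genotype_quality,
                 allele_balance = allele_balance, strand_bias = strand_bias),
            class = "qc_metrics")
}

#' SpliceAI delta scores and positions
#'
#' @param ds_ag,ds_al,ds_dg,ds_dl Delta scores (acceptor gain/loss, donor
#'   gain/loss), each in `[0, 1]`.
#' @param dp_ag,dp_al,dp_dg,dp_dl Signed base offsets of each predicted event
#'   relative to the variant position (genome axis).
#' @return A `spliceai_scores` list.
#' @export
spliceai_scores <- function(ds_ag = 0, ds_al = 0, ds_dg = 0, ds_dl = 0,
                            dp_ag = 0, dp_al = 0, dp_dg = 0, dp_dl = 0) {
  ds <- c(ds_ag, ds_al, ds_dg, ds_dl)
  if (any(is.na(ds)) || any(ds < 0 | ds > 1))
    stop("SpliceAI delta scores must be in [0, 1]")
  structure(list(ds_ag = ds_ag, ds_al = ds_al, ds_dg = ds_dg, ds_dl = ds_dl,
                 dp_ag = dp_ag, dp_al = dp_al, dp_dg = dp_dg, dp_dl = dp_dl),
            class = "spliceai_scores")
}

## ---------------------------------------------------------------------------
## Transcript model
## ---------------------------------------------------------------------------

#' Transcript model (exon/CDS intervals)
#'
#' Intervals are genomic, 1-based inclusive (GTF convention). Exons are
#' stored in transcript orientation: index 1 is the 5'-most exon of the
#' transcript, which for minus-strand transcripts is the genomically
#' rightmost one.
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (any order; sorted
#'   internally).
#' @param cds Optional data.frame with columns `start`, `end`; each CDS
#'   interval must be contained in an exon. CDS here includes the stop codon.
#' @param tags Character vector of annotation tags (e.g. `"MANE_Select"`,
#'   `"overprinted"`).
#' @return A `transcript_model` object.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exons, cds = NULL, tags = character()) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)]))
    stop("exons overlap in transcript ", transcript_id)
  if (any(exons$end < exons$start)) stop("malformed exon interval")
  if (strand == "-") exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
  rownames(exons) <- NULL

  is_coding <- !is.null(cds) && nrow(cds) > 0
  if (is_coding) {
    cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
    if (strand == "-") cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
    rownames(cds) <- NULL
    for (i in seq_len(nrow(cds))) {
      inside <- any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
      if (!inside)
        stop("CDS interval ", cds$start[i], "-", cds$end[i],
             " outside any exon of ", transcript_id)
    }
    if (sum(cds$end - cds$start + 1) < 3)
      stop("coding transcript ", transcript_id, " has CDS length < 3")
  } else {
    cds <- data.frame(start = integer(), end = integer())
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds,
                 is_coding = is_coding, tags = tags),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model %s (%s) %s%s  %d exons, %d CDS bp%s>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons),
              sum(x$cds$end - x$cds$start + 1),
              if (length(x$tags)) paste0("  [", paste(x$tags, collapse = ","), "]") else ""))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Variant bundle
## ---------------------------------------------------------------------------

PLOF_CLASSES <- c("nonsense", "frameshift", "splice_donor", "splice_acceptor")

#' One pLoF variant and its annotations
#'
#' @param chrom,pos,ref,alt Variant in VCF convention (1-based `pos`).
#' @param variant_class One of `nonsense`, `frameshift`, `splice_donor`,
#'   `splice_acceptor`.
#' @param qc [qc_metrics()] for the carrier genotype.
#' @param spliceai Raw SpliceAI annotation string (standard 10-field format)
#'   or a [spliceai_scores()] object, or `NULL`.
#' @param phase_group_id Optional haplotype/phase group identifier.
#' @param has_read_data Whether read-level data was available for inspection.
#' @param transcripts_hit data.frame with columns `transcript_id`,
#'   `is_pLoF` (logical): the transcripts the variant lands in and whether
#'   it is annotated pLoF in each.
#' @param gene_id Gene the annotation refers to.
#' @return A `variant_bundle` object.
#' @export
variant_bundle <- function(chrom, pos, ref, alt, variant_class,
                           qc = qc_metrics(), spliceai = NULL,
                           phase_group_id = NA_character_,
                           has_read_data = TRUE,
                           transcripts_hit = data.frame(transcript_id = character(),
                                                        is_pLoF = logical()),
                           gene_id = NA_character_) {
  if (!variant_class %in% PLOF_CLASSES)
    stop("variant_class must be one of: ", paste(PLOF_CLASSES, collapse = ", "))
  if (variant_class == "frameshift" &&
      abs(nchar(ref) - nchar(alt)) %% 3 == 0)
    stop("frameshift variant with in-frame length change (", ref, ">", alt, ")")
  if (variant_class == "nonsense" && nchar(ref) != nchar(alt))
    stop("nonsense variant must be a substitution")
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 variant_class = variant_class, qc = qc, spliceai = spliceai,
                 phase_group_id = phase_group_id,
                 has_read_data = isTRUE(has_read_data),
                 transcripts_hit = transcripts_hit, gene_id = gene_id),
            class = "variant_bundle")
}

#' Variant key string (chrom-pos-ref-alt)
#' @param bundle A `variant_bundle`.
#' @return Character key.
#' @export
variant_key <- function(bundle) {
  paste(bundle$chrom, bundle$pos, bundle$ref, bundle$alt, sep = "-")
}

#' @export
print.variant_bundle <- function(x, ...) {
  cat(sprintf("<variant_bundle %s %s  gene=%s%s>\n", variant_key(x),
              x$variant_class, x$gene_id,
              if (!is.na(x$phase_group_id)) paste0(" phase=", x$phase_group_id) else ""))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Pext track
## ---------------------------------------------------------------------------

#' Per-exon pext (proportion expressed across transcripts) track
#'
#' @param exon_values data.frame with columns `gene_id`, `transcript_id`,
#'   `exon_index`, `mean_pext` (values in `[0, 1]`; exon index in transcript
#'   orientation).
#' @param per_base Optional data.frame with columns `chrom`, `start`, `end`,
#'   `value` of per-base pext over genomic intervals (used for junction-drop
#'   assessment of splice sites).
#' @param gene_max Optional named numeric vector of the maximum pext per
#'   gene; computed from `exon_values` when missing.
#' @return A `pext_track` object.
#' @export
pext_track <- function(exon_values, per_base = NULL, gene_max = NULL) {
  stopifnot(all(c("gene_id", "transcript_id", "exon_index", "mean_pext") %in%
                  names(exon_values)))
  if (nrow(exon_values) && any(exon_values$mean_pext < 0 | exon_values$mean_pext > 1))
    stop("pext values must be in [0, 1]")
  if (is.null(gene_max)) {
    gene_max <- tapply(exon_values$mean_pext, exon_values$gene_id, max)
    gene_max <- setNames(as.numeric(gene_max), names(gene_max))
  } else {
    for (g in unique(exon_values$gene_id)) {
      v <- exon_values$mean_pext[exon_values$gene_id == g]
      if (!is.na(gene_max[g]) && any(v > gene_max[g] + 1e-12))
        stop("gene_max for ", g, " below a stored exon value")
    }
  }
  structure(list(exon_values = exon_values, per_base = per_base,
                 gene_max = gene_max), class = "pext_track")
}

#' Look up the mean pext of one exon
#' @param track A [pext_track()].
#' @param transcript_id,exon_index Exon key (transcript orientation).
#' @return Numeric value or `NA` when the exon has no stored value.
#' @export
pext_exon_value <- function(track, transcript_id, exon_index) {
  ev <- track$exon_values
  i <- which(ev$transcript_id == transcript_id & ev$exon_index == exon_index)
  if (!length(i)) NA_real_ else ev$mean_pext[i[1]]
}
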