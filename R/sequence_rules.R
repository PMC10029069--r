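## Sequence- and haplotype-context rules: homopolymer artifact detection,
## multi-nucleotide variant (MNV) combination, frame-restoring indel pairs,
## translational reinitiation, and per-variant technical context (QC
## thresholds, GC content, repeat-track overlap).

#' Phase group of co-occurring variants
#'
#' @param group_id Identifier.
#' @param members List of [variant_bundle()]s (or minimal records with
#'   `chrom`, `pos`, `ref`, `alt`) sharing one haplotype.
#' @return A `phase_group` object; members sorted by position.
#' @export
phase_group <- function(group_id, members) {
  chroms <- vapply(members, function(m) m$chrom, character(1))
  if (length(unique(chroms)) > 1) stop("phase group spans contigs")
  pos <- vapply(members, function(m) as.integer(m$pos), integer(1))
  structure(list(group_id = group_id, members = members[order(pos)]),
            class = "phase_group")
}

## simple-indel decomposition: one allele must be a prefix of the other
indel_bases <- function(ref, alt) {
  if (nchar(ref) == nchar(alt)) return(NULL)
  shorter <- if (nchar(ref) < nchar(alt)) ref else alt
  longer <- if (nchar(ref) < nchar(alt)) alt else ref
  if (substr(longer, 1, nchar(shorter)) != shorter) return(NULL)  # complex indel
  list(bases = substr(longer, nchar(shorter) + 1, nchar(longer)),
       type = if (nchar(ref) > nchar(alt)) "del" else "ins",
       anchor_len = nchar(shorter))
}

#' Homopolymer run length at a variant
#'
#' Indel calls inside homopolymer runs are enriched for polymerase-slippage
#' artifacts, so the flag is restricted to indels whose inserted/deleted
#' bases match the run base; SNVs report the run length but are never
#' flagged.
#'
#' @param ref_context Reference sequence window (character, genome strand).
#' @param context_start Genomic position of the first base of `ref_context`.
#' @param variant A [variant_bundle()].
#' @param profile A [rule_profile()].
#' @return List with `run_length` (longest run of one base containing or
#'   adjacent to the variant's changed bases) and `flagged`.
#' @export
homopolymer_run <- function(ref_context, context_start, variant, profile) {
  pos <- variant$pos
  ind <- indel_bases(variant$ref, variant$alt)
  ## affected genomic range: deleted bases, insertion point, or the SNV base
  if (is.null(ind)) {
    a_first <- pos; a_last <- pos + nchar(variant$ref) - 1
  } else if (ind$type == "del") {
    a_first <- pos + ind$anchor_len; a_last <- pos + nchar(variant$ref) - 1
  } else {
    a_first <- pos + ind$anchor_len - 1; a_last <- a_first + 1  # flanks of insertion point
  }
  ctx_end <- context_start + nchar(ref_context) - 1
  need <- profile$homopolymer_min_run
  if (a_first - context_start < need || ctx_end - a_last < need)
    stop("reference window too small for homopolymer assessment")

  b <- strsplit(toupper(ref_context), "")[[1]]
  r <- rle(b)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  g_start <- context_start + run_start - 1
  g_end <- context_start + run_end - 1
  ## runs containing or immediately adjacent to the affected range
  touching <- which(g_start <= a_last + 1 & g_end >= a_first - 1)

  unit <- if (!is.null(ind)) unique(strsplit(toupper(ind$bases), "")[[1]]) else character()
  if (!is.null(ind) && length(unit) == 1) {
    cand <- touching[r$values[touching] == unit]
    run_length <- if (length(cand)) max(r$lengths[cand]) else nchar(ind$bases)
    flagged <- run_length >= profile$homopolymer_min_run
  } else {
    run_length <- if (length(touching)) max(r$lengths[touching]) else 1L
    flagged <- FALSE   # SNVs and complex indels: slippage mechanism absent
  }
  list(run_length = as.integer(run_length), flagged = flagged)
}

#' Joint consequence of phased SNVs sharing a codon
#'
#' When two or more phased SNVs fall in the same codon of the assessed
#' transcript, the codon is re-translated with all substitutions applied.
#' A nonsense annotation is rescinded iff the jointly mutated codon is no
#' longer a stop.
#'
#' @param group A [phase_group()] (only SNV members are considered).
#' @param map Coding map of the assessed transcript.
#' @param ref_seq DNAStringSet reference.
#' @return One of `"nonsense_retained"`, `"missense"`, `"synonymous"`,
#'   `"not_mnv"`.
#' @export
combine_mnv <- function(group, map, ref_seq) {
  snvs <- Filter(function(m) nchar(m$ref) == 1 && nchar(m$alt) == 1,
                 group$members)
  if (length(snvs) < 2) return("not_mnv")
  off <- vapply(snvs, function(m) {
    o <- coding_offset(map, m$pos); if (is.na(o)) -1L else as.integer(o)
  }, integer(1))
  keep <- off >= 0
  snvs <- snvs[keep]; off <- off[keep]
  if (length(snvs) < 2) return("not_mnv")
  codon_idx <- off %/% 3
  tab <- table(codon_idx)
  shared <- as.integer(names(tab)[tab >= 2])
  if (!length(shared)) return("not_mnv")
  ci <- min(shared)

  codon_pos <- vapply(0:2, function(k) genomic_position(map, ci * 3 + k), numeric(1))
  ref_codon <- paste(vapply(codon_pos, function(p)
    get_ref_window(ref_seq, map$chrom, p, p, map$strand), character(1)),
    collapse = "")
  mut <- strsplit(ref_codon, "")[[1]]
  for (m in snvs[codon_idx == ci]) {
    within <- (coding_offset(map, m$pos)) %% 3 + 1
    base <- toupper(m$alt)
    if (map$strand == "-") base <- complement_base(base)
    mut[within] <- base
  }
  mut_codon <- paste(mut, collapse = "")
  if (is_stop_codon(mut_codon)) return("nonsense_retained")
  if (translate_codon(mut_codon) == translate_codon(ref_codon)) "synonymous"
  else "missense"
}

#' Net reading-frame shift of phased indels
#'
#' A frameshift call can be rescued by one or several nearby indels on the
#' same haplotype whose aggregate length change is a multiple of 3.
#'
#' @param group A [phase_group()].
#' @param profile A [rule_profile()]; members must co-occur within
#'   `indel_pair_window` bases for the rescue to count.
#' @return List with `net_shift` (sum of length deltas, reduced mod 3 into
#'   `0:2`) and `frame_restoring` (TRUE iff the net shift is 0 with at least
#'   two contributing indels inside the window).
#' @export
net_indel_frame <- function(group, profile) {
  indels <- Filter(function(m) nchar(m$ref) != nchar(m$alt), group$members)
  if (!length(indels))
    return(list(net_shift = 0L, frame_restoring = FALSE))
  deltas <- vapply(indels, function(m) nchar(m$alt) - nchar(m$ref), numeric(1))
  pos <- vapply(indels, function(m) as.numeric(m$pos), numeric(1))
  net <- ((sum(deltas) %% 3) + 3) %% 3
  within <- (max(pos) - min(pos)) <= profile$indel_pair_window
  list(net_shift = as.integer(net),
       frame_restoring = net == 0 && length(indels) >= 2 && within)
}

#' Translational reinitiation potential after an early truncation
#'
#' Scans 3' of the lesion for the first in-frame ATG within the first coding
#' exon. The fraction of coding sequence removed by reinitiating there is
#' the ATG's coding offset over the CDS length.
#'
#' @param map Coding map.
#' @param ref_seq DNAStringSet reference.
#' @param transcript The assessed [transcript_model()].
#' @param lesion_pos Genomic position of the truncating lesion; must lie in
#'   the first coding exon.
#' @param profile A [rule_profile()].
#' @param conservation_mean Optional mean per-base conservation of the
#'   removed 5' region; when supplied and below 0.5 a `strong` call is
#'   demoted to `weak` (the reinitiating methionine should be fairly well
#'   conserved).
#' @return One of `"none"`, `"weak"`, `"strong"`, `"removes_gt_threshold"`.
#' @export
reinitiation_class <- function(map, ref_seq, transcript, lesion_pos, profile,
                               conservation_mean = NA_real_) {
  les_off <- coding_offset(map, lesion_pos)
  if (is.na(les_off)) stop("lesion outside CDS")
  first_coding_exon <- which(map$exon_cds_lengths > 0)[1]
  exon1_len <- map$exon_cds_lengths[first_coding_exon]
  if (coding_exon_of(map, lesion_pos) != first_coding_exon)
    stop("reinitiation assessed only for first-coding-exon lesions")
  cseq <- coding_sequence(map, ref_seq)
  starts <- seq.int(0, exon1_len - 3, by = 3)
  starts <- starts[starts > les_off]
  hit <- NA_integer_
  for (o in starts) {
    if (substr(cseq, o + 1, o + 3) == "ATG") { hit <- o; break }
  }
  if (is.na(hit)) return("none")
  fraction <- hit / map$cds_length
  cls <- if (fraction > profile$truncation_max_fraction) "removes_gt_threshold"
         else if (fraction <= profile$reinit_strong_max_fraction) "strong"
         else "weak"
  if (cls == "strong" && !is.na(conservation_mean) && conservation_mean < 0.5)
    cls <- "weak"
  cls
}

#' Technical (artifact-risk) context of a variant
#'
#' Evaluates genotype QC metrics, GC content around the call, repeat-track
#' overlap, and strand bias against one threshold profile. Absent metrics
#' yield no flag.
#'
#' @param variant A [variant_bundle()].
#' @param ref_context Reference window (genome strand) around the variant.
#' @param context_start Genomic position of the first base of `ref_context`.
#' @param repeat_overlap_count Number of repeat-annotation intervals
#'   overlapping the variant position.
#' @param profile A [rule_profile()].
#' @param low_complexity_overlap TRUE when a low-complexity track interval
#'   overlaps the variant (taken from an input track, not recomputed).
#' @return Character vector of triggered technical subflags (subset of
#'   `low_depth`, `low_gq`, `skewed_ab`, `strand_bias`, `gc_rich`,
#'   `low_complexity`, `minor_mapping`, `complex_mapping`).
#' @export
technical_context <- function(variant, ref_context, context_start,
                              repeat_overlap_count, profile,
                              low_complexity_overlap = FALSE) {
  out <- character()
  qc <- variant$qc
  if (!is.na(qc$depth) && qc$depth < profile$depth_min) out <- c(out, "low_depth")
  if (!is.na(qc$genotype_quality) && qc$genotype_quality < profile$gq_min)
    out <- c(out, "low_gq")
  if (!is.na(qc$allele_balance) && qc$allele_balance < profile$ab_min)
    out <- c(out, "skewed_ab")
  ## strand bias: essentially all ALT reads on one strand, with enough reads
  if (!is.na(qc$strand_bias) && !is.na(qc$depth) && !is.na(qc$allele_balance)) {
    alt_reads <- qc$depth * qc$allele_balance
    if (alt_reads >= 10 && (qc$strand_bias <= 0.05 || qc$strand_bias >= 0.95))
      out <- c(out, "strand_bias")
  }
  if (!is.null(ref_context) && nchar(ref_context) > 0) {
    half <- floor(profile$gc_window / 2)
    rel <- variant$pos - context_start + 1
    win <- substr(ref_context, max(1, rel - half),
                  min(nchar(ref_context), rel + half - 1))
    gcf <- gc_fraction(win)
    if (!is.na(gcf) && gcf >= profile$gc_rich_min) out <- c(out, "gc_rich")
  }
  if (low_complexity_overlap) out <- c(out, "low_complexity")
  if (repeat_overlap_count > profile$repeat_track_min) out <- c(out, "complex_mapping")
  else if (repeat_overlap_count > 0) out <- c(out, "minor_mapping")
  out
}
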