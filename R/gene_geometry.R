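## Transcript/CDS coordinate arithmetic. All "upstream"/"downstream" logic
## and exon indices are in transcript orientation; genomic intervals stay in
## genome orientation (1-based inclusive). Coding offsets are 0-based: the
## first base of the initiation codon has offset 0.

#' Build a coding map for a transcript
#'
#' Precomputes the mapping between genomic positions and 0-based coding
#' offsets. Segments are CDS intervals in transcript orientation; for a
#' minus-strand transcript offset 0 sits at the genomically rightmost CDS
#' base.
#'
#' @param transcript A [transcript_model()]; must be coding.
#' @return A `coding_map` with fields `transcript_id`, `strand`, `chrom`,
#'   `cds_length`, `segments` (data.frame `start`, `end`, `offset0`,
#'   `exon_index`) and `exon_cds_lengths` (per exon, transcript orientation).
#' @examples
#' tx <- transcript_model("t1", "g1", "chr1", "+",
#'                        exons = data.frame(start = 101, end = 400),
#'                        cds   = data.frame(start = 101, end = 400))
#' m <- build_coding_map(tx)
#' m$cds_length            # 300
#' coding_offset(m, 101)   # 0
#' @export
build_coding_map <- function(transcript) {
  if (!inherits(transcript, "transcript_model")) stop("need a transcript_model")
  if (!transcript$is_coding) stop("non-coding transcript: ", transcript$transcript_id)
  cds <- transcript$cds
  widths <- cds$end - cds$start + 1
  offset0 <- cumsum(c(0, widths[-length(widths)]))
  exon_index <- vapply(seq_len(nrow(cds)), function(i) {
    which(transcript$exons$start <= cds$start[i] &
          transcript$exons$end >= cds$end[i])[1]
  }, integer(1))
  exon_cds_lengths <- integer(nrow(transcript$exons))
  for (i in seq_len(nrow(cds)))
    exon_cds_lengths[exon_index[i]] <- exon_cds_lengths[exon_index[i]] + widths[i]
  structure(list(transcript_id = transcript$transcript_id,
                 chrom = transcript$chrom, strand = transcript$strand,
                 cds_length = sum(widths),
                 segments = data.frame(start = cds$start, end = cds$end,
                                       offset0 = offset0,
                                       exon_index = exon_index),
                 exon_cds_lengths = exon_cds_lengths),
            class = "coding_map")
}

#' Genomic position to 0-based coding offset
#'
#' @param map A [build_coding_map()] result.
#' @param pos Genomic position (1-based).
#' @return Integer offset, or `NA` when `pos` is not a coding base.
#' @export
coding_offset <- function(map, pos) {
  seg <- map$segments
  i <- which(seg$start <= pos & seg$end >= pos)
  if (!length(i)) return(NA_integer_)
  i <- i[1]
  if (map$strand == "+") seg$offset0[i] + (pos - seg$start[i])
  else seg$offset0[i] + (seg$end[i] - pos)
}

#' 0-based coding offset to genomic position (inverse of [coding_offset()])
#' @param map A coding map.
#' @param offset Integer offset in `[0, cds_length - 1]`.
#' @return Genomic position.
#' @export
genomic_position <- function(map, offset) {
  seg <- map$segments
  w <- seg$end - seg$start + 1
  i <- which(offset >= seg$offset0 & offset < seg$offset0 + w)
  if (!length(i)) stop("offset outside CDS: ", offset)
  i <- i[1]
  d <- offset - seg$offset0[i]
  if (map$strand == "+") seg$start[i] + d else seg$end[i] - d
}

#' Exon index (transcript orientation) containing a coding position
#' @noRd
coding_exon_of <- function(map, pos) {
  seg <- map$segments
  i <- which(seg$start <= pos & seg$end >= pos)
  if (!length(i)) NA_integer_ else seg$exon_index[i[1]]
}

#' Spliced coding sequence of a transcript
#' @param map Coding map.
#' @param ref_seq DNAStringSet reference.
#' @return Character string, transcript orientation (starts with the
#'   initiation codon).
#' @export
coding_sequence <- function(map, ref_seq) {
  seg <- map$segments
  pieces <- vapply(seq_len(nrow(seg)), function(i)
    get_ref_window(ref_seq, map$chrom, seg$start[i], seg$end[i], map$strand),
    character(1))
  paste(pieces, collapse = "")
}

#' Fraction of coding sequence removed by a termination event
#'
#' Counts the termination base and everything 3' of it, in the coding space
#' of the assessed transcript: `(cds_length - offset) / cds_length`.
#'
#' @param map Coding map.
#' @param termination_genomic_pos Genomic position of the termination event
#'   (for splice events, pass the first lost coding base).
#' @return Fraction in `[0, 1]`.
#' @export
cds_fraction_removed <- function(map, termination_genomic_pos) {
  off <- coding_offset(map, termination_genomic_pos)
  if (is.na(off)) stop("non-coding position: ", termination_genomic_pos)
  (map$cds_length - off) / map$cds_length
}

#' Does a termination event escape nonsense-mediated decay?
#'
#' TRUE when the position lies in the 3'-most coding exon, within the final
#' `nmd_penultimate_window` coding bases of the penultimate coding exon, or
#' when the transcript has a single coding exon (no downstream junction, so
#' no exon-junction complex to trigger NMD).
#'
#' @param map Coding map.
#' @param transcript The matching [transcript_model()].
#' @param pos Genomic position; must map into the CDS.
#' @param profile A [rule_profile()].
#' @return Logical.
#' @export
nmd_escape <- function(map, transcript, pos, profile) {
  off <- coding_offset(map, pos)
  if (is.na(off)) stop("non-coding position: ", pos)
  coding_exons <- which(map$exon_cds_lengths > 0)
  if (length(coding_exons) == 1) return(TRUE)
  idx <- coding_exon_of(map, pos)
  last_ex <- coding_exons[length(coding_exons)]
  penult <- coding_exons[length(coding_exons) - 1]
  if (idx == last_ex) return(TRUE)
  if (idx == penult) {
    ## coding offset of the 3'-most coding base of the penultimate exon
    end_off <- sum(map$exon_cds_lengths[seq_len(penult)]) - 1
    dist <- end_off - off + 1   # bases from pos through the exon end, inclusive
    return(dist <= profile$nmd_penultimate_window)
  }
  FALSE
}

#' Is an internal coding exon in-frame?
#'
#' @param map Coding map.
#' @param exon_index Exon index (transcript orientation); must be an internal
#'   coding exon.
#' @return TRUE iff the exon's CDS length is a multiple of 3 (skipping it
#'   preserves the reading frame).
#' @export
in_frame_exon <- function(map, exon_index) {
  coding_exons <- which(map$exon_cds_lengths > 0)
  if (exon_index %in% range(coding_exons))
    stop("skipping not a rescue at terminal exons (exon ", exon_index, ")")
  if (!exon_index %in% coding_exons) stop("exon ", exon_index, " is non-coding")
  map$exon_cds_lengths[exon_index] %% 3 == 0
}

#' Pext ratio category of an exon
#'
#' The exon's mean pext is compared with the gene maximum:
#' `low` when ratio <= `low_pext_max_ratio`, `mid` when below
#' `mid_pext_max_ratio`, `close_to_max` when below 0.9, else `at_max`.
#'
#' @param track [pext_track()].
#' @param gene_id,transcript_id,exon_index Exon key.
#' @param profile [rule_profile()].
#' @return One of `"at_max"`, `"close_to_max"`, `"mid"`, `"low"`; `NA` when
#'   the exon has no pext value (absence of a score is never evidence).
#' @export
pext_category <- function(track, gene_id, transcript_id, exon_index, profile) {
  val <- pext_exon_value(track, transcript_id, exon_index)
  if (is.na(val)) return(NA_character_)
  gmax <- track$gene_max[gene_id]
  if (is.na(gmax)) return(NA_character_)
  if (gmax == 0) stop("pext uninformative: gene maximum is 0 for ", gene_id)
  ratio <- val / gmax
  if (ratio <= profile$low_pext_max_ratio) "low"
  else if (ratio < profile$mid_pext_max_ratio) "mid"
  else if (ratio < 0.9) "close_to_max"
  else "at_max"
}

#' Is the variant pLoF in a minority of coding transcripts?
#'
#' @param bundle [variant_bundle()]; its `transcripts_hit` is intersected
#'   with the supplied coding transcript universe.
#' @param coding_transcript_count Number of coding transcripts of the gene.
#' @return TRUE iff the pLoF transcript fraction is strictly below the
#'   profile's `minority_fraction`.
#' @param profile [rule_profile()].
#' @export
minority_of_transcripts <- function(bundle, coding_transcript_count, profile) {
  if (coding_transcript_count < 1) stop("zero coding transcripts")
  n_plof <- sum(bundle$transcripts_hit$is_pLoF)
  (n_plof / coding_transcript_count) < profile$minority_fraction
}

#' Does the variant sit in an overhang (exon-extension) region?
#'
#' An overhang exon is an exon extension present in a minority of
#' transcripts: in other transcripts the same exon is shorter and the
#' extended sequence is spliced out. Detected here as: the containing exon
#' of the assessed transcript overlaps an exon of another coding transcript
#' of the gene, but no exon of that transcript covers the variant position.
#'
#' @param transcript Assessed [transcript_model()].
#' @param other_transcripts List of other transcript models of the gene.
#' @param pos Genomic variant position.
#' @return Logical.
#' @export
detect_overhang <- function(transcript, other_transcripts, pos) {
  ex <- transcript$exons
  i <- which(ex$start <= pos & ex$end >= pos)
  if (!length(i)) return(FALSE)
  e <- ex[i[1], ]
  for (other in other_transcripts) {
    if (!other$is_coding || other$chrom != transcript$chrom) next
    oe <- other$exons
    overlapping <- any(oe$start <= e$end & oe$end >= e$start)
    covers_pos <- any(oe$start <= pos & oe$end >= pos)
    if (overlapping && !covers_pos) return(TRUE)
  }
  FALSE
}
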