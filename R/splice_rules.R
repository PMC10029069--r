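## Interpretation of SpliceAI delta scores for essential (+/-1-2) splice-site
## variants: cryptic-site rescue with frame arithmetic, exon skipping vs
## intron retention, stop scanning of retained sequence, and pext support of
## the annotated junction.

#' Parse a SpliceAI INFO annotation
#'
#' Standard 10-field format
#' `ALLELE|SYMBOL|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL`,
#' comma-separated per gene.
#'
#' @param info_value Raw annotation string (may be `NA`/empty).
#' @param gene_id Gene symbol to select among per-gene entries.
#' @return A [spliceai_scores()] object, or `NULL` when no entry matches.
#' @export
parse_spliceai_info <- function(info_value, gene_id) {
  if (is.null(info_value) || length(info_value) == 0) return(NULL)
  info_value <- info_value[1]
  if (is.na(info_value) || !nzchar(info_value) || info_value == ".") return(NULL)
  entries <- strsplit(info_value, ",", fixed = TRUE)[[1]]
  for (e in entries) {
    f <- strsplit(e, "|", fixed = TRUE)[[1]]
    if (length(f) != 10)
      stop("malformed SpliceAI record (", length(f), " fields): ", e)
    if (f[2] == gene_id) {
      v <- suppressWarnings(as.numeric(f[3:10]))
      if (anyNA(v)) stop("non-numeric SpliceAI fields in: ", e)
      return(spliceai_scores(ds_ag = v[1], ds_al = v[2], ds_dg = v[3],
                             ds_dl = v[4], dp_ag = v[5], dp_al = v[6],
                             dp_dg = v[7], dp_dl = v[8]))
    }
  }
  NULL
}

## Donor boundary of exon i = its 3'-most base in transcript orientation;
## acceptor boundary = its 5'-most base.
exon_donor_pos <- function(transcript, i) {
  if (transcript$strand == "+") transcript$exons$end[i] else transcript$exons$start[i]
}
exon_acceptor_pos <- function(transcript, i) {
  if (transcript$strand == "+") transcript$exons$start[i] else transcript$exons$end[i]
}

## exon (transcript orientation index) whose donor/acceptor the essential
## site variant belongs to
affected_exon_index <- function(variant, transcript) {
  n <- nrow(transcript$exons)
  if (variant$variant_class == "splice_donor") {
    d <- vapply(seq_len(n), function(i)
      abs(variant$pos - exon_donor_pos(transcript, i)), numeric(1))
  } else {
    d <- vapply(seq_len(n), function(i)
      abs(variant$pos - exon_acceptor_pos(transcript, i)), numeric(1))
  }
  which.min(d)
}

#' Coding-space anchor position of an essential splice variant
#'
#' For truncation-fraction and NMD arithmetic a splice variant is anchored
#' at the first coding base its disruption removes: the first coding base of
#' the downstream exon for a donor, the first coding base of the affected
#' exon for an acceptor.
#'
#' @param variant,map,transcript Variant, coding map, transcript model.
#' @return Genomic position, or `NA` when no coding base lies downstream.
#' @export
splice_coding_anchor <- function(variant, map, transcript) {
  i <- affected_exon_index(variant, transcript)
  if (variant$variant_class == "splice_donor") {
    off <- sum(map$exon_cds_lengths[seq_len(i)])   # offset of next exon's first coding base
  } else {
    off <- sum(map$exon_cds_lengths[seq_len(i - 1)])
  }
  if (off >= map$cds_length) return(NA_integer_)
  genomic_position(map, off)
}

#' Scan retained sequence for an in-frame termination codon
#'
#' Translates a retained genomic interval in the inherited reading frame,
#' including the junction codon split across the exon boundary.
#'
#' @param ref_seq DNAStringSet reference.
#' @param chrom Contig.
#' @param start,end Genomic interval (1-based inclusive) of the retained
#'   sequence; `start > end` means an empty interval.
#' @param strand Transcript strand.
#' @param frame_offset Bases of the current codon already consumed upstream
#'   of the retained segment (0, 1 or 2); the scan prepends that many
#'   junction bases.
#' @return TRUE iff a stop codon occurs in any complete codon.
#' @export
retained_stop_scan <- function(ref_seq, chrom, start, end, strand = "+",
                               frame_offset = 0) {
  if (is.null(start) || is.null(end) || start > end) return(FALSE)
  stopifnot(frame_offset %in% 0:2)
  if (strand == "+") {
    s <- get_ref_window(ref_seq, chrom, start - frame_offset, end, "+")
  } else {
    s <- get_ref_window(ref_seq, chrom, start, end + frame_offset, "-")
  }
  n <- nchar(s)
  if (n < 3) return(FALSE)
  starts <- seq.int(1, n - 2, by = 3)
  any(vapply(starts, function(i) is_stop_codon(substr(s, i, i + 2)), logical(1)))
}

#' Classify the predicted splicing outcome of an essential splice variant
#'
#' Applies the SpliceAI rescue threshold (0.2) and the strong-rescue margin
#' (gain within 0.2 of the site's loss score). Cryptic gains are located via
#' their delta positions and classified by frame parity of their distance
#' from the annotated site; an opposite-site loss without a qualifying gain
#' is read as exon skipping (when positioned at the exon's other boundary)
#' or intron retention (when positioned at the far end of the variant's
#' intron).
#'
#' @param variant A splice_donor/splice_acceptor [variant_bundle()].
#' @param map Coding map of the assessed transcript.
#' @param transcript The [transcript_model()].
#' @param scores A [spliceai_scores()] object or `NULL`.
#' @param profile A [rule_profile()].
#' @param ref_seq Optional DNAStringSet; enables stop-scanning of retained
#'   intervals.
#' @param adjacent_pext_category Optional pext category of the adjacent
#'   exon, used for the non-essential-site call when the site shows no
#'   predicted loss.
#' @return A `splice_event` list: `kind`, `strength`, `retained_interval`,
#'   `stop_in_retained`, `fraction_removed`, `affected_exon_index`, `detail`.
#' @export
classify_splice_event <- function(variant, map, transcript, scores, profile,
                                  ref_seq = NULL,
                                  adjacent_pext_category = NA_character_) {
  if (!variant$variant_class %in% c("splice_donor", "splice_acceptor"))
    stop("classify_splice_event requires an essential splice variant")
  donor <- variant$variant_class == "splice_donor"
  i <- affected_exon_index(variant, transcript)
  ann <- if (donor) exon_donor_pos(transcript, i) else exon_acceptor_pos(transcript, i)

  ev <- function(kind, strength = "n/a", retained = NULL, stop_ret = NA,
                 fraction = NA_real_, detail = "") {
    structure(list(kind = kind, strength = strength,
                   retained_interval = retained, stop_in_retained = stop_ret,
                   fraction_removed = fraction, affected_exon_index = i,
                   detail = detail), class = "splice_event")
  }
  if (is.null(scores)) return(ev("uncertain", detail = "no SpliceAI annotation"))

  loss <- if (donor) scores$ds_dl else scores$ds_al
  gain <- if (donor) scores$ds_dg else scores$ds_ag
  gain_site <- variant$pos + (if (donor) scores$dp_dg else scores$dp_ag)
  opp_loss <- if (donor) scores$ds_al else scores$ds_dl
  opp_site <- variant$pos + (if (donor) scores$dp_al else scores$dp_dl)

  if (loss < profile$spliceai_rescue_min) {
    if (!is.na(adjacent_pext_category) && adjacent_pext_category == "low")
      return(ev("non_essential_site",
                detail = "no predicted site loss; adjacent exon pext low"))
    return(ev("uncertain", detail = "no predicted site loss"))
  }

  ## which genomic direction is "into the intron" from the annotated site
  intron_dir <- if (donor) {
    if (transcript$strand == "+") +1 else -1
  } else {
    if (transcript$strand == "+") -1 else +1
  }

  cryptic <- NULL
  if (gain >= profile$spliceai_rescue_min) {
    d <- abs(gain_site - ann)
    inframe <- d %% 3 == 0
    intronic <- sign(gain_site - ann) == intron_dir && gain_site != ann
    if (inframe) {
      strength <- if (loss - gain <= profile$spliceai_strong_margin) "strong" else "weak"
      retained <- NULL; stop_ret <- NA; fraction <- d / map$cds_length
      if (intronic) {
        retained <- sort(c(ann + intron_dir, gain_site))
        fraction <- 0
        if (!is.null(ref_seq)) {
          phase <- if (donor) sum(map$exon_cds_lengths[seq_len(i)]) %% 3
                   else sum(map$exon_cds_lengths[seq_len(i - 1)]) %% 3
          stop_ret <- retained_stop_scan(ref_seq, map$chrom,
                                         retained[1], retained[2],
                                         transcript$strand, phase)
        }
      }
      cryptic <- ev("in_frame_cryptic_rescue", strength,
                    retained = retained, stop_ret = stop_ret,
                    fraction = fraction,
                    detail = sprintf("cryptic %s at %+d from annotated site (loss %.2f, gain %.2f)",
                                     if (donor) "donor" else "acceptor",
                                     gain_site - ann, loss, gain))
    } else {
      cryptic <- ev("out_of_frame_cryptic",
                    detail = sprintf("cryptic site %+d from annotated site (frame %d)",
                                     gain_site - ann, d %% 3))
    }
  }

  skipret <- NULL
  if (opp_loss >= profile$spliceai_rescue_min) {
    opp_exon_boundary <- if (donor) exon_acceptor_pos(transcript, i)
                         else exon_donor_pos(transcript, i)
    far_boundary <- if (donor) {
      if (i < nrow(transcript$exons)) exon_acceptor_pos(transcript, i + 1) else NA
    } else {
      if (i > 1) exon_donor_pos(transcript, i - 1) else NA
    }
    near_exon <- is.na(far_boundary) ||
      abs(opp_site - opp_exon_boundary) <= abs(opp_site - far_boundary)
    if (near_exon) {
      coding_exons <- which(map$exon_cds_lengths > 0)
      if (i %in% range(coding_exons)) {
        skipret <- ev("uncertain", detail = "skip predicted at terminal coding exon")
      } else {
        inframe <- map$exon_cds_lengths[i] %% 3 == 0
        fraction <- map$exon_cds_lengths[i] / map$cds_length
        skipret <- ev(if (inframe) "in_frame_exon_skip" else "out_of_frame_exon_skip",
                      fraction = fraction,
                      detail = sprintf("skip of exon %d (%d coding bp)",
                                       i, map$exon_cds_lengths[i]))
      }
    } else {
      intron <- if (donor) sort(c(ann + intron_dir, far_boundary - intron_dir))
                else sort(c(far_boundary - intron_dir, ann + intron_dir))
      stop_ret <- if (!is.null(ref_seq)) {
        phase <- if (donor) sum(map$exon_cds_lengths[seq_len(i)]) %% 3
                 else sum(map$exon_cds_lengths[seq_len(i - 1)]) %% 3
        retained_stop_scan(ref_seq, map$chrom, intron[1], intron[2],
                           transcript$strand, phase)
      } else NA
      skipret <- ev("intron_retention", retained = intron, stop_ret = stop_ret,
                    detail = sprintf("retention of intron %d-%d", intron[1], intron[2]))
    }
  }

  frame_of <- function(e) switch(e$kind,
    in_frame_cryptic_rescue = , in_frame_exon_skip = "in",
    out_of_frame_cryptic = , out_of_frame_exon_skip = , intron_retention = "out",
    NA_character_)
  if (!is.null(cryptic) && !is.null(skipret)) {
    f1 <- frame_of(cryptic); f2 <- frame_of(skipret)
    if (!is.na(f1) && !is.na(f2) && f1 != f2)
      return(ev("multiple_events",
                detail = paste("competing in-frame and out-of-frame events:",
                               cryptic$detail, "/", skipret$detail)))
    return(cryptic)
  }
  if (!is.null(cryptic)) return(cryptic)
  if (!is.null(skipret)) return(skipret)
  ev("uncertain", detail = sprintf("site loss %.2f without qualifying rescue", loss))
}

#' Is an annotated splice site supported by pext?
#'
#' A splice site in a transcript of low biological relevance shows either a
#' low adjacent-exon pext ratio or no drop of per-base pext across the
#' annotated junction.
#'
#' @param track A [pext_track()].
#' @param transcript,gene_id Transcript model and gene.
#' @param exon_index Adjacent (affected) exon, transcript orientation.
#' @param profile A [rule_profile()].
#' @param junction_pos Optional genomic position of the annotated junction
#'   boundary (exon-side base) for the per-base drop assessment.
#' @param window Bases averaged on each side of the junction (default 10).
#' @return TRUE (supported), FALSE (not supported), or `NA` when no pext
#'   information is available.
#' @export
splice_pext_support <- function(track, transcript, gene_id, exon_index,
                                profile, junction_pos = NULL, window = 10) {
  categ <- pext_category(track, gene_id, transcript$transcript_id,
                         exon_index, profile)
  if (!is.na(categ) && categ == "low") return(FALSE)
  if (!is.null(track$per_base) && !is.null(junction_pos)) {
    pb <- track$per_base[track$per_base$chrom == transcript$chrom, , drop = FALSE]
    mean_over <- function(a, b) {
      sel <- pb$end >= a & pb$start <= b
      if (!any(sel)) return(NA_real_)
      mean(pb$value[sel])
    }
    ex <- transcript$exons[exon_index, ]
    into_exon <- junction_pos == ex$start   # junction at genomic-left edge?
    if (into_exon) {
      exon_mean <- mean_over(junction_pos, junction_pos + window - 1)
      intron_mean <- mean_over(junction_pos - window, junction_pos - 1)
    } else {
      exon_mean <- mean_over(junction_pos - window + 1, junction_pos)
      intron_mean <- mean_over(junction_pos + 1, junction_pos + window)
    }
    if (!is.na(exon_mean) && !is.na(intron_mean) && exon_mean > 0) {
      ## no drop across the junction: intron side within 5% of the exon side
      if (abs(exon_mean - intron_mean) <= 0.05 * exon_mean) return(FALSE)
    }
  }
  if (is.na(categ)) return(NA)
  TRUE
}
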