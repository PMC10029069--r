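## Flag assembly per variant, five-level verdict resolution by
## worst-consequence precedence, and PVS1 strength adjustment.

#' Assemble the curation context shared by all variants
#'
#' @param transcripts List of [transcript_model()]s.
#' @param ref_seq DNAStringSet reference genome.
#' @param pext Optional [pext_track()].
#' @param repeats Optional data.frame of repeat/low-complexity intervals
#'   (`chrom`, `start`, `end`, `name`, 1-based inclusive); intervals whose
#'   name contains `"low_complexity"` feed the low-complexity flag, all
#'   others count toward the repeat-track overlap.
#' @param conservation Optional data.frame of per-exon conservation
#'   (`gene_id`, `transcript_id`, `exon_index`, `mean_cons`).
#' @param phase_partners Optional data.frame of phased non-pLoF companion
#'   records (`chrom`, `pos`, `ref`, `alt`, `phase_group_id`).
#' @return A `curation_context` list with precomputed coding maps.
#' @export
curation_context <- function(transcripts, ref_seq, pext = NULL, repeats = NULL,
                             conservation = NULL, phase_partners = NULL) {
  names(transcripts) <- vapply(transcripts, function(t) t$transcript_id, character(1))
  maps <- lapply(transcripts, function(t)
    if (t$is_coding) build_coding_map(t) else NULL)
  structure(list(transcripts = transcripts, maps = maps, ref_seq = ref_seq,
                 pext = pext, repeats = repeats, conservation = conservation,
                 phase_partners = phase_partners),
            class = "curation_context")
}

## phase group for a bundle: pLoF co-members plus non-pLoF partners
build_phase_group <- function(bundle, all_bundles, ctx) {
  pid <- bundle$phase_group_id
  if (is.na(pid)) return(NULL)
  members <- Filter(function(b) identical(b$phase_group_id, pid), all_bundles)
  pp <- ctx$phase_partners
  if (!is.null(pp) && nrow(pp)) {
    extra <- pp[pp$phase_group_id == pid, , drop = FALSE]
    for (k in seq_len(nrow(extra)))
      members <- c(members, list(list(chrom = extra$chrom[k], pos = extra$pos[k],
                                      ref = extra$ref[k], alt = extra$alt[k])))
  }
  if (length(members) < 2) return(NULL)
  phase_group(pid, members)
}

conservation_percentile_low <- function(conservation, gene_id, transcript_id,
                                        exon_index) {
  cs <- conservation[conservation$gene_id == gene_id, , drop = FALSE]
  if (!nrow(cs)) return(NA)
  i <- which(cs$transcript_id == transcript_id & cs$exon_index == exon_index)
  if (!length(i)) return(NA)
  cs$mean_cons[i[1]] < stats::quantile(cs$mean_cons, 0.25, names = FALSE)
}

## evaluate every rule for one (variant, transcript) pair
evaluate_transcript <- function(bundle, tx, ctx, profile,
                                all_bundles = list(bundle)) {
  flags <- no_flags(); notes <- character()
  map <- ctx$maps[[tx$transcript_id]]
  is_splice <- bundle$variant_class %in% c("splice_donor", "splice_acceptor")
  gene <- if (!is.na(bundle$gene_id)) bundle$gene_id else tx$gene_id

  add <- function(name, detail = "", fraction = NA_real_)
    flags <<- rbind(flags, make_flag(name, detail, fraction))
  note <- function(msg) notes <<- c(notes, msg)

  ctx_half <- 150L
  ctx_start <- max(1L, bundle$pos - ctx_half)
  ref_ctx <- get_ref_window(ctx$ref_seq, bundle$chrom, ctx_start,
                            bundle$pos + ctx_half, "+")

  pg <- build_phase_group(bundle, all_bundles, ctx)

  ## -- rescue by secondary sequence properties ------------------------------
  if (bundle$variant_class == "nonsense") {
    if (!is.null(pg)) {
      mnv <- combine_mnv(pg, map, ctx$ref_seq)
      if (mnv %in% c("missense", "synonymous"))
        add("mnv_rescue", sprintf("phased SNVs combine to %s", mnv))
      else if (mnv == "nonsense_retained")
        note("phased SNVs share the codon but the joint codon is still a stop")
    } else if (!is.na(bundle$phase_group_id)) {
      note("phase group named but no co-phased records available; MNV rule skipped")
    }
  }
  if (bundle$variant_class == "frameshift") {
    if (!is.null(pg)) {
      nif <- net_indel_frame(pg, profile)
      if (nif$frame_restoring)
        add("frame_restoring_indel",
            sprintf("net frame shift 0 across %s", pg$group_id))
    } else if (!is.na(bundle$phase_group_id)) {
      note("phase group named but no co-phased records available; indel rule skipped")
    } else if (!bundle$has_read_data) {
      note("no read data: frame-restoring indels cannot be excluded")
    }
  }
  if (!is_splice) {
    off <- coding_offset(map, bundle$pos)
    first_ce <- which(map$exon_cds_lengths > 0)[1]
    if (!is.na(off) && identical(coding_exon_of(map, bundle$pos), first_ce)) {
      cons_mean <- NA_real_
      if (!is.null(ctx$conservation)) {
        cs <- ctx$conservation
        k <- which(cs$transcript_id == tx$transcript_id & cs$exon_index == first_ce)
        if (length(k)) cons_mean <- cs$mean_cons[k[1]]
      }
      ri <- reinitiation_class(map, ctx$ref_seq, tx, bundle$pos, profile,
                               conservation_mean = cons_mean)
      if (ri == "strong") add("reinitiation_strong", "in-frame ATG soon after lesion")
      else if (ri == "weak") add("reinitiation_weak", "downstream in-frame ATG, weak support")
      else if (ri == "removes_gt_threshold")
        add("reinitiation_over_limit", "reinitiating ATG removes more than the truncation limit")
    }
  }

  splice_event <- NULL
  if (is_splice) {
    scores <- bundle$spliceai
    if (is.character(scores)) scores <- parse_spliceai_info(scores, gene)
    exon_idx <- affected_exon_index(bundle, tx)
    adj_cat <- if (!is.null(ctx$pext))
      pext_category(ctx$pext, gene, tx$transcript_id, exon_idx, profile)
    else NA_character_
    splice_event <- classify_splice_event(bundle, map, tx, scores, profile,
                                          ref_seq = ctx$ref_seq,
                                          adjacent_pext_category = adj_cat)
    k <- splice_event$kind
    if (k == "in_frame_cryptic_rescue") {
      if (isTRUE(splice_event$stop_in_retained))
        add("splice_rescue_stop", splice_event$detail)
      else if (splice_event$strength == "strong")
        add("splice_rescue_strong", splice_event$detail, splice_event$fraction_removed)
      else
        add("splice_rescue_weak", splice_event$detail, splice_event$fraction_removed)
    } else if (k == "out_of_frame_cryptic") {
      add("out_of_frame_cryptic", splice_event$detail)
    } else if (k == "in_frame_exon_skip") {
      if (splice_event$fraction_removed < profile$truncation_max_fraction)
        add("in_frame_exon_skip", splice_event$detail, splice_event$fraction_removed)
      else
        note(sprintf("in-frame skip removes %.0f%% of CDS (>= limit); no rescue flag",
                     100 * splice_event$fraction_removed))
    } else if (k == "out_of_frame_exon_skip") {
      add("out_of_frame_exon_skip", splice_event$detail)
    } else if (k == "intron_retention") {
      add("intron_retention", splice_event$detail)
    } else if (k == "multiple_events") {
      add("mixed_splice_events", splice_event$detail)
    } else if (k == "uncertain" && is.null(scores)) {
      note("SpliceAI annotation absent; splice rules skipped")
    }
    if (!is.null(ctx$pext)) {
      jpos <- if (bundle$variant_class == "splice_donor")
        exon_donor_pos(tx, exon_idx) else exon_acceptor_pos(tx, exon_idx)
      supported <- splice_pext_support(ctx$pext, tx, gene, exon_idx, profile,
                                       junction_pos = jpos)
      if (isFALSE(supported)) add("splice_not_supported_by_pext",
                                  "adjacent exon pext low or no drop at junction")
    } else note("pext track absent; splice support rule skipped")
  }

  ## -- NMD escape / last exon ----------------------------------------------
  anchor <- if (is_splice) splice_coding_anchor(bundle, map, tx) else bundle$pos
  anchor_off <- if (is.na(anchor)) NA_integer_ else coding_offset(map, anchor)
  if (!is.na(anchor_off)) {
    if (nmd_escape(map, tx, anchor, profile)) {
      frac <- cds_fraction_removed(map, anchor)
      if (frac < profile$truncation_max_fraction)
        add("last_exon",
            sprintf("termination escapes NMD, removes %.1f%% of CDS", 100 * frac),
            frac)
      else
        note(sprintf("NMD escape but truncation removes %.0f%% of CDS (>= limit); no flag",
                     100 * frac))
    }
  } else if (is_splice) {
    note("no coding sequence downstream of splice site; NMD rule skipped")
  }

  ## -- uncertain biological relevance --------------------------------------
  exon_idx <- if (is_splice) affected_exon_index(bundle, tx)
              else coding_exon_of(map, bundle$pos)
  categ <- NA_character_
  if (!is.null(ctx$pext) && !is.na(exon_idx)) {
    categ <- tryCatch(
      pext_category(ctx$pext, gene, tx$transcript_id, exon_idx, profile),
      error = function(e) { note(conditionMessage(e)); NA_character_ })
    if (!is.na(categ) && categ == "low" && !is_splice)
      add("low_pext", sprintf("exon %d pext ratio at or below the low threshold", exon_idx))
  } else if (is.null(ctx$pext)) {
    note("pext track absent; pext rules skipped")
  }

  gene_tx <- Filter(function(t) t$gene_id == gene && t$is_coding, ctx$transcripts)
  if (length(gene_tx) >= 1) {
    minority <- minority_of_transcripts(bundle, length(gene_tx), profile)
    if (minority) {
      if (is.na(categ)) {
        note("minority of transcripts but no pext value; combined rule skipped")
      } else if (categ == "at_max") add("minority_at_max",
        "pLoF in a minority of coding transcripts; exon pext at gene maximum")
      else if (categ == "close_to_max") add("minority_close_to_max",
        "pLoF in a minority of coding transcripts; exon pext close to gene maximum")
      else if (categ == "mid") add("minority_mid",
        "pLoF in a minority of coding transcripts; exon pext 20-50% of gene maximum")
      ## categ "low": the low_pext flag already carries the evidence
    }
  }

  if (!is.null(ctx$conservation) && !is.na(exon_idx)) {
    weak <- conservation_percentile_low(ctx$conservation, gene,
                                        tx$transcript_id, exon_idx)
    if (isTRUE(weak) && !is.na(categ)) {
      if (categ == "at_max") add("weak_conservation_at_max",
        "weakly conserved exon; pext at gene maximum")
      else if (categ == "close_to_max") add("weak_conservation_close_to_max",
        "weakly conserved exon; pext close to gene maximum")
      else if (categ == "mid") add("weak_conservation_mid",
        "weakly conserved exon; pext 20-50% of gene maximum")
    }
  }

  others <- Filter(function(t) t$gene_id == gene &&
                     t$transcript_id != tx$transcript_id, ctx$transcripts)
  if (detect_overhang(tx, others, bundle$pos))
    add("overhang_exon", "variant in an exon extension spliced out in other transcripts")
  if ("overprinted" %in% tx$tags)
    add("overprinting", "pLoF only in the overprinted (alternate-ORF) transcript")

  ## -- potential technical artifacts ---------------------------------------
  rep_count <- 0L; lc_overlap <- FALSE
  if (!is.null(ctx$repeats) && nrow(ctx$repeats)) {
    rp <- ctx$repeats
    hit <- rp$chrom == bundle$chrom & rp$start <= bundle$pos & rp$end >= bundle$pos
    lc <- grepl("low_complexity", rp$name)
    rep_count <- sum(hit & !lc)
    lc_overlap <- any(hit & lc)
  }
  tech <- technical_context(bundle, ref_ctx, ctx_start, rep_count, profile,
                            low_complexity_overlap = lc_overlap)
  for (tf in tech) add(tf, "technical context")
  if (!any(c("low_depth", "low_gq", "skewed_ab") %in% tech)) {
    cons_p <- rule_profile("conservative")
    qc <- bundle$qc
    marginal <- (!is.na(qc$depth) && qc$depth < cons_p$depth_min) ||
      (!is.na(qc$genotype_quality) && qc$genotype_quality < cons_p$gq_min) ||
      (!is.na(qc$allele_balance) && qc$allele_balance < cons_p$ab_min)
    if (marginal)
      add("genotyping_marginal",
          "QC metrics pass the active profile but fail the conservative preset")
  }
  if (nchar(bundle$ref) != nchar(bundle$alt)) {
    hp <- tryCatch(homopolymer_run(ref_ctx, ctx_start, bundle, profile),
                   error = function(e) { note(conditionMessage(e)); NULL })
    if (!is.null(hp) && hp$flagged)
      add("homopolymer",
          sprintf("indel in a %d-base homopolymer run", hp$run_length))
  }

  list(flags = flags, notes = notes, splice_event = splice_event)
}

#' Assign curation flags to a variant
#'
#' Evaluates every applicable rule against each transcript in which the
#' variant is annotated pLoF and keeps the flag set of the worst (most
#' LoF-proximal, i.e. most biologically relevant) transcript. Rules whose
#' required context is missing are skipped and recorded in the audit notes,
#' never silently.
#'
#' @param bundle A [variant_bundle()].
#' @param ctx A [curation_context()].
#' @param profile A [rule_profile()].
#' @param all_bundles All bundles of the cohort (for phase-group assembly).
#' @return List with `flags` (data.frame), `notes`, `transcript_id`.
#' @export
assign_flags <- function(bundle, ctx, profile, all_bundles = list(bundle)) {
  hits <- bundle$transcripts_hit
  tx_ids <- hits$transcript_id[hits$is_pLoF]
  tx_ids <- tx_ids[tx_ids %in% names(ctx$transcripts)]
  tx_ids <- tx_ids[vapply(tx_ids, function(id) ctx$transcripts[[id]]$is_coding,
                          logical(1))]
  if (!length(tx_ids))
    stop("variant ", variant_key(bundle),
         " is not annotated pLoF in any known coding transcript")
  evals <- lapply(tx_ids, function(id)
    evaluate_transcript(bundle, ctx$transcripts[[id]], ctx, profile, all_bundles))
  ranks <- vapply(evals, function(e)
    verdict_rank(resolve_verdict(e$flags, bundle$variant_class,
                                 bundle$has_read_data)), integer(1))
  mane <- vapply(tx_ids, function(id)
    "MANE_Select" %in% ctx$transcripts[[id]]$tags, logical(1))
  ord <- order(ranks, !mane, tx_ids)
  best <- ord[1]
  out <- evals[[best]]
  out$transcript_id <- tx_ids[best]
  out
}

#' Resolve the five-level verdict from a flag set
#'
#' The most impactful (furthest from LoF) tier among the triggered flags
#' wins. A frameshift variant without read data contributes an implicit
#' `uncertain_LoF` tier: frame-restoring indels in the surrounding sequence
#' cannot be excluded without read visualization, so such variants are
#' uncertain unless a higher-tier flag fires. No flags otherwise means the
#' variant stands as LoF.
#'
#' @param flags Flag data.frame from [assign_flags()].
#' @param variant_class Variant class string.
#' @param has_read_data Whether read data was available.
#' @return Verdict string.
#' @export
resolve_verdict <- function(flags, variant_class, has_read_data = TRUE) {
  ranks <- 1L
  if (nrow(flags)) ranks <- c(ranks, verdict_rank(flags$tier))
  if (variant_class == "frameshift" && !has_read_data)
    ranks <- c(ranks, verdict_rank("uncertain_LoF"))
  VERDICT_LEVELS[max(ranks)]
}

#' Primary reason among triggered flags
#'
#' The flag with the highest verdict tier; ties broken by category order
#' (rescue, then biological relevance, then technical), then lexicographic.
#'
#' @param flags Flag data.frame.
#' @return Flag name or `"none"`.
#' @export
primary_reason <- function(flags) {
  if (!nrow(flags)) return("none")
  ord <- order(-verdict_rank(flags$tier),
               match(flags$category, FLAG_CATEGORIES), flags$name)
  flags$name[ord[1]]
}

PVS1_CONSEQUENCES <- c("no_change", "cap_strong", "cap_moderate", "do_not_use")

#' Default PVS1 consequence map
#'
#' Maps each non-technical flag to its PVS1 consequence. Truncation-type
#' rescues (weak splice rescue, strong reinitiation, last-exon NMD escape,
#' in-frame exon skip) cap PVS1 at Strong when the event removes less than
#' 10% of the coding sequence and at Moderate otherwise, mirroring the
#' ClinGen SVI decision tree; flags that remove the biological basis for
#' PVS1 altogether (low pext, pext-unsupported splice site, overhang exon,
#' overprinting, MNV rescue, frame-restoring indel, strong splice rescue)
#' mean PVS1 should not be applied at any level.
#'
#' @param flag One-row flag data.frame.
#' @param moderate_fraction Coding-sequence fraction at or above which the
#'   truncation-type cap drops from Strong to Moderate (default 0.10).
#' @return One of `"no_change"`, `"cap_strong"`, `"cap_moderate"`,
#'   `"do_not_use"`.
#' @export
pvs1_consequence <- function(flag, moderate_fraction = 0.10) {
  do_not_use <- c("low_pext", "splice_not_supported_by_pext", "overhang_exon",
                  "overprinting", "mnv_rescue", "frame_restoring_indel",
                  "splice_rescue_strong")
  by_fraction <- c("splice_rescue_weak", "reinitiation_strong", "last_exon",
                   "in_frame_exon_skip")
  cap_strong <- c("reinitiation_weak", "mixed_splice_events", "minority_mid",
                  "weak_conservation_mid")
  if (flag$name %in% do_not_use) return("do_not_use")
  if (flag$name %in% by_fraction) {
    fr <- flag$fraction_removed
    if (!is.na(fr) && fr >= moderate_fraction) return("cap_moderate")
    return("cap_strong")
  }
  if (flag$name %in% cap_strong) return("cap_strong")
  "no_change"
}

#' PVS1 strength decision for a curated variant
#'
#' Technical-artifact flags do not modify PVS1; they demand analytical
#' confirmation of the call first, so an unconfirmed variant with any
#' technical flag is reported as `"pending_confirmation"`. Otherwise each
#' non-technical flag maps to a consequence and the single worst one is
#' applied; downgrading is never additive.
#'
#' @param verdict Verdict string from [resolve_verdict()].
#' @param flags Flag data.frame.
#' @param analytically_confirmed Has the variant call been orthogonally
#'   confirmed?
#' @param moderate_fraction See [pvs1_consequence()].
#' @return A `pvs1_decision` list: `max_strength` (one of `very_strong`,
#'   `strong`, `moderate`, `supporting`, `not_applicable`,
#'   `pending_confirmation`), `requires_analytical_confirmation`, and a
#'   `trail` data.frame of (flag, consequence) pairs.
#' @export
pvs1_decision <- function(verdict, flags, analytically_confirmed = FALSE,
                          moderate_fraction = 0.10) {
  technical <- flags[flags$category == "technical", , drop = FALSE]
  if (nrow(technical) && !analytically_confirmed) {
    trail <- data.frame(flag = technical$name,
                        consequence = "analytical_confirmation_required")
    return(structure(list(max_strength = "pending_confirmation",
                          requires_analytical_confirmation = TRUE,
                          worst_consequence = NA_character_, trail = trail),
                     class = "pvs1_decision"))
  }
  nontech <- flags[flags$category != "technical", , drop = FALSE]
  if (!nrow(nontech)) {
    worst <- if (verdict == "uncertain_LoF") "cap_strong" else "no_change"
    trail <- data.frame(flag = character(), consequence = character())
  } else {
    cons <- vapply(seq_len(nrow(nontech)), function(i)
      pvs1_consequence(nontech[i, , drop = FALSE], moderate_fraction),
      character(1))
    trail <- data.frame(flag = nontech$name, consequence = cons)
    worst <- PVS1_CONSEQUENCES[max(match(cons, PVS1_CONSEQUENCES))]
  }
  strength <- c(no_change = "very_strong", cap_strong = "strong",
                cap_moderate = "moderate", do_not_use = "not_applicable")[worst]
  structure(list(max_strength = unname(strength),
                 requires_analytical_confirmation = FALSE,
                 worst_consequence = worst, trail = trail),
            class = "pvs1_decision")
}

#' Curate one variant
#'
#' @param bundle A [variant_bundle()].
#' @param ctx A [curation_context()].
#' @param profile A [rule_profile()].
#' @param all_bundles All cohort bundles (phase groups).
#' @param analytically_confirmed Orthogonal confirmation status.
#' @return A `curation_result`: `variant`, `flags`, `verdict`,
#'   `primary_reason`, `pvs1`, `notes`, `transcript_id`.
#' @export
curate_variant <- function(bundle, ctx, profile,
                           all_bundles = list(bundle),
                           analytically_confirmed = FALSE) {
  af <- assign_flags(bundle, ctx, profile, all_bundles)
  verdict <- resolve_verdict(af$flags, bundle$variant_class, bundle$has_read_data)
  structure(list(variant = bundle, flags = af$flags, verdict = verdict,
                 primary_reason = primary_reason(af$flags),
                 pvs1 = pvs1_decision(verdict, af$flags, analytically_confirmed),
                 notes = af$notes, transcript_id = af$transcript_id),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  cat(sprintf("<curation_result %s: %s  (primary: %s; PVS1 max %s)>\n",
              variant_key(x$variant), x$verdict, x$primary_reason,
              x$pvs1$max_strength))
  if (nrow(x$flags))
    cat(paste0("  - ", x$flags$name, " [", x$flags$category, " -> ",
               x$flags$tier, "]", collapse = "\n"), "\n")
  invisible(x)
}

#' Curate a cohort of variants
#'
#' @param bundles List of [variant_bundle()]s.
#' @param ctx A [curation_context()].
#' @param profile A [rule_profile()] (default conservative preset).
#' @param analytically_confirmed Logical scalar or vector per variant.
#' @return List of `curation_result`s.
#' @export
curate_cohort <- function(bundles, ctx, profile = rule_profile("conservative"),
                          analytically_confirmed = FALSE) {
  confirmed <- rep_len(analytically_confirmed, length(bundles))
  lapply(seq_along(bundles), function(i)
    curate_variant(bundles[[i]], ctx, profile, all_bundles = bundles,
                   analytically_confirmed = confirmed[i]))
}
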