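## Readers for the standard input formats (GTF, VCF, FASTA, BED, TSV), the
## genotype prefilter applied before curation, and the per-variant report
## writer. Readers go through rtracklayer / VariantAnnotation / Biostrings;
## only the toy-scale report and fixture writers emit text directly.

#' Read a reference genome FASTA
#' @param path FASTA file.
#' @return DNAStringSet keyed by contig name (description stripped).
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Read transcript models from a GTF file
#'
#' Uses `exon` and `CDS` features carrying `gene_id`/`transcript_id`
#' attributes. CDS intervals here include the stop codon. Exons are
#' returned strand-aware: exon index 1 is the transcript's 5'-most exon
#' (the genomically rightmost one on the minus strand).
#'
#' @param path GTF file.
#' @return Named list of [transcript_model()]s.
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines[nzchar(lines) & !startsWith(lines, "#")])) {
    warning("empty GTF: ", path)
    return(list())
  }
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop("cannot parse GTF ", path, ": ",
                                          conditionMessage(e)))
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  out <- list()
  for (tid in unique(df$transcript_id[!is.na(df$transcript_id)])) {
    rows <- df[df$transcript_id == tid & !is.na(df$transcript_id), , drop = FALSE]
    ex <- rows[rows$type == "exon", , drop = FALSE]
    cd <- rows[rows$type == "CDS", , drop = FALSE]
    if (!nrow(ex)) next
    tags <- character()
    if ("tag" %in% names(rows)) tags <- unique(stats::na.omit(rows$tag))
    tx <- tryCatch(
      transcript_model(tid, rows$gene_id[1], ex$seqnames[1], ex$strand[1],
                       exons = data.frame(start = ex$start, end = ex$end),
                       cds = if (nrow(cd))
                         data.frame(start = cd$start, end = cd$end) else NULL,
                       tags = tags),
      error = function(e) stop("GTF format error for transcript ", tid, ": ",
                               conditionMessage(e)))
    out[[tid]] <- tx
  }
  out
}

#' Read a per-exon pext table
#'
#' TSV with columns `gene_id`, `transcript_id`, `exon_index`, `mean_pext`.
#'
#' @param path TSV file.
#' @param per_base_path Optional TSV of per-base values (`chrom`, `start`,
#'   `end`, `value`).
#' @return A [pext_track()].
#' @export
read_pext <- function(path, per_base_path = NULL) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  pb <- if (!is.null(per_base_path))
    utils::read.delim(per_base_path, stringsAsFactors = FALSE) else NULL
  pext_track(ev, per_base = pb)
}

#' Read repeat / low-complexity annotation intervals from BED
#'
#' BED's 0-based half-open intervals are converted to 1-based inclusive at
#' read time. Interval names containing `"low_complexity"` feed the
#' low-complexity flag; all other intervals count toward the repeat-track
#' overlap.
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_repeats <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  name <- if (!is.null(gr$name)) gr$name else rep("repeat", length(gr))
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             name = name, stringsAsFactors = FALSE)
}

parse_trhit <- function(s) {
  if (is.na(s) || !nzchar(s) || s == ".")
    return(data.frame(transcript_id = character(), is_pLoF = logical()))
  parts <- strsplit(s, "[,;]")[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  data.frame(transcript_id = vapply(kv, `[`, character(1), 1),
             is_pLoF = vapply(kv, `[`, character(1), 2) == "1",
             stringsAsFactors = FALSE)
}

HET_GENOTYPES <- c("0/1", "1/0", "0|1", "1|0")

#' Read pLoF variant calls from VCF or TSV
#'
#' The VCF path expects single-sample records with `DP`, `GQ` and `AD`
#' FORMAT fields and the INFO keys `VCLASS` (variant class), `GENE`,
#' `TRHIT` (per-transcript pLoF annotation `tx:1`), optional `SpliceAI`
#' (standard 10-field annotation), optional `PG` (phase group) and the
#' `NOREAD` flag (read data unavailable). Allele balance is computed from
#' allele depths as `alt / (ref + alt)` when not given directly.
#'
#' The TSV dialect carries the same content in columns `chrom`, `pos`,
#' `ref`, `alt`, `variant_class`, `gene_id`, `depth`, `genotype_quality`,
#' `allele_balance`, `spliceai`, `phase_group`, `has_read_data`,
#' `transcripts_hit` (entries `tx:1;tx:0`); TSV genotypes are treated as
#' heterozygous carriers.
#'
#' With `prefilter = TRUE` low-confidence genotypes are excluded before
#' curation: depth < 10, genotype quality < 20, or allele balance < 20% for
#' non-reference heterozygous calls. Exclusion counts are attached as
#' `attr(x, "prefilter")` and logged.
#'
#' Records whose class is not a pLoF class are skipped with a warning
#' unless they carry a phase group, in which case they are retained as
#' phase-context records in `attr(x, "phase_partners")` (needed for MNV and
#' frame-restoring-indel assessment).
#'
#' @param path VCF (`.vcf`) or TSV file.
#' @param prefilter Apply the genotype prefilter (default TRUE).
#' @return List of [variant_bundle()]s with attributes `prefilter` and
#'   `phase_partners`.
#' @export
read_variants <- function(path, prefilter = TRUE) {
  if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path)) read_variants_vcf(path, prefilter)
  else read_variants_tsv(path, prefilter)
}

read_variants_vcf <- function(path, prefilter) {
  vcf <- VariantAnnotation::readVcf(path)
  n <- length(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  geno <- VariantAnnotation::geno(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alts_l <- VariantAnnotation::alt(vcf)

  get_info1 <- function(key, i) {
    if (!key %in% names(info)) return(NA_character_)
    v <- info[[key]][[i]]
    if (length(v) == 0 || all(is.na(v))) NA_character_
    else paste(as.character(v), collapse = ",")
  }
  bundles <- list(); partners <- list()
  excluded <- 0L; total_alleles <- 0L
  for (i in seq_len(n)) {
    alts <- as.character(alts_l[[i]])           # multi-allelic: one bundle per alt
    dp <- if ("DP" %in% names(geno)) geno$DP[i, 1] else NA_integer_
    gq <- if ("GQ" %in% names(geno)) geno$GQ[i, 1] else NA_integer_
    gt <- if ("GT" %in% names(geno)) geno$GT[i, 1] else NA_character_
    ad <- if ("AD" %in% names(geno)) unlist(geno$AD[i, 1]) else NULL
    for (j in seq_along(alts)) {
      total_alleles <- total_alleles + 1L
      ab <- NA_real_
      if (!is.null(ad) && length(ad) >= j + 1 && sum(ad, na.rm = TRUE) > 0)
        ab <- ad[j + 1] / (ad[1] + ad[j + 1])
      if (prefilter) {
        het <- is.na(gt) || gt %in% HET_GENOTYPES
        fail <- (!is.na(dp) && dp < 10) || (!is.na(gq) && gq < 20) ||
          (het && !is.na(ab) && ab < 0.20)
        if (fail) { excluded <- excluded + 1L; next }
      }
      vclass <- get_info1("VCLASS", i)
      pg <- get_info1("PG", i)
      if (is.na(vclass) || !vclass %in% PLOF_CLASSES) {
        if (!is.na(pg)) {
          partners[[length(partners) + 1L]] <-
            data.frame(chrom = chrom[i], pos = pos[i], ref = refs[i],
                       alt = alts[j], phase_group_id = pg,
                       stringsAsFactors = FALSE)
        } else {
          warning("record ", chrom[i], ":", pos[i],
                  " has unknown variant class '", vclass, "'; skipped")
        }
        next
      }
      noread <- "NOREAD" %in% names(info) && isTRUE(info$NOREAD[i])
      sb <- if ("SB" %in% names(info)) suppressWarnings(as.numeric(get_info1("SB", i)))
            else NA_real_
      b <- tryCatch(
        variant_bundle(chrom[i], pos[i], refs[i], alts[j], vclass,
                       qc = qc_metrics(depth = as.numeric(dp),
                                       genotype_quality = as.numeric(gq),
                                       allele_balance = ab, strand_bias = sb),
                       spliceai = { s <- get_info1("SpliceAI", i)
                                    if (is.na(s)) NULL else s },
                       phase_group_id = pg, has_read_data = !noread,
                       transcripts_hit = parse_trhit(get_info1("TRHIT", i)),
                       gene_id = get_info1("GENE", i)),
        error = function(e) stop("unparseable record at ", chrom[i], ":",
                                 pos[i], ": ", conditionMessage(e)))
      bundles[[length(bundles) + 1L]] <- b
    }
  }
  pf <- list(total = total_alleles, excluded = excluded,
             retained = total_alleles - excluded)
  if (prefilter)
    message("genotype prefilter: excluded ", excluded, " of ", total_alleles,
            " genotypes (depth<10 / GQ<20 / het AB<20%)")
  attr(bundles, "prefilter") <- pf
  attr(bundles, "phase_partners") <-
    if (length(partners)) do.call(rbind, partners) else NULL
  bundles
}

read_variants_tsv <- function(path, prefilter) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(spliceai = "character",
                                         phase_group = "character"))
  need <- c("chrom", "pos", "ref", "alt", "variant_class", "gene_id",
            "depth", "genotype_quality", "allele_balance", "spliceai",
            "phase_group", "has_read_data", "transcripts_hit")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("TSV is missing columns: ", paste(miss, collapse = ", "))
  bundles <- list(); partners <- list(); excluded <- 0L
  for (i in seq_len(nrow(df))) {
    if (prefilter) {
      fail <- (!is.na(df$depth[i]) && df$depth[i] < 10) ||
        (!is.na(df$genotype_quality[i]) && df$genotype_quality[i] < 20) ||
        (!is.na(df$allele_balance[i]) && df$allele_balance[i] < 0.20)
      if (fail) { excluded <- excluded + 1L; next }
    }
    pg <- df$phase_group[i]
    if (is.na(pg) || pg == ".") pg <- NA_character_
    if (!df$variant_class[i] %in% PLOF_CLASSES) {
      if (!is.na(pg))
        partners[[length(partners) + 1L]] <-
          data.frame(chrom = df$chrom[i], pos = df$pos[i], ref = df$ref[i],
                     alt = df$alt[i], phase_group_id = pg,
                     stringsAsFactors = FALSE)
      else warning("row ", i, " has unknown variant class '",
                   df$variant_class[i], "'; skipped")
      next
    }
    sai <- df$spliceai[i]
    if (is.na(sai) || sai == ".") sai <- NULL
    bundles[[length(bundles) + 1L]] <- variant_bundle(
      df$chrom[i], df$pos[i], df$ref[i], df$alt[i], df$variant_class[i],
      qc = qc_metrics(depth = df$depth[i],
                      genotype_quality = df$genotype_quality[i],
                      allele_balance = df$allele_balance[i]),
      spliceai = sai, phase_group_id = pg,
      has_read_data = as.logical(df$has_read_data[i]),
      transcripts_hit = parse_trhit(df$transcripts_hit[i]),
      gene_id = df$gene_id[i])
  }
  pf <- list(total = nrow(df), excluded = excluded,
             retained = nrow(df) - excluded)
  if (prefilter)
    message("genotype prefilter: excluded ", excluded, " of ", nrow(df),
            " genotypes (depth<10 / GQ<20 / het AB<20%)")
  attr(bundles, "prefilter") <- pf
  attr(bundles, "phase_partners") <-
    if (length(partners)) do.call(rbind, partners) else NULL
  bundles
}

#' Turn curation results into report rows
#' @param results List of `curation_result`s.
#' @return data.frame, one row per variant.
#' @export
report_rows <- function(results) {
  rows <- do.call(rbind, lapply(results, function(r) {
    fl <- if (nrow(r$flags))
      paste(paste(r$flags$name, r$flags$category, r$flags$tier, sep = ":"),
            collapse = ";") else "."
    data.frame(variant = variant_key(r$variant),
               variant_class = r$variant$variant_class,
               transcript_id = r$transcript_id,
               flags = fl, verdict = r$verdict,
               primary_reason = r$primary_reason,
               pvs1_max_strength = r$pvs1$max_strength,
               confirmation_required = r$pvs1$requires_analytical_confirmation,
               notes = if (length(r$notes)) paste(r$notes, collapse = "; ") else ".",
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

#' Write the per-variant curation report
#'
#' Writes a TSV (one row per curated variant) and a JSON summary next to it
#' (verdict distribution, flag counts, primary reasons).
#'
#' @param results List of `curation_result`s.
#' @param path Output TSV path; the JSON summary goes to
#'   `<path minus extension>_summary.json`.
#' @return Number of data rows written (invisibly the row data.frame is
#'   attached as an attribute).
#' @export
write_report <- function(results, path) {
  rows <- report_rows(results)
  tryCatch(utils::write.table(rows, path, sep = "\t", quote = FALSE,
                              row.names = FALSE),
           error = function(e) stop("cannot write report to ", path, ": ",
                                    conditionMessage(e)))
  summ <- summarize_results(results)
  json_path <- paste0(sub("\\.[^.]*$", "", path), "_summary.json")
  jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  out <- nrow(rows)
  attr(out, "rows") <- rows
  out
}

#' Read back a curation report TSV
#' @param path Report TSV.
#' @return data.frame of report rows.
#' @export
read_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(variant = "character", flags = "character",
                                   notes = "character"))
}
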