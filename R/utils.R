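## Small sequence helpers shared across modules. Reference sequences are
## Biostrings::DNAStringSet objects keyed by contig name; slices are returned
## as plain uppercase character strings.

#' @importFrom Biostrings DNAStringSet DNAString subseq reverseComplement
#'   GENETIC_CODE
NULL

get_ref_window <- function(ref_seq, chrom, start, end, strand = "+") {
  if (!chrom %in% names(ref_seq)) stop("contig not in reference: ", chrom)
  L <- Biostrings::nchar(ref_seq[[chrom]])
  start <- max(1L, as.integer(start)); end <- min(L, as.integer(end))
  if (end < start) return("")
  s <- Biostrings::subseq(ref_seq[[chrom]], start, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  toupper(as.character(s))
}

complement_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

translate_codon <- function(codon) {
  codon <- toupper(codon)
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

is_stop_codon <- function(codon) {
  toupper(codon) %in% c("TAA", "TAG", "TGA")
}

## fraction of G/C bases in a string
gc_fraction <- function(s) {
  if (!nchar(s)) return(NA_real_)
  b <- strsplit(toupper(s), "")[[1]]
  sum(b %in% c("G", "C")) / length(b)
}
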