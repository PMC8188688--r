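# lncRNA identification cascade: resolve coding capacity, drop short and
# small-RNA transcripts, and split the surviving long noncoding RNAs into
# intergenic (lincRNA) vs antisense-overlapping (lncNAT) classes.

#' Spliced length of transcripts
#'
#' Sum of exon lengths (1-based inclusive, so each exon contributes
#' `end - start + 1`). This is the length the >= 200 nt lncRNA size filter
#' is applied to, as opposed to the genomic span.
#'
#' @param transcripts Transcript table with an `exons` list-column.
#' @return Integer vector of spliced lengths, one per transcript.
#' @export
spliced_length <- function(transcripts) {
  vapply(transcripts$exons, function(ex) {
    sum(as.integer(ex$end) - as.integer(ex$start) + 1L)
  }, integer(1))
}

#' Resolve transcript coding capacity
#'
#' Coding-potential classifiers operate upstream of this package; their
#' verdicts enter here as an override table. For transcripts without an
#' override, a longest-ORF heuristic is applied to a supplied transcript
#' sequence: the transcript is called coding when its longest forward-strand
#' open reading frame (ATG through the first in-frame stop, any of the three
#' frames, stop codon counted) reaches `min_orf_codons` codons. Overrides
#' always win. Transcripts with neither an override, a sequence, nor an
#' already-resolved `coding` flag are an error.
#'
#' @param transcripts Transcript table.
#' @param overrides Optional data.frame with columns `transcript_id` and
#'   `coding` (values `coding`/`noncoding`), or a named character vector.
#' @param min_orf_codons Minimum ORF length in codons (default 100).
#' @param sequences Optional named character vector of transcript (mRNA
#'   sense) sequences.
#' @return The transcript table with its `coding` column resolved to
#'   `coding` or `noncoding` for every row.
#' @export
assign_coding <- function(transcripts, overrides = NULL,
                          min_orf_codons = 100, sequences = NULL) {
  coding <- transcripts$coding
  if (is.null(coding)) coding <- rep("unknown", nrow(transcripts))

  if (!is.null(overrides)) {
    if (is.data.frame(overrides)) {
      ov <- stats::setNames(as.character(overrides$coding),
                            overrides$transcript_id)
    } else {
      ov <- overrides
    }
    bad <- setdiff(unique(ov), c("coding", "noncoding"))
    if (length(bad) > 0L) {
      stop("coding override values must be 'coding' or 'noncoding'; found: ",
           paste(bad, collapse = ", "))
    }
    hit <- transcripts$transcript_id %in% names(ov)
    coding[hit] <- ov[transcripts$transcript_id[hit]]
  } else {
    hit <- rep(FALSE, nrow(transcripts))
  }

  need_seq <- !hit & coding == "unknown"
  if (any(need_seq) && !is.null(sequences)) {
    have <- need_seq & transcripts$transcript_id %in% names(sequences)
    coding[have] <- ifelse(
      vapply(sequences[transcripts$transcript_id[have]],
             longest_orf_codons, integer(1)) >= min_orf_codons,
      "coding", "noncoding")
  }

  unresolved <- coding == "unknown"
  if (any(unresolved)) {
    stop("coding status unresolved (no override, no sequence) for: ",
         paste(transcripts$transcript_id[unresolved], collapse = ", "))
  }
  transcripts$coding <- coding
  transcripts
}

#' Longest open reading frame, in codons
#'
#' Scans the three forward frames of a nucleotide sequence for ATG-initiated
#' reading frames terminated by an in-frame stop (TAA/TAG/TGA). Returns the
#' codon count of the longest such ORF, counting the stop codon; 0 when no
#' complete ORF exists.
#'
#' @param seq A nucleotide string (case-insensitive).
#' @return Integer codon count.
#' @export
longest_orf_codons <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    n_cod <- (n - frame) %/% 3L
    if (n_cod < 2L) next
    pos <- frame + 1L + 3L * (seq_len(n_cod) - 1L)
    cods <- substring(s, pos, pos + 2L)
    atg <- which(cods == "ATG")
    stp <- which(cods %in% stops)
    if (length(atg) == 0L || length(stp) == 0L) next
    for (a in atg) {
      nxt <- stp[stp >= a]
      if (length(nxt) == 0L) break
      best <- max(best, nxt[1L] - a + 1L)
    }
  }
  best
}

#' Classify transcripts into mRNA / lincRNA / lncNAT
#'
#' The identification cascade for long noncoding RNAs:
#' coding transcripts are `mRNA`; noncoding transcripts with spliced length
#' below 200 nt are `excluded_short`; noncoding transcripts matching the
#' small-RNA exclusion list (miRNA/rRNA/etc. hits from an upstream database
#' scan) are `excluded_smallRNA`; the remaining long noncoding RNAs are
#' `lncNAT` when their genomic span overlaps a coding transcript's span by
#' at least one base on the opposite strand of the same chromosome, and
#' `lincRNA` otherwise.
#'
#' @param transcripts Transcript table with `coding` resolved (see
#'   [assign_coding()]); unresolved flags are an error.
#' @param small_rna_ids Character vector of transcript ids to exclude as
#'   small noncoding RNAs.
#' @param min_lnc_length Minimum spliced length for a lncRNA, in nt
#'   (default 200, boundary included).
#' @return A data.frame with `transcript_id` and `category`, in input order.
#' @export
classify_lnc <- function(transcripts, small_rna_ids = character(0),
                         min_lnc_length = 200) {
  validate_transcripts(transcripts)
  if (any(transcripts$coding == "unknown")) {
    stop("unresolved coding flag for: ",
         paste(transcripts$transcript_id[transcripts$coding == "unknown"],
               collapse = ", "))
  }
  n <- nrow(transcripts)
  category <- rep(NA_character_, n)
  is_coding <- transcripts$coding == "coding"
  category[is_coding] <- "mRNA"

  slen <- spliced_length(transcripts)
  short <- !is_coding & slen < min_lnc_length
  category[short] <- "excluded_short"
  small <- !is_coding & !short & transcripts$transcript_id %in% small_rna_ids
  category[small] <- "excluded_smallRNA"

  lnc <- which(is.na(category))
  if (length(lnc) > 0L) {
    category[lnc] <- "lincRNA"
    if (any(is_coding)) {
      lnc_gr <- transcripts_granges(transcripts[lnc, , drop = FALSE])
      # strand-flip trick: a strand-aware hit of the flipped lncRNA against a
      # coding model is an opposite-strand overlap of the original
      BiocGenerics::strand(lnc_gr) <- ifelse(
        as.character(BiocGenerics::strand(lnc_gr)) == "+", "-", "+")
      cod_gr <- transcripts_granges(transcripts[is_coding, , drop = FALSE])
      hits <- GenomicRanges::findOverlaps(lnc_gr, cod_gr, minoverlap = 1L)
      category[lnc[unique(S4Vectors::queryHits(hits))]] <- "lncNAT"
    }
  }
  data.frame(transcript_id = transcripts$transcript_id,
             category = category, stringsAsFactors = FALSE)
}
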