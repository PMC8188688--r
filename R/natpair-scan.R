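# Genome-wide cis-NAT pair detection: find all opposite-strand transcript
# pairs whose genomic spans overlap by at least min_overlap bases, and type
# each pair by orientation and by the coding capacity of its members.
#
# The scan uses the interval index behind GenomicRanges::findOverlaps, so
# cost is near-linear in transcripts + overlaps; an all-pairs double loop is
# kept in the test suite as an independent oracle, never called here.

#' Overlap of two 1-based inclusive intervals
#'
#' `overlap_len = max(0, min(a_end, b_end) - max(a_start, b_start) + 1)`.
#' Adjacent intervals (e.g. 100-200 vs 201-300) do not overlap; intervals
#' sharing a single base (100-200 vs 200-300) overlap by 1. Vectorised.
#'
#' @param a_start,a_end,b_start,b_end Interval bounds, 1-based inclusive.
#' @param a_chrom,b_chrom Optional chromosome names; if both are supplied
#'   they must match elementwise (a mismatch is a caller bug, not a
#'   zero-overlap).
#' @return data.frame with `overlap_len`, `overlap_start`, `overlap_end`
#'   (the latter two `NA` when the overlap is empty).
#' @export
span_overlap <- function(a_start, a_end, b_start, b_end,
                         a_chrom = NULL, b_chrom = NULL) {
  if (!is.null(a_chrom) && !is.null(b_chrom) && any(a_chrom != b_chrom)) {
    stop("span_overlap called on intervals from different chromosomes")
  }
  os <- pmax(a_start, b_start)
  oe <- pmin(a_end, b_end)
  len <- pmax(0, oe - os + 1)
  os[len == 0] <- NA
  oe[len == 0] <- NA
  data.frame(overlap_len = len, overlap_start = os, overlap_end = oe)
}

#' Orientation class of an overlapping antisense transcript pair
#'
#' Three mutually exclusive classes cover every opposite-strand overlap:
#' * `enclosed` — one span contains the other (boundaries included;
#'   identical spans are mutual containment);
#' * `divergent` — head-to-head: the overlap covers the 5' ends of both
#'   members (for plus-strand member P = `[p1, p2]` and minus-strand member
#'   M = `[m1, m2]`, this is `m1 < p1 <= m2 < p2`);
#' * `convergent` — tail-to-tail: the overlap covers both 3' ends
#'   (`p1 < m1 <= p2 < m2`).
#'
#' @param a,b Single-row transcript records (data.frame rows or lists with
#'   `start`, `end`, `strand`); must be on opposite strands and overlap by
#'   at least one base.
#' @return One of `"enclosed"`, `"divergent"`, `"convergent"`.
#' @export
classify_orientation <- function(a, b) {
  if (a$strand == b$strand) {
    stop("classify_orientation requires opposite-strand transcripts")
  }
  if (max(a$start, b$start) > min(a$end, b$end)) {
    stop("classify_orientation requires overlapping spans")
  }
  if (a$strand == "+") {
    orientation_code(a$start, a$end, b$start, b$end)
  } else {
    orientation_code(b$start, b$end, a$start, a$end)
  }
}

# vectorised core: P = plus-strand member [p1,p2], M = minus-strand [m1,m2]
orientation_code <- function(p1, p2, m1, m2) {
  out <- rep("convergent", length(p1))
  enc <- (p1 <= m1 & m2 <= p2) | (m1 <= p1 & p2 <= m2)
  div <- !enc & m1 < p1 & p1 <= m2 & m2 < p2
  out[enc] <- "enclosed"
  out[div] <- "divergent"
  out
}

#' Scan an annotation for natural antisense transcript pairs
#'
#' Emits every unordered pair of transcripts that lie on opposite strands of
#' the same chromosome and overlap by at least `min_overlap` bases. A
#' transcript may participate in many pairs, and isoforms of the same gene
#' form distinct pairs. Each pair is typed for orientation
#' ([classify_orientation()]) and for coding class
#' (`coding_coding` / `coding_noncoding` / `noncoding_noncoding`). For
#' coding-noncoding pairs the coding member is reported as the sense
#' transcript and the lncRNA as the antisense; otherwise the plus-strand
#' member is reported as sense.
#'
#' @param transcripts Transcript table with resolved `coding` flags
#'   (`coding`/`noncoding`).
#' @param min_overlap Minimum overlap in bases (default 25, boundary
#'   included).
#' @param overlap_mode `"span"` (default) computes the overlap on genomic
#'   spans; `"exon"` requires at least `min_overlap` bases of exon-level
#'   overlap (summed over all exon intersections) while still reporting the
#'   span-intersection interval.
#' @return data.frame with one row per pair: `pair_id`, `chrom`,
#'   `sense_id`, `sense_gene_id`, `sense_start`, `sense_end`,
#'   `antisense_id`, `antisense_gene_id`, `antisense_start`,
#'   `antisense_end`, `overlap_start`, `overlap_end`, `overlap_len`,
#'   `orientation`, `coding_class`, sorted by
#'   `(chrom, overlap_start, sense_id, antisense_id)`.
#' @export
scan_pairs <- function(transcripts, min_overlap = 25,
                       overlap_mode = c("span", "exon")) {
  overlap_mode <- match.arg(overlap_mode)
  validate_transcripts(transcripts)
  if (nrow(transcripts) > 0L &&
      !all(transcripts$coding %in% c("coding", "noncoding"))) {
    stop("scan_pairs requires resolved coding flags; run assign_coding() first")
  }
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  if (nrow(transcripts) < 2L) return(empty_pairs())

  gr <- transcripts_granges(transcripts)
  span_min <- if (overlap_mode == "span") as.integer(min_overlap) else 1L
  hits <- GenomicRanges::findOverlaps(gr, minoverlap = span_min,
                                      drop.self = TRUE, drop.redundant = TRUE,
                                      ignore.strand = TRUE)
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  opp <- transcripts$strand[i] != transcripts$strand[j]
  i <- i[opp]
  j <- j[opp]
  if (length(i) == 0L) return(empty_pairs())

  ov <- span_overlap(transcripts$start[i], transcripts$end[i],
                     transcripts$start[j], transcripts$end[j])

  if (overlap_mode == "exon") {
    if (is.null(transcripts$exons)) {
      stop("overlap_mode = 'exon' needs an exons list-column")
    }
    keep <- exon_overlap_len(transcripts, i, j) >= min_overlap
    i <- i[keep]
    j <- j[keep]
    ov <- ov[keep, , drop = FALSE]
    if (length(i) == 0L) return(empty_pairs())
  }

  # sense/antisense role assignment
  ci <- transcripts$coding[i]
  cj <- transcripts$coding[j]
  coding_class <- ifelse(ci == "coding" & cj == "coding", "coding_coding",
                  ifelse(ci == "noncoding" & cj == "noncoding",
                         "noncoding_noncoding", "coding_noncoding"))
  i_is_sense <- ifelse(coding_class == "coding_noncoding",
                       ci == "coding", transcripts$strand[i] == "+")
  s <- ifelse(i_is_sense, i, j)
  a <- ifelse(i_is_sense, j, i)

  plus_first <- transcripts$strand[s] == "+"
  p_idx <- ifelse(plus_first, s, a)
  m_idx <- ifelse(plus_first, a, s)
  orientation <- orientation_code(transcripts$start[p_idx],
                                  transcripts$end[p_idx],
                                  transcripts$start[m_idx],
                                  transcripts$end[m_idx])

  gene <- transcripts$gene_id
  if (is.null(gene)) gene <- transcripts$transcript_id
  out <- data.frame(
    pair_id = paste(transcripts$transcript_id[s],
                    transcripts$transcript_id[a], sep = "|"),
    chrom = transcripts$chrom[s],
    sense_id = transcripts$transcript_id[s],
    sense_gene_id = gene[s],
    sense_start = transcripts$start[s],
    sense_end = transcripts$end[s],
    antisense_id = transcripts$transcript_id[a],
    antisense_gene_id = gene[a],
    antisense_start = transcripts$start[a],
    antisense_end = transcripts$end[a],
    overlap_start = ov$overlap_start,
    overlap_end = ov$overlap_end,
    overlap_len = ov$overlap_len,
    orientation = orientation,
    coding_class = coding_class,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$overlap_start, out$sense_id,
                   out$antisense_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Summed width of exon-by-exon intersections for candidate transcript pairs
# (i, j). Exon models are assumed non-overlapping within a transcript, so the
# sum of pairwise exon intersections equals the exon-union overlap.
exon_overlap_len <- function(transcripts, i, j) {
  vapply(seq_along(i), function(k) {
    ea <- transcripts$exons[[i[k]]]
    eb <- transcripts$exons[[j[k]]]
    tot <- 0L
    for (r in seq_len(nrow(ea))) {
      tot <- tot + sum(pmax(0L, pmin(ea$end[r], eb$end) -
                              pmax(ea$start[r], eb$start) + 1L))
    }
    as.integer(tot)
  }, integer(1))
}

empty_pairs <- function() {
  data.frame(pair_id = character(0), chrom = character(0),
             sense_id = character(0), sense_gene_id = character(0),
             sense_start = numeric(0), sense_end = numeric(0),
             antisense_id = character(0), antisense_gene_id = character(0),
             antisense_start = numeric(0), antisense_end = numeric(0),
             overlap_start = numeric(0), overlap_end = numeric(0),
             overlap_len = numeric(0), orientation = character(0),
             coding_class = character(0), stringsAsFactors = FALSE)
}
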