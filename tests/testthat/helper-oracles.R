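# Independent brute-force oracles. These deliberately share no code with the
# package: overlaps are counted position by position, the pair scan is an
# all-pairs double loop, ORFs are enumerated codon walks, and the
# hypergeometric tail is summed from binomial coefficients.

oracle_overlap <- function(a1, a2, b1, b2) {
  length(intersect(seq(a1, a2), seq(b1, b2)))
}

# orientation by end membership: divergent iff the overlap contains both 5'
# ends (plus member's start, minus member's end); convergent iff it contains
# both 3' ends; containment checked directly
oracle_orientation <- function(p1, p2, m1, m2) {
  if ((p1 <= m1 && m2 <= p2) || (m1 <= p1 && p2 <= m2)) return("enclosed")
  ov <- intersect(seq(p1, p2), seq(m1, m2))
  five <- (p1 %in% ov) && (m2 %in% ov)
  three <- (p2 %in% ov) && (m1 %in% ov)
  stopifnot(xor(five, three))
  if (five) "divergent" else "convergent"
}

# all-pairs double loop over a transcript table
oracle_scan <- function(transcripts, min_overlap = 25) {
  n <- nrow(transcripts)
  found <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (transcripts$chrom[i] != transcripts$chrom[j]) next
      if (transcripts$strand[i] == transcripts$strand[j]) next
      len <- max(0, min(transcripts$end[i], transcripts$end[j]) -
                   max(transcripts$start[i], transcripts$start[j]) + 1)
      if (len < min_overlap) next
      ci <- transcripts$coding[i]
      cj <- transcripts$coding[j]
      if (ci != cj) {
        s <- if (ci == "coding") i else j
      } else {
        s <- if (transcripts$strand[i] == "+") i else j
      }
      a <- if (s == i) j else i
      found[[length(found) + 1L]] <- data.frame(
        sense_id = transcripts$transcript_id[s],
        antisense_id = transcripts$transcript_id[a],
        overlap_len = len, stringsAsFactors = FALSE)
    }
  }
  if (length(found) == 0L) {
    return(data.frame(sense_id = character(0), antisense_id = character(0),
                      overlap_len = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, found)
  out[order(out$sense_id, out$antisense_id), , drop = FALSE]
}

oracle_longest_orf <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  best <- 0L
  for (start in seq_len(max(0L, n - 5L))) {
    if (substr(s, start, start + 2L) != "ATG") next
    pos <- start + 3L
    len <- 1L
    while (pos + 2L <= n) {
      cod <- substr(s, pos, pos + 2L)
      len <- len + 1L
      if (cod %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, len)
        break
      }
      pos <- pos + 3L
    }
  }
  best
}

oracle_hyper_tail <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# random unstructured annotation: dense overlaps on a short chromosome
random_annotation <- function(n, region = 5000) {
  start <- sample.int(region, n, replace = TRUE)
  len <- sample(10:400, n, replace = TRUE)
  data.frame(
    transcript_id = sprintf("T%03d", seq_len(n)),
    gene_id = sprintf("G%03d", seq_len(n)),
    chrom = sample(c("chrA", "chrB"), n, replace = TRUE),
    start = start, end = start + len - 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    coding = sample(c("coding", "noncoding"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# minimal GTF writer independent of write_gtf()
write_toy_gtf <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

gtf_exon_line <- function(chrom, start, end, strand, tx, gene = "g") {
  paste(chrom, "src", "exon", start, end, ".", strand, ".",
        sprintf('gene_id "%s"; transcript_id "%s";', gene, tx), sep = "\t")
}

# small expression object built in code
toy_expr <- function(values, accessions = "A", n_rep = 3) {
  meta <- expand.grid(replicate = seq_len(n_rep),
                      condition = c("control", "drought"),
                      accession = accessions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta$sample_id <- paste(meta$accession, meta$condition, meta$replicate,
                          sep = "_")
  colnames(values) <- meta$sample_id
  nat_expr(values, meta)
}
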