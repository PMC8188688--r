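# Machine-readable fixture of a published worked example: the ten
# coding-noncoding NAT pairs whose sense genes carry stress-related GO
# terms, with the accessions each pair was responsive in. Byte-stable
# across calls.

table1_rows <- function() {
  # chrom, sense id/start/end, antisense id/start/end, GO id, accessions
  rows <- list(
    list("chr01", "MSTRG.1295.1", 8546015, 8546972,
         "Os01t0256500-02", 8546065, 8546869, "GO:0006950", "BJ89"),
    list("chr03", "MSTRG.12385.1", 16407687, 16410061,
         "Os03t0402800-01", 16407699, 16410007, "GO:0009753", "BJ89,BJ278"),
    list("chr03", "MSTRG.12385.1", 16407687, 16410061,
         "Os03t0402800-02", 16407695, 16408985, "GO:0009753", "BJ89"),
    list("chr03", "Os03t0161900-01", 3342277, 3344547,
         "MSTRG.10570.1", 3342143, 3344510, "GO:0006950", "BJ89"),
    list("chr03", "Os03t0161900-02", 3342254, 3344542,
         "MSTRG.10570.1", 3342143, 3344510, "GO:0006950", "BJ89"),
    list("chr04", "Os04t0497700-01", 24889983, 24891470,
         "MSTRG.16704.1", 24889504, 24891481, "GO:0055114", "BJ89"),
    list("chr07", "Os07t0615200-01", 25348060, 25350242,
         "MSTRG.27311.1", 25348061, 25350279, "GO:0009867", "BJ89"),
    list("chr08", "Os08t0504700-01", 24953937, 24954919,
         "MSTRG.30183.1", 24953534, 24955156, "GO:0006950",
         "Nip,BJ89,BJ278"),
    list("chr09", "MSTRG.30767.1", 656756, 658373,
         "Os09t0106700-01", 656788, 658373, "GO:0006950", "BJ89"),
    list("chr09", "MSTRG.31075.1", 5538425, 5540535,
         "Os09t0273600-00", 5538561, 5539063, "GO:0006950", "BJ89")
  )
  data.frame(
    chrom = vapply(rows, `[[`, "", 1),
    sense_id = vapply(rows, `[[`, "", 2),
    sense_start = vapply(rows, `[[`, 0, 3),
    sense_end = vapply(rows, `[[`, 0, 4),
    antisense_id = vapply(rows, `[[`, "", 5),
    antisense_start = vapply(rows, `[[`, 0, 6),
    antisense_end = vapply(rows, `[[`, 0, 7),
    go_id = vapply(rows, `[[`, "", 8),
    accessions = vapply(rows, `[[`, "", 9),
    stringsAsFactors = FALSE
  )
}

# gene id from a transcript id: annotated isoforms drop the "-NN" suffix,
# assembled isoforms (MSTRG.<gene>.<iso>) drop the trailing ".<iso>"
gene_from_tx <- function(tx) {
  ifelse(grepl("^MSTRG\\.", tx), sub("\\.[0-9]+$", "", tx),
         sub("-[0-9]+$", "", tx))
}

#' The stress-responsive NAT-pair worked example
#'
#' Ten coding-noncoding NAT pairs on the rice genome whose sense genes are
#' annotated with stress-related GO terms, as a set of machine-readable
#' tables: the pair coordinates, a gene-to-GO annotation table for the
#' sense genes, and the long-format accession membership (which accessions
#' each pair was drought-responsive in). Nine of the ten pairs are specific
#' to the wild-rice accessions (BJ89/BJ278); one is shared by all three
#' accessions.
#'
#' @return A list of three data.frames: `pairs` (with `pair_id`, the
#'   coordinate columns, `sense_gene_id`, `go_id`, `accessions` and
#'   `coding_class`), `gene2go` (`gene_id`, `go_id`), and `membership`
#'   (`pair_id`, `accession`).
#' @export
table1_fixture <- function() {
  tab <- table1_rows()
  tab$pair_id <- paste(tab$sense_id, tab$antisense_id, sep = "|")
  tab$sense_gene_id <- gene_from_tx(tab$sense_id)
  tab$antisense_gene_id <- gene_from_tx(tab$antisense_id)
  tab$coding_class <- "coding_noncoding"

  gene2go <- unique(data.frame(gene_id = tab$sense_gene_id,
                               go_id = tab$go_id, stringsAsFactors = FALSE))
  rownames(gene2go) <- NULL

  acc <- strsplit(tab$accessions, ",", fixed = TRUE)
  membership <- data.frame(
    pair_id = rep(tab$pair_id, lengths(acc)),
    accession = unlist(acc),
    stringsAsFactors = FALSE
  )
  list(pairs = tab, gene2go = gene2go, membership = membership)
}

#' Transcript annotation built from the worked-example coordinates
#'
#' Expands the fixture of [table1_fixture()] into a transcript table ready
#' for [scan_pairs()]: each unique sense transcript becomes a single-exon
#' coding model on the plus strand, each antisense lncRNA a single-exon
#' noncoding model on the minus strand.
#'
#' @return A transcript table in the format of [read_gtf()], with resolved
#'   `coding` flags.
#' @export
table1_annotation <- function() {
  tab <- table1_rows()
  sense <- unique(data.frame(
    transcript_id = tab$sense_id, chrom = tab$chrom,
    start = tab$sense_start, end = tab$sense_end,
    strand = "+", coding = "coding", stringsAsFactors = FALSE))
  anti <- unique(data.frame(
    transcript_id = tab$antisense_id, chrom = tab$chrom,
    start = tab$antisense_start, end = tab$antisense_end,
    strand = "-", coding = "noncoding", stringsAsFactors = FALSE))
  out <- rbind(sense, anti)
  out$gene_id <- gene_from_tx(out$transcript_id)
  out$exons <- lapply(seq_len(nrow(out)), function(i) {
    data.frame(start = out$start[i], end = out$end[i])
  })
  out <- out[order(out$chrom, out$start, out$transcript_id),
             c("transcript_id", "gene_id", "chrom", "start", "end",
               "strand", "coding", "exons")]
  rownames(out) <- NULL
  out
}
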