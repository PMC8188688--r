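# Reading and writing the standard formats the pipeline touches, and
# normalising them into the internal transcript table.
#
# Internal coordinate convention: 1-based, inclusive (GTF native). BED output
# converts to 0-based half-open at the boundary and nowhere else.

#' Read transcript models from a GTF file
#'
#' Parses the `exon` features of a GTF file into a transcript table: one row
#' per `transcript_id`, the transcript span being the hull of its exons.
#' Coordinates are kept 1-based inclusive throughout the package.
#'
#' Unstranded records (strand `"."`) are excluded with a warning giving the
#' number of transcripts dropped: antisense analysis is meaningless without
#' strand, but a stray unstranded model should not abort a run. A
#' `transcript_id` that appears on more than one chromosome or strand is an
#' error (ambiguous identity).
#'
#' @param path Path to a GTF file. Attributes must carry `transcript_id`;
#'   `gene_id` is used when present and falls back to the transcript id.
#' @return A data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `coding` (initialised to `"unknown"`) and a
#'   list-column `exons` of data.frames with `start`/`end`, sorted by
#'   `(chrom, start, transcript_id)`.
#' @examples
#' gtf <- tempfile(fileext = ".gtf")
#' writeLines(paste("chr1", "x", "exon", "100", "200", ".", "+", ".",
#'                  'gene_id "g1"; transcript_id "t1";', sep = "\t"), gtf)
#' read_gtf(gtf)
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    return(empty_transcripts())
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1L]
    stop("malformed GTF record at line ", keep[bad],
         ": expected 9 tab-separated fields, found ", nf[bad])
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  is_exon <- m[, 3L] == "exon"
  if (!any(is_exon)) {
    return(empty_transcripts())
  }
  line_no <- keep[is_exon]
  chrom <- m[is_exon, 1L]
  start <- suppressWarnings(as.integer(m[is_exon, 4L]))
  end <- suppressWarnings(as.integer(m[is_exon, 5L]))
  strand <- m[is_exon, 7L]
  attrs <- m[is_exon, 9L]

  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1L]
    stop("malformed GTF record at line ", line_no[bad],
         ": non-numeric coordinates")
  }
  if (any(start > end)) {
    bad <- which(start > end)[1L]
    stop("malformed GTF record at line ", line_no[bad], ": start > end")
  }
  bad_strand <- !(strand %in% c("+", "-", "."))
  if (any(bad_strand)) {
    stop("malformed GTF record at line ", line_no[which(bad_strand)[1L]],
         ": strand must be '+', '-' or '.'")
  }

  tx <- gtf_attribute(attrs, "transcript_id")
  if (anyNA(tx)) {
    stop("exon without transcript_id attribute at line ",
         line_no[which(is.na(tx))[1L]])
  }
  gene <- gtf_attribute(attrs, "gene_id")
  gene[is.na(gene)] <- tx[is.na(gene)]

  by_tx <- split(seq_along(tx), factor(tx, levels = unique(tx)))
  rows <- lapply(by_tx, function(i) {
    id <- tx[i[1L]]
    if (length(unique(chrom[i])) > 1L) {
      stop("transcript_id '", id, "' occurs on multiple chromosomes")
    }
    if (length(unique(strand[i])) > 1L) {
      stop("transcript_id '", id, "' has exons on both strands")
    }
    o <- order(start[i])
    es <- start[i][o]
    ee <- end[i][o]
    if (length(es) > 1L && any(es[-1L] <= ee[-length(ee)])) {
      stop("transcript_id '", id, "' has overlapping exons")
    }
    list(transcript_id = id, gene_id = gene[i[1L]], chrom = chrom[i[1L]],
         start = min(es), end = max(ee), strand = strand[i[1L]],
         exons = data.frame(start = es, end = ee))
  })

  out <- data.frame(
    transcript_id = vapply(rows, `[[`, "", "transcript_id"),
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, `[[`, 0, "start"),
    end = vapply(rows, `[[`, 0, "end"),
    strand = vapply(rows, `[[`, "", "strand"),
    coding = "unknown",
    stringsAsFactors = FALSE
  )
  out$exons <- unname(lapply(rows, `[[`, "exons"))

  unstranded <- out$strand == "."
  if (any(unstranded)) {
    warning("excluded ", sum(unstranded),
            " unstranded ('.') transcript(s) from the annotation")
    out <- out[!unstranded, , drop = FALSE]
  }
  out <- out[order(out$chrom, out$start, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a transcript table back to GTF
#'
#' Emits one `exon` feature per exon, carrying `gene_id` and `transcript_id`
#' attributes. `read_gtf(write_gtf(x))` reproduces `x` up to the `coding`
#' column, which GTF does not carry.
#'
#' @param transcripts A transcript table as returned by [read_gtf()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(transcripts, path) {
  validate_transcripts(transcripts)
  lines <- character(0)
  if (nrow(transcripts) > 0L) {
    lines <- unlist(lapply(seq_len(nrow(transcripts)), function(i) {
      ex <- transcripts$exons[[i]]
      sprintf("%s\tnatpairs\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
              transcripts$chrom[i], as.integer(ex$start), as.integer(ex$end),
              transcripts$strand[i], transcripts$gene_id[i],
              transcripts$transcript_id[i])
    }))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an FPKM expression matrix with its sample metadata
#'
#' @param path TSV whose first column holds transcript ids and whose remaining
#'   columns are per-sample FPKM values (header row = sample ids). Missing
#'   cells are treated as 0 (absent transcript); negative values are an error.
#' @param meta_path TSV with columns `sample_id`, `accession`, `condition`
#'   (`control` or `drought`) and `replicate`. Every sample column of the
#'   matrix must have a metadata row; `(accession, condition, replicate)`
#'   must be unique.
#' @return An object of class `nat_expr`: a list with `values` (numeric
#'   matrix, transcripts x samples) and `meta` (data.frame aligned to the
#'   matrix columns).
#' @export
read_expression <- function(path, meta_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs a transcript id column plus sample columns")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicated transcript ids in expression table")
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric FPKM values in expression table")
  vals[is.na(vals)] <- 0
  rownames(vals) <- ids

  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "accession", "condition", "replicate")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0L) {
    stop("sample metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  nat_expr(vals, meta)
}

#' Construct an expression-matrix object
#'
#' Validates the invariants the downstream differential-expression code
#' relies on: non-negative values, every sample column described by a unique
#' `(accession, condition, replicate)` metadata row, conditions limited to
#' `control`/`drought`.
#'
#' @param values Numeric matrix, transcript ids as rownames, sample ids as
#'   colnames.
#' @param meta Data.frame with `sample_id`, `accession`, `condition`,
#'   `replicate`.
#' @return An object of class `nat_expr`.
#' @export
nat_expr <- function(values, meta) {
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression values need transcript rownames and sample colnames")
  }
  if (any(values < 0)) {
    bad <- rownames(values)[which(rowSums(values < 0) > 0)[1L]]
    stop("negative FPKM value for transcript '", bad, "'")
  }
  absent <- setdiff(colnames(values), meta$sample_id)
  if (length(absent) > 0L) {
    stop("sample(s) missing from metadata: ", paste(absent, collapse = ", "))
  }
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  bad_cond <- setdiff(unique(meta$condition), c("control", "drought"))
  if (length(bad_cond) > 0L) {
    stop("condition must be 'control' or 'drought'; found: ",
         paste(bad_cond, collapse = ", "))
  }
  key <- paste(meta$accession, meta$condition, meta$replicate)
  if (anyDuplicated(key)) {
    stop("duplicated (accession, condition, replicate) in sample metadata")
  }
  structure(list(values = values, meta = meta), class = "nat_expr")
}

#' @export
print.nat_expr <- function(x, ...) {
  cat("nat_expr: ", nrow(x$values), " transcripts x ", ncol(x$values),
      " samples (", length(unique(x$meta$accession)), " accession(s))\n",
      sep = "")
  invisible(x)
}

#' Write NAT-pair overlap intervals as BED6
#'
#' Each pair contributes one row covering its overlap interval, converted
#' from the internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention. The name field is
#' `senseID|antisenseID|orientation`; rows are sorted by (chrom, start).
#'
#' @param pairs A pair table from [scan_pairs()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pairs_bed <- function(pairs, path) {
  if (nrow(pairs) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- data.frame(
    chrom = pairs$chrom,
    start = as.integer(pairs$overlap_start) - 1L,
    end = as.integer(pairs$overlap_end),
    name = paste(pairs$sense_id, pairs$antisense_id, pairs$orientation,
                 sep = "|"),
    score = as.integer(pairs$overlap_len),
    strand = "+",
    stringsAsFactors = FALSE
  )
  bed <- bed[order(bed$chrom, bed$start, bed$name), , drop = FALSE]
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# --- internal helpers --------------------------------------------------------

gtf_attribute <- function(attrs, key) {
  pat <- paste0('(^|;)\\s*', key, '\\s+"([^"]*)"')
  m <- regmatches(attrs, regexpr(pat, attrs))
  out <- rep(NA_character_, length(attrs))
  hit <- grepl(pat, attrs)
  out[hit] <- sub(pat, "\\2", regmatches(attrs, regexpr(pat, attrs)))
  out
}

empty_transcripts <- function() {
  out <- data.frame(transcript_id = character(0), gene_id = character(0),
                    chrom = character(0), start = numeric(0), end = numeric(0),
                    strand = character(0), coding = character(0),
                    stringsAsFactors = FALSE)
  out$exons <- list()
  out
}

validate_transcripts <- function(transcripts, need_exons = TRUE) {
  need <- c("transcript_id", "chrom", "start", "end", "strand")
  missing_cols <- setdiff(need, names(transcripts))
  if (length(missing_cols) > 0L) {
    stop("transcript table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(transcripts) == 0L) return(invisible(transcripts))
  if (anyDuplicated(transcripts$transcript_id)) {
    stop("duplicated transcript_id in transcript table")
  }
  if (any(transcripts$start > transcripts$end)) {
    stop("transcript with start > end")
  }
  if (!all(transcripts$strand %in% c("+", "-"))) {
    stop("transcript strand must be '+' or '-'")
  }
  if (need_exons && !is.null(transcripts$exons)) {
    ok <- vapply(seq_len(nrow(transcripts)), function(i) {
      ex <- transcripts$exons[[i]]
      all(ex$start >= transcripts$start[i]) && all(ex$end <= transcripts$end[i])
    }, TRUE)
    if (!all(ok)) stop("exon outside its transcript span")
  }
  invisible(transcripts)
}

transcripts_granges <- function(transcripts) {
  GenomicRanges::GRanges(
    seqnames = transcripts$chrom,
    ranges = IRanges::IRanges(start = transcripts$start,
                              end = transcripts$end),
    strand = transcripts$strand
  )
}
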