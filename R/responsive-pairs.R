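# Drought-response layer: per-accession differential expression calls,
# concordant/discordant NAT-pair classification, three-accession Venn
# partitioning, expression presence, GO linkage and hypergeometric
# enrichment.

#' Call differential expression for one accession
#'
#' Fold change is computed on pseudocounted condition means,
#' `(mean drought FPKM + eps) / (mean control FPKM + eps)`. The p-value
#' comes from a two-sample comparison of `log2(FPKM + eps)` across
#' replicates (noise on FPKM is treated as log-normal): by default limma's
#' moderated t statistic, which shares variance information across
#' transcripts — at two to three replicates per condition an unmoderated
#' per-transcript test has so few degrees of freedom that even strong,
#' clean effects cannot reach a stringent FDR cutoff. `method = "welch"`
#' selects a plain per-transcript Welch test instead. q-values are
#' Benjamini-Hochberg adjusted across all transcripts tested in the
#' accession, mirroring one differential run per accession contrast. Calls
#' follow the study thresholds: `DEG` when the fold change (in either
#' direction) reaches `fc_threshold` at `q <= q_threshold`, `HDEG` when it
#' additionally reaches `hdeg_fc`; the HDEG set is a subset of the DEG set
#' by construction.
#'
#' @param expr A [nat_expr()] expression object.
#' @param accession Accession to test (must appear in the metadata with at
#'   least two replicates per condition).
#' @param fc_threshold Fold-change threshold for a DEG call (default 2).
#' @param q_threshold BH-FDR threshold (default 0.01).
#' @param hdeg_fc Fold-change threshold for a highly-differential (HDEG)
#'   call (default 4).
#' @param pseudocount FPKM pseudocount `eps` added before ratios and logs
#'   (default 1), so condition-specific transcripts keep a finite fold
#'   change.
#' @param method `"moderated"` (limma eBayes, default) or `"welch"`
#'   (per-transcript unequal-variance t).
#' @return data.frame, one row per transcript: `transcript_id`,
#'   `accession`, `mean_control`, `mean_drought`, `fc` (pseudocounted
#'   drought/control ratio), `log2fc`, `p`, `q`, `call`
#'   (`none`/`DEG`/`HDEG`) and `direction` (`up`/`down`/`none`).
#' @export
call_de <- function(expr, accession, fc_threshold = 2, q_threshold = 0.01,
                    hdeg_fc = 4, pseudocount = 1,
                    method = c("moderated", "welch")) {
  method <- match.arg(method)
  stopifnot(inherits(expr, "nat_expr"))
  meta <- expr$meta
  if (!accession %in% meta$accession) {
    stop("accession '", accession, "' absent from sample metadata")
  }
  ctrl <- meta$sample_id[meta$accession == accession &
                           meta$condition == "control"]
  drt <- meta$sample_id[meta$accession == accession &
                          meta$condition == "drought"]
  if (length(ctrl) < 2L || length(drt) < 2L) {
    stop("accession '", accession,
         "' needs >= 2 replicates per condition (found ", length(ctrl),
         " control, ", length(drt), " drought)")
  }

  vc <- expr$values[, ctrl, drop = FALSE]
  vd <- expr$values[, drt, drop = FALSE]
  mean_control <- rowMeans(vc)
  mean_drought <- rowMeans(vd)
  fc <- (mean_drought + pseudocount) / (mean_control + pseudocount)
  log2fc <- log2(fc)

  lc <- log2(vc + pseudocount)
  ld <- log2(vd + pseudocount)
  p <- if (method == "moderated") moderated_p(lc, ld) else welch_p(lc, ld)
  q <- stats::p.adjust(p, method = "BH")

  magnitude <- pmax(fc, 1 / fc)
  sig <- q <= q_threshold
  call <- ifelse(sig & magnitude >= hdeg_fc, "HDEG",
          ifelse(sig & magnitude >= fc_threshold, "DEG", "none"))
  direction <- ifelse(call == "none", "none",
                      ifelse(log2fc > 0, "up", "down"))

  data.frame(transcript_id = rownames(expr$values), accession = accession,
             mean_control = mean_control, mean_drought = mean_drought,
             fc = fc, log2fc = log2fc, p = p, q = q,
             call = call, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Row-wise moderated-t p-values (limma lmFit + eBayes) for a two-group
# comparison on the log scale.
moderated_p <- function(x, y) {
  mat <- cbind(x, y)
  group <- factor(rep(c("control", "drought"), c(ncol(x), ncol(y))),
                  levels = c("control", "drought"))
  design <- stats::model.matrix(~group)
  fit <- limma::eBayes(limma::lmFit(mat, design))
  p <- fit$p.value[, 2L]
  # rows that are exactly constant everywhere carry no evidence
  flat <- rowSums(abs(mat - mat[, 1L])) == 0
  p[flat | !is.finite(p)] <- 1
  unname(p)
}

# Row-wise Welch two-sample p-values for two replicate matrices on the log
# scale. Zero pooled standard error degenerates to p = 1 (equal means) or
# p = 0 (unequal means): constant replicate rows must not abort a run.
welch_p <- function(x, y) {
  n1 <- ncol(x)
  n2 <- ncol(y)
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  t <- (m2 - m1) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  p
}

#' Classify NAT pairs as concordant, discordant or not responsive
#'
#' A pair is drought-responsive in an accession only when both its members
#' are differentially expressed there; responsive pairs are `concordant_up`
#' (both up), `concordant_down` (both down) or `discordant` (opposite
#' directions), and every (DEG, DEG) pair falls in exactly one of the three.
#'
#' @param pairs Pair table from [scan_pairs()].
#' @param de DE table from [call_de()] for one accession; every pair member
#'   must have a row (a missing transcript is an error naming it).
#' @return The pair table with `accession` and `status`
#'   (`not_responsive`/`discordant`/`concordant_up`/`concordant_down`)
#'   columns appended, plus each member's `call` and `direction`.
#' @export
classify_pair_response <- function(pairs, de) {
  accession <- unique(de$accession)
  if (length(accession) != 1L) {
    stop("de must come from a single call_de() run (one accession)")
  }
  idx <- function(ids) {
    m <- match(ids, de$transcript_id)
    if (anyNA(m)) {
      stop("no DE result for transcript '", ids[which(is.na(m))[1L]],
           "' in accession '", accession, "'")
    }
    m
  }
  s <- idx(pairs$sense_id)
  a <- idx(pairs$antisense_id)
  s_de <- de$call[s] != "none"
  a_de <- de$call[a] != "none"
  both <- s_de & a_de
  status <- rep("not_responsive", nrow(pairs))
  status[both & de$direction[s] == "up" & de$direction[a] == "up"] <-
    "concordant_up"
  status[both & de$direction[s] == "down" & de$direction[a] == "down"] <-
    "concordant_down"
  status[both & de$direction[s] != de$direction[a]] <- "discordant"
  out <- pairs
  out$accession <- accession
  out$sense_call <- de$call[s]
  out$sense_direction <- de$direction[s]
  out$antisense_call <- de$call[a]
  out$antisense_direction <- de$direction[a]
  out$status <- status
  out
}

#' Seven-region Venn partition across three accessions
#'
#' Decomposes per-accession membership sets into the seven regions of a
#' three-set Venn diagram. Region counts always sum to the union, and each
#' accession's marginal is the sum of its four regions.
#'
#' @param membership Named list mapping accession name to a vector of item
#'   ids; names outside `accessions` are an error, accessions without a list
#'   entry contribute empty sets.
#' @param accessions Ordered character vector of exactly three accession
#'   names; region names are derived from this order.
#' @return An object of class `venn_partition`: a list with `region_counts`
#'   (named integer vector over the 7 regions), `union`, `marginals` (named
#'   per-accession totals) and `accessions`.
#' @export
venn_partition <- function(membership, accessions) {
  if (length(accessions) != 3L || anyDuplicated(accessions)) {
    stop("accessions must be three distinct names")
  }
  unknown <- setdiff(names(membership), accessions)
  if (length(unknown) > 0L) {
    stop("membership given for unknown accession(s): ",
         paste(unknown, collapse = ", "))
  }
  sets <- lapply(accessions, function(a) unique(as.character(membership[[a]])))
  items <- unique(unlist(sets))
  code <- (items %in% sets[[1L]]) + 2L * (items %in% sets[[2L]]) +
    4L * (items %in% sets[[3L]])
  region_names <- venn_region_names(accessions)
  counts <- stats::setNames(integer(7), region_names)
  tab <- table(factor(code, levels = 1:7))
  counts[] <- as.integer(tab)
  marginals <- stats::setNames(lengths(sets), accessions)
  structure(list(region_counts = counts, union = length(items),
                 marginals = marginals, accessions = accessions),
            class = "venn_partition")
}

# region order: codes 1..7 = A, B, A&B, C, A&C, B&C, A&B&C
venn_region_names <- function(accessions) {
  a <- accessions
  c(paste0(a[1], "_only"), paste0(a[2], "_only"),
    paste0(a[1], "&", a[2]), paste0(a[3], "_only"),
    paste0(a[1], "&", a[3]), paste0(a[2], "&", a[3]),
    paste(a, collapse = "&"))
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition over", paste(x$accessions, collapse = ", "), "\n")
  print(x$region_counts)
  cat("union:", x$union, "\n")
  invisible(x)
}

#' Expand region counts into synthetic membership sets
#'
#' Inverse of [venn_partition()] up to item identity: builds a membership
#' list whose Venn partition has exactly the given region counts. Useful for
#' reconstructing unions and marginals from published region tallies.
#'
#' @param region_counts Named vector of counts; names must be the region
#'   names induced by `accessions` (see [venn_partition()]); absent regions
#'   count 0.
#' @param accessions Ordered character vector of three accession names.
#' @return Named list of synthetic item-id vectors, one per accession.
#' @export
expand_venn_counts <- function(region_counts, accessions) {
  region_names <- venn_region_names(accessions)
  unknown <- setdiff(names(region_counts), region_names)
  if (length(unknown) > 0L) {
    stop("unknown region name(s): ", paste(unknown, collapse = ", "))
  }
  counts <- stats::setNames(rep(0L, 7L), region_names)
  counts[names(region_counts)] <- as.integer(region_counts)
  in_region <- list(c(1), c(2), c(1, 2), c(3), c(1, 3), c(2, 3), c(1, 2, 3))
  membership <- stats::setNames(
    rep(list(character(0)), 3L), accessions)
  for (r in seq_len(7L)) {
    if (counts[r] == 0L) next
    ids <- sprintf("r%d_%d", r, seq_len(counts[r]))
    for (a in in_region[[r]]) {
      membership[[a]] <- c(membership[[a]], ids)
    }
  }
  membership
}

#' Is a transcript expressed in an accession?
#'
#' A transcript counts as expressed when its mean FPKM reaches `min_fpkm`
#' (inclusive) in at least one condition of the accession.
#'
#' @param expr A [nat_expr()] object.
#' @param transcript_id Character vector of transcript ids (all must be
#'   present).
#' @param accession Accession name.
#' @param min_fpkm Mean-FPKM threshold (default 0.1).
#' @return Named logical vector.
#' @export
expressed_in <- function(expr, transcript_id, accession, min_fpkm = 0.1) {
  stopifnot(inherits(expr, "nat_expr"))
  if (!accession %in% expr$meta$accession) {
    stop("unknown accession '", accession, "'")
  }
  missing_tx <- setdiff(transcript_id, rownames(expr$values))
  if (length(missing_tx) > 0L) {
    stop("unknown transcript(s): ", paste(missing_tx, collapse = ", "))
  }
  out <- rep(FALSE, length(transcript_id))
  for (cond in c("control", "drought")) {
    cols <- expr$meta$sample_id[expr$meta$accession == accession &
                                  expr$meta$condition == cond]
    if (length(cols) == 0L) next
    m <- rowMeans(expr$values[transcript_id, cols, drop = FALSE])
    out <- out | (m >= min_fpkm)
  }
  stats::setNames(out, transcript_id)
}

#' Link coding-noncoding NAT pairs to stress-related GO terms
#'
#' Emits one row per (pair, matching term) for every coding-noncoding pair
#' whose sense gene is annotated with at least one of the stress terms.
#' Genes without annotation simply never match. The accession set in which
#' each pair is responsive is carried through from `membership` (or from an
#' `accessions` column already on `pairs`).
#'
#' @param pairs Pair table with `pair_id`, `sense_id`, `antisense_id`,
#'   `sense_gene_id` and `coding_class` columns (as from [scan_pairs()]).
#' @param gene2go data.frame with columns `gene_id` and `go_id`.
#' @param stress_terms Character vector of GO ids to match; the default is
#'   the four drought-stress terms of the study (response to stress,
#'   response to jasmonic acid stimulus, oxidation reduction, jasmonic acid
#'   mediated signaling pathway).
#' @param membership Optional data.frame `(pair_id, accession)` giving the
#'   accessions in which each pair is responsive.
#' @return data.frame with `pair_id`, `chrom` (if present), `sense_id`,
#'   `antisense_id`, `go_id`, `accessions` (comma-joined, `NA` when
#'   unknown).
#' @export
go_link <- function(pairs, gene2go,
                    stress_terms = c("GO:0006950", "GO:0009753",
                                     "GO:0055114", "GO:0009867"),
                    membership = NULL) {
  cn <- pairs[pairs$coding_class == "coding_noncoding", , drop = FALSE]
  acc_of <- function(pid) {
    if (!is.null(membership)) {
      hit <- membership$accession[membership$pair_id == pid]
      if (length(hit) == 0L) NA_character_ else paste(hit, collapse = ",")
    } else if (!is.null(pairs$accessions)) {
      pairs$accessions[match(pid, pairs$pair_id)]
    } else {
      NA_character_
    }
  }
  rows <- list()
  for (k in seq_len(nrow(cn))) {
    terms <- intersect(gene2go$go_id[gene2go$gene_id == cn$sense_gene_id[k]],
                       stress_terms)
    for (term in terms) {
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = cn$pair_id[k],
        chrom = if (!is.null(cn$chrom)) cn$chrom[k] else NA_character_,
        sense_id = cn$sense_id[k],
        antisense_id = cn$antisense_id[k],
        go_id = term,
        accessions = acc_of(cn$pair_id[k]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(pair_id = character(0), chrom = character(0),
                      sense_id = character(0), antisense_id = character(0),
                      go_id = character(0), accessions = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hypergeometric GO-term enrichment
#'
#' For each GO term annotated to at least one study gene: `k` study genes
#' carry the term, `K` population genes carry it, `n = |study|`,
#' `N = |population|`, and the enrichment p-value is the upper-tail
#' hypergeometric probability `P(X >= k)`. q-values are BH-adjusted across
#' the tested terms. Terms are matched flat, exactly as annotated (no GO
#' graph propagation).
#'
#' @param study Character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population Character vector of background gene ids.
#' @param gene2go data.frame with `gene_id` and `go_id` columns.
#' @return data.frame with `go_id`, `k`, `K`, `n`, `N`, `p`, `q`, sorted by
#'   `p` then `go_id`.
#' @export
enrich_hypergeom <- function(study, population, gene2go) {
  study <- unique(study)
  population <- unique(population)
  outside <- setdiff(study, population)
  if (length(outside) > 0L) {
    stop("study gene(s) outside population: ",
         paste(outside, collapse = ", "))
  }
  ann <- gene2go[gene2go$gene_id %in% population, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "go_id")])
  n <- length(study)
  N <- length(population)
  terms <- unique(ann$go_id[ann$gene_id %in% study])
  if (length(terms) == 0L) {
    return(data.frame(go_id = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), stringsAsFactors = FALSE))
  }
  k <- vapply(terms, function(t) {
    sum(ann$go_id == t & ann$gene_id %in% study)
  }, integer(1))
  K <- vapply(terms, function(t) sum(ann$go_id == t), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  out <- data.frame(go_id = terms, k = k, K = K, n = n, N = N, p = p, q = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p, out$go_id), , drop = FALSE]
}
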