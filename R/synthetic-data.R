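# Seeded simulator: toy annotations and replicated FPKM matrices with fully
# known ground truth (planted transcript classes, pair orientations and
# per-accession response statuses), so the whole pipeline is testable
# without any sequencing data.

#' Simulation specification
#'
#' Defaults emulate the study design the package targets: three accessions
#' (one cultivated, two wild) x two conditions x three replicates, with
#' planted 8-fold expression effects and log-normal replicate noise.
#' The orientation mix allocates ~46% of lncRNAs to antisense pairs, split
#' 61/23/15 between enclosed, divergent and convergent geometry (the split
#' observed genome-wide in rice), leaving ~54% intergenic.
#'
#' @param seed Integer RNG seed; same seed, same output, byte for byte.
#' @param n_chromosomes,chrom_length Genome layout (default 3 x 2 Mb).
#' @param n_coding,n_lnc Numbers of coding and long-noncoding transcripts
#'   (default 500 + 500).
#' @param orientation_mix Named probabilities over
#'   `enclosed`/`divergent`/`convergent`/`none` drawn per lncRNA; `none`
#'   places the lncRNA in its own locus (a lincRNA).
#' @param coding_pair_prob Fraction of the coding transcripts left over
#'   after lncRNA pairing that are themselves paired into coding-coding
#'   NAT pairs (default 0.2).
#' @param pair_overlap_range Planted overlap lengths in bp (default
#'   `c(25, 2000)`).
#' @param tx_length_range Transcript span lengths in bp (default
#'   `c(500, 3000)`).
#' @param accessions,n_replicates Sample design (default Nip/BJ89/BJ278 x 3
#'   replicates per condition).
#' @param class_mix Named probabilities of the planted per-pair response
#'   class over `concordant_up`/`concordant_down`/`discordant`/`null`.
#' @param planted_effects Named list mapping response class to
#'   `c(sense log2 fold change, antisense log2 fold change)` applied under
#'   drought in the pair's responsive accessions (default 8-fold effects:
#'   +3/+3, -3/-3, +3/-3, 0/0).
#' @param noise_sd Replicate noise standard deviation on the log2 FPKM
#'   scale (default 0.25).
#' @param baseline_logfpkm_range Per-transcript baseline log2 FPKM drawn
#'   uniformly from this interval (default `c(3, 8)`).
#' @param locus_gap Minimum gap between planted loci in bp (default 2000),
#'   so transcripts of different loci never overlap.
#' @return A classed list of validated simulation parameters.
#' @export
sim_spec <- function(seed = 1,
                     n_chromosomes = 3,
                     chrom_length = 2e6,
                     n_coding = 500,
                     n_lnc = 500,
                     orientation_mix = c(enclosed = 0.282, divergent = 0.108,
                                         convergent = 0.070, none = 0.540),
                     coding_pair_prob = 0.2,
                     pair_overlap_range = c(25, 2000),
                     tx_length_range = c(500, 3000),
                     accessions = c("Nip", "BJ89", "BJ278"),
                     n_replicates = 3,
                     class_mix = c(concordant_up = 0.2, concordant_down = 0.2,
                                   discordant = 0.2, null = 0.4),
                     planted_effects = list(concordant_up = c(3, 3),
                                            concordant_down = c(-3, -3),
                                            discordant = c(3, -3),
                                            null = c(0, 0)),
                     noise_sd = 0.25,
                     baseline_logfpkm_range = c(3, 8),
                     locus_gap = 2000) {
  if (abs(sum(orientation_mix) - 1) > 1e-8) {
    stop("orientation_mix probabilities must sum to 1")
  }
  if (!setequal(names(orientation_mix),
                c("enclosed", "divergent", "convergent", "none"))) {
    stop("orientation_mix needs names enclosed/divergent/convergent/none")
  }
  if (abs(sum(class_mix) - 1) > 1e-8) {
    stop("class_mix probabilities must sum to 1")
  }
  if (pair_overlap_range[1] < 1 || pair_overlap_range[2] > chrom_length) {
    stop("pair_overlap_range must lie within [1, chrom_length]")
  }
  if (tx_length_range[1] < 500) {
    stop("tx_length_range minimum below 500 bp would break planted-pair geometry")
  }
  structure(list(seed = seed, n_chromosomes = n_chromosomes,
                 chrom_length = chrom_length, n_coding = n_coding,
                 n_lnc = n_lnc, orientation_mix = orientation_mix,
                 coding_pair_prob = coding_pair_prob,
                 pair_overlap_range = pair_overlap_range,
                 tx_length_range = tx_length_range, accessions = accessions,
                 n_replicates = n_replicates, class_mix = class_mix,
                 planted_effects = planted_effects, noise_sd = noise_sd,
                 baseline_logfpkm_range = baseline_logfpkm_range,
                 locus_gap = locus_gap),
            class = "sim_spec")
}

#' Simulate an annotation and expression matrix with planted ground truth
#'
#' Lays planted loci (antisense pairs and singleton transcripts) along the
#' synthetic genome with inter-locus gaps, so every overlap in the output
#' is intentional. Pair geometry is solved directly from the orientation
#' definitions (see [classify_orientation()]), guaranteeing planted labels
#' are correct by construction; half the loci are mirror-reflected with
#' flipped strands, which preserves orientation classes while varying which
#' strand the coding member sits on. Expression is baseline + planted
#' drought effect (in the pair's responsive accessions) + Normal replicate
#' noise, all on the log2 scale, exponentiated to FPKM.
#'
#' @param spec A [sim_spec()] object.
#' @param dir Optional directory; when given, the annotation (`ann.gtf`),
#'   expression (`fpkm.tsv`), metadata (`meta.tsv`), coding overrides
#'   (`coding.tsv`) and ground-truth tables are also written there as
#'   plain-text files.
#' @return A list with `transcripts` (annotation table, `coding` left
#'   `"unknown"`), `expr` ([nat_expr()]), `coding` (override data.frame),
#'   and `truth`: `transcripts` (`transcript_id`, `category`), `pairs`
#'   (`pair_id`, member ids, `orientation`, `coding_class`,
#'   `response_class`, `responsive_accessions`) and `response` (long
#'   `pair_id` x `accession` planted status).
#' @export
simulate_nat_data <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)

  rint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L
  pick <- function(x, prob) x[sample.int(length(x), 1L, prob = prob)]

  # --- allocate transcripts to loci -----------------------------------------
  lnc_ids <- sprintf("LNC%04d", seq_len(spec$n_lnc))
  cod_ids <- sprintf("COD%04d", seq_len(spec$n_coding))
  lnc_ori <- if (spec$n_lnc > 0) {
    sample(names(spec$orientation_mix), spec$n_lnc, replace = TRUE,
           prob = spec$orientation_mix)
  } else character(0)
  paired_lnc <- which(lnc_ori != "none")
  if (length(paired_lnc) > spec$n_coding) {
    stop("not enough coding transcripts to host the planted antisense pairs; ",
         "raise n_coding or the 'none' share of orientation_mix")
  }
  loci <- list()
  for (k in seq_along(paired_lnc)) {
    loci[[length(loci) + 1L]] <- list(
      type = "cn_pair", orientation = lnc_ori[paired_lnc[k]],
      sense = cod_ids[k], anti = lnc_ids[paired_lnc[k]])
  }
  used_cod <- length(paired_lnc)
  n_rem <- spec$n_coding - used_cod
  pair_ori_mix <- spec$orientation_mix[c("enclosed", "divergent", "convergent")]
  n_cc <- if (sum(pair_ori_mix) > 0) {
    floor(n_rem * spec$coding_pair_prob / 2)
  } else 0L
  for (k in seq_len(n_cc)) {
    loci[[length(loci) + 1L]] <- list(
      type = "cc_pair",
      orientation = pick(names(pair_ori_mix), pair_ori_mix),
      sense = cod_ids[used_cod + 2L * k - 1L],
      anti = cod_ids[used_cod + 2L * k])
  }
  single_cod <- cod_ids[seq_len(spec$n_coding) > used_cod + 2L * n_cc]
  for (id in single_cod) {
    loci[[length(loci) + 1L]] <- list(type = "single_coding", id = id)
  }
  for (k in setdiff(seq_len(spec$n_lnc), paired_lnc)) {
    loci[[length(loci) + 1L]] <- list(type = "single_lnc", id = lnc_ids[k])
  }
  if (length(loci) > 1L) loci <- loci[sample.int(length(loci))]

  # --- geometry -------------------------------------------------------------
  olo <- spec$pair_overlap_range[1]
  ohi <- spec$pair_overlap_range[2]
  llo <- spec$tx_length_range[1]
  lhi <- spec$tx_length_range[2]

  pair_geometry <- function(orientation, lnc_anti) {
    Ls <- rint(llo, lhi)
    s1 <- 1L
    s2 <- Ls
    if (orientation == "enclosed") {
      # a lncRNA enclosed in the coding span *is* the overlap, so keep it
      # >= 200 nt; coding members have no such floor but share the code path
      anti_inside <- isTRUE(sample(c(TRUE, FALSE), 1L))
      if (anti_inside) {
        olen <- rint(max(if (lnc_anti) 200L else olo, olo), min(Ls - 2L, ohi))
        off <- rint(1L, Ls - olen - 1L)
        a1 <- s1 + off
        a2 <- a1 + olen - 1L
      } else {
        a1 <- s1 - rint(50L, 400L)
        a2 <- s2 + rint(50L, 400L)
      }
    } else if (orientation == "divergent") {
      olen <- rint(olo, min(Ls - 1L, ohi))
      a2 <- s1 + olen - 1L
      a1 <- a2 - (olen + rint(175L, 800L)) + 1L
    } else { # convergent
      olen <- rint(olo, min(Ls - 1L, ohi))
      a1 <- s2 - olen + 1L
      a2 <- s2 + rint(175L, 800L)
    }
    list(s1 = s1, s2 = s2, a1 = a1, a2 = a2)
  }

  tx <- list()
  add_tx <- function(id, chrom, start, end, strand, coding, n_exons = 1L) {
    if (n_exons == 2L) {
      len <- end - start + 1L
      l1 <- max(1L, floor(len * 0.4))
      gap <- max(1L, floor(len * 0.1))
      exons <- data.frame(start = c(start, start + l1 + gap),
                          end = c(start + l1 - 1L, end))
    } else {
      exons <- data.frame(start = start, end = end)
    }
    tx[[length(tx) + 1L]] <<- list(id = id, chrom = chrom, start = start,
                                   end = end, strand = strand,
                                   coding = coding, exons = exons)
  }

  pairs_truth <- list()
  chrom_i <- 1L
  cursor <- 1L
  chrom_names <- sprintf("chr%02d", seq_len(spec$n_chromosomes))
  advance <- function(width) {
    while (cursor + width > spec$chrom_length) {
      chrom_i <<- chrom_i + 1L
      cursor <<- 1L
      if (chrom_i > spec$n_chromosomes) {
        stop("ran out of genome while placing loci; increase chrom_length")
      }
    }
  }

  for (locus in loci) {
    if (locus$type %in% c("cn_pair", "cc_pair")) {
      g <- pair_geometry(locus$orientation, locus$type == "cn_pair")
      lo <- min(g$s1, g$a1)
      hi <- max(g$s2, g$a2)
      width <- hi - lo + 1L
      advance(width)
      shift <- cursor - lo
      s1 <- g$s1 + shift; s2 <- g$s2 + shift
      a1 <- g$a1 + shift; a2 <- g$a2 + shift
      flip <- isTRUE(sample(c(TRUE, FALSE), 1L))
      if (flip) {
        # mirror within the locus and swap strands: preserves the
        # orientation class while varying the coding member's strand
        m <- cursor + (cursor + width - 1L)
        tmp <- c(m - s2, m - s1); s1 <- tmp[1L]; s2 <- tmp[2L]
        tmp <- c(m - a2, m - a1); a1 <- tmp[1L]; a2 <- tmp[2L]
      }
      s_strand <- if (flip) "-" else "+"
      a_strand <- if (flip) "+" else "-"
      chrom <- chrom_names[chrom_i]
      add_tx(locus$sense, chrom, s1, s2, s_strand,
             "coding")
      add_tx(locus$anti, chrom, a1, a2, a_strand,
             if (locus$type == "cn_pair") "noncoding" else "coding")
      # scan_pairs reports the coding member as sense for coding-noncoding
      # pairs and the plus-strand member for coding-coding pairs
      if (locus$type == "cn_pair" || s_strand == "+") {
        sense_id <- locus$sense; anti_id <- locus$anti
      } else {
        sense_id <- locus$anti; anti_id <- locus$sense
      }
      pairs_truth[[length(pairs_truth) + 1L]] <- list(
        sense_id = sense_id, antisense_id = anti_id,
        orientation = locus$orientation,
        coding_class = if (locus$type == "cn_pair") "coding_noncoding"
                       else "coding_coding")
      cursor <- cursor + width + rint(spec$locus_gap, 2L * spec$locus_gap)
    } else {
      len <- rint(llo, lhi)
      advance(len)
      strand <- pick(c("+", "-"), c(0.5, 0.5))
      coding <- locus$type == "single_coding"
      add_tx(locus$id, chrom_names[chrom_i], cursor, cursor + len - 1L,
             strand, if (coding) "coding" else "noncoding",
             n_exons = if (coding) 2L else 1L)
      cursor <- cursor + len + rint(spec$locus_gap, 2L * spec$locus_gap)
    }
  }

  transcripts <- data.frame(
    transcript_id = vapply(tx, `[[`, "", "id"),
    gene_id = paste0("G", vapply(tx, `[[`, "", "id")),
    chrom = vapply(tx, `[[`, "", "chrom"),
    start = vapply(tx, function(t) as.numeric(t$start), 0),
    end = vapply(tx, function(t) as.numeric(t$end), 0),
    strand = vapply(tx, `[[`, "", "strand"),
    coding = "unknown",
    stringsAsFactors = FALSE
  )
  transcripts$exons <- lapply(tx, `[[`, "exons")
  ord <- order(transcripts$chrom, transcripts$start,
               transcripts$transcript_id)
  transcripts <- transcripts[ord, , drop = FALSE]
  rownames(transcripts) <- NULL

  coding_tab <- data.frame(
    transcript_id = vapply(tx, `[[`, "", "id"),
    coding = vapply(tx, `[[`, "", "coding"),
    stringsAsFactors = FALSE
  )
  coding_tab <- coding_tab[order(coding_tab$transcript_id), , drop = FALSE]
  rownames(coding_tab) <- NULL

  # --- planted response classes --------------------------------------------
  n_pairs <- length(pairs_truth)
  n_acc <- length(spec$accessions)
  response_class <- if (n_pairs > 0) {
    sample(names(spec$class_mix), n_pairs, replace = TRUE,
           prob = spec$class_mix)
  } else character(0)
  responsive <- matrix(FALSE, nrow = n_pairs, ncol = n_acc,
                       dimnames = list(NULL, spec$accessions))
  for (k in seq_len(n_pairs)) {
    if (response_class[k] == "null") next
    repeat {
      draw <- stats::runif(n_acc) < 0.5
      if (any(draw)) break
    }
    responsive[k, ] <- draw
  }

  pairs_df <- data.frame(
    pair_id = vapply(pairs_truth, function(p)
      paste(p$sense_id, p$antisense_id, sep = "|"), ""),
    sense_id = vapply(pairs_truth, `[[`, "", "sense_id"),
    antisense_id = vapply(pairs_truth, `[[`, "", "antisense_id"),
    orientation = vapply(pairs_truth, `[[`, "", "orientation"),
    coding_class = vapply(pairs_truth, `[[`, "", "coding_class"),
    response_class = response_class,
    responsive_accessions = vapply(seq_len(n_pairs), function(k)
      paste(spec$accessions[responsive[k, ]], collapse = ","), ""),
    stringsAsFactors = FALSE
  )

  response_df <- do.call(rbind, lapply(seq_len(n_pairs), function(k) {
    data.frame(pair_id = pairs_df$pair_id[k], accession = spec$accessions,
               status = ifelse(responsive[k, ], response_class[k],
                               "not_responsive"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(response_df)) {
    response_df <- data.frame(pair_id = character(0),
                              accession = character(0),
                              status = character(0), stringsAsFactors = FALSE)
  }

  # --- expression -----------------------------------------------------------
  all_ids <- transcripts$transcript_id
  n_tx <- length(all_ids)
  baseline <- stats::runif(n_tx, spec$baseline_logfpkm_range[1],
                           spec$baseline_logfpkm_range[2])
  names(baseline) <- all_ids
  effect <- matrix(0, nrow = n_tx, ncol = n_acc,
                   dimnames = list(all_ids, spec$accessions))
  for (k in seq_len(n_pairs)) {
    eff <- spec$planted_effects[[response_class[k]]]
    acc <- spec$accessions[responsive[k, ]]
    effect[pairs_df$sense_id[k], acc] <-
      effect[pairs_df$sense_id[k], acc] + eff[1]
    effect[pairs_df$antisense_id[k], acc] <-
      effect[pairs_df$antisense_id[k], acc] + eff[2]
  }

  meta <- expand.grid(replicate = seq_len(spec$n_replicates),
                      condition = c("control", "drought"),
                      accession = spec$accessions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- meta[, c("accession", "condition", "replicate")]
  meta$sample_id <- paste(meta$accession, meta$condition, meta$replicate,
                          sep = "_")
  values <- matrix(0, nrow = n_tx, ncol = nrow(meta),
                   dimnames = list(all_ids, meta$sample_id))
  for (s in seq_len(nrow(meta))) {
    mu <- baseline +
      (meta$condition[s] == "drought") * effect[, meta$accession[s]]
    values[, s] <- 2^(mu + stats::rnorm(n_tx, 0, spec$noise_sd))
  }
  expr <- nat_expr(values, meta)

  truth_tx <- data.frame(
    transcript_id = coding_tab$transcript_id,
    category = ifelse(coding_tab$coding == "coding", "mRNA",
                      ifelse(coding_tab$transcript_id %in%
                               c(pairs_df$sense_id, pairs_df$antisense_id),
                             "lncNAT", "lincRNA")),
    stringsAsFactors = FALSE
  )

  out <- list(transcripts = transcripts, expr = expr, coding = coding_tab,
              truth = list(transcripts = truth_tx, pairs = pairs_df,
                           response = response_df),
              spec = spec)
  if (!is.null(dir)) write_simulation(out, dir)
  out
}

write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_gtf(sim$transcripts, file.path(dir, "ann.gtf"))
  fpkm <- data.frame(transcript_id = rownames(sim$expr$values),
                     sim$expr$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
  tsv(fpkm, "fpkm.tsv")
  tsv(sim$expr$meta, "meta.tsv")
  tsv(sim$coding, "coding.tsv")
  tsv(sim$truth$transcripts, "truth_transcripts.tsv")
  tsv(sim$truth$pairs, "truth_pairs.tsv")
  tsv(sim$truth$response, "truth_response.tsv")
  invisible(dir)
}
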