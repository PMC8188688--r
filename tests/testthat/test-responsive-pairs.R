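test_that("fold change uses pseudocounted condition means", {
  vals <- rbind(T1 = c(1, 1, 1, 8, 8, 8),
                T2 = c(5, 5, 5, 5, 5, 5))
  ex <- toy_expr(vals)
  de <- call_de(ex, "A")
  expect_equal(de$fc[de$transcript_id == "T1"], 4.5) # (8+1)/(1+1)
  expect_equal(de$log2fc[de$transcript_id == "T2"], 0)
  expect_equal(de$call[de$transcript_id == "T2"], "none")
  expect_equal(de$direction[de$transcript_id == "T2"], "none")

  expect_error(call_de(ex, "missing"), "absent")
  # one surviving control replicate is not enough for a variance estimate
  short <- nat_expr(ex$values[, -(1:2), drop = FALSE], ex$meta[-(1:2), ])
  expect_error(call_de(short, "A"), "replicates")
})

test_that("HDEG calls are a subset of DEG calls on noisy input", {
  withr::with_seed(5, {
    for (rep in 1:5) {
      vals <- matrix(2^rnorm(600, 5, 2), nrow = 100)
      rownames(vals) <- sprintf("T%03d", 1:100)
      ex <- toy_expr(vals)
      de <- call_de(ex, "A")
      hd <- de$transcript_id[de$call == "HDEG"]
      dg <- de$transcript_id[de$call %in% c("DEG", "HDEG")]
      expect_true(all(hd %in% dg))
      # threshold coherence on the same q: relaxing fc from 4 to 2 only adds
      deg4 <- call_de(ex, "A", fc_threshold = 4)
      expect_true(all(deg4$transcript_id[deg4$call != "none"] %in% dg))
      # BH q-values dominate p-values monotonically
      expect_true(all(de$q >= de$p - 1e-12))
      o <- order(de$p)
      expect_true(all(diff(de$q[o]) >= -1e-12))
    }
  })
})

test_that("pair response classification needs both members differential", {
  de <- data.frame(
    transcript_id = c("S", "A1", "A2", "A3"),
    accession = "Nip",
    call = c("DEG", "DEG", "DEG", "none"),
    direction = c("up", "up", "down", "none"),
    stringsAsFactors = FALSE
  )
  pairs <- data.frame(
    pair_id = c("S|A1", "S|A2", "S|A3"),
    sense_id = "S", antisense_id = c("A1", "A2", "A3"),
    stringsAsFactors = FALSE
  )
  got <- classify_pair_response(pairs, de)
  expect_equal(got$status, c("concordant_up", "discordant", "not_responsive"))

  de_dn <- de
  de_dn$direction[de_dn$transcript_id == "S"] <- "down"
  expect_equal(classify_pair_response(pairs, de_dn)$status,
               c("discordant", "concordant_down", "not_responsive"))

  expect_error(
    classify_pair_response(data.frame(pair_id = "S|X", sense_id = "S",
                                      antisense_id = "X"), de),
    "X.*Nip")
})

test_that("every doubly-differential pair gets exactly one response class", {
  dirs <- c("up", "down")
  for (d1 in dirs) for (d2 in dirs) {
    de <- data.frame(transcript_id = c("S", "A"), accession = "x",
                     call = "DEG", direction = c(d1, d2),
                     stringsAsFactors = FALSE)
    pairs <- data.frame(pair_id = "S|A", sense_id = "S", antisense_id = "A")
    st <- classify_pair_response(pairs, de)$status
    expect_true(st %in% c("concordant_up", "concordant_down", "discordant"))
    expect_equal(st == "discordant", d1 != d2)
  }
})

test_that("venn partition reproduces counts, union and marginals", {
  acc <- c("Nip", "BJ89", "BJ278")
  vp <- venn_partition(list(Nip = "x", BJ89 = "x", BJ278 = "x"), acc)
  expect_equal(unname(vp$region_counts["Nip&BJ89&BJ278"]), 1L)
  expect_equal(vp$union, 1L)

  withr::with_seed(99, {
    for (rep in 1:20) {
      membership <- lapply(stats::setNames(acc, acc), function(a) {
        sample(sprintf("i%02d", 1:40), sample(0:30, 1))
      })
      vp <- venn_partition(membership, acc)
      expect_equal(sum(vp$region_counts), vp$union)
      expect_equal(vp$union, length(unique(unlist(membership))))
      # each marginal is the sum of its four regions
      for (a in acc) {
        in_a <- grepl(paste0("(^|&)", a, "(&|$)"), names(vp$region_counts)) |
          names(vp$region_counts) == paste0(a, "_only")
        expect_equal(sum(vp$region_counts[in_a]),
                     unname(vp$marginals[a]))
      }
    }
  })

  expect_error(venn_partition(list(Other = "x"), acc), "unknown accession")
  # expand_venn_counts() is a right inverse of venn_partition()
  counts <- c("Nip_only" = 3L, "Nip&BJ89" = 2L, "Nip&BJ89&BJ278" = 5L)
  vp2 <- venn_partition(expand_venn_counts(counts, acc), acc)
  expect_equal(vp2$region_counts[names(counts)], counts)
  expect_equal(vp2$union, 10L)
})

test_that("expression presence uses per-condition means inclusively", {
  vals <- rbind(T0 = rep(0, 6),
                T1 = c(0, 0, 0, 0.25, 0.25, 0.1),
                T2 = c(0.1, 0.1, 0.1, 0, 0, 0))
  ex <- toy_expr(vals)
  got <- expressed_in(ex, c("T0", "T1", "T2"), "A")
  expect_equal(unname(got), c(FALSE, TRUE, TRUE))
  expect_error(expressed_in(ex, "T9", "A"), "T9")
  expect_error(expressed_in(ex, "T1", "Z"), "unknown accession")
})

test_that("GO linkage splits the worked-example pairs 9 to 1 by accession", {
  fx <- table1_fixture()
  ann <- table1_annotation()
  pairs <- scan_pairs(ann)
  gl <- go_link(pairs, fx$gene2go, membership = fx$membership)
  expect_equal(nrow(gl), 10L)
  acc_sets <- strsplit(gl$accessions, ",", fixed = TRUE)
  nivara_only <- !vapply(acc_sets, function(a) "Nip" %in% a, TRUE)
  expect_equal(sum(nivara_only), 9L)
  all_three <- vapply(acc_sets, function(a) {
    setequal(a, c("Nip", "BJ89", "BJ278"))
  }, TRUE)
  expect_equal(sum(all_three), 1L)
  expect_equal(gl$chrom[all_three], "chr08")

  expect_equal(nrow(go_link(pairs, fx$gene2go, stress_terms = character(0))),
               0L)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # N=20, K=5, n=5, k=5: only one of the C(20,5) draws contains all five
  gene2go <- data.frame(gene_id = sprintf("g%02d", 1:5), go_id = "GO:X")
  pop <- sprintf("g%02d", 1:20)
  out <- enrich_hypergeom(sprintf("g%02d", 1:5), pop, gene2go)
  expect_equal(out$p, 1 / choose(20, 5))
  expect_equal(out$k, 5L)
  expect_equal(out$K, 5L)

  # study = population makes every term certain
  g2g <- data.frame(gene_id = c("a", "b", "c"), go_id = "GO:Y")
  out2 <- enrich_hypergeom(c("a", "b", "c", "d"), c("a", "b", "c", "d"), g2g)
  expect_equal(out2$p, 1)

  # zero-annotation terms never appear
  g2g3 <- data.frame(gene_id = c("a", "z"), go_id = c("GO:A", "GO:B"))
  out3 <- enrich_hypergeom("a", c("a", "b", "z"), g2g3)
  expect_equal(out3$go_id, "GO:A")

  expect_error(enrich_hypergeom("q", c("a", "b"), g2g3), "outside population")

  withr::with_seed(12, {
    for (rep in 1:25) {
      N <- sample(5:20, 1)
      pop <- sprintf("p%02d", seq_len(N))
      n <- sample.int(N, 1)
      study <- sample(pop, n)
      K <- sample.int(N, 1)
      g2g <- data.frame(gene_id = sample(pop, K), go_id = "GO:T")
      out <- enrich_hypergeom(study, pop, g2g)
      k <- length(intersect(study, g2g$gene_id))
      if (k == 0) {
        expect_equal(nrow(out), 0L)
      } else {
        expect_equal(out$p, oracle_hyper_tail(k, K, n, N), tolerance = 1e-12)
      }
    }
  })
})
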