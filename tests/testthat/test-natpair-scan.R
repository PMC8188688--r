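tx_row <- function(id, chrom, start, end, strand, coding = "coding") {
  out <- data.frame(transcript_id = id, gene_id = paste0("G", id),
                    chrom = chrom, start = start, end = end, strand = strand,
                    coding = coding, stringsAsFactors = FALSE)
  out$exons <- list(data.frame(start = start, end = end))
  out
}

test_that("span overlap arithmetic matches position counting", {
  # coordinates of the chr01 worked-example pair
  ov <- span_overlap(8546015, 8546972, 8546065, 8546869)
  expect_equal(ov$overlap_len, 805)
  expect_equal(oracle_overlap(8546015, 8546972, 8546065, 8546869), 805)
  expect_equal(ov$overlap_start, 8546065)
  expect_equal(ov$overlap_end, 8546869)

  expect_equal(span_overlap(100, 200, 201, 300)$overlap_len, 0)
  expect_equal(span_overlap(100, 200, 200, 300)$overlap_len, 1)
  expect_error(span_overlap(1, 10, 5, 20, "chr1", "chr2"),
               "different chromosomes")
})

test_that("orientation classes match the end-membership oracle", {
  p <- function(s, e) list(start = s, end = e, strand = "+")
  m <- function(s, e) list(start = s, end = e, strand = "-")
  # worked-example chr03 pair: antisense fully inside the sense span
  expect_equal(classify_orientation(p(16407687, 16410061),
                                    m(16407699, 16410007)), "enclosed")
  expect_equal(classify_orientation(p(100, 300), m(50, 180)), "divergent")
  expect_equal(classify_orientation(p(100, 300), m(250, 400)), "convergent")
  # identical spans are mutual containment
  expect_equal(classify_orientation(p(100, 300), m(100, 300)), "enclosed")

  expect_error(classify_orientation(p(100, 300), p(150, 350)),
               "opposite-strand")
  expect_error(classify_orientation(p(100, 200), m(300, 400)), "overlapping")

  withr::with_seed(7, {
    for (i in 1:200) {
      p1 <- sample.int(500, 1); p2 <- p1 + sample.int(300, 1)
      repeat {
        m1 <- sample.int(800, 1); m2 <- m1 + sample.int(300, 1)
        if (max(p1, m1) <= min(p2, m2)) break
      }
      got <- classify_orientation(p(p1, p2), m(m1, m2))
      expect_equal(got, oracle_orientation(p1, p2, m1, m2),
                   info = paste(p1, p2, m1, m2))
    }
  })
})

test_that("orientation symmetries: mirroring preserves, strand swap reverses", {
  L <- 2000
  mirror_flip <- function(t) {
    # reflect the locus and flip strands: the same biological configuration
    # seen in a mirror, so head-to-head stays head-to-head
    s <- L - t$end; e <- L - t$start
    t$start <- s; t$end <- e
    t$strand <- if (t$strand == "+") "-" else "+"
    t
  }
  swap_strands <- function(t) {
    # reverse both transcripts in place: 5' ends become 3' ends, so
    # head-to-head becomes tail-to-tail
    t$strand <- if (t$strand == "+") "-" else "+"
    t
  }
  withr::with_seed(8, {
    for (i in 1:100) {
      a <- tx_row("A", "chr1", 100 + sample.int(200, 1),
                  500 + sample.int(200, 1), "+")
      b <- tx_row("B", "chr1", 100 + sample.int(200, 1),
                  500 + sample.int(200, 1), "-", coding = "noncoding")
      if (span_overlap(a$start, a$end, b$start, b$end)$overlap_len < 1) next
      before <- classify_orientation(a[1, ], b[1, ])
      mirrored <- classify_orientation(mirror_flip(a[1, ]),
                                       mirror_flip(b[1, ]))
      expect_equal(mirrored, before)
      swapped <- classify_orientation(swap_strands(a[1, ]),
                                      swap_strands(b[1, ]))
      expect_equal(swapped,
                   c(enclosed = "enclosed", divergent = "convergent",
                     convergent = "divergent")[[before]])
    }
  })
})

test_that("the pair scan respects the minimum-overlap boundary", {
  a <- tx_row("A", "chr1", 100, 1000, "+")
  b <- tx_row("B", "chr1", 977, 2000, "-", coding = "noncoding") # 24 bp
  both <- rbind(a, b)
  expect_equal(nrow(scan_pairs(both, min_overlap = 25)), 0L)
  got <- scan_pairs(both, min_overlap = 24)
  expect_equal(nrow(got), 1L)
  expect_equal(got$overlap_len, 24)
  expect_equal(got$sense_id, "A")
  expect_equal(got$coding_class, "coding_noncoding")

  # same-strand overlap never pairs
  c2 <- tx_row("C", "chr1", 500, 1500, "+")
  expect_equal(nrow(scan_pairs(rbind(a, c2))), 0L)
  # empty and unresolved inputs
  expect_equal(nrow(scan_pairs(a)), 0L)
  expect_error(scan_pairs(rbind(a, tx_row("U", "chr1", 1, 999, "-",
                                          coding = "unknown"))),
               "assign_coding")
})

test_that("scan output equals the brute-force all-pairs oracle", {
  withr::with_seed(33, {
    for (rep in 1:30) {
      tx <- random_annotation(sample(20:150, 1))
      got <- scan_pairs(tx, min_overlap = 25)
      want <- oracle_scan(tx, min_overlap = 25)
      got <- got[order(got$sense_id, got$antisense_id), ]
      expect_equal(got$sense_id, want$sense_id)
      expect_equal(got$antisense_id, want$antisense_id)
      expect_equal(got$overlap_len, want$overlap_len)
      # no duplicate unordered pairs
      key <- apply(cbind(got$sense_id, got$antisense_id), 1,
                   function(r) paste(sort(r), collapse = "|"))
      expect_false(anyDuplicated(key) > 0)
    }
  })
})

test_that("scan output is invariant under input permutation", {
  withr::with_seed(44, {
    tx <- random_annotation(80)
    ref <- scan_pairs(tx)
    for (rep in 1:5) {
      perm <- scan_pairs(tx[sample.int(nrow(tx)), ])
      expect_equal(perm, ref)
    }
  })
})

test_that("exon-level overlap mode ignores intronic-only span overlap", {
  a <- data.frame(transcript_id = "A", gene_id = "GA", chrom = "chr1",
                  start = 100, end = 1100, strand = "+", coding = "coding",
                  stringsAsFactors = FALSE)
  a$exons <- list(data.frame(start = c(100, 1000), end = c(200, 1100)))
  b <- tx_row("B", "chr1", 300, 900, "-", coding = "noncoding")
  both <- rbind(a, b)
  expect_equal(nrow(scan_pairs(both, overlap_mode = "span")), 1L)
  expect_equal(nrow(scan_pairs(both, overlap_mode = "exon")), 0L)

  # an exon poking into the partner counts its exonic bases
  c2 <- tx_row("C", "chr1", 150, 180, "-", coding = "noncoding") # 31 bp in exon 1
  expect_equal(nrow(scan_pairs(rbind(a, c2), overlap_mode = "exon")), 1L)
})
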