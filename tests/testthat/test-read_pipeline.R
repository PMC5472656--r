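mk_pair <- function(bc1, bc2, primers, insert1, insert2, qual = "I") {
  s1 <- paste0(bc1, primers$forward, insert1)
  s2 <- paste0(bc2, sub("Y", "T", primers$reverse), insert2)
  data.frame(id = "r1", seq1 = s1, qual1 = strrep(qual, nchar(s1)),
             seq2 = s2, qual2 = strrep(qual, nchar(s2)),
             stringsAsFactors = FALSE)
}

test_that("demultiplexing assigns on dual barcode + primer and strips prefixes", {
  set.seed(1)
  p <- sla_primers("short")
  bcs <- c(S1 = "ACGTAC", S2 = "GGTTCC")
  ok <- mk_pair("ACGTAC", "ACGTAC", p, "AAACCC", "GGGTTT")
  res <- demultiplex(ok, bcs, p)
  expect_equal(nrow(res$assigned), 1L)
  expect_equal(res$assigned$sample, "S1")
  expect_equal(res$assigned$seq1, "AAACCC")   # barcode+primer stripped
  expect_equal(res$assigned$seq2, "GGGTTT")
  expect_equal(nchar(res$assigned$qual1), 6L)

  # mates disagree on the barcode
  bad <- mk_pair("ACGTAC", "TTTTTT", p, "AAACCC", "GGGTTT")
  res2 <- demultiplex(bad, bcs, p)
  expect_equal(unname(res2$rejected["barcode_conflict"]), 1L)
  # no recognisable barcode at all
  none <- mk_pair("CCCCCC", "CCCCCC", p, "AAA", "TTT")
  expect_equal(unname(demultiplex(none, bcs, p)$rejected["no_barcode"]), 1L)
  # barcode fine, primer broken on mate 1
  noprim <- mk_pair("ACGTAC", "ACGTAC", p, "AAA", "TTT")
  noprim$seq1 <- paste0("ACGTAC", "TTTTTTTTTTTTTTTTTTT", "AAA")
  expect_equal(unname(demultiplex(noprim, bcs, p)$rejected["no_primer"]), 1L)
  # conservation over a batch
  batch <- rbind(ok, bad, none, noprim)
  res4 <- demultiplex(batch, bcs, p)
  expect_equal(nrow(res4$assigned) + sum(res4$rejected), nrow(batch))
})

test_that("reverse primer degeneracy is honoured during demultiplexing", {
  p <- sla_primers("short")
  bcs <- c(S1 = "ACGTAC")
  for (base in c("C", "T")) {  # Y = {C,T}
    pr <- mk_pair("ACGTAC", "ACGTAC", p, "AAACCC", "GGGTTT")
    pr$seq2 <- paste0("ACGTAC", sub("Y", base, p$reverse), "GGGTTT")
    expect_equal(nrow(demultiplex(pr, bcs, p)$assigned), 1L)
  }
})

test_that("quality trimming removes low-quality ends only", {
  q <- function(v) rawToChar(as.raw(v + 33L))
  r <- quality_trim("AACGTT", q(c(5, 12, 20, 30, 20, 12)), q_min = 17)
  expect_equal(r$seqs, "CGT")    # positions 3-5
  expect_equal(r$quals, q(c(20, 30, 20)))
  expect_false(r$discarded)
  # all above threshold: identity
  r2 <- quality_trim("ACGT", q(c(17, 20, 30, 17)))
  expect_equal(r2$seqs, "ACGT")
  # all below: discarded
  r3 <- quality_trim("ACGT", q(c(5, 5, 5, 5)))
  expect_true(r3$discarded)
  expect_equal(r3$seqs, "")
  # interior low-quality bases retained
  r4 <- quality_trim("ACGTA", q(c(30, 2, 2, 2, 30)))
  expect_equal(r4$seqs, "ACGTA")
  # never lengthens
  set.seed(2)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    s <- rdna(n)
    qq <- q(sample(2:40, n, TRUE))
    expect_lte(nchar(quality_trim(s, qq)$seqs), n)
  }
})

test_that("Phred/accuracy correspondence follows the closed form", {
  expect_equal(phred_from_accuracy(0.9), 10L)
  expect_equal(phred_from_accuracy(0.9999), 40L)
  expect_error(phred_from_accuracy(0), "strictly")
  expect_error(phred_from_accuracy(1), "strictly")
})

test_that("pair merging honours the 80%/35-nt admissibility boundary", {
  set.seed(3)
  insert <- rdna(120)
  l1 <- 80
  seq1 <- substr(insert, 1, l1)
  s2_start <- l1 - 35 + 1  # overlap exactly 35
  seq2_sense <- substr(insert, s2_start, 120)
  mutate_n <- function(seq, region, n) {
    pos <- sample(region, n)
    for (p in pos) seq <- set_base(seq, p, other_base(substr(seq, p, p)))
    seq
  }
  # 7 mismatches in the 35-nt overlap: 28/35 = 80% -> merged
  seq1_7 <- mutate_n(seq1, s2_start:l1, 7)
  m7 <- merge_pairs(seq1_7, strrep("I", l1), rc(seq2_sense), strrep("#", 120 - s2_start + 1))
  expect_false(is.null(m7))
  expect_equal(m7$overlap_len, 35L)
  expect_equal(m7$mismatches_in_overlap, 7L)
  # consensus takes the higher-quality base: mate 2 had lower quality ("#")
  expect_equal(m7$sequence, paste0(substr(seq1_7, 1, l1), substr(insert, l1 + 1, 120)))
  # 8 mismatches: 27/35 = 77.1% -> unjoined
  seq1_8 <- mutate_n(seq1, s2_start:l1, 8)
  expect_null(merge_pairs(seq1_8, strrep("I", l1), rc(seq2_sense),
                          strrep("#", 120 - s2_start + 1)))
})

test_that("noise-free merging reconstructs the insert and its length arithmetic", {
  set.seed(4)
  for (i in 1:10) {
    insert <- rdna(sample(90:200, 1))
    L <- nchar(insert)
    l1 <- sample(60:(L - 10), 1)
    start2 <- sample(2:(l1 - 40), 1)
    seq1 <- substr(insert, 1, l1)
    seq2 <- rc(substr(insert, start2, L))
    m <- merge_pairs(seq1, strrep("I", nchar(seq1)), seq2,
                     strrep("I", nchar(seq2)))
    expect_equal(m$sequence, insert)
    expect_equal(nchar(m$sequence),
                 nchar(seq1) + nchar(seq2) - m$overlap_len)
  }
})

test_that("merging agrees with the exhaustive overlap-scoring oracle", {
  set.seed(5)
  for (i in 1:40) {
    insert <- rdna(sample(80:140, 1))
    L <- nchar(insert)
    l1 <- sample(50:(L - 5), 1)
    start2 <- sample(2:max(3, l1 - 30), 1)
    s1 <- substr(insert, 1, l1)
    s2s <- substr(insert, start2, L)
    # sprinkle errors
    n_err <- sample(0:6, 1)
    if (n_err > 0) {
      for (p in sample(nchar(s1), min(n_err, nchar(s1)))) {
        s1 <- set_base(s1, p, other_base(substr(s1, p, p)))
      }
    }
    q1 <- rawToChar(as.raw(sample(35:73, nchar(s1), TRUE)))
    q2 <- rawToChar(as.raw(sample(35:73, nchar(s2s), TRUE)))
    got <- merge_pairs(s1, q1, rc(s2s), q2)
    want <- oracle_merge(s1, q1, rc(s2s), q2)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$sequence, want$sequence)
      expect_equal(got$overlap_len, want$overlap_len)
      expect_equal(got$mismatches_in_overlap, want$mismatches_in_overlap)
      expect_equal(got$shift, want$shift)
    }
  }
})

test_that("dereplication clusters exact sequences with deterministic ordering", {
  s1 <- strrep("ACGT", 10); s2 <- strrep("TGCA", 10)
  cl <- dereplicate(c(rep(s1, 25), rep(s2, 9)), "S")
  expect_equal(cl$size, c(25L, 9L))
  expect_equal(cl$rank, 1:2)
  expect_equal(cl$sequence[1], s1)
  # one-mismatch sequences form separate clusters
  s1b <- set_base(s1, 3, "T")
  cl2 <- dereplicate(c(rep(s1, 5), rep(s1b, 5)))
  expect_equal(nrow(cl2), 2L)
  # equal sizes: lexicographic order
  expect_equal(cl2$sequence, sort(c(s1, s1b)))
  expect_equal(nrow(dereplicate(character(0))), 0L)
})

test_that("size filtering keeps clusters of exactly min_reads and caps at 20", {
  cl <- dereplicate(c(rep("AAA", 25), rep("CCC", 10), rep("GGG", 9)))
  kept <- size_filter(cl)
  expect_equal(kept$size, c(25L, 10L))  # "less than 10" is strict
  set.seed(6)
  many <- data.frame(sample = "S", rank = 1:30,
                     sequence = replicate(30, rdna(20)), size = 30:59)
  expect_equal(nrow(size_filter(many, min_reads = 10, max_clusters = 20)), 20L)
  expect_equal(nrow(size_filter(cl[0, ])), 0L)
})

test_that("two-parent chimeras are flagged; lookalikes are not", {
  set.seed(7)
  A <- rdna(320)
  B <- A
  for (p in c(30, 60, 90, 200, 240, 290)) B <- set_base(B, p, other_base(substr(B, p, p)))
  crossover <- function(k) paste0(substr(A, 1, k), substr(B, k + 1, 320))
  cl <- data.frame(sample = "S", rank = 1:3,
                   sequence = c(A, B, crossover(160)),
                   size = c(100L, 100L, 40L), stringsAsFactors = FALSE)
  out <- detect_chimeras(cl)
  expect_equal(out$chimera, c(FALSE, FALSE, TRUE))
  # candidate identical to a parent is explained without chimerism
  cl2 <- cl; cl2$sequence[3] <- A
  expect_false(detect_chimeras(cl2)$chimera[3])
  # only two diagnostic sites on one side -> not flagged
  B2 <- A
  for (p in c(30, 60, 200, 240, 290)) B2 <- set_base(B2, p, other_base(substr(B2, p, p)))
  cl3 <- data.frame(sample = "S", rank = 1:3,
                    sequence = c(A, B2, paste0(substr(A, 1, 160),
                                               substr(B2, 161, 320))),
                    size = c(100L, 100L, 40L), stringsAsFactors = FALSE)
  expect_false(detect_chimeras(cl3)$chimera[3])
  # parents must be at least twice the candidate's size
  cl4 <- cl; cl4$size <- c(70L, 70L, 40L)
  expect_false(detect_chimeras(cl4)$chimera[3])
})

test_that("artifact filter separates splice variants from other off-size clusters", {
  set.seed(8)
  good <- rdna(282)
  # overlong with stops in all frames (TAA at every 4th position)
  splice <- paste0(substr(good, 1, 141), strrep("TAAA", 35), substr(good, 142, 282))
  # overlong with no stop codon anywhere
  offsize <- strrep("CAC", 140)
  cl <- data.frame(sample = "S", rank = 1:3,
                   sequence = c(good, splice, offsize),
                   size = c(100L, 20L, 50L), stringsAsFactors = FALSE)
  out <- artifact_filter(cl, expected_len = 282)
  expect_equal(out$splice_variant, c(FALSE, TRUE, FALSE))
  expect_equal(out$off_size, c(FALSE, FALSE, TRUE))
  # within tolerance passes
  out2 <- artifact_filter(data.frame(sample = "S", rank = 1L,
                                     sequence = rdna(282 + 15), size = 10L),
                          expected_len = 282, tol = 15)
  expect_false(out2$off_size)
})

test_that("dominant clusters are those above the read-fraction threshold", {
  cl <- data.frame(sample = "S", rank = 1:3, sequence = c("A", "C", "G"),
                   size = c(900L, 80L, 20L), chimera = FALSE,
                   splice_variant = FALSE, off_size = FALSE)
  dom <- dominant_clusters(cl)
  expect_equal(dom$size, c(900L, 80L))   # 20/1000 = 2% < 5%
  cl$chimera[1] <- TRUE
  dom2 <- dominant_clusters(cl)          # fractions recomputed over 100 reads
  expect_equal(dom2$size, c(80L, 20L))
})
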