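test_that("cluster identification: specific, group, novel and unclassified", {
  set.seed(1)
  pool <- make_fixture_library(3, 6, seed = 11)
  idx <- amplicon_index(pool$library, pool$primers)
  a1 <- names(idx$inserts)[1]
  # exact insert -> specific with x/x similarity
  m <- match_cluster(idx$inserts[[a1]], idx)
  expect_equal(m$status, "specific")
  expect_equal(m$match, a1)
  expect_equal(m$similarity, sprintf("%d/%d", pool$insert_len, pool$insert_len))
  # shared insert -> group call with slash-joined sorted names
  lib2 <- allele_library(c("SLA-1*01:01", "SLA-1*02:01"),
                         rep(pool$library$records$sequence[1], 2))
  idx2 <- amplicon_index(lib2, pool$primers)
  g <- match_cluster(idx2$inserts[[1]], idx2)
  expect_equal(g$status, "group")
  expect_equal(g$match, "SLA-1*01:01/SLA-1*02:01")
  # one substitution -> novel candidate, (L-1)/L similarity
  mut <- set_base(idx$inserts[[a1]], 100, other_base(substr(idx$inserts[[a1]], 100, 100)))
  n <- match_cluster(mut, idx)
  expect_equal(n$status, "novel_candidate")
  expect_equal(n$closest_match, a1)
  expect_equal(n$similarity, sprintf("%d/%d", pool$insert_len - 1, pool$insert_len))
  expect_lt(n$identity, 1)
  expect_gte(n$identity, 0.95)
  # garbage -> unclassified below the 95% floor
  u <- match_cluster(rdna(pool$insert_len), idx)
  expect_equal(u$status, "unclassified")
  expect_lt(u$identity, 0.95)
  expect_error(match_cluster("ACGT", list(index = list(), inserts = character(0))),
               "empty")
})

test_that("similarity format reproduces the 604/605 style on long inserts", {
  set.seed(2)
  ref <- rdna(605)
  lib <- allele_library(c("SLA-2*10:01", "SLA-2*06:04"),
                        c(ref, {
                          x <- ref
                          for (p in c(10, 50, 90, 130, 170, 210)) {
                            x <- set_base(x, p, other_base(substr(x, p, p)))
                          }
                          x
                        }))
  q <- set_base(ref, 300, other_base(substr(ref, 300, 300)))
  m <- match_cluster(q, lib)
  expect_equal(m$status, "novel_candidate")
  expect_equal(m$closest_match, "SLA-2*10:01")
  expect_equal(m$similarity, "604/605")
})

test_that("best-hit identity agrees with the brute-force alignment oracle", {
  set.seed(3)
  for (rep in 1:10) {
    n_ref <- sample(3:20, 1)
    refs <- replicate(n_ref, rdna(sample(80:120, 1)))
    lib <- allele_library(sprintf("SLA-1*%02d:01", seq_len(n_ref)), refs)
    # query: mutated/indel-bearing copy of one reference
    base <- sample(refs, 1)
    q <- base
    for (p in sample(nchar(q), sample(1:4, 1))) {
      q <- set_base(q, p, other_base(substr(q, p, p)))
    }
    if (runif(1) < 0.5) q <- paste0(substr(q, 1, 40), substr(q, 42, nchar(q)))
    got <- match_cluster(q, lib)
    want <- max(vapply(refs, function(r) oracle_nw_identity(q, r)$identity,
                       numeric(1)))
    expect_equal(got$identity, want, tolerance = 1e-12)
  }
})

test_that("novel registry collapses recurrent sequences and ranks by support", {
  calls <- data.frame(
    sample = c("S1", "S2", "S3", "S1"),
    rank = c(2L, 3L, 1L, 4L),
    sequence = c("AAAA", "AAAA", "CCCC", "GGGG"),
    status = c("novel_candidate", "novel_candidate", "novel_candidate",
               "specific"),
    match = c(NA, NA, NA, "SLA-1*01:01"),
    closest_match = c("SLA-1*01:01", "SLA-1*01:01", "SLA-2*01:01",
                      "SLA-1*01:01"),
    similarity = c("99/100", "99/100", "98/100", "100/100"),
    identity = c(0.99, 0.99, 0.98, 1),
    read_count = c(50L, 30L, 500L, 100L),
    stringsAsFactors = FALSE)
  reg <- call_novels(calls)
  expect_equal(reg$ns_id, c("NS#1", "NS#2"))
  expect_equal(reg$sequence, c("CCCC", "AAAA"))  # by total read support
  expect_equal(reg$n_carriers, c(1L, 2L))
  expect_equal(reg$confident, c(FALSE, TRUE))    # singleton = low confidence
  expect_equal(reg$carriers[2], "S1,S2")
  expect_equal(nrow(call_novels(calls[calls$status == "specific", ])), 0L)
})

test_that("genotype summary flags homozygosity, duplication and failure", {
  mk_calls <- function(loci, counts) {
    n <- length(loci)
    if (n == 0L) {
      return(data.frame(sample = character(0), rank = integer(0),
                        sequence = character(0), status = character(0),
                        match = character(0), closest_match = character(0),
                        similarity = character(0), identity = numeric(0),
                        read_count = integer(0), read_fraction = numeric(0),
                        locus = character(0), stringsAsFactors = FALSE))
    }
    data.frame(sample = "S", rank = seq_len(n), sequence = replicate(n, rdna(10)),
               status = "specific", match = sprintf("%s*%02d:01", loci, seq_len(n)),
               closest_match = NA, similarity = NA, identity = 1,
               read_count = counts, read_fraction = counts / sum(counts),
               locus = loci, stringsAsFactors = FALSE)
  }
  set.seed(4)
  g <- genotype_sample(mk_calls(c("SLA-1", "SLA-2", "SLA-3"), c(1000, 500, 500)))
  expect_equal(sort(g$homozygous_loci), c("SLA-1", "SLA-2", "SLA-3"))
  expect_length(g$duplication_flags, 0L)
  expect_equal(unname(g$locus_fractions[c("SLA-1", "SLA-2", "SLA-3")]),
               c(0.5, 0.25, 0.25))
  expect_false(g$typing_failed)
  # three alleles at one locus -> duplication flag
  g2 <- genotype_sample(mk_calls(c("SLA-1", "SLA-1", "SLA-1"), c(10, 10, 10)))
  expect_equal(g2$duplication_flags, "SLA-1")
  expect_length(g2$homozygous_loci, 0L)
  # no calls -> typing failed
  g3 <- genotype_sample(mk_calls(character(0), numeric(0)), sample = "S")
  expect_true(g3$typing_failed)
})

test_that("read fractions of retained calls sum to one per sample", {
  set.seed(5)
  pool <- make_fixture_library(3, 6, seed = 21, n_samples = 2)
  cfg <- sim_config(pool, depth_per_allele = 120, seed = 23)
  sim <- simulate_reads(pool, cfg)
  dmx <- demultiplex(sim$reads, pool$barcodes, pool$primers)
  t1 <- quality_trim(dmx$assigned$seq1, dmx$assigned$qual1)
  t2 <- quality_trim(dmx$assigned$seq2, dmx$assigned$qual2)
  keep <- !t1$discarded & !t2$discarded
  m <- slatyper:::merge_pairs_batch(t1$seqs[keep], t1$quals[keep],
                                    t2$seqs[keep], t2$quals[keep])
  idx <- amplicon_index(pool$library, pool$primers)
  for (s in names(pool$barcodes)) {
    seqs <- m$sequence[!is.na(m$sequence) & dmx$assigned$sample[keep] == s]
    cl <- artifact_filter(detect_chimeras(size_filter(dereplicate(seqs, s))),
                          pool$insert_len)
    calls <- match_clusters(cl, idx)
    if (nrow(calls)) {
      expect_equal(sum(calls$read_fraction), 1, tolerance = 1e-9)
      expect_true(all(calls$match[calls$status == "specific"] %in%
                        pool$library$records$name))
    }
  }
})

test_that("per-locus read fractions reproduce the SLA-2 > SLA-1 > SLA-3 pattern", {
  pool <- make_fixture_library(2, 6, seed = 31, n_samples = 4)
  cfg <- sim_config(pool, depth_per_allele = 500, seed = 33)
  sim <- simulate_reads(pool, cfg)
  dmx <- demultiplex(sim$reads, pool$barcodes, pool$primers)
  t1 <- quality_trim(dmx$assigned$seq1, dmx$assigned$qual1)
  t2 <- quality_trim(dmx$assigned$seq2, dmx$assigned$qual2)
  keep <- !t1$discarded & !t2$discarded
  m <- slatyper:::merge_pairs_batch(t1$seqs[keep], t1$quals[keep],
                                    t2$seqs[keep], t2$quals[keep])
  idx <- amplicon_index(pool$library, pool$primers)
  for (s in names(pool$barcodes)) {
    seqs <- m$sequence[!is.na(m$sequence) & dmx$assigned$sample[keep] == s]
    cl <- artifact_filter(detect_chimeras(size_filter(dereplicate(seqs, s))),
                          pool$insert_len)
    g <- genotype_sample(match_clusters(cl, idx), sample = s)
    fr <- g$locus_fractions
    expect_gt(fr[["SLA-2"]], fr[["SLA-1"]])
    expect_gt(fr[["SLA-1"]], fr[["SLA-3"]])
  }
})
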