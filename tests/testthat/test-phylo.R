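test_that("exon 2-3 assembly joins fragments at exact overlaps", {
  set.seed(1)
  core <- rdna(300)
  e2 <- paste0(rdna(100), substr(core, 1, 100))    # 100-nt exact overlap
  e3 <- paste0(substr(core, 161, 300), rdna(120))  # 140-nt exact overlap
  asm <- assemble_exon2_3(core, e2, e3, ns_id = "NS#1")
  expect_equal(asm$length, nchar(e2) + nchar(core) + nchar(e3) - 100 - 140)
  expect_equal(asm$overlap_left, 100L)
  expect_equal(asm$overlap_right, 140L)
  # the core is an exact substring of the assembly
  expect_true(grepl(core, asm$sequence, fixed = TRUE))
  expect_gte(asm$length, nchar(core))
  # completeness flags against configured exon spans (assembly is 520 nt)
  asm2 <- assemble_exon2_3(core, e2, e3, exon2_span = c(33, 302),
                           exon3_span = c(303, 480))
  expect_true(asm2$complete_exon2)
  expect_true(asm2$complete_exon3)
  asm3 <- assemble_exon2_3(core, e2, e3, exon3_span = c(303, 578))
  expect_false(asm3$complete_exon3)  # span extends past the assembly
})

test_that("fragment containment and junction mismatches are handled", {
  set.seed(2)
  core <- rdna(300)
  # exon-2 fragment equal to a prefix of the core adds nothing
  asm <- assemble_exon2_3(core, substr(core, 1, 80), substr(core, 231, 300))
  expect_equal(asm$sequence, core)
  # a single disagreeing base in the overlap is an error naming the junction
  e2bad <- paste0(rdna(100), set_base(substr(core, 1, 100), 50,
                                      other_base(substr(core, 50, 50))))
  expect_error(assemble_exon2_3(core, e2bad, substr(core, 231, 300)),
               "exon2/core.*position 50")
  # too-short fragments cannot satisfy the minimum overlap
  expect_error(assemble_exon2_3(core, rdna(10), substr(core, 231, 300)),
               "at most")
})

test_that("Jukes-Cantor distance follows the closed form with saturation cap", {
  expect_equal(as.numeric(jc_distance("ACGT", "ACGT")), 0)
  # p = 0.1
  d <- jc_distance(strrep("A", 10), paste0(strrep("A", 9), "C"))
  expect_equal(round(as.numeric(d), 6), 0.107326)
  expect_false(attr(d, "saturated"))
  # p = 0.75 saturates at the cap
  d2 <- jc_distance("AAAA", "ACCC")
  expect_equal(as.numeric(d2), 5.0)
  expect_true(attr(d2, "saturated"))
  expect_equal(as.numeric(jc_distance("AAAA", "ACCC", cap = 9)), 9)
  # non-ACGT positions are excluded from p and the compared length
  d3 <- jc_distance("AANGT", "AACGT")
  expect_equal(as.numeric(d3), 0)
  expect_error(jc_distance("NNN", "NNN"), "no comparable")
  expect_error(jc_distance("ACG", "AC"), "equal length")
})

test_that("JC distance is symmetric, identity-zero and monotone in p", {
  set.seed(3)
  L <- 200
  a <- rdna(L)
  prev <- -1
  for (k in c(0, 5, 20, 60, 100, 140)) {
    b <- a
    if (k > 0) for (p in sample(L, k)) b <- set_base(b, p, other_base(substr(b, p, p)))
    d_ab <- as.numeric(jc_distance(a, b))
    d_ba <- as.numeric(jc_distance(b, a))
    expect_equal(d_ab, d_ba)
    if (k == 0) expect_equal(d_ab, 0)
    expect_gt(d_ab, prev - 1e-12)
    prev <- d_ab
  }
})

test_that("neighbor joining recovers a 4-taxon additive tree exactly", {
  # tree ((A:1,B:2):5,C:3,D:4)
  taxa <- c("A", "B", "C", "D")
  D <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  D["A", "B"] <- 3; D["A", "C"] <- 9; D["A", "D"] <- 10
  D["B", "C"] <- 10; D["B", "D"] <- 11; D["C", "D"] <- 7
  D <- D + t(D)
  tr <- nj_tree(D)
  coph <- as.matrix(ape::cophenetic.phylo(tr))[taxa, taxa]
  expect_equal(coph, D, tolerance = 1e-9)
  expect_setequal(tr$edge.length, c(1, 2, 3, 4, 5))
})

test_that("three equidistant taxa get equal branches; degenerate inputs error", {
  D <- matrix(2, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  diag(D) <- 0
  tr <- nj_tree(D)
  expect_equal(sort(tr$edge.length), rep(1, 3))
  # two taxa: trivial single-edge tree
  D2 <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr2 <- nj_tree(D2)
  expect_equal(sort(tr2$tip.label), c("a", "b"))
  expect_equal(sum(tr2$edge.length), 4)
  expect_error(nj_tree(D2[1, 1, drop = FALSE]), "at least 2")
})

test_that("random additive matrices round-trip through neighbor joining", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    gen <- ape::rtree(n, rooted = FALSE)
    gen$edge.length <- runif(nrow(gen$edge), 0.2, 1.5)
    D <- as.matrix(ape::cophenetic.phylo(gen))
    tr <- nj_tree(D)
    coph <- as.matrix(ape::cophenetic.phylo(tr))[rownames(D), colnames(D)]
    expect_equal(coph, D, tolerance = 1e-8)
    # topology identical to the generating tree and to ape's NJ
    expect_equal(as.integer(ape::dist.topo(tr, gen)), 0L)
    expect_equal(as.integer(ape::dist.topo(tr, ape::nj(D))), 0L)
  }
})

test_that("bootstrap support is deterministic and finds certain bipartitions", {
  # two identical sequences vs a distant pair: the separating bipartition
  # must appear in every replicate
  set.seed(6)
  left <- rdna(120)
  right <- rdna(120)
  seqs <- c(A = left, B = left, C = right,
            D = set_base(right, 5, other_base(substr(right, 5, 5))))
  tr <- bootstrap_support(seqs, n_reps = 40, seed = 11)
  # the non-trivial internal bipartition has 100% support
  expect_true(100 %in% tr$node.label)
  labs <- slatyper:::bipartition_keys(tr)
  expect_equal(unname(tr$node.label[labs == "C|D"]), 100)
  # single replicate: supports are 0 or 100
  tr1 <- bootstrap_support(seqs, n_reps = 1, seed = 12)
  expect_true(all(tr1$node.label %in% c(0, 100)))
  # same seed, same supports
  tra <- bootstrap_support(seqs, n_reps = 25, seed = 13)
  trb <- bootstrap_support(seqs, n_reps = 25, seed = 13)
  expect_identical(tra$node.label, trb$node.label)
})

test_that("novel sequences are placed at the locus of their nearest clade", {
  pool <- make_fixture_library(4, 6, seed = 21)
  idx <- amplicon_index(pool$library, pool$primers)
  # one substitution away from an SLA-2 allele
  base <- idx$inserts[["SLA-2*02:01"]]
  nov <- set_base(base, 77, other_base(substr(base, 77, 77)))
  la <- assign_locus(nov, pool$library, primers = pool$primers,
                     n_reps = 100, seed = 31)
  expect_equal(la$locus, "SLA-2")
  expect_equal(la$method, "clade")
  expect_false(la$low_confidence)
  expect_gte(la$support, 50)
  # spans under 100 nt are refused
  expect_error(assign_locus(substr(nov, 1, 80), pool$library,
                            primers = pool$primers), "100 nt")
})

test_that("ambiguous placements fall back to nearest neighbour, low confidence", {
  set.seed(7)
  # two references only: a 3-taxon tree has no internal edge to lean on
  a <- rdna(150); b <- rdna(150)
  lib <- allele_library(c("SLA-1*01:01", "SLA-2*01:01"), c(a, b))
  nov <- set_base(a, 10, other_base(substr(a, 10, 10)))
  la <- assign_locus(nov, lib, n_reps = 20, seed = 8)
  expect_equal(la$method, "nearest_neighbor")
  expect_true(la$low_confidence)
  expect_equal(la$locus, "SLA-1")
})

test_that("simulated novels recover their generating locus", {
  pool <- make_fixture_library(4, 6, seed = 41)
  idx <- amplicon_index(pool$library, pool$primers)
  set.seed(42)
  n_ok <- 0L; n_tot <- 12L
  for (i in seq_len(n_tot)) {
    src <- sample(names(idx$inserts), 1)
    nov <- idx$inserts[[src]]
    for (p in sample(nchar(nov), 2)) nov <- set_base(nov, p, other_base(substr(nov, p, p)))
    la <- assign_locus(nov, pool$library, primers = pool$primers,
                       n_reps = 50, seed = 100 + i)
    if (la$locus == slatyper:::locus_of(src)) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("trees serialise to newick with supports", {
  set.seed(9)
  seqs <- c(A = rdna(100), B = rdna(100), C = rdna(100), D = rdna(100))
  tr <- bootstrap_support(seqs, n_reps = 10, seed = 10)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, names(seqs))
})
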