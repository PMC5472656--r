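# Independent oracles and fixture builders used only by the test suite.

rdna <- function(n) paste0(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rc <- function(x) chartr("ACGT", "TGCA",
                         vapply(x, function(s)
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                           character(1), USE.NAMES = FALSE))

set_base <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

other_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]

# Ends-free alignment oracle: straightforward R dynamic programme with the
# same scoring convention as the operation under test (match +1, mismatch
# -1, gap -1, free end gaps; tie preference diagonal > up > left; best end
# cell scanned over last row then last column, strict improvement only).
oracle_nw_identity <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(S[i, j] + ifelse(A[i] == B[j], 1, -1),
                             S[i, j + 1] - 1, S[i + 1, j] - 1)
    }
  }
  bi <- n; bj <- m; bs <- S[n + 1, m + 1]
  for (j in 0:m) if (S[n + 1, j + 1] > bs) { bs <- S[n + 1, j + 1]; bi <- n; bj <- j }
  for (i in 0:n) if (S[i + 1, m + 1] > bs) { bs <- S[i + 1, m + 1]; bi <- i; bj <- m }
  matches <- 0L; len <- 0L; i <- bi; j <- bj
  while (i > 0 && j > 0) {
    diag <- S[i, j] + ifelse(A[i] == B[j], 1, -1)
    if (S[i + 1, j + 1] == diag) {
      if (A[i] == B[j]) matches <- matches + 1L
      i <- i - 1L; j <- j - 1L
    } else if (S[i + 1, j + 1] == S[i, j + 1] - 1) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
    len <- len + 1L
  }
  list(matches = matches, aln_length = len, identity = matches / len)
}

# Exhaustive overlap-scoring oracle for pair merging: every ungapped shift,
# admissibility by identity, best by (identity, overlap, |shift|, shift).
oracle_merge <- function(seq1, qual1, seq2, qual2, min_overlap = 35,
                         min_match = 0.8) {
  a <- strsplit(seq1, "")[[1]]; qa <- as.integer(charToRaw(qual1))
  b <- strsplit(rc(seq2), "")[[1]]
  qb <- rev(as.integer(charToRaw(qual2)))
  n <- length(a); m <- length(b)
  best <- NULL
  for (s in (-(m - 1)):(n - 1)) {
    lo <- max(0, s); hi <- min(n, s + m)
    ov <- hi - lo
    if (ov < min_overlap) next
    ia <- (lo + 1):hi; ib <- ia - s
    mism <- sum(a[ia] != b[ib])
    id <- (ov - mism) / ov
    if (id < min_match - 1e-12) next
    cand <- list(s = s, ov = ov, mism = mism, id = id)
    if (is.null(best) ||
        id > best$id + 1e-12 ||
        (abs(id - best$id) <= 1e-12 &&
         (ov > best$ov ||
          (ov == best$ov && (abs(s) < abs(best$s) ||
                             (abs(s) == abs(best$s) && s < best$s)))))) {
      best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  s <- best$s; lo <- max(0, s); hi <- min(n, s + m)
  merged <- character(n + m - best$ov)
  p <- 0L
  if (s > 0) for (i in seq_len(s)) { p <- p + 1L; merged[p] <- a[i] }
  if (s < 0) for (j in seq_len(-s)) { p <- p + 1L; merged[p] <- b[j] }
  for (i in (lo + 1):hi) {
    p <- p + 1L
    merged[p] <- if (a[i] == b[i - s] || qa[i] >= qb[i - s]) a[i] else b[i - s]
  }
  if (s + m > n) { for (j in (n - s + 1):m) { p <- p + 1L; merged[p] <- b[j] } }
  if (s + m < n) { for (i in (s + m + 1):n) { p <- p + 1L; merged[p] <- a[i] } }
  list(sequence = paste(merged, collapse = ""), overlap_len = best$ov,
       mismatches_in_overlap = best$mism, shift = s)
}

# Brute-force resolvability: direct pairwise comparison of every pair of
# extracted inserts.
oracle_resolvability <- function(library, primers) {
  recs <- library$records
  ins <- vapply(seq_len(nrow(recs)), function(i) {
    a <- extract_amplicon(recs$sequence[i], primers)
    if (is.null(a)) NA_character_ else a$insert
  }, character(1))
  amp <- !is.na(ins)
  status <- rep("not_amplified", nrow(recs))
  for (i in which(amp)) {
    shared <- any(vapply(setdiff(which(amp), i),
                         function(j) ins[j] == ins[i], logical(1)))
    status[i] <- if (shared) "group" else "unique"
  }
  list(status = setNames(status, recs$name),
       fraction_unique = 100 * sum(status == "unique") / sum(amp),
       fraction_group = 100 * sum(status == "group") / sum(amp))
}

# Random small library with forced insert sharing (group-specific alleles).
random_test_library <- function(n_alleles, insert_len = 60,
                                n_distinct = NULL) {
  p <- sla_primers("short")
  rev_c <- sub("Y", "C", p$reverse)
  n_distinct <- n_distinct %||% max(2L, n_alleles - sample(0:2, 1))
  pool <- replicate(n_distinct, rdna(insert_len))
  ins <- sample(pool, n_alleles, replace = TRUE)
  loci <- rep(c("SLA-1", "SLA-2", "SLA-3"), length.out = n_alleles)
  nm <- sprintf("%s*%02d:01", loci, seq_len(n_alleles))
  seqs <- paste0(rdna(10), p$forward, ins, rc(rev_c), rdna(10))
  allele_library(nm, seqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
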