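# Raw paired FASTQ -> per-sample, size-filtered, artifact-free clusters of
# identical insert sequences.

#' Read a pair of FASTQ files into a read-pair table
#'
#' @param fastq1,fastq2 Paths to mate-1 and mate-2 FASTQ files (gzip allowed).
#' @return Data frame with columns id, seq1, qual1, seq2, qual2 (qualities as
#'   Phred+33 strings).
#' @export
read_fastq_pairs <- function(fastq1, fastq2) {
  # QualityScaledDNAStringSet construction warns about dropping the mcols
  # that the FASTQ parser attaches; nothing of value is lost
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastq1))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(fastq2))
  if (length(r1) != length(r2)) stop("mate files differ in read count")
  # as.character on a QualityScaledDNAStringSet warns about dropped
  # metadata columns; the qualities are extracted explicitly
  suppressWarnings(data.frame(
    id = if (length(r1)) sub(" .*", "", names(r1)) else character(0),
    seq1 = as.character(r1),
    qual1 = as.character(Biostrings::quality(r1)),
    seq2 = as.character(r2),
    qual2 = as.character(Biostrings::quality(r2)),
    stringsAsFactors = FALSE, row.names = NULL))
}

#' Write sequences and Phred+33 qualities as FASTQ
#'
#' @param seqs,quals,ids Parallel character vectors.
#' @param path Output path (`.gz` suffix compresses).
#' @export
write_fastq <- function(seqs, quals, ids, path) {
  x <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(seqs, ids)),
    Biostrings::PhredQuality(quals)))
  Biostrings::writeQualityScaledXStringSet(x, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Demultiplex barcoded read pairs by sample
#'
#' A pair is assigned to a sample iff mate 1 begins with that sample's
#' barcode immediately followed by the forward primer (degeneracy-aware,
#' zero mismatches) and mate 2 begins with the same barcode followed by the
#' reverse primer. Barcode+primer prefixes are stripped from assigned reads.
#' Rejections are tallied by reason: `no_barcode` (neither mate starts with a
#' known barcode), `barcode_conflict` (mates disagree or only one carries a
#' known barcode), `no_primer` (barcodes agree but a primer does not match).
#'
#' @param pairs Read-pair data frame as from [read_fastq_pairs()].
#' @param barcodes Named character vector, sample -> barcode (all the same
#'   length, pairwise distinct).
#' @param primers A [primer_pair()].
#' @return List with `assigned` (the pair table plus a `sample` column,
#'   prefixes stripped from sequences and qualities) and `rejected` (named
#'   integer: no_barcode, barcode_conflict, no_primer).
#' @export
demultiplex <- function(pairs, barcodes, primers) {
  stopifnot(inherits(primers, "primer_pair"))
  if (anyDuplicated(barcodes)) stop("barcodes must be distinct")
  bclen <- unique(nchar(barcodes))
  if (length(bclen) != 1L) stop("barcodes must share one length")
  n <- nrow(pairs)
  empty <- pairs[0, ]
  empty$sample <- character(0)
  if (n == 0L) {
    return(list(assigned = empty,
                rejected = c(no_barcode = 0L, barcode_conflict = 0L,
                             no_primer = 0L)))
  }
  b1 <- substr(pairs$seq1, 1L, bclen)
  b2 <- substr(pairs$seq2, 1L, bclen)
  known1 <- b1 %in% barcodes
  known2 <- b2 %in% barcodes
  agree <- known1 & known2 & b1 == b2
  no_barcode <- !known1 & !known2
  conflict <- !agree & !no_barcode
  plen_f <- nchar(primers$forward)
  plen_r <- nchar(primers$reverse)
  fwd_ok <- grepl(iupac_regex(primers$forward, anchor = FALSE),
                  substr(pairs$seq1, bclen + 1L, bclen + plen_f))
  rev_ok <- grepl(iupac_regex(primers$reverse, anchor = FALSE),
                  substr(pairs$seq2, bclen + 1L, bclen + plen_r))
  # full-length primer region required
  fwd_ok <- fwd_ok & nchar(pairs$seq1) >= bclen + plen_f
  rev_ok <- rev_ok & nchar(pairs$seq2) >= bclen + plen_r
  keep <- agree & fwd_ok & rev_ok
  no_primer <- agree & !keep
  assigned <- pairs[keep, , drop = FALSE]
  if (nrow(assigned)) {
    assigned$sample <- names(barcodes)[match(b1[keep], barcodes)]
    assigned$seq1 <- substr(assigned$seq1, bclen + plen_f + 1L,
                            nchar(assigned$seq1))
    assigned$qual1 <- substr(assigned$qual1, bclen + plen_f + 1L,
                             nchar(assigned$qual1))
    assigned$seq2 <- substr(assigned$seq2, bclen + plen_r + 1L,
                            nchar(assigned$seq2))
    assigned$qual2 <- substr(assigned$qual2, bclen + plen_r + 1L,
                             nchar(assigned$qual2))
    rownames(assigned) <- NULL
  } else {
    assigned <- empty
  }
  list(assigned = assigned,
       rejected = c(no_barcode = sum(no_barcode),
                    barcode_conflict = sum(conflict),
                    no_primer = sum(no_primer)))
}

#' Phred score equivalent to a base-call accuracy
#'
#' `round(-10 * log10(1 - acc))`; an accuracy of 98 percent corresponds to
#' Phred 17.
#'
#' @param acc Base-call accuracy, strictly between 0 and 1.
#' @return Integer Phred score.
#' @export
#' @examples
#' phred_from_accuracy(0.98)  # 17
phred_from_accuracy <- function(acc) {
  if (any(acc <= 0 | acc >= 1)) stop("accuracy must lie strictly in (0, 1)")
  as.integer(round(-10 * log10(1 - acc)))
}

#' Trim low-quality read ends
#'
#' Removes the maximal prefix and suffix consisting of bases with quality
#' below `q_min`; interior low-quality bases are retained. A read trimmed to
#' nothing is flagged discarded.
#'
#' @param seqs,quals Character vectors (qualities Phred+33).
#' @param q_min Minimum Phred score to keep at the ends (default 17, i.e.
#'   98 percent accuracy).
#' @return List with `seqs`, `quals` (trimmed) and `discarded` (logical).
#' @export
quality_trim <- function(seqs, quals, q_min = 17L) {
  stopifnot(q_min >= 0L, length(seqs) == length(quals))
  n <- length(seqs)
  out_s <- character(n); out_q <- character(n); disc <- logical(n)
  thr <- as.raw(q_min + 33L)
  for (i in seq_len(n)) {
    q <- charToRaw(quals[i])
    ok <- q >= thr
    if (!any(ok)) { disc[i] <- TRUE; out_s[i] <- ""; out_q[i] <- ""; next }
    a <- which(ok)[1]
    b <- which(ok)[length(which(ok))]
    out_s[i] <- substr(seqs[i], a, b)
    out_q[i] <- substr(quals[i], a, b)
  }
  list(seqs = out_s, quals = out_q, discarded = disc)
}

#' Merge a trimmed read pair by ungapped overlap
#'
#' Considers every ungapped placement of the reverse-complemented mate 2
#' against mate 1 with overlap at least `min_overlap`; a placement is
#' admissible iff `matches / overlap >= min_match`. Among admissible
#' placements the highest identity wins, ties broken by longer overlap, then
#' smaller shift. The consensus takes the higher-quality base at mismatches
#' (ties favour mate 1).
#'
#' @param seq1,qual1 Mate 1 (sequence, Phred+33 quality).
#' @param seq2,qual2 Mate 2; reverse-complemented internally.
#' @param min_overlap Minimum overlap length in nt (default 35).
#' @param min_match Minimum identity within the overlap (default 0.80).
#' @return A list with `sequence`, `overlap_len`, `mismatches_in_overlap`,
#'   `shift`, or `NULL` when no admissible overlap exists (unjoined).
#' @export
merge_pairs <- function(seq1, qual1, seq2, qual2, min_overlap = 35L,
                        min_match = 0.80) {
  if (!nzchar(seq1) || !nzchar(seq2)) return(NULL)
  rc2 <- revcomp(seq2)
  rq2 <- paste(rev(strsplit(qual2, "", fixed = TRUE)[[1]]), collapse = "")
  cpp_merge_pair(seq1, qual1, rc2, rq2, as.integer(min_overlap), min_match)
}

# Vectorised merge of many pairs; returns merged sequences (NA = unjoined)
# plus overlap stats.
merge_pairs_batch <- function(seqs1, quals1, seqs2, quals2, min_overlap = 35L,
                              min_match = 0.80) {
  n <- length(seqs1)
  if (n == 0L) {
    return(data.frame(sequence = character(0), overlap_len = integer(0),
                      mismatches_in_overlap = integer(0)))
  }
  rc2 <- revcomp(seqs2)
  rq2 <- vapply(quals2, function(q)
    rawToChar(rev(charToRaw(q))), character(1), USE.NAMES = FALSE)
  res <- cpp_merge_many(seqs1, quals1, rc2, rq2, as.integer(min_overlap),
                        min_match)
  joined <- !vapply(res, is.null, logical(1))
  out <- data.frame(sequence = rep(NA_character_, n),
                    overlap_len = rep(NA_integer_, n),
                    mismatches_in_overlap = rep(NA_integer_, n))
  out$sequence[joined] <- vapply(res[joined], `[[`, character(1), "sequence")
  out$overlap_len[joined] <- vapply(res[joined], `[[`, integer(1), "overlap_len")
  out$mismatches_in_overlap[joined] <-
    vapply(res[joined], `[[`, integer(1), "mismatches_in_overlap")
  out
}

#' Dereplicate merged reads of one sample into 100 percent-identity clusters
#'
#' @param sequences Character vector of merged insert sequences.
#' @param sample Sample label carried into the result.
#' @return Data frame (sample, rank, sequence, size) sorted by size
#'   descending, ties by lexicographic sequence; all member reads of a
#'   cluster are identical to its sequence.
#' @export
dereplicate <- function(sequences, sample = NA_character_) {
  if (length(sequences) == 0L) {
    return(data.frame(sample = character(0), rank = integer(0),
                      sequence = character(0), size = integer(0)))
  }
  tab <- table(sequences)
  df <- data.frame(sequence = names(tab), size = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$size, df$sequence), , drop = FALSE]
  data.frame(sample = sample, rank = seq_len(nrow(df)),
             sequence = df$sequence, size = df$size,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Discard small clusters and cap the retained list
#'
#' Clusters with fewer than `min_reads` reads are dropped ("less than" is
#' strict: a cluster of exactly `min_reads` reads is kept); the retained
#' list is then capped at the `max_clusters` largest by rank.
#'
#' @param clusters Cluster data frame from [dereplicate()].
#' @param min_reads Minimum cluster size (default 10).
#' @param max_clusters Maximum clusters retained per sample (default 20).
#' @return The retained clusters.
#' @export
size_filter <- function(clusters, min_reads = 10L, max_clusters = 20L) {
  keep <- clusters[clusters$size >= min_reads, , drop = FALSE]
  keep <- keep[order(keep$rank), , drop = FALSE]
  head(keep, max_clusters)
}

#' Flag chimeric clusters with a two-parent crossover model
#'
#' For each candidate cluster, all ordered pairs of clusters at least twice
#' its size are considered as parents. Over all single crossover points the
#' best chimeric model (left segment from parent A, right from parent B,
#' ungapped; parents must match the candidate's length) is evaluated. A
#' cluster is flagged iff some model explains it at 100 percent identity,
#' neither parent alone explains it, and each side carries at least
#' `min_diagnostic` positions at which the parents differ.
#'
#' @param clusters Ranked cluster data frame.
#' @param min_diagnostic Minimum diagnostic positions per side (default 3).
#' @return `clusters` with a logical `chimera` column.
#' @export
detect_chimeras <- function(clusters, min_diagnostic = 3L) {
  n <- nrow(clusters)
  clusters$chimera <- logical(n)
  if (n < 3L) return(clusters)
  chars <- strsplit(clusters$sequence, "", fixed = TRUE)
  lens <- nchar(clusters$sequence)
  for (i in seq_len(n)) {
    cand <- chars[[i]]
    L <- lens[i]
    parents <- setdiff(which(clusters$size >= 2L * clusters$size[i] &
                               lens == L), i)
    if (length(parents) < 2L) next
    mism <- lapply(parents, function(p) which(cand != chars[[p]]))
    names(mism) <- as.character(parents)
    # a single parent explaining the candidate exactly rules out chimerism
    if (any(lengths(mism) == 0L)) next
    flagged <- FALSE
    for (a in parents) {
      for (b in setdiff(parents, a)) {
        # perfect model A[1..k] + B[k+1..L] exists iff every candidate-vs-A
        # mismatch lies right of k and every candidate-vs-B mismatch lies at
        # or left of k
        k_lo <- max(mism[[as.character(b)]])
        k_hi <- min(mism[[as.character(a)]]) - 1L
        if (k_lo > k_hi) next
        diff_ab <- which(chars[[a]] != chars[[b]])
        # within a perfect model the candidate equals A left of the
        # crossover and B right of it, so parent-differing positions on each
        # side are exactly the side's diagnostic positions
        for (k in k_lo:k_hi) {
          if (sum(diff_ab <= k) >= min_diagnostic &&
              sum(diff_ab > k) >= min_diagnostic) {
            flagged <- TRUE
            break
          }
        }
        if (flagged) break
      }
      if (flagged) break
    }
    clusters$chimera[i] <- flagged
  }
  clusters
}

#' Flag splice-variant and off-size clusters
#'
#' Clusters whose length is within `tol` of the expected insert length pass.
#' Longer clusters containing at least one stop codon in each of the three
#' sense reading frames are flagged `splice_variant` (alternative-splicing
#' artifacts, removed from typing). Remaining off-length clusters are
#' flagged `off_size`: excluded from typing but reported, so a sample whose
#' dominant clusters are all off-size can be recognised as typing-failed
#' (the published pipeline's behaviour for a primer-mismatch sample that
#' produced only a 456-nt product).
#'
#' @param clusters Cluster data frame.
#' @param expected_len Expected insert length in nt.
#' @param tol Length tolerance in nt (default 15).
#' @return `clusters` with logical `splice_variant` and `off_size` columns.
#' @export
artifact_filter <- function(clusters, expected_len, tol = 15L) {
  stopifnot(expected_len > 0L)
  n <- nrow(clusters)
  clusters$splice_variant <- logical(n)
  clusters$off_size <- logical(n)
  if (n == 0L) return(clusters)
  lens <- nchar(clusters$sequence)
  off <- abs(lens - expected_len) > tol
  longer <- lens > expected_len
  for (i in which(off)) {
    if (longer[i] && all_frames_have_stop(clusters$sequence[i])) {
      clusters$splice_variant[i] <- TRUE
    } else {
      clusters$off_size[i] <- TRUE
    }
  }
  clusters
}

all_frames_have_stop <- function(seq) {
  stops <- c("TAA", "TAG", "TGA")
  L <- nchar(seq)
  for (frame in 0:2) {
    starts <- seq(1L + frame, L - 2L, by = 3L)
    codons <- substring(seq, starts, starts + 2L)
    if (!any(codons %in% stops)) return(FALSE)
  }
  TRUE
}

#' Identify the dominant clusters of a sample
#'
#' A retained cluster is dominant when it holds at least `min_frac` of the
#' sample's retained reads (reads in clusters that passed all filters).
#'
#' @param clusters Retained cluster data frame (post filtering; rows flagged
#'   chimera/splice_variant/off_size are excluded first if present).
#' @param min_frac Minimum read fraction (default 0.05).
#' @return The dominant subset of `clusters`.
#' @export
dominant_clusters <- function(clusters, min_frac = 0.05) {
  for (fl in c("chimera", "splice_variant", "off_size")) {
    if (fl %in% names(clusters)) {
      clusters <- clusters[!clusters[[fl]], , drop = FALSE]
    }
  }
  if (nrow(clusters) == 0L) return(clusters)
  clusters[clusters$size / sum(clusters$size) >= min_frac, , drop = FALSE]
}
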