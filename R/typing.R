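# Cluster identification against the allele library, novel-sequence
# registry, and per-sample genotypes with read-fraction transcription proxies.

#' Build an exact insert-sequence index for a library under a primer pair
#'
#' In-silico PCR is run on every allele; the primer-stripped inserts are
#' indexed so clusters (which are barcode/primer-stripped) can be looked up
#' exactly. Alleles sharing an identical insert map to the same key
#' (group-specific alleles).
#'
#' @param library An [allele_library()].
#' @param primers A [primer_pair()].
#' @return A list with `index` (insert sequence -> sorted allele names) and
#'   `inserts` (named character, allele name -> insert; non-amplified
#'   alleles are absent).
#' @export
amplicon_index <- function(library, primers) {
  recs <- library$records
  amps <- lapply(seq_len(nrow(recs)), function(i) {
    extract_amplicon(recs$sequence[i], primers, allele_name = recs$name[i])
  })
  ok <- !vapply(amps, is.null, logical(1))
  inserts <- setNames(vapply(amps[ok], `[[`, character(1), "insert"),
                      recs$name[ok])
  index <- lapply(split(names(inserts), inserts), sort)
  list(index = index, inserts = inserts)
}

#' Identify one cluster against the allele library
#'
#' An exact insert match with one allele name yields a `specific` call; with
#' several names a `group` call (names sorted and joined by "/"). Otherwise
#' the cluster is aligned against every library insert (global alignment,
#' unit costs, end gaps free) and the best identity (matches / alignment
#' length, internal gaps counted) decides: at least `min_identity` gives a
#' `novel_candidate` with its closest match and an "x/y" similarity; below
#' it the cluster is `unclassified`.
#'
#' @param sequence Cluster insert sequence.
#' @param index An [amplicon_index()] (preferred) or an [allele_library()]
#'   (matched on full coding sequences; pass `primers` to index inserts).
#' @param min_identity Identity floor for novel candidates (default 0.95).
#' @param primers Optional [primer_pair()] when `index` is a library.
#' @return A list: `status` (specific | group | novel_candidate |
#'   unclassified), `match` (name or slash-joined names, NA otherwise),
#'   `closest_match`, `similarity` ("matches/length"), `identity`.
#' @export
match_cluster <- function(sequence, index, min_identity = 0.95,
                          primers = NULL) {
  if (inherits(index, "allele_library")) {
    index <- if (is.null(primers)) {
      list(index = lapply(split(index$records$name, index$records$sequence),
                          sort),
           inserts = setNames(index$records$sequence, index$records$name))
    } else {
      amplicon_index(index, primers)
    }
  }
  if (length(index$inserts) == 0L) stop("empty allele library")
  hit <- index$index[[sequence]]
  if (!is.null(hit)) {
    nm <- paste(hit, collapse = "/")
    L <- nchar(sequence)
    return(list(status = if (length(hit) == 1L) "specific" else "group",
                match = nm, closest_match = hit[1],
                similarity = sprintf("%d/%d", L, L), identity = 1.0))
  }
  aln <- cpp_nw_identity_many(sequence, unname(index$inserts))
  # an all-negative alignment has an empty aligned region: identity 0
  identity <- ifelse(aln$aln_length > 0, aln$matches / aln$aln_length, 0)
  best <- which(identity == max(identity))
  # deterministic tie-break: lexicographically smallest allele name
  best <- best[order(names(index$inserts)[best])][1]
  id <- identity[best]
  list(status = if (id >= min_identity) "novel_candidate" else "unclassified",
       match = NA_character_,
       closest_match = names(index$inserts)[best],
       similarity = sprintf("%d/%d", aln$matches[best], aln$aln_length[best]),
       identity = id)
}

#' Call every retained cluster of every sample
#'
#' @param clusters Cluster data frame (post filtering) with columns sample,
#'   rank, sequence, size; rows flagged chimera/splice_variant/off_size are
#'   excluded from calling.
#' @param index An [amplicon_index()].
#' @param min_identity Identity floor for novel candidates.
#' @return Data frame of allele calls: sample, rank, sequence, status, match,
#'   closest_match, similarity, identity, read_count, read_fraction (of the
#'   sample's retained reads), locus. Fractions sum to 1 within a sample.
#' @export
match_clusters <- function(clusters, index, min_identity = 0.95) {
  for (fl in c("chimera", "splice_variant", "off_size")) {
    if (fl %in% names(clusters)) {
      clusters <- clusters[!clusters[[fl]], , drop = FALSE]
    }
  }
  if (nrow(clusters) == 0L) {
    return(data.frame(sample = character(0), rank = integer(0),
                      sequence = character(0), status = character(0),
                      match = character(0), closest_match = character(0),
                      similarity = character(0), identity = numeric(0),
                      read_count = integer(0), read_fraction = numeric(0),
                      locus = character(0)))
  }
  calls <- lapply(seq_len(nrow(clusters)), function(i) {
    m <- match_cluster(clusters$sequence[i], index, min_identity)
    data.frame(sample = clusters$sample[i], rank = clusters$rank[i],
               sequence = clusters$sequence[i], status = m$status,
               match = m$match, closest_match = m$closest_match,
               similarity = m$similarity, identity = m$identity,
               read_count = clusters$size[i], stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, calls)
  totals <- tapply(calls$read_count, calls$sample, sum)
  calls$read_fraction <- calls$read_count / as.numeric(totals[calls$sample])
  calls$locus <- "unassigned"
  idn <- calls$status %in% c("specific", "group")
  calls$locus[idn] <- locus_of(sub("/.*", "", calls$match[idn]))
  rownames(calls) <- NULL
  calls
}

#' Register novel sequences across samples
#'
#' Identical novel-candidate sequences observed in different samples are
#' collapsed into one registry entry. Stable ids NS#1, NS#2, ... are
#' assigned in order of discovery: by total read support descending, ties by
#' sequence. Entries carried by a single sample are labelled low-confidence;
#' recurrence across individuals (independent PCRs) is the argument against
#' a PCR-error origin.
#'
#' @param calls Call data frame from [match_clusters()].
#' @return Data frame: ns_id, sequence, n_carriers, carriers (comma-joined),
#'   total_reads, closest_match, similarity, confident.
#' @export
call_novels <- function(calls) {
  nov <- calls[calls$status == "novel_candidate", , drop = FALSE]
  if (nrow(nov) == 0L) {
    return(data.frame(ns_id = character(0), sequence = character(0),
                      n_carriers = integer(0), carriers = character(0),
                      total_reads = integer(0), closest_match = character(0),
                      similarity = character(0), confident = logical(0)))
  }
  groups <- split(nov, nov$sequence)
  reg <- do.call(rbind, lapply(groups, function(g) {
    data.frame(sequence = g$sequence[1],
               n_carriers = length(unique(g$sample)),
               carriers = paste(sort(unique(g$sample)), collapse = ","),
               total_reads = sum(g$read_count),
               closest_match = g$closest_match[1],
               similarity = g$similarity[1],
               stringsAsFactors = FALSE)
  }))
  reg <- reg[order(-reg$total_reads, reg$sequence), , drop = FALSE]
  reg <- data.frame(ns_id = sprintf("NS#%d", seq_len(nrow(reg))), reg,
                    stringsAsFactors = FALSE)
  reg$confident <- reg$n_carriers >= 2L
  rownames(reg) <- NULL
  reg
}

#' Summarise one sample's calls into a genotype
#'
#' Counts called alleles per locus (a group call counts as one carried
#' allele), flags homozygous loci (exactly one called allele), locus
#' duplications (more than two) and typing failure (no retained calls), and
#' reports per-locus aggregate read fractions, the transcription proxy that
#' should reproduce the SLA-2 > SLA-1 >> SLA-3 pattern.
#'
#' @param calls Call data frame (one sample) from [match_clusters()];
#'   novel candidates may carry a locus via `novel_loci`.
#' @param sample Sample id (defaults to the calls' single sample).
#' @param novel_loci Optional named character (sequence -> locus) assigning
#'   novel candidates to a locus; unassigned novels group under
#'   "unassigned".
#' @return A list of class `sample_genotype`: sample, calls, allele counts
#'   per locus, homozygous_loci, duplication_flags, locus_fractions,
#'   typing_failed.
#' @export
genotype_sample <- function(calls, sample = NULL, novel_loci = NULL) {
  if (is.null(sample)) {
    sample <- if (nrow(calls)) calls$sample[1] else NA_character_
  }
  calls <- calls[is.na(calls$sample) | calls$sample == sample, , drop = FALSE]
  if (!is.null(novel_loci) && nrow(calls)) {
    idx <- calls$status == "novel_candidate" & calls$sequence %in% names(novel_loci)
    calls$locus[idx] <- novel_loci[calls$sequence[idx]]
  }
  loci <- c("SLA-1", "SLA-2", "SLA-3", "unassigned")
  counts <- setNames(integer(length(loci)), loci)
  fracs <- setNames(numeric(length(loci)), loci)
  if (nrow(calls)) {
    tab <- table(factor(calls$locus, levels = loci))
    counts[] <- as.integer(tab)
    fr <- tapply(calls$read_fraction, factor(calls$locus, levels = loci), sum)
    fracs[] <- ifelse(is.na(fr), 0, fr)
  }
  classical <- c("SLA-1", "SLA-2", "SLA-3")
  structure(list(
    sample = sample,
    calls = calls,
    allele_counts = counts,
    homozygous_loci = classical[counts[classical] == 1L],
    duplication_flags = classical[counts[classical] > 2L],
    locus_fractions = fracs,
    typing_failed = nrow(calls) == 0L
  ), class = "sample_genotype")
}

#' @export
print.sample_genotype <- function(x, ...) {
  cat(sprintf("sample %s: %s%s\n", x$sample,
              if (x$typing_failed) "TYPING FAILED" else
                paste(sprintf("%s x%d", names(x$allele_counts),
                              x$allele_counts)[x$allele_counts > 0],
                      collapse = ", "),
              if (length(x$duplication_flags))
                paste0(" [duplicated: ",
                       paste(x$duplication_flags, collapse = ","), "]")
              else ""))
  invisible(x)
}
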