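#' Parse a structured SLA allele label
#'
#' SLA class I alleles are labelled `<locus>*<designation>`, with the locus
#' one of `SLA-1`, `SLA-2`, `SLA-3` and the designation either in the legacy
#' form (`SLA-1*0401`) or the colon-delimited form (`SLA-2*06:14`).
#' Group-specific labels carry several designations joined by `/`
#' (`SLA-1*0401/0402`). Labels without an `SLA-` prefix (e.g. provisional
#' novel-sequence ids such as `NS#7`) are accepted and assigned to the
#' `unassigned` locus.
#'
#' @param label Allele label, non-empty character scalar.
#' @return A list with elements `locus` (one of `"SLA-1"`, `"SLA-2"`,
#'   `"SLA-3"`, `"unassigned"`) and `designation`.
#' @export
#' @examples
#' parse_allele_name("SLA-2*06:14")
#' parse_allele_name("SLA-1*0401")
#' parse_allele_name("NS#7")
parse_allele_name <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!nzchar(label)) stop("allele label must be non-empty")
  if (startsWith(label, "SLA-")) {
    if (!grepl("*", label, fixed = TRUE)) {
      stop(sprintf("malformed allele label (no '*'): '%s'", label))
    }
    parts <- strsplit(label, "*", fixed = TRUE)[[1]]
    prefix <- parts[1]
    designation <- paste(parts[-1], collapse = "*")
    if (!nzchar(designation)) {
      stop(sprintf("malformed allele label (empty designation): '%s'", label))
    }
    locus <- if (prefix %in% c("SLA-1", "SLA-2", "SLA-3")) prefix else "unassigned"
    list(locus = locus, designation = designation)
  } else {
    list(locus = "unassigned", designation = label)
  }
}

locus_of <- function(labels) {
  vapply(labels, function(x) parse_allele_name(x)$locus, character(1),
         USE.NAMES = FALSE)
}

#' Define a PCR primer pair
#'
#' The reverse primer is given 5'->3' on the antisense strand (the
#' publication convention); in-silico PCR searches the sense strand for its
#' reverse complement. Degenerate IUPAC codes are allowed and matched
#' degeneracy-aware.
#'
#' @param name Label for the pair.
#' @param forward,reverse IUPAC DNA strings, each at least 15 nt.
#' @param expected_product_nt Expected amplicon length in nt, or `NA`.
#' @return An object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse, expected_product_nt = NA_integer_) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  if (nchar(forward) < 15L || nchar(reverse) < 15L) {
    stop("primers must be at least 15 nt")
  }
  if (!is_iupac(forward) || !is_iupac(reverse)) {
    stop("primers may contain only IUPAC nucleotide codes")
  }
  structure(list(name = name, forward = forward, reverse = reverse,
                 expected_product_nt = as.integer(expected_product_nt)),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("primer_pair '%s': fwd %s / rev %s (expected product %s nt)\n",
              x$name, x$forward, x$reverse,
              ifelse(is.na(x$expected_product_nt), "?", x$expected_product_nt)))
  invisible(x)
}

#' Build an allele reference library
#'
#' @param names Character vector of allele labels (unique).
#' @param sequences Character vector of coding sequences over A/C/G/T
#'   (lower case is upcased). Two records may share a sequence
#'   (group-specific alleles) but not a name.
#' @return An object of class `allele_library`: a list with a `records`
#'   data frame (name, locus, designation, sequence, length) and `index`,
#'   an exact-sequence lookup mapping each distinct sequence to the allele
#'   names carrying it.
#' @export
allele_library <- function(names, sequences) {
  if (length(names) == 0L) stop("allele library must contain at least one record")
  if (length(names) != length(sequences)) stop("names and sequences differ in length")
  sequences <- toupper(sequences)
  dup <- names[duplicated(names)]
  if (length(dup)) {
    stop(sprintf("duplicate allele name(s): %s", paste(unique(dup), collapse = ", ")))
  }
  bad <- !vapply(sequences, is_acgt, logical(1))
  if (any(bad)) {
    stop(sprintf("record(s) with non-ACGT characters rejected: %s",
                 paste(names[bad], collapse = ", ")))
  }
  names <- unname(names)
  sequences <- unname(sequences)
  parsed <- lapply(names, parse_allele_name)
  records <- data.frame(
    name = names,
    locus = vapply(parsed, `[[`, character(1), "locus"),
    designation = vapply(parsed, `[[`, character(1), "designation"),
    sequence = sequences,
    length = nchar(sequences),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  index <- split(records$name, records$sequence)
  structure(list(records = records, index = index), class = "allele_library")
}

#' @export
print.allele_library <- function(x, ...) {
  cat(sprintf("allele_library: %d records (%s), %d distinct sequences\n",
              nrow(x$records),
              paste(sprintf("%s: %d", names(table(x$records$locus)),
                            as.integer(table(x$records$locus))), collapse = ", "),
              length(x$index)))
  invisible(x)
}

#' Read an allele reference library from FASTA
#'
#' Headers are taken verbatim as allele labels; sequences are upcased and
#' must contain only A/C/G/T.
#'
#' @param path Path to a FASTA file.
#' @return An [allele_library()].
#' @export
read_allele_library <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop(sprintf("empty allele library: %s", path))
  allele_library(names(seqs), as.character(seqs))
}

#' Write an allele library (or named sequences) as FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param x An [allele_library()] or a named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "allele_library")) {
    x <- setNames(x$records$sequence, x$records$name)
  }
  ss <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Exact in-silico PCR of one allele with a degenerate primer pair
#'
#' Finds the 5'-most exact (degeneracy-aware, zero-mismatch) match of the
#' forward primer on the sense strand and the 5'-most exact match of the
#' reverse complement of the reverse primer downstream of it. The amplicon
#' spans from the forward-site start to the reverse-site end (1-based
#' inclusive) and includes the primer-binding regions; `insert` is the
#' primer-stripped view used for clustering and resolvability.
#'
#' @param sequence Allele sequence (A/C/G/T), or an `allele_library` record
#'   row passed as its `sequence` string.
#' @param primers A [primer_pair()].
#' @param allele_name Optional label carried into the result.
#' @return A list with `allele_name`, `sequence`, `insert`, `start`, `end`,
#'   `length`, or `NULL` (not amplified) when either primer site is absent or
#'   the reverse site precedes the forward site.
#' @export
extract_amplicon <- function(sequence, primers, allele_name = NA_character_) {
  stopifnot(inherits(primers, "primer_pair"))
  subject <- Biostrings::DNAString(sequence)
  fwd <- Biostrings::matchPattern(primers$forward, subject, fixed = FALSE)
  if (length(fwd) == 0L) return(NULL)
  f_start <- BiocGenerics::start(fwd)[1]
  f_end <- BiocGenerics::end(fwd)[1]
  rc_rev <- revcomp(primers$reverse)
  rev <- Biostrings::matchPattern(rc_rev, subject, fixed = FALSE)
  if (length(rev) == 0L) return(NULL)
  keep <- BiocGenerics::start(rev) > f_end
  if (!any(keep)) return(NULL)
  r_start <- BiocGenerics::start(rev)[keep][1]
  r_end <- BiocGenerics::end(rev)[keep][1]
  amp <- substr(sequence, f_start, r_end)
  list(allele_name = allele_name,
       sequence = amp,
       insert = substr(sequence, f_end + 1L, r_start - 1L),
       start = f_start,
       end = r_end,
       length = r_end - f_start + 1L)
}

#' Amplicon resolvability of an allele library under a primer pair
#'
#' Performs in-silico PCR on every allele and partitions the amplified
#' alleles into those with a unique insert sequence ("specific") and
#' equivalence classes of alleles sharing an identical insert
#' ("group-specific allele level"). Fractions are computed over amplified
#' alleles only; non-amplified alleles are reported but excluded from both
#' fractions. Resolvability is computed on the primer-stripped insert, since
#' primer-region bases are dictated by the primer rather than the template.
#'
#' @param library An [allele_library()].
#' @param primers A [primer_pair()].
#' @return A list of class `resolvability_report`: `per_allele` data frame
#'   (allele, status, group_members, amplicon_length), `fraction_unique` and
#'   `fraction_group` (percent of amplified alleles), `n_amplified`, and
#'   `groups` (named list of member vectors, labels = sorted names joined
#'   by "/").
#' @export
resolvability <- function(library, primers) {
  stopifnot(inherits(library, "allele_library"))
  recs <- library$records
  amps <- lapply(seq_len(nrow(recs)), function(i) {
    extract_amplicon(recs$sequence[i], primers, allele_name = recs$name[i])
  })
  amplified <- !vapply(amps, is.null, logical(1))
  insert <- rep(NA_character_, nrow(recs))
  amp_len <- rep(NA_integer_, nrow(recs))
  insert[amplified] <- vapply(amps[amplified], `[[`, character(1), "insert")
  amp_len[amplified] <- vapply(amps[amplified], `[[`, integer(1), "length")

  status <- rep("not_amplified", nrow(recs))
  group_members <- rep(NA_character_, nrow(recs))
  groups <- list()
  if (any(amplified)) {
    tab <- split(recs$name[amplified], insert[amplified])
    for (members in tab) {
      members <- sort(members)
      sel <- recs$name %in% members
      if (length(members) == 1L) {
        status[sel] <- "unique"
      } else {
        status[sel] <- "group"
        label <- paste(members, collapse = "/")
        group_members[sel] <- label
        groups[[label]] <- members
      }
    }
  }
  n_amp <- sum(amplified)
  structure(list(
    per_allele = data.frame(allele = recs$name, status = status,
                            group_members = group_members,
                            amplicon_length = amp_len,
                            stringsAsFactors = FALSE),
    fraction_unique = if (n_amp) 100 * sum(status == "unique") / n_amp else NA_real_,
    fraction_group = if (n_amp) 100 * sum(status == "group") / n_amp else NA_real_,
    n_amplified = n_amp,
    groups = if (length(groups)) groups[order(names(groups))] else groups
  ), class = "resolvability_report")
}

#' @export
print.resolvability_report <- function(x, ...) {
  cat(sprintf(
    "resolvability: %d amplified; %.1f%% specific, %.1f%% group-resolved (%d groups)\n",
    x$n_amplified, x$fraction_unique, x$fraction_group, length(x$groups)))
  invisible(x)
}

#' Write a resolvability report as TSV plus a JSON summary
#'
#' @param report A [resolvability()] result.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @export
write_resolvability <- function(report, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "resolvability_report"))
  if (!is.null(tsv_path)) {
    write.table(report$per_allele, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE, na = "")
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      n_amplified = report$n_amplified,
      fraction_unique = report$fraction_unique,
      fraction_group = report$fraction_group,
      n_groups = length(report$groups)
    ), json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
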