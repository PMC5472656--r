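# End-to-end orchestration: demultiplex -> clean -> join -> dereplicate ->
# filter -> chimera -> artifact -> identify -> genotype -> haplotypes,
# with per-stage artifacts and a loss-accounting stats JSON.

#' Pipeline run configuration
#'
#' All stage parameters default to the published pipeline settings: Phred 17
#' end trimming, ungapped joining at minimum 80 percent identity over at
#' least 35 nt, minimum cluster size 10, at most 20 retained clusters,
#' identity floor 0.95 for novel candidates, insert length tolerance 15 nt.
#'
#' @param library_fasta Path to the allele reference FASTA.
#' @param barcodes_tsv Path to a TSV with columns `sample`, `barcode`.
#' @param fastq1,fastq2 Paths to the paired FASTQ files.
#' @param out_dir Output directory.
#' @param primers A [primer_pair()] (default the short 320-nt pair).
#' @param q_min,min_overlap,min_match,min_reads,max_clusters,min_identity
#'   Stage parameters (see the stage functions).
#' @param length_tol Insert length tolerance for [artifact_filter()].
#' @param expected_insert_len Expected insert length; default derived from
#'   the primer pair's expected product minus both primer lengths.
#' @param min_dominant_frac Read fraction defining a dominant cluster.
#' @param nj_boot Bootstrap replicates for locus placement.
#' @param population Population label for haplotype inference.
#' @param seed Integer seed (bootstraps).
#' @return A `run_config` list.
#' @export
run_config <- function(library_fasta, barcodes_tsv, fastq1, fastq2, out_dir,
                       primers = sla_primers("short"), q_min = 17L,
                       min_overlap = 35L, min_match = 0.80, min_reads = 10L,
                       max_clusters = 20L, min_identity = 0.95,
                       length_tol = 15L, expected_insert_len = NULL,
                       min_dominant_frac = 0.05, nj_boot = 1000L,
                       population = "pop", seed = 42L) {
  stopifnot(inherits(primers, "primer_pair"))
  if (is.null(expected_insert_len)) {
    expected_insert_len <- primers$expected_product_nt -
      nchar(primers$forward) - nchar(primers$reverse)
  }
  stopifnot(q_min >= 0, min_overlap >= 1, min_match > 0, min_match <= 1,
            min_reads >= 1, max_clusters >= 1, min_identity > 0,
            min_identity <= 1, length_tol >= 0, expected_insert_len > 0,
            min_dominant_frac >= 0, min_dominant_frac <= 1, nj_boot >= 1)
  structure(list(library_fasta = library_fasta, barcodes_tsv = barcodes_tsv,
                 fastq1 = fastq1, fastq2 = fastq2, out_dir = out_dir,
                 primers = primers, q_min = as.integer(q_min),
                 min_overlap = as.integer(min_overlap), min_match = min_match,
                 min_reads = as.integer(min_reads),
                 max_clusters = as.integer(max_clusters),
                 min_identity = min_identity,
                 length_tol = as.integer(length_tol),
                 expected_insert_len = as.integer(expected_insert_len),
                 min_dominant_frac = min_dominant_frac,
                 nj_boot = as.integer(nj_boot), population = population,
                 seed = as.integer(seed)),
            class = "run_config")
}

read_barcode_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "barcode") %in% names(df)))
  setNames(toupper(df$barcode), df$sample)
}

#' Run the full typing pipeline
#'
#' Executes demultiplexing, quality trimming, pair merging, dereplication,
#' size filtering, chimera and artifact flagging, allele calling, novel
#' registration, per-sample genotyping and haplotype inference; writes
#' per-stage artifacts and a stats JSON mirroring the stage loss accounting.
#' Typing-failed samples (no usable clusters, or dominant clusters all
#' off-size) are reported, not fatal.
#'
#' @param config A [run_config()].
#' @return A list of class `pipeline_report`: `stats`, `clusters`, `calls`,
#'   `genotypes`, `novels`, `haplotypes`, `config`; written artifacts under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (p in c(config$library_fasta, config$barcodes_tsv, config$fastq1,
              config$fastq2)) {
    if (!file.exists(p)) stop(sprintf("missing input: %s", p))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  library <- read_allele_library(config$library_fasta)
  barcodes <- read_barcode_table(config$barcodes_tsv)
  index <- amplicon_index(library, config$primers)
  pairs <- read_fastq_pairs(config$fastq1, config$fastq2)
  message(sprintf("[demultiplex] %d read pairs in", nrow(pairs)))

  dmx <- demultiplex(pairs, barcodes, config$primers)
  asn <- dmx$assigned
  message(sprintf("[demultiplex] %d assigned, %s",
                  nrow(asn),
                  paste(sprintf("%s=%d", names(dmx$rejected), dmx$rejected),
                        collapse = ", ")))

  t1 <- quality_trim(asn$seq1, asn$qual1, config$q_min)
  t2 <- quality_trim(asn$seq2, asn$qual2, config$q_min)
  keep <- !t1$discarded & !t2$discarded
  n_trim_discard <- sum(!keep)
  message(sprintf("[clean] %d pairs discarded empty after Q%d end trimming",
                  n_trim_discard, config$q_min))

  merged <- merge_pairs_batch(t1$seqs[keep], t1$quals[keep],
                              t2$seqs[keep], t2$quals[keep],
                              config$min_overlap, config$min_match)
  joined <- !is.na(merged$sequence)
  message(sprintf("[join] %d joined, %d unjoined", sum(joined),
                  sum(!joined)))
  sample_of <- asn$sample[keep][joined]
  merged_seq <- merged$sequence[joined]

  samples <- names(barcodes)
  clusters_all <- list()
  stats_samples <- list()
  for (s in samples) {
    seqs <- merged_seq[sample_of == s]
    cl <- dereplicate(seqs, sample = s)
    retained <- size_filter(cl, config$min_reads, config$max_clusters)
    retained <- detect_chimeras(retained)
    retained <- artifact_filter(retained, config$expected_insert_len,
                                config$length_tol)
    passing <- retained[!retained$chimera & !retained$splice_variant &
                          !retained$off_size, , drop = FALSE]
    dom <- retained[!retained$chimera & !retained$splice_variant, , drop = FALSE]
    dom <- if (nrow(dom)) {
      dom[dom$size / sum(dom$size) >= config$min_dominant_frac, , drop = FALSE]
    } else dom
    typing_failed <- nrow(passing) == 0L ||
      (nrow(dom) > 0L && all(dom$off_size))
    clusters_all[[s]] <- retained
    stats_samples[[s]] <- list(
      merged_reads = length(seqs),
      clusters = nrow(cl),
      retained_clusters = nrow(retained),
      chimera_clusters = sum(retained$chimera),
      splice_variant_clusters = sum(retained$splice_variant),
      off_size_clusters = sum(retained$off_size),
      typing_failed = typing_failed)
    message(sprintf(
      "[cluster] %s: %d merged reads -> %d clusters, %d retained (chimera %d, splice %d, off-size %d)%s",
      s, length(seqs), nrow(cl), nrow(retained), sum(retained$chimera),
      sum(retained$splice_variant), sum(retained$off_size),
      if (typing_failed) " TYPING FAILED" else ""))
  }
  clusters <- do.call(rbind, c(clusters_all,
                               list(make.row.names = FALSE)))
  if (is.null(clusters)) {
    clusters <- artifact_filter(detect_chimeras(dereplicate(character(0))),
                                config$expected_insert_len)
  }

  calls <- match_clusters(clusters, index, config$min_identity)
  novels <- call_novels(calls)
  # label novel calls with their registry id for downstream tables
  calls$ns_id <- novels$ns_id[match(calls$sequence, novels$sequence)]

  genotypes <- lapply(setNames(samples, samples), function(s) {
    g <- genotype_sample(calls[calls$sample == s, , drop = FALSE], sample = s)
    g$typing_failed <- g$typing_failed || stats_samples[[s]]$typing_failed
    g
  })

  gt_rows <- calls[calls$status != "unclassified", , drop = FALSE]
  gt_rows$allele <- ifelse(is.na(gt_rows$match), gt_rows$ns_id, gt_rows$match)
  gt_df <- data.frame(animal = gt_rows$sample, locus = gt_rows$locus,
                      allele = gt_rows$allele, stringsAsFactors = FALSE)
  gt_df <- gt_df[!is.na(gt_df$allele), , drop = FALSE]
  haps <- if (nrow(gt_df)) {
    suppressWarnings(infer_haplotypes(gt_df, population = config$population))
  } else NULL

  stats <- list(
    reads_in = nrow(pairs),
    demultiplex = list(assigned = nrow(asn),
                       rejected = as.list(dmx$rejected)),
    clean = list(pairs_discarded = n_trim_discard),
    join = list(joined = sum(joined), unjoined = sum(!joined)),
    samples = stats_samples,
    n_novel_sequences = nrow(novels),
    typing_failed_samples =
      samples[vapply(genotypes, `[[`, logical(1), "typing_failed")]
  )

  write_pipeline_artifacts(config, clusters, calls, genotypes, novels, haps,
                           stats)
  structure(list(stats = stats, clusters = clusters, calls = calls,
                 genotypes = genotypes, novels = novels, haplotypes = haps,
                 config = config),
            class = "pipeline_report")
}

write_pipeline_artifacts <- function(config, clusters, calls, genotypes,
                                     novels, haps, stats) {
  out <- config$out_dir
  write.table(clusters, file.path(out, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(clusters)) {
    nm <- sprintf("%s_cluster%d_size%d", clusters$sample, clusters$rank,
                  clusters$size)
    write_fasta(setNames(clusters$sequence, nm),
                file.path(out, "clusters.fasta"))
  }
  write.table(calls, file.path(out, "calls.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  write.table(novels, file.path(out, "novel_registry.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  gt <- do.call(rbind, lapply(genotypes, function(g) {
    if (nrow(g$calls) == 0L) {
      return(data.frame(sample = g$sample, locus = NA_character_,
                        call = NA_character_, status = "typing_failed",
                        reads = NA_integer_, fraction = NA_real_,
                        flags = "", stringsAsFactors = FALSE))
    }
    data.frame(sample = g$sample, locus = g$calls$locus,
               call = ifelse(is.na(g$calls$match),
                             ifelse(is.na(g$calls$ns_id %||% NA_character_),
                                    g$calls$closest_match, g$calls$ns_id),
                             g$calls$match),
               status = g$calls$status, reads = g$calls$read_count,
               fraction = g$calls$read_fraction,
               flags = ifelse(g$calls$locus %in% g$duplication_flags,
                              "duplicated_locus", ""),
               stringsAsFactors = FALSE)
  }))
  write.table(gt, file.path(out, "genotypes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  if (!is.null(haps)) write_haplotypes(haps, out)
  jsonlite::write_json(stats, file.path(out, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf(
    "pipeline report: %d pairs in, %d assigned, %d joined; %d samples, %d novel sequence(s)\n",
    x$stats$reads_in, x$stats$demultiplex$assigned, x$stats$join$joined,
    length(x$genotypes), x$stats$n_novel_sequences))
  invisible(x)
}
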