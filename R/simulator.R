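# Synthetic fixture generation: allele libraries with embedded primer sites,
# haplotypes, sample barcodes, and barcoded paired-end reads with ground truth.

#' Generate a fixture allele library, haplotypes, primers and barcodes
#'
#' Builds a synthetic SLA class I reference: a shared ancestral insert is
#' diverged once per locus (`locus_divergence` substitutions) and then once
#' per allele (`divergence` substitutions), so between-locus distances exceed
#' within-locus distances, mimicking the classical loci. The published short
#' primer sites are embedded verbatim around every insert so the real primers
#' amplify every fixture allele; inserts are guaranteed pairwise distinct.
#' Haplotypes carry one allele per locus, sampled without replacement.
#'
#' @param n_alleles_per_locus Alleles per locus (>= 1).
#' @param divergence Substitutions from the locus ancestor per allele (>= 1).
#' @param seed Integer seed; the same seed reproduces the pool byte for byte.
#' @param n_samples Number of barcoded samples to provision.
#' @param insert_len Length of the primer-stripped insert (default 282 nt,
#'   the short-amplicon insert: 320 nt minus two 19-nt primer sites).
#' @param locus_divergence Substitutions from the shared root to each locus
#'   ancestor.
#' @param flank Length of random flanking sequence outside the primer sites.
#' @return An object of class `fixture_pool`: `library` ([allele_library()]),
#'   `haplotypes` (named list; each a named list of per-locus allele name
#'   vectors), `primers` ([primer_pair()]), `barcodes` (named character,
#'   sample -> 6-nt barcode, pairwise Hamming distance >= 2), `insert_len`.
#' @export
make_fixture_library <- function(n_alleles_per_locus = 4L, divergence = 6L,
                                 seed = 42L, n_samples = 6L,
                                 insert_len = 282L, locus_divergence = 40L,
                                 flank = 20L) {
  stopifnot(n_alleles_per_locus >= 1L, divergence >= 1L)
  set.seed(seed)
  primers <- sla_primers("short")
  loci <- c("SLA-1", "SLA-2", "SLA-3")
  root <- random_dna(insert_len)
  names_all <- character(0)
  seqs_all <- character(0)
  inserts_seen <- character(0)
  allele_names <- list()
  for (locus in loci) {
    ancestor <- mutate_seq(root, locus_divergence)
    locus_alleles <- character(0)
    for (i in seq_len(n_alleles_per_locus)) {
      ins <- NULL
      for (try in seq_len(200L)) {
        cand <- mutate_seq(ancestor, divergence)
        if (!(cand %in% inserts_seen)) { ins <- cand; break }
      }
      if (is.null(ins)) {
        stop("requested alleles exceed distinct-sequence capacity of the fixture")
      }
      inserts_seen <- c(inserts_seen, ins)
      name <- sprintf("%s*%02d:01", locus, i)
      # concrete base at the reverse primer's degenerate position
      rev_concrete <- concretize_iupac(primers$reverse)
      seq <- paste0(random_dna(flank), primers$forward, ins,
                    revcomp(rev_concrete), random_dna(flank))
      names_all <- c(names_all, name)
      seqs_all <- c(seqs_all, seq)
      locus_alleles <- c(locus_alleles, name)
    }
    allele_names[[locus]] <- locus_alleles
  }
  library <- allele_library(names_all, seqs_all)
  # haplotypes: one allele per locus, sampled without replacement per locus
  perm <- lapply(allele_names, function(a) sample(a, length(a)))
  haplotypes <- lapply(seq_len(n_alleles_per_locus), function(h) {
    lapply(perm, `[[`, h)
  })
  names(haplotypes) <- sprintf("HpSim-%d", seq_len(n_alleles_per_locus))
  barcodes <- make_barcodes(n_samples)
  names(barcodes) <- sprintf("S%d", seq_len(n_samples))
  structure(list(library = library, haplotypes = haplotypes,
                 primers = primers, barcodes = barcodes,
                 insert_len = insert_len),
            class = "fixture_pool")
}

# Replace each degenerate position by a random member of its IUPAC class.
concretize_iupac <- function(x) {
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  paste0(vapply(chars, function(ch) {
    exp <- strsplit(IUPAC_MAP[[ch]], "", fixed = TRUE)[[1]]
    if (length(exp) == 1L) exp else sample(exp, 1L)
  }, character(1)), collapse = "")
}

# Greedy sample of 6-nt barcodes with pairwise Hamming distance >= 2.
make_barcodes <- function(n, width = 6L) {
  out <- character(0)
  guard <- 0L
  while (length(out) < n) {
    guard <- guard + 1L
    if (guard > 10000L) stop("cannot find enough distinct barcodes")
    cand <- random_dna(width)
    ok <- all(vapply(out, function(b) hamming(b, cand) >= 2L, logical(1)))
    if (ok) out <- c(out, cand)
  }
  out
}

hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

#' Simulation settings for barcoded paired-end amplicon reads
#'
#' Defaults reflect the study conditions the pipeline is meant for: 2 x
#' 250-nt reads, a per-allele depth of 2,000 read pairs scaled by
#' locus-specific transcription weights SLA-2 > SLA-1 >> SLA-3, a 0.1 percent
#' mean substitution error rate driven by a per-cycle quality profile
#' declining from Q37 to Q22, 30 percent barcode-free contaminant pairs
#' (emulating the PhiX spike-in), 2 percent single-crossover chimeras and 1
#' percent overlong splice-variant templates.
#'
#' @param pool A [make_fixture_library()] pool.
#' @param genotypes Named list sample -> character(2) of haplotype ids from
#'   the pool; `NULL` assigns a deterministic mix of homozygous and
#'   heterozygous genotypes across the pool's samples.
#' @param depth_per_allele Read pairs per allele before locus weighting.
#' @param locus_weights Relative transcription weights per locus.
#' @param substitution_rate Mean per-base substitution error rate in `[0,1]`;
#'   realised per-base error probabilities scale with the drawn quality.
#' @param chimera_rate Fraction of a sample's read pairs emitted as
#'   two-parent single-crossover chimeras (requires >= 2 alleles).
#' @param spikein_fraction Fraction of read pairs emitted as barcode-free
#'   random contaminants.
#' @param splice_variant_rate Fraction of read pairs emitted from an insert
#'   lengthened by a 128-nt stop-codon-bearing filler (alternative-splicing
#'   artifact model).
#' @param read_length Read length in nt.
#' @param quality List with `q_start`, `q_end` (mean Phred at first/last
#'   cycle) and `sd` (Gaussian jitter), clamped to `[2, 40]`.
#' @param seed Integer seed for all randomness in [simulate_reads()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(pool, genotypes = NULL, depth_per_allele = 2000L,
                       locus_weights = c("SLA-1" = 1.0, "SLA-2" = 1.5,
                                         "SLA-3" = 0.3),
                       substitution_rate = 0.001, chimera_rate = 0.02,
                       spikein_fraction = 0.30, splice_variant_rate = 0.01,
                       read_length = 250L,
                       quality = list(q_start = 37, q_end = 22, sd = 3),
                       seed = 42L) {
  stopifnot(inherits(pool, "fixture_pool"))
  rates <- c(substitution_rate, chimera_rate, spikein_fraction,
             splice_variant_rate)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (depth_per_allele < 1L) stop("depth_per_allele must be >= 1")
  if (any(locus_weights <= 0)) stop("locus_weights must be positive")
  if (is.null(genotypes)) {
    K <- length(pool$haplotypes)
    hp <- names(pool$haplotypes)
    genotypes <- lapply(seq_along(pool$barcodes), function(i) {
      h1 <- hp[((i - 1L) %% K) + 1L]
      if (i %% 2L == 1L) c(h1, h1) else c(h1, hp[(i %% K) + 1L])
    })
    names(genotypes) <- names(pool$barcodes)
  }
  for (s in names(genotypes)) {
    if (!all(genotypes[[s]] %in% names(pool$haplotypes))) {
      stop(sprintf("genotype of sample %s names unknown haplotypes", s))
    }
    if (!s %in% names(pool$barcodes)) {
      stop(sprintf("sample %s has no barcode in the pool", s))
    }
  }
  structure(list(genotypes = genotypes, depth_per_allele = depth_per_allele,
                 locus_weights = locus_weights,
                 substitution_rate = substitution_rate,
                 chimera_rate = chimera_rate,
                 spikein_fraction = spikein_fraction,
                 splice_variant_rate = splice_variant_rate,
                 read_length = as.integer(read_length), quality = quality,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# 128-nt filler with stop codons in all three reading frames wherever it
# lands (TAA at every 4th position covers frames 0, 1 and 2).
splice_filler <- function() strrep("TAAA", 32L)

#' Simulate barcoded paired-end amplicon reads with ground truth
#'
#' For each sample and each allele of its genotype, emits
#' `depth_per_allele * locus_weight` read pairs: mate 1 is barcode + forward
#' primer + amplicon prefix, mate 2 is barcode + reverse primer +
#' reverse-complemented amplicon prefix, both truncated to the read length.
#' Individual pair slots are stochastically replaced by barcode-free
#' spike-ins, two-parent chimeras (single crossover at a uniform insert
#' position at least 40 nt from either end) or splice-variant templates.
#' Substitution errors are drawn per base from the realised quality profile.
#'
#' @param pool A [make_fixture_library()] pool.
#' @param config A [sim_config()].
#' @return A list of class `sim_result`: `reads` (data frame id, seq1, qual1,
#'   seq2, qual2), and `truth` with `allele_counts` (sample, allele,
#'   clean_reads), `expected` (sample -> allele set), `artifacts` (sample,
#'   chimera_reads, splice_reads), `chimeras` (per-chimera parents and
#'   crossover), `spikein_reads`, `total_pairs`.
#' @export
simulate_reads <- function(pool, config) {
  stopifnot(inherits(pool, "fixture_pool"), inherits(config, "sim_config"))
  set.seed(config$seed)
  primers <- pool$primers
  bclen <- nchar(pool$barcodes[[1]])
  min_len <- bclen + nchar(primers$forward) + 35L
  if (config$read_length < min_len) {
    stop(sprintf("read_length must be >= barcode+primer+35 = %d", min_len))
  }
  recs <- pool$library$records
  amp_cache <- lapply(setNames(recs$name, recs$name), function(nm) {
    extract_amplicon(recs$sequence[recs$name == nm], primers, nm)
  })
  not_amp <- vapply(amp_cache, is.null, logical(1))
  if (any(not_amp)) {
    stop(sprintf("fixture allele(s) not amplifiable: %s",
                 paste(names(amp_cache)[not_amp], collapse = ", ")))
  }

  amp_seq <- vapply(amp_cache, `[[`, character(1), "sequence")
  amp_rc <- setNames(revcomp(amp_seq), names(amp_seq))
  amp_insert <- vapply(amp_cache, `[[`, character(1), "insert")
  plen_f <- nchar(primers$forward)
  plen_r <- nchar(primers$reverse)
  rl <- config$read_length

  per_sample <- vector("list", length(config$genotypes))
  chim_records <- list()

  for (si in seq_along(config$genotypes)) {
    s <- names(config$genotypes)[si]
    gt <- config$genotypes[[s]]
    alleles <- unique(unlist(lapply(pool$haplotypes[gt], unlist),
                             use.names = FALSE))
    loci <- locus_of(alleles)
    depth <- round(config$depth_per_allele * config$locus_weights[loci])
    slots_allele <- rep(alleles, times = depth)
    nslots <- length(slots_allele)
    if (nslots == 0L) next
    u <- runif(nslots)
    f_s <- config$spikein_fraction
    f_c <- config$chimera_rate
    f_v <- config$splice_variant_rate
    type <- rep("clean", nslots)
    type[u < f_s + f_c + f_v] <- "splice"
    type[u < f_s + f_c] <- if (length(alleles) >= 2L) "chimera" else "clean"
    type[u < f_s] <- "spikein"
    bc <- pool$barcodes[[s]]

    # vectorised clean templates for every slot, artifact slots overwritten
    t1 <- substr(paste0(bc, amp_seq[slots_allele]), 1L, rl)
    t2 <- substr(paste0(bc, amp_rc[slots_allele]), 1L, rl)

    for (k in which(type == "chimera")) {
      a <- slots_allele[k]
      b <- sample(setdiff(alleles, a), 1L)
      L <- nchar(amp_insert[[a]])
      cp <- sample(seq(40L, L - 40L), 1L)
      chim_insert <- paste0(substr(amp_insert[[a]], 1L, cp),
                            substr(amp_insert[[b]], cp + 1L, L))
      amp <- paste0(substr(amp_seq[[a]], 1L, plen_f), chim_insert,
                    substr(amp_seq[[b]], nchar(amp_seq[[b]]) - plen_r + 1L,
                           nchar(amp_seq[[b]])))
      t1[k] <- substr(paste0(bc, amp), 1L, rl)
      t2[k] <- substr(paste0(bc, revcomp(amp)), 1L, rl)
      chim_records[[length(chim_records) + 1L]] <-
        data.frame(sample = s, parent_a = a, parent_b = b, crossover = cp,
                   stringsAsFactors = FALSE)
    }
    for (k in which(type == "splice")) {
      a <- slots_allele[k]
      ins <- amp_insert[[a]]
      L <- nchar(ins)
      mid <- L %/% 2L
      long_ins <- paste0(substr(ins, 1L, mid), splice_filler(),
                         substr(ins, mid + 1L, L))
      amp <- paste0(substr(amp_seq[[a]], 1L, plen_f), long_ins,
                    substr(amp_seq[[a]], nchar(amp_seq[[a]]) - plen_r + 1L,
                           nchar(amp_seq[[a]])))
      t1[k] <- substr(paste0(bc, amp), 1L, rl)
      t2[k] <- substr(paste0(bc, revcomp(amp)), 1L, rl)
    }
    for (k in which(type == "spikein")) {
      t1[k] <- spike_read(rl, pool$barcodes)
      t2[k] <- spike_read(rl, pool$barcodes)
    }

    ms <- rep(s, nslots); ms[type == "spikein"] <- NA_character_
    ma <- slots_allele; ma[type != "clean"] <- NA_character_
    per_sample[[si]] <- list(t1 = t1, t2 = t2, sample = ms, allele = ma,
                             type = type)
  }

  templ1 <- unlist(lapply(per_sample, `[[`, "t1"), use.names = FALSE)
  templ2 <- unlist(lapply(per_sample, `[[`, "t2"), use.names = FALSE)
  meta_sample <- unlist(lapply(per_sample, `[[`, "sample"), use.names = FALSE)
  meta_allele <- unlist(lapply(per_sample, `[[`, "allele"), use.names = FALSE)
  meta_type <- unlist(lapply(per_sample, `[[`, "type"), use.names = FALSE)

  n <- length(templ1)
  noisy1 <- add_read_noise(templ1, config)
  noisy2 <- add_read_noise(templ2, config)
  reads <- data.frame(id = sprintf("read%06d", seq_len(n)),
                      seq1 = noisy1$seqs, qual1 = noisy1$quals,
                      seq2 = noisy2$seqs, qual2 = noisy2$quals,
                      stringsAsFactors = FALSE)

  clean <- meta_type == "clean"
  allele_counts <- as.data.frame(table(sample = meta_sample[clean],
                                       allele = meta_allele[clean]),
                                 stringsAsFactors = FALSE)
  names(allele_counts)[3] <- "clean_reads"
  allele_counts <- allele_counts[allele_counts$clean_reads > 0L, ]
  allele_counts$sample <- as.character(allele_counts$sample)
  allele_counts$allele <- as.character(allele_counts$allele)
  rownames(allele_counts) <- NULL
  expected <- lapply(config$genotypes, function(gt) {
    sort(unique(unlist(lapply(pool$haplotypes[gt], unlist), use.names = FALSE)))
  })
  art <- data.frame(sample = names(config$genotypes), stringsAsFactors = FALSE)
  art$chimera_reads <- vapply(art$sample, function(s)
    sum(meta_type == "chimera" & meta_sample == s, na.rm = TRUE), integer(1))
  art$splice_reads <- vapply(art$sample, function(s)
    sum(meta_type == "splice" & meta_sample == s, na.rm = TRUE), integer(1))
  truth <- list(
    allele_counts = allele_counts,
    expected = expected,
    artifacts = art,
    chimeras = if (length(chim_records)) do.call(rbind, chim_records) else NULL,
    spikein_reads = sum(meta_type == "spikein"),
    total_pairs = n
  )
  structure(list(reads = reads, truth = truth), class = "sim_result")
}

spike_read <- function(len, barcodes) {
  x <- random_dna(len)
  bclen <- nchar(barcodes[[1]])
  while (substr(x, 1L, bclen) %in% barcodes) {
    x <- paste0(random_dna(bclen), substr(x, bclen + 1L, len))
  }
  x
}

# Draw per-cycle qualities (linear mean decline + Gaussian jitter, clamped to
# [2, 40]) and apply substitution errors with per-base probability
# proportional to 10^(-Q/10), scaled so the mean error rate over the profile
# equals config$substitution_rate.
add_read_noise <- function(seqs, config) {
  n <- length(seqs)
  if (n == 0L) return(list(seqs = character(0), quals = character(0)))
  q0 <- config$quality$q_start; q1 <- config$quality$q_end
  sdq <- config$quality$sd
  prof_full <- seq(q0, q1, length.out = config$read_length)
  scale <- if (config$substitution_rate > 0) {
    config$substitution_rate / mean(10^(-prof_full / 10))
  } else 0
  out_seq <- character(n); out_qual <- character(n)
  lens <- nchar(seqs)
  for (L in unique(lens)) {
    idx <- which(lens == L)
    k <- length(idx)
    prof <- prof_full[seq_len(L)]
    Q <- matrix(round(rep(prof, each = k) + rnorm(k * L, 0, sdq)),
                nrow = k, ncol = L)
    Q[Q < 2L] <- 2L; Q[Q > 40L] <- 40L
    chm <- matrix(unlist(strsplit(seqs[idx], "", fixed = TRUE), use.names = FALSE),
                  nrow = k, byrow = TRUE)
    if (scale > 0) {
      perr <- pmin(1, scale * 10^(-Q / 10))
      hit <- which(matrix(runif(k * L), nrow = k) < perr)
      if (length(hit)) {
        cur <- chm[hit]
        shift <- sample(1:3, length(hit), replace = TRUE)
        chm[hit] <- DNA_BASES[((match(cur, DNA_BASES) - 1L + shift) %% 4L) + 1L]
      }
    }
    out_seq[idx] <- do.call(paste0, as.data.frame(chm, stringsAsFactors = FALSE))
    qraw <- matrix(as.raw(Q + 33L), nrow = k)
    out_qual[idx] <- vapply(seq_len(k), function(i) rawToChar(qraw[i, ]),
                            character(1))
  }
  list(seqs = out_seq, quals = out_qual)
}

#' Write a simulation result and its fixture pool to disk
#'
#' Emits paired FASTQ (Phred+33), ground-truth TSVs, the fixture library
#' FASTA, the barcode TSV, and the simulation settings as YAML.
#'
#' @param pool A [make_fixture_library()] pool.
#' @param sim A [simulate_reads()] result.
#' @param config The [sim_config()] used.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(pool, sim, config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  r <- sim$reads
  write_fastq(r$seq1, r$qual1, r$id, file.path(dir, "reads_R1.fastq"))
  write_fastq(r$seq2, r$qual2, r$id, file.path(dir, "reads_R2.fastq"))
  write_fasta(pool$library, file.path(dir, "library.fasta"))
  write.table(data.frame(sample = names(pool$barcodes),
                         barcode = unname(pool$barcodes)),
              file.path(dir, "barcodes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth$allele_counts, file.path(dir, "truth_alleles.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$artifacts, file.path(dir, "truth_artifacts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- config
  cfg$genotypes <- lapply(cfg$genotypes, as.character)
  cfg$locus_weights <- as.list(cfg$locus_weights)
  if (requireNamespace("yaml", quietly = TRUE)) {
    writeLines(yaml::as.yaml(unclass(cfg)), file.path(dir, "sim_config.yaml"))
  }
  invisible(dir)
}
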