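# Breed-level haplotype inference: seed from fully homozygous animals,
# resolve heterozygotes as pairs of pool haplotypes or by complement
# subtraction, iterate to fixpoint.

CLASSICAL_LOCI <- c("SLA-1", "SLA-2", "SLA-3")

#' Construct a haplotype (per-locus allele sets)
#'
#' A haplotype is the set of SLA-1/SLA-3/SLA-2 alleles inherited together on
#' one chromosome; a locus may be empty (null, as in haplotypes lacking an
#' expressed SLA-3) or carry more than one allele (locus duplication).
#' Group-specific calls are single tokens ("a1/a2").
#'
#' @param alleles Named list locus -> character vector of allele tokens.
#' @param id Haplotype id.
#' @return A `haplotype` object.
#' @export
haplotype <- function(alleles, id = NA_character_) {
  alleles <- lapply(setNames(CLASSICAL_LOCI, CLASSICAL_LOCI), function(l) {
    sort(unique(as.character(alleles[[l]] %||% character(0))))
  })
  if (sum(lengths(alleles)) == 0L) {
    stop("a haplotype must carry at least one allele")
  }
  structure(list(id = id, alleles = alleles), class = "haplotype")
}

hap_key <- function(h) {
  paste(vapply(CLASSICAL_LOCI, function(l)
    paste(h$alleles[[l]], collapse = ","), character(1)), collapse = "|")
}

#' @export
print.haplotype <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$id, gsub("\\|", " / ", hap_key(x))))
  invisible(x)
}

# per-locus allele sets of one animal from a genotype table; NA or empty
# allele tokens (typing-failed placeholders) are ignored
animal_sets <- function(df) {
  df <- df[!is.na(df$allele) & nzchar(df$allele), , drop = FALSE]
  lapply(setNames(CLASSICAL_LOCI, CLASSICAL_LOCI), function(l) {
    sort(unique(df$allele[df$locus == l]))
  })
}

set_contains <- function(outer, inner) {
  all(vapply(CLASSICAL_LOCI, function(l)
    all(inner[[l]] %in% outer[[l]]), logical(1)))
}

set_minus <- function(a, b) {
  lapply(setNames(CLASSICAL_LOCI, CLASSICAL_LOCI), function(l)
    setdiff(a[[l]], b[[l]]))
}

set_union2 <- function(a, b) {
  lapply(setNames(CLASSICAL_LOCI, CLASSICAL_LOCI), function(l)
    sort(unique(c(a[[l]], b[[l]]))))
}

sets_equal <- function(a, b) {
  all(vapply(CLASSICAL_LOCI, function(l)
    identical(sort(a[[l]]), sort(b[[l]])), logical(1)))
}

new_hap_id <- function(k) {
  # lettered in discovery order: Hp-A.0, Hp-B.0, ..., Hp-AA.0, ...
  letters_seq <- function(i) {
    out <- ""
    while (i > 0L) {
      out <- paste0(LETTERS[((i - 1L) %% 26L) + 1L], out)
      i <- (i - 1L) %/% 26L
    }
    out
  }
  sprintf("Hp-%s.0", letters_seq(k))
}

#' Infer haplotypes of one population from per-animal allele sets
#'
#' Haplotypes are sets of SLA-1, SLA-2 and SLA-3 alleles observed together in
#' individual fully homozygous animals, or detected together in heterozygous
#' animals of the same breed that also express another defined haplotype.
#' The pool is seeded with every fully homozygous animal's allele set (at
#' most one allele at every classical locus); then, iterating to fixpoint in
#' deterministic order (animals by id, pool haplotypes by discovery order),
#' each unresolved animal is resolved either as a pair of pool haplotypes
#' whose union equals its allele set, or by complement subtraction: for a
#' pool haplotype contained in the animal's alleles, the residual is proposed
#' as a new haplotype when it carries at most `max_dup_per_locus` alleles per
#' locus. A residual that itself decomposes into two pool haplotypes marks
#' the animal as a triple-haplotype anomaly, which is reported rather than
#' force-resolved. Remaining animals are reported partial (some pool
#' haplotype contained but no valid complement) or unresolved.
#'
#' @param genotypes Data frame with columns `animal`, `locus`, `allele`
#'   (group-specific calls as single slash-joined tokens). Animals with zero
#'   calls are skipped with a warning (typing-failed).
#' @param population Population label carried into the output.
#' @param known Optional list of [haplotype()] objects (published
#'   haplotypes), consulted before new proposals; they head the pool in
#'   their given order.
#' @param max_dup_per_locus Cap on alleles per locus in a proposed
#'   complement (default 2, so duplication haplotypes can be learned from
#'   seeds but not invented beyond a duplication).
#' @return A list of class `haplotype_inference`: `pool` (list of
#'   haplotypes), `assignments` (data frame animal, status
#'   resolved|partial|unresolved|anomaly, hap1, hap2), `population`.
#' @export
infer_haplotypes <- function(genotypes, population = "pop", known = NULL,
                             max_dup_per_locus = 2L) {
  stopifnot(all(c("animal", "locus", "allele") %in% names(genotypes)))
  animals <- sort(unique(as.character(genotypes$animal)))
  sets <- lapply(setNames(animals, animals), function(a)
    animal_sets(genotypes[genotypes$animal == a, , drop = FALSE]))
  empty <- vapply(sets, function(s) sum(lengths(s)) == 0L, logical(1))
  if (any(empty)) {
    warning(sprintf("animal(s) with zero calls skipped (typing-failed): %s",
                    paste(animals[empty], collapse = ", ")))
    animals <- animals[!empty]
    sets <- sets[!empty]
  }

  pool <- list()
  keys <- character(0)
  n_new <- 0L
  add_hap <- function(alleles, id = NULL) {
    h <- haplotype(alleles, id = id %||% "")
    k <- hap_key(h)
    if (k %in% keys) return(which(keys == k))
    if (is.null(id)) {
      n_new <<- n_new + 1L
      h$id <- new_hap_id(n_new)
    }
    pool[[length(pool) + 1L]] <<- h
    keys <<- c(keys, k)
    length(pool)
  }
  for (h in known %||% list()) {
    stopifnot(inherits(h, "haplotype"))
    add_hap(h$alleles, id = h$id)
  }

  status <- setNames(rep("unresolved", length(animals)), animals)
  h1 <- setNames(rep(NA_character_, length(animals)), animals)
  h2 <- h1

  # seed: fully homozygous animals (0 or 1 allele at every classical locus)
  for (a in animals) {
    if (all(lengths(sets[[a]]) <= 1L)) {
      i <- add_hap(sets[[a]])
      status[a] <- "resolved"
      h1[a] <- pool[[i]]$id
      h2[a] <- pool[[i]]$id
    }
  }

  find_pair <- function(M) {
    for (i in seq_along(pool)) {
      for (j in i:length(pool)) {
        if (sets_equal(set_union2(pool[[i]]$alleles, pool[[j]]$alleles), M)) {
          return(c(i, j))
        }
      }
    }
    NULL
  }

  repeat {
    changed <- FALSE
    for (a in animals[status == "unresolved"]) {
      M <- sets[[a]]
      pr <- find_pair(M)
      if (!is.null(pr)) {
        status[a] <- "resolved"
        h1[a] <- pool[[pr[1]]]$id
        h2[a] <- pool[[pr[2]]]$id
        changed <- TRUE
        next
      }
      for (i in seq_along(pool)) {
        if (!set_contains(M, pool[[i]]$alleles)) next
        R <- set_minus(M, pool[[i]]$alleles)
        if (sum(lengths(R)) == 0L) next  # handled by find_pair (H,H)
        if (any(lengths(R) > max_dup_per_locus)) next
        # residual decomposing into two pool haplotypes: animal carries
        # three haplotypes -> anomaly, report rather than force-resolve
        anom <- FALSE
        for (p in seq_along(pool)) {
          for (q in p:length(pool)) {
            if (sets_equal(set_union2(pool[[p]]$alleles, pool[[q]]$alleles),
                           R)) {
              anom <- TRUE
              break
            }
          }
          if (anom) break
        }
        if (anom) {
          status[a] <- "anomaly"
          h1[a] <- pool[[i]]$id
          changed <- TRUE
          break
        }
        j <- add_hap(R)
        status[a] <- "resolved"
        h1[a] <- pool[[i]]$id
        h2[a] <- pool[[j]]$id
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }

  # remaining: partial when some pool haplotype is contained
  for (a in animals[status == "unresolved"]) {
    for (i in seq_along(pool)) {
      if (set_contains(sets[[a]], pool[[i]]$alleles)) {
        status[a] <- "partial"
        h1[a] <- pool[[i]]$id
        break
      }
    }
  }

  assignments <- data.frame(animal = animals, status = unname(status),
                            hap1 = unname(h1), hap2 = unname(h2),
                            stringsAsFactors = FALSE)
  structure(list(pool = pool, assignments = assignments,
                 population = population, animal_sets = sets),
            class = "haplotype_inference")
}

#' @export
print.haplotype_inference <- function(x, ...) {
  cat(sprintf("haplotype inference (%s): pool of %d, %d/%d animals resolved\n",
              x$population, length(x$pool),
              sum(x$assignments$status == "resolved"), nrow(x$assignments)))
  invisible(x)
}

#' Per-haplotype carrier prevalence
#'
#' Prevalence is the percentage of animals carrying the haplotype in any
#' resolved or partial slot among animals with at least one call. A
#' chromosome-frequency column (carried copies over 2N) is exposed as a
#' secondary measure.
#'
#' @param inference A [infer_haplotypes()] result.
#' @param digits Rounding for the percentage (default 0).
#' @return Data frame: hap, carriers, n_animals, prevalence_pct,
#'   chromosome_freq_pct, population.
#' @export
prevalence <- function(inference, digits = 0) {
  stopifnot(inherits(inference, "haplotype_inference"))
  asn <- inference$assignments
  n <- nrow(asn)
  if (n == 0L) stop("empty population")
  out <- do.call(rbind, lapply(inference$pool, function(h) {
    carried <- asn$hap1 %in% h$id | asn$hap2 %in% h$id
    copies <- (asn$hap1 %in% h$id) + (!is.na(asn$hap2) & asn$hap2 %in% h$id)
    data.frame(hap = h$id, carriers = sum(carried, na.rm = TRUE),
               n_animals = n,
               prevalence_pct = round(100 * sum(carried, na.rm = TRUE) / n,
                                      digits),
               chromosome_freq_pct = round(100 * sum(copies) / (2 * n), 1),
               population = inference$population,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read a known-haplotype table
#'
#' TSV with columns `id`, `SLA-1`, `SLA-3`, `SLA-2` (the publication column
#' order); multiple alleles at one locus are comma-separated, group tokens
#' keep their slashes, and `null`/`-`/empty mark a missing locus.
#'
#' @param path TSV path.
#' @return A list of [haplotype()] objects.
#' @export
read_known_haplotypes <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character", na.strings = NULL)
  stopifnot(all(c("id", CLASSICAL_LOCI) %in% names(df)))
  lapply(seq_len(nrow(df)), function(i) {
    al <- lapply(setNames(CLASSICAL_LOCI, CLASSICAL_LOCI), function(l) {
      x <- df[[l]][i]
      if (is.na(x) || x %in% c("", "-", "null")) character(0)
      else trimws(strsplit(x, ",", fixed = TRUE)[[1]])
    })
    haplotype(al, id = df$id[i])
  })
}

#' Write haplotype inference results as TSVs
#'
#' @param inference A [infer_haplotypes()] result.
#' @param dir Output directory.
#' @export
write_haplotypes <- function(inference, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pool_df <- do.call(rbind, lapply(inference$pool, function(h) {
    data.frame(id = h$id,
               `SLA-1` = paste(h$alleles[["SLA-1"]], collapse = ","),
               `SLA-3` = paste(h$alleles[["SLA-3"]], collapse = ","),
               `SLA-2` = paste(h$alleles[["SLA-2"]], collapse = ","),
               check.names = FALSE, stringsAsFactors = FALSE)
  }))
  write.table(pool_df, file.path(dir, "haplotype_pool.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(inference$assignments, file.path(dir, "haplotype_assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(prevalence(inference), file.path(dir, "haplotype_prevalence.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
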