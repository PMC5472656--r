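# Novel-allele characterisation: exon 2-3 assembly from overlapping
# amplicons, Jukes-Cantor distances, neighbor-joining with bootstrap
# support, and phylogenetic locus placement.

#' Assemble a full exon 2-3 sequence from overlapping fragments
#'
#' The initially sequenced core amplicon is extended by an exon-2-spanning
#' fragment (overlapping the core's 5' end) and an exon-3-spanning fragment
#' (overlapping its 3' end). Each junction requires a maximal exact
#' suffix-prefix overlap of at least `min_overlap` nt; any disagreement in
#' the best candidate overlap is an assembly error naming the junction and
#' the first disagreeing position.
#'
#' @param core Core amplicon sequence.
#' @param exon2_frag Fragment overlapping the core's 5' end (may equal a
#'   prefix of the core, in which case it adds nothing).
#' @param exon3_frag Fragment overlapping the core's 3' end.
#' @param min_overlap Minimum exact junction overlap (default 30 nt).
#' @param ns_id Label for the assembled novel sequence.
#' @param exon2_span,exon3_span Optional 1-based inclusive coordinate pairs
#'   of the exon boundaries on the assembled sequence; completeness flags
#'   are set when the assembly covers them.
#' @return A list of class `assembled_sequence`: ns_id, sequence, length,
#'   overlap_left, overlap_right, exon2_span, exon3_span, complete_exon2,
#'   complete_exon3.
#' @export
assemble_exon2_3 <- function(core, exon2_frag, exon3_frag, min_overlap = 30L,
                             ns_id = NA_character_, exon2_span = NULL,
                             exon3_span = NULL) {
  stopifnot(nzchar(core), nzchar(exon2_frag), nzchar(exon3_frag))
  o_left <- best_exact_overlap(exon2_frag, core, min_overlap, "exon2/core")
  o_right <- best_exact_overlap(core, exon3_frag, min_overlap, "core/exon3")
  assembled <- paste0(substr(exon2_frag, 1L, nchar(exon2_frag) - o_left),
                      core,
                      substr(exon3_frag, o_right + 1L, nchar(exon3_frag)))
  len <- nchar(assembled)
  structure(list(
    ns_id = ns_id, sequence = assembled, length = len,
    overlap_left = o_left, overlap_right = o_right,
    exon2_span = exon2_span, exon3_span = exon3_span,
    complete_exon2 = if (is.null(exon2_span)) NA else
      exon2_span[1] >= 1L && exon2_span[2] <= len,
    complete_exon3 = if (is.null(exon3_span)) NA else
      exon3_span[1] >= 1L && exon3_span[2] <= len
  ), class = "assembled_sequence")
}

# Maximal o with suffix(left, o) == prefix(right, o) and o >= min_overlap;
# otherwise an error reporting the junction and the first disagreeing
# position (in right-fragment coordinates) of the closest candidate.
best_exact_overlap <- function(left, right, min_overlap, junction) {
  max_o <- min(nchar(left), nchar(right))
  if (max_o < min_overlap) {
    stop(sprintf("assembly error at junction %s: fragments allow at most %d nt overlap (min %d)",
                 junction, max_o, min_overlap))
  }
  best_o <- NA_integer_; best_mm <- Inf; best_pos <- NA_integer_
  for (o in max_o:min_overlap) {
    suf <- substr(left, nchar(left) - o + 1L, nchar(left))
    pre <- substr(right, 1L, o)
    if (suf == pre) return(o)
    d <- which(strsplit(suf, "")[[1]] != strsplit(pre, "")[[1]])
    if (length(d) < best_mm) {
      best_mm <- length(d); best_o <- o; best_pos <- d[1]
    }
  }
  stop(sprintf("assembly error at junction %s: best overlap (%d nt) disagrees first at position %d",
               junction, best_o, best_pos))
}

#' Jukes-Cantor distance between two aligned sequences
#'
#' `d = -(3/4) * log(1 - 4p/3)` for the proportion `p` of differing
#' compared sites; positions with a non-ACGT character in either sequence
#' are excluded from both the mismatch count and the compared length. At
#' saturation (`p >= 3/4`) the distance is set to `cap` and flagged.
#'
#' @param a,b Aligned sequences of equal length.
#' @param cap Distance assigned at saturation (default 5).
#' @return Numeric distance with attribute `saturated` (logical).
#' @export
#' @examples
#' jc_distance("ACGT", "ACGT")  # 0
jc_distance <- function(a, b, cap = 5.0) {
  if (nchar(a) != nchar(b) || nchar(a) < 1L) {
    stop("sequences must be aligned and of equal length >= 1")
  }
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  ok <- ca %in% DNA_BASES & cb %in% DNA_BASES
  if (!any(ok)) stop("no comparable (ACGT) positions")
  p <- sum(ca[ok] != cb[ok]) / sum(ok)
  if (p >= 0.75) {
    return(structure(cap, saturated = TRUE))
  }
  structure(-0.75 * log(1 - 4 * p / 3), saturated = FALSE)
}

# JC distance matrix from a character matrix (rows = taxa), with "-"/N
# excluded pairwise.
jc_from_charmat <- function(m, cap = 5.0) {
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  acgt <- matrix(m %in% DNA_BASES, nrow = n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- acgt[i, ] & acgt[j, ]
      if (!any(ok)) stop("no comparable positions between taxa")
      p <- sum(m[i, ok] != m[j, ok]) / sum(ok)
      D[i, j] <- D[j, i] <- if (p >= 0.75) cap else -0.75 * log(1 - 4 * p / 3)
    }
  }
  D
}

#' Jukes-Cantor distance matrix of aligned sequences
#'
#' @param seqs Named character vector of aligned, equal-length sequences.
#' @param cap Saturation cap passed to the distance.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
jc_distance_matrix <- function(seqs, cap = 5.0) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences must share one aligned length")
  }
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- names(seqs)
  jc_from_charmat(m, cap = cap)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining (Q-criterion agglomeration). Ties in Q are
#' broken by the lexicographically smallest pair of subtree labels (the
#' smallest leaf name each subtree contains); negative branch lengths are
#' clamped to zero with the deficit moved to the sibling branch, preserving
#' the pair's total. Additive matrices are reconstructed exactly.
#'
#' @param D Symmetric distance matrix with taxon dimnames (or a `dist`).
#' @return An unrooted `ape::phylo` tree. Two taxa yield the trivial
#'   single-edge tree; fewer is an error.
#' @export
nj_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  taxa <- rownames(D)
  if (is.null(taxa)) stop("distance matrix must carry taxon names")
  n <- nrow(D)
  if (n < 2L) stop("neighbor joining needs at least 2 taxa (3 for an internal edge)")
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  # taxon labels may contain newick metacharacters (*, :, /); build the tree
  # with placeholder labels and restore the real names afterwards
  safe <- sprintf("t%06d", seq_len(n))
  restore <- function(phy) {
    phy$tip.label <- taxa[match(phy$tip.label, safe)]
    phy
  }
  if (n == 2L) {
    txt <- sprintf("(%s:%s,%s:%s);", safe[1], fmt(D[1, 2] / 2),
                   safe[2], fmt(D[1, 2] / 2))
    return(restore(ape::read.tree(text = txt)))
  }
  nwk <- safe
  minleaf <- taxa
  repeat {
    n <- nrow(D)
    if (n == 3L) break
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key1 <- pmin(minleaf[cand[, 1]], minleaf[cand[, 2]])
    key2 <- pmax(minleaf[cand[, 1]], minleaf[cand[, 2]])
    pick <- order(key1, key2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    bi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    newd <- (D[i, ] + D[j, ] - D[i, j]) / 2
    newd <- newd[-c(i, j)]
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(bi), nwk[j], fmt(bj))
    new_min <- min(minleaf[i], minleaf[j])
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd),
               c(newd, 0))
    nwk <- c(nwk[keep], new_nwk)
    minleaf <- c(minleaf[keep], new_min)
    rownames(D) <- colnames(D) <- NULL
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(b1), nwk[2], fmt(b2),
                 nwk[3], fmt(b3))
  restore(ape::read.tree(text = txt))
}

# Canonical bipartition keys of a tree's internal nodes. Each bipartition is
# represented by the tip-label side NOT containing the reference tip (the
# alphabetically first label), so the key is rooting-invariant.
bipartition_keys <- function(phy) {
  pp <- ape::prop.part(phy)
  labels <- attr(pp, "labels")
  ref <- sort(labels)[1]
  vapply(pp, function(cl) {
    side <- sort(labels[cl])
    if (ref %in% side) side <- sort(setdiff(labels, side))
    paste(side, collapse = "|")
  }, character(1))
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the Jukes-Cantor /
#' neighbor-joining tree per replicate, and reports for each internal
#' bipartition of the point-estimate tree the percentage of replicates
#' containing it (attached as node labels).
#'
#' @param seqs Named character vector of aligned equal-length sequences
#'   (or a character matrix, rows = taxa).
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param cap Saturation cap for the distances.
#' @return The point-estimate `phylo` tree with `node.label` set to the
#'   bipartition support percentages (the all-taxa partition at the root is
#'   trivially 100).
#' @export
bootstrap_support <- function(seqs, n_reps = 1000L, seed = 42L, cap = 5.0) {
  stopifnot(n_reps >= 1L)
  m <- if (is.matrix(seqs)) seqs else {
    mm <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    rownames(mm) <- names(seqs)
    mm
  }
  point <- nj_tree(jc_from_charmat(m, cap = cap))
  keys <- bipartition_keys(point)
  counts <- setNames(integer(length(keys)), keys)
  set.seed(seed)
  L <- ncol(m)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_tree <- nj_tree(jc_from_charmat(m[, cols, drop = FALSE], cap = cap))
    rep_keys <- bipartition_keys(rep_tree)
    hit <- keys %in% rep_keys
    counts[hit] <- counts[hit] + 1L
  }
  # the empty-side key (all-taxa clade at the root) is trivially present
  counts[keys == ""] <- n_reps
  point$node.label <- round(100 * counts / n_reps)
  point
}

#' Place a novel sequence at an SLA locus by phylogeny
#'
#' Builds the Jukes-Cantor / neighbor-joining tree of the novel sequence
#' plus all library alleles over the novel sequence's span and assigns the
#' locus of the smallest enclosing clade whose library members are
#' locus-pure (at least `purity` of one locus), reporting that clade's
#' bootstrap support. When no pure enclosing clade exists the
#' nearest-neighbour locus is used and flagged low-confidence (partial
#' spans are known to scramble deeper structure).
#'
#' @param novel Novel sequence (character) or an [assemble_exon2_3()] result.
#' @param library An [allele_library()].
#' @param primers Optional [primer_pair()]: when given, library alleles are
#'   reduced to their primer-stripped amplicon inserts before alignment.
#' @param n_reps Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param purity Locus purity required of the enclosing clade (default 0.9).
#' @return A list of class `locus_assignment`: locus, support (percent,
#'   `NA` for nearest-neighbour fallback), method ("clade" or
#'   "nearest_neighbor"), low_confidence, tree (with supports), distances
#'   (novel vs each library allele).
#' @export
assign_locus <- function(novel, library, primers = NULL, n_reps = 1000L,
                         seed = 42L, purity = 0.9) {
  if (inherits(novel, "assembled_sequence")) novel <- novel$sequence
  if (nchar(novel) < 100L) {
    stop("novel span shorter than 100 nt: phylogenetic placement unreliable")
  }
  refs <- if (is.null(primers)) {
    setNames(library$records$sequence, library$records$name)
  } else {
    amplicon_index(library, primers)$inserts
  }
  if (length(refs) < 2L) stop("need at least 2 library alleles for placement")
  novel_name <- "novel_query"
  aligned <- vapply(refs, project_onto, character(1), target = novel)
  m <- do.call(rbind, strsplit(c(setNames(novel, novel_name),
                                 toupper(aligned)), "", fixed = TRUE))
  rownames(m) <- c(novel_name, names(refs))
  tree <- bootstrap_support(m, n_reps = n_reps, seed = seed)
  D <- jc_from_charmat(m)
  dists <- D[novel_name, names(refs)]

  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  ntip <- length(labels)
  sides <- lapply(pp, function(cl) {
    side <- labels[cl]
    if (novel_name %in% side) side else setdiff(labels, side)
  })
  sizes <- lengths(sides)
  ord <- order(sizes)
  for (k in ord) {
    side <- sides[[k]]
    members <- setdiff(side, novel_name)
    if (length(members) == 0L || length(side) >= ntip) next
    loci <- locus_of(members)
    tab <- sort(table(loci), decreasing = TRUE)
    if (tab[1] / length(members) >= purity) {
      return(structure(list(locus = names(tab)[1],
                            support = unname(tree$node.label[k]),
                            method = "clade", low_confidence = FALSE,
                            tree = tree, distances = dists),
                       class = "locus_assignment"))
    }
  }
  nn <- names(refs)[which.min(dists)]
  structure(list(locus = locus_of(nn), support = NA_real_,
                 method = "nearest_neighbor", low_confidence = TRUE,
                 tree = tree, distances = dists),
            class = "locus_assignment")
}

#' @export
print.locus_assignment <- function(x, ...) {
  cat(sprintf("locus %s (%s%s%s)\n", x$locus, x$method,
              if (!is.na(x$support)) sprintf(", support %d%%", x$support) else "",
              if (x$low_confidence) ", LOW CONFIDENCE" else ""))
  invisible(x)
}

# Project a reference sequence onto the coordinates of a target: identity
# when lengths match, otherwise an ends-free pairwise alignment; target
# positions not covered by the reference become "-".
project_onto <- function(ref, target) {
  if (nchar(ref) == nchar(target)) return(toupper(ref))
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(toupper(ref)),
                                       Biostrings::DNAString(toupper(target)),
                                       type = "overlap")
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  out <- rep("-", nchar(target))
  pos <- Biostrings::start(Biostrings::subject(aln)) - 1L
  for (k in seq_along(sub)) {
    if (sub[k] != "-") {
      pos <- pos + 1L
      if (pat[k] != "-") out[pos] <- pat[k]
    }
  }
  paste0(out, collapse = "")
}

#' Write a tree as Newick with support labels
#'
#' @param tree An `ape::phylo`, e.g. from [bootstrap_support()].
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
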