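# Internal sequence helpers shared across modules.

IUPAC_MAP <- c(A = "A", C = "C", G = "G", T = "T",
               R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
               B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

DNA_BASES <- c("A", "C", "G", "T")

is_iupac <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  length(chars) > 0L && all(chars %in% names(IUPAC_MAP))
}

is_acgt <- function(x) {
  grepl("^[ACGT]+$", x)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Regex character-class expansion of a degenerate IUPAC primer, anchored.
iupac_regex <- function(primer, anchor = TRUE) {
  chars <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  cls <- vapply(chars, function(ch) {
    exp <- IUPAC_MAP[[ch]]
    if (nchar(exp) == 1L) exp else paste0("[", exp, "]")
  }, character(1))
  core <- paste0(cls, collapse = "")
  if (anchor) paste0("^", core) else core
}

random_dna <- function(n) {
  paste0(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Apply exactly n_sub random substitutions (distinct positions) to a sequence.
mutate_seq <- function(x, n_sub) {
  if (n_sub == 0L) return(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  pos <- sample(length(chars), min(n_sub, length(chars)))
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
  }
  paste0(chars, collapse = "")
}

# Phred+33 helpers -----------------------------------------------------------

quals_to_int <- function(q) {
  lapply(q, function(s) as.integer(charToRaw(s)) - 33L)
}

int_to_quals <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(pmin(pmax(v, 0L), 93L) + 33L)),
         character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
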