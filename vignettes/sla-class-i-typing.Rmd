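---
title: "Typing expressed SLA class I alleles from barcoded amplicon reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing expressed SLA class I alleles from barcoded amplicon reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The swine leukocyte antigen (SLA) complex is the porcine MHC. Its three
classical class I loci — *SLA-1*, *SLA-2* and *SLA-3* — encode the
peptide-presenting molecules that restrict CD8 T-cell responses, so knowing
which alleles a pig transcribes matters for vaccine design, infection models
and transplantation studies. The loci are highly polymorphic, far from fully
catalogued, and their typing is complicated by group-indistinguishable
alleles, locus duplications and null loci.

`slatyper` implements a sequence-based typing workflow for this problem:
universal primers amplify a conserved-flanked fragment of exons 2–3 from
cDNA, amplicons are barcoded per animal, pooled and sequenced paired-end,
and the reads are resolved back into per-animal allele calls, novel-sequence
candidates, transcription proxies and population-level haplotypes.

## In-silico PCR and resolvability

`extract_amplicon()` performs exact, degeneracy-aware in-silico PCR: the
5′-most zero-mismatch match of the forward primer on the sense strand, then
the 5′-most match of the reverse complement of the reverse primer downstream
of it. Zero-mismatch matching is deliberate: the primers are "universal"
only insofar as their binding sites are conserved, and an animal whose
template diverges in the primer region genuinely fails to amplify — a
failure mode the pipeline must reproduce (see the off-size handling below),
not paper over with fuzzy matching. When a site occurs twice the 5′-most
match wins, which is deterministic and mirrors the dominance of the
outermost priming site in PCR.

The amplicon object keeps two views: the full amplicon (primer regions
included, 1-based inclusive coordinates on the source sequence) and the
*insert* with primer regions stripped. All downstream comparison —
resolvability, cluster matching — uses the insert, because primer-region
bases are dictated by the primer, not the template, and carry no
discriminating information.

`resolvability()` asks, for a reference library and a primer pair, which
alleles the amplicon can distinguish. Alleles with a unique insert are
resolvable *specifically*; alleles sharing an identical insert form an
equivalence class resolvable only at the *group-specific* level, reported as
one slash-joined label of the sorted member names (`SLA-1*01:01/SLA-1*02:01`
style). Fractions are computed over amplified alleles only. Because the
computation is insert-based and library-agnostic, its headline fractions
depend entirely on the library snapshot supplied; the package makes no
assumption about which snapshot that is. A longer amplicon can only refine
the partition, so the specific fraction is monotone non-decreasing in
amplicon length — a property the test suite checks directly.

## The read pipeline

The pipeline mirrors a conservative amplicon-sequencing chain, with every
threshold exposed in `run_config()`:

| stage | rule | default |
|---|---|---|
| demultiplex | both mates must start with the same sample barcode followed by their primer, exactly | 6-nt barcodes, 0 mismatches |
| quality trim | strip maximal low-quality prefix/suffix | Q < 17 (98% accuracy) |
| merge | ungapped overlap of mate 1 with revcomp(mate 2) | ≥ 35 nt, ≥ 80% identity |
| dereplicate | clusters of 100%-identical sequences | — |
| size filter | drop small clusters, cap the list | < 10 reads dropped, top 20 kept |
| chimera | two-parent crossover model | parents ≥ 2× size, ≥ 3 diagnostic sites/side |
| artifact | length window; overlong with stops in all frames = splice variant | ± 15 nt |
| identify | exact insert lookup, else best alignment | novel if ≥ 95% identity |

Some of these choices deserve justification:

* **Exact barcode matching.** Barcodes are generated (and expected) at
  pairwise Hamming distance ≥ 2, so exact matching guarantees zero
  cross-talk between samples; pairs with damaged barcodes are counted as
  rejects (`no_barcode`, `barcode_conflict`, `no_primer`) rather than
  rescued. Reject tallies are part of the stats output because loss
  accounting per stage is how such runs are audited.
* **Trim before merge.** End-trimming first means the overlap scoring never
  sees the low-quality read tails, at the cost of slightly shorter
  overlaps. The alternative order (merge, then clean) is defensible; we fix
  clean-then-join and expose `q_min` so the trade-off is inspectable.
* **Merging is ungapped.** Amplicon mates differ by substitutions, not
  indels, at these error rates; admitting gaps would only let chimeric or
  damaged pairs through. Among admissible overlaps the highest identity
  wins, ties broken by longer overlap, then smaller shift; the consensus
  takes the higher-quality base at each mismatch (ties favour mate 1).
* **Dereplication at 100% identity.** Cluster size is the transcription
  proxy, and any denoising would blur the distinction between a true allele
  and a 1-mismatch PCR artifact. Instead, artifacts are handled by the size
  filter (error clusters are small) and the chimera/length filters.
* **Chimera flagging** is a simplified two-parent test rather than a port
  of UCHIME: a candidate is chimeric iff some single crossover between two
  clusters at least twice its size explains it at exactly 100% identity,
  neither parent explains it alone, and each side carries at least three
  positions at which the parents differ. The 100% requirement is sound
  here precisely because dereplication is exact: a true chimeric template
  is itself a noise-free sequence. The three-diagnostic-site minimum
  guards against spurious crossovers between near-identical parents.
* **Splice variants vs off-size clusters.** Overlong clusters bearing a
  stop codon in every sense reading frame are classified as alternative
  splicing artifacts and removed. Other off-length clusters are kept
  visible but excluded from typing; a sample whose dominant clusters are
  all off-size is declared typing-failed — this is exactly the signature
  of a primer-mismatch animal producing a single wrong-size product, and
  the pipeline reports it rather than typing it.

A cluster is *dominant* when it holds at least 5% of its sample's retained
reads. Dominance is only a reporting/testing notion (true allele clusters
are large; a heterozygote's weakest locus sits near 5–11% of reads at the
default transcription weights); calling itself uses all retained clusters.

## Allele calling and novel sequences

`match_cluster()` first attempts an exact insert lookup: one name is a
`specific` call, several names a `group` call. Otherwise the cluster is
aligned against every library insert with an ends-free global alignment
under unit costs, and identity is defined as matches over the alignment
length from the first to the last aligned pair — internal gaps count, free
end gaps do not. This gives the familiar "604/605" similarity notation.
At ≥ 95% identity the cluster is a `novel_candidate` with its closest
match; below that it is `unclassified`. The identity floor and the exact
match requirement mean a 1-substitution PCR error can never silently
convert into a different known allele.

`call_novels()` collapses identical novel candidates across samples and
assigns stable ids (NS#1, NS#2, …) ordered by total read support, ties
broken by sequence. A novel seen in only one animal is labelled
low-confidence: recurrence across individuals — i.e. across independent
PCRs — is the argument that a variant is real rather than a polymerase
error, and singletons lack it.

Read fractions are computed within a sample over retained clusters only,
and the package deliberately makes no cross-sample normalisation claims:
PCR efficiency varies by sample, so only the within-sample ordering (the
expected SLA-2 > SLA-1 >> SLA-3 transcription pattern) is interpreted.

## Haplotype inference

Haplotypes are sets of SLA-1/SLA-2/SLA-3 alleles inherited together. The
inference follows the definitional rule rather than a statistical model:

1. every fully homozygous animal (at most one allele at every classical
   locus) seeds the pool with its allele set;
2. iterating to fixpoint in deterministic order, an unresolved animal is
   resolved when two pool haplotypes' union equals its allele set, or by
   complement subtraction: a contained pool haplotype proposes the residual
   as a new haplotype, provided the residual carries at most
   `max_dup_per_locus` (default 2) alleles per locus;
3. a residual that itself decomposes into two pool haplotypes would imply
   three haplotypes in one animal; such animals are flagged as anomalies
   and reported, never force-resolved;
4. remaining animals are `partial` (a pool haplotype is contained but no
   valid complement exists) or `unresolved`.

Seeding requires homozygosity at *all* loci simultaneously — a strict
reading under which a partially homozygous animal contributes nothing on
its own. Group-specific calls travel as single tokens, so a haplotype
containing `a1/a2` matches only animals carrying that same group token.
Published haplotypes can be supplied as priors; they head the pool and are
consulted before any new id is proposed. New ids are lettered in discovery
order (`Hp-A.0`, `Hp-B.0`, …).

Prevalence is reported as the *carrier* percentage — animals carrying the
haplotype in any slot over animals with at least one call, rounded to the
integer — with chromosome frequency (carried copies over 2N) exposed as a
secondary column, since published prevalence tables do not always state
which of the two they use. Animals with no homozygote-compatible
decomposition stay partial; the package does not guess.

## Phylogenetic placement of novel alleles

Full exon 2–3 sequences of novel alleles are assembled from two flanking
amplicons overlapping the originally sequenced core (`assemble_exon2_3()`,
exact suffix–prefix overlaps of at least 30 nt; any disagreement is an
assembly error naming the junction and position — assembly never votes).

Distances are Jukes–Cantor, d = −(3/4)·ln(1 − 4p/3), with non-ACGT
positions excluded pairwise from both the mismatch count and the compared
length, and saturation (p ≥ 3/4) mapped to a configurable cap (default 5
substitutions/site) with a flag rather than an infinite or undefined value.

`nj_tree()` is a standard Q-criterion neighbor-joining implementation with
two determinism rules: ties in Q are broken by the lexicographically
smallest pair of subtree labels, and negative branch lengths are clamped to
zero with the deficit moved to the sibling branch so the pair's total is
preserved. Additive matrices are reconstructed exactly (the test suite
round-trips random additive trees and cross-checks topologies against
`ape::nj`). Bootstrap supports (`bootstrap_support()`) resample alignment
columns with replacement and report, for each internal bipartition of the
point-estimate tree, the percentage of replicates containing it — classic
Felsenstein supports; no consensus tree is built.

`assign_locus()` places a novel sequence by building the JC/NJ tree of the
novel plus all library alleles over the novel's span and assigning the
locus of the smallest enclosing clade whose library members are ≥ 90% one
locus, reported with that clade's bootstrap support. The 90% threshold
(rather than 100%) reflects a known property of partial-span trees: a few
reference alleles sit outside their nominal locus clade even in curated
libraries. When no sufficiently pure enclosing clade exists, the
nearest-neighbour locus is reported and flagged low-confidence. Spans
under 100 nt are refused outright — placement on such fragments is
unreliable, which is why full-length assembly precedes placement. When
library sequences differ in length from the novel they are projected onto
the novel's coordinates via an ends-free pairwise alignment, and gap
columns are excluded from the distances.

## The simulator and what passing tests mean

`make_fixture_library()` + `simulate_reads()` generate the synthetic
studies the tests run on. The fixture mimics the genetic structure that
matters to the pipeline: a shared ancestral insert diverged once per locus
(40 substitutions) and once per allele (6 substitutions), so between-locus
distances dominate within-locus distances; real primer sites embedded
verbatim; haplotypes of one allele per locus; barcodes at Hamming ≥ 2.

Read generation reflects the instrument model the defaults are tuned to:
2 × 250-nt reads; per-allele depth 2,000 pairs scaled by transcription
weights 1.0 / 1.5 / 0.3 for SLA-1 / SLA-2 / SLA-3; a per-cycle mean Phred
declining linearly from 37 to 22 with Gaussian jitter (σ = 3, clamped to
[2, 40]); substitution errors drawn per base with probability proportional
to the realised quality, scaled to a 0.1% mean; 30% barcode-free random
spike-in pairs (the role PhiX plays on a real run); 2% single-crossover
chimeras with the crossover uniform over insert positions 40..L−40 so both
sides remain diagnosable; and 1% splice-variant templates whose insert is
lengthened by a 128-nt filler carrying stop codons in every frame. All
randomness flows from one seed; identical seeds give byte-identical output,
and a ground-truth table reconciles exactly with the emitted read counts.

The simulator does *not* model indel sequencing errors, PCR-cycle-resolved
amplification bias, adapter read-through, or real PhiX genome content; its
chimera and splice rates are chosen for testability, not measured. Passing
the recovery suites therefore demonstrates that the pipeline's logic is
correct under a realistic substitution-noise regime — it does not certify
performance on a platform whose dominant error mode is indels, nor
calibrate quantitative expression claims.

## Problem sizes and numerical choices

The test and acceptance suites run at the defaults above: six samples of a
four-haplotype pool at depth 2,000 pairs/allele for the end-to-end
recovery checks (~65,000 read pairs), single-sample runs for the
cluster-count checks, 100 simulated 20-animal populations for haplotype
recovery, and libraries of up to 50 alleles for the brute-force oracle
comparisons. These sizes exercise every filter (the splice filter, for
instance, only triggers once a splice cluster crosses the 10-read floor)
while keeping a full run in minutes on one core.

Remaining numerical conventions, for reference: dereplication orders
clusters by size descending with lexicographic sequence tie-break; novel
ids are deterministic given the input; the merge consensus prefers mate 1
on quality ties; alignment identity ties prefer the lexicographically
smallest allele name; haplotype inference iterates animals by id and pool
haplotypes in discovery order. Every output is therefore byte-reproducible
from the same inputs and seed.

## Known limitations

* Group-specific alleles are inherently unresolvable at the amplicon level;
  the package reports them as groups and counts a group as one carried
  allele — it never guesses the member.
* Haplotype inference is combinatorial, not statistical: populations
  without informative homozygotes yield partial assignments rather than
  frequency estimates (EM-style estimation is out of scope).
* Locus placement of partial-length novels is only as good as the span
  allows; the low-confidence flag and the 100-nt floor encode that caveat
  rather than remove it.
* Classification against non-classical loci (e.g. *SLA-6*) is not
  attempted; a novel allele genuinely belonging to an unmodelled locus
  will be placed at its nearest classical neighbour, flagged accordingly.
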