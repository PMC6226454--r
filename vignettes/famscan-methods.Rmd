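---
title: "Methods: synthetic gene-family analysis with famscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic gene-family analysis with famscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famscan)
```

famscan re-creates, as a tested and reusable pipeline, a genome-wide
characterization of the potato Hsp70 chaperone family: identification of
family members in a proteome, physicochemical characterization,
neighbor-joining phylogeny with subfamily assignment, exon/intron structure,
conserved-motif mapping, tandem/segmental duplication classification, tissue
expression clustering, and qRT-PCR regulation calls. Because the original
analysis depended on external resources (a genome browser, an expression
atlas, wet-lab CT measurements), the package ships a seeded synthetic
genome generator that plants the family's published structure — twenty
members at their published coordinates, five subfamilies of sizes
10/3/3/1/3, five sister pairs, the reported expression and stress-response
patterns — so every downstream stage can be exercised and verified
end-to-end with no downloads. This vignette explains each model, its
assumptions, the tunable parameters, and the design decisions taken where
the published description was silent or ambiguous.

## The synthetic genome generator

### Protein architecture

Hsp70 proteins consist of an N-terminal ~44 kDa nucleotide-binding/ATPase
domain (NBD), an ~18 kDa substrate-binding domain (SBD) and a variable
C-terminal lid. The generator represents this architecture as a *scaffold*:
one resolved instance of each of the ten published consensus motifs
(`hsp70_motifs()`), concatenated in NBD-to-lid order (motifs 7, 9, 1, 4, 2,
3, then 5, 10, 6, 8) with short random linkers. The published material does
not state the linear order of the motifs; the NBD-first order is a design
choice consistent with the domain architecture, and `build_scaffold()`
accepts any order. Ambiguity letters in the consensus strings (B = D/N,
Z = E/Q, J = I/L, X = any) are resolved uniformly at random, seeded.

The final linker is the variable C-terminal tail. It is generated **once**
on the scaffold (padding the scaffold to the family's maximum length of
890 aa) and inherited down the family topology like every other segment,
then trimmed per member so that each synthetic protein has exactly its
published length (486-890 aa). Drawing tails independently per member
would inject unshared random sequence into every leaf and erase the planted
phylogenetic signal; inheriting them preserves it.

### Divergence model

Members evolve from the scaffold along a fixed two-level topology: a star
of five subfamily ancestors around the scaffold, with the five planted
sister pairs descending from shared "cherry" ancestors. Substitutions are
i.i.d. per site; each substituted residue is replaced by a uniformly drawn
different residue. Three rates shape the family:

* `substitution_rate_between` (default 0.10 substitutions/site) on the
  scaffold-to-subfamily-ancestor branches;
* `substitution_rate_within` (default 0.03) on ancestor-to-member branches;
* a `cherry_factor` (default 0.1) shortening the terminal branches of
  planted sister pairs, keeping cherries tight;
* `motif_conservation` (default 0.35) multiplies the rate inside motif
  segments, making the conserved motifs evolve slower than linkers — the
  defining property of conserved motifs.

These defaults were chosen from closed-form binomial tail bounds so that
three planted properties hold simultaneously with large margins: (i) every
core motif stays above the 0.8 presence threshold in every member
(drift probability ~1e-3 per full simulation), (ii) the five
subfamily-separating edges of the NJ tree are ~3x longer than any
within-subfamily internal edge, and (iii) sister-pair identities (~0.996)
and within-subfamily non-sister identities (~0.965) are separated by the
0.98 sister-identity floor. Indel evolution, codon-usage structure and
realistic nucleotide composition are explicit non-goals; the coding
sequences are deterministic reverse translations (one codon per residue
plus a TAA stop), which keeps the translate-round-trip invariant exact.

Two members carry planted motif losses — one subfamily-E member loses
motif 7 and the subfamily-D singleton loses motif 8 — reproducing the
published presence/absence pattern.

### Genome placement

True members are placed at the published chromosome:kb coordinates
(kb x 1000, 1-based, strand +; the source is silent on strand) with their
published intron counts. The published table prints one intron for two
subfamily-A genes that the accompanying text describes as intronless; the
generator follows the text by default (`introns_follow_text = TRUE`).
Introns fall uniformly at random inside the CDS, 100-500 bp long (lengths
are not published; this range keeps every gene inside its ~2-8 kb printed
span). Gene ends are derived from CDS + intron lengths because the printed
spans are rounded to 0.1 kb and occasionally shorter than the ORF itself;
start-to-start distances — the quantity the tandem rule uses — are exact.

The decoy design makes the identification worked example concrete: 25 raw
candidates = 20 true members + 2 *redundant* decoys (byte-identical copies
of true members at other loci) + 3 *truncated* decoys (copies each missing
one core motif). Thirty background genes (random proteins, 200-600 aa) are
interleaved, including two inside each planted tandem gap so the
intervening-gene rule of the duplication classifier is exercised.
Chromosome sequences are never materialized — coordinates are
annotation-level, written as GFF3 (with GSDS-to-GFF3 phase conversion on
the CDS features).

### Expression and CT simulation

The expression simulator assigns each member one of six tissue-pattern
classes over the eleven atlas tissues (broad, silent, root+tuber only,
root+tuber+stolon only, all-but-stamen, vegetative-high), reproducing the
published counts (two near-silent members; one member expressed in exactly
two and one in exactly three tissues). Noise is multiplicative log-normal
(`fpkm_noise_sdlog = 0.2`); zero-mean cells stay exactly zero, so FPKM
values are never negative.

The CT simulator holds the reference gene at CT 20 in expectation across
treatments and shifts the target CT of planted up-/down-regulated genes by
-/+ `ct_effect` cycles (default 2, i.e. 4-fold). Gaussian noise enters per
biological replicate (0.15 cycles, shared by that replicate's technical
replicates) and per technical replicate (0.05 cycles). With three
biological replicates this gives planted effects t-statistics far beyond
the 0.05 significance level while keeping null fold-changes well inside
the 2-fold calling window, so the planted regulation pattern — five genes
up under all four abiotic stresses, four down; 6/8/8/4 genes changed under
the IAA/ABA/GA3/SA hormones — is recovered calls-for-calls. The published
figures name only some responders; the unnamed assignments honour every
printed constraint (which genes are named, the changed-gene counts, downs
outnumbering ups under hormones) and are otherwise the generator's choice.
The biotic treatments (P. infestans, BAP, BABA, BTH) follow the results
text; where that text and the discussion disagree on the P. infestans
response, the results text wins.

All randomness flows from one top-level seed through per-stage derived
seeds (`derive_seed(seed, stage)`), so toggling one pipeline stage never
shifts another stage's random stream, and identical configurations produce
byte-identical FASTA/GFF3/TSV/JSON outputs.

### What the generator does and does not emulate

The generator reproduces the *statistical and positional structure* the
analyses assume — not real sequences. Passing tests demonstrate that the
pipeline's operations are correct and that its thresholds behave as
designed on data with known truth; they do not validate biological claims
about real potato proteins, and numerical properties of real sequences
(molecular weights, pI values, real FPKM) are not reproduced.

## Family identification

The original search used a profile-HMM domain query with an E-value below
1e-5. Re-implementing profile HMMs is out of scope; famscan replaces the
profile search with consensus-motif scoring plus a permutation E-value,
keeping the module's contract (scan, score, threshold, filter) intact:

* `match_fraction()` scores a window against a consensus as the fraction
  of compatible positions (exact match or ambiguity-code coverage).
* `scan_protein()` reports each motif's best window (leftmost on ties).
* The *family score* is the mean best-match fraction over the core motifs
  1, 3 and 4 — the motifs present in every member.
* `empirical_evalue()` computes
  `E = N_db * (1 + #{null >= score}) / (1 + n_shuffles)` where the null
  scores come from residue-permuted proteome members (999 permutations by
  default, seeded).

The empirical E-value cannot go below `N_db / (n_shuffles + 1)` (~0.06 for
the default 55-protein proteome), so the published 1e-5 cutoff has no
direct counterpart on this scale; the default `evalue_max = 0.1` sits just
above that floor and far below any null score's E-value. Both the
threshold and `n_shuffles` are configurable.

`filter_candidates()` implements the redundancy and completeness filters.
"Redundancy" is not operationally defined in the source; famscan uses:
byte-identical sequence to an already accepted candidate, or >= 50% locus
overlap with a higher-scoring accepted candidate (higher score wins, then
the lexicographically smaller id — byte order, for locale independence).
"Incomplete" means any core motif below the 0.8 presence threshold (the
presence threshold is a design choice; the source is silent).

## Protein characterization

`orf_length()` encodes the exact published relation ORF = 3 x (aa + 1) —
one codon per residue plus the stop — which reproduces the printed ORF
column for all twenty loci. Molecular weight is the sum of average
(not monoisotopic) residue masses plus one water, the ProtParam
convention. The isoelectric point solves net charge = 0 under a
Henderson-Hasselbalch model with Bjellqvist pKa values (the
ExPASy-compatible set, since the original characterization used
ProtParam); the pKa table is injectable. The solver bisects on (0, 14)
until |charge| < 1e-4 or the bracket is below 1e-7 pH units; tests verify
agreement with a dense-grid oracle to 0.01 pH units. The instability
index and other ProtParam outputs are not computed: no downstream result
uses them.

## Phylogeny

Distances use *pairwise gap deletion*: for each pair a global alignment
(BLOSUM62, affine gaps 10/0.5, via Biostrings) is computed, columns with a
gap in either sequence are dropped, and the p-distance (default) or its
Poisson correction -ln(1-p) is taken. The original study aligned all
sequences at once with a progressive multiple aligner; pairwise alignment
is a documented deviation that avoids re-implementing progressive MSA while
preserving the pairwise-gap-deletion semantics. Consequently the bootstrap
resamples each pair's own gap-deleted columns (with replacement, per
replicate, seeded) rather than shared MSA columns.

`nj_tree()` is a from-scratch Saitou-Nei neighbor joining: join the pair
minimizing `Q(i,j) = (n-2) d(i,j) - r_i - r_j`, branch lengths from the
standard closed forms, ties broken by the lexicographically smallest pair
of cluster representatives. Negative branch-length estimates are clamped
to zero with the deficit moved to the sibling branch (the convention of
mainstream NJ software). On additive matrices the output path metric
reproduces the input exactly (tested to 1e-9), and the topology matches an
independent NJ implementation on random inputs.

Bootstrap supports are the percentage of replicate trees containing each
internal edge's bipartition, computed with the package's own canonical
bipartition keys. The default is 100 replicates — the package's chosen
desk-scale default for the full pipeline — with the replicate count
configurable (the original study used 1,000).

Subfamily extraction is not described in the source (clades were read off
a figure); famscan operationalizes it as removing the k-1 longest internal
edges (ties by support, then by smallest descendant label) and grouping
the leaves of the resulting components. Edge removals that do not split
any leaf group are skipped, so exactly k groups always result (pendant
edges are cut only after internal edges are exhausted, which makes
`k = number of leaves` yield singletons). Groups are labelled A, B, C, ...
by decreasing size, ties by smallest member id. Sister pairs are terminal
cherries whose Smith-Waterman identity reaches `identity_min`
(default 0.98, chosen between the generator's sister and non-sister
identity bands).

## Duplication classification

`smith_waterman()` is an affine-gap local aligner (Rcpp) with floor at
zero and traceback from the maximum cell (ties: smallest row, then
column). Defaults follow the EMBOSS `water` conventions: BLOSUM62, gap
open 10, gap extend 0.5; in this package a gap of length L costs
`open + (L-1) * extend`. Tests verify equivalence with a brute-force
enumeration oracle on short pairs and with an independent implementation
(after reconciling the gap-cost convention, which differs by one extend
per gap).

`classify_pair()` applies the published tandem rule: same chromosome,
start-to-start distance <= 100 kb, and at most five annotated genes
strictly between. Pairs on different chromosomes are classified segmental
— a documented simplification: the original block-level evidence came from
an external genome browser, so duplicated-block lookup is not
re-implemented, but a block list can be injected (`blocks =`) to refine
different-chromosome calls. Same-chromosome pairs failing the tandem rule
are `ambiguous`, never silently tandem. One results sentence states the
tandem distance rule inconsistently ("less than 5 kb (>100 kb)"); the
methods formulation (five or fewer genes within 100 kb) is taken as
authoritative.

## Expression analysis

`normalize_expression()` divides every (pseudocounted) FPKM value by the
grand mean of the matrix and log2-transforms, so the mean of the pre-log
ratios is exactly 1. The pseudocount (default 0.01) handles zeros, which
the published processing does not address. `hcluster_expression()` is
UPGMA (average linkage) on Euclidean row distances via `stats::hclust`;
genes are the rows, the row/column convention the original heatmap tool
leaves ambiguous. "Expressed" is FPKM >= 1 by default — the published
"highly/lowly expressed" is qualitative, so the threshold is explicit and
configurable. Biotic-treatment matrices flow through the same operations.

## qPCR regulation calls

Per biological replicate, technical replicates are averaged and
dCT = CT_target - CT_reference; fold change is `2^-(dCT_t - dCT_c)` (the
Livak relative-quantification formula). Calls use a two-sample Student
(equal-variance) t-test of treated vs control replicate dCTs — Student
because the original statistics used Student's t at 0.05 — with Welch
available by flag. A gene is `up` when fold >= `fold_min` and p < alpha,
`down` when fold <= 1/`fold_min` and p < alpha, else `unchanged`. The
source states no fold threshold, only p < 0.05; the default
`fold_min = 2` guards against significant-but-tiny folds, and
`fold_min = 1` reproduces significance-only calling. No multiple-testing
correction is applied by default, matching the original analysis; `fdr =
TRUE` switches on Benjamini-Hochberg. The reference gene is named
inconsistently in the source (EF1-alpha in methods, beta-actin in figure
captions); the CT schema carries an explicit reference-gene column so
either works.

## Pipeline and problem sizes

`run_all()` chains simulate, identify, props, phylo, structure,
duplication, expression and qpcr with per-stage derived seeds and writes a
reproducible report; rerunning an identical configuration reproduces every
headline number. The default problem sizes — 55 proteins, 999 E-value
permutations, 100 bootstrap replicates, 3 biological x 3 technical
replicates — are the package's desk-scale study conditions: a full run
takes well under a minute on one CPU, and each knob scales up
independently.

## Known limitations

* The identification stage is a consensus-motif stand-in for a profile-HMM
  search; its E-values are empirical and bounded below by the permutation
  resolution.
* Segmental classification by "different chromosome" over-calls pairs that
  a block-level analysis would reject; inject a block list when one is
  available.
* The generator's divergence model has no indels beyond linker-length
  edits and no rate heterogeneity beyond the motif/linker split; real
  families violate both.
* Cross-species analyses (ortholog cherries between proteomes) run through
  the same operations but carry no count guarantees, since the multi-species
  composition depends entirely on the user-supplied sequences.
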