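---
title: "aqpscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{aqpscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`aqpscan` implements a desk-scale, fully tested version of the standard
aquaporin (AQP) gene-family study: candidate detection, multiple alignment,
ar/R selectivity-filter classification, distance phylogeny, domain motif
architecture, duplication dating by Ks, and stress-expression clustering
with GO enrichment. This vignette records the models behind each stage, the
parameters that matter, the numerical choices, and what the synthetic data
do and do not establish about real data.

## Candidate detection

AQPs carry two Asn–Pro–Ala (NPA) motifs, one in loop B and one in loop E.
`find_npa_motifs()` scans for N‑P‑x with x ∈ {A,V,S,T,L,G,M,C} — plant SIP
and NIP loop-B motifs deviate from the canonical triplet — and keeps the
candidate pair with separation in [50, 160] residues, preferring pairs with
more exact `NPA` matches and breaking remaining ties toward the leftmost
pair. The variant set and window are configurable (`aqp_config()`).

Transmembrane helices are predicted from Kyte–Doolittle hydropathy: a
19-residue sliding-window mean, runs of window centres at or above 1.6,
merged across gaps shorter than 3 and kept at length ≥ 10. These are the
classical hydropathy-plot settings; they are deterministic and recover
planted hydrophobic segments exactly, but they are a coarser instrument
than an HMM topology predictor, which is why candidate acceptance uses a
tolerant helix-count window of [5, 7] (truncated gene models in real
re-annotations routinely lose a terminal helix) together with a length
window of [200, 400] residues.

## Alignment and trimming

`progressive_align()` builds a UPGMA guide tree (`hclust`, average linkage)
on k-mer distances (k = 3; one minus the shared k-mer multiset fraction)
and merges profiles leaf-to-root with a profile–profile Needleman–Wunsch
(C++): column score is the frequency-weighted BLOSUM62 cross-product, gaps
are affine with open −10 and extend −1 (a length-L gap costs −10−(L−1)),
end gaps are penalised, and the traceback tie-break is diagonal > up >
left, so results are deterministic for a given input order. With two
sequences this reduces exactly to optimal pairwise DP, which the tests
verify against an independent implementation. Gap-rich columns are removed
by a simple gap-fraction rule (> 0.8 dropped) rather than a slope
heuristic: downstream filter location is re-anchored on the NPA columns, so
exact trimming behaviour is not load-bearing.

## ar/R filter extraction and classification

The four filter residues sit at fixed geometry relative to the NPA motifs
in the AQP fold: H2 twenty residues before the loop-B NPA asparagine; H5,
LE1 and LE2 at −12, −3 and +3 from the loop-E asparagine. These offsets are
frozen in `aqp_config()$filter_offsets`; they were fixed once from the
canonical fold geometry, and the synthetic generator plants residues at the
same offsets, so planted-filter recovery is exact by construction.
Published absolute column indices (such as "position 37 in the aligned
sequences") are properties of one specific trimmed alignment and are
deliberately not hard-coded.

In the `classify_family()` driver each sequence with detectable NPA motifs
is read at these offsets from its **own** anchors in residue space. The
column-space operations (`find_npa_columns()`, `locate_filter_columns()`,
`extract_arr_filter()`) remain the exported interface and are used for rows
without detectable motifs; per-row anchoring was adopted after observing
that a progressive alignment can occasionally insert a compensating gap
column that shifts one cohort's register, which misreads a fixed-column
extraction even though each row's own anchors are unambiguous.

Classification matches the quadruplet against a priority-ordered signature
table (shipped as editable TSV): exact subgroup patterns first
(TIP2 H‑I‑G‑R, TIP3 H‑V‑A‑R, TIP4 H‑T‑A‑M / H‑I‑A‑V / H‑I‑A‑M, NIP1
A‑I‑G‑R / S‑I‑A‑R, NIP2 G‑S‑G‑R, NIP3 W‑V/I/S‑A‑R, XIP1 I‑T‑A‑R, PIP
F‑H‑T‑R), then a set-based SIP pattern. A call requires at least three
non-missing residues all inside one subfamily's allowed sets; quadruplets
matching patterns of two subfamilies are ambiguous and are never guessed —
they go to the fallback, a best global-alignment match against the already
classified genes (ties by percent identity, then id). This mirrors the
common practice of resolving atypical filters by sequence similarity
instead of an external BLASTP binary; only best-match semantics are relied
on.

Names follow the `<prefix><subgroup>;<index>` convention with indices
assigned by position: chromosome-anchored genes first (chromosome, then
start), then scaffold-placed genes. Chromosomes are recognised by a
configurable regex (default `^chr`).

## Phylogeny and subgroups

Distances are Poisson-corrected p-distances, d = −ln(1−p), over columns
where both rows carry residues (≥ 20 required per pair; p ≥ 0.95 capped and
flagged). Neighbor joining follows Saitou–Nei with the standard Q criterion
and branch-length formulas; Q ties break toward the lexicographically
smallest id pair and negative branch estimates are clamped to zero with a
warning. NJ is exactly consistent on additive matrices, which gives a sharp
test: 200 random trees are recovered with identical topology and
path-length matrices. Subgroups propagate from labelled reference leaves to
queries by smallest patristic distance; a query whose smallest containing
split also holds labels of a second subgroup is flagged ambiguous but still
reported. Maximum-likelihood inference and bootstrap support are out of
scope — subgroup assignment only needs neighbourhood structure.

## Domain motif architecture

The trimmed alignment is tiled into exactly 14 contiguous blocks: columns
covered by predicted helices in ≥ 50% of rows form six consensus helix
intervals; termini and inter-helix loops complete a natural 13-block
tiling, and the widest non-helix blocks are halved (leftmost first on ties)
until 14 blocks exist. The count of 14 follows the field's standard AQP
domain diagram; the deterministic splitting rule is this package's own,
replacing manual inspection. Within each block, rows are single-linkage
clustered at ≥ 0.7 identity (matching residue columns over columns where
either row has a residue); clusters become motifs numbered by descending
frequency with consensus-string tie-breaks, so labels are invariant to row
order. A motif is group-specific when its within-group frequency is ≥ 0.6
and its outside frequency ≤ 0.1 — on families with planted TIP4-private
downstream blocks, exactly those blocks are reported.

## Duplication modes and Ks dating

Duplicate pairs are all-vs-all global alignments kept at identity ≥ 0.4 and
coverage ≥ 0.6. Modes use base-pair gaps between facing gene ends on the
same sequence: ≤ 100 kb tandem, ≤ 1 Mb proximal, else dispersed — a
locus-level simplification of gene-rank adjacency pipelines, appropriate
because only family loci are required inputs. Tandem arrays are connected
components of the tandem-pair graph.

Ka/Ks uses Nei–Gojobori (1986) counting on a codon alignment obtained by
back-translating the protein alignment (one trailing stop trimmed;
translation must match): synonymous site fractions per codon from the
standard code averaged over both sequences, multi-position codon
differences averaged over all minimal mutational pathways with
stop-crossing pathways excluded, and Jukes–Cantor correction
d = −(3/4)ln(1−(4/3)p), undefined at p ≥ 3/4 (saturation flag). The
implementation is verified against an independent exhaustive
pathway-enumeration oracle to 1e−12. MYN-style corrections for
transition/transversion and codon-frequency bias are a documented extension
point, not implemented.

## Expression clustering and GO enrichment

DEG selection works per stress condition against matched controls:
per-timepoint log2 fold changes log2((s+1)/(c+1)) (the +1 pseudocount
matches the log2(FPKM+1) display convention), a two-sided paired t-test
across matched stress/control observations when at least three pairs exist
(Welch otherwise), and a DEG requires p ≤ 0.05 and max |log2FC| ≥ 1. The
fold-change guard supplements the published p-value rule because a p-value
alone, at desk-scale replication, admits biologically negligible shifts.

Profiles are row-standardised; the cluster number comes from a k-means
elbow (10 restarts per k, seeded): the k with the largest second difference
of within-cluster sum of squares, accepted only when that curvature exceeds
30% of the total WSS drop over the range, otherwise the smallest k is
returned. The 30% margin was calibrated once on the generator's conditions
— smooth noise curves stay below 0.16 while genuinely clustered data score
above 0.9 — and then frozen. Fuzzy c-means uses the standard updates
(memberships ∝ d^(−2/(m−1)), centers the membership^m-weighted means) with
fuzzifier m = 1.25, the common choice for standardised expression profiles,
from a seeded random initialisation until the objective improves by < 1e−6;
the objective trace is returned and is non-increasing by construction.

Enrichment is the hypergeometric upper tail P(X ≥ k) per GO term
(unannotated genes count in the totals; no GO-graph propagation), with
Benjamini–Hochberg correction applied per cluster and a 0.01 FDR cut-off.
BH is delegated to `p.adjust` behind a validating wrapper; the tests pin
its step-up behaviour against hand-computed cases.

## Synthetic data: what it shows and what it does not

The generators are pure functions of (parameters, seed) and return
ground-truth records sufficient to score every recovery test.

*Families.* One family ancestor is drawn on a fixed 212-residue fold
(six 22-residue hydrophobic helices, hydrophilic loops, NPA triplets in
loops B and E); each subgroup diverges from it by class-preserving
substitutions (default rate 0.3, giving the 40–60% inter-subgroup identity
typical of the family — subgroups must be homologs, not unrelated
sequences, or no alignment is defensible); members add point noise outside
the NPA and filter positions, never introducing N or P so no spurious
anchors arise. Member CDS differ from the subgroup consensus CDS by a small
planted synonymous divergence (0.05), mimicking recent duplication.

*Duplications.* Pairs are an ancestor plus a copy evolved by a Poisson
substitution process whose expectation is the planted Ks (events uniform
over the available synonymous single-nucleotide changes; nonsynonymous rate
separate, default 0.02). Random ancestors for the Ks benchmark are drawn
from fourfold-degenerate codon families (GCN, GGN, CCN, ACN, GTN, TCN):
every synonymous site is then a true four-state equal-rates site, exactly
the model the Jukes–Cantor correction inverts, so the planted divergence is
an unbiased target at all levels. With mixed-degeneracy ancestors the
NG86+JC estimate is systematically high (≈ +15% at Ks = 1) because two- and
threefold sites hide fewer multiple hits than the correction assumes — a
known property of equal-pathway counting, and the reason transition-aware
estimators exist. `ancestors = "all"` keeps full-alphabet proteins for
pair-detection studies. A planted tandem array places near-identical copies
at 50 kb spacing on one chromosome.

*Expression.* Baselines are log-normal; responders add a
sustained-plus-bump induction on the log2 scale (amplitude 2 = fourfold at
the cluster's peak timepoint, 40% of it sustained across all timepoints).
The sustained component is a modelling decision: a purely transient profile
has a large across-timepoint variance, which the paired t-test design
itself penalises, making even strong responders statistically invisible;
stress-responsive transporter genes typically show sustained induction with
a temporal peak. Peak positions separate the planted clusters.

*GO maps.* Terms annotate background genes at 5%; enriched terms
over-annotate a target set (default 80%).

Passing these suites demonstrates that each algorithm recovers structure it
is designed to see, under clean statistical assumptions and at desk scale
(tens of genes, hundreds of expression rows). It does not demonstrate
performance on real proteomes: real families have indels the CDS simulator
omits, intron structure is not modelled, hydropathy-based TM prediction is
weaker than topology HMMs on real membrane proteins, and real RNA-seq has
dispersion structure a log-normal model lacks. The packaged pepper table,
transcribed from the published study, ties the reporting layer to real
numbers: 73 genes (19 PIP, 31 TIP — 42.5%, 16 NIP, 5 SIP, 2 XIP), 23 of
the TIP genes in TIP4, 10 newly annotated models, 64 chromosome-anchored
genes with 33% on chromosome 1.

## Degenerate inputs and numerical conventions

Single-record alignment requests return the record unchanged; all-gap
columns after trimming are an error; NJ requires n ≥ 3 and the three-taxon
case is solved in closed form; distance caps, Ks saturation and blocked
mutational pathways are flagged, never silently dropped; fuzzy c-means
floors squared distances at 1e−12 to avoid division by zero on exact
center hits; percentages print to one decimal and integer percentages round
half up (33 from 21/64). Every stochastic entry point takes an explicit
seed, and `run_pipeline()` writes a JSON log of parameters, seed and input
hashes; rerunning a fixed configuration is byte-identical. Problem sizes in
the shipped tests (60-gene families, 100 pairs per Ks level, 1000-gene
expression matrices) were chosen as the smallest sizes at which the
statistical properties under test are stable.
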