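---
title: "Detecting bacterial gene transfer into an archaeal family: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bacterial gene transfer into an archaeal family: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Methanogenic archaea such as *Methanosarcina* carry a substantial number
of genes of bacterial origin, acquired by horizontal gene transfer (HGT).
Estimating how many, when they arrived (before the family radiated, in
the genus ancestor, or in a single species), and from which bacterial
taxa, requires a chain of inferences: protein families must be built
across the recipient genus and family, families with a bacterial-type
similarity profile must be screened out of thousands of ordinary
archaeal families, a phylogeny of each candidate family and its
homologs must be estimated, and the transferred clade's placement inside
a bacterial clade must be read off the rooted tree. Every step has
parameters, and the final counts are sensitive to the composition of the
reference database — a bias `hgtcensus` also quantifies directly.

`hgtcensus` implements this census as a reusable pipeline, together with
a truth-labelled synthetic-universe generator, so that every stage — and
the pipeline end to end — is testable without downloading genomes or a
reference protein database.

# The detection procedure

## Orthology: groups of orthologous proteins (GOPs)

For every ordered pair of organisms in the focal genus (and, at a looser
cutoff, the focal family) we find **bidirectional best hits** (BBHs):
protein pairs that are each other's top-scoring surviving hit. Hits are
discarded when identity is below 50 % within the genus (40 % within the
family) or when the aligned region covers less than 2/3 of the shorter
protein. A **paralog rule** then adds same-genome partners that are more
similar (by alignment score, the ranking key of the search stage) to a
BBH member than that member is to its cross-genome partner. Maximal
connected components of the resulting graph are the GOPs; isolated
proteins are orphans.

Three GOP-level filters follow: groups in which strictly more than half
of the members are transposase-flagged are removed (transposons spread
promiscuously and would otherwise dominate the candidate list);
family-scope groups whose member set is contained in a genus-scope group
are redundant and dropped; and family-scope groups must contain at least
one focal-genus protein. On the redundancy rule the design was genuinely
open: dropping any family group whose *focal members* match a genus
group would also delete every group that legitimately extends a genus
group with other family species — and family-ancestor transfers would
become undetectable — so containment is tested on the whole member set.

## The similarity search

The search stage is a contract-level stand-in for an external database
search: exhaustive Smith–Waterman local alignment (BLOSUM62 with the `X`
row and column zeroed, gap open 11, gap extend 1) of each query against
every visible database record, scored in raw alignment units. All
downstream thresholds are identity-, length- and coverage-based, so no
e-value model is needed. One addition is required in its place:
`search_min_score` (default 100, roughly 40 bits) discards alignments in
the score range where unrelated proteins begin to produce spurious local
alignments that nonetheless satisfy the identity/length/coverage
thresholds. An external search tool performs the same role with its
reporting threshold.

Year-stamped **database masking** (`mask_by_year`) hides organisms of a
chosen domain sequenced after a given year without touching the records,
reproducing the historical composition of the reference database.

## Bacterial-type screening

A GOP passes the screen when *every* member, after removing hits to the
focal family and to fellow members and applying identity ≥ 30 %, HSP
length ≥ 50 and query coverage ≥ 75 %, has either its top three hits all
bacterial, or at most three archaeal hits among the top twenty with all
other top-twenty hits bacterial. Removing the focal family first is
essential: a group's own close relatives would otherwise always occupy
the top ranks and no group could ever pass. A member with no surviving
hits fails — absence of bacterial affinity is not evidence of transfer.

Focal-family homologs are, however, *kept* in the homolog set that goes
into the tree (`collect_homolog_set`): the timing rules need other
family species on the tree to distinguish a family-ancestor transfer
from a genus-ancestor transfer.

## Alignment and its reliability gate

Homolog sets (the union of each member's top 100 threshold-passing hits,
plus the members) are aligned with MAFFT, a progressive aligner using a
pairwise-distance guide tree with profile-profile merging. Column
reliability is scored as non-gap occupancy times one minus the
normalised residue entropy — a proxy, on a 0–1 scale, for the alignment
confidence score of dedicated alignment-QC tools, whose published cutoff
applies to their own scale and is not transplanted; the default
threshold here is 0.5. A set is discarded when more than half of its
columns are unreliable. Sequences are gated as well as columns: a
non-member homolog whose aligned identity to every member is below the
30 % screening floor was admitted by one lucky local alignment, carries
no usable phylogenetic signal at this depth, and is removed before tree
building (alignment-QC tools drop unreliable sequences for the same
reason).

## Trees, rooting and the transfer call

Distances are Poisson-corrected p-distances, d = −ln(1 − p), computed
over columns where both rows are non-gap, with p capped at 0.95 to keep
d finite; a pair sharing no columns receives 1.5× the maximum observed
distance. Neighbor-joining gives the tree; 100 column-resampled
bootstrap replicates give per-bipartition supports. Each replicate draws
its resample from a named sub-seed, so supports do not depend on
evaluation order and two runs with one seed agree bitwise.

Rooting follows two rules. If the non-family archaea form a clade of
the unrooted tree, the root goes on the edge between those archaea and
the bacteria. Otherwise the root goes on the internal edge that best
separates the two largest phylum-level bacterial groups; when only one
bacterial group is present, the "second group" is the non-bacterial
remainder, so the root lands between the bacteria and the transferred
clade. Ties between equally separating edges are broken by edge length
first (the divergence point between major taxa is the deep, long edge),
then by leaf-count balance, then lexicographically. Preferring balance
over length turned out to root trees on zero-length edges created by
the NJ estimate and misread the donor; the order used here was chosen
for that reason.

A transfer is called when the focal-family leaves form a monophyletic
clade whose bipartition has bootstrap support above 70, and the smallest
clade properly containing it holds only bacterial leaves besides it. A
single-leaf focal clade (the singleton path for species-specific
transfers) is trivially monophyletic with trivial support. When an
externally supplied maximum-likelihood tree is given, the monophyly and
bacterial-context conditions must hold there too; no support threshold
is applied to ML trees since their supports are not modelled.

**Timing** is read from the focal clade's composition: two or more focal
species plus another family species → family ancestor; two or more focal
species alone → genus ancestor; exactly one focal species → species
specific. **The donor** is the deepest taxonomic rank shared by the
bacterial leaves of the smallest *stable* clade containing the focal
clade — containing clades whose own bipartition lacks support are
skipped, so one waywardly placed leaf cannot name the donor; if only the
domain is shared the donor is reported as unclassified bacteria.

## Census statistics

* `hgt_trajectory` re-runs the screen (no trees) against year-masked hit
  lists and reports, per year, the focal organism's genes in passing
  GOPs over its genes in GOPs. The denominator is genes in GOPs, not all
  genes, matching the screening universe. Under archaeal-only masking
  the fraction is non-increasing in the year: masking can only remove
  archaeal hits, and every screening condition is monotone in them.
* `donor_overrepresentation` divides called GOPs per donor taxon by the
  number of sequenced genomes in that taxon, offsetting the head start
  of well-sequenced taxa; donors without a genome denominator
  (unclassified bacteria) are reported unnormalised.
* `cog_overrepresentation` computes O = (obs − exp)/exp with
  exp = reference category fraction × transferred genes with a COG
  assignment. Reference fractions are supplied as a table.
* `compare_fractions_2x2` is a Pearson chi-square on
  `[[x1, x2], [N1−x1, N2−x2]]` with 1 df and **no continuity
  correction**. The second row is the non-transferred remainder, not the
  raw genome counts: only this arrangement reproduces the published
  p-values from the published counts (0.0094 for the largest genome's
  enzymes/transporters; using raw genome rows gives ≈ 0.02).
* `expression_tally` reports the fraction of called GOPs with at least
  one member flagged as differentially expressed; absent flags count as
  not expressed.

## Operons

Operons are maximal runs of adjacent codirectional genes whose
intergenic gaps are all ≤ 150 bp, with gap(g, g′) = start′ − end − 1 (so
abutting genes have gap 0; overlapping genes count as gap 0 with a
warning; circular replicons are treated as linear — no wraparound rule
is defined). Transferred-fragment lengths sum consecutive transferred
genes and the gaps between them; a lone transferred gene in a trivial
run contributes its own length; species-specific (singleton) transfers
are excluded from the fragment analysis — "singleton" here means a
one-species transfer, not a one-gene operon, whose fragments are
explicitly defined as the gene length.

# The synthetic universe

The generator emulates the study system: a focal genus of 3 species
nested in a focal family of 6, 4 outgroup archaeal genomes, and 4
bacterial phyla of 4 genomes each (each genome its own genus, and no
ranks between phylum and genus, so a whole-phylum donor clade resolves
to the phylum). Gene families evolve along the species tree under an
equal-rates 20-state model: the root sequence is uniform, and along a
branch of length b each site substitutes with probability 1 − e^(−b) to
a uniformly chosen different residue. The model's closed-form pairwise
identity, 1/20 + (19/20)·∏(e^(−bᵢ) − (1 − e^(−bᵢ))/19), makes the
generator itself testable (the suite checks simulated identities against
it at 3σ on 10 000 sites).

Branch lengths encode the strong-signal regime the detector is specified
against, and were chosen once, as the study conditions:

* within-genus identity ≈ 85–95 % (well above the 50 % BBH cutoff);
* focal-to-other-family identity ≈ 50–60 % (above the 40 % family
  cutoff);
* transferred-gene-to-donor-clade identity ≈ 50–70 % (comfortably above
  the 30 % screening floor);
* archaea–bacteria and inter-phylum divergences deep enough that
  vertical families have *no* surviving bacterial hits and transferred
  families keep ≥ 30 % identity only to their donor phylum. Long
  exterior branches are what make the signal strong; with a shallower
  backbone, near-threshold cross-phylum homologs enter the trees with
  saturated, noise-amplified distances (the Poisson correction multiplies
  p-noise by 1/(1 − p)) and destabilise otherwise clean clades.

Planted transfers prune the recipient clade (genus, family, or one
species) and regraft it, with a stem of 0.12 expected substitutions per
site, just above the donor clade's root — inside the donor's phylum
clade, the geometry the caller looks for. A stem much shorter than ~0.1
leaves the transferred clade's bipartition with too few informative
sites at typical protein lengths (160–240 residues here) for bootstrap
support to clear 70 reliably, which is why 0.12 is the default.

Genome layouts place each organism's genes on one replicon in seeded
random order, drawing unit sizes so the expected fraction of genes in
multi-gene operons matches the target (66 %, the genome-wide fraction
reported for these genomes), intra-operon gaps uniform on [0, 120] bp
and inter-unit gaps on [200, 400] bp. The generated runs are recorded as
truth and are recovered exactly by `predict_operons` at the 150 bp
threshold, by construction.

A **confounder scenario** (off by default) adds archaeal genomes,
year-stamped at a chosen year, whose copies of planted families sit next
to the transferred clade. Masked, they are invisible and the screen
passes; once visible they contribute more than three high-ranking
archaeal hits and the screen fails — reproducing, with known truth, the
historical deflation of search-only HGT estimates as archaeal genomes
accumulated.

All randomness flows from one seed through named substreams (taxonomy,
per-family trees, sequences, layouts, bootstrap replicates), so a seed
reproduces every output byte for byte.

# What the synthetic tests do and do not show

The generator produces no indels (alignments are trivial stacks), no
rate variation across sites, no gene duplication or loss beyond the
planted transfers, no compositional bias, and taxon samples far smaller
than a real reference database. Passing the planted-recovery suite
therefore shows the *logic* of the pipeline — thresholds, graph
construction, screening, tree building, rooting, calling, timing, donor
assignment — is correct under conditions where the answer is knowable;
it does not show that the thresholds are well-calibrated for real
proteomes, where alignment quality, paralogy and database composition
dominate the error budget.

# Problem sizes and numerical choices

The shipped test suite simulates 30-family universes (~780 proteins,
26 organisms) for end-to-end recovery, a 12-family universe for the
trajectory scenario, and a 10-family universe for the bitwise
determinism check; oracle equivalences run on 200 random sequence pairs
(≤ 50 aa, against a quadratic dynamic program), 100 random graphs
(against union-find), 30 additive distance matrices (4–6 taxa), and
1 000 random 2×2 tables (against the closed form). Degenerate inputs are
pinned by tests: empty databases after masking warn and return empty hit
lists; identical sequences give zero distances and an arbitrary resolved
topology; pairs sharing no alignment columns receive 1.5× the maximum
distance with a warning; zero chi-square marginals are an error.

# Known limitations

* NJ on Poisson-corrected distances saturates near the 0.95 p-cap;
  deeply diverged homologs place unstably. The sequence-level gate
  removes the worst cases, but donors of genuinely ancient transfers
  will often resolve only to unclassified bacteria.
* Maximum-likelihood trees are accepted as external input and checked
  for topology agreement only; no ML inference or ML support threshold
  is implemented.
* The paralog rule is applied one step from each BBH anchor, not chained
  transitively; deeply nested co-ortholog structures may be split.
* The balance/length rooting heuristic is a codified stand-in for a
  manual rooting decision; pathological trees (e.g. several equally
  large bacterial groups) may root away from the true divergence.
* Archaea-to-bacteria transfer detection is supported only by swapping
  the domain roles in the configuration; it is not separately tested.
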