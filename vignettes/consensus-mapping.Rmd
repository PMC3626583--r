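---
title: "Consensus map integration and NB-LRR homolog analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus map integration and NB-LRR homolog analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cucumap)
```

cucumap implements the computational core of a cucumber consensus-mapping and
resistance-gene study: building genetic linkage maps from segregating
populations, merging several component maps into one consensus map with a
1-cM bin-mapping strategy, and characterising the genome's NB-LRR resistance
gene homologs (RGHs) — classification, physical clustering, phylogeny, EST
support and physical anchoring. This vignette explains the models, the
tunable parameters and the numerical choices; it states nothing the test
suite does not itself verify.

## Recombination-fraction estimation

For a codominant F2 intercross, a marker pair falls into nine two-locus
genotype classes. Eight classes imply a fixed number of recombinant gametes;
the double heterozygote mixes the two phase configurations (coupling
AB/ab and repulsion Ab/aB), whose mixture probability at recombination
fraction $r$ is $((1-r)^2 + r^2)/2$. `estimate_rf()` maximises the
multinomial likelihood by EM: the E-step attributes to the double
heterozygote an expected recombinant-gamete count of $2r^2/((1-r)^2+r^2)$,
and the M-step is a closed-form ratio. Numerics: start at $r = 0.25$,
clamp iterates to $[10^{-6}, 0.4999]$ to avoid boundary degeneracy, stop at
$|\Delta r| < 10^{-8}$ (max 1000 iterations); estimates at the clamp
boundaries are reported as 0 or 0.5. The suite checks the EM against a
$10^{-4}$-step grid search of the likelihood on random simulated pairs.

Recombinant inbred lines (RILs) reach homozygosity through repeated
selfing, which gives recombinants extra generations to arise: the observed
recombinant fraction $R$ between fixated homozygotes relates to the meiotic
$r$ by the Haldane–Waddington limit for selfed lines,

$$ R = \frac{2r}{1 + 2r} \quad\Longleftrightarrow\quad r = \frac{R}{2(1-R)}, $$

capped at 0.5. Residual heterozygous RIL calls are treated as missing with a
warning. The LOD score is $\log_{10} L(\hat r) - \log_{10} L(0.5)$ in both
designs; it is zero exactly when $\hat r = 0.5$.

Map distances use Kosambi by default
($d = 25\ln\frac{1+2r}{1-2r}$), switchable to Haldane
($d = -50\ln(1-2r)$); the choice is recorded in map metadata. Kosambi is
the customary default of SSR-era linkage software; since the simulator
draws crossovers without interference (below), Haldane is the exact model
for simulated data and Kosambi shortens simulated maps by a known small
margin (~3% at 3 cM spacing).

## Component-map construction

`build_component_map()` runs: pairwise estimation; grouping; ordering;
double-crossover cleaning; re-estimation on cleaned calls; cumulative cM.
Cleaning needs an order, so the pipeline orders first, cleans, then
re-estimates — the stage list is otherwise the classical one.

*Grouping* is single-linkage transitive closure over pairs with
LOD $\ge$ 5 and $\hat r \le 0.35$. The LOD default matters: with ~200
markers there are >20,000 pairs, and at $n \approx 90$ individuals sample
LOD values up to ~3.5 arise between truly unlinked chromosomes; a LOD-3
rule would occasionally chain chromosomes together. LOD 5 sits in the range
linkage packages customarily use for grouping dense maps and leaves a wide
margin on both sides (true adjacent pairs at 3 cM exceed LOD 15).

*Ordering* minimises SARF, the sum of adjacent recombination fractions:
greedy seriation seeded from the highest-LOD pair, extended at either end
by the nearest unplaced marker, then refined by 2-opt segment reversal and
single-marker reinsertion to a local optimum. Orientation is canonicalised
(lexicographically smaller terminal first) and all ties break on marker id,
so results are deterministic. Multipoint maximum-likelihood ordering is
deliberately not attempted; distances are adjacent-pair estimates. The
suite verifies the optimiser equals exhaustive permutation search on groups
of up to eight markers and recovers simulated 30-marker orders with
Spearman $|r| \ge 0.99$ at $n = 200$.

*Cleaning*: a call whose two flanking calls (3-marker window) agree with
each other but not with it implies a double recombination in a short
interval and is far more likely a genotyping error; such calls are set to
missing and counted per marker. On tight maps the flag count tracks the
planted error count within ±25%. The window is purely ordinal (no cM
condition), so on sparse maps cleaning also removes some genuine double
recombinants; this shortens maps slightly and is the main reason simulated
map lengths land ~5–8% below the genetic truth (well inside the 15%
recovery band the tests demand).

## Bin-mapping consensus integration

A *bin* groups all markers within 1 cM: a greedy left-to-right scan
anchored at each bin's first marker, starting a new bin when the next
marker lies more than 1 cM from the bin start (the anchoring choice is a
documented convention; the scan equals a brute-force interval cover on
random maps). Per bin one *representative* is selected: first markers
shared with the most other maps (bridges), then fewest missing genotypes
(our reading of "information content", which is otherwise undefined), then
lexicographic id. Exclusion regions — e.g. marker clusters created by
recombination suppression in a wide cross — are a generic configuration:
bins wholly inside them carry zero representatives.

Before any bin is seeded, markers with conflicting chromosome assignments
across maps are settled by precedence: (1) majority chromosome among mapped
markers of the same draft-genome scaffold; (2) majority vote among the
component maps; (3) the designated reference map; otherwise the marker is
dropped with a report entry. Each record names the rule applied.

The *skeleton* merges representatives per linkage group: for pairs
estimated in several populations the pooled recombination fraction is the
LOD-weighted mean $\sum w_i r_i / \sum w_i$ with $w_i = \mathrm{LOD}_i$
(an information-weighting approximation to the unpublished internals of
combined-map software; pairs with zero LOD everywhere are excluded), the
pooled LOD is the sum, and ordering/distances proceed exactly as in a
component map. Populations supplied without genotype matrices fall back to
map-distance-derived $r$ with unit weight.

*Residual refill*: each non-skeleton marker is re-introduced at its bin
representative's consensus position plus its original-map offset from that
representative, with the offset sign corrected when the consensus
orientation of the group is reversed relative to the source map, and
clamped so consensus positions stay non-decreasing (a residual violating
monotonicity is placed at the violated neighbour's position). A residual
whose bin has no mapped representative is appended at the nearest flanking
skeleton position with a warning. Since a marker's offset never exceeds its
bin span, residuals stay within their bin's consensus span — a property the
suite checks on random fixtures. Shared markers take their single source
record from the first map (in the order the maps were supplied) whose
assignment matches the resolved chromosome.

Order agreement between maps is quantified by Spearman's rank correlation
of shared-marker orders per linkage group (ties mid-ranked, undefined below
two shared markers).

## The synthetic truth and what it does (not) emulate

`simulate_truth()` generates the study conditions once: seven chromosomes of
100 cM; 30 codominant SSR-like markers per chromosome, near-evenly spaced
with jitter, hosted on draft-genome scaffolds whose physical order matches
the genetic order; and a 70-gene RGH complement — nine clusters of sizes
(2, 11, 3, 4, 2, 7, 5, 12, 6) with the published physical spans (one span
capped at 990 kb so the planted complement is consistent with the strict
< 1 Mbp cluster rule) plus 18 singletons, class counts
(25 CNL, 1 CN, 19 TNL, 5 TN, 17 NL, 3 N), and 12 genes with incomplete NB
domains so 58 enter the phylogeny. Chromosomes are 12 Mbp — a scaled-down
physical genome chosen so gene-bearing scaffolds can sit > 1 Mbp apart
(keeping planted clusters maximal runs) while scaffold sequence stays small;
all sequence is generated only for scaffolds. The default cross designs are
the study's: one F2 of 92 plants and RILs of 77 and 148 lines.

Meioses draw crossovers as a homogeneous Poisson process (rate
length/100 per chromosome) — no interference, making Haldane exact and
Kosambi an analysis choice. Suppression regions thin crossover points by a
multiplier in $[0,1]$, which reproduces the marker-clustering artifact of
recombination-suppressed wide crosses. RILs are simulated either by
meiosis-level selfing for a finite number of generations (the independent
route used to validate the Haldane–Waddington correction) or, at the
default `selfing_generations = Inf`, by a Markov chain along markers with
the fixation-limit recombinant probability. Genotyping errors are symmetric
re-draws among the other valid codes; missingness is applied after error.
One master seed drives stage-specific child seeds, so identical
configurations give byte-identical artifacts.

What passing tests on these data do *not* show: real SSR maps have
segregation distortion, dominant/failed markers, uneven marker spacing and
interference; EST contigs are planted copies rather than assembled reads;
and ortholog fixtures are mutated copies, not diverged genomes. The
statistical guarantees (estimator consistency, order recovery, conflict
resolution) transfer; absolute error rates on real data will differ.

## RGH characterisation

Classification is a grammar over ordered domain lists: NB is obligatory; CC
before the first NB gives the C prefix, TIR the T prefix (both present is
`unclassified` with a warning — no such gene exists in the published
complement); LRR after the last NB gives the L suffix; yielding N, CN, NL,
TN, TNL, CNL. A *cluster* is a maximal run of consecutive genes (per
chromosome, or per scaffold when unanchored) spanning strictly less than
1 Mbp with at least two members — "maximum 1 Mbp" is read as a strict
bound, with the boundary case tested. Span runs from the first member's
start to the last member's end (1-based inclusive); density is
100 × members / span_kb, reported to one decimal; the genetic span is the
range of the members' mapped tag positions.

The NB phylogeny uses the ~120-aa NB domain (P-loop to Kin3 region);
genes lacking a complete span are excluded. Distances are amino-acid
p-distances with pairwise gap deletion; trees are Saitou–Nei
neighbor joining with negative branch lengths clamped to zero; support is
the percentage of column-resampling bootstrap replicates (default 1000,
fixed seed) containing each internal bipartition. NJ is exact on additive
matrices, which the suite exploits as an oracle.

EST support requires a local alignment of a contig to the genic sequence at
$\ge$ 95% identity (matches / alignment length) and $\ge$ 90% coverage of
the gene. Ortholog calls require a reciprocal best match at > 90% identity
and > 95% coverage with both partners single-copy in their own genomes;
synteny membership is a lookup against configured block intervals. At
fixture scale the aligner is `Biostrings::pairwiseAlignment` behind an
exact 12-mer prefilter. Published HMM-search and coiled-coil thresholds
(1e-60, 1e-5, 90% stringency) are carried as provenance metadata on
annotation inputs, never recomputed.

## Physical anchoring

In silico PCR scans both strands for primer sites facing each other within
2000 bp (exact matching by default; mismatches configurable, with no 3'-end
special-casing). A marker is `unique` with one product genome-wide,
`no hit` with none, `multi-copy` with two or more. Scaffolds take the
majority linkage group of their uniquely assigned mapped markers (ties stay
unanchored with a warning); coverage is 100 × anchored bp / genome bp.
Genetic–physical colinearity is the Spearman correlation of cM rank against
physical order (scaffolds ordered by their markers' median cM; within a
scaffold by bp, with orientation inferred from the cM-vs-bp trend sign —
reversed scaffolds are flipped and flagged; single-marker scaffolds anchor
unoriented).

## Reporting and the pipeline

`summarize_map()` reproduces the usual consensus-map summary; the overall
mean adjacent-marker spacing divides total cM by (total loci − number of
linkage groups), i.e. the count of adjacent intervals — applied to the
bundled published per-chromosome table this yields 730.0 / 1674 = 0.44 cM.
Report rounding: cM and densities to one decimal, percentages to one
decimal. `run_pipeline()` chains simulate → map → integrate → annotate →
anchor → report from one validated configuration (unknown keys rejected),
logging every seed and parameter; re-runs reproduce identical artifact
hashes. The pipeline's bootstrap default is 200 replicates (the
operation-level default is 1000); the test suite and the acceptance script
exercise the study-scale problem sizes quoted above — 210 markers in three
populations, 70 genes, 58-leaf trees — which keep a full run in the order
of a few minutes on one CPU.

## Known limitations

No dominant-marker mixtures, outbred designs or multipoint ML mapping; no
graph-based consensus alternatives; the in silico PCR fallback searches
exact primer sites only (the published BLAST fallback's cutoffs are
unstated); whether RIL maps should report meiotic or observed distances is
ambiguous in the source material, so meiotic distances are used throughout
with the observed recombinant fraction retained in the pairwise tables.
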