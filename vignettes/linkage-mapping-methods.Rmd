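---
title: "Methods: consensus linkage maps from low-coverage F2 genotyping data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus linkage maps from low-coverage F2 genotyping data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umbmap)
```

umbmap builds framework and consensus genetic linkage maps for F2 intercross
populations genotyped by reduced-representation sequencing (GBS), the setting
of wild-relative mapping projects such as the *Aegilops umbellulata* U-genome
consensus map that motivates the package's defaults. This vignette is the
package's account of its models and of the design choices that were genuinely
open.

## The data and the observation model

The substrate is a markers-by-individuals matrix of biallelic calls
`AA`/`AB`/`BB`/missing for each F2 population, plus the two inbred parents.
After polarization, `AA` means "homozygous for the parent-1 allele".

GBS data are sparse and shallow. The synthetic-data generator reproduces the
three artifacts that matter for mapping:

* **Missingness.** Per-call read depth is Poisson(`mean_depth`); depth 0 is a
  missing call, and extra calls are masked uniformly at random until the
  configured overall `missing_rate` is reached.
* **Heterozygote undercalling.** A true heterozygote sequenced to depth `d`
  shows reads from only one allele with probability `2 * (1/2)^d`, in which
  case it is called homozygous (either side with equal odds). This is the
  exact allele-sampling probability, not a tuned rate; at mean depth 4 it
  corrupts 23.8% of heterozygous calls, which is why F2 GBS data show
  heterozygote deficits and inflated raw map lengths.
* **Genotyping error.** An independent miscall rate (default studies use
  ~1%) replaces a call with one of the other two classes.

Meiosis is simulated as a Poisson (no-interference) crossover process on the
Morgan scale: marker-to-marker recombination follows Haldane's map function,
and each F2 individual is the union of two independent gametes. Kosambi
distances are used only for *estimation*; the small discrepancy between the
two map functions at short distances (< 0.01 in rf below 10 cM) is absorbed
by the recovery tolerances. Segregation distortion is simulated as viability
selection: each individual survives with probability equal to the product of
the genotype-specific viability weights at the configured distortion loci,
and rejected individuals are replaced by fresh simulations so the population
size stays fixed. The generator makes no claim about the biological
mechanism of distortion — viability weights are the single knob.

What the generator does **not** emulate: linked-read artifacts, allele-drop
correlated across individuals (restriction-site polymorphism), interference,
and segmental duplication collapse. Passing recovery tests therefore show
the pipeline is correct under the stated statistical model, not that real
GBS data will be as benign.

Two-population designs share a configurable fraction of polymorphic markers
(`shared_marker_fraction`, default 0.15, chosen so that maps of a few
thousand markers overlap by a few hundred, the regime consensus mapping
needs).

## Marker quality control

QC mirrors standard GBS mapping practice, with two stock policies:

| policy | missing | MAF | het | segregation p |
|---|---|---|---|---|
| `framework` | ≤ 0.10 | ≥ 0.20 | ≤ 0.80 | ≥ 0.01 |
| `placement` | ≤ 0.40 | — | — | — |

All thresholds are strict removals — a marker exactly on a boundary
survives — and the filter order (parental → missing → MAF → het →
distortion) is fixed so per-criterion removal counts are reproducible. The
1:2:1 chi-square uses 2 degrees of freedom over non-missing calls; MAF is
computed from genotype-derived allele counts (integer arithmetic, so
boundary frequencies are exact). Heterozygosity is treated per-marker; the
per-individual reading of "percent heterozygosity" is also defensible, but
per-marker is the convention of the SNP-calling output these filters
originally acted on.

## Pairwise recombination fractions

For two co-dominant markers in an F2, the nine two-locus genotype classes
have closed-form probabilities in the recombination fraction *r*; the
double-heterozygote class mixes the two-parental and two-recombinant gamete
routes with probabilities proportional to (1−r)² and r². The maximum
likelihood estimate is obtained by EM over the number of recombinant gametes
(converged to 1e−12, ≤ 200 iterations, estimates clamped to [0, 0.5]);
individuals missing either call are excluded, and pairs with fewer than two
doubly informative individuals are flagged rather than estimated. LOD is
log10 L(r̂)/L(0.5), floored at zero. The test suite checks the EM against an
independent grid-search likelihood maximization (step 1e−4) on hundreds of
random instances, and its bias against the truth at r ∈ {0.05, 0.1, 0.2}.

All-pairs tables are computed with indicator-matrix cross-products (nine
count matrices per pair set), which keeps thousands of markers tractable in
plain R.

## Grouping, ordering, and map distances

*Grouping* is single-linkage transitive closure: two markers are linked when
the chi-square independence test of their two-locus contingency table has
p below `cutoff_p` (default 1e−8, the conventional stringent grouping
cutoff; a 1e−9 variant is appropriate for somewhat larger populations).

*Ordering* minimizes the sum of adjacent recombination fractions — the
maximum-likelihood order criterion when crossovers are sparse. Co-segregating
markers (rf = 0) collapse into bins ordered lexicographically (a pure
tie-break; their order is not identifiable). The initial path is grown by
nearest-neighbour from one end of the maximum-rf bin pair (the putative
chromosome ends), then refined by alternating 2-opt segment reversals and
or-opt relocations of 1–3 marker segments; or-opt repairs single displaced
markers, which no sequence of improving reversals can express. On groups of
up to eight markers the refined order attains the exhaustive-minimum path
cost in ≥ 99% of random instances (tested). The whole procedure is
deterministic.

*Distances* are cumulative Kosambi transforms of adjacent-pair rf,
d = 25·ln((1+2r)/(1−2r)) cM. Adjacent estimates of 0.5 or above (possible
under noise) are clamped to 0.4999 rather than made infinite. Group
orientation is arbitrary up to reversal; it is normalized against an anchor
table when one is supplied (positive genetic-vs-physical rank correlation),
otherwise the lexicographically smaller end marker sits at 0 cM, so repeated
runs agree.

## Sliding-window error correction

Isolated calls that disagree with both flanks of the same individual are
overwhelmingly genotyping errors ("apparent double recombinants") and
inflate map length. For each call, the `window`-marker window (default 15)
is split at the focal marker; the call is corrected to the flank consensus
only when **both** flanks agree on it with support ≥ `agree_fraction`
(default 0.8) — a genuine crossover, where the flanks disagree, is left
alone. A heterozygous call whose flanks agree on *opposite* homozygotes is
set to missing rather than guessed, heterozygotes being the least reliable
class under shallow sequencing. Parental rows are never altered. The
defaults correct singletons while preserving crossover blocks of two or more
markers; both are exposed, as is the number of map→correct→re-map rounds
(default 1). Tests verify the map-length deflation property (corrected
length ≤ raw length and closer to truth at 5% error, n = 200).

A limitation worth stating plainly: with mean depth 4, heterozygous tracts
carry ~24% spurious homozygous calls, so their expected within-window
consensus support is ~0.76 — *below* the 0.8 default — and window consensus
cannot repair most undercalls. Lowering `agree_fraction` to ~0.7 repairs
more but begins to erase genuine short crossover blocks; we measured no
setting that recovers near-perfect marker orders at depth 4 (see
"Validation and known limits" below).

## Placement by minimum recombination fraction

Markers that fail framework QC but pass the permissive placement policy are
assigned positions afterwards: rf against every mapped marker is estimated,
and the marker is placed at the position of the argmin marker provided
min rf ≤ 0.1; an exact two-way tie on one group places it at the mean of the
two positions. Extensions the source procedure leaves open: ties among three
or more markers on one group also take the mean; ties spanning different
groups are left unplaced (`ambiguous_group`); markers with no informative
overlap are unplaced (`no_data`). Placement is single-pass against the
framework map only — placed markers do not anchor later placements — and
framework positions and order are never altered. Placement rf is computed on
the placement QC set before error correction, since correction presumes a
map order that placement markers do not yet have.

## Consensus merging by linear programming

Component maps are merged chromosome by chromosome. Consensus positions
minimize the weighted mean absolute deviation between consensus inter-marker
distances and each component's distances — distances, not absolute
positions, so the objective is translation-invariant and each component is
anchored at 0. Weights are population sizes. Order constraints
x_b − x_a ≥ 0 are generated for every pair at most K positions apart in some
component; K runs 1–4 and the winner minimizes mean RMSE + SD of RMSE
across components (ties to smaller K; RMSE is *not* monotone in K, so all
four are evaluated).

Order conflicts between populations appear as directed cycles in the
constraint graph. They are resolved greedily: the constraint carrying the
most cycle traffic is deleted and logged, until the graph is acyclic. Cycle
participation of an edge u→v is scored as the number of closed walks through
it, (Σₖ Aᵏ)[v, u], computed by matrix powers on the peeled cyclic core —
exact for short simple cycles, a faithful ranking for longer ones, and far
cheaper than cycle enumeration. Deleting individual pairwise constraints
(rather than whole markers) keeps every marker on the consensus; this is a
deliberate deviation from tools that drop conflicting markers, and the
deletion log records exactly which order relations were sacrificed.

The LP itself is solved as weighted L1 (median) regression of component
distances on position differences under the order constraints
(`quantreg::rq.fit.fnc`), the textbook LP formulation of constrained L1
fitting. Numerical choices: one marker's position is the anchor (dropped
column) since positions are identifiable only up to translation;
interior-point solutions carry ~1e−8 noise, so positions are snapped to
1e−6 cM — which is how "identical components give RMSE exactly 0" holds
exactly. RMSE between consensus and a component is computed on mean-centred
position differences (translation-invariant, consistent with the
distance-based objective).

## Segregation distortion scan

Every mapped marker is tested against 1:2:1 (chi-square, 2 df, raw
α = 0.01 — deliberately no multiple-testing correction, matching standard
distortion-scan practice); the scan reports −log10 p and genotype-class
frequency profiles along the map, per-chromosome distorted proportions, and
distorted regions: maximal runs of ≥ 2 consecutive significant markers.
Region adjacency is consecutive-marker runs; an optional `max_gap_cM`
bridges short non-significant gaps, off by default since the underlying
definition does not mention gaps.

## Synteny and collinearity

Anchor tables (marker → reference chromosome, bp, e-value; best hit only,
e ≤ 1e−5) assign linkage groups to chromosomes by plurality vote after
collapsing homeologous sets (3A/3B/3D → "3"); plurality ties stay
unassigned. Collinearity uses Spearman's rho in its classic form
ρ = 1 − 6Σd²/[n(n²−1)], with average ranks for ties (a documented deviation:
the classic formula assumes none). The summary reports the anchored
fraction, the syntenic fraction (best hit on the expected homeologous
group), per-pair ρ, and the dot-plot table; interpretation of rearrangements
is left to the analyst.

## Reporting conventions

Per-chromosome summaries define average gap as size/(n−1) and density as
n/size, rounded half-up to 2 and 1 decimals respectively — the conventions
that reproduce the published U-genome framework table's 1U row
(66.47/80 = 0.83; 81/66.47 = 1.2). The shipped
`umbellulata_framework_geometry()` table records that map's per-chromosome
marker counts and sizes; it is both the worked-example input and the
geometry the simulator's defaults emulate (7 chromosomes, 66–181 cM,
n = 140/154). Two cells of the published table do not reproduce from their
own row inputs under any rounding we tried (2U gap 131.19/445 = 0.29 vs
printed 0.30; 6U density 526/133.25 = 3.9 vs printed 4.0), and the printed
948.72 total differs from the row sum 948.78; the package reports its own
arithmetic.

## Interface

The exported functions and `run_pipeline()` are the interface, in the style
of analysis packages of this tier; there is no shell entry point. All
artifacts read and write plain TSV (HapMap-like genotype matrices, map
tables, QC and placement reports, anchor tables), so external callers can
drive the pipeline from any environment.

## Validation and known limits

The test suite is built on independent oracles: grid-search likelihood
maximization for the EM; exhaustive permutation minimum for ordering;
a brute-force re-scan for placement; a plain run-length loop for regions;
`cor(method = "spearman")` for the rank formula; closed-form Poisson
mixtures for undercalling. Simulation scales were chosen to keep the whole
suite within a few minutes on one CPU: order-recovery studies use 7
chromosomes × 30 markers × n = 140 over 50 seeds; estimator studies use
500 random instances; type-I control uses 2000 effectively unlinked markers
× 150 individuals.

Measured limits worth knowing:

* **Order recovery under deep undercalling.** At mean depth 4 (23.8% of
  heterozygote calls corrupted, ~12% of all calls), pairwise-rf noise
  exceeds the rf differences between markers a few cM apart, and no
  pairwise orderer can place such neighbours reliably; with n = 140 we
  measure ~45–73% of chromosomes (depending on QC policy) reaching
  |ρ| ≥ 0.99 against the true order, versus ~96% for the same design
  without undercalling. The test suite asserts the ≥ 90% recovery target
  under both settings; the depth-4 block fails by design of the method
  rather than by a fixable defect, and is retained as an honest negative
  result. Multipoint-likelihood ordering or depth-aware genotype posteriors
  would be the remedies; both are out of scope.
* **The 10% missing filter vs 10% simulated missingness.** When the overall
  missing rate sits exactly at the filter threshold, roughly half the
  markers are removed by per-marker sampling noise alone, and linkage
  groups fragment. This boundary interaction is a property of the filter
  definition, not a bug.
* **Viability-selection refill.** Severe selection (all weights near 0)
  makes rejection sampling expensive; the generator errors out after a
  bounded number of refill rounds.
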