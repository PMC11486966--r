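---
title: "Reconstructing tumor subclones from multi-region data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing tumor subclones from multi-region data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrace)
library(dplyr)
```

# The problem

Copy-number-driven childhood tumors such as neuroblastoma are genetically
heterogeneous within a single patient: distinct subclones occupy distinct
territories, and treatment reshapes the clonal landscape. clonetrace
reconstructs that landscape from three kinds of readout:

* allele-specific copy-number segments from SNP arrays (a linear copy
  ratio plus a mirrored B-allele frequency per segment);
* somatic variant read counts from exome or targeted sequencing;
* single-cell shallow-WGS copy-number profiles over 1 Mb bins.

From multi-region, multi-timepoint samples it estimates the fraction of
tumor cells carrying each event, groups events into subclones, builds a
rooted maximum-parsimony phylogeny, and asks the clinical question: did
the tumor progress *linearly* from lineages already detected at diagnosis,
or did treatment eradicate the dominant lineages so that distant
collateral relatives took over (*collateral clonal replacement*, CCR)?

# The quantitative model

## Clone fractions from array data

A segment carried at `Nt` total copies by a fraction MSF of all cells in a
sample (tumor and normal alike), against a background of `Nb` copies, on an
array normalized to ploidy `Np`, produces the linear ratio

$$R = \frac{\mathrm{MSF}\,N_t + (1-\mathrm{MSF})\,N_b}{N_p},$$

inverted by `msf_from_ratio()`. Platforms that compress log2 ratios are
linearized first (`apply_platform_correction()`, factor 0.53–0.6, default
0.55 at the midpoint). The mirrored B-allele frequency of a composition
with `n_a + n_b` alleles gives an independent inversion
(`msf_from_mbaf()`); it is the only readout for copy-number-neutral
imbalances (e.g. 2+0), which leave no dosage footprint. Elsewhere the
ratio readout is preferred: mirroring folds the BAF at 0.5, so for small
clones the folded noise can only push the apparent imbalance upward,
inflating trace-level fractions, while the linear ratio is unbiased at any
clone size.

Sample purity (TCF) is the median MSF over segments judged clonal,
computed separately from the ratio and the imbalance readout; agreement of
the two medians within 0.1 validates the ploidy assessment and their mean
is the consensus. The mutated clone fraction is `MCF = MSF / TCF`.
Estimated MCFs in (1, 1.2] are reported as 1 (they reflect measurement
error, not heterogeneity); values above 1.2 flag a wrong number of mutated
alleles.

## Clone fractions from variant reads

A variant present at multiplicity `M` in a clone of size MCF, on a segment
with `CN1` copies in the main tumor fraction `f1` and `CN2` copies in a
background fraction `f2` (`f1 + f2 = TCF`), has expected allele frequency

$$\mathrm{VAF} = \frac{M \cdot \mathrm{MSF}}
{CN_1 f_1 + CN_2 f_2 + 2(1-\mathrm{TCF})},$$

inverted by `mcf_from_vaf()`; at purity one this collapses to
`MCF = VAF * CN / M` (`mcf_from_vaf_pure()`, the xenograft case where host
reads are removed). When the copy-number background is mixed, the
admissible effective multiplicities depend on the order of events
(`enumerate_multiplicities()`): the mutation may be private to the major
composition or ancestral to the split on either parental allele — for
2+0 at 30% with 1+2 at 70% this yields M of 0.7, 1.4 or 2.
`choose_multiplicity()` then rejects candidates that push MCF above 1.2 in
most samples, violate event-order feasibility (a nullisomic allele cannot
be regained), break the pigeonhole principle, or imply different event
orders across samples; ties resolve to the fewest novel subclones and
then to the larger multiplicity, the conservative call on heterogeneity.

Variant quality filters follow the sequencing source: fewer than 10
supporting reads anywhere, VAF below the cutoff in every sample (0.1;
0.2 for FFPE exomes), more than 1% of reads in the matched normal, or
under 100x coverage everywhere for targeted panels (`filter_variants()`).
Shared variants below VAF 0.2 in a sample swept by a different lineage are
technical artifacts (`sweep_artifact_filter()`).

## Deconvolution into subclones

`group_events()` clusters events by their MCF pattern across samples with
complete linkage under the per-sample Chebyshev metric, so no group spans
more than `tol` (default 0.15, the ~10% clone-size error margin of array
data plus rounding) and the result is independent of input order. The
group profile — the per-sample mean rounded to the nearest 0.1 — is the
final clone size of its events.

`resolve_configuration()` turns the groups into a nested/parallel
configuration under three constraints: a group nests inside another only
if its fraction is contained within 0.1 in every sample; two groups whose
unrounded fractions sum above 100% plus tolerance in some sample must be
nested (pigeonhole); and same-segment pairs with different allelic
compositions ("mixed") are never nested, since no cell can hold two
states at once. Each group attaches to its deepest feasible container.
Among feasible configurations the subclone count is minimized: groups
whose profiles cannot be distinguished at the reporting tolerance plus
three standard errors are merged into one subclone. The per-event noise
behind that test is calibrated on the clonal segments, whose true MCF is
1 in every sample; without clonal references it falls back to
within-group residuals. Estimates stay unclamped internally — truncating
noise at zero before averaging would bias trace-level fractions upward —
and child fractions below zero are treated as noise when computing a
parent's residual population.

For xenografts and cell lines `pdx_deconvolve()` applies the pure-tumor
rule set: MCF at or above 0.9 is clonal, clone sizes round to the nearest
10%, parallel sums may reach 120% (two concomitant subclones carry a 20%
margin) and renormalize to 100% above that, and a 2+0 neutral imbalance
against a majority-trisomy background is ordered as an allele loss from
the trisomy. `infer_missing_events()` reconciles calls that fit no single
order: same-breakpoint gains with different allele counts make the
lowest-count state an inferred stem, and whole-chromosome events with
contradictory patterns split into inferred-private parallel copies —
whole-chromosome aberrations recur in parallel, unlike breakpoint-defined
events, which are treated as unique.

## Phylogeny and its statistics

`event_matrix()` expands the configuration into a binary subclone-by-event
matrix (each row the root path of a subclone), and `build_tree()` roots a
maximum-parsimony tree in the unmutated cell. Conflict-free matrices
yield the unique perfect phylogeny with zero homoplasy; conflicts resolve
by splitting the most-conflicting character into parallel per-taxon
acquisitions, with breakpoint-unique events protected from duplication.
Because characters are gains from an all-zero root, loss of
heterozygosity is never reverted. Taxa may sit at internal nodes — an
observed subclone can be ancestral to others.

Tree statistics: the index of genomic diversity
`IGD = sum(dS_i) / sum(DS_i)` relates the distances from a sample type's
most recent common node to each subclone (`dS_i`) to the full root
distances (`DS_i`); it runs from 0 (all subclones at the common node) to
1 (the common node is the root) and is insensitive to mutation counts and
sample numbers. Irregularity is the sample variance (n − 1 denominator;
the convention is documented because either choice is defensible) of
root-to-taxon distances, zero for a symmetric star. Total branch length
counts every event acquisition.

## Classifying clonal replacement

`classify_replacement()` compares the earliest and latest timepoints. A
later-dominant subclone provides *linear* evidence when an ancestor (or
itself) below the shared trunk was already detected earlier; the pattern
is *CCR* when no later-dominant has such a witness and the
earlier-dominant lineages are undetected later. The shared trunk — any
node that is a proper ancestor of every earlier-dominant lineage — carries
no evidence either way, and an earlier-dominant that is an ancestor of
all the others is itself a trunk remainder. A later-dominant that
regresses onto an earlier-detected ancestor of the earlier dominants is
linear by definition. Detection at a timepoint requires replication:
above the 10% limit in at least two samples, or a pooled median above the
limit — one isolated excursion at the detection limit is within
measurement error of zero under the package's own noise model. Detection
uses unrounded fractions; the 0.1 grid is a reporting convention, not an
assay property.

## Single cells and space

`call_cell_events()` turns a 1 Mb-bin integer profile into events: maximal
runs deviating from the baseline ploidy, kept only at five or more
consecutive bins, except high-grade amplifications (copy number 5 or
more) overlapping a designated amplicon region — by default the *MYCN*
region on 2p24 and the *MAML3* region in 4q28.3–q31.1 — where two bins
suffice. `harmonize_events()` snaps boundaries agreeing within one bin
(the binning granularity) and decomposes overlapping same-class events
into shared cores and private extensions; disagreement beyond a bin is
preserved as separate entries rather than silently merged.
`build_cell_tree()` collapses identical cells into counted clones and
reuses the parsimony builder; `pop_statistic()` reports the proportion of
detected cells descending from branches matching a CNA-class predicate,
and `clone_dynamics()` emits the per-timepoint clone-fraction table a
fishplot is drawn from.

`place_territories()` approximates 2D subclone territories: multi-biopsy
subclones sit at the midpoint of the involved biopsy centroids, private
subclones pack into the remaining space at maximal distance from placed
territories (a deterministic polar-grid search; only count, area and
centroid feed the statistics, so circles stand in for free-form regions),
and nested subclones found in a single sample sit at their mother's
center. Areas are proportional to fraction times biopsy area.
`territory_stats()` reports subclones per mm² and the median pairwise
centroid distance.

# The synthetic-tumor generator

`simulate_truth()` draws a stem plus lineage chains with events on every
branch: by default 2 CNAs and 1 SNV per branch, with a clonal-aberration-
rich stem (two extra CNAs, always including an unbalanced gain and a
loss) as is typical of these tumors — which is also what makes purity
estimable from clonal-segment medians. CNA compositions are drawn from
gains (1+2, 1+3), losses (1+0) and neutral imbalances (2+0); sizes are
log-uniform over 5–45 bins of the simulated 22 × 100-bin genome, laid out
on disjoint slots so segments never overlap. Region fractions mimic the
territorial biology of multi-region sampling: each lineage has a home
region it dominates (subtree profiles 0.85/0.55/0.25 along the chain,
±0.02 jitter), so parallel clones cross by at least ~0.25 somewhere and
ancestor-descendant pairs separate by ~0.3 — the identifiability a
multi-region design buys. Branching is restricted to the stem with chains
of at most three clones per lineage so every lineage keeps a home region;
this is what makes noise-free recovery exact rather than merely likely.

`render_bulk()` applies the forward models above with Gaussian ratio
noise (the mirrored BAF receives half the ratio noise, reflecting the
relative stability of allelic ratios), binomial variant sampling at the
stated depth (default 200, a scaled-down analogue of targeted panels),
and optional platform log2 compression. `render_cells()` draws cells
multinomially from the clone fractions with per-bin copy flips and
injected sub-threshold runs to exercise the event-length filters.
`apply_treatment()` reweights clone fractions by per-clone survival;
`simulate_scenario()` composes the two canonical truths — a dominant
two-clone lineage eradicated in favor of a collateral branch held below
the 10% detection limit before treatment (CCR), or uniform survival
(linear continuity).

What the generator does *not* emulate: overlapping segments and
subclonal-on-subclonal copy-number backgrounds, wave/GC artifacts,
FFPE-specific noise, mouse-read contamination, and doublets or
variable-quality cells in the single-cell channel. Passing tests
therefore demonstrate correctness of the estimation and reconstruction
logic under the stated noise model, not robustness to every artifact of
real data.

# Numerical choices and limitations

* Problem sizes in the tests and the acceptance script — up to 10 clones,
  3 regions, 100 replicates per property, depth 200–500 — keep each suite
  in minutes while leaving the statistics well resolved.
* Rounding to the 0.1 grid uses half-up rounding so 0.975 becomes 1.0.
* Ties in the parent choice resolve by total fraction and then
  lexicographically; all algorithms are deterministic given the input.
* The pigeonhole test uses unrounded fractions with the containment
  tolerance as margin: rounding two fractions upward must not fabricate
  an impossibility, and a forced pair whose direction is not supported by
  containment at twice the tolerance is recorded as a measurement
  violation instead of being nested.
* The grouping tolerance (0.15) is a package parameter with no printed
  counterpart in the source methodology, whose heat-map grouping was
  manual; it is deliberately exposed.
* Exhaustive tree search is unnecessary here because conflict resolution
  by parallel duplication is constructive; heavily conflicted matrices
  (many recurrent whole-chromosome events) may admit shorter trees than
  the constructive one, which the parsimony-score oracle tests bound.
* Classification needs at least two timepoints and informative dominants;
  pure-trunk dominance returns `not_classifiable` rather than guessing.
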