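---
title: "Methods: separating marginal-zone from memory B cells with mzatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: separating marginal-zone from memory B cells with mzatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mzatlas)
```

## The scientific problem

Human marginal-zone (MZ) B cells (CD27+IgM+IgD+) and class-switched memory
B cells share CD27 expression and somatically mutated IGHV genes, which has
long made their relationship contentious. mzatlas implements the
computational machinery needed to ask, on three independent data
modalities, whether these populations are developmentally continuous or
separate:

1. **Suspension mass cytometry** — embed events, cluster them into nodes,
   group nodes into subset "bubbles", and test whether a focal
   subpopulation (the CD27-negative CD45RB-positive MZ precursor inside the
   naive bubble) is phenotypically distinct from its parent.
2. **Imaging mass cytometry** — treat each ~1 µm ablation spot as an event
   ("pixel-as-event"), classify pixels into subsets, and quantify where
   subsets sit relative to landmarks (germinal centre, epithelium).
3. **IgH repertoire sequencing** — quality-control amplicon reads, group
   sequences into clones with a hypermutation-aware distance, and measure
   clone sharing between subsets, sites and isotypes.

Every analysis arm is paired with a seeded synthetic-data generator that
emits ground truth, so recovery can be measured rather than assumed.

## The bootstrap distinctness test

The central statistic of the suspension arm asks: does the focal
subpopulation differ from the parent population it was found in? The null
model is resampling: draw `n_focal` events (the observed focal size) with
replacement from the parent, record the per-marker median, and repeat `B`
times (default `B = 10000`). The observed focal median is standardised
against this null:

$$ z_m = \frac{\mathrm{med}(x_{m}^{\mathrm{focal}}) - \mu_m^{\mathrm{null}}}{\sigma_m^{\mathrm{null}}} $$

Numerical choices:

* the null SD uses denominator `B` (the resample-median vector *is* the
  Monte-Carlo null distribution, not a sample estimate of one);
* when the null SD is zero, `z` is 0 if the observed median equals the null
  mean and signed-infinite otherwise;
* empirical two-sided p-values (rank of the observed median among the null
  medians, with +1 smoothing) accompany `z`, since medians are discrete and
  can be non-normal at small `n_focal`;
* the default flag threshold is `|z| >= 2`, boundary inclusive, two-sided;
  no multiple-testing correction is applied, but the marker count is
  carried in the output so users can correct;
* the parent includes the focal events by default (resampling from the
  bubble as observed), with an `exclude_focal` option.

The test is validated against exhaustive enumeration: for a parent of `n`
events and `n_focal = k` there are `n^k` equally likely ordered resamples,
so the exact null mean and SD of the median are computable by brute force
for small fixtures, and the bootstrap must agree within Monte-Carlo error.

## Suspension pipeline choices

* **Transform.** `asinh(x / 5)` — the mass-cytometry convention. The
  synthetic generator draws intensities directly on this transformed scale
  (location-scale normal truncated at zero) because every analysis step
  operates post-transform; simulating raw ion counts would add a layer the
  methods never see.
* **Embedding.** The embedding contract is pluggable: any seeded,
  neighborhood-preserving 2-D method. The default is an exact t-SNE
  (perplexity 30) run on up to 1500 events; larger tables are embedded by
  seeded subsampling with nearest-neighbour placement of the remaining
  events, the usual down-sampling scheme for event-level embeddings. A PCA
  backend is available for fast screening. No test or acceptance check
  depends on exact coordinates, only on recovery metrics.
* **Node clustering.** k-means (`k = 100` by default, Lloyd iterations,
  seeded) on the two embedding coordinates only — clustering in the
  embedded space rather than marker space, mirroring the node-on-embedding
  scheme. Node medians are then computed on *all* panel markers, which is
  what lets held-out markers (CD45RB) be read out on nodes that were
  clustered without them.
* **Bubbles.** Subset bubbles were drawn manually in the original
  workflow; here they are rule-based on node medians with a fixed priority
  order (GC, plasmablast, transitional, precursor, MZ, IgM-only, switched
  subsets, naive, then "other"). Default thresholds sit at the midpoint
  (1.9) between the synthetic negative (0.3) and positive (3.5) archetype
  locations; for real data, per-marker thresholds must be supplied.
* **Subset dendrograms.** Euclidean distance between subset median vectors
  over all measured markers, Ward linkage (`ward.D2`) by default,
  configurable.
* **Sample MDS.** Classical (Torgerson) scaling with Kruskal stress-1,
  `sqrt(sum((d - delta)^2) / sum(delta^2))`, reported as the information
  lost by the reduction.

## Imaging pipeline choices

* Pixels are the unit of analysis — no cell segmentation, exactly as in
  the pixel-as-event scheme. Coordinates are 0-based, row-major, origin
  top-left, `x` = column, `y` = row, stored on a linear scale.
* Stitching places tiles at integer offsets; where tiles overlap the later
  tile wins (the overlap rule is otherwise unspecified upstream, so it is
  fixed and documented here).
* Low-intensity cleanup zeroes values *strictly below* the per-channel
  threshold (boundary kept).
* Classification is two-stage: stage 1 clusters all pixels on all channels
  and keeps nodes whose CD19 and CD20 medians pass thresholds (default:
  the same synthetic-scale midpoint, 1.9); stage 2 re-embeds the retained
  pixels on the nine B cell markers (CD10, CD19, CD20, CD24, CD27, CD38,
  CD45RB, IgM, IgD) and assigns nodes to subsets by rule. Nodes matching
  no rule go to "other" and are excluded from all masks. "Confident
  placement" was a manual judgement upstream; here it is rule coverage
  with an explicit "other" bucket.
* Spatial statistics measure the Euclidean distance from each subset pixel
  to the nearest pixel of a reference mask (0 inside the reference), i.e.
  distance to the reference *boundary* rather than its centroid — this is
  the quantity that matches "adjacent to the GC" phrasing.
* Held-out validation compares per-subset medians of CD45RB and CD24 —
  markers not used for subset designation — between the pixel and
  suspension arms by Spearman rank correlation.

## Repertoire QC choices

Boundary semantics are deliberate and tested:

* reads shorter than 250 nt or with mean Phred below 20 are removed
  (strictly-less removal, so a read at exactly the boundary is kept);
  mean quality is computed on raw Phred scores, not in the
  error-probability domain — simpler and the common default;
* MID demultiplexing is exact-match only, at both ends; reads whose 5' and
  3' MIDs disagree are flagged and later removed as suspected chimeras;
* primer matching is ungapped at the expected offset with an inclusive
  mismatch budget of 0.2 (4 mismatches on a 20-mer pass; 5 fail); forward
  (V-region) primers are masked with Ns, reverse (constant-region) primers
  are trimmed, and the isotype is read off the reverse primer id;
* duplicate collapse keys on (sequence, MID, forward primer, reverse
  primer) and conserves read counts;
* the chimera sliding-window rule removes sequences with strictly more
  than 5 mismatches in any full-width 10-bp window against the germline;
  trailing windows shorter than 10 are not evaluated;
* mutation counts exclude N-masked positions and the junction N region
  (mutations are defined relative to germline-templated positions); the
  junction-exclusion choice is configurable in principle but is the
  default because junction nucleotides have no germline template.

V/D/J germline assignment itself is out of scope: annotation is consumed
from AIRR-style columns (real data) or generator truth (synthetic).

## Clonal grouping

Sequences are first partitioned by V gene, J gene and junction length,
with allele suffixes (`*01`, `*02`) collapsed to gene level so allele
miscalls cannot split true clones. Within a partition, the distance
between two junctions is the number of nucleotide differences, each
weighted by a 5-mer context model of hypermutation targeting and
substitution, normalised by junction length. The weight of one mismatch is
symmetrised as the mean of the two directional weights (a→b in a's
context, b→a in b's). Edge positions without a full 5-mer context fall
back to weight 1, as do Ns (excluded from the evaluated length). With a
uniform model the distance is exactly the normalized Hamming distance —
an identity the tests assert.

Clones are single-linkage connected components under `d < 0.2` (strict
inequality, matching the "less than" phrasing of the threshold's
definition). Distance-to-nearest diagnostics report each sequence's
nearest within-partition neighbour; singletons are undefined (NA), never
zero. A threshold suggestion — the deepest density valley between the two
largest modes — is diagnostic only; the operational default stays 0.2.

The published empirical 5-mer tables are not bundled; a synthetic
non-uniform toy model ships for exercising the weighting machinery, and a
user-supplied TSV (5-mer by four target bases) plugs in real weights.

Lineage trees are germline-rooted minimum spanning trees on
substitution-count distance, with ties broken by higher duplicate count
then lexicographic id, and the total edge weight reported as a
parsimony-style score. This is a documented approximation to full
maximum-parsimony search: it infers no internal nodes, but preserves the
germline rooting and mutation-count edge annotations that downstream
clone-dispersion readouts use.

## Clone-sharing statistics

* **Abundance matrices** count unique sequences per clone per
  (site, isotype) column; `log10(n + 1)` is used for display so absent
  combinations map to zero.
* **Distribution clustering** normalises each column by its total,
  compares columns by Manhattan distance and agglomerates with Ward.D.
* **Sharing percentages** are asymmetric by design: the percentage of
  subset-A sequences at site 1 whose clone contains a subset-B member at
  site 2, with subset-A-at-site-1 as denominator. Both directions are
  reported. Sharing is counted at the unique-sequence level by default
  (duplicate-weighted on request), since the weighting convention is not
  otherwise pinned down.
* **GC membership rates** report, per clone class (e.g. MZ-containing),
  the percentage of clones with at least one GC member — raw ratio kept,
  one-decimal rounding for the printed report.
* **Overlap tests** build per-donor 2x2 tables of clone class against
  contains-an-IgA-member and use the two-sided Fisher exact test
  (probability-mass rule), combined across donors by Fisher's method
  (`X2 = -2 * sum(log p)`, df = 2k). Donors with a degenerate (zero-margin)
  table are excluded rather than imputed, and a pooled-table Fisher exact
  p is reported alongside, clearly labelled as a surrogate: the exact
  per-donor margins behind the combined statistic are not recoverable from
  printed ranges alone.
* **Public clones**: the percentage of unique sequences whose exact
  nucleotide sequence occurs in more than one donor.

## What the generators emulate — and what they do not

The cytometry generator draws each event from one of twelve subset
archetypes (location-scale normal on the arcsinh scale, truncated at 0)
whose locations encode the precursor shift pattern: higher CD24, IgM,
CD45 and CD45RB than naive cells, lower BCMA, HLA-DR, IgD and CD38.
Prevalences and mild location imprinting differ by tissue so replicate
samples of a tissue cluster together. It does **not** model spillover,
acquisition drift, doublets or dead cells — passing recovery tests shows
the pipeline recovers well-separated mixture structure, not that it is
robust to those artefacts.

The tissue generator lays out an epithelial band, a peripheral memory
band, a GC disc with an MZ annulus sharing its boundary, a naive annulus
outside that, and a T zone (512 x 512 px by default; the layout scales
down to 128 px). The geometry builds in the spatial hypothesis being
quantified — MZ adjacent to the GC, memory at the periphery nearer the
epithelium — so spatial-summary tests verify that the measurement
machinery reports a known geometry correctly, not that tissues look like
this.

The repertoire generator creates clones sharing V/J and junction length
(founder junctions start with the conserved cysteine codon), members by
independent per-base substitution at `shm_rate` per lineage step (1-3
steps; star/branching topology), clone-level isotypes (so dissemination
is isotype-faithful), sites drawn per member, spliced-germline chimeras at
a configured rate (half with mismatched MIDs), and a fraction of
non-functional records. Donors never share founders, so the cross-donor
public-clone rate is zero by construction — the public-rate machinery is
exercised by explicit fixtures instead. Default rates: 150 clones,
power-law clone sizes (exponent 2, max 20), `shm_rate = 0.01` per step,
2% chimeras, 2% non-functional; these keep within-clone junction
distances well below 0.2 and between-clone distances well above, which is
the regime the 0.2 threshold was designed for. The generator uses a
bundled synthetic germline pool (10 V, 4 J segments) — real IMGT
germlines are deliberately not shipped.

## Problem sizes and determinism

The test suite and acceptance script use desk-scale sizes chosen to keep
a full run in minutes on one CPU: 6000-event cytometry samples (t-SNE on
a 1200-event subsample), `B = 2000`-`10000` bootstrap replicates,
60-300-clone repertoires, and the default 512 x 512 image. All
generators and all stochastic stages are seeded, and seeded runs are
bit-reproducible; the pipeline derives per-stage seeds from one global
seed by a fixed offset scheme so stages re-run in isolation reproduce
their in-pipeline streams.

## Known limitations

* Bubble-rule thresholds are calibrated to the synthetic scale; real data
  require user-supplied thresholds per marker.
* The lineage builder is an MST approximation, not maximum parsimony; for
  clones with convergent mutations the topology can differ from a full
  parsimony search even though the score is reported for comparison.
* The toy 5-mer model exercises the weighting code path but carries no
  biological hot-spot structure; conclusions about real hypermutation
  targeting require the published tables.
* The imaging classifier assumes zone-level marker homogeneity; it has no
  noise model for ablation artefacts, channel spillover or tissue
  autofluorescence.
* Bead normalization, file concatenation and V(D)J germline inference are
  treated as upstream steps and are not reimplemented.

## A worked end-to-end run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(out_dir = "run1", seed = 1,
                       stages = c("cyto", "distinct", "repertoire"))
man <- run_pipeline(cfg)
man$files
```

The manifest lists every output file with its MD5 checksum and record
count; re-running with the same configuration reproduces the checksums.
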