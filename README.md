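# mzatlas

Tools for separating human **marginal-zone (MZ) B cells** (CD27+IgM+IgD+)
from **class-switched memory B cells** across three data modalities, with
seeded synthetic-data generators carrying ground truth for every arm.

The two populations share CD27 and somatically mutated IGHV genes, so
telling them apart requires evidence from several directions at once.
mzatlas implements the computational core of that argument:

* **Suspension mass cytometry** — arcsinh transform, gating, seeded 2-D
  embedding (t-SNE-class, pluggable), k-means node clustering on the
  embedding, rule-based subset "bubbles" for twelve B cell subsets
  (including the CD27−CD45RB+ MZ precursor), median profiles, sample-level
  MDS with Kruskal stress, and subset dendrograms.
* **Bootstrap distinctness test** — is a focal subpopulation (e.g. the
  CD45RB+ cells inside the naive bubble) different from its parent? The
  null resamples `n_focal` events with replacement from the parent
  `B = 10000` times and records per-marker resample medians; the observed
  focal median is standardised as
  `z = (median_focal − mean_null) / sd_null`, with empirical p-values
  alongside.
* **Imaging mass cytometry** — pixel-as-event pipeline: tile stitching,
  low-intensity cleanup, two-stage pixel classification (CD19+CD20+ node
  selection, then nine-marker subset assignment), disjoint per-subset
  masks, and spatial summaries (distance to the GC boundary and to the
  epithelium).
* **IgH repertoire analysis** — read QC (length/quality filters, exact MID
  demultiplexing, primer mask/trim at a 0.2 error budget, duplicate
  collapse), chimera filters (MID mismatch; >5 mutations in a sliding
  10-bp window), clonal grouping by V/J/junction-length partition plus a
  5-mer-weighted normalized junction distance with single-linkage
  clustering at `d < 0.2`, distance-to-nearest diagnostics,
  germline-rooted lineage trees, and clone-sharing statistics
  (site-isotype abundance clustering, sharing percentages, GC-membership
  rates, per-donor Fisher exact tests combined by Fisher's method, public
  clone rate).

## Worked example

Simulate a gut-tissue sample, test whether the MZ precursor is distinct
from naive B cells, then group a synthetic repertoire into clones:

```r
library(mzatlas)

tab <- sim_cytometry_sample(default_cyto_archetypes("GALT"), 4000, seed = 1)
focal <- tab[tab$truth_subset == "precursor", ]
res <- distinctness_test(tab[tab$truth_subset %in% c("naive", "precursor"), ],
                         focal, B = 5000, seed = 2)
res[res$marker %in% c("CD24", "IgM", "CD45RB", "IgD", "CD38", "BCMA"),
    c("marker", "focal_median", "null_mean", "z", "flag")]
#>  marker focal_median null_mean         z flag
#>    CD24    3.3892536 2.3539148  20.99245 TRUE
#>    CD38    1.2399765 2.0192023 -17.54552 TRUE
#>  CD45RB    3.4814663 0.4480919  57.44432 TRUE
#>     IgM    3.6358637 2.7469409  21.91577 TRUE
#>     IgD    2.8686735 3.6122831 -18.14443 TRUE
#>    BCMA    0.9952547 1.8682306 -17.49321 TRUE
```

Positive z means the precursor over-expresses the marker relative to the
resampling null built from the parent population (CD24, IgM, CD45RB up;
IgD, CD38, BCMA down — the signature that links the precursor to the MZ
rather than the memory axis).

```r
cfg <- repertoire_config(n_clones = 60, seed = 3)
rep <- sim_repertoire(cfg)
rec <- define_clones(functionality_filter(rep)$records,
                     model = read_substitution_model())
adjusted_rand(rec$clone_id, rec$clone_id_truth)
#> [1] 1
gc_membership_rates(rec, classes = list(mz = "mz", igm_only = "igm_only"))
#>     class n_clones n_with_gc percent percent_1dp
#>        mz       20         1       5           5
#>  igm_only       12         3      25          25
```

Clone assignment recovers the generator truth exactly (adjusted Rand
index 1), and the GC-membership report counts, per clone class, how many
clones contain at least one germinal-centre member.

An end-to-end run (`run_pipeline(pipeline_config(out_dir, seed))`) writes
stage outputs plus a manifest with MD5 checksums; identical configurations
reproduce identical checksums.

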