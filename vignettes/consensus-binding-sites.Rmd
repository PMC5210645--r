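---
title: "Consensus TF binding sites from multi-caller ChIP-seq peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus TF binding sites from multi-caller ChIP-seq peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metapeaks)
```

## The model

ChIP-seq peak callers disagree: interval widths vary by an order of
magnitude between tools, and even one tool's intervals shift between
experiments on the same factor. The only quantity that is comparable across
callers is the *point* estimate of the binding position, so `metapeaks`
works exclusively with peak centers, each extracted by the convention of
the caller that produced the peak:

| caller | center rule |
|--------|-------------|
| MACS   | interval start + reported summit offset |
| GEM    | the unit-length event coordinate itself |
| PICS, SISSRs | geometric center, `floor((start + end) / 2)` |

All coordinates are 0-based half-open (BED convention); GEM's native
1-based points must be shifted by one at import, which the simulator and
interchange reader already do. Strand is ignored throughout: merging is
purely positional.

**Clusters.** For one TF and one caller, centers from all experiments are
merged by single-linkage chaining: sort the centers and cut wherever the
gap to the previous center exceeds the merge distance (default 50 bp, with
a gap of exactly 50 bp still joining). Chaining is transitive — two centers
100 bp apart share a cluster if a third lies between them — which matches
how standard interval toolchains merge features and keeps the partition
well-defined. Each cluster is summarised by

* **center** — the median of member centers (floor of the midpoint mean for
  even counts, so centers stay integral);
* **SD** — the sample standard deviation (n − 1) of member centers; a
  singleton cluster has no defined scatter, so it borrows the median SD of
  the same TF/caller's multi-peak clusters (0 when there are none);
* **width** — motif length + 4·SD, rounded half-up. The motif (PWM) length
  approximates the protein–DNA contact footprint; 20 bp is used for TFs
  without a known motif. The interval is placed symmetrically,
  `[center − floor(width/2), center + ceiling(width/2))`, and is not
  clamped at the chromosome edge (realistic coordinates never reach it).

**Metaclusters.** Cluster centers of one TF, across callers, are chained
with the same 50 bp single-linkage rule per chromosome. Each group is
represented by its highest-priority member — priority ranks callers by the
median of their directly computed (non-imputed) cluster SDs, ascending;
ties and callers without eligible clusters fall back to the fixed order
GEM > PICS > MACS > SISSRs, which is also what calibration on simulated
data recovers and what `caller_priority()` supplies as the default. If the
top caller contributes several members to one group (chaining permits
this), the member nearest the group's median center wins, then the
leftmost. The metacluster adopts the representative's interval verbatim
rather than a union of members: unions would inflate widths with the worst
caller's scatter, while the point of the priority is precisely to keep the
most reliable geometry. Groups whose members all come from one caller are
filtered out — *distinct callers*, not cluster count, is what the filter
counts — so every reported site has cross-method support.

## Parameters that matter

| parameter | default | meaning |
|-----------|---------|---------|
| `merge_distance` | 50 bp | single-linkage chaining threshold, both stages |
| `default_motif_length` | 20 bp | contact-footprint estimate for motif-less TFs |
| `sd_multiplier` | 4 | SD multiple in the width's uncertainty term |
| priority | GEM > PICS > MACS > SISSRs | fixed default; `calibrate_priority()` re-derives it |

The merge distance trades resolution against fragmentation: two sites
closer than ~50 bp will fuse, while a larger value absorbs more scatter at
the cost of merging neighbouring sites. The 4·SD term makes a cluster's
width an honest uncertainty interval (≈ ±2 SD around the center on each
side) rather than a fixed-width call.

## What the simulator emulates — and what it does not

`simulate_peaks()` draws `n_sites` ground-truth positions on a single
chromosome with pairwise gaps strictly greater than
`2 × (4·max(center_noise_sd) + 50)` bp, so neighbouring sites cannot chain
together at the default merge distance; the generator refuses parameter
combinations that cannot satisfy the spacing. Each (site, experiment,
caller) triple then yields a peak with probability `detection_prob`, its
center displaced by rounded Gaussian noise with a caller-specific SD, and
each (experiment, caller) pair adds Poisson-distributed false peaks placed
uniformly, independent across callers. Peak intervals follow each caller's
reporting convention (GEM unit-length; MACS with the summit offset pointing
at the noisy center; PICS/SISSRs symmetric intervals).

Defaults describe a well-covered factor: 9 experiments (the typical corpus
depth per TF), 200 sites on 1 Mb, caller noise SDs GEM 3 < PICS 5 < MACS 8
< SISSRs 12 bp (consistent with the published priority order), 80%
detection probability, 2 spurious peaks per experiment and caller, 150 bp
peak half-width.

The model is deliberately idealised. Real data have correlated failures
(closed chromatin hides a site from *all* callers), caller-specific
systematic shifts rather than zero-mean noise, copy-number and mappability
artifacts that produce *shared* false positives, and sites closer together
than the resolvability bound. Passing recovery tests therefore shows the
merging logic is correct and well-calibrated under the stated noise model —
not that real-data error rates will match. In particular the ≥ 2-caller
filter provably removes *independent* false positives; recurrent artifacts
that fool several callers at once survive it by design.

Validation checks run by the test suite include: recovery of the published
priority order from ordered noise; metacluster precision at least matching
the best single caller across seeds (the filter's claim); metacluster
centers within 3σ/√n of the true site for ≥ 95% of sites at n = 8 detected
peaks per site; and mean cluster width tracking motif length + 4σ within
15%. Problem sizes (100–200 sites, 8–10 experiments, ≤ 10 seeds) are chosen
so the whole suite runs in well under a minute while keeping binomial noise
on the checked fractions small.

## Numerical choices and degenerate inputs

* Even-count medians take the floor of the two middle values' mean —
  centers remain integers, deterministically.
* Width rounding is half-up (`floor(x + 0.5)`), not banker's rounding, so
  equal inputs can never round two ways.
* Grouping of exactly-threshold gaps joins (`≤`, "50 bp or closer").
* Singleton-SD imputation is scoped per (TF, caller): scatter is a property
  of a caller's center estimator and differs between callers, so pooling
  across callers would bias imputed widths; with no eligible cluster the
  imputed SD is 0 and the width reduces to the motif length.
* Priority calibration pools cluster SDs across TFs (per-TF calibration is
  possible by subsetting but needs many multi-peak clusters per TF to be
  stable).
* MACS peaks lacking a summit fall back to the geometric center with a
  warning; an explicit summit of −1 in narrowPeak is treated as absent.
* `evaluate_recovery()` matches predictions to sites greedily,
  one-to-one, nearest pair first, within 50 bp (mirroring the merge
  threshold); with zero predictions, precision is reported as
  not-applicable rather than 0/0.
* Ties in representative selection (equidistant members of the top caller)
  go to the leftmost, making results invariant under input permutation.

## Known limitations

* Merging is strand-blind and cannot separate adjacent sites closer than
  the merge distance; divergent closely spaced sites fuse.
* A metacluster's geometry is only as good as its best caller's cluster;
  no cross-caller averaging is attempted.
* Priority calibration assumes center scatter is the right proxy for caller
  reliability; a caller could localise precisely yet call spuriously, which
  scatter alone would not penalise (the two-caller filter mitigates this).
* The cluster BED serialisation does not carry member-peak provenance;
  round-tripping through `read_clusters_bed()` keeps everything the
  metacluster stage needs but not the member lists.
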