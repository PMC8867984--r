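---
title: "Models and design choices in dropspect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in dropspect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropspect)
```

`dropspect` covers the computational stages of a droplet-microfluidics
natural-product discovery campaign: encapsulation design, amplicon
diversity statistics, metabolic redundancy grouping of extracts,
genotype redundancy curation, bioactivity-guided dereplication, and
MS/MS molecular networking, together with seeded synthetic-data
generators that give every stage a known ground truth. This vignette
explains the models, the parameters that matter, and the choices made
where the design was genuinely open.

## Poisson encapsulation model

Cells loaded at number density giving a mean of $\lambda$ cells per
droplet are captured independently, so droplet occupancy is Poisson:
$P(k) = e^{-\lambda}\lambda^k/k!$. Everything in the module follows
from that closed form.

* **Co-encapsulation** is reported as the *unconditional*
  $P(k \ge 2) = 1 - e^{-\lambda}(1+\lambda)$, not the probability
  conditional on a droplet being occupied. Only the unconditional
  reading yields the sub-0.5 % guarantee at $\lambda = 0.1$
  ($P = 0.00468$); the conditional probability at that loading is an
  order of magnitude larger (0.049).
* **Occupancy distributions** list $P(0..k_{\max})$ (default
  $k_{\max} = 10$) plus the explicit tail $P(k > k_{\max})$ rather
  than truncating silently; the reported masses always sum to 1.
* **Droplet volume** converts diameter to picolitres via
  $V = \tfrac{4}{3}\pi (d/2)^3$ with 1 µm³ = 1 fl; a `floor_pl` flag
  floors to whole picolitres for report-style presentation (40 µm →
  33.51 pl → "~33 pl").
* **Throughput** is the plain product rate × 3600 × $\lambda$, printed
  exactly (1.3 kHz at $\lambda = 0.1$ → 468 000 cells/h); whether one
  reads that as "about half a million" is left to the user, since the
  generation rate itself is only known to ~kHz precision.
* `simulate_droplets()` is a seeded Monte-Carlo twin of the analytic
  model, used in tests to confirm convergence at $n = 10^6$ within
  four binomial standard errors.

## Diversity statistics

Taxon tables (rows = taxa, columns = samples, integer read counts) are
consumed as finished classification output; no sequence processing
happens in the package.

* **Rare-taxon filtering** removes taxa whose abundance pooled over
  the whole table is strictly below a fraction of the grand total
  (default $10^{-5}$, i.e. 0.001 %). The rule is strict `<`, so taxa
  exactly at the threshold survive, and the filter is idempotent.
* **Shannon index** uses natural logarithms by default (nats), the
  default of the common desktop statistics tools in this field; the
  base is an argument.
* **Kruskal–Wallis** is delegated to `stats::kruskal.test` (midranks,
  standard tie correction, $\chi^2_{g-1}$ reference); a brute-force
  rank-formula oracle in the test suite confirms equality on small
  tied instances. Fully tied data (every observation equal) would give
  0/0 in the tie-corrected statistic; the wrapper defines $H = 0$,
  $p = 1$ for that degenerate case.
* **Dunn's post hoc test** is implemented directly (no installed
  package provides it): pairwise $z$ on pooled midranks with tie
  correction $\sum(t^3-t)/(12(N-1))$, two-sided normal p-values,
  multiplicity adjustment via `stats::p.adjust` (default Bonferroni —
  deliberately conservative since the choice is otherwise
  unconstrained). The default comparison set is "every group versus
  the first" (the starting-material/reference column), with all-pairs
  available.
* The significance-star mapping is `*** < 0.001`, `** < 0.01`,
  `* < 0.1`, `ns` — including the unusually wide single-star band,
  kept as-is because it is the convention of the reports this package
  accompanies.

## Metabolic grouping of extracts

LC-MS feature lists (retention time in seconds, m/z, intensity) are
compared after discretisation onto a fixed grid:

* **Bucketing.** RT bins are linear, width 12 s over [30, 1080) s;
  m/z bins are multiplicative with constant 5 ppm width over
  [100, 1600), i.e. bin index
  $\lfloor \ln(mz/mz_{\min}) / \ln(1 + 5\times10^{-6}) \rfloor$. The
  commercial "advanced bucketing" implementations are proprietary;
  a fixed log-spaced grid anchored at the range minimum is the
  documented, reproducible stand-in, and what the pipeline is
  validated on is planted-structure recovery, not bit-compatibility
  with any vendor tool. Intensities are summed raw ("no
  transformation"); out-of-range features are counted and dropped,
  never fatal.
* **Sample exclusion.** Samples with fewer than 50 detected features
  are excluded before similarity analysis (strict `<`).
* **Cosine similarity** of bucket vectors, then hierarchical
  clustering on $1 - S$ to obtain a linear leaf order. The linkage is
  configurable (default *average*; single/complete/ward available)
  because the grouping procedure only requires *some* clustering-based
  order and no particular linkage is canonical. Samples are pre-sorted
  by label so the leaf order is deterministic and invariant to input
  order.
* **Group assignment** walks the leaf order and starts a new group
  when the adjacent-pair cosine drops below the threshold (default
  0.9). Ties at exactly the threshold join the running group (the rule
  is "0.9 or higher"). Group count is therefore monotone in the
  threshold, which the tests sweep.

## Genotype redundancy curation

* **Band registration.** Electrophoretic fragment sizes are merged
  across strains into a shared registry by single linkage at 2 %
  relative tolerance (default; the instrument software that performs
  this binning commercially is proprietary, so the tolerance is an
  explicit, configurable approximation).
* **Dice similarity** $2|A\cap B|/(|A|+|B|)$ over registered band
  sets, then **Ward clustering** via `stats::hclust(method =
  "ward.D")`, i.e. the Lance–Williams Ward update applied directly to
  the $1 -$ Dice dissimilarities. Ward on a non-Euclidean
  dissimilarity is mathematically informal but standard practice in
  fingerprint analysis; merge heights remain monotone.
* **Curation** cuts the dendrogram (default height 0.15 on the
  $1-$Dice scale — a required, documented knob, since no canonical cut
  exists) and crosses genotype clusters with metabolic groups. Strains
  sharing both are redundant; one representative per redundancy class
  is nominated deterministically (lexicographically smallest strain
  id) so the report is stable under permutation. Strains sharing a
  genotype cluster but not a metabolic group stay unique — genotypic
  near-identity with distinct chemistry is exactly what the campaign
  wants to keep.

## Bioactivity-guided dereplication

* **Normalization.** Percent inhibition is
  $100\,(G - x)/(G - M)$ with $G$ the growth-control mean and $M$ the
  medium-control mean, identical for OD and luminescence readouts.
  Values are clipped to $[-10, 110]$ with a flag; mild growth
  promotion (negative inhibition) is reported, not hidden.
* **Activity calling** is inclusive at the threshold (default
  $\ge 70\,\%$), and contiguous active fractions are reported as
  windows. Fraction $i$ occupies the half-open RT window
  $[o + (i-1)\,d,\ o + i\,d)$ with duration $d = 7$ s and offset
  $o = 30$ s by default; the offset is configurable because collection
  start and detector–collector dead volume vary by installation.
* **Mass computation.** Monoisotopic masses use most-abundant-isotope
  CODATA/AME values embedded as constants; the proton mass is the
  hydrogen-atom mass minus the electron mass (1.00727646 Da), and
  $[M+nH]^{n+}$ m/z is $(M + n\,m_p)/n$. Full precision is kept
  internally; display convention is 4 decimals. Published theoretical
  values in this compound class mix rounding and truncation in the
  last digit, so cross-checks against printed values should allow one
  unit in the fourth decimal.
* **Matching** is inclusive at the ppm tolerance (default
  $\pm 2$ ppm), hits are ranked by $|\mathrm{ppm}|$, and features
  without any hit are flagged "unknown — candidate novel", which is
  the interesting outcome in a discovery campaign. An empty reference
  table is valid input (everything unknown).

## Molecular networking

* **MGF i/o** is implemented in the package (a simple line format; no
  installed R package parses it). An absolute intensity floor
  (default 1000) is applied at read time, mirroring the common
  raw-conversion threshold filter; peaks below the floor are removed,
  spectra left empty are dropped with a warning.
* **Fragment matching** is greedy one-to-one: candidate pairs within
  tolerance, sorted by intensity product, accepted if both peaks are
  unused. Tests verify equivalence with an exhaustive optimal
  bipartite pairing on 6-peak spectra.
* **Fragment tolerance.** The tolerance is expressed in Da (default
  0.05 Da). A "0.05 ppm" reading would be ~25 µDa at m/z 500 — far
  tighter than QTOF instruments resolve — so the Da reading is the
  default and a ppm alternative is not pretended to be equivalent.
* **Spectral cosine** uses square-root intensity weighting by default
  (standard networking practice; raw weighting is a flag), normalized
  over the full spectrum so unmatched peaks dilute the score. A
  *modified cosine* flag additionally allows precursor-shifted
  matches for homologous series; the plain cosine is the default
  because the grouping rule itself is stated in terms of plain cosine.
* **Edges** require the conjunction: cosine strictly above 0.7 *and*
  at least 6 matched fragments. "Six fragments" counts matched peak
  pairs (one-to-one), the stricter of the possible readings.
  Isolated nodes stay in the network, flagged. Edge counts are
  monotone in both knobs, which the tests sweep.
* **Annotation** applies the same edge rule against a labelled
  library; the best cosine wins, exact ties report all names.
  GraphML export (via igraph) carries precursor m/z and annotation on
  nodes, cosine and matched count on edges.

## Synthetic data: what it emulates, what it does not

Each generator is seeded, byte-reproducible, restores the caller's RNG
state, and returns machine-readable ground truth next to the data.
Recovery tests consume only the data until assertion time.

* **Communities**: symmetric Dirichlet abundances + multinomial reads.
  Uniform concentration over 60 taxa gives a true Shannon index of
  $\ln 60 \approx 4.09$, the scale of a diverse soil-derived culture
  pool. Not emulated: taxonomic correlation structure, chimeras,
  sequencing error.
* **Feature tables**: each of $k$ groups owns a template of bucket
  positions (5 % drawn from a pool shared across groups); samples
  inherit 95 % of their template plus private noise features, with
  10 % log-normal intensity CV — the scale of technical run-to-run
  intensity variation in LC-MS. Dropout is concentrated on
  low-abundance features, because detection near the limit is what
  varies between runs while dominant peaks are always found; with
  uniform dropout the generated data would contradict the very
  property the grouping exploits (same-group adjacent cosine
  $\ge 0.9$). The paper-scale scenario plants 8 groups over 60
  samples with sizes (20, 10, 8, 6, 5, 4, 4, 3) — one dominant group
  and a tail, as observed redundancy structures look. Not emulated:
  retention-time drift between batches, isotope envelopes, adducts of
  one analyte landing in several buckets.
* **Fingerprints**: clone templates as random band subsets of a
  geometric size ladder (adjacent registry sizes 8 % apart, safely
  beyond the 2 % registration tolerance); copies flip bands with
  probability 0.05. Not emulated: size-measurement jitter *within*
  the tolerance, partial-digest artefacts.
* **Compound families**: derivatives share a fragment scaffold and
  step the precursor by a neutral-loss series (default CH₂ =
  14.01565 Da), plus a few private fragments each — 7 derivatives
  and 10 scaffold peaks in the paper-scale scenario. Not emulated:
  realistic fragmentation intensity patterns.
* **Fraction plates**: controls at nominal OD, spiked windows at a
  set inhibition, Gaussian noise of 2 percent points. The paper-scale
  scenario spikes fractions 84–87 at 95 %.

Passing the recovery tests shows the pipeline implements its rules
correctly and recovers structure when the planted signal dominates the
planted noise; it does not show that real campaigns present signal
that cleanly (retention drift, shared media components and adduct
redundancy all blur real bucket tables).

## Numerical conventions and problem sizes

Boundary rules follow their textual sources: activity $\ge 70\,\%$,
ppm $\le 2$, grouping cosine $\ge 0.9$ are inclusive; the network
cosine cut ($> 0.7$), the feature-count exclusion ($< 50$) and the
rare-taxon filter ($< 10^{-5}$) are strict. All leaf orders and
representative nominations break ties lexicographically so runs are
reproducible. Degenerate inputs (all-zero profiles, empty
fingerprints, empty spectra, zero-norm bucket rows) raise errors
naming the offending sample rather than propagating NaN; fully tied
rank tests return $H = 0$.

The test suite runs the Monte-Carlo encapsulation checks at $10^6$
droplets, the type-I-error calibration at 1000 trials of 3 × 8
observations, planted-structure recovery at the paper scale (60
samples / 8 groups; 3 clones × 3 copies; 12 spectra), and the
exhaustive pairing and rank-test oracles on 6-peak and ≤ 9-observation
instances — sizes at which the exhaustive oracles are exact and the
whole suite completes in seconds.

## Known limitations

* The bucketing grid is a documented stand-in for proprietary vendor
  bucketing; absolute bucket ids are not comparable across tools.
* Ward-on-Dice operates on a non-Euclidean dissimilarity; heights are
  interpretable only relatively, and the 0.15 default cut should be
  re-examined against the dendrogram for any new fingerprint assay.
* The dereplication matcher uses exact mass only; retention time and
  fragmentation agreement — part of a full dereplication argument —
  enter only through the activity-window restriction and the separate
  networking module.
* The modified-cosine option pairs each fragment at most once and
  considers only the single precursor-difference shift.
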