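---
title: "Methods: gapped k-mer SVM scoring and variant prioritization"
author: "gkmvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gapped k-mer SVM scoring and variant prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`gkmvar` implements an integrative pipeline for prioritizing noncoding
variants that may alter transcription-factor (TF) binding in regulatory
DNA: a gapped k-mer support vector machine (gkm-SVM) trained on TF-bound
sequences, exhaustive oligomer scoring, motif reconstruction, deltaSVM
allele-effect scores, a GWAS-catalog → regulatory-region → LD → eQTL
variant funnel, and quantification of electrophoretic mobility shift
assays (EMSA). A deterministic synthetic-data generator emulates every
input, so the whole pipeline is testable without any external download.
This vignette records the models, the tunable parameters, and the design
choices made where the design was genuinely open.

# The gapped k-mer model

A sequence is represented by the counts of its *gapped k-mers*: for a
word length $l$ and $k$ informative positions there are $\binom{l}{k}$
gap patterns, and each $l$ bp window contributes, for every pattern, the
length-$k$ string read at the informative positions. The similarity
between two sequences is the normalized inner product of these count
vectors,

$$K(a,b) = \frac{\langle \phi(a), \phi(b) \rangle}
{\sqrt{\langle \phi(a), \phi(a)\rangle \langle \phi(b), \phi(b)\rangle}},$$

computed in compiled code through the identity that two $l$-windows with
$m$ mismatching positions share exactly $\binom{l-m}{k}$ gapped k-mer
features. Feature maps count each window *and its reverse complement*,
so every kernel value, decision value and deltaSVM score is exactly
strand-invariant; this matches the double-stranded nature of TF binding
and the convention of counting nonredundant (canonical) oligomers once.

Defaults follow the standard recipe for TF ChIP-seq classifiers: $l =
11$, $k = 7$, soft-margin constant $C = 1$, solver tolerance
$\varepsilon = 0.005$, 5-fold cross-validation. The SVM dual is solved
by `kernlab::ksvm` on the precomputed kernel matrix; the contract is the
KKT conditions at tolerance $\varepsilon$, not a particular algorithm.
Class orientation is normalized after solving so that bound sequences
receive positive decision values. A `truncated_gkm` kernel variant
(window-pair contributions zeroed beyond $d$ mismatches) is available as
a speed knob; at the package's working scale the exact kernel is the
reference and the default.

Cross-validation assigns folds by a stable hash of sequence identifier,
stratified within class. Metrics are therefore invariant to input row
order. AUROC is the tie-aware rank statistic; AUPRC is step-interpolated
average precision, processing tie groups as blocks.

# Exhaustive k-mer scoring and motif recovery

The model scores all $4^{11}/2 = 2{,}097{,}152$ canonical 11-mers. Done
naively this is quadratic in the support set; `gkmvar` instead expands
the decision function in feature space once,
$w = \sum_i \alpha_i y_i\, \phi(s_i)/\lVert\phi(s_i)\rVert$, over the
$\binom{11}{7} \times 4^7 \approx 5.4$ million (pattern, k-string)
coordinates, and scores each oligomer as $\langle w, \phi(x)\rangle /
\lVert \phi(x) \rVert + b$ — algebraically identical to summing
normalized kernels against every support sequence. The full table builds
in seconds and doubles as the lookup table for sliding-window region
scoring and deltaSVM.

A position weight matrix is rebuilt from the top 1000 k-mers by weight
(ties broken lexicographically so the set is deterministic). Instead of
motif-discovery EM, each k-mer is aligned to the top-1 seed by the
orientation and shift (within ±2) maximizing positional identity —
the inputs are fixed-length 11-mers, so EM machinery adds nothing
testable at this scale. Counts receive a pseudocount of 0.25 per base.
Recovery is quantified as the best mean per-position Pearson correlation
between the reconstructed and planted probability rows over all shifts
and both orientations.

Footprint scoring supports two readings of "score fixed-width sequences
within footprints": the default `sliding_sum` aggregates all l-window
weights in the region (the deltaSVM-compatible convention); a
`center_window` mode scores only the central 18 bp, reproducing the
fixed-probe reading. Both are exposed because the source procedure is
ambiguous; the default is documented rather than guessed to be the
original intent.

# deltaSVM

For a variant with reference allele matching the genome base (checked,
as a guard against off-by-one coordinate bugs), the package extracts the
$(2l-1)$ bp window centered on the position, sums canonical k-mer
weights over its $l$ windows, substitutes the center base, rescores, and
reports $\Delta = \text{alt} - \text{ref}$. The per-window bias term
cancels in the difference. Negative $\Delta$ predicts loss of binding.
"Fold change" wording in this field is treated as the signed additive
delta: decision values live in margin space where ratios are
ill-defined. Prioritization requires a cardiac-tissue eQTL *and* a delta
criterion (99th-percentile |delta| by default, or top-k), ranking by max
|delta| across TF models with ties broken by rsid.

# Variant catalog

The catalog stage mirrors the standard funnel: parse a GWAS-catalog-
dialect TSV (malformed rows are reported with reasons, never silently
dropped); keep traits matching the cardiovascular keyword alternation
(`heart|cardiac|aortic|atrial|ventric|cardio|vascular|artery|coronary|`
`myocardial|valve|cardium|stroke`), case-insensitive by default because
catalog trait strings are mixed-case (a case-sensitive flag restores
literal matching); drop indels and incomplete entries (missing rsid,
chromosome, position or either allele); keep variants lying inside a
DNase footprint *and* an enhancer (both containment tests applied to the
variant point; a stricter nested-footprint mode is a config switch);
expand by LD proxies at $r^2 > 0.8$ (strictly greater, so the boundary
value is excluded) in any of the EUR/AFR/SAS/EAS/AMR panels; and join to
eQTL pairs in heart atrial appendage or left ventricle at $p < 0.1$.
Variant coordinates are 1-based; interval files are 0-based half-open
BED; the conversion happens once, in the BED reader, and a 1-based
position $p$ is inside $[\text{start}, \text{end})$ iff
$\text{start} < p \le \text{end}$. LD proxies are *not* re-filtered for
regulatory overlap before the eQTL join (they flow directly to it),
matching the expansion-then-lookup order of the funnel; a config flag
enables re-filtering for sensitivity analysis.

# EMSA quantification

Band intensities are background-corrected (`max(raw - background, 0)`;
negative values are clamped because blank-region noise routinely exceeds
faint bands, and clamps are reported), converted to fraction bound
$Y = \text{bound}/(\text{bound}+\text{unbound})$, and fit to the
one-site specific-binding law $Y = B_\max X/(K_d + X)$ by
Levenberg–Marquardt least squares (`minpack.lm::nlsLM`; initialization
$B_{\max,0} = \max Y$, $K_{d,0}$ = concentration nearest half-max;
parameter/function tolerances $10^{-14}$). Standard errors come from
the curvature at the optimum. Replicates are pooled into one fit by
default, preserving the error structure; an averaging mode mirrors
curves drawn through mean points. $B_\max$ is unconstrained by default
with an optional $B_\max \le 1$ bound. Allele comparisons call
direction from the $K_d$ difference relative to the combined standard
error: lower alternate $K_d$ beyond that error is increased binding,
higher is decreased, otherwise unchanged.

# The synthetic study

The generator produces every input with the statistical structure the
analysis assumes — and nothing more. Defaults (the study conditions used
throughout the tests):

* **Genome**: 2 chromosomes × 300 kb of i.i.d. bases at GC 0.41
  (human-like). Order-0 background is the simplest defensible null for
  kernel and classifier testing; it does not emulate repeats, CpG
  structure, or chromatin.
* **Peaks**: 550 non-overlapping 100 bp peaks, each planted with one
  instance of an 8 bp motif (consensus TTAAGTGG, consensus probability
  0.95 ≈ 1.8 bits/position — a high-information cardiac-TF-like site;
  this strength is what makes the planted signal learnable at the
  paper-like AUROC ≈ 0.95 level and is the package's definition of a
  "strong" motif). Signal is additive: baseline + 2 × instance log-odds
  + N(0, 0.5), which creates the signal-sorted structure that
  top-peak selection assumes without claiming ChIP realism.
* **Catalog**: 200 associations, 60% cardiovascular traits, 10% indels,
  10% malformed rows (empty position or empty alleles, alternating) —
  mirroring the removal rules the funnel must implement. Reference
  alleles equal the genome base at the stated position.
* **Tracks**: 1 kb enhancers with 3 × 20 bp contained footprints each
  and a 25% orphan-footprint fraction to exercise rejection.
* **LD**: proxies within 50 kb, $r^2 = e^{-2\cdot10^{-4} d}$ plus
  per-population noise (SD 0.05), self-pairs at $r^2 = 1$. Exponential
  in-block decay with nothing across blocks produces exactly the
  contrast the expansion step must detect; it is not a coalescent.
* **eQTL**: planted significant pairs in the two cardiac tissues only;
  decoys carry small p-values in non-cardiac tissues.
* **EMSA**: the five-point 50–2000 nM design in triplicate, Gaussian
  noise SD 0.02 on the bound fraction, reference $K_d$ 200 nM vs
  alternate 800 nM.
* **Planted answer**: 5 variants at centers of strong motif instances,
  inside anchored footprint-in-enhancer regions, with cardiac eQTLs;
  15 background regulatory variants (4 with eQTLs) and 2 eQTL-carrying
  LD proxies test the conjunction rule.

One global seed fans out to per-generator subseeds by a stable hash of
the generator name, so adding a generator never perturbs the others and
every file is byte-identical under regeneration. Ground truth (exact
per-stage survivor counts, planted rsids, planted eQTL pairs) is written
to a JSON sidecar *by construction*, never by running the pipeline —
downstream checks compare pipeline output against the sidecar only.

What passing on this generator shows — and what it does not: the tests
demonstrate that the implementation is correct on data satisfying its
own assumptions (single planted motif, independent background, clean
monotone LD blocks). They do not show performance on real ChIP-seq
peaks, where motif multiplicity, cofactor motifs, repeats and GC biases
all matter, and the AUROC of a real TF model depends on data quality in
ways no synthetic control can certify.

# Numerical choices and degenerate inputs

* Kernel values of sequences shorter than $l$ (empty feature vectors)
  are defined as 0 and flagged; scoring such sequences errors.
* The exhaustive weight table is guarded at $l \le 13$ ($4^l$ growth).
* Weight-table construction and direct kernel scoring agree to ~1e-9;
  the dual route is asserted in the tests.
* GC matching in null-set generation uses a ±2 percentage-point
  tolerance (the tolerance of the matched-null generation convention is
  not published; it is surfaced in the API).
* Ties: top-peak selection breaks by (chromosome, start); top-k-mer
  selection lexicographically; prioritization by rsid.
* GC content 0 or 1 is accepted in the genome generator (degenerate
  compositions are legitimate edge-case inputs).
* EMSA fits error on fewer than three distinct concentrations and on
  flat (all-equal Y) data, where $K_d$ is unidentifiable.

# Problem sizes used in the checks

The default study trains on 500 positives / 500 matched negatives of
100 bp (kernel matrix of 1000² in ~1 min on one core), scores all 2.1 M
canonical 11-mers in a few seconds, and Monte-Carlo EMSA checks use 500
simulated triplicate experiments. These sizes were chosen as the
smallest at which the statistical claims (CV metrics, recovery rates)
are stable; everything scales linearly in sequence count except the
kernel matrix, which is quadratic.

# Known limitations

* The SVM is trained on a dense kernel matrix; tens of thousands of
  sequences would require the truncated-filter algorithms of dedicated
  gkm-SVM implementations, which are out of scope here.
* The PWM builder assumes its inputs are enriched variations of a
  single motif; it will average multi-motif weight tables into a blur.
* Only biallelic single-base substitutions are scored; indels and
  multi-allelic records are filtered out upstream.
* LD tables are consumed as given; no population-genetic model is fit.
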