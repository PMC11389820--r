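---
title: "Models and methods behind tetherscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tetherscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetherscreen)
```

## The reporter model

A tethered-function splicing reporter couples two luciferases to one
minigene: Firefly luciferase upstream of the alternative (cassette) exon is
translated from every mature transcript, while Renilla luciferase downstream
is translated only when the exon is *skipped*, because the exon carries a
premature stop codon. Tethering a candidate RNA-binding protein next to the
exon (via an MS2 hairpin placed 30 nt downstream of the 5' splice site or
30 nt upstream of the 3' splice site) and reading both luminescence channels
therefore reports the protein's proximity-dependent effect on exon
inclusion.

The Firefly channel measures per-well transfection efficiency, shared by
both luciferases. The noise-robust statistic is the ratio
$r = R/F$, which cancels that efficiency. With an inert tethering control
(a FLAG peptide fused to the MS2 coat protein) measured *on the same plate*,
the relative percent-spliced-in is

$$\hat\psi \;=\; 1 - \frac{r_\text{candidate}}{\bar r_\text{NC}},
  \qquad \hat\psi \in [0, 1] \text{ after clipping.}$$

Design choices worth stating explicitly:

* **Baseline pooling.** The negative-control baseline is the mean $R/F$
  ratio over the NC wells of the same plate and reporter. A plate-matched
  baseline removes plate-level batch effects; both luminescence channels can
  be scaled by any per-plate constant without changing a single $\hat\psi$
  (this scale invariance is tested).
* **Clipping and testing.** Reported $\hat\psi$ is clipped to $[0,1]$
  because the screen is one-sided for inclusion, but all significance tests
  run on the *unclipped* values (kept alongside). Under the null,
  $\hat\psi$ scatters symmetrically around 0; clipping before testing would
  truncate the null distribution and destroy the size of the t-test.
* **Replicate summaries** use the sample standard deviation
  ($n-1$ denominator), with $n = 3$ replicate transfections as the default
  design.
* The reporter's baseline state is treated as complete skipping
  ($\psi_{NC} = 0$). The real reporter exon is *predominantly*, not
  perfectly, excluded, which is why the estimates are *relative* $\psi$
  values; no absolute calibration against RT-PCR is attempted.

## The hit-calling cascade

Candidates advance through serial gates, per reporter:

1. **Round 1** — independent two-sample, pooled-variance, one-tailed t-test
   of the candidate's replicate $\hat\psi$ against the plate-matched NC
   replicates; pass at $p < \alpha$ (default 0.05). The pooled-variance
   flavor matches the default behavior of the standard two-sample t
   routine. The skipping-screen variant reuses the same cascade with
   `direction = "less"`.
2. **Round 2** — an independent replication of round 1 restricted to the
   round-1 passers. Passing both rounds compounds the null rate to
   $\approx \alpha^2$.
3. **Gel validation** — RNA-level confirmation. Each lane is quantified as
   the bounded band ratio $I/(I+S)$ (inclusion over inclusion-plus-skipping;
   bounded, hence numerically stable when the skipping band is faint), lanes
   are compared against the pooled control lanes distributed through the
   gel, and a construct passes only at Bonferroni-corrected
   $p < \alpha/m$, where the family $m$ defaults to all constructs
   validated on that reporter's gels.
4. **Cross-reporter retest** — a hit exclusive to one reporter is measured
   once more with the opposite reporter and promoted to the `both` category
   at $p < \alpha$, in case the first screen of that reporter missed it.

Two statistical properties of this design deserve honesty:

* **Plate clustering.** All candidates on a plate share the same three NC
  wells, so their round-level pass events are positively correlated. The
  *expected* null pass rate is $\alpha$, but the realized per-screen
  fraction is over-dispersed relative to a binomial count; screens of a
  thousand constructs can land a few points away from $\alpha$ without any
  calibration defect.
* **Retest false promotions.** The retest promotes on a single unadjusted
  $p < \alpha$. With $k$ exclusive hits entering the retest, the chance
  that at least one null retest fires is $1 - (1-\alpha)^k$ (about one in
  two for $k = 15$). The promotion rate is exactly the nominal $\alpha$ —
  this is a property of the published decision rule, not of its
  implementation — so exact recovery of a planted design is a
  probabilistic, not certain, event. The package's tests assert the
  deterministic part (every planted effector clears the serial gates on its
  planted reporter, nothing clears them falsely) separately from the exact
  final category counts.

Constructs whose replicate variance is degenerate (for example, noise-free
synthetic data) are reported as *indeterminate* — never as hits.

## Integration of binding and knockdown splicing data

The downstream stage asks whether a protein's CLIP binding explains the
splicing changes seen after knocking it down.

* **Event filter.** A skipped-exon event is significant when
  $|\Delta\psi| > 0.05$ (strict), $\text{FDR} < 0.05$ (strict) and the
  junction reads summed over all samples are $\ge 150$ (inclusive). The
  strict/inclusive boundaries follow the stated thresholds to the letter
  and are pinned by boundary tests.
* **Expression filter.** Two inclusivity modes exist because the
  denominators differ: the CLIP-based denominator keeps genes at
  $\text{TPM} \ge 10$, the differential-expression prefilter requires
  $\text{TPM} > 10$.
* **Direction.** Events are labeled by the sign of
  $\Delta\psi = \psi_{KD} - \psi_{NT}$: negative means skipping after
  knockdown.
* **Bound-gene enrichment.** A gene is *bound* when at least one enriched
  window carries its id, in any region. Over the expressed denominator, the
  2×2 bound-by-sensitive table is tested one-tailed (sensitive genes more
  often bound) with the Fisher exact test. The p-value is computed directly
  from the hypergeometric tail; the odds ratio reported is the sample
  cross-product ratio, with $\infty$ allowed under complete separation.
  Tests verify the tail against brute-force enumeration of every table with
  margins up to 30 and against the standard exact-test routine.
* **Feature assignment.** Each window is placed by its genomic midpoint
  into exactly one of five transcript-oriented features (upstream exon,
  upstream intron, cassette exon, downstream intron, downstream exon), or
  none. On the minus strand the genomically-left intron is the downstream
  intron. Windows straddling a boundary follow their midpoint. The
  flanking-intron extent is the full intron between the cassette exon and
  the reported flanking exon.
* **Median window.** When several windows occupy the same feature of one
  event, the displayed point is the midpoint of the *median* window after
  sorting by (start, end); for even counts the lower-middle element (index
  $\lfloor (n-1)/2 \rfloor$, 0-based) is taken. This tie-break is
  deterministic but not mirror-symmetric: reflecting a locus maps the
  lower-middle to the upper-middle. The strand-symmetry tests therefore
  check the window-level bijection exactly and predict the reflected
  median with the corresponding index.
* **Positions** are reported transcript-oriented, as the offset of the
  window midpoint from the 5' end of the cassette exon, so upstream binding
  is negative on either strand. All coordinates are 0-based half-open
  throughout (BED and `exonStart_0base` conventions).
* **Flanking-intron comparisons** between two exon sets use the plain
  two-sided chi-squared test without continuity correction, matching the
  named test.

## The synthetic-data generator

Every input format is generated with planted ground truth, so each stage is
testable without downloads.

* **Luminescence.** Firefly is log-normal (median $10^4$ RLU, scale 0.4 —
  typical well-to-well variability of arrayed transfections); Renilla is
  $F \cdot g \cdot (1-\psi_\text{true}) \cdot \varepsilon$ with coupling
  $g = 0.5$ and $\varepsilon$ multiplicative log-normal noise of mean
  exactly 1 and CV `noise_cv` (default 0.05; luminescence is positive, so a
  CV-scaled multiplicative model is the natural noise family). At
  `noise_cv = 0` the inference stage inverts the generator exactly, to
  floating-point precision — the central consistency check.
* **NMD leakage** is exposed as a validated configuration field but is a
  documented no-op: the inclusion isoform produces no Renilla, so decay of
  that isoform cannot move the luminescence readout; at the RNA level the
  reporter was designed to be (and measured as) only marginally
  NMD-sensitive.
* **Plate batch effects** are available (`plate_effect_sd`, default 0, a
  log-scale per-plate shift) to exercise the plate-matched baseline; no
  published magnitude exists to default to, and ratios within a plate are
  invariant to it.
* **Gels.** Band intensities are proportional to $\psi$ and $1-\psi$ with
  multiplicative noise per band, and control lanes are interleaved through
  the gel. Controls carry a small nonzero baseline inclusion (default
  0.05): a literal zero would make every control ratio exactly 0 under
  multiplicative noise and leave the t-test degenerate, and real validation
  gels show a faint baseline inclusion band.
* **Loci.** Toy cassette-exon gene models (three exons, two introns,
  exons 50–300 nt, introns 200–2,000 nt, minimum 50 nt so windows fit)
  are laid on one synthetic chromosome with random strands.
* **Integration tables.** A fraction of genes (default 0.25) is
  knockdown-sensitive with $|\Delta\psi|$ = `kd_delta` (default 0.3) of
  random sign; binding is planted so sensitive genes' odds of being bound
  are `bound_gene_or` times the insensitive base odds (base rate 0.25).
  Junction read counts are binomial given a Poisson per-replicate depth
  (default 100); event p-values come from a two-proportion z-test on pooled
  counts with Benjamini–Hochberg adjustment — explicitly a generator-
  internal stand-in for the likelihood-ratio test a splicing caller would
  run, which is out of scope. The planted odds ratio is recoverable from
  the generated tables to within ±30% at 2,000 genes.

## Problem sizes and determinism

Tests and the acceptance script run at sizes chosen to make the statistical
assertions sharp while staying quick on a laptop: 1,000-construct screens
for inversion and null calibration, a 20-construct planted design (10/5/5)
for cascade recovery, 2,000 genes × 20 replicate simulations for
odds-ratio recovery, and full enumeration of 2×2 tables with margins ≤ 30
for the exact-test oracle. Every generator draws from an explicit seed;
multi-stage runs derive per-stage seed streams from one master seed, so a
configuration reproduces its report bundle byte for byte.

## What passing tests do and do not show

The generator emulates the *formats* and the *first-order statistical
structure* of the real assays: transfection-efficiency coupling,
CV-scaled positive noise, plate-matched controls, binomial junction
sampling, gene-level binding odds. It does not emulate sequence content,
position-specific binding preferences within features, correlated splicing
changes across events, NMD feedback, or antibody/IP efficiency — so green
tests demonstrate that the *analysis* is correct and calibrated under its
stated model, not that the model captures every property of real screens.
Headline counts from the published screen derive from its deposited
supplementary tables; the cascade accepts such externally supplied
per-replicate ψ tables directly (`call_round` on any PsiEstimate-shaped
table), but no download is performed here.
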