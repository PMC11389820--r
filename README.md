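# tetherscreen

Analysis of tethered-function dual-luciferase splicing screens and their
genomic follow-up.

## The problem

To learn which RNA-binding proteins (RBPs) *directly* promote inclusion of a
cassette exon, a tethered-function screen recruits each candidate protein to
a fixed position next to an alternative exon on a minigene reporter (via an
MS2 hairpin and the MS2 coat protein) and reads exon inclusion out as
luminescence. Two reporters place the tether 30 nt downstream of the 5'
splice site (`30D`) or 30 nt upstream of the 3' splice site (`30U`), so hits
separate by the position dependence of their activity. Follow-up experiments
(CLIP binding maps, knockdown RNA-seq) then ask whether candidate binding
explains endogenous splicing changes.

`tetherscreen` implements the analysis side of this design for screeners and
computational biologists:

* **Reporter model** — Firefly luciferase is translated from every
  transcript (transfection control); Renilla only from the skipping isoform.
  The relative percent-spliced-in against the plate-matched negative-control
  baseline is

  `psi = 1 − (R/F) / mean(R/F)_NC`, clipped to [0, 1].

* **Hit-calling cascade** — round-1 and round-2 one-tailed pooled-variance
  t-tests against plate-matched controls (`p < 0.05` each), Bonferroni-gated
  gel validation on band ratios `I/(I+S)`, and a cross-reporter retest of
  single-reporter hits, yielding disjoint `30D_only` / `30U_only` / `both`
  categories.

* **Integration** — filters rMATS-style skipped-exon tables
  (`|ΔPSI| > 0.05`, `FDR < 0.05`, `reads ≥ 150`), tests binding enrichment
  in knockdown-sensitive genes by one-tailed Fisher exact test over the
  expressed (`TPM ≥ 10`) denominator, and builds position-dependent
  splicing maps from enriched-window midpoints (median window per feature,
  strand-aware upstream/downstream assignment).

* **Synthetic data** — seeded generators for every input format (plate
  CSVs, gel tables, BED6+gene windows, SE tables, TPM tables) with planted
  ground truth, so the full pipeline is testable end to end without any
  download.

## Worked example

Simulate a screen with a planted design — three downstream-only effectors,
one upstream-only, one dual (true Δψ = 0.3, luminescence noise CV 0.02) —
and run the full cascade:

```r
library(tetherscreen)

design <- planted_design(n_30D_only = 3, n_30U_only = 1, n_both = 1,
                         delta_psi = 0.3)
res <- run_synthetic_screen(design, simulation_config(noise_cv = 0.02, seed = 1))
res$cascade$counts
#> 30D_only 30U_only     both
#>        3        1        1

res$cascade$hit_calls[, c("construct_id", "p_round1_30D", "p_gel_30D", "category")]
#>   construct_id p_round1_30D    p_gel_30D category
#> 1      RBP0001 7.664216e-06 2.175570e-11 30D_only
#> 2      RBP0002 9.484448e-06 1.211822e-12 30D_only
#> 3      RBP0003 8.227386e-06 1.513282e-12 30D_only
#> 4      RBP0004 4.765459e-01           NA 30U_only
#> 5      RBP0005 3.735474e-05 6.347290e-14     both
```

All five planted effectors are recovered in their planted categories: the
upstream-only construct never passes the downstream screen (round-1
`p = 0.48`, so it is never gel-validated there, hence the `NA`), while the
dual effector clears every gate on both reporters.

Integrate synthetic CLIP windows with knockdown splicing tables (planted
binding odds ratio 4):

```r
loci <- simulate_locus_set(500, seed = 2)
tabs <- simulate_integration_tables(loci, bound_gene_or = 4, seed = 3)
sig  <- filter_se_events(tabs$events)        # 121 of 500 events significant
enr  <- bound_fraction_enrichment(tabs$windows, unique(sig$GeneID),
                                  expressed_gene_set(tabs$tpm))
#> bound fraction (sensitive / insensitive): 0.529 / 0.251
#> odds ratio 3.36, one-tailed Fisher p = 2.09e-08

head(positional_map(tabs$windows, sig), 4)
#>               event_id         feature transcript_position delta_psi
#> 1     G00001:2539-2705 upstream_intron                -141   -0.2675
#> 2   G00007:46960-47160 upstream_intron                -114    0.2059
#> 3 G00017:122917-123031 upstream_intron                -696   -0.2333
#> 4 G00025:183268-183438   upstream_exon                -969   -0.3234
```

Knockdown-sensitive genes are bound twice as often as insensitive ones, and
each significant event contributes at most one point per feature — the
midpoint of the median enriched window, at a transcript-oriented offset from
the cassette exon (negative = upstream). `run_pipeline(pipeline_config())`
chains all stages and writes every table plus an auditable `summary.json`.

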