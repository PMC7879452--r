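# lncrecur

Recurrence-based discovery of tumor-specific long non-coding RNAs (lncRNAs)
from matched tumor–normal RNA-seq cohorts.

Cohorts of paired biopsies — one tumor and one matched normal per patient,
no replicates of either — are a common design in cancer transcriptomics.
`lncrecur` turns that design into a reproducible discovery pipeline for
researchers prioritizing lncRNA candidates for follow-up:

1. **Identify** lncRNAs: transcripts longer than 200 nt, not predicted
   coding by a consensus of three external coding-potential callers, split
   into *known* (catalog) and *novel candidate* classes, with an
   expression gate (count ≥ 1 in ≥ 1 sample) and machine-readable rejection
   reasons.
2. **Test** each transcript within each matched pair with a **local pooled
   error (LPE)** test: on `log2(CPM+1)`, the tumor−normal difference *d* is
   standardized by a robust scale pooled across transcripts of similar
   abundance (equal-occupancy bins, MAD around the bin median, running-median
   smoothing), `z = (d − median_bin)/σ_bin`, two-sided normal tail,
   Benjamini–Hochberg within pair. A call requires `q < 0.05` and
   `|log2FC| > 1` (both strict).
3. **Prioritize** by recurrence: *occurrence* = number of pairs in which a
   lncRNA is called DE; candidates need `occurrence > 10`, one consistent
   direction across DE pairs, and are ranked by the rank-sum of occurrence
   and |median log2FC|.
4. **Predict targets**: *cis* = protein-coding genes whose span lies within
   100 kb of the lncRNA span (strand-agnostic, boundary-inclusive);
   *trans* = genes with `|Pearson r| > 0.95` on `log2(CPM+1)` across all
   samples; plus upper-tail hypergeometric over-representation of predicted
   targets against user gene sets (GMT).

A negative-binomial simulator (`simulate_cohort()`) generates matched
cohorts with planted effects, cis neighbors at controlled distances, trans
targets with controlled correlation, and a ground-truth ledger — it is how
every stage is validated.

## Worked example

```r
library(lncrecur)

cfg <- simulation_config(seed = 1)        # 19 matched pairs, 810 transcripts
sim <- simulate_cohort(cfg)
sim$cohort
#> PairedCohort: 810 transcripts x 38 samples ( 19 matched pairs )

de <- run_paired_de(sim$cohort)           # LPE test in every pair
lnc <- sim$truth$roles$transcript_id[sim$truth$roles$role == "lncRNA"]
occ <- classify_consistency(compute_occurrence(de, lnc))
table(occ$consistency)
#> consistent_down   consistent_up    inconsistent   not_recurrent
#>               2               2               3             293

rank_candidates(occ)[, c("transcript_id", "occurrence", "n_up", "n_down",
                         "median_log2fc", "rank")]
#>   transcript_id occurrence n_up n_down median_log2fc rank
#> 1       LNC0198         14   14      0          3.35    1
#> 2       LNC0089         14    0     14         -2.62    2
#> 3       LNC0045         12    0     12         -3.07    3
#> 4       LNC0248         13   13      0          2.44    4

expr <- normalize_cpm(sim$cohort)
correlate_pair(expr, "LNC0014", "PCG0061")   # a planted trans pair
#> r = 0.974, p < 2.2e-16
```

Reading: of 300 lncRNAs, four clear the full recurrence funnel (called DE
with `q < 0.05`, `|log2FC| > 1` in more than 10 of 19 pairs, all calls in
one direction). `LNC0198` tops the ranking — DE in 14/19 pairs, all up,
median log2FC 3.35. All four are planted positives: the occurrence filter
trades recall for near-perfect precision, which is the intended operating
point. The correlation for a planted lncRNA–gene pair (0.974) clears the
trans-target threshold of 0.95.

The whole pipeline also runs as one reproducible command:

```r
run_all(list(seed = 1), "run_dir")    # simulate -> identify -> de ->
                                      # prioritize -> targets -> enrich
```

writing one TSV per stage plus `manifest.json` (resolved config, seed,
per-stage row counts, package version); identical config and seed give
byte-identical outputs. `inst/scripts/run_pipeline.R` wraps this for the
shell. To analyze your own data, point `run_all()` at a directory with
`annotation.gtf`, `counts.tsv`, `samples.tsv`, `known_catalog.txt`,
`coding_calls.tsv` via `inputs = list(dir = ...)`.

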