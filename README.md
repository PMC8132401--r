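# homeoexpr

Homoeolog expression silencing and bias analysis for allodiploid
hybrids.

## What this is for

In an allodiploid hybrid — one chromosome set from each of two parental
species, here the maternal BSB subgenome (*Megalobrama amblycephala*)
and the paternal TC subgenome (*Culter alburnus*) — every gene exists as
a homoeolog pair whose two copies compete in one nucleus. Bulk RNA-seq
of hybrid tissue mixes reads from both copies. `homeoexpr` splits that
signal by subgenome and classifies each homoeolog pair, per condition,
as:

* **BSB-HES / TC-HES** — homoeolog expression *silencing*: one copy has
  0 assigned reads in every replicate while the other has ≥ 3 in every
  replicate;
* **BSB-HEB / TC-HEB** — homoeolog expression *bias*: both copies
  expressed, with mean-count ratio B̄/T̄ ≥ 2 (BSB-biased) or ≤ 0.5
  (TC-biased), boundaries inclusive;
* **normal** — everything in between; or **excluded** — too weakly
  expressed to call.

Aggregated over pairs, TC dominance = BSB-HES + TC-HEB and BSB
dominance = TC-HES + BSB-HEB, summarized per condition with counts and
percentages. The pipeline around the classifier provides:

* reciprocal-best-hit ortholog pairing of the two parental gene sets
  (built-in Smith–Waterman, k-mer candidate screening, deterministic
  tie-breaks);
* subgenome read assignment from species-specific SNPs, with a
  one-mismatch filter that excludes diagnostic positions from the
  mismatch count, strict/majority allele voting, and exact read
  accounting;
* FPKM and library-size normalization, a mean ± k·SD replicate screen
  (provably vacuous at k = 2, n = 3 — documented, not patched), DEH
  (differential homoeolog expression) calling with BH FDR < 0.01 and
  |log2FC| > 1, and a 2^-ΔΔCt qPCR utility;
* a fully seeded synthetic-study generator (parental transcriptomes,
  SNP catalogs, hybrid FASTQ reads, truth SAM alignments, design and
  truth tables) so the whole pipeline runs and is validated with no
  external data.

See the methods vignette (`vignettes/homoeolog-dominance.Rmd`) for the
model, rule precedence, and every tunable threshold.

## Worked example

A 100-pair synthetic study (3 replicates × 2 diet groups), simulated,
paired, assigned, quantified and classified end-to-end:

```r
library(homeoexpr)
cfg <- runConfig(simulate = list(nPairs = 100, depthMean = 30), seed = 7)
res <- runPipeline(cfg, "run_out")
res$dominance[, c("condition", "BSB-HES", "TC-HEB", "TC-HES",
                  "BSB-HEB", "normal", "total", "pct_BSB-HES")]
#>   condition BSB-HES TC-HEB TC-HES BSB-HEB normal total pct_BSB-HES
#> 1        G1      12     14      7      10     54    97       12.37
#> 2        G2      12     14      7      10     54    97       12.37
res$manifest$recovery_rate
#> [1] 1
dehSummary(res$deh)
#>    up  down total
#>     5     6    11
head(res$classification, 4)
#>    pair_id condition category    ratio
#> 1 pair0001        G1   normal 1.181818
#> 2 pair0002        G1   TC-HEB 0.240625
#> 3 pair0003        G1  BSB-HES       NA
#> 4 pair0004        G1  BSB-HES       NA
```

Reading this: 97 of the 100 designed pairs were classifiable in each
group (3 were group-specific pairs, excluded in their silent group);
the classifier recovered 100% of the designed categories
(`recovery_rate`), and 11 pairs were called differentially expressed
between the two groups (the generator designs both DE and
group-specific pairs, which is what the up/down split reflects). The
dominance table is the Table-style summary: e.g. 12 BSB-silenced pairs
= 12.37% of 97.

Every stage writes a TSV under the output directory (`pairs.tsv`,
`counts.tsv`, `accounting.tsv`, `expression.tsv`, `deh.tsv`,
`classification.tsv`, `dominance_counts.tsv`, `dominance_percent.tsv`,
`recovery.tsv`) plus `manifest.json` with per-stage row counts, the
seed, and the read-accounting conservation check. Real data enter
through the `alignments` block of the config (two parental FASTAs, a
SNP catalog TSV/VCF, per-sample SAM files, a design table); an external
ortholog table can replace the pairing stage. A thin CLI wrapper lives
at `inst/scripts/homeoexpr-run.R`.

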