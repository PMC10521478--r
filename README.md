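# evlongread

Transcript integrity and degradation-direction analysis for long-read
(nanopore cDNA) transcriptomes of extracellular vesicles (EVs).

## The problem

EVs — exosomes (~50–150 nm, endosomal origin) and microvesicles
(~100–1000 nm, plasma-membrane budding) — carry RNA between cells, and most
of that RNA is not full length. Short-read sequencing cannot say *which
part* of a transcript a fragment represents; long reads can, because a
single read spans the whole surviving molecule. `evlongread` takes
transcript-space alignments of long reads and asks, per read:

1. **How much of the assigned transcript does the read cover?** The
   *coverage rate* is `|union of aligned match blocks| / transcript length`.
   A read is **intact** when coverage > 0.9 (strict), otherwise
   **fragmented**.
2. **Which end is missing?** Working in transcript 5′→3′ coordinates
   (minus-strand genes are flipped by the coordinate converter), a terminus
   counts as covered when the alignment reaches within
   δ = max(20 nt, 0.10·L) of it. A fragment that keeps the 5′ terminus but
   not the 3′ is a **3′→5′ degradation** product; the mirror case is
   **5′→3′ degradation**; neither terminus is **endodegradation**; a
   fragmented read that still touches both ends is reported separately as
   `ambiguous_internal`.

Around these calls the package provides the full comparison workflow for a
two-subtype study: quality filtering and read summaries (mean/median/N50),
EM assignment of multi-mapping reads to transcripts (NanoCount-style
mixture EM), biotype composition by *distinct transcripts* vs by *read
counts*, intrinsic genes (detected in every sample) with a 2×2 chi-square
between subtypes, group-specific transcript/gene sets, sample-correlation
matrices, a Welch t-test on per-sample intact proportions, and a two-way
ANOVA on binned read-length distributions.

A fully seeded synthetic-data generator (`sim_config()`,
`simulate_catalog()`, `simulate_sample()`, `make_study_fixture()`) emits
annotation, transcript FASTA, per-sample alignments and per-read ground
truth, so the entire pipeline is testable without sequencing data.

## Worked example

```r
library(evlongread)

dir <- tempfile()
fx  <- make_study_fixture(dir, seed = 7, cfg = sim_config(seed = 7))
cfg <- pipeline_config(fx$paths$annotation, fx$paths$sample_sheet,
                       out_dir = file.path(dir, "report"))
res <- run_pipeline(cfg)

res$integrity$per_sample
#>   sample_id group    n n_intact intact_proportion
#> 1      Exo1   Exo 5000     1752            0.3504
#> 2      Exo2   Exo 5000     1802            0.3604
#> 3      Exo3   Exo 5000     1819            0.3638
#> 4       MV1    MV 5000     1327            0.2654
#> 5       MV2    MV 5000     1246            0.2492
#> 6       MV3    MV 5000     1309            0.2618

res$integrity$test
#> Welch t: statistic = 15.6592, df = 3.85024, p = 0.0001252

round(res$direction$overall$proportions, 4)
#> deg_3to5     endo deg_5to3
#>   0.4299   0.3414   0.2287
```

The six samples come from the generator's default study conditions: a
~30/70 intact/fragmented mixture with the exosome group's intact
probability raised by 0.10 over the microvesicle group, and fragmented
reads split (0.4266, 0.3447, 0.2288) across 3′→5′ / endo / 5′→3′
degradation. The pipeline recovers the group difference (Welch
p ≈ 1.3e-4) and the direction mixture from the reads alone. The report
bundle written to `out_dir` (read summaries, biotype composition,
correlation matrix, gene sets, integrity and degradation summaries,
coverage histograms) is byte-stable across reruns and carries a
fingerprint of the analysis configuration.

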