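# repairscape

Genome-wide maps of UV-induced DNA damage and nucleotide excision repair,
from aligned reads to chromatin-context statistics.

**Who it is for.** Groups analysing Damage-seq and XR-seq libraries (with
matched RNA-seq, ChIP-seq and ATAC-seq context data) who need the standard
processing chain behind single-nucleotide damage/repair cartography:
post-alignment filters, lesion-site inference, sequence-composition controls,
strand-resolved profiles, and nucleosome-scale periodicity statistics. A
synthetic-data module generates toy genomes and reads with known ground truth,
so every stage of the pipeline has a recovery test and can be explored without
downloading data.

## The core quantities

* **Damage sites.** A Damage-seq read's 5′ end sits two nucleotides past the
  lesion: for a `+` read starting at S the lesion dinucleotide is
  `[S-2, S-1]`, reported inside a 10-nt window with the lesion at oriented
  positions 5–6, and kept only if both bases are pyrimidines (C/T) on the
  damaged strand.
* **Transcribed-strand repair bias.** XR-seq reads lie on the damaged strand,
  so reads opposite a gene's strand are transcribed-strand (TS) repair and
  same-strand reads non-transcribed (NTS). Per gene, TS/(TS+NTS) is compared
  across expression quartiles with paired two-sided Wilcoxon signed-rank
  tests and Benjamini–Hochberg correction.
* **Composition background.** For every read, one pseudo-read of identical
  length and dinucleotide multiset is placed at a random matching genomic
  position; dividing profiles by pseudo-read profiles cancels sequence
  composition (dipyrimidine density) effects.
* **Nucleosome periodicity.** For a mean-centred binned profile x of length
  N, power at candidate period p (bin units) is
  `|Σ_n x_n e^{-2πin/p}|² / N`; the SNR is the power at the target period
  (160 bp nucleosome repeat, 10 bp helical turn) over the mean power at all
  other candidates, with an empirical p-value from 1000 bin shuffles.

## Worked example

Simulate a 1-Mb genome with planted structure, recover the 160-bp nucleosome
periodicity from inferred damage sites, and quantify expression-dependent
transcribed-strand repair bias from simulated XR-seq reads:

```r
library(repairscape)

cfg <- sim_config(seed = 1)
sim <- build_toy_genome(cfg)

## Damage-seq: infer lesions, apply the dipyrimidine filter, profile +/-1 kb
## around accessible-chromatin peak summits (201 x 10-bp bins)
dm <- simulate_damage_reads(sim, cfg)
win <- infer_damage_windows(dm$reads[["0h"]], sim$genome)
sites <- damage_dinucs(dipyrimidine_filter(win))
prof <- peak_profile(sites, sim$peaks, flank = 1000, n_bins = 201)

power_spectrum(prof$mean_combined, seq(100, 250, 5))
#> power_spectrum over 31 candidate periods ( 100 - 250 bp ), N = 201 bins of 10 bp
#>   peak: 160 bp, relative power 11.32

permutation_pvalue(prof$mean_combined, 160, seq(100, 250, 5),
                   n_perm = 1000, seed = 2)
#> periodicity_test: target 160 bp, SNR 17.25 , empirical p = 0 (1000 permutations)

## XR-seq: TS/(TS+NTS) by expression quartile
xr <- simulate_xr_reads(sim, n_reads = 100000)
expr <- subset(sim$expression, tpm > 0)
genes <- sim$genes[match(expr$gene_id, sim$genes$gene_id)]
ts <- count_in_bins(xr$reads, genes, strand_mode = "opposite")
nts <- count_in_bins(xr$reads, genes, strand_mode = "same")
q <- stratify(expr$gene_id, expr$tpm, n_groups = 4)
compare_strands(ts, nts, q$group[match(expr$gene_id, q$id)])
#>   group  n n_excluded mean_fraction median_fraction        p        q
#> 1    Q1 27          0         0.506           0.506 1.05e-01 1.05e-01
#> 2    Q2 27          0         0.551           0.554 5.92e-06 7.89e-06
#> 3    Q3 27          0         0.647           0.650 1.49e-08 2.98e-08
#> 4    Q4 27          0         0.749           0.748 1.49e-08 2.98e-08
```

The spectrum peaks at the planted 160-bp period with SNR 17 and no permuted
shuffle exceeding it; the recovered TS fractions match the generator's
planted quartile biases (0.50/0.55/0.65/0.75), with the asymmetry significant
in every expressed quartile above the lowest.

The methods vignette (`vignettes/repair-cartography.Rmd`) documents the
models, parameter choices, generator conditions, and numerical conventions.

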