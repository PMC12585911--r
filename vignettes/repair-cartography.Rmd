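---
title: "Mapping UV damage and excision repair in chromatin context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping UV damage and excision repair in chromatin context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The measurement problem

Ultraviolet light creates bulky photolesions — cyclobutane pyrimidine dimers
(CPDs) and (6–4) photoproducts — at adjacent pyrimidines. Two sequencing
assays map these events at single-nucleotide resolution. **Damage-seq** reads
arise from polymerase extension products that stall at a lesion: the lesion
dinucleotide sits exactly two nucleotides upstream of each read's 5′ end, on
the strand opposite the sequenced product. **XR-seq** captures the ~24-nt
oligonucleotides excised during nucleotide excision repair; each read *is* a
piece of the damaged strand, with the lesion positioned by the dual-incision
geometry (~16 nt from the 5′ end, 6 nt from the 3′ end). Because excised
oligonucleotides come from whichever strand was damaged, comparing read
counts on the strand opposite a gene (the transcribed/template strand, TS)
with the same strand (non-transcribed, NTS) measures transcription-coupled
repair; profiles centred on accessible-chromatin peaks and nucleosome dyads
measure how chromatin architecture gates damage formation and repair.

`repairscape` implements the computational chain from aligned reads to those
quantities: post-alignment filters, damage-site inference, a
composition-preserving background simulator, strand-resolved binned profiles
with a control-normalization chain, stratified strand-asymmetry statistics,
and spectral quantification of nucleosome-scale periodicity. Reads, genes and
anchors are `GRanges`; genomes are `DNAStringSet`s; BED/GFF3/FASTA input and
output goes through `rtracklayer` and `Biostrings`.

## Damage-site inference

For a `+` read starting at 1-based position $S$ the damaged dinucleotide is
`[S-2, S-1]` and the reported window `[S-6, S+3]` (conceptually: the read
trimmed to its first 4 nt, extended 6 nt upstream, placing the lesion at
oriented positions 5–6 of a 10-mer); a `-` read ending at $E$ mirrors this
(`[E+1, E+2]`, `[E-3, E+6]`). Reads whose window would leave the chromosome
are dropped and counted rather than clipped — a clipped window cannot satisfy
the width-10 invariant. A *dipyrimidine filter* then keeps only windows whose
oriented middle two bases are both C/T; windows containing N there are
rejected.

Whether the lesion is booked on the read strand or its complement is not
dictated by the file formats, only by the assay chemistry. The default
`convention = "opposite"` reflects Damage-seq chemistry (the sequenced
extension product is complementary to the damaged strand); `"read"` is
available because downstream strand bookkeeping in published pipelines often
operates in read coordinates. The window coordinates are identical under both
conventions; only the strand label and the orientation of the reported 10-mer
change, and the middle two positions map onto themselves under reverse
complement, so symmetric analyses are insensitive to the choice.

## Background simulation

Observed damage/repair enrichment confounds biology with sequence
composition: dipyrimidine-rich DNA forms more lesions. The background module
emits, for every input read, one pseudo-read of the same length at a random
genomic position and strand whose sequence has **exactly** the same multiset
of overlapping dinucleotides (`kmer = 2`). Dividing observed profiles by
pseudo-read profiles cancels composition effects.

Sampling proceeds in two phases. Up to `sens = 20` blind candidates are drawn
per read (chromosome ∝ length, start uniform, strand uniform; N-containing
windows are redrawn without consuming an attempt) and accepted on exact
multiset match. Reads still unmatched are then assigned a position drawn
uniformly at random from the precomputed set of *all* genomic windows with a
matching multiset, so the per-read composition identity still holds exactly;
only a read whose multiset occurs nowhere in the genome is emitted from its
last blind candidate with `flagged = TRUE`. We chose this exact-index
fallback (rather than emitting a mismatching candidate after `sens`
failures) because the one-pseudo-read-per-read contract and the per-read
composition identity are both load-bearing for the downstream normalization:
on small genomes blind rejection alone almost never finds an exact match for
a 24-mer's 23-dinucleotide multiset. The trade-off is that on a small genome
many pseudo-reads land on windows compositionally identical to their source
(often the source position itself), which is conservative for background
estimation — the background then looks maximally like the input's sequence
context. On genomes of realistic size the matching set is much larger and
positions disperse. The flagged fraction is reported and flagged reads can be
excluded from composition-sensitive analyses.

## Profiles and normalization

Counting follows `bedtools intersect -c -wa -F 0.5` semantics: a read is
assigned to a region when at least half of it (inclusive boundary) lies
inside, with `strand_mode = "opposite"` selecting TS reads and `"same"` NTS —
fixed by the fact that XR-seq reads lie on the damaged strand. Gene
metaprofiles bin a TSS- or TES-anchored window (default 1 kb upstream to
500 bp downstream, 100 bins) oriented along transcription; the window span is
a parameter pair because published figure captions sometimes state the
mirrored span (500 bp upstream to 1 kb downstream), and both are expressible.
Peak/dyad windows use `n_bins` bins of `2*flank/(n_bins - 1)` bp arranged so
the central bin straddles the anchor (201 × 10 bp for ±1 kb windows). For
dyad-centred analyses we profile ±80 bp with 81 × 2-bp bins: 2-bp resolution
is needed to resolve a 10-bp helical-turn periodicity, and 81 bins keep the
centre-bin convention. Plus-strand bin order can be reversed (`orient =
TRUE`) so transcription reads left-to-right on both strands; applying the
reversal twice is the identity.

The normalization chain for damage profiles is
`x / mock`, then division by `mean(naked)`, then `/ sim`, an 11-bin centred
rolling mean (truncated at the edges — no data are invented beyond the
window), and `log2`. XR profiles divide by their simulation profile only, or
additionally by the simulation-normalized damage profile to express repair
per unit of local damage. Bins with nonpositive denominators are masked,
propagate through the smoother as missing (window means over available bins),
are excluded from statistics, and are counted. All-ones inputs map to an
identically zero log2 profile, and because every profile is RPM-scaled first,
rescaling a library leaves results bit-identical.

Stratification (expression quartiles, chromatin tertiles) ranks items
ascending, breaks ties by item identifier for determinism, optionally drops
zero-expression items and the top 0.5% of ranked keys (outlier control), and
splits into groups whose sizes differ by at most one. Box summaries report
whiskers at the 12.5th/87.5th percentiles under linear interpolation between
closest ranks (type-7 quantiles) — stated explicitly because whisker values
depend on the interpolation rule. Paired two-sided Wilcoxon signed-rank tests
compare TS with NTS per group (zero differences are discarded, as the
signed-rank procedure prescribes, and the exact null distribution is used at
small n where the normal approximation would floor the attainable p-value);
timepoints are compared paired within tertile and tertiles unpaired within
timepoint; Benjamini–Hochberg correction is applied across the family of
tests emitted by one invocation. Genome-wide similarity of repair maps is
summarized by Ward clustering (`hclust(method = "ward.D2")`) of
`1 - Spearman` distances over 2-kb-bin RPM vectors; the rank-based
correlation makes the dendrogram invariant to monotone per-sample rescaling.

## Periodicity

For a mean-centred binned signal $\tilde x_n$ of length $N$, the power at a
candidate period $p$ (in bin units, converted from bp via the bin size) is

$$\mathrm{raw\_power}(p) \;=\; \frac{1}{N}\,
  \Bigl|\sum_{n=0}^{N-1} \tilde x_n \, e^{-2\pi i n / p}\Bigr|^2 .$$

Periods need not be integer multiples of the bin size (160 bp on 10-bp bins
is 16 bins; 10 bp on 2-bp bins is 5), but must exceed 2 bins (Nyquist).
Relative power divides by the mean over the candidate set, giving a
dimensionless measure comparable across timepoints and genotypes. Default
candidate grids are 100–250 bp in 5-bp steps (nucleosome repeat, target
160 bp) and 5–20 bp in 0.5-bp steps (helical turn, target 10 bp); the grids
are parameters because only the targets are biologically fixed. The SNR is
the power at the target divided by the mean power at all other candidates —
identical whether raw or relative power is used. Significance comes from
shuffling the bins uniformly at random (1000 permutations by default,
dedicated seed), recomputing the SNR each time, and reporting the proportion
of permuted SNRs *strictly exceeding* the observed one; the positively biased
$(k+1)/(n+1)$ estimate is reported alongside, since the strict proportion can
be exactly zero. A constant signal has undefined SNR and yields $p = 1$ by
convention. Missing bins are mean-imputed before spectral analysis (keeping
$N$ fixed; the imputed count is recorded) and shuffled along with the values
in permutations. For genotypes whose repair is transcription-driven and hence
asymmetric around anchors, the analysis can be restricted to the downstream
sub-window (whole bins whose start lies at or past +250 bp for peak windows,
+20 bp for dyad windows).

## What the synthetic generator emulates — and what it does not

`build_toy_genome()` draws an iid-base genome (default one 1-Mb chromosome at
GC 0.36, nematode-like), places non-overlapping genes with a minimum
neighbour gap, assigns log-normal TPM (10% of genes silent), and scatters
peak summits and dyad centres with clearance for profiling. Defaults define
the study conditions for all recovery tests:

* 120 genes of 2.2–6 kb with ≥600-bp gaps — enough that expression quartiles
  hold ~27 genes, the minimum at which a paired signed-rank test can resolve
  p < 10⁻⁶ (the attainable floor is $2/2^{n}$);
* XR read lengths on 10–32 nt peaking at 24 nt, with a read-orientation
  dipyrimidine exactly 6 nt from the 3′ end (0-based read indices
  $(L-7, L-6)$, matching incisions 16 nt 5′ and 6 nt 3′ of the lesion);
* TS/(TS+NTS) of 0.50/0.55/0.65/0.75 across expression quartiles, reads
  placed over expressed gene bodies with gene choice ∝ gene length;
* Damage-seq lesions only at dipyrimidine sites of the damaged strand
  (an optional fraction of non-dipyrimidine "noise" lesions exercises the
  filter), each emitting one 50-bp read by the exact inverse of the
  damage-window geometry under the same strand convention;
* lesion density modulated by a 160-bp cosine (amplitude 0.5) around peak
  summits, a 10-bp cosine (amplitude 0.4) around dyads, and a Gaussian dip
  (depth 0.4, sd 75 bp) at summits — amplitudes above 1 are rejected since
  they would imply negative densities;
* timepoint survival 1/0.5/0.2/0.08 at 0/8/24/48 h as independent Bernoulli
  draws per lesion, with survival near peaks multiplied by
  $1 + 0.3\cos(2\pi d/160)$ so linker lesions are repaired preferentially and
  the damage periodicity sharpens at late timepoints;
* mock (uniform genomic) and naked-DNA (dipyrimidine density only) control
  read sets at matched depth.

The periodicity amplitudes are chosen for test power, not realism — the
corresponding amplitudes in real data are not quantified. The generator omits
repeats and mappability structure (reads are emitted as alignments, so
alignment artefacts are out of scope), sequencing errors, fragment-size
chemistry, replicate structure and cell-type mixtures. Passing recovery tests
therefore demonstrates that the *computational chain* is correct and
calibrated, not that real libraries satisfy its assumptions.

## Numerical and design choices

* Coordinates are 1-based closed `GRanges` internally; BED (0-based
  half-open) and GFF3 (1-based) conversion is delegated to `rtracklayer`.
* XR mapping-quality filter is strict (`mapq > 20`); the RNA-seq filter is
  `mapq >= 30`; both boundaries are honoured exactly, as are the 21–28 nt
  inclusive length bounds. Length distributions can be inspected before
  filtering; `positional_composition()` accepts any read-length subset, so
  composition figures can be drawn from filtered or unfiltered reads.
* Duplicate collapse keys on (chromosome, start, end, strand) and keeps the
  first occurrence; it runs before damage-window inference.
* The half-overlap counting boundary is inclusive (≥ 0.5), matching `-F 0.5`
  semantics.
* The background simulator encodes dinucleotide count vectors as two base-64
  integers (exact in doubles for reads ≤ 64 nt) and uses a single RNG stream
  seeded from its `seed` argument.
* Degenerate inputs are explicit: empty chromosome whitelists, unstranded
  regions under a stranded counting mode, all-zero denominators, constant
  samples in clustering, and sub-Nyquist candidate periods are errors;
  all-zero TPM input warns and returns zeros.

Problem sizes used by the test suite and the acceptance script — 1-Mb
genomes, 10⁴–2×10⁵ reads, 100–500 replicate seeds, 200–1000 permutations —
were chosen so each recovery has clear statistical margin while the whole
suite runs in minutes on one CPU.

## Known limitations

Reads are modelled as ungapped intervals; CIGAR-aware split reads, soft-clip
recovery and BAM-specific metadata are out of scope (BAM should be reduced to
BED6-equivalent intervals upstream). The background simulator implements
`kmer = 2` only. Peak calling, dyad inference, adapter trimming and alignment
are consumed, not performed. On very small genomes the background simulator's
exact-matching behaviour makes the background resemble the input closely (see
above); interpret simulation-normalized profiles on toy genomes accordingly.

## A compact end-to-end example

```{r example, eval = FALSE}
library(repairscape)

cfg <- sim_config(seed = 1)
sim <- build_toy_genome(cfg)

## Damage-seq: infer lesions, filter, profile around accessible peaks
dm <- simulate_damage_reads(sim, cfg)
win <- infer_damage_windows(dm$reads[["0h"]], sim$genome)
sites <- damage_dinucs(dipyrimidine_filter(win))
prof <- peak_profile(sites, sim$peaks, flank = 1000, n_bins = 201)

## nucleosome-scale periodicity with permutation significance
ps <- power_spectrum(prof$mean_combined, seq(100, 250, 5))
snr(ps, 160)
permutation_pvalue(prof$mean_combined, 160, seq(100, 250, 5),
                   n_perm = 1000, seed = 2)

## XR-seq: transcribed-strand bias by expression quartile
xr <- simulate_xr_reads(sim, n_reads = 100000)
expr <- subset(sim$expression, tpm > 0)
genes <- sim$genes[match(expr$gene_id, sim$genes$gene_id)]
ts <- count_in_bins(xr$reads, genes, strand_mode = "opposite")
nts <- count_in_bins(xr$reads, genes, strand_mode = "same")
q <- stratify(expr$gene_id, expr$tpm, n_groups = 4)
compare_strands(ts, nts, q$group[match(expr$gene_id, q$id)])
```
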