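---
title: "From per-read nanopore calls to differential methylation: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From per-read nanopore calls to differential methylation: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poreMethyl)
```

# The analysis model

Signal-level nanopore methylation callers compare, per read and per CpG
site, the likelihood of the observed current signal under a methylated
versus an unmethylated model, and emit the log-likelihood ratio (LLR).
Because the signal window spans several bases, CpGs closer than about six
bases are not separable: they are reported as one *group* (k-mer) with
shared coordinates, a motif count, and a context sequence. This package
takes those per-read rows as its raw data and makes three modelling moves.

**Per-read calling is a three-way threshold.** A read supports methylation
when `LLR > t`, non-methylation when `LLR < -t`, and is *ambiguous*
otherwise. Ambiguous reads are excluded from both numerator and
denominator — they carry no confident evidence, and counting them as
unmethylated would bias frequencies downward at exactly the low-coverage
sites where it matters most. The default `t = 2` follows the convention of
the widely used frequency-summary helpers (published versions have used
values between 2.0 and 2.5); the threshold is surfaced in logs and output
headers because estimates are not comparable across thresholds. The
frequency estimator is the maximum-likelihood binomial proportion
`called_methylated / called`.

**Groups are the default analysis unit.** Since the caller cannot resolve
members of a group, a group's frequency applies to all of its CpGs jointly.
`aggregateSites(splitGroups = TRUE)` expands groups into per-CpG records at
the CG offsets of the context sequence — useful for per-CpG summaries — but
the genome-wide comparison keeps groups intact, matching how multi-CpG
k-mers are actually observed. Read-coverage filters therefore count *reads
per group* (`called_sites / num_motifs`), never motif-multiplied counts,
and the filter is applied before any splitting.

**CpG depletion is an independent, evolutionary-scale measurement.**
Methylated cytosine deaminates to thymine; a germline-methylated sequence
loses CpGs over evolutionary time. Per sequence we compute

$$\mathrm{CpG\ O/E} = \frac{n_{CpG}}{n_C \cdot n_G}\cdot\frac{l^2}{l-1},$$

with $l$ the sequence length. Ambiguity codes (N) count toward $l$ but not
toward the base or dinucleotide counts: the formula's "length of the
sequence" is taken literally while phantom CpGs are never invented. The
statistic is undefined (flagged, not dropped) when a sequence lacks C or G
or is shorter than 2. Note the $l^2/(l-1)$ normalisation is implemented
exactly as written; some literature uses $l/(l-1)$ variants, so
cross-study comparisons of absolute values need care. Outlier bounds
$(0.001, 2)$ are strict on both sides. Agreement between nanopore-derived
methylation and CpG O/E — a negative correlation, and depressed O/E among
fully methylated transcripts — validates the sequencing-based measurement
against an orthogonal signal.

# The two-group comparison

Per-sample site tables are joined by **strict intersection**: a position
enters the matrix only with at least `minCalled` (default 3) called reads
in *every* sample. This is the literal reading of a per-sample coverage
threshold, and it guarantees the downstream tests never see missing cells;
the cost is that one shallow sample can drop many positions, which the
funnel log makes visible.

Per position we run a two-sample t-test on the per-sample frequencies.
Welch's unequal-variance flavour is the default because per-group variances
estimated from 4 samples are unstable; the pooled flavour is available and
the choice is logged. Three regimes are distinguished, using a
zero-variance tolerance of $\varepsilon = 10^{-12}$ (frequencies are ratios
of small integers, so true zeros are exactly representable):

* both group variances $< \varepsilon$ and means differing by more than
  $\varepsilon$: a **perfect difference** — the t statistic is undefined,
  and the position is reported through its own channel;
* both variances $< \varepsilon$ with equal means: $t = 0$, $p = 1$;
* otherwise: an ordinary test.

Benjamini–Hochberg runs at $\alpha = 0.05$ over the *testable* positions
only; perfect positions are not part of the FDR family because no p-value
exists for them. Flagged positions (perfect, or optionally `q ≤ α`) merge
into regions by single linkage whenever consecutive same-contig positions
are at most `maxGap` apart. The default `maxGap = 2000` bp is a judgement
call: methylation data of this kind shows differential blocks on the
10-kb scale with positions spaced tens to hundreds of bases apart, so 2 kb
bridges realistic within-block gaps without joining unrelated loci. It is a
parameter, not a claim.

The sample-level PCA centres positions but does not scale them (all
variables already live on the common $[0,1]$ frequency scale; unit-variance
scaling would inflate near-constant positions into noise axes). Signs
follow a deterministic convention — the largest-magnitude loading of each
component is made positive — so results are reproducible across BLAS/LAPACK
builds and sample orderings.

# What the generator emulates, and what it does not

The synthetic module produces every input the pipeline reads, with known
truth, under a mandatory seed.

* **Sequences** (`simulateDepletedSequences`): independent equiprobable
  bases; each CG is replaced by TG with probability
  `decayRate × methylation level`. This is a one-step caricature of
  deamination — sufficient to make CpG O/E decrease in methylation, which
  is the property the validation analysis needs. The methylation prior is
  spike-and-slab bimodal: a transcript is high-methylation with probability
  0.1, each mode collapses to its exact boundary (0 or 1) with probability
  0.5 and otherwise draws Beta(1, 20) / Beta(20, 1). The spikes reflect
  that real transcriptomes contain genes with no methylation at all, and
  they populate the exact fully-unmethylated / fully-methylated classes the
  extremes contrast is defined on.
* **Read calls** (`simulateReadCalls`): CpGs within 6 bases merge into one
  group; per read, the methylation state is Bernoulli(truth) and the LLR is
  drawn from N(+5, 1) or N(−5, 1). The modes are symmetric Gaussians
  because only the empirical shape of the caller's LLR distribution is
  known — bimodal with well-separated modes; with the default geometry,
  miscalls at threshold 2 have probability ≈ 1.3 × 10⁻¹² per read and
  ambiguity ≈ 1.3 × 10⁻³, so calling is near-perfect unless the user
  degrades `llrMu`/`llrSigma`.
* **Experiments** (`simulateExperiment`): a 4-vs-4 design with group
  baselines 0.055 and 0.059 — sparse genome-wide methylation with a subtle
  group shift, the regime in which the method's statistical behaviour is
  interesting — plus per-sample Gaussian jitter truncated to [0, 1]
  (default sd 0.002, the scale of the tiny between-animal spread such
  designs show) and optional injected DMR blocks with their own
  frequencies, spacing and jitter.
* **Frequency matrices** (`simulateFrequencyMatrix`): the high-coverage
  limit, skipping the binomial read layer so per-sample frequencies are
  continuous. At realistic depths frequencies are ratios of small
  integers, and exact between-sample ties — spurious "perfect"
  positions — occur by chance; the continuous generator isolates the
  detector's intrinsic behaviour from that discreteness, and the read-level
  generator demonstrates the discreteness itself.

Not emulated: read-length and error profiles, mapping artefacts, symbiont
(algal) DNA contamination, strand-specific effects, or any dependence of
methylation between neighbouring positions. Passing tests therefore show
that the *statistics* behave as designed on data matching the stated
generative assumptions — they do not certify performance on real nanopore
data, where upstream calling error is structured rather than Gaussian.

# Numerical and interface choices

* Coordinates: call tables and site tables on disk are 0-based inclusive
  (the upstream dialect); `GRanges` inside the package are 1-based
  inclusive (Bioconductor convention); BED export is 0-based half-open.
  Only the boundaries convert.
* Minus-strand calls collapse onto the forward-strand C of the palindromic
  CpG by default (`collapseStrands = FALSE` keeps strands apart); whether
  strand-separated coordinates were ever the right unit is data-dependent,
  so the switch exists.
* Transcript-level methylation pools counts
  ($\sum \mathrm{meth} / \sum \mathrm{called}$) rather than averaging site
  frequencies: robust to unequal per-site coverage. The unweighted mean is
  available (`weighted = FALSE`) since either convention is defensible.
* "Fully" methylated/unmethylated means *exactly* 1 or 0 after pooling; no
  tolerance band.
* Duplicate (read, group) pairs keep the first occurrence, logged. Groups
  whose rows disagree on motif count or context sequence are an error, not
  a silent majority vote.
* BH is delegated to `stats::p.adjust(method = "BH")` after validating
  p-values in (0, 1]; the test suite pins it against an independent
  brute-force step-up implementation.
* Every filter logs input count, output count, and threshold, so an
  analysis funnel (e.g. transcripts surviving coverage filters) is
  reconstructible from the log alone, and every writer echoes its
  parameters as `# key=value` header lines.

# Test problem sizes

The statistical guarantees in the test suite run at fixed seeds and these
sizes, chosen to make each property measurable while keeping the default
suite fast: FDR control on 20 replicates of 5000 null + 50 signal positions
(shift 0.4, per-sample sd 0.05); CpG O/E against brute-force enumeration on
1000 sequences of length 50–5000; aggregation against a naive reference on
10⁴-row call files; frequency recovery at 500 sites × 30 reads; depletion
correlation sign on 20 replicates of 200 length-2000 transcripts with the
null-uniformity companion at 200 replicates of 60 length-600 transcripts;
perfect-difference and region recovery on 10⁵ jittered null positions plus
a 10 kb injected block, with the block also run through the full per-read
pipeline.

# Limitations

The pipeline reproduces a specific, deliberately simple analysis: binomial
frequencies, per-position t-tests at n = 4 per group, BH, and zero-variance
region calling. It does not model coverage in the test statistic
(beta-binomial), borrow strength across positions (smoothing DMR callers),
or adjust for covariates; at four samples per group, per-position power is
modest and the perfect-difference channel is sensitive to frequency
discreteness at low coverage, which is why region size and per-group means
are always reported alongside the flags.
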