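---
title: "Detecting alternative polyadenylation from 3'UTR coverage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting alternative polyadenylation from 3'UTR coverage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Most human genes carry more than one polyadenylation site (PAS), and which
site is used decides how much of the 3' untranslated region (3'UTR) a
transcript retains. Because the 3'UTR harbors microRNA and RNA-binding
protein (RBP) elements, a shift between a proximal and a distal PAS changes
transcript stability, localization and translation without changing overall
expression — so it is invisible to standard differential-expression
analysis. apascan infers such shifts from ordinary short-read bulk RNA-seq:
no 3'-end sequencing is required, only per-base coverage over annotated
3'UTRs.

## The coverage model

For one gene, let `x_s(i)` be sample `s`'s read coverage at base
`i = 1..L` of the 3'UTR, oriented 5'→3' of the transcript. Two isoforms are
assumed: a *short* isoform ending at an unknown proximal PAS at offset `P`,
and a *long* isoform spanning the full UTR. Their superposition gives the
two-segment expectation

```
E[x_s(i)] = w_short,s + w_long,s   for i <= P
E[x_s(i)] = w_long,s               for i >  P
```

For a candidate `P` the least-squares weights are closed-form segment
means: `w_long,s = mean(x_s[(P+1)..L])` and
`w_short,s = max(0, mean(x_s[1..P]) - w_long,s)` (abundances cannot be
negative; when the clamp binds, residuals are recomputed at
`w_short = 0`). The breakpoint is chosen by minimizing the residual sum of
squares **summed over all samples of both conditions jointly**, with
residuals weighted equally across bases and samples. A single shared `P`
is essential: per-sample breakpoints would make the usage index
incomparable between samples. Ties in RSS break to the smallest `P`, so
output is deterministic.

The candidate grid runs over `[margin, L - margin]` (default
`margin = 100` nt, `stride = 1` nt). The margin prevents degenerate
one-base segments and near-end fits that only model edge effects; 100 nt is
approximately one read length, the scale over which coverage at a true PAS
decays. Genes with `L <= 2 * margin` are skipped, which is also why
annotation extraction drops UTRs shorter than `min_utr_length` (default
150 nt) — a search window must remain.

The vectorized search (cumulative sums over bases) is algebraically
identical to exhaustive per-candidate evaluation; the test suite asserts
exact agreement of `P` and weights with a brute-force oracle on random
UTRs, and exact recovery (`P = P0`, zero residual) for noiseless step
coverage.

### PDUI and differential calls

The Percentage of Distal poly(A) site Usage Index is the per-sample long
isoform share,

```
PDUI_s = w_long,s / (w_long,s + w_short,s)  in [0, 1],
```

a within-sample ratio, hence invariant to any per-sample rescaling of
coverage — sequencing-depth normalization (coverage per million mapped
reads, with library sizes supplied in the sample sheet) affects only the
expression filter and reported coverage, never the index. Group PDUIs are
unweighted means over replicates, and

```
ΔPDUI = mean PDUI(perturbed) - mean PDUI(reference),
```

so positive ΔPDUI means 3'UTR lengthening under the perturbation. A gene
is called significant when `|ΔPDUI| >= 0.1` (inclusive) *and* its
Benjamini–Hochberg adjusted p-value is below 0.05; a `p_mode = "raw"`
switch gates on unadjusted p-values instead, the appropriate convention
for low-replicate designs such as small postmortem cohorts. Both
thresholds are configurable.

The per-gene test is a deliberate, documented choice: with at least two
replicates per group, a two-sided Welch t-test on per-sample PDUIs; with a
single replicate in either group, a two-sided Fisher exact test on the
2×2 table of rounded long/short read mass (weight × segment length) pooled
per group. Replicate-level testing respects biological variability but is
conservative at n = 3; absolute gene counts are therefore sensitive to
this choice, while directions, effect sizes and relative comparisons are
not.

### Expression filter

A breakpoint fit in a sample without signal is noise, so a gene is
analyzed only when its mean depth-normalized UTR coverage reaches
`min_mean_coverage` (default 15, boundary inclusive) in **every** sample,
not merely on average. The default is a pragmatic coverage floor, not a
calibrated constant; downstream guarantees in this package's validation do
not depend on its exact value.

## Binding-site integration and overlap statistics

APA gene sets are intersected with RBP binding intervals (e.g. eCLIP
peaks) at gene level: a gene is categorized `utr3` if any site overlaps
its 3'UTR by at least one base, else `other_region` if a site overlaps the
gene body, else `none`. For `utr3` genes the signed nearest-edge distance
from the site to the distal PAS is reported, negative upstream
(transcript 5') of the PAS, with a flag for `|distance| <= 75` nt — the
zone in which binding of an RBP such as TDP-43 represses PAS usage, while
binding further downstream enhances it.

Overlaps between gene lists use the exact hypergeometric upper tail
`P[X >= overlap]`, and gene-set over-representation applies the same test
per set with BH adjustment across sets. The universe must be supplied
explicitly (for APA analyses, the natural universe is the genes passing
the expression filter): silently defaulting it would fabricate
significance, so the package refuses to guess. Only enrichment
(upper-tail) p-values are computed. Summary percentages round
half-away-from-zero to one decimal (so 51.25 prints as 51.3); in direction
summaries the shortened percentage is reported as the complement of the
lengthened one, keeping the pair summing to exactly 100.

## What the simulator emulates — and what it does not

`sim_config()` / `simulate_dataset()` generate complete synthetic
experiments with known truth: per gene a UTR length (600–1500 nt), a true
proximal PAS placed at least `margin + read_length` from either UTR end, a
baseline PDUI drawn from 0.2–0.8, and an effect class (default 60% null,
30% lengthened at ΔPDUI = +0.3, 10% shortened at −0.3 — the
lengthening-dominant regime reported for TDP-43 depletion, at a
typical 100× UTR coverage and 100-nt read length with 3 replicates per
condition). Read counts per isoform are Poisson (negative binomial when
`dispersion > 0`), and each read is placed uniformly along its isoform
including an upstream flank, so coverage at the UTR 5' end is at full
height and the drop at the true PAS is a *soft ramp* about one read length
wide — deliberately harder than an ideal step, so recovery tolerances are
honest and are stated in read-length units. One global seed expands into
per-gene, per-sample substreams by stable hashing of identifiers, making
any subset reproducible regardless of iteration order. The default
sample-sheet library size is 10^6 mapped reads, so the depth factor is 1
and raw and normalized coverage coincide — convenient for reasoning about
the expression filter at the simulated depth.

The simulator does **not** model fragment-length distributions, positional
or GC bias, multi-mapping, annotation error, more than two isoforms per
gene, or expression differences between conditions. Passing recovery tests
on these data therefore demonstrates correctness of the inference given
the two-isoform coverage model, not robustness to every artifact of real
libraries.

### Known estimator behavior on soft breakpoints

Because the fitted breakpoint settles mid-ramp, roughly half a read length
of short-isoform mass is attributed to the long isoform. This attenuates
true effects multiplicatively by about `(read_length / 2) / (L - P)` —
a few percent of |ΔPDUI| at the default geometry. Consequently ΔPDUI
estimates are additively unbiased under the null (asserted by a
simulation test) but slightly conservative for true effects; the
parameter-recovery bounds (median PDUI error ≤ 0.05, median breakpoint
error ≤ one read length at 100×) absorb this by construction.

## Validation problem sizes

The shipped validation uses simulations sized for quick, exact checks:
oracle equivalence on 100 random UTRs of ≤ 500 nt; parameter recovery on
100 genes; false-call control on a 500-gene null experiment (observed rate
0 at the dual threshold); direction consistency on a 200-gene mixed
experiment; hypergeometric exactness by full enumeration over every
configuration with universe ≤ 25. All are deterministic given their seeds.

## Design choices where the design was open

* **Regression formulation.** The breakpoint model is implemented as the
  two-segment least-squares fit described above — the formulation that is
  fully specified by coverage data alone — rather than as a distributional
  mixture whose parameters would need priors the data do not pin down.
* **Joint fit is unweighted across samples.** Depth-weighting the joint
  RSS would let one deep library dominate breakpoint placement; the
  per-sample weights already absorb scale.
* **CDS boundary for multi-transcript genes.** The UTR is defined by the
  transcript carrying the most distal end (the isoform being segmented);
  when several transcripts attain it, the boundary giving the longest UTR
  is used, deterministically. Genes with multiple annotated last exons are
  analyzed on the distal-most last exon only — an alternative last exon
  without an upstream junction appears, if at all, only through its
  overlap with that region.
* **Masking.** UTRs overlapping an *exon* of another gene are flagged and
  excluded from fitting; intronic overlap is ignored because it does not
  confound exonic coverage.
* **Inclusive thresholds.** `|ΔPDUI| >= 0.1` is inclusive, and the 75-nt
  proximity rule is inclusive at exactly 75.
* **Degenerate inputs.** All-zero genes, UTRs shorter than the search
  window, genes quantified in one group only, and gene × sample pairs with
  both weights zero are each dropped with an explicit message rather than
  silently imputed; an empty result set is an error, not an empty file.
  Two zero-variance identical groups give p = 1; zero-variance groups at
  different constants (possible only on noiseless input) give p = 0.

## Limitations

One breakpoint per UTR: genes using three or more PASs are summarized by
the single strongest transition. Intronic PASs, PAS-motif priors, de novo
last exons, covariate adjustment and paired designs are out of scope.
Absolute significant-gene counts depend on the per-gene test convention
(see above) and on the replicate number; cross-dataset comparisons should
hold the convention fixed.
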