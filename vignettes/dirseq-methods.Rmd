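---
title: "Quantifying allele-specific regulatory activity with dirseq"
author: "dirseq authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying allele-specific regulatory activity with dirseq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dirseq)
```

## The assay and its model

DiR-seq is a dinucleotide-barcode massively parallel reporter assay
(MPRA). For each candidate regulatory SNP, a 55-bp fragment centered on
the variant is synthesized for both alleles and cloned upstream of an
SV40 minimal promoter in a reporter vector that places a 2-nt barcode in
the transcribed region, so every (SNP, allele) maps to one barcode. The
pooled plasmid library — here 22 SNPs x 2 alleles plus one promoter-only
negative control, mixed equimolar — is transfected into a panel of cell
lines in biological triplicate; reporter cDNA and the plasmid input are
sequenced, and barcodes are counted.

The quantity of interest is per-construct reporter activity. With
$c_{ij}$ the barcode count of construct $i$ in cDNA sample $j$ and $p_i$
its plasmid-input count, each column is depth-normalized to counts per
million and activity is the doubly normalized ratio

$$ a_{ij} \;=\; \frac{\mathrm{cpm}(c_{ij}) / \mathrm{cpm}(p_i)}
   {\mathrm{cpm}(c_{0j}) / \mathrm{cpm}(p_0)}, $$

where index 0 is the negative control, whose activity is therefore
exactly 1 in every sample by construction. Dividing by the plasmid cpm
removes pool-composition bias; dividing by the control removes
sample-wide scale (transfection efficiency, RT yield). The cpm step is a
design choice: the source protocol does not state a depth correction,
but ratios of proportions are the standard MPRA treatment and give the
package its scale-invariance property (multiplying any one sample's
counts by a constant leaves activities unchanged). The choice is
recorded in the activity object's parameters.

A SNP is called *regulatory* in a cell line when the risk/protective
fold change of mean replicate activities leaves the band
$(0.8,\,1.2)$ **and** a two-tailed two-sample $t$-test on the linear
activities gives $p < 0.05$. The pooled-variance (Student) test is the
default, matching the assay's published analysis; Welch's correction is
available by configuration and is the default for the genotype-group
(eQTL-style) comparisons in `welch_association()`, where group variances
are not expected to be equal. No multiple-testing correction is applied
across the SNP x cell-line grid — the call rule's fold-change gate
already makes it conservative relative to its nominal $\alpha$ — but the
number of tests is attached to the call table so users can adjust.

## What the simulator emulates

`simulation_truth()` + `simulate_counts()` generate the inputs the
pipeline consumes from a declared ground truth, so every downstream
stage is testable without external data. The defaults describe the
emulated study: a 45-construct equimolar pool, biological triplicates,
eleven cell lines (nine breast, two prostate), and $10^5$ read pairs
per sample.

- **Plasmid pool**: nominally equimolar proportions with mild lognormal
  jitter (`plasmid_jitter_sd = 0.05`), sampled multinomially at the
  requested depth. The jitter models pipetting inequality in an
  "equal-mix" pool; because the same underlying proportions drive the
  cDNA means, it cancels from activity in expectation.
- **cDNA counts**: negative binomial with mean proportional to plasmid
  proportion x the construct's activity multiplier, scaled to the
  sample depth. The NB (rather than Poisson) choice reflects the
  overdispersion of biological replicates; `dispersion` is the usual
  NB $\phi$ (variance $\mu + \phi\mu^2$), with $\phi = 0$ recovering
  Poisson. The default $\phi = 0.002$ gives a per-replicate activity
  CV of about 5% for a 45-construct pool at depth $10^5$
  ($\mathrm{CV}^2 \approx \tfrac{2}{3}(1/\mu + \phi) + 2/\mu$ for a
  fold change from triplicates), consistent with the tight
  between-replicate correlation such assays report and with the
  generator's declared recovery property: engineered multipliers of
  0.5, 1 and 2 are recovered within 10% at depth $10^5$.
- **Reads**: each counted barcode is rendered as a fully overlapping
  read pair over the fixed architecture *upstream anchor + 6-nt
  sub-library tag + 2-nt barcode + downstream anchor*, where the
  downstream anchor is the reverse complement of the BarP6
  reverse-transcription primer. Substitution errors are injected
  independently per mate at `read_error_rate` (default 0.001); indels
  and quality-profile structure are deliberately out of scope, so
  merge logic is testable in closed form.
- **Ct tables**: $\mathrm{Ct} = \mathrm{baseline} - \log_e(q) +
  \mathcal{N}(0, \sigma)$ under amplification efficiency $e$ (default
  2.0, i.e. perfect doubling), with technical triplicates.
- **Traces**: four channels of unit-height Gaussian peaks at regular
  spacing (10 samples/base, peak SD 1.5 samples); at the heterozygous
  position the two allele channels share the position with heights
  proportional to the allele fractions; Gaussian intensity noise is
  added and clipped at zero.

Every artifact is a deterministic function of one integer seed, and each
generator draws from its own seeded stream so stages can be regenerated
independently.

What passing tests on these simulations do **not** show: the count model
has no PCR-jackpotting, GC or position bias, and no cross-contamination
between barcodes; the read model has no indels or quality decay; the
trace model has no dye blobs, mobility shifts or baseline drift. Results
on real data will be noisier than the recovery properties suggest, and
the fold-change gate of the call rule is the main protection against
that extra noise.

## Read merging and demultiplexing

Pairs are merged by aligning the reverse-complemented mate 2 against
mate 1 at every offset with at least `min_overlap` (default 20) bases of
overlap; the offset with the fewest substitutions wins if it has at most
`max_mismatch` (default 2), and a tie between offsets discards the pair
rather than guessing. In the merged read, overlap positions take mate
1's base — without per-base qualities there is no better arbiter, and
downstream anchor-mismatch tolerance absorbs the residual errors.

Demultiplexing requires the upstream anchor to match the read start with
at most 2 substitutions, then looks up the following 8 nt
(tag + barcode) exactly. The dinucleotide barcode is only two bases, so
any mismatch tolerance there would reassign identity; mismatches are
tolerated only in the anchor. Reads failing any step land in an
"unassigned" tally, so assigned + unassigned always equals the read
count — a conservation law asserted in the tests. Barcode assignment at
design time is lexicographic (sorted rsID, then allele role, control
last, dinucleotides AA..TT within each 6-nt sub-library tag), so a
manifest maps to one and only one library without any seed. The tag
scheme itself is this package's own self-contained stand-in for the
original vector architecture, published in `dirseq_architecture()`.

## Ct arithmetic

All qPCR quantifications assume exponential amplification at a fixed
efficiency $e$ (default 2.0; no standard curves are modeled, but $e$ is
a parameter everywhere). Technical replicates are averaged on the Ct
scale before deltas, with replicate SD propagated as
$\sqrt{s_t^2 + s_r^2}$. The getPCR readout is reconstructed as a double
delta of the allele-specific amplicon against a non-allelic reference
amplicon across edited and unedited pools; the original method's exact
normalization is not restated in the source protocol, so this
reconstruction is documented as such rather than asserted as identical.

## Under-peak areas

Allele quantification in Sanger traces integrates the called base's
channel (trapezoid rule) over a window of half-width `window_frac`
(default 0.5) times the local inter-peak spacing, after subtracting a
baseline estimated as the channel's 10th-percentile intensity over a
neighborhood five times the window. The area — not the peak height —
is the primary statistic, matching the under-peak-area readout the
assay uses, though `mode = "height"` is offered for sensitivity
checks. The percentile baseline is robust and simple; it is not the
EditR normalization, which is not reproduced here. Degenerate cases
are refused loudly: windows that cross the trace edge, allele pairs
whose areas are both zero, and genomic-DNA ratios of exactly 0 or 1
(which make the allele-specific-expression odds ratio undefined).
Indices into called bases are 1-based throughout, as everywhere in R;
the manifest's on-disk `snp_offset` column is the one 0-based quantity,
kept 0-based for interoperability and converted on load.

## Problem sizes and numerical choices in the test suite

The suite exercises the full 22-SNP/45-construct library at depth
$10^5$ for the structural and recovery checks, a 506-pair null grid for
the false-positive-rate property, 200 repeat simulations for detection
power, and nine allele fractions for trace recovery — sizes chosen so
the whole suite runs in a few minutes on one core while keeping each
stochastic assertion several standard errors away from its threshold.
Stochastic recovery is asserted on Monte-Carlo means over fixed seeds;
call correctness is asserted in every individual run. Exactness is only
ever asserted where the arithmetic is exact: the control's unit
activity, closed-form Ct identities, error-free round-trips, and
noiseless traces whose het context contains no other peak of the allele
bases (a neighboring same-base peak leaks ~0.4% of its area into the
window, which is why "exact" trace tests use such contexts).

## Known limitations

- The package analyzes and simulates; it does not call bases, parse
  vendor binary trace files, or align reads to a genome.
- The merge step is substitution-only; reads with indels will fail to
  merge rather than be rescued.
- The call rule is the published two-threshold rule; users wanting
  FDR-controlled calls should correct the reported p-values themselves.
- The fixture manifest ships synthetic flanking sequence (documented in
  `inst/extdata/README.md`); real designs should load their own
  manifest of genomic context.
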