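---
title: "Models and methods: pooled shRNA dropout screens, synergy, and DE post-processing"
author: "dropscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: pooled shRNA dropout screens, synergy, and DE post-processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropscreen)
```

# The experiment this package models

In a pooled shRNA negative-selection ("dropout") screen, a cell population
is transduced at low multiplicity with a lentiviral library in which every
short-hairpin construct carries a unique DNA barcode. After a selection
period in culture, constructs silencing genes the cells need for survival
are depleted relative to a baseline sample frozen at the start. Sequencing
the barcode amplicon before and after selection, counting barcodes, and
comparing normalized abundances yields a per-shRNA depletion fold change;
aggregating those per gene yields an essentiality ranking.

The reference design emulated throughout this package is a library of
27,500 shRNAs over roughly 5,000 signalling-pathway targets, of which
4,974 are "reliable" genes targeted by five or six distinct shRNAs each;
selection runs for 9 days; each experiment is performed in duplicate from
the transduction stage forward; cells are represented at 200--1000x the
library complexity; and arms ("settings") differ by drug and medium, e.g.
plain medium, medium with a JAK1/2 inhibitor, and stroma-conditioned
medium plus the inhibitor, so that condition-specific dependencies can be
separated from universal ones.

# The essentiality statistic

For each sample, counts are normalized to reads-per-million after adding a
pseudocount `q` to every cell:

$$\tilde c_{is} = 10^6 \cdot \frac{c_{is} + q}{\sum_j (c_{js} + q)},
  \qquad q = 0.5 \text{ by default.}$$

The depletion fold change of shRNA *i* between baseline *b* and follow-up
*f* is $\mathrm{fc}_i = \tilde c_{ib} / \tilde c_{if}$, so values above 1
mean depletion. The pseudocount keeps the ratio finite for fully depleted
shRNAs -- the expected behaviour of constructs against strong essentials --
and 0.5 is small enough to leave well-measured shRNAs essentially
untouched at screen-scale depths.

A gene's score is the **second-largest** fold change among its five or six
shRNAs: every scoring shRNA is therefore backed by a second, independent
construct with an even larger depletion, which guards the ranking against
single-shRNA off-target artifacts. Genes are ranked by descending score;
ties are broken lexicographically by gene symbol (and flagged), which
makes the ranking a deterministic total order on every platform. Only
reliable genes are ranked; auxiliary targets are carried through counting
but reported separately.

Hit calling takes the top `ceiling(fraction * n)` genes (default fraction
0.01). Genes specific to one setting are the intersection of that
setting's replicate top sets minus the union of every other setting's top
sets -- the set algebra that isolates, for example, dependencies that only
appear under a microenvironment-mimicking medium.

No p-value is attached to the ranking: the procedure ranks, it does not
test, and any probabilistic scoring model (MAGeCK/BAGEL-style) is out of
scope by design.

# The screen simulator

The simulator generates data with exactly the statistical structure the
analysis assumes, so recovery tests are meaningful end to end.

**Library.** `generateLibrary()` allocates five shRNAs per reliable gene
and distributes the remaining reliable allocation as sixth shRNAs to a
seeded random subset of genes; constructs beyond the reliable allocation
go to auxiliary targets (`AUX0001`, ...). Barcodes (default 18 nt) are
drawn uniformly from the code of sequences whose GF(4) base-sum is zero:
any two such sequences differ in at least two positions, so a
single-substitution read can never be exactly one mismatch from two
library barcodes at once. The capacity of that code, $4^{L-1}$, meets the
Singleton bound for distance-2 codes of length $L$, so the feasibility
check is tight rather than an artifact of the construction. Ambiguity
handling in the quantifier remains testable through hand-built adversarial
designs with barcodes at distance 2.

**Baseline representation.** Relative abundances are drawn from a
symmetric Dirichlet with concentration `1/dispersion` (default dispersion
0.5, i.e. concentration 2). This gives every shRNA positive abundance --
matching the observed recovery of essentially all barcodes in real
screens -- with a moderate right-skewed spread typical of plasmid pools;
`dispersion -> 0` approaches the uniform profile.

**Selection.** Abundances evolve deterministically and exponentially:
$a_i \propto a_i \exp(-r_i \cdot \text{days})$, renormalized. The rate
$r_i$ is the sum of two components:

* a planted essentiality coefficient $s_i > 0$ drawn from a normal
  (mean 0.5/day, sd 0.2/day, truncated at zero) on
  `ceiling(effectiveFraction * n)` of each essential gene's shRNAs
  (default 0.8, reflecting that not every hairpin knocks its target down
  effectively), applied either in every arm (`essential_all`) or only in
  a named arm (`essential_condition:<name>`); and
* a zero-mean **background** rate per shRNA (default sd 0.03/day) shared
  across replicates.

The background term deserves its own justification. shRNAs are not
biologically inert even when their target is dispensable: knockdown
burden, partial off-target silencing and integration effects give every
construct a small, reproducible fitness effect. Without it, the only
shared signal across replicates would be the few percent of shRNAs
targeting planted essentials, and the fold-change correlation between
replicates -- computed over *all* shRNAs -- would be near zero by rank
arithmetic no matter how clean the counting, which is qualitatively wrong:
real replicate screens show strongly correlated fold-change profiles. A
1-sigma background of 0.03/day integrates to about +/-30% over nine days,
small relative to planted effects (a mean-strength essential depletes
~90-fold) but large relative to counting noise at 500x coverage (~6% per
sample), reproducing the observed regime "replicates share the biology,
not the noise". The background lives in its own slot of `EffectMap`, so
the invariant that *neutral genes have essentiality coefficient zero*
holds exactly; set `backgroundSd = 0` for a perfectly exchangeable null.

**Sequencing.** Each sample draws reads multinomially from its abundance
profile. In FASTQ mode (`emitReads = TRUE`), each read is a fixed 5'
flank (20 nt), the barcode, and a 3' flank, with i.i.d. per-base
substitutions at `errorRate` (default 0.005; amplicon sequencing on
short-read platforms is substitution-dominated, so indels are not
modelled) and constant quality. In the default counts mode the FASTQ round
trip is skipped: reads whose barcode would survive intact (probability
$(1-e)^L$) are sampled directly into counts. Counts mode is what makes
multi-seed recovery studies cheap; the FASTQ path is exercised separately
at the million-read scale, where the quantifier must reproduce the
simulator's internal tally *exactly* at zero error rate.

**Replication and metadata.** Each replicate draws an independent baseline
shared by all of its arms (one pool, split after transduction), and a
transduction efficiency uniform in `teRange` (default `[0.10, 0.40]`),
recorded as metadata only -- it gates QC, not counts. The QC rule retains
a sample iff its efficiency lies in the closed window `[0.10, 0.40]`:
above 40% multiple integrations per cell are likely, below 10% library
representation collapses. Baselines are always retained.

The simulator does not model PCR amplification bias, cell-division
stochasticity, positive selection, puromycin kinetics, or time-varying
arm compositions (a medium switch mid-course is represented only as a
single arm label). Passing recovery tests on simulated screens therefore
demonstrates the statistical machinery, not robustness to amplification
artifacts or batch structure in real data.

# Barcode quantification

The quantifier locates the barcode at a fixed offset in each read (the
amplicon protocol fixes its position; no sliding-window search), looks it
up exactly, and -- at `maxMismatch = 1` -- falls back to a precomputed
Hamming-distance-1 neighborhood. A read equidistant from two barcodes is
discarded as ambiguous rather than fractionally assigned: conservative and
order-independent. Reads failing the length check are unassigned, never
truncated-matched. Every file satisfies the conservation identity
`total = assigned + ambiguous + unassigned`, and assignment under
1-mismatch tolerance can only gain reads relative to exact matching.

# The median-effect model and combination index

Dose-response analysis uses the median-effect equation
$\mathrm{fa}/\mathrm{fu} = (D/D_m)^m$ with fraction affected
$\mathrm{fa} = 1 - \text{viability}$ and $\mathrm{fu} = 1 - \mathrm{fa}$.
It is fitted by ordinary least squares of $\log_{10}(\mathrm{fa}/\mathrm{fu})$
on $\log_{10} D$; the slope is $m$, $D_m = 10^{-\beta_0/m}$, and the
correlation coefficient of the linearised fit is reported as quality.
IC50 is $D_m$ by definition under this model -- one parametric family
serves both potency and synergy, and no separate 4-parameter logistic is
fitted. Observed fractions are clamped into `[0.005, 0.995]` because the
logit diverges at the boundaries; zero-dose wells define the control
signal and never enter the fit (log of zero dose is undefined).

The combination index at observed effect level fa is the two-term
(mutually exclusive, Loewe-type) form
$$\mathrm{CI} = \frac{d_1}{D_{x,1}(\mathrm{fa})} +
               \frac{d_2}{D_{x,2}(\mathrm{fa})},$$
with $D_{x,i}$ from each drug's own fit. This is the conventional default
form and satisfies two exact identities used as tests: a drug combined
with itself at half-equivalent doses gives CI = 1, and a single agent at
its equivalent dose gives CI = 1. CI decreases strictly as the observed
combination effect grows at fixed doses. Classification uses the standard
bands (CI in [0.3, 0.7) "synergism", [0.7, 0.85) "moderate synergism",
[0.90, 1.10] "nearly additive", and so on), with the closed upper boundary
on the additive band so CI = 1.10 is not called antagonistic. Explicit
`(dose1, dose2, fa)` triples are accepted, which covers both
constant-ratio and non-constant-ratio designs.

# Differential-expression post-processing

Two small, rule-exact operations support downstream enrichment analysis
of external DE results. The retention filter keeps a gene iff
`p < 0.05` **and** `padj < 0.05` **and** `|log2FC| > 1`, all strict, so
boundary values are excluded; a missing adjusted p (as produced by
independent filtering in standard DE tools) fails the filter silently and
is counted in the report, since no principled rescue exists. The
pre-ranking metric is $-\log_{10}(p) \cdot \mathrm{sign}(\log_2 FC)$ with
$\mathrm{sign}(0) = 0$ and $p = 0$ clamped to the smallest positive
double; output is sorted by descending metric with ties broken by gene
symbol. Both thresholds are exposed as parameters because the conjunction
"padj and p < 0.05" does not pin the adjusted threshold independently;
0.05/0.05 is the default reading.

# Numerical and design choices

* **Fold-change orientation.** Depletion is expressed baseline/follow-up
  (>1 = depleted) so "second-largest fold change" literally selects the
  second-most-depleted construct; the alternative orientation would
  invert the quantile.
* **Seeding.** Every stochastic function takes a `seed` and restores the
  caller's RNG state; equal arguments and seed give bit-identical output,
  including FASTQ bytes and pipeline manifests.
* **Pipeline outputs** are plain TSV/JSON files with an md5 manifest --
  inspectable, diffable, and checkable for tampering; logs carry no
  timestamps so reruns are byte-identical.
* **Degenerate inputs.** All-zero count columns, samples missing
  transduction efficiencies, genes with fewer than two measured shRNAs,
  non-positive median-effect slopes and infeasible library allocations
  are explicit errors or flagged fits, never silent.

# Scales used by the test suite

The packaged checks run at deliberately reduced but structurally faithful
scales, chosen to exercise every property with comfortable margins: the
quantifier/simulator agreement at 1,000 barcodes x 10^6 reads; the
second-best statistic against a brute-force oracle on 1,000 random
fixtures of 100 genes; planted-essential recovery on 2,000 genes x 5
shRNAs at 5% essentials, 500x coverage, duplicate replicates, five seeds
(top-5% sensitivity and replicate Spearman are both comfortably above 0.9
and 0.7 respectively); and condition-specific recovery on 1,000 genes
with three arm-specific essentials, mirroring the three-gene example that
motivates the set algebra.

# Known limitations

The simulator's noise model is multinomial sampling plus substitution
errors; it cannot certify robustness to PCR jackpotting, GC bias, or
index hopping. The essentiality ranking is a pure order statistic --
genes with many weakly effective shRNAs are penalised by construction,
and no uncertainty accompanies ranks. The median-effect fit weights all
dose points equally on the logit scale, which up-weights extreme-effect
wells; heteroscedastic weighting is deliberately not implemented to keep
the fit identical to the conventional linearised procedure.
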