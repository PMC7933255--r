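---
title: "Inferring whole-genome doubling and LOH sculpting from allele-specific copy number"
author: "WGDinfer authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring whole-genome doubling and LOH sculpting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(WGDinfer)
```

# The scientific problem

Late-stage tumours are frequently hyperploid, and two different histories
can produce that state: gradual arm-level aneuploidy (stochastic gains
and losses of chromosome arms) or a single whole-genome doubling (WGD)
followed by further arm-level change. Distinguishing the two from a
static copy-number profile matters because a doubled genome tolerates
subsequent deletions — including large tracts of loss of heterozygosity
(LOH) — that a diploid genome cannot survive. This package implements a
generative model that makes the distinction quantitative, together with
the downstream accounting of what acquired LOH removes from the genome:
lost mutations, and lost predicted neoantigens.

# The branching-process model of arm copy number

The evolutionary history of a tumour genome is divided into $N$ arbitrary
time periods. In each period, every extant copy of every chromosome arm
independently

* is deleted with probability $\alpha$,
* is retained unchanged with probability $\beta$, or
* is duplicated with probability $\gamma$,

with $\alpha + \beta + \gamma = 1$. Each allele of each arm starts from a
single copy, so an arm is described by two independent single-copy
lineages. The WGD variant inserts one synchronous doubling of every
extant copy after $M$ of the $N$ periods ($1 \le M \le N$).

The per-copy offspring probability generating function (pgf) is
$f(s) = \alpha + \beta s + \gamma s^2$. The copy-number distribution of
one allele after $N$ periods is the $N$-fold composition
$F_N = f \circ \cdots \circ f$, and with a doubling after period $M$ it
is

$$G(s) = F_M\!\left(\left[F_{N-M}(s)\right]^2\right),$$

because every copy present at time $M$ leaves two daughters that then
evolve independently for the remaining $N - M$ periods.
`copyNumberPMF()` evaluates these compositions by exact polynomial
arithmetic on coefficient vectors rather than symbolic algebra: for the
default $N = 6$ the polynomial degree is at most $2^{N+1} = 128$ per
allele, so double-precision composition is exact to roughly $10^{-12}$
and needs no computer-algebra dependency. The support bound doubles with
WGD: with $N = 6$ the model represents total (two-allele) arm copy
numbers up to $2 \times 2^{6+1} = 256$ (`maxTotalCopyNumber(6, TRUE)`).

```{r pmf}
p <- copyNumberPMF(symmetricParams(0.1, nPeriods = 2))
round(pmfProbs(p), 4)
```

## Likelihood and model selection

The observation unit is the per-allele arm copy number: each determined
arm contributes $\log P(\text{major}) + \log P(\text{minor})$, treating
the two alleles as independent lineages. This choice (rather than total
copy number, which is available behind `obsUnit = "total"`) is
consistent with the model's two-allele capacity bound; the ordering
multiplicity of the observed (major, minor) pair is a data-dependent
constant that cancels from every model comparison. Whole-chromosome
events are deliberately modelled as two independent arm events — an
acknowledged simplification shared with the model's other assumptions
(no focal amplifications, no complex events, event order resolved only
to the $N$ periods).

`fitBranchingModel()` maximises the likelihood under the symmetric
constraint $\alpha = \gamma = r$ by default: a deterministic grid over
$r \in [0, 0.5]$ (step 0.005) with golden-section refinement to
$10^{-5}$, and for the WGD model an exhaustive maximisation over
$M \in \{1, \dots, N\}$. Because no stochastic optimiser is involved,
fits are reproducible bit-for-bit. The unconstrained mode searches
$(\alpha, \gamma)$ on a 2-D grid with Nelder–Mead refinement.

Model comparison uses the Akaike Information Criterion,
$\mathrm{AIC} = 2k - 2\log L$. In general the WGD model has 3 free
parameters ($\alpha$, $\gamma$, $M$) and the non-WGD model 2; under the
symmetric constraint these become 2 and 1. Applying the general counting
to constrained fits (`generalAIC()`) offsets both AIC values by the same
constant $+2$, so

$$\Delta \mathrm{AIC} = \mathrm{AIC}_{\text{non-WGD}} -
  \mathrm{AIC}_{\text{WGD}}$$

is unchanged; $\Delta \mathrm{AIC} > 0$ supports genome doubling, and
ties resolve to the more parsimonious non-WGD model. $M = 0$ is excluded
from the WGD search because a doubling before any evolution is
indistinguishable from a changed starting state.

Numerical points worth recording: log-likelihoods of observations with
zero probability are $-\infty$ and are screened with a large-negative
sentinel during the grid search so they never reach the refiner; an
observed copy number beyond the model support raises an explicit error
advising a larger $N$ (a warning is issued for $N > 8$, where the
polynomial degree $2^{N+1}$ makes fits slow); weight ties in the
arm-level modal summary of `summarizeArms()` break deterministically
towards the smaller copy-number pair, and an arm whose determined
coverage is below 50% of its length is left undetermined.

```{r fit}
prof <- simulateArmProfile(symmetricParams(0.05, nPeriods = 6,
                                           wgdTime = 3L),
                           nArms = 39, seed = 7)
sel <- selectModel(fitBranchingModel(prof, withWGD = TRUE),
                   fitBranchingModel(prof, withWGD = FALSE))
sel
```

# Allelic imbalance and acquired LOH

Segments are classified from their (major, minor) integer copy numbers:
*balanced* when the parental copy numbers are equal, *allelic imbalance
without LOH* when they differ and both are positive, and *LOH* when the
minor copy number is zero. Homozygous deletion (0, 0) is counted as LOH,
since loss of heterozygosity is implied by a zero minor allele. Genome
not covered by determined segments is reported as *undetermined* rather
than silently dropped, and mean ploidy is the length-weighted mean total
copy number over determined segments only. Integer copy-number input is
required; subclonal (non-integer) states are out of scope.

Acquired LOH between an early and a late sample of the same patient is
the interval intersection of the late sample's LOH regions with the
regions where the early sample demonstrably retained heterozygosity;
early-undetermined regions are excluded, which is conservative.
Overlapping acquired-LOH intervals from different late samples are
merged into patient-level *events* by single-linkage closure over
$\ge 1$ bp overlaps (abutting intervals stay separate). Lost mutations —
present early, absent late — are attributed to LOH by position, and
their early-disease cancer-cell fractions are reported descriptively by
group (medians, no hypothesis test).

Mirrored allelic imbalance — the same region imbalanced in two samples
with opposite parental alleles favoured — is scored from shared
heterozygous SNPs as the negated Pearson correlation of the centred
B-allele frequencies. The call requires at least 10 shared SNPs, both
samples imbalanced (mean $|\mathrm{BAF} - 0.5| > 0.1$) and a score above
0.5. Both thresholds are this package's own tuning choices, exposed as
arguments; the phenomenon itself is qualitative.

# LOH sculpting statistics

If LOH provides a fitness advantage by deleting deleterious
non-synonymous mutations, regions with more non-synonymous mutations
than expected should be lost preferentially. The expected count is
derived from the synonymous count: `codonMutability()` enumerates, for
every sense codon of the standard genetic code, its 9 single-nucleotide
neighbours, classifies each change (stop-gains count as non-synonymous,
a deliberate choice the code documents), and weights by codon usage
under a uniform substitution model over the neighbours. With
$p_{ns}$ the resulting probability that a random coding change is
non-synonymous, a segment with $n_{syn}$ synonymous mutations expects
$n_{syn} \cdot p_{ns} / p_{s}$ non-synonymous ones. The bundled human
codon usage table gives $p_{ns} \approx 0.77$. A trinucleotide-spectrum
substitution model would refine this and can be supplied through a
custom usage table; the uniform model is the default.

Only acquired-LOH segments longer than 10 Mb enter the aggregate test
(strict inequality), because short segments are enriched for
copy-number over-segmentation artefacts. The aggregate test counts
segments whose observed non-synonymous count exceeds expectation. A
segment with $sz$ mutations exceeds exactly when
$n_{nonsyn} > sz \cdot p_{ns}$, so the default null probability is the
mean over segments of the exact exceedance probability
$P(\mathrm{Bin}(sz, p_{ns}) > sz \cdot p_{ns})$ — a quantity that
depends only on the segment's mutation count, keeping the null
independent of the observed split (plugging the observed synonymous
count into the null instead couples the null to the data and destroys
the test's calibration; the package's tests verify the p-values are
uniform under null simulations). A fixed null of 0.5 is available via
`null = "half"`, and the p-value is the exact binomial upper tail in
either mode. Note that 0.5 is not the exceedance probability of a
discrete binomial count, which is why `per_segment` is the default.

Neoantigen losses are counted per LOH event: a predicted neoantigenic
mutation is lost to an event when its position lies inside the event and
it is absent from every member late sample; per-event counts and the
deduplicated patient total are reported, optionally restricted to
neoantigens in expressed genes. Mutual exclusivity of per-event
neo-antigenicity and non-synonymous load is classified by median splits
(ties to low, the package's choice where no threshold is published) and
tested with a two-sided unconditional exact test: for every table with
the observed column totals the Wald statistic is computed, and the
p-value is the maximum over a nuisance success probability grid
($\pi = 0.001, \dots, 0.999$) of the probability of tables at least as
extreme. The 999-point grid changes p-values only in the third decimal
relative to coarser grids at these table sizes. Binding ranks follow the
NetMHC percentile-rank convention (strong/weak thresholds 0.5 and 2.0);
"expressed" is membership in a configured gene list.

# The synthetic-cohort generator

Real multi-region cohorts of this kind are controlled-access, so the
package ships a generator that emulates their structure end to end:
early samples drawn from the branching process with few elapsed periods
(hence near-diploid), late samples with the full $N = 6$ periods and,
when configured, a WGD draw; acquired-LOH intervals planted by forcing
the minor allele to zero on chosen heterozygous arms of every late
sample; mutations with a planted synonymous/non-synonymous split and
presence flags; neoantigen records with planted per-event loss counts;
and BAF tracks in which SNP phase is a patient-level germline property,
so samples losing the same haplotype correlate and mirrored samples
anti-correlate.

Default conditions are the regime the inference operates in:
$r = 0.05$, $N = 6$, 39 autosomal arms (hg19 boundaries bundled at
cytogenetic-band resolution; acrocentric short arms 13p, 14p, 15p, 21p,
22p and the sex chromosomes excluded from modelling), 2 early and 3
late samples, a 25% acquired-LOH target, 75% non-synonymous mutations,
20% of mutations lost with 80% of losses inside LOH, and Gaussian BAF
noise (sd 0.03, truncated to $[0,1]$). Segment boundaries are jittered
inward by up to 1 Mb to exercise interval logic. Every planted quantity
is recorded in a ground-truth ledger computed at generation time with
plain max-of-starts/min-of-ends arithmetic, so recovery checks do not
reuse the package's own interval machinery. Each patient derives its own
RNG stream from the master seed, making bundles reproducible and stable
under adding patients. Setting `rate = 0`, `boundaryJitter = 0` and
`bafNoiseSd = 0` gives a noise-free mode in which every pipeline stage
recovers its planted quantity exactly.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data — includes subclonal and non-integer
copy number, focal and complex structural events, mutational-signature
structure in the mutation spectra, purity/segmentation error in the
inputs, and read-level noise. The generator validates its outputs
against the same readers real data would pass through.

# Problem sizes and determinism

The shipped test-suite experiments use the sizes the methods are
designed around: exact pgf-vs-enumeration agreement up to $N = 3$, a
$10^5$-lineage forward simulation against the $N = 6$ pmf
(total-variation distance below 0.01), 100 simulated 39-arm profiles per
condition for model-selection calibration (at least 90% correct calls in
both directions), 200 replicates for rate recovery (mean absolute error
below 0.02 at $r = 0.05$), and 500 replicate cohorts of 194 segments
for the calibration of the binomial excess test. Grid fits cache the
gridded pmfs per $(N, \text{step})$, which makes repeated fits across a
cohort cheap. All randomised checks run under fixed seeds; all
optimisers are deterministic.

# Limitations

The model shares the assumptions stated above (independent arms, single
WGD, no focal events); the likelihood's observation unit is an
inference, since the source analyses do not state one; arm boundaries
are bundled at band resolution for hg19 only; and the Barnard test's
Wald statistic is one of several reasonable choices for unconditional
2×2 testing — its p-values are exact in size but not guaranteed to
dominate Fisher's on every individual table.
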