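---
title: "Runs of homozygosity, genomic inbreeding and ROH islands: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Runs of homozygosity, genomic inbreeding and ROH islands: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscape)
```

## The problem

In managed animal populations — horse breeds are the motivating case —
inbreeding leaves a direct molecular footprint: long stretches of the genome
where an individual carries two copies of the same ancestral haplotype and is
therefore homozygous at every assayed SNP. These *runs of homozygosity* (ROH)
support two complementary analyses:

* **Individual inbreeding.** The fraction of the SNP-covered genome inside an
  individual's ROH is the genomic inbreeding coefficient
  $F_{ROH} = \sum L_{ROH} / L_{genome}$. Because recombination shortens
  ancestral haplotypes by roughly half each generation, the *length* of a run
  dates the inbreeding event that produced it, and $F_{ROH}$ can be split
  into recent and ancestral components.
* **Population selection signatures.** Genomic regions where many individuals
  independently carry ROH (*ROH islands*) mark loci swept toward homozygosity
  by selection rather than by chance.

`rohscape` implements this full pipeline — PLINK text input, quality control,
sliding-window ROH detection, $F_{ROH}$ decomposition, randomization-based
island calling, and gene annotation — together with a synthetic-population
generator that supplies ground truth for validating every stage, since
real datasets of this kind are typically confidential.

## Quality control

Raw array genotypes pass three filters: SNPs kept when genotyped in **at
least** 90% of samples (inclusive comparator), individuals kept when **more
than** 95% of their SNPs are genotyped (strict comparator), and markers
restricted to the 31 equine autosomes. The two comparators deliberately
differ — they mirror the asymmetric phrasing conventional in array QC — and
both thresholds are configurable (`qc_thresholds()`). The filter order
(SNP, then individual, then autosome restriction) is itself a convention,
not a mathematical necessity: the order is configurable and every step is
logged in the `qc_log` attribute so a run is auditable. Sequential
call-rate filters are not idempotent in pathological cases (removing many
low-call individuals can re-rank SNP call rates); with realistic
missingness structure a second application is a no-op, which the test suite
checks.

Heterozygosity uses the standard estimators: per-SNP observed $H_o$
(heterozygote fraction of non-missing calls) and expected $H_e = 2p(1-p)$
from the alternate-allele frequency $p$; chromosome and population means are
unweighted over SNPs. Hardy–Weinberg equilibrium is tested exactly, by full
enumeration of heterozygote counts conditional on the allele counts (the
distribution is built with the stable ratio recurrence; a mid-p variant is
available, and monomorphic SNPs return $p = 1$ by convention). An exact test
was preferred over the chi-square approximation because it is reproducible
to machine precision and trivially testable against an independent
log-factorial enumeration.

## How many SNPs must a run contain?

Chance runs of homozygosity become common when windows are short relative to
heterozygosity. The minimum SNP count is set by the false-positive control

$$ L = \frac{\ln\!\big(\alpha / (n_s\, n_i)\big)}{\ln(1 - het)} $$

where $\alpha$ is the tolerated fraction of false-positive ROH (default
0.05), $n_s$ the SNPs per individual, $n_i$ the number of individuals and
$het$ the mean heterozygosity. Both logarithms are negative, so $L > 0$; the
value is rounded to the nearest integer (half away from zero). At the
operating point of a 64,203-SNP, 506-individual equine panel with
$het = 0.323$, $L = 52$, which is the package default for both the window
size and the minimum SNPs per run.

## Sliding-window ROH detection

`detect_roh()` scans each individual × chromosome:

1. every window of $w$ consecutive SNPs (default 52) is scored homozygous
   iff it contains at most 0 heterozygous and at most 1 missing call — a
   missing call never counts as heterozygous, it only consumes the missing
   budget;
2. each SNP's support is the fraction of homozygous windows among the
   windows *actually covering it* — windows are fully contained in the
   chromosome, so SNPs near chromosome ends are covered by fewer windows
   and support is normalized accordingly; the SNP is in-run when support
   $\ge$ 0.05 (inclusive, matching the PLINK convention);
3. maximal stretches of consecutive in-run SNPs are split wherever adjacent
   SNPs lie more than 1 Mb apart;
4. surviving stretches are reported iff they contain $\ge$ 52 SNPs and span
   $\ge$ 1 Mb, with length defined as `end_bp - start_bp` (the convention
   that makes reported interval arithmetic exact).

Chromosomes with fewer SNPs than one window yield no calls and are listed in
an attribute. Run boundaries are SNP positions; a boundary SNP may be
missing (never heterozygous, given the zero-het window budget), matching the
behaviour of the sliding-window tools this scan follows.

**The density screen.** A minimum SNPs-per-bp density filter
(`min_density`, comparator $\ge$, evaluated after gap splitting) is
implemented but **disabled by default**. The nominal "1 SNP per 10 kb"
setting quoted for such screens cannot be binding on a medium-density
array: at ~1 SNP per 35 kb mean spacing, every genuine run would fail it,
yet tens of thousands of ROH are routinely reported from exactly such data.
The screen is therefore treated as an optional guard for heterogeneous
marker panels rather than part of the standard operating point.

The scanner is validated by exhaustive equivalence with a brute-force oracle
(explicit enumeration of all windows, supports and filters) on randomized
instances of up to 200 SNPs × 5 individuals with randomized parameters, and
by property tests: tightening `min_snps_in_run` or `min_length_bp` never
adds segments, relabelling the two homozygote classes never changes output,
and every reported segment satisfies every interval invariant.

## Dating inbreeding: the generational decomposition

The expected length of an autozygous tract whose common ancestor lived $g$
generations ago is $100/(2g)$ cM; at the 1 cM ≈ 1 Mb approximation this is
used as a physical length threshold, **truncated** (not rounded) to one
decimal: 16.6 Mb ($g=3$), 8.3 Mb ($g=6$), 5.5 Mb ($g=9$). Truncation is
deliberate — rounding would give 5.6 at $g = 9$ — and the comparator is
$\ge$ applied to `length_bp` against threshold × 10⁶ exactly.

`compute_froh()` reports, per individual and per scope (genome or single
chromosome, each with its own covered-length denominator):
$F_{ROH}$, $F_{ROH3G} \le F_{ROH6G} \le F_{ROH9G} \le F_{ROH}$ (nesting is
asserted in tests), and the ancestral remainder
$F_{ROHANC} = F_{ROH} - F_{ROH9G}$. When no genome specification is given,
covered length defaults to the per-chromosome span from first to last SNP —
the same end-minus-start convention as segment lengths — so that an
individual whose ROH tile a whole chromosome reaches $F_{ROH} = 1$ there.
`summarize_froh()` prints cohort means ± SD and each component's integer
percent share of mean $F_{ROH}$ (rounded half up, the presentation rule
used in the source literature's tables).

## ROH islands

`snp_incidence()` counts, per SNP, the individuals whose ROH cover it.
Significance uses the randomization null that ROH are uniformly distributed:
the observed incidence $c$ on a chromosome with maximum incidence $M$ is
compared with draws uniform on the integers $\{0, \dots, M\}$ (inclusive on
both ends). The package reports the upper tail

$$ p = P(r \ge c) = \frac{M - c + 1}{M + 1}, $$

so small $p$ marks enrichment and ties count toward the tail, making the
closed form exact and conservative. The verbal description of this test in
the source literature ("the proportion of instances where the actual
incidence exceeded the randomized one") taken literally yields $p \approx 1$
for enriched SNPs, contradicting the same source's $p < 0.01$ significance
rule; the literal reading remains available as `tail = "literal"`. The
closed form is the default; the Monte-Carlo mode (default 10⁶ draws, one
seeded stream per chromosome in increasing order, so results are
reproducible) is retained for fidelity and is tested to converge to the
closed form within 4 binomial standard deviations.

Islands are maximal stretches of consecutive SNPs with ROH frequency
$\ge 50\%$ of individuals, reported when they contain at least three SNPs
with $p < 0.01$. Two ambiguities were resolved as follows: the frequency
rule applies to *every* SNP of the island (not just a seed segment), and
`mean_p` averages all island SNPs (not only significant ones). Boundaries
are SNP positions and `length_bp = end_bp - start_bp`, the convention under
which published island tables are internally exact. Note an arithmetic
consequence of the null: $p < 0.01$ requires $M \ge 100$, i.e. island
detection at this significance level needs cohorts of roughly 170+
individuals at a 60% carrier frequency — island analyses are
population-scale by construction.

Annotation (`load_genes()` / `annotate_islands()`) reads BED (0-based
half-open, converted on input) or GFF3 (features filtered to type `gene`),
normalizes chromosome labels (`"3"`, `"chr3"`, `"ECA3"`), and reports a gene
for an island on ≥ 1 bp overlap of closed intervals; full containment is
available as `mode = "within"`. Interval intersection is delegated to
`GenomicRanges`; tests verify it against an all-pairs loop.

## The synthetic-population generator

`simulate_population()` provides ground truth the real data cannot:

* **Background**: per-SNP alternate-allele frequencies from a symmetric
  $\mathrm{Beta}(a, a)$ with $a = het/(1 - 2\,het)$ — the closed-form
  solution of $E[2p(1-p)] = het$ — and genotypes drawn independently under
  Hardy–Weinberg. Targets above 0.5 are rejected as infeasible.
* **Planted tracts**: per individual, Poisson counts in four length classes
  (<5.5, 5.5–8.3, 8.3–16.6, ≥16.6 Mb; uniform lengths within class) are
  placed without within-individual overlap and overwritten with the locally
  major homozygote. Default class rates (26.7, 4.4, 3.2, 0.65 per Gb per
  individual) reproduce a published equine landscape: ~35 ROH per Gb per
  individual in ~76/13/9/2 class proportions and mean coverage near 0.15.
* **Islands**: a configured interval is overwritten in a chosen fraction of
  individuals (the carriers).
* **Noise**: optional heterozygous "genotyping errors" inside tracts
  exercise the window budgets; missingness (default 0.5%) is applied last.

Defaults emulate the study conditions at desk scale: 28 SNPs/Mb (the density
of a ~64k array on a ~2.3 Gb genome), heterozygosity 0.32, 50 individuals on
five 100-Mb chromosomes. The generator is deliberately free of linkage
disequilibrium, recombination maps and pedigree structure: every statistic
in scope depends only on hom/het/missing run structure, and independence
keeps the false-positive probability of a chance 52-SNP homozygous window
analyzable (about $(1-het)^{52} \approx 2 \times 10^{-9}$ at $het = 0.32$,
which the background-only test confirms as zero detected runs). Passing
tests on these simulations therefore validates the *detection and
bookkeeping machinery*, not robustness to LD structure, array ascertainment
bias or clustered missingness in real data.

The truth set records every planted interval both as configured and
*snapped to the SNP grid* (first/last covered SNP), and the per-individual
planted coverage `q` uses the snapped, overlap-merged intervals over the
SNP-covered genome length — the same conventions as the detector — so that
recovery error measures the method, not grid discretization. Recovery tests
plant the full default spectrum and require mean
$|F_{ROH} - q| \le 0.01$ at $n = 50$; the residual ~0.005–0.009 bias is the
detection floor (tracts shorter than ~2 Mb hold fewer than 52 SNPs at 28
SNPs/Mb and are invisible by design — the price of the false-positive
control). Island recall is tested at $n = 506$ with a 60% carrier island on
a 3 × 100 Mb genome over 20 seeds (the cohort size the significance
arithmetic above requires), demanding recall in ≥ 19/20 seeds with zero
false islands.

## Numerical and interface choices

* Rounding: $L$ rounds half away from zero; generation thresholds truncate
  to one decimal; percent shares round half up. Each rule is chosen to
  reproduce the published values it feeds.
* Degenerate inputs: SNPs with zero non-missing calls are excluded from
  means with a warning; monomorphic SNPs have $H_e = 0$ and HWE $p = 1$;
  chromosomes with $M = 0$ incidence get $p = 1$ everywhere; cohorts
  emptied by QC raise an explicit error.
* Coordinates are 1-based inclusive everywhere internally (the MAP
  convention); BED input and output convert explicitly.
* Genotypes are phase-free and allele-order-free; every statistic is
  invariant to swapping the two homozygote labels (tested).
* `run_pipeline()` writes nine report tables plus a JSON manifest recording
  every parameter, comparator and seed; outputs are pure functions of
  (input, config, seed), which the test suite checks by rerunning.

## Limitations

Real SNP-array data bring LD, ascertainment bias, genotyping artefacts and
non-uniform marker spacing that the generator does not model; absolute
$F_{ROH}$ levels are known to be sensitive to scan parameters, so
cross-study comparisons should fix the full parameter set, not just $L$.
The island null treats SNPs independently and uniformly; it calibrates
enrichment against chromosome-wide maxima rather than modelling local
recombination-rate variation. Gene-function interpretation (ontology
enrichment, literature triage) is out of scope: the annotation stops at
interval overlap.
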