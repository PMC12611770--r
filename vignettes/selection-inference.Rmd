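---
title: "Depth-aware selection inference for duplex sequencing: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-aware selection inference for duplex sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models and their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic cohort generator does and does not
emulate, the numerical conventions, and the design choices that were
genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The neutral opportunity model

All selection statistics compare observed mutation counts with a neutral
expectation built from *trinucleotide mutational opportunity*. A
substitution is assigned to one of 96 pyrimidine-central channels (mutated
base plus flanking bases, strand-collapsed). Neutral per-channel rates are
estimated from mutation classes assumed selection-free — synonymous and
non-coding panel mutations by default, with promoter whitelist positions
excluded — as counts divided by depth-weighted opportunity, in mutations per
site-genome:

$$\hat r_c = \frac{N_c}{O_c}, \qquad
  O_c = \sum_{(s,a)\,\in\,\text{neutral},\ \text{chan}(s,a)=c} d(s),$$

where $d(s)$ is the duplex depth at site $s$ in haploid genomes. The
expected count of consequence class $k$ in gene $g$ is

$$E_{g,k} = \sum_{(s,a):\ \text{cons}(s,a)=k,\ s\in g} \hat r_{\text{chan}(s,a)}\, d(s).$$

Assumptions: (i) within a channel, the neutral mutation rate per sequenced
genome does not depend on the site's consequence — the basis of every
dN/dS-style method; (ii) counts of distinct detected mutations are
approximately Poisson with mean rate × depth, which holds when clones are
small relative to the sequenced genome count (the ultradeep duplex regime);
(iii) the estimated expectation is treated as fixed when testing. The
calibration consequences of (iii) are checked by the neutral-cohort
properties in the test suite rather than assumed.

Observed counts follow the Poisson contract: dN/dS is $N/E$, the 95%
interval is the exact Garwood interval on the count divided by $E$, the
two-sided p-value doubles the smaller Poisson tail (capped at 1), and the
driver excess is $\max(N - E, 0)$. Uncertainty in $E$ itself is ignored at
these defaults; the neutral-calibration property test quantifies the
consequences (type-I error within a binomial band of 5% under the study
conditions used there).

Truncating = nonsense + essential splice-site substitutions; frameshift
indels are tested separately with a leave-one-out background (the gene under
test never contributes to its own background rate) and an upper-tail Poisson
p-value, because enrichment is one-sided by construction. MNVs are annotated
with the worst constituent consequence and carried through catalogs, but are
excluded from dN/dS counts: the opportunity model covers single-base
substitutions.

### Promoter activation selection

Promoter substitutions are dichotomised by a whitelist of tumour-recurrent
positions (a property of the input file, not recomputed). The neutral scale
inside the promoter is calibrated so that the non-whitelist (site, alt)
pairs reproduce their observed count exactly; the whitelist expectation then
follows from relative channel rates and depth. This makes the activating
expectation robust to regional rate differences between the promoter and the
coding panel.

### Per-sample selection

Per-sample expectations reuse the cohort channel *shape* but calibrate the
*magnitude* per sample on that sample's own neutral mutation count (a
sample with twice the mutation burden gets twice the neutral expectation).
Entries with zero expectation are missing; a (gene, class) combination
enters downstream regressions only when computable for at least 80% of
samples. The boundary is sharp: 63/79 is ineligible, 64/79 eligible.

### Site, residue, exon and domain selection

The gene expectation is distributed over all possible substitutions in
proportion to channel rate × site depth, within each consequence stratum, so
unit expectations sum exactly to the gene expectation. Unit p-values are
upper Poisson tails on raw counts; the display score is
$\log_2((N + \varepsilon)/(E + \varepsilon))$ with $\varepsilon = 0.5$ only
stabilising the ratio for display. Benjamini–Hochberg correction is applied
within gene (residue tracks are reported per gene); a panel-wide family
would be the alternative and can be obtained by correcting the concatenated
tables. Units with zero expectation are suppressed and counted.

### Saturation kinetics

The theoretical curve is the Poisson-process form: a substitution with
neutral rate $r$ per site-genome is observed by cumulative depth $D$ with
probability $1 - e^{-rD}$; the curve is the mean over all possible
substitutions of the gene, evaluated on a 12-point log-spaced grid from
$10^3$ to the full cohort depth. The observed curve downsamples the catalog:
at thinning factor $f$, a mutation with $k = \text{round}(\text{VAF} \times
d)$ supporting molecules is retained when at least one supporting molecule
survives the depth subsample.

Two thinning forms are implemented. The default, `"molecule"`, subsamples
the mutation's own supporting molecules (Binomial($k$, $f$) ≥ 1): it is
exact at $f = 1$ (the catalog is reproduced) and linear in $f$ for
single-molecule variants, which makes the neutral-equivalence property
(observed ≈ theoretical under no selection) hold at every grid point. The
alternative, `"redraw"` (Binomial(round($f d$), VAF) ≥ 1), redraws support
from scratch and approximates an independent resequencing experiment at the
lower depth; its closed-form retention $1-(1-\text{VAF})^{fd}$ is what the
downsampling worked example checks. The two differ materially only for
variants near the single-molecule detection limit, where a redraw can lose a
mutation even without thinning.

### Clone fractions

The expected number of drivers of a gene in a sample is the half-up-rounded
missense excess plus the half-up-rounded truncating excess; the top
mutations by all-molecules VAF are selected, ties broken by ascending
genomic position (selection is deterministic under row shuffling). The
fraction of genomes carrying a driver is the inclusion–exclusion probability
under independence, computed in its numerically stable complement-product
form $P(G) = 1 - \prod_x (1 - p_x)$; equivalence with the alternating-sum
expansion is verified by brute force in the tests. CI-endpoint driver counts
reuse the same ranking and vary only the count. Cell fractions: two-hit
(default) cells = genomes; one-hit cells = min(1, 2 × genomes); hemizygous
male X cells = genomes.

### Covariate association

Responses (log dN/dS with a 0.05 offset, mutation densities per
depth-weighted megabase, activating promoter-mutation density) are regressed
on age (decades), sex, smoking (ever/never; unknown excluded wherever
smoking enters a model), alcohol, BMI (0–1 scaled) and chemotherapy, with a
donor random intercept absorbing the dome/trigone pairing. The two-step
design screens covariates univariately (p < 0.05) and confirms candidates in
the full multivariate model; BH q-values are computed per response family
(all screened terms of one response) and significance is called at
FDR < 0.2. For the promoter-activation density the age × smoking interaction
replaces the separate age and smoking terms. The log link for dN/dS
responses keeps multiplicative covariate effects additive; a raw-scale
response can be supplied directly. Boundary (singular) random-effect fits
are retained — they are valid ML fits with zero donor variance — whereas
optimizer failures are reported as non-converged and excluded from the FDR
family.

## The synthetic cohort generator

The generator is the ground-truth side of every property test. Its default
configuration emulates an ultradeep bladder-urothelium study: 45 donors, 34
of them with both dome and trigone samples (79 samples); a 111,876-bp panel
of 12 complete coding genes, 3 partial fragments and a 590-bp promoter
(65,086 bp coding, 46,790 bp non-coding); per-sample mean depth lognormal
with median 5,164 haploid genomes; a trinucleotide mixture of an APOBEC-like
profile, an ageing-like (CpG-transition) profile whose weight grows with
donor age, and a flat component; ~774 detected mutations per sample at
median depth under neutrality; gene × class selection multipliers (up to 20
on truncating classes, 0.3 on the purged fragment); male-specific
multipliers on the truncating selection of three genes; promoter whitelist
activation with an age × smoking dependence; and a frameshift/inframe indel
process with its own gene-level multipliers.

Mutations arise as **latent clones**: a clone has a cell fraction $w$ drawn
from a truncated Pareto law (exponent 2, range $2\times10^{-5}$ to 0.25) and
enters the catalog only when at least one of the $d$ sampled duplex
molecules carries it ($k \sim \text{Poisson}(wd)$, $k \ge 1$); its recorded
duplex VAF is the measured $k/d$ and the all-molecules VAF is measured on
2.5× as many molecules. Because the clone law reaches far below the
single-molecule detection limit, most detected mutations are
single-molecule — as in real duplex data — and detected counts grow
essentially linearly with depth, which makes the Poisson opportunity model,
the VAF law and the downsampling kinetics mutually coherent. Selection
multiplies the latent clone rate of protein-affecting classes; covariate and
donor-frailty modulation acts multiplicatively on the excess $(\omega - 1)$
so that $\omega = 1$ remains exactly neutral (purging selection,
$\omega < 1$, is kept fixed — excess modulation would drive rates
negative). The truth table records every injected parameter and the
per-sample expected detected counts.

What the generator does **not** emulate: sequencing artefacts and
consensus-calling errors (upstream of this package's scope), MNVs, copy
number or methylation second hits, X-chromosome ploidy differences
(depth files are taken at face value), multi-exon gene structure (one coding
block per gene, though the annotator supports multiple regions and partial
fragments with non-zero frame anchors), and real human sequence context
(genes are random non-stop codon sequences). Passing tests therefore
validate the statistical machinery under the stated generative model, not
robustness to artefact contamination.

Generator consequence labels are produced by an independent code path
(whole-CDS string translation) from the panel annotator (genomic codon
arithmetic); the test suite checks 100% agreement, and a third, brute-force
translator (via `seqinr`) checks the annotator on small genes.

## Numerical and convention choices

- Coordinates are 0-based half-open everywhere (BED native).
- Essential splice sites are the 2 intronic bases flanking each coding
  boundary; the window is a configurable argument of `build_panel()`.
- The spectrum pseudocount (default 0.5) is added to *empty channels only*;
  a global pseudocount measurably inflates total expectations and with it
  the neutral type-I rate. Set it to 0 for exact Poisson arithmetic.
- Sites with ambiguous reference context (N) are flagged and excluded from
  rate estimation and opportunity.
- Driver-count rounding is half-up (an excess of 2.5 selects 3), not
  banker's rounding.
- Depth is stored and used as haploid genomes per sample; no ploidy
  rescaling is applied to male X chromosomes.
- Stop-codon sites whose reference amino acid is `*` classify stop-loss
  substitutions as missense (protein-affecting, non-truncating).
- `fraction_genomes()` rejects VAFs outside (0, 1]; empty driver sets give 0.

## Problem sizes in the validation suite

The property suites run on scaled-down cohorts whose per-site,
per-sample mutation density matches the full-size default (774 mutations
per sample over 111,876 bp), so per-site recurrence behaviour is realistic
while runtimes stay in minutes: neutral calibration uses 20 cohorts of 45
donors with eight 1,101-bp genes and wide non-coding flanks (aggregate
expected counts per class ≥ 200); selection-coefficient recovery uses 50
cohorts of 18 donors with injected truncating ω ∈ {0.1, 2, 5, 10};
saturation direction checks use 12 cohorts of 45 donors; covariate-effect
recovery uses 25 cohorts of 45 donors with a +0.5 log-scale male effect on
one gene's truncating selection, each paired with a donor-level
label-permutation null. The recovery experiment is deliberately small: in
very large cohorts the exact-Poisson interval becomes narrower than the
small deflation of distinct-variant counts described below.

## Known limitations

- **Recurrent-variant collapsing.** Two independent clones carrying the same
  substitution in the same sample are indistinguishable and collapse into
  one catalog record with a summed VAF. Under strong selection at
  high-rate trinucleotide contexts this deflates distinct-mutation counts by
  a few percent relative to the event rate, so very precisely estimated
  dN/dS values sit slightly below the injected event-level ω. This is a
  property of any distinct-variant catalog, not of the estimator.
- **Detection-limit quantisation.** Measured VAFs are multiples of
  1/depth; clone fractions of single-molecule drivers are overestimated
  relative to their latent size, which limits clone-mass correlation in the
  tiny-clone regime. Clone-fraction estimation is accurate for clones well
  above the detection limit.
- **Expectation uncertainty.** Poisson tests condition on the estimated
  expectation. With few neutral mutations (small panels, shallow depth) the
  intervals under-cover; widening the neutral classes or the non-coding
  footprint of the panel restores calibration.
- **Single-transcript coding model.** One CDS model per gene; codons are
  assumed genomically contiguous, so consequences at multi-exon junction
  codons would be approximated by flanking reference bases.
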