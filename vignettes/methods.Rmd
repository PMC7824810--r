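---
title: "Imputing microsatellite genotypes from flanking SNP haplotypes: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing microsatellite genotypes from flanking SNP haplotypes: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatimpute)
```

## The problem

Livestock parentage testing has historically relied on multiallelic
microsatellites (STRs) — in sheep, the 19-marker ISAG panel — while genomic
selection programs genotype new generations on medium-density SNP chips.
Verifying a parent typed on microsatellites against an offspring typed on
SNPs requires a bridge. `msatimpute` implements one: the offspring's
microsatellite genotypes are *imputed* from the SNP haplotypes flanking each
STR locus, and the imputed genotypes are contrasted with the parent's real
ones in an exclusion-based parentage test. The package covers the whole
workflow — quality control and allele recoding, flanking-window selection,
the imputation model, masking cross-validation with accuracy metrics and
null-model baselines, genomic-relationship diagnostics, and the parentage
test — together with a pedigreed cohort simulator that provides ground truth
for every stage, since real joint STR + SNP datasets of this kind are
typically access-restricted.

## The imputation model

Each microsatellite is imputed independently from the SNPs within `W` Mb on
each side of it (total span `2W`). The engine is a Li–Stephens
haplotype-copying hidden Markov model: a target haplotype is modelled as an
imperfect mosaic of `H` phased reference haplotypes. Between adjacent sites
separated by recombination fraction $r_j$ (Haldane, from the cM distance),
the copied template switches with probability

$$\rho_j = 1 - \exp(-4 N_e r_j / H),$$

and a switch lands on a uniformly chosen template. Emissions allow a copying
error $\varepsilon$: a target allele matches its template with probability
$1-\varepsilon$. The microsatellite position enters the chain as a *silent*
site (it emits nothing); the forward–backward state posterior at that site,
summed over the STR allele carried by each reference haplotype, is the
allele posterior. A diploid target is either handled as two haploid chains
when its phase is known (the default on simulated cohorts, where true phase
is available) or by an HMM over ordered template pairs whose emission
compares summed allele dosage with the unphased genotype. The reported
genotype is the posterior-mode unordered allele pair, with ties broken
toward the lexicographically smallest pair in bp.

Production workflows of this kind typically run a BEAGLE-family
phasing/imputation engine; re-implementing that machinery is out of scope —
the package implements the Li–Stephens copying model that underlies that
tool family — but an adapter exports the merged SNP +
recoded-microsatellite VCF for users who wish to run an external engine and
read its output back.

Key parameters (`hmm_params()`):

* `n_e` (default **214**): the effective population size entering the switch
  rate, matching the pedigree-estimated value reported for the commercial
  Assaf population this pipeline emulates. It is exposed rather than fixed,
  since the original analysis does not state how its engine was tuned.
* `error_rate` (default **1e-3**): the allelic copying error; values in
  `(0, 0.5)`.
* `max_ref_haplotypes` (default **200**): reference panels larger than this
  are subsampled with a recorded seed. This caps the $O(H^2)$ diploid cost
  and keeps the haploid cost linear in panel size; on the default synthetic
  cohort, accuracy is insensitive to this cap because each ancestral
  lineage is represented many times among 200 haplotypes.

## Quality control and recoding

Thresholds follow the source protocol: microsatellites need a call rate of
at least 80% and expected heterozygosity $H_e = 1-\sum_a p_a^2$ of at least
0.095 (the $H_e$ of a biallelic locus at 5% minor-allele frequency); SNPs
need a call rate of at least 95%, with *no* MAF filter so that haplotype
diversity is preserved. All three comparisons are strict on the removal
side: a marker sitting exactly on a boundary is kept. Alleles are recoded
once, on the full dataset before any cross-validation masking: the most
common allele becomes code 0 (frequency ties break toward the shorter
allele — deterministic and sample-order invariant), the rest get consecutive
codes in ascending bp length. Because all accuracy metrics operate on bp
lengths, they are invariant under this recoding; the codes exist for the
VCF representation, which uses symbolic placeholder alleles plus an `ALEN`
INFO key carrying the real lengths (true repeat sequences are unknowable
from genotype tables).

## Windows and the low-density panel

`select_window()` takes every SNP with $|pos - pos_{STR}| \le W \cdot 10^6$
on the STR's chromosome — inclusive at the boundary, excluding a SNP at
exactly the STR position. "Window length" therefore means *per flank*; the
published per-window SNP counts (≈19/38/74 SNPs at 0.5/1/2 Mb on a ~19
SNPs/Mb chip) are consistent only under this reading. The union of all 19
windows at `W = 2` is the design of the low-density parentage chip (~1400
SNPs), exported in both 1-based inclusive and BED (0-based half-open)
conventions with the convention labelled in each header.

## Cross-validation and metrics

`run_cv_sweep()` masks the microsatellite genotypes of each validation fold,
builds the reference panel from the training fold only (training samples
with a missing observed genotype at the locus are left out of the panel),
imputes every validation sample, and scores against the observed genotypes.
The default fold plan is a disjoint 10-way partition so the whole population
is imputed exactly once; an independent-draws bootstrap mode
(`method = "bootstrap"`) is provided because the source protocol's wording
("nonparametric bootstrap of 10% of the total samples", "different animals
in each round") admits both readings, and the partition reading is the one
that covers the full population.

Metrics per marker, then averaged over markers:

* **Genotype concordance** $C$: per sample, the size of the maximum multiset
  intersection of true and imputed allele pairs divided by two (0, 0.5 or
  1); $C$ is the mean.
* **Genotype dosage (length r²)**: squared Pearson correlation between true
  and imputed per-sample sums of allele lengths. The source defines the
  metric as "the Pearson correlation" yet names it $r^2$; the squared value
  is reported to honour the symbol and the raw correlation is logged
  alongside.
* **Allelic dosage (allelic r²)**: per allele, squared Pearson correlation
  of true vs imputed copy counts (0/1/2); summarized by the unweighted mean
  over alleles with defined values, plus min and max.
* **Allele-frequency correlation** between true and imputed spectra.
* **Null models**: the *naive* imputer assigns every sample the
  most-common-allele homozygote; its expected concordance is *exactly* the
  most-common-allele frequency (each genotype contributes copies-of-m/2 —
  an algebraic identity unit-tested against enumeration). The *random*
  imputer draws uniformly from the observed genotype list; its expectation
  is the double sum of pairwise concordances over empirical genotype
  frequencies.

Undefined values (zero variance, no scored pairs) propagate as `NA` and are
excluded from averages with counts reported — never coerced to 0. Masking
integrity is structural — the imputation call receives only the training
panel and the target's SNPs — and is additionally guarded by a
data-poisoning canary test.

## The synthetic cohort

Real joint STR+SNP livestock cohorts of this kind are access-restricted, so
the simulator is a first-class module rather than a test fixture. It uses a
founder-mosaic model instead of a coalescent: `K` ancestral binary
haplotype lineages (default 20) are drawn once; every founder haplotype is
a coarse mosaic of lineages (switch rate 0.05/Mb), and each lineage carries
one founding STR allele per locus. STR alleles are thereby tagged by their
flanking haplotype background — precisely the LD the imputation exploits,
directly tunable through `K` and the switch rate. A coalescent backend is a
non-goal; no public LD-decay estimate exists for the emulated population,
so `K` and the SNP density are set to reach the published accuracy regime
rather than to match a measured decay curve.

Defaults mirror the emulated study population: 19 STR loci with the ISAG
panel's allele-count spectrum (2–25 founding alleles) and ladder starts,
one 10-Mb chromosome per locus with the STR at the midpoint (windows never
cross chromosomes, as in the per-marker analysis), SNPs placed by a Poisson
process at 19/Mb, four discrete generations of 500 individuals with 25
sires per generation (ram-heavy usage, as in AI-based dairy-sheep
nucleus programs), Haldane crossovers at 1 cM/Mb (no interference),
stepwise STR mutation (±1 two-bp unit, rate 1e-3 per meiosis — the
canonical stepwise model, which produces the length-ordered allele ladders
seen in real panels), 2% whole-genotype missingness, and a 1.66% rate of
injected pedigree misassignments (rewiring a recorded parent to a random
same-sex, same-generation individual). Gene dropping records the truth —
true genotypes, true pedigree, ancestral-lineage labels — next to the
"observed" data.

What the simulator does *not* emulate: genotyping error on SNPs, null
alleles and allele dropout in STR calling, population admixture and
migration, overlapping generations, and realistic LD decay within
chromosomes. Passing tests therefore demonstrate correctness of the
*method* under a known truth, not expected accuracy on any particular real
population.

With all randomness derived from one root seed via named substreams
(`derive_seed()`), the same seed reproduces a cohort byte-identically.

## Relatedness and effective population size

The genomic relationship matrix follows VanRaden's method 1,
$G = ZZ'/(2\sum_j p_j(1-p_j))$ with $Z$ the column-centred genotype matrix,
frequencies estimated from the data, missing genotypes mean-imputed before
centring, and fixed SNPs excluded from numerator and denominator alike. The
kinship network connects pairs with $G_{ij}$ strictly above a threshold
(0.2 and 0.5 are the conventional choices) and drops isolated individuals.
Betweenness is normalized by $(n-1)(n-2)/2$; closeness uses the
component-scaled form
$\mathrm{clo}(v) = \frac{r_v}{n-1}\cdot\frac{r_v}{\sum_u d(v,u)}$
over the $r_v$ reachable nodes, so both coefficients stay in $[0,1]$ on
disconnected graphs. The closeness normalization is this package's choice
(the source reports coefficients "ranging between 0 and 1" without giving a
formula) and is stated as such.

Effective population size is estimated from the pedigree via the individual
increase in inbreeding: Wright/tabular inbreeding coefficients $F_i$,
equivalent complete generations $t_i = 1 + (t_s + t_d)/2$, per-individual
$\Delta F_i = 1-(1-F_i)^{1/(t_i-1)}$, and $N_e = 1/(2\overline{\Delta F})$
over a reference cohort. The estimator choice is this package's (the source
used a closed-source program without naming its method); matching any
particular real-data $N_e$ is out of scope. In validation the reference
cohort is the last generation — early generations of an unrelated-founder
pedigree carry $F \approx 0$ and would dilute $\overline{\Delta F}$.

## Parentage testing

For every recorded parental link, the parent's *real* microsatellite
genotypes are contrasted with the offspring's *imputed* ones:
a marker is compatible when the two allele multisets share at least one
allele; a missing genotype on either side is non-excluding and the marker
is not counted as tested (exclusion logic must not punish missingness).
A pair is confirmed at ≥ 17 compatible markers of 19, scaling as
$\lceil 17/19 \cdot L\rceil$ when only $L$ loci are available; with fewer
testable markers than the threshold the pair is *undetermined* rather than
forced to a decision. In parallel, an opposing-homozygote check runs on the
low-density panel SNPs: the rate of SNPs where one individual is homozygous
reference and the other homozygous alternate, over jointly typed SNPs
(conflict above `tau = 0.01`, undetermined below 50 shared SNPs). The
statistic and threshold are this package's documented stand-in — the source
states that SNP windows were used for conflict detection without naming the
statistic. Under true parentage and error-free genotypes the rate is
exactly 0, so the default threshold is generous.

## Numerical and degenerate-input choices

* Forward–backward vectors are renormalized at every site; a fully
  uninformative chain returns the panel prior (with a warning for
  all-missing targets). An empty SNP window is refused outright.
* Posteriors are validated to sum to 1 within 1e-6 in tests; the compiled
  kernel is checked against an exhaustive path-sum oracle on all small
  panels (≤5 haplotypes × ≤4 SNPs) to 1e-10.
* Half-missing STR calls are rejected at parse time; missingness is
  whole-genotype, matching how STR callers report.
* Pedigrees are topologically sorted on load; a cycle is an error naming an
  individual on it; a parent never listed as an individual is auto-added as
  a founder with a warning.
* Coordinates are 1-based bp everywhere; intervals are closed. The BED
  export is the single deliberate exception, labelled in its header.

## Problem sizes used in validation

The full validation suite runs the complete default cohort (2,000
individuals, ~3,600 SNPs, 19 STR loci) through 10-fold CV at a 2-Mb flank —
about half a minute for the sweep — plus a same-scale perfect-LD cohort
(no recombination, no mosaic switching, no mutation, 8 lineages) on which
imputation is error-free by construction, and many sub-minute cohorts of
60–450 individuals for module-level properties. The oracle comparisons use
panels small enough for exhaustive path enumeration. These sizes are chosen
so the whole suite completes in a few minutes while still exercising the
defaults end to end.

## Known limitations

* Phasing is a non-goal: real-data use requires pre-phased SNP input (the
  default engine consumes phased haplotypes; the diploid engine accepts
  unphased genotypes at $O(H^2)$ cost).
* Each microsatellite is imputed independently; no multi-locus joint model.
* The simulator's LD structure is block-like rather than coalescent;
  accuracy on the synthetic default should be read as an upper bound on
  what the same pipeline would achieve on a population with comparable
  panel sizes and weaker LD.
* Null-model concordances depend strongly on the allele-frequency spectrum;
  the simulated spectra are more even than real panels, so simulated null
  concordances run lower than published real-data values. The analytic
  expectations, not those published values, are the reference in tests.
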