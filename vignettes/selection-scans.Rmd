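---
title: "Selection-signature scanning and mixed-model association with sweepscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection-signature scanning and mixed-model association with sweepscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepscan)
```

## The scientific problem

A closed livestock population under sustained directional selection — for
example a proven-bull beef-cattle nucleus selected on estimated breeding
values (EBVs) for carcass traits over several decades — accumulates
*selective sweeps*: a favored allele rises in frequency and drags a long,
unbroken haplotype with it. An unselected conservation population from the
same origin retains the ancestral haplotype structure. sweepscan implements
the statistics used to detect and localize these footprints from phased
SNP-chip data in such a paired design:

* **EHH / iHS / piHS** — within-population haplotype-extension scan;
* **EHHS / iES / Rsb** — between-population contrast of site-level
  haplotype homozygosity;
* **Fst and identity-by-state MDS** — overall differentiation and
  structure;
* **GRM + MLM-LOCO GWAS** — per-SNP association of EBV phenotypes under a
  polygenic covariance with the candidate chromosome left out;
* **decadal cohort trends** of allele frequencies and EBV means, pairwise
  LD, and haplotype bifurcation diagrams;
* a **forward Wright–Fisher two-population sweep simulator** that supplies
  phased panels with known truth for calibration and testing.

## Statistics

### EHH and iHS

For the carriers of a core allele, the extended haplotype homozygosity at a
marker $x$ is the probability that two randomly drawn carrier haplotypes are
identical at every marker between the core and $x$. With carrier count
$n_c$ partitioned into identity classes of sizes $n_h$,

$$\mathrm{EHH}(x) = \frac{\sum_h n_h (n_h - 1)}{n_c (n_c - 1)},$$

the unbiased pair-counting form. The walk proceeds outward until EHH drops
below a cutoff (default 0.05); the first sub-cutoff marker closes the arm
with its actual value and nothing is extrapolated. iHH is the trapezoidal
integral of the curve over physical distance (bp·EHH), arms summed; any
constant bp-to-cM factor cancels in the ratio below, which is why a genetic
map is not required at chip density. Arms that reach a chromosome end before
crossing the cutoff are integrated to the end and flagged; flagged SNPs are
kept by default.

The raw score is $\mathrm{iHS} = \ln(\mathrm{iHH}_a / \mathrm{iHH}_d)$ for
the ancestral and derived allele at each SNP with known ancestral state and
MAF above 0.01. Because the expected score depends on allele frequency, raw
scores are standardized to mean 0, sd 1 within derived-allele-frequency bins
(default width 0.025). Negative standardized scores mark unusually extended
*derived* haplotypes — the classic signature of an ongoing sweep — and
positive scores extended ancestral haplotypes. Significance is read on

$$p\mathrm{iHS} = -\log_{10}\!\bigl(1 - 2\,|\Phi(\mathrm{iHS}) - 0.5|\bigr),$$

the two-sided Gaussian tail of the standardized score, computed through the
upper-tail complement `2 * pnorm(|x|, lower.tail = FALSE)` so it stays
accurate far into the tails. The default significance rule is strict
piHS > 6 (about $|z| > 4.9$), with the allele class taken from the sign.

### EHHS, iES and Rsb

The site-level version pools both core alleles: the unbiased haplotype
homozygosity of *all* $n$ haplotypes over the interval, normalized by its
value at the core, so EHHS(core) = 1. Its integral iES is computed per
population on the SNPs polymorphic in both, and

$$\mathrm{Rsb} = \ln\!\left(\frac{\mathrm{iES}_{\text{pop1}}}{\mathrm{iES}_{\text{pop2}}}\right)$$

is standardized by subtracting the genome-wide *median* (robust against the
very outliers the scan is hunting) and dividing by the standard deviation.
Positive values point to longer haplotypes — candidate selection — in the
numerator population. The same two-sided tail transform gives pRsb; the
default threshold mirrors the piHS rule and is configurable.

### Fst and MDS

Per SNP, $F_{st} = (H_T - H_S)/H_T$ with $H_S$ the mean of the two
populations' expected heterozygosities $2pq$ and $H_T$ the heterozygosity at
the unweighted mean frequency (populations, not individuals, are the units).
The genome-wide summary is the ratio of sums, which is stable at low-MAF
SNPs; per-SNP values are emitted so a mean-of-ratios is also recoverable.
Classical MDS runs on 1 − IBS distances (mean shared-allele proportion per
genotype pair) through `stats::cmdscale`.

### GRM and the LOCO mixed model

The genomic relationship matrix is the VanRaden form
$A_{jk} = \frac{1}{N}\sum_i \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2p_i(1-p_i)}$
with in-sample frequencies; monomorphic SNPs are skipped. For each
chromosome the GRM is rebuilt without it, variance components of
$y = \mu + g + e$ are re-estimated by REML (one eigendecomposition reduces
the problem to an exact 1-D profile search over the variance ratio,
converged to 1e-8), and each SNP on that chromosome is tested by exact GLS
under $\sigma_g^2 K_{\mathrm{loco}} + \sigma_e^2 I$ with a 1-df Wald
chi-square on the allele-substitution effect. Leaving out the candidate's
chromosome prevents the tested SNP from being absorbed by its own polygenic
control (proximal contamination); the flip side, used deliberately in our
calibration experiments, is that same-chromosome polygenic signal is *kept*
— a type-I calibration must therefore place the background on other
chromosomes. Phenotypes are EBVs used as-is; deregression is out of scope.

## The sweep simulator

`simulate_sweep()` is a discrete-generation Wright–Fisher forward simulator
(compiled core) chosen over coalescent machinery because the analysis needs
decade snapshots of one continuing population. Design, in order of a
simulation run:

* **Founders and burn-in.** `asc_factor` (10×) candidate loci per retained
  marker start at Beta(0.5, 0.5) frequencies truncated to MAF ≥ 0.05 (a
  U-shaped neutral-SFS proxy) in linkage equilibrium, then drift for
  `g_burn = 4 n_base` generations with recombination so LD reaches drift
  equilibrium. Burn-in recombination is rescaled (`burn_rho_scale = 4`,
  holding $N_e\rho$ constant) so the deep history carries the haplotype
  diversity of an ancestral population four times larger, while the recent
  phases run at the true map rate $\rho = 10^{-8}$/bp — the usual
  rescaling argument. With drift alone ~86% of candidates fix during 4N
  generations, which is *why* the chip is ascertained afterwards:
* **Ascertainment.** At the end of the burn-in, `n_snps` evenly spaced loci
  per chromosome with MAF ≥ 0.05 become the marker panel, exactly how chip
  content is ascertained on a modern population. Dropped candidates still
  contributed recombination distance, like untyped sites between chip
  markers. The panel is fixed from here on (no new mutations; chip SNPs are
  ascertained and the simulated window is ~40 generations).
* **The focal allele.** A detectable sweep needs a *single-origin* derived
  allele: a young haplotype, identical across carriers over megabases. In a
  finite drift-equilibrium panel such configurations essentially never occur
  at usable frequencies (we measured identical spans < 1 Mb), so the
  simulator constructs one: a template haplotype's window of
  `focal_span_bp = 2.5` Mb is copied onto a fraction `focal_freq = 0.35` of
  all haplotypes, which receive the derived allele at the central marker of
  chromosome 1. This is the present-day signature of a mutation roughly
  $2/(\rho\,\cdot\,\mathrm{span}) \approx 80$ generations old that rose to
  moderate frequency — i.e. a favored standing variant about as old as the
  populations' divergence — without conditioning a forward path on an
  improbable drift ascent. The defaults aim the 30-generation program at a
  final frequency near 0.8, consistent with swept haplotypes approaching
  fixation in the motivating data.
* **Split and selection.** The base splits into a selected population
  (n = 667 by default) and an unselected one (n = 362). After a neutral
  pre-phase, the selected branch experiences genotype fitnesses
  $1 : 1+hs : 1+s$ at the focal locus ($s = 0.15$, $h = 0.5$) for the final
  `g_sel = 30` generations of the `g_split = 40`-generation divergence — a
  30-year program with early shared ancestry. Recombination draws at most
  one effective crossover per adjacent-marker gap per meiosis with
  probability $\rho \times \mathrm{gap}$ (a thinned-Poisson construction
  makes this exact); chromosomes assort freely. If the focal derived allele
  is lost before selection starts, the pre-phase is resampled (conditioning
  on segregation) and the event logged.
* **Cohorts and EBVs.** Decade cohorts (1980s–2010s by default) are drawn
  without replacement from generation snapshots spread over the selection
  phase, so later decades come from later generations — mirroring bulls
  sampled across a breeding program. True breeding values sum QTL effects
  times derived dosage plus a per-decade polygenic gain; the EBV adds noise
  scaled so $\mathrm{cor}(\mathrm{EBV}, \mathrm{TBV})^2$ equals the
  configured reliability (0.8, high-accuracy progeny-test territory).
  Default trait settings (CWT gaining ~8 kg/decade, EMA ~2 cm², MS ~0.5,
  BFT drifting slightly down) echo the qualitative decadal trends of the
  motivating program.

Everything stochastic flows from the single `seed`; outputs are bit-exact
reproducible.

### What the generator does and does not emulate

It reproduces: two low-Fst populations of shared ancestry, 50k-density
phased haplotypes with realistic LD decay, one hard selective sweep with a
known focal locus, decade cohorts with rising breeding values, and EBV-like
phenotypes of known reliability. It does not emulate: genotyping or phasing
error, new mutations, migration or admixture, overlapping generations,
pedigree structure within cohorts, or multi-locus selection on a breeding
index. Passing tests on simulated panels therefore validate the statistical
machinery and its calibration, not robustness to those real-data
complications.

### A measured limitation

Under the stated study conditions ($s = 0.15$ for 30 generations, 2000
SNPs, 400 diploids per population) the sweep is *partial*: the expected
logit gain is only $\approx s\,g/2 = 2.25$. The focal standardized iHS
lands around −3 to −4.5 while the genome-wide two-sided noise maximum among
~1900 tests is itself ~3.5–4, so the single top-scoring SNP falls within
1 Mb of the focal locus in only ~60–70% of replicate seeds (measured
16/25). Reliable top-1 localization would require a stronger or longer
sweep than these conditions provide; the corresponding acceptance check is
left to report what it measures.

## Numerical choices

* EHH cutoff 0.05 and standardization bin width 0.025 follow the standard
  practice of haplotype-scan tooling; both are arguments.
* No maximum-gap rule by default: at ~55 kb chip spacing a typical gap
  threshold would trip constantly; `max_extension_bp` exists for hard caps.
* Hardy–Weinberg QC uses the exact (enumeration) test, two-sided as the sum
  of configuration probabilities not exceeding the observed one — the same
  test PLINK applies — computed by a numerically stable log-recurrence and
  verified against a brute-force hypergeometric enumeration to 1e-10.
* QC charges each SNP to the first filter that removes it (call rate, HWE,
  MAF, in that order) so removals and survivors add up exactly; individuals
  with > 10% missing genotypes are dropped first. HWE is tested within each
  population present.
* REML maximizes the profiled restricted likelihood over
  $\log(\sigma_g^2/\sigma_e^2) \in [-14, 14]$ with `optimize` (tol 1e-8) and
  falls back to the boundary $\sigma_g^2 = 0$ when that fits no worse;
  numerically negative GRM eigenvalues are clipped at zero with a warning.
* Bifurcation trees order children deterministically (allele 0 before 1);
  ties in scans resolve by marker order.
* Degenerate inputs: monomorphic cores error in `compute_ehh` (< 2
  carriers) and yield NULL scores with reason codes in scans; a monomorphic
  pooled site contributes nothing to genome-wide Fst; standardization bins
  with fewer than two SNPs or zero spread leave scores NA with a reason.

## Problem sizes used in the checks

The automated checks run the scan stack at 2000 markers × 400 diploids per
population (25 replicate seeds for the null/sweep contrast, aggregating
over 20,000 null SNP-tests), the EHH/EHHS oracle comparison on 1000
randomized small panels (≤ 30 haplotypes × 20 markers, tolerance 1e-12),
and the mixed-model calibration at n = 500 with eight chromosomes
(> 20,000 null tests, background on four chromosomes). These sizes were
chosen as the smallest at which the targeted behaviours are statistically
unambiguous.

## A worked example

```{r example, eval = FALSE}
library(sweepscan)

cf  <- sweep_sim_config(n_sel = 400, n_unsel = 400, n_snps = 2000, seed = 42,
                        cohort_decades = NULL, trait_model = NULL)
sim <- simulate_sweep(cf)

scan <- scan_ihs(sim$panel_sel)
glance(scan)
autoplot(scan)

rsb <- scan_rsb(sim$panel_sel, sim$panel_unsel)
fst <- compute_fst(sim$panel_sel, sim$panel_unsel)
attr(fst, "fst_genome")

prof <- compute_ehh(sim$panel_sel, sim$truth$focal_id, "derived")
autoplot(prof)
```

## Known limitations

* iHS needs ancestral-state annotations; markers without them are scanned
  only by Rsb.
* The EHH walk assumes complete phased input and refuses missing alleles
  rather than imputing silently.
* Genome-wide significance for the GWAS is reported as raw and
  Bonferroni-adjusted flags; the choice of threshold is left to the user.
* The exact GLS-per-SNP strategy is $O(n^2)$ per SNP after one
  eigendecomposition per LOCO set — comfortable to a few thousand samples,
  not biobank scale.
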