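---
title: "Models and methods behind selmap"
author: "selmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind selmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

selmap analyzes SNP-array genotypes from several related populations — the
motivating setting is breed-association cattle data, where a handful of
national populations descend from a common founder stock, diverge under
independent selection programs, and are genotyped on overlapping medium-density
arrays. The package covers the whole comparative workflow: input and
harmonization, tiered quality control, genomic relationships and principal
components, diversity and differentiation statistics, an identity-by-state
population tree, linkage-disequilibrium (LD) decay, cross-population
consistency of gametic phase (CGP), runs of homozygosity (ROH) with island
calling, generation-proxy selection mapping (GPSM), and QTL-category
enrichment of candidate regions. Because real breed-association genotypes are
proprietary, a simulator with known ground truth is a first-class part of the
package and underpins every statistical claim the test suite makes.

This vignette records the models, the defaults and why they were chosen, the
numerical decisions, and what the simulation-based validation does and does
not establish about real data.

## The genotype container and harmonization

Genotypes are counts of a designated A1 allele (0/1/2, `NA` for missing) in a
samples x markers matrix with a sample table and a sorted marker map
(`genotype_dataset()`). PLINK 1 binary files are the on-disk format
(`read_plink()` / `write_plink()`, SNP-major, v1.00 magic); population labels
and birth years travel in a sidecar TSV keyed by `sample_id`, because the fam
format has no fields for them.

Cross-population analyses require a common marker set with a common allele
coding. `harmonize_and_intersect()` intersects marker ids, flips genotypes
0<->2 where one dataset coded the alleles in the opposite order, and drops
markers whose allele pairs cannot be reconciled. Strand-ambiguous A/T and C/G
markers are dropped by default: if strand cannot be resolved, the sign of the
gametic covariance D is meaningless, and CGP (which correlates signed LD
across populations) would be corrupted silently. The cost — a modest loss of
markers — is the standard price of that safety.

## Quality control

Two profiles mirror the tiered practice for array data:

* **roh profile** — call-rate filters only (samples first at 95%, then
  markers at 95% on the surviving samples). MAF and equilibrium filters are
  deliberately withheld: ROH detection depends on rare and monomorphic
  stretches that a MAF filter would erase.
* **full profile** — adds the non-autosomal filter (default chromosomes
  1–29, the cattle autosome set), a MAF floor (keep MAF >= 0.05), and a
  Hardy–Weinberg exact-test filter (keep p >= 1e-6), applied sequentially
  with an attrition report per criterion.

The HWE test is the exact conditional test (plain p, no mid-p): the summed
probability, given the allele counts, of all heterozygote counts no more
probable than the observed one. It is validated against a full enumeration
oracle for every genotype triple with total at most 10. HWE is assessed
within each population, since pooling diverged populations fails equilibrium
for purely structural reasons (Wahlund effect).

## Relationships, PCA, diversity, differentiation

The genomic relationship matrix is the VanRaden first-method construction,
G = (M − 2P)(M − 2P)′ / (2 Σ p_i(1 − p_i)), with allele frequencies estimated
from the data and missing calls mean-imputed to 2p before centering (the
convention of the formula's source; the package is explicit about it because
the choice changes G on sparse data). A per-SNP standardized variant (each
centered marker divided by its own standard deviation) is used for PCA, where
the convention is to give each marker equal weight. PCA is the
eigendecomposition of G; scores are eigenvectors scaled by the square roots
of eigenvalues and explained fractions are eigenvalues over the trace.

Diversity summaries are observed heterozygosity per individual (het count /
non-missing count), expected heterozygosity 2p(1−p) averaged over markers,
the proportion of markers with MAF above 5%, and the allele-sharing
statistic s = (IBS2 + 0.5 IBS1)/m between individual pairs. The literature
attaches the same name to both s and 1−s; both are reported
(`pairwise_shared_distance()`), and the VIF-based pruning (window 50, step
5, VIF cap 2) is applied upstream when following array-panel convention.

Pairwise differentiation uses the Weir & Cockerham (1984) variance-components
estimator computed from genotype counts, with the heterozygosity correction
and negative per-marker values retained. Two summaries are reported
deliberately. The per-marker mean with its SD is the form tabulated alongside
per-SNP scans — but each marker's theta is a noisy, skewed ratio, and its
mean sits systematically below the divergence parameter (about 0.118 when
the true F is 0.15 in a pure Beta-binomial simulation). The multi-locus
ratio-of-sums `theta_overall` — the combination Weir & Cockerham themselves
prescribe — is the consistent estimator and the one the package's recovery
checks assert. Users comparing against published per-SNP-averaged tables
should use the former; users estimating divergence should use the latter. A
Hudson-style estimator is available behind a flag for sensitivity analysis.

The population tree summarizes each population by its mean genotype vector,
takes distance(j,k) = mean |mean_j − mean_k| / 2 (bounded in [0,1]; a
Euclidean option exists), and runs Neighbor-Joining via `ape`. Additive
distance matrices are recovered exactly. Negative NJ branch lengths — an
artifact on non-additive inputs — are clamped to zero with the deficit moved
to the sibling edge, and every clamp is counted. Trees are left unrooted.

## LD, decay, pruning, and consistency of gametic phase

The working LD statistic is the genotypic (composite) r²: the squared Pearson
correlation of 0/1/2 counts over mutually non-missing individuals. It needs
no phasing and is the standard array-data choice. Signed quantities (D, D′)
come from two-locus haplotype frequencies fitted by EM over unphased
genotypes: double heterozygotes are split between the two phase
configurations by their current odds and iterated to |change| < 1e-10 (cap
1000; pairs without double heterozygotes are exact counting solutions, which
is also the EM start so those converge immediately). D = f(AB) − f(A)f(B);
D′ scales D by its maximum given the margins.

`ld_scan()` enumerates all intra-chromosomal pairs within 1 Mb with no r²
floor. Decay is summarized in half-open 10-kb bins from 10 to 100 kb and
100-kb bins to 1 Mb (final bin closed), with bins under 50 pairs flagged
unreliable; the bin assignment is tested to partition the range exactly.
Pairs under 10 kb stay in the raw table but not the decay summary.

Two pruning procedures are provided: pairwise-r² pruning (drop the later
marker of any within-window pair above the threshold) and VIF pruning
(iteratively remove the marker with the highest variance-inflation factor
until all are at or below the cap). Windows slide over the *surviving*
marker set and passes repeat to a fixed point, so the defining property —
no offending pair, no offending VIF, under any window placement on the
output — holds on independent re-check; map-order tie-breaking keeps runs
reproducible.

CGP for a population pair is the Pearson correlation, within each distance
bin, of the signed root LD (sqrt(r²) x sign(D)) over SNP pairs shared by the
two populations' tables, with D computed within each population separately.
Complete cases only; bins under the pair floor are flagged. Note one subtle
non-invariance: relabeling a marker's alleles in *both* populations negates
that pair's signed value in both tables — phase agreement is preserved, but
the Pearson correlation can shift slightly because the bin means enter the
centering. The test suite pins down exactly this behavior.

## Runs of homozygosity

Detection follows the sliding-window semantics standard for array data:
50-SNP windows tolerating at most one heterozygous and one missing call; a
marker is ROH-eligible when at least 5% of the windows covering it are
homozygous; maximal runs of eligible markers are split at inter-marker gaps
over 1,000 kb and reported when they have at least 30 SNPs, span at least
500 kb, and carry at most 50 kb per SNP. At chromosome ends, the windows
that fit are used (markers are never penalized for sitting near a
terminus); chromosomes shorter than one window use a single truncated
window. Length classes use (low, high] boundaries at 2/4/8/16 Mb.

One boundary decision deserves its own paragraph. The raw window rule
systematically overshoots segment ends: a marker just outside a homozygous
tract stays eligible as long as three of its fifty covering windows hold at
most one heterozygote, so called runs extend several markers into flanking
heterozygosity before eligibility collapses. The package therefore snaps
each called run to its longest heterozygote-free stretch by default
(`boundary = "hom_run"`; missing calls are allowed inside, as absence of a
call is not evidence of heterozygosity). On data without genotyping error
this recovers the observable autozygous tract exactly; on real data it
trades a slightly conservative boundary (a genuine ROH harboring an isolated
genotyping error near one end is trimmed at that call) for boundary
estimates that track the underlying tract. The raw PLINK-style bounds
remain available via `boundary = "window"`. Relatedly, recovery checks
compare against the *observable* tract (`observable_tract()`): markers
flanking a planted segment that are homozygous by state are
indistinguishable from it, so no detector can recover planted bp bounds more
precisely than the tract they sit in.

Island calling is per marker: the in-ROH frequency is the fraction of
individuals whose segment set covers the marker, and maximal runs of
markers at or above the threshold (default 50%) are reported with bp
bounds and peak frequency. Chromosome coverage is the mean over individuals
of the per-individual union of segments divided by the chromosome length
(last marker position by default; real lengths can be supplied).

## Generation-proxy selection mapping

GPSM asks which markers' allele frequencies have moved systematically over
time. The model regresses the generation proxy — birth year — on each SNP in
a linear mixed model:

y = mu + x_i b_i + g + e,  g ~ N(0, G sigma_g^2),  e ~ N(0, I sigma_e^2)

The polygenic term absorbs the fact that relatives cluster in time for
demographic reasons; what remains significant at a marker indicates
directional allele-frequency change — selection — rather than drift along
the pedigree. Variance components are estimated once by REML under the null
(no SNP term): after one eigendecomposition of G, the restricted likelihood
is profiled over the variance ratio with a 1-D optimizer on the heritability
scale, with an explicit boundary check at sigma_g^2 = 0. The REML surface
from the eigen path is verified against a direct-inversion oracle to 1e-6.
The per-marker scan is then generalized least squares with V fixed at the
null estimates — the standard mixed-model-association strategy (per-marker
REML would cost thousands of fits and change nothing material). The
candidate marker stays in G (no leave-one-chromosome-out), matching the
plain mixed-model mode of the field's tooling; on dense maps this costs a
little power through proximal contamination (visible in our own power
fixtures at small marker counts) but keeps the scan directly comparable.
Significance is Bonferroni: alpha = 0.05 over the number of markers tested.
Q-Q data use the (i − 0.5)/M plotting positions and the median-chi-square
inflation factor.

Measured on the simulator at n = 500, M = 2,000 and a polygenic share of
0.5: the null fraction of p < 0.05 is 0.050, the inflation factor 0.999,
and the familywise hit rate across replicates 5.0% — i.e. nominal. One
testing note: with 20 replicates, "at most one replicate with any
Bonferroni hit" is a knife-edge bar that a perfectly calibrated scan fails
about a quarter of the time; the suite therefore asserts the exact binomial
99% envelope of the nominal 5% familywise rate (at most 3 hits in 20),
which still detects genuine inflation.

## The simulator and what it establishes

`sim_config()` / `simulate_study()` generate multi-population genotypes with
known structure:

* **LD** comes from a finite founder pool: each haplotype is a mosaic of
  pool haplotypes with template switches at `recombination_rate` per Mb (a
  copying-process analogue of recombination; the default 2/Mb with a pool
  of 10 haplotypes gives background r² near 0.1 decaying over hundreds of
  kb, the magnitude seen in closed livestock populations). Marker positions
  sit on a jittered grid so pair distances populate every decay bin.
* **Divergence** follows the Balding–Nichols model: population frequencies
  are Beta draws with mean p and variance F p(1−p), clipped to [0.01, 0.99]
  to avoid fixation artifacts. Copied alleles are resampled to the
  population frequency through a maximal coupling, which preserves the
  shared haplotype background — this is what gives related populations
  shared gametic phase, and makes CGP decline smoothly as F grows.
* **Autozygosity** is planted by copying one haplotype onto the other over
  an interval, with exact truth recorded.
* **Birth years** are uniform over the configured range (default
  1961–2024). A polygenic score built from the centered genotype matrix
  plus noise is rank-mapped onto the uniform year grid so the genomic share
  of year variance hits the target in expectation (the monotone rank
  mapping attenuates it by a few percent — visible as PVE estimates a
  shade below target). Trend markers are then re-drawn per individual from
  p0 + slope (year − start), clipped to [0.01, 0.99]; re-drawing breaks
  their LD with neighbors, a documented simplification that makes power
  analytically predictable.

Everything is deterministic given the seed.

Fixture conditions are chosen to realize the regime each validation claims,
and then frozen: the ROH recovery map uses about 10-kb spacing so the
smallest qualifying tracts (0.6 Mb, about 60 SNPs) exceed one 50-SNP window
— below that density the window rule cannot see them, which is the method's
known resolution floor, not a bug — with a 100-haplotype pool so genuine
pool autozygosity does not confound planted truth; the CGP fixtures use a
4-haplotype pool with 0.25 switches/Mb so true LD stays large relative to
n = 200 sampling noise out to 1 Mb (with weak long-range LD, long-distance
CGP is noise-bounded for any estimator); the Balding–Nichols recovery and
unrelated-population fixtures use pools of 2n haplotypes, which is what
"unstructured" means in that model. Problem sizes in the suite (up to
n = 500, M = 10,000, 20 replicates) were chosen as the smallest at which
the targeted properties are statistically sharp.

What passing does **not** establish about real data: the simulator has no
genotyping error, no imputation artifacts, no pedigree structure beyond the
founder pool, no sex chromosomes, and trend markers without local LD — so
boundary-exact ROH recovery and the exact null calibration are best-case
statements. On real arrays, ROH boundaries are uncertain at the one-to-few
marker scale, and GPSM calibration should always be checked on the Q-Q plot
of the actual scan.

## Pipeline and interface

`run_pipeline()` executes the stages in dependency order from a validated
configuration list (unknown keys are rejected before any computation),
writes one TSV per stage plus a JSON manifest with the seed, parameters and
stage timings, and is byte-reproducible under a fixed seed. The package's
functions are the primary interface — the pipeline driver is a convenience,
not a separate command-line tool. GPSM, as the package's headline model, is
exposed in the classic R modelling idiom: `gpsm()` returns a classed object
with `print()`, `summary()` and `plot()` (Manhattan and Q-Q) methods; the
rest of the toolkit is deliberately plain functions over plain containers,
which is how its outputs compose into reports.

## Known limitations

* Unphased-data LD only; no inter-chromosomal LD; no haplotype phasing.
* No genotype imputation or assembly lift-over: inputs are expected on one
  assembly and panel after upstream processing.
* Enrichment is over-representation only, against user-supplied interval
  tables — never live database queries, which cannot be version-pinned.
* ROH-based inbreeding coefficients and consensus ROH across populations
  are out of scope.
* The exact HWE filter, pruning and window rules reproduce standard
  toolchain semantics; where those toolchains leave boundary behavior
  unspecified (class edges, ROH ends, enrichment background), the choices
  made here are documented above and exposed as parameters.
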