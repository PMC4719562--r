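---
title: "Accession-level SNP diversity, structure and ascertainment bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accession-level SNP diversity, structure and ascertainment bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accdiv)
```

## The setting

Genebanks keep crop diversity as *accessions* — seed lots sampled from a
single field or population. Genotyping several individuals per accession
on a fixed SNP array gives a panel with a natural three-level hierarchy:
individuals nested in accessions nested in groups (taxa, biological
types such as wild/feral/cultivated, or agro-climatic zones). `accdiv`
implements the analysis stack such a panel calls for: QC filtering,
diversity statistics within and across accessions, hierarchical AMOVA
and pairwise differentiation, geography regressions, PCA with a
within-accession dispersion statistic, in-silico pooling, and a
haplotype-merging diagnostic for SNP ascertainment bias. Everything
consumes and produces tibbles, so the stages chain with the pipe.

The genotype container is deliberately plain: a wide tibble with
`individual_id`, `accession_id` and one integer column per marker
holding the alternate-allele dosage (0/1/2, `NA` missing).

## Diversity statistics

Per locus and set of individuals we report the reference-allele
frequency $p$, observed allele count $N_a$, observed heterozygosity
$H_O$, the unadjusted gene diversity

$$H_E = 1 - p^2 - (1-p)^2 = 2p(1-p),$$

and the fixation index $F = (H_E - H_O)/H_E$, undefined where
$H_E = 0$. The unadjusted $H_E$ matches the default of the widely used
desktop packages for this kind of panel; Nei's small-sample correction
$2n/(2n-1)$ is available behind `unbiased = TRUE` and is what the
simulator-recovery tests use, because the raw estimator is biased low by
$H_E/2n$ — noticeable at five or six individuals per accession.

Group summaries come in two modes, mirroring the standard reporting
layout: the *within-accession mean* (unweighted across accessions — each
seed lot counts equally regardless of how many plants were genotyped)
and the *group total* (frequencies pooled over all the group's
individuals). Loci monomorphic within a group contribute $H_E = 0$ to
means but are excluded from mean $F$, where $F$ does not exist.

The minor-allele-frequency spectrum is compared against the folded
neutral expectation for a haploid sample of size $m$ (class $i$ weight
$\propto (1/i + 1/(m-i))/(1+[i = m-i])$), with $m$ the median of twice
the per-marker call count, rounded down to even. Array SNPs discovered
in a narrow elite panel show the classic deficit of rare alleles against
this curve.

## Distances, AMOVA and permutation tests

Between individuals we use the codominant squared genotypic distance
(identical genotypes 0, homozygote–heterozygote 1, opposite homozygotes
4), summed over shared called loci without rescaling; a per-locus
normalised variant sits behind a flag. Missing-data handling by
pair-complete summation is a documented dialect choice — panels at ~5%
missingness are insensitive to it.

The AMOVA decomposes the squared distances into among-group,
among-accession-within-group and within-accession components by the
method-of-moments equations with unequal-size coefficients. Negative
raw components are kept in the output but floored at zero for the
percentage column. Permutation schemes are level-appropriate: whole
accessions among groups for $\Phi_{CT}$, individuals among accessions
within their group for $\Phi_{SC}$, unrestricted for $\Phi_{ST}$; all
tests are one-sided with the observed value counted
($p = (\mathrm{hits}+1)/(n_{perm}+1)$).

One subtlety deserves its own paragraph. With individuals as units the
total variance has no within-individual stratum, so the among-level
$\Phi$ on genotypic distances has expectation roughly $2F/(1+F)$ rather
than $F$ — an inherent property of the distance-based Phi-PT convention,
not an implementation artefact. `amova(units = "allele")` expands each
individual into its two allele copies; the resulting $\Phi$ statistics
estimate the classical hierarchical F-statistics and recover a simulated
$F_{CT}$ to within ±0.002 in our validation. The default stays
`units = "individual"` because that is the convention of the reporting
tables this package mirrors; use `"allele"` when you need calibrated
F-statistic estimates. Pairwise FST between groups is the two-population
among-group Phi with individuals shuffled between the pair; a
Weir–Cockerham $\theta$ (ratio of sums of the 1984 moment components)
is available as an independent cross-check estimator and is reported,
not reconciled, where the two disagree.

Nei's standard distance is computed from across-loci means
$D = -\ln\left(\bar J_{xy}/\sqrt{\bar J_x \bar J_y}\right)$; disjoint
frequency profiles give $D = \infty$ with a warning. Geographic
distances are haversine great circles on a 6371 km Earth. The Mantel
test correlates upper triangles and permutes rows and columns of one
matrix jointly (one-sided positive by default, the usual
isolation-by-distance direction); diversity-versus-geography
correlations default to two-sided, as nothing fixes the sign of a
latitude trend a priori. The distance-to-origin regression measures
from (39°N, 35°E) — central Anatolia, the crop's assumed centre of
origin — and the origin is configurable because that assumption is
itself soft.

## Haplotype merging as an ascertainment diagnostic

SNPs ascertained in a narrow discovery panel under-represent alleles
rare outside it, depressing apparent diversity in other groups. Merging
$k$ neighbouring mapped SNPs (non-overlapping windows in map order;
remainders dropped; sliding windows rejected as pseudo-replication)
creates multi-allelic haplotype loci whose diversity is less sensitive
to how any single SNP was chosen. Haplotype frequencies from unphased
diploids are estimated by an EM of the Excoffier–Slatkin type over the
$2^k$-haplotype simplex (tolerance 1e-8 on the log-likelihood, max 500
iterations, 5 restarts: uniform plus 4 random, seeded). Individuals
missing any member call are excluded from that block rather than
imputed — the simplest defensible treatment. A `genotype_string` mode
that counts complete multilocus genotypes as alleles exists for
comparison. The log-likelihood is asserted non-decreasing at every EM
iteration; on phase-resolvable data (no multiple heterozygotes) EM
reduces exactly to counting.

The diagnostic itself is the ratio of a group's mean block diversity to
a reference group's, traced over $k = 1..5$: under comparable
ascertainment pressure the ratio is flat; a ratio climbing with $k$
flags diversity underestimated at the SNP level in that group. On the
package's `"biased-panel"` fixture the non-discovery clusters climb
from ~0.89 at $k=1$ to ~0.96 at $k=5$.

## In-silico pooling

Pooled-DNA genotyping scores one genotype per accession. The emulation
assumes equal molar contributions: per accession and marker, the pool
is heterozygous when the major-allele frequency is strictly below the
cutoff (default 0.75) and homozygous for the major allele otherwise; a
50/50 tie is therefore heterozygous, and frequencies are taken over
non-missing calls with equal weight per individual. The capture
fraction — pooled group-total $H_E$ over un-pooled group-total $H_E$ —
quantifies what survives; it can exceed 1 when pooling symmetrises
skewed within-accession frequencies, so no upper bound is asserted. On
the reference fixture the clusters retain 86–89% of their total
diversity, while the within-accession stratum is erased outright: the
pooled AMOVA collapses to a two-level analysis and
accession-level structure becomes untestable. That asymmetry — most
diversity kept, sub-group resolution lost — is the package's
formalisation of what pooling costs.

## PCA and PC dispersion

Accession-level PCA runs on the accessions × markers allele-frequency
matrix; individual-level PCA on dosages with locus-mean imputation of
missing calls. Both are column-centred, unscaled singular value
decompositions with a deterministic sign convention (largest-magnitude
loading positive per component), and all components are retained.
Because the rotation is orthogonal, distances in full PC space equal
distances in the centred (imputed) input space; this isometry is the
anchor of the PC-dispersion statistic — the mean and variance (population
formula, dividing by the number of pairs) of all pairwise distances
among an accession's individuals — and makes the centring/scaling choice
the only free parameter, which is why we log it in the result object.
Low dispersion means a homogeneous seed lot; an inflated dispersion
*variance* is the tell-tale of a near-identical pair (sibs or clones
from polyembryonic seed) sitting inside an otherwise diverse accession.
`flag_near_identical()` screens within-accession pairs by
identity-by-state over shared calls (default threshold 0.99 over at
least 100 shared loci — the threshold is a convention, prominently
surfaced, not an estimate), and the de-duplication helper keeps the
lexicographically first id so re-analyses are reproducible.

## The synthetic-data generator

Validation needs panels with known truth. The generator uses the
Balding–Nichols hierarchy: ancestral frequency $p_0$ per locus, cluster
frequencies Beta-distributed with variance $p_0(1-p_0)F_{CT}$,
accession frequencies likewise with $F_{SC}$, genotypes drawn with
inbreeding $F_{IS}$. Ascertainment is rejection sampling: candidate
loci are kept only when a fixed discovery sample (default 8 individuals
from cluster 1) carries at least 2 minor-allele copies, reproducing the
rare-allele deficit of real array panels; configurations whose
acceptance rate falls below 1e-4 are rejected with a diagnostic rather
than looping forever. Missing calls are masked completely at random per
cluster, labelled clones can be appended with a small per-locus error
rate (default 0.002, typical array repeatability), and map positions
and coordinates are attached.

Defaults were chosen once as a realistic mid-size panel: 3 clusters ×
8 accessions × 6 individuals, 600 markers, $F_{CT} = 0.03$,
$F_{SC} = 0.10$, $F_{IS} = 0$, ancestral frequencies Uniform(0.1, 0.9)
(array SNPs are pre-selected to be common), 4% missing calls, 7
chromosomes. What the generator does *not* emulate: linkage
disequilibrium (loci are independent, so haplotype-module tests rely on
frequency structure, not LD), selection, or demography through time.
Tests passing on these panels therefore validate the estimators'
frequency-level behaviour; they say nothing about LD-driven effects in
real data.

## Numerical choices and validation scales

Tolerances and problem sizes used by the validation suite, all chosen
as the package's own conventions: oracle equivalence of diversity,
distance, Nei-D and AMOVA computations is checked to 1e-10 against
naive loop implementations on panels of up to 30 individuals;
$F_{CT}$ recovery uses 20 replicates of the default panel shape at
targets 0.05/0.15/0.30 with an acceptance band of ±0.03; permutation
calibration uses 200 null replicates at 199 permutations each
(p-values are valid at any permutation count; the package's analysis
default remains 999) with the empirical 5% rejection rate required to
fall in [0.02, 0.09], the three-sigma binomial band around 0.05; the
PC-dispersion isometry is required to hold to 1e-8. Degenerate inputs
are errors, not silent results: empty panels after QC, constant Mantel
matrices, pairs sharing no called loci, reference groups with zero
haplotype diversity, strata with a single unit (reported as
not-testable).

## Limitations

Biallelic SNPs only; no genotype calling from intensities, no LD or
haplotype-block detection, no Bayesian clustering (the package exports
the standard two-row integer input format for external clustering
software instead), no spatially explicit models beyond the Mantel test.
The pooled emulation ignores unequal DNA contributions and read-count
noise of sequencing pools. Real deposited archives may arrive pre- or
post-QC; the loader accepts either, and `apply_qc()` on an already
clean panel is a no-op by design.
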