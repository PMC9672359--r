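---
title: "Methods: TE proximity, heterozygosity and selection across an inbreeding gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE proximity, heterozygosity and selection across an inbreeding gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

Self-fertilizing plant populations should lose heterozygosity quickly, yet
many keep evolving. One candidate mechanism is the mutagenic reach of
transposable elements (TEs): mutation and methylation effects extend a few
kilobases beyond a TE copy, particularly downstream of its orientation, so
loci near certain TE superfamilies might retain functional heterozygosity
even under intense inbreeding. `tehet` implements a reusable pipeline for
testing that idea on biallelic SNP panels: it annotates each SNP with its
nearest-TE context, quantifies inbreeding and differentiation, scans for
balancing and divergent selection with two complementary methods, models
the probability that a locus is heterozygous as a function of TE context,
and checks whether TE-associated selection signatures reproduce across
independent evolutionary lineages.

# Data model and conventions

A `genotype_table` holds a complete-case samples-by-SNPs matrix of
alternate-allele counts (0/1/2) plus population and lineage labels. SNPs
with any missing genotype are dropped first, then SNPs with pooled minor
allele frequency below 0.05; both counts are reported and always sum with
the retained count to the input count.

All coordinates are 1-based inclusive, exactly as in VCF and GFF3. The
package performs no internal coordinate conversion at all, which removes
the usual source of off-by-one drift.

Nearest-TE distance is edge-to-position in base pairs, exclusive of the TE
itself: a SNP inside a TE is at distance 0, an adjacent base at distance 1.
Ties between equidistant TEs go to the lower start coordinate, then the
lexicographically smaller identifier, so annotation is deterministic even
inside TE islands. Orientation ("sense") is TE-strand-aware by default: for
a `+` TE, positions beyond its end are downstream; for a `-` TE the
reverse; TEs of unknown strand fall back to genomic forward orientation,
and `sense_mode = "genomic"` applies that convention throughout
(annotation pipelines differ on this point, so both are provided).

# Inbreeding and differentiation

Per-sample inbreeding is `F_IS = 1 - Ho/He`, with `Ho` the sample's
heterozygous fraction over loci polymorphic in its population and `He` the
mean unbiased expected heterozygosity `2*p*q*2n/(2n-1)` from its
population's allele frequencies (`2n` = sampled alleles). The allele-count
small-sample correction makes the estimator unbiased under
Hardy-Weinberg; monomorphic loci carry no information about heterozygote
deficit and are excluded from both means. Per-locus differentiation is the
Weir-Cockerham (1984) variance-component estimator of F_ST, which may be
slightly negative at undifferentiated loci.

Relatedness clusters — the categorical correction used by the
heterozygosity models — are k-means partitions of the first K
principal-component scores of the scaled genotype matrix (default K = 3,
with 25 restarts and a fixed seed; labels are renumbered by first
appearance so equal partitions always get equal labels).

# The two selection scans

**PCA-Mahalanobis scan.** Genotypes are centered and scaled per SNP by
`sqrt(2p(1-p))`; the first K principal components describe background
structure; every SNP is regressed on the K component score vectors and the
K regression z-scores are combined into a squared Mahalanobis distance
using a robust minimum-covariance-determinant estimate of their
covariance. Distances are rescaled by the genomic inflation factor (median
distance over the chi-squared-K median) and converted to p-values on
chi-squared-K; q-values are Benjamini-Hochberg (chosen over a pi0
estimator: fewer tuning choices, conservative). K defaults to 3 — the
eigenvalue-supported choice for the panels this pipeline targets — but
should follow the scree of the panel at hand; a six-deme synthetic panel,
for example, supports K = 5.

**Bayesian F_ST decomposition.** Following the logistic decomposition of
locus-by-population F_ST into locus effects (alpha) and population effects
(beta), allele counts are beta-binomial with mean the ancestral frequency
`p_i` (uniform prior) and overdispersion `F_ST(i,j) =
plogis(alpha_i + beta_j)`. A reversible-jump move toggles each alpha
between zero and a N(0, 1) slab, with prior odds 10 : 1 for neutrality;
proposing the jump from the slab itself makes proposal and prior densities
cancel. Updates are random-walk Metropolis on logit(p), alpha and beta,
with proposal scales tuned to 25-45% acceptance during pilot runs. Desk
defaults: 10 pilot rounds of 1,000 sweeps, 5,000 burn-in, 25,000 sampling
sweeps thinned by 10; all randomness comes from R's RNG, so a seed makes
chains exactly reproducible. Evidence is the log10 posterior odds of
inclusion (clamped away from 0/1 by half a sample); loci are selected by
the Bayesian FDR rule (largest set whose mean posterior probability of
neutrality stays below 0.05) and must additionally exceed log10 PO > 0.5.
A split-chain potential-scale-reduction above 1.1 on any beta logs a
warning.

**Classification.** Balancing = MCMC outlier with negative posterior-mean
alpha. Divergent = MCMC outlier with positive alpha, or (in the default
combined mode) a PCA outlier at q < 0.01 whose Weir-Cockerham theta lies
above the SNP-set median. A `bayescan-only` switch restricts calls to the
MCMC arm, so per-superfamily outlier summaries can be produced under
either definition of an outlier.

**Purifying discrimination.** Among balancing calls (negative alpha), a
SNP is a purifying-selection candidate when (i) its minor allele frequency
is below the median MAF of neutral SNPs, and (ii) at the group level,
negative-alpha SNPs show lower median MAF at 0-fold than at 4-fold sites —
or the SNP itself is 0-fold with MAF below the 4-fold median. A per-SNP
variant of (ii) is available behind a flag; with no fold annotation the
rule falls back to (i) alone with a warning. The neutral median was fixed as the
condition-(i) reference statistic: it is robust and has no tuning.

# The heterozygosity model ladder

The response is, per SNP and relatedness cluster, the heterozygote count
out of the cluster's sample count, fitted with a binomial distribution and
complementary log-log link (IRLS, relative deviance change below 1e-8, at
most 100 iterations). Relatedness enters as fixed cluster intercepts by
default — with few clusters and many observations this is a deliberate,
cheaper stand-in for a full random-intercept formulation — and a
Laplace random-intercept option (glmmTMB) is provided; on well-separated synthetic data the two agree in sign.
Separation (|coefficient| > 15) triggers a warning and a Firth-style
Jeffreys-penalized refit. Distance to the nearest TE is rescaled to kb and
always entered with linear and quadratic terms, both reported, so a
proximal increase and an intermediate-distance peak are both testable.

The ladder: exploratory Models 0a/0b (`H ~ superfamily:sense + distance`)
on the inbred (`F_IS > 0.6`) versus outcrossed (`F_IS <= 0.6`) sample
subsets; Model 1 (`H ~ distance x TE-effect + TE-effect x sense + distance
x sense`) on everything; Models 2a/2b (`H ~ F_IS x selection + sense x
selection`) on the H_TE and H_0 SNP subsets, with F_IS entering as the
cell's mean sample value (the package fixes this aggregation); Model 3 (`H ~ TE-effect + sense`) on
an independent outcrossing lineage, split at `F_IS = -0.3` to separate
mating-system from demographic effects.

**The TE-Effect grouping** is derived from Models 0a/0b in three steps,
with CACTA as the reference superfamily (a superfamily of intermediate
heterozygosity makes contrasts interpretable in both directions):

1. *Gate.* The superfamily-by-sense term must be significant in a type-II
   analysis of deviance of Model 0a; otherwise the set is empty. Running a global test before factor-level screening is
   what keeps the procedure's family-wise false-positive rate near the
   nominal level when nothing is going on.
2. *Elevation under inbreeding.* A candidate superfamily's
   downstream-sense contrast against CACTA must be positive with Wald
   p < 0.05 in Model 0a. Membership is evaluated on the downstream
   stratum because the hypothesized mutagenic mechanism is
   downstream-specific. Significance is uncorrected p < 0.05 — factor-level
   screening, not a corrected multiple-testing procedure.
3. *Inbreeding dependence.* The candidate's 0a-minus-0b interaction
   contrast must be significantly positive. Because the identical SNP set
   underlies both subsets' cells, this difference cancels between-SNP
   allele-frequency composition exactly — a raw "not significant in 0b"
   veto does not: a superfamily whose downstream SNPs happen to sit at
   intermediate allele frequencies shows spuriously "significant"
   elevation in both subsets, because the binomial Wald test ignores
   between-SNP heterogeneity. Superfamilies elevated alike in both
   subsets (the LINE pattern) fail this step and are excluded.

H_TE labels SNPs nearest to a member superfamily; everything else is H_0.
If the set is empty, Models 2a and 3 are skipped with an explicit report
and Model 1 drops its TE-effect terms.

# The synthetic-data generator

The generator draws genotypes directly from inbreeding-adjusted
Hardy-Weinberg proportions: `P(het) = 2q(1-q)(1-F)`, `P(homALT) = q^2 +
q(1-q)F`, with F clamped to its feasible lower bound
`-min(q,1-q)/max(q,1-q)` so probabilities stay valid at negative F.
Because downstream analyses consume only F, direct draws make ground truth
exact; no generations of selfing are simulated. Per-population allele
frequencies come from beta distributions around an ancestral frequency,
with class-specific dispersion: neutral (baseline frequency uniform on
0.1-0.9, dispersion 0.05), balancing (intermediate frequency 0.45-0.55,
dispersion 0.002 — low F_ST, high MAF), divergent (dispersion set to hit a
target across-population frequency SD, default 0.35), purifying (global
MAF 0.05-0.10, low dispersion, site tagged 0-fold). Class proportions
default to 80/8/10/2%.

The TE landscape places exact per-superfamily counts (13 superfamilies, 30
copies each by default) uniformly on the chromosomes with log-normal
lengths and uniform strands; overlaps are allowed (TE islands). The TE
effect is planted as an excess-heterozygosity term: SNPs downstream of a
TE-effect superfamily (default Copia and Harbinger) within 3,500 bp — the
mutational reach reported for TEs — use `F_eff = max(0, F_pop -
delta_TE)`, with `delta_TE = 0.6` by default, a magnitude chosen once so
that the planted effect is comfortably detectable by the Model-0
procedure at panel scale; there is no canonical generative magnitude
for such an effect.
Ground truth (class, nearest-TE distance and sense computed by an
independent brute-force scan, effect flags, below-filter flags, true F per
population) is recorded alongside, and `emit_fixture()` writes
VCF/GFF3/TSV files that re-read to the same objects, byte-identically
under a fixed seed.

Default panel structures mirror typical sampling designs: a mixed-mating
13-population panel of 4 samples each spanning F from 0.9 to -0.1, and an
outcrossing 18-population panel of 2-3 samples with F from -0.64 to -0.24
(`sim_config_europe()`). Note one deliberate simplification: with the
baseline frequency spread, strongly negative F values are partially
clamped at extreme frequencies, so realized F_IS in the outcrossing panel
is less negative than the nominal range.

What the generator does **not** emulate: linkage and recombination (SNPs
are unlinked by construction, as in a one-SNP-per-RAD-locus panel),
coalescent history, explicit transposition or sequence-level mutation,
genotyping error and depth variation, and any fitness model behind the
selection classes — the scans only ever see allele-count patterns.
Passing recovery tests therefore shows the estimators and decision rules
are correct and calibrated under the assumed statistical structure, not
that the biological conclusions transfer to any particular real dataset.

# Validation scales and numerical choices

The test suite's acceptance checks run at these scales (chosen as
realistic panel sizes that keep the full suite comfortably inside a desk
session): F recovery at 6 populations x 20 samples x 3,000 neutral SNPs
(within 0.05 of truth, F from -0.3 to 0.9); nearest-TE equivalence with a
brute-force oracle on 200 random instances up to 1,000 x 1,000 including
dense landscapes with frequent ties and containment; scan calibration on
structureless simulations (inflation factor within 0.8-1.2, q < 0.01
fraction at most 2%, combined call rate at most 5% at 1,000 null SNPs with
desk-scale chains); scan power on planted divergent loci (PCA arm at 5,000
SNPs and 6 x 24 samples with scree-chosen K = 5, at least 80% at q < 0.01;
MCMC arm at 800 SNPs with desk-scale chains, at least 70% recovered with
positive alpha and log10 PO > 0.5); purifying-rule truth table; cloglog
coefficients against an independent Newton-Raphson maximization to 1e-6
and the intercept closed form `log(-log(1-p))` to 1e-10; TE-Effect
recovery of the planted {Copia, Harbinger} set over 50 seeds (at least 90%
with the planted pair recovered; at least 90% empty sets when no effect is
planted); hypergeometric-tail equality for all margins up to 50; and
cross-lineage correlation against frozen arithmetic plus a 50-seed
shared-signature power check.

The acceptance script (`scripts/acceptance.R`) reruns the whole pipeline
on two seeded panels — the 13-population x 4-sample inbreeding-gradient
lineage and the 18-population x 2-3-sample outcrossing lineage, 1,200
SNPs each — with reduced chains (4 x 400 pilot, 2,000 burn-in, 8,000
sampling sweeps) and a scree-chosen K = 12 for the PCA arm, and reports
the computed quantities as JSON. At this panel scale the posterior odds
rarely support REDUCED differentiation strongly enough to clear the
log10 PO > 0.5 bar (8 alleles per population), so balancing-class calls
can be absent even though most planted balancing loci show negative
posterior-mean alpha; quantities that are incomputable for that reason
are omitted from the JSON rather than fabricated.

Other numerical choices: the MCD covariance for the Mahalanobis step is
the fixed robust estimator (K = 1 falls back to median/MAD); monomorphic
loci report theta = 0; enrichment tests are gene-level (SNPs deduplicated
to genes to avoid pseudo-replication; a SNP-level switch exists for
analyses that treat markers as the unit) with classic independent-per-term Fisher
semantics; copy number and Ka/Ks are log1p-transformed before the
essentiality ANOVA (raw-scale option retained); genes inherit the
highest-priority class among their SNPs (balancing > divergent >
neutral).

# Known limitations

The fixed-intercept default for relatedness understates uncertainty
relative to a random-effects treatment when clusters are few and
heterogeneous; the glmmTMB option exists for that case. The Wald contrasts
of Model 0 treat SNP cells as binomial, ignoring between-SNP
heterogeneity; step 3 of the TE-Effect procedure removes the resulting
composition bias from the inbreeding-dependence decision, but step 2
inherits mild anticonservatism, which is why the exact composition of the
derived set can include an occasional extra superfamily at p < 0.05 —
consistent with uncorrected factor-level testing across 13 superfamilies.
The MCMC arm's desk-scale chains are sized for panels of a few hundred to
a few thousand loci; genome-scale runs should raise the chain lengths by
config. The generator's direct-draw model cannot reach strongly negative
F at extreme allele frequencies (clamping), and plants no linkage, so
associative-overdominance signatures cannot arise mechanistically — the
purifying rule is exercised only through its planted frequency structure.
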