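---
title: "Population genomics of structural variants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population genomics of structural variants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svpopgen)
```

# Scope

`svpopgen` analyses multi-population diploid cohorts of structural
variants (SVs): deletions, duplications, inversions, insertions and
translocations of 50 bp to 1 Mb, genotyped as biallelic
presence/absence loci in a merged multi-sample VCF. The package covers
the population-genomic stages that sit downstream of SV calling:
cohort filtering, diversity and differentiation statistics, selection
scans, breakpoint/interval genomics, genic annotation, cross-species
convergence testing, introgression scanning and association
post-processing. SV calling itself, multi-caller merging, coordinate
liftover, haplotype phasing and kinship-corrected mixed-model fitting
are out of scope.

Every stage is exercised end to end on cohorts from the package's own
simulator, whose defaults emulate the structure of large
sheep/goat-style resequencing panels: a DEL-dominant type mix, a
rare-skewed allele-frequency spectrum, drift-structured populations
partitioned into wild/native/improved groups, clustered breakpoints
and SV-linked quantitative phenotypes.

# Coordinate and genotype conventions

VCF records are 1-based inclusive; all interval arithmetic is done in
0-based half-open (BED) coordinates, with `sv_intervals()` converting
at the boundary (`[start - 1, end)`). Insertions are treated as 1-bp
points at the insertion site: length-fraction overlap rules are
undefined for sequence that is not in the reference. Genotypes are
alt-allele dosages 0/1/2 with a dedicated `NA` for missing calls, so
every frequency denominator counts non-missing calls only; a stratum
with no called genotype at a locus yields an undefined (`NA`)
frequency, never a silent zero. Multiallelic records are rejected at
the reader (merged SV call sets are biallelic presence/absence; split
upstream if needed).

# Diversity statistics

Per-site nucleotide diversity uses the small-sample-corrected pairwise
difference

$$\pi = \frac{n}{n-1}\sum_{i \ne j} x_i x_j \pi_{ij}
      = \frac{n}{n-1}\, 2p(1-p), \qquad n = 2\,n_{\text{called}},$$

which equals the mean number of allele differences over all
$\binom{n}{2}$ sequence pairs; the test suite asserts this equivalence
against a brute-force pair enumeration. Windowed values (default 10 Mb
windows) are reported under **both** window conventions — per base
pair (`pi_bp`, sum over the window divided by window length) and per
SV site (`pi_site`, mean over sites) — because field tools disagree on
the denominator and the two differ by orders of magnitude; columns are
named explicitly so no reader can confuse them.

Heterozygosity is the proportion of heterozygous calls among
non-missing calls at segregating sites. Linkage disequilibrium is the
squared Pearson correlation of genotype dosages (phase-free), computed
within chromosomes up to a 300-kb default distance cap and summarised
as mean r² per distance bin. This genotype-correlation r² is a
deliberate dialect difference from haplotype-based (EM-phased) r²: it
is deterministic and needs no phasing, at the cost of attenuation
relative to haplotype r² when genotypes are noisy.

# Differentiation and selection scans

`wc_fst()` implements the Weir–Cockerham (1984) two-level diploid
estimator from genotype counts: variance components $a$ (among
populations), $b$ (among individuals within populations) and $c$
(within individuals, driven by observed heterozygosity), with
$\hat\theta = a/(a+b+c)$. Per-site values are kept unclamped (negative
estimates are informative noise); the genome-wide value is the
weighted ratio of sums $\sum a / \sum (a+b+c)$, which is the
convention of the common command-line tools, and a mean-of-ratios
alternative is reported alongside. Loci monomorphic across both
populations (or with fewer than two called diploids in either) are
undefined and excluded from the sums, with counts reported. The
estimator is checked against an independent hand transcription of the
published formulas, and against the Balding–Nichols simulator: with
both populations at drift $F$, the genome-wide weighted estimate
recovers $F$ within ±0.03 at 5000 loci and 30+30 samples.

The **global F_ST** of a locus is the mean over populations of the
one-population-versus-rest estimate, matching the breed-versus-rest
convention used for improvement-era scans; with two populations it
degenerates to the single pairwise value.

**Permutation P-values** follow the printed rule: `B = 200` label
permutations, $P = \#\{\hat\theta_{\text{perm}} >
\hat\theta_{\text{obs}}\}/B$, strict "higher than", so $P = 0$ is
reportable. Two design points deserve attention:

* By default one label permutation per replicate is shared across all
  loci. This preserves the inter-locus correlation structure of the
  null; per-locus independent shuffles are available (`per_locus =
  TRUE`) and are what the uniformity calibration uses, since the KS
  test needs exchangeable loci.
* On discrete dosage data the statistic takes few values and
  permutation ties with the observed value are common (about 20% of
  replicates at 20-vs-20 samples). The strict rule drops ties, which
  makes it anti-conservative (roughly doubles the nominal 5% rate in
  our null experiments). This is a property of the printed rule, not
  of the implementation; `ties = "midp"` (half-weight to ties,
  approximately uniform null P) and `ties = "geq"` (all ties counted,
  always valid, conservative) are provided as opt-in alternatives, and
  the calibration tests assess uniformity on mid-P and validity on the
  `geq` rule.

**DI_SV** is the signed difference in derived-allele frequency between
a domestic and a wild population. The ancestral allele is the majority
allele among the wild population's non-missing allele copies; exact
ties are flagged ambiguous and excluded, loci without wild calls are
unpolarizable. The sign convention (domestic − wild, candidates from
the upper tail) targets derived-allele rises in domestic populations;
the polarization source can be fixed independently of the two
frequency arguments (`polarize_with`), which makes the statistic
antisymmetric under argument swap.

**PBS** uses the standard branch-length construction
$T = -\log(1 - \hat\theta)$, $\mathrm{PBS}_1 = (T_{12} + T_{13} -
T_{23})/2$, with $\hat\theta$ clamped to at most $1 - 10^{-9}$ only to
keep the logarithm finite; negative per-site estimates pass through
($T < 0$ allowed).

**Candidate calling** is rank-based: the top-$q$ threshold over $m$
defined loci is the value at rank $\lceil qm \rceil$ of the descending
order, ties at the threshold included; combined rules (e.g. permutation
$P < 0.05$ **and** top-5% DI_SV) are set intersections, and the
threshold record stored with every result makes the flags exactly
reproducible. On the simulator's study conditions (30+30 samples, 2000
loci, 5% of loci shifted by δ = 0.6) the intersection rule attains
precision and recall well above 0.5.

Group-level frequency contrasts (e.g. prolific versus non-prolific
populations) use a two-sided Wilcoxon rank-sum test on per-population
allele frequencies via `stats::wilcox.test` (exact for small untied
samples, normal approximation with tie correction otherwise), with
Benjamini–Hochberg adjustment across the tested set; fully tied inputs
report the maximal attainable $P = 1$.

# Breakpoint and interval genomics

Breakpoint density counts SV breakpoints (two per DEL/DUP/INV, one per
INS, one per TRA record) in 1-Mb windows advanced by 500 kb, so every
interior position is covered by exactly two windows and a breakpoint
deliberately counts in both. Hotspot windows are the top decile of
counts (rank cutoff with threshold ties included), computed genome-wide
by default — the per-chromosome variant is an option — and contiguous
hotspot windows merge into hotspot regions. Telomeric enrichment
compares per-1-Mb-bin breakpoint counts between the first/last 5 Mb of
each chromosome and the remainder with a two-sided Wilcoxon rank-sum
test; both chromosome ends are used because sheep and goat assembly
coordinates do not encode centromere positions (the species'
autosomes are acrocentric), and chromosomes can be excluded (the
incomplete X, for instance).

Interval comparisons all go through one fractional-overlap matcher
that reproduces the BEDtools semantics used in this field: a pair
matches when the overlap covers at least fraction $f_a$ of the first
interval and/or $f_b$ of the second (`either` = `-f x -F y -e`,
`invert` = `-v`). Novelty against a published catalog uses the 30%
reciprocal either-side rule; QTL matching uses 50% (QTLs longer than
5 Mb are excluded when read); ATAC Peak-SVs need at least 50% of the SV
length inside the *merged* peak set, with overlap allowed to
accumulate across merged peaks. QTL fold enrichment is
observed/expected under uniform placement — expected = carried SVs ×
(merged QTL span / genome span) — with a 0.5 pseudocount on zero
observed counts (flagged) so heatmaps stay finite; the formula is this
package's interpretation, since the quantity's name alone does not fix
one. Candidate enhancers are merged peaks not intersecting any
strand-aware TSS ± 2 kb promoter window, and SV-supported enhancers
must contain at least half of some SV's length.

# Genic annotation

SVs are classified into the seven genic categories (intergenic,
intronic, exonic, 2-kb upstream, 2-kb downstream, 3′ UTR, 5′ UTR) by
positional overlap of at least 1 bp — fraction rules apply only to the
QTL/peak/novelty comparisons above — and an SV spanning several
features carries several categories simultaneously; only an SV
touching no feature or flank of any gene is intergenic. UTRs are
derived from BED12-style thick (CDS) boundaries and are simply
unassignable for genes without an annotated CDS; nothing is inferred.
Summaries report both SV-category incidences and distinct-SV counts,
plus the SV-gene bookkeeping (genes with exonic/intronic SVs, their
percentages and the intron/exon gene-count ratio).

# Convergence and introgression

The convergence question — do two species' candidate gene sets share
more one-to-one orthologs than chance — is answered by drawing random
candidate sets of the observed sizes from an explicit universe of
ortholog pairs and counting shared pairs, $P = \#\{k_{\text{perm}} \ge
k_{\text{obs}}\}/B$. The universe size $U$ is a required argument
because the answer moves materially with it (all orthologous genes
versus SV-genes only), and the hypergeometric expectation $n_A n_B /
U$ is always reported alongside so that dependence is visible rather
than buried.

Introgression candidates are SVs whose allele-frequency pattern shows
a wild-to-domestic transfer signature: present in exactly one domestic
population, frequency exactly 0 in every other domestic population,
fixed (frequency exactly 1) in at least one wild species, and absent
from the designated outgroup species (to exclude shared ancestry).
"Exactly" is over observed calls with a configurable tolerance
defaulting to 0, and a population with no called genotype at a locus
fails the absence/fixation checks — missing data cannot certify
absence. Presence (frequency > 0), not fixation, is required in the
recipient. After per-SV calling, a population is reported only when it
carries strictly more than 2 candidate SVs, which guards against
drift-driven singletons.

# Association post-processing

`per_sv_association()` is a deliberate single-marker ordinary
least-squares score (slope, standard error, two-sided t-test) for
exercising the summary-statistic pipeline on simulated phenotypes;
population-structure-corrected mixed models are out of scope, and
`variance_explained()` accepts externally produced effect sizes so
real mixed-model output can be post-processed. The variance-explained
formula

$$v = \frac{2\hat\beta^2\,\mathrm{MAF}(1-\mathrm{MAF})}
{2\hat\beta^2\,\mathrm{MAF}(1-\mathrm{MAF}) +
 2N\,se(\hat\beta)^2\,\mathrm{MAF}(1-\mathrm{MAF})}$$

is evaluated as printed; the MAF factor cancels algebraically to
$\hat\beta^2/(\hat\beta^2 + N\,se^2)$, and the test suite asserts that
identity across random parameter draws. The qPCR copy-number rule
calls a normal copy number of two for ΔΔCT values in [1.414, 2.449],
bounds inclusive ("between ... and" read inclusively).

# The simulator and what it does (not) emulate

`simulate_cohort()` draws ancestral frequencies $p_0 \sim
\mathrm{Beta}(0.3, 2)$ (rare-skewed), population frequencies from the
Balding–Nichols construction $p_{\text{pop}} \sim \mathrm{Beta}(p_0
(1-F)/F,\ (1-p_0)(1-F)/F)$ and genotypes binomially — chosen over
coalescent simulation because the closed-form F_ST target enables
parameter-recovery tests at desk scale. Breakpoints mix a uniform
background with Gaussian clusters; the default type mix {DEL 0.77, DUP
0.05, INV 0.02, INS 0.10, TRA 0.06} approximates a domestic-sheep call
set; lengths are log-uniform in the calling window. Selection is
planted as a direct derived-frequency shift δ (clipped to [0, 1])
rather than a selection coefficient, because frequency differentiation
is what the scans measure; introgressed loci are constructed to
satisfy the three filter criteria exactly on realized genotypes, with
bounded resampling of the recipient's genotypes. TRA records are
simulated as single-locus records with one genotype column, matching
the merged-VCF representation. Everything is deterministic given the
scenario seed, and every stochastic operation in the package takes an
explicit seed that run manifests record.

Known gaps between the simulator and real data: loci are independent
(no LD beyond explicitly duplicated columns, no recombination maps),
there is no genotyping error model or batch structure, missingness is
not simulated by default, and the Beta ancestral law is smoother than
a real site-frequency spectrum. In particular, at 60 samples a
MAF < 0.01 threshold admits only singletons, so the published-scale
statement "about a third of SVs are rare" cannot be reproduced at that
threshold and cohort size under any Beta law; the rare-skew tests
therefore assert the spectrum's *shape* (a quarter of segregating loci
below MAF 0.05, the lowest band dominating the highest) rather than
the published percentage. Passing tests consequently demonstrate
correctness of the statistical machinery under a clean,
independent-locus null with known truth — not robustness to the
artefacts of real short-read SV call sets.

# Problem sizes and numerical choices

The test and acceptance workloads are sized for a single CPU at desk
scale: 5000 loci × 60 samples for drift recovery, 2000 loci for
selection-scan power, 600 loci for introgression and hotspot recovery,
400 null replicates for calibration rates, B = 200 permutations
(10 000 where checked against the 70-split exhaustive enumeration).
Scenario defaults are fixed once in `sv_scenario()` and shared by the
tests and `scripts/acceptance.R`.

Numerical corner cases, in one place: undefined statistics are `NA`
and never silently zero; monomorphic loci drop out of F_ST sums with a
reported count; top-fraction thresholds include ties; PBS clamps
$\hat\theta$ only at the upper end; the QTL log2 fold uses a 0.5
pseudocount flagged in output; the accumulation curve uses nested
subsamples so each replicate is monotone by construction; filters
apply length, then missingness, then MAF, and the removal tally is
reported per rule in that order.
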