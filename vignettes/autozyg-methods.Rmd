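---
title: "Models and methods in autozyg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in autozyg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the measures of inbreeding, the animal model behind the
depression regressions and the genome scan, the simulator used to
validate everything, and the numerical and design choices that were
genuinely open.

## Measures of inbreeding

**Pedigree inbreeding.** `inbreeding_ml()` computes
`F = diag(A) − 1` of the numerator relationship matrix by the
Meuwissen–Luo ancestor-tracing algorithm: animals are processed in
topological order and each `A_ii` is accumulated as `Σ_j L_ij² m_j`
over the ancestors `j` of `i`, where `m_j` is the Mendelian-sampling
variance of `j` given its parents' inbreeding. `A` is never
materialised, so memory is linear in pedigree size. A dense tabular
construction of `A` (`relationship_matrix_tabular()`, guarded at 2,000
animals) serves purely as a test oracle; the suite checks agreement to
1e-10 on dozens of random pedigrees, and checks `a_inverse()` —
Henderson's sparse rules with inbreeding — by verifying
`A⁻¹A = I` to 1e-8.

Unknown parents contribute relationship zero and founders have
`F = 0`; no genetic-group structure is modelled, because groups affect
breeding-value estimation rather than the inbreeding coefficients
computed here. Pedigree completeness over `d` generations is the
standard index `C = (1/d) Σ a_i` with `a_i` the proportion of known
ancestor slots in generation `i`; an unknown ancestor blocks its own
ancestors from counting (path blocking). Cohort selection
(`filter_cows()`) takes females with `C = 1` over the first two
generations, born in or after a configurable year (default 1995 —
"born after 1994" admits either reading of the boundary year, so the
bound is a parameter).

**Genomic measures.** With genotypes coded 0/1/2 (code 2 counts a
chosen allele) and base frequencies `p_m`:

* `grm_self_relationship()` averages the per-SNP term
  `(x² − (1+2p)x + 2p²) / (2p(1−p))` over usable SNPs. This is the
  GRM diagonal minus 1: it is 0 in expectation for a non-inbred animal
  at Hardy–Weinberg base frequencies, −1 for a fully heterozygous
  animal, +1 for a fully homozygous one. The printed form of this
  estimator in parts of the literature carries an additional "−1",
  which would send a fully heterozygous animal to −2 and every
  outbred population mean to −1; we read that "−1" as cancelling the
  implicit "1 +" of the GRM diagonal. A `variant = "vanraden_diag"`
  option provides the ratio form `Σ(x−2p)² / (2Σp(1−p)) − 1` instead.
  Monomorphic SNPs are excluded (their term divides by zero); missing
  genotypes are dropped from both the sum and its denominator.
* `homozygosity_proportion()` is the fraction of non-missing genotypes
  that are homozygous; monomorphic SNPs are retained, since nothing in
  this definition requires polymorphism.
* `detect_roh()` finds maximal stretches of consecutive homozygous
  genotypes within a chromosome. A heterozygote, a missing call or a
  chromosome end terminates a run, and runs contain no missing calls —
  the conservative choice, made explicit because array data leave the
  treatment of missing calls inside runs genuinely open. Run length is
  counted in SNPs; physical spans in Mb are reported for summaries.
  `roh_f(n)` is the proportion of all SNP positions inside runs of at
  least `n` SNPs, non-increasing in `n` by construction.

Allele frequencies default to every genotyped animal (the simulator
can add non-phenotyped "reference males"), mirroring how reference
populations are assembled in practice. Parentage is sanity-checked by
`opposing_homozygotes()`: loci where putative parent and offspring are
homozygous for different alleles. More than 20 such loci on a ~45k
array flags the pair as incompatible; at a 0.1% genotyping error rate
(read as one misread allele per erroneous call) true pairs virtually
never cross that threshold, which the suite verifies by simulation.

## The repeated-records animal model

All depression regressions and every scan position fit

y = µ + HYS + parity + month + b₁·age + (covariates) + pe + u + e,

with herd-year-season, parity and calving month as fixed factors
(treatment contrasts, first level dropped; rank-deficient columns are
detected by a QR decomposition at tolerance 1e-9 and reported as
inestimable), age at first calving as a linear covariate, a per-cow
permanent-environment effect `pe ~ N(0, I σ²_pe)`, an additive genetic
effect `u ~ N(0, A σ²_a)` through the sparse pedigree `A⁻¹`, and
residual `e ~ N(0, I σ²_e)`. Solutions come from Henderson's
mixed-model equations assembled sparsely; standard errors are the
fixed-effect block of the inverse coefficient matrix times `σ²_e`, and
p-values are two-sided Wald z-tests computed on the log scale so that
extreme significance levels do not underflow. With both random
variances zero and single records the solver reduces exactly to
ordinary least squares, and the suite checks the general case against
a dense GLS solve with an explicit `V⁻¹` on toy data.

**Variance components.** We estimate `(σ²_a, σ²_pe, σ²_e)` by REML
with a derivative-free strategy: the exact REML log-likelihood is
evaluated from one sparse Cholesky factorisation of the mixed-model
equations per candidate point,

−2ℓ = (n−p)·log σ̂²_e + q_a·log λ_a + q_pe·log λ_pe + log|A| +
log|C(λ)| + const,

with the residual variance profiled out analytically
(`σ̂²_e = y'Py/(n−p)`) and the two variance ratios maximised by
Nelder–Mead on the log scale (criterion tolerance 1e-12, with a
restart from the optimum). `log|A|` is `Σ log m_i` from the
Mendelian-sampling variances, so no dense determinant is ever formed.
An EM-style update sequence was considered and rejected: every EM step
needs traces of blocks of the *inverse* coefficient matrix, which is
dense-inverse work at tens of thousands of equations, whereas the
profiled likelihood needs only sparse factorisations and lets standard
optimisers converge in a few dozen evaluations. The test suite pins
the criterion to lme4's REML deviance on models lme4 can fit (exact to
four decimals) and to closed-form ANOVA estimators on balanced
layouts. Without repeated records `σ²_pe` is unidentifiable and is
fixed at zero with a warning. Components are re-estimated per
depression fit by default (the alternative — estimating once and
reusing — is supported by passing `vc`), since the covariate set
changes what the fixed part absorbs.

**Depression fits.** `fit_inbreeding_depression()` regresses the
phenotype on pedigree F, `GRM_F`, homozygosity or `ROH_F(n)`; a second
measure can be fitted jointly (pedigree + genomic, or `ROH_F` +
overall homozygosity), and a quadratic term can be added. The
coefficient is reported per unit of the measure and per 1%
(`b/100` identically — a reporting convention, not a refit).

## The ROH genome scan

`roh_gwas_scan()` augments the animal model at every SNP with the
genotype code (additive correction `b₃`) and a run-of-homozygosity
indicator (`b₄`). Two indicator readings are implemented because the
phrase "a run of at least n SNPs present at the position" is
ambiguous: `window_start` (default) marks position `i` when the window
of `n` SNPs beginning at `i` is entirely homozygous — the additive
covariate is then the SNP at the window's start — and `covering` marks
`i` when it lies inside any maximal run of at least `n` SNPs.
Window-start windows that would cross a chromosome end are not
testable and are skipped.

Variance components are held fixed across positions, estimated once
under the covariate-free null model (or supplied). This makes the scan
a bordered-system problem: the null mixed-model equations are
factorised once, and each position needs only two triangular solves
and a 2×2 Schur complement, which the suite verifies is *exactly* the
full joint fit (agreement to 1e-11 on `b₃`, `b₄` and `se₄`).
Per-position re-estimation of components would change estimates
negligibly while multiplying cost by the number of REML iterations.
Positions are skipped — never fatally — when carriers are fewer than
`min_carriers` (default 10, a numerical-stability floor, configurable
to 1), when the indicator is constant, or when the added covariates
are collinear with the model (relative singular-value tolerance 1e-8);
the reason is recorded per position. Missing genotype codes at the
tested SNP are mean-imputed, the standard GWAS convention; missing
calls inside a window simply prevent the window from being fully
homozygous.

Significant positions (`p < 0.001` by default) with the same effect
sign whose windows overlap are merged into regions
(`cluster_significant()`, verified against an all-pairs interval-merge
oracle); favourable/unfavourable labels combine the effect sign with
the trait polarity (milk: higher is better; calving interval: lower is
better). We merge on window overlap only, not across gaps. The FDR is
the expected-false-positive form `p(1−A/T)/((A/T)(1−p))`; `T` defaults
to the tested (non-skipped) position count with the total SNP count
reported alongside, because published applications do not always state
which was used.

## The simulator and what it does (not) emulate

`simulate_herd()` produces a pedigree, genotypes and phenotypes with
known truth:

* **Pedigree** (`simulate_pedigree()`): discrete generations; every
  mating yields an opposite-sex pair of offspring, so full-sib pairs
  always exist for close matings. A configurable fraction of matings
  pairs full sibs (compounding recent inbreeding and long ROH);
  remaining matings draw sires from a small pool (drift inbreeding).
  The paired-litter device is deliberately artificial for cattle — it
  guarantees the availability of close matings without a mate-search
  heuristic, and it leaves the inbreeding arithmetic untouched.
* **Genotypes** (`drop_genes()`): founders carry two labelled gametes
  per chromosome with allele frequencies drawn uniformly on
  [0.05, 0.5]; descendants inherit recombinants with Poisson crossover
  counts (Haldane, no interference — interference is irrelevant at the
  multi-Mb scales ROH work cares about) and 1 cM = 1 Mb. A locus is
  autozygous when both gamete labels coincide, so realised IBD is
  exact, not inferred.
* **Phenotypes** (`simulate_phenotypes()`): the animal-model equation
  above with genome-wide depression proportional to true IBD,
  locus-specific recessive effects that trigger on *autozygosity* at
  the planted locus (identity by descent, not merely by state — this
  is the biological mechanism a ROH scan targets, and it keeps power
  analyses interpretable), breeding values drawn down the pedigree
  with Mendelian-sampling variances from parental F, and HYS, parity
  and month effects drawn from normal distributions with configured
  SDs (enough to exercise factor absorption without modelling herd
  structure).

Defaults are dairy-like: phenotypic SD 1,635 L (Jersey-scale milk
yield), heritability 0.25, repeatability 0.40, depression −25 L per 1%
IBD, age effect 10 L/month. What the simulator does **not** emulate:
selection on phenotype (so no purging), genotyping-batch artefacts and
ascertainment of array SNPs, culling-driven censoring of fertility
records, herd structure in HYS, and X-chromosome dosage. Passing tests
therefore demonstrate the *estimators* behave correctly when their
assumptions hold, not that real cattle data meet those assumptions.

## Validation scales and numerical choices

The acceptance-level suite runs at these problem sizes, chosen as the
largest that keep the whole suite desk-scale while leaving the checks
statistically sharp:

* Oracle equivalence: 50 random pedigrees of 100–500 animals
  (Meuwissen–Luo vs tabular, 1e-10; `A⁻¹A = I`, 1e-8 on ten of them)
  and 100 random 5,000-SNP strings for ROH detection.
* Gene-dropping calibration: slope of realised IBD on pedigree F in
  [0.9, 1.1] with 2,000 loci on **ten** chromosomes of 200 SNPs — with
  only two long chromosomes the genome-wide IBD of related animals
  averages over too few independently segregating segments and the
  slope's sampling spread exceeds the band.
* Depression recovery: −25 L per 1% true IBD at 3,000 cows × 3
  records, recovered within 2 reported standard errors with
  REML-estimated components.
* REML recovery: (0.25, 0.15, 0.60)·σ²_P over 20 replicates of 2,000
  cows × 3 records in 25 paternal half-sib families; each component's
  mean over replicates within 2 empirical standard errors of truth.
* Scan power: a planted recessive window effect of −250 L at 2,000
  cows, 2,000 SNPs under a many-independent-full-sib-lines design:
  600+ founder pairs, five generations of within-line sib mating.
  Each line accumulates high autozygosity with long runs, so 50-SNP
  window carrier frequencies sit near 0.35–0.40 and, because lines
  segregate independently, both the carrier frequency and the
  long-range background correlation are stable across seeds. The
  genome-wide depression term is switched off in this design because
  it loads on *every* ROH indicator and would confound a
  locus-specific power measurement. Localization = the minimum-p
  position falls within 25 SNPs of the SNP span covered by windows
  containing the planted locus; ≥ 8/10 seeded replicates. Type-I: the
  significant fraction among tested positions of four null scans
  stays within 3 binomial standard errors of 0.001.

Other numerical choices: topological ordering is Kahn's algorithm with
cycle reporting; chromosome ordering is numeric-then-lexicographic;
`roh_f` ties are impossible by construction (runs are maximal and
disjoint); random-number streams for pedigree, gene dropping and
phenotypes are derived from the single configuration seed with fixed
offsets, so regenerating one stage never perturbs another.

## Known limitations

Pedigrees with selfing are handled by the tabular oracle but not
expected in the breeding simulator; binary PLINK BED files are not
read (text PED/MAP and a matrix TSV dialect are); multi-trait models,
dominance variance, genomic BLUP and survival analysis of culling are
out of scope. The scan's Wald p-values rely on fixed variance
components; with very few carriers the z approximation is the binding
constraint, which is what the `min_carriers` floor guards.
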