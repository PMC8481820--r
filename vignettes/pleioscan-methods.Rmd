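---
title: "Cross-trait pleiotropy analysis with pleioscan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-trait pleiotropy analysis with pleioscan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pleioscan)
```

pleioscan analyses the shared genetic basis of two complex traits — the
motivating application is osteoarthritis (OA) and major depression (MD) —
from GWAS summary statistics alone. It chains the standard cross-disorder
toolkit: harmonization of two studies to one reference panel, LD score
regression for heritability and genetic correlation, a Gaussian-mixture view
of polygenicity, an overlap-aware weighted-Z meta-analysis clumped into
genomic risk loci, bidirectional two-sample Mendelian randomization (MR)
with heterogeneity-based outlier removal, sign-concordance testing, and
gene/gene-set association. Every stage is exercised end to end against a
synthetic-data generator that draws from the same bivariate polygenic model
the estimators assume, so the whole pipeline is testable without downloading
any cohort data.

## The generative model

For each trait $i \in \{1,2\}$ and SNP $j$ of $M$, the causal (joint) effect
$\gamma_{ij}$ on the standardized-genotype scale follows a spike-and-slab
mixture: SNP $j$ is causal for trait 1 only, trait 2 only, both, or neither,
with probabilities $(\pi_1 - \pi_{12},\ \pi_2 - \pi_{12},\ \pi_{12},\
1 - \pi_1 - \pi_2 + \pi_{12})$. Causal effects have variances
$\sigma^2_{\beta,i}$ (the *discoverability*); effects at shared causal SNPs
are bivariate normal with correlation $\rho_\beta$. A directional causal
effect of trait 1 on trait 2 is modelled as
$\gamma_{2j} = b_{xy}\gamma_{1j} + \gamma_{2j}^{\rm specific}$. Marginal
(GWAS-observed) effects are the within-block LD convolution $R\gamma$, and

$$ z_{ij} = \sqrt{n_i}\,(R\gamma_i)_j + \varepsilon_{ij}, \qquad
   \varepsilon_i \sim N(0, R), \quad
   \operatorname{cor}(\varepsilon_{1j}, \varepsilon_{2j}) = r_0 , $$

where $r_0$ is the null Z-score correlation induced by sample overlap. On
this scale $\beta = z/\sqrt{n}$ and $\mathrm{se} = 1/\sqrt{n}$, so
case-control sampling is absorbed into $n$ and every downstream formula is
exact. Implied quantities are closed-form:
$h^2_i = M\pi_i\sigma^2_{\beta,i}$ and, with $b_{xy}=0$,
$r_g = \pi_{12}\rho_\beta/\sqrt{\pi_1\pi_2}$.

The reference panel is a chain of AR(1) LD blocks
($r_{jk} = \rho_{\rm LD}^{|j-k|}$ within a block, exactly zero across
blocks), laid out over the 22 autosomes with 5 kb SNP spacing and 1 Mb
between blocks on a chromosome. LD scores are within-block row sums of
$r^2$.

**Default study conditions.** `sim_config()` defaults emulate the OA/MD
setting: total sample sizes 455,221 and 500,199; polygenicities
$\pi_1 = 1.1\times10^{-3}$ and $\pi_2 = 1.8\times10^{-3}$ (roughly 8.7 K and
13.7 K causal variants on a ~7.8 M-SNP genome); $\rho_\beta = 0.8$ with
$\pi_{12}$ chosen so that $r_g = 0.30$; $r_0 = 0$ (the real studies share no
samples) and $b_{xy} = 0$. Because $\sigma^2_\beta$ depends on the panel
size, `sim_config_study(panel)` derives it from target heritabilities
(defaults 0.094 and 0.085). What the generator does *not* emulate: MAF- or
annotation-dependent effect sizes, long-range and cross-block LD, population
stratification, and case-control ascertainment beyond the effective-$n$
abstraction — so passing recovery tests demonstrate estimator correctness
under the assumed model, not robustness to every feature of real cohorts.

## Harmonization

Records are standardized (`z = beta/se`, odds ratios log-transformed on
read-in — detected by column name only, never by magnitude) and aligned to
the panel so the effect allele always equals the panel alternate allele.
Filters, each itemized in a conservation-checked report
(`n_input = n_output + sum(removals)`): non-autosomal, missing rsID,
non-biallelic, minor allele frequency < 1%, absent from panel, incompatible
alleles (neither direct nor strand-complement match), strand-ambiguous
palindromes, allele-frequency discordance, duplicates (smallest standard
error wins).

The conventional "15% rule" for palindromic SNPs is genuinely ambiguous
between two readings — "remove A/T and C/G SNPs with allele frequency near
0.5" and "remove SNPs whose study frequency differs from the reference by
more than 15%". Both are implemented and both default to 0.15: palindromes
with effect-allele frequency within 0.15 of 0.5 are removed as unresolvable
(`palindrome_eaf_halfwidth`), the rest are oriented by frequency matching;
independently, any SNP whose oriented frequency differs from the panel's by
more than `af_discordance_max` is removed. Neither is claimed to reproduce
the published SNP counts. Coordinates are 1-based closed; the build tag is
metadata only (no liftover).

## Heritability, genetic correlation, polygenicity

LD score regression fits $E[z^2_j] = a + n h^2 \ell_j / M$ by weighted least
squares with heteroskedasticity weights $1/\max(1, \ell_j)$ — a single pass,
deliberately simpler than the reference implementation's iterative
reweighting; the free intercept $a$ sits at 1 under pure polygenicity and
absorbs confounding-style inflation. The cross-trait version regresses
$z_{1j} z_{2j}$ on $\ell_j$ (slope $\sqrt{n_1 n_2}\,\rho_g / M$, intercept
absorbing overlap) and forms $r_g = \rho_g/\sqrt{h^2_1 h^2_2}$. All standard
errors are delete-one-block jackknives over contiguous genomic blocks
(default 200), applied to the *full* $r_g$ functional, and $r_g$ is never
clamped: out-of-range values only set a warning flag. No large-$\chi^2$ SNP
exclusion is applied by default (a cap is available).

Polygenicity and discoverability come from `mixer_em()`, a two-component
Gaussian mixture $z_j \sim (1-\pi)N(0,1) + \pi N(0, 1 + n\sigma^2_\beta
\ell_j)$ fitted by EM with the null variance pinned at 1. The M-step for
$\sigma^2_\beta$ is a one-dimensional maximization, so the log-likelihood is
non-decreasing (asserted every iteration). This is labelled **MiXeR-lite**
in all outputs: it does not model the LD *convolution* of causal effects —
$\ell$ enters only the causal-component variance — so under strong LD a
causal SNP's signal bleeds into its neighbours and $\pi$ is overestimated
(about eightfold at $\rho_{\rm LD} = 0.9$ in our panels). Its
parameter-recovery guarantee therefore holds in the weak-LD regime, and its
estimates are not comparable to the full convolution model's published
causal-variant counts.

The observed-to-liability conversion is
$h^2_{\rm liab} = h^2_{\rm obs}\,[K(1-K)]^2 / \big(P(1-P)\,\varphi(t)^2\big)$
with $K$ the population prevalence, $P$ the sample case proportion and $t$
the upper-$K$ normal quantile.

Sign concordance between one trait's genome-wide significant, LD-independent
index SNPs and the other trait's effect directions uses the exact **two-sided**
binomial test against 0.5. The two-sided convention is an inference, not a
published statement: the published $P = 4.89\times10^{-2}$ for 33/51 equals
exactly twice the one-sided tail, which the one-sided convention cannot
produce. Zero Z scores in the lookup trait count as discordant and are
logged.

## Overlap-aware meta-analysis and risk loci

The null cross-trait Z correlation $\hat r$ is the sample correlation over
SNPs with $|z| \le 1$ in **both** traits (truncation is exclusion, not
winsorizing; "either trait exceeds" removes the SNP). The covariance matrix
$\Omega$ uses the correlation form with unit diagonal — the combined-Z
formula presumes unit-variance null scores, and truncated-sample variances
are shrunken. Weights follow Lin–Sullivan,
$w = \Omega^{-1}e / (e^\top \Omega^{-1} e)$ (no sample-size term; a
$\sqrt n$-scaling flag is deliberately absent from the default path), and

$$ \hat Z_j = \frac{\sum_k w_k Z_{kj}}
  {\sqrt{\sum_k w_k^2 + \sum_{k\ne l} w_k w_l \hat r_{kl}}} . $$

Box truncation attenuates the correlation estimate substantially (a true
$r_0 = 0.6$ observes as about 0.25), so the plain estimator under-corrects
strong overlap. The default applies no de-attenuation; the
`deattenuate = TRUE` flag inverts the doubly truncated bivariate-normal
correlation mapping exactly (trapezoid quadrature + root finding), and the
package's calibration checks use it — with it, the combined-Z type-I error
at $\alpha = 5\times10^{-4}$ stays within binomial bounds for
$r_0 \in \{0, 0.3, 0.6\}$, while setting $\hat r = 0$ demonstrably inflates
it.

Genomic inflation is $\lambda_{\rm GC} = \mathrm{median}(z^2)/0.4549$ and
$\lambda_{1000} = 1 + (\lambda_{\rm GC}-1)\cdot 500\,(1/n_{\rm cases} +
1/n_{\rm controls})$, the standard case-control rescaling.

Risk loci come from greedy clumping: the best-p unassigned significant SNP
joins an existing lead's clump if $r^2 \ge$ `r2_lead` with it, otherwise
becomes a new lead and absorbs unassigned significant SNPs at $r^2 \ge$
`r2_member`; clumps within `merge_window_kb` on a chromosome merge.
Defaults (5e-8, 0.6, 0.1, 250 kb) mirror the documented defaults of the
annotation platform the field uses; because locus-merging conventions vary
across tools, locus counts are validated against a brute-force oracle
rather than any published count. Ties in p are broken by (chromosome,
position, id) for bit-reproducible output.

## Mendelian randomization

Instruments are exposure SNPs at $p \le 5\times10^{-8}$ (inclusive), greedily
pruned to pairwise $r^2 < 0.05$ within 1 Mb, intersected with the outcome.
Each instrument's Wald ratio $\hat b_{xy} = \hat b_{zy}/\hat b_{zx}$ carries
the delta-method standard error
$\sqrt{(\mathrm{se}_{zy}^2 + \hat b_{xy}^2 \mathrm{se}_{zx}^2)/b_{zx}^2}$;
instruments with $b_{zx} = 0$ are dropped, never imputed. The causal
estimate is inverse-variance weighting over the ratios. This replaces the
generalized-least-squares estimator over LD-correlated instruments: at the
$r^2 < 0.05$ pruning threshold the LD correction term is second-order, and
the deviation is recorded in every result's `method` field.

Outlier (horizontal-pleiotropy) removal is HEIDI-style but uses a
**leave-one-out** reference rather than the original top-instrument
reference: $z_i = (\hat b_i - \hat\beta_{(-i)})/
\sqrt{\mathrm{se}_i^2 + \mathrm{se}(\hat\beta_{(-i)})^2}$, one pass,
removal at $p < 0.01$ strictly. Leave-one-out keeps the test symmetric in
the instruments and avoids anchoring on a single possibly-pleiotropic top
SNP. `min_instruments` defaults to 10, the cited method's convention,
overridable for toy runs. Both directions run independently; a failure in
one (e.g. instrument shortage) never aborts the other.

## Genes and gene sets

SNPs map to a gene when within 20 kb of its (1-based, closed) bounds;
strand is ignored because the window is symmetric. The gene statistic is
$S = \sum_j z_j^2$, whose null is the eigenvalue mixture
$\sum_i \lambda_i \chi^2_1$ of the gene's LD submatrix; it is evaluated by
Satterthwaite/Brown moment matching to $a\chi^2_\nu$ with
$a = \mathrm{Var}/2E$, $\nu = 2E^2/\mathrm{Var}$, $E = \operatorname{tr}R$,
$\mathrm{Var} = 2\lVert R\rVert_F^2$ — exact when $R = I$ — with a
Monte-Carlo mode kept for verification. The same assignment and LD matrices
are reused for the meta-analysis and both per-trait Z vectors, feeding the
pleiotropic-gene filter: meta p at the Bonferroni threshold
($0.05/n_{\rm genes}$) AND both per-trait p at $1\times10^{-4}$, all
comparisons inclusive.

Competitive gene-set enrichment regresses probit-transformed gene p-values
(clipped to $[10^{-300}, 1-10^{-16}]$, with clipping logged) on set
membership plus $\log(\text{SNP count})$ and $\log(\text{gene length})$
covariates, reporting a one-sided p for a positive membership coefficient.
When gene length is unavailable the SNP count proxies it and the collinear
covariate collapses out of the design automatically.

## Numerical and testing choices

Degenerate inputs have defined behaviour: constant LD scores raise a
degenerate-design error; a duplicated Z vector in overlap estimation raises
an error rather than returning $\hat r = 1$; all-equal gene Z scores give a
zero enrichment coefficient with $p = 0.5$; EM hitting `max_iter` returns
`converged = FALSE` rather than erroring. One global seed expands into fixed
per-stage substreams, so adding a stage never perturbs earlier draws and
identical configurations are bit-reproducible.

Test problem sizes were chosen once as the package's validation conditions:
recovery runs use $M = 50{,}000$ SNPs, $n = 100{,}000$, 25 seeded
replicates, on an AR(1) panel with $\rho_{\rm LD} = 0.9$ for
heritability/correlation/MR (the wide LD-score spread gives the regression
leverage; at mild LD the spread is a few percent and slope estimates
destabilize) and $\rho_{\rm LD} = 0.2$ for the mixture model (the regime
MiXeR-lite models). Null calibration uses $10^6$ SNP pairs drawn at the
correlation the meta-analysis consumes. Oracle checks (combined-Z matrix
expression, exhaustive clumping, Monte-Carlo gene nulls, the eight-case
allele-orientation table) run on small instances where exhaustive
computation is exact.

## Known limitations

No liftover, no X/Y/MT, no multi-allelic decomposition, no INFO filtering.
No effect-size meta-analysis or heterogeneity statistics. MR estimators
beyond IVW (Egger, weighted median) are out of scope, as are partitioned
heritability, the bivariate mixture's shared-causal-count decomposition, and
all annotation-platform functional mapping. The MiXeR-lite caveat above is
the largest interpretive limitation: treat its $\hat\pi$ as an effective
count of LD-smeared signal clusters unless LD is weak.
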