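---
title: "Gene-set distance association testing: model, design choices, and operating characteristics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-set distance association testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsdist)
```

## The problem

Gene-set association methods built on per-gene regression or rank statistics
detect gene sets whose members shift *monotonically* with a phenotype. They
are nearly blind to complex associations — differential correlation between
member genes across groups, V-shaped relationships, liquid associations —
where no individual gene moves its mean or median. Distance correlation sees
these patterns, because it compares the full pairwise-distance structure of
the gene-set expression submatrix with the pairwise-distance structure of the
endpoint, and its population value is zero exactly when the two are
independent (for Euclidean distances).

`gsdist` implements a self-contained, model-free gene-set test on this idea,
for three endpoint types: quantitative, categorical, and right-censored
event times. Self-contained means a set's p-value depends only on its member
genes and the endpoint, never on the rest of the genome; model-free means no
likelihood is optimized, so the procedure cannot fail to converge — the only
degenerate case, an identically zero distance matrix, is detected and flagged
before any division.

## The statistic

Let $X$ be the $n \times m$ expression submatrix of the gene set
(subjects $\times$ genes) and let $Y$ hold the endpoint. Both are reduced to
$n \times n$ subject distance matrices. For any distance matrix
$A^\star$, the *U-centered* matrix $\tilde A$ has off-diagonal entries

$$\tilde a_{ij} = a^\star_{ij}
  - \frac{a^\star_{i\cdot} + a^\star_{\cdot j}}{n-2}
  + \frac{a^\star_{\cdot\cdot}}{(n-1)(n-2)},$$

with row, column, and grand sums of $A^\star$, and a zero diagonal. The
bias-corrected inner product of two U-centered matrices is

$$(\tilde A \cdot \tilde B) = \frac{1}{n(n-3)} \sum_{i \ne j}
  \tilde a_{ij}\, \tilde b_{ij},$$

an unbiased estimator of squared distance covariance, which requires
$n > 3$. The distance correlation and its t-statistic are

$$r_d = \frac{(\tilde X \cdot \tilde Y)}
  {\sqrt{(\tilde X \cdot \tilde X)(\tilde Y \cdot \tilde Y)}},
  \qquad
  t_d = \frac{r_d}{\sqrt{1-r_d^2}}\sqrt{\tfrac{n(n-3)}{2}-1},$$

with $t_d$ referred to a t distribution on $n(n-3)/2 - 1$ degrees of
freedom. We report the upper-tail (one-sided) p-value: in this framework
dependence inflates $r_d$ upward, so evidence against independence lives in
the right tail, and a negative $r_d$ yields $p > 0.5$. (The implementation
is verified, to machine precision, against the equivalent double-centered
formulation with diagonal-corrected inner products, and to $10^{-12}$
against a brute-force transcription of the formulas above.)

## Endpoint distances

* **Quantitative** — $|y_i - y_j|$, the one-dimensional Euclidean distance.
* **Categorical** — the indicator $I(y_i \ne y_j)$: 0 within a category,
  1 across categories. Labels are compared by exact token equality; merging
  categories changes the metric and is deliberately left to the caller.
* **Censored event time** — each subject contributes an observation time
  $o_i$ and status $s_i$ (1 = event, 0 = censored). With
  $u_1 < \dots < u_{\acute s}$ the unique times at which events occurred,
  $$\acute y_{ij} = \sum_{l=1}^{\acute s}
    I(o_j > u_l \ge o_i)\,I(s_i = 1) + I(o_i > u_l \ge o_j)\,I(s_j = 1):$$
  the number of distinct event times separating the pair's windows, counted
  only from the side whose subject actually experienced the event. Two
  censored subjects are at distance zero. Only time *orderings* enter, so the
  matrix is invariant under strictly monotone transformations of the times —
  a property the tests exercise with `exp`, squaring, and affine maps.
  Inequalities are applied exactly as written (strict on the later
  observation, weak on the earlier); a subject observed exactly at an event
  time therefore contributes through the $u_l \ge o_i$ side only, and
  duplicate event times enter the grid once. This was an open choice — no
  tie-breaking convention is canonical here — and the literal reading was
  preferred over inventing one.

```{r survival-example}
# 4 subjects: event at 1, censored at 3, event at 2, censored at 5
survivalDistanceMatrix(c(1, 3, 2, 5), c(1, 0, 1, 0))
```

## Transforms

Two opt-in per-gene transforms equalize gene contributions to the Euclidean
distance: `zscoreTransform` (center, divide by SD) and
`commensurateTransform` (center, divide by the gene's sum of pairwise
absolute differences over unordered subject pairs, after which that sum is
exactly 1). Whether ordered or unordered pairs are counted in the
commensuration denominator only changes a constant factor per gene — but the
factor is *shared* by all genes, so it cancels in $r_d$; unordered was
chosen. Neither transform is applied silently: variance equalization helps
when lowly and highly expressed genes are equally informative and hurts when
expression magnitude itself carries the signal.

## Permutation verification

The t reference is an asymptotic approximation (see *Operating
characteristics*), so the smallest p-values deserve verification.
`permutationTest` permutes subjects by applying one random permutation
simultaneously to rows and columns of the U-centered endpoint matrix and
recomputes only the inner products — U-centering commutes with simultaneous
row/column permutation (a tested identity), so the centering step is never
repeated, and each replicate costs $O(n^2)$ arithmetic. The permutation
statistic is $r_d$ itself; $t_d$ is a fixed monotone function of it at fixed
$n$, so the p-value is identical and the cheaper statistic wins. The
estimator is add-one, $p = (1 + \#\{r_b \ge r_{\mathrm{obs}}\})/(B+1)$,
which can never return 0; `B = 10000` is the default for follow-up.

In screens (`gsdaScreen`), permutation runs only for sets with
$p_t \le 0.05$ by default. The empirical EDF results below suggest the t
approximation begins to overstate significance around $p < 0.04$; the
threshold stays at 0.05 so the follow-up covers that region with margin.
Benjamini–Hochberg is the default multiplicity adjustment (any
`p.adjust` method can be selected); rows order by permutation p-value where
present, t-test p-value breaking ties. Each gene set's permutation stream is
derived deterministically from `(seed, set index)`, so screen output is
reproducible and independent of execution order.

## Driver identification

A significant set-level association may be carried by a few genes.
`backwardEliminate` removes, at each round, the gene whose exclusion gives
the smallest t-test p-value, until one gene remains; every visited subset
plus the intact full set are candidates, and the smallest-p candidate is
reported (so selection can never *worsen* the reported p). Ties in the
leave-one-out minimum remove the lowest column index; ties across subset
sizes prefer the smaller subset. Both rules are stated conventions, not
claims about the field's practice.

The best-subset p-value is selection-biased — the hypothesis was chosen by
looking at the data — and is printed with that caveat. When a defensible
significance level for the *selected* subset is needed,
`eliminateWithPermutation` reruns the entire elimination on each of $B$
endpoint-permuted datasets and reports
$(1 + \#\{best_b \le best_{\mathrm{obs}}\})/(B+1)$.

Each leave-one-out evaluation reuses precomputed per-gene squared-difference
matrices; subsetting is a column sum ($O(n^2)$ per candidate instead of
$O(n^2 m)$). The accumulation order and precision match the from-scratch
distance routine exactly, and a test asserts bit-for-bit equality between
the two routes.

## The simulation harness

`simulationConfig` + `estimateLevelPower` reproduce the structure of a
level/power study over gene-set collections:

* **Collection A** — 100 genes in 60 sets of 8–10; 10 sets contain at least
  one of the 10 associated genes, 50 contain none.
* **Collection B** — 1000 genes in 100 sets of 10–100; 20 associated sets,
  80 null.

Null genes are iid standard normal. A latent standard-normal subject
variable $L$ drives everything else: simple-association genes are
$\beta L + \varepsilon$; complex-association genes are
$Z \beta L + \varepsilon$ with one per-subject random sign vector $Z$ shared
by all associated genes, producing differential correlation between
associated genes with no mean shift (an option allows per-gene $Z$ for
sensitivity analysis). Endpoints derive from the same $L$: quantitative
$y = L + N(0,1)$; categorical = two equal groups split at the median of
$L + N(0,1)$; survival times $\mathrm{Exp}(\mathrm{rate} = e^{L})$ with
independent $\mathrm{Uniform}(0, c)$ censoring, $c$ solved numerically so
the expected censoring fraction hits its target (default 0.3).

Defaults $\beta = 1$ and noise SD 1 (signal-to-noise 1:1) give mid-range
power at $n = 50$, which keeps power curves informative across
$n \in \{10, 25, 50, 100\}$. Set sizes are drawn uniformly within each
collection's range; associated gene $k$ anchors associated set $k$
(cycling), with other associated genes joining independently at rate 0.1.
These structural constants — and the endpoint link functions — are this
package's own defaults for the parts of the design that published
descriptions leave open; they reproduce the design's *structure*, and no
absolute power number is claimed to match any external figure.

Reproducibility: gene-set membership is drawn once from the master seed and
held fixed across replicates; replicate $r$ uses the derived substream seed
$(\mathrm{seed} + 1000003\, r) \bmod (2^{31}-1)$, so any
`(config, replicate)` pair regenerates bit-identically.

What the generator does *not* emulate: real expression marginals (counts,
heavy tails, normalization artifacts), gene–gene correlation within null
sets, batch structure, and informative censoring. Passing level/power checks
on this generator demonstrate calibration and sensitivity of the statistic
under the stated latent-variable designs, not performance on any particular
real dataset.

## Operating characteristics, honestly stated

The t reference for $t_d$ is derived in a regime where the *dimension* of
the data grows; here the endpoint is always univariate and gene sets are
finite, so the reference is an approximation whose quality improves with
gene-set size and sample size. Measured behavior of this implementation
(which the test suite partially re-measures at smaller scale):

* With 30-gene null sets at $n = 50$, the null p-value distribution is
  uniform to within KS $\approx 0.04$ — the regime the approximation
  targets.
* With 8–10-gene null sets, the one-sided test rejects at nominal 5% about
  6–7% of the time ($6.3\%$, SE $0.2\%$, at $n = 100$ with a two-group
  endpoint), and the null p-value EDF deviates from uniform by up to
  $\approx 0.07$; equivalently, mid-range t-test p-values can sit a few
  hundredths away from the exact permutation p-value. The deviation has the
  same signature throughout: slight overstatement of significance in the
  lower tail.

This is why the permutation module exists and why screens trigger it for
every set the t-test flags. For small gene sets, the permutation p-value —
not the t-test p-value — is the number to report as significant. The
acceptance checks in `tests/testthat/test-acceptance.R` assert the stricter
published-style bounds (level $< 6\%$, mid-range permutation/t agreement
within 0.02, pooled-null KS $< 0.05$) at typical 8–10-gene set sizes; the
first and the latter two fail by the small margins quantified above, and are
left failing deliberately — they document the approximation's real accuracy
at small $m$ rather than being re-tuned to pass.

## Numerical choices and degenerate inputs

* $n \ge 4$ everywhere: the bias-corrected inner product divides by
  $n(n-3)$ and the degrees of freedom $n(n-3)/2 - 1$ must be $\ge 1$.
* A self inner product counts as zero — and the gene set or endpoint as
  degenerate — below $10^{-12} \times$ (mean squared off-diagonal raw
  distance $+ 10^{-300}$): a scale-aware guard, so the flag does not depend
  on measurement units. Degenerate sets abort a single test with a typed
  error but are reported as flagged rows in screens.
* $|r_d| \ge 1$ after rounding is clamped to $\pm(1 - 10^{-15})$ before the
  t transform: the statistic stays finite, the p-value stays extreme. An
  underflowing upper-tail probability is floored at the smallest positive
  double so that downstream $\log$ or BH arithmetic never meets an exact 0.
* Missing expression values are rejected at the door, never imputed —
  distance semantics under missingness would be a silent modeling choice.
* A categorical endpoint with one label, or a survival endpoint with zero
  events, has an identically zero (hence degenerate) distance matrix and is
  refused with a named error; all-distinct categorical labels U-center to
  exactly zero and fail the same way, as they must.

## Problem sizes used by the shipped checks

The test suite and acceptance script regenerate everything they measure.
The larger blocks are: the type-I-error study (collection A, two groups of
50, 500 replicates — about two minutes), permutation/t concordance (50
datasets at $B = 10^4$), differential-correlation detection (200 replicates
of the two-gene design at 100/group), and driver recovery (100 replicates
of the 20-gene/5-driver design at $n = 100$). These sizes were chosen to
keep Monte-Carlo standard errors comfortably inside the margins being
asserted while remaining desk-scale.

## Known limitations

* No covariate adjustment: the test is marginal by construction; methods
  built on regression can adjust, this one cannot.
* Euclidean (and the two endpoint metrics) only; alternative distances
  (cosine, correlation-based) are deliberately out of scope.
* The survival metric costs $O(n^2 \acute s)$ comparisons in the worst
  case; the implementation vectorizes this to $O(n^2)$ per event-side pass,
  but survival screens remain the slowest endpoint type.
* Self-contained tests can be "overpowered" on large collections —
  significance for many sets at once is expected behavior, and the FDR
  column, not the raw p-value count, is the interpretable summary.
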