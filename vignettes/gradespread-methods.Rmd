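---
title: "Methods: rank environments, progress regression and network-null testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank environments, progress regression and network-null testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradespread)
```

## The question and the data model

`gradespread` asks whether a student's academic progress over a year is
associated with the academic standing of the peers they themselves name as
friends — a social-contagion question on a sociometric friendship network.
The data model is a single school class observed twice:

* a **sociometric survey**: every respondent rates every other roster
  member as `best_friend`, `friend`, `acquaintance`, `unknown`, or
  `related`. The first three levels define three *tiers* of directed,
  self-reported ties; `unknown` and `related` are kept in the data but
  never form edges. A response is *complete* only if every non-self roster
  member received exactly one rating; incomplete responses are excluded
  from all analysis.
* **GPA records** at two timepoints a year apart (`gpa_t0`, `gpa_t1`) on a
  0–100 scale.

Tier networks can be built **cumulatively** (a tier plus all stronger
tiers — the natural reading for descriptive network statistics) or
**exclusively** (exactly one tier — the default for the regression
predictors, because cumulative sets nest and would build collinearity
directly into the design).

## From GPA to ranks

School GPA distributions are strongly negatively skewed, so all analysis
happens in rank space. A student's **academic ranking** is

$$g = N - \text{position},$$

position 1 being the highest GPA, so $g \in \{0, \dots, N-1\}$ with
larger values meaning higher standing. Ties share the average of the
rankings they span by default (`tie_policy = "average"`; `dense` and
`random` are available but flagged in the output metadata, since they
break the sum-to-zero structure or determinism respectively). **Progress**
is $y = g_{t1} - g_{t0}$; over a tie-free cohort the $y$ values sum to
zero by construction, which is one of the package's invariant tests.

The **environment score** at tier $i$ is the difference, in rank units,
between a student's out-neighbours' average standing and their own.
The phrase "difference in ranking between the neighbours' average GPA and
one's own GPA" supports two readings, and both are implemented:

* `mean_neighbor_rank` (default): $x_u = \overline{g_{\text{nbrs}(u)}} - g_u$.
  It stays entirely in rank units, like $g$ and $y$, and is invariant to
  translating all rankings.
* `rank_of_mean_gpa`: average the neighbours' raw GPAs, place that mean on
  the class ranking scale (count classmates below it, ties counted half),
  then subtract $g_u$.

The two agree on the zero case (neighbours at one's own standing) and are
highly correlated in practice; the default was chosen for unit coherence.
Students with no out-neighbours at a tier have no defined $x$: they are
excluded from that tier's correlation (`undefined_policy = "exclude"`),
while the regression keeps them with $x = 0$ and a warning — dropping the
whole row would discard their information at the other three predictors.

$x$ is always computed from first-timepoint quantities only; nothing from
$t_1$ leaks into the predictors.

## The progress regression and sequential ANOVA

The core model is ordinary least squares,

$$y = \beta_0 + \beta_g\, g + \beta_{xa}\, x_{\text{acq}} +
      \beta_{xf}\, x_{\text{friend}} + \beta_{xb}\, x_{\text{best}} + \varepsilon,$$

fitted by a QR decomposition (via `lm`); designs whose singular values
collapse are rejected with the offending columns named rather than
silently aliased. The own-ranking term $g$ is essential: $x$ and $y$ are
mechanically coupled through it (a low-ranked student has both a high $x$
and more room to rise), so the environment terms must be judged *after*
$g$.

That ordering is exactly what the **sequential (Type I) ANOVA** does: the
sum of squares of the $k$-th term is the drop in residual sum of squares
when it joins the model containing the preceding terms, in the fixed
order $g$, $x_{\text{acq}}$, $x_{\text{friend}}$, $x_{\text{best}}$
(configurable). Each term has 1 DF; $F$ is the term mean square over the
error mean square, $p$ its upper $F(1, n-5)$ tail. Term SS plus error SS
equals the corrected total SS — asserted on every random input at
relative tolerance $10^{-8}$ — and the error row of a 158-student cohort
has $153 = 158 - 1 - 4$ degrees of freedom.

## The out-degree-preserving permutation null

A positive $x_{\text{friend}}$–$y$ correlation is *expected* even with no
social influence, for the regression-to-the-mean reason above. The test
that separates structure from mechanics is a Monte Carlo null model:
rewire the friend network so that every student keeps the **number** of
friends they reported but the targets are redrawn uniformly without
replacement from the other $n-1$ students (no self-loops, no duplicates;
in-degrees free). This preserves each respondent's reporting propensity
while destroying who actually chose whom. For each of `n_reps` (default
500) rewirings, $x_{\text{friend}}$ is recomputed with the same mode and
policies as the observed analysis — through the same internal code path —
and $r(x, y)$ collected; $y$ and $g$ are never permuted.

The **empirical p-value** uses the add-one rule,
$p = (1 + \#\{r_{\text{null}} \ge r_{\text{obs}}\})/(m+1)$, so it is
never zero and is exact under exchangeability; with 500 replicates its
floor is $1/501 \approx 0.002$. A replicate whose recomputed $x$ series
is constant is recorded as missing; more than 10% missing aborts the
test. The five-number box-whisker summary of the null uses
linear-interpolation quantiles (type 7).

Sampling targets uniformly *without replacement* makes duplicate edges
impossible by construction, so no rejection loop is needed; a node of
out-degree $n-1$ has a forced (logged) neighbourhood. Only the friend
tier is rewired for the headline test; the null is about friend choice.

## The synthetic cohort generator

Real sociometric records of this kind are IRB-restricted, so the package
ships a generator whose defaults describe the study conditions end to
end; they were fixed once, before any statistical testing, and are not
tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `n_students` | 158 | a single-class cohort |
| `out_degree_means` | acq 105, friend 7, best 3 | dense acquaintance tier (students know almost everybody), sparse friendship tiers |
| `gpa_shape` | Beta(8, 2) × 100 | long left tail, mass near the top; sample skewness ≈ −0.8 |
| `drift` | +2 GPA | overall upward movement over the year |
| `contagion_delta` | 0.15 | moderate planted effect; 0 = null, 0.5 = the suite's "strong" setting |
| `noise_sd` | 5 GPA | idiosyncratic year-to-year change |
| `homophily` | 0.3 | best-friend choice biased toward similar GPA via a `exp(-|ΔGPA|/5)` kernel |

Contagion is planted in **GPA space**:
$\text{GPA}_{t1} = \text{GPA}_{t0} + \text{drift} + \delta\,
(\overline{\text{GPA}}_{\text{friends}} - \text{GPA}_{t0}) + \mathcal N(0,
\sigma^2)$, clipped to $[0, 100]$. Ranks are derived quantities, so the
pipeline must *detect* the effect through the rank transform — the honest
end-to-end test. Friend-tier out-degrees are clipped to at least 1, so
every student has a defined $x_{\text{friend}}$; the best tier may leave
a few students without best friends, which is exactly what exercises the
undefined-$x$ policies. Incomplete responses are produced by deleting a
single rating row — the minimal violation of completeness.

Two boundary caveats are worth knowing. First, the $[0,100]$ clip can tie
students at 100 when drift pushes top scores past the ceiling; with the
average tie policy those students then share a rank, so the
"zero-noise, zero-contagion implies $y \equiv 0$" identity is exact only
when the configuration leaves headroom under the ceiling (the test suite
uses such a configuration). Second, the generator draws friend targets
uniformly among classmates *not already chosen* as best friends, which
differs infinitesimally from the rewiring null's unconstrained uniform
draw; at the default degrees the discrepancy is negligible, and the
measured type-I error of the permutation test stays inside its binomial
band.

What the generator does *not* emulate: community structure and triadic
closure in the friendship graph, reciprocity correlations, covariates
(gender, attendance, discipline), GPA measurement granularity, and
school-scale confounders. Passing tests on synthetic cohorts therefore
demonstrate that the machinery is correct and calibrated under the stated
generative model — not that the substantive finding generalises to any
real school.

## Numerical and design choices

* Rank-deficiency threshold: the design must have full QR rank; collinear
  columns are reported by name. A fully partitioned class (best + friend +
  acquaintance covering everyone) makes $x_{\text{acq}}$ an exact linear
  function of the other predictors — a structural degeneracy worth knowing
  about when building tiny fixtures.
* Report serialization carries 6 significant digits; significance stars
  mark $p < 0.05$ (\*) and $p < 0.001$ (\*\*\*).
* Determinism: every stochastic entry point takes a seed; the same seed
  reproduces byte-identical cohorts, reports and null distributions.
* Directed transitivity is the fraction of directed two-paths closed by a
  direct edge; local clustering averages are computed on the symmetrized
  (logical-OR) undirected view, the standard convention when direction is
  not specified.
* Problem sizes in the statistical suite — 200 null cohorts and 100
  strong-contagion cohorts of 158 students with 500 rewirings each —
  were chosen to give binomial bands tight enough to detect mis-calibration
  (99% band 2–9% around a nominal 5%) while keeping a full run on a
  single core in the minutes range.

## Worked example

```{r, eval = FALSE}
library(gradespread)

co <- generate_cohort(cohort_config(n_students = 160, incomplete_count = 2,
                                    seed = 1))
res <- run_analyze(cohort = co, out_dir = "reports")
res$anova          # Table-style sequential ANOVA
res$fit$equation   # fitted model string

pt <- run_permtest(cohort = co, n_reps = 500, seed = 2)
pt                 # observed r vs the rewired-network null
```

## Limitations

Beyond the generator's idealisations listed above: the analysis is
observational (a permutation null rules out rank mechanics, not
homophily-driven confounding — students may choose friends who resemble
their *future* selves); tie policies other than `average` slightly change
the meaning of $y$; and the `rank_of_mean_gpa` reading of $x$ is scale-
sensitive through the neighbour-mean, so the two $x$ modes can disagree
for students whose friends' GPAs straddle dense regions of the
distribution.
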