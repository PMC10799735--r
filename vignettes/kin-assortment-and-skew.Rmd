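---
title: "Kin networks, trait assortment and reproductive skew: methods"
author: "culturekin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kin networks, trait assortment and reproductive skew: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(culturekin)
```

## The problem

Two ethnic groups with contrasting kinship systems co-reside around Lugu
Lake in southwest China: the matrilineal, duolocal Mosuo (spouses live
apart, each with their natal household) and the patrilocal Han. Both are
exposed to out-group cultural traits — the national language (Mandarin),
the regional Han language (Sichuan dialect), the Mosuo language (Naru),
and jeans-wearing — and adopt them at different rates by group and sex.
`culturekin` implements the quantitative machinery needed to study this
from a single census with pedigree links:

1. trait comparison tables with Pearson chi-square tests by ethnicity and
   sex;
2. pedigree-based additive relatedness, ego-centric biological- and
   affinal-kin networks, and node-label permutation tests of trait
   assortment on those networks;
3. multinomial reproductive-skew indices with Bayesian posterior draws
   and group contrasts;
4. a synthetic census generator with known ground truth for all of the
   above.

## Census conventions

The census is one row per individual: pedigree links
(`mother_id`/`father_id`/`partner_id`), demography (sex, ethnicity,
birth/death years, village, household), socio-economic covariates, and
the four trait codes (`mandarin`, `sichuan`, `naru` in 0/1;
`jeans` on a 1–4 wearing-frequency scale). Conventions that matter
downstream:

* **The dead have no survey age.** Individuals who died before the survey
  year get `NA` from `age_at_survey()` and are excluded from trait
  tables and networks, but remain in the pedigree and in offspring
  counts. Only living participants could answer a cultural survey.
* **Right-censored children are not imputed.** `derive_reproduction()`
  counts a child as surviving to the threshold age (default 15) only when
  that survival is observed — dead children by their lifespan, living
  children by their age at the survey. Living children still below the
  threshold count in `live_children` but not `offspring_surviving`. For
  the completed-fertility cohort (born 1911–1950, all 67+ at a 2017
  survey) this censoring is negligible.
* **Pairwise deletion.** A missing trait value drops the individual only
  from analyses of that trait, which is why the same group has different
  denominators across trait blocks.
* **`partner_id` is the current partner only.** Multiple or former
  partners are outside the data model.

## Relatedness

"Relatedness" is the additive (numerator) relationship $a_{ij}$ from the
tabular recursion over a parent-sorted pedigree:

$$a_{ii} = 1 + \tfrac12 a_{m(i)f(i)}, \qquad
  a_{ij} = \tfrac12\left(a_{j,m(i)} + a_{j,f(i)}\right)$$

with unknown parents treated as distinct, unrelated founders. Under this
scale parent–offspring and full siblings are 0.5 and half siblings 0.25,
matching the field's enumeration of "close kin"; kinship coefficients
(half these values) are never used. Inbreeding pushes the diagonal above
1 and can push pairs above 0.5; the close-kin threshold is therefore
inclusive ($a_{ij} \ge 0.5$). A full sibling requires both parents
recorded and identical — one shared plus one missing parent is a half
sibling. The matrix is dense, appropriate for populations up to roughly
$10^4$; beyond that a per-ego recursion would be needed.

The recursion is verified in the test suite against an independent
gene-dropping oracle: unique founder alleles are dropped through random
pedigrees $10^4$ times and observed identity-by-descent sharing is
compared with the matrix, pair by pair, within Monte-Carlo error.

Affinal kin are the current partner (coded relatedness 1) and the
partner's parents and full siblings, coded by their pedigree relatedness
to the partner (0.5 when non-inbred).

## Networks and assortment

Each analysis network is defined by an ego group (ethnicity × sex), a tie
type (biological or affinal) and a focal trait. It is the union of
ego–alter stars: every qualifying ego is joined to each of its close
biological kin (or affines) who were surveyed and have a known trait
value; alters may be of any sex or ethnicity; egos with no qualifying
alter are dropped; nodes and edges are deduplicated. Ties between two
alters of the same ego are *not* added — only ego–alter ties define the
topology.

Assortment is Newman's nominal assortativity computed from the
symmetrized mixing matrix $e_{gh}$ (fractions of edge ends joining label
$g$ to label $h$, $a_g = \sum_h e_{gh}$):

$$r = \frac{\sum_g e_{gg} - \sum_g a_g^2}{1 - \sum_g a_g^2}.$$

Graphs are treated as undirected and unweighted for this statistic (the
coded relatedness is kept as edge metadata); a single-label network makes
the denominator zero and raises an explicit error.

The null model is a node-label permutation: trait labels are shuffled
across **all** nodes (egos and alters jointly, preserving label counts)
on the fixed topology, 1000 times by default. The p-value is one-sided
(is assortment *higher* than chance?) with the add-one correction
$p = (1 + \#\{r_{\text{null}} \ge r_{\text{obs}}\})/(1 + n_{\text{perm}})$,
so it can never be exactly zero — 1000 permutations cannot resolve
$p < 1/1001$. Degenerate shuffles (a single label among edge ends, which
cannot occur when both labels are present on nodes of positive degree)
would be redrawn rather than raising mid-test. Because the null
distribution is discrete and can have ties, the test is slightly
conservative on small networks; it remains a valid test.

## Reproductive skew

For a group of $N$ individuals with surviving-offspring counts $r_i$
(total $R$) and exposures $\tau_i$ (years inside the reproductive
window, default ages 15–50 for women and 15–60 for men, truncated at
death or survey), let $t_i = \tau_i/\sum\tau$ and $p_i = r_i/R$.
Nonacs' binomial index generalized to the multinomial setting is

$$B = \sum_i (p_i - t_i)^2 - \frac{1 - \sum_i t_i^2}{R},$$

which has expectation zero when the $R$ offspring are allocated
multinomially with probabilities $t$. The M index normalizes $B$ by its
value under complete monopoly by the individual with the smallest
expected share:

$$M = \frac{B}{B_{\max}}, \qquad
  B_{\max} = \max_i\Big[(1-t_i)^2 + \sum_{j \ne i} t_j^2\Big]
             - \frac{1 - \sum_i t_i^2}{R},$$

giving $M = 1$ under that monopoly, $M \le 1$ always, null expectation
near zero, and stability across group sizes and mean fertilities (both
verified by simulation in the tests). Note that monopoly normalization
makes realistic $M$ values small at large $N$ — the index measures
position between "random given exposure" and "one individual has
everything".

Only individuals born inside the configured cohort window (default
1911–1950, a completed-fertility cohort predating birth-limitation
policy) enter the group inputs; individuals with non-positive exposure
are excluded with a warning.

### Posterior draws and their centring

Uncertainty comes from a Dirichlet model on the reproductive shares:
$p \sim \mathrm{Dirichlet}(r_1 + \alpha, \dots, r_N + \alpha)$ with
$\alpha = 1$ per individual by default ($\alpha$ is exposed because
small-$N$ skew estimates are prior-sensitive). A naive plug-in — compute
$S(p) = \sum_i (p_i - t_i)^2$ per draw and subtract the multinomial null
term $(1 - \sum t_i^2)/R$ — is biased: the Dirichlet draws carry
posterior sampling variance on scale $1/(R + N\alpha + 1)$ and prior
shrinkage toward uniform shares, neither of which the $1/R$ null term
matches. In simulation that variant's 90% intervals covered a true null
in as little as 7% of replicates, and — worse — the bias depends on $N$
and $R$, so contrasts between groups of different sizes (the central
comparison here, e.g. 485 vs 181 men) would be systematically distorted.

Each draw is therefore centred with the **exact expectation of $S(p)$
under the null**, i.e. under $r \sim \mathrm{Multinomial}(R, t)$ followed
by $p \mid r \sim \mathrm{Dirichlet}(r + \alpha)$. With
$A = R + N\alpha$ and $u_i = (R t_i + \alpha)/A$:

$$c_0 = \sum_i \frac{R t_i (1 - t_i) + \alpha^2 (1 - N t_i)^2}{A^2}
  + \frac{1 - \sum_i u_i^2 - \sum_i R t_i (1 - t_i)/A^2}{A + 1},$$

and the posterior draws are $M_g = (S(p_g) - c_0)/(S_{\max} - c_0)$.
Draws from null-generated data then straddle zero for any $N$, $R$ and
$\alpha$, and group contrasts between exchangeable groups are centred on
zero (verified: exclusion rates near the nominal 10% of a 90% interval).

One consequence is deliberate and documented rather than hidden: with
$\alpha = 1$ the prior shrinks the interval's centre toward the null, so
when the data really are null the 90% interval covers zero *more* than
90% of the time (~97–100% at $N/R \approx 1/3$). The interval is
conservative, never anti-conservative; reducing $\alpha$ moves coverage
toward nominal at the cost of less regularization for zero-offspring
individuals.

Intervals are equal-tailed (matching the usual "90% CI" phrasing), and
group contrasts are draw-wise differences paired by index after
equalizing draw counts.

## The synthetic generator

`generate_population()` emulates the study system, not any particular
dataset: two groups with duolocal vs patrilocal household rules,
founder couples, generation-by-generation pairing (within-group or
intermarried), Poisson female fertility, Bernoulli child survival, adult
lifespans, and a single forward pass in birth order assigning traits with
adoption log-odds
$\beta_0(\text{group}, \text{sex}) + \beta_{\text{cohort}} +
\beta_{\text{kin}} \cdot f_{\text{kin}} + \beta_{\text{aff}} \cdot
f_{\text{aff}}$, where $f$ are fractions of already-assigned close kin
and affines who adopt. Male reproductive skew is planted mechanistically:
females sample partners proportionally to per-male gamma mating weights
(shape $k$; $k = \infty$ is homogeneous), so small $k$ concentrates
matings — mirroring the hypothesized mate-competition mechanism in
duolocal men, whose default is an exponential weight ($k = 1$) against
homogeneous patrilocal males. Because every child has both parents,
female counts stay near-Poisson regardless.

Default scale was chosen once to match the study's conditions: 170 and
100 founder couples, three generations, mean completed fertility 4,
child survival 0.93 and intermarriage rates 0.08/0.15 yield roughly
1600–1750 and 650–800 surveyed adults in the two groups. Trait baselines
were set so realized adult frequencies resemble the study system
(out-group language adoption higher in males, near-universal mother
tongue in the larger group, jeans around half).

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: age-structured mortality and migration;
multi-partner histories and remarriage; any dependence of traits on the
socio-economic covariates (education, occupation, income, tourism are
generated as independent noise); equilibrium trait dynamics (the forward
pass plants assortment but no feedback over time); and near-fixed traits
(a trait at 98% prevalence with a positive-only kin effect produces
almost no label variance, hence little detectable assortment — planting
assortment at extreme prevalence would need a two-sided kin effect).

## Numerical choices

* All randomness flows from explicit integer seeds; the CLI expands one
  global seed into logged per-stage seeds; identical seeds give
  byte-identical CSV artifacts.
* Permutation tests default to 1000 shuffles (199 in the calibration
  simulations, where the add-one p-value is exactly valid and
  $p \le 0.05$ is attainable).
* Posterior summaries default to 4000 draws; simulation tests use 500–
  2000 draws per fit to keep the default suite inside a few minutes.
* The test suite's simulation sizes are scaled-down versions of the
  study design (20–30 founder couples, ~150–500 individuals per
  replicate; 200 replicates for calibration and coverage, 100 for
  power), chosen so the full suite runs in about a minute while keeping
  Monte-Carlo error well below the asserted margins.
* The gene-dropping oracle uses $10^4$ drops with a per-pair tolerance of
  three Monte-Carlo standard errors floored at 0.005, so that a joint
  check across thousands of pairs retains its per-comparison meaning.
* Degenerate inputs fail loudly: single-label networks, single-member or
  zero-offspring skew groups, zero-margin contingency tables and
  pedigree cycles all raise errors naming the offending records; trait
  cells that are entirely missing are marked unavailable rather than
  fabricated.

## Known limitations

* The exact published skew normalization is not recoverable from its
  description; this implementation satisfies the published *properties*
  (exposure adjustment, null expectation zero, group-size and fertility
  invariance, monopoly maximum) but makes no claim of numerical
  agreement with the original software's M values.
* Two published chi-square statistics (jeans-high sex difference in the
  larger group, 59.803, and its female group difference, 0.403) are not
  reproducible from any 2×2 table of the published counts; they are
  flagged in `lugu_survey_counts()` and excluded from recomputation
  checks, with the remaining 18 statistics reproduced to ±0.001.
* Whether alters' mutual ties belong in the ego-group networks is not
  derivable from the published figures; this implementation includes
  only ego–alter ties and records the choice here.
* Step-relations and adoptions are invisible to the pedigree: recorded
  parent links are treated as biological.
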