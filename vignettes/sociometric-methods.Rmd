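---
title: "Sociometric status classification: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sociometric status classification: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sociotypes)
```

## The problem

Peer nominations are the workhorse of classroom sociometry: each child
names up to three classmates they like most and up to three they like
least. The counts received — PNR and NNR — carry the information, but
turning a pair of counts into one of the five status labels (preferred,
rejected, neglected, controversial, average) requires a scoring system,
and the choice of system changes who gets which label. This package
implements the three systems side by side so that their agreement,
their disagreement, and the behavioural validity of their groups can be
studied on the same data.

## The three classifiers

**Standard-score method (CD).** Counts are standardized within the
classroom, combined into social preference (SP = Z_PNR − Z_NNR) and
social impact (SI = Z_PNR + Z_NNR), and re-standardized. The specific
criterion is a ±1 cutoff on Z_SP (preferred/rejected) or Z_SI
(controversial/neglected); supplementary criteria fix the signs of
Z_PNR and Z_NNR. Because the mapping from a raw pair to a z-score
depends on the classroom's mean and SD, the same raw pair can be
classified differently in different classrooms (*intra-method
variability*), and classrooms with little dispersion can promote very
low counts across a cutoff. `score_diagnostics()` quantifies the
mechanism: each nomination moves a z-score by 1/SD, the z-score of a
zero count is −M/SD = −1/VC, so dimensions with a small variation
coefficient (VC = SD/M) and a large mean let single nominations carry
more weight. In practice positive nominations have a smaller VC and a
larger mean than negative ones, so PNR dominates both SP and SI — one
of the method's documented construct-validity problems, along with the
curvilinear (not independent) relationship between SP and SI that
`curvilinear_association()` estimates with a cubic polynomial fit in
both directions.

One structural subtlety: the method's later descriptions sometimes add
a supplementary `Z_SI > 1` condition to the rejected criterion,
contradicting the primary definition (Z_SP < −1, Z_PNR < 0, Z_NNR > 0).
This package executes the primary definition only; the variant would
shrink the rejected group and is not applied anywhere.

**Fixed-cutoff probability method (NB).** A received count is rare when
its binomial upper-tail probability is below α. For 13–50 children and
a limit of three nominations the upper critical value is uniformly 7 —
`binomial_limits(12, 3, 12)` and `binomial_limits(49, 3, 49)` both
return UL = 7 — which is why the method can use an absolute cutoff.
Its neglected criterion is a raw-impact bound, PNR + NNR ≤ 2, which
does not distinguish the two valences.

**Adjusted probability method (GB).** Critical values are recomputed
per classroom. The trial model is
X ~ Binomial(n_voters, mean_given / (G − 1)): the nominee pool excludes
the child itself, the trial count uses only children who actually
submitted nominations of that valence minus one (a child cannot vote
for itself), and `mean_given` is the realized expansiveness of those
voters. This is what makes the method robust to non-voters: absent
voters lower both the trial count and nothing else, rather than
silently deflating everyone's expected score. Neglected status requires
PNR ≤ 1 *and* NNR < M_NNR, deliberately excluding the 2-0 pair (very
close to the typical positive mean, and disproportionately often
reciprocated) while admitting 1-2.

`enumerate_pairs()` renders each criterion as the exhaustive set of
integer pairs admissible for a status given classroom parameters. At
the typical sample means (M_PNR = 2.79, M_NNR = 2.39) the neglected
regions are eight pairs for the standard-score method (2-1 through
1-2), six for the fixed-cutoff method (2-0 through 0-2) and six for the
adjusted method (1-1, 1-0, 0-0, 0-1, 0-2, 1-2).

## Numerical conventions

- **Population SD everywhere.** A classroom is the entire population of
  interest, so all within-classroom standardization divides by N. The
  choice must be fixed somewhere: the published worked numbers
  (VC = 0.74 with Z₀ = −1.35 at M = 3) are consistent with either
  convention at two decimals, and the package declares the population
  convention canonical for counts, composites and behaviour scales
  alike.
- **Strict rarity.** "Rare at level α" means tail probability strictly
  below α. Counts are integers, so realized levels are more restrictive
  than α itself; the realized tails are reported in the
  `probability_limits` object.
- **Lower limits may be absent.** When even a count of zero is not rare
  (P(X = 0) ≥ α) the lower limit is reported as `NA` rather than
  clamped.
- **Mean comparisons are strict as printed** (`< M`, `≥ M`). Ties at
  integer means follow that printed strictness.
- **Criterion order.** The four non-average predicates of the
  probability methods are mutually exclusive by construction (the
  supplementary mean conditions see to it), which the test suite
  asserts on exhaustive pair grids; evaluation order
  preferred → rejected → controversial → neglected therefore only
  affects audit strings.
- **Display rounding.** z-quantities are conventionally reported to two
  decimals; the package keeps full precision internally and rounds only
  in audit strings.
- **Degenerate inputs.** Zero variance in a count dimension makes the
  standard-score method inapplicable and raises an error naming the
  classroom; a zero mean makes VC undefined; behaviour scales with zero
  variance in a classroom cannot be standardized and error with the
  scale named. Status groups with fewer than two members are dropped
  (with a warning) before ANOVA.

## The continuous approximation

The original adjusted-method software derived cutoffs from tables of a
continuous (Pearson type III) approximation to the binomial, whose
exact contents are not documented. The package's default is therefore
the exact tail sum, and `method = "salvosa"` opts into a
skewness-corrected normal quantile (a first-order Cornish–Fisher
adjustment with continuity correction). Over the practical grid —
group sizes 13–50, expansiveness 1 to 3 — the approximation agrees
with the exact limits to within one nomination everywhere (a property
the acceptance tests check), but it is an approximation and never the
default.

## The synthetic classroom generator

`sim_config()` / `generate_classroom()` plant a status structure and
draw nominations from it; they are the package's instrument for
recovery experiments, not a model fitted to any particular sample.

- **Planted proportions** default to meta-analytic base rates: 13%
  preferred, 13% rejected, 15% neglected, 4% controversial, remainder
  average.
- **Nomination draws.** Every voter gives the full quota of three
  positive nominations and uses each of its three negative slots with
  propensity 0.8, so mean negative expansiveness is 2.4 — matching the
  robust empirical pattern that liking is more expansive than
  disliking. Nominees are drawn without replacement with probability
  proportional to their status's attraction weight; positive and
  negative sets are disjoint per voter by default (prototypical voters
  rarely like and dislike the same peer). Default weights spread
  positive nominations broadly (preferred 2.5, average 1, rejected 0.5,
  neglected 0.3) and concentrate negative ones (rejected 5, average
  0.7, preferred 0.2): under these defaults the mean variation
  coefficient over simulated classrooms is about 0.79 for PNR and 1.26
  for NNR, reproducing the PNR-less-dispersed-than-NNR contrast that
  drives the standard-score method's biases. The `"strong"` preset
  raises the dominant weights to 10× the average child for
  planted-structure recovery experiments.
- **Behaviour scores** are the status's mean shift (in SD units) plus
  unit Gaussian noise, standardized within the classroom. Default
  shifts follow the canonical repertoires (preferred: likeable, neither
  aggressive nor withdrawn; rejected: aggressive and somewhat
  withdrawn, not likeable; neglected: low on aggression and
  likeability; controversial: high on aggression and likeability). The
  unit-variance noise is the minimal model under which the ANOVA
  homogeneity assumption holds under the null.
- **Participation** below 1 removes voters uniformly at random — no
  hypothesis is imposed about *which* status abstains, since none is
  documented.

What the generator does **not** emulate: reciprocity structure beyond
what attraction weights induce, friendship cliques and transitivity,
same-gender nomination preferences, and measurement error in the
behaviour instrument. Passing recovery tests therefore show that the
classifiers behave as specified under their own assumptions, not that
any method attains a particular accuracy on real classrooms.

## Agreement and validation machinery

Cohen's kappa is computed from the 5×5 contingency table with
marginal-product chance agreement; per-type kappas dichotomize each
status against the rest — the only definition that yields one kappa per
type from two five-way labelings. Reports default to the full roster as
denominator; a union-of-identified variant (restricting to children
either method assigned the type) is available because published
per-type tables are ambiguous about their denominators. Landis–Koch
verbal bands are attached since the literature interprets kappas
verbally.

Behavioural validation runs one one-way ANOVA per scale with status as
the factor. Homogeneity of variances is tested with median-centred
Levene's test at 0.05 (the field default; the choice of homogeneity
test is not prescribed anywhere), selecting Tukey's HSD when it holds
and Games-Howell otherwise. With three scales per sample, the
Bonferroni-adjusted level is 0.05/3 ≈ 0.017, applied across scales
within a sample and not across methods. The Games-Howell implementation
uses Welch degrees of freedom with studentized-range p-values and is
cross-checked in the tests against reference values from an independent
statistics library.

One design decision deserves record: the recovery experiments plant
behavioural separation as ±1 SD shifts — preferred and rejected moved
one SD in *opposite* directions on aggression and likeability. A
one-sided +1 SD shift of a single group among five (n = 30 per group)
has joint two-scale detection power of only about 0.91 at the adjusted
level, so no simulation could verify a 95% detection rate under it;
the symmetric profile (noncentrality 60 per scale, power ≈ 1) is also
the behaviourally realistic one, since preferred and rejected children
sit at opposite ends of both scales.

## Problem sizes

The test suite and acceptance checks run at deliberately modest scale,
chosen as the smallest sizes at which the properties are stable:
classrooms of 13–40 children, 30–200 Monte-Carlo replicates for
recovery and dispersion contrasts, 1,000 random labelings for the kappa
oracle equivalence, 40–100 seeds for the ANOVA power and type-I
checks, and the full 13–50 × {1, 1.5, …, 3} grid for the
exact-vs-approximate limit comparison.

## Limitations

- Only nominations are supported, not rating-scale sociometrics.
- The criteria are validated for a nomination limit of three; the API
  accepts other limits (and exposes the `max(LL, 1)` neglected hook
  intended for five or unlimited nominations) but makes no validity
  claims there.
- The fixed-cutoff method's behaviour outside the 13–50 group-size
  window is undefined; the classifier warns and proceeds.
- Perceived popularity and network-centrality measures are out of
  scope; social impact is the only salience measure computed.
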