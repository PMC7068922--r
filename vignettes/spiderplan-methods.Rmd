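---
title: "Plan scoring, preference-based weight elicitation, and rater agreement: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plan scoring, preference-based weight elicitation, and rater agreement: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiderplan)
```

Comparing competing radiotherapy treatment plans is a multi-criteria
decision: target coverage trades off against the sparing of many organs at
risk (OARs), and different clinicians weigh those criteria differently.
This package implements a complete scoring-and-comparison workflow: dose
metrics are scored against protocol tolerances, aggregated into weighted
group and global scores, displayed on radar diagrams, and compared under
an equivalence threshold; group weights can be elicited automatically from
clinician pairwise preferences; and rater consistency is quantified with
Brennan-Prediger agreement coefficients. This vignette describes the
models, their assumptions, and the numerical choices made.

## The scoring model

Every structure carries one or more protocol tolerance criteria, each a
DVH metric (D98 for targets; Dmax, Dmean or a dose-at-volume metric for
OARs) and a tolerance dose $D_{TC}$ in Gy. Scores express goal fulfilment
relative to the tolerance:

* targets (coverage): $s = D_{TC} / D_P$, where $D_P$ is the planned
  value of the same metric the tolerance is stated on;
* OARs (sparing): $s = D_P / D_{TC}$.

Both directions give $s = 1$ exactly at the goal and $s < 1$ when the
plan does better than the goal; **lower is better everywhere**. Scores are
deliberately *not* capped: a score of 1.3 tells the reader by how much a
goal is violated, and capping would hide exactly the information the
radar diagrams exist to show.

Structures are partitioned into clinically meaningful groups (e.g. PTV,
Critical, Salivary), each group with a relative weight and each structure
with a relative weight within its group. The global plan score is the
double weighted sum

$$ S \;=\; \sum_i w_{group(i)} \sum_{j \in i} w_{struct(j)}\, s_j, $$

with both weight levels renormalized to sum to one, so weights may be
entered as percentages. Because the weights form a convex combination,
$\min_j s_j \le S \le \max_j s_j$, and a plan sitting exactly at every
tolerance has $S = 1$.

Two policy choices matter in practice:

* a structure that is configured but missing from a plan is a **hard
  error**, not a silent renormalization — dropping a weighted structure
  would make global scores incomparable across plans;
* a structure present in the plan but absent from the configuration is
  ignored with a warning (it carries no weight);
* when one structure carries several criteria (say Dmax and Dmean), the
  per-criterion scores are averaged into the structure score. Typical
  protocols state one criterion per structure; the average keeps the
  score's "1 = exactly at goals" anchor.

## Plan comparison and the equivalence threshold

Between two plans the lower global score wins, except that a score
difference strictly below the equivalence threshold (default **0.005** on
the global-score scale) makes the plans *dosimetrically equivalent*:
below that difference the ranking is noise, and clinicians themselves
disagree on such pairs. The threshold is configurable per pathology; 0
reduces the rule to pure argmin with exact ties equivalent.

Concordance against rater choices is reported twice — ignoring the
threshold and applying it. A rater's "both"/"neither" answer matches only
an equivalent verdict; with the lenient flag set (the default), an
equivalent verdict additionally counts as agreement with *any* choice,
since either selection is acceptable when the difference is
sub-threshold. Under this rule the thresholded agreement count is
non-decreasing in the threshold, which the tests assert.

## Automatic weight elicitation

Raters compare plans pairwise within cases; choices are aggregated by
**strict majority** (a pair $(j,k)$ enters the preference set $\Omega$
when strictly more voting raters preferred $j$; "both"/"neither" answers
abstain). The elicitation model assumes each decision-maker has an
*ideal point* $x$ in group-score space and prefers plans closer to it in
the weighted distance

$$ d_j = \sqrt{\textstyle\sum_p w_p (y_{jp} - x_p)^2}. $$

The task is to find $w \ge 0$ and $x$ violating as few pairs of $\Omega$
as possible. With $v_p = w_p x_p$ the satisfaction condition
$d_j \le d_k$ is linear,

$$ \sum_p (y_{kp}^2 - y_{jp}^2) w_p \;-\; 2 \sum_p (y_{kp} - y_{jp}) v_p \;\ge\; 0, $$

and attaching one binary indicator per pair yields a mixed-integer
program minimizing the number of violated pairs.

### Normalization

The model is positively homogeneous in $(w, v)$, so a normalization must
exclude $w = 0$. A normalization sometimes used for this model — setting
the *sum of all pair-constraint left-hand sides* to 1 — is degenerate
here: for any cyclic preference set the sum telescopes to exactly zero,
making the program infeasible precisely on the instances where violations
are inevitable. This package instead constrains the weights to the unit
simplex, $\sum_p w_p = 1$, and the ideal point to a box $[L, U]$ per
coordinate, encoded exactly by $L w_p \le v_p \le U w_p$ (valid because
$w_p \ge 0$). The default box is the observed score range widened by one
full range on each side — generous enough that it never binds in
practice, while keeping the search space bounded. Wherever the pair-sum
normalization is feasible the two formulations have the same optimal
violation count, by homogeneity.

### Exact solution

No big-M constant is ever chosen: the solver searches candidate violation
sets in order of increasing cardinality and certifies each candidate by a
feasibility check on the remaining (satisfied) constraints — exactly the
$M \to \infty$ limit of the big-M formulation, and immune to the
loose-relaxation and M-tuning issues that finite constants bring.
Feasibility subproblems are solved as minimum-norm quadratic programs
(`quadprog`), which detect infeasibility reliably at this scale. The
first cardinality with a feasible satisfied set is the exact optimum.

This search is exponential in the optimum, not in $|\Omega|$; it is
intended for study-sized preference sets (tens of pairs, few majority
inversions), which it solves in milliseconds, and it guards itself with a
candidate budget rather than silently returning a bound. Noise-free
preference sets are recognized in a single feasibility check.

Among optimal models the reported $(w, x)$ maximizes the smallest
constraint slack (found by bisection), so satisfied preferences are
reproduced *strictly* wherever possible. The integer objective is the
deterministic contract; the optimizing $(w, x)$ is generally not unique.
Where $w_p$ falls below `w_tol` ($10^{-6}$ on the simplex scale) the
coordinate $x_p = v_p / w_p$ is undefined and reported as 1 by
convention: a zero-weight group plays no role in preference, so its
satisfaction point defaults to "exactly at the planning goal".

The strictness margin $\varepsilon$ (default 0) controls whether exact
distance ties satisfy a preference. The default matches the weak
inequality of the program above; `violation_count()` mirrors it by
counting only *strict* excess distance as a violation.

### The independent oracle

`brute_force_elicit()` cross-checks the solver. A dense lattice over
simplex weights and boxed ideal points is scanned — but a lattice alone
cannot certify equality, because optimal regions can be *thin* or even
lower-dimensional (optima that exist only where a distance tie holds
exactly). The oracle therefore also enumerates, for $t \le 2$, every
vertex of the arrangement formed by the pair hyperplanes and box faces in
the linearized coordinates: the violation count is piecewise constant
over this arrangement, ties count as satisfied, and each bounded cell's
minimum is attained at a vertex, so the candidate minimum is the exact
optimum. At $t = 3$ only the lattice is scanned and the result is an
upper bound to grid coarseness (the function is guarded to $t \le 3$,
$n \le 8$). The test suite checks solver-oracle equality on 50 random
instances with $t \le 2$, $n \le 6$.

## Rater agreement

For plan *selection* (nominal categories) the Brennan-Prediger
coefficient is

$$ K = \frac{p_o - 1/q}{1 - 1/q}, $$

with $p_o$ the observed exact-agreement proportion and chance agreement
fixed at $1/q$ — unlike Cohen's kappa it does not depend on the raters'
marginal frequencies. The plan-selection category set is
$\{A, B, both\}$, i.e. $q = 3$: this is the reading under which a
4-item table with 2 agreements gives $K = 0.25$ and with 1 agreement
gives $K = -0.125$ (printed $-0.13$), the reference fixtures of the test
suite.

For plan *evaluation* (ordered quality grades) the weighted extension
credits partial agreement with
$w_{kl} = 1 - \left(|k-l|/(q-1)\right)^s$, $s = 1$ (linear, the default)
or $s = 2$ (quadratic), and chance term $p_e = \sum_{kl} w_{kl}/q^2$.
With the identity weight matrix it reduces exactly to the nominal
coefficient, which the tests assert. Coefficients map to the Landis-Koch
strength bands (poor / slight / fair / moderate / substantial / almost
perfect), with the band edges read as printed: 0.20 is still "slight",
0.40 still "fair", and so on. Agreement among more than two raters is
summarized as the mean of pairwise coefficients, reported per pair as
well.

## The synthetic-data generator

The generator exists so that every module is testable with known ground
truth:

* `simulate_scores()` draws group scores i.i.d. uniform on
  $[0.3, 1.4]$ — a range spanning clearly compliant through clearly
  violating plans, matching the spread seen in practice; no distributional
  claim beyond that is intended;
* `simulate_preferences()` emulates a paired-plan rater study: plans are
  paired into cases (disjoint consecutive pairs by default, mirroring a
  two-arm study; all pairs optionally), three raters by default, each
  preferring the plan closer to the true ideal point, flipping their
  choice with probability `noise`, and answering "both" on exact ties;
* `simulate_ratings()` places an exact number of agreements at seeded
  positions, so kappa fixtures hit their targets identically.

What the generator does **not** emulate: correlated structure doses,
realistic DVH shapes, rater-specific systematic biases, or case
difficulty varying with anatomy. Green tests therefore demonstrate
algorithmic correctness — recovery of a known model from its own
preferences, agreement of two independent solvers, exact fixture
reproduction — not clinical performance, which requires a rater study.

Test problem sizes were chosen to exercise the mathematics while keeping
the suite fast: 50 solver-oracle instances at $t \le 2$, $n \le 6$ with a
25% single-rater flip rate; noise-free recovery over 20 plans and 6
groups (190 preference pairs) across 20 seeds; noisy-majority budget
checks over 30 plans in paired cases. The whole suite runs in seconds.

## Numerical choices

* Feasibility QPs use an identity objective (minimum-norm point);
  infeasibility is signalled by the dual method and treated as a
  definitive "no".
* Ties and sign decisions use a $10^{-9}$ tolerance; solver dust below
  $10^{-10}$ on weights is clipped to zero.
* Weight renormalization tolerates any positive scale and rejects
  all-zero input.
* Exact-tie verdicts in plan comparison are equivalent at any threshold,
  so `threshold = 0` stays well-defined.
* Diagram radial limits are `max(1.2, 1.1 * max score)`, keeping every
  polygon inside the frame with visible margin around the unit ring;
  with fewer than three axes a polygon is degenerate and bars are drawn
  instead.

## Known limitations

* The exact elicitation search scales exponentially with the number of
  *violated* pairs; heavily inconsistent preference sets over many pairs
  exceed its candidate budget by design (it errors rather than
  approximates).
* The $t = 3$ oracle is lattice-only; certifying solver optimality there
  relies on the $t \le 2$ equivalence plus the solver's
  cardinality-search structure.
* Multi-rater agreement is a mean of pairwise coefficients, not a joint
  multi-rater model.
* Dose metrics are taken as given (in Gy, one row per structure-metric);
  DICOM-RT parsing and DVH extraction are out of scope.
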