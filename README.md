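# spiderplan

Scoring, comparison and preference-based configuration of radiotherapy
treatment plans, with radar-diagram visualization and rater-agreement
statistics.

Choosing between competing treatment plans is a multi-criteria decision:
target coverage trades off against the sparing of many organs at risk
(OARs), and the weight each criterion deserves is a clinical judgement.
`spiderplan` turns protocol dose-tolerance criteria into per-structure
scores, aggregates them into weighted group and global plan scores,
displays them on radar diagrams against the unit "all goals met" contour,
and decides between plans with an equivalence threshold. Group weights can
be set by protocol or **elicited automatically from clinician pairwise
preferences** via an exact ideal-point mixed-integer program, and rater
consistency is quantified with Brennan-Prediger kappa coefficients on the
Landis-Koch scale.

## The model

Each structure is scored against its tolerance dose $D_{TC}$ (in Gy, on a
stated DVH metric such as D98, Dmax or Dmean):

* target coverage: $s = D_{TC}/D_P$;
* OAR sparing: $s = D_P/D_{TC}$;

so $s = 1$ means exactly at the goal, $s < 1$ better than the goal, and
lower is better throughout. Scores are never capped — values above 1 show
the magnitude of a violated goal. Structures belong to weighted groups and
the global plan score is the convex double sum

$$ S = \sum_i w_{group(i)} \sum_{j\in i} w_{struct(j)}\, s_j . $$

Two plans whose global scores differ by less than the equivalence
threshold (default 0.005) are judged dosimetrically equivalent; otherwise
the lower score wins.

For weight elicitation, each rater is modelled as preferring plans closer
(in weighted Euclidean distance) to an ideal point $x$ in group-score
space. Given majority-aggregated preference pairs, the solver finds
simplex weights $w$ and $x$ minimizing the number of violated pairs —
exactly, by cardinality search over violation sets with LP-feasibility
certificates. An exhaustive independent oracle (`brute_force_elicit`)
cross-checks the optimum on small instances.

## Worked example

```r
library(spiderplan)

tol <- tolerance_table(data.frame(
  structure = c("PTV70", "SpinalCord", "Brainstem", "Parotids"),
  metric    = c("D98", "Dmax", "Dmax", "Dmean"),
  dose_gy   = c(66.5, 45, 54, 26),          # 66.5 = 95% of the 70 Gy Rx
  role      = c("target", "oar", "oar", "oar")))

cfg <- group_config(list(                    # weights as percentages
  list(name = "PTV",      weight = 50, structures = list("PTV70")),
  list(name = "Critical", weight = 30,
       structures = list(list(name = "SpinalCord", weight = 60),
                         list(name = "Brainstem",  weight = 40))),
  list(name = "Salivary", weight = 20, structures = list("Parotids"))))

planA <- plan_metrics("A", data.frame(
  structure = c("PTV70", "SpinalCord", "Brainstem", "Parotids"),
  metric    = c("D98", "Dmax", "Dmax", "Dmean"),
  dose_gy   = c(67.9, 38.2, 49.1, 24.3)))
planB <- plan_metrics("B", data.frame(
  structure = c("PTV70", "SpinalCord", "Brainstem", "Parotids"),
  metric    = c("D98", "Dmax", "Dmax", "Dmean"),
  dose_gy   = c(68.4, 41.0, 44.8, 28.9)))

sA <- score_plan(planA, tol, cfg)
sB <- score_plan(planB, tol, cfg)
print(sA)
#> Plan A: global score 0.9385
#> Group scores:
#>   PTV          0.9794
#>   Critical     0.8730
#>   Salivary     0.9346
print(sB)
#> Plan B: global score 0.9720
#> Group scores:
#>   PTV          0.9722
#>   Critical     0.8785
#>   Salivary     1.1115
```

Plan A beats its coverage goal slightly (PTV score 0.979 < 1) and spares
the critical organs well; plan B violates the salivary goal (1.11 > 1).
The decision rule picks A — the difference (0.033) is far above the 0.005
equivalence threshold:

```r
decide(sA$global_score, sB$global_score)
#> Case NA: A = 0.9385, B = 0.9720, delta = -0.0334 -> A

render_structure_diagram(list(sA, sB), cfg, "structures.png")
render_group_diagram(list(sA, sB), cfg, "groups.png")
```

Weight elicitation from simulated rater choices with known ground truth:

```r
Y <- simulate_scores(n_plans = 20, t_groups = 3, seed = 42)
sim <- simulate_preferences(Y, c(0.5, 0.3, 0.2), c(0.8, 0.9, 1.0),
                            noise = 0, n_raters = 3, seed = 43)
omega <- build_preference_set(sim$choices, sim$cases)
solve_elicitation(Y, omega)
#> Ideal-point elicitation: 0 of 10 preference pairs violated
#>    weight weight_pct ideal_point undefined
#> G1 0.0488        4.9     -0.7788     FALSE
#> G2 0.8069       80.7      0.9426     FALSE
#> G3 0.1443       14.4      2.4712     FALSE
```

The objective (0 violated pairs) is the deterministic contract; with only
ten paired cases many weight/ideal-point combinations reproduce all
preferences, so the reported model is one certified optimum, not a unique
truth.

Intra-rater agreement on plan selection (categories A / B / both):

```r
k <- nominal_kappa(rating_table(c("A", "A", "B", "both"),
                                c("B", "A", "both", "B"),
                                categories = c("A", "B", "both")))
c(kappa = k, label = landis_koch(k))
#>    kappa    label
#>   -0.125   "poor"
```

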