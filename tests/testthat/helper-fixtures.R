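# Shared fixture builders: a small nasopharynx-like protocol with three
# structure groups, built in code so tests carry no data files.

# Two-decimal rounding with halves away from zero, the convention used
# when quoting kappa values (base round() rounds halves to even).
round_half_away <- function(x, digits = 2) {
  x <- round(x, 10)  # shed floating-point dust below print precision
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

fixture_tolerances <- function() {
  tolerance_table(data.frame(
    structure = c("PTV70", "SpinalCord", "Brainstem", "Parotids"),
    metric = c("D98", "Dmax", "Dmax", "Dmean"),
    dose_gy = c(66.5, 45, 54, 26),
    role = c("target", "oar", "oar", "oar"),
    stringsAsFactors = FALSE))
}

fixture_config <- function() {
  group_config(list(
    list(name = "PTV", weight = 50,
         structures = list(list(name = "PTV70", weight = 1))),
    list(name = "Critical", weight = 30,
         structures = list(list(name = "SpinalCord", weight = 60),
                           list(name = "Brainstem", weight = 40))),
    list(name = "Salivary", weight = 20,
         structures = list(list(name = "Parotids", weight = 1)))))
}

# Plan whose every metric sits exactly at its tolerance (all scores 1).
fixture_plan_at_tolerance <- function(plan_id = "at_tol") {
  plan_metrics(plan_id, data.frame(
    structure = c("PTV70", "SpinalCord", "Brainstem", "Parotids"),
    metric = c("D98", "Dmax", "Dmax", "Dmean"),
    dose_gy = c(66.5, 45, 54, 26),
    stringsAsFactors = FALSE))
}

# Plan with prescribed per-structure scores (inverts the scoring formulas).
fixture_plan_with_scores <- function(plan_id, s_ptv, s_cord, s_stem, s_par) {
  plan_metrics(plan_id, data.frame(
    structure = c("PTV70", "SpinalCord", "Brainstem", "Parotids"),
    metric = c("D98", "Dmax", "Dmax", "Dmean"),
    dose_gy = c(66.5 / s_ptv, 45 * s_cord, 54 * s_stem, 26 * s_par),
    stringsAsFactors = FALSE))
}

# Small random elicitation instance: scores, an ideal-point truth, and
# single-rater choices over all plan pairs with the given flip rate.
fixture_elicitation_instance <- function(seed, n, t, noise = 0.25,
                                         n_raters = 1) {
  Y <- simulate_scores(n, t, seed = seed)
  set.seed(seed + 500)
  w <- normalize_weights(runif(t))
  x <- runif(t, 0.4, 1.2)
  sim <- simulate_preferences(Y, w, x, noise = noise, n_raters = n_raters,
                              cases = "all", seed = seed + 1000)
  omega <- build_preference_set(sim$choices, sim$cases)
  list(Y = Y, omega = omega, w = w, x = x, sim = sim)
}

# The 1-D cyclic preference fixture: three plans, cyclic majority, whose
# minimum violation count is exactly 1.
fixture_cycle <- function() {
  list(Y = matrix(c(0.2, 0.5, 0.9), ncol = 1,
                  dimnames = list(c("p1", "p2", "p3"), "G1")),
       omega = data.frame(preferred = c("p1", "p2", "p3"),
                          other = c("p2", "p3", "p1"),
                          stringsAsFactors = FALSE))
}
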