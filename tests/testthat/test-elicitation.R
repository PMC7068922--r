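test_that("majority aggregation builds the preference set", {
  cases <- data.frame(case_id = "c1", plan_a = "p1", plan_b = "p2")
  mk <- function(ch) data.frame(case_id = "c1",
                                rater_id = paste0("R", seq_along(ch)),
                                choice = ch)
  # strict majority A over B
  om <- build_preference_set(mk(c("A", "A", "B")), cases)
  expect_equal(nrow(om), 1L)
  expect_equal(om$preferred, "p1")
  expect_equal(om$other, "p2")
  # 1-1 with an abstention: no majority, no pair
  expect_equal(nrow(build_preference_set(mk(c("A", "B", "both")), cases)), 0L)
  # all equivalence calls: no pair
  expect_equal(nrow(build_preference_set(mk(c("both", "both", "both")),
                                         cases)), 0L)
  # abstentions drop out of the denominator: 1 strict vote decides
  om2 <- build_preference_set(mk(c("B", "neither", "both")), cases)
  expect_equal(om2$preferred, "p2")

  empty <- data.frame(case_id = character(0), rater_id = character(0),
                      choice = character(0))
  expect_error(build_preference_set(empty, cases),
               "empty", class = "spiderplan_validation_error")
  expect_error(build_preference_set(mk("C"), cases),
               "invalid choice", class = "spiderplan_validation_error")
  expect_error(
    build_preference_set(data.frame(case_id = "cX", rater_id = "R1",
                                    choice = "A"), cases),
    "unknown case", class = "spiderplan_validation_error")
})

test_that("weighted distance matches its closed form", {
  expect_equal(weighted_distance(c(0.7, 1.1), c(1, 1), c(0.7, 1.1)), 0)
  expect_equal(weighted_distance(0.5, 1, 0), 0.5)
  expect_equal(weighted_distance(c(1, 1), c(1, 1), c(0, 0)), sqrt(2))
  expect_equal(weighted_distance(c(1, 2), c(0.25, 0.75), c(0, 0)),
               sqrt(0.25 * 1 + 0.75 * 4))
  expect_error(weighted_distance(c(1, 2), c(-1, 2), c(0, 0)),
               class = "spiderplan_validation_error")
  expect_error(weighted_distance(c(1, 2), 1, 0),
               class = "spiderplan_validation_error")
})

test_that("violation counting is consistent with the induced ordering", {
  set.seed(5)
  for (rep in 1:10) {
    t <- sample(1:3, 1)
    Y <- simulate_scores(6, t, seed = rep)
    w <- normalize_weights(runif(t))
    x <- runif(t, 0.3, 1.4)
    d2 <- as.numeric((Y - matrix(x, 6, t, byrow = TRUE))^2 %*% w)
    ord <- order(d2)
    # Omega from the model's own strict ordering: zero violations
    omega <- data.frame(preferred = rownames(Y)[ord[1:5]],
                        other = rownames(Y)[ord[2:6]])
    expect_equal(violation_count(Y, omega, w, x), 0L)
    # total inversion: every pair violated
    rev_omega <- data.frame(preferred = omega$other, other = omega$preferred)
    expect_equal(violation_count(Y, rev_omega, w, x), nrow(omega))
  }
})

test_that("simple elicitation instances solve to their known optima", {
  # two orderable plans: any ideal point near the preferred one works
  Y2 <- matrix(c(0.5, 1.0), ncol = 1, dimnames = list(c("p1", "p2"), "G1"))
  r2 <- solve_elicitation(Y2, data.frame(preferred = "p1", other = "p2"))
  expect_identical(r2$objective, 0L)
  expect_equal(violation_count(Y2, data.frame(preferred = "p1", other = "p2"),
                               r2$weights, r2$ideal_point), 0L)

  # the 1-D 3-cycle forces exactly one violation
  cyc <- fixture_cycle()
  rc <- solve_elicitation(cyc$Y, cyc$omega)
  expect_identical(rc$objective, 1L)
  expect_identical(brute_force_elicit(cyc$Y, cyc$omega), 1L)
  expect_equal(sum(rc$violations$violated), 1L)

  # solution invariants: simplex weights, consistent auxiliaries
  expect_equal(sum(rc$weights), 1)
  expect_true(all(rc$weights >= -1e-9))
  ok <- !rc$undefined
  expect_equal(rc$auxiliaries[ok], rc$weights[ok] * rc$ideal_point[ok])
})

test_that("degenerate and malformed preference sets are rejected", {
  Y <- simulate_scores(4, 2, seed = 1)
  expect_error(solve_elicitation(Y, data.frame(preferred = character(),
                                               other = character())),
               "empty", class = "spiderplan_validation_error")
  expect_error(solve_elicitation(Y, data.frame(preferred = "plan1",
                                               other = "plan9")),
               "absent", class = "spiderplan_validation_error")
  expect_error(solve_elicitation(Y, data.frame(
    preferred = c("plan1", "plan2"), other = c("plan2", "plan1"))),
    "reverse", class = "spiderplan_validation_error")
  expect_error(solve_elicitation(Y, data.frame(preferred = "plan1",
                                               other = "plan1")),
               class = "spiderplan_validation_error")
})

test_that("ideal-point recovery flags zero-weight dimensions", {
  r <- recover_ideal_point(c(0.5, 0), c(0.25, 0))
  expect_equal(r$x, c(0.5, 1))  # undefined coordinate reported as 1
  expect_equal(r$undefined, c(FALSE, TRUE))
  r2 <- recover_ideal_point(c(0.4, 0.6), c(0.2, 0.3))
  expect_false(any(r2$undefined))
  expect_equal(r2$x, c(0.5, 0.5))
})

test_that("solver objective equals the exhaustive oracle on random instances", {
  # a fast subsample of the full 50-instance acceptance sweep
  for (s in c(3, 7, 11, 14, 19, 25, 33, 42)) {
    inst <- fixture_elicitation_instance(s, n = 4 + (s %% 3),
                                         t = 1 + (s %% 2))
    if (nrow(inst$omega) == 0) next
    expect_identical(solve_elicitation(inst$Y, inst$omega)$objective,
                     brute_force_elicit(inst$Y, inst$omega),
                     info = paste("seed", s))
  }
})

test_that("noise-free preferences are recovered with zero violations", {
  for (s in 1:5) {
    Y <- simulate_scores(12, 4, seed = s)
    set.seed(s + 50)
    w <- normalize_weights(runif(4))
    x <- runif(4, 0.5, 1.1)
    sim <- simulate_preferences(Y, w, x, noise = 0, cases = "all",
                                seed = s + 100)
    omega <- build_preference_set(sim$choices, sim$cases)
    res <- solve_elicitation(Y, omega)
    expect_identical(res$objective, 0L)
    # the recovered model reproduces the full preference set
    expect_identical(violation_count(Y, omega, res$weights,
                                     res$ideal_point), 0L)
  }
})

test_that("a strictness margin can forbid tie-satisfied solutions", {
  cyc <- fixture_cycle()
  r0 <- solve_elicitation(cyc$Y, cyc$omega, epsilon = 0)
  r1 <- solve_elicitation(cyc$Y, cyc$omega, epsilon = 0.01)
  expect_gte(r1$objective, r0$objective)
  expect_gte(r1$margin, 0.01 - 1e-9)
})
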