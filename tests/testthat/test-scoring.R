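test_that("target and OAR scores match their defining ratios", {
  # at the goal, both directions score exactly 1
  expect_equal(score_target(66.5, 66.5), 1)
  expect_equal(score_oar(45, 45), 1)
  # coverage above the goal scores below 1; under-dosage above 1
  expect_equal(score_target(68, 66.5), 66.5 / 68)
  expect_equal(score_target(63, 66.5), 66.5 / 63)
  expect_gt(score_target(63, 66.5), 1)
  # sparing better than the goal scores below 1
  expect_equal(score_oar(42, 45), 42 / 45)
  expect_equal(score_oar(0, 45), 0)
  expect_error(score_target(0, 66.5), class = "spiderplan_validation_error")
  expect_error(score_oar(10, 0), class = "spiderplan_validation_error")
})

test_that("a plan exactly at tolerance scores 1 at every level", {
  ss <- score_plan(fixture_plan_at_tolerance(), fixture_tolerances(),
                   fixture_config())
  expect_equal(unname(ss$structure_scores), rep(1, 4))
  expect_equal(unname(ss$group_scores), rep(1, 3))
  expect_equal(ss$global_score, 1)
})

test_that("the global score is the group-weighted structure-weighted sum", {
  # single-structure groups with weights 0.5/0.3/0.2 and structure scores
  # 0.95 / 0.80 / 1.10: global = 0.935 by hand
  cfg <- group_config(list(
    list(name = "PTV", weight = 0.5, structures = list("PTV70")),
    list(name = "Critical", weight = 0.3, structures = list("SpinalCord")),
    list(name = "Salivary", weight = 0.2, structures = list("Parotids"))))
  plan <- plan_metrics("mix", data.frame(
    structure = c("PTV70", "SpinalCord", "Parotids"),
    metric = c("D98", "Dmax", "Dmean"),
    dose_gy = c(66.5 / 0.95, 45 * 0.80, 26 * 1.10)))
  ss <- score_plan(plan, fixture_tolerances(), cfg)
  expect_equal(unname(ss$structure_scores), c(0.95, 0.80, 1.10))
  expect_equal(ss$global_score, 0.935)

  # single group, single structure: global is that structure's score
  solo <- group_config(list(
    list(name = "Salivary", weight = 1, structures = list("Parotids"))))
  plan2 <- plan_metrics("solo", data.frame(
    structure = "Parotids", metric = "Dmean", dose_gy = 13))
  expect_equal(score_plan(plan2, fixture_tolerances(), solo)$global_score,
               0.5)
})

test_that("missing structures error, unconfigured structures warn", {
  cfg <- fixture_config()
  tol <- fixture_tolerances()
  incomplete <- plan_metrics("p", data.frame(
    structure = c("PTV70", "SpinalCord", "Brainstem"),
    metric = c("D98", "Dmax", "Dmax"),
    dose_gy = c(66.5, 45, 54)))
  expect_error(score_plan(incomplete, tol, cfg), "Parotids",
               class = "spiderplan_validation_error")

  extra <- fixture_plan_at_tolerance()
  extra$entries <- rbind(extra$entries, data.frame(
    structure = "Larynx", metric = "Dmean", dose_gy = 30))
  expect_warning(ss <- score_plan(extra, tol, cfg), "Larynx")
  expect_equal(ss$global_score, 1)
})

test_that("scores are scale-invariant and respect monotonicity bounds", {
  set.seed(11)
  for (rep in 1:10) {
    # random plan around the fixture tolerances
    f <- runif(4, 0.7, 1.3)
    plan <- plan_metrics("r", data.frame(
      structure = c("PTV70", "SpinalCord", "Brainstem", "Parotids"),
      metric = c("D98", "Dmax", "Dmax", "Dmean"),
      dose_gy = c(66.5, 45, 54, 26) * f))
    tol <- fixture_tolerances()
    cfg <- fixture_config()
    ss <- score_plan(plan, tol, cfg)

    # multiplying all planned and tolerance doses by c changes nothing
    c_ <- runif(1, 0.5, 3)
    tol2 <- tol; tol2$dose_gy <- tol2$dose_gy * c_
    plan2 <- plan; plan2$entries$dose_gy <- plan2$entries$dose_gy * c_
    expect_equal(score_plan(plan2, tol2, cfg)$global_score, ss$global_score)

    # convex-combination bound
    expect_gte(ss$global_score, min(ss$structure_scores) - 1e-12)
    expect_lte(ss$global_score, max(ss$structure_scores) + 1e-12)

    # raising an OAR dose never lowers the global score; raising target
    # coverage dose never raises the target score
    plan3 <- plan
    i <- which(plan3$entries$structure == "Parotids")
    plan3$entries$dose_gy[i] <- plan3$entries$dose_gy[i] + 5
    expect_gte(score_plan(plan3, tol, cfg)$global_score, ss$global_score)
    plan4 <- plan
    j <- which(plan4$entries$structure == "PTV70")
    plan4$entries$dose_gy[j] <- plan4$entries$dose_gy[j] + 2
    expect_lte(score_plan(plan4, tol, cfg)$structure_scores[["PTV70"]],
               ss$structure_scores[["PTV70"]])
  }
})

test_that("two-stage aggregation equals the direct weighted sum", {
  set.seed(23)
  tol <- fixture_tolerances()
  cfg <- fixture_config()
  for (rep in 1:10) {
    plan <- plan_metrics("r", data.frame(
      structure = c("PTV70", "SpinalCord", "Brainstem", "Parotids"),
      metric = c("D98", "Dmax", "Dmax", "Dmean"),
      dose_gy = c(66.5, 45, 54, 26) * runif(4, 0.6, 1.4)))
    ss <- score_plan(plan, tol, cfg)
    # direct evaluation of the double sum, independent of score_plan's path
    direct <- 0
    for (g in cfg$groups) {
      direct <- direct +
        g$weight * sum(g$structure_weights * ss$structure_scores[g$structures])
    }
    expect_equal(ss$global_score, direct, tolerance = 1e-12)
    # group invariant
    for (g in cfg$groups) {
      expect_equal(ss$group_scores[[g$name]],
                   sum(g$structure_weights * ss$structure_scores[g$structures]),
                   tolerance = 1e-12)
    }
  }
})

test_that("score sets flatten and serialize", {
  ss <- score_plan(fixture_plan_at_tolerance(), fixture_tolerances(),
                   fixture_config())
  tab <- score_set_table(ss, fixture_config())
  expect_equal(tab$structure,
               c("PTV70", "SpinalCord", "Brainstem", "Parotids"))
  expect_equal(tab$group, c("PTV", "Critical", "Critical", "Salivary"))
  expect_equal(tab$score, rep(1, 4))

  stem <- file.path(withr::local_tempdir(), "s")
  write_score_set(ss, fixture_config(), stem)
  expect_true(file.exists(paste0(stem, ".csv")))
  js <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(js$global_score, 1)
  expect_equal(js$plan_id, "at_tol")
})
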