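test_that("edits are pure and leave the original scenario untouched", {
  s <- synthesize_scenario(5, 2, 6)
  snapshot <- unserialize(serialize(s, NULL))
  dropped <- s$interventions[[3]]$name
  s2 <- edit_scenario(s, edit_drop(dropped))
  expect_identical(s, snapshot)
  expect_false(dropped %in%
                 vapply(s2$interventions, `[[`, character(1), "name"))
  expect_length(s2$interventions, length(s$interventions) - 1)

  # the empty edit list is the identity (up to the name)
  s3 <- edit_scenario(s, list(), name = s$name)
  expect_equal(s3, s)
})

test_that("scaling a dose parameter scales demand linearly", {
  s <- synthesize_scenario(6, 2, 5)
  iv <- s$interventions[[2]]
  before <- annual_demand_hours(iv, s$profile)
  s2 <- edit_scenario(s, edit_scale(iv$name, "contacts_per_year", 0.5))
  iv2 <- Filter(function(x) x$name == iv$name, s2$interventions)[[1]]
  expect_equal(annual_demand_hours(iv2, s$profile), before / 2,
               tolerance = 1e-12)
  # target-level fields are editable through the same interface
  s3 <- edit_scenario(s, edit_set(iv$name, "facility_share", 0.5))
  iv3 <- Filter(function(x) x$name == iv$name, s3$interventions)[[1]]
  expect_equal(iv3$target$facility_share, 0.5)
})

test_that("edits referencing unknown targets list the valid names", {
  s <- synthesize_scenario(5, 2, 3)
  err <- expect_error(edit_scenario(s, edit_drop("nope")), "nope")
  expect_match(conditionMessage(err), "intervention-01")
  expect_error(edit_scenario(s, edit_headcount("nope", 5)), "cadre-01")
  expect_error(
    edit_scenario(s, edit_set("intervention-01", "bogus_field", 1)),
    "bogus_field")
  # edits that violate invariants are caught at rebuild
  expect_error(
    edit_scenario(s, edit_set("intervention-01", "coverage_goal", 2)),
    "\\[0, 1\\]")
})

test_that("comparing a scenario with itself gives an all-zero delta", {
  s <- synthesize_scenario(8, 2, 6)
  d <- compare_scenarios(s, s)
  expect_equal(d$cadres$d_required_chws, rep(0, nrow(d$cadres)))
  expect_equal(d$cadres$d_load_ratio, rep(0, nrow(d$cadres)))
  expect_equal(d$interventions$d_annual_hours,
               rep(0, nrow(d$interventions)))
  expect_equal(d$interventions$d_achievable_coverage,
               rep(0, nrow(d$interventions)))
  expect_length(d$added, 0)
  expect_length(d$removed, 0)
})

test_that("compare is antisymmetric and tracks dropped interventions", {
  s <- synthesize_scenario(8, 2, 6)
  dropped <- s$interventions[[1]]$name
  cd <- s$interventions[[1]]$cadre
  s2 <- edit_scenario(s, edit_drop(dropped))
  d <- compare_scenarios(s, s2)
  expect_equal(d$removed, dropped)
  expect_length(d$added, 0)
  # the dropped intervention's cadre sheds exactly demand/supply load
  dem <- annual_demand_hours(s$interventions[[1]], s$profile)
  cov <- expected_coverage(s)
  supply <- cov$cadres$supply_hours[cov$cadres$cadre == cd]
  expect_equal(d$cadres$d_load_ratio[d$cadres$cadre == cd], -dem / supply,
               tolerance = 1e-9)

  rev <- compare_scenarios(s2, s)
  expect_equal(rev$added, dropped)
  expect_equal(rev$cadres$d_load_ratio, -d$cadres$d_load_ratio)
  expect_equal(rev$cadres$d_required_chws, -d$cadres$d_required_chws)

  # mismatched profiles are allowed but flagged
  s3 <- synthesize_scenario(9, 2, 6)
  expect_warning(compare_scenarios(s, s3), "different profiles")
})

test_that("adding workforce strictly grows coverage of an overloaded cadre", {
  s <- unit_scenario(demands = c(800, 500), available = 600, headcount = 1)
  bigger <- edit_scenario(s, edit_headcount("cadre-a", 2))
  d <- compare_scenarios(s, bigger)
  expect_gt(-d$cadres$d_load_ratio, 0)
  a <- expected_coverage(s)$cadres$aggregate_achievable_share
  b <- expected_coverage(bigger)$cadres$aggregate_achievable_share
  expect_gt(b, a)
})

test_that("the frontier flags full coverage exactly at the staffing requirement", {
  s <- unit_scenario(demands = c(800, 500), available = 600, headcount = 1)
  need <- chws_needed(s)$cadres$required_chws  # ceil(1300/600) = 3
  expect_equal(need, 3)
  fr <- frontier(s, c(1, 2, 3, 4), "cadre-a")
  expect_equal(fr$full_coverage, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(fr$aggregate_achievable_share[fr$headcount == need], 1)
  expect_equal(fr$aggregate_achievable_share[1], 600 / 1300,
               tolerance = 1e-12)
  expect_true(all(diff(fr$aggregate_achievable_share) >= -1e-12))
  # doubling the grid never lowers any share
  fr2 <- frontier(s, 2 * c(1, 2, 3, 4), "cadre-a")
  expect_true(all(fr2$aggregate_achievable_share
                  >= fr$aggregate_achievable_share - 1e-12))
  expect_error(frontier(s, integer(0), "cadre-a"), "non-empty")
  expect_error(frontier(s, c(1, -2), "cadre-a"), "positive")
  expect_error(frontier(s, 1, "ghost"), "cadre-a")
})

test_that("chained edits on disjoint targets commute", {
  s <- synthesize_scenario(10, 2, 6)
  e1 <- edit_scale("intervention-01", "minutes_per_contact", 2)
  e2 <- edit_drop("intervention-02")
  ab <- edit_scenario(edit_scenario(s, e1), e2, name = "x")
  ba <- edit_scenario(edit_scenario(s, e2), e1, name = "x")
  expect_same_outputs(ab, ba)
})
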