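test_that("annual demand composes target, goal, dose, and delivery mode", {
  prof <- build_profile_from_counts("p", 10000, c(kids = 1000))
  tgt <- target_spec("stock-group", "kids")
  # 1,000 persons x 90% goal x 4 contacts x 30 min = 1,800 h
  hv <- intervention("hv", "c", "home-visit", tgt, 4, 30,
                     coverage_goal = 0.9)
  expect_equal(annual_demand_hours(hv, prof), 1800)
  # zero goal means zero demand
  expect_equal(annual_demand_hours(
    intervention("z", "c", "home-visit", tgt, 4, 30, coverage_goal = 0),
    prof), 0)
  # group sessions: 100 persons x 12 sessions / 20 per group x 1 h = 60 h
  prof2 <- build_profile_from_counts("p2", 1000, c(kids = 100))
  gs <- intervention("gs", "c", "group-session",
                     target_spec("stock-group", "kids"), 12, 60,
                     group_size = 20)
  expect_equal(annual_demand_hours(gs, prof2), 60)
  # per-visit travel surcharge adds to contact minutes
  hv_t <- intervention("hv", "c", "home-visit", tgt, 4, 30,
                       coverage_goal = 0.9,
                       travel_minutes_per_contact = 15)
  expect_equal(annual_demand_hours(hv_t, prof), 1800 * 45 / 30)
})

test_that("group-session ceiling variant rounds session batches up", {
  prof <- build_profile_from_counts("p", 1000, c(kids = 105))
  gs <- intervention("gs", "c", "group-session",
                     target_spec("stock-group", "kids"), 1, 60,
                     group_size = 20)
  expect_equal(annual_demand_hours(gs, prof), 105 / 20)
  expect_equal(annual_demand_hours(gs, prof, group_rounding = "ceiling"), 6)
})

test_that("available service hours net out block and share-based ancillary time", {
  # 18 h/wk x 52 wk with a third of time on travel -> 624 service h/yr
  expect_equal(available_service_hours(
    time_policy(18, 52, travel_share = 1 / 3)), 624)
  # no ancillary time: gross hours pass through
  expect_equal(available_service_hours(time_policy(20, 40)), 800)
  # training can consume everything
  expect_equal(available_service_hours(
    time_policy(10, 10, training_hours_per_year = 100)), 0)
  # block hours come off before shares are applied
  expect_equal(available_service_hours(
    time_policy(10, 50, travel_share = 0.25, admin_share = 0.25,
                training_hours_per_year = 60,
                campaign_hours_per_year = 40)),
    (500 - 100) * 0.5)
})

test_that("chws_needed takes the per-cadre ceiling of demand over supply", {
  # 1,000 h demand at 624 h per CHW -> 2 CHWs
  s <- unit_scenario(demands = c(600, 400), available = 624)
  expect_equal(chws_needed(s)$cadres$required_chws, 2)
  # zero demand -> zero CHWs
  s0 <- unit_scenario(demands = numeric(0), available = 624)
  expect_equal(chws_needed(s0)$cadres$required_chws, 0)
  # demand at an exact multiple of supply must not gain a spurious +1
  for (k in c(1, 2, 7, 50)) {
    sk <- unit_scenario(demands = rep(25, 4 * k), available = 100)
    expect_equal(chws_needed(sk)$cadres$required_chws, k)
  }
  # demand with zero available time is infeasible, and names the cadre
  prof <- build_profile_from_counts("p", 100, c(g = 10))
  dead <- cadre("idle", time_policy(0, 0), headcount = 5)
  iv <- intervention("x", "idle", "home-visit",
                     target_spec("stock-group", "g"), 1, 30)
  s_bad <- scenario("bad", prof, list(dead), list(iv))
  expect_error(chws_needed(s_bad), "idle")
})

test_that("expected_coverage reports the overload share seen in practice", {
  # per-CHW demand 1,300 h vs 632 h available -> under half the workload
  s <- unit_scenario(demands = 1300 * 3, available = 632, headcount = 3)
  cov <- expected_coverage(s)
  expect_equal(cov$cadres$aggregate_achievable_share, 632 / 1300,
               tolerance = 1e-12)
  expect_lt(cov$cadres$aggregate_achievable_share, 0.5)
  expect_equal(cov$cadres$load_ratio, 1300 / 632, tolerance = 1e-12)

  # slack capacity: every goal fully achievable
  s2 <- unit_scenario(demands = c(40, 60), available = 200, headcount = 1)
  cov2 <- expected_coverage(s2)
  expect_true(all(cov2$interventions$achievable_coverage == 1))
  expect_equal(cov2$cadres$aggregate_achievable_share, 1)

  # proportional rationing: both interventions at supply/demand
  s3 <- unit_scenario(demands = c(300, 100), available = 200, headcount = 1)
  cov3 <- expected_coverage(s3)
  expect_equal(cov3$interventions$achievable_coverage, c(0.5, 0.5))
  expect_equal(cov3$interventions$allocated_hours, c(150, 50))

  # headcount is required wherever there is work
  s4 <- unit_scenario(demands = 100, headcount = NA)
  expect_error(expected_coverage(s4), "headcount unset")
})

test_that("priority-fill allocates whole interventions in rank order", {
  s <- unit_scenario(demands = c(300, 100), available = 200, headcount = 1,
                     allocation = "priority-fill", priorities = c(1, 2))
  cov <- expected_coverage(s)
  expect_equal(cov$interventions$allocated_hours, c(200, 0))
  expect_equal(cov$interventions$achievable_coverage, c(2 / 3, 0))
  # reversing the priorities reverses the fill
  s2 <- unit_scenario(demands = c(300, 100), available = 200, headcount = 1,
                      allocation = "priority-fill", priorities = c(2, 1))
  cov2 <- expected_coverage(s2)
  expect_equal(cov2$interventions$allocated_hours, c(100, 100))
  # aggregate share is allocation-mode independent
  expect_equal(cov$cadres$aggregate_achievable_share,
               cov2$cadres$aggregate_achievable_share)
})

test_that("rank_time_consumers sorts by hours with alphabetic tie-breaks and unit shares", {
  s <- unit_scenario(demands = c(10, 30, 30), names = c("A", "C", "B"))
  r <- rank_time_consumers(s)
  expect_equal(r$intervention, c("B", "C", "A"))
  expect_true(all(diff(r$annual_hours) <= 0))
  expect_equal(sum(r$share_of_cadre), 1, tolerance = 1e-9)

  s1 <- unit_scenario(demands = 42)
  expect_equal(rank_time_consumers(s1)$share_of_cadre, 1)

  # sorting oracle on a synthesized package
  syn <- synthesize_scenario(11, 3, 20)
  r2 <- rank_time_consumers(syn)
  direct <- vapply(syn$interventions, annual_demand_hours, numeric(1),
                   profile = syn$profile)
  names(direct) <- vapply(syn$interventions, `[[`, character(1), "name")
  direct <- direct[order(-direct, names(direct), method = "radix")]
  expect_equal(r2$intervention, names(direct))
  expect_equal(r2$annual_hours, unname(direct))
  for (cd in unique(r2$cadre)) {
    expect_equal(sum(r2$share_of_cadre[r2$cadre == cd]), 1,
                 tolerance = 1e-9)
  }
})

test_that("staffing and coverage are dual: needed headcounts give full coverage, one less breaks it", {
  for (seed in 1:40) {
    s <- synthesize_scenario(seed, n_cadres = 1 + seed %% 3,
                             n_interventions = 1 + seed %% 6)
    st <- chws_needed(s)$cadres
    edits <- lapply(seq_len(nrow(st)), function(i) {
      edit_headcount(st$cadre[i], st$required_chws[i])
    })
    s_need <- edit_scenario(s, edits)
    cov <- expected_coverage(s_need)
    expect_true(all(cov$interventions$achievable_coverage > 1 - 1e-8))
    expect_true(all(cov$cadres$aggregate_achievable_share > 1 - 1e-8))
    binding <- st$cadre[st$required_chws > 0]
    for (cd in binding) {
      fewer <- edit_scenario(
        s_need, edit_headcount(cd, st$required_chws[st$cadre == cd] - 1))
      cov2 <- expected_coverage(fewer)
      expect_lt(cov2$cadres$aggregate_achievable_share[
        cov2$cadres$cadre == cd], 1)
    }
  }
})

test_that("achievable share moves monotonically with headcount, hours, and demand", {
  for (seed in c(2, 9, 17, 23)) {
    s <- synthesize_scenario(seed, 2, 6)
    cov <- expected_coverage(s)
    base <- cov$cadres$aggregate_achievable_share
    # more CHWs never reduce the achievable share
    hc <- cov$cadres$headcount
    s_up <- edit_scenario(s, lapply(seq_along(hc), function(i) {
      edit_headcount(cov$cadres$cadre[i], hc[i] * 2)
    }))
    expect_true(all(expected_coverage(s_up)$cadres$aggregate_achievable_share
                    >= base - 1e-12))
    # heavier demand never increases it
    iv <- s$interventions[[1]]
    s_dem <- edit_scenario(s, edit_set(iv$name, "contacts_per_year",
                                       iv$contacts_per_year * 3))
    cov_dem <- expected_coverage(s_dem)
    expect_true(all(cov_dem$cadres$aggregate_achievable_share
                    <= base + 1e-12))
  }
})

test_that("under overload, allocated hours conserve supply and never exceed demand", {
  for (seed in 1:15) {
    for (mode in c("proportional", "priority-fill")) {
      s <- synthesize_scenario(seed, 2, 8, allocation_mode = mode)
      cov <- expected_coverage(s)
      expect_true(all(cov$interventions$allocated_hours
                      <= cov$interventions$annual_hours + 1e-9))
      agg <- aggregate(allocated_hours ~ cadre, cov$interventions, sum)
      for (i in seq_len(nrow(agg))) {
        row <- cov$cadres[cov$cadres$cadre == agg$cadre[i], ]
        expected_alloc <- min(row$supply_hours, row$total_demand_hours)
        expect_equal(agg$allocated_hours[i], expected_alloc,
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("engine demand matches per-contact brute-force enumeration on small packages", {
  for (seed in 1:12) {
    pkg <- synthesize_package(seed, 2, 1 + seed %% 5,
                              ranges = tiny_ranges(), integerize = TRUE)
    for (iv in pkg$interventions) {
      expect_equal(annual_demand_hours(iv, pkg$profile),
                   brute_force_demand_hours(iv, pkg$profile),
                   tolerance = 1e-9, label = sprintf("seed %d, %s", seed,
                                                     iv$name))
    }
  }
})

test_that("time_per_chw pairs needed and available hours per cadre", {
  s <- unit_scenario(demands = 1300 * 3, available = 632, headcount = 3)
  tp <- time_per_chw(s)
  expect_equal(tp$hours_needed_per_chw, 1300)
  expect_equal(tp$hours_available_per_chw, 632)
})
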