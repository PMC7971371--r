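# Hand-built scenario with one cadre whose interventions have exactly the
# requested annual demand hours: each intervention targets a 1-person group
# and prescribes `demand` one-hour contacts per year. The time policy is
# hours_per_week = available, weeks_per_year = 1, so service supply per CHW
# is exactly `available` hours.
unit_scenario <- function(demands, available = 100, headcount = 1,
                          allocation = "proportional",
                          names = sprintf("iv-%02d", seq_along(demands)),
                          priorities = rep(NA, length(demands))) {
  prof <- build_profile_from_counts("unit-profile", 1000, c(unit = 1))
  cad <- cadre("cadre-a", time_policy(available, weeks_per_year = 1),
               headcount = headcount)
  ints <- lapply(seq_along(demands), function(i) {
    intervention(names[i], "cadre-a", "home-visit",
                 target_spec("stock-group", "unit"),
                 contacts_per_year = demands[i], minutes_per_contact = 60,
                 priority = priorities[i])
  })
  suppressWarnings(scenario("unit", prof, list(cad), ints,
                            allocation_mode = allocation))
}

# Independent demand oracle: enumerate every (person, contact) attendance
# slot one by one, then convert slots to hours. Only valid for integerized
# inputs (whole persons and contacts, coverage goal 1).
brute_force_demand_hours <- function(iv, profile) {
  persons <- round(target_population(profile, iv$target))
  minutes <- iv$minutes_per_contact + iv$travel_minutes_per_contact
  slots <- 0
  for (p in seq_len(persons)) {
    for (k in seq_len(iv$contacts_per_year)) slots <- slots + 1
  }
  if (iv$mode == "group-session") {
    slots * minutes / (60 * iv$group_size)
  } else {
    slots * minutes / 60
  }
}

# synth ranges with tiny populations so brute-force enumeration stays fast
tiny_ranges <- function() {
  synth_ranges(total_population = c(200, 2000), headcount = c(1, 50))
}

expect_same_outputs <- function(a, b, tol = 1e-9) {
  expect_equal(chws_needed(a)$cadres, chws_needed(b)$cadres, tolerance = tol)
  expect_equal(rank_time_consumers(a), rank_time_consumers(b),
               tolerance = tol)
  ca <- expected_coverage(a); cb <- expected_coverage(b)
  expect_equal(ca$cadres, cb$cadres, tolerance = tol)
  expect_equal(ca$interventions, cb$interventions, tolerance = tol)
}
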