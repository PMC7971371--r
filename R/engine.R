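#' Annual service hours available per CHW
#'
#' Gross working time is `hours_per_week * weeks_per_year`. Annual block
#' commitments (training, campaigns) are subtracted first; the remainder is
#' scaled by `1 - travel_share - admin_share` to yield direct service time.
#'
#' @param policy A [time_policy()].
#' @return Service hours per CHW per year, in `[0, gross]`. Block hours in
#'   excess of gross time floor the result at 0.
#' @examples
#' available_service_hours(time_policy(18, 52, travel_share = 1 / 3))  # 624
#' @export
available_service_hours <- function(policy) {
  stopifnot(inherits(policy, "chw_time_policy"))
  gross <- policy$hours_per_week * policy$weeks_per_year
  net <- gross - policy$training_hours_per_year - policy$campaign_hours_per_year
  max(0, net) * (1 - policy$travel_share - policy$admin_share)
}

#' Annual service hours demanded by one intervention
#'
#' Demand at the coverage goal is
#' `target_population * coverage_goal * contacts_per_year * minutes / 60`,
#' where `minutes = minutes_per_contact + travel_minutes_per_contact`. For
#' group sessions the contact count is divided by `group_size`: by default
#' exactly (keeping demand linear in its parameters), or rounded up per
#' session batch with `group_rounding = "ceiling"`.
#'
#' @param intervention A [intervention()].
#' @param profile A [population_profile()].
#' @param group_rounding `"exact"` (default) or `"ceiling"` for
#'   whole-session batching of group sessions.
#' @return Hours per year for the whole catchment, >= 0.
#' @export
annual_demand_hours <- function(intervention, profile,
                                group_rounding = c("exact", "ceiling")) {
  stopifnot(inherits(intervention, "chw_intervention"))
  group_rounding <- match.arg(group_rounding)
  pop <- target_population(profile, intervention$target)
  contacts <- pop * intervention$coverage_goal * intervention$contacts_per_year
  units <- if (intervention$mode == "group-session") {
    s <- contacts / intervention$group_size
    if (group_rounding == "ceiling") ceiling(s) else s
  } else {
    contacts
  }
  minutes <- intervention$minutes_per_contact +
    intervention$travel_minutes_per_contact
  units * minutes / 60
}

# per-intervention demand table for a scenario (internal workhorse)
demand_table <- function(scenario) {
  ints <- scenario$interventions
  if (!length(ints)) {
    return(data.frame(intervention = character(), cadre = character(),
                      priority = numeric(), annual_hours = numeric(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    intervention = vapply(ints, `[[`, character(1), "name"),
    cadre = vapply(ints, `[[`, character(1), "cadre"),
    priority = vapply(ints, `[[`, numeric(1), "priority"),
    annual_hours = vapply(ints, annual_demand_hours, numeric(1),
                          profile = scenario$profile,
                          group_rounding = scenario$group_rounding),
    stringsAsFactors = FALSE)
}

# per-cadre summary of a scenario: available hours, headcount, demand
cadre_table <- function(scenario) {
  dem <- demand_table(scenario)
  nm <- vapply(scenario$cadres, `[[`, character(1), "name")
  data.frame(
    cadre = nm,
    headcount = vapply(scenario$cadres, `[[`, numeric(1), "headcount"),
    available_hours_per_chw = vapply(
      scenario$cadres, function(cd) available_service_hours(cd$time_policy),
      numeric(1)),
    total_demand_hours = vapply(
      nm, function(n) sum(dem$annual_hours[dem$cadre == n]), numeric(1),
      USE.NAMES = FALSE),
    stringsAsFactors = FALSE)
}

#' CHWs needed for targeted coverage (Q1)
#'
#' For each cadre, the whole-program headcount needed to serve the full
#' demand of its assigned interventions at their coverage goals:
#' `ceiling(total demand hours / service hours per CHW)`, 0 when the cadre
#' has no demand. Fractional demand is never rounded; only headcounts are
#' integers.
#'
#' @param scenario A [scenario()].
#' @return A `chw_staffing` object: per-cadre data frame with
#'   `required_chws`, `available_hours_per_chw`, `total_demand_hours`.
#' @export
chws_needed <- function(scenario) {
  stopifnot(inherits(scenario, "chw_scenario"))
  tab <- cadre_table(scenario)
  bad <- tab$cadre[tab$total_demand_hours > 0 &
                     tab$available_hours_per_chw <= 0]
  if (length(bad)) {
    stop("cadre(s) with demand but zero available service hours: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  # exact multiples must not pick up a spurious +1 from floating point
  q <- ifelse(tab$total_demand_hours > 0,
              tab$total_demand_hours / tab$available_hours_per_chw, 0)
  tab$required_chws <- ifelse(tab$total_demand_hours > 0,
                              ceiling(q - 1e-9), 0)
  structure(
    list(scenario = scenario$name,
         cadres = tab[, c("cadre", "required_chws",
                          "available_hours_per_chw", "total_demand_hours")]),
    class = "chw_staffing")
}

#' Expected coverage of a fixed workforce (Q2)
#'
#' Given headcounts, how much of the prescribed activity can each cadre
#' carry out? Supply per cadre is `headcount * service hours per CHW`. When
#' supply covers demand, every intervention reaches its coverage goal
#' (achievable share 1 of goal). Under overload, service hours are allocated
#' by the scenario's `allocation_mode`:
#' * `"proportional"` (default): every intervention of the cadre achieves
#'   the same fraction `supply / demand` of its goal;
#' * `"priority-fill"`: interventions are filled to full demand in priority
#'   order until supply is exhausted (the deprioritization logic of
#'   iterative scenario review).
#'
#' @param scenario A [scenario()].
#' @return A `chw_coverage` object with `$interventions` (demand, allocated
#'   hours, `achievable_coverage` as a fraction of the goal) and `$cadres`
#'   (`load_ratio` = demand/supply, `aggregate_achievable_share` =
#'   min(1, supply/demand)).
#' @export
expected_coverage <- function(scenario) {
  stopifnot(inherits(scenario, "chw_scenario"))
  dem <- demand_table(scenario)
  tab <- cadre_table(scenario)
  unset <- tab$cadre[is.na(tab$headcount) & tab$total_demand_hours > 0]
  if (length(unset)) {
    stop("headcount unset for cadre(s) with demand: ",
         paste(unset, collapse = ", "), call. = FALSE)
  }
  tab$supply_hours <- ifelse(is.na(tab$headcount), 0, tab$headcount) *
    tab$available_hours_per_chw
  tab$load_ratio <- ifelse(tab$total_demand_hours == 0, 0,
                           ifelse(tab$supply_hours > 0,
                                  tab$total_demand_hours / tab$supply_hours,
                                  Inf))
  tab$aggregate_achievable_share <-
    ifelse(tab$total_demand_hours == 0, 1,
           pmin(1, tab$supply_hours / tab$total_demand_hours))

  dem$allocated_hours <- numeric(nrow(dem))
  for (i in seq_len(nrow(tab))) {
    rows <- which(dem$cadre == tab$cadre[i])
    if (!length(rows)) next
    dem$allocated_hours[rows] <- allocate_hours(
      dem$annual_hours[rows], dem$priority[rows], dem$intervention[rows],
      tab$supply_hours[i], scenario$allocation_mode)
  }
  dem$achievable_coverage <- ifelse(dem$annual_hours > 0,
                                    dem$allocated_hours / dem$annual_hours, 1)
  structure(
    list(scenario = scenario$name,
         allocation_mode = scenario$allocation_mode,
         interventions = dem[, c("intervention", "cadre", "annual_hours",
                                 "allocated_hours", "achievable_coverage")],
         cadres = tab[, c("cadre", "headcount", "available_hours_per_chw",
                          "supply_hours", "total_demand_hours", "load_ratio",
                          "aggregate_achievable_share")]),
    class = "chw_coverage")
}

# allocate supply hours across one cadre's interventions; conserves supply
# (capped at demand) and never over-allocates any intervention
allocate_hours <- function(demands, priorities, names, supply, mode) {
  total <- sum(demands)
  if (total <= supply) return(demands)
  if (mode == "proportional") {
    return(demands * (supply / total))
  }
  # priority-fill: lower priority rank first, ties by name
  out <- numeric(length(demands))
  remaining <- supply
  for (j in order(priorities, names, method = "radix")) {
    take <- min(demands[j], remaining)
    out[j] <- take
    remaining <- remaining - take
    if (remaining <= 0) break
  }
  out
}

#' Rank interventions by annual time demanded
#'
#' Orders the catalog by annual service hours (decreasing; ties broken by
#' intervention name) and reports each intervention's share of its cadre's
#' total demand — the "where does the time go" view used to pick
#' deprioritization candidates.
#'
#' @param scenario A [scenario()].
#' @return Data frame with `intervention`, `cadre`, `annual_hours`,
#'   `share_of_cadre` (summing to 1 within each cadre that has demand).
#' @export
rank_time_consumers <- function(scenario) {
  stopifnot(inherits(scenario, "chw_scenario"))
  dem <- demand_table(scenario)
  cadre_tot <- tapply(dem$annual_hours, dem$cadre, sum)
  dem$share_of_cadre <- ifelse(cadre_tot[dem$cadre] > 0,
                               dem$annual_hours / cadre_tot[dem$cadre],
                               NA_real_)
  dem <- dem[order_desc_by_name(dem$annual_hours, dem$intervention), ,
             drop = FALSE]
  rownames(dem) <- NULL
  dem[, c("intervention", "cadre", "annual_hours", "share_of_cadre")]
}

#' Time needed versus time available per CHW
#'
#' Figure-data view of the coverage question: for each cadre, annual service
#' hours demanded per CHW against service hours available per CHW.
#'
#' @param scenario A [scenario()] with headcounts set for cadres with demand.
#' @return Data frame with `cadre`, `hours_needed_per_chw`,
#'   `hours_available_per_chw`.
#' @export
time_per_chw <- function(scenario) {
  tab <- cadre_table(scenario)
  unset <- tab$cadre[is.na(tab$headcount) & tab$total_demand_hours > 0]
  if (length(unset)) {
    stop("headcount unset for cadre(s) with demand: ",
         paste(unset, collapse = ", "), call. = FALSE)
  }
  data.frame(
    cadre = tab$cadre,
    hours_needed_per_chw = ifelse(!is.na(tab$headcount) & tab$headcount > 0,
                                  tab$total_demand_hours / tab$headcount,
                                  NA_real_),
    hours_available_per_chw = tab$available_hours_per_chw,
    stringsAsFactors = FALSE)
}

#' @export
print.chw_staffing <- function(x, ...) {
  cat(sprintf("<chw_staffing> scenario '%s' (CHWs needed for full coverage)\n",
              x$scenario))
  print(format_num_df(x$cadres), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.chw_staffing <- function(x, ...) x$cadres

#' @export
print.chw_coverage <- function(x, ...) {
  cat(sprintf("<chw_coverage> scenario '%s', %s allocation\n", x$scenario,
              x$allocation_mode))
  cat("Per cadre:\n")
  print(format_num_df(x$cadres), row.names = FALSE)
  invisible(x)
}

#' @export
summary.chw_coverage <- function(object, ...) {
  cat(sprintf("Scenario '%s' (%s allocation)\n", object$scenario,
              object$allocation_mode))
  for (i in seq_len(nrow(object$cadres))) {
    r <- object$cadres[i, ]
    cat(sprintf(
      "  %s: %s CHWs, %.0f h demand vs %.0f h supply -> %.1f%% of workload achievable\n",
      r$cadre,
      if (is.na(r$headcount)) "?" else format(r$headcount, big.mark = ","),
      r$total_demand_hours, r$supply_hours,
      100 * r$aggregate_achievable_share))
  }
  overloaded <- object$interventions[
    object$interventions$achievable_coverage < 1 - 1e-12, , drop = FALSE]
  if (nrow(overloaded)) {
    cat("Interventions short of goal:\n")
    print(format_num_df(overloaded), row.names = FALSE)
  }
  invisible(object)
}

#' @export
as.data.frame.chw_coverage <- function(x, ...) x$interventions

#' Paired-bar plot of time needed vs time available per CHW
#'
#' @param x A `chw_coverage` result.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the plotted matrix (hours per CHW).
#' @export
plot.chw_coverage <- function(x, ...) {
  tab <- x$cadres
  m <- rbind(needed = ifelse(!is.na(tab$headcount) & tab$headcount > 0,
                             tab$total_demand_hours / tab$headcount, 0),
             available = tab$available_hours_per_chw)
  colnames(m) <- tab$cadre
  graphics::barplot(m, beside = TRUE, legend.text = rownames(m),
                    ylab = "annual hours per CHW", ...)
  invisible(m)
}

format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 6)
  }
  df
}
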