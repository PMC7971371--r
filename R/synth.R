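#' Parameter ranges for the synthetic-scenario generator
#'
#' Default ranges emulate a national CHW program: populations from fifty
#' thousand to five million, part-time cadres of tens of hours per week,
#' intervention doses of 1-12 contacts per year at 10-60 minutes. Each
#' element is a `c(min, max)` pair (or a value set where noted).
#'
#' @param total_population,hours_per_week,travel_share,admin_share,
#'   training_hours,campaign_hours,headcount,contacts_per_year,
#'   minutes_per_contact,group_size,coverage_goal,in_need_fraction,
#'   facility_share Range pairs.
#' @param weeks_per_year Value set sampled from.
#' @param n_groups,n_event_keys Number of stock groups / event keys in the
#'   generated profile.
#' @return A named list of ranges for [synthesize_package()].
#' @export
synth_ranges <- function(total_population = c(5e4, 5e6),
                         hours_per_week = c(10, 40),
                         weeks_per_year = c(46, 48, 52),
                         travel_share = c(0, 0.4),
                         admin_share = c(0, 0.2),
                         training_hours = c(0, 60),
                         campaign_hours = c(0, 60),
                         headcount = c(20, 5000),
                         contacts_per_year = c(1, 12),
                         minutes_per_contact = c(10, 60),
                         group_size = c(5, 30),
                         coverage_goal = c(0.5, 1),
                         in_need_fraction = c(0.2, 1),
                         facility_share = c(0, 0.6),
                         n_groups = 3L, n_event_keys = 2L) {
  as.list(environment())
}

#' Generate a seeded synthetic package
#'
#' Draws a population profile, cadres, and an intervention catalog whose
#' invariants hold by construction. Deterministic for a fixed seed; the
#' caller's RNG state is left untouched. Intended for property tests and
#' the `synth` CLI command, not for representing any real program.
#'
#' @param seed Integer seed (< 2^31).
#' @param n_cadres Number of cadres (>= 1).
#' @param n_interventions Number of interventions (>= 0); cadres are
#'   assigned round-robin so each gets work when possible.
#' @param ranges Parameter ranges from [synth_ranges()].
#' @param integerize When `TRUE`, target-group counts, contact frequencies,
#'   minutes, and group sizes are integers and in-need/facility adjustments
#'   and coverage goals are 1/0/1, so demand can be cross-checked by exact
#'   per-contact enumeration.
#' @return A list with elements `profile`, `cadres`, `interventions`
#'   (which always passes [validate_package()]).
#' @export
synthesize_package <- function(seed, n_cadres = 3, n_interventions = 10,
                               ranges = synth_ranges(), integerize = FALSE) {
  stopifnot(n_cadres >= 1, n_interventions >= 0)
  bad <- names(ranges)[vapply(ranges, function(r) {
    is.numeric(r) && length(r) == 2L && r[1] > r[2]
  }, logical(1))]
  if (length(bad)) {
    stop("ill-ordered ranges: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    r <- ranges
    runit <- function(rg) stats::runif(1, rg[1], rg[2])
    total <- round(runit(r$total_population))
    groups <- paste0("group-", seq_len(r$n_groups))
    # fractions jointly below 1 so counts can coexist in one population
    frac <- stats::runif(r$n_groups, 0.02, 0.25)
    frac <- frac / max(1, sum(frac) * 1.05)
    events <- paste0("event-", seq_len(r$n_event_keys))
    rates <- stats::runif(r$n_event_keys, 0.005, 0.05)
    profile <- if (integerize) {
      build_profile_from_counts(
        sprintf("synthetic-%d", seed), total,
        stats::setNames(pmin(total, round(frac * total)), groups),
        annual_event_rates = stats::setNames(
          round(rates * total) / total, events))
    } else {
      population_profile(sprintf("synthetic-%d", seed), total,
                         stats::setNames(frac, groups),
                         stats::setNames(rates, events))
    }
    cadres <- lapply(seq_len(n_cadres), function(i) {
      hpw <- runit(r$hours_per_week)
      wpy <- sample(r$weeks_per_year, 1)
      trv <- runit(r$travel_share)
      adm <- min(runit(r$admin_share), 0.99 - trv)
      gross <- hpw * wpy
      cadre(sprintf("cadre-%02d", i),
            time_policy(hpw, wpy, travel_share = trv, admin_share = adm,
                        training_hours_per_year =
                          min(runit(r$training_hours), gross / 2),
                        campaign_hours_per_year =
                          min(runit(r$campaign_hours), gross / 4)),
            headcount = round(runit(r$headcount)))
    })
    interventions <- lapply(seq_len(n_interventions), function(i) {
      mode <- sample(c("home-visit", "group-session", "campaign",
                       "referral-accompaniment"), 1,
                     prob = c(0.5, 0.3, 0.1, 0.1))
      stock <- stats::runif(1) < 0.7
      tgt <- target_spec(
        kind = if (stock) "stock-group" else "annual-event",
        key = if (stock) sample(groups, 1) else sample(events, 1),
        in_need_fraction = if (integerize) 1 else runit(r$in_need_fraction),
        facility_share = if (integerize) 0 else runit(r$facility_share))
      cpy <- runit(r$contacts_per_year)
      mpc <- runit(r$minutes_per_contact)
      gsz <- runit(r$group_size)
      if (integerize) {
        cpy <- max(1, round(cpy)); mpc <- max(1, round(mpc))
        gsz <- max(1, round(gsz))
      }
      intervention(sprintf("intervention-%02d", i),
                   cadre = sprintf("cadre-%02d", (i - 1L) %% n_cadres + 1L),
                   mode = mode, target = tgt, contacts_per_year = cpy,
                   minutes_per_contact = mpc,
                   group_size = if (mode == "group-session") gsz else NA,
                   coverage_goal = if (integerize) 1 else
                     runit(r$coverage_goal))
    })
    suppressWarnings(validate_package(cadres, interventions))
    list(profile = profile, cadres = cadres, interventions = interventions)
  })
}

#' Generate a seeded synthetic scenario
#'
#' Wraps [synthesize_package()] into a ready-to-evaluate [scenario()].
#'
#' @inheritParams synthesize_package
#' @param allocation_mode Passed to [scenario()].
#' @return A `chw_scenario`.
#' @export
synthesize_scenario <- function(seed, n_cadres = 3, n_interventions = 10,
                                ranges = synth_ranges(), integerize = FALSE,
                                allocation_mode = c("proportional",
                                                    "priority-fill")) {
  pkg <- synthesize_package(seed, n_cadres, n_interventions, ranges,
                            integerize)
  suppressWarnings(scenario(sprintf("synthetic-%d", seed), pkg$profile,
                            pkg$cadres, pkg$interventions,
                            allocation_mode = match.arg(allocation_mode)))
}

# run expr under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
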