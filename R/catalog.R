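#' Time policy for a CHW cadre
#'
#' Defines the annual hours a CHW of a cadre can devote to direct service
#' delivery. Gross working time is `hours_per_week * weeks_per_year`; block
#' commitments (annual training and campaign hours) are subtracted first,
#' then the remainder is reduced by the shares of working time spent on
#' travel and administration. Travel is modeled as a share of working time
#' (e.g. one third of available time), not per-visit minutes; a per-visit
#' travel surcharge can instead be added to an intervention's
#' `travel_minutes_per_contact`.
#'
#' @param hours_per_week Working hours per week (>= 0).
#' @param weeks_per_year Working weeks per year. Default 48, a full year
#'   minus leave; override to 52 for policies quoted on a whole-year basis.
#' @param travel_share Fraction of working time spent travelling, in \[0, 1).
#' @param admin_share Fraction spent on administration/reporting, in \[0, 1).
#'   `travel_share + admin_share` must be < 1.
#' @param training_hours_per_year Annual block hours of training (>= 0,
#'   <= gross hours).
#' @param campaign_hours_per_year Annual block hours of campaigns and other
#'   ad hoc activities (>= 0). Campaigns are block time per CHW, not
#'   per-target contacts.
#' @return An object of class `chw_time_policy`.
#' @examples
#' time_policy(18, weeks_per_year = 52, travel_share = 1 / 3)
#' @export
time_policy <- function(hours_per_week, weeks_per_year = 48,
                        travel_share = 0, admin_share = 0,
                        training_hours_per_year = 0,
                        campaign_hours_per_year = 0) {
  check_nonneg(hours_per_week, "hours_per_week")
  check_nonneg(weeks_per_year, "weeks_per_year")
  check_fraction(travel_share, "travel_share")
  check_fraction(admin_share, "admin_share")
  check_nonneg(training_hours_per_year, "training_hours_per_year")
  check_nonneg(campaign_hours_per_year, "campaign_hours_per_year")
  if (travel_share + admin_share >= 1) {
    stop("travel_share + admin_share must be < 1", call. = FALSE)
  }
  gross <- hours_per_week * weeks_per_year
  if (training_hours_per_year > gross) {
    stop("training_hours_per_year exceeds gross annual hours", call. = FALSE)
  }
  structure(
    list(hours_per_week = as.numeric(hours_per_week),
         weeks_per_year = as.numeric(weeks_per_year),
         travel_share = as.numeric(travel_share),
         admin_share = as.numeric(admin_share),
         training_hours_per_year = as.numeric(training_hours_per_year),
         campaign_hours_per_year = as.numeric(campaign_hours_per_year)),
    class = "chw_time_policy")
}

#' CHW cadre
#'
#' A category of community health worker with a defined scope of work, a
#' headcount (optional when the question is how many are needed), and a time
#' policy governing annual service hours.
#'
#' @param name Cadre name (unique within a scenario).
#' @param time_policy A [time_policy()] object.
#' @param headcount Number of CHWs in the cadre, or `NA` when unset. Must be
#'   a non-negative whole number when set.
#' @return An object of class `chw_cadre`.
#' @export
cadre <- function(name, time_policy, headcount = NA) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!inherits(time_policy, "chw_time_policy")) {
    stop("time_policy must be a chw_time_policy", call. = FALSE)
  }
  if (!is.na(headcount)) {
    headcount <- as.numeric(headcount)
    if (headcount < 0 || headcount != round(headcount)) {
      stop("headcount must be a non-negative integer or NA", call. = FALSE)
    }
  } else {
    headcount <- NA_real_
  }
  structure(list(name = name, headcount = headcount,
                 time_policy = time_policy),
            class = "chw_cadre")
}

#' Intervention
#'
#' One service delivered by a cadre: its delivery mode, target slice of the
#' population, dose (contact frequency and duration), and coverage goal.
#'
#' @param name Intervention name (unique within a scenario).
#' @param cadre Name of the cadre delivering it.
#' @param mode One of `"home-visit"`, `"group-session"`, `"campaign"`,
#'   `"referral-accompaniment"`.
#' @param target A [target_spec()].
#' @param contacts_per_year Contacts (or sessions attended) per target
#'   individual per year (>= 0, real).
#' @param minutes_per_contact Service minutes per contact (>= 0).
#' @param group_size Participants per session; required (>= 1) iff
#'   `mode = "group-session"`.
#' @param coverage_goal Intended fraction of the in-need population reached,
#'   in \[0, 1\]. Default 1.
#' @param priority Ordinal rank; lower means higher priority under
#'   priority-fill allocation. Default `NA` (catalog order, ties by name).
#' @param travel_minutes_per_contact Optional per-visit travel surcharge in
#'   minutes, added to `minutes_per_contact` when computing demand. Use this
#'   or the time policy's `travel_share`, not both, for the same travel.
#' @return An object of class `chw_intervention`.
#' @export
intervention <- function(name, cadre, mode = c("home-visit", "group-session",
                                               "campaign",
                                               "referral-accompaniment"),
                         target, contacts_per_year, minutes_per_contact,
                         group_size = NA, coverage_goal = 1, priority = NA,
                         travel_minutes_per_contact = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(cadre), length(cadre) == 1L, nzchar(cadre))
  mode <- match.arg(mode)
  if (!inherits(target, "chw_target")) {
    stop("target must be a chw_target (see target_spec())", call. = FALSE)
  }
  check_nonneg(contacts_per_year, "contacts_per_year")
  check_nonneg(minutes_per_contact, "minutes_per_contact")
  check_nonneg(travel_minutes_per_contact, "travel_minutes_per_contact")
  check_fraction(coverage_goal, "coverage_goal")
  if (mode == "group-session") {
    if (is.na(group_size) || !is.numeric(group_size) || group_size < 1) {
      stop("group-session mode requires group_size >= 1", call. = FALSE)
    }
  } else if (!is.na(group_size)) {
    stop("group_size is only meaningful for group-session mode",
         call. = FALSE)
  }
  if (!is.na(priority)) check_nonneg(priority, "priority")
  structure(
    list(name = name, cadre = cadre, mode = mode, target = target,
         contacts_per_year = as.numeric(contacts_per_year),
         minutes_per_contact = as.numeric(minutes_per_contact),
         group_size = if (is.na(group_size)) NA_real_ else
           as.numeric(group_size),
         coverage_goal = as.numeric(coverage_goal),
         priority = if (is.na(priority)) NA_real_ else as.numeric(priority),
         travel_minutes_per_contact = as.numeric(travel_minutes_per_contact)),
    class = "chw_intervention")
}

#' Validate a cadre/intervention package
#'
#' Checks referential integrity of a package: unique cadre and intervention
#' names, every intervention assigned to an existing cadre. More than 6
#' cadres raises a warning (the stated capacity of the planning model), not
#' an error. An empty intervention list passes with a warning. Also resolves
#' effective priorities: explicitly ranked interventions precede unranked
#' ones, unset priorities keep catalog order, and ties are broken by name.
#'
#' @param cadres List of [cadre()] objects.
#' @param interventions List of [intervention()] objects.
#' @return Invisibly, a list with validated `cadres` and `interventions`
#'   (the latter with resolved numeric `priority`).
#' @export
validate_package <- function(cadres, interventions) {
  stopifnot(is.list(cadres), is.list(interventions))
  if (!all(vapply(cadres, inherits, logical(1), "chw_cadre"))) {
    stop("cadres must all be chw_cadre objects", call. = FALSE)
  }
  if (!all(vapply(interventions, inherits, logical(1), "chw_intervention"))) {
    stop("interventions must all be chw_intervention objects", call. = FALSE)
  }
  cadre_names <- vapply(cadres, `[[`, character(1), "name")
  if (anyDuplicated(cadre_names)) {
    stop("duplicate cadre names: ",
         paste(unique(cadre_names[duplicated(cadre_names)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(cadres) > 6L) {
    warning(sprintf("%d cadres exceed the model's stated capacity of 6",
                    length(cadres)), call. = FALSE)
  }
  int_names <- vapply(interventions, `[[`, character(1), "name")
  if (anyDuplicated(int_names)) {
    stop("duplicate intervention names: ",
         paste(unique(int_names[duplicated(int_names)]), collapse = ", "),
         call. = FALSE)
  }
  ref <- vapply(interventions, `[[`, character(1), "cadre")
  dangling <- setdiff(unique(ref), cadre_names)
  if (length(dangling)) {
    stop("interventions reference unknown cadres: ",
         paste(dangling, collapse = ", "), call. = FALSE)
  }
  if (length(interventions) == 0L) {
    warning("empty intervention package", call. = FALSE)
  }
  interventions <- resolve_priorities(interventions)
  invisible(list(cadres = cadres, interventions = interventions))
}

# explicitly ranked interventions come first; unset priorities default to
# catalog order after them; ties broken by name
resolve_priorities <- function(interventions) {
  if (!length(interventions)) return(interventions)
  pr <- vapply(interventions, `[[`, numeric(1), "priority")
  base <- if (all(is.na(pr))) 0 else max(pr, na.rm = TRUE)
  pr[is.na(pr)] <- base + seq_along(interventions)[is.na(pr)]
  nms <- vapply(interventions, `[[`, character(1), "name")
  rank <- order(pr, nms, method = "radix")
  eff <- integer(length(interventions))
  eff[rank] <- seq_along(interventions)
  for (i in seq_along(interventions)) interventions[[i]]$priority <- eff[i]
  interventions
}

#' @export
print.chw_time_policy <- function(x, ...) {
  cat(sprintf(
    "<chw_time_policy> %g h/wk x %g wk; travel %.1f%%, admin %.1f%%, training %g h/yr, campaigns %g h/yr -> %g service h/yr\n",
    x$hours_per_week, x$weeks_per_year, 100 * x$travel_share,
    100 * x$admin_share, x$training_hours_per_year,
    x$campaign_hours_per_year, available_service_hours(x)))
  invisible(x)
}

#' @export
print.chw_cadre <- function(x, ...) {
  cat(sprintf("<chw_cadre> %s: headcount %s, %g service h/yr per CHW\n",
              x$name,
              if (is.na(x$headcount)) "unset" else
                format(x$headcount, big.mark = ","),
              available_service_hours(x$time_policy)))
  invisible(x)
}

#' @export
print.chw_intervention <- function(x, ...) {
  cat(sprintf(
    "<chw_intervention> %s [%s, cadre %s]: %g contacts/yr x %g min, goal %.0f%%\n",
    x$name, x$mode, x$cadre, x$contacts_per_year, x$minutes_per_contact,
    100 * x$coverage_goal))
  invisible(x)
}
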