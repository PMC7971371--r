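#' Population profile
#'
#' A population profile holds everything needed to size annual target groups:
#' a total population, fractions of that population belonging to stock groups
#' (e.g. children under 5, women of reproductive age), and annual event rates
#' per person per year (e.g. live births, pregnancies). Fractions and rates
#' come from user configuration or built-in fixtures; the package never
#' fetches demographic data.
#'
#' @param name Text label for the profile.
#' @param total_population Total population (non-negative number).
#' @param group_fractions Named numeric vector or list: fraction of the total
#'   population in each stock group, each in \[0, 1\].
#' @param annual_event_rates Named numeric vector or list: events per person
#'   per year for each event key, each >= 0.
#' @return An object of class `chw_profile`.
#' @examples
#' p <- population_profile("demo", 100000,
#'   group_fractions = c(`under-5` = 0.15),
#'   annual_event_rates = c(`live-births` = 0.032))
#' @export
population_profile <- function(name, total_population,
                               group_fractions = numeric(),
                               annual_event_rates = numeric()) {
  stopifnot(is.character(name), length(name) == 1L)
  total_population <- as.numeric(total_population)
  if (length(total_population) != 1L || is.na(total_population) ||
      total_population < 0) {
    stop("total_population must be a single non-negative number", call. = FALSE)
  }
  group_fractions <- as_named_numeric(group_fractions, "group_fractions")
  annual_event_rates <- as_named_numeric(annual_event_rates,
                                         "annual_event_rates")
  if (any(group_fractions < 0 | group_fractions > 1)) {
    bad <- names(group_fractions)[group_fractions < 0 | group_fractions > 1]
    stop("group fractions outside [0, 1]: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(annual_event_rates < 0)) {
    bad <- names(annual_event_rates)[annual_event_rates < 0]
    stop("negative event rates: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(name = name, total_population = total_population,
         group_fractions = group_fractions,
         annual_event_rates = annual_event_rates),
    class = "chw_profile")
}

#' Build a profile from group head-counts
#'
#' Convenience constructor for fixtures and census-style inputs where stock
#' groups are known as counts rather than fractions. Fractions are stored as
#' `count / total`, so [target_population()] with `in_need_fraction = 1` and
#' `facility_share = 0` reproduces each entered count exactly.
#'
#' @param name Profile label.
#' @param total Total population (> 0).
#' @param group_counts Named numeric vector or list of persons per group;
#'   each count must not exceed `total`.
#' @param annual_event_rates Optional named event rates, as in
#'   [population_profile()].
#' @return A `chw_profile`.
#' @examples
#' build_profile_from_counts("east", 2600814, c(`under-5` = 338106))
#' @export
build_profile_from_counts <- function(name, total, group_counts,
                                      annual_event_rates = numeric()) {
  total <- as.numeric(total)
  if (length(total) != 1L || is.na(total) || total <= 0) {
    stop("total must be a single positive number", call. = FALSE)
  }
  group_counts <- as_named_numeric(group_counts, "group_counts")
  if (any(group_counts < 0)) {
    stop("group counts must be non-negative", call. = FALSE)
  }
  if (any(group_counts > total)) {
    bad <- names(group_counts)[group_counts > total]
    stop("group count exceeds total population: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  population_profile(name, total,
                     group_fractions = group_counts / total,
                     annual_event_rates = annual_event_rates)
}

#' Target specification
#'
#' Describes which slice of a population an intervention serves. A target is
#' either a stock group (sized as `total_population * fraction`) or an annual
#' event stream (sized as `total_population * rate`), scaled by an
#' epidemiological in-need fraction and reduced by the share expected to be
#' served at health facilities rather than by CHWs.
#'
#' @param kind `"stock-group"` or `"annual-event"`.
#' @param key Group or event key; must exist in the profile at evaluation.
#' @param in_need_fraction Fraction of the group needing the service, in
#'   \[0, 1\]. Defaults to 1 (everyone in the group). Values above 1 are
#'   rejected; caseload multipliers (repeat episodes per person) belong in
#'   `contacts_per_year`.
#' @param facility_share Fraction of the in-need group served at facilities,
#'   in \[0, 1\]. Defaults to 0 (all community-delivered).
#' @return An object of class `chw_target`.
#' @export
target_spec <- function(kind = c("stock-group", "annual-event"), key,
                        in_need_fraction = 1, facility_share = 0) {
  kind <- match.arg(kind)
  stopifnot(is.character(key), length(key) == 1L, nzchar(key))
  check_fraction(in_need_fraction, "in_need_fraction")
  check_fraction(facility_share, "facility_share")
  structure(
    list(kind = kind, key = key,
         in_need_fraction = as.numeric(in_need_fraction),
         facility_share = as.numeric(facility_share)),
    class = "chw_target")
}

#' Annual target population for a target specification
#'
#' Computes persons (stock groups) or events (annual events) per year that a
#' CHW-delivered service must reach:
#' `total_population * (fraction or rate) * in_need_fraction *
#' (1 - facility_share)`.
#'
#' @param profile A `chw_profile`.
#' @param spec A `chw_target`.
#' @return Non-negative number of persons or events per year. Counts are kept
#'   fractional; rounding is a reporting concern.
#' @examples
#' p <- population_profile("x", 10000,
#'   annual_event_rates = c(`live-births` = 0.03))
#' target_population(p, target_spec("annual-event", "live-births",
#'   facility_share = 0.5))  # 150
#' @export
target_population <- function(profile, spec) {
  stopifnot(inherits(profile, "chw_profile"), inherits(spec, "chw_target"))
  pool <- switch(spec$kind,
    "stock-group" = profile$group_fractions,
    "annual-event" = profile$annual_event_rates)
  if (!spec$key %in% names(pool)) {
    stop(sprintf("unknown %s key '%s' in profile '%s' (available: %s)",
                 if (spec$kind == "stock-group") "group" else "event",
                 spec$key, profile$name,
                 if (length(pool)) paste(names(pool), collapse = ", ")
                 else "<none>"),
         call. = FALSE)
  }
  profile$total_population * pool[[spec$key]] *
    spec$in_need_fraction * (1 - spec$facility_share)
}

#' @export
print.chw_profile <- function(x, ...) {
  cat(sprintf("<chw_profile> %s: total population %s\n", x$name,
              format(x$total_population, big.mark = ",")))
  if (length(x$group_fractions)) {
    cat("  stock groups:\n")
    for (k in names(x$group_fractions)) {
      cat(sprintf("    %-24s %.6f (%s persons)\n", k, x$group_fractions[[k]],
                  format(round(x$total_population * x$group_fractions[[k]]),
                         big.mark = ",")))
    }
  }
  if (length(x$annual_event_rates)) {
    cat("  annual event rates:\n")
    for (k in names(x$annual_event_rates)) {
      cat(sprintf("    %-24s %.6f per person-year\n", k,
                  x$annual_event_rates[[k]]))
    }
  }
  invisible(x)
}
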