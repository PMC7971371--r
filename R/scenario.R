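#' Scenario
#'
#' A complete, immutable planning bundle: population profile, CHW cadres,
#' intervention catalog, and evaluation policy. Construction validates the
#' package (see [validate_package()]); edits never modify a scenario in
#' place but return new values (see [edit_scenario()]), so what-if variants
#' can be compared side by side.
#'
#' @param name Scenario label.
#' @param profile A [population_profile()].
#' @param cadres List of [cadre()] objects (the model supports up to 6;
#'   more raises a warning).
#' @param interventions List of [intervention()] objects.
#' @param allocation_mode How an overloaded cadre's service hours are split:
#'   `"proportional"` (default) or `"priority-fill"`. See
#'   [expected_coverage()].
#' @param group_rounding `"exact"` (default) or `"ceiling"`; see
#'   [annual_demand_hours()].
#' @return An object of class `chw_scenario`.
#' @export
scenario <- function(name, profile, cadres, interventions = list(),
                     allocation_mode = c("proportional", "priority-fill"),
                     group_rounding = c("exact", "ceiling")) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!inherits(profile, "chw_profile")) {
    stop("profile must be a chw_profile", call. = FALSE)
  }
  allocation_mode <- match.arg(allocation_mode)
  group_rounding <- match.arg(group_rounding)
  v <- validate_package(cadres, interventions)
  structure(
    list(name = name, profile = profile, cadres = v$cadres,
         interventions = v$interventions, allocation_mode = allocation_mode,
         group_rounding = group_rounding),
    class = "chw_scenario")
}

#' @export
print.chw_scenario <- function(x, ...) {
  cat(sprintf(
    "<chw_scenario> %s: population %s, %d cadre(s), %d intervention(s), %s allocation\n",
    x$name, format(x$profile$total_population, big.mark = ","),
    length(x$cadres), length(x$interventions), x$allocation_mode))
  invisible(x)
}

#' @export
summary.chw_scenario <- function(object, ...) {
  print(object)
  tab <- cadre_table(object)
  print(format_num_df(tab), row.names = FALSE)
  invisible(object)
}

#' What-if edits
#'
#' Edit constructors for [edit_scenario()]. `edit_drop()` removes an
#' intervention; `edit_set()` and `edit_scale()` change a numeric field of
#' an intervention (including its target's `in_need_fraction` and
#' `facility_share`); `edit_headcount()` sets a cadre's headcount.
#'
#' @param intervention,cadre Name of the element to edit.
#' @param field Field name on the intervention (`contacts_per_year`,
#'   `minutes_per_contact`, `coverage_goal`, `group_size`, `priority`,
#'   `travel_minutes_per_contact`, `in_need_fraction`, `facility_share`).
#' @param value,factor New value / multiplicative factor.
#' @param headcount New headcount (non-negative integer, or `NA` to unset).
#' @return An edit description for [edit_scenario()].
#' @name scenario_edits
NULL

#' @rdname scenario_edits
#' @export
edit_drop <- function(intervention) {
  list(op = "drop", intervention = intervention)
}

#' @rdname scenario_edits
#' @export
edit_set <- function(intervention, field, value) {
  list(op = "set", intervention = intervention, field = field, value = value)
}

#' @rdname scenario_edits
#' @export
edit_scale <- function(intervention, field, factor) {
  list(op = "scale", intervention = intervention, field = field,
       factor = factor)
}

#' @rdname scenario_edits
#' @export
edit_headcount <- function(cadre, headcount) {
  list(op = "set_headcount", cadre = cadre, headcount = headcount)
}

target_fields <- c("in_need_fraction", "facility_share")
intervention_fields <- c("contacts_per_year", "minutes_per_contact",
                         "coverage_goal", "group_size", "priority",
                         "travel_minutes_per_contact")

#' Apply what-if edits to a scenario
#'
#' Applies a list of edits in order and returns a new validated scenario;
#' the original is never modified. Unknown edit targets raise an error
#' listing valid names.
#'
#' @param scenario A [scenario()].
#' @param edits A list of edits built with [edit_drop()], [edit_set()],
#'   [edit_scale()], [edit_headcount()]; a single edit may be passed bare.
#' @param name Optional name for the edited scenario; default appends
#'   `" (edited)"` once.
#' @return A new `chw_scenario`.
#' @examples
#' \dontrun{
#' s2 <- edit_scenario(s, list(edit_drop("tb-dot"),
#'                             edit_headcount("chv", 2200)))
#' }
#' @export
edit_scenario <- function(scenario, edits, name = NULL) {
  stopifnot(inherits(scenario, "chw_scenario"))
  if (is.list(edits) && !is.null(edits$op)) edits <- list(edits)
  ints <- scenario$interventions
  cads <- scenario$cadres
  int_names <- function() vapply(ints, `[[`, character(1), "name")
  cad_names <- function() vapply(cads, `[[`, character(1), "name")
  for (e in edits) {
    if (e$op == "set_headcount") {
      i <- match(e$cadre, cad_names())
      if (is.na(i)) {
        stop(sprintf("unknown cadre '%s' (valid: %s)", e$cadre,
                     paste(cad_names(), collapse = ", ")), call. = FALSE)
      }
      cads[[i]] <- cadre(cads[[i]]$name, cads[[i]]$time_policy,
                         headcount = e$headcount)
      next
    }
    i <- match(e$intervention, int_names())
    if (is.na(i)) {
      stop(sprintf("unknown intervention '%s' (valid: %s)", e$intervention,
                   paste(int_names(), collapse = ", ")), call. = FALSE)
    }
    if (e$op == "drop") {
      ints[[i]] <- NULL
    } else {
      old <- ints[[i]]
      fld <- e$field
      if (!fld %in% c(intervention_fields, target_fields)) {
        stop(sprintf("unknown field '%s' (valid: %s)", fld,
                     paste(c(intervention_fields, target_fields),
                           collapse = ", ")), call. = FALSE)
      }
      cur <- if (fld %in% target_fields) old$target[[fld]] else old[[fld]]
      new <- if (e$op == "set") e$value else cur * e$factor
      if (fld %in% target_fields) {
        tgt <- old$target
        tgt[[fld]] <- new
        old$target <- do.call(target_spec, tgt)
      } else {
        old[[fld]] <- new
      }
      # rebuild through the constructor to revalidate invariants
      ints[[i]] <- intervention(
        old$name, old$cadre, old$mode, old$target, old$contacts_per_year,
        old$minutes_per_contact, group_size = old$group_size,
        coverage_goal = old$coverage_goal, priority = old$priority,
        travel_minutes_per_contact = old$travel_minutes_per_contact)
    }
  }
  scenario(name %||% paste0(sub(" \\(edited\\)$", "", scenario$name),
                            " (edited)"),
           scenario$profile, cads, ints,
           allocation_mode = scenario$allocation_mode,
           group_rounding = scenario$group_rounding)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare two scenarios (Q3)
#'
#' Evaluates both scenarios and reports the change from `a` to `b`:
#' per-cadre change in required CHWs and load ratio, per-intervention change
#' in annual demand hours and achievable coverage (for interventions present
#' in both), and lists of added/removed interventions. Deltas are
#' antisymmetric: `compare_scenarios(b, a)` negates them. Quantities that
#' need headcounts (load ratio, achievable coverage) are `NA` when a cadre's
#' headcount is unset in either scenario.
#'
#' @param a,b Scenarios. A warning is raised when the profile names differ.
#' @return A `chw_delta` object.
#' @export
compare_scenarios <- function(a, b) {
  stopifnot(inherits(a, "chw_scenario"), inherits(b, "chw_scenario"))
  if (a$profile$name != b$profile$name) {
    warning(sprintf("comparing scenarios on different profiles ('%s' vs '%s')",
                    a$profile$name, b$profile$name), call. = FALSE)
  }
  eval_one <- function(s) {
    dem <- demand_table(s)
    tab <- cadre_table(s)
    st <- chws_needed(s)$cadres
    covable <- !any(is.na(tab$headcount) & tab$total_demand_hours > 0)
    cov <- if (covable) expected_coverage(s) else NULL
    list(dem = dem, tab = tab, st = st, cov = cov)
  }
  ea <- eval_one(a); eb <- eval_one(b)

  all_cadres <- union(ea$st$cadre, eb$st$cadre)
  pick <- function(df, key, col, keys) {
    out <- df[[col]][match(keys, df[[key]])]
    out
  }
  lr <- function(e, keys) {
    if (is.null(e$cov)) rep(NA_real_, length(keys))
    else pick(e$cov$cadres, "cadre", "load_ratio", keys)
  }
  cad_delta <- data.frame(
    cadre = all_cadres,
    d_required_chws = na_zero(pick(eb$st, "cadre", "required_chws",
                                   all_cadres)) -
      na_zero(pick(ea$st, "cadre", "required_chws", all_cadres)),
    d_load_ratio = lr(eb, all_cadres) - lr(ea, all_cadres),
    stringsAsFactors = FALSE)

  common <- intersect(ea$dem$intervention, eb$dem$intervention)
  ac <- function(e, keys) {
    if (is.null(e$cov)) rep(NA_real_, length(keys))
    else pick(e$cov$interventions, "intervention", "achievable_coverage",
              keys)
  }
  ha <- pick(ea$dem, "intervention", "annual_hours", common)
  hb <- pick(eb$dem, "intervention", "annual_hours", common)
  int_delta <- data.frame(
    intervention = common,
    d_annual_hours = hb - ha,
    rel_annual_hours = ifelse(ha > 0, (hb - ha) / ha,
                              ifelse(hb > 0, NA_real_, 0)),
    d_achievable_coverage = ac(eb, common) - ac(ea, common),
    stringsAsFactors = FALSE)

  structure(
    list(from = a$name, to = b$name,
         cadres = cad_delta, interventions = int_delta,
         added = setdiff(eb$dem$intervention, ea$dem$intervention),
         removed = setdiff(ea$dem$intervention, eb$dem$intervention)),
    class = "chw_delta")
}

na_zero <- function(x) ifelse(is.na(x), 0, x)

#' @export
print.chw_delta <- function(x, ...) {
  cat(sprintf("<chw_delta> '%s' -> '%s'\n", x$from, x$to))
  if (length(x$added)) cat("  added:  ", paste(x$added, collapse = ", "), "\n")
  if (length(x$removed)) cat("  removed:", paste(x$removed, collapse = ", "), "\n")
  cat("Per cadre:\n")
  print(format_num_df(x$cadres), row.names = FALSE)
  changed <- x$interventions[
    abs(na_zero(x$interventions$d_annual_hours)) > 1e-12 |
      abs(na_zero(x$interventions$d_achievable_coverage)) > 1e-12, ,
    drop = FALSE]
  if (nrow(changed)) {
    cat("Changed interventions (relative change of a zero baseline prints 'new'):\n")
    out <- format_num_df(changed)
    out$rel_annual_hours <- ifelse(is.na(changed$rel_annual_hours), "new",
                                   format(signif(changed$rel_annual_hours, 6)))
    print(out, row.names = FALSE)
  }
  invisible(x)
}

#' Coverage frontier over a headcount grid (Q3)
#'
#' Re-evaluates a scenario at each headcount in `grid` for one cadre and
#' reports the cadre's aggregate achievable share, plus a flag marking the
#' headcounts at which full coverage (every goal met) is reached — the
#' "how many CHWs to carry out all activities" curve.
#'
#' @param scenario A [scenario()].
#' @param grid Non-empty vector of positive integer headcounts.
#' @param cadre Name of the cadre to vary.
#' @return A `chw_frontier` data frame: `headcount`,
#'   `aggregate_achievable_share` (non-decreasing in headcount),
#'   `full_coverage` (true exactly where `headcount >= chws_needed`).
#' @export
frontier <- function(scenario, grid, cadre) {
  stopifnot(inherits(scenario, "chw_scenario"))
  grid <- as.numeric(grid)
  if (!length(grid) || any(is.na(grid)) || any(grid <= 0) ||
      any(grid != round(grid))) {
    stop("grid must be a non-empty vector of positive integers",
         call. = FALSE)
  }
  cn <- vapply(scenario$cadres, `[[`, character(1), "name")
  if (!cadre %in% cn) {
    stop(sprintf("unknown cadre '%s' (valid: %s)", cadre,
                 paste(cn, collapse = ", ")), call. = FALSE)
  }
  st <- chws_needed(scenario)$cadres
  need <- st$required_chws[st$cadre == cadre]
  share <- vapply(grid, function(h) {
    s <- edit_scenario(scenario, edit_headcount(cadre, h), name = scenario$name)
    cov <- expected_coverage(s)
    cov$cadres$aggregate_achievable_share[cov$cadres$cadre == cadre]
  }, numeric(1))
  out <- data.frame(headcount = grid,
                    aggregate_achievable_share = share,
                    full_coverage = grid >= need)
  class(out) <- c("chw_frontier", "data.frame")
  attr(out, "cadre") <- cadre
  attr(out, "required_chws") <- need
  out
}

#' @export
print.chw_frontier <- function(x, ...) {
  cat(sprintf("<chw_frontier> cadre '%s' (needs %d for full coverage)\n",
              attr(x, "cadre"), attr(x, "required_chws")))
  print(format_num_df(as.data.frame(x)), row.names = FALSE)
  invisible(x)
}
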