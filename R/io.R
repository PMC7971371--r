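#' Load a scenario from a YAML file
#'
#' Reads the documented single-file scenario schema. All schema violations
#' are collected and reported at once (each message names the offending
#' field path); unknown extra keys produce a warning, not an error, for
#' forward compatibility. Errors carry condition classes distinguishing
#' parse errors (`chw_parse_error`), schema violations
#' (`chw_schema_error`), and semantic violations such as dangling cadre
#' references (`chw_semantic_error`).
#'
#' @param path Path to a scenario YAML file.
#' @return A `chw_scenario`.
#' @seealso [save_scenario()] for the inverse, and the package vignette for
#'   the full field dictionary.
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) {
    stop_cond("chw_parse_error", sprintf("scenario file not found: %s", path))
  }
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) {
                    stop_cond("chw_parse_error",
                              sprintf("cannot parse %s: %s", path,
                                      conditionMessage(e)))
                  })
  scenario_from_list(raw, origin = path)
}

known_top_keys <- c("schema_version", "name", "allocation_mode",
                    "group_rounding", "profile", "cadres", "interventions",
                    "known_values")
known_policy_keys <- c("hours_per_week", "weeks_per_year", "travel_share",
                       "admin_share", "training_hours_per_year",
                       "campaign_hours_per_year")
known_int_keys <- c("name", "cadre", "mode", "target", "contacts_per_year",
                    "minutes_per_contact", "group_size", "coverage_goal",
                    "priority", "travel_minutes_per_contact")

# build a chw_scenario from a parsed config list, collecting schema errors
scenario_from_list <- function(raw, origin = "<config>") {
  errs <- character()
  add_err <- function(...) errs <<- c(errs, sprintf(...))
  warn_unknown <- function(keys, known, where) {
    extra <- setdiff(keys, known)
    if (length(extra)) {
      warning(sprintf("%s: ignoring unknown key(s) at %s: %s", origin, where,
                      paste(extra, collapse = ", ")), call. = FALSE)
    }
  }
  if (!is.list(raw)) {
    stop_cond("chw_schema_error", sprintf("%s: top level must be a mapping",
                                          origin))
  }
  warn_unknown(names(raw), known_top_keys, "top level")
  need <- function(field, where = "top level") {
    if (is.null(raw[[field]])) add_err("%s: missing required field '%s'",
                                       where, field)
  }
  need("name"); need("profile"); need("cadres")

  profile <- NULL
  p <- raw$profile
  if (is.list(p)) {
    warn_unknown(names(p), c("name", "total_population", "group_fractions",
                             "group_counts", "annual_event_rates"),
                 "profile")
    profile <- tryCatch({
      rates <- unlist(p$annual_event_rates) %||% numeric()
      if (!is.null(p$group_counts)) {
        build_profile_from_counts(p$name %||% raw$name, p$total_population,
                                  unlist(p$group_counts),
                                  annual_event_rates = rates)
      } else {
        population_profile(p$name %||% raw$name, p$total_population,
                           unlist(p$group_fractions) %||% numeric(),
                           rates)
      }
    }, error = function(e) {
      add_err("profile: %s", conditionMessage(e)); NULL
    })
  } else if (!is.null(p)) add_err("profile: must be a mapping")

  cadres <- list()
  for (i in seq_along(raw$cadres)) {
    c_ <- raw$cadres[[i]]
    where <- sprintf("cadres[%d]", i)
    warn_unknown(names(c_), c("name", "headcount", "time_policy"), where)
    tp <- c_$time_policy
    if (is.list(tp)) warn_unknown(names(tp), known_policy_keys,
                                  paste0(where, ".time_policy"))
    cd <- tryCatch({
      pol <- do.call(time_policy, tp[intersect(names(tp), known_policy_keys)])
      cadre(c_$name, pol, headcount = c_$headcount %||% NA)
    }, error = function(e) {
      add_err("%s (%s): %s", where, c_$name %||% "?", conditionMessage(e))
      NULL
    })
    if (!is.null(cd)) cadres <- c(cadres, list(cd))
  }

  interventions <- list()
  for (i in seq_along(raw$interventions)) {
    x <- raw$interventions[[i]]
    where <- sprintf("interventions[%d]", i)
    warn_unknown(names(x), known_int_keys, where)
    t_ <- x$target
    if (is.list(t_)) warn_unknown(names(t_), c("kind", "key",
                                               "in_need_fraction",
                                               "facility_share"),
                                  paste0(where, ".target"))
    iv <- tryCatch({
      tgt <- target_spec(t_$kind %||% "stock-group", t_$key,
                         in_need_fraction = t_$in_need_fraction %||% 1,
                         facility_share = t_$facility_share %||% 0)
      intervention(x$name, x$cadre, x$mode %||% "home-visit", tgt,
                   x$contacts_per_year, x$minutes_per_contact,
                   group_size = x$group_size %||% NA,
                   coverage_goal = x$coverage_goal %||% 1,
                   priority = x$priority %||% NA,
                   travel_minutes_per_contact =
                     x$travel_minutes_per_contact %||% 0)
    }, error = function(e) {
      add_err("%s (%s): %s", where, x$name %||% "?", conditionMessage(e))
      NULL
    })
    if (!is.null(iv)) interventions <- c(interventions, list(iv))
  }

  if (length(errs)) {
    stop_cond("chw_schema_error",
              sprintf("%s: %d schema violation(s):\n  - %s", origin,
                      length(errs), paste(errs, collapse = "\n  - ")))
  }
  tryCatch(
    scenario(raw$name, profile, cadres, interventions,
             allocation_mode = raw$allocation_mode %||% "proportional",
             group_rounding = raw$group_rounding %||% "exact"),
    error = function(e) {
      stop_cond("chw_semantic_error",
                sprintf("%s: %s", origin, conditionMessage(e)))
    })
}

#' Save a scenario to a YAML file
#'
#' Writes the documented schema (with `schema_version`) such that
#' [load_scenario()] reproduces a scenario with identical engine outputs.
#'
#' @param scenario A [scenario()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "chw_scenario"))
  raw <- list(
    schema_version = 1L,
    name = scenario$name,
    allocation_mode = scenario$allocation_mode,
    group_rounding = scenario$group_rounding,
    profile = list(
      name = scenario$profile$name,
      total_population = scenario$profile$total_population,
      group_fractions = as.list(scenario$profile$group_fractions),
      annual_event_rates = as.list(scenario$profile$annual_event_rates)),
    cadres = lapply(scenario$cadres, function(cd) {
      list(name = cd$name,
           headcount = if (is.na(cd$headcount)) NULL else cd$headcount,
           time_policy = unclass(cd$time_policy))
    }),
    interventions = lapply(scenario$interventions, function(x) {
      list(name = x$name, cadre = x$cadre, mode = x$mode,
           target = unclass(x$target),
           contacts_per_year = x$contacts_per_year,
           minutes_per_contact = x$minutes_per_contact,
           group_size = if (is.na(x$group_size)) NULL else x$group_size,
           coverage_goal = x$coverage_goal,
           priority = x$priority,
           travel_minutes_per_contact = x$travel_minutes_per_contact)
    }))
  writeLines(yaml::as.yaml(raw, precision = 15), path)
  invisible(path)
}

#' Import an intervention catalog from CSV
#'
#' One row per intervention. Columns: `name`, `cadre`, `mode`,
#' `target_kind`, `target_key`, `in_need_fraction`, `facility_share`,
#' `contacts_per_year`, `minutes_per_contact`, `group_size` (blank unless
#' group-session), `coverage_goal`, `priority` (blank for catalog order),
#' `travel_minutes_per_contact`. Missing optional columns take their
#' defaults.
#'
#' @param path CSV file path.
#' @return A list of [intervention()] objects.
#' @export
import_catalog_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "cadre", "target_key") %in% names(df))) {
    stop_cond("chw_schema_error",
              "catalog CSV needs at least columns name, cadre, target_key")
  }
  col <- function(nm, default) {
    if (nm %in% names(df)) df[[nm]] else rep(default, nrow(df))
  }
  lapply(seq_len(nrow(df)), function(i) {
    num_or <- function(x, default) if (is.na(x) || x == "") default else
      as.numeric(x)
    intervention(
      df$name[i], df$cadre[i], col("mode", "home-visit")[i],
      target_spec(col("target_kind", "stock-group")[i], df$target_key[i],
                  in_need_fraction = num_or(col("in_need_fraction", 1)[i], 1),
                  facility_share = num_or(col("facility_share", 0)[i], 0)),
      contacts_per_year = as.numeric(col("contacts_per_year", 1)[i]),
      minutes_per_contact = as.numeric(col("minutes_per_contact", 0)[i]),
      group_size = num_or(col("group_size", NA)[i], NA),
      coverage_goal = num_or(col("coverage_goal", 1)[i], 1),
      priority = num_or(col("priority", NA)[i], NA),
      travel_minutes_per_contact =
        num_or(col("travel_minutes_per_contact", 0)[i], 0))
  })
}

#' Write tidy CSV report tables
#'
#' Serializes an engine result to one or more CSV files (or JSON tables)
#' with stable row order and fixed number formatting — 6 significant digits
#' for fractional columns, plain integers otherwise — so repeated runs are
#' byte-identical.
#'
#' @param result A `chw_staffing`, `chw_coverage`, `chw_delta`,
#'   `chw_frontier`, or plain data frame (e.g. [rank_time_consumers()]
#'   output).
#' @param dir Output directory (created if needed).
#' @param stem File-name stem; table suffixes are appended.
#' @param format `"csv"` (default), `"json-tables"`, or `"figure-data"`
#'   (per-cadre needed-vs-available pairs, for `chw_coverage` only).
#' @return Character vector of files written, invisibly.
#' @export
write_reports <- function(result, dir, stem = "report",
                          format = c("csv", "json-tables", "figure-data")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- result_tables(result, format)
  ext <- if (format == "json-tables") "json" else "csv"
  written <- character()
  for (nm in names(tables)) {
    f <- file.path(dir, sprintf("%s-%s.%s", stem, nm, ext))
    tab <- stable_format(tables[[nm]])
    if (format == "json-tables") {
      writeLines(minimal_json(tab), f)
    } else {
      utils::write.csv(tab, f, row.names = FALSE, quote = FALSE)
    }
    written <- c(written, f)
  }
  invisible(written)
}

result_tables <- function(result, format) {
  if (inherits(result, "chw_staffing")) {
    list(cadres = result$cadres)
  } else if (inherits(result, "chw_coverage")) {
    if (format == "figure-data") {
      tab <- result$cadres
      list(`time-per-chw` = data.frame(
        cadre = tab$cadre,
        hours_needed_per_chw = ifelse(
          !is.na(tab$headcount) & tab$headcount > 0,
          tab$total_demand_hours / tab$headcount, NA_real_),
        hours_available_per_chw = tab$available_hours_per_chw))
    } else {
      list(cadres = result$cadres, interventions = result$interventions)
    }
  } else if (inherits(result, "chw_delta")) {
    list(cadres = result$cadres, interventions = result$interventions,
         membership = data.frame(
           intervention = c(result$added, result$removed),
           change = rep(c("added", "removed"),
                        c(length(result$added), length(result$removed)))))
  } else if (inherits(result, "chw_frontier")) {
    list(frontier = as.data.frame(result))
  } else if (is.data.frame(result)) {
    list(table = result)
  } else {
    stop("unsupported result type: ", paste(class(result), collapse = "/"),
         call. = FALSE)
  }
}

# fixed formatting: fractions at 6 significant digits, integers plain
stable_format <- function(df) {
  for (j in seq_along(df)) {
    x <- df[[j]]
    if (is.numeric(x)) {
      if (all(is.na(x) | x == round(x))) {
        df[[j]] <- ifelse(is.na(x), "", format(x, scientific = FALSE,
                                               trim = TRUE))
      } else {
        df[[j]] <- ifelse(is.na(x), "",
                          formatC(signif(x, 6), format = "fg", digits = 6))
      }
    } else if (is.logical(x)) {
      df[[j]] <- ifelse(x, "true", "false")
    }
  }
  df
}

minimal_json <- function(df) {
  esc <- function(s) gsub('"', '\\\\"', s)
  rows <- vapply(seq_len(nrow(df)), function(i) {
    kv <- vapply(names(df), function(nm) {
      sprintf('"%s": "%s"', esc(nm), esc(as.character(df[[nm]][i])))
    }, character(1))
    paste0("    {", paste(kv, collapse = ", "), "}")
  }, character(1))
  c("[", paste(rows, collapse = ",\n"), "]")
}

stop_cond <- function(class, message) {
  stop(structure(class = c(class, "chw_error", "error", "condition"),
                 list(message = message, call = NULL)))
}
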