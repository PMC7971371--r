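#' Built-in program fixtures
#'
#' The package ships ready-made cases encoding the published figures of two
#' national CHW program analyses: Rwanda's three-cadre program (two regional
#' typologies plus the national headcounts) and Zanzibar's community health
#' volunteer quantification. Each fixture bundles a scenario with a
#' `known_values` table of labeled published quantities and their source
#' notes; intervention-level inputs that were never published are encoded as
#' clearly labeled synthetic aggregates (see the fixture files under
#' `inst/extdata/fixtures/`).
#'
#' @param name One of `fixture_names()`, or a path to a fixture-format YAML
#'   file.
#' @return A `chw_fixture`: list with `name`, `scenario`
#'   (a [scenario()]), and `known_values` (named list of
#'   `list(value, source)`).
#' @examples
#' fx <- load_fixture("rwanda-eastern")
#' population_per_chw(fx)  # 169
#' @export
load_fixture <- function(name) {
  path <- if (file.exists(name)) {
    name
  } else {
    p <- system.file("extdata", "fixtures", paste0(name, ".yaml"),
                     package = "chwplan")
    if (!nzchar(p)) {
      stop(sprintf("unknown fixture '%s' (available: %s)", name,
                   paste(fixture_names(), collapse = ", ")), call. = FALSE)
    }
    p
  }
  raw <- yaml::read_yaml(path)
  # fixtures may legitimately omit the catalog (aggregates-only cases)
  scen <- suppressWarnings(scenario_from_list(raw, origin = path))
  structure(list(name = raw$name, scenario = scen,
                 known_values = raw$known_values %||% list()),
            class = "chw_fixture")
}

#' @rdname load_fixture
#' @export
fixture_names <- function() {
  dir <- system.file("extdata", "fixtures", package = "chwplan")
  sort(sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$")))
}

#' Population per CHW
#'
#' Total population divided by the combined headcount of all cadres, rounded
#' half-up to a whole number of persons — the catchment-size convention used
#' in program assumption tables.
#'
#' @param case A `chw_fixture` or `chw_scenario`.
#' @return Integer persons per CHW.
#' @export
population_per_chw <- function(case) {
  scen <- if (inherits(case, "chw_fixture")) case$scenario else case
  stopifnot(inherits(scen, "chw_scenario"))
  hc <- vapply(scen$cadres, `[[`, numeric(1), "headcount")
  total_chws <- sum(hc, na.rm = TRUE)
  if (!(total_chws > 0)) {
    stop("population_per_chw needs a positive total headcount", call. = FALSE)
  }
  # round half up (not banker's rounding): 168.5 -> 169
  floor(scen$profile$total_population / total_chws + 0.5)
}

#' @export
print.chw_fixture <- function(x, ...) {
  cat(sprintf("<chw_fixture> %s\n", x$name))
  print(x$scenario)
  if (length(x$known_values)) {
    cat("Known published values:\n")
    for (k in names(x$known_values)) {
      cat(sprintf("  %-32s %s  [%s]\n", k,
                  format(x$known_values[[k]]$value, big.mark = ","),
                  x$known_values[[k]]$source))
    }
  }
  invisible(x)
}
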