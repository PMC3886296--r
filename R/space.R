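#' Construct and validate a clinical scenario space
#'
#' A scenario space declares, per patient population, a set of clinical
#' variables (each with ordered levels) and a list of applicable treatment
#' options.  Scenarios are the Cartesian product of the variable levels;
#' an *indication* is one (scenario, treatment) pair, the atomic unit that
#' an appropriateness panel rates.
#'
#' @param populations Named list keyed by population (`"NAID"` and/or
#'   `"IDA"`).  Each element is a list with components `variables` (a list
#'   of `list(name, label, levels)` entries, levels in their intended
#'   display order) and `treatments` (a list of `list(name, label)`
#'   entries).  `label` entries default to the corresponding `name`.
#' @param version Character version tag for the space, e.g.
#'   `"round2-default"`.
#'
#' @return An object of class `ruam_space`: a list with elements
#'   `version` and `populations` in the normalised form described above.
#'
#' @details Validation enforces: populations drawn from `NAID`/`IDA`; at
#'   least one variable and one treatment per population; unique variable
#'   names, unique treatment names and unique levels within a variable;
#'   non-empty level lists.
#'
#' @examples
#' sp <- ruam_space(list(NAID = list(
#'   variables  = list(list(name = "activity", levels = c("inactive", "active"))),
#'   treatments = list(list(name = "oral_iron")))))
#' n_scenarios(sp)
#' @seealso [read_space_config()], [enumerate_scenarios()],
#'   [enumerate_indications()]
#' @export
ruam_space <- function(populations, version = "custom") {
  if (!is.list(populations) || is.null(names(populations)) ||
      any(!nzchar(names(populations)))) {
    stop("`populations` must be a named list", call. = FALSE)
  }
  pops <- names(populations)
  bad <- setdiff(pops, c("NAID", "IDA"))
  if (length(bad)) {
    stop("unknown population(s): ", paste(bad, collapse = ", "),
         " (must be NAID or IDA)", call. = FALSE)
  }
  if (anyDuplicated(pops)) stop("duplicate population entries", call. = FALSE)

  populations <- lapply(stats::setNames(pops, pops), function(p) {
    pop <- populations[[p]]
    if (is.null(pop$variables) || length(pop$variables) == 0L) {
      stop("population ", p, " has no variables", call. = FALSE)
    }
    if (is.null(pop$treatments) || length(pop$treatments) == 0L) {
      stop("population ", p, " has no treatments", call. = FALSE)
    }
    vars <- lapply(pop$variables, function(v) {
      if (is.null(v$name) || !nzchar(v$name)) {
        stop("variable without a name in population ", p, call. = FALSE)
      }
      levels <- as.character(unlist(v$levels))
      if (length(levels) == 0L) {
        stop("variable '", v$name, "' (", p, ") has an empty level list",
             call. = FALSE)
      }
      if (anyDuplicated(levels)) {
        stop("variable '", v$name, "' (", p, ") has duplicate levels",
             call. = FALSE)
      }
      list(name = as.character(v$name),
           label = as.character(if (is.null(v$label)) v$name else v$label),
           levels = levels)
    })
    vn <- vapply(vars, `[[`, "", "name")
    if (anyDuplicated(vn)) {
      stop("duplicate variable name(s) in population ", p, ": ",
           paste(unique(vn[duplicated(vn)]), collapse = ", "), call. = FALSE)
    }
    trts <- lapply(pop$treatments, function(t) {
      if (is.character(t)) t <- list(name = t)
      if (is.null(t$name) || !nzchar(t$name)) {
        stop("treatment without a name in population ", p, call. = FALSE)
      }
      list(name = as.character(t$name),
           label = as.character(if (is.null(t$label)) t$name else t$label))
    })
    tn <- vapply(trts, `[[`, "", "name")
    if (anyDuplicated(tn)) {
      stop("duplicate treatment name(s) in population ", p, ": ",
           paste(unique(tn[duplicated(tn)]), collapse = ", "), call. = FALSE)
    }
    list(variables = vars, treatments = trts)
  })

  structure(list(version = as.character(version), populations = populations),
            class = "ruam_space")
}

#' Read or write a scenario-space configuration file
#'
#' Configurations are YAML or JSON files with top-level keys `version` and
#' `populations`; each population holds `variables` (name, label, levels)
#' and `treatments` (name, label).  `write_space_config()` followed by
#' `read_space_config()` reproduces an identical space.
#'
#' @param path File path; format is chosen by extension (`.yaml`/`.yml`
#'   or `.json`).
#' @return `read_space_config()` returns a validated [ruam_space] object.
#' @examples
#' sp <- default_space()
#' f <- tempfile(fileext = ".json")
#' write_space_config(sp, f)
#' identical(read_space_config(f), sp)
#' @export
read_space_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- switch(config_format(path),
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = FALSE)
  )
  if (is.null(cfg$populations)) {
    stop("config has no `populations` key: ", path, call. = FALSE)
  }
  ruam_space(cfg$populations,
             version = if (is.null(cfg$version)) "custom" else cfg$version)
}

#' @rdname read_space_config
#' @param space A [ruam_space] object.
#' @export
write_space_config <- function(space, path) {
  stopifnot(inherits(space, "ruam_space"))
  cfg <- list(version = space$version, populations = space$populations)
  switch(config_format(path),
    yaml = yaml::write_yaml(cfg, path),
    json = jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  )
  invisible(path)
}

config_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) return("yaml")
  if (ext == "json") return("json")
  stop("unsupported config format '", ext, "' (use .yaml, .yml or .json)",
       call. = FALSE)
}

#' The packaged default scenario space
#'
#' Loads the `"round2-default"` configuration shipped with the package:
#' the second-round structure for iron deficiency management in
#' inflammatory bowel disease.  NAID carries previous treatment (7
#' levels), conditions with additional iron need (2) and IBD activity (2);
#' IDA additionally carries the haemoglobin band (<8, 8-<10, 10-<12 g/dL)
#' and physical symptoms (2).  It enumerates to 28 + 168 = 196 scenarios
#' and 1148 indications.
#'
#' @return A [ruam_space] object.
#' @examples
#' n_indications(default_space())
#' @export
default_space <- function() {
  read_space_config(system.file("extdata", "round2_default.yaml",
                                package = "ruam", mustWork = TRUE))
}

population_of <- function(space, population) {
  pop <- space$populations[[population]]
  if (is.null(pop)) {
    stop("population '", population, "' not in space (has: ",
         paste(names(space$populations), collapse = ", "), ")", call. = FALSE)
  }
  pop
}

variable_names <- function(space, population) {
  vapply(population_of(space, population)$variables, `[[`, "", "name")
}

treatment_names <- function(space, population) {
  vapply(population_of(space, population)$treatments, `[[`, "", "name")
}

#' Enumerate all scenarios of a population
#'
#' Expands the full Cartesian product of a population's variable levels in
#' a deterministic odometer order: variables in configuration order, the
#' last-listed variable cycling fastest, levels in declared order.
#'
#' @param space A [ruam_space].
#' @param population `"NAID"` or `"IDA"` (must be present in the space).
#' @return A `data.frame` with columns `scenario_id`, `population`, and
#'   one character column per variable.  Scenario ids have the stable form
#'   `POP|var=level|...` with variables in configuration order.
#' @examples
#' nrow(enumerate_scenarios(default_space(), "NAID"))  # 28
#' @export
enumerate_scenarios <- function(space, population) {
  stopifnot(inherits(space, "ruam_space"))
  pop <- population_of(space, population)
  levels <- lapply(pop$variables, `[[`, "levels")
  names(levels) <- vapply(pop$variables, `[[`, "", "name")
  # expand.grid cycles the first factor fastest; reverse to get odometer
  # order (last variable fastest), then restore column order.
  grid <- expand.grid(rev(levels), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(grid)), drop = FALSE]
  ids <- scenario_ids(population, grid)
  out <- cbind(data.frame(scenario_id = ids, population = population,
                          stringsAsFactors = FALSE),
               grid)
  rownames(out) <- NULL
  out
}

scenario_ids <- function(population, assignment) {
  parts <- mapply(function(v, col) paste0(v, "=", col),
                  names(assignment), assignment, SIMPLIFY = FALSE)
  paste(population, do.call(paste, c(parts, sep = "|")), sep = "|")
}

#' Enumerate all indications of a scenario space
#'
#' An indication is one (scenario, treatment) pair.  Every scenario of
#' every population is paired with each of that population's treatments
#' exactly once, scenarios outermost, treatments in declared order.
#'
#' @param space A [ruam_space].
#' @return A `data.frame` with columns `population`, `scenario_id`,
#'   `treatment`, one row per indication.
#' @examples
#' nrow(enumerate_indications(default_space()))  # 1148
#' @export
enumerate_indications <- function(space) {
  stopifnot(inherits(space, "ruam_space"))
  out <- lapply(names(space$populations), function(p) {
    sc <- enumerate_scenarios(space, p)$scenario_id
    tr <- treatment_names(space, p)
    data.frame(population = p,
               scenario_id = rep(sc, each = length(tr)),
               treatment = rep(tr, times = length(sc)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Scenario and indication counts
#'
#' @param space A [ruam_space].
#' @return Integer count over all populations.
#' @export
n_scenarios <- function(space) {
  stopifnot(inherits(space, "ruam_space"))
  sum(vapply(space$populations, function(pop) {
    prod(vapply(pop$variables, function(v) length(v$levels), 0L))
  }, 0))
}

#' @rdname n_scenarios
#' @export
n_indications <- function(space) {
  stopifnot(inherits(space, "ruam_space"))
  sum(vapply(names(space$populations), function(p) {
    pop <- space$populations[[p]]
    prod(vapply(pop$variables, function(v) length(v$levels), 0L)) *
      length(pop$treatments)
  }, 0))
}

#' @export
print.ruam_space <- function(x, ...) {
  cat("RUAM scenario space [", x$version, "]\n", sep = "")
  for (p in names(x$populations)) {
    pop <- x$populations[[p]]
    nlev <- vapply(pop$variables, function(v) length(v$levels), 0L)
    cat("  ", p, ": ", prod(nlev), " scenarios (",
        paste0(vapply(pop$variables, `[[`, "", "name"), "[", nlev, "]",
               collapse = " x "),
        "), ", length(pop$treatments), " treatments\n", sep = "")
  }
  cat("  total: ", n_scenarios(x), " scenarios, ", n_indications(x),
      " indications\n", sep = "")
  invisible(x)
}
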