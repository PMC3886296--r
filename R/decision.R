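grade_of <- function(category) {
  c(appropriate = "appropriate", uncertain = "optional",
    inappropriate = "inappropriate")[category]
}

colour_of <- function(grade) {
  c(appropriate = "green", optional = "yellow",
    inappropriate = "red")[grade]
}

#' Build a patient-profile recommendation set
#'
#' Turns a classified round into the lookup structure behind a
#' decision-support front end: one record per (scenario, treatment) with
#' the category mapped to a display grade — appropriate (green),
#' optional (yellow; the uncertain category) and inappropriate (red) —
#' plus optional free-text panel considerations.
#'
#' @param results A complete `ruam_results` object.
#' @param notes Optional `data.frame` with columns `scenario_id`,
#'   `treatment`, `considerations` to attach panel notes to individual
#'   indications.
#' @return A `ruam_recommendations` object: a data frame with columns
#'   `population`, `scenario_id`, `treatment`, `category`, `grade`,
#'   `colour`, `considerations`; attributes `space`, `version` and
#'   `provenance = "computed"`.
#' @seealso [lookup_profile()], [export_tool_json()],
#'   [transcribed_recommendations()]
#' @export
build_recommendation_set <- function(results, notes = NULL) {
  space <- check_complete_results(results)
  rec <- as.data.frame(results)[, c("population", "scenario_id", "treatment",
                                    "category")]
  rec$grade <- unname(grade_of(rec$category))
  rec$colour <- unname(colour_of(rec$grade))
  rec$considerations <- ""
  if (!is.null(notes)) {
    stopifnot(all(c("scenario_id", "treatment", "considerations") %in%
                    names(notes)))
    i <- match(paste(notes$scenario_id, notes$treatment, sep = "\r"),
               paste(rec$scenario_id, rec$treatment, sep = "\r"))
    if (anyNA(i)) {
      stop("notes refer to unknown indication(s)", call. = FALSE)
    }
    rec$considerations[i] <- as.character(notes$considerations)
  }
  rownames(rec) <- NULL
  new_recommendations(rec, space, provenance = "computed")
}

new_recommendations <- function(records, space, provenance) {
  structure(records, space = space, version = space$version,
            provenance = provenance,
            class = c("ruam_recommendations", "data.frame"))
}

#' Look up the recommendations for one patient profile
#'
#' @param set A `ruam_recommendations` object.
#' @param population `"NAID"` or `"IDA"`.
#' @param profile Named list or character vector assigning a level to
#'   *every* variable of that population, e.g.
#'   `c(prev_treatment = "none", activity = "active")`.
#' @return The matching records: a data frame with one row per
#'   applicable treatment (`treatment`, `category`, `grade`, `colour`,
#'   `considerations`).
#' @export
lookup_profile <- function(set, population, profile) {
  stopifnot(inherits(set, "ruam_recommendations"))
  space <- attr(set, "space")
  pop <- population_of(space, population)
  vars <- variable_names(space, population)
  profile <- as.list(profile)
  missing_vars <- setdiff(vars, names(profile))
  if (length(missing_vars)) {
    stop("profile does not assign variable(s): ",
         paste(missing_vars, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(profile), vars)
  if (length(extra)) {
    stop("profile assigns unknown variable(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  for (v in vars) {
    lev <- pop$variables[[match(v, vars)]]$levels
    if (!(profile[[v]] %in% lev)) {
      stop("unknown level '", profile[[v]], "' for variable '", v,
           "' (levels: ", paste(lev, collapse = ", "), ")", call. = FALSE)
    }
  }
  assignment <- as.data.frame(lapply(profile[vars], as.character),
                              stringsAsFactors = FALSE)
  id <- scenario_ids(population, assignment)
  hit <- set[set$scenario_id == id, , drop = FALSE]
  if (nrow(hit) == 0L) {
    stop("no recommendation record for profile ", id, call. = FALSE)
  }
  out <- as.data.frame(hit)[, c("treatment", "category", "grade", "colour",
                                "considerations")]
  rownames(out) <- NULL
  out
}

#' Export and re-import a recommendation set as decision-tool JSON
#'
#' The JSON document bundles everything a front end needs: the scenario
#' space definition, the per-indication records with display grades, and
#' the provenance tag.  `import_tool_json(export_tool_json(s, f))`
#' reproduces `s` exactly.
#'
#' @param set A `ruam_recommendations` object.
#' @param path Output `.json` path.
#' @return `export_tool_json()` returns `path` invisibly;
#'   `import_tool_json()` returns the `ruam_recommendations` object.
#' @export
export_tool_json <- function(set, path) {
  stopifnot(inherits(set, "ruam_recommendations"))
  space <- attr(set, "space")
  doc <- list(
    format = "ruam-decision-tool",
    version = attr(set, "version"),
    provenance = attr(set, "provenance"),
    space = list(version = space$version, populations = space$populations),
    records = as.data.frame(set))
  jsonlite::write_json(doc, path, dataframe = "rows", auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname export_tool_json
#' @export
import_tool_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$format) || doc$format != "ruam-decision-tool") {
    stop("not a decision-tool JSON document: ", path, call. = FALSE)
  }
  space <- ruam_space(doc$space$populations, version = doc$space$version)
  rec <- do.call(rbind, lapply(doc$records, function(r) {
    data.frame(population = r$population, scenario_id = r$scenario_id,
               treatment = r$treatment, category = r$category,
               grade = r$grade, colour = r$colour,
               considerations = if (is.null(r$considerations)) "" else
                 r$considerations,
               stringsAsFactors = FALSE)
  }))
  rownames(rec) <- NULL
  new_recommendations(rec, space, provenance = doc$provenance)
}

#' @export
print.ruam_recommendations <- function(x, ...) {
  cat("RUAM recommendation set [", attr(x, "version"), "], provenance: ",
      attr(x, "provenance"), "\n", sep = "")
  cat("  ", length(unique(x$scenario_id)), " profiles, ", nrow(x),
      " graded indications (",
      sum(x$grade == "appropriate"), " appropriate / ",
      sum(x$grade == "optional"), " optional / ",
      sum(x$grade == "inappropriate"), " inappropriate)\n", sep = "")
  invisible(x)
}

#' Transcribed summary recommendations for iron deficiency in IBD
#'
#' A packaged reference recommendation set encoding the consensus panel's
#' published summary guidance for iron deficiency management in IBD at
#' the granularity of its principal variables: previous treatment and
#' IBD activity for NAID, previous treatment and haemoglobin band for
#' IDA.  The encoded statements are: no active treatment is never
#' appropriate; adjusting IBD medication alone is appropriate in active
#' and inappropriate in inactive disease; oral iron is appropriate in
#' inactive NAID with no previous treatment or previous oral success,
#' and in IDA only after oral success at Hb 10-<12 g/dL; low-dose IV
#' iron is appropriate after its own previous success (in NAID also
#' after oral failure); high-dose IV iron is broadly appropriate except,
#' in IDA, after its own failure, where IV iron + ESA becomes the
#' appropriate option; blood transfusion is an option only below
#' Hb 8 g/dL.  Cells the summary guidance does not pin down are graded
#' `optional`.  This set is a transcription, not a computation — its
#' provenance tag is `"transcribed-fixture"` and it is *synthetic* in
#' the sense that the underlying raw panel ratings are not public.
#'
#' @return A `ruam_recommendations` object over a reduced
#'   `"figures-summary"` space (NAID: previous treatment x activity;
#'   IDA: previous treatment x haemoglobin band).
#' @examples
#' fix <- transcribed_recommendations()
#' lookup_profile(fix, "NAID",
#'                c(prev_treatment = "none", activity = "active"))
#' @export
transcribed_recommendations <- function() {
  prev_levels <- c("none", "oral_success", "oral_failure",
                   "iv_low_success", "iv_low_failure",
                   "iv_high_success", "iv_high_failure")
  space <- ruam_space(version = "figures-summary", list(
    NAID = list(
      variables = list(
        list(name = "prev_treatment",
             label = "Previous treatment of iron deficiency",
             levels = prev_levels),
        list(name = "activity", label = "IBD activity status",
             levels = c("inactive", "active"))),
      treatments = list(
        list(name = "none", label = "None"),
        list(name = "ibd_medication", label = "Adjusting IBD medication only"),
        list(name = "oral_iron", label = "Oral iron"),
        list(name = "iv_low", label = "Low-dose IV iron"),
        list(name = "iv_high", label = "High-dose IV iron"))),
    IDA = list(
      variables = list(
        list(name = "prev_treatment",
             label = "Previous treatment of iron deficiency",
             levels = prev_levels),
        list(name = "hb_band", label = "Haemoglobin level (g/dL)",
             levels = c("hb_lt8", "hb_8_10", "hb_10_12"))),
      treatments = list(
        list(name = "none", label = "None"),
        list(name = "oral_iron", label = "Oral iron"),
        list(name = "iv_low", label = "Low-dose IV iron"),
        list(name = "iv_high", label = "High-dose IV iron"),
        list(name = "iv_esa", label = "IV iron + ESA"),
        list(name = "transfusion", label = "Blood transfusion")))))

  grade_one <- function(population, prev, second, treatment) {
    if (treatment == "none") return("inappropriate")
    if (population == "NAID") {
      activity <- second
      switch(treatment,
        ibd_medication = if (activity == "active") "appropriate"
                         else "inappropriate",
        oral_iron = if (activity == "inactive" &&
                        prev %in% c("none", "oral_success")) "appropriate"
                    else "optional",
        iv_low = if (prev %in% c("iv_low_success", "oral_failure"))
                   "appropriate" else "optional",
        iv_high = "appropriate")
    } else {
      hb <- second
      switch(treatment,
        oral_iron = if (prev == "oral_success" && hb == "hb_10_12")
                      "appropriate"
                    else if (prev == "oral_success") "inappropriate"
                    else "optional",
        iv_low = if (prev == "iv_low_success") "appropriate" else "optional",
        iv_high = if (prev == "iv_high_failure") "optional" else "appropriate",
        iv_esa = if (prev == "iv_high_failure") "appropriate" else "optional",
        transfusion = if (hb == "hb_lt8") "optional" else "inappropriate")
    }
  }

  ind <- enumerate_indications(space)
  naid <- enumerate_scenarios(space, "NAID")  # cols 3:4 prev_treatment, activity
  ida <- enumerate_scenarios(space, "IDA")    # cols 3:4 prev_treatment, hb_band
  names(naid)[4L] <- names(ida)[4L] <- "second"
  scen <- rbind(naid, ida)
  i <- match(ind$scenario_id, scen$scenario_id)
  ind$grade <- mapply(grade_one, ind$population, scen$prev_treatment[i],
                      scen$second[i], ind$treatment)
  ind$category <- unname(
    c(appropriate = "appropriate", optional = "uncertain",
      inappropriate = "inappropriate")[ind$grade])
  ind$colour <- unname(colour_of(ind$grade))
  ind$considerations <- ""
  rec <- ind[, c("population", "scenario_id", "treatment", "category",
                 "grade", "colour", "considerations")]
  rownames(rec) <- NULL
  new_recommendations(rec, space, provenance = "transcribed-fixture")
}
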