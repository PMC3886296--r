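#' Assemble and validate a long-format panel rating table
#'
#' One row per individual rating: columns `rater_id`, `scenario_id`,
#' `treatment`, `rating` (integer 1-9) and `round` (integer, defaults
#' to 2).  Every record is validated against the scenario space; duplicate
#' (rater, scenario, treatment, round) keys are rejected.  Missing ratings
#' are never imputed — completeness is asserted where it matters
#' ([rating_vectors()], [classify_all()]).
#'
#' @param records A `data.frame` with the columns above (`round`
#'   optional).
#' @param space The [ruam_space] the ratings refer to.
#' @param panel Optional character vector fixing the panel membership and
#'   rater order.  Defaults to the sorted distinct `rater_id`s present.
#' @return A `ruam_ratings` object: the validated `data.frame` in
#'   canonical column order with attributes `panel` and `space`.
#' @seealso [read_ratings()], [rating_vectors()]
#' @export
ruam_ratings <- function(records, space, panel = NULL) {
  stopifnot(inherits(space, "ruam_space"))
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  needed <- c("rater_id", "scenario_id", "treatment", "rating")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("rating table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(records$round)) records$round <- 2L
  records <- records[, c("rater_id", "scenario_id", "treatment",
                         "rating", "round")]
  records$rater_id    <- as.character(records$rater_id)
  records$scenario_id <- as.character(records$scenario_id)
  records$treatment   <- as.character(records$treatment)

  if (nrow(records)) {
    bad <- which(!is.finite(records$rating) |
                 records$rating != as.integer(records$rating) |
                 records$rating < 1 | records$rating > 9)
    if (length(bad)) {
      stop("rating outside the integer 1-9 scale in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "),
           if (length(bad) > 5L) sprintf(" (and %d more)", length(bad) - 5L),
           call. = FALSE)
    }
    records$rating <- as.integer(records$rating)
    records$round <- as.integer(records$round)
    if (anyNA(records$round) || any(records$round < 1L)) {
      stop("`round` must be a positive integer", call. = FALSE)
    }

    ind <- enumerate_indications(space)
    known <- paste(ind$scenario_id, ind$treatment, sep = "\r")
    seen <- paste(records$scenario_id, records$treatment, sep = "\r")
    bad <- which(!(seen %in% known))
    if (length(bad)) {
      stop("unknown scenario/treatment combination in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), ", e.g. '",
           records$scenario_id[bad[1L]], "' / '",
           records$treatment[bad[1L]], "'", call. = FALSE)
    }
    key <- paste(records$rater_id, seen, records$round, sep = "\r")
    if (anyDuplicated(key)) {
      bad <- which(duplicated(key))
      stop("duplicate (rater, scenario, treatment, round) key in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
  } else {
    records$rating <- integer(0)
    records$round <- integer(0)
  }

  if (is.null(panel)) {
    panel <- sort(unique(records$rater_id))
  } else {
    panel <- as.character(panel)
    stray <- setdiff(records$rater_id, panel)
    if (length(stray)) {
      stop("rater(s) not in declared panel: ",
           paste(stray, collapse = ", "), call. = FALSE)
    }
  }
  rownames(records) <- NULL
  structure(records, panel = panel, space = space,
            class = c("ruam_ratings", "data.frame"))
}

#' Read or write panel ratings (CSV or JSON)
#'
#' The CSV schema is `rater_id,scenario_id,treatment,rating,round` with a
#' header, UTF-8; the JSON mirror is an array of record objects with the
#' same fields.  `read_ratings(write_ratings(t, f), space)` reproduces `t`
#' exactly.
#'
#' @param path File path; format chosen by extension (`.csv` or `.json`).
#' @param space The [ruam_space] to validate against.
#' @param panel Optional panel membership, as in [ruam_ratings()].
#' @return `read_ratings()` returns a `ruam_ratings` object.
#' @export
read_ratings <- function(path, space, panel = NULL) {
  if (!file.exists(path)) stop("ratings file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    out <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (length(out) == 0L) {
      data.frame(rater_id = character(0), scenario_id = character(0),
                 treatment = character(0), rating = integer(0),
                 round = integer(0))
    } else as.data.frame(out)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(rater_id = "character",
                                   scenario_id = "character",
                                   treatment = "character"))
  }
  ruam_ratings(df, space, panel = panel)
}

#' @rdname read_ratings
#' @param table A `ruam_ratings` object.
#' @export
write_ratings <- function(table, path) {
  stopifnot(inherits(table, "ruam_ratings"))
  df <- as.data.frame(table)[, c("rater_id", "scenario_id", "treatment",
                                 "rating", "round")]
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Per-indication rating vectors
#'
#' Collects, for one rating round, the P ratings of every indication into
#' an indications-by-raters integer matrix, rater order fixed to the panel
#' order.  The table must be complete: exactly one rating from every
#' panellist for every indication of the space.  Gaps are a hard error —
#' the method defines no missing-data rule.
#'
#' @param table A `ruam_ratings` object.
#' @param round Rating round to extract (default 2).
#' @return A list with `indications` (a `data.frame` of `population`,
#'   `scenario_id`, `treatment`) and `ratings` (an integer matrix, one row
#'   per indication in enumeration order, one column per panellist).
#' @export
rating_vectors <- function(table, round = 2L) {
  stopifnot(inherits(table, "ruam_ratings"))
  space <- attr(table, "space")
  panel <- attr(table, "panel")
  if (length(panel) == 0L) {
    stop("rating table has an empty panel", call. = FALSE)
  }
  df <- as.data.frame(table)
  df <- df[df$round == round, , drop = FALSE]
  ind <- enumerate_indications(space)
  ind_key <- paste(ind$scenario_id, ind$treatment, sep = "\r")

  row_i <- match(paste(df$scenario_id, df$treatment, sep = "\r"), ind_key)
  col_i <- match(df$rater_id, panel)
  m <- matrix(NA_integer_, nrow = nrow(ind), ncol = length(panel),
              dimnames = list(NULL, panel))
  m[cbind(row_i, col_i)] <- df$rating

  if (anyNA(m)) {
    gap <- which(is.na(m), arr.ind = TRUE)
    msgs <- apply(utils::head(gap, 5L), 1L, function(g) {
      paste0(panel[g[2L]], " x ", ind_key[g[1L]])
    })
    stop("incomplete rating table for round ", round, ": ",
         sum(is.na(m)), " missing rating(s), e.g. ",
         paste(gsub("\r", " / ", msgs), collapse = "; "), call. = FALSE)
  }
  list(indications = ind, ratings = m)
}

#' @export
print.ruam_ratings <- function(x, ...) {
  cat("RUAM rating table: ", nrow(x), " ratings, panel of ",
      length(attr(x, "panel")), ", round(s) ",
      paste(sort(unique(x$round)), collapse = ", "), "\n", sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}
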