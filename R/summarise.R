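result_space <- function(results) {
  space <- attr(results, "space")
  if (is.null(space)) stop("results carry no scenario space", call. = FALSE)
  space
}

check_complete_results <- function(results) {
  stopifnot(inherits(results, "ruam_results"))
  space <- result_space(results)
  ind <- enumerate_indications(space)
  have <- paste(results$scenario_id, results$treatment, sep = "\r")
  want <- paste(ind$scenario_id, ind$treatment, sep = "\r")
  if (!setequal(have, want) || anyDuplicated(have)) {
    stop("results do not cover every indication of the space exactly once",
         call. = FALSE)
  }
  invisible(space)
}

#' Appropriateness distribution per treatment
#'
#' For each population and treatment, the percentage of that population's
#' scenarios whose indication was classified inappropriate, uncertain and
#' appropriate.  Each row sums to exactly 100 before rounding; printing
#' rounds to whole percentages as such tables are conventionally
#' displayed.
#'
#' @param results A complete `ruam_results` object ([classify_all()]).
#' @return A `ruam_distribution` data frame with columns `population`,
#'   `treatment`, `inappropriate`, `uncertain`, `appropriate`
#'   (percentages, unrounded).
#' @export
appropriateness_distribution <- function(results) {
  space <- check_complete_results(results)
  rows <- list()
  for (p in names(space$populations)) {
    for (tr in treatment_names(space, p)) {
      cat_ <- results$category[results$population == p &
                               results$treatment == tr]
      n <- length(cat_)
      rows[[length(rows) + 1L]] <- data.frame(
        population = p, treatment = tr,
        inappropriate = 100 * sum(cat_ == "inappropriate") / n,
        uncertain     = 100 * sum(cat_ == "uncertain") / n,
        appropriate   = 100 * sum(cat_ == "appropriate") / n,
        stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), class = c("ruam_distribution", "data.frame"))
}

#' @export
print.ruam_distribution <- function(x, ...) {
  cat("Appropriateness figures (%) — row totals 100% before rounding\n")
  shown <- as.data.frame(x)
  for (col in c("inappropriate", "uncertain", "appropriate")) {
    shown[[col]] <- round(shown[[col]])
  }
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Panel agreement and disagreement rates
#'
#' Percentage of indications whose rating vector carried the agreement
#' (respectively disagreement) flag.
#'
#' @param results A non-empty `ruam_results` object.
#' @return A percentage in \[0, 100\].
#' @export
agreement_rate <- function(results) {
  stopifnot(inherits(results, "ruam_results"))
  if (nrow(results) == 0L) stop("no classified indications", call. = FALSE)
  100 * mean(results$agreement)
}

#' @rdname agreement_rate
#' @export
disagreement_rate <- function(results) {
  stopifnot(inherits(results, "ruam_results"))
  if (nrow(results) == 0L) stop("no classified indications", call. = FALSE)
  100 * mean(results$disagreement)
}

#' Appropriate-option counts per scenario
#'
#' Counts, per scenario, how many of its applicable treatments were
#' classified appropriate, and aggregates the share of scenarios with at
#' least one appropriate option and with exactly one.
#'
#' @param results A complete `ruam_results` object.
#' @return A list with `counts` (data frame `population`, `scenario_id`,
#'   `n_appropriate`, `n_treatments`) and the aggregate percentages
#'   `pct_at_least_one` and `pct_exactly_one`.
#' @export
scenario_option_counts <- function(results) {
  check_complete_results(results)
  app <- results$category == "appropriate"
  agg <- stats::aggregate(app, by = list(population = results$population,
                                         scenario_id = results$scenario_id),
                          FUN = sum)
  ntr <- stats::aggregate(app, by = list(population = results$population,
                                         scenario_id = results$scenario_id),
                          FUN = length)
  counts <- data.frame(population = agg$population,
                       scenario_id = agg$scenario_id,
                       n_appropriate = as.integer(agg$x),
                       n_treatments = as.integer(ntr$x),
                       stringsAsFactors = FALSE)
  counts <- counts[order(counts$population, counts$scenario_id), ]
  rownames(counts) <- NULL
  list(counts = counts,
       pct_at_least_one = 100 * mean(counts$n_appropriate >= 1L),
       pct_exactly_one = 100 * mean(counts$n_appropriate == 1L))
}

#' Preferred-option share per treatment
#'
#' For each scenario the *preferred option* is operationalised either as
#' the appropriate treatment with the strictly highest median panel score
#' (`"highest_median_among_appropriate"`, the default) or as the uniquely
#' appropriate treatment (`"unique_appropriate"`).  Scenarios where the
#' rule yields no single winner (no appropriate option, or a tie under
#' the default rule) attribute no preference; ties are reported
#' explicitly, never broken.
#'
#' @param results A complete `ruam_results` object.
#' @param rule Preference rule, see above.
#' @return A `ruam_preference` list: `shares` (data frame `population`,
#'   `treatment`, `n_preferred`, `share` as a percentage of that
#'   population's scenarios), `ties` (per population the number and share
#'   of tied scenarios), `rule`.
#' @export
preferred_option_share <- function(results,
                                   rule = c("highest_median_among_appropriate",
                                            "unique_appropriate")) {
  rule <- match.arg(rule)
  space <- check_complete_results(results)
  shares <- list(); ties <- list()
  for (p in names(space$populations)) {
    trs <- treatment_names(space, p)
    sub <- results[results$population == p, , drop = FALSE]
    scen <- unique(sub$scenario_id)
    pref <- stats::setNames(integer(length(trs)), trs)
    n_tied <- 0L
    for (s in scen) {
      rows <- sub[sub$scenario_id == s, , drop = FALSE]
      app <- rows[rows$category == "appropriate", , drop = FALSE]
      if (nrow(app) == 0L) next
      if (rule == "unique_appropriate") {
        if (nrow(app) == 1L) pref[app$treatment] <- pref[app$treatment] + 1L
        next
      }
      best <- app[app$median == max(app$median), , drop = FALSE]
      if (nrow(best) == 1L) {
        pref[best$treatment] <- pref[best$treatment] + 1L
      } else {
        n_tied <- n_tied + 1L
      }
    }
    shares[[p]] <- data.frame(population = p, treatment = trs,
                              n_preferred = as.integer(pref),
                              share = 100 * as.integer(pref) / length(scen),
                              stringsAsFactors = FALSE)
    ties[[p]] <- data.frame(population = p, n_tied = n_tied,
                            share_tied = 100 * n_tied / length(scen),
                            stringsAsFactors = FALSE)
  }
  structure(list(shares = do.call(rbind, unname(shares)),
                 ties = do.call(rbind, unname(ties)),
                 rule = rule),
            class = "ruam_preference")
}

#' @export
print.ruam_preference <- function(x, ...) {
  cat("Preferred-option share (rule: ", x$rule, ")\n", sep = "")
  shown <- x$shares
  shown$share <- round(shown$share)
  print(shown, row.names = FALSE)
  if (any(x$ties$n_tied > 0L)) {
    cat("Tied scenarios (no single preferred option):\n")
    print(x$ties, row.names = FALSE)
  }
  invisible(x)
}

#' Discriminative power of clinical variables
#'
#' Scores how strongly each clinical variable drives the appropriateness
#' outcome: over all pairs of scenarios that differ in exactly that one
#' variable, the fraction of (scenario pair, treatment) comparisons whose
#' categories differ.  A score of 1 means every such level change flips
#' some category; 0 means the variable never matters.  Variables with a
#' single level admit no pairs and are reported with an `NA` score.
#'
#' @param results A complete `ruam_results` object.
#' @return A `ruam_discriminativeness` data frame with columns
#'   `population`, `variable`, `score`, `n_comparisons`, ordered within
#'   population by decreasing score.
#' @export
discriminativeness <- function(results) {
  space <- check_complete_results(results)
  out <- list()
  for (p in names(space$populations)) {
    scen <- enumerate_scenarios(space, p)
    trs <- treatment_names(space, p)
    vars <- variable_names(space, p)
    # category matrix: scenarios x treatments
    sub <- results[results$population == p, , drop = FALSE]
    cm <- matrix(NA_character_, nrow = nrow(scen), ncol = length(trs),
                 dimnames = list(scen$scenario_id, trs))
    cm[cbind(match(sub$scenario_id, scen$scenario_id),
             match(sub$treatment, trs))] <- sub$category
    for (v in vars) {
      lev <- population_of(space, p)$variables[[match(v, vars)]]$levels
      if (length(lev) < 2L) {
        out[[length(out) + 1L]] <- data.frame(
          population = p, variable = v, score = NA_real_,
          n_comparisons = 0L, stringsAsFactors = FALSE)
        next
      }
      others <- setdiff(vars, v)
      key <- if (length(others)) {
        do.call(paste, c(scen[others], sep = "\r"))
      } else rep("", nrow(scen))
      groups <- split(seq_len(nrow(scen)), key)
      diff_n <- 0L; tot_n <- 0L
      for (g in groups) {
        if (length(g) < 2L) next
        prs <- utils::combn(g, 2L)
        for (k in seq_len(ncol(prs))) {
          i <- prs[1L, k]; j <- prs[2L, k]
          diff_n <- diff_n + sum(cm[i, ] != cm[j, ])
          tot_n <- tot_n + length(trs)
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        population = p, variable = v,
        score = if (tot_n) diff_n / tot_n else NA_real_,
        n_comparisons = tot_n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$population, -xtfrm(out$score)), ]
  rownames(out) <- NULL
  structure(out, class = c("ruam_discriminativeness", "data.frame"))
}

#' @export
print.ruam_discriminativeness <- function(x, ...) {
  cat("Discriminative-factor scores",
      "(fraction of matched-pair comparisons changing category)\n")
  print(as.data.frame(x), row.names = FALSE, digits = 3)
  invisible(x)
}
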