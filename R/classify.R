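#' Panel classification parameters
#'
#' The RUAM classification rules depend on the panel size P, the
#' agreement threshold A (minimum number of panellists rating in the same
#' section of the 9-point scale), the disagreement threshold D (minimum
#' number in *each* extreme section), and the three scale sections.
#' For the canonical 16-member panel the thresholds are A = 12 and D = 5.
#' For other panel sizes the defaults extrapolate the same fractions,
#' A = ceiling(0.75 P) and D = max(2, round(0.3125 P)); both can be
#' overridden.
#'
#' @param panel_size Number of voting panellists, P >= 1.
#' @param agreement_min Agreement threshold A (1 <= A <= P).
#' @param disagreement_min Disagreement threshold D (1 <= D <= P).
#' @param bands Named list of three inclusive integer intervals `low`,
#'   `mid`, `high` that partition 1..9.  Defaults to the standard
#'   tertiles 1-3 (inappropriate), 4-6 (uncertain), 7-9 (appropriate).
#' @return A `ruam_panel_config` list with elements `panel_size`,
#'   `agreement_min`, `disagreement_min`, `bands`.
#' @examples
#' panel_config(16)  # A = 12, D = 5
#' panel_config(6)   # A = 5,  D = 2
#' @export
panel_config <- function(panel_size,
                         agreement_min = NULL,
                         disagreement_min = NULL,
                         bands = list(low = c(1L, 3L), mid = c(4L, 6L),
                                      high = c(7L, 9L))) {
  panel_size <- as.integer(panel_size)
  if (length(panel_size) != 1L || is.na(panel_size) || panel_size < 1L) {
    stop("`panel_size` must be a single integer >= 1", call. = FALSE)
  }
  if (is.null(agreement_min)) agreement_min <- ceiling(0.75 * panel_size)
  if (is.null(disagreement_min)) {
    disagreement_min <- max(2L, as.integer(round(0.3125 * panel_size)))
  }
  agreement_min <- as.integer(agreement_min)
  disagreement_min <- as.integer(disagreement_min)
  if (agreement_min < 1L || agreement_min > panel_size) {
    stop("`agreement_min` must lie in 1..panel_size", call. = FALSE)
  }
  if (disagreement_min < 1L || disagreement_min > panel_size) {
    stop("`disagreement_min` must lie in 1..panel_size", call. = FALSE)
  }
  if (!setequal(names(bands), c("low", "mid", "high"))) {
    stop("`bands` must have elements low, mid, high", call. = FALSE)
  }
  covered <- sort(unlist(lapply(bands[c("low", "mid", "high")],
                                function(b) seq(b[1L], b[2L]))))
  if (!identical(as.integer(covered), 1:9)) {
    stop("`bands` must partition the integers 1..9", call. = FALSE)
  }
  structure(list(panel_size = panel_size,
                 agreement_min = agreement_min,
                 disagreement_min = disagreement_min,
                 bands = lapply(bands[c("low", "mid", "high")], as.integer)),
            class = "ruam_panel_config")
}

#' @export
print.ruam_panel_config <- function(x, ...) {
  cat("RUAM panel config: P = ", x$panel_size,
      ", agreement >= ", x$agreement_min, " in one section",
      ", disagreement >= ", x$disagreement_min, " in each extreme\n",
      sep = "")
  invisible(x)
}

check_vector <- function(v, cfg) {
  if (length(v) == 0L) stop("empty rating vector", call. = FALSE)
  if (!is.null(cfg) && length(v) != cfg$panel_size) {
    stop("rating vector has length ", length(v), ", panel size is ",
         cfg$panel_size, call. = FALSE)
  }
  if (anyNA(v) || any(v < 1 | v > 9) || any(v != as.integer(v))) {
    stop("ratings must be integers in 1..9", call. = FALSE)
  }
  as.integer(v)
}

#' Median panel rating
#'
#' Standard order-statistic median of one indication's ratings; for an
#' even panel the midpoint of the two central order statistics, so
#' half-integer values such as 6.5 are possible.
#'
#' @param v Integer vector of ratings 1-9.
#' @return The median, a value in \[1, 9\].
#' @export
median_rating <- function(v) {
  v <- check_vector(v, NULL)
  stats::median(v)
}

#' Agreement and disagreement flags for one rating vector
#'
#' The panel has *agreement* on an indication when at least A of the P
#' ratings fall in the same section of the 9-point scale (1-3, 4-6 or
#' 7-9); it has *disagreement* when at least D ratings fall in section
#' 1-3 *and* at least D in section 7-9.  With the canonical P = 16,
#' A = 12, D = 5 the two flags are mutually exclusive.
#'
#' @param v Integer vector of ratings 1-9, length `cfg$panel_size`.
#' @param cfg A [panel_config()].
#' @return Logical flag.
#' @export
has_agreement <- function(v, cfg) {
  v <- check_vector(v, cfg)
  b <- cfg$bands
  counts <- c(sum(v >= b$low[1L] & v <= b$low[2L]),
              sum(v >= b$mid[1L] & v <= b$mid[2L]),
              sum(v >= b$high[1L] & v <= b$high[2L]))
  max(counts) >= cfg$agreement_min
}

#' @rdname has_agreement
#' @export
has_disagreement <- function(v, cfg) {
  v <- check_vector(v, cfg)
  b <- cfg$bands
  sum(v >= b$low[1L] & v <= b$low[2L]) >= cfg$disagreement_min &&
    sum(v >= b$high[1L] & v <= b$high[2L]) >= cfg$disagreement_min
}

# Vectorised core shared by classify() and classify_all(): m is an
# n x P integer matrix of ratings.
classify_matrix <- function(m, cfg) {
  P <- cfg$panel_size
  stopifnot(is.matrix(m), ncol(m) == P)
  b <- cfg$bands
  low  <- rowSums(m >= b$low[1L]  & m <= b$low[2L])
  mid  <- rowSums(m >= b$mid[1L]  & m <= b$mid[2L])
  high <- rowSums(m >= b$high[1L] & m <= b$high[2L])
  agreement <- pmax(low, mid, high) >= cfg$agreement_min
  disagreement <- low >= cfg$disagreement_min & high >= cfg$disagreement_min

  # Median from cumulative rating counts (ratings live on 1..9): the k-th
  # order statistic is the smallest value v with #\{ratings <= v\} >= k.
  counts <- vapply(1:9, function(v) rowSums(m == v), numeric(nrow(m)))
  if (nrow(m) == 1L) counts <- matrix(counts, nrow = 1L)
  cum <- t(apply(counts, 1L, cumsum))
  kth <- function(k) max.col(cum >= k, ties.method = "first")
  med <- if (P %% 2L == 1L) {
    as.numeric(kth((P + 1L) %/% 2L))
  } else {
    (kth(P %/% 2L) + kth(P %/% 2L + 1L)) / 2
  }

  category <- rep("uncertain", nrow(m))
  category[med >= b$high[1L] & med <= b$high[2L] & !disagreement] <- "appropriate"
  category[med >= b$low[1L] & med <= b$low[2L] & !disagreement] <- "inappropriate"
  data.frame(median = med, agreement = agreement,
             disagreement = disagreement, category = category,
             stringsAsFactors = FALSE)
}

#' Classify one indication's rating vector
#'
#' Applies the RUAM panel rules: an indication is *appropriate* if the
#' median panel score lies in 7-9 without disagreement, *inappropriate*
#' if the median lies in 1-3 without disagreement, and *uncertain*
#' otherwise.  Band membership of the median is inclusive; a half-integer
#' median falling between bands (e.g. 6.5) classifies as uncertain.
#'
#' @param v Integer vector of ratings 1-9, length `cfg$panel_size`.
#' @param cfg A [panel_config()].
#' @return A list with elements `median`, `agreement`, `disagreement`,
#'   `category`.
#' @examples
#' cfg <- panel_config(16)
#' classify(rep(8L, 16), cfg)$category            # "appropriate"
#' classify(c(rep(2L, 5), rep(5L, 6), rep(8L, 5)), cfg)  # disagreement
#' @export
classify <- function(v, cfg) {
  v <- check_vector(v, cfg)
  res <- classify_matrix(matrix(v, nrow = 1L), cfg)
  list(median = res$median, agreement = res$agreement,
       disagreement = res$disagreement, category = res$category)
}

#' Classify every indication of a complete rating round
#'
#' @param table A `ruam_ratings` object, complete for `round`.
#' @param cfg A [panel_config()]; defaults to the panel size of the table
#'   with the standard threshold fractions.
#' @param round Rating round to classify (default 2).
#' @return A `ruam_results` data frame with one row per indication:
#'   `population`, `scenario_id`, `treatment`, `median`, `agreement`,
#'   `disagreement`, `category`; attributes `space` and `config`.
#' @seealso [summary.ruam_results()], [appropriateness_distribution()]
#' @export
classify_all <- function(table, cfg = NULL, round = 2L) {
  stopifnot(inherits(table, "ruam_ratings"))
  if (is.null(cfg)) cfg <- panel_config(length(attr(table, "panel")))
  rv <- rating_vectors(table, round = round)
  if (ncol(rv$ratings) != cfg$panel_size) {
    stop("panel size in config (", cfg$panel_size,
         ") does not match the table (", ncol(rv$ratings), ")",
         call. = FALSE)
  }
  res <- cbind(rv$indications, classify_matrix(rv$ratings, cfg))
  rownames(res) <- NULL
  structure(res, space = attr(table, "space"), config = cfg,
            class = c("ruam_results", "data.frame"))
}

#' @export
print.ruam_results <- function(x, ...) {
  cat("RUAM classification: ", nrow(x), " indications\n", sep = "")
  tab <- table(factor(x$category,
                      levels = c("appropriate", "uncertain", "inappropriate")))
  for (nm in names(tab)) {
    cat(sprintf("  %-14s %5d (%.1f%%)\n", nm, tab[[nm]],
                100 * tab[[nm]] / nrow(x)))
  }
  cat(sprintf("  agreement %.1f%%, disagreement %.1f%%\n",
              100 * mean(x$agreement), 100 * mean(x$disagreement)))
  invisible(x)
}

#' Summarise a classified round
#'
#' Bundles the headline analytics of a classified round: the
#' per-treatment appropriateness distribution, the agreement and
#' disagreement rates, and the per-scenario appropriate-option shares.
#'
#' @param object A `ruam_results` object.
#' @param ... Unused.
#' @return A `summary.ruam_results` list with elements `n_indications`,
#'   `agreement_rate`, `disagreement_rate`, `distribution`,
#'   `option_counts`.
#' @export
summary.ruam_results <- function(object, ...) {
  structure(list(n_indications = nrow(object),
                 agreement_rate = agreement_rate(object),
                 disagreement_rate = disagreement_rate(object),
                 distribution = appropriateness_distribution(object),
                 option_counts = scenario_option_counts(object)),
            class = "summary.ruam_results")
}

#' @export
print.summary.ruam_results <- function(x, ...) {
  cat("RUAM round summary\n")
  cat(sprintf("  indications:  %d\n", x$n_indications))
  cat(sprintf("  agreement:    %.0f%%\n", x$agreement_rate))
  cat(sprintf("  disagreement: %.0f%%\n", x$disagreement_rate))
  cat(sprintf("  scenarios with >= 1 appropriate option: %.0f%%\n",
              x$option_counts$pct_at_least_one))
  cat(sprintf("  scenarios with exactly 1 appropriate option: %.0f%%\n",
              x$option_counts$pct_exactly_one))
  cat("\n")
  print(x$distribution)
  invisible(x)
}
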