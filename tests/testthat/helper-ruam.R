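# Shared fixtures and independent oracles.  The oracles are literal
# transcriptions of the classification rules / brute-force enumerations,
# kept independent of the package's vectorised code paths.

minimal_space <- function() {
  ruam_space(list(NAID = list(
    variables = list(list(name = "v1", levels = "only")),
    treatments = list(list(name = "t1")))),
    version = "minimal")
}

# 2 x 2 NAID space with two treatments: 4 scenarios, 8 indications
toy_space <- function() {
  ruam_space(list(NAID = list(
    variables = list(
      list(name = "activity", levels = c("inactive", "active")),
      list(name = "severity", levels = c("mild", "severe"))),
    treatments = list(list(name = "oral"), list(name = "iv")))),
    version = "toy")
}

# Complete rating table on a space where every indication gets one fixed
# rating vector, supplied as a named list scenario_id||treatment -> vector
# or, if `fill` is given, the same vector everywhere.
table_from_vectors <- function(space, vectors = NULL, fill = NULL, P = NULL) {
  ind <- enumerate_indications(space)
  if (is.null(P)) P <- length(if (is.null(fill)) vectors[[1L]] else fill)
  panel <- sprintf("R%02d", seq_len(P))
  rows <- lapply(seq_len(nrow(ind)), function(i) {
    key <- paste(ind$scenario_id[i], ind$treatment[i], sep = "||")
    v <- if (!is.null(fill)) fill else vectors[[key]]
    stopifnot(!is.null(v), length(v) == P)
    data.frame(rater_id = panel, scenario_id = ind$scenario_id[i],
               treatment = ind$treatment[i], rating = as.integer(v),
               round = 2L, stringsAsFactors = FALSE)
  })
  ruam_ratings(do.call(rbind, rows), space, panel = panel)
}

# Literal transcription of the three classification sentences: median band
# (inclusive) without disagreement; agreement = >= A ratings in one section;
# disagreement = >= D in each of 1-3 and 7-9.
oracle_classify <- function(v, A, D) {
  v <- unname(v)
  P <- length(v)
  s <- sort(v)
  med <- if (P %% 2L == 1L) s[(P + 1L) %/% 2L] else
    (s[P %/% 2L] + s[P %/% 2L + 1L]) / 2
  n_low <- sum(v >= 1 & v <= 3)
  n_mid <- sum(v >= 4 & v <= 6)
  n_high <- sum(v >= 7 & v <= 9)
  agreement <- n_low >= A || n_mid >= A || n_high >= A
  disagreement <- n_low >= D && n_high >= D
  category <- if (med >= 7 && med <= 9 && !disagreement) "appropriate"
    else if (med >= 1 && med <= 3 && !disagreement) "inappropriate"
    else "uncertain"
  list(median = med, agreement = agreement, disagreement = disagreement,
       category = category)
}

# Brute-force scenario counter: explicit odometer loop, no expand.grid.
oracle_count_scenarios <- function(level_lists) {
  count <- 0L
  idx <- rep(1L, length(level_lists))
  sizes <- vapply(level_lists, length, 0L)
  repeat {
    count <- count + 1L
    pos <- length(idx)
    repeat {
      if (pos == 0L) return(count)
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= sizes[pos]) break
      idx[pos] <- 1L
      pos <- pos - 1L
    }
  }
}

random_space <- function(n_vars, max_levels = 4L, n_treatments = 2L) {
  vars <- lapply(seq_len(n_vars), function(i) {
    list(name = paste0("v", i),
         levels = paste0("l", seq_len(sample.int(max_levels, 1L))))
  })
  trts <- lapply(seq_len(n_treatments), function(i) list(name = paste0("t", i)))
  ruam_space(list(NAID = list(variables = vars, treatments = trts)))
}
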