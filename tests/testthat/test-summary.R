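# Builds a toy round with fully determined categories: each indication is
# rated with a unanimous vector so the category equals the plant.
toy_results <- function(plan, P = 16L) {
  sp <- toy_space()
  ind <- enumerate_indications(sp)
  centre <- c(appropriate = 8L, uncertain = 5L, inappropriate = 2L)
  vectors <- stats::setNames(
    lapply(plan, function(cat_) rep(centre[[cat_]], P)),
    names(plan))
  classify_all(table_from_vectors(sp, vectors = vectors, P = P))
}

# scenario order: (inactive,mild), (inactive,severe), (active,mild),
# (active,severe); treatments oral, iv
toy_plan <- c(
  "NAID|activity=inactive|severity=mild||oral"   = "appropriate",
  "NAID|activity=inactive|severity=mild||iv"     = "inappropriate",
  "NAID|activity=inactive|severity=severe||oral" = "uncertain",
  "NAID|activity=inactive|severity=severe||iv"   = "appropriate",
  "NAID|activity=active|severity=mild||oral"     = "appropriate",
  "NAID|activity=active|severity=mild||iv"       = "appropriate",
  "NAID|activity=active|severity=severe||oral"   = "inappropriate",
  "NAID|activity=active|severity=severe||iv"     = "uncertain")

test_that("the appropriateness distribution matches a hand tally", {
  res <- toy_results(toy_plan)
  d <- appropriateness_distribution(res)
  oral <- d[d$treatment == "oral", ]
  # oral: appropriate 2/4, uncertain 1/4, inappropriate 1/4
  expect_equal(oral$appropriate, 50)
  expect_equal(oral$uncertain, 25)
  expect_equal(oral$inappropriate, 25)
  iv <- d[d$treatment == "iv", ]
  expect_equal(iv$appropriate, 50)
  expect_equal(iv$uncertain, 25)
  expect_equal(iv$inappropriate, 25)
})

test_that("distribution rows sum to exactly 100 before rounding", {
  sp <- default_space()
  sim <- simulate_round(sp, sigma = 2, seed = 31)
  d <- appropriateness_distribution(classify_all(sim$ratings))
  expect_equal(d$inappropriate + d$uncertain + d$appropriate,
               rep(100, nrow(d)), tolerance = 1e-12)
  # degenerate case: one treatment entirely appropriate
  one <- classify_all(table_from_vectors(minimal_space(), fill = rep(8L, 16)))
  d1 <- appropriateness_distribution(one)
  expect_equal(unlist(d1[1L, c("inappropriate", "uncertain", "appropriate")]),
               c(inappropriate = 0, uncertain = 0, appropriate = 100))
})

test_that("agreement and disagreement rates count flagged indications", {
  res <- toy_results(toy_plan)          # unanimous vectors: all agreement
  expect_equal(agreement_rate(res), 100)
  expect_equal(disagreement_rate(res), 0)

  # planted half/half: 4 unanimous, 4 split vectors
  sp <- toy_space()
  split_v <- c(rep(2L, 8), rep(8L, 8))
  vectors <- stats::setNames(lapply(seq_along(toy_plan), function(i) {
    if (i %% 2L == 0L) split_v else rep(8L, 16)
  }), names(toy_plan))
  res2 <- classify_all(table_from_vectors(sp, vectors = vectors, P = 16L))
  expect_equal(agreement_rate(res2), 50)
  expect_equal(disagreement_rate(res2), 50)

  empty <- res[0, , drop = FALSE]
  class(empty) <- class(res)
  expect_error(agreement_rate(empty), "no classified")
})

test_that("per-scenario option counts match a hand tally", {
  res <- toy_results(toy_plan)
  oc <- scenario_option_counts(res)
  counts <- stats::setNames(oc$counts$n_appropriate, oc$counts$scenario_id)
  expect_equal(counts[["NAID|activity=inactive|severity=mild"]], 1L)
  expect_equal(counts[["NAID|activity=inactive|severity=severe"]], 1L)
  expect_equal(counts[["NAID|activity=active|severity=mild"]], 2L)
  expect_equal(counts[["NAID|activity=active|severity=severe"]], 0L)
  expect_equal(oc$pct_at_least_one, 75)
  expect_equal(oc$pct_exactly_one, 50)
})

test_that("preferred options follow the chosen rule and surface ties", {
  sp <- toy_space()
  # scenario 1: oral median 9, iv median 8 (both appropriate)
  # scenario 2: both median 8 -> tie under the default rule
  # scenario 3: only iv appropriate
  # scenario 4: none appropriate
  vectors <- list(
    "NAID|activity=inactive|severity=mild||oral"   = rep(9L, 16),
    "NAID|activity=inactive|severity=mild||iv"     = rep(8L, 16),
    "NAID|activity=inactive|severity=severe||oral" = rep(8L, 16),
    "NAID|activity=inactive|severity=severe||iv"   = rep(8L, 16),
    "NAID|activity=active|severity=mild||oral"     = rep(5L, 16),
    "NAID|activity=active|severity=mild||iv"       = rep(7L, 16),
    "NAID|activity=active|severity=severe||oral"   = rep(2L, 16),
    "NAID|activity=active|severity=severe||iv"     = rep(5L, 16))
  res <- classify_all(table_from_vectors(sp, vectors = vectors, P = 16L))

  pref <- preferred_option_share(res)
  shares <- stats::setNames(pref$shares$n_preferred, pref$shares$treatment)
  expect_equal(shares[["oral"]], 1L)   # scenario 1
  expect_equal(shares[["iv"]], 1L)     # scenario 3
  expect_equal(pref$ties$n_tied, 1L)   # scenario 2
  expect_equal(pref$shares$share, c(25, 25))

  uniq <- preferred_option_share(res, rule = "unique_appropriate")
  u <- stats::setNames(uniq$shares$n_preferred, uniq$shares$treatment)
  expect_equal(u[["oral"]], 0L)        # scenarios 1-2 have two appropriate
  expect_equal(u[["iv"]], 1L)
  expect_error(preferred_option_share(res, rule = "nonsense"))
})

test_that("discriminativeness isolates the variable that drives categories", {
  sp <- toy_space()
  # category depends only on activity
  vectors <- stats::setNames(lapply(names(toy_plan), function(key) {
    if (grepl("activity=active", key)) rep(8L, 16) else rep(2L, 16)
  }), names(toy_plan))
  res <- classify_all(table_from_vectors(sp, vectors = vectors, P = 16L))
  ds <- discriminativeness(res)
  expect_equal(ds$score[ds$variable == "activity"], 1)
  expect_equal(ds$score[ds$variable == "severity"], 0)
  expect_identical(ds$variable[1L], "activity")  # ranked first

  # constant categories -> all zero
  res0 <- classify_all(table_from_vectors(sp, fill = rep(8L, 16)))
  expect_equal(discriminativeness(res0)$score, c(0, 0))
})

test_that("discriminativeness equals a brute-force pair enumeration", {
  sp <- toy_space()
  sim <- simulate_round(sp, sigma = 3, seed = 13)
  res <- classify_all(sim$ratings)
  ds <- discriminativeness(res)

  scen <- enumerate_scenarios(sp, "NAID")
  key <- function(i, tr) res$category[res$scenario_id == scen$scenario_id[i] &
                                      res$treatment == tr]
  for (v in c("activity", "severity")) {
    diff_n <- 0L; tot_n <- 0L
    for (i in seq_len(nrow(scen) - 1L)) {
      for (j in seq(i + 1L, nrow(scen))) {
        differs <- c(scen$activity[i] != scen$activity[j],
                     scen$severity[i] != scen$severity[j])
        names(differs) <- c("activity", "severity")
        if (sum(differs) == 1L && differs[[v]]) {
          for (tr in c("oral", "iv")) {
            tot_n <- tot_n + 1L
            if (key(i, tr) != key(j, tr)) diff_n <- diff_n + 1L
          }
        }
      }
    }
    expect_equal(ds$score[ds$variable == v], diff_n / tot_n)
    expect_equal(ds$n_comparisons[ds$variable == v], tot_n)
  }
})

test_that("summaries are invariant to rater and row order", {
  sp <- toy_space()
  tab <- generate_ratings(plant_truth(sp, seed = 4), panel_size = 6L,
                          sigma = 1, seed = 4)
  df <- as.data.frame(tab)
  set.seed(8)
  shuffled <- ruam_ratings(df[sample(nrow(df)), ], sp,
                           panel = attr(tab, "panel"))
  r1 <- classify_all(tab, panel_config(6))
  r2 <- classify_all(shuffled, panel_config(6))
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(appropriateness_distribution(r1),
               appropriateness_distribution(r2))
  expect_equal(agreement_rate(r1), agreement_rate(r2))
})
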