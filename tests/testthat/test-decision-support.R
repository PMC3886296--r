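test_that("recommendation sets mirror the classification one-to-one", {
  sp <- toy_space()
  sim <- simulate_round(sp, sigma = 1, seed = 20)
  res <- classify_all(sim$ratings)
  set <- build_recommendation_set(res)

  expect_identical(attr(set, "provenance"), "computed")
  expect_identical(sort(unique(set$scenario_id)),
                   sort(enumerate_scenarios(sp, "NAID")$scenario_id))
  # category -> grade mapping
  expect_identical(unname(set$grade[set$category == "uncertain"][1]),
                   "optional")
  expect_true(all((set$grade == "optional") == (set$category == "uncertain")))
  expect_true(all((set$grade == "appropriate") ==
                    (set$category == "appropriate")))
  expect_identical(unique(set$colour[set$grade == "appropriate"]), "green")
  expect_identical(unique(set$colour[set$grade == "optional"]), "yellow")
  expect_identical(unique(set$colour[set$grade == "inappropriate"]), "red")

  # lookup agrees with classify_all for every scenario and treatment
  scen <- enumerate_scenarios(sp, "NAID")
  for (i in seq_len(nrow(scen))) {
    rec <- lookup_profile(set, "NAID",
                          c(activity = scen$activity[i],
                            severity = scen$severity[i]))
    for (j in seq_len(nrow(rec))) {
      want <- res$category[res$scenario_id == scen$scenario_id[i] &
                           res$treatment == rec$treatment[j]]
      expect_identical(rec$category[j], want)
    }
  }
})

test_that("lookup rejects incomplete or unknown profiles", {
  set <- transcribed_recommendations()
  expect_error(lookup_profile(set, "NAID", c(prev_treatment = "none")),
               "activity")
  expect_error(lookup_profile(set, "NAID",
                              c(prev_treatment = "none", activity = "active",
                                hb_band = "hb_lt8")),
               "unknown variable")
  expect_error(lookup_profile(set, "NAID",
                              c(prev_treatment = "none", activity = "busy")),
               "unknown level")
})

test_that("decision-tool JSON export round-trips identically", {
  sp <- toy_space()
  sim <- simulate_round(sp, sigma = 0.5, seed = 21)
  res <- classify_all(sim$ratings)
  notes <- data.frame(
    scenario_id = "NAID|activity=active|severity=mild", treatment = "iv",
    considerations = "only after oral intolerance")
  set <- build_recommendation_set(res, notes = notes)
  f <- tempfile(fileext = ".json")
  export_tool_json(set, f)
  back <- import_tool_json(f)
  expect_identical(as.data.frame(back), as.data.frame(set))
  expect_identical(attr(back, "space"), attr(set, "space"))
  expect_identical(attr(back, "provenance"), "computed")
  unlink(f)

  # empty-notes export keeps empty considerations fields
  set0 <- build_recommendation_set(res)
  f0 <- tempfile(fileext = ".json")
  export_tool_json(set0, f0)
  expect_true(all(import_tool_json(f0)$considerations == ""))
  unlink(f0)
})

test_that("notes must refer to existing indications", {
  sp <- minimal_space()
  res <- classify_all(table_from_vectors(sp, fill = rep(8L, 16)))
  bad <- data.frame(scenario_id = "NAID|v1=only", treatment = "ghost",
                    considerations = "x")
  expect_error(build_recommendation_set(res, notes = bad),
               "unknown indication")
})

test_that("the transcribed guidance fixture encodes the published statements", {
  fix <- transcribed_recommendations()
  expect_identical(attr(fix, "provenance"), "transcribed-fixture")
  sp <- attr(fix, "space")
  # covers every scenario of its space exactly once per treatment
  ind <- enumerate_indications(sp)
  expect_identical(sort(paste(fix$scenario_id, fix$treatment)),
                   sort(paste(ind$scenario_id, ind$treatment)))
  # grade "optional" <=> category uncertain
  expect_true(all((fix$grade == "optional") == (fix$category == "uncertain")))

  grade_at <- function(pop, profile, treatment) {
    rec <- lookup_profile(fix, pop, profile)
    rec$grade[rec$treatment == treatment]
  }

  # no active treatment is never appropriate
  expect_true(all(fix$grade[fix$treatment == "none"] == "inappropriate"))

  # adjusting IBD medication: appropriate in active, inappropriate in
  # inactive disease — for every previous-treatment history
  for (prev in c("none", "oral_failure", "iv_high_failure")) {
    expect_identical(grade_at("NAID",
                              c(prev_treatment = prev, activity = "active"),
                              "ibd_medication"), "appropriate")
    expect_identical(grade_at("NAID",
                              c(prev_treatment = prev, activity = "inactive"),
                              "ibd_medication"), "inappropriate")
  }

  # oral iron appropriate in inactive NAID without previous treatment
  expect_identical(grade_at("NAID",
                            c(prev_treatment = "none", activity = "inactive"),
                            "oral_iron"), "appropriate")
  expect_identical(grade_at("NAID",
                            c(prev_treatment = "none", activity = "active"),
                            "oral_iron"), "optional")

  # low-dose IV appropriate after its own success and after oral failure
  expect_identical(grade_at("NAID",
                            c(prev_treatment = "iv_low_success",
                              activity = "inactive"), "iv_low"),
                   "appropriate")
  expect_identical(grade_at("NAID",
                            c(prev_treatment = "oral_failure",
                              activity = "active"), "iv_low"),
                   "appropriate")

  # high-dose IV appropriate in IDA except after its own failure, where
  # IV iron + ESA becomes the appropriate option
  for (hb in c("hb_lt8", "hb_8_10", "hb_10_12")) {
    expect_identical(grade_at("IDA",
                              c(prev_treatment = "none", hb_band = hb),
                              "iv_high"), "appropriate")
    rec <- lookup_profile(fix, "IDA", c(prev_treatment = "iv_high_failure",
                                        hb_band = hb))
    expect_false(rec$grade[rec$treatment == "iv_high"] == "appropriate")
    expect_identical(rec$grade[rec$treatment == "iv_esa"], "appropriate")
  }

  # blood transfusion is an option only below Hb 8 g/dL
  tr <- fix[fix$treatment == "transfusion", ]
  expect_true(all(tr$grade[grepl("hb_band=hb_lt8", tr$scenario_id)] ==
                    "optional"))
  expect_true(all(tr$grade[!grepl("hb_band=hb_lt8", tr$scenario_id)] ==
                    "inappropriate"))
})
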