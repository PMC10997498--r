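# The synthetic campaign generator and its presets.

test_that("generation is fully reproducible from the seed", {
  spec <- preset_fixtures(seed = 123)$high_failure
  c1 <- generate_campaign(spec)
  c2 <- generate_campaign(spec)
  expect_identical(c1$records, c2$records)
  c3 <- generate_campaign(preset_fixtures(seed = 124)$high_failure)
  expect_false(identical(c1$records$outcome, c3$records$outcome))
})

test_that("failure_rate = 1 forces every outcome to exactly 0", {
  spec <- campaign_spec(
    reaction_class = "buchwald_hartwig",
    pairs = data.frame(halide = "Brc1ccccc1", nucleophile = "NCCCC",
                       baseline = 60, stringsAsFactors = FALSE),
    reagent_levels = list(base = data.frame(level = c("A", "B"),
                                            effect = c(0, 10),
                                            stringsAsFactors = FALSE)),
    n_replicates = 10, failure_rate = 1, noise_sd = 5, seed = 2)
  camp <- generate_campaign(spec)
  expect_true(all(camp$records$outcome == 0))
  expect_true(all(camp$truth$failed))
})

test_that("planted effects reproduce as mean-yield gaps (generator self-check)", {
  spec <- campaign_spec(
    reaction_class = "buchwald_hartwig",
    pairs = data.frame(halide = "Brc1ccccc1", nucleophile = "NCCCC",
                       baseline = 40, stringsAsFactors = FALSE),
    reagent_levels = list(base = data.frame(level = c("ref", "boost"),
                                            effect = c(0, 20),
                                            stringsAsFactors = FALSE)),
    n_replicates = 300, failure_rate = 0, noise_sd = 0.1, seed = 5)
  camp <- generate_campaign(spec)
  gap <- mean(camp$records$outcome[camp$records$base == "boost"]) -
    mean(camp$records$outcome[camp$records$base == "ref"])
  expect_equal(gap, 20, tolerance = 1)
})

test_that("spec validation rejects out-of-range parameters", {
  pairs <- data.frame(halide = "Brc1ccccc1", nucleophile = "NCCCC",
                      baseline = 50, stringsAsFactors = FALSE)
  lv <- list(base = data.frame(level = c("A", "B"), effect = c(0, 5),
                               stringsAsFactors = FALSE))
  expect_error(campaign_spec("x", pairs, lv, sparsity = 0), "sparsity")
  expect_error(campaign_spec("x", pairs, lv, failure_rate = 1.2),
               "failure_rate")
  expect_error(campaign_spec("x", pairs, lv, noise_sd = 0), "noise_sd")
  no_ref <- list(base = data.frame(level = c("A", "B"), effect = c(3, 5),
                                   stringsAsFactors = FALSE))
  expect_error(campaign_spec("x", pairs, no_ref), "reference")
})

test_that("presets carry their designed pair structure", {
  expect_equal(unique_pair_count(preset_campaign("ullmann_like",
                                                 seed = 1)$records), 9)
  bl <- preset_campaign("buchwald_like", seed = 1)
  expect_equal(unique_pair_count(bl$records), 29)
  # the ArBr + primary amine subdataset passes the inclusion rule
  subs <- split_subreactomes(bl$records)
  sel <- select_subdatasets(subs)
  labels <- vapply(sel, function(s) s$subclass, "")
  expect_true("ArBr + primary amine" %in% labels)
  arbr <- sel[[which(labels == "ArBr + primary amine")[1]]]
  expect_gt(nrow(arbr$records), 80)
  expect_error(preset_campaign("nope"), "unknown preset")
})

test_that("presets round-trip through cleanup with an empty log", {
  for (name in c("ullmann_like", "high_failure")) {
    camp <- preset_campaign(name, seed = 7)
    cl <- clean_dataset(camp$records)
    expect_equal(cl$log$removed_missing_temperature, 0)
    expect_equal(cl$log$removed_duplicates, 0)
    expect_equal(cl$log$removed_nonsensical, 0)
    expect_equal(nrow(cl$records), nrow(camp$records))
  }
})

test_that("ground truth marks planted levels with the intended class", {
  camp <- preset_campaign("buchwald_like", seed = 1)
  tl <- camp$truth$levels
  expect_identical(tl$intended_class[tl$level == "BrettPhos"], "best")
  expect_identical(tl$intended_class[tl$level == "PnBu3"], "worst")
  expect_identical(tl$intended_class[tl$level == "toluene"], "neutral")
  # intended best levels carry the maximal effect in their category
  for (cat in unique(tl$category)) {
    sub <- tl[tl$category == cat, ]
    if (any(sub$intended_class == "best")) {
      expect_equal(max(sub$effect),
                   max(sub$effect[sub$intended_class == "best"]))
    }
  }
})

test_that("temporal drift restricts level availability per period", {
  camp <- preset_campaign("temporal_drift", seed = 3)
  rec <- camp$records
  p1 <- rec$timestamp < as.Date("2015-01-01")
  expect_false("XPhos" %in% rec$ligand[p1])
  expect_true("XPhos" %in% rec$ligand[!p1])
})

test_that("campaigns round-trip through CSV and the ground truth serializes", {
  camp <- preset_campaign("temporal_drift", seed = 2)
  dir <- tempfile("campaign")
  write_campaign(camp, dir)
  rec <- parse_reactions(file.path(dir, "reactions.csv"))
  expect_equal(nrow(rec), nrow(camp$records))
  expect_identical(rec$ligand, camp$records$ligand)
  expect_equal(rec$outcome, camp$records$outcome)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_true(length(gt$levels) > 0)
})
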