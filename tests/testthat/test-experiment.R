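## Feature-table assembly, nested sets, sweep bookkeeping, reports.

test_that("the day-48 candidate inventory has 72 features in five groups", {
  mf <- modelField()
  ft <- mf$ft
  expect_identical(nrow(ft), 72L)
  grp <- table(featureGroups(ft))
  expect_identical(as.integer(grp[c("VI", "TI", "CC", "CHM", "LODGING")]),
                   c(24L, 45L, 1L, 1L, 1L))
  expect_identical(ncol(ft), 300L)
  ## all-band extraction yields the full per-date inventory of 162
  sea <- smallSeason()
  dem <- bareDEM(sea$scenes[["6"]], sea$layout[1:4, ])
  ft3 <- extractPlotFeatures(sea$scenes[["48"]], sea$layout[1:4, ], dem,
                             textureBands = c("R", "G", "B"))
  expect_identical(nrow(ft3), 162L)
  expect_identical(sum(featureGroups(ft3) == "TI"), 135L)
})

test_that("feature tables validate their structure", {
  m <- matrix(rnorm(8), 2, 4,
              dimnames = list(c("a", "b"), paste0("P", 1:4)))
  pd <- data.frame(plot_id = paste0("P", 1:4))
  ft <- FeatureTable(m, c("VI", "TI"), pd, date = 48L)
  expect_s4_class(ft, "FeatureTable")
  expect_identical(featureMatrix(ft), m)
  expect_error(FeatureTable(m, c("VI", "nope"), pd), "groups")
})

test_that("nested ablation sets each add exactly one feature group", {
  plan <- ablationPlan()
  expect_length(plan, 5L)
  for (k in 2:5) {
    expect_identical(setdiff(plan[[k]], plan[[k - 1]]),
                     setdiff(plan[[k]], plan[[k - 1]])[1])
    expect_true(all(plan[[k - 1]] %in% plan[[k]]))
  }
})

test_that("the ablation grid is complete, nested and counted", {
  mf <- modelField()
  ## a fast screening stand-in: keep everything
  allNames <- rownames(mf$ft)
  screened <- setdiff(allNames, c("Lodging", "CC"))
  fake <- new("ScreeningReport",
              importanceHistory = matrix(0, length(screened), 1,
                                         dimnames = list(screened, NULL)),
              timesBelowBestShadow = integer(length(screened)),
              decision = rep("keep", length(screened)),
              avgRank = rep(1, length(screened)),
              excluded = c("Lodging", "CC"), nRuns = 1L, cutoff = 1L)
  ab <- runAblation(mf$ft, reports = list(grain_number = fake),
                    targets = "grain_number",
                    methods = c("Logistic", "SVM"), seed = 3,
                    applyOCSVM = FALSE)
  expect_identical(length(ab$results), 10L) # 5 sets x 2 methods
  expect_identical(unname(ab$featureCounts),
                   c(24L, 69L, 70L, 71L, 72L))
  expect_identical(nrow(ab$table), 20L)
  ## nestedness: each set's columns are a subset of the next
  expect_true(all(diff(ab$featureCounts) > 0))
  badFt <- mf$ft[featureGroups(mf$ft) != "CHM", ]
  expect_error(runAblation(badFt, reports = list(grain_number = fake),
                           targets = "grain_number"), "CHM")
})

test_that("the date sweep produces one record per date, method, target", {
  mf <- modelField()
  sw <- runDateSweep(mf$sim$scenes, mf$sim$layout,
                     methods = c("Logistic", "SVM"), seed = 11,
                     textureBands = "R")
  expect_identical(nrow(sw$table), 2L * 2L * 2L)
  expect_true(all(sw$table$date %in% c(6, 48)))
  expect_true(all(sw$bestDate %in% c(6, 48)))
  ## the pre-emergence date is never the most informative
  for (tg in c("grain_number", "grain_weight")) {
    sub <- sw$table[sw$table$target == tg, ]
    agg <- tapply(sub$r2, sub$date, mean)
    expect_gt(agg[["48"]], agg[["6"]])
    expect_identical(unname(sw$bestDate[[tg]]), 48)
  }
  expect_error(runDateSweep(mf$sim$scenes[1], mf$sim$layout), "2 dates")
})

test_that("reports are written deterministically and validated", {
  tab <- data.frame(featureSet = "VIs", method = "SVM",
                    target = "grain_number",
                    split = c("train", "validation"),
                    r2 = c(0.5, 0.4), rmse = c(20, 25),
                    rrmse = c(33, 41))
  td <- withr::local_tempdir()
  p1 <- writeReport(tab, file.path(td, "r1"))
  p2 <- writeReport(tab, file.path(td, "r2"))
  expect_identical(readLines(p1[["csv"]]), readLines(p2[["csv"]]))
  expect_identical(readLines(p1[["json"]]), readLines(p2[["json"]]))
  expect_error(writeReport(tab[0, ], td), "no results")
})
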