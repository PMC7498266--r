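test_that("S-phase fraction is the EdU-positive proportion", {
  expect_equal(sphaseFraction(20, 100), 0.2)
  expect_equal(sphaseFraction(0, 100), 0)
  expect_error(sphaseFraction(1, 0), "must be > 0")
  expect_error(sphaseFraction(101, 100), "nNuclei")
  # binomial sampling check through the generator
  sim <- simulateEduTable(30, list(neighbor = c(nodox = 0.2, dox = 0.2)),
                          nNucleiPerPosition = 1000, seed = 4)
  tab <- sim$table
  fr <- sphaseFraction(tab$n_edu_positive, tab$n_nuclei)
  se <- sqrt(0.2 * 0.8 / tab$n_nuclei)
  expect_gt(mean(abs(fr - 0.2) <= 3 * se), 0.95)
  # degenerate fractions
  z <- simulateEduTable(3, list(a = c(nodox = 0, dox = 1)), seed = 1)$table
  expect_true(all(z$n_edu_positive[!z$dox] == 0))
  expect_true(all(z$n_edu_positive[z$dox] == z$n_nuclei[z$dox]))
})

test_that("proliferation folds normalize the parental mean to exactly 1", {
  r <- proliferationFoldChange(0.3, 0.1, parentalFolds = 1)
  expect_equal(r$fold, 3)
  expect_equal(r$normalized, 3)
  par <- c(0.9, 1.1, 1.05, 0.95)
  self <- par / mean(par)
  expect_equal(mean(self), 1, tolerance = 1e-12)
  undef <- proliferationFoldChange(0.3, 0, parentalFolds = 1)
  expect_true(is.na(undef$fold))
})

test_that("EdU fold table recovers a programmed neighbor enhancement", {
  sim <- simulateEduTable(
    16,
    fractions = list(neighbor = c(nodox = 0.1, dox = 0.3),
                     parental = c(nodox = 0.15, dox = 0.15)),
    nNucleiPerPosition = 1000, seed = 9)
  folds <- eduFoldTable(sim$table)
  nb <- folds$normalized_fold[folds$population == "neighbor"]
  expect_gt(mean(nb), 2.6)
  expect_lt(mean(nb), 3.4)
  par <- folds$normalized_fold[folds$population == "parental"]
  expect_equal(mean(par), 1, tolerance = 1e-12)
})

test_that("proportion-response rows carry the coculture composition", {
  tab <- data.frame(
    position = rep(c("p0", "p99"), each = 4),
    condition = "c",
    population = rep(c("inducible", "inducible", "neighbor", "neighbor"), 2),
    dox = rep(c(TRUE, FALSE), 4),
    n_nuclei = c(1, 1, 500, 500, 990, 990, 10, 10),
    n_edu_positive = c(0, 0, 100, 50, 150, 150, 4, 2))
  # p0: effectively no inducible nuclei among 501; p99: nearly all
  out <- proportionResponseCurve(tab)
  expect_lt(out$percent_inducible[out$position == "p0"], 1)
  expect_equal(out$percent_inducible[out$position == "p99"], 99)
  expect_equal(out$fold, c(2, 2))
})

test_that("response rises with sender proportion across compositions", {
  # dose-dependent paracrine enhancement: neighbor +Dox S-phase fraction
  # grows with the inducible percentage
  comps <- list(c(pct = 1, dox = 0.12), c(pct = 10, dox = 0.2),
                c(pct = 50, dox = 0.3))
  rows <- list()
  for (k in seq_along(comps)) {
    cc <- comps[[k]]
    sim <- simulateEduTable(
      8,
      fractions = list(inducible = c(nodox = 0.15, dox = 0.15),
                       neighbor = c(nodox = 0.1, dox = unname(cc["dox"]))),
      nNucleiPerPosition = c(inducible = 10 * cc[["pct"]],
                             neighbor = 10 * (100 - cc[["pct"]])),
      condition = paste0("mix", k), seed = 100 + k)
    tab <- sim$table
    tab$position <- paste0(tab$condition, "_", tab$position)
    rows[[k]] <- tab
  }
  curve <- proportionResponseCurve(do.call(rbind, rows))
  ct <- suppressWarnings(stats::cor.test(curve$percent_inducible,
                                         curve$fold, method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("shed-protein filter applies the p and fold boxes", {
  recs <- data.frame(
    protein = c("hit", "weakP", "weakFC", "negFC"),
    ln_fc_dox = c(log(1.6), log(2), log(1.2), -log(2)),
    ln_fc_ko = c(log(1.7), log(2), log(1.3), -log(2)),
    p_dox = c(0.04, 0.2, 0.01, 0.01),
    p_ko = c(0.01, 0.01, 0.02, 0.01))
  out <- filterShedProteins(recs)
  expect_setequal(out$protein, c("hit", "weakFC", "negFC"))
  expect_true(out$in_box[out$protein == "hit"])
  expect_false(out$in_box[out$protein == "weakFC"])
  expect_false(out$in_box[out$protein == "negFC"])
  # ranked by ln_fc_dox descending
  expect_equal(out$protein[1], "hit")
})

test_that("the filter is monotone in both thresholds", {
  set.seed(13)
  sim <- simulateShedTable(60, 6, effectLnfc = 0.8, seed = 13)
  recs <- shedRecords(sim$table)
  tight <- filterShedProteins(recs, 0.01, 2)
  loose <- filterShedProteins(recs, 0.05, 1.5)
  looser <- filterShedProteins(recs, 0.2, 1.1)
  expect_true(all(tight$protein %in% loose$protein))
  expect_true(all(loose$protein %in% looser$protein))
})

test_that("strong designated hits pass the filter; nulls stay near nominal", {
  sim <- simulateShedTable(40, 4, effectLnfc = 2, replicateCv = 0.05,
                           seed = 21)
  out <- filterShedProteins(shedRecords(sim$table))
  expect_true(all(sim$truth$hits %in% out$protein))
  expect_true(all(out$in_box[out$protein %in% sim$truth$hits]))
  # null tables: retention rate stays within twice the nominal test level
  retained <- 0; total <- 0
  for (s in 1:60) {
    nullSim <- simulateShedTable(40, 0, effectLnfc = 0, seed = 3000 + s)
    got <- filterShedProteins(shedRecords(nullSim$table))
    retained <- retained + nrow(got); total <- total + 40
  }
  expect_lte(retained / total, 2 * 0.05)
  # determinism
  a <- simulateShedTable(20, 2, seed = 5)$table
  b <- simulateShedTable(20, 2, seed = 5)$table
  expect_identical(a, b)
})
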