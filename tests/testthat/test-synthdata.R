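test_that("make_panel honours its dimension and determinism contract", {
  p <- make_panel(85, 50, tissues = sprintf("T%d", 1:6), event_prob = 0.2,
                  seed = 1)
  expect_equal(ncol(p$bem), 85)
  expect_equal(nrow(p$bem), 50)
  expect_equal(length(unique(p$tissue)), 6)
  expect_true(all(rowSums(p$bem) > 0))
  expect_identical(colnames(p$bem), p$cell_ids)
  p2 <- make_panel(85, 50, tissues = sprintf("T%d", 1:6), event_prob = 0.2,
                   seed = 1)
  expect_identical(p$bem, p2$bem)
  expect_error(make_panel(1, 10), "n_cells")
  expect_error(make_panel(10, 10, event_prob = 0), "event_prob")
})

test_that("per-gene event frequency matches the binomial rate", {
  p <- make_panel(10000, 5, event_prob = 0.5, seed = 2)
  freq <- rowMeans(p$bem)
  expect_true(all(abs(freq - 0.5) < 0.02))
})

test_that("simulate_screen is additive at delta 0 and recovers bumps", {
  panel <- make_panel(4, 3, seed = 3)
  drugs <- make_drug_library(2, rownames(panel$bem), seed = 3)
  design <- data.frame(combo_id = "C001", cell_id = panel$cell_ids[1:3],
                       drug_a = "D01", drug_b = "D02")
  sim <- simulate_screen(panel, drugs, design, background_sd = 0,
                         noise_sd = 0, seed = 5)
  expect_equal(sim$truth$delta, rep(0, 3))
  syn <- score_screen(sim$screen)
  expect_true(all(abs(syn$score) < 1))
  # untreated control is exactly 100 pre-noise
  for (drm in sim$screen) expect_equal(drm$viability[1, 1], 100)
  # determinism is bitwise
  sim2 <- simulate_screen(panel, drugs, design, background_sd = 0,
                          noise_sd = 0, seed = 5)
  expect_identical(sim$screen[[1]]$viability, sim2$screen[[1]]$viability)
  sim3 <- simulate_screen(panel, drugs, design, noise_sd = 2, seed = 6)
  sim4 <- simulate_screen(panel, drugs, design, noise_sd = 2, seed = 6)
  expect_identical(sim3$screen[[2]]$viability, sim4$screen[[2]]$viability)
  expect_error(simulate_screen(panel, drugs, design[0, ], seed = 1),
               "non-empty")
})

test_that("injected positive bump yields a positive capped score", {
  drm <- make_bump_experiment(delta = 40, seed = 7)
  r <- score_experiment(drm)
  expect_gt(r$score, 0)
  expect_lte(r$score, 100)
  expect_lt(abs(r$score - 40), 2)
})

test_that("simulate_teams hits correlation targets and orders by skill", {
  obs <- make_obs_fixture(n_combos = 50, n_cells = 10, seed = 8)
  teams <- simulate_teams(obs, 3, skill = c(0.9, 0.5, 0.1), seed = 9)
  r <- vapply(teams, function(t) cor(t$prediction, obs$score), 0)
  expect_true(all(abs(r - c(0.9, 0.5, 0.1)) < 0.1))
  expect_true(r[1] > r[2] && r[2] > r[3])
  perfect <- simulate_teams(obs, 1, skill = 1, seed = 10)[[1]]
  expect_equal(perfect$prediction, obs$score)
  expect_equal(suppressWarnings(weighted_pearson(perfect, obs)), 1)
  expect_true(all(perfect$prediction_binary %in% 0:1))
  expect_equal(perfect$prediction_binary,
               as.integer(obs$score >= 20))
  expect_error(simulate_teams(obs, 0), "n_teams")
  expect_error(simulate_teams(obs, 2, skill = 1.5), "skill")
})

test_that("simulate_classifier_teams achieves the requested accuracy", {
  set.seed(31)
  labels <- rbinom(5000, 1, 0.3)
  preds <- simulate_classifier_teams(labels, c(0.9, 0.6), seed = 11)
  bac <- apply(preds, 1, function(p)
    suppressWarnings(balanced_accuracy(p, labels)))
  expect_lt(abs(bac[1] - 0.9), 0.03)
  expect_lt(abs(bac[2] - 0.6), 0.03)
})

test_that("SC1 splits respect the 3/6-1/6-2/6 proportions", {
  mk <- function(n) data.frame(combo_id = "C001",
                               cell_id = sprintf("CL%02d", seq_len(n)))
  s12 <- make_splits(mk(12), "SC1", seed = 1)
  expect_equal(unname(table(s12$set)[c("train", "leaderboard", "validation")]),
               c(6L, 2L, 4L), ignore_attr = TRUE)
  s6 <- make_splits(mk(6), "SC1", seed = 1)
  expect_equal(sort(as.integer(table(s6$set))), c(1L, 2L, 3L))
  # a combination with < 6 cells is flagged and dropped
  mixed <- rbind(mk(6),
                 data.frame(combo_id = "C002",
                            cell_id = sprintf("CL%02d", 1:5)))
  expect_warning(s <- make_splits(mixed, "SC1", seed = 1), "excluded")
  expect_false("C002" %in% s$combo_id)
  # reproducible assignments
  expect_identical(make_splits(mk(12), "SC1", seed = 7),
                   make_splits(mk(12), "SC1", seed = 7))
})

test_that("SC2 splits 740 combinations into two disjoint halves", {
  design <- data.frame(combo_id = sprintf("C%03d", 1:740),
                       cell_id = "CL01")
  s <- make_splits(design, "SC2", seed = 2)
  expect_equal(sum(s$set == "leaderboard"), 370)
  expect_equal(sum(s$set == "validation"), 370)
  expect_length(intersect(s$combo_id[s$set == "leaderboard"],
                          s$combo_id[s$set == "validation"]), 0)
})

test_that("simulate_pdx couples benefit to the biomarker only when asked", {
  pairs <- data.frame(combo_id = "C001", drug_a = "D01", drug_b = "D02")
  off <- simulate_pdx(pairs, 1000, coupling = NULL, seed = 3)
  expect_true(all(off$event == 0))
  cohort <- simulate_pdx(pairs, 1000,
                         coupling = list(prevalence = 0.5), seed = 3)
  classed <- classify_pdx_cohort(cohort)
  tab <- table(classed$event, classed$class == "synergy")
  expect_lt(stats::chisq.test(tab)$p.value, 0.05)
  # and an uncoupled synthetic event column is independent of class
  set.seed(33)
  fake_event <- rbinom(nrow(classed), 1, 0.5)
  tab0 <- table(fake_event, classed$class == "synergy")
  expect_gt(stats::chisq.test(tab0)$p.value, 0.05)
  expect_identical(simulate_pdx(pairs, 50, seed = 9),
                   simulate_pdx(pairs, 50, seed = 9))
  expect_error(simulate_pdx(pairs, 0), "n_models")
})

test_that("mean recovered score increases strictly with delta", {
  deltas <- c(0, 10, 20, 40)
  means <- vapply(deltas, function(delta) {
    mean(vapply(1:4, function(s) {
      score_experiment(make_bump_experiment(delta, seed = 100 + s))$score
    }, 0))
  }, 0)
  expect_true(all(diff(means) > 0))
})
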