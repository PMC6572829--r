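test_that("weighted_pearson reproduces the hand-computed weighting", {
  # two combos with per-combination correlations 1 and 0 (combo B pairs
  # scores (-1,0,1) with predictions (1,0,1)), n = 5 and 3:
  # rho_w = (sqrt(4) * 1 + sqrt(2) * 0) / (sqrt(4) + sqrt(2))
  obs <- data.frame(
    combo_id = c(rep("A", 5), rep("B", 3)),
    cell_id = c(sprintf("c%d", 1:5), sprintf("c%d", 1:3)),
    score = c(1, 2, 3, 4, 5, -1, 0, 1))
  pred <- as_pred(obs, c(2, 4, 6, 8, 10, 1, 0, 1))
  # combo B: cor(c(1,0,1), c(-1,0,1)) = 0
  expect_equal(weighted_pearson(pred, obs),
               (sqrt(4) * 1 + sqrt(2) * 0) / (sqrt(4) + sqrt(2)))
  # single combination reduces to plain Pearson
  one <- obs[obs$combo_id == "A", ]
  p1 <- as_pred(one, c(5, 1, 4, 2, 6))
  expect_equal(weighted_pearson(p1, one), cor(p1$prediction, one$score))
  # perfect predictions
  expect_equal(weighted_pearson(as_pred(obs, obs$score), obs), 1)
})

test_that("weighted_pearson excludes degenerate combinations with warning", {
  obs <- data.frame(combo_id = c("A", "A", "A", "B", "B"),
                    cell_id = c("c1", "c2", "c3", "c1", "c2"),
                    score = c(1, 2, 3, 5, 5))
  pred <- as_pred(obs, c(1, 2, 3, 1, 2))
  expect_warning(r <- weighted_pearson(pred, obs), "excluded")
  expect_equal(r, 1)
  expect_error(weighted_pearson(as_pred(obs, 1:5)[1:3, ],
                                obs[c(1, 2, 4), ]), "must exist")
})

test_that("rho_w is invariant to positive affine rescaling", {
  obs <- make_obs_fixture(n_combos = 10, n_cells = 8, seed = 41)
  set.seed(42)
  pred <- as_pred(obs, obs$score + rnorm(nrow(obs), 0, 10))
  r0 <- weighted_pearson(pred, obs)
  pred2 <- pred; pred2$prediction <- 3.7 * pred$prediction + 12
  expect_equal(weighted_pearson(pred2, obs), r0, tolerance = 1e-12)
})

test_that("sc1_tiebreak restricts to combinations with a synergistic cell", {
  obs <- data.frame(
    combo_id = rep(c("A", "B", "C"), each = 4),
    cell_id = rep(sprintf("c%d", 1:4), 3),
    score = c(25, 1, 3, 2,  5, 1, 3, 2,  -4, 1, 3, 2))
  set.seed(43)
  pred <- as_pred(obs, obs$score + rnorm(12, 0, 2))
  r <- sc1_tiebreak(pred, obs)
  onlyA <- obs[obs$combo_id == "A", ]
  expect_equal(r, weighted_pearson(pred[pred$combo_id == "A", ], onlyA))
  # all combos qualify -> equals the primary metric
  obs2 <- obs; obs2$score[c(5, 9)] <- 30
  expect_equal(sc1_tiebreak(pred, obs2), weighted_pearson(pred, obs2))
  # none qualifies -> undefined
  obs3 <- obs; obs3$score[1] <- 10
  expect_warning(r3 <- sc1_tiebreak(pred, obs3), "no combination")
  expect_true(is.na(r3))
})

test_that("sc2_primary matches the brute-force nested-RSS oracle", {
  obs <- make_obs_fixture(n_combos = 20, n_cells = 12, seed = 44)
  set.seed(45)
  x <- rbinom(nrow(obs), 1, 0.3)
  r <- sc2_primary(as_pred(obs, x), obs)
  expect_lt(abs(r$p - anova_oracle_p(obs, x)), 1e-8)
  # direction: an indicator of truly high synergy gives large positive SA
  obs2 <- make_obs_fixture(n_combos = 20, n_cells = 12, seed = 46)
  x2 <- as.integer(obs2$score >= 20)
  r2 <- sc2_primary(as_pred(obs2, x2), obs2)
  expect_gt(r2$SA, 10)
  expect_lt(abs(r2$p - anova_oracle_p(obs2, x2)), 1e-8)
  # inverting the predictions flips the sign
  r3 <- sc2_primary(as_pred(obs2, 1L - x2), obs2)
  expect_lt(r3$SA, 0)
  expect_error(sc2_primary(as_pred(obs2, rep(1L, nrow(obs2))), obs2),
               "both prediction classes")
  expect_error(sc2_primary(as_pred(obs2, x2 + 1L), obs2), "binary")
})

test_that("balanced_accuracy follows the confusion-matrix arithmetic", {
  # TP=3, FN=1, TN=2, FP=2 -> (0.75 + 0.5)/2 = 0.625
  truth <- c(1, 1, 1, 1, 0, 0, 0, 0)
  pred <- c(1, 1, 1, 0, 0, 0, 1, 1)
  expect_equal(balanced_accuracy(pred, truth), 0.625)
  expect_equal(balanced_accuracy(truth, truth), 1)
  expect_equal(balanced_accuracy(rep(1, 8), truth), 0.5)
  expect_warning(r <- balanced_accuracy(c(1, 0), c(1, 1)), "absent")
  expect_true(is.na(r))
  expect_error(balanced_accuracy(c(1, 2), c(1, 0)), "binary")
})

test_that("paired bootstrap gives K = 0 for the best team and its copies", {
  obs <- make_obs_fixture(n_combos = 10, n_cells = 10, seed = 47)
  teams <- simulate_teams(obs, 3, skill = c(0.9, 0.9, 0.2), seed = 48)
  teams[[2]] <- teams[[1]]  # identical to the best
  names(teams) <- c("best", "copy", "weak")
  res <- bootstrap_bayes_factor(teams, obs, "SC1", iters = 100, seed = 1)
  expect_equal(res$K[res$team == "best"], 0)
  expect_equal(res$K[res$team == "copy"], 0)
  expect_gt(res$K[res$team == "weak"], 5)
  boot <- attr(res, "bootstrap")
  expect_equal(dim(boot), c(3, 100))
  # paired: identical teams have identical bootstrap trajectories
  expect_equal(boot["best", ], boot["copy", ])
})

test_that("K grows with injected prediction degradation", {
  obs <- make_obs_fixture(n_combos = 10, n_cells = 10, seed = 49)
  base <- simulate_teams(obs, 1, skill = 0.95, seed = 50)[[1]]
  set.seed(51)
  noisy <- function(sd) {
    p <- base; p$prediction <- p$prediction + rnorm(nrow(p), 0, sd); p
  }
  teams <- list(best = base, n1 = noisy(1), n2 = noisy(3), n3 = noisy(9))
  res <- bootstrap_bayes_factor(teams, obs, "SC1", iters = 300, seed = 2)
  K <- res$K[match(c("n1", "n2", "n3"), res$team)]
  # monotone; the harshest level may saturate at Inf
  expect_lt(K[1], K[2])
  expect_lte(K[2], K[3])
  expect_lt(K[1], K[3])
})

test_that("null_model permutes within cell lines and is reproducible", {
  obs <- make_obs_fixture(n_combos = 12, n_cells = 6, seed = 52)
  n1 <- null_model(obs, "SC1", n_perm = 100, seed = 3)
  n2 <- null_model(obs, "SC1", n_perm = 100, seed = 3)
  expect_identical(n1, n2)
  expect_lt(abs(mean(n1)), 0.15)
  # conservation: a single permutation preserves each cell's multiset
  set.seed(4)
  perm <- obs
  for (cell in unique(obs$cell_id)) {
    idx <- which(obs$cell_id == cell)
    perm$score[idx] <- obs$score[sample(idx)]
  }
  for (cell in unique(obs$cell_id)) {
    expect_equal(sort(perm$score[perm$cell_id == cell]),
                 sort(obs$score[obs$cell_id == cell]))
  }
})

test_that("replicate upper bound behaves like reproducibility", {
  obs <- make_obs_fixture(n_combos = 15, n_cells = 8, seed = 53)
  expect_equal(replicate_upper_bound(obs, obs, "SC1"), 1)
  set.seed(54)
  noisy_rep <- function(sd) {
    r <- obs; r$score <- r$score + rnorm(nrow(r), 0, sd); r
  }
  r1 <- noisy_rep(5); r2 <- noisy_rep(5)
  b_small <- replicate_upper_bound(r1, r2)
  r3 <- noisy_rep(25); r4 <- noisy_rep(25)
  b_big <- replicate_upper_bound(r3, r4)
  expect_gt(b_small, b_big)
  expect_lt(abs(replicate_upper_bound(r1, r2) -
                replicate_upper_bound(r2, r1)), 0.02)
})

test_that("better_than_random applies BH exactly as the step-up oracle", {
  set.seed(55)
  null <- rnorm(1000, 0, 0.1)
  pm <- c(a = 0.5, b = 0.05, c = -0.02, d = 0.3, e = 0.01)
  res <- better_than_random(pm, null, fdr = 0.05)
  expect_equal(res$q, stats::p.adjust(res$p, "BH"))
  expect_equal(res$p[1], 1 / 1001)  # above all nulls
  expect_true(res$pass[res$team == "a"])
  expect_false(res$pass[res$team == "c"])  # at/below the null median
})

test_that("bh_adjust equals the stats oracle on random p-vectors", {
  set.seed(56)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"), tolerance = 1e-12)
  }
})

test_that("combination_predictability applies the class bands", {
  obs <- make_obs_fixture(n_combos = 6, n_cells = 10, seed = 57)
  teams <- simulate_teams(obs, 3, skill = c(0.95, 0.9, 0.85), seed = 58)
  res <- combination_predictability(teams, obs)
  expect_true(all(res$class %in% c("poor", "intermediate", "well")))
  # classes follow the mean rho bands exactly
  expect_equal(res$class[res$mean_rho > 0.5][1], "well")
  rand_teams <- simulate_teams(obs, 3, skill = 0, seed = 59)
  res0 <- combination_predictability(rand_teams, obs)
  expect_true(any(res0$class == "poor"))
  # small combinations are excluded with a warning
  obs2 <- rbind(obs, data.frame(combo_id = "tiny", cell_id = c("x", "y"),
                                score = c(1, 2)))
  teams2 <- lapply(teams, function(t)
    rbind(t[, c("combo_id", "cell_id", "prediction")],
          data.frame(combo_id = "tiny", cell_id = c("x", "y"),
                     prediction = c(1, 2))))
  expect_warning(res2 <- combination_predictability(teams2, obs2),
                 "excluded")
  expect_false("tiny" %in% res2$combo_id)
})
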