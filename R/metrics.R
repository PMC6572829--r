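# Merge a prediction table with observations on (combo_id, cell_id).
merge_pred_obs <- function(pred, obs, pred_col = "prediction") {
  assert_that(all(c("combo_id", "cell_id", pred_col) %in% names(pred)),
              "prediction table needs combo_id, cell_id and prediction")
  assert_that(all(c("combo_id", "cell_id", "score") %in% names(obs)),
              "observation table needs combo_id, cell_id and score")
  m <- merge(pred[, c("combo_id", "cell_id", pred_col)],
             obs[, c("combo_id", "cell_id", "score")],
             by = c("combo_id", "cell_id"))
  assert_that(nrow(m) == nrow(pred),
              "every predicted (combo, cell) must exist in the observations")
  names(m)[names(m) == pred_col] <- "prediction"
  m
}

#' Average weighted Pearson correlation (primary SC1 metric)
#'
#' Per-combination Pearson correlations between predicted and observed
#' synergy scores, averaged with weights `sqrt(n_i - 1)` where `n_i` is the
#' number of cell lines of combination i:
#' \deqn{\rho_w = \sum_i \sqrt{n_i - 1}\,\rho_i / \sum_i \sqrt{n_i - 1}}
#' Combinations with fewer than 2 cells or zero variance on either side are
#' excluded from both sums with a warning.
#'
#' @param pred data.frame `combo_id`, `cell_id`, `prediction`.
#' @param obs data.frame `combo_id`, `cell_id`, `score`.
#' @return the weighted correlation (scalar).
#' @export
weighted_pearson <- function(pred, obs) {
  m <- merge_pred_obs(pred, obs)
  num <- 0; den <- 0; dropped <- character(0)
  for (combo in unique(m$combo_id)) {
    sub <- m[m$combo_id == combo, ]
    n <- nrow(sub)
    if (n < 2 || stats::sd(sub$prediction) == 0 || stats::sd(sub$score) == 0) {
      dropped <- c(dropped, combo)
      next
    }
    rho <- stats::cor(sub$prediction, sub$score)
    w <- sqrt(n - 1)
    num <- num + w * rho
    den <- den + w
  }
  if (length(dropped))
    warning(sprintf("excluded %d combination(s) with undefined correlation: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  assert_that(den > 0, "no combination with a defined correlation")
  num / den
}

#' SC1 tie-break metric
#'
#' The weighted Pearson of [weighted_pearson()] restricted to combinations
#' with at least one cell line whose observed synergy score is >= 20.
#'
#' @inheritParams weighted_pearson
#' @param threshold synergy cutoff defining the qualifying subset.
#' @return the restricted weighted correlation, or `NA` (with a warning)
#'   when no combination qualifies.
#' @export
sc1_tiebreak <- function(pred, obs, threshold = 20) {
  qual <- unique(obs$combo_id[obs$score >= threshold])
  qual <- intersect(qual, unique(pred$combo_id))
  if (length(qual) == 0) {
    warning("no combination has a cell with synergy score >= threshold")
    return(NA_real_)
  }
  weighted_pearson(pred[pred$combo_id %in% qual, , drop = FALSE],
                   obs[obs$combo_id %in% qual, , drop = FALSE])
}

#' Signed sequential three-way ANOVA score (primary SC2 metric)
#'
#' Fits the observed synergy on drug combination, then cell line, then the
#' team's binary prediction, with the intercept fixed at zero
#' (`y ~ 0 + dc + cl + x`), and takes the type-1 (sequential) F-test
#' p-value of the prediction term entered last. The score is
#' `SA = -sgn(beta_x) * log10(p)`: positive when predicted-synergy
#' experiments have higher observed synergy. P-values are floored at
#' 1e-300.
#'
#' @param pred data.frame `combo_id`, `cell_id`, `prediction` with binary
#'   0/1 predictions.
#' @param obs data.frame `combo_id`, `cell_id`, `score`.
#' @return list with `SA`, `p`, `beta` (prediction coefficient).
#' @export
sc2_primary <- function(pred, obs) {
  m <- merge_pred_obs(pred, obs)
  assert_that(all(m$prediction %in% c(0, 1)), "predictions must be binary 0/1")
  assert_that(length(unique(m$prediction)) == 2,
              "both prediction classes must be present")
  assert_that(length(unique(m$combo_id)) >= 2 &&
              length(unique(m$cell_id)) >= 2,
              "design needs >= 2 combinations and >= 2 cell lines")
  df <- data.frame(y = m$score,
                   dc = factor(m$combo_id),
                   cl = factor(m$cell_id),
                   x = m$prediction)
  fit0 <- stats::lm(y ~ 0 + dc + cl, data = df)
  fit1 <- stats::lm(y ~ 0 + dc + cl + x, data = df)
  rss0 <- sum(stats::residuals(fit0)^2)
  rss1 <- sum(stats::residuals(fit1)^2)
  df1 <- stats::df.residual(fit1)
  beta <- stats::coef(fit1)[["x"]]
  Fstat <- (rss0 - rss1) / (rss1 / df1)
  p <- max(stats::pf(Fstat, 1, df1, lower.tail = FALSE), 1e-300)
  list(SA = -sign(beta) * log10(p), p = p, beta = beta)
}

#' Balanced accuracy (SC2 tie-break metric)
#'
#' Mean of sensitivity and specificity of binary predictions against truth
#' labels derived by thresholding observed synergy at 20.
#'
#' @param pred binary 0/1 predictions.
#' @param truth binary 0/1 truth labels.
#' @return balanced accuracy in \[0, 1\], or `NA` (with warning) when a
#'   truth class is absent.
#' @export
balanced_accuracy <- function(pred, truth) {
  assert_that(length(pred) == length(truth),
              "pred and truth must have equal length")
  assert_that(all(pred %in% c(0, 1)) && all(truth %in% c(0, 1)),
              "pred and truth must be binary 0/1")
  if (length(unique(truth)) < 2) {
    warning("one truth class absent; balanced accuracy undefined")
    return(NA_real_)
  }
  sens <- mean(pred[truth == 1] == 1)
  spec <- mean(pred[truth == 0] == 0)
  (sens + spec) / 2
}

# Evaluate a team's primary metric on a (possibly resampled) index set of
# the merged observation rows.
metric_on_rows <- function(pred, obs, metric, rows = NULL) {
  if (!is.null(rows)) obs <- obs[rows, , drop = FALSE]
  if (metric == "SC1") {
    keys <- paste(obs$combo_id, obs$cell_id, sep = "\r")
    pk <- paste(pred$combo_id, pred$cell_id, sep = "\r")
    p <- pred[match(keys, pk), , drop = FALSE]
    # bootstrapping can duplicate keys; score on the resampled rows directly
    m <- data.frame(combo_id = obs$combo_id, prediction = p$prediction,
                    score = obs$score)
    num <- 0; den <- 0
    for (combo in unique(m$combo_id)) {
      sub <- m[m$combo_id == combo, ]
      n <- nrow(sub)
      if (n < 2 || stats::sd(sub$prediction) == 0 ||
          stats::sd(sub$score) == 0) next
      num <- num + sqrt(n - 1) * stats::cor(sub$prediction, sub$score)
      den <- den + sqrt(n - 1)
    }
    if (den == 0) return(NA_real_)
    num / den
  } else {
    keys <- paste(obs$combo_id, obs$cell_id, sep = "\r")
    pk <- paste(pred$combo_id, pred$cell_id, sep = "\r")
    p <- pred[match(keys, pk), , drop = FALSE]
    p$combo_id <- obs$combo_id; p$cell_id <- obs$cell_id
    res <- tryCatch(sc2_primary(p, obs), error = function(e) NULL)
    if (is.null(res)) NA_real_ else res$SA
  }
}

#' Paired-bootstrap Bayes factors against the best team
#'
#' Scores every team on the full observation set, identifies the best
#' (highest primary metric), then draws `iters` bootstrap resamples of the
#' observations — the same index sets for all teams — and recomputes the
#' primary metric each time. For team T,
#' `K_T = #(pm_T,i < pm_best,i) / #(pm_T,i >= pm_best,i)`
#' (ties count in the denominator; a zero denominator yields `Inf`).
#' Teams with `K_T <= 5` are statistically indistinguishable from the best
#' and are ranked by the tie-break metric.
#'
#' @param team_preds named list of prediction data.frames
#'   (`combo_id`, `cell_id`, `prediction`).
#' @param obs observation data.frame (`combo_id`, `cell_id`, `score`).
#' @param metric `"SC1"` (weighted Pearson) or `"SC2"` (signed ANOVA).
#' @param iters bootstrap iterations (default 1000).
#' @param bf_cutoff Bayes factor tie threshold (default 5).
#' @param seed integer seed.
#' @return data.frame per team: `team`, `pm`, `tiebreak`, `K`, `tied_with_best`,
#'   `rank`; attribute `bootstrap` holds the teams x iters metric matrix.
#' @export
bootstrap_bayes_factor <- function(team_preds, obs, metric = c("SC1", "SC2"),
                                   iters = 1000L, bf_cutoff = 5, seed = 1L) {
  metric <- match.arg(metric)
  assert_that(length(team_preds) >= 2, "need >= 2 teams")
  teams <- names(team_preds) %||% sprintf("team%02d", seq_along(team_preds))
  M <- nrow(obs)
  pm <- vapply(team_preds, metric_on_rows, numeric(1), obs = obs,
               metric = metric)
  tiebreak <- vapply(seq_along(team_preds), function(t) {
    if (metric == "SC1") {
      tryCatch(suppressWarnings(sc1_tiebreak(team_preds[[t]], obs)),
               error = function(e) NA_real_)
    } else {
      p <- merge_pred_obs(team_preds[[t]], obs)
      suppressWarnings(
        balanced_accuracy(p$prediction, as.integer(p$score >= 20)))
    }
  }, numeric(1))

  boot <- matrix(NA_real_, nrow = length(team_preds), ncol = iters,
                 dimnames = list(teams, NULL))
  with_seed(substream_seed(seed, "bootstrap_bf"), {
    for (i in seq_len(iters)) {
      rows <- sample.int(M, M, replace = TRUE)
      for (t in seq_along(team_preds)) {
        boot[t, i] <- metric_on_rows(team_preds[[t]], obs, metric, rows)
      }
    }
  })
  best <- which.max(pm)
  K <- vapply(seq_along(team_preds), function(t) {
    ok <- is.finite(boot[t, ]) & is.finite(boot[best, ])
    lt <- sum(boot[t, ok] < boot[best, ok])
    ge <- sum(boot[t, ok] >= boot[best, ok])
    if (ge == 0) Inf else lt / ge
  }, numeric(1))
  tied <- K <= bf_cutoff
  # rank: primary metric descending; within the best's statistical tie set,
  # the tie-break metric decides
  ord_key <- ifelse(tied, tiebreak, -Inf)
  rank_order <- order(!tied, -ifelse(tied, ord_key, pm), -pm)
  rk <- integer(length(pm)); rk[rank_order] <- seq_along(pm)
  out <- data.frame(team = teams, pm = pm, tiebreak = tiebreak, K = K,
                    tied_with_best = tied, rank = rk,
                    stringsAsFactors = FALSE)
  attr(out, "bootstrap") <- boot
  out
}

#' Permutation null distribution of a primary metric
#'
#' For each permutation, observed synergy values are shuffled within each
#' cell line across combinations; the permuted values are treated as the
#' prediction of the unpermuted observations and the metric recomputed.
#' For SC2 the permuted values are thresholded at 20 to give a binary
#' prediction.
#'
#' @param obs observation data.frame (`combo_id`, `cell_id`, `score`).
#' @param metric `"SC1"` or `"SC2"`.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return numeric vector of null metric values.
#' @export
null_model <- function(obs, metric = c("SC1", "SC2"), n_perm = 1000L,
                       seed = 1L) {
  metric <- match.arg(metric)
  assert_that(n_perm >= 100, "n_perm must be >= 100")
  with_seed(substream_seed(seed, "null_model"), {
    vapply(seq_len(n_perm), function(i) {
      perm <- obs
      for (cell in unique(obs$cell_id)) {
        idx <- which(obs$cell_id == cell)
        perm$score[idx] <- obs$score[sample(idx)]
      }
      pred <- data.frame(combo_id = obs$combo_id, cell_id = obs$cell_id,
                         prediction = if (metric == "SC1") perm$score
                                      else as.integer(perm$score >= 20))
      metric_on_rows(pred, obs, metric)
    }, numeric(1))
  })
}

#' Replicate-based upper bound of a primary metric
#'
#' Uses one replicate measurement to predict the other: the metric achieved
#' is the level of experimental reproducibility, the natural upper bound on
#' prediction performance.
#'
#' @param rep1,rep2 matched synergy tables (`combo_id`, `cell_id`, `score`)
#'   with identical keys.
#' @param metric `"SC1"` or `"SC2"`.
#' @return the metric value of replicate 1 predicting replicate 2.
#' @export
replicate_upper_bound <- function(rep1, rep2, metric = c("SC1", "SC2")) {
  metric <- match.arg(metric)
  assert_that(nrow(rep1) == nrow(rep2), "replicate tables must match")
  assert_that(length(unique(rep1$combo_id)) >= 2,
              "need >= 2 combinations with replicate pairs")
  pred <- data.frame(combo_id = rep1$combo_id, cell_id = rep1$cell_id,
                     prediction = if (metric == "SC1") rep1$score
                                  else as.integer(rep1$score >= 20))
  metric_on_rows(pred, rep2, metric)
}

#' Better-than-random calls at a false discovery rate
#'
#' Per-team empirical p-value against a permutation null
#' (`p = (1 + #null >= pm) / (1 + n_perm)`, the add-one estimator),
#' Benjamini-Hochberg adjusted, flagged significant at the given FDR.
#'
#' @param team_scores data.frame with `team` and `pm` (e.g. the output of
#'   [bootstrap_bayes_factor()]), or a named numeric vector of metrics.
#' @param null numeric vector from [null_model()].
#' @param fdr false discovery rate (default 0.05).
#' @return data.frame `team`, `pm`, `p`, `q`, `pass`.
#' @export
better_than_random <- function(team_scores, null, fdr = 0.05) {
  if (is.numeric(team_scores)) {
    team_scores <- data.frame(
      team = names(team_scores) %||% seq_along(team_scores),
      pm = unname(team_scores), stringsAsFactors = FALSE)
  }
  null <- null[is.finite(null)]
  p <- vapply(team_scores$pm,
              function(x) (1 + sum(null >= x)) / (1 + length(null)),
              numeric(1))
  q <- bh_adjust(p)
  data.frame(team = team_scores$team, pm = team_scores$pm, p = p, q = q,
             pass = q <= fdr, stringsAsFactors = FALSE)
}

#' Per-combination predictability classes
#'
#' Averages, over teams, the per-combination Pearson correlation between
#' predictions and observations, and classes each combination as `poor`
#' (mean correlation strictly between -0.25 and 0.25, the range of a random
#' predictor), `well` (above 0.5), else `intermediate`. Combinations with
#' fewer than 3 cells are excluded with a warning.
#'
#' @param team_preds list of prediction data.frames.
#' @param obs observation data.frame.
#' @return data.frame `combo_id`, `mean_rho`, `class`.
#' @export
combination_predictability <- function(team_preds, obs) {
  assert_that(length(team_preds) >= 2, "need >= 2 teams")
  combos <- unique(obs$combo_id)
  out <- NULL; small <- character(0)
  for (combo in combos) {
    o <- obs[obs$combo_id == combo, ]
    if (nrow(o) < 3) { small <- c(small, combo); next }
    rhos <- vapply(team_preds, function(pred) {
      p <- merge(pred, o, by = c("combo_id", "cell_id"))
      if (nrow(p) < 3 || stats::sd(p$prediction) == 0 ||
          stats::sd(p$score) == 0) return(NA_real_)
      stats::cor(p$prediction, p$score)
    }, numeric(1))
    mr <- mean(rhos, na.rm = TRUE)
    cls <- if (is.nan(mr)) NA_character_
           else if (mr > 0.5) "well"
           else if (mr > -0.25 && mr < 0.25) "poor"
           else "intermediate"
    out <- rbind(out, data.frame(combo_id = combo, mean_rho = mr,
                                 class = cls, stringsAsFactors = FALSE))
  }
  if (length(small))
    warning(sprintf("excluded %d combination(s) with < 3 cells",
                    length(small)))
  out
}
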