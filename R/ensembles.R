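#' Build a teams x experiments prediction matrix
#'
#' Aligns binary prediction tables on their (combination, cell) keys,
#' keeping only experiments predicted by all teams (complete cases), and
#' recodes predictions to \{-1, +1\}.
#'
#' @param team_preds named list of data.frames with `combo_id`, `cell_id`
#'   and a binary prediction column (`prediction_binary` if present, else
#'   `prediction`).
#' @return matrix of -1/+1 with teams as rows; column names are the
#'   experiment keys `combo_id:cell_id`.
#' @export
prediction_matrix <- function(team_preds) {
  assert_that(length(team_preds) >= 3, "SML requires >= 3 teams")
  col <- function(df) {
    if ("prediction_binary" %in% names(df)) df$prediction_binary
    else df$prediction
  }
  keys <- lapply(team_preds, function(df)
    paste(df$combo_id, df$cell_id, sep = ":"))
  common <- Reduce(intersect, keys)
  assert_that(length(common) > 0, "teams share no experiments")
  mat <- t(vapply(seq_along(team_preds), function(t) {
    v <- col(team_preds[[t]])[match(common, keys[[t]])]
    assert_that(all(v %in% c(0, 1)), "predictions must be binary 0/1")
    2 * v - 1
  }, numeric(length(common))))
  rownames(mat) <- names(team_preds) %||%
    sprintf("team%02d", seq_along(team_preds))
  colnames(mat) <- common
  mat
}

#' Spectral estimate of per-team performance without labels
#'
#' Estimates each binary classifier's balanced accuracy, up to positive
#' scale, from the spectrum of the teams x teams covariance of the
#' \{-1, +1\} recoded predictions. Under conditional independence the
#' off-diagonal covariance is rank one with factor proportional to
#' `2 * BAC - 1`; the leading eigenvector is extracted with the diagonal
#' iteratively re-imputed (up to 100 iterations, convergence 1e-8), and the
#' global sign fixed so that the majority of entries are positive.
#'
#' @param preds teams x experiments matrix in \{-1, +1\} (or 0/1, recoded),
#'   e.g. from [prediction_matrix()] or [simulate_classifier_teams()].
#' @return numeric vector `v` of per-team performance estimates (named by
#'   team); constant teams are excluded with a warning and get `NA`.
#' @export
sml_estimate <- function(preds) {
  preds <- as.matrix(preds)
  if (all(preds %in% c(0, 1))) preds <- 2 * preds - 1
  assert_that(all(preds %in% c(-1, 1)), "predictions must be binary")
  teams <- rownames(preds) %||% sprintf("team%02d", seq_len(nrow(preds)))
  keep <- apply(preds, 1, function(r) stats::sd(r) > 0)
  if (any(!keep))
    warning(sprintf("excluded %d constant team(s)", sum(!keep)))
  assert_that(sum(keep) >= 3, "need >= 3 non-constant teams")
  Q <- stats::cov(t(preds[keep, , drop = FALSE]))
  n <- nrow(Q)
  R <- Q
  diag(R) <- 0
  # initial diagonal: largest off-diagonal magnitude per row
  diag(R) <- apply(abs(R), 1, max)
  v_old <- rep(0, n)
  for (it in seq_len(100)) {
    eig <- eigen(R, symmetric = TRUE)
    lam <- eig$values[1]
    u <- eig$vectors[, 1]
    diag(R) <- lam * u^2
    v_new <- sqrt(max(lam, 0)) * u
    if (sqrt(sum((v_new - v_old)^2)) < 1e-8) { v_old <- v_new; break }
    v_old <- v_new
  }
  v <- v_old
  if (sum(v > 0) < sum(v < 0)) v <- -v
  out <- rep(NA_real_, length(keep))
  out[keep] <- v
  names(out) <- teams
  out
}

#' Spectral meta-learner ensemble prediction
#'
#' Weighted vote of the teams' \{-1, +1\} predictions with the weights
#' estimated by [sml_estimate()]; per experiment the ensemble predicts
#' `sign(sum_i v_i x_i)` mapped back to \{0, 1\} (an exactly zero sum
#' predicts 0).
#'
#' @inheritParams sml_estimate
#' @return integer vector of 0/1 ensemble predictions (named by experiment
#'   key when available).
#' @export
sml_ensemble <- function(preds) {
  preds <- as.matrix(preds)
  if (all(preds %in% c(0, 1))) preds <- 2 * preds - 1
  v <- sml_estimate(preds)
  keep <- !is.na(v)
  s <- as.numeric(v[keep] %*% preds[keep, , drop = FALSE])
  out <- as.integer(s > 0)
  names(out) <- colnames(preds)
  out
}

#' Random equal-weight aggregation baseline
#'
#' Repeatedly draws `n` teams uniformly without replacement, majority-votes
#' their binary predictions (ties predict 0), and scores balanced accuracy
#' against the truth; reports the mean and standard error over repeats.
#'
#' @inheritParams sml_estimate
#' @param n number of teams per draw (1 <= n <= number of teams).
#' @param truth 0/1 truth labels, one per experiment column.
#' @param repeats number of random draws (default 10).
#' @param seed integer seed.
#' @return list with `mean_bac`, `se`, and the per-repeat `bac` vector.
#' @export
random_aggregation <- function(preds, n, truth, repeats = 10L, seed = 1L) {
  preds <- as.matrix(preds)
  if (all(preds %in% c(0, 1))) preds <- 2 * preds - 1
  assert_that(n >= 1, "n must be >= 1")
  assert_that(n <= nrow(preds), "n must not exceed the number of teams")
  assert_that(length(truth) == ncol(preds),
              "truth must have one label per experiment")
  with_seed(substream_seed(seed, "random_aggregation"), {
    bac <- vapply(seq_len(repeats), function(r) {
      idx <- sample.int(nrow(preds), n)
      s <- colSums(preds[idx, , drop = FALSE])
      vote <- as.integer(s > 0)
      suppressWarnings(balanced_accuracy(vote, truth))
    }, numeric(1))
    list(mean_bac = mean(bac, na.rm = TRUE),
         se = stats::sd(bac, na.rm = TRUE) / sqrt(sum(is.finite(bac))),
         bac = bac)
  })
}
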